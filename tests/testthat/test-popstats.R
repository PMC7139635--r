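# hand-built homozygous lines for exact counting checks
line_from_mosaic <- function(mosaic) {
  structure(list(h1 = mosaic, h2 = mosaic), class = "individual")
}

toy_pop <- function(lines, genome) {
  structure(list(lines = lines,
                 spec = scheme_spec("dh_series", n_lines = length(lines)),
                 genome = genome, seed = 0L), class = "population")
}

test_that("breakpoint counting sums visible junctions over chromosomes", {
  genome <- toy_genome(2, 100e6)
  pure <- founder_individual(genome, 1L)
  expect_equal(count_breakpoints(pure), 0L)

  mosaic <- list("1" = list(end = c(30e6, 70e6, 100e6), founder = c(1L, 2L, 1L)),
                 "2" = list(end = 100e6, founder = 1L))
  expect_equal(count_breakpoints(line_from_mosaic(mosaic)), 2L)
})

test_that("per-line fragment length is genome length over events, in Mb", {
  genome <- toy_genome(2, 100e6)  # 200 Mb total
  mosaic <- list("1" = list(end = c(50e6, 100e6), founder = c(1L, 2L)),
                 "2" = list(end = c(25e6, 100e6), founder = c(2L, 1L)))
  ind <- line_from_mosaic(mosaic)
  expect_equal(per_line_fragment_length(ind, genome), 200 / 2)
  expect_true(is.na(per_line_fragment_length(founder_individual(genome, 1L),
                                             genome)))
  # doubling breakpoints halves the value
  mosaic4 <- list("1" = list(end = c(20e6, 40e6, 60e6, 80e6, 100e6),
                             founder = c(1L, 2L, 1L, 2L, 1L)),
                  "2" = mosaic[["2"]])
  expect_equal(per_line_fragment_length(line_from_mosaic(mosaic4), genome),
               200 / 5)
})

test_that("bin maps pool distinct window-snapped breakpoints", {
  genome <- build_genome("1", 100e6)
  l1 <- line_from_mosaic(list("1" = list(end = c(25.05e6, 50.07e6, 100e6),
                                         founder = c(1L, 2L, 1L))))
  pop1 <- toy_pop(list(l1), genome)
  bins <- build_bin_map(pop1, 125e3)
  expect_equal(nrow(bins), 3L)  # 2 breakpoints -> 3 bins
  expect_equal(bins$start[1], 0)
  expect_equal(bins$end[3], 100e6)

  # a second line with identical breakpoints adds no bins
  pop2 <- toy_pop(list(l1, l1), genome)
  expect_equal(nrow(build_bin_map(pop2, 125e3)), 3L)

  # breakpoints in the same window collapse to one boundary
  l2 <- line_from_mosaic(list("1" = list(end = c(25.06e6, 100e6),
                                         founder = c(2L, 1L))))
  pop3 <- toy_pop(list(l1, l2), genome)
  expect_equal(nrow(build_bin_map(pop3, 125e3)), 3L)
})

test_that("bin count identity: bins - chromosomes = distinct breakpoint windows", {
  mp <- default_engine()
  pop <- run_dh_series(scheme_spec("dh_series", n_lines = 40), mp, seed = 7)
  bins <- build_bin_map(pop, 125e3)
  distinct <- 0L
  for (ci in seq_len(nrow(pop$genome))) {
    bp <- unlist(lapply(pop$lines, function(l) {
      e <- line_mosaic(l)[[ci]]$end
      e[-length(e)]
    }))
    snapped <- unique(floor(bp / 125e3) * 125e3)
    distinct <- distinct + length(snapped[snapped > 0])
  }
  expect_equal(nrow(bins) - nrow(pop$genome), distinct)
})

test_that("bin counts never decrease as lines are added", {
  mp <- default_engine()
  pop <- run_dh_series(scheme_spec("dh_series", n_lines = 30), mp, seed = 8)
  counts <- vapply(c(5L, 15L, 30L), function(n) {
    sub <- pop
    sub$lines <- pop$lines[seq_len(n)]
    nrow(build_bin_map(sub, 125e3))
  }, integer(1))
  expect_true(all(diff(counts) >= 0))
})

test_that("pooled fragment lengths sum to the genome length", {
  genome <- build_genome("1", 100e6)
  l1 <- line_from_mosaic(list("1" = list(end = c(25e6, 50e6, 100e6),
                                         founder = c(1L, 2L, 1L))))
  bins <- build_bin_map(toy_pop(list(l1), genome), 125e3)
  st <- pooled_fragment_stats(bins)
  expect_equal(st$n_bins, 3L)
  expect_equal(st$median, 25)
  expect_equal(sum(bins$end - bins$start), total_length(genome))

  # no breakpoints anywhere: one bin per chromosome
  g2 <- toy_genome(2, 80e6)
  pure_pop <- toy_pop(list(founder_individual(g2, 1L)), g2)
  st2 <- pooled_fragment_stats(build_bin_map(pure_pop, 125e3))
  expect_equal(st2$n_bins, 2L)
  expect_equal(st2$mean, 80)

  mp <- default_engine()
  pop <- run_dh_series(scheme_spec("dh_series", n_lines = 50), mp, seed = 9)
  bins_full <- build_bin_map(pop, 125e3)
  expect_equal(sum(bins_full$end - bins_full$start),
               total_length(pop$genome))
})

test_that("population summaries are complete and reproducible", {
  mp <- default_engine()
  spec <- scheme_spec("dh_series", n_lines = 30)
  s1 <- summarize_population(run_dh_series(spec, mp, seed = 4))
  s2 <- summarize_population(run_dh_series(spec, mp, seed = 4))
  expect_identical(s1, s2)
  expect_equal(s1$mean_events, mean(s1$events))
  expect_equal(s1$n_lines, 30L)

  empty <- structure(list(lines = list(), spec = spec,
                          genome = maize_genome(), seed = 1L),
                     class = "population")
  expect_error(summarize_population(empty), "empty")
})

test_that("pooled fragment medians shrink from F1-DH to F6-DH", {
  mp <- default_engine()
  s1 <- summarize_population(
    run_dh_series(scheme_spec("dh_series", dh_generation = 1, n_lines = 200),
                  mp, seed = 10))
  s6 <- summarize_population(
    run_dh_series(scheme_spec("dh_series", dh_generation = 6, n_lines = 200),
                  mp, seed = 10))
  expect_lt(s1$pooled_median_mb, 1)      # sub-Mb pooled fragments
  expect_lt(s6$pooled_median_mb, s1$pooled_median_mb)
  expect_gt(s6$bin_count, s1$bin_count)
})
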