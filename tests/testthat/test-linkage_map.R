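make_small_dh_pop <- local({
  cache <- NULL
  function() {
    if (is.null(cache)) {
      genome <- toy_genome(2, 60e6)
      mp <- meiosis_params(uniform_map(genome, 1e6))
      cache <<- list(
        pop = run_dh_series(scheme_spec("dh_series", n_lines = 100),
                            mp, seed = 21),
        genome = genome)
    }
    cache
  }
})

test_that("genotype matrices sample founder labels at window midpoints", {
  fix <- make_small_dh_pop()
  grid <- make_window_grid(fix$genome, 5e6)
  gm <- genotype_matrix(fix$pop, grid)
  expect_equal(dim(gm$geno), c(100L, nrow(grid)))
  expect_false(anyNA(gm$geno))
  expect_true(all(gm$geno %in% 1:2))

  # a pure line genotypes as all-founder
  genome <- fix$genome
  pure_pop <- structure(list(lines = list(founder_individual(genome, 2L)),
                             spec = scheme_spec("dh_series", n_lines = 1),
                             genome = genome, seed = 0L),
                        class = "population")
  gp <- genotype_matrix(pure_pop, grid)
  expect_true(all(gp$geno == 2L))
})

test_that("adjacent recombination fractions count genotype flips", {
  geno <- rbind(c(1L, 1L, 2L),
                c(1L, 2L, 2L),
                c(2L, 2L, 2L),
                c(1L, 1L, 1L))
  gm <- structure(list(
    markers = data.frame(chrom = "1", pos = c(1e6, 2e6, 3e6)),
    geno = geno, window_size = 1e6), class = "genotype_matrix")
  rf <- adjacent_recfrac(gm)
  expect_equal(rf$r, c(1 / 4, 1 / 4))

  same <- gm
  same$geno <- matrix(1L, 4, 3)
  expect_equal(adjacent_recfrac(same)$r, c(0, 0))

  one_marker <- gm
  one_marker$markers <- data.frame(chrom = "1", pos = 1e6)
  one_marker$geno <- geno[, 1, drop = FALSE]
  expect_error(adjacent_recfrac(one_marker), "fewer than 2")
})

test_that("summed interval r equals mean per-line flips (counting identity)", {
  fix <- make_small_dh_pop()
  gm <- genotype_matrix(fix$pop, make_window_grid(fix$genome, 1e6))
  rf <- adjacent_recfrac(gm)
  flips <- 0L
  for (ch in unique(gm$markers$chrom)) {
    g <- gm$geno[, gm$markers$chrom == ch, drop = FALSE]
    flips <- flips + sum(g[, -1, drop = FALSE] != g[, -ncol(g), drop = FALSE])
  }
  expect_equal(sum(rf$r), flips / nrow(gm$geno))
})

test_that("the Kosambi map function matches its closed form", {
  expect_equal(kosambi(0), 0)
  expect_equal(kosambi(0.1), 25 * log(1.2 / 0.8))
  expect_equal(kosambi(0.1), 10.137, tolerance = 1e-4)
  expect_equal(kosambi(0.25), 25 * log(3))
  expect_equal(kosambi(0.25), 27.465, tolerance = 1e-4)
  expect_warning(out <- kosambi(0.6), "clipped")
  expect_lt(out, Inf)

  # monotone, convex, and above 100 r on (0, 0.5)
  r <- seq(0.01, 0.49, by = 0.01)
  d <- kosambi(r)
  expect_true(all(diff(d) > 0))
  expect_true(all(diff(diff(d)) > 0))
  expect_true(all(d > 100 * r))
})

test_that("the RIL correction inverts the selfing relation exactly", {
  r <- seq(0, 0.45, by = 0.05)
  R <- 2 * r / (1 + 2 * r)
  expect_equal(ril_correct(R), r, tolerance = 1e-12)
  expect_equal(ril_correct(0.2), 0.125)
  expect_equal(kosambi(ril_correct(0.2)), 12.77, tolerance = 1e-3)
  # corrected r never exceeds the observed fraction
  expect_true(all(ril_correct(R) <= R))
})

test_that("linkage maps accumulate Kosambi distances along physical order", {
  fix <- make_small_dh_pop()
  gm <- genotype_matrix(fix$pop, make_window_grid(fix$genome, 2e6))
  map <- build_linkage_map(gm, "DH")
  expect_s3_class(map, "linkage_map")
  for (ch in unique(map$chrom)) {
    cm <- map$cM[map$chrom == ch]
    expect_equal(cm[1], 0)
    expect_true(all(diff(cm) >= 0))
  }

  # all-identical genotypes give a flat map
  flat <- gm
  flat$geno <- matrix(1L, nrow(gm$geno), ncol(gm$geno))
  expect_true(all(build_linkage_map(flat, "DH")$cM == 0))

  # RIL treatment shrinks every interval relative to naive DH treatment
  ril_map <- build_linkage_map(gm, "RIL")
  expect_true(all(ril_map$cM <= map$cM + 1e-9))
})

test_that("map correlation is 1 for affine self-comparisons", {
  fix <- make_small_dh_pop()
  gm <- genotype_matrix(fix$pop, make_window_grid(fix$genome, 2e6))
  map <- build_linkage_map(gm, "DH")
  expect_equal(map_correlation(map, map), 1)
  scaled <- map
  scaled$cM <- 3 * scaled$cM + 5
  expect_equal(map_correlation(map, scaled), 1)
})

test_that("independent replicates of one scheme give near-identical maps", {
  fix <- make_small_dh_pop()
  genome <- fix$genome
  mp <- meiosis_params(uniform_map(genome, 1e6))
  grid <- make_window_grid(genome, 5e6)
  cors <- vapply(1:3, function(s) {
    pa <- run_dh_series(scheme_spec("dh_series", n_lines = 150), mp,
                        seed = 2 * s)
    pb <- run_dh_series(scheme_spec("dh_series", n_lines = 150), mp,
                        seed = 2 * s + 1)
    map_correlation(build_linkage_map(genotype_matrix(pa, grid), "DH"),
                    build_linkage_map(genotype_matrix(pb, grid), "DH"))
  }, numeric(1))
  expect_true(all(cors > 0.95))
})

test_that("genotype matrices and linkage maps round-trip through files", {
  fix <- make_small_dh_pop()
  gm <- genotype_matrix(fix$pop, make_window_grid(fix$genome, 5e6))
  path <- withr::local_tempfile(fileext = ".csv")
  write_genotype_matrix(gm, path)
  back <- read_genotype_matrix(path)
  expect_equal(back$geno, gm$geno)
  expect_equal(back$markers$pos, gm$markers$pos)
  expect_equal(back$markers$chrom, gm$markers$chrom)

  map <- build_linkage_map(gm, "DH")
  mpath <- withr::local_tempfile(fileext = ".tsv")
  write_linkage_map(map, mpath)
  tab <- utils::read.table(mpath, sep = "\t")
  expect_equal(nrow(tab), nrow(map))
  expect_equal(tab$V3, map$cM, tolerance = 1e-6)

  bad <- withr::local_tempfile(fileext = ".csv")
  writeLines(c("x,y", "1,2"), bad)
  expect_error(read_genotype_matrix(bad), "malformed")
})
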