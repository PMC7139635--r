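#' Breeding-scheme specification
#'
#' Describes one of the three population-construction programs:
#' * `"dh_series"` — biparental cross, single-seed-descent selfing to
#'   generation `dh_generation`, then DH induction (`dh_generation = 1`
#'   induces the F1 plant, giving an F1-DH population).
#' * `"ril"` — biparental cross followed by `selfing_generations` rounds of
#'   single seed descent (default 6).
#' * `"magic"` — `n_parents` in {8, 16, 32} founders combined through a
#'   funnel of log2(n_parents) intercross generations (per-line random
#'   founder permutation), completed either by DH induction at the funnel's
#'   final generation (`magic_method = "dh"`: F3/F4/F5 for 8/16/32 parents)
#'   or by `magic_selfing` further generations of single-seed selfing
#'   (`magic_method = "cs"`, default 5 generations).
#'
#' @param scheme One of `"dh_series"`, `"ril"`, `"magic"`.
#' @param n_lines Population size (default 200).
#' @param dh_generation Generation of the plant induced, for `dh_series`.
#' @param selfing_generations Selfing rounds for `ril` (default 6).
#' @param n_parents Number of MAGIC founders, one of 8/16/32 (biparental
#'   schemes use 2).
#' @param magic_method `"dh"` or `"cs"` for `magic`.
#' @param magic_selfing Selfing rounds after the funnel for CS-MAGIC
#'   (default 5).
#' @return Object of class `scheme_spec`.
#' @export
scheme_spec <- function(scheme = c("dh_series", "ril", "magic"),
                        n_lines = 200L,
                        dh_generation = 1L,
                        selfing_generations = 6L,
                        n_parents = 2L,
                        magic_method = c("dh", "cs"),
                        magic_selfing = 5L) {
  scheme <- match.arg(scheme)
  magic_method <- match.arg(magic_method)
  n_lines <- as.integer(n_lines)
  if (n_lines < 1L) stop("'n_lines' must be >= 1")
  if (scheme == "dh_series") {
    if (dh_generation < 1L) stop("'dh_generation' must be >= 1")
    if (n_parents != 2L) stop("the biparental DH series requires n_parents = 2")
  }
  if (scheme == "magic" && !n_parents %in% c(8L, 16L, 32L)) {
    stop("MAGIC requires n_parents in {8, 16, 32}")
  }
  structure(list(scheme = scheme, n_lines = n_lines,
                 dh_generation = as.integer(dh_generation),
                 selfing_generations = as.integer(selfing_generations),
                 n_parents = as.integer(n_parents),
                 magic_method = magic_method,
                 magic_selfing = as.integer(magic_selfing)),
            class = "scheme_spec")
}

# deterministic per-line child seed below 2^31 - 1, so populations are
# reproducible and line-order independent
.line_seed <- function(seed, i) {
  as.integer((as.numeric(seed) %% 2147483647 * 1000003 + i * 7919) %%
               2147483647)
}

.new_population <- function(lines, spec, params, seed) {
  structure(list(lines = lines, spec = spec, genome = params$genome,
                 seed = seed),
            class = "population")
}

#' Simulate a population under a breeding scheme
#'
#' Dispatches to [run_dh_series()], [run_ril()] or [run_magic()]. Each line
#' is simulated independently from a per-line seed stream derived from
#' `seed`, so a population is bit-reproducible from `(spec, seed)`.
#'
#' @param spec A `scheme_spec`.
#' @param params A `meiosis_params`.
#' @param seed Integer master seed.
#' @return An object of class `population`: list with `lines` (list of
#'   `individual`), `spec`, `genome`, `seed`.
#' @examples
#' \donttest{
#' map <- generate_synthetic_map(make_window_grid(maize_genome()), seed = 1)
#' mp <- meiosis_params(map)
#' pop <- sim_population(scheme_spec("dh_series", n_lines = 20), mp, seed = 1)
#' summary(pop)
#' }
#' @export
sim_population <- function(spec, params, seed = 1L) {
  stopifnot(inherits(spec, "scheme_spec"), inherits(params, "meiosis_params"))
  switch(spec$scheme,
         dh_series = run_dh_series(spec, params, seed),
         ril = run_ril(spec, params, seed),
         magic = run_magic(spec, params, seed))
}

#' Simulate an Fk-DH population
#'
#' Per line independently: P1 x P2 gives the F1; `dh_generation - 1`
#' generations of single-seed selfing advance the line to F_t; the F_t plant
#' is then DH-induced.
#'
#' @inheritParams sim_population
#' @return A `population` of fully homozygous lines.
#' @export
run_dh_series <- function(spec, params, seed = 1L) {
  genome <- params$genome
  p1 <- founder_individual(genome, 1L)
  p2 <- founder_individual(genome, 2L)
  f1 <- structure(list(h1 = p1$h1, h2 = p2$h1), class = "individual")
  lines <- vector("list", spec$n_lines)
  for (i in seq_len(spec$n_lines)) {
    set.seed(.line_seed(seed, i))
    ind <- f1
    for (s in seq_len(spec$dh_generation - 1L)) {
      ind <- self_cross(ind, params)
    }
    lines[[i]] <- dh_induce(ind, params)
  }
  .new_population(lines, spec, params, seed)
}

#' Simulate a RIL population by single seed descent
#'
#' Per line: F1 from P1 x P2, then `selfing_generations` rounds of selfing
#' with one offspring retained per generation.
#'
#' @inheritParams sim_population
#' @return A `population`; lines retain residual heterozygosity of about
#'   `2^-selfing_generations` of the genome.
#' @export
run_ril <- function(spec, params, seed = 1L) {
  genome <- params$genome
  p1 <- founder_individual(genome, 1L)
  p2 <- founder_individual(genome, 2L)
  f1 <- structure(list(h1 = p1$h1, h2 = p2$h1), class = "individual")
  lines <- vector("list", spec$n_lines)
  for (i in seq_len(spec$n_lines)) {
    set.seed(.line_seed(seed, i))
    ind <- f1
    for (s in seq_len(spec$selfing_generations)) {
      ind <- self_cross(ind, params)
    }
    lines[[i]] <- ind
  }
  .new_population(lines, spec, params, seed)
}

#' Simulate a MAGIC population
#'
#' Per line: the founders are shuffled and combined pairwise through a funnel
#' — 8 parents: 4 F1s, 2 F2s, 1 F3; 16 parents: to F4; 32 parents: to F5.
#' The funnel product is then DH-induced (`magic_method = "dh"`) or selfed
#' for `magic_selfing` generations by single seed descent
#' (`magic_method = "cs"`).
#'
#' @inheritParams sim_population
#' @return A `population`.
#' @export
run_magic <- function(spec, params, seed = 1L) {
  genome <- params$genome
  founders <- lapply(seq_len(spec$n_parents),
                     function(l) founder_individual(genome, l))
  lines <- vector("list", spec$n_lines)
  for (i in seq_len(spec$n_lines)) {
    set.seed(.line_seed(seed, i))
    layer <- founders[sample.int(spec$n_parents)]
    while (length(layer) > 1L) {
      layer <- lapply(seq_len(length(layer) %/% 2L), function(j) {
        cross(layer[[2L * j - 1L]], layer[[2L * j]], params)
      })
    }
    ind <- layer[[1L]]
    if (spec$magic_method == "dh") {
      lines[[i]] <- dh_induce(ind, params)
    } else {
      for (s in seq_len(spec$magic_selfing)) {
        ind <- self_cross(ind, params)
      }
      lines[[i]] <- ind
    }
  }
  .new_population(lines, spec, params, seed)
}

#' @export
print.population <- function(x, ...) {
  s <- x$spec
  lab <- switch(s$scheme,
                dh_series = sprintf("F%d-DH", s$dh_generation),
                ril = sprintf("RIL (%d selfings)", s$selfing_generations),
                magic = sprintf("%d-parent %s-MAGIC", s$n_parents,
                                toupper(s$magic_method)))
  cat(sprintf("<population> %s, %d lines, seed %d\n",
              lab, s$n_lines, x$seed))
  invisible(x)
}

#' @export
summary.population <- function(object, window_size = 125e3, ...) {
  summarize_population(object, window_size = window_size)
}
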