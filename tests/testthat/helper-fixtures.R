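# shared fixtures: small genomes and maps so engine tests stay fast

toy_genome <- function(n_chrom = 2, len = 200e6) {
  build_genome(as.character(seq_len(n_chrom)), rep(len, n_chrom))
}

# uniform-rate map on a toy genome
uniform_map <- function(genome = toy_genome(), window_size = 1e6) {
  grid <- make_window_grid(genome, window_size)
  map <- generate_synthetic_map(
    grid, synthetic_map_params(zero_fraction = 0, suppression_factor = 1,
                               shape = 1), seed = 1)
  map$rate <- rep(1, nrow(map))
  normalize_map(map)
}

# map with caller-chosen rates on a single-chromosome genome
rate_map <- function(rates, window_size = 1e6) {
  genome <- build_genome("1", length(rates) * window_size)
  map <- uniform_map(genome, window_size)
  map$rate <- rates
  normalize_map(map)
}

toy_params <- function(map = uniform_map(), ...) {
  meiosis_params(map, ...)
}

# default full-scale engine shared across expensive tests
default_engine <- local({
  cache <- NULL
  function() {
    if (is.null(cache)) {
      map <- generate_synthetic_map(
        make_window_grid(maize_genome(), 125e3), synthetic_map_params(),
        seed = 99)
      cache <<- meiosis_params(map)
    }
    cache
  }
})

f1_individual <- function(genome) {
  p1 <- founder_individual(genome, 1L)
  p2 <- founder_individual(genome, 2L)
  structure(list(h1 = p1$h1, h2 = p2$h1), class = "individual")
}
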