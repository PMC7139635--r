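#' Parameters of the synthetic recombination landscape generator
#'
#' The generator emulates the window-level recombination landscape estimated
#' from the intermated B73 x Mo17 (IBM) maize population: per-window rates
#' between 0 and `max_rate` cM with mean `target_mean` cM at 125 kb
#' resolution, strong right skew (hotspot structure), a fraction of cold
#' (zero-rate) windows, and suppressed recombination around the centromere.
#'
#' @param target_mean Target mean window rate in cM (default 3.48).
#' @param max_rate Maximum window rate in cM (default 12.1).
#' @param zero_fraction Proportion of windows forced to rate 0 (default 0.2).
#' @param centromere_span Fraction of each chromosome length, centred at
#'   `centromere_pos`, whose rates are multiplied by `suppression_factor`
#'   (default 0.2).
#' @param suppression_factor Multiplier in (0, 1] applied to centromeric
#'   windows (default 0.1).
#' @param shape Gamma shape parameter of the skewed rate draw; values < 1 give
#'   strong right skew (default 0.8).
#' @param centromere_pos Centromere position as a fraction of chromosome
#'   length (default 0.5, mid-chromosome).
#' @return A list of class `synthetic_map_params`.
#' @export
synthetic_map_params <- function(target_mean = 3.48,
                                 max_rate = 12.1,
                                 zero_fraction = 0.2,
                                 centromere_span = 0.2,
                                 suppression_factor = 0.1,
                                 shape = 0.8,
                                 centromere_pos = 0.5) {
  if (!(target_mean > 0 && target_mean <= max_rate)) {
    stop("'target_mean' must lie in (0, max_rate]")
  }
  if (zero_fraction < 0 || zero_fraction >= 1) {
    stop("'zero_fraction' must lie in [0, 1)")
  }
  if (suppression_factor <= 0 || suppression_factor > 1) {
    stop("'suppression_factor' must lie in (0, 1]")
  }
  if (shape <= 0) stop("'shape' must be positive")
  structure(list(target_mean = target_mean, max_rate = max_rate,
                 zero_fraction = zero_fraction,
                 centromere_span = centromere_span,
                 suppression_factor = suppression_factor,
                 shape = shape, centromere_pos = centromere_pos),
            class = "synthetic_map_params")
}

new_recomb_map <- function(grid, rate) {
  map <- data.frame(chrom = grid$chrom, start = grid$start, end = grid$end,
                    rate = rate, prob = NA_real_, stringsAsFactors = FALSE)
  attr(map, "window_size") <- attr(grid, "window_size")
  attr(map, "genome") <- attr(grid, "genome")
  class(map) <- c("recomb_map", "data.frame")
  normalize_map(map)
}

#' Generate a synthetic IBM-like recombination map
#'
#' Draws per-window rates from a right-skewed (gamma) distribution, zeroes a
#' fraction of windows, applies centromeric suppression, clips to
#' `max_rate`, and linearly rescales so the mean over all windows equals
#' `target_mean` exactly (clip and rescale are iterated to convergence, since
#' rescaling can push rates past the cap). Window probabilities are then
#' normalized per chromosome via [normalize_map()].
#'
#' @param grid A `window_grid`.
#' @param params A `synthetic_map_params` object.
#' @param seed Integer seed; the map is deterministic given `(grid, params,
#'   seed)`.
#' @return A `recomb_map`: data frame with columns `chrom`, `start`, `end`,
#'   `rate` (cM per window) and `prob` (per-chromosome crossover-placement
#'   probability).
#' @examples
#' grid <- make_window_grid(maize_genome(), 125e3)
#' map <- generate_synthetic_map(grid, synthetic_map_params(), seed = 1)
#' mean(map$rate)
#' @export
generate_synthetic_map <- function(grid, params = synthetic_map_params(),
                                   seed = 1L) {
  stopifnot(inherits(grid, "window_grid"), inherits(params, "synthetic_map_params"))
  genome <- attr(grid, "genome")
  set.seed(as.integer(seed))
  n <- nrow(grid)
  rate <- stats::rgamma(n, shape = params$shape,
                        scale = params$target_mean / params$shape)
  if (params$zero_fraction > 0) {
    rate[sample.int(n, size = round(params$zero_fraction * n))] <- 0
  }
  # centromeric suppression: windows overlapping the span around the centromere
  mid <- (grid$start + grid$end) / 2
  len <- genome$length[match(grid$chrom, genome$chrom)]
  cen <- params$centromere_pos * len
  half <- params$centromere_span * len / 2
  in_cen <- abs(mid - cen) <= half
  rate[in_cen] <- rate[in_cen] * params$suppression_factor
  if (all(rate == 0)) stop("all window rates are zero; cannot rescale")
  # clip-then-rescale until the mean hits target_mean within 1e-6 relative
  for (i in 1:100) {
    rate <- pmin(rate, params$max_rate)
    m <- mean(rate)
    if (abs(m - params$target_mean) / params$target_mean < 1e-9) break
    rate <- rate * (params$target_mean / m)
  }
  rate <- pmin(rate, params$max_rate)
  new_recomb_map(grid, rate)
}

#' Normalize window rates into crossover-placement probabilities
#'
#' Divides each window's rate by the summed rate of its chromosome, so that
#' per-chromosome probabilities sum to 1. The absolute cM scale of the rates
#' therefore cancels: rates act as relative placement weights.
#'
#' @param map A `recomb_map` (the `prob` column is recomputed).
#' @return The map with `prob` filled in.
#' @export
normalize_map <- function(map) {
  stopifnot(inherits(map, "recomb_map"))
  if (any(map$rate < 0)) stop("negative window rate")
  tot <- tapply(map$rate, map$chrom, sum)
  if (any(tot == 0)) {
    stop("chromosome with all-zero recombination rate: ",
         names(tot)[tot == 0][1L])
  }
  map$prob <- map$rate / as.numeric(tot[map$chrom])
  map
}

#' @export
print.recomb_map <- function(x, ...) {
  cat(sprintf(
    "<recomb_map> %d windows of %g kb; rate mean %.3f, max %.3f cM\n",
    nrow(x), attr(x, "window_size") / 1e3, mean(x$rate), max(x$rate)))
  invisible(x)
}

#' Read / write a recombination map (BED-like)
#'
#' Four tab-separated columns without header: `chrom`, `start`, `end`,
#' `rate_cM`; 0-based half-open coordinates. Windows must be non-overlapping
#' and in order within each chromosome. On reading, placement probabilities
#' are recomputed with [normalize_map()].
#'
#' @param path File path.
#' @param genome Genome the map is defined on (defaults to the window
#'   extents found in the file).
#' @param map A `recomb_map` (for writing).
#' @return `read_map` returns a `recomb_map`; `write_map` returns `path`
#'   invisibly.
#' @export
read_map <- function(path, genome = NULL) {
  tab <- utils::read.table(path, sep = "\t", header = FALSE,
                           col.names = c("chrom", "start", "end", "rate"),
                           colClasses = c("character", "numeric", "numeric",
                                          "numeric"))
  if (any(tab$start >= tab$end)) {
    bad <- which(tab$start >= tab$end)[1L]
    stop("window with start >= end at line ", bad)
  }
  if (any(tab$rate < 0)) stop("negative rate in map file")
  for (ch in unique(tab$chrom)) {
    rows <- tab[tab$chrom == ch, ]
    if (is.unsorted(rows$start, strictly = TRUE) ||
        any(rows$start[-1L] < rows$end[-nrow(rows)])) {
      stop("overlapping or out-of-order windows on chromosome ", ch)
    }
  }
  if (is.null(genome)) {
    ends <- tapply(tab$end, tab$chrom, max)
    ord <- unique(tab$chrom)
    genome <- build_genome(ord, as.numeric(ends[ord]))
  }
  ws <- max(tab$end - tab$start)
  map <- data.frame(chrom = tab$chrom, start = tab$start, end = tab$end,
                    rate = tab$rate, prob = NA_real_, stringsAsFactors = FALSE)
  attr(map, "window_size") <- ws
  attr(map, "genome") <- genome
  class(map) <- c("recomb_map", "data.frame")
  normalize_map(map)
}

#' @rdname read_map
#' @export
write_map <- function(map, path) {
  stopifnot(inherits(map, "recomb_map"))
  utils::write.table(
    data.frame(map$chrom, sprintf("%.0f", map$start),
               sprintf("%.0f", map$end), sprintf("%.6f", map$rate)),
    path, sep = "\t", quote = FALSE, row.names = FALSE, col.names = FALSE)
  invisible(path)
}
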