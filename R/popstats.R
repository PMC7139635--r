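#' Number of recombination events of a line
#'
#' Sums, over chromosomes, the number of observable breakpoints (junctions
#' between segments of different founder origin) of the line's consensus
#' mosaic. Lines must be homozygous (DH) or consensus-resolved (RIL, via
#' [line_mosaic()]).
#'
#' @param ind An `individual`.
#' @return Integer breakpoint count.
#' @export
count_breakpoints <- function(ind) {
  m <- line_mosaic(ind)
  sum(vapply(m, function(h) length(h$founder) - 1L, integer(1)))
}

#' Per-line recombination fragment length
#'
#' Total physical genome length divided by the line's breakpoint count, in
#' Mb. Undefined (NA) for lines with zero breakpoints.
#'
#' @param ind An `individual`.
#' @param genome The `genome` the line lives on.
#' @return Fragment length in Mb, or `NA` if the line has no breakpoints.
#' @export
per_line_fragment_length <- function(ind, genome) {
  k <- count_breakpoints(ind)
  if (k == 0L) return(NA_real_)
  total_length(genome) / k / 1e6
}

#' Build the recombination-bin map of a population
#'
#' Every line's breakpoints are snapped to the start of their containing
#' window; the distinct snapped positions pooled across lines partition each
#' chromosome into recombination bins — blocks within which no line carries a
#' breakpoint.
#'
#' @param pop A `population`.
#' @param window_size Snapping resolution in bp (default 125 kb).
#' @return Object of class `bin_map`: data frame with columns `chrom`,
#'   `start`, `end`.
#' @export
build_bin_map <- function(pop, window_size = 125e3) {
  stopifnot(inherits(pop, "population"))
  genome <- pop$genome
  per_chrom <- vector("list", nrow(genome))
  for (ci in seq_len(nrow(genome))) {
    bp <- unlist(lapply(pop$lines, function(ind) {
      e <- line_mosaic(ind)[[ci]]$end
      e[-length(e)]
    }))
    snapped <- sort(unique(floor(bp / window_size) * window_size))
    snapped <- snapped[snapped > 0]
    bounds <- c(0, snapped, genome$length[ci])
    per_chrom[[ci]] <- data.frame(chrom = genome$chrom[ci],
                                  start = bounds[-length(bounds)],
                                  end = bounds[-1L],
                                  stringsAsFactors = FALSE)
  }
  bins <- do.call(rbind, per_chrom)
  rownames(bins) <- NULL
  attr(bins, "window_size") <- window_size
  class(bins) <- c("bin_map", "data.frame")
  bins
}

#' Pooled fragment-length statistics of a bin map
#'
#' @param bins A `bin_map`.
#' @return Named list with `mean`, `median`, `sd` of bin lengths in Mb and
#'   `n_bins`.
#' @export
pooled_fragment_stats <- function(bins) {
  stopifnot(inherits(bins, "bin_map"))
  len <- (bins$end - bins$start) / 1e6
  list(mean = mean(len), median = stats::median(len),
       sd = if (length(len) > 1L) stats::sd(len) else 0,
       n_bins = nrow(bins))
}

#' Summarize a simulated population
#'
#' Assembles the per-line event counts (sum of breakpoints over
#' chromosomes), the per-line fragment lengths (genome length / events, Mb),
#' the pooled recombination-bin statistics at the given window resolution,
#' and scheme provenance.
#'
#' @param pop A `population`.
#' @param window_size Bin/marker resolution in bp (default 125 kb).
#' @return Object of class `pop_summary` (a list, JSON-serializable).
#' @export
summarize_population <- function(pop, window_size = 125e3) {
  stopifnot(inherits(pop, "population"))
  if (length(pop$lines) == 0L) stop("empty population")
  events <- vapply(pop$lines, count_breakpoints, integer(1))
  frag <- vapply(pop$lines, per_line_fragment_length, numeric(1),
                 genome = pop$genome)
  bins <- build_bin_map(pop, window_size)
  pooled <- pooled_fragment_stats(bins)
  s <- pop$spec
  structure(list(
    scheme = s$scheme,
    scheme_label = switch(s$scheme,
                          dh_series = sprintf("F%d-DH", s$dh_generation),
                          ril = sprintf("RIL-%dself", s$selfing_generations),
                          magic = sprintf("MAGIC-%dp-%s", s$n_parents,
                                          s$magic_method)),
    n_lines = s$n_lines,
    seed = pop$seed,
    events = as.integer(events),
    mean_events = mean(events),
    sd_events = stats::sd(events),
    median_events = stats::median(events),
    eq2_mean_fragment_mb = mean(frag, na.rm = TRUE),
    bin_count = pooled$n_bins,
    pooled_mean_mb = pooled$mean,
    pooled_median_mb = pooled$median,
    pooled_sd_mb = pooled$sd,
    window_size = window_size
  ), class = "pop_summary")
}

#' @export
print.pop_summary <- function(x, ...) {
  cat(sprintf("<pop_summary> %s, %d lines (seed %d)\n",
              x$scheme_label, x$n_lines, x$seed))
  cat(sprintf("  events/line : mean %.2f, sd %.2f, median %.1f\n",
              x$mean_events, x$sd_events, x$median_events))
  cat(sprintf("  fragment    : %.1f Mb per line (genome/events)\n",
              x$eq2_mean_fragment_mb))
  cat(sprintf("  bins (%g kb): %d; pooled length mean %.2f, median %.2f, sd %.2f Mb\n",
              x$window_size / 1e3, x$bin_count, x$pooled_mean_mb,
              x$pooled_median_mb, x$pooled_sd_mb))
  invisible(x)
}

#' Write a bin map as BED
#'
#' @param bins A `bin_map`.
#' @param path Output path.
#' @export
write_bin_map <- function(bins, path) {
  stopifnot(inherits(bins, "bin_map"))
  utils::write.table(
    data.frame(bins$chrom, sprintf("%.0f", bins$start),
               sprintf("%.0f", bins$end)),
    path, sep = "\t", quote = FALSE, row.names = FALSE, col.names = FALSE)
  invisible(path)
}
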