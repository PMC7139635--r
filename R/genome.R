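#' Build a genome definition
#'
#' A genome is an ordered set of chromosomes with physical lengths in base
#' pairs. All coordinates in the package are 0-based, half-open, in bp.
#'
#' @param chrom Character vector of unique chromosome ids.
#' @param length Numeric vector of chromosome lengths in bp (strictly
#'   positive), parallel to `chrom`.
#' @return An object of class `genome`: a data frame with columns `chrom` and
#'   `length`, and attribute `total_length` (sum of lengths in bp).
#' @examples
#' build_genome("1", 300e6)
#' maize_genome()
#' @export
build_genome <- function(chrom, length) {
  chrom <- as.character(chrom)
  length <- as.numeric(length)
  if (length(chrom) == 0L) {
    stop("genome must contain at least one chromosome")
  }
  if (length(chrom) != base::length(length)) {
    stop("'chrom' and 'length' must have the same length")
  }
  if (anyDuplicated(chrom)) {
    stop("duplicate chromosome id: ", chrom[duplicated(chrom)][1L])
  }
  if (any(!is.finite(length)) || any(length <= 0)) {
    stop("chromosome lengths must be finite and strictly positive")
  }
  g <- data.frame(chrom = chrom, length = length, stringsAsFactors = FALSE)
  attr(g, "total_length") <- sum(length)
  class(g) <- c("genome", "data.frame")
  g
}

#' Default maize-like genome
#'
#' Ten chromosomes approximating the maize B73 reference assembly
#' (total 2,060.2 Mb). Lengths are bundled constants; any analysis can
#' substitute its own table via [build_genome()] or [read_genome()].
#'
#' @return A `genome` object with 10 chromosomes.
#' @export
maize_genome <- function() {
  build_genome(
    chrom = as.character(1:10),
    length = c(301.4, 237.9, 232.2, 242.0, 217.9,
               169.2, 176.8, 175.8, 156.8, 150.2) * 1e6
  )
}

#' Total physical genome length
#'
#' @param genome A `genome` object.
#' @return Total length in bp.
#' @export
total_length <- function(genome) {
  stopifnot(inherits(genome, "genome"))
  attr(genome, "total_length")
}

#' @export
print.genome <- function(x, ...) {
  cat(sprintf("<genome> %d chromosomes, %.1f Mb total\n",
              nrow(x), attr(x, "total_length") / 1e6))
  print.data.frame(x, row.names = FALSE)
  invisible(x)
}

#' Tile a genome into fixed-size windows
#'
#' Each chromosome is partitioned into contiguous half-open windows
#' `[start, end)` of `window_size` bp; the final window of a chromosome may be
#' shorter.
#'
#' @param genome A `genome` object.
#' @param window_size Window width in bp (default 125 kb).
#' @return An object of class `window_grid`: a data frame with columns
#'   `chrom`, `start`, `end`; attributes `window_size` and `genome`.
#' @examples
#' grid <- make_window_grid(maize_genome(), 125e3)
#' nrow(grid)
#' @export
make_window_grid <- function(genome, window_size = 125e3) {
  stopifnot(inherits(genome, "genome"))
  window_size <- as.numeric(window_size)
  if (!is.finite(window_size) || window_size <= 0) {
    stop("'window_size' must be a positive number of bp")
  }
  pieces <- lapply(seq_len(nrow(genome)), function(i) {
    len <- genome$length[i]
    n_win <- ceiling(len / window_size - 1e-12)  # exact multiples: no extra window
    starts <- (seq_len(n_win) - 1) * window_size
    data.frame(chrom = genome$chrom[i],
               start = starts,
               end = pmin(starts + window_size, len),
               stringsAsFactors = FALSE)
  })
  grid <- do.call(rbind, pieces)
  rownames(grid) <- NULL
  attr(grid, "window_size") <- window_size
  attr(grid, "genome") <- genome
  class(grid) <- c("window_grid", "data.frame")
  grid
}

#' @export
print.window_grid <- function(x, ...) {
  cat(sprintf("<window_grid> %d windows of %g kb over %d chromosomes\n",
              nrow(x), attr(x, "window_size") / 1e3,
              length(unique(x$chrom))))
  invisible(x)
}

#' Read / write a genome table
#'
#' Plain TSV with two columns (`chrom`, `length_bp`), no header.
#'
#' @param path File path.
#' @param genome A `genome` object (for writing).
#' @return `read_genome` returns a `genome`; `write_genome` returns `path`
#'   invisibly.
#' @export
read_genome <- function(path) {
  tab <- utils::read.table(path, sep = "\t", header = FALSE,
                           col.names = c("chrom", "length"),
                           colClasses = c("character", "numeric"))
  build_genome(tab$chrom, tab$length)
}

#' @rdname read_genome
#' @export
write_genome <- function(genome, path) {
  stopifnot(inherits(genome, "genome"))
  utils::write.table(
    data.frame(genome$chrom, sprintf("%.0f", genome$length)),
    path, sep = "\t", quote = FALSE, row.names = FALSE, col.names = FALSE)
  invisible(path)
}
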