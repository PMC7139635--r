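#' Derive a marker genotype matrix from a population
#'
#' One marker is realized at the midpoint of every window; a line's genotype
#' at a marker is the founder label of the consensus-mosaic segment
#' containing the midpoint. Simulated output has no missing values.
#'
#' @param pop A `population` of homozygous or consensus-resolved lines.
#' @param grid A `window_grid` on the population's genome.
#' @return Object of class `genotype_matrix`: list with `markers` (data frame
#'   `chrom`, `pos`) and `geno` (integer matrix, lines x markers of founder
#'   labels).
#' @export
genotype_matrix <- function(pop, grid) {
  stopifnot(inherits(pop, "population"), inherits(grid, "window_grid"))
  genome <- pop$genome
  mids_by_chrom <- lapply(genome$chrom, function(ch) {
    w <- grid[grid$chrom == ch, ]
    (w$start + w$end) / 2
  })
  markers <- data.frame(
    chrom = rep(genome$chrom, lengths(mids_by_chrom)),
    pos = unlist(mids_by_chrom), stringsAsFactors = FALSE)
  geno <- matrix(NA_integer_, nrow = length(pop$lines), ncol = nrow(markers))
  for (i in seq_along(pop$lines)) {
    m <- line_mosaic(pop$lines[[i]])
    geno[i, ] <- unlist(lapply(seq_len(nrow(genome)), function(ci) {
      h <- m[[ci]]
      h$founder[findInterval(mids_by_chrom[[ci]], h$end) + 1L]
    }))
  }
  structure(list(markers = markers, geno = geno,
                 window_size = attr(grid, "window_size")),
            class = "genotype_matrix")
}

#' @export
print.genotype_matrix <- function(x, ...) {
  cat(sprintf("<genotype_matrix> %d lines x %d markers (%g kb windows)\n",
              nrow(x$geno), ncol(x$geno), x$window_size / 1e3))
  invisible(x)
}

#' Recombination fractions between adjacent markers
#'
#' For each pair of physically adjacent markers on a chromosome, the
#' proportion of lines whose genotypes differ.
#'
#' @param gm A `genotype_matrix`.
#' @return Data frame with columns `chrom`, `pos_left`, `pos_right`, `r`.
#' @export
adjacent_recfrac <- function(gm) {
  stopifnot(inherits(gm, "genotype_matrix"))
  out <- lapply(unique(gm$markers$chrom), function(ch) {
    idx <- which(gm$markers$chrom == ch)
    if (length(idx) < 2L) {
      stop("fewer than 2 markers on chromosome ", ch)
    }
    g <- gm$geno[, idx, drop = FALSE]
    r <- colMeans(g[, -1L, drop = FALSE] != g[, -ncol(g), drop = FALSE])
    data.frame(chrom = ch,
               pos_left = gm$markers$pos[idx[-length(idx)]],
               pos_right = gm$markers$pos[idx[-1L]],
               r = as.numeric(r), stringsAsFactors = FALSE)
  })
  res <- do.call(rbind, out)
  rownames(res) <- NULL
  res
}

#' Kosambi map function
#'
#' Converts a recombination fraction to map distance:
#' `cM = 25 * ln((1 + 2r) / (1 - 2r))`. Inputs outside `[0, 0.4999]` are
#' clipped with a warning.
#'
#' @param r Recombination fraction(s) in `[0, 0.5)`.
#' @return Map distance(s) in cM.
#' @examples
#' kosambi(0.1)   # 10.137 cM
#' kosambi(0.25)  # 27.465 cM
#' @export
kosambi <- function(r) {
  if (any(r < 0) || any(r >= 0.5)) {
    warning("recombination fractions outside [0, 0.5) clipped")
    r <- pmin(pmax(r, 0), 0.4999)
  }
  25 * log((1 + 2 * r) / (1 - 2 * r))
}

#' Correct an observed RIL recombination fraction to single-meiosis scale
#'
#' Repeated selfing inflates the observed fraction R of recombinant lines
#' relative to the per-meiosis fraction r; for selfing-derived RILs the
#' forward relation is `R = 2r / (1 + 2r)`, inverted here as
#' `r = R / (2 - 2R)`.
#'
#' @param R Observed fraction(s), must satisfy `R < 0.5` after the guard.
#' @return Single-meiosis recombination fraction(s).
#' @export
ril_correct <- function(R) {
  if (any(R >= 0.5)) {
    warning("observed RIL fractions >= 0.5 clipped")
    R <- pmin(R, 0.4999)
  }
  R / (2 - 2 * R)
}

#' Build a Kosambi linkage map from a genotype matrix
#'
#' Adjacent-interval recombination fractions are converted to cM with the
#' Kosambi function and accumulated along the physical marker order (the map
#' order is fixed to the physical order; no de-novo ordering). For RIL
#' populations the observed fractions are first corrected to single-meiosis
#' scale with [ril_correct()].
#'
#' @param gm A `genotype_matrix`.
#' @param pop_type `"DH"` or `"RIL"`.
#' @return Object of class `linkage_map`: data frame with columns `chrom`,
#'   `pos` (bp) and `cM` (cumulative genetic position, 0 at each
#'   chromosome's first marker); attribute `pop_type`.
#' @export
build_linkage_map <- function(gm, pop_type = c("DH", "RIL")) {
  pop_type <- match.arg(pop_type)
  rf <- adjacent_recfrac(gm)
  r <- if (pop_type == "RIL") ril_correct(rf$r) else rf$r
  d <- kosambi(pmin(r, 0.4999))
  out <- lapply(unique(gm$markers$chrom), function(ch) {
    idx <- which(gm$markers$chrom == ch)
    dd <- d[rf$chrom == ch]
    data.frame(chrom = ch, pos = gm$markers$pos[idx],
               cM = c(0, cumsum(dd)), stringsAsFactors = FALSE)
  })
  map <- do.call(rbind, out)
  rownames(map) <- NULL
  attr(map, "pop_type") <- pop_type
  class(map) <- c("linkage_map", "data.frame")
  map
}

#' @export
print.linkage_map <- function(x, ...) {
  tot <- tapply(x$cM, x$chrom, max)
  cat(sprintf("<linkage_map> %s, %d markers, total length %.1f cM\n",
              attr(x, "pop_type"), nrow(x), sum(tot)))
  invisible(x)
}

#' Correlation between two linkage maps of the same genome
#'
#' Cumulative genetic positions are compared at the coarser map's marker
#' positions (the finer map is evaluated there as a step function,
#' interpolation-free) and pooled over chromosomes; the Pearson correlation
#' is returned.
#'
#' @param map_a,map_b `linkage_map` objects on the same genome.
#' @return Pearson correlation coefficient.
#' @export
map_correlation <- function(map_a, map_b) {
  stopifnot(inherits(map_a, "linkage_map"), inherits(map_b, "linkage_map"))
  if (nrow(map_a) < nrow(map_b)) {
    tmp <- map_a; map_a <- map_b; map_b <- tmp
  }
  # map_b is now the coarser map
  xa <- numeric(0)
  xb <- numeric(0)
  for (ch in intersect(unique(map_a$chrom), unique(map_b$chrom))) {
    fa <- map_a[map_a$chrom == ch, ]
    fb <- map_b[map_b$chrom == ch, ]
    idx <- findInterval(fb$pos, fa$pos)
    keep <- idx >= 1L
    xa <- c(xa, fa$cM[idx[keep]])
    xb <- c(xb, fb$cM[keep])
  }
  if (length(xa) < 3L) stop("fewer than 3 shared positions between maps")
  stats::cor(xa, xb)
}

#' Write / read a genotype matrix as CSV
#'
#' First column `line`, then one column per marker named
#' `<chrom>_<position>`, integer founder labels as values.
#'
#' @param gm A `genotype_matrix`.
#' @param path File path.
#' @return `read_genotype_matrix` returns a `genotype_matrix`;
#'   `write_genotype_matrix` returns `path` invisibly.
#' @export
write_genotype_matrix <- function(gm, path) {
  stopifnot(inherits(gm, "genotype_matrix"))
  df <- as.data.frame(gm$geno)
  names(df) <- sprintf("%s_%.0f", gm$markers$chrom, gm$markers$pos)
  df <- cbind(line = sprintf("L%04d", seq_len(nrow(df))), df)
  utils::write.csv(df, path, row.names = FALSE, quote = FALSE)
  invisible(path)
}

#' @rdname write_genotype_matrix
#' @export
read_genotype_matrix <- function(path) {
  df <- utils::read.csv(path, check.names = FALSE)
  if (names(df)[1L] != "line") {
    stop("malformed genotype CSV: first column must be 'line' (", path, ")")
  }
  cols <- names(df)[-1L]
  parts <- regmatches(cols, regexpr("_[0-9.]+$", cols))
  if (length(parts) != length(cols)) {
    stop("malformed marker column name in ", path)
  }
  markers <- data.frame(
    chrom = substr(cols, 1L, nchar(cols) - nchar(parts)),
    pos = as.numeric(substring(parts, 2L)), stringsAsFactors = FALSE)
  geno <- as.matrix(df[, -1L, drop = FALSE])
  dimnames(geno) <- NULL
  structure(list(markers = markers, geno = geno, window_size = NA_real_),
            class = "genotype_matrix")
}

#' Write a linkage map as TSV
#'
#' Columns `chrom`, `position_bp`, `cumulative_cM` (6 decimals), no header.
#'
#' @param map A `linkage_map`.
#' @param path File path.
#' @export
write_linkage_map <- function(map, path) {
  stopifnot(inherits(map, "linkage_map"))
  utils::write.table(
    data.frame(map$chrom, sprintf("%.0f", map$pos), sprintf("%.6f", map$cM)),
    path, sep = "\t", quote = FALSE, row.names = FALSE, col.names = FALSE)
  invisible(path)
}
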