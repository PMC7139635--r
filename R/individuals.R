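#' Create a fully inbred founder individual
#'
#' Both haplotypes carry a single founder label across the whole genome.
#'
#' @param genome A `genome`.
#' @param label Integer founder label.
#' @return An object of class `individual`: list with haplotypes `h1`, `h2`.
#' @export
founder_individual <- function(genome, label = 1L) {
  hap <- lapply(genome$length,
                function(L) list(end = L, founder = as.integer(label)))
  names(hap) <- genome$chrom
  structure(list(h1 = hap, h2 = hap), class = "individual")
}

#' @export
print.individual <- function(x, ...) {
  j1 <- sum(vapply(x$h1, function(h) length(h$founder) - 1L, integer(1)))
  j2 <- sum(vapply(x$h2, function(h) length(h$founder) - 1L, integer(1)))
  cat(sprintf("<individual> %d chromosomes; junctions: %d | %d\n",
              length(x$h1), j1, j2))
  invisible(x)
}

#' Cross two individuals
#'
#' The offspring receives one independently formed gamete from each parent.
#'
#' @param p1,p2 Parent `individual`s on the same genome.
#' @param params A `meiosis_params`.
#' @return An `individual`.
#' @export
cross <- function(p1, p2, params) {
  structure(list(h1 = form_gamete(p1, params),
                 h2 = form_gamete(p2, params)),
            class = "individual")
}

#' Self an individual (single seed descent step)
#'
#' The offspring receives two independent gametes from the same parent;
#' exactly one offspring is retained per line per generation.
#'
#' @inheritParams cross
#' @param p Parent `individual`.
#' @return An `individual`.
#' @export
self_cross <- function(p, params) {
  cross(p, p, params)
}

#' Doubled-haploid induction
#'
#' Samples one gamete and duplicates it into both haplotypes, giving a fully
#' homozygous line whose genome is one meiosis' product.
#'
#' @inheritParams self_cross
#' @return A fully homozygous `individual`.
#' @export
dh_induce <- function(p, params) {
  g <- form_gamete(p, params)
  structure(list(h1 = g, h2 = g), class = "individual")
}

#' Consensus mosaic of a line
#'
#' The single founder-labelled mosaic used for breakpoint counting: exact for
#' homozygous (DH) lines; for near-inbred lines with residual heterozygosity
#' (RILs after finite selfing) the first haplotype's label is reported
#' deterministically.
#'
#' @param ind An `individual`.
#' @return A haplotype.
#' @export
line_mosaic <- function(ind) {
  ind$h1
}

#' Fraction of the genome heterozygous in an individual
#'
#' Total length where the two haplotypes carry different founder labels,
#' divided by genome length.
#'
#' @param ind An `individual`.
#' @return Proportion in `[0, 1]`.
#' @export
heterozygosity <- function(ind) {
  het <- 0
  tot <- 0
  for (ci in seq_along(ind$h1)) {
    a <- ind$h1[[ci]]
    b <- ind$h2[[ci]]
    cuts <- sort(unique(c(0, a$end, b$end)))
    mids <- (cuts[-1L] + cuts[-length(cuts)]) / 2
    widths <- diff(cuts)
    fa <- a$founder[findInterval(mids, a$end) + 1L]
    fb <- b$founder[findInterval(mids, b$end) + 1L]
    het <- het + sum(widths[fa != fb])
    tot <- tot + a$end[length(a$end)]
  }
  het / tot
}
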