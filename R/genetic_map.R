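#' Genetic marker map
#'
#' A genetic map is an ordered table of markers with chromosome assignment,
#' physical position (1-based bp) and a chromosomal region class
#' (`tip`, `arm` or `center`). Region classes matter because QTL in
#' *C. elegans* are enriched on the chromosome arms, and the architecture
#' simulations place QTL with arm-weighted probabilities.
#'
#' @param marker character vector of unique marker ids.
#' @param chrom chromosome per marker, one of `I, II, III, IV, V, X`.
#' @param pos_bp integer-ish physical position per marker (1-based bp),
#'   strictly increasing within each chromosome.
#' @param fractions region-class boundary fractions, see
#'   [classify_marker_region()].
#' @return A `genetic_map`: a data.frame with columns `marker`, `chrom`,
#'   `pos_bp`, `region`.
#' @seealso [default_genetic_map()], [classify_marker_region()]
#' @export
genetic_map <- function(marker, chrom, pos_bp,
                        fractions = c(tip = 0.1, arm = 0.3, center = 0.2)) {
  chromosomes <- c("I", "II", "III", "IV", "V", "X")
  marker <- as.character(marker)
  chrom <- as.character(chrom)
  pos_bp <- as.numeric(pos_bp)
  if (anyDuplicated(marker)) stopf("map error: duplicated marker ids")
  bad <- setdiff(unique(chrom), chromosomes)
  if (length(bad)) stopf("map error: unknown chromosome(s): %s",
                         paste(bad, collapse = ", "))
  map <- data.frame(marker = marker, chrom = chrom, pos_bp = pos_bp,
                    stringsAsFactors = FALSE)
  for (ch in unique(chrom)) {
    p <- map$pos_bp[map$chrom == ch]
    if (length(p) < 2L)
      stopf("map error: chromosome %s has fewer than 2 markers", ch)
    if (any(diff(p) <= 0))
      stopf("map error: positions not strictly increasing on chromosome %s", ch)
  }
  class(map) <- c("genetic_map", "data.frame")
  map$region <- classify_marker_region(map, fractions)
  map
}

#' Default synthetic genetic map
#'
#' Six chromosomes with uniformly spaced markers, emulating the physical
#' scale of the *C. elegans* genome (default 16 Mb per chromosome).
#'
#' @param n_markers markers per chromosome.
#' @param chrom_length_bp chromosome length in bp.
#' @inheritParams genetic_map
#' @return A [genetic_map()].
#' @export
default_genetic_map <- function(n_markers = 100, chrom_length_bp = 16e6,
                                fractions = c(tip = 0.1, arm = 0.3, center = 0.2)) {
  chromosomes <- c("I", "II", "III", "IV", "V", "X")
  pos <- round(seq(1, chrom_length_bp, length.out = n_markers))
  genetic_map(
    marker = paste0(rep(chromosomes, each = n_markers), "_",
                    formatC(rep(seq_len(n_markers), 6), width = 3, flag = "0")),
    chrom = rep(chromosomes, each = n_markers),
    pos_bp = rep(pos, 6),
    fractions = fractions
  )
}

#' Classify markers into chromosome tip, arm and center regions
#'
#' Boundaries are fractional positions along each chromosome's marker span,
#' mirrored around the chromosome midpoint: `tip` and `arm` are the fractions
#' occupied by each chromosome end, `center` is the middle fraction, so that
#' `2 * (tip + arm) + center == 1`. No bp boundaries for these domains are
#' fixed in the literature for arbitrary maps, so they are configurable.
#'
#' @param map a [genetic_map()] (the `region` column is ignored).
#' @param fractions named numeric vector with elements `tip`, `arm`, `center`.
#' @return factor of region labels, one per marker.
#' @export
classify_marker_region <- function(map,
                                   fractions = c(tip = 0.1, arm = 0.3, center = 0.2)) {
  if (!all(c("tip", "arm", "center") %in% names(fractions)))
    stopf("config error: fractions must name tip, arm and center")
  tot <- 2 * (fractions[["tip"]] + fractions[["arm"]]) + fractions[["center"]]
  if (abs(tot - 1) > 1e-8)
    stopf("config error: 2*(tip+arm)+center must equal 1 (got %.4f)", tot)
  region <- character(nrow(map))
  for (ch in unique(map$chrom)) {
    sel <- map$chrom == ch
    p <- map$pos_bp[sel]
    f <- (p - min(p)) / (max(p) - min(p))
    r <- rep("arm", length(f))
    tip <- fractions[["tip"]]
    half_center <- fractions[["center"]] / 2
    r[f < tip | f > 1 - tip] <- "tip"
    r[abs(f - 0.5) <= half_center] <- "center"
    region[sel] <- r
  }
  factor(region, levels = c("tip", "arm", "center"))
}

#' Closed physical interval on a chromosome
#'
#' @param chrom chromosome label.
#' @param start_bp,end_bp closed interval bounds in bp, `start_bp <= end_bp`.
#' @return A `locus_interval` (one-row data.frame).
#' @export
locus_interval <- function(chrom, start_bp, end_bp) {
  if (end_bp < start_bp) stopf("interval error: end_bp < start_bp")
  out <- data.frame(chrom = as.character(chrom), start_bp = as.numeric(start_bp),
                    end_bp = as.numeric(end_bp), stringsAsFactors = FALSE)
  class(out) <- c("locus_interval", "data.frame")
  out
}
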