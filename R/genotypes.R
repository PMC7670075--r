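#' Genotype panel (RIL, IL or parent)
#'
#' Genotypes are fully homozygous two-allele calls on the markers of a
#' [genetic_map()]. Alleles are categorical (`N2`/`CB4856`) at the interface
#' and coded numerically as -1 (N2) / +1 (CB4856) internally; the symmetric
#' coding keeps additive genetic values mean-centred at allele frequency 0.5.
#'
#' For `panel_kind = "IL"` each strain must be N2 everywhere except at most
#' one contiguous run of CB4856 markers (a single introgression); parents
#' are constant rows. Heterozygous or unknown calls are rejected: both panel
#' types are inbred by construction.
#'
#' @param alleles strains x markers matrix, either character with values
#'   `"N2"`/`"CB4856"` or numeric -1/+1; rownames are strain ids, colnames
#'   marker ids matching `map$marker`.
#' @param panel_kind one of `"RIL"`, `"IL"`, `"parent"`.
#' @param map the [genetic_map()] the columns refer to.
#' @return A `genotype_matrix`: integer matrix of -1/+1 with attributes
#'   `panel_kind` and `map`.
#' @export
genotype_matrix <- function(alleles, panel_kind = c("RIL", "IL", "parent"), map) {
  panel_kind <- match.arg(panel_kind)
  if (is.character(alleles)) {
    bad <- setdiff(unique(as.vector(alleles)), c("N2", "CB4856"))
    if (length(bad))
      stopf("format error: unknown allele symbol(s): %s", paste(bad, collapse = ", "))
    coded <- matrix(ifelse(alleles == "CB4856", 1L, -1L), nrow(alleles),
                    dimnames = dimnames(alleles))
  } else {
    if (!all(alleles %in% c(-1, 1)))
      stopf("format error: numeric alleles must be -1 (N2) or +1 (CB4856)")
    coded <- matrix(as.integer(alleles), nrow(alleles), dimnames = dimnames(alleles))
  }
  if (is.null(rownames(coded)))
    rownames(coded) <- paste0(tolower(panel_kind), sprintf("%03d", seq_len(nrow(coded))))
  if (is.null(colnames(coded))) colnames(coded) <- map$marker
  if (!identical(colnames(coded), map$marker))
    stopf("map error: genotype columns do not match map markers")
  if (panel_kind == "parent" && nrow(coded) > 0) {
    if (any(apply(coded, 1L, function(x) length(unique(x))) != 1L))
      stopf("format error: parent rows must be constant")
  }
  g <- structure(coded, panel_kind = panel_kind, map = map,
                 class = c("genotype_matrix", "matrix"))
  if (panel_kind == "IL") {
    runs <- vapply(rownames(g), function(s) nrow(introgression_segments(g, s)), 0L)
    if (any(runs > 1L))
      stopf("format error: IL strain(s) with >1 introgression run: %s",
            paste(names(runs)[runs > 1L], collapse = ", "))
  }
  g
}

#' @rdname genotype_matrix
#' @param g a `genotype_matrix`.
#' @export
panel_kind <- function(g) attr(g, "panel_kind")

#' @rdname genotype_matrix
#' @export
map_of <- function(g) attr(g, "map")

#' @export
print.genotype_matrix <- function(x, ...) {
  cat(sprintf("<genotype_matrix> %s panel: %d strains x %d markers\n",
              panel_kind(x), nrow(x), ncol(x)))
  invisible(x)
}

#' Read a genotype map file
#'
#' The file dialect is TSV (or CSV) with one row per marker: columns
#' `marker`, `chrom`, `pos_bp`, then one column per strain. The allele
#' alphabet is declared in `config` and mapped onto `N2`/`CB4856`; any other
#' symbol (including heterozygous codes) is a format error.
#'
#' @param path file path.
#' @param config list with elements `alleles` (named character vector mapping
#'   file symbols to `"N2"`/`"CB4856"`) and `panel_kind`; alternatively the
#'   path of a YAML file holding those fields.
#' @param sep field separator, `"\t"` by default.
#' @return list with elements `map` ([genetic_map()]) and `genotypes`
#'   ([genotype_matrix()], strains x markers).
#' @export
load_genotype_map <- function(path, config, sep = "\t") {
  if (is.character(config) && length(config) == 1L)
    config <- yaml::read_yaml(config)
  alphabet <- unlist(config$alleles)
  if (!all(alphabet %in% c("N2", "CB4856")))
    stopf("config error: allele mapping targets must be N2 or CB4856")
  tab <- utils::read.table(path, header = TRUE, sep = sep, check.names = FALSE,
                           stringsAsFactors = FALSE, colClasses = "character")
  if (ncol(tab) < 4L)
    stopf("format error: expected marker/chrom/pos_bp plus >=1 strain column")
  map <- genetic_map(tab[[1L]], tab[[2L]], as.numeric(tab[[3L]]),
                     fractions = config$fractions %||% c(tip = 0.1, arm = 0.3, center = 0.2))
  cells <- as.matrix(tab[, -(1:3), drop = FALSE])
  unknown <- which(!(cells %in% names(alphabet)))
  if (length(unknown)) {
    i <- ((unknown[1L] - 1L) %% nrow(cells)) + 1L
    j <- ((unknown[1L] - 1L) %/% nrow(cells)) + 1L
    stopf("format error: unknown allele symbol '%s' at marker '%s', strain '%s'",
          cells[i, j], tab[[1L]][i], colnames(cells)[j])
  }
  alleles <- matrix(alphabet[cells], nrow(cells), dimnames = dimnames(cells))
  alleles <- t(alleles)                       # strains x markers
  colnames(alleles) <- map$marker
  list(map = map,
       genotypes = genotype_matrix(alleles, config$panel_kind %||% "RIL", map))
}

#' Write a genotype map file
#'
#' Emits the same dialect [load_genotype_map()] reads, so that a
#' write/read round trip is exact.
#'
#' @param g a [genotype_matrix()].
#' @param path output path.
#' @param config same structure as for [load_genotype_map()]; the inverse of
#'   `config$alleles` is used to encode calls.
#' @param sep field separator.
#' @export
write_genotype_map <- function(g, path, config, sep = "\t") {
  map <- map_of(g)
  alphabet <- unlist(config$alleles)
  inv <- stats::setNames(names(alphabet), alphabet)
  calls <- matrix(inv[ifelse(unclass(g) > 0, "CB4856", "N2")], nrow(g),
                  dimnames = dimnames(g))
  out <- data.frame(marker = map$marker, chrom = map$chrom, pos_bp = map$pos_bp,
                    t(calls), check.names = FALSE, stringsAsFactors = FALSE)
  utils::write.table(out, path, sep = sep, quote = FALSE, row.names = FALSE)
  invisible(path)
}

#' Introgression segments of an IL strain
#'
#' Maximal contiguous runs of CB4856 markers, reported as closed bp intervals
#' spanning the first and last marker of each run.
#'
#' @param g an IL [genotype_matrix()].
#' @param strain strain id.
#' @return data.frame of [locus_interval()] rows (possibly 0-row).
#' @export
introgression_segments <- function(g, strain) {
  if (!strain %in% rownames(g))
    stopf("lookup error: strain '%s' not in panel", strain)
  map <- map_of(g)
  x <- unclass(g)[strain, ]
  out <- list()
  for (ch in unique(map$chrom)) {
    sel <- which(map$chrom == ch)
    cb <- x[sel] > 0
    if (!any(cb)) next
    r <- rle(cb)
    ends <- cumsum(r$lengths)
    starts <- ends - r$lengths + 1L
    for (k in which(r$values)) {
      out[[length(out) + 1L]] <-
        locus_interval(ch, map$pos_bp[sel[starts[k]]], map$pos_bp[sel[ends[k]]])
    }
  }
  if (!length(out))
    return(structure(data.frame(chrom = character(), start_bp = numeric(),
                                end_bp = numeric(), stringsAsFactors = FALSE),
                     class = c("locus_interval", "data.frame")))
  do.call(rbind, out)
}

#' ILs whose introgression overlaps a locus
#'
#' Overlap is any shared bp between the strain's introgression(s) and the
#' closed query interval.
#'
#' @param g an IL [genotype_matrix()].
#' @param locus a [locus_interval()].
#' @return character vector of strain ids.
#' @export
ils_covering_locus <- function(g, locus) {
  if (panel_kind(g) != "IL") stopf("ils_covering_locus requires an IL panel")
  hits <- vapply(rownames(g), function(s) {
    seg <- introgression_segments(g, s)
    any(seg$chrom == locus$chrom &
          seg$start_bp <= locus$end_bp & seg$end_bp >= locus$start_bp)
  }, logical(1))
  rownames(g)[hits]
}

#' Per-marker IL coverage
#'
#' Number of ILs carrying the CB4856 allele at each marker; used to check
#' the tiling structure of an IL panel (in the real panel the 5-95% quantiles
#' of this count are 0-5).
#'
#' @param g an IL [genotype_matrix()].
#' @return integer vector, one count per marker.
#' @export
il_marker_coverage <- function(g) {
  if (panel_kind(g) != "IL") stopf("il_marker_coverage requires an IL panel")
  colSums(unclass(g) > 0)
}
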