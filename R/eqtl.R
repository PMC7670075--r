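#' Single-marker eQTL mapping
#'
#' Per spot and marker, expression (log2 scale) is compared between the two
#' allele groups with a pooled-variance t-test — the single-marker linear
#' model. The peak marker is the one with the largest `-log10(p)`; a record
#' is emitted when the peak exceeds `threshold` (3.9 corresponds to
#' FDR = 0.05 in the source RIL study). The eQTL effect is the CB4856-group
#' mean minus the N2-group mean (log2 units), and the confidence interval is
#' the contiguous run of markers around the peak within `ci_drop` of the
#' peak LOD, taking `-log10(p)` as the LOD score (a common QTL-software
#' approximation).
#'
#' @param es an [expression_set()] of the RIL panel.
#' @param geno the RIL [genotype_matrix()]; strains shared with `es`.
#' @param threshold `-log10(p)` significance threshold (default 3.9).
#' @param ci_drop LOD drop defining the confidence interval (default 1.5).
#' @return data.frame of eQTL records: `spot_id`, `gene_chrom`, `gene_bp`,
#'   `peak_marker`, `peak_chrom`, `peak_bp`, `neg_log10_p`, `effect`,
#'   `type`, `ci_start`, `ci_end`, `environment`.
#' @export
map_eqtl_single_marker <- function(es, geno, threshold = 3.9, ci_drop = 1.5) {
  if (panel_kind(geno) != "RIL") stopf("mapping requires a RIL panel")
  map <- map_of(geno)
  strains <- intersect(samples_of_group(es, "RIL"), rownames(geno))
  if (length(strains) < 4L) stopf("too few shared strains between expression and genotypes")
  E <- log2(es$values[, strains, drop = FALSE])
  E <- E - rowMeans(E)                    # spot-wise centering for stable variances
  G <- unclass(geno)[strains, , drop = FALSE]
  Icb <- (G > 0) + 0
  nCB <- colSums(Icb); nN2 <- nrow(G) - nCB
  mono <- nCB < 2 | nN2 < 2
  if (all(mono)) stopf("all markers monomorphic (or near-monomorphic)")
  if (any(mono))
    warnf("%d marker(s) skipped: fewer than 2 strains per allele group", sum(mono))
  S1 <- E %*% Icb; S2 <- (E^2) %*% Icb
  T1 <- rowSums(E); T2 <- rowSums(E^2)
  mCB <- sweep(S1, 2, nCB, "/")
  mN2 <- sweep(-S1 + T1, 2, nN2, "/")
  ssCB <- S2 - sweep(mCB^2, 2, nCB, "*")
  ssN2 <- (T2 - S2) - sweep(mN2^2, 2, nN2, "*")
  df <- nrow(G) - 2L
  vp <- (ssCB + ssN2) / df
  se <- sqrt(sweep(vp, 2, 1 / nCB + 1 / nN2, "*"))
  eff <- mCB - mN2
  tt <- eff / se
  lod <- -stats::pt(-abs(tt), df, log.p = TRUE) / log(10) - log10(2)
  lod[se == 0 & eff == 0] <- 0
  lod[se == 0 & eff != 0] <- Inf
  lod[, mono] <- NA_real_

  chrom_of <- map$chrom
  recs <- vector("list", nrow(E))
  for (s in seq_len(nrow(E))) {
    l <- lod[s, ]
    if (all(is.na(l))) next
    peak <- which.max(l)
    if (is.na(l[peak]) || l[peak] <= threshold) next
    lo <- hi <- peak
    cut <- l[peak] - ci_drop
    while (lo > 1L && chrom_of[lo - 1L] == chrom_of[peak] &&
           !is.na(l[lo - 1L]) && l[lo - 1L] >= cut) lo <- lo - 1L
    while (hi < length(l) && chrom_of[hi + 1L] == chrom_of[peak] &&
           !is.na(l[hi + 1L]) && l[hi + 1L] >= cut) hi <- hi + 1L
    recs[[s]] <- data.frame(
      spot_id = es$spots$spot_id[s], gene_chrom = es$spots$chrom[s],
      gene_bp = es$spots$bp[s], peak_marker = map$marker[peak],
      peak_chrom = chrom_of[peak], peak_bp = map$pos_bp[peak],
      neg_log10_p = unname(l[peak]), effect = unname(eff[s, peak]),
      ci_start = map$pos_bp[lo], ci_end = map$pos_bp[hi],
      environment = es$environment, stringsAsFactors = FALSE)
  }
  out <- do.call(rbind, recs)
  if (is.null(out))
    out <- data.frame(spot_id = character(), gene_chrom = character(),
                      gene_bp = numeric(), peak_marker = character(),
                      peak_chrom = character(), peak_bp = numeric(),
                      neg_log10_p = numeric(), effect = numeric(),
                      ci_start = numeric(), ci_end = numeric(),
                      environment = character(), stringsAsFactors = FALSE)
  classify_cis_trans(out)
}

#' Classify eQTL records as cis or trans
#'
#' An eQTL is `cis` when the gene lies within `window_bp` (1 Mb) of the peak
#' marker on the same chromosome, or inside the confidence interval of the
#' peak; otherwise `trans`. Records with unknown gene position are left
#' unclassified (`NA`) with a warning.
#'
#' @param records eQTL data.frame (see [map_eqtl_single_marker()]).
#' @param window_bp cis window around the peak (default 1 Mb).
#' @return `records` with a `type` column.
#' @export
classify_cis_trans <- function(records, window_bp = 1e6) {
  same <- !is.na(records$gene_chrom) & records$gene_chrom == records$peak_chrom
  near <- same & abs(records$gene_bp - records$peak_bp) <= window_bp
  in_ci <- same & records$gene_bp >= records$ci_start &
    records$gene_bp <= records$ci_end
  type <- ifelse(near | in_ci, "cis", "trans")
  missing_pos <- is.na(records$gene_chrom) | is.na(records$gene_bp)
  if (any(missing_pos)) {
    warnf("%d record(s) with missing gene position left unclassified", sum(missing_pos))
    type[missing_pos] <- NA_character_
  }
  records$type <- type
  records
}

#' Read or write an eQTL table
#'
#' TSV dialect compatible with externally supplied eQTL mappings.
#' @param records eQTL data.frame.
#' @param path file path.
#' @export
write_eqtl_table <- function(records, path) {
  utils::write.table(records, path, sep = "\t", quote = FALSE, row.names = FALSE)
  invisible(path)
}

#' @rdname write_eqtl_table
#' @export
read_eqtl_table <- function(path) {
  utils::read.table(path, header = TRUE, sep = "\t", stringsAsFactors = FALSE)
}
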