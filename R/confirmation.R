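#' Differential expression of single strains from parental z-scores
#'
#' Each RIL/IL strain is measured once, so per-spot significance is
#' estimated from the z-score against the genetic-background parent
#' assuming normality: two-sided `p = 2 * pnorm(-|Z|)`. Two modes:
#' `confirmation` applies BH correction across spots within the strain and
#' calls spots at `q < fdr` (used for per-IL eQTL confirmation);
#' `counting` applies a fixed `p < p_cut` cutoff (1e-5, the stricter
#' threshold used when counting differentially expressed genes).
#'
#' @param z z-score matrix from [zscore_vs_parent()] (spots x samples).
#' @param mode `"confirmation"` or `"counting"`.
#' @param fdr BH threshold for confirmation mode (default 0.05).
#' @param p_cut fixed p cutoff for counting mode (default 1e-5).
#' @return logical matrix spots x samples (`NA` z-scores are not called).
#' @export
de_calls <- function(z, mode = c("confirmation", "counting"), fdr = 0.05,
                     p_cut = 1e-5) {
  mode <- match.arg(mode)
  p <- 2 * stats::pnorm(-abs(z))
  if (mode == "counting") {
    calls <- p < p_cut
  } else {
    calls <- apply(p, 2L, function(col) {
      q <- stats::p.adjust(col, method = "BH")
      q < fdr
    })
    dimnames(calls) <- dimnames(p)
  }
  calls[is.na(calls)] <- FALSE
  calls
}

#' @rdname de_calls
#' @param strain a single sample/strain id present in `z`.
#' @return `per_strain_differential_expression`: character vector of DE
#'   spot ids for that strain.
#' @export
per_strain_differential_expression <- function(z, strain,
                                               mode = c("confirmation", "counting"),
                                               fdr = 0.05, p_cut = 1e-5) {
  if (!strain %in% colnames(z)) stopf("lookup error: sample '%s' not in z matrix", strain)
  calls <- de_calls(z[, strain, drop = FALSE], mode = mode, fdr = fdr, p_cut = p_cut)
  rownames(z)[calls[, 1L]]
}

expected_eqtl_spots <- function(eqtls, geno, strain, allele = 1L) {
  idx <- match(eqtls$peak_marker, colnames(geno))
  eqtls$spot_id[unclass(geno)[strain, idx] == allele]
}

#' Per-strain eQTL confirmation rate
#'
#' For every strain, the expected eQTL are those whose peak marker carries
#' the CB4856 allele in that strain (for an IL: peaks inside its
#' introgression), split into cis and trans. An expected eQTL is confirmed
#' when its spot is differentially expressed in that strain (confirmation
#' mode of [de_calls()], z-scores against N2). The confirmation percentage
#' is reported per strain and type; strains with no expected eQTL get `NA`.
#' Applying the same procedure to the RIL panel gives the benchmark the
#' eQTL were mapped in. Direction of change is not required by default; with
#' `directional = TRUE` the strain's z-score must also match the sign of the
#' eQTL effect.
#'
#' @param de logical DE matrix (spots x strains) from [de_calls()].
#' @param eqtls eQTL records (see [map_eqtl_single_marker()]).
#' @param geno [genotype_matrix()] of the strains in `de`.
#' @param directional require matching effect direction (default `FALSE`).
#' @param z z-score matrix, only needed when `directional = TRUE`.
#' @return data.frame `strain`, `panel`, `type`, `expected`, `confirmed`,
#'   `percentage`.
#' @export
eqtl_confirmation_rate <- function(de, eqtls, geno, directional = FALSE, z = NULL) {
  strains <- intersect(colnames(de), rownames(geno))
  if (!length(strains)) stopf("no shared strains between DE calls and genotypes")
  if (directional && is.null(z)) stopf("directional mode needs the z matrix")
  rows <- list()
  for (s in strains) {
    for (ty in c("cis", "trans")) {
      sub <- eqtls[!is.na(eqtls$type) & eqtls$type == ty, , drop = FALSE]
      exp_spots <- expected_eqtl_spots(sub, geno, s)
      exp_spots <- intersect(exp_spots, rownames(de))
      hit <- exp_spots[de[exp_spots, s]]
      if (directional && length(hit)) {
        effs <- sub$effect[match(hit, sub$spot_id)]
        hit <- hit[sign(z[hit, s]) == sign(effs)]
      }
      rows[[length(rows) + 1L]] <- data.frame(
        strain = s, panel = panel_kind(geno), type = ty,
        expected = length(exp_spots), confirmed = length(hit),
        percentage = if (length(exp_spots)) 100 * length(hit) / length(exp_spots)
                     else NA_real_,
        stringsAsFactors = FALSE)
    }
  }
  do.call(rbind, rows)
}

#' Correlation of strain expression ratios with eQTL effects
#'
#' Pearson correlation between a strain's log2 ratios to the N2 parent and
#' the eQTL effect sizes, over the eQTL whose peak allele the strain carries
#' as CB4856, computed separately for cis and trans eQTL. A high correlation
#' means the strain recapitulates the mapped allelic effects.
#'
#' @param r log2-ratio matrix from [log2_ratio_vs_parent()].
#' @param strain sample id.
#' @param eqtls eQTL records.
#' @param geno [genotype_matrix()].
#' @return data.frame `strain`, `type`, `n`, `rho`, `p` (`NA` when fewer
#'   than 3 eligible eQTL).
#' @export
strain_effect_correlation <- function(r, strain, eqtls, geno) {
  out <- lapply(c("cis", "trans"), function(ty) {
    sub <- eqtls[!is.na(eqtls$type) & eqtls$type == ty, , drop = FALSE]
    spots <- intersect(expected_eqtl_spots(sub, geno, strain), rownames(r))
    x <- r[spots, strain]
    e <- sub$effect[match(spots, sub$spot_id)]
    keep <- is.finite(x) & is.finite(e)
    if (sum(keep) < 3L)
      return(data.frame(strain = strain, type = ty, n = sum(keep),
                        rho = NA_real_, p = NA_real_, stringsAsFactors = FALSE))
    ct <- stats::cor.test(x[keep], e[keep], method = "pearson")
    data.frame(strain = strain, type = ty, n = sum(keep),
               rho = unname(ct$estimate), p = ct$p.value, stringsAsFactors = FALSE)
  })
  do.call(rbind, out)
}

#' Trans-band definition
#'
#' A regulatory hotspot: a locus whose CB4856 allele carries trans-eQTL for
#' at least two member spots.
#'
#' @param id band id.
#' @param locus a [locus_interval()].
#' @param spot_id member spot ids (`>= 2`).
#' @param effect per-member trans-eQTL effects.
#' @param environment environment label.
#' @return a `trans_band` list.
#' @export
trans_band <- function(id, locus, spot_id, effect, environment = NA_character_) {
  if (length(spot_id) < 2L) stopf("a trans-band needs >= 2 member spots")
  if (length(effect) != length(spot_id)) stopf("one effect per member spot required")
  structure(list(id = id, locus = locus, spot_id = as.character(spot_id),
                 effect = as.numeric(effect), environment = environment),
            class = "trans_band")
}

#' Group mapped trans-eQTL into candidate trans-bands
#'
#' Trans-eQTL peaks on the same chromosome within `gap_bp` of each other are
#' merged; groups with at least `min_members` spots become bands.
#'
#' @param eqtls eQTL records.
#' @param min_members minimum member spots (default 5).
#' @param gap_bp maximum peak-to-peak gap within a band (default 1 Mb).
#' @return list of [trans_band()]s.
#' @export
find_trans_bands <- function(eqtls, min_members = 5, gap_bp = 1e6) {
  tr <- eqtls[!is.na(eqtls$type) & eqtls$type == "trans", , drop = FALSE]
  bands <- list()
  for (ch in unique(tr$peak_chrom)) {
    sub <- tr[tr$peak_chrom == ch, , drop = FALSE]
    sub <- sub[order(sub$peak_bp), , drop = FALSE]
    grp <- cumsum(c(1, diff(sub$peak_bp) > gap_bp))
    for (g in unique(grp)) {
      m <- sub[grp == g, , drop = FALSE]
      if (nrow(m) < min_members) next
      bands[[length(bands) + 1L]] <- trans_band(
        id = sprintf("band_%s_%d", ch, length(bands) + 1L),
        locus = locus_interval(ch, min(m$peak_bp), max(m$peak_bp)),
        spot_id = m$spot_id, effect = m$effect,
        environment = m$environment[1L])
    }
  }
  bands
}

#' Confirm a trans-band with introgression lines
#'
#' For each candidate IL (covering or flanking the band locus) the band's
#' member-eQTL effects are correlated with the IL's log2 ratios to N2. The
#' significance threshold is empirical: the highest correlation observed in
#' the N2 parental samples themselves. An IL confirms the band only when its
#' correlation is positive (effect direction matches the eQTL model) and
#' exceeds that threshold. The false-positive rate is the fraction of
#' off-band ILs (introgression not overlapping the band locus widened by
#' `near_bp`) exceeding the same threshold.
#'
#' @param band a [trans_band()].
#' @param candidates ids of ILs covering/flanking the band (2-6 typically).
#' @param r log2-ratio matrix (vs N2) with IL columns.
#' @param n2_r log2-ratio matrix of the N2 parental samples themselves.
#' @param geno IL [genotype_matrix()].
#' @param near_bp widening of the band locus when declaring ILs off-band
#'   (default 1 Mb).
#' @return list with `per_il` (data.frame `strain`, `correlation`,
#'   `confirmed`), `threshold`, `confirmed` (any IL confirms) and `fp_rate`
#'   (`NA` when no off-band ILs exist).
#' @export
confirm_trans_band <- function(band, candidates, r, n2_r, geno, near_bp = 1e6) {
  if (ncol(n2_r) < 1L) stopf("need >= 1 N2 sample with log2 ratios")
  spots <- intersect(band$spot_id, rownames(r))
  if (length(spots) < 2L) stopf("band has < 2 member spots with expression data")
  eff <- band$effect[match(spots, band$spot_id)]
  cors <- function(cols, mat) {
    vapply(cols, function(cn) stats::cor(eff, mat[spots, cn]), 0)
  }
  thr <- max(cors(colnames(n2_r), n2_r))
  per_il <- data.frame(strain = candidates,
                       correlation = cors(candidates, r),
                       stringsAsFactors = FALSE, row.names = NULL)
  per_il$confirmed <- per_il$correlation > 0 & per_il$correlation > thr
  wide <- locus_interval(band$locus$chrom,
                         max(0, band$locus$start_bp - near_bp),
                         band$locus$end_bp + near_bp)
  covering <- ils_covering_locus(geno, wide)
  off <- setdiff(intersect(rownames(geno), colnames(r)), covering)
  fp <- if (length(off)) {
    co <- cors(off, r)
    mean(co > 0 & co > thr)
  } else NA_real_
  list(per_il = per_il, threshold = thr, confirmed = any(per_il$confirmed),
       fp_rate = fp)
}

#' Expected versus observed differentially expressed genes
#'
#' The expected number of DE genes per strain versus N2 is the number of
#' eQTL whose peak allele the strain carries as CB4856 (versus CB4856: as
#' N2). Observed counts come from counting-mode DE calls ([de_calls()],
#' `p < 1e-5`). Both are normalized by the RIL-panel mean expectation (RIL
#' average set to 1) so panels can be compared, and observed is tested
#' against expected within the IL panel with a paired t-test, separately per
#' reference parent.
#'
#' @param obs_n2,obs_cb named vectors of observed DE counts per strain
#'   (versus N2 and versus CB4856 respectively), covering both panels.
#' @param eqtls eQTL records.
#' @param ril_geno,il_geno the genotype panels.
#' @return list with `table` (per strain: panel, reference, expected,
#'   observed and normalized versions) and `tests` (per reference: paired-t
#'   p and IL observed/expected fold change); tests are skipped (`NA`) when
#'   no eQTL are available.
#' @export
expected_vs_observed_deg <- function(obs_n2, obs_cb, eqtls, ril_geno, il_geno) {
  count_expected <- function(geno, allele) {
    idx <- match(eqtls$peak_marker, colnames(geno))
    apply(unclass(geno)[, idx, drop = FALSE], 1L, function(row) sum(row == allele))
  }
  tabs <- list()
  tests <- list()
  for (ref in c("N2", "CB4856")) {
    allele <- if (ref == "N2") 1L else -1L      # loci differing from the reference
    obs <- if (ref == "N2") obs_n2 else obs_cb
    exp_ril <- count_expected(ril_geno, allele)
    exp_il <- count_expected(il_geno, allele)
    norm <- mean(exp_ril)
    tab <- rbind(
      data.frame(strain = names(exp_ril), panel = "RIL", reference = ref,
                 expected = unname(exp_ril),
                 observed = unname(obs[names(exp_ril)]), stringsAsFactors = FALSE),
      data.frame(strain = names(exp_il), panel = "IL", reference = ref,
                 expected = unname(exp_il),
                 observed = unname(obs[names(exp_il)]), stringsAsFactors = FALSE))
    if (norm > 0) {
      tab$expected_norm <- tab$expected / norm
      tab$observed_norm <- tab$observed / norm
    } else {
      tab$expected_norm <- tab$observed_norm <- NA_real_
    }
    il_rows <- tab$panel == "IL" & !is.na(tab$observed)
    tests[[ref]] <- if (norm > 0 && sum(il_rows) >= 3L &&
                        stats::sd(tab$observed[il_rows] - tab$expected[il_rows]) > 0) {
      tt <- stats::t.test(tab$observed_norm[il_rows], tab$expected_norm[il_rows],
                          paired = TRUE)
      list(p = tt$p.value,
           fold = mean(tab$observed_norm[il_rows]) / mean(tab$expected_norm[il_rows]))
    } else list(p = NA_real_, fold = NA_real_)
    tabs[[ref]] <- tab
  }
  list(table = do.call(rbind, tabs), tests = tests)
}

#' Verify strain identity from cis-eQTL sign concordance
#'
#' An IL's expression should deviate from N2 in the direction of the mapped
#' cis-eQTL effects inside its introgression. The concordance score is the
#' fraction of such cis-eQTL whose effect sign matches the sign of the
#' strain's log2 ratio; mislabelled or swapped samples score near 0.5
#' (random) or 0 (sign-flipped). Strains with fewer than `min_cis` cis-eQTL
#' inside the introgression are unverifiable.
#'
#' @param r log2-ratio matrix (vs N2).
#' @param eqtls eQTL records (only `type == "cis"` used).
#' @param geno IL [genotype_matrix()].
#' @param min_cis minimum informative cis-eQTL (default 5).
#' @param cutoff concordance below which a strain is flagged (default 0.6).
#' @return data.frame `strain`, `n_cis`, `concordance`, `verifiable`,
#'   `mismatch`.
#' @export
verify_strain_identity <- function(r, eqtls, geno, min_cis = 5, cutoff = 0.6) {
  cis <- eqtls[!is.na(eqtls$type) & eqtls$type == "cis", , drop = FALSE]
  strains <- intersect(rownames(geno), colnames(r))
  rows <- lapply(strains, function(s) {
    spots <- intersect(expected_eqtl_spots(cis, geno, s), rownames(r))
    x <- r[spots, s]
    e <- cis$effect[match(spots, cis$spot_id)]
    keep <- is.finite(x) & e != 0
    n <- sum(keep)
    if (n < min_cis)
      return(data.frame(strain = s, n_cis = n, concordance = NA_real_,
                        verifiable = FALSE, mismatch = NA, stringsAsFactors = FALSE))
    sc <- mean(sign(x[keep]) == sign(e[keep]))
    data.frame(strain = s, n_cis = n, concordance = sc, verifiable = TRUE,
               mismatch = sc < cutoff, stringsAsFactors = FALSE)
  })
  do.call(rbind, rows)
}
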