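#' Configuration for an end-to-end synthetic run
#'
#' Bundles the synthetic design, the analysis thresholds (eQTL
#' `-log10(p) > 3.9`, DEG counting `p < 1e-5`, confirmation FDR 0.05,
#' parental FDR 0.1, heritability permutation level 0.05) and the
#' architecture-simulation grid. Any file paths supplied in `files` are
#' validated before computation starts.
#'
#' @param out_dir output directory (created if missing).
#' @param seed root integer seed; every stage derives its own substream
#'   from it, so stages are individually reproducible.
#' @param design a [synthetic_design()].
#' @param thresholds named list, see defaults.
#' @param n_perm permutations for heritability thresholds (scaled down from
#'   the protocol's 1000 for desk-scale runs).
#' @param sim architecture-simulation grid (models, n_loci, cluster_sizes,
#'   replicates).
#' @param panel spot counts for the planted trait panel.
#' @param files optional named list of input files (validated to exist).
#' @return a `run_config` list.
#' @export
run_config <- function(out_dir, seed = 1,
                       design = synthetic_design(seed = seed),
                       thresholds = list(eqtl = 3.9, deg_p = 1e-5,
                                         confirmation_fdr = 0.05,
                                         parental_fdr = 0.1,
                                         heritability_level = 0.05),
                       n_perm = 100,
                       sim = list(models = c(1, 5), n_loci = seq(5, 100, by = 5),
                                  cluster_sizes = 2:5, replicates = 200),
                       panel = list(n_cis = 40, n_trans_band = 12,
                                    n_balanced = 10, n_noise = 8),
                       files = NULL) {
  if (any(unlist(thresholds) <= 0)) stopf("config error: thresholds must be positive")
  for (f in unlist(files)) {
    if (!file.exists(f)) stopf("config error: input file not found: %s", f)
  }
  structure(list(out_dir = out_dir, seed = as.integer(seed), design = design,
                 thresholds = thresholds, n_perm = n_perm, sim = sim,
                 panel = panel, files = files),
            class = "run_config")
}

#' Planted trait panel for synthetic studies
#'
#' A mix of spot architectures: single cis-eQTL (gene at the QTL marker),
#' one trans-band (many spots regulated by one shared marker), balanced
#' closely-linked clusters, and pure-noise spots.
#'
#' @param map a [genetic_map()].
#' @param ril RIL panel (for informative markers).
#' @param n_cis,n_trans_band,n_balanced,n_noise spot counts per class.
#' @param seed integer seed.
#' @param effect_range absolute effect sizes drawn uniformly from this
#'   range (log2 units).
#' @return named list of [trait_model()]s.
#' @export
make_trait_panel <- function(map, ril, n_cis = 40, n_trans_band = 12,
                             n_balanced = 10, n_noise = 8, seed = 1,
                             effect_range = c(0.8, 2)) {
  set.seed(seed)
  info <- which(informative_markers(ril))
  rnd_eff <- function(n) sample(c(-1, 1), n, replace = TRUE) *
    stats::runif(n, effect_range[1], effect_range[2])
  models <- list()
  for (i in seq_len(n_cis)) {
    mk <- sample(info, 1L)
    models[[sprintf("cis%03d", i)]] <- trait_model(
      mk, rnd_eff(1L), gene_chrom = map$chrom[mk], gene_bp = map$pos_bp[mk],
      model = "cis-additive")
  }
  band_mk <- sample(info, 1L)
  other_chrom <- setdiff(unique(map$chrom), map$chrom[band_mk])
  for (i in seq_len(n_trans_band)) {
    gc <- sample(other_chrom, 1L)
    gpos <- sample(map$pos_bp[map$chrom == gc], 1L)
    models[[sprintf("trans%03d", i)]] <- trait_model(
      band_mk, rnd_eff(1L), gene_chrom = gc, gene_bp = gpos,
      model = "trans-band-member")
  }
  anchors_ok <- which(cluster_anchor_ok(map, 3L))
  for (i in seq_len(n_balanced)) {
    a <- sample(intersect(info, anchors_ok), 1L)
    e <- stats::rnorm(3L)
    e <- e - mean(e); e[3L] <- -sum(e[1:2])
    models[[sprintf("bal%03d", i)]] <- trait_model(
      a + 0:2, e, cluster = rep(1L, 3L),
      gene_chrom = map$chrom[a], gene_bp = map$pos_bp[a],
      model = "balanced-cluster")
  }
  for (i in seq_len(n_noise)) {
    gc <- sample(unique(map$chrom), 1L)
    models[[sprintf("noise%03d", i)]] <- trait_model(
      integer(0), numeric(0), gene_chrom = gc,
      gene_bp = sample(map$pos_bp[map$chrom == gc], 1L), model = "noise")
  }
  models
}

stage <- function(name, expr) {
  tryCatch(expr, error = function(e)
    stopf("stage '%s' failed: %s", name, conditionMessage(e)))
}

#' Run the full synthetic analysis pipeline
#'
#' Executes, per environment: parent-referenced transforms, parental
#' differential expression, heritability with permutation thresholds in
#' both panels, relative heritability with variance-homogeneity tests,
#' single-marker eQTL mapping with cis/trans classification, per-IL eQTL
#' confirmation (with the RIL benchmark), effect-size correlations,
#' trans-band confirmation, expected-versus-observed DEG comparison, and
#' strain-identity verification; then the architecture simulation and the
#' per-environment deconvolution of the observed R_H distribution. All
#' tables are written as TSV under `cfg$out_dir` plus a Markdown summary;
#' every derived seed and threshold is logged. Two runs with the same
#' configuration produce byte-identical outputs.
#'
#' @param cfg a [run_config()].
#' @return (invisibly) a report list with all stage outputs.
#' @export
run_full_analysis <- function(cfg) {
  dir.create(cfg$out_dir, showWarnings = FALSE, recursive = TRUE)
  base <- cfg$seed %% 1000000L
  sub_seed <- function(k) base * 1009L + k
  log_lines <- c(sprintf("root_seed\t%d", cfg$seed),
                 sprintf("threshold_%s\t%g", names(cfg$thresholds),
                         unlist(cfg$thresholds)))

  map <- stage("map", default_genetic_map())
  ril <- stage("ril_genotypes", simulate_ril_genotypes(map, cfg$design$n_rils,
                                                       seed = sub_seed(1L)))
  il <- stage("il_genotypes", simulate_il_genotypes(map, cfg$design$n_ils,
                                                    seed = sub_seed(2L)))
  models <- stage("trait_panel", do.call(make_trait_panel, c(
    list(map = map, ril = ril, seed = sub_seed(3L)), cfg$panel)))
  design <- cfg$design
  design$seed <- sub_seed(4L)
  data <- stage("expression", generate_expression_dataset(design, models, map, ril, il))
  utils::write.table(data$manifest, file.path(cfg$out_dir, "manifest.tsv"),
                     sep = "\t", quote = FALSE, row.names = FALSE)
  report <- list(environments = list())
  for (ei in seq_along(design$environments)) {
    env <- design$environments[ei]
    dat <- data$environments[[env]]
    res <- list()
    res$parent_stats <- stage("parent_stats", list(
      N2 = parent_summary_stats(dat$IL, "N2"),
      CB4856 = parent_summary_stats(dat$IL, "CB4856")))
    z_il <- stage("zscore", zscore_vs_parent(dat$IL, res$parent_stats$N2))
    z_il_cb <- zscore_vs_parent(dat$IL, res$parent_stats$CB4856)
    z_ril <- zscore_vs_parent(dat$RIL, res$parent_stats$N2)
    z_ril_cb <- zscore_vs_parent(dat$RIL, res$parent_stats$CB4856)
    r_il <- log2_ratio_vs_parent(dat$IL, res$parent_stats$N2)
    r_ril <- log2_ratio_vs_parent(dat$RIL, res$parent_stats$N2)
    res$parental_de <- stage("parental_de",
      parental_differential_expression(dat$IL, fdr = cfg$thresholds$parental_fdr))
    h_seed <- sub_seed(10L + ei)
    res$heritability <- stage("heritability", rbind(
      permutation_heritability_threshold(dat$RIL, "RIL", n_perm = cfg$n_perm,
                                         level = cfg$thresholds$heritability_level,
                                         seed = h_seed),
      permutation_heritability_threshold(dat$IL, "IL", n_perm = cfg$n_perm,
                                         level = cfg$thresholds$heritability_level,
                                         seed = h_seed + 1L)))
    log_lines <- c(log_lines, sprintf("heritability_seed_%s\t%d", env, h_seed))
    sig_spots <- unique(res$heritability$spot_id[res$heritability$significant])
    res$relative_heritability <- stage("relative_heritability",
      relative_heritability_table(dat$IL, dat$RIL,
                                  spots = if (length(sig_spots)) sig_spots else NULL))
    res$eqtl <- stage("eqtl_mapping",
      map_eqtl_single_marker(dat$RIL, ril, threshold = cfg$thresholds$eqtl))
    il_cols <- samples_of_group(dat$IL, "IL")
    ril_cols <- samples_of_group(dat$RIL, "RIL")
    de_conf_il <- de_calls(z_il[, il_cols, drop = FALSE], "confirmation",
                           fdr = cfg$thresholds$confirmation_fdr)
    de_conf_ril <- de_calls(z_ril[, ril_cols, drop = FALSE], "confirmation",
                            fdr = cfg$thresholds$confirmation_fdr)
    res$confirmation <- stage("confirmation", rbind(
      eqtl_confirmation_rate(de_conf_il, res$eqtl, il),
      eqtl_confirmation_rate(de_conf_ril, res$eqtl, ril)))
    res$effect_correlation <- stage("effect_correlation", do.call(rbind, lapply(
      il_cols, function(s) strain_effect_correlation(r_il, s, res$eqtl, il))))
    res$trans_bands <- stage("trans_bands", {
      bands <- find_trans_bands(res$eqtl)
      n2_cols <- samples_of_group(dat$IL, "N2")
      lapply(bands, function(b) {
        cand <- ils_covering_locus(il, b$locus)
        if (!length(cand)) return(NULL)
        confirm_trans_band(b, cand, r_il[, il_cols, drop = FALSE],
                           r_il[, n2_cols, drop = FALSE], il)
      })
    })
    cnt_il_n2 <- colSums(de_calls(z_il[, il_cols, drop = FALSE], "counting",
                                  p_cut = cfg$thresholds$deg_p))
    cnt_il_cb <- colSums(de_calls(z_il_cb[, il_cols, drop = FALSE], "counting",
                                  p_cut = cfg$thresholds$deg_p))
    cnt_ril_n2 <- colSums(de_calls(z_ril[, ril_cols, drop = FALSE], "counting",
                                   p_cut = cfg$thresholds$deg_p))
    cnt_ril_cb <- colSums(de_calls(z_ril_cb[, ril_cols, drop = FALSE], "counting",
                                   p_cut = cfg$thresholds$deg_p))
    res$deg_comparison <- stage("deg_comparison",
      expected_vs_observed_deg(c(cnt_il_n2, cnt_ril_n2), c(cnt_il_cb, cnt_ril_cb),
                               res$eqtl, ril, il))
    res$identity <- stage("strain_identity",
      verify_strain_identity(r_il[, il_cols, drop = FALSE], res$eqtl, il))
    for (nm in c("parental_de", "heritability", "relative_heritability",
                 "eqtl", "confirmation", "effect_correlation", "identity")) {
      utils::write.table(res[[nm]], file.path(cfg$out_dir,
                                              sprintf("%s_%s.tsv", nm, env)),
                         sep = "\t", quote = FALSE, row.names = FALSE)
    }
    report$environments[[env]] <- res
  }
  sim_seed <- sub_seed(50L)
  report$sim <- stage("architecture_sim",
    rh_distribution(map, ril, il, models = cfg$sim$models,
                    n_loci = cfg$sim$n_loci, cluster_sizes = cfg$sim$cluster_sizes,
                    replicates = cfg$sim$replicates, seed = sim_seed))
  log_lines <- c(log_lines, sprintf("architecture_sim_seed\t%d", sim_seed))
  utils::write.table(report$sim, file.path(cfg$out_dir, "rh_simulation.tsv"),
                     sep = "\t", quote = FALSE, row.names = FALSE)
  report$mixtures <- list()
  for (env in design$environments) {
    rh_obs <- report$environments[[env]]$relative_heritability$RH
    report$mixtures[[env]] <- stage("deconvolution",
      tryCatch(unclass(deconvolve_rh(rh_obs, report$sim)),
               error = function(e) list(error = conditionMessage(e))))
  }
  jsonlite::write_json(report$mixtures, file.path(cfg$out_dir, "mixture.json"),
                       auto_unbox = TRUE, digits = NA, pretty = TRUE)
  writeLines(log_lines, file.path(cfg$out_dir, "run_log.tsv"))
  writeLines(render_summary(report, design), file.path(cfg$out_dir, "summary.md"))
  invisible(report)
}

render_summary <- function(report, design) {
  lines <- c("# Synthetic RIL/IL eQTL analysis summary", "")
  for (env in design$environments) {
    res <- report$environments[[env]]
    h <- res$heritability
    conf <- res$confirmation
    mean_pct <- function(panel, type) {
      x <- conf$percentage[conf$panel == panel & conf$type == type]
      if (all(is.na(x))) NA_real_ else mean(x, na.rm = TRUE)
    }
    mix <- report$mixtures[[env]]
    lines <- c(lines, sprintf("## Environment: %s", env),
      sprintf("- eQTL mapped (RILs): %d (%d cis / %d trans)", nrow(res$eqtl),
              sum(res$eqtl$type == "cis", na.rm = TRUE),
              sum(res$eqtl$type == "trans", na.rm = TRUE)),
      sprintf("- spots with significant H2: RIL %d, IL %d",
              sum(h$significant[h$population == "RIL"]),
              sum(h$significant[h$population == "IL"])),
      sprintf("- mean confirmation %% (IL): cis %.1f, trans %.1f",
              mean_pct("IL", "cis"), mean_pct("IL", "trans")),
      sprintf("- trans-bands tested: %d, confirmed: %d", length(res$trans_bands),
              sum(vapply(res$trans_bands, function(b)
                isTRUE(b$confirmed), logical(1)))),
      if (!is.null(mix$x1))
        sprintf("- mixture estimate: %.1f additive / %.1f balanced traits",
                mix$x1, mix$x2)
      else "- mixture estimate: not solvable for this environment",
      "")
  }
  lines
}
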