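# end-to-end synthetic study shared by the confirmation tests: planted
# cis-eQTL and one trans-band, near-noiseless so truth is unambiguous
confirmation_fixture <- function(noise_sd = 0.05, seed = 301, n_cis = 15,
                                 n_trans_band = 12) {
  st <- study_panels()
  models <- make_trait_panel(st$map, st$ril, n_cis = n_cis,
                             n_trans_band = n_trans_band,
                             n_balanced = 0, n_noise = 5, seed = seed)
  des <- synthetic_design(environments = "control", noise_sd = noise_sd,
                          seed = seed + 1)
  dat <- generate_expression_dataset(des, models, st$map, st$ril, st$il)
  env <- dat$environments$control
  stats_n2 <- parent_summary_stats(env$IL, "N2")
  list(st = st, models = models, env = env, manifest = dat$manifest,
       z_il = zscore_vs_parent(env$IL, stats_n2),
       r_il = log2_ratio_vs_parent(env$IL, stats_n2),
       eqtls = map_eqtl_single_marker(env$RIL, st$ril))
}

test_that("z-score DE calls behave at the boundary and under BH", {
  z <- matrix(0, 10, 1, dimnames = list(sprintf("s%d", 1:10), "il1"))
  expect_length(per_strain_differential_expression(z, "il1", "counting"), 0)
  # |Z| = 4.417 sits at the two-sided p = 1e-5 boundary of counting mode
  expect_equal(2 * pnorm(-4.41717), 1e-5, tolerance = 1e-4)
  z["s1", 1] <- 4.45; z["s2", 1] <- 4.39
  hits <- per_strain_differential_expression(z, "il1", "counting")
  expect_identical(hits, "s1")
  # one huge z-score among 100 spots survives BH at 0.05 alone
  z2 <- matrix(rnorm(100, 0, 1), 100, 1,
               dimnames = list(sprintf("g%d", 1:100), "il1"))
  z2[37, 1] <- 10
  p <- 2 * pnorm(-abs(z2[, 1]))
  expected <- names(which(bh_oracle(p) < 0.05))
  got <- per_strain_differential_expression(z2, "il1", "confirmation")
  expect_setequal(got, expected)
  expect_true("g37" %in% got)
})

test_that("confirmation percentages are ratios of confirmed to expected eQTL", {
  map <- tiny_map(12, "I")
  g <- matrix(-1L, 2, 12, dimnames = list(c("il1", "il0"), map$marker))
  g["il1", 3:8] <- 1L
  gm <- genotype_matrix(g, "IL", map)
  eqtls <- data.frame(
    spot_id = sprintf("s%d", 1:10), gene_chrom = "I",
    gene_bp = map$pos_bp[1:10], peak_marker = map$marker[c(3:8, 3:4, 10, 11)],
    peak_chrom = "I", peak_bp = map$pos_bp[c(3:8, 3:4, 10, 11)],
    neg_log10_p = 5, effect = 1, ci_start = 1, ci_end = 2,
    environment = "control", type = c(rep("cis", 8), "cis", "cis"),
    stringsAsFactors = FALSE)
  de <- matrix(FALSE, 10, 2, dimnames = list(eqtls$spot_id, c("il1", "il0")))
  de[c("s1", "s2", "s3", "s4", "s7", "s8", "s9"), "il1"] <- TRUE
  rep <- eqtl_confirmation_rate(de, eqtls, gm)
  r1 <- rep[rep$strain == "il1" & rep$type == "cis", ]
  expect_equal(r1$expected, 8L)   # peaks at markers 3..8 carried as CB4856
  expect_equal(r1$confirmed, 6L)  # s1..s4, s7, s8 (s9 peak outside segment)
  expect_equal(r1$percentage, 75)
  # an all-N2 strain expects no eQTL: percentage undefined
  r0 <- rep[rep$strain == "il0" & rep$type == "cis", ]
  expect_equal(r0$expected, 0L)
  expect_true(is.na(r0$percentage))
})

test_that("planted cis-eQTL are mapped and fully confirmed in covering ILs", {
  fx <- confirmation_fixture()
  truth <- fx$manifest[fx$manifest$model == "cis-additive", ]
  mapped <- fx$eqtls[fx$eqtls$type == "cis", ]
  expect_gte(sum(truth$spot_id %in% mapped$spot_id), nrow(truth) - 1)
  il_cols <- grep("^IL", colnames(fx$z_il), value = TRUE)
  de <- de_calls(fx$z_il[, il_cols], "confirmation")
  conf <- eqtl_confirmation_rate(de, mapped, fx$st$il)
  cis_pct <- conf$percentage[conf$type == "cis"]
  expect_gte(mean(cis_pct, na.rm = TRUE), 95)
})

test_that("strain log2 ratios correlate with carried eQTL effects", {
  fx <- confirmation_fixture()
  il_cols <- grep("^IL", colnames(fx$r_il), value = TRUE)
  cors <- do.call(rbind, lapply(il_cols, function(s)
    strain_effect_correlation(fx$r_il, s, fx$eqtls, fx$st$il)))
  cis <- cors[cors$type == "cis", ]
  expect_gte(mean(cis$rho, na.rm = TRUE), 0.9)
  expect_true(all(cis$n[is.na(cis$rho)] < 3))
  # exact degenerate cases: ratios equal to the effects give rho 1,
  # negated ratios give rho -1
  strain <- cis$strain[which(cis$n >= 3)[1]]
  spots <- intersect(rownames(fx$r_il),
                     fx$eqtls$spot_id[fx$eqtls$type == "cis"])
  spots <- spots[unclass(fx$st$il)[strain,
    match(fx$eqtls$peak_marker[match(spots, fx$eqtls$spot_id)],
          colnames(fx$st$il))] == 1L]
  effs <- fx$eqtls$effect[match(spots, fx$eqtls$spot_id)]
  r_exact <- fx$r_il
  r_exact[spots, strain] <- effs
  out <- strain_effect_correlation(r_exact, strain, fx$eqtls, fx$st$il)
  expect_equal(out$rho[out$type == "cis"], 1, tolerance = 1e-12)
  r_exact[spots, strain] <- -effs
  out2 <- strain_effect_correlation(r_exact, strain, fx$eqtls, fx$st$il)
  expect_equal(out2$rho[out2$type == "cis"], -1, tolerance = 1e-12)
})

test_that("trans-bands are confirmed by covering ILs at a low false-positive rate", {
  confirmed <- fp <- numeric(0)
  for (seed in c(311, 322, 333)) {
    fx <- confirmation_fixture(seed = seed)
    bands <- find_trans_bands(fx$eqtls, min_members = 5)
    expect_gte(length(bands), 1L)
    b <- bands[[which.max(vapply(bands, function(x) length(x$spot_id), 0))]]
    il_cols <- grep("^IL", colnames(fx$r_il), value = TRUE)
    n2_cols <- grep("^N2", colnames(fx$r_il), value = TRUE)
    cand <- ils_covering_locus(fx$st$il, b$locus)
    res <- confirm_trans_band(b, cand, fx$r_il[, il_cols],
                              fx$r_il[, n2_cols], fx$st$il)
    confirmed <- c(confirmed, mean(res$per_il$confirmed))
    fp <- c(fp, res$fp_rate)
  }
  expect_gte(mean(confirmed), 0.8)
  # with 4 N2 samples the threshold is the maximum of 4 null correlations,
  # so a null off-band IL exceeds it with probability ~1/5 by exchangeability
  expect_lte(mean(fp), 0.3)
})

test_that("trans-band confirmation requires beating the N2 threshold positively", {
  b <- trans_band("b1", locus_interval("I", 1e6, 2e6),
                  sprintf("s%d", 1:6), c(1, -0.5, 2, 1.5, -1, 0.8))
  set.seed(91)
  r_n2 <- matrix(rnorm(12, 0, 0.1), 6, 2,
                 dimnames = list(sprintf("s%d", 1:6), c("n2a", "n2b")))
  st <- study_panels()
  # an IL mirroring the effects confirms; one anti-correlated does not
  r_il <- cbind(good = b$effect + rnorm(6, 0, 0.05),
                bad = -b$effect + rnorm(6, 0, 0.05),
                weak = rnorm(6, 0, 0.05))
  rownames(r_il) <- b$spot_id
  res <- confirm_trans_band(b, c("good", "bad", "weak"), r_il, r_n2, st$il)
  per <- setNames(res$per_il$confirmed, res$per_il$strain)
  expect_true(per[["good"]])
  expect_false(per[["bad"]])     # negative correlation never confirms
  expect_false(per[["weak"]])    # below the strongest N2 sample
})

test_that("expected-vs-observed DEG normalizes to the RIL expectation", {
  # generous parental replication so the z-score null is close to normal and
  # the counting cutoff (p < 1e-5) is honest; isolates the counting logic
  st <- study_panels()
  models <- make_trait_panel(st$map, st$ril, n_cis = 60, n_trans_band = 12,
                             n_balanced = 0, n_noise = 5, seed = 371)
  des <- synthetic_design(environments = "control", noise_sd = 0.05, seed = 372,
                          n_parent_reps = list(N2 = c(control = 12),
                                               CB4856 = c(control = 12)))
  dat <- generate_expression_dataset(des, models, st$map, st$ril, st$il)
  fx <- list(st = st, env = dat$environments$control, manifest = dat$manifest)
  fx$z_il <- zscore_vs_parent(fx$env$IL, parent_summary_stats(fx$env$IL, "N2"))
  env <- fx$env
  stats_cb <- parent_summary_stats(env$IL, "CB4856")
  z_cb <- zscore_vs_parent(env$IL, stats_cb)
  z_ril_n2 <- zscore_vs_parent(env$RIL, parent_summary_stats(env$RIL, "N2"))
  z_ril_cb <- zscore_vs_parent(env$RIL, stats_cb)
  il_cols <- grep("^IL", colnames(fx$z_il), value = TRUE)
  ril_cols <- grep("^RIL", colnames(z_ril_n2), value = TRUE)
  obs_n2 <- c(colSums(de_calls(fx$z_il[, il_cols], "counting")),
              colSums(de_calls(z_ril_n2[, ril_cols], "counting")))
  obs_cb <- c(colSums(de_calls(z_cb[, il_cols], "counting")),
              colSums(de_calls(z_ril_cb[, ril_cols], "counting")))
  # expectations from the planted truth give the cleanest additive null
  mf <- fx$manifest[fx$manifest$model != "noise", ]
  mk_idx <- match(mf$markers, fx$st$map$marker)
  truth_eqtl <- data.frame(
    spot_id = mf$spot_id, gene_chrom = mf$gene_chrom, gene_bp = mf$gene_bp,
    peak_marker = mf$markers, peak_chrom = fx$st$map$chrom[mk_idx],
    peak_bp = fx$st$map$pos_bp[mk_idx], neg_log10_p = 10,
    effect = as.numeric(mf$effects), ci_start = fx$st$map$pos_bp[mk_idx],
    ci_end = fx$st$map$pos_bp[mk_idx], environment = "control",
    type = ifelse(mf$model == "cis-additive", "cis", "trans"),
    stringsAsFactors = FALSE)
  out <- expected_vs_observed_deg(obs_n2, obs_cb, truth_eqtl,
                                  fx$st$ril, fx$st$il)
  tab <- out$table
  ril_n2 <- tab[tab$panel == "RIL" & tab$reference == "N2", ]
  expect_equal(mean(ril_n2$expected_norm), 1)          # normalization anchor
  # expected DEG per IL vs N2 equals the planted QTL inside its segment
  idx <- match(truth_eqtl$peak_marker, colnames(fx$st$il))
  n_cb <- colSums(t(unclass(fx$st$il))[idx, , drop = FALSE] == 1)
  il_n2 <- tab[tab$panel == "IL" & tab$reference == "N2", ]
  expect_equal(il_n2$expected[match(names(n_cb), il_n2$strain)], unname(n_cb))
  # additive-only data: observed tracks expected (the null contrast to the
  # many-fold discrepancy a closely-linked architecture would produce)
  fold <- out$tests$N2$fold
  expect_gt(fold, 0.6); expect_lt(fold, 1.67)
  # empty eQTL set: expectations zero, test skipped
  empty <- expected_vs_observed_deg(obs_n2, obs_cb, truth_eqtl[0, ],
                                    fx$st$ril, fx$st$il)
  expect_true(all(empty$table$expected == 0))
  expect_true(is.na(empty$tests$N2$p))
})

test_that("strain identity verification flags shuffled and sign-flipped samples", {
  # a dense cis-eQTL panel so most ILs have enough informative spots
  fx <- confirmation_fixture(seed = 351, n_cis = 300, n_trans_band = 0)
  il_cols <- grep("^IL", colnames(fx$r_il), value = TRUE)
  r <- fx$r_il[, il_cols]
  ver <- verify_strain_identity(r, fx$eqtls, fx$st$il)
  ok <- ver[ver$verifiable, ]
  expect_gte(mean(ok$concordance), 0.9)
  expect_false(any(ok$mismatch))
  # sign-flip a well-covered strain: concordance collapses, strain flagged
  victim <- ok$strain[which.max(ok$n_cis)]
  r2 <- r; r2[, victim] <- -r2[, victim]
  ver2 <- verify_strain_identity(r2, fx$eqtls, fx$st$il, min_cis = 3)
  row2 <- ver2[ver2$strain == victim, ]
  expect_lte(row2$concordance, 0.2)
  expect_true(row2$mismatch)
  # give the victim another strain's expression: near-random concordance
  donor <- setdiff(ok$strain, victim)[1]
  r3 <- r; r3[, victim] <- r[, donor]
  ver3 <- verify_strain_identity(r3, fx$eqtls, fx$st$il, min_cis = 3)
  row3 <- ver3[ver3$strain == victim, ]
  expect_true(is.na(row3$concordance) || row3$concordance < 0.75)
})
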