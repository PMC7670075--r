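test_that("architecture specs validate their fields", {
  expect_error(architecture_spec(9, 10), "model must be")
  expect_error(architecture_spec(5, 10), "need cluster_size")
  expect_error(architecture_spec(1, 10, cluster_size = 3), "must be absent")
  expect_error(architecture_spec(3, 10, cluster_size = 7), "2..5")
  expect_error(architecture_spec(1, 0), "n_loci")
})

test_that("trait models realize the requested architectures", {
  st <- study_panels()
  info <- informative_markers(st$ril)
  set.seed(101)
  # model 1, one locus: exactly one QTL, no clustering
  tm1 <- build_trait_model(architecture_spec(1, 1), st$map, informative = info)
  expect_length(tm1$loci$idx, 1L)
  expect_null(tm1$pairs)
  # balanced clusters: member effects sum to exactly zero, members adjacent
  tm5 <- build_trait_model(architecture_spec(5, 4, cluster_size = 3), st$map,
                           informative = info)
  for (cl in unique(tm5$loci$cluster)) {
    sel <- tm5$loci$cluster == cl
    expect_lt(abs(sum(tm5$loci$effect[sel])), 1e-15)
    expect_equal(diff(tm5$loci$idx[sel]), c(1L, 1L))
    expect_length(unique(st$map$chrom[tm5$loci$idx[sel]]), 1L)
  }
  # pairwise balancing cancels within adjacent pairs
  tm5b <- build_trait_model(architecture_spec(5, 3, cluster_size = 5), st$map,
                            informative = info, balance = "pairwise")
  for (cl in unique(tm5b$loci$cluster)) {
    e <- tm5b$loci$effect[tm5b$loci$cluster == cl]
    expect_identical(e[2], -e[1])
    expect_identical(e[4], -e[3])
    expect_identical(e[5], 0)
  }
  # interacting models carry pairs
  tm7 <- build_trait_model(architecture_spec(7, 4), st$map, informative = info)
  expect_length(tm7$pairs$effect, 2L)
  tm8 <- build_trait_model(architecture_spec(8, 2, cluster_size = 4), st$map,
                           informative = info)
  expect_length(tm8$pairs$effect, 4L)  # 2 pairs per 4-member cluster
})

test_that("QTL anchors follow the arm-enriched sampling weights", {
  st <- study_panels()
  info <- informative_markers(st$ril)
  w <- c(arm = 4, center = 1, tip = 1)
  set.seed(102)
  draws <- replicate(4000, build_trait_model(
    architecture_spec(1, 1), st$map, weights = w, informative = info)$loci$idx)
  reg <- as.character(st$map$region[draws])
  marker_w <- unname(w[as.character(st$map$region)]) * info
  expected_arm <- sum(marker_w[st$map$region == "arm"]) / sum(marker_w)
  expect_equal(mean(reg == "arm"), expected_arm, tolerance = 0.02)
})

test_that("genetic values follow the coding rules", {
  map <- tiny_map(10, "I")
  g <- genotype_matrix(matrix(c(rep(-1L, 10),
                                rep(1L, 10),
                                c(rep(-1L, 5), rep(1L, 5))), 3, 10,
                              byrow = TRUE,
                              dimnames = list(c("allN2", "allCB", "split"),
                                              map$marker)),
                       "RIL", map)
  # balanced 2-cluster (+e, -e) spanning the breakpoint of 'split'
  tm <- trait_model(c(5L, 6L), c(0.8, -0.8), cluster = c(1L, 1L))
  v <- genetic_values(tm, g)
  expect_equal(unname(v["allN2"]), 0)    # intact cluster cancels
  expect_equal(unname(v["allCB"]), 0)
  expect_equal(unname(v["split"]), 0.8 * -1 + -0.8 * 1)  # exposed by the split
  # one-genotype effects act only on CB4856 alleles
  tm2 <- trait_model(3L, 1.5, one_genotype = TRUE)
  v2 <- genetic_values(tm2, g)
  expect_equal(unname(v2), c(0, 1.5, 0))
  # interactions multiply codings
  tm3 <- trait_model(integer(0), numeric(0),
                     pairs = list(i = 2L, j = 9L, effect = 2))
  v3 <- genetic_values(tm3, g)
  expect_equal(unname(v3), c(2, 2, -2))
  expect_error(genetic_values(trait_model(99L, 1), g), "reference error")
})

test_that("a single QTL contributes its squared effect to the RIL variance", {
  map <- default_genetic_map()
  big <- simulate_ril_genotypes(map, 2000, seed = 103)
  tm <- trait_model(50L, 1.7)
  v <- genetic_values(tm, big)
  expect_equal(var(v), 1.7^2, tolerance = 0.05)   # var(+-e) at freq ~0.5
})

test_that("noise calibration hits the target heritability", {
  x <- sqrt(0.85 / 2) * c(-1, 1)        # sample variance exactly 0.85
  expect_equal(calibrate_noise(x, 0.85)^2, 0.15, tolerance = 1e-12)
  expect_equal(calibrate_noise(x, 1), 0)
  expect_true(is.na(calibrate_noise(c(1, 1, 1), 0.85)))
  # scaling effects by 2 scales the calibrated sd by 2 (scale equivariance)
  set.seed(104)
  vals <- rnorm(48)
  expect_equal(calibrate_noise(2 * vals, 0.85), 2 * calibrate_noise(vals, 0.85),
               tolerance = 1e-12)
})

test_that("realized heritability of simulated traits matches the target", {
  st <- study_panels()
  d <- rh_distribution(st$map, st$ril, st$il, models = 1,
                       n_loci = c(1, 3, 10, 30, 100), replicates = 400,
                       seed = 105)
  expect_equal(mean(d$h2_realized, na.rm = TRUE), 0.85, tolerance = 0.01)
  d2 <- rh_distribution(st$map, st$ril, st$il, models = 5, n_loci = c(2, 10),
                        cluster_sizes = c(2, 4), replicates = 300, seed = 106,
                        calibration = "per_batch")
  expect_equal(mean(d2$h2_realized, na.rm = TRUE), 0.85, tolerance = 0.02)
})

test_that("R_H simulations are reproducible and architecture-sensitive", {
  st <- study_panels()
  d1a <- rh_distribution(st$map, st$ril, st$il, models = 1, n_loci = c(2, 20),
                         replicates = 300, seed = 107)
  d1b <- rh_distribution(st$map, st$ril, st$il, models = 1, n_loci = c(2, 20),
                         replicates = 300, seed = 107)
  expect_identical(d1a$rh, d1b$rh)      # full determinism contract
  # balanced clusters widen the distribution at matched n_loci
  d5 <- rh_distribution(st$map, st$ril, st$il, models = 5, n_loci = c(2, 20),
                        cluster_sizes = 3, replicates = 300, seed = 108)
  for (L in c(2, 20)) {
    iqr1 <- IQR(d1a$rh[d1a$n_loci == L], na.rm = TRUE)
    iqr5 <- IQR(d5$rh[d5$n_loci == L], na.rm = TRUE)
    expect_gt(iqr5, iqr1)
    expect_lt(median(d1a$rh[d1a$n_loci == L]), 0)
  }
  # zero-variance traits: skipped mode drops and counts them
  d5s <- rh_distribution(st$map, st$ril, st$il, models = 5, n_loci = 1,
                         cluster_sizes = 2, replicates = 200, seed = 109,
                         zero_variance = "skip")
  zv <- attr(d5s, "zero_var")
  expect_equal(nrow(d5s) + sum(zv$zero_var), 200L)
  expect_gt(sum(zv$zero_var), 0)
  # retained cryptic traits appear with NA realized heritability
  d5r <- rh_distribution(st$map, st$ril, st$il, models = 5, n_loci = 1,
                         cluster_sizes = 2, replicates = 200, seed = 109)
  expect_equal(nrow(d5r), 200L)
  expect_gt(sum(is.na(d5r$h2_realized)), 0)
})

test_that("noise-dominated traits have variance ratios near zero", {
  st <- study_panels()
  d <- rh_distribution(st$map, st$ril, st$il, models = 1, n_loci = 5,
                       replicates = 300, seed = 110, target_h2 = 0.02)
  expect_lt(abs(median(d$rh)), 0.25)
})
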