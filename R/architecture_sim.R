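#' Trait architecture specification
#'
#' The eight simulated QTL architectures:
#' \enumerate{
#'   \item additive QTL at random informative markers
#'   \item additive QTL active in one genotype only (CB4856)
#'   \item clusters of closely linked QTL with random effects
#'   \item clusters of closely linked QTL active in one genotype only
#'   \item clusters of closely linked QTL balanced within the ancestral
#'     genotypes (within-cluster effects sum to zero)
#'   \item balanced clusters active in one genotype only
#'   \item randomly distributed interacting QTL
#'   \item clusters of closely linked interacting QTL
#' }
#' Cluster members occupy consecutive markers, so they only separate when a
#' recombination breakpoint happens to fall inside the cluster.
#'
#' @param model architecture id 1-8.
#' @param n_loci number of QTL (or clusters), 1-100.
#' @param cluster_size QTL per cluster, 2-5 (cluster models only; must be
#'   absent otherwise).
#' @param replicates simulated traits per (model, n_loci) combination
#'   (33331 in the source protocol; 2000 is the desk-scale default).
#' @param target_h2 mean heritability the residual noise is calibrated to
#'   (default 0.85).
#' @return an `architecture_spec` list.
#' @export
architecture_spec <- function(model, n_loci, cluster_size = NULL,
                              replicates = 2000, target_h2 = 0.85) {
  if (!model %in% 1:8) stopf("model must be 1..8")
  clustered <- model %in% c(3, 4, 5, 6, 8)
  if (clustered && is.null(cluster_size))
    stopf("cluster models need cluster_size (2..5)")
  if (!clustered && !is.null(cluster_size))
    stopf("cluster_size must be absent for non-cluster models")
  if (!is.null(cluster_size) && !cluster_size %in% 2:5)
    stopf("cluster_size must be in 2..5")
  if (n_loci < 1 || n_loci > 100) stopf("n_loci must be in 1..100")
  if (replicates < 1) stopf("replicates must be >= 1")
  structure(list(model = as.integer(model), n_loci = as.integer(n_loci),
                 cluster_size = cluster_size, replicates = as.integer(replicates),
                 target_h2 = target_h2),
            class = "architecture_spec")
}

model_names <- c("additive", "additive-one-genotype", "linked-clusters-random",
                 "linked-clusters-one-genotype", "linked-clusters-balanced",
                 "linked-clusters-balanced-one-genotype", "interacting-random",
                 "interacting-linked-clusters")

#' Trait model: realized QTL positions and effects
#'
#' @param loci_idx marker indices of the QTL.
#' @param effect additive effect per QTL (0 for purely interacting QTL).
#' @param cluster cluster membership per QTL.
#' @param one_genotype if `TRUE` effects act only when the allele is CB4856
#'   (the choice of CB4856 is arbitrary and symmetric under relabelling).
#' @param pairs optional interaction terms: list with `i`, `j` (marker
#'   indices) and `effect`; the epistatic form is the pairwise product of
#'   the -1/+1 allele codings, the minimal two-locus interaction.
#' @param sigma_e residual sd on the trait (log2) scale, or `NULL`.
#' @param gene_chrom,gene_bp optional gene position for the spot carrying
#'   this trait.
#' @param model label of the generating architecture.
#' @return a `trait_model` list.
#' @export
trait_model <- function(loci_idx, effect, cluster = seq_along(loci_idx),
                        one_genotype = FALSE, pairs = NULL, sigma_e = NULL,
                        gene_chrom = NULL, gene_bp = NULL, model = "custom") {
  structure(list(loci = list(idx = as.integer(loci_idx), effect = as.numeric(effect),
                             cluster = cluster),
                 one_genotype = one_genotype, pairs = pairs, sigma_e = sigma_e,
                 gene_chrom = gene_chrom, gene_bp = gene_bp, model = model),
            class = "trait_model")
}

#' Markers informative for QTL placement
#'
#' Markers segregating in the RIL panel (both alleles present); QTL are
#' placed only on such markers.
#'
#' @param ril_geno RIL [genotype_matrix()].
#' @return logical vector over markers.
#' @export
informative_markers <- function(ril_geno) {
  cb <- colSums(unclass(ril_geno) > 0)
  cb > 0 & cb < nrow(ril_geno)
}

# Sampling weights per marker: region weight x informativeness.
region_weights <- function(map, weights, informative) {
  w <- unname(weights[as.character(map$region)]) * informative
  if (all(w == 0)) stopf("no informative markers to place QTL on")
  w
}

# Anchor eligibility for clusters of size k: all members on one chromosome.
cluster_anchor_ok <- function(map, k) {
  n <- nrow(map)
  ok <- logical(n)
  idx <- seq_len(n - k + 1L)
  ok[idx] <- map$chrom[idx] == map$chrom[idx + k - 1L]
  ok
}

#' Build one trait model under an architecture
#'
#' QTL (or cluster anchors) are sampled with arm-enriched probabilities
#' over the informative markers, reproducing the enrichment of QTL on the
#' chromosome arms; effects are drawn from N(0, 1). Balanced clusters are
#' re-centred so the within-cluster effects sum exactly to zero; interaction
#' models pair loci and act through products of the allele codings.
#'
#' @param spec an [architecture_spec()].
#' @param map a [genetic_map()] with region classes.
#' @param weights sampling weight per region class (default arm 4,
#'   center 1, tip 1).
#' @param informative logical per marker (see [informative_markers()]);
#'   default all markers.
#' @param balance balanced-cluster scheme: `"zero_sum"` (recentre to an
#'   exact zero sum, default) or `"pairwise"` (paired sign-flipped effects;
#'   the unpaired member of odd-sized clusters gets effect 0).
#' @return a [trait_model()].
#' @export
build_trait_model <- function(spec, map,
                              weights = c(arm = 4, center = 1, tip = 1),
                              informative = rep(TRUE, nrow(map)),
                              balance = c("zero_sum", "pairwise")) {
  balance <- match.arg(balance)
  w <- region_weights(map, weights, informative)
  m <- spec$model
  L <- spec$n_loci
  if (m %in% c(1, 2, 7)) {
    idx <- sample.int(nrow(map), L, replace = TRUE, prob = w)
    if (m == 7) {
      npair <- L %/% 2L
      pairs <- if (npair > 0)
        list(i = idx[2 * seq_len(npair) - 1L], j = idx[2 * seq_len(npair)],
             effect = stats::rnorm(npair))
      else NULL
      leftover <- if (L %% 2L) idx[L] else integer(0)
      eff <- numeric(L)
      if (length(leftover)) eff[L] <- stats::rnorm(1L)
      return(trait_model(idx, eff, cluster = seq_len(L), pairs = pairs,
                         model = model_names[m]))
    }
    return(trait_model(idx, stats::rnorm(L), cluster = seq_len(L),
                       one_genotype = m == 2, model = model_names[m]))
  }
  # cluster models: anchors such that the cluster stays on one chromosome
  k <- spec$cluster_size
  wk <- w * cluster_anchor_ok(map, k)
  anchors <- sample.int(nrow(map), L, replace = TRUE, prob = wk)
  idx <- rep(anchors, each = k) + rep(0:(k - 1L), L)
  cluster <- rep(seq_len(L), each = k)
  eff <- stats::rnorm(L * k)
  if (m %in% c(5, 6)) {
    em <- matrix(eff, k, L)
    if (balance == "zero_sum") {
      em <- em - rep(colMeans(em), each = k)
      em[k, ] <- -colSums(em[-k, , drop = FALSE])   # exact zero sum
    } else {
      half <- k %/% 2L
      base <- em[seq_len(half), , drop = FALSE]
      em[] <- 0
      em[2L * seq_len(half) - 1L, ] <- base      # adjacent members cancel
      em[2L * seq_len(half), ] <- -base
    }
    eff <- as.vector(em)
  }
  if (m == 8) {
    # consecutive cluster members interact pairwise; odd member stays additive
    npair <- k %/% 2L
    i_off <- 2 * seq_len(npair) - 2L
    pairs <- list(
      i = rep(anchors, each = npair) + rep(i_off, L),
      j = rep(anchors, each = npair) + rep(i_off + 1L, L),
      effect = stats::rnorm(npair * L))
    eff <- numeric(L * k)
    if (k %% 2L) {                                   # last member additive
      em <- matrix(eff, k, L)
      em[k, ] <- stats::rnorm(L)
      eff <- as.vector(em)
    }
    return(trait_model(idx, eff, cluster = cluster, pairs = pairs,
                       model = model_names[m]))
  }
  trait_model(idx, eff, cluster = cluster, one_genotype = m %in% c(4, 6),
              model = model_names[m])
}

#' Genetic value of a trait model on a genotype panel
#'
#' Additive part: sum over QTL of effect times the -1/+1 allele coding
#' (one-genotype effects use the 0/1 CB4856 indicator instead). Interaction
#' part: sum over pairs of effect times the product of the two codings.
#'
#' @param tm a [trait_model()].
#' @param g a [genotype_matrix()].
#' @return numeric vector, one genetic value per strain.
#' @export
genetic_values <- function(tm, g) {
  x <- unclass(g)
  if (length(tm$loci$idx) && max(tm$loci$idx) > ncol(x))
    stopf("reference error: trait model references marker outside the panel")
  v <- numeric(nrow(x))
  if (length(tm$loci$idx)) {
    coding <- x[, tm$loci$idx, drop = FALSE]
    if (tm$one_genotype) coding <- (coding + 1) / 2
    v <- drop(coding %*% tm$loci$effect)
  }
  if (!is.null(tm$pairs) && length(tm$pairs$i)) {
    prod_code <- x[, tm$pairs$i, drop = FALSE] * x[, tm$pairs$j, drop = FALSE]
    v <- v + drop(prod_code %*% tm$pairs$effect)
  }
  stats::setNames(v, rownames(x))
}

#' Residual noise calibrated to a target heritability
#'
#' `sigma_e = sqrt(var_G * (1 - h2) / h2)` with `var_G` the genetic variance
#' across the RIL panel, so that `var_G / (var_G + sigma_e^2)` equals the
#' target. Traits with (numerically) zero genetic variance are not
#' calibratable and return `NA` (they are skipped and counted by the
#' simulation driver).
#'
#' @param ril_values genetic values on the RIL panel.
#' @param target_h2 target heritability (default 0.85; 1 means no noise).
#' @param effect_scale sum of squared model effects, used for the relative
#'   zero-variance tolerance.
#' @return residual standard deviation, or `NA` if not calibratable.
#' @export
calibrate_noise <- function(ril_values, target_h2 = 0.85, effect_scale = 1) {
  v <- stats::var(ril_values)
  if (v <= max(1e-300, 1e-18 * effect_scale)) return(NA_real_)
  sqrt(v * (1 - target_h2) / target_h2)
}

#' Relative-heritability distributions under simulated architectures
#'
#' For every (model, n_loci, cluster_size) combination, `replicates` traits
#' are simulated: a trait model is built on the map, genetic values are
#' computed on both panels, residual Gaussian noise calibrated to
#' `target_h2` is added to every strain, and
#' `R_H = log2(var_IL / var_RIL)` is recorded together with the realized
#' heritability on the RIL panel. Traits whose genetic variance in the RIL
#' panel is zero (e.g. a balanced cluster split by no RIL) cannot be
#' calibrated and are skipped and counted.
#'
#' @param map a [genetic_map()].
#' @param ril,il the genotype panels.
#' @param models architecture ids (subset of 1-8).
#' @param n_loci vector of QTL/cluster counts (default 1:100).
#' @param cluster_sizes cluster sizes for cluster models (default 2:5).
#' @param replicates traits per combination (default 2000).
#' @param target_h2 calibration target (default 0.85).
#' @param weights region sampling weights.
#' @param seed optional integer seed.
#' @param calibration `"per_trait"` (default: exact per-trait noise) or
#'   `"per_batch"` (one `sigma_e` per combination solving for the batch mean
#'   heritability over the calibratable traits).
#' @param zero_variance what to do with traits whose RIL-panel genetic
#'   variance is zero (e.g. a balanced cluster no RIL recombination has
#'   split): `"retain"` (default) keeps them with the batch-typical residual
#'   noise — these are the cryptic-variation traits, invisible in the RIL
#'   panel but potentially exposed by an IL breakpoint — with
#'   `h2_realized = NA`; `"skip"` drops and counts them.
#' @param balance balanced-cluster scheme, see [build_trait_model()].
#' @return an `rh_distribution`: data.frame `model`, `n_loci`,
#'   `cluster_size`, `replicate`, `rh`, `h2_realized`, with attribute
#'   `zero_var` (count of zero-genetic-variance traits per combination,
#'   retained or skipped according to `zero_variance`).
#' @export
rh_distribution <- function(map, ril, il, models = c(1, 5), n_loci = 1:100,
                            cluster_sizes = 2:5, replicates = 2000,
                            target_h2 = 0.85,
                            weights = c(arm = 4, center = 1, tip = 1),
                            seed = NULL,
                            calibration = c("per_trait", "per_batch"),
                            zero_variance = c("retain", "skip"),
                            balance = c("zero_sum", "pairwise")) {
  calibration <- match.arg(calibration)
  zero_variance <- match.arg(zero_variance)
  balance <- match.arg(balance)
  if (!is.null(seed)) set.seed(seed)
  informative <- informative_markers(ril)
  n_ril <- nrow(ril); n_il <- nrow(il)
  batches <- list()
  skipped <- list()
  for (m in models) {
    sizes <- if (m %in% c(3, 4, 5, 6, 8)) cluster_sizes else NA_integer_
    for (k in sizes) {
      for (L in n_loci) {
        spec <- architecture_spec(m, L, if (is.na(k)) NULL else k,
                                  replicates, target_h2)
        gr <- matrix(0, n_ril, replicates)
        gi <- matrix(0, n_il, replicates)
        scale2 <- numeric(replicates)
        for (rep_i in seq_len(replicates)) {
          tm <- build_trait_model(spec, map, weights, informative, balance)
          gr[, rep_i] <- genetic_values(tm, ril)
          gi[, rep_i] <- genetic_values(tm, il)
          scale2[rep_i] <- sum(tm$loci$effect^2) +
            if (is.null(tm$pairs)) 0 else sum(tm$pairs$effect^2)
        }
        vG <- col_vars(gr)
        calibratable <- vG > pmax(1e-300, 1e-18 * scale2)
        n_zero <- sum(!calibratable)
        if (zero_variance == "skip") {
          gr <- gr[, calibratable, drop = FALSE]
          gi <- gi[, calibratable, drop = FALSE]
          vG <- vG[calibratable]
          calibratable <- rep(TRUE, length(vG))
        } else if (any(!calibratable)) {
          # cryptic traits carry no genetic signal in the RIL panel; wipe the
          # ~1e-16 rounding residue of intact zero-sum clusters
          gr[, !calibratable] <- 0
          vG[!calibratable] <- 0
        }
        nk <- length(vG)
        if (nk == 0L || !any(calibratable)) {
          skipped[[length(skipped) + 1L]] <-
            data.frame(model = m, n_loci = L, cluster_size = k, zero_var = n_zero)
          next
        }
        if (calibration == "per_trait") {
          sig <- sqrt(vG * (1 - target_h2) / target_h2)
          sig[!calibratable] <- stats::median(sig[calibratable])
        } else {
          s2 <- batch_noise_variance(vG[calibratable], target_h2)
          sig <- rep(sqrt(s2), nk)
        }
        noise_r <- matrix(stats::rnorm(n_ril * nk), n_ril, nk) *
          rep(sig, each = n_ril)
        noise_i <- matrix(stats::rnorm(n_il * nk), n_il, nk) *
          rep(sig, each = n_il)
        v_ril <- col_vars(gr + noise_r)
        v_il <- col_vars(gi + noise_i)
        rh <- log2(v_il / v_ril)
        h2r <- ifelse(calibratable, vG / (vG + col_vars(noise_r)), NA_real_)
        batches[[length(batches) + 1L]] <- data.frame(
          model = m, n_loci = L, cluster_size = k,
          replicate = seq_len(nk), rh = rh, h2_realized = h2r)
        skipped[[length(skipped) + 1L]] <-
          data.frame(model = m, n_loci = L, cluster_size = k, zero_var = n_zero)
      }
    }
  }
  if (!length(batches)) stopf("all replicates had zero genetic variance")
  out <- do.call(rbind, batches)
  rownames(out) <- NULL
  attr(out, "zero_var") <- do.call(rbind, skipped)
  class(out) <- c("rh_distribution", "data.frame")
  out
}

# per-batch noise variance: solve mean(vG / (vG + s2)) = h2 for s2 >= 0.
# The batch mean heritability cannot exceed 1 and is decreasing in s2; if
# even s2 = 0 cannot reach the target (it always can unless vG has zeros,
# which are filtered before), uniroot brackets are widened as needed.
batch_noise_variance <- function(vG, target_h2) {
  f <- function(s2) mean(vG / (vG + s2)) - target_h2
  if (f(0) <= 0) return(0)
  hi <- stats::median(vG) * (1 - target_h2) / target_h2 + 1e-12
  while (f(hi) > 0) hi <- hi * 4
  stats::uniroot(f, c(0, hi), tol = 1e-12)$root
}

#' Percentile summary of an R_H distribution
#'
#' @param draws an `rh_distribution` (or any data.frame with `rh`).
#' @param probs percentiles (default 2.5, 50, 97.5).
#' @param pooled if `TRUE` (default) pool all replicates; otherwise
#'   summarize per (model, n_loci, cluster_size) combination.
#' @return data.frame of percentiles.
#' @export
rh_summary <- function(draws, probs = c(0.025, 0.5, 0.975), pooled = TRUE) {
  qf <- function(d) {
    q <- stats::quantile(d$rh[is.finite(d$rh)], probs, names = FALSE)
    stats::setNames(as.data.frame(as.list(q)), paste0("p", probs * 100))
  }
  if (pooled) return(qf(draws))
  ksz <- ifelse(is.na(draws$cluster_size), 0L, draws$cluster_size)
  parts <- split(draws, interaction(draws$model, draws$n_loci, ksz, drop = TRUE))
  out <- do.call(rbind, lapply(parts, function(d)
    cbind(d[1L, c("model", "n_loci", "cluster_size")], qf(d))))
  rownames(out) <- NULL
  out
}
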