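#' Per-spot parental summary statistics
#'
#' Mean and sample standard deviation (n-1 denominator) of the normalized
#' intensity across the replicates of one parental strain, computed per spot
#' within one environment. These are the reference quantities for the
#' z-score and log2-ratio transforms.
#'
#' @param es an [expression_set()] containing `>= 2` replicates of `parent`.
#' @param parent `"N2"` or `"CB4856"`.
#' @return data.frame with columns `spot_id`, `mu`, `sd` and attribute
#'   `parent`.
#' @export
parent_summary_stats <- function(es, parent = c("N2", "CB4856")) {
  parent <- match.arg(parent)
  reps <- group_values(es, parent)
  if (ncol(reps) < 2L)
    stopf("insufficient replicates: %d %s sample(s) in environment '%s'",
          ncol(reps), parent, es$environment)
  out <- data.frame(spot_id = es$spots$spot_id, mu = rowMeans(reps),
                    sd = sqrt(row_vars(reps)), stringsAsFactors = FALSE)
  attr(out, "parent") <- parent
  out
}

#' Z-score of expression against a parental reference
#'
#' `Z[i, j] = (I[i, j] - mu[i, P]) / sd[i, P]` for reference parent P. With
#' P = N2 this exposes the effect of CB4856 introgressions in the ILs; with
#' P = CB4856 the effect of the genetic background. Spots with zero parental
#' standard deviation are flagged missing (`NA`) with a warning. The values
#' are descriptive, not significances.
#'
#' @param es an [expression_set()].
#' @param stats output of [parent_summary_stats()] from the same environment.
#' @return numeric matrix spots x samples with attribute `reference`.
#' @export
zscore_vs_parent <- function(es, stats) {
  if (!identical(stats$spot_id, es$spots$spot_id))
    stopf("spot ids of stats and expression set disagree")
  z <- (es$values - stats$mu) / stats$sd
  zero <- stats$sd == 0
  if (any(zero)) {
    warnf("%d spot(s) with zero parental sd flagged missing", sum(zero))
    z[zero, ] <- NA_real_
  }
  attr(z, "reference") <- attr(stats, "parent")
  z
}

#' Log2 ratio of expression to the parental mean
#'
#' `R[i, j] = log2(I[i, j] / mu[i, P])`; the scale on which eQTL effects are
#' expressed, used when comparing strain-level differential expression with
#' eQTL effect sizes. Nonpositive intensities or reference means are flagged
#' missing.
#'
#' @inheritParams zscore_vs_parent
#' @return numeric matrix spots x samples with attribute `reference`.
#' @export
log2_ratio_vs_parent <- function(es, stats) {
  if (!identical(stats$spot_id, es$spots$spot_id))
    stopf("spot ids of stats and expression set disagree")
  r <- log2(es$values / stats$mu)
  bad <- stats$mu <= 0
  if (any(bad)) {
    warnf("%d spot(s) with nonpositive reference mean flagged missing", sum(bad))
    r[bad, ] <- NA_real_
  }
  attr(r, "reference") <- attr(stats, "parent")
  r
}

#' Parental differential expression
#'
#' Per-spot two-group contrast of log2 intensity between the N2 and CB4856
#' replicates: the linear model `log2(I) ~ G + e`, which for a two-level
#' genotype factor is the pooled-variance two-sample t-test (a Welch variant
#' is available). P-values are Benjamini-Hochberg adjusted across spots and
#' significance is called at `q < fdr`.
#'
#' @param es an [expression_set()] with `>= 2` replicates of each parent.
#' @param fdr BH false-discovery-rate threshold (default 0.1).
#' @param var_equal pooled variance (`TRUE`, the linear-model contrast) or
#'   Welch (`FALSE`).
#' @return data.frame `spot_id`, `effect` (log2 CB4856 - N2), `p`, `q`,
#'   `significant`.
#' @export
parental_differential_expression <- function(es, fdr = 0.1, var_equal = TRUE) {
  xN2 <- log2(group_values(es, "N2"))
  xCB <- log2(group_values(es, "CB4856"))
  n1 <- ncol(xN2); n2 <- ncol(xCB)
  if (n1 < 2L || n2 < 2L) stopf("insufficient replicates for parental contrast")
  m1 <- rowMeans(xN2); m2 <- rowMeans(xCB)
  v1 <- row_vars(xN2); v2 <- row_vars(xCB)
  effect <- m2 - m1
  if (var_equal) {
    vp <- pooled_parent_variance(v1, n1, v2, n2)
    se <- sqrt(vp * (1 / n1 + 1 / n2))
    df <- n1 + n2 - 2L
  } else {
    se <- sqrt(v1 / n1 + v2 / n2)
    df <- (v1 / n1 + v2 / n2)^2 /
      ((v1 / n1)^2 / (n1 - 1L) + (v2 / n2)^2 / (n2 - 1L))
  }
  t_stat <- effect / se
  p <- 2 * stats::pt(-abs(t_stat), df)
  # degenerate spots: no variance in either group
  degen <- se == 0
  p[degen & effect == 0] <- 1
  p[degen & effect != 0] <- 0
  q <- stats::p.adjust(p, method = "BH")
  data.frame(spot_id = es$spots$spot_id, effect = effect, p = p, q = q,
             significant = q < fdr, stringsAsFactors = FALSE, row.names = NULL)
}
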