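#' Count R_H values inside the peak and intersect intervals
#'
#' The two diagnostic intervals are where the additive and
#' balanced-closely-linked R_H distributions differ most: the additive peak
#' `(-3, -2)` and the intersect `(0.5, 1.5)`. Intervals are open by default
#' (boundary values count in neither); a closed-interval option is
#' available.
#'
#' @param rh numeric vector of R_H values (non-finite values are ignored).
#' @param intervals named list of `c(lower, upper)` intervals.
#' @param closed use closed intervals (default `FALSE`).
#' @return named integer vector of counts.
#' @export
interval_counts <- function(rh,
                            intervals = list(peak = c(-3, -2),
                                             intersect = c(0.5, 1.5)),
                            closed = FALSE) {
  rh <- rh[is.finite(rh)]
  vapply(intervals, function(iv) {
    if (closed) sum(rh >= iv[1] & rh <= iv[2])
    else sum(rh > iv[1] & rh < iv[2])
  }, 0L)
}

#' Expected interval counts per architecture model
#'
#' For each simulated architecture (a (n_loci, cluster_size) combination of
#' one model) the per-replicate probability of falling in each interval is
#' computed; the median across architectures is taken — an estimate less
#' dependent on the simulation grid — and scaled to the observed number of
#' heritable traits.
#'
#' @param draws an [rh_distribution()] containing the model's replicates.
#' @param model architecture id to extract.
#' @param n_heritable number of observed heritable traits to scale to.
#' @inheritParams interval_counts
#' @return list with `expected` (scaled counts per interval), `prob`
#'   (median interval probabilities).
#' @export
model_expectations <- function(draws, model, n_heritable,
                               intervals = list(peak = c(-3, -2),
                                                intersect = c(0.5, 1.5)),
                               closed = FALSE) {
  sub <- draws[draws$model == model, , drop = FALSE]
  if (!nrow(sub)) stopf("no replicates for model %s in draws", model)
  ksz <- ifelse(is.na(sub$cluster_size), 0L, sub$cluster_size)
  parts <- split(sub, interaction(sub$n_loci, ksz, drop = TRUE))
  probs <- t(vapply(parts, function(d) {
    n_valid <- sum(is.finite(d$rh))
    interval_counts(d$rh, intervals, closed) / n_valid
  }, numeric(length(intervals))))
  med <- apply(probs, 2L, stats::median)
  if (all(med == 0))
    warnf("model %s has zero probability in both intervals (singular expectation)",
          model)
  list(expected = med * n_heritable, prob = med)
}

#' Solve the two-interval mixture for additive vs balanced trait counts
#'
#' Solves `a_peak * x1 + b_peak * x2 = c_peak` and
#' `a_intersect * x1 + b_intersect * x2 = c_intersect` exactly, where `a`
#' and `b` are the expected counts under the additive and balanced
#' closely-linked models and `c` the observed counts of heritable traits.
#' `x1` is the estimated number of additive traits, `x2` of balanced
#' closely-linked traits. Negative solutions are reported as-is, flagged
#' invalid, and excluded from the fraction computation with a warning.
#'
#' @param a,b,c length-2 numeric vectors `(peak, intersect)`.
#' @param cond_max maximum acceptable condition number of the 2x2 system.
#' @return a `mixture_estimate`: list with `a`, `b`, `c`, `x1`, `x2`,
#'   `fraction_additive`, `fraction_balanced`, `valid`, `condition`.
#' @export
solve_mixture <- function(a, b, c, cond_max = 1e8) {
  M <- cbind(a, b)
  if (any(!is.finite(M)) || any(!is.finite(c)))
    stopf("solver error: non-finite expectations or counts")
  cond <- kappa(M, exact = TRUE)
  if (!is.finite(cond) || cond > cond_max)
    stopf("solver error: system singular or ill-conditioned (condition number %.3g)",
          cond)
  x <- solve(M, c)
  valid <- all(x >= 0)
  if (valid) {
    fr <- x / sum(x)
  } else {
    warnf("negative solved count(s); excluded from fraction computation")
    pos <- x >= 0
    fr <- rep(NA_real_, 2L)
    fr[pos] <- 1
  }
  structure(list(a = a, b = b, c = c, x1 = unname(x[1L]), x2 = unname(x[2L]),
                 fraction_additive = unname(fr[1L]),
                 fraction_balanced = unname(fr[2L]),
                 valid = valid, condition = cond),
            class = "mixture_estimate")
}

#' @export
print.mixture_estimate <- function(x, ...) {
  cat(sprintf(paste0("<mixture_estimate> x1 (additive) = %.1f, x2 (balanced) = %.1f",
                     " | fractions %.1f%% / %.1f%%%s\n"),
              x$x1, x$x2, 100 * x$fraction_additive, 100 * x$fraction_balanced,
              if (x$valid) "" else " [invalid: negative count]"))
  invisible(x)
}

#' Deconvolve an observed R_H distribution into additive and balanced parts
#'
#' End-to-end wrapper: counts the observed heritable traits in the peak and
#' intersect intervals, derives expected counts for the additive (model 1)
#' and balanced closely-linked (model 5) architectures from simulation
#' draws, and solves the 2x2 system.
#'
#' @param observed_rh R_H values of traits with significant heritability.
#' @param sim_draws an [rh_distribution()] containing models 1 and 5.
#' @inheritParams interval_counts
#' @return a `mixture_estimate` (see [solve_mixture()]).
#' @export
deconvolve_rh <- function(observed_rh,
                          sim_draws,
                          intervals = list(peak = c(-3, -2),
                                           intersect = c(0.5, 1.5)),
                          closed = FALSE) {
  n_heritable <- sum(is.finite(observed_rh))
  cc <- interval_counts(observed_rh, intervals, closed)
  a <- model_expectations(sim_draws, 1, n_heritable, intervals, closed)$expected
  b <- model_expectations(sim_draws, 5, n_heritable, intervals, closed)$expected
  solve_mixture(a, b, cc)
}
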