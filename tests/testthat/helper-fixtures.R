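# Shared fixtures, all built in code.

tiny_map <- function(n_per_chrom = 10, chroms = c("I", "II"),
                     length_bp = 9e6) {
  pos <- round(seq(1, length_bp, length.out = n_per_chrom))
  genetic_map(
    marker = paste0(rep(chroms, each = n_per_chrom), "m",
                    rep(seq_len(n_per_chrom), length(chroms))),
    chrom = rep(chroms, each = n_per_chrom),
    pos_bp = rep(pos, length(chroms)))
}

# default full-size study panels, cached per test run
study_env <- new.env()
study_panels <- function() {
  if (is.null(study_env$map)) {
    study_env$map <- default_genetic_map()
    study_env$ril <- simulate_ril_genotypes(study_env$map, 48, seed = 181)
    study_env$il <- simulate_il_genotypes(study_env$map, 57, seed = 182)
  }
  study_env
}

# hand expression set: values (spots x samples), groups per sample
manual_es <- function(values, groups, spots_chrom = NULL, spots_bp = NULL,
                      environment = "control") {
  n_spot <- nrow(values)
  spots <- data.frame(
    spot_id = rownames(values) %||% sprintf("s%03d", seq_len(n_spot)),
    chrom = spots_chrom %||% rep(NA_character_, n_spot),
    bp = spots_bp %||% rep(NA_real_, n_spot), stringsAsFactors = FALSE)
  samples <- data.frame(
    sample = colnames(values) %||% sprintf("smp%03d", seq_along(groups)),
    strain = colnames(values) %||% sprintf("smp%03d", seq_along(groups)),
    group = groups, stringsAsFactors = FALSE)
  rownames(values) <- spots$spot_id
  colnames(values) <- samples$sample
  expression_set(values, spots, samples, environment)
}

`%||%` <- function(a, b) if (is.null(a)) b else a

# brute-force BH step-up, straight from the procedure definition
bh_oracle <- function(p) {
  m <- length(p)
  o <- order(p)
  adj <- p[o] * m / seq_len(m)
  adj <- rev(cummin(rev(adj)))
  adj <- pmin(adj, 1)
  out <- numeric(m)
  out[o] <- adj
  names(out) <- names(p)
  out
}

# independent pearson correlation from the covariance formula
pearson_oracle <- function(x, y) {
  mx <- mean(x); my <- mean(y)
  sum((x - mx) * (y - my)) /
    sqrt(sum((x - mx)^2) * sum((y - my)^2))
}
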