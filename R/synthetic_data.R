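#' Design of a synthetic RIL/IL transcriptomics experiment
#'
#' Mirrors the layout of the N2 x CB4856 microarray experiments: 48 RILs and
#' 57 tiling ILs measured once per environment, plus a few parental
#' replicates per environment (N2: 4/4/3, CB4856: 3/3/5 for control,
#' heat-stress and recovery). Expression is generated on a log2 scale around
#' a baseline and exponentiated, so downstream log2-ratio transforms recover
#' the planted effects.
#'
#' @param n_rils,n_ils panel sizes.
#' @param environments environment labels.
#' @param n_parent_reps named list (`N2`, `CB4856`) of per-environment
#'   replicate counts (each `>= 2` so parental variance is estimable).
#' @param noise_sd residual standard deviation on the log2 scale, applied to
#'   every spot whose trait model does not carry its own `sigma_e`.
#' @param baseline_log2 baseline log2 intensity.
#' @param seed integer seed; the seed and design fully determine the output.
#' @return A `synthetic_design` list.
#' @export
synthetic_design <- function(n_rils = 48, n_ils = 57,
                             environments = c("control", "heatstress", "recovery"),
                             n_parent_reps = list(
                               N2 = c(control = 4, heatstress = 4, recovery = 3),
                               CB4856 = c(control = 3, heatstress = 3, recovery = 5)),
                             noise_sd = 0.2, baseline_log2 = 10, seed = 1L) {
  for (p in names(n_parent_reps)) {
    reps <- n_parent_reps[[p]]
    if (is.null(names(reps))) names(n_parent_reps[[p]]) <- names(reps) <- environments
    if (any(reps < 2))
      stopf("design error: need >=2 parental replicates (%s)", p)
  }
  structure(list(n_rils = n_rils, n_ils = n_ils, environments = environments,
                 n_parent_reps = n_parent_reps, noise_sd = noise_sd,
                 baseline_log2 = baseline_log2, seed = as.integer(seed)),
            class = "synthetic_design")
}

#' Simulate a RIL genotype panel
#'
#' Each strain is a homozygous mosaic built per chromosome: a Poisson number
#' of crossovers is placed uniformly along the chromosome and the parental
#' phase alternates from a random start. This is a single-meiosis shortcut
#' for selfing to fixation; downstream statistics depend only on the mosaic
#' structure. Expected CB4856 allele frequency is 0.5 at every marker.
#'
#' @param map a [genetic_map()].
#' @param n number of strains (`>= 2`).
#' @param seed optional integer seed.
#' @param crossover_mean Poisson mean number of breakpoints per chromosome
#'   per strain. The default 1.5 emulates the breakpoint density of selfed
#'   *C. elegans* RIL panels (roughly one obligate crossover per chromosome
#'   with modest map expansion).
#' @return A RIL [genotype_matrix()].
#' @export
simulate_ril_genotypes <- function(map, n = 48, seed = NULL, crossover_mean = 1.5) {
  if (n < 2) stopf("design error: need n >= 2 RILs")
  if (!is.null(seed)) set.seed(seed)
  chroms <- unique(map$chrom)
  g <- matrix(0L, n, nrow(map))
  for (ch in chroms) {
    sel <- which(map$chrom == ch)
    pos <- map$pos_bp[sel]
    for (i in seq_len(n)) {
      k <- stats::rpois(1L, crossover_mean)
      phase <- sample(c(-1L, 1L), 1L)
      if (k == 0L) {
        g[i, sel] <- phase
      } else {
        cuts <- sort(stats::runif(k, min(pos), max(pos)))
        g[i, sel] <- phase * (-1L)^findInterval(pos, cuts)
      }
    }
  }
  rownames(g) <- sprintf("RIL%03d", seq_len(n))
  colnames(g) <- map$marker
  genotype_matrix(g, "RIL", map)
}

#' Simulate a tiling IL genotype panel
#'
#' Each strain is N2 everywhere except one contiguous CB4856 segment.
#' Strains are allocated near-equally over chromosomes; per chromosome the
#' marker range is cut into consecutive cores (so every marker is covered by
#' at least one IL) and each core is extended on both sides by a random
#' overlap of `1 + rpois(overlap_mean - 1)` markers. With the default map
#' (100 markers/chromosome) and 57 strains this yields per-marker coverage
#' whose 5-95% quantiles sit in the 0-5 range reported for the real panel,
#' with a mean around 2.
#'
#' @param map a [genetic_map()].
#' @param n number of ILs; must be at least the number of chromosomes.
#' @param seed optional integer seed.
#' @param overlap_mean mean one-sided segment extension in markers (`>= 1`).
#' @return An IL [genotype_matrix()].
#' @export
simulate_il_genotypes <- function(map, n = 57, seed = NULL, overlap_mean = 5) {
  chroms <- unique(map$chrom)
  if (n < length(chroms))
    stopf("design error: %d ILs cannot tile %d chromosomes", n, length(chroms))
  if (!is.null(seed)) set.seed(seed)
  alloc <- diff(round(seq(0, n, length.out = length(chroms) + 1L)))
  g <- matrix(-1L, n, nrow(map))
  strain <- 0L
  for (ci in seq_along(chroms)) {
    sel <- which(map$chrom == chroms[ci])
    m <- length(sel)
    nc <- alloc[ci]
    b <- round(seq(0L, m, length.out = nc + 1L))
    for (k in seq_len(nc)) {
      strain <- strain + 1L
      lo <- b[k] + 1L
      hi <- b[k + 1L]
      ext <- 1L + stats::rpois(2L, max(overlap_mean - 1, 0))
      lo <- max(1L, lo - ext[1L])
      hi <- min(m, hi + ext[2L])
      g[strain, sel[lo:hi]] <- 1L
    }
  }
  rownames(g) <- sprintf("IL%03d", seq_len(n))
  colnames(g) <- map$marker
  genotype_matrix(g, "IL", map)
}

#' Parental genotype rows
#'
#' @param map a [genetic_map()].
#' @return A parent [genotype_matrix()] with constant rows `N2` and `CB4856`.
#' @export
parent_genotypes <- function(map) {
  g <- rbind(N2 = rep(-1L, nrow(map)), CB4856 = rep(1L, nrow(map)))
  colnames(g) <- map$marker
  genotype_matrix(g, "parent", map)
}

#' Expression matrix with sample annotation
#'
#' Container for one panel in one environment: strictly positive
#' normalized intensities (linear scale) for `spots x samples`, where the
#' samples are the panel strains plus the parental replicates measured in
#' the same environment.
#'
#' @param values numeric matrix, spots x samples, strictly positive.
#' @param spots data.frame with columns `spot_id`, `chrom`, `bp` (gene
#'   position; `NA` allowed).
#' @param samples data.frame with columns `sample` (unique), `strain`,
#'   `group` (one of `RIL`, `IL`, `N2`, `CB4856`).
#' @param environment environment label.
#' @return An `expression_set`.
#' @export
expression_set <- function(values, spots, samples, environment) {
  if (any(values <= 0)) stopf("format error: intensities must be strictly positive")
  if (anyDuplicated(spots$spot_id)) stopf("format error: duplicated spot ids")
  if (anyDuplicated(samples$sample)) stopf("format error: duplicated sample ids")
  if (nrow(values) != nrow(spots) || ncol(values) != nrow(samples))
    stopf("format error: dimensions of values, spots and samples disagree")
  rownames(values) <- spots$spot_id
  colnames(values) <- samples$sample
  structure(list(values = values, spots = spots, samples = samples,
                 environment = environment),
            class = "expression_set")
}

#' @export
print.expression_set <- function(x, ...) {
  cat(sprintf("<expression_set> %s: %d spots x %d samples (%s)\n",
              x$environment, nrow(x$values), ncol(x$values),
              paste(sprintf("%s=%d", names(table(x$samples$group)),
                            table(x$samples$group)), collapse = ", ")))
  invisible(x)
}

#' @rdname expression_set
#' @param es an `expression_set`.
#' @param group sample group(s): `RIL`, `IL`, `N2`, `CB4856`.
#' @export
samples_of_group <- function(es, group) {
  es$samples$sample[es$samples$group %in% group]
}

#' @rdname expression_set
#' @export
group_values <- function(es, group) {
  es$values[, samples_of_group(es, group), drop = FALSE]
}

#' Generate synthetic expression data under planted trait models
#'
#' For every spot the genetic value of its trait model is evaluated on each
#' strain's genotype, i.i.d. Gaussian noise is added on the log2 scale, and
#' the result is exponentiated around `baseline_log2` onto a positive linear
#' intensity scale. Parental replicates are generated from the constant
#' parental genotypes with the same noise model and shared between the RIL
#' and IL sets of an environment. A manifest records the true architecture
#' per spot.
#'
#' @param design a [synthetic_design()].
#' @param models named list of [trait_model()]s (names become spot ids; an
#'   empty-locus model yields pure noise).
#' @param map,ril_geno,il_geno the map and genotype panels.
#' @return list with `environments` (per environment, a list with `RIL` and
#'   `IL` [expression_set()]s) and `manifest` (data.frame of spot truths).
#' @export
generate_expression_dataset <- function(design, models, map, ril_geno, il_geno) {
  set.seed(design$seed)
  if (is.null(names(models)))
    names(models) <- sprintf("spot%04d", seq_along(models))
  for (m in models) {
    if (length(m$loci$idx) && any(m$loci$idx > nrow(map)))
      stopf("reference error: trait model references marker outside the map")
  }
  par_geno <- parent_genotypes(map)
  gv <- function(geno) {
    v <- vapply(models, function(m) genetic_values(m, geno), numeric(nrow(geno)))
    t(v)                                          # spots x strains
  }
  gv_ril <- gv(ril_geno); gv_il <- gv(il_geno); gv_par <- gv(par_geno)
  sds <- vapply(models, function(m) m$sigma_e %||% design$noise_sd, 0)
  spots <- data.frame(
    spot_id = names(models),
    chrom = vapply(models, function(m) m$gene_chrom %||% NA_character_, ""),
    bp = vapply(models, function(m) m$gene_bp %||% NA_real_, 0),
    stringsAsFactors = FALSE)
  n_spot <- length(models)

  noisy <- function(gmat) {
    2^(design$baseline_log2 + gmat +
         matrix(stats::rnorm(length(gmat), 0, sds), n_spot, ncol(gmat)))
  }
  out <- list()
  for (env in design$environments) {
    nN2 <- design$n_parent_reps$N2[[env]]
    nCB <- design$n_parent_reps$CB4856[[env]]
    par_mat <- noisy(cbind(gv_par[, rep("N2", nN2), drop = FALSE],
                           gv_par[, rep("CB4856", nCB), drop = FALSE]))
    par_samples <- data.frame(
      sample = c(sprintf("N2_%s_r%d", env, seq_len(nN2)),
                 sprintf("CB4856_%s_r%d", env, seq_len(nCB))),
      strain = rep(c("N2", "CB4856"), c(nN2, nCB)),
      group = rep(c("N2", "CB4856"), c(nN2, nCB)),
      stringsAsFactors = FALSE)
    mk <- function(gmat, geno, grp) {
      vals <- cbind(noisy(gmat), par_mat)
      samples <- rbind(
        data.frame(sample = rownames(geno), strain = rownames(geno),
                   group = grp, stringsAsFactors = FALSE),
        par_samples)
      expression_set(vals, spots, samples, env)
    }
    out[[env]] <- list(RIL = mk(gv_ril, ril_geno, "RIL"),
                       IL = mk(gv_il, il_geno, "IL"))
  }
  manifest <- data.frame(
    spot_id = names(models),
    model = vapply(models, function(m) m$model, ""),
    n_loci = vapply(models, function(m) length(unique(m$loci$cluster)), 0L),
    markers = vapply(models, function(m)
      paste(map$marker[m$loci$idx], collapse = ";"), ""),
    effects = vapply(models, function(m)
      paste(signif(m$loci$effect, 8), collapse = ";"), ""),
    gene_chrom = spots$chrom, gene_bp = spots$bp, sigma_e = sds,
    stringsAsFactors = FALSE)
  list(environments = out, manifest = manifest)
}

#' Write the spot-truth manifest as YAML
#' @param manifest manifest data.frame from [generate_expression_dataset()].
#' @param path output path.
#' @export
write_manifest <- function(manifest, path) {
  yaml::write_yaml(split(manifest[-1], manifest$spot_id), path)
  invisible(path)
}

#' Write an expression set as TSV
#'
#' Rows are spots (`spot_id`, `gene_chrom`, `gene_bp`), then one column per
#' sample.
#' @param es an [expression_set()].
#' @param path output path.
#' @export
write_expression_tsv <- function(es, path) {
  out <- data.frame(spot_id = es$spots$spot_id, gene_chrom = es$spots$chrom,
                    gene_bp = es$spots$bp, es$values, check.names = FALSE)
  utils::write.table(out, path, sep = "\t", quote = FALSE, row.names = FALSE)
  invisible(path)
}
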