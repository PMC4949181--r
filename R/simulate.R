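#' Simulation configuration with known ground-truth stability structure
#'
#' Defines the generative model shared by the expression-matrix and Ct
#' simulators:
#' \deqn{Ct[g,s,r] = \mu_g + \lambda_s + \beta_g x_s + \epsilon_{g,s,r}}
#' with per-sample loading offsets \eqn{\lambda_s \sim N(0,
#' \lambda_{sd}^2)}, a centered condition contrast \eqn{x_s} (+0.5 for
#' drought, -0.5 for well-watered), gene-specific condition effects
#' \eqn{\beta_g}, and residual noise \eqn{\epsilon \sim N(0,
#' \sigma_{\epsilon,g}^2)}. Expression matrices are the same model on the
#' log2 scale, stored as linear intensities \eqn{2^{\mu_g + \beta_g x_s +
#' \epsilon}} (no loading term: matrices are assumed already normalized).
#'
#' `gene_params` defaults to one stable isogene per family
#' (\eqn{\sigma_\epsilon} = 0.05, \eqn{\beta} = 0) with the remaining
#' isogenes unstable: \eqn{\sigma_\epsilon \sim U(0.5, 1)} and
#' \eqn{|\beta| \sim U(0.5, 1.5)} with random sign, reflecting that
#' drought both induces and represses genes.
#'
#' @param families named integer vector: family label -> isogene count.
#' @param n_samples samples per dataset.
#' @param n_datasets number of expression datasets to emulate.
#' @param n_replicates technical replicates per well in Ct tables.
#' @param gene_params optional data.frame with columns `gene`, `family`,
#'   `mu` (baseline Ct in cycles / baseline log2 intensity), `beta`
#'   (condition-effect size in cycles), `sigma_eps` (residual SD in
#'   cycles); drawn from the defaults above when `NULL`.
#' @param lambda_sd SD of the per-sample loading offset, cycles.
#' @param missing_rate probability a well is undetermined, in \[0, 1).
#' @param annotation_design named list of levels for `genotype`, `stage`,
#'   `tissue`, `water_status`; samples cycle through the crossed design.
#' @param seed random seed (also used to draw default `gene_params`).
#' @return an object of class `sim_config`.
#' @export
simulation_config <- function(families = c(GAPDH = 2, actin = 2,
                                           ubiquitin = 3, cyclophilin = 3),
                              n_samples = 12, n_datasets = 3,
                              n_replicates = 3, gene_params = NULL,
                              lambda_sd = 2, missing_rate = 0,
                              annotation_design = list(
                                genotype = c("IR64", "WAB56-104"),
                                stage = "seedling",
                                tissue = c("leaf", "root"),
                                water_status = c("well-watered", "drought")),
                              seed = NULL) {
  stopifnot(n_samples >= 1, n_datasets >= 1, n_replicates >= 1,
            lambda_sd >= 0, missing_rate >= 0, missing_rate < 1)
  if (is.null(names(families)) || any(families < 1))
    stopf("families must be a named vector of counts >= 1")
  if (!setequal(names(annotation_design),
                c("genotype", "stage", "tissue", "water_status")))
    stopf("annotation_design needs levels for genotype, stage, tissue, water_status")
  if (is.null(gene_params)) {
    if (!is.null(seed)) set.seed(seed %% .Machine$integer.max)
    gene_params <- default_gene_params(families)
  } else {
    need <- c("gene", "family", "mu", "beta", "sigma_eps")
    miss <- setdiff(need, names(gene_params))
    if (length(miss))
      stopf("gene_params is missing column(s): %s", paste(miss, collapse = ", "))
    if (any(gene_params$sigma_eps < 0)) stopf("sigma_eps must be >= 0")
    if (anyDuplicated(gene_params$gene)) stopf("gene_params has duplicate genes")
  }
  structure(list(families = families, n_samples = n_samples,
                 n_datasets = n_datasets, n_replicates = n_replicates,
                 gene_params = gene_params, lambda_sd = lambda_sd,
                 missing_rate = missing_rate,
                 annotation_design = annotation_design, seed = seed),
            class = "sim_config")
}

# one quiet isogene per family, the rest noisy and condition-responsive
default_gene_params <- function(families) {
  rows <- lapply(names(families), function(fam) {
    n <- families[[fam]]
    gene <- sprintf("%s_%02d", fam, seq_len(n))
    beta <- c(0, if (n > 1) runif(n - 1, 0.5, 1.5) *
                sample(c(-1, 1), n - 1, replace = TRUE))
    sigma <- c(0.05, if (n > 1) runif(n - 1, 0.5, 1.0))
    data.frame(gene = gene, family = fam, mu = runif(n, 18, 26),
               beta = beta, sigma_eps = sigma)
  })
  do.call(rbind, rows)
}

# crossed annotation design recycled to n samples; drought contrast +-0.5
build_samples <- function(config, dataset_id = NULL) {
  design <- expand.grid(config$annotation_design,
                        stringsAsFactors = FALSE)[ANNOTATION_COLS]
  idx <- rep_len(seq_len(nrow(design)), config$n_samples)
  ann <- design[idx, , drop = FALSE]
  ann <- cbind(sample = sprintf("S%02d", seq_len(config$n_samples)), ann)
  rownames(ann) <- NULL
  wet <- config$annotation_design$water_status[1]
  x <- ifelse(ann$water_status == wet, -0.5, 0.5)
  if (length(unique(ann$water_status)) == 1) x <- rep(0, nrow(ann))
  list(annotations = ann, x = x)
}

local_seed <- function(seed, offset = 0L) {
  if (!is.null(seed)) set.seed((abs(seed) + offset) %% .Machine$integer.max)
}

#' Simulate one expression dataset with known stability ordering
#'
#' Linear-scale intensities \eqn{2^{\mu_g + \beta_g x_s + \epsilon}} for
#' the configured gene families, plus the ground-truth per-gene log2
#' dispersion \eqn{\sqrt{\beta_g^2 \mathrm{var}(x) +
#' \sigma_{\epsilon,g}^2}} whose within-family ordering the CV
#' pre-screen should recover. Truth is returned alongside the data,
#' never written into it.
#'
#' @param config a [simulation_config()].
#' @param dataset_index which dataset to generate (offsets the seed so
#'   datasets differ while remaining reproducible).
#' @return list with elements `matrix` (an [expression_matrix()]) and
#'   `truth` (data.frame of gene parameters plus `true_sd`, the
#'   population log2-scale SD across samples).
#' @export
simulate_expression_matrix <- function(config, dataset_index = 1) {
  stopifnot(inherits(config, "sim_config"))
  local_seed(config$seed, 97L * as.integer(dataset_index))
  smp <- build_samples(config)
  gp <- config$gene_params
  G <- nrow(gp); n <- config$n_samples
  eps <- matrix(stats::rnorm(G * n, 0, gp$sigma_eps), G, n)
  log2_expr <- gp$mu + outer(gp$beta, smp$x) + eps
  values <- 2^log2_expr
  dimnames(values) <- list(gp$gene, smp$annotations$sample)
  em <- expression_matrix(values, smp$annotations,
                          stats::setNames(gp$family, gp$gene),
                          dataset_id = sprintf("sim%02d", dataset_index))
  truth <- gp
  truth$true_sd <- sqrt(gp$beta^2 * stats::var(smp$x) * (n - 1) / n +
                          gp$sigma_eps^2)
  list(matrix = em, truth = truth)
}

#' Simulate a Ct table with per-sample loading offsets
#'
#' Draws \eqn{Ct[g,s,r] = \mu_g + \lambda_s + \beta_g x_s +
#' \epsilon_{g,s,r}} and drops wells independently at `missing_rate`.
#' The loading offsets \eqn{\lambda_s} cancel exactly in any
#' \eqn{\Delta Ct}, which is what makes pairwise stability statistics
#' robust to unequal mRNA loading.
#'
#' @param config a [simulation_config()].
#' @return list with elements `ct` (a [ct_table()]) and `truth` (the
#'   gene-parameter data.frame, plus attributes `lambda` and `x` giving
#'   the per-sample offsets and condition contrast).
#' @export
simulate_ct_table <- function(config) {
  stopifnot(inherits(config, "sim_config"))
  local_seed(config$seed, 7919L)
  smp <- build_samples(config)
  gp <- config$gene_params
  G <- nrow(gp); n <- config$n_samples; R <- config$n_replicates
  lambda <- stats::rnorm(n, 0, config$lambda_sd)
  base <- gp$mu + outer(gp$beta, smp$x) + rep(lambda, each = G)
  entries <- expand.grid(replicate = seq_len(R), gene = gp$gene,
                         sample = smp$annotations$sample,
                         KEEP.OUT.ATTRS = FALSE, stringsAsFactors = FALSE)
  entries <- entries[c("gene", "sample", "replicate")]
  eps <- stats::rnorm(nrow(entries), 0,
                      gp$sigma_eps[match(entries$gene, gp$gene)])
  entries$ct <- as.vector(base[cbind(match(entries$gene, gp$gene),
                                     match(entries$sample,
                                           smp$annotations$sample))]) + eps
  if (config$missing_rate > 0) {
    drop <- stats::runif(nrow(entries)) < config$missing_rate
    entries$ct[drop] <- NA_real_
  }
  ct <- ct_table(entries, annotations = smp$annotations,
                 ct_range = c(-Inf, Inf))
  ct$ct_range <- c(5, 40)
  truth <- gp
  attr(truth, "lambda") <- stats::setNames(lambda, smp$annotations$sample)
  attr(truth, "x") <- stats::setNames(smp$x, smp$annotations$sample)
  list(ct = ct, truth = truth)
}

#' Simulate a cross-platform fold-change validation scenario
#'
#' Paired log2 fold changes for `n_targets` target genes: the array
#' value \eqn{x \sim N(0, 2)}, the qPCR value \eqn{y = x + N(0,
#' sd_{concordant})} for concordant targets; `n_outliers` targets
#' additionally receive a \eqn{\pm}`outlier_shift` displacement. Truth
#' records which points were planted as outliers.
#'
#' @param n_targets number of target genes.
#' @param sd_concordant SD (log2 units) of the platform disagreement for
#'   concordant targets.
#' @param n_outliers number of planted outliers (< `n_targets`).
#' @param outlier_shift displacement of outliers, log2 units.
#' @param seed random seed.
#' @return list with elements `points` (data.frame `target`, `x`, `y`)
#'   and `truth` (logical vector marking planted outliers).
#' @export
simulate_validation_scenario <- function(n_targets = 8, sd_concordant = 0.3,
                                         n_outliers = 2, outlier_shift = 4,
                                         seed = NULL) {
  stopifnot(n_targets >= 1, n_outliers >= 0, n_outliers < n_targets,
            sd_concordant >= 0)
  local_seed(seed, 104729L)
  x <- stats::rnorm(n_targets, 0, 2)
  y <- x + stats::rnorm(n_targets, 0, sd_concordant)
  is_out <- rep(FALSE, n_targets)
  if (n_outliers > 0) {
    idx <- sample.int(n_targets, n_outliers)
    y[idx] <- y[idx] + outlier_shift * sample(c(-1, 1), n_outliers,
                                              replace = TRUE)
    is_out[idx] <- TRUE
  }
  points <- data.frame(target = sprintf("T%02d", seq_len(n_targets)),
                       x = x, y = y)
  list(points = points, truth = stats::setNames(is_out, points$target))
}

#' Study conditions for reference-stability recovery experiments
#'
#' Ten candidate genes measured in 12 samples, one well per (gene,
#' sample): one quiet gene (\eqn{\sigma_\epsilon} = 0.05, \eqn{\beta} =
#' 0) and nine unstable genes with \eqn{\sigma_\epsilon \sim U(0.5, 1)}
#' and signed \eqn{|\beta| \sim U(0.5, 1.5)}. The quiet gene is the
#' ground-truth best reference.
#'
#' @param seed random seed.
#' @param n_genes number of candidates (first is the quiet gene).
#' @param n_samples samples.
#' @return a [simulation_config()]; the quiet gene is `gene_params$gene[1]`.
#' @export
stability_scenario_config <- function(seed, n_genes = 10, n_samples = 12) {
  local_seed(seed, 1L)
  gp <- data.frame(
    gene = sprintf("G%02d", seq_len(n_genes)), family = "candidate",
    mu = runif(n_genes, 18, 26),
    beta = c(0, runif(n_genes - 1, 0.5, 1.5) *
               sample(c(-1, 1), n_genes - 1, replace = TRUE)),
    sigma_eps = c(0.05, runif(n_genes - 1, 0.5, 1.0)))
  simulation_config(families = c(candidate = n_genes),
                    n_samples = n_samples, n_replicates = 1,
                    gene_params = gp, lambda_sd = 2, seed = seed)
}

#' Study conditions for the multi-gene combination benefit
#'
#' Ten candidates with independent gene noise (\eqn{\beta} = 0,
#' \eqn{\sigma_\epsilon \sim U(0.3, 0.8)}) in 12 samples, one well per
#' (gene, sample): averaging references should not worsen the best
#' attainable stability as set size grows.
#'
#' @inheritParams stability_scenario_config
#' @return a [simulation_config()].
#' @export
combination_scenario_config <- function(seed, n_genes = 10, n_samples = 12) {
  local_seed(seed, 2L)
  gp <- data.frame(
    gene = sprintf("G%02d", seq_len(n_genes)), family = "candidate",
    mu = runif(n_genes, 18, 26), beta = 0,
    sigma_eps = runif(n_genes, 0.3, 0.8))
  simulation_config(families = c(candidate = n_genes),
                    n_samples = n_samples, n_replicates = 1,
                    gene_params = gp, lambda_sd = 2, seed = seed)
}
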