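# deterministic gene x sample Ct grid with per-sample loading
make_grid <- function(n_genes = 4, n_samples = 6, seed = 42,
                      lambda_sd = 2, sigma = 0.3) {
  set.seed(seed)
  genes <- paste0("G", seq_len(n_genes))
  samples <- paste0("S", seq_len(n_samples))
  lambda <- rnorm(n_samples, 0, lambda_sd)
  grid <- outer(runif(n_genes, 18, 26), lambda, `+`) +
    matrix(rnorm(n_genes * n_samples, 0, sigma), n_genes, n_samples)
  dimnames(grid) <- list(genes, samples)
  grid
}

# minimal annotation sheet for a set of samples
make_annotations <- function(samples) {
  data.frame(sample = samples,
             genotype = rep(c("IR64", "WAB56"), length.out = length(samples)),
             stage = "seedling",
             tissue = rep(c("leaf", "root"), length.out = length(samples)),
             water_status = rep(c("well-watered", "drought"),
                                each = ceiling(length(samples) / 2),
                                length.out = length(samples)))
}

# small expression_matrix with two families
make_expression <- function(seed = 1, n_samples = 6, dataset_id = "d1") {
  set.seed(seed)
  genes <- c("famA_1", "famA_2", "famB_1", "famB_2")
  values <- matrix(2^rnorm(4 * n_samples, 10, 0.5), 4, n_samples,
                   dimnames = list(genes, paste0("S", seq_len(n_samples))))
  expression_matrix(values, make_annotations(colnames(values)),
                    c(famA_1 = "famA", famA_2 = "famA",
                      famB_1 = "famB", famB_2 = "famB"),
                    dataset_id = dataset_id)
}

# long-format Ct entries: full crossing, optional well knocked out
make_ct_entries <- function(n_genes = 2, n_samples = 3, n_reps = 3,
                            base = 20) {
  e <- expand.grid(replicate = seq_len(n_reps),
                   sample = paste0("S", seq_len(n_samples)),
                   gene = paste0("G", seq_len(n_genes)),
                   stringsAsFactors = FALSE)[c("gene", "sample", "replicate")]
  e$ct <- base + seq_len(nrow(e)) / 10
  e
}

# independent brute-force mean delta-Ct SD (no package internals)
brute_mean_sd <- function(grid, set, candidates) {
  pseudo <- colMeans(grid[set, , drop = FALSE])
  partners <- setdiff(candidates, set)
  mean(sapply(partners, function(p) {
    d <- pseudo - grid[p, ]
    sd(d[!is.na(d)])
  }))
}
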