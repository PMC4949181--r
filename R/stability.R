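#' A reference set of 1-4 genes
#'
#' @param genes character vector of 1-4 unique gene ids.
#' @return character vector of class `reference_set`.
#' @export
reference_set <- function(genes) {
  genes <- as.character(genes)
  if (length(genes) < 1 || length(genes) > 4)
    stopf("a reference set holds 1-4 genes, got %d", length(genes))
  if (anyDuplicated(genes))
    stopf("duplicate gene(s) in reference set: %s",
          paste(unique(genes[duplicated(genes)]), collapse = ", "))
  structure(genes, class = "reference_set")
}

set_label <- function(genes) paste(genes, collapse = "/")

#' Per-sample pseudo-reference Ct of a gene combination
#'
#' Arithmetic mean of the member genes' Ct values per sample, which on
#' the expression scale is the geometric mean — the standard multi-gene
#' normalization factor. A sample missing any member is missing in the
#' result.
#'
#' @param grid numeric gene x sample Ct matrix (see
#'   [collapse_replicates()]).
#' @param set gene ids of the combination (1-4 genes).
#' @return named numeric vector of per-sample pseudo-reference Ct.
#' @export
combination_ct <- function(grid, set) {
  set <- as.character(set)
  if (!length(set)) stopf("empty reference set")
  absent <- setdiff(set, rownames(grid))
  if (length(absent))
    stopf("gene(s) not in Ct grid: %s", paste(absent, collapse = ", "))
  sub <- grid[set, , drop = FALSE]
  out <- colMeans(sub)           # NA if any member missing
  out
}

#' Standard deviation of the pairwise delta-Ct of two profiles
#'
#' Sample SD (n-1) of `a - b` over the samples where both profiles are
#' observed. Constant offsets between the profiles — differences in
#' baseline expression — do not contribute; only differential behaviour
#' across samples does.
#'
#' @param a,b named numeric per-sample Ct profiles.
#' @param min_shared minimum number of pairwise-complete samples.
#' @return SD of the delta-Ct, in cycles.
#' @export
pairwise_dct_sd <- function(a, b, min_shared = 3) {
  d <- a - b
  d <- d[!is.na(d)]
  if (length(d) < min_shared)
    stopf("only %d shared sample(s) for a pair (need >= %d)",
          length(d), min_shared)
  stats::sd(d)
}

#' Mean delta-Ct SD of a reference set against its partner genes
#'
#' The stability score: the pseudo-reference profile of `set` is
#' compared against every candidate gene not in the set, and the per-
#' partner delta-Ct SDs are averaged. Lower is more stable.
#'
#' @param grid numeric gene x sample Ct matrix.
#' @param set gene ids of the reference set.
#' @param candidates full candidate gene list (partners are
#'   `setdiff(candidates, set)`).
#' @return mean SD of the delta-Ct, in cycles.
#' @export
mean_dct_sd <- function(grid, set, candidates) {
  set <- as.character(set)
  candidates <- as.character(candidates)
  if (length(candidates) < 2) stopf("need at least 2 candidate genes")
  if (!all(set %in% candidates)) stopf("set must be a subset of candidates")
  partners <- setdiff(candidates, set)
  if (!length(partners))
    stopf("no partner genes left for set %s (set equals candidates)",
          set_label(set))
  pseudo <- combination_ct(grid, set)
  sds <- vapply(partners,
                function(p) pairwise_dct_sd(pseudo, grid[p, ]), numeric(1))
  mean(sds)
}

#' Enumerate and rank all reference sets up to a given size
#'
#' Evaluates [mean_dct_sd()] for every subset of the candidates of size
#' 1..`max_size`, then ranks the sets by ascending mean delta-Ct SD both
#' within their size class and over all sets (ties take average ranks).
#' Rows are ordered by class then score; equal scores order by the set
#' members' lexicographic label for reproducible output.
#'
#' @param grid numeric gene x sample Ct matrix, or a [ct_table()]
#'   (replicates are collapsed first).
#' @param candidates candidate gene list (2-20 genes).
#' @param max_size largest combination size, between 1 and
#'   `length(candidates) - 1`. Default 4.
#' @return a data.frame of class `stability_ranking` with columns
#'   `class` (set size), `set` (members joined by "/"), `mean_sd`,
#'   `rank_in_class`, `rank_in_total`; member genes are kept in the
#'   `genes` attribute-free list column `genes`.
#' @export
enumerate_and_rank <- function(grid, candidates, max_size = 4) {
  if (inherits(grid, "ct_table")) grid <- collapse_replicates(grid)
  candidates <- as.character(candidates)
  nc <- length(candidates)
  if (nc < 2 || nc > 20)
    stopf("need 2-20 candidates, got %d", nc)
  if (max_size < 1 || max_size > nc - 1)
    stopf("max_size must be in [1, %d], got %s", nc - 1, max_size)
  absent <- setdiff(candidates, rownames(grid))
  if (length(absent))
    stopf("candidate(s) not in Ct grid: %s", paste(absent, collapse = ", "))
  n_sets <- sum(choose(nc, seq_len(max_size)))
  if (n_sets > 50000)
    stopf("%d sets to evaluate exceeds the 50000 guard; reduce candidates or max_size",
          n_sets)
  rows <- lapply(seq_len(max_size), function(k) {
    sets <- utils::combn(candidates, k, simplify = FALSE)
    data.frame(
      class = k,
      set = vapply(sets, set_label, character(1)),
      mean_sd = vapply(sets, function(s) mean_dct_sd(grid, s, candidates),
                       numeric(1)))
  })
  res <- do.call(rbind, rows)
  res$rank_in_total <- rank(res$mean_sd, ties.method = "average")
  res$rank_in_class <- stats::ave(res$mean_sd, res$class,
                                  FUN = function(x) rank(x, ties.method = "average"))
  res <- res[order(res$class, res$mean_sd, res$set), ]
  rownames(res) <- NULL
  res$genes <- strsplit(res$set, "/", fixed = TRUE)
  class(res) <- c("stability_ranking", "data.frame")
  attr(res, "candidates") <- candidates
  res
}

#' @export
print.stability_ranking <- function(x, n = 5, ...) {
  cat(sprintf("Stability ranking: %d reference sets from %d candidates\n",
              nrow(x), length(attr(x, "candidates"))))
  for (k in unique(x$class)) {
    sub <- x[x$class == k, , drop = FALSE]
    sub <- sub[order(sub$mean_sd), , drop = FALSE]
    cat(sprintf("  %d-gene (best of %d): %s  mean SD %.3f\n",
                k, nrow(sub), sub$set[1], sub$mean_sd[1]))
    if (n > 1) for (i in seq_len(min(n, nrow(sub)))[-1])
      cat(sprintf("    %26s  mean SD %.3f\n", sub$set[i], sub$mean_sd[i]))
  }
  invisible(x)
}

#' @export
summary.stability_ranking <- function(object, ...) {
  df <- as.data.frame(object)[c("class", "set", "mean_sd", "rank_in_total")]
  best <- do.call(rbind, lapply(split(df, df$class), function(s)
    s[which.min(s$mean_sd), ]))
  rownames(best) <- NULL
  structure(list(n_sets = nrow(object),
                 n_candidates = length(attr(object, "candidates")),
                 best_per_class = best),
            class = "summary.stability_ranking")
}

#' @export
print.summary.stability_ranking <- function(x, ...) {
  cat(sprintf("%d reference sets over %d candidates; best per class:\n",
              x$n_sets, x$n_candidates))
  print(x$best_per_class, digits = 3)
  invisible(x)
}

#' @export
plot.stability_ranking <- function(x, ...) {
  graphics::boxplot(mean_sd ~ class, data = x,
                    xlab = "reference-set size",
                    ylab = expression("mean SD of " * Delta * "Ct (cycles)"),
                    ...)
  best <- vapply(split(x$mean_sd, x$class), min, numeric(1))
  graphics::points(seq_along(best), best, pch = 19, col = "red3")
  graphics::lines(seq_along(best), best, col = "red3", lty = 2)
  invisible(x)
}

#' Single-pass geNorm M values
#'
#' For each candidate gene j, M_j is the mean over the other candidates
#' k of the SD across samples of the pairwise log2 expression ratio —
#' on the Ct scale, SD of (Ct_k - Ct_j). Lower M = more stable. This is
#' the geNorm gene-stability measure computed in a single pass, without
#' the stepwise exclusion of the worst gene.
#'
#' @param grid numeric gene x sample Ct matrix, or a [ct_table()].
#' @param candidates candidate gene list (>= 3 genes).
#' @return named numeric vector of M values.
#' @export
genorm_m <- function(grid, candidates) {
  if (inherits(grid, "ct_table")) grid <- collapse_replicates(grid)
  candidates <- as.character(candidates)
  if (length(candidates) < 3) stopf("geNorm M needs >= 3 candidates")
  absent <- setdiff(candidates, rownames(grid))
  if (length(absent))
    stopf("candidate(s) not in Ct grid: %s", paste(absent, collapse = ", "))
  m <- vapply(candidates, function(j) {
    partners <- setdiff(candidates, j)
    mean(vapply(partners,
                function(k) pairwise_dct_sd(grid[k, ], grid[j, ]),
                numeric(1)))
  }, numeric(1))
  m
}

#' Write a stability ranking in the tabulated layout
#'
#' One row per reference set — members joined by "/", mean delta-Ct SD
#' to 3 decimals, rank in class and rank in total — keeping the top
#' `top_k` sets of each size class.
#'
#' @param ranking a `stability_ranking`.
#' @param path output TSV path.
#' @param top_k rows kept per class (default 10).
#' @return `path`, invisibly.
#' @export
write_ranking <- function(ranking, path, top_k = 10) {
  stopifnot(inherits(ranking, "stability_ranking"), nrow(ranking) >= 1)
  keep <- unlist(lapply(split(seq_len(nrow(ranking)), ranking$class),
                        function(i) {
                          i[order(ranking$mean_sd[i], ranking$set[i])][
                            seq_len(min(top_k, length(i)))]
                        }), use.names = FALSE)
  out <- ranking[keep, c("class", "set", "mean_sd",
                         "rank_in_class", "rank_in_total")]
  names(out) <- c("class", "reference_genes", "mean_sd_dct",
                  "rank_in_class", "rank_in_total")
  out$mean_sd_dct <- sprintf("%.3f", out$mean_sd_dct)
  write_tsv(out, path)
}
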