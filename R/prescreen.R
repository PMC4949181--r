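#' Coefficient of variation of a gene's expression
#'
#' Sample standard deviation (n-1 denominator) divided by the mean, on
#' linear-scale intensities. Low CV marks a stably expressed gene.
#'
#' @param values numeric vector of linear intensities (>= 2 finite
#'   values, positive mean).
#' @return unitless CV.
#' @export
compute_cv <- function(values) {
  values <- values[is.finite(values)]
  if (length(values) < 2)
    stopf("CV needs at least 2 finite values, got %d", length(values))
  m <- mean(values)
  if (m <= 0) stopf("CV undefined: mean is %g (must be > 0)", m)
  stats::sd(values) / m
}

#' Rank genes by CV within each gene family
#'
#' Rank 1 is the lowest CV (most stable) within its family; ties take
#' the average of the spanned ranks. Families are ranked independently,
#' so ranks restart at 1 in each family. Genes without a family label
#' are excluded.
#'
#' @param cvs named numeric vector of CVs (names = gene ids).
#' @param family_map named character vector, gene id -> family label.
#' @return named numeric vector of within-family ranks.
#' @export
rank_within_family <- function(cvs, family_map) {
  genes <- intersect(names(cvs), names(family_map))
  fam <- family_map[genes]
  ranks <- unlist(lapply(split(cvs[genes], fam), rank,
                         ties.method = "average"),
                  use.names = FALSE)
  names(ranks) <- unlist(split(genes, fam), use.names = FALSE)
  ranks[genes]
}

#' Aggregate within-family ranks into a weighted rank score (WRS)
#'
#' Each within-family rank is first rescaled to a stability score
#' \eqn{s = 1 - (rank - 1) / (N - 1)} (1 for the most stable isogene in
#' a family of N, 0 for the least; s = 1 when N = 1). The WRS of a gene
#' is the weighted sum of its scores over datasets, the weight of a
#' dataset being its sample variety (number of distinct annotation
#' tuples) unless overridden; a gene absent from a dataset contributes 0
#' there. Finally each WRS is expressed as a percentage of the maximum
#' in its family, so the top isogene sits at 100.
#'
#' @param ranks data.frame with columns `gene`, `dataset`, `family`,
#'   `family_rank` (and optionally `cv`, carried through).
#' @param family_sizes data.frame with columns `family`, `dataset`, `n`:
#'   family size in that dataset.
#' @param weights named numeric vector of positive per-dataset weights.
#' @return an object of class `wrs_table`: list with `scores` (the
#'   per-(gene, dataset) rows plus the rescaled `s`) and `aggregate`
#'   (per gene: `family`, `wrs`, `wrs_pct`), sorted by family then
#'   descending WRS.
#' @export
compute_wrs <- function(ranks, family_sizes, weights) {
  need <- c("gene", "dataset", "family", "family_rank")
  miss <- setdiff(need, names(ranks))
  if (length(miss))
    stopf("ranks is missing column(s): %s", paste(miss, collapse = ", "))
  if (any(weights <= 0)) stopf("dataset weights must be > 0")
  mis_w <- setdiff(unique(ranks$dataset), names(weights))
  if (length(mis_w))
    stopf("no weight supplied for dataset(s): %s", paste(mis_w, collapse = ", "))
  key <- paste(ranks$family, ranks$dataset, sep = "\r")
  skey <- paste(family_sizes$family, family_sizes$dataset, sep = "\r")
  n_fam <- family_sizes$n[match(key, skey)]
  if (anyNA(n_fam))
    stopf("missing family size for family/dataset: %s",
          paste(unique(gsub("\r", "/", key[is.na(n_fam)])), collapse = ", "))
  scores <- ranks
  scores$s <- ifelse(n_fam == 1, 1, 1 - (scores$family_rank - 1) / (n_fam - 1))
  w <- weights[scores$dataset]
  agg <- stats::aggregate(list(wrs = w * scores$s),
                          by = list(gene = scores$gene,
                                    family = scores$family), FUN = sum)
  fam_max <- tapply(agg$wrs, agg$family, max)
  agg$wrs_pct <- 100 * agg$wrs / as.numeric(fam_max[agg$family])
  agg <- agg[order(agg$family, -agg$wrs, agg$gene), ]
  rownames(agg) <- NULL
  structure(list(scores = scores, aggregate = agg, weights = weights),
            class = "wrs_table")
}

#' @export
print.wrs_table <- function(x, ...) {
  cat(sprintf("WRS table: %d genes in %d families over %d dataset(s)\n",
              nrow(x$aggregate), length(unique(x$aggregate$family)),
              length(x$weights)))
  print(utils::head(x$aggregate, 12))
  if (nrow(x$aggregate) > 12) cat("...\n")
  invisible(x)
}

#' Pre-screen candidate reference genes across expression datasets
#'
#' Stage 1 of the workflow: for every gene in every dataset compute the
#' CV of its linear intensities, rank CVs within each gene family, and
#' aggregate the ranks into the weighted rank score. Genes whose CV is
#' undefined in a dataset (fewer than 2 values or non-positive mean)
#' are excluded from that dataset with a message.
#'
#' @param matrices list of [expression_matrix()] objects.
#' @param weights optional named numeric vector of per-dataset weights;
#'   defaults to each dataset's sample variety ([dataset_weight()]).
#' @return a `wrs_table` (see [compute_wrs()]); its `scores` element
#'   also carries each gene's per-dataset `cv`.
#' @export
prescreen <- function(matrices, weights = NULL) {
  if (inherits(matrices, "expression_matrix")) matrices <- list(matrices)
  stopifnot(length(matrices) >= 1,
            all(vapply(matrices, inherits, logical(1), "expression_matrix")))
  ids <- vapply(matrices, `[[`, character(1), "dataset_id")
  if (anyDuplicated(ids)) stopf("duplicate dataset ids: %s",
                                paste(ids[duplicated(ids)], collapse = ", "))
  if (is.null(weights))
    weights <- stats::setNames(vapply(matrices, dataset_weight, numeric(1)), ids)

  per_ds <- lapply(matrices, function(em) {
    ok <- apply(em$values, 1, function(v) {
      v <- v[is.finite(v)]
      length(v) >= 2 && mean(v) > 0
    })
    if (any(!ok))
      message(sprintf("dataset '%s': CV undefined for gene(s) %s; excluded",
                      em$dataset_id,
                      paste(rownames(em$values)[!ok], collapse = ", ")))
    vals <- em$values[ok, , drop = FALSE]
    cvs <- apply(vals, 1, compute_cv)
    r <- rank_within_family(cvs, em$family_map)
    data.frame(gene = names(r), dataset = em$dataset_id,
               family = unname(em$family_map[names(r)]),
               cv = unname(cvs[names(r)]), family_rank = unname(r))
  })
  ranks <- do.call(rbind, per_ds)
  if (is.null(ranks) || !nrow(ranks)) stopf("no rankable genes in any dataset")
  sizes <- stats::aggregate(list(n = ranks$gene),
                            by = list(family = ranks$family,
                                      dataset = ranks$dataset),
                            FUN = length)
  compute_wrs(ranks, sizes, weights)
}

#' Select candidate reference genes by family quota
#'
#' Takes the top-`quota` genes of each family by WRS; ties at a quota
#' boundary are broken deterministically by lexicographic gene id and
#' reported with a message.
#'
#' @param wrs a `wrs_table` from [prescreen()] or [compute_wrs()].
#' @param quotas named integer vector, family -> number of candidates.
#' @return character vector of candidate gene ids, ordered by family
#'   (quota order) then descending WRS.
#' @export
select_candidates <- function(wrs, quotas) {
  stopifnot(inherits(wrs, "wrs_table"))
  agg <- wrs$aggregate
  out <- character(0)
  for (fam in names(quotas)) {
    q <- quotas[[fam]]
    if (q == 0) next
    rows <- agg[agg$family == fam, , drop = FALSE]
    if (!nrow(rows)) stopf("family '%s' not present in WRS table", fam)
    if (q > nrow(rows))
      stopf("quota %d exceeds family '%s' size %d", q, fam, nrow(rows))
    rows <- rows[order(-rows$wrs, rows$gene), , drop = FALSE]
    if (nrow(rows) > q && rows$wrs[q] == rows$wrs[q + 1])
      message(sprintf(
        "family '%s': tie at quota boundary (WRS %.4g); lexicographic tie-break",
        fam, rows$wrs[q]))
    out <- c(out, rows$gene[seq_len(q)])
  }
  out
}

#' Write a WRS table to tab-delimited files
#'
#' @param wrs a `wrs_table`.
#' @param path output TSV for the per-gene aggregate (family, WRS,
#'   WRS percentage).
#' @param scores_path optional output TSV for the per-(gene, dataset)
#'   CVs and ranks.
#' @return `path`, invisibly.
#' @export
write_wrs_table <- function(wrs, path, scores_path = NULL) {
  stopifnot(inherits(wrs, "wrs_table"))
  write_tsv(wrs$aggregate, path)
  if (!is.null(scores_path)) write_tsv(wrs$scores, scores_path)
  invisible(path)
}
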