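#' Construct an expression matrix with sample annotations and a family map
#'
#' Container for one dataset of linear-scale expression intensities
#' (genes in rows, samples in columns), the per-sample annotation tuple
#' (genotype, growth stage, tissue, water status) and a gene-to-family
#' map. This is the input to the weighted-rank-score pre-screen.
#'
#' @param values numeric matrix, genes in rows (rownames = gene ids),
#'   samples in columns (colnames = sample ids); finite, non-negative,
#'   linear scale.
#' @param annotations data.frame with columns `sample`, `genotype`,
#'   `stage`, `tissue`, `water_status`; every sample in `values` must be
#'   annotated.
#' @param family_map named character vector mapping gene id to family
#'   label (e.g. `"GAPDH"`), or a data.frame with columns `gene`,
#'   `family`. Genes without a family are allowed but are excluded from
#'   per-family ranking.
#' @param dataset_id identifier for this dataset.
#' @return an object of class `expression_matrix`.
#' @seealso [read_expression_matrix()], [prescreen()]
#' @export
expression_matrix <- function(values, annotations, family_map,
                              dataset_id = "dataset1") {
  if (!is.matrix(values) || !is.numeric(values))
    stopf("values must be a numeric matrix")
  if (is.null(rownames(values)) || is.null(colnames(values)))
    stopf("values must have gene ids as rownames and sample ids as colnames")
  if (anyDuplicated(rownames(values)))
    stopf("duplicate gene id(s): %s",
          paste(unique(rownames(values)[duplicated(rownames(values))]), collapse = ", "))
  bad <- which(!is.finite(values) | values < 0, arr.ind = TRUE)
  if (nrow(bad))
    stopf("non-finite or negative intensity at gene '%s', sample '%s'",
          rownames(values)[bad[1, 1]], colnames(values)[bad[1, 2]])
  annotations <- check_annotations(
    cbind(sample = annotations$sample, annotations[setdiff(names(annotations), "sample")]),
    colnames(values))
  annotations <- cbind(sample = colnames(values), annotations[ANNOTATION_COLS])
  if (is.data.frame(family_map)) {
    if (!all(c("gene", "family") %in% names(family_map)))
      stopf("family map data.frame needs columns 'gene' and 'family'")
    family_map <- stats::setNames(as.character(family_map$family),
                                  family_map$gene)
  }
  if (anyDuplicated(names(family_map)))
    stopf("family map has duplicated gene id(s)")
  structure(
    list(dataset_id = dataset_id, values = values,
         annotations = annotations, family_map = family_map),
    class = "expression_matrix")
}

#' @export
print.expression_matrix <- function(x, ...) {
  cat(sprintf("Expression matrix '%s': %d genes x %d samples\n",
              x$dataset_id, nrow(x$values), ncol(x$values)))
  cat(sprintf("  families: %s\n",
              paste(sort(unique(x$family_map)), collapse = ", ")))
  cat(sprintf("  sample variety (distinct annotation tuples): %d\n",
              dataset_weight(x)))
  invisible(x)
}

#' Sample-variety weight of a dataset
#'
#' Number of distinct (genotype, stage, tissue, water_status) annotation
#' tuples among the samples of a dataset. Used as the per-dataset weight
#' when aggregating within-family CV ranks into the weighted rank score.
#'
#' @param em an [expression_matrix()].
#' @return integer count of distinct annotation tuples.
#' @export
dataset_weight <- function(em) {
  stopifnot(inherits(em, "expression_matrix"))
  nrow(unique(em$annotations[ANNOTATION_COLS]))
}

#' Read an expression matrix from tab-delimited files
#'
#' @param path TSV with gene ids in the first column and sample ids in
#'   the header.
#' @param annotation_path TSV sample-annotation sheet (columns `sample`,
#'   `genotype`, `stage`, `tissue`, `water_status`).
#' @param family_path TSV gene-family map (columns `gene`, `family`).
#' @param dataset_id identifier; defaults to the matrix file name.
#' @param log2 if `TRUE` the stored values are log2-scale and are
#'   exponentiated (base 2) to linear scale on read.
#' @return an [expression_matrix()].
#' @export
read_expression_matrix <- function(path, annotation_path, family_path,
                                   dataset_id = NULL, log2 = FALSE) {
  tab <- read_tsv(path)
  if (ncol(tab) < 2)
    stopf("malformed expression matrix '%s': need a gene column plus >=1 sample column", path)
  genes <- as.character(tab[[1]])
  if (anyDuplicated(genes))
    stopf("duplicate gene id(s) in '%s': %s", path,
          paste(unique(genes[duplicated(genes)]), collapse = ", "))
  values <- as.matrix(tab[-1])
  if (!is.numeric(values))
    stopf("malformed expression matrix '%s': non-numeric intensities", path)
  rownames(values) <- genes
  if (log2) values <- 2^values
  annotations <- read_tsv(annotation_path)
  fam <- read_tsv(family_path)
  expression_matrix(values, annotations, fam,
                    dataset_id = dataset_id %||% basename(path))
}

#' Write an expression matrix (and its sheets) to tab-delimited files
#'
#' @param em an [expression_matrix()].
#' @param path output TSV for the intensity grid.
#' @param annotation_path optional output TSV for the annotation sheet.
#' @param family_path optional output TSV for the family map.
#' @return `path`, invisibly.
#' @export
write_expression_matrix <- function(em, path, annotation_path = NULL,
                                    family_path = NULL) {
  stopifnot(inherits(em, "expression_matrix"))
  out <- data.frame(gene = rownames(em$values), em$values,
                    check.names = FALSE)
  write_tsv(out, path)
  if (!is.null(annotation_path)) write_tsv(em$annotations, annotation_path)
  if (!is.null(family_path))
    write_tsv(data.frame(gene = names(em$family_map),
                         family = unname(em$family_map)), family_path)
  invisible(path)
}
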