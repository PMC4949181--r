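#' Construct a Ct table
#'
#' Long-format container of threshold-cycle (Ct) values per gene, sample
#' and technical replicate. Undetermined wells are simply absent: a row
#' with a missing Ct is dropped (with the well recorded as absent), and
#' downstream operations treat absent wells as missing data.
#'
#' @param entries data.frame with columns `gene`, `sample`, `replicate`
#'   (positive integer), `ct` (cycles). Rows with `NA` Ct are dropped.
#' @param annotations optional sample-annotation sheet (columns `sample`,
#'   `genotype`, `stage`, `tissue`, `water_status`).
#' @param ct_range plausible Ct range in cycles; values outside it are
#'   rejected. Default 5-40, the usual instrument window.
#' @return an object of class `ct_table`.
#' @seealso [read_ct_table()], [collapse_replicates()]
#' @export
ct_table <- function(entries, annotations = NULL, ct_range = c(5, 40)) {
  need <- c("gene", "sample", "replicate", "ct")
  miss <- setdiff(need, names(entries))
  if (length(miss))
    stopf("Ct table is missing column(s): %s", paste(miss, collapse = ", "))
  entries <- entries[need]
  entries$gene <- as.character(entries$gene)
  entries$sample <- as.character(entries$sample)
  entries$replicate <- as.integer(entries$replicate)
  entries$ct <- as.numeric(entries$ct)

  key <- paste(entries$gene, entries$sample, entries$replicate, sep = "\r")
  if (anyDuplicated(key)) {
    d <- entries[duplicated(key), , drop = FALSE][1, ]
    stopf("duplicate well: gene '%s', sample '%s', replicate %d",
          d$gene, d$sample, d$replicate)
  }
  if (any(entries$replicate < 1, na.rm = TRUE))
    stopf("replicate indices must be >= 1")
  # consecutive replicate indices per (gene, sample), counting absent wells
  idx <- split(entries$replicate, paste(entries$gene, entries$sample, sep = "\r"))
  bad <- vapply(idx, function(r) !identical(sort(r), seq_along(r)), logical(1))
  if (any(bad)) {
    well <- strsplit(names(idx)[bad][1], "\r", fixed = TRUE)[[1]]
    stopf("replicate indices for gene '%s', sample '%s' are not consecutive from 1",
          well[1], well[2])
  }
  absent <- is.na(entries$ct)
  present <- entries[!absent, , drop = FALSE]
  out <- which(present$ct < ct_range[1] | present$ct > ct_range[2] |
                 !is.finite(present$ct))
  if (length(out)) {
    d <- present[out[1], ]
    stopf("Ct %.3g outside plausible range [%g, %g] at gene '%s', sample '%s', replicate %d",
          d$ct, ct_range[1], ct_range[2], d$gene, d$sample, d$replicate)
  }
  if (!is.null(annotations))
    annotations <- cbind(sample = unique(present$sample),
                         check_annotations(annotations, unique(present$sample)))
  structure(list(entries = present, annotations = annotations,
                 ct_range = ct_range),
            class = "ct_table")
}

#' @export
print.ct_table <- function(x, ...) {
  e <- x$entries
  cat(sprintf("Ct table: %d wells, %d genes, %d samples, up to %d replicates\n",
              nrow(e), length(unique(e$gene)), length(unique(e$sample)),
              if (nrow(e)) max(e$replicate) else 0L))
  invisible(x)
}

#' Read a Ct table from a long-format tab-delimited file
#'
#' Expects columns `gene`, `sample`, `replicate`, `ct`; "NA" or blank Ct
#' marks an undetermined well, which is recorded as absent rather than
#' raising an error.
#'
#' @inheritParams ct_table
#' @param path long-format TSV of Ct values.
#' @param annotation_path optional TSV sample-annotation sheet.
#' @return a [ct_table()].
#' @export
read_ct_table <- function(path, annotation_path = NULL, ct_range = c(5, 40)) {
  entries <- read_tsv(path, na.strings = c("NA", ""))
  annotations <- if (!is.null(annotation_path)) read_tsv(annotation_path)
  ct_table(entries, annotations = annotations, ct_range = ct_range)
}

#' Write a Ct table to a long-format tab-delimited file
#'
#' @param ct a [ct_table()].
#' @param path output TSV path.
#' @return `path`, invisibly.
#' @export
write_ct_table <- function(ct, path) {
  stopifnot(inherits(ct, "ct_table"))
  write_tsv(ct$entries, path)
}

#' Collapse technical replicates to a gene-by-sample Ct grid
#'
#' Arithmetic mean of the technical-replicate Ct values per (gene,
#' sample); wells with no usable replicate propagate as `NA`.
#'
#' @param ct a [ct_table()] or a data.frame with columns `gene`,
#'   `sample`, `ct`.
#' @return numeric matrix (genes x samples) of mean Ct values, `NA`
#'   where all replicates are missing.
#' @export
collapse_replicates <- function(ct) {
  e <- if (inherits(ct, "ct_table")) ct$entries else ct
  genes <- unique(e$gene)
  samples <- unique(e$sample)
  grid <- tapply(e$ct, list(factor(e$gene, genes), factor(e$sample, samples)),
                 mean)
  grid <- matrix(grid, nrow = length(genes),
                 dimnames = list(genes, samples))
  grid
}
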