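`%||%` <- function(a, b) if (is.null(a)) b else a

#' @keywords internal
#' @noRd
stopf <- function(fmt, ...) stop(sprintf(fmt, ...), call. = FALSE)

#' @keywords internal
#' @noRd
warnf <- function(fmt, ...) warning(sprintf(fmt, ...), call. = FALSE)

# columns required in a sample-annotation sheet
ANNOTATION_COLS <- c("genotype", "stage", "tissue", "water_status")

check_annotations <- function(annotations, samples) {
  if (!is.data.frame(annotations))
    stopf("annotations must be a data.frame")
  need <- c("sample", ANNOTATION_COLS)
  miss <- setdiff(need, names(annotations))
  if (length(miss))
    stopf("annotation sheet is missing column(s): %s", paste(miss, collapse = ", "))
  if (anyDuplicated(annotations$sample))
    stopf("annotation sheet has duplicated sample id(s): %s",
          paste(unique(annotations$sample[duplicated(annotations$sample)]), collapse = ", "))
  unannotated <- setdiff(samples, annotations$sample)
  if (length(unannotated))
    stopf("sample(s) present in data but absent from annotations: %s",
          paste(unannotated, collapse = ", "))
  incomplete <- !stats::complete.cases(annotations[need])
  if (any(incomplete))
    stopf("annotation sheet has incomplete row(s) for sample(s): %s",
          paste(annotations$sample[incomplete], collapse = ", "))
  annotations[match(samples, annotations$sample), need, drop = FALSE]
}

read_tsv <- function(path, ...) {
  if (!file.exists(path)) stopf("file not found: %s", path)
  utils::read.delim(path, sep = "\t", stringsAsFactors = FALSE,
                    check.names = FALSE, ...)
}

write_tsv <- function(x, path, row.names = FALSE) {
  utils::write.table(x, path, sep = "\t", quote = FALSE,
                     row.names = row.names, col.names = TRUE)
  invisible(path)
}
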