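#' Per-sample reference Ct of a reference set
#'
#' Same contract as [combination_ct()]: arithmetic mean of member Cts
#' per sample (geometric mean of expression), missing if any member is
#' missing.
#'
#' @inheritParams combination_ct
#' @return named numeric per-sample reference Ct.
#' @export
reference_profile <- function(grid, set) combination_ct(grid, set)

#' Relative quantification by the delta-delta-Ct method
#'
#' For each target gene: \eqn{\Delta Ct = Ct_{target} - Ct_{ref}} per
#' sample, \eqn{\Delta\Delta Ct = \Delta Ct - \overline{\Delta
#' Ct}_{calibrator}}, fold change \eqn{2^{-\Delta\Delta Ct}}
#' (amplification efficiency fixed at 2). The calibrator is a set of
#' samples (typically one condition, e.g. well-watered roots); its mean
#' delta-Ct defines fold change 1.
#'
#' @param grid numeric gene x sample Ct matrix, or a [ct_table()]
#'   (replicates collapsed first).
#' @param targets target gene ids.
#' @param set reference gene ids (1-4; see [reference_set()]).
#' @param calibrator sample ids forming the calibrator condition.
#' @return a data.frame of class `fold_change_table` with columns
#'   `target`, `sample`, `dct`, `ddct`, `log2fc` (= -ddct), `fc`
#'   (= 2^log2fc); attributes `reference` and `calibrator`. Targets
#'   whose calibrator delta-Ct is entirely missing are skipped with a
#'   warning.
#' @export
ddct_quantify <- function(grid, targets, set, calibrator) {
  if (inherits(grid, "ct_table")) grid <- collapse_replicates(grid)
  targets <- as.character(targets)
  calibrator <- as.character(calibrator)
  bad_t <- setdiff(targets, rownames(grid))
  if (length(bad_t))
    stopf("target gene(s) not in Ct grid: %s", paste(bad_t, collapse = ", "))
  bad_c <- setdiff(calibrator, colnames(grid))
  if (length(bad_c))
    stopf("calibrator sample(s) not in Ct grid: %s", paste(bad_c, collapse = ", "))
  ref <- reference_profile(grid, set)
  rows <- lapply(targets, function(tg) {
    dct <- grid[tg, ] - ref
    cal <- dct[calibrator]
    if (all(is.na(cal))) {
      warnf("target '%s': calibrator delta-Ct entirely missing; skipped", tg)
      return(NULL)
    }
    ddct <- dct - mean(cal, na.rm = TRUE)
    data.frame(target = tg, sample = colnames(grid),
               dct = unname(dct), ddct = unname(ddct),
               log2fc = -unname(ddct), fc = 2^(-unname(ddct)))
  })
  out <- do.call(rbind, rows)
  if (is.null(out)) stopf("no quantifiable targets")
  rownames(out) <- NULL
  class(out) <- c("fold_change_table", "data.frame")
  attr(out, "reference") <- as.character(set)
  attr(out, "calibrator") <- calibrator
  out
}

#' @export
print.fold_change_table <- function(x, ...) {
  cat(sprintf("Fold changes: %d target(s) x %d sample(s); reference %s; calibrator %s\n",
              length(unique(x$target)), length(unique(x$sample)),
              set_label(attr(x, "reference")),
              paste(attr(x, "calibrator"), collapse = ",")))
  print.data.frame(utils::head(x, 8), digits = 4)
  if (nrow(x) > 8) cat("...\n")
  invisible(x)
}

#' Condition-level fold-change summaries
#'
#' Mean of the per-sample log2 fold changes within each condition, with
#' the standard error over samples — the usual error-bar convention for
#' expression profiles.
#'
#' @param fct a `fold_change_table` from [ddct_quantify()].
#' @param groups named character vector mapping sample id -> condition
#'   label.
#' @return data.frame with columns `target`, `condition`, `n`,
#'   `log2fc` (mean), `se`, `fc` (2^mean).
#' @export
condition_fold_change <- function(fct, groups) {
  stopifnot(inherits(fct, "fold_change_table"))
  cond <- groups[fct$sample]
  if (anyNA(cond))
    stopf("sample(s) without condition label: %s",
          paste(unique(fct$sample[is.na(cond)]), collapse = ", "))
  sp <- split(fct$log2fc, list(target = fct$target, condition = cond),
              sep = "\r")
  rows <- lapply(names(sp), function(k) {
    v <- sp[[k]][!is.na(sp[[k]])]
    parts <- strsplit(k, "\r", fixed = TRUE)[[1]]
    data.frame(target = parts[1], condition = parts[2], n = length(v),
               log2fc = mean(v),
               se = if (length(v) > 1) stats::sd(v) / sqrt(length(v)) else NA_real_)
  })
  out <- do.call(rbind, rows)
  out$fc <- 2^out$log2fc
  out[order(out$target, out$condition), ]
}

#' Write a fold-change table to TSV
#'
#' @param fct a `fold_change_table`.
#' @param path output TSV path.
#' @return `path`, invisibly.
#' @export
write_fold_changes <- function(fct, path) {
  stopifnot(inherits(fct, "fold_change_table"))
  write_tsv(as.data.frame(fct), path)
}
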