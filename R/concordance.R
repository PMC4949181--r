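#' Residual variance against the identity line
#'
#' Goodness of fit of paired log2 fold changes to y = x, with no fitted
#' parameters: \eqn{RV = \sum_i (y_i - x_i)^2 / (n - 1)}. Lower RV =
#' better cross-platform concordance.
#'
#' @param x,y paired numeric vectors of log2 fold changes (>= 3 points).
#' @return residual variance, squared log2-fold-change units.
#' @export
residual_variance <- function(x, y) {
  ok <- !is.na(x) & !is.na(y)
  x <- x[ok]; y <- y[ok]
  n <- length(x)
  if (n < 3) stopf("residual variance needs >= 3 points, got %d", n)
  sum((y - x)^2) / (n - 1)
}

#' Flag outlying points in a cross-platform comparison
#'
#' Three policies for the residual `r = y - x`:
#' \describe{
#'   \item{residual-sd}{flag points with `|r| > param * SD(r)` (single
#'     pass; default `param = 2`).}
#'   \item{fixed-count}{flag the `param` points with the largest `|r|`
#'     (the "omit the k worst points" convention).}
#'   \item{explicit}{`param` gives the point names or indices to flag.}
#' }
#'
#' @param x,y paired numeric vectors (optionally named).
#' @param method one of `"residual-sd"`, `"fixed-count"`, `"explicit"`.
#' @param param method parameter (see above).
#' @return logical outlier mask, same length as `x`.
#' @export
detect_outliers <- function(x, y, method = c("residual-sd", "fixed-count",
                                             "explicit"),
                            param = NULL) {
  method <- match.arg(method)
  n <- length(x)
  stopifnot(length(y) == n)
  r <- y - x
  mask <- rep(FALSE, n)
  names(mask) <- names(x)
  if (method == "residual-sd") {
    if (n < 4) stopf("residual-sd outlier detection needs >= 4 points")
    param <- param %||% 2
    mask[abs(r) > param * stats::sd(r)] <- TRUE
  } else if (method == "fixed-count") {
    if (is.null(param)) stopf("fixed-count needs a count parameter")
    if (n < 4) stopf("fixed-count outlier detection needs >= 4 points")
    if (param >= n)
      stopf("cannot flag %d outliers out of %d points", param, n)
    if (param > 0)
      mask[order(-abs(r))[seq_len(param)]] <- TRUE
  } else {
    if (is.null(param)) stopf("explicit method needs point ids or indices")
    if (is.character(param)) {
      bad <- setdiff(param, names(mask))
      if (length(bad)) stopf("unknown point id(s): %s", paste(bad, collapse = ", "))
      mask[param] <- TRUE
    } else mask[param] <- TRUE
  }
  mask
}

#' Concordance of one reference set against the array platform
#'
#' @param points data.frame with columns `target`, `x` (array log2 fold
#'   change), `y` (qPCR log2 fold change).
#' @param outlier_mask logical mask of points excluded from RV.
#' @return object of class `concordance_result`: the points with their
#'   mask, the residual variance over retained points (`NA` with a
#'   warning if fewer than 3 are retained), and the retained count.
#' @export
concordance_result <- function(points, outlier_mask = rep(FALSE, nrow(points))) {
  stopifnot(all(c("target", "x", "y") %in% names(points)),
            length(outlier_mask) == nrow(points))
  keep <- !outlier_mask
  rv <- if (sum(keep) >= 3) {
    residual_variance(points$x[keep], points$y[keep])
  } else {
    warnf("only %d retained point(s); RV not reported", sum(keep))
    NA_real_
  }
  structure(list(points = cbind(points, outlier = outlier_mask),
                 rv = rv, n_used = sum(keep)),
            class = "concordance_result")
}

#' @export
print.concordance_result <- function(x, ...) {
  cat(sprintf("Concordance: RV = %.3f over %d point(s) (%d outlier(s) omitted)\n",
              x$rv, x$n_used, sum(x$points$outlier)))
  invisible(x)
}

#' @export
plot.concordance_result <- function(x, ...) {
  p <- x$points
  lim <- range(c(p$x, p$y), finite = TRUE)
  graphics::plot(p$x, p$y, xlim = lim, ylim = lim,
                 pch = ifelse(p$outlier, 4, 19),
                 col = ifelse(p$outlier, "red3", "black"),
                 xlab = expression(log[2] * " fold change (array)"),
                 ylab = expression(log[2] * " fold change (qRT-PCR)"), ...)
  graphics::abline(0, 1, lty = 2)
  graphics::legend("topleft", bty = "n",
                   legend = sprintf("RV = %.2f (n = %d)", x$rv, x$n_used))
  invisible(x)
}

#' Compare reference sets by cross-platform concordance
#'
#' For each reference set's qPCR fold changes, pairs the per-target
#' log2 fold changes with the array values, applies one outlier policy
#' to every set, and ranks the sets by ascending residual variance.
#' Targets present on only one platform are dropped with a message.
#'
#' @param fold_changes named list; each element a data.frame with
#'   columns `target` and `log2fc` (qPCR fold changes under that
#'   reference set).
#' @param array_fc data.frame with columns `target` and `log2fc` (array
#'   platform).
#' @param method,param outlier policy, as in [detect_outliers()];
#'   `method` defaults to fixed-count when `param` is a count, else
#'   residual-sd.
#' @return object of class `concordance_comparison`: a summary
#'   data.frame (`reference`, `n_used`, `rv`, `rank`) ordered by rank,
#'   with the per-set [concordance_result()] objects in `$results`.
#' @export
compare_references <- function(fold_changes, array_fc, method = NULL,
                               param = NULL) {
  stopifnot(is.list(fold_changes), length(fold_changes) >= 1,
            !is.null(names(fold_changes)))
  method <- method %||% if (!is.null(param) && is.numeric(param))
    "fixed-count" else "residual-sd"
  results <- lapply(names(fold_changes), function(nm) {
    fc <- fold_changes[[nm]]
    stopifnot(all(c("target", "log2fc") %in% names(fc)))
    shared <- intersect(fc$target, array_fc$target)
    dropped <- setdiff(union(fc$target, array_fc$target), shared)
    if (length(dropped))
      message(sprintf("reference '%s': target(s) on one platform only dropped: %s",
                      nm, paste(dropped, collapse = ", ")))
    pts <- data.frame(target = shared,
                      x = array_fc$log2fc[match(shared, array_fc$target)],
                      y = fc$log2fc[match(shared, fc$target)])
    if (nrow(pts) < 4)
      stopf("reference '%s': only %d shared target(s)", nm, nrow(pts))
    mask <- detect_outliers(stats::setNames(pts$x, pts$target), pts$y,
                            method = method, param = param)
    if (nrow(pts) - sum(mask) < 3)
      stopf("reference '%s': fewer than 3 targets retained after outlier removal", nm)
    concordance_result(pts, mask)
  })
  names(results) <- names(fold_changes)
  summary <- data.frame(reference = names(results),
                        n_used = vapply(results, `[[`, numeric(1), "n_used"),
                        rv = vapply(results, `[[`, numeric(1), "rv"))
  summary$rank <- rank(summary$rv, ties.method = "average")
  summary <- summary[order(summary$rank, summary$reference), ]
  rownames(summary) <- NULL
  structure(list(summary = summary, results = results,
                 method = method, param = param),
            class = "concordance_comparison")
}

#' @export
print.concordance_comparison <- function(x, ...) {
  cat(sprintf("Reference-set concordance (outlier policy: %s):\n", x$method))
  print(x$summary, digits = 4)
  invisible(x)
}

#' @export
plot.concordance_comparison <- function(x, ...) {
  k <- length(x$results)
  op <- graphics::par(mfrow = c(ceiling(k / 2), min(k, 2)))
  on.exit(graphics::par(op))
  for (nm in names(x$results)) {
    plot(x$results[[nm]], main = nm, ...)
  }
  invisible(x)
}

#' Write a concordance comparison to TSV
#'
#' @param cmp a `concordance_comparison`.
#' @param path output TSV for the ranked summary.
#' @param points_path optional TSV for all per-set points and outlier
#'   flags.
#' @return `path`, invisibly.
#' @export
write_concordance <- function(cmp, path, points_path = NULL) {
  stopifnot(inherits(cmp, "concordance_comparison"))
  write_tsv(cmp$summary, path)
  if (!is.null(points_path)) {
    pts <- do.call(rbind, lapply(names(cmp$results), function(nm)
      cbind(reference = nm, cmp$results[[nm]]$points)))
    write_tsv(pts, points_path)
  }
  invisible(path)
}
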