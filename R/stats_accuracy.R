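#' Diagnostic accuracy of RyR positivity as a test for viability
#'
#' The dextran assay is the truth standard: dextran-positive myocytes are
#' dead, dextran-negative myocytes are viable. The RyR signal tests FOR
#' living myocytes, so a true positive is a RyR-positive, dextran-negative
#' cell. In terms of the four viability classes: TP = live, FN =
#' double-negative, TN = dead, FP = double-positive.
#'
#' @param records Cell records from [classify_cells()], or any data frame
#'   with a \code{class} column using those levels.
#' @return An \code{accuracy_report}: confusion counts and sensitivity,
#'   specificity, PPV, NPV in percent (\code{NA} and listed in
#'   \code{$undefined} when a denominator is zero).
#' @export
accuracy_from_records <- function(records) {
  cls <- as.character(records$class)
  accuracy_from_counts(tp = sum(cls == "live"),
                       fn = sum(cls == "double_negative"),
                       tn = sum(cls == "dead"),
                       fp = sum(cls == "double_positive"))
}

#' Accuracy report from explicit confusion counts
#'
#' @param tp,fn,tn,fp Non-negative confusion counts (positive test = RyR
#'   positive, condition = viable, i.e. dextran negative).
#' @return An \code{accuracy_report} list.
#' @rdname accuracy_from_records
#' @export
accuracy_from_counts <- function(tp, fn, tn, fp) {
  stopifnot(tp >= 0, fn >= 0, tn >= 0, fp >= 0)
  rate <- function(num, den) if (den > 0) 100 * num / den else NA_real_
  rep <- list(tp = tp, fn = fn, tn = tn, fp = fp,
              sensitivity = rate(tp, tp + fn),
              specificity = rate(tn, tn + fp),
              ppv = rate(tp, tp + fp),
              npv = rate(tn, tn + fn))
  rep$undefined <- names(which(vapply(rep[c("sensitivity", "specificity",
                                            "ppv", "npv")], is.na, logical(1))))
  class(rep) <- "accuracy_report"
  rep
}

#' @export
print.accuracy_report <- function(x, ...) {
  cat(sprintf("confusion: TP=%d FN=%d TN=%d FP=%d\n", x$tp, x$fn, x$tn, x$fp))
  cat(sprintf("sensitivity %.1f%%  specificity %.1f%%  PPV %.2f%%  NPV %.2f%%\n",
              x$sensitivity, x$specificity, x$ppv, x$npv))
  if (length(x$undefined))
    cat("undefined:", paste(x$undefined, collapse = ", "), "\n")
  invisible(x)
}

#' ROC sweep of the RyR classification threshold
#'
#' Reclassifies RyR positivity over a grid of thresholds on the dilated RyR
#' pixel fraction \code{f_ryr}, against the fixed dextran truth
#' (\code{f_dextran >= theta_dx}), and reports the false and true positive
#' rates per threshold. TPR is the fraction of viable (dextran-negative)
#' cells called RyR-positive; FPR the fraction of dead (dextran-positive)
#' cells called RyR-positive. Both are nonincreasing in the threshold; the
#' area under the curve is attached as the \code{"auc"} attribute
#' (trapezoidal rule).
#'
#' @param records Cell records from [classify_cells()] (needs \code{f_ryr}
#'   and \code{f_dextran}).
#' @param theta_grid Thresholds to sweep (default 0 to 1.05 in steps of
#'   0.01, so both endpoints are included).
#' @param theta_dx Dextran truth threshold (default 0.2).
#' @return Data frame (\code{theta}, \code{fpr}, \code{tpr}) with attribute
#'   \code{auc}.
#' @export
roc_sweep <- function(records, theta_grid = seq(0, 1.05, by = 0.01),
                      theta_dx = 0.2) {
  stopifnot(length(theta_grid) > 0)
  dead <- records$f_dextran >= theta_dx
  n_pos <- sum(!dead)     # condition positive: viable cells
  n_neg <- sum(dead)
  tpr <- fpr <- rep(NA_real_, length(theta_grid))
  for (i in seq_along(theta_grid)) {
    call_pos <- records$f_ryr >= theta_grid[i]
    tpr[i] <- if (n_pos > 0) sum(call_pos & !dead) / n_pos else NA_real_
    fpr[i] <- if (n_neg > 0) sum(call_pos & dead) / n_neg else NA_real_
  }
  out <- data.frame(theta = theta_grid, fpr = fpr, tpr = tpr)
  o <- order(out$fpr, out$tpr)
  auc <- if (n_pos > 0 && n_neg > 0) {
    xs <- c(0, out$fpr[o], 1); ys <- c(0, out$tpr[o], 1)
    sum(diff(xs) * (utils::head(ys, -1) + utils::tail(ys, -1)) / 2)
  } else NA_real_
  structure(out, auc = auc)
}

#' Linear regression of contraction force on living-cell fraction
#'
#' Ordinary least squares of slice contraction force (micronewtons) on the
#' fraction of living myocytes, with the coefficient of determination and
#' the F-test p-value against the constant (intercept-only) model.
#'
#' @param living_fraction Per-slice living-cell fractions in [0, 1].
#' @param force_uN Per-slice contraction forces (micronewtons).
#' @return A \code{force_regression} list: \code{slope}, \code{intercept},
#'   \code{r_squared}, \code{p_value}, \code{n}, \code{slope_ci} (95%).
#'   Zero variance in the fractions yields \code{NA} slope with
#'   \code{degenerate = TRUE}.
#' @export
force_regression <- function(living_fraction, force_uN) {
  stopifnot(length(living_fraction) == length(force_uN))
  n <- length(living_fraction)
  if (n < 3) stop("need at least 3 slices", call. = FALSE)
  if (any(living_fraction < -1e-9 | living_fraction > 1 + 1e-9))
    stop("living_fraction must lie in [0, 1]", call. = FALSE)
  if (stats::var(living_fraction) == 0) {
    return(structure(list(slope = NA_real_, intercept = mean(force_uN),
                          r_squared = NA_real_, p_value = NA_real_, n = n,
                          slope_ci = c(NA_real_, NA_real_), degenerate = TRUE),
                     class = "force_regression"))
  }
  fit <- stats::lm(force_uN ~ living_fraction)
  # suppressWarnings: summary.lm warns on noiseless (exact-fit) inputs
  sm <- suppressWarnings(summary(fit))
  fstat <- sm$fstatistic
  p <- if (is.null(fstat)) NA_real_ else
    stats::pf(fstat[1L], fstat[2L], fstat[3L], lower.tail = FALSE)
  ci <- tryCatch(suppressWarnings(stats::confint(fit)["living_fraction", ]),
                 error = function(e) c(NA_real_, NA_real_))
  structure(list(slope = unname(stats::coef(fit)[2L]),
                 intercept = unname(stats::coef(fit)[1L]),
                 r_squared = sm$r.squared,
                 p_value = unname(p),
                 n = n,
                 slope_ci = unname(ci),
                 degenerate = FALSE),
            class = "force_regression")
}

#' @export
print.force_regression <- function(x, ...) {
  cat(sprintf("force ~ living fraction (n = %d)\n", x$n))
  cat(sprintf("slope %.1f uN/unit (95%% CI %.1f to %.1f), intercept %.1f uN\n",
              x$slope, x$slope_ci[1L], x$slope_ci[2L], x$intercept))
  cat(sprintf("R^2 = %.3f, F-test vs constant model p = %.3g\n",
              x$r_squared, x$p_value))
  invisible(x)
}

#' Median, mean and 95% confidence interval of per-image values
#'
#' Normal-approximation interval \code{mean +/- 1.96 SE}; flagged when
#' fewer than 5 values contribute and degenerate for a single value.
#'
#' @param values Numeric vector (length >= 1).
#' @return List: \code{median}, \code{mean}, \code{ci_lower},
#'   \code{ci_upper}, \code{n}, \code{flags}.
#' @export
distribution_summary <- function(values) {
  if (!length(values)) stop("no values", call. = FALSE)
  n <- length(values)
  flags <- character(0)
  if (n == 1L) {
    flags <- "degenerate"
    return(list(median = values, mean = values, ci_lower = NA_real_,
                ci_upper = NA_real_, n = 1L, flags = flags))
  }
  if (n < 5L) flags <- "small_n"
  se <- stats::sd(values) / sqrt(n)
  m <- mean(values)
  list(median = stats::median(values), mean = m,
       ci_lower = m - 1.96 * se, ci_upper = m + 1.96 * se,
       n = n, flags = flags)
}

#' Group comparisons with Holm-Bonferroni correction
#'
#' Runs a family of two-group comparisons (two-tailed Welch's t-test for
#' unpaired, paired t-test for paired designs) and adjusts the p-value
#' family by Holm's step-down procedure. Comparisons whose test is
#' degenerate (e.g. all paired differences zero) get \code{NA} p-values and
#' are flagged, not silently dropped.
#'
#' @param comparisons Named list; each element is a list with numeric
#'   vectors \code{x} and \code{y} and optional logical \code{paired}.
#' @return Data frame: \code{comparison}, \code{statistic}, \code{p_raw},
#'   \code{p_holm}, \code{degenerate}.
#' @export
group_tests <- function(comparisons) {
  stopifnot(is.list(comparisons), length(comparisons) > 0)
  rows <- lapply(seq_along(comparisons), function(i) {
    cmp <- comparisons[[i]]
    paired <- isTRUE(cmp$paired)
    if (length(cmp$x) < 2 || length(cmp$y) < 2)
      stop("each group needs at least 2 values", call. = FALSE)
    if (paired && length(cmp$x) != length(cmp$y))
      stop("paired comparison requires equal lengths", call. = FALSE)
    ht <- tryCatch(stats::t.test(cmp$x, cmp$y, paired = paired,
                                 var.equal = FALSE),
                   error = function(e) NULL)
    p <- if (is.null(ht)) NA_real_ else ht$p.value
    bad <- is.null(ht) || !is.finite(p)
    data.frame(comparison = names(comparisons)[i] %||% as.character(i),
               statistic = if (is.null(ht)) NA_real_ else unname(ht$statistic),
               p_raw = if (bad) NA_real_ else p,
               degenerate = bad)
  })
  res <- do.call(rbind, rows)
  res$p_holm <- holm_adjust(res$p_raw)
  res[, c("comparison", "statistic", "p_raw", "p_holm", "degenerate")]
}

#' Holm step-down adjustment of a p-value family
#'
#' @param p Numeric vector of raw p-values (NA allowed).
#' @return Adjusted p-values, same order as input.
#' @export
holm_adjust <- function(p) {
  stats::p.adjust(p, method = "holm")
}
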