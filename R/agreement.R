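#' Per-class classification report
#'
#' Confusion matrix (rows = truth, columns = prediction), per-class
#' precision, recall, F1 (`2PR/(P+R)`, 0 where undefined) and support,
#' overall accuracy, and macro (unweighted) and support-weighted averages —
#' the standard multi-class summary for frame-level activity recognition.
#'
#' @param pred,truth [label_sequence()] objects (or character vectors of
#'   class codes) of equal length.
#' @return An object of class `classification_report`: list with
#'   `confusion` (8x8 matrix), `per_class` data.frame, `accuracy`, `macro`
#'   and `weighted` rows.
#' @export
classification_report <- function(pred, truth) {
  p <- if (inherits(pred, "label_sequence")) pred$labels else as.character(pred)
  t_ <- if (inherits(truth, "label_sequence")) truth$labels else as.character(truth)
  if (length(p) != length(t_)) stop("pred and truth lengths differ")
  lv <- activity_levels()
  cm <- table(factor(t_, levels = lv), factor(p, levels = lv))
  cm <- matrix(as.integer(cm), 8L, 8L, dimnames = list(truth = lv, pred = lv))
  tp <- diag(cm)
  support <- rowSums(cm)
  predicted <- colSums(cm)
  precision <- ifelse(predicted > 0, tp / predicted, 0)
  recall <- ifelse(support > 0, tp / support, 0)
  f1 <- ifelse(precision + recall > 0,
               2 * precision * recall / (precision + recall), 0)
  per_class <- data.frame(class = lv, precision = precision, recall = recall,
                          f1 = f1, support = as.integer(support),
                          row.names = NULL, stringsAsFactors = FALSE)
  wt <- support / sum(support)
  structure(
    list(confusion = cm, per_class = per_class,
         accuracy = sum(tp) / length(p),
         macro = c(precision = mean(precision), recall = mean(recall),
                   f1 = mean(f1)),
         weighted = c(precision = sum(wt * precision),
                      recall = sum(wt * recall), f1 = sum(wt * f1))),
    class = "classification_report"
  )
}

#' @export
print.classification_report <- function(x, ...) {
  cat("<classification_report>\n")
  print(cbind(round(x$per_class[2:4], 3),
              support = x$per_class$support), row.names = x$per_class$class)
  cat(sprintf("accuracy %.4f | macro F1 %.4f | weighted F1 %.4f\n",
              x$accuracy, x$macro[["f1"]], x$weighted[["f1"]]))
  invisible(x)
}

.check_pairs <- function(pred_s, ref_s, n_min = 2L) {
  if (length(pred_s) != length(ref_s)) stop("paired vectors differ in length")
  if (length(pred_s) < n_min) stop("need at least ", n_min, " pairs")
  stopifnot(all(is.finite(pred_s)), all(is.finite(ref_s)))
}

#' Bias of paired measurements with 95% confidence interval
#'
#' Bias is the mean of the differences `pred - ref`; its confidence
#' interval uses the t distribution with n-1 degrees of freedom.
#'
#' @param pred_s,ref_s paired measurements (e.g., lap times in seconds).
#' @return List with `bias`, `ci` (length-2), `n`.
#' @export
bias_ci <- function(pred_s, ref_s) {
  .check_pairs(pred_s, ref_s)
  d <- pred_s - ref_s
  n <- length(d)
  se <- stats::sd(d) / sqrt(n)
  half <- stats::qt(0.975, n - 1) * se
  list(bias = mean(d), ci = c(mean(d) - half, mean(d) + half), n = n)
}

#' Typical error of measurement with 95% confidence interval
#'
#' TEM = sd(differences) / sqrt(2) (the within-pair standard error of a
#' single measurement, Hopkins' convention). The confidence interval comes
#' from the chi-squared sampling distribution of `(n-1) sd^2 / sigma^2`.
#'
#' @inheritParams bias_ci
#' @return List with `tem`, `ci`, `n`.
#' @export
tem_ci <- function(pred_s, ref_s) {
  .check_pairs(pred_s, ref_s)
  d <- pred_s - ref_s
  n <- length(d)
  s <- stats::sd(d)
  lo <- s * sqrt((n - 1) / stats::qchisq(0.975, n - 1))
  hi <- s * sqrt((n - 1) / stats::qchisq(0.025, n - 1))
  list(tem = s / sqrt(2), ci = c(lo, hi) / sqrt(2), n = n)
}

#' Bland-Altman agreement analysis
#'
#' Mean difference (bias) and limits of agreement `bias +/- 1.96 sd` of the
#' paired differences, plus the per-pair means and differences for
#' plotting.
#'
#' @inheritParams bias_ci
#' @return List with `bias`, `loa` (lower, upper), `sd`, and a data.frame
#'   `points` (mean, diff).
#' @export
bland_altman <- function(pred_s, ref_s) {
  .check_pairs(pred_s, ref_s)
  d <- pred_s - ref_s
  s <- stats::sd(d)
  b <- mean(d)
  list(bias = b, loa = c(lower = b - 1.96 * s, upper = b + 1.96 * s), sd = s,
       points = data.frame(mean = (pred_s + ref_s) / 2, diff = d))
}

#' Mean absolute percentage error of paired measurements
#'
#' `MAPE = mean(|pred - ref| / ref) * 100`, with the SD of the per-pair
#' absolute percentage errors, and additionally expressed in seconds via
#' the reference mean (`MAPE/100 * mean(ref)`), the expected measurement
#' error on a typical lap.
#'
#' @inheritParams bias_ci
#' @return List with `mape_pct`, `sd_pct`, `mape_s`, `sd_s`, `n`.
#' @export
mape <- function(pred_s, ref_s) {
  .check_pairs(pred_s, ref_s, n_min = 1L)
  if (any(ref_s <= 0)) stop("all reference values must be positive")
  ape <- abs(pred_s - ref_s) / ref_s * 100
  m <- mean(ape)
  s <- if (length(ape) > 1L) stats::sd(ape) else 0
  list(mape_pct = m, sd_pct = s,
       mape_s = m / 100 * mean(ref_s), sd_s = s / 100 * mean(ref_s),
       n = length(ape))
}

#' Full lap-time agreement report
#'
#' Bundles [bias_ci()], [tem_ci()], [bland_altman()] and [mape()] for a
#' paired lap-duration comparison, overall and optionally per lap type.
#'
#' @param pairs data.frame with columns `pred_s` and `ref_s` (e.g., the
#'   `pairs` element of [pair_lap_tables()]), optionally `lap_type`.
#' @param by_type also compute per-lap-type reports when a `lap_type`
#'   column is present.
#' @return An object of class `agreement_report`.
#' @export
agreement_report <- function(pairs, by_type = TRUE) {
  stopifnot(is.data.frame(pairs), all(c("pred_s", "ref_s") %in% names(pairs)))
  one <- function(d) {
    list(n = nrow(d),
         mean_ref = mean(d$ref_s), sd_ref = stats::sd(d$ref_s),
         mean_pred = mean(d$pred_s), sd_pred = stats::sd(d$pred_s),
         bias = bias_ci(d$pred_s, d$ref_s),
         tem = tem_ci(d$pred_s, d$ref_s),
         bland_altman = bland_altman(d$pred_s, d$ref_s),
         mape = mape(d$pred_s, d$ref_s))
  }
  out <- list(overall = one(pairs))
  if (by_type && "lap_type" %in% names(pairs)) {
    out$by_type <- lapply(split(pairs, pairs$lap_type), function(d) {
      if (nrow(d) >= 2L) one(d)
    })
  }
  structure(out, class = "agreement_report")
}

#' @export
print.agreement_report <- function(x, ...) {
  o <- x$overall
  cat(sprintf(
    paste0("<agreement_report> n = %d laps\n",
           "  bias %.3f s [%.3f; %.3f] | TEM %.3f s [%.3f; %.3f]\n",
           "  LoA [%.3f; %.3f] s | MAPE %.2f%% +/- %.2f (%.2f s)\n"),
    o$n, o$bias$bias, o$bias$ci[1], o$bias$ci[2],
    o$tem$tem, o$tem$ci[1], o$tem$ci[2],
    o$bland_altman$loa[["lower"]], o$bland_altman$loa[["upper"]],
    o$mape$mape_pct, o$mape$sd_pct, o$mape$mape_s))
  if (!is.null(x$by_type)) {
    for (tp in names(x$by_type)) {
      t_ <- x$by_type[[tp]]
      if (is.null(t_)) next
      cat(sprintf("  %-6s n=%3d  bias %+.3f s  TEM %.3f s  MAPE %.2f%%\n",
                  tp, t_$n, t_$bias$bias, t_$tem$tem, t_$mape$mape_pct))
    }
  }
  invisible(x)
}
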