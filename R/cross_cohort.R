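## Cross-cohort application of a calibration panel and prediction-bias
## diagnostics: what happens when a model set trained on one lipoprotein
## phenotype is applied to spectra from another.

#' Predict one cohort's spectra with a (possibly foreign) panel
#'
#' Thin wrapper around [predict.lp_panel()] that also summarises, per
#' model, the fraction of predictions falling outside the panel's training
#' concentration range — the first sanity check before trusting
#' cross-cohort predictions.
#'
#' @param panel an `lp_panel`.
#' @param spectra an [lp_spectra()] object.
#' @return A [conc_table()] of predictions (mg/dL) with attributes
#'   `"out_of_range"` (logical matrix) and `"frac_out_of_range"` (per-model
#'   fraction).
#' @export
cross_predict <- function(panel, spectra) {
  pred <- predict(panel, spectra)
  oor <- attr(pred, "out_of_range")
  attr(pred, "frac_out_of_range") <- colMeans(oor)
  pred
}

#' Prediction-bias report
#'
#' Per (class, species): the mean signed error (predicted minus observed,
#' mg/dL), the slope and intercept of the predicted-vs-observed
#' least-squares line, and the fraction of out-of-range predictions. A well
#' calibrated panel applied to its own cohort gives mean signed errors near
#' zero and slopes near one; a phenotype-mismatched panel does not.
#'
#' @param pred predicted [conc_table()] (e.g. from [cross_predict()]).
#' @param obs observed [conc_table()] in the same units, matched samples.
#' @param classes classes to report (default: the modeled set).
#' @return An object of class `lp_bias`: data frame with columns `class`,
#'   `lipid`, `n`, `mean_error`, `slope`, `intercept`, `frac_out_of_range`.
#' @export
bias_report <- function(pred, obs, classes = NULL) {
  common <- intersect(rownames(pred), rownames(obs))
  if (length(common) < 3) stop("need at least 3 matched samples", call. = FALSE)
  if (is.null(classes)) {
    reg <- lp_registry()
    classes <- reg$name[reg$modeled]
  }
  keys <- intersect(as.vector(outer(classes, c("TG", "CH"), paste, sep = ".")),
                    intersect(colnames(pred), colnames(obs)))
  oor <- attr(pred, "out_of_range")
  rows <- lapply(keys, function(k) {
    p <- unclass(pred)[common, k]
    o <- unclass(obs)[common, k]
    fit <- stats::lm.fit(cbind(1, o), p)$coefficients
    data.frame(class = sub("\\.(TG|CH)$", "", k),
               lipid = sub("^.*\\.", "", k),
               n = length(common),
               mean_error = mean(p - o),
               slope = fit[2], intercept = fit[1],
               frac_out_of_range = if (!is.null(oor)) mean(oor[common, k]) else NA_real_,
               stringsAsFactors = FALSE)
  })
  out <- do.call(rbind, rows)
  rownames(out) <- NULL
  attr(out, "pred") <- unclass(pred)[common, keys, drop = FALSE]
  attr(out, "obs") <- unclass(obs)[common, keys, drop = FALSE]
  class(out) <- c("lp_bias", "data.frame")
  out
}

#' @export
print.lp_bias <- function(x, ...) {
  cat("Cross-cohort prediction bias (pred - obs, mg/dL):\n")
  print.data.frame(x, digits = 3)
  invisible(x)
}

#' Predicted-versus-observed bias plot
#'
#' One panel per (class, species): predictions against observations with
#' the identity line, the visual check for systematic over- or
#' under-estimation.
#'
#' @param x an `lp_bias` report.
#' @param keys subset of `"<class>.<species>"` panels to draw (default:
#'   first 12).
#' @param ... passed to [graphics::plot()].
#' @export
plot.lp_bias <- function(x, keys = NULL, ...) {
  pred <- attr(x, "pred"); obs <- attr(x, "obs")
  if (is.null(keys)) keys <- colnames(pred)[seq_len(min(12, ncol(pred)))]
  old <- graphics::par(mfrow = grDevices::n2mfrow(length(keys)),
                       mar = c(3, 3, 2, 1), mgp = c(1.8, 0.6, 0))
  on.exit(graphics::par(old))
  for (k in keys) {
    lim <- range(c(pred[, k], obs[, k]))
    graphics::plot(obs[, k], pred[, k], xlab = "observed (mg/dL)",
                   ylab = "predicted (mg/dL)", main = k,
                   xlim = lim, ylim = lim, pch = 20, ...)
    graphics::abline(0, 1, col = "darkgreen")
  }
  invisible(x)
}
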