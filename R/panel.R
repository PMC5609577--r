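## Full calibration panel: one PLS-1 model per (lipoprotein class, lipid
## species), with Kennard-Stone split, transform decision, LV selection,
## permutation significance, and training-CV / test validation metrics.

#' Calibrate the full panel of subclass models
#'
#' Runs the complete calibration procedure for every (class, species) pair
#' (2 species x 24 classes = 48 models by default): TG models use the
#' 1746-point methylene+methyl window, CH models the 961-point methyl
#' window. Samples are split once into training and test sets by
#' Kennard-Stone on the TG window; per model the response transform is
#' decided from training skewness, the number of latent variables selected
#' by 10-fold cross-validation with a parsimony rule, the model fitted on
#' the training set, its significance assessed by response permutation, and
#' validation metrics reported for the training set (from cross-validated
#' predictions) and the held-out test set.
#'
#' @param spectra an [lp_spectra()] object.
#' @param truth a [conc_table()] in mg/dL with matching sample ids.
#' @param train_size number of Kennard-Stone training samples.
#' @param lv_range latent-variable search range.
#' @param cv_folds folds for LV selection, training metrics and permutation.
#' @param B permutations per model (`0` skips significance testing).
#' @param alpha significance level on the permutation p-value.
#' @param seed seed for fold shuffling and permutations.
#' @param split optional pre-computed split (list with `train`, `test`).
#' @param classes classes to model (default: all registry classes).
#' @param skew_threshold absolute-skewness cutoff for the sqrt transform.
#' @param parsimony_tol relative CV-RMSE slack in LV selection.
#' @return An object of class `lp_panel`: list with `models` (named
#'   `lp_pls` list), `report` (long data frame, one row per model and
#'   evaluation set), `split`, `seed`, `settings`.
#' @export
calibrate_panel <- function(spectra, truth, train_size = 80,
                            lv_range = 1:15, cv_folds = 10, B = 1000,
                            alpha = 0.001, seed = 1, split = NULL,
                            classes = NULL, skew_threshold = 1.0,
                            parsimony_tol = 0.02) {
  if (!inherits(spectra, "lp_spectra")) stop("'spectra' must be lp_spectra", call. = FALSE)
  if (!inherits(truth, "conc_table")) stop("'truth' must be a conc_table", call. = FALSE)
  if (!identical(ct_units(truth), "mg/dL")) {
    stop("'truth' must be in mg/dL", call. = FALSE)
  }
  ids_sp <- rownames(spectra$intensity)
  if (!setequal(ids_sp, rownames(truth))) {
    stop("spectra and truth must share sample ids", call. = FALSE)
  }
  truth <- truth[match(ids_sp, rownames(truth)), , drop = FALSE]

  if (is.null(classes)) classes <- lp_registry()$name
  want <- as.vector(outer(classes, c("TG", "CH"), paste, sep = "."))
  missing <- setdiff(want, colnames(truth))
  if (length(missing)) {
    stop("truth table is missing columns: ", paste(missing, collapse = ", "),
         call. = FALSE)
  }

  Xw <- list(TG = extract_window(spectra, "TG"),
             CH = extract_window(spectra, "CH"))
  if (is.null(split)) split <- kennard_stone(Xw$TG, train_size)
  tr <- split$train; te <- split$test

  folds <- make_folds(length(tr), cv_folds, child_seed(seed, "folds"))
  prep <- lapply(Xw, function(X) .cv_prep(X[tr, , drop = FALSE], folds))

  models <- list()
  rows <- list()
  modeled <- lp_registry()
  for (cl in classes) {
    for (sp in c("TG", "CH")) {
      key <- paste0(cl, ".", sp)
      y <- unclass(truth)[, key]
      y_tr <- y[tr]; y_te <- y[te]
      Xtr <- Xw[[sp]][tr, , drop = FALSE]
      sqrt_flag <- as.logical(decide_sqrt_transform(y_tr, skew_threshold))
      yt_tr <- if (sqrt_flag) sqrt(y_tr) else y_tr

      n_lv <- select_n_lv(Xtr, yt_tr, lv_range = lv_range,
                          folds = folds, prep = prep[[sp]],
                          parsimony_tol = parsimony_tol)
      model <- fit_pls(Xtr, y_tr, n_lv, sqrt_transform = sqrt_flag,
                       lp_class = cl, lipid = sp, window = sp)

      cv_pred_t <- .cv_pred_from_prep(prep[[sp]], yt_tr, n_lv, last_only = TRUE)
      cv_pred <- if (sqrt_flag) pmax(cv_pred_t, 0)^2 else cv_pred_t
      m_train <- validation_metrics(y_tr, cv_pred)
      m_test <- validation_metrics(y_te, predict(model, Xw[[sp]][te, , drop = FALSE]))

      if (B > 0) {
        perm <- permutation_test(Xtr, yt_tr, n_lv, B = B,
                                 seed = child_seed(seed, key),
                                 folds = folds, prep = prep[[sp]])
        perm_p <- perm$p
        significant <- perm_p < alpha
      } else {
        perm_p <- NA_real_; significant <- NA
      }
      model$permutation_p <- perm_p
      model$significant <- significant
      models[[key]] <- model

      rows[[length(rows) + 1L]] <- data.frame(
        class = cl, lipid = sp,
        n_lv = as.integer(n_lv), sqrt = sqrt_flag,
        set = c("test", "training"),
        Q2 = c(m_test$Q2, m_train$Q2),
        R = c(m_test$R, m_train$R),
        RMSE_mgdl = c(m_test$RMSE, m_train$RMSE),
        CV_pct = c(m_test$CV_pct, m_train$CV_pct),
        perm_p = perm_p, significant = significant,
        modeled_expected = modeled$modeled[match(cl, modeled$name)],
        stringsAsFactors = FALSE)
    }
  }
  structure(list(models = models,
                 report = do.call(rbind, rows),
                 split = split, seed = seed,
                 settings = list(train_size = train_size, lv_range = lv_range,
                                 cv_folds = cv_folds, B = B, alpha = alpha,
                                 skew_threshold = skew_threshold,
                                 parsimony_tol = parsimony_tol)),
            class = "lp_panel")
}

#' @export
print.lp_panel <- function(x, ...) {
  n_sig <- sum(x$report$significant[x$report$set == "test"], na.rm = TRUE)
  cat(sprintf("Lipoprotein calibration panel: %d models (train %d / test %d)\n",
              length(x$models), length(x$split$train), length(x$split$test)))
  if (x$settings$B > 0) {
    cat(sprintf("  %d significant at p < %g (B = %d permutations)\n",
                n_sig, x$settings$alpha, x$settings$B))
  }
  invisible(x)
}

#' Summarise a calibration panel
#'
#' @param object an `lp_panel`.
#' @param set `"test"`, `"training"`, or `"both"`.
#' @param significant_only keep only models passing the permutation test.
#' @param ... unused.
#' @return The report data frame (class, lipid, n_lv, Q2, R, RMSE_mgdl,
#'   CV_pct, perm_p, significant), shaped like a validation summary table.
#' @export
summary.lp_panel <- function(object, set = c("both", "test", "training"),
                             significant_only = FALSE, ...) {
  set <- match.arg(set)
  rep <- object$report
  if (set != "both") rep <- rep[rep$set == set, ]
  if (significant_only) rep <- rep[!is.na(rep$significant) & rep$significant, ]
  rownames(rep) <- NULL
  rep
}

#' Predict a concentration table from a calibration panel
#'
#' @param object an `lp_panel`.
#' @param newdata an [lp_spectra()] object on the calibration grid.
#' @param ... unused.
#' @return A [conc_table()] (mg/dL) of predictions, with a logical matrix
#'   attribute `"out_of_range"` flagging predictions outside each model's
#'   training concentration range.
#' @export
predict.lp_panel <- function(object, newdata, ...) {
  if (!inherits(newdata, "lp_spectra")) stop("'newdata' must be lp_spectra", call. = FALSE)
  Xw <- list(TG = extract_window(newdata, "TG"),
             CH = extract_window(newdata, "CH"))
  keys <- names(object$models)
  pred <- matrix(NA_real_, nrow(newdata$intensity), length(keys),
                 dimnames = list(rownames(newdata$intensity), keys))
  oor <- pred
  for (k in keys) {
    m <- object$models[[k]]
    p <- predict(m, Xw[[m$window]])
    pred[, k] <- pmax(p, 0)    # concentrations are reported non-negative
    oor[, k] <- attr(p, "out_of_range")
  }
  out <- conc_table(pred, "mg/dL")
  attr(out, "out_of_range") <- oor > 0
  out
}
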