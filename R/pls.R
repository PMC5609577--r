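## PLS-1 calibration engine (NIPALS), cross-validation machinery,
## latent-variable selection, response-permutation significance, metrics.

## NIPALS PLS-1 on (X, y); returns cumulative coefficient paths so one run
## yields predictions for every component count a = 1..A (nested models).
.pls1_path <- function(X, y, A) {
  X <- as.matrix(X)
  y <- as.numeric(y)
  n <- nrow(X); p <- ncol(X)
  A <- min(A, n - 1L, p)
  xmean <- colMeans(X)
  ymean <- mean(y)
  Xc <- sweep(X, 2, xmean)
  yc <- y - ymean
  W <- matrix(0, p, A); P <- matrix(0, p, A); Q <- numeric(A)
  R <- matrix(0, p, A)                        # r_a: W (P'W)^{-1} columns
  B <- matrix(0, p, A)
  scale0 <- sqrt(sum(Xc^2) * sum(yc^2)) + .Machine$double.eps
  ncomp <- 0L
  for (a in seq_len(A)) {
    w <- crossprod(Xc, yc)[, 1]
    nw <- sqrt(sum(w^2))
    if (nw < 1e-12 * scale0) break            # rank / signal exhausted
    w <- w / nw
    t_sc <- Xc %*% w
    tt <- sum(t_sc^2)
    if (tt < 1e-14 * max(1, sum(Xc^2))) break
    p_load <- crossprod(Xc, t_sc)[, 1] / tt
    q <- sum(t_sc * yc) / tt
    Xc <- Xc - tcrossprod(t_sc, p_load)
    yc <- yc - t_sc[, 1] * q
    W[, a] <- w; P[, a] <- p_load; Q[a] <- q
    ## coefficient recursion: r_a = w_a - R_{<a} (P_{<a}' w_a)
    r <- w
    if (a > 1) {
      r <- r - R[, 1:(a - 1), drop = FALSE] %*%
        crossprod(P[, 1:(a - 1), drop = FALSE], w)
    }
    R[, a] <- r
    B[, a] <- if (a > 1) B[, a - 1] + r * q else r * q
    ncomp <- a
  }
  list(xmean = xmean, ymean = ymean, ncomp = ncomp,
       W = W[, seq_len(ncomp), drop = FALSE],
       P = P[, seq_len(ncomp), drop = FALSE],
       Q = Q[seq_len(ncomp)],
       B = B[, seq_len(ncomp), drop = FALSE])
}

.pls1_predict <- function(path, Xnew, a = path$ncomp) {
  a <- min(a, path$ncomp)
  drop(path$ymean + sweep(as.matrix(Xnew), 2, path$xmean) %*% path$B[, a])
}

#' Cross-validation folds
#'
#' Seeded shuffle of `1:n` dealt into `k` near-equal folds.
#'
#' @param n number of samples; @param k number of folds; @param seed RNG seed.
#' @return List of `k` integer index vectors.
#' @export
make_folds <- function(n, k = 10, seed = 1) {
  stopifnot_scalar_count(n, "n", 2L)
  k <- min(k, n)
  idx <- with_seed(seed, sample.int(n))
  unname(split(idx, rep(seq_len(k), length.out = n)))
}

## Per-fold preprocessing reused across responses and permutation reps.
## With p >> n the training block is rotated into its row space by a thin
## SVD (X = U D V'): PLS-1 scores and predictions depend on X only through
## this basis, so fitting on Z = U D with test rows projected onto V is
## exact and turns every subsequent fit into an n x n problem.
.cv_prep <- function(X, folds) {
  X <- as.matrix(X)
  lapply(folds, function(te) {
    tr <- setdiff(seq_len(nrow(X)), te)
    xm <- colMeans(X[tr, , drop = FALSE])
    Xtr <- sweep(X[tr, , drop = FALSE], 2, xm)
    Xte <- sweep(X[te, , drop = FALSE], 2, xm)
    if (ncol(X) > length(tr)) {
      sv <- svd(Xtr)
      Ztr <- sv$u %*% diag(sv$d, length(sv$d))
      Zte <- Xte %*% sv$v
    } else {
      Ztr <- Xtr; Zte <- Xte
    }
    list(tr = tr, te = te, Ztr = Ztr, Zte = Zte)
  })
}

## CV predictions for a = 1..lv_max (matrix n x lv_max), or only for
## a = lv_max when `last_only` (vector of length n).
.cv_pred_from_prep <- function(prep, y, lv_max, last_only = FALSE) {
  n <- length(y)
  out <- if (last_only) numeric(n) else matrix(NA_real_, n, lv_max)
  for (f in prep) {
    path <- .pls1_path(f$Ztr, y[f$tr], lv_max)
    if (path$ncomp == 0L) {
      if (last_only) out[f$te] <- path$ymean else out[f$te, ] <- path$ymean
      next
    }
    Zc <- sweep(f$Zte, 2, path$xmean)
    if (last_only) {
      out[f$te] <- path$ymean + Zc %*% path$B[, path$ncomp]
    } else {
      pr <- path$ymean + Zc %*% path$B
      if (path$ncomp < lv_max) {
        pr <- cbind(pr, matrix(pr[, path$ncomp], nrow(pr),
                               lv_max - path$ncomp))
      }
      out[f$te, ] <- pr
    }
  }
  out
}

.q2 <- function(y, pred) 1 - sum((y - pred)^2) / sum((y - mean(y))^2)

#' Fit a PLS-1 calibration model
#'
#' Mean-centered NIPALS PLS-1 regression of a single concentration on a
#' spectral feature matrix. With `sqrt_transform = TRUE` the model is fitted
#' to `sqrt(y)` (the transform applied to right-skewed concentration
#' distributions) and predictions are squared back to the original scale,
#' clipping negative square-root-scale predictions to zero.
#'
#' @param X numeric matrix (samples x spectral points).
#' @param y non-negative response concentrations (original scale, mg/dL).
#' @param n_lv number of latent variables; must not exceed the rank of the
#'   centered `X`.
#' @param sqrt_transform model `sqrt(y)` instead of `y`.
#' @param lp_class,lipid,window optional metadata labels carried on the model.
#' @return An object of class `lp_pls` with components `coefficients`,
#'   `x_mean`, `y_mean`, `weights`, `loadings`, `n_lv`, `sqrt_transformed`,
#'   `y_range` (training range, original scale), `fitted`, `residuals`.
#' @export
#' @examples
#' X <- matrix(rnorm(200), 20)
#' y <- 2 + X[, 1]
#' m <- fit_pls(X, y, 1)
#' max(abs(fitted(m) - y)) < 1e-8
fit_pls <- function(X, y, n_lv, sqrt_transform = FALSE,
                    lp_class = NA_character_, lipid = NA_character_,
                    window = NA_character_) {
  X <- as.matrix(X)
  y <- as.numeric(y)
  if (nrow(X) != length(y)) stop("nrow(X) must equal length(y)", call. = FALSE)
  stopifnot_scalar_count(n_lv, "n_lv", 1L)
  if (nrow(X) < n_lv + 1) stop("need at least n_lv + 1 samples", call. = FALSE)
  if (sqrt_transform) {
    if (any(y < 0)) stop("sqrt transform requires non-negative y", call. = FALSE)
    yt <- sqrt(y)
  } else {
    yt <- y
  }
  path <- .pls1_path(X, yt, n_lv)
  if (path$ncomp < n_lv) {
    stop(sprintf("n_lv = %d exceeds the effective rank (%d components extractable)",
                 n_lv, path$ncomp), call. = FALSE)
  }
  fit_t <- .pls1_predict(path, X, n_lv)
  fitted_orig <- if (sqrt_transform) pmax(fit_t, 0)^2 else fit_t
  obj <- structure(list(
    coefficients = path$B[, n_lv],
    x_mean = path$xmean, y_mean = path$ymean,
    weights = path$W, loadings = path$P, y_loadings = path$Q,
    n_lv = as.integer(n_lv), sqrt_transformed = sqrt_transform,
    y_range = range(y),
    fitted = fitted_orig, residuals = y - fitted_orig,
    lp_class = lp_class, lipid = lipid, window = window,
    n_train = nrow(X)), class = "lp_pls")
  obj
}

#' @export
print.lp_pls <- function(x, ...) {
  lab <- if (!is.na(x$lp_class)) paste0(x$lp_class, "-", x$lipid) else "response"
  cat(sprintf("PLS-1 model for %s: %d latent variables, %d training samples%s\n",
              lab, x$n_lv, x$n_train,
              if (x$sqrt_transformed) ", sqrt-transformed response" else ""))
  cat(sprintf("  training range: [%.3g, %.3g]; training RMSE %.4g\n",
              x$y_range[1], x$y_range[2], sqrt(mean(x$residuals^2))))
  invisible(x)
}

#' @export
coef.lp_pls <- function(object, ...) object$coefficients

#' @export
fitted.lp_pls <- function(object, ...) object$fitted

#' @export
residuals.lp_pls <- function(object, ...) object$residuals

#' Predict concentrations from a fitted PLS-1 model
#'
#' @param object an `lp_pls` model.
#' @param newdata spectral feature matrix with the model's window length.
#' @param ... unused.
#' @return Numeric vector of predictions on the original concentration
#'   scale, with a logical attribute `"out_of_range"` flagging predictions
#'   outside the model's training concentration range.
#' @export
predict.lp_pls <- function(object, newdata, ...) {
  newdata <- as.matrix(newdata)
  if (ncol(newdata) != length(object$coefficients)) {
    stop(sprintf("newdata has %d columns; model expects %d",
                 ncol(newdata), length(object$coefficients)), call. = FALSE)
  }
  pred_t <- drop(object$y_mean +
                   sweep(newdata, 2, object$x_mean) %*% object$coefficients)
  pred <- if (object$sqrt_transformed) pmax(pred_t, 0)^2 else pred_t
  attr(pred, "out_of_range") <- pred < object$y_range[1] | pred > object$y_range[2]
  pred
}

#' Select the number of latent variables by cross-validation
#'
#' Runs k-fold cross-validation over the search range and returns the
#' smallest component count whose CV-RMSE is within `parsimony_tol`
#' (default 2%) of the global minimum.
#'
#' @param X spectral feature matrix; @param y response (modeling scale).
#' @param lv_range candidate latent-variable counts.
#' @param cv_folds number of folds; @param seed fold-shuffle seed.
#' @param parsimony_tol relative CV-RMSE slack for preferring fewer LVs.
#' @param folds optional pre-built fold list (overrides `cv_folds`/`seed`).
#' @param prep internal: precomputed `.cv_prep` result for `X`/`folds`.
#' @return Integer `n_lv`, with attributes `cv_rmse` (per candidate) and
#'   `seed`.
#' @export
select_n_lv <- function(X, y, lv_range = 1:15, cv_folds = 10, seed = 1,
                        parsimony_tol = 0.02, folds = NULL, prep = NULL) {
  y <- as.numeric(y)
  if (stats::var(y) < .Machine$double.eps * max(1, mean(y)^2)) {
    stop("response has zero variance; nothing to calibrate", call. = FALSE)
  }
  n <- length(y)
  if (is.null(folds)) folds <- make_folds(n, cv_folds, seed)
  if (is.null(prep)) prep <- .cv_prep(X, folds)
  lv_max <- min(max(lv_range), n - max(lengths(folds)) - 1L, ncol(as.matrix(X)))
  lv_range <- lv_range[lv_range <= lv_max]
  if (length(lv_range) == 0) stop("lv_range empty after rank capping", call. = FALSE)
  preds <- .cv_pred_from_prep(prep, y, max(lv_range))
  rmse <- sqrt(colMeans((preds[, lv_range, drop = FALSE] - y)^2))
  best <- min(rmse)
  ## absolute floor keeps the parsimony rule meaningful when the relation is
  ## (numerically) exact and every candidate RMSE is ~ machine noise
  thresh <- best * (1 + parsimony_tol) + 1e-8 * stats::sd(y)
  n_lv <- lv_range[which(rmse <= thresh)[1]]
  structure(as.integer(n_lv), cv_rmse = stats::setNames(rmse, lv_range),
            seed = seed)
}

#' Response-permutation significance test
#'
#' The observed statistic is the k-fold cross-validated Q2 of the model with
#' the true response; the null distribution is the same statistic with the
#' response permuted afresh each repetition (same folds, same number of
#' latent variables). The p-value uses the add-one estimator
#' `(#\{null >= observed\} + 1) / (B + 1)`, so with B = 1000 a model can
#' reach p < 0.001 only by beating every permutation.
#'
#' @inheritParams select_n_lv
#' @param n_lv number of latent variables (fixed, as selected for the real
#'   response).
#' @param B number of permutations.
#' @return An object of class `lp_perm`: list with `observed` (CV-Q2),
#'   `null_stats`, `p`, `B`, `seed`.
#' @export
permutation_test <- function(X, y, n_lv, B = 1000, seed = 1, cv_folds = 10,
                             folds = NULL, prep = NULL) {
  stopifnot_scalar_count(B, "B", 1L)
  y <- as.numeric(y)
  n <- length(y)
  if (is.null(folds)) folds <- make_folds(n, cv_folds, seed)
  if (is.null(prep)) prep <- .cv_prep(X, folds)
  obs_pred <- .cv_pred_from_prep(prep, y, n_lv, last_only = TRUE)
  observed <- .q2(y, obs_pred)
  null_stats <- with_seed(child_seed(seed, "perm"), {
    vapply(seq_len(B), function(b) {
      yp <- y[sample.int(n)]
      .q2(yp, .cv_pred_from_prep(prep, yp, n_lv, last_only = TRUE))
    }, numeric(1))
  })
  p <- (sum(null_stats >= observed) + 1) / (B + 1)
  structure(list(observed = observed, null_stats = null_stats, p = p,
                 B = as.integer(B), seed = seed), class = "lp_perm")
}

#' @export
print.lp_perm <- function(x, ...) {
  cat(sprintf("Response-permutation test: observed CV-Q2 = %.4f, B = %d, p = %.4g\n",
              x$observed, x$B, x$p))
  invisible(x)
}

#' Validation metrics for a calibration model
#'
#' Standard chemometric external-validation metrics, all computed on the
#' original concentration scale of the evaluated set:
#' `Q2 = 1 - sum((y - yhat)^2) / sum((y - mean(y))^2)`,
#' `RMSE = sqrt(mean((y - yhat)^2))`, `CV_pct = 100 * RMSE / mean(y)`, and
#' `R` the Pearson correlation between observed and predicted.
#'
#' @param y_obs,y_pred equal-length numeric vectors (n >= 2).
#' @return Named list with `Q2`, `R`, `RMSE`, `CV_pct`.
#' @export
#' @examples
#' validation_metrics(c(1, 2, 3), c(1, 2, 4))
validation_metrics <- function(y_obs, y_pred) {
  y_obs <- as.numeric(y_obs); y_pred <- as.numeric(y_pred)
  if (length(y_obs) != length(y_pred) || length(y_obs) < 2) {
    stop("y_obs and y_pred must be equal-length vectors with n >= 2", call. = FALSE)
  }
  tss <- sum((y_obs - mean(y_obs))^2)
  if (tss < .Machine$double.eps * max(1, mean(y_obs)^2)) {
    stop("y_obs has zero variance; Q2 is undefined", call. = FALSE)
  }
  rmse <- sqrt(mean((y_obs - y_pred)^2))
  r <- if (stats::sd(y_pred) > 0) stats::cor(y_obs, y_pred) else NA_real_
  list(Q2 = 1 - sum((y_obs - y_pred)^2) / tss,
       R = r,
       RMSE = rmse,
       CV_pct = 100 * rmse / mean(y_obs))
}
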