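## Shared fixtures, computed lazily and cached for the whole test run.

.fixture_cache <- new.env(parent = emptyenv())

fixture <- function(name, expr) {
  if (!exists(name, envir = .fixture_cache, inherits = FALSE)) {
    assign(name, force(expr), envir = .fixture_cache)
  }
  get(name, envir = .fixture_cache, inherits = FALSE)
}

## the default calibration cohort (the study conditions: n = 122, seed 1)
cohort_main <- function() {
  fixture("cohort_main", simulate_cohort("low_hdl_cm", n = 122, seed = 1))
}

cohort_other <- function() {
  fixture("cohort_other", simulate_cohort("hyperchol", n = 122, seed = 2))
}

## panels without permutation testing (Q2/RMSE/CV do not depend on B)
panel_main <- function() {
  fixture("panel_main",
          calibrate_panel(cohort_main()$spectra, cohort_main()$truth,
                          train_size = 80, B = 0, seed = 1))
}

panel_other <- function() {
  fixture("panel_other",
          calibrate_panel(cohort_other()$spectra, cohort_other()$truth,
                          train_size = 80, B = 0, seed = 2))
}

## main-cohort held-out test samples and their truth
main_test_set <- function() {
  fixture("main_test_set", {
    te <- panel_main()$split$test
    co <- cohort_main()
    list(spectra = lp_spectra(co$spectra$ppm,
                              co$spectra$intensity[te, , drop = FALSE]),
         truth = conc_table(unclass(co$truth)[te, , drop = FALSE], "mg/dL"))
  })
}

## independent brute-force Kennard-Stone oracle: literal definition,
## enumerating all distances at every step
ks_oracle <- function(X, m_train) {
  n <- nrow(X)
  D <- matrix(0, n, n)
  for (i in seq_len(n)) for (j in seq_len(n)) {
    D[i, j] <- sqrt(sum((X[i, ] - X[j, ])^2))
  }
  best <- c(1L, 2L); bestd <- -Inf
  for (i in seq_len(n - 1)) for (j in (i + 1):n) {
    if (D[i, j] > bestd) { bestd <- D[i, j]; best <- c(i, j) }
  }
  sel <- best
  while (length(sel) < m_train) {
    cand <- setdiff(seq_len(n), sel)
    mind <- sapply(cand, function(i) min(D[i, sel]))
    sel <- c(sel, cand[which.max(mind)])
  }
  sel
}

## tiny random concentration row covering a few subclasses
demo_conc <- function(classes = c("VLDL05", "LDL09", "HDL17")) {
  conc <- c(20, 50, 15, 30, 10, 5)
  names(conc) <- as.vector(outer(classes, c("TG", "CH"), paste, sep = "."))[1:6]
  conc
}
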