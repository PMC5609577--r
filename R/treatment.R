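## Crossover treatment analysis: design assembly, mixed-effects ANCOVA with
## subject random intercepts, least-squares means, percent differences, and
## Dunnett-type multiplicity adjustment.

#' Assemble the analysis design for one outcome
#'
#' Builds one analysis row per post-treatment observation of a single
#' (class, species) outcome: treatment, the subject's same-period baseline
#' concentration as a continuous covariate, gender, age, BMI, and the visit
#' factor. Subject-periods lacking a baseline are dropped with a warning;
#' listed subjects are excluded entirely.
#'
#' @param study an `lp_crossover` object (or a compatible long records data
#'   frame with a `subjects` covariate table attached the same way).
#' @param lp_class,lipid the outcome to analyse.
#' @param exclude subject ids to drop (e.g. from [detect_outliers()]).
#' @return Data frame with columns `subject, treatment, baseline, gender,
#'   age, bmi, visit, outcome` (concentrations in mmol/L).
#' @export
build_design <- function(study, lp_class, lipid, exclude = character(0)) {
  rec <- study$records
  rec <- rec[rec$class == lp_class & rec$lipid == lipid, ]
  if (nrow(rec) == 0) stop("no records for ", lp_class, "-", lipid, call. = FALSE)
  rec <- rec[!rec$subject %in% exclude, ]
  base <- rec[is.na(rec$visit), ]
  post <- rec[!is.na(rec$visit), ]
  bkey <- paste(base$subject, base$period)
  pkey <- paste(post$subject, post$period)
  post$baseline <- base$value_mmol[match(pkey, bkey)]
  if (anyNA(post$baseline)) {
    miss <- unique(pkey[is.na(post$baseline)])
    warning("dropping subject-periods without baseline: ",
            paste(miss, collapse = ", "), call. = FALSE)
    post <- post[!is.na(post$baseline), ]
  }
  i <- match(post$subject, study$subjects$subject)
  out <- data.frame(subject = factor(post$subject),
                    period = factor(post$period),
                    treatment = factor(post$treatment, levels = c("placebo", "TB")),
                    baseline = post$baseline,
                    gender = factor(study$subjects$gender[i]),
                    age = study$subjects$age[i],
                    bmi = study$subjects$bmi[i],
                    visit = factor(post$visit),
                    outcome = post$value_mmol,
                    stringsAsFactors = FALSE)
  rownames(out) <- NULL
  out
}

#' Fit the mixed-effects treatment model for one outcome
#'
#' Linear mixed model (REML) with fixed effects treatment, same-period
#' baseline, gender, age, BMI and visit, and random intercepts for subject
#' and for period within subject. The nested term matters: the same-period
#' baseline covariate carries one realisation of measurement noise shared
#' by both visits of a period, so omitting it leaves period-level
#' correlation in the residuals and an anticonservative treatment standard
#' error (treatment varies at period level). Least-squares means are the
#' model's marginal means at the mean of the continuous covariates,
#' averaging over the levels of the categorical factors; the treatment
#' p-value is the two-sided test of the TB-vs-placebo contrast
#' (Satterthwaite degrees of freedom). Boundary (singular) variance
#' estimates are accepted; only an outright fitting failure falls back to
#' a fixed-effects model with subject as a factor (dropping the
#' subject-constant covariates), with a warning.
#'
#' @param rows design rows from [build_design()].
#' @return One-row data frame: `lsmean_placebo, lsmean_tb, se_placebo,
#'   se_tb, pct_diff, p_value, method`.
#' @export
fit_mixed_model <- function(rows) {
  if (length(unique(rows$subject[rows$treatment == "placebo"])) < 2 ||
      length(unique(rows$subject[rows$treatment == "TB"])) < 2) {
    stop("need at least 2 subjects per treatment", call. = FALSE)
  }
  ## standardise continuous covariates for the fit; least-squares means at
  ## covariate means are invariant to this, and it keeps the fixed-effect
  ## columns on comparable scales
  for (v in c("baseline", "age", "bmi")) {
    if (stats::sd(rows[[v]]) > 0) {
      rows[[v]] <- as.numeric(scale(rows[[v]]))
    }
  }
  ## drop constant covariates (e.g. single-gender simulations)
  terms <- c("treatment", "baseline",
             if (nlevels(droplevels(rows$gender)) > 1) "gender",
             if (stats::sd(rows$age) > 0) "age",
             if (stats::sd(rows$bmi) > 0) "bmi",
             if (nlevels(droplevels(rows$visit)) > 1) "visit")
  fml <- stats::reformulate(c(terms, "(1 | subject)", "(1 | subject:period)"),
                            response = "outcome")
  fit <- tryCatch(
    suppressMessages(lmerTest::lmer(fml, data = rows,
                                    control = lme4::lmerControl(
                                      check.conv.singular = "ignore"))),
    error = function(e) NULL)
  method <- "lmm"
  if (is.null(fit)) {
    warning("mixed model singular or failed; falling back to subject fixed effects",
            call. = FALSE)
    terms_fe <- setdiff(terms, c("gender", "age", "bmi"))
    fml_fe <- stats::reformulate(c(terms_fe, "subject"), response = "outcome")
    fit <- stats::lm(fml_fe, data = rows)
    method <- "subject-fixed"
  }
  emm <- emmeans::emmeans(fit, "treatment",
                          lmer.df = "satterthwaite",
                          lmerTest.limit = 1e5)
  es <- as.data.frame(emm)
  ctr <- as.data.frame(emmeans::contrast(emm, method = list("TB - placebo" = c(-1, 1))))
  lsm <- stats::setNames(es$emmean, as.character(es$treatment))
  se <- stats::setNames(es$SE, as.character(es$treatment))
  data.frame(lsmean_placebo = lsm[["placebo"]], lsmean_tb = lsm[["TB"]],
             se_placebo = se[["placebo"]], se_tb = se[["TB"]],
             pct_diff = percent_difference(lsm[["placebo"]], lsm[["TB"]]),
             p_value = ctr$p.value[1], method = method,
             stringsAsFactors = FALSE)
}

#' Percent difference of least-squares means
#'
#' `100 * (lsmean_tb - lsmean_placebo) / lsmean_placebo`: the active-arm
#' effect relative to placebo.
#'
#' @param lsmean_placebo placebo LS mean (> 0); @param lsmean_tb active LS
#'   mean.
#' @return Percent difference (unrounded; report tables round to 2
#'   decimals).
#' @export
#' @examples
#' round(percent_difference(3.017, 2.859), 2) # -5.24
percent_difference <- function(lsmean_placebo, lsmean_tb) {
  if (any(lsmean_placebo <= 0)) {
    stop("placebo LS mean must be positive", call. = FALSE)
  }
  100 * (lsmean_tb - lsmean_placebo) / lsmean_placebo
}

#' Dunnett-type adjusted p-value
#'
#' Two-sided many-to-one comparison adjustment based on the equicoordinate
#' multivariate t distribution with the balanced-design correlation 0.5
#' between contrasts. With a single comparison (`k = 1`) this reduces to
#' the raw two-sided t p-value.
#'
#' @param t_value observed t statistic(s).
#' @param df degrees of freedom.
#' @param k number of active-vs-control comparisons.
#' @param rho correlation between contrasts (0.5 for balanced designs).
#' @return Adjusted p-value(s).
#' @export
dunnett_p <- function(t_value, df, k = 1, rho = 0.5) {
  vapply(seq_along(t_value), function(i) {
    a <- abs(t_value[i])
    if (k <= 1) return(2 * stats::pt(-a, df))
    S <- matrix(rho, k, k); diag(S) <- 1
    1 - mvtnorm::pmvt(lower = rep(-a, k), upper = rep(a, k),
                      df = as.integer(round(df)), corr = S)[1]
  }, numeric(1))
}

#' Post-hoc multiplicity adjustment of treatment estimates
#'
#' With exactly two treatment arms the Dunnett-type adjustment is the
#' identity, so each outcome's adjusted p equals its raw treatment-contrast
#' p; the operation exists as a labelled pass-through that generalises to
#' several active arms via [dunnett_p()].
#'
#' @param estimates an effect table (e.g. from [treatment_effects()]) with
#'   a `p_value` column.
#' @param k number of active-vs-control comparisons per outcome.
#' @param df degrees of freedom (required when `k > 1`).
#' @param t_value t statistics (required when `k > 1`).
#' @return `estimates` with columns `p_adjusted` and `adjusted` added.
#' @export
adjust_posthoc <- function(estimates, k = 1, df = NULL, t_value = NULL) {
  if (nrow(estimates) == 0) {
    estimates$p_adjusted <- numeric(0)
    estimates$adjusted <- logical(0)
    return(estimates)
  }
  if (k <= 1) {
    estimates$p_adjusted <- estimates$p_value
  } else {
    if (is.null(df) || is.null(t_value)) {
      stop("k > 1 requires 'df' and 't_value'", call. = FALSE)
    }
    estimates$p_adjusted <- dunnett_p(t_value, df, k)
  }
  estimates$adjusted <- TRUE
  estimates
}

#' Treatment-effect analysis across all modeled outcomes
#'
#' Runs outlier screening (PCA on the unit-variance scaled sample-by-outcome
#' concentration matrix, Hotelling T2 with whole-subject escalation),
#' assembles the design and fits the mixed model for every modeled
#' (class, species) outcome, and applies the two-arm post-hoc pass-through.
#'
#' @param study an `lp_crossover` object.
#' @param exclude subject ids to exclude, or `NULL` to screen automatically.
#' @param alpha significance level used for the `significant` flag.
#' @return An object of class `lp_effect`: data frame with one row per
#'   outcome (`class, lipid, lsmean_placebo, lsmean_tb, se_placebo, se_tb,
#'   pct_diff, p_value, p_adjusted, significant`), with excluded subjects in
#'   attribute `"excluded"`.
#' @export
treatment_effects <- function(study, exclude = NULL, alpha = 0.05) {
  rec <- study$records
  outcomes <- unique(rec[, c("class", "lipid")])
  if (is.null(exclude)) {
    key <- paste(rec$class, rec$lipid, sep = ".")
    sd_key <- paste(rec$subject, rec$day)
    m <- matrix(NA_real_, length(unique(sd_key)), nrow(outcomes),
                dimnames = list(unique(sd_key), unique(key)))
    m[cbind(match(sd_key, rownames(m)), match(key, colnames(m)))] <- rec$value_mmol
    keep <- stats::complete.cases(m)
    sc <- pca_scores(scale(m[keep, , drop = FALSE]), 2)
    exclude <- as.character(detect_outliers(sc, sub(" .*$", "", rownames(m)[keep])))
  }
  rows <- lapply(seq_len(nrow(outcomes)), function(i) {
    d <- build_design(study, outcomes$class[i], outcomes$lipid[i], exclude = exclude)
    cbind(outcomes[i, ], fit_mixed_model(d), row.names = NULL)
  })
  out <- do.call(rbind, rows)
  out <- adjust_posthoc(out)
  out$significant <- out$p_adjusted < alpha
  rownames(out) <- NULL
  attr(out, "excluded") <- exclude
  class(out) <- c("lp_effect", "data.frame")
  out
}

#' @export
print.lp_effect <- function(x, ...) {
  cat(sprintf("Crossover treatment effects (%d outcomes; %d excluded subjects)\n",
              nrow(x), length(attr(x, "excluded"))))
  df <- as.data.frame(x)
  df$pct_diff <- round(df$pct_diff, 2)
  print.data.frame(df, digits = 3)
  invisible(x)
}

#' Write a treatment-effect table to CSV
#'
#' @param effects an `lp_effect` table; @param path CSV file path.
#' @return `path`, invisibly.
#' @export
write_effects <- function(effects, path) {
  df <- as.data.frame(effects)
  df$pct_diff <- round(df$pct_diff, 2)
  utils::write.csv(df, path, row.names = FALSE)
  invisible(path)
}
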