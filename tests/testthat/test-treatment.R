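test_that("design assembly counts rows and handles missing baselines", {
  st <- simulate_crossover_study(n_subjects = 40, seed = 33)
  d <- build_design(st, "LDL_tot", "CH")
  expect_equal(nrow(d), 40 * 2 * 2)          # subjects x periods x visits
  expect_setequal(levels(d$treatment), c("placebo", "TB"))
  expect_true(all(table(d$subject) == 4))

  ## drop a subject's period-2 baseline: its period-2 rows disappear
  st2 <- st
  drop_row <- with(st2$records, subject == "S05" & day == "D57" &
                     class == "LDL_tot" & lipid == "CH")
  st2$records <- st2$records[!drop_row, ]
  expect_warning(d2 <- build_design(st2, "LDL_tot", "CH"), "S05 2")
  expect_equal(nrow(d2), 158)
  expect_equal(sum(d2$subject == "S05"), 2)

  ## exclusions remove whole subjects
  d3 <- build_design(st, "LDL_tot", "CH", exclude = c("S01", "S02", "S03"))
  expect_equal(nrow(d3), 37 * 4)
})

test_that("balanced no-covariate data: LSMean difference equals raw difference", {
  set.seed(34)
  n <- 16
  rows <- expand.grid(subject = sprintf("S%02d", 1:n),
                      treatment = c("placebo", "TB"), visit = c(1, 2))
  rows$treatment <- factor(rows$treatment, levels = c("placebo", "TB"))
  rows$visit <- factor(rows$visit)
  rows$subject <- factor(rows$subject)
  ## alternate sequence allocation: balanced periods
  first_tb <- as.integer(rows$subject) %% 2 == 0
  rows$period <- factor(ifelse((rows$treatment == "TB") == first_tb, 1, 2))
  rows$baseline <- 1                          # constant: drops out
  rows$gender <- factor("M", levels = c("M")) # single level: dropped
  rows$age <- 60; rows$bmi <- 29
  u <- rnorm(n, 0, 0.5)
  rows$outcome <- 5 + 0.3 * (rows$treatment == "TB") +
    u[as.integer(rows$subject)] + rnorm(nrow(rows), 0, 0.1)
  est <- suppressWarnings(suppressMessages(fit_mixed_model(rows)))
  raw <- tapply(rows$outcome, rows$treatment, mean)
  expect_equal(est$lsmean_tb - est$lsmean_placebo,
               unname(raw["TB"] - raw["placebo"]), tolerance = 1e-8)
  expect_equal(est$pct_diff,
               100 * unname(raw["TB"] - raw["placebo"]) / unname(raw["placebo"]),
               tolerance = 1e-6)
})

test_that("percent difference reproduces the published LS-mean arithmetic", {
  expect_equal(round(percent_difference(3.017, 2.859), 2), -5.24)
  expect_equal(round(percent_difference(1.424, 1.346), 2), -5.48)
  expect_equal(percent_difference(2, 2), 0)
  expect_error(percent_difference(0, 1), "positive")
})

test_that("Dunnett adjustment is identity for two arms, conservative beyond", {
  st <- simulate_crossover_study(n_subjects = 12, seed = 35)
  d <- build_design(st, "HDL_tot", "CH")
  est <- suppressWarnings(fit_mixed_model(d))
  one <- adjust_posthoc(cbind(est, class = "HDL_tot", lipid = "CH"))
  expect_equal(one$p_adjusted, one$p_value)
  expect_true(one$adjusted)

  ## three active arms vs control: adjusted p is never smaller than raw
  for (tv in c(0.5, 1.7, 2.6)) {
    raw <- 2 * stats::pt(-abs(tv), 30)
    adj <- dunnett_p(tv, 30, k = 3)
    expect_gte(adj + 1e-10, raw)
  }
  expect_equal(dunnett_p(2.1, 25, k = 1), 2 * stats::pt(-2.1, 25))

  ## empty estimate set passes through
  empty <- adjust_posthoc(data.frame(p_value = numeric(0)))
  expect_equal(nrow(empty), 0)
  expect_true("p_adjusted" %in% names(empty))
})

test_that("injected effects are recovered without material bias", {
  reps <- 24
  for (mult in c(0.95, 1.10)) {
    est <- vapply(seq_len(reps), function(i) {
      st <- simulate_crossover_study(n_subjects = 40,
                                     effect_map = c("LDL_tot.CH" = mult),
                                     seed = 4000 + i)
      d <- build_design(st, "LDL_tot", "CH")
      suppressWarnings(fit_mixed_model(d)$pct_diff)
    }, numeric(1))
    bias <- mean(est) - (mult - 1) * 100
    expect_lt(abs(bias), 1)                  # < 1 percentage point
  }
})

test_that("outlier screening integrates with the effect pipeline", {
  st <- simulate_crossover_study(n_subjects = 16, seed = 36)
  ## corrupt one subject's records tenfold so PCA screening catches it
  bad <- st$records$subject == "S09"
  st$records$value_mmol[bad] <- st$records$value_mmol[bad] * 10
  eff <- suppressWarnings(treatment_effects(st))
  expect_true("S09" %in% attr(eff, "excluded"))
  expect_s3_class(eff, "lp_effect")
  expect_equal(nrow(eff), 36)                # 18 modeled classes x 2 species
  expect_true(all(c("lsmean_placebo", "lsmean_tb", "pct_diff",
                    "p_value", "p_adjusted") %in% names(eff)))
})
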