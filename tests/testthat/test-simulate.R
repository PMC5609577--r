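test_that("rendered spectra are linear superpositions of subclass signals", {
  ax <- default_axis(max_ppm = 1.6, min_ppm = 0.4)
  conc <- demo_conc()

  ## zero concentrations, zero baseline: pure noise with mean ~ 0
  z <- render_spectrum(conc * 0, ax, noise_sd = 1, seed = 8, alanine_area = 0)
  expect_lt(abs(mean(z)), 3 / sqrt(length(ax)))

  ## doubling concentrations doubles intensity exactly (noise/alanine off)
  a <- render_spectrum(conc, ax, noise_sd = 0, alanine_area = 0)
  b <- render_spectrum(2 * conc, ax, noise_sd = 0, alanine_area = 0)
  expect_equal(b, 2 * a, tolerance = 1e-12)

  ## superposition
  set.seed(21)
  c1 <- conc; c2 <- conc * runif(length(conc))
  s12 <- render_spectrum(c1 + c2, ax, noise_sd = 0, alanine_area = 0,
                         baseline = 0.5)
  s1 <- render_spectrum(c1, ax, noise_sd = 0, alanine_area = 0, baseline = 0.5)
  s2 <- render_spectrum(c2, ax, noise_sd = 0, alanine_area = 0, baseline = 0.5)
  expect_equal(s12, s1 + s2 - 0.5, tolerance = 1e-10)

  expect_error(render_spectrum(conc, ax, noise_sd = -1), "noise_sd")
  expect_error(render_spectrum(-conc, ax), "non-negative")
})

test_that("noise-free window integral matches the truncated-Lorentzian oracle", {
  ## fine grid (1/8 the standard spacing) so Simpson integration converges
  d <- (0.8 / 1746) / 8
  ppm <- seq(1.4, 0.6, by = -d)
  conc <- demo_conc()
  y <- render_spectrum(conc, ppm, noise_sd = 0, alanine_area = 0)
  ## Simpson's rule on the (descending) uniform grid
  n <- length(ppm)
  stopifnot(n %% 2 == 1)
  w <- c(1, rep(c(4, 2), (n - 3) / 2), 4, 1)
  num <- sum(w * y) * d / 3
  ## analytic truncated areas: unit-area Lorentzian over [a, b] is
  ## (atan((b-c)/g) - atan((a-c)/g)) / pi
  sm <- signal_model()
  splits <- list(CH = c(0.85, 0.15), TG = c(0.40, 0.60))
  ana <- 0
  for (key in names(conc)) {
    cl <- sub("\\.(TG|CH)$", "", key); sp <- sub("^.*\\.", "", key)
    i <- match(cl, sm$name)
    g <- sm$hwhm_ppm[i]
    for (pk in 1:2) {
      cen <- c(sm$methyl_ppm[i], sm$methylene_ppm[i])[pk]
      frac <- splits[[sp]][pk]
      ana <- ana + conc[[key]] * frac *
        (atan((1.4 - cen) / g) - atan((0.6 - cen) / g)) / pi
    }
  }
  expect_equal(num, ana, tolerance = 1e-6)
})

test_that("subclass peak centers increase with particle diameter", {
  sm <- signal_model()
  ord <- order(sm$diameter_nm)
  expect_true(all(diff(sm$methyl_ppm[ord]) > 0))
  expect_true(all(diff(sm$methylene_ppm[ord]) > 0))
  expect_true(all(sm$methyl_ppm < sm$methylene_ppm))
  ## all centers inside the TG analysis window
  expect_true(all(sm$methyl_ppm > 0.6 & sm$methylene_ppm < 1.4))
})

test_that("cohort simulation is seed-deterministic and phenotype-contrasted", {
  co_a <- simulate_cohort("low_hdl_cm", n = 10, seed = 77)
  co_b <- simulate_cohort("low_hdl_cm", n = 10, seed = 77)
  expect_identical(co_a$spectra$intensity, co_b$spectra$intensity)
  expect_identical(unclass(co_a$truth), unclass(co_b$truth))

  tiny <- simulate_cohort("low_hdl_cm", n = 2, seed = 5)
  expect_equal(nrow(tiny$spectra$intensity), 2)

  ## Figure-1-style signature at the study size: chylomicron/large-VLDL TG
  ## higher, large-HDL CH lower in the low-HDL phenotype
  m1 <- colMeans(unclass(cohort_main()$truth))
  m2 <- colMeans(unclass(cohort_other()$truth))
  for (k in paste0(c("CM01", "CM02", "VLDL03", "VLDL04", "VLDL05"), ".TG")) {
    expect_gt(m1[k], m2[k])
  }
  for (k in paste0(c("HDL15", "HDL16", "HDL17"), ".CH")) {
    expect_lt(m1[k], m2[k])
  }
  ## simulator tables carry consistent category totals
  expect_equal(unname(unclass(cohort_main()$truth)[, "HDL_tot.CH"]),
               unname(sum_category(cohort_main()$truth, "HDL", "CH")))
})

test_that("cohort concentration means converge to the preset means", {
  tab <- phenotype_preset("low_hdl_cm")
  set.seed(31)
  conc <- liponmr:::.draw_concentrations(tab, 1000)
  rel <- abs(colMeans(conc) - tab$mean_mgdl) / tab$mean_mgdl
  expect_true(all(rel < 3 * tab$cv / sqrt(1000)))
})

test_that("crossover simulation honours the design schedule and balance", {
  st <- simulate_crossover_study(n_subjects = 8, seed = 9)
  rec <- st$records
  expect_setequal(unique(rec$day), c("D1", "D25", "D28", "D57", "D81", "D84"))
  ## every subject sees both treatments, and one treatment per period
  tt <- table(rec$subject, rec$treatment) > 0
  expect_true(all(tt))
  per_period <- tapply(rec$treatment, list(rec$subject, rec$period),
                       function(x) length(unique(x)))
  expect_true(all(per_period == 1))
  ## sequences balanced
  expect_equal(sum(st$subjects$sequence == "TP"), 4)
  ## baselines (D1/D57) have no visit number; post days do
  expect_true(all(is.na(rec$visit[rec$day %in% c("D1", "D57")])))
  expect_true(all(rec$visit[rec$day %in% c("D25", "D81")] == 1))
  ## determinism
  st2 <- simulate_crossover_study(n_subjects = 8, seed = 9)
  expect_identical(st$records$value_mmol, st2$records$value_mmol)

  expect_error(simulate_crossover_study(n_subjects = 7), "even")
})

test_that("injected multiplicative effects shift post-treatment outcomes", {
  st <- simulate_crossover_study(n_subjects = 40,
                                 effect_map = c("LDL_tot.CH" = 0.9),
                                 sigma_visit = 0.01, seed = 12)
  r <- st$records[st$records$class == "LDL_tot" & st$records$lipid == "CH" &
                    !is.na(st$records$visit), ]
  m <- tapply(r$value_mmol, list(r$subject, r$treatment), mean)
  expect_equal(mean(m[, "TB"] / m[, "placebo"]), 0.9, tolerance = 0.02)
  ## untouched outcome stays at ratio ~ 1
  r2 <- st$records[st$records$class == "HDL_tot" & st$records$lipid == "CH" &
                     !is.na(st$records$visit), ]
  m2 <- tapply(r2$value_mmol, list(r2$subject, r2$treatment), mean)
  expect_equal(mean(m2[, "TB"] / m2[, "placebo"]), 1.0, tolerance = 0.02)
})
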