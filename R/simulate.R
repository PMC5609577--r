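## Forward model: synthetic diffusion-edited-like serum spectra with
## ground-truth subclass concentrations, and a crossover-study simulator.

## Peak-position model: lipid methyl and methylene chemical shifts move
## downfield with particle diameter (the physical basis of NMR lipoprotein
## prediction). Constants are free parameters of the simulator, placed so
## all signals fall inside the 1.4-0.6 ppm analysis window.
SIM_METHYL_BASE <- 0.70
SIM_METHYL_SLOPE <- 0.055
SIM_METHYLENE_BASE <- 1.18
SIM_METHYLENE_SLOPE <- 0.040
SIM_REF_DIAMETER <- 9.8      # nm; shift model anchor
SIM_HWHM <- 0.012            # Lorentzian half-width at half-maximum, ppm
## signal-area split between the methyl and methylene resonances: CH sits
## almost entirely in the methyl region, TG mostly in the methylene region
SIM_SPLIT <- list(CH = c(methyl = 0.85, methylene = 0.15),
                  TG = c(methyl = 0.40, methylene = 0.60))
SIM_ALANINE_PPM <- c(1.490, 1.478)  # doublet; left line is the alignment anchor
SIM_ALANINE_HWHM <- 0.0025          # small molecules are much sharper than lipids

#' Subclass signal model
#'
#' Per-subclass resonance positions for the simulator: methyl and methylene
#' centers as log-linear functions of particle diameter, one shared
#' Lorentzian linewidth.
#'
#' @return Data frame with `name`, `diameter_nm`, `methyl_ppm`,
#'   `methylene_ppm`, `hwhm_ppm` for the 20 subclasses.
#' @export
signal_model <- function() {
  reg <- lp_registry()
  sub <- reg[!reg$is_total, ]
  data.frame(
    name = sub$name,
    diameter_nm = sub$diameter_nm,
    methyl_ppm = SIM_METHYL_BASE +
      SIM_METHYL_SLOPE * log(sub$diameter_nm / SIM_REF_DIAMETER),
    methylene_ppm = SIM_METHYLENE_BASE +
      SIM_METHYLENE_SLOPE * log(sub$diameter_nm / SIM_REF_DIAMETER),
    hwhm_ppm = SIM_HWHM,
    stringsAsFactors = FALSE)
}

## unit-area Lorentzian line
.lorentz <- function(ppm, center, hwhm) {
  (hwhm / pi) / ((ppm - center)^2 + hwhm^2)
}

#' Render one synthetic diffusion-edited spectrum
#'
#' Intensity is the superposition, over subclasses and lipid species, of
#' unit-area Lorentzian lines scaled by concentration (signal area = 1 per
#' mg/dL), split between the methyl and methylene resonances per species,
#' plus a constant baseline, additive Gaussian noise, and a small alanine
#' doublet at 1.49/1.478 ppm serving as the chemical-shift alignment anchor.
#'
#' @param conc named vector of subclass concentrations (mg/dL), names
#'   `"<class>.<species>"`; totals are ignored.
#' @param ppm ppm axis (see [default_axis()]).
#' @param noise_sd Gaussian noise standard deviation (>= 0).
#' @param baseline constant baseline offset.
#' @param seed RNG seed for the noise (ignored when `noise_sd == 0`).
#' @param alanine_area area of each alanine doublet line (0 disables).
#' @param model signal model table (see [signal_model()]).
#' @return Numeric intensity vector along `ppm`.
#' @export
render_spectrum <- function(conc, ppm = default_axis(), noise_sd = 1,
                            baseline = 0, seed = 1, alanine_area = 10,
                            model = signal_model()) {
  if (noise_sd < 0) stop("noise_sd must be >= 0", call. = FALSE)
  if (any(conc < 0)) stop("concentrations must be non-negative", call. = FALSE)
  y <- rep(baseline, length(ppm))
  for (sp in c("TG", "CH")) {
    split <- SIM_SPLIT[[sp]]
    for (i in seq_len(nrow(model))) {
      key <- paste0(model$name[i], ".", sp)
      if (!key %in% names(conc) || conc[[key]] == 0) next
      a <- conc[[key]]
      y <- y + a * split[["methyl"]] *
        .lorentz(ppm, model$methyl_ppm[i], model$hwhm_ppm[i])
      y <- y + a * split[["methylene"]] *
        .lorentz(ppm, model$methylene_ppm[i], model$hwhm_ppm[i])
    }
  }
  if (alanine_area > 0) {
    for (c0 in SIM_ALANINE_PPM) {
      y <- y + alanine_area * .lorentz(ppm, c0, SIM_ALANINE_HWHM)
    }
  }
  if (noise_sd > 0) {
    y <- y + with_seed(seed, stats::rnorm(length(ppm), 0, noise_sd))
  }
  y
}

#' Phenotype presets
#'
#' Loads the per-(subclass, species) concentration means and coefficients of
#' variation for the shipped cohort phenotypes: `"low_hdl_cm"` (low
#' large-HDL cholesterol, chylomicrons present, triglyceride-rich large
#' VLDL) and `"hyperchol"` (hypercholesterolemic, essentially no
#' chylomicrons, higher large-HDL cholesterol). The file is plain CSV and
#' human-editable.
#'
#' @param preset preset name, or `NULL` for the full table.
#' @return Data frame `preset, class, lipid, mean_mgdl, cv`.
#' @export
phenotype_preset <- function(preset = NULL) {
  path <- system.file("extdata", "phenotype_presets.csv", package = "liponmr")
  tab <- utils::read.csv(path, stringsAsFactors = FALSE)
  if (is.null(preset)) return(tab)
  out <- tab[tab$preset == preset, ]
  if (nrow(out) == 0) stop("unknown preset: ", preset, call. = FALSE)
  out
}

## Draw n rows of subclass concentrations for a preset: log-normal marginals
## matching each (class, species) mean/CV, with a within-category Gaussian
## copula (equicorrelation rho) linking all members of a category.
.draw_concentrations <- function(preset_tab, n, rho = 0.5) {
  keys <- paste(preset_tab$class, preset_tab$lipid, sep = ".")
  reg <- lp_registry()
  category <- reg$category[match(preset_tab$class, reg$name)]
  z <- matrix(0, n, length(keys))
  for (cat in unique(category)) {
    j <- which(category == cat)
    k <- length(j)
    S <- matrix(rho, k, k); diag(S) <- 1
    L <- chol(S)
    z[, j] <- matrix(stats::rnorm(n * k), n, k) %*% L
  }
  sdlog <- sqrt(log(1 + preset_tab$cv^2))
  meanlog <- log(preset_tab$mean_mgdl) - sdlog^2 / 2
  vals <- exp(sweep(sweep(z, 2, sdlog, `*`), 2, meanlog, `+`))
  colnames(vals) <- keys
  vals
}

#' Simulate a cohort of spectra with ground-truth concentrations
#'
#' Draws per-sample subclass concentrations from the preset's log-normal
#' distributions (within-category correlation 0.5), renders one synthetic
#' diffusion-edited spectrum per sample, and returns spectra together with
#' the ground-truth concentration table (subclasses plus category totals,
#' mg/dL) and subject covariates. Regeneration with the same seed is
#' bit-identical.
#'
#' @param preset `"low_hdl_cm"` or `"hyperchol"`.
#' @param n number of samples (>= 2).
#' @param seed master RNG seed for the cohort.
#' @param noise_sd spectral noise standard deviation.
#' @param baseline constant spectral baseline.
#' @param ppm ppm axis.
#' @return An object of class `lp_cohort`: list with `spectra`
#'   ([lp_spectra()]), `truth` ([conc_table()], mg/dL), `subjects` (data
#'   frame: `sample_id, gender, age, bmi`), `preset`, `seed`.
#' @export
simulate_cohort <- function(preset = "low_hdl_cm", n = 122, seed = 1,
                            noise_sd = 1, baseline = 0, ppm = default_axis()) {
  stopifnot_scalar_count(n, "n", 2L)
  tab <- phenotype_preset(preset)
  conc <- with_seed(child_seed(seed, "conc"), .draw_concentrations(tab, n))
  rownames(conc) <- sprintf("%s_%03d", preset, seq_len(n))
  intensity <- matrix(0, n, length(ppm), dimnames = list(rownames(conc), NULL))
  for (i in seq_len(n)) {
    intensity[i, ] <- render_spectrum(conc[i, ], ppm, noise_sd, baseline,
                                      seed = child_seed(seed, paste0("noise", i)))
  }
  subjects <- with_seed(child_seed(seed, "subjects"), data.frame(
    sample_id = rownames(conc),
    gender = sample(c("M", "F"), n, replace = TRUE, prob = c(30, 18)),
    age = round(stats::rnorm(n, 60, 6)),
    bmi = round(stats::rnorm(n, 29, 3), 1),
    stringsAsFactors = FALSE))
  truth <- add_category_totals(conc_table(conc, "mg/dL"))
  structure(list(spectra = lp_spectra(ppm, intensity),
                 truth = truth, subjects = subjects,
                 preset = preset, seed = seed),
            class = "lp_cohort")
}

#' @export
print.lp_cohort <- function(x, ...) {
  cat(sprintf("Synthetic cohort '%s': %d samples (seed %s)\n",
              x$preset, nrow(x$truth), format(x$seed)))
  invisible(x)
}

#' Simulate a two-period crossover study
#'
#' Simulates per-subject concentration outcomes for the modeled lipoprotein
#' classes over the study day schedule: period-1 baseline D1, post-treatment
#' visits D25/D28, period-2 baseline D57, post-treatment visits D81/D84.
#' Treatment sequences (placebo first vs active first) are balanced. Each
#' outcome is `preset mean x exp(subject effect) x multiplier x exp(visit
#' noise)`, with the treatment multiplier from `effect_map` applied only on
#' post-treatment days of the active-treatment period (1.0 for placebo and
#' baselines).
#'
#' @param preset phenotype preset for the baseline concentration means.
#' @param n_subjects even number of subjects.
#' @param effect_map named vector of multiplicative treatment effects per
#'   `"<class>.<species>"` outcome (unnamed outcomes default to 1.0).
#' @param sigma_subject SD of the log-scale subject random effect.
#' @param sigma_visit SD of the log-scale within-subject visit noise.
#' @param seed RNG seed.
#' @return An object of class `lp_crossover`: list with `records` (long data
#'   frame: `subject, day, period, treatment, visit, class, lipid,
#'   value_mmol`), `subjects` (covariates and sequence), `effect_map`,
#'   `seed`.
#' @export
simulate_crossover_study <- function(preset = "low_hdl_cm", n_subjects = 40,
                                     effect_map = numeric(0),
                                     sigma_subject = 0.15, sigma_visit = 0.05,
                                     seed = 1) {
  stopifnot_scalar_count(n_subjects, "n_subjects", 2L)
  if (n_subjects %% 2 != 0) {
    stop("n_subjects must be even for balanced sequence allocation", call. = FALSE)
  }
  reg <- lp_registry()
  classes <- reg$name[reg$modeled]
  tab <- phenotype_preset(preset)
  key_mean <- c(stats::setNames(tab$mean_mgdl, paste(tab$class, tab$lipid, sep = ".")))
  ## totals = sums of subclass means within category
  outcomes <- unlist(lapply(classes, function(cl) paste(cl, c("TG", "CH"), sep = ".")))
  means <- vapply(outcomes, function(k) {
    cl <- sub("\\.(TG|CH)$", "", k); sp <- sub("^.*\\.", "", k)
    if (grepl("_tot$", cl)) {
      cat <- sub("_tot$", "", cl)
      members <- reg$name[reg$category == cat & !reg$is_total]
      sum(key_mean[paste(members, sp, sep = ".")])
    } else key_mean[[k]]
  }, numeric(1))
  mm <- .molar_mass(sub("^.*\\.", "", outcomes))
  means_mmol <- means * 10 / mm

  days <- data.frame(day = c("D1", "D25", "D28", "D57", "D81", "D84"),
                     period = c(1, 1, 1, 2, 2, 2),
                     visit = c(NA, 1, 2, NA, 1, 2),
                     stringsAsFactors = FALSE)

  with_seed(child_seed(seed, "study"), {
    subjects <- data.frame(
      subject = sprintf("S%02d", seq_len(n_subjects)),
      sequence = sample(rep(c("TP", "PT"), n_subjects / 2)),  # T=active, P=placebo
      gender = sample(c("M", "F"), n_subjects, replace = TRUE, prob = c(30, 18)),
      age = round(stats::rnorm(n_subjects, 60, 6)),
      bmi = round(stats::rnorm(n_subjects, 29, 3), 1),
      stringsAsFactors = FALSE)
    u <- matrix(stats::rnorm(n_subjects * length(outcomes), 0, sigma_subject),
                n_subjects, length(outcomes), dimnames = list(subjects$subject, outcomes))
    rec <- expand.grid(subject = subjects$subject, di = seq_len(nrow(days)),
                       oi = seq_along(outcomes), stringsAsFactors = FALSE)
    rec$day <- days$day[rec$di]
    rec$period <- days$period[rec$di]
    rec$visit <- days$visit[rec$di]
    seqs <- subjects$sequence[match(rec$subject, subjects$subject)]
    rec$treatment <- ifelse((rec$period == 1) == (seqs == "TP"), "TB", "placebo")
    key <- outcomes[rec$oi]
    rec$class <- sub("\\.(TG|CH)$", "", key)
    rec$lipid <- sub("^.*\\.", "", key)
    mult <- rep(1, nrow(rec))
    post <- !is.na(rec$visit)
    active <- post & rec$treatment == "TB"
    em <- effect_map[key[active]]
    em[is.na(em)] <- 1
    mult[active] <- em
    rec$value_mmol <- means_mmol[rec$oi] *
      exp(u[cbind(rec$subject, key)]) * mult *
      exp(stats::rnorm(nrow(rec), 0, sigma_visit))
    rec <- rec[order(rec$subject, rec$di, rec$oi),
               c("subject", "day", "period", "treatment", "visit",
                 "class", "lipid", "value_mmol")]
    rownames(rec) <- NULL
    structure(list(records = rec, subjects = subjects,
                   effect_map = effect_map, seed = seed),
              class = "lp_crossover")
  })
}

#' @export
print.lp_crossover <- function(x, ...) {
  cat(sprintf("Crossover study: %d subjects, %d records, %d outcomes (seed %s)\n",
              nrow(x$subjects), nrow(x$records),
              length(unique(paste(x$records$class, x$records$lipid))),
              format(x$seed)))
  invisible(x)
}

#' Write crossover study records to CSV
#'
#' Long-format export: `subject, day, period, treatment, visit, class,
#' lipid, value_mmol_per_L`, plus subject covariates joined in.
#'
#' @param study an `lp_crossover` object.
#' @param path CSV file path.
#' @return `path`, invisibly.
#' @export
write_study <- function(study, path) {
  rec <- study$records
  i <- match(rec$subject, study$subjects$subject)
  rec$gender <- study$subjects$gender[i]
  rec$age <- study$subjects$age[i]
  rec$bmi <- study$subjects$bmi[i]
  names(rec)[names(rec) == "value_mmol"] <- "value_mmol_per_L"
  utils::write.csv(rec, path, row.names = FALSE)
  invisible(path)
}
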