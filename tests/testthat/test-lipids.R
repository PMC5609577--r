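test_that("unit conversion uses the molar masses and round-trips exactly", {
  ct <- conc_table(matrix(c(38.5, 88.4, 0, 5),
                          nrow = 2, byrow = FALSE,
                          dimnames = list(c("a", "b"),
                                          c("LDL_tot.CH", "VLDL_tot.TG"))),
                   "mg/dL")
  mm <- convert_units(ct, "mmol/L")
  expect_equal(unclass(mm)["a", "LDL_tot.CH"], 1.0)  # CH: 385 g/mol
  expect_equal(unclass(mm)["b", "VLDL_tot.TG"], 5 * 10 / 884)
  expect_equal(unclass(mm)["a", "VLDL_tot.TG"], 0)

  ## idempotence and bijection
  expect_identical(convert_units(ct, "mg/dL"), ct)
  back <- convert_units(mm, "mg/dL")
  expect_equal(unclass(back), unclass(ct), tolerance = 1e-12)

  bad <- ct
  attr(bad, "units") <- "g/L"
  expect_error(convert_units(bad, "mmol/L"), "unknown units")
})

test_that("registry has 24 size-ordered classes with the printed diameters", {
  reg <- lp_registry()
  expect_equal(nrow(reg), 24)
  expect_equal(sum(!reg$is_total), 20)
  expect_equal(reg$diameter_nm[reg$name == "VLDL03"], 64.0)
  expect_equal(reg$diameter_nm[reg$name == "CM02"], 78)
  expect_equal(reg$diameter_nm[reg$name == "HDL18"], 9.8)
  ## strictly decreasing over the scalar-diameter subclasses
  d <- reg$diameter_nm[!reg$is_total]
  expect_true(all(diff(d) < 0))
  ## modeled flags: exactly the 15 subclasses + 3 totals
  expected <- c("CM01", "CM02", paste0("VLDL0", 3:7),
                paste0("LDL", sprintf("%02d", 8:11)), paste0("HDL", 15:18),
                "VLDL_tot", "LDL_tot", "HDL_tot")
  expect_setequal(reg$name[reg$modeled], expected)
  ## unprinted diameters are flagged as interpolated and stay inside their
  ## category's neighbours
  expect_setequal(reg$name[reg$interpolated],
                  c("CM01", "LDL12", "LDL13", "HDL14", "HDL19", "HDL20"))
  expect_true(reg$diameter_nm[reg$name == "HDL14"] >
                reg$diameter_nm[reg$name == "HDL15"])
})

test_that("category sums match an elementwise oracle and are linear", {
  reg <- lp_registry()
  hdl <- reg$name[reg$category == "HDL" & !reg$is_total]
  cols <- as.vector(outer(c(hdl, "LDL08"), c("TG", "CH"), paste, sep = "."))
  zero <- conc_table(matrix(0, 3, length(cols),
                            dimnames = list(letters[1:3], cols)), "mmol/L")
  expect_equal(unname(sum_category(zero, "HDL", "CH")), c(0, 0, 0))

  m <- matrix(0, 2, length(cols), dimnames = list(c("a", "b"), cols))
  m[, paste0(hdl[1:4], ".CH")] <- 0.1
  expect_equal(unname(sum_category(conc_table(m, "mmol/L"), "HDL", "CH")),
               c(0.4, 0.4))

  set.seed(99)
  r1 <- matrix(rexp(2 * length(cols)), 2, dimnames = list(c("a", "b"), cols))
  r2 <- matrix(rexp(2 * length(cols)), 2, dimnames = list(c("a", "b"), cols))
  t1 <- conc_table(r1, "mg/dL"); t2 <- conc_table(r2, "mg/dL")
  oracle <- sapply(seq_len(2), function(i) {
    tot <- 0
    for (cl in hdl) tot <- tot + r1[i, paste0(cl, ".TG")]
    tot
  })
  expect_equal(unname(sum_category(t1, "HDL", "TG")), oracle)
  ## linearity
  comb <- conc_table(2 * r1 + 3 * r2, "mg/dL")
  expect_equal(sum_category(comb, "HDL", "TG"),
               2 * sum_category(t1, "HDL", "TG") + 3 * sum_category(t2, "HDL", "TG"))

  expect_error(sum_category(zero, "VLDL", "TG"), "missing subclass")
})

test_that("concentration tables round-trip through tidy CSV", {
  set.seed(3)
  cols <- c("LDL09.CH", "HDL17.TG", "VLDL_tot.TG")
  ct <- conc_table(matrix(runif(9), 3, dimnames = list(paste0("s", 1:3), cols)),
                   "mg/dL")
  path <- withr::local_tempfile(fileext = ".csv")
  write_conc_table(ct, path)
  back <- read_conc_table(path)
  expect_equal(unclass(back)[rownames(ct), colnames(ct)], unclass(ct),
               tolerance = 1e-12, ignore_attr = TRUE)
  expect_identical(attr(back, "units"), "mg/dL")
})

test_that("invalid concentration tables are rejected", {
  expect_error(conc_table(matrix(-1, 1, 1, dimnames = list("a", "LDL09.CH"))),
               "non-negative")
  expect_error(conc_table(matrix(1, 1, 1, dimnames = list("a", "LDL09"))),
               "must be named")
})
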