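## Domain registry: lipid species, lipoprotein classes, concentration tables.

#' Lipid species and their molar masses
#'
#' The two lipid species quantified per lipoprotein class: cholesterol (CH,
#' 385 g/mol) and triglycerides (TG, 884 g/mol). The molar masses are the
#' constants used to convert between mg/dL and mmol/L.
#'
#' @return A data frame with columns `code` and `molar_mass` (g/mol).
#' @export
#' @examples
#' lipid_species()
lipid_species <- function() {
  data.frame(code = c("TG", "CH"),
             molar_mass = c(884, 385),
             stringsAsFactors = FALSE)
}

.molar_mass <- function(species) {
  sp <- lipid_species()
  mm <- sp$molar_mass[match(species, sp$code)]
  if (anyNA(mm)) stop("unknown lipid species: ",
                      paste(setdiff(species, sp$code), collapse = ", "),
                      call. = FALSE)
  mm
}

#' Lipoprotein subclass registry
#'
#' The 20 size-ordered lipoprotein subclasses (CM01--HDL20) plus the four
#' main-class totals. Each subclass carries a particle diameter in nm;
#' diameters not available from the reference HPLC size grid (LDL12, LDL13,
#' HDL14, HDL19, HDL20) are filled in by log-linear extrapolation within
#' their category and flagged `interpolated`. CM01's censored bound
#' ("> 90 nm") is stored as the point value 95 nm and flagged. Totals carry
#' their size range as metadata only (`size_range_nm`), never a scalar
#' diameter. `modeled` marks the 15 subclasses and 3 totals for which
#' calibration models are expected to reach significance.
#'
#' @return A data frame with one row per class: `name`, `category`
#'   (CM/VLDL/LDL/HDL), `is_total`, `diameter_nm`, `interpolated`,
#'   `size_range_nm`, `modeled`, ordered from largest to smallest particle
#'   with totals last.
#' @export
#' @examples
#' reg <- lp_registry()
#' reg[reg$modeled, "name"]
lp_registry <- function() {
  ## printed diameters; NA = to be extrapolated
  sub <- data.frame(
    name = c("CM01", "CM02",
             paste0("VLDL0", 3:7),
             paste0("LDL", sprintf("%02d", 8:13)),
             paste0("HDL", 14:20)),
    category = c(rep("CM", 2), rep("VLDL", 5), rep("LDL", 6), rep("HDL", 7)),
    diameter_nm = c(95, 78,
                    64.0, 53.6, 44.5, 36.8, 31.3,
                    28.6, 25.5, 23.0, 20.7, NA, NA,
                    NA, 13.5, 12.1, 10.9, 9.8, NA, NA),
    stringsAsFactors = FALSE)
  sub$interpolated <- is.na(sub$diameter_nm)
  sub$interpolated[sub$name == "CM01"] <- TRUE # censored ">90" stored as 95

  ## log-linear fill within category: the printed diameters in each category
  ## decrease by a near-constant ratio, so extrapolate on the log scale
  for (cat in unique(sub$category)) {
    i <- which(sub$category == cat)
    d <- log(sub$diameter_nm[i])
    known <- which(!is.na(d))
    if (length(known) >= 2 && anyNA(d)) {
      step <- (d[known[length(known)]] - d[known[1]]) /
        (known[length(known)] - known[1])
      d[is.na(d)] <- d[known[1]] + step * (which(is.na(d)) - known[1])
      sub$diameter_nm[i] <- exp(d)
    }
  }

  tot <- data.frame(
    name = c("CM_tot", "VLDL_tot", "LDL_tot", "HDL_tot"),
    category = c("CM", "VLDL", "LDL", "HDL"),
    diameter_nm = NA_real_,
    interpolated = FALSE,
    stringsAsFactors = FALSE)

  reg <- rbind(sub, tot)
  reg$is_total <- reg$name %in% tot$name
  reg$size_range_nm <- NA_character_
  reg$size_range_nm[reg$name == "VLDL_tot"] <- "30-80"
  reg$size_range_nm[reg$name == "LDL_tot"] <- "16-30"
  reg$size_range_nm[reg$name == "HDL_tot"] <- "8-16"
  modeled <- c("CM01", "CM02", paste0("VLDL0", 3:7),
               paste0("LDL", sprintf("%02d", 8:11)),
               paste0("HDL", 15:18),
               "VLDL_tot", "LDL_tot", "HDL_tot")
  reg$modeled <- reg$name %in% modeled
  rownames(reg) <- NULL
  reg
}

#' Export the subclass registry
#'
#' @param path output file; format inferred from the extension (`.csv` or
#'   `.json`).
#' @return `path`, invisibly.
#' @export
write_registry <- function(path) {
  reg <- lp_registry()
  if (grepl("\\.json$", path, ignore.case = TRUE)) {
    jsonlite::write_json(reg, path, digits = NA)
  } else {
    utils::write.csv(reg, path, row.names = FALSE)
  }
  invisible(path)
}

## ---- concentration tables ------------------------------------------------

#' Construct a concentration table
#'
#' A concentration table holds one row per sample and one column per
#' (lipoprotein class, lipid species) pair, named `"<class>.<species>"`
#' (e.g. `"VLDL_tot.TG"`), in uniform units.
#'
#' @param values numeric matrix, rows = samples (rownames = sample ids),
#'   columns named `"<class>.<species>"`.
#' @param units `"mg/dL"` or `"mmol/L"`.
#' @return A `conc_table` object (a matrix with a `units` attribute).
#' @export
conc_table <- function(values, units = c("mg/dL", "mmol/L")) {
  units <- match.arg(units)
  values <- as.matrix(values)
  if (is.null(colnames(values)) || !all(grepl("\\.(TG|CH)$", colnames(values)))) {
    stop("columns must be named '<class>.<species>' with species TG or CH",
         call. = FALSE)
  }
  if (any(!is.finite(values)) || any(values < 0)) {
    stop("concentrations must be finite and non-negative", call. = FALSE)
  }
  if (is.null(rownames(values))) rownames(values) <- paste0("S", seq_len(nrow(values)))
  structure(values, units = units, class = c("conc_table", "matrix", "array"))
}

#' @export
print.conc_table <- function(x, ...) {
  cat(sprintf("Concentration table: %d samples x %d (class, species) columns [%s]\n",
              nrow(x), ncol(x), attr(x, "units")))
  print(utils::head(unclass(x)[, seq_len(min(6, ncol(x))), drop = FALSE], 4))
  if (nrow(x) > 4 || ncol(x) > 6) cat("...\n")
  invisible(x)
}

ct_units <- function(table) attr(table, "units")

.ct_split_cols <- function(table) {
  cls <- sub("\\.(TG|CH)$", "", colnames(table))
  sp <- sub("^.*\\.", "", colnames(table))
  list(class = cls, species = sp)
}

#' Convert concentration units
#'
#' mg/dL to mmol/L uses `value * 10 / molar_mass` with 385 g/mol for CH and
#' 884 g/mol for TG; the reverse direction inverts it. Converting to the
#' current units is the identity.
#'
#' @param table a [conc_table()].
#' @param target `"mg/dL"` or `"mmol/L"`.
#' @return A `conc_table` in the target units.
#' @export
#' @examples
#' ct <- conc_table(matrix(38.5, 1, 1, dimnames = list("a", "LDL_tot.CH")))
#' convert_units(ct, "mmol/L")[1, 1] # 1.0
convert_units <- function(table, target = c("mg/dL", "mmol/L")) {
  if (!inherits(table, "conc_table")) stop("'table' must be a conc_table", call. = FALSE)
  target <- match.arg(target)
  cur <- ct_units(table)
  if (is.null(cur) || !cur %in% c("mg/dL", "mmol/L")) {
    stop("table has unknown units label: ", cur, call. = FALSE)
  }
  if (cur == target) return(table)
  mm <- .molar_mass(.ct_split_cols(table)$species)
  out <- unclass(table)
  if (cur == "mg/dL") {
    out <- sweep(out, 2, 10 / mm, `*`)
  } else {
    out <- sweep(out, 2, mm / 10, `*`)
  }
  conc_table(out, target)
}

#' Sum subclass concentrations into a category total
#'
#' @param table a [conc_table()].
#' @param category one of `"CM"`, `"VLDL"`, `"LDL"`, `"HDL"`.
#' @param species lipid species to sum, `"TG"` or `"CH"`.
#' @return Named numeric vector of per-sample totals, in the table's units.
#' @export
sum_category <- function(table, category, species = c("TG", "CH")) {
  species <- match.arg(species)
  reg <- lp_registry()
  members <- reg$name[reg$category == category & !reg$is_total]
  if (length(members) == 0) stop("unknown category: ", category, call. = FALSE)
  want <- paste(members, species, sep = ".")
  missing <- setdiff(want, colnames(table))
  if (length(missing)) {
    stop("table is missing subclass columns: ", paste(missing, collapse = ", "),
         call. = FALSE)
  }
  rowSums(unclass(table)[, want, drop = FALSE])
}

## Append the four category totals (both species) to a subclass-only table.
add_category_totals <- function(table) {
  vals <- unclass(table)
  for (cat in c("CM", "VLDL", "LDL", "HDL")) {
    for (sp in c("TG", "CH")) {
      col <- paste0(cat, "_tot.", sp)
      vals <- cbind(vals, sum_category(table, cat, sp))
      colnames(vals)[ncol(vals)] <- col
    }
  }
  conc_table(vals, ct_units(table))
}

#' Read / write concentration tables as tidy CSV
#'
#' The on-disk form is long: columns `sample_id, class, lipid, value, units`.
#'
#' @param table a [conc_table()].
#' @param path CSV file path.
#' @return `write_conc_table` returns `path` invisibly; `read_conc_table`
#'   returns a `conc_table`.
#' @export
write_conc_table <- function(table, path) {
  sp <- .ct_split_cols(table)
  long <- data.frame(
    sample_id = rep(rownames(table), times = ncol(table)),
    class = rep(sp$class, each = nrow(table)),
    lipid = rep(sp$species, each = nrow(table)),
    value = as.vector(unclass(table)),
    units = ct_units(table),
    stringsAsFactors = FALSE)
  utils::write.csv(long, path, row.names = FALSE)
  invisible(path)
}

#' @rdname write_conc_table
#' @export
read_conc_table <- function(path) {
  long <- utils::read.csv(path, stringsAsFactors = FALSE)
  need <- c("sample_id", "class", "lipid", "value", "units")
  if (!all(need %in% names(long))) {
    stop("concentration CSV must have columns: ", paste(need, collapse = ", "),
         call. = FALSE)
  }
  units <- unique(long$units)
  if (length(units) != 1L) stop("mixed units in concentration CSV", call. = FALSE)
  key <- paste(long$class, long$lipid, sep = ".")
  samples <- unique(long$sample_id)
  cols <- unique(key)
  m <- matrix(NA_real_, length(samples), length(cols),
              dimnames = list(samples, cols))
  m[cbind(match(long$sample_id, samples), match(key, cols))] <- long$value
  if (anyNA(m)) stop("incomplete concentration CSV: missing (sample, class, lipid) cells",
                     call. = FALSE)
  conc_table(m, units)
}
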