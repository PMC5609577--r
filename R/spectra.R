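## ppm-axis data model, spectral windows, alignment, spectra I/O.

## Grid spacing is fixed so that the TG feature window (1.4 -> 0.6 ppm)
## holds exactly 1746 points; the CH window is its final 961 points.
PPM_SPACING <- 0.8 / 1746
TG_N_POINTS <- 1746L
CH_N_POINTS <- 961L
TG_START_PPM <- 1.4

#' Default ppm axis
#'
#' A uniform, descending ppm grid (NMR convention) with spacing 0.8/1746
#' ppm, containing a grid point exactly at 1.4 ppm and spanning at least
#' 0--4 ppm so the lactate/alanine region is available for alignment.
#'
#' @param max_ppm,min_ppm requested span; the realised axis snaps outward to
#'   the grid.
#' @return Numeric vector of ppm positions, strictly descending.
#' @export
default_axis <- function(max_ppm = 4.2, min_ppm = 0) {
  d <- PPM_SPACING
  n_up <- ceiling((max_ppm - TG_START_PPM) / d)
  n_down <- ceiling((TG_START_PPM - min_ppm) / d)
  TG_START_PPM + d * (n_up:(-n_down))
}

#' Spectral windows
#'
#' The three fixed analysis windows: `"TG"` = 1746 consecutive grid points
#' from 1.4 ppm downward (lipid methylene + methyl), `"CH"` = the final 961
#' points of the TG window (methyl only, about 1.04--0.6 ppm),
#' `"selection"` = the 0.6--1.04 ppm methyl region used for PCA-based
#' representative-sample selection, and `"full"` = the whole axis.
#'
#' @param name window name.
#' @return A `spectral_window` object.
#' @export
spectral_window <- function(name = c("TG", "CH", "selection", "full")) {
  name <- match.arg(name)
  w <- switch(name,
    TG = list(name = "TG", start_ppm = TG_START_PPM, n_points = TG_N_POINTS),
    CH = list(name = "CH", start_ppm = TG_START_PPM, n_points = TG_N_POINTS,
              tail_points = CH_N_POINTS),
    selection = list(name = "selection", bounds = c(0.6, 1.04)),
    full = list(name = "full"))
  structure(w, class = "spectral_window")
}

#' Construct a spectra set
#'
#' @param ppm strictly descending, uniformly spaced ppm axis.
#' @param intensity numeric matrix, one row per sample (rownames = sample
#'   ids), `ncol(intensity) == length(ppm)`.
#' @param kind acquisition kind, `"diffusion_edited"` or `"noesy"`.
#' @return An `lp_spectra` object.
#' @export
lp_spectra <- function(ppm, intensity, kind = c("diffusion_edited", "noesy")) {
  kind <- match.arg(kind)
  ppm <- as.numeric(ppm)
  intensity <- as.matrix(intensity)
  if (ncol(intensity) != length(ppm)) {
    stop("intensity must have one column per ppm point", call. = FALSE)
  }
  if (length(ppm) < 2 || any(diff(ppm) >= 0)) {
    stop("ppm axis must be strictly descending", call. = FALSE)
  }
  sp <- diff(ppm)
  if (max(abs(sp - sp[1])) > 1e-9) {
    stop("ppm axis must be uniformly spaced (tolerance 1e-9)", call. = FALSE)
  }
  if (any(!is.finite(intensity))) stop("intensities must be finite", call. = FALSE)
  if (is.null(rownames(intensity))) {
    rownames(intensity) <- paste0("S", seq_len(nrow(intensity)))
  }
  structure(list(ppm = ppm, intensity = intensity, kind = kind),
            class = "lp_spectra")
}

#' @export
print.lp_spectra <- function(x, ...) {
  cat(sprintf("%s 1H NMR spectra: %d samples, %d points, %.4f to %.4f ppm\n",
              x$kind, nrow(x$intensity), length(x$ppm),
              x$ppm[1], x$ppm[length(x$ppm)]))
  invisible(x)
}

#' @export
plot.lp_spectra <- function(x, samples = 1L, xlim = rev(range(x$ppm)), ...) {
  graphics::matplot(x$ppm, t(x$intensity[samples, , drop = FALSE]),
                    type = "l", lty = 1, xlim = xlim,
                    xlab = "ppm", ylab = "intensity", ...)
  invisible(x)
}

## index of the grid point nearest `ppm_value`
.nearest_idx <- function(ppm, ppm_value) which.min(abs(ppm - ppm_value))

#' Extract a spectral window as a feature matrix
#'
#' For the TG window, the slice is the 1746 consecutive points starting at
#' the grid point at 1.4 ppm, moving upfield; the CH window is the final 961
#' points of that slice. Bound-based windows take all points inside the
#' closed ppm interval.
#'
#' @param spectra an [lp_spectra()] object.
#' @param window a [spectral_window()] or window name.
#' @return Numeric matrix (samples x window points) with ppm positions as a
#'   `"ppm"` attribute.
#' @export
#' @examples
#' sp <- lp_spectra(default_axis(), matrix(0, 2, length(default_axis())))
#' ncol(extract_window(sp, "TG")) # 1746
#' ncol(extract_window(sp, "CH")) # 961
extract_window <- function(spectra, window = "TG") {
  if (is.character(window)) window <- spectral_window(window)
  ppm <- spectra$ppm
  d <- abs(ppm[2] - ppm[1])
  if (identical(window$name, "full")) {
    out <- spectra$intensity
    attr(out, "ppm") <- ppm
    return(out)
  }
  if (!is.null(window$n_points)) {
    i0 <- .nearest_idx(ppm, window$start_ppm)
    if (abs(ppm[i0] - window$start_ppm) > d / 2 + 1e-12) {
      stop("axis has no grid point at the window anchor ", window$start_ppm,
           " ppm", call. = FALSE)
    }
    idx <- i0:(i0 + window$n_points - 1L)
    if (max(idx) > length(ppm)) {
      stop("axis does not cover the ", window$name, " window", call. = FALSE)
    }
    if (!is.null(window$tail_points)) {
      idx <- idx[(length(idx) - window$tail_points + 1L):length(idx)]
    }
  } else {
    idx <- which(ppm >= window$bounds[1] - 1e-12 & ppm <= window$bounds[2] + 1e-12)
    if (length(idx) == 0) {
      stop("axis does not cover the ", window$name, " window", call. = FALSE)
    }
  }
  out <- spectra$intensity[, idx, drop = FALSE]
  attr(out, "ppm") <- ppm[idx]
  out
}

#' Align spectra to a reference peak
#'
#' Circularly shifts each spectrum by an integer number of grid points so
#' that its local maximum within `reference_ppm +/- search_halfwidth` lands
#' on the grid point nearest `reference_ppm`. The default reference is the
#' left line of the alanine doublet at 1.49 ppm, the standard serum
#' chemical-shift anchor.
#'
#' @param spectra an [lp_spectra()] object.
#' @param reference_ppm target peak position (ppm).
#' @param search_halfwidth half-width of the search region (ppm); the default
#'   stays below the alanine doublet splitting so only the left line is seen.
#' @return The aligned `lp_spectra`, with per-sample integer shifts (in grid
#'   points) in attribute `"shifts"`.
#' @export
align_to_reference <- function(spectra, reference_ppm = 1.49,
                               search_halfwidth = 0.008) {
  ppm <- spectra$ppm
  target <- .nearest_idx(ppm, reference_ppm)
  region <- which(abs(ppm - reference_ppm) <= search_halfwidth)
  if (length(region) < 3) stop("search region too narrow for this axis", call. = FALSE)
  X <- spectra$intensity
  shifts <- integer(nrow(X))
  for (i in seq_len(nrow(X))) {
    x <- X[i, ]
    r <- x[region]
    j <- which.max(r)
    ## require a genuine local maximum above the spectrum's noise floor
    floor_level <- stats::median(x) + 5 * stats::mad(x)
    interior <- j > 1 && j < length(r) && r[j] > r[j - 1] && r[j] > r[j + 1]
    if (!interior || r[j] <= floor_level) {
      stop(sprintf("sample '%s': no local maximum above the noise floor near %.3f ppm",
                   rownames(X)[i], reference_ppm), call. = FALSE)
    }
    k <- region[j] - target     # positive: peak is upfield of target
    if (k != 0) {
      n <- length(x)
      X[i, ] <- x[((seq_len(n) - 1 + k) %% n) + 1]
    }
    shifts[i] <- k
  }
  out <- lp_spectra(ppm, X, spectra$kind)
  attr(out, "shifts") <- shifts
  out
}

#' Read / write spectra as CSV
#'
#' On-disk layout: first row = the descending ppm axis (header cell
#' `sample_id`), one subsequent row per sample: its id then intensities.
#'
#' @param spectra an [lp_spectra()] object.
#' @param path CSV file path.
#' @return `write_spectra` returns `path` invisibly; `read_spectra` an
#'   `lp_spectra`.
#' @export
write_spectra <- function(spectra, path) {
  header <- c("sample_id", formatC(spectra$ppm, format = "g", digits = 17))
  con <- file(path, "w")
  on.exit(close(con))
  writeLines(paste(header, collapse = ","), con)
  ids <- rownames(spectra$intensity)
  for (i in seq_len(nrow(spectra$intensity))) {
    writeLines(paste(c(ids[i], formatC(spectra$intensity[i, ], format = "g",
                                       digits = 17)), collapse = ","), con)
  }
  invisible(path)
}

#' @rdname write_spectra
#' @param kind acquisition kind recorded on the returned object.
#' @export
read_spectra <- function(path, kind = "diffusion_edited") {
  lines <- readLines(path)
  lines <- lines[nzchar(lines)]
  if (length(lines) < 2) stop("spectra file is empty or has no samples", call. = FALSE)
  head_f <- strsplit(lines[1], ",", fixed = TRUE)[[1]]
  ppm <- suppressWarnings(as.numeric(head_f[-1]))
  if (anyNA(ppm)) stop("line 1: ppm axis is not numeric", call. = FALSE)
  n <- length(ppm)
  ids <- character(length(lines) - 1L)
  m <- matrix(NA_real_, length(lines) - 1L, n)
  for (i in seq_along(ids)) {
    f <- strsplit(lines[i + 1L], ",", fixed = TRUE)[[1]]
    if (length(f) != n + 1L) {
      stop(sprintf("line %d: expected %d intensity values, found %d",
                   i + 1L, n, length(f) - 1L), call. = FALSE)
    }
    ids[i] <- f[1]
    v <- suppressWarnings(as.numeric(f[-1]))
    if (anyNA(v)) stop(sprintf("line %d: non-numeric intensity", i + 1L), call. = FALSE)
    m[i, ] <- v
  }
  rownames(m) <- ids
  lp_spectra(ppm, m, kind)
}
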