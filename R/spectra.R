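#' Construct an ATR-FTIR spectrum
#'
#' @param wavenumber Strictly ascending wavenumbers (cm-1) within
#'   400-4000.
#' @param absorbance Absorbance values, one per wavenumber.
#' @return A data frame of class `ftir_spectrum`.
#' @export
ftir_spectrum <- function(wavenumber, absorbance) {
  if (length(wavenumber) != length(absorbance)) {
    stop("wavenumber and absorbance must have equal length", call. = FALSE)
  }
  if (any(diff(wavenumber) <= 0)) {
    stop("wavenumbers must be strictly ascending", call. = FALSE)
  }
  if (min(wavenumber) < 400 || max(wavenumber) > 4000) {
    stop("wavenumbers must lie within [400, 4000] cm-1", call. = FALSE)
  }
  out <- data.frame(wavenumber = as.numeric(wavenumber),
                    absorbance = as.numeric(absorbance))
  class(out) <- c("ftir_spectrum", "data.frame")
  out
}

#' Read a two-column spectrum file
#'
#' Plain delimited text with wavenumber (cm-1) and absorbance columns;
#' a header row is detected automatically.
#'
#' @param path File path.
#' @param sep Field delimiter.
#' @return An [ftir_spectrum()].
#' @export
read_spectrum <- function(path, sep = ",") {
  if (!file.exists(path)) stop("file not found: ", path, call. = FALSE)
  first <- readLines(path, n = 1)
  has_header <- is.na(suppressWarnings(
    as.numeric(strsplit(first, sep, fixed = TRUE)[[1]][1])))
  raw <- utils::read.table(path, header = has_header, sep = sep,
                           comment.char = "#")
  if (ncol(raw) < 2L) stop("expected two columns", call. = FALSE)
  ftir_spectrum(raw[[1]], raw[[2]])
}

#' Default wavenumber band definitions
#'
#' The cuticular/epicuticular wax (CEW) band covers 2800-3000 cm-1
#' (aliphatic C-H stretching of cutin, waxes and cutan); the five flavonol
#' fingerprint bands cover 1125-1140, 1205-1225, 1270-1310, 1435-1475 and
#' 1605-1620 cm-1 (aromatic-ring and C=C/C=O vibrations).
#'
#' @return A data frame with columns `name`, `lo`, `hi`, `group`.
#' @export
band_definitions <- function() {
  data.frame(
    name = c("cew", "flavonol_1132", "flavonol_1215", "flavonol_1290",
             "flavonol_1455", "flavonol_1612"),
    lo = c(2800, 1125, 1205, 1270, 1435, 1605),
    hi = c(3000, 1140, 1225, 1310, 1475, 1620),
    group = c("cew", rep("flavonol", 5)),
    stringsAsFactors = FALSE
  )
}

#' Baseline-corrected integrated absorbance over a wavenumber band
#'
#' With the default `local_linear` baseline, the straight line through the
#' band's endpoint absorbances is subtracted, negative residuals are
#' clipped to zero (the indices are semi-quantitative abundances), and the
#' positive part is integrated by the trapezoid rule; `none` integrates the
#' raw absorbance.
#'
#' @param spectrum An [ftir_spectrum()].
#' @param lo,hi Band limits (cm-1), `lo < hi`, inside the spectrum range.
#' @param baseline `"local_linear"` (default) or `"none"`.
#' @return Integrated absorbance (absorbance x cm-1), >= 0 for
#'   `local_linear`.
#' @export
band_index <- function(spectrum, lo, hi,
                       baseline = c("local_linear", "none")) {
  baseline <- match.arg(baseline)
  stopifnot(inherits(spectrum, "ftir_spectrum"), lo < hi)
  wn <- spectrum$wavenumber
  if (lo < min(wn) || hi > max(wn)) {
    stop("band [", lo, ", ", hi, "] outside spectrum range", call. = FALSE)
  }
  inside <- wn >= lo & wn <= hi
  if (sum(inside) < 3L) {
    stop("fewer than 3 points inside band [", lo, ", ", hi,
         "]; spectral resolution too coarse", call. = FALSE)
  }
  x <- wn[inside]
  y <- spectrum$absorbance[inside]
  if (baseline == "local_linear") {
    n <- length(x)
    base <- y[1] + (y[n] - y[1]) * (x - x[1]) / (x[n] - x[1])
    y <- pmax(y - base, 0)
  }
  pracma::trapz(x, y)
}

#' @rdname band_index
#' @details `cew_index()` integrates the 2800-3000 cm-1 wax band;
#'   `flavonol_index()` sums the five fingerprint-band integrals.
#' @export
cew_index <- function(spectrum, baseline = c("local_linear", "none")) {
  baseline <- match.arg(baseline)
  bands <- band_definitions()
  b <- bands[bands$group == "cew", ]
  band_index(spectrum, b$lo, b$hi, baseline)
}

#' @rdname band_index
#' @export
flavonol_index <- function(spectrum, baseline = c("local_linear", "none")) {
  baseline <- match.arg(baseline)
  bands <- band_definitions()
  b <- bands[bands$group == "flavonol", ]
  sum(vapply(seq_len(nrow(b)), function(i) {
    band_index(spectrum, b$lo[i], b$hi[i], baseline)
  }, 0))
}

#' Per-week treatment contrast of spectral band indices
#'
#' For a long table of per-plant band indices across sampling weeks, runs a
#' Welch t contrast (PW vs LW) per week and flags weeks significant at the
#' given level. Weeks with a single treatment are skipped with a warning.
#'
#' @param indices A data frame with columns `week`, `treatment` (PW/LW)
#'   and `value`.
#' @param alpha Significance level (default 0.05).
#' @return A data frame with one row per analysed week: `week`, `mean_pw`,
#'   `mean_lw`, `statistic`, `df`, `p`, `significant`.
#' @export
timecourse_contrast <- function(indices, alpha = 0.05) {
  stopifnot(all(c("week", "treatment", "value") %in% names(indices)))
  indices$treatment <- canonical_token(indices$treatment, c("PW", "LW"),
                                       "treatment")
  weeks <- sort(unique(indices$week))
  rows <- lapply(weeks, function(wk) {
    sub <- indices[indices$week == wk, , drop = FALSE]
    pw <- sub$value[sub$treatment == "PW"]
    lw <- sub$value[sub$treatment == "LW"]
    if (length(pw) < 2L || length(lw) < 2L) {
      warning("week ", wk, " lacks both treatments; skipped", call. = FALSE)
      return(NULL)
    }
    tt <- welch_t(lw, pw)
    data.frame(week = wk, mean_pw = mean(pw), mean_lw = mean(lw),
               statistic = tt$statistic, df = tt$df, p = tt$p,
               significant = tt$p < alpha)
  })
  out <- do.call(rbind, rows)
  if (is.null(out)) stop("no week had both treatments", call. = FALSE)
  rownames(out) <- NULL
  out
}
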