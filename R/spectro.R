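#' Built-in table of molar absorbance changes
#'
#' Extinction coefficient changes (Δε, M⁻¹ cm⁻¹) used to convert absorbance
#' rates into molar rates for the assays of NfsA-catalysed reductions.
#' Entries flagged `per_nadph` belong to coupled assays where the absorbance
#' change is expressed per NADPH oxidised (the cytochrome-c couple).  The
#' table is an ordinary data frame; append rows to extend it.
#'
#' @return Data frame with columns `species`, `wavelength_nm`, `delta_eps`
#'   and `per_nadph`.
#' @examples
#' extinction_table()
#' @export
extinction_table <- function() {
  data.frame(
    species = c("nitrofurazone", "nitrofurazone",
                "nitrofurantoin", "nitrofurantoin",
                "CB1954", "cytochrome_c", "NADPH"),
    wavelength_nm = c(420, 440, 400, 420, 420, 550, 340),
    delta_eps = c(4300, 880, 13807, 7970, 1200, 13500, 6200),
    per_nadph = c(FALSE, FALSE, FALSE, FALSE, FALSE, TRUE, FALSE),
    stringsAsFactors = FALSE
  )
}

#' Construct or look up an extinction entry
#'
#' `extinction_entry()` builds a single validated entry;
#' `lookup_extinction()` retrieves one from a table (by default the built-in
#' [extinction_table()]) by species and, where a species is monitored at
#' several wavelengths, by wavelength.
#'
#' @param species Chemical or assay identity (character).
#' @param wavelength_nm Monitoring wavelength (nm), > 0.
#' @param delta_eps Molar absorbance change (M⁻¹ cm⁻¹), > 0.
#' @param per_nadph Is Δε expressed per NADPH oxidised (coupled assay)?
#' @return A one-row data frame of class `extinction_entry`.
#' @examples
#' lookup_extinction("nitrofurazone", 420)
#' extinction_entry("custom_dye", 500, 2100)
#' @export
extinction_entry <- function(species, wavelength_nm, delta_eps,
                             per_nadph = FALSE) {
  check_scalar(wavelength_nm, "wavelength_nm", positive = TRUE)
  check_scalar(delta_eps, "delta_eps", positive = TRUE)
  structure(
    data.frame(species = as.character(species),
               wavelength_nm = wavelength_nm,
               delta_eps = delta_eps, per_nadph = isTRUE(per_nadph),
               stringsAsFactors = FALSE),
    class = c("extinction_entry", "data.frame"))
}

#' @rdname extinction_entry
#' @param table Extinction table to search (defaults to the built-in one).
#' @export
lookup_extinction <- function(species, wavelength_nm = NULL,
                              table = extinction_table()) {
  hit <- table[table$species == species, , drop = FALSE]
  if (!is.null(wavelength_nm)) {
    hit <- hit[hit$wavelength_nm == wavelength_nm, , drop = FALSE]
  }
  if (nrow(hit) == 0L) {
    nk_stop(sprintf("no extinction entry for species '%s'%s", species,
                    if (is.null(wavelength_nm)) "" else
                      sprintf(" at %g nm", wavelength_nm)),
            "nitrokin_lookup_error")
  }
  if (nrow(hit) > 1L) {
    nk_stop(sprintf(
      "species '%s' has entries at several wavelengths (%s); give wavelength_nm",
      species, paste(hit$wavelength_nm, collapse = ", ")),
      "nitrokin_lookup_error")
  }
  extinction_entry(hit$species, hit$wavelength_nm, hit$delta_eps,
                   hit$per_nadph)
}

#' Absorbance-vs-time assay trace
#'
#' @param times Sampling times (s), strictly increasing, length >= 3.
#' @param absorbances Absorbance readings (AU), same length as `times`.
#' @param wavelength_nm Monitoring wavelength (nm), optional metadata.
#' @param path_length_cm Optical path length (cm), default 1.
#' @return An object of class `assay_trace`.
#' @export
assay_trace <- function(times, absorbances, wavelength_nm = NA_real_,
                        path_length_cm = 1) {
  if (length(times) < 3L) {
    nk_stop("an assay trace needs at least 3 points",
            "nitrokin_insufficient_data")
  }
  if (length(absorbances) != length(times)) {
    nk_stop("'times' and 'absorbances' must have equal length",
            "nitrokin_input_error")
  }
  if (any(diff(times) <= 0)) {
    nk_stop("'times' must be strictly increasing", "nitrokin_input_error")
  }
  check_scalar(path_length_cm, "path_length_cm", positive = TRUE)
  structure(list(times = as.numeric(times),
                 absorbances = as.numeric(absorbances),
                 wavelength_nm = wavelength_nm,
                 path_length_cm = path_length_cm),
            class = "assay_trace")
}

#' Initial rate (slope) of an assay trace
#'
#' Ordinary least-squares slope of absorbance against time over an early
#' window of the trace.  The sign of the slope is preserved, so traces with
#' decreasing absorbance give negative slopes.  The default window is the
#' first 20% of the trace or the first 15 s, whichever is longer.
#'
#' @param trace An [assay_trace()].
#' @param window Numeric length-2 `c(t_start, t_end)` in seconds, or `NULL`
#'   for the default window.
#' @return List with `slope` (AU s⁻¹), `se` (its standard error), `n`
#'   (points used) and `window`.
#' @export
initial_rate_from_trace <- function(trace, window = NULL) {
  stopifnot(inherits(trace, "assay_trace"))
  if (is.null(window)) {
    t0 <- trace$times[1]
    span <- max(0.2 * (max(trace$times) - t0), 15)
    window <- c(t0, t0 + span)
  }
  sel <- trace$times >= window[1] & trace$times <= window[2]
  if (sum(sel) < 3L) {
    nk_stop("fewer than 3 trace points fall inside the window",
            "nitrokin_insufficient_data")
  }
  fit <- stats::lm(a ~ t, data = data.frame(t = trace$times[sel],
                                            a = trace$absorbances[sel]))
  cf <- suppressWarnings(summary(fit))$coefficients
  se <- if (nrow(cf) >= 2L) cf["t", "Std. Error"] else NA_real_
  # a perfectly linear trace has zero residual variance; lm reports NaN
  if (is.nan(se)) se <- 0
  list(slope = unname(stats::coef(fit)[["t"]]), se = unname(se),
       n = sum(sel), window = window)
}

#' Convert an absorbance rate to a molar rate
#'
#' Beer–Lambert conversion: `rate (µM/s) = 1e6 * |slope| / (Δε * path)`.
#' For `per_nadph` entries the returned rate is in NADPH-equivalents.
#'
#' @param slope Absorbance rate (AU s⁻¹); its sign is ignored.
#' @param entry An [extinction_entry()] (or one row of an extinction table).
#' @param path_length_cm Optical path length (cm), default 1.
#' @return Rate in µM s⁻¹ (non-negative).
#' @examples
#' absorbance_rate_to_molar_rate(0.0138, lookup_extinction("nitrofurantoin", 400))
#' @export
absorbance_rate_to_molar_rate <- function(slope, entry, path_length_cm = 1) {
  check_scalar(path_length_cm, "path_length_cm", positive = TRUE)
  eps <- entry$delta_eps
  check_scalar(eps, "delta_eps", positive = TRUE)
  1e6 * abs(slope) / (eps * path_length_cm)
}

# Molar absorbances used for the two-wavelength protein/FMN deconvolution.
FMN_EPS_454 <- 12200
FMN_EPS_280 <- 20970
NFSA_EPS_280 <- 31190

#' Enzyme and free-FMN concentration from two-wavelength absorbance
#'
#' NfsA and its FMN cofactor both absorb at 280 nm while only FMN absorbs
#' at 454 nm, so the free-FMN concentration is read from A454 and its
#' contribution subtracted from A280 before converting to protein
#' concentration (ε: FMN 12 200 M⁻¹cm⁻¹ at 454 nm, 20 970 at 280 nm; NfsA
#' 31 190 at 280 nm).  A negative protein concentration is reported as an
#' error, never clipped.
#'
#' @param a280,a454 Absorbances at 280 and 454 nm (AU), >= 0.
#' @param path_length_cm Optical path length (cm), default 1.
#' @return List with `nfsa_uM` and `free_fmn_uM`.
#' @examples
#' protein_concentration(a280 = 0.5197, a454 = 0.122)
#' @export
protein_concentration <- function(a280, a454, path_length_cm = 1) {
  check_scalar(a280, "a280", nonneg = TRUE)
  check_scalar(a454, "a454", nonneg = TRUE)
  check_scalar(path_length_cm, "path_length_cm", positive = TRUE)
  fmn_M <- a454 / (FMN_EPS_454 * path_length_cm)
  resid_280 <- a280 - fmn_M * FMN_EPS_280 * path_length_cm
  if (resid_280 < 0) {
    nk_stop(sprintf(
      "inconsistent absorbances: the FMN contribution at 280 nm (%.4f AU) exceeds A280 (%.4f AU)",
      fmn_M * FMN_EPS_280 * path_length_cm, a280),
      "nitrokin_inconsistent_absorbance")
  }
  list(nfsa_uM = 1e6 * resid_280 / (NFSA_EPS_280 * path_length_cm),
       free_fmn_uM = 1e6 * fmn_M)
}
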