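# Derived quantities and per-parameter significance.

#' Catalytic efficiency kcat/Km with propagated standard error
#'
#' Computes the second-order efficiency `kcat/Km` and its standard error by
#' first-order (delta-method) propagation:
#' `var(kcat/Km) = (1/Km)^2 var(kcat) + (kcat/Km^2)^2 var(Km)
#'   - 2 (kcat/Km^3) cov(kcat, Km)`.
#' Applied to an `nk_fit`, the variances and covariance are taken from the
#' fit's covariance matrix; if the covariance term is unavailable the SE is
#' computed from the variances alone and the result flagged.
#'
#' @param object Either an `nk_fit` or a numeric `kcat` value (with `Km`
#'   etc. supplied).
#' @param ... Passed to methods.
#' @return List with `efficiency` (s⁻¹ µM⁻¹), `se`, and
#'   `covariance_used` (logical flag).
#' @examples
#' derived_efficiency(42, Km = 12)$efficiency    # 3.5 s-1 uM-1
#' @export
derived_efficiency <- function(object, ...) UseMethod("derived_efficiency")

#' @rdname derived_efficiency
#' @param Km Michaelis constant (µM), > 0.
#' @param var_kcat,var_Km Variances of the two estimates (default 0).
#' @param cov_kcat_Km Their covariance; `NA` (default) means unavailable.
#' @export
derived_efficiency.default <- function(object, Km, var_kcat = 0, var_Km = 0,
                                       cov_kcat_Km = NA_real_, ...) {
  kcat <- object
  check_scalar(kcat, "kcat", positive = TRUE)
  check_scalar(Km, "Km", positive = TRUE)
  eff <- kcat / Km
  use_cov <- is.finite(cov_kcat_Km)
  v <- (1 / Km)^2 * var_kcat + (kcat / Km^2)^2 * var_Km
  if (use_cov) v <- v - 2 * (kcat / Km^3) * cov_kcat_Km
  list(efficiency = eff, se = sqrt(max(v, 0)), covariance_used = use_cov)
}

#' @rdname derived_efficiency
#' @param which For an `nk_fit`: which substrate's Km to use, `"A"` or
#'   `"B"` (ignored for single-substrate fits).
#' @param use_covariance Include the kcat–Km covariance term (default TRUE).
#' @export
derived_efficiency.nk_fit <- function(object, which = c("A", "B"),
                                      use_covariance = TRUE, ...) {
  est <- object$estimates
  if ("kcat_app" %in% names(est)) {
    kn <- "kcat_app"; mn <- "Km_app"
  } else {
    which <- match.arg(which)
    kn <- "kcat"; mn <- paste0("Km_", which)
  }
  cv <- object$covariance
  cov_term <- if (use_covariance && !is.null(cv) &&
                  all(c(kn, mn) %in% colnames(cv))) cv[kn, mn] else NA_real_
  derived_efficiency(est[[kn]], Km = est[[mn]],
                     var_kcat = (object$std_errors[[kn]])^2,
                     var_Km = (object$std_errors[[mn]])^2,
                     cov_kcat_Km = cov_term)
}

#' Two-sided significance of fitted parameters against zero
#'
#' For each estimate, `t = estimate / SE` is referred to a t distribution
#' with the fit's residual degrees of freedom and the two-sided tail
#' probability returned.  A zero estimate gives p = 1; a zero standard
#' error gives p = 0 with a `degenerate` attribute marking which
#' parameters were degenerate.
#'
#' @param fit A converged `nk_fit` with positive residual degrees of
#'   freedom.
#' @return Named numeric vector of p-values (with attribute `degenerate`).
#' @export
parameter_significance <- function(fit) {
  stopifnot(inherits(fit, "nk_fit"))
  if (fit$dof <= 0) {
    nk_stop("no residual degrees of freedom: p-values undefined",
            "nitrokin_usage_error")
  }
  est <- fit$estimates
  se <- fit$std_errors
  p <- stats::setNames(rep(NA_real_, length(est)), names(est))
  degen <- stats::setNames(rep(FALSE, length(est)), names(est))
  for (nm in names(est)) {
    if (is.na(se[[nm]])) next
    if (est[[nm]] == 0) {
      p[[nm]] <- 1
    } else if (se[[nm]] == 0) {
      p[[nm]] <- 0
      degen[[nm]] <- TRUE
    } else {
      p[[nm]] <- 2 * stats::pt(-abs(est[[nm]] / se[[nm]]), df = fit$dof)
    }
  }
  attr(p, "degenerate") <- degen
  p
}
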