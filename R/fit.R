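# Multi-start Levenberg-Marquardt least-squares engine shared by all fits.
#
# Positivity-constrained parameters (kcat, Km, Ki, b) are optimised on the
# log scale; potentials and absorbance endpoints in natural space.  The
# reported optimum is the best of all starts; ties within 1e-9 relative
# cost are broken by the smaller parameter-vector norm for determinism.

nk_multistart <- function(start, resid_fn, log_scale,
                          jitter_sd = NULL, n_starts = 8, seed = 1) {
  stopifnot(length(log_scale) == length(start))
  if (is.null(jitter_sd)) {
    jitter_sd <- ifelse(log_scale, log(3), 30)
  }
  to_work <- function(p) {
    w <- p
    w[log_scale] <- log(p[log_scale])
    w
  }
  from_work <- function(w) {
    p <- w
    p[log_scale] <- exp(w[log_scale])
    p
  }
  wfn <- function(w) resid_fn(from_work(w))
  w0 <- to_work(start)
  set.seed(seed)
  starts <- c(list(w0), lapply(seq_len(max(0, n_starts - 1)), function(i) {
    w0 + stats::rnorm(length(w0), 0, jitter_sd)
  }))
  ctl <- minpack.lm::nls.lm.control(ftol = 1e-10, ptol = 1e-8, maxiter = 1000)
  best <- NULL
  n_ok <- 0L
  for (w in starts) {
    res <- tryCatch(minpack.lm::nls.lm(par = w, fn = wfn, control = ctl),
                    error = function(e) NULL)
    if (is.null(res) || !is.finite(res$deviance)) next
    n_ok <- n_ok + 1L
    cand <- list(par = res$par, dev = res$deviance,
                 converged = res$info %in% 1:4, niter = res$niter)
    if (is.null(best)) {
      best <- cand
    } else {
      tol <- 1e-9 * max(best$dev, .Machine$double.eps)
      if (cand$dev < best$dev - tol) {
        best <- cand
      } else if (abs(cand$dev - best$dev) <= tol &&
                 sum(from_work(cand$par)^2) < sum(from_work(best$par)^2)) {
        best <- cand
      }
    }
  }
  if (is.null(best)) {
    nk_stop("least-squares optimisation failed from every start",
            "nitrokin_fit_error")
  }
  list(par = from_work(best$par), rss = best$dev, converged = best$converged,
       niter = best$niter, n_starts_tried = length(starts),
       n_starts_ok = n_ok, seed = seed)
}

# Central-difference Jacobian of the residual vector wrt natural parameters.
nk_jacobian <- function(resid_fn, par, rel = 1e-6) {
  r0 <- resid_fn(par)
  J <- matrix(NA_real_, length(r0), length(par))
  for (j in seq_along(par)) {
    h <- rel * max(abs(par[j]), 1e-6)
    pp <- par; pp[j] <- par[j] + h
    pm <- par; pm[j] <- par[j] - h
    J[, j] <- (resid_fn(pp) - resid_fn(pm)) / (2 * h)
  }
  J
}

nk_covariance <- function(resid_fn, par, rss, dof) {
  J <- nk_jacobian(resid_fn, par)
  JtJ <- crossprod(J)
  inv <- tryCatch(chol2inv(chol(JtJ)), error = function(e) {
    sv <- svd(JtJ)
    pos <- sv$d > max(sv$d) * 1e-12
    sv$v[, pos, drop = FALSE] %*%
      (t(sv$u[, pos, drop = FALSE]) / sv$d[pos])
  })
  sigma2 <- if (dof > 0) rss / dof else NA_real_
  cov <- sigma2 * inv
  dimnames(cov) <- list(names(par), names(par))
  cov
}

# Assemble the standard fit-result container.
new_nk_fit <- function(model_id, estimates, covariance, rss, n_points,
                       converged, provenance = list(), warnings = character(),
                       fixed = character()) {
  free <- setdiff(names(estimates), fixed)
  dof <- n_points - length(free)
  se <- stats::setNames(rep(NA_real_, length(estimates)), names(estimates))
  if (!is.null(covariance)) {
    d <- diag(covariance)
    d[d < 0] <- 0   # guard tiny negative diagonals from near-singularity
    se[colnames(covariance)] <- sqrt(d)
  }
  pv <- mapply(function(est, s) {
    if (is.na(s)) return(NA_real_)
    if (est == 0) return(1)
    if (s == 0) return(0)
    2 * stats::pt(-abs(est / s), df = dof)
  }, estimates, se)
  structure(list(model_id = model_id,
                 estimates = estimates,
                 std_errors = se,
                 p_values = stats::setNames(as.numeric(pv), names(estimates)),
                 rss = rss, dof = dof, n_points = n_points,
                 n_free = length(free), fixed = fixed,
                 covariance = covariance, converged = converged,
                 provenance = provenance, warnings = warnings),
            class = "nk_fit")
}

#' @export
print.nk_fit <- function(x, ...) {
  cat(sprintf("Nonlinear least-squares fit: %s\n", x$model_id))
  cat(sprintf("  %d points, %d free parameter(s), rss = %.6g, converged: %s\n",
              x$n_points, x$n_free, x$rss, x$converged))
  tab <- data.frame(estimate = x$estimates, std_error = x$std_errors,
                    p_value = signif(x$p_values, 3))
  print(tab)
  if (length(x$warnings)) cat("  warnings:", paste(x$warnings, collapse = "; "), "\n")
  invisible(x)
}

check_observations <- function(observations, need_I = FALSE) {
  req <- c("conc_A", "conc_B", "conc_E", "rate")
  if (need_I) req <- c(req, "conc_I")
  miss <- setdiff(req, names(observations))
  if (length(miss)) {
    nk_stop(sprintf("observations lack column(s): %s",
                    paste(miss, collapse = ", ")), "nitrokin_input_error")
  }
  check_conc(observations$conc_A, "conc_A")
  check_conc(observations$conc_B, "conc_B")
  if (need_I) check_conc(observations$conc_I, "conc_I")
  if (any(!is.finite(observations$rate))) {
    nk_stop("rates must be finite", "nitrokin_input_error")
  }
  if (any(observations$conc_E <= 0)) {
    nk_stop("conc_E must be > 0 to normalise rates per enzyme",
            "nitrokin_input_error")
  }
  invisible(observations)
}

#' Global fit of the ping-pong bi-substrate rate law
#'
#' Fits the three-parameter ping-pong rate law to all initial-rate
#' observations simultaneously by unweighted nonlinear least squares on the
#' per-enzyme rates `v/[E]`, minimising `sum((v/[E] - model)^2)` with equal
#' weighting of all points.  Parameters are optimised on the log scale
#' (enforcing positivity) with multi-start refinement; standard errors come
#' from the curvature of the residual surface at the optimum.
#'
#' @param observations Data frame of initial-rate measurements with columns
#'   `conc_A`, `conc_B`, `conc_E` (µM) and `rate` (µM s⁻¹); see
#'   [simulate_kinetics()] or [read_rate_table()].
#' @param n_starts Number of optimisation starts (default 8).
#' @param seed Seed controlling the start jitter (default 1).
#' @return An object of class `nk_fit` with estimates `kcat`, `Km_A`,
#'   `Km_B`, their standard errors, p-values, rss, dof and covariance.
#' @export
fit_pingpong_global <- function(observations, n_starts = 8, seed = 1) {
  check_observations(observations)
  if (nrow(observations) < 4L) {
    nk_stop("need at least 4 observations to fit 3 parameters",
            "nitrokin_design_error")
  }
  if (length(unique(observations$conc_A)) < 2L ||
      length(unique(observations$conc_B)) < 2L) {
    nk_stop(paste("design-deficient data: both substrates must be varied",
                  "(>= 2 distinct concentrations each) to identify both Km values"),
            "nitrokin_design_error")
  }
  v <- observations$rate / observations$conc_E
  A <- observations$conc_A
  B <- observations$conc_B
  model <- function(p) {
    p$kcat * A * B / (p$Km_A * B + p$Km_B * A + A * B)
  }
  resid_fn <- function(par) {
    v - model(list(kcat = par[1], Km_A = par[2], Km_B = par[3]))
  }
  start <- c(kcat = max(v), Km_A = stats::median(A[A > 0]),
             Km_B = stats::median(B[B > 0]))
  opt <- nk_multistart(start, resid_fn, log_scale = rep(TRUE, 3),
                       n_starts = n_starts, seed = seed)
  est <- stats::setNames(opt$par, names(start))
  dof <- nrow(observations) - 3L
  cov <- nk_covariance(resid_fn, est, opt$rss, dof)
  new_nk_fit("pingpong_global", est, cov, opt$rss, nrow(observations),
             opt$converged,
             provenance = list(seed = seed, n_starts = n_starts,
                               niter = opt$niter))
}

#' Apparent single-substrate (hyperbolic saturation) fit
#'
#' Fits `v/[E] = kcat_app * S / (Km_app + S)` to rates measured at a fixed
#' co-substrate concentration, as used for substrates whose co-substrate is
#' held saturating.  The apparent constants fold in the fixed co-substrate
#' level.
#'
#' @param conc Varied substrate concentrations (µM).
#' @param rate Initial rates (µM s⁻¹).
#' @param conc_E Enzyme concentration(s) (µM); default 1 treats `rate` as
#'   already per-enzyme.
#' @inheritParams fit_pingpong_global
#' @return `nk_fit` with estimates `kcat_app` and `Km_app`.
#' @export
fit_single_substrate <- function(conc, rate, conc_E = 1, n_starts = 8,
                                 seed = 1) {
  check_conc(conc, "conc")
  if (length(unique(conc)) < 3L) {
    nk_stop("need at least 3 distinct substrate concentrations",
            "nitrokin_design_error")
  }
  v <- rate / conc_E
  resid_fn <- function(par) v - par[1] * conc / (par[2] + conc)
  start <- c(kcat_app = max(v), Km_app = stats::median(conc[conc > 0]))
  opt <- nk_multistart(start, resid_fn, log_scale = c(TRUE, TRUE),
                       n_starts = n_starts, seed = seed)
  est <- stats::setNames(opt$par, names(start))
  dof <- length(conc) - 2L
  cov <- nk_covariance(resid_fn, est, opt$rss, dof)
  new_nk_fit("single_substrate", est, cov, opt$rss, length(conc),
             opt$converged,
             provenance = list(seed = seed, n_starts = n_starts,
                               niter = opt$niter))
}

#' Simultaneous fit of mixed inhibition across both ping-pong halves
#'
#' Fits the inhibited ping-pong rate law to all series (each substrate
#' varied at fixed co-substrate, with and without inhibitor)
#' simultaneously.  `mode` selects which half-reactions the inhibitor is
#' allowed to compete in: the excluded dissociation constant is held at the
#' unbounded sentinel `Inf`, making its `(1 + [I]/Ki)` factor exactly 1.
#' Fitting the restricted modes and comparing with [compare_nested()]
#' reproduces the usual extra-sum-of-squares test of whether the inhibitor
#' acts on one half or both.
#'
#' @param observations Data frame with columns `conc_A`, `conc_B`,
#'   `conc_I`, `conc_E` (µM) and `rate` (µM s⁻¹); must contain an
#'   inhibitor-free series (`conc_I == 0`) and at least one inhibited one.
#' @param mode `"both_halves"` (default), `"half_A_only"` or
#'   `"half_B_only"`.
#' @inheritParams fit_pingpong_global
#' @return `nk_fit` with estimates `kcat`, `Km_A`, `Km_B`, `Ki_A`, `Ki_B`
#'   (fixed ones reported as `Inf` with `NA` standard error).
#' @export
fit_inhibition_global <- function(observations,
                                  mode = c("both_halves", "half_A_only",
                                           "half_B_only"),
                                  n_starts = 8, seed = 1) {
  mode <- match.arg(mode)
  check_observations(observations, need_I = TRUE)
  if (!any(observations$conc_I == 0)) {
    nk_stop("design-deficient data: an inhibitor-free series (conc_I = 0) is required",
            "nitrokin_design_error")
  }
  if (!any(observations$conc_I > 0)) {
    nk_stop("design-deficient data: at least one inhibited series (conc_I > 0) is required",
            "nitrokin_design_error")
  }
  if (length(unique(observations$conc_A)) < 2L ||
      length(unique(observations$conc_B)) < 2L) {
    nk_stop("design-deficient data: both substrates must be varied",
            "nitrokin_design_error")
  }
  v <- observations$rate / observations$conc_E
  A <- observations$conc_A
  B <- observations$conc_B
  I <- observations$conc_I
  free_ki <- switch(mode,
                    both_halves = c("Ki_A", "Ki_B"),
                    half_A_only = "Ki_A",
                    half_B_only = "Ki_B")
  fixed <- setdiff(c("Ki_A", "Ki_B"), free_ki)
  par_names <- c("kcat", "Km_A", "Km_B", free_ki)
  model <- function(p) {
    KiA <- if ("Ki_A" %in% names(p)) p[["Ki_A"]] else Inf
    KiB <- if ("Ki_B" %in% names(p)) p[["Ki_B"]] else Inf
    p[["kcat"]] * A * B /
      (p[["Km_A"]] * B * (1 + I / KiA) +
       p[["Km_B"]] * A * (1 + I / KiB) + A * B)
  }
  resid_fn <- function(par) v - model(stats::setNames(as.list(par), par_names))
  ki0 <- stats::median(I[I > 0])
  start <- stats::setNames(
    c(max(v), stats::median(A[A > 0]), stats::median(B[B > 0]),
      rep(ki0, length(free_ki))), par_names)
  opt <- nk_multistart(start, resid_fn,
                       log_scale = rep(TRUE, length(start)),
                       n_starts = n_starts, seed = seed)
  est_free <- stats::setNames(opt$par, par_names)
  dof <- nrow(observations) - length(par_names)
  cov <- nk_covariance(resid_fn, est_free, opt$rss, dof)
  est <- c(est_free, stats::setNames(rep(Inf, length(fixed)), fixed))
  est <- est[c("kcat", "Km_A", "Km_B", "Ki_A", "Ki_B")]
  new_nk_fit(paste0("pingpong_inhibition_", mode), est, cov, opt$rss,
             nrow(observations), opt$converged,
             provenance = list(seed = seed, n_starts = n_starts,
                               niter = opt$niter, mode = mode),
             fixed = fixed)
}
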