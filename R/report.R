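# Structured JSON reports.  Schema "nitrokin/1": one report per run with
# estimates, uncertainties, comparison verdicts and provenance.  Reports
# carry no timestamps so identical runs produce byte-identical files.

fit_to_list <- function(fit) {
  list(model = fit$model_id,
       estimates = as.list(fit$estimates),
       std_errors = as.list(fit$std_errors),
       p_values = as.list(fit$p_values),
       rss = fit$rss, dof = fit$dof, n_points = fit$n_points,
       converged = fit$converged,
       warnings = as.list(fit$warnings),
       provenance = fit$provenance)
}

comparison_to_list <- function(cmp) {
  out <- unclass(cmp)
  out
}

#' Build a structured report from a fit
#'
#' @param x An `nk_fit`, `nk_redox_fit` or `nk_model_comparison`.
#' @param input_path Optional input file whose MD5 hash is embedded as
#'   provenance.
#' @param seed Seed used for the run, recorded in provenance.
#' @return A list ready for [write_report()].
#' @export
fit_report <- function(x, input_path = NULL, seed = NULL) {
  body <- if (inherits(x, "nk_redox_fit")) {
    list(two_step = fit_to_list(x$two_step),
         concerted = fit_to_list(x$concerted),
         comparison = comparison_to_list(x$comparison),
         endpoints = x$endpoints)
  } else if (inherits(x, "nk_fit")) {
    list(fit = fit_to_list(x))
  } else if (inherits(x, "nk_model_comparison")) {
    list(comparison = comparison_to_list(x))
  } else {
    x
  }
  prov <- list(package = "nitrokin",
               version = as.character(utils::packageVersion("nitrokin")))
  if (!is.null(seed)) prov$seed <- seed
  if (!is.null(input_path) && file.exists(input_path)) {
    prov$input <- input_path
    prov$input_md5 <- unname(tools::md5sum(input_path))
  }
  c(list(schema = "nitrokin/1"), body, list(run = prov))
}

#' Write a report as JSON
#'
#' Infinite values (the unbounded-Ki sentinel) are serialised as the
#' string `"Inf"`.
#'
#' @param report A list from [fit_report()].
#' @param path Output path.
#' @return `path`, invisibly.
#' @export
write_report <- function(report, path) {
  sanitise <- function(x) {
    if (is.list(x)) return(lapply(x, sanitise))
    if (is.numeric(x)) {
      inf <- is.infinite(x)
      if (any(inf)) {
        x <- as.list(x)
        x[inf] <- lapply(sign(unlist(lapply(x[inf], identity))),
                         function(s) if (s > 0) "Inf" else "-Inf")
      }
    }
    x
  }
  jsonlite::write_json(sanitise(report), path, auto_unbox = TRUE,
                       digits = NA, pretty = TRUE, na = "null",
                       dataframe = "rows")
  invisible(path)
}

# Flat CSV of parameter estimates for spreadsheet users.
write_estimates_csv <- function(fit, path) {
  fits <- if (inherits(fit, "nk_redox_fit")) {
    list(fit$two_step, fit$concerted)
  } else {
    list(fit)
  }
  rows <- do.call(rbind, lapply(fits, function(f) {
    data.frame(model = f$model_id, parameter = names(f$estimates),
               estimate = unname(f$estimates),
               std_error = unname(f$std_errors),
               p_value = unname(f$p_values), stringsAsFactors = FALSE)
  }))
  utils::write.csv(rows, path, row.names = FALSE)
  invisible(path)
}
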