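# Steady-state kinetics: Michaelis-Menten fitting and catalytic efficiency
# with propagated errors.

#' Fit the Michaelis--Menten equation to initial velocities
#'
#' Unweighted nonlinear least squares of `v = Vmax * S / (KM + S)` by
#' Levenberg--Marquardt, with standard errors from the fit covariance.
#' Replicate rows (identical substrate concentrations) may optionally be
#' averaged first; for noiseless data this leaves the fit unchanged.
#'
#' @param data a [generate_mm_dataset()] result or any data frame with
#'   columns `substrate_uM` and `velocity_uM_per_s`.
#' @param init optional named list with starting `vmax` and/or `km`.
#' @param average_replicates average velocities at duplicated substrate
#'   concentrations before fitting.
#' @param weights optional per-point weights (unweighted by default).
#' @return Object of class `"mm_fit"`: `vmax`, `km`, `se` (named vector),
#'   `fitted`, `residual_norm`.
#' @export
fit_mm <- function(data, init = NULL, average_replicates = FALSE,
                   weights = NULL) {
  stopifnot(is.data.frame(data))
  missing_cols <- setdiff(c("substrate_uM", "velocity_uM_per_s"), names(data))
  if (length(missing_cols) > 0L)
    stop("missing column(s): ", paste(missing_cols, collapse = ", "),
         call. = FALSE)
  S <- data$substrate_uM; v <- data$velocity_uM_per_s
  if (average_replicates) {
    agg <- stats::aggregate(v, by = list(S = S), FUN = mean)
    S <- agg$S; v <- agg$x
  }
  if (length(unique(S)) < 4L)
    stop("at least 4 distinct substrate concentrations are required",
         call. = FALSE)

  vmax0 <- if (!is.null(init$vmax)) init$vmax else max(v) * 1.2
  km0 <- if (!is.null(init$km)) init$km else stats::median(S)
  df <- data.frame(S = S, v = v)
  args <- list(v ~ vmax * S / (km + S), data = df,
               start = list(vmax = vmax0, km = km0),
               lower = c(vmax = 0, km = 0),
               control = minpack.lm::nls.lm.control(maxiter = 500,
                                                    ftol = 1e-15,
                                                    ptol = 1e-15))
  if (!is.null(weights)) args$weights <- weights
  fit <- tryCatch(
    do.call(minpack.lm::nlsLM, args),
    error = function(e)
      stop("Michaelis-Menten fit failed: ", conditionMessage(e),
           call. = FALSE))
  cf <- stats::coef(fit)
  if (cf[["vmax"]] <= 0)
    stop("fit produced a non-positive Vmax", call. = FALSE)
  if (cf[["km"]] < 1e-6 * max(S))
    warning("KM driven to the zero boundary; velocities may be saturated at ",
            "all substrate concentrations", call. = FALSE)
  se <- tryCatch(summary(fit)$coefficients[, "Std. Error"],
                 error = function(e) c(vmax = NA_real_, km = NA_real_))
  structure(list(vmax = unname(cf[["vmax"]]), km = unname(cf[["km"]]),
                 se = c(vmax = unname(se[["vmax"]]), km = unname(se[["km"]])),
                 fitted = as.numeric(stats::fitted(fit)),
                 residual_norm = sqrt(sum(stats::residuals(fit)^2))),
            class = "mm_fit")
}

#' @export
print.mm_fit <- function(x, ...) {
  cat(sprintf("MM fit: Vmax = %.4g +/- %.2g uM/s, KM = %.4g +/- %.2g uM\n",
              x$vmax, x$se[["vmax"]], x$km, x$se[["km"]]))
  invisible(x)
}

#' Catalytic efficiency with propagated error
#'
#' `kcat = Vmax / [E]`, `kcat/KM = kcat / KM`; the relative error on the
#' efficiency is propagated in quadrature from the relative errors of kcat
#' and KM.
#'
#' @param fit an `"mm_fit"`.
#' @param enzyme_conc enzyme concentration (uM), > 0.
#' @return List: `kcat` (1/s), `kcat_se`, `km`, `km_se`, `efficiency`
#'   (1/(uM s)), `efficiency_se`.
#' @examples
#' # Vmax 0.3 uM/s at [E] = 0.01 uM and KM = 40 uM: kcat 30/s, kcat/KM 0.75
#' @export
catalytic_efficiency <- function(fit, enzyme_conc) {
  stopifnot(inherits(fit, "mm_fit"))
  if (enzyme_conc <= 0) stop("enzyme_conc must be > 0", call. = FALSE)
  if (fit$km == 0) stop("KM is zero; efficiency undefined", call. = FALSE)
  kcat <- fit$vmax / enzyme_conc
  kcat_se <- fit$se[["vmax"]] / enzyme_conc
  eff <- kcat / fit$km
  rel <- sqrt((kcat_se / kcat)^2 + (fit$se[["km"]] / fit$km)^2)
  list(kcat = kcat, kcat_se = kcat_se,
       km = fit$km, km_se = fit$se[["km"]],
       efficiency = eff, efficiency_se = eff * rel)
}
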