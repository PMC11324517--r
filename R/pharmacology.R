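#' Dose-response dataset
#'
#' Container for concentration-response replicates with background wells.
#'
#' @param x Concentrations (strictly positive where log-scale models are
#'   used), one per row of \code{y}.
#' @param y Responses: a length(x) x n_replicates matrix (a vector is treated
#'   as one replicate).
#' @param background Background replicate measurements (same response units),
#'   e.g. wells with a saturating blocker.
#' @param unit Concentration unit tag (e.g. "uM", "nM").
#' @param condition Condition label.
#' @return A \code{dose_response} object.
#' @export
dose_response_dataset <- function(x, y, background = numeric(0),
                                  unit = "uM", condition = "") {
  y <- as.matrix(y)
  stopifnot(length(x) == nrow(y), ncol(y) >= 1L)
  obj <- list(x = as.numeric(x), y = y, background = as.numeric(background),
              unit = unit, condition = condition)
  class(obj) <- "dose_response"
  obj
}

#' Background-subtract and normalise a dose-response dataset to percent
#'
#' Specific signal is total minus the mean background; the mean specific
#' signal at the control concentration is set to 100 percent (in the source
#' assays the control is the lowest inhibitor concentration, or the
#' chelator-washed zero-Zn condition).
#'
#' @param d A \code{dose_response} with background replicates.
#' @param control_x Concentration value defining the 100 percent control;
#'   default is the smallest x.
#' @return A \code{dose_response} in percent units (background dropped).
#' @export
subtract_background_normalize <- function(d, control_x = min(d$x)) {
  stopifnot(inherits(d, "dose_response"))
  if (length(d$background) == 0L) stop("no background replicates present")
  spec <- d$y - mean(d$background)
  ctrl <- d$x == control_x
  if (!any(ctrl)) stop("control concentration not found in x")
  cm <- mean(spec[ctrl, , drop = FALSE])
  if (cm <= 0) stop("control mean is not positive after background subtraction")
  out <- dose_response_dataset(d$x, 100 * spec / cm, numeric(0),
                               unit = d$unit, condition = d$condition)
  attr(out, "response_unit") <- "%"
  out
}

# shared nonlinear least-squares driver: trust-region Levenberg-Marquardt via
# minpack.lm, multi-start over log-concentration starts, best fit by deviance
nls_multistart <- function(formula, data, starts_list) {
  best <- NULL
  for (st in starts_list) {
    fit <- tryCatch(
      minpack.lm::nlsLM(formula, data = data, start = st,
                        control = minpack.lm::nls.lm.control(maxiter = 200)),
      error = function(e) NULL)
    if (!is.null(fit) &&
        (is.null(best) || deviance(fit) < deviance(best))) best <- fit
  }
  if (is.null(best)) stop("nonlinear fit did not converge from any start")
  best
}

log_conc_starts <- function(x) {
  x <- x[x > 0]
  unique(c(mean(log(x)), as.numeric(quantile(log(x), c(0.25, 0.5, 0.75)))))
}

finish_fit <- function(fit, lpar, scale_pars = character(0)) {
  cf <- coef(fit)
  se <- tryCatch(summary(fit)$coefficients[, "Std. Error"],
                 error = function(e) rep(NA_real_, length(cf)))
  est <- cf
  est[lpar] <- exp(cf[lpar])
  se[lpar] <- est[lpar] * se[lpar]   # delta method for log-parameterisation
  list(estimate = est, se = se, fit = fit,
       converged = fit$convInfo$isConv %||% TRUE,
       sigma = summary(fit)$sigma)
}

`%||%` <- function(a, b) if (is.null(a)) b else a

#' Fit the Michaelis-Menten uptake model
#'
#' v = Vmax S / (Km + S), fitted by trust-region nonlinear least squares with
#' Km on the log scale and multiple starts (geometric mean and quartiles of
#' the concentrations). Standard errors come from the Jacobian at the
#' optimum; the Km standard error is back-transformed by the delta method.
#'
#' @param x Substrate concentrations (at least 3 distinct, positive).
#' @param v Rates (replicate means or pooled replicates, matched to x).
#' @return A \code{kinetic_fit}: \code{Km}, \code{Vmax}, \code{se} (named),
#'   \code{converged}, and the underlying \code{nls} object.
#' @export
michaelis_menten_fit <- function(x, v) {
  stopifnot(length(x) == length(v))
  if (length(unique(x)) < 3L) stop("need at least 3 distinct concentrations")
  if (all(abs(v - v[1]) < 1e-12)) stop("degenerate response (constant)")
  dat <- data.frame(x = x, v = v)
  starts <- lapply(log_conc_starts(x), function(lk)
    list(lkm = lk, Vmax = max(v)))
  fit <- nls_multistart(v ~ Vmax * x / (exp(lkm) + x), dat, starts)
  fin <- finish_fit(fit, "lkm")
  out <- list(Km = unname(fin$estimate["lkm"]),
              Vmax = unname(fin$estimate["Vmax"]),
              se = c(Km = unname(fin$se["lkm"]), Vmax = unname(fin$se["Vmax"])),
              converged = fin$converged, fit = fit)
  if (out$Km <= 0 || out$Vmax <= 0) stop("non-positive parameter at optimum")
  class(out) <- "kinetic_fit"
  out
}

#' @export
print.kinetic_fit <- function(x, ...) {
  cat(sprintf("Michaelis-Menten fit: Km %.3g +/- %.2g, Vmax %.4g +/- %.3g\n",
              x$Km, x$se["Km"], x$Vmax, x$se["Vmax"]))
  invisible(x)
}

#' Fit a single-site saturation binding model
#'
#' B = Bmax L / (Kd + L), same numerics as
#' \code{\link{michaelis_menten_fit}}.
#'
#' @param L Free ligand concentrations.
#' @param B Bound signal.
#' @return A \code{binding_fit}: \code{Kd}, \code{Bmax}, \code{se},
#'   \code{converged}, \code{fit}.
#' @export
saturation_binding_fit <- function(L, B) {
  stopifnot(length(L) == length(B))
  keep <- L > 0
  if (length(unique(L[keep])) < 3L) stop("need at least 3 distinct positive concentrations")
  if (all(abs(B - B[1]) < 1e-12)) stop("degenerate response (constant)")
  dat <- data.frame(x = L[keep], v = B[keep])
  starts <- lapply(log_conc_starts(dat$x), function(lk)
    list(lkd = lk, Bmax = max(dat$v)))
  fit <- nls_multistart(v ~ Bmax * x / (exp(lkd) + x), dat, starts)
  fin <- finish_fit(fit, "lkd")
  out <- list(Kd = unname(fin$estimate["lkd"]),
              Bmax = unname(fin$estimate["Bmax"]),
              se = c(Kd = unname(fin$se["lkd"]), Bmax = unname(fin$se["Bmax"])),
              converged = fin$converged, fit = fit)
  if (out$Kd <= 0) stop("non-positive Kd at optimum")
  class(out) <- "binding_fit"
  out
}

#' Fit a Hill inhibition model
#'
#' Two printed variants. Normalized response with variable slope:
#' y = 100 / (1 + (x/IC50)^h), with bottom fixed at 0 and top at 100.
#' Response with variable slope: y = bottom + (top - bottom) /
#' (1 + (x/IC50)^h). In both, (x^h)/(IC50^h) = (x/IC50)^h; the fitted curve
#' passes through 50 (resp. (top+bottom)/2) at x = IC50.
#'
#' @param x Inhibitor concentrations (at least 4 distinct, positive).
#' @param y Percent activity.
#' @param variant \code{"normalized"} or \code{"variable"}.
#' @return An \code{inhibition_fit}: \code{IC50}, \code{hill_slope},
#'   \code{top}, \code{bottom}, \code{se}, \code{variant}, \code{converged},
#'   \code{fit}.
#' @export
hill_inhibition_fit <- function(x, y, variant = c("normalized", "variable")) {
  variant <- match.arg(variant)
  stopifnot(length(x) == length(y))
  if (length(unique(x)) < 4L) stop("need at least 4 distinct concentrations")
  if (all(abs(y - y[1]) < 1e-12)) stop("degenerate response (constant)")
  dat <- data.frame(x = x, y = y)
  if (variant == "normalized") {
    starts <- lapply(log_conc_starts(x), function(li)
      list(lic = li, h = 1))
    fit <- nls_multistart(y ~ 100 / (1 + exp(h * (log(x) - lic))), dat, starts)
    fin <- finish_fit(fit, "lic")
    out <- list(IC50 = unname(fin$estimate["lic"]),
                hill_slope = unname(fin$estimate["h"]),
                top = 100, bottom = 0,
                se = c(IC50 = unname(fin$se["lic"]),
                       hill_slope = unname(fin$se["h"])))
  } else {
    starts <- lapply(log_conc_starts(x), function(li)
      list(lic = li, h = 1, top = max(y), bottom = min(y)))
    fit <- nls_multistart(
      y ~ bottom + (top - bottom) / (1 + exp(h * (log(x) - lic))), dat, starts)
    fin <- finish_fit(fit, "lic")
    out <- list(IC50 = unname(fin$estimate["lic"]),
                hill_slope = unname(fin$estimate["h"]),
                top = unname(fin$estimate["top"]),
                bottom = unname(fin$estimate["bottom"]),
                se = c(IC50 = unname(fin$se["lic"]),
                       hill_slope = unname(fin$se["h"]),
                       top = unname(fin$se["top"]),
                       bottom = unname(fin$se["bottom"])))
  }
  out$variant <- variant
  out$converged <- fin$converged
  out$fit <- fit
  if (out$IC50 <= 0) stop("non-positive IC50 at optimum")
  class(out) <- "inhibition_fit"
  out
}

#' @export
print.inhibition_fit <- function(x, ...) {
  cat(sprintf("Hill inhibition fit (%s): IC50 %.3g +/- %.2g, slope %.2f\n",
              x$variant, x$IC50, x$se["IC50"], x$hill_slope))
  invisible(x)
}

#' Predicted response of a fitted dose-response model
#'
#' @param fit A \code{kinetic_fit}, \code{binding_fit} or
#'   \code{inhibition_fit}.
#' @param x Concentrations at which to evaluate the fitted curve.
#' @return Predicted responses.
#' @export
predict_response <- function(fit, x) {
  if (inherits(fit, "kinetic_fit"))  return(fit$Vmax * x / (fit$Km + x))
  if (inherits(fit, "binding_fit"))  return(fit$Bmax * x / (fit$Kd + x))
  if (inherits(fit, "inhibition_fit"))
    return(fit$bottom + (fit$top - fit$bottom) /
             (1 + (x / fit$IC50)^fit$hill_slope))
  stop("unsupported fit object")
}

#' Estimated free Zn2+ concentration in the uptake buffer
#'
#' The chelator-washed control is taken as zero free Zn2+; otherwise the
#' buffer contributes an ambient ~100 nM (0.1 uM) on top of the added
#' concentration.
#'
#' @param added Added Zn2+ (uM), non-negative; vectorised.
#' @param edta_washed_control Logical; TRUE for the EDTA-washed zero control.
#' @param ambient Ambient buffer Zn2+ (uM).
#' @return Estimated free Zn2+ (uM).
#' @export
free_zn_concentration <- function(added, edta_washed_control = FALSE,
                                  ambient = 0.1) {
  if (any(added < 0)) stop("added concentration must be non-negative")
  if (isTRUE(edta_washed_control)) return(rep(0, length(added)))
  added + ambient
}

#' IC50 fold change between two inhibition fits
#'
#' Ratio IC50_a / IC50_b with first-order (delta-method) uncertainty
#' propagation from the two standard errors.
#'
#' @param fit_a,fit_b Converged \code{inhibition_fit} objects.
#' @return List with \code{ratio} and \code{se}.
#' @export
ic50_fold_change <- function(fit_a, fit_b) {
  stopifnot(inherits(fit_a, "inhibition_fit"), inherits(fit_b, "inhibition_fit"))
  r <- fit_a$IC50 / fit_b$IC50
  se <- r * sqrt((fit_a$se["IC50"] / fit_a$IC50)^2 +
                 (fit_b$se["IC50"] / fit_b$IC50)^2)
  list(ratio = r, se = unname(se))
}
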