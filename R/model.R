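#' Parameter set for the operational model of agonism
#'
#' Bundles the fixed and estimable parameters of the operational
#' (Black-Leff) model for one endpoint: the drug-free baseline response BL,
#' the maximum fractional suppression Imax, the shared Hill factor H, and
#' per-drug transducer constants tau, log10 dissociation constants and
#' residual standard deviations sigma.
#'
#' @param endpoint `"PI"` (Pearl Index, per 100 woman-years) or `"OR"`
#'   (ovulation rate, percent).
#' @param baseline Endpoint value with no drug on board; positive.
#' @param imax Maximum fraction of suppression, in \[0, 1\].
#' @param hill Hill factor H, positive, shared across drugs.
#' @param tau Named numeric vector of transducer constants, one per drug;
#'   all positive.
#' @param log10_kd Named numeric vector of log10 KD (pmol/L) per drug.
#' @param sigma Named numeric vector of residual standard deviations per
#'   drug, in endpoint units; all positive.
#' @param fixed Character vector naming the parameters treated as fixed
#'   rather than estimated (bookkeeping only; the fitter decides what it
#'   frees).
#' @return An object of class `operational_params`.
#' @export
operational_params <- function(endpoint = c("PI", "OR"), baseline, imax,
                               hill, tau, log10_kd, sigma,
                               fixed = c("baseline", "imax", "log10_kd")) {
  endpoint <- match.arg(endpoint)
  if (!is.numeric(baseline) || baseline <= 0) stop("baseline must be > 0")
  if (!is.numeric(imax) || imax < 0 || imax > 1) stop("imax must lie in [0, 1]")
  if (!is.numeric(hill) || hill <= 0) stop("hill must be > 0")
  if (is.null(names(tau)) || any(!nzchar(names(tau))))
    stop("tau must be a named vector (one entry per drug)")
  if (any(tau <= 0)) stop("all tau values must be > 0")
  missing_kd <- setdiff(names(tau), names(log10_kd))
  if (length(missing_kd))
    stop("log10_kd missing for drug(s): ", paste(missing_kd, collapse = ", "))
  missing_sg <- setdiff(names(tau), names(sigma))
  if (length(missing_sg))
    stop("sigma missing for drug(s): ", paste(missing_sg, collapse = ", "))
  if (any(sigma[names(tau)] <= 0)) stop("all sigma values must be > 0")
  structure(
    list(endpoint = endpoint, baseline = baseline, imax = imax, hill = hill,
         tau = tau, log10_kd = log10_kd[names(tau)],
         sigma = sigma[names(tau)], fixed = fixed),
    class = "operational_params"
  )
}

#' @export
print.operational_params <- function(x, ...) {
  cat(sprintf("<operational_params> endpoint %s: BL %.3g, Imax %.3g, H %.4g\n",
              x$endpoint, x$baseline, x$imax, x$hill))
  for (d in names(x$tau))
    cat(sprintf("  %s: tau %.4g, log10 KD %.4g, sigma %.4g\n",
                d, x$tau[[d]], x$log10_kd[[d]], x$sigma[[d]]))
  invisible(x)
}

#' Published operational-model parameter sets
#'
#' The fitted meta-analytic parameter sets for the Pearl Index and the
#' ovulation rate: BL 85 (PI) or 100 (OR) with Imax 1, shared Hill factor
#' (9.653 for PI, 25.462 for OR), transducer constants for LNG and DRSP, the
#' literature log10 KD values (3.556 LNG, 2.949 DRSP, pmol/L scale) and the
#' estimated residual standard deviations. Used as simulation truth and as
#' defaults in the scenario engine.
#'
#' @param endpoint `"PI"` or `"OR"`.
#' @return An [operational_params()] object.
#' @export
default_operational_params <- function(endpoint = c("PI", "OR")) {
  endpoint <- match.arg(endpoint)
  kd <- c(LNG = 3.556, DRSP = 2.949)
  if (endpoint == "PI") {
    operational_params("PI", baseline = 85, imax = 1, hill = 9.653,
                       tau = c(LNG = 3.046, DRSP = 2.602),
                       log10_kd = kd,
                       sigma = c(LNG = 0.493, DRSP = 0.572))
  } else {
    operational_params("OR", baseline = 100, imax = 1, hill = 25.462,
                       tau = c(LNG = 2.172, DRSP = 1.867),
                       log10_kd = kd,
                       sigma = c(LNG = 6.572, DRSP = 2.260))
  }
}

#' Reported CV% of the transducer-constant estimates
#'
#' Relative standard errors (percent) of the published tau estimates, used
#' to inflate the log-tau covariance in [build_tau_distribution()].
#'
#' @param endpoint `"PI"` or `"OR"`.
#' @return Named numeric vector of CV percent per drug.
#' @export
default_tau_cv <- function(endpoint = c("PI", "OR")) {
  endpoint <- match.arg(endpoint)
  if (endpoint == "PI") c(LNG = 8.84, DRSP = 9.59) else c(LNG = 0.19, DRSP = 0.26)
}

#' Emax (sigmoid-free) inhibition model
#'
#' Baseline * (1 - Imax * Cavg / (IC50 + Cavg)): the single-drug
#' concentration-response model the class-level operational model
#' generalises.
#'
#' @param cavg Average steady-state concentration(s), ng/mL; non-negative.
#' @param params List with elements `baseline`, `imax`, `ic50` (ng/mL) as
#'   produced by [emax_params()].
#' @return Predicted endpoint value(s), in `[baseline*(1-imax), baseline]`.
#' @export
emax_response <- function(cavg, params) {
  if (any(cavg < 0)) stop("cavg must be non-negative")
  if (params$ic50 <= 0) stop("ic50 must be > 0")
  params$baseline * (1 - params$imax * cavg / (params$ic50 + cavg))
}

#' @rdname emax_response
#' @param baseline,imax,ic50,sigma Emax model parameters; `sigma` is the
#'   residual standard deviation in endpoint units.
#' @export
emax_params <- function(baseline, imax, ic50, sigma = 1) {
  if (baseline <= 0) stop("baseline must be > 0")
  if (imax < 0 || imax > 1) stop("imax must lie in [0, 1]")
  if (ic50 <= 0) stop("ic50 must be > 0")
  if (sigma <= 0) stop("sigma must be > 0")
  list(baseline = baseline, imax = imax, ic50 = ic50, sigma = sigma)
}

# Suppression fraction of the operational model, computed in log space so
# extreme Hill factors cannot overflow: frac = 1 / (1 + ((kd + x)/(tau x))^H).
.op_fraction <- function(x, tau, hill, kd) {
  r <- exp(hill * (log(kd + x) - log(tau) - log(x)))
  1 / (1 + r)
}

#' Operational model of agonism response
#'
#' Evaluates the operational (Black-Leff) model for one drug. On the default
#' log10 concentration scale the operating variable is
#' x = log10(Cavg in pmol/L) and kd = log10(KD in pmol/L), and the response
#' is `baseline * (1 - imax * (tau*x)^H / ((kd + x)^H + (tau*x)^H))`. With
#' `scale = "linear"` the same functional form is applied to the molar
#' concentration and KD directly.
#'
#' Concentrations at or below 1 pmol/L make the log-scale operating variable
#' non-positive; by convention such inputs return the baseline (no
#' suppression) with a warning.
#'
#' @param cavg Concentration(s) in ng/mL; positive.
#' @param drug_id Drug label present in `params$tau`.
#' @param params An [operational_params()] object.
#' @param registry Drug registry supplying molecular weights; see
#'   [default_drug_registry()].
#' @param scale `"log10"` (default) or `"linear"` concentration scale.
#' @return Predicted endpoint value(s), bounded by
#'   `[baseline*(1-imax), baseline]` and non-increasing in `cavg`.
#' @export
operational_response <- function(cavg, drug_id, params,
                                 registry = default_drug_registry(),
                                 scale = c("log10", "linear")) {
  scale <- match.arg(scale)
  if (!drug_id %in% names(params$tau))
    stop("drug '", drug_id, "' has no tau in the parameter set")
  spec <- .get_spec(registry, drug_id)
  cmol <- to_molar(cavg, spec)
  tau <- params$tau[[drug_id]]
  if (scale == "log10") {
    x <- log10(cmol)
    kd <- params$log10_kd[[drug_id]]
    out <- rep(params$baseline, length(x))
    ok <- x > 0
    if (any(!ok))
      warning("concentration <= 1 pmol/L: returning baseline (no suppression) ",
              "for ", sum(!ok), " value(s)")
    if (any(ok))
      out[ok] <- params$baseline *
        (1 - params$imax * .op_fraction(x[ok], tau, params$hill, kd))
    out
  } else {
    kd <- 10^params$log10_kd[[drug_id]]
    params$baseline *
      (1 - params$imax * .op_fraction(cmol, tau, params$hill, kd))
  }
}

# Model means for a set of trial arms (vectorised per drug).
.model_means <- function(arms, params, registry, scale = "log10") {
  yhat <- numeric(nrow(arms))
  for (d in unique(arms$drug_id)) {
    idx <- arms$drug_id == d
    yhat[idx] <- operational_response(arms$cavg_ng_ml[idx], d, params,
                                      registry = registry, scale = scale)
  }
  yhat
}
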