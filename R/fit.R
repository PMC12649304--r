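# Profiled objective shared by the fitters: structural parameters in, NLL at
# the closed-form sigma out. Works on arm summaries precomputed once per fit.
.profiled_nll <- function(yhat, y, n, drug, sigma_floor) {
  r2n <- n * (y - yhat)^2
  nll <- 0
  for (d in unique(drug)) {
    idx <- drug == d
    J <- sum(idx)
    s2 <- max(mean(r2n[idx]), sigma_floor^2)
    nll <- nll + J / 2 * log(2 * pi * s2) - 0.5 * sum(log(n[idx])) +
      sum(r2n[idx]) / (2 * s2)
  }
  nll
}

# Full NLL as a function of the working-scale parameter vector psi
# (log tau per drug, optionally log hill, log sigma per drug); used for the
# Hessian at the optimum.
.full_nll_factory <- function(arms, endpoint, drugs, baseline, imax, hill,
                              log10_kd, registry, scale, free_hill) {
  y <- arms$observed; n <- arms$n_subjects; drug <- arms$drug_id
  nd <- length(drugs)
  function(psi) {
    tau <- setNames(exp(psi[seq_len(nd)]), drugs)
    h <- if (free_hill) exp(psi[nd + 1L]) else hill
    sig <- setNames(exp(psi[(nd + free_hill + 1L):(2L * nd + free_hill)]), drugs)
    p <- operational_params(endpoint, baseline = baseline, imax = imax,
                            hill = h, tau = tau, log10_kd = log10_kd,
                            sigma = sig)
    yhat <- .model_means(arms, p, registry, scale)
    s <- sig[drug]
    sum(0.5 * log(2 * pi * s^2 / n) + n * (y - yhat)^2 / (2 * s^2))
  }
}

# Bounded quasi-Newton multistart with derivative-free polishing. L-BFGS-B's
# line search can stall just short of the optimum, so the best start is
# alternately polished (Nelder-Mead, or Brent in one dimension) and restarted
# until neither step improves; convergence means the final round confirmed a
# stationary point.
.optimise_multistart <- function(obj, theta_starts, lower, upper,
                                 pgtol = 1e-8) {
  best <- NULL; best_start <- NA_integer_
  for (s in seq_along(theta_starts)) {
    res <- tryCatch(
      optim(theta_starts[[s]], obj, method = "L-BFGS-B", lower = lower,
            upper = upper, control = list(pgtol = pgtol, maxit = 1000)),
      error = function(e) NULL)
    if (!is.null(res) && (is.null(best) || res$value < best$value)) {
      best <- res; best_start <- s
    }
  }
  if (is.null(best)) return(NULL)
  converged <- best$convergence == 0
  tol <- function(v) 1e-8 * max(1, abs(v))
  for (round in 1:3) {
    polish <- tryCatch(
      if (length(best$par) > 1L)
        optim(best$par, obj, method = "Nelder-Mead",
              control = list(reltol = 1e-12, maxit = 2000))
      else
        optim(best$par, obj, method = "Brent", lower = lower, upper = upper,
              control = list(reltol = 1e-12)),
      error = function(e) NULL)
    if (is.null(polish)) break
    improve <- best$value - polish$value
    if (polish$value <= best$value) {
      best$par <- pmin(pmax(polish$par, lower), upper)
      best$value <- polish$value
    }
    if (improve < tol(best$value)) { converged <- TRUE; break }
    res <- tryCatch(
      optim(best$par, obj, method = "L-BFGS-B", lower = lower, upper = upper,
            control = list(pgtol = pgtol, maxit = 1000)),
      error = function(e) NULL)
    if (!is.null(res) && res$value <= best$value) {
      converged <- res$convergence == 0
      if (res$value > best$value - tol(best$value)) converged <- TRUE
      best <- res
    }
  }
  best$converged <- converged
  best$best_start <- best_start
  best
}

.wald_summary <- function(estimates, se) {
  cv <- 100 * se / estimates
  ci <- cbind(low = estimates - 1.96 * se, high = estimates + 1.96 * se)
  rownames(ci) <- names(estimates)
  list(cv_percent = cv, ci95 = ci)
}

#' Fit the operational model by naive-pooled weighted maximum likelihood
#'
#' Estimates the per-drug transducer constants (and, by default, the shared
#' Hill factor) by maximising the exact Gaussian likelihood of the pooled
#' trial arms, each arm weighted through the residual variance
#' `sigma_i^2 / n_ij`. The residual standard deviations are profiled out in
#' closed form ([profile_sigma()]); optimisation runs a bounded quasi-Newton
#' search on log-transformed parameters from a deterministic multistart
#' grid. Standard errors are Wald, from the inverse finite-difference
#' Hessian over (log tau, log H, log sigma) at the optimum, delta-method
#' back-transformed; 95% CIs are estimate +/- 1.96 SE on the natural scale.
#'
#' @param arms Trial-arm data frame (schema of [read_arms()]); all arms must
#'   share `endpoint`, and every drug needs at least two distinct exposure
#'   levels.
#' @param endpoint `"PI"` or `"OR"`; defaults to the arms' endpoint.
#' @param registry Drug registry; supplies molecular weights and default
#'   log10 KD values.
#' @param baseline Fixed baseline; defaults to 85 for PI, 100 for OR.
#' @param imax Fixed maximum suppression fraction (default 1).
#' @param hill `NULL` to estimate the Hill factor (default) or a positive
#'   number to fix it.
#' @param log10_kd Optional named vector overriding the registry KD values.
#' @param tau_bounds,hill_bounds Box bounds for the free parameters.
#' @param scale Concentration scale (see [operational_response()]).
#' @param sigma_floor Floor on the profiled sigma estimates.
#' @param starts Optional matrix of starting values (columns: tau start,
#'   hill start) overriding the deterministic default grid.
#' @param pgtol Projected-gradient tolerance passed to [stats::optim()].
#' @return An object of class `op_fit` with elements `estimates`, `fixed`,
#'   `se`, `cv_percent`, `ci95`, `loglik`, `converged`, `n_arms`,
#'   `n_subjects_total`, `starts`, `best_start`.
#' @export
fit_operational <- function(arms, endpoint = NULL,
                            registry = default_drug_registry(),
                            baseline = NULL, imax = 1, hill = NULL,
                            log10_kd = NULL,
                            tau_bounds = c(1e-2, 1e3),
                            hill_bounds = c(0.1, 100),
                            scale = c("log10", "linear"),
                            sigma_floor = 1e-6,
                            starts = NULL, pgtol = 1e-8) {
  scale <- match.arg(scale)
  .check_arms(arms)
  if (is.null(endpoint)) endpoint <- unique(arms$endpoint)
  if (length(unique(arms$endpoint)) != 1L || !all(arms$endpoint == endpoint))
    stop("arms must share a single endpoint matching 'endpoint'")
  if (is.null(baseline)) baseline <- if (endpoint == "PI") 85 else 100
  drugs <- sort(unique(arms$drug_id))
  for (d in drugs)
    if (length(unique(arms$cavg_ng_ml[arms$drug_id == d])) < 2L)
      stop("degenerate design: drug '", d,
           "' has fewer than two distinct exposure levels")
  if (is.null(log10_kd))
    log10_kd <- vapply(drugs, function(d) .get_spec(registry, d)$log10_kd,
                       numeric(1))
  log10_kd <- log10_kd[drugs]
  free_hill <- is.null(hill)
  nd <- length(drugs)
  y <- arms$observed; n <- arms$n_subjects; drug <- arms$drug_id

  obj <- function(theta) {
    tau <- setNames(exp(theta[seq_len(nd)]), drugs)
    h <- if (free_hill) exp(theta[nd + 1L]) else hill
    p <- operational_params(endpoint, baseline = baseline, imax = imax,
                            hill = h, tau = tau, log10_kd = log10_kd,
                            sigma = setNames(rep(1, nd), drugs))
    yhat <- suppressWarnings(.model_means(arms, p, registry, scale))
    .profiled_nll(yhat, y, n, drug, sigma_floor)
  }

  if (is.null(starts)) {
    starts <- as.matrix(expand.grid(tau = c(0.5, 3, 20), hill = c(2, 10, 40)))
    if (!free_hill) starts <- cbind(tau = c(0.1, 0.5, 3, 20, 100), hill = hill)
  }
  lower <- c(rep(log(tau_bounds[1]), nd), if (free_hill) log(hill_bounds[1]))
  upper <- c(rep(log(tau_bounds[2]), nd), if (free_hill) log(hill_bounds[2]))
  theta_starts <- lapply(seq_len(nrow(starts)), function(s)
    c(rep(log(starts[s, 1]), nd), if (free_hill) log(starts[s, 2])))
  best <- .optimise_multistart(obj, theta_starts, lower, upper, pgtol)
  if (is.null(best))
    return(structure(list(endpoint = endpoint, converged = FALSE,
                          estimates = NULL, message = "all starts failed"),
                     class = "op_fit"))

  tau_hat <- setNames(exp(best$par[seq_len(nd)]), drugs)
  hill_hat <- if (free_hill) exp(best$par[nd + 1L]) else hill
  p_hat <- operational_params(endpoint, baseline = baseline, imax = imax,
                              hill = hill_hat, tau = tau_hat,
                              log10_kd = log10_kd,
                              sigma = setNames(rep(1, nd), drugs))
  sigma_hat <- profile_sigma(p_hat, arms, registry, scale, sigma_floor)[drugs]

  est <- c(setNames(tau_hat, paste0("tau_", drugs)),
           if (free_hill) c(hill = unname(hill_hat)),
           setNames(sigma_hat, paste0("sigma_", drugs)))

  full_nll <- .full_nll_factory(arms, endpoint, drugs, baseline, imax, hill,
                                log10_kd, registry, scale, free_hill)
  psi_hat <- c(log(tau_hat), if (free_hill) log(hill_hat), log(sigma_hat))
  se <- rep(NA_real_, length(est))
  H <- tryCatch(pracma::hessian(full_nll, psi_hat), error = function(e) NULL)
  if (!is.null(H)) {
    cov_psi <- tryCatch(solve(H), error = function(e) NULL)
    if (!is.null(cov_psi)) {
      dg <- diag(cov_psi)
      se <- ifelse(dg > 0, est * sqrt(pmax(dg, 0)), NA_real_)
    }
  }
  names(se) <- names(est)
  ws <- .wald_summary(est, se)

  structure(list(
    endpoint = endpoint,
    estimates = est,
    fixed = c(baseline = baseline, imax = imax,
              if (!free_hill) c(hill = hill),
              setNames(log10_kd, paste0("log10_kd_", drugs))),
    se = se, cv_percent = ws$cv_percent, ci95 = ws$ci95,
    loglik = -full_nll(psi_hat),
    converged = best$converged,
    n_arms = nrow(arms), n_subjects_total = sum(n),
    starts = starts, best_start = best$best_start,
    scale = scale, params = {
      p_hat$sigma <- sigma_hat; p_hat
    }
  ), class = "op_fit")
}

#' Fit the single-drug Emax model
#'
#' Naive-pooled weighted maximum-likelihood fit of the baseline Emax model
#' with IC50 free and the residual standard deviations profiled in closed
#' form, using the same multistart/Wald machinery as [fit_operational()].
#'
#' @inheritParams fit_operational
#' @param ic50_bounds Box bounds for IC50 (ng/mL).
#' @return An `op_fit` object with estimates `ic50` and per-drug sigmas.
#' @export
fit_emax <- function(arms, baseline = NULL, imax = 1,
                     ic50_bounds = c(1e-4, 1e4), sigma_floor = 1e-6,
                     starts = NULL, pgtol = 1e-8) {
  .check_arms(arms)
  endpoint <- unique(arms$endpoint)
  if (length(endpoint) != 1L) stop("arms must share a single endpoint")
  if (is.null(baseline)) baseline <- if (endpoint == "PI") 85 else 100
  drugs <- sort(unique(arms$drug_id))
  y <- arms$observed; n <- arms$n_subjects; drug <- arms$drug_id

  obj <- function(theta) {
    p <- emax_params(baseline, imax, exp(theta[1]))
    .profiled_nll(emax_response(arms$cavg_ng_ml, p), y, n, drug, sigma_floor)
  }
  if (is.null(starts))
    starts <- matrix(log(c(0.01, 0.1, 1, 10, 100)), ncol = 1)
  best <- .optimise_multistart(obj, as.list(starts[, 1]),
                               log(ic50_bounds[1]), log(ic50_bounds[2]),
                               pgtol)
  if (is.null(best))
    return(structure(list(endpoint = endpoint, converged = FALSE,
                          estimates = NULL, message = "all starts failed"),
                     class = "op_fit"))
  ic50_hat <- exp(best$par[1])
  p_hat <- emax_params(baseline, imax, ic50_hat)
  yhat <- emax_response(arms$cavg_ng_ml, p_hat)
  r2n <- n * (y - yhat)^2
  sigma_hat <- pmax(sqrt(vapply(split(r2n, drug), mean, numeric(1))),
                    sigma_floor)[drugs]
  est <- c(ic50 = ic50_hat, setNames(sigma_hat, paste0("sigma_", drugs)))

  full_nll <- function(psi) {
    p <- emax_params(baseline, imax, exp(psi[1]))
    yh <- emax_response(arms$cavg_ng_ml, p)
    s <- setNames(exp(psi[-1]), drugs)[drug]
    sum(0.5 * log(2 * pi * s^2 / n) + n * (y - yh)^2 / (2 * s^2))
  }
  psi_hat <- c(log(ic50_hat), log(sigma_hat))
  se <- rep(NA_real_, length(est))
  H <- tryCatch(pracma::hessian(full_nll, psi_hat), error = function(e) NULL)
  if (!is.null(H)) {
    cov_psi <- tryCatch(solve(H), error = function(e) NULL)
    if (!is.null(cov_psi)) {
      dg <- diag(cov_psi)
      se <- ifelse(dg > 0, est * sqrt(pmax(dg, 0)), NA_real_)
    }
  }
  names(se) <- names(est)
  ws <- .wald_summary(est, se)
  structure(list(
    endpoint = endpoint, estimates = est,
    fixed = c(baseline = baseline, imax = imax),
    se = se, cv_percent = ws$cv_percent, ci95 = ws$ci95,
    loglik = -full_nll(psi_hat), converged = best$converged,
    n_arms = nrow(arms), n_subjects_total = sum(n),
    starts = starts, best_start = best$best_start, scale = "linear"
  ), class = "op_fit")
}

#' @export
print.op_fit <- function(x, ...) {
  cat(sprintf("<op_fit> endpoint %s, %s, %d arms / %d subjects, logLik %.3f\n",
              x$endpoint, if (isTRUE(x$converged)) "converged" else "NOT converged",
              x$n_arms %||% NA_integer_, x$n_subjects_total %||% NA_integer_,
              x$loglik %||% NA_real_))
  if (!is.null(x$estimates)) {
    tab <- data.frame(
      estimate = sprintf("%.4g", x$estimates),
      `cv%` = sprintf("%.2f", x$cv_percent),
      ci95 = sprintf("(%.4g, %.4g)", x$ci95[, "low"], x$ci95[, "high"]),
      check.names = FALSE)
    rownames(tab) <- names(x$estimates)
    print(tab)
    cat("fixed:", paste(sprintf("%s=%.4g", names(x$fixed), x$fixed),
                        collapse = ", "), "\n")
  }
  invisible(x)
}

`%||%` <- function(a, b) if (is.null(a)) b else a

#' Serialise / read a fit as JSON
#'
#' Writes the fit with a stable schema (`endpoint`, `estimates`, `fixed`,
#' `se`, `cv_percent`, `ci95`, `loglik`, `converged`, `n_arms`,
#' `n_subjects_total`) and reads it back into an `op_fit`.
#'
#' @param fit An `op_fit` object.
#' @param path Output (input) file path.
#' @return `write_fit()` returns `path` invisibly; `read_fit()` the fit.
#' @export
write_fit <- function(fit, path) {
  ci <- lapply(seq_len(nrow(fit$ci95)), function(i) unname(fit$ci95[i, ]))
  names(ci) <- rownames(fit$ci95)
  obj <- list(endpoint = fit$endpoint,
              estimates = as.list(fit$estimates),
              fixed = as.list(fit$fixed),
              se = as.list(fit$se),
              cv_percent = as.list(fit$cv_percent),
              ci95 = ci,
              loglik = fit$loglik,
              converged = fit$converged,
              n_arms = fit$n_arms,
              n_subjects_total = fit$n_subjects_total)
  jsonlite::write_json(obj, path, auto_unbox = TRUE, digits = NA,
                       pretty = TRUE)
  invisible(path)
}

#' @rdname write_fit
#' @export
read_fit <- function(path) {
  obj <- jsonlite::fromJSON(path)
  ci <- do.call(rbind, obj$ci95)
  colnames(ci) <- c("low", "high")
  structure(list(
    endpoint = obj$endpoint,
    estimates = unlist(obj$estimates),
    fixed = unlist(obj$fixed),
    se = unlist(obj$se),
    cv_percent = unlist(obj$cv_percent),
    ci95 = ci,
    loglik = obj$loglik, converged = obj$converged,
    n_arms = obj$n_arms, n_subjects_total = obj$n_subjects_total
  ), class = "op_fit")
}
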