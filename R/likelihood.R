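#' Naive-pooled weighted negative log-likelihood
#'
#' Exact Gaussian negative log-likelihood of a set of trial arms under the
#' operational model, with per-arm residual variance sigma_i^2 / n_ij: arms
#' with more subjects carry proportionally more weight. Lower is better.
#'
#' @param params An [operational_params()] object whose endpoint matches the
#'   arms.
#' @param arms Trial-arm data frame (see [read_arms()] for the schema) with
#'   resolved `cavg_ng_ml`.
#' @param registry Drug registry; see [default_drug_registry()].
#' @param scale Concentration scale passed to [operational_response()].
#' @return The scalar negative log-likelihood
#'   `sum(0.5*log(2*pi*sigma_i^2/n_ij) + n_ij*(y_ij - yhat_ij)^2/(2*sigma_i^2))`.
#' @export
neg_log_likelihood <- function(params, arms,
                               registry = default_drug_registry(),
                               scale = c("log10", "linear")) {
  scale <- match.arg(scale)
  .check_arms(arms)
  if (!all(arms$endpoint == params$endpoint))
    stop("arm endpoints do not all match params endpoint '", params$endpoint, "'")
  unknown <- setdiff(unique(arms$drug_id), names(params$tau))
  if (length(unknown))
    stop("arm drug(s) not in parameter set: ", paste(unknown, collapse = ", "))
  sig <- params$sigma[arms$drug_id]
  if (any(sig <= 0)) stop("all sigma values must be > 0")
  yhat <- .model_means(arms, params, registry, scale)
  n <- arms$n_subjects
  r <- arms$observed - yhat
  sum(0.5 * log(2 * pi * sig^2 / n) + n * r^2 / (2 * sig^2))
}

#' Closed-form profile estimate of the residual standard deviations
#'
#' For fixed structural parameters the residual model
#' `var(eps_ij) = sigma_i^2 / n_ij` has the closed-form maximum-likelihood
#' solution `sigma_i^2 = mean_j(n_ij * (y_ij - yhat_ij)^2)` per drug.
#' Plugging this profile estimate into [neg_log_likelihood()] attains its
#' minimum over sigma. Drugs with no arms are omitted; a small floor guards
#' against degenerate (zero-residual) data.
#'
#' @inheritParams neg_log_likelihood
#' @param sigma_floor Lower bound applied to the profile estimate.
#' @return Named numeric vector of sigma estimates, one per drug with data.
#' @export
profile_sigma <- function(params, arms,
                          registry = default_drug_registry(),
                          scale = c("log10", "linear"),
                          sigma_floor = 1e-6) {
  scale <- match.arg(scale)
  .check_arms(arms)
  yhat <- .model_means(arms, params, registry, scale)
  r2n <- arms$n_subjects * (arms$observed - yhat)^2
  out <- vapply(split(r2n, arms$drug_id), mean, numeric(1))
  pmax(sqrt(out), sigma_floor)
}

# Minimal structural validation used by the likelihood machinery.
.check_arms <- function(arms) {
  needed <- c("drug_id", "endpoint", "observed", "n_subjects", "cavg_ng_ml")
  missing <- setdiff(needed, names(arms))
  if (length(missing))
    stop("arms table lacks column(s): ", paste(missing, collapse = ", "))
  if (nrow(arms) == 0L) stop("arms table is empty")
  if (any(arms$n_subjects < 1)) stop("n_subjects must be >= 1 for every arm")
  if (any(!is.finite(arms$cavg_ng_ml)) || any(arms$cavg_ng_ml <= 0))
    stop("cavg_ng_ml must be positive for every arm")
  invisible(TRUE)
}
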