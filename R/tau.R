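#' Bivariate log-normal distribution of transducer constants
#'
#' Builds the joint distribution of (tau_PI, tau_OR) across drugs: the
#' natural logs of the fitted transducer constants form one 2-vector per
#' drug; the mean vector is the per-component mean of those logs and the
#' covariance is their sample covariance (denominator n_drugs - 1). With
#' only two drugs the 2-point sample covariance is singular and forces any
#' simulated correlation to +/-1, so the estimation uncertainty of the
#' log-tau estimates (approximately (CV%/100)^2 on the log scale) can be
#' added to the diagonal via `se_inflation`.
#'
#' @param tau_pi,tau_or Named numeric vectors of transducer constants per
#'   drug for the Pearl-Index and ovulation-rate models; the two drug sets
#'   must match and contain at least two drugs.
#' @param se_inflation Optional list with components `pi` and `or`, each a
#'   named numeric vector of standard errors of log tau per drug; their mean
#'   squares are added to the corresponding diagonal entry of the
#'   covariance. `NULL` (default) applies no inflation.
#' @return An object of class `tau_distribution` with elements `mu`
#'   (length-2 mean of log tau: PI then OR component), `sigma_mat` (2x2
#'   covariance) and `provenance`.
#' @export
build_tau_distribution <- function(tau_pi, tau_or, se_inflation = NULL) {
  if (is.null(names(tau_pi)) || is.null(names(tau_or)))
    stop("tau_pi and tau_or must be named by drug")
  if (!setequal(names(tau_pi), names(tau_or)))
    stop("tau_pi and tau_or cover different drug sets")
  if (length(tau_pi) < 2L)
    stop("at least two drugs are needed to form a covariance")
  drugs <- sort(names(tau_pi))
  if (any(tau_pi[drugs] <= 0) || any(tau_or[drugs] <= 0))
    stop("all tau values must be > 0")
  X <- cbind(pi = log(tau_pi[drugs]), or = log(tau_or[drugs]))
  mu <- colMeans(X)
  sigma_mat <- stats::cov(X)
  infl <- c(pi = 0, or = 0)
  if (!is.null(se_inflation)) {
    if (!all(c("pi", "or") %in% names(se_inflation)))
      stop("se_inflation needs components 'pi' and 'or'")
    infl <- c(pi = mean(se_inflation$pi[drugs]^2),
              or = mean(se_inflation$or[drugs]^2))
    if (any(!is.finite(infl)) || any(infl < 0))
      stop("se_inflation entries must be finite and non-negative per drug")
    sigma_mat <- sigma_mat + diag(infl)
  }
  structure(list(mu = mu, sigma_mat = sigma_mat,
                 provenance = list(tau_pi = tau_pi[drugs],
                                   tau_or = tau_or[drugs],
                                   inflation = infl)),
            class = "tau_distribution")
}

#' @export
print.tau_distribution <- function(x, ...) {
  cat("<tau_distribution>\nmu (log tau):\n"); print(x$mu)
  cat("covariance:\n"); print(x$sigma_mat)
  invisible(x)
}

# Square root of a symmetric PSD matrix via eigendecomposition, tolerating
# tiny negative eigenvalues from rounding.
.psd_sqrt <- function(S, tol = 1e-10) {
  S <- (S + t(S)) / 2
  e <- eigen(S, symmetric = TRUE)
  if (any(e$values < -tol))
    stop("covariance matrix is not positive semidefinite")
  e$vectors %*% diag(sqrt(pmax(e$values, 0)), nrow = length(e$values))
}

#' Simulate transducer-constant pairs
#'
#' Draws `n` pairs from the bivariate log-normal distribution: X ~ N(mu,
#' Sigma) on the log scale, returned as exp(X) componentwise. Reproducible
#' given `seed`.
#'
#' @param dist A [build_tau_distribution()] object.
#' @param n Number of pairs (>= 2).
#' @param seed Integer seed.
#' @return A data frame with columns `tau_pi`, `tau_or` and attributes
#'   `seed` and `n`.
#' @export
simulate_tau_pairs <- function(dist, n = 500, seed = 1L) {
  if (n < 2) stop("n must be >= 2")
  A <- .psd_sqrt(dist$sigma_mat)
  set.seed(seed)
  Z <- matrix(rnorm(2L * n), ncol = 2L)
  X <- sweep(Z %*% t(A), 2L, dist$mu, "+")
  out <- data.frame(tau_pi = exp(X[, 1]), tau_or = exp(X[, 2]))
  attr(out, "seed") <- seed
  attr(out, "n") <- n
  out
}

#' Paired t-test on simulated tau pairs
#'
#' Textbook paired t-test of tau_PI - tau_OR: mean difference, 95% CI
#' `dbar +/- t(0.975, n-1) * sd / sqrt(n)`, two-sided p. Zero-variance
#' differences are flagged (`degenerate = TRUE`) with a width-zero CI and
#' undefined p.
#'
#' @param pairs Data frame with columns `tau_pi` and `tau_or`.
#' @return List with `mean_diff`, `ci95`, `t`, `df`, `p`, `degenerate`.
#' @export
paired_t_test <- function(pairs) {
  d <- pairs$tau_pi - pairs$tau_or
  n <- length(d)
  if (n < 2) stop("need at least two pairs")
  m <- mean(d); s <- sd(d)
  if (s == 0)
    return(list(mean_diff = m, ci95 = c(m, m), t = NA_real_,
                df = n - 1L, p = NA_real_, degenerate = TRUE))
  tval <- m / (s / sqrt(n))
  list(mean_diff = m,
       ci95 = m + c(-1, 1) * qt(0.975, n - 1) * s / sqrt(n),
       t = tval, df = n - 1L,
       p = 2 * pt(-abs(tval), n - 1),
       degenerate = FALSE)
}

#' Pearson correlation with Fisher-z interval
#'
#' Sample Pearson correlation of (tau_PI, tau_OR) with the Fisher
#' z-transform 95% CI `tanh(atanh(r) +/- z(0.975)/sqrt(n-3))` and the
#' two-sided p-value from `t = r * sqrt((n-2)/(1-r^2))`.
#'
#' @param pairs Data frame with columns `tau_pi` and `tau_or`; at least 4
#'   pairs and non-constant components.
#' @return List with `r`, `ci95`, `p`, `n`.
#' @export
pearson_correlation <- function(pairs) {
  x <- pairs$tau_pi; y <- pairs$tau_or
  n <- length(x)
  if (n < 4) stop("need at least four pairs for the Fisher interval")
  if (sd(x) == 0 || sd(y) == 0)
    stop("a component is constant; correlation undefined")
  r <- cor(x, y)
  if (abs(r) < 1) {
    z <- atanh(r)
    ci <- tanh(z + c(-1, 1) * qnorm(0.975) / sqrt(n - 3))
    tval <- r * sqrt((n - 2) / (1 - r^2))
    p <- 2 * pt(-abs(tval), n - 2)
  } else {
    ci <- c(r, r); p <- 0
  }
  list(r = r, ci95 = ci, p = p, n = n)
}

#' Tau correlation analysis from two fits
#'
#' Convenience wrapper: pulls the transducer constants (and their log-scale
#' SEs, approximated by CV%/100) out of the PI and OR fits, builds the
#' inflated bivariate log-normal, simulates `n` pairs and runs the paired
#' t-test and Pearson correlation.
#'
#' @param fit_pi,fit_or `op_fit` objects for the two endpoints.
#' @param n Number of simulated pairs.
#' @param seed Integer seed.
#' @param inflate Add estimation uncertainty to the covariance diagonal
#'   (default `TRUE`; with two drugs the uninflated correlation is +/-1).
#' @return List with `distribution`, `pairs`, `t_test`, `correlation`.
#' @export
tau_correlation_analysis <- function(fit_pi, fit_or, n = 500, seed = 1L,
                                     inflate = TRUE) {
  pull_tau <- function(fit) {
    idx <- grep("^tau_", names(fit$estimates))
    setNames(fit$estimates[idx], sub("^tau_", "", names(fit$estimates)[idx]))
  }
  pull_se_ln <- function(fit) {
    idx <- grep("^tau_", names(fit$estimates))
    setNames(fit$cv_percent[idx] / 100,
             sub("^tau_", "", names(fit$estimates)[idx]))
  }
  tau_pi <- pull_tau(fit_pi); tau_or <- pull_tau(fit_or)
  infl <- if (inflate) list(pi = pull_se_ln(fit_pi), or = pull_se_ln(fit_or))
  dist <- build_tau_distribution(tau_pi, tau_or, se_inflation = infl)
  pairs <- simulate_tau_pairs(dist, n = n, seed = seed)
  list(distribution = dist, pairs = pairs,
       t_test = paired_t_test(pairs),
       correlation = pearson_correlation(pairs))
}
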