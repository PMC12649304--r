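test_that("weighted Gaussian NLL matches hand-computed values", {
  p <- tst_params(sigma = 0.5)
  reg <- tst_registry()
  mu3 <- operational_response(from_molar(10^3, reg$TST), "TST", p, reg)
  # residual zero: only the variance constant remains
  arms0 <- make_arms(3, mu3, 100)
  expect_equal(neg_log_likelihood(p, arms0, reg), -2.076793740349318,
               tolerance = 1e-12)
  # residual 0.5, n = 100, sigma = 0.5: constant + 100*0.25/0.5
  arms1 <- make_arms(3, mu3 + 0.5, 100)
  expect_equal(neg_log_likelihood(p, arms1, reg), 47.923206259650684,
               tolerance = 1e-12)
  # doubling n with zero residual lowers the NLL by log(2)/2 per arm
  arms2 <- make_arms(3, mu3, 200)
  expect_equal(neg_log_likelihood(p, arms2, reg) -
                 neg_log_likelihood(p, arms0, reg), -0.5 * log(2))
})

test_that("NLL is invariant to arm ordering", {
  set.seed(3)
  p <- tst_params()
  x <- seq(2, 5, length.out = 12)
  arms <- make_arms(x, runif(12, 0, 85), sample(50:500, 12))
  perm <- sample(nrow(arms))
  expect_lt(abs(neg_log_likelihood(p, arms, tst_registry()) -
                  neg_log_likelihood(p, arms[perm, ], tst_registry())), 1e-10)
})

test_that("profile sigma matches the closed form and minimises the likelihood", {
  p <- tst_params()
  reg <- tst_registry()
  mu <- operational_response(from_molar(10^c(3, 4), reg$TST), "TST", p, reg)
  # residuals (1, -1), n = (4, 9): sigma^2 = (4 + 9)/2 = 6.5
  arms <- make_arms(c(3, 4), mu + c(1, -1), c(4, 9))
  expect_equal(unname(profile_sigma(p, arms, reg)["TST"]), sqrt(6.5),
               tolerance = 1e-12)
  # zero residuals: floored, flagged degenerate scale
  arms0 <- make_arms(c(3, 4), mu, c(4, 9))
  expect_equal(unname(profile_sigma(p, arms0, reg)["TST"]), 1e-6)

  # closed form agrees with numeric 1-D minimisation of the NLL over sigma
  set.seed(5)
  for (i in 1:5) {
    arms_r <- make_arms(c(2.5, 3, 3.5, 4), mu <- runif(4, 0, 85),
                        sample(20:200, 4))
    s_hat <- unname(profile_sigma(p, arms_r, reg)["TST"])
    f <- function(s) {
      p2 <- p; p2$sigma <- c(TST = s)
      neg_log_likelihood(p2, arms_r, reg)
    }
    s_num <- stats::optimize(f, c(1e-4, 1e3), tol = 1e-10)$minimum
    expect_equal(s_hat, s_num, tolerance = 1e-6)
    expect_lte(f(s_hat), min(f(s_hat * 1.01), f(s_hat * 0.99)))
  }
})

test_that("noiseless data is recovered exactly and NLL at truth matches the direct evaluation", {
  reg <- tst_registry()
  truth <- tst_params(tau = 3, hill = 8)
  arms <- noiseless_arms(seq(2, 5, length.out = 12), truth, 100, reg)
  fit <- fit_operational(arms, registry = reg)
  expect_true(fit$converged)
  expect_equal(unname(fit$estimates["tau_TST"]), 3, tolerance = 1e-3)
  expect_equal(unname(fit$estimates["hill"]), 8, tolerance = 1e-3)
  # fixing the free parameters at the fit and evaluating the NLL directly
  p_hat <- tst_params(tau = fit$estimates[["tau_TST"]],
                      hill = fit$estimates[["hill"]],
                      sigma = fit$estimates[["sigma_TST"]])
  expect_equal(-fit$loglik, neg_log_likelihood(p_hat, arms, reg),
               tolerance = 1e-8)
})

test_that("Emax fit recovers a known IC50 and reports Wald summaries coherently", {
  p <- emax_params(85, 1, ic50 = 2)
  cavg <- c(0.25, 0.5, 1, 2, 4, 8, 16)
  arms <- data.frame(study_id = "s", arm_id = paste0("a", seq_along(cavg)),
                     drug_id = "TST", dose_ug = NA_real_, ee_dose_ug = NA_real_,
                     endpoint = "PI", observed = emax_response(cavg, p),
                     n_subjects = 100, cavg_ng_ml = cavg)
  fit <- fit_emax(arms)
  expect_true(fit$converged)
  expect_equal(unname(fit$estimates["ic50"]), 2, tolerance = 1e-3)
  # CV% identity and CI ordering on a noisy converged fit
  set.seed(9)
  arms$observed <- emax_response(cavg, p) + rnorm(7, 0, 0.05)
  fitn <- fit_emax(arms)
  expect_true(fitn$converged)
  ok <- is.finite(fitn$se)
  expect_equal(fitn$cv_percent[ok],
               100 * fitn$se[ok] / fitn$estimates[ok])
  expect_true(all(fitn$ci95[ok, "low"] <= fitn$estimates[ok] &
                    fitn$estimates[ok] <= fitn$ci95[ok, "high"]))
})

test_that("Emax MLE agrees with an exhaustive IC50 grid search", {
  p <- emax_params(85, 1, ic50 = 2)
  cavg <- c(0.25, 0.5, 1, 2, 4, 8, 16)
  set.seed(21)
  y <- emax_response(cavg, p) + rnorm(7, 0, 0.5)
  arms <- data.frame(study_id = "s", arm_id = paste0("a", seq_along(cavg)),
                     drug_id = "TST", dose_ug = NA_real_, ee_dose_ug = NA_real_,
                     endpoint = "PI", observed = y, n_subjects = 50,
                     cavg_ng_ml = cavg)
  n <- arms$n_subjects; J <- length(cavg)
  ic50_grid <- exp(seq(log(0.05), log(50), length.out = 2001))
  nll <- vapply(ic50_grid, function(ic) {
    mu <- 85 * (1 - cavg / (ic + cavg))
    s2 <- mean(n * (y - mu)^2)
    J / 2 * log(2 * pi * s2) + J / 2 - 0.5 * sum(log(n))
  }, numeric(1))
  best <- ic50_grid[which.min(nll)]
  fit <- fit_emax(arms)
  step <- diff(log(ic50_grid))[1]
  expect_lt(abs(log(fit$estimates[["ic50"]]) - log(best)), step)
})

test_that("Wald intervals cover the generating tau at roughly nominal rate", {
  reg <- tst_registry()
  truth <- tst_params(tau = 3, hill = 8, sigma = 0.5)
  x <- seq(2, 5, length.out = 20)
  hits <- 0L; total <- 0L
  for (rep in 1:200) {
    d <- synth_design(list(TST = x), n_per_arm = 100, true_params = truth,
                      seed = 1000L + rep)
    arms <- generate_arms(d, reg)
    fit <- fit_operational(arms, registry = reg, hill = 8,
                           starts = cbind(tau = c(1, 3, 10), hill = 8))
    if (!isTRUE(fit$converged) || !is.finite(fit$se[["tau_TST"]])) next
    total <- total + 1L
    if (fit$ci95["tau_TST", "low"] <= 3 && 3 <= fit$ci95["tau_TST", "high"])
      hits <- hits + 1L
  }
  expect_gt(total, 180)
  coverage <- hits / total
  expect_gte(coverage, 0.90)
  expect_lte(coverage, 0.99)
})
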