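test_that("log-tau distribution construction matches hand-computed moments", {
  # published transducer constants: mean of natural logs per component
  d <- build_tau_distribution(tau_pi = c(LNG = 3.046, DRSP = 2.602),
                              tau_or = c(LNG = 2.172, DRSP = 1.867))
  expect_equal(unname(d$mu), c(1.0350548172816416, 0.6999906333156374),
               tolerance = 1e-12)
  # two points force a perfectly correlated covariance
  r_off <- d$sigma_mat[1, 2] / sqrt(d$sigma_mat[1, 1] * d$sigma_mat[2, 2])
  expect_equal(abs(r_off), 1)
  # identical taus across drugs: zero covariance, mu = the common logs
  d0 <- build_tau_distribution(c(A = 2, B = 2), c(A = 1.5, B = 1.5))
  expect_equal(unname(d0$mu), log(c(2, 1.5)))
  expect_equal(unname(d0$sigma_mat), matrix(0, 2, 2))
  # zero inflation equals the plain construction
  dz <- build_tau_distribution(c(LNG = 3.046, DRSP = 2.602),
                               c(LNG = 2.172, DRSP = 1.867),
                               se_inflation = list(pi = c(LNG = 0, DRSP = 0),
                                                   or = c(LNG = 0, DRSP = 0)))
  expect_equal(dz$sigma_mat, d$sigma_mat)
  # inflation adds to the diagonal only
  di <- build_tau_distribution(c(LNG = 3.046, DRSP = 2.602),
                               c(LNG = 2.172, DRSP = 1.867),
                               se_inflation = list(pi = c(LNG = 0.1, DRSP = 0.1),
                                                   or = c(LNG = 0.2, DRSP = 0.2)))
  expect_equal(diag(di$sigma_mat), diag(d$sigma_mat) + c(0.01, 0.04),
               ignore_attr = TRUE)
  expect_equal(di$sigma_mat[1, 2], d$sigma_mat[1, 2])
  expect_error(build_tau_distribution(c(A = 1, B = 2), c(A = 1, C = 2)),
               "drug sets")
  expect_error(build_tau_distribution(c(A = 1), c(A = 1)), "two drugs")
})

test_that("pair simulation is seeded, degenerate-exact and moment-consistent", {
  d <- build_tau_distribution(c(A = 2, B = 2), c(A = 1.5, B = 1.5))
  p1 <- simulate_tau_pairs(d, n = 50, seed = 4)
  expect_true(all(p1$tau_pi == 2) && all(p1$tau_or == 1.5))
  d2 <- structure(list(mu = c(0.2, -0.1),
                       sigma_mat = diag(c(0.09, 0.04))),
                  class = "tau_distribution")
  pa <- simulate_tau_pairs(d2, n = 1000, seed = 7)
  pb <- simulate_tau_pairs(d2, n = 1000, seed = 7)
  expect_identical(pa, pb)
  big <- simulate_tau_pairs(d2, n = 100000, seed = 8)
  expect_lt(abs(mean(log(big$tau_pi)) - 0.2), 3 * 0.3 / sqrt(100000))
  expect_lt(abs(mean(log(big$tau_or)) + 0.1), 3 * 0.2 / sqrt(100000))
  expect_true(all(big$tau_pi > 0) && all(big$tau_or > 0))
  bad <- structure(list(mu = c(0, 0),
                        sigma_mat = matrix(c(1, 2, 2, 1), 2)),
                   class = "tau_distribution")
  expect_error(simulate_tau_pairs(bad, 10, 1), "positive semidefinite")
})

test_that("paired t-test matches the textbook formula", {
  pairs <- data.frame(tau_pi = c(2, 4, 6), tau_or = c(1, 2, 3))
  res <- paired_t_test(pairs)
  expect_equal(res$mean_diff, 2)
  expect_equal(res$t, 3.4641016151377544, tolerance = 1e-12)
  expect_equal(res$df, 2L)
  expect_equal(res$p, 0.07417990022744857, tolerance = 1e-12)
  expect_equal(res$ci95, c(-0.48413771175033027, 4.48413771175033),
               tolerance = 1e-10)
  # cross-check against the reference implementation
  tt <- t.test(pairs$tau_pi, pairs$tau_or, paired = TRUE)
  expect_equal(res$t, unname(tt$statistic))
  expect_equal(res$p, tt$p.value)
  expect_equal(res$ci95, as.numeric(tt$conf.int))
  # antisymmetry under component swap
  res2 <- paired_t_test(data.frame(tau_pi = pairs$tau_or,
                                   tau_or = pairs$tau_pi))
  expect_equal(res2$mean_diff, -res$mean_diff)
  expect_equal(res2$t, -res$t)
  # degenerate: identical components flagged with width-zero CI
  resd <- paired_t_test(data.frame(tau_pi = c(3, 3), tau_or = c(1, 1)))
  expect_true(resd$degenerate)
  expect_equal(resd$ci95, c(2, 2))
  expect_true(is.na(resd$p))
})

test_that("Pearson correlation matches cor.test and handles collinearity", {
  set.seed(31)
  pairs <- data.frame(tau_pi = rlnorm(60), tau_or = rlnorm(60))
  res <- pearson_correlation(pairs)
  ct <- cor.test(pairs$tau_pi, pairs$tau_or)
  expect_equal(res$r, unname(ct$estimate))
  expect_equal(res$p, ct$p.value)
  expect_equal(res$ci95, as.numeric(ct$conf.int), tolerance = 1e-10)
  # Fisher interval contains r with endpoints inside (-1, 1)
  for (i in 1:20) {
    pp <- data.frame(tau_pi = rlnorm(20), tau_or = rlnorm(20))
    rr <- pearson_correlation(pp)
    expect_true(rr$ci95[1] < rr$r && rr$r < rr$ci95[2])
    expect_true(all(rr$ci95 > -1 & rr$ci95 < 1))
  }
  x <- 1:10
  expect_equal(pearson_correlation(data.frame(tau_pi = x, tau_or = 2 * x))$r, 1)
  expect_equal(pearson_correlation(data.frame(tau_pi = x, tau_or = -x))$r, -1)
  expect_error(pearson_correlation(data.frame(tau_pi = rep(1, 10),
                                              tau_or = x)), "constant")
})

test_that("simulated pairs recover the analytic log-normal correlation", {
  # log-scale correlation 0.5 with sdlog 0.5 per component gives a
  # natural-scale Pearson correlation (e^0.125 - 1)/(e^0.25 - 1)
  r_true <- (exp(0.125) - 1) / (exp(0.25) - 1)
  d <- structure(list(mu = c(1, 0.7),
                      sigma_mat = matrix(c(0.25, 0.125, 0.125, 0.25), 2)),
                 class = "tau_distribution")
  rs <- vapply(1:50, function(s)
    pearson_correlation(simulate_tau_pairs(d, n = 500, seed = s))$r,
    numeric(1))
  expect_lt(abs(mean(rs) - r_true), 0.05)
})

test_that("fit-to-correlation wrapper inflates away the two-point degeneracy", {
  fake_fit <- function(tau, cv) {
    est <- setNames(tau, paste0("tau_", names(tau)))
    structure(list(estimates = est,
                   cv_percent = setNames(cv, names(est))),
              class = "op_fit")
  }
  fit_pi <- fake_fit(c(LNG = 3.046, DRSP = 2.602), c(8.84, 9.59))
  fit_or <- fake_fit(c(LNG = 2.172, DRSP = 1.867), c(0.19, 0.26))
  res <- tau_correlation_analysis(fit_pi, fit_or, n = 500, seed = 2)
  expect_equal(nrow(res$pairs), 500)
  expect_lt(abs(res$correlation$r), 1)
  expect_true(res$t_test$mean_diff > 0)  # tau_PI exceeds tau_OR on average
  # uninflated two-drug construction is perfectly correlated on the log scale
  res0 <- tau_correlation_analysis(fit_pi, fit_or, n = 200, seed = 2,
                                   inflate = FALSE)
  expect_equal(abs(cor(log(res0$pairs$tau_pi), log(res0$pairs$tau_or))), 1,
               tolerance = 1e-9)
})
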