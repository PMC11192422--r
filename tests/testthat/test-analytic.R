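test_that("replication accuracy follows the exponential-weighting form", {
  p <- default_rates()
  expect_equal(dna_accuracy(p, 0), 0.5)                     # no proofreading
  peq <- suppressWarnings(kpr_rates(k_minus1p = 1))
  expect_equal(dna_accuracy(peq, 7), 0.5)                   # identical rates
  # equal unbinding rates: exponentials cancel for any tau
  pk2 <- suppressWarnings(kpr_rates(k1 = 0.3, k1p = 0.1, k_minus1p = 1))
  expect_equal(dna_accuracy(pk2, 4.2), 0.3 / 0.4)
  expect_equal(dna_accuracy(p, 5), 1 / (1 + exp(-5)), tolerance = 1e-12)
  expect_error(dna_accuracy(kpr_rates(k1 = 0, k1p = 0), 1), "k1")
  # monotone nondecreasing in tau when the incorrect substrate is weaker
  taus <- seq(0, 10, by = 0.25)
  expect_false(is.unsorted(dna_accuracy(p, taus)))
})

test_that("replication mean first-passage time is exact and well-approximated", {
  p <- default_rates()
  expect_equal(dna_mfpt(p, 0), 1 / (p$k1 + p$k1p))   # instant completion
  expect_equal(dna_mfpt(p, 5), 1694.332, tolerance = 1e-4)
  rel <- abs(dna_mfpt(p, 5, approximate = TRUE) - dna_mfpt(p, 5)) /
    dna_mfpt(p, 5)
  expect_lt(rel, 0.01)
})

test_that("one-shot operating point and its ROC area are consistent", {
  p <- default_rates()
  op <- oneshot_operating_point(p, 3)
  expect_equal(op$sensitivity, exp(-3))
  expect_equal(op$specificity, 1 - exp(-6))
  expect_equal(op$auc, 2 / 3)
  peq <- suppressWarnings(kpr_rates(k_minus1p = 1))
  expect_equal(oneshot_operating_point(peq, 1)$auc, 0.5)

  # adaptive quadrature of sensitivity d(specificity) over tau
  integrand <- function(tau)
    exp(-p$k_minus1 * tau) * p$k_minus1p * exp(-p$k_minus1p * tau)
  auc_num <- integrate(integrand, 0, Inf, rel.tol = 1e-10)$value
  expect_equal(auc_num, op$auc, tolerance = 1e-6)
})

test_that("multi-shot operating point interpolates the one-shot case", {
  p <- default_rates()
  m1 <- multishot_operating_point(p, 3, 1)
  o1 <- oneshot_operating_point(p, 3)
  expect_equal(m1$sensitivity, o1$sensitivity)
  expect_equal(m1$specificity, o1$specificity)

  m0 <- multishot_operating_point(p, 0, 17)
  expect_equal(m0$sensitivity, 1)
  expect_equal(m0$specificity, 0)
  expect_equal(m0$accuracy, 0.5)

  # Monte-Carlo oracle: N Bernoulli cycles per contact
  set.seed(21)
  nmc <- 1e5
  sens_mc <- mean(rbinom(nmc, 63, exp(-3)) > 0)
  spec_mc <- mean(rbinom(nmc, 63, exp(-6)) == 0)
  m63 <- multishot_operating_point(p, 3, 63)
  expect_lt(abs(m63$sensitivity - sens_mc), 3 * sqrt(0.04 / nmc) + 1e-3)
  expect_lt(abs(m63$specificity - spec_mc), 3 * sqrt(0.15 / nmc) + 1e-3)
  expect_equal(m63$accuracy, 0.9077, tolerance = 1e-3)
})

test_that("optimal cycle number maximizes the exact accuracy", {
  p <- default_rates()
  des <- fpt_optimal_design(p, 3)
  expect_equal(des$N_continuous, 3 * exp(3) / (1 - exp(-3)), tolerance = 1e-12)
  bf <- brute_force_design(p, 3)
  # the closed-form continuous optimum (~63.4) slightly overshoots the
  # exact integer argmax
  expect_identical(des$N_opt, 62L)
  expect_identical(des$N_opt, as.integer(bf$N_opt))
  expect_equal(des$A_opt, bf$A_opt, tolerance = 1e-15)
  expect_equal(des$T_opt, des$N_opt / p$k1)

  # maximal accuracy is nondecreasing in tau and approaches 1
  taus <- c(1, 2, 3, 5, 8, 12)
  aopt <- vapply(taus, function(tt) fpt_optimal_design(p, tt)$A_opt,
                 numeric(1))
  expect_false(is.unsorted(aopt))
  expect_gt(aopt[length(aopt)], 0.999)

  # the large-tau asymptote bounds the inaccuracy up to a vanishing factor
  for (tt in c(5, 7, 10)) {
    d <- fpt_optimal_design(p, tt)
    expect_lt(1 - d$A_opt, d$inaccuracy_asymptote * 1.2)
  }
  expect_warning(fpt_optimal_design(suppressWarnings(kpr_rates(k_minus1p = 1)),
                                    3),
                 "asymptotics")
})

test_that("count moments match the occupancy closed form", {
  p <- default_rates()
  expect_equal(unname(product_count_moments(kpr_rates(k_p = 0), 3, 1000, 1)),
               c(0, 0))
  m1 <- product_count_moments(p, 3, 1000, 1)
  expect_equal(m1[["mean"]], 1000 * (0.1 / 1.1) * exp(-3), tolerance = 1e-12)
  expect_equal(m1[["mean"]], 4.5261, tolerance = 1e-4)
  expect_equal(m1[["variance"]], m1[["mean"]])
  m0 <- product_count_moments(p, 3, 1000, 0)
  expect_equal(m0[["mean"]], 0.11804, tolerance = 1e-4)
})

test_that("Gaussian-surrogate threshold analysis is internally consistent", {
  p <- default_rates()
  g <- gaussian_threshold_analysis(p, 3, 1e5)
  expect_equal(g$P_th_opt, sqrt(g$mu1 * g$mu0), tolerance = 1e-12)
  expect_equal(g$P_th_opt, 73.09, tolerance = 1e-3)

  # integer-grid maximization oracle for the optimal threshold, run at a
  # contact time where the optimum is numerically sharp (at very large T
  # the accuracy plateaus at 1 to machine precision)
  acc_at <- function(pth)
    gaussian_threshold_analysis(p, 3, 5000, P_th = pth)$accuracy
  grid_acc <- vapply(1:40, acc_at, numeric(1))
  g5k <- gaussian_threshold_analysis(p, 3, 5000, optimize_threshold = TRUE)
  expect_lt(abs(which.max(grid_acc) - g5k$P_th_opt), 2)
  expect_lt(abs(g5k$P_th_exact - which.max(grid_acc)), 1)
  # the refined threshold only improves on the zeroth-order line
  expect_gte(acc_at(g5k$P_th_exact), g5k$accuracy - 1e-12)

  # capacity estimate at the defaults, and the accuracy identity
  g1000 <- gaussian_threshold_analysis(p, 3, 1000)
  expect_equal(g1000$C_hat, 0.9628, tolerance = 1e-4)
  expect_equal(g1000$accuracy, g1000$C_hat, tolerance = 1e-15)

  # degenerate and invalid configurations
  peq <- suppressWarnings(kpr_rates(k_minus1p = 1))
  expect_equal(gaussian_threshold_analysis(peq, 2, 500)$C_hat, 0.5)
  expect_error(gaussian_threshold_analysis(kpr_rates(k1p = 0), 3, 1000),
               "mu0")
  rev <- suppressWarnings(kpr_rates(k1 = 0.01, k1p = 0.5, k_minus1p = 1))
  expect_error(gaussian_threshold_analysis(rev, 1, 1000), "mu1")
})

test_that("capacity-maximizing processing time is T-independent and matches
           the stationarity closed form", {
  p <- default_rates()
  tnum <- optimal_processing_time_product(p, T_check = c(1e3, 1e6),
                                          tol = 1e-8)
  tcf <- optimal_processing_time_product(p, method = "closed_form")
  expect_equal(tnum, tcf, tolerance = 1e-6)
  expect_equal(tnum, 0.7397, tolerance = 1e-3)

  # near-degenerate limit: k_minus1p -> k_minus1 with matched occupancy
  # gives tau_opt -> 2/k_minus1
  plim <- suppressWarnings(kpr_rates(k1p = 0.1001, k_minus1p = 1.001))
  expect_equal(optimal_processing_time_product(plim), 2, tolerance = 1e-2)

  expect_error(optimal_processing_time_product(
    suppressWarnings(kpr_rates(k_minus1p = 1))), "k_minus1p")
})

test_that("nested effective rates reproduce the quasi-steady-state algebra", {
  p <- default_rates()
  er <- nested_effective_rates(p, 3)
  expect_equal(er$ktilde_f, 4.5261e-3, tolerance = 1e-4)
  expect_equal(er$ktilde_f_p, 1.1804e-4, tolerance = 1e-4)
  occ <- occupancy_factors(p)
  expect_equal(er$ktilde_f / er$ktilde_f_p,
               (occ[["K"]] / occ[["K_p"]]) * exp((2 - 1) * 3),
               tolerance = 1e-12)
  expect_equal(er$ktilde_f / er$ktilde_f_p, 38.35, tolerance = 1e-3)
})
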