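# Closed-form accuracy, speed and capacity expressions for the deterministic
# processing-time model, with numerical optimization where the printed
# asymptotic forms are ambiguous.

#' Replication accuracy of the two-branch fidelity race
#'
#' Probability that the correct product is formed first when both substrates
#' compete for one enzyme with a deterministic processing time `tau`:
#' `k1 exp(-k_minus1 tau) / (k1 exp(-k_minus1 tau) + k1p exp(-k_minus1p tau))`.
#' The accuracy responds sigmoidally to the unbinding-rate difference, the
#' hallmark of proofreading.
#'
#' @param params a [kpr_rates()] object.
#' @param tau deterministic processing time (>= 0).
#' @return Probability that the correct product wins.
#' @examples
#' dna_accuracy(kpr_rates(), tau = 5)    # ~ 1 / (1 + exp(-5))
#' @export
dna_accuracy <- function(params, tau) {
  stopifnot(inherits(params, "kpr_rates"), is.numeric(tau), all(tau >= 0))
  a <- params$k1 * exp(-params$k_minus1 * tau)
  b <- params$k1p * exp(-params$k_minus1p * tau)
  if (any(a + b == 0))
    stop("k1 = k1p = 0: no binding, accuracy undefined", call. = FALSE)
  a / (a + b)
}

#' Mean first-passage time to either replication product
#'
#' Exact mean completion time of the two-branch fidelity race,
#' `(k1/k_minus1 (1 - exp(-k_minus1 tau)) + k1p/k_minus1p (1 - exp(-k_minus1p tau)) + 1) /
#'  (k1 exp(-k_minus1 tau) + k1p exp(-k_minus1p tau))`,
#' or, with `approximate = TRUE`, the large-discrimination approximation
#' `exp(k_minus1 tau)/k1 (k1/k_minus1 + k1p/k_minus1p + 1)` valid when the
#' correct completion flux dominates.
#'
#' @inheritParams dna_accuracy
#' @param approximate return the approximate form instead of the exact one.
#' @return Mean first-passage time to absorption.
#' @examples
#' dna_mfpt(kpr_rates(), tau = 5)    # ~ 1694
#' @export
dna_mfpt <- function(params, tau, approximate = FALSE) {
  stopifnot(inherits(params, "kpr_rates"), is.numeric(tau), all(tau >= 0))
  if (approximate)
    return(exp(params$k_minus1 * tau) / params$k1 *
             (params$k1 / params$k_minus1 + params$k1p / params$k_minus1p + 1))
  denom <- params$k1 * exp(-params$k_minus1 * tau) +
    params$k1p * exp(-params$k_minus1p * tau)
  if (any(denom == 0))
    stop("zero completion flux: mean first-passage time diverges",
         call. = FALSE)
  (params$k1 / params$k_minus1 * (1 - exp(-params$k_minus1 * tau)) +
     params$k1p / params$k_minus1p * (1 - exp(-params$k_minus1p * tau)) + 1) /
    denom
}

#' One-shot operating point and ROC area
#'
#' For a single binding cycle with deterministic processing time `tau`, the
#' activation-based classifier has sensitivity `exp(-k_minus1 tau)` and
#' specificity `1 - exp(-k_minus1p tau)`. Traced over `tau`, the family of
#' classifiers has area under the ROC curve
#' `k_minus1p / (k_minus1 + k_minus1p)`, independent of `tau`.
#'
#' @inheritParams dna_accuracy
#' @return List with `sensitivity`, `specificity`, `auc`.
#' @examples
#' oneshot_operating_point(kpr_rates(), tau = 3)$auc   # 2/3
#' @export
oneshot_operating_point <- function(params, tau) {
  stopifnot(inherits(params, "kpr_rates"), is.numeric(tau), all(tau >= 0))
  list(sensitivity = exp(-params$k_minus1 * tau),
       specificity = 1 - exp(-params$k_minus1p * tau),
       auc = params$k_minus1p / (params$k_minus1 + params$k_minus1p))
}

#' Multi-shot operating point
#'
#' Over `N` independent binding cycles the contact activates unless every
#' cycle fails: sensitivity `1 - (1 - exp(-k_minus1 tau))^N`, specificity
#' `(1 - exp(-k_minus1p tau))^N`, and balanced accuracy their mean.
#'
#' @inheritParams dna_accuracy
#' @param N number of binding cycles (>= 1).
#' @return List with `sensitivity`, `specificity`, `accuracy`.
#' @examples
#' multishot_operating_point(kpr_rates(), tau = 3, N = 63)$accuracy  # ~0.908
#' @export
multishot_operating_point <- function(params, tau, N) {
  stopifnot(inherits(params, "kpr_rates"), is.numeric(tau), all(tau >= 0),
            is.numeric(N), all(N >= 1))
  sens <- 1 - (1 - exp(-params$k_minus1 * tau))^N
  spec <- (1 - exp(-params$k_minus1p * tau))^N
  list(sensitivity = sens, specificity = spec,
       accuracy = (sens + spec) / 2)
}

# continuous-N optimum of the multi-shot accuracy
.n_opt_continuous <- function(params, tau) {
  dk <- params$k_minus1p - params$k_minus1
  dk * tau * exp(params$k_minus1 * tau) / (1 - exp(-dk * tau))
}

#' Optimal number of binding cycles for activation-based discrimination
#'
#' For a fixed processing time `tau`, the balanced accuracy of the
#' multi-shot activation classifier is maximized over the number of binding
#' cycles `N`. The accuracy is unimodal in `N`, so the exact real-valued
#' maximizer is located numerically and resolved to the better of its two
#' integer neighbors; the closed-form approximation
#' `N ~ (k_minus1p - k_minus1) tau exp(k_minus1 tau) / (1 - exp(-(k_minus1p - k_minus1) tau))`
#' is reported alongside as `N_continuous` (its integer neighbors need not
#' contain the exact argmax). The maximal accuracy is the exact accuracy at
#' the integer optimum. The large-`tau` inaccuracy asymptote is
#' `1 - A ~ (k_minus1p - k_minus1) tau exp(-(k_minus1p - k_minus1) tau) / 2`.
#'
#' @inheritParams dna_accuracy
#' @return An object of class `kpr_design`: list with `N_opt` (integer),
#'   `A_opt`, `T_opt = N_opt/k1`, `inaccuracy_asymptote`, and the
#'   continuous optimum `N_continuous`.
#' @examples
#' fpt_optimal_design(kpr_rates(), tau = 3)   # N_opt = 62, A_opt ~ 0.908
#' @export
fpt_optimal_design <- function(params, tau) {
  stopifnot(inherits(params, "kpr_rates"), is.numeric(tau), length(tau) == 1L,
            tau > 0)
  if (params$k_minus1p <= params$k_minus1)
    warning("k_minus1p <= k_minus1: the large-tau asymptotics assume the ",
            "incorrect substrate unbinds faster", call. = FALSE)
  n_cont <- .n_opt_continuous(params, tau)
  if (!is.finite(n_cont) || n_cont < 1) n_cont <- 1
  # The closed-form continuous optimum is approximate (its integer
  # neighbors need not bracket the exact argmax), so maximize the exact
  # accuracy over real N and resolve to the better of floor/ceiling; the
  # accuracy is unimodal in N.
  n_star <- stats::optimize(function(N)
    multishot_operating_point(params, tau, N)$accuracy,
    c(1, 4 * n_cont + 10), maximum = TRUE, tol = 1e-6)$maximum
  cand <- unique(pmax(1, c(floor(n_star), ceiling(n_star))))
  acc <- vapply(cand, function(N)
    multishot_operating_point(params, tau, N)$accuracy, numeric(1))
  best <- which.max(acc)
  dk <- params$k_minus1p - params$k_minus1
  structure(list(N_opt = as.integer(cand[best]), A_opt = acc[best],
                 T_opt = cand[best] / params$k1,
                 inaccuracy_asymptote = dk * tau * exp(-dk * tau) / 2,
                 N_continuous = n_cont),
            class = "kpr_design")
}

#' @export
print.kpr_design <- function(x, ...) {
  cat(sprintf("Optimal activation-based design: N_opt = %d (continuous %.4g)\n",
              x$N_opt, x$N_continuous))
  cat(sprintf("  A_opt = %.6f, T_opt = %.6g, large-tau inaccuracy asymptote = %.3g\n",
              x$A_opt, x$T_opt, x$inaccuracy_asymptote))
  invisible(x)
}

#' Steady-state product-count moments
#'
#' Poisson-surrogate moments of the product count `P(T)`: mean and variance
#' both equal `k_p T K exp(-k_minus1 tau)` for the cognate substrate
#' (`K = k1/(k1 + k_minus1)`), with the primed analog for the noncognate
#' one. The identity variance = mean is the slow-production steady-state
#' surrogate; at fast production the simulated counts are overdispersed by
#' product bursts from individual activation periods (see the package
#' vignette).
#'
#' @inheritParams dna_accuracy
#' @param T contact duration (> 0).
#' @param xi substrate label, 1 (cognate) or 0 (noncognate).
#' @return Named vector with `mean` and `variance`.
#' @examples
#' product_count_moments(kpr_rates(), tau = 3, T = 1000, xi = 1)  # ~4.53
#' @export
product_count_moments <- function(params, tau, T, xi = 1) {
  stopifnot(inherits(params, "kpr_rates"), is.numeric(tau), all(tau >= 0),
            is.numeric(T), all(T > 0), xi %in% c(0, 1))
  occ <- occupancy_factors(params)
  mu <- if (xi == 1) params$k_p * T * occ[["K"]] * exp(-params$k_minus1 * tau)
        else params$k_p * T * occ[["K_p"]] * exp(-params$k_minus1p * tau)
  c(mean = mu, variance = mu)
}

#' Gaussian-surrogate analysis of the product-count threshold classifier
#'
#' Approximates the conditional count distributions by Gaussians with
#' matched (Poisson-surrogate) mean and variance `mu1`, `mu0` and evaluates
#' the threshold classifier `X = 1{P(T) >= P_th}`:
#' sensitivity `1/2 + erf((mu1 - P_th)/sqrt(2 mu1))/2` and specificity
#' `1/2 + erf((P_th - mu0)/sqrt(2 mu0))/2`. When `P_th` is omitted it is set
#' to the accuracy-optimal zeroth-order threshold `sqrt(mu1 mu0)` (the
#' geometric mean of the two expected counts), at which the accuracy reduces
#' exactly to the capacity estimate
#' `C_hat = 1/2 + erf((sqrt(mu1) - sqrt(mu0))/sqrt(2))/2`.
#'
#' @inheritParams product_count_moments
#' @param P_th threshold on the product count; default is the zeroth-order
#'   optimum `sqrt(mu1 mu0)`.
#' @param optimize_threshold also report the numerical maximizer of the
#'   Gaussian-surrogate accuracy over a real-valued threshold (field
#'   `P_th_exact`), which refines the zeroth-order form at small `T`.
#' @return An object of class `kpr_gauss`: list with occupancy factors `K`,
#'   `K_p`, moments `mu1`, `mu0`, the threshold used `P_th`, the
#'   zeroth-order optimum `P_th_opt`, `sensitivity`, `specificity`,
#'   `accuracy`, the capacity estimate `C_hat`, and the capacity-maximizing
#'   processing time `tau_P_opt` (see
#'   [optimal_processing_time_product()]).
#' @examples
#' gaussian_threshold_analysis(kpr_rates(), tau = 3, T = 1000)$C_hat  # ~0.963
#' @export
gaussian_threshold_analysis <- function(params, tau, T, P_th = NULL,
                                        optimize_threshold = FALSE) {
  stopifnot(inherits(params, "kpr_rates"), is.numeric(tau),
            length(tau) == 1L, tau >= 0, is.numeric(T), length(T) == 1L,
            T > 0)
  occ <- occupancy_factors(params)
  mu1 <- params$k_p * T * occ[["K"]] * exp(-params$k_minus1 * tau)
  mu0 <- params$k_p * T * occ[["K_p"]] * exp(-params$k_minus1p * tau)
  if (mu0 == 0)
    stop("mu0 = 0: Gaussian surrogate undefined; estimate the channel by ",
         "simulation instead", call. = FALSE)
  if (mu1 < mu0)
    stop("mu1 < mu0: the threshold classifier assumes the cognate ",
         "substrate yields more products on average", call. = FALSE)
  erf <- function(x) 2 * stats::pnorm(x * sqrt(2)) - 1
  p_opt <- sqrt(mu1 * mu0)
  p_use <- if (is.null(P_th)) p_opt else P_th
  sens <- 0.5 + 0.5 * erf((mu1 - p_use) / sqrt(2 * mu1))
  spec <- 0.5 + 0.5 * erf((p_use - mu0) / sqrt(2 * mu0))
  out <- list(K = occ[["K"]], K_p = occ[["K_p"]], mu1 = mu1, mu0 = mu0,
              P_th = p_use, P_th_opt = p_opt, sensitivity = sens,
              specificity = spec, accuracy = (sens + spec) / 2,
              C_hat = 0.5 + 0.5 * erf((sqrt(mu1) - sqrt(mu0)) / sqrt(2)),
              tau_P_opt = if (params$k_minus1p > params$k_minus1)
                optimal_processing_time_product(params) else NA_real_)
  if (optimize_threshold) {
    acc <- function(p)
      0.5 + 0.25 * (erf((mu1 - p) / sqrt(2 * mu1)) +
                      erf((p - mu0) / sqrt(2 * mu0)))
    out$P_th_exact <- stats::optimize(acc, c(mu0, mu1),
                                      maximum = TRUE, tol = 1e-8)$maximum
  }
  structure(out, class = "kpr_gauss")
}

#' @export
print.kpr_gauss <- function(x, ...) {
  cat(sprintf("Gaussian-surrogate count channel: mu1 = %.4g, mu0 = %.4g\n",
              x$mu1, x$mu0))
  cat(sprintf("  P_th = %.4g (zeroth-order optimum %.4g)\n", x$P_th,
              x$P_th_opt))
  cat(sprintf("  sensitivity %.4f, specificity %.4f, accuracy %.4f\n",
              x$sensitivity, x$specificity, x$accuracy))
  cat(sprintf("  capacity estimate C_hat = %.4f, tau_P_opt = %.4g\n",
              x$C_hat, x$tau_P_opt))
  invisible(x)
}

#' Capacity-maximizing processing time of the product-count strategy
#'
#' Maximizes the Gaussian-surrogate capacity estimate `C_hat(tau)` over the
#' processing time. Because `C_hat` is a monotone function of
#' `sqrt(mu1(tau)) - sqrt(mu0(tau))` and both moments are proportional to
#' `T`, the maximizer is independent of the contact time; this is verified
#' internally by maximizing at two widely separated `T` values. The
#' numerical argmax coincides with the stationarity closed form
#' `2/(k_minus1p - k_minus1) log((k_minus1p/k_minus1) sqrt(K_p/K))`,
#' available via `method = "closed_form"` as a cross-check.
#'
#' @inheritParams dna_accuracy
#' @param method `"numeric"` (argmax of the capacity estimate) or
#'   `"closed_form"` (the stationarity expression).
#' @param T_check contact times at which the numerical argmax is computed
#'   and compared.
#' @param tol agreement tolerance between the two argmaxes.
#' @return The capacity-maximizing processing time (scalar).
#' @examples
#' optimal_processing_time_product(kpr_rates())   # ~0.74 at the defaults
#' @export
optimal_processing_time_product <- function(params,
                                            method = c("numeric",
                                                       "closed_form"),
                                            T_check = c(1e3, 1e6),
                                            tol = 1e-8) {
  stopifnot(inherits(params, "kpr_rates"))
  method <- match.arg(method)
  if (params$k_minus1p <= params$k_minus1)
    stop("requires k_minus1p > k_minus1: otherwise longer processing never ",
         "helps the count strategy", call. = FALSE)
  occ <- occupancy_factors(params)
  if (method == "closed_form")
    return(2 / (params$k_minus1p - params$k_minus1) *
             log(params$k_minus1p / params$k_minus1 *
                   sqrt(occ[["K_p"]] / occ[["K"]])))
  # The estimate is monotone in sqrt(mu1) - sqrt(mu0); its stationary point
  # solves k_minus1p sqrt(mu0(tau)) = k_minus1 sqrt(mu1(tau)), located by
  # root-finding on the derivative at each check value of T.
  argmax_at <- function(T) {
    dgap <- function(tau)
      params$k_minus1p *
        sqrt(params$k_p * T * occ[["K_p"]] * exp(-params$k_minus1p * tau)) -
        params$k_minus1 *
          sqrt(params$k_p * T * occ[["K"]] * exp(-params$k_minus1 * tau))
    if (dgap(0) <= 0) return(0)  # no interior maximum: tau = 0 is optimal
    upper <- 2 / params$k_minus1
    while (dgap(upper) > 0) upper <- upper * 2
    stats::uniroot(dgap, c(0, upper), tol = tol * 1e-4)$root
  }
  opt <- vapply(T_check, argmax_at, numeric(1))
  if (max(opt) - min(opt) > tol)
    stop("capacity-maximizing tau differs across contact times; ",
         "objective not unimodal for these rates", call. = FALSE)
  mean(opt)
}

#' Effective rates of the nested proofreading chain
#'
#' Quasi-steady-state rates at which products accumulate, turning product
#' accumulation to a threshold into an outer proofreading chain:
#' `ktilde_f = k_p K exp(-k_minus1 tau)` for the cognate and
#' `ktilde_f_p = k_p K_p exp(-k_minus1p tau)` for the noncognate substrate.
#'
#' @inheritParams dna_accuracy
#' @return List with `ktilde_f` and `ktilde_f_p`.
#' @examples
#' nested_effective_rates(kpr_rates(), tau = 3)
#' @export
nested_effective_rates <- function(params, tau) {
  stopifnot(inherits(params, "kpr_rates"), is.numeric(tau), all(tau >= 0))
  occ <- occupancy_factors(params)
  list(ktilde_f = params$k_p * occ[["K"]] * exp(-params$k_minus1 * tau),
       ktilde_f_p = params$k_p * occ[["K_p"]] * exp(-params$k_minus1p * tau))
}
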