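# Domain types and parameter validation shared by every other module.

.check_rate <- function(x, name, strict_positive = FALSE) {
  if (!is.numeric(x) || length(x) != 1L || !is.finite(x))
    stop(sprintf("'%s' must be a single finite number", name), call. = FALSE)
  if (strict_positive && x <= 0)
    stop(sprintf("'%s' must be > 0", name), call. = FALSE)
  if (!strict_positive && x < 0)
    stop(sprintf("'%s' must be >= 0", name), call. = FALSE)
  as.numeric(x)
}

#' Kinetic rate constants of the two-branch proofreading scheme
#'
#' Bundles all first-order rate constants of the reduced proofreading cycle
#' for the correct (cognate) and incorrect (noncognate) substrate. The
#' incorrect substrate is assumed to unbind faster (`k_minus1p > k_minus1`);
#' a violation is reported as a warning, not an error, since every formula
#' remains evaluable.
#'
#' Unset rates are filled from the scheme's standing assumptions:
#' `k_off` (unbinding of the intermediate complex) defaults to `k_minus1`,
#' and the activated-state unbinding rates `k_minus1_star` /
#' `k_minus1p_star` default to `k_minus1` / `k_minus1p`.
#'
#' @param k1,k_minus1 binding / unbinding rate of the correct substrate
#'   (1/time); `k_minus1` must be strictly positive.
#' @param k1p,k_minus1p binding / unbinding rate of the incorrect substrate
#'   (1/time); `k_minus1p` must be strictly positive.
#' @param k_off unbinding rate of the intermediate complex; defaults to
#'   `k_minus1`.
#' @param k_minus1_star,k_minus1p_star unbinding rates of the activated
#'   complex for correct / incorrect substrate; default to `k_minus1` /
#'   `k_minus1p`.
#' @param k_p product production rate from the activated state (1/time).
#' @return An object of class `kpr_rates`: a named list of the eight rates.
#' @examples
#' p <- kpr_rates()            # the default parameter set
#' p$k_off                     # filled in as k_minus1
#' @export
kpr_rates <- function(k1 = 0.1, k_minus1 = 1, k1p = 0.1, k_minus1p = 2,
                      k_off = NULL, k_minus1_star = NULL,
                      k_minus1p_star = NULL, k_p = 1) {
  k1 <- .check_rate(k1, "k1")
  k_minus1 <- .check_rate(k_minus1, "k_minus1", strict_positive = TRUE)
  k1p <- .check_rate(k1p, "k1p")
  k_minus1p <- .check_rate(k_minus1p, "k_minus1p", strict_positive = TRUE)
  k_off <- if (is.null(k_off)) k_minus1 else .check_rate(k_off, "k_off")
  k_minus1_star <- if (is.null(k_minus1_star)) k_minus1
                   else .check_rate(k_minus1_star, "k_minus1_star")
  k_minus1p_star <- if (is.null(k_minus1p_star)) k_minus1p
                    else .check_rate(k_minus1p_star, "k_minus1p_star")
  k_p <- .check_rate(k_p, "k_p")
  if (k_minus1p <= k_minus1)
    warning("k_minus1p <= k_minus1: the incorrect substrate does not unbind ",
            "faster than the correct one; proofreading cannot discriminate",
            call. = FALSE)
  structure(list(k1 = k1, k_minus1 = k_minus1, k1p = k1p,
                 k_minus1p = k_minus1p, k_off = k_off,
                 k_minus1_star = k_minus1_star,
                 k_minus1p_star = k_minus1p_star, k_p = k_p),
            class = "kpr_rates")
}

#' @export
print.kpr_rates <- function(x, ...) {
  cat("Proofreading rate constants (units of 1/time):\n")
  cat(sprintf("  correct:   k1 = %g, k_minus1 = %g, k_minus1_star = %g\n",
              x$k1, x$k_minus1, x$k_minus1_star))
  cat(sprintf("  incorrect: k1p = %g, k_minus1p = %g, k_minus1p_star = %g\n",
              x$k1p, x$k_minus1p, x$k_minus1p_star))
  cat(sprintf("  shared:    k_off = %g, k_p = %g\n", x$k_off, x$k_p))
  invisible(x)
}

#' Processing-time distribution of the proofreading chain
#'
#' The waiting time spent traversing the lumped intermediate states before
#' activation. Three families are supported: `"delta"` (deterministic time
#' `tau`, the many-step limit), `"erlang"` (sum of `m` exponential steps,
#' each with rate `m/tau`, so the mean is `tau` and the variance
#' `tau^2/m`), and `"exponential"` (mean `tau`; equals Erlang with
#' `m = 1` and recovers memoryless Michaelis-Menten processing).
#'
#' @param family one of `"delta"`, `"erlang"`, `"exponential"`.
#' @param tau mean processing time (> 0; the delta family also accepts
#'   `tau = 0`, the no-proofreading limit).
#' @param m number of proofreading steps (positive integer; used by the
#'   Erlang family).
#' @return An object of class `kpr_processing` with fields `family`, `tau`,
#'   `m`, and the per-step rate `k_f = m/tau`.
#' @examples
#' processing_model("delta", tau = 3)
#' processing_model("erlang", tau = 3, m = 4)
#' @export
processing_model <- function(family = c("delta", "erlang", "exponential"),
                             tau = 3, m = 1L) {
  family <- match.arg(family)
  # tau = 0 (no proofreading delay) is meaningful for the degenerate family
  # only; the Erlang/exponential rate m/tau would be undefined
  tau <- .check_rate(tau, "tau", strict_positive = family != "delta")
  if (!is.numeric(m) || length(m) != 1L || !is.finite(m) || m < 1 ||
      m != round(m))
    stop("'m' must be a positive integer", call. = FALSE)
  m <- as.integer(m)
  structure(list(family = family, tau = tau, m = m, k_f = m / tau),
            class = "kpr_processing")
}

#' @export
print.kpr_processing <- function(x, ...) {
  cat(sprintf("Processing-time model: %s, tau = %g%s\n", x$family, x$tau,
              if (x$family == "erlang")
                sprintf(", m = %d (k_f = %g)", x$m, x$k_f) else ""))
  invisible(x)
}

#' Contact-time model
#'
#' Duration of the receptor-ligand encounter (for T cells, the cell-cell
#' contact time) within which discrimination must happen. Either a fixed
#' duration `T` or a uniform draw on `[0, T_max]`.
#'
#' @param kind `"fixed"` or `"uniform"`.
#' @param T fixed contact duration (kind `"fixed"`).
#' @param T_max upper bound of the uniform distribution (kind `"uniform"`).
#' @return An object of class `kpr_contact`.
#' @examples
#' contact_model("fixed", T = 1000)
#' contact_model("uniform", T_max = 1e6)
#' @export
contact_model <- function(kind = c("fixed", "uniform"), T = NULL,
                          T_max = NULL) {
  kind <- match.arg(kind)
  if (kind == "fixed") {
    if (is.null(T)) stop("kind = 'fixed' requires 'T'", call. = FALSE)
    T <- .check_rate(T, "T", strict_positive = TRUE)
    structure(list(kind = kind, T = T), class = "kpr_contact")
  } else {
    if (is.null(T_max)) stop("kind = 'uniform' requires 'T_max'",
                             call. = FALSE)
    T_max <- .check_rate(T_max, "T_max", strict_positive = TRUE)
    structure(list(kind = kind, T_max = T_max), class = "kpr_contact")
  }
}

#' @export
print.kpr_contact <- function(x, ...) {
  if (x$kind == "fixed") cat(sprintf("Contact time: fixed T = %g\n", x$T))
  else cat(sprintf("Contact time: uniform on [0, %g]\n", x$T_max))
  invisible(x)
}

#' Draw processing times
#'
#' Samples from a [processing_model()]: `"delta"` returns exactly `tau`,
#' `"erlang"` draws a Gamma(shape `m`, rate `m/tau`) variate (the sum of
#' `m` exponential steps), `"exponential"` an exponential with mean `tau`.
#' Uses R's global random number stream, so draws are reproducible under
#' [set.seed()].
#'
#' @param model a [processing_model()].
#' @param n number of draws.
#' @return Numeric vector of `n` waiting times.
#' @examples
#' draw_processing_time(processing_model("delta", 3), 2)   # 3 3
#' @export
draw_processing_time <- function(model, n = 1L) {
  stopifnot(inherits(model, "kpr_processing"))
  switch(model$family,
         delta = rep(model$tau, n),
         erlang = stats::rgamma(n, shape = model$m, rate = model$m / model$tau),
         exponential = stats::rexp(n, rate = 1 / model$tau))
}

#' Validate and normalize a simulation configuration
#'
#' Re-validates a rate set and a processing-time model together and returns
#' the normalized configuration (with scheme defaults such as
#' `k_off = k_minus1` already filled in by the constructors). Plain named
#' lists are accepted and passed through the constructors, so malformed
#' fields raise errors naming the offending field and regime violations
#' (such as `k_minus1p <= k_minus1`) surface as warnings.
#'
#' @param params a [kpr_rates()] object or a named list of rates.
#' @param processing a [processing_model()] object or a named list with
#'   entries `family`, `tau`, `m`.
#' @return A list with entries `params` and `processing`, both validated.
#' @export
validate_parameters <- function(params = kpr_rates(),
                                processing = processing_model()) {
  if (!inherits(params, "kpr_rates")) {
    if (!is.list(params)) stop("'params' must be a kpr_rates object or list",
                               call. = FALSE)
    params <- do.call(kpr_rates, params)
  } else {
    params <- do.call(kpr_rates, unclass(params))
  }
  if (!inherits(processing, "kpr_processing")) {
    if (!is.list(processing))
      stop("'processing' must be a processing_model object or list",
           call. = FALSE)
    processing <- do.call(processing_model, processing)
  }
  list(params = params, processing = processing)
}

#' Occupancy factors of the bound state
#'
#' The steady-state bound fractions `K = k1/(k1 + k_minus1)` and
#' `K' = k1p/(k1p + k_minus1p)` that enter the product-count moments.
#'
#' @param params a [kpr_rates()] object.
#' @return Named vector with elements `K` and `K_p`.
#' @export
occupancy_factors <- function(params) {
  stopifnot(inherits(params, "kpr_rates"))
  c(K = params$k1 / (params$k1 + params$k_minus1),
    K_p = params$k1p / (params$k1p + params$k_minus1p))
}

#' Is an activation time censored?
#'
#' Activation times are censored (no entry into the activated state within
#' the contact window) and represented by `NA`; this helper makes the
#' branch explicit at call sites.
#'
#' @param x numeric vector of activation times, or a trajectory.
#' @return Logical vector.
#' @export
is_censored <- function(x) {
  if (inherits(x, "kpr_trajectory")) x <- x$activation_time
  is.na(x)
}
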