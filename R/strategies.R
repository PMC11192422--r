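# Map trajectories to discrimination outputs: activation (first-passage),
# product count, static count threshold, and time-dependent dynamic
# threshold; plus the decomposition of the count strategy into a family of
# threshold strategies.

#' Discrimination strategy specification
#'
#' @param kind one of `"fpt"`, `"count"`, `"static_threshold"`,
#'   `"dynamic_threshold"`.
#' @param P_th integer count threshold (static only, >= 1).
#' @param gate minimum threshold level for response initiation (dynamic
#'   only): activation is forbidden at any time where the threshold line is
#'   still below `gate`, filtering noisy transients. Default 10 products.
#' @param threshold_fn nondecreasing map `t -> P_th(t)` (dynamic only);
#'   default is the geometric-mean line from [dynamic_threshold_fn()],
#'   which requires `params` and `processing`.
#' @param params,processing model objects used to build the default
#'   `threshold_fn`.
#' @return An object of class `kpr_strategy`.
#' @export
strategy_spec <- function(kind = c("fpt", "count", "static_threshold",
                                   "dynamic_threshold"),
                          P_th = NULL, gate = 10, threshold_fn = NULL,
                          params = NULL, processing = NULL) {
  kind <- match.arg(kind)
  if (kind == "static_threshold") {
    if (is.null(P_th) || P_th < 1 || P_th != round(P_th))
      stop("static_threshold requires an integer 'P_th' >= 1", call. = FALSE)
    P_th <- as.integer(P_th)
  }
  if (kind == "dynamic_threshold") {
    if (is.null(threshold_fn)) {
      if (is.null(params) || is.null(processing))
        stop("dynamic_threshold needs 'threshold_fn', or 'params' and ",
             "'processing' to build the default line", call. = FALSE)
      threshold_fn <- dynamic_threshold_fn(params, processing)
    }
    stopifnot(is.function(threshold_fn), is.numeric(gate), gate >= 0)
  }
  structure(list(kind = kind, P_th = P_th, gate = gate,
                 threshold_fn = threshold_fn), class = "kpr_strategy")
}

#' Default dynamic threshold line
#'
#' The accuracy-optimal static threshold for a contact of length `t`,
#' applied at every instant: `P_th(t) = k_p t sqrt(K exp(-k_minus1 tau) *
#' K_p exp(-k_minus1p tau))`, the geometric mean of the two expected count
#' lines. The cell is assumed to know its own rates.
#'
#' @param params a [kpr_rates()] object.
#' @param processing a [processing_model()]; its mean `tau` enters the
#'   line.
#' @return A function of time `t`.
#' @export
dynamic_threshold_fn <- function(params, processing) {
  stopifnot(inherits(params, "kpr_rates"),
            inherits(processing, "kpr_processing"))
  occ <- occupancy_factors(params)
  slope <- params$k_p * sqrt(occ[["K"]] * exp(-params$k_minus1 *
                                                processing$tau) *
                               occ[["K_p"]] * exp(-params$k_minus1p *
                                                    processing$tau))
  function(t) slope * t
}

# accept a single trajectory or a contact ensemble; return list of
# per-trajectory fields
.traj_fields <- function(x, need_times = FALSE) {
  if (inherits(x, "kpr_trajectory")) {
    list(activation_time = x$activation_time, horizon = x$horizon,
         count = length(x$product_times), times = list(x$product_times),
         n = 1L)
  } else if (inherits(x, "kpr_ensemble") &&
             x$scheme %in% c("tcr", "multistep")) {
    if (need_times && is.null(x$product_times))
      stop("ensemble was run with keep_times = FALSE; product event times ",
           "are required", call. = FALSE)
    list(activation_time = x$activation_time, horizon = x$horizon,
         count = x$product_count, times = x$product_times, n = x$n_traj)
  } else {
    stop("expected a kpr_trajectory or a contact kpr_ensemble",
         call. = FALSE)
  }
}

#' Activation (first-passage) output
#'
#' `X = 1` iff the activated state was reached within the contact window
#' (activation time uncensored and `< horizon`).
#'
#' @param x a `kpr_trajectory` or a contact `kpr_ensemble`.
#' @return Integer 0/1 vector, one value per trajectory.
#' @export
fpt_output <- function(x) {
  f <- .traj_fields(x)
  as.integer(!is.na(f$activation_time) & f$activation_time < f$horizon)
}

#' Product-count output
#'
#' Number of products emitted within the contact window.
#'
#' @inheritParams fpt_output
#' @return Integer vector of counts.
#' @export
count_output <- function(x) {
  f <- .traj_fields(x)
  as.integer(f$count)
}

#' Static count-threshold output
#'
#' `X = 1` iff the final product count reaches `P_th`; because the count
#' path is nondecreasing this equals "the threshold was crossed at some
#' time within the window".
#'
#' @inheritParams fpt_output
#' @param P_th integer threshold (>= 1).
#' @return Integer 0/1 vector.
#' @export
static_threshold_output <- function(x, P_th) {
  if (P_th < 1 || P_th != round(P_th))
    stop("'P_th' must be an integer >= 1", call. = FALSE)
  as.integer(count_output(x) >= P_th)
}

#' Dynamic count-threshold output
#'
#' `X = 1` iff at some product event time `t_i <= horizon` (the endpoint
#' `t = horizon` is also checked) the running count satisfies
#' `P(t_i) >= threshold_fn(t_i)` while the threshold line has already
#' reached the gate level (`threshold_fn(t_i) >= gate`). Crossings are
#' checked at event times and the endpoint because the count path is
#' piecewise constant and the threshold line nondecreasing.
#'
#' @inheritParams fpt_output
#' @param spec a `"dynamic_threshold"` [strategy_spec()]; alternatively
#'   pass `threshold_fn` / `gate` directly.
#' @param threshold_fn,gate used when `spec` is missing.
#' @return Integer 0/1 vector.
#' @export
dynamic_threshold_output <- function(x, spec = NULL, threshold_fn = NULL,
                                     gate = 10) {
  if (!is.null(spec)) {
    stopifnot(inherits(spec, "kpr_strategy"),
              spec$kind == "dynamic_threshold")
    threshold_fn <- spec$threshold_fn
    gate <- spec$gate
  }
  stopifnot(is.function(threshold_fn))
  f <- .traj_fields(x, need_times = TRUE)
  # validate monotonicity of the threshold line on the relevant range
  grid <- seq(0, max(f$horizon), length.out = 101)
  if (is.unsorted(threshold_fn(grid)))
    stop("'threshold_fn' must be nondecreasing in time", call. = FALSE)
  vapply(seq_len(f$n), function(i) {
    ts <- f$times[[i]]
    ts <- ts[ts <= f$horizon[i]]
    tt <- c(ts, f$horizon[i])
    counts <- c(seq_along(ts), length(ts))
    thr <- threshold_fn(tt)
    as.integer(any(counts >= thr & thr >= gate))
  }, integer(1))
}

#' Decompose the count strategy into threshold strategies
#'
#' Computes the channel capacity of the static-threshold output for every
#' threshold in `thresholds` on a shared pair of ensembles, returns the
#' per-threshold capacities and their maximum `C_hat_max`, and verifies the
#' data-processing bound `C_hat_max <= C(xi; P(T))` on the same ensembles.
#'
#' @param ensemble0,ensemble1 contact ensembles under `xi = 0` / `xi = 1`.
#' @param thresholds nonempty integer vector of thresholds.
#' @return List with `per_threshold` (data frame: `P_th`, `capacity`),
#'   `C_hat_max`, the count-channel capacity `C_count`, and
#'   `bound_satisfied`.
#' @export
decompose_product_strategy <- function(ensemble0, ensemble1, thresholds) {
  stopifnot(length(thresholds) >= 1)
  caps <- vapply(thresholds, function(k)
    channel_capacity(empirical_channel(ensemble0, ensemble1,
                                       function(e)
                                         static_threshold_output(e, k))
                     )$capacity, numeric(1))
  c_count <- channel_capacity(empirical_channel(ensemble0, ensemble1,
                                                count_output))$capacity
  list(per_threshold = data.frame(P_th = thresholds, capacity = caps),
       C_hat_max = max(caps), C_count = c_count,
       bound_satisfied = max(caps) <= c_count + 1e-12)
}

#' Draw contact times
#'
#' @param contact a [contact_model()].
#' @param n number of draws.
#' @return Numeric vector: the fixed `T` repeated, or uniform draws on
#'   `[0, T_max]`.
#' @export
sample_contact_time <- function(contact, n = 1L) {
  stopifnot(inherits(contact, "kpr_contact"))
  if (contact$kind == "fixed") rep(contact$T, n)
  else stats::runif(n, 0, contact$T_max)
}
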