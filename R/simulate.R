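# Event-driven stochastic simulation of the reaction schemes. The per-event
# engine lives in src/sim.cpp; this layer resolves which rates apply to the
# substrate at hand (xi = 1 cognate, xi = 0 noncognate), assembles ensembles,
# and serializes them.

.family_code <- function(processing)
  match(processing$family, c("delta", "erlang", "exponential")) - 1L

# rates of the reduced cycle seen by substrate xi
.tcr_rates <- function(params, xi) {
  if (xi == 1)
    list(k_on = params$k1, k_unbind = params$k_off,
         k_star = params$k_minus1_star)
  else
    list(k_on = params$k1p, k_unbind = params$k_minus1p,
         k_star = params$k_minus1p_star)
}

.new_trajectory <- function(xi, horizon, activation_time, product_times,
                            n_binding_events) {
  structure(list(xi = xi, horizon = horizon,
                 activation_time = activation_time,
                 product_times = product_times,
                 n_binding_events = n_binding_events),
            class = "kpr_trajectory")
}

#' @export
print.kpr_trajectory <- function(x, ...) {
  cat(sprintf("Proofreading trajectory (xi = %d, horizon = %g)\n", x$xi,
              x$horizon))
  cat(sprintf("  activation: %s\n",
              if (is.na(x$activation_time)) "censored"
              else sprintf("t_a = %g", x$activation_time)))
  cat(sprintf("  products: %d, binding events: %d\n",
              length(x$product_times), x$n_binding_events))
  invisible(x)
}

#' Simulate one receptor-signaling contact
#'
#' Event-driven simulation of the reduced single-substrate cycle
#' `E + S <-> ES ~~> E*S`, where the bound complex either completes its
#' processing time (one draw from `processing`) or unbinds first, the
#' activated complex emits products at rate `k_p` until it unbinds at rate
#' `k_minus1_star`, and every unbinding fully resets the proofreading
#' progress. For the noncognate substrate (`xi = 0`) the primed rates are
#' used throughout. The simulation halts exactly at the contact time `T`;
#' if the activated state is never reached within the window the activation
#' time is censored (`NA`, see [is_censored()]).
#'
#' @param params a [kpr_rates()] object.
#' @param processing a [processing_model()].
#' @param T contact duration (>= 0).
#' @param xi substrate label: 1 cognate, 0 noncognate.
#' @param keep_times keep the product emission times (needed by
#'   [dynamic_threshold_output()]); the product count is always kept.
#' @param max_events overflow guard on the number of events per trajectory.
#' @return A `kpr_trajectory`: list with `xi`, `horizon`,
#'   `activation_time` (`NA` when censored), `product_times`
#'   (nondecreasing), `n_binding_events`.
#' @examples
#' set.seed(1)
#' simulate_tcr(kpr_rates(), processing_model("delta", 3), T = 1000, xi = 1)
#' @export
simulate_tcr <- function(params, processing, T, xi = 1, keep_times = TRUE,
                         max_events = 1e9) {
  cfg <- validate_parameters(params, processing)
  stopifnot(is.numeric(T), length(T) == 1L, T >= 0, xi %in% c(0, 1))
  r <- .tcr_rates(cfg$params, xi)
  sim <- cpp_sim_tcr(as.numeric(T), r$k_on, r$k_unbind, r$k_star,
                     cfg$params$k_p, .family_code(cfg$processing),
                     cfg$processing$tau, cfg$processing$m, FALSE,
                     max_events, TRUE)
  .new_trajectory(xi, T, sim$activation_time[1],
                  if (keep_times) sim$product_times[[1]] else numeric(0),
                  sim$n_binding_events[1])
}

#' Simulate the receptor cycle with an explicit m-step proofreading chain
#'
#' Identical to [simulate_tcr()] except that the processing time is not
#' drawn as a single waiting time: the bound complex traverses the explicit
#' Markov chain `E(0)S -> ... -> E(m-1)S -> E*S` with per-step rate `m/tau`
#' while every intermediate state can unbind (rate `k_off` for the cognate,
#' `k_minus1p` for the noncognate substrate), resetting the chain. This is
#' distribution-equivalent to [simulate_tcr()] with an Erlang(`m`)
#' processing model, and converges to the deterministic-`tau` model as
#' `m` grows.
#'
#' @inheritParams simulate_tcr
#' @param m number of proofreading steps (>= 1).
#' @param tau mean processing time; the per-step rate is `m/tau`.
#' @return A `kpr_trajectory`.
#' @export
simulate_multistep_tcr <- function(params, m, tau, T, xi = 1,
                                   keep_times = TRUE, max_events = 1e9) {
  cfg <- validate_parameters(params, processing_model("erlang", tau, m))
  stopifnot(is.numeric(T), length(T) == 1L, T >= 0, xi %in% c(0, 1))
  r <- .tcr_rates(cfg$params, xi)
  sim <- cpp_sim_tcr(as.numeric(T), r$k_on, r$k_unbind, r$k_star,
                     cfg$params$k_p, 1L, tau, cfg$processing$m, TRUE,
                     max_events, TRUE)
  .new_trajectory(xi, T, sim$activation_time[1],
                  if (keep_times) sim$product_times[[1]] else numeric(0),
                  sim$n_binding_events[1])
}

#' Simulate one replication-fidelity race
#'
#' Two-branch scheme with both substrates competing for one enzyme: from the
#' free state the enzyme binds the correct substrate with probability
#' `k1/(k1 + k1p)`; a bound complex either completes after one
#' processing-time draw or unbinds first (rate `k_minus1` / `k_minus1p`);
#' binding repeats until absorption into the correct or incorrect product.
#'
#' @inheritParams simulate_tcr
#' @param max_cycles overflow guard on the number of binding cycles.
#' @return A `kpr_dna_outcome`: list with `winner` (`"correct"` or
#'   `"incorrect"`), `completion_time`, `n_cycles`.
#' @examples
#' set.seed(1)
#' simulate_dna(kpr_rates(), processing_model("delta", 5))
#' @export
simulate_dna <- function(params, processing, max_cycles = 1e9) {
  cfg <- validate_parameters(params, processing)
  if (cfg$params$k1 + cfg$params$k1p <= 0)
    stop("k1 + k1p must be > 0: the enzyme can never bind", call. = FALSE)
  sim <- cpp_sim_dna(1L, cfg$params$k1, cfg$params$k1p, cfg$params$k_minus1,
                     cfg$params$k_minus1p, .family_code(cfg$processing),
                     cfg$processing$tau, cfg$processing$m, max_cycles)
  structure(list(winner = if (sim$winner[1] == 1L) "correct" else "incorrect",
                 completion_time = sim$completion_time[1],
                 n_cycles = sim$n_cycles[1]),
            class = "kpr_dna_outcome")
}

#' @export
print.kpr_dna_outcome <- function(x, ...) {
  cat(sprintf("Replication outcome: %s product after %d cycle(s), t = %g\n",
              x$winner, x$n_cycles, x$completion_time))
  invisible(x)
}

#' Simulate the nested effective proofreading chain
#'
#' The accumulation of products up to a threshold, reinterpreted as an outer
#' proofreading chain: the contact climbs `P_th` forward steps, each waiting
#' one draw from `forward_waiting`, while a single draw from
#' `disassembly_waiting` terminates the whole chain. The outcome is 1 if
#' level `P_th` is reached before disassembly.
#'
#' @param forward_waiting a [processing_model()] for the per-step forward
#'   waiting time.
#' @param disassembly_waiting a [processing_model()] for the single
#'   disassembly time of the chain.
#' @param P_th number of forward steps to complete (>= 1).
#' @param n number of independent replicates.
#' @return Integer vector of 0/1 outcomes, length `n`.
#' @examples
#' set.seed(1)
#' mean(simulate_nested(processing_model("exponential", 1),
#'                      processing_model("delta", 10), P_th = 5, n = 1e4))
#' @export
simulate_nested <- function(forward_waiting, disassembly_waiting, P_th,
                            n = 1L) {
  stopifnot(inherits(forward_waiting, "kpr_processing"),
            inherits(disassembly_waiting, "kpr_processing"))
  if (!is.numeric(P_th) || length(P_th) != 1L || P_th < 1 ||
      P_th != round(P_th))
    stop("'P_th' must be a positive integer", call. = FALSE)
  stopifnot(is.numeric(n), length(n) == 1L, n >= 1)
  P_th <- as.integer(P_th)
  climb <- matrix(draw_processing_time(forward_waiting, n * P_th),
                  nrow = P_th)
  total <- colSums(climb)
  dis <- draw_processing_time(disassembly_waiting, n)
  as.integer(total <= dis)
}

#' Simulate an ensemble of independent contacts
#'
#' Runs `n_traj` independent trajectories of one scheme under a stored
#' seed, so the ensemble is bit-reproducible. With a `"uniform"` contact
#' model a fresh horizon is drawn per trajectory and stored.
#'
#' @param scheme one of `"tcr"` (reduced cycle), `"dna"` (two-branch
#'   fidelity race), `"multistep"` (explicit m-step chain), `"nested"`
#'   (outer effective chain).
#' @param params a [kpr_rates()] object (schemes `"tcr"`, `"dna"`,
#'   `"multistep"`).
#' @param processing a [processing_model()] (schemes `"tcr"`, `"dna"`).
#' @param contact a [contact_model()] (schemes `"tcr"`, `"multistep"`).
#' @param xi substrate label, 0 or 1 (schemes `"tcr"`, `"multistep"`).
#' @param n_traj number of trajectories (>= 1).
#' @param seed integer seed stored in the ensemble.
#' @param m,tau explicit-chain parameters (scheme `"multistep"`).
#' @param forward_waiting,disassembly_waiting,P_th nested-scheme
#'   parameters (scheme `"nested"`).
#' @param keep_times keep per-trajectory product emission times.
#' @param max_events,max_cycles overflow guards.
#' @return A `kpr_ensemble` whose fields are column vectors over
#'   trajectories (`activation_time`, `product_count`, `horizon`, ... for
#'   contact schemes; `winner`, `completion_time`, `n_cycles` for
#'   `"dna"`; `outcome` for `"nested"`), plus the generating
#'   configuration and seed.
#' @examples
#' ens <- run_ensemble("tcr", kpr_rates(), processing_model("delta", 3),
#'                     contact_model("fixed", T = 200), xi = 1,
#'                     n_traj = 100, seed = 1)
#' summary(ens)
#' @export
run_ensemble <- function(scheme = c("tcr", "dna", "multistep", "nested"),
                         params = kpr_rates(),
                         processing = processing_model(),
                         contact = contact_model("fixed", T = 1000),
                         xi = 1, n_traj, seed = 1L, m = NULL, tau = NULL,
                         forward_waiting = NULL, disassembly_waiting = NULL,
                         P_th = NULL, keep_times = FALSE, max_events = 1e9,
                         max_cycles = 1e9) {
  scheme <- match.arg(scheme)
  if (!is.numeric(n_traj) || length(n_traj) != 1L || n_traj < 1 ||
      n_traj != round(n_traj))
    stop("'n_traj' must be a positive integer", call. = FALSE)
  n_traj <- as.integer(n_traj)
  set.seed(seed)

  out <- list(scheme = scheme, seed = seed, n_traj = n_traj)
  if (scheme %in% c("tcr", "multistep")) {
    if (scheme == "multistep") {
      stopifnot(!is.null(m), !is.null(tau))
      processing <- processing_model("erlang", tau, m)
    }
    cfg <- validate_parameters(params, processing)
    stopifnot(inherits(contact, "kpr_contact"), xi %in% c(0, 1))
    horizon <- sample_contact_time(contact, n_traj)
    r <- .tcr_rates(cfg$params, xi)
    sim <- cpp_sim_tcr(horizon, r$k_on, r$k_unbind, r$k_star,
                       cfg$params$k_p, .family_code(cfg$processing),
                       cfg$processing$tau, cfg$processing$m,
                       scheme == "multistep", max_events, keep_times)
    out <- c(out, list(params = cfg$params, processing = cfg$processing,
                       contact = contact, xi = xi, horizon = horizon,
                       activation_time = sim$activation_time,
                       n_binding_events = sim$n_binding_events,
                       product_count = sim$product_count,
                       product_times = if (keep_times) sim$product_times))
  } else if (scheme == "dna") {
    cfg <- validate_parameters(params, processing)
    if (cfg$params$k1 + cfg$params$k1p <= 0)
      stop("k1 + k1p must be > 0: the enzyme can never bind", call. = FALSE)
    sim <- cpp_sim_dna(n_traj, cfg$params$k1, cfg$params$k1p,
                       cfg$params$k_minus1, cfg$params$k_minus1p,
                       .family_code(cfg$processing), cfg$processing$tau,
                       cfg$processing$m, max_cycles)
    out <- c(out, list(params = cfg$params, processing = cfg$processing,
                       winner = sim$winner,
                       completion_time = sim$completion_time,
                       n_cycles = sim$n_cycles))
  } else {  # nested
    stopifnot(!is.null(forward_waiting), !is.null(disassembly_waiting),
              !is.null(P_th))
    out <- c(out, list(forward_waiting = forward_waiting,
                       disassembly_waiting = disassembly_waiting,
                       P_th = as.integer(P_th),
                       outcome = simulate_nested(forward_waiting,
                                                 disassembly_waiting,
                                                 P_th, n_traj)))
  }
  structure(out, class = "kpr_ensemble")
}

#' @export
print.kpr_ensemble <- function(x, ...) {
  cat(sprintf("Proofreading ensemble: scheme '%s', %d trajectories, seed %d\n",
              x$scheme, x$n_traj, x$seed))
  if (x$scheme %in% c("tcr", "multistep")) {
    cat(sprintf("  xi = %d, activation censored in %d/%d trajectories, mean product count %.3g\n",
                x$xi, sum(is.na(x$activation_time)), x$n_traj,
                mean(x$product_count)))
  } else if (x$scheme == "dna") {
    cat(sprintf("  correct product in %.4f of runs, mean completion time %.4g\n",
                mean(x$winner == 1L), mean(x$completion_time)))
  } else {
    cat(sprintf("  P_th = %d, success frequency %.4f\n", x$P_th,
                mean(x$outcome)))
  }
  invisible(x)
}

#' @export
summary.kpr_ensemble <- function(object, ...) {
  print(object)
  if (object$scheme %in% c("tcr", "multistep")) {
    act <- object$activation_time
    cat(sprintf("  activation time (uncensored): mean %.4g (n = %d)\n",
                mean(act[!is.na(act)]), sum(!is.na(act))))
    cat(sprintf("  product count: mean %.4g, var %.4g\n",
                mean(object$product_count), stats::var(object$product_count)))
  }
  invisible(object)
}

#' Extract one trajectory from a contact ensemble
#'
#' @param ensemble a `kpr_ensemble` with scheme `"tcr"` or `"multistep"`.
#' @param i trajectory index.
#' @return A `kpr_trajectory`.
#' @export
ensemble_trajectory <- function(ensemble, i) {
  stopifnot(inherits(ensemble, "kpr_ensemble"),
            ensemble$scheme %in% c("tcr", "multistep"))
  .new_trajectory(ensemble$xi, ensemble$horizon[i],
                  ensemble$activation_time[i],
                  if (!is.null(ensemble$product_times))
                    ensemble$product_times[[i]] else numeric(0),
                  ensemble$n_binding_events[i])
}

#' @export
as.data.frame.kpr_ensemble <- function(x, ...) {
  if (x$scheme %in% c("tcr", "multistep")) {
    data.frame(scheme = x$scheme, xi = x$xi, horizon = x$horizon,
               activation_time = ifelse(is.na(x$activation_time), "censored",
                                        as.character(x$activation_time)),
               product_count = x$product_count,
               n_binding_events = x$n_binding_events, seed = x$seed,
               stringsAsFactors = FALSE)
  } else if (x$scheme == "dna") {
    data.frame(scheme = x$scheme,
               winner = ifelse(x$winner == 1L, "correct", "incorrect"),
               completion_time = x$completion_time, n_cycles = x$n_cycles,
               seed = x$seed, stringsAsFactors = FALSE)
  } else {
    data.frame(scheme = x$scheme, P_th = x$P_th, outcome = x$outcome,
               seed = x$seed, stringsAsFactors = FALSE)
  }
}

#' Serialize an ensemble to CSV with a JSON parameter sidecar
#'
#' Writes one row per trajectory to `file`, the full generating
#' configuration to `meta_file` (JSON), and optionally the product event
#' times (columns `trajectory_id`, `event_time`) to `times_file` for
#' dynamic-threshold analysis.
#'
#' @param ensemble a `kpr_ensemble`.
#' @param file CSV path for the per-trajectory table.
#' @param meta_file JSON path for the configuration; default replaces the
#'   CSV extension with `.json`.
#' @param times_file optional CSV path for product event times (requires an
#'   ensemble run with `keep_times = TRUE`).
#' @return Invisibly, the paths written.
#' @export
write_ensemble <- function(ensemble, file,
                           meta_file = sub("\\.csv$", ".json", file),
                           times_file = NULL) {
  stopifnot(inherits(ensemble, "kpr_ensemble"))
  utils::write.csv(as.data.frame(ensemble), file, row.names = FALSE)
  meta <- ensemble[setdiff(names(ensemble),
                           c("horizon", "activation_time", "product_count",
                             "n_binding_events", "product_times", "winner",
                             "completion_time", "n_cycles", "outcome"))]
  meta <- lapply(meta, function(f) if (is.list(f)) unclass(f) else f)
  jsonlite::write_json(meta, meta_file, auto_unbox = TRUE, digits = NA)
  if (!is.null(times_file)) {
    if (is.null(ensemble$product_times))
      stop("ensemble was run with keep_times = FALSE; no event times stored",
           call. = FALSE)
    nt <- lengths(ensemble$product_times)
    utils::write.csv(data.frame(trajectory_id = rep(seq_along(nt), nt),
                                event_time = unlist(ensemble$product_times)),
                     times_file, row.names = FALSE)
  }
  invisible(c(file = file, meta_file = meta_file, times_file = times_file))
}
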