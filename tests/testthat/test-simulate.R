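test_that("degenerate contact simulations behave as the scheme dictates", {
  p0 <- kpr_rates(k_p = 0)
  ens <- run_ensemble("tcr", p0, processing_model("delta", 1), fixed_T(200),
                      xi = 1, n_traj = 200, seed = 1)
  expect_true(all(ens$product_count == 0))  # no production channel

  # deterministic processing longer than the contact: never activates
  ens <- run_ensemble("tcr", kpr_rates(), processing_model("delta", 10),
                      fixed_T(5), xi = 1, n_traj = 200, seed = 2)
  expect_true(all(is.na(ens$activation_time)))

  # no unbinding from the bound state: t_a = first binding + tau,
  # so E[t_a] = 1/k1 + tau = 13
  pk <- kpr_rates(k_off = 0, k_p = 0)
  ens <- run_ensemble("tcr", pk, processing_model("delta", 3), fixed_T(1000),
                      xi = 1, n_traj = 1e4, seed = 3)
  act <- ens$activation_time
  expect_true(all(!is.na(act)))
  expect_lt(abs(mean(act) - 13), 3 * sd(act) / sqrt(length(act)))
})

test_that("trajectory invariants hold along simulated paths", {
  set.seed(4)
  for (i in 1:20) {
    traj <- simulate_tcr(kpr_rates(), processing_model("delta", 1), T = 300,
                         xi = sample(0:1, 1))
    expect_false(is.unsorted(traj$product_times))
    if (length(traj$product_times)) {
      expect_false(is_censored(traj))
      expect_gte(min(traj$product_times), traj$activation_time)
      expect_lte(max(traj$product_times), traj$horizon)
    }
  }
})

test_that("product-count mean matches the steady-state closed form", {
  p <- default_rates()
  mu1 <- product_count_moments(p, 3, 1000, 1)[["mean"]]
  mu0 <- product_count_moments(p, 3, 1000, 0)[["mean"]]
  e1 <- run_ensemble("tcr", p, processing_model("delta", 3), fixed_T(1000),
                     xi = 1, n_traj = 1e4, seed = 5)
  e0 <- run_ensemble("tcr", p, processing_model("delta", 3), fixed_T(1000),
                     xi = 0, n_traj = 1e4, seed = 6)
  expect_lt(abs(mean(e1$product_count) - mu1),
            3 * sd(e1$product_count) / sqrt(1e4))
  expect_lt(abs(mean(e0$product_count) - mu0),
            3 * sd(e0$product_count) / sqrt(1e4))
})

test_that("replication race matches its first-passage closed forms", {
  # three parameter sets: winner frequency (accuracy) and mean completion
  # time against the conditioning-argument expressions
  sets <- list(list(p = kpr_rates(), tau = 3),
               list(p = kpr_rates(k1p = 0.2, k_minus1p = 3), tau = 2),
               list(p = kpr_rates(k1 = 0.05), tau = 4))
  for (s in sets) {
    ens <- run_ensemble("dna", s$p, processing_model("delta", s$tau),
                        n_traj = 3e4, seed = 7)
    acc <- dna_accuracy(s$p, s$tau)
    expect_lt(abs(mean(ens$winner) - acc),
              3 * sqrt(acc * (1 - acc) / 3e4))
    mfpt <- dna_mfpt(s$p, s$tau)
    expect_lt(abs(mean(ens$completion_time) - mfpt),
              3 * sd(ens$completion_time) / sqrt(3e4))
    expect_true(all(ens$n_cycles >= 1))
    expect_true(all(ens$completion_time > 0))
  }
  # single substrate: the correct product always wins
  one <- run_ensemble("dna", kpr_rates(k1p = 0),
                      processing_model("delta", 3), n_traj = 500, seed = 8)
  expect_true(all(one$winner == 1L))
})

test_that("per-binding activation probability matches the survival forms", {
  # single-substrate race: cycles-to-completion is geometric with success
  # probability q, so E[n_cycles] = 1/q
  p1 <- kpr_rates(k1p = 0)
  cases <- list(list(pm = processing_model("delta", 3), q = exp(-3)),
                list(pm = processing_model("erlang", 3, 4),
                     q = (1 + 3 / 4)^(-4)),
                list(pm = processing_model("erlang", 3, 1000), q = NA))
  q_delta <- exp(-3)
  for (cs in cases) {
    ens <- run_ensemble("dna", p1, cs$pm, n_traj = 5e4, seed = 9)
    q <- if (is.na(cs$q)) q_delta else cs$q  # m = 1000 ~ deterministic limit
    expect_lt(abs(mean(ens$n_cycles) - 1 / q),
              3 * sd(ens$n_cycles) / sqrt(5e4) +
                if (is.na(cs$q)) 0.05 / q_delta else 0)
  }
})

test_that("reduced Erlang engine and explicit m-step chain agree", {
  p <- default_rates()
  for (m in c(1, 4, 32)) {
    er <- run_ensemble("tcr", p, processing_model("erlang", 3, m),
                       fixed_T(200), xi = 1, n_traj = 1e4, seed = 50 + m)
    ms <- run_ensemble("multistep", p, contact = fixed_T(200), xi = 1,
                       n_traj = 1e4, seed = 80 + m, m = m, tau = 3)
    ks <- suppressWarnings(
      ks.test(er$activation_time[!is.na(er$activation_time)],
              ms$activation_time[!is.na(ms$activation_time)]))
    expect_gt(ks$p.value, 0.01)
  }
})

test_that("nested effective chain reproduces its race probabilities", {
  # deterministic forward and disassembly times: a pure race
  win <- simulate_nested(processing_model("delta", 1),
                         processing_model("delta", 10), P_th = 5, n = 50)
  expect_true(all(win == 1))        # 5 * 1 < 10
  lose <- simulate_nested(processing_model("delta", 3),
                          processing_model("delta", 10), P_th = 5, n = 50)
  expect_true(all(lose == 0))       # 5 * 3 > 10

  # exponential climb vs deterministic disassembly: Erlang CDF
  set.seed(11)
  s <- simulate_nested(processing_model("exponential", 1),
                       processing_model("delta", 10), P_th = 5, n = 1e5)
  oracle <- pgamma(10, shape = 5, rate = 1)
  expect_lt(abs(mean(s) - oracle), 3 * sqrt(oracle * (1 - oracle) / 1e5))

  # both exponential, one step: competing exponential clocks
  set.seed(12)
  s <- simulate_nested(processing_model("exponential", 2),
                       processing_model("exponential", 3), P_th = 1, n = 1e5)
  oracle <- (1 / 2) / (1 / 2 + 1 / 3)
  expect_lt(abs(mean(s) - oracle), 3 * sqrt(oracle * (1 - oracle) / 1e5))

  expect_error(simulate_nested(processing_model("exponential", 1),
                               processing_model("delta", 10), P_th = 0),
               "P_th")
})

test_that("ensembles are reproducible, validated, and well-formed", {
  p <- default_rates()
  a <- run_ensemble("tcr", p, processing_model("delta", 3), fixed_T(300),
                    xi = 1, n_traj = 200, seed = 13, keep_times = TRUE)
  b <- run_ensemble("tcr", p, processing_model("delta", 3), fixed_T(300),
                    xi = 1, n_traj = 200, seed = 13, keep_times = TRUE)
  expect_identical(unclass(a), unclass(b))

  expect_error(run_ensemble("tcr", p, n_traj = 0, seed = 1), "n_traj")
  expect_error(run_ensemble("brownian", p, n_traj = 10, seed = 1), "arg")

  u <- run_ensemble("tcr", p, processing_model("delta", 3),
                    contact_model("uniform", T_max = 100), xi = 1,
                    n_traj = 1e4, seed = 14)
  expect_true(all(u$horizon >= 0 & u$horizon <= 100))
  expect_lt(abs(mean(u$horizon) - 50), 3 * 100 / sqrt(12 * 1e4))
})

test_that("the event-count overflow guard trips with a clear message", {
  expect_error(
    run_ensemble("tcr", default_rates(), processing_model("delta", 0.01),
                 fixed_T(1e5), xi = 1, n_traj = 1, seed = 15,
                 max_events = 100),
    "overflow")
})

test_that("ensembles serialize to CSV with a JSON sidecar", {
  td <- withr::local_tempdir()
  ens <- run_ensemble("tcr", default_rates(), processing_model("delta", 3),
                      fixed_T(300), xi = 1, n_traj = 50, seed = 16,
                      keep_times = TRUE)
  csv <- file.path(td, "ens.csv")
  write_ensemble(ens, csv, times_file = file.path(td, "times.csv"))
  tab <- read.csv(csv)
  expect_equal(nrow(tab), 50)
  expect_true(all(c("xi", "horizon", "activation_time", "product_count",
                    "n_binding_events") %in% names(tab)))
  meta <- jsonlite::read_json(file.path(td, "ens.json"),
                              simplifyVector = TRUE)
  expect_equal(meta$params$k_minus1p, 2)
  times <- read.csv(file.path(td, "times.csv"))
  expect_equal(nrow(times), sum(ens$product_count))
})
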