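# Independent closed-form / brute-force oracles used across the suite.

erf <- function(x) 2 * pnorm(x * sqrt(2)) - 1

# binary entropy in bits
H2 <- function(p) {
  q <- c(p, 1 - p)
  q <- q[q > 0]
  -sum(q * log2(q))
}

# brute-force maximization of the multi-shot balanced accuracy over N
brute_force_design <- function(params, tau, N_max = 1e4) {
  N <- seq_len(N_max)
  acc <- multishot_operating_point(params, tau, N)$accuracy
  list(N_opt = N[which.max(acc)], A_opt = max(acc))
}

# dense grid-search channel capacity oracle (binary input)
grid_capacity <- function(channel, n_grid = 20001) {
  p <- seq(1e-6, 1 - 1e-6, length.out = n_grid)
  max(vapply(p, function(pp) mutual_information(channel, pp), numeric(1)))
}

# binary channel from conditional success probabilities
binary_channel <- function(p1_given_0, p1_given_1) {
  conditional_channel(pmf(c(0, 1), c(1 - p1_given_0, p1_given_0)),
                      pmf(c(0, 1), c(1 - p1_given_1, p1_given_1)))
}

default_rates <- function(k_p = 1) kpr_rates(k_p = k_p)

fixed_T <- function(T) contact_model("fixed", T = T)

# capacity of an empirical output channel built from a pair of ensembles
pair_capacity <- function(e0, e1, output_map)
  channel_capacity(empirical_channel(e0, e1, output_map))$capacity
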