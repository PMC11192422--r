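# Entropy, mutual information, channel capacity, and binary-channel
# statistics computed from analytic channels or empirical ensembles.
# Logs are base 2 throughout: capacities are in bits.

#' Finite probability mass function
#'
#' @param support finite ordered set of distinct output values (numeric).
#' @param probs nonnegative probabilities summing to 1 (within 1e-12).
#' @return An object of class `kpr_pmf`.
#' @export
pmf <- function(support, probs) {
  stopifnot(is.numeric(support), is.numeric(probs),
            length(support) == length(probs))
  if (anyDuplicated(support)) stop("support values must be distinct",
                                   call. = FALSE)
  if (any(probs < 0) || abs(sum(probs) - 1) > 1e-12)
    stop("probs must be nonnegative and sum to 1", call. = FALSE)
  o <- order(support)
  structure(list(support = support[o], probs = probs[o]), class = "kpr_pmf")
}

.empirical_pmf <- function(x) {
  tab <- table(x)
  pmf(as.numeric(names(tab)), as.numeric(tab) / length(x))
}

#' Conditional output channel for a binary input
#'
#' Pairs the output distributions given the noncognate (`xi = 0`) and
#' cognate (`xi = 1`) input; the two supports are merged to their union
#' with zero filling.
#'
#' @param pmf0,pmf1 [pmf()] of the output given `xi = 0` / `xi = 1`.
#' @param n0,n1 sample sizes behind each pmf (0 for analytic channels).
#' @return An object of class `kpr_channel` with matrices over the merged
#'   support.
#' @examples
#' ch <- conditional_channel(pmf(c(0, 1), c(0.9, 0.1)),
#'                           pmf(c(0, 1), c(0.2, 0.8)))
#' channel_capacity(ch)
#' @export
conditional_channel <- function(pmf0, pmf1, n0 = 0L, n1 = 0L) {
  stopifnot(inherits(pmf0, "kpr_pmf"), inherits(pmf1, "kpr_pmf"))
  support <- sort(unique(c(pmf0$support, pmf1$support)))
  fill <- function(p) {
    out <- numeric(length(support))
    out[match(p$support, support)] <- p$probs
    out
  }
  structure(list(support = support, p0 = fill(pmf0), p1 = fill(pmf1),
                 n0 = n0, n1 = n1), class = "kpr_channel")
}

#' @export
print.kpr_channel <- function(x, ...) {
  cat(sprintf("Binary-input channel on %d output values%s\n",
              length(x$support),
              if (x$n0 + x$n1 > 0)
                sprintf(" (empirical, n0 = %d, n1 = %d)", x$n0, x$n1)
              else " (analytic)"))
  cc <- channel_capacity(x)
  cat(sprintf("  capacity %.4f bits at P(xi = 1) = %.3f\n", cc$capacity,
              cc$p_star))
  invisible(x)
}

# Shannon entropy in bits with the 0 log 0 = 0 convention
.entropy_bits <- function(p) {
  p <- p[p > 0]
  -sum(p * log2(p))
}

#' Mutual information between a binary input and the channel output
#'
#' `I = S(xi) + S(X) - S(xi, X)` in bits, for input prior
#' `P(xi = 1) = prior`.
#'
#' @param channel a [conditional_channel()].
#' @param prior probability that the input is cognate.
#' @return Mutual information in bits.
#' @examples
#' ch <- conditional_channel(pmf(c(0, 1), c(0.89, 0.11)),
#'                           pmf(c(0, 1), c(0.11, 0.89)))
#' mutual_information(ch, 0.5)   # 1 - H2(0.11) ~ 0.5 bits
#' @export
mutual_information <- function(channel, prior = 0.5) {
  stopifnot(inherits(channel, "kpr_channel"), is.numeric(prior),
            length(prior) == 1L, prior >= 0, prior <= 1)
  joint <- rbind((1 - prior) * channel$p0, prior * channel$p1)
  .entropy_bits(c(1 - prior, prior)) + .entropy_bits(colSums(joint)) -
    .entropy_bits(joint)
}

#' Channel capacity of a binary-input channel
#'
#' Supremum of the mutual information over the input prior, computed by
#' scalar optimization on `[1e-6, 1 - 1e-6]`; the mutual information is
#' concave in the prior, so the maximizer is unique.
#'
#' @param channel a [conditional_channel()].
#' @param tol optimization tolerance on the prior.
#' @return List with `capacity` (bits) and the capacity-achieving prior
#'   `p_star`.
#' @export
channel_capacity <- function(channel, tol = 1e-6) {
  stopifnot(inherits(channel, "kpr_channel"))
  opt <- stats::optimize(function(p) mutual_information(channel, p),
                         c(1e-6, 1 - 1e-6), maximum = TRUE, tol = tol)
  list(capacity = opt$objective, p_star = opt$maximum)
}

#' Sensitivity, specificity, and balanced accuracy of a binary channel
#'
#' @param channel a [conditional_channel()] whose output support is a
#'   subset of `{0, 1}`.
#' @return List with `sensitivity = P(X = 1 | xi = 1)`,
#'   `specificity = P(X = 0 | xi = 0)`, and `accuracy`, their mean.
#' @export
binary_channel_stats <- function(channel) {
  stopifnot(inherits(channel, "kpr_channel"))
  if (!all(channel$support %in% c(0, 1)))
    stop("output is not binary; apply a threshold strategy first",
         call. = FALSE)
  p1 <- function(p) if (1 %in% channel$support)
    p[match(1, channel$support)] else 0
  sens <- p1(channel$p1)
  spec <- 1 - p1(channel$p0)
  list(sensitivity = sens, specificity = spec,
       accuracy = (sens + spec) / 2)
}

#' Fisher linear discriminant of two count samples
#'
#' `(mean1 - mean0)^2 / (var1 + var0)` with unbiased sample variances: the
#' squared separation of the product counts under the two inputs relative
#' to their pooled noise.
#'
#' @param samples0,samples1 numeric vectors of outputs under `xi = 0` and
#'   `xi = 1` (each nonempty).
#' @return The discriminant (dimensionless); `Inf` if both variances vanish
#'   with distinct means, 0 if they vanish with equal means.
#' @export
fisher_linear_discriminant <- function(samples0, samples1) {
  stopifnot(length(samples0) >= 1, length(samples1) >= 1)
  d2 <- (mean(samples1) - mean(samples0))^2
  v <- stats::var(samples1) + stats::var(samples0)
  if (is.na(v)) stop("need at least two samples per input to estimate the ",
                     "variances", call. = FALSE)
  if (v == 0) return(if (d2 == 0) 0 else Inf)
  d2 / v
}

#' Empirical channel from a pair of simulated ensembles
#'
#' Applies a strategy output function to the `xi = 0` and `xi = 1`
#' ensembles and tabulates the outputs into conditional pmfs on the raw
#' union support (no smoothing or binning), the surrogate-distribution
#' procedure used throughout.
#'
#' @param ensemble0,ensemble1 `kpr_ensemble` objects simulated under
#'   `xi = 0` and `xi = 1`.
#' @param output_map function mapping an ensemble to one output value per
#'   trajectory, e.g. [fpt_output()], [count_output()], or a closure over
#'   [static_threshold_output()] / [dynamic_threshold_output()].
#' @return A `kpr_channel` with the empirical sample sizes recorded.
#' @examples
#' e0 <- run_ensemble("tcr", xi = 0, n_traj = 200, seed = 1,
#'                    contact = contact_model("fixed", T = 500))
#' e1 <- run_ensemble("tcr", xi = 1, n_traj = 200, seed = 2,
#'                    contact = contact_model("fixed", T = 500))
#' channel_capacity(empirical_channel(e0, e1, count_output))
#' @export
empirical_channel <- function(ensemble0, ensemble1, output_map) {
  stopifnot(inherits(ensemble0, "kpr_ensemble"),
            inherits(ensemble1, "kpr_ensemble"),
            ensemble0$n_traj >= 1, ensemble1$n_traj >= 1)
  x0 <- output_map(ensemble0)
  x1 <- output_map(ensemble1)
  conditional_channel(.empirical_pmf(x0), .empirical_pmf(x1),
                      n0 = length(x0), n1 = length(x1))
}

#' Channel summary
#'
#' One-stop summary of a binary-input channel: mutual information at a
#' prior, capacity with its achieving prior, and (for binary outputs)
#' sensitivity, specificity, and balanced accuracy.
#'
#' @param channel a [conditional_channel()].
#' @param prior input prior for the mutual-information entry.
#' @return List with `mutual_info_at_prior`, `capacity`, `p_star`, and for
#'   binary outputs `sensitivity`, `specificity`, `accuracy`.
#' @export
channel_summary <- function(channel, prior = 0.5) {
  cc <- channel_capacity(channel)
  out <- list(mutual_info_at_prior = mutual_information(channel, prior),
              capacity = cc$capacity, p_star = cc$p_star)
  if (all(channel$support %in% c(0, 1)))
    out <- c(out, binary_channel_stats(channel))
  out
}

#' Parametric ROC curve of the activation classifier
#'
#' Traces the multi-shot activation classifier over a grid of processing
#' times and integrates the ROC by the trapezoid rule. For `N = 1` and a
#' dense grid the area converges to the closed form
#' `k_minus1p/(k_minus1 + k_minus1p)`.
#'
#' @inheritParams dna_accuracy
#' @param tau_grid increasing grid of processing times.
#' @param N number of binding cycles.
#' @return List with a data frame `points` (columns `tau`, `sensitivity`,
#'   `specificity`, `fpr`) and the trapezoid `auc`.
#' @examples
#' roc_curve(kpr_rates(), seq(0, 20, by = 0.01), N = 1)$auc   # ~2/3
#' @export
roc_curve <- function(params, tau_grid, N = 1) {
  stopifnot(inherits(params, "kpr_rates"), is.numeric(tau_grid),
            !is.unsorted(tau_grid))
  op <- multishot_operating_point(params, tau_grid, N)
  fpr <- 1 - op$specificity
  pts <- data.frame(tau = tau_grid, sensitivity = op$sensitivity,
                    specificity = op$specificity, fpr = fpr)
  # close the curve at (0,0) and (1,1); fpr decreases with tau
  x <- c(1, fpr, 0)
  y <- c(1, op$sensitivity, 0)
  auc <- abs(sum(diff(x) * (head(y, -1) + y[-1]) / 2))
  list(points = pts, auc = auc)
}
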