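# Shared in-code fixtures: everything is generated, nothing read from disk.

# Small synthetic stack (defaults keep module tests fast).
tiny_stack <- function(nrow = 30, ncol = 30, seed = 42L, ...) {
  generate_landscape(landscape_config(nrow = nrow, ncol = ncol,
                                      seed = seed, ...))
}

# A stack whose truth is driven by pine height and altitude only, with all
# cross-couplings off so driver recovery is identifiable.
#   ramps = "balanced": both rise intervals centred on the landscape median
#     with width 20% of the range -- equal discriminating power for the two
#     drivers (the rank-recovery harness).
#   ramps = "sharp": the restrictive default thresholds -- a rarer, more
#     contrasted truth, better suited to prediction/transfer fixtures.
two_driver_world <- function(nrow = 60, ncol = 60, seed = 1L,
                             ramps = c("balanced", "sharp")) {
  ramps <- match.arg(ramps)
  stack <- generate_landscape(landscape_config(
    nrow = nrow, ncol = ncol, seed = seed, cross_cor = 0, lapse_weight = 0))
  terms <- if (ramps == "balanced")
    list(pine_height = c(16, 24), altitude = c(770, 1030))
  else
    list(pine_height = c(15, 20), altitude = c(1100, 1280))
  tp <- truth_params(terms = terms)
  list(stack = stack, tp = tp, suit = true_suitability(stack, tp))
}

# Separable two-class sample: presences positive on feature 1.
separable_sample <- function(n_per_class = 30, p = 3, seed = 1L) {
  set.seed(seed)
  X <- matrix(rnorm(2 * n_per_class * p), ncol = p)
  colnames(X) <- paste0("f", seq_len(p))
  y <- rep(c(1, 0), each = n_per_class)
  X[, 1] <- ifelse(y == 1, abs(X[, 1]) + 0.5, -abs(X[, 1]) - 0.5)
  sample_set(X, y)
}

fast_hp <- function(...) bct_hyperparams(max_trees = 300L, ...)
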