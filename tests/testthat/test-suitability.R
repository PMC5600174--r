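test_that("sample_background draws uniformly without replacement", {
  stack <- tiny_stack(10, 10)
  n_valid <- sum(attr(stack_matrix(stack), "valid"))
  all_cells <- sample_background(stack, n_valid, seed = 1L)
  expect_equal(length(all_cells), n_valid)
  expect_equal(length(unique(all_cells)), n_valid)  # exhaustive draw

  expect_false(identical(sample_background(stack, 10, seed = 1L),
                         sample_background(stack, 10, seed = 2L)))
  expect_error(sample_background(stack, n_valid + 1), "available")

  # exclusion honoured
  ex <- 1:20
  draw <- sample_background(stack, 50, seed = 3L, exclude = ex)
  expect_length(intersect(draw, ex), 0)

  # inclusion frequencies ~ binomial(n draws, n/100)
  counts <- integer(100)
  n_rep <- 10000
  for (b in seq_len(n_rep)) {
    d <- sample_background(stack, 10, seed = 10000L + b)
    counts[d] <- counts[d] + 1L
  }
  expect_true(all(abs(counts / n_rep - 0.1) <
                    3 * sqrt(0.1 * 0.9 / n_rep) + 0.01))
})

test_that("bootstrap_presence preserves size and matches the analytic exclusion rate", {
  expect_equal(bootstrap_presence(rep(7L, 59), seed = 1L), rep(7L, 59))
  expect_identical(bootstrap_presence(1:59, seed = 4L),
                   bootstrap_presence(1:59, seed = 4L))
  # fraction of originals absent from a bootstrap ~ (1 - 1/59)^59
  absent <- vapply(1:400, function(b) {
    bs <- bootstrap_presence(1:59, seed = b)
    mean(!(1:59 %in% bs))
  }, numeric(1))
  expect_equal(mean(absent), (1 - 1 / 59)^59, tolerance = 0.02)
})

test_that("fit_bct: separable data, degenerate labels, no-learning limit", {
  s <- separable_sample()
  set.seed(1)
  m <- fit_bct(s, fast_hp(n_trees = 300L))
  expect_equal(auc_mw(m$train_prob, s$labels), 1)

  expect_error(fit_bct(sample_set(s$features, rep(1, 60)),
                       fast_hp(n_trees = 50L)), "both classes")
  both <- c(1:4, 31:34)  # 8 rows, both classes present
  expect_error(fit_bct(sample_set(s$features[both, ], s$labels[both]),
                       fast_hp(n_trees = 50L)), "at least 10")

  # nu = 0: predictions stay at the base rate
  set.seed(1)
  m0 <- fit_bct(s, bct_hyperparams(n_trees = 100L, learning_rate = 0,
                                   max_trees = 100L))
  expect_equal(unique(round(predict(m0, s$features), 12)), 0.5)
})

test_that("select_n_trees steps by 50 and collapses on pure noise", {
  s <- separable_sample(n_per_class = 30)
  nt <- select_n_trees(s, fast_hp(), seed = 1L)
  expect_gt(nt, 0)
  expect_equal(as.integer(nt) %% 50L, 0L)

  # pure-noise labels: argmin within the first patience window mostly
  set.seed(2)
  small <- vapply(1:20, function(b) {
    Xn <- matrix(rnorm(40 * 3), 40, 3)
    sn <- sample_set(Xn, rep(c(0, 1), 20))
    as.integer(select_n_trees(sn, fast_hp(), seed = b))
  }, integer(1))
  expect_gte(mean(small <= 6 * 50), 0.8)
})

test_that("auc_mw matches exhaustive pair counting and tie convention", {
  # frozen: {0.9, 0.8, 0.4 | 0.7, 0.3, 0.2} -> 8/9 by pair enumeration
  scores <- c(0.9, 0.8, 0.4, 0.7, 0.3, 0.2)
  labels <- c(1, 1, 1, 0, 0, 0)
  expect_equal(auc_mw(scores, labels), 8 / 9)
  expect_equal(auc_mw(rep(0.5, 10), rep(c(0, 1), 5)), 0.5)
  expect_equal(auc_mw(c(3, 2, 1), c(1, 1, 0)), 1)

  set.seed(8)
  for (rep in 1:20) {
    sc <- sample(seq(0, 1, by = 0.1), 30, replace = TRUE)  # with ties
    lb <- rbinom(30, 1, 0.5)
    if (length(unique(lb)) < 2) next
    expect_equal(auc_mw(sc, lb), auc_pair_oracle(sc, lb))
  }
})

test_that("cv_auc is perfect on separable data and honours fixed n_trees", {
  s <- separable_sample(n_per_class = 25)
  a <- cv_auc(s, fast_hp(n_trees = 200L), k = 5, seed = 1L)
  expect_gt(a, 0.95)
  expect_equal(attr(a, "n_trees"), 200L)
})

test_that("confusion_metrics implements the 2x2 definitions", {
  expect_equal(unname(confusion_metrics(c(0.9, 0.9, 0.1, 0.1), c(1, 1, 0, 0))),
               c(1, 1, 1, 1))
  m <- confusion_metrics(rep(1, 6), c(1, 1, 1, 0, 0, 0))
  expect_equal(unname(m[c("sensitivity", "specificity")]), c(1, 0))
  # frozen 2x2: TP 3, FN 1, FP 1, TN 3 -> all four 0.75
  pred <- c(0.9, 0.9, 0.9, 0.1, 0.9, 0.1, 0.1, 0.1)
  lab <- c(1, 1, 1, 1, 0, 0, 0, 0)
  expect_equal(unname(confusion_metrics(pred, lab)), rep(0.75, 4))
})

test_that("variable_importance normalizes to 100 and isolates single drivers", {
  s <- separable_sample(n_per_class = 30, p = 4)
  set.seed(3)
  m <- fit_bct(s, fast_hp(n_trees = 200L))
  imp <- variable_importance(m)
  expect_equal(sum(imp), 100, tolerance = 1e-6)
  expect_true(all(imp >= 0))
  expect_equal(which.max(imp), 1L, ignore_attr = TRUE)  # f1 drives labels
})

test_that("partial_dependence equals the row-loop oracle and is flat for unused variables", {
  s <- separable_sample(n_per_class = 12, p = 3)
  set.seed(4)
  m <- fit_bct(s, fast_hp(n_trees = 120L))
  grid <- seq(-2, 2, length.out = 7)
  pd <- partial_dependence(m, "f1", grid)
  expect_equal(pd$p, pd_row_oracle(m, "f1", grid), tolerance = 1e-12)

  imp <- variable_importance(m)
  if (imp["f3"] == 0) {
    pd3 <- partial_dependence(m, "f3", grid)
    expect_equal(diff(range(pd3$p)), 0)
  }
  expect_error(partial_dependence(m, "nope", grid), "unknown variable")
})

test_that("run_ensemble: determinism, averaging, prediction bounds", {
  w <- two_driver_world(nrow = 30, ncol = 30, seed = 9L)
  nests <- simulate_nests(w$suit, n = 30, seed = 2L)
  hp <- fast_hp(n_trees = 150L)
  e1 <- run_ensemble(w$stack, nests$cell, hp, n_runs = 2, master_seed = 5L,
                     pd_grid_n = 20L)
  e2 <- run_ensemble(w$stack, nests$cell, hp, n_runs = 2, master_seed = 5L,
                     pd_grid_n = 20L)
  expect_equal(e1$metrics, e2$metrics)
  expect_equal(e1$prediction$values, e2$prediction$values)
  e3 <- run_ensemble(w$stack, nests$cell, hp, n_runs = 2, master_seed = 6L,
                     pd_grid_n = 20L)
  expect_false(identical(e1$prediction$values, e3$prediction$values))

  expect_equal(sum(e1$importance), 100, tolerance = 1e-6)
  expect_true(all(e1$prediction$values >= 0 & e1$prediction$values <= 1,
                  na.rm = TRUE))

  # n_runs = 1: ensemble equals its single run
  e4 <- run_ensemble(w$stack, nests$cell, hp, n_runs = 1, master_seed = 5L,
                     pd_grid_n = 20L)
  expect_equal(unname(e4$importance),
               unname(variable_importance(e4$runs[[1]])))
  expect_true(all(is.na(e4$metrics$sd)))  # sd undefined for a single run
})

test_that("predict_map averages runs, propagates nodata, transfers to new stacks", {
  w <- two_driver_world(nrow = 30, ncol = 30, seed = 13L, ramps = "sharp")
  nests <- simulate_nests(w$suit, n = 40, seed = 3L)
  e <- run_ensemble(w$stack, nests$cell, fast_hp(n_trees = 200L),
                    n_runs = 3, master_seed = 2L, pd_grid_n = 10L,
                    predict_stack = FALSE)

  # constant stack -> constant map
  const_layers <- lapply(w$stack$layers, function(l)
    raster_grid(matrix(l$values[1, 1], 5, 5), l$cell_size))
  cm <- predict_map(e, env_stack(const_layers))
  expect_equal(diff(range(cm$values)), 0)

  # nodata propagates
  st2 <- w$stack
  st2$layers$altitude$values[1, 1] <- NA
  pm <- predict_map(e, st2)
  expect_true(is.na(pm$values[1, 1]))

  # transfer: predictions rank-correlate with truth on a fresh landscape
  w2 <- two_driver_world(nrow = 30, ncol = 30, seed = 77L, ramps = "sharp")
  pm2 <- predict_map(e, w2$stack)
  expect_gt(cor(as.vector(pm2$values), as.vector(w2$suit$values),
                method = "spearman"), 0.7)
})

test_that("area_by_suitability matches the histogram oracle and partitions area", {
  # 100 cells of 50 m at 0.6: area above 0.5 is 25 ha
  r <- raster_grid(matrix(0.6, 10, 10), 50)
  a <- area_by_suitability(r)
  expect_equal(a$above$area_ha[a$above$threshold == 0.5], 25)

  set.seed(6)
  v <- matrix(runif(400), 20, 20)
  v[sample(400, 13)] <- NA
  rm <- raster_grid(v, 50)
  breaks <- c(0, 0.5, 1)
  a2 <- area_by_suitability(rm, breaks = breaks)
  expect_equal(a2$classes$n_cells, class_count_oracle(v, breaks))
  expect_equal(sum(a2$classes$area_ha), sum(!is.na(v)) * 0.25)

  a3 <- area_by_suitability(rm)
  expect_equal(a3$classes$n_cells, class_count_oracle(v, seq(0, 1, 0.1)))
  expect_error(area_by_suitability(raster_grid(matrix(2, 2, 2), 50)),
               "0, 1")
})
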