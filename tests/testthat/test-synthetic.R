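test_that("generate_landscape is reproducible and respects ranges", {
  cfg <- landscape_config(nrow = 40, ncol = 40, seed = 7L)
  s1 <- generate_landscape(cfg)
  s2 <- generate_landscape(cfg)
  expect_identical(s1, s2)
  s3 <- generate_landscape(landscape_config(nrow = 40, ncol = 40, seed = 8L))
  expect_false(identical(s1$layers$altitude$values, s3$layers$altitude$values))

  for (nm in predictor_names()) {
    rng <- cfg$ranges[[nm]]
    v <- s1$layers[[nm]]$values
    expect_gte(min(v), rng[1])
    expect_lte(max(v), rng[2])
  }
})

test_that("cross-correlation control works at zero and at a positive value", {
  s0 <- generate_landscape(landscape_config(nrow = 100, ncol = 100,
                                            cross_cor = 0, seed = 21L))
  r0 <- cor(as.vector(s0$layers$pine_height$values),
            as.vector(s0$layers$tree_cover$values))
  expect_lt(abs(r0), 0.1)

  s9 <- generate_landscape(landscape_config(nrow = 100, ncol = 100,
                                            cross_cor = 0.9, seed = 21L))
  r9 <- cor(as.vector(s9$layers$pine_height$values),
            as.vector(s9$layers$tree_cover$values))
  expect_gt(r9, 0.6)
})

test_that("true_suitability follows the logistic-product closed form", {
  # single synthetic cell pushed through a hand-built 1x1 stack
  mk <- function(ph, tc, alt, rain) {
    layers <- lapply(predictor_names(), function(nm)
      raster_grid(matrix(0, 1, 1), 50))
    names(layers) <- predictor_names()
    layers$pine_height$values[] <- ph
    layers$tree_cover$values[] <- tc
    layers$altitude$values[] <- alt
    layers$summer_rainfall$values[] <- rain
    env_stack(layers)
  }
  tp <- truth_params()
  # high-plateau cell
  expect_gt(true_suitability(mk(25, 45, 1400, 20), tp)$values[1, 1], 0.8)
  # hostile cell
  expect_lt(true_suitability(mk(10, 10, 600, 5), tp)$values[1, 1], 0.01)
  # all-midpoint cell: each of four ramps is exactly 1/2
  expect_equal(true_suitability(mk(17.5, 31, 1190, 16.5), tp)$values[1, 1],
               0.5^4)
  # monotone in pine height across its rise interval
  suits <- vapply(seq(15, 20, by = 0.5), function(ph)
    true_suitability(mk(ph, 45, 1400, 20), tp)$values[1, 1], numeric(1))
  expect_true(all(diff(suits) >= 0))

  tp2 <- truth_params(terms = list(pine_height = c(15, 20)))
  expect_error(true_suitability(
    structure(list(layers = list()), class = "env_stack"), tp2),
    "pine_height")
})

test_that("simulate_nests: forced support, determinism, uniform frequencies", {
  v <- matrix(0, 10, 10)
  v[1:59] <- 1
  suit <- raster_grid(v, 50)
  nests <- simulate_nests(suit, n = 59, seed = 3L)
  expect_setequal(nests$cell, 1:59)

  expect_identical(simulate_nests(suit, 59, seed = 5L),
                   simulate_nests(suit, 59, seed = 5L))
  expect_error(simulate_nests(raster_grid(matrix(0, 5, 5), 50), 10),
               "positive suitability")

  # uniform suitability: per-cell selection frequencies pass a chi-square GOF
  unif <- raster_grid(matrix(1, 5, 5), 50)
  counts <- integer(25)
  for (b in 1:1000) {
    ns <- simulate_nests(unif, n = 5, seed = 1000L + b)
    counts[ns$cell] <- counts[ns$cell] + 1L
  }
  gof <- chisq.test(counts)
  expect_gt(gof$p.value, 0.01)
})

test_that("simulate_transects obeys the stated point-process limits", {
  w <- two_driver_world(nrow = 30, ncol = 30, seed = 5L)
  units <- make_transect_units(w$suit, n_units = 20)

  # density scale zero: empty process
  s0 <- simulate_transects(w$suit, units, w$tp, years = 1:3,
                           density_scale = 0, seed = 1L)
  expect_true(all(s0$counts$n_detected == 0))
  expect_equal(nrow(s0$distances), 0)

  # sigma -> Inf on a uniform surface: detected ~= true counts
  unif <- raster_grid(matrix(1, 30, 30), 50)
  tp_inf <- truth_params(terms = list(), lambda1 = 2,
                         sigma_true = 1e9)
  sim <- simulate_transects(unif, units, tp_inf, years = 1:1000, seed = 2L)
  expect_equal(mean(sim$counts$n_detected), 2, tolerance = 0.02)
  expect_equal(mean(sim$counts$n_detected), mean(sim$counts$n_true))

  # Poisson linearity: doubling the density scale doubles mean counts
  tp2 <- truth_params(terms = list(), lambda1 = 1, sigma_true = 60)
  s1 <- simulate_transects(unif, units, tp2, years = 1:300,
                           density_scale = 1, seed = 3L)
  s2 <- simulate_transects(unif, units, tp2, years = 1:300,
                           density_scale = 2, seed = 4L)
  expect_equal(mean(s2$counts$n_true) / mean(s1$counts$n_true), 2,
               tolerance = 0.05)
})

test_that("empirical detection curve of simulate_transects is half-normal", {
  # uniform surface, ~10^4 true birds; detected distances are uniform draws
  # thinned by the half-normal, so per-bin detection frequency is
  # (# detected in bin) / (expected # true in bin)
  unif <- raster_grid(matrix(1, 20, 20), 50)
  units <- make_transect_units(unif, n_units = 10)
  sigma <- 60; w_max <- 125
  tp <- truth_params(terms = list(), lambda1 = 2, sigma_true = sigma)
  sim <- simulate_transects(unif, units, tp, years = 1:500,
                            w_max = w_max, seed = 10L)
  n_true <- sum(sim$counts$n_true)
  expect_gt(n_true, 9000)
  edges <- seq(0, w_max, by = 12.5)
  obs <- table(cut(sim$distances$distance_m, edges))
  expected_per_bin <- n_true / (length(edges) - 1)
  emp <- as.numeric(obs) / expected_per_bin
  mid <- (edges[-1] + edges[-length(edges)]) / 2
  expect_lt(max(abs(emp - exp(-mid^2 / (2 * sigma^2)))), 0.05)
})
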