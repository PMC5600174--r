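test_that("suitability_at_units: constants, forced islands, brute-force oracle", {
  const <- raster_grid(matrix(0.37, 12, 12), 50)
  u <- data.frame(x = c(100, 300), y = c(100, 450))
  expect_equal(suitability_at_units(const, u), c(0.37, 0.37))

  # 4x4 island of ones centred on the centroid in a sea of zeros
  v <- matrix(0, 12, 12)
  v[5:8, 5:8] <- 1
  isl <- raster_grid(v, 50)
  centre <- data.frame(x = 6.5 * 50 - 25, y = (12 - 6.5) * 50 + 25)
  # centroid exactly at the island centre: its 16 nearest cells are the island
  centre <- data.frame(x = 300, y = 300)
  expect_equal(suitability_at_units(isl, centre), 1)

  set.seed(7)
  vr <- matrix(runif(144), 12, 12)
  vr[sample(144, 10)] <- NA
  rr <- raster_grid(vr, 50)
  pts <- data.frame(x = runif(5, 50, 550), y = runif(5, 50, 550))
  got <- suitability_at_units(rr, pts)
  want <- vapply(1:5, function(i)
    nearest_k_oracle(rr, pts$x[i], pts$y[i]), numeric(1))
  expect_equal(got, want, tolerance = 1e-12)
})

test_that("morans_i: sign structure, degenerate input, double-sum oracle", {
  # checkerboard on a rook-adjacency 4x4 grid is negatively autocorrelated
  g <- expand.grid(r = 1:4, c = 1:4)
  W <- matrix(0, 16, 16)
  for (i in 1:16) for (j in 1:16)
    if (abs(g$r[i] - g$r[j]) + abs(g$c[i] - g$c[j]) == 1) W[i, j] <- 1
  chk <- (-1)^(g$r + g$c)
  mi <- morans_i(chk, W, n_perm = 99, seed = 1L)
  expect_lt(mi$I, 0)

  expect_error(morans_i(rep(1, 16), W), "constant")

  set.seed(8)
  for (rep in 1:5) {
    vals <- rnorm(6)
    Wt <- matrix(runif(36), 6, 6); diag(Wt) <- 0
    mi2 <- morans_i(vals, Wt, n_perm = 49, seed = 2L)
    expect_equal(mi2$I, moran_oracle(vals, Wt), tolerance = 1e-12)
  }

  # permutation and normal p agree in order of magnitude on a smooth field
  smooth <- g$r + g$c + rnorm(16, 0, 0.3)
  p_perm <- morans_i(smooth, W, n_perm = 999, seed = 3L)$p
  p_norm <- morans_i(smooth, W, method = "normal")$p
  expect_lt(p_perm, 0.05)
  expect_lt(p_norm, 0.05)
})

test_that("build_sevm produces orthogonal eigenvectors with PCNM structure", {
  # collinear equally-spaced points: filters are the classic transect waves,
  # broad-scale first (one sign change), finer scales after
  line <- data.frame(x = seq(0, 900, by = 100), y = 0)
  sv <- build_sevm(line)
  sign_changes <- function(v) sum(diff(sign(v)) != 0)
  sc <- apply(sv$vectors, 2, sign_changes)
  expect_equal(sc[1], 1)
  expect_true(all(diff(sc) > 0))

  set.seed(9)
  pts <- data.frame(x = runif(30, 0, 1000), y = runif(30, 0, 1000))
  sv2 <- build_sevm(pts)
  G <- crossprod(sv2$vectors)
  expect_equal(G, diag(ncol(sv2$vectors)), tolerance = 1e-8,
               ignore_attr = TRUE)
  expect_true(all(diff(sv2$eigenvalues) <= 1e-12))  # decreasing order

  # eigenvalues match an independent dense eigensolve of the same matrix
  five <- data.frame(x = c(0, 1, 3, 7, 10), y = c(0, 2, 1, 4, 0))
  sv5 <- build_sevm(five)
  n <- 5
  D <- as.matrix(dist(five))
  W <- (D <= sv5$threshold) * 1; diag(W) <- 0
  H <- diag(n) - 1 / n
  ev <- eigen((H %*% W %*% H + t(H %*% W %*% H)) / 2)$values
  expect_equal(sv5$eigenvalues, ev[ev > 1e-8], tolerance = 1e-10)

  # gabriel alternative yields a symmetric zero-diagonal adjacency
  svg <- build_sevm(pts, connectivity = "gabriel")
  expect_true(all(svg$W == t(svg$W)) && all(diag(svg$W) == 0))
  expect_error(build_sevm(five[1:2, ]), "at least 3")
})

test_that("select_filters: planted signal, alpha = 1 boundary", {
  set.seed(10)
  pts <- data.frame(x = runif(40, 0, 1000), y = runif(40, 0, 1000))
  sv <- build_sevm(pts)
  xb <- matrix(rnorm(40), ncol = 1)

  # y equal to one candidate plus tiny noise: that filter goes in first
  y <- sv$vectors[, 2] + rnorm(40, 0, 0.01)
  sel <- select_filters(y, xb, sv, alpha = 0.05, n_perm = 199, seed = 1L)
  expect_true(2 %in% sel$selected)
  expect_equal(sel$selected[1], 2)
  expect_gt(sel$residual_p, 0.05)  # stopping contract holds post hoc

  # alpha = 1: any I is "nonsignificant", so zero filters
  sel1 <- select_filters(y, xb, sv, alpha = 1, n_perm = 99, seed = 1L)
  expect_length(sel1$selected, 0)
  expect_equal(ncol(sel1$filters), 0)
})

test_that("ols_hc4m: formula checks against the element-wise oracle", {
  # balanced leverage: delta_i = 2 for all i, so weights are e^2/(1-h)^2
  X_bal <- cbind(1, c(1, 1, -1, -1), c(1, -1, 1, -1))
  y_bal <- c(4, 2, 1, 0.5)
  f_bal <- ols_hc4m(y_bal, X_bal)
  h <- 3 / 4
  w_expect <- f_bal$residuals^2 / (1 - h)^2
  XtXinv <- solve(t(X_bal) %*% X_bal)
  cov_expect <- XtXinv %*% t(X_bal) %*% diag(w_expect) %*% X_bal %*% XtXinv
  expect_equal(unname(f_bal$cov), cov_expect, tolerance = 1e-12)

  # 5-row hand matrix vs the independent oracle
  X5 <- cbind(intercept = 1, a = c(0, 1, 2, 3, 10), b = c(1, 0, 2, 1, 3))
  y5 <- c(1, 2, 2, 4, 12)
  f5 <- ols_hc4m(y5, X5)
  expect_equal(unname(f5$cov), unname(hc4m_oracle(y5, X5)),
               tolerance = 1e-10)

  # homoscedastic large n: HC4m se ~ classical se
  set.seed(11)
  n <- 2000
  x <- rnorm(n); y <- 1 + 2 * x + rnorm(n)
  f <- ols_hc4m(y, cbind(intercept = 1, x = x))
  cls <- summary(lm(y ~ x))$coefficients[, "Std. Error"]
  expect_equal(unname(f$se / cls), c(1, 1), tolerance = 0.1)

  expect_error(ols_hc4m(y5, cbind(1, X5[, 2], X5[, 2])), "rank deficient")
})

test_that("variance_partition sums to R2_full with correct degenerate limits", {
  set.seed(12)
  n <- 200
  suit <- rnorm(n)
  filt <- matrix(rnorm(n), ncol = 1)
  suit_o <- resid(lm(suit ~ filt))  # orthogonalized
  y <- suit_o + as.numeric(filt) + rnorm(n)
  vp <- variance_partition(y, suit_o, filt)
  expect_equal(vp$unique_suitability + vp$unique_spatial + vp$shared,
               vp$total, tolerance = 1e-10)
  expect_lt(abs(vp$shared), 0.02)  # near-orthogonal regressors share ~0

  # filters identical to suitability: all shared
  vp2 <- variance_partition(y, suit_o, matrix(suit_o, ncol = 1))
  expect_equal(vp2$unique_suitability, 0, tolerance = 1e-10)
  expect_equal(vp2$unique_spatial, 0, tolerance = 1e-10)
  expect_equal(vp2$shared, vp2$total, tolerance = 1e-10)

  # known effect sizes: partition matches the analytic expectation
  set.seed(13)
  a <- 1; b <- 2
  s2 <- rnorm(5000); f2 <- rnorm(5000)
  y2 <- a * s2 + b * f2 + rnorm(5000)
  vp3 <- variance_partition(y2, s2, matrix(f2, ncol = 1))
  tot_var <- a^2 + b^2 + 1
  expect_equal(vp3$unique_suitability, a^2 / tot_var, tolerance = 0.05)
  expect_equal(vp3$unique_spatial, b^2 / tot_var, tolerance = 0.05)

  # no filters: everything loads on suitability
  vp4 <- variance_partition(y2, s2, matrix(numeric(0), nrow = 5000, ncol = 0))
  expect_equal(vp4$unique_spatial, 0)
  expect_equal(vp4$total, vp4$unique_suitability)
})

test_that("quantile_reg: exact fits, check-loss optimality, median ~ OLS", {
  # y = x exactly: slope 1, zero loss at every tau
  x <- seq(0, 1, length.out = 30)
  X <- cbind(intercept = 1, x = x)
  fit <- quantile_reg(x, X, tau = c(0.1, 0.5, 0.9), n_boot = 19, seed = 1L)
  expect_equal(fit$estimate[fit$term == "x"], rep(1, 3), tolerance = 1e-8)
  expect_true(all(attr(fit, "loss") < 1e-10))

  # solution check loss never exceeds the OLS candidate's
  set.seed(14)
  for (rep in 1:10) {
    n <- 60
    xr <- runif(n); yr <- 1 + 2 * xr + rnorm(n) * (0.2 + xr)
    Xr <- cbind(1, xr)
    b_ols <- qr.coef(qr(Xr), yr)
    for (tau in c(0.1, 0.5, 0.9)) {
      fr <- quantile_reg(yr, Xr, tau = tau, n_boot = 9, seed = rep)
      expect_lte(attr(fr, "loss")[[1]],
                 check_loss_oracle(yr, Xr, b_ols, tau) + 1e-10)
    }
  }

  # symmetric noise: median slope ~ OLS slope at n = 1000
  set.seed(15)
  n <- 1000
  xs <- runif(n); ys <- 0.5 + 1.5 * xs + rnorm(n, 0, 0.5)
  Xs <- cbind(intercept = 1, x = xs)
  f50 <- quantile_reg(ys, Xs, tau = 0.5, n_boot = 49, seed = 2L)
  b_ols <- unname(qr.coef(qr(Xs), ys)[2])
  expect_equal(f50$estimate[f50$term == "x"], b_ols, tolerance = 0.05)
  expect_error(quantile_reg(ys, Xs, tau = 1.2), "in \\(0, 1\\)")
})

test_that("link_abundance assembles the full analysis", {
  w <- two_driver_world(nrow = 30, ncol = 30, seed = 20L)
  units <- make_transect_units(w$suit, n_units = 40)
  sim <- simulate_transects(w$suit, units, w$tp, years = 1:6, seed = 4L)
  mean_count <- tapply(sim$counts$n_detected,
                       factor(sim$counts$unit_id, levels = units$unit_id),
                       mean)
  df <- data.frame(unit_id = units$unit_id, x = units$x, y = units$y,
                   mean_count = as.numeric(mean_count))
  lk <- link_abundance(df, w$suit, n_perm = 99, n_boot = 49, seed = 1L)
  expect_s3_class(lk, "link_fit")
  expect_gt(lk$ols$coefficients["suitability"], 0)
  expect_true(lk$ols$r_squared >= 0 && lk$ols$r_squared <= 1)
  part <- lk$partition
  expect_equal(part$unique_suitability + part$unique_spatial + part$shared,
               lk$ols$r_squared, tolerance = 1e-10)
  expect_equal(sort(unique(lk$quantiles$tau)), c(0.1, 0.5, 0.9))
  expect_error(link_abundance(df[, -4], w$suit), "mean_count")
})
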