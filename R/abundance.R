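#' Suitability at transect units by the nearest-16-cell rule
#'
#' For each unit centroid, the mean of the 16 non-nodata cells whose centres
#' are closest in Euclidean distance. Ties are broken deterministically by
#' (distance, row, col) lexicographic order.
#'
#' @param map a [raster_grid()]
#' @param centroids data.frame with `x`, `y` (m)
#' @param k number of nearest cells (default 16)
#' @return numeric vector, one value per centroid
#' @export
suitability_at_units <- function(map, centroids, k = 16L) {
  stopifnot(is_raster_grid(map))
  cc <- cell_centres(map)
  v <- as.vector(map$values)  # column-major; reorder cc to match
  cc <- cc[order(cc$col, cc$row), ]
  ok <- !is.na(v)
  if (sum(ok) < k) stop("fewer than ", k, " non-nodata cells in the map")
  ccx <- cc$x[ok]; ccy <- cc$y[ok]
  ccrow <- cc$row[ok]; cccol <- cc$col[ok]
  vv <- v[ok]
  vapply(seq_len(nrow(centroids)), function(i) {
    d2 <- (ccx - centroids$x[i])^2 + (ccy - centroids$y[i])^2
    o <- order(d2, ccrow, cccol)[seq_len(k)]
    mean(vv[o])
  }, numeric(1))
}

#' Moran's I with a permutation test
#'
#' `I = (n / S0) * sum_ij w_ij z_i z_j / sum_i z_i^2` with `z` the centred
#' values and `S0 = sum(W)`. The two-sided p-value is obtained either by
#' random permutation of the values over locations (`n_perm` draws,
#' comparing `|I - E|` with `E = -1/(n-1)`), or by the normal approximation
#' under the randomization assumption.
#'
#' @param values numeric vector (length >= 4, non-constant)
#' @param W square weights matrix, nonnegative, zero diagonal
#' @param n_perm permutations (default 999)
#' @param seed integer seed
#' @param method "permutation" (default) or "normal"
#' @return list `I`, `expected`, `p`
#' @export
morans_i <- function(values, W, n_perm = 999, seed = 1L,
                     method = c("permutation", "normal")) {
  method <- match.arg(method)
  n <- length(values)
  if (n < 4L) stop("need at least 4 units")
  W <- as.matrix(W)
  if (!all(dim(W) == n)) stop("W must be n x n")
  if (any(W < 0)) stop("weights must be nonnegative")
  if (any(diag(W) != 0)) stop("W must have a zero diagonal")
  if (var(values) == 0) stop("Moran's I is undefined for constant values")
  S0 <- sum(W)
  if (S0 <= 0) stop("W has no positive weights")
  I_of <- function(z) (n / S0) * as.numeric(z %*% W %*% z) / sum(z^2)
  z <- values - mean(values)
  I <- I_of(z)
  E <- -1 / (n - 1)
  if (method == "permutation") {
    set.seed(seed)
    Iperm <- vapply(seq_len(n_perm), function(b) {
      zb <- z[sample.int(n)]
      I_of(zb)
    }, numeric(1))
    p <- (1 + sum(abs(Iperm - E) >= abs(I - E) - 1e-15)) / (n_perm + 1)
  } else {
    # randomization-assumption moments (Cliff & Ord)
    S1 <- sum((W + t(W))^2) / 2
    S2 <- sum((rowSums(W) + colSums(W))^2)
    m2 <- sum(z^2) / n
    m4 <- sum(z^4) / n
    b2 <- m4 / m2^2
    varI <- (n * ((n^2 - 3 * n + 3) * S1 - n * S2 + 3 * S0^2) -
               b2 * ((n^2 - n) * S1 - 2 * n * S2 + 6 * S0^2)) /
      ((n - 1) * (n - 2) * (n - 3) * S0^2) - E^2
    p <- 2 * pnorm(-abs((I - E) / sqrt(varI)))
  }
  list(I = I, expected = E, p = p)
}

# Prim's algorithm: maximum edge weight of the minimum spanning tree --
# the smallest distance threshold keeping a threshold graph connected.
mst_max_edge <- function(D) {
  n <- nrow(D)
  in_tree <- c(TRUE, rep(FALSE, n - 1))
  best <- D[1, ]
  maxe <- 0
  for (step in seq_len(n - 1)) {
    cand <- which(!in_tree)
    j <- cand[which.min(best[cand])]
    maxe <- max(maxe, best[j])
    in_tree[j] <- TRUE
    best <- pmin(best, D[j, ])
  }
  maxe
}

gabriel_adjacency <- function(D2) {
  # edge (i, j) iff no third point lies inside the circle on diameter ij
  n <- nrow(D2)
  W <- matrix(0, n, n)
  for (i in seq_len(n - 1)) for (j in (i + 1):n) {
    ok <- TRUE
    for (m in seq_len(n)) {
      if (m == i || m == j) next
      if (D2[i, m] + D2[j, m] < D2[i, j] - 1e-12) { ok <- FALSE; break }
    }
    if (ok) W[i, j] <- W[j, i] <- 1
  }
  W
}

#' Spatial eigenvector mapping (SEVM) candidate filters
#'
#' Builds a binary spatial connectivity matrix among the unit centroids --
#' by default a distance-threshold graph at the smallest threshold that
#' keeps the graph connected (the maximum minimum-spanning-tree edge), or a
#' Gabriel graph -- double-centres it, and eigen-decomposes. The candidate
#' filters are the eigenvectors with positive eigenvalues, in decreasing
#' eigenvalue order (broad-scale spatial gradients first).
#'
#' @param centroids data.frame with `x`, `y`
#' @param connectivity "threshold" (default) or "gabriel"
#' @param threshold distance threshold (m); default: minimum keeping the
#'   graph connected
#' @return object of class `sevm_filters`: `W`, `eigenvalues` (positive
#'   ones), `vectors` (columns = candidate filters), `threshold`
#' @export
build_sevm <- function(centroids, connectivity = c("threshold", "gabriel"),
                       threshold = NULL) {
  connectivity <- match.arg(connectivity)
  n <- nrow(centroids)
  if (n < 3L) stop("need at least 3 centroids")
  D <- as.matrix(dist(centroids[, c("x", "y")]))
  if (connectivity == "threshold") {
    if (is.null(threshold)) threshold <- mst_max_edge(D)
    W <- (D <= threshold) * 1
    diag(W) <- 0
  } else {
    W <- gabriel_adjacency(D^2)
    threshold <- NA_real_
  }
  H <- diag(n) - matrix(1 / n, n, n)
  C <- H %*% W %*% H
  C <- (C + t(C)) / 2
  e <- eigen(C, symmetric = TRUE)
  pos <- which(e$values > 1e-8)
  structure(list(W = W, eigenvalues = e$values[pos],
                 vectors = e$vectors[, pos, drop = FALSE],
                 threshold = threshold, connectivity = connectivity),
            class = "sevm_filters")
}

#' Forward selection of spatial filters on residual Moran's I
#'
#' Starting from the residuals of `y ~ X_base`, repeatedly adds the
#' candidate eigenvector that most reduces the absolute residual Moran's I,
#' stopping as soon as the residual autocorrelation is nonsignificant at
#' `alpha` (p >= alpha) or candidates are exhausted.
#'
#' @param y response (counts per unit)
#' @param X_base base design matrix without intercept columns of filters
#'   (e.g. a one-column matrix of suitabilities); an intercept is added
#' @param sevm a [build_sevm()] result
#' @param alpha significance level for residual Moran's I (default 0.05)
#' @param n_perm permutations per Moran test (default 999)
#' @param seed integer seed
#' @param method Moran p-value method, see [morans_i()]
#' @return list: `selected` (candidate indices), `filters` (matrix, 0 cols
#'   if none), `residual_I`, `residual_p`, `trace` (data.frame of steps)
#' @export
select_filters <- function(y, X_base, sevm, alpha = 0.05, n_perm = 999,
                           seed = 1L, method = "permutation") {
  stopifnot(inherits(sevm, "sevm_filters"))
  X_base <- as.matrix(X_base)
  cand <- sevm$vectors
  resid_of <- function(Xf) {
    fit <- lm.fit(cbind(1, X_base, Xf), y)
    fit$residuals
  }
  selected <- integer()
  trace <- list()
  repeat {
    Xf <- cand[, selected, drop = FALSE]
    r <- resid_of(Xf)
    mi <- morans_i(r, sevm$W, n_perm = n_perm,
                   seed = derive_seed(seed, paste0("mi-", length(selected))),
                   method = method)
    trace[[length(trace) + 1L]] <-
      data.frame(n_filters = length(selected), I = mi$I, p = mi$p)
    # alpha is a rejection threshold: autocorrelation is "significant" only
    # when p < alpha, so alpha >= 1 disables filtering outright
    if (!(mi$p < alpha && alpha < 1) || length(selected) == ncol(cand)) break
    remaining <- setdiff(seq_len(ncol(cand)), selected)
    absI <- vapply(remaining, function(j) {
      rj <- resid_of(cand[, c(selected, j), drop = FALSE])
      z <- rj - mean(rj)
      abs((length(y) / sum(sevm$W)) *
            as.numeric(z %*% sevm$W %*% z) / sum(z^2))
    }, numeric(1))
    selected <- c(selected, remaining[which.min(absI)])
  }
  last <- trace[[length(trace)]]
  list(selected = selected,
       filters = cand[, selected, drop = FALSE],
       residual_I = last$I, residual_p = last$p,
       trace = do.call(rbind, trace))
}

#' OLS with the HC4m heteroscedasticity-consistent covariance
#'
#' Ordinary least squares with the HC4m sandwich covariance:
#' `cov = (X'X)^-1 X' diag(e_i^2 / (1 - h_i)^delta_i) X (X'X)^-1` where
#' `delta_i = min(1, n h_i / p) + min(1.5, n h_i / p)`, `h_i` the leverage
#' and `p` the number of columns. Two-sided t p-values on `n - p` degrees of
#' freedom.
#'
#' @param y response
#' @param X design matrix including the intercept column
#' @return list: `coefficients`, `se` (HC4m), `t`, `p`, `r_squared`, `cov`,
#'   `fitted`, `residuals`, `df`
#' @export
ols_hc4m <- function(y, X) {
  X <- as.matrix(X)
  n <- nrow(X); p <- ncol(X)
  if (n <= p) stop("need more observations than columns")
  qx <- qr(X)
  if (qx$rank < p) {
    bad <- colnames(X)[qx$pivot[(qx$rank + 1):p]] %||% qx$pivot[(qx$rank + 1):p]
    stop("design matrix is rank deficient; collinear column(s): ",
         paste(bad, collapse = ", "))
  }
  beta <- qr.coef(qx, y)
  fitted <- as.numeric(X %*% beta)
  e <- y - fitted
  XtXinv <- matrix(0, p, p)
  XtXinv[qx$pivot, qx$pivot] <- chol2inv(qr.R(qx))
  h <- rowSums((X %*% XtXinv) * X)
  delta <- pmin(1, n * h / p) + pmin(1.5, n * h / p)
  omega <- e^2 / (1 - h)^delta
  meat <- t(X) %*% (X * omega)
  cov <- XtXinv %*% meat %*% XtXinv
  dimnames(cov) <- list(colnames(X), colnames(X))
  se <- setNames(sqrt(diag(cov)), colnames(X))
  tval <- beta / se
  pval <- 2 * pt(-abs(tval), df = n - p)
  ybar <- mean(y)
  r2 <- 1 - sum(e^2) / sum((y - ybar)^2)
  list(coefficients = beta, se = se, t = tval, p = pval, r_squared = r2,
       cov = cov, fitted = fitted, residuals = e, df = n - p)
}

#' Partition response variance between suitability and space
#'
#' Classic two-set variance partitioning from the R-squared of the full,
#' suitability-only and filters-only regressions:
#' `unique_suitability = R2_full - R2_filters`,
#' `unique_spatial = R2_full - R2_suit`, `shared` the remainder; the three
#' components sum to `R2_full` exactly.
#'
#' @param y response
#' @param suitability per-unit suitability vector
#' @param filters matrix of selected spatial filters (0 columns allowed)
#' @return list `unique_suitability`, `unique_spatial`, `shared`, `total`
#' @export
variance_partition <- function(y, suitability, filters) {
  filters <- as.matrix(filters)
  r2 <- function(X) {
    fit <- lm.fit(cbind(1, X), y)
    1 - sum(fit$residuals^2) / sum((y - mean(y))^2)
  }
  r2_suit <- r2(as.matrix(suitability))
  if (ncol(filters) == 0L) {
    return(list(unique_suitability = r2_suit, unique_spatial = 0,
                shared = 0, total = r2_suit))
  }
  r2_filt <- r2(filters)
  r2_full <- r2(cbind(as.matrix(suitability), filters))
  list(unique_suitability = r2_full - r2_filt,
       unique_spatial = r2_full - r2_suit,
       shared = r2_suit + r2_filt - r2_full,
       total = r2_full)
}

# --- quantile regression -----------------------------------------------

check_loss <- function(r, tau) sum(r * (tau - (r < 0)))

# MM (Hunter-Lange) iterations for the smoothed check loss, from an OLS
# start, with a shrinking smoothing parameter.
rq_mm <- function(y, X, tau, b0 = NULL, maxit = 200, tol = 1e-10) {
  X <- as.matrix(X)
  b <- b0 %||% qr.coef(qr(X), y)
  eps <- max(sd(y), 1e-6) * 1e-2
  xt1 <- colSums(X)
  for (it in seq_len(maxit)) {
    r <- y - as.numeric(X %*% b)
    w <- 1 / (2 * (abs(r) + eps))
    XtW <- t(X * w)
    b_new <- tryCatch(
      solve(XtW %*% X, XtW %*% y + (tau - 0.5) * xt1),
      error = function(e) b)
    if (max(abs(b_new - b)) < tol * (1 + max(abs(b)))) {
      b <- b_new
      if (eps <= 1e-10) break
      eps <- eps / 10
    } else b <- as.numeric(b_new)
  }
  as.numeric(b)
}

# Exact vertex polish: a quantile-regression solution interpolates p points;
# enumerate basic solutions through the low-|residual| points near the MM
# solution and keep the check-loss minimizer.
rq_polish <- function(y, X, tau, b) {
  X <- as.matrix(X)
  p <- ncol(X)
  r <- y - as.numeric(X %*% b)
  pool <- order(abs(r))[seq_len(min(length(y), 2 * p + 4))]
  best <- b
  best_loss <- check_loss(y - as.numeric(X %*% b), tau)
  for (idx in as.data.frame(combn(pool, p))) {
    Xs <- X[idx, , drop = FALSE]
    bs <- tryCatch(solve(Xs, y[idx]), error = function(e) NULL)
    if (is.null(bs)) next
    loss <- check_loss(y - as.numeric(X %*% bs), tau)
    if (loss < best_loss - 1e-12) {
      best_loss <- loss
      best <- as.numeric(bs)
    }
  }
  structure(best, loss = best_loss)
}

#' Quantile regression with bootstrap standard errors
#'
#' Minimizes the check loss `sum rho_tau(y - Xb)` (MM iterations from the
#' OLS start plus an exact vertex polish), for each requested quantile.
#' Standard errors come from an xy-pair bootstrap; p-values use a t
#' reference with the bootstrap standard error (the convention of
#' distance-matrix quantile-regression summaries).
#'
#' @param y response
#' @param X design matrix including the intercept column
#' @param tau quantile(s) in (0, 1), default `c(0.1, 0.5, 0.9)`
#' @param n_boot bootstrap replicates (default 999)
#' @param seed integer seed
#' @return data.frame with one row per (tau, coefficient): `tau`, `term`,
#'   `estimate`, `se`, `t`, `p`; attribute `loss` holds the minimized check
#'   loss per tau
#' @export
quantile_reg <- function(y, X, tau = c(0.1, 0.5, 0.9), n_boot = 999,
                         seed = 1L) {
  X <- as.matrix(X)
  if (any(tau <= 0 | tau >= 1)) stop("tau must be in (0, 1)")
  n <- nrow(X); p <- ncol(X)
  if (n <= p) stop("need more observations than columns")
  terms <- colnames(X) %||% paste0("b", seq_len(p) - 1)
  out <- list()
  losses <- numeric(length(tau))
  for (ti in seq_along(tau)) {
    tt <- tau[ti]
    b <- rq_polish(y, X, tt, rq_mm(y, X, tt))
    losses[ti] <- attr(b, "loss")
    set.seed(derive_seed(seed, paste0("rqboot-", tt)))
    bb <- matrix(NA_real_, n_boot, p)
    for (bi in seq_len(n_boot)) {
      idx <- sample.int(n, n, replace = TRUE)
      bb[bi, ] <- rq_mm(y[idx], X[idx, , drop = FALSE], tt)
    }
    se <- apply(bb, 2, sd)
    tv <- as.numeric(b) / se
    out[[ti]] <- data.frame(tau = tt, term = terms,
                            estimate = as.numeric(b), se = se, t = tv,
                            p = 2 * pt(-abs(tv), df = n - p))
  }
  res <- do.call(rbind, out)
  rownames(res) <- NULL
  attr(res, "loss") <- setNames(losses, tau)
  res
}

#' Link local abundance to predicted suitability
#'
#' The full abundance-suitability analysis on the transect units: suitability
#' at units by the nearest-16 rule, SEVM filter selection until residual
#' Moran's I is nonsignificant, HC4m-robust OLS, variance partitioning, and
#' bootstrap quantile regression at `taus`.
#'
#' @param units data.frame `unit_id`, `x`, `y`, `mean_count`
#' @param map suitability [raster_grid()]
#' @param alpha Moran significance level for filter selection
#' @param taus quantiles for the quantile regression
#' @param n_perm Moran permutations
#' @param n_boot quantile-regression bootstrap replicates
#' @param seed integer seed
#' @param connectivity passed to [build_sevm()]
#' @return object of class `link_fit`: `suitability` (per unit), `sevm`,
#'   `selection`, `ols` (HC4m fit), `partition`, `quantiles`, `n_filters`
#' @export
link_abundance <- function(units, map, alpha = 0.05,
                           taus = c(0.1, 0.5, 0.9), n_perm = 999,
                           n_boot = 999, seed = 1L,
                           connectivity = "threshold") {
  need <- c("unit_id", "x", "y", "mean_count")
  miss <- setdiff(need, names(units))
  if (length(miss)) stop("units is missing column(s): ",
                         paste(miss, collapse = ", "))
  if (any(units$mean_count < 0)) stop("counts must be >= 0")
  y <- units$mean_count
  suit <- suitability_at_units(map, units)
  sevm <- build_sevm(units, connectivity = connectivity)
  sel <- select_filters(y, suit, sevm, alpha = alpha, n_perm = n_perm,
                        seed = derive_seed(seed, "filters"))
  X <- cbind(intercept = 1, suitability = suit)
  if (length(sel$selected))
    X <- cbind(X, setNames(as.data.frame(sel$filters),
                           paste0("filter", seq_along(sel$selected))))
  X <- as.matrix(X)
  ols <- ols_hc4m(y, X)
  part <- variance_partition(y, suit, sel$filters)
  qr_fit <- quantile_reg(y, X, tau = taus, n_boot = n_boot,
                         seed = derive_seed(seed, "quantiles"))
  structure(list(suitability = suit, sevm = sevm, selection = sel,
                 ols = ols, partition = part, quantiles = qr_fit,
                 n_filters = length(sel$selected)),
            class = "link_fit")
}

#' @export
print.link_fit <- function(x, ...) {
  cat(sprintf("link_fit: %d spatial filter(s), R2 = %.3f\n",
              x$n_filters, x$ols$r_squared))
  cat(sprintf("  suitability slope = %.3f (HC4m se %.3f, p = %.4g)\n",
              x$ols$coefficients["suitability"], x$ols$se["suitability"],
              x$ols$p["suitability"]))
  qs <- x$quantiles[x$quantiles$term == "suitability", ]
  for (i in seq_len(nrow(qs)))
    cat(sprintf("  tau = %.1f: b = %.3f (se %.3f, p = %.4g)\n",
                qs$tau[i], qs$estimate[i], qs$se[i], qs$p[i]))
  invisible(x)
}
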