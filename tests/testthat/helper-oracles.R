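# Independent brute-force oracles. These deliberately share no code with the
# package implementations they check: plain loops and quadrature only.

# Horn 8-neighbour slope/aspect at the centre of a 3x3 elevation window.
horn_oracle <- function(z, cs) {
  a <- z[1, 1]; b <- z[1, 2]; cc <- z[1, 3]
  d <- z[2, 1];               f <- z[2, 3]
  g <- z[3, 1]; h <- z[3, 2]; i <- z[3, 3]
  dzdx <- ((cc + 2 * f + i) - (a + 2 * d + g)) / (8 * cs)
  dzdy <- ((a + 2 * b + cc) - (g + 2 * h + i)) / (8 * cs)
  grad <- sqrt(dzdx^2 + dzdy^2)
  az <- atan2(-dzdx, -dzdy)
  list(slope_pct = 100 * grad,
       northness = if (grad == 0) 0 else cos(az),
       westness = if (grad == 0) 0 else -sin(az))
}

# Block means by explicit nested loops.
block_mean_oracle <- function(m, f) {
  nro <- nrow(m) %/% f; nco <- ncol(m) %/% f
  out <- matrix(NA_real_, nro, nco)
  for (i in seq_len(nro)) for (j in seq_len(nco)) {
    vals <- c()
    for (di in seq_len(f)) for (dj in seq_len(f))
      vals <- c(vals, m[(i - 1) * f + di, (j - 1) * f + dj])
    vals <- vals[!is.na(vals)]
    if (length(vals)) out[i, j] <- sum(vals) / length(vals)
  }
  out
}

# AUC by exhaustive pair counting (ties one half).
auc_pair_oracle <- function(scores, labels) {
  pos <- scores[labels == 1]; neg <- scores[labels == 0]
  tot <- 0
  for (p in pos) for (q in neg)
    tot <- tot + if (p > q) 1 else if (p == q) 0.5 else 0
  tot / (length(pos) * length(neg))
}

# Moran's I by the explicit double sum.
moran_oracle <- function(values, W) {
  n <- length(values)
  z <- values - mean(values)
  num <- 0
  for (i in seq_len(n)) for (j in seq_len(n))
    num <- num + W[i, j] * z[i] * z[j]
  (n / sum(W)) * num / sum(z^2)
}

# HC4m covariance element by element (explicit inverse and triple product).
hc4m_oracle <- function(y, X) {
  X <- as.matrix(X)
  n <- nrow(X); p <- ncol(X)
  XtX <- matrix(0, p, p)
  for (a in 1:p) for (b in 1:p)
    XtX[a, b] <- sum(X[, a] * X[, b])
  XtXinv <- solve(XtX)
  beta <- XtXinv %*% (t(X) %*% y)
  e <- as.numeric(y - X %*% beta)
  h <- numeric(n)
  for (i in 1:n) h[i] <- as.numeric(X[i, ] %*% XtXinv %*% X[i, ])
  meat <- matrix(0, p, p)
  for (i in 1:n) {
    delta <- min(1, n * h[i] / p) + min(1.5, n * h[i] / p)
    w <- e[i]^2 / (1 - h[i])^delta
    meat <- meat + w * (X[i, ] %o% X[i, ])
  }
  XtXinv %*% meat %*% XtXinv
}

# Mean of the k nearest map cells to a point, by exhaustive sort.
nearest_k_oracle <- function(map, x, y, k = 16) {
  nr <- nrow(map$values); cs <- map$cell_size
  rows <- cols <- dist <- val <- c()
  for (r in seq_len(nr)) for (cl in seq_len(ncol(map$values))) {
    if (is.na(map$values[r, cl])) next
    cx <- map$origin[1] + (cl - 0.5) * cs
    cy <- map$origin[2] + (nr - r + 0.5) * cs
    rows <- c(rows, r); cols <- c(cols, cl)
    dist <- c(dist, sqrt((cx - x)^2 + (cy - y)^2))
    val <- c(val, map$values[r, cl])
  }
  o <- order(dist, rows, cols)
  mean(val[o[seq_len(k)]])
}

# ESW by numerical quadrature of the half-normal.
esw_quad_oracle <- function(sigma, w) {
  integrate(function(x) exp(-x^2 / (2 * sigma^2)), 0, w,
            rel.tol = 1e-10)$value
}

# Partial dependence by an explicit row loop (one prediction per row).
pd_row_oracle <- function(model, variable, grid) {
  X <- model$sample$features
  j <- match(variable, colnames(X))
  vapply(grid, function(v) {
    tot <- 0
    for (i in seq_len(nrow(X))) {
      xi <- X[i, , drop = FALSE]
      xi[1, j] <- v
      tot <- tot + predict(model, xi)
    }
    tot / nrow(X)
  }, numeric(1))
}

# Suitability-class cell counts by an explicit histogram loop.
class_count_oracle <- function(v, breaks) {
  v <- v[!is.na(v)]
  n <- integer(length(breaks) - 1)
  for (x in v) for (b in seq_len(length(breaks) - 1)) {
    lo <- breaks[b]; hi <- breaks[b + 1]
    last <- b == length(breaks) - 1
    if (x >= lo && (x < hi || (last && x <= hi))) {
      n[b] <- n[b] + 1L
      break
    }
  }
  n
}

# Check loss of a quantile-regression candidate.
check_loss_oracle <- function(y, X, b, tau) {
  r <- y - as.numeric(as.matrix(X) %*% b)
  sum(r * (tau - (r < 0)))
}
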