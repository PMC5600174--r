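#' Right-truncate perpendicular detection distances
#'
#' Either at the empirical `(100 - pct)` percentile (type-1 / inverse-ECDF
#' quantile, so with `pct = 5` on 1..100 the truncation distance is exactly
#' the 95th order statistic) or at a user-fixed distance `w` (e.g. the
#' study's 125 m).
#'
#' @param d numeric vector of perpendicular distances (m)
#' @param pct percentage of far detections to discard (default 5)
#' @param w fixed truncation distance; overrides `pct`
#' @return list: `distances` (kept, `<= w`) and `w`
#' @export
truncate_distances <- function(d, pct = 5, w = NULL) {
  if (any(d < 0)) stop("distances must be >= 0")
  if (is.null(w)) {
    if (length(d) < 20L) stop("need at least 20 distances to truncate by percentile")
    w <- as.numeric(quantile(d, probs = (100 - pct) / 100, type = 1))
  }
  list(distances = d[d <= w], w = w)
}

# log-likelihood of the half-normal detection function truncated at w:
#   g(x) = exp(-x^2 / (2 sigma^2)),  integral_0^w g = sigma*sqrt(2*pi)*(Phi(w/sigma) - 1/2)
halfnormal_loglik <- function(sigma, d, w) {
  mu <- sigma * sqrt(2 * pi) * (pnorm(w / sigma) - 0.5)
  -sum(d^2) / (2 * sigma^2) - length(d) * log(mu)
}

#' Maximum-likelihood half-normal detection scale
#'
#' Maximizes the truncated half-normal likelihood by 1-D optimization of
#' `log(sigma)` (relative tolerance 1e-8). With `w = Inf` the closed form
#' `sqrt(mean(d^2))` applies and is returned directly.
#'
#' @param d distances already truncated at `w`
#' @param w truncation distance (m)
#' @return `sigma` (m), with attribute `loglik`
#' @export
fit_halfnormal <- function(d, w) {
  if (length(d) < 10L) stop("need at least 10 distances")
  if (any(d > w)) stop("distances exceed the truncation distance w")
  if (all(d == 0)) stop("all distances are zero; sigma is at the boundary")
  if (!is.finite(w)) {
    s <- sqrt(mean(d^2))
    return(structure(s, loglik = halfnormal_loglik(s, d, Inf)))
  }
  lo <- log(max(w * 1e-3, min(d[d > 0]) / 10))
  hi <- log(w * 20)
  opt <- optimize(function(ls) -halfnormal_loglik(exp(ls), d, w),
                  c(lo, hi), tol = 1e-8)
  if (!is.finite(opt$objective))
    stop("half-normal fit failed to converge; optimizer value ",
         opt$objective, " at log(sigma) = ", opt$minimum)
  structure(exp(opt$minimum), loglik = -opt$objective)
}

#' Effective strip width and detection probability
#'
#' `ESW = integral_0^w exp(-x^2 / (2 sigma^2)) dx` in closed form via the
#' Gaussian error integral; `pdet = ESW / w`, the average detection
#' probability of a bird at uniform distance within the strip.
#'
#' @param sigma half-normal scale (m, > 0)
#' @param w truncation distance (m, > 0)
#' @return list `esw` (m), `pdet` in `(0, 1]`
#' @export
esw_pdet <- function(sigma, w) {
  sigma <- as.numeric(sigma)  # strip fit attributes
  stopifnot(sigma > 0, w > 0)
  esw <- sigma * sqrt(2 * pi) * (pnorm(w / sigma) - 0.5)
  list(esw = esw, pdet = esw / w)
}

#' Line-transect density estimate
#'
#' `D = n / (2 L ESW)` expressed in birds/km2; `n` is the mean count per
#' complete survey (multi-visit years are averaged before conversion).
#'
#' @param n number of contacts (one survey, or the per-survey average)
#' @param L_km transect length (km)
#' @param esw_m effective strip width (m)
#' @return density (birds/km2)
#' @export
transect_density <- function(n, L_km, esw_m) {
  stopifnot(n >= 0, L_km > 0, esw_m > 0)
  n / (2 * L_km * esw_m / 1000)
}

#' Fit a detection function to transect contacts
#'
#' Full distance-sampling summary for one detection group (e.g. one observer
#' period): truncation, half-normal ML fit, effective strip width, detection
#' probability with a nonparametric bootstrap standard error, and density.
#'
#' @param d perpendicular distances (m)
#' @param pct truncation percentage (default 5); ignored when `w` given
#' @param w fixed truncation distance (m), optional
#' @param L_km total transect length (km), optional (density needs it)
#' @param n_surveys number of complete surveys pooled in `d` (counts are
#'   averaged over surveys before the density conversion)
#' @param n_boot bootstrap replicates for `se(pdet)` (default 999)
#' @param seed integer seed for the bootstrap
#' @return object of class `detection_fit`: `w`, `sigma`, `esw`, `pdet`,
#'   `se_pdet`, `n_used`, `density` (birds/km2, NA without `L_km`)
#' @export
fit_detection <- function(d, pct = 5, w = NULL, L_km = NULL, n_surveys = 1,
                          n_boot = 999, seed = 1L) {
  tr <- truncate_distances(d, pct = pct, w = w)
  sigma <- fit_halfnormal(tr$distances, tr$w)
  ep <- esw_pdet(sigma, tr$w)
  set.seed(seed)
  boot <- vapply(seq_len(n_boot), function(b) {
    db <- sample(tr$distances, replace = TRUE)
    if (all(db == 0)) return(NA_real_)
    sb <- fit_halfnormal(db, tr$w)
    esw_pdet(sb, tr$w)$pdet
  }, numeric(1))
  dens <- if (is.null(L_km)) NA_real_ else
    transect_density(length(tr$distances) / n_surveys, L_km, ep$esw)
  structure(list(w = tr$w, sigma = as.numeric(sigma), esw = ep$esw,
                 pdet = ep$pdet, se_pdet = sd(boot, na.rm = TRUE),
                 n_used = length(tr$distances), density = dens),
            class = "detection_fit")
}

#' @export
print.detection_fit <- function(x, ...) {
  cat(sprintf(
    "detection_fit: n = %d, w = %.1f m, sigma = %.1f m, ESW = %.1f m\n",
    x$n_used, x$w, x$sigma, x$esw))
  cat(sprintf("  pdet = %.3f (se %.3f)", x$pdet, x$se_pdet))
  if (is.finite(x$density)) cat(sprintf(", density = %.2f birds/km2", x$density))
  cat("\n")
  invisible(x)
}
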