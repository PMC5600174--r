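#' Aggregate a 50 m suitability map to 200 m cells
#'
#' Joins 16 cells of 50 x 50 m into one 200 x 200 m cell by their mean
#' suitability (delegates to [aggregate_mean()] with factor 4).
#'
#' @param map50 a [raster_grid()] at 50 m resolution
#' @return a [raster_grid()] at 200 m resolution
#' @export
cells_200m <- function(map50) {
  stopifnot(is_raster_grid(map50))
  aggregate_mean(map50, 4L)
}

#' Expected birds per aggregated cell from the suitability-abundance line
#'
#' `E_cell = max(0, intercept + slope * suitability) * area_scale`. Negative
#' linear predictions are clamped at zero (their count is reported in the
#' `n_clamped` attribute). The default `area_scale = 1` reproduces the
#' literal study procedure in which one 200 m cell carries one
#' transect-unit-equivalent count.
#'
#' @param suit200 a [raster_grid()] of aggregated suitabilities
#' @param intercept,slope regression line on the transect-unit scale
#' @param area_scale multiplier converting unit-scale counts to cell counts
#' @return a [raster_grid()] of expected birds with attribute `n_clamped`
#' @export
expected_birds <- function(suit200, intercept, slope, area_scale = 1) {
  stopifnot(is_raster_grid(suit200), is.finite(slope), is.finite(intercept))
  e <- intercept + slope * suit200$values
  n_clamped <- sum(e < 0, na.rm = TRUE)
  if (n_clamped > 0)
    message(sprintf("expected_birds: clamped %d negative prediction(s) to 0",
                    n_clamped))
  e[e < 0] <- 0
  out <- raster_grid(e * area_scale, suit200$cell_size, suit200$origin)
  attr(out, "n_clamped") <- n_clamped
  out
}

#' Correct expected bird numbers for imperfect detection
#'
#' Elementwise division by the detection probability.
#'
#' @param E a [raster_grid()] of expected (detected-scale) birds
#' @param pdet detection probability in `(0, 1]`
#' @return a [raster_grid()]
#' @export
correct_detectability <- function(E, pdet) {
  stopifnot(is_raster_grid(E))
  if (!(pdet > 0 && pdet <= 1)) stop("pdet must be in (0, 1]")
  raster_grid(E$values / pdet, E$cell_size, E$origin)
}

#' Bootstrap population estimate from per-cell expectations
#'
#' Point estimate: the sum of the per-cell expected birds. Uncertainty: the
#' cells are resampled with replacement (same count) `n_boot` times, each
#' resample summed, and the 95% interval taken as the 2.5 and 97.5
#' percentiles of the bootstrap sums.
#'
#' @param E a [raster_grid()] (or numeric vector) of per-cell expectations
#' @param n_boot bootstrap replicates (default 1000)
#' @param seed integer seed
#' @return object of class `population_estimate`: `total`, `ci` (2.5%,
#'   97.5%), `boot` (draws), `n_cells`
#' @export
estimate_population <- function(E, n_boot = 1000, seed = 1L) {
  v <- if (is_raster_grid(E)) as.vector(E$values) else as.numeric(E)
  v <- v[!is.na(v)]
  if (length(v) < 2L) stop("need at least 2 cells")
  if (any(v < 0)) stop("per-cell expectations must be >= 0")
  set.seed(seed)
  n <- length(v)
  boot <- vapply(seq_len(n_boot), function(b)
    sum(v[sample.int(n, n, replace = TRUE)]), numeric(1))
  ci <- unname(quantile(boot, c(0.025, 0.975), type = 7))
  structure(list(total = sum(v), ci = ci, boot = boot, n_cells = n),
            class = "population_estimate")
}

#' @export
print.population_estimate <- function(x, ...) {
  cat(sprintf("population_estimate: %.1f birds (95%% CI %.1f-%.1f, %d cells)\n",
              x$total, x$ci[1], x$ci[2], x$n_cells))
  invisible(x)
}

#' Full population pipeline step: suitability map to population estimate
#'
#' Aggregates the 50 m suitability map to 200 m, converts suitability to
#' expected counts with the fitted line, corrects for detectability and
#' bootstraps the total.
#'
#' @param map50 50 m suitability [raster_grid()]
#' @param intercept,slope suitability-abundance regression line
#' @param pdet detection probability in `(0, 1]`
#' @param n_boot bootstrap replicates
#' @param seed integer seed
#' @param area_scale see [expected_birds()]
#' @return a `population_estimate` with extra fields `pdet`, `intercept`,
#'   `slope`, `E` (per-cell corrected expectations)
#' @export
population_from_map <- function(map50, intercept, slope, pdet,
                                n_boot = 1000, seed = 1L, area_scale = 1) {
  suit200 <- cells_200m(map50)
  E <- expected_birds(suit200, intercept, slope, area_scale)
  Ec <- correct_detectability(E, pdet)
  est <- estimate_population(Ec, n_boot = n_boot, seed = seed)
  est$pdet <- pdet
  est$intercept <- intercept
  est$slope <- slope
  est$E <- Ec
  est
}
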