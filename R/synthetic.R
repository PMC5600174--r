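#' Names of the 12 environmental predictors
#'
#' Fixed layer set carried by every [env_stack()]: mean pine height (m), pine
#' canopy cover (%), altitude (m a.s.l.), summer (July-September) rainfall
#' (mm), terrain slope (%), incident solar radiation (kWh/m2), northness and
#' westness of the hillside (cos/-sin of aspect), shrub cover (%), shrub
#' height (m), and mean May and July temperature (degrees C).
#'
#' @export
predictor_names <- function() {
  c("pine_height", "tree_cover", "altitude", "summer_rainfall",
    "slope", "radiation", "northness", "westness",
    "shrub_cover", "shrub_height", "temp_may", "temp_july")
}

#' Co-registered stack of the 12 environmental predictor rasters
#'
#' @param layers named list of [raster_grid()]s; names must be exactly
#'   [predictor_names()] (any order)
#' @return object of class `env_stack`
#' @export
env_stack <- function(layers) {
  nm <- names(layers)
  if (is.null(nm) || anyDuplicated(nm))
    stop("layers must be uniquely named")
  miss <- setdiff(predictor_names(), nm)
  extra <- setdiff(nm, predictor_names())
  if (length(miss) || length(extra))
    stop("env_stack needs exactly the 12 predictors; missing: [",
         paste(miss, collapse = ", "), "], unexpected: [",
         paste(extra, collapse = ", "), "]")
  ref <- layers[[1]]
  for (nmx in nm) {
    l <- layers[[nmx]]
    if (!is_raster_grid(l)) stop("layer `", nmx, "` is not a raster_grid")
    if (!identical(dim(l$values), dim(ref$values)) ||
        l$cell_size != ref$cell_size || !identical(l$origin, ref$origin))
      stop("layer `", nmx, "` is not co-registered with the others")
  }
  structure(list(layers = layers[predictor_names()]), class = "env_stack")
}

#' @export
print.env_stack <- function(x, ...) {
  r <- x$layers[[1]]
  cat(sprintf("env_stack: 12 layers, %d x %d cells of %g m\n",
              nrow(r$values), ncol(r$values), r$cell_size))
  invisible(x)
}

#' Flatten an env_stack into a feature matrix
#'
#' @param stack an [env_stack()]
#' @return numeric matrix (cells x 12, column-major cell order) with
#'   attribute `valid` marking rows with no nodata
#' @export
stack_matrix <- function(stack) {
  stopifnot(inherits(stack, "env_stack"))
  m <- sapply(stack$layers, function(l) as.vector(l$values))
  colnames(m) <- predictor_names()
  attr(m, "valid") <- complete.cases(m)
  m
}

#' Configuration of a synthetic landscape
#'
#' Default per-predictor ranges reproduce the environmental spans of the
#' studied pine forests (altitude 250-1550 m, slope 0-260 %, tree cover
#' 0-99 %, pine height 0-40 m, shrub cover 0-75 %, shrub height 0-1.25 m,
#' radiation 4567-7515 kWh/m2, May temperature 17.0-21.2 C, July temperature
#' 23.6-25.9 C, summer rainfall 0-34 mm). Layers are smoothed Gaussian
#' random fields rescaled into these ranges; `cross_cor` couples pine height
#' with tree cover (taller stands carry more canopy) and `lapse_weight`
#' couples altitude with temperatures (negatively) and summer rainfall
#' (positively), emulating lapse-rate trends.
#'
#' @param nrow,ncol grid shape in cells
#' @param cell_size cell edge (m), 50 by default
#' @param ranges named list of `c(min, max)` per predictor (partial override)
#' @param cor_range spatial correlation length in cells (> 0)
#' @param cross_cor correlation of pine height with tree cover in `[-1, 1]`
#' @param lapse_weight altitude coupling of temperatures/rainfall in `[0, 1]`
#' @param seed integer seed
#' @return object of class `landscape_config`
#' @export
landscape_config <- function(nrow = 100, ncol = 100, cell_size = 50,
                             ranges = list(), cor_range = 8,
                             cross_cor = 0.5, lapse_weight = 0.7,
                             seed = 1L) {
  def <- list(
    pine_height = c(0, 40), tree_cover = c(0, 99), altitude = c(250, 1550),
    summer_rainfall = c(0, 34), slope = c(0, 260),
    radiation = c(4567, 7515), northness = c(-1, 1), westness = c(-1, 1),
    shrub_cover = c(0, 75), shrub_height = c(0, 1.25),
    temp_may = c(17.0, 21.2), temp_july = c(23.6, 25.9))
  bad <- setdiff(names(ranges), names(def))
  if (length(bad)) stop("unknown predictor in ranges: ",
                        paste(bad, collapse = ", "))
  def[names(ranges)] <- ranges
  for (nm in names(def))
    if (length(def[[nm]]) != 2L || def[[nm]][1] >= def[[nm]][2])
      stop("range for `", nm, "` must be c(min, max) with min < max")
  if (cor_range <= 0) stop("cor_range must be > 0")
  if (abs(cross_cor) > 1) stop("cross_cor must be in [-1, 1]")
  if (nrow < 4 || ncol < 4) stop("grid must be at least 4 x 4")
  structure(list(nrow = as.integer(nrow), ncol = as.integer(ncol),
                 cell_size = cell_size, ranges = def, cor_range = cor_range,
                 cross_cor = cross_cor, lapse_weight = lapse_weight,
                 seed = as.integer(seed)),
            class = "landscape_config")
}

# Standardized Gaussian random field via spectral smoothing of white noise
# (periodic boundary; correlation length `range_cells` in cell units).
gaussian_field <- function(nr, nc, range_cells) {
  wn <- matrix(rnorm(nr * nc), nr, nc)
  freq <- function(n) { k <- 0:(n - 1); pmin(k, n - k) / n }
  H <- exp(-2 * pi^2 * range_cells^2 *
             outer(freq(nr)^2, freq(nc)^2, "+"))
  z <- Re(fft(fft(wn) * H, inverse = TRUE)) / (nr * nc)
  (z - mean(z)) / sd(z)
}

rescale_range <- function(z, lo, hi) {
  zmin <- min(z); zmax <- max(z)
  if (zmax == zmin) return(matrix((lo + hi) / 2, nrow(z), ncol(z)))
  lo + (hi - lo) * (z - zmin) / (zmax - zmin)
}

#' Generate a synthetic environmental stack
#'
#' Each layer is a smoothed Gaussian random field rescaled to its configured
#' range; pine height and tree cover share a configurable correlation and
#' altitude drives lapse-type trends in the temperature and rainfall layers.
#' Fully reproducible from `cfg$seed`.
#'
#' @param cfg a [landscape_config()]
#' @return an [env_stack()]
#' @export
generate_landscape <- function(cfg) {
  stopifnot(inherits(cfg, "landscape_config"))
  set.seed(cfg$seed)
  nr <- cfg$nrow; nc <- cfg$ncol; rng <- cfg$cor_range
  g <- function() gaussian_field(nr, nc, rng)
  fields <- list()
  alt_z <- g()
  fields$altitude <- alt_z
  pine_z <- g()
  fields$pine_height <- pine_z
  rho <- cfg$cross_cor
  fields$tree_cover <- rho * pine_z + sqrt(max(0, 1 - rho^2)) * g()
  lw <- cfg$lapse_weight
  mix <- function(sign) sign * lw * alt_z + sqrt(max(0, 1 - lw^2)) * g()
  fields$summer_rainfall <- mix(+1)
  fields$temp_may <- mix(-1)
  fields$temp_july <- mix(-1)
  for (nm in c("slope", "radiation", "northness", "westness",
               "shrub_cover", "shrub_height"))
    fields[[nm]] <- g()
  layers <- lapply(predictor_names(), function(nm)
    raster_grid(rescale_range(fields[[nm]], cfg$ranges[[nm]][1],
                              cfg$ranges[[nm]][2]),
                cfg$cell_size, c(0, 0)))
  names(layers) <- predictor_names()
  env_stack(layers)
}

#' True-suitability parameters of the synthetic world
#'
#' The generative truth is a product of scaled logistic ramps on up to four
#' predictors (pine height, tree cover, altitude, summer rainfall). Each ramp
#' rises from ~0.05 at `lo` to ~0.95 at `hi` (logistic scale `(hi - lo)/6`).
#' Default rise intervals: pine height 15 to 20 m, tree cover 25 to 37 %,
#' altitude 1100 to 1280 m, summer rainfall 13 to 20 mm. `lambda1` is the
#' expected (true) number of birds attached to one transect unit / one 4-ha
#' cell at suitability 1; `sigma_true` is the half-normal detection scale in
#' metres.
#'
#' @param terms named list of `c(lo, hi)` rise intervals; restrict the names
#'   to drive truth with fewer variables
#' @param lambda1 expected birds per unit at suitability 1 (> 0)
#' @param sigma_true half-normal detection scale (m, > 0)
#' @return object of class `truth_params`
#' @export
truth_params <- function(terms = list(pine_height = c(15, 20),
                                      tree_cover = c(25, 37),
                                      altitude = c(1100, 1280),
                                      summer_rainfall = c(13, 20)),
                         lambda1 = 1.4, sigma_true = 60) {
  bad <- setdiff(names(terms), predictor_names())
  if (length(bad)) stop("unknown predictor in terms: ",
                        paste(bad, collapse = ", "))
  for (nm in names(terms))
    if (length(terms[[nm]]) != 2L || terms[[nm]][1] >= terms[[nm]][2])
      stop("term `", nm, "` must be c(lo, hi) with lo < hi")
  if (lambda1 < 0) stop("lambda1 must be >= 0")
  if (sigma_true <= 0) stop("sigma_true must be > 0")
  structure(list(terms = terms, lambda1 = lambda1, sigma_true = sigma_true),
            class = "truth_params")
}

#' Evaluate the true suitability surface of a synthetic world
#'
#' Product of the logistic ramps of [truth_params()]; values in `[0, 1]`,
#' monotone nondecreasing in every term variable.
#'
#' @param stack an [env_stack()]
#' @param tp a [truth_params()]
#' @return a [raster_grid()] of suitability
#' @export
true_suitability <- function(stack, tp) {
  stopifnot(inherits(stack, "env_stack"), inherits(tp, "truth_params"))
  miss <- setdiff(names(tp$terms), names(stack$layers))
  if (length(miss)) stop("stack is missing layer `", miss[1], "`")
  if (!length(stack$layers)) stop("stack has no layers")
  ref <- stack$layers[[1]]
  s <- matrix(1, nrow(ref$values), ncol(ref$values))
  for (nm in names(tp$terms)) {
    l <- stack$layers[[nm]]
    if (is.null(l)) stop("stack is missing layer `", nm, "`")
    lo <- tp$terms[[nm]][1]; hi <- tp$terms[[nm]][2]
    s <- s * plogis((l$values - (lo + hi) / 2) / ((hi - lo) / 6))
  }
  raster_grid(s, ref$cell_size, ref$origin)
}

#' Sample presence (successful-nest) cells from a suitability surface
#'
#' Draws `n` distinct cells without replacement with probability
#' proportional to suitability.
#'
#' @param suit a [raster_grid()] with values in `[0, 1]`
#' @param n number of nests (default 59)
#' @param seed integer seed
#' @return data.frame `row`, `col`, `cell`, `x`, `y` of the sampled cells
#' @export
simulate_nests <- function(suit, n = 59, seed = 1L) {
  stopifnot(is_raster_grid(suit))
  v <- as.vector(suit$values)
  if (any(v < -1e-9 | v > 1 + 1e-9, na.rm = TRUE))
    stop("suitability must be in [0, 1]")
  ok <- which(!is.na(v) & v > 0)
  if (length(ok) < n)
    stop(sprintf("only %d cells with positive suitability, need %d",
                 length(ok), n))
  set.seed(seed)
  cells <- sample(ok, n, replace = FALSE, prob = v[ok])
  nr <- nrow(suit$values)
  row <- ((cells - 1L) %% nr) + 1L
  col <- ((cells - 1L) %/% nr) + 1L
  cs <- suit$cell_size
  data.frame(row = row, col = col, cell = cells,
             x = suit$origin[1] + (col - 0.5) * cs,
             y = suit$origin[2] + (nr - row + 0.5) * cs)
}

#' Lay out contiguous transect-unit centroids across a raster
#'
#' Emulates a fixed survey trail: a serpentine walk across the grid with one
#' centroid every `unit_length` metres, clipped to the raster interior.
#'
#' @param r a [raster_grid()] defining the extent
#' @param n_units number of units (default 100)
#' @param unit_length unit length in metres (default 229)
#' @return data.frame `unit_id`, `x`, `y`
#' @export
make_transect_units <- function(r, n_units = 100, unit_length = 229) {
  stopifnot(is_raster_grid(r))
  cs <- r$cell_size
  width <- ncol(r$values) * cs; height <- nrow(r$values) * cs
  margin <- cs
  xs <- seq(r$origin[1] + margin, r$origin[1] + width - margin,
            by = unit_length)
  if (length(xs) < 2) stop("raster too narrow for transect units")
  rows_needed <- ceiling(n_units / length(xs))
  ys <- seq(r$origin[2] + height - margin, r$origin[2] + margin,
            length.out = max(rows_needed, 2))
  if (rows_needed > length(ys)) stop("raster too small for n_units")
  pts <- do.call(rbind, lapply(seq_along(ys), function(i) {
    x <- if (i %% 2 == 1) xs else rev(xs)
    data.frame(x = x, y = ys[i])
  }))
  pts <- pts[seq_len(n_units), , drop = FALSE]
  data.frame(unit_id = seq_len(n_units), x = pts$x, y = pts$y)
}

#' Simulate line-transect counts and detection distances
#'
#' Birds are attached to each transect unit by an inhomogeneous Poisson
#' process with mean `density_scale * lambda1 * suitability(unit)` per
#' replicate year. Each bird sits at a perpendicular distance drawn uniformly
#' in `[0, w_max]` and is detected with probability
#' `exp(-d^2 / (2 sigma_true^2))` (half-normal). Only detected birds are
#' returned, matching the data model of the distance-sampling estimator.
#'
#' @param suit a [raster_grid()] of true suitability
#' @param units data.frame `unit_id`, `x`, `y` (see [make_transect_units()])
#' @param tp a [truth_params()]
#' @param years integer vector of replicate "years" (default 1:7)
#' @param w_max maximum perpendicular distance simulated (m)
#' @param density_scale multiplier on `tp$lambda1` (default 1)
#' @param seed integer seed
#' @return list: `counts` (unit_id, year, n_detected, n_true),
#'   `distances` (unit_id, year, distance_m), `suit_unit` (per-unit true
#'   suitability, nearest-16-cell mean), `true_lambda` (per-unit expectation)
#' @export
simulate_transects <- function(suit, units, tp, years = 1:7, w_max = 125,
                               density_scale = 1, seed = 1L) {
  stopifnot(is_raster_grid(suit), inherits(tp, "truth_params"))
  set.seed(seed)
  su <- suitability_at_units(suit, units)
  lambda <- density_scale * tp$lambda1 * su
  out_counts <- vector("list", length(years) * nrow(units))
  dist_list <- list()
  k <- 0L
  for (yr in years) {
    n_true <- rpois(nrow(units), lambda)
    for (u in seq_len(nrow(units))) {
      k <- k + 1L
      nd <- 0L
      if (n_true[u] > 0) {
        d <- runif(n_true[u], 0, w_max)
        det <- runif(n_true[u]) < exp(-d^2 / (2 * tp$sigma_true^2))
        nd <- sum(det)
        if (nd > 0)
          dist_list[[length(dist_list) + 1L]] <-
            data.frame(unit_id = units$unit_id[u], year = yr,
                       distance_m = d[det])
      }
      out_counts[[k]] <- data.frame(unit_id = units$unit_id[u], year = yr,
                                    n_detected = nd, n_true = n_true[u])
    }
  }
  counts <- do.call(rbind, out_counts)
  distances <- if (length(dist_list)) do.call(rbind, dist_list) else
    data.frame(unit_id = integer(), year = integer(),
               distance_m = numeric())
  rownames(counts) <- NULL; rownames(distances) <- NULL
  list(counts = counts, distances = distances, suit_unit = su,
       true_lambda = lambda)
}
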