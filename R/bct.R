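#' Boosting hyperparameters
#'
#' Defaults follow the study protocol: learning rate 0.001, bag fraction 2/3,
#' tree complexity 5 (at most 5 splits, hence at most 11 nodes counting
#' leaves), a minimum of 5 training rows per node, tree count selected by
#' ten-fold cross-validated Bernoulli deviance evaluated every 50 trees with
#' a patience of 5 checkpoints.
#'
#' @param n_trees fixed tree count, or `NULL` to select by CV
#' @param learning_rate shrinkage nu
#' @param bag_fraction row subsample fraction per stage (without replacement)
#' @param max_splits split budget per tree
#' @param min_obs minimum training rows per node
#' @param step CV checkpoint spacing in trees
#' @param patience checkpoints without improvement before stopping
#' @param max_trees hard cap on trees grown during selection
#' @param cv_folds folds for tree selection / accuracy
#' @return list of class `bct_hyperparams`
#' @export
bct_hyperparams <- function(n_trees = NULL, learning_rate = 0.001,
                            bag_fraction = 2 / 3, max_splits = 5L,
                            min_obs = 5L, step = 50L, patience = 5L,
                            max_trees = 10000L, cv_folds = 10L) {
  stopifnot(learning_rate >= 0, bag_fraction > 0, bag_fraction <= 1,
            max_splits >= 1, min_obs >= 1, step >= 1, patience >= 1,
            max_trees >= step, cv_folds >= 2)
  structure(list(n_trees = n_trees, learning_rate = learning_rate,
                 bag_fraction = bag_fraction, max_splits = as.integer(max_splits),
                 min_obs = as.integer(min_obs), step = as.integer(step),
                 patience = as.integer(patience),
                 max_trees = as.integer(max_trees),
                 cv_folds = as.integer(cv_folds)),
            class = "bct_hyperparams")
}

#' Presence/background sample for one boosting run
#'
#' @param features numeric matrix (rows = cells, 12 predictor columns)
#' @param labels binary vector (1 = presence, 0 = background)
#' @return list of class `sample_set`
#' @export
sample_set <- function(features, labels) {
  features <- as.matrix(features)
  if (nrow(features) != length(labels)) stop("features/labels length mismatch")
  if (!all(labels %in% c(0, 1))) stop("labels must be binary 0/1")
  if (anyNA(features)) stop("sample features contain nodata")
  structure(list(features = features, labels = as.numeric(labels)),
            class = "sample_set")
}

#' Draw background (available-habitat) cells
#'
#' Uniform sample without replacement over the valid (no-nodata) cells of the
#' stack, excluding the presence cells by default.
#'
#' @param stack an [env_stack()]
#' @param n number of background cells
#' @param seed integer seed
#' @param exclude integer cell indices to exclude (presence cells)
#' @return integer vector of cell indices (column-major)
#' @export
sample_background <- function(stack, n, seed = 1L, exclude = integer()) {
  m <- stack_matrix(stack)
  pool <- setdiff(which(attr(m, "valid")), exclude)
  if (length(pool) < n)
    stop(sprintf("only %d valid background cells available, need %d",
                 length(pool), n))
  set.seed(seed)
  if (length(pool) == n) return(sort(pool))
  sample(pool, n, replace = FALSE)
}

#' Bootstrap-resample presence cells
#'
#' Same-size resample with replacement, the robustness device applied to the
#' presence set before every boosting run.
#'
#' @param cells integer vector of presence cell indices
#' @param seed integer seed
#' @return integer vector, same length as `cells`
#' @export
bootstrap_presence <- function(cells, seed = 1L) {
  if (length(cells) < 1L) stop("need at least one presence cell")
  set.seed(seed)
  cells[sample.int(length(cells), length(cells), replace = TRUE)]
}

#' Fit one boosted classification tree model
#'
#' Stage-wise gradient boosting on the Bernoulli deviance: every stage fits a
#' least-squares regression tree (best-first, at most `max_splits` splits) to
#' the current negative gradient on a fresh `bag_fraction` subsample, leaf
#' values are Newton steps for the Bernoulli loss, and the model moves by
#' `learning_rate` times the tree. Uses R's RNG; call `set.seed()` first for
#' reproducibility.
#'
#' @param s a [sample_set()]
#' @param hp a [bct_hyperparams()]; `hp$n_trees` must be set (use
#'   [select_n_trees()] first, or pass a fixed count)
#' @return object of class `bct_model`
#' @export
fit_bct <- function(s, hp = bct_hyperparams(n_trees = 1000L)) {
  stopifnot(inherits(s, "sample_set"), inherits(hp, "bct_hyperparams"))
  if (length(unique(s$labels)) < 2L)
    stop("both classes must be present in the sample")
  if (nrow(s$features) < 10L) stop("need at least 10 samples")
  nt <- hp$n_trees %||% stop("hp$n_trees is NULL; run select_n_trees() first")
  fit <- bct_boost_cpp(s$features, s$labels, as.integer(nt),
                       hp$learning_rate, hp$bag_fraction, hp$max_splits,
                       hp$min_obs, NULL, NULL, 0L, TRUE, FALSE)
  structure(list(trees = fit$trees, intercept = fit$intercept,
                 shrinkage = hp$learning_rate, n_trees = as.integer(nt),
                 importance_raw = fit$importance,
                 train_prob = fit$train_prob, sample = s, hp = hp),
            class = "bct_model")
}

#' @export
print.bct_model <- function(x, ...) {
  cat(sprintf("bct_model: %d trees (nu = %g, %d splits max)\n",
              x$n_trees, x$shrinkage, x$hp$max_splits))
  invisible(x)
}

#' Predict probabilities from a fitted BCT model
#'
#' @param object a `bct_model`
#' @param newdata numeric matrix with the 12 predictor columns
#' @param n_trees use only the first `n_trees` trees (default: all)
#' @param ... unused
#' @export
predict.bct_model <- function(object, newdata, n_trees = NULL, ...) {
  newdata <- as.matrix(newdata)
  if (ncol(newdata) != ncol(object$sample$features))
    stop("newdata must have ", ncol(object$sample$features), " columns")
  bct_predict_cpp(object$trees, object$intercept, object$shrinkage,
                  newdata, as.integer(n_trees %||% -1L))
}

# Stratified k-fold assignment (per class), returns integer fold per row.
stratified_folds <- function(labels, k) {
  fold <- integer(length(labels))
  for (cl in unique(labels)) {
    idx <- which(labels == cl)
    fold[idx] <- sample(rep_len(seq_len(k), length(idx)))
  }
  fold
}

# One full CV pass: per fold, boost to max_trees recording held-out deviance
# and held-out predictions at every `step` checkpoint. Returns the
# fold-averaged deviance curve and pooled held-out prediction matrix.
cv_boost <- function(s, hp, seed = 1L) {
  k <- hp$cv_folds
  if (min(table(s$labels)) < k)
    stop("need at least ", k, " samples per class for ", k, "-fold CV")
  set.seed(seed)
  fold <- stratified_folds(s$labels, k)
  n_check <- hp$max_trees %/% hp$step
  dev <- matrix(NA_real_, k, n_check)
  pred <- matrix(NA_real_, length(s$labels), n_check)
  for (f in seq_len(k)) {
    tr <- fold != f
    fit <- bct_boost_cpp(s$features[tr, , drop = FALSE], s$labels[tr],
                         hp$max_trees, hp$learning_rate, hp$bag_fraction,
                         hp$max_splits, hp$min_obs,
                         s$features[!tr, , drop = FALSE], s$labels[!tr],
                         hp$step, FALSE, TRUE)
    dev[f, ] <- fit$valid_dev
    pred[!tr, ] <- fit$valid_pred
  }
  list(checkpoints = seq_len(n_check) * hp$step,
       dev = colMeans(dev), pred = pred, fold = fold)
}

# Apply the patience stopping rule to a deviance curve: walk checkpoints,
# stop once `patience` consecutive checkpoints fail to improve on the best
# seen; return the argmin checkpoint among those walked.
select_from_curve <- function(dev, checkpoints, patience) {
  best <- Inf; best_i <- 1L; stall <- 0L
  for (i in seq_along(dev)) {
    if (dev[i] < best - 1e-12) {
      best <- dev[i]; best_i <- i; stall <- 0L
    } else {
      stall <- stall + 1L
      if (stall >= patience) break
    }
  }
  checkpoints[best_i]
}

#' Select the number of boosted trees by cross-validated deviance
#'
#' Trees are added in steps of `hp$step` (50); ten-fold CV predictive
#' Bernoulli deviance is tracked and growth stops once the deviance has not
#' improved for `hp$patience` checkpoints (or `hp$max_trees` is reached).
#' Returns the checkpoint with minimum CV deviance.
#'
#' @param s a [sample_set()]
#' @param hp a [bct_hyperparams()]
#' @param seed integer seed (fold assignment and bagging)
#' @return integer tree count (multiple of `hp$step`), with the CV curve in
#'   attributes `cv_dev` / `checkpoints`
#' @export
select_n_trees <- function(s, hp = bct_hyperparams(), seed = 1L) {
  cv <- cv_boost(s, hp, seed)
  nt <- select_from_curve(cv$dev, cv$checkpoints, hp$patience)
  structure(nt, cv_dev = cv$dev, checkpoints = cv$checkpoints)
}

#' Rank-based AUC (Mann-Whitney), ties counted one half
#'
#' @param scores numeric prediction scores
#' @param labels binary labels (1 = positive)
#' @return AUC in `[0, 1]`
#' @export
auc_mw <- function(scores, labels) {
  pos <- scores[labels == 1]; neg <- scores[labels == 0]
  if (!length(pos) || !length(neg)) stop("need both classes for AUC")
  r <- rank(c(pos, neg), ties.method = "average")
  (sum(r[seq_along(pos)]) - length(pos) * (length(pos) + 1) / 2) /
    (length(pos) * length(neg))
}

#' Ten-fold cross-validated AUC of a boosting configuration
#'
#' Stratified k-fold; held-out predictions are pooled and the AUC computed by
#' the rank (Mann-Whitney) formulation. If `hp$n_trees` is `NULL` the tree
#' count is selected from the same CV pass (deviance argmin with patience).
#'
#' @param s a [sample_set()]
#' @param hp a [bct_hyperparams()]
#' @param k number of folds (overrides `hp$cv_folds`)
#' @param seed integer seed
#' @return AUC, with attribute `n_trees` (count used)
#' @export
cv_auc <- function(s, hp = bct_hyperparams(), k = 10L, seed = 1L) {
  hp$cv_folds <- as.integer(k)
  if (!is.null(hp$n_trees))  # no need to boost past the fixed count
    hp$max_trees <- as.integer(ceiling(hp$n_trees / hp$step) * hp$step)
  cv <- cv_boost(s, hp, seed)
  nt <- hp$n_trees %||% select_from_curve(cv$dev, cv$checkpoints, hp$patience)
  ci <- max(1L, min(length(cv$checkpoints), nt %/% hp$step))
  structure(auc_mw(cv$pred[, ci], s$labels), n_trees = cv$checkpoints[ci])
}

#' Confusion-matrix accuracy metrics at a probability threshold
#'
#' @param pred predicted probabilities
#' @param labels binary labels
#' @param threshold classification threshold (default 0.5)
#' @return named vector: sensitivity, specificity, npv, ppv
#' @export
confusion_metrics <- function(pred, labels, threshold = 0.5) {
  if (!all(labels %in% c(0, 1))) stop("labels must be binary 0/1")
  yhat <- as.numeric(pred >= threshold)
  tp <- sum(yhat == 1 & labels == 1); fn <- sum(yhat == 0 & labels == 1)
  fp <- sum(yhat == 1 & labels == 0); tn <- sum(yhat == 0 & labels == 0)
  c(sensitivity = tp / (tp + fn), specificity = tn / (tn + fp),
    npv = tn / (tn + fn), ppv = tp / (tp + fp))
}

#' Relative variable importance of a fitted BCT model
#'
#' Friedman importance: per variable, the sum of squared-error reductions of
#' all splits on it across all trees, normalized to sum to 100.
#'
#' @param m a `bct_model`
#' @return named numeric vector (12 percentages summing to 100)
#' @export
variable_importance <- function(m) {
  stopifnot(inherits(m, "bct_model"))
  imp <- m$importance_raw
  names(imp) <- colnames(m$sample$features)
  tot <- sum(imp)
  if (tot <= 0) return(setNames(rep(0, length(imp)), names(imp)))
  100 * imp / tot
}

#' Partial dependence of model probability on one predictor
#'
#' For each grid value the predictor column of the training rows is
#' overwritten and the mean model probability recorded; for an ensemble the
#' per-run curves are averaged pointwise on a common grid.
#'
#' @param m a `bct_model` or `bct_ensemble`
#' @param variable predictor name
#' @param grid numeric grid of values (default: 100 points over the training
#'   range of the variable)
#' @return data.frame `value`, `p`
#' @export
partial_dependence <- function(m, variable, grid = NULL) {
  if (inherits(m, "bct_ensemble")) {
    pd <- m$partial_dependence[[variable]]
    if (is.null(pd)) stop("unknown variable `", variable, "`")
    if (!is.null(grid)) stop("ensemble curves are precomputed on a fixed grid")
    return(pd)
  }
  stopifnot(inherits(m, "bct_model"))
  X <- m$sample$features
  j <- match(variable, colnames(X))
  if (is.na(j)) stop("unknown variable `", variable, "`")
  if (is.null(grid))
    grid <- seq(min(X[, j]), max(X[, j]), length.out = 100L)
  p <- vapply(grid, function(v) {
    Xg <- X; Xg[, j] <- v
    mean(predict(m, Xg))
  }, numeric(1))
  data.frame(value = grid, p = p)
}

#' Run the randomized BCT ensemble
#'
#' Repeats the model `n_runs` times (20 in the study protocol); every run
#' draws a fresh bootstrap of the presence cells and a fresh uniform sample
#' of background cells, selects its tree count by ten-fold CV (unless
#' `hp$n_trees` is fixed), and is summarized by CV AUC, training confusion
#' metrics at 0.5, relative importance, partial-dependence curves and a
#' prediction surface. Per-run seeds derive from `master_seed`.
#'
#' @param stack an [env_stack()]
#' @param presence_cells integer cell indices of the presences
#' @param hp a [bct_hyperparams()]
#' @param n_runs number of randomized runs (default 20)
#' @param master_seed integer master seed
#' @param exclude_presence exclude presence cells from the background pool
#' @param pd_grid_n points per partial-dependence grid (default 100)
#' @param predict_stack compute the averaged prediction map (default TRUE)
#' @return object of class `bct_ensemble`: `runs` (models), `metrics`
#'   (mean/sd/min/max per metric), `importance` (averaged, sums to 100),
#'   `partial_dependence` (per variable), `prediction` ([raster_grid()] or
#'   NULL)
#' @export
run_ensemble <- function(stack, presence_cells, hp = bct_hyperparams(),
                         n_runs = 20L, master_seed = 1L,
                         exclude_presence = TRUE, pd_grid_n = 100L,
                         predict_stack = TRUE) {
  stopifnot(inherits(stack, "env_stack"))
  m <- stack_matrix(stack)
  if (!all(attr(m, "valid")[presence_cells]))
    stop("presence cell(s) fall on nodata")
  n_pres <- length(presence_cells)
  vars <- colnames(m)
  pd_grids <- lapply(vars, function(v) {
    rng <- range(m[attr(m, "valid"), v])
    seq(rng[1], rng[2], length.out = pd_grid_n)
  })
  names(pd_grids) <- vars

  runs <- vector("list", n_runs)
  met <- matrix(NA_real_, n_runs, 6,
                dimnames = list(NULL, c("n_trees", "cv_auc", "sensitivity",
                                        "specificity", "npv", "ppv")))
  imp <- matrix(NA_real_, n_runs, length(vars),
                dimnames = list(NULL, vars))
  pd_sum <- lapply(vars, function(v) numeric(pd_grid_n))
  names(pd_sum) <- vars
  pred_sum <- NULL
  pred_runs_sd <- NULL

  for (r in seq_len(n_runs)) {
    seed_r <- derive_seed(master_seed, paste0("ensemble-run-", r))
    pres_r <- bootstrap_presence(presence_cells,
                                 derive_seed(seed_r, "presence"))
    bg_r <- sample_background(stack, n_pres, derive_seed(seed_r, "background"),
                              exclude = if (exclude_presence)
                                unique(presence_cells) else integer())
    s <- sample_set(rbind(m[pres_r, , drop = FALSE],
                          m[bg_r, , drop = FALSE]),
                    c(rep(1, n_pres), rep(0, n_pres)))
    if (is.null(hp$n_trees)) {
      cv <- cv_boost(s, hp, derive_seed(seed_r, "cv"))
      nt <- select_from_curve(cv$dev, cv$checkpoints, hp$patience)
      ci <- nt %/% hp$step
      auc <- auc_mw(cv$pred[, ci], s$labels)
    } else {
      nt <- hp$n_trees
      auc <- cv_auc(s, hp, hp$cv_folds, derive_seed(seed_r, "cv"))
    }
    hp_r <- hp; hp_r$n_trees <- nt
    set.seed(derive_seed(seed_r, "fit"))
    mod <- fit_bct(s, hp_r)
    cm <- confusion_metrics(mod$train_prob, s$labels)
    met[r, ] <- c(nt, auc, cm)
    imp[r, ] <- variable_importance(mod)
    for (v in vars)
      pd_sum[[v]] <- pd_sum[[v]] +
        partial_dependence(mod, v, pd_grids[[v]])$p
    if (predict_stack) {
      pr <- rep(NA_real_, nrow(m))
      pr[attr(m, "valid")] <-
        predict(mod, m[attr(m, "valid"), , drop = FALSE])
      if (is.null(pred_sum)) {
        pred_sum <- pr
        pred_runs_sd <- pr^2
      } else {
        pred_sum <- pred_sum + pr
        pred_runs_sd <- pred_runs_sd + pr^2
      }
    }
    runs[[r]] <- mod
  }

  metrics <- data.frame(
    metric = colnames(met),
    mean = colMeans(met), sd = apply(met, 2, sd),
    min = apply(met, 2, min), max = apply(met, 2, max),
    row.names = NULL)
  importance <- colMeans(imp)
  importance <- 100 * importance / sum(importance)
  pd <- lapply(vars, function(v)
    data.frame(value = pd_grids[[v]], p = pd_sum[[v]] / n_runs))
  names(pd) <- vars

  prediction <- NULL
  if (predict_stack) {
    ref <- stack$layers[[1]]
    prediction <- raster_grid(
      matrix(pred_sum / n_runs, nrow(ref$values), ncol(ref$values)),
      ref$cell_size, ref$origin)
  }
  structure(list(runs = runs, metrics = metrics, importance = importance,
                 importance_runs = imp, partial_dependence = pd,
                 prediction = prediction, n_runs = n_runs,
                 master_seed = master_seed, hp = hp),
            class = "bct_ensemble")
}

#' @export
print.bct_ensemble <- function(x, ...) {
  cat(sprintf("bct_ensemble: %d runs\n", x$n_runs))
  print(x$metrics, digits = 3)
  invisible(x)
}

#' Averaged ensemble prediction over an environmental stack
#'
#' Per-cell mean probability of the run models; nodata propagates.
#'
#' @param e a `bct_ensemble`
#' @param stack an [env_stack()] (may differ from the training stack)
#' @return a [raster_grid()] of probabilities
#' @export
predict_map <- function(e, stack) {
  stopifnot(inherits(e, "bct_ensemble"), inherits(stack, "env_stack"))
  m <- stack_matrix(stack)
  valid <- attr(m, "valid")
  acc <- numeric(sum(valid))
  for (mod in e$runs)
    acc <- acc + predict(mod, m[valid, , drop = FALSE])
  pr <- rep(NA_real_, nrow(m))
  pr[valid] <- acc / length(e$runs)
  ref <- stack$layers[[1]]
  raster_grid(matrix(pr, nrow(ref$values), ncol(ref$values)),
              ref$cell_size, ref$origin)
}

#' Area by suitability class
#'
#' Tabulates the area of a suitability map per class (classes partition
#' `[0, 1]`: intervals are left-closed, the last also right-closed) and the
#' area above a set of thresholds.
#'
#' @param map a [raster_grid()] with values in `[0, 1]`
#' @param breaks increasing break points spanning `[0, 1]`
#' @param thresholds suitability thresholds for the cumulative summary
#' @return list: `classes` (data.frame class, n_cells, area_ha, area_km2)
#'   and `above` (data.frame threshold, n_cells, area_ha, area_km2)
#' @export
area_by_suitability <- function(map, breaks = seq(0, 1, by = 0.1),
                                thresholds = c(0.2, 0.5, 0.7, 0.8)) {
  stopifnot(is_raster_grid(map))
  v <- as.vector(map$values)
  v <- v[!is.na(v)]
  if (any(v < -1e-9 | v > 1 + 1e-9)) stop("map values must be in [0, 1]")
  if (breaks[1] != 0 || breaks[length(breaks)] != 1)
    stop("breaks must span [0, 1]")
  cell_ha <- map$cell_size^2 / 1e4
  # left-closed intervals; include.lowest closes the last one at 1
  cls <- cut(v, breaks, include.lowest = TRUE, right = FALSE)
  n <- as.vector(table(cls))
  classes <- data.frame(class = levels(cls), n_cells = n,
                        area_ha = n * cell_ha,
                        area_km2 = n * cell_ha / 100)
  na <- vapply(thresholds, function(t) sum(v > t), numeric(1))
  above <- data.frame(threshold = thresholds, n_cells = na,
                      area_ha = na * cell_ha, area_km2 = na * cell_ha / 100)
  list(classes = classes, above = above)
}
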