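#' Build a population dataset for position decoding
#'
#' Rows are running-trial frames; columns the chosen ROI subset's event-trace
#' values; labels are track-position classes at decoding granularity `G`
#' (equally spaced bins). Sessions with fewer than 3 observations in any
#' class are rejected with a diagnosis.
#'
#' @param event_traces Frames x ROI matrix of event-trace values (full
#'   session).
#' @param trajectory `trajectory` object or frame data.frame with `position`.
#' @param trials Running trials ([find_running_trials()]).
#' @param G Decoding granularity (number of position classes).
#' @param kinds ROI kind per column (used by `subset`).
#' @param subset `"astro"`, `"neuro"` or `"both"`.
#' @param corridor_length_cm Track length (cm).
#' @param min_per_class Minimum observations per class.
#' @return List of class `population_dataset`: `X` (frames x ROIs), `y`
#'   (integer classes `1..G`), `G`, `subset`, `frame_index`.
#' @export
build_population_dataset <- function(event_traces, trajectory, trials, G,
                                     kinds = NULL, subset = "both",
                                     corridor_length_cm = 180,
                                     min_per_class = 3) {
  event_traces <- as.matrix(event_traces)
  fr <- if (inherits(trajectory, "trajectory")) trajectory$frames else trajectory
  idx <- trial_frames(trials)
  if (!length(idx)) stop("no running-trial frames", call. = FALSE)
  keep <- seq_len(ncol(event_traces))
  if (!is.null(kinds) && subset != "both") {
    keep <- if (subset == "astro") which(grepl("^astro", kinds))
            else which(grepl("^neuron", kinds))
    if (!length(keep)) stop("no ROIs in subset '", subset, "'", call. = FALSE)
  }
  X <- event_traces[idx, keep, drop = FALSE]
  y <- equal_width_bins(fr$position[idx], G, lo = 0, hi = corridor_length_cm)
  cnt <- tabulate(y, nbins = G)
  if (any(cnt < min_per_class))
    stop("under-populated position bin(s) at G = ", G, ": bin(s) ",
         paste(which(cnt < min_per_class), collapse = ", "), " have ",
         paste(cnt[cnt < min_per_class], collapse = ", "),
         " observations (need >= ", min_per_class, ")", call. = FALSE)
  structure(list(X = X, y = as.integer(y), G = as.integer(G),
                 subset = subset, frame_index = idx),
            class = "population_dataset")
}

## stratified fold assignment: classes spread evenly over folds
stratified_folds <- function(y, k) {
  fold <- integer(length(y))
  for (cl in unique(y)) {
    idx <- sample(which(y == cl))
    fold[idx] <- rep_len(sample(k), length(idx))
  }
  fold
}

#' RBF kernel width heuristic
#'
#' The `scale` heuristic `1 / (n_features * var(X))`; the default gamma grid
#' of [decode_cv()] is this value times `c(0.1, 1, 10)`.
#'
#' @param X Feature matrix.
#' @return Scalar gamma.
#' @export
svm_gamma_scale <- function(X) {
  v <- stats::var(as.vector(X))
  if (!is.finite(v) || v == 0) v <- 1
  1 / (ncol(X) * v)
}

#' Cross-validated SVM position decoding
#'
#' Outer 10-fold cross-validation (folds stratified by position class); in
#' each outer fold the RBF-kernel SVM hyperparameters (cost, kernel width)
#' are chosen by inner 5-fold cross-validation over a log grid, the model is
#' refit on the fold's training set, and test predictions from all outer
#' folds are pooled into one confusion matrix.
#'
#' @param dataset A [build_population_dataset()] result, or a list with `X`,
#'   `y`, `G`.
#' @param folds,inner_folds Outer / inner fold counts.
#' @param cost_grid Candidate SVM regularization costs.
#' @param gamma_grid Candidate RBF widths; default is the scale heuristic
#'   `1 / (n_features * var(X))` times `c(0.1, 1, 10)`.
#' @param seed Integer seed (fold assignment); predictions are deterministic
#'   given the seed.
#' @return List of class `decoding_result`: `confusion` (G x G, true x
#'   predicted), `decoded_info` (bootstrap-corrected bits), `info_plugin`,
#'   `accuracy`, `predictions`, `hyperparameters` (per outer fold).
#' @export
decode_cv <- function(dataset, folds = 10, inner_folds = 5,
                      cost_grid = c(0.1, 1, 10, 100),
                      gamma_grid = NULL, seed = 1L) {
  X <- as.matrix(dataset$X)
  y <- factor(dataset$y, levels = seq_len(dataset$G))
  G <- dataset$G
  if (min(tabulate(as.integer(y), G)) < 1L)
    stop("empty position class: rebuild the dataset at a coarser G",
         call. = FALSE)
  if (is.null(gamma_grid))
    gamma_grid <- svm_gamma_scale(X) * c(0.1, 1, 10)
  set.seed(derive_seed(seed, 12L))
  fold <- stratified_folds(as.integer(y), folds)
  if (length(unique(fold)) < folds)
    stop("fewer than ", folds, " usable groups", call. = FALSE)
  pred <- factor(rep(NA, length(y)), levels = levels(y))
  hp <- data.frame(fold = seq_len(folds), cost = NA_real_, gamma = NA_real_)
  grid <- expand.grid(cost = cost_grid, gamma = gamma_grid)
  for (f in seq_len(folds)) {
    tr <- which(fold != f)
    te <- which(fold == f)
    best <- c(acc = -1, cost = cost_grid[1], gamma = gamma_grid[1])
    if (nrow(grid) > 1L) {
      inner <- stratified_folds(as.integer(y)[tr], inner_folds)
      for (g in seq_len(nrow(grid))) {
        acc <- 0
        for (fi in seq_len(inner_folds)) {
          itr <- tr[inner != fi]
          ite <- tr[inner == fi]
          fit <- e1071::svm(X[itr, , drop = FALSE], y[itr],
                            kernel = "radial", cost = grid$cost[g],
                            gamma = grid$gamma[g], scale = FALSE)
          acc <- acc + mean(stats::predict(fit, X[ite, , drop = FALSE]) ==
                              y[ite])
        }
        acc <- acc / inner_folds
        if (acc > best[["acc"]])
          best <- c(acc = acc, cost = grid$cost[g], gamma = grid$gamma[g])
      }
    }
    hp$cost[f] <- best[["cost"]]
    hp$gamma[f] <- best[["gamma"]]
    fit <- e1071::svm(X[tr, , drop = FALSE], y[tr], kernel = "radial",
                      cost = best[["cost"]], gamma = best[["gamma"]],
                      scale = FALSE)
    pred[te] <- stats::predict(fit, X[te, , drop = FALSE])
  }
  confusion <- table(true = y, predicted = pred)
  ev <- evaluate_confusion(confusion, seed = seed)
  structure(list(confusion = unclass(confusion),
                 decoded_info = ev$decoded_info,
                 info_plugin = ev$info_plugin,
                 accuracy = ev$accuracy,
                 predictions = as.integer(pred),
                 hyperparameters = hp),
            class = "decoding_result")
}

#' Decoded information and accuracy from a confusion matrix
#'
#' Decoded information is the plug-in MI between true and predicted position
#' (the normalized confusion matrix), corrected with the conservative
#' bootstrap method (subtracting the mean MI over permutations of the
#' predicted labels); accuracy is the fraction of correct predictions.
#'
#' @param confusion G x G counts matrix (true x predicted).
#' @param n_boot Bootstrap permutations for the bias correction.
#' @param seed Integer seed.
#' @return List: `decoded_info` (bits, corrected), `info_plugin`, `accuracy`.
#' @export
evaluate_confusion <- function(confusion, n_boot = 100, seed = 1L) {
  confusion <- as.matrix(confusion)
  total <- sum(confusion)
  if (total == 0) stop("empty confusion matrix", call. = FALSE)
  plugin <- mi_from_counts(confusion)
  ## reconstruct (true, predicted) pairs and permute predictions
  G <- nrow(confusion)
  truth <- rep(seq_len(G), rowSums(confusion))
  predicted <- unlist(lapply(seq_len(G), function(i)
    rep(seq_len(G), confusion[i, ])), use.names = FALSE)
  set.seed(derive_seed(seed, 13L))
  null <- vapply(seq_len(n_boot), function(b)
    mi_from_counts(joint_counts(truth, sample(predicted), G, G)),
    numeric(1))
  list(decoded_info = plugin - mean(null), info_plugin = plugin,
       accuracy = sum(diag(confusion)) / total)
}

#' Chance null distribution for population decoding
#'
#' Repeats the full decode-evaluate cycle after randomly permuting the
#' position labels against the responses (frame-wise), removing all position
#' information; returns the null distribution of decoded information and a
#' one-tailed p-value for the observed value.
#'
#' @param dataset A `population_dataset`.
#' @param n_perm Number of permutations.
#' @param seed Integer seed.
#' @param observed Optional precomputed [decode_cv()] result to compare.
#' @param ... Passed to [decode_cv()] (e.g. smaller grids for nulls).
#' @return List: `null_info`, `null_accuracy`, `p_value`, `observed`.
#' @export
chance_null <- function(dataset, n_perm = 1e3, seed = 1L, observed = NULL,
                        ...) {
  if (is.null(observed)) observed <- decode_cv(dataset, seed = seed, ...)
  set.seed(derive_seed(seed, 14L))
  perms <- lapply(seq_len(n_perm), function(i) sample(length(dataset$y)))
  vals <- matrix(NA_real_, n_perm, 2)
  for (i in seq_len(n_perm)) {
    ds <- dataset
    ds$y <- dataset$y[perms[[i]]]
    res <- decode_cv(ds, seed = derive_seed(seed, 100L + i), ...)
    vals[i, ] <- c(res$decoded_info, res$accuracy)
  }
  list(null_info = vals[, 1], null_accuracy = vals[, 2],
       p_value = (1 + sum(vals[, 1] >= observed$decoded_info)) / (n_perm + 1),
       observed = observed)
}

#' Trial-shuffle null for population decoding
#'
#' Within each position class, the event-trace values of each ROI are
#' independently permuted across frames, preserving single-ROI position
#' tuning (each ROI's per-class response histogram is exactly preserved)
#' while destroying within-trial correlations between ROIs; the full decode
#' cycle runs per shuffle. Tests whether temporal coupling across the
#' population adds decodable information.
#'
#' @inheritParams chance_null
#' @param n_shuffle Number of shuffles.
#' @return List: `null_info`, `null_accuracy`, `p_value`, `observed`.
#' @export
trial_shuffle_null <- function(dataset, n_shuffle = 500, seed = 1L,
                               observed = NULL, ...) {
  if (is.null(observed)) observed <- decode_cv(dataset, seed = seed, ...)
  vals <- matrix(NA_real_, n_shuffle, 2)
  for (i in seq_len(n_shuffle)) {
    set.seed(derive_seed(seed, 200L + i))
    ds <- dataset
    ds$X <- within_stimulus_shuffle(dataset$y, dataset$X)
    res <- decode_cv(ds, seed = derive_seed(seed, 300L + i), ...)
    vals[i, ] <- c(res$decoded_info, res$accuracy)
  }
  list(null_info = vals[, 1], null_accuracy = vals[, 2],
       p_value = (1 + sum(vals[, 1] >= observed$decoded_info)) /
         (n_shuffle + 1),
       observed = observed)
}

#' Decoding error profile
#'
#' Histogram of signed prediction errors (predicted minus true class) over
#' misclassified samples only, with a nonlinear least-squares Gaussian fit
#' and its R-squared.
#'
#' @param confusion G x G counts matrix (true x predicted).
#' @return List: `errors` (data.frame `distance`, `count`), `fit`
#'   (`amplitude`, `mean`, `sigma`, `r_squared`; `NULL` if the fit failed),
#'   `empty` (TRUE when the decoder made no errors).
#' @export
error_profile <- function(confusion) {
  confusion <- as.matrix(confusion)
  G <- nrow(confusion)
  d <- outer(seq_len(G), seq_len(G), function(i, j) j - i)
  off <- d != 0
  dist_vals <- (-(G - 1)):(G - 1)
  counts <- vapply(dist_vals, function(k) sum(confusion[off & d == k]),
                   numeric(1))
  if (sum(counts) == 0)
    return(list(errors = data.frame(distance = dist_vals, count = counts),
                fit = NULL, empty = TRUE))
  df <- data.frame(distance = dist_vals, count = counts)
  fit <- tryCatch({
    m <- minpack.lm::nlsLM(count ~ a * exp(-(distance - mu)^2 / (2 * s^2)),
                           data = df,
                           start = list(a = max(counts),
                                        mu = stats::weighted.mean(dist_vals,
                                                                  counts),
                                        s = max(1, stats::sd(rep(dist_vals,
                                                                 counts)))),
                           control = minpack.lm::nls.lm.control(maxiter = 200))
    cf <- stats::coef(m)
    ss_res <- sum(stats::residuals(m)^2)
    ss_tot <- sum((counts - mean(counts))^2)
    list(amplitude = cf[["a"]], mean = cf[["mu"]], sigma = abs(cf[["s"]]),
         r_squared = if (ss_tot > 0) 1 - ss_res / ss_tot else NA_real_)
  }, error = function(e) NULL)
  list(errors = df, fit = fit, empty = FALSE)
}

#' Cue-constrained shuffle decoding: genuine population information
#'
#' Repeats the decode cycle after shuffling position labels within each
#' visual-cue zone (destroying within-zone positional structure while
#' preserving cue identity). `I_V` is the mean decoded information over
#' permutations; the genuine fraction is `(I - I_V) / I`.
#'
#' @param dataset A `population_dataset` built at a granularity `G` divisible
#'   by the number of cue zones.
#' @param positions Track positions (cm) for the dataset's frames.
#' @param cue_zone Cue-zone label per dataset frame.
#' @param n_perm Number of cue-constrained permutations.
#' @param corridor_length_cm Track length (cm).
#' @param seed Integer seed.
#' @param ... Passed to [decode_cv()].
#' @return List: `I` (observed decoded info), `I_V_mean`, `I_V` (vector),
#'   `genuine_fraction`.
#' @export
cue_shuffle_decoding <- function(dataset, positions, cue_zone, n_perm = 500,
                                 corridor_length_cm = 180, seed = 1L, ...) {
  zones <- sort(unique(cue_zone))
  if (dataset$G %% length(zones) != 0)
    stop("G must be divisible by the number of cue zones", call. = FALSE)
  obs <- decode_cv(dataset, seed = seed, ...)
  iv <- numeric(n_perm)
  for (i in seq_len(n_perm)) {
    set.seed(derive_seed(seed, 400L + i))
    p2 <- positions
    for (z in zones) {
      idx <- which(cue_zone == z)
      if (length(idx) > 1L) p2[idx] <- positions[sample(idx)]
    }
    ds <- dataset
    ds$y <- equal_width_bins(p2, dataset$G, lo = 0, hi = corridor_length_cm)
    res <- decode_cv(ds, seed = derive_seed(seed, 500L + i), ...)
    iv[i] <- res$decoded_info
  }
  ivm <- mean(iv)
  list(I = obs$decoded_info, I_V_mean = ivm, I_V = iv,
       genuine_fraction = if (obs$decoded_info != 0)
         (obs$decoded_info - ivm) / obs$decoded_info else NA_real_,
       observed = obs)
}
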