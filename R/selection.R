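# Interpretable random-forest feature selection in four steps:
# (1) rank features by impurity importance averaged over many forests,
# (2) eliminate features below a CART-derived importance threshold,
# (3) pick the nested model with minimal out-of-bag (OOB) error
#     (interpretation set),
# (4) prune redundancy by sequential introduction with an error-gain
#     threshold (classification set).
# Model evaluation uses grid-searched repeated 10-fold cross-validation.

.resolve_mtry <- function(max_features, p) {
  if (identical(max_features, "sqrt")) return(max(1L, floor(sqrt(p))))
  mf <- suppressWarnings(as.numeric(max_features))
  if (is.na(mf) || mf <= 0 || mf > 1) {
    stop("max_features must be 'sqrt' or a fraction in (0, 1]")
  }
  max(1L, floor(mf * p))
}

# Permutation importance throughout: unlike impurity importance it is
# centred at zero for uninformative features, which is what the
# sd-derived elimination threshold of step two presumes.
# ranger reserves seed 0 for "unseeded", so the protocol's zero-based
# random states are offset by one to stay deterministic.
.rf_fit <- function(x, y, num_trees, mtry, seed) {
  ranger::ranger(x = x, y = y, num.trees = num_trees, mtry = mtry,
                 importance = "permutation", seed = seed + 1L,
                 num.threads = 1, respect.unordered.factors = TRUE)
}

#' Rank features by averaged forest importance
#'
#' Fits `n_runs` random forests with distinct seeds (`seed_base`,
#' `seed_base + 1`, ...) and ranks features by their mean impurity
#' importance in descending order, ties broken by original column index.
#' Defaults follow the reference protocol: 50 runs of 2000 trees with
#' `max_features = 0.3`.
#'
#' @param x Data frame or matrix of features (rows = recordings).
#' @param y Class labels (factor or coercible).
#' @param n_runs Number of forests to average over.
#' @param num_trees Trees per forest.
#' @param max_features Fraction of features tried per split, or `"sqrt"`.
#' @param seed_base First seed; run r uses `seed_base + r - 1`.
#' @return Object of class `rf_ranking`: data frame with `feature`,
#'   `index`, `mean_importance`, `sd_importance`, sorted by rank.
#' @export
rank_features <- function(x, y, n_runs = 50, num_trees = 2000,
                          max_features = 0.3, seed_base = 0) {
  x <- as.data.frame(x)
  y <- as.factor(y)
  if (nlevels(droplevels(y)) < 2) stop("need at least two classes")
  if (nrow(x) < 10) stop("need at least 10 rows")
  p <- ncol(x)
  mtry <- .resolve_mtry(max_features, p)
  imp <- matrix(0, n_runs, p)
  for (r in seq_len(n_runs)) {
    fit <- .rf_fit(x, y, num_trees, mtry, seed = seed_base + r - 1L)
    imp[r, ] <- fit$variable.importance
  }
  mean_imp <- colMeans(imp)
  sd_imp <- apply(imp, 2, stats::sd)
  ord <- order(-mean_imp, seq_len(p))
  structure(data.frame(feature = colnames(x)[ord], index = ord,
                       mean_importance = mean_imp[ord],
                       sd_importance = sd_imp[ord]),
            n_runs = n_runs, class = c("rf_ranking", "data.frame"))
}

#' Eliminate features below the CART importance threshold
#'
#' Fits a depth-limited regression tree of the importance standard
#' deviation against the rank; the threshold is the minimum predicted
#' value, and features whose mean importance falls below it are removed.
#' The surviving set is always a prefix of the ranking.
#'
#' @param ranking An `rf_ranking`.
#' @param maxdepth Depth limit of the regression tree (default 3).
#' @return The surviving subset of `ranking`, with attribute `threshold`.
#' @export
eliminate_features <- function(ranking, maxdepth = 3) {
  stopifnot(inherits(ranking, "rf_ranking"))
  rank_pos <- seq_len(nrow(ranking))
  fit <- rpart::rpart(sd ~ rank,
                      data = data.frame(sd = ranking$sd_importance,
                                        rank = rank_pos),
                      control = rpart::rpart.control(maxdepth = maxdepth,
                                                     cp = 0.01,
                                                     minsplit = 2))
  threshold <- min(stats::predict(fit))
  keep <- ranking$mean_importance >= threshold
  if (!any(keep)) {
    warning("threshold removed every feature; falling back to the top 10")
    keep <- rank_pos <= 10
  }
  out <- ranking[keep, , drop = FALSE]
  attr(out, "threshold") <- threshold
  attr(out, "n_runs") <- attr(ranking, "n_runs")
  class(out) <- class(ranking)
  out
}

#' Interpretation set by minimal out-of-bag error
#'
#' Grows nested forests over prefixes of the surviving ranking (most
#' important feature first, adding one at a time) and returns the prefix
#' with the smallest OOB error (first minimum on ties).
#'
#' @param x,y Feature table and labels (as in [rank_features()]).
#' @param surviving Surviving ranking from [eliminate_features()] (or any
#'   data frame with a `feature` column ordered by rank).
#' @param num_trees Trees per nested model (default 500).
#' @param max_features `"sqrt"` (default) or a fraction.
#' @param seed Seed used for every nested model.
#' @return List with `features` (the interpretation set), `oob_trace`
#'   (OOB error per prefix size) and `p_interp`.
#' @export
select_interpretation <- function(x, y, surviving, num_trees = 500,
                                  max_features = "sqrt", seed = 0) {
  x <- as.data.frame(x)
  y <- as.factor(y)
  feats <- as.character(surviving$feature)
  stopifnot(length(feats) >= 1)
  oob <- numeric(length(feats))
  for (k in seq_along(feats)) {
    xk <- x[, feats[seq_len(k)], drop = FALSE]
    fit <- .rf_fit(xk, y, num_trees, .resolve_mtry(max_features, k), seed)
    oob[k] <- fit$prediction.error
    if (!is.finite(oob[k])) stop("OOB error undefined for prefix size ", k)
  }
  p_interp <- which.min(oob)
  list(features = feats[seq_len(p_interp)], oob_trace = oob,
       p_interp = p_interp)
}

#' Error-gain threshold for sequential introduction
#'
#' Mean absolute first difference of the OOB-error trace between the
#' interpretation prefix and the full surviving set:
#' threshold = sum(|oob(j+1) - oob(j)|, j = p_interp .. p_elim - 1) /
#' (p_elim - p_interp).
#'
#' @param oob_trace OOB errors per prefix size.
#' @param p_interp,p_elim Interpretation and surviving set sizes.
#' @return The threshold; `NA` when `p_elim == p_interp`.
#' @export
error_gain_threshold <- function(oob_trace, p_interp, p_elim) {
  stopifnot(p_elim <= length(oob_trace), p_interp <= p_elim)
  if (p_elim == p_interp) return(NA_real_)
  js <- p_interp:(p_elim - 1L)
  sum(abs(oob_trace[js + 1L] - oob_trace[js])) / (p_elim - p_interp)
}

#' Classification set by thresholded sequential introduction
#'
#' Starting from the top-ranked interpretation feature, each further
#' interpretation feature is added only if it lowers the OOB error by
#' more than the [error_gain_threshold()]. Removes redundant features
#' while keeping classification performance.
#'
#' @param x,y Feature table and labels.
#' @param interpretation Result of [select_interpretation()].
#' @param p_elim Size of the surviving (post-elimination) set.
#' @param num_trees,max_features,seed Forest settings (defaults 500,
#'   `"sqrt"`, 0).
#' @return List with `features` (classification set), `threshold`, and
#'   `oob_path` (OOB error after each accepted feature).
#' @export
select_classification <- function(x, y, interpretation, p_elim,
                                  num_trees = 500, max_features = "sqrt",
                                  seed = 0) {
  x <- as.data.frame(x)
  y <- as.factor(y)
  feats <- interpretation$features
  thr <- error_gain_threshold(interpretation$oob_trace,
                              interpretation$p_interp, p_elim)
  if (is.na(thr)) {
    warning("threshold undefined (no eliminated tail); ",
            "classification set equals the interpretation set")
    return(list(features = feats, threshold = NA_real_,
                oob_path = interpretation$oob_trace[length(feats)]))
  }
  current <- feats[1]
  fit <- .rf_fit(x[, current, drop = FALSE], y, num_trees,
                 .resolve_mtry(max_features, 1L), seed)
  oob_cur <- fit$prediction.error
  path <- oob_cur
  for (f in feats[-1]) {
    cand <- c(current, f)
    fit <- .rf_fit(x[, cand, drop = FALSE], y, num_trees,
                   .resolve_mtry(max_features, length(cand)), seed)
    if (oob_cur - fit$prediction.error > thr) {
      current <- cand
      oob_cur <- fit$prediction.error
      path <- c(path, oob_cur)
    }
  }
  list(features = current, threshold = thr, oob_path = path)
}

#' Run the full four-step selection procedure
#'
#' @param x Feature table (data frame, rows = recordings).
#' @param y Class labels.
#' @param n_runs,rank_trees,rank_max_features Step-one settings (defaults
#'   50 runs of 2000 trees at 0.3).
#' @param nested_trees Step three/four forest size (default 500).
#' @param seed_base Base seed for step one; steps three and four use
#'   seed 0 as in the reference protocol.
#' @return Object of class `rf_selection`: list with `ranking`,
#'   `surviving`, `elimination_threshold`, `interpretation`,
#'   `classification`, `oob_trace`, `eq_threshold`.
#' @export
rf_select <- function(x, y, n_runs = 50, rank_trees = 2000,
                      rank_max_features = 0.3, nested_trees = 500,
                      seed_base = 0) {
  ranking <- rank_features(x, y, n_runs = n_runs, num_trees = rank_trees,
                           max_features = rank_max_features,
                           seed_base = seed_base)
  surv <- eliminate_features(ranking)
  interp <- select_interpretation(x, y, surv, num_trees = nested_trees)
  cls <- select_classification(x, y, interp, p_elim = nrow(surv),
                               num_trees = nested_trees)
  structure(list(ranking = ranking, surviving = as.character(surv$feature),
                 elimination_threshold = attr(surv, "threshold"),
                 interpretation = interp$features,
                 classification = cls$features,
                 oob_trace = interp$oob_trace,
                 eq_threshold = cls$threshold),
            class = "rf_selection")
}

#' @export
print.rf_selection <- function(x, ...) {
  cat("<rf_selection>\n",
      " surviving:      ", length(x$surviving), " features\n",
      " interpretation: ", paste(x$interpretation, collapse = ", "), "\n",
      " classification: ", paste(x$classification, collapse = ", "), "\n",
      sep = "")
  invisible(x)
}

# Fold assignment: stratified by class, or grouped so that all rows of a
# subject share a fold (avoiding paired-subject leakage across folds).
.make_folds <- function(y, k, groups = NULL, seed = 0) {
  set.seed(seed)
  n <- length(y)
  fold <- integer(n)
  if (is.null(groups)) {
    for (cl in levels(y)) {
      idx <- sample(which(y == cl))
      fold[idx] <- rep_len(seq_len(k), length(idx))
    }
  } else {
    gs <- sample(unique(groups))
    gf <- rep_len(seq_len(k), length(gs))
    fold <- gf[match(groups, gs)]
  }
  fold
}

#' Evaluate a feature set by grid-searched repeated cross-validation
#'
#' For each random state, features are assessed by 10-fold cross-validated
#' accuracy over a grid of forest sizes and `max_features` options; the
#' best grid accuracy is recorded, and the mean/max/min over the random
#' states reported. Default grid: trees 40 to 540 in steps of 50;
#' `max_features` 0.3, `"sqrt"`, 0.7; random states 0-29.
#'
#' @param x,y Feature table and labels.
#' @param features Character vector of feature columns to use.
#' @param num_trees_grid Grid of forest sizes.
#' @param max_features_opts List of `max_features` options.
#' @param random_states Integer vector of random states.
#' @param folds Number of CV folds (default 10).
#' @param groups Optional grouping vector (e.g. subject ids) for grouped
#'   folds.
#' @return Object of class `model_eval`: list with `mean`, `max`, `min`,
#'   `per_state` (best accuracy per random state) and `best` (modal best
#'   hyperparameters).
#' @export
evaluate_features <- function(x, y, features,
                              num_trees_grid = seq(40, 540, by = 50),
                              max_features_opts = list(0.3, "sqrt", 0.7),
                              random_states = 0:29, folds = 10,
                              groups = NULL) {
  x <- as.data.frame(x)[, features, drop = FALSE]
  y <- as.factor(y)
  if (min(table(y)) < folds) {
    warning("a class has fewer members than folds; folds remain stratified")
  }
  p <- ncol(x)
  acc_state <- numeric(length(random_states))
  best_combo <- character(length(random_states))
  for (si in seq_along(random_states)) {
    s <- random_states[si]
    fold <- .make_folds(y, folds, groups = groups, seed = s)
    best <- -Inf
    for (nt in num_trees_grid) {
      for (mf in max_features_opts) {
        mtry <- .resolve_mtry(mf, p)
        correct <- 0L
        for (f in seq_len(folds)) {
          tr <- fold != f
          if (all(tr) || !any(tr)) next
          fit <- ranger::ranger(x = x[tr, , drop = FALSE], y = y[tr],
                                num.trees = nt, mtry = mtry, seed = s + 1L,
                                num.threads = 1)
          pred <- stats::predict(fit, data = x[!tr, , drop = FALSE])
          correct <- correct + sum(pred$predictions == y[!tr])
        }
        acc <- correct / length(y)
        if (acc > best) {
          best <- acc
          best_combo[si] <- paste0(nt, "/", mf)
        }
      }
    }
    acc_state[si] <- best
  }
  structure(list(mean = mean(acc_state), max = max(acc_state),
                 min = min(acc_state), per_state = acc_state,
                 best = names(sort(table(best_combo), decreasing = TRUE))[1]),
            class = "model_eval")
}

#' @export
print.model_eval <- function(x, ...) {
  cat(sprintf("<model_eval> accuracy mean %.3f (max %.3f, min %.3f), best %s\n",
              x$mean, x$max, x$min, x$best))
  invisible(x)
}
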