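# Reduced forest settings are used throughout these unit tests; the
# reference protocol sizes (50 runs of 2000 trees, etc.) only change how
# tightly the importance estimates concentrate, not the logic under test.

test_that("ranking puts a planted deterministic feature first", {
  pt <- planted_table(n = 60, p = 10, seed = 4, effect = 2)
  rk <- rank_features(pt$x, pt$y, n_runs = 5, num_trees = 300)
  expect_s3_class(rk, "rf_ranking")
  expect_true(rk$feature[1] %in% c("V001", "V002"))
  expect_true(all(c("V001", "V002") %in% rk$feature[1:3]))
  # determinism: identical seeds give the identical ranking
  rk2 <- rank_features(pt$x, pt$y, n_runs = 5, num_trees = 300)
  expect_identical(rk$feature, rk2$feature)
  expect_identical(rk$mean_importance, rk2$mean_importance)
})

test_that("null tables produce no dominant importance", {
  set.seed(8)
  x <- as.data.frame(matrix(rnorm(60 * 10), 60))
  y <- factor(rep(c("A", "B"), 30))
  rk_null <- rank_features(x, y, n_runs = 5, num_trees = 300)
  pt <- planted_table(n = 60, p = 10, seed = 8, effect = 2)
  rk_sig <- rank_features(pt$x, pt$y, n_runs = 5, num_trees = 300)
  expect_lt(max(rk_null$mean_importance), rk_sig$mean_importance[1] / 3)
  expect_error(rank_features(x, factor(rep("A", 60))), "two classes")
})

test_that("elimination keeps a prefix and planted features survive", {
  pt <- planted_table(n = 112, p = 40, seed = 2, effect = 1.5)
  rk <- rank_features(pt$x, pt$y, n_runs = 8, num_trees = 300)
  surv <- eliminate_features(rk)
  expect_true(all(c("V001", "V002") %in% surv$feature))
  # prefix of the ranking
  expect_identical(as.character(surv$feature),
                   as.character(rk$feature[seq_len(nrow(surv))]))
  expect_true(is.finite(attr(surv, "threshold")))
  # equal importances: the threshold cannot remove anything
  flat <- structure(data.frame(feature = paste0("f", 1:8), index = 1:8,
                               mean_importance = rep(0.5, 8),
                               sd_importance = rep(0.1, 8)),
                    n_runs = 5, class = c("rf_ranking", "data.frame"))
  expect_equal(nrow(eliminate_features(flat)), 8L)
})

test_that("interpretation set minimises the nested OOB trace", {
  pt <- planted_table(n = 112, p = 12, seed = 3, effect = 1.5)
  rk <- rank_features(pt$x, pt$y, n_runs = 5, num_trees = 300)
  surv <- eliminate_features(rk)
  it <- select_interpretation(pt$x, pt$y, surv, num_trees = 200)
  expect_length(it$oob_trace, nrow(surv))
  expect_equal(it$p_interp, which.min(it$oob_trace))
  expect_true(all(c("V001", "V002") %in% it$features))
  one <- surv[1, , drop = FALSE]
  it1 <- select_interpretation(pt$x, pt$y, one, num_trees = 200)
  expect_identical(it1$features, as.character(one$feature))
})

test_that("the error-gain threshold matches hand computation", {
  expect_equal(error_gain_threshold(c(0.20, 0.18, 0.18, 0.17), 1, 4),
               (abs(0.18 - 0.20) + abs(0.18 - 0.18) + abs(0.17 - 0.18)) / 3)
  expect_equal(error_gain_threshold(c(0.20, 0.18, 0.18, 0.17), 1, 4), 0.01)
  expect_true(is.na(error_gain_threshold(c(0.2, 0.1), 2, 2)))
})

test_that("classification pruning drops an exact duplicate", {
  pt <- planted_table(n = 112, p = 110, seed = 1002, effect = 2.5,
                      duplicate = TRUE)   # V003 duplicates V001
  sel <- suppressWarnings(
    rf_select(pt$x, pt$y, n_runs = 5, rank_trees = 250,
              nested_trees = 500, seed_base = 2))
  expect_true(all(sel$classification %in% sel$interpretation))
  expect_true(all(sel$interpretation %in% sel$surviving))
  expect_false(all(c("V001", "V003") %in% sel$classification))
  expect_true(any(c("V001", "V003") %in% sel$classification))
})

test_that("degenerate classification-threshold case falls back", {
  pt <- planted_table(n = 60, p = 10, seed = 6, effect = 2)
  it <- list(features = c("V001", "V002"), oob_trace = c(0.2, 0.1),
             p_interp = 2L)
  expect_warning(
    cls <- select_classification(pt$x, pt$y, it, p_elim = 2L,
                                 num_trees = 100),
    "threshold undefined")
  expect_identical(cls$features, it$features)
})

test_that("cross-validated evaluation brackets separable and null tables", {
  pt <- planted_table(n = 80, p = 6, seed = 7, effect = 6)  # separable
  ev <- evaluate_features(pt$x, pt$y, c("V001", "V002"),
                          num_trees_grid = c(90, 190),
                          max_features_opts = list("sqrt"),
                          random_states = 0:2)
  expect_gt(ev$mean, 0.99)
  expect_true(ev$max >= ev$mean && ev$mean >= ev$min)

  set.seed(11)
  xn <- as.data.frame(matrix(rnorm(80 * 6), 80))
  yn <- factor(rep(c("A", "B"), 40))
  evn <- evaluate_features(xn, yn, names(xn)[1:3],
                           num_trees_grid = c(90, 190),
                           max_features_opts = list("sqrt"),
                           random_states = 0:4)
  expect_gt(evn$mean, 0.35)
  expect_lt(evn$mean, 0.65)
})

test_that("grouped folds never split a subject across train and test", {
  y <- factor(rep(c("A", "B"), each = 20))
  groups <- rep(1:10, each = 4)
  fold <- ppgans:::.make_folds(y, 5, groups = groups, seed = 1)
  expect_true(all(tapply(fold, groups, function(f) length(unique(f))) == 1))
})
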