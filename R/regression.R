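# Stepwise regression of the respiration-referenced spectral indices on
# selected PPG features, and paired between-state comparisons.

#' Stepwise linear regression by partial F-tests
#'
#' Forward entry with backward removal: at each step the candidate whose
#' partial regression sum of squares is most significant enters if its
#' partial F-test p-value is at most `alpha_enter`; previously entered
#' variables are then re-tested and removed while the least significant
#' exceeds `alpha_remove`. Iterates to a fixed point. Candidates whose
#' entry would make the design rank-deficient (exact collinearity) are
#' blocked.
#'
#' @param x Data frame of candidate predictors.
#' @param y Numeric response.
#' @param alpha_enter Entry significance level (default 0.05).
#' @param alpha_remove Removal significance level (default 0.10).
#' @return Object of class `stepwise_fit`: list with `selected`,
#'   `intercept`, `coefficients` (named, zero for excluded candidates),
#'   `F_value`, `p_value`, `sigma`, `r_squared`, `fitted`, `residuals`.
#' @export
stepwise_fit <- function(x, y, alpha_enter = 0.05, alpha_remove = 0.10) {
  x <- as.data.frame(x)
  stopifnot(ncol(x) >= 2, nrow(x) == length(y))
  if (nrow(x) <= ncol(x) + 2) {
    stop("need more rows than candidates + 2")
  }
  n <- nrow(x)
  selected <- character(0)
  rss_of <- function(vars) {
    if (!length(vars)) return(sum((y - mean(y))^2))
    fit <- stats::lm.fit(cbind(1, as.matrix(x[, vars, drop = FALSE])), y)
    sum(fit$residuals^2)
  }
  rank_of <- function(vars) {
    qr(cbind(1, as.matrix(x[, vars, drop = FALSE])))$rank
  }
  repeat {
    changed <- FALSE
    # forward step
    rss0 <- rss_of(selected)
    cands <- setdiff(colnames(x), selected)
    best_p <- Inf; best_c <- NULL
    for (cand in cands) {
      vars <- c(selected, cand)
      if (rank_of(vars) < length(vars) + 1L) next  # collinear, blocked
      rss1 <- rss_of(vars)
      df2 <- n - length(vars) - 1L
      if (df2 < 1 || rss1 <= 0) next
      Fp <- (rss0 - rss1) / (rss1 / df2)
      pv <- stats::pf(Fp, 1, df2, lower.tail = FALSE)
      if (pv < best_p) { best_p <- pv; best_c <- cand }
    }
    if (!is.null(best_c) && best_p <= alpha_enter) {
      selected <- c(selected, best_c)
      changed <- TRUE
    }
    # backward step(s)
    repeat {
      if (length(selected) < 1) break
      rss_full <- rss_of(selected)
      df2 <- n - length(selected) - 1L
      worst_p <- -Inf; worst_v <- NULL
      for (v in selected) {
        rss_red <- rss_of(setdiff(selected, v))
        Fp <- (rss_red - rss_full) / (rss_full / df2)
        pv <- stats::pf(Fp, 1, df2, lower.tail = FALSE)
        if (pv > worst_p) { worst_p <- pv; worst_v <- v }
      }
      if (worst_p > alpha_remove) {
        selected <- setdiff(selected, worst_v)
        changed <- TRUE
      } else break
    }
    if (!changed) break
  }
  coefs <- stats::setNames(rep(0, ncol(x)), colnames(x))
  if (length(selected)) {
    fit <- stats::lm(y ~ ., data = cbind(data.frame(y = y),
                                         x[, selected, drop = FALSE]))
    sm <- summary(fit)
    coefs[selected] <- stats::coef(fit)[-1]
    F_value <- unname(sm$fstatistic[1])
    p_value <- stats::pf(sm$fstatistic[1], sm$fstatistic[2],
                         sm$fstatistic[3], lower.tail = FALSE)
    intercept <- unname(stats::coef(fit)[1])
    fitted <- stats::fitted(fit)
    resid <- stats::residuals(fit)
    r2 <- sm$r.squared
    sigma <- sm$sigma
  } else {
    warning("no variable met the entry criterion; intercept-only model")
    intercept <- mean(y)
    F_value <- 0; p_value <- 1
    fitted <- rep(intercept, n)
    resid <- y - intercept
    r2 <- 0; sigma <- stats::sd(y)
  }
  structure(list(selected = selected, intercept = intercept,
                 coefficients = coefs, F_value = F_value, p_value = p_value,
                 sigma = sigma, r_squared = r2, fitted = fitted,
                 residuals = resid),
            class = "stepwise_fit")
}

#' @export
print.stepwise_fit <- function(x, ...) {
  cat("<stepwise_fit> ", if (length(x$selected))
    paste(x$selected, collapse = " + ") else "(intercept only)",
    sprintf("\n  F = %.4f, p = %.4g, R^2 = %.3f\n",
            x$F_value, x$p_value, x$r_squared), sep = "")
  invisible(x)
}

#' Paired between-state comparisons
#'
#' Two-sided paired t-tests of every feature between a baseline state and
#' each other state, matching recordings by subject and excluding subjects
#' missing either member of a pair. Significance tiers at 0.05 and 0.01.
#'
#' @param table Data frame with `subject_id`, `state` and feature columns.
#' @param baseline Reference state label (default `"BSL"`).
#' @param features Feature columns to compare (default: all numeric
#'   columns except `subject_id`).
#' @return Data frame with `feature`, `state`, `n_pairs`, `mean_diff`
#'   (state minus baseline), `t`, `p_value`, `tier`.
#' @export
paired_tests <- function(table, baseline = "BSL", features = NULL) {
  stopifnot(all(c("subject_id", "state") %in% names(table)))
  if (is.null(features)) {
    features <- setdiff(names(table)[vapply(table, is.numeric, logical(1))],
                        c("subject_id"))
  }
  states <- setdiff(unique(table$state), baseline)
  base <- table[table$state == baseline, ]
  out <- list()
  for (st in states) {
    other <- table[table$state == st, ]
    common <- intersect(base$subject_id, other$subject_id)
    if (length(common) < 3) {
      warning("fewer than 3 pairs for ", st, "; comparison skipped")
      next
    }
    b <- base[match(common, base$subject_id), ]
    o <- other[match(common, other$subject_id), ]
    for (f in features) {
      d <- o[[f]] - b[[f]]
      if (stats::sd(d) <= 1e-10 * max(1, abs(mean(d)))) {
        tt <- list(statistic = if (mean(d) == 0) 0 else Inf * sign(mean(d)),
                   p.value = if (mean(d) == 0) 1 else 0)
      } else {
        ht <- stats::t.test(o[[f]], b[[f]], paired = TRUE)
        tt <- list(statistic = unname(ht$statistic), p.value = ht$p.value)
      }
      out[[length(out) + 1L]] <- data.frame(
        feature = f, state = st, n_pairs = length(common),
        mean_diff = mean(d), t = tt$statistic, p_value = tt$p.value,
        tier = if (tt$p.value < 0.01) "p<0.01" else
          if (tt$p.value < 0.05) "p<0.05" else "ns")
    }
  }
  do.call(rbind, out)
}
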