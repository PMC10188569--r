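#' Percent contribution of each variable
#'
#' Credits each accepted solver update's increase in regularized gain to
#' the updated feature's source variable (product features split 50/50
#' between their two variables), floors negative per-variable totals at
#' zero, and normalizes to sum 100. Path-dependent by construction: the
#' numbers are reproducible conditional on the coordinate-descent update
#' path. See [permutation_importance()] for a path-independent cross-check.
#'
#' @param model a [maxent()] fit with a gain trace.
#' @return named numeric vector over variables, summing to 100 (all zeros
#'   with attribute `uniform = TRUE` for a coefficient-free model).
#' @export
percent_contribution <- function(model) {
  vars <- model$defs$variables
  out <- stats::setNames(numeric(length(vars)), vars)
  tr <- model$trace
  if (is.null(tr) || !nrow(tr)) {
    attr(out, "uniform") <- TRUE
    return(out)
  }
  deltas <- diff(c(0, tr$gain))
  ft <- model$defs$features
  idx <- match(tr$feature, ft$id)
  for (i in seq_along(deltas)) {
    j <- idx[i]
    if (ft$class[j] == "P") {
      out[ft$var1[j]] <- out[ft$var1[j]] + deltas[i] / 2
      out[ft$var2[j]] <- out[ft$var2[j]] + deltas[i] / 2
    } else out[ft$var1[j]] <- out[ft$var1[j]] + deltas[i]
  }
  out[out < 0] <- 0
  if (sum(out) <= 0) {
    attr(out, "uniform") <- TRUE
    return(out)
  }
  100 * out / sum(out)
}

#' Permutation importance of each variable
#'
#' For each variable, its column is shuffled jointly across presence and
#' background samples, training AUC is recomputed, and the importance is
#' the AUC drop (floored at zero), normalized to sum 100.
#'
#' @param model a [maxent()] fit retaining its samples.
#' @param seed integer seed for the shuffles.
#' @return named numeric vector summing to 100.
#' @export
permutation_importance <- function(model, seed = 1) {
  presence <- model$presence; background <- model$background
  if (is.null(presence)) stop("model does not retain its samples")
  set.seed(seed)
  auc0 <- auc_rank(predict(model, presence), predict(model, background))
  m <- nrow(presence)
  pooled <- rbind(presence, background)
  drops <- vapply(model$defs$variables, function(v) {
    perm <- pooled
    perm[[v]] <- sample(perm[[v]])
    s <- predict(model, perm)
    max(0, auc0 - auc_rank(s[seq_len(m)], s[-seq_len(m)]))
  }, numeric(1))
  if (sum(drops) <= 0) return(stats::setNames(numeric(length(drops)), names(drops)))
  100 * drops / sum(drops)
}

#' Jackknife variable importance by model gain
#'
#' For each variable fits a with-only-that-variable model and a
#' without-that-variable model, recording the regularized training gain of
#' each alongside the all-variables gain. When test presences are
#' supplied, the unregularized test gain
#' `ln N - (-(1/m) sum ln q(x_test))` is recorded as well.
#'
#' @param presence,background sample data frames (>= 2 variables).
#' @param test optional test presence sample data frame.
#' @param ... passed to [maxent()].
#' @return list with `table` (per-variable gains) and `full_gain`
#'   (all-variable model gain), plus `full_test_gain` when `test` given.
#' @export
jackknife_gains <- function(presence, background, test = NULL, ...) {
  vars <- names(presence)
  if (length(vars) < 2) stop("jackknife needs at least 2 variables")
  test_gain <- function(fit, test_df) {
    eta <- predict(fit, test_df, type = "link")
    log(fit$N) + mean(eta) - fit$logZ
  }
  full <- maxent(presence, background = background, ...)
  rows <- lapply(vars, function(v) {
    only <- maxent(presence[, v, drop = FALSE],
                   background = background[, v, drop = FALSE], ...)
    rest <- setdiff(vars, v)
    without <- maxent(presence[, rest, drop = FALSE],
                      background = background[, rest, drop = FALSE], ...)
    out <- data.frame(variable = v, gain_with_only = only$gain,
                      gain_without = without$gain, stringsAsFactors = FALSE)
    if (!is.null(test)) {
      out$test_gain_with_only <- test_gain(only, test[, v, drop = FALSE])
      out$test_gain_without <- test_gain(without, test[, rest, drop = FALSE])
    }
    out
  })
  out <- list(table = do.call(rbind, rows), full_gain = full$gain)
  if (!is.null(test)) out$full_test_gain <- test_gain(full, test)
  out
}

#' Response curve of one variable
#'
#' Marginal mode sweeps the variable across its training `[min, max]` with
#' every other variable held at its presence-sample mean; univariate mode
#' fits a fresh single-variable model and sweeps it. Output is the cloglog
#' suitability at `n_points` evenly spaced values.
#'
#' @param model a [maxent()] fit retaining its samples.
#' @param variable variable name.
#' @param n_points number of sweep points.
#' @param mode `"marginal"` or `"univariate"`.
#' @return data frame with columns `value` and `cloglog`.
#' @export
response_curve <- function(model, variable, n_points = 100,
                           mode = c("marginal", "univariate")) {
  mode <- match.arg(mode)
  if (!variable %in% model$defs$variables)
    stop(sprintf("unknown variable '%s'", variable))
  lo <- model$defs$min[[variable]]; hi <- model$defs$max[[variable]]
  sweep <- seq(lo, hi, length.out = n_points)
  if (mode == "marginal") {
    if (is.null(model$presence)) stop("model does not retain its samples")
    means <- colMeans(model$presence[model$defs$variables])
    nd <- as.data.frame(lapply(means, rep, n_points))
    nd[[variable]] <- sweep
    data.frame(value = sweep, cloglog = predict(model, nd))
  } else {
    uni <- maxent(model$presence[, variable, drop = FALSE],
                  background = model$background[, variable, drop = FALSE],
                  classes = model$defs$classes, rm = model$rm,
                  n_knots = model$defs$n_knots)
    data.frame(value = sweep,
               cloglog = predict(uni, stats::setNames(data.frame(sweep), variable)))
  }
}
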