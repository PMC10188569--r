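#' Random k-fold partition
#'
#' Splits `n` records into `k` folds whose sizes differ by at most one,
#' by random permutation. Deterministic under `seed`.
#'
#' @param n number of records.
#' @param k number of folds (>= 2).
#' @param seed integer seed.
#' @return integer vector of fold labels in `1..k`.
#' @export
kfold_partition <- function(n, k = 10, seed = 1) {
  if (k < 2) stop("k must be >= 2")
  if (n < k) stop(sprintf("cannot split %d records into %d folds", n, k))
  set.seed(seed)
  labels <- rep(seq_len(k), length.out = n)
  labels[sample.int(n)]
}

#' AICc of a fitted model over a landscape
#'
#' The raw Gibbs density is renormalized over every valid landscape cell;
#' the log-likelihood is the sum of log landscape probabilities at the `n`
#' presences; `K` counts nonzero coefficients. Returns
#' `2K - 2 lnL + 2K(K+1)/(n-K-1)`, or `NA` when `K >= n - 1` (the
#' small-sample correction is undefined).
#'
#' @param model a [maxent()] fit trained on all occurrences.
#' @param presence presence sample data frame (the `n` occurrences).
#' @param landscape sample data frame of every valid cell of the study
#'   stack (e.g. from [stack_samples()]).
#' @return AICc value, or `NA` when undefined.
#' @export
aicc <- function(model, presence, landscape) {
  eta_land <- predict(model, landscape, type = "link")
  eta_pres <- predict(model, presence, type = "link")
  mx <- max(eta_land)
  logZ_land <- mx + log(sum(exp(eta_land - mx)))
  lnL <- sum(eta_pres - logZ_land)
  K <- sum(abs(model$lambda) > 1e-12)
  n <- nrow(presence)
  if (K >= n - 1) return(NA_real_)
  2 * K - 2 * lnL + 2 * K * (K + 1) / (n - K - 1)
}

#' All jointly valid cells of a stack as a sample data frame
#'
#' @param stack a [raster_stack()].
#' @return data frame, one row per valid cell, one column per layer.
#' @export
stack_samples <- function(stack) {
  vals <- stack_cell_values(stack)
  attr(vals, "provenance") <- "background"
  vals
}

#' Cross-validated metrics for one feature-class / RM candidate
#'
#' For each fold: train on the remaining folds' presences (same
#' background), then record the validation AUC (held-out presences vs
#' background scores), the training-minus-validation AUC difference, and
#' the 10-percentile omission rate: the fraction of validation presences
#' scoring below the `ceiling(0.1 * m_train)`-th lowest training presence
#' score.
#'
#' @param presence,background sample data frames.
#' @param folds fold labels from [kfold_partition()].
#' @param classes feature classes of the candidate.
#' @param rm regularization multiplier of the candidate.
#' @param ... passed to [maxent()].
#' @return list with `auc_val_avg`, `auc_diff_avg`, `or10p_avg`.
#' @export
evaluate_candidate <- function(presence, background, folds,
                               classes, rm, ...) {
  k <- max(folds)
  auc_val <- auc_diff <- or10 <- numeric(k)
  for (i in seq_len(k)) {
    tr <- presence[folds != i, , drop = FALSE]
    va <- presence[folds == i, , drop = FALSE]
    if (!nrow(va)) stop(sprintf("fold %d has no validation presences", i))
    fit <- maxent(tr, background = background, classes = classes, rm = rm, ...)
    s_tr <- predict(fit, tr)
    s_va <- predict(fit, va)
    s_bg <- predict(fit, background)
    a_tr <- auc_rank(s_tr, s_bg)
    a_va <- auc_rank(s_va, s_bg)
    auc_val[i] <- a_va
    auc_diff[i] <- a_tr - a_va
    thr <- sort(s_tr)[ceiling(0.1 * length(s_tr))]
    or10[i] <- mean(s_va < thr)
  }
  list(auc_val_avg = mean(auc_val), auc_diff_avg = mean(auc_diff),
       or10p_avg = mean(or10))
}

#' Enumerate the candidate grid
#'
#' All nonempty subsets of the feature-class universe crossed with the
#' regularization multipliers: the default universe \{L,Q,P,T,H\} with
#' RM 0.5 to 5 in steps of 0.5 gives 31 x 10 = 310 candidates.
#'
#' @param fc_universe character vector of feature classes.
#' @param rms numeric vector of regularization multipliers.
#' @return data frame with columns `fc` (compact string) and `rm`.
#' @export
candidate_grid <- function(fc_universe = c("L", "Q", "P", "T", "H"),
                           rms = seq(0.5, 5, by = 0.5)) {
  combos <- unlist(lapply(seq_along(fc_universe), function(sz)
    utils::combn(fc_universe, sz, paste, collapse = "", simplify = FALSE)))
  out <- expand.grid(rm = rms, fc = combos, stringsAsFactors = FALSE,
                     KEEP.OUT.ATTRS = FALSE)[, c("fc", "rm")]
  rownames(out) <- NULL
  out
}

#' Tune feature classes and regularization by cross-validation and AICc
#'
#' Evaluates every candidate in the grid: k-fold cross-validation metrics
#' plus AICc of the full-data fit normalized over the landscape. The
#' selected candidate is the one with `delta_AICc = 0`; ties are broken by
#' parsimony (fewer nonzero coefficients), then smaller RM, then
#' lexicographic feature-class string.
#'
#' @param x a [raster_stack()], or a presence sample data frame (then give
#'   `background` and `landscape`).
#' @param p occurrences when `x` is a stack.
#' @param background,landscape sample data frames for the data-frame
#'   interface.
#' @param grid candidate table from [candidate_grid()].
#' @param k cross-validation folds.
#' @param seed seed for folds and the background draw.
#' @param n_knots,n_background,max_iter,tol passed to [maxent()].
#' @return object of class `maxent_tune`: `results` (one row per
#'   candidate, with `delta_AICc`), `selected` (row index), `model` (the
#'   selected full-data fit).
#' @export
tune_grid <- function(x, p = NULL, background = NULL, landscape = NULL,
                      grid = candidate_grid(), k = 10, seed = 1,
                      n_knots = 50, n_background = 10000,
                      max_iter = 5000, tol = 1e-4) {
  if (inherits(x, "raster_stack")) {
    presence <- extract_samples(x, p)
    background <- sample_background(x, n_background, seed = seed)
    landscape <- stack_samples(x)
  } else {
    presence <- x
    if (is.null(background) || is.null(landscape))
      stop("data-frame interface needs 'background' and 'landscape'")
  }
  folds <- kfold_partition(nrow(presence), k = k, seed = seed)
  res <- grid
  res$auc_val_avg <- res$auc_diff_avg <- res$or10p_avg <- NA_real_
  res$AICc <- NA_real_; res$K <- NA_integer_
  fits <- vector("list", nrow(grid))
  for (i in seq_len(nrow(grid))) {
    cv <- evaluate_candidate(presence, background, folds,
                             classes = grid$fc[i], rm = grid$rm[i],
                             n_knots = n_knots, max_iter = max_iter, tol = tol)
    res$auc_val_avg[i] <- cv$auc_val_avg
    res$auc_diff_avg[i] <- cv$auc_diff_avg
    res$or10p_avg[i] <- cv$or10p_avg
    full <- maxent(presence, background = background, classes = grid$fc[i],
                   rm = grid$rm[i], n_knots = n_knots,
                   max_iter = max_iter, tol = tol)
    res$AICc[i] <- aicc(full, presence, landscape)
    res$K[i] <- sum(abs(full$lambda) > 1e-12)
    fits[[i]] <- full
  }
  defined <- is.finite(res$AICc)
  if (!any(defined))
    stop("AICc undefined for every candidate; more occurrences are needed")
  res$delta_AICc <- res$AICc - min(res$AICc[defined])
  zero <- which(defined & res$delta_AICc < 1e-9)
  sel <- zero[order(res$K[zero], res$rm[zero], res$fc[zero])][1]
  structure(list(results = res, selected = sel, model = fits[[sel]],
                 folds = folds, seed = seed),
            class = "maxent_tune")
}

#' @export
print.maxent_tune <- function(x, ...) {
  s <- x$results[x$selected, ]
  cat(sprintf("maxent tuning over %d candidates\n", nrow(x$results)))
  cat(sprintf("  selected: FC = %s, RM = %g (delta AICc = 0)\n", s$fc, s$rm))
  cat(sprintf("  AICc = %.3f, K = %d, AUC.val.avg = %.3f, AUC.diff.avg = %.3f, or10p.avg = %.3f\n",
              s$AICc, s$K, s$auc_val_avg, s$auc_diff_avg, s$or10p_avg))
  invisible(x)
}
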