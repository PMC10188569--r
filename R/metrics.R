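#' Rank (Mann-Whitney) AUC for presence vs background scores
#'
#' `AUC = [#(p > b) + 0.5 #(p = b)] / (m N)` over all presence-background
#' pairs, computed via midranks. Invariant under strictly monotone score
#' transforms.
#'
#' @param presence_scores,background_scores numeric score vectors.
#' @return AUC in `[0, 1]`.
#' @export
auc_rank <- function(presence_scores, background_scores) {
  if (!length(presence_scores) || !length(background_scores))
    stop("both score vectors must be nonempty")
  m <- length(presence_scores); n <- length(background_scores)
  r <- rank(c(presence_scores, background_scores), ties.method = "average")
  (sum(r[seq_len(m)]) - m * (m + 1) / 2) / (m * n)
}

#' Maximum sensitivity-plus-specificity threshold
#'
#' Candidate thresholds are the unique observed scores. At threshold `t`,
#' sensitivity is the fraction of presences scoring `>= t` and specificity
#' the fraction of background scoring `< t` (background acting as the
#' pseudo-absence class). Returns the smallest candidate maximizing their
#' sum.
#'
#' @inheritParams auc_rank
#' @return the maxSSS threshold.
#' @export
maxsss_threshold <- function(presence_scores, background_scores) {
  if (!length(presence_scores) || !length(background_scores))
    stop("both score vectors must be nonempty")
  cand <- sort(unique(c(presence_scores, background_scores)))
  ss <- vapply(cand, function(t)
    mean(presence_scores >= t) + mean(background_scores < t), numeric(1))
  cand[which(ss >= max(ss) - 1e-12)[1]]
}

#' True skill statistic at a threshold
#'
#' `TSS = sensitivity + specificity - 1` with background as the
#' pseudo-absence class; presences scoring exactly at the threshold count
#' as predicted positive.
#'
#' @inheritParams auc_rank
#' @param t threshold on the score scale.
#' @export
tss_at_threshold <- function(presence_scores, background_scores, t) {
  mean(presence_scores >= t) + mean(background_scores < t) - 1
}

#' Continuous Boyce index
#'
#' Moving-window calibration statistic: windows of width
#' `window_width_fraction` of the landscape score range slide across
#' `[min, max]`; in each, `P` is the share of presences and `E` the share
#' of landscape cells. The CBI is the Spearman rank correlation between
#' `P/E` and the window centre over windows with `E > 0`. Degenerate cases
#' (constant scores, fewer than 3 usable windows, constant `P/E`) return 0
#' with attribute `degenerate = TRUE`.
#'
#' @param presence_scores scores at presences (need at least 5).
#' @param landscape_scores scores over all valid cells (or a large
#'   background sample).
#' @param n_windows number of window centres.
#' @param window_width_fraction window width as a fraction of score range.
#' @return CBI in `[-1, 1]`.
#' @export
continuous_boyce_index <- function(presence_scores, landscape_scores,
                                   n_windows = 101, window_width_fraction = 0.1) {
  if (length(presence_scores) < 5) stop("need at least 5 presence scores")
  degenerate <- function() structure(0, degenerate = TRUE)
  rng <- range(landscape_scores)
  if (rng[2] - rng[1] < 1e-12) return(degenerate())
  W <- window_width_fraction * (rng[2] - rng[1])
  centers <- seq(rng[1] + W / 2, rng[2] - W / 2, length.out = n_windows)
  P <- E <- numeric(n_windows)
  for (i in seq_len(n_windows)) {
    lo <- centers[i] - W / 2; hi <- centers[i] + W / 2
    P[i] <- mean(presence_scores >= lo & presence_scores <= hi)
    E[i] <- mean(landscape_scores >= lo & landscape_scores <= hi)
  }
  use <- E > 0
  if (sum(use) < 3) return(degenerate())
  ratio <- P[use] / E[use]
  if (max(ratio) - min(ratio) < 1e-12) return(degenerate())
  stats::cor(ratio, centers[use], method = "spearman")
}

#' Single random-split model evaluation
#'
#' Splits occurrences into training and test sets (test size
#' `ceiling((1 - train_fraction) * n)`), fits the model on the training
#' presences, and reports AUC, TSS (threshold from the training maxSSS)
#' and CBI on both sides. Background scores act as pseudo-absences; CBI
#' uses the `landscape` scores as the reference distribution.
#'
#' @param presence,background sample data frames.
#' @param landscape sample data frame of all valid cells (defaults to the
#'   background).
#' @param train_fraction fraction of occurrences used for training.
#' @param seed integer seed for the split.
#' @param ... passed to [maxent()].
#' @return list of class `evaluation_report`.
#' @export
split_evaluate <- function(presence, background, landscape = background,
                           train_fraction = 0.75, seed = 1, ...) {
  n <- nrow(presence)
  if (n < 4) stop("need at least 4 occurrences to split")
  n_test <- ceiling((1 - train_fraction) * n)
  set.seed(seed)
  test_idx <- sample.int(n, n_test)
  train <- presence[-test_idx, , drop = FALSE]
  test <- presence[test_idx, , drop = FALSE]
  fit <- maxent(train, background = background, ...)
  s_tr <- predict(fit, train); s_te <- predict(fit, test)
  s_bg <- predict(fit, background); s_land <- predict(fit, landscape)
  t <- maxsss_threshold(s_tr, s_bg)
  structure(list(model = fit, threshold = t,
                 n_train = nrow(train), n_test = nrow(test),
                 auc_train = auc_rank(s_tr, s_bg),
                 auc_test = auc_rank(s_te, s_bg),
                 tss_train = tss_at_threshold(s_tr, s_bg, t),
                 tss_test = tss_at_threshold(s_te, s_bg, t),
                 cbi_train = as.numeric(continuous_boyce_index(s_tr, s_land)),
                 cbi_test = as.numeric(continuous_boyce_index(s_te, s_land))),
            class = "evaluation_report")
}

#' @export
print.evaluation_report <- function(x, ...) {
  cat(sprintf("random-split evaluation (%d train / %d test), threshold = %.4f\n",
              x$n_train, x$n_test, x$threshold))
  cat(sprintf("  AUC  train %.3f  test %.3f\n", x$auc_train, x$auc_test))
  cat(sprintf("  TSS  train %.3f  test %.3f\n", x$tss_train, x$tss_test))
  cat(sprintf("  CBI  train %.3f  test %.3f\n", x$cbi_train, x$cbi_test))
  invisible(x)
}
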