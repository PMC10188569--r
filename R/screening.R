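#' Pairwise Pearson correlation among stack layers
#'
#' Computed over the jointly valid cells (complete cases across the whole
#' stack). A constant layer yields undefined correlations; these are
#' recorded as 0 with a warning.
#'
#' @param stack a [raster_stack()] with at least two jointly valid cells.
#' @return symmetric correlation matrix with unit diagonal, class
#'   `correlation_matrix`.
#' @export
correlation_matrix <- function(stack) {
  vals <- stack_cell_values(stack)
  if (nrow(vals) < 2) stop("need at least 2 jointly valid cells")
  m <- as.matrix(vals)
  sds <- apply(m, 2, stats::sd)
  degenerate <- sds < 1e-12
  if (any(degenerate))
    warning(sprintf("constant layer(s) with undefined correlation recorded as 0: %s",
                    paste(colnames(m)[degenerate], collapse = ", ")))
  r <- suppressWarnings(stats::cor(m))
  r[!is.finite(r)] <- 0
  diag(r) <- 1
  class(r) <- c("correlation_matrix", class(r))
  r
}

#' Greedy multicollinearity pruning
#'
#' Scans the variables in priority order, keeping a variable only when its
#' absolute correlation with every already-kept variable is below the
#' threshold. The threshold is inclusive: a pair with `|r|` exactly at the
#' threshold is treated as collinear. The retained set therefore has all
#' pairwise `|r| <` threshold, and the output preserves priority order.
#'
#' @param corr a [correlation_matrix()].
#' @param priority character vector: permutation of the variables, highest
#'   priority first (e.g. descending univariate model gain, see
#'   [univariate_gains()]).
#' @param threshold absolute-correlation cutoff (default 0.8).
#' @return character vector of retained variable names.
#' @export
greedy_select <- function(corr, priority = colnames(corr), threshold = 0.8) {
  vars <- colnames(corr)
  if (!setequal(priority, vars))
    stop("priority must be a permutation of the correlation matrix variables")
  kept <- character(0)
  for (v in priority) {
    if (!length(kept) || all(abs(corr[v, kept]) < threshold))
      kept <- c(kept, v)
  }
  kept
}

#' Univariate model gain per variable
#'
#' Fits a single-variable maxent model for each variable and returns its
#' regularized training gain. Used as the default screening priority:
#' variables explaining more of the presence signal on their own are kept
#' in preference to their collinear partners.
#'
#' @param presence,background sample data frames (points x variables).
#' @param classes feature classes for the univariate fits (default `"LQ"`,
#'   cheap and smooth).
#' @param rm regularization multiplier.
#' @param ... passed to the fitting routine.
#' @return named numeric vector of gains, same order as the columns.
#' @export
univariate_gains <- function(presence, background, classes = "LQ", rm = 1, ...) {
  vars <- names(presence)
  gains <- vapply(vars, function(v) {
    fit <- maxent(presence[, v, drop = FALSE], background = background[, v, drop = FALSE],
                  classes = classes, rm = rm, ...)
    fit$gain
  }, numeric(1))
  gains
}
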