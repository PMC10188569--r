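#' Fit feature definitions for a maxent design
#'
#' Derives, from pooled presence and background samples, everything needed
#' to expand raw predictors into bounded `[0, 1]` model features and to
#' apply the identical transform at projection time: per-variable min/max
#' scaling bounds, and per-variable knots for threshold and hinge features
#' placed at evenly spaced interior quantiles of the pooled values.
#'
#' Feature classes:
#' \describe{
#'   \item{L}{linear, `x' = (x - min)/(max - min)`}
#'   \item{Q}{quadratic, `x'^2`}
#'   \item{P}{product, `x'_i x'_j` for all unordered pairs}
#'   \item{T}{threshold, `1(x > k)` at each knot}
#'   \item{H}{hinge, forward `max(0, (x - k)/(max - k))` and reverse
#'     `max(0, (k - x)/(k - min))` at each knot}
#' }
#'
#' @param presence,background sample data frames over the same variables.
#' @param classes feature classes, e.g. `c("L","Q","H")` or a compact
#'   string `"LQH"`.
#' @param n_knots knots per variable for threshold and for each hinge
#'   direction.
#' @return an object of class `feature_defs`.
#' @export
fit_feature_defs <- function(presence, background, classes = c("L", "Q", "H"),
                             n_knots = 50) {
  classes <- parse_classes(classes)
  if (!length(classes)) stop("at least one feature class is required")
  vars <- names(presence)
  if (!identical(sort(vars), sort(names(background))))
    stop("presence and background must share the same variable set")
  pooled <- rbind(presence[vars], background[vars])
  lo <- vapply(pooled, min, numeric(1))
  hi <- vapply(pooled, max, numeric(1))
  usable <- hi - lo > 1e-12
  if (any(!usable)) {
    warning(sprintf("excluding constant variable(s): %s",
                    paste(vars[!usable], collapse = ", ")))
    vars <- vars[usable]; lo <- lo[usable]; hi <- hi[usable]
  }
  if (!length(vars)) stop("no usable (non-constant) variables")

  knots <- NULL
  if (any(c("T", "H") %in% classes)) {
    probs <- seq_len(n_knots) / (n_knots + 1)
    knots <- lapply(vars, function(v) unname(stats::quantile(pooled[[v]], probs)))
    names(knots) <- vars
  }

  feats <- list()
  add <- function(id, class, var1, var2 = NA_character_, knot = NA_real_)
    feats[[length(feats) + 1L]] <<- data.frame(id = id, class = class,
                                               var1 = var1, var2 = var2,
                                               knot = knot, stringsAsFactors = FALSE)
  if ("L" %in% classes) for (v in vars) add(paste0("L_", v), "L", v)
  if ("Q" %in% classes) for (v in vars) add(paste0("Q_", v), "Q", v)
  if ("P" %in% classes && length(vars) >= 2) {
    cmb <- utils::combn(vars, 2)
    for (i in seq_len(ncol(cmb)))
      add(paste0("P_", cmb[1, i], "_", cmb[2, i]), "P", cmb[1, i], cmb[2, i])
  }
  if ("T" %in% classes) for (v in vars) for (k in seq_len(n_knots))
    add(sprintf("T_%s_%02d", v, k), "T", v, knot = knots[[v]][k])
  if ("H" %in% classes) for (v in vars) {
    for (k in seq_len(n_knots))
      add(sprintf("Hf_%s_%02d", v, k), "Hf", v, knot = knots[[v]][k])
    for (k in seq_len(n_knots))
      add(sprintf("Hr_%s_%02d", v, k), "Hr", v, knot = knots[[v]][k])
  }
  features <- do.call(rbind, feats)
  structure(list(variables = vars, min = lo, max = hi, classes = classes,
                 n_knots = n_knots, knots = knots, features = features),
            class = "feature_defs")
}

parse_classes <- function(classes) {
  if (length(classes) == 1L && nchar(classes) > 1L)
    classes <- strsplit(classes, "")[[1]]
  classes <- toupper(classes)
  bad <- setdiff(classes, c("L", "Q", "P", "T", "H"))
  if (length(bad)) stop(sprintf("unknown feature class: %s", paste(bad, collapse = ", ")))
  unique(classes)
}

#' @export
print.feature_defs <- function(x, ...) {
  cat(sprintf("feature_defs: %d variables, classes {%s}, %d features\n",
              length(x$variables), paste(x$classes, collapse = ","),
              nrow(x$features)))
  invisible(x)
}

#' Expand raw samples into the model's feature matrix
#'
#' Applies the transforms frozen in `defs`. Inputs outside the stored
#' `[min, max]` bounds are clamped to the bounds first (the behaviour
#' needed when projecting onto novel climates), so every feature value lies
#' in `[0, 1]`.
#'
#' @param samples data frame containing all of `defs$variables`.
#' @param defs a [fit_feature_defs()] object.
#' @param clamp clamp inputs to the training bounds (default `TRUE`).
#' @return numeric matrix, rows = points, columns = features in the order
#'   of `defs$features`.
#' @export
transform_features <- function(samples, defs, clamp = TRUE) {
  missing <- setdiff(defs$variables, names(samples))
  if (length(missing))
    stop(sprintf("samples lack variable(s): %s", paste(missing, collapse = ", ")))
  n <- nrow(samples)
  scaled <- list()
  raw <- list()
  for (v in defs$variables) {
    x <- samples[[v]]
    if (clamp) x <- pmin(pmax(x, defs$min[[v]]), defs$max[[v]])
    raw[[v]] <- x
    scaled[[v]] <- (x - defs$min[[v]]) / (defs$max[[v]] - defs$min[[v]])
  }
  ft <- defs$features
  out <- matrix(0, n, nrow(ft), dimnames = list(NULL, ft$id))
  for (j in seq_len(nrow(ft))) {
    cls <- ft$class[j]; v <- ft$var1[j]
    out[, j] <- switch(cls,
      L = scaled[[v]],
      Q = scaled[[v]]^2,
      P = scaled[[v]] * scaled[[ft$var2[j]]],
      T = as.numeric(raw[[v]] > ft$knot[j]),
      Hf = {
        den <- defs$max[[v]] - ft$knot[j]
        if (den <= 1e-12) rep(0, n) else pmax(0, (raw[[v]] - ft$knot[j]) / den)
      },
      Hr = {
        den <- ft$knot[j] - defs$min[[v]]
        if (den <= 1e-12) rep(0, n) else pmax(0, (ft$knot[j] - raw[[v]]) / den)
      },
      stop(sprintf("unknown feature class '%s'", cls)))
  }
  out
}

# map each feature to its source variable(s); products split between both
feature_sources <- function(defs) {
  ft <- defs$features
  lapply(seq_len(nrow(ft)), function(j) {
    if (ft$class[j] == "P") c(ft$var1[j], ft$var2[j]) else ft$var1[j]
  })
}
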