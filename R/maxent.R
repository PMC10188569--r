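#' Per-feature L1 regularization weights
#'
#' Computes the penalty vector `beta_j = RM * beta_class(m) * s_j / sqrt(m)`
#' where `m` is the presence count, `s_j` the standard deviation of feature
#' `j` over the presences (floored at `(max - min)/sqrt(m)` of the feature's
#' observed presence spread, with a positive fallback for features constant
#' over presences), and `beta_class(m)` the class- and sample-size-dependent
#' base weight: linear/quadratic/product interpolate (0, 1.0), (10, 1.0),
#' (30, 0.2), (100, 0.05); threshold interpolates (10, 2.0), (100, 1.0);
#' hinge is constant 0.5. Values are clamped outside the tabulated range.
#'
#' @param defs a [fit_feature_defs()] object.
#' @param presence_features feature matrix of the presences.
#' @param rm regularization multiplier (global scalar).
#' @return positive numeric vector, one weight per feature.
#' @export
regularization_vector <- function(defs, presence_features, rm = 1) {
  m <- nrow(presence_features)
  if (is.null(m) || m < 2) stop("need at least 2 presences to estimate feature spread")
  ft <- defs$features
  base <- vapply(ft$class, function(cl) beta_class(cl, m), numeric(1))
  sd_j <- apply(presence_features, 2, stats::sd)
  rng_j <- apply(presence_features, 2, function(x) diff(range(x)))
  floor_j <- rng_j / sqrt(m)
  floor_j[floor_j <= 0] <- 1 / sqrt(m)  # features live in [0,1]; full-scale fallback
  spread <- pmax(sd_j, floor_j)
  beta <- rm * base * spread / sqrt(m)
  stats::setNames(beta, ft$id)
}

beta_class <- function(class, m) {
  interp <- function(ms, bs) {
    if (m <= ms[1]) return(bs[1])
    if (m >= ms[length(ms)]) return(bs[length(bs)])
    stats::approx(ms, bs, xout = m)$y
  }
  switch(class,
         L = , Q = , P = interp(c(0, 10, 30, 100), c(1, 1, 0.2, 0.05)),
         T = interp(c(10, 100), c(2, 1)),
         Hf = , Hr = , H = 0.5,
         stop(sprintf("unknown feature class '%s'", class)))
}

#' Fit the penalized maximum-entropy model on feature matrices
#'
#' Minimizes
#' `f(lambda) = -(1/m) sum_i lambda . f(x_i) + log Z(lambda) + sum_j beta_j |lambda_j|`
#' over the coefficient vector, where `Z` sums `exp(lambda . f(x))` over the
#' background rows, by cyclic coordinate descent with soft-thresholding
#' (each accepted update is checked to decrease the true objective, so the
#' regularized gain trace is nondecreasing). Iteration stops when a full
#' sweep improves the objective by less than `tol`.
#'
#' @param presence_features,background_features numeric feature matrices
#'   sharing columns. `background_features` is the normalization set (when
#'   called through [maxent()] the presences are already appended to it).
#' @param beta per-feature penalty vector from [regularization_vector()].
#' @param max_iter maximum coordinate-descent sweeps.
#' @param tol convergence threshold on per-sweep objective improvement.
#' @return list with `lambda`, `objective`, `gain`, `logZ`, `entropy`,
#'   `eta` (background linear predictor), `trace` (accepted updates:
#'   feature id and regularized gain), `iterations`, `converged`.
#' @export
fit_maxent <- function(presence_features, background_features, beta,
                       max_iter = 5000, tol = 1e-4) {
  if (is.null(nrow(presence_features)) || nrow(presence_features) == 0)
    stop("empty presence set")
  if (ncol(presence_features) != ncol(background_features))
    stop("presence and background feature matrices differ in columns")
  pbar <- colMeans(presence_features)
  res <- maxent_cd(background_features, pbar, as.numeric(beta),
                   as.integer(max_iter), tol)
  q <- exp(res$eta - res$logZ)
  entropy <- -sum(ifelse(q > 0, q * log(q), 0))
  trace <- data.frame(update = seq_along(res$trace_feature),
                      feature = colnames(background_features)[res$trace_feature],
                      gain = res$trace_gain, stringsAsFactors = FALSE)
  list(lambda = stats::setNames(res$lambda, colnames(background_features)),
       objective = res$objective, gain = res$gain, logZ = res$logZ,
       entropy = entropy, eta = res$eta, trace = trace,
       iterations = res$iterations, converged = res$converged)
}

#' Fit a maximum-entropy species distribution model
#'
#' The main fitting interface. Given either a raster stack plus occurrence
#' points, or presence and background sample data frames, it (i) freezes
#' feature definitions on the pooled samples, (ii) builds the penalty
#' vector for the chosen regularization multiplier, and (iii) fits the
#' L1-penalized Gibbs density over the background by coordinate descent.
#' By default the presences are appended to the background for
#' normalization, and up to `n_background` background cells are drawn
#' uniformly without replacement from the jointly valid cells of the stack.
#'
#' @param x a [raster_stack()] (with `p` giving occurrences), or a presence
#'   sample data frame (with `background` supplied).
#' @param p occurrence points ([occurrences()] or a data frame with
#'   `lon`/`lat`) when `x` is a stack.
#' @param background background sample data frame when `x` is a data frame
#'   of presence samples.
#' @param classes feature classes (default linear + hinge + threshold).
#' @param rm regularization multiplier.
#' @param n_knots knots per variable for threshold/hinge features.
#' @param n_background maximum number of background cells drawn from the
#'   stack.
#' @param seed seed for the background draw.
#' @param max_iter,tol solver controls.
#' @param add_samples_to_background append presences to the normalization
#'   background.
#' @param clamp clamp projection inputs to training bounds.
#' @return an object of class `maxent`.
#' @seealso [predict.maxent()], [tune_grid()], [percent_contribution()],
#'   [response_curve()], [project_map()]
#' @examples
#' cfg <- synthetic_config(nrows = 30, ncols = 30, n_variables = 4,
#'                         correlation_plan = NULL, n_occurrences = 40, seed = 7)
#' stk <- gen_climate_stack(cfg)
#' occ <- sample_occurrences(true_suitability(stk, cfg), 40, seed = 7)
#' fit <- maxent(stk, occ, classes = "LQ", n_background = 500)
#' fit
#' @export
maxent <- function(x, p = NULL, background = NULL,
                   classes = c("L", "H", "T"), rm = 1, n_knots = 50,
                   n_background = 10000, seed = 1,
                   max_iter = 5000, tol = 1e-4,
                   add_samples_to_background = TRUE, clamp = TRUE) {
  cl <- match.call()
  if (inherits(x, "raster_stack")) {
    if (is.null(p)) stop("supply occurrence points 'p' when fitting from a stack")
    presence <- extract_samples(x, p, provenance = "presence")
    bg <- sample_background(x, n_background, seed = seed)
  } else if (is.data.frame(x)) {
    if (is.null(background)) stop("supply 'background' samples when fitting from data frames")
    presence <- x; bg <- background
  } else stop("x must be a raster_stack or a presence sample data frame")
  if (nrow(presence) < 2) stop("need at least 2 presence samples")

  defs <- fit_feature_defs(presence, bg, classes = classes, n_knots = n_knots)
  Fp <- transform_features(presence, defs, clamp = FALSE)
  Fb <- transform_features(bg, defs, clamp = FALSE)
  beta <- regularization_vector(defs, Fp, rm = rm)
  Fnorm <- if (add_samples_to_background) rbind(Fb, Fp) else Fb
  fit <- fit_maxent(Fp, Fnorm, beta, max_iter = max_iter, tol = tol)

  structure(list(defs = defs, lambda = fit$lambda, beta = beta, rm = rm,
                 logZ = fit$logZ, Z = exp(fit$logZ), entropy = fit$entropy,
                 m = nrow(Fp), N = nrow(Fnorm), gain = fit$gain,
                 objective = fit$objective, trace = fit$trace,
                 iterations = fit$iterations, converged = fit$converged,
                 presence = presence, background = bg,
                 add_samples_to_background = add_samples_to_background,
                 clamp = clamp, seed = seed, call = cl),
            class = "maxent")
}

#' Draw background cells from a stack
#'
#' Uniform draw without replacement of up to `n` jointly valid cells (all
#' of them when fewer exist), returning their layer values.
#'
#' @param stack a [raster_stack()].
#' @param n maximum number of cells (default 10000).
#' @param seed integer seed.
#' @return data frame of background samples.
#' @export
sample_background <- function(stack, n = 10000, seed = 1) {
  vals <- stack_cell_values(stack)
  if (!nrow(vals)) stop("stack has no jointly valid cells")
  if (nrow(vals) > n) {
    set.seed(seed)
    vals <- vals[sample.int(nrow(vals), n), , drop = FALSE]
  }
  attr(vals, "provenance") <- "background"
  vals
}

#' Predict from a fitted maxent model
#'
#' @param object a [maxent()] fit.
#' @param newdata a sample data frame, a [raster_stack()] (returns a
#'   [raster_grid()]), or `NULL` for the training presences.
#' @param type `"cloglog"` (default; suitability in `(0,1)`,
#'   `1 - exp(-exp(H) * raw)`), `"raw"` (Gibbs probability normalized over
#'   the training background), or `"link"` (linear predictor).
#' @param clamp clamp inputs to training bounds; defaults to the fit's
#'   setting.
#' @param ... unused.
#' @export
predict.maxent <- function(object, newdata = NULL, type = c("cloglog", "raw", "link"),
                           clamp = object$clamp, ...) {
  type <- match.arg(type)
  if (inherits(newdata, "raster_stack"))
    return(project_map(object, newdata, type = type, clamp = clamp))
  if (is.null(newdata)) newdata <- object$presence
  Fm <- transform_features(newdata, object$defs, clamp = clamp)
  if (ncol(Fm) != length(object$lambda)) stop("feature-count mismatch")
  eta <- as.vector(Fm %*% object$lambda)
  switch(type,
         link = eta,
         raw = exp(eta - object$logZ),
         cloglog = {
           a <- exp(pmin(object$entropy + eta - object$logZ, 700))
           -expm1(-a)
         })
}

#' @export
coef.maxent <- function(object, nonzero = FALSE, ...) {
  if (nonzero) object$lambda[abs(object$lambda) > 1e-12] else object$lambda
}

#' @export
print.maxent <- function(x, ...) {
  cat("Maximum-entropy species distribution model\n")
  cat(sprintf("  presences: %d, background (normalization): %d\n", x$m, x$N))
  cat(sprintf("  feature classes: {%s}, RM = %g, features: %d (nonzero: %d)\n",
              paste(x$defs$classes, collapse = ","), x$rm,
              length(x$lambda), sum(abs(x$lambda) > 1e-12)))
  cat(sprintf("  regularized training gain: %.4f, entropy: %.4f nats\n",
              x$gain, x$entropy))
  cat(sprintf("  converged: %s after %d sweeps\n", x$converged, x$iterations))
  invisible(x)
}

#' @export
summary.maxent <- function(object, ...) {
  pc <- percent_contribution(object)
  out <- list(model = object, contribution = pc,
              train_scores = predict(object),
              n_nonzero = sum(abs(object$lambda) > 1e-12))
  class(out) <- "summary.maxent"
  out
}

#' @export
print.summary.maxent <- function(x, ...) {
  print(x$model)
  cat("\nPercent contribution by variable:\n")
  pc <- sort(x$contribution, decreasing = TRUE)
  for (v in names(pc)) if (pc[[v]] > 0.05) cat(sprintf("  %-8s %6.1f%%\n", v, pc[[v]]))
  cat(sprintf("\nMean training cloglog score: %.3f\n", mean(x$train_scores)))
  invisible(x)
}

#' Response-curve panel plot for a fitted model
#'
#' @param x a [maxent()] fit.
#' @param variables variables to plot (default: up to 6 by contribution).
#' @param mode `"marginal"` or `"univariate"`, see [response_curve()].
#' @param ... passed to [graphics::plot()].
#' @export
plot.maxent <- function(x, variables = NULL, mode = "marginal", ...) {
  if (is.null(variables)) {
    pc <- sort(percent_contribution(x), decreasing = TRUE)
    variables <- names(pc)[seq_len(min(6, length(pc)))]
  }
  nv <- length(variables)
  nc <- min(3, nv); nr <- ceiling(nv / nc)
  op <- graphics::par(mfrow = c(nr, nc), mar = c(4, 4, 2, 1))
  on.exit(graphics::par(op))
  for (v in variables) {
    rc <- response_curve(x, v, mode = mode)
    graphics::plot(rc$value, rc$cloglog, type = "l", xlab = v,
                   ylab = "cloglog suitability", ylim = c(0, 1), main = v, ...)
  }
  invisible(x)
}

#' Save / load a fitted model as JSON
#'
#' Serializes the feature definitions, coefficients, penalties and
#' normalization constants; samples are not stored.
#'
#' @param model a [maxent()] fit.
#' @param path file path.
#' @export
write_maxent <- function(model, path) {
  obj <- list(package = "entniche", version = "0.1.0",
              variables = model$defs$variables,
              min = as.list(model$defs$min), max = as.list(model$defs$max),
              classes = model$defs$classes, n_knots = model$defs$n_knots,
              knots = model$defs$knots,
              features = model$defs$features,
              lambda = unname(model$lambda), beta = unname(model$beta),
              rm = model$rm, logZ = model$logZ, entropy = model$entropy,
              m = model$m, N = model$N, gain = model$gain, seed = model$seed,
              clamp = model$clamp)
  jsonlite::write_json(obj, path, auto_unbox = TRUE, digits = NA, pretty = TRUE)
  invisible(path)
}

#' @rdname write_maxent
#' @export
read_maxent <- function(path) {
  obj <- jsonlite::read_json(path, simplifyVector = TRUE)
  defs <- structure(list(variables = obj$variables,
                         min = stats::setNames(unlist(obj$min), obj$variables),
                         max = stats::setNames(unlist(obj$max), obj$variables),
                         classes = obj$classes, n_knots = obj$n_knots,
                         knots = obj$knots,
                         features = as.data.frame(obj$features)),
                    class = "feature_defs")
  structure(list(defs = defs,
                 lambda = stats::setNames(obj$lambda, defs$features$id),
                 beta = stats::setNames(obj$beta, defs$features$id),
                 rm = obj$rm, logZ = obj$logZ, Z = exp(obj$logZ),
                 entropy = obj$entropy, m = obj$m, N = obj$N, gain = obj$gain,
                 trace = NULL, presence = NULL, background = NULL,
                 clamp = obj$clamp, seed = obj$seed),
            class = "maxent")
}
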