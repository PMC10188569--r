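#' Configuration for the synthetic bioclimatic landscape
#'
#' Describes a pseudo-bioclim world: spatially smooth, mutually correlated
#' predictor layers named `bio1..bio<n>`, a true suitability surface driven
#' by three of them, and occurrence counts. Defaults emulate a 19-layer
#' WorldClim-style stack in which annual-mean-temperature-like `bio1`,
#' annual-precipitation-like `bio12` and precipitation-seasonality-like
#' `bio15` drive suitability with plateau optima 22–28, 300–1000 and
#' 70–160 respectively.
#'
#' @param nrows,ncols grid size in cells.
#' @param cellsize cell edge in degrees.
#' @param xll,yll lower-left corner (degrees).
#' @param n_variables number of layers (named `bio1` ... `bio<n>`).
#' @param correlation_plan data frame with columns `source`, `clone`,
#'   `r`: layer `clone` is rebuilt as an affine mix giving sample Pearson
#'   correlation `r` with `source`.
#' @param response response specification: named list per driver variable,
#'   each a list with `low`, `high` (plateau bounds) and `width` (Gaussian
#'   falloff sd outside the plateau, in the variable's units).
#' @param n_occurrences number of occurrence points to sample.
#' @param smooth_cells moving-average smoothing kernel width (cells) for the
#'   noise fields.
#' @param seed integer seed; all generation is deterministic given it.
#' @return a list of class `synthetic_config`.
#' @export
synthetic_config <- function(nrows = 80, ncols = 80, cellsize = 0.25,
                             xll = 70, yll = 8,
                             n_variables = 19,
                             correlation_plan = default_correlation_plan(),
                             response = default_response_spec(),
                             n_occurrences = 125,
                             smooth_cells = 5,
                             seed = 1) {
  for (r in names(response)) {
    sp <- response[[r]]
    if (!(sp$low < sp$high)) stop(sprintf("response for %s: low must be < high", r))
    if (sp$width <= 0) stop(sprintf("response for %s: width must be positive", r))
  }
  if (n_occurrences < 1) stop("n_occurrences must be >= 1")
  if (!is.null(correlation_plan) && nrow(correlation_plan)) {
    if (any(abs(correlation_plan$r) > 1 | correlation_plan$r == 0))
      stop("correlation plan: target r must satisfy 0 < |r| <= 1")
  }
  structure(list(nrows = nrows, ncols = ncols, cellsize = cellsize,
                 xll = xll, yll = yll, n_variables = n_variables,
                 correlation_plan = correlation_plan, response = response,
                 n_occurrences = n_occurrences, smooth_cells = smooth_cells,
                 seed = seed),
            class = "synthetic_config")
}

#' @rdname synthetic_config
#' @export
default_correlation_plan <- function() {
  data.frame(source = c("bio1", "bio1", "bio12", "bio12", "bio4"),
             clone  = c("bio5", "bio6", "bio13", "bio16", "bio7"),
             r      = c(0.95, 0.85, 0.90, 0.85, 0.90),
             stringsAsFactors = FALSE)
}

#' @rdname synthetic_config
#' @export
default_response_spec <- function() {
  list(bio1  = list(low = 22,  high = 28,   width = 2),
       bio12 = list(low = 300, high = 1000, width = 150),
       bio15 = list(low = 70,  high = 160,  width = 20))
}

# physically plausible value range per layer role: temperature-like layers
# span ~10-35, precipitation-like ~0-2500, the seasonality layer ~20-200
variable_role_range <- function(name) {
  idx <- suppressWarnings(as.integer(sub("^bio", "", name)))
  if (is.na(idx)) return(c(0, 1))
  if (idx == 15) c(20, 200)
  else if (idx >= 12) c(0, 2500)
  else c(10, 35)
}

# moving-average smoothing of a matrix with edge replication
smooth_field <- function(m, k) {
  if (k <= 1) return(m)
  half <- floor(k / 2)
  pad <- function(x) {
    x <- rbind(matrix(rep(x[1, ], half), nrow = half, byrow = TRUE), x,
               matrix(rep(x[nrow(x), ], half), nrow = half, byrow = TRUE))
    cbind(matrix(rep(x[, 1], half), ncol = half), x,
          matrix(rep(x[, ncol(x)], half), ncol = half))
  }
  p <- pad(m)
  ker <- rep(1 / k, k)
  sm <- apply(p, 2, function(col) stats::filter(col, ker, sides = 2))
  sm <- t(apply(sm, 1, function(row) stats::filter(row, ker, sides = 2)))
  sm[(half + 1):(half + nrow(m)), (half + 1):(half + ncol(m)), drop = FALSE]
}

rescale_range <- function(m, lo, hi) {
  rng <- range(m)
  if (rng[2] - rng[1] < 1e-12) return(matrix(lo, nrow(m), ncol(m)))
  (m - rng[1]) / (rng[2] - rng[1]) * (hi - lo) + lo
}

#' Generate a synthetic bioclimatic raster stack
#'
#' Each layer is a latitudinal/longitudinal linear gradient plus a smoothed
#' seeded white-noise field, min-max rescaled into a physically plausible
#' range for its role. Layers named in the correlation plan are rebuilt as
#' `r * standardized(source) + sqrt(1 - r^2) * standardized(independent field)`
#' with the noise field residualized against the source, so the realized
#' sample correlation equals the target exactly (affine rescaling preserves
#' it). Fully deterministic under the config seed.
#'
#' @param config a [synthetic_config()].
#' @return a [raster_stack()] with `config$n_variables` layers.
#' @export
gen_climate_stack <- function(config) {
  stopifnot(inherits(config, "synthetic_config"))
  set.seed(config$seed)
  nr <- config$nrows; nc <- config$ncols
  vars <- paste0("bio", seq_len(config$n_variables))
  plan <- config$correlation_plan
  if (!is.null(plan) && nrow(plan)) {
    unknown <- setdiff(unique(c(plan$source, plan$clone)), vars)
    if (length(unknown))
      stop(sprintf("correlation plan references unknown variable(s): %s",
                   paste(unknown, collapse = ", ")))
  }
  latg <- matrix(rev(seq_len(nr)), nr, nc)        # increases northward
  long <- matrix(seq_len(nc), nr, nc, byrow = TRUE)
  latg <- (latg - mean(latg)) / stats::sd(latg)
  long <- (long - mean(long)) / stats::sd(long)

  raw_field <- function() {
    w <- stats::rnorm(3)
    noise <- smooth_field(matrix(stats::rnorm(nr * nc), nr, nc), config$smooth_cells)
    noise <- (noise - mean(noise)) / stats::sd(noise)
    f <- w[1] * latg + w[2] * long + (0.6 + abs(w[3])) * noise
    f
  }

  fields <- stats::setNames(lapply(vars, function(v) raw_field()), vars)

  if (!is.null(plan) && nrow(plan)) {
    for (i in seq_len(nrow(plan))) {
      src <- fields[[plan$source[i]]]
      r <- plan$r[i]
      s <- as.vector(src); s <- (s - mean(s)) / stats::sd(s)
      noise <- as.vector(fields[[plan$clone[i]]])
      # residualize the independent field against the source so the sample
      # correlation hits the target exactly
      resid <- noise - s * sum(noise * s) / sum(s * s) - mean(noise - s * sum(noise * s) / sum(s * s))
      resid <- resid / stats::sd(resid)
      fields[[plan$clone[i]]] <- matrix(r * s + sqrt(1 - r^2) * resid, nr, nc)
    }
  }

  layers <- lapply(vars, function(v) {
    rng <- variable_role_range(v)
    raster_grid(rescale_range(fields[[v]], rng[1], rng[2]),
                xll = config$xll, yll = config$yll, cellsize = config$cellsize)
  })
  names(layers) <- vars
  raster_stack(layers)
}

# plateau-Gaussian response: 1 inside [low, high], Gaussian falloff outside
plateau_response <- function(x, low, high, width) {
  d <- pmax(low - x, x - high, 0)
  exp(-0.5 * (d / width)^2)
}

#' True suitability surface of a synthetic landscape
#'
#' Product over driver variables of a plateau-Gaussian response: 1 inside
#' the plateau `[low, high]`, Gaussian falloff with sd `width` outside.
#' Values lie in `[0, 1]`; nodata propagates.
#'
#' @param stack stack from [gen_climate_stack()].
#' @param config the generating [synthetic_config()].
#' @return a [raster_grid()] of true suitability.
#' @export
true_suitability <- function(stack, config) {
  stopifnot(inherits(stack, "raster_stack"))
  drivers <- names(config$response)
  missing <- setdiff(drivers, names(stack$layers))
  if (length(missing))
    stop(sprintf("driver variable(s) missing from stack: %s", paste(missing, collapse = ", ")))
  ref <- stack$layers[[1]]
  s <- matrix(1, ref$nrows, ref$ncols)
  for (v in drivers) {
    sp <- config$response[[v]]
    s <- s * plateau_response(stack$layers[[v]]$values, sp$low, sp$high, sp$width)
  }
  s[!as.matrix(valid_mask(stack))] <- NA_real_
  raster_grid(s, xll = ref$xll, yll = ref$yll, cellsize = ref$cellsize,
              nodata = ref$nodata)
}

#' Sample occurrence points proportional to true suitability
#'
#' Cells are drawn without replacement with probability proportional to
#' their suitability; each point is then placed uniformly at random inside
#' its cell. Deterministic under `seed`.
#'
#' @param truth suitability [raster_grid()] (values in `[0, 1]`).
#' @param n number of points.
#' @param seed integer seed.
#' @return an [occurrences()] set with `n` rows.
#' @export
sample_occurrences <- function(truth, n, seed = 1) {
  stopifnot(inherits(truth, "raster_grid"))
  set.seed(seed)
  w <- as.vector(truth$values)
  pos <- which(is.finite(w) & w > 0)
  if (length(pos) < n)
    stop(sprintf("only %d cells with positive suitability; cannot draw %d", length(pos), n))
  cells <- if (length(pos) == 1L) pos else sample(pos, n, prob = w[pos])
  row <- ((cells - 1L) %% truth$nrows) + 1L
  col <- ((cells - 1L) %/% truth$nrows) + 1L
  ctr <- cell_center(truth, row, col)
  jit <- (matrix(stats::runif(2 * n), n, 2) - 0.5) * truth$cellsize
  occurrences(ctr[, "lon"] + jit[, 1], ctr[, "lat"] + jit[, 2],
              species = "synthetic_species")
}

#' Apply an additive/multiplicative climate delta to a stack
#'
#' Emulates a future climate scenario: each named layer becomes
#' `factor * layer + offset`; unnamed layers pass through unchanged; nodata
#' is preserved.
#'
#' @param stack a [raster_stack()].
#' @param offsets named numeric vector of additive offsets.
#' @param factors named numeric vector of multiplicative factors (must be
#'   positive).
#' @return a new [raster_stack()].
#' @export
apply_climate_delta <- function(stack, offsets = numeric(), factors = numeric()) {
  stopifnot(inherits(stack, "raster_stack"))
  if (length(factors) && any(factors <= 0)) stop("delta factors must be positive")
  layers <- lapply(names(stack$layers), function(nm) {
    g <- stack$layers[[nm]]
    f <- if (nm %in% names(factors)) factors[[nm]] else 1
    o <- if (nm %in% names(offsets)) offsets[[nm]] else 0
    raster_grid(f * g$values + o, xll = g$xll, yll = g$yll,
                cellsize = g$cellsize, nodata = g$nodata)
  })
  names(layers) <- names(stack$layers)
  raster_stack(layers)
}
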