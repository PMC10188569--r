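# small hand-built grids and independent oracles used across test files

# grid from a list of row vectors (row 1 = north)
grid_from_rows <- function(rows, xll = 0, yll = 0, cellsize = 1) {
  raster_grid(do.call(rbind, rows), xll = xll, yll = yll, cellsize = cellsize)
}

# independent objective oracle: the penalized maxent objective evaluated
# directly from its definition
maxent_objective <- function(lambda, Fp, Fbg, beta) {
  eta_p <- as.vector(Fp %*% lambda)
  eta_b <- as.vector(Fbg %*% lambda)
  -mean(eta_p) + log(sum(exp(eta_b))) + sum(beta * abs(lambda))
}

# dense grid search minimum of the objective over lambda in [-5, 5]^J,
# coarse pass plus one local refinement
grid_search_min <- function(Fp, Fbg, beta, lim = 5, n_coarse = 41) {
  J <- ncol(Fbg)
  search <- function(centers, half_width, n) {
    axes <- lapply(seq_len(J), function(j)
      seq(centers[j] - half_width, centers[j] + half_width, length.out = n))
    pts <- as.matrix(do.call(expand.grid, axes))
    eta_b <- Fbg %*% t(pts)
    mx <- apply(eta_b, 2, max)
    logZ <- mx + log(colSums(exp(sweep(eta_b, 2, mx))))
    obj <- -colMeans(Fp %*% t(pts)) + logZ + as.vector(abs(pts) %*% beta)
    list(min = min(obj), at = pts[which.min(obj), ])
  }
  step1 <- search(rep(0, J), lim, n_coarse)
  h <- 2 * lim / (n_coarse - 1)
  step2 <- search(step1$at, h, 21)
  step3 <- search(step2$at, 2 * h / 20, 21)
  min(step1$min, step2$min, step3$min)
}

# full recovery pipeline on the default 19-layer synthetic world:
# screen collinear layers (drivers given expert priority), fit at default
# settings, project, and summarize recovery of the known truth
run_recovery <- function(seed, response = default_response_spec()) {
  drivers <- c("bio1", "bio12", "bio15")
  cfg <- synthetic_config(seed = seed, response = response)
  stk <- gen_climate_stack(cfg)
  truth <- true_suitability(stk, cfg)
  occ <- sample_occurrences(truth, cfg$n_occurrences, seed = seed)
  pres <- extract_samples(stk, occ)
  bg <- sample_background(stk, 10000, seed = seed)
  gains <- univariate_gains(pres, bg)
  prio <- c(drivers, setdiff(names(sort(gains, decreasing = TRUE)), drivers))
  kept <- greedy_select(correlation_matrix(stk), priority = prio)
  fit <- maxent(pres[, kept], background = bg[, kept], seed = seed)
  map <- project_map(fit, stk)
  ok <- is.finite(truth$values) & is.finite(map$values)
  pc <- percent_contribution(fit)
  rc <- response_curve(fit, "bio1")
  list(fit = fit, truth = truth, stack = stk, kept = kept, pc = pc,
       rho = cor(map$values[ok], truth$values[ok], method = "spearman"),
       argmax = rc$value[which.max(rc$cloglog)],
       auc_train = auc_rank(predict(fit, pres[, kept]), predict(fit, bg[, kept])))
}

# narrow-plateau response spec: suitable habitat is rare, so presences and
# background separate sharply
sharp_response_spec <- function() {
  list(bio1  = list(low = 24,  high = 26,  width = 0.5),
       bio12 = list(low = 500, high = 800, width = 30),
       bio15 = list(low = 100, high = 140, width = 5))
}

# a quick small synthetic world shared by several tests
small_world <- function(seed = 1, nrows = 30, ncols = 30, n_variables = 4,
                        n_occurrences = 40) {
  cfg <- synthetic_config(nrows = nrows, ncols = ncols,
                          n_variables = n_variables,
                          correlation_plan = NULL,
                          response = list(bio1 = list(low = 22, high = 28, width = 2)),
                          n_occurrences = n_occurrences, seed = seed)
  stk <- gen_climate_stack(cfg)
  truth <- true_suitability(stk, cfg)
  occ <- sample_occurrences(truth, n_occurrences, seed = seed)
  list(cfg = cfg, stack = stk, truth = truth, occ = occ)
}
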