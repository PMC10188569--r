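make_design <- function(m = 20, N = 60, J = 2, seed = 1, classes = "L") {
  set.seed(seed)
  vars <- paste0("v", seq_len(J))
  p <- as.data.frame(matrix(runif(m * J, 0.4, 1), m, J)); names(p) <- vars
  b <- as.data.frame(matrix(runif(N * J, 0, 1), N, J)); names(b) <- vars
  d <- fit_feature_defs(p, b, classes = classes)
  list(p = p, b = b, d = d,
       Fp = transform_features(p, d), Fb = transform_features(b, d))
}

test_that("regularization weights are linear in RM and match the class tables", {
  dd <- make_design(m = 100, N = 100, J = 1, classes = "LQH")
  # hinge base weight is constant 0.5; at m = 100, beta = RM * 0.5 * sd / 10
  b1 <- regularization_vector(dd$d, dd$Fp, rm = 1)
  b2 <- regularization_vector(dd$d, dd$Fp, rm = 2)
  expect_equal(unname(b2), unname(2 * b1))
  hj <- grep("^Hf", names(b1))[1]
  sd_h <- sd(dd$Fp[, hj])
  expect_equal(unname(b1[hj]), 0.5 * sd_h / 10)
  # linear class at m = 100 has base 0.05
  expect_equal(unname(b1["L_v1"]), 0.05 * sd(dd$Fp[, "L_v1"]) / 10)
  expect_true(all(b1 > 0))
})

test_that("a feature constant over presences still gets a positive penalty", {
  p <- data.frame(x = rep(5, 10), y = runif(10))
  b <- data.frame(x = runif(10, 0, 10), y = runif(10))
  d <- fit_feature_defs(p, b, classes = "L")
  beta <- regularization_vector(d, transform_features(p, d), rm = 1)
  expect_true(all(is.finite(beta) & beta > 0))
  expect_error(regularization_vector(d, transform_features(p[1, ], d)), "2 presences")
})

test_that("infinite shrinkage collapses to the uniform model with zero gain", {
  dd <- make_design()
  fit <- fit_maxent(dd$Fp, rbind(dd$Fb, dd$Fp), rep(1e9, ncol(dd$Fp)))
  expect_equal(unname(fit$lambda), rep(0, length(fit$lambda)))
  expect_equal(fit$gain, 0)
  N <- nrow(dd$Fb) + nrow(dd$Fp)
  expect_equal(fit$entropy, log(N))
  raw <- exp(fit$eta - fit$logZ)
  expect_equal(raw, rep(1 / N, N))
})

test_that("one enriched linear feature earns a positive coefficient matching a 1-D search", {
  dd <- make_design(m = 30, N = 80, J = 1, seed = 4)
  beta <- regularization_vector(dd$d, dd$Fp, rm = 1)
  Fbg <- rbind(dd$Fb, dd$Fp)
  fit <- fit_maxent(dd$Fp, Fbg, beta, tol = 1e-10)
  expect_gt(fit$lambda[["L_v1"]], 0)
  grid <- seq(-5, 5, by = 0.001)
  obj <- vapply(grid, function(l) maxent_objective(l, dd$Fp, Fbg, beta), numeric(1))
  expect_equal(fit$lambda[["L_v1"]], grid[which.min(obj)], tolerance = 0.01)
  expect_lte(fit$objective, min(obj) + 1e-8)
})

test_that("the solver objective matches a dense grid-search minimum on a tiny instance", {
  set.seed(9)
  Fp <- matrix(runif(6), 3, 2, dimnames = list(NULL, c("f1", "f2")))
  Fbg <- rbind(matrix(runif(12), 6, 2, dimnames = list(NULL, c("f1", "f2"))), Fp)
  beta <- c(0.05, 0.05)
  fit <- fit_maxent(Fp, Fbg, beta, tol = 1e-10)
  oracle <- grid_search_min(Fp, Fbg, beta)
  expect_lt(abs(fit$objective - oracle), 1e-4)
})

test_that("raw predictions conserve probability over the training background", {
  w <- small_world(seed = 2)
  fit <- maxent(w$stack, w$occ, classes = "LQ", n_background = 400, seed = 2)
  bg_all <- if (fit$add_samples_to_background) rbind(fit$background, fit$presence) else fit$background
  raw <- predict(fit, bg_all, type = "raw")
  expect_equal(sum(raw), 1, tolerance = 1e-9)
  expect_identical(length(raw), fit$N)
})

test_that("regularized gain is nondecreasing along the accepted update trace", {
  w <- small_world(seed = 12)
  fit <- maxent(w$stack, w$occ, classes = "LQH", n_knots = 10,
                n_background = 400, seed = 3)
  expect_gt(nrow(fit$trace), 0)
  expect_true(all(diff(fit$trace$gain) >= -1e-9))
  expect_equal(fit$trace$gain[nrow(fit$trace)], fit$gain, tolerance = 1e-12)
})

test_that("cloglog output is the entropy-calibrated transform of raw", {
  w <- small_world(seed = 14)
  fit <- maxent(w$stack, w$occ, classes = "LQ", n_background = 300, seed = 1)
  samples <- rbind(fit$background[1:50, ], fit$presence[1:10, ])
  raw <- predict(fit, samples, type = "raw")
  cll <- predict(fit, samples, type = "cloglog")
  expect_equal(cll, 1 - exp(-exp(fit$entropy) * raw), tolerance = 1e-12)
  expect_true(all(cll > 0 & cll < 1))
  # strict monotonicity in raw
  ord <- order(raw)
  expect_true(all(diff(cll[ord]) >= 0))
  # uniform model: cloglog = 1 - exp(-1) everywhere
  big_beta <- maxent(w$stack, w$occ, classes = "LQ", n_background = 300,
                     seed = 1, rm = 1e9)
  expect_equal(predict(big_beta, samples),
               rep(1 - exp(-1), nrow(samples)), tolerance = 1e-9)
})

test_that("total coefficient mass shrinks as RM grows", {
  w <- small_world(seed = 17, nrows = 35, ncols = 35, n_occurrences = 50)
  mass <- vapply(c(0.5, 1.5, 4), function(rm) {
    fit <- maxent(w$stack, w$occ, classes = "LQH", n_knots = 8,
                  n_background = 400, seed = 5, rm = rm, tol = 1e-7)
    sum(abs(fit$lambda))
  }, numeric(1))
  expect_true(all(diff(mass) <= 1e-6))
})

test_that("a fitted model survives a JSON round trip", {
  w <- small_world(seed = 19)
  fit <- maxent(w$stack, w$occ, classes = "LQT", n_knots = 5,
                n_background = 300, seed = 1)
  path <- withr::local_tempfile(fileext = ".json")
  write_maxent(fit, path)
  back <- read_maxent(path)
  samples <- fit$background[1:20, ]
  expect_equal(predict(back, samples), predict(fit, samples), tolerance = 1e-12)
  expect_equal(back$gain, fit$gain)
})
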