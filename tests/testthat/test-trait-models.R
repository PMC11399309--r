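sim_bioclim_frame <- function(n, seed = 1, noise_sd = 0.2,
                              f = function(x) 0.8 * x,
                              g = function(x) 0 * x,
                              h = function(x) 0 * x) {
  simulate_additive_gam_data(
    n, effects = list(ln_mi = f, mtco = g, mgst = h),
    ranges = list(ln_mi = c(-1.5, 1), mtco = c(-15, 12),
                  mgst = c(0, 25)),
    noise_sd = noise_sd, seed = seed)
}

test_that("GAM recovers a planted linear partial effect", {
  d <- sim_bioclim_frame(800, seed = 2)
  fit <- fit_trait_gam(d, "y")
  pt <- gam_partials(fit)
  expect_gt(cor(pt[, "s(ln_mi)"], d$signal_ln_mi), 0.99)
  expect_equal(fit$deviance_explained,
               var(d$signal) / (var(d$signal) + 0.04), tolerance = 0.05)
  expect_gt(fit$adjusted_r2, 0)
  expect_lte(fit$adjusted_r2, fit$deviance_explained + 1e-9)
})

test_that("fits are invariant under uniform replication of the data", {
  d <- sim_bioclim_frame(300, seed = 3)
  f1 <- fit_trait_gam(d, "y")
  ## stacking doubles the data term of the penalized criterion, so the
  ## identical fit needs the penalty doubled too (selected smoothness is
  ## itself sample-size dependent under REML)
  f2 <- fit_trait_gam(rbind(d, d), "y", sp = 2 * f1$model$sp)
  nd <- d[seq(1, 300, by = 7), c("ln_mi", "mtco", "mgst")]
  expect_equal(predict(f1, nd), predict(f2, nd), tolerance = 1e-6)
})

test_that("degenerate and invalid inputs are handled explicitly", {
  d <- sim_bioclim_frame(200, seed = 4)
  d$y <- 5
  expect_warning(f <- fit_trait_gam(d, "y"), "constant response")
  expect_equal(f$deviance_explained, 0)
  expect_error(fit_trait_gam(d[1:12, ], "y"), "complete rows")
  expect_error(fit_trait_gam(d, "y", k = 2), "k must be")
  expect_error(fit_trait_gam(d, "nope"), "missing column")
})

test_that("varying-coefficient interactions accept cover fractions", {
  d <- sim_bioclim_frame(600, seed = 5)
  d$deciduous <- runif(600)
  d$evergreen <- runif(600) * (1 - d$deciduous)
  d$y <- d$y + 0.5 * d$deciduous * d$ln_mi
  fit <- fit_trait_gam(d, "y", interactions = c("deciduous", "evergreen"))
  expect_gt(fit$deviance_explained, 0.5)
  expect_equal(length(fit$model$smooth), 3 + 2 * (1 + 3))
})

test_that("importance shares are normalized, symmetric, and match the oracle", {
  ## planted variance contributions 50/30/20 via orthogonal uniforms
  n <- 1200
  b <- sqrt(c(0.5, 0.3, 0.2) * 12)  # var of U(0,1) is 1/12
  d <- simulate_additive_gam_data(
    n, effects = list(x1 = function(x) b[1] * x,
                      x2 = function(x) b[2] * x,
                      x3 = function(x) b[3] * x),
    ranges = list(x1 = 0:1, x2 = 0:1, x3 = 0:1),
    noise_sd = 0.3, seed = 6)
  imp <- relative_importance(d, "y", c("x1", "x2", "x3"), smooth = FALSE)
  expect_equal(sum(imp$share), 100, tolerance = 1e-6)
  expect_equal(sum(imp$share_raw), 100, tolerance = 1e-6)
  ## exact agreement with the brute-force linear Shapley oracle
  oracle <- shapley_lm_oracle(d, "y", c("x1", "x2", "x3"))
  full <- summary(stats::lm(y ~ x1 + x2 + x3, d))$r.squared
  expect_equal(imp$share, unname(100 * oracle / full), tolerance = 1e-6)
  ## permutation symmetry: relabeling predictors permutes the shares
  imp2 <- relative_importance(d, "y", c("x3", "x1", "x2"), smooth = FALSE)
  expect_equal(imp2$share[match(imp$predictor, imp2$predictor)],
               imp$share, tolerance = 1e-10)
  ## smooth fits stay near the planted 50/30/20 split
  imps <- relative_importance(d, "y", c("x1", "x2", "x3"))
  expect_equal(imps$share, c(50, 30, 20), tolerance = 5)
})

test_that("a single dominant signal takes all the importance", {
  d <- sim_bioclim_frame(700, seed = 7, noise_sd = 0.05)
  imp <- relative_importance(d, "y")
  expect_equal(imp$share[imp$predictor == "ln_mi"], 100, tolerance = 2)
  expect_equal(sum(imp$share[imp$predictor != "ln_mi"]), 0, tolerance = 2)
  ## leave-one-out variant also sums to 100
  impl <- relative_importance(d, "y", method = "loo")
  expect_equal(sum(impl$share_raw), 100, tolerance = 1e-6)
})

test_that("concurvity flags duplicated predictors and spares independent ones", {
  set.seed(8)
  d <- data.frame(a = runif(600), b = runif(600))
  d$a2 <- d$a
  d$y <- sin(2 * pi * d$a) + d$b + rnorm(600, sd = 0.1)
  dup <- fit_trait_gam(d, "y", predictors = c("a", "a2"))
  cv <- gam_concurvity(dup)
  expect_true(all(cv > 1 - 1e-6))
  ind <- fit_trait_gam(d, "y", predictors = c("a", "b"))
  cvi <- gam_concurvity(ind)
  expect_true(all(cvi < 0.1))
  expect_true(all(cvi >= 0 & cvi <= 1))
  single <- fit_trait_gam(d, "y", predictors = "a")
  expect_error(gam_concurvity(single), "not applicable")
})

test_that("climate-space grids follow the increment arithmetic and hull mask", {
  d <- sim_bioclim_frame(500, seed = 9)
  fit <- fit_trait_gam(d, "y")
  inc <- c(0.05, 0.25, 0.25)
  surf <- climate_space_surface(fit, d[, c("ln_mi", "mtco", "mgst")],
                                increments = inc)
  for (i in 1:3) {
    rng <- range(d[[fit$spec$predictors[i]]])
    expect_length(surf$axes[[i]], floor(diff(rng) / inc[i]) + 1)
  }
  ## masked nodes carry no prediction; unmasked nodes all do
  expect_true(all(is.na(surf$pred[!surf$mask])))
  expect_true(all(!is.na(surf$pred[surf$mask])))
  ## every observed point's nearest node is unmasked (verified against
  ## the independent membership oracle)
  near <- sapply(1:3, function(i)
    vapply(d[[fit$spec$predictors[i]]][1:40], function(v)
      which.min(abs(surf$axes[[i]] - v)), integer(1)))
  nodes <- cbind(surf$axes[[1]][near[, 1]], surf$axes[[2]][near[, 2]],
                 surf$axes[[3]][near[, 3]])
  obs <- as.matrix(d[, c("ln_mi", "mtco", "mgst")])
  keep <- in_hull_oracle(obs, nodes)
  expect_true(all(surf$mask[near[keep, , drop = FALSE]]))
  expect_error(climate_space_surface(fit, d[, c("ln_mi", "mtco", "mgst")],
                                     increments = c(0, 1, 1)),
               "strictly positive")
})

test_that("masked fraction shrinks as observations accumulate", {
  d <- sim_bioclim_frame(400, seed = 10)
  fit <- fit_trait_gam(d, "y")
  s1 <- climate_space_surface(fit, d[1:50, c("ln_mi", "mtco", "mgst")],
                              increments = c(0.2, 2, 2))
  s2 <- climate_space_surface(fit, d[1:400, c("ln_mi", "mtco", "mgst")],
                              increments = c(0.2, 2, 2))
  ## the hull over more observations contains the earlier one, so every
  ## node unmasked on the small-sample grid stays unmasked
  grid1 <- as.matrix(expand.grid(s1$axes))
  expect_true(all(in_hull(s2$hull, grid1)[as.vector(s1$mask)]))
})

test_that("slices snap to the nearest MTCO level of the grid", {
  d <- sim_bioclim_frame(400, seed = 11)
  fit <- fit_trait_gam(d, "y")
  surf <- climate_space_surface(fit, d[, c("ln_mi", "mtco", "mgst")],
                                increments = c(0.1, 1, 1))
  sl <- surface_slice(surf, mtco = 0)
  expect_equal(dim(sl$slice), c(length(surf$axes[[1]]),
                                length(surf$axes[[3]])))
  expect_lte(abs(sl$mtco - 0), 0.5)
})

test_that("predictions reproduce fitted values on the training points", {
  d <- sim_bioclim_frame(300, seed = 12)
  fit <- fit_trait_gam(d, "y")
  expect_equal(predict(fit, d[, c("ln_mi", "mtco", "mgst")]),
               as.numeric(stats::fitted(fit$model)), tolerance = 1e-8)
})
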