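test_that("unit conversions follow the reciprocal and ratio definitions", {
  expect_equal(lma_from_sla(10), 0.1)
  expect_equal(lma_from_sla(1), 1)
  expect_equal(lma_from_sla(25), 0.04)
  expect_error(lma_from_sla(0), "positive")
  expect_equal(area_based_from_mass(20, 10), 2)
  expect_equal(area_based_from_mass(0, 7), 0)
  expect_equal(area_based_from_mass(15, 25), 0.6)
  expect_error(area_based_from_mass(5, -1), "positive")
  expect_error(area_based_from_mass(-2, 5), ">= 0")
  ## reciprocal consistency: converting back recovers the mass basis
  sla <- c(3.7, 12.2, 31)
  m <- c(8, 21, 14.5)
  expect_equal(area_based_from_mass(m, sla) * sla, m, tolerance = 1e-12)
})

test_that("growth forms map to group probabilities; minority forms are omitted", {
  sp <- toy_species()
  expect_equal(unlist(sp[sp$taxon == "tree_d",
                         c("p_nonwoody", "p_deciduous", "p_evergreen")],
                      use.names = FALSE), c(0, 1, 0))
  expect_true(sp$omitted[sp$taxon == "fern1"])
  expect_equal(sum(unlist(sp[sp$taxon == "fern1",
                             c("p_nonwoody", "p_deciduous",
                               "p_evergreen")])), 0)
  ## configured mixed form passes its probabilities through
  expect_equal(unlist(sp[sp$taxon == "mix1",
                         c("p_nonwoody", "p_deciduous", "p_evergreen")],
                      use.names = FALSE), c(0.5, 0.25, 0.25))
  expect_error(classify_groups(data.frame(taxon = "x",
                                          growth_form = "liana")),
               "liana")
})

test_that("group coverage follows cover-times-probability with renormalization", {
  sp <- toy_species()
  gc <- group_cover(toy_comp(c("herb1", "tree_d"), c(0.6, 0.4)), sp)
  expect_equal(unlist(gc[1, group_names()], use.names = FALSE),
               c(0.6, 0.4, 0))
  ## a single mixed taxon yields its own probability triple
  gc <- group_cover(toy_comp("mix1", 1), sp)
  expect_equal(unlist(gc[1, group_names()], use.names = FALSE),
               c(0.5, 0.25, 0.25))
  ## an omitted fern contributes nothing; remaining mass renormalizes
  gc <- group_cover(toy_comp(c("herb1", "tree_e", "fern1"),
                             c(0.5, 0.3, 0.2)), sp)
  expect_equal(unlist(gc[1, group_names()], use.names = FALSE),
               c(0.5, 0, 0.3) / 0.8)
  expect_error(group_cover(toy_comp("fern1", 1), sp), "omitted")
})

test_that("every plot's group cover sums to one", {
  w <- small_world()
  gc <- group_cover(w$composition, w$species)
  expect_true(all(abs(rowSums(gc[, group_names()]) - 1) < 1e-9))
  expect_true(all(as.matrix(gc[, group_names()]) >= 0))
})

test_that("CWMs are convex averages on the native scale, logged afterwards", {
  sp <- toy_species()
  ## single species: CWM is that species' value
  cwm <- community_weighted_means(toy_comp("tree_d", 1), sp, c("H", "LMA"),
                                  group = "deciduous")
  expect_equal(unname(cwm["p1", "H"]), log(12))
  ## two species averaged on the native scale
  sp2 <- data.frame(taxon = c("a", "b"), growth_form = "herb",
                    H = c(exp(1), exp(3)))
  sp2 <- classify_groups(sp2)
  comp <- toy_comp(c("a", "b"), c(0.5, 0.5))
  cwm <- community_weighted_means(comp, sp2, "H", group = "nonwoody")
  expect_equal(unname(cwm[1, "H"]), log((exp(1) + exp(3)) / 2))
  ## mean-of-logs convention under the switch
  cwm_l <- community_weighted_means(comp, sp2, "H", group = "nonwoody",
                                    log_first = TRUE)
  expect_equal(unname(cwm_l[1, "H"]), 2)
  ## convexity: CWM bounded by contributing species values
  set.seed(5)
  spv <- data.frame(taxon = letters[1:6], growth_form = "herb",
                    H = runif(6, 0.1, 30))
  spv <- classify_groups(spv)
  w <- rgamma(6, 1); w <- w / sum(w)
  cwm <- community_weighted_means(toy_comp(letters[1:6], w), spv, "H")
  expect_gte(exp(cwm[1, "H"]), min(spv$H))
  expect_lte(exp(cwm[1, "H"]), max(spv$H))
  ## constant trait: CWM is that constant regardless of abundances
  spv$H <- 4.2
  cwm <- community_weighted_means(toy_comp(letters[1:6], rev(sort(w))),
                                  spv, "H")
  expect_equal(unname(cwm[1, "H"]), log(4.2))
})

test_that("weights renormalize over taxa with trait data, per trait", {
  sp <- data.frame(taxon = c("a", "b", "c"), growth_form = "herb",
                   H = c(2, NA, 6), LMA = c(0.1, 0.2, 0.3))
  sp <- classify_groups(sp)
  comp <- toy_comp(c("a", "b", "c"), c(0.5, 0.3, 0.2))
  cwm <- community_weighted_means(comp, sp, c("H", "LMA"))
  ## H: weights renormalize over a and c only
  expect_equal(unname(cwm[1, "H"]), log((0.5 * 2 + 0.2 * 6) / 0.7))
  expect_equal(unname(cwm[1, "LMA"]),
               log(0.5 * 0.1 + 0.3 * 0.2 + 0.2 * 0.3))
})

test_that("non-positive values require a configured offset", {
  sp <- data.frame(taxon = c("a", "b"), growth_form = "herb",
                   d15N = c(-3, 1))
  sp <- classify_groups(sp)
  comp <- toy_comp(c("a", "b"), c(0.5, 0.5))
  expect_error(community_weighted_means(comp, sp, "d15N"),
               "offset")
  cwm <- community_weighted_means(comp, sp, "d15N",
                                  offsets = c(d15N = 10))
  expect_equal(unname(cwm[1, "d15N"]), log(-1 + 10))
})

test_that("standardization gives exact z-scores and is idempotent", {
  expect_equal(unname(standardize(cbind(x = c(1, 2, 3)))[, 1]),
               c(-1, 0, 1))
  m <- matrix(rnorm(60), 20, 3, dimnames = list(NULL, c("a", "b", "c")))
  s <- standardize(m)
  expect_equal(unname(colMeans(s)), rep(0, 3), tolerance = 1e-10)
  expect_equal(unname(apply(s, 2, sd)), rep(1, 3), tolerance = 1e-10)
  expect_equal(unclass(standardize(s))[, ], s[, ], tolerance = 1e-12)
  ## missing entries are excluded from moments and preserved
  m[3, 2] <- NA
  s <- standardize(m)
  expect_true(is.na(s[3, 2]))
  expect_equal(mean(s[, 2], na.rm = TRUE), 0, tolerance = 1e-10)
  expect_error(standardize(cbind(a = rep(2, 5))), "zero-variance")
})
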