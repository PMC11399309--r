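test_that("naturalness filtering removes plots on unnatural pixels", {
  ## 2 x 2 land cover: forest | urban / grassland | water
  lc <- toy_landcover(matrix(c(50, 130, 190, 210), 2, 2))
  plots <- data.frame(plot_id = c("a", "b", "c", "d", "e"),
                      lon = c(0.5, 0.5, 1.5, 1.5, 9),
                      lat = c(1.5, 0.5, 1.5, 0.5, 0.5))
  expect_warning(kept <- filter_natural_plots(plots, lc), "outside")
  expect_equal(kept$plot_id, c("a", "b"))
  expect_equal(attr(kept, "n_removed"), 2)
  expect_equal(attr(kept, "n_outside"), 1)
})

test_that("retained share tracks the natural land fraction", {
  w <- generate_world(world_config(seed = 31, n_plots = 5000,
                                   n_species = 60,
                                   unnatural_fraction = 0.3))
  kept <- filter_natural_plots(w$plots, w$landcover)
  expect_lt(abs(nrow(kept) / nrow(w$plots) - 0.7), 0.03)
  ## agrees with the generator's own naturalness flag
  expect_setequal(kept$plot_id, w$plots$plot_id[w$plots$natural])
})

test_that("sub-class medians are componentwise, renormalized, NA when unnatural", {
  lc <- toy_landcover(matrix(c(130, 130, 130, 190), 2, 2))
  plots <- data.frame(plot_id = paste0("p", 1:4),
                      lon = c(0.2, 0.4, 0.6, 0.5),
                      lat = c(1.5, 1.5, 1.5, 0.5),
                      record_scope = c("all_vascular", "all_vascular",
                                       "all_vascular", "unspecified"))
  gcov <- data.frame(plot_id = paste0("p", 1:4),
                     nonwoody = c(0.1, 0.5, 0.9, 0.2),
                     deciduous = c(0.8, 0.3, 0.05, 0.5),
                     evergreen = c(0.1, 0.2, 0.05, 0.3))
  suppressWarnings(tab <- subclass_group_cover(plots, gcov, lc))
  row <- tab[tab$code == 130, ]
  med <- c(0.5, 0.3, 0.1)
  expect_equal(unlist(row[, group_names()], use.names = FALSE),
               med / sum(med))
  expect_equal(row$n_plots, 3)
  ## unnatural sub-classes carry NA
  expect_true(all(is.na(tab[!landcover_codes()$natural, "nonwoody"])))
  ## single-plot sub-class equals that plot; empty sub-class warns
  lc1 <- toy_landcover(matrix(c(60, 60, 60, 60), 2, 2))
  p1 <- plots[1, ]
  ws <- capture_warnings(tab1 <- subclass_group_cover(p1, gcov, lc1))
  expect_true(any(grepl("no all-vascular", ws)))
  expect_equal(unlist(tab1[tab1$code == 60, group_names()],
                      use.names = FALSE), c(0.1, 0.8, 0.1))
  ## equal medians renormalize to thirds
  gc_eq <- gcov; gc_eq[1, 2:4] <- c(0.2, 0.2, 0.2)
  suppressWarnings(tq <- subclass_group_cover(p1, gc_eq, lc1))
  expect_equal(unlist(tq[tq$code == 60, group_names()],
                      use.names = FALSE), rep(1 / 3, 3))
})

test_that("group-cover rasters block-average sub-class triples", {
  tab <- data.frame(code = c(130L, 50L),
                    nonwoody = c(1, 0), deciduous = c(0, 1),
                    evergreen = c(0, 0))
  ## uniform block
  lc <- toy_landcover(matrix(130, 4, 4), 0, 2, 0, 2)
  r <- build_group_cover_raster(lc, tab, target_resolution = 1)
  expect_equal(r$nonwoody$values, matrix(1, 2, 2))
  ## half-and-half block
  lc2 <- toy_landcover(matrix(c(130, 130, 50, 50), 2, 2), 0, 1, 0, 1)
  r2 <- build_group_cover_raster(lc2, tab, target_resolution = 1)
  expect_equal(r2$nonwoody$values[1, 1], 0.5)
  expect_equal(r2$deciduous$values[1, 1], 0.5)
  expect_equal(r2$evergreen$values[1, 1], 0)
  expect_error(build_group_cover_raster(lc, tab, target_resolution = 0.3),
               "divide")
  lc3 <- toy_landcover(matrix(999, 2, 2), 0, 1, 0, 1)
  expect_error(build_group_cover_raster(lc3, tab, 1), "unmapped")
})

test_that("world-derived group-cover rasters sum to one at valid pixels", {
  w <- small_world(n_plots = 400)
  gcov <- group_cover(w$composition, w$species)
  tab <- subclass_group_cover(w$plots, gcov, w$landcover)
  r <- build_group_cover_raster(w$landcover, tab,
                                w$config$grid_resolution)
  s <- r$nonwoody$values + r$deciduous$values + r$evergreen$values
  expect_true(all(abs(s[!is.na(s)] - 1) < 1e-6))
  expect_gt(mean(!is.na(s)), 0.5)
})

test_that("trait maps evaluate the model pointwise and propagate missingness", {
  d <- simulate_additive_gam_data(
    400, effects = list(ln_mi = function(x) x,
                        mtco = function(x) 0.1 * x,
                        mgst = function(x) 0.05 * x),
    ranges = list(ln_mi = c(-1, 1), mtco = c(-10, 10), mgst = c(0, 20)),
    noise_sd = 0.1, seed = 13)
  fit <- fit_trait_gam(d, "y")
  const <- function(v) geogrid(matrix(v, 3, 4), 0, 4, 0, 3)
  bio <- list(ln_mi = const(0.3), mtco = const(-2), mgst = const(11))
  m <- predict_trait_map(fit, bio)
  scalar <- predict(fit, data.frame(ln_mi = 0.3, mtco = -2, mgst = 11))
  expect_equal(m$values, matrix(scalar, 3, 4))
  ## a pixel without a growing season (missing MGST) is missing output
  bio$mgst$values[2, 2] <- NA
  m2 <- predict_trait_map(fit, bio)
  expect_true(is.na(m2$values[2, 2]))
  expect_equal(sum(is.na(m2$values)), 1)
  ## cropping commutes with prediction
  bioc <- lapply(bio, gg_crop, rows = 1:2, cols = 2:3)
  mc <- predict_trait_map(fit, bioc)
  expect_equal(mc$values, gg_crop(m2, 1:2, 2:3)$values)
  ## registration mismatch is reported with both grids
  bad <- bio; bad$mtco <- geogrid(matrix(0, 3, 4), 0, 4, 10, 13)
  expect_error(predict_trait_map(fit, bad), "co-registered")
  ## hull masking removes pixels outside the training climate
  bio3 <- list(ln_mi = const(5), mtco = const(-2), mgst = const(11))
  m3 <- predict_trait_map(fit, bio3, hull_mask = TRUE)
  expect_true(all(is.na(m3$values)))
})
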