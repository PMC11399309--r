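#' Default planted latent loadings
#'
#' A 6 x 2 matrix mapping the two latent, mutually orthogonal trait
#' dimensions — overall plant size and the leaf economics spectrum
#' (LES) — onto the six major log traits. Size loads plant height (H),
#' diaspore mass (DM) and leaf area (LA); the LES loads leaf mass per
#' area (LMA), area-based leaf nitrogen (Narea) and stem specific
#' density (SSD). The size dimension is planted stronger than the LES
#' so the two dimensions are identifiable from sample ordinations.
#'
#' @return numeric matrix with rownames the six traits and columns
#'   `size`, `les`; the columns are exactly orthogonal.
#' @export
default_latent_loadings <- function() {
  L <- cbind(size = c(LA = 0.9, LMA = 0, Narea = 0, SSD = 0,
                      H = 1.2, DM = 1.0),
             les = c(LA = 0, LMA = 0.5, Narea = 0.45, SSD = 0.35,
                     H = 0, DM = 0))
  stopifnot(abs(sum(L[, 1] * L[, 2])) < 1e-12)
  L
}

## log-scale intercepts giving realistic native-unit medians
## (LA mm2, LMA kg/m2, Narea g/m2, SSD g/cm3, H m, DM mg)
trait_intercepts <- function() {
  c(LA = log(1000), LMA = log(0.1), Narea = log(1.5),
    SSD = log(0.55), H = log(1.5), DM = log(1))
}

#' Planted trait-climate effect functions
#'
#' Additive smooth shifts (log scale) applied to species traits as a
#' function of the plot's bioclim triple. Each trait's effect is a list
#' of three univariate functions (`ln_mi`, `mtco`, `mgst`) whose sum is
#' the total shift, so the generative per-predictor variance shares are
#' recoverable. Defaults follow the qualitative patterns expected of
#' these traits: size traits (H, DM, LA) increase with moisture and
#' growing-season temperature, LES traits (LMA, Narea) decrease with
#' moisture. `strength` scales every effect; `zero_climate_effects()`
#' switches the climate signal off entirely.
#'
#' @param strength multiplier on all effect functions.
#' @return named list (one entry per plant group, plus identical
#'   structure reused for the pooled community) of per-trait effect
#'   lists.
#' @export
default_climate_effects <- function(strength = 1) {
  zf <- function(x) 0 * x
  eff <- function(f_mi = zf, f_mtco = zf, f_mgst = zf, s = strength) {
    list(ln_mi = function(x) s * f_mi(x),
         mtco = function(x) s * f_mtco(x),
         mgst = function(x) s * f_mgst(x))
  }
  base <- list(
    LA    = eff(function(x) 0.45 * x, function(x) 0.012 * x),
    LMA   = eff(function(x) -0.35 * x, function(x) 0.006 * x),
    Narea = eff(function(x) -0.30 * x),
    SSD   = eff(function(x) -0.10 * x, f_mgst = function(x) 0.008 * x),
    H     = eff(function(x) 0.50 * x, f_mgst = function(x) 0.045 * x),
    DM    = eff(function(x) 0.30 * x, f_mgst = function(x) 0.035 * x))
  list(nonwoody = base, deciduous = base, evergreen = base)
}

#' @rdname default_climate_effects
#' @export
zero_climate_effects <- function() default_climate_effects(strength = 0)

eval_effect <- function(eff, ln_mi, mtco, mgst) {
  eff$ln_mi(ln_mi) + eff$mtco(mtco) + eff$mgst(mgst)
}

#' Configuration of a synthetic trait-climate world
#'
#' Bundles and validates all generator settings: the spatial grid, the
#' species pool, the planted latent trait dimensions, the planted
#' trait-climate signal, community-assembly settings and the land-cover
#' mosaic.
#'
#' @param seed integer seed; the whole world is a deterministic
#'   function of the configuration.
#' @param n_species,n_plots pool and sample sizes.
#' @param extent lon/lat bounding box `c(xmin, xmax, ymin, ymax)`,
#'   degrees.
#' @param grid_resolution coarse (climate/prediction) cell size,
#'   degrees.
#' @param fine_factor land-cover cells per coarse cell per axis.
#' @param group_mix species-pool fractions of the three plant groups
#'   (non-woody, woody deciduous, woody evergreen); must sum to 1.
#' @param latent_loadings 6 x 2 loadings of the planted orthogonal
#'   (size, LES) dimensions, or a per-group list of such matrices.
#' @param climate_effects per-group, per-trait additive effect lists;
#'   see [default_climate_effects].
#' @param noise_sd standard deviation of species-level log-trait
#'   residual noise.
#' @param unnatural_fraction fraction of fine land-cover pixels given
#'   non-vegetation classes (cropland/urban/bare/water/snow).
#' @param richness_range min/max taxa per plot.
#' @param cover_concentration Dirichlet concentration of within-plot
#'   relative covers (1 = typical uneven covers).
#' @param minority_fraction fraction of species given minority growth
#'   forms (ferns etc.; excluded from group analyses).
#' @param mixed_fraction fraction of species given the mixed-probability
#'   growth form exercising probabilistic group membership.
#' @param subclass_concentration Dirichlet concentration tying a plot's
#'   group cover to its land-cover sub-class mixture.
#' @return validated list of class `world_config`.
#' @export
world_config <- function(seed = 1L, n_species = 400L, n_plots = 1000L,
                         extent = c(0, 40, 20, 60),
                         grid_resolution = 1, fine_factor = 4L,
                         group_mix = c(nonwoody = 0.4, deciduous = 0.3,
                                       evergreen = 0.3),
                         latent_loadings = default_latent_loadings(),
                         climate_effects = default_climate_effects(),
                         noise_sd = 0.2, unnatural_fraction = 0.1,
                         richness_range = c(5L, 20L),
                         cover_concentration = 1,
                         minority_fraction = 0.05,
                         mixed_fraction = 0.05,
                         subclass_concentration = 30) {
  if (n_species < 10 || n_plots < 1)
    stop("world_config: n_species/n_plots too small")
  if (grid_resolution <= 0)
    stop("world_config: grid_resolution must be > 0")
  if (noise_sd < 0) stop("world_config: noise_sd must be >= 0")
  if (abs(sum(group_mix) - 1) > 1e-12)
    stop("world_config: group_mix must sum to 1")
  if (unnatural_fraction < 0 || unnatural_fraction > 1)
    stop("world_config: unnatural_fraction must be in [0, 1]")
  if (!is.list(latent_loadings))
    latent_loadings <- list(nonwoody = latent_loadings,
                            deciduous = latent_loadings,
                            evergreen = latent_loadings)
  nx <- (extent[2] - extent[1]) / grid_resolution
  ny <- (extent[4] - extent[3]) / grid_resolution
  if (abs(nx - round(nx)) > 1e-9 || abs(ny - round(ny)) > 1e-9)
    stop("world_config: extent must be a whole number of cells")
  structure(list(seed = as.integer(seed), n_species = as.integer(n_species),
                 n_plots = as.integer(n_plots), extent = extent,
                 grid_resolution = grid_resolution,
                 fine_factor = as.integer(fine_factor),
                 group_mix = group_mix, latent_loadings = latent_loadings,
                 climate_effects = climate_effects, noise_sd = noise_sd,
                 unnatural_fraction = unnatural_fraction,
                 richness_range = richness_range,
                 cover_concentration = cover_concentration,
                 minority_fraction = minority_fraction,
                 mixed_fraction = mixed_fraction,
                 subclass_concentration = subclass_concentration),
            class = "world_config")
}

#' Land-cover code table of the synthetic world
#'
#' Integer sub-class codes in the style of a global land-cover product:
#' natural vegetation sub-classes carry a generative mixture of the
#' three plant groups; cropland, urban, bare, water and permanent
#' snow/ice sub-classes are flagged unnatural and carry no mixture.
#'
#' @return data.frame with columns `code`, `class`, `subclass`,
#'   `natural`, `mix_nonwoody`, `mix_deciduous`, `mix_evergreen`.
#' @export
landcover_codes <- function() {
  data.frame(
    code = c(50L, 60L, 70L, 80L, 100L, 120L, 130L, 150L, 180L,
             10L, 20L, 190L, 200L, 210L, 220L),
    class = c(rep("forest", 4), "mosaic", "shrubland", "grassland",
              "sparse", "wetland", "cropland", "cropland", "urban",
              "bare", "water", "snow_ice"),
    subclass = c("broadleaf_evergreen", "broadleaf_deciduous",
                 "needleleaf_evergreen", "needleleaf_deciduous",
                 "tree_shrub_herb", "shrubland", "grassland",
                 "sparse_vegetation", "herbaceous_wetland",
                 "rainfed", "irrigated", "urban", "bare", "water",
                 "permanent_snow_ice"),
    natural = c(rep(TRUE, 9), rep(FALSE, 6)),
    mix_nonwoody  = c(0.05, 0.10, 0.10, 0.10, 0.45, 0.30, 0.85, 0.70,
                      0.80, rep(NA, 6)),
    mix_deciduous = c(0.10, 0.80, 0.15, 0.75, 0.30, 0.35, 0.08, 0.15,
                      0.10, rep(NA, 6)),
    mix_evergreen = c(0.85, 0.10, 0.75, 0.15, 0.25, 0.35, 0.07, 0.15,
                      0.10, rep(NA, 6)))
}

#' Generate monthly climate fields
#'
#' Deterministic, spatially smooth monthly temperature, precipitation
#' and shortwave radiation on the coarse grid: low-order harmonics in
#' longitude plus latitudinal gradients. The seasonal temperature cycle
#' has an amplitude that increases with absolute latitude (flipping
#' phase across the equator) and precipitation is clamped at zero.
#'
#' @param config a [world_config].
#' @return a [monthly_climate_grid] with `tas` (degC), `pr` (mm) and
#'   `srad` (kJ/m2).
#' @export
generate_monthly_climate <- function(config) {
  e <- config$extent; res <- config$grid_resolution
  nc <- round((e[2] - e[1]) / res); nr <- round((e[4] - e[3]) / res)
  lon <- e[1] + (seq_len(nc) - 0.5) * res
  lat <- e[4] - (seq_len(nr) - 0.5) * res
  LON <- matrix(lon, nr, nc, byrow = TRUE)
  LAT <- matrix(lat, nr, nc)
  hemi <- ifelse(LAT >= 0, 1, -1)
  u <- 2 * pi * (LON - e[1]) / (e[2] - e[1])
  tas <- pr <- srad <- array(NA_real_, c(nr, nc, 12))
  amp_t <- 2 + 16 * abs(LAT) / 90            # seasonal amplitude, degC
  t_ann <- 26 - 0.45 * abs(LAT) + 2 * sin(u) # annual mean, degC
  p_base <- 15 + 95 * (1 + sin(u + 0.8)) / 2 +
    25 * exp(-((abs(LAT) - 45) / 15)^2)      # mm / month
  s_ann <- pmax(520 - 3.5 * abs(LAT), 50) * 1000  # kJ / m2 / month
  for (m in 1:12) {
    ph <- cos(2 * pi * (m - 7) / 12)
    tas[, , m] <- t_ann + amp_t * ph * hemi
    pr[, , m] <- pmax(p_base * (1 + 0.5 * cos(2 * pi * (m - 2) / 12)), 0)
    srad[, , m] <- pmax(s_ann + 260000 * cos(2 * pi * (m - 6.5) / 12) *
                          hemi, 20000)
  }
  monthly_climate_grid(tas, pr, srad = srad, xmin = e[1], xmax = e[2],
                       ymin = e[3], ymax = e[4])
}

#' Generate the land-cover mosaic
#'
#' Fine-resolution integer sub-class codes. Approximately
#' `unnatural_fraction` of pixels receive unnatural codes; natural
#' pixels draw a vegetation sub-class with probabilities that shift
#' along the latitudinal (thermal) gradient, producing a zoned but
#' mottled mosaic.
#'
#' @param config a [world_config].
#' @return a [geogrid] of integer codes with the code table attached as
#'   attribute `codes`.
#' @export
generate_landcover <- function(config) {
  e <- config$extent
  res <- config$grid_resolution / config$fine_factor
  nc <- round((e[2] - e[1]) / res); nr <- round((e[4] - e[3]) / res)
  lat <- e[4] - (seq_len(nr) - 0.5) * res
  codes <- landcover_codes()
  set.seed(config$seed + 1L)
  unnat <- matrix(stats::runif(nr * nc) < config$unnatural_fraction, nr, nc)
  out <- matrix(NA_real_, nr, nc)
  uncodes <- codes$code[!codes$natural]
  out[unnat] <- sample(uncodes, sum(unnat), replace = TRUE)
  ## natural sub-class probabilities vary with the thermal gradient
  natc <- codes[codes$natural, ]
  warmth <- (max(abs(lat)) - abs(lat)) / max(diff(range(abs(lat))), 1)
  for (i in seq_len(nr)) {
    w <- warmth[i]
    pw <- c(broadleaf_evergreen = 1.5 * w^2, broadleaf_deciduous = 1.2 * w,
            needleleaf_evergreen = 1.2 * (1 - w),
            needleleaf_deciduous = 0.8 * (1 - w)^2,
            tree_shrub_herb = 0.6, shrubland = 0.5,
            grassland = 0.8, sparse_vegetation = 0.4 * (1 - w),
            herbaceous_wetland = 0.2)
    pw <- pw[natc$subclass]
    free <- which(!unnat[i, ])
    if (length(free))
      out[i, free] <- sample(natc$code, length(free), replace = TRUE,
                             prob = pw)
  }
  g <- geogrid(out, e[1], e[2], e[3], e[4], name = "landcover")
  attr(g, "codes") <- codes
  g
}

## minority growth forms present in the pool
minority_forms <- c("fern", "palm", "bamboo", "succulent")

#' Generate a complete synthetic world
#'
#' Builds the full synthetic data set the pipeline consumes: a species
#' pool with traits generated from two orthogonal latent dimensions, a
#' smooth monthly climate, a land-cover mosaic, vegetation plots whose
#' composition follows the local land-cover sub-class, realized
#' per-plot species trait values carrying the planted climate signal,
#' and ground-truth surfaces for recovery tests.
#'
#' Species base log-traits are `intercept + loadings %*% factors +
#' noise`; the realized trait of a species in a plot additionally
#' receives its group's climate shift evaluated at the plot's pixel.
#'
#' @param config a [world_config].
#' @return object of class `synthetic_world`: `config`, `species`
#'   (pool with growth forms, group probabilities and native-unit
#'   traits), `plots` (metadata with coordinates, record scope,
#'   naturalness and bioclim values), `composition` (long relative
#'   covers), `plot_traits` (realized native-unit trait values per plot
#'   and taxon), `climate`, `bioclim`, `landcover`, `form_table`, and
#'   `truth` (species log traits, per-plot expected log-CWMs per group,
#'   per-pixel trait surfaces, generative importance shares).
#' @export
generate_world <- function(config) {
  if (!inherits(config, "world_config"))
    stop("generate_world: config must be a world_config")
  traits <- rownames(config$latent_loadings[[1]])
  mu <- trait_intercepts()[traits]
  climate <- generate_monthly_climate(config)
  bc <- bioclim_grid(climate)
  landcover <- generate_landcover(config)
  codes <- attr(landcover, "codes")
  groups <- group_cols

  ## ---- species pool ----
  set.seed(config$seed + 2L)
  ns <- config$n_species
  grp <- sample(groups, ns, replace = TRUE, prob = config$group_mix)
  form_of <- c(nonwoody = "herb", deciduous = "tree-deciduous",
               evergreen = "tree-evergreen")
  form <- form_of[grp]
  r <- stats::runif(ns)
  mixed <- r < config$mixed_fraction
  minority <- r >= config$mixed_fraction &
    r < config$mixed_fraction + config$minority_fraction
  form[mixed] <- "shrub-intermediate"
  form[minority] <- sample(minority_forms, sum(minority), replace = TRUE)
  z <- matrix(stats::rnorm(ns * 2), ns, 2)
  base_log <- matrix(NA_real_, ns, length(traits),
                     dimnames = list(NULL, traits))
  for (g in groups) {
    i <- grp == g
    base_log[i, ] <- z[i, , drop = FALSE] %*%
      t(config$latent_loadings[[g]])
  }
  base_log <- base_log + matrix(stats::rnorm(ns * length(traits),
                                             sd = config$noise_sd),
                                ns, length(traits))
  base_log <- sweep(base_log, 2, mu, "+")
  taxa <- sprintf("sp%04d", seq_len(ns))
  form_table <- growth_form_table(extra = data.frame(
    growth_form = "shrub-intermediate", p_nonwoody = 0.5,
    p_deciduous = 0.25, p_evergreen = 0.25))
  species <- data.frame(taxon = taxa, growth_form = unname(form))
  species <- classify_groups(species, form_table)
  species <- cbind(species, exp(base_log))

  ## ---- plots and composition ----
  set.seed(config$seed + 3L)
  np <- config$n_plots
  e <- config$extent
  plon <- stats::runif(np, e[1], e[2])
  plat <- stats::runif(np, e[3], e[4])
  pcode <- gg_extract(landcover, plon, plat)
  cm <- match(pcode, codes$code)
  natural <- codes$natural[cm]
  scope <- sample(c("all_vascular", "unspecified"), np, replace = TRUE,
                  prob = c(0.7, 0.3))
  pbio <- data.frame(ln_mi = gg_extract(bc$ln_mi, plon, plat),
                     mtco = gg_extract(bc$mtco, plon, plat),
                     mgst = gg_extract(bc$mgst, plon, plat))
  pool <- split(seq_len(ns), grp)
  mixmat <- as.matrix(codes[, c("mix_nonwoody", "mix_deciduous",
                                "mix_evergreen")])
  rich <- config$richness_range
  comp_plot <- comp_taxon <- vector("list", np)
  comp_cover <- vector("list", np)
  for (p in seq_len(np)) {
    mix <- mixmat[cm[p], ]
    if (anyNA(mix)) mix <- config$group_mix
    target <- stats::rgamma(3, shape = config$subclass_concentration * mix)
    target <- target / sum(target)
    repeat {
      S <- sample(seq(rich[1], rich[2]), 1)
      gsel <- sample(groups, S, replace = TRUE, prob = target)
      idx <- vapply(gsel, function(g) sample(pool[[g]], 1), integer(1))
      if (!all(species$omitted[idx])) break
    }
    dup <- duplicated(idx)
    idx <- idx[!dup]
    w <- stats::rgamma(length(idx), shape = config$cover_concentration)
    w <- w / sum(w)
    comp_plot[[p]] <- rep(p, length(idx))
    comp_taxon[[p]] <- taxa[idx]
    comp_cover[[p]] <- w
  }
  plot_ids <- sprintf("plot%05d", seq_len(np))
  composition <- data.frame(
    plot_id = plot_ids[unlist(comp_plot)],
    taxon = unlist(comp_taxon),
    rel_cover = unlist(comp_cover))
  plots <- data.frame(plot_id = plot_ids, lon = plon, lat = plat,
                      record_scope = scope,
                      landcover_code = pcode,
                      natural = natural, pbio)

  ## ---- realized per-plot traits (base + climate shift) ----
  prow <- match(composition$plot_id, plot_ids)
  srow <- match(composition$taxon, taxa)
  shift <- matrix(0, nrow(composition), length(traits),
                  dimnames = list(NULL, traits))
  sgrp <- grp[srow]
  for (g in groups) {
    sel <- sgrp == g
    if (!any(sel)) next
    for (t in traits) {
      eff <- config$climate_effects[[g]][[t]]
      shift[sel, t] <- eval_effect(eff, pbio$ln_mi[prow[sel]],
                                   pbio$mtco[prow[sel]],
                                   pbio$mgst[prow[sel]])
    }
  }
  realized_log <- base_log[srow, , drop = FALSE] + shift
  ## group-probability columns so plot_traits can stand alone as a
  ## plot-local species table
  plot_traits <- cbind(
    data.frame(plot_id = composition$plot_id, taxon = composition$taxon,
               growth_form = species$growth_form[srow]),
    species[srow, c("p_nonwoody", "p_deciduous", "p_evergreen",
                    "omitted")],
    exp(realized_log))
  rownames(plot_traits) <- NULL

  ## ---- ground truth ----
  pmat <- as.matrix(species[srow, c("p_nonwoody", "p_deciduous",
                                    "p_evergreen")])
  probs <- cbind(pmat, all = pmin(rowSums(pmat), 1))
  colnames(probs) <- c(groups, "all")
  truth_cwm <- list()
  for (gl in colnames(probs)) {
    w0 <- composition$rel_cover * probs[, gl]
    cwm <- matrix(NA_real_, np, length(traits),
                  dimnames = list(plot_ids, traits))
    wsum <- rowsum(w0, prow)
    for (t in traits) {
      num <- rowsum(w0 * exp(realized_log[, t]), prow)
      v <- num / wsum
      v[wsum <= 0] <- NA_real_
      cwm[as.integer(rownames(wsum)), t] <- log(v)
    }
    truth_cwm[[gl]] <- cwm
  }

  ## per-pixel surfaces: climate shift at the pixel plus the mean
  ## plot-level composition constant (per group and trait)
  surfaces <- list()
  gen_importance <- list()
  for (gl in colnames(probs)) {
    gref <- if (gl == "all") "nonwoody" else gl
    surfaces[[gl]] <- list()
    imp <- matrix(NA_real_, length(traits), 3,
                  dimnames = list(traits, c("ln_mi", "mtco", "mgst")))
    for (t in traits) {
      eff <- config$climate_effects[[gref]][[t]]
      plot_shift <- eval_effect(eff, pbio$ln_mi, pbio$mtco, pbio$mgst)
      cc <- mean(truth_cwm[[gl]][, t] - plot_shift, na.rm = TRUE)
      vals <- eval_effect(eff, bc$ln_mi$values, bc$mtco$values,
                          bc$mgst$values) + cc
      surfaces[[gl]][[t]] <- geogrid(vals, e[1], e[2], e[3], e[4],
                                     name = paste0(gl, "_", t))
      comp_var <- c(stats::var(eff$ln_mi(pbio$ln_mi)),
                    stats::var(eff$mtco(pbio$mtco)),
                    stats::var(eff$mgst(pbio$mgst)))
      imp[t, ] <- if (sum(comp_var) > 0) 100 * comp_var / sum(comp_var)
                  else NA_real_
    }
    gen_importance[[gl]] <- imp
  }

  structure(list(config = config, species = species, plots = plots,
                 composition = composition, plot_traits = plot_traits,
                 climate = climate, bioclim = bc, landcover = landcover,
                 form_table = form_table,
                 truth = list(species_log = base_log,
                              species_group = grp,
                              plot_cwm = truth_cwm,
                              surface = surfaces,
                              importance = gen_importance)),
            class = "synthetic_world")
}

#' @export
print.synthetic_world <- function(x, ...) {
  cat(sprintf("synthetic world: %d species, %d plots, %d x %d pixels\n",
              nrow(x$species), nrow(x$plots),
              nrow(x$bioclim$ln_mi$values), ncol(x$bioclim$ln_mi$values)))
  invisible(x)
}

#' Simulate a controlled additive trait-climate data set
#'
#' Draws independent uniform predictors and builds a response as the
#' sum of supplied univariate effect functions plus Gaussian noise.
#' Used for controlled recovery experiments (surface recovery,
#' predictor-importance recovery) where the planted signal must be
#' known in closed form.
#'
#' @param n number of observations.
#' @param effects named list of univariate functions, one per
#'   predictor; names become the predictor columns.
#' @param ranges named list of `c(min, max)` sampling ranges.
#' @param noise_sd residual standard deviation.
#' @param seed integer seed.
#' @return data.frame with the predictors, per-effect signal columns
#'   (`signal_<name>`), the total `signal` and the noisy response `y`.
#' @export
simulate_additive_gam_data <- function(n, effects, ranges, noise_sd,
                                       seed = 1L) {
  set.seed(seed)
  stopifnot(identical(sort(names(effects)), sort(names(ranges))))
  out <- data.frame(row.names = seq_len(n))
  sig <- 0
  for (nm in names(effects)) {
    x <- stats::runif(n, ranges[[nm]][1], ranges[[nm]][2])
    out[[nm]] <- x
    out[[paste0("signal_", nm)]] <- effects[[nm]](x)
    sig <- sig + out[[paste0("signal_", nm)]]
  }
  out$signal <- sig
  out$y <- sig + stats::rnorm(n, sd = noise_sd)
  out
}

#' Write a synthetic world to plain-text files
#'
#' Species table, plot table, composition and realized plot traits as
#' TSV; climate layers, bioclim variables, land cover and truth
#' surfaces as ESRI ASCII grids.
#'
#' @param world a [generate_world] result.
#' @param dir output directory (created if needed).
#' @return `dir`, invisibly.
#' @export
write_world <- function(world, dir) {
  dir.create(dir, recursive = TRUE, showWarnings = FALSE)
  write_tsv_table(world$species, file.path(dir, "species.tsv"))
  write_tsv_table(world$plots, file.path(dir, "plots.tsv"))
  write_tsv_table(world$composition, file.path(dir, "composition.tsv"))
  write_tsv_table(world$plot_traits, file.path(dir, "plot_traits.tsv"))
  write_tsv_table(attr(world$landcover, "codes"),
                  file.path(dir, "landcover_codes.tsv"))
  write_asc(world$landcover, file.path(dir, "landcover.asc"))
  for (nm in names(world$bioclim))
    write_asc(world$bioclim[[nm]], file.path(dir, paste0(nm, ".asc")))
  for (m in 1:12) {
    write_asc(climate_layer(world$climate, "tas", m),
              file.path(dir, sprintf("tas_%02d.asc", m)))
    write_asc(climate_layer(world$climate, "pr", m),
              file.path(dir, sprintf("pr_%02d.asc", m)))
  }
  invisible(dir)
}
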