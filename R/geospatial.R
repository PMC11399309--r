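#' Remove plots on unnatural land cover
#'
#' Looks up each plot's land-cover sub-class at the fine land-cover
#' pixel containing it and drops plots on unnatural classes (cropland,
#' urban, bare, water, permanent snow/ice). Plots outside the raster
#' extent are also excluded, with a warning.
#'
#' @param plots data.frame with `plot_id`, `lon`, `lat`.
#' @param landcover land-cover [geogrid] with a `codes` attribute (see
#'   [landcover_codes]).
#' @return the retained rows of `plots`, with attributes `n_removed`
#'   (unnatural) and `n_outside`.
#' @export
filter_natural_plots <- function(plots, landcover) {
  codes <- attr(landcover, "codes")
  if (is.null(codes))
    stop("filter_natural_plots: landcover carries no code table")
  code <- gg_extract(landcover, plots$lon, plots$lat)
  outside <- is.na(code)
  if (any(outside))
    warning("filter_natural_plots: ", sum(outside),
            " plot(s) outside the land-cover extent were excluded")
  m <- match(code, codes$code)
  if (any(!outside & is.na(m)))
    stop("filter_natural_plots: land-cover codes missing from table: ",
         paste(unique(code[!outside & is.na(m)]), collapse = ", "))
  natural <- !outside & codes$natural[m]
  out <- plots[natural, , drop = FALSE]
  attr(out, "n_removed") <- sum(!natural & !outside)
  attr(out, "n_outside") <- sum(outside)
  out
}

#' Median plant-group cover per land-cover sub-class
#'
#' Restricted to plots recording all vascular plants, computes for each
#' land-cover sub-class the componentwise median of the plots' group
#' coverage triples, renormalized to sum to one (componentwise medians
#' need not). Unnatural sub-classes get `NA`; natural sub-classes with
#' no qualifying plot get `NA` with a warning.
#'
#' @param plots data.frame with `plot_id`, `lon`, `lat`,
#'   `record_scope`.
#' @param group_covers data.frame from [group_cover] for (at least)
#'   those plots.
#' @param landcover land-cover [geogrid] with `codes` attribute.
#' @return data.frame: `code`, `subclass`, `nonwoody`, `deciduous`,
#'   `evergreen`, `n_plots`.
#' @export
subclass_group_cover <- function(plots, group_covers, landcover) {
  codes <- attr(landcover, "codes")
  keep <- plots$record_scope == "all_vascular"
  plots <- plots[keep, , drop = FALSE]
  code <- gg_extract(landcover, plots$lon, plots$lat)
  gc <- group_covers[match(plots$plot_id, group_covers$plot_id), ,
                     drop = FALSE]
  out <- data.frame(code = codes$code, subclass = codes$subclass,
                    nonwoody = NA_real_, deciduous = NA_real_,
                    evergreen = NA_real_, n_plots = 0L)
  for (i in seq_len(nrow(codes))) {
    if (!codes$natural[i]) next
    sel <- which(code == codes$code[i] & !is.na(gc$nonwoody))
    out$n_plots[i] <- length(sel)
    if (length(sel) == 0) {
      warning("subclass_group_cover: no all-vascular plots in sub-class ",
              codes$subclass[i])
      next
    }
    med <- vapply(group_cols, function(g) stats::median(gc[[g]][sel]),
                  numeric(1))
    out[i, group_cols] <- med / sum(med)
  }
  out
}

#' Fractional plant-group cover raster from land cover
#'
#' Replaces each fine land-cover pixel by its sub-class group-cover
#' triple and block-averages to the target resolution over valid
#' (natural, mapped) fine pixels. Coarse pixels with no valid fine
#' pixel are missing.
#'
#' @param landcover land-cover [geogrid] with `codes` attribute.
#' @param subclass_table data.frame from [subclass_group_cover] (or the
#'   generative `mix_*` columns of [landcover_codes] renamed to the
#'   group columns).
#' @param target_resolution coarse cell size, degrees; the fine
#'   resolution must divide it.
#' @return named list of three [geogrid]s (`nonwoody`, `deciduous`,
#'   `evergreen`); at every valid pixel the three bands sum to 1.
#' @export
build_group_cover_raster <- function(landcover, subclass_table,
                                     target_resolution) {
  res <- gg_res(landcover)[1]
  fact <- target_resolution / res
  if (abs(fact - round(fact)) > 1e-9)
    stop("build_group_cover_raster: fine resolution does not divide ",
         "the target resolution")
  code <- landcover$values
  m <- match(code, subclass_table$code)
  if (any(!is.na(code) & is.na(m)))
    stop("build_group_cover_raster: unmapped land-cover codes: ",
         paste(sort(unique(code[!is.na(code) & is.na(m)])),
               collapse = ", "))
  out <- lapply(group_cols, function(g) {
    v <- subclass_table[[g]][m]
    fine <- geogrid(matrix(v, nrow(code), ncol(code)),
                    landcover$xmin, landcover$xmax, landcover$ymin,
                    landcover$ymax, name = g)
    gg_aggregate(fine, round(fact))
  })
  names(out) <- group_cols
  out
}

#' Predict a trait map from a fitted trait-climate model
#'
#' Evaluates a fitted GAM on co-registered predictor rasters,
#' propagating missing values (a pixel missing any predictor — e.g. no
#' growing season, hence no MGST — is missing in the output).
#' Optionally masks pixels whose bioclim triple falls outside the
#' convex hull of the training data.
#'
#' @param fit a [fit_trait_gam] result.
#' @param bioclim named list of [geogrid]s covering the fit's
#'   predictors (e.g. `ln_mi`, `mtco`, `mgst`).
#' @param cover optional named list of [geogrid]s for cover-fraction
#'   covariates used by the fit.
#' @param hull_mask if `TRUE`, mask pixels outside the 3-D convex hull
#'   of `observed` (default: the model's training predictor triples).
#' @param observed optional matrix/data.frame of training bioclim
#'   triples for the hull.
#' @return a [geogrid] of predicted natural-log trait values with the
#'   trait name as layer name.
#' @export
predict_trait_map <- function(fit, bioclim, cover = NULL,
                              hull_mask = FALSE, observed = NULL) {
  layers <- c(bioclim, cover)
  need <- c(fit$spec$predictors, fit$spec$interactions)
  miss <- setdiff(need, names(layers))
  if (length(miss))
    stop("predict_trait_map: missing predictor raster(s): ",
         paste(miss, collapse = ", "))
  ref <- layers[[need[1]]]
  for (nm in need) {
    g <- layers[[nm]]
    if (!identical(dim(g$values), dim(ref$values)) ||
        any(abs(c(g$xmin - ref$xmin, g$xmax - ref$xmax,
                  g$ymin - ref$ymin, g$ymax - ref$ymax)) > 1e-9))
      stop("predict_trait_map: raster '", nm, "' is not co-registered ",
           "with '", need[1], "' (", nrow(g$values), "x", ncol(g$values),
           " [", g$xmin, ",", g$xmax, "]x[", g$ymin, ",", g$ymax,
           "] vs ", nrow(ref$values), "x", ncol(ref$values), " [",
           ref$xmin, ",", ref$xmax, "]x[", ref$ymin, ",", ref$ymax, "])")
  }
  nd <- as.data.frame(lapply(layers[need], function(g) as.vector(g$values)))
  ok <- stats::complete.cases(nd)
  if (hull_mask) {
    if (is.null(observed)) {
      mf <- fit$model$model
      observed <- mf[, fit$spec$predictors]
    }
    hull <- convex_hull_3d(as.matrix(observed[, fit$spec$predictors]))
    ok <- ok & in_hull(hull, as.matrix(nd[, fit$spec$predictors]))
  }
  pred <- rep(NA_real_, nrow(nd))
  if (any(ok)) pred[ok] <- predict(fit, nd[ok, , drop = FALSE])
  geogrid(matrix(pred, nrow(ref$values), ncol(ref$values)),
          ref$xmin, ref$xmax, ref$ymin, ref$ymax,
          name = fit$spec$response)
}
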