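#' Regrid a trait map to a coarser resolution
#'
#' Default method: valid-pixel block-mean aggregation by the integer
#' coarsening factor, with a coarse pixel kept only when at least
#' `min_valid` of its fine pixels are valid; if the target grid is not
#' an integer multiple of the source, aggregation to the nearest
#' coarser multiple is followed by bilinear alignment onto the target
#' cell centers. `method = "bilinear"` instead resamples the source
#' bilinearly at the target centers (the literal reading of
#' interpolation-based reprojection), which subsamples rather than
#' averages at strong coarsenings.
#'
#' @param map a [geogrid].
#' @param target_resolution target cell size, degrees; must not be
#'   finer than the source.
#' @param method `"block_bilinear"` (default) or `"bilinear"`.
#' @param min_valid minimum valid fine-pixel fraction per coarse pixel.
#' @return a [geogrid] at the target resolution over the same extent.
#' @export
regrid <- function(map, target_resolution,
                   method = c("block_bilinear", "bilinear"),
                   min_valid = 0.5) {
  method <- match.arg(method)
  res <- gg_res(map)
  if (abs(res[1] - res[2]) > 1e-9)
    stop("regrid: source cells must be square")
  if (target_resolution < res[1] - 1e-12)
    stop("regrid: target resolution is finer than the source; ",
         "only coarsening is supported")
  if (abs(target_resolution - res[1]) < 1e-12) return(map)
  ratio <- target_resolution / res[1]
  nx <- (map$xmax - map$xmin) / target_resolution
  ny <- (map$ymax - map$ymin) / target_resolution
  if (abs(nx - round(nx)) > 1e-9 || abs(ny - round(ny)) > 1e-9)
    stop("regrid: extent is not a whole number of target cells")
  nx <- round(nx); ny <- round(ny)
  if (method == "bilinear") {
    lon <- map$xmin + (seq_len(nx) - 0.5) * target_resolution
    lat <- map$ymax - (seq_len(ny) - 0.5) * target_resolution
    v <- gg_bilinear(map, rep(lon, each = ny), rep(lat, times = nx))
    return(geogrid(matrix(v, ny, nx), map$xmin, map$xmax, map$ymin,
                   map$ymax, name = map$name))
  }
  if (abs(ratio - round(ratio)) < 1e-9)
    return(gg_aggregate(map, round(ratio), min_valid = min_valid))
  ## non-integer ratio: aggregate by the largest factor that divides
  ## the grid, then align bilinearly onto the target centers
  fact <- max(1, floor(ratio))
  while (fact > 1 && (nrow(map$values) %% fact != 0 ||
                      ncol(map$values) %% fact != 0))
    fact <- fact - 1
  agg <- gg_aggregate(map, fact, min_valid = min_valid)
  lon <- map$xmin + (seq_len(nx) - 0.5) * target_resolution
  lat <- map$ymax - (seq_len(ny) - 0.5) * target_resolution
  v <- gg_bilinear(agg, rep(lon, each = ny), rep(lat, times = nx))
  geogrid(matrix(v, ny, nx), map$xmin, map$xmax, map$ymin, map$ymax,
          name = map$name)
}

#' Pixel-by-pixel agreement between two trait maps
#'
#' Over jointly valid pixels of two co-registered maps, regresses the
#' observed map on the predicted map by ordinary least squares and
#' reports: `r2` (squared Pearson correlation), `rrmse`
#' (root-mean-square error as a proportion of the observed mean),
#' `bias` (observed mean minus predicted mean, as a proportion of the
#' observed mean) and `slope` (of observed on predicted).
#'
#' @param predicted,observed co-registered [geogrid]s on the same
#'   value scale (conventionally natural-log trait values).
#' @return object of class `map_comparison`: list with `r2`, `rrmse`,
#'   `bias`, `slope`, `intercept`, `n_pixels`.
#' @export
compare_maps <- function(predicted, observed) {
  if (!identical(dim(predicted$values), dim(observed$values)))
    stop("compare_maps: maps are not co-registered (different grids)")
  p <- as.vector(predicted$values); o <- as.vector(observed$values)
  ok <- !is.na(p) & !is.na(o)
  if (!any(ok) && (any(!is.na(p)) || any(!is.na(o))))
    stop("compare_maps: valid masks are disjoint; no overlapping pixels")
  if (sum(ok) < 3)
    stop("compare_maps: need at least 3 jointly valid pixels, got ",
         sum(ok))
  p <- p[ok]; o <- o[ok]
  if (mean(o) == 0)
    stop("compare_maps: observed mean is zero; rrmse and bias undefined")
  fit <- stats::lm(o ~ p)
  structure(list(
    r2 = stats::cor(o, p)^2,
    rrmse = sqrt(mean((o - p)^2)) / mean(o),
    bias = (mean(o) - mean(p)) / mean(o),
    slope = unname(stats::coef(fit)[2]),
    intercept = unname(stats::coef(fit)[1]),
    n_pixels = length(o)), class = "map_comparison")
}

#' @export
print.map_comparison <- function(x, ...) {
  cat(sprintf("map comparison over %d pixels:\n", x$n_pixels))
  cat(sprintf("  R2 = %.3f, RRMSE = %.3f, bias = %.3f, slope = %.3f\n",
              x$r2, x$rrmse, x$bias, x$slope))
  invisible(x)
}

#' Does a map comparison meet the agreement thresholds?
#'
#' A comparison is flagged as agreeing when its R-squared reaches
#' `r2_min` and its regression slope lies strictly inside
#' `slope_range` — the screening rule used to separate well-matched
#' trait maps from the rest.
#'
#' @param comparison a [compare_maps] result.
#' @param r2_min minimum R-squared (default 0.13).
#' @param slope_range open interval for the regression slope (default
#'   (0.5, 2)).
#' @return logical.
#' @export
agreement_flags <- function(comparison, r2_min = 0.13,
                            slope_range = c(0.5, 2)) {
  comparison$r2 >= r2_min && comparison$slope > slope_range[1] &&
    comparison$slope < slope_range[2]
}
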