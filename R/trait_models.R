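#' Fit an additive trait-climate model
#'
#' Penalized-regression-spline GAM (Gaussian family) of a log-CWM trait
#' on bioclimatic predictors, with smoothness selected by restricted
#' maximum likelihood. Optional cover-fraction interactions are
#' varying-coefficient terms: a smooth of each bioclim variable
#' multiplied by the cover fraction, plus a smooth main effect of the
#' cover fraction itself.
#'
#' @param data data.frame holding the response and predictor columns;
#'   incomplete rows are dropped.
#' @param response name of the response column (natural-log CWM).
#' @param predictors names of the smooth predictor columns (default the
#'   bioclim triple).
#' @param k basis dimension per smooth term (>= 3).
#' @param interactions optional character vector of cover-fraction
#'   column names; each enters as a smooth main effect and as a
#'   varying-coefficient interaction with every predictor.
#' @param smooth if `FALSE` fit linear (parametric) terms instead of
#'   smooths; the model then coincides with ordinary least squares.
#' @param method smoothing-parameter selection criterion passed to
#'   [mgcv::gam] (default `"REML"`; `"GCV.Cp"` available as fallback).
#' @param sp optional fixed smoothing parameters (one per smooth term),
#'   bypassing selection — e.g. to re-fit on perturbed data at the
#'   smoothness chosen on the original data.
#' @return object of class `trait_gam`: the fitted mgcv model plus
#'   `spec`, `deviance_explained`, `adjusted_r2`, `n_obs`,
#'   `smoothing_parameters`.
#' @export
fit_trait_gam <- function(data, response, predictors = c("ln_mi", "mtco",
                                                         "mgst"),
                          k = 10, interactions = NULL, smooth = TRUE,
                          method = "REML", sp = NULL) {
  if (k < 3) stop("fit_trait_gam: k must be >= 3")
  vars <- c(response, predictors, interactions)
  miss <- setdiff(vars, names(data))
  if (length(miss))
    stop("fit_trait_gam: missing column(s): ", paste(miss, collapse = ", "))
  data <- data[stats::complete.cases(data[, vars, drop = FALSE]), vars,
               drop = FALSE]
  n_terms <- length(predictors) + length(interactions) * (1 +
    length(predictors))
  if (nrow(data) < 10 * n_terms)
    stop("fit_trait_gam: need at least ", 10 * n_terms,
         " complete rows, got ", nrow(data))
  if (!all(vapply(data, is.numeric, logical(1))))
    stop("fit_trait_gam: all model columns must be numeric")

  degenerate <- stats::var(data[[response]]) == 0
  term <- function(v, by = NULL) {
    if (!smooth) return(if (is.null(by)) v else paste0("I(", v, "*", by, ")"))
    if (is.null(by)) sprintf("s(%s, k = %d)", v, k)
    else sprintf("s(%s, by = %s, k = %d)", v, by, k)
  }
  rhs <- c(vapply(predictors, term, character(1)),
           unlist(lapply(interactions, function(cv)
             c(term(cv), vapply(predictors, term, character(1), by = cv)))))
  fml <- stats::as.formula(paste(response, "~", paste(rhs, collapse = " + ")))
  if (degenerate) {
    warning("fit_trait_gam: constant response; degenerate fit")
    fml <- stats::as.formula(paste(response, "~ 1"))
    ## intercept-only: no smoothness to select (REML's optimizer cannot
    ## handle a zero-variance response)
    fit <- mgcv::gam(fml, data = data)
  } else {
    fit <- mgcv::gam(fml, data = data, method = method, sp = sp)
  }
  sm <- summary(fit)
  dev <- if (degenerate) 0 else as.numeric(sm$dev.expl)
  structure(list(
    model = fit,
    spec = list(response = response, predictors = predictors, k = k,
                interactions = interactions, smooth = smooth,
                method = method),
    deviance_explained = dev,
    adjusted_r2 = if (degenerate) 0 else as.numeric(sm$r.sq),
    n_obs = nrow(data),
    smoothing_parameters = fit$sp), class = "trait_gam")
}

#' @export
print.trait_gam <- function(x, ...) {
  cat(sprintf("trait GAM: %s ~ %s (k = %d, %s)\n", x$spec$response,
              paste(x$spec$predictors, collapse = " + "), x$spec$k,
              x$spec$method))
  cat(sprintf("  n = %d, deviance explained = %.3f, adj. R2 = %.3f\n",
              x$n_obs, x$deviance_explained, x$adjusted_r2))
  invisible(x)
}

#' @export
predict.trait_gam <- function(object, newdata, type = "response", ...) {
  as.numeric(mgcv::predict.gam(object$model, newdata = newdata,
                               type = type, ...))
}

#' Per-term partial effects of a fitted trait GAM
#'
#' @param fit a [fit_trait_gam] result.
#' @param newdata optional data.frame (training data by default).
#' @return matrix with one column per model term (centered partial
#'   contributions).
#' @export
gam_partials <- function(fit, newdata = NULL) {
  if (is.null(newdata))
    mgcv::predict.gam(fit$model, type = "terms")
  else
    mgcv::predict.gam(fit$model, newdata = newdata, type = "terms")
}

## deviance explained of a GAM on a predictor subset
subset_dev <- function(data, response, subset, k, smooth, method) {
  if (length(subset) == 0) return(0)
  f <- tryCatch(
    fit_trait_gam(data, response, predictors = subset, k = k,
                  smooth = smooth, method = method),
    error = function(e)
      stop("relative_importance: submodel {",
           paste(subset, collapse = ", "), "} failed: ",
           conditionMessage(e)))
  f$deviance_explained
}

#' Relative importance of GAM predictors
#'
#' Decomposes the full model's deviance explained into per-predictor
#' percentage contributions. The default is the Shapley (LMG)
#' decomposition: each predictor's contribution is the increment in
#' deviance explained when it enters the model, averaged over all
#' orderings of the predictors; a cheaper leave-one-out variant
#' (`method = "loo"`) uses the drop in deviance explained when the
#' predictor is removed from the full model. Shares are normalized to
#' sum to 100%.
#'
#' @inheritParams fit_trait_gam
#' @param method `"shapley"` or `"loo"`.
#' @return object of class `importance_shares`: data.frame with
#'   `predictor`, `share` (% of the full-model deviance explained) and
#'   `share_raw` (% of the sum of raw contributions; identical for the
#'   Shapley decomposition, which is exactly additive), plus attributes
#'   `full_deviance_explained` and `method`.
#' @export
relative_importance <- function(data, response,
                                predictors = c("ln_mi", "mtco", "mgst"),
                                k = 10, smooth = TRUE,
                                method = c("shapley", "loo"),
                                gam_method = "REML") {
  method <- match.arg(method)
  p <- length(predictors)
  ## deviance explained for every non-empty subset
  subsets <- lapply(seq_len(2^p - 1), function(b)
    predictors[bitwAnd(b, 2^(seq_len(p) - 1)) > 0])
  dev <- vapply(subsets, function(s)
    subset_dev(data, response, s, k, smooth, gam_method), numeric(1))
  names(dev) <- vapply(subsets, paste, character(1), collapse = "+")
  key <- function(s) paste(sort(s), collapse = "+")
  devof <- function(s) if (length(s) == 0) 0 else
    dev[[match(key(s), vapply(subsets, key, character(1)))]]
  full <- devof(predictors)
  if (method == "shapley") {
    perms <- all_perms(p)
    contrib <- stats::setNames(numeric(p), predictors)
    for (i in seq_len(nrow(perms))) {
      before <- character(0)
      for (j in perms[i, ]) {
        v <- predictors[j]
        contrib[v] <- contrib[v] + devof(c(before, v)) - devof(before)
        before <- c(before, v)
      }
    }
    contrib <- contrib / nrow(perms)
  } else {
    contrib <- vapply(predictors, function(v)
      full - devof(setdiff(predictors, v)), numeric(1))
  }
  if (full <= 0)
    stop("relative_importance: full model explains no deviance")
  out <- data.frame(predictor = predictors,
                    share = 100 * contrib / full,
                    share_raw = 100 * contrib / sum(contrib),
                    row.names = NULL)
  structure(out, class = c("importance_shares", "data.frame"),
            full_deviance_explained = full, method = method,
            subset_deviance = dev)
}

#' Concurvity of smooth model terms
#'
#' For each smooth term, the proportion of its fitted-function variance
#' that lies in the span of the other terms' basis columns (the
#' "observed" concurvity measure of mgcv): 0 means the term is
#' independent of the others, 1 that it is entirely reproducible by
#' them.
#'
#' @param fit a [fit_trait_gam] result with at least two smooth terms.
#' @return named numeric vector in \[0, 1\], one entry per smooth term.
#' @export
gam_concurvity <- function(fit) {
  nsm <- length(fit$model$smooth)
  if (nsm < 2)
    stop("gam_concurvity: not applicable to models with fewer than two ",
         "smooth terms")
  cv <- mgcv::concurvity(fit$model, full = TRUE)
  keep <- colnames(cv) != "para"
  out <- pmin(pmax(as.numeric(cv["observed", keep]), 0), 1)
  names(out) <- colnames(cv)[keep]
  out
}

#' Evaluate a fitted trait surface on a hull-masked climate-space grid
#'
#' Builds a regular grid over the observed range of the three bioclim
#' predictors, masks grid nodes outside the 3-D convex hull of the
#' observed points (so the surface is only shown where it is
#' constrained by data), and evaluates the fitted model on the
#' remaining nodes.
#'
#' @param fit a [fit_trait_gam] result whose predictors are the three
#'   grid axes.
#' @param observed data.frame or matrix of observed predictor triples
#'   (columns named as the fit's predictors); must be non-degenerate in
#'   3-D.
#' @param increments numeric length 3, grid step per axis (defaults:
#'   0.05 for ln MI, 0.25 degC for MTCO and MGST).
#' @param at optional named list of extra covariate values (e.g. cover
#'   fractions) held constant during evaluation.
#' @return object of class `climate_surface`: `axes` (named list of
#'   axis vectors), `mask` (logical 3-D array, TRUE = inside hull),
#'   `pred` (numeric 3-D array, `NA` at masked nodes), `predictors`.
#' @export
climate_space_surface <- function(fit, observed,
                                  increments = c(0.05, 0.25, 0.25),
                                  at = NULL) {
  prd <- fit$spec$predictors
  if (length(prd) != 3)
    stop("climate_space_surface: fit must have exactly 3 predictors")
  if (any(increments <= 0))
    stop("climate_space_surface: increments must be strictly positive")
  observed <- as.data.frame(observed)[, prd]
  observed <- observed[stats::complete.cases(observed), ]
  pts <- as.matrix(observed)
  hull <- convex_hull_3d(pts)
  axes <- lapply(1:3, function(i)
    seq(min(pts[, i]), max(pts[, i]), by = increments[i]))
  names(axes) <- prd
  grid <- as.matrix(expand.grid(axes, KEEP.OUT.ATTRS = FALSE))
  mask <- in_hull(hull, grid)
  pred <- rep(NA_real_, nrow(grid))
  if (any(mask)) {
    nd <- as.data.frame(grid[mask, , drop = FALSE])
    for (nm in names(at)) nd[[nm]] <- at[[nm]]
    pred[mask] <- predict(fit, nd)
  }
  dims <- unname(lengths(axes))
  structure(list(axes = axes,
                 mask = array(mask, dims),
                 pred = array(pred, dims),
                 predictors = prd, hull = hull),
            class = "climate_surface")
}

#' Extract a fixed-MTCO slice of a climate-space surface
#'
#' @param surface a [climate_space_surface] result.
#' @param mtco the MTCO value to slice at (snapped to the nearest grid
#'   level of the second axis).
#' @return list with `slice` (matrix ln MI x MGST of predictions, `NA`
#'   outside the hull) and `mtco` (the grid level used).
#' @export
surface_slice <- function(surface, mtco) {
  ax <- surface$axes[[2]]
  j <- which.min(abs(ax - mtco))
  list(slice = surface$pred[, j, ], mtco = ax[j],
       ln_mi = surface$axes[[1]], mgst = surface$axes[[3]])
}
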