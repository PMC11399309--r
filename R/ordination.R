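## deterministic sign convention: the largest-magnitude loading on each
## axis is made positive; scores flip with their loadings.
apply_sign_convention <- function(loadings, scores) {
  for (j in seq_len(ncol(loadings))) {
    i <- which.max(abs(loadings[, j]))
    if (loadings[i, j] < 0) {
      loadings[, j] <- -loadings[, j]
      scores[, j] <- -scores[, j]
    }
  }
  list(loadings = loadings, scores = scores)
}

## eigen-analysis of t(Xc) Xc / (n-1) for a centered matrix
pca_core <- function(xc, prefix = "PC") {
  n <- nrow(xc)
  cv <- crossprod(xc) / (n - 1)
  e <- eigen(cv, symmetric = TRUE)
  ev <- pmax(e$values, 0)
  loadings <- e$vectors
  scores <- xc %*% loadings
  sc <- apply_sign_convention(loadings, scores)
  ax <- paste0(prefix, seq_along(ev))
  dimnames(sc$loadings) <- list(colnames(xc), ax)
  dimnames(sc$scores) <- list(rownames(xc), ax)
  names(ev) <- ax
  list(loadings = sc$loadings, scores = sc$scores, eigenvalues = ev)
}

#' Principal component analysis of a trait matrix
#'
#' Eigen-decomposition of the covariance matrix of the (standardized)
#' log-CWM trait matrix — equivalently the trait correlation matrix.
#' Rows with any missing value are dropped (with a message). Axis signs
#' follow a deterministic convention: the largest-magnitude loading on
#' each axis is positive.
#'
#' @param x numeric matrix, plots x traits, standardized columns.
#' @return object of class `trait_pca`: `loadings` (traits x axes,
#'   orthonormal), `scores` (plots x axes), `eigenvalues`
#'   (non-increasing), `variance_fraction` (sums to 1), `n` (rows used),
#'   `dropped` (rows removed for missingness).
#' @export
trait_pca <- function(x) {
  x <- as.matrix(x)
  cc <- stats::complete.cases(x)
  dropped <- sum(!cc)
  if (dropped > 0)
    message("trait_pca: dropped ", dropped, " incomplete row(s)")
  x <- x[cc, , drop = FALSE]
  if (nrow(x) < 2 || ncol(x) < 2)
    stop("trait_pca: need at least 2 complete rows and 2 columns")
  xc <- sweep(x, 2, colMeans(x))
  core <- pca_core(xc)
  structure(c(core,
              list(variance_fraction = core$eigenvalues /
                     sum(core$eigenvalues),
                   n = nrow(x), dropped = dropped)),
            class = "trait_pca")
}

#' @export
print.trait_pca <- function(x, ...) {
  cat("PCA of", nrow(x$loadings), "traits,", x$n, "plots\n")
  cat("variance fractions:",
      paste(sprintf("%.3f", x$variance_fraction), collapse = " "), "\n")
  invisible(x)
}

#' Redundancy analysis (constrained ordination)
#'
#' Multivariate least squares of the trait matrix on the predictors
#' followed by eigen-analysis of the fitted values (constrained axes)
#' and of the residuals (unconstrained axes). The constrained fraction
#' is the share of total trait variance captured by the predictors.
#'
#' @param y numeric matrix, plots x traits (standardized log-CWMs).
#' @param x numeric matrix, plots x predictors (standardized bioclim
#'   variables); must be full column rank.
#' @return object of class `trait_rda` with elements `constrained` and
#'   `unconstrained` (each: `loadings`, `scores`, `eigenvalues`),
#'   `biplot_scores` (predictor correlations with constrained site
#'   scores), `constrained_fraction`,
#'   `axis_fraction_total` (per constrained axis, share of total
#'   variance) and `axis_fraction_constrained` (share of constrained
#'   variance), `total_variance`, `n`.
#' @export
trait_rda <- function(y, x) {
  y <- as.matrix(y); x <- as.matrix(x)
  if (nrow(y) != nrow(x))
    stop("trait_rda: y and x must have the same rows")
  cc <- stats::complete.cases(y) & stats::complete.cases(x)
  if (sum(!cc) > 0)
    message("trait_rda: dropped ", sum(!cc), " incomplete row(s)")
  y <- y[cc, , drop = FALSE]; x <- x[cc, , drop = FALSE]
  n <- nrow(y)
  if (n < ncol(x) + 2)
    stop("trait_rda: too few rows for the number of predictors")
  yc <- sweep(y, 2, colMeans(y))
  xc <- sweep(x, 2, colMeans(x))
  qx <- qr(xc)
  if (qx$rank < ncol(xc))
    stop("trait_rda: predictors are collinear (rank ", qx$rank,
         " < ", ncol(xc), ")")
  yhat <- qr.fitted(qx, yc)
  resid <- yc - yhat
  ncon <- min(qx$rank, ncol(yc))
  con <- pca_core(yhat, prefix = "RDA")
  con$loadings <- con$loadings[, seq_len(ncon), drop = FALSE]
  con$scores <- con$scores[, seq_len(ncon), drop = FALSE]
  con$eigenvalues <- con$eigenvalues[seq_len(ncon)]
  unc <- pca_core(resid, prefix = "PC")
  total <- sum(apply(yc, 2, stats::var))
  bip <- stats::cor(xc, con$scores)
  structure(list(
    constrained = con, unconstrained = unc, biplot_scores = bip,
    constrained_fraction = sum(yhat^2) / sum(yc^2),
    axis_fraction_total = con$eigenvalues / total,
    axis_fraction_constrained = con$eigenvalues / sum(con$eigenvalues),
    total_variance = total, n = n, predictors_centered = xc),
    class = "trait_rda")
}

#' @export
print.trait_rda <- function(x, ...) {
  cat(sprintf("RDA: %d plots, constrained fraction %.3f\n",
              x$n, x$constrained_fraction))
  cat("constrained axis fractions of total variance:",
      paste(sprintf("%.3f", x$axis_fraction_total), collapse = " "), "\n")
  invisible(x)
}

## best permutation + sign of axes within equal-eigenvalue blocks so the
## loadings agree with a reference; eigenvalues are unchanged.
align_axes <- function(loadings, scores, eigenvalues, ref, tol = 1e-8) {
  ref <- as.matrix(ref)
  if (is.null(rownames(ref)) || is.null(rownames(loadings)) ||
      !setequal(rownames(ref), rownames(loadings)))
    stop("rotate_to_reference: reference trait set does not match")
  ref <- ref[rownames(loadings), , drop = FALSE]
  k <- min(ncol(loadings), ncol(ref))
  ord <- seq_len(ncol(loadings))
  ## blocks of (numerically) equal eigenvalues may be permuted
  blk <- cumsum(c(TRUE, abs(diff(eigenvalues)) >
                    tol * max(abs(eigenvalues), 1)))
  agree <- abs(crossprod(loadings, ref))  # axes x ref axes
  for (b in unique(blk)) {
    ax <- which(blk == b & ord <= k)
    if (length(ax) < 2) next
    perms <- all_perms(length(ax))
    best <- which.max(vapply(seq_len(nrow(perms)), function(i)
      sum(agree[cbind(ax[perms[i, ]], ax)]), numeric(1)))
    ord[ax] <- ax[perms[best, ]]
  }
  loadings <- loadings[, ord, drop = FALSE]
  scores <- scores[, ord, drop = FALSE]
  for (j in seq_len(k)) {
    if (sum(loadings[, j] * ref[, j]) < 0) {
      loadings[, j] <- -loadings[, j]
      scores[, j] <- -scores[, j]
    }
  }
  list(loadings = loadings, scores = scores)
}

all_perms <- function(n) {
  if (n == 1) return(matrix(1L, 1, 1))
  sub <- all_perms(n - 1)
  do.call(rbind, lapply(seq_len(n), function(i)
    cbind(i, sub + (sub >= i))))
}

#' Rotate ordination axes to agree with a reference orientation
#'
#' Chooses axis signs (and, within blocks of numerically equal
#' eigenvalues, the axis order) to maximize agreement with reference
#' loadings, e.g. so plots from different groups share an orientation.
#' Eigenvalues and the reconstruction `scores %*% t(loadings)` are
#' unchanged.
#'
#' @param result a [trait_pca] or [trait_rda] object (for RDA the
#'   constrained axes are aligned).
#' @param reference_loadings matrix with the same trait rownames.
#' @return object of the same class with aligned axes.
#' @export
rotate_to_reference <- function(result, reference_loadings) {
  UseMethod("rotate_to_reference")
}

#' @export
rotate_to_reference.trait_pca <- function(result, reference_loadings) {
  al <- align_axes(result$loadings, result$scores, result$eigenvalues,
                   reference_loadings)
  result$loadings <- al$loadings
  result$scores <- al$scores
  result
}

#' @export
rotate_to_reference.trait_rda <- function(result, reference_loadings) {
  al <- align_axes(result$constrained$loadings, result$constrained$scores,
                   result$constrained$eigenvalues, reference_loadings)
  result$constrained$loadings <- al$loadings
  result$constrained$scores <- al$scores
  result$biplot_scores <- stats::cor(result$predictors_centered, al$scores)
  result
}
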