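#' Convex hull of a 3-D point cloud
#'
#' Incremental construction of the convex hull of points in three
#' dimensions, used to delimit the region of climate space that is
#' actually constrained by observations. The hull is returned in
#' half-space form: a point `x` is inside iff `normals %*% x <= offsets`
#' (within tolerance) for every facet.
#'
#' @param pts numeric matrix, n x 3, with n >= 4 affinely independent
#'   rows.
#' @return object of class `hull3d`: list with `vertices` (coordinates
#'   used), `facets` (integer triples indexing `vertices`), `normals`
#'   (facets x 3, outward unit normals) and `offsets`.
#' @examples
#' h <- convex_hull_3d(rbind(diag(3), 0))
#' in_hull(h, rbind(c(.2, .2, .2), c(2, 2, 2)))
#' @export
convex_hull_3d <- function(pts) {
  pts <- as.matrix(pts)
  if (ncol(pts) != 3) stop("convex_hull_3d: pts must have 3 columns")
  pts <- pts[stats::complete.cases(pts), , drop = FALSE]
  n <- nrow(pts)
  if (n < 4) stop("convex_hull_3d: need at least 4 points")
  scale <- max(apply(pts, 2, function(v) diff(range(v))))
  if (scale == 0) stop("convex_hull_3d: degenerate hull (all points identical)")
  eps <- 1e-10 * scale

  ## initial simplex: mutually far points
  i1 <- which.max(rowSums(sweep(pts, 2, pts[1, ])^2))
  i2 <- which.max(rowSums(sweep(pts, 2, pts[i1, ])^2))
  e1 <- pts[i2, ] - pts[i1, ]
  cr <- function(a, b) c(a[2] * b[3] - a[3] * b[2],
                         a[3] * b[1] - a[1] * b[3],
                         a[1] * b[2] - a[2] * b[1])
  area2 <- function(j) sum(cr(e1, pts[j, ] - pts[i1, ])^2)
  i3 <- which.max(vapply(seq_len(n), area2, numeric(1)))
  nrm <- cr(e1, pts[i3, ] - pts[i1, ])
  if (sqrt(sum(nrm^2)) <= eps)
    stop("convex_hull_3d: degenerate hull (collinear sample); use fewer dimensions")
  vol <- abs(as.vector(pts %*% nrm) - sum(nrm * pts[i1, ]))
  i4 <- which.max(vol)
  if (vol[i4] <= eps * sqrt(sum(nrm^2)))
    stop("convex_hull_3d: degenerate hull (coplanar sample); consider a 2-D hull")

  verts <- c(i1, i3, i2, i4)  # order irrelevant; orientation fixed below
  interior <- colMeans(pts[verts, ])
  facets <- rbind(c(1L, 2L, 3L), c(1L, 2L, 4L), c(1L, 3L, 4L), c(2L, 3L, 4L))
  facets <- matrix(verts[facets], ncol = 3)

  plane <- function(f) {
    a <- pts[f[1], ]; nn <- cr(pts[f[2], ] - a, pts[f[3], ] - a)
    nn <- nn / sqrt(sum(nn^2))
    d <- sum(nn * a)
    if (sum(nn * interior) > d) { nn <- -nn; d <- -d }
    c(nn, d)
  }
  pl <- t(apply(facets, 1, plane))

  rest <- setdiff(seq_len(n), verts)
  for (p in rest) {
    dst <- as.vector(pl[, 1:3, drop = FALSE] %*% pts[p, ]) - pl[, 4]
    vis <- dst > eps
    if (!any(vis)) next
    ## horizon: edges used by exactly one visible facet
    vf <- facets[vis, , drop = FALSE]
    edges <- rbind(vf[, c(1, 2)], vf[, c(2, 3)], vf[, c(1, 3)])
    key <- paste(pmin(edges[, 1], edges[, 2]), pmax(edges[, 1], edges[, 2]))
    horizon <- edges[key %in% names(which(table(key) == 1)), , drop = FALSE]
    facets <- facets[!vis, , drop = FALSE]
    pl <- pl[!vis, , drop = FALSE]
    newf <- cbind(horizon, p)
    facets <- rbind(facets, newf)
    pl <- rbind(pl, t(apply(newf, 1, plane)))
  }
  structure(list(vertices = pts, facets = facets,
                 normals = pl[, 1:3, drop = FALSE], offsets = pl[, 4],
                 eps = eps),
            class = "hull3d")
}

#' Test points for membership in a 3-D convex hull
#'
#' @param hull a [convex_hull_3d] result.
#' @param pts numeric matrix, m x 3.
#' @param tol slack on the half-space inequalities; points within `tol`
#'   outside a facet still count as inside (boundary points are inside).
#' @return logical vector of length m (`NA` rows give `FALSE`).
#' @export
in_hull <- function(hull, pts, tol = NULL) {
  pts <- as.matrix(pts)
  if (ncol(pts) != 3) stop("in_hull: pts must have 3 columns")
  if (is.null(tol)) tol <- 100 * hull$eps
  out <- logical(nrow(pts))
  ok <- stats::complete.cases(pts)
  if (any(ok)) {
    ## chunked so large grids do not allocate an m x facets matrix at once
    idx <- which(ok)
    for (ch in split(idx, ceiling(seq_along(idx) / 65536))) {
      d <- pts[ch, , drop = FALSE] %*% t(hull$normals)
      out[ch] <- rowSums(sweep(d, 2, hull$offsets) > tol) == 0
    }
  }
  out
}
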