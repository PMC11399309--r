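## shared fixtures built in code

major_traits <- c("LA", "LMA", "Narea", "SSD", "H", "DM")

## small species table with pure, mixed, and minority growth forms
toy_species <- function() {
  sp <- data.frame(
    taxon = c("herb1", "herb2", "tree_d", "tree_e", "fern1", "mix1"),
    growth_form = c("herb", "graminoid", "tree-deciduous",
                    "tree-evergreen", "fern", "shrub-intermediate"),
    H = c(0.3, 0.5, 12, 18, 0.4, 2),
    LMA = c(0.04, 0.05, 0.08, 0.15, 0.06, 0.09))
  ft <- growth_form_table(extra = data.frame(
    growth_form = "shrub-intermediate", p_nonwoody = 0.5,
    p_deciduous = 0.25, p_evergreen = 0.25))
  classify_groups(sp, ft)
}

## one-plot composition data.frame
toy_comp <- function(taxa, covers, plot_id = "p1") {
  data.frame(plot_id = plot_id, taxon = taxa, rel_cover = covers)
}

## small land-cover grid with a known code layout
toy_landcover <- function(vals, xmin = 0, xmax = ncol(vals),
                          ymin = 0, ymax = nrow(vals)) {
  g <- geogrid(vals, xmin, xmax, ymin, ymax, name = "landcover")
  attr(g, "codes") <- landcover_codes()
  g
}

## fast default world for structural tests
small_world <- function(seed = 11, n_plots = 250, n_species = 150, ...) {
  generate_world(world_config(seed = seed, n_plots = n_plots,
                              n_species = n_species, ...))
}

## brute-force RDA oracle: explicit projection matrix + dense eigen
rda_oracle <- function(Y, X) {
  Y <- scale(Y, scale = FALSE)
  X <- scale(X, scale = FALSE)
  n <- nrow(Y)
  P <- X %*% solve(t(X) %*% X) %*% t(X)
  Yhat <- P %*% Y
  R <- Y - Yhat
  list(constrained_fraction = sum(Yhat^2) / sum(Y^2),
       eig_c = eigen(t(Yhat) %*% Yhat / (n - 1), symmetric = TRUE)$values,
       eig_u = eigen(t(R) %*% R / (n - 1), symmetric = TRUE)$values)
}

## brute-force Shapley decomposition of linear-model R2
shapley_lm_oracle <- function(data, response, predictors) {
  r2 <- function(s) {
    if (length(s) == 0) return(0)
    summary(stats::lm(stats::reformulate(s, response), data))$r.squared
  }
  perms <- combinat_perms(length(predictors))
  contrib <- stats::setNames(numeric(length(predictors)), predictors)
  for (i in seq_len(nrow(perms))) {
    before <- character(0)
    for (j in perms[i, ]) {
      v <- predictors[j]
      contrib[v] <- contrib[v] + r2(c(before, v)) - r2(before)
      before <- c(before, v)
    }
  }
  contrib / nrow(perms)
}

combinat_perms <- function(n) {
  if (n == 1) return(matrix(1L, 1, 1))
  sub <- combinat_perms(n - 1)
  do.call(rbind, lapply(seq_len(n), function(i) cbind(i, sub + (sub >= i))))
}

## independent point-in-hull oracle: is q a convex combination of pts?
## (simplex-constrained least squares via non-negative least squares)
in_hull_oracle <- function(pts, q, tol = 1e-7) {
  A <- rbind(t(pts), 1)
  vapply(seq_len(nrow(q)), function(i) {
    b <- c(q[i, ], 1)
    r <- pracma::lsqnonneg(A, b)
    sqrt(sum((A %*% r$x - b)^2)) < tol
  }, logical(1))
}
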