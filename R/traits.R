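#' Trait unit conversions
#'
#' Leaf mass per area (LMA, kg/m2) is the reciprocal of specific leaf
#' area (SLA, m2/kg); an area-based leaf nutrient content (g/m2) is the
#' mass-based content (mg/g) divided by SLA, the mg/kg factors
#' cancelling to g/m2.
#'
#' @param sla specific leaf area, m2/kg; must be > 0.
#' @return `lma_from_sla`: LMA in kg/m2.
#' @examples
#' lma_from_sla(10)           # 0.1 kg/m2
#' area_based_from_mass(20, 10)  # 2 g/m2
#' @export
lma_from_sla <- function(sla) {
  if (any(sla <= 0, na.rm = TRUE))
    stop("lma_from_sla: SLA must be strictly positive")
  1 / sla
}

#' @rdname lma_from_sla
#' @param mass_content mass-based content (e.g. N or P), mg/g; >= 0.
#' @return `area_based_from_mass`: area-based content in g/m2.
#' @export
area_based_from_mass <- function(mass_content, sla) {
  if (any(sla <= 0, na.rm = TRUE))
    stop("area_based_from_mass: SLA must be strictly positive")
  if (any(mass_content < 0, na.rm = TRUE))
    stop("area_based_from_mass: mass content must be >= 0")
  mass_content / sla
}

#' Growth-form to plant-group probability table
#'
#' Maps growth forms to the probability of belonging to each of the
#' three plant groups (non-woody, woody deciduous, woody evergreen).
#' Minority forms (ferns, palms, cycads, bamboos, cacti, succulents)
#' carry zero probability for every group and are omitted from all
#' group-based computations. Additional or mixed-probability forms can
#' be appended via `extra`.
#'
#' @param extra optional data.frame with columns `growth_form`,
#'   `p_nonwoody`, `p_deciduous`, `p_evergreen` to append or override.
#' @return data.frame with one row per growth form.
#' @export
growth_form_table <- function(extra = NULL) {
  tab <- data.frame(
    growth_form = c("herb", "graminoid", "forb",
                    "tree-deciduous", "shrub-deciduous",
                    "tree-evergreen", "shrub-evergreen",
                    "fern", "palm", "cycad", "bamboo", "cactus",
                    "succulent"),
    p_nonwoody  = c(1, 1, 1, 0, 0, 0, 0, 0, 0, 0, 0, 0, 0),
    p_deciduous = c(0, 0, 0, 1, 1, 0, 0, 0, 0, 0, 0, 0, 0),
    p_evergreen = c(0, 0, 0, 0, 0, 1, 1, 0, 0, 0, 0, 0, 0))
  if (!is.null(extra)) {
    need <- c("growth_form", "p_nonwoody", "p_deciduous", "p_evergreen")
    if (!all(need %in% names(extra)))
      stop("growth_form_table: extra must have columns ",
           paste(need, collapse = ", "))
    tab <- rbind(tab[!tab$growth_form %in% extra$growth_form, ],
                 extra[, need])
  }
  bad <- with(tab, p_nonwoody < 0 | p_deciduous < 0 | p_evergreen < 0 |
                p_nonwoody + p_deciduous + p_evergreen > 1 + 1e-12)
  if (any(bad))
    stop("growth_form_table: probabilities must be in [0,1] with sum <= 1")
  tab
}

#' Assign plant-group probabilities to species from their growth forms
#'
#' Populates `p_nonwoody`, `p_deciduous`, `p_evergreen` and an `omitted`
#' flag (TRUE when all three probabilities are zero, i.e. a minority
#' growth form) on a species table.
#'
#' @param species data.frame with columns `taxon` and `growth_form`.
#' @param form_table mapping from growth form to group probabilities;
#'   see [growth_form_table].
#' @return `species` with the four columns added/overwritten.
#' @export
classify_groups <- function(species, form_table = growth_form_table()) {
  if (!all(c("taxon", "growth_form") %in% names(species)))
    stop("classify_groups: species needs columns taxon, growth_form")
  m <- match(species$growth_form, form_table$growth_form)
  if (anyNA(m)) {
    unknown <- unique(species$growth_form[is.na(m)])
    stop("classify_groups: unknown growth form(s): ",
         paste(unknown, collapse = ", "))
  }
  species$p_nonwoody <- form_table$p_nonwoody[m]
  species$p_deciduous <- form_table$p_deciduous[m]
  species$p_evergreen <- form_table$p_evergreen[m]
  species$omitted <- species$p_nonwoody + species$p_deciduous +
    species$p_evergreen == 0
  species
}

group_cols <- c("nonwoody", "deciduous", "evergreen")

#' Names of the three plant groups
#'
#' The canonical column order used for group coverages and mixtures:
#' non-woody, woody deciduous, woody evergreen.
#' @return character vector of length 3.
#' @export
group_names <- function() group_cols

## per-taxon group-probability matrix for a given target group
taxon_group_prob <- function(species, group) {
  p <- as.matrix(species[, c("p_nonwoody", "p_deciduous", "p_evergreen")])
  switch(group,
         nonwoody = p[, 1], deciduous = p[, 2], evergreen = p[, 3],
         all = pmin(rowSums(p), 1),
         stop("unknown group: ", group))
}

#' Relative coverage of the three plant groups per plot
#'
#' For each plot, the relative abundance of a group is the sum over taxa
#' of relative cover times group-membership probability; group coverages
#' are these abundances renormalized to sum to one. Omitted (minority
#' growth form) taxa contribute nothing.
#'
#' @param composition long data.frame with columns `plot_id`, `taxon`,
#'   `rel_cover` (covers sum to 1 within each plot).
#' @param species species table carrying group probabilities (see
#'   [classify_groups]).
#' @return data.frame with columns `plot_id`, `nonwoody`, `deciduous`,
#'   `evergreen` (each row sums to 1). A plot whose taxa are all omitted
#'   is an error.
#' @export
group_cover <- function(composition, species) {
  m <- match(composition$taxon, species$taxon)
  if (anyNA(m))
    stop("group_cover: taxa missing from species table: ",
         paste(unique(composition$taxon[is.na(m)]), collapse = ", "))
  p <- as.matrix(species[m, c("p_nonwoody", "p_deciduous", "p_evergreen")])
  ra <- rowsum(p * composition$rel_cover, composition$plot_id)
  tot <- rowSums(ra)
  if (any(tot <= 0))
    stop("group_cover: all taxa omitted in plot(s): ",
         paste(rownames(ra)[tot <= 0], collapse = ", "))
  rc <- ra / tot
  out <- data.frame(plot_id = rownames(ra), rc, row.names = NULL)
  names(out) <- c("plot_id", group_cols)
  out
}

#' Community-weighted mean traits per plot
#'
#' For each plot and trait, the CWM is the weighted mean of species
#' trait values with weights proportional to relative cover times the
#' probability of group membership, renormalized over the taxa that have
#' the trait measured. By default averaging is done on native-unit trait
#' values and the natural log is taken afterwards; `log_first = TRUE`
#' averages log-transformed values instead (geometric-mean convention).
#'
#' @param composition long data.frame `plot_id`, `taxon`, `rel_cover`.
#' @param species species table with group probabilities and trait
#'   columns in native units. If it carries a `plot_id` column the
#'   trait values are treated as plot-local realizations and matched on
#'   (`plot_id`, `taxon`).
#' @param traits character vector of trait column names.
#' @param group one of `"all"`, `"nonwoody"`, `"deciduous"`,
#'   `"evergreen"`.
#' @param log_first average logs instead of native values.
#' @param offsets optional named numeric, per-trait additive offset
#'   applied before the log transform (for traits that can be
#'   non-positive); without an offset a non-positive CWM is an error.
#' @return numeric matrix of natural-log CWMs, rows = plot ids, columns
#'   = traits, with attribute `group_label`. Plots with no contributing
#'   taxon for a trait get `NA`.
#' @export
community_weighted_means <- function(composition, species, traits,
                                     group = c("all", "nonwoody",
                                               "deciduous", "evergreen"),
                                     log_first = FALSE, offsets = NULL) {
  group <- match.arg(group)
  if (!all(traits %in% names(species)))
    stop("community_weighted_means: missing trait columns: ",
         paste(setdiff(traits, names(species)), collapse = ", "))
  plot_local <- "plot_id" %in% names(species)
  if (plot_local) {
    key_c <- paste(composition$plot_id, composition$taxon, sep = "\r")
    key_s <- paste(species$plot_id, species$taxon, sep = "\r")
    m <- match(key_c, key_s)
  } else {
    m <- match(composition$taxon, species$taxon)
  }
  if (anyNA(m))
    stop("community_weighted_means: unresolvable taxa in composition")
  pg <- taxon_group_prob(species, group)[m]
  w0 <- composition$rel_cover * pg
  plots <- sort(unique(composition$plot_id))
  pid <- match(composition$plot_id, plots)
  out <- matrix(NA_real_, length(plots), length(traits),
                dimnames = list(plots, traits))
  for (t in traits) {
    tv <- species[[t]][m]
    off <- if (!is.null(offsets) && t %in% names(offsets)) offsets[[t]] else 0
    ok <- !is.na(tv) & w0 > 0
    if (!any(ok)) next
    wsum <- rowsum(w0[ok], pid[ok])
    if (log_first) {
      if (any(tv[ok] + off <= 0))
        stop("community_weighted_means: non-positive value for log of '",
             t, "'; configure an offset")
      num <- rowsum(w0[ok] * log(tv[ok] + off), pid[ok])
      out[as.integer(rownames(wsum)), t] <- num / wsum
    } else {
      num <- rowsum(w0[ok] * tv[ok], pid[ok])
      cwm <- num / wsum + off
      if (any(cwm <= 0))
        stop("community_weighted_means: non-positive CWM for trait '", t,
             "' in plot(s) ",
             paste(plots[as.integer(rownames(wsum))][cwm <= 0],
                   collapse = ", "),
             "; configure an offset")
      out[as.integer(rownames(wsum)), t] <- log(cwm)
    }
  }
  attr(out, "group_label") <- group
  attr(out, "log_first") <- log_first
  out
}

#' Column standardization (z-scores)
#'
#' Rescales each column to mean 0 and standard deviation 1 (n - 1
#' denominator). Missing entries are excluded from the moments and stay
#' missing.
#'
#' @param x numeric matrix or data.frame.
#' @return matrix of the same shape, with attributes `center` and
#'   `scale`. A column with fewer than 2 non-missing values or zero
#'   variance is an error.
#' @export
standardize <- function(x) {
  x <- as.matrix(x)
  nok <- colSums(!is.na(x))
  if (any(nok < 2))
    stop("standardize: column(s) with < 2 non-missing values: ",
         paste(colnames(x)[nok < 2], collapse = ", "))
  ctr <- colMeans(x, na.rm = TRUE)
  sdv <- apply(x, 2, stats::sd, na.rm = TRUE)
  if (any(sdv == 0))
    stop("standardize: zero-variance column(s): ",
         paste(colnames(x)[sdv == 0], collapse = ", "))
  out <- sweep(sweep(x, 2, ctr), 2, sdv, "/")
  attr(out, "center") <- ctr
  attr(out, "scale") <- sdv
  out
}

#' Read and write tab-separated tables
#'
#' Thin wrappers with the conventions used throughout the package (no
#' quoting, no row names, `NA` written as `NA`).
#' @param path file path.
#' @return `read_tsv_table`: a data.frame.
#' @export
read_tsv_table <- function(path) {
  utils::read.delim(path, check.names = FALSE, stringsAsFactors = FALSE)
}

#' @rdname read_tsv_table
#' @param x data.frame (or matrix) to write.
#' @export
write_tsv_table <- function(x, path) {
  utils::write.table(x, path, sep = "\t", quote = FALSE, row.names = FALSE)
  invisible(path)
}
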