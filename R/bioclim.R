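#' Monthly climate on a lon/lat grid
#'
#' Container for 12-layer monthly climate fields: mean temperature
#' (`tas`, degrees C), precipitation totals (`pr`, mm), and either
#' shortwave radiation totals (`srad`, kJ/m2) or pre-computed potential
#' evapotranspiration (`pet`, mm). Each field is an array
#' `rows x cols x 12` on the same grid convention as [geogrid] (rows
#' north to south, values at cell centers).
#'
#' @param tas,pr arrays `rows x cols x 12`.
#' @param srad,pet optional arrays of the same shape; at least one must
#'   be given before bioclimatic variables can be computed.
#' @param xmin,xmax,ymin,ymax grid extent, degrees.
#' @return object of class `climate_grid`.
#' @export
monthly_climate_grid <- function(tas, pr, srad = NULL, pet = NULL,
                                 xmin, xmax, ymin, ymax) {
  dims <- dim(tas)
  if (length(dims) != 3 || dims[3] != 12)
    stop("monthly_climate_grid: tas must be rows x cols x 12")
  for (nm in c("pr", "srad", "pet")) {
    a <- get(nm)
    if (!is.null(a) && !identical(dim(a), dims))
      stop("monthly_climate_grid: ", nm, " dimensions differ from tas")
  }
  if (any(pr < 0, na.rm = TRUE))
    stop("monthly_climate_grid: negative precipitation")
  structure(list(tas = tas, pr = pr, srad = srad, pet = pet,
                 xmin = xmin, xmax = xmax, ymin = ymin, ymax = ymax),
            class = "climate_grid")
}

## one layer of a climate_grid as a geogrid
climate_layer <- function(cl, field, month) {
  geogrid(cl[[field]][, , month], cl$xmin, cl$xmax, cl$ymin, cl$ymax,
          name = paste0(field, "_", month))
}

#' Priestley-Taylor potential evapotranspiration
#'
#' Monthly PET (mm) from mean temperature and monthly shortwave
#' radiation totals:
#' \deqn{PET = \alpha \frac{s}{s+\gamma} \frac{R_n}{\lambda}}
#' with \eqn{\alpha = 1.26}, \eqn{s} the slope of the saturation vapour
#' pressure curve at `tas` (kPa/degC, Tetens form), psychrometric
#' constant \eqn{\gamma = 0.0665} kPa/degC, latent heat of vaporization
#' \eqn{\lambda = 2.45} MJ/kg, and net radiation approximated as
#' absorbed shortwave \eqn{R_n = (1 - 0.23)\, srad} (longwave exchange
#' neglected), so PET is linear in `srad` at fixed temperature.
#'
#' @param tas mean temperature, degrees C (vectorized).
#' @param srad monthly shortwave radiation total, kJ/m2; must be >= 0.
#' @return PET in mm per month, same length as the inputs.
#' @examples
#' pet_priestley_taylor(15, 450000)
#' @export
pet_priestley_taylor <- function(tas, srad) {
  if (any(srad < 0, na.rm = TRUE))
    stop("pet_priestley_taylor: srad must be non-negative")
  es <- 0.6108 * exp(17.27 * tas / (tas + 237.3))          # kPa
  s <- 4098 * es / (tas + 237.3)^2                         # kPa / degC
  gamma <- 0.0665                                          # kPa / degC
  lambda <- 2.45                                           # MJ / kg
  rn <- (1 - 0.23) * srad / 1000                           # MJ / m2
  1.26 * s / (s + gamma) * rn / lambda                     # mm (kg/m2)
}

#' Moisture index from monthly precipitation and PET
#'
#' MI is the ratio of annual precipitation to annual potential
#' evapotranspiration; its natural log emphasizes the dry end of the
#' moisture gradient.
#'
#' @param pr 12 monthly precipitation totals, mm.
#' @param pet 12 monthly PET totals, mm.
#' @return list with `mi` and `ln_mi`. Zero annual precipitation gives
#'   `ln_mi = -Inf` with a warning; zero annual PET is an error.
#' @export
moisture_index <- function(pr, pet) {
  if (length(pr) != 12 || length(pet) != 12)
    stop("moisture_index: pr and pet must have 12 monthly values")
  spet <- sum(pet)
  if (!is.finite(spet) || spet <= 0)
    stop("moisture_index: annual PET is zero; MI undefined")
  mi <- sum(pr) / spet
  if (mi == 0)
    warning("moisture_index: zero annual precipitation; ln MI = -Inf")
  list(mi = mi, ln_mi = log(mi))
}

#' Mean temperature of the coldest month
#' @param tas 12 monthly mean temperatures, degrees C.
#' @return minimum of the 12 values, degrees C.
#' @export
mtco <- function(tas) {
  if (length(tas) != 12 || anyNA(tas))
    stop("mtco: need 12 non-missing monthly temperatures")
  min(tas)
}

#' Growing degree days above 0 degrees C from a daily series
#'
#' @param daily_tas daily mean temperatures for one year (365 or 366
#'   values), degrees C.
#' @return list with `gdd0` (heat sum over days above 0, degC day) and
#'   `ngd0` (count of days above 0).
#' @export
gdd_from_daily <- function(daily_tas) {
  if (length(daily_tas) == 0) stop("gdd_from_daily: empty series")
  if (!length(daily_tas) %in% c(365L, 366L))
    stop("gdd_from_daily: series must cover one year (365 or 366 days)")
  warm <- daily_tas > 0
  list(gdd0 = sum(daily_tas[warm]), ngd0 = sum(warm))
}

#' Mean growing-season temperature
#'
#' MGST = GDD0 / NGD0; undefined (returned as `NA`) where there is no
#' growing season (NGD0 = 0).
#'
#' @param gdd0 growing degree-day heat sum above 0 degC (degC day).
#' @param ngd0 number of days above 0 degC.
#' @return MGST in degrees C (vectorized); `NA` where `ngd0 = 0`.
#' @export
mgst <- function(gdd0, ngd0) {
  if (any(gdd0 > 0 & ngd0 == 0, na.rm = TRUE))
    stop("mgst: gdd0 > 0 with ngd0 = 0 is inconsistent")
  if (any(gdd0 < 0, na.rm = TRUE)) stop("mgst: gdd0 must be >= 0")
  out <- ifelse(ngd0 > 0, gdd0 / ngd0, NA_real_)
  out
}

#' Daily temperatures interpolated from monthly means
#'
#' Linear interpolation between month-midpoint means with periodic
#' wrap-around, used to derive GDD0/NGD0 where only monthly climate is
#' available.
#'
#' @param tas 12 monthly mean temperatures, degrees C.
#' @param n_days year length, 365 or 366.
#' @return numeric vector of `n_days` daily temperatures.
#' @export
daily_from_monthly <- function(tas, n_days = 365L) {
  if (length(tas) != 12) stop("daily_from_monthly: need 12 monthly values")
  mlen <- c(31, if (n_days == 366L) 29 else 28, 31, 30, 31, 30,
            31, 31, 30, 31, 30, 31)
  mid <- cumsum(mlen) - mlen / 2
  ## periodic extension: December before January, January after December
  x <- c(mid[12] - n_days, mid, mid[1] + n_days)
  y <- c(tas[12], tas, tas[1])
  stats::approx(x, y, xout = seq_len(n_days) - 0.5)$y
}

#' Bioclimatic variables for one location
#'
#' Computes the bioclim triple (ln MI, MTCO, MGST) from 12 monthly
#' values. PET may be supplied directly (e.g. from an external model) or
#' is derived from `srad` via [pet_priestley_taylor]. GDD0/NGD0 may be
#' supplied (as from pre-computed climatologies) or are derived from the
#' monthly temperatures via [daily_from_monthly].
#'
#' @param tas,pr 12 monthly mean temperatures (degC) and precipitation
#'   totals (mm).
#' @param pet,srad monthly PET (mm) or shortwave radiation (kJ/m2); one
#'   of the two is required.
#' @param gdd0,ngd0 optional pre-computed growing degree-day statistics.
#' @return list with `ln_mi`, `mtco`, `mgst`, plus `mi`, `gdd0`, `ngd0`.
#' @export
bioclim_point <- function(tas, pr, pet = NULL, srad = NULL,
                          gdd0 = NULL, ngd0 = NULL) {
  if (is.null(pet)) {
    if (is.null(srad))
      stop("bioclim_point: supply either pet or srad")
    pet <- pet_priestley_taylor(tas, srad)
  }
  mi <- moisture_index(pr, pet)
  if (is.null(gdd0) || is.null(ngd0)) {
    g <- gdd_from_daily(daily_from_monthly(tas))
    gdd0 <- g$gdd0; ngd0 <- g$ngd0
  }
  list(ln_mi = mi$ln_mi, mtco = mtco(tas), mgst = mgst(gdd0, ngd0),
       mi = mi$mi, gdd0 = gdd0, ngd0 = ngd0)
}

#' Bioclimatic variables on a grid
#'
#' Applies the per-location bioclim computation ([bioclim_point]) to
#' every cell of a [monthly_climate_grid], so the gridded and scalar
#' code paths agree exactly.
#'
#' @param climate a [monthly_climate_grid].
#' @return list of three [geogrid]s: `ln_mi`, `mtco`, `mgst`.
#' @export
bioclim_grid <- function(climate) {
  if (!inherits(climate, "climate_grid"))
    stop("bioclim_grid: climate must be a monthly_climate_grid")
  dims <- dim(climate$tas)
  ln_mi <- mt <- mg <- matrix(NA_real_, dims[1], dims[2])
  for (i in seq_len(dims[1])) {
    for (j in seq_len(dims[2])) {
      b <- bioclim_point(tas = climate$tas[i, j, ],
                         pr = climate$pr[i, j, ],
                         pet = if (is.null(climate$pet)) NULL
                               else climate$pet[i, j, ],
                         srad = if (is.null(climate$srad)) NULL
                                else climate$srad[i, j, ])
      ln_mi[i, j] <- b$ln_mi; mt[i, j] <- b$mtco; mg[i, j] <- b$mgst
    }
  }
  mk <- function(m, nm) geogrid(m, climate$xmin, climate$xmax,
                                climate$ymin, climate$ymax, name = nm)
  list(ln_mi = mk(ln_mi, "ln_mi"), mtco = mk(mt, "mtco"),
       mgst = mk(mg, "mgst"))
}

#' Bioclimatic variables at point locations on a climate grid
#'
#' @param climate a [monthly_climate_grid].
#' @param lon,lat point coordinates, degrees.
#' @return data.frame with columns `lon`, `lat`, `ln_mi`, `mtco`,
#'   `mgst`; points outside the grid give `NA` rows.
#' @export
bioclim_at_points <- function(climate, lon, lat) {
  g <- geogrid(climate$tas[, , 1], climate$xmin, climate$xmax,
               climate$ymin, climate$ymax)
  rc <- gg_cell(g, lon, lat)
  out <- data.frame(lon = lon, lat = lat, ln_mi = NA_real_,
                    mtco = NA_real_, mgst = NA_real_)
  for (k in seq_along(lon)) {
    if (is.na(rc[k, 1])) next
    i <- rc[k, 1]; j <- rc[k, 2]
    b <- bioclim_point(tas = climate$tas[i, j, ], pr = climate$pr[i, j, ],
                       pet = if (is.null(climate$pet)) NULL
                             else climate$pet[i, j, ],
                       srad = if (is.null(climate$srad)) NULL
                              else climate$srad[i, j, ])
    out$ln_mi[k] <- b$ln_mi; out$mtco[k] <- b$mtco; out$mgst[k] <- b$mgst
  }
  out
}
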