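# Seeded synthetic grids, meteorology, land surfaces and emission
# inventories with the statistical structure the simulator assumes:
# a latitudinal temperature gradient with a sinusoidal seasonal cycle,
# stochastic wet-day precipitation, prescribed wind regimes and clustered
# source-region emission patterns. Statistical, not dynamical: enough to
# exercise transport and the temperature/precipitation mechanisms, not a
# reanalysis stand-in.

#' Specification of a synthetic study setup
#'
#' Defaults define the standard test fixture: a 10 x 10 grid at 1 degree
#' resolution with a warm-to-cold meridional gradient compressing a
#' continental temperature span into the domain, prevailing westerlies
#' with a weak poleward component, and clustered sources in the warm
#' (southern) third of the domain.
#'
#' @param nlat,nlon,lat_min,lon_min,dlat,dlon Grid layout (see
#'   [grid_spec()]); synthetic default is a coarse 1-degree grid.
#' @param years Simulated years (365-day no-leap calendar).
#' @param seed Integer seed; fixed seed gives bit-reproducible fields.
#' @param temp_mean_warm_edge,temp_mean_cold_edge Annual-mean temperature
#'   (K) at the southern and northern domain edges.
#' @param temp_seasonal_amplitude Seasonal half-range, K (peak mid-July).
#' @param temp_noise_sd Daily temperature noise, K.
#' @param precip_mean Mean precipitation over all days, m/day.
#' @param wet_day_fraction Fraction of wet days.
#' @param wind_regime `"uniform"`, `"rotating"` or `"random-walk"`.
#' @param wind_u,wind_v Mean wind components, m/s (ALT winds are 1.5x).
#' @param source_pattern `"single-cell"`, `"clustered"` or `"banded"`.
#' @param n_clusters,cluster_size Clustered pattern: number of square
#'   clusters and their edge length (cells).
#' @param total_t_yr Domain-total emission, tonnes per year.
#' @param som_gradient Relative south-to-north change of surface SOM
#'   (e.g. 0.5 means the northern edge has 1.5x the southern SOM).
#' @return An object of class `synth_spec`.
#' @export
synth_spec <- function(nlat = 10, nlon = 10, lat_min = 20, lon_min = 100,
                       dlat = 1, dlon = 1, years = 5, seed = 1,
                       temp_mean_warm_edge = 296, temp_mean_cold_edge = 272,
                       temp_seasonal_amplitude = 10, temp_noise_sd = 2,
                       precip_mean = 0.003, wet_day_fraction = 0.3,
                       wind_regime = c("uniform", "rotating", "random-walk"),
                       wind_u = 3, wind_v = 1,
                       source_pattern = c("clustered", "single-cell", "banded"),
                       n_clusters = 2, cluster_size = 2,
                       total_t_yr = 50, som_gradient = 0) {
  wind_regime <- match.arg(wind_regime)
  source_pattern <- match.arg(source_pattern)
  if (years < 1) stop("years must be >= 1", call. = FALSE)
  if (wet_day_fraction <= 0 || wet_day_fraction > 1) {
    stop("wet_day_fraction must lie in (0, 1]", call. = FALSE)
  }
  if (precip_mean < 0 || total_t_yr < 0) {
    stop("precip_mean and total_t_yr must be >= 0", call. = FALSE)
  }
  structure(
    list(grid = grid_spec(lat_min, lon_min, nlat, nlon, dlat, dlon),
         years = as.integer(years), seed = as.integer(seed),
         temp_mean_warm_edge = temp_mean_warm_edge,
         temp_mean_cold_edge = temp_mean_cold_edge,
         temp_seasonal_amplitude = temp_seasonal_amplitude,
         temp_noise_sd = temp_noise_sd,
         precip_mean = precip_mean, wet_day_fraction = wet_day_fraction,
         wind_regime = wind_regime, wind_u = wind_u, wind_v = wind_v,
         source_pattern = source_pattern,
         n_clusters = as.integer(n_clusters),
         cluster_size = as.integer(cluster_size),
         total_t_yr = total_t_yr, som_gradient = som_gradient),
    class = "synth_spec"
  )
}

#' Generate synthetic daily gridded meteorology
#'
#' Temperature is a linear south-to-north gradient plus a sinusoidal
#' seasonal cycle (warmest mid-July) and iid daily noise. Precipitation is
#' drawn as Bernoulli wet days with exponential amounts whose mean matches
#' `precip_mean` overall. Winds follow the prescribed regime in both air
#' layers (ALT = 1.5 x ABL speed).
#'
#' @param spec A [synth_spec()].
#' @return An object of class `synth_met`: list of `[day, row, col]`
#'   arrays `temperature` (K), `precipitation` (m/day), `u_abl`, `v_abl`,
#'   `u_alt`, `v_alt` (m/s), plus `years`.
#' @export
synth_met <- function(spec) {
  stopifnot(inherits(spec, "synth_spec"))
  g <- spec$grid
  nr <- g$nlat; nc <- g$nlon
  ndays <- spec$years * 365L
  doy <- (seq_len(ndays) - 1L) %% 365L + 1L
  set.seed(spec$seed)

  frac <- if (nr > 1) (seq_len(nr) - 1) / (nr - 1) else 0
  t_lat <- spec$temp_mean_warm_edge +
    frac * (spec$temp_mean_cold_edge - spec$temp_mean_warm_edge)
  season <- spec$temp_seasonal_amplitude * cos(2 * pi * (doy - 196) / 365)
  temp <- array(rep(season, nr * nc) + rep(t_lat, each = ndays),
                dim = c(ndays, nr, nc))
  if (spec$temp_noise_sd > 0) {
    temp <- temp + array(stats::rnorm(ndays * nr * nc, 0, spec$temp_noise_sd),
                         dim = c(ndays, nr, nc))
  }

  wet <- array(stats::rbinom(ndays * nr * nc, 1L, spec$wet_day_fraction),
               dim = c(ndays, nr, nc))
  amount <- array(stats::rexp(ndays * nr * nc,
                              rate = spec$wet_day_fraction / max(spec$precip_mean, 1e-12)),
                  dim = c(ndays, nr, nc))
  precip <- wet * amount
  if (spec$precip_mean == 0) precip[] <- 0

  speed <- sqrt(spec$wind_u^2 + spec$wind_v^2)
  ang0 <- atan2(spec$wind_v, spec$wind_u)
  ang <- switch(spec$wind_regime,
    uniform = rep(ang0, ndays),
    rotating = ang0 + 2 * pi * (doy - 1) / 365,
    `random-walk` = ang0 + cumsum(stats::rnorm(ndays, 0, 0.15))
  )
  u_day <- speed * cos(ang)
  v_day <- speed * sin(ang)
  mk <- function(x) array(rep(x, nr * nc), dim = c(ndays, nr, nc))
  structure(list(temperature = temp, precipitation = precip,
                 u_abl = mk(u_day), v_abl = mk(v_day),
                 u_alt = mk(1.5 * u_day), v_alt = mk(1.5 * v_day),
                 years = spec$years),
            class = "synth_met")
}

#' Generate a synthetic gridded annual emission inventory
#'
#' Non-negative per-cell emissions (t/yr) summing exactly to the requested
#' domain total each year. Sources sit in the warm (southern) third of the
#' domain; non-source cells are exactly zero.
#'
#' @param spec A [synth_spec()].
#' @return `[year, row, col]` array of emissions, t/yr.
#' @export
synth_emissions <- function(spec) {
  stopifnot(inherits(spec, "synth_spec"))
  g <- spec$grid
  nr <- g$nlat; nc <- g$nlon
  set.seed(spec$seed + 1L)
  warm_rows <- seq_len(max(1L, ceiling(nr / 3)))
  w <- matrix(0, nr, nc)
  if (spec$total_t_yr == 0) {
    return(array(0, dim = c(spec$years, nr, nc)))
  }
  if (spec$source_pattern == "single-cell") {
    w[warm_rows[sample.int(length(warm_rows), 1L)], sample.int(nc, 1L)] <- 1
  } else if (spec$source_pattern == "banded") {
    w[seq_len(min(2L, nr)), ] <- 1
  } else {
    cs <- spec$cluster_size
    if (cs > nc || cs > nr) stop("cluster_size exceeds grid", call. = FALSE)
    anchors <- matrix(NA_integer_, 0L, 2L)
    tries <- 0L
    while (nrow(anchors) < spec$n_clusters) {
      tries <- tries + 1L
      if (tries > 1000L) stop("could not place disjoint clusters", call. = FALSE)
      rs <- warm_rows[warm_rows <= nr - cs + 1L]
      if (!length(rs)) stop("cluster_size exceeds the warm band", call. = FALSE)
      r <- rs[sample.int(length(rs), 1L)]
      c0 <- sample.int(nc - cs + 1L, 1L)
      if (nrow(anchors) &&
          any(abs(anchors[, 1] - r) < cs & abs(anchors[, 2] - c0) < cs)) next
      anchors <- rbind(anchors, c(r, c0))
    }
    for (a in seq_len(nrow(anchors))) {
      rows <- anchors[a, 1] + 0:(cs - 1L)
      cols <- anchors[a, 2] + 0:(cs - 1L)
      w[rows, cols] <- stats::rlnorm(cs * cs, 0, 0.5)
    }
  }
  if (sum(w) > 0) w <- w * spec$total_t_yr / sum(w)
  inv <- array(rep(w, each = spec$years),
               dim = c(spec$years, nr, nc))
  inv
}

#' Generate a synthetic land surface
#'
#' Uniform land-use composition across the domain with an optional
#' south-to-north gradient in surface SOM.
#'
#' @param spec A [synth_spec()].
#' @return An object of class `synth_land`: list with `fractions`
#'   (`[row, col, 7]`, soil types then water), `som` (`[row, col, 6]`
#'   surface SOM per soil type, g/g) and the scalar soil constants used by
#'   [cell_environment()].
#' @export
synth_landsurface <- function(spec) {
  stopifnot(inherits(spec, "synth_spec"))
  g <- spec$grid
  nr <- g$nlat; nc <- g$nlon
  base_fr <- c(urban = 0.05, dry_cropland = 0.30, paddy = 0.10,
               forest = 0.25, grassland = 0.15, uncultivated = 0.10,
               water = 0.05)
  base_som <- c(urban = 0.03, dry_cropland = 0.04, paddy = 0.05,
                forest = 0.08, grassland = 0.06, uncultivated = 0.02)
  fractions <- array(rep(base_fr, each = nr * nc), dim = c(nr, nc, 7L),
                     dimnames = list(NULL, NULL, names(base_fr)))
  frac_n <- if (nr > 1) (seq_len(nr) - 1) / (nr - 1) else 0
  scale <- 1 + spec$som_gradient * frac_n
  som <- array(0, dim = c(nr, nc, 6L),
               dimnames = list(NULL, NULL, SOIL_TYPES))
  for (t in 1:6) som[, , t] <- outer(scale * base_som[[t]], rep(1, nc))
  som <- pmin(som, 1)
  structure(list(fractions = fractions, som = som,
                 soil_layer_depths = c(0.001, 0.01, 0.20, 0.50),
                 soil_density = 2500,
                 soil_porosity_air = 0.2, soil_porosity_water = 0.3,
                 aerosol_volume_fraction = 2e-11,
                 water_depth = 3, sediment_depth = 0.05,
                 sediment_porosity = 0.8, sediment_oc = 0.03),
            class = "synth_land")
}

#' Cell environment for one grid cell of a synthetic land surface
#'
#' @param land A [synth_landsurface()] result.
#' @param grid The matching [grid_spec()].
#' @param row,col Cell indices (row 1 = south).
#' @return A [cell_environment()].
#' @export
land_cell_environment <- function(land, grid, row, col) {
  stopifnot(inherits(land, "synth_land"), inherits(grid, "grid_spec"))
  fr <- land$fractions[row, col, ]
  cell_environment(
    cell_area = grid$cell_area[row],
    land_use_fractions = stats::setNames(as.numeric(fr), dimnames(land$fractions)[[3]]),
    soil_layer_depths = land$soil_layer_depths,
    soil_som = stats::setNames(as.numeric(land$som[row, col, ]), SOIL_TYPES),
    soil_density = land$soil_density,
    soil_porosity_air = land$soil_porosity_air,
    soil_porosity_water = land$soil_porosity_water,
    aerosol_volume_fraction = land$aerosol_volume_fraction,
    water_depth = land$water_depth,
    sediment_depth = land$sediment_depth,
    sediment_porosity = land$sediment_porosity,
    sediment_oc = land$sediment_oc
  )
}
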