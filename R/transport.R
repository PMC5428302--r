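# Horizontal wind-driven advection of the atmospheric layers across the
# grid. First-order upwind finite volume on amounts (mol), which is
# positivity-preserving and conserves mass to round-off; open outflow /
# zero inflow boundaries with the exported mass returned to the caller.

EARTH_RADIUS <- 6371000 # m

#' Regular latitude-longitude grid specification
#'
#' Rows are ordered south to north (row 1 at `lat_min`), columns west to
#' east. Cell metrics use spherical geometry at the cell-center latitude.
#'
#' @param lat_min,lon_min Southern and western domain edges, degrees.
#' @param nlat,nlon Number of rows and columns.
#' @param dlat,dlon Cell size in degrees (defaults 1/6 and 1/4).
#' @return An object of class `grid_spec` with cell-center coordinates
#'   (`lat`, `lon`), per-row cell widths `dx` (zonal, m), `dy`
#'   (meridional, m) and per-row `cell_area` (m^2).
#' @export
grid_spec <- function(lat_min, lon_min, nlat, nlon,
                      dlat = 1 / 6, dlon = 1 / 4) {
  if (nlat < 1 || nlon < 1 || nlat != round(nlat) || nlon != round(nlon)) {
    stop("nlat and nlon must be positive integers", call. = FALSE)
  }
  if (dlat <= 0 || dlon <= 0) stop("dlat/dlon must be positive", call. = FALSE)
  lat <- lat_min + (seq_len(nlat) - 0.5) * dlat
  lon <- lon_min + (seq_len(nlon) - 0.5) * dlon
  if (max(abs(lat)) >= 90) stop("grid extends beyond the pole", call. = FALSE)
  rad <- pi / 180
  dy <- EARTH_RADIUS * dlat * rad
  dx <- EARTH_RADIUS * dlon * rad * cos(lat * rad)
  area <- dx * dy
  structure(list(lat_min = lat_min, lon_min = lon_min,
                 nlat = as.integer(nlat), nlon = as.integer(nlon),
                 dlat = dlat, dlon = dlon,
                 lat = lat, lon = lon, dx = dx, dy = dy,
                 cell_area = area),
            class = "grid_spec")
}

#' Upwind advection of an air-layer tracer field
#'
#' One day of first-order upwind finite-volume transport of per-cell
#' amounts under a cell-centered wind field. Face velocities are the
#' average of the two adjacent cells; the donor cell supplies the flux.
#' Internal sub-stepping enforces a Courant limit (`params$cfl`). Domain
#' boundaries are open: outflow is accumulated and returned, inflow is
#' zero (clean far-field air).
#'
#' @param field `nlat x nlon` matrix of amounts, mol (row 1 = south).
#' @param u,v `nlat x nlon` matrices of zonal (east positive) and
#'   meridional (north positive) wind, m/s.
#' @param grid A [grid_spec()].
#' @param dt Step, days.
#' @param params [model_params()] (Courant limit).
#' @return List with `field` (advected amounts) and `boundary_export`
#'   (mol leaving the domain during the step).
#' @export
advect <- function(field, u, v, grid, dt = 1, params = model_params()) {
  stopifnot(inherits(grid, "grid_spec"))
  nr <- grid$nlat; nc <- grid$nlon
  if (!all(dim(field) == c(nr, nc)) || !all(dim(u) == c(nr, nc)) ||
      !all(dim(v) == c(nr, nc))) {
    stop("field/u/v must all be nlat x nlon matrices", call. = FALSE)
  }
  if (any(!is.finite(u)) || any(!is.finite(v))) {
    stop("wind field contains non-finite values", call. = FALSE)
  }
  if (any(!is.finite(field)) || any(field < 0)) {
    stop("tracer amounts must be finite and >= 0", call. = FALSE)
  }
  secs <- dt * 86400
  dx <- grid$dx # per row
  cour <- max(abs(u) / dx + abs(v) / grid$dy) * secs
  nsub <- max(1L, ceiling(cour / params$cfl - 1e-9))
  dts <- secs / nsub
  export <- 0
  n <- field
  for (k in seq_len(nsub)) {
    # zonal interior faces: face j sits between columns j and j+1
    if (nc > 1L) {
      uf <- 0.5 * (u[, -nc, drop = FALSE] + u[, -1L, drop = FALSE])
      cpos <- pmax(uf, 0) * dts / dx
      cneg <- pmin(uf, 0) * dts / dx
      fe <- cpos * n[, -nc, drop = FALSE] + cneg * n[, -1L, drop = FALSE]
    } else {
      fe <- matrix(0, nr, 0L)
    }
    out_w <- pmax(-u[, 1L], 0) * dts / dx * n[, 1L]
    out_e <- pmax(u[, nc], 0) * dts / dx * n[, nc]
    # meridional interior faces: face i between rows i and i+1
    if (nr > 1L) {
      vf <- 0.5 * (v[-nr, , drop = FALSE] + v[-1L, , drop = FALSE])
      fn <- pmax(vf, 0) * dts / grid$dy * n[-nr, , drop = FALSE] +
        pmin(vf, 0) * dts / grid$dy * n[-1L, , drop = FALSE]
    } else {
      fn <- matrix(0, 0L, nc)
    }
    out_s <- pmax(-v[1L, ], 0) * dts / grid$dy * n[1L, ]
    out_n <- pmax(v[nr, ], 0) * dts / grid$dy * n[nr, ]

    div <- matrix(0, nr, nc)
    if (nc > 1L) {
      div[, -nc] <- div[, -nc, drop = FALSE] + fe
      div[, -1L] <- div[, -1L, drop = FALSE] - fe
    }
    if (nr > 1L) {
      div[-nr, ] <- div[-nr, , drop = FALSE] + fn
      div[-1L, ] <- div[-1L, , drop = FALSE] - fn
    }
    div[, 1L] <- div[, 1L] + out_w
    div[, nc] <- div[, nc] + out_e
    div[1L, ] <- div[1L, ] + out_s
    div[nr, ] <- div[nr, ] + out_n
    n <- n - div
    export <- export + sum(out_w) + sum(out_e) + sum(out_s) + sum(out_n)
  }
  list(field = n, boundary_export = export)
}

#' Vertical exchange between the two air layers of one cell
#'
#' Conservative two-box relaxation of the ABL and ALT amounts toward
#' fugacity equality, solved in closed form (exact exponential decay of
#' the fugacity difference at rate D_vert * (1/V1Z1 + 1/V2Z2)).
#'
#' @param abl,alt Amounts in the two layers, mol (>= 0).
#' @param env A [cell_environment()].
#' @param chem A [chemical_profile()].
#' @param T Temperature, K.
#' @param dt Step, days.
#' @param params [model_params()] (`abl_alt_exchange_vel`).
#' @return Numeric vector `c(abl, alt)` with the sum preserved exactly.
#' @export
vertical_exchange <- function(abl, alt, env, chem, T, dt = 1,
                              params = model_params()) {
  stopifnot(inherits(env, "cell_environment"),
            inherits(chem, "chemical_profile"))
  if (abl < 0 || alt < 0) stop("amounts must be >= 0", call. = FALSE)
  z_gas <- 1 / (R_GAS * T)
  z1 <- z_gas + env$aerosol_volume_fraction *
    .z_aerosol(chem, T, z_gas, params)
  vz1 <- env$cell_area * env$air_layer_heights[1] * z1
  vz2 <- env$cell_area * env$air_layer_heights[2] * z_gas
  d <- params$abl_alt_exchange_vel * env$cell_area * z_gas
  total <- abl + alt
  eq1 <- total * vz1 / (vz1 + vz2)
  lam <- d * (1 / vz1 + 1 / vz2)
  abl_new <- eq1 + (abl - eq1) * exp(-lam * dt * 24)
  c(abl = abl_new, alt = total - abl_new)
}
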