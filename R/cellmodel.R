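# Per-grid-cell level-IV fugacity dynamics: fugacity capacities (Z),
# transfer/loss conductances (D), and implicit one-day state updates.
#
# Compartment layout (28 scalars per cell):
#   1 air_abl, 2 air_alt, 3 water, 4 sediment,
#   4 + (type-1)*4 + layer  for 6 soil types x 4 vertical layers.
# Conductances are held in a matrix K with K[i, j] = D-value for transfer
# j -> i (mol Pa-1 h-1); fluxes are D * f.

SOIL_TYPES <- c("urban", "dry_cropland", "paddy", "forest",
                "grassland", "uncultivated")

#' Compartment names of a cell
#'
#' @return Character vector of the 28 compartment labels in model order.
#' @export
compartment_names <- function() {
  c("air_abl", "air_alt", "water", "sediment",
    paste0("soil_", rep(SOIL_TYPES, each = 4), "_L", rep(1:4, times = 6)))
}

.idx_soil <- function(type, layer) 4L + (type - 1L) * 4L + layer

#' Numerical and process parameters of the transfer model
#'
#' Every rate constant the transfer system uses is a named entry here so a
#' run can be reconfigured without touching code. Units in parentheses.
#'
#' @param ... Named overrides of the defaults; unknown names are rejected.
#' @return Named list of parameters:
#' \describe{
#'   \item{k_air_side}{air-side mass-transfer coefficient over soil and
#'     water surfaces (m/h), default 3}
#'   \item{k_water_side}{water-side MTC of the air-water interface (m/h),
#'     default 0.03}
#'   \item{diff_air, diff_water}{molecular diffusivities in air and water
#'     (m^2/h), defaults 0.04 and 4e-6; reduced in soil by a
#'     Millington-Quirk tortuosity factor}
#'   \item{dry_dep_vel}{dry particle deposition velocity (m/h), default 10.8}
#'   \item{scavenging_ratio}{wet particle scavenging ratio (-), default 2e5}
#'   \item{leach_frac}{fraction of precipitation that percolates downward
#'     through the soil column (-), default 0.3}
#'   \item{soil_mixing_diff}{bulk-phase mixing diffusivity between soil
#'     layers from bioturbation and cultivation (m^2/h), default 1e-7
#'     (about 0.9e-3 m^2/yr); couples the thin surface layer to the
#'     sub-surface reservoir}
#'   \item{abl_alt_exchange_vel}{ABL-ALT exchange velocity (m/h), default 36}
#'   \item{burial_rate_m_yr}{sediment burial rate (m/yr), default 1e-4}
#'   \item{sed_diff_mtc}{water-sediment diffusive MTC (m/h), default 4e-4}
#'   \item{f_om_aerosol}{organic-matter fraction of aerosol (-), default 0.2}
#'   \item{rho_aerosol}{aerosol particle density (kg/m^3), default 1500}
#'   \item{emission_frac_air}{fraction of primary emissions entering the
#'     ABL air (remainder to surface soil), default 1}
#'   \item{cfl}{advection Courant limit used for sub-stepping, default 1
#'     (the stability and positivity limit of first-order upwind; a
#'     Courant number of exactly 1 translates a pulse by one cell
#'     exactly)}
#' }
#' @export
model_params <- function(...) {
  p <- list(
    k_air_side = 3,
    k_water_side = 0.03,
    diff_air = 0.04,
    diff_water = 4e-6,
    dry_dep_vel = 10.8,
    scavenging_ratio = 2e5,
    leach_frac = 0.3,
    soil_mixing_diff = 1e-7,
    abl_alt_exchange_vel = 36,
    burial_rate_m_yr = 1e-4,
    sed_diff_mtc = 4e-4,
    f_om_aerosol = 0.2,
    rho_aerosol = 1500,
    emission_frac_air = 1,
    cfl = 1
  )
  ov <- list(...)
  if (length(ov)) {
    unknown <- setdiff(names(ov), names(p))
    if (length(unknown) || is.null(names(ov)) || any(!nzchar(names(ov)))) {
      stop("unknown model parameter(s): ",
           paste(unknown, collapse = ", "), call. = FALSE)
    }
    p[names(ov)] <- ov
  }
  p
}

#' Soil organic carbon from soil organic matter
#'
#' SOC is estimated as 0.56 of the SOM mass fraction.
#'
#' @param som Soil organic matter, g/g (in \[0, 1\]); vectorized.
#' @return Soil organic carbon, g/g.
#' @export
soc_from_som <- function(som) {
  if (any(!is.finite(som)) || any(som < 0 | som > 1)) {
    stop("SOM must lie in [0, 1] (g organic matter per g soil)", call. = FALSE)
  }
  0.56 * som
}

#' Static geometry and composition of one grid cell
#'
#' @param cell_area Cell area, m^2.
#' @param land_use_fractions Named fractions over the six soil types plus
#'   `water`; must sum to 1.
#' @param soil_layer_depths Depths of the four vertical soil layers, m.
#' @param soil_som Either a 6 x 4 matrix of SOM (g/g, soil type x layer) or
#'   a length-6 vector of surface SOM expanded down the column with the
#'   default attenuation profile (1, 1, 0.6, 0.3).
#' @param soil_density Density of soil solids, kg/m^3.
#' @param soil_porosity_air,soil_porosity_water Volumetric air and water
#'   contents of soil; together with the solid fraction they sum to 1.
#' @param air_layer_heights Heights of the ABL and ALT air layers, m.
#' @param aerosol_volume_fraction Volume fraction of aerosol in ABL air.
#' @param water_depth,sediment_depth Water column and active sediment
#'   depths, m.
#' @param sediment_porosity Sediment water-volume fraction.
#' @param sediment_oc Organic-carbon fraction of sediment solids, g/g.
#' @return An object of class `cell_environment`.
#' @export
cell_environment <- function(cell_area = 1.1e10,
                             land_use_fractions = c(
                               urban = 0.05, dry_cropland = 0.30,
                               paddy = 0.10, forest = 0.25,
                               grassland = 0.15, uncultivated = 0.10,
                               water = 0.05),
                             soil_layer_depths = c(0.001, 0.01, 0.20, 0.50),
                             soil_som = c(urban = 0.03, dry_cropland = 0.04,
                                          paddy = 0.05, forest = 0.08,
                                          grassland = 0.06,
                                          uncultivated = 0.02),
                             soil_density = 2500,
                             soil_porosity_air = 0.2,
                             soil_porosity_water = 0.3,
                             air_layer_heights = c(1000, 3000),
                             aerosol_volume_fraction = 2e-11,
                             water_depth = 3,
                             sediment_depth = 0.05,
                             sediment_porosity = 0.8,
                             sediment_oc = 0.03) {
  want <- c(SOIL_TYPES, "water")
  if (is.null(names(land_use_fractions)) ||
      !setequal(names(land_use_fractions), want)) {
    stop("land_use_fractions must be named over: ",
         paste(want, collapse = ", "), call. = FALSE)
  }
  land_use_fractions <- land_use_fractions[want]
  if (any(land_use_fractions < 0)) {
    stop("land-use fractions must be non-negative", call. = FALSE)
  }
  if (abs(sum(land_use_fractions) - 1) > 1e-9) {
    stop("land-use fractions must sum to 1 (got ",
         format(sum(land_use_fractions)), ")", call. = FALSE)
  }
  if (length(soil_layer_depths) != 4L || any(soil_layer_depths <= 0)) {
    stop("soil_layer_depths must be 4 positive depths (m)", call. = FALSE)
  }
  if (is.matrix(soil_som)) {
    if (!all(dim(soil_som) == c(6L, 4L))) {
      stop("soil_som matrix must be 6 soil types x 4 layers", call. = FALSE)
    }
  } else {
    if (length(soil_som) != 6L) {
      stop("soil_som must be a 6x4 matrix or a length-6 surface vector",
           call. = FALSE)
    }
    soil_som <- outer(as.numeric(soil_som), c(1, 1, 0.6, 0.3))
  }
  dimnames(soil_som) <- list(SOIL_TYPES, paste0("L", 1:4))
  if (any(soil_som < 0 | soil_som > 1)) {
    stop("SOM fractions must lie in [0, 1]", call. = FALSE)
  }
  solid <- 1 - soil_porosity_air - soil_porosity_water
  if (soil_porosity_air < 0 || soil_porosity_water < 0 || solid <= 0 ||
      abs(soil_porosity_air + soil_porosity_water + solid - 1) > 1e-9) {
    stop("soil porosities and solid fraction must be in [0,1] and sum to 1",
         call. = FALSE)
  }
  if (cell_area <= 0 || any(air_layer_heights <= 0) || water_depth <= 0 ||
      sediment_depth <= 0 || soil_density <= 0) {
    stop("areas, heights, depths and density must be strictly positive",
         call. = FALSE)
  }
  if (sediment_porosity <= 0 || sediment_porosity >= 1) {
    stop("sediment_porosity must lie in (0, 1)", call. = FALSE)
  }
  structure(
    list(cell_area = cell_area,
         land_use_fractions = land_use_fractions,
         soil_layer_depths = soil_layer_depths,
         soil_som = soil_som,
         soil_density = soil_density,
         soil_porosity_air = soil_porosity_air,
         soil_porosity_water = soil_porosity_water,
         soil_solid_fraction = solid,
         air_layer_heights = air_layer_heights,
         aerosol_volume_fraction = aerosol_volume_fraction,
         water_depth = water_depth,
         sediment_depth = sediment_depth,
         sediment_porosity = sediment_porosity,
         sediment_oc = sediment_oc),
    class = "cell_environment"
  )
}

#' Daily forcing of one cell
#'
#' @param temperature Air/surface temperature, K.
#' @param precipitation Precipitation, m/day (>= 0).
#' @param emission_to_air,emission_to_soil Primary emissions, mol/day (>= 0).
#' @return An object of class `cell_forcing`.
#' @export
cell_forcing <- function(temperature, precipitation = 0,
                         emission_to_air = 0, emission_to_soil = 0) {
  if (!is.finite(temperature) || temperature <= 0) {
    stop("temperature must be positive (K)", call. = FALSE)
  }
  if (precipitation < 0) stop("precipitation must be >= 0", call. = FALSE)
  if (emission_to_air < 0 || emission_to_soil < 0) {
    stop("emissions must be >= 0", call. = FALSE)
  }
  structure(list(temperature = temperature, precipitation = precipitation,
                 emission_to_air = emission_to_air,
                 emission_to_soil = emission_to_soil),
            class = "cell_forcing")
}

# Aerosol fugacity capacity per m^3 of particle material. Koa route
# (log Kp = log10(Koa * f_om) - 11.91, Kp in m^3/ug) when log_koa is
# available, otherwise a Junge-style fall-back from the liquid vapor
# pressure (Z_Q/Z_air = 6e6 / Vp(T)).
.z_aerosol <- function(chem, T, z_gas, params) {
  if (is.finite(chem$log_koa)) {
    koa_T <- 10^chem$log_koa * exp(chem$dU_vap / R_GAS * (1 / T - 1 / chem$T_ref))
    kp <- 10^(log10(koa_T * params$f_om_aerosol) - 11.91) # m^3 air / ug
    z_gas * kp * params$rho_aerosol * 1e9                 # ug per m^3 particle
  } else {
    z_gas * 6e6 / .vant_hoff(chem$vapor_pressure, chem$dU_vap, T, chem$T_ref)
  }
}

#' Fugacity capacity of a compartment phase
#'
#' @param chem A [chemical_profile()].
#' @param compartment One of `"air_gas"`, `"air_bulk"`, `"aerosol"`,
#'   `"water"`, `"soil_solids"`, `"soil_bulk"`, `"sediment"`.
#' @param env A [cell_environment()].
#' @param T Temperature, K.
#' @param soil_type,layer Soil type index (1-6) and layer (1-4), used for
#'   the soil compartments.
#' @param params [model_params()] (aerosol constants).
#' @return Fugacity capacity, mol m-3 Pa-1.
#' @export
z_value <- function(chem, compartment, env, T,
                    soil_type = 1L, layer = 1L, params = model_params()) {
  stopifnot(inherits(chem, "chemical_profile"),
            inherits(env, "cell_environment"))
  if (!is.finite(T) || T <= 0) stop("T must be positive (K)", call. = FALSE)
  z_gas <- 1 / (R_GAS * T)
  z_wat <- 1 / henry_constant(chem, T)
  z_sol <- function(oc) oc * chem$koc * env$soil_density * z_wat / 1000
  switch(compartment,
    air_gas = z_gas,
    aerosol = .z_aerosol(chem, T, z_gas, params),
    air_bulk = z_gas + env$aerosol_volume_fraction *
      .z_aerosol(chem, T, z_gas, params),
    water = z_wat,
    soil_solids = z_sol(soc_from_som(env$soil_som[soil_type, layer])),
    soil_bulk = env$soil_porosity_air * z_gas +
      env$soil_porosity_water * z_wat +
      env$soil_solid_fraction * z_sol(soc_from_som(env$soil_som[soil_type, layer])),
    sediment = env$sediment_porosity * z_wat +
      (1 - env$sediment_porosity) * env$sediment_oc * chem$koc *
        env$soil_density * z_wat / 1000,
    stop("unknown compartment '", compartment, "'", call. = FALSE)
  )
}

#' Compartment volumes of a cell
#'
#' @param env A [cell_environment()].
#' @return Named numeric vector of the 28 compartment volumes, m^3. Soil
#'   and water compartments with zero land-use fraction have zero volume
#'   and are treated as inactive by the solver.
#' @export
cell_volumes <- function(env) {
  stopifnot(inherits(env, "cell_environment"))
  fr <- env$land_use_fractions
  a_t <- env$cell_area * fr[SOIL_TYPES]
  a_w <- env$cell_area * fr[["water"]]
  v <- numeric(28L)
  v[1] <- env$cell_area * env$air_layer_heights[1]
  v[2] <- env$cell_area * env$air_layer_heights[2]
  v[3] <- a_w * env$water_depth
  v[4] <- a_w * env$sediment_depth
  for (t in 1:6) v[.idx_soil(t, 1:4)] <- a_t[t] * env$soil_layer_depths
  names(v) <- compartment_names()
  v
}

# Precompute every temperature-independent coefficient of the transfer
# system for one cell. Returned as an environment so the conductance
# matrix K can be reused across days without reallocation.
.cell_precomp <- function(chem, env, params) {
  pre <- new.env(parent = emptyenv())
  fr <- env$land_use_fractions
  a_t <- env$cell_area * as.numeric(fr[SOIL_TYPES])
  a_w <- env$cell_area * fr[["water"]]
  d <- env$soil_layer_depths
  phi_a <- env$soil_porosity_air
  phi_w <- env$soil_porosity_water
  phi_t <- phi_a + phi_w
  mq_a <- if (phi_a > 0) phi_a^(10 / 3) / phi_t^2 else 0
  mq_w <- if (phi_w > 0) phi_w^(10 / 3) / phi_t^2 else 0

  pre$V <- unname(cell_volumes(env))
  pre$act <- pre$V > 0
  pre$area <- env$cell_area
  pre$a_t <- a_t
  pre$a_w <- a_w
  pre$vq <- env$aerosol_volume_fraction
  pre$phi_a <- phi_a
  pre$phi_w <- phi_w
  pre$phi_s <- env$soil_solid_fraction

  # soil solid Z coefficient (x Z_water), ordered layer-fastest per type
  soc <- soc_from_som(env$soil_som)
  pre$zs_coef <- as.vector(t(soc)) * chem$koc * env$soil_density / 1000
  pre$zsed_coef <- env$sediment_porosity +
    (1 - env$sediment_porosity) * env$sediment_oc * chem$koc *
      env$soil_density / 1000 # x Z_water

  # air <-> soil layer 1: air-side film in series with soil diffusion
  l1half <- d[1] / 2
  pre$g_as_air <- params$k_air_side * a_t
  pre$g_as_soil_a <- a_t * params$diff_air * mq_a / l1half
  pre$g_as_soil_w <- a_t * params$diff_water * mq_w / l1half
  # soil layer l <-> l+1 diffusion (midpoint-to-midpoint path)
  path <- (d[1:3] + d[2:4]) / 2
  pre$g_ll_a <- outer(a_t, params$diff_air * mq_a / path)   # 6 x 3
  pre$g_ll_w <- outer(a_t, params$diff_water * mq_w / path)
  pre$g_ll_mix <- outer(a_t, params$soil_mixing_diff / path) # x bulk Z
  # one-way depositional pathways (x rain and/or Z terms daily)
  pre$g_dry <- params$dry_dep_vel * a_t * pre$vq
  pre$g_wet <- a_t * pre$vq * params$scavenging_ratio
  pre$g_rain <- a_t
  pre$g_leach <- a_t * params$leach_frac
  pre$g_dry_w <- params$dry_dep_vel * a_w * pre$vq
  pre$g_wet_w <- a_w * pre$vq * params$scavenging_ratio
  pre$g_rain_w <- a_w
  # air <-> water two-film
  pre$g_aw_air <- params$k_air_side * a_w
  pre$g_aw_wat <- params$k_water_side * a_w
  # water <-> sediment, burial, ABL <-> ALT
  pre$g_ws <- params$sed_diff_mtc * a_w
  pre$g_bur <- params$burial_rate_m_yr / 8760 * a_w
  pre$g_vert <- params$abl_alt_exchange_vel * env$cell_area

  # degradation: reference rate per compartment (Arrhenius-corrected daily)
  cls <- c("air", "air", "water", "sediment", rep("soil", 24L))
  missing <- setdiff(unique(cls[pre$act]), names(chem$half_life))
  if (length(missing)) {
    stop("chemical profile lacks half-life for class(es): ",
         paste(missing, collapse = ", "), call. = FALSE)
  }
  hl <- chem$half_life[cls]
  hl[is.na(hl)] <- Inf
  pre$k_ref <- log(2) / unname(hl)

  # index bookkeeping
  pre$i_s1 <- .idx_soil(1:6, 1L)
  pre$i_s4 <- .idx_soil(1:6, 4L)
  pre$i_up <- cbind(rep(.idx_soil(1:6, 1L), 3) + rep(0:2, each = 6),
                    rep(.idx_soil(1:6, 1L), 3) + rep(1:3, each = 6))
  pre$i_dn <- pre$i_up[, 2:1]
  pre$K <- matrix(0, 28L, 28L)
  pre
}

# Assemble the daily transfer system into pre$K (in place) and return the
# day's Z, VZ, losses and source. All conductances in mol Pa-1 h-1.
.assemble_day <- function(pre, chem, params, T, precip,
                          emis_air_mol_day, emis_soil_mol_day) {
  z_gas <- 1 / (R_GAS * T)
  h <- henry_constant(chem, T)
  z_wat <- 1 / h
  z_q <- if (pre$vq > 0) .z_aerosol(chem, T, z_gas, params) else 0
  z_soil <- pre$phi_a * z_gas + pre$phi_w * z_wat + pre$phi_s * pre$zs_coef * z_wat

  Z <- numeric(28L)
  Z[1] <- z_gas + pre$vq * z_q
  Z[2] <- z_gas
  Z[3] <- z_wat
  Z[4] <- pre$zsed_coef * z_wat
  Z[5:28] <- z_soil
  VZ <- pre$V * Z

  rain <- precip / 24 # m/h
  K <- pre$K

  # air <-> soil (layer 1), per soil type
  d_air <- pre$g_as_air * z_gas
  d_soil <- pre$g_as_soil_a * z_gas + pre$g_as_soil_w * z_wat
  d_diff <- ifelse(d_air > 0 & d_soil > 0,
                   1 / (1 / pmax(d_air, 1e-300) + 1 / pmax(d_soil, 1e-300)), 0)
  d_dep <- pre$g_dry * z_q + rain * (pre$g_wet * z_q + pre$g_rain * z_wat)
  K[cbind(pre$i_s1, 1L)] <- d_diff + d_dep
  K[cbind(1L, pre$i_s1)] <- d_diff

  # soil layer <-> layer: pore diffusion + bulk mixing (bioturbation,
  # cultivation; mean of the adjacent bulk capacities keeps D symmetric)
  # + downward leaching advection
  zb <- matrix(z_soil, nrow = 4L) # layer x type
  zb_pair <- t((zb[1:3, , drop = FALSE] + zb[2:4, , drop = FALSE]) / 2)
  d_ll <- as.vector(pre$g_ll_a * z_gas + pre$g_ll_w * z_wat +
                      pre$g_ll_mix * zb_pair)
  d_leach <- rain * pre$g_leach * z_wat # same percolation flux at all depths
  K[pre$i_dn] <- d_ll + rep(d_leach, 3)
  K[pre$i_up] <- d_ll

  # air <-> water
  if (pre$a_w > 0) {
    d_aw <- 1 / (1 / (pre$g_aw_air * z_gas) + 1 / (pre$g_aw_wat * z_wat))
    K[3L, 1L] <- d_aw + pre$g_dry_w * z_q +
      rain * (pre$g_wet_w * z_q + pre$g_rain_w * z_wat)
    K[1L, 3L] <- d_aw
    d_ws <- pre$g_ws * z_wat
    K[4L, 3L] <- d_ws
    K[3L, 4L] <- d_ws
  }

  # ABL <-> ALT
  d_v <- pre$g_vert * z_gas
  K[2L, 1L] <- d_v
  K[1L, 2L] <- d_v

  # losses
  arr <- exp(chem$Ea_deg / R_GAS * (1 / chem$T_ref - 1 / T))
  loss_deg <- pre$k_ref * arr * VZ
  loss_leach <- numeric(28L)
  loss_leach[pre$i_s4] <- rain * pre$g_leach * z_wat
  loss_bur <- numeric(28L)
  loss_bur[4L] <- pre$g_bur * Z[4]

  s <- numeric(28L)
  s[1L] <- emis_air_mol_day / 24
  if (emis_soil_mol_day > 0) {
    at <- sum(pre$a_t)
    if (at <= 0) stop("soil emission requested but cell has no soil area",
                      call. = FALSE)
    s[pre$i_s1] <- emis_soil_mol_day / 24 * pre$a_t / at
  }

  list(K = K, Z = Z, VZ = VZ, out = colSums(K),
       loss_deg = loss_deg, loss_leach = loss_leach, loss_bur = loss_bur,
       s = s, act = pre$act, i_s1 = pre$i_s1)
}

# One implicit (backward) Euler step of the cell system; f in Pa, dt in
# hours. Returns the new fugacity vector (inactive compartments stay 0).
.solve_step <- function(sys, f, dt_h) {
  B <- -sys$K
  diag(B) <- sys$VZ / dt_h + sys$out +
    sys$loss_deg + sys$loss_leach + sys$loss_bur
  rhs <- sys$VZ * f / dt_h + sys$s
  f_new <- numeric(length(f))
  act <- sys$act
  f_new[act] <- tryCatch(
    solve(B[act, act, drop = FALSE], rhs[act]),
    error = function(e) stop("cell transfer system is singular ",
                             "(degenerate environment?): ",
                             conditionMessage(e), call. = FALSE))
  f_new
}

.flux_report <- function(sys, f_new, dt_h) {
  i_s1 <- sys$i_s1
  list(
    emission_in = sum(sys$s) * dt_h,
    deposition_air_to_soil = f_new[1L] * sum(sys$K[i_s1, 1L]) * dt_h,
    volatilization_soil_to_air = sum(sys$K[1L, i_s1] * f_new[i_s1]) * dt_h,
    deposition_air_to_water = f_new[1L] * sys$K[3L, 1L] * dt_h,
    degradation = sum(sys$loss_deg * f_new) * dt_h,
    leaching_out = sum(sys$loss_leach * f_new) * dt_h,
    burial = sum(sys$loss_bur * f_new) * dt_h
  )
}

#' Build the transfer system of one cell for one day's conditions
#'
#' Assembles the fugacity-capacity vector, the inter-compartment D-value
#' matrix and the first-order loss conductances (degradation everywhere,
#' deep leaching out of soil layer 4, sediment burial) for the cell's 28
#' compartments under the given forcing. Pathways: air-soil diffusion
#' (air film in series with Millington-Quirk soil diffusion), dry particle
#' deposition, wet particle scavenging and rain dissolution (air to
#' surfaces, apportioned by land-use fraction), soil volatilization, soil
#' layer-layer diffusion plus downward leaching advection, air-water
#' two-film exchange, water-sediment diffusion, sediment burial, and
#' ABL-ALT exchange.
#'
#' @param chem A [chemical_profile()].
#' @param env A [cell_environment()].
#' @param forcing A [cell_forcing()].
#' @param params A [model_params()] list.
#' @return An object of class `transfer_system`: list with the conductance
#'   matrix `K` (`K[i, j]` = D for transfer j -> i, mol Pa-1 h-1), total
#'   outflow conductance `out`, loss vectors `loss_deg`, `loss_leach`,
#'   `loss_bur`, source vector `s` (mol/h), fugacity capacities `Z`,
#'   volume-capacity products `VZ`, and the active-compartment mask `act`.
#' @export
build_transfer_system <- function(chem, env, forcing,
                                  params = model_params()) {
  stopifnot(inherits(chem, "chemical_profile"),
            inherits(env, "cell_environment"))
  if (!inherits(forcing, "cell_forcing")) {
    forcing <- do.call(cell_forcing, as.list(forcing))
  }
  pre <- .cell_precomp(chem, env, params)
  sys <- .assemble_day(pre, chem, params,
                       T = forcing$temperature,
                       precip = forcing$precipitation,
                       emis_air_mol_day = forcing$emission_to_air,
                       emis_soil_mol_day = forcing$emission_to_soil)
  sys$K <- sys$K + 0 # detach from the reusable buffer
  sys$labels <- compartment_names()
  sys$V <- pre$V
  class(sys) <- "transfer_system"
  sys
}

#' Advance one cell by one implicit-Euler step
#'
#' Backward Euler over `dt` days: unconditionally stable for the stiff
#' cell system at daily steps and, given the sign structure of the system
#' (non-negative off-diagonals, non-positive diagonal), non-negativity
#' preserving for any step size.
#'
#' @param state Numeric vector of 28 compartment fugacities, Pa.
#' @param system A `transfer_system` from [build_transfer_system()].
#' @param dt Step length, days.
#' @return List with `state` (new fugacities) and `fluxes`, a per-step
#'   report in mol: `emission_in`, `deposition_air_to_soil`,
#'   `volatilization_soil_to_air`, `deposition_air_to_water`,
#'   `degradation`, `leaching_out`, `burial`, plus `amount_before` and
#'   `amount_after` (total mol in the cell).
#' @export
step_cell <- function(state, system, dt = 1) {
  stopifnot(inherits(system, "transfer_system"))
  if (length(state) != 28L) stop("state must have 28 fugacities", call. = FALSE)
  if (any(!is.finite(state)) || any(state < 0)) {
    stop("fugacities must be finite and >= 0", call. = FALSE)
  }
  if (dt <= 0) stop("dt must be positive (days)", call. = FALSE)
  dt_h <- dt * 24
  f_new <- .solve_step(system, as.numeric(state), dt_h)
  fluxes <- .flux_report(system, f_new, dt_h)
  fluxes$amount_before <- sum(system$VZ * state)
  fluxes$amount_after <- sum(system$VZ * f_new)
  list(state = stats::setNames(f_new, compartment_names()), fluxes = fluxes)
}

#' Air-soil fugacity fraction
#'
#' ff = f_soil / (f_air + f_soil) for the first air layer against the first
#' soil layer: 0.5 marks air-soil equilibrium, values below 0.5 net
#' deposition from air to soil, above 0.5 net volatilization from soil to
#' air.
#'
#' @param f_air,f_soil Fugacities, Pa (vectorized, >= 0).
#' @return ff in \[0, 1\]; `NA` where both fugacities are zero.
#' @export
fugacity_fraction <- function(f_air, f_soil) {
  if (any(f_air < 0, na.rm = TRUE) || any(f_soil < 0, na.rm = TRUE)) {
    stop("fugacities must be >= 0", call. = FALSE)
  }
  tot <- f_air + f_soil
  ifelse(tot > 0, f_soil / tot, NA_real_)
}
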