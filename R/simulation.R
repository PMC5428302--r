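# Multi-year gridded simulation: daily per-cell transfer steps, horizontal
# advection of both air layers, mass ledgering for the conservation audit,
# secondary-emission bookkeeping on non-source cells, and the model's
# diagnostics (fugacity-fraction fields, emission factors, Pearson
# evaluation).
#
# State is carried between days as per-compartment amounts (mol) so that
# the day-to-day change of fugacity capacities with temperature cannot
# create or destroy mass; fugacities are recovered each day from the
# current capacities.

MONTH_DAYS <- c(31L, 28L, 31L, 30L, 31L, 30L, 31L, 31L, 30L, 31L, 30L, 31L)

.month_of_doy <- rep(seq_len(12L), MONTH_DAYS)

#' Classify source vs non-source cells
#'
#' A cell is a source cell iff its cumulative primary emission over the
#' whole inventory exceeds `eps`; all other cells are non-source (their
#' soil burden can arise only from atmospheric deposition).
#'
#' @param inventory `[year, row, col]` array of non-negative emissions.
#' @param eps Threshold on the cumulative emission (same units as the
#'   inventory); default 0.
#' @return Logical `nlat x nlon` matrix, `TRUE` for source cells.
#' @export
classify_source_cells <- function(inventory, eps = 0) {
  if (any(inventory < 0)) stop("inventory must be non-negative", call. = FALSE)
  if (length(dim(inventory)) != 3L) {
    stop("inventory must be a [year, row, col] array", call. = FALSE)
  }
  apply(inventory, c(2, 3), sum) > eps
}

#' Secondary-emission factor
#'
#' EF = secondary emissions / secondary residues of a non-source cell over
#' a reporting window (window's volatilized amount over the window-mean
#' soil burden).
#'
#' @param secondary_emission Volatilized amount, mol (>= 0); vectorized.
#' @param secondary_residue Soil burden, mol (>= 0); vectorized.
#' @return Dimensionless EF; `NA` where emission and residue are both
#'   zero. A positive emission with zero residue is inconsistent and is
#'   returned as `NA` with a warning.
#' @export
emission_factor <- function(secondary_emission, secondary_residue) {
  if (any(secondary_emission < 0, na.rm = TRUE) ||
      any(secondary_residue < 0, na.rm = TRUE)) {
    stop("secondary emission and residue must be >= 0", call. = FALSE)
  }
  bad <- secondary_residue == 0 & secondary_emission > 0
  if (any(bad, na.rm = TRUE)) {
    warning("secondary emission > 0 with zero residue at ",
            sum(bad, na.rm = TRUE), " entries; returned as NA")
  }
  ifelse(secondary_residue > 0, secondary_emission / secondary_residue,
         ifelse(secondary_emission == 0, NA_real_, NA_real_))
}

#' Whole-run mass-balance audit
#'
#' Relative closure error of the ledger:
#' 100 * |inputs - (outputs + change in holdings)| / inputs, in percent.
#'
#' @param ledger A `mass_ledger` as returned in a simulation result.
#' @return Relative error, %; `NA` if the ledger saw no inputs.
#' @export
mass_balance_audit <- function(ledger) {
  stopifnot(inherits(ledger, "mass_ledger"))
  inputs <- ledger$primary_emission_in
  if (inputs <= 0) return(NA_real_)
  outputs <- ledger$advective_export + ledger$degradation_loss +
    ledger$deep_leaching_loss + ledger$burial_loss
  dh <- ledger$holdings_final - ledger$holdings_initial
  100 * abs(inputs - (outputs + dh)) / inputs
}

#' Pearson evaluation of modeled against observed values
#'
#' Sample Pearson correlation with the two-sided p-value from the t
#' transform, with an explicit exclusion list for pairs left out of the
#' comparison.
#'
#' @param modeled,observed Paired numeric vectors.
#' @param exclude Optional integer indices of pairs to exclude.
#' @return List with `R`, `p` and `n` (pairs used). Both are `NA` (with a
#'   warning) when either series has zero variance.
#' @export
evaluate_pearson <- function(modeled, observed, exclude = NULL) {
  if (length(modeled) != length(observed)) {
    stop("modeled and observed must be the same length", call. = FALSE)
  }
  if (length(exclude)) {
    modeled <- modeled[-exclude]
    observed <- observed[-exclude]
  }
  keep <- is.finite(modeled) & is.finite(observed)
  modeled <- modeled[keep]; observed <- observed[keep]
  if (length(modeled) < 3L) {
    stop("need at least 3 finite pairs", call. = FALSE)
  }
  if (stats::sd(modeled) == 0 || stats::sd(observed) == 0) {
    warning("zero variance in a series; correlation undefined")
    return(list(R = NA_real_, p = NA_real_, n = length(modeled)))
  }
  ct <- stats::cor.test(modeled, observed, method = "pearson")
  list(R = unname(ct$estimate), p = ct$p.value, n = length(modeled))
}

#' Convert an annual inventory to daily molar emission rates
#'
#' Annual inventories (t/yr) are apportioned uniformly across the 365
#' days of the model year.
#'
#' @param inventory_t_yr Emissions, t/yr (any shape; vectorized).
#' @param chem A [chemical_profile()] supplying the molar mass.
#' @return Emission rate, mol/day.
#' @export
emission_mol_day <- function(inventory_t_yr, chem) {
  stopifnot(inherits(chem, "chemical_profile"))
  if (any(inventory_t_yr < 0)) stop("emissions must be >= 0", call. = FALSE)
  inventory_t_yr * 1e6 / chem$molar_mass / 365
}

#' Run the gridded multimedia simulation
#'
#' Daily loop over the full period: per cell, the level-IV transfer system
#' is assembled for the day's temperature and precipitation and advanced
#' by one implicit-Euler step; both air layers are then advected by the
#' day's winds with upwind finite volumes. Amounts (mol) are ledgered into
#' inputs (primary emissions), outputs (degradation, deep leaching,
#' sediment burial, advective export across the domain boundary) and
#' holdings, so the run can be audited for mass conservation. Secondary
#' emissions (gross soil-to-air volatilization) and soil residues are
#' tracked per cell, with non-source cells identified from the inventory.
#'
#' @param chem A [chemical_profile()].
#' @param grid A [grid_spec()].
#' @param land A [synth_landsurface()] result (or compatible list).
#' @param met A [synth_met()] result (or compatible list of daily arrays).
#' @param emissions `[year, row, col]` inventory, t/yr.
#' @param params A [model_params()] list.
#' @param sites Optional matrix/list of `(row, col)` cells at which daily
#'   series are recorded.
#' @param source_eps Threshold for [classify_source_cells()].
#' @param progress Print one line per simulated year.
#' @return An object of class `fugrid_run`: list with
#' \describe{
#'   \item{ledger}{`mass_ledger` of cumulative mol}
#'   \item{audit}{mass-balance closure error, %}
#'   \item{source_mask}{logical source-cell matrix}
#'   \item{monthly}{per-month-per-cell arrays (`[month, row, col]`):
#'     `ff` (mean air-soil fugacity fraction, urban soil),
#'     `volatilization` (mol), `soil_burden` (mean mol),
#'     `air_conc` (mean ABL concentration, mol/m^3),
#'     `temperature` (mean K), `precipitation` (mean m/day)}
#'   \item{cumulative}{per-cell matrices: `emission` (mol),
#'     `volatilization` (mol), `residue` (final soil burden, mol)}
#'   \item{final_amounts}{`ncell x 28` amounts, mol}
#'   \item{final_fugacity}{`ncell x 28` fugacities on the last day, Pa}
#'   \item{sites}{list of daily data frames for the requested cells}
#' }
#' @export
run_simulation <- function(chem, grid, land, met, emissions,
                           params = model_params(), sites = NULL,
                           source_eps = 0, progress = FALSE) {
  stopifnot(inherits(chem, "chemical_profile"), inherits(grid, "grid_spec"))
  nr <- grid$nlat; nc <- grid$nlon; ncell <- nr * nc
  ndays <- dim(met$temperature)[1]
  if (ndays %% 365L != 0L) stop("met must cover whole 365-day years",
                                call. = FALSE)
  years <- ndays %/% 365L
  for (v in c("temperature", "precipitation", "u_abl", "v_abl",
              "u_alt", "v_alt")) {
    if (is.null(met[[v]]) || !all(dim(met[[v]]) == c(ndays, nr, nc))) {
      stop("met field '", v, "' must be a [", ndays, ", ", nr, ", ", nc,
           "] array", call. = FALSE)
    }
  }
  if (!all(dim(emissions) == c(years, nr, nc))) {
    stop("emissions must be a [", years, ", ", nr, ", ", nc, "] array ",
         "matching the met period and grid", call. = FALSE)
  }
  if (any(emissions < 0)) stop("emissions must be >= 0", call. = FALSE)

  source_mask <- classify_source_cells(emissions, source_eps)
  e_mol_day <- emission_mol_day(emissions, chem) # [year, row, col]

  pre <- vector("list", ncell)
  for (j in seq_len(nc)) for (i in seq_len(nr)) {
    env <- land_cell_environment(land, grid, i, j)
    pre[[i + (j - 1L) * nr]] <- .cell_precomp(chem, env, params)
  }

  if (!is.null(sites)) {
    sites <- matrix(as.integer(unlist(sites)), ncol = 2L, byrow = !is.matrix(sites))
    if (any(sites[, 1] < 1 | sites[, 1] > nr | sites[, 2] < 1 | sites[, 2] > nc)) {
      stop("site indices outside the grid", call. = FALSE)
    }
  }
  nsites <- if (is.null(sites)) 0L else nrow(sites)
  site_cell <- if (nsites) sites[, 1] + (sites[, 2] - 1L) * nr else integer()
  site_rec <- if (nsites) {
    lapply(seq_len(nsites), function(s)
      matrix(NA_real_, ndays, 9L,
             dimnames = list(NULL, c("day", "temperature", "precipitation",
                                     "f_air", "f_soil", "ff",
                                     "volatilization", "soil_burden",
                                     "air_conc"))))
  } else list()

  n_amt <- matrix(0, ncell, 28L)
  i_urb1 <- .idx_soil(1L, 1L)
  i_soil <- 5:28
  nmonth <- years * 12L
  zero_m <- matrix(0, nmonth, ncell)
  acc <- list(ff = zero_m, ff_n = zero_m, volat = zero_m, burden = zero_m,
              airc = zero_m, temp = zero_m, prec = zero_m)
  cum_emis <- numeric(ncell)
  cum_volat <- numeric(ncell)
  led <- c(primary = 0, export = 0, deg = 0, leach = 0, burial = 0)
  f_last <- matrix(0, ncell, 28L)
  dt_h <- 24

  day_volat <- numeric(ncell)
  for (d in seq_len(ndays)) {
    yr <- (d - 1L) %/% 365L + 1L
    doy <- (d - 1L) %% 365L + 1L
    m <- (yr - 1L) * 12L + .month_of_doy[doy]
    t_day <- matrix(met$temperature[d, , , drop = FALSE], nr, nc)
    p_day <- matrix(met$precipitation[d, , , drop = FALSE], nr, nc)
    e_day <- matrix(e_mol_day[yr, , , drop = FALSE], nr, nc)
    fa <- params$emission_frac_air

    for (k in seq_len(ncell)) {
      sys <- .assemble_day(pre[[k]], chem, params,
                           T = t_day[k], precip = p_day[k],
                           emis_air_mol_day = e_day[k] * fa,
                           emis_soil_mol_day = e_day[k] * (1 - fa))
      vz <- sys$VZ
      f <- numeric(28L)
      act <- sys$act
      f[act] <- n_amt[k, act] / vz[act]
      f_new <- .solve_step(sys, f, dt_h)
      n_new <- vz * f_new
      n_amt[k, ] <- n_new

      volat <- sum(sys$K[1L, sys$i_s1] * f_new[sys$i_s1]) * dt_h
      led[["primary"]] <- led[["primary"]] + sum(sys$s) * dt_h
      led[["deg"]] <- led[["deg"]] + sum(sys$loss_deg * f_new) * dt_h
      led[["leach"]] <- led[["leach"]] + sum(sys$loss_leach * f_new) * dt_h
      led[["burial"]] <- led[["burial"]] + sum(sys$loss_bur * f_new) * dt_h
      cum_emis[k] <- cum_emis[k] + sum(sys$s) * dt_h
      cum_volat[k] <- cum_volat[k] + volat
      day_volat[k] <- volat

      sb <- sum(n_new[i_soil])
      ffv <- f_new[1L] + f_new[i_urb1]
      acc$volat[m, k] <- acc$volat[m, k] + volat
      acc$burden[m, k] <- acc$burden[m, k] + sb
      acc$airc[m, k] <- acc$airc[m, k] + n_new[1L] / pre[[k]]$V[1L]
      acc$temp[m, k] <- acc$temp[m, k] + t_day[k]
      acc$prec[m, k] <- acc$prec[m, k] + p_day[k]
      if (ffv > 0) {
        acc$ff[m, k] <- acc$ff[m, k] + f_new[i_urb1] / ffv
        acc$ff_n[m, k] <- acc$ff_n[m, k] + 1
      }
      if (d == ndays) f_last[k, ] <- f_new
      if (nsites) {
        sidx <- which(site_cell == k)
        for (s in sidx) {
          site_rec[[s]][d, ] <- c(d, t_day[k], p_day[k], f_new[1L],
                                  f_new[i_urb1],
                                  if (ffv > 0) f_new[i_urb1] / ffv else NA_real_,
                                  volat, sb, n_new[1L] / pre[[k]]$V[1L])
        }
      }
    }

    adv1 <- advect(matrix(n_amt[, 1L], nr, nc),
                   matrix(met$u_abl[d, , , drop = FALSE], nr, nc),
                   matrix(met$v_abl[d, , , drop = FALSE], nr, nc),
                   grid, dt = 1, params = params)
    adv2 <- advect(matrix(n_amt[, 2L], nr, nc),
                   matrix(met$u_alt[d, , , drop = FALSE], nr, nc),
                   matrix(met$v_alt[d, , , drop = FALSE], nr, nc),
                   grid, dt = 1, params = params)
    n_amt[, 1L] <- adv1$field
    n_amt[, 2L] <- adv2$field
    led[["export"]] <- led[["export"]] + adv1$boundary_export +
      adv2$boundary_export

    if (progress && doy == 365L) {
      message(sprintf("year %d/%d: holdings %.4g mol", yr, years, sum(n_amt)))
    }
  }

  ledger <- structure(
    list(primary_emission_in = led[["primary"]],
         advective_export = led[["export"]],
         degradation_loss = led[["deg"]],
         deep_leaching_loss = led[["leach"]],
         burial_loss = led[["burial"]],
         holdings_initial = 0,
         holdings_final = sum(n_amt),
         holdings_by_class = c(
           air = sum(n_amt[, 1:2]), water = sum(n_amt[, 3L]),
           sediment = sum(n_amt[, 4L]), soil = sum(n_amt[, i_soil]))),
    class = "mass_ledger")

  mdays <- rep(rep(MONTH_DAYS, years), each = 1)
  to_arr <- function(x) array(x, dim = c(nmonth, nr, nc))
  monthly <- list(
    ff = to_arr(ifelse(acc$ff_n > 0, acc$ff / acc$ff_n, NA_real_)),
    volatilization = to_arr(acc$volat),
    soil_burden = to_arr(acc$burden / mdays),
    air_conc = to_arr(acc$airc / mdays),
    temperature = to_arr(acc$temp / mdays),
    precipitation = to_arr(acc$prec / mdays)
  )

  res <- list(
    grid = grid, chem = chem, params = params, years = years,
    ledger = ledger,
    audit = NA_real_,
    source_mask = source_mask,
    monthly = monthly,
    cumulative = list(emission = matrix(cum_emis, nr, nc),
                      volatilization = matrix(cum_volat, nr, nc),
                      residue = matrix(rowSums(n_amt[, i_soil, drop = FALSE]),
                                       nr, nc)),
    final_amounts = n_amt,
    final_fugacity = f_last,
    sites = if (nsites) {
      lapply(seq_len(nsites), function(s) {
        df <- as.data.frame(site_rec[[s]])
        df$row <- sites[s, 1]; df$col <- sites[s, 2]
        df
      })
    } else list()
  )
  res$audit <- mass_balance_audit(ledger)
  class(res) <- "fugrid_run"
  res
}

#' @export
print.fugrid_run <- function(x, ...) {
  cat("<fugrid_run> ", x$grid$nlat, "x", x$grid$nlon, " grid, ",
      x$years, " years, chemical ", x$chem$name, "\n",
      "  emissions in: ", signif(x$ledger$primary_emission_in, 5), " mol;",
      " mass-balance error: ", format(x$audit, digits = 3), " %\n",
      sep = "")
  invisible(x)
}

#' Gridded air-soil fugacity-fraction field
#'
#' Applies [fugacity_fraction()] of the ABL air against the first layer of
#' the chosen soil type to a matrix of per-cell fugacities.
#'
#' @param fugacity `ncell x 28` fugacity matrix (e.g.
#'   `run$final_fugacity`) in cell order `row + (col-1)*nlat`.
#' @param grid The matching [grid_spec()].
#' @param soil_type Soil type name or index; the headline diagnostic uses
#'   urban soil.
#' @return `nlat x nlon` matrix of ff; `NA` where undefined.
#' @export
fugacity_fraction_field <- function(fugacity, grid, soil_type = "urban") {
  stopifnot(inherits(grid, "grid_spec"))
  if (is.character(soil_type)) soil_type <- match(soil_type, SOIL_TYPES)
  if (is.na(soil_type) || soil_type < 1 || soil_type > 6) {
    stop("unknown soil type", call. = FALSE)
  }
  ff <- fugacity_fraction(fugacity[, 1L], fugacity[, .idx_soil(soil_type, 1L)])
  matrix(ff, grid$nlat, grid$nlon)
}

#' Monthly secondary-emission factors
#'
#' EF per calendar month and cell: the month's volatilized amount divided
#' by the month-mean soil burden (full soil column by default; first
#' layer is not separately tracked at monthly cadence).
#'
#' @param run A [run_simulation()] result.
#' @param cells Optional `n x 2` matrix of `(row, col)`; defaults to all
#'   non-source cells.
#' @return Data frame with `month`, `row`, `col`, `ef`,
#'   `temperature` and `precipitation` (monthly means).
#' @export
monthly_ef <- function(run, cells = NULL) {
  stopifnot(inherits(run, "fugrid_run"))
  nr <- run$grid$nlat; nc <- run$grid$nlon
  if (is.null(cells)) {
    cells <- which(!run$source_mask, arr.ind = TRUE)
  } else {
    cells <- matrix(as.integer(unlist(cells)), ncol = 2L,
                    byrow = !is.matrix(cells))
  }
  nmonth <- dim(run$monthly$ff)[1]
  out <- vector("list", nrow(cells))
  for (s in seq_len(nrow(cells))) {
    i <- as.integer(cells[s, 1]); j <- as.integer(cells[s, 2])
    ef <- emission_factor(run$monthly$volatilization[, i, j],
                          run$monthly$soil_burden[, i, j])
    out[[s]] <- data.frame(month = seq_len(nmonth), row = i, col = j,
                           ef = ef,
                           temperature = run$monthly$temperature[, i, j],
                           precipitation = run$monthly$precipitation[, i, j])
  }
  do.call(rbind, out)
}
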