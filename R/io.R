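# Readers and writers. Gridded fields travel as long-format CSV
# (date/row/col columns, full double precision so round-trips are
# bit-identical); configuration is YAML. The calendar is a 365-day
# no-leap calendar; dates are ISO-8601 ordinal dates "YYYY-DDD".

.fmt_num <- function(x) sprintf("%.17g", x)

.ord_date <- function(year, doy) sprintf("%04d-%03d", year, doy)

.parse_ord_date <- function(x) {
  m <- regmatches(x, regexec("^([0-9]{4})-([0-9]{3})$", x))
  bad <- vapply(m, length, 1L) != 3L
  if (any(bad)) stop("dates must be ISO ordinal 'YYYY-DDD'", call. = FALSE)
  year <- as.integer(vapply(m, `[`, "", 2L))
  doy <- as.integer(vapply(m, `[`, "", 3L))
  if (any(doy < 1L | doy > 365L)) {
    stop("day-of-year outside 1..365 (no-leap calendar)", call. = FALSE)
  }
  list(year = year, doy = doy)
}

.write_long_csv <- function(df, path, num_cols) {
  for (v in num_cols) df[[v]] <- .fmt_num(df[[v]])
  utils::write.csv(df, path, row.names = FALSE, quote = FALSE)
}

#' Write synthetic (or other) daily meteorology to CSV
#'
#' Long format: `date` (ISO ordinal `YYYY-DDD`), `row`, `col`,
#' `temperature_k`, `precipitation_m_day`, `u_abl`, `v_abl`, `u_alt`,
#' `v_alt`. Numbers are written at full double precision so the file
#' round-trips bit-identically through [read_met_csv()].
#'
#' @param met A [synth_met()]-style list of `[day, row, col]` arrays.
#' @param path Output file.
#' @param start_year First calendar year of the series (labeling only).
#' @export
write_met_csv <- function(met, path, start_year = 1L) {
  d <- dim(met$temperature)
  ndays <- d[1]; nr <- d[2]; nc <- d[3]
  day <- seq_len(ndays)
  year <- start_year + (day - 1L) %/% 365L
  doy <- (day - 1L) %% 365L + 1L
  df <- data.frame(
    date = rep(.ord_date(year, doy), nr * nc),
    row = rep(rep(seq_len(nr), each = ndays), nc),
    col = rep(seq_len(nc), each = ndays * nr),
    temperature_k = as.vector(met$temperature),
    precipitation_m_day = as.vector(met$precipitation),
    u_abl = as.vector(met$u_abl), v_abl = as.vector(met$v_abl),
    u_alt = as.vector(met$u_alt), v_alt = as.vector(met$v_alt)
  )
  .write_long_csv(df, path, setdiff(names(df), c("date", "row", "col")))
  invisible(path)
}

#' Read daily gridded meteorology from CSV
#'
#' Validates that every required variable is present (naming the missing
#' one otherwise) and that the grid addresses match `grid`. Temperature
#' may be given as `temperature_k` or `temperature_c` (converted to K).
#'
#' @param path CSV file in the [write_met_csv()] layout.
#' @param grid The expected [grid_spec()].
#' @return A `synth_met`-style list of `[day, row, col]` arrays.
#' @export
read_met_csv <- function(path, grid) {
  stopifnot(inherits(grid, "grid_spec"))
  if (!file.exists(path)) stop("no such file: ", path, call. = FALSE)
  df <- utils::read.csv(path)
  temp_col <- intersect(c("temperature_k", "temperature_c"), names(df))
  if (!length(temp_col)) {
    stop("met file is missing variable 'temperature' ",
         "(temperature_k or temperature_c)", call. = FALSE)
  }
  need <- c("date", "row", "col", "precipitation_m_day",
            "u_abl", "v_abl", "u_alt", "v_alt")
  missing <- setdiff(need, names(df))
  if (length(missing)) {
    stop("met file is missing variable(s): ",
         paste(sub("_m_day$", "", missing), collapse = ", "), call. = FALSE)
  }
  dd <- .parse_ord_date(df$date)
  day <- (dd$year - min(dd$year)) * 365L + dd$doy
  ndays <- max(day)
  nr <- grid$nlat; nc <- grid$nlon
  if (max(df$row) != nr || max(df$col) != nc || min(df$row) < 1 ||
      min(df$col) < 1) {
    stop("met grid addresses do not match the configured ", nr, "x", nc,
         " grid", call. = FALSE)
  }
  if (nrow(df) != ndays * nr * nc) {
    stop("met file is not a complete day x row x col lattice", call. = FALSE)
  }
  idx <- cbind(day, df$row, df$col)
  mk <- function(v) {
    a <- array(NA_real_, dim = c(ndays, nr, nc))
    a[idx] <- v
    a
  }
  temp <- if (temp_col[1] == "temperature_c") df[[temp_col[1]]] + 273.15
          else df[[temp_col[1]]]
  if (any(met_prec <- df$precipitation_m_day < 0)) {
    stop("negative precipitation at ", sum(met_prec), " records", call. = FALSE)
  }
  structure(list(temperature = mk(temp),
                 precipitation = mk(df$precipitation_m_day),
                 u_abl = mk(df$u_abl), v_abl = mk(df$v_abl),
                 u_alt = mk(df$u_alt), v_alt = mk(df$v_alt),
                 years = ndays %/% 365L),
            class = "synth_met")
}

#' Write an annual emission inventory to CSV
#'
#' Long format: `year`, `row`, `col`, `emission_t_yr`.
#'
#' @param inventory `[year, row, col]` array, t/yr.
#' @param path Output file.
#' @export
write_inventory_csv <- function(inventory, path) {
  d <- dim(inventory)
  df <- data.frame(
    year = rep(seq_len(d[1]), d[2] * d[3]),
    row = rep(rep(seq_len(d[2]), each = d[1]), d[3]),
    col = rep(seq_len(d[3]), each = d[1] * d[2]),
    emission_t_yr = as.vector(inventory)
  )
  df <- df[df$emission_t_yr != 0, , drop = FALSE] # sparse: sources only
  .write_long_csv(df, path, "emission_t_yr")
  invisible(path)
}

#' Read a gridded annual emission inventory
#'
#' Cells absent from the file are zero (non-source). Negative entries are
#' rejected. When a chemical profile is supplied the inventory is
#' converted from t/yr to mol/day via the molar mass.
#'
#' @param path CSV in the [write_inventory_csv()] layout.
#' @param grid The expected [grid_spec()].
#' @param years Number of inventory years expected.
#' @param chem Optional [chemical_profile()]; convert to mol/day.
#' @return `[year, row, col]` array (t/yr, or mol/day with `chem`).
#' @export
read_inventory <- function(path, grid, years, chem = NULL) {
  stopifnot(inherits(grid, "grid_spec"))
  if (!file.exists(path)) stop("no such file: ", path, call. = FALSE)
  df <- utils::read.csv(path)
  need <- c("year", "row", "col", "emission_t_yr")
  missing <- setdiff(need, names(df))
  if (length(missing)) {
    stop("inventory file is missing column(s): ",
         paste(missing, collapse = ", "), call. = FALSE)
  }
  if (any(df$emission_t_yr < 0)) {
    stop("inventory has negative emissions", call. = FALSE)
  }
  if (nrow(df) && (max(df$row) > grid$nlat || max(df$col) > grid$nlon ||
                   max(df$year) > years)) {
    stop("inventory addresses exceed the configured grid/period",
         call. = FALSE)
  }
  inv <- array(0, dim = c(years, grid$nlat, grid$nlon))
  if (nrow(df)) inv[cbind(df$year, df$row, df$col)] <- df$emission_t_yr
  if (!is.null(chem)) emission_mol_day(inv, chem) else inv
}

#' Write a land surface to CSV
#'
#' Wide per-cell format: `row`, `col`, the seven land-use fractions
#' (`frac_*`), the six surface SOM values (`som_*`) and the scalar soil
#' constants (replicated per row for self-containment).
#'
#' @param land A [synth_landsurface()] result.
#' @param path Output file.
#' @export
write_landsurface_csv <- function(land, path) {
  d <- dim(land$fractions)
  nr <- d[1]; nc <- d[2]
  df <- data.frame(row = rep(seq_len(nr), nc),
                   col = rep(seq_len(nc), each = nr))
  for (k in seq_len(7L)) {
    df[[paste0("frac_", dimnames(land$fractions)[[3]][k])]] <-
      as.vector(land$fractions[, , k])
  }
  for (k in seq_len(6L)) {
    df[[paste0("som_", SOIL_TYPES[k])]] <- as.vector(land$som[, , k])
  }
  for (v in c("soil_density", "soil_porosity_air", "soil_porosity_water",
              "aerosol_volume_fraction", "water_depth", "sediment_depth",
              "sediment_porosity", "sediment_oc")) {
    df[[v]] <- land[[v]]
  }
  for (k in 1:4) df[[paste0("depth_L", k)]] <- land$soil_layer_depths[k]
  .write_long_csv(df, path, setdiff(names(df), c("row", "col")))
  invisible(path)
}

#' Read a land surface from CSV
#'
#' @param path CSV in the [write_landsurface_csv()] layout.
#' @param grid The expected [grid_spec()].
#' @return A `synth_land` list as produced by [synth_landsurface()].
#' @export
read_landsurface_csv <- function(path, grid) {
  stopifnot(inherits(grid, "grid_spec"))
  if (!file.exists(path)) stop("no such file: ", path, call. = FALSE)
  df <- utils::read.csv(path)
  nr <- grid$nlat; nc <- grid$nlon
  if (nrow(df) != nr * nc) {
    stop("land surface does not cover the ", nr, "x", nc, " grid",
         call. = FALSE)
  }
  fr_names <- c(SOIL_TYPES, "water")
  need <- c(paste0("frac_", fr_names), paste0("som_", SOIL_TYPES))
  missing <- setdiff(need, names(df))
  if (length(missing)) {
    stop("land surface file is missing column(s): ",
         paste(missing, collapse = ", "), call. = FALSE)
  }
  idx <- cbind(df$row, df$col)
  fractions <- array(NA_real_, c(nr, nc, 7L),
                     dimnames = list(NULL, NULL, fr_names))
  for (k in seq_len(7L)) {
    m <- matrix(NA_real_, nr, nc); m[idx] <- df[[paste0("frac_", fr_names[k])]]
    fractions[, , k] <- m
  }
  som <- array(NA_real_, c(nr, nc, 6L),
               dimnames = list(NULL, NULL, SOIL_TYPES))
  for (k in seq_len(6L)) {
    m <- matrix(NA_real_, nr, nc); m[idx] <- df[[paste0("som_", SOIL_TYPES[k])]]
    som[, , k] <- m
  }
  structure(list(
    fractions = fractions, som = som,
    soil_layer_depths = as.numeric(df[1, paste0("depth_L", 1:4)]),
    soil_density = as.numeric(df$soil_density[1]),
    soil_porosity_air = as.numeric(df$soil_porosity_air[1]),
    soil_porosity_water = as.numeric(df$soil_porosity_water[1]),
    aerosol_volume_fraction = as.numeric(df$aerosol_volume_fraction[1]),
    water_depth = as.numeric(df$water_depth[1]),
    sediment_depth = as.numeric(df$sediment_depth[1]),
    sediment_porosity = as.numeric(df$sediment_porosity[1]),
    sediment_oc = as.numeric(df$sediment_oc[1])), class = "synth_land")
}

#' Read and validate a run configuration
#'
#' YAML schema (unknown keys are rejected):
#' \preformatted{
#' seed: 1
#' chemical: pcb28            # or a path to a chemical-profile YAML
#' synth:                     # synth_spec() arguments (generated inputs)
#'   nlat: 10
#'   years: 5
#' paths:                     # alternatively, files written previously
#'   met: met.csv
#'   inventory: inventory.csv
#'   landsurface: land.csv
#' grid:                      # required with 'paths'; implied by 'synth'
#'   lat_min: 20
#'   lon_min: 100
#'   nlat: 10
#'   nlon: 10
#'   dlat: 1
#'   dlon: 1
#' years: 5                   # required with 'paths'
#' params:                    # model_params() overrides
#'   leach_frac: 0.3
#' sites:                     # optional (row, col) pairs
#'   - [2, 3]
#' }
#'
#' @param path YAML file.
#' @return Validated configuration list with elements `chem`, `seed`,
#'   `synth` (a [synth_spec()] or `NULL`), `paths`, `grid`, `years`,
#'   `params`, `sites`.
#' @export
read_run_config <- function(path) {
  if (!file.exists(path)) stop("no such config file: ", path, call. = FALSE)
  y <- yaml::read_yaml(path)
  allowed <- c("seed", "chemical", "synth", "paths", "grid", "years",
               "params", "sites")
  unknown <- setdiff(names(y), allowed)
  if (length(unknown)) {
    stop("unknown config key(s): ", paste(unknown, collapse = ", "),
         call. = FALSE)
  }
  seed <- if (is.null(y$seed)) 1L else as.integer(y$seed)
  chem <- if (is.null(y$chemical) || identical(y$chemical, "pcb28")) {
    pcb28_profile()
  } else if (is.character(y$chemical)) {
    read_chemical_profile(file.path(dirname(path), y$chemical))
  } else {
    stop("'chemical' must be \"pcb28\" or a profile path", call. = FALSE)
  }
  params <- do.call(model_params, as.list(y$params))
  sites <- if (!is.null(y$sites)) {
    do.call(rbind, lapply(y$sites, as.integer))
  }
  if (!is.null(y$synth)) {
    sp <- do.call(synth_spec, c(y$synth, list(seed = seed)))
    list(chem = chem, seed = seed, synth = sp, paths = NULL,
         grid = sp$grid, years = sp$years, params = params, sites = sites)
  } else {
    if (is.null(y$paths) || is.null(y$grid) || is.null(y$years)) {
      stop("config needs either a 'synth' block or 'paths' + 'grid' + 'years'",
           call. = FALSE)
    }
    need <- c("met", "inventory", "landsurface")
    missing <- setdiff(need, names(y$paths))
    if (length(missing)) {
      stop("'paths' is missing: ", paste(missing, collapse = ", "),
           call. = FALSE)
    }
    g <- do.call(grid_spec, y$grid)
    paths <- lapply(y$paths[need], function(p) {
      if (startsWith(p, "/")) p else file.path(dirname(path), p)
    })
    list(chem = chem, seed = seed, synth = NULL, paths = paths,
         grid = g, years = as.integer(y$years), params = params,
         sites = sites)
  }
}
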