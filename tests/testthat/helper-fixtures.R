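# Shared fixtures, built in code. "Inert" chemicals/parameters switch off
# loss pathways so conservation can be tested exactly.

unit_chem <- function(...) {
  chemical_profile("unit", molar_mass = 1, solubility = 1,
                   vapor_pressure = 1, koc = 1,
                   half_life = c(air = 1e15, soil = 1e15,
                                 water = 1e15, sediment = 1e15),
                   dU_vap = 0, dU_henry = 0, Ea_deg = 0, ...)
}

# environment small enough for quick hand checks; no aerosol so all
# pathways other than the one-way rain terms are symmetric diffusive
clean_env <- function(...) {
  cell_environment(cell_area = 1e6, aerosol_volume_fraction = 0, ...)
}

# parameters with burial off (leaching is off whenever precipitation is 0)
no_burial_params <- function(...) {
  model_params(burial_rate_m_yr = 0, ...)
}

# total amount held in a cell given fugacities and a transfer system
cell_amount <- function(sys, f) sum(sys$VZ * f)

# single-cell synthetic setup under constant climate; returns a run
run_one_cell <- function(Tmean, precip, years = 2, seed = 7,
                         params = model_params(), total_t_yr = 10) {
  sp <- synth_spec(nlat = 1, nlon = 1, years = years, seed = seed,
                   temp_mean_warm_edge = Tmean, temp_mean_cold_edge = Tmean,
                   temp_seasonal_amplitude = 0, temp_noise_sd = 0,
                   precip_mean = precip, wet_day_fraction = 0.3,
                   wind_u = 0, wind_v = 0, source_pattern = "single-cell",
                   total_t_yr = total_t_yr)
  run_simulation(pcb28_profile(), sp$grid, synth_landsurface(sp),
                 synth_met(sp), synth_emissions(sp), params = params)
}

soil_layer_amount <- function(run, layer) {
  sum(run$final_amounts[, 4 + (0:5) * 4 + layer])
}
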