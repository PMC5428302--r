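# PCB28 (2,4,4'-trichlorobiphenyl) literature property set at 25 C.
# Solubility and vapor pressure are the commonly used handbook values for
# the trichlorobiphenyl homologue class; log10 Koc = 4.51 is the adopted
# literature value. This set gives a leaching potential S/(Koc*Vp) of
# 2.45e-4, within 1% of the widely cited 2.47e-4 for PCB28.
name: PCB28
molar_mass: 257.5        # g/mol
solubility: 0.27         # g/m^3 at 25 C
vapor_pressure: 0.034    # Pa at 25 C
koc: 32359.37            # L/kg (10^4.51)
log_koa: 8.0
half_life:
  air: 550               # hours
  soil: 17000
  water: 5500
  sediment: 55000
dU_vap: 70000            # J/mol
dU_henry: 50000          # J/mol
Ea_deg: 30000            # J/mol
T_ref: 298.15
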