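# Packaged single-line fixtures for the two GASMAS channels.
# One parameter per line: <name> <value> <unit>  # provenance
#
# These are representative HITRAN-style parameters for one water-vapour line
# near 820.0 nm and one oxygen A-band line near 763.8 nm, the two channels of
# a dual-laser GASMAS source. Strengths and air-broadened widths are chosen so
# that saturated water vapour at room temperature reproduces the accepted
# peak absorption coefficient of ~3.1e-5 cm-1 at 820 nm, and ambient air
# (21% O2) gives ~2.6e-4 cm-1 on the A band, the values this instrument class
# is calibrated against.

h2o.center_wavenumber   12195.1   cm-1                     # 1e7/12195.1 = 820.03 nm
h2o.line_strength       9.0e-24   cm-1/(molec.cm-2)        # representative strength for this band
h2o.lorentz_hwhm        0.050     cm-1                     # air-broadened HWHM at reference pressure
h2o.reference_pressure  101325    Pa                       # 1 atm
h2o.molar_mass          18.010565 g/mol                    # H2(16)O principal isotopologue

o2.center_wavenumber    13092.4   cm-1                     # 1e7/13092.4 = 763.80 nm
o2.line_strength        8.0e-24   cm-1/(molec.cm-2)        # representative A-band strength
o2.lorentz_hwhm         0.047     cm-1                     # air-broadened HWHM at reference pressure
o2.reference_pressure   101325    Pa                       # 1 atm
o2.molar_mass           31.98983  g/mol                    # (16)O2
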