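# Per-PFT stomatal and photosynthetic parameters.
#
# g1 values (kPa^0.5) are stand-ins spanning the range reported by the
# published leaf-level synthesis for these vegetation classes: conservative
# water use (low g1) for needleleaf and tundra vegetation, profligate
# (high g1) for crops and C3 grasses. Edit this file (or pass your own via
# `read_pft_params()`) to change the parameterisation; it is the single
# source of truth for the defaults.
#
# The default empirical scheme varies by photosynthetic pathway only.
default_scheme:
  c3:
    slope_a1: 9.0
    d0: 1.5      # kPa
    g0: 0.0
pfts:
  tundra:
    g1: 2.22
    vcmax_25: 45
    lai_peak: 1.8
    lai_winter_frac: 0.10
  evergreen_needleleaf:
    g1: 2.35
    vcmax_25: 60
    lai_peak: 3.8
    lai_winter_frac: 0.60
  deciduous_needleleaf:
    g1: 2.35
    vcmax_25: 55
    lai_peak: 3.2
    lai_winter_frac: 0.10
  deciduous_broadleaf:
    g1: 4.45
    vcmax_25: 55
    lai_peak: 4.5
    lai_winter_frac: 0.10
  c3_grass:
    g1: 5.25
    vcmax_25: 70
    lai_peak: 2.5
    lai_winter_frac: 0.20
  crop:
    g1: 5.79
    vcmax_25: 90
    lai_peak: 4.0
    lai_winter_frac: 0.05
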