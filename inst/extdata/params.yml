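# Example parameter override file for nh3_params(): any entry here replaces
# the package default of the same name (shallow merge per top-level block).
# Values not listed keep their defaults; the shipped defaults themselves are
# calibrated to the national 2016 baseline anchors (see the methods
# vignette and ?default_emission_factors).
transition:
  elasticity: -0.26      # N-rate vs mean parcel size power law
  free_range_keep: 0.115 # residual free-range pig-unit fraction
airq:
  dilution_rate: 0.01    # m/s effective ventilation
  background_mixing: 0.3
econ:
  discount_rate: 0.05
  lifetime: 20
  vsl: 250000            # US$ per statistical life
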