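Bundled input tables
====================

incidence_invasive_1980_1985.csv, bc_mortality_1980_1985.csv
  Pre-screening (1980-1985) Norwegian invasive breast-cancer incidence and
  breast-cancer mortality per 100,000 women-years, by five-year age group.

all_cause_mortality_female_1940_synthetic.csv
  SYNTHETIC stand-in for the all-cause mortality of the 1940 Norwegian female
  birth cohort: Gompertz schedule rate = 100000 * 0.0026 * exp(0.088*(age-50)),
  ages 50-100, calibrated only to generic life-table facts (remaining life
  expectancy at age 50 of about 34 years). Not registry data; supply the
  authoritative schedule for exact reproduction of published figures.

regimens.csv
  The five treatment regimens, their cumulative 10-year HUV loss, and the
  mid-point treatment distribution assumed for overdiagnosed women.

reduction_miscan_placeholder.csv, odp_miscan_placeholder.csv
  PLACEHOLDERS with invented values illustrating the file formats for a
  microsimulation-derived age-specific mortality-reduction curve and
  overdiagnosis-proportion table (the authoritative values exist only as
  figures). Scenarios built on them refuse to run unless placeholders are
  explicitly allowed.
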