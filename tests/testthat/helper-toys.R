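# toy builders shared across tests

flat_sched <- function(rate, n_ages = 3, start = 50) {
  age_schedule(start, rep(rate, n_ages))
}

# flat reduction over a wide support (covers all projection ages)
flat_curve <- function(r) {
  structure(list(ages = c(0, 200), r = c(r, r), label = "flat"),
            class = "reduction_curve")
}

# immortal cohort of n0 women over ages 50..horizon
immortal_cohort <- function(n0 = 1e5, horizon = 85) {
  z <- flat_sched(0, horizon - 50 + 1)
  project_cohort(n0, z, z, z, NULL, horizon)
}

# uniform mix over the five bundled regimens
uniform_mix <- function() {
  rg <- default_regimens()$regimen
  treatment_mix(stats::setNames(rep(1 / length(rg), length(rg)), rg))
}

single_regimen_mix <- function(name) {
  rg <- default_regimens()$regimen
  treatment_mix(stats::setNames(as.numeric(rg == name), rg))
}
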