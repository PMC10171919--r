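# shared fixtures built in code; the demo pipeline run is memoised because
# several files probe different layers of the same run

.fixtures <- new.env(parent = emptyenv())

demo_run <- function() {
  if (is.null(.fixtures$run)) {
    .fixtures$run <- suppressWarnings(run_pipeline(cea_config(seed = 11)))
  }
  .fixtures$run
}

# minimal single-endpoint records for KM-level tests
records_from <- function(time, event) {
  tibble::tibble(id = sprintf("X%03d", seq_along(time)), time = time, event = event)
}

# a deterministic transition schedule for Markov-level tests
toy_schedule <- function(p_death, p_prog) {
  structure(tibble::tibble(cycle = seq_along(p_death),
                           p_death = p_death, p_prog = p_prog),
            class = c("transition_schedule", class(tibble::tibble())))
}

# feasible MAIC targets: the cohort's own means nudged towards more adverse
# prognosis, kept strictly inside the sample support
covariate_means_shifted <- function(ipd, shift = 0.05) {
  m <- summarize_baseline(ipd)$covariate_means
  for (nm in setdiff(names(m), "age")) {
    m[nm] <- min(max(m[nm] + shift, 0.02), 0.98)
  }
  m["age"] <- m["age"] + 1
  m
}

# economic inputs with every cost zeroed (utilities / AEs kept) for
# component-isolation tests
zero_cost_inputs <- function(inputs = load_econ_inputs()) {
  for (arm in names(inputs$costs)) inputs$costs[[arm]][] <- 0
  inputs$ae$mgmt_cost <- 0
  inputs
}
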