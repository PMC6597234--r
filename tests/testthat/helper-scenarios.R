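## small, fast scenario used by engine-level tests; the full desk-scale
## configuration is exercised by the acceptance experiments
small_scenario <- function(...) {
  cfg <- default_scenario(...)
  cfg$population$n <- 3000
  cfg$simulation$horizon_years <- 12
  cfg$simulation$burn_in_years <- 4
  cfg
}
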