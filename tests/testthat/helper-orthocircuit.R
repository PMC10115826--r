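# Shared builders for small in-code fixtures.

toy_events <- function(fsc, ssc = fsc, reporter = 100, reference = 200) {
  n <- max(length(fsc), length(ssc), length(reporter), length(reference))
  data.frame(event_id = seq_len(n),
             fsc = rep_len(fsc, n), ssc = rep_len(ssc, n),
             reporter = rep_len(reporter, n),
             reference = rep_len(reference, n))
}

# population model with clean separations for deterministic checks
quiet_pop <- function(...) {
  args <- utils::modifyList(
    list(debris_frac = 0, edge_frac = 0, transfection_frac = 1,
         noise_sd_log10 = 0),
    list(...))
  do.call(cell_population_model, args)
}

# a no-op gate configuration (keeps every event)
open_gate <- function(...) {
  gate_config(fsc_min = 0, ssc_min = 0, debris = FALSE, edge = FALSE,
              reference = FALSE, ...)
}

# random positive fold-change matrix around baseline 1
random_fc_matrix <- function(n, m = n, sd_log10 = 0.3) {
  matrix(10^stats::rnorm(n * m, 0, sd_log10), n, m,
         dimnames = list(sprintf("Cas%02d", seq_len(n)),
                         sprintf("sw%02d", seq_len(m))))
}
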