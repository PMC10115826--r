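#' Describe the per-cell fluorescence population model
#'
#' Parameters of the synthetic flow-cytometry event generator. Transfected
#' (reference-positive) cells draw reference intensity from a log-normal,
#' and reporter intensity proportional to reference times the switch's
#' basal level, the planted trigger effect, and multiplicative log-normal
#' noise. Untransfected cells and debris draw autofluorescence-level
#' signal in both channels; debris additionally has low scatter. A fixed
#' fraction of intact-cell events is clamped to the channel limits to
#' emulate edge events.
#'
#' Defaults put transfected reference at 10^4 a.u. (0.3 dex spread), two
#' decades above autofluorescence (10^2, 0.2 dex), with 70% transfection,
#' 5% debris, 1% edge clamps and ~5% multiplicative reporter noise.
#'
#' @param ref_mean_log10,ref_sd_log10 Log10 mean/sd of transfected-cell
#'   reference intensity (a.u.).
#' @param noise_sd_log10 Log10 sd of the multiplicative reporter noise
#'   (0.0212 dex is about 5% noise).
#' @param transfection_frac Fraction of non-debris events that are
#'   transfected, in (0, 1].
#' @param debris_frac Fraction of events that are debris, in [0, 1).
#' @param edge_frac Fraction of non-debris events clamped to a channel
#'   limit, in [0, 1).
#' @param auto_mean_log10,auto_sd_log10 Autofluorescence log10 mean/sd
#'   (both channels, untransfected cells and mock samples).
#' @param channel_min,channel_max Instrument saturation limits (a.u.).
#' @param fsc_mean_log10,fsc_sd_log10,ssc_mean_log10,ssc_sd_log10 Scatter
#'   model of intact cells.
#' @param debris_fsc_mean_log10,debris_ssc_mean_log10,debris_scatter_sd_log10
#'   Scatter model of debris.
#' @return A `cell_population_model` list.
#' @export
cell_population_model <- function(ref_mean_log10 = 4.0,
                                  ref_sd_log10 = 0.3,
                                  noise_sd_log10 = 0.0212,
                                  transfection_frac = 0.7,
                                  debris_frac = 0.05,
                                  edge_frac = 0.01,
                                  auto_mean_log10 = 2.0,
                                  auto_sd_log10 = 0.2,
                                  channel_min = 0,
                                  channel_max = 1e6,
                                  fsc_mean_log10 = 5.0,
                                  fsc_sd_log10 = 0.08,
                                  ssc_mean_log10 = 4.7,
                                  ssc_sd_log10 = 0.08,
                                  debris_fsc_mean_log10 = 3.8,
                                  debris_ssc_mean_log10 = 3.5,
                                  debris_scatter_sd_log10 = 0.12) {
  if (transfection_frac <= 0 || transfection_frac > 1) {
    abort_oc("invalid_parameter_error", "transfection_frac must be in (0, 1]")
  }
  if (debris_frac < 0 || debris_frac >= 1) {
    abort_oc("invalid_parameter_error", "debris_frac must be in [0, 1)")
  }
  if (edge_frac < 0 || edge_frac >= 1) {
    abort_oc("invalid_parameter_error", "edge_frac must be in [0, 1)")
  }
  if (channel_max <= channel_min) {
    abort_oc("invalid_parameter_error", "channel_max must exceed channel_min")
  }
  structure(as.list(environment()), class = "cell_population_model")
}

# 32-bit FNV-1a over the utf8 bytes of a string, done in doubles so the
# intermediate products stay within exact integer range.
fnv1a32 <- function(s) {
  h <- 2166136261
  for (b in as.integer(charToRaw(s))) {
    h <- bitwXor_dbl(h, b)
    lo <- h %% 65536
    hi <- (h - lo) / 65536
    h <- (((hi * 16777619) %% 65536) * 65536 + lo * 16777619) %% 4294967296
  }
  h
}

bitwXor_dbl <- function(a, b) {
  lo <- bitwXor(as.integer(a %% 65536), as.integer(b %% 65536))
  hi <- bitwXor(as.integer(a %/% 65536), as.integer(b %/% 65536))
  hi * 65536 + lo
}

#' Derive a per-sample sub-seed from a master seed and a sample id
#'
#' Stable hash so that adding samples to a screen never perturbs the draws
#' of existing samples.
#'
#' @param seed Master integer seed.
#' @param sample_id Sample identifier string.
#' @return An integer in [1, 2^31 - 2].
#' @export
sample_subseed <- function(seed, sample_id) {
  as.integer(fnv1a32(paste(seed, sample_id, sep = "::")) %% 2147483645 + 1)
}

#' Simulate one flow-cytometry sample
#'
#' Draws `n_events` events for one switch/trigger condition of a planted
#' panel. Event composition is deterministic given the fractions
#' (counts are rounded, not binomially drawn) so that gating bookkeeping
#' has exact targets; all randomness is in the channel draws.
#'
#' @param panel A [build_ground_truth_panel()] panel.
#' @param switch_id Switch id in the panel, or `NA` for a mock
#'   (untransfected) sample.
#' @param trigger_id Trigger id, or `NA`/`NULL` for trigger-minus.
#' @param pop A [cell_population_model()].
#' @param n_events Number of events, >= 1.
#' @param seed Integer seed; identical arguments give an identical table.
#' @return An event table: `data.frame(event_id, fsc, ssc, reporter,
#'   reference)` with a `meta` attribute carrying sample metadata and the
#'   planted composition counts (`n_debris`, `n_edge`, `n_positive`).
#' @export
simulate_sample <- function(panel, switch_id, trigger_id = NULL,
                            pop = cell_population_model(),
                            n_events = 5000, seed = 1L) {
  if (n_events < 1) abort_oc("invalid_parameter_error", "n_events must be >= 1")
  mock <- is.null(switch_id) || is.na(switch_id)
  if (!mock) {
    effect <- panel_effect(panel, trigger_id, switch_id)  # validates ids
    basal <- panel$basal_reporter[[switch_id]]
  }

  set.seed(as.integer(seed))
  n_events <- as.integer(n_events)
  n_debris <- as.integer(round(n_events * pop$debris_frac))
  n_cells <- n_events - n_debris
  n_pos <- if (mock) 0L else as.integer(round(n_cells * pop$transfection_frac))
  n_neg <- n_cells - n_pos
  n_edge <- as.integer(round(n_cells * pop$edge_frac))

  ln10 <- log(10)
  rlog10 <- function(n, mu, sd) stats::rlnorm(n, mu * ln10, sd * ln10)

  # intact cells first (transfected, then untransfected), debris last;
  # a random permutation at the end removes the ordering.
  reference <- c(
    rlog10(n_pos, pop$ref_mean_log10, pop$ref_sd_log10),
    rlog10(n_neg + n_debris, pop$auto_mean_log10, pop$auto_sd_log10)
  )
  reporter <- numeric(n_events)
  if (n_pos > 0) {
    covariate <- reference[seq_len(n_pos)] / 10^pop$ref_mean_log10
    noise <- if (pop$noise_sd_log10 > 0) {
      rlog10(n_pos, 0, pop$noise_sd_log10)
    } else rep(1, n_pos)
    reporter[seq_len(n_pos)] <- basal * effect * covariate * noise
  }
  if (n_neg + n_debris > 0) {
    reporter[n_pos + seq_len(n_neg + n_debris)] <-
      rlog10(n_neg + n_debris, pop$auto_mean_log10, pop$auto_sd_log10)
  }

  fsc <- c(rlog10(n_cells, pop$fsc_mean_log10, pop$fsc_sd_log10),
           rlog10(n_debris, pop$debris_fsc_mean_log10, pop$debris_scatter_sd_log10))
  ssc <- c(rlog10(n_cells, pop$ssc_mean_log10, pop$ssc_sd_log10),
           rlog10(n_debris, pop$debris_ssc_mean_log10, pop$debris_scatter_sd_log10))

  # edge events: intact cells clamped to a channel limit (alternating
  # reporter-max / reference-max so both axes carry edge events)
  if (n_edge > 0) {
    idx <- sample.int(n_cells, n_edge)
    half <- seq_len(n_edge) %% 2L == 0L
    reporter[idx[half]] <- pop$channel_max
    reference[idx[!half]] <- pop$channel_max
  }

  clamp <- function(x) pmin(pmax(x, pop$channel_min), pop$channel_max)
  perm <- sample.int(n_events)
  out <- data.frame(
    event_id = seq_len(n_events),
    fsc = clamp(fsc)[perm],
    ssc = clamp(ssc)[perm],
    reporter = clamp(reporter)[perm],
    reference = clamp(reference)[perm]
  )
  attr(out, "meta") <- list(
    switch_id = if (mock) NA_character_ else switch_id,
    trigger_id = if (mock || is.null(trigger_id)) NA_character_ else trigger_id,
    role = if (mock) "mock" else "measurement",
    n_debris = n_debris, n_edge = n_edge, n_positive = n_pos
  )
  out
}

#' Simulate a full orthogonality screen
#'
#' For every trigger x switch combination (including the No-gRNA control
#' switch) and every replicate, generates a trigger-plus and a
#' trigger-minus sample, plus one mock sample per replicate, with
#' per-sample sub-seeds derived from `(seed, sample_id)`.
#'
#' @inheritParams simulate_sample
#' @param replicates Number of replicates, >= 1.
#' @return A `screen_dataset`: list with `events` (named list of event
#'   tables), `sample_sheet` (data.frame with columns `sample_id,
#'   switch_id, trigger_id, condition, replicate, role`), `panel`, `pop`,
#'   `seed`.
#' @export
simulate_orthogonality_screen <- function(panel,
                                          pop = cell_population_model(),
                                          n_events = 5000,
                                          replicates = 3,
                                          seed = 1L) {
  if (replicates < 1) abort_oc("invalid_parameter_error", "replicates must be >= 1")
  replicates <- as.integer(replicates)

  rows <- list()
  for (r in seq_len(replicates)) {
    for (sw in panel$switch_ids) {
      for (tr in panel$trigger_ids) {
        for (cond in c("trigger_plus", "trigger_minus")) {
          sid <- sprintf("%s.%s.%s.r%d", sw, tr,
                         if (cond == "trigger_plus") "plus" else "minus", r)
          role <- if (sw == panel$no_grna_id) "no_gRNA_control" else "measurement"
          rows[[length(rows) + 1L]] <- data.frame(
            sample_id = sid, switch_id = sw, trigger_id = tr,
            condition = cond, replicate = r, role = role
          )
        }
      }
    }
    rows[[length(rows) + 1L]] <- data.frame(
      sample_id = sprintf("mock.r%d", r), switch_id = NA_character_,
      trigger_id = NA_character_, condition = "mock", replicate = r,
      role = "mock"
    )
  }
  sheet <- do.call(rbind, rows)

  events <- vector("list", nrow(sheet))
  names(events) <- sheet$sample_id
  for (k in seq_len(nrow(sheet))) {
    row <- sheet[k, ]
    sub <- sample_subseed(seed, row$sample_id)
    events[[k]] <- if (row$role == "mock") {
      simulate_sample(panel, NA, NULL, pop, n_events, sub)
    } else {
      simulate_sample(
        panel, row$switch_id,
        trigger_id = if (row$condition == "trigger_plus") row$trigger_id else NULL,
        pop = pop, n_events = n_events, seed = sub
      )
    }
  }

  structure(list(events = events, sample_sheet = sheet, panel = panel,
                 pop = pop, seed = seed),
            class = "screen_dataset")
}

#' Simulate a logic-gate measurement panel
#'
#' For each gate specification, generates one sample per truth-table input
#' state whose expected normalized intensity (1000 x median
#' reporter/reference) equals the specified level: `on_level` in ON
#' states, the corresponding `leak_levels` entry in OFF states.
#'
#' @param gate_specs List of `list(truth_table=, on_level=, leak_levels=)`
#'   where `leak_levels` has one value per OFF state (recycled if scalar).
#'   An optional `circuit_id` names the gate.
#' @inheritParams simulate_sample
#' @return A `gate_panel_dataset`: list with `events` (named list, names
#'   `<circuit_id>.s<state>`), `sheet` (circuit_id, state, planted_ni),
#'   `mock` (an untransfected event table for gating), `specs`, `pop`,
#'   `seed`.
#' @export
simulate_gate_panel <- function(gate_specs,
                                pop = cell_population_model(),
                                n_events = 2000,
                                seed = 1L) {
  events <- list()
  rows <- list()
  ref_scale <- 10^pop$ref_mean_log10
  for (g in seq_along(gate_specs)) {
    spec <- gate_specs[[g]]
    tt <- spec$truth_table
    if (!inherits(tt, "truth_table")) {
      abort_oc("invalid_parameter_error", "each gate spec needs a truth_table")
    }
    cid <- if (!is.null(spec$circuit_id)) spec$circuit_id else sprintf("gate%03d", g)
    n_states <- length(tt$ideal)
    leaks <- rep_len(spec$leak_levels, sum(tt$ideal == 0))
    if (any(leaks < 0) || spec$on_level <= 0) {
      abort_oc("invalid_parameter_error",
               "on_level must be > 0 and leak levels >= 0")
    }
    levels <- numeric(n_states)
    levels[tt$ideal == 1] <- spec$on_level
    levels[tt$ideal == 0] <- leaks
    for (s in seq_len(n_states)) {
      sid <- sprintf("%s.s%d", cid, s)
      # one-switch panel whose basal reproduces the target NI exactly
      # (a zero leak level is floored so reporter draws stay positive)
      one <- build_ground_truth_panel(
        1, "OFF", on_target_effect = 0.5,
        basal_reporter = max(levels[s], 1e-3) / 1000 * ref_scale,
        basal_sd_log10 = 0
      )
      events[[sid]] <- simulate_sample(one, "sw01", NULL, pop, n_events,
                                       sample_subseed(seed, sid))
      rows[[length(rows) + 1L]] <- data.frame(
        circuit_id = cid, state = s, sample_id = sid, planted_ni = levels[s]
      )
    }
  }
  mock <- simulate_sample(NULL, NA, NULL, pop, n_events,
                          sample_subseed(seed, "mock"))
  structure(list(events = events, sheet = do.call(rbind, rows),
                 mock = mock, specs = gate_specs, pop = pop, seed = seed),
            class = "gate_panel_dataset")
}

#' Simulate a fold-change matrix directly from a planted panel
#'
#' Matrix-level shortcut past event simulation: each normalized
#' fold-change entry is the planted effect times multiplicative
#' log-normal noise. Useful for exercising the subset search at panel
#' sizes where full event simulation is unnecessary.
#'
#' @param panel A ground-truth panel.
#' @param noise_sd_log10 Log10 sd of the multiplicative noise per entry.
#' @param seed Integer seed.
#' @return Numeric matrix, triggers x switches (No-gRNA column dropped).
#' @export
simulate_fold_change_matrix <- function(panel, noise_sd_log10 = 0.0212,
                                        seed = 1L) {
  set.seed(as.integer(seed))
  truth <- panel$effect[, setdiff(panel$switch_ids, panel$no_grna_id),
                        drop = FALSE]
  noise <- matrix(10^stats::rnorm(length(truth), 0, noise_sd_log10),
                  nrow(truth), ncol(truth))
  truth * noise
}

#' Expected reporter levels along a translational repression cascade
#'
#' Steady-state expectation for chained OFF switches: each stage's
#' regulator scales the next stage's log-output in proportion to its own
#' level, so `level[k] = repression ^ level[k-1]` with `level[0] = 1`.
#' Outputs alternate low/high as stages are added, converging toward the
#' fixed point.
#'
#' @param n_stages Number of chained repression stages, >= 0.
#' @param repression Single-stage repression factor in (0, 1).
#' @return Numeric vector of length `n_stages + 1`: the normalized
#'   reporter level after 0, 1, ..., `n_stages` stages.
#' @export
cascade_expected_levels <- function(n_stages, repression = 0.1) {
  if (repression <= 0 || repression >= 1) {
    abort_oc("invalid_parameter_error", "repression must be in (0, 1)")
  }
  out <- numeric(n_stages + 1L)
  out[1] <- 1
  for (k in seq_len(n_stages)) out[k + 1L] <- repression^out[k]
  out
}
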