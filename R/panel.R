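#' Build a planted ground-truth switch/trigger panel
#'
#' Constructs the multiplicative effect matrix that defines a synthetic
#' orthogonality screen: one translational switch per trigger (Cas protein),
#' plus a "No gRNA" control switch that no trigger can act on. Each matrix
#' entry is the multiplicative factor applied to reporter expression from
#' that switch when that trigger is co-expressed: on-target entries are
#' below 1 for OFF switches (translational repression) and above 1 for ON
#' switches (activation); all other entries are 1 unless a crosstalk entry
#' is planted.
#'
#' @param n_triggers Number of triggers (and matched switches), >= 1.
#' @param switch_types Character vector of `"OFF"`/`"ON"`, length 1 or
#'   `n_triggers`, giving each matched switch's polarity.
#' @param on_target_effect Multiplicative on-target effect. Length 1 or
#'   `n_triggers`; must be > 0. Conventionally < 1 for OFF switches and
#'   > 1 for ON switches.
#' @param crosstalk_spec Optional list of `list(trigger=, switch=, factor=)`
#'   entries planting off-target effects; trigger/switch may be given as
#'   index or id. Duplicate (trigger, switch) entries are an error.
#' @param basal_reporter Median basal reporter level (a.u.) per switch,
#'   length 1 or `n_triggers + 1` (the extra value is the No-gRNA control).
#'   Mild switch-to-switch variation is drawn when `basal_sd_log10 > 0`.
#' @param basal_sd_log10 Log10 standard deviation of the basal variation.
#' @param seed Integer seed for the basal variation draw.
#'
#' @return A `ground_truth_panel`: list with `trigger_ids`, `switch_ids`
#'   (last id is the No-gRNA control), `switch_type`, `effect` (trigger x
#'   switch matrix), `basal_reporter`, `no_grna_id`.
#' @export
build_ground_truth_panel <- function(n_triggers,
                                     switch_types = "OFF",
                                     on_target_effect = 0.1,
                                     crosstalk_spec = NULL,
                                     basal_reporter = 2000,
                                     basal_sd_log10 = 0.1,
                                     seed = 1L) {
  if (!is.numeric(n_triggers) || length(n_triggers) != 1L || n_triggers < 1) {
    abort_oc("invalid_parameter_error", "`n_triggers` must be >= 1")
  }
  n_triggers <- as.integer(n_triggers)
  switch_types <- rep_len(toupper(switch_types), n_triggers)
  if (!all(switch_types %in% c("OFF", "ON"))) {
    abort_oc("invalid_parameter_error", "switch types must be 'OFF' or 'ON'")
  }
  on_target_effect <- rep_len(on_target_effect, n_triggers)
  if (any(!is.finite(on_target_effect)) || any(on_target_effect <= 0)) {
    abort_oc("invalid_parameter_error", "on-target effects must be positive")
  }

  trigger_ids <- sprintf("Cas%02d", seq_len(n_triggers))
  no_grna_id <- "No_gRNA"
  switch_ids <- c(sprintf("sw%02d", seq_len(n_triggers)), no_grna_id)

  effect <- matrix(1, n_triggers, n_triggers + 1L,
                   dimnames = list(trigger_ids, switch_ids))
  for (i in seq_len(n_triggers)) effect[i, i] <- on_target_effect[i]

  if (!is.null(crosstalk_spec)) {
    seen <- character(0)
    for (ct in crosstalk_spec) {
      ti <- resolve_id(ct[[1]], trigger_ids, "trigger")
      si <- resolve_id(ct[[2]], switch_ids[seq_len(n_triggers)], "switch")
      f <- ct[[3]]
      if (!is.numeric(f) || !is.finite(f) || f <= 0) {
        abort_oc("invalid_parameter_error", "crosstalk factors must be positive")
      }
      key <- paste(ti, si, sep = "\r")
      if (key %in% seen) {
        abort_oc("invalid_parameter_error",
                 sprintf("duplicate crosstalk entry (%s, %s)", ti, si))
      }
      seen <- c(seen, key)
      effect[ti, si] <- f
    }
  }

  basal <- rep_len(basal_reporter, n_triggers + 1L)
  if (any(basal <= 0)) {
    abort_oc("invalid_parameter_error", "basal reporter levels must be positive")
  }
  if (basal_sd_log10 > 0) {
    # one draw per switch id, sub-seeded, so growing the panel never
    # changes the basal level of an existing switch
    z <- vapply(switch_ids, function(sw) {
      set.seed(sample_subseed(seed, paste0("basal.", sw)))
      stats::rnorm(1, 0, basal_sd_log10)
    }, numeric(1))
    basal <- basal * 10^z
  }
  names(basal) <- switch_ids

  structure(
    list(trigger_ids = trigger_ids,
         switch_ids = switch_ids,
         switch_type = stats::setNames(switch_types, switch_ids[seq_len(n_triggers)]),
         effect = effect,
         basal_reporter = basal,
         no_grna_id = no_grna_id),
    class = "ground_truth_panel"
  )
}

resolve_id <- function(x, ids, what) {
  if (is.numeric(x)) {
    x <- as.integer(x)
    if (x < 1L || x > length(ids)) {
      abort_oc("invalid_parameter_error", sprintf("%s index out of range", what))
    }
    return(ids[x])
  }
  if (!x %in% ids) {
    abort_oc("invalid_parameter_error", sprintf("unknown %s id '%s'", what, x))
  }
  x
}

#' Look up the planted multiplicative effect of a trigger on a switch
#'
#' @param panel A `ground_truth_panel`.
#' @param trigger_id Trigger id, or `NA`/`NULL` for the trigger-minus
#'   condition (effect 1 by definition).
#' @param switch_id Switch id (may be the No-gRNA control).
#' @return The multiplicative effect factor.
#' @export
panel_effect <- function(panel, trigger_id, switch_id) {
  if (!switch_id %in% panel$switch_ids) {
    abort_oc("lookup_error", sprintf("unknown switch '%s'", switch_id))
  }
  if (is.null(trigger_id) || is.na(trigger_id)) return(1)
  if (!trigger_id %in% panel$trigger_ids) {
    abort_oc("lookup_error", sprintf("unknown trigger '%s'", trigger_id))
  }
  panel$effect[trigger_id, switch_id]
}

#' @export
print.ground_truth_panel <- function(x, ...) {
  cat(sprintf("ground_truth_panel: %d triggers x %d switches (incl. %s)\n",
              length(x$trigger_ids), length(x$switch_ids), x$no_grna_id))
  cat(sprintf("  switch types: %s\n",
              paste(sprintf("%d %s", table(x$switch_type),
                            names(table(x$switch_type))), collapse = ", ")))
  n_ct <- sum(x$effect[, -ncol(x$effect), drop = FALSE] != 1) - nrow(x$effect)
  cat(sprintf("  planted crosstalk entries: %d\n", max(0L, n_ct)))
  invisible(x)
}
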