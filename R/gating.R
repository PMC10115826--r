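#' Gating configuration
#'
#' Deterministic stand-ins for the manual gates drawn on mock samples in
#' cytometry software: a rectangular debris gate on scatter, exact
#' saturation-clamp removal on the fluorescence axes, and a
#' reference-positive threshold at a stated percentile of the mock
#' sample's reference channel.
#'
#' @param fsc_min,ssc_min Lower scatter bounds for the debris gate (a.u.).
#' @param channel_min,channel_max Saturation limits used by the edge gate;
#'   must match the acquisition settings of the event tables.
#' @param mock_percentile Percentile of mock reference intensity defining
#'   the reference-positive threshold (events strictly above it are kept);
#'   in (0, 100).
#' @param debris,edge,reference Logical flags enabling each step.
#' @return A `gate_config` list.
#' @export
gate_config <- function(fsc_min = 3e4, ssc_min = 1.2e4,
                        channel_min = 0, channel_max = 1e6,
                        mock_percentile = 99.9,
                        debris = TRUE, edge = TRUE, reference = TRUE) {
  if (mock_percentile <= 0 || mock_percentile >= 100) {
    abort_oc("invalid_parameter_error", "mock_percentile must be in (0, 100)")
  }
  if (!all(is.finite(c(fsc_min, ssc_min, channel_min, channel_max)))) {
    abort_oc("config_error", "gate bounds must be finite")
  }
  structure(as.list(environment()), class = "gate_config")
}

#' Gate configuration matching a population model
#'
#' @param pop A [cell_population_model()].
#' @param ... Overrides passed to [gate_config()].
#' @return A `gate_config` whose channel limits equal the model's.
#' @export
gate_config_for <- function(pop, ...) {
  args <- list(...)
  defaults <- list(channel_min = pop$channel_min, channel_max = pop$channel_max)
  do.call(gate_config, utils::modifyList(defaults, args))
}

check_columns <- function(events, cols) {
  missing <- setdiff(cols, names(events))
  if (length(missing)) {
    abort_oc("schema_error",
             sprintf("event table lacks column(s): %s",
                     paste(missing, collapse = ", ")))
  }
}

#' Remove debris events by rectangular scatter gate
#'
#' Retains events with `fsc >= fsc_min` and `ssc >= ssc_min`, preserving
#' order and all channel values.
#'
#' @param events Event table with `fsc`, `ssc` columns.
#' @param cfg A [gate_config()].
#' @return The filtered event table.
#' @export
remove_debris <- function(events, cfg = gate_config()) {
  check_columns(events, c("fsc", "ssc"))
  keep <- events$fsc >= cfg$fsc_min & events$ssc >= cfg$ssc_min
  events[keep, , drop = FALSE]
}

#' Remove events clamped at the chart edges
#'
#' Drops events whose reporter or reference intensity equals the channel
#' minimum or maximum exactly (instrument saturation).
#'
#' @inheritParams remove_debris
#' @return The filtered event table.
#' @export
remove_edge_events <- function(events, cfg = gate_config()) {
  check_columns(events, c("reporter", "reference"))
  if (is.null(cfg$channel_min) || is.null(cfg$channel_max)) {
    abort_oc("config_error", "channel limits missing from gate config")
  }
  at_edge <- events$reporter == cfg$channel_min |
    events$reporter == cfg$channel_max |
    events$reference == cfg$channel_min |
    events$reference == cfg$channel_max
  events[!at_edge, , drop = FALSE]
}

#' Reference-positive gate from a mock sample
#'
#' The threshold is the `mock_percentile`-th percentile of the mock
#' sample's reference intensities; events with reference strictly above
#' the threshold survive.
#'
#' @param events Event table to gate.
#' @param mock Mock (untransfected) event table defining the threshold.
#' @param cfg A [gate_config()].
#' @return A `gated_events` object: list with `events` (survivors),
#'   `removed` (named per-step counts), `threshold`, `n_input`.
#' @export
reference_positive_gate <- function(events, mock, cfg = gate_config()) {
  check_columns(events, "reference")
  if (is.null(mock) || nrow(mock) == 0) {
    abort_oc("insufficient_data_error", "mock sample is empty")
  }
  check_columns(mock, "reference")
  threshold <- unname(stats::quantile(mock$reference,
                                      cfg$mock_percentile / 100, type = 7))
  keep <- events$reference > threshold
  gated_events(events[keep, , drop = FALSE],
               removed = c(debris = 0L, edge = 0L,
                           reference_negative = sum(!keep)),
               threshold = threshold, n_input = nrow(events))
}

gated_events <- function(events, removed, threshold, n_input) {
  structure(list(events = events, removed = removed,
                 threshold = threshold, n_input = n_input),
            class = "gated_events")
}

#' @export
print.gated_events <- function(x, ...) {
  cat(sprintf("gated_events: %d of %d events survive\n",
              nrow(x$events), x$n_input))
  cat(sprintf("  removed: %s\n",
              paste(sprintf("%s=%d", names(x$removed), x$removed),
                    collapse = ", ")))
  if (!is.na(x$threshold)) {
    cat(sprintf("  reference-positive threshold: %.6g\n", x$threshold))
  }
  invisible(x)
}

#' Standard gating chain: debris, edge, reference-positive
#'
#' Applies the three gates in the fixed order used throughout the
#' analysis, accumulating per-step removal counts. Steps can be disabled
#' through the config flags; the reference gate requires a mock sample.
#'
#' @param events Event table to gate.
#' @param mock Mock event table (required when `cfg$reference` is TRUE).
#' @param cfg A [gate_config()].
#' @return A `gated_events` object with per-step `removed` counts and the
#'   reference threshold (NA when that step did not run).
#' @export
apply_standard_gating <- function(events, mock = NULL, cfg = gate_config()) {
  n0 <- nrow(events)
  cur <- events
  removed <- c(debris = 0L, edge = 0L, reference_negative = 0L)
  if (isTRUE(cfg$debris)) {
    nxt <- remove_debris(cur, cfg)
    removed["debris"] <- nrow(cur) - nrow(nxt)
    cur <- nxt
  }
  if (isTRUE(cfg$edge)) {
    nxt <- remove_edge_events(cur, cfg)
    removed["edge"] <- nrow(cur) - nrow(nxt)
    cur <- nxt
  }
  threshold <- NA_real_
  if (isTRUE(cfg$reference)) {
    # the mock passes through the same upstream gates before it defines
    # the reference-positive threshold, else its own debris/edge events
    # distort the percentile
    if (!is.null(mock)) {
      if (isTRUE(cfg$debris)) mock <- remove_debris(mock, cfg)
      if (isTRUE(cfg$edge)) mock <- remove_edge_events(mock, cfg)
    }
    rg <- reference_positive_gate(cur, mock, cfg)
    removed["reference_negative"] <- rg$removed[["reference_negative"]]
    threshold <- rg$threshold
    cur <- rg$events
  }
  gated_events(cur, removed, threshold, n0)
}

#' Gating report as a serializable list
#'
#' @param gated A `gated_events` object.
#' @return List with input/surviving counts, per-step removals and the
#'   reference threshold; suitable for [jsonlite::write_json()].
#' @export
gating_report <- function(gated) {
  list(n_input = gated$n_input,
       n_surviving = nrow(gated$events),
       removed = as.list(gated$removed),
       reference_threshold = if (is.na(gated$threshold)) NULL else gated$threshold)
}
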