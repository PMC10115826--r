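#' Canonical truth table for a named logic gate
#'
#' States are ordered with the first input varying fastest: for two
#' inputs, `[0,0], [1,0], [0,1], [1,1]`. `NIMPLY(A, B)` is `A AND NOT B`
#' and is defined for two inputs only.
#'
#' @param name One of `"AND"`, `"NAND"`, `"NOR"`, `"OR"`, `"XOR"`,
#'   `"NIMPLY"`.
#' @param n_inputs Number of inputs (default 2). XOR generalizes to odd
#'   parity.
#' @return A `truth_table`: list with `name`, `n_inputs`, `states`
#'   (matrix, one row per state) and `ideal` (0/1 vector).
#' @export
truth_table <- function(name, n_inputs = 2) {
  name <- toupper(name)
  n_inputs <- as.integer(n_inputs)
  if (n_inputs < 1) abort_oc("invalid_parameter_error", "n_inputs must be >= 1")
  states <- as.matrix(expand.grid(rep(list(0:1), n_inputs)))
  dimnames(states) <- list(
    apply(states, 1, function(s) paste0("[", paste(s, collapse = ","), "]")),
    sprintf("in%d", seq_len(n_inputs))
  )
  ideal <- switch(
    name,
    AND = as.integer(rowSums(states) == n_inputs),
    OR = as.integer(rowSums(states) > 0),
    NAND = as.integer(rowSums(states) < n_inputs),
    NOR = as.integer(rowSums(states) == 0),
    XOR = as.integer(rowSums(states) %% 2 == 1),
    NIMPLY = {
      if (n_inputs != 2) {
        abort_oc("invalid_parameter_error", "NIMPLY is defined for 2 inputs")
      }
      as.integer(states[, 1] == 1 & states[, 2] == 0)
    },
    abort_oc("invalid_parameter_error", sprintf("unknown gate '%s'", name))
  )
  structure(list(name = name, n_inputs = n_inputs,
                 states = states, ideal = ideal),
            class = "truth_table")
}

check_measurement <- function(ni, table) {
  ni <- as.numeric(ni)
  if (length(ni) != length(table$ideal)) {
    abort_oc("invalid_parameter_error",
             sprintf("measurement has %d states, truth table %d",
                     length(ni), length(table$ideal)))
  }
  if (any(!is.finite(ni)) || any(ni < 0)) {
    abort_oc("invalid_parameter_error", "state NIs must be finite and >= 0")
  }
  ni
}

#' Net fold-change of a logic gate
#'
#' Mean observed intensity over the table's ON state(s) divided by the
#' mean over its OFF states. For the 2-input AND gate this is
#' `NI([1,1]) / mean(NI over [0,0], [1,0], [0,1])`.
#'
#' @param ni Observed normalized intensities, one per state, in the
#'   table's state order.
#' @param table A [truth_table()].
#' @return The net fold-change.
#' @export
net_fold_change <- function(ni, table) {
  ni <- check_measurement(ni, table)
  on <- ni[table$ideal == 1]
  off <- ni[table$ideal == 0]
  if (length(on) == 0 || length(off) == 0) {
    abort_oc("invalid_parameter_error",
             "truth table must have at least one ON and one OFF state")
  }
  if (mean(off) <= 0) {
    abort_oc("division_domain_error", "mean OFF-state NI must be > 0")
  }
  mean(on) / mean(off)
}

#' Vector proximity angle between observed outputs and a truth table
#'
#' The angle between the ideal 0/1 truth-table vector and the observed
#' per-state intensity vector, in degrees: 0 when the observation is
#' proportional to the ideal pattern, 90 when orthogonal to it (the
#' worst case for nonnegative observations).
#'
#' @inheritParams net_fold_change
#' @return Angle in degrees, in [0, 90] for nonnegative `ni`.
#' @export
vector_proximity_angle <- function(ni, table) {
  ni <- check_measurement(ni, table)
  truth <- as.numeric(table$ideal)
  n_obs <- sqrt(sum(ni^2))
  if (n_obs == 0) {
    abort_oc("degenerate_measurement_error", "observed vector is all zero")
  }
  cosv <- sum(truth * ni) / (sqrt(sum(truth^2)) * n_obs)
  cosv <- min(1, max(-1, cosv))  # absorb rounding before arccos
  acos(cosv) * 180 / pi
}

#' Score a panel of gate measurements against one truth table
#'
#' @param measurements List of per-gate state-NI vectors (optionally
#'   named by circuit id), or a data frame with columns
#'   `circuit_id, state, ni`.
#' @param table A [truth_table()].
#' @param angle_cutoff Pass threshold in degrees (default 20); the
#'   boundary is inclusive.
#' @return A `gate_panel_scores` data frame with columns `circuit_id`,
#'   `net_fold_change`, `theta_deg`, `pass`, plus a `pass_count`
#'   attribute.
#' @export
evaluate_gate_panel <- function(measurements, table, angle_cutoff = 20) {
  if (is.data.frame(measurements)) {
    check_columns(measurements, c("circuit_id", "state", "ni"))
    split_ni <- split(measurements[order(measurements$state), ],
                      measurements$circuit_id[order(measurements$state)])
    measurements <- lapply(split_ni, `[[`, "ni")
  }
  ids <- names(measurements)
  if (is.null(ids)) ids <- sprintf("gate%03d", seq_along(measurements))
  nfc_one <- function(ni) {
    # an ideal gate with exactly zero OFF leak has unbounded fold change
    tryCatch(net_fold_change(ni, table),
             division_domain_error = function(e) Inf)
  }
  scores <- data.frame(
    circuit_id = ids,
    net_fold_change = unname(vapply(measurements, nfc_one, numeric(1))),
    theta_deg = unname(vapply(measurements, vector_proximity_angle,
                              numeric(1), table = table)),
    row.names = NULL
  )
  scores$pass <- scores$theta_deg <= angle_cutoff
  attr(scores, "pass_count") <- sum(scores$pass)
  attr(scores, "angle_cutoff") <- angle_cutoff
  class(scores) <- c("gate_panel_scores", "data.frame")
  scores
}

#' Enumerate 2-input AND circuits over a switch set
#'
#' Every circuit takes an unordered pair of switches as inputs A, B and
#' a distinct third switch as the mediator C, giving
#' `choose(k, 2) * (k - 2)` circuits for `k` switches, in deterministic
#' lexicographic order (input pair, then mediator).
#'
#' @param switch_ids Character vector of at least 3 distinct ids.
#' @return Data frame with columns `input_a`, `input_b`, `mediator`,
#'   `circuit_id`.
#' @export
enumerate_and_gate_assignments <- function(switch_ids) {
  switch_ids <- as.character(switch_ids)
  if (length(switch_ids) < 3 || anyDuplicated(switch_ids)) {
    abort_oc("invalid_parameter_error",
             "need >= 3 distinct switch ids for AND-gate assignment")
  }
  k <- length(switch_ids)
  rows <- list()
  for (a in seq_len(k - 1L)) {
    for (b in (a + 1L):k) {
      for (m in seq_len(k)) {
        if (m == a || m == b) next
        rows[[length(rows) + 1L]] <- data.frame(
          input_a = switch_ids[a], input_b = switch_ids[b],
          mediator = switch_ids[m],
          circuit_id = sprintf("%s+%s>%s", switch_ids[a], switch_ids[b],
                               switch_ids[m])
        )
      }
    }
  }
  do.call(rbind, rows)
}

#' Score a half-subtractor's difference and borrow outputs
#'
#' State intensities are first normalized to the `[0,0]` state, then the
#' difference output is scored against XOR and the borrow output against
#' NIMPLY. With inputs ordered (first, second) and
#' `borrow = "first_nimply_second"` (default), the borrow fires when
#' only the first input is present — the convention for subtracting the
#' second operand from the first when the *first* listed protein is the
#' subtrahend's complement; use `"second_nimply_first"` to swap.
#'
#' @param d_ni,bo_ni Observed intensities of the difference and borrow
#'   channels over the four states `[0,0],[1,0],[0,1],[1,1]`.
#' @param borrow Operand order of the borrow's NIMPLY.
#' @param angle_cutoff Pass threshold in degrees.
#' @return List with `difference` and `borrow`, each a list of
#'   `theta_deg`, `net_fold_change`, `pass`, `nfi` (the
#'   `[0,0]`-normalized intensities).
#' @export
evaluate_half_subtractor <- function(d_ni, bo_ni,
                                     borrow = c("first_nimply_second",
                                                "second_nimply_first"),
                                     angle_cutoff = 20) {
  borrow <- match.arg(borrow)
  xor_tt <- truth_table("XOR")
  nimply_tt <- truth_table("NIMPLY")
  if (borrow == "second_nimply_first") {
    nimply_tt$ideal <- nimply_tt$ideal[c(1, 3, 2, 4)]
  }
  score_one <- function(ni, tt) {
    ni <- check_measurement(ni, tt)
    if (ni[1] <= 0) {
      abort_oc("division_domain_error", "[0,0]-state intensity must be > 0")
    }
    nfi <- vapply(ni, normalized_fluorescence_intensity, numeric(1),
                  dv_control = ni[1])
    theta <- vector_proximity_angle(nfi, tt)
    list(theta_deg = theta,
         net_fold_change = net_fold_change(nfi, tt),
         pass = theta <= angle_cutoff,
         nfi = nfi)
  }
  list(difference = score_one(d_ni, xor_tt),
       borrow = score_one(bo_ni, nimply_tt))
}
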