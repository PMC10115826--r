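#' Read an event table from CSV
#'
#' Expects the exact header `event_id,fsc,ssc,reporter,reference`.
#'
#' @param path Path to a CSV file.
#' @return An event table data frame.
#' @export
read_events <- function(path) {
  events <- utils::read.csv(path, stringsAsFactors = FALSE)
  expected <- c("event_id", "fsc", "ssc", "reporter", "reference")
  if (!identical(names(events), expected)) {
    abort_oc("schema_error",
             sprintf("expected columns '%s', found '%s' in %s",
                     paste(expected, collapse = ","),
                     paste(names(events), collapse = ","), path))
  }
  if (anyDuplicated(events$event_id)) {
    abort_oc("schema_error", sprintf("duplicate event_id in %s", path))
  }
  events
}

#' Write an event table to CSV
#'
#' @param events Event table data frame.
#' @param path Destination path.
#' @export
write_events <- function(events, path) {
  check_columns(events, c("event_id", "fsc", "ssc", "reporter", "reference"))
  utils::write.csv(format_numeric_df(events), path, row.names = FALSE,
                   quote = FALSE)
  invisible(path)
}

#' Read a sample sheet from CSV
#'
#' Expects the header
#' `sample_id,switch_id,trigger_id,condition,replicate,role` and unique
#' sample ids.
#'
#' @param path Path to a CSV file.
#' @return A sample-sheet data frame.
#' @export
read_sample_sheet <- function(path) {
  sheet <- utils::read.csv(path, stringsAsFactors = FALSE)
  expected <- c("sample_id", "switch_id", "trigger_id", "condition",
                "replicate", "role")
  if (!identical(names(sheet), expected)) {
    abort_oc("schema_error",
             sprintf("sample sheet %s must have columns '%s'",
                     path, paste(expected, collapse = ",")))
  }
  dup <- which(duplicated(sheet$sample_id))
  if (length(dup)) {
    abort_oc("schema_error",
             sprintf("duplicate sample_id '%s' at sheet row %d",
                     sheet$sample_id[dup[1]], dup[1]))
  }
  sheet
}

# 17 significant digits so every double survives a text round trip
format_numeric_df <- function(df) {
  for (col in names(df)) {
    if (is.double(df[[col]])) df[[col]] <- sprintf("%.17g", df[[col]])
  }
  df
}

#' Write a numeric matrix as TSV
#'
#' Row names go into a leading `id` column; values are serialized with
#' 17 significant digits.
#'
#' @param mat Numeric matrix with dimnames.
#' @param path Destination path.
#' @export
write_matrix <- function(mat, path) {
  df <- data.frame(id = rownames(mat),
                   apply(mat, 2, function(x) sprintf("%.17g", x)),
                   check.names = FALSE)
  utils::write.table(df, path, sep = "\t", row.names = FALSE, quote = FALSE)
  invisible(path)
}

#' Read a numeric matrix written by [write_matrix()]
#'
#' @param path Path to the TSV file.
#' @return Numeric matrix with dimnames.
#' @export
read_matrix <- function(path) {
  df <- utils::read.delim(path, check.names = FALSE, stringsAsFactors = FALSE)
  if (names(df)[1] != "id") {
    abort_oc("schema_error", sprintf("matrix TSV %s lacks the 'id' column", path))
  }
  mat <- as.matrix(df[, -1, drop = FALSE])
  rownames(mat) <- df$id
  storage.mode(mat) <- "double"
  mat
}

#' Summarize an orthogonality screen to a fold-change matrix
#'
#' Gates every measurement sample against its replicate's mock sample,
#' computes per-sample normalized intensities, forms per-replicate
#' relative intensities (trigger-plus over trigger-minus), normalizes by
#' the No-gRNA control's RI under the same trigger and replicate, and
#' averages over replicates into the trigger-by-switch fold-change
#' matrix used by the orthogonality screen.
#'
#' @param dataset A `screen_dataset` from
#'   [simulate_orthogonality_screen()], or an equivalent list with
#'   `events`, `sample_sheet`, `panel`.
#' @param cfg A [gate_config()]; defaults to one matching the dataset's
#'   population model.
#' @param orient_off_reciprocal If TRUE, entries of OFF switches are
#'   reported as reciprocals (fold-change orientation, >= 1 on target)
#'   instead of the raw normalized fold change.
#' @return A `screen_summary`: list with `ni` (per-sample table),
#'   `comparisons` (per switch/trigger: replicate rel-expr values, mean,
#'   sd), `fc_matrix` (triggers x switches, No-gRNA column excluded) and
#'   `gating` (per-sample removal counts).
#' @export
summarize_screen <- function(dataset, cfg = NULL,
                             orient_off_reciprocal = FALSE) {
  sheet <- dataset$sample_sheet
  panel <- dataset$panel
  if (is.null(cfg)) {
    cfg <- if (!is.null(dataset$pop)) gate_config_for(dataset$pop) else gate_config()
  }

  mocks <- lapply(split(sheet, sheet$replicate), function(rows) {
    mock_id <- rows$sample_id[rows$role == "mock"]
    if (length(mock_id) != 1) {
      abort_oc("schema_error",
               sprintf("replicate %s needs exactly one mock sample",
                       rows$replicate[1]))
    }
    dataset$events[[mock_id]]
  })

  meas <- sheet[sheet$role != "mock", ]
  ni_rows <- vector("list", nrow(meas))
  gating_rows <- vector("list", nrow(meas))
  for (k in seq_len(nrow(meas))) {
    row <- meas[k, ]
    gated <- apply_standard_gating(dataset$events[[row$sample_id]],
                                   mocks[[as.character(row$replicate)]], cfg)
    ni <- normalized_intensity(gated, row$sample_id)
    ni_rows[[k]] <- data.frame(
      sample_id = row$sample_id, switch_id = row$switch_id,
      trigger_id = row$trigger_id, condition = row$condition,
      replicate = row$replicate, n_cells = ni$n_cells, NI = ni$NI
    )
    gating_rows[[k]] <- data.frame(
      sample_id = row$sample_id, n_input = gated$n_input,
      n_surviving = nrow(gated$events),
      removed_debris = gated$removed[["debris"]],
      removed_edge = gated$removed[["edge"]],
      removed_reference_negative = gated$removed[["reference_negative"]],
      reference_threshold = gated$threshold
    )
  }
  ni_tab <- do.call(rbind, ni_rows)

  key <- function(sw, tr, cond, rep) paste(sw, tr, cond, rep, sep = "\r")
  ni_of <- stats::setNames(
    ni_tab$NI, key(ni_tab$switch_id, ni_tab$trigger_id, ni_tab$condition,
                   ni_tab$replicate))

  replicates <- sort(unique(ni_tab$replicate))
  switches <- setdiff(panel$switch_ids, panel$no_grna_id)
  comp_rows <- list()
  fc <- matrix(NA_real_, length(panel$trigger_ids), length(switches),
               dimnames = list(panel$trigger_ids, switches))
  for (tr in panel$trigger_ids) {
    ri_nog <- vapply(replicates, function(r) {
      relative_intensity(ni_of[[key(panel$no_grna_id, tr, "trigger_plus", r)]],
                         ni_of[[key(panel$no_grna_id, tr, "trigger_minus", r)]])
    }, numeric(1))
    for (sw in switches) {
      vals <- vapply(seq_along(replicates), function(i) {
        r <- replicates[i]
        ri <- relative_intensity(ni_of[[key(sw, tr, "trigger_plus", r)]],
                                 ni_of[[key(sw, tr, "trigger_minus", r)]])
        relative_reporter_expression(ri, ri_nog[i])
      }, numeric(1))
      if (orient_off_reciprocal && panel$switch_type[[sw]] == "OFF") {
        vals <- 1 / vals
      }
      ms <- summarize_replicates(vals)
      fc[tr, sw] <- ms$mean
      comp_rows[[length(comp_rows) + 1L]] <- data.frame(
        switch_id = sw, trigger_id = tr,
        rel_expr_mean = ms$mean, rel_expr_sd = ms$sd,
        n_replicates = length(vals)
      )
    }
  }

  structure(list(ni = ni_tab,
                 comparisons = do.call(rbind, comp_rows),
                 fc_matrix = fc,
                 gating = do.call(rbind, gating_rows)),
            class = "screen_summary")
}

#' Summarize a simulated gate panel into per-state intensities
#'
#' Gates every state sample of every circuit against the dataset's mock
#' sample and computes its normalized intensity.
#'
#' @param dataset A `gate_panel_dataset` from [simulate_gate_panel()].
#' @param cfg A [gate_config()]; defaults to one matching the dataset's
#'   population model.
#' @return Data frame `circuit_id, state, ni` suitable for
#'   [evaluate_gate_panel()].
#' @export
summarize_gate_panel <- function(dataset, cfg = NULL) {
  if (is.null(cfg)) cfg <- gate_config_for(dataset$pop)
  sheet <- dataset$sheet
  ni <- vapply(seq_len(nrow(sheet)), function(k) {
    gated <- apply_standard_gating(dataset$events[[sheet$sample_id[k]]],
                                   dataset$mock, cfg)
    normalized_intensity(gated, sheet$sample_id[k])$NI
  }, numeric(1))
  data.frame(circuit_id = sheet$circuit_id, state = sheet$state, ni = ni)
}

#' Pipeline configuration
#'
#' Bundles every tunable of the end-to-end run; round-trips losslessly
#' through JSON via [write_config()]/[read_config()].
#'
#' @param seed Master seed for all randomness.
#' @param n_triggers,switch_types,on_target_effect,crosstalk_spec Panel
#'   construction, see [build_ground_truth_panel()].
#' @param n_events,replicates Screen size, see
#'   [simulate_orthogonality_screen()].
#' @param pop Named list of [cell_population_model()] overrides.
#' @param gate Named list of [gate_config()] overrides.
#' @param n_min,n_max Set-size range of the best-combination sweep.
#' @param threshold Orthogonality threshold.
#' @param profile_mode `"restricted"` or `"full"` profile restriction.
#' @param angle_cutoff Gate-panel pass angle in degrees.
#' @param gate_specs Optional gate specifications for
#'   [simulate_gate_panel()] (not serialized by [write_config()]).
#' @param out_dir Output directory, or NULL to skip writing.
#' @return A `run_config` list.
#' @export
run_config <- function(seed = 1L, n_triggers = 8,
                       switch_types = "OFF", on_target_effect = 0.1,
                       crosstalk_spec = NULL,
                       n_events = 5000, replicates = 3,
                       pop = list(), gate = list(),
                       n_min = 3, n_max = NULL, threshold = 0.7,
                       profile_mode = "restricted",
                       angle_cutoff = 20, gate_specs = NULL,
                       out_dir = NULL) {
  if (is.null(n_max)) n_max <- min(17, n_triggers)
  structure(list(seed = as.integer(seed), n_triggers = n_triggers,
                 switch_types = switch_types,
                 on_target_effect = on_target_effect,
                 crosstalk_spec = crosstalk_spec,
                 n_events = n_events, replicates = replicates,
                 pop = pop, gate = gate,
                 n_min = n_min, n_max = n_max, threshold = threshold,
                 profile_mode = profile_mode,
                 angle_cutoff = angle_cutoff, gate_specs = gate_specs,
                 out_dir = out_dir),
            class = "run_config")
}

#' Serialize / restore a pipeline configuration
#'
#' @param config A [run_config()].
#' @param path JSON path.
#' @export
write_config <- function(config, path) {
  conf <- unclass(config)
  conf$gate_specs <- NULL
  jsonlite::write_json(conf, path, auto_unbox = TRUE, digits = NA,
                       null = "null")
  invisible(path)
}

#' @rdname write_config
#' @export
read_config <- function(path) {
  conf <- jsonlite::read_json(path, simplifyVector = TRUE)
  if (is.list(conf$crosstalk_spec) && length(conf$crosstalk_spec) == 0) {
    conf$crosstalk_spec <- NULL
  }
  if (length(conf$out_dir) == 0) conf$out_dir <- NULL
  do.call(run_config, conf)
}

#' Run the full analysis pipeline
#'
#' simulate -> gate -> summarize -> orthogonality sweep (-> gate-panel
#' scoring), writing stage outputs and a provenance report when
#' `config$out_dir` is set. Rerunning with an identical config
#' reproduces identical numeric outputs.
#'
#' @param config A [run_config()].
#' @return Invisibly, a list with `panel`, `summary`, `fc_matrix`,
#'   `pairwise`, `sweep`, `gate_scores` (NULL without `gate_specs`) and
#'   `provenance`.
#' @export
run_pipeline <- function(config = run_config()) {
  panel <- build_ground_truth_panel(
    config$n_triggers, config$switch_types, config$on_target_effect,
    config$crosstalk_spec, seed = config$seed
  )
  pop <- do.call(cell_population_model, config$pop)
  cfg <- do.call(gate_config_for, c(list(pop = pop), config$gate))

  screen <- simulate_orthogonality_screen(panel, pop, config$n_events,
                                          config$replicates, config$seed)
  summary <- summarize_screen(screen, cfg)
  pairwise <- pairwise_cosine_distances(summary$fc_matrix)
  sweep <- sweep_best_combinations(
    summary$fc_matrix,
    n_range = seq(config$n_min, config$n_max),
    profile_mode = config$profile_mode,
    threshold = config$threshold
  )

  gate_scores <- NULL
  if (!is.null(config$gate_specs)) {
    gp <- simulate_gate_panel(config$gate_specs, pop, config$n_events,
                              config$seed)
    meas <- summarize_gate_panel(gp, cfg)
    gate_scores <- evaluate_gate_panel(meas, config$gate_specs[[1]]$truth_table,
                                       config$angle_cutoff)
  }

  provenance <- list(
    package = "orthocircuit",
    version = as.character(utils::packageVersion("orthocircuit")),
    r_version = paste(R.version$major, R.version$minor, sep = "."),
    seed = config$seed,
    parameters = list(
      n_triggers = config$n_triggers, n_events = config$n_events,
      replicates = config$replicates, n_min = config$n_min,
      n_max = config$n_max, threshold = config$threshold,
      profile_mode = config$profile_mode, angle_cutoff = config$angle_cutoff
    ),
    counts = list(
      samples = nrow(screen$sample_sheet),
      events_per_sample = config$n_events,
      events_surviving = sum(summary$gating$n_surviving),
      gates_scored = if (is.null(gate_scores)) 0L else nrow(gate_scores)
    )
  )

  if (!is.null(config$out_dir)) {
    dir.create(config$out_dir, recursive = TRUE, showWarnings = FALSE)
    p <- function(f) file.path(config$out_dir, f)
    utils::write.table(format_numeric_df(summary$ni), p("ni.tsv"),
                       sep = "\t", row.names = FALSE, quote = FALSE)
    utils::write.table(format_numeric_df(summary$comparisons),
                       p("comparisons.tsv"),
                       sep = "\t", row.names = FALSE, quote = FALSE)
    write_matrix(summary$fc_matrix, p("fc_matrix.tsv"))
    write_matrix(pairwise, p("pairwise_distances.tsv"))
    utils::write.table(format_numeric_df(sweep), p("best_combinations.tsv"),
                       sep = "\t", row.names = FALSE, quote = FALSE)
    if (!is.null(gate_scores)) {
      utils::write.table(format_numeric_df(as.data.frame(gate_scores)),
                         p("gate_scores.tsv"),
                         sep = "\t", row.names = FALSE, quote = FALSE)
    }
    write_config(config, p("config.json"))
    jsonlite::write_json(provenance, p("provenance.json"),
                         auto_unbox = TRUE, digits = NA)
  }

  invisible(list(panel = panel, summary = summary,
                 fc_matrix = summary$fc_matrix, pairwise = pairwise,
                 sweep = sweep, gate_scores = gate_scores,
                 provenance = provenance))
}
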