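#' Center a fold-change profile at the no-effect baseline
#'
#' Subtracts 1 (the fold change of a trigger with no effect) from every
#' component, so that profiles of non-interacting triggers become zero
#' vectors and the cosine geometry measures shared *deviations* from
#' baseline rather than shared baseline.
#'
#' @param fc_row Numeric vector of normalized fold changes.
#' @return The centered vector.
#' @export
centered_profile <- function(fc_row) {
  if (length(fc_row) == 0) {
    abort_oc("invalid_parameter_error", "empty fold-change profile")
  }
  as.numeric(fc_row) - 1
}

#' Cosine distance between two centered fold-change profiles
#'
#' `1 - cos` of the angle between the 1-centered profiles: 0 for
#' identical crosstalk patterns, near 1 for triggers acting on disjoint
#' switch sets (ideal orthogonality), up to 2 for opposed patterns.
#'
#' @param fc_i,fc_j Uncentered fold-change profiles of the two triggers
#'   over the same switches.
#' @param switches Optional index/logical vector restricting both
#'   profiles to a switch subset before centering.
#' @return Distance in [0, 2].
#' @export
pair_cosine_distance <- function(fc_i, fc_j, switches = NULL) {
  if (!is.null(switches)) {
    fc_i <- fc_i[switches]
    fc_j <- fc_j[switches]
  }
  if (length(fc_i) != length(fc_j)) {
    abort_oc("invalid_parameter_error", "profiles differ in length")
  }
  ci <- centered_profile(fc_i)
  cj <- centered_profile(fc_j)
  ni <- sqrt(sum(ci^2)); nj <- sqrt(sum(cj^2))
  if (ni == 0 || nj == 0) {
    abort_oc("degenerate_profile_error",
             "a profile has no effect on any switch in scope (zero centered norm)")
  }
  1 - sum(ci * cj) / (ni * nj)
}

check_fc_matrix <- function(fc) {
  if (!is.matrix(fc) || !is.numeric(fc)) {
    abort_oc("invalid_parameter_error", "fold-change matrix must be numeric")
  }
  if (any(!is.finite(fc)) || any(fc <= 0)) {
    abort_oc("invalid_parameter_error", "fold changes must be finite and > 0")
  }
  invisible(fc)
}

check_profile_mode <- function(fc, profile_mode) {
  profile_mode <- match.arg(profile_mode, c("restricted", "full"))
  if (profile_mode == "restricted" && nrow(fc) != ncol(fc)) {
    abort_oc("invalid_parameter_error",
             "restricted profile mode needs a square trigger-by-switch matrix")
  }
  profile_mode
}

#' Orthogonality of a trigger combination
#'
#' The combination's distance is the minimum pairwise cosine distance
#' over all unordered trigger pairs in `C` (ties broken by the
#' lexicographically smallest sorted pair). In `"restricted"` mode the
#' profiles are restricted to the switches matched to the triggers in
#' `C` (requires a square matrix with matched row/column order); in
#' `"full"` mode the full profiles are used.
#'
#' @param fc Numeric fold-change matrix, triggers in rows, switches in
#'   columns.
#' @param combo Integer indices (or row names) of the triggers in the
#'   combination, at least 2.
#' @param profile_mode `"restricted"` (default) or `"full"`.
#' @return A `combination_score`: list with `combination` (sorted
#'   indices), `distance`, `argmin_pair`, `N`, `profile_mode`.
#' @export
combination_distance <- function(fc, combo, profile_mode = "restricted") {
  check_fc_matrix(fc)
  profile_mode <- check_profile_mode(fc, profile_mode)
  if (is.character(combo)) combo <- match(combo, rownames(fc))
  combo <- sort(as.integer(combo))
  if (anyNA(combo) || length(combo) < 2 || any(combo < 1 | combo > nrow(fc))) {
    abort_oc("invalid_parameter_error", "combination must index >= 2 triggers")
  }
  switches <- if (profile_mode == "restricted") combo else seq_len(ncol(fc))
  best <- Inf
  best_pair <- NULL
  for (a in seq_len(length(combo) - 1L)) {
    for (b in (a + 1L):length(combo)) {
      d <- pair_cosine_distance(fc[combo[a], ], fc[combo[b], ], switches)
      if (d < best) {
        best <- d
        best_pair <- c(combo[a], combo[b])
      }
    }
  }
  combination_score(combo, best, best_pair, profile_mode)
}

combination_score <- function(combo, distance, argmin_pair, profile_mode) {
  structure(list(combination = combo, distance = distance,
                 argmin_pair = argmin_pair, N = length(combo),
                 profile_mode = profile_mode),
            class = "combination_score")
}

#' @export
print.combination_score <- function(x, ...) {
  cat(sprintf("combination_score: N=%d, min pair distance %.4f (%s mode)\n",
              x$N, x$distance, x$profile_mode))
  cat(sprintf("  combination: {%s}; argmin pair (%d, %d)\n",
              paste(x$combination, collapse = ", "),
              x$argmin_pair[1], x$argmin_pair[2]))
  invisible(x)
}

# Score one subset with incumbent pruning: returns NA_real_ as soon as
# the running pair minimum can no longer exceed `incumbent`.
combo_distance_pruned <- function(fc, combo, switches, incumbent) {
  best <- Inf
  best_pair <- NULL
  k <- length(combo)
  for (a in seq_len(k - 1L)) {
    for (b in (a + 1L):k) {
      d <- pair_cosine_distance(fc[combo[a], ], fc[combo[b], ], switches)
      if (d < best) {
        best <- d
        best_pair <- c(combo[a], combo[b])
        if (best <= incumbent) return(list(distance = NA_real_))
      }
    }
  }
  list(distance = best, argmin_pair = best_pair)
}

#' Best trigger combination by exhaustive enumeration
#'
#' Enumerates all subsets of size `N` in lexicographic order and returns
#' the maximizer of [combination_distance()]; on ties the
#' lexicographically smallest subset wins. Subsets are pruned as soon as
#' a running pair minimum falls to the incumbent optimum.
#'
#' @inheritParams combination_distance
#' @param N Subset size, `2 <= N <= nrow(fc)`.
#' @return A `combination_score` for the optimal subset.
#' @export
best_combination_bruteforce <- function(fc, N, profile_mode = "restricted") {
  check_fc_matrix(fc)
  profile_mode <- check_profile_mode(fc, profile_mode)
  n <- nrow(fc)
  if (N < 2 || N > n) {
    abort_oc("invalid_parameter_error",
             sprintf("N must be in [2, %d], got %s", n, format(N)))
  }
  N <- as.integer(N)
  best <- -Inf
  best_pair <- NULL
  best_combo <- NULL
  # in full mode pair distances are subset-independent: compute them once
  D <- if (profile_mode == "full") pairwise_distance_matrix_full(fc) else NULL
  combo <- seq_len(N)
  repeat {
    if (is.null(D)) {
      res <- combo_distance_pruned(fc, combo, combo, best)
      d <- res$distance
      pair <- res$argmin_pair
    } else {
      sub <- D[combo, combo]
      d <- min(sub[upper.tri(sub)])
      if (d <= best) d <- NA_real_ else {
        idx <- which(sub == d & upper.tri(sub), arr.ind = TRUE)
        idx <- idx[order(idx[, 1], idx[, 2]), , drop = FALSE]
        pair <- combo[idx[1, ]]
      }
    }
    if (!is.na(d) && d > best) {
      best <- d
      best_pair <- pair
      best_combo <- combo
    }
    # advance to the next combination in lexicographic order
    i <- N
    while (i >= 1L && combo[i] == n - N + i) i <- i - 1L
    if (i < 1L) break
    combo[i] <- combo[i] + 1L
    if (i < N) combo[(i + 1L):N] <- combo[i] + seq_len(N - i)
  }
  combination_score(best_combo, best, best_pair, profile_mode)
}

pairwise_distance_matrix_full <- function(fc) {
  n <- nrow(fc)
  D <- matrix(0, n, n, dimnames = list(rownames(fc), rownames(fc)))
  for (i in seq_len(n - 1L)) {
    for (j in (i + 1L):n) {
      D[i, j] <- D[j, i] <- pair_cosine_distance(fc[i, ], fc[j, ])
    }
  }
  D
}

#' Pairwise cosine-distance matrix over full profiles
#'
#' @param fc Fold-change matrix, triggers in rows.
#' @return Symmetric matrix of centered cosine distances, zero diagonal.
#' @export
pairwise_cosine_distances <- function(fc) {
  check_fc_matrix(fc)
  pairwise_distance_matrix_full(fc)
}

clique_num_at <- function(D, threshold, vertices = seq_len(nrow(D))) {
  if (length(vertices) == 0) return(0L)
  if (length(vertices) == 1) return(1L)
  A <- D[vertices, vertices, drop = FALSE] >= threshold
  diag(A) <- FALSE
  g <- igraph::graph_from_adjacency_matrix(A, mode = "undirected")
  igraph::clique_num(g)
}

# Lexicographically smallest N-clique of the threshold graph, by DFS that
# always extends with the smallest feasible vertex.
lex_smallest_clique <- function(D, threshold, N) {
  n <- nrow(D)
  A <- D >= threshold
  diag(A) <- FALSE
  recurse <- function(chosen, candidates) {
    if (length(chosen) == N) return(chosen)
    need <- N - length(chosen)
    for (v in candidates) {
      nxt <- candidates[candidates > v & A[v, candidates]]
      if (length(nxt) >= need - 1L &&
          (need == 1L || clique_num_at(D, threshold, nxt) >= need - 1L)) {
        res <- recurse(c(chosen, v), nxt)
        if (!is.null(res)) return(res)
      }
    }
    NULL
  }
  recurse(integer(0), seq_len(n))
}

#' Best trigger combination by max-min threshold search
#'
#' Optimized equivalent of [best_combination_bruteforce()] for
#' `"full"` profile mode, where pairwise distances do not depend on the
#' subset: binary search over the sorted unique pairwise distances, with
#' a maximum-clique feasibility test on the graph keeping edges at or
#' above the candidate threshold. Returns the same distance and, under
#' the lexicographic tie rule, the identical subset as the exhaustive
#' search. In `"restricted"` mode pair distances are subset-dependent
#' and the call falls back to the pruned exhaustive search.
#'
#' @inheritParams best_combination_bruteforce
#' @return A `combination_score`.
#' @export
best_combination_maxmin <- function(fc, N, profile_mode = "full") {
  check_fc_matrix(fc)
  profile_mode <- check_profile_mode(fc, profile_mode)
  n <- nrow(fc)
  if (N < 2 || N > n) {
    abort_oc("invalid_parameter_error",
             sprintf("N must be in [2, %d], got %s", n, format(N)))
  }
  if (profile_mode == "restricted") {
    return(best_combination_bruteforce(fc, N, "restricted"))
  }
  N <- as.integer(N)
  D <- pairwise_distance_matrix_full(fc)
  vals <- sort(unique(D[upper.tri(D)]))
  # largest threshold whose >=-threshold graph still has an N-clique
  lo <- 1L
  hi <- length(vals)
  while (lo < hi) {
    mid <- (lo + hi + 1L) %/% 2L
    if (clique_num_at(D, vals[mid]) >= N) lo <- mid else hi <- mid - 1L
  }
  if (clique_num_at(D, vals[lo]) < N) {
    abort_oc("invalid_parameter_error", "no feasible combination found")
  }
  combo <- lex_smallest_clique(D, vals[lo], N)
  combination_distance(fc, combo, "full")
}

#' Best combination for each set size
#'
#' Runs the best-subset search over a range of sizes. `"full"` mode uses
#' the optimized max-min search; `"restricted"` mode uses pruned
#' exhaustive enumeration.
#'
#' @inheritParams best_combination_bruteforce
#' @param n_range Integer vector of set sizes (default 3:17), inclusive.
#' @param threshold Orthogonality threshold used for the flag column.
#' @return Data frame with one row per N: `N`, `distance`, `orthogonal`
#'   (flag at `threshold`), `combination` (comma-separated indices),
#'   `argmin_pair`; the per-N `combination_score` objects are attached as
#'   the `"scores"` attribute.
#' @export
sweep_best_combinations <- function(fc, n_range = 3:17,
                                    profile_mode = "restricted",
                                    threshold = 0.7) {
  check_fc_matrix(fc)
  profile_mode <- check_profile_mode(fc, profile_mode)
  n_range <- sort(unique(as.integer(n_range)))
  if (any(n_range < 2) || any(n_range > nrow(fc))) {
    abort_oc("invalid_parameter_error", "set sizes must lie in [2, n_triggers]")
  }
  scores <- lapply(n_range, function(N) {
    if (profile_mode == "full") {
      best_combination_maxmin(fc, N, "full")
    } else {
      best_combination_bruteforce(fc, N, "restricted")
    }
  })
  out <- data.frame(
    N = n_range,
    distance = vapply(scores, `[[`, numeric(1), "distance"),
    orthogonal = vapply(scores, function(s)
      classify_orthogonal(s, threshold), logical(1)),
    combination = vapply(scores, function(s)
      paste(s$combination, collapse = ","), character(1)),
    argmin_pair = vapply(scores, function(s)
      paste(s$argmin_pair, collapse = ","), character(1))
  )
  attr(out, "scores") <- scores
  out
}

#' Flag a combination as orthogonal at a distance threshold
#'
#' @param score A `combination_score` or a bare distance.
#' @param threshold Distance threshold (default 0.7); combinations at or
#'   above it are orthogonal, strictly below it crosstalking.
#' @return Logical flag.
#' @export
classify_orthogonal <- function(score, threshold = 0.7) {
  d <- if (inherits(score, "combination_score")) score$distance else as.numeric(score)
  d >= threshold
}
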