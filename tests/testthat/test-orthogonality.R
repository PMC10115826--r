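test_that("profiles are centered at the no-effect baseline of 1", {
  expect_equal(centered_profile(c(1, 1, 1)), c(0, 0, 0))
  expect_equal(centered_profile(c(5, 1, 1)), c(4, 0, 0))
  set.seed(5)
  x <- runif(9, 0.1, 6)
  expect_equal(centered_profile(x), x - 1)
})

test_that("pair cosine distance matches hand geometry and is symmetric", {
  expect_equal(pair_cosine_distance(c(5, 1, 1), c(5, 1, 1)), 0)
  expect_equal(pair_cosine_distance(c(5, 1), c(1, 5)), 1)   # disjoint support
  expect_equal(pair_cosine_distance(c(3, 2), c(2, 3)), 0.2) # 1 - 4/5
  set.seed(6)
  for (i in 1:20) {
    a <- runif(5, 0.2, 5); b <- runif(5, 0.2, 5)
    d1 <- pair_cosine_distance(a, b)
    expect_equal(d1, pair_cosine_distance(b, a))
    expect_gte(d1, 0); expect_lte(d1, 2)
  }
  # opposed deviations reach the far end of [0, 2]
  expect_equal(pair_cosine_distance(c(2, 1), c(0.5, 1)), 2)
  expect_error(pair_cosine_distance(c(1, 1), c(2, 1)),
               class = "degenerate_profile_error")
})

test_that("combination distance is the minimum over pairs with lexicographic argmin", {
  fc <- rbind(c(5, 1, 1), c(1, 5, 1), c(1.5, 1.2, 1))
  rownames(fc) <- colnames(fc) <- NULL
  two <- combination_distance(fc, c(1, 2), profile_mode = "full")
  expect_equal(two$distance, pair_cosine_distance(fc[1, ], fc[2, ]))
  expect_equal(two$argmin_pair, c(1, 2))

  set.seed(7)
  m <- random_fc_matrix(6)
  combo <- combination_distance(m, 1:6, profile_mode = "full")
  pairs <- utils::combn(6, 2)
  oracle <- apply(pairs, 2, function(p)
    pair_cosine_distance(m[p[1], ], m[p[2], ]))
  expect_equal(combo$distance, min(oracle))
  expect_equal(combo$argmin_pair, pairs[, which.min(oracle)])

  expect_error(combination_distance(m, 3), class = "invalid_parameter_error")
})

test_that("restricted mode drops the switch columns outside the combination", {
  fc <- rbind(c(0.1, 0.5, 1), c(1, 0.1, 1), c(1, 0.6, 0.1))
  dimnames(fc) <- list(paste0("t", 1:3), paste0("s", 1:3))
  d_restricted <- combination_distance(fc, c(1, 3), "restricted")$distance
  expect_equal(d_restricted,
               pair_cosine_distance(fc[1, c(1, 3)], fc[3, c(1, 3)]))
  d_full <- combination_distance(fc, c(1, 3), "full")$distance
  expect_equal(d_full, pair_cosine_distance(fc[1, ], fc[3, ]))
  expect_false(isTRUE(all.equal(d_restricted, d_full)))
  expect_error(combination_distance(fc[, 1:2], c(1, 2), "restricted"),
               class = "invalid_parameter_error")
})

test_that("brute-force search returns the planted optimum", {
  # identity-structured matrix: every pair orthogonal, distance 1
  ident <- diag(3) * 4 + 1
  diag(ident) <- 0.1
  best <- best_combination_bruteforce(ident, 3, "full")
  expect_equal(best$distance, 1)
  expect_equal(best$combination, 1:3)

  # one crosstalky pair: the best triple avoids using both its members
  fc <- rbind(c(0.1, 0.5, 1, 1), c(1, 0.1, 1, 1),
              c(1, 1, 0.1, 1), c(1, 1, 1, 0.1))
  best3 <- best_combination_bruteforce(fc, 3, "full")
  expect_false(all(c(1, 2) %in% best3$combination))
  expect_equal(best3$combination, c(1, 3, 4))  # lexicographic winner

  # N = n admits a single candidate
  all4 <- best_combination_bruteforce(fc, 4, "full")
  expect_equal(all4$combination, 1:4)
  expect_error(best_combination_bruteforce(fc, 1, "full"),
               class = "invalid_parameter_error")
  expect_error(best_combination_bruteforce(fc, 9, "full"),
               class = "invalid_parameter_error")
})

test_that("max-min threshold search reproduces the exhaustive optimum", {
  set.seed(11)
  for (rep in 1:10) {
    n <- sample(4:8, 1)
    m <- random_fc_matrix(n)
    for (N in 2:n) {
      bf <- best_combination_bruteforce(m, N, "full")
      mm <- best_combination_maxmin(m, N, "full")
      expect_identical(mm$combination, bf$combination)
      expect_equal(mm$distance, bf$distance)
    }
  }
})

test_that("N = 2 max-min search finds the globally most distant pair", {
  set.seed(12)
  m <- random_fc_matrix(7)
  D <- pairwise_cosine_distances(m)
  best <- best_combination_maxmin(m, 2, "full")
  expect_equal(best$distance, max(D[upper.tri(D)]))
})

test_that("combination distance is monotone non-increasing under subset growth", {
  set.seed(13)
  m <- random_fc_matrix(8)
  for (rep in 1:10) {
    big <- sort(sample(8, sample(4:8, 1)))
    small <- sort(sample(big, 3))
    d_big <- combination_distance(m, big, "full")$distance
    d_small <- combination_distance(m, small, "full")$distance
    expect_lte(d_big, d_small)
  }
})

test_that("the sweep covers both endpoints and degrades monotonically", {
  ident <- matrix(1, 17, 17)
  diag(ident) <- 6
  sw <- sweep_best_combinations(ident, 3:17, profile_mode = "full")
  expect_equal(sw$N, 3:17)
  expect_true(all(sw$distance == 1))

  # a single crosstalky pair among 17 only forces a drop at N = 17
  ct <- ident
  ct[1, 2] <- 4
  sw_ct <- sweep_best_combinations(ct, 3:17, profile_mode = "full")
  expect_true(all(sw_ct$distance[sw_ct$N < 17] == 1))
  expect_lt(sw_ct$distance[sw_ct$N == 17], 1)

  set.seed(14)
  m <- random_fc_matrix(9)
  sw_r <- sweep_best_combinations(m, 2:9, profile_mode = "full")
  expect_true(all(diff(sw_r$distance) <= 1e-12))
})

test_that("restricted-mode sweep equals plain exhaustive enumeration", {
  set.seed(15)
  m <- random_fc_matrix(7)
  sw <- sweep_best_combinations(m, 2:7, profile_mode = "restricted")
  for (k in seq_along(sw$N)) {
    # independent oracle: enumerate subsets and score without pruning
    combos <- utils::combn(7, sw$N[k], simplify = FALSE)
    ds <- vapply(combos, function(cb)
      combination_distance(m, cb, "restricted")$distance, numeric(1))
    expect_equal(sw$distance[k], max(ds))
    expect_equal(attr(sw, "scores")[[k]]$combination,
                 combos[[which.max(ds)]])
  }
})

test_that("the 0.7 threshold flag is boundary inclusive", {
  expect_true(classify_orthogonal(0.7))
  expect_false(classify_orthogonal(0.69))
  expect_true(classify_orthogonal(1.0))
  sc <- combination_distance(rbind(c(5, 1), c(1, 5)), 1:2, "full")
  expect_true(classify_orthogonal(sc))
})

test_that("pairwise distance matrix is symmetric with zero diagonal", {
  set.seed(16)
  m <- random_fc_matrix(6)
  D <- pairwise_cosine_distances(m)
  expect_equal(D, t(D))
  expect_equal(unname(diag(D)), rep(0, 6))
  expect_equal(D[2, 5], pair_cosine_distance(m[2, ], m[5, ]))
})
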