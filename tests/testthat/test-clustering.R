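test_that("row standardization centers, scales and is idempotent", {
  expect_equal(unname(standardize_rows(rbind(c(1, 2, 3)))[1, ]),
               c(-1, 0, 1))
  set.seed(5)
  x <- matrix(rnorm(60, 10, 3), 10, 6,
              dimnames = list(sprintf("f%d", 1:10), NULL))
  s <- standardize_rows(x)
  expect_equal(unname(rowMeans(s)), rep(0, 10))
  expect_equal(unname(apply(s, 1, sd)), rep(1, 10))
  expect_equal(standardize_rows(s), s, tolerance = 1e-12)
  x["f3", ] <- 7
  expect_warning(s2 <- standardize_rows(x), "f3")
  expect_false("f3" %in% rownames(s2))
  expect_error(standardize_rows(matrix(1, 2, 1)), "length >= 2")
})

test_that("fuzzy c-means memberships are a valid, convergent partition", {
  sim <- simulate_profile_clusters(n_features = 60, n_clusters = 3,
                                   separation = 5, noise_sd = 1, seed = 2)
  x <- standardize_rows(sim$profiles)
  fc <- fuzzy_cmeans(x, n_clusters = 3, seed = 4)
  expect_equal(unname(rowSums(fc$membership)), rep(1, nrow(x)),
               tolerance = 1e-9)
  expect_true(all(fc$membership >= 0 & fc$membership <= 1))
  expect_true(fc$converged)
  expect_true(all(diff(fc$objective_trace) <= 1e-10))
  # determinism
  fc2 <- fuzzy_cmeans(x, n_clusters = 3, seed = 4)
  expect_identical(fc$membership, fc2$membership)
  expect_error(fuzzy_cmeans(x[1:2, ], 3), "fewer features")
  expect_error(fuzzy_cmeans(x, 3, fuzzifier = 1), "fuzzifier")
})

test_that("well-separated profiles are recovered near-perfectly", {
  sim <- simulate_profile_clusters(n_features = 120, n_conditions = 8,
                                   n_clusters = 4, separation = 5,
                                   noise_sd = 1, seed = 8)
  x <- standardize_rows(sim$profiles)
  fc <- fuzzy_cmeans(x, n_clusters = 4, seed = 1)
  hard <- apply(fc$membership, 1, which.max)
  expect_gte(adjusted_rand_index(hard, sim$labels), 0.95)
  expect_true(mean(apply(fc$membership, 1, max) > 0.5) > 0.9)
})

test_that("a huge fuzzifier drives memberships to the uniform limit", {
  sim <- simulate_profile_clusters(n_features = 40, n_clusters = 4, seed = 6)
  x <- standardize_rows(sim$profiles)
  fc <- fuzzy_cmeans(x, n_clusters = 5, fuzzifier = 100, seed = 3)
  expect_true(all(abs(fc$membership - 1 / 5) < 0.01))
})

test_that("row permutation permutes the clustering identically", {
  sim <- simulate_profile_clusters(n_features = 45, n_clusters = 3,
                                   separation = 5, noise_sd = 0.8, seed = 12)
  x <- standardize_rows(sim$profiles)
  perm <- sample(nrow(x))
  fc1 <- fuzzy_cmeans(x, n_clusters = 3, seed = 1)
  fc2 <- fuzzy_cmeans(x[perm, ], n_clusters = 3, seed = 1)
  expect_equal(fc2$membership, fc1$membership[perm, ], tolerance = 1e-8)
  expect_equal(fc2$centers, fc1$centers, tolerance = 1e-8)
})

test_that("memberships agree with an independent FCM implementation", {
  skip_if_not_installed("e1071")
  sim <- simulate_profile_clusters(n_features = 90, n_clusters = 3,
                                   separation = 6, noise_sd = 0.8, seed = 19)
  x <- standardize_rows(sim$profiles)
  ours <- fuzzy_cmeans(x, n_clusters = 3, fuzzifier = 1.765, seed = 1)
  ref <- e1071::cmeans(x, centers = ours$centers, m = 1.765,
                       iter.max = 500)
  ref_hard <- apply(ref$membership, 1, which.max)
  our_hard <- apply(ours$membership, 1, which.max)
  expect_gte(adjusted_rand_index(our_hard, ref_hard), 0.99)
})

test_that("membership thresholding uses a strict cut and stable ties", {
  cl <- list(membership = rbind(a = c(0.7, 0.2, 0.1),
                                b = rep(0.1, 3) + c(0, 0, 0),
                                c = c(0.45, 0.45, 0.10)))
  out <- membership_assign(cl, threshold = 0.2)
  expect_equal(out$cluster[out$feature_id == "a"], 1)
  expect_equal(out$membership[out$feature_id == "a"], 0.7)
  # uniform memberships below the strict cut stay unassigned
  u10 <- list(membership = matrix(0.1, 1, 10))
  expect_true(is.na(membership_assign(u10, 0.2)$cluster))
  expect_true(is.na(membership_assign(u10, 0.1)$cluster))  # strict: 0.1 !> 0.1
  # tie goes to the lowest cluster index
  expect_message(out2 <- membership_assign(cl, 0.2), "tie")
  expect_equal(out2$cluster[out2$feature_id == "c"], 1)
  # threshold 0 assigns everything
  expect_false(anyNA(membership_assign(cl, 0)$cluster))
  expect_error(membership_assign(cl, 1), "threshold")
})

test_that("adjusted Rand index matches its reference implementation", {
  skip_if_not_installed("mclust")
  set.seed(44)
  for (i in 1:10) {
    a <- sample(1:4, 30, replace = TRUE)
    b <- sample(1:3, 30, replace = TRUE)
    expect_equal(adjusted_rand_index(a, b),
                 mclust::adjustedRandIndex(a, b))
  }
  expect_equal(adjusted_rand_index(1:10, 1:10), 1)
})
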