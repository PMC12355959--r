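make_im <- function(values, groups, scale = "raw") {
  ids <- sprintf("S%d", seq_len(ncol(values)))
  colnames(values) <- ids
  if (is.null(rownames(values))) {
    rownames(values) <- sprintf("F%d", seq_len(nrow(values)))
  }
  intensity_matrix(values, data.frame(sample = ids, group = groups),
                   scale = scale)
}

test_that("reliability filter implements the per-group detection rule", {
  g <- rep(c("a", "b"), each = 4)
  v <- matrix(1, 3, 8)
  v[1, c(4, 5:8)] <- NA      # 3/4 in group a, 0/4 in group b -> retained
  v[2, c(3, 4, 7, 8)] <- NA  # 2/4 in both groups -> dropped
  im <- make_im(v, g)
  out <- suppressMessages(reliability_filter(im, 3 / 4))
  expect_setequal(rownames(out$values), c("F1", "F3"))
  # fully observed matrix is untouched at any threshold
  full <- make_im(matrix(1:16, 2, 8), g)
  expect_equal(suppressMessages(reliability_filter(full, 1))$values,
               full$values)
  expect_error(reliability_filter(im, 0), "min_fraction")
  expect_error(reliability_filter(im, 1.2), "min_fraction")
})

test_that("reliability filter equals brute-force counting on random matrices", {
  set.seed(101)
  for (i in 1:20) {
    g <- sample(c("a", "b", "c"), 9, replace = TRUE)
    while (length(unique(g)) < 2) g <- sample(c("a", "b", "c"), 9,
                                              replace = TRUE)
    v <- matrix(rexp(9 * 12), 12, 9)
    v[runif(length(v)) < 0.4] <- NA
    frac <- sample(c(1 / 2, 2 / 3, 3 / 4, 1), 1)
    im <- make_im(v, g)
    keep <- reliability_filter_bruteforce(im$values, g, frac)
    out <- suppressMessages(reliability_filter(im, frac))
    expect_identical(rownames(out$values), rownames(im$values)[keep])
  }
})

test_that("stabilization is scale-invariant, idempotent and equalizes MADs", {
  set.seed(7)
  base <- matrix(2^rnorm(200, 20, 2), 50, 4)
  # columns 2..4 are scalar multiples of column 1
  v <- base
  v[, 2] <- v[, 1] * 3.7; v[, 3] <- v[, 1] * 0.2; v[, 4] <- v[, 1] * 11
  out <- log_transform_stabilize(make_im(v, rep("g", 4), "raw"))
  expect_equal(out$scale, "log2")
  for (j in 2:4) expect_equal(out$values[, j], out$values[, 1],
                              ignore_attr = TRUE)
  # heteroscedastic columns end with equal MADs
  het <- matrix(2^(rnorm(400, 20, rep(c(1, 4, 2, 0.5), each = 100))), 100, 4)
  sout <- log_transform_stabilize(make_im(het, rep("g", 4), "raw"))
  mads <- apply(sout$values, 2, mad)
  expect_lt(max(mads) - min(mads), 1e-9)
  # idempotence: re-stabilizing the (exponentiated) output changes nothing
  again <- log_transform_stabilize(make_im(2^sout$values, rep("g", 4), "raw"))
  expect_equal(again$values, sout$values)
  # non-positive values name their coordinates
  bad <- make_im(matrix(c(0, 1, 2, 3), 2, 2), c("g", "g"), "raw")
  expect_error(log_transform_stabilize(bad), "non-positive")
})

test_that("site-to-protein normalization is per-sample log subtraction", {
  g <- c("a", "a")
  prot <- make_im(matrix(c(8, 8), 1, 2), g, "log2")
  rownames(prot$values) <- "PROT1"
  sites <- make_im(matrix(c(10, 11, 8, 8), 2, 2, byrow = TRUE), g, "log2")
  rownames(sites$values) <- c("site1", "site2")
  map <- data.frame(site_id = c("site1", "site2", "ghost"),
                    protein_id = c("PROT1", "PROT1", "NOPE"))
  out <- normalize_sites_to_protein(sites, prot, map)
  expect_equal(unname(out$values["site1", ]), c(2, 3))
  expect_equal(unname(out$values["site2", ]), c(0, 0))  # identity case
  # missing protein value makes the site missing in that sample
  prot$values[1, 2] <- NA
  out2 <- normalize_sites_to_protein(sites, prot, map)
  expect_true(is.na(out2$values["site1", 2]))
  # unmapped sites are dropped with a warning
  sites3 <- make_im(matrix(1, 1, 2), g, "log2")
  rownames(sites3$values) <- "orphan"
  expect_warning(normalize_sites_to_protein(sites3, prot, map), "map entry")
  expect_error(normalize_sites_to_protein(sites, make_im(
    matrix(1, 1, 2), g, "raw"), map), "log2")
})

test_that("differential test matches the textbook two-sample t oracle", {
  a <- c(0.9, 1.1, 1.0, 1.0); b <- c(1.9, 2.1, 2.0, 2.0)
  im <- make_im(rbind(c(a, b)), rep(c("A", "B"), each = 4), "log2")
  res <- differential_test(im, "A", "B")
  expect_equal(res$log2fc, -1)
  oracle <- student_t_oracle(a, b)
  expect_equal(res$p_value, oracle$p)
  expect_equal(res$t_stat, oracle$t)
  expect_lt(res$p_value, 0.001)

  # identical groups: zero fold change, nothing significant
  v <- matrix(rnorm(40), 5, 8)
  v[, 5:8] <- v[, 1:4]
  res0 <- differential_test(make_im(v, rep(c("A", "B"), each = 4), "log2"),
                            "A", "B")
  expect_equal(res0$log2fc, rep(0, 5))
  expect_false(any(res0$significant))
  expect_error(differential_test(im, "A", "nope"), "unknown group")
})

test_that("group swap negates fold changes and preserves p-values", {
  set.seed(31)
  v <- matrix(rnorm(80, 20), 10, 8)
  v[runif(80) < 0.15] <- NA
  im <- make_im(v, rep(c("A", "B"), each = 4), "log2")
  ok <- rowSums(!is.na(v[, 1:4])) >= 2 & rowSums(!is.na(v[, 5:8])) >= 2
  fwd <- differential_test(im, "A", "B")
  rev <- differential_test(im, "B", "A")
  expect_equal(fwd$log2fc, -rev$log2fc)
  expect_equal(fwd$p_value, rev$p_value)
  expect_equal(nrow(fwd), sum(ok))
})

test_that("BH adjustment follows the step-up oracle", {
  expect_equal(bh_adjust(c(0.01, 0.02, 0.03, 0.04)), rep(0.04, 4))
  expect_equal(bh_adjust(c(0.005, 0.04, 0.9)), c(0.015, 0.06, 0.9))
  expect_equal(bh_adjust(0.3), 0.3)
  expect_equal(bh_adjust(rep(0.2, 5)), rep(0.2, 5))
  expect_error(bh_adjust(c(0.5, 1.2)), "\\[0, 1\\]")
  set.seed(17)
  for (i in 1:50) {
    p <- runif(sample(1:40, 1))
    q <- bh_adjust(p)
    expect_equal(q, bh_stepup_bruteforce(p))
    expect_true(all(q >= p))
    expect_true(all(diff(q[order(p)]) >= -1e-15))
  }
})

test_that("planted effects are recovered with controlled FDR", {
  sim <- simulate_ptm_dataset(
    ptm_sim_config(n_proteins = 1500, sites_per_protein = 1,
                   effect_log2fc = 1, frac_differential = 0.1,
                   noise_sd = 0.3, dropout_rate = 0.05, seed = 23))
  res <- differential_test(sim$proteins, "treated", "control")
  truth <- sim$truth[sim$truth$level == "protein", ]
  truth <- truth[match(res$feature_id, truth$feature_id), ]
  hit <- truth$is_perturbed
  expect_lt(abs(mean(res$log2fc[hit]) - 1), 0.15)
  called <- res$significant
  expect_lte(sum(called & !hit) / max(1, sum(called)), 0.1)
  expect_gt(mean(called[hit]), 0.2)
})
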