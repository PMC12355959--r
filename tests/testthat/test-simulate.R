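test_that("melting simulator is deterministic and reference-constrained", {
  cfg <- tpp_sim_config(n_proteins = 10, seed = 42)
  s1 <- simulate_melting_dataset(cfg)
  s2 <- simulate_melting_dataset(cfg)
  expect_identical(s1, s2)
  ref <- s1$tpp$temperature == tpp_gradient()[1]
  expect_true(all(s1$tpp$rel_abundance[ref] == 1))
  expect_true(all(s1$tpp$rel_abundance >= 0))
})

test_that("truth table satisfies the melt model and the planted counts", {
  cfg <- tpp_sim_config(n_proteins = 500, frac_interactors = 0.1, seed = 7)
  truth <- simulate_melting_dataset(cfg)$truth
  expect_equal(nrow(truth), 500)
  expect_false(anyDuplicated(truth$protein_id) > 0)
  expect_equal(sum(truth$is_perturbed), 50)
  # f(true_tm) = 0.5 to 1e-9 for every protein, both arms
  f_v <- melt_model(truth$true_tm, truth$a, truth$b, truth$plateau)
  f_t <- melt_model(truth$true_tm_treated, truth$a, truth$b_treated,
                    truth$plateau)
  expect_true(all(abs(f_v - 0.5) < 1e-9))
  expect_true(all(abs(f_t - 0.5) < 1e-9))
  # planted shift is exactly delta_tm_true for interactors, 0 otherwise
  d <- truth$true_tm_treated - truth$true_tm
  expect_equal(d[truth$is_perturbed], rep(-3, 50), tolerance = 1e-9)
  expect_equal(d[!truth$is_perturbed], rep(0, 450))
})

test_that("no noise and no interactors make the arms identical", {
  sim <- simulate_melting_dataset(
    tpp_sim_config(n_proteins = 8, frac_interactors = 0, noise_sd = 0,
                   seed = 5))
  veh <- sim$tpp[sim$tpp$condition == "vehicle", ]
  trt <- sim$tpp[sim$tpp$condition == "treated", ]
  key <- function(d) order(d$protein_id, d$replicate, d$temperature)
  expect_equal(veh$rel_abundance[key(veh)], trt$rel_abundance[key(trt)])
})

test_that("single-protein series reproduces the closed form at Tm", {
  cfg <- tpp_sim_config(n_proteins = 1, frac_interactors = 0, noise_sd = 0,
                        n_replicates = 2, a_range = c(2000, 2000),
                        b_range = c(40, 40), plateau_range = c(0, 0),
                        gradient = c(37.1, 44.1, 50, 56.2, 67.2), seed = 1)
  sim <- simulate_melting_dataset(cfg)
  at50 <- sim$tpp$rel_abundance[sim$tpp$temperature == 50]
  expect_equal(unique(at50), 0.5)   # Tm = a/b = 50 when plateau = 0
})

test_that("simulator config validation names the offending field", {
  expect_error(tpp_sim_config(n_replicates = 1), "n_replicates")
  expect_error(tpp_sim_config(noise_sd = -1), "noise_sd")
  expect_error(tpp_sim_config(frac_interactors = 1.2), "frac_interactors")
  expect_error(tpp_sim_config(gradient = numeric(0)), "gradient")
  expect_error(tpp_sim_config(plateau_range = c(0, 0.6)), "plateau_range")
})

test_that("PTM simulator is deterministic with group-structured truth", {
  cfg <- ptm_sim_config(n_proteins = 40, seed = 9)
  s1 <- simulate_ptm_dataset(cfg)
  s2 <- simulate_ptm_dataset(cfg)
  expect_identical(s1, s2)
  expect_equal(nrow(s1$truth), 40 + nrow(s1$site_map))
  expect_silent(validate_site_map(s1$site_map))
  # noiseless, no dropout, nothing planted: group means identical
  s0 <- simulate_ptm_dataset(
    ptm_sim_config(n_proteins = 15, frac_differential = 0, noise_sd = 0,
                   dropout_rate = 0, seed = 2))
  g <- s0$proteins$samples$group
  m1 <- rowMeans(s0$proteins$values[, g == "control"])
  m2 <- rowMeans(s0$proteins$values[, g == "treated"])
  expect_equal(m1, m2)
})

test_that("site-level effects are isolated by protein normalization", {
  # site effect +1 log2, zero protein effect, no noise or dropout
  cfg <- ptm_sim_config(n_proteins = 50, frac_differential = 0.2,
                        effect_log2fc = 1, noise_sd = 0, dropout_rate = 0,
                        seed = 13)
  sim <- simulate_ptm_dataset(cfg)
  # strip the protein-level plant to isolate the site effect
  prot_hit <- sim$truth$feature_id[sim$truth$level == "protein" &
                                     sim$truth$is_perturbed]
  keep <- !(rownames(sim$proteins$values) %in% prot_hit) &
    !(sim$site_map$protein_id[match(rownames(sim$sites$values),
                                    sim$site_map$site_id)] %in% prot_hit)
  sites <- intensity_matrix(sim$sites$values[keep, , drop = FALSE],
                            sim$sites$samples, scale = "log2")
  norm <- normalize_sites_to_protein(sites, sim$proteins, sim$site_map)
  diff <- differential_test(norm, "treated", "control")
  truth <- sim$truth[match(diff$feature_id, sim$truth$feature_id), ]
  expect_equal(diff$log2fc, truth$true_log2fc, tolerance = 1e-9)
})

test_that("profile simulator honors the template and label contracts", {
  sim <- simulate_profile_clusters(n_features = 100, n_clusters = 4,
                                   noise_sd = 0, seed = 3)
  expect_equal(length(unique(sim$labels)), 4)
  # noiseless rows equal their templates: identical rows within a cluster
  for (k in 1:4) {
    rows <- sim$profiles[sim$labels == k, , drop = FALSE]
    expect_equal(max(abs(sweep(rows, 2, rows[1, ]))), 0)
  }
  expect_error(simulate_profile_clusters(n_features = 3, n_clusters = 4),
               "n_features")
  expect_error(simulate_profile_clusters(n_conditions = 1), "n_conditions")
})
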