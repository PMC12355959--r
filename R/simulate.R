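# Run code under a local RNG state so simulators are seeded without
# clobbering the caller's stream.
with_local_seed <- function(seed, code) {
  if (!is.null(seed)) {
    old <- if (exists(".Random.seed", envir = globalenv()))
      get(".Random.seed", envir = globalenv()) else NULL
    on.exit({
      if (is.null(old)) {
        if (exists(".Random.seed", envir = globalenv()))
          rm(".Random.seed", envir = globalenv())
      } else assign(".Random.seed", old, envir = globalenv())
    })
    set.seed(seed)
  }
  code
}

#' Configuration for a simulated TPP melting experiment
#'
#' Defines the study conditions of a simulated two-arm (vehicle/treated)
#' TMT melting experiment on the ten-temperature gradient: per-protein
#' sigmoid parameters drawn uniformly from the given ranges, a planted
#' subpopulation of "interactors" whose treated-arm melting point is
#' shifted by `delta_tm_true`, additive Gaussian measurement noise on the
#' relative abundances, and four replicates per arm.
#'
#' Defaults give true melting points inside the gradient (roughly
#' 42-59 degrees C) and a noise level of 0.02 relative-abundance units, a
#' typical reporter-ion scatter for reference-normalized TMT series.
#'
#' @param n_proteins number of simulated proteins.
#' @param frac_interactors fraction of proteins with a true Tm shift,
#'   in `[0, 1]`.
#' @param delta_tm_true signed true shift (degrees C) applied to
#'   interactors in the treated arm.
#' @param gradient temperature gradient; defaults to [tpp_gradient()].
#' @param n_replicates replicates per arm, >= 2.
#' @param noise_sd Gaussian noise SD in relative-abundance units, >= 0.
#' @param a_range,b_range,plateau_range uniform sampling intervals for the
#'   sigmoid parameters; the plateau upper bound must stay below 0.5 so
#'   every simulated protein has a defined Tm.
#' @param seed integer RNG seed.
#' @return Validated config list of class `tpp_sim_config`.
#' @export
tpp_sim_config <- function(n_proteins = 500, frac_interactors = 0.1,
                           delta_tm_true = -3, gradient = tpp_gradient(),
                           n_replicates = 4, noise_sd = 0.02,
                           a_range = c(1800, 2200), b_range = c(38, 44),
                           plateau_range = c(0, 0.2), seed = 1L) {
  cfg <- list(n_proteins = n_proteins, frac_interactors = frac_interactors,
              delta_tm_true = delta_tm_true, gradient = gradient,
              n_replicates = n_replicates, noise_sd = noise_sd,
              a_range = a_range, b_range = b_range,
              plateau_range = plateau_range, seed = as.integer(seed))
  if (n_proteins < 1) stop("n_proteins: must be >= 1", call. = FALSE)
  if (frac_interactors < 0 || frac_interactors > 1) {
    stop("frac_interactors: must lie in [0, 1]", call. = FALSE)
  }
  if (n_replicates < 2) stop("n_replicates: must be >= 2", call. = FALSE)
  if (noise_sd < 0) stop("noise_sd: must be >= 0", call. = FALSE)
  validate_gradient(gradient)
  if (plateau_range[2] >= 0.5 || plateau_range[1] < 0) {
    stop("plateau_range: must be a sub-interval of [0, 0.5) so Tm is defined",
         call. = FALSE)
  }
  if (a_range[1] <= 0 || b_range[1] <= 0) {
    stop("a_range/b_range: lower bounds must be positive", call. = FALSE)
  }
  class(cfg) <- "tpp_sim_config"
  cfg
}

#' Simulate a two-arm TPP melting experiment with known ground truth
#'
#' Draws per-protein sigmoid parameters, plants a true melting-point shift
#' of `delta_tm_true` in a random subset of `frac_interactors * n_proteins`
#' proteins (rounded), and emits noisy melting series for both arms. The
#' shift is realized by adjusting `b` in closed form while holding `a` and
#' `plateau` fixed, so the planted quantity is exactly the Tm difference.
#' Gaussian noise (sd `noise_sd`) is added at every temperature except the
#' reference, which is definitionally 1 after normalization; values are
#' clipped at 0. Each replicate's vehicle/treated pair shares the protein's
#' baseline parameters (split-lysate design), so both paired and unpaired
#' shift tests apply downstream. Identical seeds give identical output.
#'
#' @param config a [tpp_sim_config()].
#' @return List with `tpp`, the long-format table (`protein_id`,
#'   `condition`, `replicate`, `temperature`, `rel_abundance`), and
#'   `truth`, one row per protein (`protein_id`, `a`, `b`, `plateau`,
#'   `b_treated`, `is_perturbed`, `true_tm`, `true_tm_treated`).
#' @examples
#' sim <- simulate_melting_dataset(tpp_sim_config(n_proteins = 5, seed = 7))
#' head(sim$tpp); sim$truth
#' @export
simulate_melting_dataset <- function(config = tpp_sim_config()) {
  stopifnot(inherits(config, "tpp_sim_config"))
  with_local_seed(config$seed, {
    n <- config$n_proteins
    grad <- config$gradient
    a <- stats::runif(n, config$a_range[1], config$a_range[2])
    b <- stats::runif(n, config$b_range[1], config$b_range[2])
    plat <- stats::runif(n, config$plateau_range[1], config$plateau_range[2])
    n_hit <- round(config$frac_interactors * n)
    perturbed <- rep(FALSE, n)
    if (n_hit > 0) perturbed[sample.int(n, n_hit)] <- TRUE

    tm0 <- melting_point(a, b, plat)
    tm1 <- ifelse(perturbed, tm0 + config$delta_tm_true, tm0)
    # b' solves Tm + dTm under the closed form, holding a and plateau fixed
    b_treated <- a / tm1 + log(0.5 / (0.5 - plat))

    ids <- sprintf("P%04d", seq_len(n))
    truth <- data.frame(
      protein_id = ids, a = a, b = b, plateau = plat,
      b_treated = b_treated, is_perturbed = perturbed,
      true_tm = tm0, true_tm_treated = tm1, stringsAsFactors = FALSE)

    nt <- length(grad)
    reps <- config$n_replicates
    make_arm <- function(bvec, condition) {
      clean <- outer(seq_len(n), seq_len(nt),
                     function(i, j) melt_model(grad[j], a[i], bvec[i], plat[i]))
      do.call(rbind, lapply(seq_len(reps), function(r) {
        noisy <- clean
        if (config$noise_sd > 0) {
          noisy[, -1L] <- noisy[, -1L] +
            stats::rnorm(n * (nt - 1L), sd = config$noise_sd)
        }
        noisy <- pmax(noisy, 0)
        noisy[, 1L] <- 1
        data.frame(protein_id = rep(ids, times = nt),
                   condition = condition,
                   replicate = r,
                   temperature = rep(grad, each = n),
                   rel_abundance = as.vector(noisy),
                   stringsAsFactors = FALSE)
      }))
    }
    tpp <- rbind(make_arm(b, "vehicle"), make_arm(b_treated, "treated"))
    ord <- order(tpp$protein_id, tpp$condition, tpp$replicate,
                 tpp$temperature)
    tpp <- tpp[ord, , drop = FALSE]
    rownames(tpp) <- NULL
    list(tpp = tpp, truth = truth)
  })
}

#' Configuration for a simulated PTM/proteome intensity dataset
#'
#' Study conditions for a two-level simulation: a protein log2-intensity
#' matrix with group structure, and a site matrix whose values are the
#' parent protein's signal plus a site offset plus (for planted sites) a
#' site-level effect, so site-to-protein normalization isolates the site
#' effect exactly. Missingness is missing-at-random dropout.
#'
#' @param n_proteins number of proteins.
#' @param sites_per_protein PTM sites per protein (a single count, or a
#'   vector of length `n_proteins`).
#' @param groups named integer vector of replicates per group
#'   (>= 2 each); the planted effects apply to the last group versus the
#'   first.
#' @param effect_log2fc signed planted effect (log2 units).
#' @param frac_differential fraction of proteins (and, independently, of
#'   sites) carrying a planted effect.
#' @param dropout_rate independent missingness probability, in `[0, 1)`.
#' @param noise_sd measurement noise SD, log2 units.
#' @param seed integer RNG seed.
#' @return Validated config list of class `ptm_sim_config`.
#' @export
ptm_sim_config <- function(n_proteins = 500, sites_per_protein = 2,
                           groups = c(control = 4, treated = 4),
                           effect_log2fc = 1, frac_differential = 0.1,
                           dropout_rate = 0.1, noise_sd = 0.3, seed = 1L) {
  cfg <- list(n_proteins = n_proteins, sites_per_protein = sites_per_protein,
              groups = groups, effect_log2fc = effect_log2fc,
              frac_differential = frac_differential,
              dropout_rate = dropout_rate, noise_sd = noise_sd,
              seed = as.integer(seed))
  if (is.null(names(groups)) || any(names(groups) == "")) {
    stop("groups: must be a named vector of replicate counts", call. = FALSE)
  }
  if (length(groups) < 2) stop("groups: need >= 2 groups", call. = FALSE)
  if (any(groups < 2)) stop("groups: every group needs >= 2 replicates",
                            call. = FALSE)
  if (dropout_rate < 0 || dropout_rate >= 1) {
    stop("dropout_rate: must lie in [0, 1)", call. = FALSE)
  }
  if (frac_differential < 0 || frac_differential > 1) {
    stop("frac_differential: must lie in [0, 1]", call. = FALSE)
  }
  if (noise_sd < 0) stop("noise_sd: must be >= 0", call. = FALSE)
  class(cfg) <- "ptm_sim_config"
  cfg
}

#' Simulate protein and PTM-site intensity matrices with known truth
#'
#' Protein log2 intensities are a per-protein baseline plus a group effect
#' for planted proteins plus Gaussian noise. Site intensities are the
#' parent protein's true signal plus a site-specific offset plus a planted
#' site-level effect (for a random `frac_differential` of sites) plus
#' independent noise. Entries of both matrices are removed independently
#' with probability `dropout_rate`. Matrices are returned on the log2
#' scale.
#'
#' @param config a [ptm_sim_config()].
#' @return List with `proteins` and `sites` ([intensity_matrix()] objects,
#'   scale `"log2"`), `site_map` (columns `site_id`, `protein_id`,
#'   `residue`, `position`, `modification`), and `truth` (one row per
#'   feature: `feature_id`, `level` in {protein, site}, `is_perturbed`,
#'   `true_log2fc` — for sites, the site-level effect net of the protein).
#' @export
simulate_ptm_dataset <- function(config = ptm_sim_config()) {
  stopifnot(inherits(config, "ptm_sim_config"))
  with_local_seed(config$seed, {
    n <- config$n_proteins
    groups <- config$groups
    group_of <- rep(names(groups), times = groups)
    n_samp <- length(group_of)
    sample_ids <- sprintf("%s_R%d", group_of,
                          unlist(lapply(groups, seq_len), use.names = FALSE))
    samples <- data.frame(sample = sample_ids, group = group_of,
                          replicate = unlist(lapply(groups, seq_len),
                                             use.names = FALSE),
                          stringsAsFactors = FALSE)
    target <- names(groups)[length(groups)]   # effect group

    prot_ids <- sprintf("PROT%04d", seq_len(n))
    baseline <- stats::rnorm(n, mean = 25, sd = 2)
    prot_hit <- rep(FALSE, n)
    n_hit <- round(config$frac_differential * n)
    if (n_hit > 0) prot_hit[sample.int(n, n_hit)] <- TRUE
    prot_effect <- ifelse(prot_hit, config$effect_log2fc, 0)

    # true (noise-free) protein signal per sample
    eff_mat <- outer(prot_effect, as.numeric(group_of == target))
    prot_true <- baseline + eff_mat
    prot_obs <- prot_true +
      matrix(stats::rnorm(n * n_samp, sd = config$noise_sd), n, n_samp)

    spp <- rep_len(config$sites_per_protein, n)
    n_sites <- sum(spp)
    site_parent <- rep(seq_len(n), times = spp)
    site_idx <- unlist(lapply(spp, seq_len), use.names = FALSE)
    modif <- sample(c("acetyl", "phospho"), n_sites, replace = TRUE)
    residue <- ifelse(modif == "acetyl", "K",
                      sample(c("S", "T", "Y"), n_sites, replace = TRUE))
    position <- sample.int(800, n_sites, replace = TRUE)
    site_ids <- sprintf("%s_%s%d", prot_ids[site_parent], residue, position)
    site_ids <- make.unique(site_ids, sep = "_")
    site_map <- data.frame(site_id = site_ids,
                           protein_id = prot_ids[site_parent],
                           residue = residue, position = position,
                           modification = modif, stringsAsFactors = FALSE)

    site_hit <- rep(FALSE, n_sites)
    n_site_hit <- round(config$frac_differential * n_sites)
    if (n_site_hit > 0) site_hit[sample.int(n_sites, n_site_hit)] <- TRUE
    site_effect <- ifelse(site_hit, config$effect_log2fc, 0)
    site_offset <- stats::rnorm(n_sites, mean = -2, sd = 1)

    site_true <- prot_true[site_parent, , drop = FALSE] + site_offset +
      outer(site_effect, as.numeric(group_of == target))
    site_obs <- site_true +
      matrix(stats::rnorm(n_sites * n_samp, sd = config$noise_sd),
             n_sites, n_samp)

    if (config$dropout_rate > 0) {
      prot_obs[stats::runif(length(prot_obs)) < config$dropout_rate] <- NA
      site_obs[stats::runif(length(site_obs)) < config$dropout_rate] <- NA
    }
    dimnames(prot_obs) <- list(prot_ids, sample_ids)
    dimnames(site_obs) <- list(site_ids, sample_ids)

    truth <- rbind(
      data.frame(feature_id = prot_ids, level = "protein",
                 is_perturbed = prot_hit, true_log2fc = prot_effect,
                 stringsAsFactors = FALSE),
      data.frame(feature_id = site_ids, level = "site",
                 is_perturbed = site_hit, true_log2fc = site_effect,
                 stringsAsFactors = FALSE))

    list(proteins = intensity_matrix(prot_obs, samples, scale = "log2"),
         sites = intensity_matrix(site_obs, samples, scale = "log2"),
         site_map = site_map, truth = truth)
  })
}

#' Simulate condition profiles around cluster templates
#'
#' Test bed for soft clustering: `n_clusters` phase-shifted cosine
#' templates over `n_conditions` points, scaled by `separation`, with rows
#' assigned cyclically to clusters and Gaussian noise added. With
#' `noise_sd = 0` every row equals its template exactly.
#'
#' @param n_features rows to simulate (>= `n_clusters`).
#' @param n_conditions profile length (>= 2).
#' @param n_clusters number of templates (>= 2).
#' @param separation template amplitude in noise-SD units.
#' @param noise_sd Gaussian noise SD.
#' @param seed integer RNG seed.
#' @return List with `profiles` (matrix, rownames `F1..`) and `labels`
#'   (integer ground-truth cluster per row).
#' @export
simulate_profile_clusters <- function(n_features = 100, n_conditions = 8,
                                      n_clusters = 4, separation = 5,
                                      noise_sd = 1, seed = 1L) {
  if (n_clusters < 2) stop("n_clusters: must be >= 2", call. = FALSE)
  if (n_features < n_clusters) {
    stop("n_features: must be >= n_clusters", call. = FALSE)
  }
  if (n_conditions < 2) stop("n_conditions: must be >= 2", call. = FALSE)
  with_local_seed(seed, {
    tgrid <- 2 * pi * (seq_len(n_conditions) - 1) / n_conditions
    templates <- t(vapply(seq_len(n_clusters), function(j) {
      separation * cos(tgrid + 2 * pi * (j - 1) / n_clusters)
    }, numeric(n_conditions)))
    labels <- rep_len(seq_len(n_clusters), n_features)
    profiles <- templates[labels, , drop = FALSE]
    if (noise_sd > 0) {
      profiles <- profiles +
        matrix(stats::rnorm(length(profiles), sd = noise_sd),
               nrow = n_features)
    }
    rownames(profiles) <- sprintf("F%d", seq_len(n_features))
    colnames(profiles) <- sprintf("C%d", seq_len(n_conditions))
    list(profiles = profiles, labels = labels)
  })
}
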