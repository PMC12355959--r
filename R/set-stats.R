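#' Fisher's exact over-representation of gene sets
#'
#' For each set, intersects its members with the universe (all tested
#' features), counts the overlap with the differential features, and
#' computes the one-sided hypergeometric tail P(X >= k) — Fisher's exact
#' test for over-representation (`alternative = "two.sided"` switches to
#' the two-sided exact test). P-values are BH-adjusted across tested sets
#' and each record carries the median log2 fold change of the set's
#' differential members. Sets with fewer than `min_set_size` in-universe
#' members are skipped (recorded) to avoid vacuous tests.
#'
#' @param differential character vector of differential feature ids; must
#'   be a subset of `universe`.
#' @param universe character vector of all tested feature ids.
#' @param sets a [read_gmt()] collection or named list of member vectors.
#' @param log2fc_lookup named numeric vector of log2 fold changes (names =
#'   feature ids), used for `median_log2fc`; optional.
#' @param min_set_size smallest in-universe set tested (default 3).
#' @param alternative `"greater"` (over-representation, default) or
#'   `"two.sided"`.
#' @return Data frame with one row per tested set: `set_id`, `overlap_k`,
#'   `set_size_K`, `n_differential`, `universe_N`, `p_value`, `q_value`,
#'   `median_log2fc`, ordered by p. Skipped sets are in the `"skipped"`
#'   attribute.
#' @examples
#' sets <- list(S1 = c("a", "b", "c", "d", "e"))
#' fisher_enrichment(c("a", "b", "c"), letters[1:10], sets)
#' @export
fisher_enrichment <- function(differential, universe, sets,
                              log2fc_lookup = NULL, min_set_size = 3,
                              alternative = c("greater", "two.sided")) {
  alternative <- match.arg(alternative)
  universe <- unique(universe)
  differential <- unique(differential)
  stray <- setdiff(differential, universe)
  if (length(stray)) {
    stop("differential features not in the universe: ",
         paste(utils::head(stray, 5), collapse = ", "), call. = FALSE)
  }
  n_u <- length(universe)
  n_d <- length(differential)

  rows <- list(); skipped <- character(0)
  for (set_id in names(sets)) {
    members <- intersect(unique(sets[[set_id]]), universe)
    k_size <- length(members)
    if (k_size < min_set_size) {
      skipped <- c(skipped, set_id)
      next
    }
    k <- length(intersect(members, differential))
    p <- if (alternative == "greater") {
      stats::phyper(k - 1, k_size, n_u - k_size, n_d, lower.tail = FALSE)
    } else {
      stats::fisher.test(matrix(c(k, k_size - k, n_d - k,
                                  n_u - k_size - n_d + k), 2),
                         alternative = "two.sided")$p.value
    }
    med <- if (k > 0 && !is.null(log2fc_lookup)) {
      stats::median(log2fc_lookup[intersect(members, differential)],
                    na.rm = TRUE)
    } else NA_real_
    rows[[set_id]] <- data.frame(
      set_id = set_id, overlap_k = k, set_size_K = k_size,
      n_differential = n_d, universe_N = n_u, p_value = p,
      median_log2fc = med, stringsAsFactors = FALSE)
  }
  if (!length(rows)) {
    stop("no set has >= ", min_set_size, " members in the universe",
         call. = FALSE)
  }
  out <- do.call(rbind, rows)
  out$q_value <- bh_adjust(out$p_value)
  out <- out[order(out$p_value), c("set_id", "overlap_k", "set_size_K",
                                   "n_differential", "universe_N",
                                   "p_value", "q_value", "median_log2fc")]
  rownames(out) <- NULL
  if (length(skipped)) {
    message(length(skipped), " set(s) skipped (< ", min_set_size,
            " in-universe members)")
  }
  attr(out, "skipped") <- skipped
  out
}

#' Permutational multivariate analysis of variance (PERMANOVA)
#'
#' One-factor PERMANOVA on a distance matrix: the pseudo-F statistic is
#' formed from the among/within decomposition of squared inter-point
#' distances,
#' \deqn{F = \frac{SS_A / (g - 1)}{SS_W / (n - g)}}
#' with \eqn{SS_T = \sum_{i<j} d_{ij}^2 / n} and \eqn{SS_W} the analogous
#' within-group sums. Significance is assessed by seeded random label
#' permutation: `p = (1 + #[F* >= F]) / (n_perm + 1)`, so the smallest
#' attainable p is `1 / (n_perm + 1)`.
#'
#' @param d distances: a `dist` object or a symmetric matrix with zero
#'   diagonal.
#' @param groups group label per observation; >= 2 groups, each with
#'   >= 2 observations.
#' @param n_perm number of label permutations (default 999).
#' @param seed RNG seed for the permutations.
#' @return A `permanova_result`: `pseudo_f`, `p_value`, `n_perm`, `seed`,
#'   `df` (among, within), `ss` (total, among, within).
#' @export
permanova <- function(d, groups, n_perm = 999, seed = 1L) {
  dm <- as.matrix(d)
  if (nrow(dm) != ncol(dm) || max(abs(dm - t(dm))) > 1e-8 ||
      any(abs(diag(dm)) > 1e-12)) {
    stop("d must be a symmetric distance matrix with zero diagonal",
         call. = FALSE)
  }
  groups <- as.factor(groups)
  n <- nrow(dm)
  if (length(groups) != n) stop("groups length must match d", call. = FALSE)
  if (nlevels(groups) < 2) stop("need >= 2 groups", call. = FALSE)
  if (any(table(groups) < 2)) {
    stop("every group needs >= 2 observations", call. = FALSE)
  }
  d2 <- dm^2
  g <- nlevels(groups)
  ss_total <- sum(d2[upper.tri(d2)]) / n

  within_ss <- function(lab) {
    ss <- 0
    for (lv in levels(lab)) {
      idx <- which(lab == lv)
      sub <- d2[idx, idx, drop = FALSE]
      ss <- ss + sum(sub[upper.tri(sub)]) / length(idx)
    }
    ss
  }
  pseudo_f <- function(lab) {
    ssw <- within_ss(lab)
    ((ss_total - ssw) / (g - 1)) / (ssw / (n - g))
  }
  f_obs <- pseudo_f(groups)
  exceed <- with_local_seed(seed, {
    sum(vapply(seq_len(n_perm), function(i) {
      pseudo_f(groups[sample.int(n)]) >= f_obs
    }, logical(1)))
  })
  ssw_obs <- within_ss(groups)
  structure(list(pseudo_f = f_obs,
                 p_value = (1 + exceed) / (n_perm + 1),
                 n_perm = n_perm, seed = seed,
                 df = c(among = g - 1, within = n - g),
                 ss = c(total = ss_total, among = ss_total - ssw_obs,
                        within = ssw_obs)),
            class = "permanova_result")
}

#' @export
print.permanova_result <- function(x, ...) {
  cat(sprintf("PERMANOVA: pseudo-F = %.3f, p = %.4g (%d permutations)\n",
              x$pseudo_f, x$p_value, x$n_perm))
  invisible(x)
}
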