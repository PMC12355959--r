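#' Row standardization of profile matrices
#'
#' Scales each row (feature profile) to mean 0 and standard deviation 1
#' (n - 1 denominator), the usual preprocessing before soft clustering so
#' that cluster distances reflect profile shape, not amplitude. Rows with
#' zero variance carry no shape and are dropped with a warning naming
#' them. Standardizing twice equals standardizing once.
#'
#' @param x numeric matrix, features in rows (>= 2 columns).
#' @return The standardized matrix, possibly with fewer rows.
#' @examples
#' standardize_rows(rbind(a = c(1, 2, 3)))
#' @export
standardize_rows <- function(x) {
  if (!is.matrix(x)) x <- as.matrix(x)
  if (ncol(x) < 2) stop("rows must have length >= 2", call. = FALSE)
  sds <- apply(x, 1, stats::sd)
  flat <- !is.finite(sds) | sds == 0
  if (any(flat)) {
    warning("dropping ", sum(flat), " zero-variance row(s): ",
            paste(utils::head(rownames(x)[flat], 5), collapse = ", "),
            call. = FALSE)
    x <- x[!flat, , drop = FALSE]
    sds <- sds[!flat]
  }
  (x - rowMeans(x)) / sds
}

#' Fuzzy c-means clustering of abundance profiles
#'
#' Standard fuzzy c-means with alternating updates: memberships
#' proportional to inverse squared Euclidean distance raised to
#' `1/(m - 1)`, centers as membership^m-weighted means. Defaults follow
#' the soft-clustering setup used for differential-protein profiles:
#' 10 clusters and fuzzifier m = 1.765. Iteration stops when the largest
#' membership change falls below `tol` or `max_iter` is reached; the
#' objective (membership^m-weighted within-cluster squared distance) is
#' recorded per iteration and is non-increasing.
#'
#' Initialization: `"maximin"` (default) is a deterministic farthest-point
#' scheme — the first center is the row of largest norm, each next center
#' the row farthest from those chosen, ties broken by comparing row
#' values — so results do not depend on row order or on the seed.
#' `"random"` draws distinct data rows under `seed`.
#'
#' @param x numeric matrix of (typically row-standardized) profiles.
#' @param n_clusters number of clusters c, >= 2 and <= nrow(x).
#' @param fuzzifier membership exponent m > 1; m near 1 approaches hard
#'   clustering, large m pushes every membership towards 1/c.
#' @param seed RNG seed, used by `init = "random"`.
#' @param max_iter,tol convergence controls (max membership change).
#' @param init `"maximin"` or `"random"`.
#' @return A `fuzzy_clustering` object: `centers` (c x D), `membership`
#'   (N x c, rows summing to 1), `fuzzifier`, `n_clusters`, `objective`,
#'   `objective_trace`, `iterations`, `converged`, `seed`.
#' @export
fuzzy_cmeans <- function(x, n_clusters = 10, fuzzifier = 1.765, seed = 1L,
                         max_iter = 1000, tol = 1e-6,
                         init = c("maximin", "random")) {
  init <- match.arg(init)
  if (!is.matrix(x)) x <- as.matrix(x)
  n <- nrow(x)
  if (n_clusters < 2) stop("n_clusters must be >= 2", call. = FALSE)
  if (n < n_clusters) {
    stop("fewer features (", n, ") than clusters (", n_clusters, ")",
         call. = FALSE)
  }
  if (fuzzifier <= 1) stop("fuzzifier must be > 1", call. = FALSE)

  centers <- if (init == "maximin") maximin_centers(x, n_clusters)
  else with_local_seed(seed, x[sample.int(n, n_clusters), , drop = FALSE])
  # shrink initial centers halfway towards the centroid: keeps the
  # symmetry-breaking directions but avoids the degenerate fixed point in
  # which a center stays locked onto the data row it was seeded from
  centroid <- colMeans(x)
  centers <- sweep(0.5 * centers, 2, 0.5 * centroid, "+")

  exp_u <- 1 / (fuzzifier - 1)
  u_old <- NULL
  trace <- numeric(0)
  converged <- FALSE
  iter <- 0L
  repeat {
    iter <- iter + 1L
    d2 <- sq_dist(x, centers)                       # N x c
    u <- memberships_from_d2(d2, exp_u)
    um <- u^fuzzifier
    centers <- (t(um) %*% x) / colSums(um)
    trace[iter] <- sum(um * sq_dist(x, centers))
    if (!is.null(u_old) && max(abs(u - u_old)) < tol) {
      converged <- TRUE
      break
    }
    if (iter >= max_iter) break
    u_old <- u
  }
  dimnames(u) <- list(rownames(x), sprintf("cluster_%d", seq_len(n_clusters)))
  dimnames(centers) <- list(sprintf("cluster_%d", seq_len(n_clusters)),
                            colnames(x))
  structure(list(centers = centers, membership = u, fuzzifier = fuzzifier,
                 n_clusters = n_clusters, objective = trace[iter],
                 objective_trace = trace, iterations = iter,
                 converged = converged, seed = seed),
            class = "fuzzy_clustering")
}

# squared Euclidean distances between rows of x and rows of centers
sq_dist <- function(x, centers) {
  d2 <- outer(rowSums(x^2), rep(1, nrow(centers))) +
    outer(rep(1, nrow(x)), rowSums(centers^2)) -
    2 * x %*% t(centers)
  pmax(d2, 0)
}

memberships_from_d2 <- function(d2, exp_u) {
  # floor distances at a tiny fraction of their mean: a point sitting on a
  # center then gets near-crisp membership for moderate fuzzifiers while
  # the uniform 1/c limit for very large fuzzifiers is preserved
  d2 <- pmax(d2, 1e-12 * (mean(d2) + .Machine$double.xmin))
  w <- d2^(-exp_u)
  w / rowSums(w)
}

# deterministic, order-independent farthest-point initialization:
# ties broken by lexicographic comparison of row values
maximin_centers <- function(x, k) {
  tie_order <- do.call(order, c(list(), as.data.frame(x)))
  rank_of <- order(tie_order)
  norms <- rowSums(x^2)
  pick <- function(score) {
    best <- which(score == max(score))
    best[which.min(rank_of[best])]
  }
  chosen <- pick(norms)
  mind2 <- sq_dist(x, x[chosen, , drop = FALSE])[, 1]
  while (length(chosen) < k) {
    nxt <- pick(mind2)
    chosen <- c(chosen, nxt)
    mind2 <- pmin(mind2, sq_dist(x, x[nxt, , drop = FALSE])[, 1])
  }
  x[chosen, , drop = FALSE]
}

#' @export
print.fuzzy_clustering <- function(x, ...) {
  cat(sprintf(
    "fuzzy_clustering: %d features, %d clusters, m = %.3f\n",
    nrow(x$membership), x$n_clusters, x$fuzzifier))
  cat(sprintf("objective %.4f after %d iterations (converged: %s)\n",
              x$objective, x$iterations, x$converged))
  invisible(x)
}

#' Threshold cluster assignment from a fuzzy clustering
#'
#' Assigns each feature to its argmax-membership cluster iff that
#' membership strictly exceeds `threshold` (default 0.2, the conventional
#' plotting cut for soft-clustered profiles); otherwise the feature is
#' left unassigned (`NA`). Ties go to the lowest cluster index (reported).
#'
#' @param clustering a [fuzzy_cmeans()] result.
#' @param threshold membership cut in `[0, 1)`; strict inequality.
#' @return Data frame with `feature_id`, `cluster` (integer or `NA`),
#'   `membership` (the max membership).
#' @export
membership_assign <- function(clustering, threshold = 0.2) {
  if (threshold < 0 || threshold >= 1) {
    stop("threshold must lie in [0, 1)", call. = FALSE)
  }
  u <- clustering$membership
  best <- apply(u, 1, which.max)                 # leftmost max on ties
  best_u <- u[cbind(seq_len(nrow(u)), best)]
  ties <- rowSums(abs(u - best_u) < 1e-12) > 1
  if (any(ties)) {
    message(sum(ties), " tie(s) broken by lowest cluster index")
  }
  data.frame(
    feature_id = if (is.null(rownames(u)))
      as.character(seq_len(nrow(u))) else rownames(u),
    cluster = ifelse(best_u > threshold, best, NA_integer_),
    membership = best_u,
    stringsAsFactors = FALSE)
}

#' Adjusted Rand index between two partitions
#'
#' Chance-corrected agreement between two labelings of the same items;
#' 1 means identical partitions, 0 the expected agreement of random ones.
#' Used to score cluster recovery against simulation ground truth.
#'
#' @param a,b label vectors of equal length.
#' @return The adjusted Rand index.
#' @export
adjusted_rand_index <- function(a, b) {
  stopifnot(length(a) == length(b))
  tab <- table(a, b)
  comb2 <- function(x) x * (x - 1) / 2
  sum_ij <- sum(comb2(tab))
  sum_a <- sum(comb2(rowSums(tab)))
  sum_b <- sum(comb2(colSums(tab)))
  n2 <- comb2(length(a))
  expected <- sum_a * sum_b / n2
  max_index <- (sum_a + sum_b) / 2
  if (max_index == expected) return(1)
  (sum_ij - expected) / (max_index - expected)
}
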