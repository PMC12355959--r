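#' Benjamini-Hochberg FDR adjustment
#'
#' Step-up BH adjustment with monotonicity enforcement, order-preserving
#' with respect to the input indexing (thin wrapper over
#' [stats::p.adjust()] with input validation).
#'
#' @param p_values numeric vector of p-values in `[0, 1]`.
#' @return q-values aligned to the input; always `>= p` element-wise.
#' @examples
#' bh_adjust(c(0.005, 0.04, 0.9))  # 0.015 0.060 0.900
#' @export
bh_adjust <- function(p_values) {
  if (any(!is.na(p_values) & (p_values < 0 | p_values > 1))) {
    stop("p-values must lie in [0, 1]", call. = FALSE)
  }
  stats::p.adjust(p_values, method = "BH")
}

#' Per-feature differential abundance test between two groups
#'
#' For every feature with at least two non-missing values in each group,
#' computes the log2 fold change as mean(A) minus mean(B) and a two-sided
#' Student's t-test (equal-variance pooled by default; Welch by
#' `var_equal = FALSE`). P-values are BH-adjusted across all tested
#' features of the matrix and significance is called at `q <= q_threshold`.
#'
#' Degenerate features (zero pooled variance) get p = 1 when the group
#' means agree and p = 0 otherwise.
#'
#' @param im log2-scale [intensity_matrix()].
#' @param group_a,group_b group labels present in the sample sheet; the
#'   fold change is A minus B.
#' @param var_equal pooled-variance Student's t (default) or Welch.
#' @param q_threshold FDR threshold for the `significant` flag
#'   (default 0.05).
#' @return Data frame with one row per tested feature: `feature_id`,
#'   `mean_a`, `mean_b`, `log2fc`, `t_stat`, `df`, `p_value`, `q_value`,
#'   `significant`. Features skipped for insufficient observations are in
#'   the `"skipped"` attribute with a reason.
#' @export
differential_test <- function(im, group_a, group_b, var_equal = TRUE,
                              q_threshold = 0.05) {
  stopifnot(inherits(im, "intensity_matrix"))
  if (im$scale != "log2") {
    stop("differential testing expects log2-scale intensities", call. = FALSE)
  }
  for (g in c(group_a, group_b)) {
    if (!g %in% im$samples$group) {
      stop("unknown group label: ", g, call. = FALSE)
    }
  }
  xa <- im$values[, im$samples$group == group_a, drop = FALSE]
  xb <- im$values[, im$samples$group == group_b, drop = FALSE]

  na_ <- rowSums(!is.na(xa))
  nb_ <- rowSums(!is.na(xb))
  testable <- na_ >= 2 & nb_ >= 2
  if (!any(testable)) stop("no testable features", call. = FALSE)

  ma <- rowMeans(xa, na.rm = TRUE)
  mb <- rowMeans(xb, na.rm = TRUE)
  va <- apply(xa, 1, stats::var, na.rm = TRUE)
  vb <- apply(xb, 1, stats::var, na.rm = TRUE)

  idx <- which(testable)
  na_t <- na_[idx]; nb_t <- nb_[idx]
  va_t <- va[idx]; vb_t <- vb[idx]
  diff <- (ma - mb)[idx]

  if (var_equal) {
    sp2 <- ((na_t - 1) * va_t + (nb_t - 1) * vb_t) / (na_t + nb_t - 2)
    se <- sqrt(sp2 * (1 / na_t + 1 / nb_t))
    df <- na_t + nb_t - 2
  } else {
    se <- sqrt(va_t / na_t + vb_t / nb_t)
    df <- (va_t / na_t + vb_t / nb_t)^2 /
      ((va_t / na_t)^2 / (na_t - 1) + (vb_t / nb_t)^2 / (nb_t - 1))
  }
  tstat <- diff / se
  p <- 2 * stats::pt(-abs(tstat), df)
  zero_se <- !is.finite(se) | se == 0
  p[zero_se & diff == 0] <- 1
  p[zero_se & diff != 0] <- 0
  tstat[zero_se] <- ifelse(diff[zero_se] == 0, 0, sign(diff[zero_se]) * Inf)

  q <- bh_adjust(p)
  out <- data.frame(
    feature_id = rownames(im$values)[idx],
    mean_a = ma[idx], mean_b = mb[idx], log2fc = diff,
    t_stat = tstat, df = df, p_value = p, q_value = q,
    significant = q <= q_threshold,
    stringsAsFactors = FALSE)
  rownames(out) <- NULL
  skipped <- rownames(im$values)[!testable]
  attr(out, "skipped") <- if (length(skipped))
    data.frame(feature_id = skipped,
               reason = "fewer than 2 observations in a group",
               stringsAsFactors = FALSE) else NULL
  attr(out, "groups") <- c(a = group_a, b = group_b)
  out
}
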