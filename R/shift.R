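#' Melting-point shift for one protein
#'
#' Computes the treatment-minus-vehicle melting-point shift and its
#' two-sided Student's t-test p-value from the per-replicate Tm estimates of
#' the two arms. Direction consistency requires every pairwise
#' treated-versus-vehicle difference to carry the same sign: per-replicate
#' differences in paired mode, all cross-pairs in unpaired mode; a zero
#' difference is not "the same direction" and fails consistency.
#'
#' @param tm_vehicle,tm_treated numeric vectors of replicate melting points
#'   (degrees C); `NA` entries (undefined Tm) are dropped.
#' @param paired use a paired t-test and per-replicate direction pairing
#'   (vectors must then align by replicate). Default unpaired,
#'   equal-variance.
#' @param min_r2 minimum R2 over the contributing curve fits, carried along
#'   for candidate filtering (optional).
#' @return List of class `shift_record`: `delta_tm` (mean treated - mean
#'   vehicle), `p_value`, `direction_consistent`, `min_r2`, `n_vehicle`,
#'   `n_treated`, `n_pairs`, `degenerate` (TRUE when both arms have zero
#'   variance but the shift is nonzero; `p_value` is then 0).
#' @examples
#' compute_shift(c(50.1, 49.9, 50.2, 49.8), c(47.1, 46.9, 47.2, 46.8))
#' @export
compute_shift <- function(tm_vehicle, tm_treated, paired = FALSE,
                          min_r2 = NA_real_) {
  v <- tm_vehicle[is.finite(tm_vehicle)]
  t_ <- tm_treated[is.finite(tm_treated)]
  if (length(v) < 2L || length(t_) < 2L) {
    stop("insufficient replicates: need >= 2 defined melting points per arm (",
         "vehicle ", length(v), ", treated ", length(t_), ")", call. = FALSE)
  }
  if (paired) {
    ok <- is.finite(tm_vehicle) & is.finite(tm_treated)
    if (length(tm_vehicle) != length(tm_treated)) {
      stop("paired mode requires replicate-aligned Tm vectors", call. = FALSE)
    }
    v <- tm_vehicle[ok]; t_ <- tm_treated[ok]
    if (length(v) < 2L) {
      stop("insufficient replicates: need >= 2 complete pairs", call. = FALSE)
    }
    diffs <- t_ - v
  } else {
    diffs <- as.vector(outer(t_, v, "-"))
  }
  delta <- mean(t_) - mean(v)

  degenerate <- FALSE
  p <- if (paired) {
    if (stats::var(diffs) == 0) {
      if (all(diffs == 0)) 1 else { degenerate <- TRUE; 0 }
    } else {
      stats::t.test(t_, v, paired = TRUE)$p.value
    }
  } else {
    if (stats::var(v) == 0 && stats::var(t_) == 0) {
      if (delta == 0) 1 else { degenerate <- TRUE; 0 }
    } else {
      stats::t.test(t_, v, var.equal = TRUE)$p.value
    }
  }

  out <- list(
    delta_tm = delta,
    p_value = p,
    direction_consistent = all(diffs > 0) || all(diffs < 0),
    min_r2 = min_r2,
    n_vehicle = length(v),
    n_treated = length(t_),
    n_pairs = length(diffs),
    degenerate = degenerate
  )
  class(out) <- "shift_record"
  out
}

#' Per-protein melting-point shifts for a fitted dataset
#'
#' Groups the per-series fits of [fit_melting_dataset()] by protein and
#' computes a [compute_shift()] record for each. Proteins with fewer than
#' two defined melting points in either arm are excluded with reason
#' `"insufficient replicates"` (available in the `"excluded"` attribute);
#' every excluded protein carries exactly one primary reason.
#'
#' @param fits data frame from [fit_melting_dataset()].
#' @param paired paired t-test across replicate-matched lysate splits.
#' @param vehicle,treated condition labels for the two arms.
#' @return Data frame with one row per tested protein: `protein_id`,
#'   `delta_tm`, `p_value`, `direction_consistent`, `min_r2`, `n_vehicle`,
#'   `n_treated`, `n_pairs`, `degenerate`.
#' @export
compute_shifts <- function(fits, paired = FALSE,
                           vehicle = "vehicle", treated = "treated") {
  stopifnot(all(c("protein_id", "condition", "replicate", "tm", "r2")
                %in% names(fits)))
  rows <- list(); excluded <- list()
  for (pid in unique(fits$protein_id)) {
    sub <- fits[fits$protein_id == pid, , drop = FALSE]
    vs <- sub[sub$condition == vehicle, , drop = FALSE]
    ts <- sub[sub$condition == treated, , drop = FALSE]
    if (paired) {
      vs <- vs[order(vs$replicate), , drop = FALSE]
      ts <- ts[order(ts$replicate), , drop = FALSE]
      reps <- intersect(vs$replicate, ts$replicate)
      vs <- vs[match(reps, vs$replicate), , drop = FALSE]
      ts <- ts[match(reps, ts$replicate), , drop = FALSE]
    }
    rec <- tryCatch(
      compute_shift(vs$tm, ts$tm, paired = paired,
                    min_r2 = suppressWarnings(
                      min(c(vs$r2, ts$r2)[is.finite(c(vs$tm, ts$tm))]))),
      error = function(e) conditionMessage(e))
    if (is.character(rec)) {
      excluded[[length(excluded) + 1L]] <- data.frame(
        protein_id = pid,
        reason = if (grepl("insufficient replicates", rec))
          "insufficient replicates" else rec,
        stringsAsFactors = FALSE)
      next
    }
    rows[[length(rows) + 1L]] <- data.frame(
      protein_id = pid, delta_tm = rec$delta_tm, p_value = rec$p_value,
      direction_consistent = rec$direction_consistent, min_r2 = rec$min_r2,
      n_vehicle = rec$n_vehicle, n_treated = rec$n_treated,
      n_pairs = rec$n_pairs, degenerate = rec$degenerate,
      stringsAsFactors = FALSE)
  }
  out <- if (length(rows)) do.call(rbind, rows) else
    data.frame(protein_id = character(), delta_tm = numeric(),
               p_value = numeric(), direction_consistent = logical(),
               min_r2 = numeric(), n_vehicle = integer(),
               n_treated = integer(), n_pairs = integer(),
               degenerate = logical())
  rownames(out) <- NULL
  attr(out, "excluded") <-
    if (length(excluded)) do.call(rbind, excluded) else NULL
  out
}

#' Candidate filtering cascade for Tm shifts
#'
#' Applies the three-criterion candidate cascade to shift records: a
#' significant shift (raw `p < alpha`; no multiple-testing correction is
#' applied to the decision, matching the raw-p screening convention of
#' thermal-shift candidate discovery, but a BH-adjusted column `q_value`
#' is emitted for transparency), a curve fit with R2 above `r2_min` for
#' all contributing replicates, and a shift direction shared by all
#' pairwise solvent-versus-treatment comparisons. The candidate flag is the
#' AND of the three per-criterion flags, all of which are retained for
#' audit.
#'
#' @param shifts data frame from [compute_shifts()].
#' @param alpha significance level on the raw two-sided p (default 0.05).
#' @param r2_min minimum R2 required of every contributing fit
#'   (default 0.9, strict inequality).
#' @return The shift table ordered by p then decreasing |delta Tm|, with
#'   columns `pass_p`, `pass_r2`, `pass_direction`, `candidate`, `q_value`.
#' @export
filter_candidates <- function(shifts, alpha = 0.05, r2_min = 0.9) {
  out <- shifts
  if (nrow(out) == 0L) {
    out$pass_p <- logical(); out$pass_r2 <- logical()
    out$pass_direction <- logical(); out$candidate <- logical()
    out$q_value <- numeric()
    return(out)
  }
  out$pass_p <- out$p_value < alpha
  out$pass_r2 <- !is.na(out$min_r2) & out$min_r2 > r2_min
  out$pass_direction <- out$direction_consistent
  out$candidate <- out$pass_p & out$pass_r2 & out$pass_direction
  out$q_value <- stats::p.adjust(out$p_value, method = "BH")
  out <- out[order(out$p_value, -abs(out$delta_tm)), , drop = FALSE]
  rownames(out) <- NULL
  attr(out, "alpha") <- alpha
  attr(out, "r2_min") <- r2_min
  out
}

#' Volcano-plot export of a candidate table
#'
#' One row per protein with the shift, `-log10(p)` (p floored at 1e-300),
#' and the audit flags, ready for plotting.
#'
#' @param table candidate table from [filter_candidates()].
#' @return Data frame with columns `protein_id`, `delta_tm`,
#'   `neg_log10_p`, `pass_p`, `pass_r2`, `pass_direction`, `candidate`.
#' @export
volcano_export <- function(table) {
  data.frame(
    protein_id = table$protein_id,
    delta_tm = table$delta_tm,
    neg_log10_p = -log10(pmax(table$p_value, 1e-300)),
    pass_p = table$pass_p,
    pass_r2 = table$pass_r2,
    pass_direction = table$pass_direction,
    candidate = table$candidate,
    stringsAsFactors = FALSE
  )
}

#' Candidate funnel counts
#'
#' Counts of proteins surviving each stage of the candidate cascade, in
#' filter order: quantified, testable (>= 2 Tm per arm), significant shift,
#' + R2 criterion, + direction criterion (= candidates).
#'
#' @param n_quantified number of proteins entering the pipeline.
#' @param candidates candidate table from [filter_candidates()].
#' @return Named integer vector of monotone non-increasing counts.
#' @export
candidate_funnel <- function(n_quantified, candidates) {
  c(quantified = as.integer(n_quantified),
    tested = nrow(candidates),
    significant = sum(candidates$pass_p),
    good_fit = sum(candidates$pass_p & candidates$pass_r2),
    candidates = sum(candidates$candidate))
}
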