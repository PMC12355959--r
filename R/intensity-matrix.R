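#' Intensity matrix with sample metadata
#'
#' The package's container for features x samples intensity data (proteins
#' or PTM sites), carrying per-sample group/replicate metadata and the
#' scale of the values. Missing values are allowed; raw-scale values must
#' be non-negative where present.
#'
#' @param values numeric matrix, features in rows (unique rownames =
#'   feature ids), samples in columns (colnames = sample ids).
#' @param samples data frame with columns `sample`, `group`, and optionally
#'   `replicate`; one row per column of `values`, matched by name.
#' @param scale `"raw"` or `"log2"`.
#' @return An `intensity_matrix` object (list with `values`, `samples`,
#'   `scale`).
#' @export
intensity_matrix <- function(values, samples,
                             scale = c("raw", "log2")) {
  scale <- match.arg(scale)
  if (!is.matrix(values) || !is.numeric(values)) {
    stop("values must be a numeric matrix", call. = FALSE)
  }
  if (nrow(values) > 0L &&
      (is.null(rownames(values)) || anyDuplicated(rownames(values)))) {
    dup <- unique(rownames(values)[duplicated(rownames(values))])
    stop("feature ids must be unique rownames",
         if (length(dup)) paste0("; duplicated: ",
                                 paste(utils::head(dup, 5), collapse = ", ")),
         call. = FALSE)
  }
  if (!all(c("sample", "group") %in% names(samples))) {
    stop("samples needs columns 'sample' and 'group'", call. = FALSE)
  }
  if (is.null(colnames(values))) {
    stop("values must have sample ids as colnames", call. = FALSE)
  }
  if (!setequal(colnames(values), samples$sample) ||
      anyDuplicated(samples$sample)) {
    stop("sample sheet does not match matrix columns", call. = FALSE)
  }
  samples <- samples[match(colnames(values), samples$sample), , drop = FALSE]
  rownames(samples) <- NULL
  if (scale == "raw" && any(values < 0, na.rm = TRUE)) {
    stop("raw-scale intensities must be >= 0", call. = FALSE)
  }
  structure(list(values = values, samples = samples, scale = scale),
            class = "intensity_matrix")
}

#' @export
print.intensity_matrix <- function(x, ...) {
  cat(sprintf("intensity_matrix: %d features x %d samples (%s scale)\n",
              nrow(x$values), ncol(x$values), x$scale))
  cat("groups:", paste(sprintf("%s (n=%d)", names(table(x$samples$group)),
                               table(x$samples$group)), collapse = ", "), "\n")
  cat(sprintf("missing: %.1f%%\n", 100 * mean(is.na(x$values))))
  invisible(x)
}

#' @export
dim.intensity_matrix <- function(x) dim(x$values)

#' Reliability filter on per-group detection
#'
#' A feature is retained iff, in at least one sample group, it is observed
#' (non-missing) in at least `ceiling(min_fraction * group size)`
#' replicates. The per-group rule lets a feature present only under one
#' condition survive; `scope = "global"` instead requires the fraction over
#' all samples. Presets from common designs: 3/4 (four-replicate cell
#' data), 5/7, 2/3 and 3/3 (tissue).
#'
#' @param im an [intensity_matrix()].
#' @param min_fraction required detection fraction, in `(0, 1]`.
#' @param scope `"any_group"` (default) or `"global"`.
#' @return The filtered `intensity_matrix`; retained/dropped counts are in
#'   the `"filter_report"` attribute and reported via `message()`.
#' @export
reliability_filter <- function(im, min_fraction = 3 / 4,
                               scope = c("any_group", "global")) {
  scope <- match.arg(scope)
  stopifnot(inherits(im, "intensity_matrix"))
  if (min_fraction <= 0 || min_fraction > 1) {
    stop("min_fraction must lie in (0, 1]", call. = FALSE)
  }
  obs <- !is.na(im$values)
  if (scope == "global") {
    keep <- rowSums(obs) >= ceiling(min_fraction * ncol(obs))
  } else {
    keep <- rep(FALSE, nrow(obs))
    for (g in unique(im$samples$group)) {
      idx <- im$samples$group == g
      need <- ceiling(min_fraction * sum(idx))
      keep <- keep | rowSums(obs[, idx, drop = FALSE]) >= need
    }
  }
  out <- intensity_matrix(im$values[keep, , drop = FALSE], im$samples,
                          scale = im$scale)
  report <- c(input = nrow(obs), retained = sum(keep),
              dropped = sum(!keep))
  attr(out, "filter_report") <- report
  message(sprintf("reliability_filter: retained %d / %d features (%s, >= %s)",
                  report["retained"], report["input"], scope,
                  format(min_fraction)))
  out
}

#' Log2 transform and variance stabilization
#'
#' Transforms raw intensities to log2 and stabilizes sample-to-sample
#' scale: each sample (column) is centered to median 0 and rescaled so its
#' median absolute deviation equals the pooled (median) MAD across
#' samples. The procedure is invariant to per-sample scalar factors on the
#' raw scale and idempotent on already-stabilized data; missing values are
#' untouched. `method = "log2_only"` skips the stabilization.
#'
#' @param im raw-scale [intensity_matrix()] with positive values where
#'   present.
#' @param method `"mad"` (default) or `"log2_only"`.
#' @return A log2-scale `intensity_matrix`.
#' @export
log_transform_stabilize <- function(im, method = c("mad", "log2_only")) {
  method <- match.arg(method)
  stopifnot(inherits(im, "intensity_matrix"))
  if (im$scale != "raw") {
    stop("input must be on the raw scale (got ", im$scale, ")", call. = FALSE)
  }
  bad <- which(im$values <= 0, arr.ind = TRUE)
  if (nrow(bad)) {
    stop("non-positive intensities cannot be log-transformed: ",
         paste(sprintf("[%s, %s]", rownames(im$values)[bad[, 1]],
                       colnames(im$values)[bad[, 2]])[seq_len(min(5, nrow(bad)))],
               collapse = ", "), call. = FALSE)
  }
  v <- log2(im$values)
  if (method == "mad") {
    med <- apply(v, 2, stats::median, na.rm = TRUE)
    v <- sweep(v, 2, med, "-")
    mads <- apply(v, 2, stats::mad, na.rm = TRUE)
    if (any(!is.finite(mads) | mads == 0)) {
      stop("a sample has zero or undefined MAD; cannot stabilize",
           call. = FALSE)
    }
    target <- stats::median(mads)
    v <- sweep(v, 2, target / mads, "*")
  }
  intensity_matrix(v, im$samples, scale = "log2")
}

#' Normalize PTM-site intensities to their parent proteins
#'
#' Site abundances are normalized to the corresponding protein levels:
#' on the log2 scale, normalized site value = site log2 minus parent
#' protein log2, element-wise per sample. Sites whose parent protein is
#' absent from the protein matrix are dropped (warned); where the protein
#' value is missing in a sample, the normalized site value is missing
#' there (a site is never carried unnormalized).
#'
#' @param sites,proteins log2-scale [intensity_matrix()] objects over the
#'   identical sample set.
#' @param map site map data frame with columns `site_id`, `protein_id`
#'   (and optionally `residue`, `position`, `modification`; see
#'   [validate_site_map()]).
#' @return Log2-scale `intensity_matrix` of protein-normalized site
#'   abundances; provenance counts in the `"provenance"` attribute.
#' @export
normalize_sites_to_protein <- function(sites, proteins, map) {
  stopifnot(inherits(sites, "intensity_matrix"),
            inherits(proteins, "intensity_matrix"))
  if (sites$scale != "log2" || proteins$scale != "log2") {
    stop("both matrices must be on the log2 scale", call. = FALSE)
  }
  if (!setequal(colnames(sites$values), colnames(proteins$values))) {
    stop("site and protein matrices have different sample sets",
         call. = FALSE)
  }
  prot_v <- proteins$values[, colnames(sites$values), drop = FALSE]

  site_ids <- rownames(sites$values)
  parent <- map$protein_id[match(site_ids, map$site_id)]
  unmapped <- is.na(parent)
  if (any(unmapped)) {
    warning(sum(unmapped), " site(s) without a map entry dropped: ",
            paste(utils::head(site_ids[unmapped], 5), collapse = ", "),
            call. = FALSE)
  }
  no_protein <- !unmapped & !(parent %in% rownames(prot_v))
  if (any(no_protein)) {
    warning(sum(no_protein),
            " site(s) dropped because the parent protein is not quantified",
            call. = FALSE)
  }
  keep <- !unmapped & !no_protein
  v <- sites$values[keep, , drop = FALSE] -
    prot_v[parent[keep], , drop = FALSE]
  out <- intensity_matrix(v, sites$samples, scale = "log2")
  attr(out, "provenance") <- c(input = length(site_ids),
                               normalized = sum(keep),
                               unmapped = sum(unmapped),
                               missing_protein = sum(no_protein))
  out
}

#' Validate a site map
#'
#' Checks the residue/modification compatibility convention: lysine (K)
#' for acetylation; serine, threonine or tyrosine (S/T/Y) for
#' phosphorylation. Positions are 1-based indices in the protein sequence.
#'
#' @param map data frame with columns `site_id`, `protein_id`, `residue`,
#'   `position`, `modification`.
#' @return The map, invisibly, if valid.
#' @export
validate_site_map <- function(map) {
  need <- c("site_id", "protein_id", "residue", "position", "modification")
  miss <- setdiff(need, names(map))
  if (length(miss)) {
    stop("site map missing columns: ", paste(miss, collapse = ", "),
         call. = FALSE)
  }
  if (any(map$position < 1)) stop("positions must be >= 1", call. = FALSE)
  ok <- (map$modification == "acetyl" & map$residue == "K") |
    (map$modification == "phospho" & map$residue %in% c("S", "T", "Y"))
  if (!all(ok)) {
    stop("incompatible residue/modification for site(s): ",
         paste(utils::head(map$site_id[!ok], 5), collapse = ", "),
         call. = FALSE)
  }
  invisible(map)
}
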