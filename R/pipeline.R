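#' End-to-end TPP candidate discovery
#'
#' Chains the melting-curve stages: reference normalization and sigmoid
#' fitting of every series, per-protein Tm shift computation, and the
#' three-criterion candidate cascade. Deterministic given its inputs; the
#' funnel of counts surviving each filter step is part of the result and
#' is written to the run log.
#'
#' @param tpp long-format TPP table (data frame or TSV path).
#' @param gradient temperature gradient.
#' @param alpha significance level on the shift test (default 0.05).
#' @param r2_min minimum per-replicate fit R2 (default 0.9).
#' @param paired paired shift test across split-lysate replicates.
#' @param out_dir if given, writes `candidates.tsv`, `volcano.tsv` and
#'   `fit_report.tsv` there with config metadata in comment headers.
#' @return List with `fits`, `shifts`, `candidates`, `volcano`, `funnel`,
#'   `excluded` (per-stage exclusion tables with one primary reason each).
#' @export
run_tpp <- function(tpp, gradient = tpp_gradient(), alpha = 0.05,
                    r2_min = 0.9, paired = FALSE, out_dir = NULL) {
  if (is.character(tpp)) tpp <- read_tpp_table(tpp)
  n_quantified <- length(unique(tpp$protein_id))
  fits <- fit_melting_dataset(tpp, gradient = gradient)
  shifts <- compute_shifts(fits, paired = paired)
  candidates <- filter_candidates(shifts, alpha = alpha, r2_min = r2_min)
  volcano <- volcano_export(candidates)
  funnel <- candidate_funnel(n_quantified, candidates)
  message(paste(sprintf("%s: %d", names(funnel), funnel), collapse = " -> "))

  if (!is.null(out_dir)) {
    dir.create(out_dir, showWarnings = FALSE, recursive = TRUE)
    hdr <- c(alpha = format(alpha), r2_min = format(r2_min),
             paired = as.character(paired),
             gradient = paste(gradient, collapse = ","))
    write_tsv_with_header(candidates, file.path(out_dir, "candidates.tsv"),
                          hdr)
    write_tsv_with_header(volcano, file.path(out_dir, "volcano.tsv"), hdr)
    write_tsv_with_header(fits, file.path(out_dir, "fit_report.tsv"), hdr)
  }
  list(fits = fits, shifts = shifts, candidates = candidates,
       volcano = volcano, funnel = funnel,
       excluded = list(series = attr(fits, "excluded"),
                       proteins = attr(shifts, "excluded")))
}

#' End-to-end differential PTM/proteome analysis
#'
#' Chains the intensity-matrix stages for a proteome matrix and any number
#' of PTM site matrices: reliability filtering, log2 transform with
#' variance stabilization (raw-scale input only), site-to-protein
#' normalization, two-group differential testing with BH FDR, and
#' (optionally) Fisher's-exact set enrichment of the significant proteins
#' against a GMT collection, with the tested features as universe.
#'
#' @param proteins protein [intensity_matrix()].
#' @param group_a,group_b the two groups to contrast (A minus B).
#' @param sites optional named list of site `intensity_matrix` objects
#'   (e.g. acetylome, phosphoproteome).
#' @param site_map site map data frame; required when `sites` is given.
#' @param min_fraction reliability-filter detection fraction
#'   (default 3/4).
#' @param q_threshold FDR significance threshold (default 0.05).
#' @param gmt optional gene-set collection for enrichment of the protein
#'   results.
#' @param out_dir if given, writes one differential TSV per matrix and an
#'   `enrichment.tsv`.
#' @return List with `proteins` (differential table), `sites` (named list
#'   of differential tables on protein-normalized values), `enrichment`
#'   (or `NULL`), and `filtered` (the filtered, transformed matrices).
#' @export
run_ptm <- function(proteins, group_a, group_b, sites = NULL,
                    site_map = NULL, min_fraction = 3 / 4,
                    q_threshold = 0.05, gmt = NULL, out_dir = NULL) {
  if (!is.null(sites) && is.null(site_map)) {
    stop("site matrices require a site map", call. = FALSE)
  }
  prep <- function(im) {
    im <- reliability_filter(im, min_fraction = min_fraction)
    if (im$scale == "raw") im <- log_transform_stabilize(im)
    im
  }
  prot <- prep(proteins)
  prot_diff <- differential_test(prot, group_a, group_b,
                                 q_threshold = q_threshold)

  site_diff <- NULL
  norm_sites <- list()
  if (!is.null(sites)) {
    if (inherits(sites, "intensity_matrix")) sites <- list(sites = sites)
    site_diff <- lapply(sites, function(sm) {
      sm <- prep(sm)
      sm <- normalize_sites_to_protein(sm, prot, site_map)
      differential_test(sm, group_a, group_b, q_threshold = q_threshold)
    })
    norm_sites <- sites
  }

  enrichment <- NULL
  if (!is.null(gmt)) {
    fc <- stats::setNames(prot_diff$log2fc, prot_diff$feature_id)
    sig <- prot_diff$feature_id[prot_diff$significant]
    enrichment <- if (length(sig)) {
      fisher_enrichment(sig, prot_diff$feature_id, gmt, log2fc_lookup = fc)
    } else NULL
  }

  if (!is.null(out_dir)) {
    dir.create(out_dir, showWarnings = FALSE, recursive = TRUE)
    hdr <- c(group_a = group_a, group_b = group_b,
             min_fraction = format(min_fraction),
             q_threshold = format(q_threshold))
    write_tsv_with_header(prot_diff,
                          file.path(out_dir, "differential_proteins.tsv"),
                          hdr)
    for (nm in names(site_diff)) {
      write_tsv_with_header(
        site_diff[[nm]],
        file.path(out_dir, sprintf("differential_%s.tsv", nm)), hdr)
    }
    if (!is.null(enrichment)) {
      write_tsv_with_header(enrichment,
                            file.path(out_dir, "enrichment.tsv"), hdr)
    }
  }
  list(proteins = prot_diff, sites = site_diff, enrichment = enrichment,
       filtered = c(list(proteins = prot), norm_sites))
}
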