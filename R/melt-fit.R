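#' Normalize a melting series to the reference temperature
#'
#' Relative abundances are computed against the lowest incubation
#' temperature (the first gradient point), so the reference temperature
#' obtains a relative abundance of exactly 1. Normalizing an already
#' normalized series is the identity.
#'
#' @param intensities numeric vector of raw (or already relative)
#'   intensities aligned to the gradient; the first element is the
#'   reference-temperature value.
#' @param gradient optional gradient used only to check alignment.
#' @return Numeric vector of relative abundances with `[1] == 1`.
#' @examples
#' normalize_to_reference(c(100, 90, 50, 10, 5))
#' @export
normalize_to_reference <- function(intensities, gradient = NULL) {
  if (!is.null(gradient) && length(intensities) != length(gradient)) {
    stop("intensities and gradient lengths differ (",
         length(intensities), " vs ", length(gradient), ")", call. = FALSE)
  }
  ref <- intensities[1L]
  if (!is.finite(ref) || ref <= 0) {
    stop("reference-temperature intensity must be positive and non-missing; got ",
         ref, call. = FALSE)
  }
  intensities / ref
}

#' Fit the denaturation sigmoid to one melting series
#'
#' Bounded nonlinear least squares (Levenberg-Marquardt via
#' [minpack.lm::nlsLM()]) of the [melt_model()] parameters `(a, b, plateau)`
#' on a normalized melting series, with `plateau` constrained to `[0, 1)`
#' and `a, b > 0`. Start values are data driven: `plateau0` is the smallest
#' observed value (floored at 0), `b0 = 10`, and `a0 = b0` times the
#' temperature whose abundance lies nearest the curve half-maximum.
#' A failed or non-converged optimization never raises an error: the fit is
#' returned with `converged = FALSE` and an undefined Tm.
#'
#' @param rel_abundance relative abundances aligned to `temperature`
#'   (reference-normalized; see [normalize_to_reference()]). Missing values
#'   are dropped; at least 5 finite points are required.
#' @param temperature temperatures in degrees C.
#' @return A `melt_fit` object: list with elements `a`, `b`, `plateau`,
#'   `r2` (1 - SSres/SStot on the input values; `NA` when the series is
#'   constant), `tm` (degrees C, `NA` when undefined), `converged`,
#'   `n_points`.
#' @examples
#' grad <- tpp_gradient()
#' fit <- fit_melting_curve(melt_model(grad, 2000, 40, 0.1), grad)
#' fit$tm
#' @export
fit_melting_curve <- function(rel_abundance, temperature = tpp_gradient()) {
  if (length(rel_abundance) != length(temperature)) {
    stop("rel_abundance and temperature lengths differ", call. = FALSE)
  }
  keep <- is.finite(rel_abundance) & is.finite(temperature)
  y <- rel_abundance[keep]
  tt <- temperature[keep]
  if (length(y) < 5L) {
    stop("at least 5 finite points are required to fit a melting curve (got ",
         length(y), ")", call. = FALSE)
  }

  p0 <- min(max(0, min(y)), 0.9)
  half <- (1 + p0) / 2
  t_half <- tt[which.min(abs(y - half))]
  starts <- list(
    c(a = 10 * t_half, b = 10, plateau = p0),
    c(a = 25 * t_half, b = 25, plateau = p0),
    c(a = 50 * t_half, b = 50, plateau = min(p0 + 0.05, 0.9))
  )
  # the model is linear on the logit scale in 1/T: regressing
  # logit((y - plateau)/(1 - plateau)) on 1/T gives a near-exact start
  frac <- pmin(pmax((y - p0) / (1 - p0), 0.01), 0.99)
  lf <- stats::lm.fit(cbind(1, 1 / tt), stats::qlogis(frac))$coefficients
  if (all(is.finite(lf)) && lf[2] > 0) {
    starts <- c(list(c(a = unname(lf[2]), b = unname(-lf[1]), plateau = p0)),
                starts)
  }

  fit <- NULL
  best <- Inf
  for (st in starts) {
    st["b"] <- max(st["b"], 1e-6)
    cand <- tryCatch(
      suppressWarnings(minpack.lm::nlsLM(
        y ~ (1 - plateau) / (1 + exp(-(a / tt - b))) + plateau,
        start = as.list(st),
        lower = c(a = 1e-8, b = 1e-8, plateau = 0),
        upper = c(a = Inf, b = Inf, plateau = 1 - 1e-9),
        control = minpack.lm::nls.lm.control(maxiter = 200)
      )),
      error = function(e) NULL
    )
    if (!is.null(cand)) {
      dev <- sum(stats::residuals(cand)^2)
      if (dev < best) {
        best <- dev
        fit <- cand
      }
      if (best < 1e-10) break
    }
  }

  if (is.null(fit)) {
    out <- list(a = NA_real_, b = NA_real_, plateau = NA_real_,
                r2 = NA_real_, tm = NA_real_, converged = FALSE,
                n_points = length(y))
    class(out) <- "melt_fit"
    return(out)
  }

  cf <- stats::coef(fit)
  ss_res <- sum(stats::residuals(fit)^2)
  ss_tot <- sum((y - mean(y))^2)
  r2 <- if (ss_tot > 0) 1 - ss_res / ss_tot else NA_real_
  out <- list(
    a = unname(cf["a"]), b = unname(cf["b"]), plateau = unname(cf["plateau"]),
    r2 = r2,
    tm = melting_point(cf["a"], cf["b"], cf["plateau"]),
    converged = isTRUE(fit$convInfo$isConv),
    n_points = length(y)
  )
  class(out) <- "melt_fit"
  out
}

#' @export
print.melt_fit <- function(x, ...) {
  cat(sprintf(
    "melt_fit: a=%.4g b=%.4g plateau=%.4g  R2=%.4f  Tm=%s  converged=%s (n=%d)\n",
    x$a, x$b, x$plateau, x$r2,
    if (is.na(x$tm)) "undefined" else sprintf("%.2f C", x$tm),
    x$converged, x$n_points))
  invisible(x)
}

#' Fit melting curves for every series of a long-format TPP table
#'
#' Splits a long TPP table into per-protein, per-condition, per-replicate
#' series, reference-normalizes each (series whose reference intensity is
#' missing or non-positive are excluded and reported), and fits the
#' denaturation sigmoid.
#'
#' @param tpp long-format data frame with columns `protein_id`, `condition`,
#'   `replicate`, `temperature`, `rel_abundance` (see
#'   [simulate_melting_dataset()] for the layout).
#' @param gradient temperature gradient the series are aligned to.
#' @param normalize re-normalize each series to its reference temperature
#'   (the default; a no-op on already normalized data).
#' @return Data frame with one row per fitted series: `protein_id`,
#'   `condition`, `replicate`, `a`, `b`, `plateau`, `r2`, `tm`, `converged`.
#'   Excluded series (bad reference, too few points) are recorded in the
#'   `"excluded"` attribute with a reason.
#' @export
fit_melting_dataset <- function(tpp, gradient = tpp_gradient(),
                                normalize = TRUE) {
  validate_gradient(gradient)
  need <- c("protein_id", "condition", "replicate", "temperature",
            "rel_abundance")
  miss <- setdiff(need, names(tpp))
  if (length(miss)) {
    stop("tpp table is missing columns: ", paste(miss, collapse = ", "),
         call. = FALSE)
  }
  key <- interaction(tpp$protein_id, tpp$condition, tpp$replicate,
                     drop = TRUE, lex.order = TRUE)
  pieces <- split(tpp, key)
  rows <- vector("list", length(pieces))
  excluded <- list()
  for (i in seq_along(pieces)) {
    sl <- pieces[[i]]
    ord <- order(sl$temperature)
    y <- sl$rel_abundance[ord]
    tt <- sl$temperature[ord]
    res <- tryCatch({
      if (normalize) y <- normalize_to_reference(y)
      fit_melting_curve(y, tt)
    }, error = function(e) conditionMessage(e))
    id <- list(protein_id = sl$protein_id[1L], condition = sl$condition[1L],
               replicate = sl$replicate[1L])
    if (is.character(res)) {
      excluded[[length(excluded) + 1L]] <-
        data.frame(id, reason = res, stringsAsFactors = FALSE)
      next
    }
    rows[[i]] <- data.frame(
      id, a = res$a, b = res$b, plateau = res$plateau, r2 = res$r2,
      tm = res$tm, converged = res$converged, stringsAsFactors = FALSE)
  }
  out <- do.call(rbind, rows[!vapply(rows, is.null, logical(1))])
  rownames(out) <- NULL
  attr(out, "excluded") <-
    if (length(excluded)) do.call(rbind, excluded) else NULL
  out
}
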