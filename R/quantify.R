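#' Summarize peptide areas into the top3 protein metric
#'
#' The top3 metric for a protein is the average of its three highest peptide
#' areas in a sample. Proteins with fewer than three quantified peptides are
#' averaged over what is available.
#'
#' @param peptide_areas data.frame with columns `protein_id`, `sample_id`,
#'   `area` (positive peptide peak areas).
#' @return data.frame with columns `protein_id`, `sample_id`, `top3`.
#' @export
top3_summarize <- function(peptide_areas) {
  stopifnot(is.data.frame(peptide_areas),
            all(c("protein_id", "sample_id", "area") %in% names(peptide_areas)))
  if (any(peptide_areas$area <= 0, na.rm = TRUE)) {
    stop("peptide areas must be strictly positive")
  }
  key <- interaction(peptide_areas$protein_id, peptide_areas$sample_id, drop = TRUE)
  top3 <- tapply(peptide_areas$area, key, function(a) {
    mean(sort(a, decreasing = TRUE)[seq_len(min(3L, length(a)))])
  })
  parts <- do.call(rbind, strsplit(names(top3), ".", fixed = TRUE))
  data.frame(protein_id = parts[, 1], sample_id = parts[, 2],
             top3 = as.numeric(top3), row.names = NULL)
}

#' Calibrate the top3 metric against a UPS2 spike-in standard
#'
#' Fits ordinary least squares of log10(amount) on log10(top3) over the
#' spiked-in standard proteins, giving the calibration
#' `log10(A) = a + b * log10(top3)` that converts top3 intensities to
#' absolute loaded amounts on the scale of the standard.
#'
#' @param standard_amounts numeric vector of known spiked amounts (> 0).
#' @param standard_top3 numeric vector of measured top3 intensities (> 0),
#'   same length as `standard_amounts`.
#' @return An object of class `ups2_calibration` with elements
#'   `intercept_a`, `slope_b`, `fit_r2`, `n_points`.
#' @examples
#' fit_ups2_calibration(c(1, 10, 100), c(1, 10, 100))
#' @export
fit_ups2_calibration <- function(standard_amounts, standard_top3) {
  if (length(standard_amounts) != length(standard_top3)) {
    stop("standard_amounts and standard_top3 must have the same length")
  }
  keep <- !is.na(standard_amounts) & !is.na(standard_top3)
  standard_amounts <- standard_amounts[keep]
  standard_top3 <- standard_top3[keep]
  if (length(standard_amounts) < 3L) {
    stop("at least 3 standards are required to calibrate")
  }
  bad <- which(standard_amounts <= 0 | standard_top3 <= 0)
  if (length(bad)) {
    stop("nonpositive value in standards at position(s): ",
         paste(bad, collapse = ", "))
  }
  la <- log10(standard_amounts)
  fit <- stats::lm(la ~ log10(standard_top3))
  sst <- sum((la - mean(la)) ^ 2)
  r2 <- if (sst == 0) NA_real_ else 1 - sum(stats::resid(fit) ^ 2) / sst
  out <- list(intercept_a = unname(stats::coef(fit)[1]),
              slope_b = unname(stats::coef(fit)[2]),
              fit_r2 = r2,
              n_points = length(standard_amounts))
  if (!is.finite(out$slope_b) || out$slope_b == 0) {
    stop("degenerate calibration: slope is zero or non-finite")
  }
  class(out) <- "ups2_calibration"
  out
}

#' @export
print.ups2_calibration <- function(x, ...) {
  cat(sprintf("UPS2 top3 calibration: log10(A) = %.4f + %.4f * log10(top3)\n",
              x$intercept_a, x$slope_b))
  cat(sprintf("  r^2 = %.4f on %d standards\n", x$fit_r2, x$n_points))
  invisible(x)
}

#' Apply a top3 calibration to a protein intensity table
#'
#' Converts observed top3 intensities into calibrated loaded amounts
#' `A = 10^(a + b * log10(top3))`. Missing values stay missing; zero
#' intensities are unquantifiable and are left missing with a warning.
#'
#' @param top3_table numeric matrix, proteins x samples, of top3 intensities.
#' @param model a `ups2_calibration` object (or a list of one per sample,
#'   named by the sample columns of `top3_table`).
#' @return numeric matrix of calibrated amounts, same dimensions and names.
#' @export
apply_calibration <- function(top3_table, model) {
  top3_table <- as.matrix(top3_table)
  zero <- which(!is.na(top3_table) & top3_table == 0)
  if (length(zero)) {
    warning(length(zero), " zero intensities flagged unquantifiable, left missing")
    top3_table[zero] <- NA_real_
  }
  if (any(top3_table < 0, na.rm = TRUE)) stop("negative top3 intensities")
  if (inherits(model, "ups2_calibration")) {
    return(10 ^ (model$intercept_a + model$slope_b * log10(top3_table)))
  }
  stopifnot(is.list(model), !is.null(colnames(top3_table)),
            all(colnames(top3_table) %in% names(model)))
  out <- top3_table
  for (s in colnames(top3_table)) {
    m <- model[[s]]
    out[, s] <- 10 ^ (m$intercept_a + m$slope_b * log10(top3_table[, s]))
  }
  out
}

#' Convert calibrated amounts to mass concentrations per gram dry weight
#'
#' Normalizes amounts within each sample and scales by the total protein
#' budget gamma, so that `C_i = gamma * A_i / sum_j A_j`. Each sample's
#' concentrations sum exactly to gamma.
#'
#' @param amounts numeric matrix, proteins x samples, of calibrated amounts.
#' @param gamma total protein concentration per unit dry weight, in
#'   micromole per gram dry weight. Default 13.94.
#' @return numeric matrix of concentrations (umol/gDW); missing entries
#'   contribute zero to the sample total.
#' @export
to_mass_concentration <- function(amounts, gamma = 13.94) {
  amounts <- as.matrix(amounts)
  totals <- colSums(amounts, na.rm = TRUE)
  empty <- colnames(amounts)[totals <= 0 | colSums(!is.na(amounts)) == 0]
  if (length(empty)) {
    stop("sample(s) with no positive amounts: ", paste(empty, collapse = ", "))
  }
  sweep(amounts, 2, totals, "/") * gamma
}

#' Per-sample protein mass fractions
#'
#' Normalizes each sample so quantified proteins sum to 1. This is the
#' representation consumed by the compendium and allocation stages;
#' gamma-scaled concentrations are for reporting.
#'
#' @inheritParams to_mass_concentration
#' @return numeric matrix of fractions summing to 1 per sample.
#' @export
mass_fractions <- function(amounts) {
  to_mass_concentration(amounts, gamma = 1)
}

#' Calibrate a multi-sample top3 table against per-sample UPS2 standards
#'
#' Each experimental sample carries its own UPS2 spike, so calibration is
#' fit per sample by default; `pooled = TRUE` fits a single regression on
#' all standards at once. Samples whose per-sample fit has r^2 below
#' `r2_warn` are reported with a warning (they are retained).
#'
#' @param top3_table proteins x samples matrix of top3 intensities.
#' @param standards data.frame with columns `protein_id`, `sample_id`,
#'   `spiked_amount`, `top3` for the UPS2 proteins in each sample.
#' @param pooled fit one calibration across all samples instead.
#' @param r2_warn warn when a per-sample calibration r^2 falls below this.
#' @return list with `amounts` (calibrated matrix), `calibrations`
#'   (per-sample list or single model), and `report` (data.frame of a, b,
#'   r2, n per sample).
#' @export
calibrate_proteome <- function(top3_table, standards, pooled = FALSE,
                               r2_warn = 0.9) {
  stopifnot(all(c("sample_id", "spiked_amount", "top3") %in% names(standards)))
  if (pooled) {
    model <- fit_ups2_calibration(standards$spiked_amount, standards$top3)
    report <- data.frame(sample_id = "pooled", a = model$intercept_a,
                         b = model$slope_b, r2 = model$fit_r2,
                         n = model$n_points)
    return(list(amounts = apply_calibration(top3_table, model),
                calibrations = model, report = report))
  }
  samples <- colnames(top3_table)
  missing <- setdiff(samples, unique(standards$sample_id))
  if (length(missing)) {
    stop("no UPS2 standards for sample(s): ", paste(missing, collapse = ", "))
  }
  models <- lapply(samples, function(s) {
    std <- standards[standards$sample_id == s, ]
    fit_ups2_calibration(std$spiked_amount, std$top3)
  })
  names(models) <- samples
  low <- samples[vapply(models, function(m) m$fit_r2, 0) < r2_warn]
  if (length(low)) {
    warning("calibration r^2 below ", r2_warn, " for: ",
            paste(low, collapse = ", "))
  }
  report <- data.frame(
    sample_id = samples,
    a = vapply(models, function(m) m$intercept_a, 0),
    b = vapply(models, function(m) m$slope_b, 0),
    r2 = vapply(models, function(m) m$fit_r2, 0),
    n = vapply(models, function(m) m$n_points, 0L),
    row.names = NULL)
  list(amounts = apply_calibration(top3_table, models),
       calibrations = models, report = report)
}
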