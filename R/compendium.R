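#' Drop features with low detection coverage
#'
#' Removes features observed (non-missing) in strictly less than
#' `min_fraction` of the samples of the concatenated table. Run before
#' imputation, on the full multi-batch matrix.
#'
#' @param raw features x samples numeric matrix, possibly with NAs.
#' @param min_fraction minimum fraction of samples a feature must be
#'   observed in to be retained (default 0.5).
#' @return the matrix restricted to retained features.
#' @export
filter_low_coverage <- function(raw, min_fraction = 0.5) {
  stopifnot(min_fraction > 0, min_fraction <= 1)
  raw <- as.matrix(raw)
  coverage <- rowMeans(!is.na(raw))
  keep <- coverage >= min_fraction
  if (!any(keep)) {
    stop("no features pass coverage filter (", sum(keep), " of ", nrow(raw), ")")
  }
  raw[keep, , drop = FALSE]
}

#' Impute missing abundances with the global minimum
#'
#' Every missing cell is replaced by the minimum observed abundance of the
#' whole matrix, reflecting that undetected proteins sit at or below the
#' detection floor.
#'
#' @param matrix numeric matrix with at least one observed value.
#' @return matrix with no missing values; attribute `global_min` records
#'   the value used.
#' @export
impute_missing_min <- function(matrix) {
  matrix <- as.matrix(matrix)
  if (all(is.na(matrix))) stop("no observed values to impute from")
  gmin <- min(matrix, na.rm = TRUE)
  matrix[is.na(matrix)] <- gmin
  attr(matrix, "global_min") <- gmin
  matrix
}

#' Log-transform per-sample fractions to log2(PPM + 1)
#'
#' Scales fractions by one million (parts per million) and applies
#' `log2(PPM + 1)`, the same convention as the log2(TPM + 1)
#' transcriptome transform.
#'
#' @param matrix numeric matrix of per-sample fractions (values >= 0).
#' @return matrix of log2(1e6 * fraction + 1) values.
#' @export
log_transform_ppm <- function(matrix) {
  matrix <- as.matrix(matrix)
  if (any(matrix < 0, na.rm = TRUE)) stop("fractions must be non-negative")
  log2(1e6 * matrix + 1)
}

replicate_groups <- function(metadata) {
  split(metadata$sample_id, metadata$condition_id)
}

#' Drop replicate samples with poor concordance
#'
#' For each condition, computes pairwise squared Pearson correlation (R^2)
#' between its replicate columns. Two-member groups below `r2_min` are
#' dropped entirely; in larger groups, individual samples are dropped
#' (worst offender first) until all remaining pairs meet the threshold.
#' Singleton conditions pass through untouched.
#'
#' @param matrix features x samples numeric matrix (log scale by default
#'   convention; pass pre-log values to assess concordance on raw scale).
#' @param metadata data.frame with columns `sample_id`, `condition_id`.
#' @param r2_min minimum pairwise squared Pearson correlation (default 0.9).
#' @return list with `matrix`, `metadata` (filtered), and `dropped`
#'   (character vector of removed sample ids).
#' @export
filter_replicates <- function(matrix, metadata, r2_min = 0.9) {
  matrix <- as.matrix(matrix)
  stopifnot(all(metadata$sample_id %in% colnames(matrix)))
  dropped <- character()
  for (grp in replicate_groups(metadata)) {
    grp <- intersect(grp, colnames(matrix))
    while (length(grp) >= 2L) {
      r2 <- stats::cor(matrix[, grp, drop = FALSE]) ^ 2
      diag(r2) <- NA
      if (min(r2, na.rm = TRUE) >= r2_min) break
      if (length(grp) == 2L) {
        dropped <- c(dropped, grp)
        grp <- character()
      } else {
        # drop the sample least concordant with the rest of its group
        worst <- grp[which.min(rowMeans(r2, na.rm = TRUE))]
        dropped <- c(dropped, worst)
        grp <- setdiff(grp, worst)
      }
    }
  }
  keep <- setdiff(colnames(matrix), dropped)
  list(matrix = matrix[, keep, drop = FALSE],
       metadata = metadata[metadata$sample_id %in% keep, , drop = FALSE],
       dropped = dropped)
}

#' Center each batch on its reference-condition profile
#'
#' Subtracts, within each batch, the mean log-scale profile of that batch's
#' reference-condition samples from every sample of the batch. A shared
#' reference condition across batches thereby removes batch offsets while
#' preserving within-batch differences exactly.
#'
#' @param matrix features x samples numeric matrix (log scale).
#' @param metadata data.frame with columns `sample_id`, `is_reference`,
#'   and optionally `batch` (a single batch is assumed if absent).
#' @return centered matrix.
#' @export
center_to_reference <- function(matrix, metadata) {
  matrix <- as.matrix(matrix)
  if (is.null(metadata$batch)) metadata$batch <- "batch1"
  md <- metadata[metadata$sample_id %in% colnames(matrix), , drop = FALSE]
  out <- matrix
  for (b in unique(md$batch)) {
    in_batch <- md$sample_id[md$batch == b]
    refs <- md$sample_id[md$batch == b & as.logical(md$is_reference)]
    if (!length(refs)) stop("batch without reference samples: ", b)
    ref_profile <- rowMeans(matrix[, refs, drop = FALSE])
    out[, in_batch] <- matrix[, in_batch, drop = FALSE] - ref_profile
  }
  out
}

#' Compile a quality-controlled omics compendium
#'
#' Runs the fixed pipeline: coverage filter, minimum imputation, per-sample
#' renormalization to mass fractions, log2(PPM+1) transform, replicate
#' concordance filter, reference centering. The input is a raw per-sample
#' fraction (or abundance) table possibly containing missing values.
#'
#' @param raw features x samples numeric matrix of abundances or fractions.
#' @param metadata sample metadata (`sample_id`, `condition_id`,
#'   `is_reference`, optional `batch`).
#' @param min_coverage coverage threshold (see [filter_low_coverage()]).
#' @param r2_min replicate concordance threshold (see [filter_replicates()]).
#' @param renormalize renormalize each sample to fractions after imputation
#'   (TRUE for abundance inputs; fractions are renormalized regardless after
#'   feature removal).
#' @return object of class `omics_compendium`: list with `values` (centered
#'   log matrix, no missing values), `fractions` (raw-scale mass fractions
#'   of the retained features/samples), `metadata`, and `report`.
#' @export
compile_compendium <- function(raw, metadata, min_coverage = 0.5,
                               r2_min = 0.9, renormalize = TRUE) {
  raw <- as.matrix(raw)
  stopifnot(!is.null(rownames(raw)), !is.null(colnames(raw)))
  if (anyDuplicated(rownames(raw)) || anyDuplicated(colnames(raw))) {
    stop("feature and sample identifiers must be unique")
  }
  if (!any(as.logical(metadata$is_reference))) {
    stop("metadata flags no reference condition")
  }
  n0 <- nrow(raw)
  filt <- filter_low_coverage(raw, min_coverage)
  imp <- impute_missing_min(filt)
  gmin <- attr(imp, "global_min")
  frac <- if (renormalize) mass_fractions(imp) else imp
  logm <- log_transform_ppm(frac)
  rep_filt <- filter_replicates(logm, metadata, r2_min)
  if (ncol(rep_filt$matrix) == 0L) {
    stop("replicate filter removed every sample (r2_min = ", r2_min, ")")
  }
  centered <- center_to_reference(rep_filt$matrix, rep_filt$metadata)
  frac <- frac[, colnames(centered), drop = FALSE]
  # re-close fractions after any sample removal (feature set unchanged)
  frac <- sweep(frac, 2, colSums(frac), "/")
  structure(list(
    values = centered,
    fractions = frac,
    metadata = rep_filt$metadata,
    report = list(features_in = n0, features_kept = nrow(centered),
                  samples_in = ncol(raw), samples_kept = ncol(centered),
                  samples_dropped = rep_filt$dropped, global_min = gmin,
                  min_coverage = min_coverage, r2_min = r2_min)
  ), class = "omics_compendium")
}

#' @export
print.omics_compendium <- function(x, ...) {
  r <- x$report
  cat(sprintf("omics compendium: %d features x %d samples (log2(PPM+1), reference-centered)\n",
              nrow(x$values), ncol(x$values)))
  cat(sprintf("  %d/%d features passed coverage >= %.2f; %d/%d samples kept (replicate R^2 >= %.2f)\n",
              r$features_kept, r$features_in, r$min_coverage,
              r$samples_kept, r$samples_in, r$r2_min))
  invisible(x)
}

#' Replicate versus random-pair correlation distributions
#'
#' Returns Pearson correlations for all within-condition replicate pairs and
#' for `n_random_pairs` random pairs of samples from different conditions,
#' the ingredients of a replicate-concordance histogram.
#'
#' @param matrix features x samples numeric matrix.
#' @param metadata data.frame with `sample_id`, `condition_id`.
#' @param n_random_pairs number of random cross-condition pairs to draw.
#' @param seed integer seed for the random pairs.
#' @return list with numeric vectors `replicate` and `random`.
#' @export
replicate_correlation_histogram <- function(matrix, metadata,
                                            n_random_pairs = 100L,
                                            seed = 1L) {
  matrix <- as.matrix(matrix)
  groups <- replicate_groups(metadata)
  rep_r <- numeric()
  for (grp in groups) {
    grp <- intersect(grp, colnames(matrix))
    if (length(grp) < 2L) next
    cm <- stats::cor(matrix[, grp, drop = FALSE])
    rep_r <- c(rep_r, cm[upper.tri(cm)])
  }
  rand_r <- numeric(0)
  if (n_random_pairs > 0L) {
    set.seed(seed)
    cond <- stats::setNames(metadata$condition_id, metadata$sample_id)
    ids <- intersect(metadata$sample_id, colnames(matrix))
    rand_r <- vapply(seq_len(n_random_pairs), function(i) {
      repeat {
        pair <- sample(ids, 2L)
        if (cond[pair[1]] != cond[pair[2]]) break
      }
      stats::cor(matrix[, pair[1]], matrix[, pair[2]])
    }, 0)
  }
  list(replicate = rep_r, random = rand_r)
}
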