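#' Subset a compendium to shared features and matched conditions
#'
#' The transcriptome decomposition used for cross-omics comparison is
#' recomputed on the features covered by both layers and on the samples
#' whose conditions appear in both compendia. This helper performs that
#' subsetting.
#'
#' @param matrix features x samples numeric matrix.
#' @param metadata sample metadata with `sample_id`, `condition_id`.
#' @param features feature identifiers to keep.
#' @param conditions condition identifiers to keep.
#' @return list with `matrix` and `metadata` restricted accordingly.
#' @export
matched_subset <- function(matrix, metadata, features, conditions) {
  matrix <- as.matrix(matrix)
  keep_f <- intersect(rownames(matrix), features)
  md <- metadata[metadata$condition_id %in% conditions &
                   metadata$sample_id %in% colnames(matrix), , drop = FALSE]
  list(matrix = matrix[keep_f, md$sample_id, drop = FALSE], metadata = md)
}

#' Average activities over replicates within each condition
#'
#' @param A components x samples activity matrix.
#' @param metadata sample metadata with `sample_id`, `condition_id`.
#' @return components x conditions matrix of replicate means.
#' @export
condition_average <- function(A, metadata) {
  A <- as.matrix(A)
  md <- metadata[metadata$sample_id %in% colnames(A), , drop = FALSE]
  conds <- unique(md$condition_id)
  out <- vapply(conds, function(cd) {
    rowMeans(A[, md$sample_id[md$condition_id == cd], drop = FALSE])
  }, numeric(nrow(A)))
  out <- matrix(out, nrow = nrow(A), dimnames = list(rownames(A), conds))
  out
}

#' Match proteome components to transcriptome components by gene weights
#'
#' Computes the Pearson correlation of every pair of component weight
#' vectors restricted to the features shared by the two decompositions; a
#' pair is matched when |r| is at least `r_min`. A proteome component may
#' match several transcriptome components (a lumped module).
#'
#' @param M_t features x components weight matrix of the transcriptome
#'   decomposition (or an `ica_decomposition`).
#' @param M_p same for the proteome decomposition.
#' @param r_min correlation-magnitude threshold (default 0.25).
#' @return data.frame of class `match_table` with columns `pi`, `ti`, `r`
#'   (signed correlation over shared features), one row per matched pair,
#'   sorted by |r| within `pi`.
#' @export
match_components <- function(M_t, M_p, r_min = 0.25) {
  if (inherits(M_t, "ica_decomposition")) M_t <- M_t$M
  if (inherits(M_p, "ica_decomposition")) M_p <- M_p$M
  shared <- intersect(rownames(M_t), rownames(M_p))
  if (length(shared) < 3L) {
    stop("fewer than 3 shared features between the decompositions")
  }
  R <- stats::cor(M_p[shared, , drop = FALSE], M_t[shared, , drop = FALSE])
  hits <- which(abs(R) >= r_min, arr.ind = TRUE)
  out <- data.frame(pi = colnames(M_p)[hits[, 1]],
                    ti = colnames(M_t)[hits[, 2]],
                    r = R[hits])
  out <- out[order(out$pi, -abs(out$r)), , drop = FALSE]
  rownames(out) <- NULL
  attr(out, "shared_features") <- shared
  class(out) <- c("match_table", "data.frame")
  out
}

#' Recall of a matched iModulon pair
#'
#' `both` is the intersection of the two member sets; each side's recall is
#' |both| divided by that side's member count. The quadrant label uses a
#' 0.5/0.5 split of the two recalls.
#'
#' @param pi_members,ti_members character vectors of member features over
#'   the shared feature universe.
#' @return list with `pi_recall`, `ti_recall`, `both` (character vector),
#'   and `quadrant`.
#' @export
compute_recall <- function(pi_members, ti_members) {
  both <- intersect(pi_members, ti_members)
  pi_recall <- if (length(pi_members)) length(both) / length(pi_members) else NA_real_
  ti_recall <- if (length(ti_members)) length(both) / length(ti_members) else NA_real_
  quadrant <- if (anyNA(c(pi_recall, ti_recall))) {
    "undefined"
  } else {
    paste0(if (pi_recall >= 0.5) "high-pi" else "low-pi", "/",
           if (ti_recall >= 0.5) "high-ti" else "low-ti")
  }
  list(pi_recall = pi_recall, ti_recall = ti_recall, both = both,
       quadrant = quadrant)
}

#' Differential iModulon activity between matched components
#'
#' Replicate-averages both activity series per condition, restricts to the
#' conditions present in both layers, optionally standardizes each axis,
#' and flags conditions whose proteome activity deviates from the robust
#' cross-layer trend by more than the significance band (`band` standard
#' deviations of the deviation series). The trend is a robust (Huber)
#' line of the proteome on the transcriptome series; when the two layers
#' track each other it is the identity and the deviation reduces to the
#' plain difference of standardized activities.
#'
#' @param ti_activity named numeric vector: transcriptome component
#'   activities per sample (a row of A).
#' @param pi_activity same for the proteome component.
#' @param metadata_t,metadata_p sample metadata for each layer.
#' @param band width of the significance band, in standard deviations of
#'   the per-condition difference (default 1.5).
#' @param standardize center and scale each activity series across
#'   conditions before differencing (default TRUE). Scaling is robust
#'   (median and scaled MAD), so a handful of genuinely differential
#'   conditions does not shrink its own signal through the scale estimate.
#' @param sign_align flip the proteome series if the two series correlate
#'   negatively (component signs are arbitrary; default TRUE).
#' @return object of class `dima_result`: list with `conditions`
#'   (data.frame: condition, ti_activity, pi_activity, diff, differential,
#'   side), `correlation`, `band`.
#' @export
dima <- function(ti_activity, pi_activity, metadata_t, metadata_p,
                 band = 1.5, standardize = TRUE, sign_align = TRUE) {
  avg <- function(a, md) {
    m <- condition_average(matrix(a, nrow = 1,
                                  dimnames = list(NULL, names(a))), md)
    stats::setNames(m[1, ], colnames(m))
  }
  ti <- avg(ti_activity, metadata_t)
  pi <- avg(pi_activity, metadata_p)
  conds <- intersect(names(ti), names(pi))
  if (length(conds) < 3L) stop("fewer than 3 matched conditions")
  ti <- ti[conds]
  pi <- pi[conds]
  if (sign_align && stats::cor(ti, pi) < 0) pi <- -pi
  correlation <- stats::cor(ti, pi)
  if (standardize) {
    rs <- function(v) {
      s <- stats::mad(v)
      if (s == 0) s <- stats::sd(v)
      (v - stats::median(v)) / s
    }
    ti <- rs(ti)
    pi <- rs(pi)
  }
  trend <- tryCatch(
    stats::fitted(MASS::rlm(pi ~ ti, maxit = 50)),
    error = function(e) stats::fitted(stats::lm(pi ~ ti)))
  d <- pi - trend
  halfwidth <- band * stats::sd(d)
  differential <- abs(d) > halfwidth
  side <- ifelse(!differential, "none", ifelse(d > 0, "pi", "ti"))
  structure(list(
    conditions = data.frame(condition = conds, ti_activity = ti,
                            pi_activity = pi, diff = d,
                            differential = differential, side = side,
                            row.names = NULL),
    correlation = correlation, band = band), class = "dima_result")
}

#' @export
print.dima_result <- function(x, ...) {
  cat(sprintf("DiMA: %d matched conditions, r = %.3f, band = %.2f sd\n",
              nrow(x$conditions), x$correlation, x$band))
  cat(sprintf("  %d differential (%d transcriptome-side, %d proteome-side)\n",
              sum(x$conditions$differential),
              sum(x$conditions$side == "ti"), sum(x$conditions$side == "pi")))
  invisible(x)
}

#' Classify the regulatory dominance of a matched pair
#'
#' Among differentially activated conditions: when at least a `majority`
#' share lies on the transcriptome side (transcript signal stronger than
#' protein) and that one-sidedness is unlikely under a fair coin (exact
#' sign test at `alpha`), the pair is transcriptome-dominant; the mirror
#' case is proteome-dominant; otherwise, or with no differential
#' conditions, the pair is neutral. The sign-test guard keeps a pair with
#' only a few band exceedances scattered on both sides — the expected
#' picture under pure noise — from being called dominant.
#'
#' @param dima_result a `dima_result`.
#' @param majority required share of differential conditions on one side
#'   (default 2/3).
#' @param alpha one-sided sign-test level for the majority side of the
#'   differential conditions (default 0.05; set to 1 to disable the guard).
#' @return one of "transcriptome-dominant", "proteome-dominant", "neutral".
#' @export
classify_dominance <- function(dima_result, majority = 2 / 3, alpha = 0.05) {
  side <- dima_result$conditions$side
  diff <- side[side != "none"]
  if (!length(diff)) return("neutral")
  k <- max(sum(diff == "ti"), sum(diff == "pi"))
  p_side <- stats::pbinom(k - 1L, length(diff), 0.5, lower.tail = FALSE)
  if (p_side > alpha) return("neutral")
  if (k / length(diff) < majority) return("neutral")
  if (sum(diff == "ti") >= sum(diff == "pi")) "transcriptome-dominant"
  else "proteome-dominant"
}

#' Differential iModulon membership table for a matched pair
#'
#' Per shared feature: the two gene weights (proteome weights sign-aligned
#' so the cross-layer correlation is positive) and membership flags for
#' each side and their intersection — the data behind a DiMM scatter plot.
#'
#' @param w_t,w_p named weight vectors (columns of the two M matrices).
#' @param members_t,members_p thresholded member sets of the two components.
#' @return data.frame with columns `feature`, `ti_weight`, `pi_weight`,
#'   `in_ti`, `in_pi`, `in_both`.
#' @export
dimm_table <- function(w_t, w_p, members_t, members_p) {
  shared <- intersect(names(w_t), names(w_p))
  if (!length(shared)) stop("no shared features")
  wt <- w_t[shared]
  wp <- w_p[shared]
  if (stats::cor(wt, wp) < 0) wp <- -wp
  data.frame(feature = shared, ti_weight = unname(wt), pi_weight = unname(wp),
             in_ti = shared %in% members_t, in_pi = shared %in% members_p,
             in_both = shared %in% intersect(members_t, members_p),
             row.names = NULL)
}
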