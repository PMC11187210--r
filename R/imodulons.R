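#' D'Agostino-Pearson K-squared normality statistic
#'
#' Omnibus statistic combining the standardized skewness (D'Agostino) and
#' kurtosis (Anscombe-Glynn) z-scores, `K2 = z_skew^2 + z_kurt^2`. Large
#' values indicate heavy tails / outliers relative to a normal distribution.
#'
#' @param x numeric vector, length >= 8.
#' @return the K-squared statistic (0 for a constant vector).
#' @export
dagostino_k2 <- function(x) {
  n <- length(x)
  if (n < 8L) stop("K-squared requires at least 8 observations")
  m <- mean(x)
  m2 <- mean((x - m) ^ 2)
  if (m2 == 0) return(0)
  g1 <- mean((x - m) ^ 3) / m2 ^ 1.5
  b2 <- mean((x - m) ^ 4) / m2 ^ 2

  # skewness z-score
  Y <- g1 * sqrt((n + 1) * (n + 3) / (6 * (n - 2)))
  beta2 <- 3 * (n ^ 2 + 27 * n - 70) * (n + 1) * (n + 3) /
    ((n - 2) * (n + 5) * (n + 7) * (n + 9))
  W2 <- -1 + sqrt(2 * (beta2 - 1))
  delta <- 1 / sqrt(log(sqrt(W2)))
  alpha <- sqrt(2 / (W2 - 1))
  z1 <- delta * log(Y / alpha + sqrt((Y / alpha) ^ 2 + 1))

  # kurtosis z-score
  Eb2 <- 3 * (n - 1) / (n + 1)
  varb2 <- 24 * n * (n - 2) * (n - 3) / ((n + 1) ^ 2 * (n + 3) * (n + 5))
  xs <- (b2 - Eb2) / sqrt(varb2)
  sqrtbeta1 <- 6 * (n ^ 2 - 5 * n + 2) / ((n + 7) * (n + 9)) *
    sqrt(6 * (n + 3) * (n + 5) / (n * (n - 2) * (n - 3)))
  A <- 6 + 8 / sqrtbeta1 * (2 / sqrtbeta1 + sqrt(1 + 4 / sqrtbeta1 ^ 2))
  term <- (1 - 2 / A) / (1 + xs * sqrt(2 / (A - 4)))
  z2 <- ((1 - 2 / (9 * A)) - sign(term) * abs(term) ^ (1 / 3)) /
    sqrt(2 / (9 * A))
  z1 ^ 2 + z2 ^ 2
}

#' Threshold a component's gene weights into iModulon members
#'
#' Iterative outlier rule: while the K-squared statistic of the remaining
#' weights exceeds `cutoff`, remove the largest-magnitude weight. The
#' membership threshold is the magnitude of the last removed weight;
#' members are the features beyond it (either sign).
#'
#' The threshold is placed halfway between the magnitude of the last
#' removed weight and the largest remaining one, so every removed outlier
#' is a member. A component whose weights are already near-normal yields
#' an empty membership (threshold just above the largest magnitude).
#'
#' @param weights named numeric vector of gene weights (a column of M),
#'   length >= 10.
#' @param cutoff K-squared cutoff (default 550, the iModulon workflow
#'   convention; exposed for tuning).
#' @return list with `threshold` (magnitude cutoff) and `members`
#'   (character vector of feature names, or indices if unnamed).
#' @export
threshold_component <- function(weights, cutoff = 550) {
  stopifnot(length(weights) >= 10L)
  ids <- names(weights)
  if (is.null(ids)) ids <- as.character(seq_along(weights))
  ord <- order(abs(weights), decreasing = TRUE)
  aw <- abs(weights)[ord]
  i <- 0L
  while (length(aw) - i > 8L &&
         dagostino_k2(weights[ord][(i + 1L):length(aw)]) > cutoff) {
    i <- i + 1L
  }
  if (i == 0L) {
    return(list(threshold = max(aw) * (1 + 1e-8) + 1e-12,
                members = character(0)))
  }
  threshold <- (aw[i] + aw[i + 1L]) / 2
  list(threshold = threshold, members = ids[abs(weights) > threshold])
}

#' Hypergeometric regulator enrichment of a member set
#'
#' One-sided hypergeometric test of the overlap between an iModulon's
#' members and each regulon (restricted to the measured background), with
#' Benjamini-Hochberg adjustment across regulons. Optionally also tests
#' pairwise unions of regulons, to capture modules governed jointly by two
#' regulators.
#'
#' @param members character vector of member features (subset of background).
#' @param regulon_db named list mapping regulator name to its gene set, or a
#'   two-column data.frame (`regulator`, `gene`).
#' @param background character vector of all measured features.
#' @param include_pairs also test unions of each pair of regulons.
#' @return data.frame sorted by adjusted p-value with columns `regulator`,
#'   `pvalue`, `adjusted_pvalue`, `precision`, `recall`, `overlap`; the
#'   overlapping genes are in the list column `overlap_genes`.
#' @export
enrich_regulators <- function(members, regulon_db, background,
                              include_pairs = FALSE) {
  if (is.data.frame(regulon_db)) {
    regulon_db <- split(regulon_db$gene, regulon_db$regulator)
  }
  empty <- data.frame(regulator = character(0), pvalue = numeric(0),
                      adjusted_pvalue = numeric(0), precision = numeric(0),
                      recall = numeric(0), overlap = integer(0))
  if (!length(members)) return(empty)
  stopifnot(all(members %in% background))
  sets <- lapply(regulon_db, intersect, background)
  sets <- sets[vapply(sets, length, 0L) > 0L]
  if (include_pairs && length(sets) > 1L) {
    prs <- utils::combn(names(sets), 2L, simplify = FALSE)
    for (p in prs) {
      sets[[paste(p, collapse = "/")]] <- union(sets[[p[1]]], sets[[p[2]]])
    }
  }
  if (!length(sets)) return(empty)
  N <- length(background)
  n <- length(members)
  rows <- lapply(names(sets), function(rg) {
    K <- length(sets[[rg]])
    ov <- intersect(members, sets[[rg]])
    x <- length(ov)
    p <- stats::phyper(x - 1L, K, N - K, n, lower.tail = FALSE)
    list(regulator = rg, pvalue = p, precision = x / n, recall = x / K,
         overlap = x, overlap_genes = ov)
  })
  out <- data.frame(
    regulator = vapply(rows, `[[`, "", "regulator"),
    pvalue = vapply(rows, `[[`, 0, "pvalue"),
    precision = vapply(rows, `[[`, 0, "precision"),
    recall = vapply(rows, `[[`, 0, "recall"),
    overlap = vapply(rows, `[[`, 0L, "overlap"))
  out$adjusted_pvalue <- stats::p.adjust(out$pvalue, method = "BH")
  out$overlap_genes <- lapply(rows, `[[`, "overlap_genes")
  out <- out[order(out$adjusted_pvalue, out$pvalue), c(
    "regulator", "pvalue", "adjusted_pvalue", "precision", "recall",
    "overlap", "overlap_genes")]
  rownames(out) <- NULL
  out
}

#' Characterize decomposition components as iModulons
#'
#' Applies weight thresholding to every component, runs regulator
#' enrichment when a regulon database is supplied, and assigns a category:
#' `regulatory` when the best adjusted enrichment p-value passes the
#' cutoff, `technical/single-gene` for memberships of at most one feature,
#' curated labels (`biological`, `genomic`, custom names) when a curation
#' table is supplied, and `uncharacterized` otherwise.
#'
#' @param decomp an `ica_decomposition`.
#' @param regulon_db regulator to gene-set mapping (list or two-column
#'   data.frame), or NULL to skip enrichment.
#' @param adj_p_cutoff adjusted p-value cutoff for `regulatory` (default 1e-3).
#' @param k2_cutoff threshold for [threshold_component()].
#' @param curation optional data.frame with columns `component_index`,
#'   `category`, `name` overriding automatic labels.
#' @param include_pairs test pairwise regulon unions in enrichment.
#' @return object of class `imodulon_set`: a list of iModulons, each with
#'   `component_index`, `name`, `weights`, `threshold`, `members`,
#'   `category`, `enrichment`, `explained_variance`.
#' @export
characterize_components <- function(decomp, regulon_db = NULL,
                                    adj_p_cutoff = 1e-3, k2_cutoff = 550,
                                    curation = NULL, include_pairs = FALSE) {
  background <- rownames(decomp$M)
  ims <- lapply(seq_len(ncol(decomp$M)), function(j) {
    w <- decomp$M[, j]
    th <- threshold_component(w, cutoff = k2_cutoff)
    enr <- NULL
    category <- "uncharacterized"
    name <- colnames(decomp$M)[j]
    if (length(th$members) <= 1L) {
      category <- "technical/single-gene"
    } else if (!is.null(regulon_db)) {
      enr <- enrich_regulators(th$members, regulon_db, background,
                               include_pairs = include_pairs)
      if (nrow(enr) && enr$adjusted_pvalue[1] <= adj_p_cutoff) {
        category <- "regulatory"
        name <- enr$regulator[1]
      }
    }
    if (!is.null(curation)) {
      cur <- curation[curation$component_index == j, , drop = FALSE]
      if (nrow(cur)) {
        if (!is.na(cur$category[1])) category <- cur$category[1]
        if (!is.null(cur$name) && !is.na(cur$name[1])) name <- cur$name[1]
      }
    }
    list(component_index = j, name = name, weights = w,
         threshold = th$threshold, members = th$members,
         category = category, enrichment = enr,
         explained_variance = decomp$component_ev[j])
  })
  structure(ims, class = "imodulon_set")
}

#' @export
print.imodulon_set <- function(x, ...) {
  cat(sprintf("iModulon set: %d components\n", length(x)))
  print(as.data.frame(x))
  invisible(x)
}

#' @export
as.data.frame.imodulon_set <- function(x, ...) {
  data.frame(
    component = vapply(x, `[[`, 0L, "component_index"),
    name = vapply(x, `[[`, "", "name"),
    category = vapply(x, `[[`, "", "category"),
    n_members = vapply(x, function(i) length(i$members), 0L),
    threshold = vapply(x, `[[`, 0, "threshold"),
    explained_variance = vapply(x, `[[`, 0, "explained_variance"),
    best_regulator = vapply(x, function(i) {
      if (is.null(i$enrichment) || !nrow(i$enrichment)) NA_character_
      else i$enrichment$regulator[1]
    }, ""),
    row.names = NULL)
}

#' Mass-fraction invariance statistics in and out of iModulons
#'
#' For every protein, computes the mean mass fraction and coefficient of
#' variation (CV = sd/mean) across samples on the raw fraction scale, then
#' partitions proteins into those inside the union of iModulon memberships
#' and those outside. Proteins with CV below the cutoff are invariant.
#'
#' @param fractions proteins x samples matrix of raw mass fractions
#'   (columns sum to 1).
#' @param member_union character vector: union of iModulon member proteins.
#' @param cv_cutoff invariance cutoff (default 1).
#' @param strict use CV < cutoff (TRUE, compendium-statistics convention)
#'   or CV <= cutoff (FALSE, allocation-treemap convention).
#' @return list with the per-protein data.frame `proteins` (mean, cv,
#'   in_imodulon, invariant) and a two-row `summary` data.frame per
#'   partition: n, n_invariant, fraction_invariant, mass_share,
#'   median_mean_fraction.
#' @export
invariance_stats <- function(fractions, member_union, cv_cutoff = 1.0,
                             strict = TRUE) {
  fractions <- as.matrix(fractions)
  mu <- rowMeans(fractions)
  sdv <- apply(fractions, 1, stats::sd)
  zero <- mu == 0
  if (any(zero)) {
    message(sum(zero), " zero-mean protein(s) excluded (CV undefined)")
  }
  cv <- ifelse(zero, NA_real_, sdv / mu)
  inv <- if (strict) cv < cv_cutoff else cv <= cv_cutoff
  prot <- data.frame(protein = rownames(fractions), mean_fraction = mu,
                     cv = cv, in_imodulon = rownames(fractions) %in% member_union,
                     invariant = inv, row.names = NULL)
  prot <- prot[!zero, , drop = FALSE]
  parts <- split(prot, prot$in_imodulon)
  summ <- do.call(rbind, lapply(names(parts), function(k) {
    p <- parts[[k]]
    data.frame(partition = if (k == "TRUE") "in_imodulon" else "not_in_imodulon",
               n = nrow(p), n_invariant = sum(p$invariant),
               fraction_invariant = mean(p$invariant),
               mass_share = sum(p$mean_fraction) / sum(prot$mean_fraction),
               median_mean_fraction = stats::median(p$mean_fraction))
  }))
  rownames(summ) <- NULL
  list(proteins = prot, summary = summ)
}
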