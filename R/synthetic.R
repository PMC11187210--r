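# Seeded generator of matched transcriptome/proteome compendia with planted
# module structure: sparse gene-weight modules with heavy-tailed (Laplace)
# activities for ICA identifiability, proteome modules that may lump two
# transcriptome modules, per-module activity-to-mass-fraction mapping laws
# (linear / exponential / broken line), post-transcriptional dominance
# perturbations acting on the protein layer only, top-abundance proteome
# coverage, replicate noise, and a common reference condition.

rlaplace <- function(n, scale = 1) {
  stats::rexp(n, 1 / scale) - stats::rexp(n, 1 / scale)
}

default_sim_config <- function() {
  list(
    sparsity_range = c(0.01, 0.03),   # module size as fraction of genes
    weight_range = c(0.5, 1),         # nonzero weight magnitudes pre-norm
    activity_scale = 2,               # Laplace scale of module activities
    n_lumped = 1L,                    # pi modules that union 2 ti modules
    coverage_fraction = 1 / 3,        # proteome-detected share of genes
    sigma_rep = 0.02,                 # replicate noise sd (log2 scale)
    baseline_mean = 7, baseline_sd = 1.5,  # transcript baseline (log2)
    mapping_families = c("linear", "exponential", "broken_line"),
    linear_params = c(intercept = 0.02, slope = 0.004),
    exponential_params = c(offset = 0.01, scale = 0.005, rate = 0.6),
    broken_params = c(breakpoint = 0, intercept = 0.02, slope_left = 0,
                      slope_right = 0.01),
    fraction_floor = 0.002,           # planted module mass never below this
    fraction_cap_total = 0.6,         # planted modules jointly bounded
    n_dominant_each = 1L,             # modules per non-neutral dominance class
    n_perturbed_conditions = 5L,
    suppress_factor = 0.15, boost_factor = 3,
    missing_rate = 0                  # extra proteome missingness
  )
}

planted_mapping_value <- function(mapping, a) {
  p <- mapping$params
  switch(mapping$family,
         linear = p["intercept"] + p["slope"] * a,
         exponential = p["offset"] + p["scale"] * exp(p["rate"] * a),
         broken_line = p["intercept"] + p["slope_left"] * a +
           (p["slope_right"] - p["slope_left"]) * pmax(a - p["breakpoint"], 0))
}

#' Generate planted ground truth for a matched-omics simulation
#'
#' Samples disjoint sparse transcriptome modules with unit-norm weights,
#' heavy-tailed mean-zero activities, a lumping map in which some proteome
#' modules union two transcriptome modules, an activity-to-mass-fraction
#' mapping family per proteome module, dominance perturbations for a
#' configurable subset of modules, and a log-normal baseline abundance
#' spectrum whose top fraction defines proteome coverage (planted proteome
#' module genes are placed in the covered set, emulating detection of the
#' most abundant proteins).
#'
#' @param n_genes,n_conditions,k_t,k_p problem dimensions; `k_p <= k_t`,
#'   `n_conditions >= 20`.
#' @param seed integer master seed; all randomness flows from it.
#' @param config named list overriding entries of the default
#'   configuration (see the package vignette for the full list).
#' @return object of class `imod_ground_truth`.
#' @export
generate_ground_truth <- function(n_genes = 2000L, n_conditions = 60L,
                                  k_t = 12L, k_p = 8L, seed = 1L,
                                  config = list()) {
  stopifnot(k_p <= k_t, n_conditions >= 20L)
  cfg <- utils::modifyList(default_sim_config(), config)
  set.seed(seed)
  gene_ids <- sprintf("g%04d", seq_len(n_genes))
  condition_ids <- c("ref", sprintf("cond%02d", seq_len(n_conditions - 1L)))

  sizes <- pmax(3L, round(stats::runif(k_t, cfg$sparsity_range[1],
                                       cfg$sparsity_range[2]) * n_genes))
  if (sum(sizes) > n_genes) stop("infeasible sparsity: modules exceed gene count")
  pool <- sample(gene_ids)
  module_genes <- vector("list", k_t)
  offset <- 0L
  for (k in seq_len(k_t)) {
    module_genes[[k]] <- sort(pool[(offset + 1L):(offset + sizes[k])])
    offset <- offset + sizes[k]
  }
  M0_t <- matrix(0, n_genes, k_t, dimnames = list(gene_ids,
                                                  paste0("mod", seq_len(k_t))))
  for (k in seq_len(k_t)) {
    w <- stats::runif(sizes[k], cfg$weight_range[1], cfg$weight_range[2]) *
      sample(c(-1, 1), sizes[k], replace = TRUE, prob = c(0.2, 0.8))
    M0_t[module_genes[[k]], k] <- w
  }
  M0_t <- orient_components(M0_t)

  A0 <- matrix(rlaplace(k_t * n_conditions, cfg$activity_scale), k_t,
               n_conditions, dimnames = list(colnames(M0_t), condition_ids))
  A0 <- A0 - rowMeans(A0)

  # lumping: first n_lumped proteome modules union two transcriptome
  # modules; the rest map one-to-one
  n_lumped <- min(cfg$n_lumped, k_p, k_t - k_p)
  lumping_map <- vector("list", k_p)
  ti_idx <- 1L
  for (j in seq_len(k_p)) {
    take <- if (j <= n_lumped) 2L else 1L
    lumping_map[[j]] <- seq(ti_idx, length.out = take)
    ti_idx <- ti_idx + take
  }
  names(lumping_map) <- paste0("pmod", seq_len(k_p))

  fams <- rep_len(cfg$mapping_families, k_p)
  mapping <- lapply(seq_len(k_p), function(j) {
    params <- switch(fams[j],
                     linear = cfg$linear_params,
                     exponential = cfg$exponential_params,
                     broken_line = cfg$broken_params)
    list(family = fams[j], params = params)
  })
  names(mapping) <- names(lumping_map)

  # dominance: defaults plant one transcriptome-dominant module (protein
  # suppressed in a few conditions) and one proteome-dominant (boosted)
  classes <- rep("neutral", k_p)
  nd <- cfg$n_dominant_each
  if (k_p >= 2L && nd > 0L) {
    classes[seq_len(min(nd, k_p))] <- "transcriptome-dominant"
    classes[seq(min(nd, k_p) + 1L, length.out = min(nd, k_p - nd))] <-
      "proteome-dominant"
  }
  dominance <- lapply(seq_len(k_p), function(j) {
    if (classes[j] == "neutral") {
      return(list(class = "neutral", conditions = character(0), factor = 1))
    }
    conds <- sample(condition_ids[-1], cfg$n_perturbed_conditions)
    list(class = classes[j], conditions = conds,
         factor = if (classes[j] == "transcriptome-dominant")
           cfg$suppress_factor else cfg$boost_factor)
  })
  names(dominance) <- names(lumping_map)

  baseline_t <- stats::rnorm(n_genes, cfg$baseline_mean, cfg$baseline_sd)
  names(baseline_t) <- gene_ids
  baseline_p <- stats::rlnorm(n_genes, meanlog = 0, sdlog = 1.5)
  names(baseline_p) <- gene_ids
  # proteome module genes are detected by construction: boost their
  # baseline into the top-abundance tier, then take the top fraction
  pi_genes <- unique(unlist(module_genes[unlist(lumping_map)]))
  baseline_p[pi_genes] <- baseline_p[pi_genes] +
    stats::quantile(baseline_p, 1 - cfg$coverage_fraction / 2)
  n_cov <- round(cfg$coverage_fraction * n_genes)
  coverage_mask <- names(sort(baseline_p, decreasing = TRUE))[seq_len(n_cov)]

  structure(list(
    gene_ids = gene_ids, condition_ids = condition_ids,
    module_genes = module_genes, M0_t = M0_t, A0 = A0,
    lumping_map = lumping_map, mapping = mapping, dominance = dominance,
    baseline_t = baseline_t, baseline_p = baseline_p,
    coverage_mask = sort(coverage_mask), sigma_rep = cfg$sigma_rep,
    seed = seed, config = cfg,
    k_t = k_t, k_p = k_p, n_genes = n_genes, n_conditions = n_conditions),
    class = "imod_ground_truth")
}

#' @export
print.imod_ground_truth <- function(x, ...) {
  cat(sprintf("planted ground truth: %d genes, %d conditions, %d transcriptome / %d proteome modules (seed %d)\n",
              x$n_genes, x$n_conditions, x$k_t, x$k_p, x$seed))
  cat(sprintf("  coverage %d genes; lumped modules: %d; non-neutral dominance: %d\n",
              length(x$coverage_mask),
              sum(lengths(x$lumping_map) > 1L),
              sum(vapply(x$dominance, `[[`, "", "class") != "neutral")))
  invisible(x)
}

#' Planted proteome weight matrix implied by the lumping map
#'
#' Each proteome module's weight column is the normalized sum of its
#' constituent transcriptome columns, restricted to covered genes.
#'
#' @param gt an `imod_ground_truth`.
#' @return covered-features x k_p unit-norm weight matrix.
#' @export
planted_proteome_weights <- function(gt) {
  M <- vapply(gt$lumping_map, function(tis) {
    rowSums(gt$M0_t[gt$coverage_mask, tis, drop = FALSE])
  }, numeric(length(gt$coverage_mask)))
  M <- matrix(M, nrow = length(gt$coverage_mask),
              dimnames = list(gt$coverage_mask, names(gt$lumping_map)))
  orient_components(M)
}

# per-condition planted mass fraction of each proteome module
planted_module_fractions <- function(gt) {
  vals <- vapply(seq_len(gt$k_p), function(j) {
    a <- colSums(gt$A0[gt$lumping_map[[j]], , drop = FALSE])
    f <- planted_mapping_value(gt$mapping[[j]], a)
    dom <- gt$dominance[[j]]
    f[gt$condition_ids %in% dom$conditions] <-
      f[gt$condition_ids %in% dom$conditions] * dom$factor
    pmax(f, gt$config$fraction_floor)
  }, numeric(gt$n_conditions))
  fm <- t(matrix(vals, nrow = gt$n_conditions,
                 dimnames = list(gt$condition_ids, names(gt$lumping_map))))
  # keep the planted sectors jointly below a plausible share of the
  # proteome: extreme activity tails otherwise outgrow the total budget
  tot <- colSums(fm)
  over <- tot > gt$config$fraction_cap_total
  if (any(over)) {
    fm[, over] <- sweep(fm[, over, drop = FALSE], 2,
                        gt$config$fraction_cap_total / tot[over], "*")
  }
  fm
}

#' Generate matched transcriptome and proteome compendia from ground truth
#'
#' The transcriptome is baseline plus planted module signal plus replicate
#' noise (log2 scale). The proteome is built directly in mass-fraction
#' space: each proteome module's genes share the module's mapped mass
#' `f(activity)` (dominance perturbations multiply it in the perturbed
#' conditions), background covered genes share the remaining mass in
#' proportion to their baseline abundance, replicate noise acts
#' multiplicatively, and every sample is re-closed to sum 1.
#'
#' @param gt an `imod_ground_truth`.
#' @param replicates biological replicates per condition (default 2).
#' @return list with `transcriptome` (genes x samples, log2 scale),
#'   `proteome` (covered genes x samples mass fractions, with NAs if the
#'   configured missingness is positive), `metadata` (shared by both
#'   layers), and `gt`.
#' @export
generate_matched_compendia <- function(gt, replicates = 2L) {
  cfg <- gt$config
  set.seed(gt$seed + 1L)
  conds <- rep(gt$condition_ids, each = replicates)
  reps <- rep(seq_len(replicates), times = gt$n_conditions)
  sample_ids <- paste0(conds, "_r", reps)
  metadata <- data.frame(sample_id = sample_ids, condition_id = conds,
                         replicate = reps, batch = "batch1",
                         is_reference = conds == gt$condition_ids[1])

  signal <- gt$M0_t %*% gt$A0[, conds, drop = FALSE]
  X_t <- gt$baseline_t + signal +
    matrix(stats::rnorm(length(signal), 0, gt$sigma_rep), nrow(signal))
  dimnames(X_t) <- list(gt$gene_ids, sample_ids)

  mod_frac <- planted_module_fractions(gt)  # k_p x conditions
  covered <- gt$coverage_mask
  pi_gene_sets <- lapply(gt$lumping_map, function(tis) {
    intersect(unique(unlist(gt$module_genes[tis])), covered)
  })
  bg_genes <- setdiff(covered, unlist(pi_gene_sets))
  bg_w <- gt$baseline_p[bg_genes] / sum(gt$baseline_p[bg_genes])
  P <- matrix(0, length(covered), length(sample_ids),
              dimnames = list(covered, sample_ids))
  for (s in seq_along(sample_ids)) {
    cd <- conds[s]
    fm <- mod_frac[, cd]
    for (j in seq_len(gt$k_p)) {
      genes <- pi_gene_sets[[j]]
      u <- gt$baseline_p[genes] / sum(gt$baseline_p[genes])
      P[genes, s] <- u * fm[j]
    }
    P[bg_genes, s] <- bg_w * (1 - sum(fm))
  }
  P <- P * exp(matrix(stats::rnorm(length(P), 0, gt$sigma_rep), nrow(P)))
  P <- sweep(P, 2, colSums(P), "/")
  if (cfg$missing_rate > 0) {
    drop <- matrix(stats::runif(length(P)) < cfg$missing_rate, nrow(P))
    P[drop] <- NA_real_
  }
  list(transcriptome = X_t, proteome = P, metadata = metadata, gt = gt)
}

#' Simulate one activity/mass-fraction series from a planted mapping law
#'
#' Draws condition activities, applies the requested family's planted
#' parameters, and adds Gaussian noise scaled to the response range — the
#' unit-level benchmark for regression family recovery.
#'
#' @param family "linear", "exponential", or "broken_line".
#' @param n number of conditions (default 57).
#' @param noise noise standard deviation as a fraction of the response
#'   range (default 0.05).
#' @param seed integer seed.
#' @param config overrides of the planted parameter defaults.
#' @return list with `x`, `y`, `family`, `params`.
#' @export
simulate_allocation_xy <- function(family = c("linear", "exponential",
                                              "broken_line"),
                                   n = 57L, noise = 0.05, seed = 1L,
                                   config = list()) {
  family <- match.arg(family)
  cfg <- utils::modifyList(default_sim_config(), config)
  set.seed(seed)
  x <- rlaplace(n, cfg$activity_scale)
  x <- x - mean(x)
  mapping <- list(family = family,
                  params = switch(family, linear = cfg$linear_params,
                                  exponential = cfg$exponential_params,
                                  broken_line = cfg$broken_params))
  y0 <- planted_mapping_value(mapping, x)
  y <- y0 + stats::rnorm(n, 0, noise * diff(range(y0)))
  list(x = x, y = y, family = family, params = mapping$params)
}

#' Simulate a matched activity pair with a planted dominance scenario
#'
#' Transcriptome activities are heavy-tailed across conditions; proteome
#' activities follow them up to replicate-scale noise. In a
#' transcriptome-dominant scenario the protein signal is suppressed in a
#' few conditions (transcript present, protein absent); proteome-dominant
#' boosts it; neutral leaves it untouched.
#'
#' @param class planted dominance class.
#' @param n_conditions,n_perturbed conditions overall and perturbed.
#' @param shift perturbation size in activity units (default 3).
#' @param noise sd of the proteome-activity noise around the transcriptome
#'   series (default 0.25).
#' @param seed integer seed.
#' @return list with `ti_activity`, `pi_activity` (named by condition),
#'   `metadata` (one sample per condition), `perturbed`, `class`.
#' @export
simulate_dima_scenario <- function(class = c("neutral",
                                             "transcriptome-dominant",
                                             "proteome-dominant"),
                                   n_conditions = 50L, n_perturbed = 5L,
                                   shift = 3, noise = 0.25, seed = 1L) {
  class <- match.arg(class)
  set.seed(seed)
  conds <- sprintf("cond%02d", seq_len(n_conditions))
  ti <- rlaplace(n_conditions, 1)
  pi_act <- ti + stats::rnorm(n_conditions, 0, noise)
  perturbed <- character(0)
  if (class != "neutral") {
    perturbed <- sample(conds, n_perturbed)
    idx <- conds %in% perturbed
    pi_act[idx] <- pi_act[idx] +
      if (class == "transcriptome-dominant") -shift else shift
  }
  md <- data.frame(sample_id = conds, condition_id = conds, replicate = 1L,
                   batch = "batch1", is_reference = seq_along(conds) == 1L)
  list(ti_activity = stats::setNames(ti, conds),
       pi_activity = stats::setNames(pi_act, conds),
       metadata = md, perturbed = perturbed, class = class)
}

#' Score pipeline recovery against planted ground truth
#'
#' For every planted transcriptome module: the best absolute correlation
#' between its planted weights and any recovered component, and the
#' Jaccard index between the planted gene set and the best component's
#' thresholded membership. When a match table between recovered proteome
#' and transcriptome decompositions is supplied (with the decompositions),
#' recovered links are mapped back to planted modules by best correlation
#' and planted-link recall/precision is reported; when allocation fits are
#' supplied, family recovery per planted proteome module is reported.
#'
#' @param gt an `imod_ground_truth`.
#' @param decomp_t recovered transcriptome `ica_decomposition`.
#' @param decomp_p optional recovered proteome decomposition.
#' @param matches optional `match_table` computed between `decomp_t` and
#'   `decomp_p`.
#' @param fits optional `allocation_set` named by planted module.
#' @return list of class `recovery_report` with elements `modules`
#'   (data.frame), and optionally `link_recall`, `link_precision`,
#'   `family_recovery`.
#' @export
recovery_report <- function(gt, decomp_t, decomp_p = NULL, matches = NULL,
                            fits = NULL) {
  R <- abs(stats::cor(gt$M0_t, decomp_t$M[rownames(gt$M0_t), , drop = FALSE]))
  best <- apply(R, 1, which.max)
  jac <- vapply(seq_len(gt$k_t), function(k) {
    mem <- threshold_component(decomp_t$M[, best[k]])$members
    planted <- gt$module_genes[[k]]
    length(intersect(mem, planted)) / length(union(mem, planted))
  }, 0)
  modules <- data.frame(module = colnames(gt$M0_t),
                        best_component = colnames(decomp_t$M)[best],
                        abs_r = R[cbind(seq_len(gt$k_t), best)],
                        jaccard = jac, row.names = NULL)
  out <- list(modules = modules)
  # recovered -> planted maps by best absolute weight correlation
  ti_of <- stats::setNames(
    colnames(gt$M0_t)[apply(R, 2, which.max)], colnames(decomp_t$M))
  if (!is.null(matches) && !is.null(decomp_p)) {
    Mp0 <- planted_proteome_weights(gt)
    shared_p <- intersect(rownames(Mp0), rownames(decomp_p$M))
    Rp <- abs(stats::cor(Mp0[shared_p, ], decomp_p$M[shared_p, , drop = FALSE]))
    pi_of <- stats::setNames(colnames(Mp0)[apply(Rp, 2, which.max)],
                             colnames(decomp_p$M))
    found <- unique(paste(pi_of[matches$pi], ti_of[matches$ti]))
    planted_links <- unlist(lapply(names(gt$lumping_map), function(p) {
      paste(p, colnames(gt$M0_t)[gt$lumping_map[[p]]])
    }))
    out$link_recall <- mean(planted_links %in% found)
    out$link_precision <- mean(found %in% planted_links)
  }
  if (!is.null(fits)) {
    # planted family of each transcriptome module = the mapping family of
    # the proteome module containing it
    fam_ti <- character(0)
    for (p in names(gt$lumping_map)) {
      fam_ti[colnames(gt$M0_t)[gt$lumping_map[[p]]]] <-
        gt$mapping[[p]]$family
    }
    keys <- names(fits)
    mapped <- ifelse(keys %in% names(ti_of), ti_of[keys], keys)
    shared <- which(mapped %in% names(fam_ti))
    out$family_recovery <- if (length(shared)) {
      mean(vapply(shared, function(i) {
        fits[[i]]$family == fam_ti[mapped[i]]
      }, TRUE))
    } else NA_real_
  }
  class(out) <- "recovery_report"
  out
}

#' @export
print.recovery_report <- function(x, ...) {
  cat("planted-module recovery:\n")
  print(transform(x$modules, abs_r = round(abs_r, 3),
                  jaccard = round(jaccard, 3)))
  if (!is.null(x$link_recall)) {
    cat(sprintf("link recall %.2f, precision %.2f\n",
                x$link_recall, x$link_precision))
  }
  if (!is.null(x$family_recovery)) {
    cat(sprintf("mapping family recovery %.2f\n", x$family_recovery))
  }
  invisible(x)
}
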