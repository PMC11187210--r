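# End-to-end orchestration: simulate (or load) matched compendia, compile
# both layers, decompose, characterize, match, compare activities, and fit
# allocation regressions, writing every intermediate artifact.

pipeline_defaults <- function() {
  list(
    seed = 1L,
    simulate = list(n_genes = 2000L, n_conditions = 60L, k_t = 12L,
                    k_p = 8L, replicates = 2L, config = list()),
    compile = list(min_coverage = 0.5, r2_min = 0.9),
    ica = list(k_t = 12L, k_p = 8L, n_runs = 10L),
    imodulons = list(adj_p_cutoff = 1e-3, k2_cutoff = 550),
    matching = list(r_min = 0.25, band = 1.5),
    allocation = list(r2_min = 0.3),
    out_dir = NULL
  )
}

validate_config <- function(config, template = pipeline_defaults()) {
  unknown <- setdiff(names(config), names(template))
  if (length(unknown)) {
    stop("unknown configuration key(s): ", paste(unknown, collapse = ", "))
  }
  for (nm in names(config)) {
    if (is.list(template[[nm]]) && nm != "simulate") {
      bad <- setdiff(names(config[[nm]]), names(template[[nm]]))
      if (length(bad)) stop("unknown key(s) in '", nm, "': ",
                            paste(bad, collapse = ", "))
    }
  }
  utils::modifyList(template, config)
}

#' Run the full matched-omics modularization pipeline
#'
#' Sequences the analysis stages on synthetic (default) or supplied data:
#' compile both compendia, decompose each with robust ICA, characterize
#' components, match proteome to transcriptome modules, compute DiMA and
#' dominance per matched pair, fit allocation regressions, and summarize
#' sequential proteome allocation. With an `out_dir` every intermediate
#' table is written along with a JSON manifest of seeds and parameters.
#'
#' @param config nested list overriding [pipeline_defaults()]; unknown
#'   keys are rejected.
#' @param data optional list with `transcriptome`, `proteome`, `metadata`
#'   (as produced by [generate_matched_compendia()] or read from disk);
#'   when NULL, data are simulated from `config$simulate` and
#'   `config$seed`.
#' @param regulon_db optional regulator to gene-set mapping for enrichment.
#' @return list of class `imod_pipeline` with the compendia,
#'   decompositions, iModulon sets, match table, DiMA results, dominance
#'   labels, allocation fits and summary, and (synthetic runs) the ground
#'   truth and recovery report.
#' @export
run_pipeline <- function(config = list(), data = NULL, regulon_db = NULL) {
  cfg <- validate_config(config)
  stage <- "simulate"
  result <- tryCatch({
    if (is.null(data)) {
      gt <- generate_ground_truth(cfg$simulate$n_genes,
                                  cfg$simulate$n_conditions,
                                  cfg$simulate$k_t, cfg$simulate$k_p,
                                  seed = cfg$seed,
                                  config = cfg$simulate$config)
      data <- generate_matched_compendia(gt, cfg$simulate$replicates)
    }
    stage <- "compile"
    # the transcriptome arrives on log scale; only the proteome needs the
    # fraction -> log2(PPM+1) chain
    comp_p <- compile_compendium(data$proteome, data$metadata,
                                 min_coverage = cfg$compile$min_coverage,
                                 r2_min = cfg$compile$r2_min)
    ct <- center_to_reference(data$transcriptome, data$metadata)
    comp_t <- structure(list(values = ct, fractions = NULL,
                             metadata = data$metadata,
                             report = list(features_kept = nrow(ct))),
                        class = "omics_compendium")

    stage <- "decompose"
    dec_t <- run_robust_ica(comp_t$values, cfg$ica$k_t,
                            n_runs = cfg$ica$n_runs, seed = cfg$seed)
    dec_p <- run_robust_ica(comp_p$values, cfg$ica$k_p,
                            n_runs = cfg$ica$n_runs, seed = cfg$seed + 1L)

    stage <- "characterize"
    ims_t <- characterize_components(dec_t, regulon_db,
                                     adj_p_cutoff = cfg$imodulons$adj_p_cutoff,
                                     k2_cutoff = cfg$imodulons$k2_cutoff)
    ims_p <- characterize_components(dec_p, regulon_db,
                                     adj_p_cutoff = cfg$imodulons$adj_p_cutoff,
                                     k2_cutoff = cfg$imodulons$k2_cutoff)

    stage <- "match"
    matches <- match_components(dec_t, dec_p, r_min = cfg$matching$r_min)

    stage <- "dima"
    dimas <- list()
    dominance <- character(0)
    for (i in seq_len(nrow(matches))) {
      key <- paste(matches$pi[i], matches$ti[i], sep = "~")
      d <- dima(dec_t$A[matches$ti[i], ], dec_p$A[matches$pi[i], ],
                comp_t$metadata, comp_p$metadata,
                band = cfg$matching$band)
      dimas[[key]] <- d
      dominance[key] <- classify_dominance(d)
    }

    stage <- "allocate"
    # modules without enrichment keep their automatic categories; in
    # synthetic runs everything with >1 member is eligible
    ims_t_eligible <- ims_t
    if (is.null(regulon_db)) {
      for (i in seq_along(ims_t_eligible)) {
        if (length(ims_t_eligible[[i]]$members) > 1L) {
          ims_t_eligible[[i]]$category <- "regulatory"
        }
      }
    }
    fits <- fit_allocation(ims_t_eligible, dec_t$A, comp_p$fractions,
                           comp_t$metadata, comp_p$metadata,
                           r2_min = cfg$allocation$r2_min)
    summary_alloc <- if (length(fits)) {
      summarize_allocation(fits, comp_p$fractions)
    } else NULL

    out <- list(config = cfg, compendium_t = comp_t, compendium_p = comp_p,
                decomposition_t = dec_t, decomposition_p = dec_p,
                imodulons_t = ims_t, imodulons_p = ims_p,
                matches = matches, dima = dimas, dominance = dominance,
                allocation = fits, allocation_summary = summary_alloc)
    if (!is.null(data$gt)) {
      out$gt <- data$gt
      out$recovery <- recovery_report(data$gt, dec_t, dec_p, matches, fits)
    }
    out
  }, error = function(e) {
    stop("pipeline failed at stage '", stage, "': ", conditionMessage(e),
         call. = FALSE)
  })

  if (!is.null(cfg$out_dir)) {
    dir.create(cfg$out_dir, recursive = TRUE, showWarnings = FALSE)
    write_matrix(result$decomposition_t$M, file.path(cfg$out_dir, "M_t.tsv"))
    write_matrix(result$decomposition_t$A, file.path(cfg$out_dir, "A_t.tsv"),
                 id_col = "component")
    write_matrix(result$decomposition_p$M, file.path(cfg$out_dir, "M_p.tsv"))
    write_matrix(result$decomposition_p$A, file.path(cfg$out_dir, "A_p.tsv"),
                 id_col = "component")
    utils::write.table(result$matches, file.path(cfg$out_dir, "matches.tsv"),
                       sep = "\t", quote = FALSE, row.names = FALSE)
    if (!is.null(result$allocation_summary)) {
      utils::write.table(result$allocation_summary,
                         file.path(cfg$out_dir, "allocation_summary.tsv"),
                         sep = "\t", quote = FALSE, row.names = FALSE)
    }
    manifest <- list(seed = cfg$seed, parameters = cfg,
                     n_robust_t = result$decomposition_t$n_robust,
                     n_robust_p = result$decomposition_p$n_robust,
                     timestamp = format(Sys.time(), "%Y-%m-%dT%H:%M:%S"))
    write_report(manifest, file.path(cfg$out_dir, "manifest.json"))
  }
  class(result) <- "imod_pipeline"
  result
}

#' @export
print.imod_pipeline <- function(x, ...) {
  cat("matched-omics modularization pipeline\n")
  cat(sprintf("  transcriptome: %d features -> %d robust components\n",
              nrow(x$decomposition_t$M), x$decomposition_t$n_robust))
  cat(sprintf("  proteome:      %d features -> %d robust components\n",
              nrow(x$decomposition_p$M), x$decomposition_p$n_robust))
  cat(sprintf("  matched pairs: %d; dominance: %s\n", nrow(x$matches),
              paste(names(table(x$dominance)), table(x$dominance),
                    sep = "=", collapse = ", ")))
  if (length(x$allocation)) {
    tab <- table(vapply(x$allocation, `[[`, "", "strength"))
    cat(sprintf("  allocation fits: %d (%s)\n", length(x$allocation),
                paste(names(tab), tab, sep = "=", collapse = ", ")))
  }
  invisible(x)
}
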