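#' Run the screening funnel end to end
#'
#' Orchestrates the pipeline stages in canonical order:
#' `simulate` (synthetic screen, expression experiment, annotation flags),
#' `normalize` (QC filter + per-plate robust z), `call_hits` (replicate-rule
#' primary hits), `de` (expression t-tests + modulation classification),
#' `integrate` (candidate selection), `deconvolve` (individual-siRNA
#' rescreen of the candidates, normalized and validated), `report` (funnel
#' counts and validation rate) and `evaluate` (recovery metrics against
#' ground truth). Each stage consumes artifacts produced by earlier stages;
#' requesting a stage whose inputs are missing — from both the current run
#' and `artifacts` — fails with an error naming the missing artifact.
#' All randomness derives from `sim_config$seed`, so a rerun with the same
#' configurations reproduces every table byte-for-byte.
#'
#' @param sim_config A [sim_config()] describing the synthetic screen.
#' @param config A [screen_config()] with the analysis thresholds.
#' @param stages Character vector of stages to run (default: all, in order).
#' @param artifacts Optional named list of precomputed artifacts (e.g.
#'   `wells` read from disk) to resume from.
#' @param out_dir Optional directory; when given, every table is written as
#'   CSV with deterministic row order, plus a `manifest.txt` recording the
#'   package version, seed, configuration snapshot and per-table row counts.
#' @return A named list of all artifacts produced (invisible).
#' @export
run_pipeline <- function(sim_config = NULL, config = screen_config(),
                         stages = c("simulate", "normalize", "call_hits",
                                    "de", "integrate", "deconvolve",
                                    "report", "evaluate"),
                         artifacts = list(), out_dir = NULL) {
  order_all <- c("simulate", "normalize", "call_hits", "de", "integrate",
                 "deconvolve", "report", "evaluate")
  bad <- setdiff(stages, order_all)
  if (length(bad)) stop("unknown stage(s): ", paste(bad, collapse = ", "),
                        call. = FALSE)
  stages <- order_all[order_all %in% stages]
  art <- artifacts
  need <- function(what, stage) {
    if (is.null(art[[what]])) {
      stop(sprintf("stage '%s' requires missing artifact '%s'; run the producing stage first",
                   stage, what), call. = FALSE)
    }
    art[[what]]
  }

  for (st in stages) {
    switch(st,
      simulate = {
        if (is.null(sim_config)) stop("stage 'simulate' requires sim_config",
                                      call. = FALSE)
        sim <- simulate_screen(sim_config)
        art$design <- sim$design
        art$wells <- sim$wells
        art$truth <- sim$truth
        art$expression <- simulate_expression(sim_config, sim$truth)
        art$flags <- sim$truth[, c("gene", "lipid_gwas_flag")]
      },
      normalize = {
        wells <- need("wells", st)
        norm <- normalize_screen(wells, config)
        art$wellz <- norm$wellz
        art$plate_stats <- norm$plate_stats
      },
      call_hits = {
        wellz <- need("wellz", st)
        design_genes <- if (!is.null(art$design)) art$design$genes else NULL
        summ <- summarize_genes(wellz, design_genes = design_genes)
        art$summaries <- call_primary_hits(
          summ, t = config$primary_z_threshold,
          k = config$primary_min_replicates)
        art$ranked_hits <- rank_hits(art$summaries)
      },
      de = {
        expr <- need("expression", st)
        art$de <- run_de(expr, config)
        art$modulated <- classify_modulated(art$de, alpha = config$de_alpha,
                                            fc_threshold = config$de_fc_threshold)
      },
      integrate = {
        art$candidates <- integrate_candidates(
          need("summaries", st), need("modulated", st), need("flags", st),
          policy = config$integration_policy)
      },
      deconvolve = {
        cand <- need("candidates", st)
        truth <- need("truth", st)
        if (is.null(sim_config)) stop("stage 'deconvolve' requires sim_config",
                                      call. = FALSE)
        cand_genes <- cand$gene[cand$candidate]
        dc <- simulate_deconvolution(sim_config, truth, cand_genes)
        art$deconv_wells <- dc$wells
        if (nrow(dc$wells)) {
          dnorm <- normalize_screen(dc$wells, config)
          art$deconv_wellz <- dnorm$wellz
          recs <- aggregate_deconvolution(
            dnorm$wellz, cand[cand$candidate, c("gene", "hit_call")])
          art$deconv <- validate_deconvolution(
            recs, t = config$deconv_z_threshold, m = config$deconv_min_sirnas)
        } else {
          art$deconv <- NULL
        }
      },
      report = {
        art$funnel <- funnel_report(need("candidates", st),
                                    deconv = art$deconv,
                                    summaries = art$summaries)
      },
      evaluate = {
        truth <- need("truth", st)
        summaries <- need("summaries", st)
        cand <- need("candidates", st)
        scorable <- summaries$gene[summaries$scorable]
        hit_calls <- data.frame(
          gene = summaries$gene[summaries$hit_call != "none"],
          direction = summaries$hit_call[summaries$hit_call != "none"],
          stringsAsFactors = FALSE)
        m <- list(recovery_metrics(hit_calls, truth, universe = scorable,
                                   stage = "primary_hits"))
        cand_calls <- hit_calls[hit_calls$gene %in% cand$gene[cand$candidate], ,
                                drop = FALSE]
        m <- c(m, list(recovery_metrics(cand_calls, truth, universe = scorable,
                                        stage = "candidates")))
        if (!is.null(art$deconv)) {
          val_calls <- hit_calls[hit_calls$gene %in%
                                   art$deconv$gene[art$deconv$validated], ,
                                 drop = FALSE]
          m <- c(m, list(recovery_metrics(val_calls, truth,
                                          universe = scorable,
                                          stage = "validated")))
        }
        art$metrics <- do.call(rbind, m)
      }
    )
  }

  if (!is.null(out_dir)) .write_pipeline_outputs(art, sim_config, config, out_dir)
  invisible(art)
}

.write_pipeline_outputs <- function(art, sim_config, config, out_dir) {
  dir.create(out_dir, recursive = TRUE, showWarnings = FALSE)
  counts <- c()
  wr <- function(name, df, writer = write_result_table) {
    if (is.null(df)) return(invisible(NULL))
    writer(df, file.path(out_dir, paste0(name, ".csv")))
    counts[[name]] <<- nrow(df)
  }
  wr("wells", art$wells, write_well_table)
  wr("expression", art$expression, write_expression_table)
  wr("flags", art$flags, write_flag_table)
  wr("truth", art$truth)
  wr("plate_stats", art$plate_stats)
  wr("wellz", art$wellz)
  if (!is.null(art$summaries)) {
    s <- art$summaries
    s$replicate_z <- vapply(s$replicate_z, function(z)
      paste(format(z, digits = 15), collapse = ";"), character(1))
    wr("hits", s)
  }
  wr("de", art$de)
  wr("modulated", art$modulated)
  wr("candidates", art$candidates)
  wr("deconvolution", art$deconv)
  wr("metrics", art$metrics)
  if (!is.null(art$funnel)) wr("funnel", funnel_as_table(art$funnel))
  # manifest: configuration snapshot + row counts (no timestamps, so that a
  # rerun with identical inputs is byte-identical)
  man <- c(
    sprintf("package_version: %s",
            as.character(utils::packageVersion("screenfunnel"))),
    if (!is.null(sim_config))
      sprintf("sim.%s: %s", names(unclass(sim_config)),
              vapply(unclass(sim_config), function(v)
                paste(format(v, digits = 15), collapse = ","), character(1))),
    sprintf("config.%s: %s", names(unclass(config)),
            vapply(unclass(config), function(v)
              paste(format(v, digits = 15), collapse = ","), character(1))),
    sprintf("rows.%s: %d", names(counts), unlist(counts))
  )
  writeLines(man, file.path(out_dir, "manifest.txt"))
  invisible(out_dir)
}
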