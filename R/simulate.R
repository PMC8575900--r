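#' Synthetic screen simulation configuration
#'
#' Parameters of the generator that emulates an arrayed genome-wide RNAi
#' uptake screen: multiplicative lognormal plate effects and well noise on a
#' positive fluorescence baseline, per-plate randomly placed controls
#' (non-silencing, NPC1 positive at +30 percent uptake, LDLR negative,
#' cytotoxic KIF11), Poisson cell counts with cytotoxic knockdowns centred
#' low, and a matched two-condition (statin / native-LDL vs control)
#' duplicate expression experiment with a subset of truly sterol-modulated
#' genes.
#'
#' @param n_genes Number of sample genes screened.
#' @param n_replicates Screen replicates (default 3, the triplicate design).
#' @param wells_per_plate Plate format, 96 or 384 (default 384).
#' @param n_ns_per_plate,n_pos_per_plate,n_neg_per_plate,n_cytotox_per_plate
#'   Control wells per plate (defaults 16, 4, 4, 4).
#' @param baseline_intensity Mean well fluorescence of a no-effect well in
#'   arbitrary units (default 1000).
#' @param well_noise_cv Coefficient of variation of the lognormal
#'   multiplicative well noise (default 0.10, typical of five-field averaged
#'   image intensities).
#' @param plate_effect_sd SD (log scale) of the lognormal multiplicative
#'   plate factor (default 0.15).
#' @param frac_true_up,frac_true_down Fractions of genes whose knockdown
#'   truly increases / decreases uptake (defaults 0.025 each).
#' @param effect_size_range Range of the fractional uptake change drawn for
#'   spiked genes (default 0.35 to 0.8).
#' @param pos_control_effect Fractional uptake change of the NPC1 positive
#'   control (default +0.30, the reported increase at 8 h).
#' @param neg_control_effect Fractional change of the LDLR negative control
#'   (default -0.70; the knockdown decreases uptake but no published effect
#'   size exists, so this is a free parameter).
#' @param cytotox_fraction Fraction of sample genes whose knockdown is
#'   cytotoxic (low cell counts; default 0.01).
#' @param cell_count_mean,cytotox_cell_count_mean Poisson means of the valid
#'   object count for healthy and cytotoxic wells (defaults 1500, 200).
#' @param gwas_flag_rate Independent Bernoulli rate of the lipid-GWAS
#'   annotation flag (default 0.10).
#' @param expr_n_replicates Biological replicates per expression condition
#'   (default 2, the duplicate array design).
#' @param expr_noise_sd SD of Gaussian noise on log2 expression
#'   (default 0.15).
#' @param expr_baseline_log2_range Range of per-gene baseline log2
#'   expression (default 6 to 12).
#' @param frac_modulated Fraction of genes truly sterol-modulated: statin
#'   (cholesterol depletion) raises their expression, native LDL lowers it
#'   (default 0.30).
#' @param modulated_log2fc_range Range of the true |log2 fold-change| of
#'   modulated genes (default 0.15 to 1.0).
#' @param deconv_efficacy_range Range of the per-siRNA efficacy factor in
#'   the deconvolution screen (default 0.3 to 1.0): each individual siRNA
#'   inherits the pool's true effect attenuated by an independent uniform
#'   draw, reflecting heterogeneous knockdown efficiency.
#' @param seed Integer seed; every generator is deterministic given the
#'   configuration.
#' @return An object of class `sim_config` (a named list).
#' @export
sim_config <- function(n_genes = 1000L,
                       n_replicates = 3L,
                       wells_per_plate = 384L,
                       n_ns_per_plate = 16L,
                       n_pos_per_plate = 4L,
                       n_neg_per_plate = 4L,
                       n_cytotox_per_plate = 4L,
                       baseline_intensity = 1000,
                       well_noise_cv = 0.10,
                       plate_effect_sd = 0.15,
                       frac_true_up = 0.025,
                       frac_true_down = 0.025,
                       effect_size_range = c(0.35, 0.8),
                       pos_control_effect = 0.30,
                       neg_control_effect = -0.70,
                       cytotox_fraction = 0.01,
                       cell_count_mean = 1500,
                       cytotox_cell_count_mean = 200,
                       gwas_flag_rate = 0.10,
                       expr_n_replicates = 2L,
                       expr_noise_sd = 0.15,
                       expr_baseline_log2_range = c(6, 12),
                       frac_modulated = 0.30,
                       modulated_log2fc_range = c(0.15, 1.0),
                       deconv_efficacy_range = c(0.3, 1.0),
                       seed = 1L) {
  cfg <- as.list(environment())
  cfg$n_genes <- as.integer(n_genes)
  cfg$n_replicates <- as.integer(n_replicates)
  cfg$wells_per_plate <- as.integer(wells_per_plate)
  cfg$seed <- as.integer(seed)
  stopifnot(
    cfg$n_genes >= 1L, cfg$n_replicates >= 1L,
    baseline_intensity > 0, well_noise_cv > 0, plate_effect_sd >= 0,
    frac_true_up >= 0, frac_true_down >= 0,
    frac_true_up + frac_true_down <= 1,
    cytotox_fraction >= 0, cytotox_fraction <= 1,
    cell_count_mean > 0, cytotox_cell_count_mean > 0,
    gwas_flag_rate >= 0, gwas_flag_rate <= 1,
    expr_n_replicates >= 2L, expr_noise_sd > 0,
    frac_modulated >= 0, frac_modulated <= 1,
    length(effect_size_range) == 2L, all(effect_size_range > 0),
    length(deconv_efficacy_range) == 2L,
    all(deconv_efficacy_range >= 0), all(deconv_efficacy_range <= 1)
  )
  n_ctrl <- cfg$n_ns_per_plate + cfg$n_pos_per_plate +
    cfg$n_neg_per_plate + cfg$n_cytotox_per_plate
  if (n_ctrl >= cfg$wells_per_plate) {
    stop("control wells exceed plate capacity", call. = FALSE)
  }
  class(cfg) <- "sim_config"
  cfg
}

# run code under a seed without disturbing the caller's RNG stream
.with_seed <- function(seed, code) {
  had <- exists(".Random.seed", envir = globalenv(), inherits = FALSE)
  old <- if (had) get(".Random.seed", envir = globalenv()) else NULL
  on.exit({
    if (had) assign(".Random.seed", old, envir = globalenv())
    else if (exists(".Random.seed", envir = globalenv(), inherits = FALSE))
      rm(".Random.seed", envir = globalenv())
  })
  set.seed(seed)
  code
}

.sigma_from_cv <- function(cv) sqrt(log(1 + cv^2))

# mean-1 lognormal multiplicative noise
.lognorm_noise <- function(n, cv) {
  s <- .sigma_from_cv(cv)
  exp(stats::rnorm(n, mean = -s^2 / 2, sd = s))
}

.control_block <- function(cfg) {
  data.frame(
    gene = c(rep("NS", cfg$n_ns_per_plate),
             rep("siNPC1", cfg$n_pos_per_plate),
             rep("siLDLR", cfg$n_neg_per_plate),
             rep("siKIF11", cfg$n_cytotox_per_plate)),
    role = c(rep("ns_control", cfg$n_ns_per_plate),
             rep("pos_control_npc1", cfg$n_pos_per_plate),
             rep("neg_control_ldlr", cfg$n_neg_per_plate),
             rep("cytotox_control_kif11", cfg$n_cytotox_per_plate)),
    stringsAsFactors = FALSE
  )
}

.draw_ground_truth <- function(cfg) {
  n <- cfg$n_genes
  genes <- sprintf("g%05d", seq_len(n))
  effect <- numeric(n)
  n_up <- round(cfg$frac_true_up * n)
  n_dn <- round(cfg$frac_true_down * n)
  spiked <- sample.int(n, n_up + n_dn)
  if (n_up > 0) effect[spiked[seq_len(n_up)]] <-
    stats::runif(n_up, cfg$effect_size_range[1], cfg$effect_size_range[2])
  if (n_dn > 0) effect[spiked[n_up + seq_len(n_dn)]] <-
    -stats::runif(n_dn, cfg$effect_size_range[1], cfg$effect_size_range[2])
  cytotoxic <- stats::runif(n) < cfg$cytotox_fraction
  gwas <- stats::runif(n) < cfg$gwas_flag_rate
  modulated <- stats::runif(n) < cfg$frac_modulated
  statin_lfc <- ifelse(modulated,
    stats::runif(n, cfg$modulated_log2fc_range[1], cfg$modulated_log2fc_range[2]), 0)
  nldl_lfc <- ifelse(modulated,
    -stats::runif(n, cfg$modulated_log2fc_range[1], cfg$modulated_log2fc_range[2]), 0)
  data.frame(
    gene = genes,
    true_screen_effect = effect,
    cytotoxic = cytotoxic,
    true_statin_log2fc = statin_lfc,
    true_nldl_log2fc = nldl_lfc,
    lipid_gwas_flag = gwas,
    stringsAsFactors = FALSE
  )
}

# lay sample units + controls onto plates for one replicate; a unit is a
# (gene, sirna) pair with its expected fractional effect and cytotoxicity
.layout_replicate <- function(units, cfg, replicate, plate_prefix) {
  ctrl <- .control_block(cfg)
  capacity <- cfg$wells_per_plate - nrow(ctrl)
  n_plates <- ceiling(nrow(units) / capacity)
  ids <- well_ids(cfg$wells_per_plate)
  out <- vector("list", n_plates)
  for (p in seq_len(n_plates)) {
    idx <- ((p - 1L) * capacity + 1L):min(p * capacity, nrow(units))
    blk <- units[idx, , drop = FALSE]
    plate_df <- data.frame(
      gene = c(blk$gene, ctrl$gene),
      role = c(rep("sample", nrow(blk)), ctrl$role),
      sirna = c(blk$sirna, rep(0L, nrow(ctrl))),
      effect = c(blk$effect,
                 rep(0, cfg$n_ns_per_plate),
                 rep(cfg$pos_control_effect, cfg$n_pos_per_plate),
                 rep(cfg$neg_control_effect, cfg$n_neg_per_plate),
                 rep(0, cfg$n_cytotox_per_plate)),
      low_count = c(blk$low_count,
                    rep(FALSE, cfg$n_ns_per_plate + cfg$n_pos_per_plate +
                          cfg$n_neg_per_plate),
                    rep(TRUE, cfg$n_cytotox_per_plate)),
      stringsAsFactors = FALSE
    )
    n_fill <- cfg$wells_per_plate - nrow(plate_df)
    if (n_fill > 0) {
      plate_df <- rbind(plate_df, data.frame(
        gene = rep("EMPTY", n_fill), role = rep("empty", n_fill),
        sirna = rep(0L, n_fill), effect = rep(0, n_fill),
        low_count = rep(FALSE, n_fill)))
    }
    # controls (and everything else) at randomised positions
    plate_df <- plate_df[sample.int(nrow(plate_df)), , drop = FALSE]
    plate_df$plate <- sprintf("%sR%d_P%03d", plate_prefix, replicate, p)
    plate_df$well <- ids
    plate_df$replicate <- replicate
    out[[p]] <- plate_df
  }
  do.call(rbind, out)
}

# draw measurements for laid-out wells under the multiplicative model
.measure_wells <- function(layout, cfg) {
  plates <- unique(layout$plate)
  pf <- exp(stats::rnorm(length(plates), 0, cfg$plate_effect_sd))
  names(pf) <- plates
  n <- nrow(layout)
  intensity <- pf[layout$plate] * cfg$baseline_intensity *
    (1 + layout$effect) * .lognorm_noise(n, cfg$well_noise_cv)
  counts <- ifelse(layout$low_count,
                   stats::rpois(n, cfg$cytotox_cell_count_mean),
                   stats::rpois(n, cfg$cell_count_mean))
  empty <- layout$role == "empty"
  intensity[empty] <- 0
  counts[empty] <- 0L
  layout$valid_object_count <- as.integer(counts)
  layout$mean_intensity <- as.numeric(intensity)
  layout
}

.finish_well_table <- function(layout, keep_sirna = FALSE) {
  cols <- c("plate", "well", "replicate", "gene", "role",
            if (keep_sirna) "sirna",
            "valid_object_count", "mean_intensity")
  df <- layout[, cols, drop = FALSE]
  rownames(df) <- NULL
  .order_wells(df)
}

#' Simulate a complete arrayed RNAi screen with known ground truth
#'
#' Genes are chunked onto plates per replicate; each plate carries randomly
#' positioned control wells. Well intensity follows
#' `plate_factor x baseline x (1 + true_effect) x lognormal noise` with an
#' independent lognormal factor per plate; valid object counts are Poisson,
#' with cytotoxic knockdowns (and the KIF11 control) centred at the
#' cytotoxic mean. Deterministic given `config$seed`.
#'
#' @param config A [sim_config()] object.
#' @return A list with elements `design` (genes, replicate count, plate
#'   format and the gene placement layout), `wells` (the well measurement
#'   table, one row per well) and `truth` (per-gene true screen effect,
#'   cytotoxicity, true expression log2 fold-changes and GWAS flag).
#' @export
simulate_screen <- function(config) {
  stopifnot(inherits(config, "sim_config"))
  .with_seed(config$seed, {
    truth <- .draw_ground_truth(config)
    units <- data.frame(gene = truth$gene, sirna = 0L,
                        effect = truth$true_screen_effect,
                        low_count = truth$cytotoxic,
                        stringsAsFactors = FALSE)
    layout <- do.call(rbind, lapply(seq_len(config$n_replicates), function(r) {
      .layout_replicate(units, config, r, plate_prefix = "")
    }))
    layout <- .measure_wells(layout, config)
    wells <- .finish_well_table(layout)
    design <- list(
      genes = truth$gene,
      n_replicates = config$n_replicates,
      wells_per_plate = config$wells_per_plate,
      layout = wells[, c("plate", "well", "replicate", "gene", "role")]
    )
    list(design = design, wells = wells, truth = truth)
  })
}

#' Simulate the deconvolution screen for a candidate list
#'
#' Each candidate gene is re-tested with its three individual siRNAs, each
#' inheriting the gene's true effect attenuated by an independent per-siRNA
#' efficacy factor drawn uniformly from `config$deconv_efficacy_range`. The
#' plate layout, control complement and noise model match the primary
#' screen. An empty candidate list returns an empty well table.
#'
#' @param config A [sim_config()] object.
#' @param truth Ground-truth table from [simulate_screen()].
#' @param candidate_genes Character vector of genes to deconvolve; must be a
#'   subset of `truth$gene`.
#' @param n_sirnas Individual siRNAs per gene (default 3).
#' @param seed Seed for this stage (default `config$seed + 1`).
#' @return A list with `wells` (well table with an extra `sirna` column,
#'   0 for controls) and `efficacy` (gene x sirna efficacy factors drawn).
#' @export
simulate_deconvolution <- function(config, truth, candidate_genes,
                                   n_sirnas = 3L, seed = config$seed + 1L) {
  stopifnot(inherits(config, "sim_config"))
  missing <- setdiff(candidate_genes, truth$gene)
  if (length(missing)) {
    stop("candidate gene(s) not in simulated screen: ",
         paste(utils::head(missing, 5), collapse = ", "), call. = FALSE)
  }
  if (length(candidate_genes) == 0L) {
    empty <- data.frame(plate = character(), well = character(),
                        replicate = integer(), gene = character(),
                        role = character(), sirna = integer(),
                        valid_object_count = integer(),
                        mean_intensity = numeric(), stringsAsFactors = FALSE)
    return(list(wells = empty,
                efficacy = data.frame(gene = character(), sirna = integer(),
                                      efficacy = numeric())))
  }
  .with_seed(seed, {
    tr <- truth[match(candidate_genes, truth$gene), ]
    eff <- data.frame(
      gene = rep(tr$gene, each = n_sirnas),
      sirna = rep(seq_len(n_sirnas), times = nrow(tr)),
      efficacy = stats::runif(nrow(tr) * n_sirnas,
                              config$deconv_efficacy_range[1],
                              config$deconv_efficacy_range[2]),
      stringsAsFactors = FALSE
    )
    units <- data.frame(
      gene = eff$gene, sirna = eff$sirna,
      effect = rep(tr$true_screen_effect, each = n_sirnas) * eff$efficacy,
      low_count = rep(tr$cytotoxic, each = n_sirnas),
      stringsAsFactors = FALSE
    )
    layout <- do.call(rbind, lapply(seq_len(config$n_replicates), function(r) {
      .layout_replicate(units, config, r, plate_prefix = "DC_")
    }))
    layout <- .measure_wells(layout, config)
    list(wells = .finish_well_table(layout, keep_sirna = TRUE),
         efficacy = eff)
  })
}

#' Simulate the two-condition expression experiment
#'
#' Log2 expression of each gene is a uniform baseline plus the condition
#' shift (statin: `+true_statin_log2fc`; nLDL: `+true_nldl_log2fc`;
#' control: 0) plus Gaussian noise; values are emitted on the linear scale
#' with `config$expr_n_replicates` replicates per condition.
#'
#' @param config A [sim_config()] object.
#' @param truth Ground-truth table from [simulate_screen()].
#' @param seed Seed for this stage (default `config$seed + 2`).
#' @return An expression data.frame (`gene, condition, replicate,
#'   expression`).
#' @export
simulate_expression <- function(config, truth, seed = config$seed + 2L) {
  stopifnot(inherits(config, "sim_config"))
  .with_seed(seed, {
    n <- nrow(truth)
    baseline <- stats::runif(n, config$expr_baseline_log2_range[1],
                             config$expr_baseline_log2_range[2])
    shift <- cbind(control = rep(0, n),
                   nLDL = truth$true_nldl_log2fc,
                   statin = truth$true_statin_log2fc)
    rows <- expand.grid(replicate = seq_len(config$expr_n_replicates),
                        condition = EXPR_CONDITIONS,
                        gene_idx = seq_len(n),
                        stringsAsFactors = FALSE)
    log2e <- baseline[rows$gene_idx] +
      shift[cbind(rows$gene_idx, match(rows$condition, colnames(shift)))] +
      stats::rnorm(nrow(rows), 0, config$expr_noise_sd)
    out <- data.frame(gene = truth$gene[rows$gene_idx],
                      condition = rows$condition,
                      replicate = as.integer(rows$replicate),
                      expression = 2^log2e,
                      stringsAsFactors = FALSE)
    out <- out[order(out$gene, out$condition, out$replicate), ]
    rownames(out) <- NULL
    out
  })
}
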