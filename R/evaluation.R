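#' Direction-aware recovery metrics against simulation ground truth
#'
#' Scores a stage of the funnel (primary hits, candidates or validated
#' genes) against the generator's ground truth. A call is a true positive
#' only when its direction matches the sign of the true screen effect; an
#' up-call on a true down-regulator is a false positive (and the regulator
#' is still missed, so it also counts as a false negative). Genes outside
#' `universe` (e.g. unscorable genes) enter no denominator. An optional
#' gray zone (`min_effect`) drops weak true effects from both the positive
#' and negative sides.
#'
#' @param calls Data.frame with columns `gene` and `direction`
#'   (`"up"`/`"down"`), one row per called gene at this stage.
#' @param truth Ground-truth table from [simulate_screen()] (columns `gene`,
#'   `true_screen_effect`); must be non-empty.
#' @param universe Optional character vector restricting the scored gene
#'   universe (default: all truth genes).
#' @param min_effect True effects with `0 < |effect| < min_effect` are
#'   excluded from scoring entirely (default 0: any nonzero effect is a
#'   true regulator).
#' @param stage Label stored in the result (default "primary_hits").
#' @return A one-row data.frame: `stage, tp, fp, fn, precision, recall`
#'   (precision/recall NA when their denominator is zero).
#' @export
recovery_metrics <- function(calls, truth, universe = NULL, min_effect = 0,
                             stage = "primary_hits") {
  if (is.null(truth) || nrow(truth) == 0L) {
    stop("ground truth is empty", call. = FALSE)
  }
  if (is.null(universe)) universe <- truth$gene
  tr <- truth[truth$gene %in% universe, , drop = FALSE]
  gray <- abs(tr$true_screen_effect) > 0 &
    abs(tr$true_screen_effect) < min_effect
  tr <- tr[!gray, , drop = FALSE]
  calls <- calls[calls$gene %in% tr$gene, , drop = FALSE]
  dup <- unique(calls$gene[duplicated(calls$gene)])
  if (length(dup)) stop("duplicate called gene(s): ",
                        paste(utils::head(dup, 5), collapse = ", "),
                        call. = FALSE)
  true_dir <- ifelse(tr$true_screen_effect > 0, "up",
                     ifelse(tr$true_screen_effect < 0, "down", "none"))
  names(true_dir) <- tr$gene
  called_dir <- calls$direction
  names(called_dir) <- calls$gene
  tp <- sum(called_dir == true_dir[names(called_dir)])
  fp <- nrow(calls) - tp
  n_regulators <- sum(true_dir != "none")
  fn <- n_regulators - tp
  data.frame(stage = stage, tp = tp, fp = fp, fn = fn,
             precision = if (tp + fp > 0) tp / (tp + fp) else NA_real_,
             recall = if (tp + fn > 0) tp / (tp + fn) else NA_real_,
             stringsAsFactors = FALSE)
}

#' Gene-level null hit probability under the replicate rule
#'
#' Exact probability that a null gene is called a hit when each of `r`
#' independent replicate wells lands beyond +t with probability `p_up` and
#' beyond -t with probability `p_down`: the rule calls a hit when at least
#' `k` replicates exceed on the same side (a gene exceeding in both
#' directions simultaneously is called none). Computed by trinomial
#' enumeration over the replicate outcomes.
#'
#' @param p_up,p_down Per-replicate exceedance probabilities.
#' @param r Replicates (default 3).
#' @param k Concordant replicates required (default 2).
#' @return The null hit probability.
#' @export
gene_null_probability <- function(p_up, p_down, r = 3L, k = 2L) {
  stopifnot(p_up >= 0, p_down >= 0, p_up + p_down <= 1, r >= 1L, k >= 1L)
  if (k > r) return(0)
  p0 <- 1 - p_up - p_down
  P <- 0
  for (a in 0:r) for (b in 0:(r - a)) {
    hit_up <- a >= k; hit_dn <- b >= k
    if (xor(hit_up, hit_dn)) {
      P <- P + choose(r, a) * choose(r - a, b) *
        p_up^a * p_down^b * p0^(r - a - b)
    }
  }
  P
}

# Monte-Carlo estimate of the single-well robust-z exceedance under the
# generator's plate model: full plates of null sample wells plus the control
# complement (positive and negative controls shift the plate MAD slightly,
# so they are simulated too); cytotoxic wells are QC-excluded and never
# enter the statistics. Written directly from the noise model, independent
# of the normalization code path.
.mc_exceedance <- function(config, t, mad_constant, n_draws) {
  n_ctrl_in <- config$n_ns_per_plate + config$n_pos_per_plate +
    config$n_neg_per_plate
  n_samples <- config$wells_per_plate - n_ctrl_in - config$n_cytotox_per_plate
  n_cyto <- round(config$cytotox_fraction * n_samples)
  n_s_ok <- n_samples - n_cyto
  n_inc <- n_s_ok + n_ctrl_in
  effects <- c(rep(0, n_s_ok + config$n_ns_per_plate),
               rep(config$pos_control_effect, config$n_pos_per_plate),
               rep(config$neg_control_effect, config$n_neg_per_plate))
  n_plates <- ceiling(n_draws / n_s_ok)
  s <- .sigma_from_cv(config$well_noise_cv)
  n_up <- 0; n_dn <- 0; n_tot <- 0
  chunk <- max(1L, floor(2e6 / n_inc))
  done <- 0L
  while (done < n_plates) {
    m <- min(chunk, n_plates - done)
    x <- matrix(exp(stats::rnorm(n_inc * m, -s^2 / 2, s)), n_inc, m) *
      (1 + effects)
    med <- apply(x, 2, stats::median)
    madv <- apply(abs(sweep(x, 2, med)), 2, stats::median) * mad_constant
    z <- sweep(sweep(x[seq_len(n_s_ok), , drop = FALSE], 2, med), 2, madv, "/")
    n_up <- n_up + sum(z >= t)
    n_dn <- n_dn + sum(z <= -t)
    n_tot <- n_tot + length(z)
    done <- done + m
  }
  list(p_up = n_up / n_tot, p_down = n_dn / n_tot, n = n_tot)
}

#' Null calibration of the primary hit rule
#'
#' Simulates a zero-effect screen, runs the full normalization and
#' hit-calling pipeline, and compares the empirical fraction of scorable
#' genes called hits with the exact gene-level expectation from
#' [gene_null_probability()], whose per-replicate exceedance probabilities
#' `p_up` and `p_down` are estimated by an independent Monte-Carlo oracle
#' (>= `n_oracle_draws` simulated wells drawn directly from the noise
#' model). The two exceedance sides are estimated separately because the
#' lognormal well noise is right-skewed, so upward exceedances of the raw
#' MAD threshold are more likely than downward ones.
#'
#' @param config A [sim_config()]; its effect fractions must be zero.
#' @param pipeline_config A [screen_config()].
#' @param n_oracle_draws Minimum Monte-Carlo draws for the exceedance oracle
#'   (default 1e6).
#' @param oracle_seed Seed for the oracle stream (default
#'   `config$seed + 10`).
#' @return A list: `empirical_fraction`, `n_scorable`, `n_hits`,
#'   `analytic_expectation`, `p_up`, `p_down`, `se_empirical` (binomial SE
#'   of the empirical fraction at the analytic expectation).
#' @export
null_calibration <- function(config, pipeline_config = screen_config(),
                             n_oracle_draws = 1e6,
                             oracle_seed = config$seed + 10L) {
  if (config$frac_true_up != 0 || config$frac_true_down != 0) {
    stop("null calibration requires a zero-effect configuration", call. = FALSE)
  }
  sim <- simulate_screen(config)
  norm <- normalize_screen(sim$wells, pipeline_config)
  summ <- summarize_genes(norm$wellz)
  hits <- call_primary_hits(summ,
                            t = pipeline_config$primary_z_threshold,
                            k = pipeline_config$primary_min_replicates)
  scorable <- hits[hits$scorable, , drop = FALSE]
  n_hits <- sum(scorable$hit_call != "none")
  emp <- n_hits / nrow(scorable)
  mc <- .with_seed(oracle_seed,
                   .mc_exceedance(config,
                                  t = pipeline_config$primary_z_threshold,
                                  mad_constant = pipeline_config$mad_constant,
                                  n_draws = n_oracle_draws))
  analytic <- gene_null_probability(mc$p_up, mc$p_down,
                                    r = config$n_replicates,
                                    k = pipeline_config$primary_min_replicates)
  list(empirical_fraction = emp,
       n_scorable = nrow(scorable),
       n_hits = n_hits,
       analytic_expectation = analytic,
       p_up = mc$p_up,
       p_down = mc$p_down,
       n_oracle_draws = mc$n,
       se_empirical = sqrt(analytic * (1 - analytic) / nrow(scorable)))
}
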