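#' Signed fold-change of two positive group means
#'
#' Returns the ratio `r = mean_treat / mean_ctrl` when `r >= 1` and `-1/r`
#' otherwise, so down-regulation is a negative number of magnitude >= 1 and
#' no value falls in (-1, 1). Vectorized; antisymmetric in its arguments
#' (`signed_fold_change(a, b) == -signed_fold_change(b, a)` for `a != b`)
#' and exactly 1 when the means are equal.
#'
#' @param mean_treat,mean_ctrl Positive group means (linear scale).
#' @return Numeric vector of signed fold-changes.
#' @export
signed_fold_change <- function(mean_treat, mean_ctrl) {
  if (any(mean_treat <= 0) || any(mean_ctrl <= 0)) {
    stop("group means must be strictly positive", call. = FALSE)
  }
  r <- mean_treat / mean_ctrl
  ifelse(r >= 1, r, -1 / r)
}

# pooled two-sample two-sided Student t on already-extracted values
.pooled_t <- function(m1, m2, v1, v2, n1, n2) {
  df <- n1 + n2 - 2
  sp2 <- ((n1 - 1) * v1 + (n2 - 1) * v2) / df
  se <- sqrt(sp2 * (1 / n1 + 1 / n2))
  t <- (m2 - m1) / se
  p <- 2 * stats::pt(-abs(t), df)
  degen <- sp2 == 0
  # both groups constant: identical means are evidence of nothing (p = 1),
  # distinct means are infinitely significant under the model (p = 0)
  p[degen] <- ifelse(m1[degen] == m2[degen], 1, 0)
  t[degen] <- ifelse(m1[degen] == m2[degen], 0, Inf * sign(m2 - m1)[degen])
  list(t = t, df = df, p = p, degenerate = degen)
}

#' Two-sample Student t-test with signed fold-change for one gene
#'
#' Unpaired, two-sided, pooled-variance Student t-test comparing one
#' treatment condition against control for a single gene, plus the signed
#' fold-change of the linear-scale group means. The default tests the
#' linear-scale values directly (the original analysis applies a Student t
#' to expression intensities); `log_scale = TRUE` tests log2 values
#' instead, leaving the fold-change definition unchanged.
#'
#' @param treat,ctrl Numeric vectors of linear-scale expression values
#'   (>= 2 replicates each, all positive).
#' @param log_scale Test on log2-transformed values (default FALSE).
#' @return A one-row data.frame: `signed_fc, t_stat, df, p_value,
#'   degenerate_variance`.
#' @export
de_test <- function(treat, ctrl, log_scale = FALSE) {
  if (length(treat) < 2L || length(ctrl) < 2L) {
    stop("at least 2 replicates per group are required", call. = FALSE)
  }
  if (any(treat <= 0) || any(ctrl <= 0)) {
    stop("expression values must be positive (linear scale)", call. = FALSE)
  }
  fc <- signed_fold_change(mean(treat), mean(ctrl))
  xt <- if (log_scale) log2(treat) else treat
  xc <- if (log_scale) log2(ctrl) else ctrl
  tt <- .pooled_t(mean(xc), mean(xt), stats::var(xc), stats::var(xt),
                  length(xc), length(xt))
  data.frame(signed_fc = fc, t_stat = tt$t, df = tt$df, p_value = tt$p,
             degenerate_variance = tt$degenerate)
}

.de_contrast <- function(expr, treat_cond, log_scale, fdr, alpha, fc_threshold) {
  genes <- sort(unique(expr$gene))
  gf <- function(cond) {
    sub <- expr[expr$condition == cond, , drop = FALSE]
    g <- factor(sub$gene, levels = genes)
    x <- if (log_scale) log2(sub$expression) else sub$expression
    list(n = as.integer(tapply(x, g, length)),
         m = as.numeric(tapply(x, g, mean)),
         v = as.numeric(tapply(x, g, stats::var)),
         mlin = as.numeric(tapply(sub$expression, g, mean)))
  }
  ct <- gf("control"); tr <- gf(treat_cond)
  short <- genes[is.na(ct$n) | is.na(tr$n) | ct$n < 2L | tr$n < 2L]
  if (length(short)) {
    stop("gene(s) with fewer than 2 replicates in a group for contrast ",
         treat_cond, "_vs_control: ",
         paste(utils::head(short, 5), collapse = ", "), call. = FALSE)
  }
  tt <- .pooled_t(ct$m, tr$m, ct$v, tr$v, ct$n, tr$n)
  p <- if (fdr) stats::p.adjust(tt$p, method = "BH") else tt$p
  fc <- signed_fold_change(tr$mlin, ct$mlin)
  dir <- rep("none", length(genes))
  dir[p <= alpha & fc >= fc_threshold] <- "up"
  dir[p <= alpha & fc <= -fc_threshold] <- "down"
  data.frame(gene = genes,
             contrast = paste0(tolower(treat_cond), "_vs_control"),
             signed_fc = fc, t_stat = tt$t, df = tt$df, p_value = p,
             degenerate_variance = tt$degenerate,
             modulated_direction = dir,
             stringsAsFactors = FALSE)
}

#' Differential expression for both sterol contrasts
#'
#' Runs the thresholded Student t-test gene-by-gene for
#' `statin_vs_control` and `nldl_vs_control`. P-values are raw by default
#' (`de_fdr = FALSE` in the configuration), matching an analysis thresholded
#' at P <= 0.05 without multiple-testing correction.
#'
#' @param expr Expression table (`gene, condition, replicate, expression`).
#' @param config A [screen_config()]; uses `de_alpha`, `de_fc_threshold`,
#'   `de_log_scale`, `de_fdr`.
#' @return A data.frame with one row per gene per contrast: `gene, contrast,
#'   signed_fc, t_stat, df, p_value, degenerate_variance,
#'   modulated_direction`.
#' @export
run_de <- function(expr, config = screen_config()) {
  rbind(
    .de_contrast(expr, "statin", config$de_log_scale, config$de_fdr,
                 config$de_alpha, config$de_fc_threshold),
    .de_contrast(expr, "nLDL", config$de_log_scale, config$de_fdr,
                 config$de_alpha, config$de_fc_threshold)
  )
}

#' Classify genes as cholesterol-modulated
#'
#' A gene is sterol-modulated when its expression goes up with statin
#' (cholesterol depletion; signed FC >= threshold, P <= alpha) and/or down
#' with native LDL (cholesterol enrichment; signed FC <= -threshold,
#' P <= alpha). Significant changes in the opposite directions do not
#' qualify.
#'
#' @param de Output of [run_de()]; both contrasts must be present for every
#'   gene.
#' @param alpha Significance level (default 0.05).
#' @param fc_threshold Signed fold-change magnitude threshold (default 1.1).
#' @return A data.frame: `gene, statin_up, nldl_down, cholesterol_modulated`.
#' @export
classify_modulated <- function(de, alpha = 0.05, fc_threshold = 1.1) {
  st <- de[de$contrast == "statin_vs_control", , drop = FALSE]
  nl <- de[de$contrast == "nldl_vs_control", , drop = FALSE]
  genes <- sort(unique(de$gene))
  i_st <- match(genes, st$gene); i_nl <- match(genes, nl$gene)
  if (anyNA(i_st) || anyNA(i_nl)) {
    stop("missing contrast for gene(s): ",
         paste(utils::head(genes[is.na(i_st) | is.na(i_nl)], 5),
               collapse = ", "), call. = FALSE)
  }
  statin_up <- st$p_value[i_st] <= alpha & st$signed_fc[i_st] >= fc_threshold
  nldl_down <- nl$p_value[i_nl] <= alpha & nl$signed_fc[i_nl] <= -fc_threshold
  data.frame(gene = genes, statin_up = statin_up, nldl_down = nldl_down,
             cholesterol_modulated = statin_up | nldl_down,
             stringsAsFactors = FALSE)
}
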