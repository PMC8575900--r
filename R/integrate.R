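#' Integrate functional hits with expression and GWAS evidence
#'
#' A gene is a funnel candidate when its knockdown was a primary screen hit
#' (up or down) and its expression is sterol-modulated and/or it carries a
#' lipid-GWAS association flag ("and/or" is an inclusive OR; alternative
#' policies are available for sensitivity analysis). Gene universes are
#' reconciled by outer join: hits missing from the expression or flag table
#' default to not-modulated / not-flagged, so the hit universe is never
#' silently shrunk; the number of such genes is recorded in attributes
#' `n_unmeasured_expression` and `n_unflagged`.
#'
#' @param hits Output of [call_primary_hits()] (columns `gene`, `hit_call`).
#' @param modulated Output of [classify_modulated()] (columns `gene`,
#'   `cholesterol_modulated`).
#' @param flags Annotation table (columns `gene`, `lipid_gwas_flag`).
#' @param policy `"or"` (default), `"and"` or `"expression_only"`.
#' @return A data.frame with one row per hit-universe gene: `gene, hit_call,
#'   mean_z, cholesterol_modulated, lipid_gwas_flag, candidate`, ordered by
#'   gene. Duplicate gene rows in any input are an error.
#' @export
integrate_candidates <- function(hits, modulated, flags,
                                 policy = c("or", "and", "expression_only")) {
  policy <- match.arg(policy)
  for (nm in c("hits", "modulated", "flags")) {
    df <- get(nm)
    dup <- unique(df$gene[duplicated(df$gene)])
    if (length(dup)) {
      stop(sprintf("duplicate gene row(s) in %s: %s", nm,
                   paste(utils::head(dup, 5), collapse = ", ")), call. = FALSE)
    }
  }
  genes <- sort(unique(hits$gene))
  i_m <- match(genes, modulated$gene)
  i_f <- match(genes, flags$gene)
  mod <- modulated$cholesterol_modulated[i_m]
  mod[is.na(mod)] <- FALSE
  flg <- flags$lipid_gwas_flag[i_f]
  flg[is.na(flg)] <- FALSE
  i_h <- match(genes, hits$gene)
  hit_call <- hits$hit_call[i_h]
  evidence <- switch(policy,
                     or = mod | flg,
                     and = mod & flg,
                     expression_only = mod)
  out <- data.frame(gene = genes,
                    hit_call = hit_call,
                    mean_z = if ("mean_z" %in% names(hits)) hits$mean_z[i_h] else NA_real_,
                    cholesterol_modulated = mod,
                    lipid_gwas_flag = flg,
                    candidate = hit_call != "none" & evidence,
                    stringsAsFactors = FALSE)
  attr(out, "n_unmeasured_expression") <- sum(is.na(i_m))
  attr(out, "n_unflagged") <- sum(is.na(i_f))
  out
}

#' Stage-by-stage funnel report
#'
#' Counts the attrition from genes screened through primary hits,
#' integrated candidates, rescreened genes and deconvolution-validated
#' hits, and computes the validation rate as
#' `100 * n_validated / n_rescreened` (stored at full precision; rounding
#' is presentation-only). The monotone chain
#' `validated <= rescreened <= candidates <= primary hits <= scorable <=
#' screened` is asserted over the stages that are available; a violation is
#' an error, not a warning.
#'
#' @param candidates Output of [integrate_candidates()].
#' @param deconv Optional output of [validate_deconvolution()]; when absent
#'   the rescreen stages are reported as NA.
#' @param summaries Optional output of [summarize_genes()]; provides the
#'   screened and scorable counts.
#' @return An object of class `funnel_report` (a named list of counts plus
#'   `validation_rate_percent`, NA when nothing was rescreened).
#' @export
funnel_report <- function(candidates, deconv = NULL, summaries = NULL) {
  n_screened <- if (!is.null(summaries)) nrow(summaries) else NA_integer_
  n_scorable <- if (!is.null(summaries)) sum(summaries$scorable) else NA_integer_
  is_hit <- candidates$hit_call %in% c("up", "down")
  n_hits <- sum(is_hit)
  n_up <- sum(candidates$hit_call == "up")
  n_down <- sum(candidates$hit_call == "down")
  n_cand <- sum(candidates$candidate)
  n_rescreened <- if (!is.null(deconv)) nrow(deconv) else NA_integer_
  n_validated <- if (!is.null(deconv)) sum(deconv$validated) else NA_integer_
  rate <- if (!is.null(deconv) && n_rescreened > 0) {
    100 * n_validated / n_rescreened
  } else NA_real_
  chain <- c(validated = n_validated, rescreened = n_rescreened,
             candidates = n_cand, primary_hits = n_hits,
             scorable = n_scorable, screened = n_screened)
  present <- chain[!is.na(chain)]
  if (length(present) > 1 && any(diff(present) < 0)) {
    stop("funnel counts violate monotonicity: ",
         paste(sprintf("%s=%d", names(present), present), collapse = ", "),
         call. = FALSE)
  }
  out <- list(n_genes_screened = n_screened,
              n_scorable = n_scorable,
              n_primary_hits = n_hits,
              n_hits_up = n_up,
              n_hits_down = n_down,
              n_candidates = n_cand,
              n_rescreened = n_rescreened,
              n_validated = n_validated,
              validation_rate_percent = rate)
  class(out) <- "funnel_report"
  out
}

#' @export
print.funnel_report <- function(x, ...) {
  fmt <- function(v) if (is.na(v)) "NA" else format(v)
  cat("Screening funnel\n")
  cat("  genes screened:      ", fmt(x$n_genes_screened), "\n")
  cat("  scorable genes:      ", fmt(x$n_scorable), "\n")
  cat("  primary hits:        ", fmt(x$n_primary_hits),
      sprintf(" (up %s / down %s)\n", fmt(x$n_hits_up), fmt(x$n_hits_down)))
  cat("  integrated candidates:", fmt(x$n_candidates), "\n")
  cat("  rescreened:          ", fmt(x$n_rescreened), "\n")
  cat("  validated:           ", fmt(x$n_validated), "\n")
  cat("  validation rate:     ",
      if (is.na(x$validation_rate_percent)) "not applicable"
      else sprintf("%.1f%%", x$validation_rate_percent), "\n")
  invisible(x)
}

#' Funnel report as a one-row data.frame
#' @param report A `funnel_report`.
#' @return A one-row data.frame of the counts and rate.
#' @export
funnel_as_table <- function(report) {
  stopifnot(inherits(report, "funnel_report"))
  as.data.frame(unclass(report), stringsAsFactors = FALSE)
}
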