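#' Summarize well z-scores per gene across replicates
#'
#' Collects, for each sample gene, the robust z-score of its well in every
#' replicate in which that well passed QC. Replicates whose wells were
#' excluded (low cell count or degenerate plate) are dropped; genes with
#' fewer than `min_usable_replicates` usable replicates are flagged
#' unscorable and never enter the hit universe. The per-gene score used for
#' ranking is the mean of the usable replicate z-scores.
#'
#' @param wellz Well z table from [normalize_screen()] or [robust_z()].
#' @param design_genes Optional character vector of genes expected in the
#'   design; genes with no measurement at all are listed in the
#'   `missing_genes` attribute of the result (a completeness report, not an
#'   error).
#' @param min_usable_replicates Usable replicates required for a gene to be
#'   scorable (default 2).
#' @return A data.frame with one row per gene: `gene, n_replicates_used,
#'   mean_z, scorable` and a list-column `replicate_z`.
#' @export
summarize_genes <- function(wellz, design_genes = NULL,
                            min_usable_replicates = 2L) {
  samples <- wellz[wellz$role == "sample", , drop = FALSE]
  ok <- samples[samples$qc_flag == "ok" & !is.na(samples$z), , drop = FALSE]
  genes <- sort(unique(samples$gene))
  zs <- split(ok$z, factor(ok$gene, levels = genes))
  n_used <- lengths(zs)
  mean_z <- vapply(zs, function(v) if (length(v)) mean(v) else NA_real_,
                   numeric(1))
  out <- data.frame(gene = genes,
                    n_replicates_used = as.integer(n_used),
                    mean_z = unname(mean_z),
                    scorable = unname(n_used) >= min_usable_replicates,
                    stringsAsFactors = FALSE)
  out$replicate_z <- unname(zs)
  rownames(out) <- NULL
  if (!is.null(design_genes)) {
    attr(out, "missing_genes") <- setdiff(design_genes, genes)
  }
  out
}

#' Call primary hits by the replicate-concordance rule
#'
#' A gene is an `up` hit when at least `k` of its usable replicates have
#' robust z >= `t`, a `down` hit when at least `k` have z <= `-t`
#' (thresholds inclusive, as printed: deviation >= 2.0 or <= -2.0). A gene
#' satisfying both directions under a permissive configuration is called
#' `none`: a directional phenotype cannot point both ways. Unscorable genes
#' are always `none`.
#'
#' @param summaries Output of [summarize_genes()].
#' @param t Robust z threshold (default 2.0).
#' @param k Minimum concordant replicates (default 2).
#' @return `summaries` with integer columns `n_beyond_up`, `n_beyond_down`
#'   and a `hit_call` column in `up/down/none`.
#' @export
call_primary_hits <- function(summaries, t = 2.0, k = 2L) {
  stopifnot(t > 0, k >= 1L)
  n_up <- vapply(summaries$replicate_z, function(z) sum(z >= t), integer(1))
  n_dn <- vapply(summaries$replicate_z, function(z) sum(z <= -t), integer(1))
  up <- summaries$scorable & n_up >= k
  dn <- summaries$scorable & n_dn >= k
  call <- rep("none", nrow(summaries))
  call[up & !dn] <- "up"
  call[dn & !up] <- "down"
  summaries$n_beyond_up <- n_up
  summaries$n_beyond_down <- n_dn
  summaries$hit_call <- call
  summaries
}

#' Rank called hits by mean robust z
#'
#' Up-hits sorted by descending mean z, then down-hits by ascending mean z
#' (strongest phenotype first in each direction); ties broken by gene
#' identifier for a stable, reproducible order.
#'
#' @param summaries Output of [call_primary_hits()].
#' @return The hit rows (hit_call != "none") in rank order.
#' @export
rank_hits <- function(summaries) {
  if (!"hit_call" %in% names(summaries)) {
    stop("hit calls not assigned; run call_primary_hits() first", call. = FALSE)
  }
  up <- summaries[summaries$hit_call == "up", , drop = FALSE]
  dn <- summaries[summaries$hit_call == "down", , drop = FALSE]
  up <- up[order(-up$mean_z, up$gene), , drop = FALSE]
  dn <- dn[order(dn$mean_z, dn$gene), , drop = FALSE]
  out <- rbind(up, dn)
  rownames(out) <- NULL
  out
}

#' Aggregate deconvolution well z-scores into per-siRNA records
#'
#' Mirrors the primary screen's aggregation: each individual siRNA's score
#' is the mean robust z over its QC-passing replicates. The candidate's
#' primary hit direction is attached from the primary screen summaries.
#'
#' @param deconv_wellz Normalized deconvolution well table (must carry a
#'   `sirna` column; see [simulate_deconvolution()]).
#' @param primary_hits Data.frame with columns `gene` and `hit_call`
#'   (up/down) for the rescreened candidates.
#' @param n_sirnas siRNAs per gene (default 3).
#' @return A data.frame with one row per gene: `gene, primary_direction`
#'   and `sirna_z_1 .. sirna_z_<n>` (NA when every replicate of that siRNA
#'   failed QC).
#' @export
aggregate_deconvolution <- function(deconv_wellz, primary_hits, n_sirnas = 3L) {
  if (!"sirna" %in% names(deconv_wellz)) {
    stop("deconvolution well table lacks a 'sirna' column", call. = FALSE)
  }
  ok <- deconv_wellz[deconv_wellz$role == "sample" &
                       deconv_wellz$qc_flag == "ok" &
                       !is.na(deconv_wellz$z), , drop = FALSE]
  genes <- sort(unique(deconv_wellz$gene[deconv_wellz$role == "sample"]))
  zmat <- matrix(NA_real_, nrow = length(genes), ncol = n_sirnas,
                 dimnames = list(genes, NULL))
  if (nrow(ok)) {
    agg <- stats::aggregate(z ~ gene + sirna, data = ok, FUN = mean)
    zmat[cbind(match(agg$gene, genes), agg$sirna)] <- agg$z
  }
  dir <- primary_hits$hit_call[match(genes, primary_hits$gene)]
  out <- data.frame(gene = genes, primary_direction = dir,
                    stringsAsFactors = FALSE)
  for (s in seq_len(n_sirnas)) out[[paste0("sirna_z_", s)]] <- zmat[, s]
  rownames(out) <- NULL
  out
}

#' Validate deconvolution records against the primary direction
#'
#' A candidate validates when at least `m` of its individual siRNAs score
#' beyond the threshold on the same side as the primary screen phenotype:
#' z >= `t` for primary up-hits, z <= `-t` for down-hits (inclusive, as
#' printed). siRNAs whose wells all failed QC (NA score) cannot count
#' toward validation.
#'
#' @param records Output of [aggregate_deconvolution()] (columns `gene`,
#'   `primary_direction`, `sirna_z_*`). A record without a primary
#'   direction is an error: validation is direction-conditional.
#' @param t Deconvolution z threshold (default 1.6).
#' @param m Minimum validating siRNAs (default 1).
#' @return `records` with `n_validating` and logical `validated` columns.
#' @export
validate_deconvolution <- function(records, t = 1.6, m = 1L) {
  stopifnot(t > 0, m >= 1L)
  zcols <- grep("^sirna_z_", names(records), value = TRUE)
  if (!length(zcols)) stop("records carry no sirna_z_* columns", call. = FALSE)
  bad <- is.na(records$primary_direction) |
    !records$primary_direction %in% c("up", "down")
  if (any(bad)) {
    stop("record(s) without a primary hit direction: ",
         paste(utils::head(records$gene[bad], 5), collapse = ", "),
         call. = FALSE)
  }
  zmat <- as.matrix(records[, zcols, drop = FALSE])
  up <- records$primary_direction == "up"
  beyond <- matrix(FALSE, nrow(zmat), ncol(zmat))
  beyond[up, ] <- zmat[up, , drop = FALSE] >= t
  beyond[!up, ] <- zmat[!up, , drop = FALSE] <= -t
  n_val <- rowSums(beyond, na.rm = TRUE)
  records$n_validating <- as.integer(n_val)
  records$validated <- n_val >= m
  records
}
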