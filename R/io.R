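#' Well roles recognised in screen tables
#'
#' Each well on a screening plate is either a sample (one siRNA pool
#' targeting one gene), one of the plate controls, or empty. The role column
#' is authoritative; control wells additionally carry the control label
#' (NS, siLDLR, siNPC1, siKIF11) in the gene column.
#'
#' @format Character vector of the six valid roles.
#' @export
WELL_ROLES <- c("sample", "ns_control", "pos_control_npc1",
                "neg_control_ldlr", "cytotox_control_kif11", "empty")

#' Expression conditions recognised in expression tables
#' @format Character vector: vehicle control, native-LDL (cholesterol
#'   enrichment) and statin (cholesterol depletion).
#' @export
EXPR_CONDITIONS <- c("control", "nLDL", "statin")

.well_cols <- c("plate", "well", "replicate", "gene", "role",
                "valid_object_count", "mean_intensity")

.detect_sep <- function(path) {
  header <- readLines(path, n = 1L, warn = FALSE)
  if (grepl("\t", header, fixed = TRUE)) "\t" else ","
}

.read_delim <- function(path, sep = NULL) {
  if (!file.exists(path)) stop("file not found: ", path, call. = FALSE)
  if (is.null(sep)) sep <- .detect_sep(path)
  utils::read.table(path, header = TRUE, sep = sep, quote = "\"",
                    stringsAsFactors = FALSE, check.names = FALSE,
                    comment.char = "", encoding = "UTF-8")
}

.require_cols <- function(df, cols, path) {
  missing <- setdiff(cols, names(df))
  if (length(missing)) {
    stop(sprintf("%s: missing required column(s): %s",
                 path, paste(missing, collapse = ", ")), call. = FALSE)
  }
}

# data row i lives on file line i + 1 (header)
.row_err <- function(path, rows, what) {
  stop(sprintf("%s: %s in row(s) %s (file line %s)", path, what,
               paste(rows, collapse = ", "),
               paste(rows + 1L, collapse = ", ")), call. = FALSE)
}

#' Read a well-level screen measurement table
#'
#' Reads a delimited (comma or tab; auto-detected unless `sep` is given)
#' UTF-8 table with header columns `plate, well, replicate, gene, role,
#' valid_object_count, mean_intensity`. Every row is validated: the role
#' must be one of [WELL_ROLES], replicate a positive integer, the valid
#' object count a non-negative integer and the mean intensity a
#' non-negative finite number. Violations are reported with the offending
#' row number.
#'
#' @param path File path.
#' @param sep Field separator; `NULL` (default) auto-detects comma vs tab.
#' @return A data.frame of well measurements, one row per well. Extra
#'   columns (e.g. a `sirna` index in deconvolution tables) are preserved.
#' @export
read_well_table <- function(path, sep = NULL) {
  df <- .read_delim(path, sep)
  .require_cols(df, .well_cols, path)
  df$plate <- as.character(df$plate)
  df$well <- as.character(df$well)
  df$gene <- as.character(df$gene)
  df$role <- as.character(df$role)

  bad <- which(!df$role %in% WELL_ROLES)
  if (length(bad)) .row_err(path, bad, sprintf(
    "invalid role '%s'", df$role[bad[1]]))

  rep_num <- suppressWarnings(as.numeric(df$replicate))
  bad <- which(is.na(rep_num) | rep_num < 1 | rep_num != round(rep_num))
  if (length(bad)) .row_err(path, bad, "replicate must be a positive integer")
  df$replicate <- as.integer(rep_num)

  cnt <- suppressWarnings(as.numeric(df$valid_object_count))
  bad <- which(is.na(cnt) | cnt < 0 | cnt != round(cnt))
  if (length(bad)) .row_err(path, bad, "valid_object_count must be a non-negative integer")
  df$valid_object_count <- as.integer(cnt)

  mi <- suppressWarnings(as.numeric(df$mean_intensity))
  bad <- which(is.na(mi) | mi < 0 | !is.finite(mi))
  if (length(bad)) .row_err(path, bad, "mean_intensity must be non-negative and finite")
  df$mean_intensity <- mi

  df
}

.order_wells <- function(df) df[order(df$plate, df$well, df$replicate), , drop = FALSE]

#' Write a well-level screen measurement table
#'
#' Emits a header and deterministic row order (plate, then well, then
#' replicate) so that identical inputs produce byte-identical files.
#'
#' @param wells Data.frame as returned by [read_well_table()] or
#'   [simulate_screen()].
#' @param path Output path.
#' @param sep Field separator (default comma).
#' @return `path`, invisibly.
#' @export
write_well_table <- function(wells, path, sep = ",") {
  .require_cols(wells, .well_cols, "well table")
  wells <- .order_wells(wells)
  utils::write.table(wells, path, sep = sep, row.names = FALSE,
                     quote = FALSE, fileEncoding = "UTF-8")
  invisible(path)
}

#' Read a gene expression table
#'
#' Columns `gene, condition, replicate, expression`. Conditions are matched
#' case-insensitively against [EXPR_CONDITIONS] and normalised to the
#' canonical spelling. Expression values are linear-scale and must be
#' strictly positive.
#'
#' @inheritParams read_well_table
#' @return A data.frame with one row per gene x condition x replicate.
#' @export
read_expression_table <- function(path, sep = NULL) {
  df <- .read_delim(path, sep)
  .require_cols(df, c("gene", "condition", "replicate", "expression"), path)
  df$gene <- as.character(df$gene)
  cond_idx <- match(tolower(as.character(df$condition)), tolower(EXPR_CONDITIONS))
  bad <- which(is.na(cond_idx))
  if (length(bad)) .row_err(path, bad, sprintf(
    "unknown condition '%s' (expected one of %s)",
    df$condition[bad[1]], paste(EXPR_CONDITIONS, collapse = "/")))
  df$condition <- EXPR_CONDITIONS[cond_idx]

  rep_num <- suppressWarnings(as.numeric(df$replicate))
  bad <- which(is.na(rep_num) | rep_num < 1 | rep_num != round(rep_num))
  if (length(bad)) .row_err(path, bad, "replicate must be a positive integer")
  df$replicate <- as.integer(rep_num)

  ex <- suppressWarnings(as.numeric(df$expression))
  bad <- which(is.na(ex) | ex <= 0 | !is.finite(ex))
  if (length(bad)) .row_err(path, bad, "expression must be positive and finite (linear scale)")
  df$expression <- ex
  df
}

#' Write a gene expression table
#' @param expr Data.frame as returned by [read_expression_table()].
#' @inheritParams write_well_table
#' @return `path`, invisibly.
#' @export
write_expression_table <- function(expr, path, sep = ",") {
  .require_cols(expr, c("gene", "condition", "replicate", "expression"), "expression table")
  expr <- expr[order(expr$gene, expr$condition, expr$replicate), , drop = FALSE]
  utils::write.table(expr, path, sep = sep, row.names = FALSE,
                     quote = FALSE, fileEncoding = "UTF-8")
  invisible(path)
}

#' Read a gene annotation-flag table
#'
#' Columns `gene, lipid_gwas_flag`, one row per gene; the flag marks genes
#' previously associated with altered blood lipid levels or cardiovascular
#' disease in GWAS. The flag is parsed as logical (TRUE/FALSE/1/0).
#'
#' @inheritParams read_well_table
#' @return A data.frame with columns `gene` and `lipid_gwas_flag`.
#' @export
read_flag_table <- function(path, sep = NULL) {
  df <- .read_delim(path, sep)
  .require_cols(df, c("gene", "lipid_gwas_flag"), path)
  df$gene <- as.character(df$gene)
  dup <- df$gene[duplicated(df$gene)]
  if (length(dup)) stop(sprintf("%s: duplicated gene(s): %s", path,
                                paste(unique(dup), collapse = ", ")), call. = FALSE)
  flag <- as.logical(toupper(as.character(df$lipid_gwas_flag)))
  flag[df$lipid_gwas_flag %in% c("1", 1)] <- TRUE
  flag[df$lipid_gwas_flag %in% c("0", 0)] <- FALSE
  bad <- which(is.na(flag))
  if (length(bad)) .row_err(path, bad, "lipid_gwas_flag must be TRUE/FALSE or 1/0")
  data.frame(gene = df$gene, lipid_gwas_flag = flag, stringsAsFactors = FALSE)
}

#' Write a gene annotation-flag table
#' @param flags Data.frame with columns `gene`, `lipid_gwas_flag`.
#' @inheritParams write_well_table
#' @return `path`, invisibly.
#' @export
write_flag_table <- function(flags, path, sep = ",") {
  .require_cols(flags, c("gene", "lipid_gwas_flag"), "flag table")
  flags <- flags[order(flags$gene), , drop = FALSE]
  utils::write.table(flags, path, sep = sep, row.names = FALSE,
                     quote = FALSE, fileEncoding = "UTF-8")
  invisible(path)
}

#' Write a generic result table (z-scores, hits, DE results, candidates)
#'
#' Header + deterministic row order; used by [run_pipeline()] for every
#' derived table so reruns are byte-identical.
#'
#' @param df Any data.frame.
#' @param path Output path.
#' @param sep Field separator (default comma).
#' @return `path`, invisibly.
#' @export
write_result_table <- function(df, path, sep = ",") {
  utils::write.table(df, path, sep = sep, row.names = FALSE,
                     quote = FALSE, fileEncoding = "UTF-8")
  invisible(path)
}

#' Well identifiers for a plate format
#'
#' Standard microtiter naming: row letter plus zero-padded column, "A01"
#' through "P24" for 384-well and "A01" through "H12" for 96-well plates.
#'
#' @param wells_per_plate 96 or 384.
#' @return Character vector of well ids in row-major order.
#' @export
well_ids <- function(wells_per_plate = 384L) {
  dims <- switch(as.character(wells_per_plate),
                 "96" = c(8L, 12L), "384" = c(16L, 24L),
                 stop("wells_per_plate must be 96 or 384", call. = FALSE))
  rows <- LETTERS[seq_len(dims[1])]
  as.vector(t(outer(rows, sprintf("%02d", seq_len(dims[2])), paste0)))
}
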