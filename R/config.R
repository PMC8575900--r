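#' Pipeline configuration
#'
#' Construct the analysis configuration holding every threshold the funnel
#' uses. Defaults follow the screen's published operating point: wells with
#' fewer than 500 valid objects (segmented nuclei) are excluded as cytotoxic,
#' primary hits require two or more replicates at robust z beyond +/-2.0,
#' deconvolution validation requires at least one of three individual siRNAs
#' beyond +/-1.6 in the primary direction, and expression modulation requires
#' a two-sided Student t-test P <= 0.05 with signed fold-change magnitude
#' >= 1.1.
#'
#' @param min_valid_objects Minimum valid object (cell) count for a well to
#'   pass QC; wells with fewer cells are excluded (default 500).
#' @param mad_constant Consistency constant applied to the plate MAD. The
#'   default 1.0 leaves the scale in raw MAD units so that the hit rule
#'   "2 MAD away" is literally `|z| >= 2`; set 1.4826 for a
#'   Gaussian-consistent scale.
#' @param primary_z_threshold Robust z threshold for the primary screen
#'   (default 2.0, inclusive).
#' @param primary_min_replicates Replicates required beyond the threshold in
#'   the same direction to call a hit (default 2).
#' @param deconv_z_threshold Robust z threshold for deconvolution validation
#'   (default 1.6, inclusive).
#' @param deconv_min_sirnas Individual siRNAs required beyond the threshold
#'   on the primary-hit side (default 1).
#' @param de_alpha Significance level for the expression t-test (default
#'   0.05, raw p-values; see `de_fdr`).
#' @param de_fc_threshold Signed fold-change magnitude threshold (default
#'   1.1; must be > 1).
#' @param de_log_scale Run the t-test on log2 expression instead of the
#'   linear scale (default FALSE, matching an unpaired Student t on linear
#'   intensities).
#' @param de_fdr Apply Benjamini-Hochberg correction before thresholding
#'   p-values (default FALSE: raw P <= alpha, as in the original analysis).
#' @param center_scope Which wells define the plate center and scale:
#'   `"plate"` (default; all QC-passing, non-empty wells, samples and
#'   controls alike, i.e. plate-median normalization) or `"ns_controls"`
#'   (non-silencing control wells only).
#' @param min_wells_per_plate Minimum QC-passing wells for a plate to be
#'   usable (default 8).
#' @param integration_policy How expression modulation and GWAS flags
#'   combine for candidate selection: `"or"` (default, "and/or" in the
#'   funnel), `"and"`, or `"expression_only"`.
#' @param random_seed Integer seed recorded with the configuration.
#'
#' @return An object of class `screen_config` (a named list).
#' @examples
#' cfg <- screen_config()
#' cfg$primary_z_threshold
#' @export
screen_config <- function(min_valid_objects = 500L,
                          mad_constant = 1.0,
                          primary_z_threshold = 2.0,
                          primary_min_replicates = 2L,
                          deconv_z_threshold = 1.6,
                          deconv_min_sirnas = 1L,
                          de_alpha = 0.05,
                          de_fc_threshold = 1.1,
                          de_log_scale = FALSE,
                          de_fdr = FALSE,
                          center_scope = c("plate", "ns_controls"),
                          min_wells_per_plate = 8L,
                          integration_policy = c("or", "and", "expression_only"),
                          random_seed = 1L) {
  center_scope <- match.arg(center_scope)
  integration_policy <- match.arg(integration_policy)
  cfg <- list(
    min_valid_objects = as.integer(min_valid_objects),
    mad_constant = as.numeric(mad_constant),
    primary_z_threshold = as.numeric(primary_z_threshold),
    primary_min_replicates = as.integer(primary_min_replicates),
    deconv_z_threshold = as.numeric(deconv_z_threshold),
    deconv_min_sirnas = as.integer(deconv_min_sirnas),
    de_alpha = as.numeric(de_alpha),
    de_fc_threshold = as.numeric(de_fc_threshold),
    de_log_scale = isTRUE(de_log_scale),
    de_fdr = isTRUE(de_fdr),
    center_scope = center_scope,
    min_wells_per_plate = as.integer(min_wells_per_plate),
    integration_policy = integration_policy,
    random_seed = as.integer(random_seed)
  )
  validate_screen_config(cfg)
  class(cfg) <- "screen_config"
  cfg
}

validate_screen_config <- function(cfg) {
  stopifnot(
    cfg$min_valid_objects >= 0L,
    cfg$mad_constant > 0,
    cfg$primary_z_threshold > 0,
    cfg$primary_min_replicates >= 1L,
    cfg$deconv_z_threshold > 0,
    cfg$deconv_min_sirnas >= 1L,
    cfg$de_alpha > 0, cfg$de_alpha < 1,
    cfg$min_wells_per_plate >= 1L
  )
  if (!(cfg$de_fc_threshold > 1)) {
    stop("de_fc_threshold must be > 1 (signed fold-change units)", call. = FALSE)
  }
  invisible(cfg)
}

#' @export
print.screen_config <- function(x, ...) {
  cat("screen_config\n")
  for (k in names(x)) cat(sprintf("  %-24s %s\n", k, format(x[[k]])))
  invisible(x)
}

# fields that are logical / character / numeric when read from text
.config_field_parsers <- list(
  min_valid_objects = as.integer,
  mad_constant = as.numeric,
  primary_z_threshold = as.numeric,
  primary_min_replicates = as.integer,
  deconv_z_threshold = as.numeric,
  deconv_min_sirnas = as.integer,
  de_alpha = as.numeric,
  de_fc_threshold = as.numeric,
  de_log_scale = function(v) as.logical(toupper(v)),
  de_fdr = function(v) as.logical(toupper(v)),
  center_scope = as.character,
  min_wells_per_plate = as.integer,
  integration_policy = as.character,
  random_seed = as.integer
)

#' Load a pipeline configuration from a flat key/value file
#'
#' The file holds one `key: value` (or `key = value`) pair per line; blank
#' lines and lines starting with `#` are ignored. Keys absent from the file
#' take the [screen_config()] defaults. Unknown keys are an error, never
#' silently ignored, so a typo cannot quietly revert a threshold to its
#' default.
#'
#' @param path Path to the configuration file. An empty file yields the full
#'   default configuration.
#' @param quiet Suppress the echo of the resolved configuration
#'   (default TRUE).
#' @return A `screen_config` object.
#' @export
load_config <- function(path, quiet = TRUE) {
  if (!file.exists(path)) stop("config file not found: ", path, call. = FALSE)
  lines <- readLines(path, warn = FALSE)
  lines <- trimws(lines)
  lines <- lines[nzchar(lines) & !startsWith(lines, "#")]
  overrides <- list()
  for (i in seq_along(lines)) {
    m <- regmatches(lines[i], regexec("^([A-Za-z0-9_.]+)\\s*[:=]\\s*(.*)$", lines[i]))[[1]]
    if (length(m) != 3L) {
      stop(sprintf("config line %d is not 'key: value': %s", i, lines[i]), call. = FALSE)
    }
    key <- m[2]; val <- trimws(m[3])
    if (!key %in% names(.config_field_parsers)) {
      stop(sprintf("unknown config key '%s' (line %d)", key, i), call. = FALSE)
    }
    overrides[[key]] <- .config_field_parsers[[key]](val)
  }
  cfg <- do.call(screen_config, overrides)
  if (!quiet) print(cfg)
  cfg
}
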