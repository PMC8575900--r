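#' Cytotoxicity QC filter on valid object counts
#'
#' Partitions wells by the valid-object (cell) count: a well is excluded
#' if and only if it detected fewer than `min_valid_objects` cells, the
#' screen's proxy for a cytotoxic knockdown. Excluded wells are flagged
#' `excluded_low_cell_count` and contribute to no downstream statistic.
#' Empty wells are set aside regardless of the threshold.
#'
#' @param wells Well measurement table.
#' @param min_valid_objects Exclusion threshold; a well passes iff
#'   `valid_object_count >= min_valid_objects` (default 500, i.e. "fewer
#'   than 500 cells" fails).
#' @return A list with data.frames `passing` and `excluded`; `excluded`
#'   carries a `qc_flag` column.
#' @export
qc_filter <- function(wells, min_valid_objects = 500L) {
  stopifnot(min_valid_objects >= 0)
  measurable <- wells[wells$role != "empty", , drop = FALSE]
  fail <- measurable$valid_object_count < min_valid_objects
  excluded <- measurable[fail, , drop = FALSE]
  if (nrow(excluded)) excluded$qc_flag <- "excluded_low_cell_count"
  else excluded$qc_flag <- character(0)
  list(passing = measurable[!fail, , drop = FALSE], excluded = excluded)
}

#' Per-plate robust location and scale
#'
#' For each plate, the center is the median of `mean_intensity` over the
#' QC-passing, non-empty wells and the scale is the median absolute
#' deviation about that center times the consistency constant
#' `mad_constant`. With the default `center_scope = "plate"` samples and
#' controls alike enter the statistics (plate-median normalization, with
#' the randomly distributed non-silencing controls included by
#' construction); `"ns_controls"` restricts center and scale to the
#' non-silencing control wells. Medians of even-sized samples are the mean
#' of the two central order statistics.
#'
#' @param passing QC-passing well table (see [qc_filter()]).
#' @param mad_constant Consistency constant c multiplying the raw MAD
#'   (default 1.0; 1.4826 gives a Gaussian-consistent scale).
#' @param center_scope `"plate"` or `"ns_controls"`.
#' @param min_wells_per_plate Minimum QC-passing wells for a plate to be
#'   usable; plates under the floor raise an error naming them.
#' @param excluded Optional excluded-well table, used only to report
#'   `n_qc_fail` per plate.
#' @return A data.frame with one row per plate: `plate, center, scale,
#'   mad_constant, n_qc_pass, n_qc_fail, degenerate` (`degenerate` is TRUE
#'   when the scale is zero).
#' @export
compute_plate_stats <- function(passing, mad_constant = 1.0,
                                center_scope = c("plate", "ns_controls"),
                                min_wells_per_plate = 8L,
                                excluded = NULL) {
  center_scope <- match.arg(center_scope)
  stopifnot(mad_constant > 0)
  passing <- passing[passing$role != "empty", , drop = FALSE]
  if (!nrow(passing)) stop("no QC-passing wells to normalize", call. = FALSE)
  plates <- sort(unique(passing$plate))
  n_pass <- table(factor(passing$plate, levels = plates))
  short <- plates[n_pass < min_wells_per_plate]
  if (length(short)) {
    stop("plate(s) with fewer than ", min_wells_per_plate,
         " QC-passing wells, unusable: ", paste(short, collapse = ", "),
         call. = FALSE)
  }
  scope <- if (center_scope == "ns_controls") {
    passing[passing$role == "ns_control", , drop = FALSE]
  } else passing
  missing_scope <- setdiff(plates, unique(scope$plate))
  if (length(missing_scope)) {
    stop("no wells in center_scope '", center_scope, "' on plate(s): ",
         paste(missing_scope, collapse = ", "), call. = FALSE)
  }
  by_plate <- split(scope$mean_intensity, factor(scope$plate, levels = plates))
  center <- vapply(by_plate, stats::median, numeric(1))
  scale <- vapply(seq_along(by_plate), function(i) {
    stats::median(abs(by_plate[[i]] - center[i])) * mad_constant
  }, numeric(1))
  n_fail <- if (is.null(excluded) || !nrow(excluded)) {
    integer(length(plates))
  } else {
    as.integer(table(factor(excluded$plate, levels = plates)))
  }
  data.frame(plate = plates,
             center = unname(center),
             scale = unname(scale),
             mad_constant = mad_constant,
             n_qc_pass = as.integer(n_pass),
             n_qc_fail = n_fail,
             degenerate = unname(scale) == 0,
             stringsAsFactors = FALSE)
}

#' Robust z-scores from plate statistics
#'
#' Converts each QC-passing well to `z = (intensity - center) / scale` using
#' its plate's robust statistics. Wells on degenerate plates (zero scale)
#' get `qc_flag = "excluded_degenerate_scale"` and no z value. An intensity
#' exactly at the plate center maps to z = 0, and the transform is invariant
#' under per-plate affine rescaling of the raw intensities.
#'
#' @param wells QC-passing well table.
#' @param plate_stats Output of [compute_plate_stats()]; an error names any
#'   plate present in `wells` but absent from the statistics.
#' @return The input table with `z` and `qc_flag` columns appended
#'   (`qc_flag = "ok"` where z is defined).
#' @export
robust_z <- function(wells, plate_stats) {
  wells <- wells[wells$role != "empty", , drop = FALSE]
  idx <- match(wells$plate, plate_stats$plate)
  if (anyNA(idx)) {
    stop("no plate statistics for plate(s): ",
         paste(unique(wells$plate[is.na(idx)]), collapse = ", "),
         call. = FALSE)
  }
  degen <- plate_stats$degenerate[idx]
  z <- (wells$mean_intensity - plate_stats$center[idx]) / plate_stats$scale[idx]
  z[degen] <- NA_real_
  wells$z <- z
  wells$qc_flag <- ifelse(degen, "excluded_degenerate_scale", "ok")
  wells
}

#' Normalize a screen: QC filter, plate statistics, robust z
#'
#' Convenience wrapper chaining [qc_filter()], [compute_plate_stats()] and
#' [robust_z()] under a single [screen_config()].
#'
#' @param wells Well measurement table.
#' @param config A [screen_config()].
#' @return A list with `wellz` (all measurable wells with `z` and `qc_flag`;
#'   QC-excluded wells have `z = NA`) and `plate_stats`.
#' @export
normalize_screen <- function(wells, config = screen_config()) {
  qc <- qc_filter(wells, config$min_valid_objects)
  ps <- compute_plate_stats(qc$passing,
                            mad_constant = config$mad_constant,
                            center_scope = config$center_scope,
                            min_wells_per_plate = config$min_wells_per_plate,
                            excluded = qc$excluded)
  scored <- robust_z(qc$passing, ps)
  excl <- qc$excluded
  if (nrow(excl)) {
    excl$z <- NA_real_
    excl <- excl[, names(scored), drop = FALSE]
    wellz <- rbind(scored, excl)
  } else {
    wellz <- scored
  }
  wellz <- wellz[order(wellz$plate, wellz$well, wellz$replicate), , drop = FALSE]
  rownames(wellz) <- NULL
  list(wellz = wellz, plate_stats = ps)
}
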