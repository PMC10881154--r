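# Readers and writers for the pipeline's CSV dialects. All files are
# header-row CSV, UTF-8, "." decimal separator (spreadsheet-style ImageJ
# exports). Readers validate invariants and cite offending row numbers;
# malformed input is never silently coerced.

read_checked <- function(path, required, validator = NULL) {
  if (!file.exists(path)) stop("file not found: ", path, call. = FALSE)
  df <- utils::read.csv(path, stringsAsFactors = FALSE)
  missing_cols <- setdiff(required, names(df))
  if (length(missing_cols))
    stop(sprintf("%s: missing column%s %s", basename(path),
                 if (length(missing_cols) > 1) "s" else "",
                 paste(missing_cols, collapse = ", ")), call. = FALSE)
  if (!is.null(validator)) validator(df)
  df
}

#' Read spindle-pole annotations
#'
#' Expected columns: `division_id, condition, mouse_id, ax, ay, bx, by`
#' plus either `ref_dx, ref_dy` (explicit basal reference) or `trace_id`
#' (link into a trace file).
#' @param path CSV path.
#' @return validated data frame.
#' @export
read_angle_annotations <- function(path) {
  read_checked(path, c("division_id", "condition", "mouse_id", "ax", "ay", "bx", "by"),
    function(df) {
      coincident <- which(df$ax == df$bx & df$ay == df$by)
      if (length(coincident)) abort_rows("coincident spindle poles", coincident)
      if (!("trace_id" %in% names(df)) && !all(c("ref_dx", "ref_dy") %in% names(df)))
        stop("annotations need either ref_dx/ref_dy or trace_id", call. = FALSE)
    })
}

#' Read basement-membrane traces
#' Expected columns: `trace_id, point_index, x, y`.
#' @param path CSV path.
#' @return validated data frame.
#' @export
read_traces <- function(path) {
  read_checked(path, c("trace_id", "point_index", "x", "y"), function(df) {
    bad <- which(!is.finite(df$x) | !is.finite(df$y))
    if (length(bad)) abort_rows("non-finite trace coordinates", bad)
    n_per <- table(df$trace_id)
    if (any(n_per < 2)) stop("every trace needs >= 2 points", call. = FALSE)
  })
}

#' Read per-division angle tables
#' Expected columns: `division_id, condition, mouse_id, angle_deg`.
#' @param path CSV path.
#' @return validated data frame.
#' @export
read_angles <- function(path) {
  read_checked(path, c("division_id", "condition", "mouse_id", "angle_deg"),
    function(df) {
      bad <- which(!is.finite(df$angle_deg) | df$angle_deg < 0 | df$angle_deg > 90)
      if (length(bad)) abort_rows("angle outside [0, 90] degrees", bad)
    })
}

#' Read section count tables
#' Expected columns: `section_id, condition, mouse_id, layer, marker_class,
#' count`.
#' @param path CSV path.
#' @return validated data frame.
#' @export
read_counts <- function(path) {
  read_checked(path, c("section_id", "condition", "mouse_id", "layer", "marker_class", "count"),
    function(df) {
      bad <- which(!is.finite(df$count) | df$count < 0 | df$count != round(df$count))
      if (length(bad)) abort_rows("counts must be non-negative integers", bad)
      bad_layer <- which(!df$layer %in% c("basal", "spinous", "granular_cornified"))
      if (length(bad_layer)) abort_rows("unknown layer label", bad_layer)
    })
}

#' Read section geometry tables
#' Expected columns: `section_id, bm_length_um, tissue_span_um`.
#' @param path CSV path.
#' @return validated data frame.
#' @export
read_geometry <- function(path) {
  read_checked(path, c("section_id", "bm_length_um", "tissue_span_um"),
    function(df) {
      bad <- which(!is.finite(df$bm_length_um) | df$bm_length_um <= 0 |
                   !is.finite(df$tissue_span_um) | df$tissue_span_um <= 0)
      if (length(bad)) abort_rows("section lengths must be positive", bad)
    })
}

#' Read tumor tables
#' Expected columns: `mouse_id, genotype, site, tumor_index, volume_mm3`
#' (optional `eyelids_affected`).
#' @param path CSV path.
#' @return validated data frame.
#' @export
read_tumors <- function(path) {
  read_checked(path, c("mouse_id", "genotype", "site", "tumor_index", "volume_mm3"),
    function(df) {
      bad <- which(!is.na(df$volume_mm3) & df$volume_mm3 < 0)
      if (length(bad)) abort_rows("tumor volumes must be >= 0", bad)
    })
}

#' Read live-imaging track tables
#' Expected columns: `division_id, condition, angle_t0, angle_t60`.
#' @param path CSV path.
#' @return validated data frame.
#' @export
read_tracks <- function(path) {
  read_checked(path, c("division_id", "condition", "angle_t0", "angle_t60"),
    function(df) {
      bad <- which(!is.finite(df$angle_t0) | df$angle_t0 < 0 | df$angle_t0 > 90 |
                   (!is.na(df$angle_t60) & (df$angle_t60 < 0 | df$angle_t60 > 90)))
      if (length(bad)) abort_rows("track angles outside [0, 90] degrees", bad)
    })
}

#' Read per-frame daughter-layer tables
#' Expected columns: `division_id, daughter_id, frame, layer`.
#' @param path CSV path.
#' @return validated data frame.
#' @export
read_frames <- function(path) {
  read_checked(path, c("division_id", "daughter_id", "frame", "layer"),
    function(df) {
      bad <- which(!df$layer %in% c("basal", "suprabasal"))
      if (length(bad)) abort_rows("layer must be basal or suprabasal", bad)
    })
}

#' Write a table as CSV (header row, UTF-8, unrounded numbers)
#' @param df data frame.
#' @param path output CSV path; parent directories are created.
#' @return `path`, invisibly.
#' @export
write_table <- function(df, path) {
  dir.create(dirname(path), recursive = TRUE, showWarnings = FALSE)
  utils::write.csv(df, path, row.names = FALSE)
  invisible(path)
}

#' Write a summary object as JSON
#' @param x a list-like summary (classes are dropped).
#' @param path output path.
#' @return `path`, invisibly.
#' @export
write_json_summary <- function(x, path) {
  dir.create(dirname(path), recursive = TRUE, showWarnings = FALSE)
  jsonlite::write_json(unclass(x), path, auto_unbox = TRUE, digits = NA, pretty = TRUE)
  invisible(path)
}
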