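# Live-imaging division-track classification. Explants are imaged every
# 5 min; angles are measured at anaphase onset (t0) and 60 min later (t60),
# and each daughter carries a per-frame layer label (basal / suprabasal).

FRAME_MIN <- 5

#' Classify t0 -> t60 angle resolution of a division
#'
#' Live-imaged divisions are planar when their angle is at or below the
#' planar threshold (default 20 degrees, the live-imaging planar criterion,
#' which is distinct from the 30-degree fixed-tissue bin). A division that
#' starts non-planar is `resolved` when its t60 angle has come down to the
#' planar range, `persistent` when it is still above threshold at t60, and
#' `censored` when no t60 measurement exists. Divisions planar at onset are
#' reported as `planar_at_onset`.
#'
#' @param angle_t0 angle at anaphase onset, degrees; may be a vector.
#' @param angle_t60 angle 60 min later; NA when censored.
#' @param planar_threshold planar criterion in degrees (default 20).
#' @return factor with levels `planar_at_onset`, `resolved`, `persistent`,
#'   `censored`.
#' @export
t0_t60_resolution <- function(angle_t0, angle_t60, planar_threshold = 20) {
  if (anyNA(angle_t0)) stop("angle_t0 must be present for every track", call. = FALSE)
  if (any(angle_t0 < 0 | angle_t0 > 90, na.rm = TRUE) ||
      any(angle_t60 < 0 | angle_t60 > 90, na.rm = TRUE))
    stop("angles must lie in [0, 90] degrees", call. = FALSE)
  out <- ifelse(angle_t0 <= planar_threshold, "planar_at_onset",
         ifelse(is.na(angle_t60), "censored",
         ifelse(angle_t60 <= planar_threshold, "resolved", "persistent")))
  factor(out, levels = c("planar_at_onset", "resolved", "persistent", "censored"))
}

#' Classify basal reintegration of suprabasally positioned daughters
#'
#' After a non-planar division one daughter can be positioned above the
#' basal layer; some of these cells move down and realign with the basal
#' layer hours after mitosis. A track is `reintegrated` when a suprabasal
#' daughter's layer label becomes basal within the observation window and
#' stays basal to the end of the track; `retained` when the track spans at
#' least the window with no such transition; `censored` when the track ends
#' before the window without a transition.
#'
#' @param frames data frame of per-frame labels for one division's
#'   daughters: columns `daughter_id`, `frame` (5-min frames) and `layer`
#'   (`"basal"` or `"suprabasal"`).
#' @param window_h observation window in hours (default 6; tracked cells
#'   were followed for more than 6 h).
#' @return `"reintegrated"`, `"retained"` or `"censored"`.
#' @export
classify_reintegration <- function(frames, window_h = 6) {
  fr <- as.data.frame(frames)
  if (!all(c("daughter_id", "frame", "layer") %in% names(fr)))
    stop("frames must have columns daughter_id, frame, layer", call. = FALSE)
  window_frames <- window_h * 60 / FRAME_MIN
  per_daughter <- lapply(split(fr, fr$daughter_id), function(d) {
    d <- d[order(d$frame), ]
    if (d$layer[1] != "suprabasal") return(NULL) # basal daughters are not at issue
    span <- d$frame[length(d$frame)] - d$frame[1]
    basal <- d$layer == "basal"
    # first switch to basal after which the cell stays basal
    stay <- rev(cumprod(rev(basal))) == 1
    idx <- which(stay)[1]
    if (!is.na(idx) && (d$frame[idx] - d$frame[1]) <= window_frames) return("reintegrated")
    if (span >= window_frames) return("retained")
    "censored"
  })
  per_daughter <- unlist(per_daughter)
  if (is.null(per_daughter))
    stop("no initially suprabasal daughter: reintegration is not assessable", call. = FALSE)
  if (any(per_daughter == "reintegrated")) return("reintegrated")
  if (any(per_daughter == "retained")) return("retained")
  "censored"
}

#' Classify a table of live-imaging division tracks
#'
#' Applies [t0_t60_resolution()] to every track and
#' [classify_reintegration()] to every track with an initially suprabasal
#' daughter.
#'
#' @param tracks data frame with columns `division_id`, `angle_t0`,
#'   `angle_t60` (NA allowed).
#' @param frames long data frame `division_id`, `daughter_id`, `frame`,
#'   `layer`.
#' @param planar_threshold,window_h see the per-track classifiers.
#' @return `tracks` with added columns `resolution` and `reintegration`
#'   (NA where no suprabasal daughter exists).
#' @export
classify_tracks <- function(tracks, frames = NULL, planar_threshold = 20, window_h = 6) {
  tr <- as.data.frame(tracks)
  tr$resolution <- t0_t60_resolution(tr$angle_t0, tr$angle_t60, planar_threshold)
  tr$reintegration <- NA_character_
  if (!is.null(frames) && nrow(frames) > 0) {
    by_division <- split(as.data.frame(frames), frames$division_id)
    cls <- vapply(by_division, function(f) {
      has_suprabasal <- any(vapply(split(f, f$daughter_id), function(d)
        d$layer[order(d$frame)][1] == "suprabasal", TRUE))
      if (has_suprabasal) classify_reintegration(f, window_h) else NA_character_
    }, "")
    idx <- match(tr$division_id, names(cls))
    tr$reintegration <- ifelse(is.na(idx), NA_character_, cls[idx])
  }
  tr
}
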