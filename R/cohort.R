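# Tumor-cohort summaries. Inputs are one row per tumor (mouse_id, genotype,
# site, volume_mm3, optionally eyelids_affected) plus a mouse roster so that
# tumor-free animals enter the denominators.

#' Tumor incidence at a body site
#' @param tumors data frame of tumors with columns `mouse_id`, `site`.
#' @param mice data frame with column `mouse_id` listing every animal in the
#'   cohort (tumor-free animals included).
#' @param site body site label (`snout`, `eyelid`, `paw`); NULL = any site.
#' @return percentage of mice with at least one tumor at the site.
#' @export
incidence <- function(tumors, mice, site = NULL) {
  if (nrow(mice) < 1) stop("empty cohort", call. = FALSE)
  tt <- tumors[!is.na(tumors$volume_mm3), ]
  if (!is.null(site)) tt <- tt[tt$site == site, ]
  100 * sum(mice$mouse_id %in% tt$mouse_id) / nrow(mice)
}

#' Per-mouse tumor burden
#'
#' Burden is the summed tumor volume of one animal at a site; animals with
#' no tumors have burden 0.
#'
#' @param volumes numeric vector of tumor volumes (mm³) for one mouse;
#'   may be empty.
#' @return total volume in mm³.
#' @export
burden <- function(volumes) {
  volumes <- volumes[!is.na(volumes)]
  if (any(volumes < 0)) stop("volumes must be >= 0", call. = FALSE)
  sum(volumes)
}

#' Fold difference between two summary values
#' @param value_a numerator value.
#' @param value_b denominator (comparison-group) value, non-zero.
#' @param rounding `"none"` or `"nearest_int"`.
#' @return the ratio `value_a / value_b`, optionally rounded.
#' @export
fold_change <- function(value_a, value_b, rounding = c("none", "nearest_int")) {
  rounding <- match.arg(rounding)
  if (value_b == 0) stop("zero denominator in fold change", call. = FALSE)
  r <- value_a / value_b
  if (rounding == "nearest_int") round(r) else r
}

#' Cohort summary per genotype and site
#'
#' Per-mouse tumor counts and burdens are formed first (tumor-free mice
#' contribute count 0 and burden 0), then summarized over the cohort. The
#' zero-inclusive mean burden is the default reading; the tumor-bearing-only
#' mean is reported alongside.
#'
#' @param tumors tumor table (`mouse_id`, `genotype`, `site`, `volume_mm3`;
#'   rows with NA volume mark tumor-free mice and are ignored as tumors).
#' @param mice roster (`mouse_id`, `genotype`).
#' @param site site label; NULL pools all sites.
#' @return data frame, one row per genotype: `n_mice`, `incidence_pct`,
#'   `mean_tumor_count`, `max_tumor_count`, `mean_burden_mm3` (zero-
#'   inclusive), `mean_burden_affected_mm3`, `largest_tumor_mm3`.
#' @export
cohort_summary <- function(tumors, mice, site = NULL) {
  tumors <- as.data.frame(tumors); mice <- as.data.frame(mice)
  tt <- tumors[!is.na(tumors$volume_mm3), ]
  if (!is.null(site)) tt <- tt[tt$site == site, ]
  out <- do.call(rbind, lapply(split(mice, mice$genotype), function(mm) {
    tg <- tt[tt$mouse_id %in% mm$mouse_id, ]
    counts <- vapply(mm$mouse_id, function(id) sum(tg$mouse_id == id), 0)
    burdens <- vapply(mm$mouse_id, function(id) burden(tg$volume_mm3[tg$mouse_id == id]), 0)
    data.frame(genotype = mm$genotype[1], n_mice = nrow(mm),
               incidence_pct = 100 * mean(counts > 0),
               mean_tumor_count = mean(counts),
               max_tumor_count = max(counts),
               mean_burden_mm3 = mean(burdens),
               mean_burden_affected_mm3 = if (any(counts > 0)) mean(burdens[counts > 0]) else 0,
               largest_tumor_mm3 = if (nrow(tg) > 0) max(tg$volume_mm3) else 0)
  }))
  rownames(out) <- NULL
  attr(out, "burden_mean") <- "zero-inclusive over all mice (affected-only reported alongside)"
  out
}
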