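# Tissue morphometry from per-section count annotations. Counts are stored
# long: one row per (section, layer, marker_class); the marker_class "total"
# is the layer's cell total. Geometry per section: basement-membrane arc
# length and straight-line tissue span, both in micrometres.

#' Cells per micrometre of basement membrane
#' @param count non-negative cell count.
#' @param bm_length basement-membrane length in µm, > 0.
#' @return density in cells/µm.
#' @export
cell_density <- function(count, bm_length) {
  if (any(bm_length <= 0)) stop("bm_length must be > 0", call. = FALSE)
  if (any(count < 0)) stop("counts must be >= 0", call. = FALSE)
  count / bm_length
}

#' Tissue folding ratio
#'
#' Basement-membrane arc length divided by the straight-line tissue span;
#' a perfectly flat membrane gives 1.
#' @param bm_length,tissue_span lengths in µm, both > 0.
#' @return dimensionless ratio.
#' @export
tissue_folding <- function(bm_length, tissue_span) {
  if (any(bm_length <= 0) || any(tissue_span <= 0))
    stop("lengths must be > 0", call. = FALSE)
  bm_length / tissue_span
}

#' Marker-positive percentage of a layer
#' @param positive_count marker-positive cells, `0 <= positive <= total`.
#' @param layer_total layer cell total, > 0.
#' @return percentage in `[0, 100]`.
#' @export
marker_fraction <- function(positive_count, layer_total) {
  if (any(layer_total <= 0)) stop("layer_total must be > 0", call. = FALSE)
  if (any(positive_count < 0)) stop("counts must be >= 0", call. = FALSE)
  if (any(positive_count > layer_total))
    stop("inconsistent annotation: positive count exceeds layer total", call. = FALSE)
  100 * positive_count / layer_total
}

#' Rare-event frequency per micrometre of basement membrane
#'
#' Rare events (e.g. TUNEL+ cells, proliferative KRT5- Ki67+ spinous cells)
#' are counted per µm of basement membrane. Pooling across sections sums
#' counts and lengths before dividing — never the mean of per-section
#' ratios.
#'
#' @param event_count event counts, one per section (or a single total).
#' @param bm_length matching basement-membrane lengths in µm.
#' @return pooled frequency in events/µm.
#' @export
rare_event_frequency <- function(event_count, bm_length) {
  if (any(bm_length <= 0)) stop("bm_length must be > 0", call. = FALSE)
  if (any(event_count < 0)) stop("counts must be >= 0", call. = FALSE)
  sum(event_count) / sum(bm_length)
}

#' Arc length of a polyline trace
#' @param trace two-column matrix/data frame of ordered vertices (µm).
#' @return total length in µm.
#' @export
polyline_length <- function(trace) {
  pts <- as.matrix(trace)
  sum(sqrt(rowSums(diff(pts)^2)))
}

count_of <- function(counts, layer, marker) {
  v <- counts$count[counts$layer == layer & counts$marker_class == marker]
  if (length(v) == 0) 0 else sum(v)
}

#' Morphometry summary for one or more pooled tissue sections
#'
#' Computes layer densities, the folding ratio, marker fractions and
#' rare-event frequencies from long-format counts plus section geometry.
#' When several sections are passed they are pooled: counts and lengths are
#' summed before any ratio is formed, so two identical sections give the
#' same summary as one.
#'
#' @param counts data frame with columns `section_id`, `layer`
#'   (`basal`, `spinous`, `granular_cornified`), `marker_class` and `count`.
#'   `marker_class == "total"` rows carry layer totals.
#' @param geometry data frame with columns `section_id`, `bm_length_um`,
#'   `tissue_span_um`.
#' @return `morphometry_summary` list: `basal_density`, `spinous_density`
#'   (cells/µm), `folding`, `krt10_basal_fraction`, `ki67_basal_fraction`,
#'   `phh3_basal_fraction` (percent), and `rare_event_frequency_by_class`
#'   (events/µm) for proliferative-spinous and per-layer TUNEL classes.
#' @export
summarize_section <- function(counts, geometry) {
  counts <- as.data.frame(counts)
  geometry <- as.data.frame(geometry)
  ids <- unique(counts$section_id)
  geometry <- geometry[geometry$section_id %in% ids, ]
  if (nrow(geometry) == 0) stop("no geometry rows for the given sections", call. = FALSE)
  bm <- sum(geometry$bm_length_um)
  span <- sum(geometry$tissue_span_um)
  basal_total <- count_of(counts, "basal", "total")
  spinous_total <- count_of(counts, "spinous", "total")
  frac <- function(marker) {
    pos <- count_of(counts, "basal", marker)
    if (basal_total == 0) 0 else marker_fraction(pos, basal_total)
  }
  rare <- c(
    proliferative_spinous = rare_event_frequency(
      count_of(counts, "spinous", "Ki67+KRT10+KRT5-"), bm),
    tunel_basal = rare_event_frequency(count_of(counts, "basal", "TUNEL+"), bm),
    tunel_suprabasal = rare_event_frequency(count_of(counts, "spinous", "TUNEL+"), bm),
    tunel_granular_cornified = rare_event_frequency(
      count_of(counts, "granular_cornified", "TUNEL+"), bm))
  structure(list(
    basal_density = cell_density(basal_total, bm),
    spinous_density = cell_density(spinous_total, bm),
    folding = tissue_folding(bm, span),
    krt10_basal_fraction = frac("KRT10+"),
    ki67_basal_fraction = frac("Ki67+"),
    phh3_basal_fraction = frac("pHH3+"),
    rare_event_frequency_by_class = rare,
    bm_length_um = bm, tissue_span_um = span,
    n_sections = length(ids)), class = "morphometry_summary")
}

#' Per-animal and per-condition morphometry
#'
#' The unit of replication is the animal: sections are pooled within each
#' mouse (summed counts over summed lengths), and condition-level values are
#' means of the per-animal values.
#'
#' @param counts long count table with `condition` and `mouse_id` columns in
#'   addition to the [summarize_section()] schema.
#' @param geometry section geometry table.
#' @return list with `per_animal` and `per_condition` data frames.
#' @export
aggregate_morphometry <- function(counts, geometry) {
  counts <- as.data.frame(counts)
  key <- interaction(counts$condition, counts$mouse_id, drop = TRUE)
  per_animal <- do.call(rbind, lapply(split(counts, key), function(cc) {
    s <- summarize_section(cc, geometry)
    data.frame(condition = cc$condition[1], mouse_id = cc$mouse_id[1],
               basal_density = s$basal_density, spinous_density = s$spinous_density,
               folding = s$folding,
               krt10_basal_fraction = s$krt10_basal_fraction,
               ki67_basal_fraction = s$ki67_basal_fraction,
               phh3_basal_fraction = s$phh3_basal_fraction,
               proliferative_spinous_per_um = s$rare_event_frequency_by_class[["proliferative_spinous"]],
               tunel_basal_per_um = s$rare_event_frequency_by_class[["tunel_basal"]],
               tunel_suprabasal_per_um = s$rare_event_frequency_by_class[["tunel_suprabasal"]],
               tunel_granular_cornified_per_um = s$rare_event_frequency_by_class[["tunel_granular_cornified"]],
               n_sections = s$n_sections)
  }))
  rownames(per_animal) <- NULL
  metric_cols <- setdiff(names(per_animal), c("condition", "mouse_id", "n_sections"))
  per_condition <- do.call(rbind, lapply(split(per_animal, per_animal$condition), function(pa) {
    out <- data.frame(condition = pa$condition[1], n_mice = nrow(pa))
    for (mc in metric_cols) out[[mc]] <- mean(pa[[mc]])
    out
  }))
  rownames(per_condition) <- NULL
  list(per_animal = per_animal, per_condition = per_condition,
       aggregation = "mean of per-animal values (animal = unit of replication)")
}
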