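# Synthetic-data generators. Every generator takes a seed, is fully
# deterministic under it, and returns its ground truth alongside the data so
# each downstream stage can be tested for parameter recovery without any
# external data.

fold90 <- function(x) {
  x <- abs(x) %% 180
  ifelse(x > 90, 180 - x, x)
}

#' Simulate division angles from a planar/uniform/perpendicular mixture
#'
#' Each angle is drawn from a three-component mixture on `[0, 90]` degrees:
#' a planar half-normal `|N(0, planar_sd)|`, a uniform component `U(0, 90)`,
#' and an optional perpendicular component `90 - |N(0, perp_sd)|`, all
#' folded into the domain. Half-normal components are used (rather than
#' circular distributions) because the domain is a folded quarter-circle
#' and the half-normal CDF gives closed-form expectations for bin
#' proportions.
#'
#' @param n sample size.
#' @param p_planar,p_uniform,p_perp non-negative mixture weights summing
#'   to 1.
#' @param planar_sd,perp_sd component spreads in degrees, > 0.
#' @param seed integer seed.
#' @param condition label attached to the sample.
#' @return an [angle_sample()] with attribute `component` giving each
#'   draw's ground-truth mixture component.
#' @export
simulate_angles <- function(n, p_planar = 0.8, p_uniform = 0.2, p_perp = 0,
                            planar_sd = 10, perp_sd = 10, seed = 1,
                            condition = "simulated") {
  w <- c(planar = p_planar, uniform = p_uniform, perpendicular = p_perp)
  if (any(w < 0) || abs(sum(w) - 1) > 1e-9)
    stop("mixture weights must be >= 0 and sum to 1", call. = FALSE)
  if (planar_sd <= 0 || perp_sd <= 0) stop("component sds must be > 0", call. = FALSE)
  set.seed(substream_seed(seed, 0))
  comp <- sample(names(w), n, replace = TRUE, prob = w)
  ang <- numeric(n)
  ang[comp == "planar"] <- fold90(stats::rnorm(sum(comp == "planar"), 0, planar_sd))
  ang[comp == "uniform"] <- stats::runif(sum(comp == "uniform"), 0, 90)
  ang[comp == "perpendicular"] <- fold90(90 - abs(stats::rnorm(sum(comp == "perpendicular"), 0, perp_sd)))
  out <- angle_sample(ang, condition)
  attr(out, "component") <- comp
  out
}

#' Simulate an angle sample with fixed orientation-bin counts
#'
#' Draws exactly `bin_counts` angles uniformly within the parallel
#' (0-30), oblique (30-60) and perpendicular (60-90) bins. Used to build
#' scenario samples whose bin percentages match a prescribed pattern.
#'
#' @param bin_counts integer vector length 3 (parallel, oblique,
#'   perpendicular).
#' @param seed integer seed.
#' @param condition label.
#' @return an [angle_sample()] of size `sum(bin_counts)`.
#' @export
simulate_binned_angles <- function(bin_counts, seed = 1, condition = "simulated") {
  if (length(bin_counts) != 3L || any(bin_counts < 0) || sum(bin_counts) < 1)
    stop("bin_counts must be 3 non-negative counts with a positive sum", call. = FALSE)
  set.seed(substream_seed(seed, 0))
  ang <- c(stats::runif(bin_counts[1], 0, 30),
           stats::runif(bin_counts[2], 30, 60),
           stats::runif(bin_counts[3], 60, 90))
  angle_sample(sample(ang), condition)
}

#' The four study conditions as fixed-bin scenario samples
#'
#' Returns the genotype conditions of the fixed-tissue angle analysis with
#' their observed sample sizes and orientation-bin proportions: wild type
#' (n = 45, strongly planar), LGN-null (n = 45), PTEN-deleted at 14 d
#' (n = 49), and the combined PTEN/LGN loss (n = 44, near-uniform). These
#' are the generator's study conditions, not tunable dials.
#'
#' @param seed integer seed; each condition draws from its own substream.
#' @return named list of [angle_sample()] objects in the order
#'   `LGN_wt`, `LGN_ko`, `PTEN_LGN_wt`, `PTEN_LGN_ko`.
#' @export
division_orientation_scenarios <- function(seed = 1) {
  specs <- list(
    LGN_wt      = c(36, 6, 3),   # 80.0 / 13.3 /  6.7 % of 45
    LGN_ko      = c(24, 9, 12),  # 53.3 / 20.0 / 26.7 % of 45
    PTEN_LGN_wt = c(32, 10, 7),  # 65.3 / 20.4 / 14.3 % of 49
    PTEN_LGN_ko = c(15, 17, 12)) # 34.1 / 38.6 / 27.3 % of 44
  out <- lapply(seq_along(specs), function(i)
    simulate_binned_angles(specs[[i]], seed = substream_seed(seed, i),
                           condition = names(specs)[i]))
  names(out) <- names(specs)
  out
}

# amplitude of y = A sin(2*pi*x/period) giving a prescribed arc/span ratio
solve_sine_amplitude <- function(span, period, folding_target) {
  arc_ratio <- function(A) {
    w <- 2 * pi / period
    f <- function(x) sqrt(1 + (A * w * cos(w * x))^2)
    stats::integrate(f, 0, span, subdivisions = 1000L)$value / span
  }
  if (folding_target == 1) return(0)
  stats::uniroot(function(A) arc_ratio(A) - folding_target,
                 lower = 0, upper = period, tol = 1e-10)$root
}

#' Simulate tissue sections with known density, folding and marker fractions
#'
#' The basement membrane of each section is a sinusoid whose amplitude is
#' solved numerically so that arc length / span equals `folding_target`.
#' Layer cell totals are Poisson at `density x arc length`; marker labels
#' are Bernoulli at the stated fractions; rare events are Poisson at
#' `rate x arc length`.
#'
#' @param span_um horizontal extent of each section, µm.
#' @param folding_target basement-membrane arc length over span, >= 1.
#' @param basal_density,spinous_density cells per µm of basement membrane.
#' @param krt10_basal,ki67_basal,phh3_basal basal marker fractions in [0,1].
#' @param proliferative_spinous_rate,tunel_rate rare-event rates, events/µm
#'   (TUNEL applied per layer).
#' @param n_sections sections per mouse; `n_mice` mice per condition.
#' @param condition label; `seed` integer seed.
#' @param wave_period_um sinusoid period, µm.
#' @return list with `counts` (long table), `geometry`, `traces` (vertex
#'   table, 1 µm sampling), and `truth` (the generating parameters).
#' @export
simulate_tissue <- function(span_um = 2000, folding_target = 1.3,
                            basal_density = 0.16, spinous_density = 0.19,
                            krt10_basal = 0.46, ki67_basal = 0.25,
                            phh3_basal = 0.02,
                            proliferative_spinous_rate = 0.0007,
                            tunel_rate = 0.0005,
                            n_sections = 3, n_mice = 3,
                            condition = "simulated", seed = 1,
                            wave_period_um = 200) {
  if (folding_target < 1) stop("folding_target must be >= 1", call. = FALSE)
  if (any(c(basal_density, spinous_density, proliferative_spinous_rate, tunel_rate) < 0))
    stop("rates must be >= 0", call. = FALSE)
  A <- solve_sine_amplitude(span_um, wave_period_um, folding_target)
  xs <- seq(0, span_um, by = 1)
  ys <- A * sin(2 * pi * xs / wave_period_um)
  counts <- list(); geometry <- list(); traces <- list()
  k <- 0
  for (mi in seq_len(n_mice)) {
    for (si in seq_len(n_sections)) {
      k <- k + 1
      set.seed(substream_seed(seed, k))
      sid <- sprintf("%s_m%d_s%d", condition, mi, si)
      arc <- polyline_length(cbind(xs, ys))
      nb <- stats::rpois(1, basal_density * arc)
      ns <- stats::rpois(1, spinous_density * arc)
      ng <- stats::rpois(1, 0.5 * spinous_density * arc) # upper layers, thinner
      counts[[k]] <- data.frame(
        section_id = sid, condition = condition, mouse_id = sprintf("%s_m%d", condition, mi),
        layer = c("basal", "basal", "basal", "basal", "basal",
                  "spinous", "spinous", "spinous",
                  "granular_cornified", "granular_cornified"),
        marker_class = c("total", "KRT10+", "Ki67+", "pHH3+", "TUNEL+",
                         "total", "Ki67+KRT10+KRT5-", "TUNEL+",
                         "total", "TUNEL+"),
        count = c(nb,
                  stats::rbinom(1, nb, krt10_basal),
                  stats::rbinom(1, nb, ki67_basal),
                  stats::rbinom(1, nb, phh3_basal),
                  stats::rpois(1, tunel_rate * arc),
                  ns,
                  stats::rpois(1, proliferative_spinous_rate * arc),
                  stats::rpois(1, tunel_rate * arc),
                  ng,
                  stats::rpois(1, 3 * tunel_rate * arc)))
      geometry[[k]] <- data.frame(section_id = sid, bm_length_um = arc,
                                  tissue_span_um = span_um)
      traces[[k]] <- data.frame(trace_id = sid, point_index = seq_along(xs),
                                x = xs, y = ys)
    }
  }
  list(counts = do.call(rbind, counts),
       geometry = do.call(rbind, geometry),
       traces = do.call(rbind, traces),
       truth = list(span_um = span_um, folding_target = folding_target,
                    basal_density = basal_density, spinous_density = spinous_density,
                    krt10_basal = krt10_basal, ki67_basal = ki67_basal,
                    phh3_basal = phh3_basal,
                    proliferative_spinous_rate = proliferative_spinous_rate,
                    tunel_rate = tunel_rate, amplitude_um = A))
}

#' Simulate a tumor cohort with zero-inflated burdens
#'
#' Per mouse: affected with probability `incidence_prob`; if affected, the
#' tumor count is zero-truncated Poisson with rate `count_lambda` and tumor
#' volumes are iid log-normal `(meanlog, sdlog)` in mm³.
#'
#' @param n_mice number of animals.
#' @param incidence_prob probability a mouse bears at least one tumor.
#' @param count_lambda Poisson rate of the zero-truncated tumor count.
#' @param meanlog,sdlog log-normal volume parameters.
#' @param genotype,site labels; `seed` integer seed.
#' @return list with `tumors` (one row per tumor; affected-free mice absent
#'   from the table), `mice` (roster) and `truth`.
#' @export
simulate_cohort <- function(n_mice = 20, incidence_prob = 0.35,
                            count_lambda = 1.5, meanlog = 3.5, sdlog = 1,
                            genotype = "simulated", site = "snout", seed = 1) {
  if (incidence_prob < 0 || incidence_prob > 1) stop("incidence_prob in [0,1]", call. = FALSE)
  if (sdlog <= 0) stop("sdlog must be > 0", call. = FALSE)
  mice <- data.frame(mouse_id = sprintf("%s_m%02d", genotype, seq_len(n_mice)),
                     genotype = genotype)
  rows <- list()
  for (i in seq_len(n_mice)) {
    set.seed(substream_seed(seed, i))
    if (stats::runif(1) < incidence_prob) {
      p0 <- stats::dpois(0, count_lambda)
      cnt <- stats::qpois(stats::runif(1, p0, 1), count_lambda) # zero-truncated
      vols <- stats::rlnorm(cnt, meanlog, sdlog)
      rows[[length(rows) + 1]] <- data.frame(
        mouse_id = mice$mouse_id[i], genotype = genotype, site = site,
        tumor_index = seq_len(cnt), volume_mm3 = vols)
    }
  }
  tumors <- if (length(rows)) do.call(rbind, rows) else
    data.frame(mouse_id = character(), genotype = character(), site = character(),
               tumor_index = integer(), volume_mm3 = numeric())
  ztp_mean <- count_lambda / (1 - exp(-count_lambda))
  list(tumors = tumors, mice = mice,
       truth = list(incidence_prob = incidence_prob, count_lambda = count_lambda,
                    ztp_mean = ztp_mean, meanlog = meanlog, sdlog = sdlog,
                    expected_burden = incidence_prob * ztp_mean * exp(meanlog + sdlog^2 / 2)))
}

#' Simulate live-imaging division tracks
#'
#' Anaphase-onset angles come from a planar/uniform mixture. Non-planar
#' divisions (t0 above `planar_threshold`) resolve to planar by t60 with
#' probability `resolution_prob`; unresolved divisions position one daughter
#' suprabasally, and that daughter descends back to the basal layer with
#' probability `reintegration_prob` after `reintegration_delay` frames
#' (5-min frames), staying basal thereafter.
#'
#' @param n_tracks number of divisions.
#' @param p_planar,planar_sd mixture of t0 angles (uniform weight is
#'   `1 - p_planar`).
#' @param planar_threshold live-imaging planar criterion, degrees.
#' @param resolution_prob probability a non-planar division is planar at t60.
#' @param reintegration_prob probability a suprabasal daughter reintegrates.
#' @param reintegration_delay frames after t60 at which reintegration occurs.
#' @param track_length total frames per track (5-min interval).
#' @param condition label; `seed` integer seed.
#' @return list with `tracks`, `frames` (long per-frame layer labels for
#'   daughters of non-planar unresolved divisions) and `truth` (per-track
#'   ground-truth labels).
#' @export
simulate_tracks <- function(n_tracks = 36, p_planar = 0.9, planar_sd = 8,
                            planar_threshold = 20, resolution_prob = 0.2,
                            reintegration_prob = 0.4, reintegration_delay = 36,
                            track_length = 156, condition = "simulated", seed = 1) {
  if (any(c(p_planar, resolution_prob, reintegration_prob) < 0) ||
      any(c(p_planar, resolution_prob, reintegration_prob) > 1))
    stop("probabilities must lie in [0,1]", call. = FALSE)
  tracks <- list(); frames <- list(); truth <- list()
  t60_frame <- 12 # 60 min at 5-min frames
  for (i in seq_len(n_tracks)) {
    set.seed(substream_seed(seed, i))
    id <- sprintf("%s_d%03d", condition, i)
    planar_comp <- stats::runif(1) < p_planar
    t0 <- if (planar_comp) fold90(stats::rnorm(1, 0, planar_sd)) else stats::runif(1, 0, 90)
    is_planar <- t0 <= planar_threshold
    resolved <- NA; reint <- NA
    if (is_planar) {
      t60 <- fold90(t0 + stats::rnorm(1, 0, 3))
      t60 <- min(t60, planar_threshold) # planar divisions stay planar
    } else {
      resolved <- stats::runif(1) < resolution_prob
      t60 <- if (resolved) stats::runif(1, 0, planar_threshold) else
        min(90, max(planar_threshold + 1e-6, t0 + stats::rnorm(1, 0, 5)))
    }
    if (!is_planar && !resolved) {
      reint <- stats::runif(1) < reintegration_prob
      fr <- t60_frame:track_length
      layer_b <- rep("basal", length(fr))
      layer_s <- if (reint) {
        ifelse(fr - t60_frame < reintegration_delay, "suprabasal", "basal")
      } else rep("suprabasal", length(fr))
      frames[[length(frames) + 1]] <- data.frame(
        division_id = id,
        daughter_id = rep(paste0(id, c("_a", "_b")), each = length(fr)),
        frame = c(fr, fr), layer = c(layer_b, layer_s))
    }
    tracks[[i]] <- data.frame(division_id = id, condition = condition,
                              angle_t0 = t0, angle_t60 = t60,
                              duration_frames = track_length)
    truth[[i]] <- data.frame(division_id = id, planar_at_onset = is_planar,
                             resolved = resolved, reintegrated = reint)
  }
  list(tracks = do.call(rbind, tracks),
       frames = if (length(frames)) do.call(rbind, frames) else
         data.frame(division_id = character(), daughter_id = character(),
                    frame = integer(), layer = character()),
       truth = do.call(rbind, truth))
}

#' Simulate a complete synthetic study
#'
#' Bundles the four fixed-tissue angle conditions, tissue sections for the
#' four genotypes, two tumor cohorts, and a live-imaging track set, all
#' under one root seed. This is the input of the end-to-end pipeline run.
#'
#' @param seed integer root seed.
#' @return named list: `angle_samples`, `tissue` (counts/geometry/traces),
#'   `cohorts` (tumors + mice for two genotypes), `tracks`, `frames`.
#' @export
simulate_study <- function(seed = 1) {
  angle_samples <- division_orientation_scenarios(seed = substream_seed(seed, 101))
  tissue_specs <- list(
    LGN_wt      = list(basal_density = 0.16, spinous_density = 0.19, krt10_basal = 0.46,
                       ki67_basal = 0.25, phh3_basal = 0.02, proliferative_spinous_rate = 0.0002),
    LGN_ko      = list(basal_density = 0.18, spinous_density = 0.20, krt10_basal = 0.49,
                       ki67_basal = 0.26, phh3_basal = 0.04, proliferative_spinous_rate = 0.0002),
    PTEN_LGN_wt = list(basal_density = 0.21, spinous_density = 0.31, krt10_basal = 0.38,
                       ki67_basal = 0.40, phh3_basal = 0.016, proliferative_spinous_rate = 0.0007),
    PTEN_LGN_ko = list(basal_density = 0.22, spinous_density = 0.36, krt10_basal = 0.46,
                       ki67_basal = 0.34, phh3_basal = 0.013, proliferative_spinous_rate = 0.0015))
  tissue <- lapply(seq_along(tissue_specs), function(i)
    do.call(simulate_tissue,
            c(tissue_specs[[i]], list(condition = names(tissue_specs)[i],
                                      seed = substream_seed(seed, 200 + i)))))
  counts <- do.call(rbind, lapply(tissue, `[[`, "counts"))
  geometry <- do.call(rbind, lapply(tissue, `[[`, "geometry"))
  traces <- do.call(rbind, lapply(tissue, `[[`, "traces"))
  wt <- simulate_cohort(n_mice = 17, incidence_prob = 0.12, count_lambda = 0.4,
                        meanlog = log(2.5) - 0.5, sdlog = 1, genotype = "PTEN_LGN_wt",
                        seed = substream_seed(seed, 301))
  ko <- simulate_cohort(n_mice = 20, incidence_prob = 0.35, count_lambda = 1.5,
                        meanlog = log(56) - 0.5, sdlog = 1, genotype = "PTEN_LGN_ko",
                        seed = substream_seed(seed, 302))
  trk <- simulate_tracks(n_tracks = 36, seed = substream_seed(seed, 401),
                         condition = "LGN_wt_live")
  list(angle_samples = angle_samples,
       tissue = list(counts = counts, geometry = geometry, traces = traces,
                     truth = lapply(tissue, `[[`, "truth")),
       cohorts = list(tumors = rbind(wt$tumors, ko$tumors),
                      mice = rbind(wt$mice, ko$mice),
                      truth = list(PTEN_LGN_wt = wt$truth, PTEN_LGN_ko = ko$truth)),
       tracks = trk$tracks, frames = trk$frames, track_truth = trk$truth,
       seed = seed)
}
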