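test_that("densities, folding, fractions and frequencies are exact arithmetic", {
  expect_equal(cell_density(16, 100), 0.16)
  expect_equal(cell_density(0, 50), 0)
  expect_equal(cell_density(36, 100), 0.36)
  expect_error(cell_density(5, 0), "> 0")
  expect_equal(tissue_folding(100, 100), 1)
  expect_equal(tissue_folding(150, 100), 1.5)
  expect_error(tissue_folding(-1, 100), "> 0")
  expect_equal(marker_fraction(46, 100), 46)
  expect_equal(marker_fraction(0, 300), 0)
  expect_equal(marker_fraction(2, 100), 2)
  expect_error(marker_fraction(101, 100), "inconsistent")
  expect_equal(rare_event_frequency(7, 3500), 0.002)
  expect_equal(rare_event_frequency(0, 100), 0)
})

test_that("pooled frequency divides total events by total length, not mean of ratios", {
  expect_equal(rare_event_frequency(c(3, 4), c(1000, 2500)), 7 / 3500)
  expect_false(isTRUE(all.equal(rare_event_frequency(c(3, 4), c(1000, 2500)),
                                mean(c(3 / 1000, 4 / 2500)))))
})

test_that("densities and frequencies are invariant to scaling counts and lengths together", {
  for (c_scale in c(2, 10, 0.5)) {
    expect_equal(cell_density(16 * c_scale, 100 * c_scale), cell_density(16, 100))
    expect_equal(rare_event_frequency(7 * c_scale, 3500 * c_scale),
                 rare_event_frequency(7, 3500))
    expect_equal(tissue_folding(150 * c_scale, 100 * c_scale), tissue_folding(150, 100))
  }
})

make_section <- function(sid = "s1", mouse = "m1") {
  list(
    counts = data.frame(
      section_id = sid, condition = "cond", mouse_id = mouse,
      layer = c("basal", "basal", "basal", "basal", "basal",
                "spinous", "spinous", "spinous", "granular_cornified", "granular_cornified"),
      marker_class = c("total", "KRT10+", "Ki67+", "pHH3+", "TUNEL+",
                       "total", "Ki67+KRT10+KRT5-", "TUNEL+", "total", "TUNEL+"),
      count = c(200, 92, 50, 4, 1, 240, 2, 0, 100, 3)),
    geometry = data.frame(section_id = sid, bm_length_um = 1250, tissue_span_um = 1000))
}

test_that("summarize_section matches hand-computed values on a fixture", {
  s <- make_section()
  out <- summarize_section(s$counts, s$geometry)
  expect_equal(out$basal_density, 200 / 1250)
  expect_equal(out$spinous_density, 240 / 1250)
  expect_equal(out$folding, 1.25)
  expect_equal(out$krt10_basal_fraction, 46)
  expect_equal(out$ki67_basal_fraction, 25)
  expect_equal(out$phh3_basal_fraction, 2)
  expect_equal(unname(out$rare_event_frequency_by_class["proliferative_spinous"]), 2 / 1250)
  expect_equal(unname(out$rare_event_frequency_by_class["tunel_basal"]), 1 / 1250)
  expect_equal(unname(out$rare_event_frequency_by_class["tunel_granular_cornified"]), 3 / 1250)
})

test_that("pooling two identical sections reproduces the single-section summary", {
  s1 <- make_section("s1"); s2 <- make_section("s2")
  counts2 <- rbind(s1$counts, s2$counts)
  geom2 <- rbind(s1$geometry, s2$geometry)
  a <- summarize_section(s1$counts, s1$geometry)
  b <- summarize_section(counts2, geom2)
  for (f in c("basal_density", "spinous_density", "folding", "krt10_basal_fraction"))
    expect_equal(b[[f]], a[[f]])
  expect_equal(b$rare_event_frequency_by_class, a$rare_event_frequency_by_class)
})

test_that("missing marker classes give zero fractions without error", {
  counts <- data.frame(section_id = "s", condition = "c", mouse_id = "m",
                       layer = c("basal", "spinous"), marker_class = "total",
                       count = c(100, 120))
  geom <- data.frame(section_id = "s", bm_length_um = 500, tissue_span_um = 500)
  out <- summarize_section(counts, geom)
  expect_equal(out$krt10_basal_fraction, 0)
  expect_equal(unname(out$rare_event_frequency_by_class["tunel_basal"]), 0)
})

test_that("condition-level values are means of per-animal values", {
  s1 <- make_section("s1", "m1")
  s2 <- make_section("s2", "m2")
  s2$counts$count[s2$counts$marker_class == "total" & s2$counts$layer == "basal"] <- 400
  agg <- aggregate_morphometry(rbind(s1$counts, s2$counts),
                               rbind(s1$geometry, s2$geometry))
  expect_equal(nrow(agg$per_animal), 2)
  expect_equal(agg$per_condition$basal_density,
               mean(c(200 / 1250, 400 / 1250)))
})

test_that("synthetic tissue recovers density, folding and fractions within 5%", {
  tis <- simulate_tissue(span_um = 2000, folding_target = 1.3, basal_density = 0.16,
                         spinous_density = 0.19, krt10_basal = 0.46, ki67_basal = 0.25,
                         n_sections = 3, n_mice = 3, seed = 91)
  # >= 300 cells per animal as generated
  per_mouse_basal <- tapply(tis$counts$count[tis$counts$marker_class == "total" &
                                             tis$counts$layer == "basal"],
                            tis$counts$mouse_id[tis$counts$marker_class == "total" &
                                                tis$counts$layer == "basal"], sum)
  expect_true(all(per_mouse_basal >= 300))
  agg <- aggregate_morphometry(tis$counts, tis$geometry)
  pc <- agg$per_condition
  expect_lt(abs(pc$basal_density - 0.16) / 0.16, 0.05)
  expect_lt(abs(pc$spinous_density - 0.19) / 0.19, 0.05)
  expect_lt(abs(pc$folding - 1.3) / 1.3, 0.05)
  expect_lt(abs(pc$krt10_basal_fraction - 46) / 46, 0.05)
  expect_lt(abs(pc$ki67_basal_fraction - 25) / 25, 0.05)
})

test_that("the emitted sinusoidal trace has the programmed arc-length factor", {
  tis <- simulate_tissue(span_um = 200, folding_target = 1.3, n_sections = 1,
                         n_mice = 1, seed = 3)
  tr <- tis$traces
  measured <- tissue_folding(polyline_length(cbind(tr$x, tr$y)), 200)
  expect_gte(measured, 1.29); expect_lte(measured, 1.31)
  # numeric arc-length oracle on the underlying sinusoid
  A <- tis$truth$amplitude_um
  oracle <- arc_length_numeric(function(x) A * sin(2 * pi * x / 200), 200) / 200
  expect_equal(measured, oracle, tolerance = 1e-3)
})
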