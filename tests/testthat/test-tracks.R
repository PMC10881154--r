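test_that("t0 -> t60 resolution classifies against the planar threshold", {
  expect_equal(as.character(t0_t60_resolution(35, 10)), "resolved")
  expect_equal(as.character(t0_t60_resolution(35, 33)), "persistent")
  expect_equal(as.character(t0_t60_resolution(10, 12)), "planar_at_onset")
  expect_equal(as.character(t0_t60_resolution(35, NA)), "censored")
  # vectorised and threshold-sensitive
  expect_equal(as.character(t0_t60_resolution(c(25, 25), c(10, 10), planar_threshold = 30)),
               c("planar_at_onset", "planar_at_onset"))
  expect_error(t0_t60_resolution(NA, 10), "present")
  expect_error(t0_t60_resolution(95, 10), "\\[0, 90\\]")
})

frames_for <- function(layers_daughter, n_frames = length(layers_daughter)) {
  rbind(
    data.frame(division_id = "d", daughter_id = "a", frame = seq_len(n_frames),
               layer = "basal"),
    data.frame(division_id = "d", daughter_id = "b", frame = seq_len(n_frames),
               layer = layers_daughter))
}

test_that("reintegration requires descent within the window and persistence to track end", {
  # suprabasal for 40 frames (~3.3 h), basal thereafter, 10 h track
  fr <- frames_for(c(rep("suprabasal", 40), rep("basal", 80)))
  expect_equal(classify_reintegration(fr, window_h = 6), "reintegrated")
  # suprabasal throughout an 8 h track
  expect_equal(classify_reintegration(frames_for(rep("suprabasal", 96)), window_h = 6),
               "retained")
  # track ends at 4 h without a transition
  expect_equal(classify_reintegration(frames_for(rep("suprabasal", 48)), window_h = 6),
               "censored")
  # a dip to basal that does not persist is not reintegration
  fr_dip <- frames_for(c(rep("suprabasal", 30), rep("basal", 10), rep("suprabasal", 80)))
  expect_equal(classify_reintegration(fr_dip, window_h = 6), "retained")
  # no suprabasal daughter at all is a misuse
  expect_error(classify_reintegration(frames_for(rep("basal", 96))), "not assessable")
})

test_that("programmed reintegrations are recovered exactly on a small cohort", {
  # 5 suprabasal daughters, exactly 2 programmed to descend
  descend <- c(TRUE, FALSE, TRUE, FALSE, FALSE)
  frames <- do.call(rbind, lapply(1:5, function(i) {
    layers <- if (descend[i]) c(rep("suprabasal", 30), rep("basal", 90))
              else rep("suprabasal", 120)
    data.frame(division_id = paste0("d", i), daughter_id = paste0("d", i, "_s"),
               frame = 1:120, layer = layers)
  }))
  tracks <- data.frame(division_id = paste0("d", 1:5),
                       angle_t0 = rep(40, 5), angle_t60 = rep(35, 5))
  cl <- classify_tracks(tracks, frames)
  expect_equal(sum(cl$reintegration == "reintegrated", na.rm = TRUE), 2)
  expect_equal(cl$reintegration[descend], rep("reintegrated", 2))
  expect_equal(cl$reintegration[!descend], rep("retained", 3))
})

test_that("simulated tracks honour resolution_prob = 0 and all-planar specs", {
  tr <- simulate_tracks(n_tracks = 60, p_planar = 0.3, resolution_prob = 0, seed = 15)
  cl <- classify_tracks(tr$tracks, tr$frames)
  nonplanar <- cl$resolution[cl$resolution != "planar_at_onset"]
  expect_true(all(nonplanar == "persistent"))
  # all-planar spec: nothing eligible for reintegration analysis
  tr2 <- simulate_tracks(n_tracks = 40, p_planar = 1, planar_sd = 3, seed = 16)
  expect_equal(nrow(tr2$frames), 0)
  cl2 <- classify_tracks(tr2$tracks, tr2$frames)
  expect_true(all(is.na(cl2$reintegration)))
})

test_that("classifier recovers resolution and reintegration probabilities within 3 SE", {
  n <- 10000
  tr <- simulate_tracks(n_tracks = n, p_planar = 0, resolution_prob = 0.3,
                        reintegration_prob = 0.4, seed = 17)
  cl <- classify_tracks(tr$tracks, tr$frames)
  nonplanar <- cl$resolution != "planar_at_onset"
  p_res <- mean(cl$resolution[nonplanar] == "resolved")
  se_res <- sqrt(0.3 * 0.7 / sum(nonplanar))
  expect_lt(abs(p_res - 0.3), 3 * se_res)
  assessed <- !is.na(cl$reintegration)
  p_reint <- mean(cl$reintegration[assessed] == "reintegrated")
  se_reint <- sqrt(0.4 * 0.6 / sum(assessed))
  expect_lt(abs(p_reint - 0.4), 3 * se_reint)
  # generator ground truth agrees with the classifier on every track
  truth <- tr$truth
  merged <- merge(cl, truth, by = "division_id")
  res_rows <- !merged$planar_at_onset
  expect_equal(merged$resolution[res_rows] == "resolved", merged$resolved[res_rows])
})
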