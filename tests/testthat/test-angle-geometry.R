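test_that("local_tangent returns the direction of the nearest segment", {
  expect_equal(local_tangent(rbind(c(0, 0), c(100, 0)), c(50, 8)), c(1, 0))
  expect_equal(local_tangent(rbind(c(0, 0), c(0, 100)), c(5, 50)), c(0, 1))
  # L-shaped trace: brute-force nearest-segment search agrees
  trace <- rbind(c(0, 0), c(10, 0), c(10, 10))
  pt <- c(9, 6)
  d_seg1 <- abs(pt[2] - 0)                  # distance to y = 0, x in [0,10]
  d_seg2 <- abs(pt[1] - 10)                 # distance to x = 10, y in [0,10]
  expect_true(d_seg2 < d_seg1)
  expect_equal(local_tangent(trace, pt), c(0, 1))
  expect_error(local_tangent(rbind(c(1, 1), c(1, 1)), c(0, 0)), "degenerate")
})

test_that("spindle_angle folds the pole axis into [0, 90] against the reference", {
  expect_equal(spindle_angle(c(0, 0), c(10, 0), reference = c(1, 0)), 0)
  expect_equal(spindle_angle(c(0, 0), c(0, 10), reference = c(1, 0)), 90)
  expect_equal(spindle_angle(c(0, 0), c(10, 10), reference = c(1, 0)), 45)
  # raw angle against (0,1) is 135 degrees; acute-angle rule folds to 45
  expect_equal(spindle_angle(c(0, 0), c(10, 10), reference = c(0, 1)), 45)
  expect_error(spindle_angle(c(1, 2), c(1, 2), reference = c(1, 0)), "coincident")
})

test_that("spindle_angle is invariant under pole swap, reference negation and rigid motion", {
  set.seed(42)
  for (i in 1:30) {
    a <- runif(2, -50, 50); b <- a + runif(2, -10, 10)
    if (all(a == b)) next
    ref <- c(cos(runif(1, 0, 2 * pi)), sin(runif(1, 0, 2 * pi)))
    ang <- spindle_angle(a, b, reference = ref)
    expect_equal(spindle_angle(b, a, reference = ref), ang, tolerance = 1e-9)
    expect_equal(spindle_angle(a, b, reference = -ref), ang, tolerance = 1e-9)
    theta <- runif(1, 0, 2 * pi); shift <- runif(2, -100, 100)
    pts <- apply_rigid(rbind(a, b), theta, shift)
    expect_equal(spindle_angle(pts[1, ], pts[2, ], reference = rotate_vec(ref, theta)),
                 ang, tolerance = 1e-9)
  }
})

test_that("spindle_angle resolves the reference from a trace at the pole-axis midpoint", {
  # membrane flat then rising: midpoint of the pole axis sits over the flat part
  trace <- rbind(c(0, 0), c(100, 0), c(100, 100))
  expect_equal(spindle_angle(c(20, 5), c(40, 25), trace = trace), 45, tolerance = 1e-9)
})

test_that("bin_angle partitions [0, 90] with closed outer boundaries", {
  expect_equal(as.character(bin_angle(30)), "parallel")
  expect_equal(as.character(bin_angle(60)), "perpendicular")
  expect_equal(as.character(bin_angle(45)), "oblique")
  expect_error(bin_angle(-1), "\\[0, 90\\]")
  expect_error(bin_angle(90.5), "\\[0, 90\\]")
  # partition: every angle lands in exactly one class
  angles <- seq(0, 90, by = 0.25)
  cls <- bin_angle(angles)
  expect_false(anyNA(cls))
  expect_equal(sum(table(cls)), length(angles))
})

test_that("distribution_summary reports exact bin percentages and quartiles", {
  s <- distribution_summary(angle_sample(c(10, 20, 40, 70)))
  expect_equal(s$pct_parallel, 50)
  expect_equal(s$pct_oblique, 25)
  expect_equal(s$pct_perpendicular, 25)
  expect_equal(s$median, 30)
  expect_equal(distribution_summary(angle_sample(c(0, 0, 0)))$pct_parallel, 100)
  expect_error(angle_sample(numeric(0)), "at least one")
  # construction mirroring the wild-type proportions: 36 + 6 + 3 of 45
  set.seed(7)
  ang <- c(runif(36, 0, 30), runif(6, 30, 60), runif(3, 60, 90))
  s45 <- distribution_summary(angle_sample(ang))
  expect_equal(s45$pct_parallel, 80)
  expect_equal(s45$pct_oblique, 100 * 6 / 45)
  expect_equal(s45$pct_perpendicular, 100 * 3 / 45)
  expect_true(s45$q25 <= s45$median && s45$median <= s45$q75)
})

test_that("bin percentages always sum to 100 and are duplication-invariant", {
  set.seed(11)
  for (i in 1:20) {
    ang <- runif(sample(3:60, 1), 0, 90)
    s1 <- distribution_summary(angle_sample(ang))
    expect_equal(s1$pct_parallel + s1$pct_oblique + s1$pct_perpendicular, 100,
                 tolerance = 1e-12)
    s2 <- distribution_summary(angle_sample(c(ang, ang)))
    expect_equal(s2$pct_parallel, s1$pct_parallel, tolerance = 1e-12)
    expect_equal(s2$pct_oblique, s1$pct_oblique, tolerance = 1e-12)
    expect_equal(s2$median, s1$median, tolerance = 1e-12)
  }
})

test_that("compute_division_angles handles explicit references and trace links", {
  ann <- data.frame(division_id = c("d1", "d2"), condition = "c", mouse_id = "m",
                    ax = c(0, 0), ay = c(0, 0), bx = c(10, 10), by = c(0, 10),
                    ref_dx = c(1, NA), ref_dy = c(0, NA),
                    trace_id = c(NA, "t1"))
  traces <- data.frame(trace_id = "t1", point_index = 1:2, x = c(-50, 50), y = 0)
  out <- compute_division_angles(ann, traces)
  expect_equal(out$angle_deg, c(0, 45))
  expect_equal(as.character(out$orientation), c("parallel", "oblique"))
  ann_bad <- ann; ann_bad$trace_id[2] <- "missing"
  expect_error(compute_division_angles(ann_bad, traces), "unknown trace_id")
})
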