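test_that("diffuser segment honours the distal-at-target convention", {
  traj <- fiber_trajectory(c(0, 0, 0), c(100, 0, 0), 30)
  seg <- diffuser_segment(traj)
  expect_equal(seg["proximal", ], c(70, 0, 0))
  expect_equal(seg["distal", ], c(100, 0, 0))
  flipped <- diffuser_segment(traj, distal_at_target = FALSE)
  expect_equal(flipped["proximal", ], c(0, 0, 0))

  short <- fiber_trajectory(c(0, 0, 0), c(25, 0, 0), 30)
  expect_error(diffuser_segment(short), "shorter than")
  expect_error(fiber_trajectory(c(1, 2, 3), c(1, 2, 3), 20), "coincide")
})

test_that("segment minimum distance matches closed forms and the
           grid-search oracle", {
  a <- rbind(c(0, 0, 0), c(10, 0, 0))
  expect_equal(segment_min_distance(a, rbind(c(0, 10, 0), c(10, 10, 0))), 10)
  expect_equal(segment_min_distance(a, rbind(c(5, -5, 0), c(5, 5, 0))), 0)
  expect_equal(segment_min_distance(a, rbind(c(0, 3, 4), c(10, 3, 4))), 5)

  set.seed(23)
  for (i in 1:40) {
    p <- matrix(runif(6, -20, 20), 2, 3, byrow = TRUE)
    q <- matrix(runif(6, -20, 20), 2, 3, byrow = TRUE)
    d <- segment_min_distance(p, q)
    expect_equal(d, segment_distance_oracle(p, q), tolerance = 1e-6)
    expect_equal(d, segment_min_distance(q, p)) # symmetry
    expect_gte(d, 0)
  }
})

test_that("plan validation raises the documented alert kinds", {
  g <- homogeneous_phantom(100, 1)
  mk <- function(x, L = 20) fiber_trajectory(c(x, 50, 0), c(x, 50, 60), L)

  # 8 mm apart -> spacing violation; 9.0 mm -> clean
  a8 <- validate_plan(ipdt_plan(list(mk(40), mk(48))), g)
  expect_equal(a8$kind, "spacing-violation")
  expect_equal(a8$value, 8, tolerance = 1e-12)
  expect_equal(nrow(validate_plan(ipdt_plan(list(mk(40), mk(49))), g)), 0)

  # single fiber: no pairwise alerts
  expect_equal(nrow(validate_plan(ipdt_plan(list(mk(50))), g)), 0)

  # disallowed diffuser length
  a35 <- validate_plan(ipdt_plan(list(mk(50, L = 35))), g)
  expect_equal(a35$kind, "invalid-length")

  # crossing trajectories (well-spaced diffusers can still cross paths)
  c1 <- fiber_trajectory(c(20, 20, 0), c(80, 80, 90), 20)
  c2 <- fiber_trajectory(c(80, 20, 0), c(20, 80, 90), 20)
  ax <- validate_plan(ipdt_plan(list(c1, c2)), g)
  expect_true("trajectory-crossing" %in% ax$kind)

  # diffuser leaving the volume
  out <- fiber_trajectory(c(50, 50, 40), c(50, 50, 110), 20)
  expect_true("out-of-grid" %in%
                validate_plan(ipdt_plan(list(out)), g)$kind)
})

test_that("alert set is invariant under fiber reordering", {
  g <- homogeneous_phantom(100, 1)
  f <- list(fiber_trajectory(c(40, 50, 0), c(40, 50, 60), 20),
            fiber_trajectory(c(46, 50, 0), c(46, 50, 60), 20),
            fiber_trajectory(c(70, 50, 0), c(70, 50, 60), 35))
  a1 <- validate_plan(ipdt_plan(f), g)
  a2 <- validate_plan(ipdt_plan(f[c(3, 1, 2)]), g)
  expect_equal(sort(table(a1$kind)), sort(table(a2$kind)))
  expect_equal(sort(a1$value), sort(a2$value))
})

test_that("bisection localizes the smallest accepted spacing at exactly
           the configured minimum", {
  g <- homogeneous_phantom(100, 1)
  accepted <- function(sep) {
    f <- list(fiber_trajectory(c(40, 50, 0), c(40, 50, 60), 20),
              fiber_trajectory(c(40 + sep, 50, 0), c(40 + sep, 50, 60), 20))
    !"spacing-violation" %in% validate_plan(ipdt_plan(f), g)$kind
  }
  lo <- 5; hi <- 15
  for (i in 1:50) {
    mid <- (lo + hi) / 2
    if (accepted(mid)) hi <- mid else lo <- mid
  }
  expect_equal(hi, 9, tolerance = 1e-9)
  expect_true(accepted(9))
  expect_false(accepted(9 - 1e-6))
})

test_that("world/voxel transforms are mutually inverse", {
  g <- voxel_grid(array(1L, c(10, 10, 10)), 1) # identity affine
  expect_equal(world_to_voxel(c(5, 5, 5), g), matrix(c(5, 5, 5), 1))
  expect_error(world_to_voxel(c(30, 5, 5), g), "outside")

  aff <- diag(c(0.8, 0.8, 2, 1)); aff[1:3, 4] <- c(-10, 4, 7)
  g2 <- voxel_grid(array(1L, c(20, 20, 12)), c(0.8, 0.8, 2), affine = aff)
  set.seed(3)
  idx <- cbind(runif(1000, 0, 19), runif(1000, 0, 19), runif(1000, 0, 11))
  w <- voxel_to_world(idx, g2)
  back <- world_to_voxel(w, g2, continuous = TRUE)
  expect_equal(back, idx, tolerance = 1e-9)
})

test_that("plans round-trip through TSV and reports through JSON", {
  f <- list(fiber_trajectory(c(10.25, 20.5, 30), c(40, 50.75, 60), 20),
            fiber_trajectory(c(70, 25, 35), c(90.5, 55, 65), 25))
  plan <- ipdt_plan(f, treatment_time = 3600, n_packets = 1024L, seed = 9L)
  tmp <- tempfile(fileext = ".tsv")
  write_plan(plan, tmp)
  back <- read_plan(tmp, treatment_time = 3600, n_packets = 1024L, seed = 9L)
  for (i in 1:2) {
    expect_equal(back$fibers[[i]]$entry, f[[i]]$entry, tolerance = 1e-6)
    expect_equal(back$fibers[[i]]$target, f[[i]]$target, tolerance = 1e-6)
  }

  g <- homogeneous_phantom(100, 1)
  alerts <- validate_plan(plan, g)
  expect_equal(nrow(alerts), 0)
  dose <- structure(data.frame(treated_volume_cm3 = 1.23,
                               coverage_index_pct = 87.5,
                               treatment_time_s = 3600,
                               threshold_J_cm2 = 25,
                               high_dose_volume_cm3 = 0.2),
                    class = c("dose_summary", "data.frame"))
  srcs <- lapply(f, build_line_source)
  rep_path <- tempfile(fileext = ".json")
  export_plan_report(plan, alerts, dose = dose, sources = srcs,
                     path = rep_path)
  rep <- read_plan_report(rep_path)
  expect_equal(unlist(rep$fibers[[1]]$entry_mm), f[[1]]$entry,
               tolerance = 1e-6)
  expect_identical(rep$dosimetry$coverage_index_pct, 87.5)
  expect_equal(rep$fibers[[2]]$emission_pdf$order, 3)

  # gate: a plan with alerts is refused
  bad <- ipdt_plan(list(fiber_trajectory(c(40, 50, 0), c(40, 50, 60), 20),
                        fiber_trajectory(c(44, 50, 0), c(44, 50, 60), 20)))
  bad_alerts <- validate_plan(bad, g)
  expect_gt(nrow(bad_alerts), 0)
  expect_error(export_plan_report(bad, bad_alerts, path = tempfile()),
               "refusing")
})
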