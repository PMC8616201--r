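test_that("Henyey-Greenstein sampling matches its closed form and first
           moment", {
  expect_equal(henyey_greenstein_cosine(0, 0.75), 0.5)
  expect_equal(henyey_greenstein_cosine(0.9, 0.5), 0.98550,
               tolerance = 1e-5)
  expect_error(henyey_greenstein_cosine(1.2, 0.5), "<= 1")

  set.seed(2)
  u <- runif(1e6)
  ct <- henyey_greenstein_cosine(0.85, u)
  expect_true(all(ct >= -1 & ct <= 1))
  # E[cos] = g; sd of the HG cosine at g = 0.85 is well under 0.3
  se <- stats::sd(ct) / 1000
  expect_lt(abs(mean(ct) - 0.85), 3 * se)
})

test_that("ray-voxel traversal returns exact chords", {
  g <- homogeneous_phantom(c(10, 10, 10), 1)
  # axis-aligned ray entering voxel centres: unit chords
  tr <- traverse_voxels(c(2.5, 3.5, 3.5), c(1, 0, 0), g)
  expect_equal(nrow(tr), 8) # from mid-voxel i=2 out through i=9
  expect_equal(tr$length, c(0.5, rep(1, 7)), tolerance = 1e-6)
  expect_equal(tr$j, rep(3, 8))
  expect_equal(sum(tr$length), 7.5, tolerance = 1e-7)

  # diagonal through a unit cube: single chord sqrt(3)
  g1 <- homogeneous_phantom(c(1, 1, 1), 1)
  tr <- traverse_voxels(c(1e-9, 1e-9, 1e-9), c(1, 1, 1), g1)
  expect_equal(sum(tr$length), sqrt(3), tolerance = 1e-6)

  # chord sums equal the in-grid ray length (slab-clipping oracle)
  set.seed(9)
  for (i in 1:200) {
    o <- runif(3, 0.5, 9.5)
    d <- sample_isotropic_direction(1)[1, ]
    tr <- traverse_voxels(o, d, g)
    expect_equal(sum(tr$length), slab_ray_length(o, d, c(10, 10, 10), 1),
                 tolerance = 1e-7)
  }
  expect_error(traverse_voxels(c(-1, 5, 5), c(1, 0, 0), g), "outside")
})

test_that("packet weight is conserved exactly with roulette disabled", {
  tab <- toy_table(mu_a = 0.5, mu_s = 2, g = 0.5)
  g <- homogeneous_phantom(15, 1, label = 1L)
  src <- point_source(c(7.5, 7.5, 7.5), power = 1)
  res <- run_transport(g, tab, src, n_packets = 2000, seed = 3,
                       roulette = FALSE)
  cs <- conservation_summary(res)
  expect_equal(cs$rouletted, 0)
  expect_lt(abs(cs$relative_error), 1e-9)
  expect_true(all(res$fluence_rate >= 0))
  expect_true(all(res$deposited_weight >= 0))
})

test_that("identical seed gives bit-identical tallies", {
  tab <- toy_table(0.3, 5, 0.8)
  g <- homogeneous_phantom(21, 1, label = 1L)
  src <- point_source(c(10.5, 10.5, 10.5), power = 2)
  r1 <- run_transport(g, tab, src, n_packets = 3000, seed = 17)
  r2 <- run_transport(g, tab, src, n_packets = 3000, seed = 17)
  expect_identical(r1$fluence_rate, r2$fluence_rate)
  expect_identical(r1$escaped_weight, r2$escaped_weight)
  r3 <- run_transport(g, tab, src, n_packets = 3000, seed = 18)
  expect_false(identical(r1$fluence_rate, r3$fluence_rate))
})

test_that("track-length and absorption tallies agree on a homogeneous
           phantom", {
  tab <- toy_table(0.3, 5, 0.8)
  g <- homogeneous_phantom(21, 1, label = 1L)
  src <- point_source(c(10.5, 10.5, 10.5), power = 1)
  res <- run_transport(g, tab, src, n_packets = 20000, seed = 21)
  rad <- voxel_radii(g, c(10.5, 10.5, 10.5))
  for (r0 in c(2, 4, 6)) {
    tl <- shell_mean(res$fluence_rate, rad, r0)
    ab <- shell_mean(res$fluence_rate_absorption, rad, r0)
    expect_equal(ab / tl, 1, tolerance = 0.05)
  }
})

test_that("fluence is mirror-symmetric about a central source", {
  tab <- toy_table(0.3, 5, 0.8)
  g <- homogeneous_phantom(21, 1, label = 1L)
  src <- point_source(c(10.5, 10.5, 10.5), power = 1)
  halves <- sapply(c(101, 202, 303, 404), function(sd) {
    res <- run_transport(g, tab, src, n_packets = 5000, seed = sd)
    c(left = sum(res$fluence_rate[1:10, , ]),
      right = sum(res$fluence_rate[12:21, , ]))
  })
  diffs <- halves["left", ] - halves["right", ]
  expect_lt(abs(mean(diffs)), 3 * stats::sd(diffs) / sqrt(4) + 1e-12)
})

test_that("transparent voxels give free flight but still tally fluence", {
  tab <- toy_table(mu_a = 0, mu_s = 0, g = 0)
  g <- homogeneous_phantom(11, 1, label = 1L)
  src <- point_source(c(5.5, 5.5, 5.5), power = 1)
  res <- run_transport(g, tab, src, n_packets = 500, seed = 4)
  expect_equal(res$escaped_weight, 500) # everything escapes
  expect_equal(sum(res$deposited_weight), 0)
  expect_gt(sum(res$fluence_rate), 0) # track tally active en route
})

test_that("packets sitting exactly on a voxel face with a near-tangent
           direction still make progress", {
  # regression: a face-aligned position plus a direction component of
  # ~1e-12 toward the face used to stall the fixed-path-length nudge
  tab <- toy_table(0.17, 24.1, 0.9)
  g <- homogeneous_phantom(20, 1, label = 1L)
  u <- c(-1e-12, sqrt(0.5), sqrt(0.5 - 1e-24))
  pos <- matrix(c(10, 10, 10), 4, 3, byrow = TRUE) # on faces in all axes
  dirs <- rbind(u, -u, c(1e-14, -1, 0), c(0, 1e-14, 1))
  dirs <- dirs / sqrt(rowSums(dirs^2))
  set.seed(1)
  res <- mc_transport_cpp(as.integer(g$dims), g$voxel_size,
                          as.integer(g$labels), props_matrix(g, tab),
                          pos, dirs, TRUE, 1e-4, 0.1, 1e9)
  total <- sum(res$absorbed) + res$escaped_weight + res$rouletted_weight
  expect_gt(total, 3.5) # all four packets terminated normally

  tr <- traverse_voxels(c(10, 10, 5.5), c(-1e-13, 1e-13, 1), g)
  expect_equal(sum(tr$length), 14.5, tolerance = 1e-6)
})

test_that("geometry errors are raised for sources outside the grid", {
  tab <- default_tissue_table()
  g <- homogeneous_phantom(20, 1)
  expect_error(run_transport(g, tab, point_source(c(50, 5, 5)), 10, 1),
               "outside")
  labs <- g$labels; labs[1] <- 99L
  g2 <- voxel_grid(labs, 1)
  expect_error(run_transport(g2, tab, point_source(c(5, 5, 5)), 10, 1),
               "absent from the tissue table")
})
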