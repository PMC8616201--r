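test_that("fluence-rate summation is exact elementwise addition", {
  set.seed(31)
  d <- c(8, 7, 6)
  maps <- lapply(1:3, function(i) array(runif(prod(d)), dim = d))
  s <- sum_fluence_rates(maps)
  expect_identical(s, maps[[1]] + maps[[2]] + maps[[3]])
  expect_identical(sum_fluence_rates(maps[1]), maps[[1]])
  expect_identical(sum_fluence_rates(list(maps[[1]], maps[[1]])),
                   2 * maps[[1]])
  expect_error(sum_fluence_rates(list()), "at least one")
  expect_error(sum_fluence_rates(list(maps[[1]], array(0, c(2, 2, 2)))),
               "different grids")
})

test_that("fluence = rate x time with the mW -> W conversion", {
  expect_equal(compute_fluence(6.944, 3600), 24.9984)
  expect_equal(compute_fluence(1, 1000), 1)
  m <- array(runif(27), dim = c(3, 3, 3))
  expect_identical(compute_fluence(m, 0), array(0, c(3, 3, 3)))
  expect_error(compute_fluence(m, -1), ">= 0")
})

test_that("effective treated volume counts voxels strictly above threshold", {
  g <- homogeneous_phantom(20, 1)
  region <- array(FALSE, g$dims); region[1:10, 1:10, 1:10] <- TRUE # 1000 vox
  fl <- uniform_fluence_fixture(g, 30, region)
  etv <- effective_treated_volume(fl, g, 25)
  expect_equal(etv$volume_cm3, 1.000)
  expect_identical(etv$mask, region)

  # boundary: exactly at threshold is not treated (strict "higher than")
  fl25 <- uniform_fluence_fixture(g, 25, region)
  expect_equal(effective_treated_volume(fl25, g, 25)$volume_cm3, 0)
  expect_equal(effective_treated_volume(fl25, g, 25,
                                        strict = FALSE)$volume_cm3, 1)

  # saturation: everything treated
  all_fl <- array(26, g$dims)
  expect_equal(effective_treated_volume(all_fl, g, 25)$volume_cm3,
               prod(g$dims) / 1000)
})

test_that("coverage index equals brute-force mask arithmetic", {
  d <- c(10, 10, 10)
  target <- array(FALSE, d); target[1:2, 1:2, 1:2] <- TRUE # 8 voxels
  treated <- target; treated[1, 1, 1:2] <- FALSE           # 6 remain
  expect_equal(coverage_index(treated, target), 75)
  expect_equal(coverage_index(target, target), 100)
  expect_equal(coverage_index(array(FALSE, d), target), 0)
  expect_error(coverage_index(treated, array(FALSE, d)), "empty")

  set.seed(13)
  for (i in 1:20) {
    tm <- array(runif(prod(d)) > 0.5, d)
    gm <- array(runif(prod(d)) > 0.8, d)
    if (sum(gm) == 0) next
    brute <- 100 * sum(tm & gm) / sum(gm)
    expect_equal(coverage_index(tm, gm), brute)
  }
})

test_that("high-dose region is a strict mask nested inside the treated one", {
  g <- homogeneous_phantom(12, 1)
  set.seed(41)
  fl <- array(runif(prod(g$dims), 0, 400), g$dims)
  hd <- high_dose_region(fl, 250)
  expect_equal(sum(hd), sum(fl > 250))
  tv <- effective_treated_volume(fl, g, 25)$mask
  expect_true(all(!hd | tv)) # hd subset of treated
  expect_false(any(high_dose_region(array(100, c(2, 2, 2)), 250)))
})

test_that("treated volume is monotone in time and threshold", {
  g <- homogeneous_phantom(15, 1)
  set.seed(8)
  rate <- array(rexp(prod(g$dims), rate = 0.2), g$dims) # mW/cm^2
  times <- c(600, 1800, 3600, 7200)
  vols <- sapply(times, function(tt)
    effective_treated_volume(compute_fluence(rate, tt), g, 25)$volume_cm3)
  expect_true(all(diff(vols) >= 0))
  ths <- c(5, 15, 25, 50, 100)
  volt <- sapply(ths, function(th)
    effective_treated_volume(compute_fluence(rate, 3600), g, th)$volume_cm3)
  expect_true(all(diff(volt) <= 0))
})

test_that("doubling source power halves the time to reach a fixed treated
           volume", {
  g <- homogeneous_phantom(15, 1)
  set.seed(80)
  rate <- array(rexp(prod(g$dims), 0.2), g$dims)
  vol_at <- function(r, tt) effective_treated_volume(
    compute_fluence(r, tt), g, 25)$volume_cm3
  expect_equal(vol_at(2 * rate, 1800), vol_at(rate, 3600))
})

test_that("photosensitizer weighting scales healthy tissue down by the
           concentration ratio", {
  ph <- generate_phantom(phantom_spec(dims = 40, r_necrotic = 3,
                                      r_enhancing = 5, r_non_enhancing = 7,
                                      r_oedema = 9))
  fl <- array(100, ph$grid$dims)
  w <- ppix_weighted_fluence(fl, ph$grid, ratio = 100)
  expect_equal(max(w[ph$grid$labels == tissue_labels[["enhancing"]]]), 100)
  expect_equal(max(w[ph$grid$labels == tissue_labels[["white_matter"]]]), 1)
  expect_equal(max(w[ph$grid$labels == tissue_labels[["background"]]]), 0)
})

test_that("multi-fiber dosimetry is the superposition of single-fiber
           runs with matching seeds", {
  tab <- toy_table(0.17, 10, 0.9, tissue = "tumor-like")
  g <- homogeneous_phantom(50, 1, label = 1L)
  f1 <- fiber_trajectory(c(20, 25, 0), c(20, 25, 35), 20)
  f2 <- fiber_trajectory(c(30, 25, 0), c(30, 25, 35), 20)
  plan <- ipdt_plan(list(f1, f2), treatment_time = 3600,
                    n_packets = 3000L, seed = 5L)
  sim <- simulate_plan(g, plan, table = tab)

  manual <- lapply(1:2, function(i) {
    src <- build_line_source(plan$fibers[[i]], linear_power = 200)
    run_transport(g, tab, src, n_packets = 3000L, seed = 5L + i - 1L)
  })
  expect_identical(sim$fluence_rate,
                   manual[[1]]$fluence_rate + manual[[2]]$fluence_rate)
  expect_equal(sim$dose$treated_volume_cm3,
               effective_treated_volume(
                 compute_fluence(sim$fluence_rate, 3600), g, 25)$volume_cm3)
})
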