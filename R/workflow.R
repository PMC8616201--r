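#' Run configuration
#'
#' Bundles the planning defaults: 635 nm optical properties, 200 mW/cm
#' linear source power, 131072 photon packets per fiber, 3600 s
#' illumination, the 25 J/cm^2 therapeutic and 250 J/cm^2 display
#' thresholds, and the 9 mm minimum diffuser spacing.
#'
#' @param wavelength_nm Informational wavelength tag (the tissue table must
#'   correspond to it).
#' @param linear_power Source power per diffuser length, mW/cm.
#' @param n_packets Photon packets per fiber.
#' @param treatment_time Illumination time, s.
#' @param threshold Therapeutic fluence threshold, J/cm^2.
#' @param display_threshold High-dose display threshold, J/cm^2.
#' @param min_spacing Minimum diffuser spacing, mm (hard rule; may be
#'   relaxed to 7 mm for sensitivity analyses).
#' @param crossing_clearance Trajectory crossing clearance, mm.
#' @param seed Base RNG seed.
#' @return A `run_config` list.
#' @export
run_config <- function(wavelength_nm = 635, linear_power = 200,
                       n_packets = 131072L, treatment_time = 3600,
                       threshold = 25, display_threshold = 250,
                       min_spacing = 9, crossing_clearance = 1,
                       seed = 1L) {
  structure(list(wavelength_nm = wavelength_nm,
                 linear_power = linear_power,
                 n_packets = as.integer(n_packets),
                 treatment_time = treatment_time, threshold = threshold,
                 display_threshold = display_threshold,
                 min_spacing = min_spacing,
                 crossing_clearance = crossing_clearance,
                 seed = as.integer(seed)),
            class = "run_config")
}

#' Simulate an approved treatment plan
#'
#' End-to-end dosimetry for a validated plan: the plan is re-validated
#' (simulation is refused while alerts stand, mirroring the planning
#' workflow gate); one Monte Carlo transport run per fiber produces a
#' per-fiber fluence-rate map (fiber i seeded with `seed + i - 1`); the
#' maps are summed, multiplied by the illumination time, and thresholded
#' into the effective treated volume and coverage index.
#'
#' @param grid A labelled [voxel_grid()].
#' @param plan An [ipdt_plan()].
#' @param target_mask Optional logical target array for the coverage index.
#' @param table Tissue table (default [default_tissue_table()]).
#' @param profiles Optional list of [super_gaussian()] emission parameters
#'   (or fitted profiles), one per fiber; defaults to
#'   [default_diffuser_profile()].
#' @param config A [run_config()].
#' @return An `ipdt_simulation`: per-fiber results, total fluence-rate and
#'   fluence arrays, treated and high-dose masks, `dose` summary,
#'   `conservation` ledger (one row per fiber), `sources` and the inputs.
#' @export
simulate_plan <- function(grid, plan, target_mask = NULL,
                          table = default_tissue_table(), profiles = NULL,
                          config = run_config(seed = plan$seed)) {
  alerts <- validate_plan(plan, grid, min_spacing = config$min_spacing,
                          crossing_clearance = config$crossing_clearance)
  if (nrow(alerts) > 0)
    stop("plan failed validation with ", nrow(alerts), " alert(s); ",
         "simulation refused:\n", paste("-", alerts$message, collapse = "\n"))

  nf <- length(plan$fibers)
  sources <- vector("list", nf)
  results <- vector("list", nf)
  for (i in seq_len(nf)) {
    params <- if (!is.null(profiles)) profiles[[i]] else NULL
    sources[[i]] <- build_line_source(plan$fibers[[i]], params = params,
                                      linear_power = config$linear_power)
    results[[i]] <- run_transport(grid, table, sources[[i]],
                                  n_packets = plan$n_packets,
                                  seed = plan$seed + i - 1L)
  }
  rate <- sum_fluence_rates(lapply(results, `[[`, "fluence_rate"))
  fluence <- compute_fluence(rate, plan$treatment_time)
  dose <- dose_summary(fluence, grid, target_mask,
                       treatment_time = plan$treatment_time,
                       threshold = config$threshold,
                       display_threshold = config$display_threshold)
  cons <- do.call(rbind, lapply(results, conservation_summary))
  cons$fiber <- seq_len(nf)
  structure(list(plan = plan, config = config, sources = sources,
                 per_fiber = results, fluence_rate = rate,
                 fluence = fluence,
                 treated_mask = effective_treated_volume(
                   fluence, grid, config$threshold)$mask,
                 high_dose_mask = high_dose_region(
                   fluence, config$display_threshold),
                 dose = dose, conservation = cons, alerts = alerts),
            class = "ipdt_simulation")
}

#' @export
print.ipdt_simulation <- function(x, ...) {
  cat(sprintf("<ipdt_simulation> %d fiber(s), %d packets each\n",
              length(x$per_fiber), x$plan$n_packets))
  cat(sprintf("  treated volume: %.3f cm^3 (> %g J/cm^2 in %g s)\n",
              x$dose$treated_volume_cm3, x$dose$threshold_J_cm2,
              x$dose$treatment_time_s))
  if (!is.na(x$dose$coverage_index_pct))
    cat(sprintf("  coverage index: %.1f %%\n", x$dose$coverage_index_pct))
  cat(sprintf("  high-dose volume: %.3f cm^3\n",
              x$dose$high_dose_volume_cm3))
  invisible(x)
}

#' Tidy per-fiber conservation ledger of a simulation
#' @param x An `ipdt_simulation`.
#' @param ... Unused.
#' @return Data frame, one row per fiber.
#' @export
tidy.ipdt_simulation <- function(x, ...) x$conservation

#' One-row dosimetry summary of a simulation
#' @inheritParams tidy.ipdt_simulation
#' @export
glance.ipdt_simulation <- function(x, ...) x$dose

#' @export
tidy <- function(x, ...) UseMethod("tidy")

#' @export
glance <- function(x, ...) UseMethod("glance")

#' Plot an axial fluence slice
#'
#' Heat map of one k-slice of the fluence map with the treated-volume
#' (25 J/cm^2) and high-dose (250 J/cm^2) contours, via ggplot2.
#'
#' @param sim An `ipdt_simulation`.
#' @param k 0-based slice index (default: middle slice).
#' @export
plot_fluence_slice <- function(sim, k = NULL) {
  if (!requireNamespace("ggplot2", quietly = TRUE))
    stop("ggplot2 is required for plotting")
  d <- dim(sim$fluence)
  if (is.null(k)) k <- d[3] %/% 2
  sl <- sim$fluence[, , k + 1L]
  df <- expand.grid(i = seq_len(d[1]), j = seq_len(d[2]))
  df$fluence <- as.vector(sl)
  ggplot2::ggplot(df, ggplot2::aes(i, j)) +
    ggplot2::geom_raster(ggplot2::aes(fill = log10(pmax(fluence, 1e-3)))) +
    ggplot2::geom_contour(ggplot2::aes(z = fluence),
                          breaks = c(sim$dose$threshold_J_cm2,
                                     sim$config$display_threshold),
                          colour = "white") +
    ggplot2::scale_fill_viridis_c(name = "log10 J/cm2") +
    ggplot2::coord_equal() +
    ggplot2::labs(title = sprintf("Fluence, axial slice k = %d", k))
}

#' Plot an emission-profile fit
#'
#' Measured (or synthetic) profile points with the fitted super-Gaussian
#' PDF overlaid.
#'
#' @param profile An [emission_profile()].
#' @param params A fitted [super_gaussian()].
#' @export
plot_emission_fit <- function(profile, params) {
  if (!requireNamespace("ggplot2", quietly = TRUE))
    stop("ggplot2 is required for plotting")
  zg <- seq(0, params$length, length.out = 400)
  fitdf <- data.frame(position = zg,
                      intensity = super_gaussian_pdf(zg, params))
  ggplot2::ggplot(profile, ggplot2::aes(position, intensity)) +
    ggplot2::geom_point() +
    ggplot2::geom_line(data = fitdf, colour = "steelblue") +
    ggplot2::labs(x = "axial position (mm)", y = "normalized emission")
}
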