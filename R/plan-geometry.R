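#' Stereotactic fiber trajectory
#'
#' An optical-fiber insertion defined by its skull entry point and its
#' target point (tip of the inserted fiber) in stereotactic millimetre
#' coordinates — X medial-lateral, Y anterior-posterior, Z cranial-caudal —
#' plus the length of the diffusing part.
#'
#' @param entry,target Length-3 numeric vectors, mm. Must differ.
#' @param diffuser_length Diffusing-part length, mm. Validated against
#'   [allowed_diffuser_lengths] by [validate_plan()], not here, so that
#'   invalid plan files can be read and reported.
#' @return A `fiber_trajectory`.
#' @export
fiber_trajectory <- function(entry, target, diffuser_length) {
  entry <- as.numeric(entry); target <- as.numeric(target)
  if (length(entry) != 3L || length(target) != 3L)
    stop("entry and target must be 3-vectors")
  if (all(entry == target)) stop("entry and target points coincide")
  structure(list(entry = entry, target = target,
                 diffuser_length = as.numeric(diffuser_length)),
            class = "fiber_trajectory")
}

#' @export
print.fiber_trajectory <- function(x, ...) {
  cat(sprintf(
    "<fiber_trajectory> entry (%.1f, %.1f, %.1f) -> target (%.1f, %.1f, %.1f) mm, diffuser %g mm\n",
    x$entry[1], x$entry[2], x$entry[3],
    x$target[1], x$target[2], x$target[3], x$diffuser_length))
  invisible(x)
}

#' Treatment plan
#'
#' @param fibers List of [fiber_trajectory()] objects (at least one).
#' @param treatment_time Illumination time, s (default 3600 — a one-hour
#'   illumination).
#' @param n_packets Photon packets per fiber (default 131072).
#' @param seed Base RNG seed; fiber i uses `seed + i - 1`.
#' @return An `ipdt_plan`.
#' @export
ipdt_plan <- function(fibers, treatment_time = 3600, n_packets = 131072L,
                      seed = 1L) {
  if (inherits(fibers, "fiber_trajectory")) fibers <- list(fibers)
  if (length(fibers) < 1L) stop("a plan needs at least one fiber")
  ok <- vapply(fibers, inherits, logical(1), "fiber_trajectory")
  if (!all(ok)) stop("fibers must be fiber_trajectory objects")
  if (treatment_time < 0) stop("treatment_time must be >= 0")
  structure(list(fibers = fibers, treatment_time = treatment_time,
                 n_packets = as.integer(n_packets), seed = as.integer(seed)),
            class = "ipdt_plan")
}

#' @export
print.ipdt_plan <- function(x, ...) {
  cat(sprintf("<ipdt_plan> %d fiber(s), %g s illumination, %d packets/fiber, seed %d\n",
              length(x$fibers), x$treatment_time, x$n_packets, x$seed))
  for (f in x$fibers) print(f)
  invisible(x)
}

#' Diffusing-part segment of a trajectory
#'
#' The diffuser lies on the entry-to-target axis; by convention its distal
#' end sits at the target point and it extends `diffuser_length` back
#' toward the entry point.
#'
#' @param traj A [fiber_trajectory()].
#' @param distal_at_target Flip to place the proximal end at the target.
#' @return 2 x 3 matrix: proximal and distal endpoint, mm.
#' @export
diffuser_segment <- function(traj, distal_at_target = TRUE) {
  track <- traj$target - traj$entry
  tl <- sqrt(sum(track^2))
  if (tl < traj$diffuser_length)
    stop(sprintf(
      "track length %.2f mm is shorter than the %g mm diffusing part",
      tl, traj$diffuser_length))
  u <- track / tl
  if (distal_at_target) {
    seg <- rbind(traj$target - traj$diffuser_length * u, traj$target)
  } else {
    seg <- rbind(traj$entry, traj$entry + traj$diffuser_length * u)
  }
  rownames(seg) <- c("proximal", "distal")
  seg
}

#' Minimum distance between two 3D segments
#'
#' Exact closed-form minimum Euclidean distance between two closed
#' segments, each a 2 x 3 matrix of endpoints. Used for the 9 mm
#' diffuser-spacing rule and the trajectory-crossing check.
#'
#' @param a,b 2 x 3 matrices (rows = endpoints), mm.
#' @return Distance in mm.
#' @export
segment_min_distance <- function(a, b) {
  p <- a[1, ]; u <- a[2, ] - a[1, ]
  q <- b[1, ]; v <- b[2, ] - b[1, ]
  w0 <- p - q
  A <- sum(u * u); B <- sum(u * v); C <- sum(v * v)
  D <- sum(u * w0); E <- sum(v * w0)
  den <- A * C - B * B
  if (den > 1e-12 * max(A * C, 1e-300)) {
    s <- (B * E - C * D) / den
    t <- (A * E - B * D) / den
  } else { # (near-)parallel: fix s = 0
    s <- 0
    t <- if (C > 0) E / C else 0
  }
  s <- min(max(s, 0), 1)
  # re-optimize t for clamped s, then s for clamped t (standard clamping)
  t <- if (C > 0) min(max((B * s + E) / C, 0), 1) else 0
  s <- if (A > 0) min(max((B * t - D) / A, 0), 1) else 0
  d <- w0 + s * u - t * v
  sqrt(sum(d * d))
}

#' Validate a treatment plan
#'
#' Applies the geometric safety rules before any simulation is allowed:
#' diffusing parts of distinct fibers must be at least `min_spacing` apart
#' (closer spacing risks a thermal hot spot above the 43 degree C tissue
#' tolerance); full insertion paths must not cross (approach within
#' `crossing_clearance`); diffuser lengths must come from the allowed set
#' and fit on their track; diffusers must lie inside the grid.
#'
#' @param plan An [ipdt_plan()].
#' @param grid Optional [voxel_grid()] for the containment check.
#' @param min_spacing Minimum diffuser separation, mm (default 9; exactly
#'   `min_spacing` passes).
#' @param crossing_clearance Minimum approach of two insertion paths, mm
#'   (default 1) before a crossing alert is raised.
#' @return A data frame of alerts (zero rows for a valid plan) with columns
#'   `kind` (`spacing-violation`, `trajectory-crossing`, `invalid-length`,
#'   `out-of-grid`), `fibers`, `value` (the offending measurement, mm) and
#'   `message`.
#' @export
validate_plan <- function(plan, grid = NULL, min_spacing = 9,
                          crossing_clearance = 1) {
  alerts <- list()
  add <- function(kind, fibers, value, message) {
    alerts[[length(alerts) + 1L]] <<- data.frame(
      kind = kind, fibers = paste(fibers, collapse = ","),
      value = value, message = message, stringsAsFactors = FALSE)
  }
  nf <- length(plan$fibers)

  segs <- vector("list", nf)
  for (i in seq_len(nf)) {
    f <- plan$fibers[[i]]
    if (!f$diffuser_length %in% allowed_diffuser_lengths)
      add("invalid-length", i, f$diffuser_length,
          sprintf("fiber %d: diffuser length %g mm not in {%s} mm", i,
                  f$diffuser_length,
                  paste(allowed_diffuser_lengths, collapse = ", ")))
    tl <- sqrt(sum((f$target - f$entry)^2))
    if (tl < f$diffuser_length) {
      add("invalid-length", i, tl,
          sprintf("fiber %d: track %.2f mm shorter than diffuser %g mm",
                  i, tl, f$diffuser_length))
    } else {
      segs[[i]] <- diffuser_segment(f)
      if (!is.null(grid)) {
        inside <- tryCatch({
          world_to_voxel(segs[[i]], grid); TRUE
        }, error = function(e) FALSE)
        if (!inside)
          add("out-of-grid", i, NA_real_,
              sprintf("fiber %d: diffusing part extends outside the volume", i))
      }
    }
  }

  if (nf >= 2L) {
    for (i in seq_len(nf - 1L)) for (j in seq((i + 1L), nf)) {
      if (!is.null(segs[[i]]) && !is.null(segs[[j]])) {
        d <- segment_min_distance(segs[[i]], segs[[j]])
        if (d < min_spacing)
          add("spacing-violation", c(i, j), d,
              sprintf("diffusers of fibers %d and %d are %.2f mm apart (< %g mm)",
                      i, j, d, min_spacing))
      }
      ti <- rbind(plan$fibers[[i]]$entry, plan$fibers[[i]]$target)
      tj <- rbind(plan$fibers[[j]]$entry, plan$fibers[[j]]$target)
      dt <- segment_min_distance(ti, tj)
      if (dt < crossing_clearance)
        add("trajectory-crossing", c(i, j), dt,
            sprintf("insertion paths of fibers %d and %d approach to %.2f mm",
                    i, j, dt))
    }
  }

  if (length(alerts)) do.call(rbind, alerts)
  else data.frame(kind = character(), fibers = character(),
                  value = numeric(), message = character(),
                  stringsAsFactors = FALSE)
}

#' Read / write a fiber plan as delimited text
#'
#' One fiber per row: `entry_x entry_y entry_z target_x target_y target_z
#' length_mm` (tab-separated, `#` comments).
#'
#' @param path File path.
#' @param treatment_time,n_packets,seed Plan-level settings attached on
#'   read (see [ipdt_plan()]).
#' @return `read_plan()`: an [ipdt_plan()].
#' @export
read_plan <- function(path, treatment_time = 3600, n_packets = 131072L,
                      seed = 1L) {
  tab <- utils::read.delim(path, comment.char = "#")
  needed <- c("entry_x", "entry_y", "entry_z",
              "target_x", "target_y", "target_z", "length_mm")
  missing <- setdiff(needed, names(tab))
  if (length(missing))
    stop("plan file ", path, " lacks column(s): ",
         paste(missing, collapse = ", "))
  fibers <- lapply(seq_len(nrow(tab)), function(i)
    fiber_trajectory(unlist(tab[i, 1:3]), unlist(tab[i, 4:6]),
                     tab$length_mm[i]))
  ipdt_plan(fibers, treatment_time = treatment_time,
            n_packets = n_packets, seed = seed)
}

#' @rdname read_plan
#' @param plan An [ipdt_plan()] to write.
#' @export
write_plan <- function(plan, path) {
  rows <- t(vapply(plan$fibers, function(f)
    c(f$entry, f$target, f$diffuser_length), numeric(7)))
  colnames(rows) <- c("entry_x", "entry_y", "entry_z",
                      "target_x", "target_y", "target_z", "length_mm")
  utils::write.table(as.data.frame(rows), path, sep = "\t",
                     row.names = FALSE, quote = FALSE)
  invisible(path)
}

#' Export the plan report
#'
#' Writes the approved plan as a structured JSON report: per fiber the
#' stereotactic entry/target coordinates, diffuser length, linear power and
#' fitted emission-PDF parameters; plus the dosimetry summary, thresholds,
#' seeds and software version. Refused when the plan carries validation
#' alerts, mirroring the gate that prevents simulation of an invalid plan.
#'
#' @param plan An [ipdt_plan()].
#' @param alerts Alert data frame from [validate_plan()].
#' @param dose A `dose_summary` data frame (see [dose_summary()]); optional.
#' @param sources Optional list of `line_source` objects (one per fiber)
#'   whose emission parameters are echoed into the report.
#' @param path Output JSON path.
#' @export
export_plan_report <- function(plan, alerts, dose = NULL, sources = NULL,
                               path) {
  if (nrow(alerts) > 0)
    stop("plan has ", nrow(alerts), " validation alert(s); refusing to ",
         "export a report:\n",
         paste("-", alerts$message, collapse = "\n"))
  fibers <- lapply(seq_along(plan$fibers), function(i) {
    f <- plan$fibers[[i]]
    rec <- list(index = i, entry_mm = f$entry, target_mm = f$target,
                diffuser_length_mm = f$diffuser_length)
    if (!is.null(sources)) {
      s <- sources[[i]]
      rec$linear_power_mW_per_cm <- s$linear_power
      rec$total_power_mW <- s$total_power
      rec$emission_pdf <- list(center = s$pdf$center, width = s$pdf$width,
                               order = s$pdf$order, length = s$pdf$length)
    }
    rec
  })
  report <- list(
    software = paste("ipdt",
                     as.character(utils::packageVersion("ipdt"))),
    seed = plan$seed, n_packets = plan$n_packets,
    treatment_time_s = plan$treatment_time,
    fibers = fibers,
    dosimetry = if (!is.null(dose)) as.list(dose) else NULL)
  jsonlite::write_json(report, path, auto_unbox = TRUE, digits = NA,
                       pretty = TRUE)
  invisible(path)
}

#' Read back an exported plan report
#' @param path JSON report path.
#' @return Nested list mirroring the report structure.
#' @export
read_plan_report <- function(path) {
  jsonlite::read_json(path, simplifyVector = TRUE, simplifyDataFrame = FALSE)
}
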