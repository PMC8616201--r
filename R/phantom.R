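#' Synthetic segmented-brain phantom specification
#'
#' Describes a concentric glioblastoma-like lesion embedded in a spherical
#' head: necrotic core, enhancing rim, non-enhancing region and oedema
#' shell (strictly nested radii), inside white matter bounded by a
#' grey-matter cortical shell, with optional ventricle-like CSF
#' inclusions. Geometry is deterministic; the seed is carried for
#' components that may become stochastic in derived specs.
#'
#' @param dims Grid size in voxels (length 1 or 3; default 120).
#' @param voxel_size Voxel size, mm (default 1, the usual MRI slice scale).
#' @param tumor_center Lesion centre, mm (world; default grid centre).
#' @param r_necrotic,r_enhancing,r_non_enhancing,r_oedema Strictly nested
#'   compartment radii, mm.
#' @param grey_thickness Cortical grey-matter shell thickness, mm.
#' @param csf_centers,csf_radius Optional CSF sphere centres (n x 3 mm
#'   matrix, NULL for none) and common radius.
#' @param head_radius Outer head radius, mm (default: fits the grid).
#' @param seed Integer seed recorded in the spec.
#' @return A `phantom_spec`.
#' @export
phantom_spec <- function(dims = 120, voxel_size = 1, tumor_center = NULL,
                         r_necrotic = 6, r_enhancing = 10,
                         r_non_enhancing = 14, r_oedema = 20,
                         grey_thickness = 3, csf_centers = NULL,
                         csf_radius = 4, head_radius = NULL, seed = 1L) {
  dims <- rep_len(as.integer(dims), 3L)
  voxel_size <- rep_len(as.numeric(voxel_size), 3L)
  extent <- dims * voxel_size
  if (is.null(tumor_center)) tumor_center <- extent / 2
  if (is.null(head_radius)) head_radius <- min(extent) / 2 - max(voxel_size)
  radii <- c(r_necrotic, r_enhancing, r_non_enhancing, r_oedema)
  if (any(diff(radii) <= 0) || any(radii <= 0))
    stop("compartment radii must be positive and strictly nested")
  if (sqrt(sum((tumor_center - extent / 2)^2)) + r_oedema > head_radius)
    stop("tumor compartments extend outside the head")
  structure(list(dims = dims, voxel_size = voxel_size,
                 tumor_center = tumor_center, r_necrotic = r_necrotic,
                 r_enhancing = r_enhancing,
                 r_non_enhancing = r_non_enhancing, r_oedema = r_oedema,
                 grey_thickness = grey_thickness,
                 csf_centers = csf_centers, csf_radius = csf_radius,
                 head_radius = head_radius, seed = as.integer(seed)),
            class = "phantom_spec")
}

#' Generate a segmented phantom and its target mask
#'
#' Rasterizes the [phantom_spec()] compartments onto the voxel grid (a
#' voxel belongs to a compartment when its centre does). The target mask is
#' the union of the necrotic, enhancing and non-enhancing compartments —
#' the contoured tumor — optionally extended to the oedema shell, echoing
#' the open clinical question of whether to treat the infiltrated
#' perilesional oedema.
#'
#' @param spec A [phantom_spec()].
#' @param target_includes_oedema Include the oedema shell in the target
#'   mask (default FALSE).
#' @return List with `grid` (a [voxel_grid()]) and `target` (logical
#'   array).
#' @export
generate_phantom <- function(spec, target_includes_oedema = FALSE) {
  set.seed(spec$seed)
  d <- spec$dims; h <- spec$voxel_size
  cx <- (seq_len(d[1]) - 0.5) * h[1]
  cy <- (seq_len(d[2]) - 0.5) * h[2]
  cz <- (seq_len(d[3]) - 0.5) * h[3]
  extent <- d * h
  hc <- extent / 2 # head centre

  dist2 <- function(center) {
    outer(outer((cx - center[1])^2, (cy - center[2])^2, `+`),
          (cz - center[3])^2, `+`)
  }
  r2_head <- dist2(hc)
  r2_tum <- dist2(spec$tumor_center)

  lab <- array(tissue_labels[["background"]], dim = d)
  inside <- r2_head <= spec$head_radius^2
  lab[inside] <- tissue_labels[["white_matter"]]
  greys <- inside & r2_head > (spec$head_radius - spec$grey_thickness)^2
  lab[greys] <- tissue_labels[["grey_matter"]]
  if (!is.null(spec$csf_centers)) {
    ccs <- as_point_matrix(spec$csf_centers)
    for (i in seq_len(nrow(ccs)))
      lab[dist2(ccs[i, ]) <= spec$csf_radius^2 & inside] <-
        tissue_labels[["csf"]]
  }
  lab[r2_tum <= spec$r_oedema^2] <- tissue_labels[["oedema"]]
  lab[r2_tum <= spec$r_non_enhancing^2] <- tissue_labels[["non_enhancing"]]
  lab[r2_tum <= spec$r_enhancing^2] <- tissue_labels[["enhancing"]]
  lab[r2_tum <= spec$r_necrotic^2] <- tissue_labels[["necrotic"]]

  target_r <- if (target_includes_oedema) spec$r_oedema else
    spec$r_non_enhancing
  target <- r2_tum <= target_r^2

  # affine: world = voxel-centre index * h (0-based), i.e. cx above minus h/2
  aff <- diag(c(h, 1)); aff[1:3, 4] <- h / 2
  list(grid = voxel_grid(lab, voxel_size = h, affine = aff),
       target = target)
}

#' Homogeneous single-tissue phantom
#'
#' A grid filled with one tissue label — the standard configuration for
#' validating the transport engine against homogeneous-medium closed
#' forms.
#'
#' @param dims Grid size in voxels (length 1 or 3).
#' @param voxel_size Voxel size, mm.
#' @param label Tissue label filling the grid.
#' @return A [voxel_grid()].
#' @export
homogeneous_phantom <- function(dims, voxel_size = 1,
                                label = tissue_labels[["white_matter"]]) {
  dims <- rep_len(as.integer(dims), 3L)
  aff <- diag(c(rep_len(voxel_size, 3L), 1))
  aff[1:3, 4] <- rep_len(voxel_size, 3L) / 2
  voxel_grid(array(as.integer(label), dim = dims), voxel_size,
             affine = aff)
}

#' Generate a synthetic diffuser emission profile
#'
#' Samples the normalized super-Gaussian PDF at equally spaced axial
#' positions and adds Gaussian noise (clipped at zero) — a synthetic
#' stand-in for a bench-measured diffuser profile.
#'
#' @param length Diffuser length, mm.
#' @param center,width,order Super-Gaussian parameters (see
#'   [super_gaussian()]).
#' @param noise_sd Gaussian noise standard deviation (on the PDF scale).
#' @param n Number of sample positions (default 61).
#' @param seed Optional seed.
#' @return An [emission_profile()].
#' @export
generate_emission_profile <- function(length, center = length / 2,
                                      width = 0.4 * length, order = 3,
                                      noise_sd = 0, n = 61L, seed = NULL) {
  if (!is.null(seed)) set.seed(seed)
  params <- super_gaussian(center, width, order, length)
  z <- seq(0, length, length.out = n)
  y <- super_gaussian_pdf(z, params)
  if (noise_sd > 0) y <- pmax(y + stats::rnorm(n, sd = noise_sd), 0)
  emission_profile(z, y)
}

#' Uniform fluence fixture
#'
#' A fluence map holding a constant value inside a region and zero outside
#' — used to exercise threshold logic deterministically.
#'
#' @param grid A [voxel_grid()].
#' @param value Fluence value, J/cm^2.
#' @param region_mask Logical array on the grid.
#' @return Fluence array.
#' @export
uniform_fluence_fixture <- function(grid, value, region_mask) {
  if (!identical(dim(region_mask), dim(grid$labels)))
    stop("region mask is not on the grid")
  out <- array(0, dim = grid$dims)
  out[region_mask] <- value
  out
}
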