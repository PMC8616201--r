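#' Tissue label coding
#'
#' Integer codes for the seven segmented brain tissue classes plus
#' background. Label volumes consumed by the planner must use this coding
#' (or a custom table registered with the same labels).
#'
#' @format Named integer vector: background 0, csf 1, grey_matter 2,
#'   white_matter 3, necrotic 4, non_enhancing 5, enhancing 6, oedema 7.
#' @export
tissue_labels <- c(
  background = 0L, csf = 1L, grey_matter = 2L, white_matter = 3L,
  necrotic = 4L, non_enhancing = 5L, enhancing = 6L, oedema = 7L
)

#' Read a tissue optical-property table
#'
#' The table maps each tissue label to its absorption coefficient `mu_a`
#' (per mm), scattering coefficient `mu_s` (per mm), anisotropy factor `g`
#' and refractive index `n_ri` at the treatment wavelength. The packaged
#' default holds the seven-class segmentation values at 635 nm; an
#' alternative table with the same columns may be supplied (e.g. to the
#' command-line tool via `--tissue-table`).
#'
#' @param path Path to a tab-delimited file with columns `label`, `tissue`,
#'   `mu_a`, `mu_s`, `g`, `n_ri`. Lines starting with `#` are comments.
#' @return A `tissue_table` data frame.
#' @export
read_tissue_table <- function(path) {
  tab <- utils::read.delim(path, comment.char = "#", stringsAsFactors = FALSE)
  validate_tissue_table(tab)
}

#' Default optical properties at 635 nm
#'
#' @return The packaged seven-tissue `tissue_table`.
#' @export
default_tissue_table <- function() {
  read_tissue_table(system.file("extdata", "tissue_optics_635nm.tsv",
                                package = "ipdt", mustWork = TRUE))
}

validate_tissue_table <- function(tab) {
  needed <- c("label", "tissue", "mu_a", "mu_s", "g", "n_ri")
  missing <- setdiff(needed, names(tab))
  if (length(missing))
    stop("tissue table lacks column(s): ", paste(missing, collapse = ", "))
  if (anyDuplicated(tab$label))
    stop("tissue table has duplicated labels")
  if (any(tab$label == 0L))
    stop("label 0 is reserved for background and cannot carry properties")
  if (any(tab$mu_a < 0) || any(tab$mu_s < 0))
    stop("mu_a and mu_s must be non-negative")
  if (any(abs(tab$g) > 1))
    stop("anisotropy g must lie in [-1, 1]")
  if (any(tab$n_ri < 1))
    stop("refractive index must be >= 1")
  class(tab) <- c("tissue_table", "data.frame")
  tab
}

#' Look up the optical properties of one tissue
#'
#' @param table A `tissue_table`.
#' @param label Integer label code or tissue name.
#' @return A one-row list with `mu_a`, `mu_s`, `g`, `n_ri` (class
#'   `optical_props`).
#' @export
lookup_properties <- function(table, label) {
  if (is.character(label)) {
    row <- which(table$tissue == label)
  } else {
    row <- which(table$label == as.integer(label))
  }
  if (length(row) != 1L)
    stop("tissue label not registered in table: ", label)
  props <- as.list(table[row, c("mu_a", "mu_s", "g", "n_ri")])
  props$tissue <- table$tissue[row]
  props$label <- table$label[row]
  class(props) <- "optical_props"
  props
}

#' Reduced scattering coefficient
#'
#' `mu_s' = mu_s * (1 - g)`, per mm.
#'
#' @param props An `optical_props` (or any list/data frame with `mu_s`, `g`).
#' @return Numeric, per mm.
#' @export
reduced_scattering <- function(props) {
  props$mu_s * (1 - props$g)
}

#' Effective attenuation coefficient
#'
#' `mu_eff = sqrt(3 * mu_a * (mu_a + mu_s'))`, per mm — the asymptotic decay
#' constant of diffuse light in a scattering-dominated medium.
#'
#' @inheritParams reduced_scattering
#' @return Numeric, per mm.
#' @export
effective_attenuation <- function(props) {
  sqrt(3 * props$mu_a * (props$mu_a + reduced_scattering(props)))
}

#' Diffusion-theory fluence rate of an isotropic point source
#'
#' Infinite homogeneous medium solution
#' `phi(r) = P * exp(-mu_eff * r) / (4 * pi * D * r)` with diffusion
#' coefficient `D = 1 / (3 * (mu_a + mu_s'))`. Valid where scattering
#' dominates absorption and r exceeds a few transport mean free paths; used
#' as an analytic cross-check of the Monte Carlo engine.
#'
#' @inheritParams reduced_scattering
#' @param power Source power in mW.
#' @param r Radial distance(s) from the source in mm; must be > 0.
#' @return Fluence rate(s) in mW/cm^2.
#' @export
diffusion_point_fluence <- function(props, power, r) {
  if (any(r <= 0)) stop("r must be > 0")
  musp <- reduced_scattering(props)
  D <- 1 / (3 * (props$mu_a + musp))      # mm
  mu_eff <- effective_attenuation(props)  # per mm
  phi_mm2 <- power * exp(-mu_eff * r) / (4 * pi * D * r) # mW/mm^2
  per_mm2_to_per_cm2(phi_mm2)
}

# All internal lengths are mm; fluence is reported per cm^2 (as in the
# 25 J/cm^2 therapeutic threshold). This is the single conversion point.
per_mm2_to_per_cm2 <- function(x) 100 * x

#' @export
print.optical_props <- function(x, ...) {
  cat(sprintf("<optical_props> %s (label %d): mu_a=%g/mm mu_s=%g/mm g=%g n=%g\n",
              x$tissue, x$label, x$mu_a, x$mu_s, x$g, x$n_ri))
  invisible(x)
}

#' @export
print.tissue_table <- function(x, ...) {
  cat("<tissue_table> optical properties,", nrow(x), "tissues\n")
  print.data.frame(x, row.names = FALSE)
  invisible(x)
}
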