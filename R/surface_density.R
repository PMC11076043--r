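# Absolute surface densities from dilute labeled-species counting and from
# lipid mole fractions.

#' Surface density from single-particle counts of a dilute labeled fraction
#'
#' Counting a sparse, fluorescently labeled subpopulation and dividing by the
#' labeled fraction gives the total density of the (mostly dark) species:
#' `density = (mean count / area) / labeled_fraction`. When per-frame counts
#' are supplied they are averaged before conversion and a Poisson standard
#' error is attached.
#'
#' @param n_particles Particle count, or a vector of per-frame counts.
#' @param area_um2 Observed area in um^2.
#' @param labeled_fraction Fraction of molecules carrying the label, in
#'   (0, 1] (e.g. 1e-4 for a 1:10,000 doping ratio).
#' @param species Optional species label.
#' @return An object of class `SurfaceDensity`: list with `value`
#'   (molecules/um^2), `se`, `species`, `method = "counts"`.
#' @examples
#' density_from_particle_counts(1200, 3000, 1e-4)$value  # 4000 molecules/um^2
#' @export
density_from_particle_counts <- function(n_particles, area_um2,
                                         labeled_fraction,
                                         species = NA_character_) {
  check_positive(area_um2, "area_um2")
  if (!is.numeric(labeled_fraction) || length(labeled_fraction) != 1L ||
      labeled_fraction <= 0 || labeled_fraction > 1)
    stop("`labeled_fraction` must be in (0, 1]", call. = FALSE)
  if (any(n_particles < 0)) stop("counts must be non-negative", call. = FALSE)
  m <- mean(n_particles)
  # Poisson SE of the mean count, propagated through the linear conversion.
  se <- sqrt(m / length(n_particles)) / area_um2 / labeled_fraction
  structure(list(value = (m / area_um2) / labeled_fraction, se = se,
                 species = species, method = "counts"),
            class = "SurfaceDensity")
}

#' Lipid surface density from a mole fraction and per-lipid footprint
#'
#' Accessible-leaflet convention: only the solution-facing leaflet is counted,
#' so `density = mole_fraction * 1e6 / footprint_nm2` lipids per um^2 (1 um^2
#' = 1e6 nm^2). With the phosphatidylcholine footprint of 0.72 nm^2, a 2 mol%
#' lipid gives 2.8e4 lipids/um^2.
#'
#' @param mole_fraction Mole fraction of the lipid in the bilayer mix, in
#'   \[0, 1\].
#' @param footprint_nm2 Area per lipid in nm^2 (default 0.72).
#' @param species Optional species label.
#' @return An object of class `SurfaceDensity` with `method = "footprint"`.
#' @examples
#' lipid_surface_density(0.02)$value  # ~2.8e4 lipids/um^2
#' @export
lipid_surface_density <- function(mole_fraction, footprint_nm2 = 0.72,
                                  species = NA_character_) {
  check_fraction(mole_fraction, "mole_fraction")
  check_positive(footprint_nm2, "footprint_nm2")
  structure(list(value = mole_fraction * 1e6 / footprint_nm2, se = NA_real_,
                 species = species, method = "footprint"),
            class = "SurfaceDensity")
}
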