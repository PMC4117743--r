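#' Physical parameters of the coarse-grained chromatin fiber
#'
#' Bundles the physical constants of the bead-chain chromatin model: a
#' 30 nm fiber discretised into beads of one fiber diameter, grouped into
#' rigid persistence units of one persistence length (150 nm = 5 beads),
#' each bead carrying 3 kb of DNA. Chains are grown inside a spherical
#' confinement whose diameter defaults to the nuclear sub-volume
#' available to a 15 Mb chain (1.5 um).
#'
#' @param bead_diameter_nm Fiber (bead) diameter in nm.
#' @param persistence_length_nm Persistence length in nm; must be an
#'   integer multiple of `bead_diameter_nm`.
#' @param bp_per_bead DNA content of one bead in base pairs.
#' @param k_states Number of discrete candidate growth directions per step.
#' @param confinement_diameter_um Diameter of the confining sphere in
#'   micrometers; use `Inf` for unconfined (free-space) growth.
#' @param contact_radius_nm Centre-to-centre distance below which two
#'   beads count as being in contact. Defaults to two bead diameters
#'   (60 nm), a touching-to-near-touching criterion; scaling exponents
#'   are insensitive to this prefactor.
#'
#' @return An object of class `csac_params`: a list with the fields above
#'   plus `beads_per_unit` (persistence length / bead diameter).
#' @examples
#' p <- csac_params()
#' p$beads_per_unit  # 5
#' @export
csac_params <- function(bead_diameter_nm = 30,
                        persistence_length_nm = 150,
                        bp_per_bead = 3000,
                        k_states = 100,
                        confinement_diameter_um = 1.5,
                        contact_radius_nm = 60) {
  stopifnot(bead_diameter_nm > 0, persistence_length_nm > 0,
            bp_per_bead > 0, k_states >= 2, contact_radius_nm > 0)
  ratio <- persistence_length_nm / bead_diameter_nm
  if (abs(ratio - round(ratio)) > 1e-9) {
    abort(paste0("persistence_length_nm (", persistence_length_nm,
                 ") must be an integer multiple of bead_diameter_nm (",
                 bead_diameter_nm, ")"), class = "csac_config_error")
  }
  if (!is.infinite(confinement_diameter_um) &&
      confinement_diameter_um * 1000 <= bead_diameter_nm) {
    abort("confinement diameter must exceed one bead diameter",
          class = "csac_config_error")
  }
  structure(
    list(
      bead_diameter_nm = bead_diameter_nm,
      persistence_length_nm = persistence_length_nm,
      bp_per_bead = bp_per_bead,
      beads_per_unit = as.integer(round(ratio)),
      k_states = as.integer(k_states),
      confinement_diameter_um = confinement_diameter_um,
      contact_radius_nm = contact_radius_nm
    ),
    class = "csac_params"
  )
}

#' @export
print.csac_params <- function(x, ...) {
  cat("<csac_params>\n")
  cat(sprintf("  bead diameter      : %g nm (%g bp)\n",
              x$bead_diameter_nm, x$bp_per_bead))
  cat(sprintf("  persistence length : %g nm (%d beads/unit)\n",
              x$persistence_length_nm, x$beads_per_unit))
  cat(sprintf("  k candidate states : %d\n", x$k_states))
  cat(sprintf("  confinement        : %s\n",
              if (is.infinite(x$confinement_diameter_um)) "free space"
              else paste0(x$confinement_diameter_um, " um sphere")))
  cat(sprintf("  contact radius     : %g nm\n", x$contact_radius_nm))
  invisible(x)
}

#' Number of monomer beads in a chain of `n_units` persistence units
#'
#' A chain of N persistence units has one boundary bead plus, for each of
#' the N - 1 units, `beads_per_unit` interpolated/boundary beads:
#' N' = N + (N - 1) (L_p / d_f - 1). With defaults, `bead_count(1000)`
#' is 4996.
#'
#' @param n_units Number of persistence units (>= 1).
#' @param params A [csac_params()] object.
#' @return Integer bead count N'.
#' @examples
#' bead_count(1000)  # 4996
#' @export
bead_count <- function(n_units, params = csac_params()) {
  stopifnot(n_units >= 1)
  as.integer(n_units + (n_units - 1) * (params$beads_per_unit - 1))
}

#' Confinement diameter at equal DNA density
#'
#' Diameter of the nuclear sub-sphere available to a chain of
#' `chain_bp` base pairs, assuming the genome fills the nucleus at
#' uniform density: D = D_nucleus (chain_bp / genome_bp)^(1/3).
#' For a 15 Mb chain in an 11 um nucleus holding 6 Gb this gives about
#' 1.5 um; conversely ~400 such 15 Mb regions pack into a sphere of
#' 400^(1/3) ~ 7.4 D ~ 11 um.
#'
#' @param chain_bp DNA content of the chain in bp.
#' @param nucleus_diameter_um Nuclear diameter in micrometers.
#' @param genome_bp Genome size in bp.
#' @return Confinement diameter in micrometers.
#' @examples
#' confinement_diameter_for(15e6, 11, 6e9)  # ~1.5
#' @export
confinement_diameter_for <- function(chain_bp, nucleus_diameter_um = 11,
                                     genome_bp = 6e9) {
  stopifnot(chain_bp > 0, nucleus_diameter_um > 0, genome_bp > 0)
  if (chain_bp > genome_bp) {
    abort("chain_bp must not exceed genome_bp", class = "csac_config_error")
  }
  nucleus_diameter_um * (chain_bp / genome_bp)^(1 / 3)
}
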