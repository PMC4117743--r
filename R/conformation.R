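#' Construct a conformation object
#'
#' A conformation is one chain: an N' x 3 matrix of bead centre
#' coordinates in nm, its Rosenbluth log-weight, and its growth
#' condition. Unit-boundary beads sit at rows 1, 1 + b, 1 + 2b, ...
#' where b is `params$beads_per_unit`.
#'
#' @param coords Numeric matrix (N' x 3) of bead centres in nm.
#' @param n_units Number of persistence units.
#' @param log_weight Log importance weight, `sum(log(m_t / k))` over
#'   growth steps (0 for an unobstructed chain).
#' @param params A [csac_params()] object.
#' @param seed Integer seed recorded for provenance (may be `NA`).
#' @param validate Run the self-avoidance and confinement predicates.
#' @return An object of class `csac_conformation`.
#' @export
conformation <- function(coords, n_units, log_weight = 0,
                         params = csac_params(), seed = NA_integer_,
                         validate = FALSE) {
  coords <- as.matrix(coords)
  storage.mode(coords) <- "double"
  stopifnot(ncol(coords) == 3)
  expected <- bead_count(n_units, params)
  if (nrow(coords) != expected) {
    abort(sprintf("expected %d beads for %d units, got %d",
                  expected, n_units, nrow(coords)),
          class = "csac_validation_error")
  }
  x <- structure(
    list(coords = coords, n_units = as.integer(n_units),
         log_weight = log_weight, params = params,
         confinement_um = params$confinement_diameter_um,
         seed = seed),
    class = "csac_conformation"
  )
  if (validate) {
    sa <- check_self_avoidance(x)
    if (!sa$ok) {
      abort(sprintf("conformation violates self-avoidance (%d pairs)",
                    nrow(sa$pairs)), class = "csac_validation_error")
    }
    if (!is.infinite(x$confinement_um) &&
        !check_confinement(x, x$confinement_um)) {
      abort("conformation violates confinement", class = "csac_validation_error")
    }
  }
  x
}

#' @export
print.csac_conformation <- function(x, ...) {
  cat(sprintf("<csac_conformation> %d units / %d beads, log-weight %.3f, %s\n",
              x$n_units, nrow(x$coords), x$log_weight,
              if (is.infinite(x$confinement_um)) "free space"
              else paste0("D = ", x$confinement_um, " um")))
  invisible(x)
}

#' Indices of persistence-unit boundary beads
#'
#' @param conf A `csac_conformation`.
#' @return Integer vector of row indices into `conf$coords`.
#' @export
unit_indices <- function(conf) {
  seq(1L, nrow(conf$coords), by = conf$params$beads_per_unit)
}

#' Coordinates of the persistence-unit boundary beads
#'
#' @param conf A `csac_conformation`.
#' @return An `n_units` x 3 matrix in nm.
#' @export
unit_coords <- function(conf) {
  conf$coords[unit_indices(conf), , drop = FALSE]
}

#' Check the excluded-volume (self-avoidance) constraint
#'
#' Every non-bonded bead pair (|i - j| >= 2) must be at least one bead
#' diameter apart (within `tol`). Directly bonded neighbours sit at
#' exactly one bead diameter by construction and are exempt. The check
#' runs on a uniform cell grid; tests verify it against a brute-force
#' all-pairs oracle.
#'
#' @param conf A `csac_conformation` (or bare coordinate matrix).
#' @param params A [csac_params()] object (ignored when `conf` carries one).
#' @param tol Tolerance in nm on the equality boundary.
#' @return A list with `ok` (logical) and `pairs` (two-column matrix of
#'   violating bead index pairs, possibly empty).
#' @export
check_self_avoidance <- function(conf, params = csac_params(), tol = 1e-6) {
  if (inherits(conf, "csac_conformation")) {
    coords <- conf$coords
    params <- conf$params
  } else {
    coords <- as.matrix(conf)
  }
  if (nrow(coords) < 2) {
    return(list(ok = TRUE, pairs = matrix(integer(0), 0, 2)))
  }
  pairs <- cpp_overlap_pairs(coords, params$bead_diameter_nm, tol)
  list(ok = nrow(pairs) == 0, pairs = pairs)
}

#' Check spherical confinement
#'
#' All bead centres must lie within radius D/2 - d_f/2 of the origin so
#' that beads are entirely inside the sphere (set
#' `whole_bead = FALSE` for a centre-only test).
#'
#' @param conf A `csac_conformation` (or coordinate matrix).
#' @param D_um Confinement diameter in micrometers.
#' @param params A [csac_params()] object (ignored when `conf` carries one).
#' @param whole_bead Subtract one bead radius from the allowed radius.
#' @return Logical.
#' @export
check_confinement <- function(conf, D_um, params = csac_params(),
                              whole_bead = TRUE) {
  if (inherits(conf, "csac_conformation")) {
    coords <- conf$coords
    params <- conf$params
    if (missing(D_um)) D_um <- conf$confinement_um
  } else {
    coords <- as.matrix(conf)
  }
  if (is.infinite(D_um)) return(TRUE)
  if (D_um * 1000 <= params$bead_diameter_nm) {
    abort("confinement diameter must exceed one bead diameter",
          class = "csac_config_error")
  }
  r_allow <- D_um * 1000 / 2 - if (whole_bead) params$bead_diameter_nm / 2 else 0
  all(rowSums(coords^2) <= r_allow^2 + 1e-9)
}

#' Radius of gyration of a conformation
#'
#' @param conf A `csac_conformation`.
#' @param resolution Use all beads or unit-boundary beads only.
#' @return Radius of gyration in nm.
#' @export
radius_of_gyration <- function(conf, resolution = c("beads", "units")) {
  resolution <- match.arg(resolution)
  m <- if (resolution == "beads") conf$coords else unit_coords(conf)
  ctr <- colMeans(m)
  sqrt(mean(rowSums(sweep(m, 2, ctr)^2)))
}

#' Pairwise spatial distance matrix of one conformation
#'
#' @param conf A `csac_conformation`.
#' @param resolution `"units"` (default) for unit-boundary beads,
#'   `"beads"` for all beads.
#' @return A symmetric matrix of Euclidean distances in nm.
#' @export
distance_matrix <- function(conf, resolution = c("units", "beads")) {
  resolution <- match.arg(resolution)
  m <- if (resolution == "units") unit_coords(conf) else conf$coords
  as.matrix(stats::dist(m))
}
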