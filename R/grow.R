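#' Candidate growth directions on the unit sphere
#'
#' Builds the k-state candidate set used at every growth step: k
#' near-uniform unit vectors from a Fibonacci-sphere construction,
#' optionally rotated by a uniformly random rotation (one rotation per
#' chain restores the rotational isotropy a fixed discrete set would
#' break).
#'
#' @param k Number of candidate directions (>= 2).
#' @param seed Integer seed for the random rotation; ignored when
#'   `rotate = FALSE`.
#' @param rotate Apply a random rotation to the base set.
#' @return A k x 3 matrix of unit vectors.
#' @export
make_candidate_set <- function(k, seed = 1L, rotate = TRUE) {
  stopifnot(k >= 2)
  dirs <- cpp_fibonacci_sphere(as.integer(k))
  if (rotate) dirs <- dirs %*% t(cpp_random_rotation(as.double(seed)))
  dirs
}

#' Feasible growth moves from the tip of a partial chain
#'
#' A candidate direction is feasible when the whole next persistence
#' unit -- the new boundary bead and every interpolated bead on the
#' rigid segment -- neither overlaps any existing bead nor leaves the
#' confining sphere.
#'
#' @param coords Bead coordinates of the valid partial chain (the last
#'   row is the growth tip).
#' @param candidates A k x 3 matrix of unit directions.
#' @param D_um Confinement diameter in micrometers (`Inf` for free space).
#' @param params A [csac_params()] object.
#' @return Integer vector of feasible candidate row indices (may be empty).
#' @export
feasible_moves <- function(coords, candidates, D_um = Inf,
                           params = csac_params()) {
  coords <- as.matrix(coords)
  r_allow <- if (is.infinite(D_um)) -1
             else D_um * 1000 / 2 - params$bead_diameter_nm / 2
  ok <- cpp_feasible_moves(coords, as.matrix(candidates), r_allow,
                           params$bead_diameter_nm, params$beads_per_unit)
  which(ok)
}

r_allow_nm <- function(D_um, params) {
  if (is.infinite(D_um)) return(-1)
  D_um * 1000 / 2 - params$bead_diameter_nm / 2
}

#' Grow a single self-avoiding chain
#'
#' Grows a chain of `n_units` persistence units one unit at a time by
#' sequential importance sampling: at each step the next unit is chosen
#' uniformly among the feasible members of the k-state candidate set and
#' the Rosenbluth log-weight accumulates `log(m_t / k)`. A step with no
#' feasible move is a dead end; the chain is restarted from scratch (up
#' to `max_attempts` times) and the failures are reported as attrition.
#'
#' @param n_units Number of persistence units (>= 2).
#' @param D_um Confinement diameter in micrometers; `Inf` for free space.
#' @param params A [csac_params()] object.
#' @param seed Integer master seed.
#' @param chain_index Index used (with `seed`) to derive the per-attempt
#'   RNG stream, so ensembles are reproducible chain by chain.
#' @param max_attempts Restart budget before giving up.
#' @param rotate Randomly rotate the candidate set once per chain
#'   (restores rotational isotropy; disable only for enumeration-style
#'   tests on the fixed direction set).
#' @return A `csac_conformation` with attributes `attempts` and
#'   `m_counts` (feasible-candidate count per step), or `NULL` with a
#'   warning if every attempt dead-ended.
#' @examples
#' conf <- grow_chain(10, D_um = 1.5, seed = 7)
#' check_self_avoidance(conf)$ok
#' @export
grow_chain <- function(n_units, D_um = 1.5, params = csac_params(),
                       seed = 1L, chain_index = 0L, max_attempts = 1000L,
                       rotate = TRUE) {
  stopifnot(n_units >= 2)
  res <- cpp_grow_chain(as.integer(n_units), r_allow_nm(D_um, params),
                        params$bead_diameter_nm, params$beads_per_unit,
                        params$k_states, as.double(seed),
                        as.integer(chain_index), as.integer(max_attempts),
                        isTRUE(rotate))
  if (!res$completed) {
    warn(sprintf("all %d growth attempts dead-ended at N = %d, D = %g um",
                 res$attempts, n_units, D_um))
    return(NULL)
  }
  params <- utils::modifyList(params, list(confinement_diameter_um = D_um))
  class(params) <- "csac_params"
  conf <- conformation(res$coords, n_units, res$log_weight, params,
                       seed = as.integer(seed))
  attr(conf, "attempts") <- res$attempts
  attr(conf, "m_counts") <- res$m_counts
  conf
}

#' Grow a weighted ensemble of chains
#'
#' Generates `n_chains` completed chains under one (N, D) condition.
#' Dead-ended growth attempts are restarted with fresh deterministic
#' sub-seeds and counted in `attrition_count`; per-chain seeds derive
#' from the master seed so the ensemble is reproducible and
#' order-independent.
#'
#' @inheritParams grow_chain
#' @param n_chains Number of completed chains required.
#' @param max_attempts_per_chain Restart budget per chain; growth aborts
#'   with a diagnostic if any chain exhausts it (attrition ceiling).
#' @return A `csac_ensemble`: list of conformations plus condition
#'   metadata, log-weights and attrition statistics.
#' @examples
#' ens <- grow_ensemble(20, 30, D_um = 1.5, seed = 42)
#' ess(ens)
#' @export
grow_ensemble <- function(n_chains, n_units, D_um = 1.5,
                          params = csac_params(), seed = 1L,
                          max_attempts_per_chain = 1000L, rotate = TRUE) {
  stopifnot(n_chains >= 1, n_units >= 2)
  res <- cpp_grow_ensemble(as.integer(n_chains), as.integer(n_units),
                           r_allow_nm(D_um, params),
                           params$bead_diameter_nm, params$beads_per_unit,
                           params$k_states, as.double(seed),
                           as.integer(max_attempts_per_chain),
                           isTRUE(rotate))
  params <- utils::modifyList(params, list(confinement_diameter_um = D_um))
  class(params) <- "csac_params"
  confs <- lapply(seq_len(n_chains), function(i) {
    conformation(res$coords[[i]], n_units, res$log_weight[i], params,
                 seed = as.integer(seed))
  })
  structure(
    list(conformations = confs, n_units = as.integer(n_units),
         confinement_um = D_um, params = params,
         log_weights = as.numeric(res$log_weight),
         attrition_count = res$attrition_count,
         attempts = res$attempts, master_seed = seed),
    class = "csac_ensemble"
  )
}

#' @export
print.csac_ensemble <- function(x, ...) {
  cat(sprintf(paste0("<csac_ensemble> %d chains of %d units, %s\n",
                     "  attrition: %d restarts; ESS %.1f\n"),
              length(x$conformations), x$n_units,
              if (is.infinite(x$confinement_um)) "free space"
              else paste0("D = ", x$confinement_um, " um"),
              x$attrition_count, ess(x)))
  invisible(x)
}

#' @export
length.csac_ensemble <- function(x) length(x$conformations)

#' Normalized importance weights of an ensemble
#'
#' Weights are kept as log-weights internally (raw Rosenbluth weights
#' underflow for long chains); this returns `exp(lw - max(lw))`
#' normalized to sum to one.
#'
#' @param ensemble A `csac_ensemble`.
#' @return Numeric vector summing to 1.
#' @export
ensemble_weights <- function(ensemble) {
  lw <- ensemble$log_weights
  w <- exp(lw - max(lw))
  w / sum(w)
}

#' Effective sample size of an importance-weighted ensemble
#'
#' `(sum w)^2 / sum(w^2)`: the number of equally weighted chains the
#' ensemble is statistically worth.
#'
#' @param ensemble A `csac_ensemble` or a vector of (log-)weights.
#' @param log Treat a bare numeric vector as log-weights.
#' @return A single number in `[1, n]`.
#' @export
ess <- function(ensemble, log = TRUE) {
  w <- if (inherits(ensemble, "csac_ensemble")) {
    ensemble_weights(ensemble)
  } else if (log) {
    exp(ensemble - max(ensemble))
  } else {
    ensemble
  }
  w <- w / sum(w)
  1 / sum(w^2)
}
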