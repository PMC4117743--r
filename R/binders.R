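#' Randomly place binding sites along the chain
#'
#' Draws a uniform random subset of persistence-unit indices without
#' replacement covering the requested fraction of the chain.
#'
#' @param n_units Number of persistence units.
#' @param coverage Fraction of units carrying a binding site (0, 1].
#' @param seed Integer seed.
#' @return Sorted integer vector of unit indices (1-based) of size
#'   `round(coverage * n_units)`.
#' @export
place_sites <- function(n_units, coverage, seed = 1L) {
  stopifnot(coverage > 0, coverage <= 1)
  m <- round(coverage * n_units)
  set.seed(seed)
  sort(sample.int(n_units, m))
}

#' Count proximal binding-site pairs in one conformation
#'
#' Number of unordered site pairs, at least two units apart along the
#' chain, whose unit-boundary beads lie within the contact radius --
#' each such pair can be bridged by a binder.
#'
#' @param conf A `csac_conformation`.
#' @param sites Unit indices (1-based) carrying binding sites.
#' @param r_c Proximity radius in nm (default: contact radius).
#' @return Integer pair count.
#' @export
count_bound_pairs <- function(conf, sites, r_c = NULL) {
  if (is.null(r_c)) r_c <- conf$params$contact_radius_nm
  if (length(sites) == 0) return(0L)
  stopifnot(all(sites >= 1), all(sites <= conf$n_units))
  uc <- unit_coords(conf)
  cpp_count_bound_pairs(uc[sites, , drop = FALSE], as.integer(sites), r_c)
}

#' Binder configuration
#'
#' @param coverage_fraction Fraction of units carrying a site.
#' @param binding_energy_kBT Energy gained per bridged site pair, in
#'   units of kT (default 6).
#' @param relative_temperature Temperature scale tau; the Boltzmann
#'   factor uses `binding_energy_kBT / tau` (tau = 1 and tau = 10 are
#'   the two scales examined).
#' @param site_seed Seed for random site placement.
#' @return A `csac_binder_config` list.
#' @export
binder_config <- function(coverage_fraction, binding_energy_kBT = 6,
                          relative_temperature = 1, site_seed = 1L) {
  stopifnot(coverage_fraction > 0, coverage_fraction <= 1,
            binding_energy_kBT >= 0, relative_temperature > 0)
  structure(list(coverage_fraction = coverage_fraction,
                 binding_energy_kBT = binding_energy_kBT,
                 relative_temperature = relative_temperature,
                 site_seed = as.integer(site_seed)),
            class = "csac_binder_config")
}

#' Reweight an ensemble under binder-mediated looping
#'
#' Chains with many binding sites in spatial proximity gain energy
#' `-epsilon` per bridged pair, hence Boltzmann weight
#' `exp(n_pairs * epsilon / tau)` on top of the growth weight. The
#' arithmetic stays in log-weights (no overflow); the input ensemble is
#' not modified and normalisation is deferred to the estimators.
#'
#' @param ensemble A `csac_ensemble`.
#' @param binder A [binder_config()]; all chains share one random site
#'   set drawn from `binder$site_seed`.
#' @param sites Optional explicit unit-index site set (overrides the
#'   random placement).
#' @return A new `csac_ensemble` with updated log-weights and an
#'   attribute `n_pairs` (per-chain bridged-pair counts).
#' @export
reweight <- function(ensemble, binder, sites = NULL) {
  if (is.null(sites)) {
    sites <- place_sites(ensemble$n_units, binder$coverage_fraction,
                         binder$site_seed)
  }
  n_pairs <- vapply(ensemble$conformations, count_bound_pairs,
                    integer(1), sites = sites)
  out <- ensemble
  boost <- n_pairs * binder$binding_energy_kBT / binder$relative_temperature
  out$log_weights <- ensemble$log_weights + boost
  for (i in seq_along(out$conformations)) {
    out$conformations[[i]]$log_weight <- out$log_weights[i]
  }
  attr(out, "n_pairs") <- n_pairs
  attr(out, "binder") <- binder
  out
}

#' Scaling-exponent sensitivity to binder coverage
#'
#' Recomputes the spatial-distance exponent nu and the contact exponent
#' alpha after binder reweighting, for every combination of coverage
#' and relative temperature, and reports the change against the
#' unreweighted baseline together with the baseline bootstrap interval.
#' Reweighted estimates whose effective sample size falls below
#' `ess_floor` are flagged: with a strong Boltzmann factor the
#' reweighted ensemble can be dominated by few chains.
#'
#' @param ensemble The baseline confined `csac_ensemble`.
#' @param coverages Coverage fractions to scan.
#' @param temperatures Relative temperatures tau to scan.
#' @param energy_kBT Binding energy per pair.
#' @param site_seed Seed for site placement.
#' @param nu_range,alpha_range Fit ranges in persistence units.
#' @param min_contacts Support floor for the contact fit.
#' @param n_boot,boot_seed Baseline bootstrap settings (`n_boot = 0`
#'   skips the CI columns).
#' @param ess_floor Effective-sample-size warning threshold.
#' @param weighting Chain-combination rule for all profile estimates in
#'   the report, as in [contact_probability()]; `"truncated"` is
#'   recommended for long confined chains.
#' @return A tibble with one row per (coverage, tau): exponents, deltas
#'   vs baseline, ESS and `low_ess` flag; baseline row has coverage 0.
#' @export
binder_sensitivity_report <- function(ensemble, coverages = seq(0.1, 0.5, 0.1),
                                      temperatures = c(1, 10),
                                      energy_kBT = 6, site_seed = 1L,
                                      nu_range = c(5, 25),
                                      alpha_range = c(5, 125),
                                      min_contacts = 5,
                                      n_boot = 0, boot_seed = 1L,
                                      ess_floor = 30,
                                      weighting = c("is", "truncated",
                                                    "uniform")) {
  weighting <- match.arg(weighting)
  fit_both <- function(en) {
    nu <- fit_power_law(msd_profile(en, weighting = weighting),
                        range = nu_range)$exponent
    al <- fit_power_law(contact_probability(en, weighting = weighting),
                        range = alpha_range,
                        min_contacts = min_contacts)$exponent
    c(nu = nu, alpha = al)
  }
  base <- fit_both(ensemble)
  ci_nu <- ci_al <- c(NA_real_, NA_real_)
  if (n_boot > 0) {
    cache_msd <- precompute_msd(ensemble)
    ci_nu <- bootstrap_ci(function(en, idx) {
      refit_nu_from_cache(cache_msd, en, idx, nu_range, weighting)
    }, ensemble, n_boot = n_boot, seed = boot_seed)
    cache_pc <- precompute_contacts(ensemble)
    ci_al <- bootstrap_ci(function(en, idx) {
      refit_alpha_from_cache(cache_pc, en, idx, alpha_range, min_contacts,
                             weighting)
    }, ensemble, n_boot = n_boot, seed = boot_seed)
  }
  grid <- expand.grid(coverage = coverages, tau = temperatures)
  rows <- purrr::pmap_dfr(grid, function(coverage, tau) {
    rw <- reweight(ensemble,
                   binder_config(coverage, energy_kBT, tau, site_seed))
    e <- fit_both(rw)
    tibble::tibble(coverage = coverage, tau = tau,
                   nu = unname(e["nu"]), alpha = unname(e["alpha"]),
                   delta_nu = unname(e["nu"] - base["nu"]),
                   delta_alpha = unname(e["alpha"] - base["alpha"]),
                   ess = ess(rw), low_ess = ess(rw) < ess_floor)
  })
  dplyr::bind_rows(
    tibble::tibble(coverage = 0, tau = NA_real_, nu = unname(base["nu"]),
                   alpha = unname(base["alpha"]), delta_nu = 0,
                   delta_alpha = 0,
                   ess = ess(ensemble), low_ess = ess(ensemble) < ess_floor),
    rows
  ) |>
    dplyr::mutate(nu_ci_low = ci_nu[1], nu_ci_high = ci_nu[2],
                  alpha_ci_low = ci_al[1], alpha_ci_high = ci_al[2])
}

# per-chain observable caches so bootstrap resampling is O(resample)
precompute_msd <- function(ensemble, s_values = NULL) {
  if (is.null(s_values)) s_values <- default_s_grid(ensemble$n_units)
  s_values <- sort(unique(as.integer(s_values)))
  mat <- vapply(ensemble$conformations,
                function(conf) cpp_msd_by_s(unit_coords(conf), s_values),
                numeric(length(s_values)))
  list(s = s_values, mat = matrix(mat, nrow = length(s_values)))
}

refit_nu_from_cache <- function(cache, ensemble, idx, nu_range,
                                weighting = "is") {
  w <- resample_weights(ensemble$log_weights[idx], weighting)
  r2 <- as.vector(cache$mat[, idx, drop = FALSE] %*% w)
  prof <- tibble::tibble(s = cache$s, R2 = r2)
  fit_power_law(prof, range = nu_range, target = "nu_from_R2",
                x = "s", y = "R2")$exponent
}

precompute_contacts <- function(ensemble, s_values = NULL, r_c = NULL) {
  if (is.null(s_values)) s_values <- default_s_grid(ensemble$n_units)
  if (is.null(r_c)) r_c <- ensemble$params$contact_radius_nm
  s_values <- sort(unique(as.integer(s_values)))
  frac <- vapply(ensemble$conformations, function(conf) {
    cc <- cpp_contact_counts(unit_coords(conf), s_values, r_c)
    ifelse(cc$windows > 0, cc$hits / cc$windows, NA_real_)
  }, numeric(length(s_values)))
  hits <- vapply(ensemble$conformations, function(conf) {
    as.numeric(cpp_contact_counts(unit_coords(conf), s_values, r_c)$hits)
  }, numeric(length(s_values)))
  list(s = s_values, frac = matrix(frac, nrow = length(s_values)),
       hits = matrix(hits, nrow = length(s_values)))
}

refit_alpha_from_cache <- function(cache, ensemble, idx, alpha_range,
                                   min_contacts, weighting = "is") {
  w <- resample_weights(ensemble$log_weights[idx], weighting)
  pc <- as.vector(cache$frac[, idx, drop = FALSE] %*% w)
  prof <- tibble::tibble(s = cache$s, Pc = pc,
                         n_contacts = rowSums(cache$hits[, idx, drop = FALSE]))
  keep <- prof$n_contacts >= min_contacts & prof$Pc > 0
  fit_power_law(prof[keep, ], range = alpha_range, target = "alpha_from_Pc",
                x = "s", y = "Pc")$exponent
}

# normalized (optionally truncated) weights from resampled log-weights
resample_weights <- function(lw, weighting) {
  w <- exp(lw - max(lw))
  w <- w / sum(w)
  if (identical(weighting, "truncated")) {
    w <- pmin(w, mean(w) * sqrt(length(w)))
    w <- w / sum(w)
  } else if (identical(weighting, "uniform")) {
    w <- rep(1 / length(w), length(w))
  }
  w
}
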