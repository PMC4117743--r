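#' Importance-weighted mean
#'
#' @param values Numeric vector.
#' @param weights Non-negative weights of the same length.
#' @return `sum(w * v) / sum(w)`.
#' @export
weighted_mean <- function(values, weights) {
  stopifnot(length(values) == length(weights), all(weights >= 0))
  if (all(weights == 0)) {
    abort("all weights are zero", class = "csac_config_error")
  }
  sum(values * weights) / sum(weights)
}

chain_weights <- function(ensemble, weighting) {
  w <- ensemble_weights(ensemble)
  switch(weighting,
    is = w,
    uniform = rep(1 / length(w), length(w)),
    truncated = {
      w2 <- pmin(w, mean(w) * sqrt(length(w)))
      w2 / sum(w2)
    })
}

default_s_grid <- function(n_units, n = 60, s_min = 2) {
  s_max <- n_units - 1
  sort(unique(round(exp(seq(log(s_min), log(s_max), length.out = n)))))
}

new_profile <- function(tbl, type, condition) {
  structure(tbl, class = c("csac_profile", class(tbl)),
            profile_type = type, condition = condition)
}

#' Mean-square spatial distance profile R^2(s)
#'
#' For each contour separation s (in persistence units), the
#' weighted-ensemble mean of the squared Euclidean distance between
#' unit-boundary beads i and i + s: windows are pooled with equal weight
#' within each chain, then chains are combined by importance weight.
#' This is the model analogue of the FISH mean-square distance versus
#' genomic separation.
#'
#' @param ensemble A `csac_ensemble`.
#' @param s_values Contour separations in persistence units (default: a
#'   log-spaced grid over `[2, N - 1]`).
#' @param weighting Chain-combination rule as in
#'   [contact_probability()]: plain importance weights (`"is"`,
#'   default), truncated importance weights (`"truncated"`, for
#'   slope-sensitive uses such as plateau detection on long confined
#'   chains where plain weights are degenerate), or the unweighted
#'   proposal ensemble (`"uniform"`).
#' @return A tibble of class `csac_profile` with columns `s`, `R2`
#'   (nm^2) and `n_windows`.
#' @export
msd_profile <- function(ensemble, s_values = NULL,
                        weighting = c("is", "truncated", "uniform")) {
  weighting <- match.arg(weighting)
  if (length(ensemble) == 0) {
    abort("empty ensemble", class = "csac_config_error")
  }
  if (is.null(s_values)) s_values <- default_s_grid(ensemble$n_units)
  s_values <- sort(unique(as.integer(s_values)))
  stopifnot(all(s_values >= 1), all(s_values < ensemble$n_units))
  w <- chain_weights(ensemble, weighting)
  per_chain <- vapply(
    ensemble$conformations,
    function(conf) cpp_msd_by_s(unit_coords(conf), s_values),
    numeric(length(s_values))
  )
  per_chain <- matrix(per_chain, nrow = length(s_values))
  r2 <- as.vector(per_chain %*% w)
  n_windows <- (ensemble$n_units - s_values) * length(ensemble)
  new_profile(
    tibble::tibble(s = s_values, R2 = r2, n_windows = n_windows),
    "msd", list(n_units = ensemble$n_units, D_um = ensemble$confinement_um)
  )
}

#' Mean end-to-end distance of an ensemble
#'
#' Importance-weighted mean Euclidean distance between the first and
#' last beads.
#'
#' @param ensemble A `csac_ensemble`.
#' @return Mean end-to-end distance in nm.
#' @export
end_to_end <- function(ensemble) {
  if (length(ensemble) == 0) {
    abort("empty ensemble", class = "csac_config_error")
  }
  d <- vapply(ensemble$conformations, function(conf) {
    m <- conf$coords
    sqrt(sum((m[nrow(m), ] - m[1, ])^2))
  }, numeric(1))
  weighted_mean(d, ensemble_weights(ensemble))
}

#' Contact probability profile Pc(s) from independent ensembles
#'
#' For each contour separation s, the probability that unit-boundary
#' beads i and i + s lie within the contact radius. Partial chains
#' (windows) are harvested from every supplied ensemble whose full
#' length exceeds s -- pooling across independent ensembles of different
#' full lengths removes the self-correlation that windows from a single
#' fixed-length ensemble carry. Within a chain all windows are averaged
#' with equal weight, chains are combined by importance weight, and
#' contributing ensembles are combined with equal weight.
#'
#' Note that `Pc(1) = 0` exactly: consecutive unit-boundary beads sit at
#' precisely one persistence length (150 nm) because units are rigid, so
#' they are never within the default 60 nm contact radius.
#'
#' @param ensembles A `csac_ensemble` or list of them.
#' @param s_values Contour separations in persistence units.
#' @param r_c Contact radius in nm (default: the parameter set's
#'   `contact_radius_nm`).
#' @param min_ess Drop ensembles whose effective sample size is below
#'   this floor before pooling: a weight-degenerate ensemble
#'   contributes a one-chain estimate that only adds noise and bias to
#'   the equal-weight ensemble average. 0 keeps everything.
#' @param weighting How chains are combined within an ensemble:
#'   `"is"` -- plain self-normalized importance weights;
#'   `"truncated"` -- importance weights clipped at `mean(w) * sqrt(n)`
#'   and renormalized (truncated importance sampling), which bounds the
#'   variance of rare-event averages such as contact fractions when the
#'   raw weights are degenerate, at the price of a small bias;
#'   `"uniform"` -- the unweighted growth (proposal) ensemble, as a
#'   diagnostic.
#' @return A tibble of class `csac_profile` with columns `s`, `Pc`,
#'   `n_contacts` (raw unweighted contact count, a statistical-support
#'   diagnostic) and `n_windows`.
#' @export
contact_probability <- function(ensembles, s_values = NULL, r_c = NULL,
                                min_ess = 0,
                                weighting = c("is", "truncated",
                                              "uniform")) {
  weighting <- match.arg(weighting)
  if (inherits(ensembles, "csac_ensemble")) ensembles <- list(ensembles)
  stopifnot(length(ensembles) >= 1)
  if (min_ess > 0) {
    keep <- vapply(ensembles, ess, numeric(1)) >= min_ess
    if (!any(keep)) {
      abort("no ensemble reaches the requested effective sample size",
            class = "csac_config_error")
    }
    ensembles <- ensembles[keep]
  }
  if (is.null(r_c)) r_c <- ensembles[[1]]$params$contact_radius_nm
  n_max <- max(vapply(ensembles, function(e) e$n_units, integer(1)))
  if (is.null(s_values)) s_values <- default_s_grid(n_max)
  s_values <- sort(unique(as.integer(s_values)))
  if (any(s_values >= n_max)) {
    abort("some s exceed every ensemble's chain length",
          class = "csac_config_error")
  }
  per_ens <- lapply(ensembles, function(en) {
    use <- s_values < en$n_units
    if (!any(use)) {
      return(list(pc = rep(NA_real_, length(s_values)),
                  hits = rep(0, length(s_values)),
                  windows = rep(0, length(s_values))))
    }
    sv <- s_values[use]
    w <- chain_weights(en, weighting)
    hits <- numeric(length(sv)); wins <- numeric(length(sv))
    acc <- numeric(length(sv))
    for (j in seq_along(en$conformations)) {
      cc <- cpp_contact_counts(unit_coords(en$conformations[[j]]), sv, r_c)
      frac <- ifelse(cc$windows > 0, cc$hits / cc$windows, NA_real_)
      acc <- acc + w[j] * frac
      hits <- hits + cc$hits
      wins <- wins + cc$windows
    }
    pc <- rep(NA_real_, length(s_values))
    pc[use] <- acc
    h <- numeric(length(s_values)); h[use] <- hits
    wn <- numeric(length(s_values)); wn[use] <- wins
    list(pc = pc, hits = h, windows = wn)
  })
  pc_mat <- vapply(per_ens, `[[`, numeric(length(s_values)), "pc")
  pc_mat <- matrix(pc_mat, nrow = length(s_values))
  pc <- apply(pc_mat, 1, function(r) mean(r, na.rm = TRUE))
  new_profile(
    tibble::tibble(
      s = s_values, Pc = pc,
      n_contacts = rowSums(matrix(vapply(per_ens, `[[`,
                                         numeric(length(s_values)), "hits"),
                                  nrow = length(s_values))),
      n_windows = rowSums(matrix(vapply(per_ens, `[[`,
                                        numeric(length(s_values)),
                                        "windows"),
                                 nrow = length(s_values)))
    ),
    "contact",
    list(conditions = lapply(ensembles, function(e)
      list(n_units = e$n_units, D_um = e$confinement_um)),
      r_c = r_c)
  )
}
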