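#' Fit a power law on log-log axes
#'
#' Ordinary least squares of log10(y) on log10(x), restricted to a fit
#' range. The reported exponent depends on the target quantity:
#' `nu_from_R2` reports slope/2 (since R^2(s) ~ s^(2 nu)),
#' `alpha_from_Pc` reports -slope (since Pc(s) ~ 1/s^alpha), and the
#' free-space targets `nu_free` (end-to-end distance vs N) and
#' `alpha_free` (contact probability vs length) report the raw slope.
#'
#' @param data A `csac_profile` tibble (columns auto-detected) or any
#'   data frame with the columns named in `x` and `y`.
#' @param range Numeric `c(min, max)` fit range on the x variable
#'   (inclusive). Defaults to the full range.
#' @param target One of `"slope"`, `"nu_from_R2"`, `"alpha_from_Pc"`,
#'   `"nu_free"`, `"alpha_free"`; auto-chosen for profile tibbles.
#' @param x,y Column names when `data` is a plain data frame.
#' @param min_contacts For contact profiles, drop s points whose raw
#'   contact count is below this floor (insufficient statistical
#'   support); 0 keeps all positive points.
#' @return An object of class `csac_fit`; see [tidy.csac_fit()] and
#'   [glance.csac_fit()].
#' @examples
#' d <- data.frame(s = 1:50, y = 4 * (1:50)^1.5)
#' fit_power_law(d, x = "s", y = "y")$exponent  # 1.5
#' @export
fit_power_law <- function(data, range = NULL,
                          target = c("auto", "slope", "nu_from_R2",
                                     "alpha_from_Pc", "nu_free",
                                     "alpha_free"),
                          x = NULL, y = NULL, min_contacts = 0) {
  target <- match.arg(target)
  ptype <- attr(data, "profile_type")
  if (is.null(x)) {
    if (identical(ptype, "msd")) {
      x <- "s"; y <- "R2"
      if (target == "auto") target <- "nu_from_R2"
    } else if (identical(ptype, "contact")) {
      x <- "s"; y <- "Pc"
      if (target == "auto") target <- "alpha_from_Pc"
    } else {
      abort("supply x and y column names for a plain data frame",
            class = "csac_config_error")
    }
  }
  if (target == "auto") target <- "slope"
  xs <- data[[x]]; ys <- data[[y]]
  keep <- !is.na(xs) & !is.na(ys)
  if (min_contacts > 0 && "n_contacts" %in% names(data)) {
    keep <- keep & data$n_contacts >= min_contacts
  }
  if (is.null(range)) range <- range(xs[keep])
  keep <- keep & xs >= range[1] & xs <= range[2]
  if (any(keep & ys <= 0)) {
    abort("nonpositive values inside the fit range",
          class = "csac_config_error")
  }
  if (sum(keep) < 3) {
    abort("need at least 3 points inside the fit range",
          class = "csac_config_error")
  }
  lx <- log10(xs[keep]); ly <- log10(ys[keep])
  fit <- lm(ly ~ lx)
  sst <- sum((ly - mean(ly))^2)
  ssr <- sum(fit$residuals^2)
  r2 <- if (sst < 1e-28) 1 else 1 - ssr / sst
  slope <- unname(coef(fit)[2])
  exponent <- switch(target,
    nu_from_R2 = slope / 2,
    alpha_from_Pc = -slope,
    slope)
  structure(
    list(exponent = exponent, slope = slope,
         amplitude = 10^unname(coef(fit)[1]),
         fit_range = range, target = target,
         n_points = sum(keep),
         r_squared = r2,
         ci_low = NA_real_, ci_high = NA_real_, n_bootstrap = 0L),
    class = "csac_fit"
  )
}

#' @export
print.csac_fit <- function(x, ...) {
  lbl <- c(nu_from_R2 = "nu", alpha_from_Pc = "alpha",
           nu_free = "nu (free)", alpha_free = "alpha (free)",
           slope = "slope")[x$target]
  cat(sprintf("<csac_fit> %s = %.4f (range [%g, %g], %d points, R2 %.4f)\n",
              lbl, x$exponent, x$fit_range[1], x$fit_range[2],
              x$n_points, x$r_squared))
  if (x$n_bootstrap > 0) {
    cat(sprintf("  bootstrap 95%% CI: [%.4f, %.4f] (%d resamples)\n",
                x$ci_low, x$ci_high, x$n_bootstrap))
  }
  invisible(x)
}

#' Tidy a power-law fit
#'
#' @param x A `csac_fit`.
#' @param ... Unused.
#' @return One row per fitted quantity (exponent, amplitude).
#' @export
tidy.csac_fit <- function(x, ...) {
  tibble::tibble(
    term = c("exponent", "amplitude"),
    estimate = c(x$exponent, x$amplitude),
    conf.low = c(x$ci_low, NA_real_),
    conf.high = c(x$ci_high, NA_real_)
  )
}

#' One-row summary of a power-law fit
#'
#' @param x A `csac_fit`.
#' @param ... Unused.
#' @export
glance.csac_fit <- function(x, ...) {
  tibble::tibble(
    target = x$target, exponent = x$exponent, amplitude = x$amplitude,
    ci_low = x$ci_low, ci_high = x$ci_high,
    fit_min = x$fit_range[1], fit_max = x$fit_range[2],
    n_points = x$n_points, r_squared = x$r_squared,
    n_bootstrap = x$n_bootstrap
  )
}

#' Detect the onset of the confinement plateau (leveling-off)
#'
#' Under confinement R^2(s) stops growing at large s because chains
#' cannot extend beyond the sphere. The onset is estimated as the
#' smallest s beyond which the running local log-log slope (mean over a
#' window of point-to-point slopes) stays below `slope_threshold` for
#' the rest of the grid.
#'
#' @param profile A `csac_profile` (or data frame with columns `s` and a
#'   value column as its second column).
#' @param slope_threshold Local slope below which the profile counts as
#'   flat (in R^2(s) terms: 2 nu below this value).
#' @param window Number of consecutive point-to-point slopes averaged.
#' @return The onset `s*` in persistence units, or `NA` if the profile
#'   never flattens.
#' @export
detect_plateau_onset <- function(profile, slope_threshold = 0.1,
                                 window = 5) {
  s <- profile$s
  v <- profile[[setdiff(names(profile), c("s", "n_windows", "n_contacts"))[1]]]
  keep <- !is.na(v) & v > 0
  s <- s[keep]; v <- v[keep]
  if (length(s) < window + 2) {
    abort("too few points for plateau detection", class = "csac_config_error")
  }
  if (max(s) / min(s) < 10) {
    abort("profile must cover at least a decade of s",
          class = "csac_config_error")
  }
  local <- diff(log10(v)) / diff(log10(s))
  run <- vapply(seq_len(length(local) - window + 1),
                function(i) mean(local[i:(i + window - 1)]), numeric(1))
  flat <- run < slope_threshold
  # first window from which flatness persists to the end of the grid
  idx <- which(flat & rev(cumprod(rev(flat))) == 1)[1]
  if (is.na(idx)) return(NA_real_)
  s[idx]
}

#' Percentile bootstrap confidence interval over chains
#'
#' Resamples whole chains with replacement (each chain carries its
#' importance weight) and recomputes an ensemble-level statistic. The
#' statistic closure is either `f(ensemble)` (called on the resampled
#' ensemble) or, for expensive statistics with per-chain caches,
#' `f(ensemble, idx)` (called with the original ensemble and the
#' resample indices).
#'
#' @param stat_fn The statistic closure.
#' @param ensemble A `csac_ensemble`.
#' @param n_boot Number of bootstrap resamples (>= 100).
#' @param seed Integer seed for resampling.
#' @param level Confidence level.
#' @return Named numeric `c(ci_low, ci_high)` with the resample
#'   statistics in attribute `"replicates"`.
#' @export
bootstrap_ci <- function(stat_fn, ensemble, n_boot = 200, seed = 1L,
                         level = 0.95) {
  stopifnot(n_boot >= 100)
  n <- length(ensemble)
  if (n < 2) {
    abort("bootstrap needs at least 2 chains", class = "csac_config_error")
  }
  two_arg <- length(formals(stat_fn)) >= 2
  rng <- local({ set.seed(seed); function(m) sample.int(n, m, replace = TRUE) })
  reps <- vapply(seq_len(n_boot), function(b) {
    idx <- rng(n)
    if (two_arg) {
      stat_fn(ensemble, idx)
    } else {
      stat_fn(subset_ensemble(ensemble, idx))
    }
  }, numeric(1))
  a <- (1 - level) / 2
  out <- unname(quantile(reps, c(a, 1 - a), na.rm = TRUE, names = FALSE))
  out <- c(ci_low = out[1], ci_high = out[2])
  attr(out, "replicates") <- reps
  out
}

#' Subset or resample an ensemble by chain index
#'
#' @param ensemble A `csac_ensemble`.
#' @param idx Chain indices (repeats allowed).
#' @return A `csac_ensemble` with the selected chains.
#' @export
subset_ensemble <- function(ensemble, idx) {
  out <- ensemble
  out$conformations <- ensemble$conformations[idx]
  out$log_weights <- ensemble$log_weights[idx]
  out$attempts <- ensemble$attempts[idx]
  out
}

#' Per-confinement exponent table
#'
#' Fits the spatial-distance exponent nu (from the largest-N ensemble at
#' each confinement diameter) and the contact exponent alpha (from the
#' pooled multi-length contact profile) for every D, and flags whether
#' both are non-decreasing in D -- larger nuclei give more open chains
#' with larger exponents.
#'
#' @param ensembles_by_D Named list: one entry per confinement diameter
#'   (name = D in micrometers), each a list of `csac_ensemble`s of
#'   different chain lengths grown at that D.
#' @param nu_range,alpha_range Fit ranges in persistence units.
#' @param s_values Contact-profile grid (default: grid of the longest
#'   chain).
#' @param min_contacts Support floor passed to [fit_power_law()].
#' @return A tibble with one row per D (`D_um`, `nu`, `alpha`, fit
#'   metadata) carrying attributes `nu_monotone` / `alpha_monotone`.
#' @export
exponent_report <- function(ensembles_by_D, nu_range = c(5, 25),
                            alpha_range = c(5, 125), s_values = NULL,
                            min_contacts = 5) {
  stopifnot(length(ensembles_by_D) >= 2, !is.null(names(ensembles_by_D)))
  rows <- purrr::map2_dfr(
    ensembles_by_D, names(ensembles_by_D),
    function(ens_list, d_name) {
      if (inherits(ens_list, "csac_ensemble")) ens_list <- list(ens_list)
      n_max <- which.max(vapply(ens_list, function(e) e$n_units, integer(1)))
      prof_r2 <- msd_profile(ens_list[[n_max]])
      fit_nu <- fit_power_law(prof_r2, range = nu_range)
      prof_pc <- contact_probability(ens_list, s_values = s_values)
      fit_a <- fit_power_law(prof_pc, range = alpha_range,
                             min_contacts = min_contacts)
      tibble::tibble(
        D_um = as.numeric(d_name),
        nu = fit_nu$exponent, alpha = fit_a$exponent,
        nu_r2 = fit_nu$r_squared, alpha_r2 = fit_a$r_squared,
        nu_min = nu_range[1], nu_max = nu_range[2],
        alpha_min = alpha_range[1], alpha_max = alpha_range[2],
        n_chains = sum(vapply(ens_list, length, integer(1)))
      )
    }
  )
  rows <- dplyr::arrange(rows, .data$D_um)
  attr(rows, "nu_monotone") <- !is.unsorted(rows$nu + 1e-12)
  attr(rows, "alpha_monotone") <- !is.unsorted(rows$alpha + 1e-12)
  rows
}

#' End-to-end scaling across chain lengths
#'
#' Weighted mean end-to-end distance for each ensemble, as a tidy table
#' ready for [fit_power_law()] with `target = "nu_free"` -- the
#' free-space validation that the growth algorithm reproduces the
#' self-avoiding-walk exponent nu ~ 0.59.
#'
#' @param ensembles List of `csac_ensemble`s of different lengths.
#' @return A tibble with columns `n_units`, `e2e_nm`, `ess`, `n_chains`.
#' @export
end_to_end_scaling <- function(ensembles) {
  purrr::map_dfr(ensembles, function(en) {
    tibble::tibble(n_units = en$n_units, e2e_nm = end_to_end(en),
                   ess = ess(en), n_chains = length(en))
  })
}
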