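#' Minimal enclosing sphere of a point set
#'
#' Exact smallest enclosing sphere (Welzl's randomized incremental
#' algorithm with at most four support points).
#'
#' @param coords An n x 3 matrix of points.
#' @return Named vector `x, y, z, radius`.
#' @export
min_enclosing_sphere <- function(coords) {
  coords <- as.matrix(coords)
  stopifnot(ncol(coords) == 3, nrow(coords) >= 1)
  cpp_min_enclosing_sphere(coords)
}

#' Detect highly interactive (domain-like) substructures
#'
#' Scans a chain for contiguous stretches dense enough to be captured by
#' a sphere of `sphere_diameter_nm` while holding more than `min_kbp`
#' of DNA -- the model analogue of a topological-domain-like region.
#' Two scan policies are available:
#'
#' * `"cover"` (default): a sphere of the given diameter is centred on
#'   each persistence-unit boundary bead in turn and the maximal
#'   contiguous bead run inside it is taken; qualifying runs (DNA
#'   content above threshold) that overlap on the chain are merged into
#'   one substructure. This reading -- spheres placed *along the chain*
#'   -- is the default because it reproduces the reference statistics
#'   (~6.5 substructures per 15 Mb confined chain, ~41% interactive).
#' * `"greedy_mes"`: greedy left-to-right maximal windows whose exact
#'   minimal enclosing sphere stays within the diameter; each accepted
#'   window is skipped past. Stricter containment reading; yields more,
#'   wall-to-wall substructures on strongly confined chains.
#'
#' @param conf A `csac_conformation`.
#' @param sphere_diameter_nm Sphere diameter in nm.
#' @param min_kbp Minimum DNA content of a substructure in kb
#'   (content is bead count x 3 kb with defaults).
#' @param method Scan policy, see above.
#' @return A tibble with one row per substructure: `start_bead`,
#'   `end_bead` (1-based, inclusive), `n_beads`, `dna_kbp`,
#'   `enclosing_diameter_nm`.
#' @export
find_substructures <- function(conf, sphere_diameter_nm = 800,
                               min_kbp = 400,
                               method = c("cover", "greedy_mes")) {
  method <- match.arg(method)
  p <- conf$params
  min_beads <- floor(min_kbp * 1000 / p$bp_per_bead) + 1  # content > min_kbp
  iv <- if (method == "cover") {
    cpp_scan_substructures_cover(conf$coords, sphere_diameter_nm / 2,
                                 as.integer(min_beads),
                                 as.integer(p$beads_per_unit))
  } else {
    cpp_scan_substructures(conf$coords, sphere_diameter_nm,
                           as.integer(min_beads))
  }
  if (nrow(iv) == 0) {
    return(tibble::tibble(start_bead = integer(0), end_bead = integer(0),
                          n_beads = integer(0), dna_kbp = numeric(0),
                          enclosing_diameter_nm = numeric(0)))
  }
  diam <- vapply(seq_len(nrow(iv)), function(q) {
    2 * min_enclosing_sphere(conf$coords[iv[q, 1]:iv[q, 2], ,
                                         drop = FALSE])[["radius"]]
  }, numeric(1))
  tibble::tibble(
    start_bead = iv[, 1], end_bead = iv[, 2],
    n_beads = iv[, 2] - iv[, 1] + 1L,
    dna_kbp = (iv[, 2] - iv[, 1] + 1L) * p$bp_per_bead / 1000,
    enclosing_diameter_nm = diam
  )
}

#' Classify substructures as interactive or independent
#'
#' A substructure is *interactive* when more than `threshold` (default
#' 20%) of its persistence units have any bead within the contact
#' radius of a bead belonging to a different substructure of the same
#' chain; otherwise it is *independent*. The stricter reading of
#' independence -- no unit proximal at all -- is reported in
#' `strictly_independent`.
#'
#' @param substructures A tibble from [find_substructures()].
#' @param conf The conformation the substructures came from.
#' @param r_c Proximity radius in nm (default: contact radius).
#' @param threshold Interactive classification threshold on the unit
#'   fraction.
#' @return The input tibble with `interaction_fraction`, `category`
#'   (factor interactive/independent) and `strictly_independent` added.
#' @export
classify_substructures <- function(substructures, conf, r_c = NULL,
                                   threshold = 0.20) {
  if (is.null(r_c)) r_c <- conf$params$contact_radius_nm
  n <- nrow(substructures)
  if (n == 0) {
    return(dplyr::mutate(substructures,
                         interaction_fraction = numeric(0),
                         category = factor(character(0),
                                           c("interactive", "independent")),
                         strictly_independent = logical(0)))
  }
  fr <- cpp_interaction_fractions(conf$coords,
                                  as.integer(substructures$start_bead),
                                  as.integer(substructures$end_bead),
                                  r_c, conf$params$beads_per_unit)
  dplyr::mutate(
    substructures,
    interaction_fraction = fr[, 1],
    category = factor(ifelse(fr[, 1] > threshold, "interactive",
                             "independent"),
                      c("interactive", "independent")),
    strictly_independent = fr[, 2] == 0
  )
}

#' Substructure summary over an ensemble
#'
#' Runs [find_substructures()] and [classify_substructures()] on every
#' chain and aggregates with importance weights.
#'
#' @param ensemble A `csac_ensemble`.
#' @param ... Passed to [find_substructures()].
#' @param r_c,threshold Passed to [classify_substructures()].
#' @param weighting Chain-combination rule as in
#'   [contact_probability()]; counts and fractions are per-chain
#'   integers/ratios, so plain degenerate importance weights reduce
#'   them to single-chain values -- `"truncated"` is recommended for
#'   long confined chains.
#' @return A list with `per_chain` (tibble: chain, n_substructures,
#'   coverage, n_interactive), `mean_per_chain`,
#'   `interactive_fraction`, `mean_coverage` (all weighted) and
#'   `substructures` (row-bound per-chain tables).
#' @export
substructure_summary <- function(ensemble, ..., r_c = NULL,
                                 threshold = 0.20,
                                 weighting = c("is", "truncated",
                                               "uniform")) {
  w <- chain_weights(ensemble, match.arg(weighting))
  per <- purrr::imap(ensemble$conformations, function(conf, i) {
    subs <- find_substructures(conf, ...)
    subs <- classify_substructures(subs, conf, r_c = r_c,
                                   threshold = threshold)
    subs$chain <- i
    subs
  })
  tab <- dplyr::bind_rows(per)
  n_beads <- nrow(ensemble$conformations[[1]]$coords)
  per_chain <- purrr::imap_dfr(per, function(subs, i) {
    tibble::tibble(
      chain = i,
      n_substructures = nrow(subs),
      n_interactive = sum(subs$category == "interactive"),
      coverage = sum(subs$n_beads) / n_beads
    )
  })
  frac_int <- vapply(per, function(subs) {
    if (nrow(subs) == 0) NA_real_
    else mean(subs$category == "interactive")
  }, numeric(1))
  has <- !is.na(frac_int)
  list(
    per_chain = per_chain,
    substructures = tab,
    mean_per_chain = weighted_mean(per_chain$n_substructures, w),
    mean_coverage = weighted_mean(per_chain$coverage, w),
    interactive_fraction = if (any(has)) {
      weighted_mean(frac_int[has], w[has])
    } else NA_real_
  )
}

#' Cluster an ensemble by conformational similarity
#'
#' Chain-to-chain dissimilarity is the root-mean-square difference
#' between unit-level pairwise distance matrices; average-linkage
#' hierarchical clustering is cut at `n_clusters`. Per-cluster contact
#' exponents are fitted from the pooled within-cluster contact profile,
#' mirroring the chromosome-to-chromosome spread of the Hi-C scaling
#' exponent.
#'
#' @param ensemble A `csac_ensemble`.
#' @param n_clusters Number of clusters to cut.
#' @param stride Use every `stride`-th persistence unit in the distance
#'   matrices (memory/time control for long chains).
#' @param fit_alpha Also fit per-cluster contact exponents.
#' @param alpha_range,s_values,min_contacts Passed to the per-cluster
#'   [fit_power_law()] when `fit_alpha` is `TRUE`.
#' @return A list with `labels` (integer per chain), `hclust` (merge
#'   history), and `per_cluster` (tibble with sizes and optional
#'   `alpha`).
#' @export
cluster_ensemble <- function(ensemble, n_clusters = 20, stride = 1,
                             fit_alpha = FALSE, alpha_range = NULL,
                             s_values = NULL, min_contacts = 5) {
  n <- length(ensemble)
  if (n_clusters > n) {
    abort("more clusters than chains", class = "csac_config_error")
  }
  sel <- seq(1, ensemble$n_units, by = stride)
  mats <- lapply(ensemble$conformations, function(conf) {
    m <- unit_coords(conf)[sel, , drop = FALSE]
    as.matrix(stats::dist(m))
  })
  npair <- length(sel)^2
  dmat <- matrix(0, n, n)
  for (i in seq_len(n - 1)) {
    for (j in (i + 1):n) {
      dmat[i, j] <- dmat[j, i] <- sqrt(sum((mats[[i]] - mats[[j]])^2) / npair)
    }
  }
  hc <- hclust(as.dist(dmat), method = "average")
  labels <- cutree(hc, k = n_clusters)
  per_cluster <- tibble::tibble(
    cluster = sort(unique(labels)),
    n_chains = as.integer(table(labels))
  )
  if (fit_alpha) {
    per_cluster$alpha <- vapply(per_cluster$cluster, function(cl) {
      sub <- subset_ensemble(ensemble, which(labels == cl))
      prof <- contact_probability(sub, s_values = s_values)
      fit <- tryCatch(
        fit_power_law(prof, range = alpha_range,
                      min_contacts = min_contacts),
        error = function(e) NULL)
      if (is.null(fit)) NA_real_ else fit$exponent
    }, numeric(1))
  }
  list(labels = labels, hclust = hc, per_cluster = per_cluster)
}

#' Classify chains as open, compact or intermediate
#'
#' Each chain's radius of gyration is normalised by the rigid-rod upper
#' bound for its contour length; chains below the `compact` quantile of
#' the pooled normalised distribution are compact, above the `open`
#' quantile open, the rest intermediate. Fractions are importance
#' weighted.
#'
#' @param ensemble A `csac_ensemble` (or list pooled together).
#' @param quantiles `c(compact, open)` quantile thresholds.
#' @param breaks Optional fixed numeric thresholds on the normalised
#'   radius of gyration (overrides `quantiles`) -- use to compare
#'   ensembles across confinements on a common scale.
#' @return A list with `fractions` (named: compact, intermediate, open),
#'   `per_chain` tibble, and the thresholds used.
#' @export
classify_compactness <- function(ensemble, quantiles = c(0.2, 0.8),
                                 breaks = NULL) {
  ensembles <- if (inherits(ensemble, "csac_ensemble")) list(ensemble)
               else ensemble
  per <- purrr::map_dfr(ensembles, function(en) {
    w <- ensemble_weights(en)
    rod <- rod_rg(en$n_units, en$params)
    tibble::tibble(
      n_units = en$n_units, D_um = en$confinement_um,
      rg_norm = vapply(en$conformations, radius_of_gyration,
                       numeric(1)) / rod,
      weight = w / length(ensembles)
    )
  })
  if (is.null(breaks)) {
    breaks <- unname(quantile(per$rg_norm, quantiles))
  }
  lab <- cut(per$rg_norm, c(-Inf, breaks, Inf),
             labels = c("compact", "intermediate", "open"))
  per$class <- lab
  fr <- vapply(levels(lab), function(l) {
    sum(per$weight[lab == l]) / sum(per$weight)
  }, numeric(1))
  list(fractions = fr, per_chain = per, thresholds = breaks)
}

# radius of gyration of a straight rod of the chain's contour length
rod_rg <- function(n_units, params) {
  L <- (bead_count(n_units, params) - 1) * params$bead_diameter_nm
  L / sqrt(12)
}
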