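# Independent brute-force oracles used to cross-check the accelerated
# (cell-grid / Welzl) implementations.

# all-pairs overlap oracle: violating non-bonded pairs (|i-j| >= 2) closer
# than one bead diameter
oracle_overlap_pairs <- function(coords, bead_d = 30, tol = 1e-6) {
  n <- nrow(coords)
  out <- NULL
  for (i in seq_len(n - 1)) {
    for (j in (i + 2):n) {
      if (j > n) break
      if (sqrt(sum((coords[i, ] - coords[j, ])^2)) < bead_d - tol) {
        out <- rbind(out, c(i, j))
      }
    }
  }
  if (is.null(out)) matrix(integer(0), 0, 2) else out
}

# brute-force feasibility of candidate directions from the chain tip
oracle_feasible <- function(coords, dirs, D_um = Inf,
                            params = csac_params()) {
  d <- params$bead_diameter_nm
  bpu <- params$beads_per_unit
  r_allow <- if (is.infinite(D_um)) Inf else D_um * 1000 / 2 - d / 2
  tip <- coords[nrow(coords), ]
  ok <- logical(nrow(dirs))
  for (c in seq_len(nrow(dirs))) {
    feas <- TRUE
    for (j in seq_len(bpu)) {
      p <- tip + j * d * dirs[c, ]
      if (sqrt(sum(p^2)) > r_allow) { feas <- FALSE; break }
      dd <- sqrt(rowSums(sweep(coords, 2, p)^2))
      if (any(dd < d - 1e-6)) { feas <- FALSE; break }
    }
    ok[c] <- feas
  }
  which(ok)
}

# exhaustive minimal enclosing sphere: try every support of 1..4 points
oracle_mes <- function(pts) {
  n <- nrow(pts)
  best <- NULL
  contains_all <- function(ctr, r) all(sqrt(rowSums(sweep(pts, 2, ctr)^2)) <= r + 1e-7)
  consider <- function(ctr, r) {
    if (contains_all(ctr, r) && (is.null(best) || r < best$r - 1e-12)) {
      best <<- list(ctr = ctr, r = r)
    }
  }
  for (i in seq_len(n)) consider(pts[i, ], 0)
  if (n >= 2) {
    for (ij in utils::combn(n, 2, simplify = FALSE)) {
      ctr <- colMeans(pts[ij, , drop = FALSE])
      consider(ctr, sqrt(sum((pts[ij[1], ] - ctr)^2)))
    }
  }
  if (n >= 3) {
    for (ijk in utils::combn(n, 3, simplify = FALSE)) {
      s <- circumsphere3(pts[ijk[1], ], pts[ijk[2], ], pts[ijk[3], ])
      if (!is.null(s)) consider(s$ctr, s$r)
    }
  }
  if (n >= 4) {
    for (q in utils::combn(n, 4, simplify = FALSE)) {
      s <- circumsphere4(pts[q[1], ], pts[q[2], ], pts[q[3], ], pts[q[4], ])
      if (!is.null(s)) consider(s$ctr, s$r)
    }
  }
  best
}

circumsphere3 <- function(a, b, c) {
  ab <- b - a; ac <- c - a
  cr <- c(ab[2] * ac[3] - ab[3] * ac[2],
          ab[3] * ac[1] - ab[1] * ac[3],
          ab[1] * ac[2] - ab[2] * ac[1])
  cr2 <- sum(cr^2)
  if (cr2 < 1e-18) return(NULL)
  t1 <- sum(ab^2) * ac - sum(ac^2) * ab
  ctr <- a + c(t1[2] * cr[3] - t1[3] * cr[2],
               t1[3] * cr[1] - t1[1] * cr[3],
               t1[1] * cr[2] - t1[2] * cr[1]) / (2 * cr2)
  list(ctr = ctr, r = sqrt(sum((a - ctr)^2)))
}

circumsphere4 <- function(a, b, c, d) {
  A <- rbind(b - a, c - a, d - a)
  rhs <- 0.5 * rowSums(A^2)
  if (abs(det(A)) < 1e-12) return(NULL)
  u <- solve(A, rhs)
  list(ctr = a + u, r = sqrt(sum(u^2)))
}

# wrap a list of conformations as an ensemble (fixtures have log-weight 0
# unless given)
as_test_ensemble <- function(confs, log_weights = NULL, D_um = Inf) {
  if (inherits(confs, "csac_conformation")) confs <- list(confs)
  if (is.null(log_weights)) log_weights <- rep(0, length(confs))
  structure(
    list(conformations = confs, n_units = confs[[1]]$n_units,
         confinement_um = D_um, params = confs[[1]]$params,
         log_weights = log_weights, attrition_count = 0L,
         attempts = rep(1L, length(confs)), master_seed = NA_integer_),
    class = "csac_ensemble"
  )
}

# build a conformation from given unit-boundary positions, interpolating
# beads linearly inside each unit (geometry fixture; bond lengths within a
# unit equal the boundary spacing / beads_per_unit)
conf_from_units <- function(units, params = csac_params()) {
  bpu <- params$beads_per_unit
  n_units <- nrow(units)
  coords <- units[1, , drop = FALSE]
  for (t in 2:n_units) {
    for (j in seq_len(bpu)) {
      coords <- rbind(coords,
                      units[t - 1, ] + (units[t, ] - units[t - 1, ]) * j / bpu)
    }
  }
  conformation(coords, n_units, 0, params)
}
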