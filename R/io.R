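#' Write an ensemble to an extended-XYZ file
#'
#' One frame per chain: an atom-count line, a comment line of
#' `key=value` pairs (`chain_id`, `n_units`, `D_um`, `log_weight`,
#' `seed`), then one `C x y z` record per bead with coordinates in nm at
#' fixed 1e-4 nm precision. Extended XYZ is used rather than PDB because
#' nm-scale coordinates overflow PDB's fixed-width fields for
#' micrometre-sized systems.
#'
#' @param ensemble A `csac_ensemble`.
#' @param path Output file path.
#' @param manifest_path Optional CSV manifest path (chain id, units,
#'   confinement, log-weight, attempts); defaults to `path` with a
#'   `.manifest.csv` suffix, `NA` to skip.
#' @return `path`, invisibly.
#' @export
write_conformations <- function(ensemble, path,
                                manifest_path = paste0(path,
                                                       ".manifest.csv")) {
  if (length(ensemble) == 0) {
    abort("refusing to write an empty ensemble", class = "csac_io_error")
  }
  con <- file(path, "w")
  on.exit(close(con))
  for (i in seq_along(ensemble$conformations)) {
    conf <- ensemble$conformations[[i]]
    writeLines(as.character(nrow(conf$coords)), con)
    writeLines(sprintf(
      "chain_id=%d n_units=%d D_um=%s log_weight=%.10g seed=%s",
      i, conf$n_units,
      if (is.infinite(conf$confinement_um)) "free"
      else format(conf$confinement_um),
      conf$log_weight,
      if (is.na(conf$seed)) "NA" else format(conf$seed)), con)
    writeLines(sprintf("C %.4f %.4f %.4f", conf$coords[, 1],
                       conf$coords[, 2], conf$coords[, 3]), con)
  }
  if (!is.na(manifest_path)) {
    utils::write.csv(ensemble_manifest(ensemble), manifest_path,
                     row.names = FALSE)
  }
  invisible(path)
}

#' Per-chain manifest of an ensemble
#'
#' @param ensemble A `csac_ensemble`.
#' @return A tibble: `chain_id`, `n_units`, `D_um`, `log_weight`,
#'   `weight_normalized`, `attempts`.
#' @export
ensemble_manifest <- function(ensemble) {
  tibble::tibble(
    chain_id = seq_along(ensemble$conformations),
    n_units = ensemble$n_units,
    D_um = ensemble$confinement_um,
    log_weight = ensemble$log_weights,
    weight_normalized = ensemble_weights(ensemble),
    attempts = if (is.null(ensemble$attempts)) NA_integer_
               else ensemble$attempts
  )
}

#' Read conformations from an extended-XYZ file
#'
#' Parses the dialect written by [write_conformations()] and rebuilds a
#' validated ensemble: every chain is checked for self-avoidance and
#' (when confined) confinement, unless `validate = FALSE`.
#'
#' @param path File path.
#' @param params A [csac_params()] object describing the geometry.
#' @param validate Run validity predicates on every chain.
#' @return A `csac_ensemble`.
#' @export
read_conformations <- function(path, params = csac_params(),
                               validate = TRUE) {
  lines <- readLines(path)
  confs <- list()
  lws <- numeric(0)
  i <- 1L
  frame <- 0L
  while (i <= length(lines)) {
    if (!grepl("^\\s*\\d+\\s*$", lines[i])) {
      abort(sprintf("parse error at line %d: expected an atom count", i),
            class = "csac_io_error")
    }
    n <- as.integer(lines[i])
    frame <- frame + 1L
    if (i + 1L + n > length(lines)) {
      abort(sprintf("truncated file: frame %d needs %d atom lines", frame, n),
            class = "csac_io_error")
    }
    kv <- parse_kv(lines[i + 1L])
    rec <- lines[(i + 2L):(i + 1L + n)]
    parts <- matrix(unlist(strsplit(trimws(rec), "\\s+")), nrow = n,
                    byrow = TRUE)
    if (ncol(parts) < 4) {
      abort(sprintf("parse error in frame %d: bad atom record", frame),
            class = "csac_io_error")
    }
    coords <- matrix(as.numeric(parts[, 2:4]), ncol = 3)
    D_um <- if (identical(kv[["D_um"]], "free")) Inf
            else as.numeric(kv[["D_um"]])
    p <- utils::modifyList(params, list(confinement_diameter_um = D_um))
    class(p) <- "csac_params"
    conf <- conformation(coords, as.integer(kv[["n_units"]]),
                         as.numeric(kv[["log_weight"]]), p,
                         seed = suppressWarnings(as.integer(kv[["seed"]])))
    confs[[frame]] <- conf
    lws[frame] <- conf$log_weight
    i <- i + 2L + n
  }
  if (frame == 0L) {
    abort("no frames found", class = "csac_io_error")
  }
  if (validate) {
    bad <- which(!vapply(confs, function(cf) {
      check_self_avoidance(cf)$ok && check_confinement(cf)
    }, logical(1)))
    if (length(bad) > 0) {
      abort(paste0("validation failed for chain(s) ",
                   paste(bad, collapse = ", ")),
            class = "csac_validation_error")
    }
  }
  structure(
    list(conformations = confs, n_units = confs[[1]]$n_units,
         confinement_um = confs[[1]]$confinement_um,
         params = confs[[1]]$params, log_weights = lws,
         attrition_count = NA_integer_, attempts = NULL,
         master_seed = NA_integer_),
    class = "csac_ensemble"
  )
}

parse_kv <- function(line) {
  toks <- strsplit(trimws(line), "\\s+")[[1]]
  kv <- strsplit(toks, "=", fixed = TRUE)
  stats::setNames(
    vapply(kv, function(p) if (length(p) >= 2) p[2] else NA_character_,
           character(1)),
    vapply(kv, `[`, character(1), 1)
  )
}

#' Deterministic fixture conformations with closed-form properties
#'
#' Hand-constructable geometries used throughout the test-suite and
#' examples:
#'
#' * `rod`: all units collinear -- end-to-end distance is exactly
#'   `(n_units - 1) * L_p` and no two non-bonded beads are ever in
#'   contact.
#' * `hairpin`: two antiparallel arms joined by a wide U-turn, offset by
#'   `gap_nm`; the number of cross-arm unit contacts follows from the
#'   gap.
#' * `dense_ball`: beads wound on a compact spherical spiral with
#'   spacing exactly one bead diameter, fitting inside `radius_nm`.
#' * `two_family`: a list of rods and dense balls with a `family` label,
#'   for clustering and classification tests.
#'
#' Fixtures satisfy bonded spacing and self-avoidance by construction;
#' they are geometric test objects, not samples from the growth
#' distribution.
#'
#' @param kind Fixture type.
#' @param n_units Number of persistence units.
#' @param params A [csac_params()] object.
#' @param gap_nm Hairpin arm separation in nm.
#' @param radius_nm Target ball radius in nm.
#' @param n_each For `two_family`: chains per family.
#' @return A `csac_conformation`, or for `two_family` a list with
#'   elements `conformations` and `family`.
#' @export
make_fixture <- function(kind = c("rod", "hairpin", "dense_ball",
                                  "two_family"),
                         n_units = 10, params = csac_params(),
                         gap_nm = 50, radius_nm = 400, n_each = 5) {
  kind <- match.arg(kind)
  d <- params$bead_diameter_nm
  switch(kind,
    rod = {
      n <- bead_count(n_units, params)
      coords <- cbind((seq_len(n) - 1) * d, 0, 0)
      conformation(coords, n_units, 0, params)
    },
    hairpin = {
      # rectangular U on a lattice of spacing d: two antiparallel arms
      # along x separated by gap_nm (rounded to a multiple of d), joined
      # by a vertical connector; min non-bonded distance is d exactly
      stopifnot(n_units >= 4)
      n <- bead_count(n_units, params)
      g <- max(2, round(gap_nm / d))
      half <- floor((n - (g - 1)) / 2)
      up <- cbind((seq_len(half) - 1) * d, 0, 0)
      conn <- cbind((half - 1) * d, seq_len(g - 1) * d, 0)
      down_len <- n - half - (g - 1)
      down <- cbind((half - seq_len(down_len)) * d, g * d, 0)
      conformation(rbind(up, conn, down), n_units, 0, params)
    },
    dense_ball = {
      n <- bead_count(n_units, params)
      conformation(snake_cube(n, d, radius_nm), n_units, 0, params)
    },
    two_family = {
      rods <- lapply(seq_len(n_each), function(i) {
        conf <- make_fixture("rod", n_units, params)
        conf$coords <- conf$coords + matrix(rep(c(0, 0, (i - 1) * 4 * d),
                                                each = nrow(conf$coords)), ncol = 3)
        conf
      })
      balls <- lapply(seq_len(n_each), function(i) {
        conf <- make_fixture("dense_ball", n_units, params,
                             radius_nm = radius_nm)
        conf$coords <- conf$coords + matrix(rep(c(0, (i - 1) * 4 * d, 0),
                                                each = nrow(conf$coords)), ncol = 3)
        conf
      })
      list(conformations = c(rods, balls),
           family = rep(c("rod", "ball"), each = n_each))
    }
  )
}

# boustrophedon walk through a cubic lattice of spacing d: consecutive
# beads are lattice neighbours and every non-bonded pair is >= d apart
snake_cube <- function(n, d, radius_nm) {
  m <- ceiling(n^(1 / 3))
  iz <- rep(seq_len(m), each = m * m)
  iy <- rep(rep(seq_len(m), each = m), times = m)
  ix <- rep(seq_len(m), times = m * m)
  # reverse x on alternating y rows, and y on alternating z layers
  flip_y <- iy %% 2 == 0
  ix <- ifelse(xor(flip_y, iz %% 2 == 0), m + 1 - ix, ix)
  iy <- ifelse(iz %% 2 == 0, m + 1 - iy, iy)
  pts <- (cbind(ix, iy, iz)[seq_len(n), , drop = FALSE] - (m + 1) / 2) * d
  if (max(sqrt(rowSums(pts^2))) > radius_nm) {
    warn("dense ball exceeds requested radius; increase radius_nm")
  }
  pts
}
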