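test_that("candidate set is near-isotropic and rotation-invariant", {
  d2 <- make_candidate_set(2, rotate = FALSE)
  expect_lt(sqrt(sum(colMeans(d2)^2)), 0.5)
  d100 <- make_candidate_set(100, rotate = FALSE)
  expect_true(all(abs(sqrt(rowSums(d100^2)) - 1) < 1e-9))
  expect_lt(sqrt(sum(colMeans(d100)^2)), 0.05)
  # no duplicate directions
  expect_gt(min(stats::dist(d100)), 1e-3)
  # rotation preserves the pairwise-angle multiset, changes directions
  ra <- make_candidate_set(100, seed = 1)
  rb <- make_candidate_set(100, seed = 2)
  expect_equal(sort(as.vector(stats::dist(ra))),
               sort(as.vector(stats::dist(rb))), tolerance = 1e-9)
  expect_gt(max(abs(ra - rb)), 0.01)
})

test_that("feasible moves equal the brute-force oracle", {
  p <- csac_params()
  dirs <- make_candidate_set(100, seed = 5)
  # an isolated seed bead at the centre: every direction is feasible
  expect_length(feasible_moves(matrix(0, 1, 3), dirs, 1.5, p), 100)
  # a seed bead near the boundary: outward directions become infeasible
  near <- matrix(c(735 - 75, 0, 0), 1, 3)
  got <- feasible_moves(near, dirs, 1.5, p)
  expect_lt(length(got), 100)
  expect_equal(got, oracle_feasible(near, dirs, 1.5, p))
  # a dense folded partial chain
  conf <- grow_chain(30, D_um = 1.5, seed = 9)
  expect_equal(feasible_moves(conf$coords, dirs, 1.5, p),
               oracle_feasible(conf$coords, dirs, 1.5, p))
  # free space also agrees
  expect_equal(feasible_moves(conf$coords, dirs, Inf, p),
               oracle_feasible(conf$coords, dirs, Inf, p))
})

test_that("growth is deterministic under a fixed seed", {
  a <- grow_chain(10, D_um = 1.5, seed = 42)
  b <- grow_chain(10, D_um = 1.5, seed = 42)
  expect_identical(a$coords, b$coords)
  expect_identical(a$log_weight, b$log_weight)
  c <- grow_chain(10, D_um = 1.5, seed = 43)
  expect_false(isTRUE(all.equal(a$coords, c$coords)))
})

test_that("an unobstructed two-unit chain has weight exactly one", {
  conf <- grow_chain(2, D_um = Inf, seed = 1)
  expect_identical(conf$log_weight, 0)
  expect_equal(attr(conf, "m_counts"), 100L, ignore_attr = TRUE)
})

test_that("emitted chains always satisfy both validity predicates", {
  en <- grow_ensemble(100, 50, D_um = 1.5, seed = 7)
  expect_length(en, 100)
  ok <- vapply(en$conformations, function(conf) {
    check_self_avoidance(conf)$ok && check_confinement(conf)
  }, logical(1))
  expect_true(all(ok))
  # log-weights are non-positive: w = prod(m_t/k) lies in (0, 1]
  expect_true(all(en$log_weights <= 1e-12))
  # brute-force oracle agreement on a few chains
  for (i in c(1, 50, 100)) {
    expect_identical(nrow(oracle_overlap_pairs(en$conformations[[i]]$coords)),
                     0L)
  }
})

test_that("two master seeds agree within Monte Carlo error", {
  e1 <- grow_ensemble(150, 30, D_um = 1.5, seed = 101)
  e2 <- grow_ensemble(150, 30, D_um = 1.5, seed = 202)
  d1 <- vapply(e1$conformations, function(conf)
    sqrt(sum((conf$coords[nrow(conf$coords), ] - conf$coords[1, ])^2)),
    numeric(1))
  d2 <- vapply(e2$conformations, function(conf)
    sqrt(sum((conf$coords[nrow(conf$coords), ] - conf$coords[1, ])^2)),
    numeric(1))
  se <- sqrt(sd(d1)^2 / length(d1) + sd(d2)^2 / length(d2))
  expect_lt(abs(mean(d1) - mean(d2)), 3 * se)
})

test_that("attrition rises as the confinement tightens", {
  att <- vapply(c(0.8, 3.0), function(D) {
    grow_ensemble(60, 60, D_um = D, seed = 5)$attrition_count
  }, numeric(1))
  expect_gte(att[1], att[2])
})

test_that("weighted shape frequencies reproduce the uniform target on an
           enumerable candidate set", {
  # free space, k = 6 fixed directions, 4 units: every self-avoiding
  # 3-step direction sequence is enumerable, and the target distribution
  # is uniform over them; Rosenbluth weighting must undo the growth bias
  p <- csac_params(k_states = 6)
  dirs <- make_candidate_set(6, rotate = FALSE)
  d <- p$bead_diameter_nm
  bpu <- p$beads_per_unit
  seqs <- expand.grid(a = 1:6, b = 1:6, c = 1:6)
  build <- function(sq) {
    pts <- matrix(0, 1, 3)
    tip <- c(0, 0, 0)
    for (ci in sq) {
      for (j in seq_len(bpu)) pts <- rbind(pts, tip + j * d * dirs[ci, ])
      tip <- tip + bpu * d * dirs[ci, ]
    }
    pts
  }
  feasible <- vapply(seq_len(nrow(seqs)), function(r) {
    nrow(oracle_overlap_pairs(build(as.integer(seqs[r, ])))) == 0
  }, logical(1))
  n_shapes <- sum(feasible)
  expect_gt(n_shapes, 6)  # backfolds are excluded, most shapes survive

  en <- grow_ensemble(4000, 4, D_um = Inf, params = p, seed = 31,
                      rotate = FALSE)
  # identify each grown chain's direction sequence
  key_of <- function(conf) {
    u <- unit_coords(conf)
    steps <- diff(u) / (bpu * d)
    idx <- apply(steps, 1, function(v) which.max(dirs %*% v))
    paste(idx, collapse = "-")
  }
  keys <- vapply(en$conformations, key_of, character(1))
  w <- ensemble_weights(en)
  freq <- tapply(w, keys, sum)
  expect_lte(length(freq), n_shapes)
  # uniform target: each shape has probability 1/n_shapes
  mc_tol <- 5 / sqrt(length(en))
  expect_lt(max(abs(freq - 1 / n_shapes)), mc_tol)
  # every enumerated feasible shape is reachable, none infeasible appears
  enum_keys <- apply(seqs[feasible, ], 1, paste, collapse = "-")
  expect_true(all(keys %in% enum_keys))
})
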