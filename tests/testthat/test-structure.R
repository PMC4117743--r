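test_that("distance matrices are exact for rods and symmetric in general", {
  rod <- make_fixture("rod", 12)
  m <- distance_matrix(rod, "units")
  want <- abs(outer(1:12, 1:12, "-")) * 150
  expect_equal(m, want, tolerance = 1e-10, ignore_attr = TRUE)
  conf <- grow_chain(15, D_um = 1.5, seed = 3)
  mm <- distance_matrix(conf)
  expect_equal(mm, t(mm))
  expect_equal(diag(mm), rep(0, 15), ignore_attr = TRUE)
  # spot-check against direct arithmetic
  u <- unit_coords(conf)
  expect_equal(mm[2, 9], sqrt(sum((u[2, ] - u[9, ])^2)), tolerance = 1e-12)
})

test_that("minimal enclosing sphere matches exhaustive support search", {
  set.seed(42)
  for (rep in 1:15) {
    n <- sample(4:12, 1)
    pts <- matrix(rnorm(3 * n, sd = 50), ncol = 3)
    got <- min_enclosing_sphere(pts)
    want <- oracle_mes(pts)
    expect_equal(got[["radius"]], want$r, tolerance = 1e-6)
    # all points contained
    ctr <- got[c("x", "y", "z")]
    expect_true(all(sqrt(rowSums(sweep(pts, 2, ctr)^2)) <=
                      got[["radius"]] + 1e-6))
  }
  # degenerate cases: single point, collinear points
  expect_equal(min_enclosing_sphere(matrix(1:3, 1, 3))[["radius"]], 0)
  line <- cbind(seq(0, 90, by = 30), 0, 0)
  expect_equal(min_enclosing_sphere(line)[["radius"]], 45, tolerance = 1e-9)
})

test_that("rigid rods contain no substructures under either scan policy", {
  rod <- make_fixture("rod", 300)  # 1496 beads, 3990+ nm span per window
  expect_identical(nrow(find_substructures(rod, method = "cover")), 0L)
  expect_identical(nrow(find_substructures(rod, method = "greedy_mes")), 0L)
})

test_that("a planted dense ball flanked by rods is found as one
           substructure", {
  p <- csac_params()
  d <- p$bead_diameter_nm
  n_units <- 100  # 496 beads: 150 rod + 196 ball + 150 rod
  ball <- make_fixture("dense_ball", 40, radius_nm = 500)$coords  # 196 beads
  left <- cbind(seq(-150 * d, -d, by = d), 0, 0)
  right <- cbind(seq(d, 150 * d, by = d), 0, 0)
  ball <- sweep(ball, 2, c(0, 300, 0), "+")
  coords <- rbind(left, ball, right)
  conf <- conformation(coords, n_units, 0, p)
  for (method in c("cover", "greedy_mes")) {
    subs <- find_substructures(conf, method = method)
    expect_identical(nrow(subs), 1L)
    # the detected interval contains the ball core
    expect_lte(subs$start_bead, 160)
    expect_gte(subs$end_bead, 330)
    expect_gt(subs$dna_kbp, 400)
  }
})

test_that("substructure intervals never overlap and cover at most the
           chain", {
  en <- grow_ensemble(5, 300, D_um = 1.0, seed = 55)
  for (conf in en$conformations) {
    subs <- find_substructures(conf)
    if (nrow(subs) > 1) {
      expect_true(all(subs$start_bead[-1] > subs$end_bead[-nrow(subs)]))
    }
    expect_lte(sum(subs$n_beads), nrow(conf$coords))
    expect_true(all(subs$dna_kbp > 400))
  }
})

test_that("interactivity classification separates far and interdigitated
           substructures", {
  p <- csac_params()
  ball <- make_fixture("dense_ball", 40, radius_nm = 500)$coords  # 196 beads
  # two balls 5 um apart, bridged by a straight connector
  far <- rbind(ball,
               cbind(seq(200, 4800, length.out = 104), 0, 0),
               sweep(ball, 2, c(5000, 0, 0), "+"))
  conf_far <- conformation(far, 100, 0, p)
  subs <- tibble::tibble(start_bead = c(1L, 301L), end_bead = c(196L, 496L),
                         n_beads = c(196L, 196L),
                         dna_kbp = c(588, 588),
                         enclosing_diameter_nm = c(260, 260))
  cl <- classify_substructures(subs, conf_far)
  expect_identical(as.character(cl$category), rep("independent", 2))
  expect_true(all(cl$strictly_independent))
  expect_identical(cl$interaction_fraction, c(0, 0))

  # one dense ball split into two interdigitated halves
  conf_mix <- conformation(rbind(ball, sweep(ball, 2, c(15, 15, 15), "+"),
                                 cbind(seq(300, 900, length.out = 104), 0, 0)),
                           100, 0, p)
  subs2 <- tibble::tibble(start_bead = c(1L, 197L), end_bead = c(196L, 392L),
                          n_beads = c(196L, 196L), dna_kbp = c(588, 588),
                          enclosing_diameter_nm = c(260, 260))
  cl2 <- classify_substructures(subs2, conf_mix)
  expect_identical(as.character(cl2$category), rep("interactive", 2))
  expect_true(all(cl2$interaction_fraction > 0.2))

  # order invariance and r_c monotonicity
  cl2r <- classify_substructures(subs2[2:1, ], conf_mix)
  expect_identical(as.character(cl2r$category), rev(as.character(cl2$category)))
  cl_small <- classify_substructures(subs2, conf_mix, r_c = 10)
  expect_true(all(cl_small$interaction_fraction <= cl2$interaction_fraction))
})

test_that("clustering separates constructed conformational families", {
  fam <- make_fixture("two_family", n_units = 20, n_each = 5)
  en <- as_test_ensemble(fam$conformations)
  cl <- cluster_ensemble(en, n_clusters = 2)
  expect_identical(length(unique(cl$labels[fam$family == "rod"])), 1L)
  expect_identical(length(unique(cl$labels[fam$family == "ball"])), 1L)
  expect_false(cl$labels[1] == cl$labels[10])
  expect_error(cluster_ensemble(en, n_clusters = 11),
               class = "csac_config_error")
  # identical chains: all dissimilarities vanish, clusters stay pure
  same <- as_test_ensemble(rep(fam$conformations[1], 8))
  cl_same <- cluster_ensemble(same, n_clusters = 2)
  expect_identical(max(cl_same$hclust$height), 0)
})

test_that("compactness classification orders rods above balls", {
  fam <- make_fixture("two_family", n_units = 20, n_each = 4)
  en <- as_test_ensemble(fam$conformations)
  res <- classify_compactness(en, breaks = c(0.2, 0.8))
  cls <- as.character(res$per_chain$class)
  expect_true(all(cls[fam$family == "rod"] == "open"))
  expect_true(all(cls[fam$family == "ball"] == "compact"))
  expect_equal(sum(res$fractions), 1)
  # all-identical chains concentrate in one class
  same <- as_test_ensemble(rep(fam$conformations[1], 5))
  res_same <- classify_compactness(same, breaks = c(0.2, 0.8))
  expect_equal(max(res_same$fractions), 1)
})

test_that("open-structure fraction grows with the confinement diameter", {
  ens <- lapply(c(1.2, 5), function(D)
    grow_ensemble(40, 60, D_um = D, seed = 17))
  pooled <- classify_compactness(ens)  # thresholds from pooled quantiles
  open_by_D <- tapply(pooled$per_chain$class == "open",
                      pooled$per_chain$D_um, mean)
  expect_gt(open_by_D[["5"]], open_by_D[["1.2"]])
})
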