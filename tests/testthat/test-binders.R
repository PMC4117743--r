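test_that("site placement covers the requested fraction of units", {
  expect_identical(place_sites(50, 1), 1:50)
  s <- place_sites(1000, 0.1, seed = 3)
  expect_length(s, 100)
  expect_identical(anyDuplicated(s), 0L)
  s2 <- place_sites(1000, 0.1, seed = 4)
  expect_length(s2, 100)
  expect_false(identical(s, s2))
})

# a rectangular U whose arms sit exactly one contact radius apart: the
# aligned cross-arm unit pairs (1,8), (2,7), (3,6) are proximal, (4,5)
# is adjacent and excluded, so 3 bound pairs when all units carry sites
u_fixture <- function() {
  units <- rbind(cbind(0:3 * 150, 0, 0), cbind(3:0 * 150, 60, 0))
  conf_from_units(units)
}

test_that("bound-pair counting matches hand-checkable geometry", {
  rod <- make_fixture("rod", 12)
  expect_identical(count_bound_pairs(rod, 1:12), 0L)
  u <- u_fixture()
  expect_identical(count_bound_pairs(u, 1:8), 3L)
  expect_identical(count_bound_pairs(u, c(1, 2, 7, 8)), 2L)
  expect_identical(count_bound_pairs(u, integer(0)), 0L)
  # all-pairs oracle on the same fixture
  uc <- unit_coords(u)
  want <- 0L
  for (i in 1:7) for (j in (i + 2):8) {
    if (j <= 8 && sqrt(sum((uc[i, ] - uc[j, ])^2)) <= 60) want <- want + 1L
  }
  expect_identical(count_bound_pairs(u, 1:8), want)
})

test_that("Boltzmann reweighting follows the closed form and preserves the
           original ensemble", {
  rod <- make_fixture("rod", 8)
  u <- u_fixture()
  en <- as_test_ensemble(list(rod, u))
  # zero energy: identity
  rw0 <- reweight(en, binder_config(1, binding_energy_kBT = 0))
  expect_identical(rw0$log_weights, en$log_weights)
  # epsilon = 6, tau = 1, sites {1,2,7,8}: 0 vs 2 pairs -> ratio e^12
  rw <- reweight(en, binder_config(0.5, 6, 1), sites = c(1, 2, 7, 8))
  expect_equal(rw$log_weights[2] - rw$log_weights[1], 12)
  expect_identical(en$log_weights, c(0, 0))  # input untouched
  # tau = 10 scales the energy down tenfold
  rw10 <- reweight(en, binder_config(0.5, 6, 10), sites = c(1, 2, 7, 8))
  expect_equal(rw10$log_weights[2] - rw10$log_weights[1], 1.2)
  # single chain: normalized estimators unchanged regardless of energy
  solo <- as_test_ensemble(list(u))
  rw_solo <- reweight(solo, binder_config(1, 50, 1))
  expect_equal(ensemble_weights(rw_solo), 1)
  expect_equal(end_to_end(rw_solo), end_to_end(solo))
})

test_that("log-weight arithmetic survives extreme Boltzmann factors", {
  u <- u_fixture()
  en <- as_test_ensemble(list(make_fixture("rod", 8), u))
  # n_pairs * eps / tau up to 700 in log space: no overflow, no NaN
  rw <- reweight(en, binder_config(1, 350, 1), sites = 1:8)  # 2 pairs * 350
  expect_true(all(is.finite(rw$log_weights)))
  w <- ensemble_weights(rw)
  expect_true(all(is.finite(w)))
  expect_equal(sum(w), 1)
  expect_gt(w[2], 0.999)  # looped chain dominates
  # reweighting preserves the ordering of chains by pair count
  expect_gt(rw$log_weights[2], rw$log_weights[1])
})

test_that("reweighting boosts a planted looped subpopulation's contacts", {
  # rods (no contacts) mixed with U-shapes (contact at s = 7): binder
  # reweighting must shift Pc(7) upward
  units_u <- rbind(cbind(0:3 * 150, 0, 0), cbind(3:0 * 150, 50, 0))
  loops <- replicate(5, conf_from_units(units_u), simplify = FALSE)
  rods <- replicate(5, make_fixture("rod", 8), simplify = FALSE)
  en <- as_test_ensemble(c(rods, loops))
  before <- contact_probability(en, s_values = 7)$Pc
  rw <- reweight(en, binder_config(1, 6, 1), sites = 1:8)
  after <- contact_probability(rw, s_values = 7)$Pc
  expect_gt(after, before)
  expect_equal(after, 1, tolerance = 1e-3)  # loops dominate at e^{-...}
})

test_that("sensitivity report returns exact zeros at zero energy and flags
           low effective sample size", {
  en <- grow_ensemble(25, 40, D_um = 1.5, seed = 19)
  rep0 <- binder_sensitivity_report(en, coverages = c(0.2, 0.4),
                                    temperatures = 1, energy_kBT = 0,
                                    nu_range = c(2, 20),
                                    alpha_range = c(2, 30),
                                    min_contacts = 1)
  expect_equal(rep0$delta_nu, rep(0, nrow(rep0)))
  expect_equal(rep0$delta_alpha, rep(0, nrow(rep0)))
  expect_true(all(c("ess", "low_ess") %in% names(rep0)))
  # strong reweighting collapses the ESS and the flag reports it
  rep6 <- binder_sensitivity_report(en, coverages = 0.5, temperatures = 1,
                                    energy_kBT = 6, nu_range = c(2, 20),
                                    alpha_range = c(2, 30),
                                    min_contacts = 1, ess_floor = 30)
  expect_true(rep6$low_ess[rep6$coverage == 0.5])
})
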