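test_that("synthetic titrations are seeded, clipped and truth-carrying", {
  ds1 <- generate_titration(1e6, 1e3, 0.01, 1e-5, sigma = 0.02, seed = 42)
  ds2 <- generate_titration(1e6, 1e3, 0.01, 1e-5, sigma = 0.02, seed = 42)
  expect_identical(ds1, ds2)
  ds3 <- generate_titration(1e6, 1e3, 0.01, 1e-5, sigma = 0.02, seed = 43)
  expect_false(identical(ds1$response, ds3$response))
  expect_true(all(ds1$response >= 0 & ds1$response <= 1))
  expect_equal(attr(ds1, "metadata")$truth$keq_lw, 1e6)
  expect_error(
    generate_titration(1e6, 1e3, 0.01, 1e-5, sigma = -0.1, seed = 1),
    ">= 0"
  )
  expect_error(generate_titration(1e6, 1e3, 0.01, 1e-5), "seed")
})

test_that("generation leaves the caller's RNG state untouched", {
  set.seed(999)
  before <- .Random.seed
  invisible(generate_titration(1e6, 1e3, 0.01, 1e-5, sigma = 0.02, seed = 1))
  expect_identical(.Random.seed, before)
})

test_that("noiseless generation equals the exact solver output", {
  ds <- generate_titration(1e6, 1e3, 0.01, 1e-5, sigma = 0, seed = 1)
  comp <- system_composition(1e-8, 1e-5, 0.01)
  ref <- saturation_curve(1e6, 1e3, comp, lt_grid = ds$lt_molar)
  expect_equal(ds$response, ref$saturation)
})

test_that("full fit on the seed-42 noisy dataset recovers the truth", {
  ds <- generate_titration(
    keq_lw = 1e6, kp_lb_lw = 1e3, alpha_lb = 0.01,
    protein_total = 1e-5, sigma = 0.02, n_points = 20, seed = 42
  )
  fit <- fit_titration(ds, "full")
  expect_true(fit$converged)
  expect_lt(abs(fit$estimates[[1]] - 1e6), 3 * fit$stderr[[1]])
})

test_that("scenario ids are validated", {
  expect_error(run_scenario("fig999"), "unknown scenario")
  expect_error(run_scenario(42), "unknown scenario")
})

test_that("apparent-vs-lipid table is unbiased at zero lipid", {
  tab <- run_scenario("apparent_vs_lipid", n_grid = 5)
  at0 <- tab[tab$alpha_lb == 0, ]
  expect_equal(at0$keq_app_lw, rep(1e6, nrow(at0)), tolerance = 1e-4)
  # hyperbola fit also recovers Keq at zero lipid only for low protein;
  # its bias grows with protein concentration at any fixed lipid level
  at_max <- tab[tab$alpha_lb == max(tab$alpha_lb), ]
  expect_true(all(diff(at_max$keq_app_lt[order(at_max$pt_molar)]) < 0))
  # depletion-corrected fits track the closed-form prediction
  expect_equal(tab$keq_app_lw, tab$bias_prediction, tolerance = 0.01)
})

test_that("lipid-titration table matches the closed-form bias", {
  tab <- run_scenario("lipid_titration", n_grid = 7)
  prot <- protein_spec(50000)
  alpha_p <- 1e-6 * prot$molar_volume
  ref <- mapply(
    function(lkp, a) bias_general(10^lkp, a, alpha_p)$ratio,
    tab$log_kp, tab$alpha_lb
  )
  expect_equal(tab$ratio, ref, tolerance = 1e-9)
  # polar branch: ~10% apparent-affinity gain at 10% v/v bilayer
  polar <- tab[tab$log_kp == -1 & abs(tab$alpha_lb - 0.10) < 0.013, ]
  expect_true(all(polar$ratio > 1.08 & polar$ratio < 1.13))
  # at every alpha_lb > 0, the ratio strictly decreases with KP >= 1
  for (a in unique(tab$alpha_lb)) {
    if (a == 0) next
    sub <- tab[tab$alpha_lb == a & tab$log_kp >= 0 & tab$lt_molar == 1e-6, ]
    expect_true(all(diff(sub$ratio[order(sub$log_kp)]) < 0))
  }
  # fractions are a partition of the ligand
  expect_true(all(tab$f_w >= 0 & tab$f_lb >= 0))
  expect_true(all(tab$f_w + tab$f_lb <= 1 + 1e-12))
})

test_that("lipophilicity-scaling cases follow their defining couplings", {
  tab <- run_scenario("lipophilicity_scaling", n_grid = 9)
  vbar <- molar_volume(50000)
  ci <- tab[tab$case == "constant_intrinsic", ]
  expect_equal(ci$keq_lw, rep(1e6, nrow(ci)))
  expect_true(all(diff(ci$kp_p_lb) < 0)) # cycle closure: kp up, kp_p_lb down
  cp <- tab[tab$case == "constant_protein_lipid", ]
  expect_equal(cp$kp_p_lb, rep(1, nrow(cp)))
  expect_equal(cp$keq_lw, vbar * cp$kp_lb_lw)
  su <- tab[tab$case == "supralinear", ]
  expect_equal(su$keq_lw, vbar * su$kp_lb_lw^2)
  # supralinear scenario reaches the 1e11 1/M scale at KP = 1e5
  expect_equal(max(su$keq_lw), 4.2e11)
  # every case shares the same apparent/intrinsic ratio profile
  expect_equal(ci$keq_app_lw / ci$keq_lw, su$keq_app_lw / su$keq_lw)
})

test_that("apparent constant is non-increasing in lipid load for kp > 1", {
  tab <- run_scenario("apparent_vs_lipophilicity", n_grid = 6)
  sub <- tab[tab$kp_lb_lw > 1 & tab$keq_lw == 1e6, ]
  for (kp in unique(sub$kp_lb_lw)) {
    s <- sub[sub$kp_lb_lw == kp, ]
    expect_true(all(diff(s$keq_app_lw[order(s$alpha_lb)]) <= 0))
  }
})

test_that("saturation-curve scenario reports fits alongside the data", {
  tab <- run_scenario("saturation_curves", n_grid = 12)
  expect_true(all(c(
    "alpha_lb", "lt_molar", "saturation",
    "fit_lipid_neglect", "resid_lipid_neglect",
    "fit_excess_ligand", "resid_excess_ligand"
  ) %in% names(tab)))
  # residuals are consistent with data minus fit
  expect_equal(tab$resid_lipid_neglect, tab$saturation - tab$fit_lipid_neglect)
  # apparent constants decrease with lipid load
  ka <- unique(tab[, c("alpha_lb", "keq_app_lw")])
  expect_true(all(diff(ka$keq_app_lw[order(ka$alpha_lb)]) < 0))
})
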