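test_that("with no binding agents all ligand stays free", {
  comp <- system_composition(1e-5, protein_total = 0, alpha_lb = 0)
  for (solver in list(solve_dilute, solve_general)) {
    d <- solver(1e6, 0, comp)
    expect_equal(d$l_w, 1e-5)
    expect_equal(d$l_lb, 0)
    expect_equal(d$l_p, 0)
    expect_equal(d$saturation, 0)
  }
})

test_that("dilute solver reproduces the frozen moderate-affinity example", {
  # Keq = 1e6 1/M, KP = 1e3, PT = LT = 10 uM, alpha_lb = 0.01, 50 kDa
  comp <- system_composition(1e-5, 1e-5, 0.01)
  d <- suppressWarnings(solve_dilute(1e6, 1e3, comp))
  # frozen values validated against the bisection oracle
  expect_equal(d$l_w, 5.726e-7, tolerance = 1e-3)
  expect_equal(d$l_lb, 5.786e-6, tolerance = 1e-3)
  expect_equal(d$l_p, 3.641e-6, tolerance = 1e-3)
  lw_oracle <- bisect_lw_dilute(1e6, 1e3, 1e-5, 1e-5, 0.01, comp$alpha_w)
  expect_equal(d$l_w, lw_oracle, tolerance = 1e-10)
  # conservation
  expect_equal(d$l_w + d$l_lb + d$l_p, 1e-5, tolerance = 1e-12)
  expect_equal(d$l_p + d$p_free, 1e-5, tolerance = 1e-12)
})

test_that("all outputs vanish as total ligand goes to zero", {
  comp <- system_composition(1e-15, 1e-5, 0.01)
  d <- suppressWarnings(solve_dilute(1e6, 1e3, comp))
  expect_lt(d$l_w, 1e-15)
  expect_lt(d$saturation, 1e-8)
  comp0 <- system_composition(0, 1e-5, 0.01)
  d0 <- solve_general(1e6, 1e3, comp0)
  expect_equal(d0$l_w + d0$l_lb + d0$l_p, 0)
})

test_that("mass and protein conservation hold over random draws", {
  set.seed(101)
  for (i in 1:200) {
    keq <- 10^runif(1, 2, 10)
    kp <- 10^runif(1, -2, 6)
    alb <- runif(1, 0, 0.15)
    pt <- 10^runif(1, -8, -4)
    lt <- 10^runif(1, -9, -3)
    comp <- system_composition(lt, pt, alb)
    for (d in list(
      suppressWarnings(solve_dilute(keq, kp, comp)),
      solve_general(keq, kp, comp)
    )) {
      expect_true(all(c(d$l_w, d$l_lb, d$l_p, d$p_free) >= 0))
      expect_equal(d$l_w + d$l_lb + d$l_p, lt, tolerance = 1e-10)
      expect_equal(d$l_p + d$p_free, pt, tolerance = 1e-10)
      expect_gte(d$saturation, 0)
      expect_lte(d$saturation, 1 + 1e-12)
    }
  }
})

test_that("analytical root matches the bisection oracle to 1e-8 relative", {
  set.seed(202)
  for (i in 1:200) {
    keq <- 10^runif(1, 2, 10)
    kp <- 10^runif(1, -2, 6)
    alb <- runif(1, 0, 0.15)
    pt <- 10^runif(1, -8, -4)
    lt <- 10^runif(1, -9, -3)
    comp <- system_composition(lt, pt, alb)
    d <- suppressWarnings(solve_dilute(keq, kp, comp))
    expect_equal(
      d$l_w, bisect_lw_dilute(keq, kp, lt, pt, alb, comp$alpha_w),
      tolerance = 1e-8
    )
    g <- solve_general(keq, kp, comp)
    cw <- bisect_cw_general(keq, kp, lt, pt, alb, comp$alpha_w)
    expect_equal(g$l_w, cw * comp$alpha_w, tolerance = 1e-8)
  }
})

test_that("lipid/water partition ratio is honored exactly on output", {
  comp <- system_composition(3e-6, 1e-6, 0.02)
  d <- suppressWarnings(solve_dilute(1e7, 500, comp))
  expect_equal(d$l_lb / d$l_w, 500 * 0.02 / comp$alpha_w, tolerance = 1e-12)
  g <- solve_general(1e7, 500, comp)
  expect_equal(g$l_lb / g$l_w, 500 * 0.02 / comp$alpha_w, tolerance = 1e-12)
})

test_that("general and dilute solvers agree in the dilute regime", {
  comp <- system_composition(1e-6, 1e-6, 1e-3)
  d <- solve_dilute(1e6, 1e3, comp)
  g <- solve_general(1e6, 1e3, comp)
  for (f in c("l_w", "l_lb", "l_p", "saturation")) {
    expect_equal(g[[f]], d[[f]], tolerance = 1e-3)
  }
})

test_that("bilayer exclusion of a polar ligand increases protein saturation", {
  # kp < 1: the bilayer concentrates the ligand in the aqueous phase
  keq <- 1e6
  kp <- 0.1
  with_lipid <- solve_general(keq, kp, system_composition(1e-6, 1e-6, 0.10))
  no_lipid <- solve_general(keq, kp, system_composition(1e-6, 1e-6, 0))
  expect_gt(with_lipid$saturation, no_lipid$saturation)
})

test_that("saturation is monotone in ligand, affinity and lipid load", {
  lt_grid <- 10^seq(-8, -3, length.out = 25)
  comp <- system_composition(1e-6, 1e-6, 0.01)
  sat <- saturation_curve(1e6, 1e3, comp, lt_grid)$saturation
  expect_true(all(diff(sat) >= -1e-12))
  # non-decreasing in Keq
  sat_hi <- saturation_curve(1e7, 1e3, comp, lt_grid)$saturation
  expect_true(all(sat_hi >= sat - 1e-12))
  # non-increasing in alpha_lb for a lipophilic ligand (kp > 1),
  # non-decreasing for an excluded ligand (kp < 1)
  alphas <- c(0, 0.01, 0.05, 0.1)
  for (kp in c(1e3, 0.1)) {
    sats <- sapply(alphas, function(a) {
      saturation_curve(
        1e6, kp, system_composition(1e-6, 1e-6, a), lt_grid
      )$saturation
    })
    dirs <- apply(sats, 1, diff)
    if (kp > 1) {
      expect_true(all(dirs <= 1e-12))
    } else {
      expect_true(all(dirs >= -1e-12))
    }
  }
})

test_that("saturation curve reduces to single solves and known limits", {
  comp <- system_composition(1e-6, 1e-5, 0.01)
  one <- saturation_curve(1e6, 1e3, comp, lt_grid = 2e-6)
  full <- solve_general(1e6, 1e3, system_composition(2e-6, 1e-5, 0.01))
  expect_equal(one$saturation, full$saturation)
  # half-saturation at LT = 1/Keq in the no-lipid, vanishing-protein limit
  comp0 <- system_composition(1e-6, 1e-12, 0)
  half <- saturation_curve(1e6, 0, comp0, lt_grid = 1e-6)$saturation
  expect_equal(half, 0.5, tolerance = 1e-5)
  expect_error(saturation_curve(1e6, 1e3, comp, numeric(0)), "non-empty")
  expect_error(saturation_curve(1e6, 1e3, comp, c(2e-6, 1e-6)), "sorted")
  expect_error(saturation_curve(1e6, 1e3, comp, c(-1e-6, 1e-6)), "positive")
})

test_that("dilute solver warns outside its validity region", {
  comp <- system_composition(1e-6, 1e-6, 0.05)
  expect_warning(solve_dilute(1e6, 1e3, comp), "alpha_w")
  expect_silent(solve_dilute(1e6, 1e3, system_composition(1e-6, 1e-6, 0.001)))
})

test_that("increasing lipid load orders the saturation curves downward", {
  # lipophilic ligand at the reference condition: each added increment of
  # bilayer lowers the whole binding curve
  lt_grid <- 10^seq(-7, -4, length.out = 15)
  sats <- sapply(c(0, 0.001, 0.01, 0.05), function(a) {
    saturation_curve(
      1e6, 1e3, system_composition(1e-6, 1e-5, a), lt_grid
    )$saturation
  })
  expect_true(all(apply(sats, 1, diff) <= 1e-12))
})
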