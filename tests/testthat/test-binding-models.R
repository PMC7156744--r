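test_that("bound fraction from the one-site quadratic matches bisection", {
  mass_action_theta <- function(Mt, Xt, n, kd) {
    # solve for free ligand X by bisection of X + n Mt X/(Kd+X) = Xt
    f <- function(x) x + n * Mt * x / (kd + x) - Xt
    lo <- 0; hi <- Xt
    for (i in 1:200) {
      mid <- (lo + hi) / 2
      if (f(mid) > 0) hi <- mid else lo <- mid
    }
    x <- (lo + hi) / 2
    (x / (kd + x))  # site occupancy
  }
  withr::with_seed(101, {
    for (i in 1:20) {
      Mt <- runif(1, 1, 100)
      Xt <- runif(1, 0.1, 200)
      n <- runif(1, 0.3, 2)
      kd <- 10^runif(1, -3, 1)
      got <- napscan:::one_site_theta(Mt, Xt, n, kd)
      want <- mass_action_theta(Mt, Xt, n, kd)
      expect_equal(got, want, tolerance = 1e-6)
    }
  })
})

test_that("titration limits behave: stoichiometric step and zero enthalpy", {
  # kd -> 0: constant heat per injection until molar ratio n, then ~0
  sim <- simulate_one_site_titration(n = 0.5, kd_nM = 1e-4, dH_kcal = -10)
  dq <- sim$injections$heat_ucal
  conc <- napscan:::titration_concentrations(sim)
  ratio <- conc$Xt / conc$Mt
  pre <- dq[ratio < 0.45]
  post <- dq[ratio > 0.6]
  expect_lt(stats::sd(pre) / abs(mean(pre)), 0.02)
  expect_true(all(abs(post) < 0.02 * abs(mean(pre))))

  expect_equal(simulate_one_site_titration(0.5, 83, 0)$injections$heat_ucal,
               rep(0, 19))
})

test_that("one-site fit round-trips a parameter grid exactly on noise-free data", {
  for (n in c(0.25, 0.5, 1)) {
    for (kd in c(30, 300, 3000)) {
      for (dH in c(-15, -5, 8)) {
        sim <- simulate_one_site_titration(n, kd, dH)
        fit <- fit_one_site(sim)
        expect_lt(abs(fit$params$n - n) / n, 0.01)
        expect_lt(abs(fit$params$kd_nM - kd) / kd, 0.01)
        expect_lt(abs(fit$params$dH_kcal - dH) / abs(dH), 0.01)
      }
    }
  }
})

test_that("one-site fit is robust to realistic noise", {
  sim0 <- simulate_one_site_titration(0.5, 83, -10)
  noise <- 0.05 * max(abs(sim0$injections$heat_ucal))
  res <- vapply(1:100, function(s) {
    sim <- simulate_one_site_titration(0.5, 83, -10, noise_sd = noise, seed = s)
    fit <- suppressWarnings(fit_one_site(sim))
    c(abs(fit$params$kd_nM - 83) / 83, abs(fit$params$n - 0.5) / 0.5)
  }, numeric(2))
  # at these concentrations the isotherm is steep (c = n*Mt/Kd ~ 150), so
  # Kd carries most of the noise while n is pinned by the equivalence point
  expect_lt(stats::median(res[1, ]), 0.25)
  expect_lt(stats::median(res[2, ]), 0.02)
})

test_that("fit errors are informative for degenerate titrations", {
  flat <- titration_series(heats_ucal = rep(0, 19))
  expect_error(fit_one_site(flat), "flat")
  short <- titration_series(injection_volumes_ul = rep(2, 3),
                            heats_ucal = c(-1, -2, -3))
  expect_error(fit_one_site(short), "5 injections")
})

test_that("thermodynamic derivation is internally consistent", {
  p <- one_site_params(n = 0.5, kd_nM = 83, dH_kcal = -10)
  # dG = RT ln Kd at 25 C; Kd 83 nM -> about -9.66 kcal/mol
  expect_equal(p$dG_kcal, -9.66, tolerance = 0.01)
  expect_equal(p$dH_kcal - p$dG_kcal, 298.15 * p$dS_cal / 1000,
               tolerance = 1e-9)
})

test_that("fraction-bound Kd fitting is definitional and round-trips", {
  # exact half-saturation: f = 0.5 at P = kd
  curve <- tibble::tibble(protein_uM = c(0.1, 0.4, 1.6),
                          fraction_bound = c(0.1, 0.4, 1.6) / (0.4 + c(0.1, 0.4, 1.6)))
  expect_equal(fit_fraction_bound_kd(curve)$kd_uM, 0.4, tolerance = 1e-6)

  for (kd in c(0.4, 1.1, 2.5, 4.0)) {
    cv <- simulate_fraction_bound(kd)
    expect_lt(abs(fit_fraction_bound_kd(cv)$kd_uM - kd) / kd, 0.02)
  }

  expect_error(fit_fraction_bound_kd(
    tibble::tibble(protein_uM = 1:3, fraction_bound = c(0, 0, 0))
  ), "unidentifiable")
})

test_that("competition occupancy has the closed-form half-inhibition point", {
  expect_equal(competition_occupancy(1, 0, kd_dna_uM = 0.9, kd_ligand_uM = 0.083),
               1.0)
  expect_lt(competition_occupancy(1, 1e6, 0.9, 0.083), 1e-3)

  # monotone non-increasing in ligand
  lig <- 10^seq(-3, 3, length.out = 50)
  occ <- competition_occupancy(4, lig, 0.9, 0.083)
  expect_true(all(diff(occ) <= 0))

  # half-inhibition at K_lig (1 + P/K_dna) for m = 1, found numerically
  P <- 4; kdna <- 0.9; klig <- 0.083
  half_pred <- klig * (1 + P / kdna)
  root <- stats::uniroot(
    function(c) competition_occupancy(P, c, kdna, klig) - 0.5,
    c(1e-6, 1e4)
  )$root
  expect_equal(root, half_pred, tolerance = 1e-4)
})

test_that("copy-number conversion follows Avogadro arithmetic", {
  # 1 complex in 1.661 fL is 1 nM
  expect_equal(copies_to_concentration(1, 1, 1.661), 1e-3, tolerance = 1e-3)
  # doubling the volume halves the concentration
  c1 <- copies_to_concentration(5000, 2, 1.0)
  c2 <- copies_to_concentration(5000, 2, 2.0)
  expect_equal(c1 / c2, 2)
  expect_error(copies_to_concentration(100, 1, 0), "volume")
})

test_that("immunoblot standard-curve quantification inverts a linear ladder", {
  amounts <- c(1, 2, 4, 8)      # ng
  intens <- 100 * amounts       # perfectly linear, zero intercept
  # sample equal to a standard recovers that standard's mass
  q <- standard_curve_quantify(amounts, intens, sample_intensity = 400,
                               molecular_weight_Da = 12000,
                               cells_loaded = 1e8)
  expect_equal(q$mass_ng, 4, tolerance = 1e-9)
  # copies by hand: 4e-9 g / (12000 g/mol) * N_A / 1e8 cells
  expect_equal(q$copies_per_cell, 4e-9 / 12000 * 6.02214076e23 / 1e8,
               tolerance = 1e-9)
  expect_equal(
    suppressWarnings(
      standard_curve_quantify(amounts, intens, 0, 12000, 1e8)
    )$copies_per_cell,
    0, tolerance = 1e-9
  )
  expect_warning(
    standard_curve_quantify(amounts, intens, 1e5, 12000, 1e8),
    "outside"
  )
  expect_warning(
    standard_curve_quantify(amounts, c(100, 90, 400, 800), 300, 12000, 1e8),
    "monotone"
  )
  # compose with the concentration conversion: one hand computation
  conc <- copies_to_concentration(q$copies_per_cell, 4, 1.32)
  expect_equal(conc, (q$copies_per_cell / 4) / (6.02214076e23 * 1.32e-15) * 1e6,
               tolerance = 1e-12)
})

test_that("SEC mass interpolation is log-linear and monotone", {
  ladder <- tibble::tibble(
    elution_ml = c(10, 12, 14, 16),
    mass_kDa = 10^(3 - 0.25 * (c(10, 12, 14, 16) - 10))  # exactly log-linear
  )
  expect_equal(sec_mass_from_elution(ladder, 12), ladder$mass_kDa[2],
               tolerance = 1e-9)
  # midpoint volume -> geometric mean of flanking masses
  expect_equal(sec_mass_from_elution(ladder, 13),
               sqrt(ladder$mass_kDa[2] * ladder$mass_kDa[3]),
               tolerance = 1e-9)
  expect_gt(sec_mass_from_elution(ladder, 11), sec_mass_from_elution(ladder, 15))
  expect_warning(sec_mass_from_elution(ladder, 20), "outside")
  expect_equal(unname(sec_standard_masses()["thyroglobulin"]), 669)
})

test_that("comparative-Ct fold changes follow the 2^-ddCt rule", {
  expect_equal(delta_delta_ct(20, 15, 20, 15), 1.0)
  expect_equal(delta_delta_ct(21, 15, 20, 15), 0.5)
  expect_equal(delta_delta_ct(18, 15, 20, 15), 4.0)
  expect_error(delta_delta_ct(NA, 15, 20, 15), "finite")
})

test_that("tidiers expose fit results as tibbles", {
  fit <- fit_one_site(simulate_one_site_titration(0.5, 83, -10))
  td <- tidy(fit)
  expect_equal(td$estimate[td$term == "n"], 0.5, tolerance = 1e-4)
  expect_true(glance(fit)$converged)
  ef <- fit_fraction_bound_kd(simulate_fraction_bound(1.1))
  expect_equal(tidy(ef)$estimate, 1.1, tolerance = 1e-4)
})
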