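# Allocation core: light response, quadratic quota relations, closed-form
# growth inversion, storage partition, caps and full composition.

test_that("photosynthesis rate is saturating with the documented anchors", {
  p <- par_small
  expect_identical(photosynthesis_rate(0, p), 0)
  expect_equal(photosynthesis_rate(1e7, p), p$v_I_max)
  expect_equal(photosynthesis_rate(log(2) / abs(p$A_I), p), p$v_I_max / 2)
  I <- seq(0, 500, by = 5)
  v <- photosynthesis_rate(I, p)
  expect_true(all(diff(v) >= 0))
  expect_true(all(v <= p$v_I_max))
  expect_error(photosynthesis_rate(-1, p), "I must be >= 0")
})

test_that("light coefficients follow (1+E)/v_I and m/v_I", {
  p0 <- with_params(par_small, E = 0, m = 0)
  lc <- light_coefficients(120, p0)
  expect_equal(lc$A_Chl, 1 / lc$v_I)
  expect_identical(lc$B_Chl, 0)
  # direct re-evaluation oracle at an arbitrary light level
  I <- 87.3
  lc2 <- light_coefficients(I, par_small)
  v <- par_small$v_I_max * (1 - exp(-par_small$A_I * I))
  expect_equal(lc2$A_Chl, (1 + par_small$E) / v, tolerance = 1e-14)
  expect_equal(lc2$B_Chl, par_small$m / v, tolerance = 1e-14)
  # halving v_I (via a modified v_I_max) doubles both coefficients
  lc3 <- light_coefficients(I, with_params(par_small,
                                           v_I_max = par_small$v_I_max / 2))
  expect_equal(lc3$A_Chl, 2 * lc2$A_Chl, tolerance = 1e-14)
  expect_equal(lc3$B_Chl, 2 * lc2$B_Chl, tolerance = 1e-14)
  expect_error(light_coefficients(0, par_small), "degenerate light")
  expect_error(light_coefficients(-2, par_small), "must be >= 0")
})

test_that("quota coefficients match the independent pool-summation oracle", {
  for (p in list(par_small, par_large)) {
    for (I in c(20, 100, 350)) {
      qc <- lapply(c(N = "N", P = "P", C = "C"), quota_coefficients,
                   I = I, params = p)
      mu_max <- growth_if_limited("C", 1, I, p)  # feasible carbon budget
      for (mu in mu_max * c(0, 0.2, 0.6, 0.95)) {
        comp <- macromolecular_composition(mu, I, list(N = 0, P = 0, Fe = 0), p)
        non_sto_C <- comp$Q_C_Pro_Pho + comp$Q_C_Pro_Bio + comp$Q_C_Pro_Other +
          comp$Q_C_Chl + comp$Q_C_RNA + comp$Q_C_DNA + comp$Q_C_Other +
          comp$Q_C_PlipThy
        expect_equal(comp$Q_N, qc$N$a * mu^2 + qc$N$b * mu + qc$N$c,
                     tolerance = 1e-12)
        expect_equal(comp$Q_P, qc$P$a * mu^2 + qc$P$b * mu + qc$P$c,
                     tolerance = 1e-12)
        expect_equal(non_sto_C, qc$C$a * mu^2 + qc$C$b * mu + qc$C$c,
                     tolerance = 1e-12)
      }
    }
  }
})

test_that("c_C assembles the structural carbon pools scaled by B_Chl", {
  lc <- light_coefficients(150, par_small)
  qc <- quota_coefficients("C", 150, par_small)
  p <- par_small
  chl_cost <- 1 + p$A_Pho + p$A_Pho_PChl * p$Y_Plip_CP
  expect_equal(qc$c,
               chl_cost * lc$B_Chl + p$Q_C_Pro_Other +
                 p$Q_P_min_RNA * p$Y_RNA_CP + p$Q_C_DNA + p$Q_C_Other,
               tolerance = 1e-14)
  expect_error(quota_coefficients("Fe", 150, par_small))
  expect_error(quota_coefficients("X", 150, par_small))
})

test_that("zero RNA coefficient collapses all quadratics to linear", {
  p0 <- with_params(par_small, A_RNA_P = 0)
  for (el in c("N", "P", "C")) {
    expect_identical(quota_coefficients(el, 100, p0)$a, 0)
  }
  # linear fallback still inverts correctly
  qc <- quota_coefficients("N", 100, p0)
  mu <- 0.6
  Q <- qc$b * mu + qc$c
  expect_equal(growth_if_limited("N", Q, 100, p0), mu, tolerance = 1e-12)
})

test_that("growth inversion round-trips and matches brute-force bisection", {
  set.seed(42)
  for (p in list(par_small, par_large)) {
    mu_star <- runif(200, 0, 1.5)
    I <- runif(200, 5, 400)
    for (el in c("N", "P")) {
      Q <- structural_quota(el, mu_star, I, p)
      mu_back <- growth_if_limited(el, Q, I, p)
      expect_equal(mu_back, mu_star, tolerance = 1e-10)
    }
    # Fe linear inversion round-trip
    Q_fe <- structural_quota("Fe", mu_star, I, p)
    expect_equal(growth_if_limited("Fe", Q_fe, I, p), mu_star,
                 tolerance = 1e-10)
  }
  # random quadratic cases against the bisection oracle
  n <- 500
  a <- runif(n, 1e-4, 0.1); b <- runif(n, 0.01, 0.5); c <- runif(n, 0.01, 0.8)
  Q <- c + runif(n, 0, 0.5)
  mu_closed <- phytoalloc:::.solve_quota_quadratic(a, b, c, Q)
  mu_oracle <- bisect_mu(a, b, c, Q)
  expect_equal(mu_closed, mu_oracle, tolerance = 1e-10)
})

test_that("growth clamps to zero at and below the structural minimum", {
  qc <- quota_coefficients("P", 80, par_small)
  expect_identical(growth_if_limited("P", qc$c, 80, par_small), 0)
  expect_identical(growth_if_limited("P", qc$c * 0.5, 80, par_small), 0)
  # Fe zero point: quota equal to the maintenance photosystem demand
  lc <- light_coefficients(80, par_small)
  expect_identical(
    growth_if_limited("Fe", par_small$A_Pho_Fe * lc$B_Chl, 80, par_small), 0)
  expect_error(growth_if_limited("N", -0.1, 80, par_small), "Q_i must be > 0")
})

test_that("Liebig growth takes the minimum with N-first tie-breaking", {
  I <- 150
  # build a state where all four single-element rates coincide
  mu_star <- 0.5
  st <- cell_state(structural_quota("N", mu_star, I, par_small),
                   structural_quota("P", mu_star, I, par_small),
                   structural_quota("Fe", mu_star, I, par_small))
  lg <- liebig_growth(st, I, par_small)
  expect_equal(lg$mu, mu_star, tolerance = 1e-10)
  expect_identical(lg$limiter, "N")
  # exhaustive argmin oracle on random states
  set.seed(7)
  for (k in 1:50) {
    st <- cell_state(runif(1, 0.05, 0.4), runif(1, 0.002, 0.03),
                     runif(1, 1e-5, 1e-4))
    lg <- liebig_growth(st, I, par_small)
    mu_i <- c(growth_if_limited("N", st$Q_N, I, par_small),
              growth_if_limited("P", st$Q_P, I, par_small),
              growth_if_limited("C", 1, I, par_small),
              growth_if_limited("Fe", st$Q_Fe, I, par_small))
    expect_equal(lg$mu, min(mu_i), tolerance = 1e-14)
    expect_identical(lg$limiter, c("N", "P", "C", "Fe")[which.min(mu_i)])
    expect_true(all(lg$mu <= lg$mu_i + 1e-14))
  }
  # raising a non-limiting quota cannot decrease growth
  st <- cell_state(0.09, 0.004, 3e-5)
  mu0 <- liebig_growth(st, I, par_small)$mu
  st2 <- cell_state(0.09, 0.008, 3e-5)
  expect_gte(liebig_growth(st2, I, par_small)$mu, mu0)
})

test_that("structural quota is the zero-storage composition sum", {
  I <- 90
  for (el in c("N", "P", "C", "Fe")) {
    q0 <- structural_quota(el, 0, I, par_large)
    if (el == "Fe") {
      lc <- light_coefficients(I, par_large)
      expect_equal(q0, par_large$A_Pho_Fe * lc$B_Chl, tolerance = 1e-14)
    } else {
      expect_equal(q0, quota_coefficients(el, I, par_large)$c,
                   tolerance = 1e-14)
    }
    mus <- seq(0, 1.4, by = 0.2)
    expect_true(all(diff(structural_quota(el, mus, I, par_large)) > 0))
  }
  comp <- macromolecular_composition(0.9, I, list(N = 0, P = 0, Fe = 0),
                                     par_large)
  expect_equal(structural_quota("N", 0.9, I, par_large), comp$Q_N,
               tolerance = 1e-12)
  expect_equal(structural_quota("Fe", 0.9, I, par_large), comp$Q_Fe,
               tolerance = 1e-12)
})

test_that("storage partition floors, zeroes the limiter and closes carbon", {
  I <- 150
  st <- cell_state(0.17, 0.006, 6e-5)   # P-limited, with real N and Fe storage
  lg <- liebig_growth(st, I, par_small)
  expect_identical(lg$limiter, "P")
  sto <- storage_partition(st, lg$mu, lg$limiter, I, par_small)
  expect_identical(sto[[lg$limiter]], 0)
  expect_true(all(unlist(sto[c("N", "P", "C", "Fe")]) >= 0))
  # closure oracle: structural + storage pools reassemble the state
  comp <- macromolecular_composition(lg$mu, I, sto, par_small)
  expect_equal(comp$Q_N, st$Q_N, tolerance = 1e-10)
  expect_equal(comp$Q_P, st$Q_P, tolerance = 1e-10)
  expect_equal(comp$Q_Fe, st$Q_Fe, tolerance = 1e-10)
  cpools <- sum(unlist(comp[grep("^Q_C_", names(comp))]))
  expect_equal(cpools, 1, tolerance = 1e-10)
  # zero N storage means C storage is the full residual
  st2 <- cell_state(structural_quota("N", lg$mu, I, par_small) * 0.999,
                    0.012, 6e-5)
  lg2 <- liebig_growth(st2, I, par_small)
  sto2 <- storage_partition(st2, lg2$mu, lg2$limiter, I, par_small)
  expect_identical(sto2$N, 0)
  expect_equal(sto2$C,
               1 - structural_quota("C", lg2$mu, I, par_small),
               tolerance = 1e-10)
})

test_that("oversized N storage is shrunk to keep carbon closure", {
  # huge N quota at low light: the carbon cost of the diagnosed N storage
  # would overfill the cell
  I <- 8
  st <- cell_state(0.9, 0.01, 6e-5)
  lg <- liebig_growth(st, I, par_small)
  sto <- storage_partition(st, lg$mu, lg$limiter, I, par_small)
  expect_true(sto$adjusted)
  expect_identical(sto$C, 0)
  non_C <- structural_quota("C", lg$mu, I, par_small)
  expect_lte(non_C + sto$N * par_small$Y_Nsto_CN, 1 + 1e-12)
})

test_that("maximum quotas: dynamic N cap, fixed P and Fe class caps", {
  tr_s <- traits_default$small; tr_l <- traits_default$large
  I <- 120
  caps <- max_quota("N", c(0.2, 0.6, 1.0), I, tr_s)
  expect_true(all(diff(caps) > 0))
  expect_identical(max_quota("P", 0.3, I, tr_s), tr_s$caps$Q_P_max)
  expect_identical(max_quota("P", 1.2, 400, tr_s), tr_s$caps$Q_P_max)
  expect_gt(max_quota("P", 0.5, I, tr_l), max_quota("P", 0.5, I, tr_s))
  expect_error(max_quota("C", 0.5, I, tr_s))
})

test_that("excess accounting: storage + structural + excess = quota", {
  tr <- traits_default$small
  I <- 150
  mu_target <- 0.4
  qmaxP <- tr$caps$Q_P_max
  st <- cell_state(structural_quota("N", mu_target, I, tr$params),
                   qmaxP + 0.004, 5e-5)
  lg <- liebig_growth(st, I, tr$params)
  ex <- excess_quota(st, lg$mu, I, tr, limiter = lg$limiter)
  expect_equal(ex$excess$P, st$Q_P - qmaxP, tolerance = 1e-12)
  expect_identical(ex$excess$N, 0)
  non_P <- structural_quota("P", lg$mu, I, tr$params)
  expect_equal(ex$storage$P + non_P + ex$excess$P, st$Q_P, tolerance = 1e-12)
  # quota exactly at the cap has zero excess
  st2 <- cell_state(st$Q_N, qmaxP, 5e-5)
  ex2 <- excess_quota(st2, liebig_growth(st2, I, tr$params)$mu, I, tr,
                      limiter = "N")
  expect_identical(ex2$excess$P, 0)
})

test_that("composition at zero growth holds only maintenance pools", {
  lc <- light_coefficients(60, par_small)
  comp <- macromolecular_composition(0, 60, list(N = 0, P = 0, Fe = 0),
                                     par_small)
  expect_equal(comp$Q_C_Chl, lc$B_Chl, tolerance = 1e-14)
  expect_identical(comp$Q_C_Pro_Bio, 0)
  expect_equal(comp$Q_Fe_Pho,
               par_small$A_Pho_Fe * (lc$A_Chl * 0.0 + lc$B_Chl),
               tolerance = 1e-14)
  # over-full cell is an explicit infeasibility error
  expect_error(
    macromolecular_composition(1.0, 60, list(N = 0.5, P = 0, Fe = 0),
                               par_small),
    "overflow")
})

test_that("chlorophyll demand falls with light; growth ceases in the dark", {
  Is <- c(5, 20, 80, 320)
  cN <- vapply(Is, function(I) quota_coefficients("N", I, par_small)$c,
               numeric(1))
  cC <- vapply(Is, function(I) quota_coefficients("C", I, par_small)$c,
               numeric(1))
  expect_true(all(diff(cN) < 0))
  expect_true(all(diff(cC) < 0))
  # as I -> 0+ the carbon budget cannot close and feasible growth vanishes
  expect_identical(growth_if_limited("C", 1, 1e-4, par_small), 0)
})

test_that("parameter loading validates invariants and trait ordering", {
  expect_s3_class(traits_default$small, "size_class_traits")
  expect_error(validate_alloc_params(with_params(par_small, A_Pho = -1)),
               "non-positive")
  expect_error(validate_alloc_params(with_params(par_small,
                                                 m = par_small$v_I_max + 1)),
               "v_I_max")
  bad <- tempfile(fileext = ".ini")
  writeLines(c("[shared]", "A_RNA_P = 0.008"), bad)
  expect_error(read_traits(bad), "must contain")
  expect_error(read_traits(tempfile()), "not found")
})
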