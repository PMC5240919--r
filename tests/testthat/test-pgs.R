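test_that("single-study PGS R2 matches the closed-form reduction", {
  # R2 = rho^2 h^4 / (S/N + h2) for one study, equal h2
  for (case in list(c(N = 250000, h2 = 0.5, rho = 0.5, S = 1e5),
                    c(N = 111749, h2 = 0.157, rho = 0.468, S = 250000))) {
    d <- equal_design(case["N"], 1, h2 = case["h2"], cgr_among = 1,
                      cgr_holdout = case["rho"])
    got <- pgs_r2(d$panel, d$cgr, architecture(case["S"], 100))$r2
    expect_equal(got,
                 case[["rho"]]^2 * case[["h2"]]^2 /
                   (case[["S"]] / case[["N"]] + case[["h2"]]),
                 tolerance = 1e-14)
  }
})

test_that("PGS report satisfies its internal identities", {
  for (seed in 1:15) {
    d <- random_design(seed)
    rep <- pgs_r2(d$panel, d$cgr, d$arch)
    expect_equal(rep$r2, rep$pgs_pheno_cov^2 / rep$pgs_variance,
                 tolerance = 1e-12)
    expect_gte(rep$r2, 0)
    expect_lte(rep$r2, 1)
  }
})

test_that("single-study designs respect the R2 upper limit rho^2 h2_holdout", {
  # the rho^2 h2 ceiling is a single-discovery-study property; with many
  # imperfectly correlated studies the averaging of study-specific effect
  # components pushes R2 beyond it
  arch <- architecture(5e4, 500)
  for (rho in c(0.2, 0.5, 0.8, 1)) {
    d <- equal_design(1e9, 1, h2 = 0.5, cgr_among = 1, cgr_holdout = rho,
                      h2_holdout = 0.4)
    expect_lte(pgs_r2(d$panel, d$cgr, arch)$r2, rho^2 * 0.4 + 1e-12)
  }
  d50 <- equal_design(1e9, 50, h2 = 0.5, cgr_among = 0.2, h2_holdout = 0.5)
  expect_gt(pgs_r2(d50$panel, d50$cgr, arch)$r2, 0.2^2 * 0.5)
})

test_that("zero correlation with the hold-out sample kills the R2", {
  d <- equal_design(1e6, 10, h2 = 0.5, cgr_among = 0.8, cgr_holdout = 0)
  expect_identical(pgs_r2(d$panel, d$cgr, architecture(1e5, 1000))$r2, 0)
})

test_that("single-study R2 is exactly quadratic in the hold-out CGR", {
  arch <- architecture(1e5, 1000)
  base <- equal_design(250000, 1, h2 = 0.5, cgr_among = 1, cgr_holdout = 1)
  r2_1 <- pgs_r2(base$panel, base$cgr, arch)$r2
  for (rho in c(0.1, 0.25, 0.5, 0.9)) {
    d <- equal_design(250000, 1, h2 = 0.5, cgr_among = 1, cgr_holdout = rho)
    expect_equal(pgs_r2(d$panel, d$cgr, arch)$r2 / r2_1, rho^2,
                 tolerance = 1e-12)
  }
})

test_that("R2 approaches rho^2 h2 as the discovery sample grows", {
  arch <- architecture(1e5, 1000)
  d <- equal_design(1e13, 1, h2 = 0.5, cgr_among = 1, cgr_holdout = 0.6)
  expect_equal(pgs_r2(d$panel, d$cgr, arch)$r2, 0.6^2 * 0.5,
               tolerance = 1e-6)
})

test_that("R2 is monotone in hold-out CGR and in C at fixed total N", {
  arch <- architecture(1e5, 1000)
  r2_of <- function(C, rho) {
    d <- equal_design(250000, C, h2 = 0.5, cgr_among = rho,
                      cgr_holdout = rho)
    pgs_r2(d$panel, d$cgr, arch)$r2
  }
  expect_true(all(diff(sapply(c(0.2, 0.4, 0.6, 0.8), function(r)
    r2_of(10, r))) > 0))
  # splitting a fixed total N over more studies helps when CGR < 1 ...
  expect_true(all(diff(sapply(c(1, 2, 10, 100), r2_of, rho = 0.5)) > 0))
  # ... and is neutral when CGR = 1
  expect_equal(r2_of(1, 1), r2_of(50, 1), tolerance = 1e-12)
})

test_that("R2 responds to discovery and hold-out heritability as published", {
  arch <- architecture(1e5, 1000)
  d_hi_disc <- equal_design(250000, 50, h2 = 0.5, cgr_among = 0.8,
                            h2_holdout = 0.25)
  d_hi_hold <- equal_design(250000, 50, h2 = 0.25, cgr_among = 0.8,
                            h2_holdout = 0.5)
  r2_disc <- pgs_r2(d_hi_disc$panel, d_hi_disc$cgr, arch)$r2
  r2_hold <- pgs_r2(d_hi_hold$panel, d_hi_hold$cgr, arch)$r2
  # hold-out heritability matters slightly more than discovery h2
  expect_gt(r2_hold, r2_disc)
})
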