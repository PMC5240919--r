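arch_default <- architecture(1e5, 1000)

test_that("single-study Z variance reduces to 1 + N h2 / M", {
  d <- equal_design(250000, 1, h2 = 0.5, cgr_among = 1)
  expect_identical(meta_z_variance(d$panel, d$cgr, arch_default),
                   1 + 250000 * 0.5 / 1000)
  d0 <- equal_design(250000, 1, h2 = 0, cgr_among = 1)
  expect_identical(meta_z_variance(d0$panel, d0$cgr, arch_default), 1)
})

test_that("two equal studies reduce to 1 + (h2/M) N (1 + rho)", {
  for (rho in c(0, 0.3, 0.7, 1)) {
    d <- equal_design(2 * 50000, 2, h2 = 0.4, cgr_among = rho)
    expect_equal(meta_z_variance(d$panel, d$cgr, architecture(1e5, 500)),
                 1 + 0.4 / 500 * 50000 * (1 + rho), tolerance = 1e-14)
  }
})

test_that("Z variance matches brute-force covariance construction", {
  for (seed in 1:20) {
    d <- random_design(seed)
    expect_equal(
      meta_z_variance(d$panel, d$cgr, d$arch),
      brute_force_sigma2(d$panel$sizes, d$panel$heritabilities,
                         d$cgr$among, d$arch$m_causal),
      tolerance = 1e-12)
  }
})

test_that("two-cluster design gives sigma2 = 63.5 at zero between-set CGR", {
  d <- two_set_design(250000, 50, h2 = 0.5, cgr_between = 0)
  s2 <- meta_z_variance(d$panel, d$cgr, arch_default)
  expect_equal(s2, 63.5, tolerance = 1e-12)
  # brute-force oracle on the explicit 100 x 100 covariance matrix
  expect_equal(
    brute_force_sigma2(d$panel$sizes, d$panel$heritabilities, d$cgr$among,
                       1000),
    63.5, tolerance = 1e-12)
})

test_that("Z variance is invariant to study permutation", {
  d <- random_design(42)
  perm <- sample(seq_len(d$panel$n_studies))
  pp <- study_panel(d$panel$sizes[perm], d$panel$heritabilities[perm])
  pc <- cgr_structure(d$cgr$among[perm, perm, drop = FALSE],
                      d$cgr$to_holdout[perm], d$cgr$holdout_h2)
  expect_equal(meta_z_variance(pp, pc, d$arch),
               meta_z_variance(d$panel, d$cgr, d$arch), tolerance = 1e-14)
})

test_that("power equals alpha under the null variance and is monotone", {
  for (al in c(5e-8, 5e-4, 0.05))
    expect_equal(power_per_causal_snp(1, al), al, tolerance = 1e-12)
  s2 <- c(1, 1.5, 3, 10, 100, 1e4)
  b <- power_per_causal_snp(s2, 5e-8)
  expect_true(all(diff(b) > 0))
  expect_error(power_per_causal_snp(0.99, 5e-8), ">= 1")
  expect_error(power_per_causal_snp(2, 1.5), "between 0 and 1")
})

test_that("power matches the Monte-Carlo rejection rate of N(0, sigma2)", {
  withr::with_seed(101, {
    for (case in list(c(126, 5e-8), c(2.7, 5e-4), c(63.5, 5e-8))) {
      s2 <- case[1]; al <- case[2]
      thr <- qnorm(1 - al / 2)
      z <- rnorm(1e6, sd = sqrt(s2))
      emp <- mean(abs(z) > thr)
      se <- sqrt(emp * (1 - emp) / 1e6)
      expect_lt(abs(power_per_causal_snp(s2, al) - emp), 3 * se + 1e-12)
    }
  })
})

test_that("power responds monotonically to N, h2 and CGR", {
  beta_of <- function(n_total, h2, rho) {
    d <- equal_design(n_total, 10, h2 = h2, cgr_among = rho)
    power_per_causal_snp(meta_z_variance(d$panel, d$cgr, arch_default), 5e-8)
  }
  expect_true(all(diff(sapply(c(1e4, 1e5, 1e6, 1e7), beta_of,
                              h2 = 0.3, rho = 0.5)) > 0))
  expect_true(all(diff(sapply(c(0.1, 0.3, 0.5, 0.8), function(h)
    beta_of(250000, h, 0.5))) > 0))
  expect_true(all(diff(sapply(c(0, 0.25, 0.5, 0.75, 1), function(r)
    beta_of(250000, 0.3, r))) > 0))
})

test_that("detection counts partition causal and null SNPs", {
  arch <- architecture(250000, 20000)
  for (beta in c(0, 1e-6, 0.032, 0.5, 1)) {
    rep <- detection_report(beta, arch)
    expect_equal(rep$expected_true_pos + rep$expected_false_neg,
                 arch$m_causal, tolerance = 1e-9)
    expect_equal(rep$expected_false_pos + rep$expected_true_neg,
                 arch$s_total - arch$m_causal, tolerance = 1e-9)
    expect_equal(rep$expected_hits,
                 rep$expected_true_pos + rep$expected_false_pos)
  }
})

test_that("degenerate detection cases follow the count formulas", {
  arch <- architecture(250000, 20000)
  rep0 <- detection_report(0, arch)
  expect_equal(rep0$expected_hits, 5e-8 * 230000)
  expect_equal(rep0$expected_true_pos, 0)
  expect_equal(rep0$p_any_true_pos, 0)
  # no null SNPs: all hits are true positives
  archMS <- architecture(1000, 1000)
  repMS <- detection_report(0.5, archMS)
  expect_equal(repMS$expected_false_pos, 0)
  expect_equal(repMS$p_any_hit, 1 - 0.5^1000)
})

test_that("extreme tails survive large M and tiny beta without underflow", {
  arch <- architecture(1e7, 1e6, alpha = 5e-8)
  rep <- detection_report(1e-300, arch)
  expect_gt(rep$p_any_true_pos, 0)
  expect_equal(rep$p_any_true_pos, 1e-294, tolerance = 1e-6)
  expect_true(is.finite(rep$expected_hits))
  # beta for a huge but finite design stays positive
  expect_gt(power_per_causal_snp(1 + 1e-6, 5e-8), 0)
})
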