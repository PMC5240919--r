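small_scenario <- function(...) {
  defaults <- list(sizes = c(800, 800), h2 = 0.5, cgr = 0.5,
                   s_total = 300, m_causal = 60, alpha = 5e-4,
                   maf = maf_fixed(0.3), n_replicates = 5, seed = 99)
  args <- utils::modifyList(defaults, list(...))
  do.call(sim_scenario, args)
}

test_that("identical scenario and seed give bit-identical results", {
  a <- simulate_scenario(small_scenario())
  b <- simulate_scenario(small_scenario())
  expect_identical(a$power_replicates, b$power_replicates)
  expect_identical(a$r2_replicates, b$r2_replicates)
  c <- simulate_scenario(small_scenario(seed = 100))
  expect_false(identical(a$power_replicates, c$power_replicates))
})

test_that("scenario validation rejects impossible settings", {
  expect_error(small_scenario(sizes = c(10, 800)), ">= 30")
  expect_error(small_scenario(overlap = list(q = 0.005, rho_e = 1),
                              m_causal = 60), "q \\* M >= 1")
  expect_error(small_scenario(overlap = list(q = 0.1, rho_e = 1),
                              m_causal = 200, s_total = 300),
               "distinct causal loci")
})

test_that("drawn effects recover the target cross-study correlation", {
  sc <- small_scenario(m_causal = 5000, s_total = 5000, cgr = 0.5)
  withr::with_seed(7, { eff <- draw_effects(sc) })
  b <- eff$effects[eff$causal[[1]], ]
  got <- cor(b[, 1], b[, 2])
  se <- (1 - 0.5^2) / sqrt(5000)
  expect_lt(abs(got - 0.5), 3 * se)
  # per-study expected genetic variance is the target heritability
  expect_equal(sum(b[, 1]^2), 0.5, tolerance = 5 * sqrt(2 / 5000))
})

test_that("perfect CGR with equal-R2 coupling duplicates effect vectors", {
  sc <- small_scenario(cgr = 1, cgr_holdout = 1, maf = maf_fixed(0.3),
                       maf_effect_coupling = -1)
  withr::with_seed(8, { eff <- draw_effects(sc) })
  expect_equal(eff$effects[, 1], eff$effects[, 2], tolerance = 1e-12)
  expect_equal(eff$effects[, 1], eff$effects[, 3], tolerance = 1e-12)
})

test_that("fixed-magnitude effects have constant size and target sign-coupling", {
  sc <- small_scenario(m_causal = 4000, s_total = 4000, cgr = 0.6,
                       effect_model = "fixed_magnitude",
                       maf_effect_coupling = -1)
  withr::with_seed(9, { eff <- draw_effects(sc) })
  b <- eff$effects[eff$causal[[1]], ]
  expect_equal(abs(b[, 1]), rep(sqrt(0.5 / 4000), 4000), tolerance = 1e-12)
  expect_lt(abs(cor(b[, 1], b[, 2]) - 0.6), 3 / sqrt(4000) * (1 - 0.36) * 2)
})

test_that("overlap scenarios share q*M loci and imply CGR = q * rho_e", {
  sc <- small_scenario(m_causal = 2000, s_total = 8000,
                       overlap = list(q = 0.5, rho_e = 1))
  expect_equal(sc$effective_cgr, 0.5)
  withr::with_seed(10, { eff <- draw_effects(sc) })
  shared <- intersect(eff$causal[[1]], eff$causal[[2]])
  expect_length(shared, 1000)
  expect_length(eff$causal[[1]], 2000)
  # genome-wide correlation across the union of causal loci
  uni <- union(eff$causal[[1]], eff$causal[[2]])
  got <- cor(eff$effects[uni, 1], eff$effects[uni, 2])
  expect_lt(abs(got - 0.5), 3 / sqrt(length(uni)) * 2)
})

test_that("simulated genotypes match their binomial frequencies", {
  G <- simulate_genotypes(1000, rep(0.5, 50), seed = 123)
  expect_true(all(G %in% 0:2))
  se_mean <- sqrt(2 * 0.5 * 0.5 / (1000 * 50))
  expect_lt(abs(mean(G) - 1), 3 * se_mean)
  expect_identical(G, simulate_genotypes(1000, rep(0.5, 50), seed = 123))
})

test_that("a null trait yields standard-normal GWAS Z statistics", {
  z <- unlist(lapply(1:4, function(r) {
    st <- simulate_study(rep(0, 400), n = 2000, freqs = rep(0.3, 400),
                         h2 = 0, seed = 1000 + r)
    st$z
  }))
  expect_lt(abs(mean(z)), 3 / sqrt(length(z)))
  expect_lt(abs(var(z) - 1), 3 * sqrt(2 / length(z)))
})

test_that("realized genetic variance tracks the scenario heritability", {
  sc <- small_scenario(m_causal = 300, s_total = 300)
  gv <- vapply(1:10, function(r) {
    withr::with_seed(r, { eff <- draw_effects(sc) })
    simulate_study(eff$effects[, 1], 800, rep(0.3, 300), h2 = 0.5,
                   seed = 2000 + r)$gen_var
  }, numeric(1))
  expect_lt(abs(mean(gv) - 0.5), 3 * sd(gv) / sqrt(10))
})

test_that("meta-analysis weights renormalize around excluded SNPs", {
  mk <- function(coeff, excluded) list(coeff = coeff, excluded = excluded)
  studies <- list(mk(c(0.1, 0.2, 0.3), c(FALSE, TRUE, TRUE)),
                  mk(c(0.4, 0.5, 0.6), c(FALSE, FALSE, TRUE)))
  meta <- run_gwas_and_meta(studies, sizes = c(100, 300))
  expect_equal(meta$effect[1], (100 * 0.1 + 300 * 0.4) / 400)
  expect_equal(meta$z[1], (100 * 0.1 + 300 * 0.4) / sqrt(400))
  expect_equal(meta$effect[2], 0.5)       # only study 2 contributes
  expect_equal(meta$z[2], sqrt(300) * 0.5)
  expect_true(is.na(meta$z[3]))           # excluded everywhere
  expect_equal(meta$n_effective, c(400, 300, 0))
  # single study: meta Z is the study Z
  one <- run_gwas_and_meta(studies[1], sizes = 100)
  expect_equal(one$z[1], sqrt(100) * 0.1)
})

test_that("causal meta-Z variance matches the two-study closed form", {
  # 2 equal studies, perfect CGR: Var(Z_meta) = 1 + 2 n h2 / M
  sc <- small_scenario(sizes = c(1500, 1500), cgr = 1, cgr_holdout = 1,
                       m_causal = 150, s_total = 300, n_replicates = 12)
  res <- simulate_scenario(sc)
  zz <- unlist(lapply(1:12, function(r) {
    set.seed((99 + 104729 * r) %% 2147483629)
    freqs <- metagwaspower:::draw_freqs(sc)
    eff <- draw_effects(sc, freqs)
    studies <- lapply(1:2, function(cc)
      simulate_study(eff$effects[, cc], 1500, freqs[[cc]], 0.5,
                     seed = (99 + 48271 * r + 8191 * cc) %% 2147483629))
    run_gwas_and_meta(studies, c(1500, 1500))$z[eff$causal[[1]]]
  }))
  expected <- 1 + 2 * 1500 * 0.5 / 150
  expect_lt(abs(var(zz) - expected),
            3 * expected * sqrt(2 / length(zz)) * 1.5)
})

test_that("empirical hold-out R2 matches the closed form at reduced scale", {
  sc <- sim_scenario(sizes = 4000, h2 = 0.5, cgr = 1, cgr_holdout = 0.5,
                     s_total = 500, m_causal = 50, alpha = 5e-4,
                     maf = maf_fixed(0.3), n_replicates = 25, seed = 7)
  res <- simulate_scenario(sc)
  expect_lt(abs(res$empirical_r2 - res$theory_r2),
            3 * res$se_r2 + 0.01)
  expect_lt(abs(res$empirical_power - res$theory_power),
            3 * res$se_power + 0.01)
})

test_that("zero hold-out CGR leaves only sampling-noise R2", {
  sc <- sim_scenario(sizes = 2000, h2 = 0.5, cgr = 1, cgr_holdout = 0,
                     n_holdout = 2000, s_total = 400, m_causal = 50,
                     alpha = 5e-4, maf = maf_fixed(0.3),
                     n_replicates = 10, seed = 31)
  res <- simulate_scenario(sc)
  expect_lt(res$empirical_r2, 0.01)
})

test_that("population-moment standardization is available for oracles", {
  st <- simulate_study(rep(0, 100), n = 500, freqs = rep(0.4, 100),
                       h2 = 0, seed = 5, standardize = "population")
  G <- simulate_genotypes(500, rep(0.4, 100), seed = 5)
  gs <- (G[, 1] - 0.8) / sqrt(2 * 0.4 * 0.6)
  expect_equal(st$coeff[1], sum(gs * st$y) / 500, tolerance = 1e-12)
})

test_that("validation grids warn when replicates cannot reach a target SE", {
  sc <- small_scenario(n_replicates = 3)
  expect_warning(validate_grid(list(sc), target_se = 1e-6),
                 "achieved power SE")
})

test_that("scenario lists round-trip through the JSON specification", {
  spec <- list(list(sizes = c(800, 800), h2 = 0.5, cgr = 0.5,
                    s_total = 300, m_causal = 60, alpha = 5e-4,
                    maf = list(type = "fixed", value = 0.3),
                    n_replicates = 5, seed = 99))
  path <- withr::local_tempfile(fileext = ".json")
  jsonlite::write_json(spec, path, auto_unbox = TRUE, digits = NA)
  got <- read_scenarios_json(path)[[1]]
  ref <- small_scenario()
  expect_equal(got$sizes, ref$sizes)
  expect_equal(got$cgr_target$among, ref$cgr_target$among)
  expect_identical(simulate_scenario(got)$power_replicates,
                   simulate_scenario(ref)$power_replicates)
})
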