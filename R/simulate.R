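#' Allele-frequency models for the simulator
#'
#' `maf_fixed()` gives every SNP the same allele frequency in every study.
#' `maf_uniform()` draws each SNP's frequency from `Uniform(lo, hi)`; with
#' `per_study = TRUE` frequencies are redrawn independently for every study
#' (and the hold-out sample), emulating allele-frequency differences across
#' studies.
#'
#' @param value,lo,hi allele frequencies in `(0, 0.5]`.
#' @param per_study redraw frequencies per study?
#' @return A list describing the frequency model.
#' @export
maf_fixed <- function(value = 0.5) {
  stopifnot(value > 0, value <= 0.5)
  list(type = "fixed", value = value, per_study = FALSE)
}

#' @rdname maf_fixed
#' @export
maf_uniform <- function(lo = 0.05, hi = 0.5, per_study = FALSE) {
  stopifnot(lo > 0, hi <= 0.5, lo < hi)
  list(type = "uniform", lo = lo, hi = hi, per_study = isTRUE(per_study))
}

#' Simulation scenario for the multi-study random-effects world
#'
#' Describes one generative setting: integer per-study sample sizes, a
#' hold-out sample, SNP heritabilities, the target cross-study correlation
#' of causal effects, the SNP architecture, the allele-frequency model, the
#' coupling between allele frequency and effect size, and (optionally) a
#' causal-locus overlap structure in which the genome-wide CGR emerges from
#' partial sharing of causal loci.
#'
#' @param sizes integer per-study sample sizes (each >= 30).
#' @param h2 per-study SNP heritability (scalar recycled, or length-C).
#' @param cgr constant CGR among discovery studies, or a full
#'   [cgr_structure()] (its `to_holdout`/`holdout_h2` are then used).
#' @param cgr_holdout correlation of each study's effects with the hold-out
#'   effects (scalar; default `cgr`). Ignored when `cgr` is a structure.
#' @param h2_holdout hold-out SNP heritability (default mean of `h2`).
#' @param n_holdout hold-out sample size (default: first study size).
#' @param s_total,m_causal,alpha architecture of independent SNPs; `alpha`
#'   defaults to the relaxed `5e-4` used for simulation-based validation,
#'   where empirical power at `5e-8` would need enormous samples (the
#'   closed forms are statements about the Z variance, valid at any alpha).
#' @param maf allele-frequency model, from [maf_fixed()] or
#'   [maf_uniform()].
#' @param maf_effect_coupling exponent `s`: causal-effect variance on raw
#'   genotypes proportional to `[2f(1-f)]^s`, so the variance on
#'   standardized genotypes is proportional to `[2f(1-f)]^(s+1)` and
#'   renormalized to the study's h2. `s = -1` gives the equal-R2 assumption
#'   on standardized SNPs; `s = 0` gives equal raw-effect variance (a
#'   violation of equal-R2).
#' @param overlap `NULL`, or `list(q =, rho_e =)`: each study (and the
#'   hold-out) is causal at a shared core of `round(q * m_causal)` loci,
#'   whose effects correlate `rho_e` across studies, plus its own private
#'   loci (independent effects) up to `m_causal` in total. The implied
#'   genome-wide effective CGR is `q * rho_e`.
#' @param effect_model `"gaussian"` (the random-effects model) or
#'   `"fixed_magnitude"` (strict equal-R2: every causal effect has fixed
#'   magnitude and random sign, signs coupled across studies through a
#'   latent Gaussian with correlation `sin(pi * rho / 2)` so the sign
#'   correlation hits the target CGR).
#' @param standardize `"sample"` (within-study sample moments, as in GWAS
#'   practice) or `"population"` (theoretical moments `2f`,
#'   `sqrt(2f(1-f))`; useful for oracle checks).
#' @param n_replicates number of Monte-Carlo replicates.
#' @param seed integer master seed; all replicate/study substreams are
#'   derived from it by fixed offsets.
#' @param label optional scenario name.
#' @return An object of class `sim_scenario`.
#' @export
sim_scenario <- function(sizes, h2, cgr, cgr_holdout = NULL,
                         h2_holdout = NULL, n_holdout = NULL,
                         s_total, m_causal, alpha = 5e-4,
                         maf = maf_uniform(), maf_effect_coupling = -1,
                         overlap = NULL,
                         effect_model = c("gaussian", "fixed_magnitude"),
                         standardize = c("sample", "population"),
                         n_replicates = 200, seed = 1, label = NULL) {
  effect_model <- match.arg(effect_model)
  standardize <- match.arg(standardize)
  if (any(sizes != round(sizes)) || any(sizes < 30))
    stop("simulator sizes must be integers >= 30", call. = FALSE)
  sizes <- as.integer(sizes)
  C <- length(sizes)
  h2 <- rep_len(h2, C)
  if (is.null(h2_holdout)) h2_holdout <- mean(h2)
  if (is.null(n_holdout)) n_holdout <- sizes[1]
  if (inherits(cgr, "cgr_structure")) {
    cgr_target <- cgr
    if (cgr_target$n_studies != C)
      stop("cgr structure does not match number of studies", call. = FALSE)
    cgr_target$holdout_h2 <- h2_holdout
  } else {
    if (is.null(cgr_holdout)) cgr_holdout <- cgr
    cgr_target <- cgr_structure(cgr, cgr_holdout, h2_holdout, n_studies = C)
  }
  arch <- architecture(s_total, m_causal, alpha)
  effective_cgr <- NULL
  if (!is.null(overlap)) {
    if (!is.list(overlap) || is.null(overlap$q) || is.null(overlap$rho_e))
      stop("`overlap` must be list(q =, rho_e =)", call. = FALSE)
    q <- overlap$q
    if (q <= 0 || q > 1) stop("overlap fraction q must be in (0, 1]",
                              call. = FALSE)
    core_m <- round(q * m_causal)
    if (core_m < 1)
      stop("overlap requires q * M >= 1 shared causal loci", call. = FALSE)
    priv_m <- m_causal - core_m
    if (core_m + (C + 1) * priv_m > s_total)
      stop("overlap structure needs ", core_m + (C + 1) * priv_m,
           " distinct causal loci but only S = ", s_total, " SNPs",
           call. = FALSE)
    # genome-wide CGR implied by partial causal overlap
    effective_cgr <- q * overlap$rho_e
  }
  structure(
    list(sizes = sizes, h2 = h2, h2_holdout = h2_holdout,
         n_holdout = as.integer(n_holdout), cgr_target = cgr_target,
         arch = arch, maf = maf,
         maf_effect_coupling = maf_effect_coupling, overlap = overlap,
         effective_cgr = effective_cgr, effect_model = effect_model,
         standardize = standardize, n_replicates = as.integer(n_replicates),
         seed = as.integer(seed),
         label = if (is.null(label)) "scenario" else label),
    class = "sim_scenario")
}

#' @export
print.sim_scenario <- function(x, ...) {
  cat("Simulation scenario '", x$label, "': C = ", length(x$sizes),
      ", n = ", paste(unique(x$sizes), collapse = "/"),
      ", S = ", x$arch$s_total, ", M = ", x$arch$m_causal,
      ", h2 = ", paste(unique(x$h2), collapse = "/"), "\n", sep = "")
  if (!is.null(x$overlap))
    cat("  causal overlap q =", x$overlap$q, ", effect corr =",
        x$overlap$rho_e, "-> effective CGR", x$effective_cgr, "\n")
  cat("  effects:", x$effect_model, " MAF coupling s =",
      x$maf_effect_coupling, " replicates:", x$n_replicates,
      " seed:", x$seed, "\n")
  invisible(x)
}

draw_freqs <- function(scenario) {
  S <- scenario$arch$s_total
  n_samples <- length(scenario$sizes) + 1L
  maf <- scenario$maf
  if (maf$type == "fixed") {
    rep(list(rep(maf$value, S)), n_samples)
  } else if (maf$per_study) {
    lapply(seq_len(n_samples), function(j) runif(S, maf$lo, maf$hi))
  } else {
    rep(list(runif(S, maf$lo, maf$hi)), n_samples)
  }
}

# correlated standard-normal draws tolerant of singular correlation
# matrices (e.g. all correlations 1)
corr_normals <- function(m, R) {
  if (all(R == 1))  # perfect correlation: exactly identical draws
    return(matrix(rnorm(m), m, ncol(R)))
  e <- eigen(R, symmetric = TRUE)
  lam <- pmax(e$values, 0)
  A <- e$vectors %*% diag(sqrt(lam), nrow = length(lam))
  matrix(rnorm(m * ncol(R)), m) %*% t(A)
}

#' Draw correlated causal-SNP effects
#'
#' Standardized-scale causal effects for the `C` discovery studies and the
#' hold-out sample (columns; hold-out last), jointly Gaussian across
#' studies with the scenario's target correlation structure. Per-SNP
#' variance follows the MAF-effect coupling and is renormalized so each
#' study's effects sum to its SNP heritability. Under an overlap scenario,
#' all studies share a causal core whose effects correlate `rho_e`, and
#' each study has its own private causal loci with independent effects.
#'
#' Uses R's RNG; seed with `set.seed()` for reproducibility (the scenario
#' driver [simulate_scenario()] does this per replicate).
#'
#' @param scenario a [sim_scenario()].
#' @param freqs list of `C + 1` per-sample allele-frequency vectors
#'   (hold-out last); defaults to a draw from the scenario's MAF model.
#' @return List with `effects` (an `S x (C+1)` matrix, zero at non-causal
#'   indices), `causal` (list of causal index vectors per sample) and
#'   `core` (shared causal indices; all of them when there is no overlap).
#' @export
draw_effects <- function(scenario, freqs = draw_freqs(scenario)) {
  S <- scenario$arch$s_total
  M <- scenario$arch$m_causal
  C <- length(scenario$sizes)
  h2_all <- c(scenario$h2, scenario$h2_holdout)
  s_exp <- scenario$maf_effect_coupling + 1
  eff <- matrix(0, S, C + 1L)
  scale_effects <- function(z, idx, j) {
    u <- (2 * freqs[[j]][idx] * (1 - freqs[[j]][idx]))^s_exp
    z * sqrt(h2_all[j] * u / sum(u))
  }
  draw_block <- function(m, R) {
    if (scenario$effect_model == "gaussian") {
      corr_normals(m, R)
    } else {
      # fixed magnitude, sign-coupled: sign corr (2/pi) asin(rho_lat)
      R_lat <- sin(pi / 2 * R)
      diag(R_lat) <- 1
      sign(corr_normals(m, R_lat))
    }
  }
  if (is.null(scenario$overlap)) {
    causal <- sort(sample.int(S, M))
    z <- draw_block(M, full_cgr_matrix(scenario$cgr_target))
    for (j in seq_len(C + 1L))
      eff[causal, j] <- scale_effects(z[, j], causal, j)
    list(effects = eff, causal = rep(list(causal), C + 1L), core = causal)
  } else {
    core_m <- round(scenario$overlap$q * M)
    priv_m <- M - core_m
    picks <- sample.int(S, core_m + (C + 1L) * priv_m)
    core <- sort(picks[seq_len(core_m)])
    R_core <- constant_corr(C + 1L, scenario$overlap$rho_e)
    z_core <- draw_block(core_m, R_core)
    causal <- vector("list", C + 1L)
    for (j in seq_len(C + 1L)) {
      priv <- if (priv_m > 0)
        sort(picks[core_m + (j - 1L) * priv_m + seq_len(priv_m)])
      else integer(0)
      idx <- c(core, priv)
      z <- c(z_core[, j],
             if (scenario$effect_model == "gaussian") rnorm(priv_m)
             else sign(rnorm(priv_m)))
      eff[idx, j] <- scale_effects(z, idx, j)
      causal[[j]] <- sort(idx)
    }
    list(effects = eff, causal = causal, core = core)
  }
}

#' Simulate one study's GWAS
#'
#' Draws `n` individuals with independent 0/1/2 genotypes at the scenario
#' frequencies, standardizes genotypes (by default with within-study sample
#' moments), forms the phenotype as the standardized-genotype effects plus
#' Gaussian noise of variance `1 - h2`, standardizes the phenotype, and
#' regresses it on each SNP: the per-SNP coefficient is the sample
#' correlation and `z = sqrt(n) * coeff`. Monomorphic simulated SNPs are
#' flagged in `excluded` and dropped from that study's GWAS.
#'
#' @param effects length-S vector of standardized-scale effects (zeros at
#'   non-causal SNPs).
#' @param n sample size (integer >= 30).
#' @param freqs length-S allele-frequency vector.
#' @param h2 SNP heritability of this study (noise variance `1 - h2`).
#' @param seed integer substream seed.
#' @param weights optional length-S PGS weights; when given, the sample's
#'   polygenic score is accumulated and returned.
#' @param standardize `"sample"` or `"population"` moments.
#' @return List with `coeff`, `z`, `excluded`, `y` (standardized
#'   phenotype), `gen_var` (realized variance of the genetic component),
#'   `n`, and `pgs` when `weights` was supplied.
#' @export
simulate_study <- function(effects, n, freqs, h2, seed, weights = NULL,
                           standardize = c("sample", "population")) {
  standardize <- match.arg(standardize)
  if (n < 30) stop("simulated studies need n >= 30", call. = FALSE)
  res <- sim_study_core(as.integer(n), freqs, effects,
                        env_sd = sqrt(1 - h2), seed = seed,
                        sample_moments = standardize == "sample",
                        pgs_weights = weights)
  res$z <- sqrt(n) * res$coeff
  res$n <- as.integer(n)
  res
}

#' Simulate a raw genotype matrix
#'
#' Allele counts 0/1/2 from the same per-column random streams used by
#' [simulate_study()]; intended for small designs, tests and oracle checks.
#'
#' @param n number of individuals.
#' @param freqs allele-frequency vector (one per SNP).
#' @param seed integer substream seed.
#' @return An `n x S` integer matrix.
#' @export
simulate_genotypes <- function(n, freqs, seed) {
  sim_genotypes_core(as.integer(n), freqs, seed)
}

#' Fixed-effects meta-analysis of simulated per-study GWAS
#'
#' Combines per-study per-SNP sample correlations with the sample-size
#' weights of the closed-form framework: meta Z uses
#' \eqn{w_c = \sqrt{N_c / N_T}} on study Z scores, the meta effect uses
#' \eqn{w_c = N_c / N_T} on coefficients. SNPs excluded in some studies are
#' meta-analyzed over the remaining studies with renormalized weights; a
#' SNP excluded everywhere gets `NA`.
#'
#' @param studies list of [simulate_study()] results (discovery studies).
#' @param sizes integer vector of the study sample sizes.
#' @return List with `z` (meta Z per SNP), `effect` (meta effect estimate
#'   per SNP) and `n_effective` (total N contributing per SNP).
#' @export
run_gwas_and_meta <- function(studies, sizes) {
  stopifnot(length(studies) >= 1, length(studies) == length(sizes))
  A <- vapply(studies, `[[`, numeric(length(studies[[1]]$coeff)), "coeff")
  A <- matrix(A, ncol = length(studies))
  Ex <- vapply(studies, `[[`, logical(nrow(A)), "excluded")
  Ex <- matrix(Ex, ncol = length(studies))
  A[Ex] <- 0
  num <- drop(A %*% sizes)
  denom <- drop((!Ex) %*% sizes)
  z <- ifelse(denom > 0, num / sqrt(denom), NA_real_)
  eff <- ifelse(denom > 0, num / denom, NA_real_)
  list(z = z, effect = eff, n_effective = denom)
}

#' Empirical hold-out PGS R-squared
#'
#' Squared Pearson correlation between the hold-out phenotype and the
#' polygenic score built from meta-analysis effect estimates over all S
#' SNPs (no SNP selection; unestimated SNPs contribute zero weight).
#'
#' @param holdout a [simulate_study()] result produced with
#'   `weights = ` the meta effect estimates.
#' @return The squared correlation.
#' @export
holdout_pgs_r2 <- function(holdout) {
  if (is.null(holdout$pgs))
    stop("hold-out study was simulated without PGS weights", call. = FALSE)
  if (var(holdout$pgs) <= 0)
    stop("degenerate polygenic score: zero variance", call. = FALSE)
  cor(holdout$pgs, holdout$y)^2
}

#' Run a simulation scenario and compare with the closed forms
#'
#' For each replicate: draw allele frequencies and correlated causal
#' effects, simulate each discovery study's GWAS, meta-analyze, measure the
#' fraction of causal SNPs passing the significance threshold, simulate
#' the hold-out sample and measure the PGS R-squared. Causal SNPs are the
#' union of the discovery studies' causal loci (identical across studies
#' unless an overlap scenario is active). The matched closed-form values
#' use the scenario's target CGR -- the effective genome-wide CGR
#' `q * rho_e` under overlap.
#'
#' Randomness is fully determined by `scenario$seed`: replicate and study
#' substreams are derived by fixed integer offsets, so results are
#' reproducible and adding scenarios to a grid never perturbs existing
#' ones.
#'
#' @param scenario a [sim_scenario()].
#' @return An object of class `sim_result`: empirical and theoretical
#'   power and R-squared with Monte-Carlo standard errors, per-replicate
#'   vectors, and the scenario.
#' @export
simulate_scenario <- function(scenario) {
  C <- length(scenario$sizes)
  arch <- scenario$arch
  cgr_eff <- if (!is.null(scenario$overlap)) {
    cgr_structure(scenario$effective_cgr, scenario$effective_cgr,
                  scenario$h2_holdout, n_studies = C)
  } else scenario$cgr_target
  panel <- study_panel(scenario$sizes, scenario$h2)
  theory_power <- power_per_causal_snp(meta_z_variance(panel, cgr_eff, arch),
                                       arch$alpha)
  theory_r2 <- pgs_r2(panel, cgr_eff, arch)$r2
  R <- scenario$n_replicates
  pow <- numeric(R)
  r2 <- numeric(R)
  base <- as.numeric(scenario$seed)
  for (r in seq_len(R)) {
    set.seed((base + 104729 * r) %% 2147483629)
    freqs <- draw_freqs(scenario)
    eff <- draw_effects(scenario, freqs)
    studies <- lapply(seq_len(C), function(cc)
      simulate_study(eff$effects[, cc], scenario$sizes[cc], freqs[[cc]],
                     scenario$h2[cc],
                     seed = (base + 48271 * r + 8191 * cc) %% 2147483629,
                     standardize = scenario$standardize))
    meta <- run_gwas_and_meta(studies, scenario$sizes)
    causal <- sort(unique(unlist(eff$causal[seq_len(C)])))
    pow[r] <- mean(abs(meta$z[causal]) > arch$threshold, na.rm = TRUE)
    w <- ifelse(is.na(meta$effect), 0, meta$effect)
    holdout <- simulate_study(eff$effects[, C + 1L], scenario$n_holdout,
                              freqs[[C + 1L]], scenario$h2_holdout,
                              seed = (base + 48271 * r +
                                        8191 * (C + 1L)) %% 2147483629,
                              weights = w,
                              standardize = scenario$standardize)
    r2[r] <- holdout_pgs_r2(holdout)
  }
  structure(
    list(empirical_power = mean(pow),
         se_power = sd(pow) / sqrt(R),
         empirical_r2 = mean(r2),
         se_r2 = sd(r2) / sqrt(R),
         theory_power = theory_power,
         theory_r2 = theory_r2,
         power_replicates = pow, r2_replicates = r2,
         scenario = scenario),
    class = "sim_result")
}

#' @export
print.sim_result <- function(x, ...) {
  cat("Simulation result '", x$scenario$label, "' (",
      x$scenario$n_replicates, " replicates)\n", sep = "")
  cat(sprintf("  power: empirical %.4f (SE %.4f)  theory %.4f\n",
              x$empirical_power, x$se_power, x$theory_power))
  cat(sprintf("  R2:    empirical %.4f (SE %.4f)  theory %.4f\n",
              x$empirical_r2, x$se_r2, x$theory_r2))
  invisible(x)
}
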