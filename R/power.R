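#' Variance of the meta-analysis Z statistic at a causal SNP
#'
#' Under the multi-study random-effects model, the fixed-effects
#' (sample-size-weighted) meta-analysis Z statistic of a causal SNP is
#' normally distributed with mean zero and variance
#' \deqn{\sigma^2 = 1 + \frac{1}{M N_T} \sum_{c} \sum_{d}
#'       N_c N_d \rho_{cd} \sqrt{h^2_c h^2_d},}
#' with \eqn{\rho_{cc} = 1}. This is the variance of
#' \eqn{\sum_c \sqrt{N_c / N_T}\, Z_c} where the study-level statistics have
#' \eqn{\mathrm{Var}(Z_c) = 1 + N_c h^2_c / M} and
#' \eqn{\mathrm{Cov}(Z_c, Z_d) = \sqrt{N_c N_d}\, \rho_{cd}
#' \sqrt{h^2_c h^2_d} / M}. For a single study it reduces to
#' \eqn{1 + N h^2 / M}; for two equal studies with common heritability it
#' reduces to \eqn{1 + (h^2/M) N (1 + \rho)}.
#'
#' @param panel a [study_panel()].
#' @param cgr a [cgr_structure()] with as many studies as `panel`.
#' @param arch an [architecture()]; only `m_causal` enters the variance.
#' @return The scalar variance \eqn{\sigma^2 \ge 1}.
#' @examples
#' d <- equal_design(250000, 1, h2 = 0.5, cgr_among = 1)
#' meta_z_variance(d$panel, d$cgr, architecture(1e5, 1000))  # 1 + N h2 / M
#' @export
meta_z_variance <- function(panel, cgr, arch) {
  check_panel_cgr(panel, cgr)
  if (!inherits(arch, "architecture"))
    stop("`arch` must be an architecture", call. = FALSE)
  if (panel$n_studies == 1L)  # exact single-study reduction
    return(1 + panel$sizes * panel$heritabilities / arch$m_causal)
  a <- panel$sizes * sqrt(panel$heritabilities)
  quad <- drop(crossprod(a, cgr$among %*% a))
  1 + quad / (arch$m_causal * panel$n_total)
}

#' Power per causal SNP
#'
#' Probability that a causal SNP's meta-analysis Z statistic exceeds the
#' two-sided significance threshold: \eqn{\beta = 2\Phi(-t/\sigma)} with
#' \eqn{t = \Phi^{-1}(1 - \alpha/2)} and \eqn{\sigma^2} from
#' [meta_z_variance()]. Under jointly Gaussian random effects the marginal
#' distribution of Z is exactly normal, so no integration over the effect
#' distribution is needed.
#'
#' @param sigma2 variance of the meta-analysis Z statistic at a causal SNP
#'   (must be >= 1).
#' @param alpha two-sided significance level in `(0, 1)`.
#' @return The power \eqn{\beta \in [\alpha, 1]}.
#' @examples
#' power_per_causal_snp(1, 5e-8)    # equals alpha: null distribution
#' power_per_causal_snp(126, 5e-8)  # ~0.63: one study of 250k, h2=0.5, M=1000
#' @export
power_per_causal_snp <- function(sigma2, alpha = 5e-8) {
  if (!is.numeric(sigma2) || any(sigma2 < 1))
    stop("`sigma2` must be >= 1 (it includes the unit sampling variance)",
         call. = FALSE)
  if (!is.numeric(alpha) || length(alpha) != 1L || alpha <= 0 || alpha >= 1)
    stop("`alpha` must lie strictly between 0 and 1", call. = FALSE)
  thr <- qnorm(alpha / 2, lower.tail = FALSE)
  2 * pnorm(-thr / sqrt(sigma2))
}

#' Expected discovery counts and detection probabilities
#'
#' Given the power per causal SNP, reports the expected numbers of hits,
#' true positives, false positives, false negatives and true negatives among
#' the `S` independent SNPs, and the probabilities of at least one true
#' positive and at least one hit:
#' \deqn{E[\#hits] = \beta M + \alpha (S - M), \quad
#'       P[\#hits \ge 1] = 1 - (1-\beta)^M (1-\alpha)^{S-M}.}
#' The products \eqn{(1-\beta)^M} and \eqn{(1-\alpha)^{S-M}} are accumulated
#' in log space (`log1p`/`expm1`) so the probabilities survive `M` up to
#' `1e6` and `beta` down to `1e-300` without underflow.
#'
#' @param beta power per causal SNP, in `[0, 1]`.
#' @param arch an [architecture()].
#' @param z_variance optionally, the Z variance that produced `beta`; stored
#'   in the report.
#' @return An object of class `power_report`: a list with fields
#'   `z_variance`, `beta`, `expected_hits`, `expected_true_pos`,
#'   `expected_false_pos`, `expected_false_neg`, `expected_true_neg`,
#'   `p_any_true_pos`, `p_any_hit`.
#' @examples
#' detection_report(0.5, architecture(100, 100))  # no null SNPs
#' @export
detection_report <- function(beta, arch, z_variance = NA_real_) {
  if (!inherits(arch, "architecture"))
    stop("`arch` must be an architecture", call. = FALSE)
  if (!is.numeric(beta) || length(beta) != 1L || beta < 0 || beta > 1)
    stop("`beta` must be a probability", call. = FALSE)
  M <- arch$m_causal
  S <- arch$s_total
  alpha <- arch$alpha
  e_tp <- beta * M
  e_fp <- alpha * (S - M)
  structure(
    list(z_variance = z_variance,
         beta = beta,
         expected_hits = e_tp + e_fp,
         expected_true_pos = e_tp,
         expected_false_pos = e_fp,
         expected_false_neg = (1 - beta) * M,
         expected_true_neg = (1 - alpha) * (S - M),
         p_any_true_pos = -expm1(M * log1p(-beta)),
         p_any_hit = -expm1(M * log1p(-beta) + (S - M) * log1p(-alpha))),
    class = "power_report")
}

#' @export
print.power_report <- function(x, ...) {
  cat("GWAS meta-analysis power report\n")
  if (is.finite(x$z_variance))
    cat("  Var(Z) at causal SNP:  ", signif(x$z_variance, 6), "\n")
  cat("  power per causal SNP:  ", signif(x$beta, 4), "\n")
  cat("  E[# hits]:             ", round(x$expected_hits, 2), "\n")
  cat("  E[# true positives]:   ", round(x$expected_true_pos, 2), "\n")
  cat("  E[# false positives]:  ", round(x$expected_false_pos, 2), "\n")
  cat("  E[# false negatives]:  ", round(x$expected_false_neg, 2), "\n")
  cat("  E[# true negatives]:   ", round(x$expected_true_neg, 2), "\n")
  cat("  P[>=1 true positive]:  ", signif(x$p_any_true_pos, 4), "\n")
  cat("  P[>=1 hit]:            ", signif(x$p_any_hit, 4), "\n")
  invisible(x)
}

#' Full power report for a study design
#'
#' Convenience wrapper chaining [meta_z_variance()],
#' [power_per_causal_snp()] and [detection_report()].
#'
#' @inheritParams meta_z_variance
#' @return A `power_report`; see [detection_report()].
#' @examples
#' d <- equal_design(253288, 79, h2 = 0.449, cgr_among = 0.965)
#' power_report(d$panel, d$cgr, architecture(250000, 20000))
#' @export
power_report <- function(panel, cgr, arch) {
  s2 <- meta_z_variance(panel, cgr, arch)
  detection_report(power_per_causal_snp(s2, arch$alpha), arch,
                   z_variance = s2)
}
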