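#' Theoretical hold-out polygenic-score R-squared
#'
#' R-squared between the phenotype of a hold-out sample and a polygenic
#' score (PGS) built over all `S` SNPs with effect-size meta-analysis
#' weights \eqn{w_c = N_c / N_T}. With standardized phenotype and genotypes,
#' \deqn{\mathrm{Cov}(\hat S, y) = \sum_c \frac{N_c}{N_T} \rho_{ch}
#'       \sqrt{h^2_c h^2_h}, \qquad
#'       \mathrm{Var}(\hat S) = \frac{S}{N_T} + \frac{1}{N_T^2}
#'       \sum_c \sum_d N_c N_d \rho_{cd} \sqrt{h^2_c h^2_d},}
#' and \eqn{R^2 = \mathrm{Cov}^2 / \mathrm{Var}(\hat S)}. For a single
#' discovery study with \eqn{h^2_c = h^2_h = h^2} and CGR \eqn{\rho} this
#' reduces to \eqn{R^2 = \rho^2 h^4 / (S/N + h^2)}; as \eqn{N_T \to \infty}
#' it approaches \eqn{\rho^2 h^2}, so the full hold-out heritability cannot
#' be captured while the CGR is imperfect.
#'
#' @inheritParams meta_z_variance
#' @return An object of class `pgs_report`: list with `r2`, `pgs_variance`
#'   (\eqn{\mathrm{Var}(\hat S)}) and `pgs_pheno_cov`
#'   (\eqn{\mathrm{Cov}(\hat S, y)}).
#' @examples
#' d <- equal_design(250000, 1, h2 = 0.5, cgr_among = 1, cgr_holdout = 0.5)
#' pgs_r2(d$panel, d$cgr, architecture(1e5, 1000))  # R2 ~ 6.9%
#' @export
pgs_r2 <- function(panel, cgr, arch) {
  check_panel_cgr(panel, cgr)
  if (!inherits(arch, "architecture"))
    stop("`arch` must be an architecture", call. = FALSE)
  NT <- panel$n_total
  a <- panel$sizes * sqrt(panel$heritabilities)
  cov_sy <- sum(panel$sizes / NT * cgr$to_holdout *
                  sqrt(panel$heritabilities * cgr$holdout_h2))
  var_s <- arch$s_total / NT + drop(crossprod(a, cgr$among %*% a)) / NT^2
  structure(
    list(r2 = cov_sy^2 / var_s,
         pgs_variance = var_s,
         pgs_pheno_cov = cov_sy),
    class = "pgs_report")
}

#' @export
print.pgs_report <- function(x, ...) {
  cat("Hold-out polygenic score report\n")
  cat("  R2:          ", sprintf("%.1f%%", 100 * x$r2),
      paste0("(", signif(x$r2, 6), ")"), "\n")
  cat("  Var(PGS):    ", signif(x$pgs_variance, 6), "\n")
  cat("  Cov(PGS, y): ", signif(x$pgs_pheno_cov, 6), "\n")
  invisible(x)
}
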