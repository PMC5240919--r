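#' Discovery-study panel
#'
#' Describes the `C` discovery studies entering a fixed-effects GWAS
#' meta-analysis: per-study sample sizes \eqn{N_c} and per-study SNP
#' heritabilities \eqn{h^2_c}.
#'
#' Sizes may be fractional: equal designs built by [equal_design()] keep the
#' exact per-study size \eqn{N_T/C} unrounded, because rounding to integers
#' perturbs expected hit counts in the second decimal for published designs.
#' The simulator, which draws actual individuals, requires integer sizes.
#'
#' @param sizes numeric vector of per-study sample sizes (each >= 1).
#' @param heritabilities numeric vector of per-study SNP heritabilities,
#'   each in `[0, 1]`, same length as `sizes`.
#' @return An object of class `study_panel`: a list with elements `sizes`,
#'   `heritabilities`, `n_total` (sum of sizes) and `n_studies`.
#' @examples
#' study_panel(sizes = c(10000, 20000), heritabilities = c(0.5, 0.4))
#' @seealso [cgr_structure()], [architecture()], [equal_design()]
#' @export
study_panel <- function(sizes, heritabilities) {
  if (!is.numeric(sizes) || length(sizes) < 1L)
    stop("`sizes` must be a numeric vector with at least one study", call. = FALSE)
  if (!is.numeric(heritabilities) || length(heritabilities) != length(sizes))
    stop("`heritabilities` must match `sizes` in length (one h2 per study)",
         call. = FALSE)
  if (any(!is.finite(sizes)) || any(sizes < 1))
    stop("every per-study sample size must be finite and >= 1", call. = FALSE)
  if (any(!is.finite(heritabilities)) ||
      any(heritabilities < 0) || any(heritabilities > 1))
    stop("every per-study SNP heritability must lie in [0, 1]", call. = FALSE)
  structure(
    list(sizes = as.numeric(sizes),
         heritabilities = as.numeric(heritabilities),
         n_total = sum(as.numeric(sizes)),
         n_studies = length(sizes)),
    class = "study_panel")
}

#' @export
print.study_panel <- function(x, ...) {
  cat("Study panel:", x$n_studies, "studies, total N =",
      format(x$n_total, big.mark = ","), "\n")
  cat("  sizes:", paste(signif(x$sizes, 6), collapse = ", "), "\n")
  cat("  h2:   ", paste(signif(x$heritabilities, 4), collapse = ", "), "\n")
  invisible(x)
}

#' Cross-study genetic-correlation structure
#'
#' Correlations of causal-SNP effects between every pair of discovery studies
#' (`among`, a `C x C` matrix with unit diagonal) and between each discovery
#' study and the hold-out sample in which the polygenic score is evaluated
#' (`to_holdout`, length `C`), together with the hold-out SNP heritability.
#'
#' The full bordered `(C+1) x (C+1)` matrix (discovery block bordered by the
#' hold-out row/column) must be a valid correlation matrix; positive
#' semidefiniteness is checked with tolerance `1e-8` on the smallest
#' eigenvalue and violations are reported with that eigenvalue.
#'
#' @param among `C x C` symmetric matrix of cross-study effect correlations
#'   with diagonal exactly 1, or a single scalar used as the constant
#'   off-diagonal correlation (requires `n_studies`).
#' @param to_holdout numeric vector (length `C`, recycled from a scalar) of
#'   correlations between each study and the hold-out sample.
#' @param holdout_h2 SNP heritability of the hold-out sample, in `[0, 1]`.
#' @param n_studies required when `among` is given as a scalar.
#' @return An object of class `cgr_structure` with elements `among`,
#'   `to_holdout`, `holdout_h2`, `n_studies`.
#' @examples
#' cgr_structure(among = 0.9, to_holdout = 0.8, holdout_h2 = 0.5, n_studies = 3)
#' @export
cgr_structure <- function(among, to_holdout, holdout_h2, n_studies = NULL) {
  if (is.matrix(among)) {
    C <- nrow(among)
  } else if (length(among) == 1L) {
    if (is.null(n_studies))
      stop("`n_studies` is required when `among` is a scalar correlation",
           call. = FALSE)
    C <- as.integer(n_studies)
    among <- constant_corr(C, among)
  } else {
    stop("`among` must be a C x C matrix or a single scalar", call. = FALSE)
  }
  if (nrow(among) != ncol(among))
    stop("`among` must be square", call. = FALSE)
  if (length(to_holdout) == 1L) to_holdout <- rep(as.numeric(to_holdout), C)
  if (length(to_holdout) != C)
    stop("`to_holdout` must have one entry per study (length ", C, ")",
         call. = FALSE)
  if (!isTRUE(all.equal(among, t(among), tolerance = 1e-12)))
    stop("`among` must be symmetric", call. = FALSE)
  if (any(abs(diag(among) - 1) > 1e-12))
    stop("`among` must have unit diagonal", call. = FALSE)
  if (any(abs(among) > 1 + 1e-12) || any(abs(to_holdout) > 1 + 1e-12))
    stop("all correlations must lie in [-1, 1]", call. = FALSE)
  if (!is.numeric(holdout_h2) || length(holdout_h2) != 1L ||
      holdout_h2 < 0 || holdout_h2 > 1)
    stop("`holdout_h2` must be a single value in [0, 1]", call. = FALSE)
  obj <- structure(
    list(among = unname(among), to_holdout = as.numeric(to_holdout),
         holdout_h2 = as.numeric(holdout_h2), n_studies = C),
    class = "cgr_structure")
  lambda_min <- min(eigen(full_cgr_matrix(obj), symmetric = TRUE,
                          only.values = TRUE)$values)
  if (lambda_min < -1e-8)
    stop("bordered correlation matrix is not positive semidefinite ",
         "(smallest eigenvalue ", format(lambda_min), ")", call. = FALSE)
  obj
}

#' @export
print.cgr_structure <- function(x, ...) {
  cat("CGR structure for", x$n_studies, "studies + hold-out\n")
  off <- x$among[upper.tri(x$among)]
  if (length(off) == 0) {
    cat("  among: (single study)\n")
  } else if (diff(range(off)) < 1e-12) {
    cat("  among: constant", signif(off[1], 4), "\n")
  } else {
    cat("  among: matrix, off-diagonal range [",
        signif(min(off), 4), ",", signif(max(off), 4), "]\n")
  }
  cat("  to hold-out:", paste(signif(unique(x$to_holdout), 4), collapse = ", "),
      " hold-out h2:", signif(x$holdout_h2, 4), "\n")
  invisible(x)
}

#' Full bordered correlation matrix
#'
#' The `(C+1) x (C+1)` correlation matrix formed by the among-study block
#' bordered with the hold-out row and a unit diagonal entry.
#'
#' @param cgr a [cgr_structure()].
#' @return A `(C+1) x (C+1)` numeric matrix; the hold-out sample is last.
#' @export
full_cgr_matrix <- function(cgr) {
  rbind(cbind(cgr$among, cgr$to_holdout), c(cgr$to_holdout, 1))
}

constant_corr <- function(C, rho) {
  m <- matrix(as.numeric(rho), C, C)
  diag(m) <- 1
  m
}

#' Genetic architecture of independent SNPs
#'
#' The genome is abstracted as `s_total` independent haplotype blocks, each
#' tagged by exactly one SNP; `m_causal` of these tag blocks with a causal
#' influence on the phenotype, and jointly account for the full SNP
#' heritability with equal theoretical R-squared per causal SNP.
#'
#' @param s_total effective number of independent SNPs `S` (positive).
#' @param m_causal number of causal (trait-associated) SNPs `M`,
#'   `1 <= M <= S`.
#' @param alpha two-sided genome-wide significance level, in `(0, 1)`.
#'   Default `5e-8`.
#' @return An object of class `architecture` with elements `s_total`,
#'   `m_causal`, `alpha` and the two-sided threshold `threshold`
#'   \eqn{t = \Phi^{-1}(1 - \alpha/2)}.
#' @examples
#' architecture(s_total = 250000, m_causal = 20000)
#' @export
architecture <- function(s_total, m_causal, alpha = 5e-8) {
  if (!is.numeric(s_total) || length(s_total) != 1L || s_total < 1)
    stop("`s_total` must be a single positive number of SNPs", call. = FALSE)
  if (!is.numeric(m_causal) || length(m_causal) != 1L ||
      m_causal < 1 || m_causal > s_total)
    stop("`m_causal` must satisfy 1 <= M <= S", call. = FALSE)
  if (!is.numeric(alpha) || length(alpha) != 1L || alpha <= 0 || alpha >= 1)
    stop("`alpha` must lie strictly between 0 and 1", call. = FALSE)
  thr <- qnorm(alpha / 2, lower.tail = FALSE)
  if (!is.finite(thr) || thr <= 0)
    stop("significance threshold is not finite and positive", call. = FALSE)
  structure(
    list(s_total = as.numeric(s_total), m_causal = as.numeric(m_causal),
         alpha = as.numeric(alpha), threshold = thr),
    class = "architecture")
}

#' @export
print.architecture <- function(x, ...) {
  cat("Architecture: S =", format(x$s_total, big.mark = ","),
      "independent SNPs, M =", format(x$m_causal, big.mark = ","),
      "causal, alpha =", format(x$alpha), "(|Z| >", round(x$threshold, 4),
      ")\n")
  invisible(x)
}

#' Equal-size, equal-heritability, constant-CGR design
#'
#' Builds the design used throughout published contour figures and reference
#' tables: `C` studies of size `n_total / C` (kept fractional), a common SNP
#' heritability, a constant correlation among studies and a constant
#' correlation of each study with the hold-out sample.
#'
#' @param n_total total discovery sample size \eqn{N_T}.
#' @param n_studies number of studies `C` (`1 <= C <= n_total`).
#' @param h2 common per-study SNP heritability.
#' @param cgr_among constant cross-study genetic correlation.
#' @param cgr_holdout constant correlation between each study and the
#'   hold-out sample; defaults to `cgr_among`.
#' @param h2_holdout hold-out SNP heritability; defaults to `h2`.
#' @return A list with components `panel` ([study_panel]) and `cgr`
#'   ([cgr_structure]).
#' @examples
#' d <- equal_design(250000, 50, h2 = 0.5, cgr_among = 0.5)
#' d$panel
#' @export
equal_design <- function(n_total, n_studies, h2, cgr_among,
                         cgr_holdout = cgr_among, h2_holdout = h2) {
  if (!is.numeric(n_total) || n_total <= 0 ||
      !is.numeric(n_studies) || n_studies < 1)
    stop("`n_total` and `n_studies` must be positive", call. = FALSE)
  if (n_studies > n_total)
    stop("more studies (", n_studies, ") than individuals (", n_total, ")",
         call. = FALSE)
  C <- as.integer(n_studies)
  panel <- study_panel(rep(n_total / C, C), rep(h2, C))
  cgr <- cgr_structure(cgr_among, cgr_holdout, h2_holdout, n_studies = C)
  list(panel = panel, cgr = cgr)
}

#' Two-cluster block-correlation design
#'
#' Two equally sized sets of studies (for example, two ancestry clusters)
#' with a within-set CGR and a lower between-set CGR.
#'
#' @param n_total total discovery sample size across both sets.
#' @param studies_per_set number of studies in each of the two sets.
#' @param h2 common per-study SNP heritability.
#' @param cgr_within constant CGR within each set (default 1).
#' @param cgr_between constant CGR between studies in different sets.
#' @param cgr_holdout correlation of every study with the hold-out sample;
#'   defaults to `cgr_between`.
#' @param h2_holdout hold-out SNP heritability; defaults to `h2`.
#' @return A list with components `panel` and `cgr`, as [equal_design()].
#' @examples
#' d <- two_set_design(250000, 50, h2 = 0.5, cgr_between = 0.5)
#' @export
two_set_design <- function(n_total, studies_per_set, h2, cgr_within = 1,
                           cgr_between, cgr_holdout = cgr_between,
                           h2_holdout = h2) {
  C <- 2L * as.integer(studies_per_set)
  if (C > n_total)
    stop("more studies (", C, ") than individuals (", n_total, ")",
         call. = FALSE)
  among <- matrix(cgr_between, C, C)
  idx1 <- seq_len(studies_per_set)
  among[idx1, idx1] <- cgr_within
  among[-idx1, -idx1] <- cgr_within
  diag(among) <- 1
  panel <- study_panel(rep(n_total / C, C), rep(h2, C))
  cgr <- cgr_structure(among, cgr_holdout, h2_holdout)
  list(panel = panel, cgr = cgr)
}

check_panel_cgr <- function(panel, cgr) {
  if (!inherits(panel, "study_panel"))
    stop("`panel` must be a study_panel", call. = FALSE)
  if (!inherits(cgr, "cgr_structure"))
    stop("`cgr` must be a cgr_structure", call. = FALSE)
  if (cgr$n_studies != panel$n_studies)
    stop("configuration error: panel has ", panel$n_studies,
         " studies but CGR structure describes ", cgr$n_studies, call. = FALSE)
  invisible(TRUE)
}
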