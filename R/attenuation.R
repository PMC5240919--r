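#' Attenuation relative to the perfect-correlation benchmark
#'
#' Computes expected hits and hold-out PGS R-squared twice -- once with the
#' given CGR structure and once with every cross-study and study-to-holdout
#' correlation set to 1 -- and reports the relative loss
#' \eqn{1 - \mathrm{value}(\mathrm{CGR}) / \mathrm{value}(\mathrm{CGR}=1)}
#' for each quantity. A design whose CGR structure is already all ones has
#' zero attenuation by construction.
#'
#' If a benchmark value is numerically zero (below `1e-300`) the
#' corresponding attenuation is reported as `NA` with `defined = FALSE`
#' rather than dividing by zero.
#'
#' @inheritParams meta_z_variance
#' @return An object of class `attenuation_report`: list with
#'   `hits` and `r2` (relative losses in `[0, 1]`, or `NA`),
#'   `defined` (named logical), and the two underlying pairs
#'   `hits_cgr`, `hits_perfect`, `r2_cgr`, `r2_perfect`.
#' @examples
#' d <- equal_design(111749, 1, h2 = 0.157, cgr_among = 1, cgr_holdout = 0.468)
#' attenuation(d$panel, d$cgr, architecture(250000, 20000))  # R2 loss ~78%
#' @export
attenuation <- function(panel, cgr, arch) {
  check_panel_cgr(panel, cgr)
  perfect <- cgr_structure(constant_corr(cgr$n_studies, 1), 1,
                           cgr$holdout_h2)
  hits_c <- power_report(panel, cgr, arch)$expected_hits
  hits_1 <- power_report(panel, perfect, arch)$expected_hits
  r2_c <- pgs_r2(panel, cgr, arch)$r2
  r2_1 <- pgs_r2(panel, perfect, arch)$r2
  rel_loss <- function(x, x1) {
    if (x1 < 1e-300) return(NA_real_)
    1 - x / x1
  }
  structure(
    list(hits = rel_loss(hits_c, hits_1),
         r2 = rel_loss(r2_c, r2_1),
         defined = c(hits = hits_1 >= 1e-300, r2 = r2_1 >= 1e-300),
         hits_cgr = hits_c, hits_perfect = hits_1,
         r2_cgr = r2_c, r2_perfect = r2_1),
    class = "attenuation_report")
}

#' @export
print.attenuation_report <- function(x, ...) {
  fmt <- function(v) if (is.na(v)) "undefined" else sprintf("%.1f%%", 100 * v)
  cat("Attenuation vs CGR = 1 benchmark\n")
  cat("  expected hits:", round(x$hits_cgr, 2), "vs", round(x$hits_perfect, 2),
      "-> loss", fmt(x$hits), "\n")
  cat("  PGS R2:       ", sprintf("%.2f%%", 100 * x$r2_cgr), "vs",
      sprintf("%.2f%%", 100 * x$r2_perfect), "-> loss", fmt(x$r2), "\n")
  invisible(x)
}
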