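#' Evaluate power and PGS R-squared over a two-dimensional design grid
#'
#' Produces the long-format table behind contour-style summaries: two design
#' axes are crossed, all remaining factors are held fixed, and each grid
#' point is evaluated with [meta_z_variance()], [power_per_causal_snp()] and
#' [pgs_r2()].
#'
#' Two grid types are supported. `"equal"` evaluates the constant-CGR
#' equal design (axes and fixed factors from `n_total`, `n_studies`, `h2`,
#' `cgr`, `cgr_holdout`, `h2_holdout`, `s_total`, `m_causal`, `alpha`).
#' `"two_set"` evaluates the two-cluster block design (factors
#' `n_total`, `studies_per_set`, `h2`, `cgr_within`, `cgr_between`,
#' `cgr_holdout`, `h2_holdout`, `s_total`, `m_causal`, `alpha`), where the
#' CGR between the two sets of studies is typically one of the axes.
#'
#' @param axes named list of exactly two numeric vectors (the grid axes),
#'   each with at least one point.
#' @param fixed named list of the remaining design factors.
#' @param type `"equal"` or `"two_set"`.
#' @return A data frame with the two axis columns plus `sigma2`, `beta`,
#'   `r2`, one row per grid point, suitable for contour plotting.
#' @examples
#' run_grid(axes = list(n_studies = c(1, 2, 10, 100), cgr = 0.5),
#'          fixed = list(n_total = 250000, h2 = 0.5,
#'                       s_total = 1e5, m_causal = 1000))
#' @export
run_grid <- function(axes, fixed = list(), type = c("equal", "two_set")) {
  type <- match.arg(type)
  valid <- if (type == "equal") {
    c("n_total", "n_studies", "h2", "cgr", "cgr_holdout", "h2_holdout",
      "s_total", "m_causal", "alpha")
  } else {
    c("n_total", "studies_per_set", "h2", "cgr_within", "cgr_between",
      "cgr_holdout", "h2_holdout", "s_total", "m_causal", "alpha")
  }
  if (!is.list(axes) || length(axes) != 2L || is.null(names(axes)) ||
      any(names(axes) == ""))
    stop("`axes` must be a named list of two numeric vectors", call. = FALSE)
  bad <- setdiff(c(names(axes), names(fixed)), valid)
  if (length(bad))
    stop("unknown axis/factor name(s) ", paste(bad, collapse = ", "),
         " for type \"", type, "\"; valid names are: ",
         paste(valid, collapse = ", "), call. = FALSE)
  pts <- expand.grid(axes[[1]], axes[[2]], KEEP.OUT.ATTRS = FALSE)
  names(pts) <- names(axes)
  out <- vapply(seq_len(nrow(pts)), function(i) {
    fac <- c(as.list(pts[i, , drop = FALSE]), fixed)
    arch <- architecture(fac$s_total, fac$m_causal,
                         if (is.null(fac$alpha)) 5e-8 else fac$alpha)
    d <- if (type == "equal") {
      equal_design(fac$n_total, fac$n_studies, fac$h2, cgr_among = fac$cgr,
                   cgr_holdout = if (is.null(fac$cgr_holdout)) fac$cgr
                                 else fac$cgr_holdout,
                   h2_holdout = if (is.null(fac$h2_holdout)) fac$h2
                                else fac$h2_holdout)
    } else {
      two_set_design(fac$n_total, fac$studies_per_set, fac$h2,
                     cgr_within = if (is.null(fac$cgr_within)) 1
                                  else fac$cgr_within,
                     cgr_between = fac$cgr_between,
                     cgr_holdout = if (is.null(fac$cgr_holdout))
                                     fac$cgr_between else fac$cgr_holdout,
                     h2_holdout = if (is.null(fac$h2_holdout)) fac$h2
                                  else fac$h2_holdout)
    }
    s2 <- meta_z_variance(d$panel, d$cgr, arch)
    c(s2, power_per_causal_snp(s2, arch$alpha),
      pgs_r2(d$panel, d$cgr, arch)$r2)
  }, numeric(3))
  cbind(pts, data.frame(sigma2 = out[1, ], beta = out[2, ], r2 = out[3, ]))
}
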