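#' Default validation grids
#'
#' Scenario grids used to validate the closed forms empirically, at the
#' relaxed significance level `alpha = 5e-4` and 200 replicates per cell.
#'
#' The `"baseline"` grid stresses the equal-R2 assumption: effects have
#' equal raw-scale variance (`maf_effect_coupling = 0`) while allele
#' frequencies are non-uniform (`Uniform(0.05, 0.5)`) and redrawn
#' independently per study. Its six cells span S in \{1000, 2000\}, M/S in
#' \{0.1, 1\}, C in \{2, 5\}, per-study n in \{2000, 10000\}, h2 in
#' \{0.2, 0.5\} and CGR in \{0.3, 0.7, 1.0\} (a spanning selection rather
#' than the full cross, so the grid runs in minutes).
#'
#' The `"overlap"` grid generates the CGR from partial causal-locus
#' sharing: each study is causal at a shared core (fraction `q` of its M
#' loci, effect correlation `rho_e` across studies) plus private loci, so
#' the genome-wide CGR equals `q * rho_e`. Cells keep the per-SNP signal
#' `n h2 / M` moderate, where the single-variance closed form is an
#' accurate summary of the shared/private mixture.
#'
#' @param type `"baseline"` or `"overlap"`.
#' @param n_replicates replicates per cell (default 200).
#' @param seed integer master seed for the grid; per-cell seeds are derived
#'   by fixed offsets.
#' @return A list of [sim_scenario()] objects.
#' @seealso [validate_grid()]
#' @export
default_validation_grid <- function(type = c("baseline", "overlap"),
                                    n_replicates = 200, seed = 20170117) {
  type <- match.arg(type)
  cell_seed <- function(i) as.integer((seed + 1000003 * i) %% 2147483629)
  if (type == "baseline") {
    cells <- list(
      list(S = 1000, M = 100,  C = 2, n = 2000,  h2 = 0.2, rho = 0.3),
      list(S = 1000, M = 1000, C = 2, n = 2000,  h2 = 0.5, rho = 0.7),
      list(S = 2000, M = 200,  C = 5, n = 2000,  h2 = 0.5, rho = 1.0),
      list(S = 2000, M = 2000, C = 2, n = 2000,  h2 = 0.2, rho = 0.7),
      list(S = 1000, M = 100,  C = 2, n = 10000, h2 = 0.5, rho = 0.3),
      list(S = 1000, M = 1000, C = 5, n = 2000,  h2 = 0.2, rho = 1.0))
    lapply(seq_along(cells), function(i) {
      p <- cells[[i]]
      sim_scenario(
        sizes = rep(p$n, p$C), h2 = p$h2, cgr = p$rho,
        s_total = p$S, m_causal = p$M, alpha = 5e-4,
        maf = maf_uniform(0.05, 0.5, per_study = TRUE),
        maf_effect_coupling = 0,
        n_replicates = n_replicates, seed = cell_seed(i),
        label = sprintf("baseline_S%d_M%d_C%d_n%d_h%.1f_r%.1f",
                        p$S, p$M, p$C, p$n, p$h2, p$rho))
    })
  } else {
    cells <- list(
      list(S = 2000, M = 1000, C = 2, n = 2000, h2 = 0.5, q = 0.5,
           rho_e = 1.0),
      list(S = 2000, M = 1000, C = 2, n = 2000, h2 = 0.2, q = 0.5,
           rho_e = 0.6),
      list(S = 2000, M = 1000, C = 2, n = 2000, h2 = 0.5, q = 0.8,
           rho_e = 1.0),
      list(S = 2000, M = 1000, C = 5, n = 2000, h2 = 0.2, q = 0.8,
           rho_e = 0.75))
    lapply(seq_along(cells), function(i) {
      p <- cells[[i]]
      sim_scenario(
        sizes = rep(p$n, p$C), h2 = p$h2, cgr = p$q * p$rho_e,
        s_total = p$S, m_causal = p$M, alpha = 5e-4,
        maf = maf_uniform(0.05, 0.5, per_study = FALSE),
        maf_effect_coupling = -1,
        overlap = list(q = p$q, rho_e = p$rho_e),
        n_replicates = n_replicates, seed = cell_seed(100 + i),
        label = sprintf("overlap_S%d_M%d_C%d_n%d_h%.1f_q%.1f_re%.2f",
                        p$S, p$M, p$C, p$n, p$h2, p$q, p$rho_e))
    })
  }
}

#' Validate the closed forms over a scenario grid
#'
#' Runs every scenario with [simulate_scenario()], tabulates empirical
#' versus closed-form power and PGS R-squared, and aggregates the
#' root-mean-square error in percentage points.
#'
#' @param scenarios list of [sim_scenario()] objects (>= 1; a meaningful
#'   grid spans h2, CGR and C).
#' @param target_se optional: warn when a scenario's Monte-Carlo standard
#'   error of power exceeds this value (insufficient replicates).
#' @return A data frame (class `validation_report`) with one row per
#'   scenario (`label`, design columns, theory/empirical power and R2 and
#'   their standard errors, deltas in percentage points) and attributes
#'   `rmse_power_pp` and `rmse_r2_pp`.
#' @examples
#' \donttest{
#' grid <- default_validation_grid("baseline", n_replicates = 20)
#' rep <- validate_grid(grid[1:2])
#' attr(rep, "rmse_power_pp")
#' }
#' @export
validate_grid <- function(scenarios, target_se = NULL) {
  if (!length(scenarios)) stop("empty scenario list", call. = FALSE)
  if (inherits(scenarios, "sim_scenario")) scenarios <- list(scenarios)
  rows <- lapply(scenarios, function(sc) {
    res <- simulate_scenario(sc)
    if (!is.null(target_se) && res$se_power > target_se)
      warning("scenario '", sc$label, "': achieved power SE ",
              signif(res$se_power, 3), " exceeds target ", target_se,
              "; increase n_replicates", call. = FALSE)
    data.frame(
      label = sc$label, n_studies = length(sc$sizes), n_per_study = sc$sizes[1],
      s_total = sc$arch$s_total, m_causal = sc$arch$m_causal,
      h2 = sc$h2[1],
      cgr = if (!is.null(sc$effective_cgr)) sc$effective_cgr
            else sc$cgr_target$among[1, min(2, ncol(sc$cgr_target$among))],
      theory_power = res$theory_power,
      empirical_power = res$empirical_power, se_power = res$se_power,
      theory_r2 = res$theory_r2,
      empirical_r2 = res$empirical_r2, se_r2 = res$se_r2,
      delta_power_pp = 100 * (res$empirical_power - res$theory_power),
      delta_r2_pp = 100 * (res$empirical_r2 - res$theory_r2),
      stringsAsFactors = FALSE)
  })
  out <- do.call(rbind, rows)
  attr(out, "rmse_power_pp") <- sqrt(mean(out$delta_power_pp^2))
  attr(out, "rmse_r2_pp") <- sqrt(mean(out$delta_r2_pp^2))
  class(out) <- c("validation_report", class(out))
  out
}

#' @export
print.validation_report <- function(x, ...) {
  cat("Closed-form validation over", nrow(x), "scenarios\n")
  df <- as.data.frame(x)
  num <- vapply(df, is.numeric, logical(1))
  df[num] <- lapply(df[num], signif, 4)
  print(df, row.names = FALSE)
  cat(sprintf("\naggregate RMSE: power %.3f pp, R2 %.3f pp\n",
              attr(x, "rmse_power_pp"), attr(x, "rmse_r2_pp")))
  invisible(x)
}

#' Write a validation report
#'
#' `write_validation_tsv()` writes the per-scenario table;
#' `write_validation_json()` writes the table plus the aggregate RMSEs.
#'
#' @param report a `validation_report` from [validate_grid()].
#' @param path output file path.
#' @return The path, invisibly.
#' @export
write_validation_tsv <- function(report, path) {
  write.table(as.data.frame(report), path, sep = "\t", quote = FALSE,
              row.names = FALSE)
  invisible(path)
}

#' @rdname write_validation_tsv
#' @export
write_validation_json <- function(report, path) {
  jsonlite::write_json(
    list(scenarios = as.data.frame(report),
         rmse_power_pp = attr(report, "rmse_power_pp"),
         rmse_r2_pp = attr(report, "rmse_r2_pp")),
    path, auto_unbox = TRUE, digits = NA, dataframe = "rows")
  invisible(path)
}

#' Read a scenario list from a JSON specification
#'
#' Each element of the JSON array carries the fields of [sim_scenario()]
#' (`sizes`, `h2`, `cgr`, `s_total`, `m_causal`, ...); `maf` is given as
#' `{"type": "fixed", "value": ...}` or
#' `{"type": "uniform", "lo": ..., "hi": ..., "per_study": ...}`.
#'
#' @param path path to the JSON file.
#' @return A list of [sim_scenario()] objects.
#' @export
read_scenarios_json <- function(path) {
  raw <- jsonlite::fromJSON(path, simplifyDataFrame = FALSE)
  lapply(raw, function(x) {
    if (!is.null(x$maf)) {
      x$maf <- if (x$maf$type == "fixed") maf_fixed(x$maf$value)
               else maf_uniform(x$maf$lo, x$maf$hi,
                                isTRUE(x$maf$per_study))
    }
    x$sizes <- as.numeric(unlist(x$sizes))
    do.call(sim_scenario, x)
  })
}
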