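#' Calculator configuration
#'
#' Two input modes mirror the two ways a multi-study design can be
#' specified. In `"scalar"` mode the design is the constant-correlation
#' equal design: total (or average per-study) sample size, one common
#' heritability, and exactly two CGR values -- one among the discovery
#' studies and one between each study and the hold-out sample. In
#' `"matrix"` mode per-study sizes and heritabilities are given together
#' with a full `(C+1) x (C+1)` bordered correlation matrix (hold-out last).
#'
#' @param mode `"scalar"` or `"matrix"`.
#' @param n_total,n_studies,h2,cgr,cgr_holdout scalar-mode design:
#'   total sample size, number of studies, common per-study h2, among-study
#'   CGR and study-to-holdout CGR.
#' @param n_list,h2_list,cgr_matrix matrix-mode design: per-study sizes,
#'   per-study heritabilities, and the bordered correlation matrix.
#' @param h2_holdout hold-out SNP heritability (both modes; scalar mode
#'   defaults to `h2`).
#' @param s_total,m_causal,alpha architecture; see [architecture()].
#' @param format output format for [run_calculator()] printing: `"text"`,
#'   `"json"` or `"tsv"`.
#' @return An object of class `calculator_config`.
#' @examples
#' calculator_config(mode = "scalar", n_total = 253288, n_studies = 79,
#'                   h2 = 0.449, cgr = 0.965, cgr_holdout = 0.965,
#'                   s_total = 250000, m_causal = 20000)
#' @export
calculator_config <- function(mode = c("scalar", "matrix"),
                              n_total = NULL, n_studies = NULL, h2 = NULL,
                              cgr = NULL, cgr_holdout = NULL,
                              n_list = NULL, h2_list = NULL,
                              cgr_matrix = NULL, h2_holdout = NULL,
                              s_total, m_causal, alpha = 5e-8,
                              format = c("text", "json", "tsv")) {
  mode <- match.arg(mode)
  format <- match.arg(format)
  if (mode == "scalar") {
    missing_fields <- c("n_total", "n_studies", "h2")[
      c(is.null(n_total), is.null(n_studies), is.null(h2))]
    if (length(missing_fields))
      stop("scalar mode requires fields: ",
           paste(missing_fields, collapse = ", "), call. = FALSE)
    if (is.null(cgr) || is.null(cgr_holdout))
      stop("scalar mode requires exactly two CGR values: ",
           "`cgr` (among studies) and `cgr_holdout`", call. = FALSE)
    if (length(cgr) != 1L || length(cgr_holdout) != 1L)
      stop("scalar mode takes single values for `cgr` and `cgr_holdout`",
           call. = FALSE)
    if (is.null(h2_holdout)) h2_holdout <- h2
  } else {
    if (is.null(n_list) || is.null(h2_list) || is.null(cgr_matrix))
      stop("matrix mode requires `n_list`, `h2_list` and `cgr_matrix`",
           call. = FALSE)
    if (length(n_list) != length(h2_list))
      stop("`n_list` and `h2_list` must have the same length", call. = FALSE)
    cgr_matrix <- as.matrix(cgr_matrix)
    if (nrow(cgr_matrix) != length(n_list) + 1L ||
        ncol(cgr_matrix) != length(n_list) + 1L)
      stop("`cgr_matrix` must be (C+1) x (C+1) with C = length(n_list) = ",
           length(n_list), "; got ", nrow(cgr_matrix), " x ",
           ncol(cgr_matrix), call. = FALSE)
    if (is.null(h2_holdout))
      stop("matrix mode requires `h2_holdout`", call. = FALSE)
  }
  structure(
    list(mode = mode, n_total = n_total, n_studies = n_studies, h2 = h2,
         cgr = cgr, cgr_holdout = cgr_holdout, n_list = n_list,
         h2_list = h2_list, cgr_matrix = cgr_matrix,
         h2_holdout = h2_holdout, s_total = s_total, m_causal = m_causal,
         alpha = alpha, format = format),
    class = "calculator_config")
}

config_to_design <- function(config) {
  arch <- architecture(config$s_total, config$m_causal, config$alpha)
  if (config$mode == "scalar") {
    d <- equal_design(config$n_total, config$n_studies, config$h2,
                      cgr_among = config$cgr,
                      cgr_holdout = config$cgr_holdout,
                      h2_holdout = config$h2_holdout)
  } else {
    C <- length(config$n_list)
    m <- config$cgr_matrix
    panel <- study_panel(config$n_list, config$h2_list)
    cgr <- cgr_structure(m[seq_len(C), seq_len(C), drop = FALSE],
                         m[seq_len(C), C + 1L], config$h2_holdout)
    d <- list(panel = panel, cgr = cgr)
  }
  c(d, list(arch = arch))
}

#' Run the power and PGS accuracy calculator
#'
#' Evaluates a [calculator_config()]: the causal-SNP Z variance, power per
#' causal SNP, all expected discovery counts and detection probabilities,
#' the theoretical hold-out PGS R-squared, and attenuation of hits and
#' R-squared relative to the same design with all correlations set to 1.
#'
#' @param config a [calculator_config()].
#' @return An object of class `calculator_report`: list with elements
#'   `power` ([detection_report()] fields), `pgs` ([pgs_r2()] fields),
#'   `attenuation` ([attenuation()]) and the `config`.
#' @examples
#' cfg <- calculator_config(mode = "scalar", n_total = 253288, n_studies = 79,
#'                          h2 = 0.449, cgr = 0.965, cgr_holdout = 0.965,
#'                          s_total = 250000, m_causal = 20000)
#' run_calculator(cfg)
#' @export
run_calculator <- function(config) {
  if (!inherits(config, "calculator_config"))
    stop("`config` must be a calculator_config", call. = FALSE)
  d <- config_to_design(config)
  structure(
    list(power = power_report(d$panel, d$cgr, d$arch),
         pgs = pgs_r2(d$panel, d$cgr, d$arch),
         attenuation = attenuation(d$panel, d$cgr, d$arch),
         config = config),
    class = "calculator_report")
}

#' @export
print.calculator_report <- function(x, ...) {
  print(x$power)
  print(x$pgs)
  print(x$attenuation)
  invisible(x)
}

report_values <- function(report) {
  p <- report$power
  g <- report$pgs
  a <- report$attenuation
  list(z_variance = p$z_variance, beta = p$beta,
       expected_hits = p$expected_hits,
       expected_true_pos = p$expected_true_pos,
       expected_false_pos = p$expected_false_pos,
       expected_false_neg = p$expected_false_neg,
       expected_true_neg = p$expected_true_neg,
       p_any_true_pos = p$p_any_true_pos, p_any_hit = p$p_any_hit,
       r2 = g$r2, pgs_variance = g$pgs_variance,
       pgs_pheno_cov = g$pgs_pheno_cov,
       attenuation_hits = a$hits, attenuation_r2 = a$r2)
}

#' Serialize a calculator report
#'
#' `report_json()` renders results plus configuration as JSON at full
#' precision (the round trip [read_calculator_config()] ->
#' [run_calculator()] reproduces identical numbers); `report_tsv()` renders
#' a two-column key/value TSV.
#'
#' @param report a `calculator_report` from [run_calculator()].
#' @param path optional file to write to; the string is returned invisibly
#'   when writing.
#' @return A JSON string / TSV string.
#' @export
report_json <- function(report, path = NULL) {
  cfg <- report$config
  cfg_list <- cfg[!vapply(cfg, is.null, logical(1))]
  cfg_list$cgr_matrix <- if (!is.null(cfg$cgr_matrix))
    apply(cfg$cgr_matrix, 1, as.numeric, simplify = FALSE)
  cfg_list <- cfg_list[!vapply(cfg_list, is.null, logical(1))]
  out <- jsonlite::toJSON(list(config = cfg_list,
                               results = report_values(report)),
                          auto_unbox = TRUE, digits = NA, null = "null")
  if (!is.null(path)) {
    writeLines(out, path)
    return(invisible(out))
  }
  out
}

#' @rdname report_json
#' @export
report_tsv <- function(report, path = NULL) {
  vals <- report_values(report)
  lines <- paste(names(vals),
                 vapply(vals, function(v) format(v, digits = 17),
                        character(1)),
                 sep = "\t")
  out <- paste(lines, collapse = "\n")
  if (!is.null(path)) {
    writeLines(out, path)
    return(invisible(out))
  }
  out
}

#' Read a calculator configuration from JSON
#'
#' Accepts either a bare configuration object (keys as in
#' [calculator_config()]) or the `config` element of a JSON report written
#' by [report_json()].
#'
#' @param path path to a JSON file.
#' @return A [calculator_config()].
#' @export
read_calculator_config <- function(path) {
  x <- jsonlite::fromJSON(path, simplifyMatrix = TRUE)
  if (!is.null(x$config)) x <- x$config
  if (!is.null(x$cgr_matrix)) x$cgr_matrix <- as.matrix(x$cgr_matrix)
  known <- setdiff(names(formals(calculator_config)), "...")
  bad <- setdiff(names(x), known)
  if (length(bad))
    stop("unknown configuration fields: ", paste(bad, collapse = ", "),
         call. = FALSE)
  do.call(calculator_config, x[intersect(names(x), known)])
}

#' Read a bordered CGR matrix from CSV
#'
#' Headerless CSV of floats, one row per line; row order is the discovery
#' studies followed by the hold-out sample, matching
#' [full_cgr_matrix()].
#'
#' @param path path to the CSV file.
#' @return A square numeric matrix.
#' @export
read_cgr_csv <- function(path) {
  m <- as.matrix(read.table(path, sep = ",", header = FALSE))
  dimnames(m) <- NULL
  storage.mode(m) <- "double"
  if (nrow(m) != ncol(m))
    stop("CGR matrix in ", path, " is not square (",
         nrow(m), " x ", ncol(m), ")", call. = FALSE)
  m
}
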