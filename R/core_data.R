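#' @keywords internal
"_PACKAGE"

#' Default eight-metal panel
#'
#' The heavy-metal panel used throughout: Hg, Cd, Pb, As, Cr, Cu, Ni, Zn.
#'
#' @return Character vector of metal names.
#' @export
default_panel <- function() c("Hg", "Cd", "Pb", "As", "Cr", "Cu", "Ni", "Zn")

#' Construct a sample table
#'
#' Wraps a data frame of soil samples into a validated `sample_table`:
#' one row per sample, one column per panel metal (concentrations in mg/kg)
#' plus any covariate columns. Negative or non-numeric concentration cells
#' are converted to `NA` with a warning; they are never silently zeroed.
#'
#' @param df Data frame with a `sample_id` column (created if absent) and one
#'   numeric column per panel metal.
#' @param panel Character vector of metal column names.
#' @return A `sample_table`: the data frame with attributes `metals` (the
#'   panel) and `n_flagged` (count of cells flagged missing on validation).
#' @export
sample_table <- function(df, panel = default_panel()) {
  stopifnot(is.data.frame(df), length(panel) > 0)
  if (anyDuplicated(panel)) stop("duplicate metal names in panel")
  missing_cols <- setdiff(panel, names(df))
  if (length(missing_cols) > 0) {
    stop("missing metal column(s): ", paste(missing_cols, collapse = ", "))
  }
  df <- as.data.frame(df, stringsAsFactors = FALSE)
  if (!"sample_id" %in% names(df)) {
    df$sample_id <- sprintf("S%04d", seq_len(nrow(df)))
  }
  df$sample_id <- as.character(df$sample_id)
  if (anyDuplicated(df$sample_id)) stop("sample_id values must be unique")
  n_flagged <- 0L
  for (m in panel) {
    x <- df[[m]]
    if (!is.numeric(x)) x <- suppressWarnings(as.numeric(as.character(x)))
    bad <- !is.na(x) & x < 0
    n_flagged <- n_flagged + sum(bad) + sum(is.na(x) & !is.na(df[[m]]))
    x[bad] <- NA_real_
    df[[m]] <- x
  }
  if (n_flagged > 0) {
    warning(sprintf("%d concentration cell(s) flagged missing (negative or non-numeric)",
                    n_flagged))
  }
  structure(df, metals = panel, n_flagged = n_flagged,
            class = c("sample_table", "data.frame"))
}

#' @export
print.sample_table <- function(x, ...) {
  cat(sprintf("<sample_table> %d samples, %d-metal panel: %s\n",
              nrow(x), length(attr(x, "metals")),
              paste(attr(x, "metals"), collapse = ", ")))
  NextMethod()
}

#' Panel metals of a sample table
#' @param samples A `sample_table`.
#' @return Character vector of metal names.
#' @export
metals <- function(samples) attr(samples, "metals")

#' Concentration matrix of a sample table
#' @param samples A `sample_table`.
#' @return Numeric matrix, samples x metals, rownames = sample ids.
#' @export
conc_matrix <- function(samples) {
  m <- as.matrix(as.data.frame(samples)[, metals(samples), drop = FALSE])
  rownames(m) <- samples$sample_id
  m
}

#' Read a sample table from CSV
#'
#' Reads a wide-format survey CSV (one row per sample, one column per metal,
#' mg/kg) and validates it. Negative or non-numeric concentrations are
#' flagged missing with a warning.
#'
#' @param path Path to a CSV file with a header row.
#' @param panel Metal column names expected in the header.
#' @return A [sample_table()].
#' @export
read_samples <- function(path, panel = default_panel()) {
  if (!file.exists(path)) stop("file not found: ", path)
  df <- utils::read.csv(path, check.names = FALSE, stringsAsFactors = FALSE)
  if (nrow(df) == 0) stop("empty sample file: ", path)
  sample_table(df, panel = panel)
}

#' Write a sample table to CSV
#' @param samples A `sample_table`.
#' @param path Output CSV path.
#' @return `path`, invisibly.
#' @export
write_samples <- function(samples, path) {
  utils::write.csv(as.data.frame(samples), path, row.names = FALSE)
  invisible(path)
}

#' Read a reference-value configuration
#'
#' Loads per-metal background values, Hakanson toxicity coefficients,
#' optional screening/control values, method detection limits, and the
#' conservative reference element used for enrichment factors, from a YAML
#' file. The bundled default carries the Yunnan Province soil backgrounds
#' and agricultural-land thresholds.
#'
#' @param path YAML config path; default is the bundled Yunnan reference set.
#' @param panel Metals that must have background and toxicity values.
#' @return A `reference_set` list with elements `metals`, `background`,
#'   `toxicity`, `screening`, `control`, `mdl` (named numeric vectors; the
#'   optional ones may have `NA` for unavailable metals) and `ref_element`
#'   (list: `name`, `column`, `background`).
#' @export
read_reference <- function(path = system.file("extdata", "yunnan_reference.yml",
                                              package = "soilsrc"),
                           panel = default_panel()) {
  cfg <- yaml::read_yaml(path)
  pull <- function(field, required) {
    vals <- cfg[[field]]
    out <- stats::setNames(rep(NA_real_, length(panel)), panel)
    for (m in intersect(names(vals), panel)) out[m] <- as.numeric(vals[[m]])
    if (required && anyNA(out)) {
      stop("reference config missing ", field, " for: ",
           paste(panel[is.na(out)], collapse = ", "))
    }
    if (any(!is.na(out) & out <= 0)) {
      stop("non-positive ", field, " value in reference config")
    }
    out
  }
  ref <- list(
    metals     = panel,
    background = pull("background", required = TRUE),
    toxicity   = pull("toxicity", required = TRUE),
    screening  = pull("screening", required = FALSE),
    control    = pull("control", required = FALSE),
    mdl        = pull("mdl", required = FALSE),
    ref_element = cfg$ref_element
  )
  if (!is.null(ref$ref_element)) {
    ref$ref_element$background <- as.numeric(ref$ref_element$background)
    if (!is.finite(ref$ref_element$background) || ref$ref_element$background <= 0)
      stop("ref_element background must be > 0")
  }
  structure(ref, class = "reference_set")
}

#' Descriptive summary of a metal panel
#'
#' Per-metal minimum, maximum, mean, sample (n-1) standard deviation,
#' coefficient of variation (\%), and exceedance proportions against the
#' background, screening and control thresholds. Exceedance is the
#' percentage of samples strictly above the threshold; thresholds marked
#' unavailable give `NA`. Missing cells are excluded per metal with their
#' count reported.
#'
#' @param samples A [sample_table()].
#' @param ref A [read_reference()] reference set.
#' @return Data frame, one row per metal: `metal, n, n_missing, min, max,
#'   mean, sd, cv, pct_above_background, pct_above_screening,
#'   pct_above_control`.
#' @export
summarize_metals <- function(samples, ref) {
  if (nrow(samples) < 2) stop("need at least 2 samples")
  X <- conc_matrix(samples)
  rows <- lapply(metals(samples), function(m) {
    x <- X[, m]
    miss <- sum(is.na(x))
    x <- x[!is.na(x)]
    if (length(x) == 0) stop("metal ", m, " has no observed values")
    exceed <- function(thr) {
      if (is.na(thr)) NA_real_ else 100 * sum(x > thr) / length(x)
    }
    data.frame(
      metal = m, n = length(x), n_missing = miss,
      min = min(x), max = max(x), mean = mean(x), sd = stats::sd(x),
      cv = if (mean(x) > 0) 100 * stats::sd(x) / mean(x) else NA_real_,
      pct_above_background = exceed(ref$background[m]),
      pct_above_screening = exceed(ref$screening[m]),
      pct_above_control = exceed(ref$control[m]),
      stringsAsFactors = FALSE
    )
  })
  out <- do.call(rbind, rows)
  rownames(out) <- NULL
  if (sum(out$n_missing) > 0) {
    message(sum(out$n_missing), " missing cell(s) excluded from summaries")
  }
  out
}

#' Pairwise correlation matrix of panel metals
#'
#' @param samples A [sample_table()].
#' @param method `"pearson"` or `"spearman"`.
#' @return Symmetric matrix of correlation coefficients, unit diagonal.
#'   Zero-variance metals give `NA` entries (flagged with a warning), never 0.
#' @export
correlation_matrix <- function(samples, method = c("pearson", "spearman")) {
  method <- match.arg(method)
  if (nrow(samples) < 3) stop("need at least 3 samples")
  X <- conc_matrix(samples)
  sds <- apply(X, 2, stats::sd, na.rm = TRUE)
  R <- suppressWarnings(
    stats::cor(X, method = method, use = "pairwise.complete.obs"))
  if (any(sds == 0, na.rm = TRUE)) {
    degenerate <- names(sds)[sds == 0]
    R[degenerate, ] <- NA_real_
    R[, degenerate] <- NA_real_
    diag(R) <- 1
    warning("zero-variance metal(s): ", paste(degenerate, collapse = ", "),
            "; correlations flagged undefined")
  }
  R
}

#' Printed marginal moments of the reference survey
#'
#' Per-metal min/max/mean/sd (mg/kg) of a 1790-sample agricultural-soil
#' survey in a central-Yunnan dry-hot valley, as published in summary form.
#' Used to calibrate [simulate_survey()] and for worked index examples from
#' printed inputs.
#'
#' @return Data frame with columns `metal, min, max, mean, sd`.
#' @export
survey_moments <- function() {
  path <- system.file("extdata", "yunnan_survey_summary.csv", package = "soilsrc")
  utils::read.csv(path, stringsAsFactors = FALSE)
}
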