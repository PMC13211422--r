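# Pollution and ecological-risk indices with their standard grade scales.

#' Enrichment factor
#'
#' Double ratio of a target metal to a conservative reference element in the
#' sample versus the regional background:
#' `EF = (c_metal / c_ref) / (b_metal / b_ref)`. Values near 1 indicate no
#' anthropogenic enrichment.
#'
#' @param c_metal Sample concentration of the target metal (mg/kg), > 0.
#' @param c_ref Sample concentration of the reference element (mg/kg), > 0.
#' @param b_metal Background value of the target metal (mg/kg), > 0.
#' @param b_ref Background value of the reference element (mg/kg), > 0.
#' @return Numeric EF values (vectorized).
#' @export
enrichment_factor <- function(c_metal, c_ref, b_metal, b_ref) {
  if (any(c(c_metal, c_ref, b_metal, b_ref) <= 0, na.rm = TRUE))
    stop("enrichment factor requires strictly positive inputs")
  (c_metal / c_ref) / (b_metal / b_ref)
}

#' Geoaccumulation index
#'
#' Mueller's sediment contamination index:
#' `Igeo = log2(c / (1.5 * b))`, the 1.5 allowing for natural background
#' fluctuation.
#'
#' @param c Measured concentration (mg/kg), > 0.
#' @param b Background value (mg/kg), > 0.
#' @return Numeric Igeo values (vectorized).
#' @export
igeo <- function(c, b) {
  if (any(c <= 0, na.rm = TRUE) || any(b <= 0, na.rm = TRUE))
    stop("igeo requires strictly positive concentrations and backgrounds")
  log2(c / (1.5 * b))
}

#' Single-factor pollution index
#'
#' `Pi = c / b`: measured concentration over the background value.
#'
#' @param c Measured concentration (mg/kg), >= 0.
#' @param b Background value (mg/kg), > 0.
#' @return Numeric Pi values (vectorized).
#' @export
single_factor_index <- function(c, b) {
  if (any(b <= 0, na.rm = TRUE)) stop("background must be > 0")
  if (any(c < 0, na.rm = TRUE)) stop("concentration must be >= 0")
  c / b
}

#' Nemerow integrated pollution index
#'
#' Root mean square of the maximum and arithmetic-mean single-factor index,
#' `PN = sqrt((Pi_max^2 + Pi_avg^2) / 2)`, emphasizing the worst site.
#' Either a vector of per-sample Pi values or the (max, avg) pair may be
#' supplied.
#'
#' @param pi_values Non-negative per-sample Pi values for one metal.
#' @param pi_max,pi_avg Alternative direct inputs; both must be given
#'   together and `pi_values` left missing.
#' @return The scalar PN.
#' @export
nemerow_index <- function(pi_values, pi_max = NULL, pi_avg = NULL) {
  if (missing(pi_values)) {
    stopifnot(!is.null(pi_max), !is.null(pi_avg))
  } else {
    if (length(pi_values) == 0) stop("empty Pi list")
    if (any(pi_values < 0, na.rm = TRUE)) stop("Pi values must be >= 0")
    pi_max <- max(pi_values, na.rm = TRUE)
    pi_avg <- mean(pi_values, na.rm = TRUE)
  }
  sqrt((pi_max^2 + pi_avg^2) / 2)
}

#' Single-metal environmental risk index
#'
#' Hakanson's `Ei = Ti * Pi`: the single-factor index weighted by the
#' metal's toxicity response coefficient.
#'
#' @param pi Single-factor pollution index, >= 0.
#' @param t Toxicity response coefficient, > 0.
#' @return Numeric Ei values (vectorized).
#' @export
env_risk_index <- function(pi, t) {
  if (any(pi < 0, na.rm = TRUE)) stop("Pi must be >= 0")
  if (any(t <= 0, na.rm = TRUE)) stop("toxicity coefficient must be > 0")
  t * pi
}

#' Potential ecological risk index
#'
#' `RI = sum(Ei)` over the full metal panel for one sample.
#'
#' @param ei_by_metal Named numeric vector, one Ei per panel metal.
#' @param panel Metals that must all be present.
#' @return The scalar RI.
#' @export
potential_ecological_risk <- function(ei_by_metal, panel = names(ei_by_metal)) {
  if (!all(panel %in% names(ei_by_metal)) || anyNA(ei_by_metal[panel]))
    stop("RI requires an Ei value for every panel metal")
  sum(ei_by_metal[panel])
}

# Grade scales, as printed interval lists; left-closed / right-open.
.grade_scales <- list(
  ef = list(breaks = c(-Inf, 1, 2, 5, 20, 40, Inf),
            labels = c("not enriched", "mildly enriched", "moderately enriched",
                       "highly enriched", "intensely enriched",
                       "very highly enriched")),
  igeo = list(breaks = c(-Inf, 0, 1, 2, 3, 4, 5, Inf),
              labels = c("practically unpolluted", "unpolluted to moderately",
                         "moderately polluted", "moderately to strongly",
                         "strongly polluted", "strong to very strong",
                         "very strong pollution")),
  pi = list(breaks = c(-Inf, 1, 2, 3, 5, Inf),
            labels = c("unpolluted", "mild pollution", "low pollution",
                       "moderate pollution", "severe pollution")),
  pn = list(breaks = c(-Inf, 0.7, 1, 2, 3, Inf),
            labels = c("unpolluted", "mild pollution", "low pollution",
                       "moderate pollution", "severe pollution")),
  ri = list(breaks = c(-Inf, 150, 300, 600, Inf),
            labels = c("low risk", "moderate risk", "high risk",
                       "very high risk"))
)

#' Grade an index value
#'
#' Maps a finite index value to its published grade label. Intervals are
#' left-closed / right-open as printed (e.g. mildly enriched is
#' `1 <= EF < 2`; severe pollution is `PN >= 3`; low risk is `RI < 150`).
#'
#' @param index_kind One of `"ef"`, `"igeo"`, `"pi"`, `"pn"`, `"ri"`.
#' @param value Finite numeric value(s).
#' @param labels Optional replacement label vector of the same length as the
#'   scale's default labels.
#' @return Character grade label(s).
#' @export
classify_index <- function(index_kind, value, labels = NULL) {
  scale <- .grade_scales[[index_kind]]
  if (is.null(scale)) stop("unknown index kind: ", index_kind)
  if (any(!is.finite(value))) stop("index value must be finite")
  lab <- if (is.null(labels)) scale$labels else labels
  stopifnot(length(lab) == length(scale$labels))
  lab[findInterval(value, scale$breaks, left.open = FALSE)]
}

#' Full index assessment of a sample table
#'
#' Computes per-sample, per-metal EF (when a reference-element column is
#' present), Igeo, Pi and Ei; per-metal means of each, the region-level
#' Nemerow index PN, and grade-proportion tables; and per-sample RI with
#' region-level RI grade counts. Per-metal means are means of per-sample
#' index values (not indices of mean concentrations). Cells unusable for a
#' log/ratio index (non-positive concentrations for Igeo/EF) are excluded
#' with a logged count; a sample missing any panel metal gets `NA` RI rather
#' than a partial sum.
#'
#' @param samples A [sample_table()].
#' @param ref A [read_reference()] reference set.
#' @return An `index_report` list: `per_sample` (long data frame of
#'   sample/metal/ef/igeo/pi/ei), `per_metal` (mean_ef, mean_igeo, mean_pi,
#'   mean_ei, pn per metal), `grade_proportions` (percent of samples per
#'   metal in each Igeo and Pi grade), `ri` (per-sample RI and grade), and
#'   `ri_grade_counts`.
#' @export
assess_table <- function(samples, ref) {
  X <- conc_matrix(samples)
  panel <- metals(samples)
  n <- nrow(X)

  ref_col <- ref$ref_element$column
  have_ef <- !is.null(ref_col) && ref_col %in% names(samples)
  c_ref <- if (have_ef) as.numeric(samples[[ref_col]]) else rep(NA_real_, n)

  per_sample <- do.call(rbind, lapply(panel, function(m) {
    x <- X[, m]
    b <- ref$background[m]
    pi <- ifelse(is.na(x), NA_real_, x / b)
    pos <- !is.na(x) & x > 0
    ig <- rep(NA_real_, n)
    ig[pos] <- igeo(x[pos], b)
    ef <- rep(NA_real_, n)
    if (have_ef) {
      ok <- pos & !is.na(c_ref) & c_ref > 0
      ef[ok] <- enrichment_factor(x[ok], c_ref[ok], b, ref$ref_element$background)
    }
    data.frame(sample_id = samples$sample_id, metal = m,
               ef = ef, igeo = ig, pi = pi,
               ei = ref$toxicity[m] * pi, stringsAsFactors = FALSE)
  }))
  n_excluded <- sum(is.na(per_sample$igeo) & !is.na(per_sample$pi))
  if (n_excluded > 0) {
    message(n_excluded, " non-positive cell(s) excluded from log/ratio indices")
  }

  per_metal <- do.call(rbind, lapply(panel, function(m) {
    d <- per_sample[per_sample$metal == m, ]
    data.frame(
      metal = m,
      mean_ef = mean(d$ef, na.rm = TRUE),
      mean_igeo = mean(d$igeo, na.rm = TRUE),
      mean_pi = mean(d$pi, na.rm = TRUE),
      mean_ei = mean(d$ei, na.rm = TRUE),
      pn = nemerow_index(d$pi[!is.na(d$pi)]),
      stringsAsFactors = FALSE
    )
  }))
  rownames(per_metal) <- NULL

  grade_prop <- function(values, kind) {
    v <- values[!is.na(values)]
    labs <- .grade_scales[[kind]]$labels
    tab <- table(factor(classify_index(kind, v), levels = labs))
    100 * as.numeric(tab) / length(v)
  }
  grade_proportions <- do.call(rbind, lapply(panel, function(m) {
    d <- per_sample[per_sample$metal == m, ]
    rbind(
      data.frame(metal = m, index = "igeo",
                 grade = .grade_scales$igeo$labels,
                 percent = grade_prop(d$igeo, "igeo"), stringsAsFactors = FALSE),
      data.frame(metal = m, index = "pi",
                 grade = .grade_scales$pi$labels,
                 percent = grade_prop(d$pi, "pi"), stringsAsFactors = FALSE)
    )
  }))
  rownames(grade_proportions) <- NULL

  # per_sample stacks metal blocks in panel order, so this reshapes to n x m;
  # no na.rm: a sample missing any metal gets NA RI, never a partial sum
  ri_vals <- rowSums(matrix(per_sample$ei, nrow = n))
  ri <- data.frame(sample_id = samples$sample_id, ri = ri_vals,
                   grade = NA_character_, stringsAsFactors = FALSE)
  ok <- !is.na(ri$ri)
  ri$grade[ok] <- classify_index("ri", ri$ri[ok])
  ri_grade_counts <- table(factor(ri$grade, levels = .grade_scales$ri$labels))

  structure(list(per_sample = per_sample, per_metal = per_metal,
                 grade_proportions = grade_proportions,
                 ri = ri, ri_grade_counts = ri_grade_counts,
                 n_excluded = n_excluded),
            class = "index_report")
}

#' @export
print.index_report <- function(x, ...) {
  cat("<index_report>\n")
  print(x$per_metal, digits = 3)
  cat("RI grade counts:\n")
  print(x$ri_grade_counts)
  invisible(x)
}

#' Write an index report to disk
#'
#' Writes the per-metal summary, grade-proportion table and per-sample long
#' file as CSV, plus a JSON summary of RI grade counts.
#'
#' @param report An [assess_table()] result.
#' @param dir Output directory (created if needed).
#' @return Character vector of written paths, invisibly.
#' @export
write_index_report <- function(report, dir) {
  dir.create(dir, recursive = TRUE, showWarnings = FALSE)
  paths <- c(
    per_metal = file.path(dir, "indices_per_metal.csv"),
    grades = file.path(dir, "indices_grade_proportions.csv"),
    per_sample = file.path(dir, "indices_per_sample.csv"),
    ri = file.path(dir, "ri_grade_counts.json")
  )
  utils::write.csv(report$per_metal, paths["per_metal"], row.names = FALSE)
  utils::write.csv(report$grade_proportions, paths["grades"], row.names = FALSE)
  utils::write.csv(report$per_sample, paths["per_sample"], row.names = FALSE)
  jsonlite::write_json(as.list(report$ri_grade_counts), paths["ri"],
                       auto_unbox = TRUE)
  invisible(paths)
}
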