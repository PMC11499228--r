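## Drift and mismatch quantification: distance fields between registered
## surfaces, RMS/mean/SD summaries, per-vertex heat-map export, and the
## cohort statistics (M +/- SD, paired differences, t tests) reported for a
## specimen series.

#' Distance field between a moving model and a reference surface
#'
#' Applies `t` to `moving`, computes each point's exact nearest distance to
#' the reference mesh, and summarizes.
#'
#' @param moving a `tri_mesh` (its vertices are measured) or `point_cloud`.
#' @param reference a `tri_mesh`.
#' @param t [rigid_transform()] applied to `moving` first (default identity).
#' @param metric `"point_to_mesh"` (default; exact nearest-surface distance)
#'   or `"point_to_point"` (corresponding-vertex displacement, requiring the
#'   same vertex count -- use when moving and reference share connectivity,
#'   e.g. to recover a known injected displacement; nearest-surface distances
#'   under-report translations whose direction is tangential to the surface).
#' @param source_label,target_label free-text labels carried in the report.
#' @return List of class `drift_report`: `distances` (mm per point), `rms`,
#'   `mean`, `sd`, `max`, labels.
#' @export
drift_field <- function(moving, reference, t = rigid_transform(),
                        metric = c("point_to_mesh", "point_to_point"),
                        source_label = "moving", target_label = "reference") {
  stopifnot(inherits(reference, "tri_mesh"))
  metric <- match.arg(metric)
  moved <- apply_transform(moving, t)
  d <- if (metric == "point_to_mesh") {
    nearest_distances(moved, reference)
  } else {
    mp <- .query_matrix(moved)
    if (nrow(mp) != nrow(reference$vertices))
      stop("point_to_point metric requires matching vertex counts")
    sqrt(rowSums((mp - reference$vertices)^2))
  }
  structure(list(distances = d, rms = rms(d), mean = mean(d),
                 sd = if (length(d) > 1) sd(d) else 0, max = max(d),
                 source_label = source_label, target_label = target_label),
            class = "drift_report")
}

#' @export
print.drift_report <- function(x, ...) {
  cat(sprintf("drift_report [%s -> %s]: rms %.4f mm, mean %.4f mm, sd %.4f mm, max %.4f mm (n=%d)\n",
              x$source_label, x$target_label, x$rms, x$mean, x$sd, x$max,
              length(x$distances)))
  invisible(x)
}

#' Skeletal drift residual to the surface registration
#'
#' The pre/postoperative surface registration is applied to the preoperative
#' skeletal model (the sub-matrix adjustment: bones ride along with the
#' surface alignment) and the remaining distance to the postoperative
#' skeletal model is the skeletal drift -- displacement of the bone over and
#' above what the surface explains.
#'
#' @param pre_bone,post_bone `tri_mesh` skeletal models.
#' @param surface_alignment [rigid_transform()] from the pre/post surface
#'   registration (pre -> post space).
#' @param metric distance convention, see [drift_field()].
#' @return A `drift_report`.
#' @export
skeletal_drift <- function(pre_bone, post_bone, surface_alignment,
                           metric = c("point_to_mesh", "point_to_point")) {
  stopifnot(inherits(pre_bone, "tri_mesh"), inherits(post_bone, "tri_mesh"))
  drift_field(pre_bone, post_bone, surface_alignment, metric = metric,
              source_label = "preoperative skeleton (surface-aligned)",
              target_label = "postoperative skeleton")
}

#' Cohort summary: M +/- SD
#'
#' Arithmetic mean and sample standard deviation (n-1 denominator), the
#' convention used for specimen-series results.
#'
#' @param values numeric vector (n >= 2), mm.
#' @return List of class `cohort_summary`: `n`, `mean`, `sd`.
#' @export
cohort_summary <- function(values) {
  values <- as.numeric(values)
  if (length(values) < 2L) stop("cohort summary needs at least 2 values")
  structure(list(n = length(values), mean = mean(values), sd = sd(values)),
            class = "cohort_summary")
}

#' Round half away from zero for display
#'
#' Display convention for reported tables (3 decimals, 0.0005 rounds up),
#' unlike R's banker's rounding. Raw values are never rounded internally.
#'
#' @param x numeric.
#' @param digits decimal places (default 3).
#' @return Rounded numeric.
#' @export
round_half_up <- function(x, digits = 3L) {
  p <- 10^digits
  sign(x) * floor(abs(x) * p + 0.5) / p
}

#' @export
print.cohort_summary <- function(x, ...) {
  cat(sprintf("%0.3f ± %0.3f (n = %d)\n",
              round_half_up(x$mean), round_half_up(x$sd), x$n))
  invisible(x)
}

#' @export
format.cohort_summary <- function(x, digits = 3L, ...) {
  sprintf(paste0("%.", digits, "f ± %.", digits, "f"),
          round_half_up(x$mean, digits), round_half_up(x$sd, digits))
}

#' Paired difference summary with t statistic
#'
#' Summarizes `a_i - b_i` as a cohort and reports the paired t statistic
#' with n-1 degrees of freedom and its two-sided p value.
#'
#' @param a,b numeric vectors of equal length (n >= 2), mm.
#' @return List of class `paired_summary`: `n`, `mean`, `sd`, `t`, `df`,
#'   `p_value` (`t` and `p_value` are `NA` when all differences are zero).
#' @export
paired_difference <- function(a, b) {
  a <- as.numeric(a); b <- as.numeric(b)
  if (length(a) != length(b)) stop("paired vectors must have equal length")
  if (length(a) < 2L) stop("paired difference needs at least 2 pairs")
  d <- a - b
  cs <- cohort_summary(d)
  if (cs$sd < 1e-300) {
    tstat <- NA_real_; pval <- NA_real_
  } else {
    tstat <- cs$mean / (cs$sd / sqrt(cs$n))
    pval <- 2 * pt(-abs(tstat), df = cs$n - 1L)
  }
  structure(list(n = cs$n, mean = cs$mean, sd = cs$sd,
                 t = tstat, df = cs$n - 1L, p_value = pval),
            class = "paired_summary")
}

#' @export
print.paired_summary <- function(x, ...) {
  cat(sprintf("paired difference: %.3f ± %.3f mm (n = %d), t(%d) = %s, p = %s\n",
              round_half_up(x$mean), round_half_up(x$sd), x$n, x$df,
              if (is.na(x$t)) "NA" else sprintf("%.3f", x$t),
              if (is.na(x$p_value)) "NA" else format.pval(x$p_value, digits = 3)))
  invisible(x)
}

#' One-sample t test against zero
#'
#' Auxiliary statistic for reporting that a cohort of drift values differs
#' from zero.
#'
#' @param values numeric vector (n >= 2).
#' @return List with `t`, `df`, `p_value`.
#' @export
t_against_zero <- function(values) {
  cs <- cohort_summary(values)
  tstat <- cs$mean / (cs$sd / sqrt(cs$n))
  list(t = tstat, df = cs$n - 1L, p_value = 2 * pt(-abs(tstat), df = cs$n - 1L))
}

#' Load the shipped specimen alignment/drift table
#'
#' Per-specimen RMS alignment errors and surface/skeletal drift values (mm)
#' for a 20-limb cadaver series: columns `specimen`, `rms_ct_sli`
#' (preoperative CT vs intraoperative SLI), `rms_ct_ct` (preoperative vs
#' postoperative CT), `surface_drift`, `skeletal_drift`.
#'
#' @param path optional path to an equivalent CSV; defaults to the shipped
#'   fixture.
#' @return A data.frame with 20 rows.
#' @export
read_drift_table <- function(path = NULL) {
  if (is.null(path))
    path <- system.file("extdata", "specimen_drift_table.csv", package = "punctnav")
  df <- read.csv(path)
  need <- c("specimen", "rms_ct_sli", "rms_ct_ct", "surface_drift", "skeletal_drift")
  if (!all(need %in% names(df))) stop("drift table lacks required columns")
  df
}

#' Summarize a specimen drift table
#'
#' Recomputes the cohort rows (M +/- SD per column) and the two paired
#' comparisons: pre/post CT alignment error minus CT/SLI alignment error, and
#' skeletal minus surface drift.
#'
#' @param df a data.frame as from [read_drift_table()].
#' @return List with `columns` (named list of `cohort_summary`) and `paired`
#'   (named list of `paired_summary`).
#' @export
summarize_drift_table <- function(df = read_drift_table()) {
  cols <- c("rms_ct_sli", "rms_ct_ct", "surface_drift", "skeletal_drift")
  columns <- lapply(cols, function(cn) cohort_summary(df[[cn]]))
  names(columns) <- cols
  paired <- list(
    ct_ct_minus_ct_sli = paired_difference(df$rms_ct_ct, df$rms_ct_sli),
    skeletal_minus_surface = paired_difference(df$skeletal_drift, df$surface_drift))
  list(columns = columns, paired = paired)
}

#' Export a per-vertex distance heat map as colored PLY
#'
#' Writes the mesh with the distances in the `quality` property and an 8-bit
#' blue-to-red color ramp clamped to `[ramp_min, ramp_max]`.
#'
#' @param mesh a `tri_mesh`.
#' @param distances numeric vector, one value per vertex, mm.
#' @param path output PLY path.
#' @param ramp_min,ramp_max clamp range, mm (default 0 to 1).
#' @param format `"binary"` or `"ascii"` PLY.
#' @return `path`, invisibly.
#' @export
export_heatmap <- function(mesh, distances, path, ramp_min = 0, ramp_max = 1,
                           format = c("binary", "ascii")) {
  stopifnot(inherits(mesh, "tri_mesh"))
  if (length(distances) != nrow(mesh$vertices))
    stop("distances count must equal vertex count")
  if (ramp_max <= ramp_min) stop("ramp_max must exceed ramp_min")
  cols <- heatmap_colors(distances, ramp_min, ramp_max)
  write_ply(mesh, path, format = match.arg(format), colors = cols,
            scalars = distances)
  invisible(path)
}

#' Map values to the 8-bit heat-map ramp
#'
#' Blue (cold, ramp minimum) through green to red (hot, ramp maximum);
#' values outside the range are clamped.
#'
#' @param values numeric vector.
#' @param ramp_min,ramp_max clamp range.
#' @return n x 3 integer matrix of RGB values in 0..255.
#' @export
heatmap_colors <- function(values, ramp_min = 0, ramp_max = 1) {
  t <- pmin(1, pmax(0, (values - ramp_min) / (ramp_max - ramp_min)))
  ramp <- grDevices::colorRamp(c("#0000ff", "#00ff00", "#ff0000"))(t)
  matrix(as.integer(round(ramp)), ncol = 3L)
}
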