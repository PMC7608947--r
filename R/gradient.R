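# Grain-diameter regressions, slope normalization, arc/row gradient tests.

#' Linear regression of response versus mean particle diameter
#'
#' Ordinary least squares of the (optionally per-point max-normalized) mean
#' feature value against mean particle diameter in um. The abscissa is the
#' diameter itself, not the P-number; set `log_diameter = TRUE` for a
#' log-abscissa variant.
#'
#' @param value Mean feature value per texture (>= 3 textures).
#' @param diameter Mean particle diameter per texture (um), distinct values.
#' @param normalize Divide the points by their maximum before fitting, so
#'   each whisker's curve peaks at 1.
#' @param log_diameter Regress on `log(diameter)` instead.
#' @return A `linear_fit`: list with `slope` (per um), `intercept`, `r2`,
#'   `n`.
#' @export
fit_grain_response <- function(value, diameter, normalize = TRUE,
                               log_diameter = FALSE) {
  if (length(value) != length(diameter))
    wp_abort("value and diameter lengths differ")
  if (length(unique(diameter)) < 3L)
    wp_abort("need at least 3 textures with distinct diameters")
  if (stats::var(diameter) == 0) wp_abort("zero diameter variance")
  y <- if (normalize) value / max(value) else value
  x <- if (log_diameter) log(diameter) else diameter
  fit <- stats::lm(y ~ x)
  rss <- sum(stats::residuals(fit)^2)
  tss <- sum((y - mean(y))^2)
  structure(list(slope = unname(stats::coef(fit)[2L]),
                 intercept = unname(stats::coef(fit)[1L]),
                 r2 = if (tss > 0) 1 - rss / tss else NA_real_,
                 n = length(y)),
            class = "linear_fit")
}

#' @export
print.linear_fit <- function(x, ...) {
  cat(sprintf("<linear_fit: slope %.4g per um, r2 %.3f, n = %d>\n",
              x$slope, if (is.na(x$r2)) NA else x$r2, x$n))
  invisible(x)
}

#' Normalize slopes to the arc-4 reference of each session
#'
#' Divides every slope by its session's arc-4 slope, so the rostral
#' reference whisker is exactly 1 and normalized slopes are comparable
#' across sessions.
#'
#' @param fits data.frame with columns `session`, `arc`, `slope` (extra
#'   columns pass through).
#' @param ref_arc Reference arc (default 4).
#' @return The input with an added `norm_slope` column.
#' @export
normalize_slopes <- function(fits, ref_arc = 4L) {
  if (!all(c("session", "arc", "slope") %in% names(fits)))
    wp_abort("fits must have columns session, arc, slope")
  out <- fits
  out$norm_slope <- NA_real_
  for (s in unique(fits$session)) {
    sel <- fits$session == s
    ref <- fits$slope[sel & fits$arc == ref_arc]
    if (length(ref) != 1L || !is.finite(ref) || ref == 0)
      wp_abort(sprintf("session '%s' has no usable arc-%d reference fit",
                       s, ref_arc))
    out$norm_slope[sel] <- fits$slope[sel] / ref
  }
  out
}

#' Neuronal grain-response slopes, normalized to the steepest unit
#'
#' For each unit, regresses its per-texture mean firing rate (max-normalized
#' per unit) on mean particle diameter; slopes are then normalized to the
#' steepest slope in the analyzed sample.
#'
#' @param rates Long data.frame with columns `unit_id`, `arc`, `condition`,
#'   `diameter_um`, `value` (trial firing rates or per-texture means).
#' @return data.frame `unit_id`, `arc`, `slope`, `r2`, `norm_slope` with
#'   `max(norm_slope) == 1`.
#' @export
fit_neuronal_response <- function(rates) {
  need <- c("unit_id", "arc", "condition", "diameter_um", "value")
  if (!all(need %in% names(rates)))
    wp_abort(sprintf("rates must have columns %s", paste(need, collapse = ", ")))
  rows <- lapply(split(rates, rates$unit_id), function(df) {
    agg <- stats::aggregate(value ~ condition + diameter_um, df, mean)
    fit <- fit_grain_response(agg$value, agg$diameter_um)
    data.frame(unit_id = df$unit_id[1L], arc = df$arc[1L],
               slope = fit$slope, r2 = fit$r2, stringsAsFactors = FALSE)
  })
  out <- do.call(rbind, rows)
  rownames(out) <- NULL
  steepest <- max(out$slope)
  if (!is.finite(steepest) || steepest == 0)
    wp_abort("no unit with a positive slope to normalize to")
  out$norm_slope <- out$slope / steepest
  out
}

#' One-way gradient ANOVA with Tukey contrasts
#'
#' One-way analysis of variance of a response grouped by arc (or row); when
#' the omnibus F test is significant at 0.05, Tukey's honest significant
#' difference method flags pairwise differences at the 0.05 and 0.01
#' levels.
#'
#' @param value Numeric response values.
#' @param group Group label per value (>= 2 groups with >= 2 values each).
#' @return A `gradient_test`: list with `f`, `p`, `groups`, and `tukey`
#'   (data.frame `pair`, `diff`, `p_adj`, `sig_05`, `sig_01`, or `NULL`
#'   when the omnibus test is not significant).
#' @export
arc_anova <- function(value, group) {
  group <- factor(group)
  if (nlevels(group) < 2L) wp_abort("need at least 2 groups")
  if (any(table(group) < 2L)) wp_abort("every group needs at least 2 values")
  fit <- stats::aov(value ~ group)
  tab <- summary(fit)[[1L]]
  f <- tab[["F value"]][1L]
  p <- tab[["Pr(>F)"]][1L]
  tukey <- NULL
  if (is.finite(p) && p < 0.05) {
    tk <- stats::TukeyHSD(fit)$group
    tukey <- data.frame(pair = rownames(tk), diff = tk[, "diff"],
                        p_adj = tk[, "p adj"],
                        sig_05 = tk[, "p adj"] < 0.05,
                        sig_01 = tk[, "p adj"] < 0.01,
                        stringsAsFactors = FALSE)
    rownames(tukey) <- NULL
  }
  structure(list(f = f, p = p, groups = levels(group), tukey = tukey),
            class = "gradient_test")
}

#' @export
print.gradient_test <- function(x, ...) {
  cat(sprintf("<gradient_test: F = %.3f, p = %.3g over groups %s>\n",
              x$f, x$p, paste(x$groups, collapse = ", ")))
  if (!is.null(x$tukey))
    cat(sprintf("  Tukey: %d/%d pairs significant at 0.05\n",
                sum(x$tukey$sig_05), nrow(x$tukey)))
  invisible(x)
}
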