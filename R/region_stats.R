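#' Extract per-subject tissue values at a peak and its mirror
#'
#' Reads each subject's smoothed, modulated tissue map at a peak world
#' coordinate and at the mirrored coordinate `(-x, y, z)` by
#' nearest-voxel sampling (the peak is a reported voxel location, so no
#' interpolation is applied). With `sphere_radius_mm > 0` a small-sphere
#' average around each location is returned instead of the single voxel.
#'
#' @param maps List of per-subject tissue `vol`s (smoothed modulated maps).
#' @param peak_mm World coordinate of the peak (length 3).
#' @param groups Character vector of group labels, one per subject.
#' @param sphere_radius_mm Optional averaging radius (default 0 = single
#'   voxel).
#' @return A `peak_extraction`: data.frame with columns `id`, `group`,
#'   `value_peak`, `value_mirror`, plus attributes `peak_mm` and
#'   `mirror_mm`. When the peak is on the right (`x > 0`), `value_peak` is
#'   the right-hemisphere value.
#' @export
extract_peak_values <- function(maps, peak_mm, groups,
                                sphere_radius_mm = 0) {
  if (length(maps) != length(groups))
    stop("'groups' must have one label per map")
  mirror_mm <- peak_mm * c(-1, 1, 1)
  sample_at <- function(v, xyz) {
    ijk <- world_to_voxel(v, xyz)  # errors if out of grid
    if (sphere_radius_mm <= 0)
      return(v$data[ijk[1] + 1L, ijk[2] + 1L, ijk[3] + 1L])
    d <- dim(v$data)
    vs <- voxel_sizes(v)
    r <- ceiling(sphere_radius_mm / vs)
    rng <- lapply(1:3, function(ax)
      max(0L, ijk[ax] - r[ax]):min(d[ax] - 1L, ijk[ax] + r[ax]))
    g <- as.matrix(expand.grid(rng))
    w <- voxel_to_world(v, g)
    keep <- rowSums(sweep(w, 2, xyz)^2) <= sphere_radius_mm^2
    mean(v$data[g[keep, , drop = FALSE] + 1L])
  }
  vp <- vapply(maps, sample_at, numeric(1), xyz = peak_mm)
  vm <- vapply(maps, sample_at, numeric(1), xyz = mirror_mm)
  ids <- if (!is.null(names(maps))) names(maps) else
    sprintf("s%02d", seq_along(maps))
  out <- data.frame(id = ids, group = groups, value_peak = vp,
                    value_mirror = vm, stringsAsFactors = FALSE)
  attr(out, "peak_mm") <- peak_mm
  attr(out, "mirror_mm") <- mirror_mm
  class(out) <- c("peak_extraction", "data.frame")
  out
}

#' Mixed Group-by-Hemisphere ANOVA at a peak, with LSD comparisons
#'
#' Two-way mixed-design ANOVA of the extracted peak values: Group is the
#' between-subject factor, Hemisphere (peak side vs mirror side) the
#' within-subject factor. The within-subject error stratum is
#' subject-within-group. Post-hoc LSD comparisons are plain (unadjusted)
#' t tests built on the ANOVA error terms: within-group hemisphere
#' contrasts use the within-subject mean square, between-group contrasts
#' at a fixed hemisphere use the pooled between+within error of a cell
#' comparison.
#'
#' @param extraction A `peak_extraction` from [extract_peak_values()].
#' @return List with `anova` (data.frame: effect, df1, df2, F, p),
#'   `lsd` (data.frame of pairwise comparisons), `cell_means`.
#' @export
anova_group_by_hemisphere <- function(extraction) {
  gr <- factor(extraction$group)
  if (any(table(gr) < 2)) stop("each group needs at least 2 subjects")
  n_g <- table(gr)
  long <- data.frame(
    id = factor(rep(extraction$id, 2)),
    group = factor(rep(extraction$group, 2)),
    hemisphere = factor(rep(c("peak", "mirror"), each = nrow(extraction))),
    value = c(extraction$value_peak, extraction$value_mirror))
  fit <- stats::aov(value ~ group * hemisphere + Error(id/hemisphere),
                    data = long)
  s <- summary(fit)
  between <- as.data.frame(s[["Error: id"]][[1]])
  within <- as.data.frame(s[["Error: id:hemisphere"]][[1]])
  rownames(between) <- trimws(rownames(between))
  rownames(within) <- trimws(rownames(within))
  ms_between_err <- between["Residuals", "Mean Sq"]
  df_between_err <- between["Residuals", "Df"]
  ms_within_err <- within["Residuals", "Mean Sq"]
  df_within_err <- within["Residuals", "Df"]
  an <- data.frame(
    effect = c("group", "hemisphere", "group:hemisphere"),
    ss = c(between["group", "Sum Sq"], within["hemisphere", "Sum Sq"],
           within["group:hemisphere", "Sum Sq"]),
    df1 = c(between["group", "Df"], within["hemisphere", "Df"],
            within["group:hemisphere", "Df"]),
    df2 = c(df_between_err, df_within_err, df_within_err),
    err_ss = c(between["Residuals", "Sum Sq"], within["Residuals", "Sum Sq"],
               within["Residuals", "Sum Sq"]),
    stringsAsFactors = FALSE)
  ss_total <- sum((long$value - mean(long$value))^2)
  ss_raw <- sum(long$value^2)
  an <- finalize_mixed_anova(an, ss_total = ss_total, ss_raw = ss_raw)
  ## treat numerically-zero error strata as exactly zero for the LSD step
  if (within["Residuals", "Sum Sq"] <= anova_zero_tol(ss_total, ss_raw))
    ms_within_err <- 0
  if (between["Residuals", "Sum Sq"] <= anova_zero_tol(ss_total, ss_raw))
    ms_between_err <- 0

  cm <- stats::aggregate(value ~ group + hemisphere, data = long, FUN = mean)
  getm <- function(g, h) cm$value[cm$group == g & cm$hemisphere == h]

  lsd <- NULL
  for (g in levels(gr)) {
    diff <- getm(g, "peak") - getm(g, "mirror")
    se <- sqrt(2 * ms_within_err / n_g[[g]])
    t <- if (se > 0) diff / se else if (diff == 0) 0 else
      stop("degenerate LSD: zero error term with a nonzero difference")
    lsd <- rbind(lsd, data.frame(
      comparison = sprintf("%s: peak - mirror", g),
      estimate = diff, t = t, df = df_within_err,
      p = 2 * stats::pt(-abs(t), df_within_err), stringsAsFactors = FALSE))
  }
  gl <- levels(gr)
  if (length(gl) == 2) {
    for (h in c("peak", "mirror")) {
      diff <- getm(gl[1], h) - getm(gl[2], h)
      ## cell comparison across groups mixes both error strata
      ms_cell <- (ms_between_err + ms_within_err) / 2
      se <- sqrt(ms_cell * (1 / n_g[[gl[1]]] + 1 / n_g[[gl[2]]]))
      df_cell <- df_between_err + df_within_err
      t <- diff / se
      lsd <- rbind(lsd, data.frame(
        comparison = sprintf("%s hemisphere: %s - %s", h, gl[1], gl[2]),
        estimate = diff, t = t, df = df_cell,
        p = 2 * stats::pt(-abs(t), df_cell), stringsAsFactors = FALSE))
    }
  }
  rownames(lsd) <- NULL
  list(anova = an, lsd = lsd, cell_means = cm)
}

## Numerical zero for aov sums of squares: relative to the centred total
## SS, with a floor relative to the raw scale of the data (constant data
## have ss_total == 0 but aov still reports ~1e-32 rounding noise).
anova_zero_tol <- function(ss_total, ss_raw = ss_total) {
  max(1e-9 * ss_total, 1e-12 * ss_raw, 1e-300)
}

## Shared F/p finishing for the mixed two-way ANOVAs: a zero-SS effect is a
## zero effect (F = 0) even over a zero error stratum; a nonzero effect
## over a zero error stratum has no valid test.
finalize_mixed_anova <- function(an, ss_total, ss_raw = ss_total) {
  tol <- anova_zero_tol(ss_total, ss_raw)
  an$F <- ifelse(an$ss <= tol, 0,
                 ifelse(an$err_ss <= tol, Inf,
                        (an$ss / an$df1) / (an$err_ss / an$df2)))
  if (any(!is.finite(an$F)))
    stop("degenerate ANOVA: zero error term with a nonzero effect (no within-cell variability)")
  an$p <- stats::pf(an$F, an$df1, an$df2, lower.tail = FALSE)
  an$ss <- NULL
  an$err_ss <- NULL
  an
}

#' Levene test for homogeneity of variance
#'
#' One-way ANOVA on the absolute deviations of each observation from its
#' group mean (the original mean-centered Levene form; the median-centered
#' Brown-Forsythe variant is available via `center`).
#'
#' @param values Numeric vector of observations.
#' @param groups Group labels (coercible to factor), same length.
#' @param center `"mean"` (default) or `"median"`.
#' @return List with `W` (the F statistic of the deviation ANOVA), `df1`,
#'   `df2`, `p`, `center`.
#' @examples
#' levene_test(c(1, 3, 2, 4), rep(c("a", "b"), each = 2))  # W = 0, p = 1
#' @export
levene_test <- function(values, groups, center = c("mean", "median")) {
  center <- match.arg(center)
  g <- factor(groups)
  if (nlevels(g) < 2) stop("need at least 2 groups")
  if (any(table(g) < 2)) stop("each group needs at least 2 values")
  if (stats::var(values) == 0)
    stop("degenerate input: all values identical")
  cfun <- if (center == "mean") mean else stats::median
  ctr <- tapply(values, g, cfun)
  dev <- abs(values - ctr[as.integer(g)])
  if (stats::var(dev) == 0) {
    ## all deviations equal (e.g. all-identical inputs per group)
    return(list(W = 0, df1 = nlevels(g) - 1,
                df2 = length(values) - nlevels(g), p = 1, center = center))
  }
  an <- stats::anova(stats::lm(dev ~ g))
  list(W = an$`F value`[1], df1 = an$Df[1], df2 = an$Df[2],
       p = an$`Pr(>F)`[1], center = center)
}
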