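#' Specify a synthetic two-group phantom cohort
#'
#' Describes a phantom study: a mirror-symmetric tissue template built from
#' smooth blobs, asymmetric effect blobs injected with per-group amplitudes,
#' spatially smooth subject noise, demographics, and an optional link from a
#' blob's asymmetry to a behavioral score. The defaults are a desk-scale
#' emulation of a two-group (14 + 14) adult reading study: a rightward
#' gray-matter excess in mid superior-temporal cortex present in controls
#' but absent in patients, and a left posterior superior-temporal
#' white-matter blob whose asymmetry drives the patients' monaural
#' speech-in-noise score.
#'
#' Blob profiles are compactly supported quartic bumps
#' `amplitude * (1 - (r/radius)^2)^2` where r is below the radius: smooth, and exactly
#' zero beyond `radius`, so symmetry and containment are easy to guarantee.
#'
#' @param grid_shape Voxel counts; the first (x) dimension should be odd so
#'   the mid-sagittal plane passes through voxel centres.
#' @param voxel_size_mm Isotropic voxel edge length in mm.
#' @param template_blobs List of template blobs, each
#'   `list(center_mm =, radius_mm =, amplitude =, tissue = "GM"|"WM")`.
#'   Off-midline blobs are automatically paired with their mirror so the
#'   template is exactly symmetric.
#' @param effect_blobs Named list of effect blobs, each
#'   `list(center_mm =, radius_mm =, amplitude = c(control =, patient =),
#'   subject_sd =, tissue =)`. The amplitude is added on the blob's own side
#'   only (the side of `center_mm`), creating a known asymmetry;
#'   `subject_sd` adds per-subject amplitude variability.
#' @param noise_fwhm_mm Smoothness of the subject noise field.
#' @param noise_sd Marginal standard deviation of the (smoothed) subject
#'   noise, in tissue units.
#' @param n_per_group Subjects per group.
#' @param age_mean,age_sd Length-2 vectors `(control, patient)` for the age
#'   distributions in years.
#' @param n_female Females per group (genders are coded 1 = female,
#'   0 = male, deterministically assigned).
#' @param behavior_link `NULL`, or `list(blob =, slope =, base =,
#'   noise_sd =, group =)`: for subjects of `group`, the monaural score is
#'   `base + slope * meanAI(blob)` plus Gaussian noise, truncated to the unit interval.
#' @param behavior_null Named list of `(mean, sd)` pairs per score column
#'   for subjects not covered by `behavior_link`.
#' @param ai_eps,ai_fwhm_mm Asymmetry-index parameters used when the
#'   generator needs blob-level AI values for the behavioral link.
#' @param seed RNG seed for [simulate_cohort()].
#' @return A `phantom_spec` object (a validated list).
#' @export
phantom_spec <- function(grid_shape = c(49, 49, 49),
                         voxel_size_mm = 2,
                         template_blobs = default_template_blobs(),
                         effect_blobs = default_effect_blobs(),
                         noise_fwhm_mm = 8,
                         noise_sd = 0.04,
                         n_per_group = 14,
                         age_mean = c(control = 26.07, patient = 23.29),
                         age_sd = c(control = 6.19, patient = 6.08),
                         n_female = 6,
                         behavior_link = default_behavior_link(),
                         behavior_null = default_behavior_null(),
                         ai_eps = 0.05,
                         ai_fwhm_mm = 10,
                         seed = 1L) {
  spec <- list(grid_shape = as.integer(grid_shape),
               voxel_size_mm = voxel_size_mm,
               template_blobs = template_blobs,
               effect_blobs = effect_blobs,
               noise_fwhm_mm = noise_fwhm_mm, noise_sd = noise_sd,
               n_per_group = as.integer(n_per_group),
               age_mean = age_mean, age_sd = age_sd,
               n_female = as.integer(n_female),
               behavior_link = behavior_link,
               behavior_null = behavior_null,
               ai_eps = ai_eps, ai_fwhm_mm = ai_fwhm_mm,
               seed = as.integer(seed))
  class(spec) <- "phantom_spec"
  validate_phantom_spec(spec)
  spec
}

#' @rdname phantom_spec
#' @export
default_template_blobs <- function() {
  list(
    list(center_mm = c(0, 0, 0), radius_mm = 42, amplitude = 0.55,
         tissue = "GM"),
    list(center_mm = c(0, 0, 0), radius_mm = 36, amplitude = 0.55,
         tissue = "WM")
  )
}

#' @rdname phantom_spec
#' @export
default_effect_blobs <- function() {
  list(
    ## Rightward GM excess in controls only (mid temporal cortex analogue).
    gm_right_sts = list(center_mm = c(24, -8, 0), radius_mm = 14,
                        amplitude = c(control = 0.18, patient = 0),
                        subject_sd = 0, tissue = "GM"),
    ## Leftward WM excess in both groups, with per-subject variability that
    ## the behavioral link converts into a score correlation in patients.
    wm_left_pstg = list(center_mm = c(-22, 12, 6), radius_mm = 12,
                        amplitude = c(control = 0.08, patient = 0.08),
                        subject_sd = 0.05, tissue = "WM")
  )
}

#' @rdname phantom_spec
#' @export
default_behavior_link <- function() {
  ## slope/base map the blob AI distribution (mean ~0.185, sd ~0.205 under
  ## the default spec) onto monaural scores of mean ~0.71, sd ~0.10
  list(blob = "wm_left_pstg", slope = 0.48, base = 0.62, noise_sd = 0.02,
       group = "patient", score = "score_monaural")
}

#' @rdname phantom_spec
#' @export
default_behavior_null <- function() {
  list(score_dichotic  = list(control = c(1.00, 0.00), patient = c(0.98, 0.03)),
       score_monaural  = list(control = c(0.80, 0.03), patient = c(0.71, 0.10)),
       score_spatialized = list(control = c(0.96, 0.03), patient = c(0.97, 0.03)))
}

validate_phantom_spec <- function(spec) {
  if (length(spec$grid_shape) != 3L || any(spec$grid_shape < 3L))
    stop("grid_shape must be 3 dimensions of at least 3 voxels")
  if (spec$n_per_group < 2L)
    stop("n_per_group must be at least 2")
  if (spec$n_female < 0L || spec$n_female > spec$n_per_group)
    stop("n_female must lie between 0 and n_per_group")
  half_extent <- spec$voxel_size_mm * (spec$grid_shape - 1) / 2
  for (b in c(spec$template_blobs, spec$effect_blobs)) {
    if (b$radius_mm <= 0) stop("blob radii must be positive")
    if (any(abs(b$center_mm) + b$radius_mm > half_extent + 1e-9))
      stop(sprintf("blob at (%g, %g, %g) with radius %g mm extends outside the grid",
                   b$center_mm[1], b$center_mm[2], b$center_mm[3],
                   b$radius_mm))
    if (!b$tissue %in% c("GM", "WM")) stop("blob tissue must be 'GM' or 'WM'")
  }
  if (!is.null(spec$behavior_link) &&
      !spec$behavior_link$blob %in% names(spec$effect_blobs))
    stop("behavior_link references unknown effect blob: ",
         spec$behavior_link$blob)
  invisible(spec)
}

## World-coordinate grids for a spec (one vector per axis).
spec_axes <- function(spec) {
  a <- centered_affine(spec$grid_shape, spec$voxel_size_mm)
  lapply(1:3, function(ax)
    a[ax, ax] * (seq_len(spec$grid_shape[ax]) - 1) + a[ax, 4])
}

## Quartic bump profile evaluated over the whole grid, as an array.
blob_profile <- function(spec, center_mm, radius_mm) {
  ax <- spec_axes(spec)
  dx2 <- (ax[[1]] - center_mm[1])^2
  dy2 <- (ax[[2]] - center_mm[2])^2
  dz2 <- (ax[[3]] - center_mm[3])^2
  r2 <- outer(outer(dx2, dy2, "+"), dz2, "+") / radius_mm^2
  p <- (1 - r2)^2
  p[r2 >= 1] <- 0
  p
}

#' Build the symmetric tissue template of a phantom spec
#'
#' Sums the spec's template blob profiles for one tissue class. Blobs
#' centred off the midline are paired with their mirror image, so the
#' result is exactly flip-invariant.
#'
#' @param spec A [phantom_spec()].
#' @param tissue `"GM"` or `"WM"`.
#' @return A `vol` with `template == flip_x(template)` bit-wise.
#' @export
make_symmetric_template <- function(spec, tissue = c("GM", "WM")) {
  tissue <- match.arg(tissue)
  validate_phantom_spec(spec)
  acc <- array(0, dim = spec$grid_shape)
  for (b in spec$template_blobs) {
    if (b$tissue != tissue) next
    acc <- acc + b$amplitude * blob_profile(spec, b$center_mm, b$radius_mm)
    if (abs(b$center_mm[1]) > 1e-12) {
      m <- b$center_mm * c(-1, 1, 1)
      acc <- acc + b$amplitude * blob_profile(spec, m, b$radius_mm)
    }
  }
  ## Symmetrize exactly: averaging with the index-reversed array removes
  ## any floating-point asymmetry from summation order.
  acc <- 0.5 * (acc + acc[dim(acc)[1]:1, , , drop = FALSE])
  vol(acc, centered_affine(spec$grid_shape, spec$voxel_size_mm),
      space_tag = "phantom")
}

## Smooth unit-variance Gaussian random field on the spec grid.
noise_field <- function(spec) {
  w <- array(stats::rnorm(prod(spec$grid_shape)), dim = spec$grid_shape)
  if (spec$noise_fwhm_mm > 0) {
    v <- smooth_gaussian(vol(w, centered_affine(spec$grid_shape,
                                                spec$voxel_size_mm)),
                         spec$noise_fwhm_mm)
    w <- v$data / smoothed_noise_sd_factor(spec$voxel_size_mm,
                                           spec$noise_fwhm_mm)
  }
  w
}

## Per-subject effect amplitudes, drawn once per subject.
draw_effect_amplitudes <- function(spec, group) {
  vapply(spec$effect_blobs, function(b) {
    a <- b$amplitude[[group]] +
      if (b$subject_sd > 0) stats::rnorm(1, 0, b$subject_sd) else 0
    a
  }, numeric(1))
}

#' Simulate one subject's tissue maps
#'
#' Subject map = symmetric template + one-sided effect blobs (the group's
#' amplitude, plus optional per-subject jitter) + spatially smooth Gaussian
#' noise, clipped at 0. Uses the current RNG state; draw order per subject
#' is: effect amplitudes (one normal per blob with `subject_sd > 0`), then
#' the GM noise field, then the WM noise field.
#'
#' @param spec A [phantom_spec()].
#' @param template_gm,template_wm Symmetric templates from
#'   [make_symmetric_template()].
#' @param group `"control"` or `"patient"`.
#' @param amplitudes Optional named amplitude vector overriding the random
#'   per-subject draw (used internally for truth bookkeeping).
#' @param tissues Which tissue maps to produce (default both).
#' @return A list with `gm` and `wm` (`vol`s, `NULL` if not requested) and
#'   `amplitudes`.
#' @export
simulate_subject <- function(spec, template_gm, template_wm, group,
                             amplitudes = NULL, tissues = c("GM", "WM")) {
  if (!group %in% c("control", "patient"))
    stop("unknown group label: ", group)
  tissues <- match.arg(tissues, several.ok = TRUE)
  if (is.null(amplitudes)) amplitudes <- draw_effect_amplitudes(spec, group)
  maps <- list(GM = if ("GM" %in% tissues) template_gm$data,
               WM = if ("WM" %in% tissues) template_wm$data)
  for (nm in names(spec$effect_blobs)) {
    b <- spec$effect_blobs[[nm]]
    if (is.null(maps[[b$tissue]])) next
    maps[[b$tissue]] <- maps[[b$tissue]] +
      amplitudes[[nm]] * one_sided_profile(spec, b)
  }
  for (tis in tissues) {
    x <- maps[[tis]] + spec$noise_sd * noise_field(spec)
    x[x < 0] <- 0
    maps[[tis]] <- x
  }
  aff <- centered_affine(spec$grid_shape, spec$voxel_size_mm)
  list(gm = if (!is.null(maps$GM)) vol(maps$GM, aff, "phantom"),
       wm = if (!is.null(maps$WM)) vol(maps$WM, aff, "phantom"),
       amplitudes = amplitudes)
}

## Effect profile restricted to the blob's own hemisphere (sign of center x).
one_sided_profile <- function(spec, b) {
  p <- blob_profile(spec, b$center_mm, b$radius_mm)
  if (abs(b$center_mm[1]) > 1e-12) {
    ax <- spec_axes(spec)[[1]]
    off_side <- if (b$center_mm[1] > 0) ax < 0 else ax > 0
    p[off_side, , ] <- 0
  }
  p
}

## Binary truth mask of an effect blob (profile above half maximum).
truth_mask <- function(spec, blob_name) {
  b <- spec$effect_blobs[[blob_name]]
  p <- one_sided_profile(spec, b)
  vol((p >= 0.5) + 0, centered_affine(spec$grid_shape, spec$voxel_size_mm),
      "phantom")
}

#' Simulate a full two-group phantom cohort
#'
#' Generates `n_per_group` controls and patients: demographics, tissue maps
#' via [simulate_subject()], and behavioral scores. The RNG is seeded once
#' from `spec$seed`; the stream order is ages (controls then patients),
#' then per-subject maps in table order, then behavioral scores in table
#' order, so any fixed seed reproduces the cohort bit for bit.
#'
#' Behavioral scores: subjects covered by `behavior_link` get
#' `base + slope * meanAI` over the linked blob (AI computed from the
#' subject's own smoothed asymmetry map) plus noise; all other
#' subject/score combinations are drawn from `behavior_null`. All scores
#' are truncated to the unit interval.
#'
#' @param spec A [phantom_spec()].
#' @param tissues Tissue maps to generate (default both); generating a
#'   single tissue halves the cost when only one is analysed.
#' @return A `cohort`: list with `subjects` (data.frame: id, group, age,
#'   gender, score_dichotic, score_monaural, score_spatialized), `gm_maps`,
#'   `wm_maps` (lists of `vol`s), `templates`, `truth` (injected
#'   parameters, per-subject amplitudes, truth masks), and `spec`.
#' @export
simulate_cohort <- function(spec, tissues = c("GM", "WM")) {
  validate_phantom_spec(spec)
  tissues <- match.arg(tissues, several.ok = TRUE)
  set.seed(spec$seed)
  n <- spec$n_per_group
  groups <- rep(c("control", "patient"), each = n)
  ids <- sprintf("%s%02d", ifelse(groups == "control", "C", "P"),
                 rep(seq_len(n), 2))
  ages <- c(stats::rnorm(n, spec$age_mean[["control"]], spec$age_sd[["control"]]),
            stats::rnorm(n, spec$age_mean[["patient"]], spec$age_sd[["patient"]]))
  ages <- pmax(18, ages)
  gender <- rep(c(rep(1L, spec$n_female), rep(0L, n - spec$n_female)), 2)

  template_gm <- make_symmetric_template(spec, "GM")
  template_wm <- make_symmetric_template(spec, "WM")

  gm_maps <- vector("list", 2 * n)
  wm_maps <- vector("list", 2 * n)
  amps <- matrix(NA_real_, 2 * n, length(spec$effect_blobs),
                 dimnames = list(ids, names(spec$effect_blobs)))
  for (i in seq_along(ids)) {
    s <- simulate_subject(spec, template_gm, template_wm, groups[i],
                          tissues = tissues)
    gm_maps[i] <- list(s$gm)  # keeps NULL placeholders when a tissue is skipped
    wm_maps[i] <- list(s$wm)
    if (length(spec$effect_blobs)) amps[i, ] <- s$amplitudes
  }
  names(gm_maps) <- names(wm_maps) <- ids

  subjects <- data.frame(id = ids, group = groups, age = ages,
                         gender = gender, stringsAsFactors = FALSE)
  link <- spec$behavior_link
  link_ai <- rep(NA_real_, 2 * n)
  if (!is.null(link)) {
    b <- spec$effect_blobs[[link$blob]]
    if (!b$tissue %in% tissues) {
      link <- NULL  # linked tissue not generated; scores fall back to null
    } else {
      tmask <- truth_mask(spec, link$blob)$data > 0
      maps <- if (b$tissue == "GM") gm_maps else wm_maps
      for (i in seq_along(ids)) {
        am <- smooth_ai(compute_ai(maps[[i]], eps = spec$ai_eps),
                        spec$ai_fwhm_mm)
        link_ai[i] <- mean(am$ai$data[tmask])
      }
    }
  }
  for (score in names(spec$behavior_null)) {
    vals <- numeric(2 * n)
    for (i in seq_along(ids)) {
      if (!is.null(link) && score == link$score && groups[i] == link$group) {
        vals[i] <- link$base + link$slope * link_ai[i] +
          stats::rnorm(1, 0, link$noise_sd)
      } else {
        ms <- spec$behavior_null[[score]][[groups[i]]]
        vals[i] <- if (ms[2] > 0) stats::rnorm(1, ms[1], ms[2]) else ms[1]
      }
    }
    subjects[[score]] <- pmin(1, pmax(0, vals))
  }

  truth <- list(effect_blobs = spec$effect_blobs,
                amplitudes = amps,
                link = link,
                link_ai = link_ai,
                masks = lapply(names(spec$effect_blobs),
                               function(nm) truth_mask(spec, nm)))
  names(truth$masks) <- names(spec$effect_blobs)

  structure(list(subjects = subjects, gm_maps = gm_maps, wm_maps = wm_maps,
                 templates = list(GM = template_gm, WM = template_wm),
                 truth = truth, spec = spec),
            class = "cohort")
}

#' @export
print.cohort <- function(x, ...) {
  cat(sprintf("<cohort> %d subjects (%d control, %d patient), grid %s at %g mm\n",
              nrow(x$subjects), sum(x$subjects$group == "control"),
              sum(x$subjects$group == "patient"),
              paste(x$spec$grid_shape, collapse = "x"),
              x$spec$voxel_size_mm))
  invisible(x)
}

#' Write a cohort to disk
#'
#' Writes one NIfTI per subject and tissue, the subject table as CSV, and
#' the injected truth parameters as YAML.
#'
#' @param cohort A `cohort` from [simulate_cohort()].
#' @param dir Output directory (created if needed).
#' @return `dir`, invisibly.
#' @export
write_cohort <- function(cohort, dir) {
  dir.create(dir, recursive = TRUE, showWarnings = FALSE)
  utils::write.csv(cohort$subjects, file.path(dir, "subjects.csv"),
                   row.names = FALSE)
  for (i in seq_len(nrow(cohort$subjects))) {
    id <- cohort$subjects$id[i]
    if (!is.null(cohort$gm_maps[[i]]))
      write_volume(cohort$gm_maps[[i]], file.path(dir, paste0(id, "_gm.nii.gz")))
    if (!is.null(cohort$wm_maps[[i]]))
      write_volume(cohort$wm_maps[[i]], file.path(dir, paste0(id, "_wm.nii.gz")))
  }
  truth <- cohort$truth
  yaml::write_yaml(list(
    effect_blobs = lapply(truth$effect_blobs, function(b)
      list(center_mm = as.numeric(b$center_mm), radius_mm = b$radius_mm,
           amplitude = as.list(b$amplitude), subject_sd = b$subject_sd,
           tissue = b$tissue)),
    amplitudes = as.data.frame(truth$amplitudes),
    link = truth$link), file.path(dir, "truth.yaml"))
  invisible(dir)
}
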