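# Shared fixtures: small volumes and phantom specs built in code.

# Volume with a single nonzero voxel (1-based index).
delta_vol <- function(dim = c(9, 9, 9), at = (dim + 1) / 2, value = 1,
                      voxel_size = 1) {
  a <- array(0, dim = dim)
  a[at[1], at[2], at[3]] <- value
  vol(a, centered_affine(dim, voxel_size))
}

random_vol <- function(dim = c(7, 7, 7), voxel_size = 1) {
  vol(array(runif(prod(dim)), dim = dim), centered_affine(dim, voxel_size))
}

# Tiny phantom spec: the GM template is a mirrored blob pair whose value is
# exactly 0.5 at the effect centre (20, 0, 0); one right-sided GM effect
# blob; cheap to simulate.
tiny_spec <- function(amp_control = 0.15, amp_patient = 0, subject_sd = 0,
                      noise_sd = 0.03, n_per_group = 6, seed = 1,
                      behavior_link = NULL, ...) {
  phantom_spec(
    grid_shape = c(25, 25, 25), voxel_size_mm = 4,
    template_blobs = list(
      list(center_mm = c(20, 0, 0), radius_mm = 14, amplitude = 0.5,
           tissue = "GM"),
      list(center_mm = c(0, 0, 0), radius_mm = 44, amplitude = 0.5,
           tissue = "WM")),
    effect_blobs = list(
      gm_right = list(center_mm = c(20, 0, 0), radius_mm = 14,
                      amplitude = c(control = amp_control,
                                    patient = amp_patient),
                      subject_sd = subject_sd, tissue = "GM")),
    noise_fwhm_mm = 8, noise_sd = noise_sd,
    n_per_group = n_per_group, n_female = floor(n_per_group / 2),
    behavior_link = behavior_link, seed = seed, ...)
}

# Mixed two-way ANOVA oracle: brute-force sums-of-squares decomposition for
# a complete Group (between) x Condition (within) design.
# df columns: id, group, cond, y.
mixed_anova_oracle <- function(df) {
  g_mean <- mean(df$y)
  subj_means <- tapply(df$y, df$id, mean)
  group_of <- tapply(as.character(df$group), df$id, `[`, 1)
  group_means <- tapply(df$y, df$group, mean)
  cond_means <- tapply(df$y, df$cond, mean)
  cell_means <- tapply(df$y, list(df$group, df$cond), mean)
  n_cond <- length(unique(df$cond))
  n_subj_g <- table(group_of)

  ss_group <- n_cond * sum(n_subj_g * (group_means - g_mean)^2)
  ss_subj_within <- n_cond *
    sum((subj_means - group_means[group_of])^2)
  n_total_subj <- length(subj_means)
  ss_cond <- n_total_subj * sum((cond_means - g_mean)^2)
  ss_int <- 0
  for (g in rownames(cell_means)) for (cc in colnames(cell_means))
    ss_int <- ss_int + n_subj_g[[g]] *
      (cell_means[g, cc] - group_means[[g]] - cond_means[[cc]] + g_mean)^2
  ss_total <- sum((df$y - g_mean)^2)
  ss_err <- ss_total - ss_group - ss_subj_within - ss_cond - ss_int

  df_group <- length(n_subj_g) - 1
  df_subj <- n_total_subj - length(n_subj_g)
  df_cond <- n_cond - 1
  df_int <- df_group * df_cond
  df_err <- df_subj * df_cond
  list(
    F_group = (ss_group / df_group) / (ss_subj_within / df_subj),
    F_cond = (ss_cond / df_cond) / (ss_err / df_err),
    F_int = (ss_int / df_int) / (ss_err / df_err),
    df = c(group = df_group, subj = df_subj, cond = df_cond,
           int = df_int, err = df_err),
    ss = c(group = ss_group, subj = ss_subj_within, cond = ss_cond,
           int = ss_int, err = ss_err, total = ss_total))
}
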