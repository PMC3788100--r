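# Small deterministic map sets for permutation tests.
maps_from_matrix <- function(Y, dim) {
  lapply(seq_len(nrow(Y)), function(i)
    vol(array(Y[i, ], dim = dim), centered_affine(dim, 1)))
}

test_that("exhaustive sign-flip p matches brute-force enumeration (n = 4)", {
  set.seed(31)
  y <- c(0.8, 1.3, 0.7, 1.1)   # single voxel, 4 subjects
  maps <- maps_from_matrix(matrix(y, 4, 1), c(1, 1, 1))
  subjects <- data.frame(id = 1:4)
  des <- glm_design(subjects, "one_sample", covariates = character())

  res <- permutation_fwe(maps, des, B = 15, seed = 1)  # 2^4 - 1: exhaustive
  expect_equal(res$n_permutations, 15)

  # oracle: every one of the 16 sign patterns
  tstat <- function(v) mean(v) / (sd(v) / sqrt(length(v)))
  signs <- as.matrix(expand.grid(rep(list(c(1, -1)), 4)))
  t_all <- apply(signs, 1, function(s) tstat(s * y))
  t_obs <- tstat(y)
  p_oracle <- mean(t_all >= t_obs)
  expect_equal(res$voxel_p_fwe$data[1, 1, 1], p_oracle)

  expect_warning(permutation_fwe(maps, des, B = 50, seed = 1),
                 "reduced to exhaustive")
})

test_that("a dominant observed statistic attains the p floor 1/(B+1)", {
  set.seed(32)
  n <- 12
  dimv <- c(7, 7, 7)
  Y <- matrix(rnorm(n * prod(dimv), sd = 0.05), n)
  blob <- 172:176                       # a few central voxels
  Y[1:6, blob] <- Y[1:6, blob] + 5      # controls hugely elevated
  subjects <- data.frame(id = 1:n,
                         group = rep(c("control", "patient"), each = 6))
  des <- glm_design(subjects, "two_sample", covariates = character())
  res <- permutation_fwe(maps_from_matrix(Y, dimv), des, B = 99, seed = 2)
  expect_equal(min(res$voxel_p_fwe$data, na.rm = TRUE), 1 / 100)
  expect_equal(min(res$clusters$p_cluster_fwe), 1 / 100)
  expect_true(any(res$clusters$significant))
})

test_that("swapping the groups wholesale exactly negates the t map", {
  set.seed(33)
  n <- 10
  Y <- matrix(rnorm(n * 27), n)
  subjects <- data.frame(id = 1:n,
                         group = rep(c("control", "patient"), each = 5))
  swapped <- subjects
  swapped$group <- rev(subjects$group)
  des1 <- glm_design(subjects, "two_sample", covariates = character())
  des2 <- glm_design(swapped, "two_sample", covariates = character())
  f1 <- fit_glm_t(maps_from_matrix(Y, c(3, 3, 3)), des1)
  f2 <- fit_glm_t(maps_from_matrix(Y, c(3, 3, 3)), des2)
  expect_equal(f1$t_map$data, -f2$t_map$data, tolerance = 1e-12)
})

test_that("permutation results are deterministic in the seed", {
  sp <- tiny_spec(noise_sd = 0.03, seed = 41)
  co <- simulate_cohort(sp, tissues = "GM")
  ai <- lapply(co$gm_maps, function(x) smooth_ai(compute_ai(x), 8))
  des <- glm_design(co$subjects, "two_sample")
  r1 <- permutation_fwe(ai, des, B = 49, seed = 9)
  r2 <- permutation_fwe(ai, des, B = 49, seed = 9)
  expect_identical(r1$null_max_t, r2$null_max_t)
  expect_identical(r1$clusters, r2$clusters)
  r3 <- permutation_fwe(ai, des, B = 49, seed = 10)
  expect_false(identical(r1$null_max_t, r3$null_max_t))
  # the attainable p floor rises as B falls
  r4 <- permutation_fwe(ai, des, B = 19, seed = 9)
  expect_gte(min(r4$voxel_p_fwe$data, na.rm = TRUE), 1 / 20)
  expect_gte(min(r1$voxel_p_fwe$data, na.rm = TRUE), 1 / 50)
})

test_that("restricting to the whole mask reproduces the whole-brain result", {
  sp <- tiny_spec(noise_sd = 0.03, seed = 43)
  co <- simulate_cohort(sp, tissues = "GM")
  ai <- lapply(co$gm_maps, function(x) smooth_ai(compute_ai(x), 8))
  des <- glm_design(co$subjects, "two_sample")
  whole <- permutation_fwe(ai, des, B = 49, seed = 4)
  svc <- small_volume_correct(ai, des, whole$mask, B = 49, seed = 4)
  expect_equal(svc$clusters, whole$clusters)
  expect_equal(svc$voxel_p_fwe$data, whole$voxel_p_fwe$data)
})

test_that("an ROI that excludes the effect removes its clusters", {
  sp <- tiny_spec(amp_control = 0.3, noise_sd = 0.02, n_per_group = 8,
                  seed = 44)
  co <- simulate_cohort(sp, tissues = "GM")
  ai <- lapply(co$gm_maps, function(x) smooth_ai(compute_ai(x), 8))
  des <- glm_design(co$subjects, "two_sample")
  whole <- permutation_fwe(ai, des, B = 99, seed = 5)
  expect_true(any(whole$clusters$side == "right"))  # blob found at x > 0

  left_roi <- whole$mask
  nx <- dim(left_roi$data)[1]
  left_roi$data[((nx + 1) / 2):nx, , ] <- 0         # keep x < 0 only
  svc <- small_volume_correct(ai, des, left_roi, B = 99, seed = 5)
  expect_true(all(svc$clusters$side == "left") || nrow(svc$clusters) == 0)

  expect_error(small_volume_correct(ai, des, vol(array(0, dim = dim(left_roi$data)),
                                                 left_roi$affine)),
               "empty")
})

test_that("small-volume p at the peak never exceeds the whole-brain p", {
  # the SVC maximum is over a subset, so with matched permutations the
  # corrected p at any voxel inside the ROI is <= the whole-brain p
  for (s in 1:3) {
    sp <- tiny_spec(amp_control = 0.2, noise_sd = 0.03, seed = 50 + s)
    co <- simulate_cohort(sp, tissues = "GM")
    ai <- lapply(co$gm_maps, function(x) smooth_ai(compute_ai(x), 8))
    des <- glm_design(co$subjects, "two_sample")
    whole <- permutation_fwe(ai, des, B = 49, seed = s)
    roi <- whole$mask
    nx <- dim(roi$data)[1]
    roi$data[1:((nx - 1) / 2), , ] <- 0             # right half only
    svc <- small_volume_correct(ai, des, roi, B = 49, seed = s)
    inroi <- !is.na(svc$voxel_p_fwe$data)
    expect_true(all(svc$voxel_p_fwe$data[inroi] <=
                      whole$voxel_p_fwe$data[inroi]))
  }
})

test_that("freedman-lane correlation inference recovers a strong link", {
  link <- list(blob = "gm_right", slope = 0.6, base = 0.5, noise_sd = 0.01,
               group = "patient", score = "score_monaural")
  sp <- tiny_spec(amp_control = 0.1, amp_patient = 0.1, subject_sd = 0.06,
                  noise_sd = 0.02, n_per_group = 12, seed = 45,
                  behavior_link = link)
  co <- simulate_cohort(sp, tissues = "GM")
  pat <- which(co$subjects$group == "patient")
  ai <- lapply(co$gm_maps[pat], function(x) smooth_ai(compute_ai(x), 8))
  des <- glm_design(co$subjects[pat, ], "covariate",
                    covariate = "score_monaural")
  expect_equal(des$scheme, "freedman_lane")
  res <- permutation_fwe(ai, des, B = 99, seed = 6)
  sig <- res$clusters[res$clusters$significant, , drop = FALSE]
  expect_gt(nrow(sig), 0)
  expect_true(any(sig$side == "right"))
})

test_that("invalid schemes and probabilities are rejected", {
  sp <- tiny_spec(n_per_group = 3, seed = 46)
  co <- simulate_cohort(sp, tissues = "GM")
  ai <- lapply(co$gm_maps, function(x) compute_ai(x))
  des <- glm_design(co$subjects, "two_sample")
  expect_error(permutation_fwe(ai, des, scheme = "bootstrap"),
               "unknown permutation scheme")
  expect_error(permutation_fwe(ai, des, cluster_forming_p = 0), "0, 1")
  expect_error(permutation_fwe(ai, des, B = 0), "at least 1")
})
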