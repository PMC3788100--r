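test_that("peak extraction reads mirrored voxel pairs", {
  d <- c(9, 9, 9)
  v <- vol(array(0.5, dim = d), centered_affine(d, 2))
  pk <- world_to_voxel(v, c(6, 0, 0)) + 1L
  mr <- world_to_voxel(v, c(-6, 0, 0)) + 1L
  v$data[pk[1], pk[2], pk[3]] <- 0.6
  v$data[mr[1], mr[2], mr[3]] <- 0.4
  sym <- vol(array(0.5, dim = d), centered_affine(d, 2))

  ex <- extract_peak_values(list(a = v, b = sym), c(6, 0, 0),
                            groups = c("control", "patient"))
  expect_equal(ex$value_peak, c(0.6, 0.5))
  expect_equal(ex$value_mirror, c(0.4, 0.5))
  expect_equal(attr(ex, "mirror_mm"), c(-6, 0, 0))
  expect_error(extract_peak_values(list(v), c(500, 0, 0), "control"),
               "outside")
})

test_that("sphere averaging reduces to the voxel value on constant maps", {
  d <- c(9, 9, 9)
  v <- vol(array(0.3, dim = d), centered_affine(d, 2))
  ex <- extract_peak_values(list(v), c(4, 0, 0), "control",
                            sphere_radius_mm = 4)
  expect_equal(ex$value_peak, 0.3)
})

test_that("group-by-hemisphere ANOVA matches the brute-force decomposition", {
  # toy table: controls asymmetric (peak > mirror), patients flat
  set.seed(60)
  n <- 6
  ctl_peak <- 0.6 + rnorm(n, 0, 0.02)
  ctl_mirr <- 0.4 + rnorm(n, 0, 0.02)
  pat_peak <- 0.5 + rnorm(n, 0, 0.02)
  pat_mirr <- 0.5 + rnorm(n, 0, 0.02)
  ex <- data.frame(id = c(sprintf("c%d", 1:n), sprintf("p%d", 1:n)),
                   group = rep(c("control", "patient"), each = n),
                   value_peak = c(ctl_peak, pat_peak),
                   value_mirror = c(ctl_mirr, pat_mirr))
  res <- anova_group_by_hemisphere(ex)

  long <- data.frame(id = rep(ex$id, 2), group = rep(ex$group, 2),
                     cond = rep(c("peak", "mirror"), each = nrow(ex)),
                     y = c(ex$value_peak, ex$value_mirror))
  oracle <- mixed_anova_oracle(long)
  an <- res$anova
  expect_equal(an$F[an$effect == "group"], oracle$F_group, tolerance = 1e-9)
  expect_equal(an$F[an$effect == "hemisphere"], oracle$F_cond,
               tolerance = 1e-9)
  expect_equal(an$F[an$effect == "group:hemisphere"], oracle$F_int,
               tolerance = 1e-9)
  expect_equal(an$df2[an$effect == "group:hemisphere"],
               unname(oracle$df["err"]))

  # the asymmetric pattern: interaction present, controls' LSD significant,
  # patients' not
  expect_lt(an$p[an$effect == "group:hemisphere"], 0.05)
  lsd <- res$lsd
  expect_lt(lsd$p[lsd$comparison == "control: peak - mirror"], 0.01)
  expect_gt(lsd$p[lsd$comparison == "patient: peak - mirror"], 0.05)
})

test_that("hemisphere-flat data yield zero hemisphere and interaction F", {
  set.seed(61)
  vals <- rnorm(8, 0.5, 0.05)
  ex <- data.frame(id = sprintf("s%d", 1:8),
                   group = rep(c("control", "patient"), each = 4),
                   value_peak = vals, value_mirror = vals)
  res <- anova_group_by_hemisphere(ex)
  an <- res$anova
  expect_equal(an$F[an$effect == "hemisphere"], 0)
  expect_equal(an$F[an$effect == "group:hemisphere"], 0)
  lsd <- res$lsd
  expect_equal(lsd$p[lsd$comparison == "control: peak - mirror"], 1)

  # zero error term under a real cell difference has no valid test
  # (exactly representable values so the zero strata are exact)
  ex2 <- data.frame(id = sprintf("s%d", 1:8),
                    group = rep(c("control", "patient"), each = 4),
                    value_peak = rep(c(3, 1), each = 4),
                    value_mirror = rep(c(1, 1), each = 4))
  expect_error(anova_group_by_hemisphere(ex2), "degenerate")

  ex3 <- ex2[c(1, 5), ]   # a group with < 2 subjects
  expect_error(anova_group_by_hemisphere(ex3), "at least 2")
})

test_that("interaction F is invariant to shifts and joint hemisphere swap", {
  set.seed(62)
  ex <- data.frame(id = sprintf("s%d", 1:10),
                   group = rep(c("control", "patient"), each = 5),
                   value_peak = rnorm(10, 0.6, 0.05),
                   value_mirror = rnorm(10, 0.45, 0.05))
  f0 <- anova_group_by_hemisphere(ex)$anova
  ex_shift <- ex
  ex_shift$value_peak <- ex$value_peak + 5
  ex_shift$value_mirror <- ex$value_mirror + 5
  f1 <- anova_group_by_hemisphere(ex_shift)$anova
  ex_swap <- ex
  ex_swap$value_peak <- ex$value_mirror
  ex_swap$value_mirror <- ex$value_peak
  f2 <- anova_group_by_hemisphere(ex_swap)$anova
  int <- function(a) a$F[a$effect == "group:hemisphere"]
  expect_equal(int(f1), int(f0), tolerance = 1e-9)
  expect_equal(int(f2), int(f0), tolerance = 1e-9)
})

test_that("levene test: hand-computed case, null case, and power case", {
  # groups {1,3} and {2,4}: all absolute deviations equal 1 -> W = 0, p = 1
  r <- levene_test(c(1, 3, 2, 4), rep(c("a", "b"), each = 2))
  expect_equal(r$W, 0)
  expect_equal(r$p, 1)

  # identically drawn groups: W = 0 exactly when samples coincide
  x <- c(0.1, 0.5, 0.9)
  r2 <- levene_test(c(x, x), rep(c("a", "b"), each = 3))
  expect_equal(r2$W, 0, tolerance = 1e-12)

  # 10x spread difference, n = 50 per group: overwhelmingly significant
  set.seed(63)
  g1 <- rnorm(50, 0, 1)
  g2 <- rnorm(50, 0, 10)
  r3 <- levene_test(c(g1, g2), rep(c("a", "b"), each = 50))
  expect_lt(r3$p, 0.01)
  expect_error(levene_test(c(1, 1, 1, 1), rep(c("a", "b"), each = 2)))
})

test_that("levene test agrees with the car implementation", {
  skip_if_not_installed("car")
  set.seed(64)
  vals <- c(rnorm(12, 0, 1), rnorm(15, 0, 2.5))
  grp <- rep(c("a", "b"), c(12, 15))
  mine <- levene_test(vals, grp, center = "mean")
  ref <- car::leveneTest(vals ~ factor(grp), center = mean)
  expect_equal(mine$W, ref$`F value`[1], tolerance = 1e-10)
  expect_equal(mine$p, ref$`Pr(>F)`[1], tolerance = 1e-10)
  mine_med <- levene_test(vals, grp, center = "median")
  ref_med <- car::leveneTest(vals ~ factor(grp), center = median)
  expect_equal(mine_med$W, ref_med$`F value`[1], tolerance = 1e-10)
})
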