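make_maps <- function(Yvox, dim = c(5, 5, 5)) {
  # Yvox: n x V matrix of voxel data, V = prod(dim)
  lapply(seq_len(nrow(Yvox)), function(i)
    vol(array(Yvox[i, ], dim = dim), centered_affine(dim, 1)))
}

test_that("mass-univariate t maps match a per-voxel lm oracle", {
  set.seed(21)
  n <- 10
  dimv <- c(5, 5, 5)
  V <- prod(dimv)
  subjects <- data.frame(
    id = sprintf("s%02d", 1:n),
    group = rep(c("control", "patient"), each = n / 2),
    age = rnorm(n, 25, 5), gender = rep(c(0, 1), n / 2),
    score_monaural = runif(n))
  Y <- matrix(rnorm(n * V), n, V)
  for (kind in c("one_sample", "two_sample", "covariate")) {
    des <- glm_design(subjects, kind, covariate = "score_monaural")
    fit <- fit_glm_t(make_maps(Y, dimv), des)
    t_pkg <- as.vector(fit$t_map$data)
    # independent oracle: per-voxel lm with the same model
    t_ref <- vapply(seq_len(V), function(j) {
      d <- cbind(subjects, y = Y[, j])
      if (kind == "one_sample") {
        m <- lm(y ~ 1 + scale(age, scale = FALSE) +
                  scale(gender, scale = FALSE), data = d)
        unname(coef(summary(m))["(Intercept)", "t value"])
      } else if (kind == "two_sample") {
        m <- lm(y ~ 0 + group + scale(age, scale = FALSE) +
                  scale(gender, scale = FALSE), data = d)
        ct <- c(1, -1, 0, 0)
        v <- vcov(m)
        unname(sum(ct * coef(m)) / sqrt(drop(t(ct) %*% v %*% ct)))
      } else {
        m <- lm(y ~ scale(score_monaural, scale = FALSE) +
                  scale(age, scale = FALSE) +
                  scale(gender, scale = FALSE), data = d)
        unname(coef(summary(m))[2, "t value"])
      }
    }, numeric(1))
    expect_lt(max(abs(t_pkg - t_ref)), 1e-10)
    expect_equal(fit$df, n - ncol(des$X))
  }
})

test_that("two-sample t on {1..6} split in halves matches the hand value", {
  subjects <- data.frame(id = letters[1:6],
                         group = rep(c("control", "patient"), each = 3))
  Y <- matrix(1:6, 6, 1)
  des <- glm_design(subjects, "two_sample", covariates = character())
  fit <- fit_glm_t(make_maps(matrix(rep(1:6, 1), 6, 1), dim = c(1, 1, 1)),
                   des)
  expect_equal(fit$t_map$data[1, 1, 1], -3.674, tolerance = 1e-3)
  expect_equal(fit$df, 4)
})

test_that("degenerate voxels are excluded; pure-zero voxels give t = 0", {
  set.seed(22)
  n <- 8
  dimv <- c(3, 3, 3)
  Y <- matrix(rnorm(n * prod(dimv)), n)
  Y[, 1] <- 5          # identical across subjects: zero residual variance
  Y[, 2] <- 0          # all-zero voxel: t = 0
  subjects <- data.frame(id = 1:n, group = rep(c("control", "patient"), 4))
  des <- glm_design(subjects, "one_sample", covariates = character())
  fit <- fit_glm_t(make_maps(Y, dimv), des)
  expect_equal(fit$mask$data[1, 1, 1], 0)      # excluded
  expect_true(is.na(fit$t_map$data[1, 1, 1]))
  expect_equal(fit$t_map$data[2, 1, 1], 0)     # defined, exactly 0
})

test_that("rank-deficient designs are rejected", {
  subjects <- data.frame(id = 1:6, group = rep("control", 6),
                         age = rnorm(6), gender = rep(1, 6))
  expect_error(glm_design(subjects, "one_sample"), "rank deficient")
})

test_that("summary-statistic t reproduces printed group comparisons", {
  # age row: groups of 14, means 23.29 / 26.07, sds 6.08 / 6.19 -> p 0.241
  r_age <- summary_two_sample_t(23.29, 6.08, 14, 26.07, 6.19, 14)
  expect_equal(round(r_age$p, 3), 0.241)
  # handedness row: 84.29 (10.16) vs 90 (11.09) -> p 0.167
  r_hand <- summary_two_sample_t(84.29, 10.16, 14, 90, 11.09, 14)
  expect_equal(round(r_hand$p, 3), 0.167)
  expect_equal(r_age$df, 26)

  r_eq <- summary_two_sample_t(5, 1, 10, 5, 1, 10)
  expect_equal(r_eq$t, 0)
  expect_equal(r_eq$p, 1)
  expect_equal(summary_two_sample_t(5, 0, 5, 5, 0, 5)$p, 1)
  expect_error(summary_two_sample_t(5, 0, 5, 6, 0, 5), "degenerate")
  # cross-check the pooled form against t.test on raw data
  set.seed(30)
  x <- rnorm(9); y <- rnorm(11, 0.5)
  r <- summary_two_sample_t(mean(x), sd(x), 9, mean(y), sd(y), 11)
  tt <- t.test(x, y, var.equal = TRUE)
  expect_equal(r$t, unname(tt$statistic), tolerance = 1e-12)
  expect_equal(r$p, tt$p.value, tolerance = 1e-12)
  rw <- summary_two_sample_t(mean(x), sd(x), 9, mean(y), sd(y), 11,
                             welch = TRUE)
  tw <- t.test(x, y)
  expect_equal(rw$p, tw$p.value, tolerance = 1e-12)
})
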