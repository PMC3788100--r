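#' Build a design matrix for the voxel-wise GLM
#'
#' Constructs the standard designs of a voxel-based asymmetry study from a
#' subject table. Nuisance covariates (age, gender, and any behavioral
#' covariate) are mean-centered so that group columns estimate adjusted
#' group means.
#'
#' * `"one_sample"`: intercept + nuisance; contrast on the intercept tests
#'   the mean asymmetry of the group.
#' * `"two_sample"`: one indicator column per group (cell-means coding) +
#'   nuisance; contrast `control - patient` tests the group difference.
#' * `"covariate"`: intercept + centered covariate + nuisance; contrast on
#'   the covariate column tests the voxel-wise association (e.g. AI versus
#'   a behavioral score).
#'
#' @param subjects Data frame with at least the columns named by
#'   `covariates` and, for `"two_sample"`, a `group` column with levels
#'   `control` / `patient`.
#' @param kind Design kind (see above).
#' @param covariates Character vector of nuisance columns (default
#'   `c("age", "gender")`; use `character()` for none).
#' @param covariate For `kind = "covariate"`, the column holding the score
#'   of interest.
#' @return A `glm_design`: list with `X` (matrix), `contrast` (numeric),
#'   `scheme` (default permutation scheme for the design), and `kind`.
#' @export
glm_design <- function(subjects, kind = c("one_sample", "two_sample",
                                          "covariate"),
                       covariates = c("age", "gender"),
                       covariate = NULL) {
  kind <- match.arg(kind)
  n <- nrow(subjects)
  Z <- NULL
  if (length(covariates)) {
    Z <- as.matrix(subjects[, covariates, drop = FALSE])
    storage.mode(Z) <- "double"
    Z <- scale(Z, center = TRUE, scale = FALSE)
    colnames(Z) <- covariates
  }
  if (kind == "one_sample") {
    X <- cbind(intercept = rep(1, n), Z)
    contrast <- c(1, rep(0, ncol(X) - 1L))
    scheme <- "sign_flip"
  } else if (kind == "two_sample") {
    if (!all(subjects$group %in% c("control", "patient")))
      stop("two-sample design needs a 'group' column with levels control/patient")
    g <- subjects$group
    X <- cbind(control = as.numeric(g == "control"),
               patient = as.numeric(g == "patient"), Z)
    contrast <- c(1, -1, rep(0, ncol(X) - 2L))
    scheme <- "label_permute"
  } else {
    if (is.null(covariate) || !covariate %in% names(subjects))
      stop("'covariate' must name a column of 'subjects'")
    s <- as.numeric(subjects[[covariate]])
    s <- s - mean(s)
    X <- cbind(intercept = rep(1, n), score = s, Z)
    colnames(X)[2] <- covariate
    contrast <- c(0, 1, rep(0, ncol(X) - 2L))
    scheme <- "freedman_lane"
  }
  if (qr(X)$rank < ncol(X))
    stop("design matrix is rank deficient")
  structure(list(X = X, contrast = contrast, scheme = scheme, kind = kind),
            class = "glm_design")
}

## Stack a list of asym_maps or vols into an n x V matrix over mask voxels.
## Returns list(Y, mask_idx, dim, affine).
stack_maps <- function(maps, mask = NULL) {
  get_vol <- function(m) if (inherits(m, "asym_map")) m$ai else m
  vols <- lapply(maps, get_vol)
  d <- dim(vols[[1]]$data)
  aff <- vols[[1]]$affine
  for (v in vols)
    if (!identical(dim(v$data), d) || max(abs(v$affine - aff)) > 1e-6)
      stop("all maps must share the same grid and affine")
  if (is.null(mask)) {
    keep <- rep(TRUE, prod(d))
    for (m in maps)
      if (inherits(m, "asym_map")) keep <- keep & (m$mask$data > 0)
  } else {
    mk <- if (is_vol(mask)) mask$data else mask
    if (!identical(dim(mk), d)) stop("mask grid does not match maps")
    keep <- as.vector(mk > 0)
  }
  idx <- which(keep)
  Y <- matrix(NA_real_, length(vols), length(idx))
  for (i in seq_along(vols)) Y[i, ] <- vols[[i]]$data[idx]
  list(Y = Y, mask_idx = idx, dim = d, affine = aff)
}

## Core mass-univariate OLS t computation.
## X: n x p, Y: n x V, contrast: length p. Returns list(t, se, df, cb, ok):
## ok flags voxels with positive residual variance.
glm_t_core <- function(X, Y, contrast, sumY2 = NULL, fast = FALSE) {
  n <- nrow(X); p <- ncol(X)
  XtX <- crossprod(X)
  R <- chol(XtX)
  XtY <- crossprod(X, Y)                        # p x V
  Rty <- forwardsolve(t(R), XtY)
  cb <- drop(crossprod(contrast, backsolve(R, Rty)))  # c'beta, length V
  ## RSS via the Cholesky factor: RSS = sum(Y^2) - ||R^-T X'Y||^2
  if (is.null(sumY2)) sumY2 <- colSums(Y^2)
  rss <- sumY2 - colSums(Rty^2)
  rss[rss < 0] <- 0
  df <- n - p
  sigma2 <- rss / df
  cXXc <- drop(crossprod(contrast,
                         backsolve(R, forwardsolve(t(R), contrast))))
  se <- sqrt(sigma2 * cXXc)
  if (fast)  # permutation path: t only, on the frozen voxel set
    return(list(t = cb / se, df = df))
  ok <- sigma2 > max(1e-24, 1e-12 * stats::median(sigma2[sigma2 > 0], na.rm = TRUE))
  ok[is.na(ok)] <- FALSE
  t <- rep(NA_real_, length(cb))
  t[ok] <- cb[ok] / se[ok]
  ## a voxel that is constant with a zero contrast estimate (e.g. all-zero
  ## data) is a null voxel, t = 0; constant with a nonzero estimate stays
  ## undefined and is excluded
  null_vox <- !ok & abs(cb) < 1e-12
  t[null_vox] <- 0
  ok[null_vox] <- TRUE
  list(t = t, se = se, df = df, cb = cb, ok = ok)
}

#' Fit the mass-univariate GLM and return a t map
#'
#' Per-voxel ordinary least squares of the subject maps on a design matrix,
#' with the t statistic \eqn{t = c'\hat\beta / \sqrt{\hat\sigma^2
#' c'(X'X)^{-1}c}}. Voxels with (numerically) zero residual variance have
#' an undefined t and are excluded from the returned mask.
#'
#' @param maps List of per-subject `asym_map`s or `vol`s, one per design
#'   row, all on the same grid.
#' @param design A [glm_design()].
#' @param mask Optional analysis mask (`vol` or array); by default the
#'   intersection of the maps' own masks (all voxels for plain `vol`s).
#' @return List with `t_map` (`vol`, `NA` outside the mask), `df`,
#'   `mask` (binary `vol` after excluding undefined-t voxels).
#' @export
fit_glm_t <- function(maps, design, mask = NULL) {
  stopifnot(inherits(design, "glm_design"))
  st <- stack_maps(maps, mask)
  if (nrow(st$Y) != nrow(design$X))
    stop("number of maps does not match design rows")
  if (nrow(design$X) <= ncol(design$X))
    stop("need more subjects than design columns")
  res <- glm_t_core(design$X, st$Y, design$contrast)
  t_arr <- array(NA_real_, dim = st$dim)
  t_arr[st$mask_idx] <- res$t
  m_arr <- array(0, dim = st$dim)
  m_arr[st$mask_idx[res$ok]] <- 1
  list(t_map = vol(t_arr, st$affine), df = res$df,
       mask = vol(m_arr, st$affine))
}

#' Two-sample pooled t test from summary statistics
#'
#' Student's pooled-variance two-sample t computed from group means,
#' standard deviations and sizes, as used to compare groups from a summary
#' table. With `welch = TRUE` the Welch unequal-variance form is used
#' instead.
#'
#' @param mean1,sd1,n1 First group's mean, SD, size.
#' @param mean2,sd2,n2 Second group's mean, SD, size.
#' @param welch Use the Welch-Satterthwaite form (default `FALSE`).
#' @return List with `t`, `df`, `p` (two-sided).
#' @examples
#' # Age comparison of two groups of 14 from printed summaries:
#' summary_two_sample_t(23.29, 6.08, 14, 26.07, 6.19, 14)$p  # 0.241
#' @export
summary_two_sample_t <- function(mean1, sd1, n1, mean2, sd2, n2,
                                 welch = FALSE) {
  if (n1 < 2 || n2 < 2) stop("both groups need n >= 2")
  if (sd1 < 0 || sd2 < 0) stop("standard deviations must be nonnegative")
  if (sd1 == 0 && sd2 == 0) {
    if (mean1 == mean2) return(list(t = 0, df = n1 + n2 - 2, p = 1))
    stop("degenerate comparison: zero variance in both groups with unequal means")
  }
  if (welch) {
    v1 <- sd1^2 / n1; v2 <- sd2^2 / n2
    se <- sqrt(v1 + v2)
    df <- (v1 + v2)^2 / (v1^2 / (n1 - 1) + v2^2 / (n2 - 1))
  } else {
    sp2 <- ((n1 - 1) * sd1^2 + (n2 - 1) * sd2^2) / (n1 + n2 - 2)
    se <- sqrt(sp2 * (1 / n1 + 1 / n2))
    df <- n1 + n2 - 2
  }
  t <- (mean1 - mean2) / se
  list(t = t, df = df, p = 2 * stats::pt(-abs(t), df))
}
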