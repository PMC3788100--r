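#' Permutation-calibrated voxel- and cluster-level FWE inference
#'
#' Mass-univariate GLM over subject maps with family-wise error control by
#' permutation. For each of `B` permutations the maximum t over the mask
#' (voxel-level FWE) and the maximum cluster statistic above the
#' cluster-forming threshold (cluster-level FWE) are recorded; corrected
#' p-values use the add-one convention `p = (b + 1) / (B + 1)`, which
#' counts the observed statistic as a member of its own null sample.
#' Because the null is built from the data's own permutation distribution,
#' the cluster inference is robust to non-stationary smoothness of the
#' maps — no stationarity assumption enters, unlike random-field-theory
#' cluster p-values. Cluster mass (the sum of `t` in excess of the
#' threshold) is the default cluster statistic; extent is available.
#'
#' Permutation schemes:
#' * `"sign_flip"` (one-sample): subject-wise sign flipping; valid for
#'   asymmetry-index maps because under the null of no asymmetry the index
#'   is symmetric about zero by construction.
#' * `"label_permute"` (two-sample): permutes group labels while nuisance
#'   covariates stay attached to their subjects.
#' * `"freedman_lane"` (covariate): permutes residuals from the
#'   nuisance-only model, the standard exchangeability-preserving scheme
#'   for designs with a covariate of interest.
#'
#' If `B` reaches the number of distinct non-identity permutations, the
#' test becomes exhaustive (with a warning when `B` had to be reduced).
#'
#' @param maps List of per-subject `asym_map`s or `vol`s.
#' @param design A [glm_design()].
#' @param B Number of permutations (default 999).
#' @param cluster_forming_p Uncorrected voxel-level p defining the
#'   cluster-forming t threshold (default 0.001).
#' @param cluster_alpha FWE level used to flag significant clusters
#'   (default 0.05).
#' @param statistic Cluster statistic, `"mass"` (default) or `"extent"`.
#' @param alternative `"greater"` (default; positive one-sided, appropriate
#'   for antisymmetric AI maps where every effect surfaces on its dominant
#'   hemisphere) or `"two.sided"`.
#' @param connectivity Cluster connectivity (default 18).
#' @param scheme Permutation scheme; defaults to the design's natural one.
#' @param mask Optional analysis mask; defaults to the intersection of the
#'   maps' masks.
#' @param roi Optional region-of-interest `vol`/array: all maxima are taken
#'   inside `roi` only (small volume correction).
#' @param seed RNG seed for the permutation draw.
#' @return A `stat_result`: list with `t_map` (`vol`), `df`,
#'   `voxel_p_fwe` (`vol`), `clusters` (data.frame with corrected cluster-
#'   and peak-level p-values), `n_permutations`, `cluster_forming_p`,
#'   `t_threshold`, `statistic_kind`, `cluster_alpha`, `scheme`,
#'   `null_max_t`, `null_max_cluster`, `mask` (`vol`).
#' @export
permutation_fwe <- function(maps, design, B = 999,
                            cluster_forming_p = 0.001,
                            cluster_alpha = 0.05,
                            statistic = c("mass", "extent"),
                            alternative = c("greater", "two.sided"),
                            connectivity = 18,
                            scheme = NULL, mask = NULL, roi = NULL,
                            seed = 1L) {
  statistic <- match.arg(statistic)
  alternative <- match.arg(alternative)
  stopifnot(inherits(design, "glm_design"))
  if (is.null(scheme)) scheme <- design$scheme
  if (!scheme %in% c("sign_flip", "label_permute", "freedman_lane"))
    stop("unknown permutation scheme: ", scheme)
  if (B < 1) stop("B must be at least 1")
  if (!(cluster_forming_p > 0 && cluster_forming_p < 1) ||
      !(cluster_alpha > 0 && cluster_alpha < 1))
    stop("probabilities must lie in (0, 1)")

  st <- stack_maps(maps, mask)
  if (!is.null(roi)) {
    rmk <- if (is_vol(roi)) roi$data else roi
    if (!identical(dim(rmk), st$dim)) stop("roi grid does not match maps")
    inroi <- as.vector(rmk > 0)[st$mask_idx]
    if (!any(inroi)) stop("roi is empty within the analysis mask")
    st$mask_idx <- st$mask_idx[inroi]
    st$Y <- st$Y[, inroi, drop = FALSE]
  }
  X <- design$X
  contrast <- design$contrast
  n <- nrow(X)
  if (nrow(st$Y) != n) stop("number of maps does not match design rows")
  if (n <= ncol(X)) stop("need more subjects than design columns")

  obs <- glm_t_core(X, st$Y, contrast)
  ## Freeze the voxel set where t is defined in the observed fit.
  keep <- obs$ok
  st$mask_idx <- st$mask_idx[keep]
  st$Y <- st$Y[, keep, drop = FALSE]
  t_obs <- obs$t[keep]
  df <- obs$df

  t_thr <- if (alternative == "greater")
    stats::qt(1 - cluster_forming_p, df)
  else stats::qt(1 - cluster_forming_p / 2, df)
  stat_of <- function(tv) if (alternative == "greater") tv else abs(tv)

  ## --- permutation plan -------------------------------------------------
  perms <- build_permutations(scheme, X, contrast, n, B, seed)
  B <- perms$B

  ## Freedman-Lane: residualize against nuisance-only model once.
  if (scheme == "freedman_lane") {
    Znul <- X[, contrast == 0, drop = FALSE]
    Yr <- if (ncol(Znul)) {
      Hz <- Znul %*% solve(crossprod(Znul), t(Znul))
      st$Y - Hz %*% st$Y
    } else st$Y
    sumYr2 <- colSums(Yr^2)
  }
  sumY2 <- colSums(st$Y^2)

  null_max_t <- numeric(B)
  null_max_c <- numeric(B)
  for (b in seq_len(B)) {
    if (scheme == "sign_flip") {
      Xb <- X * perms$signs[, b]
      tb <- glm_t_core(Xb, st$Y, contrast, sumY2 = sumY2, fast = TRUE)$t
    } else if (scheme == "label_permute") {
      Xb <- X
      act <- contrast != 0
      Xb[, act] <- X[perms$orders[, b], act, drop = FALSE]
      tb <- glm_t_core(Xb, st$Y, contrast, sumY2 = sumY2, fast = TRUE)$t
    } else {
      tb <- glm_t_core(X, Yr[perms$orders[, b], , drop = FALSE], contrast,
                       sumY2 = sumYr2, fast = TRUE)$t
    }
    sb <- stat_of(tb)
    null_max_t[b] <- if (all(is.na(sb))) -Inf else max(sb, na.rm = TRUE)
    null_max_c[b] <- perm_max_cluster(sb, st$mask_idx, st$dim, t_thr,
                                      statistic, connectivity, alternative,
                                      tb)
  }

  ## --- corrected p-values ----------------------------------------------
  s_obs <- stat_of(t_obs)
  vox_p <- (vapply(s_obs, function(x) sum(null_max_t >= x), numeric(1)) + 1) /
    (B + 1)

  tab <- observed_clusters(t_obs, st$mask_idx, st$dim, st$affine, t_thr,
                           alternative, connectivity)
  if (nrow(tab)) {
    cstat <- if (statistic == "extent") tab$size else tab$mass
    tab$p_cluster_fwe <- (vapply(cstat, function(x) sum(null_max_c >= x),
                                 numeric(1)) + 1) / (B + 1)
    tab$p_voxel_fwe <- (vapply(tab$t_max, function(x) sum(null_max_t >= x),
                               numeric(1)) + 1) / (B + 1)
    tab$significant <- tab$p_cluster_fwe <= cluster_alpha
  } else {
    tab$p_cluster_fwe <- numeric(0)
    tab$p_voxel_fwe <- numeric(0)
    tab$significant <- logical(0)
  }

  t_arr <- array(NA_real_, dim = st$dim)
  t_arr[st$mask_idx] <- t_obs
  p_arr <- array(NA_real_, dim = st$dim)
  p_arr[st$mask_idx] <- vox_p
  m_arr <- array(0, dim = st$dim)
  m_arr[st$mask_idx] <- 1

  structure(list(t_map = vol(t_arr, st$affine),
                 df = df,
                 voxel_p_fwe = vol(p_arr, st$affine),
                 clusters = tab,
                 n_permutations = B,
                 cluster_forming_p = cluster_forming_p,
                 t_threshold = t_thr,
                 statistic_kind = statistic,
                 cluster_alpha = cluster_alpha,
                 alternative = alternative,
                 scheme = scheme,
                 null_max_t = null_max_t,
                 null_max_cluster = null_max_c,
                 mask = vol(m_arr, st$affine)),
            class = "stat_result")
}

## Permutation plan: exhaustive enumeration when B reaches the number of
## distinct non-identity rearrangements, otherwise B random draws.
build_permutations <- function(scheme, X, contrast, n, B, seed) {
  set.seed(seed)
  if (scheme == "sign_flip") {
    total <- 2^n
    if (B >= total - 1) {
      if (B > total - 1)
        warning(sprintf("B reduced to exhaustive %d sign patterns", total - 1))
      g <- as.matrix(expand.grid(rep(list(c(1, -1)), n)))
      signs <- t(g[-1, , drop = FALSE])  # drop the identity pattern
      return(list(signs = unname(signs), B = ncol(signs)))
    }
    signs <- matrix(sample(c(-1, 1), n * B, replace = TRUE), n, B)
    return(list(signs = signs, B = B))
  }
  if (scheme == "label_permute") {
    act <- which(contrast != 0)
    g1 <- which(X[, act[1]] != 0)
    ## only permutations that keep the permuted design estimable enter the
    ## null set (group labels can align exactly with a binary covariate)
    estimable <- function(ord) {
      Xb <- X
      Xb[, act] <- X[ord, act, drop = FALSE]
      qr(Xb)$rank == ncol(X)
    }
    total <- choose(n, length(g1))
    if (B >= total - 1 && total <= 1e5) {
      if (B > total - 1)
        warning(sprintf("B reduced to exhaustive %d label assignments",
                        total - 1))
      sets <- utils::combn(n, length(g1))
      orders <- matrix(0L, n, 0)
      for (j in seq_len(ncol(sets))) {
        if (identical(as.integer(sort(sets[, j])), as.integer(sort(g1))))
          next  # identity assignment
        ord <- integer(n)
        ord[sets[, j]] <- g1                                   # new group-1 set
        ord[setdiff(seq_len(n), sets[, j])] <- setdiff(seq_len(n), g1)
        if (estimable(ord)) orders <- cbind(orders, ord)
      }
      return(list(orders = orders, B = ncol(orders)))
    }
    orders <- matrix(0L, n, B)
    for (b in seq_len(B)) {
      for (try in 1:1000) {
        ord <- sample.int(n)
        if (estimable(ord)) break
        if (try == 1000)
          stop("could not draw an estimable label permutation")
      }
      orders[, b] <- ord
    }
    return(list(orders = orders, B = B))
  }
  ## freedman_lane
  total <- factorial(n)
  if (n <= 7 && B >= total - 1) {
    if (B > total - 1)
      warning(sprintf("B reduced to exhaustive %d permutations", total - 1))
    allp <- all_permutations(n)
    orders <- allp[, -1, drop = FALSE]  # first column is the identity
    return(list(orders = orders, B = ncol(orders)))
  }
  orders <- replicate(B, sample.int(n))
  list(orders = orders, B = B)
}

all_permutations <- function(n) {
  if (n == 1L) return(matrix(1L, 1, 1))
  sub <- all_permutations(n - 1L)
  out <- matrix(0L, n, n * ncol(sub))
  k <- 0L
  for (j in seq_len(ncol(sub))) for (pos in n:1) {
    k <- k + 1L
    out[, k] <- append(sub[, j], n, after = pos - 1L)
  }
  ## put the identity first
  id <- which(colSums(out == seq_len(n)) == n)[1]
  out[, c(id, setdiff(seq_len(ncol(out)), id)), drop = FALSE]
}

## Max cluster statistic of a permuted t vector; for two-sided tests the
## positive and negative suprathreshold sets form separate clusters.
perm_max_cluster <- function(svals, mask_idx, d, t_thr, statistic,
                             connectivity, alternative, tvals) {
  if (alternative == "greater")
    return(max_cluster_stat(svals, mask_idx, d, t_thr, statistic,
                            connectivity))
  max(max_cluster_stat(tvals, mask_idx, d, t_thr, statistic, connectivity),
      max_cluster_stat(-tvals, mask_idx, d, t_thr, statistic, connectivity))
}

## Observed cluster table (handles the two-sided split by sign).
observed_clusters <- function(t_obs, mask_idx, d, affine, t_thr,
                              alternative, connectivity = 18) {
  arr <- array(NA_real_, dim = d)
  arr[mask_idx] <- t_obs
  if (alternative == "greater") {
    tab <- cluster_table_core(arr, !is.na(arr) & arr >= t_thr, t_thr,
                              connectivity, affine)
    tab$direction <- rep("positive", nrow(tab))
  } else {
    pos <- cluster_table_core(arr, !is.na(arr) & arr >= t_thr, t_thr,
                              connectivity, affine)
    pos$direction <- rep("positive", nrow(pos))
    neg_arr <- -arr
    neg <- cluster_table_core(neg_arr, !is.na(neg_arr) & neg_arr >= t_thr,
                              t_thr, connectivity, affine)
    neg$direction <- rep("negative", nrow(neg))
    attr(pos, "labels") <- NULL; attr(neg, "labels") <- NULL
    tab <- rbind(pos, neg)
    tab <- tab[order(-tab$size), , drop = FALSE]
    rownames(tab) <- NULL
  }
  tab
}

#' @export
print.stat_result <- function(x, ...) {
  cat(sprintf("<stat_result> %s / %s, df = %d, B = %d, cluster-forming p = %g (t > %.3f)\n",
              x$scheme, x$statistic_kind, x$df, x$n_permutations,
              x$cluster_forming_p, x$t_threshold))
  if (nrow(x$clusters) == 0) {
    cat("  no suprathreshold clusters\n")
  } else {
    sig <- sum(x$clusters$significant)
    cat(sprintf("  %d cluster(s), %d significant at cluster FWE %g\n",
                nrow(x$clusters), sig, x$cluster_alpha))
  }
  invisible(x)
}

#' Small volume correction within a region of interest
#'
#' Reruns the permutation machinery of [permutation_fwe()] with every
#' maximum (voxel and cluster) taken inside `roi_mask` only. Restricting
#' the search a priori to a (symmetric) ROI is the standard way to retain
#' power for focused hypotheses such as covariate correlations.
#'
#' @param maps,design,... As in [permutation_fwe()].
#' @param roi_mask Nonempty binary `vol`/array on the maps' grid.
#' @return A `stat_result` (see [permutation_fwe()]).
#' @export
small_volume_correct <- function(maps, design, roi_mask, ...) {
  if (is.null(roi_mask)) stop("roi_mask is required")
  rmk <- if (is_vol(roi_mask)) roi_mask$data else roi_mask
  if (!any(rmk > 0)) stop("roi_mask is empty")
  permutation_fwe(maps, design, roi = roi_mask, ...)
}
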