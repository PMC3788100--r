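#' Label suprathreshold clusters in a t map
#'
#' Connected components of the suprathreshold set `{t >= t_threshold}`
#' inside the analysis mask, under 6-, 18- or 26-connectivity
#' (18-connectivity — faces and edges — is the SPM-family convention and
#' the default). Each cluster's extent (voxels), mass (sum of `t -
#' t_threshold` over the cluster), peak t and peak world coordinate are
#' reported.
#'
#' @param t_map A `vol` of t statistics (may contain `NA` outside the
#'   mask), or a numeric 3D array.
#' @param mask Optional binary `vol`/array restricting the search.
#' @param t_threshold Positive cluster-forming threshold on t.
#' @param connectivity 6, 18 or 26.
#' @return A data.frame (possibly 0-row) with columns `cluster_id`, `size`,
#'   `mass`, `t_max`, `peak_x`, `peak_y`, `peak_z` (mm, when an affine is
#'   available), `side` (`"left"`/`"right"` by the sign of `peak_x`),
#'   sorted by size descending. The integer label array is attached as
#'   attribute `"labels"`.
#' @export
label_clusters <- function(t_map, mask = NULL, t_threshold,
                           connectivity = 18) {
  if (!is.numeric(t_threshold) || t_threshold <= 0)
    stop("'t_threshold' must be positive")
  arr <- if (is_vol(t_map)) t_map$data else t_map
  affine <- if (is_vol(t_map)) t_map$affine else NULL
  keep <- !is.na(arr) & arr >= t_threshold
  if (!is.null(mask)) {
    mk <- if (is_vol(mask)) mask$data else mask
    keep <- keep & (mk > 0)
  }
  tab <- cluster_table_core(arr, keep, t_threshold, connectivity, affine)
  tab
}

## Shared cluster summarisation. Returns the sorted data.frame with the
## label array attached.
cluster_table_core <- function(arr, keep, t_threshold, connectivity,
                               affine = NULL) {
  d <- dim(arr)
  labels <- .label_components_3d(as.logical(keep), as.integer(d),
                                 as.integer(connectivity))
  nlab <- max(labels)
  if (nlab == 0L) {
    out <- data.frame(cluster_id = integer(0), size = integer(0),
                      mass = numeric(0), t_max = numeric(0),
                      peak_x = numeric(0), peak_y = numeric(0),
                      peak_z = numeric(0), side = character(0),
                      stringsAsFactors = FALSE)
    attr(out, "labels") <- labels
    return(out)
  }
  idx <- which(labels > 0L)
  lab <- labels[idx]
  tv <- arr[idx]
  size <- tabulate(lab, nlab)
  mass <- as.vector(rowsum(tv - t_threshold, lab))
  ## peak voxel per cluster
  ord <- order(lab, -tv)
  first <- ord[!duplicated(lab[ord])]
  peak_idx <- idx[first][order(lab[first])]
  t_max <- tv[first][order(lab[first])]
  pk <- arrayInd(peak_idx, d) - 1L
  if (!is.null(affine)) {
    w <- cbind(pk, 1) %*% t(affine)
    px <- w[, 1]; py <- w[, 2]; pz <- w[, 3]
  } else {
    px <- pk[, 1]; py <- pk[, 2]; pz <- pk[, 3]
  }
  out <- data.frame(cluster_id = seq_len(nlab), size = size, mass = mass,
                    t_max = t_max, peak_x = px, peak_y = py, peak_z = pz,
                    side = ifelse(px < 0, "left", "right"),
                    stringsAsFactors = FALSE)
  out <- out[order(-out$size), , drop = FALSE]
  rownames(out) <- NULL
  attr(out, "labels") <- labels
  out
}

## Fast path for the permutation loop: maximum cluster statistic of the
## suprathreshold set of t values over masked voxel indices, on a grid of
## dimension d. Returns 0 when nothing is suprathreshold.
max_cluster_stat <- function(tvals, mask_idx, d, t_threshold, statistic,
                             connectivity) {
  sup <- which(!is.na(tvals) & tvals >= t_threshold)
  if (!length(sup)) return(0)
  keep <- logical(prod(d))
  keep[mask_idx[sup]] <- TRUE
  labels <- .label_components_3d(keep, as.integer(d),
                                 as.integer(connectivity))
  lab <- labels[mask_idx[sup]]
  if (statistic == "extent") {
    max(tabulate(lab, max(lab)))
  } else {
    max(rowsum(tvals[sup] - t_threshold, lab))
  }
}
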