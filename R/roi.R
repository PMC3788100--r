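#' Build a binary ROI mask from an integer label volume
#'
#' Unions the voxels of the selected anatomical labels, mirroring the
#' flip-and-combine ROI workflow used for small-volume corrections. Any
#' integer-label NIfTI atlas (e.g. an AAL-style parcellation) can be used;
#' the synthetic truth label volume plays the same role for phantom runs.
#'
#' @param label_volume A `vol` of integer labels.
#' @param label_ids Integer vector of labels to include (nonempty, all
#'   present in the volume).
#' @param name Name recorded on the mask.
#' @return An `roi_mask`: list with `mask` (binary `vol`), `name`,
#'   `construction_log`.
#' @export
combine_labels <- function(label_volume, label_ids, name = "roi") {
  stopifnot(is_vol(label_volume))
  if (!length(label_ids)) stop("'label_ids' must be nonempty")
  present <- unique(as.vector(label_volume$data))
  missing_ids <- setdiff(label_ids, present)
  if (length(missing_ids))
    stop("unknown label id(s): ", paste(missing_ids, collapse = ", "))
  m <- array(as.numeric(label_volume$data %in% label_ids),
             dim = dim(label_volume$data))
  structure(list(mask = vol(m, label_volume$affine, label_volume$space_tag),
                 name = name,
                 construction_log = sprintf("union of labels {%s}",
                                            paste(label_ids, collapse = ","))),
            class = "roi_mask")
}

#' Symmetrize an ROI about the mid-sagittal plane
#'
#' Combines a mask with its mirror image so the result is exactly
#' flip-invariant — the property small-volume corrections on asymmetry
#' maps require. Rules: `"union"` (default; keeps full bilateral coverage),
#' `"intersection"` (keeps only voxels present on both sides), and
#' `"mean_threshold"` (mean of the 0/1 pair at least 0.5, which for binary
#' input is the union — the 0.5 tie from a one-sided voxel is included).
#'
#' @param roi An `roi_mask` or binary `vol`.
#' @param rule Combination rule.
#' @param tol_mm Grid-symmetry tolerance for the flip.
#' @return An `roi_mask` with a flip-invariant mask. An intersection that
#'   comes out empty is flagged invalid with a warning.
#' @export
symmetrize <- function(roi, rule = c("union", "intersection",
                                     "mean_threshold"), tol_mm = 0.1) {
  rule <- match.arg(rule)
  m <- if (inherits(roi, "roi_mask")) roi$mask else roi
  stopifnot(is_vol(m))
  f <- flip_x(m, tol_mm)
  a <- m$data > 0
  b <- f$data > 0
  out <- switch(rule,
                union = a | b,
                intersection = a & b,
                mean_threshold = (a + b) / 2 >= 0.5)
  if (!any(out))
    warning("symmetrized ROI is empty")
  name <- if (inherits(roi, "roi_mask")) roi$name else "roi"
  log0 <- if (inherits(roi, "roi_mask")) roi$construction_log else character(0)
  structure(list(mask = vol(out + 0, m$affine, m$space_tag),
                 name = name,
                 construction_log = c(log0, sprintf("symmetrize(%s)", rule))),
            class = "roi_mask")
}

#' @export
print.roi_mask <- function(x, ...) {
  cat(sprintf("<roi_mask> '%s', %d voxels [%s]\n", x$name,
              sum(x$mask$data > 0),
              paste(x$construction_log, collapse = "; ")))
  invisible(x)
}

#' Read an integer-label volume with its label-name table
#'
#' @param nifti_path Path to an integer-label NIfTI volume.
#' @param table_path Optional CSV with columns `id`, `name`.
#' @return List with `volume` (`vol`) and `labels` (data.frame or `NULL`).
#' @export
read_label_volume <- function(nifti_path, table_path = NULL) {
  v <- read_volume(nifti_path)
  labels <- if (!is.null(table_path))
    utils::read.csv(table_path, stringsAsFactors = FALSE)
  list(volume = v, labels = labels)
}
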