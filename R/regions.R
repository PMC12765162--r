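#' ROI atlas
#'
#' Integer label map plus a label table mapping each label to a region
#' name. The region vocabulary covers total gray matter, the vascular
#' territories (ACA, MCA, posterior circulation) and the AD-related
#' cortical regions (precuneus, frontal cortex, anterior and posterior
#' cingulate).
#'
#' @param label_map 3D integer array of non-negative labels (0 =
#'   background).
#' @param label_table Data frame with columns `label` (integer) and `name`
#'   (unique character).
#' @return An object of class `roi_atlas`.
#' @export
roi_atlas <- function(label_map, label_table) {
  if (any(label_map < 0)) stop("labels must be non-negative")
  if (anyDuplicated(label_table$name)) stop("ROI names must be unique")
  structure(list(label_map = label_map, label_table = label_table),
            class = "roi_atlas")
}

.roi_voxels <- function(atlas, roi_name, gm_mask) {
  row <- atlas$label_table[atlas$label_table$name == roi_name, ]
  if (nrow(row) == 0) stop("unknown ROI: ", roi_name)
  atlas$label_map == row$label & gm_mask > 0
}

#' Mean of a parameter map over one ROI
#'
#' Mean over the voxels of the ROI intersected with the gray-matter mask,
#' excluding NaN (masked-out or non-converged) voxels.
#'
#' @param map 3D numeric array.
#' @param atlas A [roi_atlas()].
#' @param roi_name Region name present in the atlas label table.
#' @param gm_mask Logical or 0/1 array of the same shape.
#' @return List with `mean` and `n_voxels` (NaN-excluded count).
#' @export
roi_mean <- function(map, atlas, roi_name, gm_mask) {
  sel <- .roi_voxels(atlas, roi_name, gm_mask)
  x <- map[sel]
  x <- x[is.finite(x)]
  if (length(x) == 0)
    stop("ROI '", roi_name, "' has no finite voxels inside the GM mask")
  list(mean = mean(x), n_voxels = length(x))
}

#' Size-weighted anterior circulation mean
#'
#' The anterior circulation territory is the size-weighted average of the
#' ACA and MCA territories: `(n_ACA * mean_ACA + n_MCA * mean_MCA) /
#' (n_ACA + n_MCA)`, which equals the plain voxel mean over their union
#' when the territories are disjoint.
#'
#' @inheritParams roi_mean
#' @return List with `mean` and `n_voxels`.
#' @export
anterior_circulation <- function(map, atlas, gm_mask) {
  aca <- roi_mean(map, atlas, "ACA", gm_mask)
  mca <- roi_mean(map, atlas, "MCA", gm_mask)
  n <- aca$n_voxels + mca$n_voxels
  list(mean = (aca$n_voxels * aca$mean + mca$n_voxels * mca$mean) / n,
       n_voxels = n)
}

#' Anterior-to-posterior circulation ratio
#'
#' Ratio of the size-weighted anterior circulation mean to the posterior
#' territory mean.
#'
#' @inheritParams roi_mean
#' @return The ratio (numeric scalar).
#' @export
ant_post_ratio <- function(map, atlas, gm_mask) {
  ant <- anterior_circulation(map, atlas, gm_mask)
  post <- roi_mean(map, atlas, "posterior", gm_mask)
  if (post$mean == 0) stop("posterior circulation mean is zero")
  ant$mean / post$mean
}

#' ROI metrics table for one subject's parameter maps
#'
#' Long-format table of ROI means for the three parameter maps (Tex, CBF,
#' ATT), over every named ROI plus the composite anterior circulation and
#' the anterior/posterior ratio.
#'
#' @param pmap A `parameter_map` from [fit_volume()] (or a list with
#'   `tex_map`, `cbf_map`, `att_map`).
#' @param atlas A [roi_atlas()].
#' @param gm_mask Mask array.
#' @param subject Subject identifier for the output table.
#' @return Data frame (subject, roi, metric, value, n_voxels).
#' @export
roi_metrics <- function(pmap, atlas, gm_mask, subject = "sub-01") {
  maps <- list(tex = pmap$tex_map, cbf = pmap$cbf_map, att = pmap$att_map)
  rois <- atlas$label_table$name
  has_territories <- all(c("ACA", "MCA", "posterior") %in% rois)
  rows <- list()
  for (metric in names(maps)) {
    for (r in rois) {
      m <- roi_mean(maps[[metric]], atlas, r, gm_mask)
      rows[[length(rows) + 1]] <- data.frame(
        subject = subject, roi = r, metric = metric,
        value = m$mean, n_voxels = m$n_voxels)
    }
    if (has_territories) {
      ant <- anterior_circulation(maps[[metric]], atlas, gm_mask)
      rows[[length(rows) + 1]] <- data.frame(
        subject = subject, roi = "anterior", metric = metric,
        value = ant$mean, n_voxels = ant$n_voxels)
      rows[[length(rows) + 1]] <- data.frame(
        subject = subject, roi = "ant_post_ratio", metric = metric,
        value = ant_post_ratio(maps[[metric]], atlas, gm_mask),
        n_voxels = NA_integer_)
    }
  }
  do.call(rbind, rows)
}
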