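#' The 25 visual-area ROIs and their cortical territories
#'
#' Maximum-probability visual-area atlases label 25 topographic ROIs per
#' hemisphere; for summaries these are grouped into five cortical
#' territories: early visual (V1v, V1d, V2v, V2d, V3v, V3d), ventral (hV4,
#' VO1, VO2, PHC1, PHC2), lateral occipital (MST, hMT, LO1, LO2, V3a, V3b),
#' dorsal (IPS0-IPS5, SPL1) and frontal (FEF).
#'
#' @return Named character vector mapping ROI name to territory.
#' @export
wang_territories <- function() {
  c(V1v = "early_visual", V1d = "early_visual", V2v = "early_visual",
    V2d = "early_visual", V3v = "early_visual", V3d = "early_visual",
    hV4 = "ventral", VO1 = "ventral", VO2 = "ventral",
    PHC1 = "ventral", PHC2 = "ventral",
    MST = "lateral_occipital", hMT = "lateral_occipital",
    LO1 = "lateral_occipital", LO2 = "lateral_occipital",
    V3a = "lateral_occipital", V3b = "lateral_occipital",
    IPS0 = "dorsal", IPS1 = "dorsal", IPS2 = "dorsal", IPS3 = "dorsal",
    IPS4 = "dorsal", IPS5 = "dorsal", SPL1 = "dorsal",
    FEF = "frontal")
}

#' Atlas volume container
#'
#' A 3D integer label image (0 = background) together with its voxel size
#' and a table naming each label.
#'
#' @param labels 3D integer array of ROI labels.
#' @param voxel_size_mm Voxel edge lengths in mm (scalar or length 3).
#' @param label_table Data frame with columns `label`, `roi`, `hemisphere`.
#' @return An object of class `atlas_volume`.
#' @export
atlas_volume <- function(labels, voxel_size_mm = 1, label_table) {
  stopifnot(length(dim(labels)) == 3,
            all(c("label", "roi", "hemisphere") %in% names(label_table)))
  if (any(labels < 0)) stop("atlas labels must be non-negative")
  present <- unique(as.vector(labels))
  missing <- setdiff(label_table$label, present)
  if (length(missing) > 0) {
    stop("atlas labels with no voxels: ",
         paste(missing, collapse = ", "))
  }
  structure(list(labels = labels,
                 voxel_size_mm = rep_len(voxel_size_mm, 3),
                 label_table = label_table),
            class = "atlas_volume")
}

#' Percentage of each atlas ROI lost to the lesion
#'
#' For every ROI, the fraction of its voxels that fall inside the binary
#' lesion mask, expressed as a percentage: 0% indicates total sparing of the
#' region, 100% complete loss. ROIs untouched by the lesion are reported at
#' 0% rather than dropped.
#'
#' @param lesion_mask Binary 3D array (0/1 or logical) on the same grid as
#'   the atlas.
#' @param atlas An [atlas_volume()].
#' @return Data frame with one row per ROI: `roi`, `hemisphere`,
#'   `territory`, `roi_voxels`, `lesion_voxels_in_roi`, `loss_pct`.
#' @export
roi_loss <- function(lesion_mask, atlas) {
  stopifnot(inherits(atlas, "atlas_volume"))
  if (!identical(dim(lesion_mask), dim(atlas$labels))) {
    stop(sprintf("grid mismatch: lesion %s vs atlas %s",
                 paste(dim(lesion_mask), collapse = "x"),
                 paste(dim(atlas$labels), collapse = "x")))
  }
  m <- as.vector(lesion_mask)
  if (!all(m %in% c(0, 1))) stop("lesion mask must be binary (0/1)")
  lab <- as.vector(atlas$labels)
  tab <- atlas$label_table
  terr <- wang_territories()
  unknown <- setdiff(tab$roi, names(terr))
  if (length(unknown) > 0) {
    stop("unknown ROI name(s): ", paste(unknown, collapse = ", "))
  }
  roi_n <- vapply(tab$label, function(l) sum(lab == l), numeric(1))
  les_n <- vapply(tab$label, function(l) sum(m[lab == l]), numeric(1))
  data.frame(roi = tab$roi,
             hemisphere = tab$hemisphere,
             territory = unname(terr[tab$roi]),
             roi_voxels = as.integer(roi_n),
             lesion_voxels_in_roi = as.integer(les_n),
             loss_pct = 100 * les_n / roi_n)
}

#' Group ROI losses into cortical territories
#'
#' @param entries A [roi_loss()] table.
#' @param weighted Use an ROI-voxel-weighted mean (default); set `FALSE` for
#'   the unweighted mean across ROIs.
#' @return Data frame per territory (and hemisphere, if present):
#'   `territory`, `n_rois`, `mean_loss_pct`.
#' @export
group_territories <- function(entries, weighted = TRUE) {
  terr <- wang_territories()
  unknown <- setdiff(entries$roi, names(terr))
  if (length(unknown) > 0) {
    stop("unknown ROI name(s): ", paste(unknown, collapse = ", "))
  }
  entries$territory <- unname(terr[entries$roi])
  by_cols <- intersect(c("territory", "hemisphere"), names(entries))
  groups <- split(entries, entries[by_cols], drop = TRUE)
  rows <- lapply(groups, function(g) {
    w <- if (weighted) g$roi_voxels else rep(1, nrow(g))
    out <- g[1, by_cols, drop = FALSE]
    out$n_rois <- nrow(g)
    out$mean_loss_pct <- sum(w * g$loss_pct) / sum(w)
    out
  })
  out <- do.call(rbind, rows)
  rownames(out) <- NULL
  out
}
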