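#' ROI specification
#'
#' @param name ROI name.
#' @param kind `"disk"` (centre + radius, mm) or `"label_region"` (id into
#'   a label image).
#' @param centre,radius Disk parameters, mm.
#' @param label Region id for `kind = "label_region"`.
#' @return An object of class `roi_spec`.
#' @export
roi_spec <- function(name, kind = c("disk", "label_region"),
                     centre = NULL, radius = NULL, label = NULL) {
  kind <- match.arg(kind)
  if (kind == "disk" && (is.null(centre) || is.null(radius)))
    stop("disk ROIs need `centre` and `radius`")
  if (kind == "label_region" && is.null(label))
    stop("label ROIs need `label`")
  structure(list(name = name, kind = kind, centre = centre, radius = radius,
                 label = label), class = "roi_spec")
}

roi_mask <- function(roi, grid, labels = NULL) {
  if (is.logical(roi)) return(roi)
  stopifnot(inherits(roi, "roi_spec"))
  if (roi$kind == "disk") {
    disk_mask(grid, roi$centre, roi$radius)
  } else {
    if (is.null(labels)) stop("label ROI needs a label image")
    labels == roi$label
  }
}

#' ROI statistics of an image
#'
#' Sample mean and sample standard deviation (n-1 denominator) of the voxel
#' values inside the ROI, optionally intersected with a display mask.
#'
#' @param img An [image_grid()].
#' @param roi An [roi_spec()] or a logical matrix.
#' @param mask Optional mask [image_grid()] or logical matrix; only voxels
#'   inside both are used.
#' @param labels Optional label matrix for label-region ROIs.
#' @return List with `mean`, `sd` and `n_voxels`.
#' @export
roi_stats <- function(img, roi, mask = NULL, labels = NULL) {
  sel <- roi_mask(roi, img, labels)
  if (!is.null(mask)) {
    mv <- if (inherits(mask, "image_grid")) mask$values > 0 else mask
    sel <- sel & mv
  }
  if (!any(sel)) stop("ROI does not intersect the mask")
  v <- img$values[sel]
  list(mean = mean(v), sd = if (length(v) > 1) sd(v) else 0,
       n_voxels = length(v))
}

#' Lesion signal-to-noise ratio
#'
#' `SNR = |lesion mean - background mean| / background sd`, the lesion
#' contrast in units of the background voxel noise.
#'
#' @param lesion_mean,bg_mean ROI means.
#' @param bg_sd Background ROI standard deviation (> 0).
#' @return The SNR.
#' @examples
#' snr(0.863, 0.999, 0.041) # about 3.3
#' @export
snr <- function(lesion_mean, bg_mean, bg_sd) {
  if (bg_sd <= 0) stop("background sd must be positive")
  abs(lesion_mean - bg_mean) / bg_sd
}

#' ROI report for a lifetime result
#'
#' Evaluates [roi_stats()] of the lifetime image over a set of ROIs inside
#' the display mask and, when `lesion` and `background` ROIs are both
#' present, the lesion SNR.
#'
#' @param result A `lifetime_result`.
#' @param rois Named list of ROI masks or [roi_spec()]s (e.g. from
#'   [phantom_rois()]).
#' @return A data.frame with one row per ROI (`roi`, `mean`, `sd`,
#'   `n_voxels`) carrying the SNR as attribute `"snr"` when computable.
#' @export
evaluate_rois <- function(result, rois) {
  rows <- lapply(names(rois), function(nm) {
    st <- roi_stats(result$m, rois[[nm]], mask = result$mask)
    data.frame(roi = nm, mean = st$mean, sd = st$sd,
               n_voxels = st$n_voxels)
  })
  out <- do.call(rbind, rows)
  if (all(c("lesion", "background") %in% out$roi)) {
    les <- out[out$roi == "lesion", ]
    bg <- out[out$roi == "background", ]
    attr(out, "snr") <- snr(les$mean, bg$mean, bg$sd)
  }
  out
}
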