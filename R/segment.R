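#' Segmentation parameters
#'
#' Controls for threshold-based cell segmentation: a fixed grey-value
#' threshold or Otsu's automatic threshold, an object-area band that rejects
#' specks and clumps, and the saturated-pixel fraction above which a
#' region's count is flagged as unreliable.
#'
#' @param threshold_mode `"fixed"` (use `threshold_value`) or `"automatic"`
#'   (Otsu's method on the image histogram).
#' @param threshold_value Grey value in 0..65535; required in fixed mode.
#' @param min_area_px,max_area_px Retained object area band, pixels.
#' @param saturation_fraction_limit Fraction in (0, 1] of dtype-saturated
#'   pixels above which a region is flagged.
#' @return An object of class `segmentation_params`.
#' @export
segmentation_params <- function(threshold_mode = c("fixed", "automatic"),
                                threshold_value = NULL,
                                min_area_px = 1,
                                max_area_px = Inf,
                                saturation_fraction_limit = 0.5) {
  threshold_mode <- match.arg(threshold_mode)
  if (threshold_mode == "fixed") {
    if (is.null(threshold_value)) {
      stop_input("fixed mode requires 'threshold_value'")
    }
    check_scalar_number(threshold_value, "threshold_value", min = 0,
                        max = 65535)
  }
  check_scalar_number(min_area_px, "min_area_px", min = 0)
  check_scalar_number(max_area_px, "max_area_px", min = min_area_px)
  check_scalar_number(saturation_fraction_limit, "saturation_fraction_limit",
                      min = 0, max = 1, strict_min = TRUE)
  structure(list(threshold_mode = threshold_mode,
                 threshold_value = threshold_value,
                 min_area_px = min_area_px, max_area_px = max_area_px,
                 saturation_fraction_limit = saturation_fraction_limit),
            class = "segmentation_params")
}

# 8-connected labeling: EBImage::bwlabel is 4-connected, so components that
# touch only diagonally are merged afterwards with a union-find pass.
label_components_8 <- function(mask) {
  lab <- EBImage::bwlabel(mask)
  lab <- matrix(as.integer(round(lab)), nrow = nrow(mask))
  nlab <- max(lab)
  if (nlab <= 1L) return(lab)
  h <- nrow(lab); w <- ncol(lab)
  # diagonal neighbour pairs with differing nonzero labels
  a1 <- lab[-h, -w]; b1 <- lab[-1, -1]   # down-right
  a2 <- lab[-h, -1]; b2 <- lab[-1, -w]   # down-left
  pairs <- rbind(cbind(as.vector(a1), as.vector(b1)),
                 cbind(as.vector(a2), as.vector(b2)))
  pairs <- pairs[pairs[, 1] != 0L & pairs[, 2] != 0L &
                   pairs[, 1] != pairs[, 2], , drop = FALSE]
  if (nrow(pairs)) {
    parent <- seq_len(nlab)
    find <- function(x) {
      while (parent[x] != x) {
        parent[x] <<- parent[parent[x]]
        x <- parent[x]
      }
      x
    }
    for (i in seq_len(nrow(pairs))) {
      ra <- find(pairs[i, 1]); rb <- find(pairs[i, 2])
      if (ra != rb) parent[max(ra, rb)] <- min(ra, rb)
    }
    roots <- vapply(seq_len(nlab), find, integer(1))
    relab <- match(roots, sort(unique(roots)))
    nz <- lab != 0L
    lab[nz] <- relab[lab[nz]]
  }
  lab
}

#' Segment labeled cells in a fluorescence slice
#'
#' Thresholds a single-channel grayscale image (fixed grey value, or Otsu's
#' method in automatic mode), labels 8-connected foreground components, and
#' retains components whose pixel area lies in
#' `[min_area_px, max_area_px]` as cells. Touching cells merge into one
#' component: no watershed splitting is attempted, so clumps are
#' under-counted by design.
#'
#' @param signal Integer matrix of grey values 0..65535 (single channel).
#' @param params A [segmentation_params()].
#' @return A list of class `cell_segmentation`:
#'   \describe{
#'     \item{labels}{Integer matrix; retained objects numbered 1..n.}
#'     \item{objects}{data.frame `object, area, row, col` (centroids).}
#'     \item{threshold}{Grey-value threshold actually applied.}
#'   }
#' @export
segment_cells <- function(signal, params) {
  stopifnot(inherits(params, "segmentation_params"))
  signal <- as.matrix(signal)
  if (length(dim(signal)) != 2L) stop_input("'signal' must be single-channel")
  thr <- if (params$threshold_mode == "fixed") {
    params$threshold_value
  } else {
    EBImage::otsu(EBImage::Image(signal / 65535), range = c(0, 1),
                  levels = 256L) * 65535
  }
  mask <- signal >= thr
  if (!any(mask)) {
    return(structure(list(labels = matrix(0L, nrow(signal), ncol(signal)),
                          objects = data.frame(object = integer(),
                                               area = integer(),
                                               row = numeric(),
                                               col = numeric()),
                          threshold = thr),
                     class = "cell_segmentation"))
  }
  lab <- label_components_8(mask)
  areas <- tabulate(lab[lab > 0L])
  keep <- which(areas >= params$min_area_px & areas <= params$max_area_px)
  relab <- integer(length(areas))
  relab[keep] <- seq_along(keep)
  nz <- lab > 0L
  lab[nz] <- relab[lab[nz]]

  objects <- if (length(keep)) {
    idx <- which(lab > 0L)
    obj <- lab[idx]
    rr <- (idx - 1L) %% nrow(lab) + 1L
    cc <- (idx - 1L) %/% nrow(lab) + 1L
    data.frame(
      object = seq_along(keep),
      area = as.integer(tabulate(obj, nbins = length(keep))),
      row = as.vector(tapply(rr, obj, mean)),
      col = as.vector(tapply(cc, obj, mean))
    )
  } else {
    data.frame(object = integer(), area = integer(), row = numeric(),
               col = numeric())
  }
  structure(list(labels = lab, objects = objects, threshold = thr),
            class = "cell_segmentation")
}

#' Count segmented cells per atlas region
#'
#' Assigns every retained object to the region whose code lies under the
#' object's centroid (objects whose centroid falls on background are
#' dropped), and reports per-region cell counts with hemisphere attribution
#' from the region table. Regions in which the fraction of dtype-saturated
#' pixels (grey value 65535) exceeds `saturation_fraction_limit` are flagged
#' as unreliable: their counts are still reported but should be replaced by
#' manual quantification.
#'
#' @param segmentation A [segment_cells()] result.
#' @param label_map A [region_label_map()] on the same pixel grid.
#' @param params A [segmentation_params()].
#' @param signal The segmented image (needed for saturation flagging).
#' @return A list of class `region_counts`:
#'   \describe{
#'     \item{counts}{data.frame `code, name, hemisphere, cell_count,
#'       flagged_saturated`, one row per region in the table.}
#'     \item{dropped}{Number of objects whose centroid fell on background.}
#'   }
#' @export
count_per_region <- function(segmentation, label_map, params, signal) {
  stopifnot(inherits(segmentation, "cell_segmentation"),
            inherits(label_map, "region_label_map"),
            inherits(params, "segmentation_params"))
  signal <- as.matrix(signal)
  if (!identical(dim(segmentation$labels), dim(label_map$labels)) ||
      !identical(dim(signal), dim(label_map$labels))) {
    stop_input("signal, segmentation and label map must share one pixel grid")
  }
  obj <- segmentation$objects
  regions <- label_map$regions
  assigned <- if (nrow(obj)) {
    label_map$labels[cbind(as.integer(round(obj$row)),
                           as.integer(round(obj$col)))]
  } else integer(0)
  dropped <- sum(assigned == 0L)
  tab <- table(factor(assigned[assigned != 0L], levels = regions$code))

  sat_frac <- vapply(regions$code, function(code) {
    px <- label_map$labels == code
    if (!any(px)) return(0)
    mean(signal[px] == 65535L)
  }, numeric(1))

  counts <- data.frame(
    code = regions$code,
    name = regions$name,
    hemisphere = regions$hemisphere,
    cell_count = as.integer(tab),
    flagged_saturated = sat_frac > params$saturation_fraction_limit,
    stringsAsFactors = FALSE
  )
  structure(list(counts = counts, dropped = dropped),
            class = "region_counts")
}

#' Fraction of a brain region sampled by a section series
#'
#' When sections of a given thickness are collected at a fixed interval,
#' the counted fraction of the region is `thickness / interval` (e.g. 30 um
#' sections at a 180 um interval sample 1/6, i.e. 16.67%, of the region).
#'
#' @param section_thickness_um Section thickness, micrometres (> 0).
#' @param interval_um Collection interval, micrometres (>= thickness).
#' @return The sampled fraction in (0, 1].
#' @export
#' @examples
#' series_sampling_fraction(30, 180)  # 1/6
series_sampling_fraction <- function(section_thickness_um, interval_um) {
  check_scalar_number(section_thickness_um, "section_thickness_um",
                      min = 0, strict_min = TRUE)
  check_scalar_number(interval_um, "interval_um",
                      min = section_thickness_um)
  section_thickness_um / interval_um
}

#' Concordance between automated and manual counts
#'
#' Percent agreement between automated and manual per-region counts over
#' unflagged regions: `100 * (1 - sum(|auto - manual|) / sum(manual))`.
#' Conventions: if the manual total is 0 and any automated counts are
#' nonzero the agreement is 0%; if both are all-zero it is 100%.
#'
#' @param auto_counts A [count_per_region()] result, or a data.frame with
#'   columns `code`, `cell_count` and optionally `flagged_saturated`.
#' @param manual_counts data.frame with columns `code` and `count` (or
#'   `cell_count`) over the same region set.
#' @return A list: `percent` agreement, and `deltas` data.frame
#'   (`code, auto, manual, delta`) over the compared regions.
#' @export
concordance <- function(auto_counts, manual_counts) {
  if (inherits(auto_counts, "region_counts")) auto_counts <- auto_counts$counts
  mcol <- intersect(c("count", "cell_count"), names(manual_counts))[1]
  if (is.na(mcol)) stop_input("'manual_counts' needs a count column")
  if (!setequal(auto_counts$code, manual_counts$code)) {
    stop_input("region sets differ between automated and manual counts: ",
               paste(union(setdiff(auto_counts$code, manual_counts$code),
                           setdiff(manual_counts$code, auto_counts$code)),
                     collapse = ", "))
  }
  flagged <- if ("flagged_saturated" %in% names(auto_counts)) {
    auto_counts$flagged_saturated
  } else rep(FALSE, nrow(auto_counts))
  auto <- auto_counts[!flagged, , drop = FALSE]
  manual <- manual_counts[match(auto$code, manual_counts$code), , drop = FALSE]
  a <- auto$cell_count
  m <- manual[[mcol]]
  deltas <- data.frame(code = auto$code, auto = a, manual = m,
                       delta = a - m)
  total_m <- sum(m)
  percent <- if (total_m == 0) {
    if (sum(a) == 0) 100 else 0
  } else {
    100 * (1 - sum(abs(a - m)) / total_m)
  }
  list(percent = percent, deltas = deltas)
}
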