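#' Specification for a synthetic labeled slice image
#'
#' Parameters for rendering a grayscale 16-bit slice with a known number of
#' disk-shaped labeled cells per atlas region over Gaussian background
#' noise. Optionally a set of regions is rendered fully saturated, emulating
#' slices where the tracer signal is too intense for automated counting.
#'
#' @param label_map A [region_label_map()] giving the region geometry.
#' @param cells_per_region Named integer vector or data.frame
#'   (`code`, `count`): requested cells per region code. Codes absent from
#'   the label map's region table are rejected.
#' @param cell_radius_px Disk radius in pixels (>= 1).
#' @param cell_intensity Grey value of cell pixels; must exceed
#'   `background_mean`.
#' @param background_mean,background_sd Gaussian background noise
#'   parameters (grey values).
#' @param saturated_regions Optional integer vector of region codes to fill
#'   at the dtype maximum (65535).
#' @param allow_overlap Allow cell disks to overlap (default `FALSE`;
#'   non-overlap is enforced by rejection sampling).
#' @param max_retries Placement attempts per cell before giving up.
#' @param seed Integer seed.
#' @return An object of class `image_spec`.
#' @export
image_spec <- function(label_map,
                       cells_per_region,
                       cell_radius_px = 3,
                       cell_intensity = 30000,
                       background_mean = 1000,
                       background_sd = 200,
                       saturated_regions = integer(),
                       allow_overlap = FALSE,
                       max_retries = 1000,
                       seed = 1L) {
  stopifnot(inherits(label_map, "region_label_map"))
  if (is.data.frame(cells_per_region)) {
    cells_per_region <- stats::setNames(
      as.integer(cells_per_region$count), cells_per_region$code)
  }
  codes <- as.integer(names(cells_per_region))
  if (any(is.na(codes)) || !all(codes %in% label_map$regions$code)) {
    stop_input("'cells_per_region' names must be region codes in the label map")
  }
  if (any(cells_per_region < 0)) stop_input("cell counts must be >= 0")
  check_scalar_number(cell_radius_px, "cell_radius_px", min = 1)
  check_scalar_number(cell_intensity, "cell_intensity",
                      min = background_mean, strict_min = TRUE, max = 65535)
  check_scalar_number(background_mean, "background_mean", min = 0, max = 65535)
  check_scalar_number(background_sd, "background_sd", min = 0)
  saturated_regions <- as.integer(saturated_regions)
  if (!all(saturated_regions %in% label_map$regions$code)) {
    stop_input("'saturated_regions' must be region codes in the label map")
  }
  structure(
    list(label_map = label_map,
         cells_per_region = stats::setNames(as.integer(cells_per_region),
                                            codes),
         cell_radius_px = as.integer(cell_radius_px),
         cell_intensity = as.integer(cell_intensity),
         background_mean = background_mean, background_sd = background_sd,
         saturated_regions = saturated_regions,
         allow_overlap = isTRUE(allow_overlap),
         max_retries = as.integer(max_retries), seed = as.integer(seed)),
    class = "image_spec"
  )
}

# Offsets of a filled disk of radius r around a centre pixel.
disk_offsets <- function(r) {
  g <- expand.grid(dr = -r:r, dc = -r:r)
  g[g$dr^2 + g$dc^2 <= r^2, , drop = FALSE]
}

#' Render a synthetic slice image with known per-region cell counts
#'
#' Places the requested number of non-overlapping disks (radius
#' `cell_radius_px`, grey value `cell_intensity`) uniformly at random within
#' each region's pixel mask, over Gaussian background noise. Disks are kept
#' fully inside their region and, unless `allow_overlap`, centres are kept
#' at least `2 * radius + 2` pixels apart so rendered cells stay resolvable
#' as separate connected components. Regions listed in `saturated_regions`
#' are filled wholesale at the 16-bit maximum.
#'
#' @param spec An [image_spec()].
#' @return A list with:
#'   \describe{
#'     \item{image}{Integer matrix of grey values 0..65535.}
#'     \item{truth}{Ground-truth sidecar data.frame
#'       `code, name, hemisphere, count` holding the requested counts
#'       (saturated regions keep their requested count even though their
#'       rendered cells are not resolvable; downstream counting flags them).}
#'     \item{centers}{data.frame `code, row, col` of placed cell centres.}
#'   }
#' @export
#' @examples
#' lm <- demo_label_map(c("A", "B"), width = 80, height = 80)
#' out <- generate_slice_image(image_spec(lm, c("1" = 5, "2" = 3), seed = 7))
#' out$truth
generate_slice_image <- function(spec) {
  if (!inherits(spec, "image_spec")) {
    stop_input("'spec' must be created by image_spec()")
  }
  lm <- spec$label_map
  labels <- lm$labels
  h <- nrow(labels); w <- ncol(labels)
  r <- spec$cell_radius_px
  offs <- disk_offsets(r)
  min_sep2 <- (2 * r + 2)^2

  with_seed(spec$seed, {
    img <- matrix(
      pmin(65535, pmax(0, round(stats::rnorm(h * w, spec$background_mean,
                                             spec$background_sd)))),
      nrow = h, ncol = w)

    centers <- list()
    for (code in names(spec$cells_per_region)) {
      n_cells <- spec$cells_per_region[[code]]
      if (n_cells == 0L) next
      code_i <- as.integer(code)
      idx <- which(labels == code_i)
      if (!length(idx)) {
        stop_input("region ", code, " has no pixels in the label map")
      }
      # candidate centres: pixels whose whole disk stays inside the region
      cand_r <- (idx - 1L) %% h + 1L
      cand_c <- (idx - 1L) %/% h + 1L
      inside <- cand_r > r & cand_r <= h - r & cand_c > r & cand_c <= w - r
      cand_r <- cand_r[inside]; cand_c <- cand_c[inside]
      if (length(cand_r)) {
        full_in <- vapply(seq_along(cand_r), function(i) {
          all(labels[cbind(cand_r[i] + offs$dr, cand_c[i] + offs$dc)] == code_i)
        }, logical(1))
        cand_r <- cand_r[full_in]; cand_c <- cand_c[full_in]
      }
      if (!length(cand_r)) {
        stop_input("region ", code, " is too small to hold a cell of radius ",
                   r)
      }
      placed_r <- integer(0); placed_c <- integer(0)
      for (k in seq_len(n_cells)) {
        ok <- FALSE
        for (try in seq_len(spec$max_retries)) {
          j <- sample.int(length(cand_r), 1L)
          pr <- cand_r[j]; pc <- cand_c[j]
          if (spec$allow_overlap || !length(placed_r) ||
              all((placed_r - pr)^2 + (placed_c - pc)^2 >= min_sep2)) {
            ok <- TRUE
            break
          }
        }
        if (!ok) {
          stop_input("could not place ", n_cells, " non-overlapping cells in ",
                     "region ", code, " after ", spec$max_retries, " retries")
        }
        placed_r <- c(placed_r, pr); placed_c <- c(placed_c, pc)
        img[cbind(pr + offs$dr, pc + offs$dc)] <- spec$cell_intensity
      }
      centers[[code]] <- data.frame(code = code_i, row = placed_r,
                                    col = placed_c)
    }
  })

  for (code in spec$saturated_regions) {
    img[labels == code] <- 65535L
  }

  truth <- lm$regions[, c("code", "name", "hemisphere")]
  truth$count <- 0L
  hit <- match(as.integer(names(spec$cells_per_region)), truth$code)
  truth$count[hit] <- unname(spec$cells_per_region)
  rownames(truth) <- NULL

  storage.mode(img) <- "integer"
  list(image = img, truth = truth,
       centers = if (length(centers)) do.call(rbind, c(centers, list(make.row.names = FALSE)))
                 else data.frame(code = integer(), row = integer(),
                                 col = integer()))
}
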