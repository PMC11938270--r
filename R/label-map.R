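#' Region label map
#'
#' An integer-coded atlas template: a 2D image in which every nonzero pixel
#' value identifies one atlas region on one hemisphere (0 is background),
#' plus a region table mapping each code to a region name, a hemisphere
#' (`ipsi` or `contra`, relative to the injection site) and a coarse
#' anatomical group. This generalises hex-colour template images to plain
#' integer codes.
#'
#' @param labels Integer matrix (rows = image rows); 0 is background.
#' @param regions data.frame with columns `code` (positive integer), `name`,
#'   `hemisphere` (`"ipsi"` or `"contra"`), and optionally `group`.
#' @return An object of class `region_label_map` with elements `labels` and
#'   `regions`.
#' @export
region_label_map <- function(labels, regions) {
  labels <- as.matrix(labels)
  storage.mode(labels) <- "integer"
  if (any(labels < 0, na.rm = TRUE)) stop_input("label codes must be >= 0")
  req <- c("code", "name", "hemisphere")
  if (!all(req %in% names(regions))) {
    stop_input("'regions' needs columns: ", paste(req, collapse = ", "))
  }
  regions <- as.data.frame(regions, stringsAsFactors = FALSE)
  if (!("group" %in% names(regions))) regions$group <- NA_character_
  regions$code <- as.integer(regions$code)
  if (any(regions$code <= 0)) stop_input("region codes must be positive")
  if (anyDuplicated(regions$code)) stop_input("duplicate region codes")
  if (!all(regions$hemisphere %in% c("ipsi", "contra"))) {
    stop_input("hemisphere must be 'ipsi' or 'contra'")
  }
  if (anyDuplicated(regions[, c("name", "hemisphere")])) {
    stop_input("each (name, hemisphere) pair must have exactly one code")
  }
  present <- setdiff(unique(as.vector(labels)), 0L)
  missing <- setdiff(present, regions$code)
  if (length(missing)) {
    stop_input("label image contains codes absent from the region table: ",
               paste(missing, collapse = ", "))
  }
  structure(list(labels = labels, regions = regions),
            class = "region_label_map")
}

#' @export
print.region_label_map <- function(x, ...) {
  cat(sprintf("region_label_map: %d x %d pixels, %d regions (%d in image)\n",
              nrow(x$labels), ncol(x$labels), nrow(x$regions),
              length(setdiff(unique(as.vector(x$labels)), 0L))))
  invisible(x)
}

#' Simple rectangular demo label map
#'
#' Tiles `n_regions` named regions as rectangles on the left (ipsi) half of
#' the image and mirrors them on the right (contra) half, each hemisphere
#' half of each region carrying its own code (ipsi: 1..n, contra: n+1..2n).
#' A background margin separates tiles. Intended for synthetic slices and
#' tests, not as an anatomically realistic atlas.
#'
#' @param region_names Character vector of region names.
#' @param width,height Image size in pixels.
#' @param margin Background margin between tiles, pixels.
#' @return A [region_label_map()].
#' @export
demo_label_map <- function(region_names = vsb_regions(),
                           width = 240, height = 240, margin = 4) {
  n <- length(region_names)
  nrow_t <- ceiling(sqrt(n))
  ncol_t <- ceiling(n / nrow_t)
  half <- floor(width / 2)
  tile_w <- floor(half / ncol_t)
  tile_h <- floor(height / nrow_t)
  if (tile_w - 2 * margin < 3 || tile_h - 2 * margin < 3) {
    stop_input("image too small for ", n, " regions")
  }
  labels <- matrix(0L, nrow = height, ncol = width)
  for (i in seq_len(n)) {
    r <- (i - 1) %/% ncol_t
    c <- (i - 1) %% ncol_t
    rows <- (r * tile_h + margin + 1):((r + 1) * tile_h - margin)
    cols <- (c * tile_w + margin + 1):((c + 1) * tile_w - margin)
    labels[rows, cols] <- i                     # ipsi, left half
    labels[rows, width + 1 - cols] <- n + i     # contra, mirrored
  }
  regions <- data.frame(
    code = c(seq_len(n), n + seq_len(n)),
    name = rep(region_names, 2),
    hemisphere = rep(c("ipsi", "contra"), each = n),
    group = NA_character_,
    stringsAsFactors = FALSE
  )
  region_label_map(labels, regions)
}

#' Fit a label template to a slice with an affine transform
#'
#' Resamples the label image under a user-supplied 2D affine transform using
#' nearest-neighbour interpolation, so region codes are never blended. This
#' replaces interactive per-slice template adjustment: the caller supplies
#' the affine that registers the template onto the slice.
#'
#' The transform is a 3x3 matrix in homogeneous coordinates mapping template
#' pixel positions `(row, col, 1)` to output positions; the output image is
#' filled by inverse mapping, so every output pixel takes the code of the
#' nearest template pixel (background 0 outside the template).
#'
#' @param label_map A [region_label_map()].
#' @param transform 3x3 invertible affine matrix (third row `c(0, 0, 1)`).
#' @param dim Output image size `c(rows, cols)`; defaults to the input size.
#' @return A [region_label_map()] with resampled labels and the region table
#'   unchanged.
#' @export
#' @examples
#' lm <- demo_label_map(c("A", "B"), width = 40, height = 40)
#' ident <- diag(3)
#' stopifnot(identical(apply_template(lm, ident)$labels, lm$labels))
apply_template <- function(label_map, transform, dim = NULL) {
  stopifnot(inherits(label_map, "region_label_map"))
  transform <- as.matrix(transform)
  if (!identical(base::dim(transform), c(3L, 3L))) {
    stop_input("'transform' must be a 3x3 affine matrix")
  }
  det_t <- det(transform[1:2, 1:2, drop = FALSE])
  if (!is.finite(det_t) || abs(det_t) < .Machine$double.eps * 100) {
    stop_input("'transform' is singular and cannot be inverted")
  }
  src <- label_map$labels
  out_dim <- dim %||% base::dim(src)
  inv <- solve(transform)
  # inverse-map every output pixel centre to template coordinates
  grid <- cbind(
    rep(seq_len(out_dim[1]), times = out_dim[2]),
    rep(seq_len(out_dim[2]), each = out_dim[1]),
    1
  )
  tmpl <- grid %*% t(inv)
  ri <- as.integer(round(tmpl[, 1]))
  ci <- as.integer(round(tmpl[, 2]))
  ok <- ri >= 1L & ri <= nrow(src) & ci >= 1L & ci <= ncol(src)
  vals <- integer(nrow(grid))
  vals[ok] <- src[cbind(ri[ok], ci[ok])]
  region_label_map(matrix(vals, nrow = out_dim[1], ncol = out_dim[2]),
                   label_map$regions)
}

#' Read and write label maps and slice images
#'
#' Label maps are stored as a 16-bit single-channel TIFF (integer codes)
#' plus a region CSV `code,name,hemisphere,group`; slice images as 16-bit
#' single-channel TIFF with grey values 0..65535.
#'
#' @param label_map A [region_label_map()].
#' @param tiff_path,csv_path Output/input file paths.
#' @return `read_label_map()` returns a [region_label_map()]; the writers
#'   return their first argument invisibly.
#' @name label_map_io
#' @export
write_label_map <- function(label_map, tiff_path, csv_path) {
  stopifnot(inherits(label_map, "region_label_map"))
  write_slice_image(label_map$labels, tiff_path)
  utils::write.csv(label_map$regions, csv_path, row.names = FALSE)
  invisible(label_map)
}

#' @rdname label_map_io
#' @export
read_label_map <- function(tiff_path, csv_path) {
  labels <- read_slice_image(tiff_path)
  regions <- utils::read.csv(csv_path, stringsAsFactors = FALSE)
  region_label_map(labels, regions)
}

#' @rdname label_map_io
#' @param image Integer matrix of grey values in 0..65535.
#' @param path TIFF file path.
#' @export
write_slice_image <- function(image, path) {
  m <- as.matrix(image)
  if (any(m < 0 | m > 65535)) stop_input("pixel values must lie in 0..65535")
  tiff::writeTIFF(m / 65535, path, bits.per.sample = 16L)
  invisible(image)
}

#' @rdname label_map_io
#' @export
read_slice_image <- function(path) {
  m <- tiff::readTIFF(path)
  if (length(dim(m)) == 3L) m <- m[, , 1]
  m <- round(m * 65535)
  storage.mode(m) <- "integer"
  m
}
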