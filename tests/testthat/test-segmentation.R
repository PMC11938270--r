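fixed_params <- function(...) {
  segmentation_params("fixed", threshold_value = 10000, ...)
}

test_that("a blank noise image below threshold yields zero objects", {
  set.seed(1)
  img <- matrix(as.integer(round(rnorm(40 * 40, 1000, 200))), 40, 40)
  seg <- segment_cells(img, fixed_params())
  expect_equal(nrow(seg$objects), 0)
  expect_true(all(seg$labels == 0L))
})

test_that("disjoint synthetic disks are segmented one object per cell", {
  lm <- two_region_map()
  out <- generate_slice_image(image_spec(lm, c("1" = 5), seed = 6))
  seg <- segment_cells(out$image, fixed_params(min_area_px = 5))
  expect_equal(nrow(seg$objects), 5)
})

test_that("touching disks merge into a single component (no splitting)", {
  img <- matrix(0L, 40, 40)
  offs <- expand.grid(dr = -3:3, dc = -3:3)
  offs <- offs[offs$dr^2 + offs$dc^2 <= 9, ]
  img[cbind(20 + offs$dr, 15 + offs$dc)] <- 30000L
  img[cbind(20 + offs$dr, 21 + offs$dc)] <- 30000L  # overlapping disks
  seg <- segment_cells(img, fixed_params())
  expect_equal(nrow(seg$objects), 1)
})

test_that("components touching only diagonally are one 8-connected object", {
  img <- matrix(0L, 20, 20)
  img[5:7, 5:7] <- 30000L
  img[8:10, 8:10] <- 30000L  # corner contact at (7,7)-(8,8)
  seg <- segment_cells(img, fixed_params())
  expect_equal(nrow(seg$objects), 1)
  img2 <- matrix(0L, 20, 20)
  img2[5:7, 5:7] <- 30000L
  img2[9:11, 9:11] <- 30000L  # gap: two objects
  expect_equal(nrow(segment_cells(img2, fixed_params())$objects), 2)
})

test_that("the object-area band filters specks and clumps", {
  img <- matrix(0L, 40, 40)
  img[5, 5] <- 30000L                 # area 1
  img[10:12, 10:12] <- 30000L         # area 9
  img[20:29, 20:29] <- 30000L         # area 100
  params <- segmentation_params("fixed", threshold_value = 10000,
                                min_area_px = 5, max_area_px = 50)
  seg <- segment_cells(img, params)
  expect_equal(nrow(seg$objects), 1)
  expect_equal(seg$objects$area, 9)
})

test_that("automatic (Otsu) thresholding separates cells from background", {
  lm <- two_region_map()
  out <- generate_slice_image(image_spec(lm, c("1" = 4, "2" = 3), seed = 8))
  params <- segmentation_params("automatic", min_area_px = 5)
  seg <- segment_cells(out$image, params)
  expect_equal(nrow(seg$objects), 7)
  expect_gt(seg$threshold, 2000)
  expect_lt(seg$threshold, 30000)
})

test_that("per-region counts equal the ground-truth sidecar", {
  lm <- two_region_map()
  out <- generate_slice_image(image_spec(lm, c("1" = 5, "2" = 3), seed = 9))
  params <- fixed_params(min_area_px = 5)
  seg <- segment_cells(out$image, params)
  res <- count_per_region(seg, lm, params, out$image)
  expect_equal(res$counts$cell_count[res$counts$code == 1], 5)
  expect_equal(res$counts$cell_count[res$counts$code == 2], 3)
  expect_equal(res$dropped, 0)
  expect_false(any(res$counts$flagged_saturated))
})

test_that("count conservation: region counts + dropped = retained objects", {
  lm <- two_region_map()
  out <- generate_slice_image(image_spec(lm, c("1" = 6, "2" = 4), seed = 10))
  img <- out$image
  # add an object on background (margin strip) so one centroid is dropped
  img[1:3, 1:3] <- 30000L
  params <- fixed_params(min_area_px = 5)
  seg <- segment_cells(img, params)
  res <- count_per_region(seg, lm, params, img)
  expect_equal(sum(res$counts$cell_count) + res$dropped, nrow(seg$objects))
  expect_equal(res$dropped, 1)
})

test_that("saturated regions are flagged but still counted", {
  lm <- two_region_map()
  out <- generate_slice_image(image_spec(lm, c("1" = 3),
                                         saturated_regions = 2L, seed = 3))
  params <- fixed_params(min_area_px = 5, saturation_fraction_limit = 0.5)
  seg <- segment_cells(out$image, params)
  res <- count_per_region(seg, lm, params, out$image)
  expect_true(res$counts$flagged_saturated[res$counts$code == 2])
  expect_false(res$counts$flagged_saturated[res$counts$code == 1])
  expect_equal(res$counts$cell_count[res$counts$code == 1], 3)
})

test_that("mismatched pixel grids are rejected", {
  lm <- two_region_map(60)
  img <- matrix(0L, 40, 40)
  params <- fixed_params()
  seg <- segment_cells(img, params)
  expect_error(count_per_region(seg, lm, params, img), "grid")
})

test_that("recovery: counts equal truth on nearly all seeded slices", {
  # non-overlapping cells at SNR >= 5 (intensity 30000 over 1000 +/- 200)
  lm <- two_region_map(80)
  params <- segmentation_params("automatic", min_area_px = 5)
  exact <- 0L
  n_img <- 100L
  for (s in seq_len(n_img)) {
    out <- generate_slice_image(image_spec(lm, c("1" = 6, "2" = 4),
                                           seed = 1000 + s))
    seg <- segment_cells(out$image, params)
    res <- count_per_region(seg, lm, params, out$image)
    ok <- identical(res$counts$cell_count[match(out$truth$code,
                                                res$counts$code)],
                    out$truth$count)
    if (ok) exact <- exact + 1L
  }
  expect_gte(exact, 99L)
})

test_that("sampling fraction follows thickness / interval and is scale-free", {
  expect_equal(series_sampling_fraction(30, 180), 1 / 6)
  expect_equal(series_sampling_fraction(30, 30), 1)
  expect_equal(series_sampling_fraction(10, 40), 0.25)
  for (k in c(0.1, 2, 7.5)) {
    expect_equal(series_sampling_fraction(30 * k, 180 * k), 1 / 6)
  }
  expect_error(series_sampling_fraction(0, 180), "section_thickness_um")
  expect_error(series_sampling_fraction(40, 30), "interval_um")
})

test_that("concordance follows its arithmetic and edge conventions", {
  auto <- data.frame(code = 1:3, cell_count = c(10L, 20L, 30L),
                     flagged_saturated = FALSE)
  manual <- data.frame(code = 1:3, count = c(10L, 20L, 30L))
  expect_equal(concordance(auto, manual)$percent, 100)
  # one region off by its full manual count m = 20, total M = 60
  auto2 <- auto; auto2$cell_count[2] <- 0L
  expect_equal(concordance(auto2, manual)$percent, 100 * (1 - 20 / 60))
  # both all-zero -> 100; manual zero with auto counts -> 0
  zauto <- data.frame(code = 1:2, cell_count = c(0L, 0L),
                      flagged_saturated = FALSE)
  zman <- data.frame(code = 1:2, count = c(0L, 0L))
  expect_equal(concordance(zauto, zman)$percent, 100)
  zauto$cell_count[1] <- 4L
  expect_equal(concordance(zauto, zman)$percent, 0)
  # flagged regions are excluded from the comparison
  auto3 <- auto; auto3$flagged_saturated[2] <- TRUE
  auto3$cell_count[2] <- 999L
  expect_equal(concordance(auto3, manual)$percent, 100)
  expect_error(concordance(auto, data.frame(code = 1:2, count = c(1L, 2L))),
               "region sets differ")
})
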