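# Imaging module: IO, frame averaging, validity thresholds, background
# correction, per-pixel Fpol images, pseudo-color, quantification,
# segmentation.

test_that("image pairs survive a TIFF write/read round trip with geometry", {
  sim <- simulate_cell_field(cell_field_spec(n_cells = 3),
                             instrument_profile(image_size_px = 128),
                             seed = 1)
  pair <- sim$frames[[1]]
  co_p <- withr::local_tempfile(fileext = ".tif")
  cr_p <- withr::local_tempfile(fileext = ".tif")
  write_image_pair(pair, co_p, cr_p)
  back <- read_image_pair(co_p, cr_p, field_of_view_um = 205)
  expect_equal(back$co, pair$co, ignore_attr = TRUE)
  expect_equal(back$cross, pair$cross, ignore_attr = TRUE)
  expect_equal(back$pixel_size_um, 205 / 128)

  mask_p <- withr::local_tempfile(fileext = ".tif")
  write_label_mask(sim$truth$label_mask, mask_p)
  expect_identical(read_label_mask(mask_p), sim$truth$label_mask)

  # quantitative Fpol image round trip preserves values and NA flags
  fimg <- compute_fpol_image(back, g = 0.75)
  fp <- withr::local_tempfile(fileext = ".tif")
  write_fpol_image(fimg, tiff_path = fp)
  restored <- read_fpol_image(fp)
  expect_equal(is.na(restored), is.na(fimg), ignore_attr = TRUE)
  ok <- !is.na(fimg)
  expect_equal(unclass(restored)[ok], unclass(fimg)[ok], tolerance = 1e-4)

  # mismatched dimensions refuse to pair
  small <- matrix(10, 64, 64)
  sp <- withr::local_tempfile(fileext = ".tif")
  tiff::writeTIFF(small / 255, sp, bits.per.sample = 8L)
  expect_error(read_image_pair(co_p, sp, pixel_size_um = 0.4),
               class = "fpol_data_error")
  expect_error(read_image_pair("no/such/file.tif", cr_p, pixel_size_um = 0.4),
               class = "fpol_data_error")
})

test_that("frame averaging is the per-pixel mean and shrinks noise ~1/N", {
  one <- fpol_pair(matrix(10, 8, 8), matrix(20, 8, 8), 0.4)
  avg1 <- average_frames(list(one))
  expect_equal(avg1$co, one$co)
  expect_equal(avg1$frame_count_averaged, 1L)

  two <- fpol_pair(matrix(20, 8, 8), matrix(10, 8, 8), 0.4)
  avg <- average_frames(list(one, two))
  expect_true(all(avg$co == 15) && all(avg$cross == 15))
  expect_equal(avg$frame_count_averaged, 2L)

  expect_error(average_frames(list()), class = "fpol_data_error")
  bad <- fpol_pair(matrix(1, 4, 4), matrix(1, 4, 4), 0.4)
  expect_error(average_frames(list(one, bad)), class = "fpol_data_error")

  # variance of the frame mean scales ~1/N on repeated noisy acquisitions
  instr <- instrument_profile(image_size_px = 64,
                              frames_per_acquisition = 16)
  sim <- simulate_cell_field(cell_field_spec(n_cells = 0), instr, seed = 2)
  v1 <- var(as.vector(sim$frames[[1]]$co))
  vN <- var(as.vector(average_frames(sim$frames)$co))
  expect_lt(vN, v1 / 8)
})

test_that("validity mask censors noise-floor and saturated pixels in either channel", {
  co <- matrix(100, 4, 4); cross <- matrix(100, 4, 4)
  co[1, 1] <- 1        # below the low threshold
  co[2, 2] <- 255      # saturated
  cross[3, 3] <- 0     # below low, other channel
  pair <- fpol_pair(co, cross, 0.4)
  v <- build_validity_mask(pair)
  expect_false(v[1, 1]); expect_false(v[2, 2]); expect_false(v[3, 3])
  expect_equal(sum(!v), 3)

  # boundary values are inclusive
  co[4, 4] <- 2; cross[4, 4] <- 254
  expect_true(build_validity_mask(fpol_pair(co, cross, 0.4))[4, 4])

  # multiple frames: a pixel must be valid in every frame
  f2 <- fpol_pair(matrix(100, 4, 4), matrix(100, 4, 4), 0.4)
  f2$co[4, 4] <- 1
  v2 <- build_validity_mask(list(pair, f2))
  expect_false(v2[4, 4])

  expect_error(build_validity_mask(pair, low = 200, high = 100), "low < high")
})

test_that("background correction recovers background-free quantification", {
  spec <- cell_field_spec(n_cells = 6)
  bg_on <- instrument_profile(photon_noise = FALSE, read_noise_sd = 0,
                              background_level = 10, image_size_px = 256,
                              quantize = TRUE)
  bg_off <- instr_quantized(256)
  sim_bg <- simulate_cell_field(spec, bg_on, seed = 6)
  sim_0 <- simulate_cell_field(spec, bg_off, seed = 6)

  v <- build_validity_mask(sim_bg$frames[[1]])
  corr <- background_correct(sim_bg$frames[[1]],
                             cell_mask = sim_bg$truth$label_mask,
                             validity = v)
  rec_corr <- quantify_cells(corr, sim_bg$truth$label_mask, g = 0.75,
                             validity = v)
  rec_0 <- quantify_cells(sim_0$frames[[1]], sim_0$truth$label_mask,
                          g = 0.75, validity = all_valid(sim_0$frames[[1]]))
  expect_equal(rec_corr$fpol_display, rec_0$fpol_display, tolerance = 0.05)

  # zero-background input is unchanged (median background is 0);
  # validity must be supplied since true zeros sit below the threshold
  zpair <- sim_0$frames[[1]]
  zcorr <- background_correct(zpair, cell_mask = sim_0$truth$label_mask,
                              validity = all_valid(zpair))
  expect_equal(zcorr$co, zpair$co)

  # no background pixels available: warn, no-op
  allfg <- matrix(1L, 256, 256)
  expect_warning(
    unchanged <- background_correct(sim_bg$frames[[1]], cell_mask = allfg,
                                    validity = v),
    "no background")
  expect_equal(unchanged$co, sim_bg$frames[[1]]$co)

  # idempotence: correcting twice equals correcting once
  corr2 <- background_correct(corr, cell_mask = sim_bg$truth$label_mask,
                              validity = v)
  expect_equal(corr2$co, corr$co)
  expect_equal(corr2$cross, corr$cross)
})

test_that("per-pixel Fpol image applies the display-scale ratio with NA flags", {
  co <- matrix(100, 3, 3); cross <- matrix(80, 3, 3)
  co[2, 2] <- 60; cross[2, 2] <- 80   # co = g*cross -> 0
  co[3, 3] <- 255                      # saturated -> invalid
  pair <- fpol_pair(co, cross, 0.4)
  img <- compute_fpol_image(pair, g = 0.75)
  expect_equal(img[1, 1], 25.0)
  expect_equal(img[2, 2], 0.0)
  expect_true(is.na(img[3, 3]))
  expect_equal(attr(img, "display_range"), c(0, 40))
})

test_that("pseudo-color clips to the display range and maps monotonically", {
  vals <- matrix(c(0, 40, 55, NA, 20, 10), 2, 3)
  img <- structure(vals, display_range = c(0, 40),
                   class = c("fpol_image", "matrix"))
  rgb <- pseudo_color(img)
  pal <- attr(rgb, "colorbar")
  expect_equal(rgb[1, 1, ], as.vector(col2rgb(pal[1]) / 255))
  # 40 and an over-range 55 render identically (both clipped to max)
  expect_equal(rgb[2, 1, ], rgb[1, 2, ])
  # undefined renders black
  expect_equal(rgb[2, 2, ], c(0, 0, 0))

  # a monotone ramp maps to monotone colormap indices
  ramp <- structure(matrix(seq(0, 40, length.out = 32), 1),
                    display_range = c(0, 40),
                    class = c("fpol_image", "matrix"))
  idx <- apply(pseudo_color(ramp)[1, , , drop = TRUE], 1, function(px)
    which.min(colSums((col2rgb(pal) / 255 - px)^2)))
  expect_true(all(diff(idx) >= 0))
})

test_that("quantification is means-then-ratio and equals the emission-weighted pixel mean", {
  co <- matrix(100, 10, 10); cross <- matrix(80, 10, 10)
  mask <- matrix(0L, 10, 10); mask[3:8, 3:8] <- 1L
  pair <- fpol_pair(co, cross, 0.4)
  rec <- quantify_cells(pair, mask, g = 0.75)
  expect_equal(rec$fpol_display, 25.0)
  # 36 pixels at 0.4 um -> 5.76 um2; and a 100-px cell at 0.4 um -> 16 um2
  expect_equal(rec$cell_size_um2, 36 * 0.16)
  mask100 <- matrix(0L, 20, 20); mask100[1:10, 1:10] <- 1L
  rec100 <- quantify_cells(fpol_pair(matrix(100, 20, 20),
                                     matrix(80, 20, 20), 0.4),
                           mask100, g = 0.75)
  expect_equal(rec100$cell_size_um2, 16.0)

  # heterogeneous region: ratio of means == emission-weighted mean of
  # per-pixel Fpol (algebraic identity), not the plain per-pixel mean
  set.seed(12)
  co_h <- matrix(runif(400, 40, 200), 20, 20)
  cross_h <- matrix(runif(400, 30, 150), 20, 20)
  pair_h <- fpol_pair(co_h, cross_h, 0.4)
  g <- 0.75
  rec_h <- quantify_cells(pair_h, mask100, g = g,
                          validity = all_valid(pair_h))
  sel <- mask100 == 1L
  w <- co_h[sel] + g * cross_h[sel]
  pix <- 100 * (co_h[sel] - g * cross_h[sel]) / w
  expect_equal(rec_h$fpol_display, sum(w * pix) / sum(w), tolerance = 1e-9)

  # and agrees with the region mean of the per-pixel Fpol image
  img <- compute_fpol_image(pair_h, g = g, mask = all_valid(pair_h))
  expect_equal(rec_h$fpol_display,
               sum(w * img[sel]) / sum(w), tolerance = 1e-6)

  # regions below min_valid_pixels are dropped with a reason
  tiny <- matrix(0L, 10, 10); tiny[1, 1:3] <- 1L
  rec_t <- quantify_cells(pair, tiny, g = 0.75, min_valid_pixels = 10)
  expect_equal(nrow(rec_t), 0)
  expect_match(attr(rec_t, "dropped")[[1]]$reason, "valid pixels")

  expect_error(quantify_cells(pair, matrix(0L, 4, 4), g = 0.75),
               class = "fpol_data_error")
})

test_that("automatic segmentation recovers well-separated disks", {
  sim <- simulate_cell_field(
    cell_field_spec(n_cells = 10, radius_um_range = c(6, 9)),
    instrument_profile(), seed = 13)
  avg <- average_frames(sim$frames)
  seg <- segment_cells(avg, g = 0.75)
  expect_equal(max(seg), 10)
  # mean intersection-over-union against ground truth
  ious <- vapply(1:10, function(i) {
    truth_i <- sim$truth$label_mask == i
    hit <- seg[truth_i]
    lab <- as.integer(names(which.max(table(hit[hit > 0]))))
    pred <- seg == lab
    sum(pred & truth_i) / sum(pred | truth_i)
  }, 1)
  expect_gt(mean(ious), 0.9)

  # blank field yields an empty mask
  blank <- fpol_pair(matrix(0, 64, 64), matrix(0, 64, 64), 0.4)
  expect_true(all(segment_cells(blank, g = 0.75) == 0))

  # minimum-area filter: a region is kept iff area >= filter
  co <- matrix(0, 64, 64)
  co[10:19, 10:19] <- 200       # 100 px = 16 um2 at 0.4 um
  co[40:42, 40:42] <- 200       # 9 px = 1.44 um2
  pair <- fpol_pair(co, co * 0, 0.4)
  seg2 <- segment_cells(pair, g = 0.75, min_area_um2 = 16)
  expect_equal(max(seg2), 1)
  seg3 <- segment_cells(pair, g = 0.75, min_area_um2 = 1)
  expect_equal(max(seg3), 2)
})

test_that("noisy end-to-end recovery is unbiased with sub-unit dispersion", {
  errs <- numeric(0)
  for (s in 1:7) {
    sim <- simulate_cell_field(cell_field_spec(n_cells = 30),
                               instrument_profile(), seed = 100 + s)
    v <- build_validity_mask(sim$frames)
    avg <- average_frames(sim$frames)
    corr <- background_correct(avg, cell_mask = sim$truth$label_mask,
                               validity = v)
    rec <- quantify_cells(corr, sim$truth$label_mask, g = 0.75,
                          validity = v)
    errs <- c(errs, rec$fpol_display -
                100 * sim$truth$cells$true_fpol[rec$cell_id])
  }
  expect_gte(length(errs), 200)
  expect_lt(abs(mean(errs)), 0.3)
  expect_lt(sd(errs), 1.0)
})
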