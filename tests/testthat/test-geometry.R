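test_that("pad_to_square_map follows the pad-right/bottom convention", {
  p <- pad_to_square_map(600, 400)
  expect_equal(p$side, 600L)
  expect_equal(c(p$map$offset_y, p$map$offset_x), c(0, 0))
  expect_equal(c(p$map$scale_y, p$map$scale_x), c(1, 1))

  p2 <- pad_to_square_map(512, 512)
  expect_equal(p2$side, 512L)

  pt <- landmark(10, 20, "ORIGINAL")
  rt <- unmap_point(map_point(pt, p$map), p$map)
  expect_equal(c(rt$y, rt$x), c(10, 20))

  psym <- pad_to_square_map(600, 400, "symmetric")
  expect_equal(psym$map$offset_x, 100)
  expect_equal(psym$pad_left + psym$pad_right, 200L)

  expect_error(pad_to_square_map(0, 4), class = "ettc_input_error")
})

test_that("resample_map rescales coordinates and spacing", {
  rs <- resample_map(600, 600, 512, 512, spacing = pixel_spacing(0.5))
  expect_equal(rs$map$scale_y, 512 / 600)
  p <- map_point(landmark(300, 200, "PADDED"), rs$map)
  expect_equal(c(p$y, p$x), c(300 * 512 / 600, 200 * 512 / 600))
  expect_equal(p$y, 256)
  expect_equal(p$x, 170.666667, tolerance = 1e-6)
  expect_equal(rs$spacing$row_mm_per_px, 0.5 * 600 / 512)
  expect_equal(rs$spacing$row_mm_per_px, 0.5859375)

  ident <- resample_map(512, 512, 512, 512, spacing = pixel_spacing(0.7))
  expect_equal(ident$map$scale_y, 1)
  expect_equal(ident$spacing$row_mm_per_px, 0.7)
})

test_that("effective spacing satisfies spacing_eff * dst = spacing * src", {
  for (i in 1:50) {
    src <- sample(100:3000, 1); dst <- sample(100:1024, 1)
    sp <- runif(1, 0.1, 1)
    rs <- resample_map(src, src, dst, dst, spacing = pixel_spacing(sp))
    # up to one ulp of float rounding in the product
    expect_equal(rs$spacing$row_mm_per_px * dst, sp * src, tolerance = 1e-14)
  }
})

test_that("map/unmap pairs are mutual inverses over random points", {
  set.seed(42)
  for (i in 1:20) {
    m <- affine_map(runif(1, 0.1, 3), runif(1, 0.1, 3),
                    runif(1, -100, 100), runif(1, -100, 100),
                    "ORIGINAL", "MODEL")
    ys <- runif(50, -500, 500); xs <- runif(50, -500, 500)
    for (j in 1:50) {
      p <- landmark(ys[j], xs[j], "ORIGINAL")
      rt <- unmap_point(map_point(p, m), m)
      expect_lt(abs(rt$y - p$y) + abs(rt$x - p$x), 1e-9)
    }
  }
})

test_that("map composition matches sequential application", {
  m1 <- affine_map(0.8, 1.2, 3, -2, "ORIGINAL", "PADDED")
  m2 <- affine_map(2, 0.5, -1, 7, "PADDED", "MODEL")
  p <- landmark(12.5, -3.25, "ORIGINAL")
  via <- map_point(map_point(p, m1), m2)
  direct <- map_point(p, compose_maps(m1, m2))
  expect_equal(c(direct$y, direct$x), c(via$y, via$x))
  expect_error(compose_maps(m2, m1), class = "ettc_frame_error")
})

test_that("frame mismatches are rejected", {
  m <- affine_map(1, 1, 0, 0, "PADDED", "MODEL")
  expect_error(map_point(landmark(1, 1, "ORIGINAL"), m),
               class = "ettc_frame_error")
  expect_error(unmap_point(landmark(1, 1, "PADDED"), m),
               class = "ettc_frame_error")
  expect_error(crop_window_for_carina(landmark(1, 1, "CROP"), 512, 512),
               class = "ettc_frame_error")
})

test_that("crop window matches the 50%/25% hard-attention geometry", {
  w <- crop_window_for_carina(landmark(300, 256, "MODEL"), 512, 512)
  expect_equal(c(w$row_start, w$row_stop), c(172, 428))
  expect_equal(c(w$col_start, w$col_stop), c(192, 320))
  expect_equal(c(w$out_h, w$out_w), c(256L, 128L))
  expect_equal(w$out_h / w$out_w, 2)  # 2:1 height-to-width

  w2 <- crop_window_for_carina(landmark(60, 40, "MODEL"), 512, 512)
  expect_equal(c(w2$row_start, w2$row_stop), c(-68, 188))
  expect_equal(c(w2$col_start, w2$col_stop), c(-24, 104))
})

test_that("crop window centers the carina (within rounding)", {
  set.seed(7)
  for (i in 1:200) {
    cy <- runif(1, 0, 511); cx <- runif(1, 0, 511)
    w <- crop_window_for_carina(landmark(cy, cx, "MODEL"), 512, 512)
    expect_lte(abs((w$row_start + w$row_stop) / 2 - cy), 0.5)
    expect_lte(abs((w$col_start + w$col_stop) / 2 - cx), 0.5)
    # MODEL -> CROP map sends the window corners onto the output grid
    tl <- map_point(landmark(w$row_start, w$col_start, "MODEL"), w$map)
    expect_lt(abs(tl$y) + abs(tl$x), 1e-9)
    br <- map_point(landmark(w$row_stop, w$col_stop, "MODEL"), w$map)
    expect_lt(abs(br$y - w$out_h) + abs(br$x - w$out_w), 1e-9)
  }
})

test_that("normalize/denormalize coordinates", {
  expect_equal(normalize_coords(landmark(256, 256, "MODEL"), 512, 512),
               c(0.5, 0.5))
  expect_equal(normalize_coords(landmark(0, 0, "MODEL"), 512, 512), c(0, 0))
  expect_equal(normalize_coords(landmark(128, 64, "CROP"), 256, 128),
               c(0.5, 0.5))
  p <- denormalize_coords(0.3, 0.9, 256, 128, "CROP")
  expect_equal(normalize_coords(p, 256, 128), c(0.3, 0.9))
})

test_that("distance_cm handles isotropic and anisotropic spacing", {
  sp <- pixel_spacing(0.7)
  d <- distance_cm(landmark(300, 256, "MODEL"), landmark(220, 250, "MODEL"), sp)
  expect_equal(d, 0.7 * sqrt(80^2 + 6^2) / 10)
  expect_equal(d, 5.61571, tolerance = 1e-5)

  p <- landmark(5, 5, "MODEL")
  expect_equal(distance_cm(p, p, sp), 0)

  aniso <- pixel_spacing(1.0, 0.5)
  expect_equal(distance_cm(landmark(0, 0, "MODEL"), landmark(0, 10, "MODEL"),
                           aniso), 0.5)

  expect_error(distance_cm(landmark(0, 0, "MODEL"), landmark(0, 0, "CROP"), sp),
               class = "ettc_frame_error")
  expect_error(distance_cm(p, landmark(1, 1, "MODEL"), NULL),
               class = "ettc_spacing_error")
  px <- distance_cm(landmark(0, 0, "MODEL"), landmark(3, 4, "MODEL"), NULL,
                    allow_pixels = TRUE)
  expect_equal(as.numeric(px), 5)
  expect_equal(attr(px, "units"), "px")
})

test_that("distance is a metric on random triples", {
  set.seed(1)
  sp <- pixel_spacing(0.8, 0.6)
  for (i in 1:200) {
    a <- landmark(runif(1, 0, 512), runif(1, 0, 512), "MODEL")
    b <- landmark(runif(1, 0, 512), runif(1, 0, 512), "MODEL")
    cc <- landmark(runif(1, 0, 512), runif(1, 0, 512), "MODEL")
    expect_equal(distance_cm(a, b, sp), distance_cm(b, a, sp))
    expect_gte(distance_cm(a, b, sp), 0)
    expect_lte(distance_cm(a, cc, sp),
               distance_cm(a, b, sp) + distance_cm(b, cc, sp) + 1e-12)
  }
  a <- landmark(3.5, 9.25, "MODEL")
  expect_identical(distance_cm(a, a, sp), 0)
})

test_that("pixel_spacing and affine_map validate their invariants", {
  expect_error(pixel_spacing(0), class = "ettc_input_error")
  expect_error(pixel_spacing(0.5, -1), class = "ettc_input_error")
  expect_error(affine_map(0, 1), class = "ettc_input_error")
  expect_error(landmark(NaN, 0, "MODEL"), class = "ettc_input_error")
})
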