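test_that("geometry sampling is deterministic and class-mix aware", {
  expect_identical(sample_geometry(7), sample_geometry(7))
  # class_mix extremes force the label through the rule engine
  for (i in 1:10) {
    g1 <- sample_geometry(i, class_mix = 1.0)
    expect_equal(decide(geometry_measurements(g1))$plan, "transcatheter")
    g0 <- sample_geometry(i + 100, class_mix = 0.0)
    expect_equal(decide(geometry_measurements(g0))$plan, "surgical")
  }
  # A4C septum accommodates defect plus both rims
  g <- sample_geometry(3)
  expect_gte(g$septum_length_mm + 1e-6,
             g$defect_diameter_mm[["A4C"]] + g$rim_lengths_mm[["roof"]] +
               g$rim_lengths_mm[["mitral"]])
})

test_that("rendering is deterministic and respects the intensity range", {
  g <- sample_geometry(5, class_mix = 1)
  c1 <- render_case(g, rng_seed = 9, image_size = 64)
  c2 <- render_case(g, rng_seed = 9, image_size = 64)
  for (v in view_ids()) {
    expect_identical(c1$frames[[v]]$pixels, c2$frames[[v]]$pixels)
    expect_true(all(c1$frames[[v]]$pixels >= 0 &
                    c1$frames[[v]]$pixels <= 255))
  }
  # noise-free rendering is independent of the speckle seed
  nf <- noise_params(speckle_strength = 0, blur_sigma_px = 0)
  sc <- scale_info(mm_per_pixel = 0.45)
  a <- render_case(g, nf, scale = sc, rng_seed = 1, image_size = 96)
  b <- render_case(g, nf, scale = sc, rng_seed = 2, image_size = 96)
  expect_identical(a$frames$A4C$pixels, b$frames$A4C$pixels)
})

test_that("keypoint geometry maps exactly to pixels through the scale", {
  # 12 mm defect at 0.2 mm/px must separate the endpoints by 60 px
  g <- sample_geometry(5, class_mix = 1)
  g$defect_diameter_mm[] <- 12
  g$septum_length_mm <- 12 + g$rim_lengths_mm[["roof"]] +
    g$rim_lengths_mm[["mitral"]]
  cs <- render_case(g, scale = scale_info(mm_per_pixel = 0.2),
                    rng_seed = 3, image_size = 256)
  for (v in view_ids()) {
    ends <- cs$keypoints[[v]]$points[1:2, ]
    expect_equal(pixel_distance(ends[1, ], ends[2, ]), 60,
                 tolerance = 1e-9)
  }
  # scale soundness across sampled scales
  for (i in 1:5) {
    case <- small_view_case(400 + i, image_size = 96)
    m <- unlist(measure_case(case))
    gm <- unlist(geometry_measurements(case$geometry))
    expect_equal(m[names(gm)], gm, tolerance = 1e-9)
  }
})

test_that("stored labels equal the rule engine applied to the geometry", {
  cases <- generate_cases(30, rng_seed = 17, class_mix = 0.6,
                          image_size = 64)
  for (cs in cases) {
    d <- decide(geometry_measurements(cs$geometry))
    expect_identical(cs$label_plan, d$plan)
    if (d$plan == "transcatheter")
      expect_identical(cs$label_size_mm, d$suggested_size_mm)
    else expect_null(cs$label_size_mm)
  }
  mix <- mean(vapply(cases, function(cs)
    cs$label_plan == "transcatheter", logical(1)))
  expect_gt(mix, 0.3); expect_lt(mix, 0.9)
})

test_that("oversized anatomy at a fixed small scale fails to render", {
  g <- sample_geometry(5, class_mix = 1)
  expect_error(render_case(g, scale = scale_info(mm_per_pixel = 0.05),
                           rng_seed = 1, image_size = 64),
               "does not fit")
})

test_that("datasets round-trip to disk with reproducible hashes", {
  out1 <- withr::local_tempdir()
  out2 <- withr::local_tempdir()
  m1 <- generate_dataset(4, rng_seed = 3, out_dir = out1, image_size = 64)
  m2 <- generate_dataset(4, rng_seed = 3, out_dir = out2, image_size = 64)
  expect_equal(nrow(m1), 4)
  expect_length(list.files(out1, pattern = "\\.png$"), 12)
  expect_length(list.files(out1, pattern = "_[A-Z0-9]+\\.json$"), 12)
  h <- function(d) unname(tools::md5sum(sort(list.files(d, full.names = TRUE,
                                                        pattern = "png|json"))))
  expect_identical(h(out1), h(out2))
  # annotations reload to the stored keypoints
  ann <- read_annotation(m1$annotation_PSSAX[1])
  cases <- generate_cases(4, rng_seed = 3, image_size = 64)
  expect_equal(ann$keypoints$points, cases[[1]]$keypoints$PSSAX$points)
})

test_that("the Doppler-style jet raises intensity inside the defect gap", {
  g <- sample_geometry(5, class_mix = 1)
  sc <- scale_info(mm_per_pixel = 0.45)
  nf0 <- noise_params(speckle_strength = 0, blur_sigma_px = 0,
                      jet_overlay = FALSE)
  nf1 <- noise_params(speckle_strength = 0, blur_sigma_px = 0,
                      jet_overlay = TRUE)
  plain <- render_case(g, nf0, scale = sc, rng_seed = 1, image_size = 96)
  jet <- render_case(g, nf1, scale = sc, rng_seed = 1, image_size = 96)
  ends <- jet$keypoints$SXLAX$points[1:2, ]
  mid <- round(colMeans(ends)) + 1
  expect_gt(jet$frames$SXLAX$pixels[mid[2], mid[1]],
            plain$frames$SXLAX$pixels[mid[2], mid[1]])
})
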