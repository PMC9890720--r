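# small deconvolved image fixture shared across this file
tc_channels <- function() cached("tc_chan", {
  core <- cached("tc_core", generate_core(core_spec(core_diameter = 320,
                                                    pixel_size = 2, seed = 11)))
  deconvolve(rgb_to_od(core$images$CD8, pixel_size = 2))
})

test_that("feature stack has the expected schema and degenerate behaviour", {
  ch <- tc_channels()
  f <- extract_features(ch, scales = c(1, 2))
  expect_equal(dim(f$features)[3], 3 * 2 * 3)  # channels x scales x kinds
  expect_equal(length(f$names), dim(f$features)[3])
  expect_true(all(is.finite(f$features)))

  # constant image: all gradient and local-sd features vanish
  const <- structure(list(conc = array(0.5, c(20, 20, 3)), pixel_size = 2),
                     class = "stain_channels")
  fc <- extract_features(const, scales = c(1, 4))
  grad_sd <- grepl("_grad|_sd", fc$names)
  expect_lt(max(abs(fc$features[, , grad_sd])), 1e-6)
  expect_equal(max(abs(fc$features[, , !grad_sd] - 0.5)), 0, tolerance = 1e-6)
})

test_that("features are equivariant under horizontal flip", {
  ch <- tc_channels()
  f <- extract_features(ch, scales = c(2))
  flipped <- structure(list(conc = ch$conc[, dim(ch$conc)[2]:1, , drop = FALSE],
                            pixel_size = ch$pixel_size),
                       class = "stain_channels")
  ff <- extract_features(flipped, scales = c(2))
  back <- ff$features[, dim(ff$features)[2]:1, , drop = FALSE]
  expect_equal(back, f$features, tolerance = 1e-7)
})

test_that("Gaussian smoothing at scale 8 matches a direct convolution oracle", {
  set.seed(6)
  x <- matrix(0, 40, 40); x[, 21:40] <- 1          # step edge
  x <- x + matrix(rnorm(1600, 0, 0.05), 40)
  sm <- immunotopo:::gauss_smooth_reflect(x, 8)
  # oracle: direct spatial convolution with the same truncated Gaussian
  # kernel and reflected borders, summed by kernel offsets
  sigma <- 8; half <- ceiling(3 * sigma)
  k1 <- dnorm(-half:half, sd = sigma)
  kern <- outer(k1, k1); kern <- kern / sum(kern)
  refl <- function(i, n) {  # symmetric (edge-repeating) reflection
    i <- ifelse(i < 1, 1 - i, i)
    ifelse(i > n, 2 * n + 1 - i, i)
  }
  direct <- matrix(0, 40, 40)
  for (dy in -half:half) for (dx in -half:half) {
    ri <- refl(seq_len(40) + dy, 40); ci <- refl(seq_len(40) + dx, 40)
    direct <- direct + kern[dy + half + 1, dx + half + 1] * x[ri, ci]
  }
  expect_equal(sm, direct, tolerance = 1e-6)
})

test_that("annotations validate, rasterize and round-trip through JSON", {
  expect_error(annotation_set(list(list(polygon = cbind(1, 1), class = "tumour"))),
               "polygon")
  expect_error(annotation_set(list(list(polygon = cbind(c(1, 5, 5), c(1, 1, 5)),
                                        class = "necrosis"))), "class")
  ann <- annotation_set(list(
    list(polygon = cbind(c(2, 10, 10, 2), c(2, 2, 10, 10)), class = "tumour"),
    list(polygon = cbind(c(12, 18, 18, 12), c(12, 12, 18, 18)), class = "stroma")),
    image_id = "img1")
  path <- withr::local_tempfile(fileext = ".json")
  write_annotations(ann, path)
  back <- read_annotations(path)
  expect_equal(back$image_id, "img1")
  expect_equal(length(back$polygons), 2)
  expect_equal(back$polygons[[1]]$class, "tumour")
  # rasterization: an axis-aligned square covers its interior pixel centres
  pix <- immunotopo:::polygon_pixels(ann$polygons[[1]]$polygon, 20, 20)
  expect_setequal(unique(pix$row), 3:10)
  expect_setequal(unique(pix$col), 3:10)
})

test_that("classifier separates distinct textures and is reproducible", {
  # two regions with disjoint constant colours are perfectly separable
  conc <- array(0, c(40, 40, 3))
  conc[, 1:20, 1] <- 1; conc[, 21:40, 2] <- 1
  ch <- structure(list(conc = conc, pixel_size = 2), class = "stain_channels")
  f <- extract_features(ch, scales = c(1, 2))
  ann <- annotation_set(list(
    list(polygon = cbind(c(2, 18, 18, 2), c(2, 2, 38, 38)), class = "tumour"),
    list(polygon = cbind(c(22, 38, 38, 22), c(2, 2, 38, 38)), class = "stroma")))
  m <- train_pixel_classifier(f, ann, n_trees = 50, seed = 2)
  expect_equal(m$holdout_accuracy, 1)

  m2 <- train_pixel_classifier(f, ann, n_trees = 50, seed = 2)
  tis <- tissue_mask(matrix(TRUE, 40, 40), 2)
  expect_identical(classify_pixels(m, f, tis)$labels,
                   classify_pixels(m2, f, tis)$labels)

  # missing class rejected
  expect_error(train_pixel_classifier(f, annotation_set(list(
    list(polygon = cbind(c(2, 18, 18, 2), c(2, 2, 38, 38)), class = "tumour")))),
    "both")

  # schema mismatch rejected
  f2 <- extract_features(ch, scales = c(1))
  expect_error(classify_pixels(m, f2, tis), "schema")
})

test_that("tumour/stroma segmentation recovers the generated geometry", {
  core <- cached("tc_core", generate_core(core_spec(core_diameter = 320,
                                                    pixel_size = 2, seed = 11)))
  ch <- tc_channels()
  f <- extract_features(ch)
  ann <- immunotopo:::auto_annotations(core$truth$mask, seed = 3)
  m <- train_pixel_classifier(f, ann, seed = 3)
  od <- rgb_to_od(core$images$CD8, pixel_size = 2)
  tis <- simple_tissue_detection(od)
  mask <- classify_pixels(m, f, tis)

  # partition invariant: labels partition the frame
  expect_equal(sum(mask$labels == 0) + sum(mask$labels == 1) +
                 sum(mask$labels == 2), length(mask$labels))
  # tumour + stroma area equals tissue area exactly
  expect_equal(sum(mask$areas), tis$area_mm2)

  post <- post_process(mask)
  truth <- core$truth$mask$labels
  joint <- truth > 0 & post$labels > 0
  acc_raw <- mean(mask$labels[joint] == truth[joint])
  acc_post <- mean(post$labels[joint] == truth[joint])
  expect_gt(acc_post, 0.9)
  expect_gte(round(acc_post, 3), round(acc_raw, 3) - 0.005)

  # tumour-area fraction close to the generated fraction
  frac <- post$areas[["tumour"]] / sum(post$areas)
  expect_lt(abs(frac - 0.4), 0.05)

  # empty tissue -> all background
  none <- tissue_mask(matrix(FALSE, dim(f$features)[1], dim(f$features)[2]), 2)
  expect_true(all(classify_pixels(m, f, none)$labels == 0))

  # persist -> load -> predict is identical
  path <- withr::local_tempfile(fileext = ".rds")
  save_pixel_classifier(m, path)
  m_re <- load_pixel_classifier(path)
  expect_identical(classify_pixels(m_re, f, tis)$labels, mask$labels)
})

test_that("post-processing removes speckle islands and fixes clean masks", {
  lab <- matrix(2L, 30, 30)
  lab[1:3, ] <- 0L
  lab[15, 15] <- 1L  # single-pixel tumour island
  m <- compartment_mask(lab, 2)
  out <- post_process(m, min_region_area = 50, mode_filter_radius = 0)
  expect_equal(out$labels[15, 15], 2L)
  expect_true(all(out$labels[1:3, ] == 0L))

  clean <- compartment_mask(rbind(matrix(1L, 15, 30), matrix(2L, 15, 30)), 2)
  out2 <- post_process(clean, min_region_area = 50, mode_filter_radius = 0)
  expect_identical(out2$labels, clean$labels)
})
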