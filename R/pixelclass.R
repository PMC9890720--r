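#' Multiscale per-pixel features for tissue classification
#'
#' Builds the feature stack used by the tumour/stroma pixel classifier:
#' for each deconvolved stain channel (haematoxylin, DAB, residual) and
#' each smoothing scale, the Gaussian-smoothed intensity, the gradient
#' magnitude of the smoothed intensity, and the local standard deviation
#' under the same Gaussian window. Borders are handled by reflection.
#'
#' @param channels a `stain_channels` object from [deconvolve()].
#' @param scales smoothing scales in pixels.
#' @return A `feature_stack`: list with `features` (array
#'   `[rows, cols, n_features]`), `names`, `pixel_size`.
#' @export
extract_features <- function(channels, scales = c(1, 2, 4, 8)) {
  conc <- channels$conc
  d <- dim(conc)
  ch_names <- dimnames(conc)[[3]]
  if (is.null(ch_names)) ch_names <- paste0("ch", seq_len(d[3]))
  feats <- list()
  for (ci in seq_len(d[3])) {
    x <- conc[, , ci]
    for (s in scales) {
      sm <- gauss_smooth_reflect(x, s)
      sm2 <- gauss_smooth_reflect(x^2, s)
      gy <- rbind(sm[2, ] - sm[1, ],
                  (sm[-(1:2), ] - sm[seq_len(nrow(sm) - 2), ]) / 2,
                  sm[nrow(sm), ] - sm[nrow(sm) - 1, ])
      gx <- cbind(sm[, 2] - sm[, 1],
                  (sm[, -(1:2)] - sm[, seq_len(ncol(sm) - 2)]) / 2,
                  sm[, ncol(sm)] - sm[, ncol(sm) - 1])
      base <- paste0(ch_names[ci], "_s", s)
      feats[[paste0(base, "_smooth")]] <- sm
      feats[[paste0(base, "_grad")]] <- sqrt(gx^2 + gy^2)
      feats[[paste0(base, "_sd")]] <- sqrt(pmax(0, sm2 - sm^2))
    }
  }
  arr <- array(unlist(feats, use.names = FALSE),
               dim = c(d[1], d[2], length(feats)))
  structure(list(features = arr, names = names(feats),
                 pixel_size = channels$pixel_size), class = "feature_stack")
}

# Gaussian smoothing with reflected borders (pad, blur, crop)
gauss_smooth_reflect <- function(x, sigma) {
  pad <- ceiling(3 * sigma) + 1L
  nr <- nrow(x); nc <- ncol(x)
  ri <- c(pmin(pad:1, nr), seq_len(nr), nr + 1 - pmin(seq_len(pad), nr))
  ci <- c(pmin(pad:1, nc), seq_len(nc), nc + 1 - pmin(seq_len(pad), nc))
  xp <- x[ri, ci]
  sm <- as.matrix(EBImage::imageData(EBImage::gblur(EBImage::Image(xp),
                                                    sigma = sigma)))
  # quantize away FFT last-bit jitter so thresholds and tree splits are
  # bit-reproducible across runs
  round(sm[pad + seq_len(nr), pad + seq_len(nc)], 8)
}

#' Annotation sets for classifier training
#'
#' Annotations are polygons (in pixel coordinates, 0-based, x right /
#' y down) labelled `tumour` or `stroma`, as drawn over representative
#' areas of a core. They are stored as portable, diffable JSON.
#'
#' @param polygons list of lists with elements `polygon` (n x 2 matrix of
#'   x, y pixel coordinates) and `class` ("tumour" or "stroma").
#' @param image_id identifier of the source image.
#' @export
annotation_set <- function(polygons, image_id = "") {
  for (p in polygons) {
    if (!is.matrix(p$polygon) || ncol(p$polygon) != 2L || nrow(p$polygon) < 3L)
      stop("each polygon must be an n x 2 coordinate matrix, n >= 3", call. = FALSE)
    if (!p$class %in% c("tumour", "stroma"))
      stop("annotation class must be 'tumour' or 'stroma'", call. = FALSE)
  }
  structure(list(polygons = polygons, image_id = image_id),
            class = "annotation_set")
}

#' @rdname annotation_set
#' @param x an `annotation_set`.
#' @param path JSON file path.
#' @export
write_annotations <- function(x, path) {
  jsonlite::write_json(list(image_id = x$image_id,
                            polygons = lapply(x$polygons, function(p)
                              list(class = p$class,
                                   xy = unname(as.matrix(p$polygon))))),
                       path, auto_unbox = TRUE, digits = NA)
  invisible(path)
}

#' @rdname annotation_set
#' @export
read_annotations <- function(path) {
  j <- jsonlite::read_json(path, simplifyVector = TRUE)
  polys <- lapply(seq_len(nrow(j$polygons)), function(i)
    list(polygon = matrix(unlist(j$polygons$xy[[i]]), ncol = 2),
         class = j$polygons$class[[i]]))
  annotation_set(polys, j$image_id)
}

# even-odd (ray casting) point-in-polygon, vectorised over points
points_in_polygon <- function(px, py, poly) {
  n <- nrow(poly)
  inside <- rep(FALSE, length(px))
  j <- n
  for (i in seq_len(n)) {
    xi <- poly[i, 1]; yi <- poly[i, 2]
    xj <- poly[j, 1]; yj <- poly[j, 2]
    cross <- ((yi > py) != (yj > py)) &
      (px < (xj - xi) * (py - yi) / (yj - yi) + xi)
    inside <- xor(inside, cross)
    j <- i
  }
  inside
}

# pixel indices (row, col) covered by a polygon (pixel centres tested)
polygon_pixels <- function(poly, nr, nc) {
  cs <- max(1L, floor(min(poly[, 1]))):min(nc, ceiling(max(poly[, 1])) + 1L)
  rs <- max(1L, floor(min(poly[, 2]))):min(nr, ceiling(max(poly[, 2])) + 1L)
  grid <- expand.grid(row = rs, col = cs)
  keep <- points_in_polygon(grid$col - 0.5, grid$row - 0.5, poly)
  grid[keep, , drop = FALSE]
}

#' Train the tumour/stroma random-forest pixel classifier
#'
#' Samples pixels from the annotated polygons (stratified, capped per
#' class), then fits a random forest on the multiscale feature stack.
#' Training is fully seeded: the same features, annotations and seed give
#' an identical model and identical predictions.
#'
#' @param features a `feature_stack` from [extract_features()].
#' @param annotations an [annotation_set()] with at least one polygon per
#'   class.
#' @param n_trees,max_depth forest size and depth cap.
#' @param sample_cap maximum training pixels per class.
#' @param holdout fraction of sampled pixels held out to report accuracy.
#' @param seed integer seed.
#' @return A `pixel_classifier`: list with the fitted forest, feature
#'   schema, classes, seed and `holdout_accuracy`.
#' @export
train_pixel_classifier <- function(features, annotations, n_trees = 100,
                                   max_depth = 16, sample_cap = 5000,
                                   holdout = 0.2, seed = 1L) {
  arr <- features$features
  nr <- dim(arr)[1]; nc <- dim(arr)[2]; nf <- dim(arr)[3]
  cls <- vapply(annotations$polygons, `[[`, "", "class")
  if (!all(c("tumour", "stroma") %in% cls))
    stop("annotations must include both tumour and stroma polygons",
         call. = FALSE)
  with_seed(seed, {
    pix <- list()
    for (k in c("tumour", "stroma")) {
      pk <- do.call(rbind, lapply(annotations$polygons[cls == k],
                                  function(p) polygon_pixels(p$polygon, nr, nc)))
      pk <- unique(pk)
      if (!nrow(pk)) stop("annotation polygons cover no pixels for class ", k,
                          call. = FALSE)
      if (nrow(pk) > sample_cap)
        pk <- pk[sample.int(nrow(pk), sample_cap), , drop = FALSE]
      pk$class <- k
      pix[[k]] <- pk
    }
    pix <- do.call(rbind, pix)
    flat <- matrix(arr, ncol = nf)
    x <- flat[(pix$col - 1L) * nr + pix$row, , drop = FALSE]
    colnames(x) <- features$names
    y <- factor(pix$class, levels = c("tumour", "stroma"))
    n <- nrow(x)
    test_idx <- sample.int(n, max(1L, round(holdout * n)))
    dtrain <- data.frame(x[-test_idx, , drop = FALSE], .class = y[-test_idx],
                         check.names = FALSE)
    rf <- ranger::ranger(dependent.variable.name = ".class", data = dtrain,
                         num.trees = n_trees, max.depth = max_depth,
                         mtry = floor(sqrt(nf)), seed = seed,
                         num.threads = 1)
    pred <- stats::predict(rf, data.frame(x[test_idx, , drop = FALSE],
                                          check.names = FALSE),
                           num.threads = 1, seed = seed)$predictions
    acc <- mean(pred == y[test_idx])
    structure(list(forest = rf, feature_names = features$names,
                   classes = levels(y), seed = seed,
                   holdout_accuracy = acc), class = "pixel_classifier")
  })
}

#' Classify tissue pixels into tumour and stroma
#'
#' Predicts the class of every tissue pixel with the trained forest;
#' pixels outside the tissue mask become background. Per-class areas are
#' reported in mm^2.
#'
#' @param model a `pixel_classifier`.
#' @param features a `feature_stack` with the schema the model was trained
#'   on.
#' @param tissue a [tissue_mask()].
#' @return A [compartment_mask()].
#' @export
classify_pixels <- function(model, features, tissue) {
  if (!identical(model$feature_names, features$names))
    stop("feature schema does not match the trained model", call. = FALSE)
  arr <- features$features
  nr <- dim(arr)[1]; nc <- dim(arr)[2]; nf <- dim(arr)[3]
  labels <- matrix(0L, nr, nc)
  idx <- which(tissue$mask)
  if (length(idx)) {
    flat <- matrix(arr, ncol = nf)
    x <- data.frame(flat[idx, , drop = FALSE], check.names = FALSE)
    colnames(x) <- features$names
    # fixed seed: vote ties in the forest are broken reproducibly
    pred <- stats::predict(model$forest, x, num.threads = 1,
                           seed = model$seed)$predictions
    labels[idx] <- ifelse(pred == "tumour", 1L, 2L)
  }
  compartment_mask(labels, features$pixel_size)
}

#' Clean up a compartment mask
#'
#' Applies a circular mode (majority) filter within the tissue, then
#' reassigns connected tumour/stroma regions smaller than
#' `min_region_area` to the opposite class.
#'
#' @param mask a [compartment_mask()].
#' @param min_region_area minimum region area in square micrometres.
#' @param mode_filter_radius majority-filter radius in pixels (0 disables).
#' @export
post_process <- function(mask, min_region_area = 500, mode_filter_radius = 2) {
  labels <- mask$labels
  px <- mask$pixel_size
  tissue <- labels > 0L
  if (mode_filter_radius > 0 && any(tissue)) {
    k <- EBImage::makeBrush(2L * as.integer(mode_filter_radius) + 1L, "disc")
    # votes are integer counts; round away FFT noise so ties are stable
    votes <- lapply(1:2, function(v)
      round(as.matrix(EBImage::imageData(
        EBImage::filter2(EBImage::Image((labels == v) * 1), k)))))
    new <- ifelse(votes[[1]] >= votes[[2]], 1L, 2L)
    labels[tissue] <- new[tissue]
  }
  min_px <- min_region_area / px^2
  for (v in 1:2) {
    lab <- as.matrix(EBImage::imageData(EBImage::bwlabel(EBImage::Image((labels == v) * 1))))
    sizes <- tabulate(lab)
    small <- which(sizes > 0 & sizes < min_px)
    if (length(small)) labels[lab %in% small] <- c(2L, 1L)[v]
  }
  labels[!tissue] <- 0L
  compartment_mask(labels, px)
}

#' Persist and reload a pixel classifier
#'
#' Round-tripping through disk reloads to bit-identical predictions.
#' @param model a `pixel_classifier`.
#' @param path file path (RDS).
#' @export
save_pixel_classifier <- function(model, path) {
  saveRDS(model, path)
  invisible(path)
}

#' @rdname save_pixel_classifier
#' @export
load_pixel_classifier <- function(path) {
  m <- readRDS(path)
  if (!inherits(m, "pixel_classifier"))
    stop("file does not contain a pixel_classifier", call. = FALSE)
  m
}
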