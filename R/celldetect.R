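#' Cell detection parameters
#'
#' Parameter set for [detect_cells()], mirroring the usual parameter
#' classes of brightfield positive-cell detection. All physical units;
#' defaults suit nuclear immune-cell markers and are meant to be adjusted
#' per staining type through configuration.
#'
#' @param smoothing_sigma Gaussian smoothing sigma, micrometres.
#' @param background_radius rolling-ball (grey-scale opening) radius for
#'   background subtraction, micrometres.
#' @param detection_threshold OD threshold on the detection channel
#'   (haematoxylin + DAB OD sum).
#' @param min_area,max_area area filter for detected cells, square
#'   micrometres.
#' @param dab_positive_threshold mean-cell DAB OD above which a cell is
#'   called marker-positive.
#' @param watershed_split split touching cells on the distance transform.
#' @return A `detection_params` object.
#' @export
detection_params <- function(smoothing_sigma = 1.5, background_radius = 8,
                             detection_threshold = 0.1,
                             min_area = 10, max_area = 400,
                             dab_positive_threshold = 0.2,
                             watershed_split = TRUE) {
  stopifnot_scalar_pos(smoothing_sigma, "smoothing_sigma")
  stopifnot_scalar_pos(background_radius, "background_radius")
  stopifnot_scalar_pos(detection_threshold, "detection_threshold")
  stopifnot_scalar_pos(dab_positive_threshold, "dab_positive_threshold")
  if (min_area >= max_area) stop("min_area must be < max_area", call. = FALSE)
  structure(list(smoothing_sigma = smoothing_sigma,
                 background_radius = background_radius,
                 detection_threshold = detection_threshold,
                 min_area = min_area, max_area = max_area,
                 dab_positive_threshold = dab_positive_threshold,
                 watershed_split = isTRUE(watershed_split)),
            class = "detection_params")
}

#' Simple tissue detection
#'
#' Flags pixels whose total OD exceeds a threshold, closes the mask
#' morphologically, fills holes below `min_hole_area` and drops objects
#' below `min_object_area`. An empty result raises a warning so the core
#' can be excluded downstream as unusable.
#'
#' @param od an `od_image`.
#' @param od_threshold total-OD threshold for tissue.
#' @param min_hole_area,min_object_area hole-filling and object-size limits
#'   in square micrometres.
#' @return A [tissue_mask()].
#' @export
simple_tissue_detection <- function(od, od_threshold = 0.1,
                                    min_hole_area = 2500,
                                    min_object_area = 2500) {
  px <- od$pixel_size
  tot <- od$od[, , 1] + od$od[, , 2] + od$od[, , 3]
  m <- tot >= od_threshold
  if (any(m) && !all(m)) {
    img <- EBImage::Image(m * 1)
    img <- EBImage::closing(img, EBImage::makeBrush(5, "disc"))
    m <- img > 0.5
    m <- fill_small_holes(m, min_hole_area / px^2)
    m <- drop_small_objects(m, min_object_area / px^2)
  }
  if (!any(m))
    warning("empty tissue mask: core unusable", call. = FALSE)
  tissue_mask(m, px)
}

# fill background components not touching the border and below max_px
fill_small_holes <- function(m, max_px) {
  holes <- EBImage::bwlabel(EBImage::Image(!m * 1))
  h <- as.matrix(EBImage::imageData(holes))
  border <- unique(c(h[1, ], h[nrow(h), ], h[, 1], h[, ncol(h)]))
  sizes <- tabulate(h)
  fill <- setdiff(which(sizes > 0 & sizes <= max_px), border)
  m[h %in% fill] <- TRUE
  m
}

drop_small_objects <- function(m, min_px) {
  lab <- as.matrix(EBImage::imageData(EBImage::bwlabel(EBImage::Image(m * 1))))
  sizes <- tabulate(lab)
  drop <- which(sizes > 0 & sizes < min_px)
  m[lab %in% drop] <- FALSE
  m
}

#' Detect cells on deconvolved stain channels
#'
#' Detection pipeline: Gaussian smoothing of the detection channel (the
#' haematoxylin + DAB OD sum, so strongly DAB-positive cells with weak
#' counterstain are not missed), rolling-ball background subtraction
#' (grey-scale opening), fixed OD threshold, connected components, optional
#' watershed split on the distance transform, then an area filter.
#' Detections whose centroid lies outside the tissue mask are discarded;
#' output is sorted by (y, x) for determinism.
#'
#' @param channels a `stain_channels` object from [deconvolve()].
#' @param params a [detection_params()].
#' @param tissue a [tissue_mask()]; detections outside it are dropped.
#' @return Data frame with columns x_um, y_um, area_um2, mean_h_od,
#'   mean_dab_od, max_dab_od, positive, compartment (initially
#'   "unassigned").
#' @export
detect_cells <- function(channels, params = detection_params(), tissue = NULL) {
  px <- channels$pixel_size
  h_od <- channels$conc[, , 1]
  dab_od <- channels$conc[, , 2]
  det <- h_od + dab_od

  sigma_px <- params$smoothing_sigma / px
  img <- EBImage::Image(det)
  sm <- as.matrix(EBImage::imageData(EBImage::gblur(img, sigma = max(sigma_px, 0.3))))
  sm <- round(sm, 8)  # FFT smoothing is reproducible only to ~1e-15

  # rolling-ball approximation: subtract the grey-scale opening
  br_px <- max(1L, round(params$background_radius / px))
  bg <- EBImage::opening(EBImage::Image(sm),
                         EBImage::makeBrush(2L * br_px + 1L, "disc"))
  fg <- round(sm - as.matrix(EBImage::imageData(bg)), 8)

  bin <- fg > params$detection_threshold
  if (!any(bin)) return(empty_detections())

  if (params$watershed_split) {
    # seeded watershed: local maxima of the background-subtracted channel
    # seed an intensity-guided propagation, splitting touching nuclei
    mx <- EBImage::dilate(EBImage::Image(fg), EBImage::makeBrush(3, "box"))
    peaks <- bin & (fg >= as.matrix(EBImage::imageData(mx)) - 1e-9)
    seeds <- EBImage::bwlabel(EBImage::Image(peaks * 1))
    lab <- EBImage::propagate(EBImage::Image(fg), seeds,
                              mask = EBImage::Image(bin * 1))
  } else {
    lab <- EBImage::bwlabel(EBImage::Image(bin * 1))
  }
  lab <- as.matrix(EBImage::imageData(lab))
  lab[] <- match(lab, sort(unique(lab[lab > 0]))); lab[is.na(lab)] <- 0L

  n_obj <- max(lab)
  if (n_obj == 0L) return(empty_detections())
  idx <- which(lab > 0L)
  obj <- lab[idx]
  row <- ((idx - 1L) %% nrow(lab)) + 1L
  col <- ((idx - 1L) %/% nrow(lab)) + 1L
  npix <- tabulate(obj, n_obj)
  cx <- rowsum(col - 0.5, obj)[, 1] / npix
  cy <- rowsum(row - 0.5, obj)[, 1] / npix
  mh <- rowsum(h_od[idx], obj)[, 1] / npix
  md <- rowsum(dab_od[idx], obj)[, 1] / npix
  xd <- tapply(dab_od[idx], obj, max)

  out <- data.frame(x_um = cx * px, y_um = cy * px,
                    area_um2 = npix * px^2,
                    mean_h_od = mh, mean_dab_od = md,
                    max_dab_od = as.numeric(xd),
                    positive = FALSE, compartment = "unassigned")
  keep <- out$area_um2 >= params$min_area & out$area_um2 <= params$max_area
  out <- out[keep, , drop = FALSE]
  if (!is.null(tissue) && nrow(out)) {
    ccol <- pmin(ncol(tissue$mask), pmax(1L, floor(out$x_um / px) + 1L))
    crow <- pmin(nrow(tissue$mask), pmax(1L, floor(out$y_um / px) + 1L))
    out <- out[tissue$mask[cbind(crow, ccol)], , drop = FALSE]
  }
  out <- out[order(out$y_um, out$x_um), , drop = FALSE]
  rownames(out) <- NULL
  classify_positive(out, params)
}

empty_detections <- function() {
  data.frame(x_um = numeric(0), y_um = numeric(0), area_um2 = numeric(0),
             mean_h_od = numeric(0), mean_dab_od = numeric(0),
             max_dab_od = numeric(0), positive = logical(0),
             compartment = character(0))
}

#' Flag marker-positive cells by mean DAB OD
#'
#' A detection is positive iff its mean DAB OD exceeds
#' `dab_positive_threshold`; raising the threshold can therefore never
#' increase the positive count.
#'
#' @param detections data frame from [detect_cells()].
#' @param params a [detection_params()].
#' @export
classify_positive <- function(detections, params = detection_params()) {
  detections$positive <- detections$mean_dab_od > params$dab_positive_threshold
  detections
}
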