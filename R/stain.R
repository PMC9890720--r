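#' Haematoxylin/DAB stain vector set
#'
#' Bundles the three unit stain vectors (haematoxylin, DAB and a residual
#' completing the basis) used for colour deconvolution in optical-density
#' space, plus the per-channel background (white) intensity `I0`. The
#' defaults are the widely used published H-DAB vectors; both can be
#' overridden, e.g. with vectors estimated from an image by
#' [estimate_stain_vectors()].
#'
#' @param haematoxylin,dab numeric length-3 OD(R,G,B) direction of each
#'   stain; normalised internally to unit Euclidean norm.
#' @param background per-channel background intensity `I0` (default 255 for
#'   8-bit brightfield images).
#' @return An object of class `stain_vectors`: a list with `vectors` (3x3
#'   matrix, rows haematoxylin/dab/residual) and `background`.
#' @export
hdab_stains <- function(haematoxylin = c(0.650, 0.704, 0.286),
                        dab = c(0.269, 0.568, 0.778),
                        background = c(255, 255, 255)) {
  stain_vectors(rbind(haematoxylin = haematoxylin, dab = dab), background)
}

#' @rdname hdab_stains
#' @param vectors 2x3 or 3x3 matrix of stain directions in OD(R,G,B) space
#'   (rows = stains). With two rows the third (residual) vector is completed
#'   as the unit cross product.
#' @export
stain_vectors <- function(vectors, background = c(255, 255, 255)) {
  vectors <- as.matrix(vectors)
  if (ncol(vectors) != 3L || !nrow(vectors) %in% 2:3)
    stop("'vectors' must be a 2x3 or 3x3 matrix", call. = FALSE)
  if (nrow(vectors) == 2L) {
    res <- c(vectors[1, 2] * vectors[2, 3] - vectors[1, 3] * vectors[2, 2],
             vectors[1, 3] * vectors[2, 1] - vectors[1, 1] * vectors[2, 3],
             vectors[1, 1] * vectors[2, 2] - vectors[1, 2] * vectors[2, 1])
    vectors <- rbind(vectors, residual = res)
  }
  nrm <- sqrt(rowSums(vectors^2))
  if (any(nrm == 0)) stop("zero-length stain vector", call. = FALSE)
  vectors <- vectors / nrm
  if (abs(det(vectors)) < 1e-8)
    stop("stain vectors are linearly dependent", call. = FALSE)
  if (any(!is.finite(background)) || any(background <= 0))
    stop("background intensities must be positive", call. = FALSE)
  rownames(vectors) <- c(rownames(vectors)[1:2], "residual")[1:3]
  structure(list(vectors = vectors, background = rep_len(background, 3L)),
            class = "stain_vectors")
}

#' Convert an RGB brightfield image to optical density
#'
#' Applies the Beer-Lambert transform `OD_c = -log10((I_c + eps) / I0_c)`
#' per channel, clamped at zero, so stain contributions become additive.
#'
#' @param image numeric array `[rows, cols, 3]` of intensities in
#'   `[0, I0]` (typically 0..255).
#' @param background per-channel background intensity `I0`.
#' @param pixel_size physical pixel size in micrometres.
#' @param eps small constant guarding `log(0)`; the inverse transform
#'   [od_to_rgb()] uses the same constant so the round trip is exact.
#' @return An `od_image`: list with `od` (array `[rows, cols, 3]`) and
#'   `pixel_size`.
#' @export
rgb_to_od <- function(image, background = c(255, 255, 255), pixel_size = 1,
                      eps = 1e-3) {
  if (any(!is.finite(background)) || any(background <= 0))
    stop("background intensities must be positive", call. = FALSE)
  stopifnot_scalar_pos(pixel_size, "pixel_size")
  d <- dim(image)
  if (length(d) != 3L || d[3] != 3L)
    stop("'image' must be a rows x cols x 3 array", call. = FALSE)
  i0 <- rep_len(background, 3L)
  od <- image
  for (c in 1:3) od[, , c] <- -log10((image[, , c] + eps) / i0[c])
  od[od < 0] <- 0
  structure(list(od = od, pixel_size = pixel_size), class = "od_image")
}

#' @rdname rgb_to_od
#' @param od an `od_image` (or bare OD array).
#' @export
od_to_rgb <- function(od, background = c(255, 255, 255), eps = 1e-3) {
  arr <- if (inherits(od, "od_image")) od$od else od
  i0 <- rep_len(background, 3L)
  out <- arr
  for (c in 1:3) out[, , c] <- i0[c] * 10^(-arr[, , c]) - eps
  out
}

#' Colour deconvolution of an OD image into per-stain channels
#'
#' Solves, for every pixel, the 3x3 linear system expressing the observed
#' OD vector as a non-negative mix of the stain vectors. Negative
#' coefficients (noise outside the stain simplex) are clamped to zero.
#'
#' @param od an `od_image` from [rgb_to_od()].
#' @param stains a `stain_vectors` object.
#' @return A `stain_channels` object: list with `conc` (array
#'   `[rows, cols, 3]`, slices haematoxylin/dab/residual) and `pixel_size`.
#' @export
deconvolve <- function(od, stains = hdab_stains()) {
  if (!inherits(od, "od_image")) stop("'od' must be an od_image", call. = FALSE)
  m <- stains$vectors
  if (abs(det(m)) < 1e-8) stop("degenerate stain matrix", call. = FALSE)
  d <- dim(od$od)
  flat <- matrix(od$od, ncol = 3L)          # pixels x channels
  conc <- flat %*% solve(m)                 # od = conc %*% m
  conc[conc < 0] <- 0
  conc <- array(conc, dim = d)
  dimnames(conc) <- list(NULL, NULL, rownames(m))
  structure(list(conc = conc, pixel_size = od$pixel_size),
            class = "stain_channels")
}

#' Forward-render per-stain concentrations to an OD image
#'
#' Inverse of [deconvolve()]: mixes stain concentration maps through the
#' stain matrix into an OD image. Used by the synthetic-core generator and
#' as the round-trip oracle for deconvolution.
#'
#' @param conc array `[rows, cols, k]` of per-stain OD amplitudes
#'   (k = 2 or 3; a missing residual slice is treated as zero).
#' @inheritParams deconvolve
#' @param pixel_size micrometres per pixel.
#' @export
render_stains <- function(conc, stains = hdab_stains(), pixel_size = 1) {
  d <- dim(conc)
  if (length(d) != 3L) stop("'conc' must be a 3-d array", call. = FALSE)
  m <- stains$vectors[seq_len(d[3]), , drop = FALSE]
  od <- matrix(conc, ncol = d[3]) %*% m
  structure(list(od = array(od, dim = c(d[1], d[2], 3L)),
                 pixel_size = pixel_size), class = "od_image")
}

#' Estimate stain vectors from a stained image
#'
#' Robust plane-fitting estimator: tissue pixels above an OD floor are
#' projected onto the principal plane of the OD point cloud, and the two
#' stain directions are taken at extreme percentiles of the angular
#' distribution in that plane. With too few stained pixels the published
#' default H-DAB vectors are returned with a warning (attribute
#' `fallback = TRUE`).
#'
#' @inheritParams deconvolve
#' @param od_floor minimum total OD for a pixel to count as stained tissue.
#' @param percentiles lower/upper angular percentiles defining the extreme
#'   stain directions.
#' @param min_pixels minimum number of stained pixels required.
#' @param background background intensities for the returned set.
#' @return A `stain_vectors` object; rows ordered haematoxylin, dab by
#'   proximity to the default vectors.
#' @export
estimate_stain_vectors <- function(od, od_floor = 0.15,
                                   percentiles = c(0.01, 0.99),
                                   min_pixels = 200,
                                   background = c(255, 255, 255)) {
  flat <- matrix(od$od, ncol = 3L)
  keep <- rowSums(flat) > od_floor
  fallback <- function(msg) {
    warning(paste0("stain estimation failed (", msg,
                   "); falling back to default H-DAB vectors"), call. = FALSE)
    out <- hdab_stains(background = background)
    attr(out, "fallback") <- TRUE
    out
  }
  if (sum(keep) < min_pixels) return(fallback("too few stained pixels"))
  x <- flat[keep, , drop = FALSE]
  sv <- svd(x, nu = 0, nv = 3)
  plane <- sv$v[, 1:2]
  # orient the first axis towards the data so angles are well defined
  proj <- x %*% plane
  if (mean(proj[, 1]) < 0) { plane[, 1] <- -plane[, 1]; proj[, 1] <- -proj[, 1] }
  phi <- atan2(proj[, 2], proj[, 1])
  qs <- stats::quantile(phi, probs = percentiles, names = FALSE)
  vecs <- sapply(qs, function(a) plane %*% c(cos(a), sin(a)))
  vecs <- t(vecs)
  vecs[rowSums(vecs) < 0, ] <- -vecs[rowSums(vecs) < 0, ]  # stains have positive OD
  vecs <- vecs / sqrt(rowSums(vecs^2))
  # label rows by angular proximity to the published defaults
  ref <- hdab_stains()$vectors
  a11 <- sum(vecs[1, ] * ref[1, ]); a12 <- sum(vecs[1, ] * ref[2, ])
  if (a12 > a11) vecs <- vecs[2:1, , drop = FALSE]
  rownames(vecs) <- c("haematoxylin", "dab")
  stain_vectors(vecs, background = background)
}
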