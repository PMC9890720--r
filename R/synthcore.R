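#' Specification of a synthetic TMA core
#'
#' Describes one circular tissue-microarray core: geometry, tumour-nest
#' layout, per-marker immune-cell densities, nucleus rendering and staining
#' optics. [generate_core()] turns a spec into one RGB image per marker
#' (emulating serial sections of the same core) plus exact ground truth.
#'
#' @param core_diameter core diameter in micrometres.
#' @param pixel_size micrometres per pixel.
#' @param tumour_fraction fraction of the tissue disk occupied by tumour
#'   nests, in (0, 1).
#' @param nest_count number of tumour nests (Gaussian bumps whose
#'   thresholded sum forms irregular nests).
#' @param marker_densities named list, marker -> c(tumour, stroma) density
#'   of marker-positive cells per mm^2.
#' @param nucleus_densities c(tumour, stroma) density of unstained
#'   (counterstain-only) nuclei per mm^2, rendered on every marker image.
#' @param cell_radius c(mean, sd) of cell radius in micrometres.
#' @param h_amplitude haematoxylin OD amplitude of a nucleus disc.
#' @param dab_amplitude DAB OD amplitude of a positive cell disc.
#' @param background_od c(tumour, stroma) diffuse haematoxylin background,
#'   giving the two compartments distinguishable texture.
#' @param noise_sd standard deviation of additive Gaussian OD noise.
#' @param stains `stain_vectors` used for Beer-Lambert rendering.
#' @param seed integer seed; identical (spec, seed) pairs generate
#'   bit-identical output.
#' @return A `core_spec` object (validated list).
#' @export
core_spec <- function(core_diameter = 800, pixel_size = 2,
                      tumour_fraction = 0.4, nest_count = 6,
                      marker_densities = list(CD8 = c(tumour = 500, stroma = 400)),
                      nucleus_densities = c(tumour = 1200, stroma = 500),
                      cell_radius = c(mean = 3.5, sd = 0.5),
                      h_amplitude = 0.7, dab_amplitude = 0.8,
                      background_od = c(tumour = 0.18, stroma = 0.06),
                      noise_sd = 0.02,
                      stains = hdab_stains(), seed = 1L) {
  stopifnot_scalar_pos(core_diameter, "core_diameter")
  stopifnot_scalar_pos(pixel_size, "pixel_size")
  if (!is.numeric(tumour_fraction) || tumour_fraction <= 0 || tumour_fraction >= 1)
    stop("tumour_fraction must lie strictly between 0 and 1", call. = FALSE)
  if (nest_count < 1) stop("nest_count must be >= 1", call. = FALSE)
  if (!length(marker_densities) || is.null(names(marker_densities)))
    stop("marker_densities must be a named list", call. = FALSE)
  for (m in names(marker_densities)) {
    d <- marker_densities[[m]]
    if (length(d) != 2L || any(d < 0))
      stop("each marker density must be c(tumour, stroma) >= 0", call. = FALSE)
  }
  if (any(nucleus_densities < 0)) stop("nucleus densities must be >= 0", call. = FALSE)
  structure(list(core_diameter = core_diameter, pixel_size = pixel_size,
                 tumour_fraction = tumour_fraction, nest_count = nest_count,
                 marker_densities = marker_densities,
                 nucleus_densities = nucleus_densities,
                 cell_radius = cell_radius, h_amplitude = h_amplitude,
                 dab_amplitude = dab_amplitude, background_od = background_od,
                 noise_sd = noise_sd, stains = stains, seed = seed),
            class = "core_spec")
}

# irregular tumour-nest geometry: threshold the sum of random Gaussian
# bumps at the quantile that yields exactly the requested pixel fraction
nest_field <- function(npx, radius_px, nest_count) {
  cx <- (npx + 1) / 2
  xs <- seq_len(npx)
  field <- matrix(0, npx, npx)
  for (k in seq_len(nest_count)) {
    a <- stats::runif(1, 0, 2 * pi)
    r <- sqrt(stats::runif(1)) * 0.75 * radius_px
    mx <- cx + r * cos(a); my <- cx + r * sin(a)
    w <- stats::runif(1, 0.22, 0.42) * radius_px
    field <- field + exp(-(outer((xs - my)^2, (xs - mx)^2, "+")) / (2 * w^2))
  }
  field
}

# stamp anti-aliased discs (additive) into a matrix; coordinates in pixels
add_discs <- function(mat, x_px, y_px, r_px, amp) {
  nr <- nrow(mat); nc <- ncol(mat)
  for (i in seq_along(x_px)) {
    r <- r_px[i]
    cs <- max(1L, floor(x_px[i] - r)):min(nc, ceiling(x_px[i] + r + 1))
    rs <- max(1L, floor(y_px[i] - r)):min(nr, ceiling(y_px[i] + r + 1))
    d <- sqrt(outer((rs - 0.5 - y_px[i])^2, (cs - 0.5 - x_px[i])^2, "+"))
    mat[rs, cs] <- mat[rs, cs] + amp * pmin(1, pmax(0, r + 0.5 - d))
  }
  mat
}

# draw n points uniformly over the pixels with the given label
scatter_in <- function(labels, value, n, pixel_size) {
  idx <- which(labels == value)
  if (n == 0L || !length(idx))
    return(data.frame(x_um = numeric(0), y_um = numeric(0)))
  pick <- idx[sample.int(length(idx), n, replace = TRUE)]
  row <- ((pick - 1L) %% nrow(labels)) + 1L
  col <- ((pick - 1L) %/% nrow(labels)) + 1L
  data.frame(x_um = (col - 1 + stats::runif(n)) * pixel_size,
             y_um = (row - 1 + stats::runif(n)) * pixel_size)
}

#' Generate one synthetic TMA core with ground truth
#'
#' Renders, for every marker in the spec, an RGB brightfield image of the
#' same core geometry (as on serial sections): a circular tissue disk with
#' irregular tumour nests, counterstained nuclei everywhere, DAB-positive
#' marker cells at the per-compartment Poisson densities, mixed through the
#' stain matrix by Beer-Lambert optics, plus Gaussian OD noise.
#'
#' @param spec a [core_spec()].
#' @param seed integer seed (defaults to `spec$seed`).
#' @return A list with `images` (named list marker -> integer RGB array in
#'   0..255), `truth` (list with `cells` data frame: x_um, y_um, marker,
#'   positive, compartment; and `mask`, a [compartment_mask()]) and `spec`.
#' @export
generate_core <- function(spec, seed = spec$seed) {
  if (!inherits(spec, "core_spec")) stop("'spec' must be a core_spec", call. = FALSE)
  with_seed(seed, {
    px <- spec$pixel_size
    npx <- round(spec$core_diameter / px)
    radius_px <- npx / 2
    cx <- (npx + 1) / 2
    xs <- seq_len(npx)
    dist2 <- outer((xs - cx)^2, (xs - cx)^2, "+")
    tissue <- dist2 <= radius_px^2
    field <- nest_field(npx, radius_px, spec$nest_count)
    thr <- stats::quantile(field[tissue], 1 - spec$tumour_fraction, names = FALSE)
    labels <- matrix(0L, npx, npx)
    labels[tissue] <- 2L
    labels[tissue & field > thr] <- 1L
    mask <- compartment_mask(labels, px)

    rmean <- spec$cell_radius[["mean"]]; rsd <- spec$cell_radius[["sd"]]
    draw_cells <- function(marker, dens_tum, dens_str, positive) {
      out <- list()
      for (k in 1:2) {
        dens <- if (k == 1) dens_tum else dens_str
        n <- stats::rpois(1, dens * mask$areas[[k]])
        pts <- scatter_in(labels, k, n, px)
        if (nrow(pts)) {
          pts$marker <- marker
          pts$positive <- positive
          pts$compartment <- c("tumour", "stroma")[k]
          out[[k]] <- pts
        }
      }
      do.call(rbind, out)
    }

    cells <- list(); images <- list()
    for (marker in names(spec$marker_densities)) {
      d <- spec$marker_densities[[marker]]
      pos <- draw_cells(marker, d[[1]], d[[2]], TRUE)
      neg <- draw_cells(marker, spec$nucleus_densities[[1]],
                        spec$nucleus_densities[[2]], FALSE)
      mcells <- rbind(pos, neg)
      if (is.null(mcells))
        mcells <- data.frame(x_um = numeric(0), y_um = numeric(0),
                             marker = character(0), positive = logical(0),
                             compartment = character(0))
      cells[[marker]] <- mcells

      conc <- array(0, dim = c(npx, npx, 3L))
      h <- matrix(0, npx, npx)
      h[labels == 1L] <- spec$background_od[["tumour"]]
      h[labels == 2L] <- spec$background_od[["stroma"]]
      if (nrow(mcells)) {
        radii <- pmax(1, stats::rnorm(nrow(mcells), rmean, rsd)) / px
        h <- add_discs(h, mcells$x_um / px, mcells$y_um / px, radii,
                       spec$h_amplitude)
        ip <- which(mcells$positive)
        dab <- matrix(0, npx, npx)
        if (length(ip))
          dab <- add_discs(dab, mcells$x_um[ip] / px, mcells$y_um[ip] / px,
                           radii[ip], spec$dab_amplitude)
        conc[, , 2] <- dab
      }
      conc[, , 1] <- h
      od <- render_stains(conc, spec$stains, pixel_size = px)
      if (spec$noise_sd > 0) {
        od$od <- od$od + stats::rnorm(length(od$od), 0, spec$noise_sd)
        od$od[od$od < 0] <- 0
      }
      rgb <- od_to_rgb(od, background = spec$stains$background)
      rgb <- round(pmin(pmax(rgb, 0), 255))
      storage.mode(rgb) <- "integer"
      images[[marker]] <- rgb
    }
    cells <- do.call(rbind, c(cells, list(make.row.names = FALSE)))
    list(images = images, truth = list(cells = cells, mask = mask), spec = spec)
  })
}

#' Write and read a synthetic core image
#'
#' Cores are written as RGB TIFFs (one file per marker); masks as 8-bit
#' label PNGs via [write_mask_png()].
#' @param image integer RGB array (0..255) from [generate_core()].
#' @param path output path.
#' @export
write_core_tiff <- function(image, path) {
  tiff::writeTIFF(image / 255, path)
  invisible(path)
}

#' @rdname write_core_tiff
#' @export
read_core_tiff <- function(path) {
  img <- tiff::readTIFF(path)
  img <- round(img * 255)
  storage.mode(img) <- "integer"
  img
}
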