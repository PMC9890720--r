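#' Assign detections to tumour or stroma compartments
#'
#' Each detection takes the compartment of the mask label at its centroid
#' pixel; centroids on background (or outside the frame, with a warning)
#' become "unassigned" and are excluded from both compartment counts.
#'
#' @param detections data frame from [detect_cells()] (columns x_um, y_um).
#' @param mask a [compartment_mask()].
#' @export
assign_cells <- function(detections, mask) {
  if (!nrow(detections)) {
    detections$compartment <- character(0)
    return(detections)
  }
  lab <- mask_label_at(mask, detections$x_um, detections$y_um)
  if (anyNA(lab)) {
    warning(sum(is.na(lab)), " detection(s) outside the image frame",
            call. = FALSE)
    lab[is.na(lab)] <- 0L
  }
  detections$compartment <- c("unassigned", "tumour", "stroma")[lab + 1L]
  detections
}

#' Per-case, per-marker compartment density record
#'
#' Counts positive detections per compartment and divides by the
#' compartment areas of the mask. Cases with zero tumour or stroma area are
#' flagged unusable (as with fragmented or lost TMA cores).
#'
#' @param detections assigned detections (see [assign_cells()]); only rows
#'   with `positive == TRUE` are counted.
#' @param mask a [compartment_mask()].
#' @param case_id,marker identifiers for the output record.
#' @return One-row data frame: case_id, marker, tumour_count, stroma_count,
#'   tumour_area, stroma_area, tumour_density, stroma_density,
#'   overall_density, usable.
#' @export
compute_density <- function(detections, mask, case_id = "", marker = "") {
  pos <- detections[detections$positive, , drop = FALSE]
  tc <- sum(pos$compartment == "tumour")
  sc <- sum(pos$compartment == "stroma")
  ta <- mask$areas[["tumour"]]; sa <- mask$areas[["stroma"]]
  usable <- ta > 0 && sa > 0
  if (ta + sa <= 0) warning("zero tissue area: case unusable", call. = FALSE)
  data.frame(case_id = case_id, marker = marker,
             tumour_count = tc, stroma_count = sc,
             tumour_area = ta, stroma_area = sa,
             tumour_density = if (ta > 0) tc / ta else NA_real_,
             stroma_density = if (sa > 0) sc / sa else NA_real_,
             overall_density = if (ta + sa > 0) (tc + sc) / (ta + sa) else NA_real_,
             usable = usable)
}

#' Cohort-level density thresholds
#'
#' Derives one cutoff per marker from the cohort's density records. The
#' default derivation takes the median over cases of the overall density
#' (counts over both compartments divided by total area); the alternative
#' pools the per-case tumour and stroma densities and takes their joint
#' median. Even-sized samples use the mean of the middle pair.
#'
#' @param records density records (rows as from [compute_density()]).
#' @param derivation `"cohort_median_overall"` or
#'   `"pooled_compartment_median"`.
#' @return Data frame: marker, cutoff, derivation.
#' @export
cohort_median_threshold <- function(records,
                                    derivation = c("cohort_median_overall",
                                                   "pooled_compartment_median")) {
  derivation <- match.arg(derivation)
  if ("usable" %in% names(records))
    records <- records[records$usable, , drop = FALSE]
  if (!nrow(records)) stop("no usable density records", call. = FALSE)
  out <- lapply(split(records, records$marker), function(r) {
    v <- switch(derivation,
                cohort_median_overall = r$overall_density,
                pooled_compartment_median = c(r$tumour_density, r$stroma_density))
    v <- v[is.finite(v)]
    if (!length(v)) stop("no usable densities for marker ", r$marker[1],
                         call. = FALSE)
    data.frame(marker = r$marker[1], cutoff = stats::median(v),
               derivation = derivation)
  })
  out <- do.call(rbind, c(out, list(make.row.names = FALSE)))
  out[order(out$marker), , drop = FALSE]
}

#' Hot / cold / excluded tumour-immune phenotype call
#'
#' Decision order: *hot* if the intratumoural density reaches the cutoff;
#' otherwise *excluded* if the stromal density reaches it; otherwise
#' *cold*. "High in compartment" uses `>=` (ties count as high).
#'
#' @param tumour_density,stroma_density densities in cells/mm^2
#'   (vectorised).
#' @param cutoff positive density cutoff (single value or per-element).
#' @return Character vector in `{"hot", "cold", "excluded"}`; `NA` where a
#'   density is missing.
#' @export
call_phenotype <- function(tumour_density, stroma_density, cutoff) {
  if (any(cutoff <= 0)) stop("cutoff must be positive", call. = FALSE)
  out <- ifelse(tumour_density >= cutoff, "hot",
                ifelse(stroma_density >= cutoff, "excluded", "cold"))
  out[!is.finite(tumour_density) | !is.finite(stroma_density)] <- NA_character_
  out
}

#' Combined-marker phenotype call
#'
#' For marker combinations (e.g. CD3/CD8 T-cells), a compartment counts as
#' high under the default `"and"` rule only if *every* constituent marker
#' is high there; `"or"` requires any; `"mean"` compares the mean of
#' cutoff-normalised densities to 1. The hot/excluded/cold decision order
#' then matches [call_phenotype()]. Any unusable constituent yields `NA`.
#'
#' @param tumour_densities,stroma_densities numeric vectors, one value per
#'   constituent marker.
#' @param cutoffs per-marker cutoffs, same order.
#' @param rule `"and"`, `"or"` or `"mean"`.
#' @export
combine_markers <- function(tumour_densities, stroma_densities, cutoffs,
                            rule = c("and", "or", "mean")) {
  rule <- match.arg(rule)
  if (length(tumour_densities) != length(cutoffs) ||
      length(stroma_densities) != length(cutoffs))
    stop("densities and cutoffs must have one entry per marker", call. = FALSE)
  if (any(!is.finite(tumour_densities)) || any(!is.finite(stroma_densities)))
    return(NA_character_)
  high <- function(d) switch(rule,
                             "and" = all(d >= cutoffs),
                             "or" = any(d >= cutoffs),
                             "mean" = mean(d / cutoffs) >= 1)
  if (high(tumour_densities)) "hot"
  else if (high(stroma_densities)) "excluded"
  else "cold"
}

#' Dichotomize a density at a cutoff
#'
#' `high` iff the density strictly exceeds the cutoff; the boundary value
#' falls in the low group (low = "<= cutoff").
#'
#' @param density overall densities (cells/mm^2).
#' @param cutoff cutoff from [cohort_median_threshold()].
#' @return factor with levels `low`, `high`.
#' @export
dichotomize <- function(density, cutoff) {
  factor(ifelse(density > cutoff, "high", "low"), levels = c("low", "high"))
}

#' PD-L1 combined positive score
#'
#' CPS = 100 x (PD-L1-positive tumour cells + lymphocytes + macrophages) /
#' viable tumour cells, capped at 100; `high` iff CPS >= `cutoff`
#' (default 10, the clinical positivity cut-off).
#'
#' @param n_positive PD-L1-positive cells of all scored types.
#' @param n_viable_tumour viable tumour cells (> 0).
#' @param cutoff CPS positivity cutoff.
#' @param case_id identifier.
#' @return One-row data frame: case_id, n_positive, n_viable_tumour, cps,
#'   high.
#' @export
compute_cps <- function(n_positive, n_viable_tumour, cutoff = 10,
                        case_id = "") {
  if (n_viable_tumour <= 0)
    stop("CPS undefined: no viable tumour cells", call. = FALSE)
  if (n_positive < 0) stop("negative cell count", call. = FALSE)
  cps <- min(100, 100 * n_positive / n_viable_tumour)
  data.frame(case_id = case_id, n_positive = n_positive,
             n_viable_tumour = n_viable_tumour, cps = cps,
             high = cps >= cutoff)
}

#' Semiquantitative TILs score from a density
#'
#' Maps a density onto the ordinal scale none (0) / few (+) /
#' moderate (++) / extensive (+++) by interval membership against three
#' strictly increasing bin edges. A density of 0 always maps to "0".
#'
#' @param density densities (cells/mm^2), vectorised.
#' @param bin_edges three strictly increasing edges; densities < edge1 map
#'   to "0", < edge2 to "+", < edge3 to "++", else "+++".
#' @return Ordered factor with levels `0 < + < ++ < +++`.
#' @export
semiquant_bins <- function(density, bin_edges = c(10, 100, 500)) {
  if (length(bin_edges) != 3L || any(diff(bin_edges) <= 0))
    stop("bin_edges must be three strictly increasing values", call. = FALSE)
  lev <- c("0", "+", "++", "+++")
  idx <- findInterval(density, bin_edges) + 1L
  idx[density == 0] <- 1L
  factor(lev[idx], levels = lev, ordered = TRUE)
}

#' Average duplicate cores per patient
#'
#' TMA slides may carry two cores per patient; densities are averaged per
#' (case, marker) before thresholding and phenotyping.
#'
#' @param records density records, possibly with repeated
#'   (case_id, marker) rows.
#' @export
average_cores <- function(records) {
  key <- interaction(records$case_id, records$marker, drop = TRUE)
  out <- lapply(split(records, key), function(r) {
    if (nrow(r) == 1L) return(r)
    m <- r[1, , drop = FALSE]
    for (col in c("tumour_count", "stroma_count", "tumour_area", "stroma_area",
                  "tumour_density", "stroma_density", "overall_density"))
      if (col %in% names(r)) m[[col]] <- mean(r[[col]])
    if ("usable" %in% names(r)) m$usable <- any(r$usable)
    m
  })
  out <- do.call(rbind, c(out, list(make.row.names = FALSE)))
  out[order(out$case_id, out$marker), , drop = FALSE]
}
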