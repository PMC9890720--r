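#' Pipeline configuration
#'
#' Assembles and validates the configuration for [run_pipeline()]. Unknown
#' keys are rejected so configuration typos fail before any stage runs.
#'
#' @param out_dir output directory for stage CSVs.
#' @param seed global seed; all stage randomness derives from it.
#' @param cohort list of [cohort_spec()] arguments for the simulate stage.
#' @param stains list: `haematoxylin`, `dab` OD triples, `background`,
#'   `od_floor`, `estimate_per_image` (logical).
#' @param detection named list of [detection_params()] argument lists, one
#'   per marker (`default` used otherwise).
#' @param classifier list: `n_trees`, `max_depth`, `sample_cap`,
#'   `scales`, `n_train_cases`.
#' @param threshold_derivation cutoff derivation, see
#'   [cohort_median_threshold()].
#' @param combos named list of marker combinations for combined phenotype
#'   calls.
#' @param combo_rule `"and"`, `"or"` or `"mean"`.
#' @param cps_cutoff CPS positivity cutoff.
#' @param log_level `"info"` or `"quiet"`.
#' @return A validated `pipeline_config`.
#' @export
pipeline_config <- function(out_dir = tempfile("immunotopo_"), seed = 1L,
                            cohort = list(), stains = list(),
                            detection = list(), classifier = list(),
                            threshold_derivation = "cohort_median_overall",
                            combos = list(`CD3/CD8` = c("CD3", "CD8")),
                            combo_rule = "and", cps_cutoff = 10,
                            log_level = "info") {
  cfg <- list(out_dir = out_dir, seed = as.integer(seed), cohort = cohort,
              stains = stains, detection = detection, classifier = classifier,
              threshold_derivation = threshold_derivation, combos = combos,
              combo_rule = combo_rule, cps_cutoff = cps_cutoff,
              log_level = log_level)
  validate_config(cfg)
}

#' @rdname pipeline_config
#' @param cfg a (possibly hand-assembled) configuration list.
#' @export
validate_config <- function(cfg) {
  known <- c("out_dir", "seed", "cohort", "stains", "detection", "classifier",
             "threshold_derivation", "combos", "combo_rule", "cps_cutoff",
             "log_level")
  extra <- setdiff(names(cfg), known)
  if (length(extra))
    stop("unknown configuration key(s): ", paste(extra, collapse = ", "),
         call. = FALSE)
  for (k in setdiff(known, names(cfg))) cfg[[k]] <- formals(pipeline_config)[[k]]
  if (!cfg$threshold_derivation %in%
      c("cohort_median_overall", "pooled_compartment_median"))
    stop("invalid threshold_derivation", call. = FALSE)
  if (!cfg$combo_rule %in% c("and", "or", "mean"))
    stop("invalid combo_rule", call. = FALSE)
  structure(cfg, class = "pipeline_config")
}

#' @rdname pipeline_config
#' @param path YAML file with the same keys.
#' @export
read_pipeline_config <- function(path) {
  cfg <- yaml::read_yaml(path)
  cfg$combos <- lapply(cfg$combos, unlist)
  validate_config(cfg)
}

log_msg <- function(cfg, ...) {
  if (!identical(cfg$log_level, "quiet"))
    message("[immunotopo] ", ...)
}

# Derive training annotations from a ground-truth mask: small axis-aligned
# squares fully contained in one class, mirroring a user annotating
# representative areas of tumour and stroma.
auto_annotations <- function(mask, n_per_class = 5, size_px = 14, seed = 1L) {
  with_seed(seed, {
    polys <- list()
    half <- size_px %/% 2
    er_brush <- EBImage::makeBrush(2L * half + 1L, "box")
    for (v in 1:2) {
      core <- EBImage::erode(EBImage::Image((mask$labels == v) * 1), er_brush)
      idx <- which(as.matrix(EBImage::imageData(core)) > 0.5)
      if (!length(idx))
        stop("no annotatable region for class ",
             c("tumour", "stroma")[v], call. = FALSE)
      pick <- idx[sample.int(length(idx), min(n_per_class, length(idx)))]
      row <- ((pick - 1L) %% nrow(mask$labels)) + 1L
      col <- ((pick - 1L) %/% nrow(mask$labels)) + 1L
      for (i in seq_along(pick)) {
        x0 <- col[i] - half; x1 <- col[i] + half
        y0 <- row[i] - half; y1 <- row[i] + half
        polys[[length(polys) + 1L]] <- list(
          polygon = cbind(c(x0, x1, x1, x0), c(y0, y0, y1, y1)),
          class = c("tumour", "stroma")[v])
      }
    }
    annotation_set(polys)
  })
}

write_stage_csv <- function(df, path, cfg) {
  hash <- substr(digest_config(cfg), 1, 12)
  con <- file(path, "w", encoding = "UTF-8")
  on.exit(close(con))
  writeLines(sprintf("# immunotopo config=%s seed=%d", hash, cfg$seed), con)
  utils::write.csv(df, con, row.names = FALSE)
  invisible(path)
}

#' @rdname pipeline_config
#' @export
read_stage_csv <- function(path) {
  utils::read.csv(path, comment.char = "#")
}

digest_config <- function(cfg) {
  # dependency-free content hash over the keys that affect results
  # (out_dir and log_level do not)
  cfg <- unclass(cfg)
  cfg <- cfg[setdiff(names(cfg), c("out_dir", "log_level"))]
  raw <- serialize(cfg[order(names(cfg))], NULL, ascii = TRUE)
  v <- as.numeric(raw)
  h <- c(17, 31)
  for (i in seq_along(v)) {
    j <- 1L + (i %% 2L)
    h[j] <- (h[j] * 131 + v[i]) %% 1000000007
  }
  sprintf("%08x%08x", as.integer(h[1]), as.integer(h[2]))
}

#' Run the full pipeline on a synthetic cohort
#'
#' Stage order: simulate -> stain separation -> tissue detection -> cell
#' detection -> pixel classification -> topography -> statistics. One
#' pixel classifier is trained per cohort from ground-truth-derived
#' annotations on the first `n_train_cases` cases and applied to all
#' cores. Every output CSV carries a header comment with the
#' configuration hash and seed; rerunning with identical configuration
#' and seed reproduces the outputs byte for byte.
#'
#' @param config a [pipeline_config()].
#' @return Invisibly, a list with `densities`, `thresholds`, `phenotypes`,
#'   `combos`, `results` (statistics), `clinical`, `classifier`, and the
#'   per-case predicted masks.
#' @export
run_pipeline <- function(config) {
  cfg <- validate_config(config)
  dir.create(cfg$out_dir, showWarnings = FALSE, recursive = TRUE)
  cspec <- do.call(cohort_spec, c(cfg$cohort, list(seed = cfg$seed)))
  log_msg(cfg, "simulate: ", cspec$n_cases, " cases, markers ",
          paste(cspec$markers, collapse = "/"))
  cohort <- generate_cohort(cspec, detail = "images")

  st <- cfg$stains
  stains <- hdab_stains(
    haematoxylin = st$haematoxylin %||% c(0.650, 0.704, 0.286),
    dab = st$dab %||% c(0.269, 0.568, 0.778),
    background = st$background %||% c(255, 255, 255))
  scales <- cfg$classifier$scales %||% c(1, 2, 4, 8)
  n_train <- cfg$classifier$n_train_cases %||% 2L

  det_params <- function(marker) {
    args <- cfg$detection[[marker]] %||% cfg$detection$default %||% list()
    do.call(detection_params, args)
  }

  # train one shared pixel classifier from the first cases' first-marker
  # images, with annotations derived from the ground-truth masks
  ref_marker <- cspec$markers[1]
  train_feats <- NULL; train_ann <- NULL; model <- NULL
  n_unusable <- 0L
  densities <- list(); masks <- list()
  for (i in seq_along(cohort$cases)) {
    case <- cohort$cases[[i]]
    od <- rgb_to_od(case$images[[ref_marker]], background = stains$background,
                    pixel_size = case$spec$pixel_size)
    tissue <- simple_tissue_detection(od)
    if (tissue$area_mm2 == 0) {
      log_msg(cfg, case$case_id, ": empty tissue, flagged unusable")
      n_unusable <- n_unusable + 1L
      next
    }
    chan <- deconvolve(od, stains)
    feats <- extract_features(chan, scales)
    if (is.null(model)) {
      if (is.null(train_feats)) {
        train_feats <- feats
        train_ann <- auto_annotations(case$truth$mask, seed = cfg$seed)
      }
      if (i >= n_train || i == length(cohort$cases)) {
        model <- train_pixel_classifier(train_feats, train_ann,
                                        n_trees = cfg$classifier$n_trees %||% 100,
                                        max_depth = cfg$classifier$max_depth %||% 16,
                                        seed = cfg$seed)
        log_msg(cfg, "pixel classifier trained, held-out accuracy ",
                round(model$holdout_accuracy, 3))
      } else next
    }
    mask <- post_process(classify_pixels(model, feats, tissue))
    masks[[case$case_id]] <- mask
    for (marker in cspec$markers) {
      mo <- rgb_to_od(case$images[[marker]], background = stains$background,
                      pixel_size = case$spec$pixel_size)
      mc <- deconvolve(mo, stains)
      cells <- detect_cells(mc, det_params(marker), tissue)
      cells <- assign_cells(cells, mask)
      densities[[paste(case$case_id, marker)]] <-
        compute_density(cells, mask, case$case_id, marker)
    }
  }
  # first pass skipped cases while collecting training data: run them now
  done <- unique(vapply(densities, function(d) d$case_id[1], ""))
  for (case in cohort$cases) {
    if (case$case_id %in% done || is.null(case$images)) next
    od <- rgb_to_od(case$images[[ref_marker]], background = stains$background,
                    pixel_size = case$spec$pixel_size)
    tissue <- simple_tissue_detection(od)
    if (tissue$area_mm2 == 0) next
    chan <- deconvolve(od, stains)
    feats <- extract_features(chan, scales)
    mask <- post_process(classify_pixels(model, feats, tissue))
    masks[[case$case_id]] <- mask
    for (marker in cspec$markers) {
      mo <- rgb_to_od(case$images[[marker]], background = stains$background,
                      pixel_size = case$spec$pixel_size)
      mc <- deconvolve(mo, stains)
      cells <- detect_cells(mc, det_params(marker), tissue)
      cells <- assign_cells(cells, mask)
      densities[[paste(case$case_id, marker)]] <-
        compute_density(cells, mask, case$case_id, marker)
    }
  }
  densities <- do.call(rbind, c(unname(densities), list(make.row.names = FALSE)))
  densities <- densities[order(densities$case_id, densities$marker), ]
  rownames(densities) <- NULL
  densities <- average_cores(densities)
  log_msg(cfg, "densities: ", length(unique(densities$case_id)),
          " usable cases (", n_unusable, " flagged)")

  out <- summarize_cohort(densities, cohort$clinical, cfg)
  out$masks <- masks
  out$classifier <- model
  out$clinical <- cohort$clinical
  out$cohort <- cohort
  write_stage_csv(densities, file.path(cfg$out_dir, "densities.csv"), cfg)
  write_stage_csv(out$thresholds, file.path(cfg$out_dir, "thresholds.csv"), cfg)
  write_stage_csv(out$phenotypes, file.path(cfg$out_dir, "phenotypes.csv"), cfg)
  write_stage_csv(out$results, file.path(cfg$out_dir, "results.csv"), cfg)
  write_stage_csv(cohort$clinical, file.path(cfg$out_dir, "clinical.csv"), cfg)
  invisible(out)
}

#' Topography and statistics from a density table
#'
#' The analysis half of [run_pipeline()]: derives cohort thresholds,
#' single-marker and combined phenotype calls, dichotomized densities and
#' the association/survival statistics, from any density table (pipeline
#' output or ground truth).
#'
#' @param densities density records (as from [compute_density()]).
#' @param clinical clinical table with case_id, fgfr3, cps_high, os_months,
#'   event columns.
#' @param cfg a [pipeline_config()].
#' @return List with `densities`, `thresholds`, `phenotypes`, `combos`,
#'   `results`.
#' @export
summarize_cohort <- function(densities, clinical, cfg = pipeline_config()) {
  cfg <- validate_config(cfg)
  thresholds <- cohort_median_threshold(densities, cfg$threshold_derivation)
  cut_of <- function(m) thresholds$cutoff[match(m, thresholds$marker)]
  phen <- densities
  phen$cutoff <- cut_of(phen$marker)
  phen$phenotype <- call_phenotype(phen$tumour_density, phen$stroma_density,
                                   phen$cutoff)
  phen$density_group <- dichotomize(phen$overall_density, phen$cutoff)
  phenotypes <- phen[, c("case_id", "marker", "tumour_density",
                         "stroma_density", "overall_density", "cutoff",
                         "phenotype", "density_group")]

  combos <- list()
  for (cname in names(cfg$combos)) {
    mk <- cfg$combos[[cname]]
    if (!all(mk %in% phenotypes$marker)) next
    by_case <- split(phenotypes[phenotypes$marker %in% mk, ],
                     phenotypes$case_id[phenotypes$marker %in% mk])
    rows <- lapply(by_case, function(d) {
      d <- d[match(mk, d$marker), , drop = FALSE]
      if (anyNA(d$case_id) || nrow(d) < length(mk)) return(NULL)
      data.frame(case_id = d$case_id[1], combo = cname,
                 phenotype = combine_markers(d$tumour_density,
                                             d$stroma_density,
                                             cut_of(mk), cfg$combo_rule))
    })
    combos[[cname]] <- do.call(rbind, rows)
  }
  combos <- if (length(combos))
    do.call(rbind, c(unname(combos), list(make.row.names = FALSE)))
  else NULL

  results <- cohort_statistics(phenotypes, combos, clinical)
  list(densities = densities, thresholds = thresholds,
       phenotypes = phenotypes, combos = combos, results = results)
}

# the statistical battery over the cohort tables
cohort_statistics <- function(phenotypes, combos, clinical) {
  res <- list()
  add <- function(analysis, tr) {
    res[[length(res) + 1L]] <<- data.frame(
      analysis = analysis, method = tr$method,
      statistic = tr$statistic, df = tr$df, p_value = tr$p_value,
      effect = tr$effect, n = tr$n)
  }
  for (m in unique(phenotypes$marker)) {
    d <- phenotypes[phenotypes$marker == m, ]
    d <- merge(d, clinical, by = "case_id")
    # density group x FGFR3 mutation
    if ("fgfr3" %in% names(d) && length(unique(d$fgfr3)) == 2L) {
      tab <- table(d$density_group, d$fgfr3)[, c("neg", "pos"), drop = FALSE]
      if (all(dim(tab) == 2L) && !any(rowSums(tab) == 0) &&
          !any(colSums(tab) == 0))
        add(paste0("fgfr3_x_", m, "_density"),
            suppressWarnings(pearson_chi_square(tab)))
    }
    # density group x PD-L1 CPS status
    if ("cps_high" %in% names(d) && length(unique(d$cps_high)) == 2L) {
      tab <- table(d$density_group, d$cps_high)
      if (all(dim(tab) == 2L) && !any(rowSums(tab) == 0) &&
          !any(colSums(tab) == 0))
        add(paste0("cps_x_", m, "_density"),
            suppressWarnings(pearson_chi_square(tab)))
    }
    # overall survival by density group
    if (all(c("os_months", "event") %in% names(d)) &&
        nlevels(droplevels(d$density_group)) == 2L && any(d$event))
      add(paste0("os_x_", m, "_density"),
          logrank(d$os_months, d$event, d$density_group))
  }
  if (!is.null(combos)) for (cname in unique(combos$combo)) {
    d <- merge(combos[combos$combo == cname, ], clinical, by = "case_id")
    d <- d[!is.na(d$phenotype), ]
    if ("cps_high" %in% names(d) && length(unique(d$cps_high)) == 2L &&
        length(unique(d$phenotype)) >= 2L) {
      tab <- table(factor(d$phenotype, c("hot", "cold", "excluded")),
                   d$cps_high)
      tab <- tab[rowSums(tab) > 0, , drop = FALSE]
      if (ncol(tab) == 2L && !any(colSums(tab) == 0))
        add(paste0("cps_x_", cname, "_phenotype"),
            tryCatch(fisher_exact(tab),
                     error = function(e) suppressWarnings(pearson_chi_square(tab))))
    }
  }
  # CD3 vs CD8 density correlation (co-expression check)
  if (all(c("CD3", "CD8") %in% phenotypes$marker)) {
    a <- phenotypes[phenotypes$marker == "CD3", c("case_id", "tumour_density")]
    b <- phenotypes[phenotypes$marker == "CD8", c("case_id", "tumour_density")]
    ab <- merge(a, b, by = "case_id")
    if (nrow(ab) >= 3) {
      sp <- spearman(ab$tumour_density.x, ab$tumour_density.y)
      res[[length(res) + 1L]] <- data.frame(
        analysis = "spearman_cd3_cd8_tumour", method = "spearman",
        statistic = sp$rho, df = NA_real_, p_value = sp$p_value,
        effect = sp$rho, n = sp$n)
    }
  }
  do.call(rbind, c(res, list(make.row.names = FALSE)))
}

`%||%` <- function(a, b) if (is.null(a)) b else a
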