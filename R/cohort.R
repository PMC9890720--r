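#' Specification of a synthetic TMA cohort
#'
#' Defines the statistical structure of a simulated squamous bladder cancer
#' TMA cohort: the mix of planned tumour-immune phenotype classes
#' (hot / cold / excluded), per-marker reference density medians with
#' class-conditional multipliers, the CD3-CD8 co-expression correlation, a
#' logistic model tying PD-L1 CPS positivity to hot phenotypes, an FGFR3
#' mutation model that attenuates CD8 / perforin / CD79A densities, and a
#' proportional-hazards survival model with a protective effect of high
#' perforin density.
#'
#' Default reference medians are typical overall per-case medians for
#' immune-cell markers in squamous bladder cancer (cells/mm^2). Densities
#' are drawn log-normally around the class-conditional medians
#' (strictly positive and right-skewed, like observed densities).
#'
#' @param n_cases number of cases.
#' @param phenotype_mix named probabilities for hot / cold / excluded;
#'   must sum to 1.
#' @param markers marker panel.
#' @param marker_medians named reference overall density medians
#'   (cells/mm^2) per marker.
#' @param class_multipliers 3x2 matrix (rows hot/cold/excluded, columns
#'   tumour/stroma): multiplicative offsets applied to the reference median.
#' @param density_sdlog log-normal within-class spread of densities.
#' @param marker_corr latent Gaussian correlation between CD3 and CD8
#'   densities (lineage co-expression), in \[-1, 1\].
#' @param pdl1_model list: `baseline_prob` P(CPS >= 10) for non-hot cases
#'   and `odds_ratio` for hot cases.
#' @param fgfr3_model list: `prevalence` of activating FGFR3 mutations and
#'   `density_effect` (< 1) multiplying CD8 / perforin / CD79A densities in
#'   mutated cases.
#' @param survival_model list: `baseline_hazard` per month, `hr_perforin_high`
#'   hazard ratio for perforin-high cases, `censoring_rate` (fraction with
#'   random uniform censoring; the rest are censored administratively at
#'   `max_followup`) and `max_followup` months.
#' @param core list of [core_spec()] arguments overriding the per-case core
#'   geometry (densities are filled in per case).
#' @param seed cohort seed; all per-case seeds are derived from it.
#' @return A `cohort_spec` object.
#' @export
cohort_spec <- function(n_cases = 60,
                        phenotype_mix = c(hot = 1/3, cold = 1/3, excluded = 1/3),
                        markers = c("CD3", "CD8", "CD79A", "Perforin"),
                        marker_medians = c(CD3 = 582.3, CD8 = 291.6,
                                           CD79A = 85.9, Perforin = 9.0),
                        class_multipliers = rbind(hot = c(tumour = 4, stroma = 1.2),
                                                  cold = c(tumour = 0.25, stroma = 0.3),
                                                  excluded = c(tumour = 0.2, stroma = 4)),
                        density_sdlog = 0.25,
                        marker_corr = 0.9,
                        pdl1_model = list(baseline_prob = 0.05, odds_ratio = 8),
                        fgfr3_model = list(prevalence = 0.15, density_effect = 0.35),
                        survival_model = list(baseline_hazard = 0.03,
                                              hr_perforin_high = 0.35,
                                              censoring_rate = 0.3,
                                              max_followup = 120),
                        core = list(), seed = 1L) {
  if (abs(sum(phenotype_mix) - 1) > 1e-8)
    stop("phenotype_mix must sum to 1", call. = FALSE)
  if (any(phenotype_mix < 0) || any(phenotype_mix > 1))
    stop("phenotype_mix probabilities must lie in [0, 1]", call. = FALSE)
  if (!all(c("hot", "cold", "excluded") %in% names(phenotype_mix)))
    stop("phenotype_mix must name hot, cold and excluded", call. = FALSE)
  if (abs(marker_corr) > 1) stop("marker_corr must lie in [-1, 1]", call. = FALSE)
  if (!all(markers %in% names(marker_medians)))
    stop("every marker needs a reference median", call. = FALSE)
  if (survival_model$baseline_hazard <= 0 || survival_model$hr_perforin_high <= 0)
    stop("hazards must be positive", call. = FALSE)
  if (pdl1_model$baseline_prob <= 0 || pdl1_model$baseline_prob >= 1)
    stop("pdl1 baseline_prob must lie in (0, 1)", call. = FALSE)
  structure(list(n_cases = as.integer(n_cases), phenotype_mix = phenotype_mix,
                 markers = markers, marker_medians = marker_medians,
                 class_multipliers = class_multipliers,
                 density_sdlog = density_sdlog, marker_corr = marker_corr,
                 pdl1_model = pdl1_model, fgfr3_model = fgfr3_model,
                 survival_model = survival_model, core = core,
                 seed = as.integer(seed)),
            class = "cohort_spec")
}

#' Generate a synthetic TMA cohort
#'
#' Draws, for each case, a planned phenotype class, class-conditional
#' per-compartment densities for every marker (CD3 and CD8 correlated via a
#' Gaussian copula at `marker_corr`), PD-L1 CPS status from the logistic
#' odds model, FGFR3 status with its density attenuation, and overall
#' survival from the proportional-hazards model. Ground truth is produced
#' at the requested level of `detail`:
#'
#' * `"counts"` - planned densities plus Poisson cell counts on the nominal
#'   compartment areas (fast; sufficient for all statistics downstream of
#'   the density table),
#' * `"cells"` - additionally a compartment mask and exact cell coordinates
#'   per case,
#' * `"images"` - additionally rendered RGB images per marker.
#'
#' @param spec a [cohort_spec()].
#' @param detail one of `"counts"`, `"cells"`, `"images"`.
#' @return A `synthetic_cohort`: list with `clinical` (data frame), `truth`
#'   (per-case planned class, per-marker densities and Poisson counts),
#'   `densities` (ground-truth [density records][compute_density] usable
#'   directly by the topography stage) and `cases` (per-case specs, plus
#'   masks/cells/images at higher detail).
#' @export
generate_cohort <- function(spec, detail = c("counts", "cells", "images")) {
  if (!inherits(spec, "cohort_spec")) stop("'spec' must be a cohort_spec", call. = FALSE)
  detail <- match.arg(detail)
  n <- spec$n_cases
  seeds <- derive_seeds(spec$seed, n + 1L)
  core_args <- spec$core
  core_proto <- do.call(core_spec, core_args)
  tf <- core_proto$tumour_fraction
  disk_mm2 <- pi * (core_proto$core_diameter / 2000)^2
  area_tum <- disk_mm2 * tf
  area_str <- disk_mm2 * (1 - tf)

  with_seed(seeds[n + 1L], {
    classes <- sample(names(spec$phenotype_mix), n, replace = TRUE,
                      prob = spec$phenotype_mix)
    # latent correlated copula draws for CD3/CD8; independent otherwise
    z <- matrix(stats::rnorm(n * length(spec$markers)), n,
                dimnames = list(NULL, spec$markers))
    if (all(c("CD3", "CD8") %in% spec$markers)) {
      r <- spec$marker_corr
      z[, "CD8"] <- r * z[, "CD3"] + sqrt(1 - r^2) * z[, "CD8"]
    }
    fgfr3 <- stats::rbinom(n, 1, spec$fgfr3_model$prevalence) == 1
    dens <- list()
    for (m in spec$markers) {
      mult <- spec$class_multipliers[classes, , drop = FALSE]
      med <- spec$marker_medians[[m]]
      eff <- ifelse(fgfr3 & m %in% c("CD8", "Perforin", "CD79A"),
                    spec$fgfr3_model$density_effect, 1)
      # one latent draw per case shifts tumour and stroma jointly
      lat <- exp(spec$density_sdlog * z[, m])
      dens[[m]] <- data.frame(
        marker = m, case = seq_len(n), class = classes,
        tumour = med * mult[, "tumour"] * eff * lat,
        stroma = med * mult[, "stroma"] * eff * lat)
    }
    dens <- do.call(rbind, c(dens, list(make.row.names = FALSE)))
    overall <- (dens$tumour * tf + dens$stroma * (1 - tf))
    perf_high <- if ("Perforin" %in% spec$markers) {
      po <- overall[dens$marker == "Perforin"]
      po > spec$marker_medians[["Perforin"]]
    } else rep(FALSE, n)

    pm <- spec$pdl1_model
    is_hot <- classes == "hot"
    p_cps <- stats::plogis(stats::qlogis(pm$baseline_prob) +
                             log(pm$odds_ratio) * is_hot)
    cps_high <- stats::rbinom(n, 1, p_cps) == 1

    sm <- spec$survival_model
    rate <- sm$baseline_hazard * ifelse(perf_high, sm$hr_perforin_high, 1)
    death <- stats::rexp(n, rate)
    cens <- ifelse(stats::runif(n) < sm$censoring_rate,
                   stats::runif(n, 0, sm$max_followup), sm$max_followup)
    os <- pmin(death, cens)
    event <- death <= cens

    clinical <- data.frame(
      case_id = sprintf("case_%03d", seq_len(n)),
      subtype = sample(c("pure", "mix"), n, replace = TRUE, prob = c(0.6, 0.4)),
      age = round(stats::rnorm(n, 68, 10)),
      sex = sample(c("male", "female"), n, replace = TRUE),
      stage = sample(c("pT1", "pT2", "pT3", "pT4"), n, replace = TRUE,
                     prob = c(0.08, 0.08, 0.5, 0.34)),
      nodal = sample(c("pN0", "pN+"), n, replace = TRUE, prob = c(0.75, 0.25)),
      fgfr3 = ifelse(fgfr3, "pos", "neg"),
      cps_high = cps_high,
      perforin_high_true = perf_high,
      os_months = round(os, 2),
      event = event)

    # Poisson ground-truth counts on the nominal compartment areas
    dens$case_id <- clinical$case_id[dens$case]
    dens$tumour_count <- stats::rpois(nrow(dens), dens$tumour * area_tum)
    dens$stroma_count <- stats::rpois(nrow(dens), dens$stroma * area_str)
    # class implied by the true densities under the cohort's own median
    # threshold: FGFR3 attenuation and the log-normal spread can move a
    # case across the cutoff, in which case the density-implied class -
    # not the originally sampled label - is the recoverable ground truth
    true_class <- character(nrow(dens))
    for (m in unique(dens$marker)) {
      ix <- which(dens$marker == m)
      true_class[ix] <- call_phenotype(dens$tumour[ix], dens$stroma[ix],
                                       stats::median(overall[ix]))
    }
    truth <- data.frame(case_id = dens$case_id, marker = dens$marker,
                        class = dens$class, true_class = true_class,
                        overall_density = overall,
                        tumour_density = dens$tumour, stroma_density = dens$stroma,
                        tumour_count = dens$tumour_count,
                        stroma_count = dens$stroma_count)
    records <- data.frame(case_id = dens$case_id, marker = dens$marker,
                          tumour_count = dens$tumour_count,
                          stroma_count = dens$stroma_count,
                          tumour_area = area_tum, stroma_area = area_str)
    records$tumour_density <- records$tumour_count / records$tumour_area
    records$stroma_density <- records$stroma_count / records$stroma_area
    records$overall_density <- (records$tumour_count + records$stroma_count) /
      (records$tumour_area + records$stroma_area)

    cases <- NULL
    if (detail != "counts") {
      cases <- vector("list", n)
      for (i in seq_len(n)) {
        md <- lapply(split(dens[dens$case == i, ], dens$marker[dens$case == i]),
                     function(d) c(tumour = d$tumour, stroma = d$stroma))
        cs <- do.call(core_spec,
                      c(core_args, list(marker_densities = md, seed = seeds[i])))
        gc_out <- generate_core(cs, seed = seeds[i])
        if (detail == "cells") gc_out$images <- NULL
        cases[[i]] <- c(list(case_id = clinical$case_id[i]), gc_out)
      }
      names(cases) <- clinical$case_id
    }
    structure(list(spec = spec, clinical = clinical, truth = truth,
                   densities = records, cases = cases, detail = detail),
              class = "synthetic_cohort")
  })
}

#' Write a synthetic cohort to disk
#'
#' Writes `<case_id>_<marker>.tiff` images (if rendered),
#' `<case_id>_mask.png` label masks (if present), `<case_id>_cells.csv`
#' ground-truth cell tables, the cohort-level `clinical.csv` and the spec
#' echoed to `cohort.yaml`.
#'
#' @param cohort a `synthetic_cohort`.
#' @param dir output directory (created if missing).
#' @export
write_cohort <- function(cohort, dir) {
  dir.create(dir, showWarnings = FALSE, recursive = TRUE)
  utils::write.csv(cohort$clinical, file.path(dir, "clinical.csv"),
                   row.names = FALSE)
  utils::write.csv(cohort$truth, file.path(dir, "truth.csv"), row.names = FALSE)
  spec <- cohort$spec
  echo <- lapply(spec[setdiff(names(spec), "core")], function(x)
    if (is.matrix(x)) apply(x, 1, as.list, simplify = FALSE) else x)
  yaml::write_yaml(echo, file.path(dir, "cohort.yaml"))
  if (!is.null(cohort$cases)) {
    for (cs in cohort$cases) {
      utils::write.csv(cs$truth$cells,
                       file.path(dir, paste0(cs$case_id, "_cells.csv")),
                       row.names = FALSE)
      write_mask_png(cs$truth$mask, file.path(dir, paste0(cs$case_id, "_mask.png")))
      for (m in names(cs$images))
        write_core_tiff(cs$images[[m]],
                        file.path(dir, paste0(cs$case_id, "_", m, ".tiff")))
    }
  }
  invisible(dir)
}
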