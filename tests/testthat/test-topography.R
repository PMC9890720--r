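test_that("cells take the compartment of the mask label under their centroid", {
  lab <- matrix(0L, 10, 10)
  lab[, 1:5] <- 1L; lab[, 6:10] <- 2L; lab[1, ] <- 0L
  mask <- compartment_mask(lab, 10)  # 10 um pixels
  det <- data.frame(x_um = c(25, 75, 25, 150), y_um = c(55, 55, 5, 55),
                    positive = TRUE)
  expect_warning(out <- assign_cells(det, mask), "outside")
  expect_equal(out$compartment, c("tumour", "stroma", "unassigned", "unassigned"))
  # conservation: every detection lands in exactly one bucket
  expect_equal(sum(table(out$compartment)), nrow(det))
})

test_that("density records follow count/area arithmetic and dimensional scaling", {
  lab <- matrix(2L, 10, 10); lab[1:5, ] <- 1L
  det <- data.frame(x_um = runif(10, 0, 100), y_um = runif(10, 0, 50),
                    positive = TRUE, compartment = "tumour")
  # 10 positives in 0.05 mm^2 of tumour -> 200 cells/mm^2
  mask <- compartment_mask(lab, sqrt(0.05 * 1e6 / 50))
  rec <- compute_density(det, mask, "c", "CD8")
  expect_equal(rec$tumour_density, 10 / 0.05)
  # doubling pixel size multiplies areas x4 and divides densities by 4
  mask2 <- compartment_mask(lab, 2 * sqrt(0.05 * 1e6 / 50))
  rec2 <- compute_density(det, mask2, "c", "CD8")
  expect_equal(rec2$tumour_area, 4 * rec$tumour_area)
  expect_equal(rec2$tumour_density, rec$tumour_density / 4)
  # overall density pools counts and areas
  expect_equal(rec$overall_density,
               (rec$tumour_count + rec$stroma_count) /
                 (rec$tumour_area + rec$stroma_area))
})

test_that("cohort median thresholds use the stated median conventions", {
  rec <- function(d, m = "CD8", id = paste0("c", seq_along(d)))
    data.frame(case_id = id, marker = m, tumour_density = d, stroma_density = d,
               overall_density = d, usable = TRUE)
  expect_equal(cohort_median_threshold(rec(c(100, 200, 300)))$cutoff, 200)
  expect_equal(cohort_median_threshold(rec(c(100, 200, 300, 400)))$cutoff, 250)
  # permutation invariance
  r <- rec(c(7, 1, 9, 4, 2))
  expect_identical(cohort_median_threshold(r),
                   cohort_median_threshold(r[sample(5), ]))
  # pooled-compartment alternative pools tumour and stroma densities
  r2 <- data.frame(case_id = c("a", "b"), marker = "CD8",
                   tumour_density = c(10, 20), stroma_density = c(30, 40),
                   overall_density = c(15, 35), usable = TRUE)
  expect_equal(cohort_median_threshold(r2, "pooled_compartment_median")$cutoff, 25)
  expect_error(cohort_median_threshold(r2[0, ]), "usable")
})

test_that("hot/cold/excluded calls follow the decision order", {
  c0 <- 100
  expect_equal(call_phenotype(2 * c0, 0, c0), "hot")
  expect_equal(call_phenotype(0, 2 * c0, c0), "excluded")
  expect_equal(call_phenotype(0, 0, c0), "cold")
  # boundary: >= counts as high in a compartment
  expect_equal(call_phenotype(c0, 0, c0), "hot")
  expect_equal(call_phenotype(0, c0, c0), "excluded")
  expect_true(is.na(call_phenotype(NA, 50, c0)))
  expect_error(call_phenotype(1, 1, 0), "cutoff")
  # partition: proportions over callable cases sum to 1
  set.seed(8)
  calls <- call_phenotype(runif(200, 0, 300), runif(200, 0, 300), 100)
  expect_equal(sum(table(calls)), 200)
  expect_true(all(calls %in% c("hot", "cold", "excluded")))
})

test_that("combined-marker calls apply the AND rule and its degenerate cases", {
  cuts <- c(100, 100)
  # both markers tumour-high -> hot
  expect_equal(combine_markers(c(150, 120), c(10, 10), cuts), "hot")
  # CD3 tumour-high, CD4 tumour-low, both stroma-high -> excluded under AND
  expect_equal(combine_markers(c(150, 50), c(120, 130), cuts), "excluded")
  # both compartments below -> cold
  expect_equal(combine_markers(c(50, 50), c(50, 50), cuts), "cold")
  # single-marker combo equals the single-marker call
  expect_equal(combine_markers(180, 20, 100), call_phenotype(180, 20, 100))
  # OR and mean rules
  expect_equal(combine_markers(c(150, 50), c(10, 10), cuts, rule = "or"), "hot")
  expect_equal(combine_markers(c(150, 70), c(10, 10), cuts, rule = "mean"), "hot")
  # unusable constituent -> no call
  expect_true(is.na(combine_markers(c(NA, 50), c(10, 10), cuts)))
})

test_that("density dichotomization puts the boundary in the low group", {
  expect_equal(as.character(dichotomize(291.6, 291.6)), "low")
  expect_equal(as.character(dichotomize(0, 291.6)), "low")
  expect_equal(as.character(dichotomize(291.7, 291.6)), "high")
  # exactly half of an even cohort with distinct values is high at its median
  set.seed(9)
  d <- sample(1:1000, 50)
  expect_equal(sum(dichotomize(d, median(d)) == "high"), 25)
})

test_that("CPS follows the positive/viable ratio with cap and cutoff", {
  expect_equal(compute_cps(0, 100)$cps, 0)
  expect_false(compute_cps(0, 100)$high)
  r <- compute_cps(20, 200)
  expect_equal(r$cps, 10)
  expect_true(r$high)   # boundary: CPS >= cutoff is high
  expect_equal(compute_cps(300, 200)$cps, 100)
  expect_error(compute_cps(5, 0), "viable")
})

test_that("semiquantitative bins are ordinal and monotone", {
  expect_equal(as.character(semiquant_bins(0)), "0")
  expect_equal(as.character(semiquant_bins(250, c(10, 100, 500))), "++")
  expect_equal(as.character(semiquant_bins(c(5, 50, 600))), c("0", "+", "+++"))
  d <- sort(runif(100, 0, 1000))
  expect_true(all(diff(as.integer(semiquant_bins(d))) >= 0))
  expect_error(semiquant_bins(1, c(10, 5, 100)), "increasing")
})

test_that("duplicate cores per patient are averaged before thresholding", {
  rec <- data.frame(case_id = c("p1", "p1", "p2"), marker = "CD8",
                    tumour_count = c(10, 20, 5), stroma_count = c(2, 4, 1),
                    tumour_area = c(0.1, 0.1, 0.1), stroma_area = c(0.2, 0.2, 0.2),
                    tumour_density = c(100, 200, 50),
                    stroma_density = c(10, 20, 5),
                    overall_density = c(40, 80, 20), usable = TRUE)
  avg <- average_cores(rec)
  expect_equal(nrow(avg), 2)
  expect_equal(avg$tumour_density[avg$case_id == "p1"], 150)
  expect_equal(avg$overall_density[avg$case_id == "p1"], 60)
})

test_that("planned phenotype classes are recovered from ground-truth densities", {
  ph <- do.call(rbind, lapply(21:23, function(s) {
    coh <- generate_cohort(cohort_spec(n_cases = 60, seed = s))
    out <- summarize_cohort(coh$densities, coh$clinical,
                            pipeline_config(combos = list()))
    merge(out$phenotypes, coh$truth, by = c("case_id", "marker"))
  }))
  expect_gt(mean(ph$phenotype == ph$true_class), 0.9)
  # class proportions partition the callable cases
  expect_equal(sum(table(ph$phenotype)), nrow(ph))
})
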