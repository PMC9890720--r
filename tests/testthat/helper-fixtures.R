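# Shared fixtures and independent oracles for the test suite.
# Everything is generated in code; heavier fixtures are cached across files.

.fx <- new.env(parent = emptyenv())

cached <- function(key, expr) {
  if (!exists(key, envir = .fx)) assign(key, force(expr), envir = .fx)
  get(key, envir = .fx)
}

# default-geometry core used by several files
fixture_core <- function() cached("core42", generate_core(core_spec(seed = 42)))

# greedy one-to-one centroid matching within `radius` micrometres
match_centroids <- function(det, truth, radius = 3.5) {
  nd <- nrow(det); nt <- nrow(truth)
  if (!nd || !nt)
    return(list(matched = 0L, f1 = 0, precision = 0, recall = 0))
  d2 <- outer(det$x_um, truth$x_um, "-")^2 + outer(det$y_um, truth$y_um, "-")^2
  used_d <- logical(nd); used_t <- logical(nt); m <- 0L
  for (k in order(d2)) {
    if (d2[k] > radius^2) break
    i <- (k - 1L) %% nd + 1L; j <- (k - 1L) %/% nd + 1L
    if (!used_d[i] && !used_t[j]) { used_d[i] <- used_t[j] <- TRUE; m <- m + 1L }
  }
  list(matched = m, f1 = 2 * m / (nd + nt), precision = m / nd, recall = m / nt)
}

# enumeration oracle for the 2x2 test of independence: conditional null
# with fixed margins, chi-square statistic as the ordering criterion.
# midp = TRUE gives the continuity-matched (mid-p) version for comparison
# against the continuous asymptotic p.
exact_cond_chisq_p <- function(tab, midp = FALSE) {
  r1 <- sum(tab[1, ]); c1 <- sum(tab[, 1]); N <- sum(tab)
  a_range <- max(0, c1 - (N - r1)):min(r1, c1)
  stat <- function(a) {
    E <- outer(c(r1, N - r1), c(c1, N - c1)) / N
    O <- matrix(c(a, c1 - a, r1 - a, N - r1 - c1 + a), 2)
    sum((O - E)^2 / E)
  }
  stats <- vapply(a_range, stat, 0)
  pr <- stats::dhyper(a_range, r1, N - r1, c1)
  s_obs <- stat(tab[1, 1])
  if (midp)
    sum(pr[stats > s_obs + 1e-9]) + 0.5 * sum(pr[abs(stats - s_obs) <= 1e-9])
  else sum(pr[stats >= s_obs - 1e-9])
}

# independent binary disc rasterizer for constructed detection fixtures
# (deliberately simpler than the generator's anti-aliased renderer)
stamp_discs <- function(n, x_px, y_px, r_px, amp) {
  m <- matrix(0, n, n)
  rows <- matrix(seq_len(n) - 0.5, n, n)   # y at [r, c]
  cols <- t(rows)                          # x at [r, c]
  for (i in seq_along(x_px))
    m <- m + amp * ((rows - y_px[i])^2 + (cols - x_px[i])^2 <= r_px[i]^2)
  m
}

# published reference contingency tables for squamous bladder cancer
# (counts of cases; rows = low/high density or hot/cold/excluded phenotype,
# columns = the clinical/molecular variable) with the p-values reported
# alongside them, at the printed precision
reference_tables <- function() {
  list(
    chisq = list(
      cd8_density_x_subtype = list(tab = matrix(c(38, 27, 15, 26), 2, byrow = TRUE),
                                   p = 0.028, digits = 3),
      fgfr3_x_cd8 = list(tab = matrix(c(20, 5, 31, 1), 2, byrow = TRUE),
                         p = 0.039, digits = 3),
      fgfr3_x_cd79a = list(tab = matrix(c(24, 6, 31, 1), 2, byrow = TRUE),
                           p = 0.036, digits = 3),
      fgfr3_x_perforin = list(tab = matrix(c(13, 4, 32, 1), 2, byrow = TRUE),
                              p = 0.022, digits = 3),
      cps_x_cd3 = list(tab = matrix(c(46, 3, 37, 11), 2, byrow = TRUE),
                       p = 0.019, digits = 3),
      cps_x_cd8 = list(tab = matrix(c(43, 3, 35, 11), 2, byrow = TRUE),
                       p = 0.020, digits = 3),
      cps_x_cd163 = list(tab = matrix(c(47, 4, 35, 10), 2, byrow = TRUE),
                         p = 0.046, digits = 3),
      ki67_x_cd3cd8_topo = list(tab = matrix(c(7, 20, 18, 13, 19, 15), 3, byrow = TRUE),
                                p = 0.025, digits = 3),
      ki67_x_allimmune_topo = list(tab = matrix(c(8, 20, 16, 16, 19, 12), 3, byrow = TRUE),
                                   p = 0.039, digits = 3),
      perforin_x_cd3cd4_topo = list(tab = matrix(c(9, 17, 19, 9, 17, 18), 3, byrow = TRUE),
                                    p = 0.049, digits = 3),
      perforin_x_cd3cd8_topo = list(tab = matrix(c(7, 19, 21, 9, 17, 16), 3, byrow = TRUE),
                                    p = 0.006, digits = 3)),
    fisher = list(
      cps_x_cd3cd4_topo = list(tab = matrix(c(19, 9, 25, 2, 35, 3), 3, byrow = TRUE),
                               p = 0.022, digits = 3),
      cps_x_cd3cd8_topo = list(tab = matrix(c(20, 9, 26, 3, 32, 2), 3, byrow = TRUE),
                               p = 0.021, digits = 3),
      cps_x_cd79a_topo = list(tab = matrix(c(4, 3, 8, 1, 71, 10), 3, byrow = TRUE),
                              p = 0.099, digits = 3),
      cps_x_macrophage_topo = list(tab = matrix(c(18, 10, 26, 4, 37, 0), 3, byrow = TRUE),
                                   p = 0.001, digits = NA),  # reported as < 0.001
      cps_x_allimmune_topo = list(tab = matrix(c(18, 10, 28, 3, 31, 1), 3, byrow = TRUE),
                                  p = 0.002, digits = 3))
  )
}
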