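#' Build a validated contingency table
#'
#' @param counts matrix of non-negative integer counts (r x c).
#' @param row_labels,col_labels optional dimension labels.
#' @return An integer matrix of class `contingency_table`.
#' @export
contingency_table <- function(counts, row_labels = NULL, col_labels = NULL) {
  counts <- as.matrix(counts)
  if (any(counts < 0) || any(counts != round(counts)))
    stop("counts must be non-negative integers", call. = FALSE)
  if (sum(counts) == 0) stop("grand total must be positive", call. = FALSE)
  storage.mode(counts) <- "integer"
  if (!is.null(row_labels)) rownames(counts) <- row_labels
  if (!is.null(col_labels)) colnames(counts) <- col_labels
  structure(counts, class = c("contingency_table", class(counts)))
}

check_margins <- function(tab) {
  if (any(rowSums(tab) == 0) || any(colSums(tab) == 0))
    stop("degenerate table: zero row or column margin", call. = FALSE)
  invisible(tab)
}

test_result <- function(method, statistic = NA_real_, df = NA_real_,
                        p_value, effect = NA_real_, n = NA_integer_,
                        note = NA_character_) {
  structure(list(method = method, statistic = unname(statistic),
                 df = unname(df), p_value = unname(p_value),
                 effect = unname(effect), n = n, note = note),
            class = "test_result")
}

#' @export
print.test_result <- function(x, ...) {
  cat(x$method, ": statistic = ", signif(x$statistic, 4),
      if (is.finite(x$df)) paste0(", df = ", x$df),
      ", p = ", signif(x$p_value, 4), "\n", sep = "")
  invisible(x)
}

#' Pearson chi-square test of independence
#'
#' Classic chi-square on an r x c table with expected counts
#' `row x col / N` and **no continuity correction** (the convention that
#' reproduces p-values reported alongside such tables in the clinical
#' literature). Cells with expected count < 5 trigger a warning but the
#' test is still run.
#'
#' @param tab a [contingency_table()] (or plain count matrix), r, c >= 2.
#' @return A `test_result` with statistic, df = (r-1)(c-1), p-value, and
#'   for 2x2 tables the sample odds ratio.
#' @export
pearson_chi_square <- function(tab) {
  tab <- contingency_table(tab)
  if (nrow(tab) < 2L || ncol(tab) < 2L)
    stop("table must be at least 2 x 2", call. = FALSE)
  check_margins(tab)
  expected <- outer(rowSums(tab), colSums(tab)) / sum(tab)
  if (any(expected < 5))
    warning("expected count < 5 in ", sum(expected < 5),
            " cell(s); chi-square approximation may be inaccurate",
            call. = FALSE)
  res <- suppressWarnings(stats::chisq.test(tab, correct = FALSE))
  or <- if (all(dim(tab) == 2L)) {
    t2 <- if (any(tab == 0)) tab + 0.5 else tab  # Haldane-Anscombe
    (t2[1, 1] * t2[2, 2]) / (t2[1, 2] * t2[2, 1])
  } else NA_real_
  test_result("pearson_chi_square", res$statistic, res$parameter,
              res$p.value, effect = or, n = sum(tab))
}

#' Fisher's exact test (2 x 2 and Freeman-Halton r x c)
#'
#' Two-sided exact test: for 2 x 2 tables the hypergeometric convention
#' (sum of table probabilities no larger than the observed one); for
#' larger tables the Freeman-Halton extension enumerating all tables with
#' the observed margins. Tables with a grand total above `max_total` are
#' rejected (use [pearson_chi_square()] instead).
#'
#' @param tab a [contingency_table()].
#' @param max_total enumeration guard on the grand total.
#' @return A `test_result`; for 2 x 2 tables `effect` carries the
#'   conditional MLE odds ratio.
#' @export
fisher_exact <- function(tab, max_total = 1000) {
  tab <- contingency_table(tab)
  check_margins(tab)
  if (sum(tab) > max_total)
    stop("table total ", sum(tab), " exceeds the enumeration guard (",
         max_total, "); use pearson_chi_square()", call. = FALSE)
  res <- stats::fisher.test(tab)
  or <- if (all(dim(tab) == 2L)) unname(res$estimate) else NA_real_
  test_result("fisher_exact", p_value = res$p.value, effect = or,
              n = sum(tab))
}

#' Spearman rank correlation with midranks
#'
#' rho is the Pearson correlation of midranks (average ranks for ties);
#' the p-value uses the t approximation with n - 2 degrees of freedom.
#'
#' @param x,y paired numeric vectors, n >= 3.
#' @return List with `rho`, `p_value`, `n` (class `correlation_result`).
#' @export
spearman <- function(x, y) {
  ok <- is.finite(x) & is.finite(y)
  x <- x[ok]; y <- y[ok]
  n <- length(x)
  if (n < 3L) stop("need at least 3 complete pairs", call. = FALSE)
  if (stats::sd(x) == 0 || stats::sd(y) == 0)
    stop("undefined correlation: constant input", call. = FALSE)
  rx <- rank(x); ry <- rank(y)
  rho <- stats::cor(rx, ry)
  p <- if (abs(rho) >= 1) 0 else {
    tstat <- rho * sqrt((n - 2) / (1 - rho^2))
    2 * stats::pt(-abs(tstat), df = n - 2)
  }
  structure(list(rho = rho, p_value = p, n = n), class = "correlation_result")
}

#' Mann-Whitney U test
#'
#' Exact enumeration for small tie-free samples (fewer than 50 values in
#' total); otherwise the normal approximation with tie-corrected variance
#' and no continuity correction.
#'
#' @param x,y numeric samples from the two groups.
#' @return A `test_result` with the U statistic for the first group.
#' @export
mann_whitney <- function(x, y) {
  if (!length(x) || !length(y)) stop("both groups must be non-empty", call. = FALSE)
  r <- rank(c(x, y))
  u <- sum(r[seq_along(x)]) - length(x) * (length(x) + 1) / 2
  res <- suppressWarnings(stats::wilcox.test(x, y, correct = FALSE))
  p <- res$p.value
  if (is.nan(p)) p <- 1  # zero-variance case: U exactly at its mean
  test_result("mann_whitney", statistic = u, p_value = p,
              n = length(x) + length(y))
}

#' Kruskal-Wallis rank ANOVA
#'
#' @param groups list of numeric vectors (>= 2 non-empty groups).
#' @return A `test_result` with the tie-corrected H statistic.
#' @export
kruskal_wallis <- function(groups) {
  if (length(groups) < 2L || any(!lengths(groups)))
    stop("need at least two non-empty groups", call. = FALSE)
  x <- unlist(groups, use.names = FALSE)
  g <- factor(rep(seq_along(groups), lengths(groups)))
  res <- suppressWarnings(stats::kruskal.test(x, g))
  p <- if (is.nan(res$p.value)) 1 else res$p.value
  h <- if (is.nan(res$statistic)) 0 else unname(res$statistic)
  test_result("kruskal_wallis", statistic = h, df = res$parameter,
              p_value = p, n = length(x))
}

#' Dunn's post hoc test on pooled midranks
#'
#' Pairwise z statistics on mean pooled midranks with the tie-corrected
#' variance; two-sided p-values adjusted by Holm (default) or reported
#' unadjusted.
#'
#' @param groups named list of numeric vectors.
#' @param adjustment `"holm"` or `"none"`.
#' @return Data frame: group1, group2, z, p_value, p_adjusted.
#' @export
dunn_posthoc <- function(groups, adjustment = c("holm", "none")) {
  adjustment <- match.arg(adjustment)
  if (length(groups) < 2L || any(!lengths(groups)))
    stop("need at least two non-empty groups", call. = FALSE)
  if (is.null(names(groups))) names(groups) <- seq_along(groups)
  x <- unlist(groups, use.names = FALSE)
  n <- length(x)
  r <- rank(x)
  ni <- lengths(groups)
  mean_r <- tapply(r, rep(names(groups), ni), mean)[names(groups)]
  ties <- table(x)
  tie_corr <- sum(ties^3 - ties) / (12 * (n - 1))
  pairs <- utils::combn(names(groups), 2)
  out <- apply(pairs, 2, function(p) {
    se <- sqrt((n * (n + 1) / 12 - tie_corr) *
                 (1 / ni[[p[1]]] + 1 / ni[[p[2]]]))
    z <- (mean_r[[p[1]]] - mean_r[[p[2]]]) / se
    data.frame(group1 = p[1], group2 = p[2], z = z,
               p_value = 2 * stats::pnorm(-abs(z)))
  })
  out <- do.call(rbind, out)
  out$p_adjusted <- stats::p.adjust(out$p_value, method = adjustment)
  rownames(out) <- NULL
  out
}

#' Kaplan-Meier estimate, log-rank test and restricted mean survival
#'
#' `km_estimate` returns the product-limit curve as a step function plus
#' the restricted mean survival time (area under the curve up to `tau`,
#' by default the largest observed time) with its standard error - the
#' "mean survival" reported by standard statistics suites.
#'
#' @param time follow-up times in months (>= 0).
#' @param event logical/0-1 event indicator (FALSE = censored).
#' @param tau truncation time for the restricted mean.
#' @return `km_estimate`: list with `curve` (data frame time, n_risk,
#'   n_event, survival), `rmean`, `rmean_se`, `tau`.
#' @export
km_estimate <- function(time, event, tau = NULL) {
  if (any(time < 0)) stop("negative survival time", call. = FALSE)
  fit <- survival::survfit(survival::Surv(time, event) ~ 1)
  if (is.null(tau)) tau <- max(time)
  tab <- summary(fit, rmean = tau)$table
  curve <- data.frame(time = fit$time, n_risk = fit$n.risk,
                      n_event = fit$n.event, survival = fit$surv)
  structure(list(curve = curve, rmean = unname(tab[["rmean"]]),
                 rmean_se = unname(tab[["se(rmean)"]]), tau = tau,
                 n = length(time), fit = fit),
            class = "km_estimate")
}

#' @rdname km_estimate
#' @param group group labels (two or more groups).
#' @return `logrank`: a `test_result` with the chi-square statistic,
#'   df = groups - 1, and for two groups the observed/expected hazard
#'   ratio of the *last* group level relative to the first as `effect`.
#' @export
logrank <- function(time, event, group) {
  group <- as.factor(group)
  if (nlevels(droplevels(group)) < 2L)
    stop("log-rank needs at least two groups", call. = FALSE)
  if (!any(event)) stop("log-rank undefined: no events observed", call. = FALSE)
  sd <- survival::survdiff(survival::Surv(time, event) ~ group)
  df <- length(sd$n) - 1
  p <- stats::pchisq(sd$chisq, df, lower.tail = FALSE)
  hr <- if (df == 1) (sd$obs[2] / sd$exp[2]) / (sd$obs[1] / sd$exp[1]) else NA_real_
  test_result("logrank", statistic = unname(sd$chisq), df = df, p_value = p,
              effect = hr, n = sum(sd$n))
}

#' @rdname km_estimate
#' @param km a `km_estimate`.
#' @export
restricted_mean <- function(km, tau = km$tau) {
  tab <- summary(km$fit, rmean = tau)$table
  c(mean = unname(tab[["rmean"]]), se = unname(tab[["se(rmean)"]]))
}
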