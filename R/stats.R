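#' Bundle grouped measurements for testing
#'
#' @param groups Named list of numeric vectors (one per group); at least
#'   two groups with at least three values each are needed for testing.
#' @param measure,units Labels carried into reports.
#' @return A `grouped_measurements` object.
#' @export
grouped_measurements <- function(groups, measure = NA_character_, units = NA_character_) {
  stopifnot(is.list(groups), length(groups) >= 1L)
  if (is.null(names(groups)) || anyDuplicated(names(groups))) {
    stop("groups must have unique names", call. = FALSE)
  }
  groups <- lapply(groups, as.numeric)
  structure(list(groups = groups, measure = measure, units = units),
            class = "grouped_measurements")
}

#' Descriptive summary: center plus SEM
#'
#' Reports either mean or median as the center; the spread is the standard
#' error of the mean (sample SD over the square root of n) in both
#' branches, matching the convention of pairing SEM with whichever center
#' the normality gate selected. A single value gets SEM 0 by convention.
#'
#' @param values Numeric vector (n >= 1).
#' @param center "mean" or "median".
#' @return List with `center`, `center_type`, `sem`, `n`.
#' @export
describe <- function(values, center = c("mean", "median")) {
  center <- match.arg(center)
  values <- as.numeric(values)
  n <- length(values)
  if (n == 0L) stop("cannot describe an empty sample", call. = FALSE)
  c_val <- if (center == "mean") mean(values) else stats::median(values)
  sem <- if (n == 1L) 0 else stats::sd(values) / sqrt(n)
  list(center = c_val, center_type = center, sem = sem, n = n)
}

# Holm-Sidak step-down adjustment: p-values ordered ascending get
# 1 - (1 - p)^(m - i + 1), then a running maximum enforces monotonicity.
holm_sidak_adjust <- function(p) {
  m <- length(p)
  ord <- order(p)
  adj <- numeric(m)
  running <- 0
  for (i in seq_len(m)) {
    a <- 1 - (1 - p[ord[i]])^(m - i + 1)
    running <- max(running, a)
    adj[ord[i]] <- min(running, 1)
  }
  adj
}

# Dunn's rank-based pairwise z test after Kruskal-Wallis, with tie
# correction; two-sided p-values, optionally multiplicity-adjusted.
dunn_test <- function(groups, adjust = c("holm-sidak", "none")) {
  adjust <- match.arg(adjust)
  labels <- names(groups)
  values <- unlist(groups, use.names = FALSE)
  g <- rep(labels, lengths(groups))
  n_total <- length(values)
  r <- rank(values)
  rbar <- tapply(r, g, mean)
  n <- tapply(r, g, length)
  ties <- table(values)
  tie_term <- sum(ties^3 - ties) / (12 * (n_total - 1))
  combs <- utils::combn(labels, 2L)
  res <- apply(combs, 2L, function(pr) {
    i <- pr[1L]; j <- pr[2L]
    se <- sqrt((n_total * (n_total + 1) / 12 - tie_term) * (1 / n[[i]] + 1 / n[[j]]))
    z <- (rbar[[i]] - rbar[[j]]) / se
    c(z = z, p = 2 * stats::pnorm(-abs(z)))
  })
  p_raw <- res["p", ]
  p_adj <- if (adjust == "holm-sidak") holm_sidak_adjust(p_raw) else p_raw
  tibble::tibble(group1 = combs[1L, ], group2 = combs[2L, ],
                 z = res["z", ], p_raw = p_raw, p_adj = p_adj)
}

# Pairwise t tests with the ANOVA's pooled SD, Holm-Sidak adjusted.
holm_sidak_posthoc <- function(groups) {
  labels <- names(groups)
  n <- lengths(groups)
  means <- vapply(groups, mean, numeric(1L))
  vars <- vapply(groups, stats::var, numeric(1L))
  df_w <- sum(n) - length(groups)
  pooled <- sum((n - 1) * vars) / df_w
  combs <- utils::combn(labels, 2L)
  res <- apply(combs, 2L, function(pr) {
    i <- pr[1L]; j <- pr[2L]
    se <- sqrt(pooled * (1 / n[[i]] + 1 / n[[j]]))
    t <- (means[[i]] - means[[j]]) / se
    c(t = t, p = 2 * stats::pt(-abs(t), df_w))
  })
  p_raw <- res["p", ]
  tibble::tibble(group1 = combs[1L, ], group2 = combs[2L, ],
                 statistic = res["t", ], p_raw = p_raw,
                 p_adj = holm_sidak_adjust(p_raw))
}

#' Normality-gated statistical comparison
#'
#' Implements the test-selection rule used throughout the analyses: every
#' group is screened with the Shapiro-Wilk test at `alpha_normality`. If
#' all groups pass, the parametric branch runs (unpaired t test for two
#' groups, one-way ANOVA with Holm-Sidak post-hoc pairwise comparisons for
#' more) and centers are reported as means. Otherwise the non-parametric
#' branch runs (Mann-Whitney U for two groups, Kruskal-Wallis with Dunn's
#' post-hoc for more) and centers are reported as medians. SEM accompanies
#' either center.
#'
#' A group with zero variance cannot be screened by Shapiro-Wilk and is
#' treated as failing the gate (non-parametric branch).
#'
#' @param g A [grouped_measurements()] with >= 2 groups of >= 3 values.
#' @param alpha_normality Per-group Shapiro-Wilk threshold (default 0.05).
#' @return A `test_report`: list with `test_name`, `p_value`, `normal`
#'   (gate outcome), `shapiro_p`, `descriptives` tibble, `posthoc` tibble
#'   (present iff > 2 groups) and `stars`.
#' @export
dispatch_test <- function(g, alpha_normality = 0.05) {
  stopifnot(inherits(g, "grouped_measurements"))
  groups <- g$groups
  if (length(groups) < 2L) stop("need at least two groups", call. = FALSE)
  small <- names(groups)[lengths(groups) < 3L]
  if (length(small) > 0L) {
    stop("group(s) with fewer than 3 values: ", paste(small, collapse = ", "),
         call. = FALSE)
  }
  shapiro_p <- vapply(groups, function(v) {
    if (stats::sd(v) == 0) return(0)  # degenerate: cannot be normal-screened
    stats::shapiro.test(v)$p.value
  }, numeric(1L))
  normal <- all(shapiro_p >= alpha_normality)
  k <- length(groups)
  posthoc <- NULL
  if (normal) {
    center <- "mean"
    if (k == 2L) {
      ht <- stats::t.test(groups[[1L]], groups[[2L]], var.equal = TRUE)
      test_name <- "unpaired t-test"
      p <- ht$p.value
    } else {
      values <- unlist(groups, use.names = FALSE)
      fac <- factor(rep(names(groups), lengths(groups)))
      fit <- stats::aov(values ~ fac)
      p <- summary(fit)[[1L]][["Pr(>F)"]][1L]
      posthoc <- holm_sidak_posthoc(groups)
      test_name <- "one-way ANOVA + Holm-Sidak"
    }
  } else {
    center <- "median"
    if (k == 2L) {
      ht <- suppressWarnings(stats::wilcox.test(groups[[1L]], groups[[2L]],
                                                exact = FALSE, correct = TRUE))
      test_name <- "Mann-Whitney U"
      p <- ht$p.value
    } else {
      values <- unlist(groups, use.names = FALSE)
      fac <- factor(rep(names(groups), lengths(groups)))
      p <- stats::kruskal.test(values, fac)$p.value
      posthoc <- dunn_test(groups)
      test_name <- "Kruskal-Wallis + Dunn"
    }
  }
  desc <- do.call(rbind, lapply(names(groups), function(nm) {
    d <- describe(groups[[nm]], center)
    tibble::tibble(group = nm, n = d$n, center = d$center,
                   center_type = d$center_type, sem = d$sem)
  }))
  structure(
    list(test_name = test_name, p_value = p, normal = normal,
         shapiro_p = shapiro_p, descriptives = desc, posthoc = posthoc,
         stars = significance_stars(p)),
    class = "test_report"
  )
}

#' Significance stars
#'
#' Conventional coding: `***` for p <= 0.001, `**` for p <= 0.01, `*` for
#' p <= 0.05, `n.s.` above.
#'
#' @param p P-value(s).
#' @return Character vector.
#' @export
significance_stars <- function(p) {
  vapply(p, function(pp) {
    if (!is.finite(pp)) return(NA_character_)
    if (pp <= 0.001) "***" else if (pp <= 0.01) "**" else if (pp <= 0.05) "*" else "n.s."
  }, "")
}

#' @export
print.test_report <- function(x, ...) {
  cat("<test_report>", x$test_name,
      sprintf("p = %.4g %s\n", x$p_value, x$stars))
  for (i in seq_len(nrow(x$descriptives))) {
    d <- x$descriptives[i, ]
    cat(sprintf("  %s: %s %.4g +/- %.4g (n = %d)\n",
                d$group, d$center_type, d$center, d$sem, d$n))
  }
  if (!is.null(x$posthoc)) {
    cat("  post-hoc pairs:", nrow(x$posthoc), "\n")
  }
  invisible(x)
}

#' Bootstrap confidence interval for a median
#'
#' The main reports pair medians with SEM for consistency with the
#' dispatch convention; this clearly-labeled extra provides a percentile
#' bootstrap CI for users who want a distribution-appropriate interval.
#'
#' @param values Numeric vector.
#' @param conf Confidence level (default 0.95).
#' @param n_boot Bootstrap replicates (default 2000).
#' @return Numeric `c(lower, upper)`.
#' @export
median_boot_ci <- function(values, conf = 0.95, n_boot = 2000L) {
  stopifnot(length(values) >= 2L)
  meds <- vapply(seq_len(n_boot), function(i) {
    stats::median(sample(values, replace = TRUE))
  }, numeric(1L))
  a <- (1 - conf) / 2
  stats::quantile(meds, c(a, 1 - a), names = FALSE)
}
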