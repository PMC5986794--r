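# The statistical comparison machinery: cohort assignment, the
# variance-guided decision tree (Levene -> ANOVA/Welch -> Tukey+Bonferroni /
# Games-Howell), and paired t tests for learning effects.

#' Assign subjects to strategy groups and retest subgroups
#'
#' 24 subjects are randomly split into three main groups of 8 (RAW, FLT,
#' AUG). Within each group, subgroups of 4 are earmarked for retests probing
#' learning effects around the audio-augmented strategy: 4 of the RAW group
#' retest AUG, 4 of the FLT group retest AUG, and the AUG group splits into
#' 4 retesting RAW and 4 retesting FLT.
#'
#' @param seed Integer seed for the random assignment.
#' @param n_subjects Cohort size (default 24; must be divisible by 3, with
#'   groups divisible by 2).
#' @return A data frame with columns `subject`, `strategy`, `retest`
#'   (strategy retested, or `NA`), `subgroup` (label such as `"RAW->AUG"`,
#'   or `NA`).
#' @export
assign_cohort <- function(seed = 1L, n_subjects = 24L) {
  n_subjects <- as.integer(n_subjects)
  if (n_subjects %% 6L != 0L) {
    stop("`n_subjects` must be divisible by 6", call. = FALSE)
  }
  per_group <- n_subjects %/% 3L
  half <- per_group %/% 2L
  ids <- with_seed(seed, sample.int(n_subjects))
  strategy <- rep(c("RAW", "FLT", "AUG"), each = per_group)
  retest <- rep(NA_character_, n_subjects)
  # indices within the shuffled order
  raw_idx <- 1:per_group
  flt_idx <- (per_group + 1):(2 * per_group)
  aug_idx <- (2 * per_group + 1):(3 * per_group)
  retest[raw_idx[seq_len(half)]] <- "AUG"
  retest[flt_idx[seq_len(half)]] <- "AUG"
  retest[aug_idx[seq_len(half)]] <- "RAW"
  retest[aug_idx[half + seq_len(half)]] <- "FLT"
  out <- data.frame(subject = ids, strategy = strategy, retest = retest)
  out$subgroup <- ifelse(is.na(out$retest), NA_character_,
                         paste0(out$strategy, "->", out$retest))
  out[order(out$subject), ]
}

#' Games-Howell post hoc test
#'
#' Pairwise comparisons for unequal variances and sample sizes: the test
#' statistic uses per-group variances, the degrees of freedom follow
#' Welch-Satterthwaite, and p-values come from the studentized range
#' distribution with the number of groups as the number of means.
#'
#' @param values Numeric outcome vector.
#' @param groups Factor (or coercible) of group labels.
#' @return Data frame with `group1`, `group2`, `diff`, `t`, `df`, `p`.
#' @export
games_howell <- function(values, groups) {
  groups <- factor(groups)
  k <- nlevels(groups)
  means <- tapply(values, groups, mean)
  vars <- tapply(values, groups, stats::var)
  ns <- tapply(values, groups, length)
  pairs <- utils::combn(levels(groups), 2)
  res <- apply(pairs, 2, function(pr) {
    i <- pr[1]; j <- pr[2]
    se2 <- vars[[i]] / ns[[i]] + vars[[j]] / ns[[j]]
    if (!is.finite(se2) || se2 <= 0) {
      return(c(diff = means[[i]] - means[[j]], t = NA_real_,
               df = NA_real_, p = NA_real_))
    }
    tstat <- (means[[i]] - means[[j]]) / sqrt(se2)
    df <- se2^2 / ((vars[[i]] / ns[[i]])^2 / (ns[[i]] - 1) +
                     (vars[[j]] / ns[[j]])^2 / (ns[[j]] - 1))
    p <- suppressWarnings(
      stats::ptukey(abs(tstat) * sqrt(2), nmeans = k, df = df,
                    lower.tail = FALSE))
    if (!is.finite(p)) p <- NA_real_
    c(diff = means[[i]] - means[[j]], t = tstat, df = df, p = p)
  })
  data.frame(group1 = pairs[1, ], group2 = pairs[2, ],
             diff = res["diff", ], t = res["t", ], df = res["df", ],
             p = res["p", ], row.names = NULL)
}

#' Compare an outcome across strategy groups
#'
#' Follows the variance-guided decision tree: Levene's test (median-centered)
#' for homogeneity of variances at `alpha`; if homogeneous, a one-way ANOVA
#' followed (when significant) by both Tukey HSD and Bonferroni-adjusted
#' pairwise t tests, reporting both with the smaller adjusted p flagged as
#' the headline; if heterogeneous, a robust Welch ANOVA followed by the
#' Games-Howell test. Zero-variance groups are flagged as degenerate and
#' force the Welch branch.
#'
#' @param values Numeric outcome vector.
#' @param groups Group labels (>= 2 groups with >= 2 values each).
#' @param outcome Name of the outcome (for the report).
#' @param alpha Significance criterion (default 0.05).
#' @return An object of class `comparison_result`: a list with
#'   `outcome`, `group_stats` (mean, sd, sem, n per group), `homogeneity_p`,
#'   `variance_homogeneous`, `omnibus` (test name, F, df, p), `posthoc`
#'   (pairwise table or `NULL` when the omnibus is not significant),
#'   `posthoc_method`, `alpha`, `degenerate`.
#' @export
compare_strategies <- function(values, groups, outcome = "outcome",
                               alpha = 0.05) {
  keep <- is.finite(values)
  values <- values[keep]
  groups <- factor(groups[keep])
  groups <- droplevels(groups)
  ns <- tapply(values, groups, length)
  if (nlevels(groups) < 2L || any(ns < 2L)) {
    stop("need at least 2 groups with at least 2 values each", call. = FALSE)
  }
  vars <- tapply(values, groups, stats::var)
  # variance below numerical resolution (e.g. every trial at the efficiency
  # ceiling) counts as degenerate
  tolv <- 1e-9 * mean(values)^2 + 1e-12
  degenerate <- any(vars <= tolv)
  group_stats <- data.frame(
    group = levels(groups),
    n = as.integer(ns),
    mean = as.numeric(tapply(values, groups, mean)),
    sd = as.numeric(sqrt(vars))
  )
  group_stats$sem <- group_stats$sd / sqrt(group_stats$n)

  if (degenerate) {
    homogeneity_p <- 0
    homogeneous <- FALSE
  } else {
    lev <- suppressWarnings(car::leveneTest(values ~ groups,
                                            center = stats::median))
    homogeneity_p <- lev[["Pr(>F)"]][1]
    if (!is.finite(homogeneity_p)) {
      # homogeneity untestable (e.g. two observations per group make the
      # median-deviation fit exact); do not assume it
      homogeneity_p <- NA_real_
      homogeneous <- FALSE
    } else {
      homogeneous <- homogeneity_p >= alpha
    }
  }

  posthoc <- NULL
  posthoc_method <- NULL
  if (homogeneous) {
    fit <- stats::aov(values ~ groups)
    tab <- summary(fit)[[1]]
    omnibus <- list(test = "one-way ANOVA",
                    statistic = tab[["F value"]][1],
                    df1 = tab[["Df"]][1], df2 = tab[["Df"]][2],
                    p = tab[["Pr(>F)"]][1])
    if (is.finite(omnibus$p) && omnibus$p < alpha) {
      tuk <- stats::TukeyHSD(fit)$groups
      pairs_lbl <- rownames(tuk)
      bonf <- stats::pairwise.t.test(values, groups,
                                     p.adjust.method = "bonferroni",
                                     pool.sd = TRUE)$p.value
      split_lbl <- strsplit(pairs_lbl, "-", fixed = TRUE)
      p_bonf <- vapply(split_lbl, function(pr) {
        p <- bonf[pr[1], pr[2]]
        if (is.null(p) || is.na(p)) p <- bonf[pr[2], pr[1]]
        p
      }, numeric(1))
      posthoc <- data.frame(
        group1 = vapply(split_lbl, `[`, character(1), 1),
        group2 = vapply(split_lbl, `[`, character(1), 2),
        diff = tuk[, "diff"],
        p_tukey = tuk[, "p adj"],
        p_bonferroni = pmin(1, p_bonf),
        row.names = NULL
      )
      posthoc$p_headline <- pmin(posthoc$p_tukey, posthoc$p_bonferroni)
      posthoc$headline_test <- ifelse(posthoc$p_tukey <= posthoc$p_bonferroni,
                                      "tukey", "bonferroni")
      posthoc_method <- "Tukey HSD + Bonferroni (smaller adjusted p flagged)"
    }
  } else if (all(vars <= tolv)) {
    # every group is (numerically) constant: no variability to test
    omnibus <- list(test = "robust Welch ANOVA", statistic = NA_real_,
                    df1 = NA_real_, df2 = NA_real_, p = NA_real_)
  } else {
    wel <- tryCatch(
      suppressWarnings(stats::oneway.test(values ~ groups,
                                          var.equal = FALSE)),
      error = function(e) NULL)
    if (!is.null(wel) && !is.finite(wel$p.value)) wel <- NULL
    omnibus <- if (is.null(wel)) {
      list(test = "robust Welch ANOVA", statistic = NA_real_,
           df1 = NA_real_, df2 = NA_real_, p = NA_real_)
    } else {
      list(test = "robust Welch ANOVA",
           statistic = unname(wel$statistic),
           df1 = unname(wel$parameter[1]), df2 = unname(wel$parameter[2]),
           p = unname(wel$p.value))
    }
    if (is.finite(omnibus$p) && omnibus$p < alpha) {
      posthoc <- games_howell(values, groups)
      posthoc_method <- "Games-Howell"
    }
  }
  structure(
    list(outcome = outcome, group_stats = group_stats,
         homogeneity_p = homogeneity_p,
         variance_homogeneous = homogeneous,
         omnibus = omnibus, posthoc = posthoc,
         posthoc_method = posthoc_method, alpha = alpha,
         degenerate = degenerate),
    class = "comparison_result"
  )
}

#' @export
print.comparison_result <- function(x, ...) {
  cat(sprintf("<comparison_result: %s>\n", x$outcome))
  cat(sprintf("  Levene p = %.4g -> %s\n", x$homogeneity_p,
              if (x$variance_homogeneous) "homogeneous" else "heterogeneous"))
  cat(sprintf("  %s: F(%.3g, %.3g) = %.3g, p = %.4g\n", x$omnibus$test,
              x$omnibus$df1, x$omnibus$df2, x$omnibus$statistic, x$omnibus$p))
  if (!is.null(x$posthoc)) {
    cat(sprintf("  post hoc (%s):\n", x$posthoc_method))
    print(x$posthoc, digits = 3)
  } else {
    cat("  post hoc: not run (omnibus not significant)\n")
  }
  invisible(x)
}

#' Paired two-sample t test with degenerate-case handling
#'
#' Closed-form paired t: `t = mean(d) / (sd(d)/sqrt(n))` with `df = n - 1`
#' and a two-sided p. Identical pairs give `t = 0, p = 1`; a constant
#' non-zero shift has zero pair variance and is flagged as degenerate
#' (`t = +/-Inf, p = 0`).
#'
#' @param x,y Equal-length paired samples (n >= 2).
#' @return A list with `t`, `df`, `p`, `mean_diff`, `degenerate`.
#' @export
paired_t <- function(x, y) {
  if (length(x) != length(y) || length(x) < 2L) {
    stop("`x` and `y` must be equal-length with n >= 2", call. = FALSE)
  }
  d <- x - y
  n <- length(d)
  m <- mean(d)
  s <- stats::sd(d)
  if (s == 0) {
    if (m == 0) {
      return(list(t = 0, df = n - 1L, p = 1, mean_diff = 0,
                  degenerate = FALSE))
    }
    return(list(t = sign(m) * Inf, df = n - 1L, p = 0, mean_diff = m,
                degenerate = TRUE))
  }
  tstat <- m / (s / sqrt(n))
  list(t = tstat, df = n - 1L, p = 2 * stats::pt(-abs(tstat), n - 1),
       mean_diff = m, degenerate = FALSE)
}

#' Learning-effect paired t tests for the retest subgroups
#'
#' For each subgroup and each outcome column, compares first-exposure values
#' with retest values by a dependent paired t test. With the four subgroups
#' and the seven outcome columns (adaptation rate, JND, internal-model
#' uncertainty, and path efficiency and accuracy split by axis class) this
#' enumerates 28 tests.
#'
#' @param first Data frame of first-exposure outcomes; must contain
#'   `subject`, `subgroup` and the outcome columns.
#' @param retest Data frame of retest outcomes for the same subjects (matched
#'   by `subject`).
#' @param outcomes Character vector of outcome column names.
#' @return Data frame: `subgroup`, `outcome`, `n`, `mean_first`,
#'   `mean_retest`, `t`, `df`, `p`, `degenerate`.
#' @export
paired_learning_tests <- function(first, retest,
                                  outcomes = c("adaptation_rate", "jnd",
                                               "p_param",
                                               "path_efficiency_on",
                                               "path_efficiency_off",
                                               "accuracy_on",
                                               "accuracy_off")) {
  stopifnot(all(c("subject", "subgroup") %in% names(first)),
            "subject" %in% names(retest))
  rows <- list()
  for (sg in sort(unique(stats::na.omit(first$subgroup)))) {
    f <- first[!is.na(first$subgroup) & first$subgroup == sg, ]
    r <- retest[match(f$subject, retest$subject), ]
    for (oc in outcomes) {
      x <- f[[oc]]
      y <- r[[oc]]
      ok <- is.finite(x) & is.finite(y)
      if (sum(ok) < 2L) next
      tt <- paired_t(x[ok], y[ok])
      rows[[length(rows) + 1L]] <- data.frame(
        subgroup = sg, outcome = oc, n = sum(ok),
        mean_first = mean(x[ok]), mean_retest = mean(y[ok]),
        t = tt$t, df = tt$df, p = tt$p, degenerate = tt$degenerate
      )
    }
  }
  do.call(rbind, rows)
}
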