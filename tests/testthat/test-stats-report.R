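# Cohort assignment and the variance-guided statistical decision tree.

test_that("cohort structure is 3 groups of 8 with 4 subgroups of 4", {
  plan <- assign_cohort(seed = 4)
  expect_equal(nrow(plan), 24L)
  expect_equal(unname(table(plan$strategy)[c("RAW", "FLT", "AUG")]),
               rep(8L, 3), ignore_attr = TRUE)
  sub <- table(plan$subgroup)
  expect_setequal(names(sub), c("RAW->AUG", "FLT->AUG", "AUG->RAW",
                                "AUG->FLT"))
  expect_true(all(sub == 4L))
  # subgroups are subsets of their parent groups
  expect_true(all(plan$strategy[plan$subgroup == "AUG->FLT" &
                                  !is.na(plan$subgroup)] == "AUG"))
  expect_true(all(is.na(plan$retest) |
                    substr(plan$subgroup, 1, 3) == plan$strategy |
                    plan$strategy == "AUG"))
})

test_that("different seeds shuffle membership but not structure", {
  a <- assign_cohort(seed = 1)
  b <- assign_cohort(seed = 2)
  expect_false(identical(a$strategy, b$strategy))
  expect_equal(table(b$strategy), table(a$strategy))
  expect_identical(assign_cohort(seed = 1), a)
})

test_that("homogeneous shifted groups take the ANOVA + Tukey/Bonferroni branch", {
  set.seed(21)
  values <- c(rnorm(20, 0, 1), rnorm(20, 1.5, 1), rnorm(20, 3, 1))
  groups <- rep(c("A", "B", "C"), each = 20)
  res <- compare_strategies(values, groups, outcome = "shifted")
  expect_gte(res$homogeneity_p, 0.05)
  expect_true(res$variance_homogeneous)
  expect_equal(res$omnibus$test, "one-way ANOVA")
  expect_lt(res$omnibus$p, 0.05)
  expect_false(is.null(res$posthoc))
  expect_true(all(c("p_tukey", "p_bonferroni", "p_headline") %in%
                    names(res$posthoc)))
  expect_true(all(res$posthoc$p_headline ==
                    pmin(res$posthoc$p_tukey, res$posthoc$p_bonferroni)))
  # the extreme pair is clearly separated
  ac <- res$posthoc[res$posthoc$group1 == "C" & res$posthoc$group2 == "A", ]
  expect_lt(ac$p_headline, 0.001)
})

test_that("a 10x-variance group forces the Welch + Games-Howell branch", {
  set.seed(22)
  values <- c(rnorm(20, 0, 1), rnorm(20, 0.5, 10), rnorm(20, 3, 1))
  groups <- rep(c("A", "B", "C"), each = 20)
  res <- compare_strategies(values, groups, outcome = "heteroscedastic")
  expect_lt(res$homogeneity_p, 0.05)
  expect_false(res$variance_homogeneous)
  expect_equal(res$omnibus$test, "robust Welch ANOVA")
  if (res$omnibus$p < 0.05) {
    expect_false(is.null(res$posthoc))
    expect_equal(res$posthoc_method, "Games-Howell")
  }
})

test_that("null groups rarely trigger the posthoc and report SEM", {
  set.seed(23)
  ps <- replicate(40, {
    values <- rnorm(30)
    compare_strategies(values, rep(c("A", "B", "C"), 10))$omnibus$p
  })
  # roughly uniform omnibus p under the null
  expect_gt(mean(ps > 0.05), 0.8)
  res <- compare_strategies(rnorm(30), rep(c("A", "B", "C"), 10))
  expect_true(all(abs(res$group_stats$sem -
                        res$group_stats$sd / sqrt(res$group_stats$n)) <
                    1e-12))
  if (res$omnibus$p >= 0.05) expect_null(res$posthoc)
})

test_that("a zero-variance group is flagged degenerate and branches to Welch", {
  values <- c(rep(1, 5), rnorm(5, 2), rnorm(5, 3))
  res <- compare_strategies(values, rep(c("A", "B", "C"), each = 5))
  expect_true(res$degenerate)
  expect_false(res$variance_homogeneous)
  expect_equal(res$omnibus$test, "robust Welch ANOVA")
})

test_that("games_howell agrees with Welch t on two groups", {
  set.seed(24)
  x <- rnorm(15, 0, 1); y <- rnorm(15, 1, 3)
  gh <- games_howell(c(x, y), rep(c("A", "B"), each = 15))
  tt <- t.test(x, y, var.equal = FALSE)
  expect_equal(abs(gh$t), abs(unname(tt$statistic)), tolerance = 1e-10)
  expect_equal(gh$df, unname(tt$parameter), tolerance = 1e-10)
  # with 2 means the studentized range p equals the Welch two-sided p
  expect_equal(gh$p, tt$p.value, tolerance = 1e-6)
})

test_that("paired t matches the closed form on a 4-pair example", {
  x <- c(10.2, 11.5, 9.8, 12.1)
  y <- c(9.1, 10.9, 9.9, 10.8)
  d <- x - y
  t_manual <- mean(d) / (sd(d) / 2)
  p_manual <- 2 * pt(-abs(t_manual), 3)
  res <- paired_t(x, y)
  expect_equal(res$t, t_manual, tolerance = 1e-10)
  expect_equal(res$df, 3L)
  expect_equal(res$p, p_manual, tolerance = 1e-10)
  ref <- t.test(x, y, paired = TRUE)
  expect_equal(res$t, unname(ref$statistic), tolerance = 1e-10)
  expect_equal(res$p, ref$p.value, tolerance = 1e-10)
})

test_that("degenerate pairings are handled explicitly", {
  res <- paired_t(c(1, 2, 3, 4), c(1, 2, 3, 4))
  expect_equal(res$t, 0)
  expect_equal(res$p, 1)
  expect_false(res$degenerate)
  res <- paired_t(c(1, 2, 3, 4), c(2, 3, 4, 5))
  expect_true(res$degenerate)
  expect_true(is.infinite(res$t))
  expect_equal(res$p, 0)
  expect_error(paired_t(1, 1), "n >= 2")
})

test_that("learning tests enumerate subgroup x outcome combinations", {
  set.seed(25)
  first <- data.frame(subject = 1:8,
                      subgroup = rep(c("RAW->AUG", "FLT->AUG"), each = 4),
                      adaptation_rate = rnorm(8, 0.5, 0.1),
                      jnd = rnorm(8, 45, 5))
  retest <- data.frame(subject = 1:8,
                       adaptation_rate = rnorm(8, 0.7, 0.1),
                       jnd = rnorm(8, 40, 5))
  tab <- paired_learning_tests(first, retest,
                               outcomes = c("adaptation_rate", "jnd"))
  expect_equal(nrow(tab), 4L)   # 2 subgroups x 2 outcomes
  expect_true(all(tab$n == 4))
  expect_true(all(tab$df == 3))
  # verify one cell against the closed form
  f <- first[first$subgroup == "RAW->AUG", ]
  r <- retest[match(f$subject, retest$subject), ]
  ref <- paired_t(f$jnd, r$jnd)
  cell <- tab[tab$subgroup == "RAW->AUG" & tab$outcome == "jnd", ]
  expect_equal(cell$t, ref$t)
  expect_equal(cell$p, ref$p)
})
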