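test_that("Lilliefors KS accepts normal-shaped samples and rejects exponential", {
  # sample placed exactly on fitted normal quantiles: minimal distance
  x <- qnorm(ppoints(50))
  res <- ks_normality(x, n_mc = 2000, seed = 1)
  expect_gt(res$p_value, 0.5)

  y <- withr::with_seed(2, rexp(200))
  expect_lt(ks_normality(y, n_mc = 2000, seed = 1)$p_value, 0.05)

  expect_error(ks_normality(c(1, 2, 3)), "at least 4")
  expect_error(ks_normality(rep(5, 10)), "constant")
})

test_that("Lilliefors Monte-Carlo p agrees with the nortest approximation", {
  x <- withr::with_seed(3, rnorm(40, 5, 2))
  mine <- ks_normality(x, n_mc = 4000, seed = 1)
  ref <- nortest::lillie.test(x)
  expect_equal(mine$statistic, unname(ref$statistic), tolerance = 1e-12)
  expect_equal(mine$p_value, ref$p.value, tolerance = 0.08)
})

test_that("pooled t matches the hand-evaluated formula and is antisymmetric", {
  d <- tibble::tibble(y = c(1, 2, 3, 2, 3, 4), g = rep(c("x", "y"), each = 3))
  res <- t_test_two_sample(d, y, g)
  expect_equal(res$statistic, -1.224745, tolerance = 1e-6)
  expect_identical(res$df, 4)

  d2 <- d
  d2$g <- rep(c("y", "x"), each = 3) # swap labels
  res2 <- t_test_two_sample(d2, y, g)
  expect_equal(res2$statistic, -res$statistic)
  expect_equal(res2$p_value, res$p_value)
})

test_that("degenerate t inputs follow the contract", {
  same <- tibble::tibble(y = rep(c(2, 2, 2), 2), g = rep(c("a", "b"), each = 3))
  res <- t_test_two_sample(same, y, g)
  expect_equal(res$statistic, 0)
  expect_equal(res$p_value, 1)

  apart <- tibble::tibble(y = rep(c(1, 2), each = 3), g = rep(c("a", "b"), each = 3))
  expect_error(t_test_two_sample(apart, y, g), "undefined")

  ident <- tibble::tibble(y = c(1, 2, 3, 1, 2, 3), g = rep(c("a", "b"), each = 3))
  expect_equal(t_test_two_sample(ident, y, g)$statistic, 0)
})

test_that("one-way ANOVA reproduces hand-computed sums of squares", {
  d <- tibble::tibble(y = c(1, 2, 3, 2, 3, 4, 3, 4, 5),
                      g = rep(c("a", "b", "c"), each = 3))
  gl <- glance(one_way_anova(d, y, g))
  # SS_between = 3 * ((2-3)^2 + 0 + (4-3)^2) = 6, MS_b = 3
  # SS_within = 3 * 2 = 6, MS_w = 1 -> F = 3 on (2, 6) df
  expect_equal(gl$statistic, 3)
  expect_identical(c(gl$df_between, gl$df_within), c(2L, 6L))
  expect_equal(gl$ms_between, 3)
  expect_equal(gl$ms_within, 1)

  # translation invariance
  d$y <- d$y + 100
  expect_equal(glance(one_way_anova(d, y, g))$statistic, 3)

  flatd <- tibble::tibble(y = rep(c(1, 2, 3), 3), g = rep(c("a", "b", "c"), each = 3))
  expect_equal(glance(one_way_anova(flatd, y, g))$statistic, 0)
  expect_equal(glance(one_way_anova(flatd, y, g))$p_value, 1)

  expect_error(one_way_anova(tibble::tibble(y = c(1, 2, 3), g = c("a", "a", "b")),
                             y, g), "at least 2")
})

test_that("F = t^2 for two groups", {
  d <- withr::with_seed(8, tibble::tibble(y = c(rnorm(6), rnorm(6) + 1),
                                          g = rep(c("a", "b"), each = 6)))
  f <- glance(one_way_anova(d, y, g))$statistic
  t <- t_test_two_sample(d, y, g)$statistic
  expect_equal(f, t^2, tolerance = 1e-9)
})

test_that("two-way ANOVA matches a brute-force cell-means decomposition", {
  # balanced 2x2 with 3 replicates, effects constructed explicitly
  cells <- expand.grid(A = c("a1", "a2"), B = c("b1", "b2"),
                       rep = 1:3, stringsAsFactors = FALSE)
  mu <- 10
  a_eff <- c(a1 = -2, a2 = 2)
  b_eff <- c(b1 = -1, b2 = 1)
  ab_eff <- function(a, b) ifelse(a == "a2" & b == "b2", 1.5,
                                  ifelse(a == "a1" & b == "b1", 1.5, -1.5))
  noise <- c(-1, 0, 1)[cells$rep] * 0.5
  cells$y <- mu + a_eff[cells$A] + b_eff[cells$B] +
    ab_eff(cells$A, cells$B) + noise

  res <- tidy(two_way_anova(cells, y, A, B))
  # direct projection onto the effect subspaces: each A level spans 6 cells
  expect_equal(res$sumsq[res$term == "A"], 6 * sum(a_eff^2))
  expect_equal(res$sumsq[res$term == "B"], 6 * sum(b_eff^2))
  expect_equal(res$sumsq[res$term == "A:B"], 3 * 4 * 1.5^2)
  expect_equal(res$sumsq[res$term == "residuals"], 4 * sum((c(-1, 0, 1) * 0.5)^2))
})

test_that("null effects and unbalanced designs are handled", {
  cells <- expand.grid(A = c("a1", "a2"), B = c("b1", "b2"),
                       rep = 1:3, stringsAsFactors = FALSE)
  cells$y <- ifelse(cells$A == "a1", 1, 3) + c(-0.1, 0, 0.1)[cells$rep]
  res <- tidy(two_way_anova(cells, y, A, B))
  expect_equal(res$statistic[res$term == "B"], 0, tolerance = 1e-9)
  expect_equal(res$statistic[res$term == "A:B"], 0, tolerance = 1e-9)
  expect_gt(res$statistic[res$term == "A"], 100)

  unb <- cells[-1, ]
  expect_error(two_way_anova(unb, y, A, B), "unbalanced")
})

test_that("Tukey HSD agrees with stats::TukeyHSD and orders p sensibly", {
  d <- letter_chain_data(c(a = 0, b = 1.5, c = 6))
  tk <- tukey_hsd(d, y, g)
  fit <- aov(y ~ factor(g), data = d)
  ref <- TukeyHSD(fit)$`factor(g)`
  expect_equal(tk$p_adj, unname(ref[, "p adj"]), tolerance = 1e-9)
  expect_equal(tk$diff, unname(ref[, "diff"]), tolerance = 1e-12)

  # identical groups: no significance
  same <- tibble::tibble(y = rep(c(1, 2, 3), 3), g = rep(c("a", "b", "c"), each = 3))
  expect_false(any(tukey_hsd(same, y, g)$significant))

  # adjusted p never below the unadjusted pairwise p on the same error term
  df_w <- attr(tk, "df_within")
  for (i in seq_len(nrow(tk))) {
    p_raw <- 2 * pt(-tk$q[i] / sqrt(2), df_w) # q = |t| * sqrt(2)
    expect_gte(tk$p_adj[i] + 1e-12, p_raw)
  }
})

test_that("compact letters cover the non-significance graph", {
  # far-separated pair significant, chain A~B, B~C, A!=C
  chain <- letter_chain_data(c(a = 0, b = 1.5, c = 3))
  tk <- tukey_hsd(chain, y, g)
  expect_identical(tk$significant, c(FALSE, TRUE, FALSE)) # ab ns, ac sig, bc ns
  lt <- assign_letters(tk)
  expect_identical(lt$letters, c("a", "ab", "b"))

  far <- letter_chain_data(c(a = 0, b = 20, c = 40))
  lt2 <- assign_letters(tukey_hsd(far, y, g))
  expect_identical(lt2$letters, c("a", "b", "c"))

  same <- tibble::tibble(y = rep(c(1, 2, 3), 3), g = rep(c("a", "b", "c"), each = 3))
  lt3 <- assign_letters(tukey_hsd(same, y, g))
  expect_identical(lt3$letters, c("a", "a", "a"))
})

test_that("group summaries report mean, sample SD and letters", {
  d <- tibble::tibble(y = c(1, 2, 3, 5, 5, 5), g = rep(c("a", "b"), each = 3))
  s <- summarize_groups(d, y, g)
  expect_equal(s$mean, c(2, 5))
  expect_equal(s$sd, c(1, 0))
  expect_identical(s$n, c(3L, 3L))
  expect_true(all(c("group", "letters") %in% names(s)))

  d10 <- d
  d10$y <- 10 * d$y
  s10 <- summarize_groups(d10, y, g)
  expect_equal(s10$mean, 10 * s$mean)
  expect_equal(s10$sd, 10 * s$sd)
})

test_that("statistics are invariant to within-group value order", {
  d <- withr::with_seed(10, tibble::tibble(y = rnorm(12), g = rep(c("a", "b", "c"), 4)))
  shuffled <- withr::with_seed(11, d[sample(nrow(d)), ])
  expect_equal(glance(one_way_anova(d, y, g)), glance(one_way_anova(shuffled, y, g)))
  expect_equal(tibble::as_tibble(tukey_hsd(d, y, g)),
               tibble::as_tibble(tukey_hsd(shuffled, y, g)))
})
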