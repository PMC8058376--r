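# The study's statistical battery: Kolmogorov-Smirnov normality with
# Lilliefors Monte-Carlo calibration, Student's pooled-variance t, one- and
# two-way fixed-effects ANOVA with Tukey HSD multiple comparisons, compact
# letter display, and mean +/- SD group summaries. Model fitting is
# delegated to base R (aov, TukeyHSD, t.test); the Lilliefors calibration is
# implemented here because plain KS p-values are conservative when the
# normal parameters are estimated from the sample.

lilliefors_statistic <- function(x) {
  n <- length(x)
  z <- sort((x - mean(x)) / stats::sd(x))
  F <- stats::pnorm(z)
  i <- seq_len(n)
  max(max(i / n - F), max(F - (i - 1) / n))
}

#' Kolmogorov-Smirnov normality check with Lilliefors calibration
#'
#' One-sample KS statistic against a normal distribution with mean and SD
#' estimated from the sample. Because the parameters are estimated, the
#' p-value comes from a Monte-Carlo null distribution (Lilliefors
#' calibration): the statistic is recomputed on `n_mc` standard-normal
#' samples of the same size, each standardized by its own estimates.
#'
#' @param x Numeric sample, `n >= 4`, non-constant.
#' @param n_mc Monte-Carlo replicates (default 10000).
#' @param seed Seed for the Monte-Carlo null (fixed for reproducibility).
#' @return A one-row tibble with `statistic`, `p_value`, `n`, `n_mc`.
#' @examples
#' ks_normality(rnorm(50), n_mc = 500)
#' @export
ks_normality <- function(x, n_mc = 10000, seed = 1) {
  x <- as.numeric(x)
  if (length(x) < 4) stop("need at least 4 observations", call. = FALSE)
  if (stats::sd(x) == 0) stop("constant sample: SD is zero", call. = FALSE)
  D <- lilliefors_statistic(x)
  n <- length(x)
  null_D <- withr::with_seed(as.integer(seed), {
    vapply(seq_len(n_mc), function(i) lilliefors_statistic(stats::rnorm(n)),
           numeric(1))
  })
  p <- (1 + sum(null_D >= D)) / (n_mc + 1)
  tibble::tibble(statistic = D, p_value = p, n = n, n_mc = n_mc)
}

# pull a numeric value column and a factor group column out of a data frame
grouped_values <- function(data, value, group, min_n = 2, min_groups = 2) {
  v <- rlang::eval_tidy(rlang::enquo(value), data)
  g <- factor(rlang::eval_tidy(rlang::enquo(group), data))
  stopifnot(is.numeric(v), length(v) == length(g))
  n <- table(g)
  if (length(n) < min_groups) {
    stop("need at least ", min_groups, " groups", call. = FALSE)
  }
  if (any(n < min_n)) {
    stop("every group needs at least ", min_n, " observations", call. = FALSE)
  }
  data.frame(value = v, group = g)
}

#' Two-sample Student's t-test (pooled variance)
#'
#' @param data Data frame with one value column and one two-level group
#'   column.
#' @param value,group Bare column names.
#' @return A one-row tibble: `statistic` (t), `df`, `p_value`, `mean_1`,
#'   `mean_2`, and the group labels. The sign convention is
#'   `mean(group 1) - mean(group 2)` in the groups' factor-level order.
#' @details With zero pooled variance and equal means the statistic is 0 and
#'   the p-value 1; zero pooled variance with unequal means is an error.
#' @examples
#' d <- tibble::tibble(y = c(1, 2, 3, 2, 3, 4), g = rep(c("a", "b"), each = 3))
#' t_test_two_sample(d, y, g)
#' @export
t_test_two_sample <- function(data, value, group) {
  d <- grouped_values(data, {{ value }}, {{ group }}, min_groups = 2)
  if (nlevels(d$group) != 2) stop("group must have exactly 2 levels", call. = FALSE)
  sp <- split(d$value, d$group)
  x <- sp[[1]]; y <- sp[[2]]
  pooled <- ((length(x) - 1) * stats::var(x) + (length(y) - 1) * stats::var(y)) /
    (length(x) + length(y) - 2)
  if (pooled == 0) {
    if (mean(x) == mean(y)) {
      return(tibble::tibble(statistic = 0, df = length(x) + length(y) - 2,
                            p_value = 1, mean_1 = mean(x), mean_2 = mean(y),
                            group_1 = levels(d$group)[1], group_2 = levels(d$group)[2]))
    }
    stop("zero pooled variance with unequal means: t is undefined", call. = FALSE)
  }
  ht <- stats::t.test(x, y, var.equal = TRUE)
  tibble::tibble(
    statistic = unname(ht$statistic), df = unname(ht$parameter),
    p_value = ht$p.value, mean_1 = mean(x), mean_2 = mean(y),
    group_1 = levels(d$group)[1], group_2 = levels(d$group)[2]
  )
}

#' One-way fixed-effects ANOVA
#'
#' @param data Data frame in long format.
#' @param value,group Bare column names (numeric response, grouping factor
#'   with >= 2 levels of >= 2 observations each).
#' @return A `qeeg_anova` object; use [generics::tidy()] for the per-term
#'   table and [generics::glance()] for the one-row F/df/p summary.
#' @examples
#' d <- tibble::tibble(y = c(1, 2, 3, 2, 3, 4, 3, 4, 5),
#'                     g = rep(letters[1:3], each = 3))
#' glance(one_way_anova(d, y, g)) # F = 3 on (2, 6) df
#' @export
one_way_anova <- function(data, value, group) {
  d <- grouped_values(data, {{ value }}, {{ group }})
  fit <- stats::aov(value ~ group, data = d)
  an <- stats::anova(fit)
  tab <- tibble::tibble(
    term = c("group", "residuals"),
    df = an$Df, sumsq = an$`Sum Sq`, meansq = an$`Mean Sq`,
    statistic = an$`F value`, p_value = an$`Pr(>F)`
  )
  structure(list(table = tab, fit = fit, data = d), class = "qeeg_anova")
}

#' Two-way fixed-effects ANOVA with interaction
#'
#' Requires a balanced design (equal replicates in every factor-A by
#' factor-B cell, at least 2 per cell); unbalanced designs are rejected
#' because the sums-of-squares decomposition is then ambiguous.
#'
#' @param data Data frame in long format.
#' @param value,factor_a,factor_b Bare column names.
#' @return A `qeeg_anova` object with terms for A, B, the interaction and
#'   residuals.
#' @export
two_way_anova <- function(data, value, factor_a, factor_b) {
  v <- rlang::eval_tidy(rlang::enquo(value), data)
  a <- factor(rlang::eval_tidy(rlang::enquo(factor_a), data))
  b <- factor(rlang::eval_tidy(rlang::enquo(factor_b), data))
  cells <- table(a, b)
  if (length(unique(as.vector(cells))) != 1) {
    stop("unsupported design: cells are unbalanced", call. = FALSE)
  }
  if (cells[1] < 2) stop("need at least 2 replicates per cell", call. = FALSE)
  d <- data.frame(value = v, A = a, B = b)
  fit <- stats::aov(value ~ A * B, data = d)
  an <- stats::anova(fit)
  tab <- tibble::tibble(
    term = c("A", "B", "A:B", "residuals"),
    df = an$Df, sumsq = an$`Sum Sq`, meansq = an$`Mean Sq`,
    statistic = an$`F value`, p_value = an$`Pr(>F)`
  )
  structure(list(table = tab, fit = fit, data = d), class = "qeeg_anova")
}

#' @export
print.qeeg_anova <- function(x, ...) {
  cat("<qeeg_anova>\n")
  print(x$table)
  invisible(x)
}

#' @importFrom generics tidy
#' @export
generics::tidy

#' @importFrom generics glance
#' @export
generics::glance

#' @export
tidy.qeeg_anova <- function(x, ...) x$table

#' @export
glance.qeeg_anova <- function(x, ...) {
  tab <- x$table
  eff <- tab[tab$term != "residuals", ][1, ]
  res <- tab[tab$term == "residuals", ]
  tibble::tibble(
    statistic = eff$statistic, df_between = eff$df, df_within = res$df,
    ms_between = eff$meansq, ms_within = res$meansq, p_value = eff$p_value
  )
}

#' Tukey HSD multiple comparisons
#'
#' All pairwise comparisons after a one-way ANOVA, with the studentized
#' range statistic `q = |mean_i - mean_j| / sqrt(MS_within / n_h)`
#' (`n_h` the harmonic mean of the pair's sizes, i.e. the Tukey-Kramer
#' correction for unequal n) and adjusted p-values from the studentized
#' range distribution.
#'
#' @param data,value,group As in [one_way_anova()].
#' @param alpha Family-wise significance level (default 0.05).
#' @return A `qeeg_tukey` tibble: `group_1`, `group_2`, `diff`, `q`,
#'   `p_adj`, `significant`; attributes carry the group levels and alpha.
#' @examples
#' d <- tibble::tibble(y = c(rnorm(5), rnorm(5) + 10), g = rep(c("a", "b"), each = 5))
#' tukey_hsd(d, y, g)
#' @export
tukey_hsd <- function(data, value, group, alpha = 0.05) {
  d <- grouped_values(data, {{ value }}, {{ group }})
  fit <- stats::aov(value ~ group, data = d)
  ms_within <- stats::anova(fit)$`Mean Sq`[2]
  df_within <- stats::df.residual(fit)
  k <- nlevels(d$group)
  means <- tapply(d$value, d$group, mean)
  ns <- tapply(d$value, d$group, length)
  pairs <- utils::combn(levels(d$group), 2)
  res <- purrr::map_dfr(seq_len(ncol(pairs)), function(j) {
    g1 <- pairs[1, j]; g2 <- pairs[2, j]
    diff <- means[[g2]] - means[[g1]]
    se <- sqrt(ms_within / 2 * (1 / ns[[g1]] + 1 / ns[[g2]]))
    q <- abs(diff) / se
    p <- stats::ptukey(q, nmeans = k, df = df_within, lower.tail = FALSE)
    tibble::tibble(group_1 = g1, group_2 = g2, diff = diff, q = q, p_adj = p)
  })
  res$significant <- res$p_adj < alpha
  structure(res, class = c("qeeg_tukey", class(res)),
            groups = levels(d$group), alpha = alpha,
            ms_within = ms_within, df_within = df_within)
}

#' @export
tidy.qeeg_tukey <- function(x, ...) tibble::as_tibble(x)

#' Compact letter display from a Tukey result
#'
#' Groups that are not significantly different share at least one letter;
#' significantly different groups share none. Letters come from a greedy
#' clique cover of the non-significance graph: groups are processed in
#' label order, each joining every existing letter-clique it is compatible
#' with, opening a new letter (and absorbing compatible earlier groups)
#' otherwise; redundant letters are pruned.
#'
#' @param tk A `qeeg_tukey` from [tukey_hsd()].
#' @return A tibble with columns `group` and `letters`.
#' @export
assign_letters <- function(tk) {
  stopifnot(inherits(tk, "qeeg_tukey"))
  groups <- attr(tk, "groups")
  k <- length(groups)
  sig <- matrix(FALSE, k, k, dimnames = list(groups, groups))
  for (i in seq_len(nrow(tk))) {
    sig[tk$group_1[i], tk$group_2[i]] <- tk$significant[i]
    sig[tk$group_2[i], tk$group_1[i]] <- tk$significant[i]
  }
  cliques <- list()
  for (g in groups) {
    compatible <- vapply(cliques, function(cl) !any(sig[g, cl]), logical(1))
    if (any(compatible)) {
      for (ci in which(compatible)) cliques[[ci]] <- c(cliques[[ci]], g)
    } else {
      newcl <- g
      for (h in groups[seq_len(match(g, groups) - 1)]) {
        if (!any(sig[h, newcl])) newcl <- c(newcl, h)
      }
      cliques[[length(cliques) + 1]] <- newcl
    }
  }
  # prune cliques whose membership is a subset of another's
  keep <- rep(TRUE, length(cliques))
  for (i in seq_along(cliques)) {
    for (j in seq_along(cliques)) {
      if (i != j && keep[j] && all(cliques[[i]] %in% cliques[[j]]) &&
          (length(cliques[[i]]) < length(cliques[[j]]) || i > j)) {
        keep[i] <- FALSE
      }
    }
  }
  cliques <- cliques[keep]
  letters_of <- function(g) {
    paste(letters[which(vapply(cliques, function(cl) g %in% cl, logical(1)))],
          collapse = "")
  }
  tibble::tibble(group = groups,
                 letters = vapply(groups, letters_of, character(1),
                                  USE.NAMES = FALSE))
}

#' Mean, SD and significance letters per group
#'
#' @param data,value,group As in [one_way_anova()].
#' @param letters If `TRUE` (default) run [tukey_hsd()] + [assign_letters()]
#'   and attach the compact letter display (requires >= 2 groups).
#' @param alpha Significance level for the letters.
#' @return A tibble: `group`, `n`, `mean`, `sd` (sample SD, n-1 denominator),
#'   and `letters` when requested.
#' @export
summarize_groups <- function(data, value, group, letters = TRUE, alpha = 0.05) {
  d <- grouped_values(data, {{ value }}, {{ group }},
                      min_groups = if (letters) 2 else 1)
  out <- d |>
    dplyr::group_by(group) |>
    dplyr::summarise(n = dplyr::n(), mean = mean(value), sd = stats::sd(value),
                     .groups = "drop") |>
    dplyr::rename(group = group)
  if (letters) {
    tk <- tukey_hsd(d, value, group, alpha = alpha)
    out <- dplyr::left_join(out, assign_letters(tk), by = "group")
  }
  out
}
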