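# Table-1 / Table-2 style descriptive statistics and univariate tests

#' Percentage from a count
#'
#' `100 * count / denom`, rounded half-up to one decimal: the convention of
#' printed "% (n/total n)" table cells.
#'
#' @param count nonnegative integer.
#' @param denom positive integer, `count <= denom`.
#' @return Percentage to one decimal.
#' @export
proportion <- function(count, denom) {
  stopifnot(length(count) == 1, length(denom) == 1)
  if (denom == 0) stop("denominator must be positive")
  if (count < 0 || count > denom) stop("count must lie in [0, denom]")
  round_half_up(100 * count / denom, 1)
}

#' Median and range
#'
#' Sample median (midpoint convention for even n), minimum and maximum.
#'
#' @param values nonempty numeric vector; missing values are dropped.
#' @return List with `median`, `min`, `max`.
#' @export
median_range <- function(values) {
  values <- values[!is.na(values)]
  if (length(values) == 0) stop("no non-missing values")
  list(median = stats::median(values), min = min(values), max = max(values))
}

#' Pearson chi-square test of independence
#'
#' `sum((O - E)^2 / E)` over an r x c count table with expectations from the
#' independence margins; `df = (r - 1)(c - 1)`, upper-tail p-value. No
#' continuity correction by default (set `correct = TRUE` for the Yates
#' correction in 2 x 2 tables).
#'
#' @param tab matrix of nonnegative counts, at least 2 x 2.
#' @param correct apply Yates continuity correction?
#' @return List with `statistic`, `df`, `p_value`, `expected`.
#' @export
pearson_chi2 <- function(tab, correct = FALSE) {
  tab <- as.matrix(tab)
  if (nrow(tab) < 2 || ncol(tab) < 2) stop("table must be at least 2 x 2")
  if (any(tab < 0)) stop("counts must be nonnegative")
  if (any(rowSums(tab) == 0) || any(colSums(tab) == 0))
    stop("zero row or column margin: ",
         paste(c(which(rowSums(tab) == 0), which(colSums(tab) == 0)), collapse = ", "))
  res <- suppressWarnings(stats::chisq.test(tab, correct = correct))
  list(statistic = unname(res$statistic), df = unname(res$parameter),
       p_value = res$p.value, expected = res$expected)
}

#' Mann-Whitney U test
#'
#' Two-sided rank-sum test. When the combined sample size is at most 12 and
#' there are no ties, the exact p-value is computed by enumeration; otherwise
#' the normal approximation with tie correction is used.
#'
#' @param group1,group2 nonempty numeric vectors.
#' @return List with `U` (statistic for `group1`) and `p_value`.
#' @export
mann_whitney <- function(group1, group2) {
  group1 <- group1[!is.na(group1)]; group2 <- group2[!is.na(group2)]
  if (length(group1) == 0 || length(group2) == 0) stop("both groups must be nonempty")
  n <- length(group1) + length(group2)
  exact <- n <= 12 && !any(duplicated(c(group1, group2)))
  res <- suppressWarnings(
    stats::wilcox.test(group1, group2, exact = exact, correct = FALSE)
  )
  list(U = unname(res$statistic), p_value = res$p.value)
}

#' Normality check
#'
#' Shapiro-Wilk test, or the Lilliefors-corrected Kolmogorov-Smirnov test
#' against a fitted normal. The table generator uses it to choose between the
#' t-test and the Mann-Whitney test (p < 0.05 in either group selects the
#' nonparametric test). Constant samples (and samples too small to assess,
#' n < 3 for Shapiro-Wilk, n < 4 for Lilliefors) return a non-normal verdict
#' with p-value 0.
#'
#' @param values numeric vector.
#' @param method `"shapiro_wilk"` or `"kolmogorov_smirnov"`.
#' @return List with `statistic` and `p_value`.
#' @export
normality_check <- function(values, method = c("shapiro_wilk", "kolmogorov_smirnov")) {
  method <- match.arg(method)
  values <- values[!is.na(values)]
  min_n <- if (method == "shapiro_wilk") 3 else 4
  if (length(values) < min_n || length(unique(values)) == 1)
    return(list(statistic = NA_real_, p_value = 0))
  res <- if (method == "shapiro_wilk") {
    stats::shapiro.test(if (length(values) > 5000) sample(values, 5000) else values)
  } else {
    nortest::lillie.test(values)
  }
  list(statistic = unname(res$statistic), p_value = res$p.value)
}

#' One-way ANOVA across groups
#'
#' Thin wrapper for comparing a continuous variable across 3 or more groups.
#'
#' @param values numeric vector.
#' @param group factor or character vector, parallel to `values`.
#' @return List with `statistic` (F), `df`, `p_value`.
#' @export
oneway_anova <- function(values, group) {
  fit <- stats::oneway.test(values ~ factor(group), var.equal = TRUE)
  list(statistic = unname(fit$statistic), df = unname(fit$parameter),
       p_value = fit$p.value)
}

#' Descriptive group-comparison table
#'
#' Builds a Table-1-style comparison of baseline variables between the exposed
#' and control groups of one model: continuous variables as median and range
#' with a t-test or Mann-Whitney test (nonparametric when either group fails
#' the normality check at 0.05), categorical variables as percent (n/total n)
#' per level with a Pearson chi-square test across levels.
#'
#' @param cohort cohort data frame.
#' @param model `"model1"` or `"model2"`.
#' @param variables cohort column names to summarize.
#' @param normality_method passed to [normality_check()].
#' @return Data frame with one row per variable level: group summaries,
#'   `p_value` and `test_used`.
#' @export
cohort_table1 <- function(cohort, model = c("model2", "model1"),
                          variables = c("age", "sex", "aml_history", "wbc",
                                        "platelets", "hemoglobin",
                                        "cytogenetic_risk", "cad",
                                        "valvular_disease", "heart_failure",
                                        "acei_arb", "beta_blocker",
                                        "anthracycline_dose"),
                          normality_method = "shapiro_wilk") {
  model <- match.arg(model)
  ms <- model_subset(cohort, model)
  sub <- ms$cohort; exposed <- ms$exposed
  out <- NULL
  fmt_cont <- function(x) {
    mr <- median_range(x)
    sprintf("%.1f (%.1f-%.1f)", mr$median, mr$min, mr$max)
  }
  for (v in variables) {
    x <- sub[[v]]
    if (is.numeric(x)) {
      x1 <- x[exposed & !is.na(x)]; x0 <- x[!exposed & !is.na(x)]
      if (length(x1) == 0 || length(x0) == 0) next
      normal <- normality_check(x1, normality_method)$p_value >= 0.05 &&
        normality_check(x0, normality_method)$p_value >= 0.05
      if (normal && length(x1) >= 2 && length(x0) >= 2) {
        p <- unpaired_ttest(x1, x0)$p_value
        test <- "t_test"
      } else {
        p <- mann_whitney(x1, x0)$p_value
        test <- "mann_whitney"
      }
      out <- rbind(out, data.frame(
        variable = v, level = "",
        exposed = fmt_cont(x1), control = fmt_cont(x0),
        n_exposed = length(x1), n_control = length(x0),
        p_value = p, test_used = test, stringsAsFactors = FALSE))
    } else {
      lv <- if (is.logical(x)) c(TRUE, FALSE) else sort(unique(x[!is.na(x)]))
      avail1 <- sum(exposed & !is.na(x)); avail0 <- sum(!exposed & !is.na(x))
      if (avail1 == 0 || avail0 == 0) next
      counts <- vapply(lv, function(l) c(sum(x[exposed] == l, na.rm = TRUE),
                                         sum(x[!exposed] == l, na.rm = TRUE)),
                       numeric(2))
      tab <- t(counts)                       # levels x groups
      p <- tryCatch(pearson_chi2(tab[rowSums(tab) > 0, , drop = FALSE])$p_value,
                    error = function(e) NA_real_)
      show_lv <- if (is.logical(x)) TRUE else lv
      for (l in show_lv) {
        c1 <- sum(x[exposed] == l, na.rm = TRUE)
        c0 <- sum(x[!exposed] == l, na.rm = TRUE)
        out <- rbind(out, data.frame(
          variable = v, level = as.character(l),
          exposed = sprintf("%.1f (%d/%d)", proportion(c1, avail1), c1, avail1),
          control = sprintf("%.1f (%d/%d)", proportion(c0, avail0), c0, avail0),
          n_exposed = avail1, n_control = avail0,
          p_value = p, test_used = "chi_square", stringsAsFactors = FALSE))
      }
    }
  }
  out
}
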