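# semiquantitative sarcomere-organization grading of cardiomyocytes

#' Grade sarcomere organization
#'
#' Bins the fraction of cell area showing organized sarcomeres into the
#' semiquantitative grades 1-4: `[0, 0.10)` is grade 1, `[0.10, 0.50)` grade 2,
#' `[0.50, 0.90]` grade 3, and `(0.90, 1]` grade 4 (only the grade-4 boundary,
#' strictly above 90%, is unambiguous in the original scheme; the lower
#' boundaries follow the half-open convention and can be shifted via
#' `breaks`). The bins partition `[0, 1]`, so the grade is a monotone
#' nondecreasing function of the organized fraction.
#'
#' @param organized_fraction numeric vector of proportions in `[0, 1]`.
#' @param breaks the three inner cut points (defaults `c(0.10, 0.50, 0.90)`).
#' @return Integer vector of grades 1-4.
#' @export
grade_sarcomere <- function(organized_fraction, breaks = c(0.10, 0.50, 0.90)) {
  if (any(is.na(organized_fraction)) ||
      any(organized_fraction < 0 | organized_fraction > 1))
    stop("organized_fraction must lie in [0, 1]")
  stopifnot(length(breaks) == 3, !is.unsorted(breaks))
  g <- rep(1L, length(organized_fraction))
  g[organized_fraction >= breaks[1]] <- 2L
  g[organized_fraction >= breaks[2]] <- 3L
  g[organized_fraction > breaks[3]] <- 4L
  g
}

#' Compare grade distributions between two conditions
#'
#' Tabulates the percentage of cells per grade in each condition and compares
#' the two grade distributions with a Pearson chi-square test over the grades
#' observed in either condition.
#'
#' @param cells data frame with columns `condition` and either `grade` or
#'   `organized_fraction` (graded on the fly).
#' @param condition_a,condition_b the two condition labels to compare.
#' @return List with `table` (per-grade counts and percentages per condition)
#'   and `test` (the [pearson_chi2()] result).
#' @export
grade_distribution <- function(cells, condition_a, condition_b) {
  stopifnot(is.data.frame(cells), "condition" %in% names(cells))
  if (!("grade" %in% names(cells))) {
    cells$grade <- grade_sarcomere(cells$organized_fraction)
  }
  a <- cells$grade[cells$condition == condition_a]
  b <- cells$grade[cells$condition == condition_b]
  if (length(a) == 0 || length(b) == 0)
    stop("both conditions must have at least one cell")
  grades <- 1:4
  counts <- rbind(table(factor(a, levels = grades)),
                  table(factor(b, levels = grades)))
  rownames(counts) <- c(condition_a, condition_b)
  tab <- data.frame(
    grade = grades,
    count_a = counts[1, ], count_b = counts[2, ],
    percent_a = vapply(counts[1, ], proportion, numeric(1), denom = length(a)),
    percent_b = vapply(counts[2, ], proportion, numeric(1), denom = length(b)),
    row.names = NULL
  )
  names(tab)[2:5] <- c(paste0("count_", c(condition_a, condition_b)),
                       paste0("percent_", c(condition_a, condition_b)))
  used <- counts[, colSums(counts) > 0, drop = FALSE]
  if (ncol(used) < 2)
    stop("degenerate comparison: zero margin for every grade but grade ",
         colnames(used)[1])
  test <- pearson_chi2(used)
  list(table = tab, test = test)
}
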