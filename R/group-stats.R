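# Group comparisons of per-cell metrics with unpaired t-tests.

#' Significance stars
#'
#' The reporting convention used for per-cell metrics: `***` for
#' p <= 0.001, `*` for p <= 0.05, `ns` otherwise.
#'
#' @param p p-value(s)
#' @return character vector of stars
#' @export
significance_stars <- function(p) {
  ifelse(p <= 0.001, "***", ifelse(p <= 0.05, "*", "ns"))
}

#' Two-sided unpaired t-test between two groups of per-cell values
#'
#' Welch's unequal-variance test by default (robust to variance
#' heterogeneity between treatment groups); the pooled-variance Student test
#' is available via `var_equal = TRUE`.
#'
#' @param x,y numeric value vectors (each of length >= 2)
#' @param var_equal pool the variances (Student) instead of Welch
#' @param labels optional `c(name_x, name_y)` group labels
#' @return a `group_comparison` object: group labels, means, standard
#'   deviations, sample sizes, `t`, two-sided `p`, and `stars`
#' @export
unpaired_t_test <- function(x, y, var_equal = FALSE,
                            labels = c("x", "y")) {
  if (length(x) < 2L || length(y) < 2L) {
    stopf("each sample needs at least 2 values (got %d and %d)",
          length(x), length(y), class = "chromamech_stats_error")
  }
  if (stats::sd(x) == 0 && stats::sd(y) == 0) {
    stopf("both samples have zero variance; t-test is degenerate",
          class = "chromamech_degenerate_test")
  }
  ht <- stats::t.test(x, y, var.equal = var_equal, alternative = "two.sided")
  structure(
    list(group_a = labels[1], group_b = labels[2],
         mean_a = mean(x), mean_b = mean(y),
         sd_a = stats::sd(x), sd_b = stats::sd(y),
         n_a = length(x), n_b = length(y),
         t = unname(ht$statistic), p = ht$p.value,
         stars = significance_stars(ht$p.value),
         var_equal = var_equal),
    class = "group_comparison"
  )
}

#' @export
print.group_comparison <- function(x, ...) {
  cat(sprintf("%s vs %s: mean %.4g vs %.4g, t = %.3f, p = %.3g %s\n",
              x$group_a, x$group_b, x$mean_a, x$mean_b, x$t, x$p, x$stars))
  invisible(x)
}

as_row <- function(cmp, metric = NA_character_) {
  data.frame(metric = metric, group_a = cmp$group_a, group_b = cmp$group_b,
             n_a = cmp$n_a, n_b = cmp$n_b, mean_a = cmp$mean_a,
             mean_b = cmp$mean_b, t = cmp$t, p = cmp$p, stars = cmp$stars,
             stringsAsFactors = FALSE)
}

#' Compare every treatment group against a reference
#'
#' Runs one unpaired t-test per non-reference group against the reference
#' (each treated group vs control), optionally adding all remaining pairwise
#' comparisons. Results are ordered by group label for determinism.
#'
#' @param values per-cell metric values
#' @param groups group label per value
#' @param reference reference (control) group label
#' @param metric metric name carried into the output
#' @param pairwise also include all non-reference pairwise comparisons
#' @param var_equal see [unpaired_t_test()]
#' @return data frame with one row per comparison: `metric, group_a,
#'   group_b, n_a, n_b, mean_a, mean_b, t, p, stars`; zero rows when only
#'   the reference group is present
#' @export
compare_all <- function(values, groups, reference, metric = "metric",
                        pairwise = FALSE, var_equal = FALSE) {
  keep <- is.finite(values)
  values <- values[keep]; groups <- as.character(groups)[keep]
  lev <- sort(unique(groups))
  if (!reference %in% lev) {
    stopf("reference group '%s' not present (groups: %s)", reference,
          paste(lev, collapse = ", "), class = "chromamech_stats_error")
  }
  others <- setdiff(lev, reference)
  pairs <- lapply(others, function(g) c(g, reference))
  if (pairwise && length(others) > 1L) {
    combs <- utils::combn(others, 2L, simplify = FALSE)
    pairs <- c(pairs, combs)
  }
  rows <- lapply(pairs, function(pr) {
    as_row(unpaired_t_test(values[groups == pr[1]], values[groups == pr[2]],
                           var_equal = var_equal, labels = pr),
           metric = metric)
  })
  if (length(rows) == 0L) {
    return(data.frame(metric = character(0), group_a = character(0),
                      group_b = character(0), n_a = integer(0),
                      n_b = integer(0), mean_a = numeric(0),
                      mean_b = numeric(0), t = numeric(0), p = numeric(0),
                      stars = character(0), stringsAsFactors = FALSE))
  }
  do.call(rbind, rows)
}
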