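# Shared statistics layer: replicate summaries, pairwise independent-sample
# (Welch) t-tests, and the significance-star annotation used in figure
# tables.

#' Two-sided Welch t-test between two samples
#'
#' Pairwise independent-sample comparison with unequal variances (Welch) by
#' default; set `var_equal = TRUE` for the classical Student test. Built on
#' [stats::t.test()]. When both samples are constant the test statistic is
#' undefined: equal means return `p = 1` (no evidence of difference),
#' unequal means return `p = 0` with an infinite statistic.
#'
#' @param a,b Numeric vectors, each with at least 2 values.
#' @param var_equal Assume equal variances (default `FALSE` = Welch).
#'
#' @return List with `p_value`, `t`, and `df`.
#' @export
welch_t_test <- function(a, b, var_equal = FALSE) {
  if (length(a) < 2L || length(b) < 2L)
    stop("each sample needs at least 2 values", call. = FALSE)
  if (anyNA(a) || anyNA(b)) stop("samples must not contain NA", call. = FALSE)
  if (stats::var(a) == 0 && stats::var(b) == 0) {
    if (mean(a) == mean(b))
      return(list(p_value = 1, t = 0, df = length(a) + length(b) - 2))
    return(list(p_value = 0, t = sign(mean(b) - mean(a)) * Inf,
                df = length(a) + length(b) - 2))
  }
  ht <- stats::t.test(a, b, var.equal = var_equal)
  list(p_value = unname(ht$p.value), t = unname(ht$statistic),
       df = unname(ht$parameter))
}

#' Significance stars for a p-value
#'
#' The annotation convention of the study's figure legends: `"***"` for
#' p < 0.001, `"**"` for p < 0.01, `"*"` for p < 0.05, `"n.s."` otherwise.
#' Boundaries are half-open exactly as stated (p = 0.05 is `"n.s."`).
#'
#' @param p_value Numeric vector of p-values in (0, 1].
#'
#' @return Character vector of labels.
#' @export
significance_stars <- function(p_value) {
  if (any(is.na(p_value)) || any(p_value <= 0 | p_value > 1))
    stop("p-values must lie in (0, 1]", call. = FALSE)
  ifelse(p_value < 0.001, "***",
         ifelse(p_value < 0.01, "**",
                ifelse(p_value < 0.05, "*", "n.s.")))
}

#' Replicate summary of a group
#'
#' @param values Numeric replicate values (n >= 1).
#' @param label Group label.
#'
#' @return List with `label`, `n`, `mean`, `sd` (`NA` for n = 1).
#' @export
group_summary <- function(values, label = "") {
  if (length(values) < 1L) stop("empty group", call. = FALSE)
  list(label = label, n = length(values), mean = mean(values),
       sd = if (length(values) > 1L) stats::sd(values) else NA_real_)
}
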