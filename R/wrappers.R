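# Thin wrappers over the standard tests used around the bespoke statistics:
# a Shapiro-Wilk normality gate choosing between Student's t and the
# Mann-Whitney rank test for two groups, and between one-way ANOVA and
# Kruskal-Wallis for three or more.

#' Compare two groups with a normality-gated two-sample test
#'
#' Applies the Shapiro-Wilk test to each sample; when both pass at the 0.05
#' level the comparison uses the unpaired two-tailed Student's t test,
#' otherwise the two-tailed Mann-Whitney (Wilcoxon rank-sum) test. Samples
#' with fewer than 3 values (where Shapiro-Wilk is undefined) or constant
#' samples force the rank test.
#'
#' @param a,b non-empty numeric samples.
#' @return list with `test_used` (`"t"` or `"mann_whitney"`), `p_value`, and
#'   `shapiro_p` (per-sample gate p-values, NA where undefined).
#' @export
compare_groups <- function(a, b) {
  if (length(a) < 1L || length(b) < 1L) stop("both samples must be non-empty", call. = FALSE)
  shap <- function(x) {
    if (length(x) < 3L || length(x) > 5000L || stats::sd(x) == 0) return(NA_real_)
    stats::shapiro.test(x)$p.value
  }
  pa <- shap(a); pb <- shap(b)
  normal <- !is.na(pa) && !is.na(pb) && pa > 0.05 && pb > 0.05
  if (normal) {
    res <- stats::t.test(a, b, var.equal = TRUE)
    list(test_used = "t", p_value = res$p.value, shapiro_p = c(a = pa, b = pb))
  } else {
    res <- suppressWarnings(stats::wilcox.test(a, b, exact = NULL))
    p <- res$p.value
    if (is.nan(p)) p <- 1 # every observation tied: no evidence of a shift
    list(test_used = "mann_whitney", p_value = p, shapiro_p = c(a = pa, b = pb))
  }
}

#' Compare three or more groups with a normality-gated omnibus test
#'
#' One-way ANOVA when every group passes Shapiro-Wilk at 0.05, otherwise
#' the Kruskal-Wallis rank test.
#'
#' @param values numeric vector of observations.
#' @param groups group labels, same length as `values`; at least 3 groups.
#' @return list with `test_used` (`"anova"` or `"kruskal_wallis"`) and
#'   `p_value`.
#' @export
compare_conditions <- function(values, groups) {
  groups <- as.factor(groups)
  if (nlevels(groups) < 3L) stop("need >= 3 groups; use compare_groups() for two", call. = FALSE)
  shap_ok <- vapply(split(values, groups), function(x) {
    if (length(x) < 3L || stats::sd(x) == 0) return(FALSE)
    stats::shapiro.test(x)$p.value > 0.05
  }, TRUE)
  if (all(shap_ok)) {
    fit <- stats::aov(values ~ groups)
    p <- summary(fit)[[1]][["Pr(>F)"]][1]
    list(test_used = "anova", p_value = p)
  } else {
    res <- stats::kruskal.test(values, groups)
    list(test_used = "kruskal_wallis", p_value = res$p.value)
  }
}
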