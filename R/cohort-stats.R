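#' Two-sample t-test from group summaries
#'
#' Welch statistic t = (m1 - m2) / sqrt(s1^2/n1 + s2^2/n2) with the
#' Welch-Satterthwaite degrees of freedom and a two-sided p-value; with
#' `var_equal = TRUE`, the pooled-variance Student test instead (the
#' variant classical SPSS demographics tables print). Applied to raw
#' data's own mean/SD/n it reproduces `t.test(x, y, var.equal = ...)`
#' exactly.
#'
#' @param mean1,sd1,n1 summary of group 1.
#' @param mean2,sd2,n2 summary of group 2.
#' @param var_equal pool the variances (Student) instead of Welch.
#' @return List with `t`, `df`, `p`, and `degenerate` (TRUE if both SDs 0).
#' @export
welch_t_from_summary <- function(mean1, sd1, n1, mean2, sd2, n2,
                                 var_equal = FALSE) {
  stopifnot(n1 >= 2, n2 >= 2, sd1 >= 0, sd2 >= 0)
  if (sd1 == 0 && sd2 == 0) {
    return(list(t = if (mean1 == mean2) 0 else sign(mean1 - mean2) * Inf,
                df = NA_real_, p = if (mean1 == mean2) 1 else 0,
                degenerate = TRUE))
  }
  if (var_equal) {
    sp2 <- ((n1 - 1) * sd1^2 + (n2 - 1) * sd2^2) / (n1 + n2 - 2)
    t <- (mean1 - mean2) / sqrt(sp2 * (1 / n1 + 1 / n2))
    df <- n1 + n2 - 2
  } else {
    v1 <- sd1^2 / n1; v2 <- sd2^2 / n2
    t <- (mean1 - mean2) / sqrt(v1 + v2)
    df <- (v1 + v2)^2 / (v1^2 / (n1 - 1) + v2^2 / (n2 - 1))
  }
  list(t = t, df = df, p = 2 * stats::pt(-abs(t), df), degenerate = FALSE)
}

#' Pearson chi-square test for a 2x2 table
#'
#' Without continuity correction: chi2 = n (ad - bc)^2 /
#' ((a+b)(c+d)(a+c)(b+d)), df = 1.
#'
#' @param a,b,c,d cell counts (first row a, b; second row c, d).
#' @param correct apply the Yates continuity correction.
#' @return List with `chi2`, `df`, `p`.
#' @export
chi_square_2x2 <- function(a, b, c, d, correct = FALSE) {
  stopifnot(all(c(a, b, c, d) >= 0), all(c(a, b, c, d) == round(c(a, b, c, d))))
  n <- a + b + c + d
  margins <- c(a + b, c + d, a + c, b + d)
  if (any(margins == 0)) stop("zero margin in 2x2 table")
  num <- abs(a * d - b * c)
  if (correct) num <- max(0, num - n / 2)
  chi2 <- n * num^2 / prod(margins)
  list(chi2 = chi2, df = 1, p = stats::pchisq(chi2, 1, lower.tail = FALSE))
}

#' Group-comparison demographics table
#'
#' Per continuous variable (age, education, MMSE, ...), group mean +/- SD
#' and a Welch t-test; for sex, male:female counts and a Pearson chi-square
#' test. Accepts either a cohort manifest (raw rows) or a list of two
#' `GroupSummary`-style lists with `n`, `mean`, `sd` per variable.
#'
#' @param manifest an `hr_manifest` with `label` and demographic columns.
#' @param variables continuous variables to compare (present columns only).
#' @param var_equal use the pooled-variance t-test (default TRUE, the SPSS
#'   table convention) rather than Welch.
#' @return Data.frame with one row per variable: group summaries, the test
#'   statistic and p-value.
#' @export
demographics_table <- function(manifest,
                               variables = c("age", "education", "mmse"),
                               var_equal = TRUE) {
  labs <- unique(manifest$label)
  labs <- labs[order(toupper(labs), method = "radix")]
  stopifnot(length(labs) == 2)
  g1 <- manifest[manifest$label == labs[1], , drop = FALSE]
  g2 <- manifest[manifest$label == labs[2], , drop = FALSE]
  rows <- list(data.frame(
    variable = "n", group1 = nrow(g1), group2 = nrow(g2),
    statistic = NA_real_, p = NA_real_, test = NA_character_,
    stringsAsFactors = FALSE))
  for (v in variables) {
    if (!v %in% names(manifest)) next
    w <- welch_t_from_summary(mean(g1[[v]]), stats::sd(g1[[v]]), nrow(g1),
                              mean(g2[[v]]), stats::sd(g2[[v]]), nrow(g2),
                              var_equal = var_equal)
    rows[[length(rows) + 1L]] <- data.frame(
      variable = v,
      group1 = sprintf("%.2f ± %.2f", mean(g1[[v]]), stats::sd(g1[[v]])),
      group2 = sprintf("%.2f ± %.2f", mean(g2[[v]]), stats::sd(g2[[v]])),
      statistic = w$t, p = w$p,
      test = if (var_equal) "pooled t" else "Welch t",
      stringsAsFactors = FALSE)
  }
  if ("sex" %in% names(manifest)) {
    m1 <- sum(g1$sex == "M"); f1 <- sum(g1$sex == "F")
    m2 <- sum(g2$sex == "M"); f2 <- sum(g2$sex == "F")
    cs <- chi_square_2x2(m1, f1, m2, f2)
    rows[[length(rows) + 1L]] <- data.frame(
      variable = "sex (M:F)", group1 = paste0(m1, ":", f1),
      group2 = paste0(m2, ":", f2), statistic = cs$chi2, p = cs$p,
      test = "chi-square", stringsAsFactors = FALSE)
  }
  out <- do.call(rbind, lapply(rows, function(r) {
    r$group1 <- as.character(r$group1); r$group2 <- as.character(r$group2); r
  }))
  names(out)[2:3] <- labs
  out
}
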