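#' Pooled-SD Cohen's d
#'
#' Standardised mean difference using the (n-1)-weighted pooled standard
#' deviation, without small-sample (Hedges) correction:
#' \deqn{d = (m_1 - m_2) / s_p,\quad
#'   s_p^2 = ((n_1{-}1)s_1^2 + (n_2{-}1)s_2^2)/(n_1+n_2-2).}
#' Sign convention: group 1 (MetS) minus group 2 (non-MetS).
#'
#' @param m1,s1,n1 mean, SD and size of group 1.
#' @param m2,s2,n2 mean, SD and size of group 2.
#' @return the standardised difference `d`.
#' @examples
#' pooled_cohens_d(113.984, 15.114, 315, 105.225, 18.059, 1464)  # ~0.498
#' @export
pooled_cohens_d <- function(m1, s1, n1, m2, s2, n2) {
  stopifnot(n1 >= 2, n2 >= 2, s1 >= 0, s2 >= 0)
  sp2 <- ((n1 - 1) * s1^2 + (n2 - 1) * s2^2) / (n1 + n2 - 2)
  if (sp2 <= 0) stop("zero pooled variance")
  (m1 - m2) / sqrt(sp2)
}

#' Odds ratio from a 2x2 table
#'
#' `OR = (a/b) / (c/d)`, the odds of the first level in group 1 relative to
#' group 2. In the sample-characteristics table the orientation is the odds
#' of female sex in the MetS group versus the non-MetS group, i.e.
#' `(a, b) = (female, male)` counts among MetS and `(c, d)` among non-MetS.
#' No continuity correction is applied; a zero count on the denominator path
#' is an error.
#'
#' @param a,b,c,d nonnegative counts.
#' @export
odds_ratio <- function(a, b, c, d) {
  stopifnot(a >= 0, b >= 0, c >= 0, d >= 0)
  if (b == 0 || c == 0 || d == 0)
    stop("zero cell on the denominator path; odds ratio undefined")
  (a / b) / (c / d)
}

#' Two-sample Student's t test (pooled variance)
#'
#' Wrapper around [stats::t.test()] with `var.equal = TRUE` (the pooled
#' test); two-sided p from the t distribution with `n1 + n2 - 2` df. A Welch
#' test is available behind `welch = TRUE` but is off by default.
#'
#' @param x,y numeric vectors, each of length >= 2.
#' @param welch use the Welch unequal-variance test instead.
#' @return list with `statistic` (t) and `p_value`.
#' @export
student_t <- function(x, y, welch = FALSE) {
  stopifnot(length(x) >= 2, length(y) >= 2)
  if (!welch) {
    sp2 <- ((length(x) - 1) * stats::var(x) + (length(y) - 1) * stats::var(y)) /
      (length(x) + length(y) - 2)
    if (sp2 <= 0) stop("zero pooled variance")
  }
  ht <- stats::t.test(x, y, var.equal = !welch)
  list(statistic = unname(ht$statistic), p_value = ht$p.value)
}

#' Pearson chi-square test on a contingency table
#'
#' [stats::chisq.test()] without continuity correction. Errors when any
#' expected cell is zero (degenerate margin).
#'
#' @param contingency a 2 x k matrix of nonnegative counts.
#' @return list with `statistic`, `p_value`, `df`.
#' @export
chi_square <- function(contingency) {
  contingency <- as.matrix(contingency)
  stopifnot(all(contingency >= 0))
  expected <- outer(rowSums(contingency), colSums(contingency)) /
    sum(contingency)
  if (any(expected == 0)) stop("zero expected cell")
  ht <- suppressWarnings(stats::chisq.test(contingency, correct = FALSE))
  list(statistic = unname(ht$statistic), p_value = ht$p.value,
       df = unname(ht$parameter))
}

#' Significance stars
#'
#' `*` p < 0.05, `**` p < 0.01, `***` p < 0.001 (the footnote convention of
#' the sample-characteristics table).
#'
#' @param p p-value(s).
#' @return character vector of star codes.
#' @export
p_stars <- function(p) {
  ifelse(p < 0.001, "***", ifelse(p < 0.01, "**", ifelse(p < 0.05, "*", "")))
}

#' Default variable specification for the group summary
#'
#' @return `data.frame` (`variable`, `kind`) covering the sample-
#'   characteristics layout: sex, age, anthropometrics, blood pressure,
#'   labs, the ten PHQ items and the PHQ total.
#' @export
default_variable_spec <- function() {
  cont <- c("age", "weight", "waist", "bmi", "sbp", "dbp", "glucose",
            "triglycerides", "hdl", phq_cols(), "phq_total")
  data.frame(variable = c("sex", cont),
             kind = c("categorical", rep("continuous", length(cont))),
             stringsAsFactors = FALSE)
}

#' Group summary table with effect sizes
#'
#' Reproduces the sample-characteristics layout: per-group n, mean and SD for
#' continuous variables (pooled t test, Cohen's d), counts and proportions
#' for categorical variables (chi-square test, odds ratio oriented as odds
#' of female in the MetS group), with significance stars. `phq_total` is
#' derived as the sum of items 1-9 (the questionnaire total score) when not
#' already a column.
#'
#' @param mets_group,non_mets_group cohort `data.frame`s (both nonempty).
#' @param variables a `data.frame` (`variable`, `kind`) as returned by
#'   [default_variable_spec()]; order is preserved in the output.
#' @param welch passed to [student_t()].
#' @return `data.frame`, one row per variable: group summaries, `effect`
#'   (d or OR), `statistic`, `p_value`, `stars`. For categorical rows the
#'   `mean_*` columns hold the proportion of the first level and `levels`
#'   names the level counts.
#' @export
summary_table <- function(mets_group, non_mets_group,
                          variables = default_variable_spec(),
                          welch = FALSE) {
  stopifnot(nrow(mets_group) > 0, nrow(non_mets_group) > 0)
  add_total <- function(df) {
    if (!"phq_total" %in% names(df) && all(paste0("phq", 1:9) %in% names(df)))
      df$phq_total <- rowSums(df[paste0("phq", 1:9)])
    df
  }
  g1 <- add_total(mets_group)
  g2 <- add_total(non_mets_group)
  rows <- lapply(seq_len(nrow(variables)), function(i) {
    v <- variables$variable[i]
    kind <- variables$kind[i]
    if (!v %in% names(g1) || !v %in% names(g2))
      stop("variable not present in cohort: ", v)
    if (kind == "continuous") {
      x <- g1[[v]]; y <- g2[[v]]
      if (anyNA(x) || anyNA(y)) stop("missing values in variable: ", v)
      ht <- student_t(x, y, welch = welch)
      d <- pooled_cohens_d(mean(x), stats::sd(x), length(x),
                           mean(y), stats::sd(y), length(y))
      data.frame(variable = v, kind = kind,
                 n_mets = length(x), mean_mets = mean(x),
                 sd_mets = stats::sd(x),
                 n_non_mets = length(y), mean_non_mets = mean(y),
                 sd_non_mets = stats::sd(y),
                 levels = NA_character_, effect_type = "cohens_d",
                 effect = d, statistic = ht$statistic,
                 p_value = ht$p_value, stars = p_stars(ht$p_value),
                 stringsAsFactors = FALSE)
    } else {
      lv <- sort(unique(c(g1[[v]], g2[[v]])))
      if (identical(sort(lv), c("female", "male"))) lv <- c("female", "male")
      c1 <- vapply(lv, function(l) sum(g1[[v]] == l), numeric(1))
      c2 <- vapply(lv, function(l) sum(g2[[v]] == l), numeric(1))
      tab <- rbind(mets = c1, non_mets = c2)
      ht <- chi_square(tab)
      eff <- if (length(lv) == 2) odds_ratio(c1[1], c1[2], c2[1], c2[2])
             else NA_real_
      data.frame(variable = v, kind = kind,
                 n_mets = sum(c1), mean_mets = c1[1] / sum(c1),
                 sd_mets = NA_real_,
                 n_non_mets = sum(c2), mean_non_mets = c2[1] / sum(c2),
                 sd_non_mets = NA_real_,
                 levels = paste0(lv, "=", c1, "/", c2, collapse = "; "),
                 effect_type = "odds_ratio", effect = eff,
                 statistic = ht$statistic, p_value = ht$p_value,
                 stars = p_stars(ht$p_value), stringsAsFactors = FALSE)
    }
  })
  out <- do.call(rbind, rows)
  rownames(out) <- NULL
  out
}

#' Write a summary table as TSV plus a JSON twin
#'
#' @param tbl output of [summary_table()].
#' @param path_tsv,path_json output paths (either may be `NULL` to skip).
#' @return `tbl`, invisibly.
#' @export
write_summary_table <- function(tbl, path_tsv = NULL, path_json = NULL) {
  if (!is.null(path_tsv))
    utils::write.table(tbl, path_tsv, sep = "\t", quote = FALSE,
                       row.names = FALSE)
  if (!is.null(path_json))
    jsonlite::write_json(tbl, path_json, dataframe = "rows", digits = NA,
                         auto_unbox = TRUE, pretty = TRUE, na = "null")
  invisible(tbl)
}
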