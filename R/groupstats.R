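#' Two-by-two mixed-design repeated-measures ANOVA
#'
#' One within-subject factor with two levels and one between-subject factor
#' with two groups, the design of the study's inferential statistics.
#' Effects are computed from subject sum and difference scores, which for a
#' 2 x 2 design reproduces the classical (SPSS-style, Type III) mixed-model
#' sums of squares also under unequal group sizes: the between-subjects
#' main effect is tested against subjects-within-groups, the within main
#' effect and the interaction against the subject x within residual, and
#' every effect has numerator df 1 and denominator df `N - 2`. Partial eta
#' squared is `SS_effect / (SS_effect + SS_error)` for each effect's own
#' error term.
#'
#' @param data Long tibble with one row per subject x within level.
#' @param dv Name of the value column (string).
#' @param within,between,subject Names of the within-factor, between-factor
#'   and subject-id columns. The within and between factors must each have
#'   exactly two levels; level order follows factor levels or sort order.
#' @return An object of class `mmn_anova`; `tidy()` gives the effect table
#'   (term, sumsq, df, df_error, statistic, p.value, pes), including the
#'   two error strata as rows with `NA` statistics.
#' @examples
#' d <- tidyr::expand_grid(subject_id = sprintf("s%d", 1:8),
#'                         condition = c("a", "b"))
#' d$gender <- rep(c("female", "male"), each = 8)
#' set.seed(1); d$value <- rnorm(16)
#' tidy(mixed_anova_2x2(d, "value"))
#' @export
mixed_anova_2x2 <- function(data, dv, within = "condition",
                            between = "gender", subject = "subject_id") {
  cols <- c(dv, within, between, subject)
  if (!all(cols %in% names(data))) {
    abort(sprintf("`data` must contain columns: %s.", paste(cols, collapse = ", ")))
  }
  df <- data.frame(
    y = data[[dv]],
    w = factor(data[[within]]),
    g = factor(data[[between]]),
    s = as.character(data[[subject]])
  )
  if (nlevels(df$w) != 2 || nlevels(df$g) != 2) {
    abort("Both factors must have exactly two levels.")
  }
  if (any(is.na(df$y))) abort("Missing values in the response.")
  counts <- table(df$s, df$w)
  bad <- rownames(counts)[rowSums(counts != 1) > 0]
  if (length(bad)) {
    abort(sprintf("Incomplete design: subject(s) %s lack exactly one value per within level.",
                  paste(bad, collapse = ", ")))
  }
  sub_gender <- tapply(as.character(df$g), df$s, unique)
  if (any(lengths(sub_gender) != 1)) {
    abort("Each subject must belong to exactly one between-factor level.")
  }

  wl <- levels(df$w)
  gl <- levels(df$g)
  x1 <- df$y[df$w == wl[1]][match(unique(df$s), df$s[df$w == wl[1]])]
  x2 <- df$y[df$w == wl[2]][match(unique(df$s), df$s[df$w == wl[2]])]
  gg <- factor(unlist(sub_gender[unique(df$s)]), levels = gl)
  n1 <- sum(gg == gl[1]); n2 <- sum(gg == gl[2])
  if (n1 < 2 || n2 < 2) abort("Each group needs at least 2 subjects.")
  N <- n1 + n2
  df_err <- N - 2L

  s_i <- (x1 + x2) / 2           # subject means
  d_i <- x2 - x1                 # within-level differences

  ss_s <- sum(tapply(s_i, gg, function(v) sum((v - mean(v))^2)))
  ss_d <- sum(tapply(d_i, gg, function(v) sum((v - mean(v))^2)))
  ss_err_b <- 2 * ss_s           # subjects within groups, original scale
  ss_err_w <- ss_d / 2           # subject x within residual

  if (ss_err_b == 0 && ss_err_w == 0 && var(df$y) == 0) {
    tab <- tibble::tibble(
      term = c(between, within, paste(between, within, sep = ":"),
               "error: subjects", "error: within"),
      sumsq = 0, df = c(1L, 1L, 1L, df_err, df_err),
      df_error = c(df_err, df_err, df_err, NA, NA),
      statistic = c(0, 0, 0, NA, NA),
      p.value = c(1, 1, 1, NA, NA),
      pes = c(0, 0, 0, NA, NA)
    )
    return(structure(list(table = tab, degenerate = TRUE,
                          n = setNames(c(n1, n2), gl), df_error = df_err),
                     class = "mmn_anova"))
  }

  sp2_s <- ss_s / df_err         # pooled variance of subject means
  sp2_d <- ss_d / df_err         # pooled variance of differences
  hmean <- 1 / n1 + 1 / n2

  sbar <- tapply(s_i, gg, mean)
  dbar <- tapply(d_i, gg, mean)

  f_between <- if (sp2_s > 0) (sbar[1] - sbar[2])^2 / (sp2_s * hmean) else 0
  f_within  <- if (sp2_d > 0) ((dbar[1] + dbar[2]) / 2)^2 / (sp2_d * hmean / 4) else 0
  f_inter   <- if (sp2_d > 0) (dbar[1] - dbar[2])^2 / (sp2_d * hmean) else 0

  ms_err_b <- ss_err_b / df_err
  ms_err_w <- ss_err_w / df_err
  Fv <- unname(c(f_between, f_within, f_inter))
  ss_eff <- Fv * c(ms_err_b, ms_err_w, ms_err_w)
  ss_err <- c(ss_err_b, ss_err_w, ss_err_w)

  tab <- tibble::tibble(
    term = c(between, within, paste(between, within, sep = ":"),
             "error: subjects", "error: within"),
    sumsq = c(ss_eff, ss_err_b, ss_err_w),
    df = c(1L, 1L, 1L, df_err, df_err),
    df_error = c(df_err, df_err, df_err, NA, NA),
    statistic = c(Fv, NA, NA),
    p.value = c(pf(Fv, 1, df_err, lower.tail = FALSE), NA, NA),
    pes = c(ss_eff / (ss_eff + ss_err), NA, NA)
  )
  structure(list(table = tab, degenerate = FALSE,
                 n = setNames(c(n1, n2), gl), df_error = df_err,
                 levels = list(within = wl, between = gl)),
            class = "mmn_anova")
}

#' @export
print.mmn_anova <- function(x, ...) {
  cat(sprintf("2 x 2 mixed ANOVA (n = %s; denominator df = %d)%s\n",
              paste(sprintf("%s %d", names(x$n), x$n), collapse = ", "),
              x$df_error,
              if (x$degenerate) " [degenerate: zero total variance]" else ""))
  print(as.data.frame(x$table), digits = 4, row.names = FALSE)
  invisible(x)
}

#' @export
tidy.mmn_anova <- function(x, ...) x$table

#' @export
glance.mmn_anova <- function(x, ...) {
  eff <- x$table[!is.na(x$table$statistic), ]
  tibble::tibble(
    n_subjects = sum(x$n),
    df_error = x$df_error,
    min_p = min(eff$p.value),
    degenerate = x$degenerate
  )
}

new_ttest <- function(t, df, p, d, kind, estimate) {
  structure(list(t = unname(t), df = unname(df), p = unname(p),
                 d = unname(d), kind = kind, estimate = unname(estimate)),
            class = "mmn_ttest")
}

#' Paired t-test with Cohen's d
#'
#' Classical paired t; Cohen's d is the mean difference divided by the SD
#' of the differences. The degenerate case of identical vectors returns
#' `t = 0, p = 1`; constant non-zero differences (infinite t) raise an
#' error.
#'
#' @param x,y Paired numeric vectors, matched by subject.
#' @return An `mmn_ttest` with elements `t`, `df`, `p`, `d`, `estimate`.
#' @export
paired_t <- function(x, y) {
  if (length(x) != length(y) || length(x) < 2) {
    abort("`x` and `y` must be equal-length vectors with n >= 2.")
  }
  delta <- x - y
  if (sd(delta) == 0) {
    if (mean(delta) == 0) {
      return(new_ttest(0, length(x) - 1L, 1, 0, "paired", 0))
    }
    abort("Differences have zero variance with non-zero mean (infinite t).")
  }
  ht <- stats::t.test(x, y, paired = TRUE)
  new_ttest(ht$statistic, ht$parameter, ht$p.value,
            mean(delta) / sd(delta), "paired", mean(delta))
}

#' Independent-samples t-test (pooled variance) with Cohen's d
#'
#' Student's t with pooled variance and df `n1 + n2 - 2`; Cohen's d is the
#' mean difference over the pooled SD. Agrees exactly with
#' [t_from_summary()] applied to the groups' own summary statistics.
#'
#' @param x,y Numeric vectors for the two groups (each n >= 2).
#' @return An `mmn_ttest`.
#' @export
independent_t <- function(x, y) {
  if (length(x) < 2 || length(y) < 2) abort("Each group needs n >= 2.")
  sp2 <- ((length(x) - 1) * var(x) + (length(y) - 1) * var(y)) /
    (length(x) + length(y) - 2)
  if (sp2 == 0) {
    if (mean(x) == mean(y)) {
      return(new_ttest(0, length(x) + length(y) - 2L, 1, 0, "independent", 0))
    }
    abort("Zero pooled variance with unequal means (infinite t).")
  }
  ht <- stats::t.test(x, y, var.equal = TRUE)
  new_ttest(ht$statistic, ht$parameter, ht$p.value,
            (mean(x) - mean(y)) / sqrt(sp2), "independent", mean(x) - mean(y))
}

#' t-test reconstructed from group summary statistics
#'
#' Rebuilds each group's SD as `sem * sqrt(n)` and computes the
#' pooled-variance Student t with `df = n1 + n2 - 2`, its two-sided p, and
#' Cohen's d as the absolute mean difference over the pooled SD. Agreement
#' with values printed from rounded summaries is limited by that rounding
#' (about +/-0.02 on d).
#'
#' @param mean1,sem1,n1 First group: mean, standard error of the mean, n.
#' @param mean2,sem2,n2 Second group.
#' @return An `mmn_ttest` (kind `"from_summary"`).
#' @examples
#' t_from_summary(173.55, 9.06, 14, 142.58, 6.76, 15)$t  # 2.76...
#' @export
t_from_summary <- function(mean1, sem1, n1, mean2, sem2, n2) {
  if (!is_count(n1) || !is_count(n2) || n1 < 2 || n2 < 2) {
    abort("Group sizes must be integers >= 2.")
  }
  if (sem1 < 0 || sem2 < 0) abort("SEMs must be >= 0.")
  if (sem1 == 0 && sem2 == 0) abort("Both SEMs are zero: t is undefined.")
  sd1 <- sem1 * sqrt(n1)
  sd2 <- sem2 * sqrt(n2)
  sp <- sqrt(((n1 - 1) * sd1^2 + (n2 - 1) * sd2^2) / (n1 + n2 - 2))
  df <- n1 + n2 - 2
  tt <- (mean1 - mean2) / (sp * sqrt(1 / n1 + 1 / n2))
  p <- 2 * pt(abs(tt), df, lower.tail = FALSE)
  new_ttest(tt, df, p, abs(mean1 - mean2) / sp, "from_summary", mean1 - mean2)
}

#' @export
print.mmn_ttest <- function(x, ...) {
  cat(sprintf("%s t-test: t(%g) = %.3f, p = %.4g, d = %.3f\n",
              x$kind, x$df, x$t, x$p, x$d))
  invisible(x)
}

#' @export
tidy.mmn_ttest <- function(x, ...) {
  tibble::tibble(kind = x$kind, estimate = x$estimate, statistic = x$t,
                 df = x$df, p.value = x$p, cohens_d = x$d)
}

#' @export
glance.mmn_ttest <- function(x, ...) tidy(x)
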