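#' Select extreme-low and control groups from a phenotype table
#'
#' Ranks samples by the trait (TG by default) and takes the `n_extreme`
#' lowest samples at or below `tg_threshold` as the extreme group. The control
#' group is drawn from the stratum above the threshold; with `matching = TRUE`
#' a greedy sex-stratified nearest-age matcher balances the control group's
#' sex counts and mean age against the extreme group.
#'
#' @param phenotypes Phenotype data.frame with columns `sample_id`, `sex`,
#'   `age` and the trait column.
#' @param tg_threshold Trait threshold (mmol/L for TG) defining the extreme
#'   stratum (values at or below it are eligible).
#' @param n_extreme,n_control Group sizes to select.
#' @param matching Match control selection on sex and age (greedy).
#' @param trait Name of the trait column used for ranking.
#' @return Object of class `cohort_design`: list with `tg_threshold`,
#'   `extreme_ids`, `control_ids`, `matching`, `trait`.
#' @export
select_extremes <- function(phenotypes, tg_threshold = 0.45,
                            n_extreme, n_control, matching = TRUE,
                            trait = "tg") {
  stopifnot(is.data.frame(phenotypes),
            all(c("sample_id", trait) %in% names(phenotypes)))
  x <- phenotypes[[trait]]
  low <- phenotypes[!is.na(x) & x <= tg_threshold, , drop = FALSE]
  if (nrow(low) < n_extreme)
    stop("only ", nrow(low), " samples at or below threshold ", tg_threshold,
         "; ", n_extreme, " requested (shortfall ", n_extreme - nrow(low), ")")
  low <- low[order(low[[trait]], low$sample_id), , drop = FALSE]
  extreme <- low[seq_len(n_extreme), , drop = FALSE]
  pool <- phenotypes[!is.na(x) & x > tg_threshold, , drop = FALSE]
  if (nrow(pool) < n_control)
    stop("only ", nrow(pool), " samples above threshold ", tg_threshold,
         "; ", n_control, " requested (shortfall ", n_control - nrow(pool), ")")
  if (matching && all(c("sex", "age") %in% names(phenotypes))) {
    target_male <- round(n_control * mean(extreme$sex == "male"))
    mean_age <- mean(extreme$age)
    pick_stratum <- function(stratum, k) {
      stratum <- stratum[order(abs(stratum$age - mean_age),
                               stratum$sample_id), , drop = FALSE]
      stratum[seq_len(min(k, nrow(stratum))), , drop = FALSE]
    }
    males <- pick_stratum(pool[pool$sex == "male", , drop = FALSE], target_male)
    females <- pick_stratum(pool[pool$sex == "female", , drop = FALSE],
                            n_control - nrow(males))
    control <- rbind(males, females)
    if (nrow(control) < n_control) {
      # one stratum exhausted: top up greedily from the remainder by age
      rest <- pool[!pool$sample_id %in% control$sample_id, , drop = FALSE]
      control <- rbind(control,
                       pick_stratum(rest, n_control - nrow(control)))
    }
  } else {
    control <- pool[order(pool$sample_id), , drop = FALSE][seq_len(n_control), ]
  }
  structure(list(tg_threshold = tg_threshold,
                 extreme_ids = extreme$sample_id,
                 control_ids = control$sample_id,
                 matching = matching, trait = trait),
            class = "cohort_design")
}

#' @export
print.cohort_design <- function(x, ...) {
  cat("cohort_design:", length(x$extreme_ids), "extreme /",
      length(x$control_ids), "control samples;", x$trait, "<=",
      x$tg_threshold, "\n")
  invisible(x)
}

summary_mean_sd <- function(x)
  sprintf("%.2f (%.2f)", mean(x), stats::sd(x))
summary_median_iqr <- function(x)
  sprintf("%.2f (%.2f)", stats::median(x), stats::IQR(x))

# Shapiro-Wilk normality gate; Kolmogorov-Smirnov available by flag.
# Zero-variance or out-of-range n counts as non-normal.
is_normalish <- function(x, alpha = 0.05, method = c("shapiro", "ks")) {
  method <- match.arg(method)
  if (length(x) < 3 || stats::sd(x) == 0) return(FALSE)
  p <- if (method == "shapiro") {
    if (length(x) > 5000) x <- sample(x, 5000)
    stats::shapiro.test(x)$p.value
  } else {
    suppressWarnings(stats::ks.test(scale(x), "pnorm")$p.value)
  }
  p > alpha
}

#' Baseline comparison table for a two-group design
#'
#' For each quantitative trait, normality is assessed per group (Shapiro-Wilk
#' by default); when both groups pass, groups are summarized as mean (SD) and
#' compared by a two-sample pooled-variance t-test (Welch by flag), otherwise
#' as median (IQR) with a Mann-Whitney rank-sum test. Sex is compared by a
#' chi-square test on the 2x2 table. The pooled column is computed over the
#' union of the two groups.
#'
#' @param phenotypes Phenotype data.frame.
#' @param design A [select_extremes()] design.
#' @param traits Character vector of trait columns; defaults to every numeric
#'   column except `sample_id`.
#' @param normality_alpha Per-group significance level of the normality gate.
#' @param normality_method `"shapiro"` (default) or `"ks"`.
#' @param welch Use the Welch t-test instead of pooled variance.
#' @return Data frame with one row per trait: group summaries, pooled summary,
#'   the test used and its p-value. Traits with zero variance in both groups
#'   get p = 1 with a warning.
#' @export
baseline_table <- function(phenotypes, design, traits = NULL,
                           normality_alpha = 0.05,
                           normality_method = "shapiro", welch = FALSE) {
  stopifnot(inherits(design, "cohort_design"))
  rownames(phenotypes) <- phenotypes$sample_id
  e <- phenotypes[design$extreme_ids, , drop = FALSE]
  c_ <- phenotypes[design$control_ids, , drop = FALSE]
  if (nrow(e) == 0 || nrow(c_) == 0) stop("both groups must be non-empty")
  if (is.null(traits)) {
    num <- vapply(phenotypes, is.numeric, logical(1))
    traits <- setdiff(names(phenotypes)[num], "sample_id")
  }
  rows <- lapply(traits, function(tr) {
    xe <- e[[tr]]; xc <- c_[[tr]]
    pooled <- c(xe, xc)
    if (stats::sd(xe) == 0 && stats::sd(xc) == 0) {
      warning("trait ", tr, " has zero variance in both groups; p set to 1")
      return(data.frame(trait = tr, extreme = summary_mean_sd(xe),
                        control = summary_mean_sd(xc),
                        pooled = summary_mean_sd(pooled),
                        test = "t", p = 1, stringsAsFactors = FALSE))
    }
    normal <- is_normalish(xe, normality_alpha, normality_method) &&
      is_normalish(xc, normality_alpha, normality_method)
    if (normal) {
      p <- stats::t.test(xe, xc, var.equal = !welch)$p.value
      data.frame(trait = tr, extreme = summary_mean_sd(xe),
                 control = summary_mean_sd(xc),
                 pooled = summary_mean_sd(pooled), test = "t", p = p,
                 stringsAsFactors = FALSE)
    } else {
      p <- suppressWarnings(stats::wilcox.test(xe, xc)$p.value)
      data.frame(trait = tr, extreme = summary_median_iqr(xe),
                 control = summary_median_iqr(xc),
                 pooled = summary_median_iqr(pooled), test = "rank-sum", p = p,
                 stringsAsFactors = FALSE)
    }
  })
  out <- do.call(rbind, rows)
  if ("sex" %in% names(phenotypes)) {
    tab <- rbind(table(factor(e$sex, c("male", "female"))),
                 table(factor(c_$sex, c("male", "female"))))
    p <- if (any(suppressWarnings(stats::chisq.test(tab))$expected < 1)) {
      stats::fisher.test(tab)$p.value
    } else {
      suppressWarnings(stats::chisq.test(tab)$p.value)
    }
    fmt <- function(tb, n) sprintf("%d (%.1f)", tb[1], 100 * tb[1] / n)
    out <- rbind(data.frame(
      trait = "sex (male, %)", extreme = fmt(tab[1, ], nrow(e)),
      control = fmt(tab[2, ], nrow(c_)),
      pooled = fmt(tab[1, ] + tab[2, ], nrow(e) + nrow(c_)),
      test = "chi-square", p = p, stringsAsFactors = FALSE), out)
  }
  rownames(out) <- NULL
  out
}

#' Size-weighted pooled mean
#'
#' Combines per-group means into the pooled ("totality") column of a report
#' table, weighting each mean by its group size and rounding to the reporting
#' precision (round-half-even).
#'
#' @param group_means List of `c(mean, n)` pairs, or a two-column
#'   matrix/data.frame (mean, n).
#' @param digits Reporting precision; `NULL` for the unrounded value.
#' @return The pooled mean.
#' @export
#' @examples
#' pooled_mean(list(c(1.28, 102), c(1.56, 111)))  # 1.43
pooled_mean <- function(group_means, digits = 2) {
  if (is.list(group_means)) group_means <- do.call(rbind, group_means)
  if (is.null(group_means) || length(group_means) == 0)
    stop("no group summaries supplied")
  group_means <- as.matrix(group_means)
  if (any(group_means[, 2] <= 0)) stop("group sizes must be positive")
  m <- sum(group_means[, 1] * group_means[, 2]) / sum(group_means[, 2])
  if (is.null(digits)) m else round(m, digits)
}

#' Cohen's d from group summary statistics
#'
#' Standardized mean difference `|m1 - m2| / s_p` with the pooled SD
#' `s_p = sqrt(((n1-1) s1^2 + (n2-1) s2^2) / (n1 + n2 - 2))`.
#'
#' @param mean1,sd1,n1 First group summary.
#' @param mean2,sd2,n2 Second group summary.
#' @return Effect size (unitless, non-negative).
#' @export
cohens_d <- function(mean1, sd1, n1, mean2, sd2, n2) {
  stopifnot(sd1 >= 0, sd2 >= 0, n1 >= 2, n2 >= 2)
  if (sd1 == 0 && sd2 == 0)
    stop("Cohen's d undefined: both group SDs are zero")
  sp <- sqrt(((n1 - 1) * sd1^2 + (n2 - 1) * sd2^2) / (n1 + n2 - 2))
  abs(mean1 - mean2) / sp
}

#' Power of the two-sided two-sample t-test
#'
#' Analytic power via the noncentral t distribution with noncentrality
#' `d * sqrt(n1 n2 / (n1 + n2))` and `n1 + n2 - 2` degrees of freedom.
#'
#' @param d Cohen's d (>= 0).
#' @param n1,n2 Group sizes.
#' @param alpha Two-sided significance level, in (0, 1).
#' @return Power (probability of rejecting at level `alpha`); equals `alpha`
#'   at d = 0.
#' @export
#' @examples
#' ttest_power(0.65, 111, 102)  # > 0.90
ttest_power <- function(d, n1, n2, alpha = 0.05) {
  stopifnot(d >= 0, n1 >= 2, n2 >= 2)
  if (alpha <= 0 || alpha >= 1) stop("alpha must lie in (0, 1)")
  df <- n1 + n2 - 2
  ncp <- d * sqrt(n1 * n2 / (n1 + n2))
  tc <- stats::qt(1 - alpha / 2, df)
  stats::pt(tc, df, ncp = ncp, lower.tail = FALSE) +
    stats::pt(-tc, df, ncp = ncp)
}
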