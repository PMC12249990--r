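# Clinical/functional/radiological endpoint derivation and descriptive
# group-comparison statistics.

LLN_Z <- -1.645
ULN_Z <- 1.645

#' Derive binary endpoints from lung-function z-scores
#'
#' Obstruction is flagged when the FEV1/FVC z-score (and, as a separate
#' endpoint, the FEV1 z-score) falls below the lower limit of normal
#' (z < -1.645); air trapping when RV (resp. RV/TLC) exceeds the upper
#' limit of normal (z > +1.645); gas-exchange impairment when DLCO falls
#' below the LLN. Quantitative endpoints are passed through.
#'
#' @param endpoints Data frame with columns `fev1_z`, `fvc_z`,
#'   `fev1_fvc_z`, `rv_z`, `rv_tlc_z`, `dlco_z` (e.g. from
#'   [generate_cohort()]).
#' @return The input with added logical columns `obstruction_fev1_fvc`,
#'   `obstruction_fev1`, `air_trapping_rv`, `air_trapping_rv_tlc`,
#'   `gas_exchange_impairment`.
#' @export
derive_endpoints <- function(endpoints) {
  required <- c("fev1_z", "fvc_z", "fev1_fvc_z", "rv_z", "rv_tlc_z",
                "dlco_z")
  missing_cols <- setdiff(required, names(endpoints))
  if (length(missing_cols)) {
    stop("missing required column(s): ",
         paste(missing_cols, collapse = ", "), call. = FALSE)
  }
  endpoints$obstruction_fev1_fvc <- endpoints$fev1_fvc_z < LLN_Z
  endpoints$obstruction_fev1 <- endpoints$fev1_z < LLN_Z
  endpoints$air_trapping_rv <- endpoints$rv_z > ULN_Z
  endpoints$air_trapping_rv_tlc <- endpoints$rv_tlc_z > ULN_Z
  endpoints$gas_exchange_impairment <- endpoints$dlco_z < LLN_Z
  endpoints
}

#' Compare a variable between groups with automatic test selection
#'
#' Quantitative variables: when every group looks Gaussian by the
#' Shapiro-Wilk test (p >= `shapiro_alpha` in each group), Welch's t-test
#' (two groups) or one-way ANOVA (more); otherwise the Mann-Whitney U-test
#' or the Kruskal-Wallis test. Categorical variables: Pearson's chi-square,
#' or Fisher's exact test when any expected cell count falls below 5. The
#' chosen test is always reported so the decision is auditable.
#'
#' @param values Vector of observations (numeric for `"quantitative"`).
#' @param groups Group labels (coerced to factor).
#' @param kind `"quantitative"` or `"categorical"`.
#' @param shapiro_alpha Normality-gate level per group.
#' @return A `group_comparison` list with `variable_kind`, `test`,
#'   `statistic`, `p_value`, and per-group summaries.
#' @export
compare_groups <- function(values, groups,
                           kind = c("quantitative", "categorical"),
                           shapiro_alpha = 0.05) {
  kind <- match.arg(kind)
  groups <- droplevels(factor(groups))
  ok <- !is.na(values) & !is.na(groups)
  values <- values[ok]; groups <- droplevels(groups[ok])
  k <- nlevels(groups)
  if (k < 2L) stop("need at least two groups", call. = FALSE)

  if (kind == "quantitative") {
    split_vals <- split(values, groups)
    if (any(vapply(split_vals, function(v) length(v) < 2L, logical(1)))) {
      stop("need >= 2 observations per group", call. = FALSE)
    }
    summaries <- lapply(split_vals, function(v) {
      c(n = length(v), mean = mean(v), sd = stats::sd(v),
        median = stats::median(v))
    })
    constant <- vapply(split_vals, function(v) stats::sd(v) == 0, logical(1))
    if (all(constant) && length(unique(values)) == 1L) {
      return(structure(list(variable_kind = kind, test = "none",
                            statistic = NA_real_, p_value = NA_real_,
                            group_summaries = summaries,
                            note = "degenerate: constant in all groups"),
                       class = "group_comparison"))
    }
    normal <- vapply(split_vals, function(v) {
      if (length(v) < 3L || stats::sd(v) == 0) return(FALSE)
      stats::shapiro.test(v)$p.value >= shapiro_alpha
    }, logical(1))
    if (all(normal)) {
      if (k == 2L) {
        tt <- stats::t.test(values ~ groups)  # Welch by default
        res <- list(test = "Welch t", statistic = unname(tt$statistic),
                    p_value = tt$p.value)
      } else {
        av <- stats::oneway.test(values ~ groups, var.equal = FALSE)
        res <- list(test = "ANOVA", statistic = unname(av$statistic),
                    p_value = av$p.value)
      }
    } else {
      if (k == 2L) {
        wt <- suppressWarnings(stats::wilcox.test(values ~ groups))
        res <- list(test = "Mann-Whitney U",
                    statistic = unname(wt$statistic), p_value = wt$p.value)
      } else {
        kw <- stats::kruskal.test(values, groups)
        res <- list(test = "Kruskal-Wallis",
                    statistic = unname(kw$statistic), p_value = kw$p.value)
      }
    }
  } else {
    tab <- table(values, groups)
    summaries <- as.data.frame.matrix(tab)
    if (nrow(tab) < 2L) {
      return(structure(list(variable_kind = kind, test = "none",
                            statistic = NA_real_, p_value = NA_real_,
                            group_summaries = summaries,
                            note = "degenerate: single level"),
                       class = "group_comparison"))
    }
    expected <- suppressWarnings(stats::chisq.test(tab)$expected)
    if (any(expected < 5)) {
      ft <- stats::fisher.test(tab)
      res <- list(test = "Fisher exact", statistic = NA_real_,
                  p_value = ft$p.value)
    } else {
      ct <- stats::chisq.test(tab, correct = FALSE)
      res <- list(test = "chi-square", statistic = unname(ct$statistic),
                  p_value = ct$p.value)
    }
  }
  structure(c(list(variable_kind = kind), res,
              list(group_summaries = summaries)),
            class = "group_comparison")
}

#' @export
print.group_comparison <- function(x, ...) {
  cat(sprintf("<group_comparison> %s: %s, statistic %.4g, p = %.4g\n",
              x$variable_kind, x$test, x$statistic, x$p_value))
  invisible(x)
}
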