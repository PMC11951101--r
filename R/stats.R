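# Group-comparison tests and proportion-vs-disease-severity association.

#' Compare donor-level values between groups
#'
#' A thin, uniform front end over the standard tests used for cohort
#' figures: Welch two-tailed t, paired t (pairs matched by donor), the
#' Mann-Whitney rank test, and one-way fixed-effects ANOVA with Tukey's
#' honestly-significant-difference multiple comparisons. All p values are
#' two-sided. Degenerate zero-variance inputs with equal group means return
#' statistic 0 and p 1 rather than an error.
#'
#' @param values numeric vector of (typically per-donor) values.
#' @param group_labels group label per value.
#' @param test one of `"t_two_tailed"`, `"paired_t"`, `"mann_whitney"`,
#'   `"anova_tukey"`.
#' @param pair_ids donor/pair key per value, required for `paired_t`;
#'   unmatched pairs are an error listing the offending ids.
#' @return object of class `group_comparison`: `test`, `statistic`,
#'   `p_value`, `estimate` (group means), `pairwise` (Tukey table or NULL),
#'   `n` per group.
#' @export
compare_groups <- function(values,
                           group_labels,
                           test = c("t_two_tailed", "paired_t",
                                    "mann_whitney", "anova_tukey"),
                           pair_ids = NULL) {
  test <- match.arg(test)
  keep <- !is.na(values) & !is.na(group_labels)
  values <- values[keep]
  group_labels <- as.character(group_labels)[keep]
  if (!is.null(pair_ids)) pair_ids <- as.character(pair_ids)[keep]
  groups <- sort(unique(group_labels))
  if (length(groups) < 2) stop("need at least 2 groups")
  est <- vapply(groups, function(g) mean(values[group_labels == g]),
                numeric(1))
  ns <- vapply(groups, function(g) sum(group_labels == g), numeric(1))
  pairwise <- NULL

  if (test %in% c("t_two_tailed", "mann_whitney", "paired_t") &&
      length(groups) != 2) {
    stop(test, " requires exactly 2 groups (got ", length(groups), ")")
  }

  if (test == "t_two_tailed") {
    x <- values[group_labels == groups[1]]
    y <- values[group_labels == groups[2]]
    if (sd(x) == 0 && sd(y) == 0 && mean(x) == mean(y)) {
      statistic <- 0; p <- 1
    } else {
      tt <- t.test(x, y, var.equal = FALSE)
      statistic <- unname(tt$statistic); p <- tt$p.value
    }
  } else if (test == "paired_t") {
    if (is.null(pair_ids)) stop("paired_t requires pair_ids")
    x_ids <- pair_ids[group_labels == groups[1]]
    y_ids <- pair_ids[group_labels == groups[2]]
    unmatched <- c(setdiff(x_ids, y_ids), setdiff(y_ids, x_ids))
    if (length(unmatched) > 0 || anyDuplicated(x_ids) || anyDuplicated(y_ids)) {
      stop("pairing error: unmatched or duplicated pair ids: ",
           paste(unique(c(unmatched, x_ids[duplicated(x_ids)],
                          y_ids[duplicated(y_ids)])), collapse = ", "))
    }
    x <- values[group_labels == groups[1]][order(x_ids)]
    y <- values[group_labels == groups[2]][order(y_ids)]
    d <- x - y
    if (sd(d) == 0 && mean(d) == 0) {
      statistic <- 0; p <- 1
    } else {
      tt <- t.test(x, y, paired = TRUE)
      statistic <- unname(tt$statistic); p <- tt$p.value
    }
  } else if (test == "mann_whitney") {
    x <- values[group_labels == groups[1]]
    y <- values[group_labels == groups[2]]
    wt <- suppressWarnings(wilcox.test(x, y, exact = FALSE))
    statistic <- unname(wt$statistic); p <- wt$p.value
  } else { # anova_tukey
    df <- data.frame(y = values, g = factor(group_labels))
    if (sd(values) == 0) {
      statistic <- 0; p <- 1
      cmb <- utils::combn(groups, 2)
      pairwise <- data.frame(comparison = paste(cmb[2, ], cmb[1, ],
                                                sep = "-"),
                             diff = 0, p_adj = 1, stringsAsFactors = FALSE)
    } else {
      fit <- aov(y ~ g, data = df)
      an <- summary(fit)[[1]]
      statistic <- an[["F value"]][1]
      p <- an[["Pr(>F)"]][1]
      tk <- TukeyHSD(fit)$g
      pairwise <- data.frame(comparison = rownames(tk),
                             diff = unname(tk[, "diff"]),
                             p_adj = unname(tk[, "p adj"]),
                             stringsAsFactors = FALSE)
    }
  }

  structure(list(test = test, statistic = statistic, p_value = p,
                 estimate = est, n = ns, pairwise = pairwise),
            class = "group_comparison")
}

#' @export
print.group_comparison <- function(x, ...) {
  cat("Group comparison (", x$test, ")\n", sep = "")
  cat("  group means: ",
      paste(sprintf("%s=%.4g (n=%d)", names(x$estimate), x$estimate, x$n),
            collapse = ", "), "\n", sep = "")
  cat(sprintf("  statistic = %.4g, p = %.4g\n", x$statistic, x$p_value))
  if (!is.null(x$pairwise)) {
    cat("  Tukey-adjusted pairwise comparisons:\n")
    print(x$pairwise, row.names = FALSE)
  }
  invisible(x)
}

#' Correlate per-donor proportions with disease-severity scores
#'
#' Pearson correlation (two-sided test) between a donor-level cell-subset
#' proportion and a disease-severity score (e.g. SES-CD), with the
#' least-squares line for regression bands.
#'
#' @param proportions numeric per-donor values.
#' @param scores numeric per-donor disease scores, same order/length.
#' @return object of class `association_result`: `n`, `pearson_r`,
#'   `p_value`, `slope`, `intercept`.
#' @export
correlate_with_disease <- function(proportions, scores) {
  keep <- !is.na(proportions) & !is.na(scores)
  x <- proportions[keep]
  y <- scores[keep]
  if (length(x) < 3) {
    stop("insufficient data: need >= 3 donors with both values (got ",
         length(x), ")")
  }
  if (sd(x) == 0 || sd(y) == 0) {
    stop("undefined correlation: zero variance in ",
         if (sd(x) == 0) "proportions" else "scores")
  }
  ct <- cor.test(x, y, method = "pearson")
  slope <- cov(x, y) / var(x)
  structure(list(n = length(x),
                 pearson_r = unname(ct$estimate),
                 p_value = ct$p.value,
                 slope = slope,
                 intercept = mean(y) - slope * mean(x)),
            class = "association_result")
}

#' Correlate many compartment proportions with disease scores
#'
#' Runs [correlate_with_disease()] for each compartment of a long
#' proportions table against per-donor disease scores (the dot-plot
#' workflow: one association per cell subset and tissue). Raw Pearson p
#' values are reported by default; `adjust = "bh"` adds
#' Benjamini-Hochberg-adjusted values across the tested compartments.
#'
#' @param proportions data.frame with `donor_id`, `proportion` and the
#'   compartment columns named in `by`.
#' @param scores data.frame with `donor_id` and `disease_score`.
#' @param by compartment-defining columns (default `"compartment"`).
#' @param adjust `"none"` (default) or `"bh"`.
#' @return data.frame: `by` columns, `n`, `pearson_r`, `p_value`, `slope`,
#'   `intercept` and (with adjustment) `p_adjusted`; compartments that are
#'   not estimable (too few donors, zero variance) are returned with `NA`
#'   and the reason.
#' @export
correlate_compartments <- function(proportions, scores, by = "compartment",
                                   adjust = c("none", "bh")) {
  adjust <- match.arg(adjust)
  stopifnot(all(c("donor_id", "proportion") %in% names(proportions)),
            all(by %in% names(proportions)),
            all(c("donor_id", "disease_score") %in% names(scores)))
  key <- group_key(proportions, by)
  keys <- sort(unique(key))
  rows <- lapply(keys, function(k) {
    sub <- proportions[key == k, , drop = FALSE]
    m <- merge(sub, scores[, c("donor_id", "disease_score")], by = "donor_id")
    res <- tryCatch(correlate_with_disease(m$proportion, m$disease_score),
                    error = function(e) conditionMessage(e))
    base <- sub[1, by, drop = FALSE]
    if (is.character(res)) {
      cbind(base, data.frame(n = nrow(m), pearson_r = NA_real_,
                             p_value = NA_real_, slope = NA_real_,
                             intercept = NA_real_, reason = res,
                             stringsAsFactors = FALSE))
    } else {
      cbind(base, data.frame(n = res$n, pearson_r = res$pearson_r,
                             p_value = res$p_value, slope = res$slope,
                             intercept = res$intercept,
                             reason = NA_character_,
                             stringsAsFactors = FALSE))
    }
  })
  out <- do.call(rbind, rows)
  rownames(out) <- NULL
  if (adjust == "bh") out$p_adjusted <- stats::p.adjust(out$p_value, "BH")
  out
}

#' @export
print.association_result <- function(x, ...) {
  cat(sprintf(
    "Pearson association (n = %d donors): r = %.3f, p = %.4g\n",
    x$n, x$pearson_r, x$p_value))
  cat(sprintf("  least-squares line: y = %.3f + %.3f x\n",
              x$intercept, x$slope))
  invisible(x)
}
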