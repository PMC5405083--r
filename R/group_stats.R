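#' Assign IQ groups from scores
#'
#' Applies the interval rule: scores in `removal_scores` are excluded,
#' scores inside `low_interval` are "low", inside `high_interval` are
#' "high", anything else is "mid". Defaults are the printed study
#' intervals: low \[4, 10\] (median minus one quartile), high \[22, 24\]
#' (median plus one quartile up to the maximum score), with the two
#' score-3 subjects removed.
#'
#' @param records data.frame with an `iq_score` column.
#' @param low_interval,high_interval inclusive `[lo, hi]` bounds; must be
#'   disjoint with low below high.
#' @param removal_scores scores removed from analysis entirely.
#' @return `records` with a `group` column set; group counts attached as
#'   the `"counts"` attribute.
#' @export
form_iq_groups <- function(records, low_interval = c(4, 10),
                           high_interval = c(22, 24), removal_scores = 3) {
  stopifnot(length(low_interval) == 2L, length(high_interval) == 2L,
            low_interval[1] <= low_interval[2],
            high_interval[1] <= high_interval[2])
  if (low_interval[2] >= high_interval[1])
    stop("intervals must be disjoint with the low interval below the high one")
  if (nrow(records) == 0L) {
    records$group <- character(0)
    attr(records, "counts") <- table(factor(character(0),
                                            levels = c("low", "mid", "high", "excluded")))
    return(records)
  }
  s <- records$iq_score
  group <- rep("mid", length(s))
  group[s >= low_interval[1] & s <= low_interval[2]] <- "low"
  group[s >= high_interval[1] & s <= high_interval[2]] <- "high"
  group[s %in% removal_scores] <- "excluded"
  records$group <- group
  attr(records, "counts") <- table(factor(group, levels = c("low", "mid", "high", "excluded")))
  records
}

#' Shifted natural-log transform
#'
#' `x -> log(x + constant)` elementwise, with the tiny constant (1e-24)
#' guarding exact zeros; used to pull right-skewed nonnegative metric
#' distributions toward normality before ANOVA.
#'
#' @param values numeric vector.
#' @param constant additive constant (default 1e-24).
#' @return Transformed vector.
#' @export
log_transform <- function(values, constant = 1e-24) {
  if (any(values <= -constant, na.rm = TRUE))
    stop("log_transform requires values > -", format(constant))
  log(values + constant)
}

#' One-way unbalanced ANOVA for two groups
#'
#' Classic fixed-effects one-way ANOVA (pooled within-group variance) on
#' two groups of unequal size: F = MS_between / MS_within on
#' (1, n_a + n_b - 2) degrees of freedom. Degenerate inputs with zero
#' within-group variance yield F = 0, p = 1 when the means agree and
#' F = Inf, p = 0 (flagged) when they differ.
#'
#' @param group_a,group_b numeric vectors, each of length >= 2.
#' @return List with `F`, `p`, `df`, and `degenerate`.
#' @export
one_way_anova <- function(group_a, group_b) {
  a <- group_a[!is.na(group_a)]
  b <- group_b[!is.na(group_b)]
  if (length(a) < 2L || length(b) < 2L)
    stop("each group needs at least 2 observations")
  df <- c(1L, length(a) + length(b) - 2L)
  ssw <- sum((a - mean(a))^2) + sum((b - mean(b))^2)
  if (ssw == 0) {
    if (mean(a) == mean(b))
      return(list(F = 0, p = 1, df = df, degenerate = TRUE))
    return(list(F = Inf, p = 0, df = df, degenerate = TRUE))
  }
  vals <- c(a, b)
  g <- factor(rep(c("a", "b"), c(length(a), length(b))))
  fit <- stats::oneway.test(vals ~ g, var.equal = TRUE)
  list(F = unname(fit$statistic), p = fit$p.value, df = df,
       degenerate = FALSE)
}

#' Benjamini-Hochberg FDR correction
#'
#' Step-up adjusted p-values (`stats::p.adjust(method = "BH")`) and the
#' rejection set at level `alpha`.
#'
#' @param p_values vector of raw p-values in \[0, 1\].
#' @param alpha significance level (default 0.05).
#' @return List with `adjusted` and logical `reject`.
#' @export
fdr_bh <- function(p_values, alpha = 0.05) {
  if (length(p_values) == 0L)
    return(list(adjusted = numeric(0), reject = logical(0)))
  if (any(p_values < 0 | p_values > 1, na.rm = TRUE))
    stop("p-values must lie in [0, 1]")
  adjusted <- stats::p.adjust(p_values, method = "BH")
  list(adjusted = adjusted, reject = !is.na(adjusted) & adjusted <= alpha)
}

#' Default group/gender contrast design
#'
#' The five standard two-population contrasts: low vs high IQ overall,
#' low vs high within each gender, and male vs female within each IQ
#' group.
#'
#' @return List of contrasts, each `list(label, a, b)` where `a`/`b` are
#'   named filters on the metadata columns.
#' @export
default_contrasts <- function() {
  list(
    list(label = "low_vs_high",
         a = list(group = "low"), b = list(group = "high")),
    list(label = "males_low_vs_high",
         a = list(group = "low", gender = "male"),
         b = list(group = "high", gender = "male")),
    list(label = "females_low_vs_high",
         a = list(group = "low", gender = "female"),
         b = list(group = "high", gender = "female")),
    list(label = "low_males_vs_females",
         a = list(group = "low", gender = "male"),
         b = list(group = "low", gender = "female")),
    list(label = "high_males_vs_females",
         a = list(group = "high", gender = "male"),
         b = list(group = "high", gender = "female"))
  )
}

.filter_rows <- function(table, filter) {
  keep <- rep(TRUE, nrow(table))
  for (nm in names(filter)) keep <- keep & table[[nm]] == filter[[nm]]
  which(keep)
}

#' Run the group-comparison design over a metric panel
#'
#' For every contrast and metric: natural-log transform (with the 1e-24
#' constant; metrics named in `shift`, by default the degree correlation
#' `r_deg` which lives in (-1, 1\], are shifted first so the log is
#' defined), one-way unbalanced ANOVA on the transformed values, then
#' Benjamini-Hochberg correction across the metric family within the
#' contrast. Group means and SDs are reported on the original
#' (pre-transform) scale. Metrics that cannot be tested in a contrast
#' (fewer than 2 finite values per group, or zero pooled variance) are
#' skipped with a message.
#'
#' @param table data.frame with one row per subject: metadata columns
#'   (at least those referenced by the contrast filters) plus numeric
#'   metric columns.
#' @param metrics character vector of metric column names; defaults to all
#'   numeric columns not named `subject_id`/`iq_score`/`mrt`.
#' @param contrasts contrast list as from [default_contrasts()]; contrasts
#'   whose populations are empty raise an error unless `drop_empty = TRUE`.
#' @param alpha FDR level (default 0.05).
#' @param transform apply the log transform before testing (default TRUE).
#' @param shift named vector of pre-transform additive shifts.
#' @param drop_empty silently drop contrasts with an empty population.
#' @return data.frame of class `comparison_result`: one row per contrast x
#'   metric with columns `contrast`, `metric`, `n_a`, `n_b`, `mean_a`,
#'   `sd_a`, `mean_b`, `sd_b`, `F`, `p`, `p_fdr`, `significant`.
#' @export
run_contrasts <- function(table, metrics = NULL, contrasts = default_contrasts(),
                          alpha = 0.05, transform = TRUE,
                          shift = c(r_deg = 1), drop_empty = FALSE) {
  if (is.null(metrics)) {
    num <- vapply(table, is.numeric, TRUE)
    metrics <- setdiff(names(table)[num], c("subject_id", "iq_score", "mrt"))
  }
  out <- list()
  for (ct in contrasts) {
    ia <- .filter_rows(table, ct$a)
    ib <- .filter_rows(table, ct$b)
    if (!length(ia) || !length(ib)) {
      if (drop_empty) next
      stop("contrast '", ct$label, "' has an empty population")
    }
    rows <- list()
    for (met in metrics) {
      xa <- table[[met]][ia]
      xb <- table[[met]][ib]
      xa <- xa[is.finite(xa)]; xb <- xb[is.finite(xb)]
      if (length(xa) < 2L || length(xb) < 2L) {
        message("skipping metric '", met, "' in contrast '", ct$label,
                "': too few finite values")
        next
      }
      ta <- xa; tb <- xb
      if (transform) {
        off <- if (met %in% names(shift)) shift[[met]] else 0
        ta <- log_transform(xa + off)
        tb <- log_transform(xb + off)
      }
      if (stats::var(c(ta, tb)) == 0) {
        message("skipping metric '", met, "' in contrast '", ct$label,
                "': zero variance")
        next
      }
      an <- one_way_anova(ta, tb)
      rows[[met]] <- data.frame(
        contrast = ct$label, metric = met,
        n_a = length(xa), n_b = length(xb),
        mean_a = mean(xa), sd_a = stats::sd(xa),
        mean_b = mean(xb), sd_b = stats::sd(xb),
        F = an$F, p = an$p, stringsAsFactors = FALSE)
    }
    if (!length(rows)) next
    res <- do.call(rbind, rows)
    bh <- fdr_bh(res$p, alpha = alpha)
    res$p_fdr <- bh$adjusted
    res$significant <- bh$reject
    out[[ct$label]] <- res
  }
  res <- do.call(rbind, out)
  rownames(res) <- NULL
  class(res) <- c("comparison_result", "data.frame")
  res
}
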