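# Statistics module: cutoff classification of single cells, per-specimen
# summaries, and the linear mixed-effects group analysis
# (cell Fpol ~ group fixed effect + specimen random intercept, REML),
# with least-squares means, Wald standard errors, and pairwise contrasts.

#' Classify cells against the malignancy cutoff
#'
#' A cell is flagged malignant-like iff its Fpol (display scale) is
#' strictly greater than the cutoff; cells at or below the cutoff —
#' including exactly at it — form the complementary class. The default
#' cutoff of 23.3 (x10^-2) is the empirically determined single-cell
#' criterion the package reproduces; it is a configurable parameter, not
#' a re-estimated quantity.
#'
#' @param records data frame with a `fpol_display` column and optionally
#'   a `group` column; without `group` all cells form one group.
#' @param cutoff_display cutoff on the display (x10^-2) scale.
#' @return An object of class `"cutoff_summary"`: per-group data frame
#'   with `n_above`, `n_at_or_below`, `n_total`, exact proportions, and
#'   integer display percentages.
#' @export
#' @examples
#' rec <- data.frame(fpol_display = c(25, 23.3, 20), group = "malignant")
#' classify_cells(rec)
classify_cells <- function(records, cutoff_display = 23.3) {
  records <- as.data.frame(records)
  if (nrow(records) == 0L) {
    out <- data.frame(group = character(0), n_above = integer(0),
                      n_at_or_below = integer(0), n_total = integer(0),
                      prop_above = numeric(0), pct_above = integer(0),
                      pct_at_or_below = integer(0))
    return(structure(out, cutoff_display = cutoff_display,
                     class = c("cutoff_summary", class(out))))
  }
  if (!("fpol_display" %in% names(records)))
    stop("records must have an fpol_display column", call. = FALSE)
  grp <- if ("group" %in% names(records)) as.character(records$group)
         else rep("all", nrow(records))
  above <- records$fpol_display > cutoff_display
  out <- do.call(rbind, lapply(unique(grp), function(gname) {
    sel <- grp == gname
    n_above <- sum(above[sel]); n_tot <- sum(sel)
    data.frame(group = gname, n_above = n_above,
               n_at_or_below = n_tot - n_above, n_total = n_tot,
               prop_above = n_above / n_tot,
               pct_above = as.integer(round(100 * n_above / n_tot)),
               pct_at_or_below = as.integer(round(100 * (n_tot - n_above) / n_tot)))
  }))
  rownames(out) <- NULL
  structure(out, cutoff_display = cutoff_display,
            class = c("cutoff_summary", class(out)))
}

#' @export
print.cutoff_summary <- function(x, ...) {
  cat(sprintf("Cutoff classification at Fpol > %.1f (x10^-2)\n",
              attr(x, "cutoff_display")))
  print.data.frame(x, row.names = FALSE, ...)
  invisible(x)
}

#' Per-specimen Fpol summaries
#'
#' Arithmetic mean and sample SD of the display-scale Fpol per specimen
#' — the per-specimen averages that a spectroscopic (non-imaging)
#' measurement over tens of cells would deliver. Single-cell specimens
#' have an undefined SD and are flagged.
#'
#' @param records data frame with `specimen_id` and `fpol_display`
#'   columns; `group` is carried through when present.
#' @return Data frame with one row per specimen: `specimen_id`, `n`,
#'   `mean_fpol_display`, `sd_fpol_display` (`NA` when `n == 1`),
#'   `sd_defined`.
#' @export
specimen_summary <- function(records) {
  records <- as.data.frame(records)
  stopifnot(all(c("specimen_id", "fpol_display") %in% names(records)))
  ids <- unique(as.character(records$specimen_id))
  out <- do.call(rbind, lapply(ids, function(id) {
    x <- records$fpol_display[records$specimen_id == id]
    data.frame(specimen_id = id, n = length(x),
               mean_fpol_display = mean(x),
               sd_fpol_display = if (length(x) > 1) sd(x) else NA_real_,
               sd_defined = length(x) > 1,
               group = if ("group" %in% names(records))
                 as.character(records$group[records$specimen_id == id][1])
               else NA_character_)
  }))
  rownames(out) <- NULL
  out
}

.grouping_column <- function(grouping) {
  switch(grouping,
         diagnostic3 = "group",
         histologic5 = "histology",
         grade3 = "grade",
         stop("unknown grouping: ", grouping, call. = FALSE))
}

#' Mixed-effects group analysis of per-cell Fpol
#'
#' Fits the linear mixed-effects model
#' \deqn{Fpol_{ij} = \mu_{g(i)} + b_i + \epsilon_{ij}} for cell *j* in
#' specimen *i*, with a fixed effect per group and a specimen-level
#' random intercept \eqn{b_i \sim N(0, \sigma_b^2)}, by REML via
#' [lme4::lmer()]. Least-squares means are the fixed-effect group
#' estimates with Wald standard errors from the estimated
#' variance-covariance matrix; pairwise comparisons use Wald z-tests on
#' LS-mean differences. Cells are sampled within specimens, so the
#' specimen is the random-effect unit by default; set
#' `unit = "subject"` to nest intercepts by subject instead.
#'
#' Significance defaults follow the analysis conventions the package
#' reproduces: alpha 0.001 for the diagnostic (malignant/benign/normal)
#' and histologic (IDC/ILC/FA/IDP/normal) groupings, 0.05 for tumor
#' grade.
#'
#' @param records data frame of cell records with `fpol_display`,
#'   `specimen_id` (and `subject_id` if `unit = "subject"`), plus the
#'   grouping column (`group`, `histology`, or `grade`).
#' @param grouping `"diagnostic3"`, `"histologic5"`, or `"grade3"`.
#' @param alpha significance level for flagging pairwise comparisons;
#'   default depends on `grouping` as above.
#' @param unit random-intercept unit, `"specimen"` or `"subject"`.
#' @param adjust p-value adjustment across the pairwise comparisons:
#'   `"none"` (default, matching per-comparison reporting) or `"holm"`.
#' @return An object of class `"group_model_result"`: list with
#'   `grouping`, `alpha`, `ls_means` (group, estimate, SE, n_cells,
#'   n_specimens), `comparisons` (pairwise differences, SEs, z, p,
#'   significance flags), `variance_components`
#'   (between-specimen and residual SDs), `singular` flag, and `fit`
#'   (the underlying `lmerMod`).
#' @export
fit_group_model <- function(records,
                            grouping = c("diagnostic3", "histologic5",
                                         "grade3"),
                            alpha = NULL,
                            unit = c("specimen", "subject"),
                            adjust = c("none", "holm")) {
  grouping <- match.arg(grouping)
  unit <- match.arg(unit)
  adjust <- match.arg(adjust)
  if (is.null(alpha))
    alpha <- if (grouping == "grade3") 0.05 else 0.001
  records <- as.data.frame(records)
  col <- .grouping_column(grouping)
  need <- c("fpol_display", "specimen_id", col,
            if (unit == "subject") "subject_id")
  missing_cols <- setdiff(need, names(records))
  if (length(missing_cols))
    stop("records are missing columns: ",
         paste(missing_cols, collapse = ", "), call. = FALSE)
  records <- records[!is.na(records[[col]]), , drop = FALSE]
  d <- data.frame(y = records$fpol_display,
                  g = factor(records[[col]]),
                  specimen = factor(records$specimen_id))
  if (unit == "subject") d$specimen <- factor(records$subject_id)
  if (nlevels(d$g) < 2L)
    stop("need at least 2 groups to fit contrasts; got ",
         nlevels(d$g), call. = FALSE)
  spec_per_group <- tapply(d$specimen, d$g,
                           function(s) length(unique(s)))
  if (any(spec_per_group < 2L))
    warning("group(s) with a single specimen: ",
            paste(names(spec_per_group)[spec_per_group < 2L],
                  collapse = ", "),
            "; their SEs rest on the pooled variance components",
            call. = FALSE)

  fit <- suppressMessages(lme4::lmer(
    y ~ 0 + g + (1 | specimen), data = d, REML = TRUE,
    control = lme4::lmerControl(check.conv.singular = "ignore",
                                calc.derivs = FALSE)))
  singular <- lme4::isSingular(fit)
  beta <- lme4::fixef(fit)
  V <- as.matrix(stats::vcov(fit))
  lev <- levels(d$g)
  names(beta) <- lev
  ls_means <- data.frame(
    group = lev,
    estimate = as.numeric(beta),
    se = sqrt(diag(V)),
    n_cells = as.integer(table(d$g)[lev]),
    n_specimens = as.integer(spec_per_group[lev]))
  rownames(ls_means) <- NULL

  pairs <- utils::combn(seq_along(lev), 2)
  comparisons <- do.call(rbind, lapply(seq_len(ncol(pairs)), function(k) {
    i <- pairs[1, k]; j <- pairs[2, k]
    diff <- beta[i] - beta[j]
    se <- sqrt(V[i, i] + V[j, j] - 2 * V[i, j])
    z <- diff / se
    data.frame(comparison = paste(lev[i], "vs", lev[j]),
               difference = as.numeric(diff), se = se, z = as.numeric(z),
               p_value = 2 * pnorm(-abs(z)))
  }))
  if (adjust == "holm")
    comparisons$p_value <- stats::p.adjust(comparisons$p_value, "holm")
  comparisons$significant <- comparisons$p_value < alpha
  rownames(comparisons) <- NULL

  vc <- as.data.frame(lme4::VarCorr(fit))
  between_sd <- vc$sdcor[vc$grp == "specimen"]
  resid_sd <- vc$sdcor[vc$grp == "Residual"]

  structure(
    list(grouping = grouping, alpha = alpha, unit = unit,
         adjust = adjust,
         ls_means = ls_means, comparisons = comparisons,
         variance_components = c(between_specimen_sd = between_sd,
                                 residual_sd = resid_sd),
         singular = singular, fit = fit),
    class = "group_model_result")
}

#' @export
print.group_model_result <- function(x, ...) {
  cat(sprintf("Mixed-effects group analysis [%s], alpha = %g%s\n",
              x$grouping, x$alpha,
              if (x$singular) " (singular fit: between-specimen variance at 0)"
              else ""))
  cat(sprintf("Random intercept per %s: SD %.3f; residual SD %.3f\n",
              x$unit, x$variance_components[["between_specimen_sd"]],
              x$variance_components[["residual_sd"]]))
  cat("LS-means (Fpol, x10^-2):\n")
  lm2 <- x$ls_means
  lm2$estimate <- round(lm2$estimate, 2)
  lm2$se <- round(lm2$se, 2)
  print.data.frame(lm2, row.names = FALSE)
  cat("Pairwise comparisons:\n")
  cmp <- x$comparisons
  cmp$difference <- round(cmp$difference, 2)
  cmp$se <- round(cmp$se, 2)
  cmp$z <- round(cmp$z, 2)
  cmp$p_value <- signif(cmp$p_value, 3)
  print.data.frame(cmp, row.names = FALSE)
  invisible(x)
}

#' Tumor-grade analysis of malignant cells
#'
#' Restricts the records to malignant specimens with grade labels and
#' fits the same specimen-random-intercept model with tumor grade
#' (1/2/3) as the fixed effect, at alpha 0.05.
#'
#' @param records data frame of cell records; rows with
#'   `group == "malignant"` and a non-missing `grade` are used (if no
#'   `group` column is present, all graded rows are used).
#' @param alpha significance level (default 0.05).
#' @param ... passed to [fit_group_model()].
#' @return A `"group_model_result"`.
#' @export
grade_analysis <- function(records, alpha = 0.05, ...) {
  records <- as.data.frame(records)
  if ("group" %in% names(records))
    records <- records[records$group == "malignant", , drop = FALSE]
  if (!("grade" %in% names(records)) || all(is.na(records$grade)))
    stop("grade labels are required on malignant specimens", call. = FALSE)
  records <- records[!is.na(records$grade), , drop = FALSE]
  fit_group_model(records, grouping = "grade3", alpha = alpha, ...)
}

#' Plain-text report of the group analysis
#'
#' Lays out specimen counts, cell counts, and LS-means +/- SE per group
#' in the style of a cohort characteristics table (2-decimal display
#' scale), followed by the pairwise comparisons.
#'
#' @param result a `"group_model_result"`.
#' @return A character vector of report lines, invisibly printable with
#'   `cat(..., sep = "\n")`.
#' @export
format_group_report <- function(result) {
  stopifnot(inherits(result, "group_model_result"))
  lm <- result$ls_means
  lines <- c(
    sprintf("Group analysis [%s] — LS-means on the x10^-2 display scale",
            result$grouping),
    sprintf("%-12s %10s %8s %18s", "Group", "Specimens", "Cells",
            "Mean Fpol +/- SE"),
    sprintf("%-12s %10d %8d %11.2f +/- %.2f",
            lm$group, lm$n_specimens, lm$n_cells, lm$estimate, lm$se),
    "",
    sprintf("Pairwise comparisons (alpha = %g):", result$alpha),
    sprintf("  %-28s diff %6.2f  p = %-9.3g %s",
            result$comparisons$comparison, result$comparisons$difference,
            result$comparisons$p_value,
            ifelse(result$comparisons$significant, "*", "")))
  lines
}
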