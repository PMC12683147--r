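#' @describeIn panel_average Average line-scale scores across raters.
#'   Returns one row per (product, serving, attribute) with the arithmetic
#'   mean over raters and the contributing rater count.  A serving missing
#'   an attribute that other servings have is flagged in
#'   `attr(, "missing_cells")`.
#' @export
panel_average.qda_dataset <- function(x, ...) {
  rec <- x$records
  key <- interaction(rec$product, rec$serving, rec$attribute, drop = TRUE,
                     sep = "\r")
  agg <- do.call(rbind, lapply(split(rec, key), function(g) {
    data.frame(product = g$product[1L], serving = g$serving[1L],
               attribute = g$attribute[1L], score = mean(g$score),
               n_raters = nrow(g), stringsAsFactors = FALSE)
  }))
  rownames(agg) <- NULL
  agg <- agg[order(agg$product, agg$serving, agg$attribute), ]
  servings <- unique(agg$serving)
  attrs <- unique(agg$attribute)
  have <- table(factor(agg$serving, servings), factor(agg$attribute, attrs))
  missing_cells <- which(have == 0L, arr.ind = TRUE)
  out <- structure(agg, class = c("qda_panel_means", "data.frame"),
                   factors = x$factors)
  if (nrow(missing_cells)) {
    attr(out, "missing_cells") <- data.frame(
      serving = servings[missing_cells[, 1L]],
      attribute = attrs[missing_cells[, 2L]])
    warning(sprintf("%d serving x attribute cell(s) have no records",
                    nrow(missing_cells)))
  }
  out
}

sig_code <- function(p) {
  ifelse(p < 0.001, "***", ifelse(p < 0.01, "**", ifelse(p < 0.05, "*", "")))
}

# attach factor levels (by product) to a table with a product column
join_factors <- function(tab, factors, wanted) {
  if (is.null(factors)) abort_validation("no design-factor table available")
  miss <- setdiff(wanted, colnames(factors))
  if (length(miss)) {
    abort_validation(sprintf("unknown design factor(s): %s",
                             paste(miss, collapse = ", ")))
  }
  for (f in wanted) {
    lev <- factors[tab$product, f]
    if (any(is.na(lev))) abort_validation("a product is missing a factor level")
    tab[[f]] <- factor(lev)
  }
  tab
}

#' Per-attribute ANOVA of panel-averaged evaluations
#'
#' For each attribute, fits a least-squares linear model of the
#' panel-averaged score on one or two design factors and reports the F-test
#' of each factor (and optionally their interaction).  Significance codes
#' follow the usual convention: `*` p < 0.05, `**` p < 0.01, `***` p < 0.001.
#'
#' @param x A `qda_panel_means` table from [panel_average.qda_dataset()].
#' @param factors Character vector naming 1 or 2 design factors present in
#'   the dataset's factor table.
#' @param interaction For two factors, also test their interaction.
#' @return Data frame with columns `attribute`, `term`, `F`, `df1`, `df2`,
#'   `p_value`, `N`, `sig`.
#' @export
attribute_anova <- function(x, factors, interaction = FALSE) {
  stopifnot(inherits(x, "qda_panel_means"))
  if (!length(factors) %in% 1:2) abort_usage("supply 1 or 2 design factors")
  ftab <- attr(x, "factors")
  out <- do.call(rbind, lapply(split(as.data.frame(x), x$attribute), function(g) {
    g <- join_factors(g, ftab, factors)
    for (f in factors) {
      if (nlevels(g[[f]]) < 2L) {
        abort_validation(sprintf("factor '%s' has fewer than 2 levels", f))
      }
    }
    rhs <- paste(factors, collapse = if (interaction) " * " else " + ")
    fit <- stats::lm(stats::as.formula(paste("score ~", rhs)), data = g)
    if (fit$df.residual < 1L) abort_validation("zero error degrees of freedom")
    an <- stats::anova(fit)
    terms <- setdiff(rownames(an), "Residuals")
    data.frame(attribute = g$attribute[1L], term = terms,
               F = an[terms, "F value"], df1 = an[terms, "Df"],
               df2 = fit$df.residual, p_value = an[terms, "Pr(>F)"],
               N = nrow(g), sig = sig_code(an[terms, "Pr(>F)"]),
               stringsAsFactors = FALSE)
  }))
  rownames(out) <- NULL
  out
}

#' Pairwise group comparisons for one attribute
#'
#' All unordered pairs of factor levels, using the pooled residual standard
#' deviation from the one-way fit on the panel-averaged scores (so the t
#' statistics are consistent with the overall F-test and with confidence
#' bars drawn from a common error term).  Welch's unequal-variance test is
#' available behind a flag.  Per-group means with their own confidence
#' intervals are returned alongside the per-difference intervals.
#'
#' @param x A `qda_panel_means` table.
#' @param attribute Attribute to analyse.
#' @param factor Name of the design factor.
#' @param adjust Multiplicity adjustment across the pair family:
#'   `"none"`, `"holm"` or `"bonferroni"`.
#' @param conf_level Confidence level (default 0.95).
#' @param welch Use Welch's t-test instead of the pooled fit.
#' @return Object of class `pairwise_comparisons`: data frame of pairs
#'   (`group_a`, `group_b`, `diff`, `ci_lo`, `ci_hi`, `t`, `df`, `p_value`,
#'   `p_adjusted`, `flag`) with the per-group means in
#'   `attr(, "group_means")`.
#' @export
pairwise_ttests <- function(x, attribute, factor,
                            adjust = c("none", "holm", "bonferroni"),
                            conf_level = 0.95, welch = FALSE) {
  stopifnot(inherits(x, "qda_panel_means"))
  adjust <- match.arg(adjust)
  g <- as.data.frame(x)[x$attribute == attribute, , drop = FALSE]
  if (!nrow(g)) abort_validation(sprintf("unknown attribute '%s'", attribute))
  g <- join_factors(g, attr(x, "factors"), factor)
  grp <- g[[factor]]
  if (nlevels(grp) < 2L) abort_validation("need at least 2 groups")
  lv <- levels(grp)
  means <- tapply(g$score, grp, mean)
  ns <- tapply(g$score, grp, length)
  ss_within <- sum(tapply(g$score, grp, function(v) sum((v - mean(v))^2)))
  df_pool <- nrow(g) - nlevels(grp)
  s_pool <- if (df_pool > 0) sqrt(ss_within / df_pool) else NA_real_
  tq <- stats::qt(1 - (1 - conf_level) / 2, df_pool)
  group_means <- data.frame(group = lv, mean = as.numeric(means),
                            n = as.integer(ns),
                            ci_lo = means - tq * s_pool / sqrt(ns),
                            ci_hi = means + tq * s_pool / sqrt(ns))
  pairs <- utils::combn(lv, 2L)
  res <- do.call(rbind, apply(pairs, 2L, function(pr) {
    a <- pr[1L]; b <- pr[2L]
    flag <- if (ns[a] < 2L || ns[b] < 2L) "single-observation group" else ""
    d <- means[a] - means[b]
    if (welch) {
      va <- stats::var(g$score[grp == a]); vb <- stats::var(g$score[grp == b])
      se <- sqrt(va / ns[a] + vb / ns[b])
      df <- se^4 / ((va / ns[a])^2 / (ns[a] - 1) + (vb / ns[b])^2 / (ns[b] - 1))
    } else {
      se <- s_pool * sqrt(1 / ns[a] + 1 / ns[b])
      df <- df_pool
    }
    tt <- d / se
    tc <- stats::qt(1 - (1 - conf_level) / 2, df)
    data.frame(group_a = a, group_b = b, diff = d,
               ci_lo = d - tc * se, ci_hi = d + tc * se,
               t = tt, df = df,
               p_value = 2 * stats::pt(-abs(tt), df),
               flag = flag, stringsAsFactors = FALSE)
  }))
  res$p_adjusted <- if (adjust == "none") res$p_value else
    adjust_p(res$p_value, method = adjust)
  rownames(res) <- NULL
  structure(res, class = c("pairwise_comparisons", "data.frame"),
            group_means = group_means, attribute = attribute,
            conf_level = conf_level)
}

#' Per-attribute ANOVA with subject (rater) fixed effects
#'
#' Analyses panelist-level records: for each attribute the score is modelled
#' by least squares on a rater indicator (fixed subject effects absorbing
#' panelist-specific scale use) plus the design factor; the reported F-test
#' compares the full model against the rater-only model.  Set
#' `subject_effect = "random"` to delegate to a mixed-model fitter (requires
#' the lme4 package; not part of the core surface).
#'
#' @param dataset A [qda_dataset()].
#' @param factor Name of the design factor in the dataset's factor table.
#' @param subject_effect `"fixed"` (default, plain least squares) or
#'   `"random"`.
#' @return Data frame with columns `attribute`, `term`, `F`, `df1`, `df2`,
#'   `p_value`, `N`, `sig`.
#' @export
subject_effects_anova <- function(dataset, factor,
                                  subject_effect = c("fixed", "random")) {
  stopifnot(inherits(dataset, "qda_dataset"))
  subject_effect <- match.arg(subject_effect)
  rec <- join_factors(dataset$records, dataset$factors, factor)
  rec$rater <- base::factor(rec$rater)
  out <- do.call(rbind, lapply(split(rec, rec$attribute), function(g) {
    grp <- g[[factor]]
    if (nlevels(droplevels(grp)) < 2L) {
      abort_validation(sprintf("factor '%s' has fewer than 2 levels", factor))
    }
    if (subject_effect == "random") {
      if (!requireNamespace("lme4", quietly = TRUE)) {
        abort_usage("subject_effect = 'random' requires the lme4 package")
      }
      f1 <- lme4::lmer(stats::as.formula(paste("score ~", factor, "+ (1 | rater)")),
                       data = g, REML = FALSE)
      f0 <- lme4::lmer(score ~ 1 + (1 | rater), data = g, REML = FALSE)
      lrt <- stats::anova(f0, f1)
      return(data.frame(attribute = g$attribute[1L], term = factor,
                        F = NA_real_, df1 = lrt$Df[2L] - lrt$Df[1L],
                        df2 = NA_real_, p_value = lrt$`Pr(>Chisq)`[2L],
                        N = nrow(g), sig = sig_code(lrt$`Pr(>Chisq)`[2L]),
                        stringsAsFactors = FALSE))
    }
    many_raters <- nlevels(droplevels(g$rater)) > 1L
    rhs0 <- if (many_raters) "rater" else "1"
    fit0 <- stats::lm(stats::as.formula(paste("score ~", rhs0)), data = g)
    fit1 <- stats::lm(stats::as.formula(paste("score ~", rhs0, "+", factor)),
                      data = g)
    # confounding check: the group factor must add estimable contrasts
    added <- fit0$df.residual - fit1$df.residual
    if (added < nlevels(droplevels(grp)) - 1L) {
      abort_validation(sprintf(
        "design factor '%s' is confounded with raters (rank-deficient fit)",
        factor))
    }
    if (fit1$df.residual < 1L) abort_validation("zero error degrees of freedom")
    an <- stats::anova(fit0, fit1)
    p <- an$`Pr(>F)`[2L]
    data.frame(attribute = g$attribute[1L], term = factor, F = an$F[2L],
               df1 = an$Df[2L], df2 = fit1$df.residual, p_value = p,
               N = nrow(g), sig = sig_code(p), stringsAsFactors = FALSE)
  }))
  rownames(out) <- NULL
  out
}

#' ECDF uniformity diagnostic for a set of p-values
#'
#' With no true effects, p-values are (super-)uniform and their empirical
#' cumulative distribution function hugs the diagonal; systematic departure
#' below the diagonal indicates real effects, above it conservatism.  The
#' Kolmogorov-Smirnov distance to the uniform, sup |ECDF(p) - p|, summarises
#' the departure.  An optional grouping label supports per-study curves and
#' a pooled curve.
#'
#' @param p Numeric vector of p-values in \[0, 1\].
#' @param group Optional vector of study labels, same length as `p`.
#' @return Object of class `ecdf_diagnostic`: `p_sorted`, plotting step
#'   points (`step_x`, `step_y`), `ks_distance`, `n`, and, when `group` is
#'   given, a `by_group` list of per-group diagnostics.
#' @export
pvalue_ecdf <- function(p, group = NULL) {
  if (!length(p)) abort_validation("empty p-value vector")
  if (any(!is.finite(p) | p < 0 | p > 1)) {
    abort_validation("p-values must lie in [0, 1]")
  }
  ps <- sort(p)
  n <- length(ps)
  i <- seq_len(n)
  ks <- max(pmax(i / n - ps, ps - (i - 1) / n))
  out <- list(p_sorted = ps,
              step_x = c(0, ps, 1), step_y = c(0, i / n, 1),
              ks_distance = ks, n = n)
  if (!is.null(group)) {
    stopifnot(length(group) == length(p))
    out$by_group <- lapply(split(p, group), pvalue_ecdf)
  }
  structure(out, class = "ecdf_diagnostic")
}

#' @export
print.ecdf_diagnostic <- function(x, ...) {
  cat(sprintf("p-value ECDF: n = %d, KS distance to uniform = %.4f\n",
              x$n, x$ks_distance))
  if (!is.null(x$by_group)) {
    for (g in names(x$by_group)) {
      cat(sprintf("  %s: n = %d, KS = %.4f\n", g, x$by_group[[g]]$n,
                  x$by_group[[g]]$ks_distance))
    }
  }
  invisible(x)
}
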