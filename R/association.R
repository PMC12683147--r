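#' Construct a contingency table
#'
#' @param counts Nonnegative integer matrix (rows = factor levels, columns =
#'   cluster ids).
#' @param row_labels,col_labels Optional dimnames.
#' @return Object of class `contingency_table` with `counts`, `row_labels`,
#'   `col_labels` and grand total `N`.
#' @export
contingency_table <- function(counts, row_labels = rownames(counts),
                              col_labels = colnames(counts)) {
  counts <- as.matrix(counts)
  if (any(counts < 0) || any(counts != round(counts))) {
    abort_validation("counts must be nonnegative integers")
  }
  storage.mode(counts) <- "integer"
  if (sum(counts) == 0L) abort_validation("all-zero contingency table")
  if (is.null(row_labels)) row_labels <- as.character(seq_len(nrow(counts)))
  if (is.null(col_labels)) col_labels <- as.character(seq_len(ncol(counts)))
  dimnames(counts) <- list(as.character(row_labels), as.character(col_labels))
  structure(list(counts = counts, row_labels = rownames(counts),
                 col_labels = colnames(counts), N = sum(counts)),
            class = "contingency_table")
}

#' @export
print.contingency_table <- function(x, ...) {
  cat(sprintf("Contingency table (%d x %d), N = %d\n",
              nrow(x$counts), ncol(x$counts), x$N))
  print(x$counts)
  invisible(x)
}

#' Cross-tabulate cluster membership against a design factor
#'
#' Counts products per (factor level, cluster).  Guardrail: associations may
#' only be tested against product characteristics that were *not* used for
#' clustering.  Factors derived from the panelists' own descriptors are used
#' (at least implicitly) when placing the products, so testing them against
#' cluster membership is circular; pass `descriptor_derived = TRUE` to
#' declare such a factor, which errors unless `force = TRUE`.
#'
#' @param labels Named cluster assignment (product -> cluster id).
#' @param factors Named character vector (product -> factor level).
#' @param descriptor_derived Is the factor derived from panelist
#'   verbalizations? (default `FALSE`).
#' @param force Override the descriptor-derived guardrail with a warning.
#' @return A [contingency_table()] with rows/columns sorted by label.
#' @export
build_contingency <- function(labels, factors, descriptor_derived = FALSE,
                              force = FALSE) {
  if (descriptor_derived) {
    if (!force) {
      abort_usage(paste0(
        "refusing to tabulate a descriptor-derived factor against cluster ",
        "membership: the raters' verbalizations inform their placements, so ",
        "dependence holds by design; use force = TRUE to override"))
    }
    warning("testing a descriptor-derived factor against cluster membership is circular")
  }
  miss <- setdiff(names(labels), names(factors))
  if (length(miss)) {
    abort_validation(sprintf("product(s) missing a factor level: %s",
                             paste(miss, collapse = ", ")))
  }
  lv <- sort(unique(as.character(factors[names(labels)])))
  cl <- sort(unique(labels))
  counts <- matrix(0L, length(lv), length(cl),
                   dimnames = list(lv, as.character(cl)))
  for (p in names(labels)) {
    counts[as.character(factors[[p]]), as.character(labels[[p]])] <-
      counts[as.character(factors[[p]]), as.character(labels[[p]])] + 1L
  }
  contingency_table(counts)
}

# log multivariate-hypergeometric probability machinery: for a table with
# fixed margins, log P = sum(lfact(row margins)) + sum(lfact(col margins))
#                        - lfact(N) - sum(lfact(cells))
lfact <- function(x) lgamma(x + 1)

# enumerate all nonnegative integer matrices with the given margins,
# calling visit(log_cell_term) with the -sum(lfact(cells)) part;
# returns number of tables visited (errors past budget)
enumerate_margin_tables <- function(row_m, col_m, visit, budget = 1e7) {
  R <- length(row_m)
  count <- 0L
  rec_row <- function(r, rem_col, acc) {
    if (r == R) {
      # last row forced by the remaining column margins
      count <<- count + 1L
      if (count > budget) {
        abort_budget(sprintf(
          "enumeration exceeded budget of %g tables; use freeman_halton_mc()",
          budget))
      }
      visit(acc - sum(lfact(rem_col)))
      return(invisible())
    }
    fill_row(r, 1L, row_m[r], rem_col, acc)
  }
  C <- length(col_m)
  fill_row <- function(r, j, left, rem_col, acc) {
    if (j == C) {
      if (left > rem_col[C]) return(invisible())
      rem_col[C] <- rem_col[C] - left
      rec_row(r + 1L, rem_col, acc - lfact(left))
      return(invisible())
    }
    # cell (r, j) can take 0..min(left, rem_col[j]); remaining columns must
    # be able to absorb what is left
    hi <- min(left, rem_col[j])
    lo <- max(0L, left - sum(rem_col[(j + 1L):C]))
    if (lo > hi) return(invisible())
    for (v in lo:hi) {
      rem2 <- rem_col
      rem2[j] <- rem2[j] - v
      fill_row(r, j + 1L, left - v, rem2, acc - lfact(v))
    }
  }
  rec_row(1L, col_m, 0)
  count
}

table_log_prob <- function(counts) {
  row_m <- rowSums(counts); col_m <- colSums(counts); N <- sum(counts)
  sum(lfact(row_m)) + sum(lfact(col_m)) - lfact(N) - sum(lfact(counts))
}

#' Freeman-Halton exact test of independence on an RxC table
#'
#' The generalization of Fisher's exact test to RxC tables: conditioning on
#' both margins, every margin-compatible table has a multivariate
#' hypergeometric probability, and the two-sided p-value is the sum of the
#' probabilities of all tables no more probable than the observed one (with
#' a small relative tolerance for floating-point ties).  Enumeration is by
#' recursive cell filling with margin-feasibility pruning; probabilities are
#' computed in log space from log-factorials.
#'
#' @param table A [contingency_table()].
#' @param budget Maximum number of margin-compatible tables to enumerate
#'   before erroring with a suggestion to use [freeman_halton_mc()].
#' @param tie_tol Relative tolerance classifying a table as "no more
#'   probable" than the observed one (default 1e-7).
#' @return Object of class `exact_test_result`: `p_value`, `method`,
#'   `n_tables` enumerated, `prob_observed`.
#' @export
freeman_halton <- function(table, budget = 1e7, tie_tol = 1e-7) {
  stopifnot(inherits(table, "contingency_table"))
  counts <- table$counts
  # all-zero rows/columns carry no information and would stall enumeration
  counts <- counts[rowSums(counts) > 0L, colSums(counts) > 0L, drop = FALSE]
  row_m <- rowSums(counts); col_m <- colSums(counts)
  lp_obs <- table_log_prob(counts)
  cut <- lp_obs + log1p(tie_tol)
  p_sum <- 0
  margin_const <- sum(lfact(row_m)) + sum(lfact(col_m)) - lfact(sum(counts))
  n_tab <- enumerate_margin_tables(row_m, col_m, function(cell_term) {
    lp <- margin_const + cell_term
    if (lp <= cut) p_sum <<- p_sum + exp(lp)
  }, budget = budget)
  p <- min(1, p_sum)
  structure(list(p_value = p, adjusted_p = NULL, method = "Freeman-Halton exact test",
                 n_tables = n_tab, prob_observed = exp(lp_obs)),
            class = "exact_test_result")
}

#' Monte-Carlo Freeman-Halton test for large tables
#'
#' Estimates the exact two-sided p-value by sampling margin-fixed tables
#' from the null (multivariate hypergeometric) distribution via Patefield's
#' algorithm and counting tables no more probable than the observed one.
#' The estimate uses the (1 + k) / (n_sim + 1) convention and reports a
#' binomial standard error.
#'
#' @param table A [contingency_table()].
#' @param n_sim Number of sampled tables (>= 1e4).
#' @param seed Integer seed.
#' @inheritParams freeman_halton
#' @return An `exact_test_result` with `std_error` and `n_sim`.
#' @export
freeman_halton_mc <- function(table, n_sim = 1e5, seed = NULL,
                              tie_tol = 1e-7) {
  stopifnot(inherits(table, "contingency_table"))
  if (n_sim < 1e4) abort_usage("n_sim must be at least 1e4")
  counts <- table$counts
  counts <- counts[rowSums(counts) > 0L, colSums(counts) > 0L, drop = FALSE]
  if (nrow(counts) == 1L || ncol(counts) == 1L) {
    return(structure(list(p_value = 1, adjusted_p = NULL,
                          method = "Freeman-Halton (Monte Carlo)",
                          n_tables = 1L, prob_observed = 1,
                          std_error = 0, n_sim = as.integer(n_sim)),
                     class = "exact_test_result"))
  }
  lp_obs <- table_log_prob(counts)
  cut <- lp_obs + log1p(tie_tol)
  if (!is.null(seed)) set.seed(seed)
  sims <- stats::r2dtable(n_sim, rowSums(counts), colSums(counts))
  margin_const <- sum(lfact(rowSums(counts))) + sum(lfact(colSums(counts))) -
    lfact(sum(counts))
  lps <- vapply(sims, function(t) margin_const - sum(lfact(t)), numeric(1))
  k <- sum(lps <= cut)
  p <- (1 + k) / (n_sim + 1)
  structure(list(p_value = p, adjusted_p = NULL,
                 method = "Freeman-Halton (Monte Carlo)",
                 n_tables = NA_integer_, prob_observed = exp(lp_obs),
                 std_error = sqrt(p * (1 - p) / n_sim),
                 n_sim = as.integer(n_sim)),
            class = "exact_test_result")
}

#' @export
print.exact_test_result <- function(x, ...) {
  cat(sprintf("%s: p = %.5g", x$method, x$p_value))
  if (!is.null(x$std_error)) cat(sprintf(" (MC se %.2g)", x$std_error))
  if (!is.null(x$adjusted_p)) cat(sprintf(", adjusted p = %.5g", x$adjusted_p))
  cat("\n")
  if (!is.na(x$n_tables)) {
    cat(sprintf("  %d margin-compatible tables enumerated; P(observed) = %.4g\n",
                x$n_tables, x$prob_observed))
  }
  invisible(x)
}

#' Familywise multiplicity adjustment of p-values
#'
#' Bonferroni multiplies each p-value by the number of tests `m`; Holm is
#' the uniformly less conservative step-down variant with cumulative-max
#' monotonicity.  `m` is supplied by the caller (it may exceed the number of
#' p-values passed, e.g. when the same analysis was run on sister studies);
#' it is never inferred silently beyond defaulting to `length(p)`.
#'
#' @param p Numeric vector of p-values in \[0, 1\].
#' @param method `"bonferroni"` or `"holm"`.
#' @param m Number of tests in the family (default `length(p)`).
#' @return Adjusted p-values, in input order, capped at 1.
#' @export
adjust_p <- function(p, method = c("bonferroni", "holm"), m = length(p)) {
  method <- match.arg(method)
  if (any(!is.finite(p) | p < 0 | p > 1)) {
    abort_validation("p-values must lie in [0, 1]")
  }
  if (m < length(p)) abort_usage("m cannot be smaller than length(p)")
  if (method == "bonferroni") return(pmin(1, m * p))
  ord <- order(p)
  mult <- m - seq_along(p) + 1L
  adj <- pmin(1, cummax(mult * p[ord]))
  adj[order(ord)]
}
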