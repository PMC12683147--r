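#' Construct a product distance matrix
#'
#' Symmetric, nonnegative product-by-product distances with a zero diagonal.
#' `NA` cells mark missing information (e.g. a product pair never co-placed
#' by any rater); they are distinct from zero, which means coincidence.
#'
#' @param values Square numeric matrix; row/column names are the product
#'   labels unless `labels` is given.
#' @param labels Optional character vector of product labels.
#' @param provenance One of `"per-rater"`, `"panel-averaged"`,
#'   `"concatenated"`, `"latent"`.
#' @param support Optional integer matrix: for panel-averaged matrices, the
#'   number of raters contributing to each cell.
#' @return An object of class `distance_matrix`.
#' @export
distance_matrix <- function(values,
                            labels = rownames(values),
                            provenance = c("per-rater", "panel-averaged",
                                           "concatenated", "latent"),
                            support = NULL) {
  provenance <- match.arg(provenance)
  values <- as.matrix(values)
  if (nrow(values) != ncol(values)) abort_validation("distance matrix must be square")
  if (is.null(labels)) labels <- as.character(seq_len(nrow(values)))
  labels <- as.character(labels)
  if (length(labels) != nrow(values)) abort_validation("labels/values size mismatch")
  dimnames(values) <- list(labels, labels)
  ok <- is.na(values) | (t(values) == values) |
    (abs(values - t(values)) <= 1e-8 * (1 + abs(values)))
  ok[is.na(t(values)) != is.na(values)] <- FALSE
  if (!all(ok)) abort_validation("distance matrix is not symmetric")
  values[] <- (values + t(values)) / 2
  placed_diag <- !is.na(diag(values))
  if (any(abs(diag(values)[placed_diag]) > 1e-12)) {
    abort_validation("distance matrix diagonal must be zero")
  }
  if (any(values < 0, na.rm = TRUE)) abort_validation("negative distance")
  structure(list(labels = labels, values = values,
                 provenance = provenance, support = support),
            class = "distance_matrix")
}

#' @export
print.distance_matrix <- function(x, ...) {
  cat(sprintf("%s distance matrix, %d products\n", x$provenance,
              length(x$labels)))
  print(round(x$values, 3))
  invisible(x)
}

#' @export
as.matrix.distance_matrix <- function(x, ...) x$values

#' @export
as.dist.distance_matrix <- function(m, diag = FALSE, upper = FALSE) {
  if (anyNA(m$values)) abort_validation("distance matrix has missing cells")
  stats::as.dist(m$values, diag = diag, upper = upper)
}

#' Per-rater product distances from one Napping sheet
#'
#' The placements on a rater's 2-D sheet carry an arbitrary coordinate frame;
#' only the pairwise Euclidean distances between the placed products are
#' meaningful, and those are invariant to rotation, reflection and
#' translation of the sheet.  Products the rater did not place get `NA`
#' (missing, not zero).
#'
#' @param sheet Numeric matrix of placements (rows named by product, columns
#'   x/y), e.g. one element of `napping_dataset$sheets`.
#' @param products Ordered character vector of the full product list.
#' @return A `"per-rater"` [distance_matrix()].
#' @export
rater_distances <- function(sheet, products) {
  products <- as.character(products)
  placed <- intersect(products, rownames(sheet))
  if (length(placed) < 2L) {
    abort_insufficient("sheet places fewer than 2 of the listed products")
  }
  n <- length(products)
  v <- matrix(NA_real_, n, n, dimnames = list(products, products))
  d <- as.matrix(stats::dist(sheet[placed, , drop = FALSE]))
  v[placed, placed] <- d
  distance_matrix(v, provenance = "per-rater")
}

#' Panel aggregation of distances
#'
#' Generic: averages per-rater distance matrices into a single
#' panel-averaged product distance matrix (the core aggregation step of the
#' distance-and-cluster approach to Napping data).
#'
#' For a [qda_dataset()] this instead averages line-scale scores across
#' raters; see [panel_average.qda_dataset()].
#'
#' @param x A list of `"per-rater"` [distance_matrix()] objects, a
#'   [napping_dataset()], or a [qda_dataset()].
#' @param ... Passed to methods.
#' @export
panel_average <- function(x, ...) UseMethod("panel_average")

#' @describeIn panel_average Average a list of per-rater distance matrices.
#'   Cell (i, j) is the arithmetic mean of the per-rater distances (or of the
#'   squared distances, then square-rooted, when `squared = TRUE`) over the
#'   raters that placed both products.  The number of contributing raters is
#'   recorded per cell in `$support`.  A pair placed by no rater is missing;
#'   by default this is an error because downstream clustering needs a
#'   complete matrix.
#' @param squared Average squared distances and take the square root
#'   (default `FALSE`: plain distances, whose mean is again a metric).
#' @param normalize Divide each rater's matrix by its root-mean-square
#'   distance before averaging, neutralising rater-specific sheet extents
#'   (default `FALSE`; no such normalisation is implied by the method itself).
#' @param allow_missing Keep zero-support cells as `NA` instead of erroring.
#' @export
panel_average.list <- function(x, squared = FALSE, normalize = FALSE,
                               allow_missing = FALSE, ...) {
  if (length(x) < 1L) abort_validation("need at least one distance matrix")
  if (!all(vapply(x, inherits, logical(1), "distance_matrix"))) {
    abort_validation("all elements must be distance_matrix objects")
  }
  labels <- x[[1L]]$labels
  for (m in x) {
    if (!identical(m$labels, labels)) {
      abort_validation("all matrices must share the same label universe")
    }
  }
  n <- length(labels)
  acc <- matrix(0, n, n)
  supp <- matrix(0L, n, n)
  for (m in x) {
    v <- m$values
    if (normalize) {
      rms <- sqrt(mean(v[upper.tri(v)]^2, na.rm = TRUE))
      if (!is.finite(rms) || rms <= 0) abort_degenerate("cannot normalize a zero-spread sheet")
      v <- v / rms
    }
    if (squared) v <- v^2
    seen <- !is.na(v)
    acc[seen] <- acc[seen] + v[seen]
    supp <- supp + seen
  }
  avg <- acc / supp
  avg[supp == 0L] <- NA_real_
  if (squared) avg <- sqrt(avg)
  diag(avg) <- ifelse(diag(supp) > 0L, 0, NA_real_)
  off <- upper.tri(avg)
  if (any(is.na(avg[off]))) {
    if (!allow_missing) {
      abort_incomplete_panel(
        "some product pair was placed by no rater; set allow_missing = TRUE to keep NA cells")
    }
  }
  dimnames(avg) <- dimnames(supp) <- list(labels, labels)
  distance_matrix(avg, provenance = "panel-averaged", support = supp)
}

#' @describeIn panel_average Compute per-rater distances for every sheet in
#'   the dataset, then average them.
#' @export
panel_average.napping_dataset <- function(x, ...) {
  mats <- lapply(x$sheets, rater_distances, products = x$products)
  panel_average(unname(mats), ...)
}

#' Product distances in the concatenated (2m)-dimensional rater space
#'
#' Each product is described by the 2m-vector of its (x, y) coordinates
#' across all m raters; distances are Euclidean in that space.  Requires a
#' complete panel (every rater placed every product).  With
#' `center_per_rater`, each rater's coordinate pair is column-mean-centered
#' first (translation invariance); with `weight_per_rater`, each rater's
#' centered block is divided by its first singular value (the MFA group
#' weighting), which makes these distances identical to distances between
#' full-dimensional MFA scores.
#'
#' @param dataset A [napping_dataset()] with complete sheets.
#' @param center_per_rater Center each rater's columns (default `TRUE`).
#' @param weight_per_rater Apply 1/sigma1 MFA block weighting (default
#'   `FALSE`: raw-scale distances).
#' @return A `"concatenated"` [distance_matrix()].
#' @export
concatenated_distances <- function(dataset, center_per_rater = TRUE,
                                   weight_per_rater = FALSE) {
  X <- panel_block_matrix(dataset, center = center_per_rater,
                          weight = weight_per_rater)
  v <- as.matrix(stats::dist(X))
  dimnames(v) <- list(dataset$products, dataset$products)
  distance_matrix(v, provenance = "concatenated")
}

# n x 2m matrix of placements, products in dataset order, one 2-column block
# per rater; errors on incomplete panels.
panel_block_matrix <- function(dataset, center = TRUE, weight = FALSE) {
  products <- dataset$products
  blocks <- lapply(dataset$raters, function(r) {
    s <- dataset$sheets[[r]]
    if (is.null(s) || !all(products %in% rownames(s))) {
      abort_incomplete_panel(sprintf(
        "rater '%s' did not place every product; use panel_average() for pairwise-complete aggregation", r))
    }
    b <- s[products, , drop = FALSE]
    bc <- sweep(b, 2L, colMeans(b))
    if (weight) {
      s1 <- svd(bc, nu = 0, nv = 0)$d[1L]
      if (s1 <= 1e-12) {
        abort_degenerate(sprintf(
          "rater '%s' placed all products at one point (zero first singular value)", r))
      }
    }
    out <- if (center) bc else b
    if (weight) out <- out / s1
    out
  })
  X <- do.call(cbind, blocks)
  rownames(X) <- products
  colnames(X) <- paste(rep(dataset$raters, each = 2L), c("x", "y"), sep = ".")
  X
}
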