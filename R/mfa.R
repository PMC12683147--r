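#' Multiple Factor Analysis of a Napping panel
#'
#' Each rater contributes one group of two variables (the x and y
#' coordinates of the products on that rater's sheet).  Every group is
#' column-centered (no unit-variance scaling of coordinates) and divided by
#' its first singular value, so no single rater dominates the first global
#' dimension; the weighted blocks are concatenated into an n x 2m matrix and
#' decomposed by SVD.  Scores are U D; eigenvalues are the squared singular
#' values of the weighted, centered matrix (no n - 1 scaling -- percent
#' variance is scale-free either way).
#'
#' Sign convention: each dimension is flipped so that its largest-magnitude
#' score is positive, for reproducible orientation.
#'
#' @param dataset A [napping_dataset()] with a complete panel and `n >= 3`
#'   products.
#' @param n_dims Number of dimensions to retain (default: all nontrivial,
#'   at most `min(n - 1, 2m)`).
#' @param partial Also return per-rater partial coordinates (default FALSE).
#' @return An object of class `mfa_result`: `eigenvalues`, `scores` (n x D),
#'   `percent_variance`, `group_weights` (per-rater 1/sigma1), `loadings`,
#'   and optionally `partial` (list per rater).
#' @export
fit_mfa <- function(dataset, n_dims = NULL, partial = FALSE) {
  n <- length(dataset$products)
  m <- length(dataset$raters)
  if (n < 3L) abort_validation("MFA needs at least 3 products")
  X <- panel_block_matrix(dataset, center = TRUE, weight = FALSE)
  sigma1 <- vapply(seq_len(m), function(r) {
    svd(X[, (2L * r - 1L):(2L * r), drop = FALSE], nu = 0, nv = 0)$d[1L]
  }, numeric(1))
  degen <- which(sigma1 <= 1e-12)
  if (length(degen)) {
    abort_degenerate(sprintf(
      "rater '%s' placed all products at one point (zero first singular value)",
      dataset$raters[degen[1L]]))
  }
  Xw <- X / rep(sigma1, each = 2L)[col(X)]
  sv <- svd(Xw)
  keep <- which(sv$d > max(sv$d[1L], 1) * 1e-10)
  D_max <- length(keep)
  if (is.null(n_dims)) n_dims <- D_max
  n_dims <- min(n_dims, D_max)
  d <- sv$d[seq_len(n_dims)]
  scores <- sv$u[, seq_len(n_dims), drop = FALSE] %*% diag(d, n_dims)
  loadings <- sv$v[, seq_len(n_dims), drop = FALSE]
  # reproducible orientation
  for (j in seq_len(n_dims)) {
    if (scores[which.max(abs(scores[, j])), j] < 0) {
      scores[, j] <- -scores[, j]
      loadings[, j] <- -loadings[, j]
    }
  }
  eig_all <- sv$d[keep]^2
  rownames(scores) <- dataset$products
  colnames(scores) <- paste0("Dim", seq_len(n_dims))
  rownames(loadings) <- colnames(X)
  colnames(loadings) <- colnames(scores)
  out <- list(eigenvalues = eig_all[seq_len(n_dims)],
              eigenvalues_all = eig_all,
              scores = scores,
              percent_variance = 100 * eig_all[seq_len(n_dims)] / sum(eig_all),
              percent_variance_all = 100 * eig_all / sum(eig_all),
              group_weights = stats::setNames(1 / sigma1, dataset$raters),
              loadings = loadings,
              n_products = n, n_raters = m, n_dims = n_dims)
  if (partial) {
    out$partial <- lapply(seq_len(m), function(r) {
      cols <- (2L * r - 1L):(2L * r)
      P <- m * (Xw[, cols, drop = FALSE] %*% loadings[cols, , drop = FALSE])
      dimnames(P) <- dimnames(scores)
      P
    })
    names(out$partial) <- dataset$raters
  }
  structure(out, class = "mfa_result")
}

#' @export
print.mfa_result <- function(x, ...) {
  cat(sprintf("MFA of %d products x %d raters; %d dimensions retained\n",
              x$n_products, x$n_raters, x$n_dims))
  pv <- round(x$percent_variance, 1)
  cat("  % variance:", paste(pv, collapse = ", "), "\n")
  invisible(x)
}

#' Orthogonal Procrustes alignment (rotation/reflection + translation)
#'
#' Aligns configuration `A` onto reference `B` by translating both to their
#' centroids, rotating/reflecting `A` (no scaling), and restoring `B`'s
#' centroid.  Used to remove the arbitrary orientation of refitted MFA
#' configurations before comparing them.
#'
#' @param A,B Numeric matrices of identical dimension (rows = points).
#' @return The aligned version of `A`.
#' @export
procrustes_align <- function(A, B) {
  stopifnot(all(dim(A) == dim(B)))
  cA <- colMeans(A); cB <- colMeans(B)
  Ac <- sweep(A, 2L, cA)
  Bc <- sweep(B, 2L, cB)
  s <- svd(crossprod(Ac, Bc))
  R <- s$u %*% t(s$v)
  sweep(Ac %*% R, 2L, cB, `+`)
}

#' Bootstrap confidence ellipses for MFA product positions
#'
#' Raters are resampled with replacement (size m) B times; the MFA is refit
#' on each resample and its first two dimensions are aligned to the reference
#' configuration by orthogonal Procrustes (rotation + reflection +
#' translation, no scaling).  Each product's ellipse is the bivariate-normal
#' approximation of its bootstrap cloud at the requested level (chi-square
#' quantile with 2 df).
#'
#' @param dataset A [napping_dataset()] with a complete panel.
#' @param B Number of bootstrap replicates (>= 50; default 500).
#' @param level Confidence level in (0, 1); default 0.95.
#' @param seed Integer seed making the resampling reproducible.
#' @return Object of class `ellipse_set`: a data frame `ellipses` with
#'   columns `product`, `cx`, `cy`, `semi_major`, `semi_minor`, `angle`
#'   (radians), plus `level`, `B`, `B_used`, `n_skipped`, `seed`, the
#'   reference 2-D `scores`, and the aligned bootstrap `samples`
#'   (n x 2 x B_used array).
#' @export
bootstrap_ellipses <- function(dataset, B = 500L, level = 0.95, seed = NULL) {
  if (B < 50L) abort_usage("B must be at least 50")
  if (level <= 0 || level >= 1) abort_usage("level must be in (0, 1)")
  ref <- fit_mfa(dataset)
  ref2 <- ref$scores[, 1:2, drop = FALSE]
  m <- length(dataset$raters)
  n <- length(dataset$products)
  if (!is.null(seed)) set.seed(seed)
  samples <- array(NA_real_, c(n, 2L, B))
  used <- 0L
  skipped <- 0L
  for (b in seq_len(B)) {
    pick <- sample.int(m, m, replace = TRUE)
    boot <- resample_raters(dataset, pick)
    fit <- tryCatch(fit_mfa(boot, n_dims = 2L),
                    sensmap_degenerate_error = function(e) NULL)
    if (is.null(fit) || ncol(fit$scores) < 2L) {
      skipped <- skipped + 1L
      next
    }
    used <- used + 1L
    samples[, , used] <- procrustes_align(fit$scores[, 1:2, drop = FALSE], ref2)
  }
  if (skipped > 0L) {
    warning(sprintf("%d degenerate bootstrap replicate(s) skipped", skipped))
  }
  samples <- samples[, , seq_len(used), drop = FALSE]
  q <- stats::qchisq(level, df = 2L)
  ell <- do.call(rbind, lapply(seq_len(n), function(i) {
    pts <- t(samples[i, , , drop = TRUE])
    if (used == 1L) pts <- matrix(samples[i, , 1L], nrow = 1L)
    ctr <- colMeans(pts)
    S <- stats::cov(pts)
    if (anyNA(S)) S <- matrix(0, 2L, 2L)
    e <- eigen(S, symmetric = TRUE)
    ev <- pmax(e$values, 0)
    data.frame(product = dataset$products[i], cx = ctr[1L], cy = ctr[2L],
               semi_major = sqrt(ev[1L] * q), semi_minor = sqrt(ev[2L] * q),
               angle = atan2(e$vectors[2L, 1L], e$vectors[1L, 1L]))
  }))
  structure(list(ellipses = ell, level = level, B = B, B_used = used,
                 n_skipped = skipped, seed = seed, scores = ref2,
                 samples = samples),
            class = "ellipse_set")
}

#' @export
print.ellipse_set <- function(x, ...) {
  cat(sprintf("Bootstrap ellipses: %d products, level %.2f, B = %d (%d used)\n",
              nrow(x$ellipses), x$level, x$B, x$B_used))
  print(x$ellipses, digits = 4)
  invisible(x)
}

# dataset with raters drawn (with replacement) by index; duplicated raters
# are disambiguated so the result is a valid dataset
resample_raters <- function(dataset, pick) {
  new_ids <- sprintf("%s.%d", dataset$raters[pick], seq_along(pick))
  sheets <- dataset$sheets[dataset$raters[pick]]
  names(sheets) <- new_ids
  napping_dataset(dataset$products, new_ids, sheets,
                  descriptors = list(), metadata = dataset$metadata)
}

#' Projection-distortion diagnostic for the 2-D MFA map
#'
#' The 2-D MFA map is only a projection: two products that look close there
#' may be far apart in the full score space.  This report gives the percent
#' variance captured by the first two dimensions and, for every product
#' pair, the ratio of the full-dimensional score distance to the 2-D score
#' distance, flagging pairs whose 2-D distance understates the full distance
#' by more than `factor` (default 2).
#'
#' @param dataset A [napping_dataset()] with a complete panel.
#' @param factor Understatement ratio above which a pair is flagged.
#' @return Object of class `distortion_report`: `percent_variance_2d`,
#'   a `pairs` data frame (`product_a`, `product_b`, `d2`, `d_full`,
#'   `ratio`, `flagged`), and `worst` (the worst-offender pair row).
#' @export
projection_distortion <- function(dataset, factor = 2) {
  fit <- fit_mfa(dataset)
  d_full <- as.matrix(stats::dist(fit$scores))
  d2 <- as.matrix(stats::dist(fit$scores[, seq_len(min(2L, ncol(fit$scores))),
                                         drop = FALSE]))
  idx <- which(upper.tri(d_full), arr.ind = TRUE)
  ratio <- ifelse(d2[idx] > 0, d_full[idx] / d2[idx],
                  ifelse(d_full[idx] > 0, Inf, 1))
  pairs <- data.frame(product_a = dataset$products[idx[, 1L]],
                      product_b = dataset$products[idx[, 2L]],
                      d2 = d2[idx], d_full = d_full[idx], ratio = ratio,
                      flagged = ratio > factor)
  pv2 <- sum(fit$percent_variance_all[seq_len(min(2L, length(fit$percent_variance_all)))])
  structure(list(percent_variance_2d = pv2, pairs = pairs,
                 worst = pairs[which.max(pairs$ratio), ],
                 factor = factor),
            class = "distortion_report")
}

#' @export
print.distortion_report <- function(x, ...) {
  cat(sprintf("First 2 MFA dimensions explain %.1f%% of total variance\n",
              x$percent_variance_2d))
  nf <- sum(x$pairs$flagged)
  cat(sprintf("%d pair(s) understated by > %gx; worst: %s-%s (ratio %.2f)\n",
              nf, x$factor, x$worst$product_a, x$worst$product_b,
              x$worst$ratio))
  invisible(x)
}
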