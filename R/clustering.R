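#' Agglomerative average-linkage (UPGMA) clustering of products
#'
#' Builds the full merge history from a complete product distance matrix
#' using Lance-Williams updates for average linkage: after merging clusters
#' A and B, the distance of the merged cluster to any other cluster K is the
#' size-weighted mean (|A| d(A,K) + |B| d(B,K)) / (|A| + |B|), i.e. the mean
#' of all cross-cluster pairwise product distances (UPGMA).  Ties are broken
#' deterministically by the lexicographically smallest pair of cluster
#' indices (clusters indexed by creation order, leaves first).
#'
#' Average linkage admits no inversions, so merge heights are non-decreasing.
#'
#' @param dist A complete [distance_matrix()] with `n >= 2` products.
#' @return An object of class `cluster_result` with elements
#'   `merges` (list of `list(a, b, height)` member sets), `merge`/`height`
#'   (hclust-style encoding), and `labels`.
#' @seealso [cut.cluster_result()], [suggest_k()], [descriptor_profile()]
#' @export
agglomerate <- function(dist) {
  stopifnot(inherits(dist, "distance_matrix"))
  D <- dist$values
  n <- nrow(D)
  if (n < 2L) abort_validation("need at least 2 products")
  if (anyNA(D)) abort_validation("distance matrix has missing cells; aggregate with panel_average first")

  # active working copy indexed by cluster id (leaves 1..n, merges n+1..2n-1)
  size <- rep(1L, n)
  members <- as.list(seq_len(n))
  active <- seq_len(n)
  W <- matrix(NA_real_, 2L * n - 1L, 2L * n - 1L)
  W[1:n, 1:n] <- D
  merges <- vector("list", n - 1L)
  hc_merge <- matrix(0L, n - 1L, 2L)
  heights <- numeric(n - 1L)
  code <- -seq_len(n)  # hclust coding: leaves negative, merges positive

  for (step in seq_len(n - 1L)) {
    sub <- W[active, active, drop = FALSE]
    dmin <- min(sub[upper.tri(sub)])
    # lexicographically smallest (i, j) pair among ties
    hit <- which(sub == dmin & upper.tri(sub), arr.ind = TRUE)
    hit <- hit[order(hit[, 1L], hit[, 2L]), , drop = FALSE]
    i <- active[hit[1L, 1L]]
    j <- active[hit[1L, 2L]]
    new <- n + step
    size[new] <- size[i] + size[j]
    members[[new]] <- sort(c(members[[i]], members[[j]]))
    merges[[step]] <- list(a = dist$labels[members[[i]]],
                           b = dist$labels[members[[j]]],
                           height = dmin)
    hc_merge[step, ] <- sort(c(code[i], code[j]))
    heights[step] <- dmin
    code[new] <- step
    rest <- setdiff(active, c(i, j))
    if (length(rest)) {
      upd <- (size[i] * W[i, rest] + size[j] * W[j, rest]) / size[new]
      W[new, rest] <- W[rest, new] <- upd
    }
    active <- c(rest, new)
  }

  structure(list(merges = merges, merge = hc_merge, height = heights,
                 labels = dist$labels, n = n),
            class = "cluster_result")
}

#' @export
print.cluster_result <- function(x, ...) {
  cat(sprintf("Agglomerative (UPGMA) clustering of %d products; merge heights %s\n",
              x$n, paste(signif(x$height, 4), collapse = ", ")))
  invisible(x)
}

#' @export
as.hclust.cluster_result <- function(x, ...) {
  order <- leaf_order(x$merge, x$n)
  structure(list(merge = x$merge, height = x$height, order = order,
                 labels = x$labels, method = "average",
                 call = match.call(), dist.method = "euclidean"),
            class = "hclust")
}

leaf_order <- function(merge, n) {
  walk <- function(k) {
    if (k < 0L) return(-k)
    c(walk(merge[k, 1L]), walk(merge[k, 2L]))
  }
  walk(nrow(merge))
}

#' Cut a merge tree into k clusters (or at a height)
#'
#' Exactly one of `k` and `h` must be supplied.  Cluster ids are renumbered
#' by first product appearance in the dataset's product order, so labels are
#' stable across platforms.
#'
#' @param x A `cluster_result`.
#' @param k Number of clusters (1..n).
#' @param h Height threshold: all merges at height `<= h` are applied.
#' @param ... Unused.
#' @return Named integer vector: product -> cluster id.
#' @export
cut.cluster_result <- function(x, k = NULL, h = NULL, ...) {
  if (!is.null(k) && !is.null(h)) abort_usage("give either k or h, not both")
  if (is.null(k) && is.null(h)) abort_usage("one of k or h is required")
  n <- x$n
  if (!is.null(k)) {
    if (k < 1L || k > n) abort_usage(sprintf("k must be in 1..%d", n))
    n_merges <- n - k
  } else {
    if (h < 0) abort_usage("h must be >= 0")
    n_merges <- sum(x$height <= h)
  }
  grp <- seq_len(n)
  for (s in seq_len(n_merges)) {
    m <- x$merges[[s]]
    idx <- match(c(m$a, m$b), x$labels)
    grp[grp %in% grp[idx]] <- min(grp[idx])
  }
  ids <- match(grp, unique(grp))  # renumber by first appearance
  names(ids) <- x$labels
  ids
}

#' Advisory choice of the number of clusters by mean silhouette width
#'
#' The cut is a user decision (typically made on the dendrogram); this helper
#' scores candidate k by the mean silhouette width computed from the input
#' distance matrix and flags the maximiser.  It is advisory only and never
#' auto-applied.
#'
#' @param result A `cluster_result` from [agglomerate()].
#' @param dist The [distance_matrix()] that was clustered.
#' @param k_range Candidate numbers of clusters, within `[2, n - 1]`.
#' @return Data frame with columns `k`, `mean_silhouette`, `best`.
#' @export
suggest_k <- function(result, dist, k_range = NULL) {
  n <- result$n
  if (n < 3L) abort_validation("silhouette needs at least 3 products")
  if (is.null(k_range)) k_range <- 2:(n - 1L)
  if (any(k_range < 2L | k_range > n - 1L)) {
    abort_usage(sprintf("k_range must lie within [2, %d]", n - 1L))
  }
  ms <- vapply(k_range, function(k) {
    mean(silhouette_widths(cut(result, k = k), dist$values))
  }, numeric(1))
  data.frame(k = k_range, mean_silhouette = ms,
             best = seq_along(k_range) == which.max(ms))
}

# silhouette width per point from a full distance matrix;
# singletons get 0 by the usual convention, as does a(i)=b(i)=0
silhouette_widths <- function(labels, D) {
  vapply(seq_along(labels), function(i) {
    own <- which(labels == labels[i])
    if (length(own) == 1L) return(0)
    a <- mean(D[i, setdiff(own, i)])
    b <- min(vapply(setdiff(unique(labels), labels[i]), function(cl) {
      mean(D[i, labels == cl])
    }, numeric(1)))
    if (max(a, b) == 0) 0 else (b - a) / max(a, b)
  }, numeric(1))
}

#' Descriptor-frequency profile of each cluster
#'
#' Counts free-text descriptor tokens per cluster over all (rater, product)
#' mentions whose product belongs to the cluster -- the frequency semantics
#' behind cluster word clouds.  Tokens were already split, trimmed and
#' lower-cased at load; an optional stop list removes uninformative tokens.
#'
#' @param dataset A [napping_dataset()] with descriptors.
#' @param labels Named cluster assignment (product -> cluster id), e.g. from
#'   [cut.cluster_result()].
#' @param stoplist Character vector of tokens to drop (default none).
#' @param top_k How many top tokens to list per cluster (default 10).
#' @return Object of class `descriptor_profile`: per cluster a sorted named
#'   count vector, the total token count, and the top-k tokens.
#' @export
descriptor_profile <- function(dataset, labels, stoplist = character(),
                               top_k = 10L) {
  missing_lab <- setdiff(dataset$products, names(labels))
  if (length(missing_lab)) {
    abort_validation(sprintf("no cluster label for product(s): %s",
                             paste(missing_lab, collapse = ", ")))
  }
  clusters <- sort(unique(labels))
  prof <- lapply(clusters, function(cl) {
    prods <- names(labels)[labels == cl]
    toks <- unlist(lapply(dataset$descriptors, function(by_prod) {
      unlist(by_prod[intersect(names(by_prod), prods)], use.names = FALSE)
    }), use.names = FALSE)
    toks <- setdiff_keep(toks, stoplist)
    counts <- sort(table(toks), decreasing = TRUE)
    counts <- stats::setNames(as.integer(counts), names(counts))
    list(cluster = cl, counts = counts, total = sum(counts),
         top = utils::head(names(counts), top_k))
  })
  names(prof) <- as.character(clusters)
  structure(prof, class = "descriptor_profile")
}

setdiff_keep <- function(x, drop) x[!(x %in% drop)]

#' @export
print.descriptor_profile <- function(x, ...) {
  for (p in x) {
    cat(sprintf("cluster %s (%d tokens): %s\n", p$cluster, p$total,
                paste(p$top, collapse = ", ")))
  }
  invisible(x)
}

#' Serialize a merge tree as Newick
#'
#' Ultrametric convention: a node at merge height h sits at depth h/2, so a
#' child branch length is (h_parent - h_child) / 2 and leaves sit at depth 0.
#'
#' @param result A `cluster_result`.
#' @return A single Newick string (with trailing semicolon).
#' @export
cluster_newick <- function(result) {
  merge <- result$merge
  build <- function(k) {
    if (k < 0L) return(list(str = result$labels[-k], h = 0))
    a <- build(merge[k, 1L])
    b <- build(merge[k, 2L])
    h <- result$height[k]
    list(str = sprintf("(%s:%.10g,%s:%.10g)", a$str, (h - a$h) / 2,
                       b$str, (h - b$h) / 2),
         h = h)
  }
  paste0(build(nrow(merge))$str, ";")
}

#' Indented text rendering of the merge tree
#' @param result A `cluster_result`.
#' @return Character vector of lines.
#' @export
cluster_text_tree <- function(result) {
  merge <- result$merge
  lines <- character(0)
  walk <- function(k, depth) {
    pad <- strrep("  ", depth)
    if (k < 0L) {
      lines <<- c(lines, paste0(pad, result$labels[-k]))
    } else {
      lines <<- c(lines, sprintf("%s+ h=%.4g", pad, result$height[k]))
      walk(merge[k, 1L], depth + 1L)
      walk(merge[k, 2L], depth + 1L)
    }
  }
  walk(nrow(merge), 0L)
  lines
}
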