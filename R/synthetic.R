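#' Configuration for a simulated Napping panel
#'
#' The generator emulates m raters independently observing a latent 2-D
#' product configuration with cluster structure.  Each rater sees the latent
#' points through their own similarity transform -- rotation uniform on
#' \[0, 2pi), reflection with probability 1/2, translation uniform in a box,
#' log-normal sheet scale (median 1) -- plus isotropic Gaussian placement
#' noise, and emits free-text descriptors drawn from the product's cluster
#' vocabulary with a stated probability (otherwise from a shared noise
#' pool).
#'
#' Defaults mirror a realistic minced-sample panel: 10 products in 4 latent
#' clusters of sizes 2, 6, 1, 1 (two replicate servings of five
#' breed-by-feeding groups), 12 trained raters, cluster centers about 20 cm
#' apart on the sheet, 1 cm within-cluster spread and 1 cm placement noise,
#' and a fixed sheet scale (log-SD 0) so that distances are exactly
#' recoverable in the noise-free limit.
#'
#' @param n_products Number of products (>= 2).
#' @param cluster_assignment Integer vector (length `n_products`) of latent
#'   cluster ids.
#' @param cluster_centers Matrix (k x 2) of latent cluster centers, cm.
#' @param within_sd Within-cluster latent spread SD, cm.
#' @param m_raters Number of raters (>= 1).
#' @param translation_box Half-width of the uniform translation box, cm.
#' @param scale_log_sd Log-SD of the per-rater log-normal sheet scale
#'   (median 1; 0 = all raters use the same scale).
#' @param reflect_prob Probability a rater's sheet is mirror-imaged.
#' @param noise_sd Isotropic placement noise SD, cm.
#' @param vocab List (one character vector per cluster) of cluster
#'   descriptor vocabularies.
#' @param emission_prob Probability a descriptor token comes from the
#'   product's cluster vocabulary rather than the noise pool.
#' @param noise_pool Shared pool of uninformative descriptor tokens.
#' @param descriptors_per_product Tokens emitted per (rater, product).
#' @return A validated `napping_sim_config` list.
#' @export
napping_sim_config <- function(n_products = 10L,
                               cluster_assignment = c(1L, 2L, 2L, 2L, 3L,
                                                      1L, 2L, 2L, 2L, 4L),
                               cluster_centers = NULL,
                               within_sd = 1,
                               m_raters = 12L,
                               translation_box = 10,
                               scale_log_sd = 0,
                               reflect_prob = 0.5,
                               noise_sd = 1,
                               vocab = list(c("sweet", "umami"),
                                            c("stable-like", "cabbage"),
                                            c("sour", "metallic"),
                                            c("fatty", "pepper")),
                               emission_prob = 0.8,
                               noise_pool = c("meaty", "bland", "juicy", "dry"),
                               descriptors_per_product = 2L) {
  if (n_products < 2L) abort_validation("n_products must be >= 2")
  if (m_raters < 1L) abort_validation("m_raters must be >= 1")
  if (length(cluster_assignment) != n_products) {
    abort_validation("cluster_assignment must have one entry per product")
  }
  k <- max(cluster_assignment)
  if (is.null(cluster_centers)) {
    # centers on a 20 cm grid: pairwise separation >= 20 cm
    grid <- expand.grid(x = c(0, 20), y = c(0, 20))
    if (k > nrow(grid)) {
      ang <- 2 * pi * seq_len(k) / k
      cluster_centers <- 20 * cbind(cos(ang), sin(ang))
    } else {
      cluster_centers <- as.matrix(grid[seq_len(k), ])
    }
  }
  cluster_centers <- as.matrix(cluster_centers)
  if (nrow(cluster_centers) < k) abort_validation("fewer centers than clusters")
  if (within_sd < 0 || noise_sd < 0 || scale_log_sd < 0) {
    abort_validation("SDs must be nonnegative")
  }
  if (emission_prob < 0 || emission_prob > 1 ||
      reflect_prob < 0 || reflect_prob > 1) {
    abort_validation("probabilities must lie in [0, 1]")
  }
  if (length(vocab) < k) abort_validation("need a vocabulary per cluster")
  structure(list(n_products = as.integer(n_products),
                 cluster_assignment = as.integer(cluster_assignment),
                 cluster_centers = cluster_centers, within_sd = within_sd,
                 m_raters = as.integer(m_raters),
                 translation_box = translation_box,
                 scale_log_sd = scale_log_sd, reflect_prob = reflect_prob,
                 noise_sd = noise_sd, vocab = vocab,
                 emission_prob = emission_prob, noise_pool = noise_pool,
                 descriptors_per_product = as.integer(descriptors_per_product)),
            class = "napping_sim_config")
}

# one deterministic sub-seed per rater so adding raters never perturbs
# earlier raters' data; kept below 2^31 - 1
rater_seed <- function(seed, r) (as.numeric(seed) + r * 7919) %% 2147483647

#' Simulate a Napping panel with known ground truth
#'
#' @param config A [napping_sim_config()].
#' @param seed Integer seed; the latent configuration uses `seed` directly
#'   and each rater a derived sub-stream.
#' @return List with `dataset` (a [napping_dataset()] including a
#'   `breed_feeding`-style metadata factor), `latent` (n x 2 latent
#'   coordinates), `truth` (named latent cluster ids), and `config`.
#' @export
simulate_napping <- function(config, seed = 1L) {
  stopifnot(inherits(config, "napping_sim_config"))
  n <- config$n_products
  m <- config$m_raters
  products <- sprintf("P%02d", seq_len(n))
  set.seed(seed)
  latent <- config$cluster_centers[config$cluster_assignment, , drop = FALSE] +
    matrix(stats::rnorm(2L * n, sd = config$within_sd), n, 2L)
  dimnames(latent) <- list(products, c("x", "y"))
  raters <- sprintf("R%02d", seq_len(m))
  sheets <- list()
  descriptors <- list()
  for (r in seq_len(m)) {
    set.seed(rater_seed(seed, r))
    theta <- stats::runif(1L, 0, 2 * pi)
    R <- matrix(c(cos(theta), sin(theta), -sin(theta), cos(theta)), 2L, 2L)
    if (stats::runif(1L) < config$reflect_prob) R <- R %*% diag(c(1, -1))
    s <- exp(stats::rnorm(1L, 0, config$scale_log_sd))
    tr <- stats::runif(2L, -config$translation_box, config$translation_box)
    obs <- s * (latent %*% R) +
      matrix(tr, n, 2L, byrow = TRUE) +
      matrix(stats::rnorm(2L * n, sd = config$noise_sd), n, 2L)
    dimnames(obs) <- list(products, c("x", "y"))
    sheets[[raters[r]]] <- obs
    if (config$descriptors_per_product > 0L) {
      by_prod <- lapply(seq_len(n), function(i) {
        cl <- config$cluster_assignment[i]
        vapply(seq_len(config$descriptors_per_product), function(j) {
          if (stats::runif(1L) < config$emission_prob) {
            sample(config$vocab[[cl]], 1L)
          } else {
            sample(config$noise_pool, 1L)
          }
        }, character(1))
      })
      names(by_prod) <- products
      descriptors[[raters[r]]] <- by_prod
    }
  }
  # five breed/feeding groups over replicate pairs, the design the panel
  # world emulates (two servings per group)
  groups <- c("STD", "BIExWR_NOR", "RAMxWR_NOR", "BIExWR_ALF", "RAMxWR_ALF")
  metadata <- data.frame(
    breed_feeding = groups[(seq_len(n) - 1L) %% length(groups) + 1L],
    row.names = products)
  dataset <- napping_dataset(products, raters, sheets,
                             descriptors = descriptors, metadata = metadata)
  truth <- stats::setNames(config$cluster_assignment, products)
  list(dataset = dataset, latent = latent, truth = truth, config = config)
}

#' Configuration for a simulated QDA panel
#'
#' Scores are generated as group mean + rater offset + residual noise,
#' truncated to the line scale.  Defaults mirror the trained-panel design:
#' 16 attributes, 12 raters, 5 breed/feeding groups with 2 servings each on
#' a 15 cm line scale, rater offset SD and residual SD of 1 scale unit, and
#' no true group differences (a null panel) -- effects are switched on
#' explicitly via `group_means`.
#'
#' @param n_groups Number of design groups.
#' @param n_attributes Number of attributes.
#' @param n_raters Number of raters.
#' @param servings_per_group Servings (samples) per group.
#' @param group_means Matrix (n_groups x n_attributes) of true means on the
#'   scale; default all 7.5 (mid-scale, no effects).
#' @param rater_offset_sd SD of rater-by-attribute offsets.
#' @param noise_sd Residual SD.
#' @param scale_max Line-scale upper bound (default 15).
#' @return A validated `qda_sim_config` list.
#' @export
qda_sim_config <- function(n_groups = 5L, n_attributes = 16L, n_raters = 12L,
                           servings_per_group = 2L, group_means = NULL,
                           rater_offset_sd = 1, noise_sd = 1,
                           scale_max = 15) {
  if (is.null(group_means)) {
    group_means <- matrix(scale_max / 2, n_groups, n_attributes)
  }
  group_means <- as.matrix(group_means)
  if (!all(dim(group_means) == c(n_groups, n_attributes))) {
    abort_validation("group_means must be n_groups x n_attributes")
  }
  if (any(group_means < 0 | group_means > scale_max)) {
    abort_validation("group means must lie within the scale bounds")
  }
  if (rater_offset_sd < 0 || noise_sd < 0) abort_validation("SDs must be nonnegative")
  structure(list(n_groups = as.integer(n_groups),
                 n_attributes = as.integer(n_attributes),
                 n_raters = as.integer(n_raters),
                 servings_per_group = as.integer(servings_per_group),
                 group_means = group_means,
                 rater_offset_sd = rater_offset_sd, noise_sd = noise_sd,
                 scale_max = scale_max),
            class = "qda_sim_config")
}

#' Simulate a QDA panel with known ground truth
#'
#' @param config A [qda_sim_config()].
#' @param seed Integer seed.
#' @return List with `dataset` (a [qda_dataset()] whose factor table has a
#'   `group` column), `group_means`, and `config`.  Scores are truncated to
#'   `[0, scale_max]`; with means >= 4 SD inside the bounds truncation is
#'   rare by construction.
#' @export
simulate_qda <- function(config, seed = 1L) {
  stopifnot(inherits(config, "qda_sim_config"))
  set.seed(seed)
  groups <- sprintf("G%d", seq_len(config$n_groups))
  attrs <- sprintf("attr%02d", seq_len(config$n_attributes))
  raters <- sprintf("R%02d", seq_len(config$n_raters))
  products <- sprintf("%s", rep(groups, each = config$servings_per_group))
  servings <- sprintf("%s_s%d", products,
                      rep(seq_len(config$servings_per_group), config$n_groups))
  products <- sprintf("%s_p%d", products,
                      rep(seq_len(config$servings_per_group), config$n_groups))
  offsets <- matrix(stats::rnorm(config$n_raters * config$n_attributes,
                                 sd = config$rater_offset_sd),
                    config$n_raters, config$n_attributes)
  grid <- expand.grid(rater = seq_along(raters), serving = seq_along(servings),
                      attribute = seq_along(attrs))
  gidx <- rep(seq_len(config$n_groups), each = config$servings_per_group)
  score <- config$group_means[cbind(gidx[grid$serving], grid$attribute)] +
    offsets[cbind(grid$rater, grid$attribute)] +
    stats::rnorm(nrow(grid), sd = config$noise_sd)
  score <- pmin(pmax(score, 0), config$scale_max)
  records <- data.frame(rater = raters[grid$rater],
                        product = products[grid$serving],
                        serving = servings[grid$serving],
                        attribute = attrs[grid$attribute],
                        score = score, stringsAsFactors = FALSE)
  factors <- data.frame(group = groups[gidx], row.names = products)
  dataset <- qda_dataset(records, factors = factors,
                         scale_max = config$scale_max)
  list(dataset = dataset, group_means = config$group_means, config = config)
}

#' The published worked-example contingency table
#'
#' The 5 x 4 cross-tabulation of five breed/feeding groups (rows
#' BIExWR_ALF, BIExWR_NOR, RAMxWR_ALF, RAMxWR_NOR, STD) against the four
#' product clusters found for the minced-thigh Napping panel: each group
#' contributed two replicate products, and the exact test of this table is
#' the package's reference worked example.
#'
#' @return A [contingency_table()] with N = 10.
#' @export
fixture_table10 <- function() {
  counts <- rbind(BIExWR_ALF = c(0L, 2L, 0L, 0L),
                  BIExWR_NOR = c(0L, 2L, 0L, 0L),
                  RAMxWR_ALF = c(0L, 0L, 1L, 1L),
                  RAMxWR_NOR = c(0L, 2L, 0L, 0L),
                  STD        = c(2L, 0L, 0L, 0L))
  colnames(counts) <- as.character(1:4)
  contingency_table(counts)
}
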