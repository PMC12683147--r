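# explicit-oracle MFA: build the weighted matrix step by step and take a
# dense eigendecomposition of its cross-product
oracle_mfa_eigen <- function(dataset) {
  blocks <- lapply(dataset$raters, function(r) {
    b <- dataset$sheets[[r]][dataset$products, ]
    b <- sweep(b, 2, colMeans(b))
    b / svd(b)$d[1]
  })
  X <- do.call(cbind, blocks)
  ev <- eigen(X %*% t(X), symmetric = TRUE)$values
  ev[ev > 1e-10]
}

test_that("a collinear single-rater panel is one-dimensional", {
  sheet <- make_sheet(P1 = c(0, 0), P2 = c(1, 1), P3 = c(2, 2), P4 = c(5, 5))
  d <- napping_dataset(paste0("P", 1:4), "r1", list(r1 = sheet))
  fit <- fit_mfa(d)
  expect_equal(fit$percent_variance[1], 100)
  expect_equal(fit$n_dims, 1)
})

test_that("duplicating the panel preserves the variance profile", {
  panel <- random_panel(n = 6, m = 4, seed = 14)
  dup_sheets <- c(panel$sheets, setNames(panel$sheets, paste0("dup_",
                                                              panel$raters)))
  dup <- napping_dataset(panel$products, names(dup_sheets), dup_sheets)
  f1 <- fit_mfa(panel)
  f2 <- fit_mfa(dup)
  expect_equal(f2$percent_variance_all, f1$percent_variance_all,
               tolerance = 1e-10)
  # under 1/sigma1 block weighting, duplication doubles every eigenvalue, so
  # scores match up to sign after rescaling by sqrt(2)
  expect_equal(abs(f2$scores), sqrt(2) * abs(f1$scores), tolerance = 1e-8)
})

test_that("eigenvalues match the explicit weighted-matrix oracle", {
  panel <- random_panel(n = 10, m = 12, seed = 15)
  fit <- fit_mfa(panel)
  expect_equal(fit$eigenvalues_all, oracle_mfa_eigen(panel), tolerance = 1e-8)
  # percent variances sum to 100, eigenvalues are sorted and nonnegative
  expect_equal(sum(fit$percent_variance_all), 100, tolerance = 1e-8)
  expect_true(all(diff(fit$eigenvalues_all) <= 1e-10))
  expect_true(all(fit$eigenvalues_all >= -1e-10))
  expect_lte(length(fit$eigenvalues_all), min(10 - 1, 2 * 12))
})

test_that("after weighting every rater block has first singular value 1", {
  panel <- random_panel(n = 7, m = 5, seed = 16)
  fit <- fit_mfa(panel)
  for (r in panel$raters) {
    b <- panel$sheets[[r]][panel$products, ]
    b <- sweep(b, 2, colMeans(b))
    expect_equal(svd(b * fit$group_weights[[r]])$d[1], 1, tolerance = 1e-10)
  }
})

test_that("rigid motions leave eigenvalues fixed and rotate scores at most", {
  panel <- random_panel(n = 6, m = 4, seed = 17)
  set.seed(4)
  moved <- panel
  for (r in moved$raters) {
    moved$sheets[[r]] <- transform_sheet(moved$sheets[[r]],
                                         theta = runif(1, 0, 2 * pi),
                                         reflect = runif(1) < 0.5,
                                         translate = runif(2, -30, 30))
  }
  f1 <- fit_mfa(panel)
  f2 <- fit_mfa(moved)
  expect_equal(f2$eigenvalues_all, f1$eigenvalues_all, tolerance = 1e-8)
  expect_equal(f2$percent_variance_all, f1$percent_variance_all,
               tolerance = 1e-8)
  aligned <- procrustes_align(f2$scores, f1$scores)
  expect_lt(max(abs(aligned - f1$scores)), 1e-8)
})

test_that("degenerate raters are reported by name", {
  sheets <- list(r1 = make_sheet(P1 = c(0, 0), P2 = c(1, 0), P3 = c(0, 1)),
                 bad = make_sheet(P1 = c(2, 2), P2 = c(2, 2), P3 = c(2, 2)))
  d <- napping_dataset(paste0("P", 1:3), c("r1", "bad"), sheets)
  expect_error(fit_mfa(d), "bad", class = "sensmap_degenerate_error")
})

test_that("full-space score distances equal weighted concatenated distances", {
  panel <- random_panel(n = 8, m = 6, seed = 18)
  fit <- fit_mfa(panel)
  d_scores <- as.matrix(dist(fit$scores))
  d_concat <- concatenated_distances(panel, center_per_rater = TRUE,
                                     weight_per_rater = TRUE)$values
  expect_lt(max(abs(d_scores - d_concat)), 1e-8)
})

test_that("bootstrap ellipses are seed-deterministic and collapse for m = 1", {
  panel <- random_panel(n = 5, m = 4, seed = 19)
  e1 <- bootstrap_ellipses(panel, B = 60, seed = 123)
  e2 <- bootstrap_ellipses(panel, B = 60, seed = 123)
  expect_identical(e1$ellipses, e2$ellipses)
  e3 <- bootstrap_ellipses(panel, B = 60, seed = 124)
  expect_false(identical(e1$ellipses, e3$ellipses))

  single <- napping_dataset(panel$products, "R01", panel$sheets["R01"])
  es <- bootstrap_ellipses(single, B = 50, seed = 1)
  expect_lt(max(es$ellipses$semi_major), 1e-10)

  expect_error(bootstrap_ellipses(panel, B = 10), class = "sensmap_usage_error")
})

test_that("95% ellipses cover the aligned truth for most products", {
  # scaled-down coverage check (outer replicates and B reduced to fit the
  # test budget; the generator's panel is the stated 12-rater, 10-product
  # world with isotropic 1 cm noise)
  cfg <- napping_sim_config()
  # similarity (scaled) Procrustes: the latent map is in cm while MFA scores
  # live on the sigma1-weighted scale, so the test alignment must rescale
  scaled_align <- function(A, B) {
    Ac <- sweep(A, 2, colMeans(A)); Bc <- sweep(B, 2, colMeans(B))
    s <- svd(crossprod(Ac, Bc))
    R <- s$u %*% t(s$v)
    sc <- sum(s$d) / sum(Ac^2)
    sweep(sc * Ac %*% R, 2, colMeans(B), `+`)
  }
  n_outer <- 25
  hits <- 0L
  total <- 0L
  for (i in seq_len(n_outer)) {
    sim <- simulate_napping(cfg, seed = 9000 + i)
    ell <- bootstrap_ellipses(sim$dataset, B = 80, seed = 100 + i)
    ref <- fit_mfa(sim$dataset)$scores[, 1:2]
    truth_aligned <- scaled_align(sim$latent, ref)
    for (p in seq_len(nrow(ref))) {
      mu <- c(ell$ellipses$cx[p], ell$ellipses$cy[p])
      ang <- ell$ellipses$angle[p]
      R <- matrix(c(cos(ang), sin(ang), -sin(ang), cos(ang)), 2, 2)
      z <- t(R) %*% (truth_aligned[p, ] - mu)
      md <- (z[1] / ell$ellipses$semi_major[p])^2 +
        (z[2] / ell$ellipses$semi_minor[p])^2
      hits <- hits + (md <= 1)
      total <- total + 1L
    }
  }
  expect_gte(hits / total, 0.9)
})

test_that("projection_distortion reports honest 2-D maps as exact", {
  sheet <- make_sheet(P1 = c(0, 0), P2 = c(4, 1), P3 = c(1, 5), P4 = c(6, 6))
  same <- napping_dataset(paste0("P", 1:4), c("r1", "r2"),
                          list(r1 = sheet, r2 = sheet))
  rep_same <- projection_distortion(same)
  expect_equal(rep_same$percent_variance_2d, 100, tolerance = 1e-8)
  expect_lt(max(abs(rep_same$pairs$ratio - 1)), 1e-8)

  # m = 1: rank <= 2, so the 2-D scores reproduce full distances exactly
  single <- napping_dataset(paste0("P", 1:4), "r1", list(r1 = sheet))
  rep1 <- projection_distortion(single)
  expect_lt(max(abs(rep1$pairs$d2 - rep1$pairs$d_full)), 1e-10)

  # high-m random panel: full score distances equal weighted concatenation
  panel <- random_panel(n = 6, m = 10, seed = 20)
  repm <- projection_distortion(panel)
  dw <- concatenated_distances(panel, TRUE, TRUE)$values
  for (row in seq_len(nrow(repm$pairs))) {
    expect_equal(repm$pairs$d_full[row],
                 dw[repm$pairs$product_a[row], repm$pairs$product_b[row]],
                 tolerance = 1e-8)
  }
})
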