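test_that("panel_average averages scores across raters", {
  rec <- data.frame(rater = c("r1", "r2"), product = "p1", serving = "s1",
                    attribute = "a", score = c(40, 60) / 10)
  d <- qda_dataset(rec, scale_max = 15)
  pm <- panel_average(d)
  expect_equal(pm$score, 5)        # mean of 4 and 6
  expect_equal(pm$n_raters, 2L)

  # single rater: identity
  d1 <- two_group_qda()
  pm1 <- panel_average(d1)
  expect_equal(sort(pm1$score), 1:6)

  # random panel vs an explicit group-by loop
  sim <- simulate_qda(qda_sim_config(n_attributes = 3), seed = 6)
  pm2 <- panel_average(sim$dataset)
  rec2 <- sim$dataset$records
  for (row in sample(nrow(pm2), 10)) {
    sel <- rec2$serving == pm2$serving[row] & rec2$attribute == pm2$attribute[row]
    expect_equal(pm2$score[row], mean(rec2$score[sel]), tolerance = 1e-12)
  }
})

test_that("panel_average flags servings missing an attribute", {
  rec <- data.frame(rater = "r1", product = c("p1", "p1", "p2"),
                    serving = c("s1", "s1", "s2"),
                    attribute = c("a", "b", "a"), score = 1:3)
  d <- qda_dataset(rec)
  expect_warning(pm <- panel_average(d), "no records")
  mc <- attr(pm, "missing_cells")
  expect_equal(mc$serving, "s2")
  expect_equal(mc$attribute, "b")
})

test_that("attribute_anova matches the hand sum-of-squares computation", {
  pm <- panel_average(two_group_qda())
  res <- attribute_anova(pm, "group")
  expect_equal(res$F, 13.5)
  expect_equal(res$df1, 1L)
  expect_equal(res$df2, 4L)
  expect_equal(res$N, 6L)
  expect_equal(res$sig, sig <- if (res$p_value < 0.05) "*" else "")
})

test_that("two-way attribute_anova matches an explicit least-squares oracle", {
  set.seed(77)
  fac <- expand.grid(breed = c("A", "B", "C"), feeding = c("ALF", "NOR"))
  fac <- fac[rep(seq_len(nrow(fac)), each = 2), ]   # 2 servings per cell
  n <- nrow(fac)
  prods <- sprintf("p%02d", seq_len(n))
  score <- 5 + (fac$breed == "B") * 1.5 + (fac$feeding == "ALF") * 0.8 +
    rnorm(n, sd = 0.5)
  rec <- data.frame(rater = "r1", product = prods, serving = prods,
                    attribute = "a", score = score)
  d <- qda_dataset(rec, factors = data.frame(breed = fac$breed,
                                             feeding = fac$feeding,
                                             row.names = prods))
  res <- attribute_anova(panel_average(d), c("breed", "feeding"))

  # oracle: sequential F-tests from explicit normal-equations fits
  rss <- function(X) {
    beta <- solve(t(X) %*% X, t(X) %*% score)
    sum((score - X %*% beta)^2)
  }
  X0 <- matrix(1, n)
  Xb <- cbind(X0, fac$breed == "B", fac$breed == "C")
  Xbf <- cbind(Xb, fac$feeding == "NOR")
  df_res <- n - ncol(Xbf)
  s2 <- rss(Xbf) / df_res
  F_breed <- ((rss(X0) - rss(Xb)) / 2) / s2
  F_feed <- ((rss(Xb) - rss(Xbf)) / 1) / s2
  expect_equal(res$F[res$term == "breed"], F_breed, tolerance = 1e-8)
  expect_equal(res$F[res$term == "feeding"], F_feed, tolerance = 1e-8)
  expect_equal(unique(res$df2), df_res)

  # interaction flag adds the interaction term
  res_i <- attribute_anova(panel_average(d), c("breed", "feeding"),
                           interaction = TRUE)
  expect_true("breed:feeding" %in% res_i$term)
})

test_that("attribute_anova rejects degenerate designs", {
  rec <- data.frame(rater = "r1", product = c("p1", "p2"),
                    serving = c("s1", "s2"), attribute = "a", score = c(1, 2))
  d <- qda_dataset(rec, factors = data.frame(group = c("A", "B"),
                                             row.names = c("p1", "p2")))
  expect_error(attribute_anova(panel_average(d), "group"),
               class = "sensmap_validation_error")
  expect_error(attribute_anova(panel_average(d), "nope"),
               class = "sensmap_validation_error")
})

test_that("pairwise_ttests uses the pooled one-way error", {
  pm <- panel_average(two_group_qda())
  res <- pairwise_ttests(pm, "attr", "group")
  expect_equal(nrow(res), 1L)
  expect_equal(res$diff, -3)
  expect_equal(abs(res$t), 3 / sqrt(2 / 3), tolerance = 1e-10)
  expect_equal(res$df, 4)
  expect_true(res$ci_lo <= res$diff && res$diff <= res$ci_hi)

  # F = t^2 bridge with the one-way ANOVA
  an <- attribute_anova(pm, "group")
  expect_equal(an$F, res$t^2, tolerance = 1e-10)

  # group means carry their own confidence intervals
  gm <- attr(res, "group_means")
  expect_equal(gm$mean, c(2, 5))
  expect_true(all(gm$ci_lo < gm$mean & gm$mean < gm$ci_hi))
})

test_that("pairwise_ttests enumerates all pairs and adjusts the family", {
  sim <- simulate_qda(qda_sim_config(n_groups = 4, n_attributes = 1),
                      seed = 12)
  pm <- panel_average(sim$dataset)
  res <- pairwise_ttests(pm, "attr01", "group", adjust = "holm")
  expect_equal(nrow(res), 4 * 3 / 2)
  expect_equal(res$p_adjusted, adjust_p(res$p_value, "holm"))
  # identical groups give t = 0, p = 1
  rec <- data.frame(rater = "r1", product = c("a1", "a2", "b1", "b2"),
                    serving = c("a1", "a2", "b1", "b2"), attribute = "z",
                    score = c(1, 3, 1, 3))
  d <- qda_dataset(rec, factors = data.frame(group = c("A", "A", "B", "B"),
                                             row.names = c("a1", "a2", "b1", "b2")))
  r0 <- pairwise_ttests(panel_average(d), "z", "group")
  expect_equal(r0$t, 0)
  expect_equal(r0$p_value, 1)
})

test_that("subject fixed effects absorb rater offsets", {
  sim <- simulate_qda(qda_sim_config(n_attributes = 2, n_raters = 6,
                                     rater_offset_sd = 2), seed = 13)
  base <- subject_effects_anova(sim$dataset, "group")

  # adding a constant to one rater's scores changes nothing in the
  # subject-effects F ...
  shifted <- sim$dataset
  sel <- shifted$records$rater == "R01"
  shifted$records$score[sel] <- shifted$records$score[sel] + 3
  shifted_res <- subject_effects_anova(shifted, "group")
  expect_equal(shifted_res$F, base$F, tolerance = 1e-10)
  expect_equal(shifted_res$p_value, base$p_value, tolerance = 1e-10)

  # ... but does change the plain ANOVA on raw panelist-level data
  raw_anova <- function(ds) {
    rec <- ds$records
    sapply(split(rec, rec$attribute), function(g) {
      g$group <- factor(ds$factors[g$product, "group"])
      anova(lm(score ~ group, data = g))$`F value`[1]
    })
  }
  expect_false(isTRUE(all.equal(raw_anova(shifted), raw_anova(sim$dataset),
                                tolerance = 1e-6)))
})

test_that("subject_effects_anova handles single raters and confounding", {
  d1 <- two_group_qda()
  res <- subject_effects_anova(d1, "group")
  # single rater: no subject variation to absorb; equals the plain one-way
  plain <- attribute_anova(panel_average(d1), "group")
  expect_equal(res$F, plain$F, tolerance = 1e-10)
  expect_equal(res$p_value, plain$p_value, tolerance = 1e-10)

  # every rater sees only one group: confounded
  rec <- data.frame(rater = rep(c("r1", "r2"), each = 4),
                    product = rep(c("a1", "a2", "b1", "b2"), each = 2),
                    serving = paste0("s", 1:8), attribute = "z",
                    score = rnorm(8, 5))
  d <- qda_dataset(rec, factors = data.frame(group = c("A", "A", "B", "B"),
                                             row.names = c("a1", "a2", "b1", "b2")))
  expect_error(subject_effects_anova(d, "group"),
               class = "sensmap_validation_error")
})

test_that("pvalue_ecdf measures departure from uniformity", {
  n <- 20
  grid <- (1:n) / n
  e <- pvalue_ecdf(grid)
  expect_lte(e$ks_distance, 1 / n + 1e-12)

  e0 <- pvalue_ecdf(rep(0, 5))
  expect_equal(e0$ks_distance, 1)

  set.seed(99)
  p <- runif(16)
  e1 <- pvalue_ecdf(p)
  expect_equal(e1$ks_distance, oracle_ks_uniform(p), tolerance = 1e-12)
  expect_true(all(diff(e1$step_y) >= 0))
  expect_equal(range(e1$step_y), c(0, 1))

  grouped <- pvalue_ecdf(c(p, p / 2), group = rep(c("s1", "s2"), each = 16))
  expect_length(grouped$by_group, 2)

  expect_error(pvalue_ecdf(numeric(0)), class = "sensmap_validation_error")
  expect_error(pvalue_ecdf(c(0.5, 2)), class = "sensmap_validation_error")
})
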