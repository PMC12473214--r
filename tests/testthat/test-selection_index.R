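test_that("the published index weights follow from the bundled PCA tables", {
  ref <- alfalfa_reference()
  loadings <- as.matrix(ref$loadings[, -1]); rownames(loadings) <- ref$loadings$trait
  coef <- component_coefficients(loadings, ref$variance$eigenvalue)
  model <- build_index(coef, variance_pct = ref$variance$variance_pct)
  printed <- setNames(ref$index_weights$weight, ref$index_weights$trait)
  expect_lt(max(abs(model$weights - printed[trait_names()])), 5e-4 + 1e-9)
})

test_that("a single retained component makes the weights its coefficients", {
  coef <- matrix(c(0.4, -0.3, 0.5, 0.2, -0.1, 0.67), ncol = 1,
                 dimnames = list(trait_names(), "PC1"))
  model <- build_index(coef, variance_pct = 40)
  expect_equal(unname(model$weights), unname(drop(coef))) # normalization cancels
})

test_that("weights equal the explicit sum-and-divide oracle", {
  set.seed(31)
  for (i in 1:10) {
    coef <- matrix(rnorm(18), 6, dimnames = list(trait_names(), NULL))
    v <- runif(3, 5, 40)
    w <- build_index(coef, variance_pct = v)$weights
    manual <- sapply(1:6, function(j) sum(coef[j, ] * v) / sum(v))
    expect_equal(unname(w), manual, tolerance = 1e-12)
  }
})

test_that("an empty retention is an error", {
  tab <- random_trait_table(50, seed = 32)
  pca <- pca_correlation(standardize(tab))
  expect_error(build_index(pca, k = 0), "retained|k in")
})

test_that("composite scores are weighted sums with mean zero", {
  ref <- alfalfa_reference()
  w <- setNames(ref$index_weights$weight, ref$index_weights$trait)[trait_names()]
  model <- structure(list(weights = w, scoring_scale = "standardized"),
                     class = "index_model")
  z_unit <- structure(list(z = diag(6)[2, , drop = FALSE], ids = "u",
                           center = rep(0, 6), scale = rep(1, 6)),
                      class = "standardized_matrix")
  colnames(z_unit$z) <- trait_names()
  expect_equal(composite_scores(model, z_unit)$score, 0.360) # branch weight
  z_unit$z[] <- 0
  expect_equal(composite_scores(model, z_unit)$score, 0)

  tab <- random_trait_table(2000, seed = 33)
  z <- standardize(tab)
  pca <- pca_correlation(z)
  model <- build_index(pca)
  sc <- composite_scores(model, z)
  expect_lt(abs(mean(sc$score)), 1e-8)
  manual <- sapply(1:15, function(i) sum(model$weights * z$z[i, ]))
  expect_equal(sc$score[1:15], manual, tolerance = 1e-12)
})

test_that("two-step component-score route equals the direct weighted sum", {
  tab <- random_trait_table(200, seed = 34)
  z <- standardize(tab)
  pca <- pca_correlation(z)
  model <- build_index(pca)
  k <- model$k
  direct <- composite_scores(model, z)$score
  pcs <- component_scores(z, pca$coefficients[, 1:k, drop = FALSE])
  v <- pca$variance_pct[1:k]
  two_step <- drop(pcs %*% v) / sum(v)
  expect_equal(direct, unname(two_step), tolerance = 1e-10)
})

test_that("centered scoring uses raw mean-deviations", {
  tab <- random_trait_table(100, seed = 35)
  z <- standardize(tab)
  pca <- pca_correlation(z)
  model <- build_index(pca, scoring_scale = "centered")
  sc <- composite_scores(model, z)
  dev <- sweep(as.matrix(as.data.frame(tab)[trait_names()]), 2, z$center, "-")
  expect_equal(sc$score, unname(drop(dev %*% model$weights)), tolerance = 1e-9)
  # dry weight has by far the widest raw range, so it dominates the variance
  expect_gt(sd(sc$score), sd(composite_scores(build_index(pca), z)$score))
})

test_that("threshold selection on the published ranking picks the 28 elites", {
  scores <- alfalfa_reference()$f1_scores
  scores$id <- sprintf("F1_%02d", scores$rank)
  sel <- rank_and_select(scores[c("id", "score")], select_threshold(1))
  expect_length(sel$selected_ids, 28)
  expect_equal(sel$fraction, 28 / 90, tolerance = 1e-12)
  expect_equal(sel$ranking$score[28], 1.54)  # last one in
  expect_false(sel$ranking$selected[29])     # 0.95 stays out
  expect_equal(sel$ranking$score[29], 0.95)
  expect_true(all(sel$ranking$score[sel$ranking$selected] >=
                    max(sel$ranking$score[!sel$ranking$selected])))
})

test_that("tie and boundary semantics are explicit", {
  scores <- data.frame(id = c("a", "b", "c", "d"), score = c(3, 2, 2, 1))
  expect_message(sel <- rank_and_select(scores, select_top_n(2)), "realized")
  expect_length(sel$selected_ids, 3) # the tie at 2 is absorbed
  expect_equal(sel$fraction, 0.75)
  expect_equal(sel$ranking$rank, c(1, 2, 2, 3)) # dense ranks

  none <- rank_and_select(scores, select_threshold(10))
  expect_length(none$selected_ids, 0)

  # ties exactly at a threshold are excluded (strictly greater than)
  at <- rank_and_select(scores, select_threshold(2))
  expect_equal(at$selected_ids, "a")

  expect_error(rank_and_select(scores[0, ], select_threshold(0)), "empty")
  expect_error(select_top_fraction(1.2), "fraction")
})

test_that("threshold and top-n selections coincide without boundary ties", {
  set.seed(36)
  scores <- data.frame(id = sprintf("s%03d", 1:50), score = rnorm(50))
  t <- 0.3
  sel_t <- rank_and_select(scores, select_threshold(t))
  sel_n <- rank_and_select(scores, select_top_n(sum(scores$score > t)))
  expect_setequal(sel_t$selected_ids, sel_n$selected_ids)
})

test_that("raising a positively weighted trait never lowers an individual's rank", {
  tab <- random_trait_table(50, seed = 37)
  z <- standardize(tab)
  model <- build_index(pca_correlation(z))
  pos_trait <- names(which(model$weights > 0))[1]
  sc0 <- composite_scores(model, z)
  r0 <- rank_and_select(sc0, select_threshold(-Inf))$ranking
  for (bump in c(0.5, 1, 2)) {
    z2 <- z
    z2$z[5, pos_trait] <- z$z[5, pos_trait] + bump
    r1 <- rank_and_select(composite_scores(model, z2),
                          select_threshold(-Inf))$ranking
    id5 <- z$ids[5]
    expect_lte(r1$rank[r1$id == id5], r0$rank[r0$id == id5])
  }
})
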