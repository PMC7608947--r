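test_that("AUC satisfies its rank-statistic identities", {
  expect_identical(auc(c(1, 2, 3), c(1, 2, 3)), 0.5)
  expect_identical(auc(1:5, 6:10), 1)
  expect_identical(auc(6:10, 1:5), 0)
  expect_equal(auc(c(1, 2, 3), c(2, 3, 4)), 7 / 9)
  expect_error(auc(numeric(0), 1:3), "nonempty")

  withr::local_seed(11)
  for (i in 1:50) {
    a <- sample(0:8, sample(2:40, 1), replace = TRUE)  # ties guaranteed
    b <- sample(0:8, sample(2:40, 1), replace = TRUE)
    expect_equal(auc(a, b) + auc(b, a), 1)
    expect_equal(auc(a, b), auc_brute(a, b), tolerance = 1e-12)
    expect_equal(auc(exp(a), exp(b)), auc(a, b))  # monotone-transform invariant
  }
})

test_that("the ROC curve integrates to the rank AUC", {
  withr::local_seed(12)
  a <- rnorm(40)
  b <- rnorm(35, mean = 0.8)
  rc <- roc_curve(a, b)
  expect_equal(c(rc$fa[1], rc$hit[1]), c(1, 1))
  expect_equal(c(rc$fa[nrow(rc)], rc$hit[nrow(rc)]), c(0, 0))
  area <- -sum(diff(rc$fa) * (rc$hit[-1] + rc$hit[-nrow(rc)]) / 2)
  expect_equal(area, auc(a, b), tolerance = 1e-12)
})

test_that("pairwise mean AUC averages all unordered condition pairs", {
  withr::local_seed(13)
  v2 <- c(rnorm(20), rnorm(20, 2))
  c2 <- rep(c("P1200", "P120"), each = 20)
  r2 <- pairwise_mean_auc(v2, c2)
  expect_identical(r2$n_pairs, 1L)
  expect_equal(r2$mean_auc, auc(v2[c2 == "P1200"], v2[c2 == "P120"]))
  expect_gt(r2$mean_auc, 0.5)   # coarser texture is the signal group

  conds <- c("P120", "P220", "P600", "P800", "P1200")
  v5 <- rnorm(100)
  c5 <- rep(conds, each = 20)
  r5 <- pairwise_mean_auc(v5, c5)
  expect_identical(r5$n_pairs, 10L)   # C(5,2)
  expect_identical(nrow(r5$pairs), 10L)

  expect_error(pairwise_mean_auc(c(1, 2, 3), c("a", "a", "b")), "fewer than 2")
  expect_error(pairwise_mean_auc(1:4, rep("a", 4)), "at least 2 conditions")

  # folding reflects below-chance pairs
  vf <- c(rnorm(20, 2), rnorm(20))
  rf <- pairwise_mean_auc(vf, c2, fold = TRUE)
  expect_gte(rf$mean_auc, 0.5)
})

test_that("the permutation null is centered at chance with the closed-form spread", {
  withr::local_seed(14)
  v <- rnorm(200)
  cond <- rep(c("P120", "P1200"), each = 100)
  nd <- permutation_null(v, cond, n_shuffles = 400, seed = 15)
  expect_equal(mean(nd$samples), 0.5, tolerance = 0.01)
  expect_equal(sd(nd$samples), sqrt((100 + 100 + 1) / (12 * 100 * 100)),
               tolerance = 0.1)
  expect_equal(nd$threshold,
               stats::quantile(nd$samples, 0.9, names = FALSE))
  expect_identical(nd$n_shuffles, 400)
  expect_error(permutation_null(v, cond, n_shuffles = 0), ">= 1")
})

test_that("pooled nulls recompute the ensemble threshold", {
  withr::local_seed(16)
  nds <- lapply(1:4, function(i) {
    v <- rnorm(100)
    permutation_null(v, rep(c("a", "b"), each = 50), n_shuffles = 100,
                     seed = i)
  })
  pooled <- pool_nulls(nds)
  expect_identical(length(pooled$samples), 400L)
  expect_equal(pooled$threshold,
               stats::quantile(unlist(lapply(nds, `[[`, "samples")), 0.9,
                               names = FALSE))
})

test_that("whisker pooling averages aligned trials", {
  trials <- data.frame(
    whisker = rep(c("gamma", "C2"), each = 6),
    condition = rep(rep(c("P120", "P1200"), each = 3), 2),
    value = c(1, 2, 3, 4, 5, 6, 7, 8, 9, 10, 11, 12))
  # singleton set is the identity
  one <- combine_whiskers(trials, "gamma")
  expect_equal(one$value, c(1, 2, 3, 4, 5, 6))
  # duplicated identical whisker equals the original
  dup <- rbind(trials[trials$whisker == "gamma", ],
               transform(trials[trials$whisker == "gamma", ],
                         whisker = "gamma2"))
  expect_equal(combine_whiskers(dup)$value, c(1, 2, 3, 4, 5, 6))
  # plain mean across whiskers
  both <- combine_whiskers(trials)
  expect_equal(both$value, c(4, 5, 6, 7, 8, 9))
  # unequal counts trim to the shortest
  uneq <- rbind(trials, data.frame(whisker = "gamma", condition = "P120",
                                   value = 99))
  expect_identical(nrow(combine_whiskers(uneq)[
    combine_whiskers(uneq)$condition == "P120", ]), 3L)
  expect_error(combine_whiskers(trials, character(0)), "nonempty")
})

test_that("the linearity index is exactly 1 for a duplicated whisker", {
  withr::local_seed(17)
  v <- c(rnorm(30), rnorm(30, 1))
  one <- data.frame(whisker = "gamma",
                    condition = rep(c("P1200", "P120"), each = 30), value = v)
  dup <- rbind(one, transform(one, whisker = "gamma_copy"))
  li <- linearity_index(dup)
  expect_identical(li$index, 1)
  expect_error(linearity_index(one), "at least 2")
})

test_that("independent-noise channels pool supralinearly", {
  withr::local_seed(18)
  mu <- c(P1200 = 0, P600 = 0.6, P120 = 1.2)
  make_w <- function(w) do.call(rbind, lapply(names(mu), function(cc)
    data.frame(whisker = w, condition = cc, value = mu[[cc]] + rnorm(150))))
  trials <- rbind(make_w("gamma"), make_w("C2"))
  li <- linearity_index(trials)
  expect_gt(li$index, 1)
  expect_gt(li$combined_auc, max(li$single_aucs))
})

test_that("texture-versus-edge AUC separates rate distributions", {
  expect_identical(texture_edge_auc(c(5, 5, 5), c(5, 5, 5)), 0.5)
  expect_identical(texture_edge_auc(c(100, 100), c(10, 10)), 1)
  expect_error(texture_edge_auc(numeric(0), 1:3), "present")
})
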