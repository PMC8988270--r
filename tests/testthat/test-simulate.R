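test_that("density 0 gives a diagonal precision with no nonzero partials", {
  m <- make_precision_model(p = 5, density = 0, seed = 1)
  expect_equal(m$precision, diag(5))
  expect_true(all(m$partials[upper.tri(m$partials)] == 0))
  expect_equal(nrow(m$edge_set), 0)
})

test_that("a single-edge model matches the closed-form partial-correlation identity", {
  # p = 3, one edge with partial 0.5: precision proportional to
  # [[1,-0.5,0],[-0.5,1,0],[0,0,1]]; recomputing partials returns 0.5/0/0
  m <- make_precision_model(p = 3, density = 1 / 3, weight_range = c(0.5, 0.5),
                            positive_only = TRUE, seed = 7)
  expect_equal(nrow(m$edge_set), 1)
  i <- m$edge_set$i[1]; j <- m$edge_set$j[1]
  expect_equal(m$partials[i, j], 0.5, tolerance = 1e-12)
  other <- setdiff(1:3, c(i, j))
  expect_equal(m$partials[i, other], 0)
  expect_equal(m$partials[j, other], 0)
  # numeric-inversion cross-check of the identity
  sigma <- solve(m$precision)
  rho_cond <- -solve(sigma)[i, j] /
    sqrt(solve(sigma)[i, i] * solve(sigma)[j, j])
  expect_equal(rho_cond, 0.5, tolerance = 1e-10)
})

test_that("generated precisions are positive definite for any seed and density", {
  for (seed in 1:10) {
    m <- make_precision_model(p = 10, density = 0.6,
                              weight_range = c(0.2, 0.45), seed = seed)
    ev <- eigen(m$precision, symmetric = TRUE, only.values = TRUE)$values
    expect_gt(min(ev), 0)
    # partials are recomputed from the adjusted precision
    expect_equal(m$partials, partials_from_precision(m$precision))
    expect_true(all(abs(m$partials[upper.tri(m$partials)]) < 1))
  }
})

test_that("sampling is deterministic given the seed and monotone in the latent", {
  m <- make_precision_model(p = 4, density = 0.5, seed = 3)
  arch <- group_archetype("A", n = 50, mean_shift = 0.3)
  a <- sample_group(m, arch, seed = 11)
  b <- sample_group(m, arch, seed = 11)
  expect_equal(as.data.frame(a), as.data.frame(b))

  rule <- discretization_rule()
  x <- sort(runif(100, -3, 3))
  expect_true(!is.unsorted(discretize_latent(x, rule)))
  expect_true(all(discretize_latent(x, rule) %in% 0:3))
})

test_that("item means match the analytic discretized-normal mean", {
  # no covariate effects, no shift: latent is standard normal per item
  m <- make_precision_model(p = 3, density = 1 / 3,
                            weight_range = c(0.3, 0.3), seed = 2)
  arch <- group_archetype("A", n = 10000, mean_shift = 0,
                          age_effect = 0, sex_effect = 0)
  rule <- discretization_rule()
  cohort <- sample_group(m, arch, rule, seed = 5)
  scores <- as.matrix(cohort[, paste0("item_", 1:3)])
  sds <- sqrt(diag(solve(m$precision)))
  for (k in 1:3) {
    mu_th <- discretized_normal_mean(0, sds[k], rule$thresholds)
    var_th <- sum((0:3)^2 * diff(c(0, pnorm(rule$thresholds, 0, sds[k]), 1))) -
      mu_th^2
    se <- sqrt(var_th / 10000)
    expect_lt(abs(mean(scores[, k]) - mu_th), 3 * se)
  }
})

test_that("latent reconstruction tracks the true partials at large n", {
  theta <- chain_precision(p = 6, partial = 0.4)
  set.seed(9)
  lat <- sample_latent(50000, theta)
  est <- -stats::cov2cor(solve(cov(lat)))
  diag(est) <- 0
  truth <- partials_from_precision(theta)
  expect_lt(max(abs(est - truth)), 0.03)
  # non-edges shrink toward zero
  nonedge <- truth[upper.tri(truth)] == 0
  expect_lt(mean(abs(est[upper.tri(est)][nonedge])), 0.05)
})

test_that("the four-group fixture has the study sizes and shared/empty structures", {
  fx <- four_group_fixture(seed = 1)
  expect_equal(levels(fx$cohort$group), c("CD", "RD", "SD", "HC"))
  expect_equal(as.vector(table(fx$cohort$group)), c(294, 118, 184, 257))
  expect_identical(fx$models$CD$edge_set, fx$models$RD$edge_set)
  expect_equal(nrow(fx$models$HC$edge_set), 0)
  expect_gt(nrow(fx$models$CD$edge_set), nrow(fx$models$SD$edge_set))
  expect_true(all(as.matrix(fx$cohort[, paste0("item_", 1:21)]) %in% 0:3))
})

test_that("pooled residual means rank the current-depression group highest", {
  wins <- 0L
  for (seed in 1:10) {
    fx <- four_group_fixture(seed = seed, p = 8,
                             sizes = c(CD = 294, RD = 118, SD = 184, HC = 257))
    rm <- residual_means(residualize_items(fx$cohort, scope = "pooled"))
    avg <- tapply(rm$mean_residual, rm$group, mean)
    if (which.max(avg) == which(names(avg) == "CD")) wins <- wins + 1L
  }
  expect_gte(wins, 9L)
})
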