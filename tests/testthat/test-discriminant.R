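# Stepwise selection, canonical functions, classification, LOO, Press's Q.

planted_signal_data <- function(seed = 31, p = 8, sep = 5, n = 30, k = 3) {
  set.seed(seed)
  means <- matrix(0, k, p)
  means[, 1] <- (seq_len(k) - 1) * sep   # only variable 1 is informative
  sim <- mvn_sites(means, n)
  colnames(sim$x) <- paste0("E", seq_len(p))
  sim
}

test_that("stepwise recovers the single informative variable", {
  sim <- planted_signal_data()
  # oracle: exhaustive single-variable Wilks scan
  lam1 <- vapply(seq_len(ncol(sim$x)), function(j) {
    manova_wilks(sim$x[, j, drop = FALSE], sim$labels)$wilks_lambda
  }, numeric(1))
  expect_equal(which.min(lam1), 1L)
  for (crit in c("wilks", "mahalanobis_closest_pair")) {
    tr <- stepwise_select(sim$x, sim$labels, criterion = crit)
    expect_identical(attr(tr, "selected"), "E1")
  }
})

test_that("unreachable entry threshold yields an empty, flagged selection", {
  sim <- planted_signal_data()
  expect_warning(
    tr <- stepwise_select(sim$x, sim$labels, f_enter = Inf, f_remove = 1),
    "no admissible")
  expect_length(attr(tr, "selected"), 0)
  expect_true(attr(tr, "flagged_empty"))
  expect_error(stepwise_select(sim$x, sim$labels, f_enter = 1, f_remove = 2),
               "f_enter")
})

test_that("greedy selection matches exhaustive same-size search on 6
           independent candidates", {
  set.seed(33)
  p <- 6
  means <- matrix(0, 3, p)
  means[, 1] <- c(0, 3, 6)     # strong
  means[, 2] <- c(0, 1.5, 3)   # moderate
  means[, 3] <- c(0, 1, 1)     # weak
  sim <- mvn_sites(means, 25)
  tr <- stepwise_select(sim$x, sim$labels, criterion = "wilks")
  sel <- attr(tr, "selected")
  m <- length(sel)
  expect_gt(m, 0)
  combos <- utils::combn(colnames(sim$x), m, simplify = FALSE)
  lam <- vapply(combos, function(s)
    manova_wilks(sim$x[, s, drop = FALSE], sim$labels)$wilks_lambda,
    numeric(1))
  best <- combos[[which.min(lam)]]
  expect_setequal(sel, best)
})

test_that("canonical fit: k=2, one variable gives rc^2 = squared
           point-biserial correlation", {
  set.seed(34)
  y <- c(rnorm(14), rnorm(18, 2))
  g <- rep(c("A", "B"), c(14, 18))
  x <- matrix(y, dimnames = list(NULL, "E1"))
  fit <- fit_canonical(x, g)
  expect_equal(fit$n_functions, 1L)
  # regression oracle: R^2 of score on the group indicator
  score <- predict_scores(fit, x)[, 1]
  r2 <- summary(stats::lm(score ~ (g == "B")))$r.squared
  expect_equal(fit$canonical_correlations[1]^2, r2, tolerance = 1e-10)
})

test_that("canonical scores have identity pooled within-group covariance
           and lambda identity holds", {
  set.seed(35)
  sim <- mvn_sites(matrix(rnorm(24), 4, 6), 14)
  fit <- fit_canonical(sim$x, sim$labels)
  sc <- predict_scores(fit, sim$x)
  w <- scatter <- matrix(0, ncol(sc), ncol(sc))
  for (g in unique(sim$labels)) {
    xg <- sc[sim$labels == g, , drop = FALSE]
    w <- w + crossprod(sweep(xg, 2, colMeans(xg)))
  }
  Sw <- w / (nrow(sc) - length(unique(sim$labels)))
  expect_equal(Sw, diag(ncol(sc)), tolerance = 1e-8, ignore_attr = TRUE)
  expect_equal(sum(fit$variance_shares), 1, tolerance = 1e-12)
  direct <- manova_wilks(sim$x, sim$labels)$wilks_lambda
  expect_equal(prod(1 / (1 + fit$eigenvalues)), direct, tolerance = 1e-8)
})

test_that("duplicated groups give zero eigenvalues", {
  set.seed(36)
  x <- matrix(rnorm(40), 10, 4)
  fit <- fit_canonical(rbind(x, x), rep(c("A", "B"), each = 10))
  expect_equal(fit$eigenvalues, rep(0, fit$n_functions), tolerance = 1e-8)
})

test_that("classification: centroid hit, forced separation, tie rule, and
           agreement with an independent LDA", {
  set.seed(37)
  sim <- mvn_sites(matrix(c(0, 0, 10, 0, 0, 10), 3, 2, byrow = TRUE,
                          dimnames = list(c("A", "B", "C"), NULL)), 12)
  fit <- fit_canonical(sim$x, sim$labels)
  # training points from 10-sigma-separated spherical groups: all correct
  pred <- classify(fit, sim$x)
  expect_identical(pred$site, sim$labels)
  # a bird exactly at a centroid has D^2 = 0 there
  cen_scores <- fit$centroids[, seq_len(fit$n_retained), drop = FALSE]
  # invert: find a z giving exactly centroid scores (use group mean)
  gm <- colMeans(sim$x[sim$labels == "B", , drop = FALSE])
  d2 <- classify(fit, matrix(gm, 1,
                             dimnames = list(NULL, colnames(sim$x))))$d2
  expect_equal(unname(d2[1, "B"]), 0, tolerance = 1e-10)
  # equal priors: agrees with MASS::lda on well-separated data
  l <- MASS::lda(sim$x, grouping = sim$labels,
                 prior = rep(1 / 3, 3))
  expect_identical(pred$site, as.character(predict(l)$class))
})

test_that("exact ties go to the first site in library order", {
  fit <- list(elements = c("E1", "E2"),
              sites = c("S1", "S2"),
              coefficients = diag(2), constant = c(0, 0),
              centroids = matrix(c(-1, 1, 0, 0), 2, 2,
                                 dimnames = list(c("S1", "S2"), NULL)),
              n_retained = 2L, n_functions = 2L)
  class(fit) <- "fingerprint_library"
  z <- matrix(c(0, 5), 1, dimnames = list("tie", c("E1", "E2")))
  expect_identical(classify(fit, z)$site, "S1")
})

test_that("leave-one-out: perfect at 10 sigma, chance under permuted
           labels", {
  set.seed(38)
  sim <- mvn_sites(matrix(c(0, 0, 10, 0, 0, 10), 3, 2, byrow = TRUE), 10)
  rep3 <- loo_crossvalidate(sim$x, sim$labels)
  expect_equal(rep3$overall_pct, 100)
  expect_true(all(rowSums(rep3$loo) == table(sim$labels)[rep3$sites]))

  set.seed(39)
  k <- 10
  sim0 <- mvn_sites(matrix(0, k, 5), 20)
  labs <- sample(sim0$labels)
  rep0 <- loo_crossvalidate(sim0$x, labs)
  # binomial 99% CI around 1/k for N = 200
  half <- 2.576 * sqrt(0.1 * 0.9 / 200)
  expect_gt(rep0$overall_pct / 100, 0.1 - half)
  expect_lt(rep0$overall_pct / 100, 0.1 + half)
})

test_that("Press's Q follows the closed form", {
  expect_equal(press_q(10, 2, 10)$q, 10)
  expect_equal(press_q(10, 2, 5)$q, 0)     # pure chance
  pq <- press_q(105, 10, 83)
  expect_equal(pq$q, 725^2 / 945)
  expect_equal(round(pq$q, 2), 556.22)
  expect_lt(pq$p_value, 1e-4)
  expect_error(press_q(10, 1, 5), "K")
  expect_error(press_q(10, 2, 11), "n_correct")
})
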