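# Centroid-ratio assignment and immigrant/unassigned detection.

toy_library <- function(seed = 41, sep = 6) {
  set.seed(seed)
  means <- matrix(c(0, 0, sep, 0, 0, sep), 3, 2, byrow = TRUE,
                  dimnames = list(c("A", "B", "C"), NULL))
  sim <- mvn_sites(means, 15)
  list(fit = fit_canonical(sim$x, sim$labels), sim = sim)
}

test_that("a bird at a site centroid has all ratios 1 and distance 0", {
  lib <- toy_library()$fit
  r <- lib$n_retained
  cen <- lib$centroids[, seq_len(r), drop = FALSE]
  sc <- cen["B", , drop = FALSE]
  rho <- centroid_normalize(lib, sc)
  expect_equal(unname(rho[1, "B", ]), rep(1, r), tolerance = 1e-12)
  asg <- assign_origin(lib, scores = sc)
  expect_identical(asg$assigned_site, "B")
  expect_equal(asg$d_B, 0, tolerance = 1e-12)
  expect_false(asg$immigrant_unassigned)
  # doubled scores give ratios of exactly 2
  rho2 <- centroid_normalize(lib, 2 * sc)
  expect_equal(unname(rho2[1, "B", ]), rep(2, r), tolerance = 1e-12)
})

test_that("near-zero centroid components are dropped with a warning", {
  lib <- toy_library()$fit
  lib$centroids["A", 1] <- 0
  expect_warning(rho <- centroid_normalize(lib, lib$centroids["A", ,
                                                              drop = FALSE]),
                 "undefined")
  expect_true(is.na(rho[1, "A", 1]))
  # closeness for site A still defined from the remaining cells
  expect_warning(asg <- assign_origin(lib, scores = lib$centroids[
    "A", seq_len(lib$n_retained), drop = FALSE]))
  expect_false(is.na(asg$d_A))
})

test_that("a bird far from every centroid is flagged immigrant", {
  lib <- toy_library()$fit
  r <- lib$n_retained
  # direct D^2 oracle: place the bird 10 canonical units beyond centroid A
  # along the direction away from the other centroids
  far <- lib$centroids["A", seq_len(r)] +
    10 * c(-1, rep(0, r - 1))
  d2_direct <- min(apply(lib$centroids[, seq_len(r), drop = FALSE], 1,
                         function(cc) sum((far - cc)^2)))
  expect_gt(d2_direct, qchisq(0.95, df = r))
  asg <- assign_origin(lib, scores = matrix(far, 1))
  expect_true(asg$immigrant_unassigned)
  expect_identical(asg$origin_call, "immigrant_unassigned")
  expect_equal(asg$min_d2, d2_direct, tolerance = 1e-10)
})

test_that("equidistant birds go to the first site in library order", {
  # exact tie by construction: symmetric centroids, bird on the axis
  lib <- list(elements = c("E1", "E2"), sites = c("A", "B"),
              coefficients = diag(2), constant = c(0, 0),
              centroids = matrix(c(-1, 1, 0, 0), 2, 2,
                                 dimnames = list(c("A", "B"), NULL)),
              n_retained = 2L, n_functions = 2L)
  class(lib) <- "fingerprint_library"
  asg <- assign_origin(lib, scores = matrix(c(0, 3), 1),
                       method = "mahalanobis")
  expect_identical(asg$assigned_site, "A")
})

test_that("context summaries tabulate percentages that sum to 100", {
  lib <- toy_library()$fit
  r <- lib$n_retained
  sc <- lib$centroids[rep("B", 10), seq_len(r)]
  asg <- assign_origin(lib, scores = sc)
  s <- summarize_by_context(asg, rep("vineyard_orchard", 10))
  expect_equal(s$vineyard_orchard$table$pct, 100)
  expect_identical(s$vineyard_orchard$table$source, "B")

  # 4 local + 4 flagged -> 50/50
  far <- sweep(matrix(0, 4, r), 2, lib$centroids["A", seq_len(r)], `+`) + 50
  asg2 <- assign_origin(lib, scores = rbind(sc[1:4, ], far))
  s2 <- summarize_by_context(asg2, rep("dairy_feedlot", 8))
  expect_equal(sort(s2$dairy_feedlot$table$pct), c(50, 50))
  expect_equal(sum(s2$dairy_feedlot$table$pct), 100, tolerance = 0.1)
  expect_error(summarize_by_context(asg2, rep("nowhere", 8)), "context")

  # regional roll-up
  s3 <- summarize_by_context(asg2, rep("dairy_feedlot", 8),
                             regions = list(north = c("A", "B"),
                                            south = "C"))
  reg <- s3$dairy_feedlot$regional
  expect_setequal(reg$region, c("north", "immigrant_unassigned"))
  expect_equal(sum(reg$pct), 100, tolerance = 0.1)
})

test_that("a 60/40 local/immigrant mixture is recovered from generator
           ground truth", {
  cfg <- synth_config(seed = 47, immigrant_fraction = 0.4,
                      mixture_weights = c(1, rep(0, 9)))  # all from Kelowna
  libtab <- generate_library(cfg)
  prob <- generate_problem_birds(cfg)
  built <- suppressWarnings(build_library(libtab))
  zp <- apply_scaler(built$library$scaler, normalize_to_calcium(prob))
  asg <- assign_origin(built$library, zp)
  truth_imm <- prob$true_origin == "immigrant"
  # essentially every injected 10-sigma immigrant is flagged
  expect_gte(mean(asg$immigrant_unassigned[truth_imm]), 0.95)
  # flagged share tracks the realized immigrant share
  expect_gte(mean(asg$immigrant_unassigned), mean(truth_imm) - 0.05)
  expect_lte(mean(asg$immigrant_unassigned), mean(truth_imm) + 0.15)
  # the true source site is the modal call among unflagged locals
  loc <- !truth_imm & !asg$immigrant_unassigned
  calls <- table(asg$assigned_site[loc])
  expect_identical(names(which.max(calls)), "Kelowna")
})

test_that("self-assignment false-flag rate is near alpha for
           multivariate-normal sites", {
  set.seed(48)
  means <- matrix(rnorm(50, sd = 2), 5, 10)
  sim <- mvn_sites(means, 25)
  fit <- fit_canonical(sim$x, sim$labels)
  asg <- assign_origin(fit, sim$x, method = "mahalanobis", alpha = 0.05)
  rate <- mean(asg$immigrant_unassigned)
  se3 <- 3 * sqrt(0.05 * 0.95 / nrow(sim$x))
  expect_lte(rate, 0.05 + se3)
})

test_that("ratio and mahalanobis closeness agree near centroids", {
  set.seed(49)
  means <- matrix(rnorm(40, sd = 4), 4, 10)
  sim <- mvn_sites(means, 20)
  fit <- fit_canonical(sim$x, sim$labels)
  r <- fit$n_retained
  # birds within 1 pooled SD of a random centroid
  agree <- replicate(100, {
    s <- sample(rownames(fit$centroids), 1)
    u <- rnorm(r); u <- u / sqrt(sum(u^2)) * runif(1)
    sc <- matrix(fit$centroids[s, seq_len(r)] + u, 1)
    a1 <- assign_origin(fit, scores = sc, method = "ratio")$assigned_site
    a2 <- assign_origin(fit, scores = sc,
                        method = "mahalanobis")$assigned_site
    a1 == a2
  })
  expect_gte(mean(agree), 0.95)
})
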