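# Distances, agglomeration, tree cutting and multiscale-bootstrap support.

test_that("pairwise distances follow their definitions", {
  x <- rbind(a = c(0, 0), b = c(3, 4), c = c(0, 0))
  d <- as.matrix(pairwise_distance(x, "euclidean"))
  expect_equal(d["a", "b"], 5)
  expect_equal(d["a", "c"], 0)    # identical rows

  y <- rbind(p = c(1, 2, 3), q = c(3, 2, 1), r = c(2, 4, 6))
  dc <- as.matrix(pairwise_distance(y, "correlation"))
  expect_equal(dc["p", "q"], 2)   # perfectly anticorrelated
  expect_equal(dc["p", "r"], 0)   # perfectly correlated

  bad <- rbind(ok = c(1, 2, 3), flat = c(5, 5, 5))
  expect_error(pairwise_distance(bad, "correlation"), "flat")
})

test_that("agglomeration reproduces the hand-worked 1-D example", {
  x <- matrix(c(0, 1, 10, 11), ncol = 1,
              dimnames = list(c("a", "b", "c", "d"), NULL))
  tr <- agglomerate(stats::dist(x), "average")
  expect_equal(nrow(tr$merges), 3)   # n-1 merges
  cl <- clades_of(tr)
  expect_true("a|b" %in% cl && "c|d" %in% cl)
  expect_equal(max(tr$merges$height), 10)  # root: mean cross distance
  expect_equal(sort(tr$merges$height), c(1, 1, 10))

  # identical points merge at height 0
  z <- matrix(c(1, 1, 5), ncol = 1)
  tr0 <- agglomerate(stats::dist(z), "average")
  expect_equal(min(tr0$merges$height), 0)

  # malformed inputs
  m <- matrix(c(0, 1, 2, 0), 2, 2)
  expect_error(agglomerate(m, "average"), "symmetric")
  dn <- stats::dist(x); dn[1] <- NaN
  expect_error(agglomerate(dn, "average"), "NA")
})

test_that("agglomerate matches the brute-force Lance-Williams oracle on
           small instances", {
  for (seed in 61:64) {
    set.seed(seed)
    n <- sample(4:6, 1)
    x <- matrix(rnorm(n * 3), n, dimnames = list(letters[1:n], NULL))
    d <- stats::dist(x)
    for (link in c("ward.D", "ward.D2", "average")) {
      tr <- agglomerate(d, link)
      oracle <- lw_brute_force(d, link)
      expect_equal(sort(tr$merges$height), oracle$heights,
                   tolerance = 1e-10,
                   label = paste(link, "heights, seed", seed))
      expect_identical(clades_of(tr), oracle$clades,
                       label = paste(link, "clades, seed", seed))
    }
  }
})

test_that("tree cutting by height and by k", {
  x <- matrix(c(0, 1, 10, 11), ncol = 1,
              dimnames = list(c("a", "b", "c", "d"), NULL))
  tr <- agglomerate(stats::dist(x), "average")
  expect_equal(length(unique(cut_dendrogram(tr, height = 1e9))), 1)
  expect_equal(length(unique(cut_dendrogram(tr, height = -1e-9))), 4)
  k2 <- cut_dendrogram(tr, k = 2)
  expect_equal(unname(k2[c("a", "b")]), rep(k2[["a"]], 2))
  expect_equal(unname(k2[c("c", "d")]), rep(k2[["c"]], 2))
  expect_false(k2[["a"]] == k2[["c"]])
  expect_error(cut_dendrogram(tr, k = 9), "between 1")
  expect_error(cut_dendrogram(tr), "height or k")
})

test_that("universally supported clades get BP = AU = 1 and support values
           stay in [0, 1]", {
  set.seed(65)
  # two blocks with huge separation across every feature
  x <- rbind(matrix(rnorm(5 * 20), 5, 20),
             matrix(rnorm(5 * 20, mean = 50), 5, 20))
  rownames(x) <- paste0("b", 1:10)
  cs <- multiscale_bootstrap(x, metric = "euclidean", linkage = "average",
                             B = 120, seed = 7)
  blocks <- c(paste(sort(paste0("b", 1:5)), collapse = "|"),
              paste(sort(paste0("b", 6:10)), collapse = "|"))
  sup <- cs$support
  for (cl in blocks) {
    row <- sup[sup$clade == cl, ]
    expect_equal(row$bp, 1)
    expect_equal(row$au, 1)
  }
  expect_true(all(sup$au >= 0 & sup$au <= 1, na.rm = TRUE))
  expect_true(all(sup$bp >= 0 & sup$bp <= 1))
  expect_true(all(cs$bp_by_scale >= 0 & cs$bp_by_scale <= 1))
})

test_that("multiscale bootstrap is reproducible under a fixed seed", {
  set.seed(66)
  x <- matrix(rnorm(8 * 15), 8, 15, dimnames = list(paste0("b", 1:8), NULL))
  cs1 <- multiscale_bootstrap(x, B = 100, seed = 123)
  cs2 <- multiscale_bootstrap(x, B = 100, seed = 123)
  expect_identical(cs1$support, cs2$support)
  expect_identical(cs1$bp_by_scale, cs2$bp_by_scale)
  cs3 <- multiscale_bootstrap(x, B = 100, seed = 124)
  expect_false(identical(cs1$bp_by_scale, cs3$bp_by_scale))
})

test_that("with a single unit scale and c = 0 the AU estimate reduces to
           BP", {
  for (bp in c(0.2, 0.5, 0.8)) {
    fit <- traceassign:::fit_au(bp, r = 1, B = 200, constrain_c0 = TRUE)
    expect_equal(fit$au, bp, tolerance = 1e-10)
  }
})

test_that("degenerate bootstrap outcomes are flagged", {
  never <- traceassign:::fit_au(rep(0, 5), r = seq(0.6, 1.4, 0.2), B = 100)
  expect_equal(never$au, 0)
  expect_identical(never$flag, "never_observed")
  always <- traceassign:::fit_au(rep(1, 5), r = seq(0.6, 1.4, 0.2), B = 100)
  expect_equal(always$au, 1)
  expect_identical(always$flag, "always_observed")
  expect_error(multiscale_bootstrap(matrix(rnorm(40), 5, 8),
                                    scales = c(1.1, 1.2), B = 100),
               "below and above 1")
  expect_error(multiscale_bootstrap(matrix(rnorm(40), 5, 8), B = 50),
               "at least 100")
})
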