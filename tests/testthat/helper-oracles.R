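# Independent oracles and small fixture builders used across the suite.

# Brute-force Lance-Williams agglomeration, written directly from the
# recurrence formulas (no shared code with agglomerate()). Returns the
# sorted merge heights and the set of clades (as sorted label strings).
lw_brute_force <- function(d, linkage) {
  d <- as.matrix(d)
  n <- nrow(d)
  labs <- rownames(d)
  if (is.null(labs)) labs <- as.character(seq_len(n))
  clusters <- lapply(seq_len(n), function(i) labs[i])
  sizes <- rep(1, n)
  active <- rep(TRUE, n)
  heights <- numeric(0)
  clades <- character(0)
  dm <- d
  diag(dm) <- Inf
  for (step in seq_len(n - 1)) {
    idx <- which(active)
    sub <- dm[idx, idx, drop = FALSE]
    pos <- which(sub == min(sub), arr.ind = TRUE)[1, ]
    i <- idx[min(pos)]; j <- idx[max(pos)]
    h <- dm[i, j]
    heights <- c(heights, h)
    merged <- c(clusters[[i]], clusters[[j]])
    clades <- c(clades, paste(sort(merged), collapse = "|"))
    ni <- sizes[i]; nj <- sizes[j]
    for (k in idx) {
      if (k == i || k == j) next
      nk <- sizes[k]
      dik <- dm[i, k]; djk <- dm[j, k]; dij <- dm[i, j]
      newd <- switch(linkage,
        average = (ni * dik + nj * djk) / (ni + nj),
        ward.D = ((ni + nk) * dik + (nj + nk) * djk - nk * dij) /
          (ni + nj + nk),
        ward.D2 = sqrt(((ni + nk) * dik^2 + (nj + nk) * djk^2 -
                          nk * dij^2) / (ni + nj + nk)))
      dm[i, k] <- dm[k, i] <- newd
    }
    clusters[[i]] <- merged
    sizes[i] <- ni + nj
    active[j] <- FALSE
    dm[j, ] <- dm[, j] <- Inf
  }
  list(heights = sort(heights), clades = sort(clades))
}

clades_of <- function(tree) {
  hc <- if (inherits(tree, "dendro_fit")) tree$hclust else tree
  n <- nrow(hc$merge) + 1
  sets <- vector("list", nrow(hc$merge))
  out <- character(nrow(hc$merge))
  for (i in seq_len(nrow(hc$merge))) {
    members <- unlist(lapply(hc$merge[i, ], function(j)
      if (j < 0) hc$labels[-j] else sets[[j]]))
    sets[[i]] <- members
    out[i] <- paste(sort(members), collapse = "|")
  }
  sort(out)
}

# Multivariate-normal z-space site data: k groups, n per group, p variables,
# group means supplied as a k x p matrix (identity within covariance).
mvn_sites <- function(means, n_per, sd = 1) {
  k <- nrow(means); p <- ncol(means)
  if (length(n_per) == 1) n_per <- rep(n_per, k)
  x <- do.call(rbind, lapply(seq_len(k), function(g)
    matrix(rnorm(n_per[g] * p, sd = sd), n_per[g], p, byrow = TRUE) +
      matrix(means[g, ], n_per[g], p, byrow = TRUE)))
  colnames(x) <- paste0("E", seq_len(p))
  rownames(x) <- paste0("b", seq_len(nrow(x)))
  list(x = x, labels = rep(rownames(means) %||%
                             paste0("S", seq_len(k)), n_per))
}

`%||%` <- function(a, b) if (is.null(a)) b else a

# A tiny valid 3-row sample table over the default 21-element panel.
toy_sample_table <- function(n = 3, seed = 99) {
  set.seed(seed)
  panel <- element_panel()
  df <- data.frame(bird_id = paste0("bird", seq_len(n)),
                   site = rep(c("X", "Y"), length.out = n),
                   age_class = "juvenile", season = "summer",
                   context = "library", stringsAsFactors = FALSE)
  for (el in panel$elements) {
    df[[el]] <- if (el == "Ca") runif(n, 2e5, 3e5) else runif(n, 0.01, 50)
  }
  sample_table(df, panel)
}

# Small synthetic config for fast pipeline tests: 4 sites, 32 birds.
small_cfg <- function(seed = 5, ...) {
  synth_config(sites = c("N1", "N2", "S1", "S2"),
               site_n = c(8, 8, 8, 8), seed = seed, ...)
}
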