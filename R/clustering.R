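# Hierarchical clustering of bird fingerprints with multiscale-bootstrap
# AU/BP support values per internal node.

#' Pairwise distances between bird fingerprints
#'
#' @param z Numeric matrix or `z_table` (birds x elements).
#' @param metric `"euclidean"` (L2 between rows) or `"correlation"`
#'   (1 - Pearson r between rows).
#' @return A `dist` object.
#' @export
pairwise_distance <- function(z, metric = c("euclidean", "correlation")) {
  metric <- match.arg(metric)
  if (inherits(z, "z_table") || inherits(z, "ratio_table")) z <- z_matrix(z)
  z <- as.matrix(z)
  if (nrow(z) < 2) stop("need at least 2 rows", call. = FALSE)
  if (metric == "euclidean") return(stats::dist(z, method = "euclidean"))
  rv <- apply(z, 1, stats::var)
  if (any(rv == 0)) {
    bad <- rownames(z)[rv == 0]
    if (is.null(bad)) bad <- which(rv == 0)
    stop("zero-variance row(s) under correlation metric: ",
         paste(bad, collapse = ", "), call. = FALSE)
  }
  stats::as.dist(1 - stats::cor(t(z)))
}

#' Agglomerative hierarchical clustering
#'
#' Lance-Williams agglomeration of a dissimilarity matrix. `"ward.D"`
#' applies the Ward update coefficients to the supplied (unsquared)
#' dissimilarities — the classic convention; `"ward.D2"` squares them first;
#' `"average"` is UPGMA.
#'
#' @param d A `dist` or symmetric non-negative matrix with zero diagonal.
#' @param linkage `"ward.D"`, `"ward.D2"` or `"average"`.
#' @return A `dendro_fit`: the `hclust` object plus `labels`, `linkage`,
#'   `metric` (if known) and the ordered merge list as a data frame
#'   (`left`, `right`, `height`).
#' @export
agglomerate <- function(d, linkage = c("ward.D", "ward.D2", "average")) {
  linkage <- match.arg(linkage)
  if (is.matrix(d)) {
    if (!isSymmetric(unname(d)) || any(diag(d) != 0) || any(d < 0)) {
      stop("distance matrix must be symmetric, non-negative, ",
           "zero-diagonal", call. = FALSE)
    }
    d <- stats::as.dist(d)
  }
  if (anyNA(d) || any(!is.finite(d))) {
    stop("distance matrix contains NA/NaN/Inf", call. = FALSE)
  }
  hc <- stats::hclust(d, method = linkage)
  if (is.null(hc$labels)) hc$labels <- as.character(seq_len(nrow(hc$merge) + 1))
  merges <- data.frame(left = hc$merge[, 1], right = hc$merge[, 2],
                       height = hc$height)
  structure(list(hclust = hc, labels = hc$labels, linkage = linkage,
                 merges = merges),
            class = "dendro_fit")
}

#' @export
print.dendro_fit <- function(x, ...) {
  cat("Dendrogram:", length(x$labels), "leaves,", x$linkage, "linkage,",
      nrow(x$merges), "merges\n")
  invisible(x)
}

#' Cut a dendrogram into flat clusters
#'
#' Severs merges above a height, or finds the smallest height giving exactly
#' `k` clusters.
#'
#' @param tree A `dendro_fit` (or `hclust`).
#' @param height Cut height.
#' @param k Desired number of clusters (alternative to `height`).
#' @return Named integer vector of cluster memberships.
#' @export
cut_dendrogram <- function(tree, height = NULL, k = NULL) {
  hc <- if (inherits(tree, "dendro_fit")) tree$hclust else tree
  n <- nrow(hc$merge) + 1
  if (!is.null(k) && (k < 1 || k > n)) {
    stop("k must be between 1 and the number of leaves (", n, ")",
         call. = FALSE)
  }
  if (is.null(height) && is.null(k)) stop("supply height or k", call. = FALSE)
  stats::cutree(hc, k = k, h = height)
}

# Leaf sets of every internal node, as canonical "a|b|c" strings.
clade_strings <- function(hc) {
  n <- nrow(hc$merge) + 1
  labs <- hc$labels
  sets <- vector("list", nrow(hc$merge))
  for (i in seq_len(nrow(hc$merge))) {
    members <- unlist(lapply(hc$merge[i, ], function(j)
      if (j < 0) labs[-j] else sets[[j]]))
    sets[[i]] <- members
  }
  vapply(sets, function(s) paste(sort(s), collapse = "|"), character(1))
}

#' Multiscale-bootstrap support for dendrogram clades
#'
#' For each scale r the feature columns are resampled with replacement to
#' size round(r * n_features), the birds are reclustered, and the fraction
#' of replicates containing each original clade gives BP(r). The probit
#' transform psi(r) = qnorm(1 - BP(r)) is fitted across scales as
#' psi(r) ~ sqrt(r) v + c/sqrt(r) by weighted least squares (binomial
#' weights), and the approximately unbiased support is AU = 1 - pnorm(v-c).
#' BP is the observed bootstrap probability at r = 1. BP values of 0 or 1
#' are clamped to 1/(2B) and 1 - 1/(2B) before the probit transform.
#'
#' @param z Numeric matrix or `z_table` (birds x features).
#' @param metric Distance metric, see [pairwise_distance()].
#' @param linkage Linkage, see [agglomerate()].
#' @param scales Relative bootstrap sample sizes; must include values below
#'   and above 1 (default 0.5 ... 1.4).
#' @param B Bootstrap replicates per scale (>= 100).
#' @param seed Integer seed; fixed seed gives identical AU/BP.
#' @return A `cluster_support`: the `dendro_fit` of the original data plus a
#'   data frame `support` with one row per internal node (`node`, `au`,
#'   `bp`, `v`, `c`, `flag`), the per-scale BP matrix, `scales`, `B`,
#'   `seed`.
#' @export
multiscale_bootstrap <- function(z, metric = "euclidean",
                                 linkage = "ward.D",
                                 scales = seq(0.5, 1.4, by = 0.1),
                                 B = 1000, seed = 1) {
  if (inherits(z, "z_table") || inherits(z, "ratio_table")) z <- z_matrix(z)
  z <- as.matrix(z)
  if (any(scales <= 0)) stop("scales must be positive", call. = FALSE)
  if (B < 100) stop("B must be at least 100", call. = FALSE)
  if (min(scales) >= 1 || max(scales) <= 1) {
    stop("scales must span values below and above 1", call. = FALSE)
  }
  tree <- agglomerate(pairwise_distance(z, metric), linkage)
  clades <- clade_strings(tree$hclust)
  p <- ncol(z)
  set.seed(seed)
  bp <- matrix(0, nrow = length(clades), ncol = length(scales),
               dimnames = list(NULL, paste0("r", scales)))
  for (si in seq_along(scales)) {
    m <- max(2L, round(scales[si] * p))
    counts <- numeric(length(clades))
    for (b in seq_len(B)) {
      cols <- sample.int(p, m, replace = TRUE)
      zb <- z[, cols, drop = FALSE]
      db <- tryCatch(pairwise_distance(zb, metric), error = function(e) NULL)
      if (is.null(db)) next
      hb <- stats::hclust(db, method = linkage)
      hb$labels <- rownames(z)
      counts <- counts + (clades %in% clade_strings(hb))
    }
    bp[, si] <- counts / B
  }
  # actual resample sizes give the effective scales used in the fit
  r_eff <- pmax(2L, round(scales * p)) / p
  support <- lapply(seq_along(clades), function(i)
    fit_au(bp[i, ], r_eff, B))
  support <- do.call(rbind, support)
  support$node <- seq_along(clades)
  support$clade <- clades
  i1 <- which.min(abs(scales - 1))
  support$bp <- bp[, i1]
  support <- support[, c("node", "au", "bp", "v", "c", "flag", "clade")]
  structure(list(tree = tree, support = support, bp_by_scale = bp,
                 scales = scales, B = B, seed = seed,
                 metric = metric, linkage = linkage),
            class = "cluster_support")
}

# WLS fit of psi(r) = sqrt(r) v + c / sqrt(r); AU = 1 - Phi(v - c).
fit_au <- function(bp_r, r, B, constrain_c0 = FALSE) {
  if (all(bp_r == 0)) {
    return(data.frame(au = 0, v = NA_real_, c = NA_real_,
                      flag = "never_observed", stringsAsFactors = FALSE))
  }
  if (all(bp_r == 1)) {
    return(data.frame(au = 1, v = NA_real_, c = NA_real_,
                      flag = "always_observed", stringsAsFactors = FALSE))
  }
  bp_c <- pmin(pmax(bp_r, 1 / (2 * B)), 1 - 1 / (2 * B))
  psi <- stats::qnorm(1 - bp_c)
  # binomial delta-method weights: Var(psi) ~ bp(1-bp) / (B phi(psi)^2)
  w <- B * stats::dnorm(psi)^2 / (bp_c * (1 - bp_c))
  usable <- is.finite(psi) & is.finite(w) & w > 0
  if (sum(usable) < 2 && !constrain_c0) {
    return(data.frame(au = NA_real_, v = NA_real_, c = NA_real_,
                      flag = "too_few_scales", stringsAsFactors = FALSE))
  }
  X <- cbind(sqrt(r), 1 / sqrt(r))[usable, , drop = FALSE]
  if (constrain_c0) X <- X[, 1, drop = FALSE]
  fit <- stats::lm.wfit(X, psi[usable], w[usable])
  v <- fit$coefficients[1]
  cc <- if (constrain_c0) 0 else fit$coefficients[2]
  data.frame(au = 1 - stats::pnorm(v - cc), v = unname(v), c = unname(cc),
             flag = "", stringsAsFactors = FALSE)
}

#' @export
print.cluster_support <- function(x, ...) {
  cat("Multiscale bootstrap:", nrow(x$support), "internal nodes,",
      length(x$scales), "scales x", x$B, "replicates (seed", x$seed, ")\n")
  strong <- sum(x$support$au >= 0.95, na.rm = TRUE)
  cat("  nodes with AU >= 0.95:", strong, "\n")
  invisible(x)
}

#' Write per-node support values as CSV
#'
#' @param cs A `cluster_support`.
#' @param path Output path.
#' @return `path`, invisibly.
#' @export
write_support_csv <- function(cs, path) {
  utils::write.csv(cs$support[, c("node", "au", "bp", "v", "c", "flag")],
                   path, row.names = FALSE)
  invisible(path)
}
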