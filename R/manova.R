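# One-way MANOVA across sites: Wilks' lambda with Rao's F approximation.

scatter_matrices <- function(x, labels) {
  x <- as.matrix(x)
  labels <- as.character(labels)
  stopifnot(nrow(x) == length(labels))
  groups <- unique(labels)
  k <- length(groups)
  if (k < 2) stop("need at least 2 groups", call. = FALSE)
  grand <- colMeans(x)
  p <- ncol(x)
  W <- matrix(0, p, p, dimnames = list(colnames(x), colnames(x)))
  B <- matrix(0, p, p, dimnames = list(colnames(x), colnames(x)))
  for (g in groups) {
    xg <- x[labels == g, , drop = FALSE]
    mg <- colMeans(xg)
    cg <- sweep(xg, 2, mg)
    W <- W + crossprod(cg)
    B <- B + nrow(xg) * tcrossprod(mg - grand)
  }
  list(W = W, B = B, N = nrow(x), p = p, k = k, groups = groups)
}

wilks_from_scatter <- function(W, B) {
  dT <- det(W + B)
  dW <- det(W)
  if (!is.finite(dW) || dW <= 0) {
    stop("within-group scatter matrix is singular", call. = FALSE)
  }
  min(max(dW / dT, 0), 1)
}

#' Rao's F approximation for Wilks' lambda
#'
#' Closed-form mapping from Wilks' lambda to an F statistic:
#' with m = N - 1 - (p + k)/2 and
#' t = sqrt((p^2 (k-1)^2 - 4) / (p^2 + (k-1)^2 - 5)) (t = 1 when the
#' denominator is non-positive), df1 = p(k-1), df2 = m t - df1/2 + 1 and
#' F = ((1 - L^(1/t)) / L^(1/t)) (df2/df1).
#'
#' @param lambda Wilks' lambda in (0, 1].
#' @param p Number of response variables.
#' @param k Number of groups.
#' @param N Total sample size.
#' @return List with `f_stat`, `df1`, `df2`, `p_value`.
#' @export
rao_f <- function(lambda, p, k, N) {
  m <- N - 1 - (p + k) / 2
  denom <- p^2 + (k - 1)^2 - 5
  t <- if (denom > 0) sqrt((p^2 * (k - 1)^2 - 4) / denom) else 1
  df1 <- p * (k - 1)
  df2 <- m * t - df1 / 2 + 1
  lam_t <- lambda^(1 / t)
  f_stat <- ((1 - lam_t) / lam_t) * (df2 / df1)
  list(f_stat = f_stat, df1 = df1, df2 = df2,
       p_value = stats::pf(f_stat, df1, df2, lower.tail = FALSE))
}

#' One-way MANOVA with Wilks' lambda
#'
#' Tests whether multivariate group mean vectors differ across sites. Wilks'
#' lambda is det(W)/det(W+B) from the within- and between-group scatter
#' matrices; significance uses Rao's F approximation (see [rao_f()]), which
#' is exact for p <= 2 or k <= 3 and otherwise an excellent approximation.
#'
#' @param z Numeric matrix or `z_table` (birds x elements).
#' @param labels Site label per row (defaults to the table's `site` column).
#' @return A `manova_result`: `wilks_lambda`, `f_stat`, `df1`, `df2`,
#'   `p_value`, `bartlett_chisq`/`bartlett_df`/`bartlett_p`, `N`, `p`, `k`.
#' @export
manova_wilks <- function(z, labels = NULL) {
  if (inherits(z, "z_table") || inherits(z, "ratio_table")) {
    if (is.null(labels)) labels <- z$site
    z <- z_matrix(z)
  }
  if (is.null(labels)) stop("labels required for a plain matrix", call. = FALSE)
  sc <- scatter_matrices(z, labels)
  if (sc$N <= sc$p + sc$k) {
    stop("too few rows: need N > p + k for an invertible within scatter",
         call. = FALSE)
  }
  lambda <- wilks_from_scatter(sc$W, sc$B)
  fr <- rao_f(lambda, sc$p, sc$k, sc$N)
  # Bartlett's chi-square, used for residual-function tests downstream
  bart_mult <- sc$N - 1 - (sc$p + sc$k) / 2
  bart <- -bart_mult * log(lambda)
  bart_df <- sc$p * (sc$k - 1)
  structure(
    list(wilks_lambda = lambda, f_stat = fr$f_stat, df1 = fr$df1,
         df2 = fr$df2, p_value = fr$p_value,
         bartlett_chisq = bart, bartlett_df = bart_df,
         bartlett_p = stats::pchisq(bart, bart_df, lower.tail = FALSE),
         N = sc$N, p = sc$p, k = sc$k),
    class = "manova_result"
  )
}

#' @export
print.manova_result <- function(x, ...) {
  cat(sprintf(
    "One-way MANOVA (Wilks): lambda = %.4g, F = %.3f, df = %d, %.3f, p %s\n",
    x$wilks_lambda, x$f_stat, x$df1, x$df2,
    format.pval(x$p_value, digits = 3)))
  cat(sprintf("  N = %d birds, p = %d variables, k = %d groups\n",
              x$N, x$p, x$k))
  invisible(x)
}
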