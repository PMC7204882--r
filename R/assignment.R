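# Assigning fall-caught problem birds to natal sites by centroid-ratio
# closeness, with immigrant/unassigned detection.

#' Centroid-ratio normalization of canonical scores
#'
#' For every bird and every site, divides each retained canonical score by
#' the site centroid's value on that function: a bird lying exactly at a
#' site's centroid scores 1 on every function with respect to that site.
#' Near-zero centroid components (|centroid| < `eps`) make the ratio
#' unstable; those cells are returned as NA and excluded from that site's
#' closeness.
#'
#' @param lib A `fingerprint_library`.
#' @param scores Matrix of canonical scores (birds x retained functions), as
#'   from [predict_scores()] with `retained_only = TRUE`.
#' @param eps Centroid-magnitude guard (default 1e-9).
#' @return 3-d array `[bird, site, function]` of ratios (NA where the
#'   centroid component is below `eps`).
#' @export
centroid_normalize <- function(lib, scores, eps = 1e-9) {
  scores <- as.matrix(scores)
  r <- lib$n_retained
  if (ncol(scores) < r) stop("scores have fewer columns than retained ",
                             "functions", call. = FALSE)
  scores <- scores[, seq_len(r), drop = FALSE]
  cen <- lib$centroids[, seq_len(r), drop = FALSE]
  undef <- abs(cen) < eps
  if (any(undef)) {
    warning(sum(undef), " centroid component(s) below ", eps,
            "; corresponding ratio cells marked undefined", call. = FALSE)
  }
  out <- array(NA_real_,
               dim = c(nrow(scores), nrow(cen), r),
               dimnames = list(rownames(scores), lib$sites,
                               colnames(cen)))
  for (s in seq_len(nrow(cen))) {
    for (j in seq_len(r)) {
      if (!undef[s, j]) out[, s, j] <- scores[, j] / cen[s, j]
    }
  }
  out
}

#' Assign problem birds to natal sites
#'
#' Two closeness measures are offered. `method = "ratio"` follows the
#' centroid-ratio reading: d_s = sqrt(sum_j (rho_sj - 1)^2) over the defined
#' cells, i.e. the Euclidean distance of the bird's centroid-normalized
#' score vector from all-ones. `method = "mahalanobis"` uses the squared
#' canonical-space distance to each centroid directly. Either way the bird
#' is assigned the site minimizing d_s (ties to the first site in library
#' order), and is flagged immigrant/unassigned when its smallest
#' Mahalanobis D-squared to any centroid exceeds `tau`, i.e. when its
#' fingerprint is too far from every sampled source.
#'
#' By default `tau` is the (1 - `alpha`) quantile of the training birds'
#' leave-one-out min-D-squared distribution stored in the library by
#' [build_library()]: for new birds exchangeable with the library this
#' gives a false-flag rate of about `alpha` under any within-site
#' distribution, absorbing the inflation of out-of-sample distances caused
#' by estimating coefficients, centroids and covariance from a finite
#' library. For a library without stored calibration the threshold falls
#' back to the chi-square quantile at 1 - `alpha` with df = retained
#' functions, which is calibrated only for in-sample multivariate-normal
#' scores and flags out-of-sample birds too readily.
#'
#' @param lib A `fingerprint_library`.
#' @param z Numeric matrix or `z_table` of birds (library element columns
#'   required), or a pre-computed score matrix via `scores`.
#' @param method `"ratio"` (centroid-ratio closeness) or `"mahalanobis"`.
#' @param alpha Immigrant test size used for the default threshold.
#' @param tau Override for the D-squared cutoff; bypasses both defaults.
#' @param scores Optional score matrix (retained functions) instead of `z`.
#' @return An `origin_assignment` data frame: `bird_id`, the retained
#'   canonical scores, per-site closeness `d_<site>`, `min_d2`,
#'   `assigned_site`, logical `immigrant_unassigned`, and `origin_call`
#'   (assigned site or "immigrant_unassigned"). The threshold and method are
#'   attached as attributes.
#' @export
assign_origin <- function(lib, z = NULL, method = c("ratio", "mahalanobis"),
                          alpha = 0.05, tau = NULL, scores = NULL) {
  method <- match.arg(method)
  if (is.null(scores)) {
    if (is.null(z)) stop("supply z or scores", call. = FALSE)
    scores <- predict_scores(lib, z, retained_only = TRUE)
  }
  scores <- as.matrix(scores)[, seq_len(lib$n_retained), drop = FALSE]
  tau_source <- "user"
  if (is.null(tau)) {
    if (!is.null(lib$calibration$loo_min_d2)) {
      tau <- unname(stats::quantile(lib$calibration$loo_min_d2, 1 - alpha))
      tau_source <- "loo_calibrated"
    } else {
      tau <- stats::qchisq(1 - alpha, df = lib$n_retained)
      tau_source <- "chisq"
    }
  }
  cen <- lib$centroids[, seq_len(lib$n_retained), drop = FALSE]
  d2 <- outer(rowSums(scores^2), rep(1, nrow(cen))) -
    2 * scores %*% t(cen) +
    outer(rep(1, nrow(scores)), rowSums(cen^2))
  d2 <- pmax(d2, 0)
  colnames(d2) <- lib$sites
  if (method == "ratio") {
    rho <- centroid_normalize(lib, scores)
    d <- apply(rho, c(1, 2), function(v) {
      v <- v[!is.na(v)]
      if (length(v) == 0) NA_real_ else sqrt(sum((v - 1)^2))
    })
    d <- matrix(d, nrow = nrow(scores), dimnames = dimnames(d2))
  } else {
    d <- d2
  }
  if (any(apply(d, 1, function(r) all(is.na(r))))) {
    stop("bird(s) with no defined closeness to any site", call. = FALSE)
  }
  idx <- apply(d, 1, which.min)
  min_d2 <- apply(d2, 1, min)
  flagged <- min_d2 > tau
  assigned <- lib$sites[idx]
  out <- data.frame(
    bird_id = if (is.null(rownames(scores)))
      as.character(seq_len(nrow(scores))) else rownames(scores),
    scores, stringsAsFactors = FALSE, check.names = FALSE
  )
  dd <- as.data.frame(d)
  names(dd) <- paste0("d_", lib$sites)
  out <- cbind(out, dd)
  out$min_d2 <- min_d2
  out$assigned_site <- assigned
  out$immigrant_unassigned <- flagged
  out$origin_call <- ifelse(flagged, "immigrant_unassigned", assigned)
  structure(out, method = method, tau = tau, tau_source = tau_source,
            alpha = alpha,
            class = c("origin_assignment", "data.frame"))
}

#' Summarize assigned origins by capture context
#'
#' Per capture context (e.g. vineyards/orchards vs dairies/feedlots),
#' tabulates the percentage of problem birds assigned to each source site
#' plus the immigrant/unassigned share, with an optional regional roll-up
#' (e.g. north/central/south groupings of the sites).
#'
#' @param assignments An `origin_assignment`.
#' @param context Character vector of capture contexts, one per bird.
#' @param regions Optional named list mapping region name -> character
#'   vector of site names, for the roll-up.
#' @return A `contribution_summary`: list of per-context data frames
#'   (`source`, `n`, `pct`) and, when `regions` is given, a `regional`
#'   element per context.
#' @export
summarize_by_context <- function(assignments, context, regions = NULL) {
  stopifnot(inherits(assignments, "origin_assignment"))
  context <- as.character(context)
  if (length(context) != nrow(assignments)) {
    stop("context must have one entry per assigned bird", call. = FALSE)
  }
  bad <- setdiff(unique(context), CONTEXT_LEVELS)
  if (length(bad)) stop("unknown context value(s): ",
                        paste(bad, collapse = ", "), call. = FALSE)
  out <- list()
  for (ctx in unique(context)) {
    calls <- assignments$origin_call[context == ctx]
    tab <- sort(table(calls), decreasing = TRUE)
    df <- data.frame(source = names(tab), n = as.numeric(tab),
                     pct = 100 * as.numeric(tab) / length(calls),
                     stringsAsFactors = FALSE)
    entry <- list(table = df, n_total = length(calls))
    if (!is.null(regions)) {
      region_of <- function(src) {
        if (src == "immigrant_unassigned") return("immigrant_unassigned")
        hit <- names(regions)[vapply(regions, function(s) src %in% s,
                                     logical(1))]
        if (length(hit) == 0) "unmapped" else hit[1]
      }
      reg <- vapply(calls, region_of, character(1))
      rtab <- sort(table(reg), decreasing = TRUE)
      entry$regional <- data.frame(
        region = names(rtab), n = as.numeric(rtab),
        pct = 100 * as.numeric(rtab) / length(calls),
        stringsAsFactors = FALSE)
    }
    out[[ctx]] <- entry
  }
  structure(out, class = "contribution_summary")
}

#' @export
print.contribution_summary <- function(x, ...) {
  for (ctx in names(x)) {
    cat(ctx, " (n = ", x[[ctx]]$n_total, "):\n", sep = "")
    df <- x[[ctx]]$table
    for (i in seq_len(nrow(df))) {
      cat(sprintf("  %-22s %3d  (%.1f%%)\n", df$source[i], df$n[i],
                  df$pct[i]))
    }
  }
  invisible(x)
}

#' Write assignments to CSV
#'
#' @param assignments An `origin_assignment`.
#' @param path Output path.
#' @return `path`, invisibly.
#' @export
write_assignments <- function(assignments, path) {
  utils::write.csv(as.data.frame(assignments), path, row.names = FALSE)
  invisible(path)
}
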