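# The juvenile fingerprint library: stepwise variable selection, canonical
# discriminant functions, Mahalanobis classification, leave-one-out
# cross-validation and Press's Q.

resolve_z_labels <- function(z, labels) {
  if (inherits(z, "z_table") || inherits(z, "ratio_table")) {
    if (is.null(labels)) labels <- z$site
    z <- z_matrix(z)
  }
  if (is.null(labels)) stop("labels required for a plain matrix", call. = FALSE)
  list(z = as.matrix(z), labels = as.character(labels))
}

subset_wilks <- function(W, T, vars) {
  if (length(vars) == 0) return(1)
  dW <- det(W[vars, vars, drop = FALSE])
  dT <- det(T[vars, vars, drop = FALSE])
  if (!is.finite(dW) || !is.finite(dT) || dT <= 0) return(NA_real_)
  dW / dT
}

min_pairwise_d2 <- function(x, labels, vars, N, k) {
  xs <- x[, vars, drop = FALSE]
  groups <- unique(labels)
  means <- do.call(rbind, lapply(groups, function(g)
    colMeans(xs[labels == g, , drop = FALSE])))
  W <- scatter_matrices(xs, labels)$W
  Sw <- W / (N - k)
  Swi <- tryCatch(solve(Sw), error = function(e) NULL)
  if (is.null(Swi)) return(NA_real_)
  d2 <- Inf
  for (i in seq_len(length(groups) - 1)) {
    for (j in seq(i + 1, length(groups))) {
      d <- means[i, ] - means[j, ]
      d2 <- min(d2, drop(t(d) %*% Swi %*% d))
    }
  }
  d2
}

#' Stepwise selection of discriminating elements
#'
#' Greedy forward selection with backward removal, gated by partial F as in
#' classical stepwise discriminant analysis. At each step the excluded
#' variables are screened by their F-to-enter
#' F = ((N - k - q)/(k - 1)) (Lambda_q / Lambda_{q+1} - 1) (q = current
#' model size); among those reaching `f_enter` the entrant is the one that
#' best improves the selection criterion — `"wilks"` minimizes the model
#' Wilks' lambda (equivalently, maximizes F-to-enter) and
#' `"mahalanobis_closest_pair"` maximizes the smallest pairwise Mahalanobis
#' D-squared between group centroids. After every entry, any included
#' variable whose F-to-remove drops below `f_remove` is removed. The loop
#' stops when no entry or removal is possible.
#'
#' @param z Numeric matrix or `z_table`.
#' @param labels Site label per row.
#' @param criterion `"wilks"` or `"mahalanobis_closest_pair"`.
#' @param f_enter,f_remove Partial-F thresholds (classical defaults 3.84 and
#'   2.71); `f_enter` must exceed `f_remove`.
#' @return A `stepwise_trace`: data frame of steps (action, element,
#'   criterion value, partial F) with attributes `selected` (final element
#'   set, in entry order) and `flagged_empty`.
#' @export
stepwise_select <- function(z, labels = NULL,
                            criterion = c("mahalanobis_closest_pair", "wilks"),
                            f_enter = 3.84, f_remove = 2.71) {
  criterion <- match.arg(criterion)
  if (f_enter <= f_remove) {
    stop("f_enter must be greater than f_remove", call. = FALSE)
  }
  zl <- resolve_z_labels(z, labels)
  x <- zl$z
  labels <- zl$labels
  sc <- scatter_matrices(x, labels)
  W <- sc$W; T <- W + sc$B; N <- sc$N; k <- sc$k
  panel_order <- colnames(x)
  if (is.null(panel_order)) panel_order <- paste0("V", seq_len(ncol(x)))
  colnames(x) <- panel_order
  dimnames(W) <- dimnames(T) <- list(panel_order, panel_order)

  selected <- character(0)
  trace <- list()
  step <- 0L
  seen_states <- character(0)
  repeat {
    state <- paste(sort(selected), collapse = ",")
    if (state %in% seen_states) break  # cycle guard
    seen_states <- c(seen_states, state)
    lam_cur <- subset_wilks(W, T, selected)
    q <- length(selected)
    candidates <- setdiff(panel_order, selected)
    if (N - k - q < 1) break
    entry <- NULL
    if (length(candidates) > 0) {
      f_to_enter <- rep(NA_real_, length(candidates))
      lam_new <- rep(NA_real_, length(candidates))
      for (i in seq_along(candidates)) {
        lam <- subset_wilks(W, T, c(selected, candidates[i]))
        if (is.na(lam) || lam <= .Machine$double.eps) {
          # collinear candidate: within scatter (numerically) singular
          if (!is.na(lam) && lam <= .Machine$double.eps) {
            warning("skipping collinear candidate '", candidates[i], "'",
                    call. = FALSE)
          }
          next
        }
        lam_new[i] <- lam
        f_to_enter[i] <- ((N - k - q) / (k - 1)) * (lam_cur / lam - 1)
      }
      admissible <- which(!is.na(f_to_enter) & f_to_enter >= f_enter)
      if (length(admissible) > 0) {
        crit_val <- switch(
          criterion,
          wilks = -lam_new[admissible],  # maximize => minimize lambda
          mahalanobis_closest_pair = vapply(admissible, function(i)
            min_pairwise_d2(x, labels, c(selected, candidates[i]), N, k),
            numeric(1))
        )
        # ties: larger partial F, then panel order
        ord <- order(-crit_val, -f_to_enter[admissible],
                     match(candidates[admissible], panel_order))
        best <- admissible[ord[1]]
        entry <- list(element = candidates[best],
                      criterion = if (criterion == "wilks")
                        lam_new[best] else crit_val[ord[1]],
                      partial_f = f_to_enter[best])
      }
    }
    acted <- FALSE
    if (!is.null(entry)) {
      selected <- c(selected, entry$element)
      step <- step + 1L
      trace[[step]] <- data.frame(step = step, action = "enter",
                                  element = entry$element,
                                  criterion = entry$criterion,
                                  partial_f = entry$partial_f,
                                  stringsAsFactors = FALSE)
      acted <- TRUE
    }
    # removal pass: drop weakest included variable while below f_remove
    repeat {
      if (length(selected) == 0) break
      lam_full <- subset_wilks(W, T, selected)
      q2 <- length(selected)
      f_rm <- vapply(selected, function(v) {
        lam_wo <- subset_wilks(W, T, setdiff(selected, v))
        ((N - k - (q2 - 1)) / (k - 1)) * (lam_wo / lam_full - 1)
      }, numeric(1))
      worst <- which.min(f_rm)
      if (is.na(f_rm[worst]) || f_rm[worst] >= f_remove) break
      el <- selected[worst]
      selected <- setdiff(selected, el)
      step <- step + 1L
      trace[[step]] <- data.frame(step = step, action = "remove",
                                  element = el,
                                  criterion = subset_wilks(W, T, selected),
                                  partial_f = f_rm[worst],
                                  stringsAsFactors = FALSE)
      acted <- TRUE
    }
    if (!acted) break
  }
  out <- if (length(trace)) do.call(rbind, trace) else
    data.frame(step = integer(0), action = character(0),
               element = character(0), criterion = numeric(0),
               partial_f = numeric(0))
  flagged <- length(selected) == 0
  if (flagged) warning("no admissible variable entered the model",
                       call. = FALSE)
  structure(out, selected = selected, flagged_empty = flagged,
            criterion = criterion, f_enter = f_enter, f_remove = f_remove,
            class = c("stepwise_trace", "data.frame"))
}

#' @export
print.stepwise_trace <- function(x, ...) {
  sel <- attr(x, "selected")
  cat("Stepwise trace (", attr(x, "criterion"), "): ",
      nrow(x), " step(s); selected: ",
      if (length(sel)) paste(sel, collapse = ", ") else "<none>", "\n",
      sep = "")
  NextMethod()
}

#' Fit canonical discriminant functions
#'
#' Eigen-decomposition of W^-1 B on the selected elements. Raw coefficients
#' are scaled so each canonical score has pooled within-group variance 1 and
#' grand mean 0; eigenvalues come in descending order, with canonical
#' correlations rc_i = sqrt(lambda_i/(1+lambda_i)), variance shares
#' lambda_i/sum(lambda), residual Wilks tests (Bartlett chi-square) and
#' per-site centroids in canonical space. Functions with eigenvalue above
#' `retention_threshold` are marked retained (all are kept in the object).
#'
#' @param z Numeric matrix or `z_table`, already restricted or restrictable
#'   to the selected elements.
#' @param labels Site label per row.
#' @param selected Elements to use (default: all columns).
#' @param retention_threshold Eigenvalue cutoff for retained functions
#'   (default 1). At least one function is always retained.
#' @param scaler Optional `element_scaler` to store with the library so
#'   problem birds can be projected into the same reference frame.
#' @return A `fingerprint_library`.
#' @export
fit_canonical <- function(z, labels = NULL, selected = NULL,
                          retention_threshold = 1, scaler = NULL) {
  zl <- resolve_z_labels(z, labels)
  x <- zl$z; labels <- zl$labels
  if (!is.null(selected)) {
    miss <- setdiff(selected, colnames(x))
    if (length(miss)) stop("selected element(s) absent from data: ",
                           paste(miss, collapse = ", "), call. = FALSE)
    x <- x[, selected, drop = FALSE]
  }
  if (ncol(x) == 0) stop("no variables selected", call. = FALSE)
  sc <- scatter_matrices(x, labels)
  W <- sc$W; B <- sc$B; N <- sc$N; k <- sc$k; p <- sc$p
  sites <- sc$groups
  n_fun <- min(p, k - 1)
  U <- tryCatch(chol(W), error = function(e)
    stop("within-group scatter is singular", call. = FALSE))
  Ui <- backsolve(U, diag(p))
  A <- t(Ui) %*% B %*% Ui
  eig <- eigen((A + t(A)) / 2, symmetric = TRUE)
  lambda <- pmax(eig$values[seq_len(n_fun)], 0)
  # raw coefficients: a' W a = I  =>  scale by sqrt(N-k) for unit pooled
  # within-group variance of the scores
  a <- Ui %*% eig$vectors[, seq_len(n_fun), drop = FALSE] * sqrt(N - k)
  # sign convention: largest-|coefficient| element positive
  for (j in seq_len(n_fun)) {
    i <- which.max(abs(a[, j]))
    if (a[i, j] < 0) a[, j] <- -a[, j]
  }
  rownames(a) <- colnames(x)
  colnames(a) <- paste0("CF", seq_len(n_fun))
  grand <- colMeans(x)
  constant <- -drop(grand %*% a)
  scores <- sweep(x %*% a, 2, -constant)
  centroids <- do.call(rbind, lapply(sites, function(g)
    colMeans(scores[labels == g, , drop = FALSE])))
  dimnames(centroids) <- list(sites, colnames(a))
  # standardized coefficients: raw * pooled within-group SD of each element
  Sw <- W / (N - k)
  std <- a * sqrt(diag(Sw))
  var_shares <- if (sum(lambda) > 0) lambda / sum(lambda) else
    rep(0, n_fun)
  rc <- sqrt(lambda / (1 + lambda))
  # residual Wilks: after removing the first j functions
  m <- N - 1 - (p + k) / 2
  res <- lapply(0:(n_fun - 1), function(j) {
    lam_j <- prod(1 / (1 + lambda[seq_len(n_fun) > j]))
    df <- (p - j) * (k - 1 - j)
    chisq <- -m * log(lam_j)
    data.frame(after_function = j, wilks = lam_j, chisq = chisq, df = df,
               p_value = stats::pchisq(chisq, df, lower.tail = FALSE))
  })
  res <- do.call(rbind, res)
  n_ret <- max(1L, sum(lambda > retention_threshold))
  structure(
    list(elements = colnames(x), sites = sites,
         group_sizes = stats::setNames(
           vapply(sites, function(g) sum(labels == g), numeric(1)), sites),
         coefficients = a, std_coefficients = std, constant = constant,
         eigenvalues = lambda, canonical_correlations = rc,
         variance_shares = var_shares, residual_wilks = res,
         centroids = centroids, within_cov = Sw,
         n_functions = as.integer(n_fun), n_retained = as.integer(n_ret),
         retention_threshold = retention_threshold,
         N = as.integer(N), k = as.integer(k), scaler = scaler),
    class = "fingerprint_library"
  )
}

#' @export
print.fingerprint_library <- function(x, ...) {
  cat("Fingerprint library:", x$k, "sites, N =", x$N, "birds\n")
  cat("  elements:", paste(x$elements, collapse = ", "), "\n")
  cat("  canonical functions:", x$n_functions,
      sprintf("(%d retained, eigenvalue > %g)\n",
              x$n_retained, x$retention_threshold))
  cat("  eigenvalues:", paste(sprintf("%.3f", x$eigenvalues),
                              collapse = ", "), "\n")
  cat("  variance shares:",
      paste(sprintf("%.1f%%", 100 * x$variance_shares), collapse = ", "),
      "\n")
  invisible(x)
}

#' Project birds into canonical space
#'
#' @param lib A `fingerprint_library`.
#' @param z Numeric matrix or `z_table` containing the library's elements.
#' @param retained_only Keep only the retained functions?
#' @return Matrix of canonical scores (rows = birds).
#' @export
predict_scores <- function(lib, z, retained_only = FALSE) {
  if (inherits(z, "z_table") || inherits(z, "ratio_table")) z <- z_matrix(z)
  z <- as.matrix(z)
  miss <- setdiff(lib$elements, colnames(z))
  if (length(miss)) stop("data lack library element(s): ",
                         paste(miss, collapse = ", "), call. = FALSE)
  s <- sweep(z[, lib$elements, drop = FALSE] %*% lib$coefficients, 2,
             -lib$constant)
  if (retained_only) s <- s[, seq_len(lib$n_retained), drop = FALSE]
  s
}

#' Classify birds against the fingerprint library
#'
#' Nearest-centroid rule in the retained canonical space: because the
#' canonical scores have unit pooled within-group variance, squared
#' Euclidean distance to a site centroid is the Mahalanobis D-squared. Ties
#' go to the first site in library order. Priors are equal across sites.
#'
#' @param lib A `fingerprint_library`.
#' @param z Numeric matrix or `z_table` of birds to classify.
#' @return List: `site` (character vector), `d2` (matrix of per-site
#'   D-squared, birds x sites), `scores`.
#' @export
classify <- function(lib, z) {
  scores <- predict_scores(lib, z, retained_only = TRUE)
  cen <- lib$centroids[, seq_len(lib$n_retained), drop = FALSE]
  d2 <- outer(rowSums(scores^2), rep(1, nrow(cen))) -
    2 * scores %*% t(cen) +
    outer(rep(1, nrow(scores)), rowSums(cen^2))
  d2 <- pmax(d2, 0)
  colnames(d2) <- lib$sites
  rownames(d2) <- rownames(scores)
  idx <- apply(d2, 1, which.min)  # which.min takes the first on ties
  list(site = lib$sites[idx], d2 = d2, scores = scores)
}

#' Press's Q statistic
#'
#' Tests whether a classifier beats chance: Q = (N - nK)^2 / (N(K-1)) with n
#' the number correct and K the number of groups, referred to chi-square
#' with 1 df.
#'
#' @param N Total classified.
#' @param K Number of groups (>= 2).
#' @param n_correct Number correctly classified.
#' @return List with `q` and `p_value`.
#' @export
press_q <- function(N, K, n_correct) {
  if (K < 2) stop("K must be at least 2", call. = FALSE)
  if (n_correct < 0 || n_correct > N) {
    stop("n_correct must be between 0 and N", call. = FALSE)
  }
  q <- (N - n_correct * K)^2 / (N * (K - 1))
  list(q = q, p_value = stats::pchisq(q, 1, lower.tail = FALSE))
}

confusion_matrix <- function(truth, predicted, sites) {
  m <- table(factor(truth, levels = sites),
             factor(predicted, levels = sites))
  m <- matrix(as.numeric(m), nrow = length(sites),
              dimnames = list(truth = sites, predicted = sites))
  m
}

#' Leave-one-out cross-validated classification
#'
#' Each bird is held out, the canonical functions are refitted on the
#' remaining N-1 birds (the selected element set stays fixed, matching the
#' classical "cross-validation" of discriminant analysis; set
#' `reselect = TRUE` for full nested re-selection) and the held-out bird is
#' classified. Also reports the resubstitution matrix and Press's Q on the
#' cross-validated counts.
#'
#' @param z Numeric matrix or `z_table`.
#' @param labels Site label per row.
#' @param selected Element set used by the classifier (fixed during LOO).
#' @param retention_threshold Eigenvalue cutoff passed to [fit_canonical()].
#' @param reselect Re-run [stepwise_select()] inside every fold?
#' @param ... Passed to [stepwise_select()] when `reselect = TRUE`.
#' @return A `classification_report`: confusion matrices (`resubstitution`,
#'   `loo`, counts), `per_site_pct`, `overall_pct`, `N`, `K`, `n_correct`,
#'   `press_q`, `press_q_p`, the LOO predictions, and `loo_min_d2` (each
#'   held-out bird's smallest D-squared to any centroid — the reference
#'   distribution used to calibrate the immigrant threshold).
#' @export
loo_crossvalidate <- function(z, labels = NULL, selected = NULL,
                              retention_threshold = 1, reselect = FALSE,
                              ...) {
  zl <- resolve_z_labels(z, labels)
  x <- zl$z; labels <- zl$labels
  if (is.null(selected)) selected <- colnames(x)
  sites <- unique(labels)
  if (any(table(labels) < 2)) {
    warning("site(s) with a single bird: that bird's holdout fold keeps ",
            "the site with no training row and can never self-assign",
            call. = FALSE)
  }
  full <- fit_canonical(x, labels, selected = selected,
                        retention_threshold = retention_threshold)
  resub_pred <- classify(full, x)$site
  loo_pred <- character(nrow(x))
  loo_min_d2 <- numeric(nrow(x))
  for (i in seq_len(nrow(x))) {
    sel_i <- selected
    if (reselect) {
      tr <- stepwise_select(x[-i, , drop = FALSE], labels[-i], ...)
      sel_i <- attr(tr, "selected")
      if (length(sel_i) == 0) sel_i <- selected
    }
    fit_i <- fit_canonical(x[-i, , drop = FALSE], labels[-i],
                           selected = sel_i,
                           retention_threshold = retention_threshold)
    pred <- classify(fit_i, x[i, , drop = FALSE])
    # a site absent from the fold's training data can never be predicted;
    # the held-out bird is simply assigned its nearest remaining centroid
    loo_pred[i] <- pred$site
    loo_min_d2[i] <- min(pred$d2)
  }
  cm_resub <- confusion_matrix(labels, resub_pred, sites)
  cm_loo <- confusion_matrix(labels, loo_pred, sites)
  n_correct <- sum(diag(cm_loo))
  N <- nrow(x); K <- length(sites)
  pq <- press_q(N, K, n_correct)
  per_site <- 100 * diag(cm_loo) / rowSums(cm_loo)
  structure(
    list(resubstitution = cm_resub, loo = cm_loo,
         per_site_pct = per_site,
         overall_pct = 100 * n_correct / N,
         resub_overall_pct = 100 * sum(diag(cm_resub)) / N,
         N = N, K = K, n_correct = n_correct,
         press_q = pq$q, press_q_p = pq$p_value,
         loo_predicted = loo_pred, loo_min_d2 = loo_min_d2,
         sites = sites),
    class = "classification_report"
  )
}

#' @export
print.classification_report <- function(x, ...) {
  cat(sprintf(
    "Leave-one-out classification: %.1f%% correct (%d/%d, %d sites)\n",
    x$overall_pct, x$n_correct, x$N, x$K))
  cat(sprintf("  Press's Q = %.2f (p %s); resubstitution %.1f%%\n",
              x$press_q, format.pval(x$press_q_p, digits = 3),
              x$resub_overall_pct))
  cat("  per-site %:",
      paste(sprintf("%s %.0f", names(x$per_site_pct), x$per_site_pct),
            collapse = ", "), "\n")
  invisible(x)
}

#' Write a confusion matrix as row-percentage CSV
#'
#' One row per true site with predicted-site percentages and the site's n,
#' mirroring the usual cross-validated classification table layout.
#'
#' @param report A `classification_report`.
#' @param path Output path.
#' @param which `"loo"` or `"resubstitution"`.
#' @return `path`, invisibly.
#' @export
write_confusion_csv <- function(report, path, which = c("loo",
                                                        "resubstitution")) {
  which <- match.arg(which)
  cm <- report[[which]]
  pct <- round(100 * cm / rowSums(cm), 1)
  out <- data.frame(site = rownames(cm), pct, n = rowSums(cm),
                    check.names = FALSE)
  utils::write.csv(out, path, row.names = FALSE)
  invisible(path)
}

#' Train the full fingerprint library from a sample table
#'
#' Convenience wrapper for the canonical workflow: calcium ratios, z-scoring
#' (scaler fitted on this table and stored in the library), stepwise element
#' selection, canonical fit and leave-one-out cross-validation. The LOO
#' min-D-squared distribution of the training birds is stored in the
#' library (`calibration`) so [assign_origin()] can use a threshold with
#' the nominal false-flag rate for new birds (see that function's details).
#'
#' @param st A [sample_table()] of known-origin (library) birds.
#' @param panel The element panel.
#' @param criterion,f_enter,f_remove Passed to [stepwise_select()].
#' @param retention_threshold Passed to [fit_canonical()].
#' @return List with `library` (a `fingerprint_library`), `trace`
#'   (`stepwise_trace`), `z` (the training `z_table`), `manova` and `cv`
#'   (the LOO `classification_report`).
#' @export
build_library <- function(st, panel = attr(st, "panel"),
                          criterion = "mahalanobis_closest_pair",
                          f_enter = 3.84, f_remove = 2.71,
                          retention_threshold = 1) {
  prep <- preprocess_samples(st, panel)
  trace <- stepwise_select(prep$z, criterion = criterion,
                           f_enter = f_enter, f_remove = f_remove)
  sel <- attr(trace, "selected")
  if (length(sel) == 0) stop("stepwise selection retained no element",
                             call. = FALSE)
  lib <- fit_canonical(prep$z, selected = sel,
                       retention_threshold = retention_threshold,
                       scaler = prep$scaler)
  cv <- loo_crossvalidate(prep$z, selected = sel,
                          retention_threshold = retention_threshold)
  lib$calibration <- list(loo_min_d2 = cv$loo_min_d2)
  list(library = lib, trace = trace, z = prep$z,
       manova = manova_wilks(prep$z), cv = cv)
}
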