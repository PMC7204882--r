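# Readers and writers: CSV sample tables, JSON fingerprint libraries,
# Newick dendrograms.

#' Read a sample table from CSV
#'
#' Expects a comma-separated, UTF-8, "."-decimal file with a header row
#' containing `bird_id`, the metadata columns (`site`, `age_class`,
#' `season`, `context`) and one column per panel element.
#'
#' @param path Path to the CSV file.
#' @param panel An [element_panel()].
#' @return A validated [sample_table()], element columns in panel order.
#' @export
read_sample_table <- function(path, panel = element_panel()) {
  if (!file.exists(path)) stop("file not found: ", path, call. = FALSE)
  df <- utils::read.csv(path, stringsAsFactors = FALSE,
                        fileEncoding = "UTF-8", check.names = FALSE)
  sample_table(df, panel)
}

#' Write a sample table to CSV
#'
#' @param st A [sample_table()].
#' @param path Output path.
#' @return `path`, invisibly.
#' @export
write_sample_table <- function(st, path) {
  utils::write.csv(as.data.frame(st), path, row.names = FALSE,
                   fileEncoding = "UTF-8")
  invisible(path)
}

#' Serialize a fingerprint library to JSON
#'
#' Stores every numeric field of the trained library (selected elements,
#' canonical coefficients, eigenvalues, centroids, pooled within-group
#' covariance, scaler statistics, ...) in a single human-inspectable JSON
#' document at full double precision, matrices row-major with their label
#' arrays.
#'
#' @param lib A `fingerprint_library` as returned by [build_library()] or
#'   [fit_canonical()].
#' @param path Output path.
#' @return `path`, invisibly.
#' @seealso [read_library()]
#' @export
write_library <- function(lib, path) {
  stopifnot(inherits(lib, "fingerprint_library"))
  ser <- list(
    format = "traceassign_library",
    version = 1L,
    elements = lib$elements,
    sites = lib$sites,
    group_sizes = as.numeric(lib$group_sizes),
    coefficients = mat_ser(lib$coefficients),
    std_coefficients = mat_ser(lib$std_coefficients),
    constant = as.numeric(lib$constant),
    eigenvalues = as.numeric(lib$eigenvalues),
    canonical_correlations = as.numeric(lib$canonical_correlations),
    variance_shares = as.numeric(lib$variance_shares),
    residual_wilks = lib$residual_wilks,
    centroids = mat_ser(lib$centroids),
    within_cov = mat_ser(lib$within_cov),
    n_functions = lib$n_functions,
    n_retained = lib$n_retained,
    retention_threshold = lib$retention_threshold,
    N = lib$N,
    k = lib$k,
    scaler = if (is.null(lib$scaler)) NULL else list(
      elements = lib$scaler$elements,
      center = as.numeric(lib$scaler$center),
      scale = as.numeric(lib$scaler$scale)
    ),
    calibration = if (is.null(lib$calibration)) NULL else list(
      loo_min_d2 = as.numeric(lib$calibration$loo_min_d2)
    )
  )
  jsonlite::write_json(ser, path, auto_unbox = TRUE, digits = NA,
                       null = "null")
  invisible(path)
}

mat_ser <- function(m) {
  list(rows = rownames(m), cols = colnames(m), dim = dim(m),
       data = as.numeric(t(m)))  # row-major
}

mat_deser <- function(s) {
  m <- matrix(as.numeric(unlist(s$data)), nrow = s$dim[[1]],
              ncol = s$dim[[2]], byrow = TRUE)
  rn <- unlist(s$rows)
  cn <- unlist(s$cols)
  if (length(rn)) rownames(m) <- rn
  if (length(cn)) colnames(m) <- cn
  m
}

#' Read a fingerprint library from JSON
#'
#' Lossless inverse of [write_library()]: all numeric fields are restored to
#' full stored precision.
#'
#' @param path Path to a library JSON file.
#' @return A `fingerprint_library`.
#' @export
read_library <- function(path) {
  if (!file.exists(path)) stop("file not found: ", path, call. = FALSE)
  ser <- tryCatch(
    jsonlite::read_json(path, simplifyVector = FALSE),
    error = function(e) stop("cannot parse library file '", path, "': ",
                             conditionMessage(e), call. = FALSE)
  )
  need <- c("format", "elements", "sites", "coefficients", "eigenvalues",
            "centroids", "within_cov")
  if (!is.list(ser) || !all(need %in% names(ser)) ||
      !identical(ser$format, "traceassign_library")) {
    stop("corrupt or partial library file: ", path, call. = FALSE)
  }
  rw <- lapply(ser$residual_wilks, function(r)
    lapply(r, function(x) if (is.null(x)) NA_real_ else x))
  rw <- do.call(rbind, lapply(rw, as.data.frame))
  lib <- list(
    elements = unlist(ser$elements),
    sites = unlist(ser$sites),
    group_sizes = stats::setNames(as.numeric(unlist(ser$group_sizes)),
                                  unlist(ser$sites)),
    coefficients = mat_deser(ser$coefficients),
    std_coefficients = mat_deser(ser$std_coefficients),
    constant = as.numeric(unlist(ser$constant)),
    eigenvalues = as.numeric(unlist(ser$eigenvalues)),
    canonical_correlations = as.numeric(unlist(ser$canonical_correlations)),
    variance_shares = as.numeric(unlist(ser$variance_shares)),
    residual_wilks = rw,
    centroids = mat_deser(ser$centroids),
    within_cov = mat_deser(ser$within_cov),
    n_functions = as.integer(ser$n_functions),
    n_retained = as.integer(ser$n_retained),
    retention_threshold = as.numeric(ser$retention_threshold),
    N = as.integer(ser$N),
    k = as.integer(ser$k),
    scaler = if (is.null(ser$scaler)) NULL else {
      el <- unlist(ser$scaler$elements)
      structure(list(
        elements = el,
        center = stats::setNames(as.numeric(unlist(ser$scaler$center)), el),
        scale = stats::setNames(as.numeric(unlist(ser$scaler$scale)), el)
      ), class = "element_scaler")
    },
    calibration = if (is.null(ser$calibration)) NULL else list(
      loo_min_d2 = as.numeric(unlist(ser$calibration$loo_min_d2))
    )
  )
  class(lib) <- "fingerprint_library"
  lib
}

#' Export a dendrogram as Newick text
#'
#' Leaf labels are the bird identifiers; branch lengths are derived from the
#' merge heights (each leaf/internal edge spans the height difference to its
#' parent, so two leaves merged at height h sit at depth h/2 each).
#'
#' @param tree A `dendro_fit` from [agglomerate()] (or a plain `hclust`).
#' @param path Optional output path; when `NULL` the Newick string is
#'   returned.
#' @return Newick string (invisibly when written to `path`).
#' @export
export_newick <- function(tree, path = NULL) {
  hc <- if (inherits(tree, "dendro_fit")) tree$hclust else tree
  if (!inherits(hc, "hclust")) stop("not a dendrogram", call. = FALSE)
  if (length(hc$labels) < 2 || nrow(hc$merge) < 1) {
    stop("dendrogram must have at least 2 leaves", call. = FALSE)
  }
  phy <- ape::as.phylo(hc)
  txt <- ape::write.tree(phy)
  if (is.null(path)) return(txt)
  writeLines(txt, path)
  invisible(txt)
}
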