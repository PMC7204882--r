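# Preprocessing: per-bird calcium-ratio normalization, then per-element
# z-standardization with the training statistics kept for later application
# to unknown (problem) birds.

#' Normalize concentrations to calcium
#'
#' Divides every non-calcium element concentration by the bird's calcium
#' concentration, cancelling row-level variation in mineral:collagen content
#' of bone. The calcium column is consumed; metadata is carried through.
#'
#' @param st A [sample_table()].
#' @param panel The [element_panel()]; defaults to the table's own panel.
#' @return A `ratio_table`: data frame with the metadata columns and one
#'   dimensionless ratio column per non-calcium element.
#' @export
normalize_to_calcium <- function(st, panel = attr(st, "panel")) {
  if (is.null(panel)) panel <- element_panel()
  st <- sample_table(as.data.frame(st), panel)  # revalidates Ca > 0
  ca <- st[[panel$calcium]]
  out <- st[, METADATA_COLS, drop = FALSE]
  for (el in panel$analytes) out[[el]] <- st[[el]] / ca
  extra <- setdiff(names(st), c(METADATA_COLS, panel$elements))
  for (col in extra) out[[col]] <- st[[col]]
  structure(as.data.frame(out), elements = panel$analytes,
            class = c("ratio_table", "data.frame"))
}

ratio_elements <- function(rt) {
  el <- attr(rt, "elements")
  if (is.null(el)) stop("not a ratio_table", call. = FALSE)
  el
}

#' Fit a z-scoring scaler
#'
#' Computes per-element mean and standard deviation (n-1 denominator) of the
#' calcium ratios over a training table. The fitted statistics define the
#' reference frame later applied to problem birds.
#'
#' @param rt A `ratio_table` from [normalize_to_calcium()].
#' @return An `element_scaler` with fields `elements`, `center`, `scale`.
#' @export
fit_scaler <- function(rt) {
  el <- ratio_elements(rt)
  if (nrow(rt) < 2) stop("need at least 2 rows to fit a scaler", call. = FALSE)
  center <- vapply(rt[el], mean, numeric(1))
  scale <- vapply(rt[el], stats::sd, numeric(1))
  if (any(scale <= 0 | !is.finite(scale))) {
    bad <- el[scale <= 0 | !is.finite(scale)]
    stop("degenerate (constant) ratio column(s): ",
         paste(bad, collapse = ", "), call. = FALSE)
  }
  structure(list(elements = el, center = center, scale = scale),
            class = "element_scaler")
}

#' Apply a fitted scaler
#'
#' Standardizes each ratio column as z = (ratio - mu)/sigma using the
#' training statistics stored in the scaler, so every element contributes on
#' a comparable scale to the multivariate analyses.
#'
#' @param scaler An `element_scaler` from [fit_scaler()].
#' @param rt A `ratio_table` whose element set matches the scaler's.
#' @return A `z_table`: metadata columns plus standardized element columns.
#' @export
apply_scaler <- function(scaler, rt) {
  stopifnot(inherits(scaler, "element_scaler"))
  el <- ratio_elements(rt)
  if (!setequal(el, scaler$elements)) {
    miss <- setdiff(scaler$elements, el)
    extra <- setdiff(el, scaler$elements)
    stop("element set mismatch between scaler and table",
         if (length(miss)) paste0("; missing: ", paste(miss, collapse = ", ")),
         if (length(extra)) paste0("; unexpected: ",
                                   paste(extra, collapse = ", ")),
         call. = FALSE)
  }
  out <- rt[, intersect(names(rt), setdiff(names(rt), el)), drop = FALSE]
  for (e in scaler$elements) {
    out[[e]] <- (rt[[e]] - scaler$center[[e]]) / scaler$scale[[e]]
  }
  structure(as.data.frame(out), elements = scaler$elements,
            class = c("z_table", "data.frame"))
}

#' Extract the numeric z-matrix from a z-table
#'
#' @param zt A `z_table` (or `ratio_table`).
#' @return Numeric matrix, one row per bird (rownames = bird_id), one column
#'   per element.
#' @export
z_matrix <- function(zt) {
  el <- attr(zt, "elements")
  if (is.null(el)) stop("not a z_table/ratio_table", call. = FALSE)
  m <- as.matrix(as.data.frame(zt)[el])
  rownames(m) <- zt$bird_id
  m
}

#' Calcium-normalize and z-score in one step
#'
#' Convenience wrapper: ratios, then a scaler fitted on (or supplied for)
#' the same table.
#'
#' @param st A [sample_table()].
#' @param panel The element panel.
#' @param scaler Optional pre-fitted `element_scaler` (e.g. the juvenile
#'   library's); when `NULL` a scaler is fitted on `st` itself.
#' @return List with `z` (the `z_table`) and `scaler`.
#' @export
preprocess_samples <- function(st, panel = attr(st, "panel"), scaler = NULL) {
  rt <- normalize_to_calcium(st, panel)
  if (is.null(scaler)) scaler <- fit_scaler(rt)
  list(z = apply_scaler(scaler, rt), scaler = scaler)
}
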