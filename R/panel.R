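# Element panels and the sample table container.

#' Default 21-element bone panel
#'
#' The element symbols measured in starling tarsometatarsus bone: 20 trace
#' elements plus calcium, the normalizer that cancels variable
#' mineral:collagen content.
#'
#' @format Character vector of 21 element symbols.
#' @export
DEFAULT_ELEMENTS <- c(
  "Al", "Ag", "Ba", "Ca", "Cd", "Co", "Cr", "Cu", "Mo", "Mn",
  "Pb", "S", "Sc", "Se", "Sn", "Sr", "V", "Zn", "Mg", "Na", "K"
)

#' Define an element panel
#'
#' An element panel fixes the ordered set of measured elements and names the
#' calcium column used as the normalizer. Downstream analyses see the
#' remaining elements (20 under the default panel) as calcium ratios.
#'
#' @param elements Ordered character vector of element symbols.
#' @param calcium Symbol of the normalizing element; must be in `elements`.
#' @return Object of class `element_panel` with fields `elements`, `calcium`
#'   and `analytes` (the non-calcium elements, in panel order).
#' @examples
#' p <- element_panel()
#' length(p$analytes)  # 20
#' @export
element_panel <- function(elements = DEFAULT_ELEMENTS, calcium = "Ca") {
  elements <- as.character(elements)
  if (anyDuplicated(elements)) {
    stop("element panel contains duplicated symbols", call. = FALSE)
  }
  if (!calcium %in% elements) {
    stop("calcium symbol '", calcium, "' is not a member of the panel",
         call. = FALSE)
  }
  structure(
    list(
      elements = elements,
      calcium = calcium,
      analytes = setdiff(elements, calcium)
    ),
    class = "element_panel"
  )
}

#' @export
print.element_panel <- function(x, ...) {
  cat("Element panel:", length(x$elements), "elements (normalizer:",
      x$calcium, ")\n")
  cat(" ", paste(x$elements, collapse = " "), "\n")
  invisible(x)
}

AGE_LEVELS <- c("juvenile", "adult_lt1y", "adult_1plus")
SEASON_LEVELS <- c("summer", "fall")
CONTEXT_LEVELS <- c("vineyard_orchard", "dairy_feedlot", "library", "unknown")

METADATA_COLS <- c("bird_id", "site", "age_class", "season", "context")

#' Construct and validate a sample table
#'
#' A sample table holds one row per bird: identifier, capture metadata and
#' one concentration column per panel element (a single consistent
#' concentration unit, e.g. ug/g). Calcium must be strictly positive in
#' every row; bird identifiers must be unique.
#'
#' @param df Data frame with columns `bird_id`, `site`, `age_class`,
#'   `season`, `context` and one numeric column per panel element. Extra
#'   columns (e.g. simulation ground truth) are carried through.
#' @param panel An [element_panel()].
#' @return `df`, validated, with element columns reordered to panel order
#'   and classed `sample_table` (panel attached as attribute).
#' @export
sample_table <- function(df, panel = element_panel()) {
  stopifnot(is.data.frame(df))
  df <- as.data.frame(df, stringsAsFactors = FALSE)
  missing_meta <- setdiff(METADATA_COLS, names(df))
  if (length(missing_meta) > 0) {
    stop("sample table is missing metadata column(s): ",
         paste(missing_meta, collapse = ", "), call. = FALSE)
  }
  missing_el <- setdiff(panel$elements, names(df))
  if (length(missing_el) > 0) {
    stop("sample table is missing element column(s): ",
         paste(missing_el, collapse = ", "), call. = FALSE)
  }
  df$bird_id <- as.character(df$bird_id)
  if (anyDuplicated(df$bird_id)) {
    dup <- unique(df$bird_id[duplicated(df$bird_id)])
    stop("duplicate bird_id value(s): ", paste(dup, collapse = ", "),
         call. = FALSE)
  }
  bad_age <- setdiff(unique(df$age_class), AGE_LEVELS)
  if (length(bad_age) > 0) {
    stop("unknown age_class value(s): ", paste(bad_age, collapse = ", "),
         call. = FALSE)
  }
  bad_season <- setdiff(unique(df$season), SEASON_LEVELS)
  if (length(bad_season) > 0) {
    stop("unknown season value(s): ", paste(bad_season, collapse = ", "),
         call. = FALSE)
  }
  bad_ctx <- setdiff(unique(df$context), CONTEXT_LEVELS)
  if (length(bad_ctx) > 0) {
    stop("unknown context value(s): ", paste(bad_ctx, collapse = ", "),
         call. = FALSE)
  }
  for (el in panel$elements) {
    v <- df[[el]]
    if (!is.numeric(v)) {
      v <- suppressWarnings(as.numeric(v))
      if (anyNA(v) && !anyNA(df[[el]])) {
        stop("non-numeric concentration in column '", el, "'", call. = FALSE)
      }
      df[[el]] <- v
    }
    if (anyNA(df[[el]])) {
      bad <- df$bird_id[is.na(df[[el]])]
      stop("missing or non-numeric concentration for element '", el,
           "' in bird(s): ", paste(bad, collapse = ", "), call. = FALSE)
    }
    if (any(df[[el]] < 0)) {
      bad <- df$bird_id[df[[el]] < 0]
      stop("negative concentration for element '", el, "' in bird(s): ",
           paste(bad, collapse = ", "), call. = FALSE)
    }
  }
  if (any(df[[panel$calcium]] <= 0)) {
    bad <- df$bird_id[df[[panel$calcium]] <= 0]
    stop(panel$calcium, " must be strictly positive; offending bird(s): ",
         paste(bad, collapse = ", "), call. = FALSE)
  }
  extra <- setdiff(names(df), c(METADATA_COLS, panel$elements))
  df <- df[, c(METADATA_COLS, panel$elements, extra), drop = FALSE]
  rownames(df) <- NULL
  structure(df, panel = panel, class = c("sample_table", "data.frame"))
}

#' @export
print.sample_table <- function(x, ...) {
  panel <- attr(x, "panel")
  cat("Sample table:", nrow(x), "birds,", length(panel$elements),
      "elements,", length(unique(x$site)), "site(s)\n")
  NextMethod()
}
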