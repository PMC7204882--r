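# End-to-end orchestration: config, seeded runs, JSON run report.

#' Run configuration
#'
#' Bundles every tunable of the workflow. All randomness derives from the
#' single `seed`.
#'
#' @param seed Integer master seed.
#' @param f_enter,f_remove Stepwise partial-F thresholds (classical defaults
#'   3.84 / 2.71); `f_enter > f_remove` required.
#' @param selection_criterion `"mahalanobis_closest_pair"` or `"wilks"`.
#' @param eigenvalue_retention_threshold Canonical functions with
#'   eigenvalues above this are used downstream (default 1).
#' @param immigrant_alpha Size of the immigrant/unassigned chi-square cut.
#' @param assignment_method `"ratio"` or `"mahalanobis"`.
#' @param scaler_mode `"library"` applies the juvenile-library scaler to
#'   problem birds; `"pooled"` refits the scaler on juveniles + problem
#'   birds jointly (used for the all-birds clustering view).
#' @param cluster_linkage,cluster_metric Clustering defaults.
#' @param bootstrap_scales,bootstrap_B Multiscale-bootstrap settings.
#' @param regions Named list mapping region -> site names for the
#'   contribution roll-up.
#' @return A `run_config` list.
#' @export
run_config <- function(seed = 1, f_enter = 3.84, f_remove = 2.71,
                       selection_criterion = "mahalanobis_closest_pair",
                       eigenvalue_retention_threshold = 1,
                       immigrant_alpha = 0.05,
                       assignment_method = "ratio",
                       scaler_mode = c("library", "pooled"),
                       cluster_linkage = "ward.D",
                       cluster_metric = "euclidean",
                       bootstrap_scales = seq(0.5, 1.4, by = 0.1),
                       bootstrap_B = 1000,
                       regions = list(
                         north = c("Salmon Arm", "Mara", "Armstrong",
                                   "Hullcar", "Vernon"),
                         central = "Kelowna",
                         south = c("Penticton", "Keremeos", "Oliver",
                                   "Osoyoos"))) {
  if (f_enter <= f_remove) stop("f_enter must exceed f_remove",
                                call. = FALSE)
  if (immigrant_alpha <= 0 || immigrant_alpha >= 1) {
    stop("immigrant_alpha must be in (0, 1)", call. = FALSE)
  }
  if (any(bootstrap_scales <= 0)) stop("bootstrap scales must be positive",
                                       call. = FALSE)
  structure(
    list(seed = as.integer(seed), f_enter = f_enter, f_remove = f_remove,
         selection_criterion = match.arg(selection_criterion,
                                         c("mahalanobis_closest_pair",
                                           "wilks")),
         eigenvalue_retention_threshold = eigenvalue_retention_threshold,
         immigrant_alpha = immigrant_alpha,
         assignment_method = match.arg(assignment_method,
                                       c("ratio", "mahalanobis")),
         scaler_mode = match.arg(scaler_mode),
         cluster_linkage = cluster_linkage,
         cluster_metric = cluster_metric,
         bootstrap_scales = bootstrap_scales,
         bootstrap_B = as.integer(bootstrap_B),
         regions = regions),
    class = "run_config"
  )
}

#' Run the full fingerprinting workflow
#'
#' Preprocess -> MANOVA -> stepwise canonical library -> LOO
#' cross-validation -> problem-bird assignment -> clustering with bootstrap
#' support, returning everything in one run report. Identical
#' config + inputs give an identical report (timestamps excluded).
#'
#' @param library_birds [sample_table()] of known-origin juveniles.
#' @param problem_birds Optional [sample_table()] of birds to assign.
#' @param config A [run_config()].
#' @param panel The element panel.
#' @param bootstrap Compute multiscale-bootstrap support? (The slowest
#'   step; disable for quick runs.)
#' @return A `run_report` list: `config`, `manova`, `trace`, `library`,
#'   `classification`, `assignments`, `contributions`, `cluster_support`,
#'   `version`, `seed`.
#' @export
run_pipeline <- function(library_birds, problem_birds = NULL,
                         config = run_config(),
                         panel = attr(library_birds, "panel"),
                         bootstrap = TRUE) {
  built <- build_library(library_birds, panel,
                         criterion = config$selection_criterion,
                         f_enter = config$f_enter,
                         f_remove = config$f_remove,
                         retention_threshold =
                           config$eigenvalue_retention_threshold)
  report <- built$cv
  assignments <- NULL
  contributions <- NULL
  if (!is.null(problem_birds)) {
    rt_prob <- normalize_to_calcium(problem_birds, panel)
    scaler <- if (config$scaler_mode == "library") built$library$scaler else {
      rt_all <- rbind(
        as.data.frame(normalize_to_calcium(library_birds, panel))[
          , c(METADATA_COLS, panel$analytes)],
        as.data.frame(rt_prob)[, c(METADATA_COLS, panel$analytes)])
      fit_scaler(structure(rt_all, elements = panel$analytes,
                           class = c("ratio_table", "data.frame")))
    }
    zp <- apply_scaler(scaler, rt_prob)
    rownames_z <- zp$bird_id
    assignments <- assign_origin(built$library, zp,
                                 method = config$assignment_method,
                                 alpha = config$immigrant_alpha)
    assignments$bird_id <- rownames_z
    contributions <- summarize_by_context(assignments,
                                          problem_birds$context,
                                          regions = config$regions)
  }
  support <- NULL
  if (bootstrap) {
    support <- multiscale_bootstrap(
      built$z, metric = config$cluster_metric,
      linkage = config$cluster_linkage,
      scales = config$bootstrap_scales, B = config$bootstrap_B,
      seed = config$seed + 7L)
  }
  structure(
    list(config = config, manova = built$manova, trace = built$trace,
         library = built$library, classification = report,
         assignments = assignments, contributions = contributions,
         cluster_support = support,
         version = as.character(utils::packageVersion("traceassign")),
         seed = config$seed),
    class = "run_report"
  )
}

#' @export
print.run_report <- function(x, ...) {
  cat("== Fingerprinting run report (seed", x$seed, ")==\n")
  print(x$manova)
  print(x$library)
  print(x$classification)
  if (!is.null(x$contributions)) print(x$contributions)
  if (!is.null(x$cluster_support)) print(x$cluster_support)
  invisible(x)
}

#' Serialize a run report to JSON
#'
#' Flattens the report's numeric content (config echo, MANOVA, stepwise
#' trace, library summary, classification, assignment calls, cluster
#' support) into one JSON document. Every number is regenerable from
#' config + inputs.
#'
#' @param report A `run_report`.
#' @param path Output path.
#' @return `path`, invisibly.
#' @export
write_run_report <- function(report, path) {
  lib <- report$library
  ser <- list(
    version = report$version,
    seed = report$seed,
    config = unclass(report$config),
    manova = unclass(report$manova),
    stepwise = list(
      steps = as.data.frame(report$trace),
      selected = attr(report$trace, "selected")
    ),
    library = list(
      elements = lib$elements, sites = lib$sites,
      eigenvalues = lib$eigenvalues,
      canonical_correlations = lib$canonical_correlations,
      variance_shares = lib$variance_shares,
      n_retained = lib$n_retained,
      centroids = mat_ser(lib$centroids)
    ),
    classification = list(
      loo = mat_ser(report$classification$loo),
      per_site_pct = as.list(report$classification$per_site_pct),
      overall_pct = report$classification$overall_pct,
      n_correct = report$classification$n_correct,
      N = report$classification$N, K = report$classification$K,
      press_q = report$classification$press_q,
      press_q_p = report$classification$press_q_p
    ),
    assignments = if (is.null(report$assignments)) NULL else
      as.data.frame(report$assignments),
    contributions = if (is.null(report$contributions)) NULL else
      lapply(unclass(report$contributions), function(e)
        list(n_total = e$n_total, table = e$table,
             regional = e$regional)),
    cluster_support = if (is.null(report$cluster_support)) NULL else
      list(support = report$cluster_support$support,
           scales = report$cluster_support$scales,
           B = report$cluster_support$B,
           seed = report$cluster_support$seed)
  )
  jsonlite::write_json(ser, path, auto_unbox = TRUE, digits = NA,
                       null = "null", dataframe = "columns")
  invisible(path)
}
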