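#' Read a pipeline run configuration
#'
#' Reads a JSON or YAML configuration for [run_pipeline()] (the dialect is
#' picked by file extension; `.json` via jsonlite, anything else via yaml).
#'
#' @param path Configuration file.
#' @return A named list.
#' @export
read_run_config <- function(path) {
  if (!file.exists(path)) {
    abort(sprintf("Config file '%s' does not exist.", path))
  }
  if (grepl("\\.json$", path, ignore.case = TRUE)) {
    jsonlite::read_json(path, simplifyVector = TRUE)
  } else {
    yaml::read_yaml(path)
  }
}

# Fill missing config entries with defaults, recursively one level deep.
config_defaults <- function(config) {
  defaults <- list(
    seed = 1L,
    output_dir = NULL,
    readings = NULL,
    simulate = list(),
    preprocess = list(ref_scope = "plate", analyte_key = "class_label",
                      min_dynamic_range = 0.05, on_missing = "drop"),
    outliers = list(alpha = 0.05, drop_threshold = 2, max_outliers = "auto",
                    grouping = "class"),
    cv = list(classifiers = c("gaussian_naive_bayes",
                              "k_nearest_neighbours",
                              "linear_discriminant_analysis",
                              "adaboost", "svc_linear", "svc_rbf",
                              "dummy_uniform", "dummy_stratified"),
              k_outer = 5, k_inner = 3),
    selection = list(k_features = 5, n_trees = 500, n_permutations = 50,
                     importance_model = "linear_discriminant_analysis"),
    compare = TRUE
  )
  for (nm in names(defaults)) {
    if (is.null(config[[nm]])) {
      config[[nm]] <- defaults[[nm]]
    } else if (is.list(defaults[[nm]]) && is.list(config[[nm]])) {
      config[[nm]] <- utils::modifyList(defaults[[nm]], config[[nm]])
    }
  }
  config
}

#' Run the full differential-sensing analysis pipeline
#'
#' Orchestrates simulate (optional) -> preprocess -> outlier screen ->
#' nested-CV classification -> feature ranking -> reduced-panel comparison,
#' writing each stage's artifact into `output_dir` (when given) and
#' returning everything invisibly as a list. All randomness is governed by
#' the single `seed` entry; rerunning the same configuration reproduces the
#' same fingerprint matrix, screen and results.
#'
#' The configuration is a named list (or a path readable by
#' [read_run_config()]) with entries:
#' \describe{
#'   \item{seed}{integer master seed (default 1).}
#'   \item{output_dir}{where to write artifacts; `NULL` writes nothing.}
#'   \item{readings}{path to a raw readings CSV; mutually exclusive with
#'     `simulate`.}
#'   \item{simulate}{list of arguments split between [sim_panel()] and
#'     [sim_config()]; used when `readings` is absent.}
#'   \item{preprocess, outliers, cv, selection}{stage parameter lists, see
#'     [preprocess_plates()], [outlier_config()], [nested_cv()],
#'     [rank_barrels()].}
#'   \item{compare}{if `TRUE` (default) run [reduce_and_compare()] with the
#'     best non-dummy classifier and the dummy comparison F-test.}
#' }
#'
#' Artifacts written: `resolved_config.json`, `fingerprints.csv`,
#' `screen_report.json`, `cv_results.csv`, `confusion_<algorithm>.csv`,
#' `feature_ranking.csv`, `comparison.json` (and `readings.csv` plus ground
#' truth when simulating).
#'
#' @param config Named list or path to a JSON/YAML file.
#' @return Invisibly, a list with `fingerprints`, `screen`, `cv_results`
#'   (named list of `bs_cv`), `ranking`, `reduction`, `dummy_ftest`,
#'   `config`.
#' @export
#' @examples
#' res <- run_pipeline(list(
#'   seed = 1,
#'   simulate = list(n_barrels = 8, n_classes = 2, n_informative = 3,
#'                   n_samples_per_class = 5, n_technical_reps = 2),
#'   cv = list(classifiers = c("linear_discriminant_analysis", "dummy_uniform")),
#'   selection = list(k_features = 2, n_trees = 100, n_permutations = 10)
#' ))
#' glance(res$cv_results$linear_discriminant_analysis)
run_pipeline <- function(config) {
  if (is.character(config)) config <- read_run_config(config)
  if (!is.list(config)) abort("`config` must be a list or a file path.")
  config <- config_defaults(config)
  seed <- as.integer(config$seed)
  out_dir <- config$output_dir
  if (!is.null(out_dir)) dir.create(out_dir, recursive = TRUE, showWarnings = FALSE)

  save_json <- function(x, name) {
    if (!is.null(out_dir)) {
      jsonlite::write_json(x, file.path(out_dir, name), auto_unbox = TRUE,
                           digits = NA, pretty = TRUE)
    }
  }
  save_csv <- function(x, name) {
    if (!is.null(out_dir)) readr::write_csv(x, file.path(out_dir, name))
  }
  save_json(config[setdiff(names(config), "output_dir")], "resolved_config.json")

  ## Stage 1: obtain raw readings ------------------------------------------
  sim <- NULL
  if (!is.null(config$readings)) {
    if (!file.exists(config$readings)) {
      abort(sprintf("Readings file '%s' does not exist.", config$readings))
    }
    readings <- read_raw_readings(config$readings)
  } else {
    sim_args <- config$simulate
    panel_names <- intersect(names(sim_args), names(formals(sim_panel)))
    cfg_names <- intersect(names(sim_args), names(formals(sim_config)))
    panel <- do.call(sim_panel, c(sim_args[setdiff(panel_names, "seed")],
                                  list(seed = seed)))
    scfg <- do.call(sim_config, c(sim_args[setdiff(cfg_names, "seed")],
                                  list(seed = seed + 1L)))
    sim <- simulate_raw_plates(panel, scfg)
    readings <- sim$readings
    if (!is.null(out_dir)) write_sim(sim, out_dir)
  }

  ## Stage 2: preprocess -----------------------------------------------------
  pp <- config$preprocess
  fingerprints <- preprocess_plates(readings, ref_scope = pp$ref_scope,
                                    analyte_key = pp$analyte_key,
                                    min_dynamic_range = pp$min_dynamic_range,
                                    on_missing = pp$on_missing)
  save_csv(fingerprints, "fingerprints.csv")

  ## Stage 3: outlier screen -------------------------------------------------
  oc <- config$outliers
  screen <- screen_fingerprints(
    fingerprints,
    outlier_config(alpha = oc$alpha, drop_threshold = oc$drop_threshold,
                   max_outliers = oc$max_outliers, grouping = oc$grouping)
  )
  save_json(list(summary = as.list(glance(screen)),
                 flags = screen$flags,
                 dropped = screen$dropped$sample_id),
            "screen_report.json")
  retained <- screen$retained

  ## Stage 4: classification -------------------------------------------------
  cvc <- config$cv
  cv_results <- list()
  for (i in seq_along(cvc$classifiers)) {
    alg <- cvc$classifiers[[i]]
    cv_results[[alg]] <- nested_cv(retained, classifier_spec(alg),
                                   k_outer = cvc$k_outer,
                                   k_inner = cvc$k_inner,
                                   seed = seed + 100L + i)
  }
  cv_table <- purrr::map_dfr(cv_results, glance)
  save_csv(cv_table, "cv_results.csv")
  if (!is.null(out_dir)) {
    for (alg in names(cv_results)) {
      save_csv(tibble::as_tibble(as.data.frame(cv_results[[alg]]$confusion)),
               sprintf("confusion_%s.csv", alg))
    }
  }

  ## Stage 5: feature ranking ------------------------------------------------
  sel <- config$selection
  ranking <- rank_barrels(
    retained,
    spec = classifier_spec(sel$importance_model),
    n_trees = sel$n_trees, n_permutations = sel$n_permutations,
    seed = seed + 200L
  )
  save_csv(tibble::as_tibble(ranking), "feature_ranking.csv")

  ## Stage 6: reduced panel and dummy comparison -----------------------------
  reduction <- NULL
  dummy_ftest <- NULL
  if (isTRUE(config$compare)) {
    non_dummy <- cv_table[!grepl("^dummy", cv_table$algorithm), ]
    best_alg <- non_dummy$algorithm[which.max(non_dummy$accuracy)]
    best_spec <- classifier_spec(best_alg)
    k <- min(sel$k_features, nrow(ranking))
    reduction <- reduce_and_compare(retained, ranking, k = k,
                                    spec = best_spec, seed = seed + 300L,
                                    k_outer = cvc$k_outer,
                                    k_inner = cvc$k_inner)
    dummy_ftest <- ftest_5x2cv(retained, best_spec,
                               classifier_spec("dummy_stratified"),
                               seed = seed + 400L)
    save_json(list(
      best_algorithm = best_alg,
      reduced_features = reduction$features,
      full = as.list(glance(reduction$full_cv)),
      reduced = as.list(glance(reduction$reduced_cv)),
      reduced_vs_full = as.list(glance(reduction$ftest)),
      best_vs_dummy = as.list(glance(dummy_ftest))
    ), "comparison.json")
  }

  invisible(list(
    fingerprints = fingerprints,
    screen = screen,
    cv_results = cv_results,
    cv_table = cv_table,
    ranking = ranking,
    reduction = reduction,
    dummy_ftest = dummy_ftest,
    sim = sim,
    config = config
  ))
}
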