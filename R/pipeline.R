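# End-to-end pipeline stages and the run manifest: simulate -> build-models
# -> screen -> call -> stats -> viz, each writing versioned artifacts.

#' Run configuration for the pipeline stages
#'
#' @param out_dir Output directory for all stage artifacts.
#' @param cohort [cohort_config()] for the simulate stage.
#' @param screening [screening_config()].
#' @param definitions [pathway_definitions()] output.
#' @param alpha Significance level for the stats stage.
#' @param n_calibration Random sequences per model for calibration.
#' @param seed Master integer seed; stage seeds derive from it.
#' @return A `run_config` list.
#' @export
run_config <- function(out_dir = tempfile("reservescan_run_"),
                       cohort = cohort_config(),
                       screening = screening_config(),
                       definitions = pathway_definitions(),
                       alpha = 0.05, n_calibration = 200L, seed = 1L) {
  structure(list(out_dir = out_dir, cohort = cohort, screening = screening,
                 definitions = definitions, alpha = alpha,
                 n_calibration = as.integer(n_calibration),
                 seed = as.integer(seed)),
            class = "run_config")
}

#' Load a YAML run configuration
#'
#' Reads the keys of [run_config()] (plus nested `cohort:` and `screening:`
#' blocks) from a YAML file; unset keys fall back to the defaults.
#'
#' @param path Path to a YAML file.
#' @return A `run_config`.
#' @export
read_run_config <- function(path) {
  y <- yaml::read_yaml(path)
  coh <- do.call(cohort_config, c(
    y$cohort[setdiff(names(y$cohort),
                     c("decoy_count_sampler", "decoy_length_sampler"))],
    lapply(y$cohort[intersect(names(y$cohort),
                              c("decoy_count_sampler",
                                "decoy_length_sampler"))],
           function(s) do.call(sampler_spec, s))
  ))
  scr <- do.call(screening_config, y$screening %||% list())
  run_config(out_dir = y$out_dir %||% tempfile("reservescan_run_"),
             cohort = coh, screening = scr,
             definitions = pathway_definitions(y$glgb %||% "GH13"),
             alpha = y$alpha %||% 0.05,
             n_calibration = y$n_calibration %||% 200L,
             seed = y$seed %||% 1L)
}

stage_path <- function(config, ...) file.path(config$out_dir, ...)

require_artifact <- function(config, file, produced_by) {
  p <- stage_path(config, file)
  if (!file.exists(p)) {
    stop("missing upstream artifact '", file, "': run the '", produced_by,
         "' stage first", call. = FALSE)
  }
  p
}

write_manifest <- function(config, stage, outputs, extra = list()) {
  manifest <- c(list(
    stage = stage,
    package_version = as.character(utils::packageVersion("reservescan")),
    seed = config$seed,
    config_hash = rlang::hash(config[setdiff(names(config), "out_dir")]),
    timestamp = format(Sys.time(), "%Y-%m-%dT%H:%M:%S%z"),
    outputs = outputs
  ), extra)
  jsonlite::write_json(manifest,
                       stage_path(config, paste0("manifest_", stage, ".json")),
                       auto_unbox = TRUE, digits = NA)
}

#' Run one pipeline stage
#'
#' Stages mirror the screening workflow: `simulate` writes a synthetic
#' cohort; `build-models` constructs and calibrates the profile models;
#' `screen` produces hit tables and enzyme copy counts; `call` the pathway
#' matrix; `stats` the group-size comparisons; `viz` the Newick tree and
#' iTOL layers; `all` chains everything. Each stage writes its artifacts
#' plus a JSON manifest (seed, config hash, outputs) under
#' `config$out_dir`, and fails with a dependency error if an upstream
#' artifact is missing.
#'
#' @param stage One of `"simulate"`, `"build-models"`, `"screen"`,
#'   `"call"`, `"stats"`, `"viz"`, `"all"`.
#' @param config A [run_config()].
#' @param registry Seed registry.
#' @return Stage result, invisibly (the matrix for `"call"`, comparison
#'   table for `"stats"`, file tibble for `"viz"`, result list for
#'   `"all"`).
#' @export
run_stage <- function(stage = c("simulate", "build-models", "screen", "call",
                                "stats", "viz", "all"),
                      config = run_config(), registry = seed_registry()) {
  stage <- match.arg(stage)
  dir.create(config$out_dir, recursive = TRUE, showWarnings = FALSE)

  if (stage == "all") {
    for (s in c("simulate", "build-models", "screen", "call", "stats",
                "viz")) {
      res <- run_stage(s, config, registry)
    }
    return(invisible(res))
  }

  if (stage == "simulate") {
    coh <- config$cohort
    coh$rng_seed <- config$seed
    cohort <- generate_cohort(coh, registry)
    write_cohort(cohort, stage_path(config, "cohort"))
    write_manifest(config, "simulate",
                   list(cohort_dir = "cohort"),
                   list(n_proteomes = length(cohort$proteomes)))
    return(invisible(cohort))
  }

  if (stage == "build-models") {
    models <- build_model_set(registry, seed = config$seed + 1L)
    models <- calibrate_models(models, config$n_calibration,
                               seed = config$seed + 2L)
    dir.create(stage_path(config, "models"), showWarnings = FALSE)
    for (m in models) {
      write_profile_model(m, stage_path(config, "models",
                                        paste0(gsub(":", "_", m$model_id),
                                               ".json")))
    }
    write_manifest(config, "build-models", list(models_dir = "models"),
                   list(n_models = length(models)))
    return(invisible(models))
  }

  if (stage == "screen") {
    require_artifact(config, "cohort", "simulate")
    mdir <- require_artifact(config, "models", "build-models")
    models <- lapply(list.files(mdir, pattern = "\\.json$",
                                full.names = TRUE), read_profile_model)
    names(models) <- vapply(models, `[[`, character(1), "model_id")
    res <- screen_cohort(models, stage_path(config, "cohort"), registry,
                         config$screening, keep_hits = TRUE)
    readr::write_tsv(res$hits, stage_path(config, "hits.tsv"))
    readr::write_tsv(res$profiles, stage_path(config, "profiles.tsv"))
    write_manifest(config, "screen",
                   list(hits = "hits.tsv", profiles = "profiles.tsv"),
                   list(n_kept_hits = nrow(res$hits)))
    return(invisible(res))
  }

  if (stage == "call") {
    p <- require_artifact(config, "profiles.tsv", "screen")
    profiles <- readr::read_tsv(p, show_col_types = FALSE)
    taxonomy <- readr::read_tsv(
      file.path(require_artifact(config, "cohort", "simulate"),
                "taxonomy.tsv"), show_col_types = FALSE)
    matrix <- build_matrix(profiles, config$definitions, taxonomy)
    write_matrix_tsv(matrix, stage_path(config, "pathway_matrix.tsv"))
    jsonlite::write_json(tibble::as_tibble(matrix),
                         stage_path(config, "pathway_matrix.json"),
                         auto_unbox = TRUE, digits = NA)
    write_manifest(config, "call", list(matrix = "pathway_matrix.tsv"))
    return(invisible(matrix))
  }

  if (stage == "stats") {
    p <- require_artifact(config, "pathway_matrix.tsv", "call")
    matrix <- readr::read_tsv(p, show_col_types = FALSE)
    comparisons <- compare_all_pathways(matrix, alpha = config$alpha)
    readr::write_tsv(comparisons, stage_path(config, "comparisons.tsv"))
    write_manifest(config, "stats", list(comparisons = "comparisons.tsv"))
    return(invisible(comparisons))
  }

  # viz
  p <- require_artifact(config, "pathway_matrix.tsv", "call")
  matrix <- readr::read_tsv(p, show_col_types = FALSE)
  taxonomy <- readr::read_tsv(
    file.path(require_artifact(config, "cohort", "simulate"),
              "taxonomy.tsv"), show_col_types = FALSE)
  newick <- build_tree(taxonomy)
  writeLines(newick, stage_path(config, "taxonomy.nwk"))
  layers <- export_layers(matrix, newick, dir = stage_path(config, "itol"))
  write_manifest(config, "viz",
                 list(tree = "taxonomy.nwk", layers_dir = "itol"))
  invisible(list(newick = newick, layers = layers, matrix = matrix))
}

#' Run the whole pipeline in memory
#'
#' Convenience wrapper chaining every stage without touching disk (unless
#' `out_dir` is given): returns the cohort, models, profiles, matrix,
#' comparisons, tree and layer values in one list.
#'
#' @param config A [run_config()].
#' @param registry Seed registry.
#' @param write Write stage artifacts under `config$out_dir` too.
#' @return List with `cohort`, `models`, `profiles`, `hits`, `matrix`,
#'   `comparisons`, `newick`.
#' @export
run_pipeline <- function(config = run_config(), registry = seed_registry(),
                         write = FALSE) {
  if (write) {
    res <- run_stage("all", config, registry)
  }
  coh <- config$cohort
  coh$rng_seed <- config$seed
  cohort <- generate_cohort(coh, registry)
  models <- build_model_set(registry, seed = config$seed + 1L)
  models <- calibrate_models(models, config$n_calibration,
                             seed = config$seed + 2L)
  scr <- screen_cohort(models, cohort, registry, config$screening,
                       keep_hits = TRUE)
  matrix <- build_matrix(scr$profiles, config$definitions, cohort$taxonomy)
  comparisons <- compare_all_pathways(matrix, alpha = config$alpha)
  newick <- build_tree(cohort$taxonomy)
  list(cohort = cohort, models = models, profiles = scr$profiles,
       hits = scr$hits, matrix = matrix, comparisons = comparisons,
       newick = newick)
}
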