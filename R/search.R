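# Screening proteomes against profile models: local Viterbi scoring,
# Gumbel E-value calibration, the acceptance-rule filter and per-proteome
# enzyme copy counting.

#' Screening acceptance thresholds
#'
#' The acceptance rule keeps a hit iff its E-value is strictly below
#' `evalue_max` and its query coverage strictly above `min_query_coverage`
#' (defaults: E < 1e-10 and coverage > 60% of the query model).
#'
#' @param evalue_max Positive E-value bound (strict "less than").
#' @param min_query_coverage Coverage bound in (0, 1] (strict
#'   "greater than").
#' @param database_size_policy `"PER_PROTEOME"` (E-values use each
#'   proteome's protein count as the number of targets) or `"FIXED_N"`.
#' @param fixed_n Target count used under `"FIXED_N"`.
#' @return A `screening_config` list.
#' @export
screening_config <- function(evalue_max = 1e-10, min_query_coverage = 0.60,
                             database_size_policy = c("PER_PROTEOME", "FIXED_N"),
                             fixed_n = NULL) {
  database_size_policy <- match.arg(database_size_policy)
  if (!is.numeric(evalue_max) || evalue_max <= 0) {
    stop("evalue_max must be positive", call. = FALSE)
  }
  if (!is.numeric(min_query_coverage) || min_query_coverage <= 0 ||
      min_query_coverage > 1) {
    stop("min_query_coverage must lie in (0, 1]", call. = FALSE)
  }
  if (database_size_policy == "FIXED_N" &&
      (is.null(fixed_n) || fixed_n < 1)) {
    stop("FIXED_N policy needs fixed_n >= 1", call. = FALSE)
  }
  structure(list(evalue_max = evalue_max,
                 min_query_coverage = min_query_coverage,
                 database_size_policy = database_size_policy,
                 fixed_n = fixed_n),
            class = "screening_config")
}

#' Score one protein against a profile model
#'
#' Best local alignment log-odds score (bits) of the protein against the
#' model under Viterbi over match/insert/delete states with a background
#' null: entry and exit are free at any match state, inserts emit at
#' background, insert-delete transitions are forbidden. Spans are 0-based
#' half-open; ambiguity codes (X/B/Z/U) score as background.
#'
#' @param model A `profile_model`.
#' @param protein Non-empty amino-acid string.
#' @return A one-row tibble: `bit_score`, `query_start`, `query_end`,
#'   `target_start`, `target_end`, `query_coverage` (query span length over
#'   `query_length_aa`).
#' @export
score_sequence <- function(model, protein) {
  validate_profile_model(model)
  if (!nzchar(protein)) {
    stop("protein must be non-empty", call. = FALSE)
  }
  res <- cpp_score_proteins(model_log_odds(model), model_log_trans(model),
                            list(encode_sequence(protein)))
  tibble::tibble(bit_score = unname(res[1, 1]),
                 query_start = as.integer(res[1, 2]),
                 query_end = as.integer(res[1, 3]),
                 target_start = as.integer(res[1, 4]),
                 target_end = as.integer(res[1, 5]),
                 query_coverage = unname(res[1, 3] - res[1, 2]) /
                   model$query_length_aa)
}

#' Calibrate a model's E-value parameters
#'
#' Scores `n_random` background-sampled sequences of the model's consensus
#' length and fits a Gumbel distribution to the scores by maximum
#' likelihood; the fitted `(lambda, mu)` (lambda = 1/scale) are stored on
#' the model and drive [evalue_of()].
#'
#' @param model A `profile_model`.
#' @param n_random Number of random sequences (>= 100; default 200).
#' @param seed Optional integer seed (otherwise the current RNG stream is
#'   used).
#' @return The calibrated `profile_model`.
#' @export
calibrate <- function(model, n_random = 200L, seed = NULL) {
  validate_profile_model(model)
  if (n_random < 100) {
    stop("n_random must be >= 100", call. = FALSE)
  }
  draw <- function() {
    seqs <- lapply(seq_len(n_random), function(i) {
      sample.int(20L, model$match_length, replace = TRUE,
                 prob = model$background) - 1L
    })
    cpp_score_proteins(model_log_odds(model), model_log_trans(model),
                       seqs)[, 1]
  }
  scores <- if (is.null(seed)) draw() else withr::with_seed(as.integer(seed), draw())
  fit <- fit_gumbel(scores)
  model$calibration <- fit
  model
}

# Maximum-likelihood Gumbel fit; returns list(lambda = 1/beta, mu).
fit_gumbel <- function(x) {
  if (sd(x) < 1e-12) {
    stop("degenerate score distribution (zero variance); cannot calibrate",
         call. = FALSE)
  }
  # moment start, then ML via the profile equation for beta
  beta <- sd(x) * sqrt(6) / pi
  for (it in 1:200) {
    w <- exp(-x / beta)
    beta_new <- mean(x) - sum(x * w) / sum(w)
    if (!is.finite(beta_new) || beta_new <= 0) break
    if (abs(beta_new - beta) < 1e-10) {
      beta <- beta_new
      break
    }
    beta <- beta_new
  }
  mu <- -beta * log(mean(exp(-x / beta)))
  list(lambda = 1 / beta, mu = mu)
}

#' Convert a bit score to an E-value
#'
#' Gumbel tail approximation `E = n_targets * exp(-lambda * (score - mu))`,
#' capped at `n_targets`: monotone decreasing in score and linear in the
#' number of targets.
#'
#' @param score Bit score(s).
#' @param model A calibrated `profile_model`.
#' @param n_targets Number of target sequences searched.
#' @return Non-negative E-value(s).
#' @export
evalue_of <- function(score, model, n_targets) {
  if (is.null(model$calibration)) {
    stop("model ", model$model_id, " is not calibrated", call. = FALSE)
  }
  lam <- model$calibration$lambda
  mu <- model$calibration$mu
  pmin(n_targets * exp(-lam * (score - mu)), n_targets)
}

#' Calibrate every model in a set
#'
#' @param models Named list of `profile_model`s.
#' @param n_random Random sequences per model.
#' @param seed Integer seed; each model gets a distinct derived stream.
#' @return Named list of calibrated models.
#' @export
calibrate_models <- function(models, n_random = 200L, seed = 11L) {
  withr::with_seed(as.integer(seed), {
    lapply(models, calibrate, n_random = n_random)
  })
}

#' Score every protein of one proteome against every model
#'
#' Emits the raw (unfiltered) hit table: one row per protein x model with
#' the best local alignment. Apply [filter_hits()] for the acceptance rule.
#'
#' @param models Named list of calibrated `profile_model`s.
#' @param proteins Tibble with `id`, `sequence` (one proteome).
#' @param proteome_id Proteome identifier stored on the hits.
#' @param config A [screening_config()] (sets the E-value target count).
#' @return Hit tibble: `enzyme_id`, `model_id`, `proteome_id`, `protein_id`,
#'   `bit_score`, `evalue`, `query_start`, `query_end`, `target_start`,
#'   `target_end`, `query_coverage`.
#' @export
search_proteome <- function(models, proteins, proteome_id,
                            config = screening_config()) {
  n_targets <- if (config$database_size_policy == "PER_PROTEOME") {
    nrow(proteins)
  } else {
    config$fixed_n
  }
  enc <- lapply(proteins$sequence, encode_sequence)
  out <- lapply(models, function(model) {
    res <- cpp_score_proteins(model_log_odds(model), model_log_trans(model),
                              enc)
    tibble::tibble(
      enzyme_id = model$enzyme_id,
      model_id = model$model_id,
      proteome_id = proteome_id,
      protein_id = proteins$id,
      bit_score = unname(res[, 1]),
      evalue = evalue_of(res[, 1], model, n_targets),
      query_start = as.integer(res[, 2]),
      query_end = as.integer(res[, 3]),
      target_start = as.integer(res[, 4]),
      target_end = as.integer(res[, 5]),
      query_coverage = unname(res[, 3] - res[, 2]) / model$query_length_aa
    )
  })
  dplyr::bind_rows(out)
}

#' Apply the screening acceptance rule
#'
#' Keeps exactly the hits with `evalue < evalue_max` and
#' `query_coverage > min_query_coverage` (both strict), preserving order.
#'
#' @param hits Hit tibble (see [search_proteome()]).
#' @param config A [screening_config()].
#' @return Filtered hit tibble.
#' @export
filter_hits <- function(hits, config = screening_config()) {
  dplyr::filter(hits,
                .data$evalue < config$evalue_max,
                .data$query_coverage > config$min_query_coverage)
}

#' Count enzyme copies in one proteome from kept hits
#'
#' The copy number of an enzyme is the number of distinct proteins accepted
#' as its homologs: a protein with several (e.g. tandem) hits to one model
#' counts once, and for a multi-domain `PFAM_DOMAINS` enzyme a protein
#' counts iff *every* listed domain model has a kept hit on it.
#'
#' @param kept_hits Filtered hit tibble for one proteome.
#' @param registry Seed registry (defines enzymes and their domain models).
#' @param proteins Tibble with `id`, `sequence` for the proteome.
#' @param proteome_id Proteome identifier.
#' @return One-row wide tibble: `proteome_id`, `proteome_size`, one
#'   integer column per registry enzyme.
#' @export
count_copies <- function(kept_hits, registry, proteins, proteome_id) {
  unknown <- setdiff(kept_hits$protein_id, proteins$id)
  if (length(unknown) > 0) {
    stop("hits reference unknown protein id(s): ",
         paste(head(unknown, 3), collapse = ", "), call. = FALSE)
  }
  counts <- setNames(integer(nrow(registry)), registry$enzyme_id)
  for (i in seq_len(nrow(registry))) {
    eid <- registry$enzyme_id[i]
    model_ids <- if (registry$model_policy[i] == "DE_NOVO_FULL") {
      eid
    } else {
      paste(eid, registry$pfam_domain_ids[[i]], sep = ":")
    }
    hit_sets <- lapply(model_ids, function(m) {
      unique(kept_hits$protein_id[kept_hits$model_id == m])
    })
    counts[eid] <- length(Reduce(intersect, hit_sets))
  }
  out <- tibble::tibble(proteome_id = proteome_id,
                        proteome_size = nrow(proteins))
  for (eid in names(counts)) out[[eid]] <- counts[[eid]]
  out
}

#' Screen a whole cohort for enzyme copy numbers
#'
#' Runs [search_proteome()], [filter_hits()] and [count_copies()] over every
#' proteome. Deterministic given the (calibrated) models and config.
#'
#' @param models Named list of calibrated `profile_model`s.
#' @param cohort A `reserve_cohort`, or a named list of protein tibbles
#'   (`id`, `sequence`), or a directory of per-proteome FASTA files.
#' @param registry Seed registry.
#' @param config A [screening_config()].
#' @param keep_hits Also return the filtered hit table (default `FALSE`).
#' @return Wide profile tibble (one row per proteome, one column per
#'   enzyme); with `keep_hits = TRUE`, a list `(profiles, hits)`.
#' @export
screen_cohort <- function(models, cohort, registry = seed_registry(),
                          config = screening_config(), keep_hits = FALSE) {
  proteomes <- if (inherits(cohort, "reserve_cohort")) {
    cohort$proteomes
  } else if (is.character(cohort) && length(cohort) == 1) {
    paths <- sort(list.files(cohort, pattern = "\\.fa(sta)?$",
                             full.names = TRUE))
    if (length(paths) == 0) {
      stop("no FASTA files found in ", cohort, call. = FALSE)
    }
    setNames(lapply(paths, read_fasta),
             sub("\\.fa(sta)?$", "", basename(paths)))
  } else {
    cohort
  }
  uncal <- vapply(models, function(m) is.null(m$calibration), logical(1))
  if (any(uncal)) {
    stop("uncalibrated model(s): ",
         paste(names(models)[uncal], collapse = ", "), call. = FALSE)
  }
  profiles <- vector("list", length(proteomes))
  hits_out <- if (keep_hits) vector("list", length(proteomes)) else NULL
  for (i in seq_along(proteomes)) {
    pid <- names(proteomes)[i]
    hits <- search_proteome(models, proteomes[[i]], pid, config)
    kept <- filter_hits(hits, config)
    profiles[[i]] <- count_copies(kept, registry, proteomes[[i]], pid)
    if (keep_hits) hits_out[[i]] <- kept
  }
  profiles <- dplyr::bind_rows(profiles)
  if (keep_hits) {
    list(profiles = profiles, hits = dplyr::bind_rows(hits_out))
  } else {
    profiles
  }
}

#' Read a HMMER3 --domtblout table as a hit tibble
#'
#' Adapter for an external search engine: maps the per-domain table onto
#' this package's hit records (query coverage = HMM span / query length;
#' coordinates converted to 0-based half-open).
#'
#' @param path Path to a `--domtblout` file.
#' @param proteome_id Proteome identifier to stamp on the hits.
#' @return Hit tibble compatible with [filter_hits()].
#' @export
read_domtblout <- function(path, proteome_id = NA_character_) {
  lines <- readLines(path)
  lines <- lines[!grepl("^#", lines) & nzchar(lines)]
  if (length(lines) == 0) {
    return(tibble::tibble(enzyme_id = character(), model_id = character(),
                          proteome_id = character(), protein_id = character(),
                          bit_score = numeric(), evalue = numeric(),
                          query_start = integer(), query_end = integer(),
                          target_start = integer(), target_end = integer(),
                          query_coverage = numeric()))
  }
  parts <- strsplit(trimws(lines), "\\s+")
  f <- function(k, mode = "c") {
    v <- vapply(parts, `[[`, character(1), k)
    switch(mode, c = v, n = as.numeric(v), i = as.integer(v))
  }
  qlen <- f(6, "n")
  hmm_from <- f(16, "n")
  hmm_to <- f(17, "n")
  tibble::tibble(
    enzyme_id = f(4), model_id = f(4), proteome_id = proteome_id,
    protein_id = f(1),
    bit_score = f(14, "n"), evalue = f(13, "n"),
    query_start = as.integer(hmm_from - 1), query_end = as.integer(hmm_to),
    target_start = f(18, "i") - 1L, target_end = f(20, "i"),
    query_coverage = (hmm_to - hmm_from + 1) / qlen
  )
}
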