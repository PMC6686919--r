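# Synthetic proteome cohorts with known ground truth.
#
# The generator plants mutated copies of the seed enzymes among random decoy
# proteins, assigns proteomes to toy clades with clade-restricted pathway
# complements, and shifts decoy counts of pathway-positive proteomes by a
# configurable size effect, so screening, pathway calling, group statistics
# and tree export can all be validated against a recorded truth table.

#' Distribution specification for cohort samplers
#'
#' @param family `"uniform"` (integer-uniform over `min..max`) or `"normal"`
#'   (rounded normal, floored at `min`).
#' @param ... Family parameters: `min`, `max` for uniform; `mean`, `sd` and
#'   optional floor `min` (default 1) for normal.
#' @return A sampler spec list.
#' @export
sampler_spec <- function(family = c("uniform", "normal"), ...) {
  family <- match.arg(family)
  spec <- c(list(family = family), list(...))
  if (family == "uniform") {
    stopifnot(is.numeric(spec$min), is.numeric(spec$max), spec$min <= spec$max)
  } else {
    stopifnot(is.numeric(spec$mean), is.numeric(spec$sd), spec$sd >= 0)
    if (is.null(spec$min)) spec$min <- 1
  }
  structure(spec, class = "sampler_spec")
}

draw_sampler <- function(spec, n) {
  if (spec$family == "uniform") {
    sample(seq(spec$min, spec$max), n, replace = TRUE)
  } else {
    pmax(as.integer(spec$min), as.integer(round(rnorm(n, spec$mean, spec$sd))))
  }
}

#' Scenario table entry: one clade and its planted pathway complement
#'
#' @param clade Clade label used as the phylum rank of the toy taxonomy.
#' @param enzymes Character vector of registry enzyme ids planted in every
#'   proteome of the clade (optionally named integers for copy counts > 1);
#'   empty vector = pathway-negative clade.
#' @param fraction Fraction of the cohort assigned to this clade.
#' @return A scenario list.
#' @export
scenario <- function(clade, enzymes = character(), fraction) {
  if (is.null(names(enzymes))) {
    enzymes <- setNames(rep(1L, length(enzymes)), as.character(enzymes))
  }
  stopifnot(is.numeric(fraction), fraction >= 0, fraction <= 1)
  list(clade = clade, enzymes = enzymes, fraction = fraction)
}

#' Default cohort scenarios
#'
#' Three toy clades emulating the distribution patterns seen across real
#' bacteria: an Actinobacteria-like clade carrying the trehalose (GlgE)
#' glycogen pathway, WS/DGAT, complete polyP metabolism and Group 1 PhaC; a
#' Proteobacteria-like clade carrying the classical glycogen pathway, the
#' PhaABC pathway (Group 2 PhaC), complete polyP, WS/DGAT and the remaining
#' auxiliary enzymes; and a Mollicutes-like clade with no reserve enzymes at
#' all (the pathway-negative, small-proteome group).
#'
#' @return List of [scenario()] entries with fractions summing to 1.
#' @export
default_scenarios <- function() {
  list(
    scenario("Actinobacteria_like",
             c("treS", "pep2", "glgE", "glgB_GH13", "ws_dgat",
               "ppk1", "ppk2", "ppx", "phaC_group1", "rv3032",
               "fabG", "fabD"),
             fraction = 0.3),
    scenario("Proteobacteria_like",
             c("glgC", "glgA", "glgB_GH13", "glgB_GH57", "phaA", "phaB",
               "phaC_group2", "ppk1", "ppk2", "ppx", "ws_dgat", "phaJ",
               "sucD", "hbd4", "orfZ", "pdat"),
             fraction = 0.4),
    scenario("Mollicutes_like", character(), fraction = 0.3)
  )
}

#' Cohort generator configuration
#'
#' @param n_proteomes Number of proteomes (>= 2).
#' @param scenario_table List of [scenario()] entries; fractions must sum
#'   to 1.
#' @param homolog_identity_range Length-2 numeric in (0, 1]: planted-homolog
#'   identity to the seed is drawn uniformly from this range.
#' @param decoy_count_sampler,decoy_length_sampler [sampler_spec()]s for the
#'   number and length of decoy proteins per proteome.
#' @param size_effect Integer added to the decoy count of every
#'   pathway-positive proteome (non-empty planted complement), so pathway
#'   presence and proteome size can be coupled at a controlled effect size.
#' @param rng_seed Integer seed; fixes the whole cohort byte-for-byte.
#' @return A `cohort_config` list.
#' @export
cohort_config <- function(n_proteomes = 100L,
                          scenario_table = default_scenarios(),
                          homolog_identity_range = c(0.85, 0.95),
                          decoy_count_sampler = sampler_spec("uniform", min = 50, max = 80),
                          decoy_length_sampler = sampler_spec("uniform", min = 80, max = 500),
                          size_effect = 20L,
                          rng_seed = 1L) {
  stopifnot(n_proteomes >= 2)
  fr <- vapply(scenario_table, `[[`, numeric(1), "fraction")
  if (abs(sum(fr) - 1) > 1e-8) {
    stop("scenario fractions must sum to 1", call. = FALSE)
  }
  r <- homolog_identity_range
  if (length(r) != 2 || r[1] <= 0 || r[2] > 1 || r[1] > r[2]) {
    stop("homolog_identity_range must lie within (0, 1] with low <= high",
         call. = FALSE)
  }
  structure(list(n_proteomes = as.integer(n_proteomes),
                 scenario_table = scenario_table,
                 homolog_identity_range = r,
                 decoy_count_sampler = decoy_count_sampler,
                 decoy_length_sampler = decoy_length_sampler,
                 size_effect = as.integer(size_effect),
                 rng_seed = as.integer(rng_seed)),
            class = "cohort_config")
}

#' Mutate a seed sequence to an exact target identity
#'
#' Substitutes residues at uniformly chosen positions (without replacement)
#' with uniform draws over the 19 alternative residues, so the returned
#' sequence has Hamming identity `round(target_identity * L) / L` to the
#' seed and identical length. A stand-in for natural homolog divergence.
#'
#' @param seed_sequence Amino-acid string.
#' @param target_identity Fraction in (0, 1].
#' @return Mutated amino-acid string (uses the current RNG stream).
#' @export
mutate_homolog <- function(seed_sequence, target_identity) {
  if (!is.numeric(target_identity) || target_identity <= 0 ||
      target_identity > 1) {
    stop("target_identity must lie in (0, 1]", call. = FALSE)
  }
  if (nchar(seed_sequence) == 0) {
    stop("seed_sequence must be non-empty", call. = FALSE)
  }
  chars <- strsplit(seed_sequence, "", fixed = TRUE)[[1]]
  len <- length(chars)
  n_sub <- len - round(target_identity * len)
  if (n_sub == 0) {
    return(seed_sequence)
  }
  pos <- sample.int(len, n_sub)
  for (p in pos) {
    chars[p] <- sample(setdiff(AA20, chars[p]), 1L)
  }
  paste(chars, collapse = "")
}

#' Generate a random decoy protein
#'
#' @param length Positive integer.
#' @param background Named residue frequency vector (default uniform); see
#'   [background_frequencies()].
#' @return Amino-acid string drawn i.i.d. from `background`.
#' @export
generate_decoy <- function(length, background = background_frequencies("uniform")) {
  if (!is.numeric(length) || length < 1) {
    stop("length must be >= 1", call. = FALSE)
  }
  paste(sample(AA20, length, replace = TRUE, prob = background),
        collapse = "")
}

# Draw clade assignment and proteome sizes (decoy counts) for a cohort.
# This is the size model behind generate_cohort(); the group statistics
# sweeps run directly on it.
sample_cohort_frame <- function(config) {
  n <- config$n_proteomes
  fr <- vapply(config$scenario_table, `[[`, numeric(1), "fraction")
  counts <- floor(fr * n)
  rem <- n - sum(counts)
  if (rem > 0) { # distribute the rounding remainder in scenario order
    counts[seq_len(rem)] <- counts[seq_len(rem)] + 1L
  }
  scen_idx <- rep(seq_along(config$scenario_table), counts)
  positive <- vapply(config$scenario_table,
                     function(s) length(s$enzymes) > 0, logical(1))
  decoys <- draw_sampler(config$decoy_count_sampler, n) +
    ifelse(positive[scen_idx], config$size_effect, 0L)
  tibble::tibble(
    proteome_id = sprintf("prot%04d", seq_len(n)),
    clade = vapply(config$scenario_table, `[[`, character(1),
                   "clade")[scen_idx],
    scenario = scen_idx,
    pathway_positive = positive[scen_idx],
    decoy_count = as.integer(decoys)
  )
}

#' Generate a synthetic proteome cohort with ground truth
#'
#' For each proteome: plants the clade's enzyme complement as mutated copies
#' of the registry seed sequences at identities drawn from
#' `homolog_identity_range`, adds random decoy proteins, and records every
#' planted copy (with its realized identity) in a truth table. Protein ids
#' follow `"<proteome>|p<idx>"`.
#'
#' @param config A [cohort_config()].
#' @param registry Seed registry with sequences, see [seed_registry()].
#' @return A `reserve_cohort` list: `proteomes` (named list of
#'   tibbles with `id`, `sequence`), `taxonomy` (tibble `proteome_id`,
#'   `taxid`, `domain`, `phylum`, `class`), `truth` (tibble `proteome_id`,
#'   `enzyme_id`, `copies`, `identities` list-column), `sizes` (tibble with
#'   decoy and total protein counts) and `config`.
#' @export
generate_cohort <- function(config = cohort_config(), registry = seed_registry()) {
  validate_registry(registry)
  planted_ids <- unique(unlist(lapply(config$scenario_table,
                                      function(s) names(s$enzymes))))
  unknown <- setdiff(planted_ids, registry$enzyme_id)
  if (length(unknown) > 0) {
    stop("scenario enzymes not in registry: ",
         paste(unknown, collapse = ", "), call. = FALSE)
  }
  withr::with_seed(config$rng_seed, {
    frame <- sample_cohort_frame(config)
    seqs_by_enzyme <- setNames(registry$sequence, registry$enzyme_id)
    proteomes <- vector("list", nrow(frame))
    names(proteomes) <- frame$proteome_id
    truth <- vector("list", nrow(frame))
    for (i in seq_len(nrow(frame))) {
      scen <- config$scenario_table[[frame$scenario[i]]]
      planted <- scen$enzymes
      rows <- list()
      idents <- list()
      for (e in names(planted)) {
        ids <- numeric(planted[[e]])
        for (k in seq_len(planted[[e]])) {
          tgt <- runif(1, config$homolog_identity_range[1],
                       config$homolog_identity_range[2])
          rows[[length(rows) + 1L]] <-
            list(enzyme_id = e,
                 sequence = mutate_homolog(seqs_by_enzyme[[e]], tgt))
          ids[k] <- tgt
        }
        idents[[e]] <- ids
      }
      n_dec <- frame$decoy_count[i]
      dec_len <- draw_sampler(config$decoy_length_sampler, n_dec)
      for (k in seq_len(n_dec)) {
        rows[[length(rows) + 1L]] <-
          list(enzyme_id = NA_character_,
               sequence = generate_decoy(dec_len[k]))
      }
      prot_ids <- sprintf("%s|p%d", frame$proteome_id[i], seq_along(rows))
      proteomes[[i]] <- tibble::tibble(
        id = prot_ids,
        sequence = vapply(rows, `[[`, character(1), "sequence"),
        planted_enzyme = vapply(rows, `[[`, character(1), "enzyme_id")
      )
      truth[[i]] <- tibble::tibble(
        proteome_id = frame$proteome_id[i],
        enzyme_id = names(planted) %||% character(),
        copies = as.integer(unname(planted)),
        identities = unname(idents[names(planted)] %||% list())
      )
    }
    taxonomy <- tibble::tibble(
      proteome_id = frame$proteome_id,
      taxid = 100000L + seq_len(nrow(frame)),
      domain = "Bacteria",
      phylum = frame$clade,
      class = sprintf("%s_c%d", frame$clade,
                      1L + (seq_len(nrow(frame)) %% 2L))
    )
    sizes <- frame
    sizes$proteome_size <- unname(vapply(proteomes, nrow, integer(1)))
    structure(list(proteomes = proteomes, taxonomy = taxonomy,
                   truth = dplyr::bind_rows(truth), sizes = sizes,
                   config = config),
              class = "reserve_cohort")
  })
}

`%||%` <- function(a, b) if (is.null(a)) b else a

#' @export
print.reserve_cohort <- function(x, ...) {
  cat("<reserve_cohort> ", length(x$proteomes), " proteomes, ",
      sum(x$sizes$proteome_size), " proteins, ",
      length(unique(x$taxonomy$phylum)), " clades (seed ",
      x$config$rng_seed, ")\n", sep = "")
  invisible(x)
}

#' Write a cohort to disk
#'
#' One multi-FASTA per proteome plus `taxonomy.tsv`, `truth.tsv` and
#' `truth.json`.
#'
#' @param cohort A `reserve_cohort`.
#' @param dir Output directory (created if needed).
#' @return `dir`, invisibly.
#' @export
write_cohort <- function(cohort, dir) {
  dir.create(dir, recursive = TRUE, showWarnings = FALSE)
  for (pid in names(cohort$proteomes)) {
    write_fasta(cohort$proteomes[[pid]], file.path(dir, paste0(pid, ".fasta")))
  }
  readr::write_tsv(cohort$taxonomy, file.path(dir, "taxonomy.tsv"))
  flat <- tidyr::unnest(cohort$truth, "identities", keep_empty = TRUE)
  readr::write_tsv(flat, file.path(dir, "truth.tsv"))
  jsonlite::write_json(cohort$truth, file.path(dir, "truth.json"),
                       auto_unbox = TRUE, digits = NA)
  invisible(dir)
}

#' Planted enzyme copy counts as a wide profile table
#'
#' The ground-truth analog of [screen_cohort()]'s output: one row per
#' proteome, one column per registry enzyme with the planted copy count.
#'
#' @param cohort A `reserve_cohort`.
#' @param registry Seed registry (defines the enzyme columns).
#' @return Tibble with `proteome_id`, `proteome_size` and enzyme columns.
#' @export
truth_profiles <- function(cohort, registry = seed_registry()) {
  base <- tibble::tibble(proteome_id = names(cohort$proteomes),
                         proteome_size = cohort$sizes$proteome_size)
  wide <- tidyr::pivot_wider(
    dplyr::select(cohort$truth, "proteome_id", "enzyme_id", "copies"),
    names_from = "enzyme_id", values_from = "copies", values_fill = 0L
  )
  out <- dplyr::left_join(base, wide, by = "proteome_id")
  for (e in registry$enzyme_id) {
    if (!e %in% names(out)) out[[e]] <- 0L
    out[[e]][is.na(out[[e]])] <- 0L
  }
  dplyr::select(out, "proteome_id", "proteome_size",
                dplyr::all_of(registry$enzyme_id))
}
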