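# Independent oracles and small fixtures used across the suite.

# Random profile model with Dirichlet-ish random emissions and transitions.
random_tiny_model <- function(n_states, peaked = FALSE) {
  em <- matrix(stats::runif(n_states * 20) + if (peaked) 0 else 0.2,
               n_states, 20)
  if (peaked) {
    for (j in seq_len(n_states)) {
      em[j, sample.int(20, 1)] <- em[j, sample.int(20, 1)] + 8
    }
  }
  em <- em / rowSums(em)
  colnames(em) <- reservescan:::AA20
  tr <- matrix(0, n_states, 7,
               dimnames = list(NULL, c("mm", "mi", "md", "im", "ii",
                                       "dm", "dd")))
  for (j in seq_len(n_states)) {
    a <- stats::runif(3) + 0.1
    tr[j, c("mm", "mi", "md")] <- a / sum(a)
    b <- stats::runif(2) + 0.1
    tr[j, c("im", "ii")] <- b / sum(b)
    d <- stats::runif(2) + 0.1
    tr[j, c("dm", "dd")] <- d / sum(d)
  }
  reservescan:::new_profile_model(
    paste0("tiny", n_states), "tiny", em, tr,
    background_frequencies("uniform"))
}

# Exhaustive enumeration over every legal local state path (free entry/exit
# at match states, background inserts, no insert<->delete transitions).
# Completely independent of the dynamic-programming scorer.
enum_best_score <- function(model, protein) {
  a <- reservescan:::encode_sequence(protein) + 1L
  M <- model$match_length
  L <- length(a)
  emlo <- log2(sweep(model$match_emissions, 2, model$background, "/"))
  trlo <- log2(model$transitions)
  best <- -Inf

  extend <- function(i, j, state, score) {
    if (state == "M") {
      best <<- max(best, score) # free exit from any match state
      if (i < L && j < M) {
        extend(i + 1, j + 1, "M",
               score + trlo[j, "mm"] + emlo[j + 1, a[i + 1]])
      }
      if (i < L) {
        extend(i + 1, j, "I", score + trlo[j, "mi"])
      }
      if (j < M) {
        extend(i, j + 1, "D", score + trlo[j, "md"])
      }
    } else if (state == "I") {
      if (i < L && j < M) {
        extend(i + 1, j + 1, "M",
               score + trlo[j, "im"] + emlo[j + 1, a[i + 1]])
      }
      if (i < L) {
        extend(i + 1, j, "I", score + trlo[j, "ii"])
      }
    } else { # D
      if (i < L && j < M) {
        extend(i + 1, j + 1, "M",
               score + trlo[j, "dm"] + emlo[j + 1, a[i + 1]])
      }
      if (j < M) {
        extend(i, j + 1, "D", score + trlo[j, "dd"])
      }
    }
  }

  for (i0 in seq_len(L)) {
    for (j0 in seq_len(M)) {
      extend(i0, j0, "M", emlo[j0, a[i0]])
    }
  }
  best
}

random_protein <- function(len) {
  paste(sample(reservescan:::AA20, len, replace = TRUE), collapse = "")
}

# Three-enzyme registry with short seeds: one de novo full-length model,
# one single-domain and one two-domain Pfam-policy enzyme.
mini_registry <- function(len = 120L) {
  withr::with_seed(424242L, {
    tibble::tibble(
      enzyme_id = c("enzA", "enzB", "enzC"),
      gene = c("enzA", "enzB", "enzC"),
      enzyme_name = paste("Enzyme", c("A", "B", "C")),
      reference_species = "Synthetica testii",
      uniprot_id = c("S00001", "S00002", "S00003"),
      length_aa = c(len, len, len),
      pfam_domain_ids = list("PF90001", "PF90002", c("PF90003", "PF90004")),
      model_policy = c("DE_NOVO_FULL", "PFAM_DOMAINS", "PFAM_DOMAINS"),
      sequence = vapply(1:3, function(i) random_protein(len), character(1))
    )
  })
}

mini_scenarios <- function() {
  list(
    scenario("CladeA", c("enzA", "enzC"), fraction = 0.5),
    scenario("CladeB", character(), fraction = 0.5)
  )
}

mini_config <- function(n = 6L, seed = 99L, size_effect = 0L,
                        identity = c(0.85, 0.95)) {
  cohort_config(
    n_proteomes = n,
    scenario_table = mini_scenarios(),
    homolog_identity_range = identity,
    decoy_count_sampler = sampler_spec("uniform", min = 8, max = 14),
    decoy_length_sampler = sampler_spec("uniform", min = 60, max = 160),
    size_effect = size_effect,
    rng_seed = seed
  )
}

mini_models <- function(registry = mini_registry(), seed = 5L) {
  models <- build_model_set(registry, seed = seed)
  calibrate_models(models, n_random = 120L, seed = seed + 1L)
}

# Profile-free pathway definitions for the mini registry.
mini_definitions <- function() {
  tibble::tibble(pathway_id = c("ac", "b"),
                 label = c("A and C", "B alone"),
                 required = list(c("enzA", "enzC"), "enzB"))
}
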