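# Profile model estimation, the Table-1 model policy, serialization.

test_that("match emissions follow the background-weighted pseudocount formula", {
  msa <- build_msa(rep("ACD", 5))
  w <- 2.5
  q <- background_frequencies("uniform")
  mod <- build_profile(msa, pseudocount_weight = w)

  expect_equal(mod$match_length, 3)
  expect_equal(mod$query_length_aa, 3)
  # 5 observed 'A' at state 1: (5 + w q_A) / (5 + w)
  expect_equal(unname(mod$match_emissions[1, "A"]),
               (5 + w * q[["A"]]) / (5 + w))
  expect_equal(unname(mod$match_emissions[2, "C"]),
               (5 + w * q[["C"]]) / (5 + w))
  expect_equal(unname(mod$match_emissions[1, "W"]),
               (0 + w * q[["W"]]) / (5 + w))

  expect_equal(rowSums(mod$match_emissions), rep(1, 3), tolerance = 1e-12)
  expect_error(build_profile(msa, pseudocount_weight = 0), "positive")
})

test_that("vanishing pseudocount weight recovers empirical column frequencies", {
  seqs <- c("ACD", "ACD", "AWD", "ACD")
  mod <- build_profile(build_msa(seqs), pseudocount_weight = 1e-9)
  expect_equal(unname(mod$match_emissions[2, "C"]), 3 / 4, tolerance = 1e-8)
  expect_equal(unname(mod$match_emissions[2, "W"]), 1 / 4, tolerance = 1e-8)
  expect_equal(unname(mod$match_emissions[1, "A"]), 1, tolerance = 1e-8)
})

test_that("all probability vectors of built models are normalized within 1e-9", {
  withr::with_seed(23, {
    base <- random_protein(60)
    seqs <- vapply(1:6, function(i) mutate_homolog(base, runif(1, 0.7, 0.95)),
                   character(1))
    mod <- build_profile(build_msa(seqs))
    expect_silent(validate_profile_model(mod))
    tr <- mod$transitions
    expect_equal(rowSums(tr[, c("mm", "mi", "md")]), rep(1, mod$match_length),
                 tolerance = 1e-9)
    expect_equal(rowSums(tr[, c("im", "ii")]), rep(1, mod$match_length),
                 tolerance = 1e-9)
    expect_equal(rowSums(tr[, c("dm", "dd")]), rep(1, mod$match_length),
                 tolerance = 1e-9)
  })
})

test_that("degenerate alignments are rejected at model building", {
  thin <- reservescan:::new_msa(tibble::tibble(
    sequence_id = c("a", "b", "c"),
    aligned = c("A--", "-C-", "--D")))
  expect_error(build_profile(thin), "occupancy")
  single <- reservescan:::new_msa(tibble::tibble(sequence_id = "a",
                                                 aligned = "ACD"))
  expect_error(build_profile(single), ">= 2 rows")
})

test_that("resolve_models applies the per-enzyme model policy", {
  reg <- mini_registry()
  store <- synthesize_homolog_store(reg, n_homologs = 8, seed = 3L)
  dstore <- build_domain_store(reg, store)

  # DE_NOVO_FULL: one full-length model
  ms_a <- resolve_models(reg[1, ], store, dstore)
  expect_length(ms_a, 1)
  expect_identical(ms_a[[1]]$model_id, "enzA")
  # the trimmed full model spans (nearly all of) the seed
  expect_gt(ms_a[[1]]$match_length, 0.9 * reg$length_aa[1])

  # single Pfam domain -> one domain model
  ms_b <- resolve_models(reg[2, ], store, dstore)
  expect_length(ms_b, 1)
  expect_identical(ms_b[[1]]$model_id, "enzB:PF90002")

  # two Pfam domains -> two models
  ms_c <- resolve_models(reg[3, ], store, dstore)
  expect_length(ms_c, 2)
  expect_setequal(vapply(ms_c, `[[`, character(1), "model_id"),
                  c("enzC:PF90003", "enzC:PF90004"))

  expect_error(resolve_models(reg[1, ], list(), dstore), "enzA")
  expect_error(resolve_models(reg[3, ], store, dstore["enzC:PF90003"]),
               "enzC:PF90004")
})

test_that("the full registry resolves to the documented model counts", {
  reg <- seed_registry()
  denovo <- reg$enzyme_id[reg$model_policy == "DE_NOVO_FULL"]
  expect_setequal(denovo, c("ppk1", "glgB_GH57", "glgB_GH13", "treS",
                            "pep2", "glgE"))
  # PFAM_DOMAINS enzymes contribute one model per listed domain
  n_domain_models <- sum(lengths(
    reg$pfam_domain_ids[reg$model_policy == "PFAM_DOMAINS"]))
  expect_equal(n_domain_models, 22)
})

test_that("a homolog-built model ranks the seed far above shuffled seeds", {
  withr::with_seed(29, {
    base <- random_protein(100)
    homs <- vapply(1:12, function(i) mutate_homolog(base, runif(1, 0.8, 0.95)),
                   character(1))
    mod <- reservescan:::build_model_from_homologs(homs, "m", "m")
    seed_score <- score_sequence(mod, base)$bit_score
    shuffle_scores <- vapply(1:100, function(i) {
      shuf <- paste(sample(strsplit(base, "")[[1]]), collapse = "")
      score_sequence(mod, shuf)$bit_score
    }, numeric(1))
    expect_gt(seed_score, max(shuffle_scores))
  })
})

test_that("profile models serialize to JSON and back losslessly", {
  withr::with_seed(31, {
    base <- random_protein(40)
    homs <- vapply(1:5, function(i) mutate_homolog(base, 0.9), character(1))
    mod <- reservescan:::build_model_from_homologs(homs, "mj", "ej")
    mod <- calibrate(mod, 150, seed = 2)
  })
  path <- withr::local_tempfile(fileext = ".json")
  write_profile_model(mod, path)
  back <- read_profile_model(path)
  expect_equal(back$match_emissions, mod$match_emissions)
  expect_equal(back$transitions, mod$transitions)
  expect_equal(back$calibration, mod$calibration)
  expect_identical(back$model_id, mod$model_id)
})

test_that("HMMER3 ASCII profiles import with sane structure", {
  path <- test_path("fixtures", "synthetic_domain.hmm")
  mod <- read_hmmer_profile(path)
  expect_s3_class(mod, "profile_model")
  expect_equal(mod$match_length, 25)
  expect_silent(validate_profile_model(mod))
  # consensus of the source alignment scores positively after calibration
  mod <- calibrate(mod, 150, seed = 4)
  cons <- paste(reservescan:::AA20[apply(mod$match_emissions, 1, which.max)],
                collapse = "")
  expect_gt(score_sequence(mod, cons)$bit_score, 0)
})
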