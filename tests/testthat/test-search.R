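# Local Viterbi scoring, E-value calibration, the acceptance filter and
# copy counting.

test_that("Viterbi equals exhaustive path enumeration on tiny cases", {
  withr::with_seed(41, {
    for (k in 1:40) {
      mod <- random_tiny_model(sample(1:4, 1), peaked = (k %% 2 == 0))
      prot <- random_protein(sample(3:8, 1))
      expect_equal(score_sequence(mod, prot)$bit_score,
                   enum_best_score(mod, prot), tolerance = 1e-9)
    }
  })
})

test_that("a consensus protein scores positively with full query coverage", {
  withr::with_seed(42, {
    mod <- random_tiny_model(5, peaked = TRUE)
    cons <- paste(reservescan:::AA20[apply(mod$match_emissions, 1,
                                           which.max)], collapse = "")
    hit <- score_sequence(mod, cons)
    expect_gt(hit$bit_score, 0)
    expect_equal(hit$query_start, 0L)
    expect_equal(hit$query_end, 5L)
    expect_equal(hit$query_coverage, 1)

    # appending unrelated decoy residues far from the hit leaves the local
    # score unchanged
    padded <- paste0(cons, generate_decoy(50))
    expect_equal(score_sequence(mod, padded)$bit_score, hit$bit_score,
                 tolerance = 1e-9)
  })
})

test_that("calibration responds to shifts and scales as a Gumbel fit should", {
  withr::with_seed(43, {
    x <- 5 + 2 * (-log(-log(runif(500))))
  })
  fit <- reservescan:::fit_gumbel(x)
  fit_shift <- reservescan:::fit_gumbel(x + 3)
  expect_equal(fit_shift$mu, fit$mu + 3, tolerance = 1e-6)
  expect_equal(fit_shift$lambda, fit$lambda, tolerance = 1e-6)
  fit_scale <- reservescan:::fit_gumbel(2 * x)
  expect_equal(fit_scale$lambda, fit$lambda / 2, tolerance = 1e-6)
  # and the ML fit recovers the generating parameters reasonably
  expect_equal(1 / fit$lambda, 2, tolerance = 0.2)
  expect_equal(fit$mu, 5, tolerance = 0.3)

  expect_error(reservescan:::fit_gumbel(rep(1, 200)), "degenerate")
})

test_that("calibrate is deterministic under a fixed seed and feeds evalue_of", {
  withr::with_seed(44, {
    base <- random_protein(50)
    homs <- vapply(1:6, function(i) mutate_homolog(base, 0.9), character(1))
  })
  mod <- reservescan:::build_model_from_homologs(homs, "m", "m")
  expect_error(evalue_of(10, mod, 100), "not calibrated")

  c1 <- calibrate(mod, 150, seed = 9)
  c2 <- calibrate(mod, 150, seed = 9)
  expect_equal(c1$calibration, c2$calibration)
  expect_error(calibrate(mod, 50), "n_random")

  lam <- c1$calibration$lambda
  mu <- c1$calibration$mu
  # score = mu -> E capped at n_targets; linear in n_targets below the cap
  expect_equal(evalue_of(mu, c1, 500), 500)
  s <- mu + 5
  expect_equal(evalue_of(s, c1, 200) / evalue_of(s, c1, 100), 2)
  # algebraic inversion: E = 1 at mu + ln(n)/lambda
  expect_equal(evalue_of(mu + log(300) / lam, c1, 300), 1, tolerance = 1e-9)
  # monotone decreasing in score
  scores <- seq(mu - 5, mu + 30, length.out = 50)
  expect_true(all(diff(evalue_of(scores, c1, 100)) <= 0))
})

test_that("filter_hits applies both strict thresholds and preserves order", {
  hits <- tibble::tibble(
    enzyme_id = "e", model_id = "e", proteome_id = "p",
    protein_id = paste0("x", 1:4),
    bit_score = 100,
    evalue = c(5e-11, 1e-10, 1e-12, 2e-11),
    query_start = 0L, query_end = 10L, target_start = 0L, target_end = 10L,
    query_coverage = c(0.75, 0.75, 0.60, 0.80))
  kept <- filter_hits(hits, screening_config())
  expect_identical(kept$protein_id, c("x1", "x4"))
  expect_equal(nrow(filter_hits(hits[0, ], screening_config())), 0)
})

test_that("copy counting deduplicates proteins and needs all domains", {
  reg <- mini_registry()
  proteins <- tibble::tibble(id = paste0("p|", 1:4), sequence = "ACDEF")
  hit_row <- function(model, prot) {
    tibble::tibble(enzyme_id = sub(":.*", "", model), model_id = model,
                   proteome_id = "p", protein_id = prot, bit_score = 50,
                   evalue = 1e-20, query_start = 0L, query_end = 90L,
                   target_start = 0L, target_end = 90L,
                   query_coverage = 0.9)
  }
  # 3 distinct proteins hit enzA -> 3 copies; tandem double hit counts once
  hits <- dplyr::bind_rows(
    hit_row("enzA", "p|1"), hit_row("enzA", "p|2"), hit_row("enzA", "p|3"),
    hit_row("enzA", "p|3"),
    # enzC needs both domains: p|1 has one domain only, p|2 has both
    hit_row("enzC:PF90003", "p|1"),
    hit_row("enzC:PF90003", "p|2"), hit_row("enzC:PF90004", "p|2"))
  prof <- count_copies(hits, reg, proteins, "p")
  expect_equal(prof$enzA, 3L)
  expect_equal(prof$enzB, 0L)
  expect_equal(prof$enzC, 1L)
  expect_equal(prof$proteome_size, 4L)

  bad <- hit_row("enzA", "nonexistent")
  expect_error(count_copies(bad, reg, proteins, "p"), "unknown protein")
})

test_that("screening recovers planted truth on a mini cohort", {
  reg <- mini_registry()
  models <- mini_models(reg)
  coh <- generate_cohort(mini_config(n = 6, seed = 101), reg)
  res <- screen_cohort(models, coh, reg, keep_hits = TRUE)
  truth <- truth_profiles(coh, reg)
  expect_equal(res$profiles[order(res$profiles$proteome_id), ],
               truth[order(truth$proteome_id), ])
  # determinism
  res2 <- screen_cohort(models, coh, reg)
  expect_identical(res2, res$profiles)
  expect_error(screen_cohort(list(m = reservescan:::build_model_from_homologs(
    synthesize_homolog_store(reg, 5, seed = 2)$enzA, "m", "enzA")),
    coh, reg), "uncalibrated")
})

test_that("screening a cohort directory equals screening in memory", {
  reg <- mini_registry()
  models <- mini_models(reg)
  coh <- generate_cohort(mini_config(n = 4, seed = 103), reg)
  dir <- withr::local_tempdir()
  write_cohort(coh, dir)
  from_dir <- screen_cohort(models, dir, reg)
  in_mem <- screen_cohort(models, coh, reg)
  expect_equal(from_dir[order(from_dir$proteome_id), ],
               in_mem[order(in_mem$proteome_id), ])
})

test_that("the domtblout adapter maps external hits onto the hit schema", {
  hits <- read_domtblout(test_path("fixtures", "synthetic_domtbl.txt"),
                         proteome_id = "ext")
  expect_equal(nrow(hits), 2)
  expect_setequal(hits$protein_id, c("t1", "t2"))
  expect_true(all(hits$query_coverage == 1))
  expect_true(all(hits$evalue < 1e-10))
  # filter + downstream counting are backend-agnostic
  kept <- filter_hits(hits, screening_config())
  expect_equal(nrow(kept), 2)
})
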