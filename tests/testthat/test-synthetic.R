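# Synthetic cohort generator: identity contracts, decoys, cohort structure.

test_that("mutate_homolog hits the exact substitution count and is seeded", {
  seq100 <- withr::with_seed(1, random_protein(100))

  expect_identical(withr::with_seed(2, mutate_homolog(seq100, 1.0)), seq100)

  mut <- withr::with_seed(3, mutate_homolog(seq100, 0.7))
  expect_equal(nchar(mut), 100)
  mism <- sum(strsplit(mut, "")[[1]] != strsplit(seq100, "")[[1]])
  expect_equal(mism, 30)

  a <- withr::with_seed(7, mutate_homolog(seq100, 0.8))
  b <- withr::with_seed(7, mutate_homolog(seq100, 0.8))
  expect_identical(a, b)

  expect_error(mutate_homolog(seq100, 0), "target_identity")
  expect_error(mutate_homolog(seq100, 1.2), "target_identity")
  expect_error(mutate_homolog("", 0.9), "non-empty")
})

test_that("mutate_homolog realizes identities within one substitution of target", {
  seqs <- withr::with_seed(11, replicate(20, random_protein(sample(50:300, 1))))
  withr::with_seed(12, {
    for (s in seqs) {
      tgt <- runif(1, 0.5, 1)
      mut <- mutate_homolog(s, tgt)
      ident <- mean(strsplit(mut, "")[[1]] == strsplit(s, "")[[1]])
      expect_lte(abs(ident - tgt), 1 / nchar(s) + 1e-12)
    }
  })
})

test_that("generate_decoy draws i.i.d. residues from the background", {
  d <- withr::with_seed(5, generate_decoy(50))
  expect_equal(nchar(d), 50)
  expect_true(all(strsplit(d, "")[[1]] %in% reservescan:::AA20))
  expect_identical(withr::with_seed(6, generate_decoy(40)),
                   withr::with_seed(6, generate_decoy(40)))
  expect_error(generate_decoy(0), "length")

  # multinomial check: 1e5 residues, each frequency within 3 sigma of 1/20
  big <- withr::with_seed(8, generate_decoy(1e5))
  freqs <- table(factor(strsplit(big, "")[[1]],
                        levels = reservescan:::AA20)) / 1e5
  sigma <- sqrt(0.05 * 0.95 / 1e5)
  expect_true(all(abs(freqs - 0.05) <= 3 * sigma))
})

test_that("generate_cohort plants the scenario complements with clade restriction", {
  reg <- mini_registry()
  coh <- generate_cohort(mini_config(n = 8, seed = 21), reg)

  expect_length(coh$proteomes, 8)
  # every CladeA proteome has enzA and enzC planted; CladeB has nothing
  clade_a <- coh$taxonomy$proteome_id[coh$taxonomy$phylum == "CladeA"]
  for (pid in clade_a) {
    planted <- coh$truth$enzyme_id[coh$truth$proteome_id == pid]
    expect_setequal(planted, c("enzA", "enzC"))
  }
  expect_false(any(coh$truth$proteome_id %in%
                     setdiff(names(coh$proteomes), clade_a)))

  # protein count = decoys + planted copies, consistent with the FASTA
  for (i in seq_along(coh$proteomes)) {
    pid <- names(coh$proteomes)[i]
    n_planted <- sum(coh$truth$copies[coh$truth$proteome_id == pid])
    expect_equal(nrow(coh$proteomes[[i]]),
                 coh$sizes$decoy_count[i] + n_planted)
  }
})

test_that("cohorts are byte-identical under a fixed seed and round-trip via FASTA", {
  reg <- mini_registry()
  c1 <- generate_cohort(mini_config(n = 4, seed = 77), reg)
  c2 <- generate_cohort(mini_config(n = 4, seed = 77), reg)
  expect_identical(c1$proteomes, c2$proteomes)
  expect_identical(c1$truth, c2$truth)

  dir <- withr::local_tempdir()
  write_cohort(c1, dir)
  for (pid in names(c1$proteomes)) {
    rec <- read_fasta(file.path(dir, paste0(pid, ".fasta")))
    expect_equal(nrow(rec), nrow(c1$proteomes[[pid]]))
    expect_identical(rec$sequence, c1$proteomes[[pid]]$sequence)
  }
})

test_that("size_effect shifts pathway-positive decoy counts by the stated amount", {
  reg <- mini_registry()
  cfg <- mini_config(n = 60, seed = 31, size_effect = 2000L)
  coh <- generate_cohort(cfg, reg)
  pos <- coh$sizes$decoy_count[coh$sizes$pathway_positive]
  neg <- coh$sizes$decoy_count[!coh$sizes$pathway_positive]
  # uniform(8, 14) sampler: group means within sampling error of the shift
  se <- 2 * sqrt(var(pos) / length(pos) + var(neg) / length(neg)) + 2
  expect_lt(abs((mean(pos) - mean(neg)) - 2000), se)
})

test_that("cohort_config validates its invariants", {
  expect_error(cohort_config(n_proteomes = 1), "n_proteomes")
  expect_error(cohort_config(homolog_identity_range = c(0, 0.9)),
               "identity_range")
  expect_error(cohort_config(homolog_identity_range = c(0.9, 0.8)),
               "identity_range")
  bad <- list(scenario("X", "enzA", fraction = 0.5))
  expect_error(cohort_config(scenario_table = bad), "sum to 1")
  expect_error(generate_cohort(mini_config(), seed_registry(sequences = FALSE)),
               "missing columns")
})
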