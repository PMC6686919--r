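# Pairwise identity, dereplication, progressive MSA, terminal trimming.

test_that("pairwise identity matches hand counts and is symmetric", {
  expect_equal(pairwise_identity("ACDEFGHIK", "ACDEFGHIK"), 1.0)
  expect_equal(pairwise_identity("ACDEFGHIK", "ACDEFGHIR"), 8 / 9)
  expect_error(pairwise_identity("", "ACD"), "non-empty")

  withr::with_seed(13, {
    for (k in 1:100) {
      a <- random_protein(sample(10:60, 1))
      b <- if (k %% 3 == 0) a else random_protein(sample(10:60, 1))
      expect_equal(pairwise_identity(a, b), pairwise_identity(b, a))
    }
  })
})

test_that("identity equals 1 only for identical sequences", {
  withr::with_seed(14, {
    for (k in 1:25) {
      a <- random_protein(40)
      b <- mutate_homolog(a, 0.95)
      expect_lt(pairwise_identity(a, b), 1)
      expect_equal(pairwise_identity(a, a), 1)
    }
  })
})

test_that("dereplication removes >98% pairs, keeps 97% pairs, is idempotent", {
  base <- withr::with_seed(15, random_protein(200))
  # two byte-identical sequences collapse
  expect_length(dereplicate(c(base, base)), 1)

  # a pair at 97% identity survives the default threshold
  near <- withr::with_seed(16, mutate_homolog(base, 0.97))
  expect_length(dereplicate(c(base, near)), 2)
  # ... and a 99%-identity copy is removed
  close <- withr::with_seed(17, mutate_homolog(base, 0.99))
  expect_length(dereplicate(c(base, close)), 1)

  expect_error(dereplicate(character()), "non-empty")
  expect_error(dereplicate(base, threshold = 0), "threshold")

  withr::with_seed(18, {
    for (k in 1:5) {
      set <- vapply(1:8, function(i) mutate_homolog(base, runif(1, 0.9, 1)),
                    character(1))
      once <- dereplicate(set)
      expect_identical(dereplicate(once), once)
      expect_lte(length(once), length(set))
      expect_true(all(once %in% set))
      if (length(once) > 1) {
        pairs <- utils::combn(length(once), 2)
        ids <- apply(pairs, 2, function(p) {
          pairwise_identity(once[p[1]], once[p[2]])
        })
        expect_true(all(ids <= 0.98))
      }
    }
  })
})

test_that("progressive MSA aligns gaps optimally and round-trips inputs", {
  m <- build_msa(c("ACDEF", "ACDEF"))
  expect_equal(m$column_count, 5)
  expect_false(any(grepl("-", m$rows$aligned)))

  m2 <- build_msa(c("ACDEF", "ACEF"))
  expect_equal(m2$column_count, 5)
  expect_equal(sum(strsplit(m2$rows$aligned[2], "")[[1]] == "-"), 1)
  expect_identical(reservescan:::degap(m2$rows$aligned[2]), "ACEF")

  expect_error(build_msa("ACDEF"), "at least 2")

  withr::with_seed(19, {
    base <- random_protein(80)
    seqs <- c(base, vapply(1:6, function(i) mutate_homolog(base, 0.85),
                           character(1)))
    msa <- build_msa(seqs)
    expect_identical(vapply(msa$rows$aligned, reservescan:::degap,
                            character(1), USE.NAMES = FALSE),
                     seqs)
  })
})

test_that("terminal trimming removes only ragged ends", {
  rows <- tibble::tibble(
    sequence_id = paste0("s", 1:4),
    aligned = c("AC--------",
                "--CDEFGHIK",
                "--CDEFGHIK",
                "--CDEFGHIK"))
  msa <- reservescan:::new_msa(rows)
  # first two columns have occupancy 1/4 < 0.5 -> trimmed to 8 columns
  trimmed <- trim_termini(msa, 0.5)
  expect_equal(trimmed$column_count, 8)
  expect_identical(substr(trimmed$rows$aligned[2], 1, 3), "CDE")

  # gap-free alignment unchanged; zero threshold vacuous
  gapless <- build_msa(c("ACDEF", "ACDEF"))
  expect_identical(trim_termini(gapless, 0.5), gapless)
  expect_identical(trim_termini(msa, 0), msa)

  empty <- reservescan:::new_msa(tibble::tibble(
    sequence_id = c("a", "b"), aligned = c("A---", "---C")))
  expect_error(trim_termini(empty, 0.6), "degenerate")
})

test_that("alignment files round-trip in aligned FASTA and Stockholm", {
  msa <- build_msa(c("ACDEF", "ACEF", "ACDEF"))
  for (fmt in c("afa", "stockholm")) {
    path <- withr::local_tempfile(fileext = paste0(".", fmt))
    write_msa(msa, path, fmt)
    back <- read_msa(path, fmt)
    expect_identical(back$rows$aligned, msa$rows$aligned)
    expect_identical(back$rows$sequence_id, msa$rows$sequence_id)
  }
})
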