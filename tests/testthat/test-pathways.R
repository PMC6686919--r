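# Pathway calling, PhaC grouping, the call matrix and prevalence summary.

full_profile <- function(...) {
  reg <- seed_registry(sequences = FALSE)
  counts <- setNames(rep(0L, nrow(reg)), reg$enzyme_id)
  over <- c(...)
  counts[names(over)] <- over
  counts
}

test_that("call_pathway requires every member enzyme", {
  defs <- pathway_definitions()
  classical <- defs[defs$pathway_id == "classical_glycogen", ]
  expect_true(call_pathway(full_profile(glgC = 1L, glgA = 2L,
                                        glgB_GH13 = 1L), classical))
  expect_false(call_pathway(full_profile(glgC = 1L, glgA = 1L), classical))
  expect_false(call_pathway(full_profile(), classical))
  expect_error(call_pathway(c(glgC = 1L), classical), "missing enzyme")

  # PhaC of either group satisfies the PhaABC slot
  pha <- defs[defs$pathway_id == "phaABC", ]
  expect_true(call_pathway(full_profile(phaA = 1L, phaB = 1L,
                                        phaC_group1 = 1L), pha))
  expect_true(call_pathway(full_profile(phaA = 1L, phaB = 1L,
                                        phaC_group2 = 2L), pha))
  expect_false(call_pathway(full_profile(phaA = 1L, phaB = 1L), pha))
})

test_that("call_pathway agrees with subset enumeration for all definitions", {
  defs <- pathway_definitions()
  for (k in seq_len(nrow(defs))) {
    req <- defs$required[[k]]
    if (length(req) > 4) next
    # enumerate every presence/absence pattern of the required set
    n_true <- 0
    for (mask in 0:(2^length(req) - 1)) {
      present <- req[bitwAnd(mask, 2^(seq_along(req) - 1)) > 0]
      prof <- full_profile()
      real <- gsub("phaC_any", "phaC_group1", present)
      real <- gsub("glgB_any", "glgB_GH13", real)
      prof[real] <- 1L
      got <- call_pathway(prof, defs[k, ])
      expect_identical(got, length(present) == length(req))
      n_true <- n_true + got
    }
    expect_equal(n_true, 1) # exactly one of the 2^k patterns is complete
  }
})

test_that("adding copies never turns a pathway call off", {
  defs <- pathway_definitions()
  withr::with_seed(61, {
    for (r in 1:50) {
      prof <- full_profile()
      prof[sample(names(prof), 8)] <- sample(0:3, 8, replace = TRUE)
      for (k in seq_len(nrow(defs))) {
        before <- call_pathway(prof, defs[k, ])
        bump <- sample(names(prof), 1)
        bumped <- prof
        bumped[bump] <- bumped[bump] + 1L
        expect_true(!before || call_pathway(bumped, defs[k, ]))
      }
    }
  })
})

test_that("PhaC groups classify by which Pfam-domain family is present", {
  expect_identical(classify_phac(full_profile(phaC_group1 = 2L)), "GROUP1")
  expect_identical(classify_phac(full_profile(phaC_group2 = 1L)), "GROUP2")
  expect_identical(classify_phac(full_profile(phaC_group1 = 1L,
                                              phaC_group2 = 1L)), "BOTH")
  expect_identical(classify_phac(full_profile()), "NONE")
})

test_that("build_matrix derives pathway booleans, polyP status and PhaC group", {
  reg <- seed_registry(sequences = FALSE)
  profs <- tibble::tibble(proteome_id = c("a", "b", "c"),
                          proteome_size = c(100L, 200L, 300L))
  for (e in reg$enzyme_id) profs[[e]] <- 0L
  profs[1, c("ppk1", "ppk2", "ppx")] <- 1L       # complete polyP
  profs[2, "ppk1"] <- 2L                          # partial
  profs[1, c("glgC", "glgA", "glgB_GH13")] <- 1L
  profs[3, "phaC_group2"] <- 1L

  m <- build_matrix(profs)
  expect_identical(m$polyp_status, c("complete", "partial", "absent_all"))
  expect_identical(m$phac_group, c("NONE", "NONE", "GROUP2"))
  expect_identical(m$pathway_classical_glycogen, c(TRUE, FALSE, FALSE))
  expect_identical(m$pathway_polyp_complete, c(TRUE, FALSE, FALSE))
  # boolean true implies every member count >= 1
  expect_true(all(profs[m$pathway_classical_glycogen,
                        c("glgC", "glgA", "glgB_GH13")] >= 1))
  expect_error(build_matrix(dplyr::bind_rows(profs, profs[1, ])),
               "duplicate")

  # GH57 may satisfy the branching slot only under the "either" setting
  profs2 <- profs
  profs2[1, "glgB_GH13"] <- 0L
  profs2[1, "glgB_GH57"] <- 1L
  m13 <- build_matrix(profs2)
  m_any <- build_matrix(profs2, pathway_definitions(glgb = "either"))
  expect_false(m13$pathway_classical_glycogen[1])
  expect_true(m_any$pathway_classical_glycogen[1])
})

test_that("polyP statuses partition the cohort", {
  reg <- seed_registry(sequences = FALSE)
  withr::with_seed(62, {
    profs <- tibble::tibble(proteome_id = sprintf("p%02d", 1:40),
                            proteome_size = 100L)
    for (e in reg$enzyme_id) profs[[e]] <- 0L
    for (e in c("ppk1", "ppk2", "ppx")) {
      profs[[e]] <- sample(0:1, 40, replace = TRUE)
    }
  })
  m <- build_matrix(profs)
  expect_equal(sum(m$polyp_status == "complete") +
                 sum(m$polyp_status == "partial") +
                 sum(m$polyp_status == "absent_all"), 40)
})

test_that("prevalence summary computes printed-style percentages", {
  reg <- seed_registry(sequences = FALSE)
  profs <- tibble::tibble(proteome_id = sprintf("p%d", 1:10),
                          proteome_size = 100L)
  for (e in reg$enzyme_id) profs[[e]] <- 0L
  profs$ws_dgat[1:3] <- 1L
  m <- build_matrix(profs)
  s <- summarize_counts(m)
  expect_equal(s$n_present[s$feature == "ws_dgat" & s$kind == "enzyme"], 3)
  expect_equal(s$percentage[s$feature == "ws_dgat" & s$kind == "enzyme"], 30)
  expect_equal(s$percentage[s$feature == "we_tag" & s$kind == "pathway"], 30)
  expect_equal(s$percentage[s$feature == "ppk1" & s$kind == "enzyme"], 0)
  expect_error(summarize_counts(m[0, ]), "empty")

  expect_equal(percent_present(0, 100), 0)
  expect_equal(percent_present(1, 3), 33.33)
})
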