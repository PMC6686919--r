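# Pathway presence/absence calling and the proteome x enzyme/pathway matrix
# (the supplementary-table analog of the screen).

#' Pathway definitions for the five energy reserves
#'
#' Each pathway is a non-empty set of required enzymes with AND semantics:
#' classical glycogen (GlgC, GlgA, GlgB), the trehalose/GlgE route (TreS,
#' Pep2, GlgE, GlgB), PhaABC (PhaA, PhaB, PhaC of either Pfam group), the
#' single-enzyme WS/DGAT, PDAT and Rv3032 screens, the auxiliary PHA routes
#' (FabG; PhaJ; FabD; SucD+4HbD+OrfZ) and complete polyP metabolism
#' (PPK1, PPK2, PPX; see [build_matrix()] for the three-way polyP status).
#'
#' The pseudo-enzyme `"phaC_any"` resolves to the sum of the two PhaC group
#' counts. The branching-enzyme slot of the two glycogen pathways defaults
#' to the dominant bacterial GH13 family; `glgb = "either"` lets the
#' archaeal-type GH57 family satisfy it too (as `"glgB_any"`).
#'
#' @param glgb `"GH13"` (default) or `"either"`.
#' @return Tibble with `pathway_id`, `label` and list-column `required`.
#' @export
pathway_definitions <- function(glgb = c("GH13", "either")) {
  glgb <- match.arg(glgb)
  branch <- if (glgb == "GH13") "glgB_GH13" else "glgB_any"
  tibble::tribble(
    ~pathway_id, ~label, ~required,
    "classical_glycogen", "Classical glycogen synthesis (GlgC-GlgA-GlgB)",
    c("glgC", "glgA", branch),
    "trehalose_glycogen", "Trehalose/GlgE glycogen synthesis (TreS-Pep2-GlgE-GlgB)",
    c("treS", "pep2", "glgE", branch),
    "phaABC", "Classical PHA synthesis (PhaA-PhaB-PhaC)",
    c("phaA", "phaB", "phaC_any"),
    "polyp_complete", "Complete polyP metabolism (PPK1-PPK2-PPX)",
    c("ppk1", "ppk2", "ppx"),
    "we_tag", "Wax ester / TAG synthesis (WS/DGAT)", "ws_dgat",
    "pdat", "Acyl-CoA-independent TAG synthesis (PDAT)", "pdat",
    "rv3032", "Rv3032 alpha-1,4-glucan elongation", "rv3032",
    "pha_fabG", "PHA synthesis via FabG", "fabG",
    "pha_phaJ", "PHA synthesis via PhaJ", "phaJ",
    "pha_fabD", "PHA synthesis via FabD", "fabD",
    "pha_sucD_4hbD_orfZ", "PHA synthesis via SucD-4HbD-OrfZ",
    c("sucD", "hbd4", "orfZ")
  )
}

# Resolve pseudo-enzyme ids on a named count vector.
resolve_pseudo_counts <- function(counts) {
  if (all(c("phaC_group1", "phaC_group2") %in% names(counts))) {
    counts[["phaC_any"]] <- counts[["phaC_group1"]] + counts[["phaC_group2"]]
  }
  if (all(c("glgB_GH13", "glgB_GH57") %in% names(counts))) {
    counts[["glgB_any"]] <- counts[["glgB_GH13"]] + counts[["glgB_GH57"]]
  }
  counts
}

#' Call one pathway on one enzyme profile
#'
#' `TRUE` iff every required enzyme has copy count >= 1.
#'
#' @param profile Named integer vector of enzyme copy counts, or a one-row
#'   profile tibble (as from [screen_cohort()]).
#' @param definition One row of [pathway_definitions()] (or a list with
#'   `required`).
#' @return Logical.
#' @export
call_pathway <- function(profile, definition) {
  if (is.data.frame(profile)) {
    stopifnot(nrow(profile) == 1)
    keep <- !names(profile) %in% c("proteome_id", "proteome_size")
    profile <- unlist(profile[1, keep, drop = FALSE])
  }
  counts <- resolve_pseudo_counts(profile)
  req <- definition$required
  if (is.list(req)) req <- req[[1]]
  missing <- setdiff(req, names(counts))
  if (length(missing) > 0) {
    stop("profile is missing enzyme(s): ", paste(missing, collapse = ", "),
         call. = FALSE)
  }
  all(counts[req] >= 1)
}

#' Classify the PhaC synthase group of a profile
#'
#' `GROUP1` iff only Abhydrolase_1-type (PF00561) PhaC homologs are present,
#' `GROUP2` iff only PhaC_N-type (PF07167), `BOTH`/`NONE` accordingly.
#'
#' @param profile Named counts or one-row profile tibble covering
#'   `phaC_group1` and `phaC_group2`.
#' @return One of `"GROUP1"`, `"GROUP2"`, `"BOTH"`, `"NONE"`.
#' @export
classify_phac <- function(profile) {
  if (is.data.frame(profile)) {
    stopifnot(nrow(profile) == 1)
    profile <- unlist(profile[1, c("phaC_group1", "phaC_group2")])
  }
  g1 <- profile[["phaC_group1"]] >= 1
  g2 <- profile[["phaC_group2"]] >= 1
  if (g1 && g2) "BOTH" else if (g1) "GROUP1" else if (g2) "GROUP2" else "NONE"
}

polyp_status_of <- function(counts) {
  present <- c(counts[["ppk1"]] >= 1, counts[["ppk2"]] >= 1,
               counts[["ppx"]] >= 1)
  if (all(present)) "complete" else if (!any(present)) "absent_all" else "partial"
}

#' Build the proteome x enzyme/pathway call matrix
#'
#' One row per proteome: enzyme copy counts, one boolean column per pathway
#' (named `pathway_<id>`), the three-way polyP status (`complete` /
#' `partial` / `absent_all`) and the PhaC group label. With a taxonomy
#' table, `taxid` and lineage columns are joined in.
#'
#' @param profiles Wide profile tibble from [screen_cohort()] (or
#'   [truth_profiles()]).
#' @param definitions [pathway_definitions()] output.
#' @param taxonomy Optional tibble with `proteome_id`, `taxid`, rank
#'   columns.
#' @return A `pathway_matrix` tibble.
#' @export
build_matrix <- function(profiles, definitions = pathway_definitions(),
                         taxonomy = NULL) {
  if (anyDuplicated(profiles$proteome_id)) {
    stop("duplicate proteome ids in profiles", call. = FALSE)
  }
  out <- profiles
  enz_cols <- setdiff(names(profiles), c("proteome_id", "proteome_size"))
  counts <- profiles[enz_cols]
  if (all(c("phaC_group1", "phaC_group2") %in% enz_cols)) {
    counts$phaC_any <- counts$phaC_group1 + counts$phaC_group2
  }
  if (all(c("glgB_GH13", "glgB_GH57") %in% enz_cols)) {
    counts$glgB_any <- counts$glgB_GH13 + counts$glgB_GH57
  }
  for (k in seq_len(nrow(definitions))) {
    pid <- definitions$pathway_id[k]
    req <- definitions$required[[k]]
    missing <- setdiff(req, names(counts))
    if (length(missing) > 0) {
      stop("profiles are missing enzyme(s): ",
           paste(missing, collapse = ", "), call. = FALSE)
    }
    out[[paste0("pathway_", pid)]] <-
      Reduce(`&`, lapply(req, function(e) counts[[e]] >= 1))
  }
  if (all(c("ppk1", "ppk2", "ppx") %in% enz_cols)) {
    n_polyp <- (counts$ppk1 >= 1) + (counts$ppk2 >= 1) + (counts$ppx >= 1)
    out$polyp_status <- dplyr::case_when(n_polyp == 3 ~ "complete",
                                         n_polyp == 0 ~ "absent_all",
                                         TRUE ~ "partial")
  }
  if (all(c("phaC_group1", "phaC_group2") %in% enz_cols)) {
    g1 <- counts$phaC_group1 >= 1
    g2 <- counts$phaC_group2 >= 1
    out$phac_group <- dplyr::case_when(g1 & g2 ~ "BOTH", g1 ~ "GROUP1",
                                       g2 ~ "GROUP2", TRUE ~ "NONE")
  }
  if (!is.null(taxonomy)) {
    out <- dplyr::left_join(taxonomy, out, by = "proteome_id")
  }
  class(out) <- c("pathway_matrix", class(tibble::tibble()))
  out
}

#' Summarize enzyme and pathway prevalence
#'
#' Per enzyme (copy count >= 1) and per pathway: the number of proteomes
#' with the feature, the total, and the percentage (2 decimals).
#'
#' @param matrix A `pathway_matrix`.
#' @return Tibble `feature`, `kind` (`"enzyme"`/`"pathway"`), `n_present`,
#'   `n_total`, `percentage`.
#' @export
summarize_counts <- function(matrix) {
  if (nrow(matrix) == 0) {
    stop("empty matrix", call. = FALSE)
  }
  n_total <- nrow(matrix)
  enz_cols <- names(matrix)[vapply(matrix, is.numeric, logical(1))]
  enz_cols <- setdiff(enz_cols, c("proteome_size", "taxid"))
  path_cols <- grep("^pathway_", names(matrix), value = TRUE)
  rows <- c(
    lapply(enz_cols, function(e) {
      tibble::tibble(feature = e, kind = "enzyme",
                     n_present = sum(matrix[[e]] >= 1), n_total = n_total)
    }),
    lapply(path_cols, function(p) {
      tibble::tibble(feature = sub("^pathway_", "", p), kind = "pathway",
                     n_present = sum(matrix[[p]]), n_total = n_total)
    })
  )
  out <- dplyr::bind_rows(rows)
  out$percentage <- percent_present(out$n_present, out$n_total)
  out
}

#' Prevalence percentage, as printed
#'
#' `100 * n_present / n_total`, rounded to 2 decimals — the arithmetic
#' behind every "present in X% bacteria" figure.
#'
#' @param n_present,n_total Counts.
#' @return Numeric percentage(s).
#' @examples
#' percent_present(4500, 8282) # 54.33
#' percent_present(785, 8282)  # 9.48
#' @export
percent_present <- function(n_present, n_total) {
  round(100 * n_present / n_total, 2)
}

#' Write a pathway matrix as TSV
#'
#' @param matrix A `pathway_matrix`.
#' @param path Output path.
#' @return `path`, invisibly.
#' @export
write_matrix_tsv <- function(matrix, path) {
  readr::write_tsv(tibble::as_tibble(matrix), path)
  invisible(path)
}
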