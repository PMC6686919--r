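#' Seed-enzyme registry for the five energy reserves
#'
#' One row per key enzyme screened in the study: polyphosphate metabolism
#' (PPK1, PPK2, PPX), the classical and trehalose glycogen synthesis pathways
#' plus Rv3032 and the two glycogen branching-enzyme families (GH13, GH57),
#' the PhaABC polyhydroxyalkanoate route with the two Pfam-defined PhaC
#' groups and four auxiliary PHA enzymes sets, wax-ester/TAG synthesis
#' (WS/DGAT) and the eukaryotic-type PDAT.
#'
#' Each row records the reference species, gene, UniProt accession, sequence
#' length, Pfam domain composition and the model-construction policy:
#' `DE_NOVO_FULL` for seeds whose models are built from scratch over the full
#' sequence (more than two non-redundant domains, or Pfam domains too short
#' or of unknown function), `PFAM_DOMAINS` for seeds screened through their
#' listed Pfam domains.
#'
#' The amino-acid sequences attached to the registry are *synthetic*: they
#' are deterministic random sequences of the documented lengths, generated so
#' the whole pipeline can run and be validated without access to UniProt.
#' For real screens, replace the `sequence` column with the true UniProt
#' sequences (same accessions) via [read_fasta()].
#'
#' @param sequences Attach synthetic seed sequences (default `TRUE`).
#' @return A tibble with columns `enzyme_id`, `gene`, `enzyme_name`,
#'   `reference_species`, `uniprot_id`, `length_aa`, `pfam_domain_ids`
#'   (list-column), `model_policy` and (optionally) `sequence`.
#' @examples
#' seed_registry()[, c("enzyme_id", "length_aa", "model_policy")]
#' @export
seed_registry <- function(sequences = TRUE) {
  reg <- tibble::tribble(
    ~enzyme_id, ~gene, ~enzyme_name, ~reference_species, ~uniprot_id,
    ~length_aa, ~pfam_domain_ids, ~model_policy,
    "ppk1", "ppk1", "Polyphosphate kinase", "Escherichia coli", "E7QTB5",
    688L, list(c("PF02503", "PF13090", "PF17941", "PF13089")), "DE_NOVO_FULL",
    "ppk2", "ppk2", "Polyphosphate kinase 2", "Mycobacterium tuberculosis",
    "O05877", 295L, list("PF03976"), "PFAM_DOMAINS",
    "ppx", "ppx", "Ppx/GppA phosphatase", "Escherichia coli", "P0AFL6",
    513L, list("PF02541"), "PFAM_DOMAINS",
    "glgC", "glgC", "Glucose-1-phosphate adenylyltransferase",
    "Escherichia coli", "P0A6V1", 431L, list("PF00483"), "PFAM_DOMAINS",
    "glgA", "glgA", "Glycogen synthase", "Escherichia coli", "P0A6U8",
    477L, list(c("PF08323", "PF00534")), "PFAM_DOMAINS",
    "glgB_GH57", "glgB", "Alpha-1,4-glucan branching enzyme (GH57)",
    "Thermococcus kodakaraensis", "Q5JDJ7", 675L,
    list(c("PF09210", "PF03065", "PF14520")), "DE_NOVO_FULL",
    "glgB_GH13", "glgB", "Alpha-1,4-glucan branching enzyme (GH13)",
    "Escherichia coli", "P07762", 728L,
    list(c("PF02922", "PF00128", "PF02806")), "DE_NOVO_FULL",
    "treS", "treS", "Trehalose synthase/amylase",
    "Mycobacterium tuberculosis", "P9WQ19", 601L,
    list(c("PF00128", "PF16657")), "DE_NOVO_FULL",
    "pep2", "pep2", "Maltokinase", "Mycobacterium tuberculosis", "Q7DAF6",
    455L, list("PF18085"), "DE_NOVO_FULL",
    "glgE", "glgE", "Alpha-1,4-glucan: maltose-1-phosphate maltosyltransferase",
    "Mycobacterium tuberculosis", "P9WQ17", 701L,
    list(c("PF00128", "PF11896")), "DE_NOVO_FULL",
    "rv3032", "Rv3032", "Glycogen synthase (Rv3032)",
    "Mycobacterium tuberculosis", "P9WMY9", 414L,
    list(c("PF13439", "PF00534")), "PFAM_DOMAINS",
    "phaA", "phaA", "Acetyl-CoA acetyltransferase", "Cupriavidus necator",
    "P14611", 246L, list(c("PF02803", "PF00108")), "PFAM_DOMAINS",
    "phaB", "phaB", "Acetoacetyl-CoA reductase", "Cupriavidus necator",
    "P14697", 393L, list("PF00106"), "PFAM_DOMAINS",
    "phaC_group1", "phaC", "Poly(3-hydroxyalkanoate) polymerase subunit C (Group 1)",
    "Allochromatium vinosum", "P45370", 355L, list("PF00561"), "PFAM_DOMAINS",
    "phaC_group2", "phaC", "Class II poly(R)-hydroxyalkanoic acid synthase (Group 2)",
    "Pseudomonas aeruginosa", "Q51513", 559L, list("PF07167"), "PFAM_DOMAINS",
    "fabG", "fabG", "3-Oxoacyl-[acyl-carrier-protein] reductase",
    "Escherichia coli", "P0AEK2", 244L, list("PF13561"), "PFAM_DOMAINS",
    "phaJ", "phaJ", "(R)-Enoyl-CoA hydratase I", "Pseudomonas aeruginosa",
    "Q9LBK2", 156L, list("PF01575"), "PFAM_DOMAINS",
    "fabD", "fabD", "Malonyl CoA-acyl carrier protein transacylase",
    "Escherichia coli", "P0AAI9", 209L, list("PF00698"), "PFAM_DOMAINS",
    "sucD", "sucD", "Succinic semialdehyde dehydrogenase",
    "Clostridium kluyveri", "P38947", 453L, list("PF00171"), "PFAM_DOMAINS",
    "hbd4", "4hbD", "NAD-dependent 4-hydroxybutyrate dehydrogenase",
    "Clostridium kluyveri", "P38945", 371L, list("PF00465"), "PFAM_DOMAINS",
    "orfZ", "orfZ", "4-Hydroxybutyrate CoA-transferase",
    "Clostridium kluyveri", "A0A1L5FD42", 437L,
    list(c("PF02550", "PF13336")), "PFAM_DOMAINS",
    "pdat", "PDAT", "Phospholipid:diacylglycerol acyltransferase",
    "Saccharomyces cerevisiae", "P40345", 661L, list("PF02450"),
    "PFAM_DOMAINS",
    "ws_dgat", "wax-dgaT",
    "Wax ester synthase/acyl-CoA:diacylglycerol acyltransferase",
    "Acinetobacter baylyi", "Q8GGG1", 458L,
    list(c("PF06974", "PF03007")), "PFAM_DOMAINS"
  )
  # tribble wraps list-cells one level deeper than a plain list-column
  reg$pfam_domain_ids <- lapply(reg$pfam_domain_ids, unlist)
  if (sequences) {
    reg$sequence <- synthetic_seed_sequences(reg)
  }
  reg
}

# Deterministic synthetic seed sequences of the documented lengths.
synthetic_seed_sequences <- function(registry) {
  withr::with_seed(20180401L, {
    vapply(seq_len(nrow(registry)), function(i) {
      paste(sample(AA20, registry$length_aa[i], replace = TRUE),
            collapse = "")
    }, character(1))
  })
}

validate_registry <- function(registry) {
  stopifnot(is.data.frame(registry), nrow(registry) >= 1)
  need <- c("enzyme_id", "length_aa", "pfam_domain_ids", "model_policy",
            "sequence")
  missing <- setdiff(need, names(registry))
  if (length(missing) > 0) {
    stop("registry is missing columns: ", paste(missing, collapse = ", "),
         call. = FALSE)
  }
  if (anyDuplicated(registry$enzyme_id)) {
    stop("registry enzyme_id values must be unique", call. = FALSE)
  }
  if (!all(registry$model_policy %in% c("DE_NOVO_FULL", "PFAM_DOMAINS"))) {
    stop("model_policy must be DE_NOVO_FULL or PFAM_DOMAINS", call. = FALSE)
  }
  if (!all(nchar(registry$sequence) == registry$length_aa)) {
    stop("length_aa must equal nchar(sequence) for every registry row",
         call. = FALSE)
  }
  if (any(lengths(registry$pfam_domain_ids) == 0)) {
    stop("every registry row needs at least one Pfam domain id",
         call. = FALSE)
  }
  invisible(registry)
}

# Contiguous per-domain segments of a seed sequence: the seed length is split
# evenly over its listed domains (remainder to the last one). Used to build
# synthetic per-domain models when the real Pfam profiles are not supplied.
domain_segments <- function(length_aa, n_domains) {
  base <- length_aa %/% n_domains
  starts <- (seq_len(n_domains) - 1L) * base + 1L
  ends <- c(starts[-1] - 1L, length_aa)
  tibble::tibble(start = starts, end = ends)
}
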