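#' Read a protein multi-FASTA into a tibble
#'
#' Wraps [Biostrings::readAAStringSet()] with validation: duplicate record
#' ids and empty files are rejected, and sequences may contain only the 20
#' standard residues plus an allowed ambiguity set. CRLF and LF files parse
#' identically.
#'
#' @param path Path to a FASTA file.
#' @param ambiguity Allowed non-standard residue letters (scored as
#'   background by the search engine).
#' @return A tibble with columns `id` and `sequence`.
#' @export
read_fasta <- function(path, ambiguity = AA_AMBIGUOUS) {
  if (!file.exists(path)) {
    stop("FASTA file not found: ", path, call. = FALSE)
  }
  set <- withCallingHandlers(
    Biostrings::readAAStringSet(path),
    warning = function(w) {
      if (grepl("invalid one-letter sequence codes", conditionMessage(w))) {
        stop("FASTA file contains non-amino-acid characters: ", path,
             call. = FALSE)
      }
      invokeRestart("muffleWarning")
    })
  if (length(set) == 0) {
    stop("FASTA file contains no records: ", path, call. = FALSE)
  }
  ids <- sub("\\s.*$", "", names(set))
  if (anyDuplicated(ids)) {
    stop("duplicate FASTA record ids in ", path, ": ",
         paste(unique(ids[duplicated(ids)]), collapse = ", "),
         call. = FALSE)
  }
  seqs <- toupper(as.character(set))
  assert_aa(seqs, ambiguity)
  tibble::tibble(id = ids, sequence = unname(seqs))
}

#' Write protein records to FASTA
#'
#' @param records Tibble/data frame with columns `id` and `sequence`.
#' @param path Output path.
#' @param width Line width for wrapping.
#' @return `path`, invisibly.
#' @export
write_fasta <- function(records, path, width = 70L) {
  stopifnot(all(c("id", "sequence") %in% names(records)))
  if (anyDuplicated(records$id)) {
    stop("duplicate record ids", call. = FALSE)
  }
  set <- Biostrings::AAStringSet(setNames(records$sequence, records$id))
  Biostrings::writeXStringSet(set, path, width = width)
  invisible(path)
}
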