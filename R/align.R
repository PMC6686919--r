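# Homolog-set preparation: pairwise identity, greedy dereplication,
# progressive multiple alignment and terminal trimming.

identity_submat <- function() {
  m <- matrix(-1, 26, 26, dimnames = list(LETTERS, LETTERS))
  diag(m) <- 1
  m
}

#' Pairwise sequence identity under global alignment
#'
#' Identity is the number of identical aligned columns divided by the total
#' alignment length (gap columns included), computed on a Needleman-Wunsch
#' global alignment with match +1, mismatch -1 and a linear gap penalty of 2
#' per gapped position (via [Biostrings::pairwiseAlignment()]).
#'
#' @param a,b Non-empty amino-acid strings.
#' @return Identity fraction in \[0, 1\]; 1 iff the sequences are identical.
#' @examples
#' pairwise_identity("ACDEFGHIK", "ACDEFGHIR") # 8/9
#' @export
pairwise_identity <- function(a, b) {
  if (!nzchar(a) || !nzchar(b)) {
    stop("sequences must be non-empty", call. = FALSE)
  }
  if (identical(a, b)) {
    return(1)
  }
  pa <- Biostrings::pairwiseAlignment(
    Biostrings::AAString(a), Biostrings::AAString(b),
    substitutionMatrix = identity_submat(),
    gapOpening = 0, gapExtension = 2, type = "global"
  )
  Biostrings::pid(pa, type = "PID1") / 100
}

# Vectorized identity of many sequences against one reference (one
# pairwiseAlignment call); exact matches short-circuit to 1.
pairwise_identity_many <- function(seqs, ref) {
  out <- numeric(length(seqs))
  exact <- seqs == ref
  out[exact] <- 1
  if (any(!exact)) {
    pa <- Biostrings::pairwiseAlignment(
      Biostrings::AAStringSet(seqs[!exact]), Biostrings::AAString(ref),
      substitutionMatrix = identity_submat(),
      gapOpening = 0, gapExtension = 2, type = "global"
    )
    out[!exact] <- Biostrings::pid(pa, type = "PID1") / 100
  }
  out
}

#' Greedy dereplication of a homolog set
#'
#' Processes sequences in input order and keeps a sequence iff its identity
#' to every previously kept representative is at most `threshold` — i.e.
#' sequences with *more than* `threshold` identity to an earlier
#' representative are removed. Order-preserving and idempotent.
#'
#' @param sequences Character vector of amino-acid sequences.
#' @param threshold Removal threshold in (0, 1]; default 0.98.
#' @return Character vector of representatives (a subset, in input order).
#' @export
dereplicate <- function(sequences, threshold = 0.98) {
  if (length(sequences) == 0) {
    stop("sequences must be non-empty", call. = FALSE)
  }
  if (!is.numeric(threshold) || threshold <= 0 || threshold > 1) {
    stop("threshold must lie in (0, 1]", call. = FALSE)
  }
  kept <- character()
  for (s in sequences) {
    redundant <- length(kept) > 0 &&
      any(pairwise_identity_many(kept, s) > threshold)
    if (!redundant) {
      kept <- c(kept, s)
    }
  }
  kept
}

new_msa <- function(rows) {
  widths <- nchar(rows$aligned)
  stopifnot(length(unique(widths)) == 1)
  structure(list(rows = rows, column_count = widths[1]),
            class = "reserve_msa")
}

#' @export
print.reserve_msa <- function(x, ...) {
  cat("<reserve_msa> ", nrow(x$rows), " sequences x ", x$column_count,
      " columns\n", sep = "")
  invisible(x)
}

msa_matrix <- function(msa) {
  do.call(rbind, strsplit(msa$rows$aligned, "", fixed = TRUE))
}

msa_occupancy <- function(msa) {
  m <- msa_matrix(msa)
  colMeans(m != "-")
}

degap <- function(x) gsub("-", "", x, fixed = TRUE)

# Column frequency matrix (columns x 21: AA20 + gap) of an alignment.
profile_freqs <- function(aligned) {
  m <- do.call(rbind, strsplit(aligned, "", fixed = TRUE))
  f <- matrix(0, ncol(m), 21)
  for (a in seq_along(AA20)) {
    f[, a] <- colMeans(m == AA20[a])
  }
  f[, 21] <- colMeans(m == "-")
  f
}

#' Progressive multiple sequence alignment
#'
#' Builds the alignment by successively aligning each sequence to the
#' growing profile with global profile-sequence dynamic programming
#' (match +2, mismatch -1, linear gap -2). The guide order is by pairwise
#' identity: the sequence with the highest mean identity to the others seeds
#' the profile, and the rest join in decreasing identity to that centre
#' (ties broken by input order). Deleting gaps from any output row recovers
#' its input sequence.
#'
#' @param sequences Character vector (>= 2) of amino-acid sequences, or a
#'   tibble with `id` and `sequence` columns.
#' @return A `reserve_msa`: `rows` tibble (`sequence_id`, `aligned`) in the
#'   input row order, and `column_count`.
#' @export
build_msa <- function(sequences) {
  if (is.data.frame(sequences)) {
    ids <- sequences$id
    seqs <- sequences$sequence
  } else {
    seqs <- sequences
    ids <- sprintf("seq%d", seq_along(seqs))
  }
  if (length(seqs) < 2) {
    stop("build_msa needs at least 2 sequences", call. = FALSE)
  }
  assert_aa(seqs)
  n <- length(seqs)

  if (n == 2) {
    order_idx <- c(1L, 2L)
  } else {
    idm <- matrix(1, n, n)
    for (i in seq_len(n - 1)) {
      rest <- seq(i + 1, n)
      idvals <- pairwise_identity_many(seqs[rest], seqs[i])
      idm[i, rest] <- idm[rest, i] <- idvals
    }
    centre <- which.max(rowMeans(idm))
    rest <- setdiff(seq_len(n), centre)
    rest <- rest[order(-idm[centre, rest], rest)]
    order_idx <- c(centre, rest)
  }

  aligned <- seqs[order_idx[1]]
  for (k in seq(2, n)) {
    s <- seqs[order_idx[k]]
    path <- cpp_align_seq_profile(profile_freqs(aligned),
                                  encode_sequence(s),
                                  match = 2, mismatch = -1, gap = -2)
    # rebuild rows along the path
    prof_chars <- strsplit(aligned, "", fixed = TRUE)
    s_chars <- strsplit(s, "", fixed = TRUE)[[1]]
    ncolumns <- length(path)
    new_rows <- vapply(prof_chars, function(row) {
      out <- character(ncolumns)
      ci <- 0L
      for (p in seq_along(path)) {
        if (path[p] %in% c(0L, 1L)) {
          ci <- ci + 1L
          out[p] <- row[ci]
        } else {
          out[p] <- "-"
        }
      }
      paste(out, collapse = "")
    }, character(1))
    si <- 0L
    new_s <- character(ncolumns)
    for (p in seq_along(path)) {
      if (path[p] %in% c(0L, 2L)) {
        si <- si + 1L
        new_s[p] <- s_chars[si]
      } else {
        new_s[p] <- "-"
      }
    }
    aligned <- c(new_rows, paste(new_s, collapse = ""))
  }

  rows <- tibble::tibble(sequence_id = ids[order_idx], aligned = aligned)
  rows <- rows[order(match(rows$sequence_id, ids)), ]
  new_msa(rows)
}

#' Trim low-occupancy alignment termini
#'
#' Removes leading and trailing runs of columns whose non-gap occupancy is
#' below `min_occupancy`; interior columns are never touched. This automates
#' the removal of ragged N-/C-terminal alignment ends before model building.
#'
#' @param msa A `reserve_msa`.
#' @param min_occupancy Occupancy threshold in \[0, 1\]; default 0.5.
#' @return A trimmed `reserve_msa`.
#' @export
trim_termini <- function(msa, min_occupancy = 0.5) {
  stopifnot(inherits(msa, "reserve_msa"))
  occ <- msa_occupancy(msa)
  keep <- occ >= min_occupancy
  if (!any(keep)) {
    stop("trimming would remove every column (degenerate alignment)",
         call. = FALSE)
  }
  first <- which(keep)[1]
  last <- which(keep)[length(which(keep))]
  if (first == 1 && last == length(occ)) {
    return(msa)
  }
  rows <- msa$rows
  rows$aligned <- substr(rows$aligned, first, last)
  new_msa(rows)
}

#' Write an alignment in aligned FASTA or Stockholm format
#'
#' @param msa A `reserve_msa`.
#' @param path Output path.
#' @param format `"afa"` (aligned FASTA) or `"stockholm"`.
#' @return `path`, invisibly.
#' @export
write_msa <- function(msa, path, format = c("afa", "stockholm")) {
  format <- match.arg(format)
  if (format == "afa") {
    lines <- as.vector(rbind(paste0(">", msa$rows$sequence_id),
                             msa$rows$aligned))
  } else {
    lines <- c("# STOCKHOLM 1.0",
               sprintf("%-30s %s", msa$rows$sequence_id, msa$rows$aligned),
               "//")
  }
  writeLines(lines, path)
  invisible(path)
}

#' Read an alignment written by [write_msa()]
#'
#' @param path Input path.
#' @param format `"afa"` or `"stockholm"`.
#' @return A `reserve_msa`.
#' @export
read_msa <- function(path, format = c("afa", "stockholm")) {
  format <- match.arg(format)
  lines <- readLines(path)
  if (format == "afa") {
    heads <- grep("^>", lines)
    ids <- sub("^>", "", lines[heads])
    ends <- c(heads[-1] - 1L, length(lines))
    aligned <- vapply(seq_along(heads), function(i) {
      paste(lines[seq(heads[i] + 1L, ends[i])], collapse = "")
    }, character(1))
  } else {
    body <- lines[!grepl("^#", lines) & !grepl("^//", lines) & nzchar(lines)]
    parts <- strsplit(trimws(body), "\\s+")
    ids <- vapply(parts, `[[`, character(1), 1)
    aligned <- vapply(parts, `[[`, character(1), 2)
  }
  new_msa(tibble::tibble(sequence_id = ids,
                         aligned = toupper(gsub("\\.", "-", aligned))))
}
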