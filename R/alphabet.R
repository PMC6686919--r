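# Amino-acid alphabet helpers (internal).

AA20 <- c("A", "C", "D", "E", "F", "G", "H", "I", "K", "L",
          "M", "N", "P", "Q", "R", "S", "T", "V", "W", "Y")

AA_AMBIGUOUS <- c("X", "B", "Z", "U")

# Robinson & Robinson background amino-acid frequencies, ordered as AA20.
ROBINSON_FREQS <- c(
  A = 0.07805, C = 0.01925, D = 0.05364, E = 0.06295, F = 0.03856,
  G = 0.07377, H = 0.02199, I = 0.05142, K = 0.05744, L = 0.09019,
  M = 0.02243, N = 0.04487, P = 0.05203, Q = 0.04264, R = 0.05129,
  S = 0.07120, T = 0.05841, V = 0.06441, W = 0.01330, Y = 0.03216
)
ROBINSON_FREQS <- ROBINSON_FREQS / sum(ROBINSON_FREQS)

uniform_background <- function() {
  setNames(rep(1 / 20, 20), AA20)
}

#' Background residue frequency tables
#'
#' @param name `"uniform"` (default decoy background) or `"robinson"`
#'   (Robinson-Robinson empirical protein frequencies).
#' @return Named numeric vector of length 20 summing to 1.
#' @export
background_frequencies <- function(name = c("uniform", "robinson")) {
  name <- match.arg(name)
  if (name == "uniform") uniform_background() else ROBINSON_FREQS
}

# Encode an amino-acid string to 0-based codes; ambiguity codes map to 20.
encode_sequence <- function(x, ambiguity = AA_AMBIGUOUS) {
  chars <- strsplit(x, "", fixed = TRUE)[[1]]
  codes <- match(chars, AA20) - 1L
  amb <- is.na(codes) & chars %in% ambiguity
  codes[amb] <- 20L
  if (anyNA(codes)) {
    bad <- unique(chars[is.na(codes)])
    stop("sequence contains non-amino-acid characters: ",
         paste(bad, collapse = ", "), call. = FALSE)
  }
  codes
}

assert_aa <- function(x, ambiguity = AA_AMBIGUOUS) {
  invisible(vapply(x, function(s) {
    encode_sequence(s, ambiguity)
    TRUE
  }, logical(1)))
}
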