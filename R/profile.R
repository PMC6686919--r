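# Profile models: position-specific match/insert/delete models with
# background-weighted Dirichlet pseudocounts and Gumbel E-value calibration.

new_profile_model <- function(model_id, enzyme_id, match_emissions,
                              transitions, background,
                              insert_emissions = background,
                              calibration = NULL,
                              query_length_aa = nrow(match_emissions)) {
  m <- structure(list(model_id = model_id,
                      enzyme_id = enzyme_id,
                      match_length = nrow(match_emissions),
                      query_length_aa = as.integer(query_length_aa),
                      match_emissions = match_emissions,
                      insert_emissions = insert_emissions,
                      transitions = transitions,
                      background = background,
                      calibration = calibration),
                 class = "profile_model")
  validate_profile_model(m)
  m
}

#' Validate a profile model's normalization invariants
#'
#' Checks that every match-emission row, the insert-emission vector, the
#' background and every outgoing transition distribution sum to 1 within
#' 1e-9, and that the model has at least one match state.
#'
#' @param model A `profile_model`.
#' @return The model, invisibly; errors otherwise.
#' @export
validate_profile_model <- function(model) {
  stopifnot(inherits(model, "profile_model"))
  if (model$match_length < 1) {
    stop("model must have at least one match state", call. = FALSE)
  }
  tol <- 1e-9
  em_ok <- all(abs(rowSums(model$match_emissions) - 1) <= tol)
  bg_ok <- abs(sum(model$background) - 1) <= tol
  ins_ok <- abs(sum(model$insert_emissions) - 1) <= tol
  tr <- model$transitions
  tr_ok <- all(abs(rowSums(tr[, c("mm", "mi", "md"), drop = FALSE]) - 1) <= tol) &&
    all(abs(rowSums(tr[, c("im", "ii"), drop = FALSE]) - 1) <= tol) &&
    all(abs(rowSums(tr[, c("dm", "dd"), drop = FALSE]) - 1) <= tol)
  if (!em_ok || !bg_ok || !ins_ok || !tr_ok) {
    stop("profile model probability vectors are not normalized within 1e-9",
         call. = FALSE)
  }
  invisible(model)
}

#' @export
print.profile_model <- function(x, ...) {
  cat("<profile_model> ", x$model_id, ": ", x$match_length,
      " match states (enzyme ", x$enzyme_id, ")",
      if (!is.null(x$calibration)) {
        sprintf(", calibrated (lambda=%.3f, mu=%.2f)",
                x$calibration$lambda, x$calibration$mu)
      } else {
        ", uncalibrated"
      }, "\n", sep = "")
  invisible(x)
}

#' Estimate a profile model from a trimmed alignment
#'
#' Match states are the alignment columns with non-gap occupancy >= 0.5.
#' Match emissions use background-weighted Dirichlet pseudocounts:
#' `(count + w * q_a) / (n_residues + w)` for pseudocount weight `w` and
#' background `q`. State-transition probabilities are estimated the same way
#' from the per-row state paths (uniform prior over each state's legal
#' successors; insert-delete transitions are forbidden). Insert states emit
#' the background.
#'
#' @param msa A `reserve_msa` with >= 2 rows (typically [trim_termini()]
#'   output).
#' @param pseudocount_weight Positive Dirichlet weight `w`; default 1.
#' @param background Named residue frequency vector; default uniform.
#' @param model_id,enzyme_id Identifiers stored on the model.
#' @return A `profile_model` with `query_length_aa = match_length`.
#' @export
build_profile <- function(msa, pseudocount_weight = 1,
                          background = background_frequencies("uniform"),
                          model_id = "model", enzyme_id = model_id) {
  stopifnot(inherits(msa, "reserve_msa"))
  if (nrow(msa$rows) < 2) {
    stop("model building needs an alignment with >= 2 rows", call. = FALSE)
  }
  if (!is.numeric(pseudocount_weight) || pseudocount_weight <= 0) {
    stop("pseudocount_weight must be positive", call. = FALSE)
  }
  w <- pseudocount_weight
  mat <- msa_matrix(msa)
  occ <- colMeans(mat != "-")
  match_cols <- which(occ >= 0.5)
  if (length(match_cols) == 0) {
    stop("no column reaches occupancy 0.5 (degenerate alignment)",
         call. = FALSE)
  }
  M <- length(match_cols)

  em <- matrix(0, M, 20, dimnames = list(NULL, AA20))
  for (j in seq_len(M)) {
    col <- mat[, match_cols[j]]
    res <- col[col != "-"]
    counts <- table(factor(res, levels = AA20))
    em[j, ] <- (as.numeric(counts) + w * background) / (length(res) + w)
  }

  # per-row state paths over match columns: residue -> M, gap -> D;
  # residues in non-match columns -> I at the preceding match state
  succ_m <- c("mm", "mi", "md")
  succ_i <- c("im", "ii")
  succ_d <- c("dm", "dd")
  counts <- matrix(0, M, 7,
                   dimnames = list(NULL, c(succ_m, succ_i, succ_d)))
  is_match <- seq_len(ncol(mat)) %in% match_cols
  state_of_col <- cumsum(is_match) # match-state index at/before each column
  for (r in seq_len(nrow(mat))) {
    prev_state <- NULL # c(type, j)
    for (cc in seq_len(ncol(mat))) {
      ch <- mat[r, cc]
      cur <- NULL
      if (is_match[cc]) {
        cur <- c(if (ch == "-") "D" else "M", state_of_col[cc])
      } else if (ch != "-") {
        cur <- c("I", state_of_col[cc])
      }
      if (is.null(cur)) next
      if (!is.null(prev_state) && cur[1] != "I") {
        j <- as.integer(prev_state[2])
        key <- paste0(tolower(prev_state[1]), tolower(cur[1]))
        if (j >= 1 && key %in% colnames(counts)) {
          counts[j, key] <- counts[j, key] + 1
        }
      } else if (!is.null(prev_state) && cur[1] == "I") {
        j <- as.integer(cur[2])
        key <- paste0(tolower(prev_state[1]), "i")
        if (j >= 1 && key %in% colnames(counts) && prev_state[1] != "D") {
          counts[j, key] <- counts[j, key] + 1
        }
      }
      # I->D and D->I are forbidden; a gap row position after an insert run
      # is attributed as M/D continuation from the last emitting state
      if (!(cur[1] == "I" && !is.null(prev_state) && prev_state[1] == "D")) {
        prev_state <- cur
      }
    }
  }
  tr <- matrix(0, M, 7, dimnames = list(NULL, colnames(counts)))
  for (j in seq_len(M)) {
    cm <- counts[j, succ_m]
    tr[j, succ_m] <- (cm + w / 3) / (sum(cm) + w)
    ci <- counts[j, succ_i]
    tr[j, succ_i] <- (ci + w / 2) / (sum(ci) + w)
    cd <- counts[j, succ_d]
    tr[j, succ_d] <- (cd + w / 2) / (sum(cd) + w)
  }

  new_profile_model(model_id, enzyme_id, em, tr, background)
}

# log2-odds emission matrix (M x 21, ambiguity column = 0) and log2
# transition matrix used by the C++ scorer.
model_log_odds <- function(model) {
  lo <- log2(sweep(model$match_emissions, 2, model$background, "/"))
  cbind(lo, 0)
}

model_log_trans <- function(model) {
  log2(model$transitions[, c("mm", "mi", "md", "im", "ii", "dm", "dd"),
                         drop = FALSE])
}

#' Synthesize homolog sets for every registry enzyme
#'
#' Generates `n_homologs` mutated copies of each seed sequence at identities
#' drawn uniformly from `identity_range` — the model-building counterpart of
#' the cohort generator's planted homologs (independent draws).
#'
#' @param registry Seed registry with sequences.
#' @param n_homologs Homologs per enzyme (default 20).
#' @param identity_range Identity range to the seed, default `c(0.85, 0.95)`.
#' @param seed Integer RNG seed.
#' @return Named list (enzyme id) of character vectors of sequences.
#' @export
synthesize_homolog_store <- function(registry, n_homologs = 20,
                                     identity_range = c(0.85, 0.95),
                                     seed = 7L) {
  validate_registry(registry)
  withr::with_seed(as.integer(seed), {
    out <- lapply(seq_len(nrow(registry)), function(i) {
      vapply(seq_len(n_homologs), function(k) {
        mutate_homolog(registry$sequence[i],
                       runif(1, identity_range[1], identity_range[2]))
      }, character(1))
    })
    setNames(out, registry$enzyme_id)
  })
}

# Dereplicate, align, trim and build one de novo model from a homolog set.
build_model_from_homologs <- function(sequences, model_id, enzyme_id,
                                      dereplication_threshold = 0.98,
                                      min_occupancy = 0.5,
                                      pseudocount_weight = 1,
                                      background = background_frequencies("uniform")) {
  reps <- dereplicate(sequences, dereplication_threshold)
  if (length(reps) < 2) {
    reps <- c(reps, sequences[!sequences %in% reps][1])
    reps <- reps[!is.na(reps)]
  }
  msa <- trim_termini(build_msa(reps), min_occupancy)
  build_profile(msa, pseudocount_weight, background,
                model_id = model_id, enzyme_id = enzyme_id)
}

#' Build the per-domain model store for PFAM_DOMAINS enzymes
#'
#' For every registry row under the `PFAM_DOMAINS` policy, the seed and its
#' homolog set are segmented into contiguous per-domain blocks (the seed
#' length split evenly over its listed domains) and one profile model is
#' built per block. Models are keyed `"<enzyme_id>:<pfam_id>"`: with
#' synthetic seeds, a Pfam id shared by two enzymes (PF00534 in glgA and
#' Rv3032) does not correspond to one shared sequence family, so domain
#' models are scoped per enzyme. Supply externally built models (e.g. via
#' [read_hmmer_profile()]) under the same keys to override.
#'
#' @param registry Seed registry.
#' @param homolog_store Named list of homolog sequences per enzyme, see
#'   [synthesize_homolog_store()].
#' @inheritParams build_model_from_homologs
#' @return Named list of `profile_model`s.
#' @export
build_domain_store <- function(registry, homolog_store,
                               dereplication_threshold = 0.98,
                               min_occupancy = 0.5, pseudocount_weight = 1,
                               background = background_frequencies("uniform")) {
  store <- list()
  for (i in seq_len(nrow(registry))) {
    if (registry$model_policy[i] != "PFAM_DOMAINS") next
    eid <- registry$enzyme_id[i]
    homs <- homolog_store[[eid]]
    if (is.null(homs)) {
      stop("missing homolog set for enzyme ", eid, call. = FALSE)
    }
    pfams <- registry$pfam_domain_ids[[i]]
    segs <- domain_segments(registry$length_aa[i], length(pfams))
    for (d in seq_along(pfams)) {
      key <- paste(eid, pfams[d], sep = ":")
      seg_seqs <- substr(homs, segs$start[d], segs$end[d])
      store[[key]] <- build_model_from_homologs(
        seg_seqs, model_id = key, enzyme_id = eid,
        dereplication_threshold = dereplication_threshold,
        min_occupancy = min_occupancy,
        pseudocount_weight = pseudocount_weight, background = background
      )
    }
  }
  store
}

#' Resolve the screening models for one seed enzyme
#'
#' Applies the registry's model policy: `DE_NOVO_FULL` enzymes get a single
#' full-sequence model built from their homolog set (dereplicated at 98%,
#' aligned, termini trimmed); `PFAM_DOMAINS` enzymes get one model per
#' listed Pfam domain from the domain store.
#'
#' @param seed One registry row (one-row tibble or list).
#' @param homolog_store Named list of homolog sequences per enzyme.
#' @param domain_model_store Named list of domain `profile_model`s keyed
#'   `"<enzyme_id>:<pfam_id>"`.
#' @inheritParams build_model_from_homologs
#' @return List of `profile_model`s for this enzyme.
#' @export
resolve_models <- function(seed, homolog_store, domain_model_store = list(),
                           dereplication_threshold = 0.98,
                           min_occupancy = 0.5, pseudocount_weight = 1,
                           background = background_frequencies("uniform")) {
  eid <- seed$enzyme_id[[1]]
  policy <- seed$model_policy[[1]]
  if (policy == "DE_NOVO_FULL") {
    homs <- homolog_store[[eid]]
    if (is.null(homs)) {
      stop("missing homolog set for enzyme ", eid, call. = FALSE)
    }
    list(build_model_from_homologs(
      homs, model_id = eid, enzyme_id = eid,
      dereplication_threshold = dereplication_threshold,
      min_occupancy = min_occupancy,
      pseudocount_weight = pseudocount_weight, background = background
    ))
  } else {
    pfams <- seed$pfam_domain_ids[[1]]
    keys <- paste(eid, pfams, sep = ":")
    missing <- keys[!keys %in% names(domain_model_store)]
    if (length(missing) > 0) {
      stop("missing domain model(s) for enzyme ", eid, ": ",
           paste(missing, collapse = ", "), call. = FALSE)
    }
    unname(domain_model_store[keys])
  }
}

#' Build all screening models for a registry
#'
#' Convenience wrapper: synthesizes (or accepts) homolog sets, builds the
#' domain store, and resolves the model list of every enzyme.
#'
#' @param registry Seed registry.
#' @param homolog_store Named list of homolog sequences per enzyme; default
#'   synthesizes one with [synthesize_homolog_store()].
#' @param seed RNG seed for homolog synthesis.
#' @inheritParams build_model_from_homologs
#' @return Flat named list of `profile_model`s (names = model ids).
#' @export
build_model_set <- function(registry = seed_registry(),
                            homolog_store = NULL, seed = 7L,
                            dereplication_threshold = 0.98,
                            min_occupancy = 0.5, pseudocount_weight = 1,
                            background = background_frequencies("uniform")) {
  validate_registry(registry)
  if (is.null(homolog_store)) {
    homolog_store <- synthesize_homolog_store(registry, seed = seed)
  }
  dstore <- build_domain_store(registry, homolog_store,
                               dereplication_threshold, min_occupancy,
                               pseudocount_weight, background)
  models <- list()
  for (i in seq_len(nrow(registry))) {
    ms <- resolve_models(registry[i, ], homolog_store, dstore,
                         dereplication_threshold, min_occupancy,
                         pseudocount_weight, background)
    for (m in ms) models[[m$model_id]] <- m
  }
  models
}

#' Serialize a profile model to JSON
#'
#' Versioned JSON dialect carrying all emission/transition matrices, the
#' background and any calibration.
#'
#' @param model A `profile_model`.
#' @param path Output path.
#' @return `path`, invisibly.
#' @export
write_profile_model <- function(model, path) {
  validate_profile_model(model)
  obj <- list(format = "reservescan-profile/1",
              model_id = model$model_id,
              enzyme_id = model$enzyme_id,
              match_length = model$match_length,
              query_length_aa = model$query_length_aa,
              alphabet = AA20,
              match_emissions = unname(apply(model$match_emissions, 1,
                                             identity, simplify = FALSE)),
              insert_emissions = unname(model$insert_emissions),
              transitions = unname(apply(model$transitions, 1, identity,
                                         simplify = FALSE)),
              transition_order = colnames(model$transitions),
              background = unname(model$background),
              calibration = model$calibration)
  jsonlite::write_json(obj, path, auto_unbox = TRUE, digits = NA)
  invisible(path)
}

#' Read a profile model written by [write_profile_model()]
#'
#' @param path Input path.
#' @return A `profile_model`.
#' @export
read_profile_model <- function(path) {
  obj <- jsonlite::read_json(path, simplifyVector = TRUE)
  if (!identical(obj$format, "reservescan-profile/1")) {
    stop("not a reservescan profile JSON: ", path, call. = FALSE)
  }
  as_mat <- function(x) if (is.matrix(x)) x else do.call(rbind, x)
  em <- as_mat(obj$match_emissions)
  colnames(em) <- AA20
  tr <- as_mat(obj$transitions)
  colnames(tr) <- obj$transition_order
  cal <- obj$calibration
  if (!is.null(cal)) cal <- list(lambda = cal$lambda, mu = cal$mu)
  new_profile_model(obj$model_id, obj$enzyme_id, em, tr,
                    setNames(obj$background, AA20),
                    insert_emissions = setNames(obj$insert_emissions, AA20),
                    calibration = cal,
                    query_length_aa = obj$query_length_aa)
}

#' Import a HMMER3 ASCII profile (match emissions and length)
#'
#' Minimal adapter for externally built models: parses the `.hmm` node
#' table (match emission, insert emission and transition lines, stored as
#' negative natural logs) into a `profile_model`. The HMMER alphabet order
#' matches this package's; begin/end-specific transitions beyond the core
#' seven are ignored.
#'
#' @param path Path to a HMMER3 ASCII `.hmm` file (single model).
#' @param background Background frequencies to attach (default uniform).
#' @return A `profile_model` (uncalibrated; run [calibrate()] before use).
#' @export
read_hmmer_profile <- function(path, background = background_frequencies("uniform")) {
  lines <- readLines(path)
  if (!grepl("^HMMER3", lines[1])) {
    stop("not a HMMER3 ASCII profile: ", path, call. = FALSE)
  }
  name <- trimws(sub("^NAME", "", grep("^NAME", lines, value = TRUE)[1]))
  leng <- as.integer(trimws(sub("^LENG", "", grep("^LENG", lines,
                                                  value = TRUE)[1])))
  hmm_at <- grep("^HMM\\s", lines)[1]
  body <- lines[(hmm_at + 2):length(lines)] # skip transition-header line
  body <- body[!grepl("^//", body)]
  # drop the COMPO block (one emission line + insert + transition line)
  if (grepl("^\\s*COMPO", body[1])) body <- body[-(1:3)]
  to_p <- function(tok) {
    v <- ifelse(tok == "*", Inf, suppressWarnings(as.numeric(tok)))
    exp(-v)
  }
  em <- matrix(0, leng, 20, dimnames = list(NULL, AA20))
  tr <- matrix(0, leng, 7,
               dimnames = list(NULL, c("mm", "mi", "md", "im", "ii",
                                       "dm", "dd")))
  for (j in seq_len(leng)) {
    mline <- strsplit(trimws(body[3 * (j - 1) + 1]), "\\s+")[[1]]
    tline <- strsplit(trimws(body[3 * (j - 1) + 3]), "\\s+")[[1]]
    em[j, ] <- to_p(mline[2:21])
    em[j, ] <- em[j, ] / sum(em[j, ])
    tv <- to_p(tline[1:7])
    tr[j, c("mm", "mi", "md")] <- tv[1:3] / sum(tv[1:3])
    tr[j, c("im", "ii")] <- tv[4:5] / sum(tv[4:5])
    tr[j, c("dm", "dd")] <- if (is.finite(sum(tv[6:7])) && sum(tv[6:7]) > 0) {
      tv[6:7] / sum(tv[6:7])
    } else {
      c(1, 0)
    }
  }
  new_profile_model(name, name, em, tr, background)
}
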