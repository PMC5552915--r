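#' Score protein sequences against a profile HMM
#'
#' Computes, for each sequence, the Viterbi (best single path) and forward
#' (all paths) log2-odds scores of the profile against an i.i.d. background
#' model.  In `"local"` mode the model allows free flanking residues
#' (emitted by background flank states with self-loop probability
#' `flank_loop`), uniform entry over match states and a geometric exit, so
#' fragmentary CDS score on the segment they cover.  In `"global"` mode the
#' whole sequence must traverse the whole model.  `X` residues score as
#' wildcards (odds 1 in every state).
#'
#' @param profile A `profile_hmm`.
#' @param sequences Character vector of protein sequences.
#' @param mode `"local"` (default) or `"global"`.
#' @param flank_loop Flank self-loop probability in local mode.
#' @return Data frame with columns `viterbi_bits` and `forward_bits`.
#' @export
score_sequences <- function(profile, sequences, mode = c("local", "global"),
                            flank_loop = 0.95) {
  mode <- match.arg(mode)
  validate_profile(profile)
  if (length(sequences) == 0L) {
    return(data.frame(viterbi_bits = numeric(0), forward_bits = numeric(0)))
  }
  enc <- encode_sequences(sequences, profile$alphabet)
  L <- profile$L
  mo <- sweep(profile$match_emissions, 2, profile$background, "/")
  # rows 2..L of insert_emissions are the internal insert nodes I_1..I_{L-1}
  io <- sweep(profile$insert_emissions[seq_len(L) + 1L, , drop = FALSE],
              2, profile$background, "/")
  tr <- profile$transitions
  res <- phmm_score_batch_cpp(mo, io,
                              tr$tMM, tr$tMI, tr$tMD,
                              tr$tIM, tr$tII, tr$tDM, tr$tDD,
                              enc, mode == "local", flank_loop)
  data.frame(viterbi_bits = res[, 1], forward_bits = res[, 2])
}

encode_sequences <- function(sequences, alphabet) {
  letters_ <- aa_letters(alphabet)
  K <- length(letters_)
  lapply(sequences, function(s) {
    if (!nzchar(s)) stop("empty sequence")
    ch <- strsplit(s, "", fixed = TRUE)[[1L]]
    code <- match(ch, letters_) - 1L
    x_at <- ch == "X"
    code[x_at] <- K
    if (anyNA(code)) {
      bad <- which(is.na(code))[[1L]]
      stop("invalid character '", ch[[bad]], "' at position ", bad)
    }
    code
  })
}

#' Forward log-odds score in bits
#' @inheritParams score_sequences
#' @param sequence A single protein sequence.
#' @return Numeric scalar, `log2(P(seq | profile) / P(seq | background))`
#'   summed over all state paths.
#' @export
forward_bits <- function(profile, sequence, mode = c("local", "global"),
                         flank_loop = 0.95) {
  score_sequences(profile, sequence, mode, flank_loop)$forward_bits
}

#' Viterbi (best-path) log-odds score in bits
#' @inheritParams forward_bits
#' @return Numeric scalar; always at most the forward score.
#' @export
viterbi_bits <- function(profile, sequence, mode = c("local", "global"),
                         flank_loop = 0.95) {
  score_sequences(profile, sequence, mode, flank_loop)$viterbi_bits
}

#' Screen one site's CDS set against a set of family profiles
#'
#' Scores every (CDS, family) pair, accepts hits whose forward bit score
#' reaches `threshold`, and tallies per-family raw hit counts.  One CDS
#' contributes at most one count to any family but may be accepted by
#' several families.
#'
#' @param profiles List of `profile_hmm` objects.
#' @param cds Data frame of protein records ([read_fasta()] layout).
#' @param threshold Acceptance threshold in bits (forward score).
#' @param site_id Site identifier recorded on the hits.
#' @param mode,flank_loop Passed to [score_sequences()].
#' @return An object of class `hit_table`: list with `site_id`, `hits`
#'   (one row per accepted CDS/family pair, with scores), and `counts`
#'   (data frame `family`, `n` covering every profile family).
#' @export
search_site <- function(profiles, cds, threshold = 25, site_id = "site",
                        mode = c("local", "global"), flank_loop = 0.95) {
  stopifnot(length(profiles) >= 1L, is.finite(threshold) || threshold == Inf)
  mode <- match.arg(mode)
  fam_names <- vapply(profiles, `[[`, character(1), "family_name")
  hit_rows <- vector("list", length(profiles))
  counts <- integer(length(profiles))
  for (j in seq_along(profiles)) {
    if (nrow(cds) == 0L) {
      hit_rows[[j]] <- NULL
      next
    }
    sc <- score_sequences(profiles[[j]], cds$sequence, mode, flank_loop)
    acc <- sc$forward_bits >= threshold
    counts[[j]] <- sum(acc)
    if (any(acc)) {
      hit_rows[[j]] <- data.frame(
        site_id = site_id,
        family = fam_names[[j]],
        cds_id = cds$id[acc],
        bit_score = sc$forward_bits[acc],
        viterbi_bits = sc$viterbi_bits[acc],
        accepted = TRUE,
        stringsAsFactors = FALSE
      )
    }
  }
  hits <- do.call(rbind, hit_rows[!vapply(hit_rows, is.null, logical(1))])
  if (is.null(hits)) {
    hits <- data.frame(site_id = character(0), family = character(0),
                       cds_id = character(0), bit_score = numeric(0),
                       viterbi_bits = numeric(0), accepted = logical(0),
                       stringsAsFactors = FALSE)
  }
  structure(list(site_id = site_id, hits = hits,
                 counts = data.frame(family = fam_names, n = counts,
                                     stringsAsFactors = FALSE)),
            class = "hit_table")
}

#' @export
print.hit_table <- function(x, ...) {
  cat("<hit_table> site:", x$site_id, " accepted hits:", nrow(x$hits), "\n")
  print(x$counts)
  invisible(x)
}

#' Screen a site through an external scoring engine
#'
#' Adapter for HMMER-compatible engines: `engine` is a function
#' `(profile, cds) -> data.frame(cds_id, bit_score, viterbi_bits)` that
#' supplies per-sequence bit scores (for engines without a best-path
#' score, `viterbi_bits` may equal `bit_score`).  The result has the
#' identical `hit_table` schema as [search_site()], so all downstream
#' modules are engine-agnostic.
#'
#' @param engine Scoring function as described above.
#' @param profiles List of `profile_hmm` objects (or engine-native
#'   handles; they are passed through untouched apart from
#'   `family_name`).
#' @param cds Data frame of protein records.
#' @param threshold Acceptance threshold in bits.
#' @param site_id Site identifier.
#' @return A `hit_table`.
#' @export
search_site_engine <- function(engine, profiles, cds, threshold = 25,
                               site_id = "site") {
  fam_names <- vapply(profiles, `[[`, character(1), "family_name")
  hit_rows <- list()
  counts <- integer(length(profiles))
  for (j in seq_along(profiles)) {
    sc <- engine(profiles[[j]], cds)
    stopifnot(all(c("cds_id", "bit_score", "viterbi_bits") %in% names(sc)))
    acc <- sc$bit_score >= threshold
    counts[[j]] <- sum(acc)
    if (any(acc)) {
      hit_rows[[length(hit_rows) + 1L]] <- data.frame(
        site_id = site_id, family = fam_names[[j]],
        cds_id = sc$cds_id[acc], bit_score = sc$bit_score[acc],
        viterbi_bits = sc$viterbi_bits[acc], accepted = TRUE,
        stringsAsFactors = FALSE)
    }
  }
  hits <- if (length(hit_rows)) do.call(rbind, hit_rows) else
    data.frame(site_id = character(0), family = character(0),
               cds_id = character(0), bit_score = numeric(0),
               viterbi_bits = numeric(0), accepted = logical(0),
               stringsAsFactors = FALSE)
  structure(list(site_id = site_id, hits = hits,
                 counts = data.frame(family = fam_names, n = counts,
                                     stringsAsFactors = FALSE)),
            class = "hit_table")
}

#' Empirical false-hit rate from shuffled decoys
#'
#' Shuffles each CDS sequence (preserving composition and length), scores
#' the decoys against the profile, and reports the fraction at or above
#' the threshold.  Used to calibrate the bit-score acceptance threshold
#' for a given site.
#'
#' @param profile A `profile_hmm`.
#' @param cds Data frame of protein records.
#' @param threshold Bit-score threshold under evaluation.
#' @param seed Seed for the shuffle.
#' @param mode,flank_loop Passed to [score_sequences()].
#' @return Fraction of decoys scoring at or above `threshold`.
#' @export
decoy_fdr <- function(profile, cds, threshold, seed = 1L,
                      mode = c("local", "global"), flank_loop = 0.95) {
  stopifnot(nrow(cds) >= 1L)
  mode <- match.arg(mode)
  decoys <- with_seed(seed, vapply(cds$sequence, function(s) {
    paste(sample(strsplit(s, "", fixed = TRUE)[[1L]]), collapse = "")
  }, character(1), USE.NAMES = FALSE))
  if (threshold == -Inf) return(1.0)
  if (threshold == Inf) return(0.0)
  sc <- score_sequences(profile, decoys, mode, flank_loop)
  mean(sc$forward_bits >= threshold)
}

#' Collapse hit tables to one hits data frame
#' @param hit_tables List of `hit_table` objects.
#' @return Data frame of all accepted hits.
#' @export
bind_hits <- function(hit_tables) {
  do.call(rbind, lapply(hit_tables, `[[`, "hits"))
}
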