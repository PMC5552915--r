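#' Assign match columns of an alignment
#'
#' A column becomes a match state when its non-gap fraction (residues and
#' `X` both count as occupied) is at least `occupancy_threshold`.  Columns
#' below the threshold become insert regions.
#'
#' @param alignment Data frame from [read_alignment()] (columns `id`,
#'   `aligned_sequence`).
#' @param occupancy_threshold Minimum occupied fraction, in (0, 1].
#' @return Ascending 1-based column indices of the match columns.
#' @export
assign_match_columns <- function(alignment, occupancy_threshold = 0.5) {
  stopifnot(nrow(alignment) >= 1L,
            occupancy_threshold > 0, occupancy_threshold <= 1)
  m <- alignment_matrix(alignment)
  occ <- colMeans(m != "-")
  idx <- which(occ >= occupancy_threshold)
  if (length(idx) == 0L) {
    stop("no column reaches occupancy ", occupancy_threshold,
         " (max is ", signif(max(occ), 3),
         "); lower the occupancy threshold")
  }
  idx
}

alignment_matrix <- function(alignment) {
  chars <- strsplit(alignment$aligned_sequence, "", fixed = TRUE)
  matrix(unlist(chars), nrow = nrow(alignment), byrow = TRUE)
}

#' Representative reference length of a protein family
#'
#' The family length used by the RecA length-ratio normalization: the
#' median (default) or mean of the ungapped reference sequence lengths,
#' rounded half-up to an integer.
#'
#' @param records Data frame with a `sequence` or `aligned_sequence`
#'   column.
#' @param statistic `"median"` or `"mean"`.
#' @return Integer length in amino acids.
#' @export
reference_length <- function(records, statistic = c("median", "mean")) {
  statistic <- match.arg(statistic)
  col <- if ("sequence" %in% names(records)) "sequence" else "aligned_sequence"
  if (is.null(records[[col]]) || nrow(records) == 0L) {
    stop("reference_length needs at least one record")
  }
  lens <- nchar(gsub("-", "", records[[col]], fixed = TRUE))
  x <- if (statistic == "median") stats::median(lens) else mean(lens)
  as.integer(floor(x + 0.5))
}

#' Build a profile HMM from a family alignment
#'
#' Estimates match emissions from column residue counts with
#' background-weighted Laplace smoothing
#' `(count_r + pseudocount * q_r) / (residues_in_column + pseudocount)`,
#' sets insert emissions to the background, and estimates per-node
#' M/I/D transitions from the observed per-sequence state paths (gap in a
#' match column reads as a delete, residue in a non-match column as an
#' insert) with the same total pseudocount weight spread uniformly over
#' each state's outgoing branches.  `X` counts as occupied for column
#' assignment but contributes to no residue count.
#'
#' @param alignment Data frame from [read_alignment()].
#' @param occupancy_threshold Match-column occupancy threshold.
#' @param pseudocount Total smoothing weight (> 0).
#' @param background Background residue probabilities (default uniform).
#' @param family_name Name stored on the profile.
#' @param alphabet Residue alphabet (default the 20 amino acids).
#' @param ref_stat Statistic for [reference_length()].
#' @return An object of class `profile_hmm` with fields `family_name`,
#'   `L`, `alphabet`, `match_emissions` (L x K), `insert_emissions`
#'   ((L+1) x K; the first and last rows describe the flanking regions),
#'   `transitions` (list of per-node vectors `tMM`, `tMI`, `tMD`, `tIM`,
#'   `tII`, `tDM`, `tDD`), `background`, and `reference_length`.
#' @export
build_profile <- function(alignment, occupancy_threshold = 0.5,
                          pseudocount = 1,
                          background = NULL,
                          family_name = "family",
                          alphabet = AA_ALPHABET20,
                          ref_stat = c("median", "mean")) {
  stopifnot(pseudocount > 0)
  letters_ <- aa_letters(alphabet)
  K <- length(letters_)
  if (is.null(background)) background <- rep(1 / K, K)
  stopifnot(length(background) == K, all(background > 0),
            abs(sum(background) - 1) < 1e-9)

  match_cols <- assign_match_columns(alignment, occupancy_threshold)
  L <- length(match_cols)
  m <- alignment_matrix(alignment)
  nseq <- nrow(m)

  # --- match emissions -------------------------------------------------
  match_em <- matrix(0, nrow = L, ncol = K, dimnames = list(NULL, letters_))
  for (j in seq_len(L)) {
    col <- m[, match_cols[[j]]]
    counts <- tabulate(match(col, letters_), nbins = K)  # X and '-' drop out
    match_em[j, ] <- (counts + pseudocount * background) /
      (sum(counts) + pseudocount)
  }
  insert_em <- matrix(rep(background, L + 1), nrow = L + 1, byrow = TRUE,
                      dimnames = list(NULL, letters_))

  # --- transitions from observed state paths ---------------------------
  # path per sequence over match columns: M (residue) or D (gap); insert
  # residues between consecutive match columns attach to the left node.
  nM <- matrix(0, L, 3, dimnames = list(NULL, c("MM", "MI", "MD")))
  nI <- matrix(0, L, 2, dimnames = list(NULL, c("IM", "II")))
  nD <- matrix(0, L, 2, dimnames = list(NULL, c("DM", "DD")))
  is_gap <- m == "-"
  if (L > 1L) {
    for (s in seq_len(nseq)) {
      for (k in seq_len(L - 1L)) {
        from <- if (is_gap[s, match_cols[[k]]]) "D" else "M"
        to <- if (is_gap[s, match_cols[[k + 1L]]]) "D" else "M"
        between <- seq(match_cols[[k]] + 1L, length.out = match_cols[[k + 1L]] - match_cols[[k]] - 1L)
        nins <- if (length(between)) sum(!is_gap[s, between]) else 0L
        if (nins > 0L) {
          # paths through inserts: X -> I, (nins-1) x I -> I, I -> Y.
          # I -> D and D -> I are not modeled; such rare paths are folded
          # into I -> M and D -> M respectively.
          if (from == "M") nM[k, "MI"] <- nM[k, "MI"] + 1
          else nD[k, "DM"] <- nD[k, "DM"] + 1
          nI[k, "II"] <- nI[k, "II"] + nins - 1L
          nI[k, "IM"] <- nI[k, "IM"] + 1
        } else {
          if (from == "M" && to == "M") nM[k, "MM"] <- nM[k, "MM"] + 1
          else if (from == "M" && to == "D") nM[k, "MD"] <- nM[k, "MD"] + 1
          else if (from == "D" && to == "M") nD[k, "DM"] <- nD[k, "DM"] + 1
          else nD[k, "DD"] <- nD[k, "DD"] + 1
        }
      }
    }
  }
  smooth <- function(counts, pc) {
    w <- ncol(counts)
    (counts + pc / w) / (rowSums(counts) + pc)
  }
  pM <- smooth(nM, pseudocount)
  pI <- smooth(nI, pseudocount)
  pD <- smooth(nD, pseudocount)

  prof <- structure(list(
    family_name = family_name,
    L = L,
    alphabet = alphabet,
    match_emissions = match_em,
    insert_emissions = insert_em,
    transitions = list(
      tMM = pM[, "MM"], tMI = pM[, "MI"], tMD = pM[, "MD"],
      tIM = pI[, "IM"], tII = pI[, "II"],
      tDM = pD[, "DM"], tDD = pD[, "DD"]
    ),
    background = background,
    reference_length = reference_length(alignment, match.arg(ref_stat)),
    match_columns = match_cols,
    occupancy_threshold = occupancy_threshold,
    pseudocount = pseudocount
  ), class = "profile_hmm")
  validate_profile(prof)
}

#' Validate a `profile_hmm` object
#'
#' Checks the structural invariants: emission rows and outgoing transition
#' probabilities sum to one (within 1e-9), all probabilities are strictly
#' positive, and the reference length is at least 1.
#'
#' @param prof A `profile_hmm`.
#' @return The profile, invisibly on success; otherwise an error.
#' @export
validate_profile <- function(prof) {
  stopifnot(inherits(prof, "profile_hmm"))
  K <- length(aa_letters(prof$alphabet))
  with(prof, {
    if (L < 1L) stop("profile must have at least one match state")
    if (!all(dim(match_emissions) == c(L, K)) ||
        !all(dim(insert_emissions) == c(L + 1L, K))) {
      stop("emission matrix dimensions inconsistent with L")
    }
    if (any(match_emissions <= 0) || any(insert_emissions <= 0) ||
        any(background <= 0)) {
      stop("all emission probabilities must be > 0 (pseudocounts guarantee this)")
    }
    if (max(abs(rowSums(match_emissions) - 1)) > 1e-9 ||
        max(abs(rowSums(insert_emissions) - 1)) > 1e-9 ||
        abs(sum(background) - 1) > 1e-9) {
      stop("emission rows must sum to 1 within 1e-9")
    }
    tr <- transitions
    if (any(vapply(tr, function(v) any(v <= 0) || length(v) != L, logical(1)))) {
      stop("transition vectors must have length L with all entries > 0")
    }
    if (max(abs(tr$tMM + tr$tMI + tr$tMD - 1)) > 1e-9 ||
        max(abs(tr$tIM + tr$tII - 1)) > 1e-9 ||
        max(abs(tr$tDM + tr$tDD - 1)) > 1e-9) {
      stop("outgoing transition probabilities must sum to 1 within 1e-9")
    }
    if (reference_length < 1L) stop("reference_length must be >= 1")
  })
  invisible(prof)
}

#' @export
print.profile_hmm <- function(x, ...) {
  cat("<profile_hmm> family:", x$family_name,
      " L:", x$L,
      " alphabet:", x$alphabet,
      " reference_length:", x$reference_length, "\n")
  invisible(x)
}

#' Serialize a profile HMM to JSON
#' @param prof A `profile_hmm`.
#' @param path Output path.
#' @export
write_profile_json <- function(prof, path) {
  validate_profile(prof)
  obj <- list(
    family_name = prof$family_name, L = prof$L, alphabet = prof$alphabet,
    match_emissions = unname(prof$match_emissions),
    insert_emissions = unname(prof$insert_emissions),
    transitions = lapply(prof$transitions, unname),
    background = prof$background,
    reference_length = prof$reference_length
  )
  jsonlite::write_json(obj, path, digits = NA, auto_unbox = TRUE)
  invisible(path)
}

#' Load a profile HMM from JSON, validating all invariants
#' @param path Path to a JSON profile written by [write_profile_json()].
#' @return A `profile_hmm`.
#' @export
read_profile_json <- function(path) {
  obj <- jsonlite::read_json(path, simplifyVector = TRUE)
  prof <- structure(list(
    family_name = obj$family_name,
    L = as.integer(obj$L),
    alphabet = obj$alphabet,
    match_emissions = as.matrix(obj$match_emissions),
    insert_emissions = as.matrix(obj$insert_emissions),
    transitions = lapply(obj$transitions, as.numeric),
    background = as.numeric(obj$background),
    reference_length = as.integer(obj$reference_length)
  ), class = "profile_hmm")
  validate_profile(prof)
  prof
}
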