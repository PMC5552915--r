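#' Local pairwise protein alignment score and identity
#'
#' Smith-Waterman local alignment under BLOSUM62 with affine gaps (open
#' 11, extend 1; a gap of length g costs 11 + g).  Percent identity is
#' `100 * identical columns / aligned columns`, with gap columns counted
#' in the denominator.
#'
#' @param query,ref Protein sequences (non-empty strings).
#' @param gap_open,gap_extend Gap penalties (positive costs).
#' @return List with `score` and `percent_identity`.
#' @export
pairwise_align <- function(query, ref, gap_open = 11, gap_extend = 1) {
  stopifnot(nzchar(query), nzchar(ref))
  aln <- Biostrings::pairwiseAlignment(
    Biostrings::AAString(query), Biostrings::AAString(ref),
    type = "local", substitutionMatrix = blosum62(),
    gapOpening = gap_open, gapExtension = gap_extend
  )
  p <- as.character(Biostrings::alignedPattern(aln))
  s <- as.character(Biostrings::alignedSubject(aln))
  list(score = Biostrings::score(aln),
       percent_identity = percent_identity_cols(p, s))
}

percent_identity_cols <- function(a, b) {
  ca <- strsplit(a, "", fixed = TRUE)[[1L]]
  cb <- strsplit(b, "", fixed = TRUE)[[1L]]
  100 * sum(ca == cb & ca != "-") / length(ca)
}

blosum62 <- function() {
  e <- new.env()
  utils::data("BLOSUM62", package = "Biostrings", envir = e)
  e$BLOSUM62
}

#' Parse a lineage string from a reference record description
#'
#' Reference databases carry lineages in FASTA headers using the
#' convention `>id lineage=Domain;Phylum;Class;...`.
#'
#' @param description Header description text.
#' @param id Record id (for error messages).
#' @return Character vector of ranks, domain first.
#' @export
parse_lineage <- function(description, id = "?") {
  m <- regmatches(description, regexpr("lineage=\\S+", description))
  if (length(m) == 0L || !nzchar(m)) {
    stop("record '", id, "': description does not contain a ",
         "'lineage=Domain;Phylum;...' tag")
  }
  ranks <- strsplit(sub("^lineage=", "", m), ";", fixed = TRUE)[[1L]]
  ranks <- ranks[nzchar(ranks)]
  if (length(ranks) == 0L) stop("record '", id, "': empty lineage")
  ranks
}

#' Assign hits to taxa by best-hit protein alignment
#'
#' Each hit sequence is aligned against every record of the
#' lineage-labeled reference database (optionally restricted to the
#' hit's own family); the single best-scoring reference at or above
#' `min_score` supplies the assignment.  Ties are broken by higher
#' percent identity, then lexicographic reference id.  Hits below
#' `min_score` everywhere are reported unassigned.
#'
#' @param hits Data frame with columns `cds_id`, `family`, `sequence`.
#' @param refdb Data frame of reference records ([read_fasta()] layout)
#'   whose descriptions parse with [parse_lineage()]; an optional
#'   `family` column restricts each hit's search to its own family's
#'   references.
#' @param min_score Minimum alignment score for an assignment.
#' @return Data frame with `cds_id`, `family`, `best_ref_id`, `score`,
#'   `percent_identity`, `lineage` (semicolon-joined; NA when
#'   unassigned).
#' @export
assign_hits <- function(hits, refdb, min_score = 50) {
  stopifnot(nrow(refdb) >= 1L)
  lineages <- vapply(seq_len(nrow(refdb)), function(i) {
    paste(parse_lineage(refdb$description[[i]], refdb$id[[i]]), collapse = ";")
  }, character(1))
  out <- data.frame(
    cds_id = hits$cds_id,
    family = if ("family" %in% names(hits)) hits$family else NA_character_,
    best_ref_id = NA_character_, score = NA_real_,
    percent_identity = NA_real_, lineage = NA_character_,
    stringsAsFactors = FALSE
  )
  if (nrow(hits) == 0L) return(out)
  by_fam <- "family" %in% names(refdb) && "family" %in% names(hits)
  groups <- if (by_fam) split(seq_len(nrow(hits)), hits$family) else
    list(all = seq_len(nrow(hits)))
  b62 <- blosum62()
  for (g in names(groups)) {
    hidx <- groups[[g]]
    ridx <- if (by_fam) which(refdb$family == g) else seq_len(nrow(refdb))
    if (length(ridx) == 0L) next
    qset <- Biostrings::AAStringSet(hits$sequence[hidx])
    # pass 1: scores of every hit against every candidate reference
    scores <- matrix(NA_real_, nrow = length(hidx), ncol = length(ridx))
    for (j in seq_along(ridx)) {
      scores[, j] <- Biostrings::pairwiseAlignment(
        qset, Biostrings::AAString(refdb$sequence[[ridx[[j]]]]),
        type = "local", substitutionMatrix = b62,
        gapOpening = 11, gapExtension = 1, scoreOnly = TRUE)
    }
    # pass 2: full alignments (for identity) only for the winning pairs,
    # vectorized per reference; score ties are resolved by identity then
    # lexicographic reference id
    best <- apply(scores, 1, max)
    assignable <- which(best >= min_score)
    chosen <- rep(NA_integer_, length(hidx))  # column index into ridx
    tied <- list()
    for (i in assignable) {
      cand <- which(scores[i, ] == best[[i]])
      if (length(cand) == 1L) chosen[[i]] <- cand else tied[[as.character(i)]] <- cand
    }
    pid_out <- rep(NA_real_, length(hidx))
    for (i in assignable) {
      if (!is.na(chosen[[i]])) next
      cand <- tied[[as.character(i)]]
      pid <- vapply(cand, function(j) {
        pairwise_align(hits$sequence[[hidx[[i]]]],
                       refdb$sequence[[ridx[[j]]]])$percent_identity
      }, numeric(1))
      keep <- cand[pid == max(pid)]
      keep <- keep[order(refdb$id[ridx[keep]])][[1L]]
      chosen[[i]] <- keep
      pid_out[[i]] <- pid[[which(cand == keep)[[1L]]]]
    }
    for (j in sort(unique(chosen[!is.na(chosen)]))) {
      grp <- which(!is.na(chosen) & chosen == j & is.na(pid_out))
      if (length(grp) == 0L) next
      aln <- Biostrings::pairwiseAlignment(
        Biostrings::AAStringSet(hits$sequence[hidx[grp]]),
        Biostrings::AAString(refdb$sequence[[ridx[[j]]]]),
        type = "local", substitutionMatrix = b62,
        gapOpening = 11, gapExtension = 1)
      pa <- as.character(Biostrings::alignedPattern(aln))
      sa <- as.character(Biostrings::alignedSubject(aln))
      pid_out[grp] <- vapply(seq_along(grp), function(q) {
        percent_identity_cols(pa[[q]], sa[[q]])
      }, numeric(1))
    }
    ok <- which(!is.na(chosen))
    out$best_ref_id[hidx[ok]] <- refdb$id[ridx[chosen[ok]]]
    out$score[hidx[ok]] <- best[ok]
    out$percent_identity[hidx[ok]] <- pid_out[ok]
    out$lineage[hidx[ok]] <- lineages[ridx[chosen[ok]]]
  }
  out
}

#' Mean percent identity of assigned hits
#' @param assignments Data frame from [assign_hits()].
#' @return Arithmetic mean of `percent_identity` over assigned hits.
#' @export
mean_identity <- function(assignments) {
  pid <- assignments$percent_identity
  pid <- pid[!is.na(pid)]
  if (length(pid) == 0L) stop("no assigned hits: mean identity undefined")
  mean(pid)
}

#' Aggregate taxonomic assignments into a rank hierarchy
#'
#' Truncates each assignment's lineage at `depth` ranks and counts
#' assignments per distinct (truncated) lineage.  Counts are conserved
#' at every level: an internal node's count equals the sum over its
#' children plus assignments whose lineage ends at that node.
#'
#' @param assignments Data frame from [assign_hits()]; unassigned rows
#'   are dropped.
#' @param depth Number of ranks to keep (default: full depth).
#' @return Object of class `rank_hierarchy`: list with `leaves` (data
#'   frame `lineage`, `count`, sorted by lineage), `total`, `depth`.
#' @export
aggregate_ranks <- function(assignments, depth = Inf) {
  lin <- assignments$lineage[!is.na(assignments$lineage)]
  if (length(lin) == 0L) stop("no assigned hits to aggregate")
  trunc1 <- vapply(strsplit(lin, ";", fixed = TRUE), function(r) {
    paste(utils::head(r, depth), collapse = ";")
  }, character(1))
  tab <- table(trunc1)
  leaves <- data.frame(lineage = names(tab), count = as.integer(tab),
                       stringsAsFactors = FALSE)
  leaves <- leaves[order(leaves$lineage, method = "radix"), , drop = FALSE]
  rownames(leaves) <- NULL
  structure(list(leaves = leaves, total = length(lin), depth = depth),
            class = "rank_hierarchy")
}

#' Counts per taxon at a given rank level
#' @param hierarchy A `rank_hierarchy`.
#' @param level Rank level (1 = domain).
#' @return Named integer vector of counts at that level (taxa whose
#'   lineage is shallower than `level` are dropped).
#' @export
rank_counts <- function(hierarchy, level = 1) {
  parts <- strsplit(hierarchy$leaves$lineage, ";", fixed = TRUE)
  keep <- lengths(parts) >= level
  key <- vapply(parts[keep], function(r) paste(r[seq_len(level)], collapse = ";"),
                character(1))
  counts <- tapply(hierarchy$leaves$count[keep], key, sum)
  setNames(as.integer(counts), names(counts))
}

#' @export
print.rank_hierarchy <- function(x, ...) {
  cat("<rank_hierarchy> total:", x$total, " leaves:", nrow(x$leaves), "\n")
  invisible(x)
}

#' Write a hierarchy as Krona importable text
#'
#' One line per leaf lineage: count, TAB, then the rank names from
#' domain downward (the `ktImportText` dialect).  Lines are sorted by
#' lineage so output is deterministic.
#'
#' @param hierarchy A `rank_hierarchy` (or NULL for an empty file).
#' @param path Output path.
#' @export
write_krona_text <- function(hierarchy, path) {
  if (is.null(hierarchy) || nrow(hierarchy$leaves) == 0L) {
    writeLines(character(0), path, useBytes = TRUE)
    return(invisible(path))
  }
  lines <- paste0(hierarchy$leaves$count, "\t",
                  gsub(";", "\t", hierarchy$leaves$lineage, fixed = TRUE))
  con <- file(path, open = "w", encoding = "UTF-8")
  on.exit(close(con))
  writeLines(lines, con)
  invisible(path)
}
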