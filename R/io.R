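#' Read a protein FASTA file
#'
#' Parses a (plain or gzipped) protein FASTA file into a data frame of
#' records.  Sequences are upper-cased and trailing `*` stop symbols are
#' stripped.  Only the 20 standard amino acids plus the ambiguity code `X`
#' are accepted; the ambiguity codes B, Z, U and J are rejected with a
#' message naming the record and position, as is any gap character
#' (predicted-CDS inputs must be unaligned).
#'
#' @param path Path to a FASTA file.
#' @return A data frame with columns `id` (first whitespace-delimited token
#'   of the header), `sequence`, and `description` (remainder of the
#'   header, possibly empty).
#' @export
read_fasta <- function(path) {
  stopifnot(is.character(path), length(path) == 1L)
  if (!file.exists(path)) stop("no such file: ", path)
  set <- Biostrings::readBStringSet(path, format = "fasta")
  if (length(set) == 0L) stop("empty FASTA file: ", path)
  headers <- names(set)
  ids <- sub("\\s.*$", "", headers)
  desc <- ifelse(grepl("\\s", headers), sub("^\\S+\\s+", "", headers), "")
  if (any(ids == "")) stop("record with empty id in ", path)
  dup <- ids[duplicated(ids)]
  if (length(dup) > 0L) stop("duplicate id: ", dup[[1L]])
  seqs <- toupper(as.character(set))
  seqs <- sub("\\*+$", "", seqs)
  if (any(!nzchar(seqs))) {
    stop("empty sequence for record '", ids[!nzchar(seqs)][[1L]], "'")
  }
  check_protein_alphabet(seqs, ids, allow_gaps = FALSE)
  data.frame(id = unname(ids), sequence = unname(seqs),
             description = unname(desc), stringsAsFactors = FALSE)
}

check_protein_alphabet <- function(seqs, ids, allow_gaps = FALSE) {
  ok <- paste0(AA_ALPHABET20, "X", if (allow_gaps) "-")
  bad <- regexpr(sprintf("[^%s]", ok), seqs)
  hit <- which(bad > 0L)
  if (length(hit) > 0L) {
    i <- hit[[1L]]
    ch <- substr(seqs[[i]], bad[[i]], bad[[i]])
    stop("invalid character '", ch, "' in record '", ids[[i]],
         "' at position ", bad[[i]],
         " (only the 20 standard amino acids and X are accepted)")
  }
  invisible(TRUE)
}

#' Write protein records to FASTA
#'
#' @param records Data frame with columns `id`, `sequence` and optionally
#'   `description`.
#' @param path Output path.
#' @export
write_fasta <- function(records, path) {
  stopifnot(is.data.frame(records), all(c("id", "sequence") %in% names(records)))
  desc <- if ("description" %in% names(records)) records$description else ""
  header <- ifelse(nzchar(desc), paste(records$id, desc), records$id)
  writeLines(paste0(">", header, "\n", records$sequence), path, sep = "\n")
  invisible(path)
}

#' Read a protein multiple alignment
#'
#' Reads an aligned FASTA or Stockholm file into a data frame of aligned
#' records.  `.` gap characters are normalized to `-` and sequences are
#' upper-cased.  All aligned sequences must have equal length and each must
#' contain at least one non-gap character.
#'
#' @param path Path to the alignment file.
#' @param format `"auto"` (detect Stockholm by its `# STOCKHOLM` header),
#'   `"fasta"`, or `"stockholm"`.
#' @return Data frame with columns `id` and `aligned_sequence`.
#' @export
read_alignment <- function(path, format = c("auto", "fasta", "stockholm")) {
  format <- match.arg(format)
  if (!file.exists(path)) stop("no such file: ", path)
  if (format == "auto") {
    first <- readLines(path, n = 1L, warn = FALSE)
    format <- if (length(first) > 0L && grepl("^#\\s*STOCKHOLM", first))
      "stockholm" else "fasta"
  }
  if (format == "stockholm") {
    aln <- read_stockholm(path)
  } else {
    set <- Biostrings::readBStringSet(path, format = "fasta")
    if (length(set) == 0L) stop("empty alignment file: ", path)
    ids <- sub("\\s.*$", "", names(set))
    aln <- data.frame(id = unname(ids),
                      aligned_sequence = unname(as.character(set)),
                      stringsAsFactors = FALSE)
  }
  dup <- aln$id[duplicated(aln$id)]
  if (length(dup) > 0L) stop("duplicate id: ", dup[[1L]])
  aln$aligned_sequence <- chartr(".", "-", toupper(aln$aligned_sequence))
  lens <- nchar(aln$aligned_sequence)
  if (length(unique(lens)) > 1L) {
    u <- unique(lens)
    stop("ragged alignment: ", u[[1L]], " vs ", u[[2L]])
  }
  if (any(gsub("-", "", aln$aligned_sequence, fixed = TRUE) == "")) {
    stop("alignment record with no residues")
  }
  check_protein_alphabet(aln$aligned_sequence, aln$id, allow_gaps = TRUE)
  aln
}

# Minimal Stockholm 1.0 reader: sequence lines only, multi-block files
# concatenated per id; '#' annotations and '//' terminator ignored.
read_stockholm <- function(path) {
  lines <- readLines(path, warn = FALSE)
  seqs <- list()
  order <- character(0)
  for (ln in lines) {
    if (grepl("^\\s*$", ln) || grepl("^#", ln) || grepl("^//", ln)) next
    parts <- strsplit(trimws(ln), "\\s+")[[1L]]
    if (length(parts) != 2L) stop("malformed Stockholm line: ", ln)
    id <- parts[[1L]]
    if (is.null(seqs[[id]])) {
      seqs[[id]] <- parts[[2L]]
      order <- c(order, id)
    } else {
      seqs[[id]] <- paste0(seqs[[id]], parts[[2L]])
    }
  }
  if (length(seqs) == 0L) stop("empty alignment file: ", path)
  data.frame(id = order,
             aligned_sequence = unlist(seqs[order], use.names = FALSE),
             stringsAsFactors = FALSE)
}

#' Write a uniform table as TSV
#'
#' All tabular pipeline output is tab-separated (lineage strings contain
#' commas).  Accepts a data frame or a list of identically-named lists.
#' Numeric columns keep full double precision; row order is preserved.
#'
#' @param rows Data frame, or list of named lists sharing one field set.
#' @param path Output path.
#' @export
write_table <- function(rows, path) {
  if (!is.data.frame(rows)) {
    if (!is.list(rows)) stop("rows must be a data frame or list of records")
    if (length(rows) == 0L) stop("cannot infer a header from an empty record list")
    fields <- names(rows[[1L]])
    for (r in rows) {
      if (!identical(sort(names(r)), sort(fields))) {
        stop("heterogeneous rows: fields {", paste(names(r), collapse = ","),
             "} vs {", paste(fields, collapse = ","), "}")
      }
    }
    rows <- do.call(rbind, lapply(rows, function(r) {
      as.data.frame(r[fields], stringsAsFactors = FALSE)
    }))
  }
  utils::write.table(format_table_cols(rows), path, sep = "\t",
                     quote = FALSE, row.names = FALSE, col.names = TRUE)
  invisible(path)
}

# render doubles with 15 significant digits so round-trips are stable
format_table_cols <- function(df) {
  for (j in seq_along(df)) {
    if (is.double(df[[j]])) {
      df[[j]] <- vapply(df[[j]], function(x) {
        if (is.na(x)) "NA" else format(x, digits = 15, scientific = FALSE, trim = TRUE)
      }, character(1))
    }
  }
  df
}

#' Read a TSV written by [write_table()]
#' @param path Path to a TSV file.
#' @return Data frame.
#' @export
read_table_tsv <- function(path) {
  utils::read.delim(path, sep = "\t", stringsAsFactors = FALSE, check.names = FALSE)
}

#' Read the pooled CDS set for one site
#'
#' A site's CDS set is the union of all FASTA files listed for it (the
#' annotated and unannotated predicted-CDS files are screened together).
#' Ids duplicated across files get a `_f<index>` suffix so records remain
#' uniquely addressable.
#'
#' @param paths Character vector of FASTA paths.
#' @return Data frame of protein records as from [read_fasta()].
#' @export
read_site_cds <- function(paths) {
  stopifnot(length(paths) >= 1L)
  recs <- lapply(paths, read_fasta)
  if (length(recs) == 1L) return(recs[[1L]])
  seen <- character(0)
  out <- vector("list", length(recs))
  for (i in seq_along(recs)) {
    r <- recs[[i]]
    clash <- r$id %in% seen
    if (any(clash)) r$id[clash] <- paste0(r$id[clash], "_f", i)
    seen <- c(seen, r$id)
    out[[i]] <- r
  }
  do.call(rbind, out)
}
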