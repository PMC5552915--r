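#' Build all family profiles for a run
#'
#' Reads each family's reference alignment (aligned FASTA or Stockholm;
#' equal-length unaligned references are accepted as a trivial
#' alignment) and builds its profile HMM.
#'
#' @param config A `run_config`.
#' @param verbose Log progress to stderr.
#' @return Named list of `profile_hmm` objects.
#' @export
build_profiles <- function(config, verbose = FALSE) {
  profs <- list()
  for (i in seq_len(nrow(config$families))) {
    fam <- config$families$name[[i]]
    aln <- tryCatch(
      read_alignment(config$families$path[[i]]),
      error = function(e) {
        stop("stage build-profiles, family ", fam, ": ", conditionMessage(e),
             call. = FALSE)
      }
    )
    profs[[fam]] <- build_profile(
      aln, occupancy_threshold = config$occupancy_threshold,
      pseudocount = config$pseudocount, family_name = fam,
      ref_stat = config$ref_stat
    )
    log_msg("built profile ", fam, " (L=", profs[[fam]]$L, ")",
            verbose = verbose)
  }
  profs
}

#' Screen all sites of a run
#'
#' @param config A `run_config`.
#' @param profiles Named list from [build_profiles()].
#' @param verbose Log progress.
#' @return Named list of `hit_table` objects, one per site, in manifest
#'   order.
#' @export
search_sites <- function(config, profiles, verbose = FALSE) {
  out <- list()
  for (i in seq_len(nrow(config$sites))) {
    sid <- config$sites$site_id[[i]]
    cds <- tryCatch(
      read_site_cds(unlist(config$sites$paths[[i]])),
      error = function(e) {
        stop("stage search, site ", sid, ": ", conditionMessage(e),
             call. = FALSE)
      }
    )
    out[[sid]] <- search_site(profiles, cds, threshold = config$threshold,
                              site_id = sid, mode = config$mode,
                              flank_loop = config$flank_loop)
    log_msg("site ", sid, ": ", nrow(cds), " CDS, ",
            nrow(out[[sid]]$hits), " accepted hits", verbose = verbose)
  }
  out
}

#' Taxonomic assignment stage
#'
#' Assigns the accepted hits of the configured families to the
#' lineage-labeled reference DB, aggregates ranks, and returns the
#' assignments plus the rank hierarchy.
#'
#' @param config A `run_config` with a `refdb` path.
#' @param hit_tables List of `hit_table` objects.
#' @param verbose Log progress.
#' @return List with `assignments` and `hierarchy` (NULL when there are
#'   no assignable hits).
#' @export
taxonomy_stage <- function(config, hit_tables, verbose = FALSE) {
  if (is.null(config$refdb)) return(NULL)
  refdb <- read_fasta(config$refdb)
  fam_tag <- regmatches(refdb$description,
                        regexpr("family=\\S+", refdb$description))
  if (length(fam_tag) == nrow(refdb)) {
    refdb$family <- sub("^family=", "", fam_tag)
  }
  fams <- config$taxonomy_families
  hits <- bind_hits(hit_tables)
  if (!is.null(fams)) hits <- hits[hits$family %in% fams, , drop = FALSE]
  if (nrow(hits) == 0L) return(list(assignments = NULL, hierarchy = NULL))
  # attach hit sequences from the site CDS files
  seq_map <- new.env(parent = emptyenv())
  for (i in seq_len(nrow(config$sites))) {
    cds <- read_site_cds(unlist(config$sites$paths[[i]]))
    for (j in seq_len(nrow(cds))) assign(cds$id[[j]], cds$sequence[[j]], seq_map)
  }
  hits$sequence <- vapply(hits$cds_id, function(id) get(id, seq_map),
                          character(1), USE.NAMES = FALSE)
  asn <- assign_hits(hits, refdb, min_score = config$min_assign_score)
  log_msg("assigned ", sum(!is.na(asn$lineage)), "/", nrow(asn), " hits",
          verbose = verbose)
  hier <- if (any(!is.na(asn$lineage))) aggregate_ranks(asn) else NULL
  list(assignments = asn, hierarchy = hier)
}

#' Run the full screening pipeline
#'
#' build-profiles, search, quantify, compare, and (when a reference DB
#' is configured) taxonomy, writing all result tables under `out_dir`:
#' `profiles/<family>.json`, `hits.tsv`, `abundance.tsv`,
#' `comparison.tsv`, `assignments.tsv`, `krona.txt`, and a
#' `run_log.yaml` recording the config hash, seed and package version.
#' The run is deterministic given (config, seed): rerunning yields
#' byte-identical tables.
#'
#' @param config A `run_config` or path to a YAML config.
#' @param out_dir Output directory.
#' @param verbose Log stage progress to stderr.
#' @return List of class `run_result`: the in-memory stage results plus
#'   the output paths.
#' @export
run_all <- function(config, out_dir = tempfile("phoscreen_run"),
                    verbose = FALSE) {
  if (is.character(config)) config <- read_run_config(config)
  stopifnot(inherits(config, "run_config"))
  dir.create(file.path(out_dir, "profiles"), recursive = TRUE,
             showWarnings = FALSE)

  log_msg("stage build-profiles", verbose = verbose)
  profiles <- build_profiles(config, verbose = verbose)
  for (fam in names(profiles)) {
    write_profile_json(profiles[[fam]],
                       file.path(out_dir, "profiles", paste0(fam, ".json")))
  }

  log_msg("stage search", verbose = verbose)
  hit_tables <- search_sites(config, profiles, verbose = verbose)
  hits_path <- file.path(out_dir, "hits.tsv")
  write_table(bind_hits(hit_tables), hits_path)

  log_msg("stage quantify", verbose = verbose)
  abundance <- quantify_sites(hit_tables, profiles, config)
  abundance_path <- file.path(out_dir, "abundance.tsv")
  write_table(as.data.frame(abundance), abundance_path)

  log_msg("stage compare", verbose = verbose)
  comparison <- compare_groups(abundance, config)
  comparison_path <- file.path(out_dir, "comparison.tsv")
  write_table(comparison, comparison_path)

  assignments_path <- krona_path <- NULL
  tax <- taxonomy_stage(config, hit_tables, verbose = verbose)
  if (!is.null(tax) && !is.null(tax$assignments)) {
    assignments_path <- file.path(out_dir, "assignments.tsv")
    write_table(tax$assignments[, setdiff(names(tax$assignments), "sequence")],
                assignments_path)
    krona_path <- file.path(out_dir, "krona.txt")
    write_krona_text(tax$hierarchy, krona_path)
  }

  log_path <- file.path(out_dir, "run_log.yaml")
  yaml::write_yaml(list(
    config_hash = config_hash(config),
    seed = config$seed,
    package_version = as.character(utils::packageVersion("phoscreen")),
    n_sites = nrow(config$sites),
    n_families = nrow(config$families)
  ), log_path)

  structure(list(
    config = config, profiles = profiles, hit_tables = hit_tables,
    abundance = abundance, comparison = comparison, taxonomy = tax,
    paths = list(hits = hits_path, abundance = abundance_path,
                 comparison = comparison_path, assignments = assignments_path,
                 krona = krona_path, run_log = log_path),
    out_dir = out_dir
  ), class = "run_result")
}

#' MD5 hash of a run configuration
#' @param config A `run_config`.
#' @return Hex digest string.
#' @export
config_hash <- function(config) {
  tmp <- tempfile(fileext = ".yaml")
  on.exit(unlink(tmp))
  write_run_config(config, tmp)
  unname(tools::md5sum(tmp))
}

#' @export
print.run_result <- function(x, ...) {
  cat("<run_result>", nrow(x$config$sites), "sites,",
      nrow(x$config$families), "families, outputs in", x$out_dir, "\n")
  invisible(x)
}

#' Estimated carriage recovery against a study's ground truth
#'
#' Joins a run's abundance table with a synthetic study's truth table
#' and reports per-(site, family) estimated versus realized carriage
#' with absolute errors.
#'
#' @param abundance An `abundance_table`.
#' @param truth Truth data frame from [make_study()].
#' @return Data frame with `site_id`, `family`, `group`, `estimated`,
#'   `realized`, `abs_error`; attribute `mae` carries the mean absolute
#'   error.
#' @export
recovery_error <- function(abundance, truth) {
  tgt <- abundance[abundance$role == "target",
                   c("site_id", "family", "frequency")]
  m <- merge(truth, tgt, by = c("site_id", "family"), sort = TRUE)
  out <- data.frame(
    site_id = m$site_id, family = m$family, group = m$group,
    estimated = m$frequency, realized = m$realized_carriage,
    abs_error = abs(m$frequency - m$realized_carriage),
    stringsAsFactors = FALSE
  )
  attr(out, "mae") <- mean(out$abs_error)
  out
}
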