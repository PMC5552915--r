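#' Length-normalize a raw hit count to RecA
#'
#' Fragment-derived hit counts scale with protein length, so raw counts
#' are corrected by the family-to-RecA length ratio.  The default
#' direction scales counts of longer genes down:
#' `n_normalized = n * L_RecA / L_f`.  The alternative direction
#' (`"length_weighted"`, `n * L_f / L_RecA`) is exposed for comparison.
#'
#' @param n Raw hit count (non-negative).
#' @param L_f Family reference length in amino acids.
#' @param L_recA RecA reference length in amino acids.
#' @param direction `"length_corrected"` (default) or `"length_weighted"`.
#' @return Normalized count (double).
#' @export
normalize_count <- function(n, L_f, L_recA,
                            direction = c("length_corrected", "length_weighted")) {
  direction <- match.arg(direction)
  stopifnot(all(n >= 0))
  if (any(L_f <= 0) || any(L_recA <= 0)) stop("reference lengths must be >= 1")
  if (direction == "length_corrected") n * L_recA / L_f else n * L_f / L_recA
}

#' Average genome equivalent of a site
#'
#' The mean of the normalized counts of the five single-copy housekeeping
#' genes (RecA, RpoB, AtpB, GyrB, SucD): an estimate of how many genomes
#' the site's CDS set represents.
#'
#' @param housekeeping_normalized Named numeric vector of normalized
#'   counts; must contain every family in `required`.
#' @param required Families entering the mean.
#' @return The genome equivalent `G` (>= 0).  `G = 0` (no housekeeping
#'   hits at all) triggers a warning: gene frequencies at that site are
#'   undefined.
#' @export
genome_equivalents <- function(housekeeping_normalized,
                               required = HOUSEKEEPING_FAMILIES) {
  missing_fam <- setdiff(required, names(housekeeping_normalized))
  if (length(missing_fam) > 0L) {
    stop("missing housekeeping famil",
         if (length(missing_fam) > 1) "ies: " else "y: ",
         paste(missing_fam, collapse = ", "))
  }
  vals <- housekeeping_normalized[required]
  stopifnot(all(vals >= 0))
  g <- mean(vals)
  if (g == 0) {
    warning("all housekeeping counts are zero; genome equivalent is 0 ",
            "and gene frequencies for this site are undefined")
  }
  g
}

#' Per-genome gene frequency
#'
#' The fraction (and percentage) of genomes carrying the gene, assuming
#' `copy_number` copies per carrying genome:
#' `f = n_normalized / (G * copy_number)`.  Values above 1 (100%) are
#' flagged, never clamped — they diagnose multi-copy genes or a
#' miscalibrated threshold.
#'
#' @param n_norm Normalized hit count.
#' @param G Genome equivalents of the site (> 0).
#' @param copy_number Assumed copies per carrying genome (>= 1).
#' @return List with `fraction`, `percent`, and logical `flagged`.
#' @export
gene_frequency <- function(n_norm, G, copy_number = 1) {
  stopifnot(copy_number >= 1)
  if (!is.finite(G) || G <= 0) {
    stop("genome equivalent must be > 0 to define a gene frequency")
  }
  f <- n_norm / (G * copy_number)
  list(fraction = f, percent = 100 * f, flagged = f > 1)
}

#' Quantify gene frequencies across sites
#'
#' Composes [normalize_count()], [genome_equivalents()] and
#' [gene_frequency()] over all sites and families: the full abundance
#' table, including the headline quantity — the percentage of bacteria
#' containing each target gene per site.
#'
#' @param hit_tables List of `hit_table` objects, one per site.
#' @param profiles List of `profile_hmm` objects (supplies the reference
#'   lengths).
#' @param config A `run_config` (roles, groups, copy numbers,
#'   normalization direction).
#' @return Data frame of class `abundance_table` with columns `site_id`,
#'   `group`, `family`, `role`, `raw_count`, `reference_length`,
#'   `normalized_count`, `genome_equivalents`, `frequency`, `percent`,
#'   `flag`.  Frequencies are reported for target families; housekeeping
#'   rows carry NA.
#' @export
quantify_sites <- function(hit_tables, profiles, config) {
  fam_names <- vapply(profiles, `[[`, character(1), "family_name")
  ref_len <- setNames(vapply(profiles, `[[`, numeric(1), "reference_length"),
                      fam_names)
  if (!"RecA" %in% fam_names) stop("a RecA profile is required for normalization")
  L_recA <- ref_len[["RecA"]]
  roles <- setNames(config$families$role, config$families$name)
  groups <- setNames(config$sites$group, config$sites$site_id)
  cn <- config$copy_number
  copy_of <- function(fam) {
    if (length(cn) == 1L && is.null(names(cn))) cn
    else if (fam %in% names(cn)) cn[[fam]] else 1
  }

  rows <- lapply(hit_tables, function(ht) {
    counts <- setNames(ht$counts$n, ht$counts$family)
    nn <- normalize_count(counts, ref_len[names(counts)], L_recA,
                          config$normalization_direction)
    hk <- nn[intersect(names(nn), config$ge_families)]
    G <- genome_equivalents(hk, config$ge_families)
    out <- data.frame(
      site_id = ht$site_id,
      group = unname(groups[[ht$site_id]]),
      family = names(counts),
      role = unname(roles[names(counts)]),
      raw_count = unname(counts),
      reference_length = unname(ref_len[names(counts)]),
      normalized_count = unname(nn),
      genome_equivalents = G,
      frequency = NA_real_, percent = NA_real_, flag = "",
      stringsAsFactors = FALSE
    )
    tgt <- which(out$role == "target")
    for (i in tgt) {
      if (G > 0) {
        fr <- gene_frequency(out$normalized_count[[i]], G, copy_of(out$family[[i]]))
        out$frequency[[i]] <- fr$fraction
        out$percent[[i]] <- fr$percent
        out$flag[[i]] <- if (fr$flagged) "over_100pct" else "ok"
      } else {
        out$flag[[i]] <- "undefined_G"
      }
    }
    out
  })
  res <- do.call(rbind, rows)
  rownames(res) <- NULL
  class(res) <- c("abundance_table", class(res))
  res
}

#' Genome census for alkaline-phosphatase presence
#'
#' Screens whole genomes (full-length proteins, not fragments) for each
#' APase family and reports, per taxon group, how many genomes carry at
#' least one of the designated families — the genome-database census mode.
#'
#' @param genomes List of genomes, each a list with `genome_id`, `taxon`
#'   (grouping label, e.g. phylum), and `proteins` (data frame with `id`,
#'   `sequence`).  A `synthetic_community` (see [simulate_community()])
#'   may be passed instead.
#' @param apase_profiles List of `profile_hmm` objects for the APase
#'   families.
#' @param threshold Acceptance threshold in bits.
#' @param mode,flank_loop Passed to [score_sequences()].
#' @return List with `genomes` (per-genome presence/absence per family
#'   plus `any_apase`) and `taxa` (per-taxon `n_with_apase`, `n_total`,
#'   `fraction = n_with_apase / n_total`).
#' @export
census_genomes <- function(genomes, apase_profiles, threshold = 25,
                           mode = c("local", "global"), flank_loop = 0.95) {
  mode <- match.arg(mode)
  if (inherits(genomes, "synthetic_community")) genomes <- community_genomes(genomes)
  stopifnot(length(genomes) >= 1L)
  fam_names <- vapply(apase_profiles, `[[`, character(1), "family_name")
  pres <- matrix(FALSE, nrow = length(genomes), ncol = length(fam_names),
                 dimnames = list(NULL, fam_names))
  for (i in seq_along(genomes)) {
    g <- genomes[[i]]
    if (nrow(g$proteins) == 0L) next
    for (j in seq_along(apase_profiles)) {
      sc <- score_sequences(apase_profiles[[j]], g$proteins$sequence,
                            mode, flank_loop)
      pres[i, j] <- any(sc$forward_bits >= threshold)
    }
  }
  per_genome <- data.frame(
    genome_id = vapply(genomes, `[[`, character(1), "genome_id"),
    taxon = vapply(genomes, `[[`, character(1), "taxon"),
    stringsAsFactors = FALSE
  )
  per_genome <- cbind(per_genome, as.data.frame(pres))
  per_genome$any_apase <- apply(pres, 1, any)
  agg <- split(per_genome$any_apase, per_genome$taxon)
  taxa <- data.frame(
    taxon = names(agg),
    n_with_apase = vapply(agg, sum, numeric(1)),
    n_total = vapply(agg, length, numeric(1)),
    stringsAsFactors = FALSE, row.names = NULL
  )
  taxa$fraction <- taxa$n_with_apase / taxa$n_total
  list(genomes = per_genome, taxa = taxa)
}
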