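#' Build a pipeline run configuration
#'
#' Collects every tunable choice of the screening pipeline in one validated
#' object: the family manifest (reference FASTA per family, target or
#' housekeeping role), the site manifest (CDS FASTA paths and low/high-pH
#' group label per site), the bit-score acceptance threshold, and the
#' statistical settings.  RecA must be present as a housekeeping family —
#' it anchors the length normalization.
#'
#' @param families Data frame with columns `name`, `path`, `role`
#'   (`"target"` or `"housekeeping"`).
#' @param sites Data frame with columns `site_id`, `group` (`"low_pH"` or
#'   `"high_pH"`), and `paths` (list column of FASTA path vectors, or a
#'   single path column).
#' @param threshold Acceptance threshold in bits for the forward score
#'   (default 25).
#' @param ref_stat Statistic for family reference lengths: `"median"`
#'   (default) or `"mean"`.
#' @param ttest_variant `"pooled"` (classical two-sample t, default) or
#'   `"welch"`.
#' @param alpha Significance level for group comparisons (default 0.05).
#' @param copy_number Assumed gene copies per genome: a single number
#'   (default 1) or a named per-family vector.
#' @param seed Integer seed recorded with the run.
#' @param mode Alignment mode for scoring: `"local"` (free flanking
#'   residues, default — CDS are fragments) or `"global"`.
#' @param flank_loop Self-loop probability of the flanking background
#'   states in local mode (default 0.95).
#' @param occupancy_threshold Minimum non-gap column fraction for a match
#'   state when building profiles (default 0.5).
#' @param pseudocount Total pseudocount weight for profile estimation
#'   (default 1).
#' @param normalization_direction `"length_corrected"` (default; counts of
#'   longer genes are scaled down, `n * L_RecA / L_f`) or
#'   `"length_weighted"` (`n * L_f / L_RecA`).
#' @param p_adjust `"none"` (default, per-gene reporting) or `"BH"`.
#' @param ge_families Families averaged into the genome equivalent
#'   (default the five single-copy housekeeping genes).
#' @param refdb Optional path to a lineage-labeled reference protein FASTA
#'   for taxonomic assignment.
#' @param taxonomy_families Families whose hits are taxonomically assigned
#'   (default the three alkaline phosphatases, where present).
#' @param min_assign_score Minimum pairwise alignment score for a
#'   taxonomic assignment (default 50).
#' @return A validated list of class `run_config`.
#' @export
run_config <- function(families, sites,
                       threshold = 25, ref_stat = c("median", "mean"),
                       ttest_variant = c("pooled", "welch"), alpha = 0.05,
                       copy_number = 1, seed = 1L,
                       mode = c("local", "global"), flank_loop = 0.95,
                       occupancy_threshold = 0.5, pseudocount = 1,
                       normalization_direction = c("length_corrected", "length_weighted"),
                       p_adjust = c("none", "BH"),
                       ge_families = HOUSEKEEPING_FAMILIES,
                       refdb = NULL,
                       taxonomy_families = NULL,
                       min_assign_score = 50) {
  cfg <- list(
    families = as.data.frame(families, stringsAsFactors = FALSE),
    sites = normalize_site_manifest(sites),
    threshold = threshold,
    ref_stat = match.arg(ref_stat),
    ttest_variant = match.arg(ttest_variant),
    alpha = alpha,
    copy_number = copy_number,
    seed = as.integer(seed),
    mode = match.arg(mode),
    flank_loop = flank_loop,
    occupancy_threshold = occupancy_threshold,
    pseudocount = pseudocount,
    normalization_direction = match.arg(normalization_direction),
    p_adjust = match.arg(p_adjust),
    ge_families = ge_families,
    refdb = refdb,
    taxonomy_families = taxonomy_families,
    min_assign_score = min_assign_score
  )
  class(cfg) <- "run_config"
  validate_run_config(cfg)
}

normalize_site_manifest <- function(sites) {
  sites <- as.data.frame(sites, stringsAsFactors = FALSE)
  if (!"paths" %in% names(sites) && "path" %in% names(sites)) {
    sites$paths <- as.list(sites$path)
    sites$path <- NULL
  }
  if (!is.list(sites$paths)) sites$paths <- as.list(sites$paths)
  sites
}

validate_run_config <- function(cfg) {
  fam <- cfg$families
  if (!all(c("name", "path", "role") %in% names(fam))) {
    stop("families manifest needs columns name, path, role")
  }
  if (!all(fam$role %in% c("target", "housekeeping"))) {
    stop("family role must be 'target' or 'housekeeping'")
  }
  if (anyDuplicated(fam$name)) stop("duplicate family name in manifest")
  hk <- fam$name[fam$role == "housekeeping"]
  if (sum(hk == "RecA") != 1L) {
    stop("exactly one housekeeping family named 'RecA' is required ",
         "(it anchors the length normalization)")
  }
  if (!any(fam$role == "target")) stop("at least one target family is required")
  st <- cfg$sites
  if (!all(c("site_id", "group", "paths") %in% names(st))) {
    stop("site manifest needs columns site_id, group, paths")
  }
  if (anyDuplicated(st$site_id)) stop("duplicate site_id in manifest")
  if (!all(st$group %in% c("low_pH", "high_pH"))) {
    stop("every site needs a group label 'low_pH' or 'high_pH'")
  }
  if (!(is.numeric(cfg$alpha) && cfg$alpha > 0 && cfg$alpha < 1)) {
    stop("alpha must lie in (0, 1)")
  }
  if (!is.numeric(cfg$threshold) || !is.finite(cfg$threshold)) {
    stop("threshold must be a finite number of bits")
  }
  cn <- cfg$copy_number
  if (!(is.numeric(cn) && all(cn >= 1))) stop("copy_number must be >= 1")
  if (!(cfg$flank_loop > 0 && cfg$flank_loop < 1)) {
    stop("flank_loop must lie in (0, 1)")
  }
  cfg
}

#' Read a run configuration from YAML
#'
#' Relative family/site/refdb paths are resolved against the directory
#' containing the YAML file.
#'
#' @param path Path to a YAML config (as written by [write_run_config()]
#'   or [make_study()]).
#' @return A `run_config` object.
#' @export
read_run_config <- function(path) {
  raw <- yaml::read_yaml(path)
  base <- dirname(normalizePath(path))
  resolve <- function(p) {
    ifelse(grepl("^(/|[A-Za-z]:)", p), p, file.path(base, p))
  }
  fam <- do.call(rbind, lapply(raw$families, function(f) {
    data.frame(name = f$name, path = resolve(f$path), role = f$role,
               stringsAsFactors = FALSE)
  }))
  sites <- data.frame(
    site_id = vapply(raw$sites, `[[`, character(1), "site_id"),
    group = vapply(raw$sites, `[[`, character(1), "group"),
    stringsAsFactors = FALSE
  )
  sites$paths <- lapply(raw$sites, function(s) resolve(unlist(s$paths)))
  args <- raw[setdiff(names(raw), c("families", "sites", "refdb"))]
  args <- args[names(args) %in% names(formals(run_config))]
  if (!is.null(raw$refdb)) args$refdb <- resolve(raw$refdb)
  if (!is.null(args$copy_number)) args$copy_number <- unlist(args$copy_number)
  do.call(run_config, c(list(families = fam, sites = sites), args))
}

#' Write a run configuration to YAML
#' @param cfg A `run_config` object.
#' @param path Output path.
#' @param relative_to Optional directory; paths under it are written
#'   relative so the config is relocatable.
#' @export
write_run_config <- function(cfg, path, relative_to = NULL) {
  strip <- function(p) {
    if (is.null(relative_to)) return(p)
    pref <- paste0(sub("/+$", "", relative_to), "/")
    sub(paste0("^", gsub("([][{}()+*^$|\\\\?.])", "\\\\\\1", pref)), "", p)
  }
  out <- list(
    families = lapply(seq_len(nrow(cfg$families)), function(i) {
      list(name = cfg$families$name[[i]], path = strip(cfg$families$path[[i]]),
           role = cfg$families$role[[i]])
    }),
    sites = lapply(seq_len(nrow(cfg$sites)), function(i) {
      list(site_id = cfg$sites$site_id[[i]], group = cfg$sites$group[[i]],
           paths = as.list(strip(unlist(cfg$sites$paths[[i]]))))
    }),
    threshold = cfg$threshold, ref_stat = cfg$ref_stat,
    ttest_variant = cfg$ttest_variant, alpha = cfg$alpha,
    copy_number = as.list(cfg$copy_number), seed = cfg$seed,
    mode = cfg$mode, flank_loop = cfg$flank_loop,
    occupancy_threshold = cfg$occupancy_threshold,
    pseudocount = cfg$pseudocount,
    normalization_direction = cfg$normalization_direction,
    p_adjust = cfg$p_adjust, ge_families = as.list(cfg$ge_families),
    min_assign_score = cfg$min_assign_score
  )
  if (!is.null(cfg$refdb)) out$refdb <- strip(cfg$refdb)
  if (!is.null(cfg$taxonomy_families))
    out$taxonomy_families <- as.list(cfg$taxonomy_families)
  yaml::write_yaml(out, path)
  invisible(path)
}
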