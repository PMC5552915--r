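#' Default synthetic lineage pool
#'
#' Lineages (domain;phylum;class) and sampling weights used when
#' labeling synthetic genomes and reference sequences, weighted toward
#' the phyla that dominate soil communities.
#'
#' @return Data frame with columns `lineage` and `weight`.
#' @export
default_lineage_pool <- function() {
  data.frame(
    lineage = c(
      "Bacteria;Proteobacteria;Gammaproteobacteria",
      "Bacteria;Proteobacteria;Alphaproteobacteria",
      "Bacteria;Actinobacteria;Actinomycetia",
      "Bacteria;Firmicutes;Bacilli",
      "Bacteria;Acidobacteria;Acidobacteriia",
      "Bacteria;Bacteroidetes;Bacteroidia",
      "Bacteria;Cyanobacteria;Cyanophyceae"
    ),
    weight = c(0.20, 0.15, 0.20, 0.15, 0.10, 0.10, 0.10),
    stringsAsFactors = FALSE
  )
}

random_protein <- function(len, letters_) {
  paste(sample(letters_, len, replace = TRUE), collapse = "")
}

# i.i.d. substitution: each position mutates with prob `rate` to one of
# the other 19 residues, uniformly.  No indels, so reference families
# stay trivially aligned and identity expectations are analytic.
mutate_protein <- function(seq, rate, letters_) {
  ch <- strsplit(seq, "", fixed = TRUE)[[1L]]
  hit <- stats::runif(length(ch)) < rate
  if (any(hit)) {
    K <- length(letters_)
    idx <- match(ch[hit], letters_)
    shift <- sample.int(K - 1L, sum(hit), replace = TRUE)
    ch[hit] <- letters_[((idx - 1L + shift) %% K) + 1L]
  }
  paste(ch, collapse = "")
}

#' Generate a synthetic protein family
#'
#' Draws a random consensus protein and `n_refs` reference descendants
#' by i.i.d. substitution at the given divergence rate (no indels, so
#' the true alignment is the trivial one).  Deterministic per seed.
#'
#' @param family_name Family label.
#' @param consensus_length Consensus length in amino acids (>= 30).
#' @param n_refs Number of reference sequences.
#' @param divergence Per-position substitution rate in \[0, 0.5\].
#' @param seed RNG seed.
#' @return List of class `synthetic_family`: `family_name`, `consensus`,
#'   `refs` (protein records), `alignment` (aligned records, identical
#'   to the sequences).
#' @export
make_family <- function(family_name, consensus_length = 150, n_refs = 60,
                        divergence = 0.15, seed = 1L) {
  stopifnot(consensus_length >= 30, divergence >= 0, divergence <= 0.5,
            n_refs >= 1)
  letters_ <- aa_letters()
  with_seed(seed, {
    consensus <- random_protein(consensus_length, letters_)
    refs <- vapply(seq_len(n_refs), function(i) {
      mutate_protein(consensus, divergence, letters_)
    }, character(1))
    ids <- sprintf("%s_ref%03d", family_name, seq_len(n_refs))
    structure(list(
      family_name = family_name,
      consensus = consensus,
      refs = data.frame(id = ids, sequence = refs, description = "",
                        stringsAsFactors = FALSE),
      alignment = data.frame(id = ids, aligned_sequence = refs,
                             stringsAsFactors = FALSE),
      divergence = divergence, seed = seed
    ), class = "synthetic_family")
  })
}

#' Simulate a community of genomes with planted gene carriage
#'
#' Each genome carries every housekeeping family in exactly one copy;
#' each target family is carried independently with its planted
#' carriage probability (one copy when carried — the copy-number-one
#' assumption is the simulator's ground truth).  Carried sequences are
#' diverged copies of the family consensus.
#'
#' @param families List of `synthetic_family` objects (targets and the
#'   five housekeeping families).
#' @param carriage Named per-family carriage fractions for the target
#'   families; families not named are treated as housekeeping and
#'   always carried.
#' @param n_genomes Number of genomes (>= 10).
#' @param divergence Substitution rate of carried copies from the family
#'   consensus.
#' @param seed RNG seed.
#' @param lineage_pool Data frame as [default_lineage_pool()].
#' @return Object of class `synthetic_community`: `genomes` (data frame
#'   `genome_id`, `lineage`), `membership` (logical genome x family
#'   matrix), `proteins` (data frame `genome_id`, `family`, `id`,
#'   `sequence`), `carriage` (planted), `realized` (realized carriage
#'   fractions), `seed`.
#' @export
simulate_community <- function(families, carriage, n_genomes = 500,
                               divergence = 0.15, seed = 1L,
                               lineage_pool = default_lineage_pool()) {
  stopifnot(n_genomes >= 10)
  fam_names <- vapply(families, `[[`, character(1), "family_name")
  stopifnot(all(names(carriage) %in% fam_names),
            all(carriage >= 0), all(carriage <= 1))
  letters_ <- aa_letters()
  with_seed(seed, {
    genome_ids <- sprintf("g%04d", seq_len(n_genomes))
    lineages <- sample(lineage_pool$lineage, n_genomes, replace = TRUE,
                       prob = lineage_pool$weight)
    membership <- matrix(FALSE, nrow = n_genomes, ncol = length(fam_names),
                         dimnames = list(genome_ids, fam_names))
    rows <- vector("list", length(fam_names))
    for (j in seq_along(families)) {
      fam <- fam_names[[j]]
      p <- if (fam %in% names(carriage)) carriage[[fam]] else 1
      carried <- stats::runif(n_genomes) < p
      membership[, j] <- carried
      if (!any(carried)) next
      seqs <- vapply(which(carried), function(i) {
        mutate_protein(families[[j]]$consensus, divergence, letters_)
      }, character(1))
      rows[[j]] <- data.frame(
        genome_id = genome_ids[carried], family = fam,
        id = paste0(genome_ids[carried], "_", fam),
        sequence = seqs, stringsAsFactors = FALSE
      )
    }
    proteins <- do.call(rbind, rows[!vapply(rows, is.null, logical(1))])
    structure(list(
      genomes = data.frame(genome_id = genome_ids, lineage = lineages,
                           stringsAsFactors = FALSE),
      membership = membership,
      proteins = proteins,
      carriage = carriage,
      realized = colMeans(membership),
      divergence = divergence,
      seed = seed
    ), class = "synthetic_community")
  })
}

# reshape a community into the per-genome list census_genomes() consumes;
# taxon = phylum (second lineage rank)
community_genomes <- function(community) {
  phy <- vapply(strsplit(community$genomes$lineage, ";", fixed = TRUE),
                `[[`, character(1), 2L)
  lapply(seq_len(nrow(community$genomes)), function(i) {
    gid <- community$genomes$genome_id[[i]]
    pr <- community$proteins[community$proteins$genome_id == gid, , drop = FALSE]
    list(genome_id = gid, taxon = phy[[i]],
         proteins = pr[, c("id", "sequence"), drop = FALSE])
  })
}

#' Fragment a community's proteins into read-derived CDS
#'
#' Emulates predicted-CDS calls from short reads: each protein yields a
#' Poisson(`coverage`) number of fragments with geometric-tailed lengths
#' (mean `fragment_length_mean`) clipped to `[min_length, protein
#' length]` and uniform start positions.  Unrelated background proteins
#' (i.i.d. residues, lengths from the same fragment distribution) are
#' appended.
#'
#' @param community A `synthetic_community`.
#' @param fragment_length_mean Mean fragment length in amino acids.
#' @param min_length Minimum fragment length (>= 10).
#' @param coverage Expected fragments per protein (> 0).
#' @param n_background Number of background proteins to append.
#' @param seed RNG seed.
#' @param id_prefix Prefix for fragment ids.
#' @return Data frame of protein records (`id`, `sequence`,
#'   `description`); descriptions carry the source family
#'   (`source=<family>` or `source=background`).
#' @export
fragment_cds <- function(community, fragment_length_mean = 45,
                         min_length = 30, coverage = 2,
                         n_background = 500, seed = 1L, id_prefix = "cds") {
  stopifnot(coverage > 0, min_length >= 10,
            fragment_length_mean >= min_length)
  letters_ <- aa_letters()
  pr <- community$proteins
  with_seed(seed, {
    nfrag <- stats::rpois(nrow(pr), coverage)
    total <- sum(nfrag)
    ids <- character(total); seqs <- character(total); src <- character(total)
    gmean <- fragment_length_mean - min_length  # geometric tail above the minimum
    pgeom_ <- 1 / (gmean + 1)
    k <- 0L
    for (i in seq_len(nrow(pr))) {
      if (nfrag[[i]] == 0L) next
      plen <- nchar(pr$sequence[[i]])
      lens <- pmin(min_length + stats::rgeom(nfrag[[i]], pgeom_), plen)
      starts <- floor(stats::runif(nfrag[[i]]) * (plen - lens + 1)) + 1L
      for (f in seq_len(nfrag[[i]])) {
        k <- k + 1L
        ids[[k]] <- sprintf("%s_%s_%d", id_prefix, pr$id[[i]], f)
        seqs[[k]] <- substr(pr$sequence[[i]], starts[[f]], starts[[f]] + lens[[f]] - 1L)
        src[[k]] <- pr$family[[i]]
      }
    }
    out <- data.frame(id = ids[seq_len(k)], sequence = seqs[seq_len(k)],
                      description = paste0("source=", src[seq_len(k)]),
                      stringsAsFactors = FALSE)
    if (n_background > 0L) {
      blens <- min_length + stats::rgeom(n_background, pgeom_)
      bg <- data.frame(
        id = sprintf("%s_bg%05d", id_prefix, seq_len(n_background)),
        sequence = vapply(blens, random_protein, character(1), letters_ = letters_),
        description = "source=background",
        stringsAsFactors = FALSE
      )
      out <- rbind(out, bg)
    }
    out
  })
}

#' Two-group study design for the synthetic generator
#'
#' Defaults mirror the 8-site soil survey contrast: four low-pH and four
#' high-pH sites; the three alkaline phosphatases planted with strong
#' group effects (high-pH carriage 0.47/0.56/0.20 for PhoX/PhoD/PhoA
#' versus 0.03/0.07/0.01 in low-pH sites) and the three nonspecific acid
#' phosphatase classes planted equal across groups.
#'
#' @param n_per_group Sites per group.
#' @param carriage_high,carriage_low Named per-family carriage fractions
#'   for the target families.
#' @param n_genomes Genomes per site.
#' @param divergence Substitution rate (references and community copies).
#' @param consensus_length Family consensus length in amino acids (one
#'   length for all families; see the methods vignette).
#' @param n_refs Reference sequences per family.
#' @param fragment_length_mean,min_length,coverage,n_background
#'   Fragmentation parameters (see [fragment_cds()]).
#' @param threshold Acceptance threshold written into the run config.
#' @return List of class `site_design`.
#' @export
study_design <- function(n_per_group = 4,
                         carriage_high = c(PhoX = 0.47, PhoD = 0.56, PhoA = 0.20,
                                           ClassA = 0.15, ClassB = 0.12, ClassC = 0.10),
                         carriage_low = c(PhoX = 0.03, PhoD = 0.07, PhoA = 0.01,
                                          ClassA = 0.15, ClassB = 0.12, ClassC = 0.10),
                         n_genomes = 500, divergence = 0.15,
                         consensus_length = 150, n_refs = 60,
                         fragment_length_mean = 45, min_length = 30,
                         coverage = 2, n_background = 500,
                         threshold = 25) {
  stopifnot(identical(sort(names(carriage_high)), sort(names(carriage_low))),
            all(carriage_high >= 0 & carriage_high <= 1),
            all(carriage_low >= 0 & carriage_low <= 1),
            min_length >= 10)
  structure(list(
    n_per_group = n_per_group,
    carriage_high = carriage_high, carriage_low = carriage_low,
    n_genomes = n_genomes, divergence = divergence,
    consensus_length = consensus_length, n_refs = n_refs,
    fragment_length_mean = fragment_length_mean, min_length = min_length,
    coverage = coverage, n_background = n_background,
    threshold = threshold
  ), class = "site_design")
}

#' Generate a complete synthetic study on disk
#'
#' Builds the target and housekeeping families, simulates one community
#' per site under the per-group planted carriage, fragments each into a
#' CDS FASTA, and writes everything a pipeline run needs: family
#' reference FASTAs, per-site CDS FASTAs, a lineage-labeled reference DB
#' (`refdb.fasta`, synthetic lineages), a YAML run config, and a
#' ground-truth table (planted and realized carriage per site and
#' family).  Byte-identical output for identical (design, seed).
#'
#' @param design A [study_design()].
#' @param seed Master seed.
#' @param out_dir Output directory (created if needed).
#' @return List with `config` (a `run_config`), `config_path`,
#'   `truth_path`, `truth` (data frame), `families`, and `communities`.
#' @export
make_study <- function(design = study_design(), seed = 1L,
                       out_dir = tempfile("phoscreen_study")) {
  stopifnot(inherits(design, "site_design"))
  dir.create(file.path(out_dir, "families"), recursive = TRUE, showWarnings = FALSE)
  dir.create(file.path(out_dir, "sites"), showWarnings = FALSE)

  target_names <- names(design$carriage_high)
  fam_names <- c(target_names, HOUSEKEEPING_FAMILIES)
  n_sites <- 2L * design$n_per_group
  seeds <- derive_seeds(seed, length(fam_names) + n_sites + 1L)

  families <- list()
  for (i in seq_along(fam_names)) {
    families[[fam_names[[i]]]] <- make_family(
      fam_names[[i]], design$consensus_length, design$n_refs,
      design$divergence, seeds[[i]]
    )
  }
  fam_paths <- character(length(fam_names))
  for (i in seq_along(fam_names)) {
    fam_paths[[i]] <- file.path(out_dir, "families",
                                paste0(fam_names[[i]], ".fasta"))
    write_fasta(families[[fam_names[[i]]]]$refs, fam_paths[[i]])
  }

  # lineage-labeled reference DB from the family references
  pool <- default_lineage_pool()
  refdb_path <- file.path(out_dir, "refdb.fasta")
  refdb <- with_seed(seeds[[length(fam_names) + n_sites + 1L]], {
    do.call(rbind, lapply(families, function(fam) {
      r <- fam$refs
      r$description <- paste0("family=", fam$family_name, " lineage=",
                              sample(pool$lineage, nrow(r), replace = TRUE,
                                     prob = pool$weight))
      r
    }))
  })
  write_fasta(refdb, refdb_path)

  site_ids <- c(paste0("L", seq_len(design$n_per_group)),
                paste0("H", seq_len(design$n_per_group)))
  groups <- rep(c("low_pH", "high_pH"), each = design$n_per_group)
  site_paths <- character(n_sites)
  truth_rows <- list()
  communities <- list()
  for (s in seq_len(n_sites)) {
    carr <- if (groups[[s]] == "low_pH") design$carriage_low else design$carriage_high
    sseed <- seeds[[length(fam_names) + s]]
    comm <- simulate_community(families, carr, design$n_genomes,
                               design$divergence, sseed)
    cds <- fragment_cds(comm, design$fragment_length_mean, design$min_length,
                        design$coverage, design$n_background,
                        seed = sseed + 1L, id_prefix = site_ids[[s]])
    site_paths[[s]] <- file.path(out_dir, "sites", paste0(site_ids[[s]], ".fasta"))
    write_fasta(cds, site_paths[[s]])
    communities[[site_ids[[s]]]] <- comm
    truth_rows[[s]] <- data.frame(
      site_id = site_ids[[s]], group = groups[[s]], family = target_names,
      true_carriage = unname(carr[target_names]),
      realized_carriage = unname(comm$realized[target_names]),
      stringsAsFactors = FALSE
    )
  }
  truth <- do.call(rbind, truth_rows)
  truth_path <- file.path(out_dir, "truth.tsv")
  write_table(truth, truth_path)

  cfg <- run_config(
    families = data.frame(
      name = fam_names, path = fam_paths,
      role = c(rep("target", length(target_names)),
               rep("housekeeping", length(HOUSEKEEPING_FAMILIES))),
      stringsAsFactors = FALSE
    ),
    sites = data.frame(site_id = site_ids, group = groups,
                       paths = I(as.list(site_paths)),
                       stringsAsFactors = FALSE),
    threshold = design$threshold,
    seed = seed,
    refdb = refdb_path,
    taxonomy_families = intersect(c("PhoX", "PhoD", "PhoA"), target_names)
  )
  config_path <- file.path(out_dir, "config.yaml")
  write_run_config(cfg, config_path, relative_to = out_dir)

  list(config = cfg, config_path = config_path, truth_path = truth_path,
       truth = truth, families = families, communities = communities,
       out_dir = out_dir)
}
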