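# minimal hand-built fixtures for the normalization chain
fake_hit_table <- function(site_id, counts) {
  structure(list(
    site_id = site_id,
    hits = data.frame(),
    counts = data.frame(family = names(counts), n = unname(counts),
                        stringsAsFactors = FALSE)
  ), class = "hit_table")
}

fake_profile <- function(name, ref_len) {
  aln <- data.frame(id = "a", aligned_sequence = rand_protein(ref_len))
  p <- build_profile(aln, family_name = name)
  stopifnot(p$reference_length == ref_len)
  p
}

fake_config <- function(targets = "PhoX", copy_number = 1, ...) {
  fam <- data.frame(
    name = c(targets, HOUSEKEEPING_FAMILIES()),
    path = "x.fasta",
    role = c(rep("target", length(targets)), rep("housekeeping", 5)),
    stringsAsFactors = FALSE
  )
  sites <- data.frame(site_id = c("s1", "s2", "s3", "s4"),
                      group = c("low_pH", "low_pH", "high_pH", "high_pH"),
                      path = "y.fasta", stringsAsFactors = FALSE)
  run_config(fam, sites, copy_number = copy_number, ...)
}

HOUSEKEEPING_FAMILIES <- function() c("RecA", "RpoB", "AtpB", "GyrB", "SucD")

test_that("length normalization follows the RecA ratio", {
  expect_equal(normalize_count(100, L_f = 700, L_recA = 350), 50)
  expect_equal(normalize_count(100, L_f = 350, L_recA = 350), 100)
  expect_equal(normalize_count(0, L_f = 123, L_recA = 350), 0)
  expect_equal(normalize_count(100, 700, 350, direction = "length_weighted"), 200)
  expect_error(normalize_count(10, 0, 350), "lengths")
})

test_that("genome equivalents average the five housekeeping genes", {
  hk <- c(RecA = 10, RpoB = 10, AtpB = 10, GyrB = 10, SucD = 10)
  expect_equal(genome_equivalents(hk), 10)
  expect_equal(genome_equivalents(c(RecA = 8, RpoB = 9, AtpB = 10,
                                    GyrB = 11, SucD = 12)), 10)
  expect_error(genome_equivalents(hk[-2]), "RpoB")
  expect_warning(g0 <- genome_equivalents(hk * 0), "undefined")
  expect_equal(g0, 0)
})

test_that("gene frequency scales with counts, G, and copy number", {
  fr <- gene_frequency(4.7, 10, 1)
  expect_equal(fr$percent, 47)
  expect_false(fr$flagged)
  expect_equal(gene_frequency(0, 10)$percent, 0)
  expect_equal(gene_frequency(12, 10, copy_number = 2)$percent, 60)
  over <- gene_frequency(15, 10, 1)
  expect_true(over$flagged)
  expect_equal(over$percent, 150)
  expect_error(gene_frequency(1, 0), "genome equivalent")
})

test_that("quantify_sites composes the chain (identity and length cases)", {
  cfg <- fake_config()
  profs <- lapply(c(PhoX = 350, RecA = 350, RpoB = 350, AtpB = 350,
                    GyrB = 350, SucD = 350),
                  function(l) NULL)
  set.seed(12)
  profs <- mapply(fake_profile, names(profs),
                  c(350, 350, 350, 350, 350, 350), SIMPLIFY = FALSE)
  counts <- c(PhoX = 5, RecA = 10, RpoB = 10, AtpB = 10, GyrB = 10, SucD = 10)
  hts <- lapply(c("s1", "s2", "s3", "s4"), fake_hit_table, counts = counts)
  ab <- quantify_sites(hts, profs, cfg)
  phox <- ab[ab$family == "PhoX", ]
  expect_equal(phox$percent, rep(50, 4))
  expect_equal(phox$normalized_count, phox$raw_count)  # equal lengths

  # PhoX twice the RecA length -> frequency halves
  set.seed(13)
  profs2 <- mapply(fake_profile, names(counts),
                   c(700, 350, 350, 350, 350, 350), SIMPLIFY = FALSE)
  ab2 <- quantify_sites(hts, profs2, cfg)
  expect_equal(ab2$percent[ab2$family == "PhoX"], rep(25, 4))
})

test_that("frequencies are invariant to scaling all counts at a site", {
  cfg <- fake_config()
  set.seed(14)
  profs <- mapply(fake_profile,
                  c("PhoX", "RecA", "RpoB", "AtpB", "GyrB", "SucD"),
                  c(420, 350, 350, 500, 350, 350), SIMPLIFY = FALSE)
  counts <- c(PhoX = 6, RecA = 11, RpoB = 9, AtpB = 14, GyrB = 10, SucD = 8)
  for (k in c(2, 5)) {
    hts1 <- lapply(c("s1", "s2", "s3", "s4"), fake_hit_table, counts = counts)
    htsk <- lapply(c("s1", "s2", "s3", "s4"), fake_hit_table, counts = k * counts)
    ab1 <- quantify_sites(hts1, profs, cfg)
    abk <- quantify_sites(htsk, profs, cfg)
    expect_equal(abk$normalized_count, k * ab1$normalized_count, tolerance = 1e-12)
    expect_equal(abk$genome_equivalents, k * ab1$genome_equivalents, tolerance = 1e-12)
    expect_equal(abk$frequency, ab1$frequency, tolerance = 1e-12)
  }
})

test_that("frequency is monotone in counts and antitone in G and copy number", {
  f1 <- gene_frequency(5, 10, 1)$fraction
  expect_gt(gene_frequency(6, 10, 1)$fraction, f1)
  expect_lt(gene_frequency(5, 12, 1)$fraction, f1)
  expect_lt(gene_frequency(5, 10, 2)$fraction, f1)
})

test_that("the genome census counts carriers of at least one APase once", {
  fams <- list(
    PhoX = make_family("PhoX", consensus_length = 60, n_refs = 10, seed = 61),
    PhoD = make_family("PhoD", consensus_length = 60, n_refs = 10, seed = 62)
  )
  profs <- lapply(fams, function(f) build_profile(f$alignment, family_name = f$family_name))
  mk_genome <- function(id, taxon, seqs) {
    list(genome_id = id, taxon = taxon,
         proteins = data.frame(id = paste0(id, "_p", seq_along(seqs)),
                               sequence = seqs, stringsAsFactors = FALSE))
  }
  set.seed(63)
  noise <- rand_protein(60)
  g1 <- mk_genome("g1", "Proteobacteria", c(fams$PhoX$consensus, noise))
  g2 <- mk_genome("g2", "Proteobacteria", noise)
  res <- census_genomes(list(g1, g2), profs, threshold = 25)
  expect_equal(res$taxa$fraction, 0.5)

  # carrying both families still counts once
  g3 <- mk_genome("g3", "Proteobacteria",
                  c(fams$PhoX$consensus, fams$PhoD$consensus))
  g4 <- mk_genome("g4", "Proteobacteria", fams$PhoD$consensus)
  res2 <- census_genomes(list(g1, g2, g3, g4), profs, threshold = 25)
  expect_equal(res2$taxa$n_with_apase, 3)
  expect_equal(res2$taxa$n_total, 4)
  expect_equal(res2$taxa$fraction, 0.75)
  expect_true(res2$genomes$PhoX[res2$genomes$genome_id == "g3"])
  expect_true(res2$genomes$PhoD[res2$genomes$genome_id == "g3"])
})
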