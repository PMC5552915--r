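test_that("pairwise identity handles exact and near matches", {
  expect_equal(pairwise_align("MKVL", "MKVL")$percent_identity, 100)
  expect_equal(pairwise_align("MKVL", "MKIL")$percent_identity, 75)
  # the alignment score is symmetric for any pair; identity is symmetric
  # whenever the optimal alignment is unique (homologous pairs), though
  # co-optimal tracebacks on unrelated pairs may differ
  set.seed(90)
  letters20 <- strsplit("ACDEFGHIKLMNPQRSTVWY", "")[[1]]
  for (rep in 1:5) {
    a <- rand_protein(20); b <- rand_protein(25)
    expect_equal(pairwise_align(a, b)$score, pairwise_align(b, a)$score,
                 tolerance = 1e-9)
    hom <- strsplit(a, "")[[1]]
    i <- sample(20, 3)
    hom[i] <- vapply(hom[i], function(x) sample(setdiff(letters20, x), 1),
                     character(1))
    hom <- paste(hom, collapse = "")
    expect_equal(pairwise_align(a, hom)$percent_identity,
                 pairwise_align(hom, a)$percent_identity, tolerance = 1e-9)
  }
})

test_that("alignment scores equal a brute-force Smith-Waterman DP", {
  b62 <- getFromNamespace("blosum62", "phoscreen")()
  set.seed(91)
  for (rep in 1:15) {
    a <- rand_protein(sample(4:12, 1))
    b <- rand_protein(sample(4:12, 1))
    expect_equal(pairwise_align(a, b)$score, oracle_sw(a, b, b62),
                 tolerance = 1e-9)
  }
  # a pair that forces a gap
  a <- "MKVLWAAD"; b <- "MKVLAAD"
  expect_equal(pairwise_align(a, b)$score, oracle_sw(a, b, b62),
               tolerance = 1e-9)
})

test_that("lineage parsing extracts ranks and names offending records", {
  expect_equal(parse_lineage("family=PhoX lineage=Bacteria;Proteobacteria", "r1"),
               c("Bacteria", "Proteobacteria"))
  expect_error(parse_lineage("no tag here", "r9"), "r9")
})

test_that("hits are assigned to the best reference with documented tie-breaks", {
  refdb <- data.frame(
    id = c("ref1", "ref2"),
    sequence = c("MKVLWDESTAKLYP", "MKVLWDESTAKLYG"),
    description = c("lineage=Bacteria;Proteobacteria;Gamma",
                    "lineage=Bacteria;Actinobacteria;Actino"),
    stringsAsFactors = FALSE
  )
  hits <- data.frame(cds_id = "h1", family = "PhoX",
                     sequence = "MKVLWDESTAKLYP", stringsAsFactors = FALSE)
  asn <- assign_hits(hits, refdb, min_score = 10)
  expect_equal(asn$best_ref_id, "ref1")
  expect_equal(asn$percent_identity, 100)
  expect_equal(asn$lineage, "Bacteria;Proteobacteria;Gamma")

  # below min_score everywhere -> unassigned
  weak <- data.frame(cds_id = "h2", family = "PhoX", sequence = "GGGGG",
                     stringsAsFactors = FALSE)
  asn2 <- assign_hits(weak, refdb, min_score = 50)
  expect_true(is.na(asn2$best_ref_id))
  expect_true(is.na(asn2$lineage))

  # equal scores, tie broken by identity: query differs from ref1 only at a
  # position where the substitution scores like the ref2 mismatch does
  refdb3 <- data.frame(
    id = c("refA", "refB"),
    sequence = c("MKVLW", "MKVLW"),
    description = c("lineage=Bacteria;P1", "lineage=Bacteria;P2"),
    stringsAsFactors = FALSE
  )
  h <- data.frame(cds_id = "h3", family = "PhoX", sequence = "MKVLW",
                  stringsAsFactors = FALSE)
  asn3 <- assign_hits(h, refdb3, min_score = 10)
  expect_equal(asn3$best_ref_id, "refA")  # identity ties -> lexicographic id
})

test_that("mean identity averages assigned hits only", {
  asn <- data.frame(percent_identity = c(60, 70, 80, NA))
  expect_equal(mean_identity(asn), 70)
  expect_equal(mean_identity(data.frame(percent_identity = 100)), 100)
  expect_error(mean_identity(data.frame(percent_identity = NA_real_)),
               "no assigned hits")
})

test_that("rank aggregation conserves counts and truncates at depth", {
  asn <- data.frame(lineage = c("Bacteria;Proteobacteria",
                                "Bacteria;Proteobacteria",
                                "Bacteria;Actinobacteria"),
                    percent_identity = 99, stringsAsFactors = FALSE)
  h <- aggregate_ranks(asn)
  expect_equal(h$total, 3L)
  expect_equal(sum(h$leaves$count), 3L)
  cnt <- rank_counts(h, 2)
  expect_equal(unname(cnt[order(names(cnt))]), c(1L, 2L))

  h1 <- aggregate_ranks(asn, depth = 1)
  expect_equal(h1$leaves$lineage, "Bacteria")
  expect_equal(h1$leaves$count, 3L)
})

test_that("top-phylum fractions agree whether computed from the tree or the list", {
  set.seed(95)
  pool <- default_lineage_pool()
  lin <- sample(pool$lineage, 200, replace = TRUE, prob = pool$weight)
  asn <- data.frame(lineage = lin, stringsAsFactors = FALSE)
  h <- aggregate_ranks(asn)
  phyla <- rank_counts(h, 2)
  top3_tree <- sum(sort(phyla, decreasing = TRUE)[1:3]) / h$total
  phy_list <- vapply(strsplit(lin, ";"), function(r) paste(r[1:2], collapse = ";"),
                     character(1))
  top3_list <- sum(sort(table(phy_list), decreasing = TRUE)[1:3]) / length(lin)
  expect_equal(top3_tree, unname(top3_list), tolerance = 1e-12)
})

test_that("Krona text preserves counts, sorting and the tab layout", {
  asn <- data.frame(lineage = c("Bacteria;Proteobacteria",
                                "Bacteria;Proteobacteria",
                                "Bacteria;Actinobacteria"),
                    stringsAsFactors = FALSE)
  h <- aggregate_ranks(asn)
  f <- withr::local_tempfile(fileext = ".txt")
  write_krona_text(h, f)
  expect_equal(readLines(f), c("1\tBacteria\tActinobacteria",
                               "2\tBacteria\tProteobacteria"))

  write_krona_text(NULL, f)
  expect_length(readLines(f), 0L)

  # count conservation on fuzzed hierarchies
  set.seed(96)
  pool <- default_lineage_pool()
  for (rep in 1:5) {
    n <- sample(10:300, 1)
    lin <- sample(pool$lineage, n, replace = TRUE, prob = pool$weight)
    hh <- aggregate_ranks(data.frame(lineage = lin), depth = sample(1:3, 1))
    write_krona_text(hh, f)
    lead <- as.integer(sub("\t.*", "", readLines(f)))
    expect_equal(sum(lead), n)
    for (lev in 1:2) {
      rc <- rank_counts(hh, lev)
      if (length(rc)) expect_lte(sum(rc), n)
      if (lev == 1) expect_equal(sum(rc), n)  # every lineage starts at domain
    }
  }
})

test_that("hits diverged 30% from their reference average about 70% identity", {
  fam <- make_family("PhoX", consensus_length = 150, n_refs = 20,
                     divergence = 0.15, seed = 97)
  refdb <- fam$refs
  refdb$description <- "lineage=Bacteria;Proteobacteria"
  letters20 <- strsplit("ACDEFGHIKLMNPQRSTVWY", "")[[1]]
  set.seed(98)
  mut30 <- function(s) {
    ch <- strsplit(s, "")[[1]]
    hit <- runif(length(ch)) < 0.3
    ch[hit] <- vapply(ch[hit], function(x)
      sample(setdiff(letters20, x), 1), character(1))
    paste(ch, collapse = "")
  }
  src <- sample(nrow(refdb), 15, replace = TRUE)
  hits <- data.frame(cds_id = paste0("h", 1:15), family = "PhoX",
                     sequence = vapply(refdb$sequence[src], mut30, character(1)),
                     stringsAsFactors = FALSE)
  refdb$family <- "PhoX"
  asn <- assign_hits(hits, refdb, min_score = 50)
  expect_true(all(!is.na(asn$percent_identity)))
  expect_lt(abs(mean_identity(asn) - 70), 5)
})
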