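test_that("global score of a one-state profile is the closed-form log odds", {
  aln <- data.frame(id = c("a", "b"), aligned_sequence = c("A", "A"))
  p <- build_profile(aln, pseudocount = 0.3)
  emA <- p$match_emissions[1, "A"]
  expect_equal(forward_bits(p, "A", mode = "global"), unname(log2(emA / 0.05)),
               tolerance = 1e-12)
  # one path: forward equals viterbi exactly
  expect_equal(viterbi_bits(p, "A", mode = "global"),
               forward_bits(p, "A", mode = "global"), tolerance = 1e-12)
})

test_that("forward and Viterbi agree with path enumeration on small cases", {
  set.seed(17)
  for (L in c(1, 3)) {
    prof <- build_profile(abc_test_alignment(L), alphabet = "ABC",
                          pseudocount = 0.7)
    seqs <- c("A", "BC", "CAB", "ABCA", "XAX")
    for (mode in c("local", "global")) {
      eng <- score_sequences(prof, seqs, mode = mode, flank_loop = 0.9)
      for (i in seq_along(seqs)) {
        orc <- oracle_score(prof, seqs[i], mode, eta = 0.9)
        expect_equal(eng$forward_bits[i], orc$forward_bits, tolerance = 1e-9)
        expect_equal(eng$viterbi_bits[i], orc$viterbi_bits, tolerance = 1e-9)
      }
    }
  }
})

test_that("an all-X sequence scores finite through the wildcard emissions", {
  p <- build_profile(data.frame(id = "a", aligned_sequence = "MKVLW"))
  b <- forward_bits(p, "XXXX")
  expect_true(is.finite(b))
  expect_true(is.finite(viterbi_bits(p, "XXXX")))
})

test_that("forward dominates Viterbi for random profiles and sequences", {
  set.seed(23)
  for (rep in 1:10) {
    fam <- make_family("f", consensus_length = 40, n_refs = 6,
                       divergence = 0.25, seed = rep)
    p <- build_profile(fam$alignment)
    seqs <- vapply(sample(10:60, 8, TRUE), rand_protein, character(1))
    sc <- score_sequences(p, seqs)
    expect_true(all(sc$forward_bits >= sc$viterbi_bits - 1e-6))
  }
})

test_that("empty sequences are rejected", {
  p <- build_profile(data.frame(id = "a", aligned_sequence = "MKV"))
  expect_error(forward_bits(p, ""), "empty sequence")
})

test_that("search_site counts planted homologs and ignores background", {
  fam <- make_family("PhoX", consensus_length = 120, n_refs = 30,
                     divergence = 0.15, seed = 31)
  prof <- build_profile(fam$alignment, family_name = "PhoX")
  set.seed(32)
  letters20 <- strsplit("ACDEFGHIKLMNPQRSTVWY", "")[[1]]
  mutate15 <- function(s) {
    ch <- strsplit(s, "")[[1]]
    mut <- runif(length(ch)) < 0.15
    ch[mut] <- vapply(ch[mut], function(x) sample(setdiff(letters20, x), 1),
                      character(1))
    paste(ch, collapse = "")
  }
  planted <- vapply(1:3, function(i) {
    substr(mutate15(fam$consensus), 20, 89)  # 70 aa fragment of a diverged homolog
  }, character(1))
  background <- vapply(rep(70, 100), rand_protein, character(1))
  cds <- data.frame(id = paste0("c", 1:103),
                    sequence = c(planted, background),
                    description = "", stringsAsFactors = FALSE)
  ht <- search_site(list(prof), cds, threshold = 25, site_id = "s1")
  expect_equal(ht$counts$n, 3L)
  expect_setequal(ht$hits$cds_id, c("c1", "c2", "c3"))
  expect_true(all(ht$hits$bit_score >= ht$hits$viterbi_bits - 1e-6))

  # permutation invariance of the counts
  ht2 <- search_site(list(prof), cds[sample(nrow(cds)), ], threshold = 25,
                     site_id = "s1")
  expect_equal(ht2$counts, ht$counts)

  # degenerate inputs
  empty <- search_site(list(prof), cds[0, ], threshold = 25, site_id = "s1")
  expect_equal(empty$counts$n, 0L)
  inf <- search_site(list(prof), cds, threshold = Inf, site_id = "s1")
  expect_equal(inf$counts$n, 0L)
})

test_that("the consensus outscores length-matched shuffled sequences", {
  fam <- make_family("f", consensus_length = 80, n_refs = 20,
                     divergence = 0.2, seed = 77)
  p <- build_profile(fam$alignment)
  cons <- forward_bits(p, fam$consensus)
  set.seed(78)
  shuffled <- vapply(1:25, function(i) {
    paste(sample(strsplit(fam$consensus, "")[[1]]), collapse = "")
  }, character(1))
  med <- median(score_sequences(p, shuffled)$forward_bits)
  expect_gt(cons, med)
})

test_that("decoy false-hit rates behave at the threshold extremes", {
  fam <- make_family("f", consensus_length = 50, n_refs = 10, seed = 55)
  p <- build_profile(fam$alignment)
  cds <- data.frame(id = paste0("c", 1:30),
                    sequence = vapply(rep(45, 30), rand_protein, character(1)),
                    stringsAsFactors = FALSE)
  expect_equal(decoy_fdr(p, cds, -Inf, seed = 1), 1.0)
  expect_equal(decoy_fdr(p, cds, Inf, seed = 1), 0.0)

  # recompute decoy scores directly: a cutoff above the max decoy -> 0
  decoys <- with(cds, {
    set.seed(1)  # same seed convention as decoy_fdr
    vapply(sequence, function(s)
      paste(sample(strsplit(s, "")[[1]]), collapse = ""), character(1))
  })
  mx <- max(score_sequences(p, decoys)$forward_bits)
  expect_equal(decoy_fdr(p, cds, mx + 1e-6, seed = 1), 0.0)
  expect_gt(decoy_fdr(p, cds, mx - 1e-6, seed = 1), 0.0)
})

test_that("an external scoring engine yields the identical hit table schema", {
  fam <- make_family("PhoX", consensus_length = 60, n_refs = 10, seed = 91)
  prof <- build_profile(fam$alignment, family_name = "PhoX")
  set.seed(92)
  cds <- data.frame(
    id = paste0("c", 1:20),
    sequence = c(vapply(1:4, function(i) {
      ch <- strsplit(fam$consensus, "")[[1]]
      mut <- runif(60) < 0.1
      ch[mut] <- sample(strsplit("ACDEFGHIKLMNPQRSTVWY", "")[[1]], sum(mut), TRUE)
      substr(paste(ch, collapse = ""), 10, 55)
    }, character(1)),
      vapply(rep(46, 16), rand_protein, character(1))),
    stringsAsFactors = FALSE
  )
  native <- search_site(list(prof), cds, threshold = 25, site_id = "s")
  engine <- function(profile, cds) {
    sc <- score_sequences(profile, cds$sequence)
    data.frame(cds_id = cds$id, bit_score = sc$forward_bits,
               viterbi_bits = sc$viterbi_bits, stringsAsFactors = FALSE)
  }
  adapted <- search_site_engine(engine, list(prof), cds, threshold = 25,
                                site_id = "s")
  expect_s3_class(adapted, "hit_table")
  expect_identical(names(adapted$hits), names(native$hits))
  expect_equal(adapted$counts, native$counts)
  expect_equal(adapted$hits$bit_score, native$hits$bit_score)
})
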