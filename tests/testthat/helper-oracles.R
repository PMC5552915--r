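# Independent oracles used by the tests.  These deliberately avoid the
# package's DP code paths: scores come from explicit path enumeration /
# plain matrix DP, p-values from the closed-form statistic plus the t CDF.

# Exhaustive path-enumeration score for the profile HMM architecture:
# N flank (self-loop eta) -> uniform entry over match states -> M/I/D core
# with geometric exit eps_k = 1/(L-k+1) -> C flank.  Sums (forward) or
# maximizes (viterbi) over every explicit state path.
oracle_score <- function(profile, seq, mode = "local", eta = 0.95) {
  letters_ <- strsplit(profile$alphabet, "")[[1]]
  K <- length(letters_)
  ch <- strsplit(seq, "")[[1]]
  x <- match(ch, letters_)
  x[ch == "X"] <- K + 1L
  stopifnot(!anyNA(x))
  n <- length(x)
  L <- profile$L
  mo <- sweep(profile$match_emissions, 2, profile$background, "/")
  io <- sweep(profile$insert_emissions[1 + seq_len(L), , drop = FALSE],
              2, profile$background, "/")
  em <- function(k, i) if (x[i] > K) 1 else mo[k, x[i]]
  iem <- function(k, i) if (x[i] > K) 1 else io[k, x[i]]
  tr <- profile$transitions
  local <- mode == "local"
  eps <- if (local) 1 / (L - seq_len(L) + 1) else c(rep(0, L - 1), 1)
  aMM <- (1 - eps) * tr$tMM
  aMI <- (1 - eps) * tr$tMI
  aMD <- (1 - eps) * tr$tMD
  fromM <- function(k, i) {
    out <- numeric(0)
    if (local) out <- c(out, eps[k] * eta^(n - i) * (1 - eta))
    else if (k == L && i == n) out <- c(out, 1)
    if (k < L) {
      if (i < n) out <- c(out, aMM[k] * em(k + 1, i + 1) * fromM(k + 1, i + 1))
      if (i < n) out <- c(out, aMI[k] * iem(k, i + 1) * fromI(k, i + 1))
      out <- c(out, aMD[k] * fromD(k + 1, i))
    }
    out
  }
  fromI <- function(k, i) {
    out <- numeric(0)
    if (i < n) {
      out <- c(out, tr$tII[k] * iem(k, i + 1) * fromI(k, i + 1))
      out <- c(out, tr$tIM[k] * em(k + 1, i + 1) * fromM(k + 1, i + 1))
    }
    out
  }
  fromD <- function(k, i) {
    out <- numeric(0)
    if (k == L) {
      if (local) out <- c(out, eta^(n - i) * (1 - eta))
      else if (i == n) out <- c(out, 1)
    } else {
      if (i < n) out <- c(out, tr$tDM[k] * em(k + 1, i + 1) * fromM(k + 1, i + 1))
      out <- c(out, tr$tDD[k] * fromD(k + 1, i))
    }
    out
  }
  paths <- numeric(0)
  if (local) {
    for (i0 in seq_len(n)) {
      pre <- eta^(i0 - 1) * (1 - eta) / L
      for (k0 in seq_len(L)) {
        paths <- c(paths, pre * em(k0, i0) * fromM(k0, i0))
      }
    }
  } else {
    paths <- em(1, 1) * fromM(1, 1)
  }
  list(forward_bits = if (length(paths)) log2(sum(paths)) else -Inf,
       viterbi_bits = if (length(paths)) log2(max(paths)) else -Inf)
}

# plain-matrix affine-gap Smith-Waterman (gap of length g costs open + g*ext)
oracle_sw <- function(a, b, mat, open = 11, ext = 1) {
  ca <- strsplit(a, "")[[1]]
  cb <- strsplit(b, "")[[1]]
  n <- length(ca)
  m <- length(cb)
  H <- matrix(0, n + 1, m + 1)
  E <- matrix(-Inf, n + 1, m + 1)
  F <- matrix(-Inf, n + 1, m + 1)
  best <- 0
  for (i in 2:(n + 1)) {
    for (j in 2:(m + 1)) {
      E[i, j] <- max(H[i, j - 1] - open - ext, E[i, j - 1] - ext)
      F[i, j] <- max(H[i - 1, j] - open - ext, F[i - 1, j] - ext)
      H[i, j] <- max(0, H[i - 1, j - 1] + mat[ca[i - 1], cb[j - 1]],
                     E[i, j], F[i, j])
      best <- max(best, H[i, j])
    }
  }
  best
}

# closed-form pooled two-sample t with the t CDF
oracle_pooled_t <- function(a, b) {
  na <- length(a); nb <- length(b)
  sp2 <- ((na - 1) * var(a) + (nb - 1) * var(b)) / (na + nb - 2)
  t <- (mean(a) - mean(b)) / sqrt(sp2 * (1 / na + 1 / nb))
  df <- na + nb - 2
  list(t = t, df = df, p = 2 * pt(-abs(t), df))
}

# random protein string over the 20-letter alphabet
rand_protein <- function(len) {
  paste(sample(strsplit("ACDEFGHIKLMNPQRSTVWY", "")[[1]], len, replace = TRUE),
        collapse = "")
}

# small random alignment over the ABC test alphabet with a controlled
# number of match columns: `L` fully occupied columns plus one
# low-occupancy column that becomes an insert region (for L >= 2)
abc_test_alignment <- function(L, nseq = 4) {
  letters3 <- c("A", "B", "C")
  m <- matrix(sample(letters3, nseq * L, replace = TRUE), nseq, L)
  if (L >= 2) {
    ins <- c(sample(letters3, 1), rep("-", nseq - 1))
    m <- cbind(m[, 1, drop = FALSE], ins, m[, -1, drop = FALSE])
  }
  data.frame(id = paste0("s", seq_len(nseq)),
             aligned_sequence = apply(m, 1, paste, collapse = ""),
             stringsAsFactors = FALSE)
}

all_abc_sequences <- function(max_len = 5) {
  letters3 <- c("A", "B", "C")
  unlist(lapply(seq_len(max_len), function(len) {
    apply(expand.grid(rep(list(letters3), len)), 1, paste, collapse = "")
  }), use.names = FALSE)
}

# a fast, deliberately small study design for pipeline-level tests
tiny_design <- function(...) {
  study_design(
    n_per_group = 2,
    carriage_high = c(PhoX = 0.6, ClassA = 0.3),
    carriage_low = c(PhoX = 0.1, ClassA = 0.3),
    n_genomes = 30, divergence = 0.12, consensus_length = 60,
    n_refs = 12, fragment_length_mean = 40, min_length = 30,
    coverage = 1.5, n_background = 40, ...
  )
}
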