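#' Unpaired two-sample t-test
#'
#' Classical pooled-variance Student's t (default) or Welch's t, two
#' tailed.  Degenerate inputs are handled explicitly: zero variance in
#' both groups with equal means gives `t = 0, p = 1`; zero variance with
#' unequal means gives `p = 0` flagged as degenerate.
#'
#' @param a,b Numeric vectors (each of length >= 2, finite).
#' @param variant `"pooled"` or `"welch"`.
#' @return List with `t`, `df`, `p`, and logical `degenerate`.
#' @export
ttest_unpaired <- function(a, b, variant = c("pooled", "welch")) {
  variant <- match.arg(variant)
  stopifnot(length(a) >= 2L, length(b) >= 2L,
            all(is.finite(a)), all(is.finite(b)))
  va <- stats::var(a); vb <- stats::var(b)
  df0 <- if (variant == "pooled") length(a) + length(b) - 2 else NA_real_
  if (va == 0 && vb == 0) {
    if (mean(a) == mean(b)) {
      return(list(t = 0, df = df0, p = 1, degenerate = TRUE))
    }
    return(list(t = sign(mean(a) - mean(b)) * Inf, df = df0, p = 0,
                degenerate = TRUE))
  }
  res <- stats::t.test(a, b, var.equal = (variant == "pooled"))
  list(t = unname(res$statistic), df = unname(res$parameter),
       p = res$p.value, degenerate = FALSE)
}

#' Compare gene frequencies between low- and high-pH site groups
#'
#' Per target family, an unpaired t-test of the per-site gene frequencies
#' in the low-pH group against the high-pH group (the t statistic is
#' low minus high, so a negative t means lower frequency in low-pH
#' soils).  No multiple-testing correction is applied by default,
#' matching per-gene reporting; Benjamini-Hochberg is available via the
#' config.
#'
#' @param abundance An `abundance_table` from [quantify_sites()].
#' @param config A `run_config` (test variant, alpha, p_adjust).
#' @param on `"frequency"` (default) or `"normalized_count"`.
#' @return Data frame with one row per target family: group means and
#'   SDs, `t`, `df`, `p` (and `p_adj` when adjustment is on),
#'   `significant`, `degenerate`.
#' @export
compare_groups <- function(abundance, config, on = c("frequency", "normalized_count")) {
  on <- match.arg(on)
  tgt <- abundance[abundance$role == "target", , drop = FALSE]
  fams <- unique(tgt$family)
  rows <- lapply(fams, function(fam) {
    d <- tgt[tgt$family == fam, , drop = FALSE]
    lo <- d[[on]][d$group == "low_pH"]
    hi <- d[[on]][d$group == "high_pH"]
    if (length(lo) < 2L || length(hi) < 2L) {
      stop("family ", fam, ": each group needs at least 2 sites (got ",
           length(lo), " low_pH, ", length(hi), " high_pH)")
    }
    tt <- ttest_unpaired(lo, hi, config$ttest_variant)
    data.frame(
      family = fam,
      mean_low = mean(lo), mean_high = mean(hi),
      sd_low = stats::sd(lo), sd_high = stats::sd(hi),
      t = tt$t, df = tt$df, p = tt$p,
      degenerate = tt$degenerate,
      stringsAsFactors = FALSE
    )
  })
  out <- do.call(rbind, rows)
  if (config$p_adjust == "BH") {
    out$p_adj <- stats::p.adjust(out$p, method = "BH")
    out$significant <- out$p_adj < config$alpha & !out$degenerate
  } else {
    out$significant <- out$p < config$alpha & !out$degenerate
  }
  # a family absent everywhere is degenerate (0 vs 0), never significant
  rownames(out) <- NULL
  out
}

#' Simulate per-site gene frequencies for test calibration
#'
#' Draws, for each site and family, the realized carriage fraction
#' `Binomial(n_genomes, p) / n_genomes` under the planted per-group
#' carriage, and returns a minimal abundance table suitable for
#' [compare_groups()].  This is the sampling noise the pipeline's
#' frequency estimates inherit from a finite community.
#'
#' @param carriage_low,carriage_high Named per-family carriage fractions.
#' @param n_per_group Sites per group.
#' @param n_genomes Genomes per site.
#' @param seed RNG seed.
#' @return An `abundance_table`-shaped data frame (target rows only).
#' @export
simulate_frequency_design <- function(carriage_low, carriage_high,
                                      n_per_group = 4, n_genomes = 500,
                                      seed = 1L) {
  stopifnot(identical(sort(names(carriage_low)), sort(names(carriage_high))))
  fams <- names(carriage_low)
  with_seed(seed, {
    rows <- list()
    for (grp in c("low_pH", "high_pH")) {
      carr <- if (grp == "low_pH") carriage_low else carriage_high
      for (s in seq_len(n_per_group)) {
        f <- stats::rbinom(length(fams), n_genomes, carr[fams]) / n_genomes
        rows[[length(rows) + 1L]] <- data.frame(
          site_id = paste0(substr(grp, 1, 1), s), group = grp,
          family = fams, role = "target",
          frequency = f, percent = 100 * f,
          normalized_count = f * n_genomes,
          stringsAsFactors = FALSE
        )
      }
    }
    do.call(rbind, rows)
  })
}

#' Monte-Carlo calibration of the group comparison
#'
#' Repeatedly simulates the two-group design with
#' [simulate_frequency_design()] and runs [compare_groups()], returning
#' per-family rejection rates.  With equal carriage in both groups this
#' estimates the empirical type-I error of the test machinery; with a
#' planted group effect it estimates power.
#'
#' @param carriage_low,carriage_high Named per-family carriage fractions.
#' @param n_reps Number of replicates.
#' @param n_per_group,n_genomes Design size per replicate.
#' @param alpha Significance level.
#' @param variant t-test variant.
#' @param seed Master seed (one child seed per replicate).
#' @return Named vector of rejection rates per family.
#' @export
calibrate_compare_groups <- function(carriage_low, carriage_high,
                                     n_reps = 1000, n_per_group = 4,
                                     n_genomes = 500, alpha = 0.05,
                                     variant = "pooled", seed = 1L) {
  fams <- names(carriage_low)
  cfg <- list(ttest_variant = variant, alpha = alpha, p_adjust = "none")
  seeds <- derive_seeds(seed, n_reps)
  rej <- matrix(FALSE, nrow = n_reps, ncol = length(fams),
                dimnames = list(NULL, fams))
  for (r in seq_len(n_reps)) {
    ab <- simulate_frequency_design(carriage_low, carriage_high,
                                    n_per_group, n_genomes, seeds[[r]])
    cmp <- compare_groups(ab, cfg)
    rej[r, cmp$family] <- cmp$significant
  }
  colMeans(rej)
}
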