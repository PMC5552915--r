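---
title: "Methods: profile-HMM screening of phosphorus-scavenging genes"
output: rmarkdown::html_vignette
vignette: >
  %\VignetteIndexEntry{Methods: profile-HMM screening of phosphorus-scavenging genes}
  %\VignetteEngine{knitr::rmarkdown}
  %\VignetteEncoding{UTF-8}
---

```{r setup, include = FALSE}
knitr::opts_chunk$set(eval = FALSE)
```

# The problem

Soil bacteria liberate inorganic orthophosphate (Pi) from organic
phosphorus esters by secreting phosphatases: the alkaline phosphatases
PhoX, PhoD and PhoA, the nonspecific acid phosphatases (classes A, B
and C), and related enzymes such as the 5'-nucleotidase UshA.  Soil
metagenomes let us ask how common these genes are in a community
without cultivation: screen the predicted-CDS protein set of each site
for each gene family, convert hit counts into "what fraction of the
community's genomes carry this gene", and compare sites.  Because
predicted CDS are read-derived protein *fragments*, every step has to
tolerate partial sequences, and raw counts must be normalized both for
gene length and for how deeply each site was sampled.

`phoscreen` implements that workflow end to end, together with a
synthetic-community generator that plants known gene-carriage
fractions so every stage can be validated against ground truth.

# The screening model

## Profile HMMs

Each family is modeled by a position-specific profile hidden Markov
model built from a curated reference alignment.  Columns whose
occupancy (non-gap fraction; `X` counts as occupied) is at least the
`occupancy_threshold` (default 0.5) become match states.  Match
emissions are estimated from column residue counts with
background-weighted Laplace smoothing,

$$e_k(r) = \frac{c_k(r) + \tau\, q_r}{\sum_s c_k(s) + \tau},$$

with total pseudocount weight $\tau = 1$ and a uniform background
$q_r = 1/20$ by default.  Insert emissions equal the background.
Per-node M/I/D transitions are counted from each sequence's state path
through the alignment (gap in a match column = delete; residue in a
non-match column = insert) and smoothed with the same total weight
spread uniformly over each state's outgoing branches.  We chose this
simple smoothing over Dirichlet mixtures deliberately: every number in
the profile can be recomputed by hand, which is what the unit tests
do.  Sequence weighting is not applied; with the curated,
phylogenetically spread reference sets this workflow expects
(50–80 sequences per family), redundancy weighting changes little, and
it is flagged as an extension.

The profile records a `reference_length` per family — the median (by
default) ungapped reference length — used later by the normalization.
Median rather than mean because curated sets occasionally contain
truncated or fused outliers.

## Scoring: local alignment with free flanks

A CDS is scored as $\log_2 P(x \mid \text{profile}) / P(x \mid
\text{background})$, either summed over all state paths (forward, the
score used for acceptance) or maximized (Viterbi, reported alongside).
The architecture is local: background-emitting flank states with
self-loop probability `flank_loop` (default 0.95) absorb unmodeled
prefix/suffix residues, entry is uniform over match states, and exit
uses a geometric rule $\varepsilon_k = 1/(L-k+1)$ so that, conditional
on the entry point, the exit point is close to uniform.  Deletions are
interior only.  This matches the data type: a 45-aa fragment of a
600-aa protein must be able to align to any stretch of the model
without paying for the unobserved remainder.  A `global` mode (entry
at node 1, exit at node $L$) exists for full-length genome screening
and for closed-form unit tests.

Numerics: Viterbi runs in log2-odds space; forward runs in odds space
with per-row rescaling (rescale when the row maximum leaves
$[10^{-100}, 10^{100}]$), accumulating the log of the scales, and the
per-position exit terms are combined by log-sum-exp.  Both recursions
are exact — the test suite checks them against exhaustive path
enumeration to $10^{-9}$ on a dense grid of small profiles — and
`forward >= viterbi` holds by construction.  `X` is the only accepted
ambiguity code and scores odds 1 (emission equal to background) in
every state; B/Z/U/J are rejected at parse time so the DP engine never
sees them.

## Acceptance threshold

A CDS is a hit for a family when its forward score reaches the
configured threshold, 25 bits by default.  The threshold is a bit
score, not an E-value: desk-scale analyses have no stable database
size to calibrate an E-value against, and a bit score is reproducible
verbatim.  `decoy_fdr()` supports site-specific calibration by scoring
composition-preserving shuffles of the actual CDS set; at 25 bits the
decoy hit rate on the synthetic data is zero for every family.  One
CDS counts at most once per family (best score per sequence; no domain
splitting) because the downstream normalization consumes per-site hit
counts, not domain architectures.

# From counts to "percent of bacteria"

For site $s$ and family $f$ with raw count $n_{sf}$:

* **Length normalization**: $\tilde n_{sf} = n_{sf} \cdot L_{\mathrm{RecA}} / L_f$.
  Fragment-derived hit counts scale with protein length, so counts of
  longer genes are corrected *down*.  The length ratio itself is fixed
  by the method; which way to apply it is a genuine choice, and the
  package exposes `normalization_direction = "length_weighted"`
  ($n \cdot L_f/L_{\mathrm{RecA}}$) for comparison.
* **Genome equivalents**: $G_s$ = mean of $\tilde n$ over the five
  single-copy housekeeping genes RecA, RpoB, AtpB, GyrB and SucD — an
  estimate of how many genomes the site's CDS set represents.  All
  five (including RecA itself) enter the mean by default; the set is
  configurable.
* **Gene frequency**: $f_{sf} = \tilde n_{sf} / (G_s\, c_f)$ with an
  assumed copy number $c_f = 1$ per carrying genome; reported both as
  a fraction and a percentage.  Values above 100% are flagged and
  never clamped — they diagnose multi-copy families or a threshold
  set too low.  A site with $G_s = 0$ has undefined frequencies and
  is flagged rather than silently dropped.

The invariants the tests enforce: $\tilde n = n$ when $L_f =
L_{\mathrm{RecA}}$; scaling every count at a site by $k$ scales
$\tilde n$ and $G$ by $k$ and leaves every frequency unchanged; $f$ is
increasing in $\tilde n$ and decreasing in $G$ and $c$.

# Group comparison

Per target family, the per-site frequencies of the low-pH group are
compared with the high-pH group by an unpaired t-test.  "Unpaired
t-test" is read as the classical pooled-variance Student's t (the most
common reading); Welch is available via `ttest_variant = "welch"`.
Tests are two-tailed on untransformed frequencies, and no
multiple-testing correction is applied by default, matching per-gene
reporting; Benjamini–Hochberg sits behind `p_adjust = "BH"` for users
screening many families.  Degenerate inputs are defined rather than
left to error: both groups constant and equal gives $t=0, p=1$;
constant but unequal gives $p=0$ flagged degenerate (a family absent
everywhere is therefore "degenerate, not significant", never a
discovery).  `calibrate_compare_groups()` re-derives the test's
operating characteristics by Monte Carlo under binomial sampling
noise: with 4+4 sites and 500-genome communities the empirical type-I
error sits at the nominal 5% (the acceptance suite requires
[0.03, 0.07] over 1000 replicates) and power against the planted
APase contrast is essentially 1.

# Taxonomic assignment

Accepted hits of the configured families (the three APases by
default) are assigned to the best-scoring record of a curated,
lineage-labeled protein database by Smith–Waterman local alignment
under BLOSUM62 with gap open 11 / extend 1 (a gap of length $g$ costs
$11 + g$) — stated exactly so scores are reproducible bit for bit.
Percent identity counts identical columns over all aligned columns,
gaps included in the denominator.  Assignment requires a minimum
alignment score (default 50); ties are broken by higher identity, then
lexicographic reference id.  The original BLASTP protocol used an
E-value cutoff of 1e-10 against a large database; a raw-score floor is
its desk-scale analogue, since the E-value of a score depends on
database size ($E \approx Kmn\,2^{-S'}$), and users matching a
specific E-value regime should raise or lower `min_assign_score`
accordingly.  Lineages are read from a documented header convention
(`>id lineage=Domain;Phylum;Class;...`) rather than from a live
taxonomy service, keeping runs offline and reproducible.
Assignments aggregate into a rank hierarchy whose counts are conserved
at every level, exported in the Krona `ktImportText` dialect
(`count TAB rank1 TAB rank2 ...`, sorted by lineage).

# The synthetic generator: what it emulates, what it does not

`make_study()` generates the whole study: per family a random
consensus and 60 reference descendants at i.i.d. substitution rate
0.15 (no indels, so the true alignment is trivial and identity
expectations are analytic); per site a community of 500 genomes in
which every genome carries each housekeeping gene exactly once and
each target family with its planted group carriage; per protein a
Poisson(2) number of fragments with geometric-tailed lengths (mean 45
aa, minimum 30 aa, uniform starts), plus 500 background proteins of
i.i.d. composition per site.  The default design plants the low-
versus high-pH contrast at carriage 0.47/0.56/0.20 (high) versus
0.03/0.07/0.01 (low) for PhoX/PhoD/PhoA, with the three acid
phosphatase classes equal across groups — so the correct qualitative
outcome (APases reduced at low pH, ACPases flat) is known by
construction.  Everything is a pure function of (parameters, seed).

Two scale choices are the package's own.  First, all families share
one consensus length (150 aa).  The generator fragments each protein
with a length-independent Poisson count, so hit counts do not scale
with gene length in the simulation; equal lengths keep the length
normalization exactly neutral there, making planted carriage the
estimand rather than a length-confounded version of it.  (On real
data, fragment counts do scale with gene length — that is precisely
what the normalization corrects.)  Second, the 150-aa consensus and
45-aa fragments are scaled-down but structurally faithful: scores
accumulate ~3 bits per aligned column at 15% divergence, so a 30-aa
fragment clears the 25-bit threshold by a wide margin, just as real
fragments of real families do.

What the simulator does **not** emulate: phylogenetic correlation
among references (i.i.d. substitution only), indels within families,
codon-level artifacts of ORF calling, log-normal community abundance
structure, and any relationship between a genome's lineage label and
its sequence content (labels are drawn from a fixed soil-like pool).
Passing the planted-recovery tests therefore shows the *pipeline
arithmetic and detection machinery* are correct; it does not certify
detection sensitivity on real, indel-rich, unevenly diverged families.

# Problem sizes and runtimes

The validation suite runs the full default study (8 sites x 500
genomes, coverage 2, 11 families) once — a few minutes on one core,
dominated by ~50,000 fragment-versus-profile forward/Viterbi DPs — and
keeps the remaining tests at toy scale: the DP oracle grid uses all
363 sequences of length ≤ 5 over a 3-letter alphabet against profiles
of 1–4 match states (small enough for exhaustive path enumeration);
calibration uses 1000 null and 100 effect replicates at the
frequency level; determinism is checked on a 4-site, 30-genome study
run twice.

# Known limitations

* The engine is a faithful but minimal profile HMM: no Dirichlet
  mixture priors, no sequence weighting, no MSV/bias acceleration
  heuristics, and no Gumbel-calibrated E-values.  Scores are exact for
  the stated model rather than approximations of HMMER's.
* Reference alignments are an input.  Unaligned references of unequal
  length are rejected with advice to align them first; only the
  synthetic generator's gapless families are accepted as trivially
  aligned.
* The copy-number-one assumption converts frequencies into "percent
  of bacteria" only as far as it holds; flagged >100% values are the
  symptom to watch.
* Best-hit taxonomy is not an LCA: a hit equidistant between two
  phyla is assigned to one of them, deterministically but arbitrarily
  within the documented tie-break.
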