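---
title: "Methods: simulation-backed assembly and knockdown quantitation for an insect retina"
output: rmarkdown::html_vignette
vignette: >
  %\VignetteIndexEntry{Methods: simulation-backed assembly and knockdown quantitation for an insect retina}
  %\VignetteEngine{knitr::rmarkdown}
  %\VignetteEncoding{UTF-8}
---

```{r setup, include = FALSE}
knitr::opts_chunk$set(collapse = TRUE, comment = "#>", eval = FALSE)
```

# The problem this package addresses

Targeted studies of insect phototransduction identify a handful of retinal
genes — opsins and the TRP-family channels that carry the light-activated
current — from bulk short-read data, then silence them in vivo and quantify
the consequences. The computational chain behind such a study has six
distinct stages, each simple in isolation but easy to get subtly wrong in
combination:

1. **Grooming**: retain, from each raw read, the longest contiguous run of
   bases with Phred quality above 19, keeping reads whose run is at least
   80 nt.
2. **Seed search**: find candidate reads of a gene family by low-stringency
   ungapped comparison of a homologous query (peptide, under
   BLOSUM45/62/80; or nucleotide, +1/−1) against all six translation frames
   of every read.
3. **Transcriptome walking**: extend a seed read to a full transcript by
   repeated overlap-and-consensus against the read pool, until the coding
   sequence and its 3' stop codon are covered.
4. **Read-count abundance**: count, per gene, reads with at least 90
   identical bases (of 100) against the gene's reading frame at some
   ungapped offset on either strand; normalize by frame length and express
   relative to actin.
5. **qPCR quantitation**: efficiency-corrected comparative-Cq ratios with
   geometric multi-reference normalization (actin + GAPDH), from triplicate
   plates over three animals.
6. **ERG statistics**: flash-response amplitudes relative to a pre-flash
   baseline, pooled across eyes, tested against controls with the
   two-tailed Mann–Whitney test.

Real retinas cannot be re-sequenced on demand, so the package is built
around a **ground-truthed generator**: a synthetic seven-gene retina whose
defaults encode the published composition and knockdown outcomes of the
emulated study. Every estimator is then validated by *parameter recovery* —
simulate raw data from known truth, run the full chain, and check that the
truth comes back out.

# The synthetic retina

`retina_composition()` fixes the cast: two green-opsin paralogs at 100:1
(`pGO1`, `pGO2`), a UV opsin at 2 (the geometric middle of its reported
25–100-fold deficit below pGO1 — the source reports only a range, so this
default is a declared choice, not a reported value), channels at 1:10
(`pTRP`, `pTRPL`), actin at 100 and GAPDH at 30 arbitrary copy units. GAPDH
has no published point value; nothing actin-relative depends on it.
CDS lengths are desk-scale (1.0–1.65 kb) rather than full channel length;
all ratio-valued checks compare same-length pairs, so this costs no
generality.

Three generator details matter downstream:

* **Paralog divergence is stratified.** `pGO2` is derived from `pGO1` by
  one substitution per equal-width block (15% of positions at the default
  85% identity), never touching start/stop codons and never creating an
  in-frame stop. Stratification guarantees every 100-nt window carries
  more than 10 differences, so the 90/100 counting criterion *provably*
  cannot cross-count error-free paralog reads — with uniformly scattered
  substitutions roughly a tenth of windows would slip under the threshold
  and the 100:1 ratio would be unrecoverable.
* **UTRs contain no ATG**, so the longest open reading frame of each
  transcript is its true CDS and walking termination is well defined.
* **Quality model.** Per-read logistic decay with a random midpoint
  (plateau Phred ≈ 38, floor ≈ 12, midpoint ~ N(85, 12) along a 100-nt
  read) plus jitter. This makes grooming consequential: roughly 60% of
  default-model reads survive the 80-base rule, emulating the retention
  fraction of the emulated sequencing run without claiming a platform
  error profile. Sequencing errors are uniform substitutions
  (default 1%); realistic error spectra are a stated non-goal.

Fragments are drawn with probability proportional to copy number times
transcript length (each transcript copy sheds fragments in proportion to
its length), unstranded, with both mates recorded and full per-read
provenance retained for oracle tests.

# Walking: parameters and failure modes

Walking uses a k-mer read index (k = 15, 2-bit-packed into 32-bit integer
codes — hence k ≤ 15; k ≥ 8 to keep postings selective) and, per step,
aligns candidate reads sharing an exact k-mer with the terminal 25-nt
anchor, keeps those with at most 1 mismatch inside the anchor, and lets
their overhangs vote. Extension takes the strict-majority base while at
least 3 reads cover the position, at most 50 nt per step. Ties and support
loss stop the walk — no arbitrary base calls. These defaults favor
correctness on 100-nt reads: one anchor mismatch tolerates a sequencing
error but excludes the 85%-identical paralog (expected ≈ 3.75 differences
per 25-nt anchor window).

Two design decisions came out of testing rather than first principles:

* **No ORF-based early termination.** A partial contig can contain a long
  *internal* ATG-initiated closed frame; stopping when "a complete CDS" is
  seen truncates genes whose true start lies further 5'. Walking therefore
  runs to support loss in both directions, which on an adequately covered
  library is the transcript ends — strictly after the CDS and its stop.
* **Seed polishing.** Every contig base *except the original seed* is a
  majority vote; a sequencing error inside the seed read survives assembly
  and can fabricate a premature stop codon. After walking, the seed span
  is re-called from all overlapping reads (kept when their whole-overlap
  mismatch fraction is ≤ 6% — below paralog divergence, above the error
  rate). With polishing, assemblies at depth ≥ 20 reproduce the generator
  truth exactly over the covered interval.

The final contig is reported in the orientation with the longest reading
frame, so seeds from either strand give identical transcripts. A walk is
fully deterministic given library, seed and parameters.

# Seed search

Scores are ungapped local segments (the best contiguous positive-sum
diagonal run), not gapped Smith–Waterman: 100-nt reads against conserved
receptor/channel motifs essentially never need gaps, and low stringency is
achieved through the matrix (BLOSUM45 for distant homologs) rather than
through gap modelling. `X` and `*` score −4 against everything so
stop-riddled wrong frames cannot seed alignments. Score thresholds are not
inherited from anywhere: when unset, the threshold is calibrated from a
permutation null (base-shuffled reads, 99.9th percentile, fixed seed), so
"low stringency" has an operational definition. The pipeline's query
sequences are themselves synthetic "related species" homologs — the true
peptides degraded to 70% amino-acid identity — so the search is tested
under realistic divergence, not against its own answer.

# Read-count abundance

The criterion is absolute — at least 90 identical bases at a single
ungapped offset, either strand, against the CDS only — so trimmed reads
below 90 nt can never count, and a read may legitimately count for several
genes (it is a per-gene criterion, not an assignment; the diagnostics
attribute reports how often that happened — zero on the default retina).
The implementation screens with exact 9-mers: any placement achieving 90
matches within a ≤ 100-nt overlap leaves at most 11 mismatch-free runs
covering ≥ 90 positions, hence a run of ≥ 9, so the screen is provably
equivalent to the exhaustive scan above threshold; equivalence is also
tested directly against per-read exhaustive alignment. Counts are divided
by frame length and referenced to actin.

# qPCR model

The simulator inverts the quantitation model: `Cq = cq_unit −
log_(1+E)(quantity) + noise`, with Table-style per-assay efficiencies
(E = 0.856–0.963), technical noise of 0.2 cycles, and log-normal
between-animal variability (sd 0.2 on log2 quantity). Quantitation runs
the other way: replicate Cq values are averaged within gene × animal, each
treated animal is compared against the pooled untreated baseline, per-gene
factors `(1+E)^ΔCq` are normalized by the **geometric** mean over actin and
GAPDH, and per-animal ratios are summarized as mean ± sd over n = 3. The
geometric mean is the field convention for multi-reference normalization
("the mean of two references" is ambiguous in prose; the arithmetic version
fails the directed unit test and would not cancel a global Cq shift).
Saline sham injections are simulated as occasional 1–2× inflation (per
animal × gene, probability 0.5) — present in plates, irrelevant to the
untreated baseline.

The qPCR *abundance* route (as opposed to knockdown ratios) compares
quantities back-calculated as `(1+E)^(cq_unit − Cq)` across assays, which
is only meaningful under a shared single-threshold calibration constant;
`cq_at_unit` is therefore treated as instrument metadata, like E itself.

# ERG model and statistics

Amplitude is the absolute difference between the mean voltage in the 1-s
flash window and the mean in a 0.5-s pre-flash baseline (the baseline
length is a declared default; the convention's source does not state one).
Recording positions have strongly different baseline amplitudes (3, 0.5
and 5 mV at top, center, bottom); the tiny center signal (position 2) is
simulated but excluded from analysis. Eyes are pooled; left/right never
differ by construction.

The link from silencing to function is deliberately minimal: amplitude
scales with the functional-protein fraction
`f(t) = r + (1 − r)·2^(−(t − lag)/h)` (residual mRNA fraction `r`,
per-gene protein half-life `h`, dead-time `lag`; multi-target injections
multiply their fractions). Injected animals are non-responders with
probability 2/16 (both eyes unaffected), matching the observed one-or-more
normal animals per batch of eight. Because reported cohort means *include*
non-responders, the kinetic constants were solved analytically so that the
expected cohort mean reproduces the published attenuation under this
non-responder rate: opsin `h` = 2.40 d (75% mean reduction at day 7, with
its 98.8% mRNA knockdown), TRP `h` = 27.75 d (30% at day 21 — slow channel
turnover is the model's explanation for the weak TRP effect), TRPL
`h` = 3.41 d after a 7-day dead time (weak at one week, ≈ 75% by day 21).
The TRPL dead time is an extension of a pure first-order lag: no single
exponential with floor 0.09 can be both near-ineffective at day 7 and at
75% attenuation by day 21. These constants were fixed from the printed
figures before any recovery test was run and are not tuned thereafter.

`mann_whitney_u()` computes `U = #{(i, j): x_i > y_j}` and, for tie-free
samples with `n1 + n2 ≤ 20`, the exact two-tailed
`P(|U − n1·n2/2| ≥ |u − n1·n2/2|)` from the full permutation null
(dynamic-programming counts; verified against complete enumeration for all
tie-free inputs with `n1 + n2 ≤ 10` and against the classical
implementation); otherwise a tie-corrected normal approximation with
continuity correction. No multiple-testing correction is applied across
days/positions by default, mirroring the emulated analysis; Holm
adjustment is available via `adjust = "holm"`.

On significance *patterns*: the strong opsin effect reproduces as `***`
robustly, and the weak TRP effect as significant-but-weaker; the exact
star count of a marginal wet-lab p-value (p ≈ 0.02–0.03) depends on
between-animal variance structure that the published text does not
constrain, and is not asserted.

# Problem sizes, tolerances, numerical choices

* Recovery runs use 200,000 read pairs (abundance), 200 Monte-Carlo
  plate experiments of 3 animals × 3 replicates (knockdown), and 30
  replicate cohorts of 15 control + 8 treated animals (ERG) — sizes at
  which the minor paralog still receives ≈ 1,900 reads and Monte-Carlo
  means have coefficients of variation well under the recovery
  tolerances. The whole recovery suite runs in minutes on one CPU.
* Tie-breaks are deterministic everywhere: leftmost longest grooming run;
  smallest query-then-subject offset in alignment; closed-then-smallest
  start reading frames; consensus ties stop the walk.
* Ratio estimators average per-animal ratios (arithmetic mean of a
  log-normal-ish quantity), giving a small upward convexity bias
  (≈ +2–3% at the default noise) — visible in recovered values like
  0.0123 vs 0.012 and accepted as a property of the published estimator
  rather than corrected away.
* Degenerate inputs fail loudly: empty libraries, missing efficiencies,
  zero-read reference genes, overlapping ERG windows and length-mismatched
  read/quality pairs are errors, not warnings.

# What the simulations do and do not show

Passing recovery tests show the *estimators* are correct and unbiased
under the generator's assumptions: uniform substitution errors, exact
composition, log-normal biological noise, square-pulse ERG responses,
instant mRNA knockdown with first-order protein decay. They do not show
robustness to platform-specific error spectra, alternative splicing or
isoform mixtures, amplification inhibitors and plate position effects,
non-stationary ERG baselines, or partial dsRNA uptake dynamics — none of
which the generator attempts to emulate. The package is a faithful,
testable implementation of the analysis chain, not evidence about any
particular real retina.

# Session

```{r, eval = FALSE}
library(retinawalk)
rep <- run_replication(replication_config(), seed = 1)
rep
```
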