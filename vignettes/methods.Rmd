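---
title: "Quantifying giant viruses in cellular-size-fraction metagenomes: models and design"
output: rmarkdown::html_vignette
vignette: >
  %\VignetteIndexEntry{Quantifying giant viruses in cellular-size-fraction metagenomes: models and design}
  %\VignetteEngine{knitr::rmarkdown}
  %\VignetteEncoding{UTF-8}
---

```{r setup, include = FALSE}
knitr::opts_chunk$set(collapse = TRUE, comment = "#>")
library(ncldvscope)
```

## The problem

Nucleo-cytoplasmic large DNA viruses (NCLDVs — Megaviridae/Mimiviridae,
Phycodnaviridae and their relatives) have virions and genomes so large
that many of them are caught in the "microbial" size fraction
(0.2–1.6 µm) of sea-water filtration series rather than in the viral
fraction. A shotgun metagenome of that fraction therefore carries a
mixture of prokaryote, picoeukaryote and giant-virus DNA, and the
relative abundance of NCLDV *genomes* can be read out of it — provided
one counts genomes rather than raw reads. `ncldvscope` implements the
complete analysis chain this requires, end to end and testable on
synthetic data:

1. removal of pyrosequencing artificial duplicate reads,
2. six-frame peptide extraction,
3. single-copy marker-gene scanning and density estimation,
4. dual-search last-common-ancestor (2bLCA) taxonomic annotation,
5. rescaling of relative NCLDV abundance to genomes per ml using
   prokaryote cell counts,
6. taxon co-occurrence networks on the taxon-by-sample matrix
   (two methods, including a permutation–renormalization null), and
7. a taxonomically masked reciprocal-best-hit screen for virus-to-cell
   horizontal gene transfer (HGT).

## Models and their assumptions

### Duplicate-read removal

454-style pyrosequencing re-emits near-copies of template reads that
share the exact 5' start. `remove_duplicates()` clusters greedily:
reads sorted by descending length (ties by id) join the first exemplar
that shares the first 5 nt and has global-alignment identity at least
0.97, computed over a global alignment of the shorter read against the
equally long prefix of the exemplar. The end-anchored global alignment
is deliberate: the artefact being removed shares its start point, so an
alignment anchored at position 0 measures exactly the quantity the
artefact model predicts. The clustering rule (greedy,
length-then-lexical order) is spelled out because published replicate
filters leave their tie-breaking unspecified; making it explicit makes
the operation reproducible and testable against an all-pairs oracle.

### Homology search and E-values

The built-in search engine computes Smith–Waterman local alignments
(BLOSUM62, affine gaps: a gap of length $g$ costs $11 + g$) and converts
raw scores with ungapped Karlin–Altschul statistics,
$E = K m n e^{-\lambda S}$ with $\lambda = 0.3176$, $K = 0.134$, $m$ the
query length and $n$ the database size in residues. Using ungapped
$(\lambda, K)$ for gapped alignments is a calibration choice, not an
oversight: within this package absolute E-values only gate fixed
thresholds (1e-5 for annotation, 1e-3 for marker scanning) and define
the adaptive 2bLCA cutoff, so internal consistency is what matters.
Users who need parity with an external engine load its tabular output
through `load_tabular_hits()`, which enforces the same HSP contract.
Only the single best HSP per query–subject pair is kept, and E-value
ties break on lexical subject id so every downstream result is
deterministic.

### 2bLCA annotation

Each read longer than 100 bp is annotated in two passes: a translated
search (B1) finds the best-scoring HSP at $E \le 10^{-5}$; the subject
residues inside that HSP are re-searched (B2) against the same database
with an adaptive cutoff equal to the B1 E-value. The subjects of all B2
hits at that cutoff or better form the close-homolog set H, whose
lineage last common ancestor becomes the read's annotation. The logic is
that the aligned database fragment "stands in" for the read: any
database protein at least as similar to that fragment as the read was is
an equally plausible source, so the annotation must be no more specific
than their LCA. Reads whose H spans more than one top-level domain
(Bacteria, Archaea, Eukaryota, Viruses — the virosphere counted as a
domain here because the downstream bins need it) are `ambiguous`. The B2
query's own source protein always qualifies via its self-hit and is
retained in H; it contributes the best-hit lineage itself and guarantees
H is never empty. The `>100 bp` gate is strict: a 101-bp read is
annotated, a 100-bp read is not.

### Marker-gene densities and absolute abundance

Genome abundance is estimated from genes that occur exactly once per
genome, so that homolog counts are genome counts. Profiles are ungapped
position-specific score matrices in log-odds bits; a peptide's score is
the best window alignment with at least 30 aligned columns, and
$E = m L\, 2^{-S}$ (Gumbel-type with $\lambda = \ln 2$ per bit).
There is no profile-HMM engine in this package's dependency stack, and
none is needed at this scale: for well-conserved single-copy markers an
ungapped PSSM scan with a conservative E-value is an adequate detector,
and the score-table format is plain TSV so externally built profiles can
be imported. Hits at $E \le 10^{-3}$ are counted once per (read, marker)
and binned taxonomically; a hit whose 2bLCA bin contradicts its
profile's group is counted in its *bin*, because binning happens after
homolog identification.

Density is hits per Mbp, $d = 10^6 \cdot n_{\text{hits}} /
\text{total bp}$; the size-normalised variant divides by the profile's
reference-alignment length $L$ to correct for longer genes collecting
more hits. Markers with zero hits contribute explicit zero densities to
group summaries — omitting them would bias small samples upward. The
per-sample NCLDV:prokaryote ratio $r$ uses the *mean* across markers
(each marker is one estimator of genome density; the mean is the natural
combiner per sample), while the pooled overview across a whole data set
uses the *median* (robust against one marker family dominating); both
modes are exposed. Absolute abundance is
$A = r \cdot \varphi \cdot C$ with $C$ the measured prokaryote cell
concentration (cells/ml) and $\varphi = 0.9$ the assumed fraction of
prokaryotic cells that pass the 1.6-µm glass-fibre pre-filter. When both
flow-cytometry and microscopy counts exist, one estimate per count
source is emitted rather than an average — the two measurements are not
interchangeable and plotting both shows their spread.

### Co-occurrence networks

The taxon-by-sample matrix holds, for every taxonomy node of depth at
most 5, the number of reads annotated at or below that node. The "at
most 5" reading (rather than "exactly 5") is a declared interpretation:
published association tables print taxa of varying depth, which only a
node set spanning several depths can produce. Cells are normalised by
the sample's total read count — ancestor rows double-count reads, so
column sums exceed the totals by design and are not a valid denominator.
Taxa with fewer than 5 total reads are dropped (strictly fewer: a
5-read row stays).

**Method 1** computes Spearman's $\rho$ (average ranks) for every pair
over all samples, the two-sided asymptotic t-approximation p-value
($t = \rho\sqrt{(n-2)/(1-\rho^2)}$, $df = n-2$), and tail-area FDR
q-values ($q(p) = \hat\eta_0\, p\, m / \mathrm{rank}(p)$, monotone,
with $\hat\eta_0$ estimated from the flat right tail of the p-value
histogram). Associations pass at $|\rho| > 0.7$ and $q < 0.05$.
Parent–child pairs are *not* excluded here — such pairs appear among
method-1 results by construction and are left to the reader, matching
the published behaviour.

**Method 2** is more stringent: the two OMZ samples are excluded (their
biome-specific presence/absence patterns would otherwise dominate),
parent–child pairs are excluded, and two measures are computed per
pair — Spearman's $\rho'$ and a symmetrised Kullback–Leibler divergence
(pseudocount $10^{-9}$; low KL ranks as co-presence, high as mutual
exclusion). The top- and bottom-ranking edges of each measure are then
evaluated with the ReBoot scheme: the null permutes the edge's two rows
independently while the rest of the matrix is unchanged, then restores
the compositional bias by renormalising every column to its original
sum; a column bootstrap provides a confidence interval. The edge
p-value is the two-sided normal tail of the observed score's z-score
against the permuted null. The z-based (continuous) p-value was chosen
over an empirical tail after examining both: the empirical tail is
floored at $1/(n_{\text{perm}}+1)$, which destroys the resolution the
downstream combination and FDR steps need at reduced permutation
counts, whereas the z-approximation is well calibrated for both
measures under the renormalised null (type-I rate at $p<0.05$ measured
at 0.04–0.06). The bootstrap distribution is reported as a CI and a
stability flag (CI excludes the null mean) rather than being folded
into the p-value — folding it in deflates the null variance calibration.

The two measure p-values are combined with Brown's method (Fisher's
statistic referred to a scaled $\chi^2$ whose variance absorbs the
covariance of the $-2\ln p$ values, estimated empirically across the
candidate set and clamped to $[0, 4]$), and Benjamini–Hochberg
q'-values are computed over the evaluated candidate set. Two properties
pin the implementation down: with zero covariance Brown reduces exactly
to Fisher, and with duplicated p-value vectors (covariance 4) it
returns the single-test p-value.

**A selection caveat, stated openly.** Evaluating only the top- and
bottom-ranking edges and then correcting within that candidate set is
what the published procedure describes, but it is not distribution-free:
when the candidate lists are a heavily selected sliver of a null
matrix, their p-values are extreme by selection and the within-candidate
BH correction can be anti-conservative. When the candidate set covers
most scored pairs the correction behaves nominally (this regime is what
the null-calibration test exercises). The `top_k` default follows the
published value (1000); for desk-scale matrices it should be scaled to
roughly the same *fraction* of scored pairs as in the original setting
(~1%), which is what the power analyses in this package do.

### HGT screen

A (viral peptide, cellular protein) pair is a transfer candidate when
(i) the cellular protein is the peptide's best cellular homolog at
$E \le 10^{-5}$ and (ii) searching that cellular protein against the
combined cellular+viral database — with every cellular protein sharing
its first three lineage labels masked — returns a viral best hit. The
3-level mask removes the query's own taxonomic group, so vertically
inherited relatives cannot outcompete the putative viral donor; a
*coarser* mask (fewer levels) silences more cellular competitors and can
only enlarge the candidate list. Ties between a viral and a cellular
best hit resolve by bit score and reject on a residual tie
(conservative). Phylogenetic confirmation of candidates is out of scope
by design; the screen emits candidates for external tree building.

## The synthetic-data generators

Every input has a generator with complete ground truth, and all
generators are pure functions of (parameters, seed).

* `make_taxonomy()` builds a labelled tree with the four domains at
  level 1 and NCLDV family labels under the dsDNA node, so virus leaves
  carry realistic lineages.
* `make_reference_db()` draws ancestral proteins per leaf-parent and
  mutates them per leaf (default 10% per leaf, so siblings share ~80%
  identity), exercising the LCA behaviour of the annotator across a
  known mutation ladder.
* `make_marker_profiles()` fabricates single-copy marker consensus
  peptides and their score matrices (emission probability 0.9 for the
  consensus residue against a uniform background). The real marker sets
  (16 NCLDV + 35 cellular genes) are not bundled; the synthetic markers
  have the same formal role with known ground truth.
* `sim_community()` builds compact model genomes (default 2 kb) carrying
  exactly one diverged copy of each applicable marker at evenly spaced
  positions, with lognormal relative abundances scaled so the summed
  NCLDV abundance is exactly `ncldv_fraction` times the prokaryote
  abundance. Identical genome lengths and marker lengths on both sides
  make the NCLDV:prokaryote density ratio an unbiased estimator of the
  planted genome ratio, so recovery error measures counting noise, not
  construction bias.
* `simulate_sample()` draws reads (default 350 bp, matching the
  published per-sample average read sizes of ~250–400 bp) uniformly
  from genomes proportionally to abundance × length, with uniform
  substitution errors; artificial duplicates re-emit an earlier read
  with an identical 5' start, at most 3% divergence and an optionally
  truncated tail. The error model is substitution-only: homopolymer
  indel artefacts are out of scope beyond the duplicate mechanism
  itself.
* `make_coupled_matrix()` draws lognormal-Poisson counts closed to a
  fixed sequencing depth (overdispersion plus compositional closure —
  the two features the ReBoot null is designed for). Planted pairs
  share a latent per-sample log-abundance factor (default scale 2, i.e.
  ~94% of pre-closure log-abundance variance). Pair members are drawn
  from the 35th–75th abundance percentiles: abundant enough to survive
  the sparse-taxon filter, but not so dominant that their shared swings
  move the compositional denominator and induce closure correlations
  across the whole matrix (with very strong, very abundant planted
  factors, *every* taxon pair becomes genuinely correlated through the
  denominator — a real property of compositional data, not a bug, but
  it would make "planted pair recovery" meaningless as a metric).

What the generators do *not* emulate: real marine taxon frequencies,
real marker sequences, 454 homopolymer error profiles, strain-level
variation within taxa, and databases with uneven taxonomic coverage.
Passing tests on this synthetic universe therefore demonstrate the
*correctness of the computations* (each against an independent oracle
or planted truth), not field-accuracy of the biological estimates.

## Problem sizes and numerical choices

The validation suite runs at desk scale, chosen so each check is
statistically meaningful:

* 2bLCA oracle equivalence: 50 simulated 150-bp reads against a
  30-protein, 4-domain database, compared read-by-read (status, lineage
  and the full homolog set H) with a literal brute-force
  re-implementation (pure-R Gotoh alignment with traceback).
* Abundance recovery: 20 samples of 25,000 reads with planted
  NCLDV:prokaryote ratios log-spaced on [0.002, 0.06] (the published
  0.2–5.6% range). At the lowest ratio a sample carries only ~50 NCLDV
  reads, so the ±25% tolerance is dominated by Poisson noise; the
  median absolute relative error lands near 3%.
* Network calibration: 500 random edges of a null 100 × 15 matrix at
  200 permutations + 200 bootstraps per edge; planted-pair power over
  20 replicates of 40 × 15 matrices with 2 planted pairs each,
  `top_k = 10` (~1% of the 780 scored pairs, the published selection
  fraction).
* Duplicate-filter recovery: 10,000 reads at a planted 16% duplicate
  rate (the published overall reduction) over ~2.2 Mb of genome space —
  large enough that same-start read collisions contribute < 0.2
  percentage points.
* HGT: 5 planted transfers among 10 cross-group decoy families and 5
  cellular-homolog-free viral peptides, recovered exactly.

Numerical conventions: all coordinates are 0-based half-open on the
forward strand; lineage separator is ";" with optional spaces; E-value
ties break lexically; with a fixed seed every stochastic result
(including the whole method-2 edge table) is bit-reproducible. Seeds are
taken by every generator and every resampling routine, and the RNG state
of the session is restored afterwards.

## Known limitations

* The built-in aligner is quadratic per pair and meant for desk-scale
  databases; genuine survey-scale searches should come in through the
  tabular adapter.
* Ungapped Karlin–Altschul calibration means absolute E-values differ
  from BLAST's for gapped alignments; thresholds are internally
  consistent but not engine-portable.
* The PSSM marker scanner is ungapped; a marker homolog fragmented by
  an indel inside the scanned window scores lower than a profile-HMM
  would score it.
* The method-2 q'-values inherit the selection caveat discussed above.
* Profile binning of marker hits (`bin_by = "profile"`) equals 2bLCA
  binning only when the marker set is group-pure, as it is for the
  synthetic profiles; with real markers shared across domains the
  2bLCA route is the correct one.
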