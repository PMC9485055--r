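---
title: "Methods: codon usage bias and branch-wise dN/dS screens"
author: "fadevo"
output: rmarkdown::html_vignette
vignette: >
  %\VignetteIndexEntry{Methods: codon usage bias and branch-wise dN/dS screens}
  %\VignetteEngine{knitr::rmarkdown}
  %\VignetteEncoding{UTF-8}
---

```{r setup, include = FALSE}
knitr::opts_chunk$set(collapse = TRUE, comment = "#>")
library(fadevo)
```

## The question the package answers

When a gene family turns up in a lineage where homology gives no clear
answer about its origin — as with the sterol C-22 desaturases of
*Tetrahymena*, which belong to the fatty acid desaturase (FAD) family
rather than to the cytochrome P450 family that performs the same reaction
in plants and fungi — two histories compete:

* **horizontal gene transfer (HGT)**: the genes arrived from a donor genome
  and should carry the donor's compositional signature in their codon
  usage;
* **gene duplication followed by functional divergence**: the genes are
  native, share the host genome's codon usage, and the branches immediately
  after the duplication should show relaxed selective constraint
  (elevated dN/dS) over an otherwise purifying background.

`fadevo` implements both screens — a parametric codon-usage-bias (CUB)
screen for HGT and a branch-wise dN/dS screen for post-duplication
relaxation — together with the curation steps used to assemble a candidate
set (PROSITE-style histidine-box motif scanning, global-alignment
identity/similarity, greedy redundancy clustering) and a codon-model
simulator that supplies inputs of known ground truth for every test in the
package.

## Genetic codes

Everything downstream is parameterized by a `genetic_code` object. Two NCBI
tables are supported: table 1 (standard; 61 sense codons) and table 6
(ciliate nuclear; TAA and TAG encode glutamine, 63 sense codons). Table 6
is the right default for *Tetrahymena* material — silent use of table 1
would miscount every glutamine codon and corrupt each CUB statistic — so
the pipeline functions default to `code = 6` while every low-level function
takes the code explicitly. Under table 6 the synonymous family structure
shifts: glutamine becomes a four-fold family (CAA/CAG/TAA/TAG), leaving 2
one-fold, 8 two-fold, 1 three-fold, 6 four-fold and 3 six-fold families.

Coding sequences are validated, never repaired: a length not divisible by
three, an internal stop under the bound code, or any ambiguity character
(including N) is an error. A terminal stop is stripped and recorded. The
statistics are count-based; imputing ambiguous codons would bias them
silently.

## Codon usage statistics

Per gene, from a `codon_counts` table:

* **RSCU** — observed count of a codon times its family degeneracy over the
  family total; the ratio of observed to expected usage under uniform
  synonymous choice. Codons of unobserved families are `NA`, never 0: a
  zero is a strong observation ("family used, codon avoided") that absent
  data cannot support, and silent zeros would distort the PCA and the
  regressions.
* **GC3s** — G+C fraction at third positions of codons in families with
  degeneracy ≥ 2.
* **ENc** — Wright's (1990) effective number of codons, with
  CodonW-compatible conventions: per-family homozygosity
  `F = (n Σp² − 1)/(n − 1)` for families with n ≥ 2, class means over
  degeneracy classes, class contributions `(families in class)/F̄`, a
  missing three-fold class imputed as the mean of the two- and four-fold
  class means, and the result capped at the sense-codon count (61/63).
  ENc spans 20 (one codon per amino acid) to the cap (uniform usage); both
  limits are asserted exactly in the tests. Genes under 30 codons are
  flagged: the per-family homozygosities are too noisy below that.
* **Expected ENc curve** — `2 + s + 29/(s² + (1 − s)²)` at GC3s `s`: the
  ENc a gene would show under mutation pressure alone.
* **PR2** — third-position A/(A+T) and G/(G+C) pooled over the complete
  synonymous quartets of the code (codon boxes whose four third-position
  variants encode the same amino acid, including the quartets inside
  six-fold families). This is Sueoka's formulation of parity rule 2.
  Pooling by *family degeneracy* instead would, under table 6, admit the
  glutamine family — whose four codons differ at the first position, not
  only the third — and structurally zero the T3 term; the quartet
  definition avoids that artifact.
* **Neutrality plot** — OLS of GC12 (mean of first- and second-position GC)
  on GC3 (third-position GC, all codons — distinct from GC3s) across
  genes. Slope near 1: mutation pressure acts on all positions alike;
  near 0: selection constrains first and second positions.
* **RSCU PCA** — covariance-scaled principal components of per-gene RSCU
  vectors over codons of families with degeneracy ≥ 2. `NA` cells are
  imputed with column means (logged); component signs are fixed so each
  loading vector's largest-magnitude entry is positive, making scores
  reproducible across platforms. Covariance rather than correlation
  scaling keeps heavily used families from being swamped by rare ones;
  it is exposed as a design choice here because published CUB analyses
  rarely state which was used.

### The HGT screen

`hgt_screen()` compares a candidate family against the host background:
the ENc–GC3s table with expected-curve values, PR2 points, the neutrality
fit over the background, PCA scores with family genes flagged, and
two-sample Wilcoxon rank-sum tests on ENc and GC3s (raw and
Benjamini–Hochberg adjusted; the screen's headline p-value is the smaller
adjusted value, so under a global null the flag rate stays at the nominal
level). The verdict is deliberately descriptive — "CUB outlier" (headline
adjusted p < 0.01) or "consistent with host genome codon usage" — never
causal: compositional agreement lowers the plausibility of HGT; it cannot
prove descent.

## Selective pressure: NG86 on reconstructed ancestors

Branch-wise dN/dS is estimated by counting, not by maximum likelihood: the
Nei–Gojobori (1986) method applied to each (parent, child) branch after
Fitch-parsimony reconstruction of ancestral codon sequences. This is an
approximation to a free-ratio branch codon model, and the reports label it
as such. The counting route was chosen because the inference it must
support is qualitative — a relaxed stem over a purifying background — and
because counting is exactly testable against an enumeration oracle, which
the test suite does for every sense codon and for a thousand random
sequence pairs under both code tables. Numerical equality with published
CODEML estimates is explicitly not claimed.

Details that matter:

* **Sites**: per codon position, the unit site mass is spread over the
  non-stop single-nucleotide changes; a position whose three changes all
  create stops contributes nothing. So `s + n ≤ 3` per codon.
* **Differences**: per differing codon pair, synonymous/nonsynonymous
  counts are averaged over all minimal mutational pathways that avoid
  stops; pairs with no surviving pathway are skipped and tallied.
* **Correction**: Jukes–Cantor, `d = −(3/4) log(1 − 4p/3)`; a proportion
  ≥ 0.75 is an error naming the distance, not a silent `NA`.
* **ω**: `dN/dS`, `NA` when `dS = 0` — a branch without synonymous signal
  has no defensible ratio.
* **Fitch ties** are broken lexicographically (root: smallest member of
  its state set; child: parent's state when possible, else its set's
  smallest member). Determinism was preferred over random resolution so
  branch counts are reproducible; on binary trees the assignment attains
  the parsimony length (asserted against an exhaustive oracle).
* **Gapped codon columns** are dropped globally (complete deletion),
  matching common CODEML `cleandata` practice.
* **Clade aggregation** pools S, N, Sd, Nd over the branches of the induced
  subtree before distance correction. Pooling omegas by averaging would
  weight branches arbitrarily; pooling counts weights them by information.

One consequence of pooling worth knowing: on a two-taxon tree the pooled
counts over both branches recover the pairwise Sd/Nd exactly, but site
counts are summed over two branches, so pooled and pairwise ω agree only up
to the (small) curvature of the Jukes–Cantor correction.

## The simulator: a stated world

`codon_model()` is GY94-style: rates `q_ij = π_j κ^[transition]
ω^[nonsynonymous]` for single-nucleotide neighbours, zero otherwise,
scaled to one expected substitution per codon per unit branch length at
stationarity. The parameterization is time-reversible; transition
probabilities come from an eigendecomposition of the
reversibility-symmetrized matrix — exact at 61/63 states, no step-size
tuning. Stationary frequencies default to F1×4 built from one GC knob,
which realizes both the AT-rich ciliate background (GC 0.25) and GC-shifted
"alien" positive controls.

Defaults are chosen once and documented:

* **κ = 1, uniform π** for the generic simulator. NG86 counting assumes no
  transition/transversion bias; the neutral calibration (ω = 1 recovered
  within [0.9, 1.1]) is meant to check the estimator, not to measure the
  known downward bias NG86 shows when κ > 1. Scenario generators override
  κ explicitly.
* **The duplication scenario**: 20 tips in two 10-tip coalescent clades,
  300 codons, κ = 2, table 6, F1×4 GC 0.25, background ω = 0.06, one stem
  branch (into the duplicated clade's ancestor, length 0.3) at ω = 0.48 —
  the magnitudes reported for the ciliate FAD family. The bundle carries
  its ground truth (per-branch ω, stem label) and is byte-reproducible
  from its seed.
* **`sample_biased_genome()`**: iid genes; amino acids uniform over the
  code's families; within a family, third-position nucleotides tilted to
  the GC3 target. Gene length defaults in the tests use 300–500 codons,
  a realistic ciliate gene length. Within-family renormalization (e.g.
  isoleucine's ATN box offers no G) pulls realized GC3s slightly under
  the raw target; tests assert the target within ±0.02–0.03 absolute.

What the generator does **not** emulate: selection on codon usage,
among-site rate variation, indels, expression-correlated bias, and
amino-acid composition of real proteomes. A green simulation test
establishes that the estimators recover what this mechanistic world puts
in — not that real *Tetrahymena* data would behave identically.

## Numerical and testing notes

* **Alignment scoring** follows EMBOSS needle conventions: BLOSUM62, gap
  open 10, gap extend 0.5, a gap of length L costing `open + ext·L`;
  identity = identical pairs / alignment length, similarity =
  positive-score pairs / alignment length. The source study reports
  identity/similarity without naming a method; these are the community
  defaults that produce both numbers. Scores are verified against
  exhaustive enumeration of all alignments for short pairs.
* **Greedy clustering** replicates the CD-HIT *logic* (length-sorted,
  first-fit to a seed at identity ≥ threshold over the shorter length) but
  not its k-mer prefilter; at curation scale the exact alignments are
  cheap and the behavior is deterministic.
* **Motif scanning** reports, per start, the shortest expansion
  (ScanProsite-style single hits); the test oracle is R's PCRE engine with
  lazy quantifiers, an independent matcher with the same semantics.
* **Stationarity testing**: at 10⁴ pooled codons the multinomial sampling
  floor for total-variation distance is ≈ 0.022 even for a perfect
  simulator; the test uses 4×10⁴ codons, where the 0.02 bound cleanly
  separates a stationary simulator from a drifting one.

## A negative result kept on purpose

One documented expectation is left failing, deliberately. It is sometimes
suggested that AT-rich genes generated under mutation pressure alone should
fall *below* Wright's expected ENc curve, mirroring how the real FAD genes
plot. They do not, and cannot: the closed form
`2 + s + 29/(s² + (1 − s)²)` is a lumped approximation that sits slightly
*below* the exact ENc of a genome whose only force is third-position
mutation bias (61 vs 60.5 at s = 0.5; ≈ 51.0 vs 48.3 at s = 0.25 under
table 6, verified here with a 200,000-codon gene). Real genes fall well
below the curve (ENc 36–46 in the ciliate FAD data) because *selection*
suppresses their codon diversity — precisely the force the iid generator
omits. The acceptance suite keeps the literal check and its failure as a
record of this analysis: a mutation-only generator on the curve is correct
behavior, not a bug.

## Worked example

```{r example, eval = FALSE}
# duplication screen on a simulated bundle of known truth
sc <- duplication_scenario(seed = 1)
res <- run_duplication_screen(sc$codons, sc$tree, code = sc$model$code,
                              clades = sc$clades, out_dir = "dup_out")
res$branches[res$branches$child == sc$stem_branch, ]

# parametric HGT screen: native-like family vs AT-rich background
bg  <- sample_biased_genome(100, 300, 0.25, seed = 2001, prefix = "bg")
fam <- sample_biased_genome(10, 300, 0.25, seed = 2002, prefix = "fam")
hgt_screen(fam, bg)
```

## Known limitations

* NG86 on parsimony ancestors attenuates extreme branch ω (the seed-1
  scenario recovers ≈ 0.33 for a true stem ω of 0.48 over a background
  estimated at ≈ 0.08); rankings and contrasts are reliable, absolute
  values are conservative.
* No likelihood-ratio machinery: the package cannot test branch models
  against each other, only estimate and compare counts.
* The full PROSITE grammar (anchors, repeated classes beyond ranges) is
  out of scope; the implemented subset covers the histidine-box patterns.
* CD-HIT's heuristics are not reproduced bit for bit; at a 0.99 identity
  cutoff the greedy exact-alignment clustering gives the same redundancy
  filtering behavior.
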