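---
title: "Mining actinobacterial cellulose-utilization systems: methods and design"
output: rmarkdown::html_vignette
vignette: >
  %\VignetteIndexEntry{Mining actinobacterial cellulose-utilization systems: methods and design}
  %\VignetteEngine{knitr::rmarkdown}
  %\VignetteEncoding{UTF-8}
---

```{r setup, include = FALSE}
knitr::opts_chunk$set(collapse = TRUE, comment = "#>")
library(celluminer)
```

## The problem

Aerobic cellulolytic actinobacteria degrade cellulose with free (non-
cellulosomal) enzymes: endocellulases that cut chains internally,
exocellulases (cellobiohydrolases) that processively release cellobiose
from reducing or non-reducing chain ends, and processive endocellulases
that combine both modes. The released cellobiose is imported by an ABC
transporter and hydrolysed intracellularly by β-glucosidases (or
phosphorolysed by cellobiose phosphorylase). In *Thermobifida fusca* the
whole system is controlled by CelR, a LacI-family repressor that binds a
14-bp palindromic operator and releases it when cellobiose accumulates.

`celluminer` turns the comparative-genomics side of this biology into a
reusable, fully testable pipeline: given an annotated high-GC genome and
a protein domain table it

1. inventories glycoside hydrolase (GH) family enzymes and classifies
   their predicted activity and domain-architecture type,
2. scans the genome for CelR-like degenerate palindromic operator sites
   within a mismatch budget,
3. partitions genes into operons and predicts the regulon controlled by
   each operator, including cellobiose ABC-transporter operons, and
4. can rediscover operator motifs de novo from upstream regions with a
   ZOOPS expectation-maximization search.

Because the organisms of interest are published genomes that cannot be
shipped, a seeded synthetic-genome generator reproduces every relevant
feature of the real inputs with known ground truth; all correctness
claims in the test suite are made against that ground truth.

## Operator model and mismatch arithmetic

An operator consensus is a fixed-width pattern whose position *i* allows
a non-empty subset of {A,C,G,T} — written either in IUPAC one-letter
code (`TGGGAWCGWTCCCA`) or in the literature's alternate notation
(`TGGGA(A/T)CG(A/T)TCCCA`). A window base *matches* a position iff it is
a member of the allowed set; there is no partial credit, and an `N` in
the genome never matches. This is the simplest rule consistent with the
integer mismatch counts used to describe operator variants ("a site with
one mismatch", "one base change per half-site"), and it makes mismatch
counts of a window and its reverse complement equal whenever the
consensus is palindromic — which is what licenses reporting a palindrome
hit once per locus with strand `"."`.

The shipped CelR 14-mer, `TGGGAGCGCTCCCA`, is a **reconstruction**: the
operator's sequence is known from the *T. fusca* CelE operator
literature rather than printed alongside the variant annotations this
package reproduces. The reconstruction is pinned down by requiring that
every published variant annotation holds simultaneously —
`TGGGAACGCTCCCG` at two mismatches, `TGGGAGCGCTCCAT` at two,
`TGAGAGCGCTCTCA` at one change per half-site, `GGAGAGCGCTCTCC` at two
per half-site — together with perfect palindromy. Those constraints are
the acceptance tests; any failure falsifies the reconstruction. The
consensus is a plain argument everywhere, so a user can override it.

### Scanning

`scan_genome()` integer-encodes each contig and accumulates, for each of
the *w* pattern positions, an indicator of disallowed bases over all
windows — O(wL) with vectorized inner loops. Hits on both strands are
enumerated; for palindromic consensi forward/reverse hits at one locus
are collapsed to a single strand-`"."` hit carrying the forward mismatch
count (no information is lost, by the symmetry above). Non-palindromic
degenerate sites are *not* collapsed: reported counts are (start,
strand) loci. Overlapping hits are all reported; there is no greedy
masking. Site counts quoted per genome are computed over all contigs of
the assembly. The scanner is verified in the test suite against a naive
oracle that enumerates every window on both strands and applies
`count_mismatches()` directly.

## Operons, upstream windows, regulons

Operons are called with the standard annotation-only rule: runs of
adjacent genes on one contig and strand with every intergenic gap
strictly below 100 bp (`build_operons()`, threshold configurable). The
strict inequality matters at the boundary and is exercised explicitly by
generated genomes with 99/100-bp gaps. Same-strandedness is required
even though the distance rule alone would not demand it: divergent genes
cannot be co-transcribed.

Upstream regions are the 300 bp 5′ of an operon leader's translational
start on its coding strand, truncated at contig edges and deliberately
*not* truncated at a neighbouring gene: operator sites commonly overlap
a neighbour's 3′ end. A site is assigned `upstream` of every operon
whose leader window overlaps any part of it — a site between divergent
promoters legitimately gets two rows — else `intragenic` if it overlaps
a CDS, else `unassigned`. Reported offsets are the distance from the
target's start to the nearest site base, clamped into [1, window], so
users can re-filter with their own distance cut-offs. Assignment is to
the operon, so internal operon genes inherit regulation through their
leader, matching how operator sites are interpreted for multi-gene
transcription units.

Cellobiose ABC-transporter operons are detected structurally: a window
of up to 8 consecutive genes containing at least one sugar-ABC
substrate-binding protein and two permease components, annotated with
whichever optional members (ATPase, GH1/GH3 β-glucosidase, LacI
regulator, aldose 1-epimerase, GH94 cellobiose phosphorylase) are
present. The 8-gene bound is a declared operational choice; published
clusters are 4–6 genes. Detection works from an editable domain-label →
role map (with product-string regexes as fallback) because the original
identification route — similarity to a characterized *Streptomyces
reticuli* cellobiose transporter — needs a reference database that
cannot be shipped. One cluster is reported per transporter core: the
minimal window covering the core is grown over adjacent role-bearing
genes, rather than reporting every shifted window containing the core.

## Cellulase classification

Family membership is read from a domain-label → GH-family map (Pfam
names and bare family names both accepted). Family alone fixes activity
where the biology is unambiguous: GH48 enzymes are reducing-end
exocellulases; GH5, GH8, GH12 and GH51 catalytic domains are labelled
endocellulase with no subfamily logic. Two families need more:

* **GH9** — processive endocellulases carry the "Theme B" architecture:
  GH9 catalytic domain followed by CBM3, an fn3 domain, and a CBM2 or a
  second CBM3. `classify_gh9()` tests whether that chain is a
  subsequence of the protein's N→C domain layout; anything else is a
  non-processive endocellulase. The call depends only on domain order,
  never on coordinates.
* **GH6** — the family splits into an exocellulase clade and an
  endocellulase clade that domain content cannot separate. Instead of
  phylogenetic placement (external tools, non-deterministic across
  runs), `classify_gh6()` scores the catalytic domain against a labelled
  anchor set by deterministic local alignment (BLOSUM62) and returns the
  best anchor's label, abstaining (`unknown`) on ties or when the best
  score falls below a floor of 150 — set above the score range that
  shuffled query sequences reach against the shipped anchors (≲115), and
  far below genuine within-clade scores (~1000). The shipped anchor
  FASTA is a *synthetic* stand-in (two divergent sequence families
  mimicking the two-clade structure, generated from a fixed seed);
  production use should replace it with real catalytic-domain sequences
  via the `references` argument.

Architecture typing encodes the conserved CBM-placement dichotomy: for
GH48 and GH6 *exo*cellulases an N-terminal CBM marks type I
(*Thermobifida*-like) and a C-terminal CBM type II (*Cellulomonas*-
like); for GH6 *endo*cellulases the arrangement is reversed. No CBM, or
CBMs on both sides, is `untyped`. `system_type()` then calls a genome
`Thermobifida_type_I` / `Cellulomonas_type_II` when all typed enzymes
agree, `mixed` when both occur, `undetermined` when nothing is typed.
Pseudogene calls are produced and flagged but never enter totals.

All classification is deterministic: ties abstain rather than being
broken randomly.

## ZOOPS-EM motif discovery

`discover_motif()` re-implements the classic operator-discovery
configuration: zero-or-one motif occurrence per sequence (ZOOPS), motif
width 6–20, both strands, 0-order background estimated from the input
(strand-symmetrized — appropriate for high-GC inputs). For each
candidate width the E-step computes, per sequence, a posterior over site
positions on both strands and over site presence; the M-step
re-estimates the PWM with a pseudocount of 0.25 per base and the site
prior γ as the mean presence posterior. The pseudocount makes the
M-step a MAP update under a Dirichlet(1.25) prior on PWM columns, so
the quantity EM provably never decreases is the *penalized* objective
(data log-likelihood plus 0.25·Σ log p); that objective is what the
reported trace records and what the test suite asserts to be monotone
for every run, while the data log-likelihood alone (reported up to the
constant background term) is used for model comparison. Iteration
stops when the objective changes by less than 1e-6, or at 500
iterations.

EM on motifs is multimodal, so initialization is treated seriously:
40 candidate seeds per width, each derived from one input subsequence,
are pre-screened by their one-step ZOOPS likelihood; the best four are
run 20 iterations; the best of those is run to convergence; converged
models are re-seeded at ±1–2 column shifts (phase refinement); and each
width also inherits the previous width's converged PWM extended by a
background column (cross-width seeding). Everything is driven by one
seed, restored afterwards, so results are bit-reproducible.

**Width selection.** Widths compete on a penalized log-likelihood with
3·width free parameters. A subtlety dominates the penalty's scale: for a
palindromic core the two-strand alignment freedom lets every site
present whichever flank base fits an added edge column better, so the
likelihood gain of widening past the true motif grows in proportion to
the number of sites — classic information criteria, whose penalty grows
only logarithmically, then select ever-wider motifs. The per-column
penalty is therefore floored at 0.55 nats per expected site
(γ·n\_seq): safely above that selection gain, and below log 2 ≈ 0.69,
the per-site contribution of a genuine two-base degenerate column, so
real degenerate positions (e.g. the (A/T) columns of operator variants)
are never sacrificed. Edge columns with under 0.5 bits of information
content are additionally trimmed from the selected model and the fit
re-converged. `pwm_to_consensus()` (allowed set = bases with probability
≥ 0.25, argmax always included) bridges discovered PWMs back to the
degenerate notation the scanner consumes.

## The synthetic-genome generator

`generate_synthetic_genome()` is first-class, tested code, and its
defaults *are* the study conditions the rest of the package is verified
under: GC 0.70 chromosomes (the actinobacterial range), gene models on
both strands with operon sizes 1–4 and intergenic gap sampling that
deliberately straddles the 100-bp boundary (including exact 99/100-bp
gaps), CelR sites planted at 0 or 1 mismatches at offsets within the
300-bp upstream windows of designated operon leaders plus an intergenic
site, one protein of each major cellulase architecture, and a
five-gene cellobiose-transporter cluster modelled on the *T. fusca*
arrangement (a four-gene variant without β-glucosidase models the
*C. flavigena* exception). Default sizes — 12 operons, ~30 genes,
~40 kb — were chosen as the smallest layout in which every structural
feature (boundary gaps, divergent neighbours, multiple targeted
leaders) occurs; tests that need long contigs raise `n_operons`.

Details that make recovery testing exact rather than probabilistic:

* **Background scrubbing.** After assembly the generator brute-rescans
  the genome and mutates one base of every chance occurrence of a
  planted consensus within the scan budget (never touching planted
  sites), iterating until clean — so planted counts are exact by
  construction, and a failed count is a scanner bug, not bad luck.
* **Translation consistency.** Genes carrying planted architectures get
  protein sequences reverse-translated into GC-biased codons, with
  amino-acid composition itself biased toward GC-rich codons
  (Ala/Gly/Pro/Arg-heavy), mirroring high-GC proteomes and keeping
  ≥50-kb contigs within ±2 GC points of specification. If a scrub
  mutation lands in annotated coding sequence, translations are
  re-derived so annotation and sequence stay consistent. Plain genes
  carry no protein sequence — generation stays cheap.
* **GH6 recoverability.** Planted GH6 proteins splice an anchor-derived
  catalytic core, perturbed at a 5% substitution rate, into a random
  backbone, so nearest-anchor classification is tested against genuine
  sequence noise rather than identity.
* **Determinism.** One seed fixes everything, including emitted GenBank/
  GFF3/FASTA/TSV/JSON files byte-for-byte.

What the generator does *not* emulate: real codon usage and promoter
structure, repeat content, mobile elements, operator-site clustering
biology, or the phylogenetic correlation structure of real proteomes.
Passing recovery tests therefore demonstrates the pipeline's logic and
arithmetic — coordinate conventions, rule boundaries, classification
order-dependence, count exactness — not that the biological predictions
on real genomes are correct. Genome-scale validation against the
published assemblies needs their multi-megabase downloads and ships
separately in `scripts/validate_published_genomes.R`.

## Numerical and degenerate-input choices

* Coordinates are 0-based half-open internally; conversion happens only
  in `genome_io` readers/writers. The invariant `translate(spanned
  sequence) == annotated translation` is tested on generated genomes.
* `N` bases are accepted in contigs and never match any consensus
  position; windows of discovery sequences containing `N` contribute
  background-only likelihood.
* EM convergence: absolute log-likelihood change < 1e-6, cap 500
  iterations; PWM rows are kept strictly positive by the 0.25
  pseudocount; γ is clamped to [1e-4, 1].
* Classification ties (GH6 exo-vs-endo score ties, CBMs on both sides of
  a catalytic domain) abstain — `unknown` / `untyped` — rather than
  being broken arbitrarily.
* Problem sizes in the test suite (200 × 5-kb oracle contigs, 100
  recovery genomes, 50 discovery replicates at 20 × 300 bp) are the
  package's declared verification conditions; they keep the full suite
  in the tens of minutes on one core.

## Known limitations

* The GH6 anchor set is synthetic; until replaced with real catalytic
  domains, GH6 exo/endo calls on real proteins should be treated as
  placeholders (the classification *mechanics* are what the package
  tests).
* Whether published per-genome site counts collapsed strands for
  non-palindromic variants is not documented; this package counts
  (start, strand) loci for non-palindromes and collapsed loci for
  palindromes, and genome-scale comparisons should expect deviations
  explainable by that convention.
* No statistical model of site-count significance is provided; counts
  are exact pattern-match counts.
* SignalP-style secretion predictions are accepted as an optional
  annotation column but never computed.
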