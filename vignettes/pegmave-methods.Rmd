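---
title: "Designing and scoring curated prime-editing variant libraries"
output: rmarkdown::html_vignette
vignette: >
  %\VignetteIndexEntry{Designing and scoring curated prime-editing variant libraries}
  %\VignetteEngine{knitr::rmarkdown}
  %\VignetteEncoding{UTF-8}
---

```{r setup, include = FALSE}
knitr::opts_chunk$set(collapse = TRUE, comment = "#>")
library(pegmave)
```

# The experiment this package models

A curated-locus prime-editing MAVE scores the disease-gene variants that
actually occur in ClinVar and gnomAD, rather than saturating every
codon. A library of engineered pegRNAs (epegRNAs) installs one single
nucleotide variant per cell in a haploid line; cells are selected on the
function of the gene; and the variant composition of selected versus
unselected pools is read out by high-depth amplicon sequencing. The
enrichment of each variant between the two pools, combined across
biological replicates, is its functional score.

`pegmave` implements every computational stage of that experiment:
catalog curation, epegRNA/nicking-gRNA design and oligo emission, k-mer
based quantification, and random-effects scoring — plus a simulator that
generates statistically realistic inputs so the whole stack can be
validated end to end.

# Variant curation and truth sets

ClinVar and gnomAD web exports drift in column naming, so both parsers
address columns through a logical field map with documented defaults and
tolerate extra columns. Only single-nucleotide variants are designable;
anything else is returned in a rejects table with a reason rather than
silently dropped. ClinVar SNVs are resolved from the Canonical SPDI
column (0-based positions, converted to 1-based records).

Classification is a pure function of (source, consequence, significance
text, allele count): pathogenic/likely-pathogenic missense becomes PLP,
benign/likely-benign becomes BLB, uncertain becomes VUS. Compound or
conflicting significance strings ("Likely benign, other", "Conflicting
classifications…") are conservatively classed OTHER — a deliberate
choice: controls anchor the assay's calibration, so ambiguous labels
must not enter the control sets. gnomAD variants at or above a minimal
allele count become population controls (POP_SYN / POP_MISSENSE). The
default `ac_min = 5` suits autosomal-dominant genes; for recessive genes
the threshold must rise steeply, since even well-known pathogenic
alleles can reach allele counts near 20,000.

Two truth sets gate the experiment: the assay-validation set (population
synonymous negatives vs designed stop-gain PTC positives) and the
clinical set (BLB vs PLP). `validate_truth_sets()` enforces the
recommended minimums — 20 synonymous, 20 PTC and 25 clinical variants —
and reports every unmet minimum. PTC controls are enumerated
exhaustively within each selected editing window; substitutions in the
final codon of the last coding exon are excluded because a stop there
does not truncate the protein meaningfully.

# Design geometry

The prime-editing geometry is not stated by the protocols this workflow
follows in the field, so the defaults encode standard practice and every
one of them is a `design_params()` argument:

| parameter | default | meaning |
|---|---|---|
| nick position | between protospacer bases 17/18 | SpCas9 nickase cut, 3 nt 5′ of the NGG PAM |
| `pbs_len` | 13 nt | primer-binding site, reverse complement of the bases 5′ of the nick |
| `rtt_3p_homology` | 10 nt | post-edit homology in the RT template |
| `max_edit_offset` | 30 nt | farthest edit downstream of the nick |
| `ngrna_offset_range` | 40–90 bp, prefer 60 | PE3 nick-to-nick distance |
| `library_cap` | 60 | epegRNAs per library |
| `min_archetypes` | 12 | archetypal epegRNAs to pre-screen |

Window selection is a greedy cover: each pick maximises the number of
not-yet-covered variants of the strategy class (`vus` maximises VUS
density; `controls` maximises ClinVar PLP/BLB coverage), with ties
broken by the other strategy's score, then leftmost nick, then strand —
every tie-break is lexicographic so identical inputs give byte-identical
order sheets. Oversubscribed windows are truncated to the library cap by
class priority (strategy class, then clinical controls, then PTC and
population controls, then position), which protects the truth sets
before filling with lower-priority variants.

Each epegRNA is assembled as spacer + scaffold + RT template + PBS +
tevopreQ1 motif. The RT template is the reverse complement of the
edited-strand segment from the nick through the edit plus the homology
tail, with the variant substituted; a leading G is prepended to the
spacer only when it does not already start with G (U6 initiation).
Designs whose epegRNA would contain a BsaI recognition site, or a
homopolymer run of five in the variable segments, are **flagged, never
silently mutated** — the flag policy extends to PAM-disrupting silent
co-edits, which this package deliberately does not introduce because
they would change the assayed allele. The homopolymer check covers the
variable spacer/RTT/PBS segments; the constant scaffold itself contains
a five-adenine run that is synthesis-proven, so flagging it on every
design would make the flag useless. Every constructed design is
self-checked at build time: synthesising the 3′ flap from the RT
template and copying it onto the nicked strand must reproduce the
reference locus with exactly the one intended substitution.

The exact scaffold and 3′ motif sequences are shipped as configurable
constants sourced from the prime-editing plasmid literature
(`pe_constants()`), as are the Golden-Gate acceptor junctions: the
oligo-pool entries carry constant 20-nt primer-landing tails, the two
constant amplification primers append BsaI sites via 5′ extensions, and
the in-silico round trip (`simulate_golden_gate()`) PCRs, digests and
ligates each entry into a modelled acceptor whose overhangs match the
tail junctions, recovering the epegRNA core exactly. The model keeps the
landing tails inside the cassette as constant vector-junction sequence;
since real acceptor maps vary by lab, the junctions are configuration,
not contract.

# Quantification

Variants are quantified by dictionary-restricted k-mer counting. The
dictionary holds one k-mer per variant — the k-window centred on the
edited base in the edited amplicon, shifted minimally at amplicon edges
— plus one wild-type window per editing window. k defaults to 25 and
must be odd, so no k-mer can equal its own reverse complement; global
uniqueness (including across reverse complements) is enforced at build
time and collisions abort the build with the offending pair named.

Counting follows k-mer-counter semantics: every read offset is a
potential occurrence (not once-per-read), windows containing N never
match, canonical mode accepts a window equal to the k-mer or its
reverse complement, and base qualities are ignored. The implementation
uses Biostrings' preprocessed dictionary matching; the test suite pins
it against a naive two-strand sliding-window scan on hundreds of random
FASTQ files. Read-1 and read-2 counts are summed per sample — the
downstream score is a ratio of frequencies, so it is invariant to this
merge choice. Depth QC requires at least 200,000 reads per sample
(inclusive at the boundary).

# Scoring

Allele frequency is count over sample depth. Variants below 0.1%
frequency in the unselected pools are excluded before scoring: such
variants (low editing efficiency or low pool abundance) produce
out-of-range scores with high replicate variance. The test is strict —
a variant exactly at 0.1% is retained — and the conservative default
excludes on any low control replicate (`any_replicate`), configurable
to `all_replicates`.

Per-replicate scores use natural-log enrichment with 0.5 pseudocounts
and count-reciprocal variances; replicates are combined by the
closed-form DerSimonian–Laird random-effects estimator. DL was chosen
over likelihood-based heterogeneity estimates because it is
deterministic, has no convergence failures, and matches the
random-effects framework recommended for MAVE count data. The suite
verifies the estimator against closed forms and against an independent
meta-analysis implementation (metafor) on a thousand random fixtures.
Cross-library normalisation centres each library's neutral anchor
(synonymous + BLB median) at zero, optionally rescaling by the absolute
PTC median; libraries with fewer than three anchors are left
unnormalised with a warning rather than shifted on noise.

Truth-set separation is reported as rank-based AUROC (synonymous vs PTC
and BLB vs PLP), oriented as the probability that a negative-control
variant scores above a positive-control variant, which is the natural
direction for a depletion selection.

# The simulator

`sim_config()` fixes the study conditions: a 3 kb gene with four coding
exons; a catalog of 40 VUS, 15 PLP, 15 BLB, 25 population synonymous
and 10 population missense variants plus 20+ PTC controls; per-variant
editing efficiency drawn from Beta(2, 6) (right-skewed, mean 0.25 —
matching the qualitative variability of prime-editing efficiency);
all-or-none variant dropout at 33%, the aggregate rate reported for
this kind of curated library; a depletion selection with fitness 0.2
for PTC and PLP variants; 300,000 read pairs per sample at 2 × 150 bp
with a 0.1% per-base error rate; and three biological replicates.

The locus generator samples coding sequence with codon usage biased
toward codons rich in synonymous and stop-gain single-nucleotide
neighbours, then plants the catalog into the two candidate editing
windows with the best truth-set capacity, at least 300 bp apart. A
sampled sequence without sufficient capacity is rejected and redrawn
from a deterministic sub-seed (at most 25 attempts), so generation is
reproducible and always satisfies the truth-set minimums. Selection is
modelled multiplicatively on pool fractions with a wild-type remainder;
between-replicate lognormal jitter (σ = 0.15) gives the random-effects
model real heterogeneity to absorb. Reads are drawn multinomially from
the allele fractions; amplicons are 240 bp so both 150-bp mates cover
the central k-mer window, making each true allele copy contribute one
occurrence per mate.

What the simulator does **not** emulate: position-dependent Illumina
error profiles, PCR duplicates and jackpotting, FACS gating noise,
partial (heterozygous-like) editing outcomes, and correlated dropout
between neighbouring variants. Passing end-to-end tests therefore
demonstrates that the analysis recovers known truth under idealised
noise, not that any particular wet-lab dataset will separate as
cleanly.

# Numerical and interface choices

* Coordinates are 1-based inclusive everywhere, records and internals
  alike — the native R and Bioconductor convention; SPDI input is
  converted on parse.
* All tie-breaks (window selection, nicking-guide choice, truncation)
  are lexicographic and documented, so outputs are reproducible
  byte-for-byte.
* Every stochastic step derives its stream from a single integer seed
  through a fixed hash, keeping derived seeds valid 32-bit integers.
* Problem sizes in the shipped tests: the shared fixture designs ~120
  epegRNAs on one synthetic locus; counter-vs-oracle equivalence runs
  100 random FASTQ files; the estimator equivalence runs 1000 random
  fixtures; the end-to-end check runs one full default simulation and
  20 pool simulations for the dropout aggregate.
* The archetype check counts one archetypal epegRNA per candidate
  window with at least one reachable variant, against the recommended
  pre-screen minimum of 12.

# Known limitations

* Only single-nucleotide variants are designed; inframe indels are
  parsed as rejects, by scope.
* Screening-primer design is out of scope (an external primer-design
  tool is the right instrument); `validate_amplicon()` only validates a
  proposed pair against length, uniqueness and target clearance.
* The random-effects model scores each variant independently; no
  mixture model is fitted over the score distribution, and clinical
  evidence-strength calibration is left to dedicated frameworks.
* The Golden-Gate round trip models one acceptor topology; exotic
  multi-fragment assemblies are not simulated.
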