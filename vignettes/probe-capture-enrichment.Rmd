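---
title: "Probe-capture enrichment of amoA genes: models, parameters and design choices"
output: rmarkdown::html_vignette
vignette: >
  %\VignetteIndexEntry{Probe-capture enrichment of amoA genes: models, parameters and design choices}
  %\VignetteEngine{knitr::rmarkdown}
  %\VignetteEncoding{UTF-8}
---

```{r setup, include = FALSE}
knitr::opts_chunk$set(collapse = TRUE, comment = "#>")
library(amoacap)
```

# Scope

`amoacap` models targeted-gene enrichment sequencing of *amoA*/CuMMO genes
end to end: probe design over a curated reference collection, an in-silico
rendition of the wet-lab experiment (plasmid mock communities, solution
hybrid selection, LM-PCR, paired-end and amplicon sequencing), and the
de-novo OTU workflow with RPKMS quantification, taxonomy and trees. This
vignette explains the models behind each stage, the tunable parameters and
their defaults, what the synthetic-data generator does and does not emulate,
and the numerical conventions that make every run reproducible.

# The mock community and its closed forms

The validation substrate is an equimolar set of six circular constructs,
each a shared random vector backbone of 2739 nt carrying one synthetic
*amoA*-like insert. Default insert lengths are 654, 702, 738, 768, 792 and
846 nt (mean 750), spanning the length range typical of *amoA* coding
sequences; the molar dilution series adds an empty 2786 nt vector at
`2 : x` molar parts. Three expectations are available in closed form for a
community with ratios $r_i$, insert lengths $g_i$ and total lengths $G_i$:

* insert base fraction $\sum_i r_i g_i / \sum_i r_i G_i$ — with the
  defaults, 0.2150, i.e. 21% to the nearest percent;
* contained-fragment probability for fragments of length $L$ placed
  uniformly on the circle,
  $\sum_i r_i \max(g_i - L + 1, 0) / \sum_i r_i G_i$ — at $L = 200$,
  0.1579. This is the expected mapped-read ratio of an unenriched shotgun
  sample, and the gap to 21% is exactly the edge-straddling fragments that
  fail to map;
* gene copies per nanogram, the mass balance
  $\sum_i r_i n_i / (\sum_i r_i G_i\, m_{bp})$ with
  $m_{bp} = 650\,\mathrm{g\,mol^{-1}} / N_A$. The 650 g/mol per-base-pair
  convention is the common dsDNA figure; the order-of-magnitude conclusions
  are insensitive to any choice in 615–660 g/mol. At 2 : 1000 the default
  community holds $6.6\times 10^5 \approx 10^6$ copies/ng.

```{r closed-forms}
genes <- generate_gene_family(seed = 1)
mock <- build_mock(genes, seed = 1)
c(insert = expected_insert_fraction(mock),
  contained_200 = expected_contained_fraction(mock, 200))
```

The Monte-Carlo fragment simulator (`fragment_community`) reproduces both
fractions within sampling error; the test suite checks convergence at
$3$ standard errors and `scripts/acceptance.R` reports the contained
percentage at $n = 10^6$.

# What the generator emulates — and what it does not

`generate_gene_family` emits frame-consistent coding sequences: an ATG
start, a single terminal stop, no internal in-frame stops, and pairwise
global identities verified to stay at or below 0.85 (resampling with a
bounded retry budget), so each gene founds its own OTU at the 97% threshold.
The sequences are otherwise uniform-random codons. They therefore carry no
real *amoA* conservation structure: no shared motifs, no codon bias, no
phylogenetic signal beyond what `diverge_cds` plants. Consequences worth
keeping in mind:

* Capture of *diverged* targets is exercised by building probes from
  relatives at a controlled divergence, not by natural sequence families.
* Cross-hybridisation between paralogues (e.g. *amoA* vs *pmoA*) is not
  represented; random genes share no 12-mers, so off-target capture in the
  simulation comes only from the nonspecific carry-over rate.
* Passing the end-to-end tests shows the workflow's logic is correct under
  the stated noise model; it does not certify performance on real libraries
  with adapter chimeras, quality-degraded tails or GC-dependent coverage.

The synthetic vector backbone places stop codons in all six frames (a G-free
`TTAA` repeat block) on both flanks of the cloning site, as real cloning
vectors carry stops and terminators around their multiple cloning sites.
This guarantees that the maximal-ORF rule recovers an inserted CDS exactly —
the role a trained gene caller plays on real constructs.

The mock contaminant observed at trace level in capture experiments is
modelled as a seventh gene: a frame-preserving 8%-diverged copy of one
reference member on its own backbone, spiked at read level (default 0.09%
of each capture sample). It passes the protein homology filter comfortably
but sits below 97% nucleotide identity to everything, so it founds its own
OTU when its reads suffice to assemble the CDS.

# The capture model

Hybridisation is modelled as alignment, not thermodynamics. A fragment is
retained by a capture round when its best ungapped alignment to any probe
(either strand) covers at least `min_overlap` nt at `min_identity` or
better; otherwise it survives with probability `nonspecific_rate`.
Defaults: `min_overlap = 100` (one probe length), `min_identity = 0.80`
(hybridisation tolerates mismatches), `nonspecific_rate = 1e-4` per round,
`rounds` 0/1/2 for the non-/single-/double-capture arms.

Candidate probes are found by exact 12-mer seeding (`PDict`), then verified
by Hamming identity on the seeded diagonal. Desk-scale fragments differ
from probes by substitutions only, so an ungapped check is exact here; a
capture event additionally requires at least one clean 12-mer seed, which at
the 0.80 identity floor is essentially always available. The three knobs are
deliberately exposed rather than derived: no attempt is made to predict
capture efficiencies from first principles, and the observed mapped ratios
of the simulated arms are emergent, not fitted.

# PCR, chimeras and sequencing

LM-PCR follows a per-cycle Bernoulli doubling process: each molecule
duplicates with probability `efficiency` (default 0.9) per cycle, so a
perfect template reaches $(1+e)^c$ expected copies. Cycle-count presets
mirror the experiment's profiles (9/11 pre-capture, 20 or 5+20 / 7+14 /
7+20 post-capture, 35/40 for amplicons). Chimeric molecules are
materialised per template lineage with probability
$1-(1-\rho)^c$ — the first-order equivalent of a per-duplication rate
$\rho$ (default $10^{-4}$) that avoids instantiating the full branching
tree — and each joins the prefix of its template to the suffix of another
at an exact shared 12-mer, mimicking template switching.

Paired-end sequencing reads both fragment ends at 2×300; fragments shorter
than the read length yield mates truncated to the fragment (adapter
read-through is thereby implicitly trimmed), so 200 bp fragments give fully
overlapping pairs. Errors are uniform substitutions (default $10^{-3}$)
with the matching constant Phred score — no quality degradation profile, no
indels. Amplicon simulation locates degenerate primer sites (IUPAC-aware,
up to 3 mismatches per primer), weights templates by
$(1 + e\,\pi^{m_f+m_r})^c$ with mismatch penalty $\pi = 0.5$, and emits
either one near-perfect long read per product or 2×300 pairs. With the
archaeal *amoA* primer pair a zero-mismatch template amplifies a 635 nt
product and, against 2–3-mismatch competitors over 35 cycles, takes
essentially the whole read pool — the primer-bias regime the capture
approach is designed to avoid.

# The OTU workflow

The pipeline stages and their defaults:

* **QC** — end-trim at Phred < 20; discard reads < 100 nt or with a
  DUST-style complexity score above 7. The score is computed over the whole
  read: with $w = L-2$ triplets and counts $c_t$,
  $100 \sum_t \binom{c_t}{2} / \binom{w}{2}$ (homopolymer = 100, random
  $\approx 3$). Pairs stay synchronised: losing one mate drops both.
  HiFi-style long reads get the length window 400–1000 nt first, then 20 nt
  trimmed from each terminal.
* **Merging** — smallest-shift (largest-overlap) suffix–prefix merge with
  mismatch density ≤ 0.25, consensus by higher quality; unmergeable pairs
  pass through flagged and can be mapped under the same-OTU pair rule.
* **Assembly** — a deterministic greedy overlap-consensus assembler: seed
  with the most abundant unused read, join reads through exact 30-mer
  terminal windows (verification tolerates a 5% mismatch fraction so
  errored reads are not orphaned), extend one base at a time by
  abundance-weighted majority vote, both directions, both strands; absorb
  contained reads; finally polish by a pileup consensus over every consumed
  read. Contigs need ≥ 2 supporting reads. This replaces a de Bruijn
  assembler, which desk-scale inputs neither need nor reward; it is exact
  on the simulated libraries and its determinism (fixed seed order,
  lexicographic vote ties) makes runs reproducible.
* **ORFs** — six-frame maximal start-to-stop ORFs (starts ATG/GTG/TTG),
  ≥ 100 aa, reported in coding orientation. A stand-in for a trained gene
  caller; exact on stop-flanked constructs.
* **Homology filter** — local BLOSUM62 alignment of each ORF translation
  against the reference proteins; best hit must reach 60% identity and 50%
  query and subject coverage, then the 400–1000 nt window applies. The
  identity/coverage pair replaces an e-value cut-off, whose meaning depends
  on database size; at these lengths the two criteria coincide in effect.
* **Chimera removal** — queries in ascending abundance against strictly
  more abundant parents; flagged when some crossover splits the query into
  segments whose identities to two *different* parents each exceed the best
  whole-length identity by ≥ 1.5 percentage points *and* reach at least
  0.9 absolute. The absolute floor encodes the physics — PCR chimeras copy
  their parents up to polymerase error — and protects distant relatives
  from segment-level fluctuation false positives; both-segments-exceed
  protects anything with a single dominant parent, since two segments
  cannot both beat their own full-length average.
* **Clustering** — greedy centroid clustering of the pooled samples
  ("sample concatenating"), processing by abundance descending (ties:
  length descending, then id ascending); a sequence joins the first
  centroid reached at ≥ 0.97 identity over ≥ 0.50 of the shorter sequence,
  else founds a centroid; singletons are discarded. The threshold is
  inclusive (≥ 97%), and coverage is measured on the shorter sequence;
  both choices are exposed in the configuration.

# Quantification and classification

Reads map to OTU representatives by multi-seed exact matching (three
non-overlapping 22-mers, so one substitution can break at most one seed —
the practical equivalent of a one-mismatch seed allowance) followed by
ungapped verification requiring 90% of the read aligned. Equal-best ties
across OTUs are discarded rather than randomly placed: abundance estimates
stay bias-free at the cost of a few reads. Merged reads map singly;
unmerged pairs require both mates on the same OTU.

RPKMS divides mapped reads by gene length (kb) and by the sample's
*sequenced* (quality-controlled) read count in millions — not its mapped
count — so values are comparable across enrichment levels. Rarefaction uses
the exact hypergeometric expectation
$E[S_m] = \sum_i \left(1 - \binom{N-n_i}{m}\big/\binom{N}{m}\right)$
rather than resampling, removing the seed dependence a permutation
implementation would add; samples with fewer than 100 mapped reads are
excluded.

Taxonomy transfers the best-hit label (identity recorded; ties keep only
the rank shared by all tied hits) with a 75% identity floor and a coverage
condition — a short perfect local hit carries no taxonomic signal. The
ecotype map is exactly the three-way correspondence NP-ε-2 → WCA,
NP-α-2.2.2.1 → WCB, NP-γ-2.1 → NMC, applied only to archaeal *amoA* OTUs.
Trees are neighbour-joining on Jukes–Cantor-corrected pairwise global
distances — a deliberate, flagged stand-in for likelihood inference,
adequate for grouping and visualisation; the newick output lets users
re-estimate with model-based tools.

# Reproducibility and problem sizes

One global seed drives a run; every module draws a sub-seed from a
deterministic hash of the seed and a stream label, so stages are
reproducible independently of evaluation order, and all sub-seeds stay
below $2^{31}$. All coordinates in interchange tables are 0-based
half-open; circular coordinates wrap modulo construct length. Tabular
outputs are TSV with commented headers naming units, and every CLI run
writes its fully resolved configuration next to its outputs.

The package's own validation runs at desk scale: the end-to-end mock
experiment uses five samples (one single-capture, three double-capture
LM-PCR profiles, one non-capture arm) of 50,000 read pairs each, a scale
chosen so the complete suite runs comfortably on a laptop while leaving
every gene's CDS hundreds-fold covered; the Monte-Carlo containment check
uses $10^6$ fragments. At those sizes the expected outcomes are sharp:
exactly seven OTUs (six inserts plus the spiked contaminant), six of them
complete sequence matches to the generated genes.

# Known limitations

Uniform substitution errors and constant qualities understate real MiSeq
error structure; the capture model is geometric, not thermodynamic, so
melting behaviour, bead kinetics and GC effects are out of scope; the
assembler and ORF caller are exact for desk-scale synthetic data but are
not replacements for production assemblers and gene callers on real
metagenomes; and the NJ tree is a working phylogeny, not a publication
phylogeny. The quantitative mapped ratios of real capture experiments
emerge from chemistry the model does not attempt to derive — the simulator
reproduces their qualitative ordering (capture ≫ non-capture; double
capture enriches slightly more but with less material) rather than their
exact values.
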