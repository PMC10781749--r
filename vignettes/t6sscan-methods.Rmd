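---
title: "Detecting and validating the Bacteroidota T6SS-iii: methods and design"
output: rmarkdown::html_vignette
vignette: >
  %\VignetteIndexEntry{Detecting and validating the Bacteroidota T6SS-iii: methods and design}
  %\VignetteEngine{knitr::rmarkdown}
  %\VignetteEncoding{UTF-8}
---

```{r setup, include = FALSE}
knitr::opts_chunk$set(collapse = TRUE, comment = "#>")
library(t6sscan)
```

The type VI secretion system (T6SS) is a contact-dependent bacterial
weapon built from three sub-assemblies: a membrane complex (MC), a
baseplate and a contractile tail-tube complex. In the phylum
Bacteroidota the system occurs as a distinct subtype, T6SS-iii, whose
membrane complex is formed not by the proteobacterial TssJLM proteins
but by five phylum-specific components: TssN, TssO, TssP, TssQ and
TssR. `t6sscan` implements the computational side of characterizing
such a system: finding its gene clusters in annotated genomes with a
quorum model, summarizing how the genes are organized across a phylum
as a contiguity graph, validating predicted protein structures against
crosslinking mass-spectrometry (XL-MS) restraints, and estimating the
stoichiometry of the purified complex from spectral counts. Every
stage has a seeded simulator that produces inputs with known ground
truth, so the whole pipeline is testable end to end.

## The quorum detection model

A *system model* (`system_model()`) declares the component families of
a multi-gene system, marks each as mandatory or accessory, and states
the co-localization rule under which a genome is scored:

* `min_mandatory` — minimum number of *distinct* mandatory components;
* `min_total` — minimum number of distinct components overall;
* `inter_gene_max_distance` (`d_max`) — the maximum number of
  intervening genes allowed between consecutive component genes of one
  cluster;
* `multi_loci` — whether all clusters of a genome are pooled before
  the quorum is evaluated.

Two ready-made models ship with the package. The MC-anchored model
(`t6ss_iii_model()`) lists the nine universal T6SS components
(TssB–TssK) as accessory and the five MC components (TssN, TssO, TssP,
TssQ, TssR) as mandatory, with a quorum of 1 mandatory and 8 distinct
genes overall, `d_max = 10`, multi-locus pooling on. The
universal-only model (`t6ss_universal_model()`) searches for T6SS loci
independently of the MC: the nine universal components all mandatory,
quorum 6/6, same distance and pooling. The quorum values are
deliberately permissive on the mandatory side because in this subtype
several MC components are frequently absent or too diverged for
profile detection, while requiring eight distinct genes overall keeps
isolated spurious hits from being called systems.

**Distances are gene counts, not base pairs.** Every gene receives a
0-based *rank*, its position in annotation order along its replicon,
re-derived from coordinate order at load time (`load_gene_table()`).
All distance thresholds count genes: two component genes with ranks
$r_i < r_j$ are separated by $r_j - r_i - 1$ intervening genes. This
matches the semantics of quorum-based system finders, which reason
about gene neighborhoods rather than nucleotide spans, and makes the
rule robust to annotation differences in intergenic lengths.

**Clustering** (`cluster_hits()`): component genes are chained; a
chain continues while the gap to the next component gene is at most
`d_max` intervening genes. Intervening genes of any kind never break a
chain — only distance does. Clusters are maximal, and on replicons
declared circular the wrap-around gap is also considered (the default
is linear when topology is unstated, since most complete genome
records do not annotate topology reliably in gene tables).

**Quorum evaluation** (`evaluate_systems()`): with multi-locus pooling
all clusters of a genome form one candidate system, because in many
Bacteroidota genomes — conspicuously in *Chryseobacterium* — the
system is encoded in up to four or five loci scattered in the genome.
Pooling is genome-wide with no inter-locus distance constraint, and
each genome yields at most one pooled candidate per model; counting
multiple independent systems in one genome is out of scope (a
limitation worth remembering for genomes that genuinely carry two
systems). A candidate is complete iff it reaches both quorums on
*distinct* components; copy counts (e.g. multiple *tssD* paralogs)
enter the per-component inventory but not the quorum.

`mc_completeness()` reports which of the five MC components a detected
system carries; aggregated over a census (`absence_fractions()`) this
reproduces the kind of per-component absence statistics that
characterize the subtype (in the wild, *tssO*, *tssQ* and *tssR* are
each missing from roughly a quarter to a third of detected systems).
`presence_absence_matrix()` emits the genome-by-component copy matrix,
writable as TSV or as a tree-annotation text for plotting presence and
absence along a phylogeny.

## The contiguity graph

Gene organization across a phylum is summarized by a graph whose nodes
are components and whose edge weights count how often two components
are *neighbors* (`find_neighbor_pairs()`,
`build_contiguity_graph()`). Two component genes are neighbors iff
they are less than `g_max = 10` genes apart — implemented as
intervening-gene count strictly less than `g_max`, i.e. rank
difference at most 10 — *and* no gene encoding another key component
lies between them. The blocking clause is the important difference
from clustering: in the consecutive arrangement …*tssK*, *tssN*,
*tssG*…, the pairs K–N and N–G are emitted but K–G is not, because
*tssN* intervenes. Same-component pairs (paralog adjacencies such as
*tssD*–*tssD*) are emitted and flagged. Pairs are counted per
occurrence across all genomes, since the edge weight is meant to be
proportional to the number of times two components are found together;
a per-genome deduplication switch is provided for sensitivity
analysis. Graphs are `igraph` objects exported as GraphML or a plain
edge TSV for external layout tools.

The "less than 10 genes apart" phrasing admits an off-by-one reading;
`g_max` is therefore a parameter, and the default implements the
strict reading (10 intervening genes do *not* qualify).

## Crosslink-to-structure validation

XL-MS reports residue pairs covalently tethered by a crosslinker (DSS
here), each with xQuest-style confidence scores. The validation stage:

1. **filters** identifications (`filter_crosslinks()`) at
   `ld_score >= 25` and `delta_s < 0.95`, then deduplicates to unique
   unordered residue pairs keeping the best-scoring observation. The
   ld boundary is inclusive; where sources disagree between ">= 25"
   and "> 25" the inclusive methods-grade threshold is the default and
   the parameter is exposed.
2. **maps** intra-protein links onto per-protein Cα coordinate models
   (`read_structure_ca()`, first PDB model, altloc blank or A) and
   computes Euclidean Cα–Cα distances. Cα is the standard reference
   atom for DSS restraints at an effective maximum of 35 Å (11.4 Å
   spacer plus two lysine side chains plus coordinate error).
3. **classifies** each link (`classify_links()`): satisfied iff
   distance ≤ 35 Å — a link at exactly the threshold is satisfied,
   since "violated" means the distance *exceeds* the crosslinker's
   maximal length. Inter-protein links are never classified against
   monomer models; they and links touching unmodeled residues are
   reported as unmapped with a reason.
4. **summarizes** (`violation_summary()`): per-protein totals and
   violations, the overall violated fraction, and the number of
   satisfied links spanning at least 20 residues in sequence — the
   long-range links that validate tertiary rather than local
   structure.

Raising the distance threshold can only shrink the violated set
(monotonicity), and classification is invariant under swapping the two
residues; both properties are enforced by tests.

## emPAI stoichiometry and assay metrics

The exponentially modified protein abundance index of a protein is
$\mathrm{emPAI} = 10^{N_\mathrm{obs}/N_\mathrm{obsable}} - 1$, with
$N_\mathrm{obs}$ observed unique parent peptides and
$N_\mathrm{obsable}$ observable peptides. emPAI is proportional to
molar abundance, so within a purified complex the estimated copy
number is $S_\mathrm{est} = 2\,\mathrm{emPAI}$ and relative integer
stoichiometries follow by dividing by the smallest positive
$S_\mathrm{est}$ and rounding half-up (`estimated_stoichiometry()`).
Half-up rounding (rather than R's round-half-even) keeps monotone
inputs mapping onto the expected integer ladder. The published formula
typesets ambiguously between $2(10^x - 1)$ and $2\cdot 10^x - 1$; the
default is the former because it equals $2\times\mathrm{emPAI}$ with
emPAI in its canonical form, and a strict-typeset mode provides the
latter.

With replicated measurements, `pooled_stoichiometry()` averages emPAI
per protein across replicates *before* forming integers. This is both
the conventional way replicate emPAI values are reported and the
statistically sensible choice: the least abundant member contributes
the noisiest single-replicate emPAI, and it sits in the denominator of
every ratio, so per-replicate integer estimates are heavy-tailed
upward while the pooled estimate concentrates tightly on the true
ladder.

`tryptic_observable_peptides()` supplies a simple stand-in for
$N_\mathrm{obsable}$ when only sequences are available: fully-tryptic,
zero-missed-cleavage peptides (cleave after K/R, never before P) with
length in [6, 30]. Search engines count observable peptides with
mass-window and modification rules this proxy does not model, so a
directly supplied $N_\mathrm{obsable}$ always takes precedence.

Two wet-lab metrics round out the quantitative stage. The competitive
index of a co-culture assay is the final donor:recipient CFU ratio
divided by the initial one (`competitive_index()`); it is
scale-invariant in the counts, and a pseudo-count option (off by
default) is the only remedy offered for zero recipient counts. The
Hcp-secretion ELISA readout is blank-corrected and normalized by the
starting culture density: $(\mathrm{OD}_{450} -
\mathrm{blank})/\mathrm{OD}_{600}$ (`normalized_hcp_signal()`).

## The simulators and what they do (not) show

Each generator takes an explicit integer seed, restores the caller's
RNG state, and returns a machine-readable truth record; identical
seeds give identical outputs.

`simulate_genomes()` emulates annotated genomes as runs of background
genes with an implanted component operon: contiguous, split into *k*
blocks placed at random positions at least `d_max + 5` genes apart
(so planted blocks never merge), or degraded by deleting listed
components. Spurious isolated hits are sprinkled on background genes
at a small rate (≤ 0.05 per gene), away from implants so they add
loci rather than extending them. Defaults (20–60 genomes of 200–300
genes, single replicon) keep test runtimes in seconds while exercising
every architecture. What this does *not* emulate: real component
divergence (hits are certain, not probabilistic), pseudogenes,
multi-replicon systems, or profile cross-matching between related
components — so passing recovery tests demonstrates the correctness of
the clustering and quorum logic, not the sensitivity of any upstream
homology search.

`simulate_structure_and_links()` builds a Cα chain as a self-avoiding
random walk with fixed 3.8 Å steps and a 4.0 Å minimum distance
between residues two or more apart in sequence; the excluded volume
prevents degenerate ultra-compact chains on which every link would be
trivially satisfied. Links are sampled so that exactly
`round(n_links * target_violation_fraction)` planted links exceed
35 Å, all planted links carry passing confidence scores, and optional
decoys carry failing ones. A real protein fold has secondary
structure and a crosslinker-accessible surface this walk does not
model; the simulation validates the measurement pipeline (filtering,
mapping, classification, summary), not structure quality itself.

`simulate_peptide_counts()` inverts the stoichiometry relation —
expected observed fraction $p = \log_{10}(1 + \mathrm{copies}/2)$ —
and either returns the exact real-valued $N_\mathrm{obs}$ (noiseless
mode, an inverse-identity contract tested to machine precision) or
draws $N_\mathrm{obs} \sim \mathrm{Binomial}(N_\mathrm{obsable}, p)$
per replicate. Copy numbers implying $p > 1$ are rejected with an
error naming the remedy. Real spectral counting has correlated,
overdispersed noise; the binomial model is the minimal noise that
exercises the pooling estimator.

## Numerical and design choices

* Gene ranks are 0-based; residues 1-based; genomic TSV coordinates
  1-based inclusive (GFF3 convention); all distances in Å.
* Threshold defaults: `d_max = 10`, `g_max = 10`, `D = 35` Å,
  `min_ld = 25`, `max_delta_s = 0.95`, long-range separation 20,
  reference integer 1. All are exposed as function arguments.
* Component assignment from hits keeps exactly one component per gene
  (best score, ties to the lexicographically first component name);
  multi-domain genes are out of scope.
* All file writers are deterministic: fixed column order, doubles at 6
  significant digits, sorted keys.
* Test problem sizes: oracle-equivalence sweeps use 50 genomes of
  2,000 genes (clustering and neighbor finding are compared against
  literal O(n²) oracles), the crosslink recovery uses a 250–300
  residue chain with 64 planted links, and the stoichiometry recovery
  uses 100 binomial replicates at 40 observable peptides — sizes at
  which every recovery is exact or near-exact and the full suite runs
  in well under a minute per stage.

## Known limitations

Detection accepts component hits as given and does not run or emulate
profile searches; sensitivity to sequence divergence is therefore
outside what the tests can show. Pooling reports at most one system
per genome and model. Circular-topology handling requires an explicit
replicon declaration. Inter-protein crosslinks are catalogued but
never scored against monomer models, and the observable-peptide proxy
ignores mass windows. Reproducing the published genome census (443
systems in 1,253 Bacteroidota genomes, 149 species, 44 genera) and the
published crosslink statistics requires the original genome lists, HMM
profiles and deposited XL-MS tables as inputs; the package provides
the downstream computation, and its synthetic acceptance runs mirror
those statistics' structure (64 unique links, 12.5% violated, 6 of 18
on one protein, a 5:5:4:2:1 stoichiometry) with ground truth instead.
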