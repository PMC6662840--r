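---
title: "Tracing keratin gene loss: methods and design"
author: "dollotrace"
output: rmarkdown::html_vignette
vignette: >
  %\VignetteIndexEntry{Tracing keratin gene loss: methods and design}
  %\VignetteEngine{knitr::rmarkdown}
  %\VignetteEncoding{UTF-8}
---

```{r setup, include = FALSE}
knitr::opts_chunk$set(collapse = TRUE, comment = "#>")
library(dollotrace)
```

## The problem

Keratin K24 is a type I intermediate-filament keratin encoded at one end of
the type I keratin cluster, flanked by *KRT222* and *KRT25*, inside the
locus bordered by the conserved anchors *KRT222* and *KRT12*. Comparative
genomics of this window across tetrapods shows that the gene arose in an
amniote ancestor and was subsequently inactivated, independently, in three
mammalian clades: the genus *Camelus* (while the alpaca keeps an intact
gene), the cetaceans (while the hippopotamus does), and the Otaroidea —
eared seals plus walrus — within the pinnipeds (while the earless seals
do). `dollotrace` implements that inference chain as a tested pipeline:

1. **locus maps and synteny** — parse per-species gene-coordinate maps,
   extract the anchor-bounded window, and call positional orthologs from
   gene order;
2. **ORF integrity** — detect premature stops, frameshifts and start-codon
   loss in coding models, predict nonsense-mediated decay (NMD), and call
   functional vs nonfunctional genes;
3. **gain/loss reconstruction** — Dollo maximum parsimony on a rooted
   timed species tree, with branch-interval dating and a Sankoff
   generalization;
4. **co-evolution and heterodimers** — compare loss patterns between
   keratins and list putative type I:type II dimers per species;
5. **qPCR quantification** — the efficiency-exponent relative-expression
   model with max-normalization to 10 arbitrary units and an exact
   Mann-Whitney U test;
6. **synthetic data** — generators with known ground truth for every input
   the pipeline consumes.

## Synteny-anchored orthology

A `LocusMap` is a sorted, validated set of gene features of one region in
one species. Orthology is positional: the target gene's nearest conserved
anchors are located in a reference map, and the corresponding window of
the query map is inspected.

* Exactly one exact-symbol candidate between both anchors → `ORTHOLOG`
  (evidence 2, one anchor per side; the per-side requirement is fixed at
  one and exposed through the `anchorSet` argument).
* A name matching the homolog pattern (default `"<symbol>-like"`) or
  several candidates → `HOMOLOG_UNRESOLVED`. The caller never picks
  arbitrarily among candidates; sequence-based phylogenetics, which is
  outside this package's scope, is the tool that would resolve them.
* Both anchors present but nothing in between → `ABSENT_FROM_WINDOW`.
* A missing anchor → `WINDOW_INCOMPLETE`, which maps downstream to
  presence state `UNKNOWN`, never `ABSENT`: fragmented assemblies must not
  fabricate gene losses.

Sidedness is strand-aware by default ("5′-side" means upstream in the
focal gene's transcription direction); `sidedness = "genomic"` restores
plain coordinate left/right. Windows read anchor-to-anchor: extracting
from an inverted assembly reverses the feature list and flips strands, so
both orientations compare equal — a property the tests verify by
constructing both orientations from one template.

## Lesions, NMD and functionality

`scanORF()` translates the spliced CDS in frame 0. Stops before the last
codon are `PREMATURE_STOP` lesions (all occurrences), a non-ATG first
codon is `START_LOSS`, a missing final stop `TERMINAL_STOP_LOSS`. Codons
containing N are counted as ambiguous and never become lesions; a CDS
length not divisible by three is refused with a pointer to
`compareToReference()`, because a frameshift must be located by alignment.

`compareToReference()` aligns the query globally against an intact
reference with match +1, mismatch −1, gap open −4, gap extend −1 (the
deterministic Biostrings traceback). Gap runs with length ≢ 0 (mod 3) are
`FRAMESHIFT_INDEL`s at the codon of their first aligned reference base;
the query is then re-scanned in its own frame 0, which is the reading
frame implied by the cumulative indels. Under other alignment scores a
lesion's position can slide by about one codon inside repeats; the tests
therefore allow ±1 codon when recovering planted frameshifts, while
planted stops must be recovered exactly.

The NMD rule is deliberately the literal one: a premature stop at least
`margin` nucleotides 5′ of the last exon–exon junction predicts decay,
with `margin = 0` as default ("before the last exon") and `margin = 50`
giving the canonical 50-nt rule. Single-exon models never predict NMD.
`assessFunctionality()` calls a gene nonfunctional iff NMD is predicted,
or a frameshift exists, or a premature stop truncates the annotated rod
(central intermediate-filament) domain — the domain required for filament
assembly. Without a rod annotation any premature stop counts, because no
safe default interval exists for an arbitrary keratin. Near-C-terminal
stops downstream of the rod, without NMD, are tolerated as functional.

`sharedLesions()` maps premature stops onto columns of a user-supplied
multiple alignment; species sharing a stop column are grouped, and
`countIndependentLosses()` collapses the group's losses onto the stem of
their MRCA — the walrus/sea-lion situation, where a stop at a conserved
position indicates a single ancestral inactivation.

## Dollo reconstruction

States binarize as INTACT → 1, PSEUDOGENE/ABSENT → 0 (the matrix records
*functional* genes; a pseudogene is no functional gene), UNKNOWN and
HOMOLOG_UNRESOLVED → uninformative. Under Dollo parsimony the gain sits on
the edge above the MRCA of all 1-leaves — or at/above the root for genes
like *KRT24* that are known to predate the sampled clade
(`ancestralAtRoot`) — and one loss sits on each maximal edge whose subtree
contains a known 0 and no 1. Uninformative leaves never force a loss. This
reconstruction is unique, so no tie-breaking is ever needed in Dollo mode,
and the event count is provably the minimum number of losses given a
single gain; the test suite checks that claim against a brute-force
enumeration of all ancestral assignments.

The exhaustive sweep runs all $2^n$ binary columns for every tree in a
fixed bank of hand-picked shapes (3–6 leaves: cherries, caterpillars,
balanced trees) plus seeded random trees at 7 and 8 leaves, and the full
3-state alphabet at 4 leaves — a few thousand reconstructions, each
verified against the enumeration oracle. Enumerating every labeled
topology at 8 leaves (135,135 of them) would add nothing but runtime: the
oracle equality is shape-wise, and the random trees cover shapes the bank
does not.

`sankoffReconstruct()` is the classical two-state dynamic program with
per-edge transition costs, plus `costGain` charged when the root itself
carries the gene (it must have been gained on the root stem). The
backtrace resolves ties toward the shallower event placement (state 0) in
pre-order; the alternative — preferring presence — would push losses below
uninformative leaves and break the documented equivalence with Dollo at
`costGain ≥ (1 + n_leaves) · costLoss`, which the suite checks on 1,000
fuzzed columns.

Dating is honest about parsimony's resolution: an event maps to a branch,
so its age is the interval `[age(parent), age(child)]` in MY, never a
point. A gain at `"ROOT"` has an unknown older bound (`NA`). Fixture
branch lengths are approximate divergence times for dating illustration
only.

## Co-evolution and heterodimers

Strict co-evolution is set identity of loss branches. The Jaccard
concordance and its permutation null are package-defined quantifications
of that qualitative notion (and are labeled as such in output): losses are
re-placed uniformly on the eligible edges (strict descendants of each
gene's gain; nested placements rejected), and
$p = (1 + \#\{J_{null} \ge J_{obs}\})/(1 + n_{perm})$ with a required
seed. Because the Jaccard statistic on small trees is highly discrete and
the estimator adds one, the p-value is *valid but conservative*: the tests
check $P(p \le \alpha) \le \alpha$ under independence (plus agreement with
exhaustive enumeration on small trees) rather than exact uniformity, which
a discrete statistic cannot deliver.

Heterodimer inference is rule-driven: each intact type I keratin is paired
with its highest-priority intact type II partner; a promiscuous type I
keratin (K24 is the motivating case — K3 first, K4/K5 where K3 is absent,
as in the mouse cornea) lists all intact partners from its top available
rank down. Nothing not INTACT is ever listed.

## qPCR model

Relative quantity is $E_t^{-Ct_t} / E_r^{-Ct_r}$ with per-gene efficiency
$E \in [1, 2]$ defaulting to 2 (perfect doubling), since no efficiencies
are reported for the assays this reproduces; with $E = 2$ the familiar
$2^{\Delta Ct}$ form results. Values are scaled so the maximum sample is
exactly 10 a.u. The Mann-Whitney U test doubles the smaller exact tail
(full enumeration of $\binom{n_A+n_B}{n_A}$ labelings for $n \le 20$
without ties, e.g. 1,287 at the 8-vs-5 design), capped at 1; with ties the
automatic path switches to the tie- and continuity-corrected normal
approximation, while `exact = TRUE` forces a well-defined midrank
permutation enumeration.

## Synthetic data: what it emulates, what it does not

`simulateDolloCharacter()` draws losses per edge with probability
$1 - e^{-\lambda t}$, irreversibly — the generative counterpart of the
Dollo assumption. Because a loss requires a carrying parent, planted
losses are never nested. Recovery by `dolloReconstruct()` is guaranteed
exactly when every planted loss edge's parent retains a functional
descendant leaf; otherwise sibling losses merge onto their stem or the
inferred gain clade shrinks, and parsimony undercounts by construction.
The tests assert 100% recovery under that separation condition and only
bound the event count otherwise. The Monte-Carlo suite (10,000 replicates
in the acceptance tests, at $\lambda$ chosen so the expected loss count is
near 3 on the mammal fixture) verifies the per-edge loss frequency against
the closed form within three standard errors.

`mutateCDS()` plants stops, frameshifts and start-loss with recorded
ground truth; `shuffleLocus()` edits gene order (drop/insert/invert) on a
deterministic coordinate grid; `simulateQpcr()` generates Ct tables under
the efficiency-2 model with Gaussian noise, at the 8-vs-5 cornea/epidermis
design by default in the examples.

What the generators do **not** emulate: sequence evolution (no
substitution models — lesion positions are planted, not evolved), assembly
artifacts beyond a missing anchor, copy-number variation (the marsupial
double *Krt10* stays a fixture note), and real Ct dispersion structure
(noise is i.i.d. Gaussian). Passing tests therefore demonstrate
correctness of the inference machinery on data matching its assumptions,
not robustness to everything a real genome browser will show.

## Fixtures and their provenance rule

A fixture cell exists only if the species' state is explicitly documented;
unstudied species are omitted, not guessed (several figure rows in the
underlying study enumerate more species than the running text — only
text-stated cells are packaged, and each fixture file header lists what it
encodes). Topologies follow the documented clade relationships; branch
lengths are approximate. The `krt24_states`/`mammal_tree` pair reproduces
the three independent losses (stems of Camelus, Cetacea, Otaroidea); the
`fig4_states` pair places losses of two distinct flanking genes — KRT223
on the terminal human branch, KRT224 on the placental stem — on the
root-to-human path; the platypus locus map carries exactly three
Krt24-like genes.

```{r headline}
tree <- loadFixture("mammal_tree")
pm <- loadFixture("krt24_states")
ev <- dolloReconstruct(binarizeStates(pm, "KRT24"), tree,
                       ancestralAtRoot = TRUE, gene = "KRT24")
ev
countIndependentLosses(ev)
eventIntervals(ev)
```

## Numerical and degenerate-input choices

* Coordinates are 1-based inclusive internally; BED is shifted on read.
* Empty locus files parse to empty maps; empty windows are legal.
* Alignment scores are pinned (above); ties in Biostrings' traceback are
  deterministic, and frameshift positions are documented as ±1 codon
  under other schemes.
* A CDS with more than 10% ambiguous bases should be mapped to `UNKNOWN`
  upstream rather than scanned for lesions.
* `normalizeToMax()` refuses all-zero input; `mannWhitneyU()` caps the
  doubled tail at 1; the permutation null refuses more losses than
  eligible edges.
* All generator randomness flows through explicit seeds and restores the
  caller's RNG state.

## Problem sizes used by the shipped tests

The exhaustive Dollo sweep covers the tree bank and seeded 7/8-leaf trees
(a few thousand columns); the Sankoff–Dollo equivalence uses 1,000 fuzzed
columns; the lesion round trip 1,000 planted mutations (600 stops, 400
frameshifts); the loss-frequency Monte Carlo 10,000 replicates on a
4-leaf tree plus 3,000 on the mammal tree in the unit suite. These sizes
were chosen to give the oracles real coverage while keeping a full run in
the minutes range on a single core.

## Known limitations

* Orthology is positional only; molecular-phylogenetic confirmation is
  out of scope, which is why ambiguous candidates stay
  `HOMOLOG_UNRESOLVED`.
* The binary presence model cannot represent copy number or partial
  genes; a three-state (functional/pseudogene/absent) mode is not
  implemented.
* Dating inherits the fixture trees' approximate branch lengths.
* The qPCR stage implements the calculation procedure; the study's actual
  per-sample Ct values are not published, so its bar charts are not
  reproducible and are not asserted anywhere in this package.
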