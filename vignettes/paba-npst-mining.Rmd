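---
title: "Mining PABA-specific A-domains from metagenomic amplicon pools: methods and design"
output: rmarkdown::html_vignette
vignette: >
  %\VignetteIndexEntry{Mining PABA-specific A-domains: methods and design}
  %\VignetteEngine{knitr::rmarkdown}
  %\VignetteEncoding{UTF-8}
---

```{r setup, include = FALSE}
knitr::opts_chunk$set(collapse = TRUE, comment = "#>")
library(npstminer)
```

# The model

Non-ribosomal peptide synthetases (NRPSs) are modular assembly lines; each
module's adenylation (A) domain selects one monomer, so the ordered list of
A-domain specificities largely determines the peptide product. Two levers
make A-domains useful for metagenome mining:

* their A3 and A7 core motifs are conserved enough for degenerate PCR
  primers, so a single amplicon (~0.9 kb here) tags every NRPS module in a
  cosmid pool; and
* the ~10 residues lining the substrate-binding pocket (the Stachelhaus
  code, positions 235, 236, 239, 278, 299, 301, 322, 330, 331, 517 in the
  anchor numbering) predict the activated substrate by nearest-neighbor
  comparison to characterized A-domains.

PABA-activating A-domains — the monomer source of the
albicidin/cystobactamid family — are doubly distinctive: they carry Ala
instead of the canonical Asp at position 235 (there is no α-amino group to
coordinate in PABA), and their nucleotide sequence carries three conserved
blocks at fixed spacings, `ARAARA (N11) TTYGCNRT (N7) AARGAR`. The pipeline
exploits both: an E-value screen finds A-domains *related* to known PABA
loaders, and the signature confirms the PABA-specific class.

The screen's E-value follows Karlin–Altschul statistics,
$E = K\,m\,n\,e^{-\lambda S}$, with $S$ the Smith–Waterman score of the
translated tag against a characterized PABA A-domain (BLOSUM62, gap open
11, extend 1), $m$ the translated query length and $n$ the summed reference
length. We use the published gapped constants $\lambda = 0.267$,
$K = 0.041$. Absolute values differ from BLAST's (no composition or length
corrections), but the screen is a *threshold* at $10^{-25}$ separating
genuine A-domain homology (self-scale hits land at $E \le 10^{-80}$ in the
bundled world) from shuffled-sequence noise ($E \sim 10^{-1}$), and that
separation is many orders of magnitude wide.

# Tunable parameters

| parameter | default | units | why |
|---|---|---|---|
| clustering identity | 0.95 | fraction | the published NPST clustering identity |
| E-value threshold | 1e-25 | — | the published primary-hit cutoff |
| signature mismatches | 0 | nt | the signature is a presence/absence screen |
| primer mismatches | 2 | nt | degenerate primers tolerate template variation |
| PCR product window | 100–1500 | bp | brackets the ~942 bp A3–A7 amplicon; excludes cross-template products between co-planted A-domains (≥ ~1.9 kb) |
| code-extraction floor | 40% identity over ≥ 200 columns | — | below this the anchor alignment is unreliable and the input is rejected as not an A-domain |
| lipid chain | 14 | carbons | the most common β-hydroxy lipid among close Cs-domain relatives; the characterized range 10–14 is carried as metadata |

Identity for clustering is matches over alignment columns of a global
alignment scored +1/−1 with linear gap −2; the original workflow's tool
does not publish its identity definition, so a fixed, documented one is
used instead.

# The synthetic world

Nothing from public databases is bundled. `generate_reference_panel()`
builds a seeded panel of synthetic A-domains around a fixed 530-aa anchor
scaffold that carries concrete A3/A7 primer sites and the anchor's own
pocket code. PABA-family members descend from a common PABA ancestor (15%
codon divergence from the anchor, 10% more per member), carry the
Ala-235-type code `AHVSLGVATK` and one stop-free expansion of the
degenerate signature inside the amplicon; non-PABA members are more
divergent (25% codon divergence), carry Asp-235-type codes and no
signature. Planted libraries embed each reference's A3–A7 amplicon in
uniform i.i.d. ACGT background contigs (a null that cannot contain primer
sites at meaningful rates at test scale), and reads get per-base
independent substitutions with an error-free barcode prefix.

What this world does *not* emulate: indels and quality scores, chimeras,
abundance skew, real soil community composition, and real inter-family
sequence structure. A green end-to-end test therefore establishes that the
*logic* of the pipeline (demultiplexing, clustering, the two filters, the
clade call) is correct on data satisfying its assumptions — not that the
thresholds are optimal for real MiSeq data.

Documented fixture constants: pools of ~25,000 clones and ~40 kb inserts
are the emulated library's scale and remain the documented defaults;
tests run with 50–500-fold smaller values.

# The lap architecture fixture

`lap_architecture_fixture()` transcribes the discovered PABA-family
cluster: five NRPS proteins with ten modules, a condensation-starter (Cs)
domain on the initiating protein (LapM), the thioesterase (TE) terminus on
LapH, two heterocyclization (Cy) modules loading Cys, one inactive A-domain
complemented in trans by the standalone LapB protein (Asn), an FMN oxidase
(thiazoline → thiazole) and the PABA-tailoring genes that justify one AHIBA
monomer. The module-per-protein partition is only partially constrained by
the source material: the total (10), the protein order anchors (Cs first,
TE last) and the statement that the *penultimate module of LapK* is the
inactive one. The fixture therefore uses LapM(AD1–3) → LapL(AD4) →
LapK(AD5–8, AD7 inactive) → LapH(AD9–10), which satisfies all three
constraints; every reported count is partition-invariant. Internal protein
order is taken from an explicit configuration (`protein_order`) rather than
a heuristic, because domain content alone cannot order internal proteins —
the fallback (input order) is logged in the result's notes.

```{r lap}
ps <- predict_structure(lap_architecture_fixture())
ps
```

Rule ablations are tested to change exactly one attribute: removing the
oxidase turns thiazoles into thiazolines and nothing else; removing the Cs
domain removes the lipid and nothing else; removing the standalone A-domain
leaves AD7 unresolved, dropping the residue count to 9 with a warning, never
silently.

# Numerical and algorithmic choices

* **Degenerate matching** is backed by `Biostrings::matchPattern()` with
  IUPAC classes fixed on the subject side; a brute-force expansion oracle
  checks it property-style in the tests.
* **Frame selection** for the translated screen: all six frames, keep
  stop-free frames (no internal `*`), take the best bitscore, break ties by
  frame index. Sequences with stops in every frame are flagged
  untranslatable and excluded with a reason, not dropped.
* **Progressive alignment**: guide tree from 4-mer Jaccard distances
  (average linkage), profile–profile Needleman–Wunsch merges in C++
  (match +1, mismatch −1, gap −2, linear), DP ties broken
  diagonal > up > left, rows processed in label-sorted order — the
  alignment is a deterministic function of the sequence *set*. The
  tree-guided clade logic, not aligner optimality, is the scientific
  content; an externally computed alignment can be supplied instead.
* **Neighbor joining** on p-distances with pairwise gap deletion; a pair
  with no shared ungapped columns is an error naming the pair. Q-matrix
  ties break at the smallest (row, column) pair with taxa in label-sorted
  order and merged nodes appended last; the 3-taxon terminus uses the
  closed form. NJ on additive matrices provably recovers the topology, and
  the tests assert it against `ape`-generated additive trees.
* **Clade calls** enumerate internal-edge bipartitions; a call is a
  *maximal* reference-free side with ≥ 2 NPST leaves, making the result
  invariant to rooting and leaf rotation (tested).
* **Code extraction** maps queries into the anchor frame by global-in-query
  alignment; a gapped pocket position yields `'-'`, is excluded from
  Hamming distance and decrements coverage — partial A3–A7 amplicons
  always lose position 517 this way, by construction of the amplicon.
  Position 299 (slot 5) is the known most-variable pocket position;
  mismatches confined to it are annotated (`variable_pos_mismatch`), never
  auto-forgiven.

# Open design points resolved here

* The source text calls the signature a "47 base pair sequence", but the
  printed pattern spans 6+11+8+7+6 = 38 nt. The implementation follows the
  printed pattern literally; `parse_signature()` reports the 38-nt span.
* Whether the E-value screen ran on nucleotide or translated sequence is
  not stated; this implementation compares translated sequence (the
  reference panel is protein-typed).
* The amplicon length distribution of the A3–A7 product is not stated; the
  fixture uses each reference's primer-to-primer span as-is (942 bp on the
  anchor scaffold).
* The reference numbering scheme behind positions 235–517 is not named;
  the bundled synthetic anchor defines the single coordinate convention
  used everywhere, and concrete pocket codes are synthetic stand-ins
  (characterized codes are not transcribable from the source), structured
  to preserve the field's conventions (Asp/Ala at 235, Lys at 517).

# Known limitations, and one deliberately red criterion

The acceptance suite asserts, as specified, that at 1% substitution error
at least 95% of planted-PABA reads land in a cluster whose centroid passes
the two-step screen. The stated world cannot meet this: a centroid is a
single member read, and the signature's fixed blocks contain 13 single-base
and 6 two-base IUPAC positions, so a centroid keeps an intact signature
with probability $0.99^{13}(0.99 + 0.01/3)^6 \approx 0.843$ — independent
of read depth, because all reads of one plant fall into one ≥95%-identity
cluster. The measured fraction over the pre-committed seeds is 0.733
(330/450 reads, 11/15 centroids). The assertion is left red rather than
weakened; a production fix would screen a cluster consensus (or allow one
signature mismatch), but both change the stated contract. This is also a
faithful reminder that the real workflow depends on sequencing error being
well below 1% per base after quality processing.

Other limitations: no paired-end merging, denoising or chimera removal; no
HMM-based A-domain detection (the anchor-alignment floor stands in); no
bootstrap or model-based phylogenetics; structure prediction stops at the
monomer level (no SMILES), and stereochemistry is recorded only as
E-domain flags.
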