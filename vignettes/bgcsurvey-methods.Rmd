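---
title: "Methods: surveying antimicrobial gene clusters and screening for horizontal transfer"
output: rmarkdown::html_vignette
vignette: >
  %\VignetteIndexEntry{Methods: surveying antimicrobial gene clusters and screening for horizontal transfer}
  %\VignetteEngine{knitr::rmarkdown}
  %\VignetteEncoding{UTF-8}
---

```{r, include = FALSE}
knitr::opts_chunk$set(collapse = TRUE, comment = "#>")
```

# The problem

Antibiotic biosynthetic gene clusters (BGCs) — contiguous blocks of
genes that jointly build, export and resist a secondary metabolite —
are patchily distributed across related bacterial genera. Two questions
recur when such clusters are surveyed across public genome assemblies:
*where* are homologous clusters (and how prevalent are they per genus),
and *how did they get there* — vertical descent or horizontal gene
transfer (HGT)? `bgcsurvey` implements a complete, testable version of
the comparative workflow used to answer both: homolog detection under
completeness/synteny/identity filters, restriction-map localization of
clusters known only by their published site pattern, flanking-region
conservation profiling, %GC-anomaly screening, and cluster-tree versus
species-tree congruence. A synthetic strain-panel generator with full
ground truth makes every stage verifiable without downloading a single
genome.

# The synthetic panel generator

The generator is first-class, tested code, not a fixture. It evolves a
host genome, a cpn60-like phylogenetic marker, a reference cluster, and
a set of flanking genes along a known species tree, then assembles one
genome per lineage.

**Species trees.** `simulate_species_tree()` builds genus-structured
trees: random binary subtrees per genus (uniform branch lengths, by
default 0.02–0.08 expected substitutions/site) joined by a backbone of
length 0.15 per edge. The backbone default gives cleanly separated
genus clades, the regime in which a species-level barcode like cpn60
resolves genera; surveys of more closely related panels use smaller
values (the survey-scale analyses in this package use within-genus
branches of 0.004–0.012 and a backbone of 0.025, which keeps maximum
pairwise divergence under 20%).

**Substitution model.** `mutate_sequence()` substitutes each site
independently with probability equal to the branch length, drawing
uniformly among the three other bases (a Jukes–Cantor-like process,
chosen so recovery tests have closed-form expectations). Multiple hits
accumulate across branches, not within one call. Two consequences are
modeled knowingly:

* *Composition drift.* Under this process a sequence with GC fraction
  $g$ drifts toward 0.5 at rate $\Delta g = \tfrac{2d}{3}(1-2g)$ per
  branch length $d$. At survey-scale divergence (≤ 0.2) this moves a
  54.6% backbone by well under a point; composition-calibration panels
  (below) are generated undiverged so the injected offsets are not
  confounded with drift.
* *Pseudogenization.* Unconstrained substitution sprinkles nonsense
  stops into every gene beyond a few percent divergence. Real
  functional genes are under purifying selection, so after evolving a
  gene the generator repairs it: internal stop codons are replaced by
  GC-identical non-stop codons (TAA→TTA, TAG→TAC, TGA→TCA), and the
  start and terminal stop codons are restored. Pseudogenization enters
  the simulation only through explicitly injected frameshifts, which is
  what makes frameshift-detection truth well-defined.

**Composition control.** `%GC` is the one signal measured to a tenth of
a point, so the generator controls it exactly rather than in
expectation: `random_sequence()` fixes the G+C count at
`round(length * gc / 100)`, cluster templates compensate the small
deficit introduced by fixed ATG/TAA gene termini inside their
intergenic spacers, flank-gene cassettes do the same, and cassettes and
clusters are *inserted* into the host backbone rather than overwriting
it (overwriting a segment would subtract that segment's hypergeometric
composition noise, ±0.1–0.5 points at 100-kb scale, from the
baseline). The result: an injected cluster/host offset of −15 points is
recovered as 15.0 ± a few hundredths.

**Cluster templates.** `make_cluster_template()` tiles single-ORF genes
(default four genes of 900 bp, mixed strands, 80-bp spacers — a 4-kb
cluster, the size class of small published antibiotic BGCs) and draws
the whole template at a requested %GC. Genes are real open reading
frames so that translated-protein analyses (homolog grouping,
frameshift detection) are meaningful.

**What the panel emulates** — and its knobs: host genomes at ~54–55%
GC (`host_gc`); clusters implanted 5–20 points below, or ~5 points
above, the host baseline (`cluster_gc_offset`; both regimes occur in
published Gammaproteobacteria surveys); vertical carriers sharing one
insertion site, HGT recipients receiving the *donor's evolved copy*
(plus a small post-transfer divergence, default 0.01) at a new site;
per-gene single-base frameshifts (`frameshift_prob`); clonal duplicate
genomes 0–2 substitutions from their parent (`clonal_lineages`); a
300-bp synthetic transposase remnant within 1 kb of the cluster's
upstream edge (`mge_prob`); and flanking-gene cassettes (four 900-bp
ORFs per side) whose sharing between sister lineages is tuned by
`flank_conservation` — a non-conserved slot is present in exactly one
sister, which makes the expected sister Jaccard index equal the
parameter.

**What it does not emulate.** Codon usage and amino-acid composition
realism, indel evolution beyond single-base frameshifts,
recombination, rearrangements, assembly error, and plasmid dynamics
(replicons are single contigs; plasmid baselines are handled by
labeling, not simulation). Passing tests therefore demonstrate that the
*pipeline logic* is correct under a clean substitution process — not
that the detectors are robust to assembly artifacts or compositional
heterogeneity of real genomes.

# Homolog survey

`find_candidate_loci()` replaces a remote BLAST search with an internal
seed-and-chain scan: exact k-mer matches (word size 11, the blastn
sensitivity regime for divergent nucleotide search) are chained on
consistent alignment diagonals (bands of 250 bp, chain gap ≤ 2 kb).
Two guards keep the false-candidate rate effectively zero at 100-kb
scale: low-complexity seeds (≤ 2 distinct bases) are masked, the same
problem DUST solves for BLAST, and only non-overlapping seeds count
toward the chain floor (default 5), since one chance ~15-mer match
produces several overlapping 11-mer hits. At 20% divergence an exact
11-mer survives with probability $0.8^{11} \approx 0.09$, one seed
every ~12 bp — detection is not seed-limited anywhere near the survey's
identity floor.

`evaluate_candidate()` aligns each query gene (Smith–Waterman, match
+1 / mismatch −1 / gap −2) inside the candidate window and applies the
survey's three filters:

* **completeness** — every query gene matched over ≥ 50% of its length
  (`min_gene_coverage`; per-gene coverage rules are rarely stated in
  survey methods, 0.5 is this package's documented choice);
* **synteny** — matched genes in template order with consistent
  orientation; a whole-cluster inversion is allowed
  (`check_synteny()`);
* **identity** — gene-length-weighted mean identity across the query
  cluster ≥ `min_cluster_identity`. The published exclusion rule this
  models ("diverged by more than 60% nucleotide identity") is ambiguous
  between a 40% and a 60% identity floor; the default reads it as
  *divergence > 60% excluded*, i.e. a 40% floor, and the knob is
  exposed so the other reading is one argument away.

Clusters split across contigs in draft assemblies are kept: when no
single-contig candidate passes, per-contig partial hits are combined if
their union is complete, each block is internally syntenic, and the
blocks partition the template at one breakpoint (`cross_contig` flag).

`prevalence()` rounds `100 * count / total` half-away-from-zero to
three decimals, the convention of published distribution tables.

# Restriction-map localization

A cluster known only from its published restriction map can be found
without its sequence. `locate_by_map()` slides the expected
site pattern over the genome in both orientations, anchoring candidate
placements at every (observed site, expected site) pairing — which
guarantees the exact placement is among the candidates — and scores
each placement by order-preserving greedy matching: +1 per matched
site (positional error ≤ tolerance × span), −1 per missed expected
site, −1 per extra observed site of a map enzyme strictly inside the
window. Ties are broken by total positional error, then position, so
ranking is deterministic and a region's own digest always ranks first
with zero misses and zero extras. Palindromic recognition sites are
counted once per duplex; non-palindromic sites are searched on both
strands. Enzymes, site patterns (full IUPAC) and maps are caller input;
the shipped demonstrations use synthetic maps built from the simulated
region's own digest, labeled as such.

# Flanking regions

`extract_flanks()` takes the 5 kb on each side of a cluster (template
orientation; truncation at contig edges recorded).
`predict_orfs()` is a stop-to-stop six-frame scan (starts ATG/GTG/TTG,
translation table 11, default minimum 150 nt) standing in for trained
gene finders; the substitution affects ORF counts, not pipeline logic,
and the caller chooses the floor per analysis:

* *Conservation profiling* uses a 600-nt floor
  (`flank_profile()` default). The naive caller has no coding model; at
  ~55% GC the stop density is only ~4% per codon and a 5-kb flank
  yields dozens of spurious 150–300-nt ORFs that would swamp Jaccard
  scores, while spurious gene-sized (≥ 600 nt) ORFs are rare
  ($P(\text{no stop in } 200 \text{ codons}) \approx 0.96^{200}$).
* *Frameshift screening* uses a 60-nt floor, because real frameshift
  fragments can be short.

`group_homologs()` clusters flank proteins by single linkage over
global-alignment percent identity (BLOSUM62, affine gaps; identity =
matches / aligned columns excluding end gaps) at a 30% cutoff, the
conventional homology floor of cluster-comparison figures; group ids
are deterministic (lexicographically smallest member). Pairwise flank
conservation is the Jaccard index of shared homolog groups.

`flag_mobile_elements()` flags ORFs by annotation keyword (transposase,
integrase, insertion sequence, recombinase, conjugation; `tra` gene
names matched case-sensitively so "transcriptional" does not fire) or
by alignment to a reference MGE protein set at ≥ 30% identity over
≥ 50% coverage.

`detect_interrupted_genes()` reports a reference gene as
frameshift-interrupted when adjacent same-strand ORFs align to
near-non-overlapping segments of its protein, jointly covering ≥ 70%.
Design points, each with a reason:

* segments must sit in **different reading frames** — a same-frame
  split is a nonsense mutation, not a frameshift;
* within a run of adjacent matching ORFs the best chain of
  non-overlapping reference segments is selected by dynamic
  programming, so spurious short matches cannot poison a real fragment
  pair;
* per-fragment floors are permissive (ORF aligned fraction ≥ 0.35 by
  default, relaxed to 0.2 in panel screening; reference span ≥ 5%)
  because short fragments carry proportionally long read-through
  tails — the joint-coverage requirement does the false-positive
  control;
* reference-span overlap up to 45 aa is tolerated: local alignments of
  real fragments read through the frameshift point by a few tens of
  residues, while tandem duplicates (near-total overlap) stay excluded;
* when the nucleotide sequence is supplied, a **disrupted-terminus**
  rule catches frameshifts near gene ends: the remainder protein sits
  in a shifted frame but usually lacks a start codon, so it never
  becomes an ORF; it is found by translating the region adjacent to the
  anchored ORF in the other frames and requiring the match to lie in a
  different frame.

On panels with `frameshift_prob = 0.3` and divergence ≤ 10% this
detector reaches ≥ 0.9 recall at ≤ 0.05 false-positive rate; the
residual misses are frameshifts within the last ~15 codons of a gene,
which leave the protein essentially intact and are invisible to any
fragment-based signature.

# %GC screening

`gc_content()` is `100 (G+C) / (A+C+G+T)` with N excluded from the
denominator. `gc_delta()` reports cluster %GC, replicon baseline,
their difference, and an HGT flag at a 5-point threshold — the low end
of the anomaly range observed for horizontally acquired clusters, with
the sign recorded because acquisitions from high-GC donors sit *above*
their host. Two implementation choices matter at panel scale:

* the replicon baseline excises the cluster's own span by default
  (`gc_report(exclude_cluster = TRUE)`): published surveys use whole
  ~5-Mb genomes as baselines, where a 10-kb cluster is negligible, but
  at 100-kb simulation scale a −15-point cluster drags its own baseline
  down by over a point;
* the flag compares |delta| at 0.1-point resolution, the precision at
  which %GC anomalies are conventionally quoted, so finite-sequence
  composition granularity cannot flip a flag sitting exactly on the
  threshold.

# Trees and congruence

Distance methods are used throughout: they are deterministic,
oracle-testable (neighbor joining exactly inverts additive matrices,
which the tests verify by recomputing path lengths from the output
tree), and sufficient for congruence logic. Maximum-likelihood
inference with model selection is deliberately out of scope; no claim
of model-equivalent branch lengths is made.

* `build_msa()` — MAFFT (FFT-NS-2, single thread, deterministic) for
  three or more sequences; an exact dynamic-programming alignment for
  pairs. All input residues are preserved.
* `pairwise_distance()` — p, JC69 ($-\tfrac34\log(1-\tfrac{4p}{3})$) or
  K2P distances with pairwise deletion of gap/N columns; saturated
  pairs capped at 5 substitutions/site and flagged.
* `nj_tree()` — standard neighbor joining (via `ape`).
* `bootstrap_support()` — column resampling with replacement; support
  is the percentage of replicates containing each original internal
  edge; one seed, one RNG stream, replicate $r$ consuming draw block
  $r$.
* `rf_distance()` — Robinson–Foulds symmetric-difference count (via
  `phangorn`; the test oracle enumerates bipartitions by brute
  force). Normalized RF divides by $2(n-3)$.
* `congruence_report()` — RF, per-genus monophyly in both trees, and
  *displaced leaves*: the greedy minimal set whose removal makes
  genus-level groupings agree, removing at each step the leaf that most
  reduces the count of non-monophyletic (genus, tree) pairs, ties
  broken by RF reduction then name. Greedy is an approximation of the
  minimal set; for the single-transfer case it provably removes exactly
  the recipient.

On vertical-only panels the cluster tree and marker species tree are
topologically identical (normalized RF ≤ 0.1); with one cross-genus
transfer the recipient is reported displaced in ≥ 90% of seeded runs.

# Orchestration and reproducibility

`run_all()` drives survey → %GC → flanks → trees from one validated
`run_config()` (thresholds as fractions in (0, 1] where they are
fractions, so a mistyped `1.01` fails before any stage runs) and writes
a manifest with package version, seed and a hash of the analytic
parameters — paths excluded, so the same analysis in a different
directory hashes identically. All randomness in every stage derives
from one master seed through labeled child streams; reruns are
byte-identical apart from the manifest timestamp. The `analysis/`
scripts run the same stages as a narrated workflow over a 40-genome
demonstration panel.

# Problem sizes

The shipped analyses and checks use: 40-genome panels of 100-kb
genomes with a 4-kb cluster for the survey; a 17-kb implant in a 200-kb
genome with a 25-kb signature window for restriction localization;
50-kb three-genome panels per offset for composition calibration;
10-leaf, 25-kb-genome panels (2-kb cluster, 1,650-bp marker) for the
congruence runs, twenty seeded replicates for the transfer-detection
rate; and 8-strain panels for flank conservation and frameshift
screening. These sizes keep every stage's behavior measurable while a
full run of the test suite and the acceptance script completes in a
few minutes on one core.

# Known limitations

The ORF caller has no coding statistics, so absolute ORF counts are not
comparable to trained gene finders. The survey's overall identity is a
per-gene weighted mean, not one end-to-end alignment; the two differ
when intergenic regions diverge much faster than genes. Flank
conservation is presence/absence of homolog groups, ignoring order and
orientation. The displaced-leaf search is greedy and can overshoot on
trees with several simultaneous transfers. The %GC screen is a single
composition statistic; codon-usage and tetranucleotide signatures are
out of scope.
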