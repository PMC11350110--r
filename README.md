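# bgcsurvey

Comparative-genomics survey of antimicrobial biosynthetic gene clusters
(BGCs) in bacterial genomes, with a focus on how clusters travel:
vertical descent or horizontal gene transfer (HGT).

Antibiotic BGCs — contiguous blocks of genes that build, export and
resist a secondary metabolite — are patchily distributed across related
genera of Gammaproteobacteria. Given a reference cluster (sequence plus
gene table) and a set of genome assemblies, this package answers the
two questions such surveys ask:

* **Where is the cluster?** Seed-and-chain homolog detection (word
  size 11) with the survey's inclusion filters — completeness (every
  query gene present), synteny (template gene order, whole-cluster
  inversion allowed) and an overall nucleotide-identity floor across
  the query cluster (default 40%) — plus per-genus prevalence tables,
  support for clusters split across draft-assembly contigs, and
  localization of clusters known only from a published restriction-site
  pattern.
* **How did it get there?** Three independent HGT signals:
  %GC anomaly of the cluster against its host replicon (flagged at 5
  percentage points, signed — acquisitions from high-GC donors sit
  *above* their host); conservation of the 5-kb flanking regions
  (ORF prediction, homolog grouping at 30% amino-acid identity,
  Jaccard conservation scores, transposase-remnant flags,
  frameshift-interrupted gene detection); and congruence between the
  cluster tree and a cpn60 marker species tree (neighbor joining over
  JC69/K2P distances, bootstrap supports, Robinson–Foulds distance,
  genus monophyly, displaced-leaf identification).

Because the real survey inputs are thousands of public assemblies, the
package ships a first-class synthetic strain-panel generator: genomes
evolved along a known species tree with implanted clusters at
controlled %GC offsets, horizontal transfers carrying donor-derived
divergence, frameshift-degraded copies, clonal duplicates, transposase
remnants and tunable flank conservation — all with a complete ground
truth table, so every stage of the pipeline is testable end to end
without a single download.

## Worked example

The `analysis/` scripts run the whole workflow as a narrated analysis
over a 40-lineage demonstration panel (four genera, 100-kb genomes at
54.6% GC, a 4-kb four-gene cluster implanted at 40% GC in half the
lineages, one cross-genus transfer, frameshifts, a clonal isolate):

```sh
Rscript analysis/01_simulate.R     # panel + ground truth -> results/panel/
Rscript analysis/02_survey.R       # homolog survey       -> results/survey/
Rscript analysis/03_restriction.R  # site-pattern localization
Rscript analysis/04_flanks.R       # flank conservation, MGEs, frameshifts
Rscript analysis/05_gc.R           # %GC anomaly screen
Rscript analysis/06_phylo.R        # trees + congruence   -> results/phylo/
```

What they print (abridged):

```
panel: 41 genomes (22 carriers, 1 via transfer), results/panel
accepted hits: 22 of 41 genomes
precision 1.000, recall 1.000 vs simulated truth
            cluster  genus n_carriers n_surveyed percent
1 synthetic_cluster genusA          7         11  63.636
2 synthetic_cluster genusB          5         10  50.000
...
exact map: top hit at 50200 (true 50200), 0 missed, 0 extra
5% of sites dropped: top hit at 50200 (error 0 bp)
22 of 22 clusters flagged as compositional outliers
mean cluster %GC 40.48, mean replicon baseline 54.09, mean delta 13.61 points
simulated transfer recipients: genusA_s6
reported displaced leaves: genusA_s6
```

Reading the output: every one of the 22 implanted clusters (and no
non-carrier) passes the completeness/synteny/identity filters; the
prevalence column is `100 * carriers / surveyed` rounded to three
decimals, e.g. 7/11 → 63.636; the restriction-map search pins the
signature region to the exact base even after 5% of its sites are
dropped; every cluster sits ~14 points below its host baseline and is
flagged; and the one strain that received the cluster horizontally is
exactly the leaf the tree-congruence report names as displaced.

The same stages are available as one call — `run_all(run_config(...))`
— which writes the full report bundle plus a manifest (package
version, seed, config hash); reruns are byte-identical apart from the
timestamp.

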