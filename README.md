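# rein: silencer prediction on regulatory element interaction networks

Silencers repress transcription, often by looping into contact with their
target promoters, yet they carry no single diagnostic chromatin mark —
which makes them the hardest class of cis-regulatory element to find
computationally. `rein` implements a structure-aware approach for people
working with ChIA-PET-style chromatin interaction data: instead of
classifying candidate regions in isolation, it places them on a
**regulatory element interaction network (REIN)** — merged loop anchors as
nodes, loops as edges — and classifies anchor nodes with a hybrid neural
model that reads both the node's linear genomic signature and its position
in the network.

## What it does

* **Network construction** (`readBedpe()`, `filterLoops()`,
  `mergeAnchors()`, `buildREIN()`, `assignLabels()`,
  `extractComponents()`, `sampleNegatives()`): keeps loops whose anchors
  are both < 1000 nt, merges overlapping anchors to closure, connects
  merged nodes by loops (self-loops where a loop's anchors merged),
  annotates nodes with element classes by strict >300-nt overlap of
  600-nt normalized elements under the priority silencer > non-silencer >
  enhancer > promoter, keeps components with > 100 nodes, and draws a
  balanced supervised set (all silencers vs all non-silencers + enhancers
  + `floor(10%)` of promoters per component).
* **Featurization** (`buildFeatures()`): per node, a `21 x 600` tensor —
  one-hot sequence (A/T/C/G rows, N all-zero) over the node's 600-nt
  window stacked with 17 per-base ChIP-seq signal tracks (12600 values
  flattened) — plus a 10-d structural descriptor feeding the graph branch.
* **Model** (`trainREIN()`, `predictREIN()`): a four-unit CNN
  (21→100→100→100→100 channels, LeakyReLU, max-pool, dropout 0.2, global
  max) over the linear features, two rounds of mean-aggregator GraphSAGE

  `h_v ← σ( W · mean({h_v} ∪ {h_u : u ∈ N(v)}) )`

  (10→100→100) over the network, concatenated into an MLP head
  (256, 64, 2). Class-weighted cross-entropy (w = 1.2 on silencers),
  L2 λ = 1e-4, Adam at lr 1e-4 with lr ← 0.95·lr whenever the training
  loss rises, early stopping on a stratified validation split. Seeded and
  bit-reproducible; backprop is hand-written and pinned to finite
  differences in the tests.
* **Evaluation** (`confusionMetrics()`, `aurocScore()`, `auprScore()`,
  `repeatedCV()`, `daviesBouldin()`, `motifEnrichmentScores()`,
  `apaScores()`, `ablate()`): Acc/Sen/Spe/PPV/F1/MCC, rank-based
  AUROC/AUPR, repeated stratified 5×5-fold CV with mean ± SD, the
  Davies–Bouldin two-set separation index
  `d = (v(T+) + v(T−)) / |m(T+) − m(T−)|²` (population variance), motif
  enrichment scores `e_k = −ln(c_k / Σ c_j)`, and aggregate peak analysis
  P2LL / ZscoreLL on contact-submatrix stacks.
* **Synthetic fixtures** (`fixtureSpec()`, `generateFixture()`): fully
  synthetic genomes, loops, elements and signal tracks with planted,
  parameterized class structure (signal shifts, sequence motifs, topology
  boosts), so the whole pipeline is testable end to end without any
  downloads.

## Worked example

Generate a synthetic benchmark with planted silencer signal, build the
network, train and evaluate:

```r
library(rein)

dir <- tempfile()
spec <- fixtureSpec(nChroms = 2, chromLength = 5e5, nLoops = 300,
                    nElements = c(silencer = 40, non_silencer = 15,
                                  enhancer = 15, promoter = 60),
                    seed = 7)
generateFixture(spec, dir)

res <- reinPipeline(dir, config = reinConfig(seed = 3), minComponent = 50)
res$graph
round(res$metrics, 3)
```

```
REINGraph with 200 nodes and 303 edges (6 self-loops)
  components: 2
  labels: silencer=40 non_silencer=15 enhancer=15 promoter=60 unlabeled=70

  Acc   Sen   Spe   PPV    F1   MCC AUROC  AUPR
    1     1     1     1     1     1     1     1
```

The 300 loops merge into 200 anchor nodes forming one component per
chromosome; 130 nodes carry planted element labels and the rest stay
unlabeled. The held-out metrics are computed on the 30% of labeled nodes
never seen in training: with the default +2 SD planted shifts on
H3K27me3/CTCF/H3K9me3 the classifier separates silencers from negatives
perfectly (AUROC 1), which is the expected behavior at this planted effect
size — the interesting calibration checks (chance behavior under zero
effects, topology-only signal) are run by the acceptance script below.

A thin CLI over the same functions is installed at
`inst/scripts/rein.R` (`simulate`, `build`, `dataset`, `evaluate`, `apa`,
`motif-score`).

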