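# tcrtarget

Predicting the peptide–MHC (pMHC) target of a paired alpha/beta T-cell
receptor (TCR) from its similarity to receptors with known targets.

TCRs that bind the same pMHC tend to share sequence and structural
features, concentrated in the six complementarity-determining region
(CDR) loops. `tcrtarget` turns that observation into a nearest-neighbor
classifier: a query TCR is scored against a labeled reference database
and inherits the label of its top-ranked (most similar) hit. The package
is aimed at immunoinformaticians benchmarking specificity inference on
curated repertoires (VDJdb-style tables plus, optionally, structural
models of each receptor), and at method developers who need a fully
synthetic, seeded test bed.

## The measures at its core

* **CDR string kernel** — alignment-free similarity of two loop
  sequences *f*, *g*: with a BLOSUM62-derived residue matrix
  *B(a,b) = (q(a,b)/p(a)p(b))^β*,

  K(u,v) = ∏ᵢ B(uᵢ,vᵢ),  cdr(f,g) = Σ K(u,v) over all equal-length
  contiguous substring pairs (k = 1…min(|f|,|g|)),
  CDR(f,g) = cdr(f,g) / √(cdr(f,f)·cdr(g,g)) ∈ (0,1].

  A TCR-level score is the weighted mean over the six loops, written in
  the field's notation `CDR(a1:a2:a3-b1:b2:b3)` (alpha triplet first).
* **SeqID** — whole-chain percent identity (Smith–Waterman, BLOSUM62,
  gap 11/1), normalized by the shorter chain, averaged over chains;
  used both as a baseline predictor `SeqID(wa:wb)` and as the
  **Max SeqID hold-out**: database entries more similar to the query
  than a cutoff are removed before prediction, probing performance when
  no near neighbor exists.
* **Mutual-nearest Cα RMSD** — all six CDR loops of two structural
  models are superposed simultaneously (Kabsch); per loop, only atom
  pairs that are each other's nearest neighbors contribute:
  RMSD = √(Σd²/N). Model `RMSD(1:1:1-1:1:1)`.
* **Combined model** —
  `CDR+RMSD = W·[1−CDR(1:1:4-1:1:4)] + (1−W)·RMSD(1:1:1-1:1:1)/5.0`,
  default W = 0.9.

Benchmarks are scored by accuracy and the Adjusted Rand Index (ARI; 1 =
perfect, ≈0 = random) with bootstrap intervals over the prediction
outcome (1,000 iterations).

## Worked example

Everything below runs on generated data — no downloads.

```r
library(tcrtarget)

cfg <- synth_config(n_epitopes = 4, tcrs_per_epitope = 10,
                    mutation_rate = 0.05, seed = 42)
synth <- generate_repertoire(cfg)
db <- synth$repertoire[-(1:2), ]    # database: 38 TCRs with known targets
queries <- synth$repertoire[1:2, ]  # two held-out queries

ann <- tcr_annotator(db, model = "CDR(1:1:4-1:1:4)", max_seqid = 99)
ann
#> TCR specificity annotator
#>   database: 38 TCR(s), 4 pMHC label(s)
#>   model: CDR(1:1:4-1:1:4)
#>   Max SeqID hold-out: 99%

pred <- predict(ann, queries)
pred[, c("query_id", "peptide", "mhc", "best_hit", "score", "n_candidates")]
#>   query_id   peptide   mhc best_hit      score n_candidates
#> 1  E01T001 HGASISDAF H2-Db  E01T006 0.00000000           38
#> 2  E01T002 HGASISDAF H2-Db  E01T006 0.02323496           38
```

Both queries are assigned the pMHC label of their nearest database
neighbor (`best_hit`); `score` is the weighted CDR kernel dissimilarity
(0 means every weighted loop is identical) and `n_candidates` is the
database size left after the identity hold-out. Here both predictions
recover the queries' true epitope.

Sweeping the hold-out shows how performance decays as increasingly close
neighbors are removed:

```r
benchmark_curve(synth$repertoire, "CDR(1:1:4-1:1:4)",
                thresholds = c(99, 95, 90), n_boot = 1000, seed = 1)
#>   threshold  n n_abstained accuracy       ari ari_lower ari_upper
#> 1        99 40           0    1.000 1.0000000 1.0000000 1.0000000
#> 2        95 40           0    1.000 1.0000000 1.0000000 1.0000000
#> 3        90 40           0    0.875 0.6912367 0.5022439 0.9172998
```

At a 90% cutoff every same-epitope near-duplicate has been removed and
leave-one-out accuracy drops to 0.875 (ARI 0.69 with a [0.50, 0.92]
bootstrap interval).

Individual measures are available directly:

```r
B <- blosum62_kernel_matrix()
cdr_similarity("CASSLGETQYF", "CASSLGDTQYF", B)
#> [1] 0.9698423
```

Database construction (`build_database()` = germline V/J splicing +
cross-reactivity removal + 99% redundancy clustering), structural
scoring (`read_tcr_structures()`, `structural_dissimilarity()`) and a
command-line front end (`inst/cli/tcrtarget.R`, subcommands `simulate`,
`build-db`, `kernel`, `seqid`, `rmsd`, `predict`, `evaluate`, `curve`,
each writing a JSON run manifest) round out the pipeline. The methods
vignette (`vignettes/tcr-target-inference.Rmd`) documents the models,
parameters, numerical choices and limitations.

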