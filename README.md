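# TieSig

Molecular signatures — gene sets plus a classifier predicting a phenotype
from expression profiles — are rarely unique: when several genes carry
equivalent information about the phenotype, many distinct, equally
accurate, non-redundant signatures exist, and reporting a single one
misses most of the relevant biology.  TieSig is an R package for research
groups developing such signatures from normalized (e.g. RMA-processed)
expression data.  It provides:

* **Markov-boundary induction** (`hitonPC`): semi-interleaved HITON-PC
  without symmetry correction, using Fisher's Z test for vanishing partial
  correlations with bounded conditioning-set size (*max-k*), returning one
  maximally predictive, non-redundant gene set.
* **Signature multiplicity enumeration** (`tieStar`): the TIE* scheme —
  systematically hide subsets of discovered signature genes, re-induce a
  boundary on the reduced data, and accept candidates that verify as
  information-equivalent to the primary signature.  The result is the
  complete set of maximally predictive, non-redundant signatures.
* **Redundancy assessment** (`assessRedundancy`): flag genes carrying no
  information about the phenotype beyond another signature member
  (conditional-independence screen), and remove them only if a DeLong
  comparison of cross-validated linear-SVM AUCs shows no significant loss.
* **Preprocessing bias audit** (`auditBias`): permute the phenotype,
  apply a preprocessing method (six are built in, from global centering to
  per-cohort reference-mean subtraction and parametric empirical-Bayes
  batch correction), count FDR-significant genes, and repeat — a direct
  measurement of how phenotype-aware preprocessing manufactures false
  positives under the null.
* **Synthetic generators with exact ground truth** (`generateTiedLike`,
  `generateCohortData`, `generateSeparationFixture`,
  `generateLinearGaussianNetwork`) for validating every stage, including a
  750 × 999 equivalence-class benchmark with exactly 72 true signatures of
  5 genes each.

The model underneath: a Markov boundary **M** of phenotype *T* is a
minimal gene set with *T* ⊥ *X* | **M** for every gene *X* ∉ **M**;
independence is judged by the Fisher Z statistic
√(n − |S| − 3) · atanh(r) on the sample partial correlation *r*.  Under
this test a signature is maximally predictive and non-redundant exactly
when it is a Markov boundary, and multiplicity corresponds to
information-equivalent gene classes.  See the vignette
(`vignettes/signature-multiplicity.Rmd`) for the full account.

## Worked example

```r
library(TieSig)

## a small equivalence-class dataset: classes {X1,X2} and {X3,X4,X5},
## always-present gene X6, 54 noise genes -> 2 x 3 = 6 true signatures
tied <- generateTiedLike(equivalenceSpec(nSamples = 400, nGenes = 60,
                                         classSizes = c(2, 3), seed = 11))
sigs <- tieStar(tied$data)
sigs
#> SignatureSet with 6 signature(s)
#>   sizes: min 3 / mean 3 / max 3
#>   union: 6 distinct genes
#>   [1] X2, X3, X6
#>   [2] X1, X3, X6
#>   [3] X2, X4, X6
#>   [4] X1, X4, X6
#>   [5] X2, X5, X6
#>   ...

head(summarizeSignatures(sigs)$participation)
#>   gene   percent
#> 1   X6 100.00000
#> 2   X1  50.00000
#> 3   X2  50.00000
#> 4   X3  33.33333
#> 5   X4  33.33333
#> 6   X5  33.33333
```

All six equivalent signatures are recovered; the always-present gene
participates in 100 % of them, each class member in 1/|class| of them.
Pooling all six signatures' genes and asking which are redundant removes
one member of every equivalence pair and keeps the accuracy:

```r
assessRedundancy(unionGenes(sigs), tied$data, evalParams(cvRepeats = 3))
#> Redundancy assessment
#>   retained (3): X2, X3, X6
#>   removed  (3): X1, X4, X5
#>   CV AUC 0.9226 -> 0.9226 (DeLong p = 0.48)
```

The audit shows how a phenotype-aware batch correction biases selection
under the null while no preprocessing stays calibrated:

```r
ed <- generateCohortData(cohortSpec(nGenes = 500, seed = 5))
auditBias(ed, "none", nPermutations = 100, seed = 3)
#> Permutation bias audit (100 permutations, FDR q = 0.2)
#>   method: none
#>   significant genes: mean 0.440, sd 0.925, stderr 0.0925
#>   95% interval: [0.0, 2.0]
auditBias(ed, "cohort_uninfected_mean", nPermutations = 100, seed = 3)
#> Permutation bias audit (100 permutations, FDR q = 0.2)
#>   method: cohort_uninfected_mean
#>   significant genes: mean 1.330, sd 2.362, stderr 0.2362
#>   95% interval: [0.0, 6.5]
```

Not a single gene is truly associated with the phenotype in either run;
the reference-mean correction triples the false-positive count, and the
effect grows with panel size (the shipped checks observe a >5× inflation
at 2,000 genes).

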