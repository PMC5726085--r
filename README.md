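# citescreen

Semi-supervised active learning for the citation-screening phase of
systematic reviews.

## The problem

Screening is the review stage where every retrieved bibliographic record is
judged eligible (include) or ineligible (exclude) from its title and
abstract. Corpora run to tens of thousands of records with only 2–14%
eligible; at ~30 s per decision a 15,544-record review costs about 130
hours of reviewer time. Prioritised screening trains a classifier on the
records screened so far and proposes what to read next, so eligible records
surface early — but in the first iterations the labelled set is tiny and
the model weak, precisely when ranking quality matters most.

`citescreen` implements and evaluates a semi-supervised remedy: propagate
labels from screened citations to their *k* nearest unlabelled neighbours
(the cluster assumption — nearby documents tend to share a label) and train
on the augmented set. Neighbourhoods are computed either in the TF-IDF
bag-of-words space or in a *p*-dimensional spectral embedding
(default *p* = 50, *k* = 3).

## The method in brief

* **Representation.** TF-IDF with natural-log IDF,
  `X[d,w] = c_dw · log(1/f_w)`; square-root term shares
  `r_dw = sqrt(X_dw / Σ X_dw')`, so `⟨r_d, r_d'⟩` is the Bhattacharyya
  coefficient of the two term-share distributions.
* **Embedding.** Top-*p* eigenpairs of the symmetrically normalised
  similarity operator `C̃ = D^{-1/2} R Rᵀ D^{-1/2}`, computed with sparse
  matrix-vector products only (ARPACK); `Z = [u_1√λ_1, …, u_p√λ_p]`.
* **Loop.** Random seed batch → propagate labels → train a linear SVM
  (cost 1) → score the pool → screen the top batch (certainty mode:
  most-likely-eligible first; uncertainty mode: least-confident first) →
  repeat to exhaustion.
* **Metrics.** yield = `(tp_h + tp_a)/(tp_h + tp_a + fn_a)`,
  burden = `(n_h + tp_a + fp_a)/n`,
  utility = `(β·yield + (1 − burden))/(β + 1)` with β = 19; average
  utility@R over the first R iterations; exact one-tailed sign test for
  cross-dataset comparisons.

A synthetic-corpus generator (topic-mixture multinomial with reserved
eligible topics, scattered eligible singletons, and realistic imbalance)
makes the whole pipeline testable without any external data.

## Worked example

```r
library(citescreen)

corpus <- generate_corpus(generator_params(n = 2000, ratio = 0.05,
                                           scatter_frac = 0, rng_seed = 42))
sum(corpus$label == 1)       # 103 eligible of 2000

sim <- simulate_screening(corpus, modes = "certainty",
                          semis = c("none", "spectral"),
                          repeats = 5, checkpoints = c(0.05, 0.10),
                          p = 50, max_fraction = 0.10)
sim$summary[, c("mode", "semi", "checkpoint",
                "mean_avg_utility", "sd_avg_utility")]
#>        mode     semi checkpoint mean_avg_utility sd_avg_utility
#> 1 certainty     none       0.05            0.486         0.1945
#> 2 certainty     none       0.10            0.741         0.0973
#> 3 certainty spectral       0.05            0.509         0.1992
#> 4 certainty spectral       0.10            0.752         0.0997
```

Reading the numbers: after manually screening 5% of the corpus, the plain
certainty-based active learner averages utility 0.486 over its iterations
so far, while the spectrally propagated variant averages 0.509 — the
semi-supervised model finds eligible citations earlier while the labelled
set is still small, and the margin narrows as screening proceeds (0.741 vs
0.752 at 10%). Utility combines 19-parts yield (fraction of eligible
citations identified) with 1-part saved burden, so a fully manual screen
scores exactly 0.95:

```r
sign_test_pvalue(6, 6)    # 0.015625 — six wins of six paired comparisons
manual_workload_hours(15544)  # 129.53 hours of hand screening
```

A thin command-line wrapper over the same functions ships in `inst/cli/`:

```sh
inst/cli/screen generate --n 2000 --ratio 0.05 --rng 7 --out synth.tsv
inst/cli/screen run --input synth.tsv --mode certainty --semi spectral \
    --k 3 --p 50 --rng 7 --out traj.csv
```

Every command writes a JSON manifest (config, input digest, seeds,
version) sufficient to replay the run bit-identically.

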