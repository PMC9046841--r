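# dgcn — annotation-free retinal image grading with a graph correlation network

Diabetic retinopathy screening grades macula-centered fundus photographs on
the five-level international scale (none / mild / moderate / severe /
proliferative). Supervised graders need large expert-annotated corpora;
`dgcn` implements an annotation-free alternative for researchers studying
unsupervised representation learning on medical images: it learns an image
embedding from unlabeled images and grades new images by nearest match to a
small labeled gallery.

## The method

Per mini-batch of B images:

1. a convolutional encoder maps each image independently to features
   `F_k = r(I_k; θ)`;
2. a K-nearest-neighbor graph over the batch defines the adjacency
   `A_kj = 1` iff j is among the K nearest neighbors of k (symmetrized,
   self-loops added for propagation);
3. graph convolution propagates
   `X^(l) = σ(D^{-1/2} (A+I) D^{-1/2} X^(l-1) W^(l))`, giving embeddings Z;
4. training minimizes `L = L_pc + α·L_gc + β·L_ti`, where
   - `L_gc = ½ Σ_kj A_kj ‖Z_j − Z_k‖²` (graph-center: pull neighbors
     together),
   - `L_pc = (1/2N) Σ_pairs [ l·d² + (1−l)·max(m−d, 0)² ]` with pairwise
     pseudo-labels `l(k,j) = 1` iff the two samples share strictly more
     than λ of their K nearest neighbors (pseudo-contrastive),
   - `L_ti = (1/B) Σ_k ‖Z_k − Z′_k‖` with `Z′_k` the embedding of a
     randomly rotated copy of image k (transform-invariant).

No label enters training; at prediction time a query inherits the grade of
its nearest gallery embedding, and referable disease (moderate or worse,
grade ≥ 2) is reported with sensitivity, specificity, accuracy (Wilson 95%
CIs) and ROC/AUC.

A synthetic fundus-like image generator with a known severity gradient
(lesion count and extent growing with grade, under illumination / contrast /
viewpoint nuisance) makes the whole pipeline testable at desk scale with no
data downloads.

## Worked example

```r
library(dgcn)

# synthetic 3-grade study: 60 images/grade at 64 px, train 15 epochs
# without labels, grade 165 held-out queries against a 5-per-class gallery
res <- run_grade_recovery_study(seed = 0, epochs = 15)
print(res$trained)
#> grade accuracy (all levels): 0.497
#> referable accuracy   0.752 (95% CI 0.680-0.811)
#> referable sensitivity 0.291 (95% CI 0.188-0.421)
#> referable specificity 0.982 (95% CI 0.936-0.995)
#> AUC 0.549 over 165 queries

round(res$untrained$metrics$multiclass_accuracy, 3)   # untrained baseline
#> [1] 0.485
round(res$ti_ratio, 3)   # held-out invariance loss, trained / initialized
#> [1] 0.038
```

Reading these numbers: three-level grade accuracy is ~0.50 against a 0.33
chance rate, and — the package's central honest finding — unsupervised
training does not beat the untrained (randomly initialized) encoder at this
desk scale, although it drives the transform-invariance loss to a small
fraction of its starting value. The methods vignette
(`vignettes/methods.Rmd`) analyses why: with 180 unlabeled images the
shared-neighbor pseudo-labels are too noisy to bootstrap, while a
supervised probe on the same images reaches ~0.89, so the data itself is
learnable.

## Command-line use

```sh
Rscript inst/cli/dgcn.R synth --out data/ --n-per-grade 60 --image-size 64 --seed 0 --grades 0,1,2
Rscript inst/cli/dgcn.R train --data data/ --out run/            # labels never read
Rscript inst/cli/dgcn.R predict --checkpoint run/checkpoint.bin \
    --gallery gal/ --gallery-manifest gal/manifest.tsv --query qry/ --out predictions.tsv
Rscript inst/cli/dgcn.R evaluate --checkpoint run/checkpoint.bin \
    --gallery gal/ --gallery-manifest gal/manifest.tsv \
    --query qry/ --truth qry/manifest.tsv --out metrics.json
```

`train` writes `checkpoint.bin`, `loss_trace.tsv` (per-step pc/gc/ti/total),
and the resolved config; two runs with the same config and seed are
byte-identical.

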