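# seedscore

Image-based scoring of single-seed germination with a k-nearest-neighbour
classifier.

Germination of small, non-sterile seed (the motivating case is a
*Miscanthus* germination trial) is usually scored by eye: the seed counts as
germinated once the radicle has visibly emerged. Manual scoring of tens of
thousands of per-seed photographs is slow and poorly reproducible, and
automation is confounded by mould growth, seed swelling from water uptake,
and broken seed. `seedscore` implements a seed-by-seed pipeline that scores
each image tile independently and is evaluated per image, not per plate:

1. **Segment** each RGB tile (one seed position at one time point): collapse
   to grey, threshold (Otsu by default, seeds dark on a light background),
   label 8-connected components and keep the object closest to the tile
   centre.
2. **Describe** the object with 25 morphology/intensity features (area,
   bounding box, centroid and mass-centre offsets, grey statistics,
   circularity, elongation, ...) plus 1536 colour-histogram features: the
   pixel counts at each of the 256 levels of R, G, B and of hue, saturation
   and brightness (quantised to 0–255), giving 1561 features per image.
3. **Reduce**: min–max normalise every feature to [0, 1] on the training
   data, optionally followed by PCA to 21 components.
4. **Classify** with a Euclidean k-NN majority vote (default k = 7): for a
   query image the k nearest training images vote; the *score* is the
   germinated fraction m/k of the vote and the *certainty* is
   max(m, k − m)/k ∈ [0.5, 1]. With k = 7 and a 4-vote majority the
   certainty is 4/7 ≈ 0.57.
5. **Curate**: because germination is scored on time series (a seed once
   germinated stays germinated; labels propagate forward in time), human
   reference labels contain systematic errors. `amend_until_stable()`
   repeatedly surfaces the least-certain images for review and applies
   corrections sequence-consistently until no amendment is needed.
6. **Evaluate** with ROC curves and AUC — the probability that a random
   germinated image is ranked above a random un-germinated one — plus
   false-positive/false-negative fractions at the majority-vote decision.

A synthetic tile generator (`generate_dataset()`, presets `"easy"` and
`"hard"`) emulates the phenotype diversity of a real trial — ellipsoidal
seeds, radicle protrusion, swelling, mould speckle, broken seed — so the
whole pipeline is testable without a camera.

## Worked example

```r
library(seedscore)

cfg <- presets(n_seeds = 60, n_timepoints = 4, rng_seed = 1234)$easy
ds  <- generate_dataset(cfg)
ds
#> <seed_dataset> 60 seeds x 4 timepoints (30 germinating), tile 282 x 341

feats <- dataset_features(ds)     # render + segment + extract, per tile
res <- run_experiment("pca", features = feats, labels = ds$labels,
                      k = 7, rng_seed = 1234)
res
#> <experiment_result> mode=pca  180 images x 1561 features, k=7, 1 repeat(s)
#>   mean AUC 0.9821  FP frac 0.0000  FN frac 0.0333
```

The run propagates labels forward in time, drops the 60 pre-test
(time-zero) frames, splits the *seeds* 1:1 into training and test halves,
fits normalization and the 21-component PCA on the training half only, and
scores the 90 test images: an AUC of 0.982 means a randomly chosen
germinated test image outranks a randomly chosen un-germinated one 98.2% of
the time; 3.3% of test images are false negatives at the k = 7 majority
decision.

Single tiles work the same way outside the experiment driver:

```r
tile <- render_seed_tile(ds, "s0001", 2)
f <- extract_features(tile)       # named vector, length 1561
f[c("area", "mean_grey", "elongation")]
#>       area  mean_grey elongation
#>    3727.00      83.46       1.37
```

A thin command-line wrapper with subcommands
`simulate / extract / classify / amend / evaluate / run` is installed at
`system.file("scripts", "seedscore", package = "seedscore")`.

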