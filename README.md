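# connectofuse

Tractography admits many defensible ways to weight the connection between two
gray-matter regions — streamline count (NSTR) or proportion (PSTR),
ROI-size-corrected streamline density (SD), tract volume (TV), average tract
length (ATL), centroid Euclidean distance (ED), or tract-averaged tensor
metrics (FA, MD, RD) — and downstream graph statistics can disagree across
those choices. `connectofuse` is for connectomics researchers who want a
single, principled structural brain network per scan instead of nine
arbitrary ones. It:

1. builds the nine weighted networks per scan from a tract table
   (`build_nws()`), with streamline white-matter-length thresholding and the
   density correction $w_{ij} = \frac{2}{g_i + g_j}\,|S_{ij}|$;
2. compares them with the **graph diffusion distance**
   $d_{gdd}(W_1, W_2) = \max_{t>0} \lVert e^{-tL_1} - e^{-tL_2} \rVert_F^2$
   over Laplacian exponential kernels (`gddm_distance()`,
   `pairwise_dissimilarity()`);
3. fuses them into one **integrated weighted structural brain network**
   (IWSBN) using normalised dissimilarity row sums as convex weights
   (`integrate_nws()`);
4. topologically filters the fusion by accumulating **orthogonal minimal
   spanning trees** and stopping at the peak of global cost efficiency
   $J = GE - \mathrm{Cost}$ (`omst_filter()`), yielding the sparse
   IWSBN^TF;
5. evaluates the result: weighted network metrics (`network_metrics()`),
   test-retest reliability via Shrout–Fleiss ICC (`icc()`), rank-sum
   comparisons, leave-one-out k-NN scan fingerprinting over diffusion
   distances (`knn_recognition()`), a quality-of-clustering index (`qci()`),
   classical MDS embeddings (`mds_embed()`), and lesion-based node weighting
   (`node_lesion_weights()`).

A synthetic test-retest cohort generator (`generate_roi_geometry()`,
`generate_cohort()`) emulates a 5-subjects × 5-scans × 90-ROIs design with
subject-specific modular topology, per-edge fingerprints and per-scan
negative-binomial counting noise, so the entire pipeline runs and is tested
without any MRI data. See `vignettes/methods.Rmd` for the model details and
design decisions.

## Worked example

```r
library(connectofuse)

geom   <- generate_roi_geometry(n_rois = 90, seed = 1)
cohort <- generate_cohort(n_subjects = 5, n_scans = 5, geometry = geom, seed = 1)
cohort
#> <cohort> 5 subjects x 5 scans, 90 ROIs, 98222 tract records (seed 1)

fit <- cohort_pipeline(cohort, variants = c("IWSBN", "IWSBN_TF"), metrics = FALSE)
fit
#> <cohort_fit> 25 scans, 5 subjects
#>   IWSBN    recognition accuracy 0.440 (k = 4), QCI 1.120
#>   IWSBN_TF recognition accuracy 0.960 (k = 4), QCI 1.441
```

Reading this: on a cohort with realistic counting noise, leave-one-out k-NN
(k = 4) over diffusion distances identifies the right subject for 44% of
scans from the dense fused network, but 96% from its topologically filtered
version, and the filtered network separates subjects better (QCI 1.44 vs
1.12; 1 would mean no separation). With low scan noise the filtered network's
accuracy reaches 1.0 — every scan assigned to its owner. The filtering step
itself:

```r
of <- fit$filtered[[1]]
of
#> <omst_fit> 2 rounds kept, 178 edges, density 100.0% -> 4.4%, peak J = 0.0712
glance(of)
#> # A tibble: 1 x 7
#>   n_rounds n_edges   cost global_efficiency      j input_density ...
#> 1        2     178 0.0582             0.129 0.0712             1
```

Two orthogonal spanning trees (2 × 89 = 178 edges) carry 5.8% of the total
weight yet already maximise efficiency-minus-cost; the remaining ~96% of
edges are dropped. `autoplot(of)` draws the cost-efficiency curve with the
selected peak; `tidy(of)` returns it as a tibble.

A thin command-line front end wraps the same functions:

```sh
inst/cli/connectofuse simulate --n-rois 90 --n-subjects 5 --n-scans 5 --seed 1 --out-dir out/
inst/cli/connectofuse run-all  --seed 1 --out-dir out/
```

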