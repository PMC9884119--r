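# blastocyto

Nucleus-level image cytometry for multi-channel confocal z-stacks of
preimplantation mouse embryos.

Blastocysts carry three lineages — epiblast (EPI), primitive endoderm
(PrE) and trophectoderm (TE) — whose identities are read out by
immunofluorescence for markers such as NANOG, TFCP2L1 and STAT3
phosphorylated at Y705 (pY705, the transcriptionally active form).
Questions like *"does pY705 intensify in the embryonic region during
diapause?"* need a per-nucleus readout from stacks in which ICM nuclei are
small, bright and tightly packed. `blastocyto` provides the full chain:

1. **3D segmentation by z-linking** — per-slice 2D detection on the DNA
   channel (unsharp mask radius 15 px / weight 0.6 → percentile
   normalization to the 1.0–99.9 window → threshold 0.2 → watershed
   splitting of touching nuclei → area filter strictly inside (5, 30) µm²),
   then greedy nearest-neighbour linking of detections through consecutive
   optical sections; 3D objects spanning ≤ 5 sections are discarded.
2. **Quantification** — per nucleus: centroid (µm), volume, and per channel
   the mean intensity and the *integrated density*
   `intden = Σ voxel values` (so `intden = mean × voxel_count`).
3. **Quality control** — open-interval windows on mean DAPI signal (2, 10)
   and volume (150, 700) µm³ remove erroneous segmentations; a 3D ROI mask
   restricts analysis to the embryonic region (mural TE cropped away).
4. **Stage statistics** — Levene (Brown–Forsythe) and Shapiro–Wilk
   diagnostics, Kruskal–Wallis across stages, all pairwise two-sided
   Wilcoxon rank-sum tests (exact for small tie-free samples), and star
   labels: ns p>0.05, `*` ≤0.05, `**` ≤0.01, `***` ≤0.001, `****` ≤0.0001.
5. **Gating and "in silico embryos"** — threshold and polygon gates in a
   2D co-expression space (boundary points inside, by convention), spatial
   map-back of selections to centroid point clouds, region-enrichment
   ratios with a hypergeometric p, per-embryo summaries and a Spearman
   size-vs-intensity correlation.
6. **A ground-truthed synthetic generator** — blastocyst-like stacks (TE
   shell + z-flattened ICM cluster, anisotropic Gaussian nuclei, lognormal
   stage/lineage intensity profiles, shot + read noise, 8-bit
   quantization) with exact per-nucleus ground truth, so the whole
   pipeline is testable at desk scale.

## Worked example

Simulate a small three-stage cohort, run the full pipeline, and compare
pY705 integrated density across stages:

```r
library(blastocyto)

cohort  <- make_cohort(2, synthetic_embryo_spec(), seed = 42)
manifest <- write_cohort(cohort, "demo/in")
res <- run_pipeline(manifest, pipeline_config(), "demo/out")
print(res$stats$py705)
```

```
Stage comparison on intden_py705 (per-nucleus)

    stage  n  min      q1  median       q3   max      mean
     E3.5 33 2540 3733.00  6935.0 18869.00 54209 14288.636
     E4.5 37 3298 4472.00  8961.0 13302.00 20844  9389.297
 diapause 38 2692 6616.25 25897.5 46665.25 73802 27484.737

           test                   groups   statistic      p_value        n label
         levene E3.5 vs E4.5 vs diapause  20.3166656 3.477339e-08 33/37/38  ****
        shapiro                     E3.5   0.7866119 1.811411e-05       33  ****
        shapiro                     E4.5   0.9198616 1.101635e-02       37     *
        shapiro                 diapause   0.8990746 2.400268e-03       38    **
 kruskal_wallis E3.5 vs E4.5 vs diapause  12.8328239 1.634510e-03 33/37/38    **
       wilcoxon             E3.5 vs E4.5 617.0000000 9.390416e-01    33/37    ns
       wilcoxon         E3.5 vs diapause 384.0000000 5.087454e-03    33/38    **
       wilcoxon         E4.5 vs diapause 390.0000000 9.101441e-04    37/38   ***
```

Reading the output: group variances are unequal (Levene) and no stage is
normally distributed (Shapiro) — hence the rank-based tests. The
Kruskal–Wallis test finds a significant stage effect on per-nucleus pY705
integrated density, and the pairwise Wilcoxon tests localize it: diapause
exceeds both E3.5 and E4.5, while E3.5 vs E4.5 is not significant at these
sample sizes (here n is the number of in-region, QC-passed *nuclei* pooled
over 2 embryos per stage). Against ground truth, segmentation of one of
these embryos recovers every planted nucleus:

```r
emb <- cohort[[5]]                        # a diapause embryo
seg <- segment_stack(emb$stack)
length(seg$tracks)                        # 29 nuclei found, 29 planted
```

Gating works on the exported tables:

```r
tab <- res$tables
sel <- gate_select(tab, gate_threshold("py705", 2.5e4))  # high-pY705 cells
enr <- region_enrichment(tab[tab$stage == "diapause", ], sel)
pts <- reconstruct(tab, "py705", sel)     # 3D point cloud, selected flagged
```

A thin command-line front end covering the same steps
(`simulate | segment | quantify | stats | gate | run-all`) is installed at
`inst/scripts/blastocyto`.

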