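# repliccs

Cell-cycle sorting of nuclei from replication-foci (EdU) images and
per-nucleus colocalization by image cross-correlation spectroscopy (ICCS),
for quantitative nuclear-organization studies in fluorescence microscopy.

## What it does

A single optical section of an EdU image is enough to tell where a cell is
in S phase: early S cells show sparse dim replication foci, mid S dense
bright foci, late S few large bright foci, and G1/G2 cells none. `repliccs`

1. **segments nuclei** from a DNA counterstain into a labelled count mask
   (isodata threshold, hole filling, 8-connected components);
2. **sorts every nucleus** into G1/G2, Early, Middle or Late from two
   per-cell measurements on the binarized foci image — the foci pixel
   density ρ_RF = N_RF/N_nuc and the foci pixel intensity I_RF — using
   population-derived thresholds
   ρ_min = N_min/⟨N_nuc⟩, ρ_thr = k_ρ·ρ_max, I_thr = k·I_min
   (defaults N_min = 10 px, k_ρ = 0.4, k = 3, plus a nuclear-size guard
   k_size = 1.2 on the Early group);
3. **quantifies colocalization** between the replication channel and a
   second channel (e.g. transcription foci), cell by cell, by masked-FFT
   spatial correlation: auto-correlation functions of each channel, the
   cross-correlation function, radial Gaussian fits
   G(r) = B·exp(−r²/w²) + G∞, and the colocalized fractions
   f1 = Bcc/B22, f2 = Bcc/B11 ∈ [−1, 1];
4. **reports** a per-cell CSV, derived thresholds in a reproducible run
   manifest, per-phase summaries (mean ± s.e.m., median, IQR) and
   Mann–Whitney group comparisons;
5. ships a **synthetic scene generator** with ground-truth phase labels and
   a controllable true colocalized fraction φ, so the entire pipeline is
   testable without microscopy data.

## Worked example

```r
library(repliccs)

## synthetic batch: Early nuclei carry transcription-coincident foci
## (phi = 0.8), Middle/Late mostly segregated foci (phi = 0.1)
sp <- scene_spec(seed = 5,
                 coloc_fraction_phi = c(EARLY = 0.8, MIDDLE = 0.1,
                                        LATE = 0.1, G1G2 = 0))
sc <- generate_scene(sp)
res <- run_pipeline(list(list(dna = sc$dna, rf = sc$rf, tf = sc$tf)))
res$summary
#>    phase n_cells n_value       mean        sem     median       iqr
#> 1   G1G2      15       0         NA         NA         NA        NA
#> 2  EARLY      15      15 0.41891217 0.02632281 0.40975656 0.1365513
#> 3 MIDDLE      15      15 0.12862631 0.03160046 0.12023208 0.1047123
#> 4   LATE      15      15 0.04553873 0.05350508 0.08437388 0.3139792
res$comparisons$EARLY_vs_MIDDLE
#> <group_comparison> EARLY (n=15) vs MIDDLE (n=15): U = 216, p = 1.935e-05 (normal-approximation)
```

All 60 nuclei are sorted into their phase from the replication channel
alone; the f1 column then quantifies, per cell, the fraction of replication
signal cross-correlated with the transcription channel — highest in Early
(where foci were placed coincident), near zero in Middle/Late, mirroring
the euchromatin-first progression of the replication program.

The same pipeline runs on real TIFF data:

```r
res <- run_pipeline(list(list(dna = "dna.tif", rf = "edu.tif",
                              tf = "pol2.tif")),
                    output_dir = "out")   # cells.csv, manifest.yaml, scatter.png
```

A thin CLI (`inst/scripts/repliccs-cli.R`) exposes `simulate` and `run`
subcommands over the same functions.

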