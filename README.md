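# vtsubstrate

Structural substrate analysis of re-entrant ventricular tachycardia
(VT) from late gadolinium enhancement (LGE) cardiovascular MR and
electroanatomic mapping data, for cardiac electrophysiology and imaging
researchers.

After myocardial infarction, the diastolic component of a re-entrant VT
circuit (the protected isthmus) tends to live in tissue that is
structurally distinctive: **non-transmural scar**, **mildly thinned
wall**, proximity to **heterogeneous border-zone tissue (HT)** and to
**steep gradients in wall thickness**. This package implements the
image-analysis chain needed to quantify those characteristics at mapped
electrogram locations:

1. **Tissue classification** — scar and HT by maximum-referenced signal
   intensity thresholds within the myocardial mask
   (`SI >= 0.60 M` scar, `0.40 M <= SI < 0.60 M` HT).
2. **Wall thickness and transmurality** — solve the Laplace equation
   `div(grad u) = 0` across the wall (`u = 0` endocardium, `u = 1`
   epicardium), trace field lines endo-to-epi by RK4 on the normalised
   gradient; thickness is the streamline arc length and scar/HT
   transmurality the label proportion along the path
   (non-transmural < 95% combined).
3. **Surface metrics** — marching-tetrahedra endocardial mesh, radial
   basis function (polyharmonic `r^3`) interpolation of thickness with
   analytic tangential gradients, steep-gradient regions, and Euclidean
   distance maps to HT and to steep-gradient vertices.
4. **Co-registration** — landmark (Kabsch) + trimmed point-to-surface
   ICP alignment of mapping points to the imaging mesh; assignment to
   mesh nodes within 1 mm.
5. **Activation analysis** — conduction-block lines where adjacent
   mapped points differ by more than 15 ms, with block extent from
   binned midpoint centrelines; early/mid/late diastolic phase by
   window tertiles.
6. **Statistics** — medians/IQR, Shapiro–Wilk, Mann–Whitney U (exact by
   enumeration for small samples), Kruskal–Wallis, Dunn–Bonferroni,
   paired t, Pearson.

Every stage is validated against a synthetic phantom generator
(`phantom_spec()` / `phantom_volume()`) with complete ground truth:
slab, spherical-shell and truncated-ellipsoid walls, scar patches of
controlled transmural fraction with HT rims and infarct-like thinning,
displaced electroanatomic frames, and two-wavefront activation maps
with known lines of block. See the methods vignette
(`vignettes/substrate-analysis.Rmd`) for the model, numerical choices
and limitations.

## Worked example

The end-to-end pipeline on the default phantom — an infarcted 20/30 mm
shell ventricle at 1.2 mm voxels with one 50%-transmural patch (2.5 mm
HT rim, 3 mm wall thinning), 100 diastolic points seeded on the scar
border zone and 100 normal points in remote wall, exported in a
displaced frame (15 degrees + 5 mm) and re-registered:

```r
library(vtsubstrate)
res <- run_pipeline(pipeline_config(seed = 7))
res
#> <substrate_result>
#>   2994 endocardial nodes, 15590 mesh vertices
#>   registration RMS 0.149 mm; 200/200 points mapped
#> # A tibble: 12 x 2
#>    quantity                                   value
#>    <chr>                                      <dbl>
#>  1 median_thickness_diastolic_mm           7.13e+ 0
#>  2 median_thickness_normal_mm              1.00e+ 1
#>  3 p_thickness                             6.67e-34
#>  4 median_scar_transmurality_diastolic_pct 4.8 e+ 1
#>  5 median_ht_transmurality_diastolic_pct   2.8 e+ 1
#>  6 median_dist_ht_diastolic_mm             2.87e+ 0
#>  7 median_dist_ht_normal_mm                2.39e+ 1
#>  8 p_dist_ht                               2.56e-34
#>  9 median_dist_steep_diastolic_noscar_mm   0
#> 10 median_dist_steep_normal_noscar_mm      2.11e+ 1
#> 11 p_dist_steep                            8.53e-14
#> 12 pct_diastolic_non_transmural            9.9 e+ 1
```

Reading the output: tissue at diastolic locations is thinner than
remote healthy tissue (median 7.1 vs 10.0 mm — the phantom thins the
infarct by 3 mm), carries close to the constructed 50% scar
transmurality, sits a few millimetres from HT versus ~24 mm for normal
points, and
diastolic points without scar lie on the steep thickness gradient at
the patch border (distance 0) while remote normal points are ~21 mm
away; 99% of diastolic points are in non-transmural (< 95%) scar/HT.
All three group contrasts are significant by Mann–Whitney.

Individual stages compose with pipes and return tibbles:

```r
ph  <- phantom_volume(phantom_spec("shell", r_endo = 20, r_epi = 30))
seg <- classify_tissue(ph$intensity, ph$label)
fld <- solve_laplace(seg)
endocardial_map(seg, fld) |> dplyr::summarise(median(thickness_mm))
```

A thin command-line wrapper over the same functions is installed at
`inst/cli/vtsubstrate.R` (subcommands `phantom`, `segment`,
`thickness`, `register`, `analyze`, `run`).

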