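# patchstoich

Single-molecule stoichiometry and spatial clustering of membrane receptor
assemblies, in R.

Membrane receptors such as chemokine receptors work as oligomeric
assemblies. Two imaging readouts constrain that organisation, and this
package implements the complete analysis for both:

* **Molecular counting from single-molecule image sequences.** In
  Slimfield/PaTCH microscopy of GFP-tagged receptors, each
  diffraction-limited focus is one assembly and its background-subtracted
  integrated intensity is proportional to the number of GFP tags. With the
  single-GFP brightness `I_1` calibrated from the same data (modal
  post-photobleach focus brightness, cross-checked against Chung–Kennedy
  photobleaching step intervals), the stoichiometry of a track is
  `S = I0 / I_1`, where `I0` is the track's initial intensity extrapolated
  back to first laser exposure over its first five frames. The modal
  nearest-neighbour spacing between the peaks of the stoichiometry
  distribution — the *periodicity* — reveals the oligomeric building block:
  a periodicity near 2 molecules means dimeric sub-units.
* **Spatial clustering of super-resolution puncta.** SIM images of
  labelled receptors are binarized (global AND local Otsu, rolling disk
  radius 25 px), object centroids are extracted, and clustering is
  quantified with Ripley's statistics
  `K(r) = (A/n²) ΣᵢΣⱼ≠ᵢ e_ij 1(d_ij ≤ r)`, `L = √(K/π)`, `H = L − r`:
  `H ≡ 0` under complete spatial randomness, `H > 0` for clustering,
  `H < 0` for dispersion. The modal gradient `dH/dr` summarises clustering
  across the analysed range and the initial minimum of `H` estimates the
  nearest-neighbour distance between puncta.

Every stage has a synthetic-data generator with exact ground truth
(photobleaching image stacks, intensity traces, CSR / jittered-lattice /
Thomas point patterns), and condition comparisons use the Brunner–Munzel
test at a Bonferroni-adjusted significance level (0.05 / 5 = 0.01).

## Worked example

Simulate one "cell" of immobile dimeric assemblies, run the full
single-molecule branch, and estimate the periodicity:

```r
library(patchstoich)
cfg <- patch_config(seed = 7L)

sim    <- simulate_assembly_stack(n_assemblies = 50, dim_hw = c(256, 256),
                                  n_frames = 300, i1 = 100, p_bleach = 0.03,
                                  seed = 7)
foci   <- detect_foci(sim$stack, cfg)
linked <- link_foci(foci, cfg)
cal    <- single_fluorophore_brightness(sim$stack, foci, linked,
                                        "modal_postbleach", cfg)
cal
#> single-fluorophore brightness: I_1 = 101.3 counts (modal_postbleach, support = 882)

st  <- track_stoichiometry(linked, cal, cfg)
inc <- st[st$included, ]
mean(inc$S); mean(sim$truth$stoichiometry)
#> [1] 20.57434
#> [1] 19.8

periodicity(inc$S)
#> stoichiometry periodicity: 1.95 +/- 0.15 molecules (kde_peaks; 44 tracks, 8 intervals under peak)
```

The calibration recovers the generator's unitary brightness (100 counts)
to within a few percent, the mean stoichiometry matches the simulated
truth, and the periodicity estimate sits at 2 molecules — the dimeric
building block planted by the generator. Pooling several cells tightens
the estimate (the test suite runs nine).

For the clustering branch:

```r
pat <- simulate_point_pattern("clustered", c(15000, 15000),
                              parent_per_um2 = 0.3, mean_offspring = 15,
                              offspring_sd_nm = 150, seed = 2001)$pattern
rc  <- ripley_h(pat, r_nm = seq(0, 400, 20), correction = "translation")
clustering_gradient(rc)
#> modal clustering gradient dH/dr = 0.5682 (20 gradient values)
```

A thin command-line front end over the same functions lives at
`inst/cli/patchstoich.R`
(`Rscript patchstoich.R simulate|detect|track|stoich|cluster|compare ...`).

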