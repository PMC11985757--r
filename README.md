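# glioquant

Spatial quantification of manually marked glial cells in anatomical nuclei
of the auditory brainstem (superior olivary complex: MNTB, MSO, LSO, dLSO,
control regions), for developmental studies of oligodendrocyte arrangement.

The package is aimed at microscopists who annotate sections by hand —
nucleus outlines drawn over a structural channel, one point per soma,
marker identities per point — and need the downstream numbers: densities,
normalized density maps, tonotopic profiles, co-labeling fractions,
calyx-proximity counts and single-cell process morphometry, each with the
matching statistics.

## What it computes

**Normalized density maps.** Each nucleus outline's bounding box is mapped
to [0, 100]% per axis, marks are binned into a fixed 20 × 20 grid of 5%
increments (half-open bins, last bin closed), and each section's grid is
divided by its maximum bin count:

$$D_{ij} = \frac{c_{ij}}{\max_{kl} c_{kl}} \in [0,1],$$

then averaged element-wise across sections per nucleus and age group, and
rendered as gray values (1 → black). Cell density per section is
$\rho = N/A$ with $A$ the shoelace polygon area times the squared pixel
size.

**Tonotopic profiles and edge comparison.** Profiles along the tonotopic
axis average the map over an orthogonal band (central 50%, center shiftable
by ±10%), or along a curved control-point path with a ±15% transverse
window for the LSO. Per-section means over relative locations [5, 15]% and
[85, 95]% are compared with the gated dispatch below. Multi-channel image
line scans average a rectangle's columns over its height, medial → lateral.

**Co-labeling and calyx proximity.** Point sets from two marker channels
are overlaid by greedy mutual-nearest-neighbor matching within a tolerance
(5 µm somata, 1 µm axon profiles), giving single/double fractions. Around a
calyx of diameter $d_c$, the sampling circle has diameter $d_c + d_s$
($d_s$ = 17 µm average soma); a cell counts when its soma disc lies fully
inside.

**Morphometry.** Process counts by class (primary / secondary / blind,
myelinating flagged by a two-peak cross-profile detector), polyline arc
lengths, five-point mean diameters (widths at arc fractions
0.1, 0.3, …, 0.9), chord orientations folded to [0, 90]°, and the coverage
polygon: convex hull with exact rotating-caliper Feret minimum/maximum,
shape ratio $F_{\min}/F_{\max}$ and Feret angle.

**Statistics.** Every comparison passes a Shapiro–Wilk gate (all groups at
α = 0.05): parametric branch (t test / ANOVA + Holm–Šídák) with mean ± SEM,
otherwise non-parametric (Mann–Whitney U / Kruskal–Wallis + Dunn) with
median ± SEM.

**Synthetic data.** Seeded generators emulate every input class — gradient
point patterns, banded tri-channel nucleus images, hollow/filled myelin
chips, calyx scenes, analytic oligodendrocyte cells — and export ground
truth, so the whole chain is validated by parameter recovery. See the
methods vignette (`vignettes/glioquant-methods.Rmd`) for the model details
and design decisions.

## Worked example

```r
library(glioquant)

roi   <- nucleus_roi("sec1", "MNTB",
                     rbind(c(40, 30), c(340, 20), c(360, 210), c(30, 230)),
                     axis_spec = "medio-lateral")
frame <- section_frame("sec1", pixel_size_um = 0.598, age_group = "P54")

# one synthetic section: 180 somata, 2:1 lateral:medial gradient
gp <- gen_points(roi, n = 180, gradient_axis = "x", gradient_ratio = 2, seed = 11)
density_records(gp$marks, list(roi), frame)
#>   section_id nucleus age_group count area_mm2 density_per_mm2
#> 1 sec1       MNTB    P54         180   0.0220           8185.

# 14 sections -> per-section density maps -> medio-lateral band profiles
profiles <- lapply(1:14, function(s) {
  marks <- gen_points(roi, n = 150, gradient_axis = "x", gradient_ratio = 2,
                      seed = 100 + s)$marks
  band_profile(section_density_grid(marks, roi), axis = "medio-lateral")
})
ec <- edge_compare(profiles)
#> medial edge 0.071 vs lateral edge 0.170, unpaired t-test: p = 6.8e-07

# myelin cross-profile on a generated 5.55 um chip
chip <- gen_tube_chip(filled = FALSE, snr = 6, seed = 5)
detect_myelin(chip_profile(chip$chip))
#> [1] TRUE

# single-cell morphometry on a planted cell
m <- cell_morphometry(gen_oligo_cell(n_primary = 5, n_secondary = 2,
                                     n_blind = 3, seed = 7)$cell)
m$counts
#>     primary   secondary       blind myelinating
#>           5           2           3           5
c(m$coverage$area_um2, m$coverage$shape_ratio)
#> coverage 2317 um^2, Feret ratio 0.45
```

The density record says: 180 cells in a 0.022 mm² nucleus give
~8,200 cells/mm². The edge comparison recovers the planted lateral
accumulation (higher normalized density at 85–95% than at 5–15%,
p < 0.001). The planted cell's composition is recovered exactly, and its
elongated arbor shows in the Feret ratio of 0.45.

A thin command-line front end over the same functions is installed at
`inst/cli/glioquant.R` (subcommands `density`, `stats`, `simulate`).

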