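# trackmech

Quantifies the reciprocal mechanics between migrating tumor cells and the
collagen microtracks that confine them, from multi-channel time-lapse
stacks. Cells in laser-ablated collagen channels either push narrow walls
apart or pull wide walls inward until the track matches their own
diameter; the collagen reflection speckle deforms with the matrix, so
tracking it yields displacement, strain, and — through a linear elastic
model — the traction force the cell exerts on the wall.

The package is aimed at labs doing 3D collagen migration assays who want
the image-analysis chain behind such measurements as programmable,
testable R functions rather than a sequence of interactive Fiji steps.

## The model at the core

Strain is the relative deformation of the collagen with respect to the
first time point. Two tracked speckles at positions $p_a(t)$, $p_b(t)$
spanning the deforming zone give

$$s(t) = \frac{\lVert p_a(t) - p_b(t)\rVert - L_0}{L_0},$$

and the simplified linear elastic relation $E = \sigma/s$ with
$\sigma = F/A$ turns strain into traction force

$$F(t) = E \, |s(t)| \, A,$$

with $E = 340$ Pa for 6 mg/ml fibrillar collagen and a
$20\times20\ \mu m$ contact patch, $A = 400\ \mu m^2$
(1 Pa·µm² = 10⁻³ nN). Around this sit drift stabilization, the channel
filtering recipe, kymographs, automated track-width measurement with
before/during/after phase labels, migration kinematics (speed including
stop phases, path/beeline persistence, cell length, relative nuclear
position), nuclear morphometry (minor diameter, irregularity index,
counts, proteolysis index), and Kruskal–Wallis/Dunn and Mann–Whitney
statistics.

Because raw microscopy for such assays is rarely publicly deposited, the
package
ships a seeded synthetic-scene generator (`scene()`, `generate_stack()`)
that renders a migrating cell deforming a speckled microtrack with exact
ground truth — every pipeline stage is validated against it.

## Worked example

Render the 40 nN wide-track benchmark and recover the prescribed force
end to end (stabilize → filter → track speckle pairs → strain → force):

```r
library(trackmech)
g <- generate_stack(force_scenario(40, seed = 1))
max(g$truth$mechanics$force_nN)   # ground truth peak
#> [1] 40
rec <- recover_wall_force(g)
rec$peak_force_nN                 # median over speckle pairs
#> [1] 40.0641
round(rec$pair_peaks_nN, 1)       # individual wall-adjacent/far pairs
#> [1] 39.9 40.3 40.5 40.1 40.0 40.2 34.0
```

The recovered 40.1 nN is within 0.2% of the prescribed 40 nN; the median
over pairs shrugs off the one mistracked pair (34.0). Track narrowing in
the default pull scenario (22 µm track, 18.7 nN peak):

```r
sc <- scene(seed = 1)
g <- generate_stack(sc)
m <- which.max(g$truth$mechanics$d_um)
measure_track_width(g$stack, sc$x_ref, 1)$width_um   # before passage
#> [1] 22.33711
measure_track_width(g$stack, sc$x_ref, m)$width_um   # at peak pull
#> [1] 11.38196
```

i.e. the wall-attached cell pulls a 22 µm track down to ~11.4 µm — a 49%
reduction — and a 17 µm target (8.5 nN) reproduces the ~23% bound of the
same worked example.

The numbered scripts under `analysis/` run the full study on synthetic
data: `01_simulate.R` (scenes + ground truth), `02_track_mechanics.R`
(force recovery), `03_track_width.R` (width dynamics and phases),
`04_kinematics.R`, `05_morphometry.R`, `06_stats.R`; outputs land in
`results/`.

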