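# telotrack

Adaptive eight-sector mean-shift tracking of cells in phase-contrast
time-lapse microscopy, with a small query-by-example image-retrieval
component.

## The problem

Telocytes — interstitial cells with very long, thin extensions — are
cultured and imaged label-free by phase-contrast microscopy. Phase
contrast renders a cell body as a **dark spot surrounded by a bright
halo** on a mid-gray background. `telotrack` exploits that pattern to
follow one cell through a frame sequence and to adapt to its changing
size and shape, which is what a biologist needs to quantify migration
and morphology dynamics without labels. The retrieval component ranks a
small image collection by similarity to an example crop, supporting
query-by-example browsing of cell archives.

## The method

Tracking is intensity-weighted **mean shift** with a pair of concentric
polygonal kernels centered at x = (x0, y0):

* a *white* kernel with per-sector radii rw_i that is attracted to the
  bright halo, and
* a *black* kernel with radii rb_i = f · rw_i (0 < f < 1) attracted to
  the dark cell body.

Each kernel is split into 8 triangular sectors (half-angle θ = π/8).
With a sector radius r, the sector triangles in the kernel-local frame
have outer vertices at distance r/cos(π/8) on the bounding rays — for
the first quadrant: cy = r/cos(π/8), bx = 2·r·sin(π/8),
by = 2·r·cos(π/8) − r/cos(π/8), ax = r/cos(π/8) — and the remaining
sectors follow by axis reflections. Pixel membership is decided by
even-odd **ray casting** inside the kernel's bounding rectangle.

Each frame is histogram-equalized and thresholded (default T = 200)
inside the kernel's dilated bounding box; the dark mask is the same
threshold applied to the reversed gray image (g ← 255 − g). The center
then iterates

    m(x) = ( w1 · m1(x) + w2 · m2(x) ) / (w1 + w2)

where m1 is the weighted mean of pixel positions under the white
kernel (halo foreground) and m2 under the black kernel (dark-body
foreground), until the shift falls below tolerance. After convergence
the foreground **weight center** of every white sector gives a distance
d_i to the kernel center, and every radius adapts as

    rw_i(t+1) = k · ( β · d̄(t) + (1 − β) · d_i(t) )

with defaults k = 1.55, β = 0.05 and initial radius 16 px, so the
kernel tracks growth, shrinkage and anisotropic deformation per sector.

Retrieval uses a 64-bin gray histogram plus shape descriptors of the
binarized mask (area, perimeter, circularity, eccentricity, major-axis
orientation and the seven Hu moment invariants), compared by weighted
Euclidean or Mahalanobis distance.

## Worked example

The package ships a seeded generator of phase-contrast-like sequences
with exact ground truth, so the whole pipeline runs without any data:

```r
library(telotrack)

scene <- scene_config()                 # 12 frames, shrinking drifting cell
seqd  <- generate_sequence(scene)
trk   <- track_cells(seqd$frames, seed_point = c(38, 40))  # 10 px off
trk
#> Cell track: 12 frames, seed (38, 40), 0 lost
#>   final center (37.56, 34.81), mean white radius 17.33 px

err <- track_errors(trk, seqd$truth)
round(head(err, 4), 2)
#>   frame error lost rho mean_rb mean_rw
#> 1     0  0.06    0 8.0   11.48   22.96
#> 2     1  0.14    0 7.6   11.15   22.31
#> 3     2  0.07    0 7.2   10.98   21.96
#> 4     3  0.16    0 6.8   10.69   21.38
```

`error` is the Euclidean distance to the true center in pixels — the
seed was 10 px off and the tracker locks on within a tenth of a pixel.
`mean_rb` is the mean black-kernel radius; as the true core radius
`rho` shrinks 8 → 3.6 px, `mean_rb` falls in lockstep (Spearman
correlation 1.00 after a 3-frame burn-in), which is the per-sector
radius adaptation doing its job. `plot(trk)` draws the center path and
the radius trace; `write_trajectory(trk, "traj.csv")` exports the
per-frame state.

A thin command-line interface wraps the same functions
(`system.file("cli/telotrack", package = "telotrack")`) with verbs
`synth`, `track`, `eval`, `index` and `query`.

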