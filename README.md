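# icetrack

Probabilistic streamline tractography suffers from *path-length dependency*
(PLD): because every propagation step adds angular noise, the fraction of
streamlines that survive to a voxel decays with its distance from the seed
region. PICo-style connection-confidence maps therefore cannot be segmented
with one global threshold — a level low enough to keep the distal tract also
admits a halo of near-seed false positives, and the decay steepens abruptly
wherever the tract traverses a crossing-fiber region, so no linear
distance-correction can repair it.

`icetrack` implements **ICE-T** (Iterative Confidence Enhancement of
Tractography), a region-growing wrapper around probabilistic tracking that
removes the PLD confound, together with everything needed to study it without
real diffusion MRI data: a FACT-style probabilistic tracker over synthetic
fiber-orientation fields, PICo map construction with waypoint/exclusion
filtering, phantom generators with ground truth (straight, crossing and
branching bundles), along-tract profile analysis, and parameter-sweep
experiments. It is aimed at researchers studying tractography methodology and
at anyone who needs a fully controlled, reproducible test bed for
segmentation-by-tractography pipelines.

## The method

Given a seed region `ROI_1` and two parameters — `ICE-T_streams` (streamlines
emitted per seed voxel, default 20) and `ICE-T_threshold` (per-iteration PICo
level, default 0.01) — iteration `i`:

1. emit `ICE-T_streams` streamlines from every voxel of `ROI_i`, counting
   only streamlines that pass through the waypoint `ROI_(i-2)` (the original
   seed for i ≤ 2);
2. form the PICo map `P(v) = (# counted streamlines visiting v) / (# emitted)`;
3. grow: `ROI_(i+1) = ROI_i ∪ { v : P(v) ≥ ICE-T_threshold }`;
4. stop when `|ROI_(i+1)| = |ROI_i|`.

Re-seeding tractography from the final `ROI_I` yields the *Intra-Tract
Confidence* map — each voxel's connectedness to the rest of the segmented
tract — which, with the distance decay gone, admits a single global threshold
(`segmentTract()`). The tracker honors an inner-product threshold of 0.5
between consecutive step directions (a 60° within-voxel curvature bound),
propagates bidirectionally from each seed voxel, and derives a deterministic
RNG substream per (voxel, streamline), so cached, re-generated and
repository-subsampled streamlines are bit-identical.

## Worked example

Path-length dependency on a synthetic bundle, and its removal by ICE-T:

```r
library(icetrack)

phantom  <- makeStraightBundle(length = 40, radius = 2, dispersion = 20)
seed     <- phantom@regions$seed
tracking <- TrackingParams(rngSeed = 7)

## plain probabilistic tractography: ~1e4 streamlines from the end seed
streams <- emitFromROI(phantom@field, seed, 770, tracking, storePoints = FALSE)
pico    <- computePICo(streams)
profile <- extractProfile(pico, phantom@centerlines$bundle, seed)
pico
#> PICoMap: 50x11x11 grid, 10010 emitted streamlines, 1002 voxels > 0, max 0.0962
profile@value[c(1, 21, 40)]          # centerline PICo at d = 0, 20, 39
#> [1] 0.0790 0.0377 0.0107
declineStatistic(profile)            # Spearman rho of value vs distance
#> [1] -0.990

## ICE-T: grow the seed, re-seed, segment with one global threshold
state <- runICET(phantom@field, seed,
                 ICETParams(icetStreams = 20, icetThreshold = 0.01), tracking)
state
#> ICETState: 14 iterations, converged, |ROI| 13 -> 579
diceCoefficient(finalROI(state),
                regionFromMask(phantom@bundleMasks$bundle))
#> [1] 0.965
confidence  <- intraTractConfidence(phantom@field, finalROI(state), 100, tracking)
confProfile <- extractProfile(confidence, phantom@centerlines$bundle, seed)
confProfile@value[c(1, 21, 40)]      # flat along the whole bundle
#> [1] 0.047 0.067 0.045
declineStatistic(confProfile)
#> [1] 0.003
segmentTract(confidence, 0.005)
#> Region: 566 voxels on a 50x11x11 grid
```

The plain profile decays by an order of magnitude along the bundle (rank
correlation −0.99 with distance); after ICE-T the confidence profile is flat
(rank correlation ≈ 0) and the segmentation recovers the ground-truth bundle
with Dice 0.97.

A thin command-line front end covers the same pipeline from a shell
(`inst/exec/icetrack`, installed under `exec/` in the package library):

```sh
icetrack make-phantom --kind straight --out ph --length 40 --radius 2 --dispersion 20
icetrack track --field ph --roi ph/region_seed.nii.gz --streams 20 --seed 1 --out tracks.tck
icetrack icet  --field ph --seed-roi ph/region_seed.nii.gz --streams 20 \
               --threshold 0.01 --global-threshold 0.005 --seed 1 --out out
icetrack sweep --config sweep.json
```

Volumes are NIfTI, streamlines TCK, profiles and sweeps CSV, configurations
and run logs JSON.

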