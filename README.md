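# mitoez

Quantitative image analysis of the mitotic ER **exclusion zone** and of
**ensheathed chromosomes** — misaligned chromosomes wrapped in layers of
endomembrane outside the zone — from multi-channel 3D+time fluorescence
microscopy.

During mitosis the endoplasmic reticulum is excluded from an ellipsoid
region around the spindle. Misaligned chromosomes that end up beyond this
zone can be ensheathed by endomembranes, fail to congress, and produce
micronuclei. `mitoez` provides the measurement layer for this biology as a
tested, reusable R package:

* **Exclusion-zone geometry.** For each kinetochore *P*, with *C* the
  centroid of the aligned kinetochores and *Q* the point where the ray from
  *C* through *P* crosses the ER/exclusion-zone boundary, the position
  statistic is

  log2( |CP| / |CQ| )

  — 0 on the boundary, negative inside, +1 as far outside the zone as the
  boundary is from the centroid (`ez_ratios()`, `boundary_intersection()`),
  plus canonical-frame registration for spatially averaged kinetochore
  views (`register_canonical()`).
* **3D segmentation** on anisotropic voxel grids: ER binarization, cell
  mask from a plasma-membrane channel (or the ER hull), exclusion-zone
  delineation as the largest interior ER cavity, and DNA object labeling
  with plate identification (`binarize_channel()`, `segment_cell()`,
  `delineate_exclusion_zone()`, `label_dna_objects()`).
* **4D tracking**: chromosome linking, congression (merge with the plate)
  and anaphase onset (persistent plate split) detection, chromosome/plate
  fluorescence ratios with planar 3-pixel ROI expansion, and pooled linear
  regression of checkpoint (Mad2) decay against time to anaphase
  (`link_objects()`, `detect_congression()`, `detect_anaphase()`,
  `quantify_signal()`, `mad2_regression()`).
* **ER clearance**: volume traces, largest-decrease detection with a
  significance call, a random-occurrence null for control cells,
  misaligned-chromosome distance traces and the 80-minute rescue
  classification (`detect_clearance()`, `null_clearance_distribution()`,
  `misalignment_trace()`, `classify_rescue()`).
* **Colocalization**: 3D puncta detection and exact nearest-neighbour
  kinetochore–kinastrin distances with the <600 nm attachment criterion
  (`detect_puncta()`, `nearest_distance()`, `fraction_within()`).
* **Statistics**: per-class timing ECDFs, Kolmogorov–Smirnov, Fisher's
  exact (uncorrected) and Wilcoxon tests, Kaplan–Meier congression curves,
  and class-by-fate tables (`cumulative_timing()`, `km_congression()`,
  `fate_summary()`).
* **A synthetic scene generator with exhaustive ground truth**
  (`make_scene()`, `render_stack()`, `render_timeseries()`), so every
  stage above is testable end-to-end without external data.

I/O covers OME-style multi-page TIFF hyperstacks with a JSON sidecar
(`read_stack()`/`write_stack()`), Fiji Cell Counter marker XML
(`read_points_xml()`), and CSV/JSON tables. A command-line front end
(`ez_cli()`, installed as `exec/mitoez`) chains the stages
(`simulate`, `segment`, `ezratio`, `track`, `clearance`, `coloc`,
`report`) from YAML configs.

## Worked example

Simulate one mitotic cell with a free and an ensheathed chromosome, segment
it, and place every kinetochore relative to the exclusion-zone boundary:

```r
library(mitoez)

scene <- make_scene(scene_params(n_free = 1, n_ensheathed = 1), seed = 42)
acq   <- acq_params(channels = c("ER", "DNA", "PM"))
stack <- render_stack(scene, frame = 1, acq)

er   <- binarize_channel(stack, "ER")
cell <- segment_cell(stack)
ez   <- delineate_exclusion_zone(er, cell)
ez
#> mask3d: 96x96x20 voxels, 5978 foreground (29.9 µm³), method largest_interior_cavity

gt <- scene_ground_truth(scene, 1, acq, channels = c("ER", "DNA"))
kt <- gt$kinetochores_um
ks <- kinetochore_set(rbind(
  data.frame(x_um = kt$x, y_um = kt$y, z_um = kt$z, label = kt$class),
  data.frame(x_um = scene_offset(acq)[1] + c(1.6, -1.6),
             y_um = scene_offset(acq)[2], z_um = scene_offset(acq)[3],
             label = "pole")))
rr <- ez_ratios(ks, ez)
aggregate(log2_ratio ~ class, rr, median)
#>        class log2_ratio
#> 1    aligned -1.2970927
#> 2 ensheathed  1.2848063
#> 3       free -0.4160801
```

Aligned kinetochores sit deep inside the zone (median log2 ratio ≈ −1.3,
i.e. at about 40% of the boundary distance), the free chromosome's
kinetochores lie inside near the boundary (≈ −0.4), and the ensheathed
chromosome's kinetochores fall clearly outside it (≈ +1.3, about 2.4× the
boundary distance) — the three-way spatial separation the statistic was
designed to expose. Classifying the same two chromosomes from the ER mask
alone (`classify_misaligned()`) scores the fraction of a 0.5 µm shell
around each chromosome occupied by ER: 0.96 for the ensheathed one, 0.34
for the free one, against an ensheathed threshold of 0.75.

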