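# bmRSA

Searchlight representational similarity analysis (RSA) of multidimensional
point-light biological motion, as a fully synthetic, fully tested R
pipeline.

## The problem

When people watch a point-light walker they simultaneously extract its
facing direction, its gender and its emotional state. fMRI studies probe
how these attributes are encoded in voxel patterns by combining:

* **theoretical RDMs** — for each attribute, an 8×8 binary
  representational dissimilarity matrix over the 2×2×2 stimulus crossing
  (1 = between-category pair, 0 = within-category pair);
* **a V1 model RDM** — 1 − Pearson distance between HMAX C1 feature
  vectors of the stimuli, controlling for low-level image structure;
* **searchlight multiple-regression RSA** — in every 200-voxel (here
  k-voxel) neighborhood, the neural RDM (1 − Pearson between condition
  t-patterns) is regressed on the four predictor RDMs; standardized
  coefficients β map each attribute's encoding, Fisher-transformed group
  t-tests with sign-flip Monte Carlo cluster correction give corrected
  maps;
* **scrambled-RDM hierarchy analysis** — the target attribute's map is
  re-estimated with the other two theoretical RDMs label-scrambled
  (n_perm times, z maps averaged); the Dice coefficient
  DC = 2·N_C/(N₁+N₂) between standard and scrambled corrected maps
  measures how independent the attribute's encoding is of the others;
* **MVPA** — leave-one-run-out linear SVM decoding of each dichotomy,
  cluster-level accuracies tested against chance (0.5) and between
  attributes with BH-FDR correction;
* **behavior linkage** — per-subject correlation between behavioral
  rating RDMs (|mean rating difference|, 1–7 scale, 96 trials) and
  cluster-restricted neural RDMs.

bmRSA implements this whole chain and, because real scanner data cannot
ship with a package, pairs it with a generator that simulates the
block-design acquisition (6 runs × 24 12-s blocks + 6-s fixations,
TR 2 s, 219 volumes/run) with *planted* multivoxel attribute codes, so
every stage is validated against ground truth: planted regions are
recovered, null calibration is nominal, planted couplings lower the Dice
coefficient, and planted codes decode attribute-specifically.

## A worked example

```r
library(bmRSA)

labels <- stimulusLabels()
theo   <- theoreticalRDMs(labels)
round(cor(sapply(theo, rdmVec)), 3)
#>         facing gender emotion
#> facing   1.000 -0.167  -0.167
#> gender  -0.167  1.000  -0.167
#> emotion -0.167 -0.167   1.000

# stimuli + V1 model RDM (8 walkers, 30 frames, 128 px)
ss <- buildStimulusSet()
v1 <- v1RDM(lapply(ss$stacks, stimulusFeature))

# one synthetic subject at the default operating point (20^3 grid,
# 1% planted effects in three ball ROIs, pattern SNR ~ 0.5)
sub <- simulateSubject(designSpec(), effectSpec(), labels, seed = 7)
sub
#> SubjectData: 6 runs x 219 volumes, 3544 mask voxels (grid 20x20x20), seed 7

tm  <- conditionTMaps(sub)                       # 8 condition t-maps
sl  <- defineSearchlights(subjectMask(sub), searchlightSpec(19))
rsa <- searchlightRSA(tm, theo, v1, sl)          # 4 coefficient maps
rsa
#> VoxelMap: 3544 voxels on a 20x20x20 grid; statistics: facing, gender, emotion, v1
```

With a 20-subject group (`simulateGroup()`), `monteCarloCluster()` on the
Fisher-transformed coefficient maps yields corrected clusters; in the
shipped configuration the corrected maps recover each planted ROI with a
Dice coefficient of ~0.6–0.7 against truth while covering <5% of the
non-ROI mask, and the hierarchy DCs are ~0.95 for independent attributes,
dropping to ~0.6 for a gender map when the gender region also encodes
emotion. The whole orchestration is available as
`fullPipeline(pipelineConfig(seed = 1, profile = "test"))`.

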