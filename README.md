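# alloDyn

Quantitative detection of allosteric communication in homotrimeric
tautomerases of the MIF family (macrophage migration inhibitory factor and
its homolog D-dopachrome tautomerase / MIF-2). These enzymes couple an
N-terminal catalytic proline to a solvent-channel gating residue
(Tyr99/Phe100) and the C terminus; `alloDyn` provides the analyses used to
measure that coupling from molecular dynamics trajectories, NMR data and
crystal structures - plus synthetic-data generators with known ground truth
so every stage is testable without simulations or spectrometers.

For whom: structural biologists and biophysicists analysing correlated
motions, channel hydration, hydrogen-bond networks, NMR spin relaxation and
crystal-structure perturbations in oligomeric proteins.

## The core statistic

Correlated motion between residues *i* and *j* is measured by the
generalized correlation coefficient, a [0,1] map of the mutual information
between their 3-vector displacement series:

    r[x_i, x_j] = sqrt(1 - exp(-(2/3) * I[x_i, x_j]))
    I[x_i, x_j] = H[x_i] + H[x_j] - H[x_i, x_j]     (nats)

Entropies are estimated from aligned-trajectory displacements with a
Kraskov-type k-nearest-neighbour estimator (k = 4). For Gaussian
displacements with isotropic per-component correlation rho, the closed form
is `I = -(3/2) ln(1 - rho^2)` and `r = |rho|`, which anchors the tests.

Around it, the package implements:

* `extractDisplacements()`, `mutualInformation()`, `correlationMatrix()` -
  correlated-motion maps with intra-/inter-monomer block views;
* `channelMembership()`, `countChannelWaters()`, `channelExpansion()`,
  `buildOccupancyGrid()` - solvent-channel water statistics between gating
  residues;
* `hbondPresent()`, `hbondFrequency()` - geometric hydrogen-bond criteria
  (<= 3.0 A donor-acceptor, <= 30 degrees) and bonds-per-frame statistics;
* `fitRelaxationRates()`, `computeNOE()`, `r1r2Product()`, `combinedCSP()`,
  `thresholdProfile()`, `correlationOutliers()` - NMR relaxation fitting
  with replicate-based uncertainties and 10%-trimmed-mean / 1.5-sigma
  outlier calling;
* `readStructure()`, `superpose()`, `atomDisplacement()`,
  `ligandContacts()`, `atomDistance()` - crystal-structure comparison
  (Kabsch RMSD, displacement and contact metrics);
* `simulateCorrelatedTrajectory()`, `simulateDecayCurves()`,
  `simulateChannelFrame()`, `simulateStructurePair()` - ground-truth
  generators;
* `runPipeline()` - a YAML-configured, manifest-logged pipeline over all
  stages.

## Worked example

Plant a rho = 0.9 correlation between residues 1 and 3 of a four-residue
system, then recover it:

```r
library(alloDyn)

C <- diag(4); C[1, 3] <- C[3, 1] <- 0.9
series <- simulateCorrelatedTrajectory(nFrames = 20000, nResidues = 4,
                                       correlation = C, seed = 7)
res <- correlationMatrix(series)
round(generalizedCorrelationMatrix(res), 3)
#>       A:1   A:2   A:3   A:4
#> A:1 1.000 0.015 0.893 0.000
#> A:2 0.015 1.000 0.000 0.034
#> A:3 0.893 0.000 1.000 0.059
#> A:4 0.000 0.034 0.059 1.000
```

The planted pair (A:1, A:3) stands out at 0.893 - the k-NN estimator's
slight low bias at high correlation is visible but inside the expected
±0.05 band - while independent pairs stay near 0.

Fit longitudinal relaxation rates from synthetic decays (true rate
2.0 s^-1, 2% intensity noise, duplicate delays for uncertainties):

```r
dec <- simulateDecayCurves(rep(2.0, 3), noiseSd = 0.02, seed = 7)
fitRelaxationRates(dec)
#>   residue     rate     rateSd       I0 negative
#> 1       1 2.054738 0.08516309 101.8699    FALSE
#> 2       2 1.939952 0.07993554 100.5356    FALSE
#> 3       3 2.022335 0.08487644 100.0617    FALSE
```

Each fitted rate sits within its quoted uncertainty of the truth; `rateSd`
comes from the replicate-delay noise estimate propagated through the fit
covariance.

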