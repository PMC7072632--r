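# ecvnet

Condition-differential subnetworks from sample-specific edge contributions
in B-spline Bayesian gene networks.

## The problem

Gene networks estimated from expression data routinely contain 10^5 edges
over ~20,000 genes — far too many to interpret, and structure-based
comparisons between conditions need many samples per condition. `ecvnet`
implements a different route for experiments with very few samples (its
motivating design is 3 cell lines x 2 conditions x 3 replicates = 18
arrays): estimate **one** basal network from all samples, then quantify
every edge *per sample* and compare those per-sample edge weights between
conditions.

The model is a Bayesian network whose local densities are additive
B-spline regressions,

x_ij = m_1^(j)(pa_i1) + ... + m_qj^(j)(pa_iqj) + eps_j,   eps_j ~ N(0, sigma_j^2),

with each component m_k^(j) a cubic B-spline curve (M = 20 basis
functions on the observed range of that parent). The **edge contribution
value** of edge j_k -> j in sample i is

ECv^(i)(j_k -> j) = m_k^(j)(pa_ik^(j)),

the edge's share of its child's predicted expression in that sample, and

dECv = | mean_S ECv - mean_T ECv |

is the differential-edge statistic between sample groups S and T (each may
be a single sample). On log2 expression, dECv > 1 corresponds to a
two-fold change transmitted through an edge. Edges exceeding the threshold
in every cell line form the differential subnetwork (extracted edges plus
the basal-network edges among their genes); trained component functions
can be re-evaluated on an external cohort's expression ("ECv transfer"),
and patients can be stratified by ward.D2 clustering of their ECv
patterns, with a log-rank test between the resulting groups.

For whom: computational biologists who want condition-specific or
sample-specific network readouts from small designed experiments, and a
fully seeded synthetic workflow to validate the machinery end to end.

## Worked example

Simulate the 18-sample design with three planted condition-responsive
edges, estimate the basal network by iterated subnetwork sampling, fit the
local models, and extract the differential edges:

```r
library(ecvnet)
gt <- makeGroundTruth(p = 10, nPerturbed = 3, seed = 1)
X  <- simulateExpression(gt, seed = 2)

freq   <- nnsrEstimate(X, tIter = 200, subsetSize = 4, seed = 1)
basal  <- thresholdNetwork(freq, 0.1)      # BasalNetwork: 10 genes, 10 edges
models <- fitAllModels(X, basal)
E      <- computeEcvMatrix(models, X)      # EcvMatrix: 18 samples x 10 edges

si <- sampleInfo(X)
groups <- setNames(lapply(sort(unique(si$line)), function(l) list(
  S = rownames(si)[si$condition == "treated" & si$line == l],
  T = rownames(si)[si$condition == "control" & si$line == l])),
  sort(unique(si$line)))
tab  <- deltaEcvTable(E, groups)
hits <- extractDifferentialEdges(tab, threshold = 1.0, mode = "all")
hits
#>   parent child line1 line2 line3
#> 1    g08   g05  1.59  2.38  2.03
#> 2    g09   g06  1.98  1.31  2.03
#> 3    g08   g07  2.29  1.94  1.83
#> 4    g07   g10  2.27  2.10  1.51
```

The numbers are the per-line dECv values: every extracted edge changed its
contribution by more than 1 (i.e. a transmitted two-fold change) in all
three lines. The planted regulator-target pairs were (g05, g08),
(g06, g09), (g07, g10); all three are recovered — two in the reversed
orientation, which is expected, since edge direction is only weakly
identifiable from 18 samples, while the dECv signal lives on the gene
pair. The fourth edge links two treatment-responsive genes.

```r
buildSubnetwork(basal, hits)
#> Subnetwork: 6 nodes, 7 edges (4 extracted + 3 basal fill)

tests <- ecvEdgeTests(E, S = rownames(si)[si$condition == "treated"],
                      T = rownames(si)[si$condition == "control"])
subset(tests, q < 0.01)       # Welch t per edge, BH-adjusted, 9 vs 9
#>   parent child     t        p        q
#> 5    g08   g05  7.49 1.94e-06 9.72e-06
#> 8    g08   g07 11.40 3.56e-08 3.56e-07
#> ...
```

`transferEcv()` evaluates the trained models on a new cohort (shared genes
only, out-of-range values clamped, dropped edges reported),
`wardCluster()` + `logrankTest()` stratify the cohort by ECv pattern, and
`runPipeline()` drives the whole flow from one YAML/list configuration,
writing every intermediate as TSV/SIF/GraphML/JSON. A thin command-line
wrapper lives in `inst/scripts/ecvnet-cli.R`.

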