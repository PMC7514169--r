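# efemin

Expected float entropy minimisation: learning the weighted relations a
multivariate categorical system defines, and using them to complete
partially observed states.

## The idea

Consider a system of `n` nodes, each observed in one of `m` repertoire
states (the canonical example: a 3×3 grid of pixel locations sampled
from four-shade greyscale images). Two *weighted relations* — reflexive
symmetric maps into [0, 1] — parameterise the system's structure: `U`
relates repertoire states to each other, and `R` relates nodes to each
other. Any complete observation *induces* a node relation by reading
`U` at the pair of states it assigns to each node pair.

The *float entropy* of an observation is the log2-count of system
states whose induced relation lies no farther (in the `d1` matrix
distance) from `R` than the observation's own does — the information
needed to specify the state beyond what the relations already say. The
*expected float entropy* (efe) averages this over the observed data.
Minimising efe over `(R, U)` recovers the relations the system defines:
on image-patch data, `R` recovers the spatial geometry of the sampling
grid (nearby pixels strongly related) and `U` recovers the similarity
of neighbouring shades.

The learned relations are then applied in reverse: *minimum float
entropy completion* fills deleted node states by choosing, among all
candidate completions, those with minimal float entropy. The package
provides the whole pipeline — exact state-space enumeration, a fast
C++ distance engine, coordinate-bisection learning with grid-symmetry
support, Monte-Carlo null histograms, the completion experiment with
mode and guessing baselines, a conditional-Shannon-entropy
reformulation, multi-relational float entropy over derived tuple
nodes, and a synthetic generator of spatially correlated posterised
data standing in for photograph corpora.

## Worked example

Generate synthetic typical data under the canonical study conditions
(3×3 grid sampled every 10 px from spatially correlated four-shade
fields), learn the relation pair on the five-node "plus" subset, and
extend to all nine nodes by grid symmetry:

```r
library(efemin)

T <- generateTypicalData(400, fieldParams(), seed = 1)
T
#> TypicalData: 400 observations of 9 nodes, 4 repertoire states
#>   repertoire: shade1, shade2, shade3, shade4

fit <- minimiseEfe(T, subset = c("node2", "node4", "node5",
                                 "node6", "node8"))
Rfull <- extendBySymmetry(fit$R, systemLayout(T))
Rfull
#> WeightedRelation on 9 labels (reflexive, symmetric)
#>         node1   node2   node3   node4   node5   node6
#> node1 1.00000 0.95312 0.68750 0.95312 0.85938 0.68750
#> node2 0.95312 1.00000 0.95312 0.85938 0.95312 0.85938
#> node3 0.68750 0.95312 1.00000 0.68750 0.85938 0.95312
#> node4 0.95312 0.85938 0.68750 1.00000 0.95312 0.68750
#> node5 0.85938 0.95312 0.85938 0.95312 1.00000 0.95312
#> node6 0.68750 0.85938 0.95312 0.68750 0.95312 1.00000
#>   ... (9x9 matrix)
```

The learned node relation is constant on grid displacement classes and
ordered exactly as the geometry demands: adjacent pairs (0.95312) >
diagonal pairs (0.85938) > distance-2 pairs (0.68750). The repertoire
relation ranks neighbouring shades far above the extremes:

```r
fit$U
#> WeightedRelation on 4 labels (reflexive, symmetric)
#>         shade1  shade2  shade3  shade4
#> shade1 1.00000 0.42188 0.01562 0.01562
#> shade2 0.42188 1.00000 0.48438 0.01562
#> shade3 0.01562 0.48438 1.00000 0.45312
#> shade4 0.01562 0.01562 0.45312 1.00000
```

The solution's efe sits far below anything uniformly random relations
achieve:

```r
efeFull <- efeValue(efeEmpirical(Rfull, fit$U, T))
set.seed(2)
h <- efeHistogram(T, 2000, marker = efeFull)
h
#> EfeHistogram: 2000 samples, bin 0.05 bpe; range [ 14.618 , 17.824 ]
#>   marker: 9.8386 bpe (percentile 0 %)
```

Finally, hide four of the nine node states in each of 200 fresh test
observations and complete them by minimum float entropy, against the
per-node-mode and uniform-guessing baselines:

```r
W <- generateTypicalData(200, fieldParams(), seed = 2)
set.seed(3)
res <- runCompletionExperiment(Rfull, fit$U, W, T, k = 4)
res$minFe$meanCorrect   # 2.2725 of 4 hidden nodes correct on average
res$mode$meanCorrect    # 1.395 for the independent-mode baseline
res$guessing$expectation  # 1 for uniform guessing
res$guessingTailExact   # 4.6e-81: not luck
```

## Documentation

The methods vignette (`vignettes/efemin-methods.Rmd`) details the
model, the optimiser reconstruction, the tie-exact counting rules, the
synthetic generator's design rationale, and the package's limitations.
`greyscaleExample()` ships a fully worked 9-node reference system with
an approximate minimal-efe relation pair.
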