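# qdabiplot

Two-dimensional visualisation of **quadratic discriminant analysis (QDA)**,
for analysts who need to *see* how variables drive the separation of groups
with unequal covariance structures — the classic situation when diseased
patients are more variable than healthy ones, or when binary
presence/absence panels (pathogen detections, 0/1 indicators) differ in
spread between patient groups.

## The idea

The classical CVA/LDA biplot assumes one shared within-group covariance, so
a single canonical transformation maps all samples into one display space.
QDA drops that assumption: each class *j* gets its own covariance *S*ⱼ and
its own quadratic score

```
phi_j^2(x) = (x - xbar_j)' S_j^{-1} (x - xbar_j) + log|S_j|
```

with classification to `argmax_j { log(pi_j) - phi_j^2(x) / 2 }`. There is
then no single linear map to a common space — so the package uses the J
scores themselves as new variables: standardize each column of the n × J
score matrix to mean 0 / SD 1, take the first two principal components as
sample coordinates, and colour classification regions by **back-projecting**
every display point to its J approximate scores and applying the same rule.
Original variables are overlaid as **calibrated axes** (regression method:
orthogonal projection onto an axis reads off the fitted value in original
units), optionally translated orthogonally out of the point cloud for
readability. For two groups the display is exact and the equal-prior
boundary of the raw-score scatter is literally the line *y = x*. The
classical CVA biplot with nearest-canonical-mean regions is included for
the equal-covariance case.

## Worked example

The bundled benchmark: three four-variate normal groups of 50 samples with
means (1,1,1,1), (−1,2,3,4), (1,1,5,5) and covariances I, 2I and unit
variance with equicorrelation 0.7 — three genuinely different covariance
structures.

```r
library(qdabiplot)
d  <- simulateNormal(threeGroupSpec())        # seeded 150 x 4 draw
m  <- buildPhiMatrix(d, fitQuadratic(d, priors = "proportional"))
m
#> QuadraticModel: 3 classes, 4 variables
#>   priors: g1=0.333, g2=0.333, g3=0.333
#>   log|S_j|: -0.3576, 2.228, -2.502
#>   standardized score matrix: 150 x 3

lay <- buildRegionGrid(qdaScores(d, m), m, resolution = 200)
lay@axes <- translateAxes(regressionAxes(lay, d), lay)
lay
#> BiplotLayout (qda): 150 samples, 3 classes
#>   4 calibrated axes
#>   region grid 200 x 200

plot(lay)                                     # or renderBiplot(lay, "biplot.svg")

pred <- classifyDisplayPoint(sampleScores(lay), lay, m)
table(observed = groupLabels(d), predicted = pred)
#>         predicted
#> observed  1  2  3
#>       g1 40 10  0
#>       g2  5 40  5
#>       g3  0 22 28
```

The log-determinants rank the groups by volume: group 2 (covariance 2I) is
by far the most diffuse (log|S₂| ≈ 2.23), group 3's strong correlation
concentrates it (≈ −2.50). In the display every group keeps the majority of
its samples inside its own region; the confusion shows what the 2-D
approximation costs for three groups (direct `qdaClassify()` on the same
data is 145/150 correct — the display regions are a picture of the rule,
not a replacement for it). Projecting the sample cloud onto the calibrated
V3/V4 axes shows group 1 lowest and group 3 highest, exactly the pattern
put into the generating means.

For a two-class binary panel:

```r
b <- pathogenPanel(100, 15, probs = rbind(runif(15, .1, .4),
                                          runif(15, .3, .8)), seed = 9)
mb <- buildPhiMatrix(b, fitQuadratic(b))
plot(buildRegionGrid(qdaScores(b, mb), mb), collapseBinary = TRUE, data = b)
```

Identical response patterns collapse to one glyph sized by multiplicity and
coloured by majority vote. If a class has a within-class constant indicator
(its covariance is then singular), refit with `fitQuadratic(..., ridge = 0.05)`.

The same pipeline runs from the shell:

```sh
Rscript inst/cli/qda-biplot.R simulate --out sim.csv --seed 42
Rscript inst/cli/qda-biplot.R fit-plot --input sim.csv --kind qda \
    --priors proportional --resolution 400 --out biplot.svg \
    --labels labels.csv --confusion confusion.csv
```

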