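# motifsyntax

Cis-acting mRNA elements — RNA-binding-protein motifs, microRNA seeds,
upstream AUGs — regulate translation efficiency and transcript
stability, and they act combinatorially: the joint effect of two
co-occurring motifs frequently deviates from the sum of their individual
effects. Deep sequence-to-function models learn this regulatory code but
do not surface it. `motifsyntax` is for computational biologists who
train such models (on mean-ribosome-load reporter assays, half-life
compendia, or synthetic libraries) and want the code back out:

* **Predictor** — a hybrid convolutional–recurrent network
  (layer-norm / conv / max-pool blocks, a GRU, a dense head) mapping an
  encoded RNA sequence to a scalar label, trained with Adam and early
  stopping; fully seed-deterministic, implemented in base R linear
  algebra with gradients verified against finite differences.
* **Motif discovery** — maximal-activation seqlets per convolutional
  neuron, decoupled into one or more position probability matrices by
  k-means with silhouette model selection (multifaceted neurons yield
  several motifs instead of one blurred average), annotated against a
  motif library with permutation q-values (significant at q ≤ 0.001).
* **Contribution analysis** — for each neuron, sequences are split by
  whether they activate it (above 0.5 of the dataset-wide maximum), and
  the two groups' labels are compared by a Mann–Whitney test: a
  significantly higher activating group means the motif enhances the
  property, lower means it represses.
* **Interaction analysis** — combinatorial in-silico mutagenesis per
  co-occurring pair: predictions `o` (intact), `a` (B scrambled), `b`
  (A scrambled), `n` (both scrambled); a Wilcoxon signed-rank test of
  the joint effect against the sum of marginals,

  `d_i = (o - n)_i - [(a - n)_i + (b - n)_i]`,

  classifies each pair as synergistic, antagonistic, additive, or (for
  opposite-sign motifs) sign-epistatic.
* **Simulation benchmark** — synthetic datasets with planted motif
  effects and interactions (`y = Σ e_m I_m + Σ s_ij e_ij I_i I_j + ε`),
  random versus designed sequence composition, an upstream-AUG label
  shortcut and its filter, and an end-to-end score of how many planted
  interactions the whole pipeline recovers (TPR).

## Worked example

Generate a designed dataset in which every 50-nt sequence carries one of
the six pairs from a four-motif library, with all six pair interactions
planted (three synergistic, three antagonistic), train the 3-block
predictor variant, and run the complete interpretation pipeline:

```r
library(motifsyntax)

spec <- simulation_spec(20000, "designed", dense_interactions = TRUE,
                        seed = 1)
print(spec)
#> <simulation_spec> 20000 designed sequences of 50 nt; 4 motifs; noise sd 0.3
#>   epistatic pairs: m6A:PUF (syn 1), m6A:ARE (ant 1), m6A:CGG (syn 1), PUF:ARE (ant 1), PUF:CGG (ant 1), ARE:CGG (syn 1)

bm <- recovery_benchmark(spec, max_clusters = 8)
print(bm)
#> <recovery_benchmark> designed dataset, n = 20000: TPR 83% (5/6 planted interactions)
#>   model validation r = 0.935; 6 pair(s) proposed
#>  motif_a motif_b         type     direction recovered
#>      m6A     PUF  synergistic joint_greater      TRUE
#>      m6A     ARE antagonistic joint_smaller      TRUE
#>      m6A     CGG  synergistic joint_greater      TRUE
#>      PUF     ARE antagonistic joint_greater     FALSE
#>      PUF     CGG antagonistic joint_smaller      TRUE
#>      ARE     CGG  synergistic joint_greater      TRUE
```

Reading the output: the trained model predicts held-out labels at
r = 0.93; interpreting its deepest convolutional layer proposed all six
motif pairs; and for five of the six the paired signed-rank direction of
`(o - n)` versus `(a - n) + (b - n)` matched the planted interaction
type, giving a true positive rate of 5/6. The persistent miss (PUF:ARE
here) is one of the two pair interactions that are mathematically
absorbable into additive per-motif effects in an all-pairs design and
are identified only through chance third-motif occurrences — see the
vignette for that analysis. The same pipeline on 20,000 uniformly
*random* sequences proposes no pairs at all (TPR 0%): chance
co-occurrence of two specific motifs in a 50-mer is too rare to enrich
any combination, which is the central argument for designed over random
training libraries.

Individual stages are available directly: `train_predictor()`,
`interpret_layer()`, `annotate_motifs()`, `neuron_contributions()`,
`test_motif_pair()`, `interaction_map()`. A thin command-line front end
(`inst/cli/motifsyntax.R`) exposes `train` / `interpret` /
`contribution` / `interactions` / `simulate` / `benchmark` subcommands
over TSV/FASTA data, MEME motif files, and flat YAML configs.

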