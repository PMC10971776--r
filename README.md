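# mhcgraph

Graph-attention prediction of MHC class I–peptide binding from molecular
structure, with downstream neoantigen-load survival analysis.

## The problem

MHC class I molecules present 9-mer peptide fragments to cytotoxic T
cells. A tumour mutation that yields a peptide binding the patient's MHC
(IC50 ≤ 500 nM in a competitive binding assay) is a neoantigen candidate,
and the per-patient count of predicted binders — the *neoantigen load* —
is a candidate biomarker for immune-checkpoint-inhibitor response.
`mhcgraph` models binding from chemistry rather than from sequence
letters: the MHC binding groove (its 34-residue NetMHCpan-style
pseudo-sequence) and the candidate peptide are each built into an
explicit-hydrogen molecular graph from curated residue templates, joined
as the two disconnected components of a single graph, featurized
atom-by-atom and bond-by-bond, and classified by a graph attention
network.

## The model

Each atom is a 31-dimensional one-hot feature vector (element H/C/N/O/S,
hybridization, degree, bonded-hydrogen count, chirality, aromaticity,
ring membership, formal charge, radical electrons); each bond contributes
two directed edges with a 12-dimensional vector (bond type, stereo, ring,
conjugation). The classifier stacks four multi-head graph-attention
layers — per head, for edge $j \to i$ with bond features $e_{ij}$,

$$\alpha_{ij} = \operatorname{softmax}_j \operatorname{LeakyReLU}
\left(a_\mathrm{dst}^\top W h_i + a_\mathrm{src}^\top W h_j +
a_\mathrm{edge}^\top U e_{ij}\right),
\qquad h_i' = \Vert_h \sum_j \alpha_{ij} W h_j,$$

each followed by graph normalization and an ELU — then a mean readout
over all atoms of both chains, and a 1-D convolution head
(Conv1D → BatchNorm → ReLU → Conv1D with an identity skip connection,
average pooling, fully-connected sigmoid). Training uses ADAM on binary
cross-entropy, batch size 64, with labels from the 500 nM rule and a
seeded 80/20 split. Forward and backward passes are written in
vectorized R with C++ (Rcpp) kernels for the per-edge hot loops; every
analytic gradient is verified against finite differences in the test
suite.

Evaluation reports AUC-ROC with a DeLong 95% confidence interval,
and sensitivity / specificity / F1 with Wilson and bootstrap intervals.
The application stage enumerates the 9-mer windows covering a missense
position, counts predicted-binder (allele, peptide) pairs per patient,
splits the cohort at the median load, and compares groups by the
Mantel–Cox log-rank test on overall survival and Mann–Whitney rank-sum
tests on stromal/immune/ESTIMATE scores.

Because full-scale IEDB training data and patient cohorts cannot ship
with a package, `mhcgraph` includes a synthetic-data generator with a
planted anchor-residue binding rule (preferred residues at peptide
positions 2 and 9, per synthetic allele) and a cohort generator with
load-dependent exponential survival, so the whole pipeline is testable
end to end with known ground truth. See the methods vignette
(`vignettes/mhcgraph-methods.Rmd`) for the model, its assumptions, all
tunable parameters and the benchmark's scope.

## Worked example

```r
library(mhcgraph)

# a synthetic affinity benchmark with a planted two-anchor binding rule
cfg <- synth_config(n_alleles = 4, pseudo_length = 8, n_records = 2500,
                    seed = 1)
ds  <- generate_affinity_dataset(cfg)
head(ds$records, 3)
#>      allele   peptide       ic50 label
#> 1 SYN-03:01 EKFFNGEGE    55.1431     1
#> 2 SYN-02:01 SVFSLHFKK    61.1047     1
#> 3 SYN-02:01 KVDNRKAAR 21518.5866     0

g <- featurize_pair(ds$mapping[[1]], ds$records$peptide[1], ds$records$label[1])
dim(g$x)          # one row of 31 features per atom, hydrogens included
#> [1] 290  31
g$n_components    # MHC chain and peptide are disconnected components
#> [1] 2

samples <- featurize_records(ds$records, ds$mapping)
sp <- split_train_test(samples, 0.8, seed = 1)     # 2000 / 500
model <- train_model(sp$train,
                     model_config(attention_heads = 4, gat_hidden = 8,
                                  conv_channels = 8),
                     train_config(epochs = 30, learning_rate = 3e-3,
                                  seed = 1))
ev <- evaluate_model(model, sp$test)
round(c(auc = ev$auc, ev$auc_ci, sens = ev$sensitivity,
        spec = ev$specificity, f1 = ev$f1), 3)
#>   auc lower upper  sens  spec    f1
#> 0.956 0.938 0.975 0.996 0.801 0.903
```

The held-out AUC of 0.956 says the network has recovered most of the
planted anchor rule from raw molecular graphs; the DeLong interval
(0.938–0.975) is its sampling uncertainty over the 500 test pairs. The
asymmetric sensitivity/specificity (0.996 / 0.801) shows the desk-scale
model trades false positives for a very low false-negative rate at the
0.5 threshold.

The trained model drives the cohort stage: `neoantigen_analysis()` takes
a patient table (alleles, protein sequence, mutation position) and a
clinical table, computes loads, and returns the median-split group
assignment with the log-rank and rank-sum statistics.

A command-line wrapper with `synth` / `featurize` / `train` / `evaluate`
/ `predict` / `neoload` subcommands is installed at
`inst/cli/mhcgraph.R`:

```sh
Rscript "$(Rscript -e 'cat(system.file("cli/mhcgraph.R", package="mhcgraph"))')" help
```

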