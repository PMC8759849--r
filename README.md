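# ktafs

Feature selection and classification for high-dimensional gene-expression
profiles (microarray or RNA-seq style samples-by-genes matrices with
cancer-subtype labels).

The central problem is the classic "large p, small n" one: tens of
thousands of genes, a few hundred samples, and only a handful of genes that
actually separate tumour subtypes. `ktafs` implements an unsupervised
**kernel-target alignment** selector together with the standard filter and
wrapper baselines, and a compact 1-D convolutional softmax classifier to
evaluate the selected genes.

## The method

Samples are preprocessed with the count transform `x = log2(y + 1)`, a
low-expression filter (a gene survives iff its mean log2 expression exceeds
1.19), standardisation, and PCA. A low-dimensional latent embedding `z` of
the samples (PCA projection by default, a trained autoencoder bottleneck as
an alternative) defines a *target kernel*

    K_Z[i, j] = exp(-gamma ||z_i - z_j||^2).

One Gaussian kernel `K_f` is built per gene, and non-negative weights `mu`
are fitted to maximise the centered kernel-target alignment

    A(K_mu, K_Z) = <K_mu, K_Z>_F / (||K_mu||_F ||K_Z||_F),
    K_mu = sum_f mu_f K_f,   mu_f >= 0,

optionally with an L1 penalty. Genes with large weights carry the sample
similarity structure of the latent space; the top-p weights form the
selection. Baselines provided at the same interface: information gain,
mRMR (MID and MIQ criteria built on the one-way ANOVA F statistic and
Pearson redundancy), Relief-F / Relief-D, CFS merit search, and an
artificial-bee-colony wrapper scored by cross-validated accuracy of a
nearest-centroid reference classifier.

Classification uses a single-block 1-D CNN — convolution (32 filters,
width 5) → ReLU → max-pooling (2) → softmax — trained with Adam, decoupled
weight decay (1e-8), batch size 10 and early stopping (patience 10),
evaluated by stratified 2-fold cross-validation repeated 3 times.
Confusion matrices and classification reports (precision / recall / F1 /
support, macro and weighted averages) follow the standard conventions,
including reconstruction of integer counts from proportion-form matrices.

## Worked example

```r
library(ktafs)

gen <- generate_dataset(n_per_class = c(200, 200), d = 500,
                        n_informative = 10, effect_size = 2, seed = 1)
lg  <- log_transform(gen$data)
fl  <- filter_genes(lg, threshold = 1.19)
pc  <- pca_reduce(fl$data, n_components = 133)
emb <- encode(fit_latent(pc$scores, backend = "pca", latent_dim = 8),
              pc$scores)
w   <- fit_alignment_weights(fl$data, gaussian_kernel(emb))
sel <- select_features(w, rule = "top_p", p = 20)
recovery_score(sel, gen$truth)
#> [1] 1
glance(w)
#> # A tibble: 1 x 5
#>   alignment n_nonzero iterations converged lambda
#>       <dbl>     <int>      <int> <lgl>      <dbl>
#> 1     0.857       333         41 TRUE           0

cv <- cross_validate(lg, k = 2, repeats = 3, seed = 0)
cv
#> 2-fold CV x 3 repeats: mean accuracy 0.995 (sd 0.004)
```

All 20 planted genes land in the top-20 alignment weights
(`recovery_score = 1`), and the CNN separates the two synthetic subtypes
at ~99.5% cross-validated accuracy.

Report utilities reproduce published-style tables from proportion-form
confusion matrices:

```r
cm <- counts_from_proportions(rbind(c(0.12, 0.06), c(0.03, 0.79)), 33)
classification_report(cm)
#>                precision    recall  f1-score   support
#> 0                   0.80      0.67      0.73         6
#> 1                   0.93      0.96      0.95        27
#> accuracy                                0.91        33
#> macro avg           0.86      0.81      0.84        33
#> weighted avg        0.91      0.91      0.91        33
```

A full config-driven run (load → preprocess → latent → select → CNN CV →
report) is available as `run_pipeline()` or the thin CLI in
`inst/exec/ktafs-pipeline`.

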