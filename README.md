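# phnet

Protein function prediction by random walk with restart on a heterogeneous
protein–domain network.

## The problem and the method

Most function-prediction methods read a protein's Gene Ontology (GO)
annotations off its interaction neighbours, but protein–protein interaction
(PPI) data are noisy and incomplete, and flattening extra evidence (protein
complexes, Pfam domains) into a single network discards what makes each data
type informative. `phnet` instead keeps two node types — proteins and
domains — in one **heterogeneous network** and diffuses functional
similarity over it:

1. **Weighted protein layer.** For a protein *u* with direct-neighbour set
   S₁ and level-2-neighbour set S₂, the topological similarity is

   fs(u,v) = 1 if v ∈ S₁∩S₂;  α if v ∈ S₁−S₂;  1−α if v ∈ S₂−S₁;  0 otherwise,

   with α ∈ (0,1) (default 0.8). Complex co-membership contributes the
   module similarity ms(u,v) = |C_u ∩ C_v|² / (|C_u|·|C_v|), where C_u is
   the set of complexes containing *u*. The layer weight is the blend
   **mpp(u,v) = β·fs(u,v) + (1−β)·ms(u,v)**, with β defaulting to 0.8 (BP),
   0.7 (MF) or 0.9 (CC).

2. **Domain layer.** The binary protein–domain incidence mpd links the two
   layers. Domain–domain similarity is derived from the weighted protein
   layer: with S_PD(u, PL) = max over p ∈ PL of mpp(u,p) and PL(d) the
   protein list of domain *d*,

   mdd(dᵢ,dⱼ) = [Σ_{p∈PL(dᵢ)} S_PD(p,PL(dᵢ)) + Σ_{q∈PL(dⱼ)} S_PD(q,PL(dⱼ))] / (|PL(dᵢ)|+|PL(dⱼ)|).

3. **Propagation.** The blocks [[MPP, MPD], [MPDᵀ, MDD]] are row-normalized
   into a transition matrix in which a node with links in both layers
   reserves probability λ (default 0.2) for switching layers. Starting from
   the restart profile pr⁰ = [mpp(u,·); per-domain max of it], the scores
   iterate **pr ← (1−γ)·T·pr + γ·pr⁰** (γ = 0.5) until the L1 change drops
   below 1e−6.

4. **Annotation.** Candidate terms from all positive-score partners are
   ranked by S(fn) = Σ_partners pr(j)·[j carries fn], and the target
   receives the top **L** terms, where L is the annotation count of its
   most similar annotated partner.

The package ships readers for the standard formats (two-column PPI edge
lists, CYC2008-style complex catalogs, Pfam-style association tables,
GAF 2.x), a planted-module synthetic benchmark generator, and the full
evaluation protocol: leave-one-out and k-fold cross-validation,
precision/recall with the harmonic-mean F-measure of the dataset averages,
top-K ROC ladders with AUROC, and a β sweep. It is aimed at method
developers and systems-biology analysts who want a transparent,
fully-testable reference implementation.

## Worked example

```r
library(phnet)

ds  <- generate_dataset(synthetic_config(seed = 7))   # 60 proteins, 8 complexes
fit <- phn(ds$graph, ds$complexes, ds$domains, ontology = "BP")
fit
#> Heterogeneous protein-domain propagation network
#>   proteins: 60   domains: 16
#>   ontology: BP   alpha = 0.8, beta = 0.8, lambda = 0.2

predict(fit, "P008", ds$annotations)
#> phn_prediction for P008: L = 3, 24 candidate terms, 58 partners
#>   rank       term    score
#> 1    1 GO:0000004 4.032569
#> 2    2 GO:0000016 4.032569
#> 3    3 GO:0000009 4.028051

protein_terms(ds$annotations, "P008")
#> [1] "GO:0000004" "GO:0000009" "GO:0000016"
```

The target's own annotations are hidden before scoring; the three planted
terms of its complex are still recovered exactly (L = 3 because its most
similar annotated partner carries three terms; the scores are the summed
propagation mass of the partners carrying each term).

```r
ev <- leave_one_out(fit, ds$annotations)
ev
#> phn_evaluation (loocv, BP): 52 proteins
#>   precision = 0.865  recall = 0.859  F-measure = 0.862

roc_curve(ev$ranked, ds$annotations)
#> roc_curve: K = 1..24 over 52 proteins, AUROC = 0.9503
```

A command-line interface wrapping the same functions is installed at
`system.file("cli", "phn", package = "phnet")` with subcommands `simulate`,
`build-network`, `predict`, `evaluate` and `sweep-beta`.

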