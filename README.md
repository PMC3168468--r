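# ensembledyn

Comparative analysis of protein conformational ensembles from molecular
dynamics, built for the question cold-adaptation studies keep asking: when
a psychrophilic enzyme is mutated toward its mesophilic homolog, *which*
interactions and collective motions actually shift? The package compares
two or more ensembles residue by residue through a structural
correspondence, using five observables:

- **Surrounding hydrophobicity** — per residue *i*,
  `Hp(i) = Σ_{j≠i} H(r_d − r_ij) h_j` over Cα–Cα distances `r_ij` with
  cutoff `r_d = 0.8` nm and transfer-free-energy indices `h_j` (kcal/mol);
- **Hydrogen bonds** — geometric detection (donor–acceptor ≤ 0.35 nm,
  donor-vertex angle ≤ 30°) with the percentage of donors+acceptors
  engaged;
- **Essential dynamics** — diagonalisation of the Cα covariance matrix;
  per-residue rmsf after projection on the essential subspace (70%
  variance by default), anisotropic U-tensors (probability-0.1
  ellipsoid convention), cosine content and RMSIP sampling diagnostics,
  sliding-window rmsf convergence (1–20 ns windows, 500 ps step);
- **Cross-correlation networks** — `C(i,j) = c(i,j)/√(c(i,i)c(j,j))`
  averaged over non-overlapping 1 ns windows, filtered to significant
  (`|C| > 0.4`) long-range (`|i−j| > 12`) couplings, and differenced
  across systems through the correspondence;
- **Salt-bridge networks** — oppositely charged groups within 0.4 nm in
  at least 24% of the macro-trajectory frames, the cutoff selectable by
  the SVM + 4-NN classifier procedure on the bimodal persistence
  distribution (noise < 10%, signal > 30%), spatial-proximity clusters
  (bridge arcs plus |i−j| < 5 sequence arcs), conservation groups
  (I/IV/II-III) across wild types and mutants, and Pearson correlation
  of acquired mesophilic-like bridges with Tm and kcat/Km.

Synthetic-ensemble generators with analytic ground truth
(`gen_gaussian_ensemble`, `gen_contact_series`, `gen_homolog_pair`,
`gen_two_system_fixture`) make every stage verifiable without any
trajectory download. MD itself, DSSP, structural alignment and SASA are
out of scope: ensembles, label tables and correspondences are inputs.

## Worked example

Two synthetic systems that differ by exactly one planted long-range
correlated pair and one planted high-persistence salt bridge:

```r
library(ensembledyn)

fx  <- gen_two_system_fixture(seed = 42)
cfg <- analysis_config(systems = list(cold = fx$a, variant = fx$b),
                       reference = "cold")
rep <- run_pipeline(cfg)
rep
#> Comparative ensemble analysis of 2 system(s): cold, variant
#>   cold vs variant: correlation edges +1/-0; salt bridges +1/-0

rep$comparisons$variant$network$only_b
#>   i  j         c
#> 1 8 30 0.6543115

rep$comparisons$variant$bridges$only_b
#>   res_a res_b name_a name_b persistence
#> 3    47    48    GLU    LYS       0.909
```

The report finds one correlation edge and one salt bridge present only
in the variant — the planted differences (`fx$truth`), and nothing else:
residues 8 and 30 move together with averaged correlation 0.65 (above
the 0.4 significance cutoff, 22 residues apart in sequence), and the
GLU47–LYS48 pair is formed in 90.9% of frames (far above the 24%
persistence cutoff). Classifier-based cutoff selection on a bimodal
persistence sample:

```r
select_persistence_cutoff(rpersistence_mixture(200, seed = 42)$p)
#> Persistence cutoff 0.230 (SVM 0.220, 4-NN 0.240, disagreement 0.019)
#>   trained on 111 noise (< 0.10) and 89 signal (> 0.30) interactions
```

Both classifiers place the boundary inside the empty (0.10, 0.30) gap
between transient encounters and structural bridges.

Setting `outdir` in `analysis_config()` writes every table (Hp, rmsf,
eigenvalue spectra, correlation edges, salt-bridge persistences,
clusters, cross-system diffs) as TSV with a commented parameter header;
reruns are byte-identical.

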