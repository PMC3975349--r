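# pseaacg

Fixed-length numeric descriptors for protein sequences: the thirteen
standard modes of general-form pseudo-amino-acid composition (PseAAC),
computed from FASTA input at scale.

Sequence-based prediction of protein attributes (subcellular location,
structural class, enzyme family, ...) needs each variable-length sequence
mapped to a fixed-length feature vector. Plain amino-acid composition does
that but loses all sequence order; PseAAC retains partial order
information by appending *sequence-order correlation factors* to the 20
residue frequencies, and its general form admits any feature source —
physicochemical correlations, GO terms, functional domains, PSSM profiles
— as vector components. This package is for anyone building such feature
matrices for downstream machine learning.

## The modes

| mode | descriptor | dimensionality |
|---|---|---|
| `aac`, `dpc`, `tpc` | amino-acid / di-peptide / tri-peptide composition | 20 / 400 / 8000 |
| `pseaac1` | Type I PseAAC: `x_u = f_u/(1+w·Στ_j)`, `τ_j = mean_i Θ(R_i,R_{i+j})` with `Θ` the mean squared standardized-property difference | 20 + λ |
| `pseaac2` | Type II (amphiphilic) PseAAC: interleaved lagged hydrophobicity/hydrophilicity products | 20 + 2λ |
| `nmbroto`, `moran`, `geary` | autocorrelation of a property profile at lags 1..D | properties × D each |
| `ctd` | composition–transition–distribution over 3-class attribute groupings (7 bundled) | 21 per grouping |
| `qso` | quasi-sequence-order: coupling numbers `τ_d = Σ d(R_i,R_{i+d})²` over a distance matrix (2 bundled) | (20 + D) per matrix |
| `go`, `fdom` | binary presence vectors over an annotation-term universe | universe size |
| `psepssm` | PSSM column means + lagged squared differences | 20 + 20ξ |

Defaults: λ = 30, w = 0.05 (Type I/II), D = 30, QSO w = 0.1, ξ = 10. Any
AAindex-format property table can back the property-driven modes
(`load_property_table(..., "aaindex1")`); with a full 544-property table
the built-in modes at defaults span 57,977 descriptor values. User-defined
modes plug into the same registry (`mode_spec()` + `register_plugin()`)
and batch engine.

## Worked example

```r
library(pseaacg)

recs <- synth_proteins(seed = 1, n = 3, length_range = c(60L, 90L))
v <- type1_pseaac(recs[[1]], lambda = 5, w = 0.05)
round(v[c(1:3, 21:25)], 4)
#>    PseAAC1_A    PseAAC1_C    PseAAC1_D PseAAC1_lam1 PseAAC1_lam2 PseAAC1_lam3
#>       0.0391       0.0313       0.0078       0.0606       0.0763       0.0610
#> PseAAC1_lam4 PseAAC1_lam5
#>       0.0675       0.0776
sum(v)
#> [1] 1
```

The first 20 components are residue frequencies down-weighted by the
correlation mass; the `lam` components carry the tier-wise sequence-order
correlations; the vector sums to one by construction (a homopolymer would
reduce it exactly to plain composition).

Batch processing streams a FASTA file in constant memory and writes CSV,
TSV or svmlight:

```r
fa <- tempfile(fileext = ".fasta"); write_fasta(recs, fa)
run_batch(run_config(fa, "pseaac1", "features.csv", params = list(lambda = 5L)))
#> <run_report>
#>  records read:    3
#>  records skipped: 0
#>  rows written:    3
#>  dimensionality:  25
#>  output:          features.csv (csv)
#>  elapsed:         0.01 s
```

The same job runs from a shell via the bundled CLI:

```sh
Rscript "$(Rscript -e 'cat(system.file("cli", "pseaac.R", package = "pseaacg"))')" \
  run --mode pseaac1 --in proteins.fasta --out features.csv --param lambda=5
```

(`modes` lists the registry with dimensionalities; `enumerate` prints the
descriptor-space size; a YAML config via `--config` mirrors all flags.)

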