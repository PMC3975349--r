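---
title: "General-form PseAAC descriptors: models, parameters and design"
output: rmarkdown::html_vignette
vignette: >
  %\VignetteIndexEntry{General-form PseAAC descriptors: models, parameters and design}
  %\VignetteEngine{knitr::rmarkdown}
  %\VignetteEncoding{UTF-8}
---

```{r setup, include = FALSE}
knitr::opts_chunk$set(collapse = TRUE, comment = "#>")
library(pseaacg)
```

## Why pseudo-amino-acid composition

Machine-learning models of protein attributes (subcellular location,
structural class, enzyme family, ...) need a fixed-length numeric
representation of a variable-length sequence. Plain amino-acid composition
achieves that but discards all sequence order. Pseudo-amino-acid
composition (PseAAC) augments the 20 residue frequencies with a small
number of *sequence-order correlation factors*, so that two proteins with
identical composition but different residue arrangement map to different
vectors. The *general form* of PseAAC goes further: any feature source —
physicochemical correlations, GO annotations, functional domains,
evolutionary profiles — can populate the vector components. This package
generates the thirteen standard modes of that family from FASTA input,
plus arbitrary user-defined modes via a plugin registry.

## The descriptor families

**Composition** (`aac`, `dipeptide`, `tripeptide`). Frequencies of the
20 residues, 400 ordered pairs, and 8000 ordered triples over overlapping
windows, normalized by the window count (`L`, `L-1`, `L-2`). Each vector
sums to one, making vectors comparable across sequence lengths.

**Type I PseAAC** (`type1_pseaac`). The coupling function
$\Theta(a,b) = \frac1k \sum_{p=1}^{k} (P_p(b) - P_p(a))^2$ averages squared
differences of $k$ standardized properties. Tier $j$ correlation:
$\tau_j = \frac{1}{L-j}\sum_{i=1}^{L-j} \Theta(R_i, R_{i+j})$, for
$j = 1..\lambda$. The emitted vector is
$x_u = f_u / (1 + w\sum_j \tau_j)$ for $u \le 20$ and
$x_{20+j} = w\tau_j / (1 + w\sum_j \tau_j)$ — non-negative, summing to one
because $\Theta \ge 0$. Defaults $\lambda = 30$, $w = 0.05$, properties =
the classic hydrophobicity / hydrophilicity / side-chain-mass triple;
these are the conventional choices in the PseAAC literature, and any
subset of a loaded property table may be substituted.

**Type II (amphiphilic) PseAAC** (`type2_pseaac`). Uses exactly two
properties, interleaving their lagged products
$\tau_{2j-1} = \frac{1}{L-j}\sum_i H^1_i H^1_{i+j}$,
$\tau_{2j} = \frac{1}{L-j}\sum_i H^2_i H^2_{i+j}$ (20 + 2$\lambda$
features). Because standardized products can be negative, the denominator
$1 + w\sum\tau$ can in principle reach zero; the package raises a
degenerate-normalization error reporting $\sum\tau$ rather than emitting
unbounded values.

**Autocorrelation families** (`moreau_broto`, `moran`, `geary`,
`autocorr_vector`). For a standardized property profile $P_i$ along the
sequence:

* normalized Moreau–Broto: $AC(d) = \frac{1}{L-d}\sum P_i P_{i+d}$;
* Moran: centred product ratio with variance denominator $\frac1L\sum(P_i-\bar P)^2$;
* Geary: $\frac{\frac{1}{2(L-d)}\sum (P_i - P_{i+d})^2}{\frac{1}{L-1}\sum (P_i - \bar P)^2}$.

Default `max_lag = 30`, the convention in the descriptor literature; one
feature per (property, lag) pair. Whether Moran's variance term should use
an $L$ or $L-d$ divisor is genuinely ambiguous across implementations; the
package fixes the forms above and tests them against brute-force loops, so
users comparing against other tools know exactly which dialect this is.

**CTD** (`ctd_vector`). Each of seven bundled attributes partitions the
alphabet into three classes; per attribute the descriptor concatenates
class percentages (3), class-crossing transition percentages (3), and the
scaled positions of the first/25%/50%/75%/last occurrence per class (15).
Values are on the percent scale, the dominant dialect in the CTD
literature (a `[0,1]` dialect also circulates — divide by 100 to convert).
The occurrence index for fraction $q$ is $\lceil q \, n_k \rceil$ with the
first occurrence at index 1; a class absent from a sequence emits five 0s
rather than NaN, keeping batch matrices finite.

**Quasi-sequence order** (`qso_vector`). Coupling number
$\tau_d = \sum_{i=1}^{L-d} d(R_i,R_{i+d})^2$ over an amino-acid distance
matrix; the vector normalizes frequencies and couplings together
(defaults $D = 30$, $w = 0.1$). Two matrices ship with the package and are
both applied by default, giving concatenated blocks of $20+D$ features
each. The `grantham` matrix is recomputed from the published
composition/polarity/volume indices and formula (mean pairwise distance
scaled to 100) and kept at full precision, so individual entries can
differ by one unit from the familiar rounded table. The second matrix is
**synthetic**: an RMS distance over the three standardized classic
properties, constructed in the style of physicochemical distance scales
whose per-pair values are not redistributable. Its role is structural
(two-block output, scaling laws); it is not a literature scale.

**Annotation modes** (`binary_vector`, modes `go` and `fdom`). Binary
presence vectors over a deterministic, lexicographically sorted term
universe. Proteins missing from the map yield all-zero rows *with a
warning* instead of being dropped, so descriptor rows stay aligned with
FASTA order. Annotations are supplied offline as TSV
(`accession<TAB>term1;term2;...`); the package performs no ontology-graph
propagation — a protein is annotated with exactly the terms given. A
versioned binary cache (magic `PSBEM1`) supports fast reload of large
universes.

**Sequential-evolution mode** (`psepssm`). From a PSI-BLAST ASCII PSSM,
rows are standardized over their 20 scores; the descriptor is the 20
column means followed by lag-$g$ squared-difference terms
$\theta_j^{(g)} = \frac{1}{L-g}\sum_i (E'_{i,j} - E'_{i+g,j})^2$ for
$g = 1..\xi$ (default $\xi = 10$). Row z-scoring is used rather than the
sigmoid squashing that some PsePSSM implementations apply; both dialects
exist, and the z-score form keeps this mode consistent with the
standardization used everywhere else in the package. PSSMs are
caller-supplied files — the package never runs PSI-BLAST, which keeps it
fully offline and testable.

## Numerical conventions

* **One canonical residue order.** Everything internal is indexed by the
  alphabetical order `ACDEFGHIKLMNPQRSTVWY`; AAindex flat files and
  PSI-BLAST PSSMs (both in `ARNDCQEGHILKMFPSTWYV` order) are re-mapped on
  load. A single order eliminates a whole class of off-by-one/permutation
  bugs.
* **Divisor-20 standardization.** Property vectors (and PSSM rows) are
  standardized with the population SD over the 20 values. Tools using a
  divisor of 19 will produce slightly different correlation factors; this
  is documented rather than configurable.
* **Strict length preconditions.** `L > λ`, `L > D`, `L > ξ` are enforced
  with errors naming both quantities; short sequences are rejected, never
  zero-padded, because padding silently biases every `τ`.
* **Ambiguous residues.** The default policy is a hard error: silently
  corrupted descriptors are worse than a stopped run. `skip_record` and
  `map_to_nearest` (B→D, Z→E, U→C, O→K, J→L; X unresolvable → skip) are
  explicit opt-ins, and every skip is warned and counted in the run
  report.
* **Degenerate inputs.** Zero-variance property profiles return 0 (with a
  warning) for Moran/Geary instead of NaN; constant properties are
  unusable for correlation modes and error at the point of use; constant
  PSSM rows standardize to zero rows with a warning.
* **Deterministic output.** Floats are written with 12 significant
  digits via a fixed format, so identical inputs give byte-identical
  files; svmlight output omits zero features and carries the accession as
  a trailing comment.

## The synthetic-data generator

`synth_proteins()` draws i.i.d. uniform residues with lengths uniform on
a range (default 50–300, a realistic span for globular protein chains);
`synth_property_table()`, `synth_annotation_map()` and `synth_pssm()`
provide placeholder side inputs, and `synth_fixtures()` bundles all of
them under one seed. These fixtures emulate the *structure* of real data
— alphabet, lengths, file dialects, universe sizes — not its statistics:
real proteins have biased composition, autocorrelated hydrophobicity and
non-uniform annotation depth. Tests built on these fixtures therefore
verify algebraic correctness (oracle equivalence, normalization
identities, invariances, determinism), not biological discrimination
power.

Test and verification problem sizes are deliberately modest — fuzzing at
100 cases per family with sequences up to a few hundred residues, one
streaming run of 10,000 records at chunk size 256 — chosen so the whole
suite exercises every contract while remaining quick to run routinely.

## Design choices that were genuinely open

* **Property bundle.** Only the classic three-property table is vendored;
  a 544-entry AAindex-derived table is loadable by the user
  (`load_property_table(..., "aaindex1")`) but its values are not asserted
  as ground truth, since the exact property set behind the canonical
  "544" count is tied to a specific AAindex release. Dimensionality
  checks use a synthetic 544-entry table.
* **Plugins instead of an embedded scripting language.** User-defined
  modes are R files returning a `mode_spec` (name, dimensionality
  function, compute function). This preserves maximal extensibility — a
  plugin is indistinguishable from a built-in at run time, and the
  registry verifies `dim(params)` against every emitted vector — without
  embedding an interpreter. Broken plugins fail loudly and leave the
  registry untouched.
* **Both QSO matrices by default.** Emitting both distance-matrix blocks
  is the richer default and matches common practice; a single matrix can
  be selected by passing `matrices` explicitly.
* **Streaming as a contract, not an optimization.** The FASTA reader is
  chunked (`fasta_apply`) and the batch engine writes rows as they are
  computed, so memory is bounded by the chunk size, independent of file
  size. The tests assert the chunk bound via the batch engine's chunk
  hook.

## Known limitations

* No nucleotide support, no reduced or gapped alphabets.
* No GO-graph ancestor propagation and no term-frequency weighting in the
  annotation modes; vectors reflect the supplied map verbatim.
* PsePSSM supports PSI-BLAST ASCII matrices only (no HMM profiles), and
  the sigmoid normalization dialect is not implemented.
* The synthetic distance matrix is a structural stand-in, not a
  literature scale; results that depend on absolute QSO values should use
  the Grantham block or a user-supplied matrix.

## A worked example

```{r example}
recs <- synth_proteins(seed = 1, n = 3, length_range = c(60L, 90L))
v <- type1_pseaac(recs[[1]], lambda = 5, w = 0.05)
round(v[c(1:3, 21:25)], 4)
sum(v)
```

The first 20 components are down-weighted residue frequencies; the last
`lambda` components are the weighted correlation tiers; the whole vector
sums to one by construction.
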