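# disprof

Sequence-based profiling of intrinsically disordered proteins (IDPs) in R.

Intrinsically disordered proteins and regions lack a single native 3D
structure, so their biochemistry must be read directly off the primary
structure. Two sequence properties separate disordered from ordered
proteins remarkably well: **net charge** (charge repulsion extends the
chain) and **hydropathy** (hydrophobic deficiency prevents collapse into
a core). `disprof` implements the classic charge/hydropathy family of
disorder indicators as tidy, pipe-friendly functions for anyone — from
bench biologists triaging a candidate protein to bioinformaticians
screening whole proteomes.

## What it computes

With `h` the **mean scaled hydropathy** (Kyte–Doolittle values rescaled
so Arg = 0.0 and Ile = 1.0, i.e. `(KD + 4.5)/9`) and `q` the **mean net
charge per residue** (Henderson–Hasselbalch fractional charges, acids
`-1/(1+10^(pKa-pH))`, bases `+1/(1+10^(pH-pKa))`, IPC_protein pKa set by
default, pH 7.0):

- **Charge–hydropathy (Uversky) classification** — the boundary
  `|q| = 2.785·h − 1.151` separates extended/disordered from
  collapsed/compact proteins; sequences with `h ≥ 0.7` are flagged
  insoluble.
- **FoldIndex** — the boundary applied per sliding window (51 residues
  by default): `score = 2.785·h_w − |q_w| − 1.151`; windows scoring
  below zero are predicted disordered, and maximal same-call runs are
  reported as regions.
- **Local charge and hydropathy profiles** — 9-residue sliding-window
  means at each center position.
- **Structural tendency** — residues classified as disorder-promoting
  (P, E, S, Q, K, A, G), order-promoting (M, N, V, H, L, F, Y, I, W, C)
  or disorder-neutral (D, T, R), plus compositional summaries and
  optional enrichment against a user-supplied reference.
- **Sequence maps** — per-residue values laid out on a row-major grid
  for whole-protein visualisation.
- **Substitution matrices** — a reader/validator for NCBI/EMBOSS-style
  matrix text (BLOSUM/PAM and the IDP-derived EDSSMat, Disorder and
  DUNMat families obtained from their original sources), plus scoring of
  aligned pairs with affine gap penalties.
- **Synthetic fixtures** — seeded generators for disorder-rich,
  order-rich, acidic, basic and uniform-composition sequences.

## Worked example

```r
library(disprof)

idr <- generate_fixture("disorder-rich", 300, seed = 42)
prof <- disorder_profile(idr)
glance(prof)
#> # A tibble: 1 × 8
#>   id     length mean_hydropathy mean_net_charge label mean_score frac_disordered
#>   <chr>   <int>           <dbl>           <dbl> <chr>      <dbl>           <dbl>
#> 1 disor…    300           0.339          0.0378 exte…     -0.260               1
#> # ℹ 1 more variable: frac_disorder_promoting <dbl>

prof$foldindex$regions
#> # A tibble: 1 × 4
#>   id                    start   end call
#>   <chr>                 <int> <int> <chr>
#> 1 disorder-rich_300_s42    26   275 disordered
```

The fixture's mean scaled hydropathy (0.339) and near-zero mean net
charge put it on the extended/disordered side of the `2.785h − 1.151`
boundary, every 51-residue FoldIndex window scores negative
(`frac_disordered = 1`), and the windows collapse into one disordered
region covering all reported positions (26–275; the first and last 25
positions have no full window). A hydrophobic, charge-balanced control
lands on the other side:

```r
charge_hydropathy(c(globular = strrep("LIVFAKDE", 10)))
#> # A tibble: 1 × 6
#>   id       length mean_hydropathy mean_net_charge label                ph
#>   <chr>     <int>           <dbl>           <dbl> <chr>             <dbl>
#> 1 globular     80           0.586          -0.126 collapsed/compact     7
```

`plot_charge_hydropathy()`, `plot_local_profile()`, `plot_tendency()`
and `autoplot()` on FoldIndex / composition / sequence-map objects give
the corresponding ggplot2 figures.

The same analyses are available from a shell via the installed
`disprof` script, e.g.

```sh
disprof run --fasta proteins.fasta --out results/
disprof fixture --kind acidic --length 200 --seed 7 --out fixtures/
```

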