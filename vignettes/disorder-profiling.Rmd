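---
title: "Charge, hydropathy and disorder: the methods behind disprof"
output: rmarkdown::html_vignette
vignette: >
  %\VignetteIndexEntry{Charge, hydropathy and disorder: the methods behind disprof}
  %\VignetteEngine{knitr::rmarkdown}
  %\VignetteEncoding{UTF-8}
---

```{r, include = FALSE}
knitr::opts_chunk$set(collapse = TRUE, comment = "#>")
library(disprof)
```

## The model

Intrinsically disordered proteins (IDPs) stay extended in solution
because they combine two sequence properties: a large net charge at
physiological pH (electrostatic repulsion stretches the chain) and a
deficiency of hydrophobic residues (no core to collapse around).
`disprof` quantifies both directly from the one-letter sequence and
combines them in the two classical ways — a whole-sequence
classification and a sliding-window profile.

### Fractional charge

Each ionizable group is assigned its Henderson–Hasselbalch fractional
charge at the working pH:

- acids (D, E, C, Y and the free C-terminus): $q = -1 / (1 + 10^{\,\mathrm{p}K_a - \mathrm{pH}})$
- bases (H, K, R and the free N-terminus): $q = +1 / (1 + 10^{\,\mathrm{pH} - \mathrm{p}K_a})$

Non-ionizable residues contribute exactly zero, and a group at
pH = p$K_a$ is exactly half-ionized ($\pm 0.5$). Histidine is treated as
an ordinary base with its set's p$K_a$ — no special casing — which at
pH 7 leaves it with a small partial positive charge. The default p$K_a$
set is IPC_protein, optimised against experimental protein isoelectric
points; EMBOSS's set is also built in, and any other set can be loaded
from a two-column text file. Whole-sequence net charge includes the two
terminal groups by default (`include_termini = TRUE`); sliding windows
never include them, because the interior of a chain has no free
termini. The *mean* net charge divides by the number of residues; the
termini are extra ionizable groups, not extra residues.

### Scaled hydropathy

Kyte–Doolittle hydropathy values (raw range $-4.5$ for Arg to $+4.5$
for Ile) are rescaled linearly onto $[0, 1]$:
$h = (\mathrm{KD} + 4.5) / 9$, so Arg is exactly 0 and Ile exactly 1.
The two anchor points force the scaling; nothing else is tuned.
Alternative scales can be supplied as files with the same schema, but
only the scaled Kyte–Doolittle table ships.

### Whole-sequence classification

In the (mean scaled hydropathy $\langle h \rangle$, mean net charge per
residue $\langle q \rangle$) plane, the boundary

$$ |\langle q \rangle| = 2.785\,\langle h \rangle - 1.151 $$

separates extended/disordered ($|\langle q \rangle|$ above the line)
from collapsed/compact proteins. Sequences with
$\langle h \rangle \ge 0.7$ are labelled insoluble regardless of
charge; this override is applied *before* the boundary rule. Two
boundary conventions had to be fixed: a point exactly *on* the cutoff
line is called collapsed (extension requires a strict inequality), and
$\langle h \rangle$ exactly 0.7 is insoluble. Both are measure-zero
choices made for determinism.

### FoldIndex

The same boundary, folded into a signed per-window score:

$$ s_w = 2.785\,\langle h \rangle_w - |\langle q \rangle_w| - 1.151 $$

over an odd sliding window (default 51 residues), reported at the
window's center. Negative scores predict disorder, positive scores
order; an exact zero is called ordered, again a deterministic
convention on a measure-zero boundary. The score is bounded by
$[-1.151, 1.634]$: the minimum at $h_w = 0$ with no charge, the maximum
for a fully hydrophobic, uncharged window such as poly-Ile
($2.785 - 1.151 = 1.634$, an exact anchor used in the tests).

Windows shorter than the requested width are never padded or shrunk:
positions within $(w-1)/2$ of either end simply carry no value, so every
reported number is a true full-window mean. A sequence *shorter* than
the window is scored once as a single whole-sequence window at its
central position and flagged `whole_sequence = TRUE`, so short peptides
still get a (coarse) call rather than an error. Maximal runs of
identical calls over the reported positions are returned as regions
with 1-based inclusive coordinates; edge positions without a window
belong to no region.

### Structural tendency and composition

Residues are partitioned into disorder-promoting (P, E, S, Q, K, A, G),
order-promoting (M, N, V, H, L, F, Y, I, W, C) and disorder-neutral
(D, T, R) classes, the classic partition derived from compositional
enrichment of disordered versus ordered proteins. Any user scheme is
accepted provided it covers the 20 standard residues exactly once —
the disjoint-cover invariant is validated, so a residue can never be
counted in two classes. Compositional enrichment,
$(f_i - r_i)/r_i$ for residue $i$, requires an explicit reference
composition $r$: none is shipped as authoritative because no defensible
default exists — different reference databases give materially
different enrichments — so the reference is a user input, with
`"uniform"` (1/20 each) available as an explicit, clearly labelled
baseline.

## Parameters that matter

| Parameter | Default | Units | Why |
|---|---|---|---|
| `ph` | 7.0 | pH | physiological conditions; all charges move with it |
| `pka` | IPC_protein | p$K_a$ | protein-optimised set; swappable per run |
| `window` (profiles) | 9 | residues | local chemistry at ~2 turns of chain; any odd width ≤ length is accepted as a per-run choice |
| `window` (FoldIndex) | 51 | residues | the scale at which disorder is defined (IDRs ≈ 30+ residues); odd |
| `include_termini` | TRUE | — | whole-sequence net charge counts the real free ends |
| `unknown` | "strict" | — | see below |

Window widths must be odd so the value sits at a real center residue.
Even widths are rejected rather than rounded — silently changing a
window is worse than an error.

## Handling non-standard residues

Real FASTA records contain B, Z, X, and occasionally U, O or J. The
default policy is strict rejection with the character and position
named, because an X silently treated as (say) alanine biases every mean
the classification depends on. The alternative `"mask"` policy replaces
ambiguity codes with a sentinel `X`, warns, and then *excludes* masked
positions from every average: a window's mean is taken over its known
residues only (NA if none). This keeps each reported value a true mean
of known residues at the cost of slightly unequal effective window
sizes near masked positions.

## The synthetic-sequence generator

`generate_fixture()` draws i.i.d. residues from class-biased
compositions: 80% of sampling mass on the target tendency set for
`disorder-rich` / `order-rich`; 60% on D/E (excluding K, R, H) for
`acidic` and 60% on K/R (excluding D, E) for `basic`, so the sign of
the net charge is guaranteed by construction; `mixed` is uniform. The
same `(kind, length, seed)` always yields the same sequence and the
global RNG state is untouched.

These fixtures emulate *composition*, which is exactly what every
statistic in this package consumes — charge, hydropathy and tendency
are all position-wise functions of residue identity, and window means
are permutation-local. They do **not** emulate the positional
autocorrelation of real proteins (charge blocks, repeats, motifs,
domain boundaries), so passing tests demonstrate correctness of the
computations and the direction of compositional effects, not predictive
accuracy on real proteomes.

## Numerical choices

- Window means are computed from cumulative sums ($O(n)$ per profile);
  agreement with a brute-force loop over every window is asserted to
  $10^{-10}$ in the tests, the residual being ordinary floating-point
  reassociation.
- Output values are never rounded inside the package; rounding is left
  to display and export layers, so downstream comparisons can use full
  precision.
- Ties (score exactly 0; a point exactly on the cutoff line; $h$ exactly
  0.7) are resolved as documented above — toward "ordered", "collapsed"
  and "insoluble" respectively — and are all stated in the function
  documentation.
- Degenerate inputs: empty sequences are rejected at parse time; a
  window larger than the sequence is an error for the local profiles
  (use the whole-sequence mean instead) but a documented fallback for
  FoldIndex.

## Problem sizes used in the checks

The test suite and `scripts/acceptance.R` exercise: a grid sweep of
10,201 points for the classification rule; 200 random fixtures (lengths
9–500, odd windows 3–51) against brute-force window oracles; 50 seeded
pairs of 500-residue disorder-rich vs order-rich fixtures for the
directional contrast; and 20 acidic 200-residue fixtures for the charge
sign. These sizes make the full suite run in well under a minute while
leaving the directional comparisons far from marginal.

## Known limitations

- Charge–hydropathy and FoldIndex see composition through two scalar
  summaries; they miss disorder encoded in charge *patterning* (e.g.
  blocky versus interspersed charges) and context-dependent folding.
- The Henderson–Hasselbalch model assigns each group an independent,
  fixed p$K_a$; real proteins shift p$K_a$s with local environment.
- Post-translational modifications (notably phosphorylation) are out of
  scope; modified residues cannot be represented in the 20-letter
  alphabet.
- The substitution-matrix module reads, validates and scores with
  matrices; it deliberately does not implement alignment search —
  matrices are meant to be handed to a dedicated aligner. The numeric
  tables of the IDP-derived matrix families are not embedded; users
  load them from their original distribution files, which the parser
  accepts directly.
- The one remote facility, `fetch_uniprot()`, retrieves only the
  sequence and is off unless `network = TRUE`; nothing else in the
  package touches the network.
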