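---
title: "Methods: deriving and assessing a DFIRE protein–ligand potential"
output: rmarkdown::html_vignette
vignette: >
  %\VignetteIndexEntry{Methods: deriving and assessing a DFIRE protein–ligand potential}
  %\VignetteEngine{knitr::rmarkdown}
  %\VignetteEncoding{UTF-8}
---

```{r setup, include = FALSE}
knitr::opts_chunk$set(collapse = TRUE, comment = "#>")
library(dfirescore)
```

## The model

`dfirescore` builds a distance-dependent statistical potential for
protein–ligand interactions. For protein atom type $i$, ligand atom
type $k$ and distance shell $r$,

$$
\bar u(i,k,r) =
\begin{cases}
-\eta RT \,\ln \dfrac{N'_{\mathrm{obs}}(i,k,r)}
 {\left(\frac{r}{r_{\mathrm{cut}}}\right)^{\alpha}
  \frac{\Delta r}{\Delta r_{\mathrm{cut}}}\,
  N'_{\mathrm{obs}}(i,k,r_{\mathrm{cut}})}, & r < r_{\mathrm{cut}}\\[4pt]
0, & r \ge r_{\mathrm{cut}}.
\end{cases}
$$

The denominator is the *distance-scaled, finite, ideal-gas reference
state* (DFIRE): the pair count expected if atoms did not interact. In
an infinite ideal gas that count grows as $r^2$; in finite, compact
molecules the effective exponent is smaller, and $\alpha = 1.61$ is the
established DFIRE value. The underlying assumptions are the usual ones
for statistical potentials: pair decomposability of the interaction
free energy, a Boltzmann-like relation between observed pair
frequencies and energies, and transferability of statistics harvested
from folded proteins to protein–ligand interfaces.

The distinctive step is that the statistics come from **protein monomer
chains only**. Protein atoms carry 167 residue-specific types (each
heavy atom of the 20 standard amino acids, identified jointly by
residue and PDB v3 atom name); ligand atoms carry 11 canonical SYBYL
mol2 types. A surjective map $map(j)$ from the 167 protein types onto
the 11 mol2 types lets protein–protein pair counts stand in for
protein–ligand counts:

$$
N'_{\mathrm{obs}}(i,k,r) = \sum_j N_{\mathrm{obs}}(i,j,r)\,
\delta(map(j), k).
$$

Each protein atom thus keeps its full residue context on the $i$ side
while acting as a proxy for a ligand chemotype on the $k$ side.

## Parameters

| parameter | default | units | role |
|---|---|---|---|
| $\alpha$ | 1.61 | — | reference-state distance exponent |
| $r_{\mathrm{cut}}$ | 15 | Å | interaction cutoff; energies are identically 0 beyond it |
| $\Delta r$ | 0.5 | Å | shell width (30 shells; all equal, so $\Delta r/\Delta r_{\mathrm{cut}} = 1$) |
| $\eta RT$ | 0.01 | — | overall scale; with $\eta = 0.01/RT$ at $T = 300$ K the energies are dimensionless scores, so the product is exposed directly as `eta_rt` |
| $\sigma$ | 0.5 | counts | additive pseudo-count on observed and reference counts |

`dfire_params()` carries all of these; `binning_scheme()` owns the
shells, which are half-open $[b\Delta r, (b+1)\Delta r)$ with the
midpoint as the representative distance.

## Numerical choices

**Bin representative and the cutoff boundary.** The ratio
$(r/r_{\mathrm{cut}})^\alpha$ is evaluated at shell midpoints, with
$r_{\mathrm{cut}}$ represented by the last midpoint (14.75 Å). This
makes the derived energy *exactly* zero in the cutoff shell — the ratio
there is $N'/N'$ — so the boundary condition of the defining equation
holds bit-for-bit rather than approximately, and the scoring contract
("0 at and beyond $r_{\mathrm{cut}}$") is testable as an identity.

**Low-count smoothing.** Cells of the $167 \times 11 \times 30$ count
tensor can be sparse. We apply a symmetric additive pseudo-count:
$\ln[(N' + \sigma)/(\mathrm{ref} + \sigma)]$. This (a) is finite for
every input, (b) vanishes as counts grow, and (c) sends pairs with no
observations at all to zero energy via $\ln(\sigma/\sigma)$ — a neutral
prior. With $\sigma = 0$ the uncorrected log-odds is recovered exactly
when all needed counts are positive; a zero count against a positive
partner is then an error naming the offending cell, never a silent
infinity. The exact Bayesian correction used historically for such
potentials is not fully specified in the accessible literature;
$\sigma$-smoothing is our declared, parameterised choice and is exposed
on the CLI.

**Pair-counting conventions.** Counting is per chain; intra-residue
pairs are excluded and all inter-residue pairs are included
(`min_res_sep = 1`), with the sequence-separation threshold exposed
because conventions differ across the statistical-potential
literature. Each unordered pair increments both $(i,j,b)$ and
$(j,i,b)$; this symmetric double storage is what makes the one-sided
collapse $\sum_j$ well defined for every protein index $i$. The
distance kernel is a vectorized all-pairs evaluation; the test suite
holds it to exact integer agreement with an explicit double loop.

**Structure input policies.** PDB parsing (via bio3d) keeps model 1
only, heavy atoms only, `ATOM` records plus `MSE` (typed as MET with
SE→SD); alternate locations resolve per atom by highest occupancy,
ties preferring altloc `A`, then file order. These policies are
declared rather than inferred — the training literature rarely states
them — and are centralised in `read_pdb_chain()`. Terminal `OXT` is
typed as the backbone `O` of its residue. Multi-pose mol2 files are
read one pose per `MOLECULE` block, in file order.

## The type map

The exact published assignment of the 167 protein types to mol2 types
is not available to us, so the package ships a chemically reasoned
default as an editable, versioned text file
(`inst/extdata/type_map.txt`): backbone `N/CA/C/O` →
`N.am/C.3/C.2/O.2`; carboxylates to `O.co2`, hydroxyls to `O.3`,
thioether/thiol sulfur to `S.3`, aromatic ring atoms to `C.ar`/`N.ar`,
guanidinium nitrogens to `N.2`, lysine `NZ` to `N.3`, amide side chains
to `N.am`/`O.2`, and so on. The handful of anchor assignments that are
fixed by the method's own description (e.g. `GLU.CB` and `LYS.CE` both
collapsing to `C.3`; backbone O to `O.2`) are honoured and tested.
Ligand SYBYL types outside the canonical 11 resolve through fallbacks
in the same file: phosphorus is scored as the sulfur bucket (`P.3` →
`S.3`), halogens by size (`F` → `O.3`; `Cl/Br/I` → `S.3`), off-list
carbon and nitrogen hybridisations to their nearest canonical state,
and common metal cations to the small-cation bucket (`N.3`). Hydrogens,
dummies and lone pairs are ignored. Everything else is *untypeable*:
typing never crashes, it signals, and callers decide whether to skip or
abort. Receptor cofactors and foreign `HETATM` residues are excluded
entirely rather than being silently typed as protein.

The loader validates totality (all 167 covered exactly once), the
image (exactly the 11 canonical types) and fallback targets; the
canonical serialization is hashed, and potential files carry the hash
so a table derived under one map cannot be silently scored under
another.

## Scoring and assessment protocols

A complex score is the plain sum of $\bar u$ over receptor–ligand heavy
atom pairs within the cutoff. The sign convention is: `energy` (lower
is better) is stored, and `score = -energy` is presented to
correlation and ranking code, since scores should correlate positively
with measured affinity. Best-of-$n$ pose rescoring takes the
minimum-energy pose, ties to the earliest pose.

* **Scoring power** — Pearson correlation between score and
  experimental affinity, and the RMSE of residuals after the OLS fit
  `affinity ~ score` (intercept included).
* **Docking power** — a complex succeeds at top-$n$ if any of its $n$
  best-scored poses has RMSD $< 2.0$ Å (strict) to the native pose.
  RMSD is computed over corresponding heavy atoms without
  superposition (poses share the receptor frame) and without symmetry
  correction — a documented limitation for symmetric ligands.
* **Ranking power** — per ligand cluster: high-level success requires
  the predicted order to equal the experimental order exactly;
  low-level success only that the best binder is ranked first.
  Clusters with tied experimental affinities are skipped with a
  warning.
* **Screening power** — enrichment factor
  $EF^{x\%} = (N_{\mathrm{true}}/N_{\mathrm{sel}}) /
  (N_{\mathrm{active}}/N_{\mathrm{total}})$ with
  $N_{\mathrm{sel}} = \lceil x\% \cdot N_{\mathrm{total}}\rceil$
  (ceiling chosen for determinism; the convention is not standardised);
  rank-based ROC AUC with ties counting one half; and logAUC, the area
  under the ROC against $\log_{10}$ FPR on $[\lambda, 1]$ with
  $\lambda = 0.001$, normalised by $\log_{10}(1/\lambda)$ and reported
  in percent. We report the raw normalised area (no subtraction of the
  random baseline), under which random scores give
  $100(1-\lambda)/\ln(1/\lambda) \approx 14.5\%$. The piecewise-linear
  ROC is integrated segment-exactly on the log axis (each trapezoid
  contributes $a\ln(f_2/f_1) + b(f_2 - f_1)$, up to the $\ln 10$
  normalisation) rather than by trapezoids on log-transformed vertices;
  for the same ROC polyline this is exact, and it reproduces the
  analytic random value to Monte-Carlo accuracy.

Score ties everywhere are broken by input order after a stable sort, so
every metric is a deterministic function of its input table.

## The synthetic-data generator

The generator exists so that every stage — file I/O, typing, counting,
derivation, scoring, metrics — can be exercised end to end with
controlled statistics and no external data. It emulates:

* residue composition and per-residue heavy-atom complements (exactly
  typeable by construction), on a 3.8 Å C$\alpha$ random walk with
  side-chain atoms within 2.5 Å of C$\alpha$ — realistic *pair-distance
  scales*, deliberately not realistic stereochemistry;
* ligands as box-uniform atoms over the 11 canonical SYBYL types;
* docking pose sets as rigid shifts plus Gaussian coordinate noise
  around a native pose;
* screening sets as the two-normal model (actives
  $\mathcal N(\mathrm{effect}, 1)$, decoys $\mathcal N(0,1)$, 50
  decoys per active by default, matching common benchmark ratios),
  whose ROC AUC has the closed form $\Phi(\mathrm{effect}/\sqrt 2)$;
* count tables as multinomial draws from the distribution a known
  bounded potential implies, $p(b) \propto (r_b/r_{30})^{\alpha}
  e^{-u(b)/\eta RT}$.

What it does **not** emulate: bonded geometry, sterics and excluded
volume, real rotamer and secondary-structure statistics, realistic
decoy property matching, or the composition biases of curated training
sets. Passing tests therefore demonstrate *algorithmic correctness and
statistical calibration*, not benchmark performance on experimental
structures; potentials trained on fixtures are not production
potentials.

For the potential-recovery check we sample $10^6$ pairs from a bounded
attractive two-well profile (a contact wall plus a shallow outer well,
range about $7\,\eta RT$, zero at the cutoff bin). An attractive
profile is used deliberately: it keeps even the smallest inner shells —
whose reference volume shrinks as $r^{1.61}$ — populated with enough
counts that the derivation's sampling error stays within the 5%-of-range
recovery bound the check asserts; a strongly repulsive profile at short
range would starve those shells and test nothing but shot noise.

## Problem sizes

The test suite and the acceptance script run on deliberately small
instances: training sets of 10–20 chains of 30–60 residues, complexes
of ≤ 50 receptor atoms with ≤ 10 ligand atoms for oracle comparisons
(100 seeded cases), $10^6$ multinomial samples for recovery, and
screening sets of $10^3$–$10^4$ ligands for metric nulls. These sizes
give the statistical checks comfortable Monte-Carlo margins while
keeping the whole suite in the tens of seconds; the algorithms are the
same at any scale, and counting cost grows with the square of atoms
per chain.

## Known limitations

* The shipped 167→11 map is chemically reasoned, not fitted; users can
  supply their own file, and the map hash guards consistency.
* Pairwise, distance-only energies: no solvation, entropy, torsional or
  polarisation terms; scores are relative, not absolute free energies.
* Piecewise-constant distance dependence (0.5 Å steps), no
  interpolation between shells.
* RMSD has no graph-automorphism correction; symmetric ligands can be
  penalised.
* Metal ions and cofactors on the receptor side are excluded rather
  than modelled.
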