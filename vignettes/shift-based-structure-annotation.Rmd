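---
title: "Methods: eleven-class secondary structure annotation from backbone chemical shifts"
output: rmarkdown::html_vignette
vignette: >
  %\VignetteIndexEntry{Methods: eleven-class secondary structure annotation from backbone chemical shifts}
  %\VignetteEngine{knitr::rmarkdown}
  %\VignetteEncoding{UTF-8}
---

```{r setup, include = FALSE}
knitr::opts_chunk$set(collapse = TRUE, comment = "#>")
library(nmrsecstr)
```

## The problem and the model

Assigned backbone chemical shifts (H, HA, CA, CB, C, N) carry enough
structural information to place secondary structure elements along a protein
chain without NOEs or coordinates. `nmrsecstr` turns a shift file (NMR-STAR
2.1, NMR-STAR 3.1 or SHIFTY) plus an optional backbone torsion table
(TALOS-N prediction-table dialect) into an eleven-class annotation: helix,
β-strand, coil, β-turn types I, II, I′, II′ and VIII, β-hairpins, and edge
versus interior β-strands.

The pipeline runs in a fixed order, each stage consuming only the contracts
of the previous ones:

1. **Secondary shifts.** Δδ(i, a) = observed(i, a) − randomcoil(aa(i), a).
   Glycine's HA uses the mean of HA2/HA3. The random-coil table ships as a
   TSV and is replaceable.
2. **Ternary CSI filter.** Per nucleus (HA, CA, CB, C), index = +1 if
   Δδ strictly exceeds the nucleus cutoff, −1 if it falls strictly below
   −cutoff, else 0. Defaults: HA 0.1, CA 0.7, CB 0.7, C 0.5 ppm. Exactly at
   the cutoff means "not significant", hence 0. ^15N is parsed but not
   used by the filter.
3. **Consensus and 3-state assignment.** Nucleus indices are harmonized to a
   common convention (downfield HA/CB = strand evidence, downfield CA/C =
   helix evidence) and the majority of non-zero votes decides; ties give 0.
   Maximal helix runs of ≥ 4 become H, strand runs of ≥ 3 become B
   (β-bridges of ≤ 2 residues are coil), everything else C.
4. **Order parameter S².** A random-coil-index style estimator (below).
   Coil residues with S² ≤ 0.7 are excluded from turn typing; the gate is
   strictly `> 0.7`.
5. **Turn typing.** Every window i..i+3 whose central pair is coil, gated,
   and covered by the torsion table is compared with the canonical central
   torsions of the five turn types. A type matches when at least 3 of the 4
   circular deviations are ≤ 30° and the remaining one ≤ 45° (inclusive).
   Overlapping matches are resolved greedily by ascending (total deviation,
   start index); two turns overlap when their central pairs share a residue.
6. **fASA and hairpins.** A logistic accessibility estimator scores each
   residue; a hairpin is reported when two sequential strands are joined by
   a loop of ≤ 6 residues containing a selected turn (any of the five types
   by default; a strict I′/II′ mode is configurable).
7. **Edge/interior strands.** Seven one-point criteria per strand:
   alternating HA secondary-shift signs; mean strand fASA > 0.3; strict
   majority (> 0.50) of exposed residues (fASA > 0.25); rigid fraction
   (S² > 0.90) < 0.40; hydropathy periodicity; charged-residue pattern
   (proportion ≥ 0.25 of D/E/K/R/H, or a charged residue in the central
   third); length < 5. A score exceeding 4 — that is, ≥ 5 of 7 — calls an
   edge strand.

The first stage deliberately implements the classic ternary-filter CSI
rather than a trained model: the downstream phases depend only on the
per-residue H/B/C contract, so a stronger 3-state assigner can be swapped in
without touching anything else.

## Estimator details and defaults

**S² (order parameter).** Per residue, the weighted mean of |Δδ|/normalizer
over available nuclei (weights 1; normalizers twice the CSI cutoffs: HA 0.2,
CA 1.4, CB 1.4, C 1.0 ppm) is smoothed with a centered moving average of
width 3 and mapped by

s² = clamp(1 − k / max(m, floor), 0, 1),  k = 0.08, floor = 0.02.

The map is monotone (more shift displacement ⇒ more order), pins
near-random-coil residues to ≈ 0 and strongly shifted residues to ≈ 0.9+.
Residues with no usable nuclei get undefined S², which conservatively fails
every "greater-than" gate and passes every "less-than" gate. The published
RCI coefficient set is not reproduced here; only the threshold semantics
(0.7, 0.90) that downstream logic consumes are contractual, and external S²
values can be supplied per residue via a TSV to bypass the estimator.

**fASA.** fasa = logistic(0.5 + 2.0·(1 − s²) − 1.5·h − 2.0·d), where h is
the Kyte–Doolittle index scaled by 1/4.5 and d the same smoothed normalized
shift magnitude used for S². Signs encode the intended ordering: exposed
residues are flexible, hydrophilic and near random coil. The coefficients
were fixed once, before any acceptance measurement, to place a rigid
hydrophobic strand core below the 0.25 exposure cutoff and a flexible
glycine above 0.5; like S², fASA can be supplied externally.

**Canonical turn angles.** Type I (−60, −30, −90, 0), II (−60, 120, 80, 0),
I′ (60, 30, 90, 0), II′ (60, −120, −80, 0), VIII (−60, −30, −120, 120);
shipped as a TSV because the rule (30°/45°) and the constants are
independently replaceable. Negating all four angles maps I ↔ I′ and
II ↔ II′ exactly, which the tests exploit as an invariance check. When all
four deviations are within 30° the relaxed 45° allowance is simply unused.

**Tie-breaks.** Among turn types matching the same window, smallest total
deviation wins, with canonical table order (I, II, I′, II′, VIII) breaking
exact ties. Greedy turn selection orders by (total deviation, start), which
makes the output byte-deterministic. The optional positional-propensity
tie-break between co-matching types is off by default because no weighting
scheme is published.

## What the synthetic generator emulates

`generate_protein()` forward-models a declared topology: per-state mean
secondary shifts at twice the CSI cutoffs (helix: CA/C downfield, HA/CB
upfield; strand: the opposite), so that at zero noise the filter inverts
them exactly; edge strands emit at 1.5× the cutoffs with alternating HA
signs, alternating K/V sequences and a charged central residue, which lowers
their apparent rigidity below the 0.90 gate while staying above the 0.7 turn
gate; interior strands are uniformly hydrophobic (poly-V, length ≥ 5);
ordered coil emits sub-threshold magnitudes (0.7× cutoff, alternating sign)
so genuine turn regions stay rigid enough to be typed; disordered segments
emit near-zero shifts and are labelled `None` in the torsion table. Default
noise is Gaussian per nucleus (HA/H 0.02, CA/CB/C/N 0.10 ppm; torsions 5°),
a plausible assignment-uncertainty scale.

Ground-truth hairpins are derived from the truth layout by the hairpin
definition itself (consecutive strands, loop ≤ 6, a declared turn's central
pair inside the loop) — not by running the pipeline. Hairpin loops are
restricted to 2..6 residues because a 1-residue loop cannot contain a turn's
central pair and would be undetectable by the rule as published.

A green closed-loop test therefore establishes that the implementation
inverts its own stated emission model exactly — it does not establish
accuracy on real proteins, which depends on the upstream 3-state assigner,
real torsion predictions and genuine random-coil references. The generator
produces idealized block topologies; it does not model neighbor-dependent
random-coil corrections, chemical-shift referencing errors, β-bulges, or
sheet pairings beyond the hairpin rule.

Two deliberate consequences of the estimator design show up in testing.
First, the width-3 smoothing of S² bleeds one residue of order across a
boundary between a disordered segment and a strand, so the
disordered-recovery check uses disordered linkers embedded in coil (their
typical context); directly abutting a strand, the single boundary residue
can rise above 0.7. Second, recovery under noise decays toward the trivial
baseline of each class, and for rare classes (turn types) that baseline lies
above the deepest dip; the monotone-degradation check therefore spans the
signal-degradation regime (noise scales 0–10×), with the approach to
baseline asserted separately at an extreme scale (100×), allowing a fixed
0.02 Monte-Carlo jitter on 50 replicates.

## Degenerate inputs and edge behavior

Duplicate (residue, atom) shifts, HA2/HA3 on non-glycine, or a glycine
carrying both HA and HA2/HA3 are parse errors, not warnings. Unknown atom
names are dropped with a warning and counted, so records are never silently
lost. Author residue numbering is remapped to contiguous 1..N (mapping
retained); only the first entity of a multi-entity STAR file is read, with a
warning. Torsion rows with class `None` or 9999-style sentinels are
dropped; angles wrap to [−180, 180). Proline has no amide H and glycine no
CB, so completeness excludes those cells from the expected set. Shift
re-referencing is out of scope: inputs are assumed correctly referenced.

## Known limitations

* The 3-state stage is the classic CSI consensus, not a trained model;
  its real-data accuracy is below modern assigners, which bounds everything
  downstream.
* S² and fASA are monotone surrogates, not the published RCI /
  side-chain-RCI parameterizations; use the TSV override to supply real
  values when available.
* Torsions come from an external table; without one, turns and hairpins
  cannot be typed (the pipeline says so and continues).
* All strands get an edge/interior call, including isolated strands with no
  inferable sheet partner.
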