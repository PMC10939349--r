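---
title: "Methods: selecting, partitioning, and annotating gut-specific archaeal protein clusters"
author: "archannot"
output: rmarkdown::html_vignette
vignette: >
  %\VignetteIndexEntry{Methods: selecting, partitioning, and annotating gut-specific archaeal protein clusters}
  %\VignetteEngine{knitr::rmarkdown}
  %\VignetteEncoding{UTF-8}
---

```{r setup, include = FALSE}
knitr::opts_chunk$set(collapse = TRUE, comment = "#>")
library(archannot)
```

## Scope and model

`archannot` operationalizes a workflow for characterizing proteins of
gut-associated archaea (in practice dominated by *Methanobrevibacter
smithii*) from MAG-derived protein catalogs. The pipeline consumes
pre-computed artifacts — MAG metadata with sampling environments,
level-1 protein clusters (greedy sequence clustering at ~90%
identity/coverage), level-2 superclusters (MinHash sketch grouping), KO
tables, and parsed structure-evidence records — and never re-runs the
upstream tools (gene prediction, clustering, structure prediction,
read mapping are out of scope). Three ideas carry the analysis:

1. **Environment exclusivity.** A protein cluster is gut-specific iff
   every member protein is encoded by a MAG sampled in the human gut. A
   single member from any other environment excludes the cluster. This
   is deliberately strict: it trades recall for a clean claim about
   habitat specificity.
2. **KO-sharing partition.** With KEGG orthologs as the sole homology
   currency, an archaeal supercluster is *homologous* (`h*`) when its KO
   set intersects the bacterial KO universe, *unique* (`u*`) otherwise.
   KO identity, not sequence similarity, defines sharing — consistent
   with using orthology identifiers as a cross-domain common language.
3. **Confidence-tier reconciliation.** Sequence- and structure-based
   annotations disagree often; the ladder resolves conflicts by explicit,
   printed thresholds rather than judgment calls, so results are
   reproducible and auditable.

## Tier bands and the reconciliation ladder

Structure-match E-values and template TM-scores are banded into
equivalent confidence tiers (rank 4 down to 0):

| rank | structure-match likelihood | E-value | template significance | TM-score |
|---|---|---|---|---|
| 4 | certain   | < 1e-6 | very high | > 0.7 |
| 3 | probable  | < 0.01 | high      | > 0.5 |
| 2 | possible  | < 0.1  | medium    | > 0.4 |
| 1 | long shot | < 10   | low       | > 0.3 |
| 0 | none      | ≥ 10   | none      | ≤ 0.3 |

All comparisons are strict, exactly as the thresholds are written; a
value sitting on a boundary falls to the weaker tier (`classify_pf_likelihood(1e-6)`
is `probable`, `classify_tr_significance(0.7)` is `high`). Template hits
enter the ladder only when admissible: confidence > 0.6, E-value
< 0.001, coverage > 0.3, again all strict.

`reconcile()` then applies, in order:

1. *Best candidates.* Structure matches from both report sections
   (sequence-vs-PDB and 3D functional templates) form one pool ordered
   by E-value, 3D templates preferred at ties. The best template hit is
   the admissible hit with the highest TM-score (ties: coverage,
   identity, template id). Structure matches may assign a function only
   at tier *certain*.
2. *Consensus.* Same label (case-insensitive) from both sides → source
   `consensus`, tier = the higher rank.
3. *Conflict.* A structure match below *certain* cannot assign, so the
   template wins; a report with no 3D functional hits also yields to the
   template, even against a certain sequence-vs-PDB match — we read this
   rule as an override, taking precedence over rank comparison, because
   the 3D-functional-hit requirement is about the kind of evidence, not
   its strength. Otherwise the higher rank wins; at equal rank the
   higher coverage (template coverage vs fitted-segment ratio), then the
   higher identity, then the template (a fixed last tie-break so equal
   evidence cannot depend on input order).
4. *Single source.* A lone admissible template assigns at its tier; a
   lone structure match assigns only at *certain*.
5. *Support and agreement.* Term predictions with score > 0.7 whose name
   shares a word token (≥ 4 characters, case-insensitive) with the final
   label set `df_supported`; they never set the label — the tool is
   auxiliary by design. The same token rule classifies agreement between
   the structure call and the sequence KO label (`consistent`,
   `disparate`, `structure_only`, `sequence_only`, `unannotated`).
   Token overlap, rather than exact equality, is the default because the
   three vocabularies word the same function differently; an exact mode
   is available (`agreement_match = "exact"`).

Two independent checks guard this logic in the test suite: an
exhaustively enumerated descriptor grid (576 tier/label/kind/tie
combinations) compared against a separate table-driven rule interpreter,
and boundary probes at ±1e-12 around every threshold.

## Metrics

- **Relative occurrence** is `n_select / n_total × 1e6` — a per-million
  scaling chosen purely for readable plots.
- **Diagnostic ratios** are implemented exactly as their formulas are
  printed: `sensitivity = N_str / (N_str + N_seq)`, `specificity =
  N_seq / (N_seq + N_str)`, `PLR = sensitivity / (1 − specificity)`,
  `NLR = (1 − sensitivity) / specificity`. Because specificity is the
  complement of sensitivity under these definitions, PLR and NLR are
  identically 1 whenever both counts are positive. We implement the
  formulas as printed and flag the degeneracy in the result object
  (`degenerate = TRUE`; 0/0 ratios are `NA` plus a flag) rather than
  silently substituting a different contingency design.
- **Agreement percentages** use half-away-from-zero rounding to integer
  percent (`percent_share()`); e.g. 13/28 → 46, 1/28 → 4. Note that
  11/45 = 24.44% rounds to 24 under this (or any nearest-value) rule.
- **Expression aggregation** averages member genes within each sample
  first, then averages across samples (member-then-sample order; the
  alternative order changes results only for unbalanced coverage and is
  not exposed). Genes absent from the coverage table are missing, never
  zero — zeros would silently deflate cluster means. "Relatively high"
  expression has no printed definition; the default flags clusters at or
  above the 75th percentile of cluster overall means (type-7 quantile),
  configurable via `high_expr_percentile`.

## Synteny windows

`extract_flank_window()` spans 10 kb up- and downstream of the target
gene's boundaries (not midpoints), truncated at coordinate 1 and never
crossing contigs. Membership is ≥ 1 bp overlap with the window — a
partially overlapping neighbor is visible in a synteny plot — with a
containment mode available. HGT-context flags require the motif KO
strictly on the stated side of the target (recombinase K06400 upstream,
pilus assembly K02662/K02664 downstream), measured in contig coordinates
by default; `strand_relative = TRUE` orients sides by the target strand.

## The synthetic generator

`generate_dataset()` emulates the *structure* of real MAG-catalog
inputs, not their content: multi-environment MAG provenance with a
gut-dominated mixture (default 70% gut, 15% soil, 15% marine),
cross-domain KO overlap controlled by `shared_ko_fraction` (default
0.4), archaeal clusters of 1–8 members against the ≥ 2 gate and
bacterial clusters of 8–16 members against the ≥ 10 gate, a 10%
annotation-incompleteness rate to exercise the completeness gate,
evidence confidence values spanning every tier, and flank-gene motifs
planted at exact signed distances inside and outside the 10-kb window.
Default sizes (24 + 30 MAGs, 40 + 25 clusters, ~450 proteins) keep a
full bundle under a tenth of a second to generate while leaving every
funnel stage non-trivially populated; tests run dozens to a hundred
bundles of this size.

Design choices worth knowing:

- **Sequences are random amino-acid strings** (uniform over the 20
  letters, lengths 80–600). Clustering execution is out of scope, so no
  attempt is made to make sequences clustering-realistic. Consequently,
  passing tests demonstrate correctness of the selection/partition/
  reconciliation logic — not robustness to real-world clustering noise,
  annotation-transfer errors, or taxonomy misassignment, which live
  upstream of this package's inputs.
- **Evidence values are drawn strictly inside open tier intervals**
  (e.g. certain E-values in (1e-12, 1e-7)), so no generated value sits
  on a classification boundary and tier labels are unambiguous by
  construction.
- **The truth manifest is re-derived, not copied.** Gut-exclusivity is
  recomputed from the generated metadata by plain set operations; the
  unique/homologous group of each supercluster is recomputed from the KO
  tables; the expected final label of each subject is produced by a
  straight-line re-implementation of the ladder inside the generator.
  The pipeline modules are never called, so a test comparing pipeline
  output to the manifest is a genuine dual-route check.
- **Superclusters are built after selection**, mirroring the study
  design in which MinHash grouping is applied to the fully annotated,
  selected clusters; the bacterial KO universe used for both the
  manifest and the pipeline is the union over selected bacterial
  clusters.
- **One named RNG stream per file type** is derived from the single
  master seed, so adding a generated file type never perturbs existing
  fixtures; two runs with the same config are byte-identical.

## Numerical and degenerate-input conventions

- Coordinates are 1-based inclusive everywhere (Prodigal/GFF3
  convention); no half-open intervals are stored.
- Environment labels are compared by exact string equality after
  lowercasing/whitespace normalization; no fuzzy matching
  (predictability over recall).
- Writers are deterministic: fixed column order, floats at six
  significant digits, byte-identical reruns.
- Cluster representatives are the longest member sequence, ties broken
  lexicographically by protein id (no representative rule is printed
  upstream; this one is reproducible and favors complete ORFs).
- Level-1 clusters mixing archaeal and bacterial members are rejected as
  malformed input (domains are clustered separately upstream).
- Selection stages run environment → size → annotation; the size and
  annotation gates commute (asserted in tests), so stage order affects
  intermediate funnel counts only.
- An empty evidence bundle reconciles to `unannotated`/`none`; a subject
  listed in the label map without a bundle produces a warning and an
  unannotated row rather than an error.

## Limitations

- KO sharing is evaluated against the *global* bacterial KO universe of
  retained clusters (the documented default); a narrower
  within-supercluster reading can be obtained by passing a restricted
  universe to `partition_by_ko()`.
- The u*/h* label numbering is by supercluster id by default; occurrence
  -ranked numbering is available but requires member counts.
- The diagnostic-ratio formulas are degenerate as printed (see above);
  they are reported for fidelity, with flags, and should not be read as
  informative likelihood ratios.
- The generator does not simulate reads, phylogenetic signal, or
  structure coordinates; claims about those layers are outside what the
  test suite can establish.
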