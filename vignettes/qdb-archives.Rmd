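---
title: "QDB archives: the data model, its invariants, and how this package tests them"
output: rmarkdown::html_vignette
vignette: >
  %\VignetteIndexEntry{QDB archives: the data model, its invariants, and how this package tests them}
  %\VignetteEngine{knitr::rmarkdown}
  %\VignetteEncoding{UTF-8}
---

```{r setup, include = FALSE}
knitr::opts_chunk$set(collapse = TRUE, comment = "#>")
library(qsardb)
```

## The problem

Most QSAR/QSPR models are communicated through printed tables: a regression
equation, a descriptor matrix, a column of experimental activities.  Reusing
such a model means re-keying all of it, and most published models beyond
simple linear regressions are effectively unrecoverable.  The QsarDB (QDB)
archive format addresses this by storing a data set and its models as a
small tree of plain-text files with fixed naming conventions, so that the
whole *in silico* experiment — structures, experimental values, descriptors,
the model, and its predictions — travels as one self-describing unit.

This package implements the format: the typed container model, both storage
backends, the system cargo codecs, a linear-regression PMML subset with an
evaluator, archive validation, table conversion, on-demand statistics, and a
CLI.  Model *training* is deliberately out of scope — it belongs to external
statistics environments; the archive stores the trained model and its
provenance.

## The data model

An archive holds five registries, one per concrete container type:

* **Compound** — a chemical compound, optionally carrying a CAS registry
  number (shape `N{2,7}-NN-N`, mod-10 weighted check digit) and a standard
  InChI (prefix `InChI=1S`).  Chemical structures (SMILES, MDL Molfile,
  CML, ...) are attached as cargos whose identifiers derive from the
  Chemical MIME type by stripping `chemical/x-`; SMILES is special-cased
  because flavours other than Daylight SMILES cannot be told apart reliably
  and all share the shorthand identifier `smiles`.
* **Property** — an experimentally measured endpoint (dependent variable),
  with free-text endpoint classification and optional binomial species name.
* **Descriptor** — an independent variable, with the name/version of the
  software that computed it.
* **Model** — a mathematical relationship predicting exactly one property
  (`property_id` attribute); the full variable information lives in its
  `pmml` cargo.
* **Prediction** — the result of executing a model, typed as `training`,
  `validation` or `testing`.

Property, Descriptor and Prediction share the *Parameter* role: a `values`
cargo (TSV, compound id then value), a `references` cargo (TSV, compound id
then BibTeX key, resolvable against the sibling `bibtex` cargo), and a
`ucum` unit string.  All containers additionally carry an identifier, name,
description, labels (set-forming tags) and the declared cargo list.

The text of the format's description states Container has "six attributes"
while enumerating five (Id, Name, Description, Labels, Cargos), and its
inheritance diagram also shows five.  This package implements the five that
are actually enumerated; `qdb_schema()` introspects the implemented
hierarchy rather than reporting hard-coded counts.

Strong relationships (`Property <- Model <- Prediction`) are declared by
right-hand-side attributes and enforced by the API: `qdb_remove()` refuses
to orphan a referenced container, and the left-hand side stores no
back-references (deleting a compound requires no registry scan).  Weak
relationships — compound ids inside parameter tables, variable ids inside
PMML — are *not* enforced at mutation time; they are the validator's
business, so that imperfect archives remain loadable and inspectable.

## Storage and paths

Paths are fixed by convention: `archive.xml` for the descriptor,
`<plural>/<plural>.xml` per non-empty registry, `<plural>/<id>/<cargo>` per
cargo, with `/` separators everywhere.  Both backends (directory tree, ZIP
with the recommended `.qdb.zip` double extension) produce identical
relative paths.  Two numerical/engineering choices deserve a note:

* **Canonical serialisation.**  The registry XML dialect (lowercase
  attribute-name elements under a per-type element, namespace
  `urn:qsardb:schema:1.0`) is written deterministically, so
  `save(load(save(A)))` is byte-identical to `save(A)`.  The normative XML
  Schema of the original format ships as supplementary material that is not
  part of this package's inputs; the dialect here is therefore this
  package's own, versioned by the namespace URI, with round-trip fidelity
  and the path conventions as the compatibility surface.
* **Reproducible ZIPs.**  ZIP entries embed timestamps, which would make
  byte-level reproducibility impossible; the writer stamps all staged files
  with a fixed epoch (2010-01-01 UTC) and writes entries in a fixed order
  (descriptor, registries, cargos sorted by path, extras), so identical
  content yields identical bytes.

Unrecognised files (e.g. `license.txt`) are preserved verbatim as
unofficial extensions and written back on save, never interpreted.

## Values and precision

Parameter values are verbatim strings.  A token is *normal* iff it parses
as a number in the simplified US form (dot decimal separator, optional sign
and exponent, no grouping — `1,204` is abnormal); every other token
(`N/A` or a custom error code) is *abnormal* and is carried through all
computations rather than dropped, because a recorded void measurement is
information.  The library never reformats a stored value; numbers the
package computes itself (predictions, synthetic data) are formatted with
`%.17g`, which round-trips IEEE doubles exactly.  This is what makes the
"noiseless archive fits perfectly" test exact rather than approximate: the
generator and the PMML evaluator share one arithmetic path (same summation
order), so stored property values and recomputed predictions are
bit-identical when the noise term is zero.

## The PMML subset

Only single-target linear regression is supported: the converter's
regression option and the evaluator need nothing more, and a consumer that
silently half-understands a richer model type is worse than one that
refuses.  The writer pins PMML 4.2; the reader accepts any version whose
regression vocabulary matches and rejects other model elements by name.
Variable names use prefixed identifiers (`properties/p1`,
`descriptors/logp`) — the container's abstract archive path — which removes
any ambiguity when both registries number their members `1`, `2`, `3`.
Models carry no per-prediction values cargo of their own; predictions do
(they have the Parameter role, models do not).

## Validation

`qdb_validate()` runs ten rules (r1–r10, listed in its help page) and
returns findings rather than throwing.  Severities: everything is an
`error` except case-insensitive identifier collisions (r5), which the
format phrases as "should be treated as case-insensitive" — a warning.
Dangling weak references (r3) are errors at validation time but never block
load or removal.  External curation services (name parsing, structure
resolution) are excluded by design; only the offline-checkable parts of
curation — CAS check digit, InChI prefix, intra-archive consistency — are
implemented.

## Statistics on demand

Goodness-of-fit figures are computed when asked and never persisted: the
archive stores primary data only.  `qdb_fit()` pairs experimental and
predicted values by compound id, drops pairs with an abnormal member, and
reports `n`, `r_squared = 1 - SS_res/SS_tot` and `rmse = sqrt(SS_res/n)`.
Three choices the format leaves open are fixed here:

* residuals are `predicted - experimental`;
* `SS_tot` is taken about the experimental mean of the *paired subset*, not
  of the full registry;
* `r_squared` is `NA` when `n < 2` or `SS_tot = 0`, and is reported
  unclamped (a fit worse than the mean gives a negative value).

Validation predictions are sub-typed by set algebra against the model's
training prediction: `internal` (contained), `external` (disjoint), or
`mixed`, the last with an R warning since mixed sets are expected to be
split before archiving.  An empty validation set is vacuously `internal`.

Label queries use a small boolean grammar (`label`, `NOT`, `AND`, `OR`,
parentheses; case-sensitive keywords; precedence `NOT > AND > OR`); labels
share the identifier character set, which keeps the grammar unambiguous.

## The synthetic generator — and what a green test does not establish

`qdb_generate()` emulates a small digitised toxicity data set: compounds
with checksum-correct CAS numbers and single-line SMILES from a fixed
alphabet of real molecules, descriptors drawn uniform(0, 1), one property
`pLC50` produced by a known linear model plus Gaussian noise, the model's
PMML cargo carrying the true coefficients, and its training prediction.
Defaults — 30 compounds, 2 descriptors, coefficients alternating 1.5/−0.8,
intercept 0.5, noise sigma 0.1, 5% `N/A` rows — describe a modest but
realistic QSAR training exercise; they were chosen once and are not tuned
to test outcomes.

What the generator does *not* emulate: chemically meaningful
structure–activity correlation (SMILES strings are plumbing, not
chemistry), correlated or heavy-tailed descriptor distributions,
non-linear relationships, and inter-laboratory heterogeneity of real
measured endpoints.  A green round-trip or fit test therefore establishes
that the *format machinery* is correct — paths, codecs, fidelity,
arithmetic — not that any scientific modelling claim holds.

## Degenerate inputs and tie-breaks

* Empty registries are legal everywhere and simply omitted from storage.
* A zero-compound archive still supports `qdb_attach_regression()`; the
  training table is empty.
* Empty table cells in a values column become `"N/A"`, never dropped rows.
* Duplicate BibTeX keys make every reference to them *ambiguous* findings;
  resolution is never silently first-match.
* `qdb_parse_values()` is strict about duplicate compound rows; the
  validator re-parses leniently so rule r10 can report what strict parsing
  would reject.

## Known limitations

No applicability-domain formalism (left open by the format), no Q² or
cross-validation loops, no unit algebra on UCUM strings, no chemistry
toolkit integration (structure payloads are opaque bytes), no descriptor
recomputation, and no native XLS/ODS parsing (export to CSV/TSV first).
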