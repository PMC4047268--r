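# qsardb

Tools for **QDB archives** — a plain-text container/cargo format for
QSAR/QSPR data sets and models.

A QDB archive stores a complete *in silico* experiment as a small file
tree: an archive descriptor (`archive.xml`), one XML registry per container
type (**compounds**, **properties**, **descriptors**, **models**,
**predictions**), and one file per cargo attachment (SMILES structures,
tab-separated value tables, UCUM unit strings, BibTeX references, BODO
descriptor-ontology records, PMML model documents).  Strong relationships
run `Property ← Model ← Prediction`; predictions are typed `training`,
`validation` or `testing`.  The model cargo is a linear-regression PMML
subset

    y = b0 + b1·x1 + … + bk·xk

whose variables are prefixed container identifiers (`properties/p1`,
`descriptors/logp`).  Goodness of fit is computed on demand — R² = 1 −
SS_res/SS_tot and RMSE = √(SS_res/n) over compound-paired normal values —
and never stored in the archive.

The package is for anyone who archives, exchanges, validates or re-executes
QSAR models: it provides the in-memory type system, directory and
`*.qdb.zip` storage backends with byte-reproducible output, cargo codecs,
a PMML evaluator, a ten-rule archive validator (including CAS registry
number check digits), a table-to-archive converter, label queries, a
synthetic-archive generator and a `qdb` command-line toolkit.

## Worked example

```r
library(qsardb)

a <- qdb_generate(qdb_synthetic_spec(n_compounds = 10, seed = 42))
a
#> <qdb archive> 'Synthetic linear QSAR data set'
#>   compounds    10
#>   properties   1
#>   descriptors  2
#>   models       1
#>   predictions  1

qdb_fit(a, "m1-training")
#> <qdb fit> n = 10, R^2 = 0.938608, RMSE = 0.109821

qdb_validate(a)
#> No findings: the archive is valid.

qdb_query(a, "train AND NOT test")
#> [1] "2"  "3"  "4"  "6"  "7"  "8"  "9"  "10"
```

The fit line reads: all 10 compounds had paired normal experimental and
predicted values; the synthetic property was generated from the stored
model plus Gaussian noise (sigma = 0.1), so R² is high but not 1 and the
RMSE is near the noise level.  The query selects the compounds labelled
`train` in registry order.

Saving and loading (backend chosen from the path):

```r
qdb_save(a, "example.qdb.zip")   # or a directory path
b <- qdb_load("example.qdb.zip")
identical(a, b)
#> [1] TRUE
```

Converting a spreadsheet export and attaching a regression model in one go:

```sh
qdb import --in table.tsv \
    --map "0=cas" --map "1=cargo:smiles" \
    --map "2=property:pLC50" --map "3=descriptor:logp" \
    --equation "pLC50 = 1.0 + 1.5*logp" \
    --out example.qdb.zip
qdb validate example.qdb.zip      # exit 0: no findings
qdb stats example.qdb.zip --prediction m1-training
```

(`exec/qdb` is a thin Rscript wrapper around `qsardb::qdb_cli()`; column
indices in `--map` are 0-based.)

## Package layout

* `R/schema.R` — containers, registries, strong relationships, introspection
* `R/storage.R` — path conventions, directory/ZIP backends, XML dialect
* `R/codecs.R` — values/references TSV, BibTeX, BODO YAML, UCUM, structure MIME
* `R/pmml.R` — PMML regression subset and evaluator
* `R/validation.R` — CAS/InChI checks and rules r1–r10
* `R/conversion.R` — table conversion, equation grammar
* `R/analytics.R` — fit statistics, validation subtype, label queries
* `R/synthetic.R`, `R/cli.R` — generator and command-line toolkit
* `vignettes/qdb-archives.Rmd` — the data model, design decisions, limits
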