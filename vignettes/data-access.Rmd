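---
title: "Format-agnostic access to MS proteomics data: model, methods and design"
author: "ProteoAccess"
output: rmarkdown::html_vignette
vignette: >
  %\VignetteIndexEntry{Format-agnostic access to MS proteomics data}
  %\VignetteEngine{knitr::rmarkdown}
  %\VignetteEncoding{UTF-8}
---

```{r setup, include = FALSE}
knitr::opts_chunk$set(collapse = TRUE, comment = "#>")
library(ProteoAccess)
```

## The problem

Mass-spectrometry proteomics data arrives in an unusually fragmented set of
file formats: raw-spectra containers (mzML, mzXML, mzData), plain-text peak
lists produced by instrument and search tooling (mgf, dta, pkl, ms2, apl),
identification XML (mzIdentML, PRIDE XML) and the tab-separated summary
format mzTab. Code that analyses such data tends to accrete one ad-hoc
parser per format, and the translation layer dominates the tool instead of
the science. ProteoAccess puts one metadata-oriented data model over all of
these formats and hands every file to the caller through the same
data-access controller contract, so downstream code is file-format
agnostic.

## Data model

The model has three layers:

* **Proteomics data**: `Spectrum` (peak arrays plus a `Precursor`),
  `Chromatogram`, and the identification hierarchy `Protein` → `Peptide` →
  `PSM` with scores, ranks, threshold flags and decoy flags.
* **Features and properties**: every entity carries a `ParamGroup` holding
  ordered `CvParam` (controlled-vocabulary, e.g. PSI-MS terms) and
  `UserParam` (free-form) annotations. Scores and thresholds travel as
  cvParams, so nothing is lost when a format has no dedicated field.
* **Metadata**: `ExperimentMetadata` with instrument params and
  `ProteinDetectionProtocol` entries (software, enzyme, search database,
  threshold).

A controller advertises three capability groups — spectra,
identifications, quantification — instead of one monolithic interface; a
peak-list file must not stub out twenty identification methods. All getters
are pure: call order never changes results.

Conventions applied uniformly across every reader:

* **Identifier policy.** Source-native ids are preserved verbatim. Formats
  that carry no ids (dta, pkl) get deterministic `index=<0-based ordinal>`
  ids.
* **Modification coordinates.** 1-based residue positions, with 0 for the
  N-terminus and sequence length + 1 for the C-terminus (the mzIdentML
  convention), applied to every format.
* **Sequence alphabet.** The canonical 20 letters ACDEFGHIKLMNPQRSTVWY.
  Parsed sequences may contain other letters (real search output does);
  the physicochemical calculators reject them with an error naming the
  residue and its position, because property arithmetic on B/Z/X/U/O is
  undefined and silent averaging would corrupt downstream comparisons.

## Format subsets

Full schema engines are out of scope; each reader implements a documented
subset and skips unknown elements silently (mzML 1.1.0, mzIdentML 1.1.0,
mzXML 3.x, mzData 1.05, PRIDE XML 2.1, mzTab 1.0). Binary peak arrays are
base64, 32- or 64-bit floats, optionally zlib-compressed; mzML and mzData
are little-endian, mzXML uses network byte order with interleaved
m/z-intensity pairs. Numpress and other non-zlib compressions raise a
clear unsupported-feature error rather than decoding garbage.

mzML is read lazily: a single streaming pass (chunked byte scanner,
constant memory) records the header and the byte range of every
`<spectrum>` and `<chromatogram>` element; `getSpectrum()` re-reads and
parses only that slice. Peak memory is therefore bounded by the largest
single element, not the file — the property the validation suite checks on
a generated 10,000-spectrum file by sampling live memory during a full
iteration. The other XML formats are parsed as a whole document: their
role here (identification graphs, embedded spectra) keeps files small
relative to raw data.

## Cache design

Access patterns in MS workflows are bimodal: metadata and id lists are
touched by everything, while individual spectra are fetched sporadically.
The cache mirrors this with two tiers:

* a **whole-object hot tier** holding parsed objects under an LRU policy
  with a fixed capacity (default 512 entries) — metadata and id lists are
  pinned and always served whole;
* a **cold tier of byte offsets**: entities evicted from the hot tier are
  re-read on demand by slice-parsing `[offset, offset + length)` from the
  source, for the framed formats (mgf, pkl, ms2, apl blocks and mzML
  elements). dta is a single-spectrum format and has no framing.

LRU is this package's concrete reading of "frequently requested objects
stay whole"; any bounded recency policy would satisfy the transparency
contract, which is the real invariant: for any access sequence, cached and
uncached controllers return content-equal objects, and the hot tier never
exceeds its capacity.

Offset indexes embed an md5 of the source. A checksum mismatch at access
time is an error, never a silent re-index — a corrupt partial read is
strictly worse than a loud failure. Re-hashing on every access would be
absurdly slow, so verification is memoized on (size, mtime): any
modification that changes either triggers a full re-hash. An index can be
persisted as a small JSON sidecar and reloaded, keyed by the same
checksum.

## mzTab export and quality filters

`convertToMzTab()` turns any identification-capable controller into an
mzTab 1.0 document. "High-quality" is not a standardised notion, so the
filter is explicit, fully parameterised and applied in a documented order:

1. drop decoy proteins and decoy PSMs (`dropDecoys`);
2. drop PSMs failing their search threshold (`requirePassThreshold`);
3. drop PSMs with rank > `maxRank`;
4. drop proteins failing their detection threshold;
5. drop proteins with fewer than `minPeptidesPerProtein` surviving
   distinct peptides (a peptide survives while it keeps one surviving
   PSM).

The order matters — a protein can lose a peptide at step 2 and then fail
step 5 — and the suite fuzz-tests exact PSM-row conservation against an
independent brute-force filter over random fixtures and random settings.
The defaults (`requirePassThreshold = TRUE`, `maxRank = 1`,
`dropDecoys = TRUE`, `minPeptidesPerProtein = 1`) mirror common community
practice and the mzIdentML `passThreshold` semantics; every field is
overridable from the API and the CLI. One PSM row is emitted per surviving
(PSM, protein) pair; absent values are written as `"null"` per the mzTab
convention. The writer refuses any document whose structural check
reports errors; the checker is report-based with stable codes, never an
exception. Table cells are kept as strings exactly as serialised, which
is what makes write → parse the identity and repeated writes
byte-stable.

## Physicochemical calculators

**Net charge and isoelectric point.** The classic Henderson–Hasselbalch
charge model: at pH $p$, each basic group (N-terminus, H, K, R)
contributes $10^{pK_a - p} / (1 + 10^{pK_a - p})$ and each acidic group
(C-terminus, D, E, C, Y) contributes $-10^{p - pK_a} / (1 + 10^{p -
pK_a})$, summed with residue multiplicities. The net charge is strictly
decreasing in pH, so the isoelectric point — its unique zero — is found by
bisection on [0, 14]. The iteration stops when the absolute charge drops
below `tol` (default 1e-4) *and* the pH bracket is narrower than 1e-6:
the second condition matters because the charge curve can be nearly flat
around the zero, where a charge-only stop would leave the pH imprecise.
For a peptide with no ionizable side chains the model reduces to the
amphoteric closed form $(pK_a^{N} + pK_a^{C})/2$, which the tests assert.

The pKa constants ship as a named, swappable plain-text table; the default
is the Bjellqvist set (N-term 7.50, C-term 3.55; D 4.05, E 4.45, C 9.0,
Y 10.0, H 5.98, K 10.0, R 12.0), without neighbour-dependent corrections.
Other tables in the same layout can be dropped in via `loadPkaTable()`.

**Monoisotopic mass.** $M = \sum_i m_{res}(s_i) + m_{H_2O} + \sum_j
\Delta_j$ over residues and modification deltas, with $m_{H_2O} =
18.010565$ Da; with a charge $z$ the ion m/z $(M + z \cdot 1.007276)/z$
is returned. Residue masses are standard monoisotopic reference values
vendored as a constants file with provenance comments.

**GRAVY.** The grand average of hydropathy: the arithmetic mean of
Kyte–Doolittle per-residue values, shipped as the same kind of table.

**CV homogenisation.** A bundled rule table maps native field names
(`TITLE` in mgf, `precursorMz` in mzXML, …) onto PSI-MS terms so the same
concept carries the same accession everywhere. The mapping is total by
design: unmapped keys pass through as userParams and are never dropped.

## The synthetic-experiment generator

All verification runs on seeded synthetic experiments rendered to every
supported format; no downloads are involved. Default conditions: 10
proteins, 4 peptides per protein (random canonical sequences of length
7–25), 1 PSM per peptide at charge 2–3, 30 peaks per spectrum, a 0.2
decoy fraction and a 0.1 failing-threshold fraction — sizes chosen as a
small but structurally complete identification experiment in which every
filter and every branch of the hierarchy is exercised. Each PSM's
spectrum has its precursor m/z tied to the peptide's monoisotopic mass at
the PSM charge, which welds the fixture to the calculators. One RNG
namespace per entity kind is derived from the master seed, so changing
the protein count does not perturb the spectra stream; the manifest is
byte-identical for equal seeds.

Spectral peaks are uniform-random m/z in [100, 2000) with log-uniform
intensities. This deliberately emulates *transport*, not physics: there is
no fragment-ion model, no isotope envelopes, no noise floor, no
retention-time structure, and quantification is limited to placeholder
abundances. Passing tests therefore demonstrate faithful round-tripping,
referential closure and filter arithmetic on realistic *shapes* of data —
they say nothing about peak interpretation, which this library never
attempts.

## Numerical choices and degenerate inputs

* Text output uses shortest-round-trip float formatting, so text
  round-trips are exact at 64-bit; declared 32-bit arrays (mzXML) are
  compared at 1e-6 relative.
* Zero-intensity peaks are preserved; filtering is the caller's decision.
* mgf `CHARGE` lists ("2+ and 3+") keep the first charge — the model has
  one precursor charge slot — and retain the raw string as a userParam;
  ms2 keeps every `Z` line as a charge-state cvParam for the same reason.
* dta streams hold one spectrum (classic SEQUEST); concatenated dta is
  out of scope because tools disagree on its framing. The dta precursor
  is stored as M+H and converted to m/z as $(M_H + (z-1) \cdot
  1.007276)/z$, with the M+H provenance recorded as a userParam.
* Empty peak lists, empty protein lists and an empty mzTab document are
  valid objects, not errors.
* Parse errors in the text formats carry 1-based line numbers; dangling
  references in mzIdentML name the offending reference.

## Validation problem sizes

The test suite and the reproduction script run entirely on generated
data: the cross-format and round-trip checks use the default experiment
(40 PSMs across 11 renderings), the calculator oracles use 1000 random
peptides, filter conservation fuzzes 100 (fixture, filter) pairs, cache
transparency replays 1000 random accesses, and the bounded-memory check
iterates a generated 10,000-spectrum mzML. These sizes keep a full run in
the order of a minute or two while leaving every code path exercised.

## Known limitations

* Schema subsets, not schema engines: exotic but valid documents of these
  formats may parse incompletely (unknown elements are skipped).
* No protein inference or grouping: each detection hypothesis is one
  protein; ambiguity-group membership is kept as an annotation only.
* No numpress, no mzTab 2.0 / mzTab-M, no small-molecule sections, no
  network retrieval.
* The pKa table choice is documented, not asserted equivalent to any
  other tool's; swap the table to match a different lineage.
* PRIDE XML carries no rank or threshold semantics, so PSMs read from it
  report rank 1 and passing thresholds; decoy status uses the PRIDE
  decoy-hit term.
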