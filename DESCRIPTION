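Package: ProteoAccess
Title: Unified Data Model and Format-Agnostic Access to Mass Spectrometry
    Proteomics Data
Version: 0.9.0
Authors@R: person("Package", "Author", email = "author@example.org",
    role = c("aut", "cre"))
Description: A metadata-oriented data model for mass spectrometry based
    proteomics, with data-access controllers over the common peak-list
    formats (mgf, dta, pkl, ms2, apl), the XML spectra containers (mzML,
    mzXML, mzData), the identification formats (mzIdentML, PRIDE XML) and
    mzTab 1.0. Every controller exposes the same interface, so downstream
    code is file-format agnostic. Includes a two-tier cache (whole-object
    LRU plus byte-offset index for random access), an mzTab exporter with
    identification-quality filters, controlled-vocabulary term
    homogenisation, peptide physicochemical calculators (isoelectric
    point by charge-balance bisection, monoisotopic mass, GRAVY), and a
    seeded synthetic-experiment generator that renders to every supported
    format.
License: MIT
Encoding: UTF-8
Depends: R (>= 4.2)
Imports:
    methods,
    stats,
    utils,
    tools,
    xml2,
    jsonlite
Suggests:
    testthat (>= 3.0.0),
    optparse
Config/testthat/edition: 3
Roxygen: list(markdown = TRUE)
RoxygenNote: 7.3.3
Collate:
    'AllClasses.R'
    'AllGenerics.R'
    'params.R'
    'constants.R'
    'sequence-utils.R'
    'peaklist-io.R'
    'binary-arrays.R'
    'scan.R'
    'offset-index.R'
    'xml-spectra.R'
    'xml-ident.R'
    'controller.R'
    'cache.R'
    'mztab.R'
    'fixtures.R'
    'cli.R'
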