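## Core data model: S4 classes shared by every format controller.
##
## Design notes
## - Optional scalar fields are NA of the right type, never NULL, so slots keep
##   a fixed class and validity stays cheap.
## - Entities carry a ParamGroup so controlled-vocabulary (cvParam) and
##   free-form (userParam) annotations survive every format translation.

#' Canonical amino-acid alphabet
#'
#' The twenty canonical residues accepted by the physicochemical calculators.
#' Parsers tolerate other letters (with a warning); calculators reject them.
#'
#' @export
CANONICAL_RESIDUES <- strsplit("ACDEFGHIKLMNPQRSTVWY", "")[[1]]

#' @importFrom methods setClass new validObject slot is setValidity
NULL

#' CvParam: controlled-vocabulary annotation
#'
#' An ontology-anchored key/value pair (for example a PSI-MS term) attached to
#' spectra, identifications and metadata, mirroring the cvParam element of the
#' PSI XML formats.
#'
#' @slot cvLabel short ontology label, e.g. `"MS"`.
#' @slot accession ontology accession, e.g. `"MS:1000744"`.
#' @slot name human-readable term name.
#' @slot value optional value (NA when the term is a flag).
#' @slot unitAccession,unitName optional unit term.
#' @export
setClass("CvParam", representation(
    cvLabel = "character", accession = "character", name = "character",
    value = "character", unitAccession = "character", unitName = "character"))

setValidity("CvParam", function(object) {
    if (length(object@accession) != 1L || is.na(object@accession) ||
        !nzchar(object@accession)) return("accession must be non-empty")
    if (length(object@cvLabel) != 1L || is.na(object@cvLabel) ||
        !nzchar(object@cvLabel)) return("cvLabel must be non-empty")
    TRUE
})

#' UserParam: free-form annotation
#'
#' A user-defined parameter for information not (yet) covered by a controlled
#' vocabulary.
#'
#' @slot name parameter name (non-empty).
#' @slot value optional value.
#' @export
setClass("UserParam", representation(name = "character", value = "character"))

setValidity("UserParam", function(object) {
    if (length(object@name) != 1L || is.na(object@name) || !nzchar(object@name))
        return("name must be non-empty")
    TRUE
})

#' ParamGroup: ordered container of CvParams and UserParams
#'
#' Order is preserved; lookup by accession returns the first match.
#'
#' @slot cvParams list of [CvParam-class] objects.
#' @slot userParams list of [UserParam-class] objects.
#' @export
setClass("ParamGroup", representation(cvParams = "list", userParams = "list"),
    prototype(cvParams = list(), userParams = list()))

setValidity("ParamGroup", function(object) {
    if (!all(vapply(object@cvParams, is, logical(1L), "CvParam")))
        return("cvParams must all be CvParam")
    if (!all(vapply(object@userParams, is, logical(1L), "UserParam")))
        return("userParams must all be UserParam")
    TRUE
})

#' Precursor: the selected ion fragmented to give an MSn spectrum
#'
#' @slot mz selected-ion m/z in Thomson (positive).
#' @slot charge optional signed charge (NA when unknown).
#' @slot intensity optional precursor intensity (NA when unknown).
#' @export
setClass("Precursor", representation(
    mz = "numeric", charge = "integer", intensity = "numeric"),
    prototype(charge = NA_integer_, intensity = NA_real_))

setValidity("Precursor", function(object) {
    if (length(object@mz) != 1L || is.na(object@mz) || object@mz <= 0)
        return("precursor mz must be a single positive number")
    if (!is.na(object@charge) && object@charge == 0L)
        return("precursor charge must be nonzero when present")
    if (!is.na(object@intensity) && object@intensity < 0)
        return("precursor intensity must be non-negative")
    TRUE
})

setClassUnion("PrecursorOrNULL", c("Precursor", "NULL"))

#' Spectrum: one mass spectrum, the unit of random access
#'
#' @slot id native identifier, unique within its source file.
#' @slot index 0-based ordinal position in the source.
#' @slot msLevel MS level (1 = survey, 2 = fragment, ...).
#' @slot mz m/z array, non-decreasing, non-negative (Th).
#' @slot intensity intensity array, non-negative, same length as `mz`.
#' @slot precursor optional [Precursor-class].
#' @slot params [ParamGroup-class] of annotations.
#' @export
setClass("Spectrum", representation(
    id = "character", index = "integer", msLevel = "integer",
    mz = "numeric", intensity = "numeric",
    precursor = "PrecursorOrNULL", params = "ParamGroup"))

setValidity("Spectrum", function(object) {
    if (length(object@mz) != length(object@intensity))
        return("mz and intensity arrays must have equal length")
    if (length(object@mz) && (any(object@mz < 0) || is.unsorted(object@mz)))
        return("mz array must be non-negative and non-decreasing")
    if (length(object@intensity) && any(object@intensity < 0))
        return("intensity array must be non-negative")
    if (is.na(object@index) || object@index < 0L)
        return("index must be >= 0")
    if (is.na(object@msLevel) || object@msLevel < 1L)
        return("msLevel must be a positive integer")
    TRUE
})

#' Chromatogram: an intensity trace over retention time
#'
#' @slot id native identifier.
#' @slot time retention times in minutes, non-decreasing.
#' @slot intensity intensities, same length as `time`.
#' @slot params [ParamGroup-class].
#' @export
setClass("Chromatogram", representation(
    id = "character", time = "numeric", intensity = "numeric",
    params = "ParamGroup"))

setValidity("Chromatogram", function(object) {
    if (length(object@time) != length(object@intensity))
        return("time and intensity arrays must have equal length")
    if (length(object@time) && is.unsorted(object@time))
        return("time array must be non-decreasing")
    if (length(object@intensity) && any(object@intensity < 0))
        return("intensity array must be non-negative")
    TRUE
})

#' Modification: a mass shift on a peptide
#'
#' Position convention (uniform across all readers): 1-based residue
#' positions; 0 is the N-terminus and `nchar(sequence) + 1` the C-terminus.
#'
#' @slot accession modification accession (UNIMOD / PSI-MOD).
#' @slot name modification name.
#' @slot monoDelta monoisotopic mass delta in Dalton.
#' @slot position position on the owning peptide (see convention above).
#' @export
setClass("Modification", representation(
    accession = "character", name = "character",
    monoDelta = "numeric", position = "integer"))

setValidity("Modification", function(object) {
    if (is.na(object@position) || object@position < 0L)
        return("position must be >= 0")
    if (length(object@monoDelta) != 1L || is.na(object@monoDelta))
        return("monoDelta must be a single number")
    TRUE
})

#' PSM: a peptide-spectrum match
#'
#' @slot id native identifier.
#' @slot sequence uppercase amino-acid sequence.
#' @slot modifications list of [Modification-class].
#' @slot spectrumRef optional id of the matched spectrum.
#' @slot charge assumed precursor charge.
#' @slot experimentalMz observed precursor m/z (Th).
#' @slot calculatedMz theoretical precursor m/z (NA when not reported).
#' @slot rank search-engine rank (1 = best).
#' @slot passThreshold whether the identification passed the search threshold.
#' @slot scores [ParamGroup-class] of search-engine scores.
#' @slot isDecoy decoy flag.
#' @export
setClass("PSM", representation(
    id = "character", sequence = "character", modifications = "list",
    spectrumRef = "character", charge = "integer",
    experimentalMz = "numeric", calculatedMz = "numeric",
    rank = "integer", passThreshold = "logical",
    scores = "ParamGroup", isDecoy = "logical"),
    prototype(spectrumRef = NA_character_, calculatedMz = NA_real_,
        modifications = list(), isDecoy = FALSE))

setValidity("PSM", function(object) {
    if (!grepl("^[A-Z]+$", object@sequence))
        return("sequence must be a non-empty uppercase letter string")
    if (is.na(object@rank) || object@rank < 1L) return("rank must be >= 1")
    if (is.na(object@experimentalMz) || object@experimentalMz <= 0)
        return("experimentalMz must be positive")
    if (!is.na(object@calculatedMz) && object@calculatedMz <= 0)
        return("calculatedMz must be positive when present")
    n <- nchar(object@sequence)
    for (m in object@modifications)
        if (m@position > n + 1L)
            return("modification position outside [0, length + 1]")
    TRUE
})

#' Peptide: a distinct peptide with its supporting PSMs
#'
#' @slot id native identifier.
#' @slot sequence amino-acid sequence shared by all referenced PSMs.
#' @slot modifications representative list of [Modification-class].
#' @slot psmIds non-empty character vector of PSM ids.
#' @export
setClass("Peptide", representation(
    id = "character", sequence = "character", modifications = "list",
    psmIds = "character"), prototype(modifications = list()))

setValidity("Peptide", function(object) {
    if (length(object@psmIds) < 1L) return("psmIds must be non-empty")
    if (!grepl("^[A-Z]+$", object@sequence))
        return("sequence must be a non-empty uppercase letter string")
    TRUE
})

#' Protein: an identified protein with its peptides
#'
#' @slot id native identifier.
#' @slot accession database accession (non-empty).
#' @slot dbSequence optional database amino-acid sequence.
#' @slot passThreshold whether the protein passed the detection threshold.
#' @slot scores [ParamGroup-class] of protein-level scores.
#' @slot peptideIds character vector of peptide ids (unique).
#' @slot isDecoy decoy flag.
#' @export
setClass("Protein", representation(
    id = "character", accession = "character", dbSequence = "character",
    passThreshold = "logical", scores = "ParamGroup",
    peptideIds = "character", isDecoy = "logical"),
    prototype(dbSequence = NA_character_, isDecoy = FALSE,
        passThreshold = TRUE))

setValidity("Protein", function(object) {
    if (length(object@accession) != 1L || is.na(object@accession) ||
        !nzchar(object@accession)) return("accession must be non-empty")
    if (anyDuplicated(object@peptideIds)) return("peptideIds must be unique")
    TRUE
})

#' ProteinDetectionProtocol: how the identifications were produced
#'
#' Houses the software list, enzyme, search database and threshold that the
#' identification XML formats report.
#'
#' @slot software list of `c(name, version)` character pairs.
#' @slot enzyme optional enzyme name.
#' @slot enzymeParams [ParamGroup-class] for the enzyme.
#' @slot searchDatabaseName,searchDatabaseVersion optional database identity.
#' @slot databaseParams [ParamGroup-class] for the database.
#' @slot threshold [ParamGroup-class] stating the acceptance threshold.
#' @export
setClass("ProteinDetectionProtocol", representation(
    software = "list", enzyme = "character", enzymeParams = "ParamGroup",
    searchDatabaseName = "character", searchDatabaseVersion = "character",
    databaseParams = "ParamGroup", threshold = "ParamGroup"),
    prototype(software = list(), enzyme = NA_character_,
        searchDatabaseName = NA_character_,
        searchDatabaseVersion = NA_character_))

#' ExperimentMetadata: experiment-level metadata
#'
#' @slot title optional experiment title.
#' @slot sourceFormat format tag of the source file.
#' @slot instrument [ParamGroup-class] describing the instrument.
#' @slot protocols list of [ProteinDetectionProtocol-class].
#' @slot contacts list of [ParamGroup-class].
#' @slot params additional [ParamGroup-class].
#' @export
setClass("ExperimentMetadata", representation(
    title = "character", sourceFormat = "character",
    instrument = "ParamGroup", protocols = "list", contacts = "list",
    params = "ParamGroup"),
    prototype(title = NA_character_, protocols = list(), contacts = list()))

setValidity("ExperimentMetadata", function(object) {
    if (!object@sourceFormat %in% c(FORMAT_TAGS, "memory"))
        return(sprintf("unknown sourceFormat '%s'", object@sourceFormat))
    TRUE
})

#' QuantValue: one per-assay abundance value
#'
#' @slot assayId assay identifier.
#' @slot value optional finite non-negative abundance.
#' @slot unit optional [CvParam-class] unit.
#' @export
setClass("QuantValue", representation(
    assayId = "character", value = "numeric", unit = "ANY"),
    prototype(value = NA_real_, unit = NULL))

setValidity("QuantValue", function(object) {
    if (!is.na(object@value) && (!is.finite(object@value) || object@value < 0))
        return("value must be finite and non-negative when present")
    TRUE
})

#' Supported format tags
#' @export
FORMAT_TAGS <- c("mgf", "dta", "pkl", "ms2", "apl", "mzml", "mzxml",
    "mzdata", "mzidentml", "pridexml", "mztab")

## ---- mzTab document model -------------------------------------------------

#' MzTabDocument: an mzTab 1.0 document ready for serialisation
#'
#' @slot metadata ordered named list of MTD key/value strings (keys unique).
#' @slot proteinTable data.frame of PRT rows (columns per mzTab 1.0 PRH).
#' @slot psmTable data.frame of PSM rows (columns per PSH).
#' @slot peptideTable optional data.frame of PEP rows (may have zero rows).
#' @export
setClass("MzTabDocument", representation(
    metadata = "list", proteinTable = "data.frame", psmTable = "data.frame",
    peptideTable = "data.frame"),
    prototype(peptideTable = data.frame()))

#' QualityFilter: identification-quality filter settings
#'
#' All fields are explicit; there are no silent defaults once a filter object
#' exists. See [convertToMzTab()] for the documented application order.
#'
#' @slot requirePassThreshold drop PSMs that failed the search threshold.
#' @slot maxRank keep PSMs with rank <= maxRank.
#' @slot dropDecoys drop decoy proteins and decoy PSMs.
#' @slot minPeptidesPerProtein keep proteins with at least this many
#'   surviving distinct peptides.
#' @export
setClass("QualityFilter", representation(
    requirePassThreshold = "logical", maxRank = "integer",
    dropDecoys = "logical", minPeptidesPerProtein = "integer"))

setValidity("QualityFilter", function(object) {
    if (is.na(object@maxRank) || object@maxRank < 1L)
        return("maxRank must be >= 1")
    if (is.na(object@minPeptidesPerProtein) ||
        object@minPeptidesPerProtein < 1L)
        return("minPeptidesPerProtein must be >= 1")
    if (is.na(object@requirePassThreshold) || is.na(object@dropDecoys))
        return("boolean filter fields must be TRUE or FALSE")
    TRUE
})

## ---- cache ----------------------------------------------------------------

#' OffsetIndex: byte offsets of randomly accessible entities
#'
#' Maps entity ids to `[offset, offset + length)` byte ranges in the source
#' file, so a single entity can be re-read and parsed without touching the
#' rest of the file. A content checksum guards against the source changing
#' after indexing.
#'
#' @slot formatTag format of the source file.
#' @slot sourcePath path of the indexed file.
#' @slot checksum md5 of the source content at indexing time.
#' @slot fileSize source size in bytes at indexing time.
#' @slot entries data.frame with columns `id`, `offset`, `length`, `ordinal`.
#' @export
setClass("OffsetIndex", representation(
    formatTag = "character", sourcePath = "character", checksum = "character",
    fileSize = "numeric", entries = "data.frame"))

setValidity("OffsetIndex", function(object) {
    e <- object@entries
    need <- c("id", "offset", "length", "ordinal")
    if (!all(need %in% names(e)))
        return("entries must have id/offset/length/ordinal columns")
    if (anyDuplicated(e$id)) return("entry ids must be unique")
    if (nrow(e) && any(e$offset < 0)) return("offsets must be non-negative")
    if (nrow(e) && any(e$length <= 0)) return("lengths must be positive")
    if (nrow(e) && any(e$offset + e$length > object@fileSize))
        return("entries must lie within the file")
    TRUE
})

## ---- controllers ----------------------------------------------------------

#' MsDataController: the uniform data-access contract
#'
#' Virtual parent of every format controller. A controller advertises which
#' capability groups it supports (spectra, identifications, quantification)
#' and answers the shared getters ([spectrumIds()], [getSpectrum()],
#' [proteinIds()], [peptideIds()], ...). All getters are pure: call order
#' never changes results.
#'
#' @slot path source file path.
#' @slot formatTag detected format tag.
#' @slot metadata [ExperimentMetadata-class].
#' @slot capabilities named logical: `spectra`, `identifications`,
#'   `quantification`.
#' @export
setClass("MsDataController", representation("VIRTUAL",
    path = "character", formatTag = "character",
    metadata = "ExperimentMetadata", capabilities = "logical"))

#' InMemoryController: fully parsed controller
#'
#' Backs the text peak-list formats and the identification XML formats, whose
#' defined subsets are parsed into the data model in one pass.
#'
#' @slot spectra named list of [Spectrum-class].
#' @slot spectrumOrder spectrum ids in file order.
#' @slot proteins,peptides,psms named lists of model objects.
#' @slot proteinOrder protein ids in file order.
#' @slot quant named list (by protein accession) of lists of
#'   [QuantValue-class].
#' @export
setClass("InMemoryController", contains = "MsDataController", representation(
    spectra = "list", spectrumOrder = "character",
    proteins = "list", proteinOrder = "character",
    peptides = "list", psms = "list", quant = "list"),
    prototype(spectra = list(), spectrumOrder = character(),
        proteins = list(), proteinOrder = character(),
        peptides = list(), psms = list(), quant = list()))

#' MzMLController: lazy, offset-indexed mzML reader
#'
#' Holds only the header metadata and a byte-offset index; each spectrum or
#' chromatogram element is read and parsed on demand, so peak memory is
#' bounded by the largest single element rather than the file.
#'
#' @slot index [OffsetIndex-class] over spectrum elements.
#' @slot chromIndex [OffsetIndex-class] over chromatogram elements.
#' @export
setClass("MzMLController", contains = "MsDataController", representation(
    index = "OffsetIndex", chromIndex = "OffsetIndex"))

#' CachedController: two-tier caching wrapper
#'
#' Wraps any spectra-capable controller with a whole-object LRU hot tier of
#' fixed capacity; entities evicted from the hot tier are re-read on demand
#' through the wrapped controller (or its offset index), so results are
#' content-identical either way. Metadata and id lists are always served
#' whole. Mutable cache state lives in environments so the wrapper itself
#' stays copy-safe.
#'
#' @slot inner the wrapped [MsDataController-class].
#' @slot capacity hot-tier capacity (number of whole objects).
#' @slot hot environment holding the hot tier.
#' @slot state environment holding LRU stamps and [cacheStats()] counters.
#' @export
setClass("CachedController", contains = "MsDataController", representation(
    inner = "MsDataController", capacity = "integer",
    hot = "environment", state = "environment"))

## ---- fixtures -------------------------------------------------------------

#' SyntheticExperiment: a seeded synthetic proteomics experiment
#'
#' Deterministic given its seed; referential closure holds between proteins,
#' peptides, PSMs and spectra; all counts are recorded in the manifest
#' ([writeManifest()]).
#'
#' @slot seed master seed.
#' @slot generatorParams named list of the generator arguments.
#' @slot proteins,peptides,psms,spectra named lists of model objects.
#' @slot proteinOrder,spectrumOrder ids in generation order.
#' @slot metadata [ExperimentMetadata-class] with fixed software, enzyme and
#'   search-database entries.
#' @export
setClass("SyntheticExperiment", representation(
    seed = "integer", generatorParams = "list",
    proteins = "list", proteinOrder = "character",
    peptides = "list", psms = "list",
    spectra = "list", spectrumOrder = "character",
    metadata = "ExperimentMetadata"))
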