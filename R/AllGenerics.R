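## Generics for the uniform controller contract and small shared accessors.

#' @importFrom methods setGeneric setMethod show
NULL

#' Capability queries
#'
#' Controllers advertise three capability groups rather than stubbing a
#' monolithic interface: `spectra`, `identifications` and `quantification`.
#'
#' @param object a [MsDataController-class].
#' @return a logical scalar.
#' @aliases hasSpectra hasIdentifications hasQuantification
#' @export
setGeneric("hasSpectra", function(object) standardGeneric("hasSpectra"))

#' @rdname hasSpectra
#' @export
setGeneric("hasIdentifications",
    function(object) standardGeneric("hasIdentifications"))

#' @rdname hasSpectra
#' @export
setGeneric("hasQuantification",
    function(object) standardGeneric("hasQuantification"))

#' Spectrum access
#'
#' @param object a spectra-capable controller.
#' @param id a spectrum id as returned by `spectrumIds()`.
#' @return `spectrumIds()`: character vector in file order; `getSpectrum()`:
#'   a [Spectrum-class].
#' @aliases spectrumIds getSpectrum
#' @export
setGeneric("spectrumIds", function(object) standardGeneric("spectrumIds"))

#' @rdname spectrumIds
#' @export
setGeneric("getSpectrum", function(object, id) standardGeneric("getSpectrum"))

#' Chromatogram access
#' @param object a controller.
#' @param id chromatogram id.
#' @aliases chromatogramIds getChromatogram
#' @export
setGeneric("chromatogramIds",
    function(object) standardGeneric("chromatogramIds"))

#' @rdname chromatogramIds
#' @export
setGeneric("getChromatogram",
    function(object, id) standardGeneric("getChromatogram"))

#' Identification access
#'
#' The identification hierarchy is protein -> peptide -> PSM.
#' `peptideIds(object, proteinId)` lists the peptides of one protein;
#' `peptideSequence(object, proteinId, peptideId)` is the convenience used to
#' feed the physicochemical calculators.
#'
#' @param object an identification-capable controller.
#' @param id entity id.
#' @param proteinId,peptideId ids within the hierarchy.
#' @aliases proteinIds peptideIds psmIds getProtein getPeptide getPSM
#'   peptideSequence
#' @export
setGeneric("proteinIds", function(object) standardGeneric("proteinIds"))

#' @rdname proteinIds
#' @export
setGeneric("peptideIds",
    function(object, proteinId) standardGeneric("peptideIds"))

#' @rdname proteinIds
#' @export
setGeneric("psmIds", function(object, peptideId) standardGeneric("psmIds"))

#' @rdname proteinIds
#' @export
setGeneric("getProtein", function(object, id) standardGeneric("getProtein"))

#' @rdname proteinIds
#' @export
setGeneric("getPeptide", function(object, id) standardGeneric("getPeptide"))

#' @rdname proteinIds
#' @export
setGeneric("getPSM", function(object, id) standardGeneric("getPSM"))

#' @rdname proteinIds
#' @export
setGeneric("peptideSequence", function(object, proteinId, peptideId)
    standardGeneric("peptideSequence"))

#' Quantification access
#' @param object a quantification-capable controller.
#' @param accession protein accession.
#' @return list of [QuantValue-class].
#' @export
setGeneric("proteinQuant",
    function(object, accession) standardGeneric("proteinQuant"))

#' Experiment metadata of a controller
#' @param object a controller.
#' @return an [ExperimentMetadata-class].
#' @export
setGeneric("experimentMetadata",
    function(object) standardGeneric("experimentMetadata"))

#' Source format tag of a controller
#' @param object a controller.
#' @export
setGeneric("formatTag", function(object) standardGeneric("formatTag"))

## Small shared accessors ----------------------------------------------------

#' Peak and param accessors
#'
#' @param object a model object.
#' @aliases mzValues intensityValues precursorOf paramsOf
#' @export
setGeneric("mzValues", function(object) standardGeneric("mzValues"))

#' @rdname mzValues
#' @export
setGeneric("intensityValues",
    function(object) standardGeneric("intensityValues"))

#' @rdname mzValues
#' @export
setGeneric("precursorOf", function(object) standardGeneric("precursorOf"))

#' @rdname mzValues
#' @export
setGeneric("paramsOf", function(object) standardGeneric("paramsOf"))

#' Look up the first CvParam with a given accession
#'
#' @param object a [ParamGroup-class] (or an object holding one).
#' @param accession ontology accession string.
#' @return a [CvParam-class] or `NULL`.
#' @export
setGeneric("cvParamByAccession", function(object, accession)
    standardGeneric("cvParamByAccession"))

#' Look up the first UserParam with a given name
#' @param object a [ParamGroup-class].
#' @param name parameter name.
#' @return a [UserParam-class] or `NULL`.
#' @export
setGeneric("userParamByName",
    function(object, name) standardGeneric("userParamByName"))
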