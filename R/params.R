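## Constructors and methods for the param/metadata types.

#' Create a CvParam
#'
#' @param cvLabel ontology label (e.g. `"MS"`).
#' @param accession ontology accession (e.g. `"MS:1000744"`).
#' @param name term name.
#' @param value optional value.
#' @param unitAccession,unitName optional unit term.
#' @return a [CvParam-class].
#' @examples
#' CvParam("MS", "MS:1000744", "selected ion m/z", "445.12")
#' @export
CvParam <- function(cvLabel, accession, name, value = NA_character_,
                    unitAccession = NA_character_, unitName = NA_character_) {
    new("CvParam", cvLabel = as.character(cvLabel),
        accession = as.character(accession), name = as.character(name),
        value = if (is.null(value)) NA_character_ else as.character(value),
        unitAccession = as.character(unitAccession),
        unitName = as.character(unitName))
}

#' Create a UserParam
#' @param name parameter name.
#' @param value optional value.
#' @return a [UserParam-class].
#' @export
UserParam <- function(name, value = NA_character_) {
    new("UserParam", name = as.character(name),
        value = if (is.null(value)) NA_character_ else as.character(value))
}

#' Create a ParamGroup
#' @param cvParams list of [CvParam-class].
#' @param userParams list of [UserParam-class].
#' @return a [ParamGroup-class].
#' @export
ParamGroup <- function(cvParams = list(), userParams = list()) {
    new("ParamGroup", cvParams = cvParams, userParams = userParams)
}

#' Create a Precursor
#' @param mz selected-ion m/z (Th).
#' @param charge optional signed integer charge.
#' @param intensity optional intensity.
#' @return a [Precursor-class].
#' @export
Precursor <- function(mz, charge = NA_integer_, intensity = NA_real_) {
    new("Precursor", mz = as.numeric(mz),
        charge = as.integer(charge), intensity = as.numeric(intensity))
}

#' Create a Spectrum
#' @param id spectrum id.
#' @param index 0-based ordinal.
#' @param mz,intensity equal-length peak arrays.
#' @param msLevel MS level.
#' @param precursor optional [Precursor-class].
#' @param params [ParamGroup-class].
#' @return a [Spectrum-class].
#' @export
Spectrum <- function(id, index, mz = numeric(), intensity = numeric(),
                     msLevel = 2L, precursor = NULL, params = ParamGroup()) {
    new("Spectrum", id = as.character(id), index = as.integer(index),
        msLevel = as.integer(msLevel), mz = as.numeric(mz),
        intensity = as.numeric(intensity), precursor = precursor,
        params = params)
}

#' Create a Modification
#' @param accession,name modification identity.
#' @param monoDelta monoisotopic mass delta (Da).
#' @param position 1-based residue position; 0 = N-term, length+1 = C-term.
#' @return a [Modification-class].
#' @export
Modification <- function(accession, name, monoDelta, position) {
    new("Modification", accession = as.character(accession),
        name = as.character(name), monoDelta = as.numeric(monoDelta),
        position = as.integer(position))
}

#' Create a QualityFilter
#'
#' @param requirePassThreshold drop PSMs failing the search threshold.
#' @param maxRank maximum PSM rank kept.
#' @param dropDecoys drop decoy proteins and PSMs.
#' @param minPeptidesPerProtein minimum surviving distinct peptides per
#'   protein.
#' @return a [QualityFilter-class].
#' @export
QualityFilter <- function(requirePassThreshold = TRUE, maxRank = 1L,
                          dropDecoys = TRUE, minPeptidesPerProtein = 1L) {
    new("QualityFilter",
        requirePassThreshold = as.logical(requirePassThreshold),
        maxRank = as.integer(maxRank),
        dropDecoys = as.logical(dropDecoys),
        minPeptidesPerProtein = as.integer(minPeptidesPerProtein))
}

## ---- methods --------------------------------------------------------------

#' @describeIn cvParamByAccession first matching CvParam in a ParamGroup.
#' @export
setMethod("cvParamByAccession", "ParamGroup", function(object, accession) {
    for (p in object@cvParams) if (p@accession == accession) return(p)
    NULL
})

#' @describeIn userParamByName first matching UserParam in a ParamGroup.
#' @export
setMethod("userParamByName", "ParamGroup", function(object, name) {
    for (p in object@userParams) if (p@name == name) return(p)
    NULL
})

#' @describeIn mzValues peak m/z array of a Spectrum.
#' @export
setMethod("mzValues", "Spectrum", function(object) object@mz)

#' @describeIn mzValues peak intensity array of a Spectrum.
#' @export
setMethod("intensityValues", "Spectrum", function(object) object@intensity)

#' @describeIn mzValues precursor of a Spectrum (or NULL).
#' @export
setMethod("precursorOf", "Spectrum", function(object) object@precursor)

#' @describeIn mzValues ParamGroup of a Spectrum.
#' @export
setMethod("paramsOf", "Spectrum", function(object) object@params)

setMethod("show", "CvParam", function(object) {
    cat(sprintf("[%s, %s, %s, %s]\n", object@cvLabel, object@accession,
        object@name, ifelse(is.na(object@value), "", object@value)))
})

setMethod("show", "Spectrum", function(object) {
    cat(sprintf("Spectrum '%s' (index %d, MS%d): %d peaks", object@id,
        object@index, object@msLevel, length(object@mz)))
    if (!is.null(object@precursor))
        cat(sprintf(", precursor m/z %.4f", object@precursor@mz))
    cat("\n")
})

setMethod("show", "ParamGroup", function(object) {
    cat(sprintf("ParamGroup: %d cvParams, %d userParams\n",
        length(object@cvParams), length(object@userParams)))
})

## Content equality used by round-trip tests and the cache transparency
## contract: structural identity of the data model, with numeric arrays
## compared exactly (parsers are expected to be bit-stable).

#' Compare two spectra for content equality
#'
#' @param a,b [Spectrum-class] objects.
#' @param tolerance relative tolerance on the peak arrays (0 = exact).
#' @return logical scalar.
#' @export
spectraEqual <- function(a, b, tolerance = 0) {
    eqNum <- function(x, y) {
        if (length(x) != length(y)) return(FALSE)
        if (!length(x)) return(TRUE)
        if (tolerance == 0) return(isTRUE(all.equal(x, y, tolerance = 1e-12)))
        isTRUE(all.equal(x, y, tolerance = tolerance))
    }
    if (a@id != b@id || a@msLevel != b@msLevel) return(FALSE)
    if (!eqNum(a@mz, b@mz) || !eqNum(a@intensity, b@intensity)) return(FALSE)
    pa <- a@precursor; pb <- b@precursor
    if (is.null(pa) != is.null(pb)) return(FALSE)
    if (!is.null(pa)) {
        if (!eqNum(pa@mz, pb@mz)) return(FALSE)
        if (!identical(pa@charge, pb@charge)) return(FALSE)
    }
    TRUE
}
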