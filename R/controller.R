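## The uniform data-access contract: format detection, openController() and
## the InMemoryController methods. Identifier policy: source-native ids are
## preserved verbatim; formats without ids (dta, pkl) get deterministic
## "index=<0-based ordinal>" ids.

.newInMemoryController <- function(formatTag, path, spectra = list(),
        proteins = list(), peptides = list(), psms = list(),
        metadata = NULL, quant = list()) {
    specIds <- vapply(spectra, function(s) s@id, character(1L))
    names(spectra) <- specIds
    protIds <- vapply(proteins, function(p) p@id, character(1L))
    names(proteins) <- protIds
    names(peptides) <- vapply(peptides, function(p) p@id, character(1L))
    names(psms) <- vapply(psms, function(p) p@id, character(1L))
    if (is.null(metadata))
        metadata <- new("ExperimentMetadata", sourceFormat = formatTag,
            instrument = ParamGroup(), params = ParamGroup())
    new("InMemoryController",
        path = if (file.exists(path)) normalizePath(path) else path,
        formatTag = formatTag, metadata = metadata,
        capabilities = c(spectra = length(spectra) > 0,
            identifications = length(proteins) > 0 || length(psms) > 0,
            quantification = length(quant) > 0),
        spectra = spectra, spectrumOrder = specIds,
        proteins = proteins, proteinOrder = protIds,
        peptides = peptides, psms = psms, quant = quant)
}

## ---- capability and getter methods ----------------------------------------

setMethod("hasSpectra", "MsDataController",
    function(object) unname(object@capabilities["spectra"]))
setMethod("hasIdentifications", "MsDataController",
    function(object) unname(object@capabilities["identifications"]))
setMethod("hasQuantification", "MsDataController",
    function(object) unname(object@capabilities["quantification"]))
setMethod("experimentMetadata", "MsDataController",
    function(object) object@metadata)
setMethod("formatTag", "MsDataController", function(object) object@formatTag)

.needCapability <- function(object, what) {
    if (!isTRUE(unname(object@capabilities[what])))
        .errCond(sprintf("source format '%s' has no %s capability",
            object@formatTag, what), "capabilityError")
    invisible(TRUE)
}

setMethod("spectrumIds", "InMemoryController", function(object) {
    .needCapability(object, "spectra")
    object@spectrumOrder
})

setMethod("getSpectrum", "InMemoryController", function(object, id) {
    .needCapability(object, "spectra")
    sp <- object@spectra[[id]]
    if (is.null(sp))
        .errCond(sprintf("unknown spectrum id '%s'", id), "notFoundError")
    sp
})

setMethod("chromatogramIds", "InMemoryController",
    function(object) character())
setMethod("getChromatogram", "InMemoryController", function(object, id)
    .errCond(sprintf("unknown chromatogram id '%s'", id), "notFoundError"))

setMethod("proteinIds", "InMemoryController", function(object) {
    .needCapability(object, "identifications")
    object@proteinOrder
})

setMethod("getProtein", "InMemoryController", function(object, id) {
    .needCapability(object, "identifications")
    p <- object@proteins[[id]]
    if (is.null(p))
        .errCond(sprintf("unknown protein id '%s'", id), "notFoundError")
    p
})

setMethod("peptideIds", "InMemoryController", function(object, proteinId) {
    getProtein(object, proteinId)@peptideIds
})

setMethod("getPeptide", "InMemoryController", function(object, id) {
    .needCapability(object, "identifications")
    p <- object@peptides[[id]]
    if (is.null(p))
        .errCond(sprintf("unknown peptide id '%s'", id), "notFoundError")
    p
})

setMethod("psmIds", "InMemoryController", function(object, peptideId) {
    getPeptide(object, peptideId)@psmIds
})

setMethod("getPSM", "InMemoryController", function(object, id) {
    .needCapability(object, "identifications")
    p <- object@psms[[id]]
    if (is.null(p))
        .errCond(sprintf("unknown PSM id '%s'", id), "notFoundError")
    p
})

setMethod("peptideSequence", "InMemoryController",
    function(object, proteinId, peptideId) {
        if (!peptideId %in% peptideIds(object, proteinId))
            .errCond(sprintf("peptide '%s' does not belong to protein '%s'",
                peptideId, proteinId), "notFoundError")
        getPeptide(object, peptideId)@sequence
    })

setMethod("proteinQuant", "InMemoryController", function(object, accession) {
    .needCapability(object, "quantification")
    q <- object@quant[[accession]]
    if (is.null(q))
        .errCond(sprintf("no quantification for accession '%s'", accession),
            "notFoundError")
    q
})

setMethod("show", "MsDataController", function(object) {
    caps <- names(object@capabilities)[object@capabilities]
    cat(sprintf("%s over %s file '%s'\n  capabilities: %s\n", class(object),
        object@formatTag, basename(object@path),
        paste(caps, collapse = ", ")))
    if (hasSpectra(object))
        cat(sprintf("  spectra: %d\n", length(spectrumIds(object))))
    if (hasIdentifications(object))
        cat(sprintf("  proteins: %d\n", length(proteinIds(object))))
})

## ---- format detection ------------------------------------------------------

.EXTENSION_MAP <- c(mgf = "mgf", dta = "dta", pkl = "pkl", ms2 = "ms2",
    apl = "apl", mzml = "mzml", mzxml = "mzxml", mzdata = "mzdata",
    mzid = "mzidentml", mzidentml = "mzidentml", xml = NA, mztab = "mztab")

.sniffContent <- function(path) {
    con <- file(path, "rb")
    on.exit(close(con))
    head <- rawToChar(readBin(con, "raw", 4096L))
    lines <- strsplit(head, "\r?\n")[[1]]
    lines <- lines[nzchar(trimws(lines))]
    if (grepl("<indexedmzML|<mzML", head)) return("mzml")
    if (grepl("<mzXML", head)) return("mzxml")
    if (grepl("<ExperimentCollection", head)) return("pridexml")
    if (grepl("<mzData", head)) return("mzdata")
    if (grepl("<MzIdentML|<mzIdentML", head, ignore.case = FALSE))
        return("mzidentml")
    if (any(grepl("^BEGIN IONS", lines))) return("mgf")
    if (any(grepl("^peaklist start", lines))) return("apl")
    if (any(grepl("^MTD\t", lines))) return("mztab")
    if (length(lines) && grepl("^[HSZI][ \t]", lines[[1L]])) return("ms2")
    if (length(lines)) {
        tok <- strsplit(trimws(lines[[1L]]), "[ \t]+")[[1]]
        num <- suppressWarnings(as.numeric(tok))
        if (!anyNA(num) && length(tok) == 3L) return("pkl")
        if (!anyNA(num) && length(tok) == 2L) return("dta")
    }
    NA_character_
}

#' Detect the format of an MS data file
#'
#' Extension first, then content sniffing.
#'
#' @param path file path.
#' @param formatHint optional format tag overriding detection.
#' @return a format tag (see `FORMAT_TAGS`).
#' @export
detectFormat <- function(path, formatHint = NULL) {
    if (!is.null(formatHint)) {
        formatHint <- tolower(formatHint)
        if (!formatHint %in% FORMAT_TAGS)
            .errCond(sprintf("unknown format hint '%s'", formatHint),
                "unsupportedFormatError")
        return(formatHint)
    }
    ext <- tolower(sub("^.*\\.", "", basename(path)))
    tag <- if (ext %in% names(.EXTENSION_MAP)) .EXTENSION_MAP[[ext]]
        else NA_character_
    if (!is.na(tag)) return(tag)
    tag <- .sniffContent(path)
    if (is.na(tag))
        .errCond(sprintf(paste0(
            "cannot detect format of '%s'; tried extension map and content ",
            "detectors (mzml, mzxml, mzdata, mzidentml, pridexml, mgf, apl, ",
            "mztab, ms2, pkl, dta)"), path), "unsupportedFormatError")
    tag
}

#' Open a data-access controller over an MS data file
#'
#' The single entry point of the library: detects the format (unless a hint
#' is given) and returns a controller exposing the uniform contract —
#' capability queries, [spectrumIds()] / [getSpectrum()],
#' [proteinIds()] / [peptideIds()] / [getPSM()], [experimentMetadata()] —
#' independent of the underlying file format.
#'
#' @param path file path.
#' @param formatHint optional format tag; when absent the format is
#'   auto-detected from the extension, then by content sniffing.
#' @return an [MsDataController-class].
#' @examples
#' \dontrun{
#' ctrl <- openController("file.mzid")
#' for (id in proteinIds(ctrl))
#'     for (pepId in peptideIds(ctrl, id))
#'         print(isoelectricPoint(peptideSequence(ctrl, id, pepId)))
#' }
#' @export
openController <- function(path, formatHint = NULL) {
    if (!file.exists(path))
        .errCond(sprintf("cannot read '%s'", path), "ioError")
    tag <- detectFormat(path, formatHint)
    switch(tag,
        mgf = .newInMemoryController("mgf", path, spectra = parseMgf(path)),
        dta = .newInMemoryController("dta", path,
            spectra = list(parseDta(path))),
        pkl = .newInMemoryController("pkl", path, spectra = parsePkl(path)),
        ms2 = {
            res <- .parseMs2Lines(.readTextLines(path))
            .newInMemoryController("ms2", path, spectra = res$spectra,
                metadata = new("ExperimentMetadata", sourceFormat = "ms2",
                    instrument = ParamGroup(),
                    params = ParamGroup(userParams = res$headerParams)))
        },
        apl = .newInMemoryController("apl", path, spectra = parseApl(path)),
        mzml = parseMzML(path),
        mzxml = parseMzXML(path),
        mzdata = parseMzData(path),
        mzidentml = parseMzIdentML(path),
        pridexml = parsePrideXml(path),
        mztab = mzTabToController(parseMzTab(path), path),
        .errCond(sprintf("no controller for format '%s'", tag),
            "unsupportedFormatError"))
}
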