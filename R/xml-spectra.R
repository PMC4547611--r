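## Readers for the XML spectra containers.
##
## Supported subsets (documented, not full schema engines; unknown elements
## are skipped, never an error):
##   mzML 1.1.0   - spectrumList / chromatogramList, binaryDataArray (m/z,
##                  intensity, time), precursor selected ion, instrument and
##                  software cvParams; indexed-mzML wrapper tolerated.
##   mzXML 3.x    - scan elements with base64 peaks (network byte order,
##                  pairOrder/contentType "m/z-int"), precursorMz, msLevel.
##   mzData 1.05  - spectrumList, mzArrayBinary / intenArrayBinary,
##                  precursor ionSelection cvParams (little-endian).
##
## mzML is read lazily: one scan pass records the byte range of every
## spectrum / chromatogram element plus the header, and elements are parsed
## on demand from their slice, so peak memory is bounded by the largest
## single element.

.xmlCvParams <- function(node) {
    kids <- xml2::xml_find_all(node, "./cvParam")
    lapply(kids, function(k) {
        CvParam(
            cvLabel = {
                l <- xml2::xml_attr(k, "cvRef")
                if (is.na(l)) l <- xml2::xml_attr(k, "cvLabel")
                if (is.na(l)) "MS" else l
            },
            accession = xml2::xml_attr(k, "accession"),
            name = xml2::xml_attr(k, "name"),
            value = xml2::xml_attr(k, "value"),
            unitAccession = xml2::xml_attr(k, "unitAccession"),
            unitName = xml2::xml_attr(k, "unitName"))
    })
}

.xmlUserParams <- function(node) {
    kids <- xml2::xml_find_all(node, "./userParam")
    lapply(kids, function(k)
        UserParam(xml2::xml_attr(k, "name"), xml2::xml_attr(k, "value")))
}

.cvValue <- function(params, accession) {
    for (p in params) if (p@accession == accession) return(p@value)
    NA_character_
}

## ---- mzML -----------------------------------------------------------------

.mzmlDecodeArrays <- function(node, id) {
    out <- list()
    for (bda in xml2::xml_find_all(node,
        "./binaryDataArrayList/binaryDataArray")) {
        cvs <- .xmlCvParams(bda)
        acc <- vapply(cvs, function(p) p@accession, character(1L))
        precision <- if ("MS:1000521" %in% acc) 32L else 64L
        if (any(acc %in% c("MS:1002312", "MS:1002313", "MS:1002314")))
            .errCond(sprintf(
                "spectrum '%s': numpress compression is not supported", id),
                "unsupportedFeatureError")
        compressed <- "MS:1000574" %in% acc
        kind <- if ("MS:1000514" %in% acc) "mz"
            else if ("MS:1000515" %in% acc) "intensity"
            else if ("MS:1000595" %in% acc) "time"
            else next
        b64 <- xml2::xml_text(xml2::xml_find_first(bda, "./binary"))
        out[[kind]] <- decodeBinaryArray(b64, precision, compressed,
            endian = "little")
    }
    out
}

.mzmlPrecursorFromNode <- function(node) {
    ion <- xml2::xml_find_first(node,
        "./precursorList/precursor/selectedIonList/selectedIon")
    if (inherits(ion, "xml_missing")) return(NULL)
    cvs <- .xmlCvParams(ion)
    mz <- as.numeric(.cvValue(cvs, "MS:1000744"))
    if (is.na(mz)) return(NULL)
    z <- .cvValue(cvs, "MS:1000041")
    it <- .cvValue(cvs, "MS:1000042")
    Precursor(mz, charge = if (is.na(z)) NA_integer_ else as.integer(z),
        intensity = if (is.na(it)) NA_real_ else as.numeric(it))
}

.mzmlSpectrumFromNode <- function(node, index) {
    xml2::xml_ns_strip(node)
    id <- xml2::xml_attr(node, "id")
    declared <- suppressWarnings(
        as.integer(xml2::xml_attr(node, "defaultArrayLength")))
    cvs <- .xmlCvParams(node)
    msLevel <- as.integer(.cvValue(cvs, "MS:1000511"))
    arrays <- .mzmlDecodeArrays(node, id)
    if (is.null(arrays$mz) || is.null(arrays$intensity))
        .errCond(sprintf(
            "spectrum '%s': required binaryDataArray (m/z or intensity) missing",
            id), "formatError")
    if (!is.na(declared) && length(arrays$mz) != declared)
        .errCond(sprintf(
            "spectrum '%s': %d decoded values but defaultArrayLength=%d",
            id, length(arrays$mz), declared), "formatError")
    Spectrum(id = id, index = index, mz = arrays$mz,
        intensity = arrays$intensity,
        msLevel = if (is.na(msLevel)) 1L else msLevel,
        precursor = .mzmlPrecursorFromNode(node),
        params = ParamGroup(cvs, .xmlUserParams(node)))
}

.mzmlChromFromNode <- function(node, index) {
    xml2::xml_ns_strip(node)
    id <- xml2::xml_attr(node, "id")
    arrays <- .mzmlDecodeArrays(node, id)
    if (is.null(arrays$time) || is.null(arrays$intensity))
        .errCond(sprintf(
            "chromatogram '%s': time or intensity array missing", id),
            "formatError")
    new("Chromatogram", id = id, time = arrays$time,
        intensity = arrays$intensity,
        params = ParamGroup(.xmlCvParams(node), .xmlUserParams(node)))
}

## One pass over the file: header text (everything before the first indexed
## element) plus byte ranges of every <spectrum> and <chromatogram> element.
.scanMzmlLayout <- function(path) {
    env <- new.env(parent = emptyenv())
    env$header <- character(); env$headerDone <- FALSE
    env$sIds <- character(); env$sOff <- numeric(); env$sLen <- numeric()
    env$cIds <- character(); env$cOff <- numeric(); env$cLen <- numeric()
    env$start <- NA_real_; env$id <- NA_character_; env$kind <- ""
    .scanFileLines(path, function(text, offset, nbytes, lineNo) {
        if (!env$headerDone) {
            if (grepl("<(spectrumList|chromatogramList)[ >]", text)) {
                env$headerDone <- TRUE
            } else {
                env$header[length(env$header) + 1L] <- text
                return(invisible(NULL))
            }
        }
        if (is.na(env$start)) {
            open <- regmatches(text, regexec(
                "<(spectrum|chromatogram) [^>]*\\bid=\"([^\"]*)\"", text))[[1]]
            if (length(open) == 3L) {
                env$start <- offset; env$kind <- open[2L]; env$id <- open[3L]
            }
        }
        if (!is.na(env$start)) {
            closeTag <- paste0("</", env$kind, ">")
            if (grepl(closeTag, text, fixed = TRUE)) {
                if (env$kind == "spectrum") {
                    env$sIds[length(env$sIds) + 1L] <- env$id
                    env$sOff[length(env$sOff) + 1L] <- env$start
                    env$sLen[length(env$sLen) + 1L] <-
                        offset + nbytes - env$start
                } else {
                    env$cIds[length(env$cIds) + 1L] <- env$id
                    env$cOff[length(env$cOff) + 1L] <- env$start
                    env$cLen[length(env$cLen) + 1L] <-
                        offset + nbytes - env$start
                }
                env$start <- NA_real_
            }
        }
        invisible(NULL)
    })
    list(header = paste(env$header, collapse = "\n"),
        spectra = data.frame(id = env$sIds, offset = env$sOff,
            length = env$sLen, ordinal = seq_along(env$sIds) - 1L,
            stringsAsFactors = FALSE),
        chromatograms = data.frame(id = env$cIds, offset = env$cOff,
            length = env$cLen, ordinal = seq_along(env$cIds) - 1L,
            stringsAsFactors = FALSE))
}

.extractXmlBlock <- function(text, tag) {
    m <- regmatches(text, regexec(
        sprintf("(?s)<%s[ >].*?</%s>", tag, tag), text, perl = TRUE))[[1]]
    if (length(m)) m[1L] else NULL
}

.mzmlHeaderMetadata <- function(headerText, path) {
    software <- list()
    instrument <- ParamGroup()
    sw <- .extractXmlBlock(headerText, "softwareList")
    if (!is.null(sw)) {
        doc <- xml2::read_xml(sw)
        xml2::xml_ns_strip(doc)
        for (s in xml2::xml_find_all(doc, "./software")) {
            nm <- .cvValue(.xmlCvParams(s), "MS:1000531")
            if (is.na(nm)) nm <- xml2::xml_attr(s, "id")
            software[[length(software) + 1L]] <-
                c(nm, xml2::xml_attr(s, "version"))
        }
    }
    ic <- .extractXmlBlock(headerText, "instrumentConfigurationList")
    if (!is.null(ic)) {
        doc <- xml2::read_xml(ic)
        xml2::xml_ns_strip(doc)
        first <- xml2::xml_find_first(doc, "./instrumentConfiguration")
        if (!inherits(first, "xml_missing"))
            instrument <- ParamGroup(.xmlCvParams(first),
                .xmlUserParams(first))
    }
    new("ExperimentMetadata", title = NA_character_, sourceFormat = "mzml",
        instrument = instrument,
        protocols = list(new("ProteinDetectionProtocol",
            software = software)),
        contacts = list(), params = ParamGroup())
}

#' Open an mzML file with the lazy, offset-indexed reader
#'
#' One streaming pass records the header metadata and the byte range of
#' every `spectrum` and `chromatogram` element; elements are parsed on
#' demand from their byte slice, so memory stays bounded by the largest
#' single element. Spectrum and precursor cvParams are copied verbatim into
#' the model. The indexed-mzML wrapper is tolerated.
#'
#' @param path mzML file.
#' @return an [MzMLController-class] with the spectra capability.
#' @export
parseMzML <- function(path) {
    layout <- .scanMzmlLayout(path)
    checksum <- unname(tools::md5sum(path))
    size <- file.size(path)
    norm <- normalizePath(path)
    new("MzMLController", path = norm, formatTag = "mzml",
        metadata = .mzmlHeaderMetadata(layout$header, path),
        capabilities = c(spectra = TRUE, identifications = FALSE,
            quantification = FALSE),
        index = new("OffsetIndex", formatTag = "mzml", sourcePath = norm,
            checksum = checksum, fileSize = size, entries = layout$spectra),
        chromIndex = new("OffsetIndex", formatTag = "mzml",
            sourcePath = norm, checksum = checksum, fileSize = size,
            entries = layout$chromatograms))
}

setMethod("spectrumIds", "MzMLController",
    function(object) object@index@entries$id)

setMethod("getSpectrum", "MzMLController", function(object, id) {
    e <- object@index@entries[object@index@entries$id == id, ]
    if (nrow(e) != 1L)
        .errCond(sprintf("unknown spectrum id '%s'", id), "notFoundError")
    .verifyIndexFresh(object@index)
    node <- xml2::read_xml(.sliceText(object@path, e$offset, e$length))
    .mzmlSpectrumFromNode(node, e$ordinal[[1L]])
})

setMethod("chromatogramIds", "MzMLController",
    function(object) object@chromIndex@entries$id)

setMethod("getChromatogram", "MzMLController", function(object, id) {
    e <- object@chromIndex@entries[object@chromIndex@entries$id == id, ]
    if (nrow(e) != 1L)
        .errCond(sprintf("unknown chromatogram id '%s'", id),
            "notFoundError")
    .verifyIndexFresh(object@chromIndex)
    node <- xml2::read_xml(.sliceText(object@path, e$offset, e$length))
    .mzmlChromFromNode(node, e$ordinal[[1L]])
})

## ---- mzXML ----------------------------------------------------------------

.mzxmlScanToSpectrum <- function(node, index) {
    id <- xml2::xml_attr(node, "num")
    msLevel <- suppressWarnings(as.integer(xml2::xml_attr(node, "msLevel")))
    peaks <- xml2::xml_find_first(node, "./peaks")
    if (inherits(peaks, "xml_missing"))
        .errCond(sprintf("scan '%s': peaks element missing", id),
            "formatError")
    pairOrder <- xml2::xml_attr(peaks, "pairOrder")
    if (is.na(pairOrder)) pairOrder <- xml2::xml_attr(peaks, "contentType")
    if (!is.na(pairOrder) && pairOrder != "m/z-int")
        .errCond(sprintf("scan '%s': unsupported pairOrder '%s'",
            id, pairOrder), "formatError")
    byteOrder <- xml2::xml_attr(peaks, "byteOrder")
    endian <- if (!is.na(byteOrder) && byteOrder != "network")
        "little" else "big"
    precision <- suppressWarnings(
        as.integer(xml2::xml_attr(peaks, "precision")))
    if (is.na(precision)) precision <- 32L
    comp <- xml2::xml_attr(peaks, "compressionType")
    declared <- suppressWarnings(
        as.integer(xml2::xml_attr(node, "peaksCount")))
    vals <- decodeBinaryArray(xml2::xml_text(peaks), precision,
        compressed = !is.na(comp) && comp == "zlib", endian = endian,
        expectedLength = if (is.na(declared)) NULL else declared * 2L)
    odd <- seq_len(length(vals) / 2L) * 2L - 1L
    prec <- NULL
    pmzNode <- xml2::xml_find_first(node, "./precursorMz")
    if (!inherits(pmzNode, "xml_missing")) {
        z <- suppressWarnings(
            as.integer(xml2::xml_attr(pmzNode, "precursorCharge")))
        pint <- suppressWarnings(
            as.numeric(xml2::xml_attr(pmzNode, "precursorIntensity")))
        prec <- Precursor(as.numeric(xml2::xml_text(pmzNode)), z, pint)
    }
    Spectrum(id = id, index = index, mz = vals[odd],
        intensity = vals[odd + 1L],
        msLevel = if (is.na(msLevel)) 1L else msLevel, precursor = prec)
}

#' Parse an mzXML file
#'
#' Supported subset: `scan` elements with base64 `peaks` (network byte
#' order, interleaved m/z-intensity pairs), `precursorMz` and `msLevel`.
#' The scan number becomes the spectrum id.
#'
#' @param path mzXML file.
#' @return an [InMemoryController-class] with the spectra capability.
#' @export
parseMzXML <- function(path) {
    doc <- xml2::read_xml(path)
    xml2::xml_ns_strip(doc)
    nodes <- xml2::xml_find_all(doc, "//scan")
    spectra <- lapply(seq_along(nodes), function(i)
        .mzxmlScanToSpectrum(nodes[[i]], i - 1L))
    .newInMemoryController("mzxml", path, spectra = spectra,
        metadata = new("ExperimentMetadata", sourceFormat = "mzxml",
            instrument = ParamGroup(), params = ParamGroup()))
}

## ---- mzData ---------------------------------------------------------------

.mzdataArray <- function(node, what, id) {
    data <- xml2::xml_find_first(node, sprintf("./%s/data", what))
    if (inherits(data, "xml_missing"))
        .errCond(sprintf("spectrum '%s': %s missing", id, what),
            "formatError")
    precision <- suppressWarnings(
        as.integer(xml2::xml_attr(data, "precision")))
    endian <- xml2::xml_attr(data, "endian")
    declared <- suppressWarnings(as.integer(xml2::xml_attr(data, "length")))
    decodeBinaryArray(xml2::xml_text(data),
        if (is.na(precision)) 64L else precision, compressed = FALSE,
        endian = if (!is.na(endian) && endian == "big") "big" else "little",
        expectedLength = if (is.na(declared)) NULL else declared)
}

.mzdataSpectrumFromNode <- function(node, index) {
    id <- xml2::xml_attr(node, "id")
    msLevel <- suppressWarnings(as.integer(xml2::xml_attr(
        xml2::xml_find_first(node,
            ".//spectrumSettings/spectrumInstrument"), "msLevel")))
    prec <- NULL
    ion <- xml2::xml_find_first(node, ".//precursorList/precursor/ionSelection")
    if (!inherits(ion, "xml_missing")) {
        cvs <- .xmlCvParams(ion)
        byName <- function(nm) {
            for (p in cvs) if (p@name == nm) return(p@value)
            NA_character_
        }
        mz <- as.numeric(byName("MassToChargeRatio"))
        if (!is.na(mz)) {
            z <- byName("ChargeState")
            prec <- Precursor(mz,
                charge = if (is.na(z)) NA_integer_ else as.integer(z))
        }
    }
    mzArr <- .mzdataArray(node, "mzArrayBinary", id)
    intArr <- .mzdataArray(node, "intenArrayBinary", id)
    Spectrum(id = id, index = index, mz = mzArr, intensity = intArr,
        msLevel = if (is.na(msLevel)) 2L else msLevel, precursor = prec)
}

.mzdataSpectraFromDoc <- function(root) {
    nodes <- xml2::xml_find_all(root, ".//spectrumList/spectrum")
    lapply(seq_along(nodes), function(i)
        .mzdataSpectrumFromNode(nodes[[i]], i - 1L))
}

#' Parse an mzData file
#'
#' Supported subset: `spectrumList` with `mzArrayBinary` /
#' `intenArrayBinary` (little-endian by convention) and precursor
#' `ionSelection` cvParams.
#'
#' @param path mzData file.
#' @return an [InMemoryController-class] with the spectra capability.
#' @export
parseMzData <- function(path) {
    doc <- xml2::read_xml(path)
    xml2::xml_ns_strip(doc)
    .newInMemoryController("mzdata", path,
        spectra = .mzdataSpectraFromDoc(doc),
        metadata = new("ExperimentMetadata", sourceFormat = "mzdata",
            instrument = ParamGroup(), params = ParamGroup()))
}
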