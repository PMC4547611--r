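## Byte-offset indexing: the cold tier of the cache design. Entities that are
## not held as whole objects are remembered as [offset, length) ranges in the
## source file and re-parsed from that slice alone on demand.
##
## Framed formats (random-access capable): mgf blocks, pkl blocks, ms2
## S-records, apl blocks, mzML <spectrum> elements. dta is a single-spectrum
## format and has no framing.

.FRAMED_FORMATS <- c("mgf", "pkl", "ms2", "apl", "mzml")

#' Build a byte-offset index over a framed file
#'
#' For every entity id the index records the byte range whose slice, parsed
#' alone, yields a [Spectrum-class] content-equal to the sequential parse.
#' The source content hash is embedded so later access fails loudly if the
#' file changed ([fetchByOffset()]).
#'
#' @param path source file.
#' @param formatTag one of `mgf`, `pkl`, `ms2`, `apl`, `mzml`.
#' @return an [OffsetIndex-class].
#' @export
buildOffsetIndex <- function(path, formatTag) {
    if (!formatTag %in% .FRAMED_FORMATS)
        .errCond(sprintf(
            "format '%s' has no random-access framing", formatTag),
            "unsupportedFeatureError")
    ids <- character(); offs <- numeric(); lens <- numeric()
    env <- new.env(parent = emptyenv())
    env$start <- NA_real_; env$id <- NULL; env$n <- 0L
    openEntry <- function(offset, id = NULL) {
        env$start <- offset; env$id <- id
    }
    closeEntry <- function(endOffset) {
        if (is.na(env$start)) return()
        id <- if (is.null(env$id)) sprintf("index=%d", env$n) else env$id
        ids[length(ids) + 1L] <<- id
        offs[length(offs) + 1L] <<- env$start
        lens[length(lens) + 1L] <<- endOffset - env$start
        env$start <- NA_real_; env$id <- NULL; env$n <- env$n + 1L
    }
    lineFun <- switch(formatTag,
        mgf = function(text, offset, nbytes, lineNo) {
            t <- trimws(text)
            if (t == "BEGIN IONS") openEntry(offset)
            else if (t == "END IONS") closeEntry(offset + nbytes)
            else if (!is.na(env$start) && is.null(env$id) &&
                     startsWith(text, "TITLE="))
                env$id <- sub("^TITLE=", "", text)
        },
        pkl = function(text, offset, nbytes, lineNo) {
            if (nzchar(trimws(text))) {
                if (is.na(env$start)) openEntry(offset)
                env$last <- offset + nbytes
            } else closeEntry(if (is.null(env$last)) offset else env$last)
        },
        ms2 = function(text, offset, nbytes, lineNo) {
            tag <- substr(text, 1L, 1L)
            if (tag == "S") {
                closeEntry(offset)
                tok <- strsplit(trimws(text), "[ \t]+")[[1]]
                openEntry(offset, if (length(tok) > 1L) tok[2L] else NULL)
            }
            env$last <- offset + nbytes
        },
        apl = function(text, offset, nbytes, lineNo) {
            t <- trimws(text)
            if (t == "peaklist start") openEntry(offset)
            else if (t == "peaklist end") closeEntry(offset + nbytes)
            else if (!is.na(env$start) && startsWith(t, "header="))
                env$id <- sub("^header=", "", t)
        },
        mzml = function(text, offset, nbytes, lineNo) {
            if (grepl("<spectrum[ >]", text, fixed = FALSE)) {
                m <- regmatches(text,
                    regexec("<spectrum[^>]*\\bid=\"([^\"]*)\"", text))[[1]]
                openEntry(offset, if (length(m) == 2L) m[2L] else NULL)
            }
            if (grepl("</spectrum>", text, fixed = TRUE))
                closeEntry(offset + nbytes)
        })
    .scanFileLines(path, lineFun)
    ## pkl/ms2: final entry closed at EOF
    if (formatTag %in% c("pkl", "ms2") && !is.na(env$start))
        closeEntry(env$last)
    entries <- data.frame(id = ids, offset = offs, length = lens,
        ordinal = seq_along(ids) - 1L, stringsAsFactors = FALSE)
    new("OffsetIndex", formatTag = formatTag,
        sourcePath = normalizePath(path),
        checksum = unname(tools::md5sum(path)),
        fileSize = file.size(path), entries = entries)
}

## Staleness guard: re-hash only when mtime or size changed since the last
## verification, so repeated random access stays cheap while modification of
## the source is still caught (a changed file changes its mtime).
.verifyIndexFresh <- function(index) {
    path <- index@sourcePath
    info <- file.info(path)
    if (is.na(info$size))
        .errCond(sprintf("indexed source '%s' no longer exists", path),
            "staleIndexError")
    key <- paste0("fresh:", path)
    memo <- .paCache[[key]]
    sig <- paste(info$size, format(info$mtime, "%Y%m%d%H%M%OS6"))
    if (!is.null(memo) && identical(memo$sig, sig) &&
        identical(memo$checksum, index@checksum)) return(invisible(TRUE))
    sum <- unname(tools::md5sum(path))
    if (!identical(sum, index@checksum))
        .errCond(sprintf(
            "source '%s' changed since indexing (checksum mismatch)", path),
            "staleIndexError")
    .paCache[[key]] <- list(sig = sig, checksum = sum)
    invisible(TRUE)
}

#' Fetch one entity by slice-parsing its byte range
#'
#' Verifies the source checksum, reads only `[offset, offset + length)` and
#' parses that slice with the format's block parser.
#'
#' @param index an [OffsetIndex-class].
#' @param id entity id present in the index.
#' @return a [Spectrum-class].
#' @export
fetchByOffset <- function(index, id) {
    .verifyIndexFresh(index)
    e <- index@entries[index@entries$id == id, ]
    if (nrow(e) != 1L)
        .errCond(sprintf("id '%s' not in offset index", id), "notFoundError")
    ord <- e$ordinal[[1L]]
    if (index@formatTag == "mzml") {
        node <- xml2::read_xml(.sliceText(index@sourcePath, e$offset, e$length))
        return(.mzmlSpectrumFromNode(node, ord))
    }
    lines <- .sliceLines(index@sourcePath, e$offset, e$length)
    sp <- switch(index@formatTag,
        mgf = .parseMgfLines(lines, baseIndex = ord),
        pkl = .parsePklLines(lines, baseIndex = ord),
        ms2 = .parseMs2Lines(lines, baseIndex = ord)$spectra,
        apl = .parseAplLines(lines, baseIndex = ord))
    sp[[1L]]
}

#' Persist / load an offset index sidecar
#'
#' The sidecar is a small JSON document keyed by the source checksum; loading
#' against a changed source fails with a checksum error at first use.
#'
#' @param index an [OffsetIndex-class].
#' @param path sidecar file path.
#' @return `readOffsetIndex()` returns the [OffsetIndex-class].
#' @export
writeOffsetIndex <- function(index, path) {
    jsonlite::write_json(list(
        format_tag = index@formatTag, source_path = index@sourcePath,
        checksum = index@checksum, file_size = index@fileSize,
        entries = index@entries), path, auto_unbox = TRUE, digits = NA)
    invisible(path)
}

#' @rdname writeOffsetIndex
#' @export
readOffsetIndex <- function(path) {
    x <- jsonlite::read_json(path, simplifyVector = TRUE)
    e <- as.data.frame(x$entries, stringsAsFactors = FALSE)
    e$offset <- as.numeric(e$offset)
    e$length <- as.numeric(e$length)
    e$ordinal <- as.integer(e$ordinal)
    new("OffsetIndex", formatTag = x$format_tag, sourcePath = x$source_path,
        checksum = x$checksum, fileSize = as.numeric(x$file_size),
        entries = e)
}
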