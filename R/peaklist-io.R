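## Readers for the text peak-list formats (mgf, dta, pkl, ms2, apl) and the
## mgf writer. All parsers:
##   - accept \n and \r\n, UTF-8 with ASCII-compatible fallback;
##   - preserve zero-intensity peaks (filtering is the caller's job);
##   - return spectra in file order with Spectrum@index == ordinal;
##   - raise parse errors carrying the 1-based line number.
## dta holds a single spectrum (classic SEQUEST); concatenated dta is out of
## scope. Only mgf has a writer; the other text formats are read-only.

.readTextLines <- function(path) {
    con <- file(path, "r", encoding = "UTF-8")
    on.exit(close(con))
    sub("\r$", "", readLines(con, warn = FALSE))
}

.parseError <- function(lineNo, msg) {
    stop(errorCondition(
        sprintf("parse error at line %d: %s", lineNo, msg),
        line = lineNo, class = c("parseError", "proteoAccessError")))
}

.parsePeakLine <- function(line, lineNo) {
    tok <- strsplit(trimws(line), "[ \t]+")[[1]]
    if (length(tok) < 2L)
        .parseError(lineNo, "peak line needs at least m/z and intensity")
    vals <- suppressWarnings(as.numeric(tok[1:2]))
    if (anyNA(vals))
        .parseError(lineNo, sprintf("non-numeric peak line '%s'", line))
    vals
}

.numericOr <- function(x, lineNo, what) {
    v <- suppressWarnings(as.numeric(x))
    if (is.na(v)) .parseError(lineNo, sprintf("non-numeric %s '%s'", what, x))
    v
}

## shortest decimal representation that round-trips the double exactly
.fmtShortest <- function(x) {
    vapply(x, function(v) {
        for (d in c(1L, 6L, 9L, 12L, 15L, 17L)) {
            s <- sprintf("%.*g", d, v)
            if (as.numeric(s) == v) return(s)
        }
        sprintf("%.17g", v)
    }, character(1L))
}

.parseMgfCharge <- function(text) {
    ## "2+", "3-", bare "2", or a list like "2+ and 3+": first value kept
    first <- strsplit(trimws(text), "[, ]+")[[1]][1L]
    m <- regmatches(first, regexec("^([0-9]+)([+-]?)$", first))[[1]]
    if (length(m) == 0L) return(NA_integer_)
    z <- as.integer(m[2L])
    if (m[3L] == "-") z <- -z
    z
}

## mgf block body -> Spectrum; `lines` excludes BEGIN/END IONS lines
.mgfBlockToSpectrum <- function(lines, lineNos, index) {
    id <- NULL; pmz <- NA_real_; pint <- NA_real_; charge <- NA_integer_
    cvs <- list(); ups <- list()
    mz <- numeric(); int <- numeric()
    for (k in seq_along(lines)) {
        line <- lines[[k]]
        if (!nzchar(trimws(line)) || startsWith(line, "#")) next
        if (grepl("^[A-Za-z_]+=", line)) {
            key <- sub("=.*$", "", line)
            val <- sub("^[A-Za-z_]+=", "", line)
            if (key == "TITLE") {
                id <- val
            } else if (key == "PEPMASS") {
                tok <- strsplit(trimws(val), "[ \t]+")[[1]]
                pmz <- .numericOr(tok[1L], lineNos[[k]], "PEPMASS")
                if (length(tok) > 1L)
                    pint <- .numericOr(tok[2L], lineNos[[k]],
                        "PEPMASS intensity")
            } else if (key == "CHARGE") {
                charge <- .parseMgfCharge(val)
                if (is.na(charge))
                    .parseError(lineNos[[k]],
                        sprintf("unparseable CHARGE '%s'", val))
                if (grepl("[, ]", trimws(val)))   # charge list: keep raw too
                    ups <- c(ups, list(UserParam("CHARGE_raw", val)))
            } else {
                p <- mapCvTerm("mgf", key, val)
                if (is(p, "CvParam")) cvs <- c(cvs, list(p))
                else ups <- c(ups, list(p))
            }
        } else {
            vals <- .parsePeakLine(line, lineNos[[k]])
            mz <- c(mz, vals[1L]); int <- c(int, vals[2L])
        }
    }
    prec <- if (!is.na(pmz)) Precursor(pmz, charge, pint) else NULL
    Spectrum(id = if (is.null(id)) sprintf("index=%d", index) else id,
        index = index, mz = mz, intensity = int,
        msLevel = if (is.null(prec)) 1L else 2L, precursor = prec,
        params = ParamGroup(cvs, ups))
}

.parseMgfLines <- function(lines, lineOffset = 0L, baseIndex = 0L) {
    spectra <- list()
    inBlock <- FALSE
    blk <- character(); blkNos <- integer()
    for (i in seq_along(lines)) {
        line <- lines[[i]]; lineNo <- lineOffset + i
        t <- trimws(line)
        if (t == "BEGIN IONS") {
            if (inBlock) .parseError(lineNo, "nested BEGIN IONS")
            inBlock <- TRUE; blk <- character(); blkNos <- integer()
        } else if (t == "END IONS") {
            if (!inBlock) .parseError(lineNo, "END IONS without BEGIN IONS")
            spectra[[length(spectra) + 1L]] <- .mgfBlockToSpectrum(
                blk, blkNos, baseIndex + length(spectra))
            inBlock <- FALSE
        } else if (inBlock) {
            blk <- c(blk, line); blkNos <- c(blkNos, lineNo)
        }
        ## content outside blocks (comments, junk) is skipped
    }
    if (inBlock)
        .parseError(lineOffset + length(lines), "BEGIN IONS without END IONS")
    spectra
}

#' Parse a Mascot Generic Format (mgf) file
#'
#' One [Spectrum-class] per `BEGIN IONS`/`END IONS` block. `TITLE` becomes
#' the spectrum id (a deterministic `index=<ordinal>` id is synthesised when
#' absent); the first `PEPMASS` token is the precursor m/z and an optional
#' second token its intensity; `CHARGE` accepts `2+` / `3-` style (charge
#' lists keep the first value and retain the raw string as a userParam).
#' Blank lines and `#` comments are skipped.
#'
#' @param path mgf file path.
#' @return list of [Spectrum-class] in file order.
#' @export
parseMgf <- function(path) .parseMgfLines(.readTextLines(path))

#' Write spectra as Mascot Generic Format
#'
#' Floats are written in shortest-round-trip form, so output re-parses to
#' content-equal spectra. A spectrum without a precursor is written without
#' a `PEPMASS` line (an MS1-style block).
#'
#' @param spectra list of [Spectrum-class].
#' @param path output path.
#' @export
writeMgf <- function(spectra, path) {
    out <- character()
    for (s in spectra) {
        out <- c(out, "BEGIN IONS", paste0("TITLE=", s@id))
        p <- s@precursor
        if (!is.null(p)) {
            pm <- paste0("PEPMASS=", .fmtShortest(p@mz))
            if (!is.na(p@intensity))
                pm <- paste(pm, .fmtShortest(p@intensity))
            out <- c(out, pm)
            if (!is.na(p@charge))
                out <- c(out, sprintf("CHARGE=%d%s", abs(p@charge),
                    if (p@charge < 0) "-" else "+"))
        }
        if (length(s@mz))
            out <- c(out, paste(.fmtShortest(s@mz),
                .fmtShortest(s@intensity)))
        out <- c(out, "END IONS", "")
    }
    writeLines(out, path)
}

## ---- dta ------------------------------------------------------------------

.PROTON_MASS <- 1.007276

#' Parse a SEQUEST dta file (one spectrum)
#'
#' The header line holds the singly protonated mass (M+H) and the charge;
#' the precursor m/z is recovered as `(MH + (z - 1) * m_proton) / z` with
#' `m_proton = 1.007276` Da. The M+H provenance is recorded as a
#' `precursor_is_mh` userParam.
#'
#' @param path dta file path.
#' @param spectrumIndex ordinal assigned to the spectrum (ids are
#'   synthesised as `index=<ordinal>` since dta carries none).
#' @return a single [Spectrum-class].
#' @export
parseDta <- function(path, spectrumIndex = 0L) {
    lines <- .readTextLines(path)
    body <- which(nzchar(trimws(lines)))
    if (!length(body)) .parseError(1L, "empty dta file")
    h <- body[1L]
    tok <- strsplit(trimws(lines[[h]]), "[ \t]+")[[1]]
    if (length(tok) != 2L)
        .parseError(h, sprintf("dta header needs 2 tokens, got %d",
            length(tok)))
    mh <- .numericOr(tok[1L], h, "M+H mass")
    z <- as.integer(.numericOr(tok[2L], h, "charge"))
    mz <- numeric(); int <- numeric()
    for (i in body[-1L]) {
        vals <- .parsePeakLine(lines[[i]], i)
        mz <- c(mz, vals[1L]); int <- c(int, vals[2L])
    }
    Spectrum(id = sprintf("index=%d", spectrumIndex), index = spectrumIndex,
        mz = mz, intensity = int, msLevel = 2L,
        precursor = Precursor((mh + (z - 1L) * .PROTON_MASS) / z, z),
        params = ParamGroup(userParams = list(
            UserParam("precursor_is_mh", "true"),
            UserParam("dta_mh", .fmtShortest(mh)))))
}

## ---- pkl ------------------------------------------------------------------

.pklBlockToSpectrum <- function(lines, lineNos, index) {
    tok <- strsplit(trimws(lines[[1L]]), "[ \t]+")[[1]]
    if (length(tok) != 3L)
        .parseError(lineNos[[1L]],
            sprintf("pkl header needs 3 tokens, got %d", length(tok)))
    pmz <- .numericOr(tok[1L], lineNos[[1L]], "precursor m/z")
    pint <- .numericOr(tok[2L], lineNos[[1L]], "precursor intensity")
    z <- as.integer(.numericOr(tok[3L], lineNos[[1L]], "charge"))
    mz <- numeric(); int <- numeric()
    for (k in seq_along(lines)[-1L]) {
        vals <- .parsePeakLine(lines[[k]], lineNos[[k]])
        mz <- c(mz, vals[1L]); int <- c(int, vals[2L])
    }
    Spectrum(id = sprintf("index=%d", index), index = index, mz = mz,
        intensity = int, msLevel = 2L, precursor = Precursor(pmz, z, pint))
}

.parsePklLines <- function(lines, lineOffset = 0L, baseIndex = 0L) {
    spectra <- list()
    blk <- character(); blkNos <- integer()
    flush <- function() {
        if (length(blk)) {
            spectra[[length(spectra) + 1L]] <<- .pklBlockToSpectrum(
                blk, blkNos, baseIndex + length(spectra))
            blk <<- character(); blkNos <<- integer()
        }
    }
    for (i in seq_along(lines)) {
        line <- lines[[i]]
        if (!nzchar(trimws(line))) flush()
        else { blk <- c(blk, line); blkNos <- c(blkNos, lineOffset + i) }
    }
    flush()
    spectra
}

#' Parse a Micromass pkl file
#'
#' Blank-line separated blocks; each block header is
#' `<precursor m/z> <intensity> <charge>` followed by peak lines. Ids are
#' synthesised as `index=<ordinal>`.
#'
#' @param path pkl file path.
#' @return list of [Spectrum-class] in file order.
#' @export
parsePkl <- function(path) .parsePklLines(.readTextLines(path))

## ---- ms2 ------------------------------------------------------------------

.parseMs2Lines <- function(lines, lineOffset = 0L, baseIndex = 0L) {
    spectra <- list(); header <- list()
    cur <- NULL
    flush <- function() {
        if (is.null(cur)) return()
        spectra[[length(spectra) + 1L]] <<- Spectrum(
            id = cur$id, index = baseIndex + length(spectra), mz = cur$mz,
            intensity = cur$int, msLevel = 2L,
            precursor = Precursor(cur$pmz, cur$charge),
            params = ParamGroup(cur$cvs, cur$ups))
        cur <<- NULL
    }
    for (i in seq_along(lines)) {
        line <- lines[[i]]; lineNo <- lineOffset + i
        if (!nzchar(trimws(line))) next
        tag <- substr(line, 1L, 1L)
        tok <- strsplit(trimws(line), "[ \t]+")[[1]]
        if (tag == "H") {
            header[[length(header) + 1L]] <- UserParam(
                if (length(tok) > 1L) tok[2L] else "H",
                paste(tok[-(1:2)], collapse = " "))
        } else if (tag == "S") {
            if (length(tok) < 4L)
                .parseError(lineNo, "S line needs scan numbers and m/z")
            flush()
            cur <- list(id = tok[2L],
                pmz = .numericOr(tok[4L], lineNo, "precursor m/z"),
                charge = NA_integer_, mz = numeric(), int = numeric(),
                cvs = list(), ups = list())
        } else if (tag == "Z") {
            if (is.null(cur)) .parseError(lineNo, "Z line before first S")
            z <- as.integer(.numericOr(tok[2L], lineNo, "charge"))
            if (is.na(cur$charge)) cur$charge <- z
            cur$cvs <- c(cur$cvs,
                list(mapCvTerm("ms2", "Z", tok[2L])))
            if (length(tok) > 2L)
                cur$ups <- c(cur$ups, list(UserParam(
                    sprintf("Z_mh_z%s", tok[2L]), tok[3L])))
        } else if (tag == "I") {
            if (is.null(cur)) .parseError(lineNo, "I line before first S")
            cur$ups <- c(cur$ups, list(UserParam(tok[2L],
                paste(tok[-(1:2)], collapse = " "))))
        } else {
            if (is.null(cur)) .parseError(lineNo, "peak line before first S")
            vals <- .parsePeakLine(line, lineNo)
            cur$mz <- c(cur$mz, vals[1L]); cur$int <- c(cur$int, vals[2L])
        }
    }
    flush()
    list(spectra = spectra, headerParams = header)
}

#' Parse an ms2 file
#'
#' `S` lines start spectra (scan number becomes the id, the fourth field the
#' precursor m/z); the first `Z` line supplies the charge and every `Z` line
#' is retained as a charge-state cvParam; `I` lines become per-spectrum
#' userParams. File-level `H` lines surface as experiment metadata when the
#' file is opened through [openController()].
#'
#' @param path ms2 file path.
#' @return list of [Spectrum-class] in file order.
#' @export
parseMs2 <- function(path) .parseMs2Lines(.readTextLines(path))$spectra

## ---- apl ------------------------------------------------------------------

.parseAplLines <- function(lines, lineOffset = 0L, baseIndex = 0L) {
    spectra <- list()
    cur <- NULL
    for (i in seq_along(lines)) {
        line <- trimws(lines[[i]]); lineNo <- lineOffset + i
        if (!nzchar(line)) next
        if (line == "peaklist start") {
            if (!is.null(cur)) .parseError(lineNo, "nested peaklist start")
            cur <- list(id = NULL, pmz = NA_real_, charge = NA_integer_,
                mz = numeric(), int = numeric(), cvs = list(), ups = list())
        } else if (line == "peaklist end") {
            if (is.null(cur))
                .parseError(lineNo, "peaklist end without matching start")
            idx <- baseIndex + length(spectra)
            prec <- if (!is.na(cur$pmz))
                Precursor(cur$pmz, cur$charge) else NULL
            spectra[[length(spectra) + 1L]] <- Spectrum(
                id = if (is.null(cur$id)) sprintf("index=%d", idx) else cur$id,
                index = idx, mz = cur$mz, intensity = cur$int, msLevel = 2L,
                precursor = prec, params = ParamGroup(cur$cvs, cur$ups))
            cur <- NULL
        } else if (is.null(cur)) {
            .parseError(lineNo, "content outside peaklist block")
        } else if (grepl("^[A-Za-z_]+=", line)) {
            key <- sub("=.*$", "", line)
            val <- sub("^[A-Za-z_]+=", "", line)
            if (key == "header") cur$id <- val
            else if (key == "mz") cur$pmz <- .numericOr(val, lineNo, "mz")
            else if (key == "charge")
                cur$charge <- as.integer(.numericOr(val, lineNo, "charge"))
            else cur$ups <- c(cur$ups, list(UserParam(key, val)))
        } else {
            vals <- .parsePeakLine(line, lineNo)
            cur$mz <- c(cur$mz, vals[1L]); cur$int <- c(cur$int, vals[2L])
        }
    }
    if (!is.null(cur))
        .parseError(lineOffset + length(lines),
            "peaklist start without matching end")
    spectra
}

#' Parse a MaxQuant Andromeda apl file
#'
#' `peaklist start` / `peaklist end` blocks with `key=value` header lines:
#' `header` becomes the spectrum id, `mz` the precursor m/z and `charge` the
#' precursor charge; unknown header keys are preserved as userParams.
#'
#' @param path apl file path.
#' @return list of [Spectrum-class] in file order.
#' @export
parseApl <- function(path) .parseAplLines(.readTextLines(path))
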