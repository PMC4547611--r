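## Chunked line scanner: visits a file line by line while tracking byte
## offsets, holding at most one chunk (plus a partial-line carry) in memory.
## This backs both the offset indexer and the bounded-memory mzML reader.

.errCond <- function(msg, class) {
    stop(errorCondition(msg, class = c(class, "proteoAccessError")))
}

## lineFun(text, offset, nbytes, lineNo): text without the line terminator,
## offset = 0-based byte offset of the line start, nbytes includes the
## terminator. Returns nothing; stop scanning is not supported (files are
## scanned once, fully).
.scanFileLines <- function(path, lineFun, chunkSize = 262144L) {
    con <- file(path, "rb")
    on.exit(close(con))
    bufStart <- 0
    carry <- raw(0)
    lineNo <- 0L
    nlByte <- as.raw(10L)
    repeat {
        chunk <- readBin(con, "raw", chunkSize)
        eof <- length(chunk) < chunkSize
        buf <- c(carry, chunk)
        if (!length(buf)) break
        nl <- which(buf == nlByte)
        start <- 1L
        for (p in nl) {
            lineNo <- lineNo + 1L
            text <- rawToChar(buf[start:p])
            lineFun(sub("\r?\n$", "", text), bufStart + start - 1,
                p - start + 1L, lineNo)
            start <- p + 1L
        }
        if (eof) {
            if (start <= length(buf)) {
                lineNo <- lineNo + 1L
                text <- sub("\r$", "", rawToChar(buf[start:length(buf)]))
                lineFun(text, bufStart + start - 1,
                    length(buf) - start + 1L, lineNo)
            }
            break
        }
        carry <- if (start <= length(buf)) buf[start:length(buf)] else raw(0)
        bufStart <- bufStart + start - 1L
    }
    invisible(NULL)
}

## read [offset, offset + length) and return the text split into lines
.sliceLines <- function(path, offset, length) {
    con <- file(path, "rb")
    on.exit(close(con))
    seek(con, where = offset, origin = "start")
    txt <- rawToChar(readBin(con, "raw", length))
    sub("\r$", "", strsplit(txt, "\n", fixed = TRUE)[[1]])
}

.sliceText <- function(path, offset, length) {
    con <- file(path, "rb")
    on.exit(close(con))
    seek(con, where = offset, origin = "start")
    rawToChar(readBin(con, "raw", length))
}
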