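## Base64 / zlib binary arrays as used by the XML spectra containers.
## mzML and mzData declare little-endian floats; mzXML uses network (big
## endian) byte order. Compression beyond zlib (e.g. numpress) is not
## supported and fails with a clear unsupported-feature error.

#' Decode a base64 binary data array
#'
#' @param text base64 payload (whitespace tolerated).
#' @param precision 32 or 64 (bits per float).
#' @param compressed logical; zlib-compressed payload.
#' @param endian `"little"` (mzML, mzData) or `"big"` (mzXML network order).
#' @param expectedLength declared element count (checked when given; for
#'   interleaved mzXML peaks pass pairs * 2).
#' @return numeric vector in declared element order.
#' @export
decodeBinaryArray <- function(text, precision = 64L, compressed = FALSE,
                              endian = c("little", "big"),
                              expectedLength = NULL) {
    endian <- match.arg(endian)
    if (!precision %in% c(32L, 64L))
        .errCond(sprintf("unsupported precision %s", precision),
            "formatError")
    text <- gsub("[ \t\r\n]", "", text)
    raw <- tryCatch(jsonlite::base64_dec(text),
        error = function(e) .errCond(
            paste0("invalid base64 payload: ", conditionMessage(e)),
            "formatError"))
    if (compressed && length(raw))
        raw <- tryCatch(memDecompress(raw, type = "gzip"),
            error = function(e) .errCond(
                paste0("zlib inflation failed: ", conditionMessage(e)),
                "formatError"))
    bytes <- precision %/% 8L
    if (length(raw) %% bytes != 0L)
        .errCond(sprintf(
            "payload length %d not divisible by %d-bit element size",
            length(raw), precision), "formatError")
    vals <- readBin(raw, "double", n = length(raw) %/% bytes, size = bytes,
        endian = endian)
    if (!is.null(expectedLength) && length(vals) != expectedLength)
        .errCond(sprintf(
            "decoded %d elements but %d were declared",
            length(vals), expectedLength), "formatError")
    vals
}

#' Encode a numeric vector as a base64 binary data array
#'
#' @param values numeric vector.
#' @param precision 32 or 64.
#' @param compressed zlib-compress before encoding.
#' @param endian byte order of the encoded floats.
#' @return single base64 string (no line breaks).
#' @export
encodeBinaryArray <- function(values, precision = 64L, compressed = FALSE,
                              endian = c("little", "big")) {
    endian <- match.arg(endian)
    stopifnot(precision %in% c(32L, 64L))
    raw <- writeBin(as.numeric(values), raw(), size = precision %/% 8L,
        endian = endian)
    if (compressed && length(raw)) raw <- memCompress(raw, type = "gzip")
    gsub("[\r\n]", "", jsonlite::base64_enc(raw))
}
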