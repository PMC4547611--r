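## Two-tier cache: a whole-object LRU hot tier over any spectra-capable
## controller, with the offset index (offset-index.R) as the cold tier.
## Frequently requested spectra stay resident as parsed objects; entries
## evicted from the hot tier fall back to a byte-range re-read. Metadata and
## id lists are pinned (always whole-object): every workflow touches them.

#' Wrap a controller with the two-tier cache
#'
#' @param controller a spectra-capable [MsDataController-class].
#' @param capacity hot-tier capacity in whole objects (default 512).
#' @param useOffsetIndex build an [OffsetIndex-class] over the source when
#'   the format supports random-access framing, so cold fetches re-read only
#'   the entity's byte range.
#' @return a [CachedController-class] that is content-transparent: for any
#'   access sequence it returns objects content-equal to the wrapped
#'   controller's.
#' @export
cachedController <- function(controller, capacity = 512L,
                             useOffsetIndex = TRUE) {
    if (!hasSpectra(controller))
        .errCond("cachedController needs a spectra-capable controller",
            "capabilityError")
    capacity <- as.integer(capacity)
    stopifnot(capacity >= 1L)
    state <- new.env(parent = emptyenv())
    state$hits <- 0; state$misses <- 0; state$evictions <- 0
    state$clock <- 0; state$stamps <- new.env(parent = emptyenv())
    state$index <- NULL
    if (useOffsetIndex && controller@formatTag %in% .FRAMED_FORMATS &&
        file.exists(controller@path))
        state$index <- tryCatch(
            buildOffsetIndex(controller@path, controller@formatTag),
            error = function(e) NULL)
    new("CachedController", path = controller@path,
        formatTag = controller@formatTag, metadata = controller@metadata,
        capabilities = controller@capabilities, inner = controller,
        capacity = capacity, hot = new.env(parent = emptyenv()),
        state = state)
}

.cacheEvictLRU <- function(object) {
    ids <- ls(object@hot)
    if (length(ids) <= object@capacity) return(invisible(NULL))
    stamps <- vapply(ids, function(i) object@state$stamps[[i]], numeric(1L))
    victim <- ids[which.min(stamps)]
    rm(list = victim, envir = object@hot)
    rm(list = victim, envir = object@state$stamps)
    object@state$evictions <- object@state$evictions + 1
    invisible(NULL)
}

.cacheFetchSpectrum <- function(object, id) {
    st <- object@state
    st$clock <- st$clock + 1
    if (!is.null(object@hot[[id]])) {
        st$hits <- st$hits + 1
        st$stamps[[id]] <- st$clock
        return(object@hot[[id]])
    }
    st$misses <- st$misses + 1
    sp <- if (!is.null(st$index) && id %in% st$index@entries$id)
        fetchByOffset(st$index, id)
    else getSpectrum(object@inner, id)
    object@hot[[id]] <- sp
    st$stamps[[id]] <- st$clock
    .cacheEvictLRU(object)
    sp
}

#' Cache statistics
#'
#' @param object a [CachedController-class].
#' @return list with `hits`, `misses`, `wholeObjectEntries`, `evictions`;
#'   `hits + misses` equals the total number of lookups.
#' @export
cacheStats <- function(object) {
    stopifnot(is(object, "CachedController"))
    list(hits = object@state$hits, misses = object@state$misses,
        wholeObjectEntries = length(ls(object@hot)),
        evictions = object@state$evictions)
}

## ---- controller contract: cached paths ------------------------------------

#' @describeIn cachedController cached spectrum fetch (LRU hot tier, offset
#'   cold tier).
#' @param object,id see generic.
#' @export
setMethod("getSpectrum", "CachedController", function(object, id) {
    if (!hasSpectra(object))
        .errCond("controller has no spectra capability", "capabilityError")
    if (!id %in% spectrumIds(object))
        .errCond(sprintf("unknown spectrum id '%s'", id), "notFoundError")
    .cacheFetchSpectrum(object, id)
})

setMethod("spectrumIds", "CachedController",
    function(object) spectrumIds(object@inner))
setMethod("chromatogramIds", "CachedController",
    function(object) chromatogramIds(object@inner))
setMethod("getChromatogram", "CachedController",
    function(object, id) getChromatogram(object@inner, id))
setMethod("proteinIds", "CachedController",
    function(object) proteinIds(object@inner))
setMethod("peptideIds", "CachedController",
    function(object, proteinId) peptideIds(object@inner, proteinId))
setMethod("psmIds", "CachedController",
    function(object, peptideId) psmIds(object@inner, peptideId))
setMethod("getProtein", "CachedController",
    function(object, id) getProtein(object@inner, id))
setMethod("getPeptide", "CachedController",
    function(object, id) getPeptide(object@inner, id))
setMethod("getPSM", "CachedController",
    function(object, id) getPSM(object@inner, id))
setMethod("peptideSequence", "CachedController",
    function(object, proteinId, peptideId)
        peptideSequence(object@inner, proteinId, peptideId))
setMethod("proteinQuant", "CachedController",
    function(object, accession) proteinQuant(object@inner, accession))

setMethod("show", "CachedController", function(object) {
    s <- cacheStats(object)
    cat(sprintf(
        "CachedController over %s '%s'\n  capacity %d, resident %d, %s\n",
        object@formatTag, basename(object@path), object@capacity,
        s$wholeObjectEntries,
        sprintf("hits %d / misses %d / evictions %d",
            s$hits, s$misses, s$evictions)))
})
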