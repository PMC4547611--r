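test_that("offset index entries slice-parse to the sequential result", {
    exp <- smallExperiment(nProteins = 2L, peptidesPerProtein = 3L,
        psmsPerPeptide = 1L)
    for (tag in c("mgf", "pkl", "ms2", "apl", "mzml")) {
        path <- renderTmp(exp, tag)
        idx <- buildOffsetIndex(path, tag)
        ctrl <- openController(path, tag)
        ids <- spectrumIds(ctrl)
        expect_identical(idx@entries$id, ids, info = tag)
        for (id in ids)
            expect_true(spectraEqual(fetchByOffset(idx, id),
                getSpectrum(ctrl, id)), info = paste(tag, id))
    }
    expect_error(buildOffsetIndex(renderTmp(exp, "dta"), "dta"),
        class = "unsupportedFeatureError")
})

test_that("a modified source is refused with a checksum error", {
    exp <- smallExperiment(nProteins = 1L, peptidesPerProtein = 2L,
        psmsPerPeptide = 1L)
    path <- renderTmp(exp, "mgf")
    idx <- buildOffsetIndex(path, "mgf")
    id <- idx@entries$id[[1L]]
    expect_s4_class(fetchByOffset(idx, id), "Spectrum")
    Sys.sleep(0.02)   # ensure a distinct mtime
    cat("# tampered\n", file = path, append = TRUE)
    expect_error(fetchByOffset(idx, id), class = "staleIndexError")
})

test_that("the index sidecar persists and reloads", {
    exp <- smallExperiment(nProteins = 1L, peptidesPerProtein = 2L,
        psmsPerPeptide = 1L)
    path <- renderTmp(exp, "mgf")
    idx <- buildOffsetIndex(path, "mgf")
    side <- tempfile(fileext = ".json")
    writeOffsetIndex(idx, side)
    idx2 <- readOffsetIndex(side)
    expect_identical(idx2@checksum, idx@checksum)
    expect_identical(idx2@entries$offset, idx@entries$offset)
    expect_true(spectraEqual(fetchByOffset(idx2, idx@entries$id[[1L]]),
        fetchByOffset(idx, idx@entries$id[[1L]])))
})

test_that("cache counts hits and misses per the contract", {
    exp <- smallExperiment(nProteins = 2L, peptidesPerProtein = 2L,
        psmsPerPeptide = 1L)
    ctrl <- openController(renderTmp(exp, "mgf"))
    cc <- cachedController(ctrl, capacity = 8L)
    id <- spectrumIds(cc)[[1L]]
    invisible(getSpectrum(cc, id))
    invisible(getSpectrum(cc, id))
    s <- cacheStats(cc)
    expect_identical(s$misses, 1)
    expect_identical(s$hits, 1)
    expect_error(getSpectrum(cc, "nope"), class = "notFoundError")
    s2 <- cacheStats(cc)            # failed lookups are not cached/counted
    expect_identical(s2$misses, 1)
})

test_that("LRU eviction demotes and re-reads without changing content", {
    exp <- smallExperiment(nProteins = 2L, peptidesPerProtein = 2L,
        psmsPerPeptide = 1L)
    ctrl <- openController(renderTmp(exp, "mgf"))
    cc <- cachedController(ctrl, capacity = 2L)
    ids <- spectrumIds(cc)
    first <- getSpectrum(cc, ids[[1L]])
    invisible(getSpectrum(cc, ids[[2L]]))
    invisible(getSpectrum(cc, ids[[3L]]))      # evicts ids[1]
    again <- getSpectrum(cc, ids[[1L]])        # miss: re-read via offsets
    s <- cacheStats(cc)
    expect_identical(s$misses, 4)
    expect_identical(s$hits, 0)
    expect_gte(s$evictions, 2)
    expect_true(spectraEqual(first, again))
    expect_lte(s$wholeObjectEntries, 2L)
})

test_that("cached and uncached controllers agree over random access", {
    exp <- smallExperiment(seed = 5L)
    path <- renderTmp(exp, "mzml")
    plain <- openController(path)
    cc <- cachedController(openController(path), capacity = 4L)
    ids <- spectrumIds(plain)
    set.seed(99)
    seq <- sample(ids, 300L, replace = TRUE)
    for (id in seq) {
        expect_true(spectraEqual(getSpectrum(cc, id),
            getSpectrum(plain, id)))
        expect_lte(cacheStats(cc)$wholeObjectEntries, 4L)
    }
    s <- cacheStats(cc)
    expect_identical(s$hits + s$misses, 300)
})

test_that("identification getters pass through the cache wrapper", {
    exp <- smallExperiment(nProteins = 2L)
    path <- renderTmp(exp, "pridexml")
    plain <- openController(path)
    cc <- cachedController(plain, capacity = 4L)
    expect_identical(proteinIds(cc), proteinIds(plain))
    pid <- proteinIds(cc)[[1L]]
    expect_identical(peptideIds(cc, pid), peptideIds(plain, pid))
    expect_error(cachedController(
        openController(renderTmp(exp, "mzidentml"))),
        class = "capabilityError")   # no spectra to cache
})
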