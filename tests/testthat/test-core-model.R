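test_that("param types enforce their invariants", {
    expect_error(CvParam("MS", "", "name"), "accession")
    expect_error(CvParam("", "MS:1", "name"), "cvLabel")
    expect_error(UserParam(""), "name")
    p <- CvParam("MS", "MS:1000744", "selected ion m/z", "445.12")
    expect_identical(p@value, "445.12")

    g <- ParamGroup(
        cvParams = list(CvParam("MS", "MS:1", "a", "first"),
            CvParam("MS", "MS:2", "b"), CvParam("MS", "MS:1", "a", "second")),
        userParams = list(UserParam("k", "v")))
    ## order preserved, lookup returns first match
    expect_identical(cvParamByAccession(g, "MS:1")@value, "first")
    expect_null(cvParamByAccession(g, "MS:999"))
    expect_identical(userParamByName(g, "k")@value, "v")
})

test_that("spectrum and identification types validate their invariants", {
    expect_error(Spectrum("s", 0L, mz = c(1, 2), intensity = 1), "length")
    expect_error(Spectrum("s", 0L, mz = c(2, 1), intensity = c(1, 1)),
        "non-decreasing")
    expect_error(Spectrum("s", -1L), "index")
    expect_error(Precursor(0), "positive")
    expect_error(new("PSM", id = "x", sequence = "pep", charge = 2L,
        experimentalMz = 500, rank = 1L, passThreshold = TRUE,
        scores = ParamGroup()), "uppercase")
    expect_error(new("PSM", id = "x", sequence = "PEPTIDE", charge = 2L,
        experimentalMz = 500, rank = 0L, passThreshold = TRUE,
        scores = ParamGroup()), "rank")
    ## modification outside [0, len + 1]
    expect_error(new("PSM", id = "x", sequence = "GG", charge = 2L,
        experimentalMz = 500, rank = 1L, passThreshold = TRUE,
        scores = ParamGroup(),
        modifications = list(Modification("UNIMOD:1", "Acetyl",
            42.010565, 4L))), "position")
    expect_error(new("Protein", id = "p", accession = "A",
        passThreshold = TRUE, scores = ParamGroup(),
        peptideIds = c("x", "x")), "unique")
    expect_error(new("Peptide", id = "p", sequence = "GG",
        psmIds = character()), "non-empty")
})

test_that("openController reports capabilities per format", {
    exp <- smallExperiment()
    mgf <- openController(renderTmp(exp, "mgf"))
    expect_true(hasSpectra(mgf))
    expect_false(hasIdentifications(mgf))
    expect_error(proteinIds(mgf), class = "capabilityError")

    mzid <- openController(renderTmp(exp, "mzidentml"))
    expect_true(hasIdentifications(mzid))
    expect_false(hasSpectra(mzid))
    ## the canonical iteration: proteins -> peptides succeeds throughout
    for (id in proteinIds(mzid))
        for (pepId in peptideIds(mzid, id))
            expect_true(nzchar(getPeptide(mzid, pepId)@sequence))

    pride <- openController(renderTmp(exp, "pridexml"))
    expect_true(hasSpectra(pride) && hasIdentifications(pride))
})

test_that("format is detected by content when the extension is opaque", {
    exp <- smallExperiment()
    for (tag in c("pkl", "mgf", "apl", "ms2", "mzml", "mzidentml",
        "mztab")) {
        src <- renderTmp(exp, tag)
        anon <- tempfile()   # no informative extension
        file.copy(src, anon)
        expect_identical(detectFormat(anon), tag)
    }
    bad <- tempfile()
    writeLines("certainly not mass spectrometry data, no numbers", bad)
    expect_error(openController(bad), class = "unsupportedFormatError")
    expect_error(openController(tempfile()), class = "ioError")
})

test_that("protein and peptide id getters are stable, closed and checked", {
    exp <- smallExperiment(nProteins = 2L)
    ctrl <- openController(renderTmp(exp, "mzidentml"))
    ids <- proteinIds(ctrl)
    expect_length(ids, 2L)
    expect_false(anyDuplicated(ids) > 0L)
    expect_identical(ids, proteinIds(ctrl))     # repeated calls identical
    expect_error(peptideIds(ctrl, "ZZZ"), class = "notFoundError")
    ## union over proteins covers every peptide reachable in the source
    union <- unlist(lapply(ids, function(i) peptideIds(ctrl, i)))
    expect_setequal(union, names(exp@peptides))
    ## referential closure: peptides resolve, PSMs resolve
    for (pepId in union) {
        pep <- getPeptide(ctrl, pepId)
        for (psmId in pep@psmIds)
            expect_identical(getPSM(ctrl, psmId)@sequence, pep@sequence)
    }
})

test_that("an identification source with zero proteins yields empty lists", {
    doc <- MzTabDocument()
    ctrl <- mzTabToController(doc)
    expect_false(hasIdentifications(ctrl))
})

test_that("spectrum access is deterministic and index-consistent", {
    exp <- smallExperiment()
    path <- renderTmp(exp, "mgf")
    ctrl <- openController(path)
    ids <- spectrumIds(ctrl)
    s1 <- getSpectrum(ctrl, ids[[3L]])
    s2 <- getSpectrum(ctrl, ids[[3L]])
    expect_identical(mzValues(s1), mzValues(s2))
    expect_error(getSpectrum(ctrl, "no-such-id"), class = "notFoundError")
    ## offset-indexed fetch agrees with the sequential parse
    idx <- buildOffsetIndex(path, "mgf")
    for (id in ids)
        expect_true(spectraEqual(fetchByOffset(idx, id),
            getSpectrum(ctrl, id)))
})
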