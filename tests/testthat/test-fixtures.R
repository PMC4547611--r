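test_that("generated entity counts follow the requested arithmetic", {
    exp <- generateExperiment(seed = 1L, nProteins = 2L,
        peptidesPerProtein = 3L, psmsPerPeptide = 1L,
        peaksPerSpectrum = 10L, decoyFraction = 0,
        failThresholdFraction = 0)
    expect_length(exp@proteins, 2L)
    expect_length(exp@peptides, 6L)
    expect_length(exp@psms, 6L)
    expect_length(exp@spectra, 6L)
    expect_true(all(vapply(exp@spectra, function(s) length(s@mz) == 10L,
        logical(1L))))
    ## decoy rounding rule: round(nProteins * decoyFraction)
    exp2 <- generateExperiment(seed = 1L, nProteins = 10L,
        peptidesPerProtein = 1L, decoyFraction = 0.5)
    expect_identical(sum(vapply(exp2@proteins, slot, logical(1L),
        "isDecoy")), 5L)
    expect_identical(sum(grepl("^DECOY_", vapply(exp2@proteins, slot,
        character(1L), "accession"))), 5L)
})

test_that("the same seed reproduces a byte-identical manifest", {
    f1 <- tempfile(); f2 <- tempfile()
    writeManifest(smallExperiment(seed = 9L), f1)
    writeManifest(smallExperiment(seed = 9L), f2)
    expect_identical(readBin(f1, "raw", file.size(f1)),
        readBin(f2, "raw", file.size(f2)))
    ## and a different seed does not
    f3 <- tempfile()
    writeManifest(smallExperiment(seed = 10L), f3)
    expect_false(identical(readLines(f1), readLines(f3)))
})

test_that("spectrum precursors are tied to the peptide mass calculator", {
    exp <- smallExperiment(seed = 3L, decoyFraction = 0,
        failThresholdFraction = 0)
    for (psm in exp@psms) {
        want <- monoisotopicMass(psm@sequence, psm@modifications,
            charge = psm@charge)
        expect_equal(psm@calculatedMz, want, tolerance = 1e-12)
        sp <- exp@spectra[[psm@spectrumRef]]
        expect_equal(sp@precursor@mz, psm@experimentalMz,
            tolerance = 1e-12)
        expect_lt(abs(sp@precursor@mz - want), 1e-3)
    }
})

test_that("every renderer round-trips through its reader", {
    exp <- smallExperiment(seed = 17L, nProteins = 2L,
        peptidesPerProtein = 2L, psmsPerPeptide = 1L)
    specTol <- c(mgf = 0, mzml = 0, mzdata = 0, apl = 0, pkl = 0,
        ms2 = 0, mzxml = 1e-6)
    for (tag in names(specTol)) {
        ctrl <- openController(renderTmp(exp, tag), tag)
        ids <- spectrumIds(ctrl)
        expect_length(ids, length(exp@spectra))
        for (i in seq_along(exp@spectrumOrder)) {
            want <- exp@spectra[[exp@spectrumOrder[[i]]]]
            got <- getSpectrum(ctrl, ids[[i]])
            if (specTol[[tag]] == 0) {
                expect_identical(got@mz, want@mz, info = tag)
                expect_identical(got@intensity, want@intensity,
                    info = tag)
            } else {
                expect_lt(max(abs(got@mz - want@mz) / want@mz),
                    specTol[[tag]])
            }
        }
    }
    ## dta holds the first spectrum only
    s <- getSpectrum(openController(renderTmp(exp, "dta"), "dta"),
        "index=0")
    want <- exp@spectra[[exp@spectrumOrder[[1L]]]]
    expect_identical(s@mz, want@mz)
    expect_equal(s@precursor@mz, want@precursor@mz, tolerance = 1e-9)
})

test_that("identification renderers preserve the hierarchy counts", {
    exp <- smallExperiment(seed = 23L)
    want <- identSummary(asController(exp))
    for (tag in c("mzidentml", "pridexml")) {
        got <- identSummary(openController(renderTmp(exp, tag), tag))
        expect_identical(got$accessions, want$accessions, info = tag)
        expect_identical(got$sequences, want$sequences, info = tag)
        expect_identical(got$nPsms, want$nPsms, info = tag)
    }
    ## mztab with no-op filters conserves the generated PSM count
    doc <- parseMzTab(renderTmp(exp, "mztab"))
    expect_identical(nrow(doc@psmTable), length(exp@psms))
})

test_that("rendering refuses capability mismatches", {
    empty <- generateExperiment(seed = 1L, nProteins = 0L)
    expect_error(renderExperiment(empty, "mgf", tempfile()),
        class = "capabilityError")
    expect_error(renderExperiment(empty, "mzidentml", tempfile()),
        class = "capabilityError")
})
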