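test_that("binary arrays survive encode/decode in all declared layouts", {
    expect_equal(decodeBinaryArray(
        encodeBinaryArray(c(1.0, 2.0), 64L, FALSE, "little"),
        64L, FALSE, "little"), c(1.0, 2.0))
    expect_identical(decodeBinaryArray("", 64L, FALSE, "little"),
        numeric())
    set.seed(42)
    x <- runif(1000, 100, 2000)
    got <- decodeBinaryArray(encodeBinaryArray(x, 32L, TRUE, "little"),
        32L, TRUE, "little", expectedLength = 1000L)
    expect_lt(max(abs(got - x) / x), 1e-6)        # 32-bit precision
    ## same values through both byte orders decode identically
    expect_equal(
        decodeBinaryArray(encodeBinaryArray(x, 64L, FALSE, "big"),
            64L, FALSE, "big"),
        decodeBinaryArray(encodeBinaryArray(x, 64L, FALSE, "little"),
            64L, FALSE, "little"))
    expect_error(decodeBinaryArray("!!!notbase64???", 64L, FALSE,
        "little"), class = "formatError")
    expect_error(decodeBinaryArray(encodeBinaryArray(x, 64L), 64L,
        FALSE, "little", expectedLength = 999L), class = "formatError")
})

test_that("mzML controller exposes ids, precursors and exact peak arrays", {
    exp <- smallExperiment(nProteins = 2L, psmsPerPeptide = 1L)
    path <- renderTmp(exp, "mzml")
    ctrl <- openController(path)
    expect_s4_class(ctrl, "MzMLController")
    expect_identical(spectrumIds(ctrl), exp@spectrumOrder)
    for (id in exp@spectrumOrder) {
        got <- getSpectrum(ctrl, id)
        want <- exp@spectra[[id]]
        expect_identical(got@mz, want@mz)           # 64-bit round trip
        expect_identical(got@intensity, want@intensity)
        expect_equal(got@precursor@mz, want@precursor@mz)
        expect_identical(got@precursor@charge, want@precursor@charge)
    }
    ## spectrum-level cvParams are copied verbatim
    s <- getSpectrum(ctrl, exp@spectrumOrder[[1L]])
    expect_identical(cvParamByAccession(s@params, "MS:1000511")@value, "2")
    ## header metadata: software survives
    proto <- experimentMetadata(ctrl)@protocols[[1L]]
    expect_identical(proto@software[[1L]][[1L]], "ProteoAccessGenerator")
})

test_that("hand-built mzML maps the selected-ion term onto the precursor", {
    f <- tempfile(fileext = ".mzml")
    writeLines(c('<?xml version="1.0"?>',
        '<mzML xmlns="http://psi.hupo.org/ms/mzml" version="1.1.0">',
        '  <run id="r">',
        '    <spectrumList count="1">',
        '      <spectrum index="0" id="s1" defaultArrayLength="2">',
        '        <cvParam cvRef="MS" accession="MS:1000511" name="ms level" value="2"/>',
        '        <precursorList count="1"><precursor><selectedIonList count="1"><selectedIon>',
        '          <cvParam cvRef="MS" accession="MS:1000744" name="selected ion m/z" value="445.12"/>',
        '        </selectedIon></selectedIonList></precursor></precursorList>',
        '        <binaryDataArrayList count="2">',
        '        <binaryDataArray>',
        '          <cvParam cvRef="MS" accession="MS:1000523" name="64-bit float"/>',
        '          <cvParam cvRef="MS" accession="MS:1000514" name="m/z array"/>',
        sprintf('          <binary>%s</binary>',
            encodeBinaryArray(c(100, 200))),
        '        </binaryDataArray>',
        '        <binaryDataArray>',
        '          <cvParam cvRef="MS" accession="MS:1000523" name="64-bit float"/>',
        '          <cvParam cvRef="MS" accession="MS:1000515" name="intensity array"/>',
        sprintf('          <binary>%s</binary>',
            encodeBinaryArray(c(1, 2))),
        '        </binaryDataArray>',
        '        </binaryDataArrayList>',
        '      </spectrum>',
        '    </spectrumList>',
        '  </run>', '</mzML>'), f)
    ctrl <- parseMzML(f)
    s <- getSpectrum(ctrl, "s1")
    expect_equal(s@precursor@mz, 445.12)
    expect_equal(s@mz, c(100, 200))
})

test_that("mzML without a required binary array names the spectrum", {
    f <- tempfile(fileext = ".mzml")
    writeLines(c('<mzML version="1.1.0">', '<run id="r">',
        '<spectrumList count="1">',
        '      <spectrum index="0" id="broken" defaultArrayLength="0">',
        '        <binaryDataArrayList count="0">',
        '        </binaryDataArrayList>',
        '      </spectrum>',
        '</spectrumList>', '</run>', '</mzML>'), f)
    ctrl <- parseMzML(f)
    err <- tryCatch(getSpectrum(ctrl, "broken"), error = function(e) e)
    expect_s3_class(err, "formatError")
    expect_match(conditionMessage(err), "broken")
})

test_that("mzXML decodes network-order interleaved peaks", {
    exp <- smallExperiment(nProteins = 2L, psmsPerPeptide = 1L)
    ctrl <- openController(renderTmp(exp, "mzxml"))
    ids <- spectrumIds(ctrl)
    expect_identical(ids, exp@spectrumOrder)
    s <- getSpectrum(ctrl, ids[[1L]])
    want <- exp@spectra[[ids[[1L]]]]
    expect_identical(s@msLevel, 2L)
    expect_equal(s@precursor@mz, want@precursor@mz)
    ## 32-bit arrays: relative 1e-6
    expect_lt(max(abs(s@mz - want@mz) / want@mz), 1e-6)
    ## unsupported pairOrder is refused
    f <- tempfile(fileext = ".mzxml")
    writeLines(c('<mzXML><msRun scanCount="1">',
        '<scan num="1" msLevel="2" peaksCount="1">',
        sprintf('<peaks precision="32" byteOrder="network" pairOrder="int-m/z">%s</peaks>',
            encodeBinaryArray(c(1, 2), 32L, FALSE, "big")),
        '</scan></msRun></mzXML>'), f)
    expect_error(parseMzXML(f), class = "formatError")
})

test_that("mzData decodes little-endian arrays and ionSelection params", {
    exp <- smallExperiment(nProteins = 3L, peptidesPerProtein = 1L,
        psmsPerPeptide = 1L)
    ctrl <- openController(renderTmp(exp, "mzdata"))
    ids <- spectrumIds(ctrl)
    expect_length(ids, 3L)
    for (id in ids) {
        s <- getSpectrum(ctrl, id)
        expect_identical(s@mz, exp@spectra[[id]]@mz)
        expect_equal(s@precursor@mz, exp@spectra[[id]]@precursor@mz)
    }
})

test_that("endianness conventions agree across containers for one fixture", {
    exp <- smallExperiment(nProteins = 1L, peptidesPerProtein = 2L,
        psmsPerPeptide = 1L)
    le <- openController(renderTmp(exp, "mzml"))       # little-endian
    be <- openController(renderTmp(exp, "mzxml"))      # big-endian 32-bit
    md <- openController(renderTmp(exp, "mzdata"))     # little-endian
    for (id in exp@spectrumOrder) {
        a <- getSpectrum(le, id)@mz
        b <- getSpectrum(be, id)@mz
        c_ <- getSpectrum(md, id)@mz
        expect_identical(a, c_)
        expect_lt(max(abs(a - b) / a), 1e-6)
    }
})

test_that("mzIdentML builds the full identification graph", {
    exp <- smallExperiment(nProteins = 2L, peptidesPerProtein = 3L,
        psmsPerPeptide = 2L, decoyFraction = 0, failThresholdFraction = 0)
    ctrl <- openController(renderTmp(exp, "mzidentml"))
    expect_length(proteinIds(ctrl), 2L)
    s <- identSummary(ctrl)
    expect_identical(s$nPsms, 12L)
    expect_setequal(s$sequences, unname(vapply(exp@peptides, slot,
        character(1L), "sequence")))
    ## scores, threshold flags, charges, m/z survive
    psm <- getPSM(ctrl, "psm_1")
    want <- exp@psms[["psm_1"]]
    expect_equal(psm@experimentalMz, want@experimentalMz)
    expect_equal(psm@calculatedMz, want@calculatedMz)
    expect_identical(psm@charge, want@charge)
    expect_identical(psm@rank, want@rank)
    expect_identical(
        cvParamByAccession(psm@scores, "MS:1001155")@value,
        cvParamByAccession(want@scores, "MS:1001155")@value)
    ## protocol metadata
    proto <- experimentMetadata(ctrl)@protocols[[1L]]
    expect_identical(proto@enzyme, "Trypsin")
    expect_identical(proto@searchDatabaseName, "SYNTH-DB")
})

test_that("modification coordinates are 1-based with 0 as the N-terminus", {
    exp <- smallExperiment(nProteins = 1L, peptidesPerProtein = 5L,
        psmsPerPeptide = 1L, decoyFraction = 0)
    ## peptide 5 carries an N-terminal acetylation by construction
    acetylated <- Filter(function(p) any(vapply(p@modifications,
        function(m) m@accession == "UNIMOD:1", logical(1L))),
        exp@peptides)
    expect_gte(length(acetylated), 1L)
    ctrl <- openController(renderTmp(exp, "mzidentml"))
    pep <- getPeptide(ctrl, acetylated[[1L]]@id)
    acetyl <- Filter(function(m) m@accession == "UNIMOD:1",
        pep@modifications)[[1L]]
    expect_identical(acetyl@position, 0L)
    expect_equal(acetyl@monoDelta, 42.010565)
    ## and the PRIDE XML rendering preserves the same position
    pride <- openController(renderTmp(exp, "pridexml"))
    seqs <- identSummary(pride)
    psmMods <- unlist(lapply(proteinIds(pride), function(i)
        lapply(peptideIds(pride, i), function(p)
            getPeptide(pride, p)@modifications)), recursive = FALSE)
    prideAcetyl <- Filter(function(ms) any(vapply(ms,
        function(m) m@accession == "UNIMOD:1", logical(1L))), psmMods)
    expect_gte(length(prideAcetyl), 1L)
})

test_that("dangling references in mzIdentML are named in the error", {
    f <- tempfile(fileext = ".mzid")
    writeLines(c('<MzIdentML version="1.1.0">',
        '<SequenceCollection>',
        '<Peptide id="P1"><PeptideSequence>GGG</PeptideSequence></Peptide>',
        '<PeptideEvidence id="E1" peptide_ref="P1" dBSequence_ref="MISSING" isDecoy="false"/>',
        '</SequenceCollection>', '</MzIdentML>'), f)
    err <- tryCatch(parseMzIdentML(f), error = function(e) e)
    expect_s3_class(err, "formatError")
    expect_match(conditionMessage(err), "MISSING")
})

test_that("PRIDE XML exposes spectra and identifications together", {
    exp <- smallExperiment(nProteins = 2L, peptidesPerProtein = 2L,
        psmsPerPeptide = 1L, decoyFraction = 0)
    ctrl <- openController(renderTmp(exp, "pridexml"))
    expect_true(hasSpectra(ctrl))
    expect_true(hasIdentifications(ctrl))
    expect_length(proteinIds(ctrl), 2L)
    expect_identical(identSummary(ctrl)$nPsms, 4L)
    ## embedded mzData spectra equal the fixture arrays
    for (id in exp@spectrumOrder)
        expect_identical(getSpectrum(ctrl, id)@mz, exp@spectra[[id]]@mz)
    ## PSMs link to in-file spectra
    psmId <- psmIds(ctrl, peptideIds(ctrl, proteinIds(ctrl)[[1L]])[[1L]])[[1L]]
    ref <- getPSM(ctrl, psmId)@spectrumRef
    expect_true(ref %in% spectrumIds(ctrl))
})

test_that("mzIdentML and PRIDE XML renderings of one fixture agree", {
    exp <- smallExperiment(seed = 11L)
    a <- identSummary(openController(renderTmp(exp, "mzidentml")))
    b <- identSummary(openController(renderTmp(exp, "pridexml")))
    expect_identical(a$accessions, b$accessions)
    expect_identical(a$sequences, b$sequences)
    expect_identical(a$nPsms, b$nPsms)
})
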