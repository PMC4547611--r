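noopFilters <- function() QualityFilter(requirePassThreshold = FALSE,
    maxRank = .Machine$integer.max, dropDecoys = FALSE,
    minPeptidesPerProtein = 1L)

test_that("conversion emits one PSM row per surviving PSM", {
    ## 2 proteins, 4 PSMs, no decoys, all pass -> PRT 2 rows, PSM 4 rows
    exp <- smallExperiment(nProteins = 2L, peptidesPerProtein = 2L,
        psmsPerPeptide = 1L, decoyFraction = 0, failThresholdFraction = 0)
    doc <- convertToMzTab(asController(exp), QualityFilter())
    expect_identical(nrow(doc@proteinTable), 2L)
    expect_identical(nrow(doc@psmTable), 4L)
    ## 1 decoy protein of 2 -> one PRT row after drop_decoys
    exp2 <- smallExperiment(nProteins = 2L, peptidesPerProtein = 2L,
        psmsPerPeptide = 1L, decoyFraction = 0.5,
        failThresholdFraction = 0)
    doc2 <- convertToMzTab(asController(exp2), QualityFilter())
    expect_identical(nrow(doc2@proteinTable), 1L)
    expect_false(any(grepl("^DECOY_", doc2@proteinTable$accession)))
})

test_that("the documented filter order decides protein survival", {
    ## protein with 2 peptides; one peptide's only PSM fails the threshold;
    ## minPeptidesPerProtein = 2 -> the protein is dropped, because PSM
    ## filters run before the per-protein peptide count
    psm1 <- new("PSM", id = "s1", sequence = "PEPTIDEK", charge = 2L,
        experimentalMz = 500, rank = 1L, passThreshold = TRUE,
        scores = ParamGroup())
    psm2 <- new("PSM", id = "s2", sequence = "GGGGGGGR", charge = 2L,
        experimentalMz = 400, rank = 1L, passThreshold = FALSE,
        scores = ParamGroup())
    pep1 <- new("Peptide", id = "p1", sequence = "PEPTIDEK",
        psmIds = "s1")
    pep2 <- new("Peptide", id = "p2", sequence = "GGGGGGGR",
        psmIds = "s2")
    prot <- new("Protein", id = "pr", accession = "ACC1",
        passThreshold = TRUE, scores = ParamGroup(),
        peptideIds = c("p1", "p2"))
    ctrl <- ProteoAccess:::.newInMemoryController("memory", "",
        proteins = list(prot), peptides = list(pep1, pep2),
        psms = list(psm1, psm2))
    res <- applyQualityFilters(ctrl, QualityFilter(
        requirePassThreshold = TRUE, maxRank = 1L, dropDecoys = TRUE,
        minPeptidesPerProtein = 2L))
    expect_length(res$proteins, 0L)
    expect_identical(nrow(res$rows), 0L)
    ## with minPeptidesPerProtein = 1 the protein survives on one peptide
    res2 <- applyQualityFilters(ctrl, QualityFilter(
        minPeptidesPerProtein = 1L))
    expect_length(res2$proteins, 1L)
    expect_identical(res2$rows$psmId, "s1")
})

test_that("PSM row conservation holds over random fixtures and filters", {
    set.seed(2024)
    for (i in 1:60) {
        exp <- generateExperiment(seed = i, nProteins = sample(2:4, 1L),
            peptidesPerProtein = sample(1:3, 1L),
            psmsPerPeptide = sample(1:3, 1L), peaksPerSpectrum = 3L,
            decoyFraction = runif(1, 0, 0.6),
            failThresholdFraction = runif(1, 0, 0.6))
        filters <- QualityFilter(
            requirePassThreshold = sample(c(TRUE, FALSE), 1L),
            maxRank = sample(1:3, 1L),
            dropDecoys = sample(c(TRUE, FALSE), 1L),
            minPeptidesPerProtein = sample(1:2, 1L))
        doc <- convertToMzTab(asController(exp), filters)
        expect_identical(nrow(doc@psmTable),
            referenceFilterRows(exp, filters),
            info = sprintf("fixture %d", i))
    }
})

test_that("writer output re-parses to an equal document, byte-stably", {
    exp <- smallExperiment()
    doc <- convertToMzTab(asController(exp), noopFilters())
    f1 <- tempfile(fileext = ".mztab")
    writeMzTab(doc, f1)
    doc2 <- parseMzTab(f1)
    expect_identical(doc2@metadata, doc@metadata)
    expect_identical(doc2@proteinTable, doc@proteinTable)
    expect_identical(doc2@psmTable, doc@psmTable)
    f2 <- tempfile(fileext = ".mztab")
    writeMzTab(doc, f2)
    expect_identical(readBin(f1, "raw", file.size(f1)),
        readBin(f2, "raw", file.size(f2)))
    ## minimal document: MTD-only file that re-parses equal
    mini <- MzTabDocument()
    f3 <- tempfile()
    writeMzTab(mini, f3)
    expect_true(all(startsWith(readLines(f3), "MTD")))
    back <- parseMzTab(f3)
    expect_identical(back@metadata, mini@metadata)
    expect_identical(nrow(back@psmTable), 0L)
})

test_that("the parser reports structural problems with line numbers", {
    f <- tempfile()
    writeLines(c("MTD\tmzTab-version\t1.0",
        "PSM\tPEPTIDEK\t1\tACC"), f)
    expect_error(parseMzTab(f), "line 2")
    f2 <- tempfile()
    writeLines(c("MTD\tmzTab-version\t1.0",
        "PSH\tsequence\tPSM_ID\taccession",
        "PSM\tPEPTIDEK\t1"), f2)
    err <- tryCatch(parseMzTab(f2), error = function(e) e)
    expect_match(conditionMessage(err), "line 3")
    ## null cells become NA in the reconstructed controller
    f3 <- tempfile()
    writeLines(c("MTD\tmzTab-version\t1.0",
        "MTD\tmzTab-mode\tComplete",
        "MTD\tmzTab-type\tIdentification",
        "PSH\tsequence\tPSM_ID\taccession\tcharge\texp_mass_to_charge\tspectra_ref",
        "PSM\tPEPTIDEK\tpsm1\tACC\t2\t450.5\tnull"), f3)
    ctrl <- mzTabToController(parseMzTab(f3))
    expect_true(is.na(getPSM(ctrl, "psm1")@spectrumRef))
})

test_that("the checker flags violations with stable codes", {
    exp <- smallExperiment()
    doc <- convertToMzTab(asController(exp), QualityFilter())
    expect_identical(nrow(checkMzTab(doc)), 0L)

    ## undeclared ms_run
    bad <- doc
    bad@metadata[["ms_run[1]-location"]] <- NULL
    rep <- checkMzTab(bad)
    expect_true("PSM_MSRUN_UNDECLARED" %in% rep$code)
    expect_error(writeMzTab(bad, tempfile()), "PSM_MSRUN_UNDECLARED")

    ## mutation oracle: each injected violation adds exactly one report row
    mutations <- list(
        function(d) { d@metadata[["mzTab-version"]] <- "2.0"; d },
        function(d) { d@metadata[["mzTab-mode"]] <- "Partial"; d },
        function(d) { d@metadata[["mzTab-type"]] <- "Banana"; d },
        function(d) {
            d@proteinTable <- rbind(d@proteinTable, d@proteinTable[1L, ])
            d
        },
        function(d) {
            d@metadata[["psm_search_engine_score[1]"]] <- NULL
            d
        })
    for (k in seq_along(mutations)) {
        mutated <- mutations[[k]](doc)
        expect_identical(nrow(checkMzTab(mutated)), 1L,
            info = sprintf("mutation %d", k))
    }
    combo <- mutations[[1L]](mutations[[4L]](doc))
    expect_identical(nrow(checkMzTab(combo)), 2L)
})

test_that("the showcased pipeline runs end to end and checker-clean", {
    ## open mzIdentML -> convert -> check -> print -> parse back
    exp <- smallExperiment(seed = 21L)
    ctrl <- openController(renderTmp(exp, "mzidentml"))
    doc <- convertToMzTab(ctrl, QualityFilter())
    expect_identical(nrow(checkMzTab(doc)), 0L)
    out <- tempfile(fileext = ".mztab")
    writeMzTab(doc, out)
    back <- parseMzTab(out)
    expect_identical(back@psmTable, doc@psmTable)
    ## and the reconstructed controller supports the uniform contract
    ctrl2 <- openController(out)
    expect_true(hasIdentifications(ctrl2))
    expect_setequal(
        vapply(proteinIds(ctrl2), function(i)
            getProtein(ctrl2, i)@accession, character(1L)),
        doc@proteinTable$accession)
})
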