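## Shared fixture helpers: everything is generated in code at test time.

extFor <- function(tag) {
    map <- c(mzidentml = "mzid", pridexml = "xml")
    if (tag %in% names(map)) map[[tag]] else tag
}

renderTmp <- function(exp, tag) {
    path <- tempfile(fileext = paste0(".", extFor(tag)))
    renderExperiment(exp, tag, path)
    path
}

smallExperiment <- function(seed = 1L, ...) {
    defaults <- list(seed = seed, nProteins = 3L, peptidesPerProtein = 3L,
        psmsPerPeptide = 2L, peaksPerSpectrum = 12L, decoyFraction = 0.34,
        failThresholdFraction = 0.15)
    args <- utils::modifyList(defaults, list(...))
    do.call(generateExperiment, args)
}

## sorted identification summary used by the cross-format agreement checks
identSummary <- function(ctrl) {
    protIds <- proteinIds(ctrl)
    acc <- sort(unname(vapply(protIds,
        function(i) getProtein(ctrl, i)@accession, character(1L))))
    seqs <- sort(unname(unlist(lapply(protIds, function(i)
        vapply(peptideIds(ctrl, i),
            function(p) getPeptide(ctrl, p)@sequence, character(1L))))))
    psm <- unique(unlist(lapply(protIds, function(i)
        unlist(lapply(peptideIds(ctrl, i),
            function(p) psmIds(ctrl, p))))))
    list(accessions = acc, sequences = seqs, nPsms = length(psm))
}

## Brute-force reference for the quality-filter order, working directly on
## the experiment's slots (independent of applyQualityFilters).
referenceFilterRows <- function(exp, filters) {
    psms <- exp@psms
    keepPsm <- names(psms)
    if (filters@dropDecoys)
        keepPsm <- keepPsm[!vapply(psms[keepPsm], slot, logical(1L),
            "isDecoy")]
    if (filters@requirePassThreshold)
        keepPsm <- keepPsm[vapply(psms[keepPsm], slot, logical(1L),
            "passThreshold")]
    keepPsm <- keepPsm[vapply(psms[keepPsm], slot, integer(1L),
        "rank") <= filters@maxRank]
    rows <- 0L
    for (pid in exp@proteinOrder) {
        prot <- exp@proteins[[pid]]
        if (filters@dropDecoys && prot@isDecoy) next
        if (!prot@passThreshold) next
        pepPsms <- lapply(prot@peptideIds, function(p)
            intersect(exp@peptides[[p]]@psmIds, keepPsm))
        nPeps <- sum(lengths(pepPsms) > 0L)
        if (nPeps < filters@minPeptidesPerProtein) next
        rows <- rows + sum(lengths(pepPsms))
    }
    rows
}

## stream a large synthetic mzML directly to disk (random peaks, no
## experiment object), for the bounded-memory reader checks
writeBigMzml <- function(path, nSpectra, peaksPerSpectrum = 100L,
                         seed = 1L) {
    set.seed(seed)
    con <- file(path, "wb")
    on.exit(close(con))
    writeLines(c('<?xml version="1.0" encoding="UTF-8"?>',
        '<mzML xmlns="http://psi.hupo.org/ms/mzml" version="1.1.0">',
        '  <run id="run1">',
        sprintf('    <spectrumList count="%d">', nSpectra)), con,
        sep = "\n")
    for (i in seq_len(nSpectra)) {
        mz <- sort(runif(peaksPerSpectrum, 100, 2000))
        int <- runif(peaksPerSpectrum, 1, 1e6)
        writeLines(c(
            sprintf('      <spectrum index="%d" id="%d" defaultArrayLength="%d">',
                i - 1L, i, peaksPerSpectrum),
            '        <cvParam cvRef="MS" accession="MS:1000511" name="ms level" value="2"/>',
            '        <binaryDataArrayList count="2">',
            '        <binaryDataArray>',
            '          <cvParam cvRef="MS" accession="MS:1000523" name="64-bit float"/>',
            '          <cvParam cvRef="MS" accession="MS:1000576" name="no compression"/>',
            '          <cvParam cvRef="MS" accession="MS:1000514" name="m/z array"/>',
            sprintf('          <binary>%s</binary>',
                encodeBinaryArray(mz, 64L, FALSE, "little")),
            '        </binaryDataArray>',
            '        <binaryDataArray>',
            '          <cvParam cvRef="MS" accession="MS:1000523" name="64-bit float"/>',
            '          <cvParam cvRef="MS" accession="MS:1000576" name="no compression"/>',
            '          <cvParam cvRef="MS" accession="MS:1000515" name="intensity array"/>',
            sprintf('          <binary>%s</binary>',
                encodeBinaryArray(int, 64L, FALSE, "little")),
            '        </binaryDataArray>',
            '        </binaryDataArrayList>',
            '      </spectrum>'), con, sep = "\n")
    }
    writeLines(c('    </spectrumList>', '  </run>', '</mzML>'), con,
        sep = "\n")
    invisible(path)
}

randomPeptideSeq <- function(minLen = 7L, maxLen = 25L) {
    n <- sample(minLen:maxLen, 1L)
    paste(sample(CANONICAL_RESIDUES, n, replace = TRUE), collapse = "")
}
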