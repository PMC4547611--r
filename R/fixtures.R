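## Seeded synthetic-experiment generator and renderers to every supported
## format: the test bed that makes the library verifiable without downloads.
##
## Determinism: one RNG namespace per entity kind, each seeded from the
## master seed, so changing n_proteins does not perturb the spectra stream.
## Spectral peaks are uniform-random m/z in [100, 2000) sorted ascending
## with log-uniform intensities; no fragmentation model is attempted — the
## library transports peaks, it never interprets them.

.subSeed <- function(seed, k) as.integer((seed * 1009 + k) %% 2147483629)

.withSeed <- function(seed, expr) {
    old <- if (exists(".Random.seed", globalenv(), inherits = FALSE))
        get(".Random.seed", globalenv()) else NULL
    on.exit(if (is.null(old))
        suppressWarnings(rm(".Random.seed", envir = globalenv()))
        else assign(".Random.seed", old, envir = globalenv()))
    set.seed(seed)
    expr
}

.randomPeptide <- function() {
    n <- sample(7:25, 1L)
    paste(sample(CANONICAL_RESIDUES, n, replace = TRUE), collapse = "")
}

.OXIDATION <- list(accession = "UNIMOD:35", name = "Oxidation",
    delta = 15.994915)
.ACETYL <- list(accession = "UNIMOD:1", name = "Acetyl", delta = 42.010565)

#' Generate a seeded synthetic proteomics experiment
#'
#' Peptide sequences are drawn over the canonical alphabet (length 7-25);
#' every PSM gets one spectrum whose precursor m/z equals the peptide's
#' [monoisotopicMass()] at the PSM charge, tying the fixture to the
#' calculators. Decoy count is `round(nProteins * decoyFraction)` (the last
#' proteins become decoys); failing-threshold PSM count is
#' `round(nPsms * failThresholdFraction)`. Same seed, same experiment,
#' byte-identical manifest.
#'
#' @param seed master seed (integer).
#' @param nProteins number of proteins.
#' @param peptidesPerProtein peptides generated per protein.
#' @param psmsPerPeptide PSMs per peptide (ranks 1, 2, ... within the
#'   peptide).
#' @param peaksPerSpectrum fragment peaks per spectrum.
#' @param decoyFraction fraction of decoy proteins in `[0, 1]`.
#' @param failThresholdFraction fraction of PSMs failing the search
#'   threshold.
#' @return a [SyntheticExperiment-class].
#' @examples
#' exp <- generateExperiment(1, nProteins = 2, peptidesPerProtein = 3)
#' length(exp@psms)
#' @export
generateExperiment <- function(seed = 1L, nProteins = 10L,
        peptidesPerProtein = 4L, psmsPerPeptide = 1L,
        peaksPerSpectrum = 30L, decoyFraction = 0.2,
        failThresholdFraction = 0.1) {
    seed <- as.integer(seed)
    stopifnot(nProteins >= 0, peptidesPerProtein >= 0, psmsPerPeptide >= 0,
        peaksPerSpectrum >= 0, decoyFraction >= 0, decoyFraction <= 1,
        failThresholdFraction >= 0, failThresholdFraction <= 1)
    nDecoy <- round(nProteins * decoyFraction)
    decoyFlags <- c(rep(FALSE, nProteins - nDecoy), rep(TRUE, nDecoy))

    proteins <- list(); peptides <- list(); psms <- list(); spectra <- list()
    sequences <- .withSeed(.subSeed(seed, 1L), {
        lapply(seq_len(nProteins), function(i)
            vapply(seq_len(peptidesPerProtein), function(j)
                .randomPeptide(), character(1L)))
    })
    dbSeqs <- .withSeed(.subSeed(seed, 2L), {
        vapply(seq_len(nProteins), function(i)
            paste(sample(CANONICAL_RESIDUES, 60, replace = TRUE),
                collapse = ""), character(1L))
    })
    charges <- .withSeed(.subSeed(seed, 3L), {
        sample(2:3, nProteins * peptidesPerProtein * psmsPerPeptide,
            replace = TRUE)
    })
    scores <- .withSeed(.subSeed(seed, 4L), {
        round(stats::runif(
            nProteins * peptidesPerProtein * psmsPerPeptide, 1, 6), 4)
    })
    mzNoise <- .withSeed(.subSeed(seed, 5L), {
        round(stats::runif(
            nProteins * peptidesPerProtein * psmsPerPeptide,
            -5e-4, 5e-4), 6)
    })
    nPsmsTotal <- nProteins * peptidesPerProtein * psmsPerPeptide
    nFail <- round(nPsmsTotal * failThresholdFraction)
    failIdx <- .withSeed(.subSeed(seed, 6L),
        if (nFail > 0) sample.int(nPsmsTotal, nFail) else integer())
    peakSeed <- .subSeed(seed, 7L)

    psmNo <- 0L
    for (i in seq_len(nProteins)) {
        accession <- sprintf("%sPROT%05d",
            if (decoyFlags[[i]]) "DECOY_" else "", i)
        protId <- sprintf("protein_%d", i)
        pepIds <- character()
        for (j in seq_len(peptidesPerProtein)) {
            sq <- sequences[[i]][[j]]
            pepId <- sprintf("peptide_%d_%d", i, j)
            mods <- list()
            if (j %% 3L == 0L) {
                mpos <- regexpr("M", sq, fixed = TRUE)
                if (mpos > 0L) mods <- c(mods, list(Modification(
                    .OXIDATION$accession, .OXIDATION$name,
                    .OXIDATION$delta, as.integer(mpos))))
            }
            if (j %% 5L == 0L)
                mods <- c(mods, list(Modification(.ACETYL$accession,
                    .ACETYL$name, .ACETYL$delta, 0L)))
            psmIdsOfPep <- character()
            for (k in seq_len(psmsPerPeptide)) {
                psmNo <- psmNo + 1L
                z <- charges[[psmNo]]
                calcMz <- monoisotopicMass(sq, mods, charge = z)
                psmId <- sprintf("psm_%d", psmNo)
                specId <- as.character(psmNo)
                psms[[psmId]] <- new("PSM", id = psmId, sequence = sq,
                    modifications = mods, spectrumRef = specId,
                    charge = as.integer(z),
                    experimentalMz = calcMz + mzNoise[[psmNo]],
                    calculatedMz = calcMz, rank = k,
                    passThreshold = !psmNo %in% failIdx,
                    scores = ParamGroup(list(CvParam("MS", "MS:1001155",
                        "SEQUEST:xcorr", .fmtShortest(scores[[psmNo]])))),
                    isDecoy = decoyFlags[[i]])
                spectra[[specId]] <- .withSeed(
                    .subSeed(peakSeed, psmNo), {
                    mz <- sort(stats::runif(peaksPerSpectrum, 100, 2000))
                    int <- round(10^stats::runif(peaksPerSpectrum, 2, 6), 3)
                    Spectrum(id = specId, index = psmNo - 1L,
                        mz = round(mz, 5), intensity = int, msLevel = 2L,
                        precursor = Precursor(calcMz + mzNoise[[psmNo]],
                            as.integer(z)))
                })
                psmIdsOfPep <- c(psmIdsOfPep, psmId)
            }
            peptides[[pepId]] <- new("Peptide", id = pepId, sequence = sq,
                modifications = mods, psmIds = psmIdsOfPep)
            pepIds <- c(pepIds, pepId)
        }
        proteins[[protId]] <- new("Protein", id = protId,
            accession = accession, dbSequence = dbSeqs[[i]],
            passThreshold = TRUE,
            scores = ParamGroup(list(CvParam("MS", "MS:1001171",
                "Mascot:score", .fmtShortest(round(40 + 10 * i %% 7, 2))))),
            peptideIds = pepIds, isDecoy = decoyFlags[[i]])
    }

    metadata <- new("ExperimentMetadata",
        title = sprintf("Synthetic experiment seed=%d", seed),
        sourceFormat = "memory", instrument = ParamGroup(list(
            CvParam("MS", "MS:1000031", "instrument model",
                "synthetic instrument"))),
        protocols = list(new("ProteinDetectionProtocol",
            software = list(c("ProteoAccessGenerator", "0.9")),
            enzyme = "Trypsin", searchDatabaseName = "SYNTH-DB",
            searchDatabaseVersion = "1.0",
            threshold = ParamGroup(list(CvParam("MS", "MS:1001494",
                "no threshold"))))),
        contacts = list(), params = ParamGroup())

    new("SyntheticExperiment", seed = seed,
        generatorParams = list(nProteins = nProteins,
            peptidesPerProtein = peptidesPerProtein,
            psmsPerPeptide = psmsPerPeptide,
            peaksPerSpectrum = peaksPerSpectrum,
            decoyFraction = decoyFraction,
            failThresholdFraction = failThresholdFraction),
        proteins = proteins, proteinOrder = as.character(names(proteins)),
        peptides = peptides, psms = psms, spectra = spectra,
        spectrumOrder = as.character(names(spectra)), metadata = metadata)
}

#' View a synthetic experiment as an in-memory controller
#'
#' @param experiment a [SyntheticExperiment-class].
#' @return an [InMemoryController-class] with spectra and identifications.
#' @export
asController <- function(experiment) {
    .newInMemoryController("memory", "", spectra = experiment@spectra,
        proteins = experiment@proteins, peptides = experiment@peptides,
        psms = experiment@psms, metadata = experiment@metadata)
}

#' Write the experiment manifest
#'
#' A key=value text file recording the seed, the generator parameters and
#' all entity counts; byte-identical for equal seeds and parameters.
#'
#' @param experiment a [SyntheticExperiment-class].
#' @param path output path.
#' @export
writeManifest <- function(experiment, path) {
    p <- experiment@generatorParams
    lines <- c(
        sprintf("seed=%d", experiment@seed),
        sprintf("n_proteins=%d", p$nProteins),
        sprintf("peptides_per_protein=%d", p$peptidesPerProtein),
        sprintf("psms_per_peptide=%d", p$psmsPerPeptide),
        sprintf("peaks_per_spectrum=%d", p$peaksPerSpectrum),
        sprintf("decoy_fraction=%s", .fmtShortest(p$decoyFraction)),
        sprintf("fail_threshold_fraction=%s",
            .fmtShortest(p$failThresholdFraction)),
        sprintf("count_proteins=%d", length(experiment@proteins)),
        sprintf("count_decoy_proteins=%d", sum(vapply(experiment@proteins,
            slot, logical(1L), "isDecoy"))),
        sprintf("count_peptides=%d", length(experiment@peptides)),
        sprintf("count_psms=%d", length(experiment@psms)),
        sprintf("count_psms_passing=%d", sum(vapply(experiment@psms,
            slot, logical(1L), "passThreshold"))),
        sprintf("count_spectra=%d", length(experiment@spectra)))
    con <- file(path, "wb")
    on.exit(close(con))
    writeLines(lines, con, sep = "\n")
    invisible(path)
}

## ---- renderers -------------------------------------------------------------

.xmlEscape <- function(x) {
    x <- gsub("&", "&amp;", x, fixed = TRUE)
    x <- gsub("<", "&lt;", x, fixed = TRUE)
    x <- gsub(">", "&gt;", x, fixed = TRUE)
    gsub("\"", "&quot;", x, fixed = TRUE)
}

.renderMgf <- function(exp, path) {
    writeMgf(exp@spectra[exp@spectrumOrder], path)
}

## dta carries exactly one spectrum: the experiment's first (classic
## single-spectrum SEQUEST convention). The header stores M+H at charge z.
.renderDta <- function(exp, path) {
    s <- exp@spectra[[exp@spectrumOrder[[1L]]]]
    z <- s@precursor@charge
    mh <- s@precursor@mz * z - (z - 1L) * .PROTON_MASS
    lines <- c(paste(.fmtShortest(mh), z),
        paste(.fmtShortest(s@mz), .fmtShortest(s@intensity)))
    writeLines(lines, path)
}

.renderPkl <- function(exp, path) {
    out <- character()
    for (id in exp@spectrumOrder) {
        s <- exp@spectra[[id]]
        pint <- s@precursor@intensity
        out <- c(out, paste(.fmtShortest(s@precursor@mz),
            if (is.na(pint)) "0" else .fmtShortest(pint),
            s@precursor@charge),
            paste(.fmtShortest(s@mz), .fmtShortest(s@intensity)), "")
    }
    writeLines(out, path)
}

.renderMs2 <- function(exp, path) {
    out <- c("H\tCreationDate\t2015-01-01",
             "H\tExtractor\tProteoAccessGenerator")
    for (id in exp@spectrumOrder) {
        s <- exp@spectra[[id]]
        z <- s@precursor@charge
        mh <- s@precursor@mz * z - (z - 1L) * .PROTON_MASS
        out <- c(out,
            paste("S", s@id, s@id, .fmtShortest(s@precursor@mz)),
            paste("Z", z, .fmtShortest(mh)),
            paste(.fmtShortest(s@mz), .fmtShortest(s@intensity)))
    }
    writeLines(out, path)
}

.renderApl <- function(exp, path) {
    out <- character()
    for (id in exp@spectrumOrder) {
        s <- exp@spectra[[id]]
        out <- c(out, "peaklist start",
            paste0("mz=", .fmtShortest(s@precursor@mz)),
            paste0("charge=", s@precursor@charge),
            paste0("header=", s@id),
            paste(.fmtShortest(s@mz), .fmtShortest(s@intensity)),
            "peaklist end", "")
    }
    writeLines(out, path)
}

.renderMzml <- function(exp, path, zlib = TRUE) {
    n <- length(exp@spectrumOrder)
    proto <- if (length(exp@metadata@protocols))
        exp@metadata@protocols[[1L]] else new("ProteinDetectionProtocol")
    sw <- if (length(proto@software)) proto@software[[1L]]
        else c("unknown", "0")
    instCv <- vapply(exp@metadata@instrument@cvParams, function(p)
        sprintf(
            '        <cvParam cvRef="%s" accession="%s" name="%s"%s/>',
            p@cvLabel, p@accession, .xmlEscape(p@name),
            if (is.na(p@value)) ""
            else sprintf(' value="%s"', .xmlEscape(p@value))),
        character(1L))
    head <- c('<?xml version="1.0" encoding="UTF-8"?>',
        '<mzML xmlns="http://psi.hupo.org/ms/mzml" version="1.1.0">',
        '  <cvList count="1">',
        '    <cv id="MS" fullName="PSI-MS" URI="https://raw.githubusercontent.com/HUPO-PSI/psi-ms-CV/master/psi-ms.obo"/>',
        '  </cvList>',
        '  <softwareList count="1">',
        sprintf('    <software id="%s" version="%s"/>', sw[[1L]], sw[[2L]]),
        '  </softwareList>',
        '  <instrumentConfigurationList count="1">',
        '    <instrumentConfiguration id="IC1">', instCv,
        '    </instrumentConfiguration>',
        '  </instrumentConfigurationList>',
        '  <run id="run1">',
        sprintf('    <spectrumList count="%d">', n))
    con <- file(path, "wb")
    on.exit(close(con))
    writeLines(head, con, sep = "\n")
    compCv <- if (zlib)
        '          <cvParam cvRef="MS" accession="MS:1000574" name="zlib compression"/>'
    else
        '          <cvParam cvRef="MS" accession="MS:1000576" name="no compression"/>'
    for (i in seq_len(n)) {
        s <- exp@spectra[[exp@spectrumOrder[[i]]]]
        mzB <- encodeBinaryArray(s@mz, 64L, zlib, "little")
        intB <- encodeBinaryArray(s@intensity, 64L, zlib, "little")
        lines <- c(
            sprintf('      <spectrum index="%d" id="%s" defaultArrayLength="%d">',
                i - 1L, .xmlEscape(s@id), length(s@mz)),
            sprintf('        <cvParam cvRef="MS" accession="MS:1000511" name="ms level" value="%d"/>',
                s@msLevel))
        if (!is.null(s@precursor)) {
            p <- s@precursor
            lines <- c(lines,
                '        <precursorList count="1"><precursor><selectedIonList count="1"><selectedIon>',
                sprintf('          <cvParam cvRef="MS" accession="MS:1000744" name="selected ion m/z" value="%s"/>',
                    .fmtShortest(p@mz)),
                if (!is.na(p@charge)) sprintf(
                    '          <cvParam cvRef="MS" accession="MS:1000041" name="charge state" value="%d"/>',
                    p@charge),
                '        </selectedIon></selectedIonList></precursor></precursorList>')
        }
        lines <- c(lines,
            '        <binaryDataArrayList count="2">',
            sprintf('        <binaryDataArray encodedLength="%d">',
                nchar(mzB)),
            '          <cvParam cvRef="MS" accession="MS:1000523" name="64-bit float"/>',
            compCv,
            '          <cvParam cvRef="MS" accession="MS:1000514" name="m/z array"/>',
            sprintf('          <binary>%s</binary>', mzB),
            '        </binaryDataArray>',
            sprintf('        <binaryDataArray encodedLength="%d">',
                nchar(intB)),
            '          <cvParam cvRef="MS" accession="MS:1000523" name="64-bit float"/>',
            compCv,
            '          <cvParam cvRef="MS" accession="MS:1000515" name="intensity array"/>',
            sprintf('          <binary>%s</binary>', intB),
            '        </binaryDataArray>',
            '        </binaryDataArrayList>',
            '      </spectrum>')
        writeLines(lines, con, sep = "\n")
    }
    writeLines(c('    </spectrumList>', '  </run>', '</mzML>'), con,
        sep = "\n")
}

.renderMzxml <- function(exp, path, precision = 32L) {
    n <- length(exp@spectrumOrder)
    out <- c('<?xml version="1.0" encoding="UTF-8"?>',
        '<mzXML xmlns="http://sashimi.sourceforge.net/schema_revision/mzXML_3.2">',
        sprintf('  <msRun scanCount="%d">', n))
    for (i in seq_len(n)) {
        s <- exp@spectra[[exp@spectrumOrder[[i]]]]
        interleaved <- as.vector(rbind(s@mz, s@intensity))
        b64 <- encodeBinaryArray(interleaved, precision, FALSE, "big")
        p <- s@precursor
        out <- c(out,
            sprintf('    <scan num="%s" msLevel="%d" peaksCount="%d">',
                .xmlEscape(s@id), s@msLevel, length(s@mz)),
            if (!is.null(p)) sprintf(
                '      <precursorMz precursorCharge="%d">%s</precursorMz>',
                p@charge, .fmtShortest(p@mz)),
            sprintf('      <peaks precision="%d" byteOrder="network" pairOrder="m/z-int">%s</peaks>',
                precision, b64),
            '    </scan>')
    }
    writeLines(c(out, '  </msRun>', '</mzXML>'), path)
}

.mzdataSpectrumXml <- function(s, indent = "      ") {
    p <- s@precursor
    mzB <- encodeBinaryArray(s@mz, 64L, FALSE, "little")
    intB <- encodeBinaryArray(s@intensity, 64L, FALSE, "little")
    c(sprintf('%s<spectrum id="%s">', indent, .xmlEscape(s@id)),
      sprintf('%s  <spectrumDesc><spectrumSettings><spectrumInstrument msLevel="%d"/></spectrumSettings>',
          indent, s@msLevel),
      if (!is.null(p)) c(
          sprintf('%s  <precursorList count="1"><precursor msLevel="1" spectrumRef="0"><ionSelection>',
              indent),
          sprintf('%s    <cvParam cvLabel="psi" accession="PSI:1000040" name="MassToChargeRatio" value="%s"/>',
              indent, .fmtShortest(p@mz)),
          if (!is.na(p@charge)) sprintf(
              '%s    <cvParam cvLabel="psi" accession="PSI:1000041" name="ChargeState" value="%d"/>',
              indent, p@charge),
          sprintf('%s  </ionSelection></precursor></precursorList>',
              indent)),
      sprintf('%s  </spectrumDesc>', indent),
      sprintf('%s  <mzArrayBinary><data precision="64" endian="little" length="%d">%s</data></mzArrayBinary>',
          indent, length(s@mz), mzB),
      sprintf('%s  <intenArrayBinary><data precision="64" endian="little" length="%d">%s</data></intenArrayBinary>',
          indent, length(s@intensity), intB),
      sprintf('%s</spectrum>', indent))
}

.renderMzdata <- function(exp, path) {
    n <- length(exp@spectrumOrder)
    out <- c('<?xml version="1.0" encoding="UTF-8"?>',
        '<mzData version="1.05">',
        sprintf('  <spectrumList count="%d">', n))
    for (id in exp@spectrumOrder)
        out <- c(out, .mzdataSpectrumXml(exp@spectra[[id]], "    "))
    writeLines(c(out, '  </spectrumList>', '</mzData>'), path)
}

.renderMzIdentml <- function(exp, path) {
    proto <- exp@metadata@protocols[[1L]]
    sw <- proto@software[[1L]]
    out <- c('<?xml version="1.0" encoding="UTF-8"?>',
        '<MzIdentML xmlns="http://psidev.info/psi/pi/mzIdentML/1.1" version="1.1.0" id="MZID1">',
        '  <cvList><cv id="MS" fullName="PSI-MS"/><cv id="UNIMOD" fullName="UNIMOD"/></cvList>',
        '  <AnalysisSoftwareList>',
        sprintf('    <AnalysisSoftware id="AS1" name="%s" version="%s"/>',
            sw[[1L]], sw[[2L]]),
        '  </AnalysisSoftwareList>',
        '  <SequenceCollection>')
    for (pid in exp@proteinOrder) {
        pr <- exp@proteins[[pid]]
        out <- c(out, sprintf(
            '    <DBSequence id="DBSeq_%s" accession="%s">%s</DBSequence>',
            pr@accession, pr@accession,
            if (is.na(pr@dbSequence)) ""
            else sprintf("<Seq>%s</Seq>", pr@dbSequence)))
    }
    for (pepId in names(exp@peptides)) {
        pep <- exp@peptides[[pepId]]
        modXml <- vapply(pep@modifications, function(m) sprintf(
            '      <Modification location="%d" monoisotopicMassDelta="%s"><cvParam cvRef="UNIMOD" accession="%s" name="%s"/></Modification>',
            m@position, .fmtShortest(m@monoDelta), m@accession,
            .xmlEscape(m@name)), character(1L))
        out <- c(out,
            sprintf('    <Peptide id="%s">', pepId),
            sprintf('      <PeptideSequence>%s</PeptideSequence>',
                pep@sequence),
            modXml, '    </Peptide>')
    }
    ## one PeptideEvidence per (peptide, owning protein)
    evOfPep <- list()
    for (pid in exp@proteinOrder) {
        pr <- exp@proteins[[pid]]
        for (pepId in pr@peptideIds) {
            evId <- sprintf("PE_%s_%s", pepId, pr@accession)
            evOfPep[[pepId]] <- c(evOfPep[[pepId]], evId)
            out <- c(out, sprintf(
                '    <PeptideEvidence id="%s" peptide_ref="%s" dBSequence_ref="DBSeq_%s" isDecoy="%s"/>',
                evId, pepId, pr@accession,
                if (pr@isDecoy) "true" else "false"))
        }
    }
    thrCv <- vapply(proto@threshold@cvParams, function(p) sprintf(
        '        <cvParam cvRef="%s" accession="%s" name="%s"%s/>',
        p@cvLabel, p@accession, .xmlEscape(p@name),
        if (is.na(p@value)) "" else sprintf(' value="%s"',
            .xmlEscape(p@value))), character(1L))
    out <- c(out, '  </SequenceCollection>',
        '  <AnalysisProtocolCollection>',
        '    <SpectrumIdentificationProtocol id="SIP1" analysisSoftware_ref="AS1">',
        '      <Enzymes>',
        sprintf('        <Enzyme id="ENZ1" name="%s"/>', proto@enzyme),
        '      </Enzymes>',
        '      <Threshold>', thrCv, '      </Threshold>',
        '    </SpectrumIdentificationProtocol>',
        '  </AnalysisProtocolCollection>',
        '  <DataCollection>',
        '    <Inputs>',
        sprintf('      <SearchDatabase id="SDB1" name="%s" version="%s"/>',
            proto@searchDatabaseName, proto@searchDatabaseVersion),
        '    </Inputs>',
        '    <AnalysisData>',
        '      <SpectrumIdentificationList id="SIL1">')
    ## group PSMs by spectrum
    psmsBySpec <- list()
    pepOfPsm <- list()
    for (pepId in names(exp@peptides))
        for (psmId in exp@peptides[[pepId]]@psmIds)
            pepOfPsm[[psmId]] <- pepId
    for (psmId in names(exp@psms)) {
        ref <- exp@psms[[psmId]]@spectrumRef
        psmsBySpec[[ref]] <- c(psmsBySpec[[ref]], psmId)
    }
    sirNo <- 0L
    for (specRef in names(psmsBySpec)) {
        sirNo <- sirNo + 1L
        out <- c(out, sprintf(
            '        <SpectrumIdentificationResult id="SIR_%d" spectrumID="%s" spectraData_ref="SD1">',
            sirNo, .xmlEscape(specRef)))
        for (psmId in psmsBySpec[[specRef]]) {
            p <- exp@psms[[psmId]]
            scoreCv <- vapply(p@scores@cvParams, function(q) sprintf(
                '            <cvParam cvRef="%s" accession="%s" name="%s" value="%s"/>',
                q@cvLabel, q@accession, .xmlEscape(q@name),
                .xmlEscape(q@value)), character(1L))
            pepId <- pepOfPsm[[psmId]]
            out <- c(out, sprintf(
                '          <SpectrumIdentificationItem id="%s" rank="%d" chargeState="%d" experimentalMassToCharge="%s" calculatedMassToCharge="%s" peptide_ref="%s" passThreshold="%s">',
                psmId, p@rank, p@charge, .fmtShortest(p@experimentalMz),
                .fmtShortest(p@calculatedMz), pepId,
                if (p@passThreshold) "true" else "false"),
                vapply(evOfPep[[pepId]], function(e) sprintf(
                    '            <PeptideEvidenceRef peptideEvidence_ref="%s"/>',
                    e), character(1L)),
                scoreCv,
                '          </SpectrumIdentificationItem>')
        }
        out <- c(out, '        </SpectrumIdentificationResult>')
    }
    out <- c(out, '      </SpectrumIdentificationList>',
        '      <ProteinDetectionList id="PDL1">')
    pagNo <- 0L
    for (pid in exp@proteinOrder) {
        pr <- exp@proteins[[pid]]
        pagNo <- pagNo + 1L
        scoreCv <- vapply(pr@scores@cvParams, function(q) sprintf(
            '            <cvParam cvRef="%s" accession="%s" name="%s" value="%s"/>',
            q@cvLabel, q@accession, .xmlEscape(q@name),
            .xmlEscape(q@value)), character(1L))
        pepHyp <- unlist(lapply(pr@peptideIds, function(pepId) {
            evId <- sprintf("PE_%s_%s", pepId, pr@accession)
            refs <- vapply(exp@peptides[[pepId]]@psmIds, function(i)
                sprintf('              <SpectrumIdentificationItemRef spectrumIdentificationItem_ref="%s"/>',
                    i), character(1L))
            c(sprintf('            <PeptideHypothesis peptideEvidence_ref="%s">',
                evId), refs, '            </PeptideHypothesis>')
        }))
        out <- c(out,
            sprintf('        <ProteinAmbiguityGroup id="PAG_%d">', pagNo),
            sprintf('          <ProteinDetectionHypothesis id="PDH_%s" dBSequence_ref="DBSeq_%s" passThreshold="%s">',
                pr@accession, pr@accession,
                if (pr@passThreshold) "true" else "false"),
            pepHyp, scoreCv,
            '          </ProteinDetectionHypothesis>',
            '        </ProteinAmbiguityGroup>')
    }
    out <- c(out, '      </ProteinDetectionList>', '    </AnalysisData>',
        '  </DataCollection>', '</MzIdentML>')
    writeLines(out, path)
}

.renderPrideXml <- function(exp, path) {
    out <- c('<?xml version="1.0" encoding="UTF-8"?>',
        '<ExperimentCollection version="2.1">',
        '  <Experiment>',
        sprintf('    <Title>%s</Title>',
            .xmlEscape(exp@metadata@title)),
        sprintf('    <mzData version="1.05"><spectrumList count="%d">',
            length(exp@spectrumOrder)))
    for (id in exp@spectrumOrder)
        out <- c(out, .mzdataSpectrumXml(exp@spectra[[id]], "      "))
    out <- c(out, '    </spectrumList></mzData>')
    for (pid in exp@proteinOrder) {
        pr <- exp@proteins[[pid]]
        out <- c(out, '    <GelFreeIdentification>',
            sprintf('      <Accession>%s</Accession>', pr@accession))
        for (pepId in pr@peptideIds) {
            pep <- exp@peptides[[pepId]]
            for (psmId in pep@psmIds) {
                p <- exp@psms[[psmId]]
                modXml <- unlist(lapply(p@modifications, function(m) c(
                    '        <ModificationItem>',
                    sprintf('          <ModLocation>%d</ModLocation>',
                        m@position),
                    sprintf('          <ModAccession>%s</ModAccession>',
                        m@accession),
                    sprintf('          <ModName>%s</ModName>',
                        .xmlEscape(m@name)),
                    sprintf('          <ModMonoDelta>%s</ModMonoDelta>',
                        .fmtShortest(m@monoDelta)),
                    '        </ModificationItem>')))
                scoreCv <- vapply(p@scores@cvParams, function(q) sprintf(
                    '          <cvParam cvLabel="%s" accession="%s" name="%s" value="%s"/>',
                    q@cvLabel, q@accession, .xmlEscape(q@name),
                    .xmlEscape(q@value)), character(1L))
                out <- c(out, '      <PeptideItem>',
                    sprintf('        <Sequence>%s</Sequence>', p@sequence),
                    sprintf('        <SpectrumReference>%s</SpectrumReference>',
                        .xmlEscape(p@spectrumRef)),
                    modXml,
                    '        <additional>',
                    sprintf('          <cvParam cvLabel="PSI" accession="PSI:1000040" name="MassToChargeRatio" value="%s"/>',
                        .fmtShortest(p@experimentalMz)),
                    sprintf('          <cvParam cvLabel="PSI" accession="PSI:1000041" name="ChargeState" value="%d"/>',
                        p@charge),
                    scoreCv,
                    '        </additional>',
                    '      </PeptideItem>')
            }
        }
        out <- c(out, '      <Score>100.0</Score>',
            if (pr@isDecoy) c('      <additional>',
                '        <cvParam cvLabel="PRIDE" accession="PRIDE:0000303" name="Decoy hit"/>',
                '      </additional>'),
            '    </GelFreeIdentification>')
    }
    out <- c(out, '  </Experiment>', '</ExperimentCollection>')
    writeLines(out, path)
}

#' Render a synthetic experiment to a supported format
#'
#' The master round-trip property: the emitted file parses back, via the
#' corresponding reader, to a model equal to the experiment (native ids are
#' preserved where the format carries ids; dta and pkl synthesise
#' `index=<ordinal>` ids). Identification formats require identifications;
#' rendering identifications to a spectra-only format is a capability
#' error. `mztab` renders through [convertToMzTab()] with no-op filters, so
#' the PSM row count equals the generated PSM count.
#'
#' @param experiment a [SyntheticExperiment-class].
#' @param formatTag one of `FORMAT_TAGS`.
#' @param path output path.
#' @export
renderExperiment <- function(experiment, formatTag, path) {
    formatTag <- match.arg(formatTag, FORMAT_TAGS)
    identFormats <- c("mzidentml", "pridexml", "mztab")
    if (formatTag %in% identFormats && !length(experiment@proteins))
        .errCond(sprintf(
            "cannot render an experiment without identifications to %s",
            formatTag), "capabilityError")
    if (!formatTag %in% identFormats && !length(experiment@spectra))
        .errCond(sprintf(
            "cannot render an experiment without spectra to %s", formatTag),
            "capabilityError")
    switch(formatTag,
        mgf = .renderMgf(experiment, path),
        dta = .renderDta(experiment, path),
        pkl = .renderPkl(experiment, path),
        ms2 = .renderMs2(experiment, path),
        apl = .renderApl(experiment, path),
        mzml = .renderMzml(experiment, path),
        mzxml = .renderMzxml(experiment, path),
        mzdata = .renderMzdata(experiment, path),
        mzidentml = .renderMzIdentml(experiment, path),
        pridexml = .renderPrideXml(experiment, path),
        mztab = {
            doc <- convertToMzTab(asController(experiment),
                QualityFilter(requirePassThreshold = FALSE,
                    maxRank = .Machine$integer.max, dropDecoys = FALSE,
                    minPeptidesPerProtein = 1L))
            writeMzTab(doc, path)
        })
    invisible(path)
}

setMethod("show", "SyntheticExperiment", function(object) {
    cat(sprintf(
        "SyntheticExperiment seed=%d: %d proteins, %d peptides, %d PSMs, %d spectra\n",
        object@seed, length(object@proteins), length(object@peptides),
        length(object@psms), length(object@spectra)))
})
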