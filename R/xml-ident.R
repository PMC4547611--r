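## Readers for the identification XML formats.
##
## Supported subsets:
##   mzIdentML 1.1.0 - SequenceCollection (DBSequence, Peptide with
##       Modification monoisotopicMassDelta + location, PeptideEvidence),
##       SpectrumIdentificationList (Result/Item: rank, chargeState,
##       experimental/calculatedMassToCharge, passThreshold, cvParam
##       scores), ProteinDetectionList (each ProteinDetectionHypothesis
##       becomes one Protein; the ambiguity group id is kept as a cvParam),
##       AnalysisProtocolCollection (software, Enzymes, SearchDatabase,
##       Threshold).
##   PRIDE XML 2.1 - embedded mzData block (spectra), GelFree / TwoDimensional
##       identifications with PeptideItem (Sequence, SpectrumReference,
##       ModificationItem), Score, experiment metadata.
## Unknown elements are skipped with no error.

.xmlAttrOr <- function(node, attr, default = NA_character_) {
    v <- xml2::xml_attr(node, attr)
    if (is.na(v)) default else v
}

.xmlModifications <- function(pepNode) {
    lapply(xml2::xml_find_all(pepNode, "./Modification"), function(m) {
        cv <- xml2::xml_find_first(m, "./cvParam")
        acc <- if (inherits(cv, "xml_missing")) "MOD:unknown"
            else xml2::xml_attr(cv, "accession")
        nm <- if (inherits(cv, "xml_missing")) "unknown modification"
            else xml2::xml_attr(cv, "name")
        Modification(acc, nm,
            as.numeric(xml2::xml_attr(m, "monoisotopicMassDelta")),
            as.integer(xml2::xml_attr(m, "location")))
    })
}

#' Parse an mzIdentML 1.1 file
#'
#' Builds the full protein -> peptide -> PSM graph with referential closure;
#' the analysis protocol (software, enzyme, search database, threshold)
#' populates a [ProteinDetectionProtocol-class]; decoy flags come from
#' `PeptideEvidence/@isDecoy`. Dangling `peptide_ref` / `dBSequence_ref`
#' references fail with an error naming the reference.
#'
#' @param path mzIdentML file.
#' @return an [InMemoryController-class] with the identifications
#'   capability.
#' @export
parseMzIdentML <- function(path) {
    doc <- xml2::read_xml(path)
    xml2::xml_ns_strip(doc)

    dbseq <- list()   # id -> list(accession, seq)
    for (n in xml2::xml_find_all(doc, ".//SequenceCollection/DBSequence"))
        dbseq[[xml2::xml_attr(n, "id")]] <- list(
            accession = xml2::xml_attr(n, "accession"),
            seq = {
                s <- xml2::xml_find_first(n, "./Seq")
                if (inherits(s, "xml_missing")) NA_character_
                else xml2::xml_text(s)
            })

    pepDefs <- list() # id -> list(sequence, modifications)
    for (n in xml2::xml_find_all(doc, ".//SequenceCollection/Peptide"))
        pepDefs[[xml2::xml_attr(n, "id")]] <- list(
            sequence = xml2::xml_text(
                xml2::xml_find_first(n, "./PeptideSequence")),
            modifications = .xmlModifications(n))

    evidence <- list() # id -> list(peptideRef, dbRef, isDecoy)
    for (n in xml2::xml_find_all(doc,
        ".//SequenceCollection/PeptideEvidence")) {
        pr <- xml2::xml_attr(n, "peptide_ref")
        dr <- xml2::xml_attr(n, "dBSequence_ref")
        if (is.null(pepDefs[[pr]]))
            .errCond(sprintf("dangling peptide_ref '%s'", pr), "formatError")
        if (is.null(dbseq[[dr]]))
            .errCond(sprintf("dangling dBSequence_ref '%s'", dr),
                "formatError")
        evidence[[xml2::xml_attr(n, "id")]] <- list(peptideRef = pr,
            dbRef = dr,
            isDecoy = identical(.xmlAttrOr(n, "isDecoy", "false"), "true"))
    }

    ## PSMs from SpectrumIdentificationList
    psms <- list()
    psmEvidence <- list() # psm id -> first evidence id
    for (res in xml2::xml_find_all(doc, ".//SpectrumIdentificationResult")) {
        spectrumID <- .xmlAttrOr(res, "spectrumID")
        for (item in xml2::xml_find_all(res,
            "./SpectrumIdentificationItem")) {
            id <- xml2::xml_attr(item, "id")
            pr <- xml2::xml_attr(item, "peptide_ref")
            if (is.null(pepDefs[[pr]]))
                .errCond(sprintf("dangling peptide_ref '%s'", pr),
                    "formatError")
            evRefs <- xml2::xml_attr(xml2::xml_find_all(item,
                "./PeptideEvidenceRef"), "peptideEvidence_ref")
            isDecoy <- FALSE
            if (length(evRefs)) {
                if (is.null(evidence[[evRefs[[1L]]]]))
                    .errCond(sprintf(
                        "dangling peptideEvidence_ref '%s'", evRefs[[1L]]),
                        "formatError")
                isDecoy <- evidence[[evRefs[[1L]]]]$isDecoy
                psmEvidence[[id]] <- evRefs[[1L]]
            }
            calc <- suppressWarnings(as.numeric(
                xml2::xml_attr(item, "calculatedMassToCharge")))
            psms[[id]] <- new("PSM", id = id,
                sequence = pepDefs[[pr]]$sequence,
                modifications = pepDefs[[pr]]$modifications,
                spectrumRef = spectrumID,
                charge = as.integer(xml2::xml_attr(item, "chargeState")),
                experimentalMz = as.numeric(
                    xml2::xml_attr(item, "experimentalMassToCharge")),
                calculatedMz = calc,
                rank = as.integer(xml2::xml_attr(item, "rank")),
                passThreshold = identical(
                    .xmlAttrOr(item, "passThreshold", "true"), "true"),
                scores = ParamGroup(.xmlCvParams(item),
                    .xmlUserParams(item)),
                isDecoy = isDecoy)
            attr(psms[[id]], "peptideRef") <- pr
        }
    }

    ## Peptides: one per Peptide definition, linking its PSMs
    psmsByPep <- split(names(psms),
        vapply(psms, function(p) attr(p, "peptideRef"), character(1L)))
    peptides <- list()
    for (pid in names(pepDefs)) {
        ids <- psmsByPep[[pid]]
        if (is.null(ids)) next   # unreferenced definition: skip
        peptides[[pid]] <- new("Peptide", id = pid,
            sequence = pepDefs[[pid]]$sequence,
            modifications = pepDefs[[pid]]$modifications, psmIds = ids)
    }

    ## Proteins from ProteinDetectionList (hypotheses flattened)
    proteins <- list()
    for (pag in xml2::xml_find_all(doc, ".//ProteinAmbiguityGroup")) {
        groupId <- xml2::xml_attr(pag, "id")
        for (pdh in xml2::xml_find_all(pag,
            "./ProteinDetectionHypothesis")) {
            dr <- xml2::xml_attr(pdh, "dBSequence_ref")
            if (is.null(dbseq[[dr]]))
                .errCond(sprintf("dangling dBSequence_ref '%s'", dr),
                    "formatError")
            evRefs <- xml2::xml_attr(xml2::xml_find_all(pdh,
                "./PeptideHypothesis"), "peptideEvidence_ref")
            pepRefs <- unique(vapply(evRefs, function(e) {
                if (is.null(evidence[[e]]))
                    .errCond(sprintf(
                        "dangling peptideEvidence_ref '%s'", e),
                        "formatError")
                evidence[[e]]$peptideRef
            }, character(1L)))
            pepRefs <- pepRefs[pepRefs %in% names(peptides)]
            decoys <- vapply(evRefs,
                function(e) evidence[[e]]$isDecoy, logical(1L))
            scoreCvs <- c(.xmlCvParams(pdh), list(CvParam("MS",
                "MS:1002470", "protein group id", groupId)))
            id <- xml2::xml_attr(pdh, "id")
            proteins[[id]] <- new("Protein", id = id,
                accession = dbseq[[dr]]$accession,
                dbSequence = dbseq[[dr]]$seq,
                passThreshold = identical(
                    .xmlAttrOr(pdh, "passThreshold", "true"), "true"),
                scores = ParamGroup(scoreCvs),
                peptideIds = unname(pepRefs),
                isDecoy = length(decoys) > 0 && all(decoys))
        }
    }

    ## protocol: software, enzyme, search database, threshold
    software <- lapply(xml2::xml_find_all(doc, ".//AnalysisSoftware"),
        function(n) c(.xmlAttrOr(n, "name", xml2::xml_attr(n, "id")),
            .xmlAttrOr(n, "version")))
    enzymeNode <- xml2::xml_find_first(doc, ".//Enzymes/Enzyme")
    enzyme <- if (inherits(enzymeNode, "xml_missing")) NA_character_
        else {
            nm <- xml2::xml_attr(enzymeNode, "name")
            if (is.na(nm)) {
                cv <- xml2::xml_find_first(enzymeNode, ".//EnzymeName/cvParam")
                if (!inherits(cv, "xml_missing"))
                    nm <- xml2::xml_attr(cv, "name")
            }
            nm
        }
    sdb <- xml2::xml_find_first(doc, ".//SearchDatabase")
    thr <- xml2::xml_find_first(doc,
        ".//SpectrumIdentificationProtocol/Threshold")
    protocol <- new("ProteinDetectionProtocol", software = software,
        enzyme = enzyme,
        searchDatabaseName = if (inherits(sdb, "xml_missing")) NA_character_
            else .xmlAttrOr(sdb, "name", xml2::xml_attr(sdb, "id")),
        searchDatabaseVersion = if (inherits(sdb, "xml_missing"))
            NA_character_ else .xmlAttrOr(sdb, "version"),
        threshold = if (inherits(thr, "xml_missing")) ParamGroup()
            else ParamGroup(.xmlCvParams(thr), .xmlUserParams(thr)))

    psms <- lapply(psms, function(p) { attr(p, "peptideRef") <- NULL; p })
    .newInMemoryController("mzidentml", path, proteins = proteins,
        peptides = peptides, psms = psms,
        metadata = new("ExperimentMetadata", sourceFormat = "mzidentml",
            instrument = ParamGroup(), protocols = list(protocol),
            params = ParamGroup()))
}

## ---- PRIDE XML ------------------------------------------------------------

.prideModifications <- function(pepItem) {
    lapply(xml2::xml_find_all(pepItem, "./ModificationItem"), function(m) {
        txt <- function(x) {
            n <- xml2::xml_find_first(m, x)
            if (inherits(n, "xml_missing")) NA_character_
            else xml2::xml_text(n)
        }
        Modification(
            accession = {
                a <- txt("./ModAccession")
                if (is.na(a)) "MOD:unknown" else a
            },
            name = {
                n <- txt("./ModName")
                if (is.na(n)) "unknown modification" else n
            },
            monoDelta = as.numeric(txt("./ModMonoDelta")),
            position = as.integer(txt("./ModLocation")))
    })
}

#' Parse a PRIDE XML file
#'
#' One controller exposing both the spectra (embedded mzData block, parsed
#' with the mzData machinery) and the identifications (GelFree /
#' TwoDimensional). Each `PeptideItem` is one PSM; peptides are grouped per
#' protein and sequence. A `SpectrumReference` naming an absent spectrum is
#' a logged warning and the link stays unresolved, since PRIDE XML in the
#' wild is inconsistent. The decoy flag is the PRIDE decoy-hit cvParam
#' (PRIDE:0000303).
#'
#' @param path PRIDE XML file.
#' @return an [InMemoryController-class] with spectra and identifications.
#' @export
parsePrideXml <- function(path) {
    doc <- xml2::read_xml(path)
    xml2::xml_ns_strip(doc)
    mzdataNode <- xml2::xml_find_first(doc, ".//mzData")
    spectra <- if (inherits(mzdataNode, "xml_missing")) list()
        else .mzdataSpectraFromDoc(mzdataNode)
    spectrumIdSet <- vapply(spectra, function(s) s@id, character(1L))

    proteins <- list(); peptides <- list(); psms <- list()
    idNodes <- xml2::xml_find_all(doc,
        ".//GelFreeIdentification | .//TwoDimensionalIdentification")
    for (gi in seq_along(idNodes)) {
        idn <- idNodes[[gi]]
        txt <- function(x, node = idn) {
            n <- xml2::xml_find_first(node, x)
            if (inherits(n, "xml_missing")) NA_character_
            else xml2::xml_text(n)
        }
        accession <- txt("./Accession")
        protId <- sprintf("PRIDE_protein_%d", gi)
        addl <- xml2::xml_find_first(idn, "./additional")
        protCvs <- if (inherits(addl, "xml_missing")) list()
            else .xmlCvParams(addl)
        isDecoy <- any(vapply(protCvs,
            function(p) p@accession == "PRIDE:0000303", logical(1L)))
        score <- txt("./Score")
        scoreCvs <- protCvs
        if (!is.na(score))
            scoreCvs <- c(scoreCvs, list(CvParam("PRIDE", "PRIDE:0000069",
                "Mascot score", score)))
        pepIdsOfProt <- character()
        bySeq <- list()   # sequence -> psm ids, in file order
        pepNodes <- xml2::xml_find_all(idn, "./PeptideItem")
        for (pi in seq_along(pepNodes)) {
            pn <- pepNodes[[pi]]
            sequence <- txt("./Sequence", pn)
            psmId <- sprintf("%s_psm_%d", protId, pi)
            specRef <- txt("./SpectrumReference", pn)
            if (!is.na(specRef) && length(spectrumIdSet) &&
                !specRef %in% spectrumIdSet) {
                message(sprintf(
                    "PeptideItem references absent spectrum '%s'; link left unresolved",
                    specRef))
                specRef <- NA_character_
            }
            pAddl <- xml2::xml_find_first(pn, "./additional")
            pCvs <- if (inherits(pAddl, "xml_missing")) list()
                else .xmlCvParams(pAddl)
            num <- function(acc, default = NA_real_) {
                v <- .cvValue(pCvs, acc)
                if (is.na(v)) default else as.numeric(v)
            }
            charge <- num("PSI:1000041")
            if (is.na(charge)) charge <- num("MS:1000041", 2)
            expMz <- num("PSI:1000040")
            if (is.na(expMz)) expMz <- num("MS:1000744")
            if (is.na(expMz)) expMz <- 1   # PRIDE XML may omit the m/z
            psms[[psmId]] <- new("PSM", id = psmId, sequence = sequence,
                modifications = .prideModifications(pn),
                spectrumRef = specRef, charge = as.integer(charge),
                experimentalMz = expMz, rank = 1L, passThreshold = TRUE,
                scores = ParamGroup(pCvs), isDecoy = isDecoy)
            bySeq[[sequence]] <- c(bySeq[[sequence]], psmId)
        }
        for (sq in names(bySeq)) {
            pepId <- sprintf("%s_pep_%s", protId, sq)
            firstPsm <- psms[[bySeq[[sq]][[1L]]]]
            peptides[[pepId]] <- new("Peptide", id = pepId, sequence = sq,
                modifications = firstPsm@modifications,
                psmIds = bySeq[[sq]])
            pepIdsOfProt <- c(pepIdsOfProt, pepId)
        }
        proteins[[protId]] <- new("Protein", id = protId,
            accession = accession,
            passThreshold = TRUE, scores = ParamGroup(scoreCvs),
            peptideIds = pepIdsOfProt, isDecoy = isDecoy)
    }

    title <- {
        t <- xml2::xml_find_first(doc, ".//Title")
        if (inherits(t, "xml_missing")) NA_character_ else xml2::xml_text(t)
    }
    .newInMemoryController("pridexml", path, spectra = spectra,
        proteins = proteins, peptides = peptides, psms = psms,
        metadata = new("ExperimentMetadata", title = title,
            sourceFormat = "pridexml", instrument = ParamGroup(),
            params = ParamGroup()))
}
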