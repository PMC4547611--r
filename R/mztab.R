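## mzTab 1.0: document model, converter from identification controllers with
## quality filters, writer, parser and structural checker.
##
## All table cells are kept as strings exactly as serialised ("null" maps to
## NA in the model), which makes write -> parse the identity and repeated
## writes byte-stable.

.MZTAB_NULL <- "null"

.cellOrNull <- function(x) {
    x <- as.character(x)
    ifelse(is.na(x) | !nzchar(x), .MZTAB_NULL, x)
}

.nullToNA <- function(x) ifelse(x == .MZTAB_NULL, NA_character_, x)

.mztabParam <- function(cvLabel, accession, name, value = "") {
    sprintf("[%s, %s, %s, %s]",
        ifelse(is.na(cvLabel), "", cvLabel),
        ifelse(is.na(accession), "", accession),
        ifelse(is.na(name), "", name),
        ifelse(is.na(value), "", value))
}

#' Construct an mzTab document
#'
#' @param metadata ordered named list of MTD key/value strings. Must include
#'   `mzTab-version`, `mzTab-mode` and `mzTab-type`.
#' @param proteinTable,psmTable,peptideTable data.frames of character
#'   columns (`NA` = mzTab "null").
#' @return an [MzTabDocument-class].
#' @export
MzTabDocument <- function(metadata = list(`mzTab-version` = "1.0",
        `mzTab-mode` = "Complete", `mzTab-type` = "Identification"),
        proteinTable = data.frame(), psmTable = data.frame(),
        peptideTable = data.frame()) {
    new("MzTabDocument", metadata = metadata, proteinTable = proteinTable,
        psmTable = psmTable, peptideTable = peptideTable)
}

setMethod("show", "MzTabDocument", function(object) {
    cat(sprintf(
        "MzTabDocument (%s, %s): %d MTD lines, %d PRT rows, %d PSM rows\n",
        object@metadata[["mzTab-mode"]], object@metadata[["mzTab-type"]],
        length(object@metadata), nrow(object@proteinTable),
        nrow(object@psmTable)))
})

## ---- quality filters -------------------------------------------------------

#' Apply identification-quality filters to a controller
#'
#' The documented filter order is:
#' 1. drop decoy proteins and decoy PSMs (`dropDecoys`);
#' 2. drop PSMs failing the search threshold (`requirePassThreshold`);
#' 3. drop PSMs with rank greater than `maxRank`;
#' 4. drop proteins failing their detection threshold;
#' 5. drop proteins whose surviving distinct-peptide count is below
#'    `minPeptidesPerProtein` (a peptide survives while it keeps at least
#'    one surviving PSM).
#'
#' One PSM row is emitted per surviving (PSM, protein) pair.
#'
#' @param controller identification-capable controller.
#' @param filters a [QualityFilter-class].
#' @return list with `proteins` (list of kept Protein with surviving
#'   peptide ids), `peptides`, `psms` (kept, named by id), `rows`
#'   (data.frame psmId/accession/proteinId in emission order) and `summary`
#'   (named counts before/after each stage).
#' @export
applyQualityFilters <- function(controller, filters = QualityFilter()) {
    if (!hasIdentifications(controller))
        .errCond("controller has no identification capability",
            "capabilityError")
    protIds <- proteinIds(controller)
    proteins <- lapply(protIds, function(i) getProtein(controller, i))
    names(proteins) <- protIds
    peptides <- list(); psms <- list()
    for (p in proteins) for (pepId in p@peptideIds) {
        if (is.null(peptides[[pepId]])) {
            pep <- getPeptide(controller, pepId)
            peptides[[pepId]] <- pep
            for (psmId in pep@psmIds)
                if (is.null(psms[[psmId]]))
                    psms[[psmId]] <- getPSM(controller, psmId)
        }
    }
    summary <- c(proteins_in = length(proteins), psms_in = length(psms))

    keepPsm <- vapply(psms, function(x) TRUE, logical(1L))
    keepProt <- vapply(proteins, function(x) TRUE, logical(1L))
    if (filters@dropDecoys) {
        keepPsm <- keepPsm & !vapply(psms, slot, logical(1L), "isDecoy")
        keepProt <- keepProt &
            !vapply(proteins, slot, logical(1L), "isDecoy")
    }
    summary <- c(summary, psms_after_decoy = sum(keepPsm),
        proteins_after_decoy = sum(keepProt))
    if (filters@requirePassThreshold)
        keepPsm <- keepPsm &
            vapply(psms, slot, logical(1L), "passThreshold")
    summary <- c(summary, psms_after_threshold = sum(keepPsm))
    keepPsm <- keepPsm &
        vapply(psms, slot, integer(1L), "rank") <= filters@maxRank
    summary <- c(summary, psms_after_rank = sum(keepPsm))
    keepProt <- keepProt &
        vapply(proteins, slot, logical(1L), "passThreshold")
    summary <- c(summary, proteins_after_threshold = sum(keepProt))

    survivingPsms <- names(psms)[keepPsm]
    outProteins <- list(); rows <- list()
    for (pid in names(proteins)[keepProt]) {
        prot <- proteins[[pid]]
        keptPeps <- character()
        for (pepId in prot@peptideIds) {
            ids <- intersect(peptides[[pepId]]@psmIds, survivingPsms)
            if (length(ids)) keptPeps <- c(keptPeps, pepId)
        }
        if (length(keptPeps) < filters@minPeptidesPerProtein) next
        prot@peptideIds <- keptPeps
        outProteins[[pid]] <- prot
        for (pepId in keptPeps)
            for (psmId in intersect(peptides[[pepId]]@psmIds,
                survivingPsms))
                rows[[length(rows) + 1L]] <- data.frame(psmId = psmId,
                    accession = prot@accession, proteinId = pid,
                    stringsAsFactors = FALSE)
    }
    summary <- c(summary, proteins_out = length(outProteins),
        psm_rows_out = length(rows))
    rows <- if (length(rows)) do.call(rbind, rows)
        else data.frame(psmId = character(), accession = character(),
            proteinId = character(), stringsAsFactors = FALSE)
    list(proteins = outProteins,
        peptides = peptides[unique(unlist(lapply(outProteins,
            slot, "peptideIds")))],
        psms = psms[unique(rows$psmId)], rows = rows, summary = summary)
}

## ---- conversion ------------------------------------------------------------

.numericScoreParams <- function(group) {
    keep <- list()
    for (p in group@cvParams)
        if (!is.na(p@value) &&
            !is.na(suppressWarnings(as.numeric(p@value))))
            keep[[length(keep) + 1L]] <- p
    keep
}

.collectScoreDefs <- function(objects) {
    defs <- list()
    for (obj in objects)
        for (p in .numericScoreParams(obj@scores))
            if (is.null(defs[[p@accession]]))
                defs[[p@accession]] <- p
    defs
}

.modString <- function(mods) {
    if (!length(mods)) return(.MZTAB_NULL)
    paste(vapply(mods, function(m)
        sprintf("%d-%s", m@position, m@accession), character(1L)),
        collapse = ",")
}

#' Convert an identification controller to an mzTab 1.0 document
#'
#' Applies [applyQualityFilters()] (see there for the documented filter
#' order), then emits one PSM row per surviving (PSM, protein) pair and one
#' PRT row per surviving protein. The metadata section is populated from
#' the controller's [ExperimentMetadata-class] (software, search database
#' and enzyme as fixed-form MTD lines); search-engine scores are exported
#' in declaration order as `search_engine_score[n]` with their cvParam
#' accessions preserved in the metadata. Absent values are written as
#' `"null"`.
#'
#' @param controller identification-capable controller.
#' @param filters a [QualityFilter-class]; the defaults
#'   (`requirePassThreshold = TRUE`, `maxRank = 1`, `dropDecoys = TRUE`,
#'   `minPeptidesPerProtein = 1`) mirror common practice for "high-quality"
#'   identification export and are all overridable.
#' @return an [MzTabDocument-class]; the per-stage filter counts are
#'   attached as `attr(doc, "filterSummary")`.
#' @export
convertToMzTab <- function(controller, filters = QualityFilter()) {
    res <- applyQualityFilters(controller, filters)
    md <- experimentMetadata(controller)
    protocol <- if (length(md@protocols)) md@protocols[[1L]]
        else new("ProteinDetectionProtocol")

    psmScoreDefs <- .collectScoreDefs(res$psms[unique(res$rows$psmId)])
    if (!length(psmScoreDefs))
        psmScoreDefs <- list("MS:1001153" = CvParam("MS", "MS:1001153",
            "search engine specific score"))
    protScoreDefs <- .collectScoreDefs(res$proteins)
    if (!length(protScoreDefs))
        protScoreDefs <- psmScoreDefs[1L]

    software <- if (length(protocol@software))
        vapply(protocol@software, function(s)
            paste(s[!is.na(s)], collapse = " "), character(1L))
        else "unknown"
    searchEngine <- .mztabParam("MS", "MS:1001456", "analysis software",
        software[[1L]])

    meta <- list(
        `mzTab-version` = "1.0",
        `mzTab-mode` = "Complete",
        `mzTab-type` = "Identification",
        description = sprintf("Converted from %s by ProteoAccess",
            formatTag(controller)))
    meta[["ms_run[1]-location"]] <-
        if (nzchar(controller@path) && !is.na(controller@path))
            paste0("file://", controller@path) else .MZTAB_NULL
    for (i in seq_along(software))
        meta[[sprintf("software[%d]", i)]] <-
            .mztabParam("MS", "MS:1001456", "analysis software",
                software[[i]])
    for (i in seq_along(psmScoreDefs)) {
        p <- psmScoreDefs[[i]]
        meta[[sprintf("psm_search_engine_score[%d]", i)]] <-
            .mztabParam(p@cvLabel, p@accession, p@name)
    }
    for (i in seq_along(protScoreDefs)) {
        p <- protScoreDefs[[i]]
        meta[[sprintf("protein_search_engine_score[%d]", i)]] <-
            .mztabParam(p@cvLabel, p@accession, p@name)
    }
    meta[["fixed_mod[1]"]] <- .mztabParam("MS", "MS:1002453",
        "No fixed modifications searched")
    meta[["variable_mod[1]"]] <- .mztabParam("MS", "MS:1002454",
        "No variable modifications searched")
    db <- protocol@searchDatabaseName
    meta[["custom[1]"]] <- .mztabParam(NA, NA, "search database",
        if (is.na(db)) "unknown" else paste(stats::na.omit(
            c(db, protocol@searchDatabaseVersion)), collapse = " "))
    meta[["custom[2]"]] <- .mztabParam(NA, NA, "enzyme",
        if (is.na(protocol@enzyme)) "unknown" else protocol@enzyme)

    dbName <- .cellOrNull(db)
    dbVer <- .cellOrNull(protocol@searchDatabaseVersion)
    scoreOf <- function(group, def) {
        p <- cvParamByAccession(group, def@accession)
        if (is.null(p)) .MZTAB_NULL else .cellOrNull(p@value)
    }

    prt <- lapply(res$proteins, function(prot) {
        row <- c(accession = prot@accession, description = .MZTAB_NULL,
            taxid = .MZTAB_NULL, species = .MZTAB_NULL,
            database = dbName, database_version = dbVer,
            search_engine = searchEngine)
        for (i in seq_along(protScoreDefs))
            row[[sprintf("best_search_engine_score[%d]", i)]] <-
                scoreOf(prot@scores, protScoreDefs[[i]])
        nPsms <- length(unique(
            res$rows$psmId[res$rows$proteinId == prot@id]))
        c(row, ambiguity_members = .MZTAB_NULL, modifications = .MZTAB_NULL,
            `opt_global_pass_threshold` =
                if (prot@passThreshold) "1" else "0",
            `opt_global_decoy` = if (prot@isDecoy) "1" else "0",
            `opt_global_num_psms` = as.character(nPsms))
    })

    seqProteinCount <- tapply(res$rows$accession,
        vapply(res$rows$psmId, function(i) res$psms[[i]]@sequence,
            character(1L)),
        function(a) length(unique(a)))
    psm <- lapply(seq_len(nrow(res$rows)), function(k) {
        p <- res$psms[[res$rows$psmId[[k]]]]
        row <- c(PSM_ID = p@id, sequence = p@sequence,
            accession = res$rows$accession[[k]],
            unique = if (seqProteinCount[[p@sequence]] > 1L) "0" else "1",
            database = dbName, database_version = dbVer,
            search_engine = searchEngine)
        for (i in seq_along(psmScoreDefs))
            row[[sprintf("search_engine_score[%d]", i)]] <-
                scoreOf(p@scores, psmScoreDefs[[i]])
        c(row, modifications = .modString(p@modifications),
            retention_time = .MZTAB_NULL,
            charge = as.character(p@charge),
            exp_mass_to_charge = .fmtShortest(p@experimentalMz),
            calc_mass_to_charge = if (is.na(p@calculatedMz)) .MZTAB_NULL
                else .fmtShortest(p@calculatedMz),
            spectra_ref = if (is.na(p@spectrumRef)) .MZTAB_NULL
                else paste0("ms_run[1]:", p@spectrumRef),
            pre = .MZTAB_NULL, post = .MZTAB_NULL, start = .MZTAB_NULL,
            end = .MZTAB_NULL,
            `opt_global_rank` = as.character(p@rank),
            `opt_global_pass_threshold` =
                if (p@passThreshold) "1" else "0",
            `opt_global_decoy` = if (p@isDecoy) "1" else "0")
    })

    toDf <- function(rows) {
        if (!length(rows)) return(data.frame())
        m <- do.call(rbind, rows)
        rownames(m) <- NULL
        as.data.frame(m, stringsAsFactors = FALSE, check.names = FALSE)
    }
    doc <- MzTabDocument(metadata = meta, proteinTable = toDf(prt),
        psmTable = toDf(psm))
    attr(doc, "filterSummary") <- res$summary
    doc
}

## ---- writer ----------------------------------------------------------------

.sectionLines <- function(tab, headerPrefix, rowPrefix) {
    if (!nrow(tab)) return(character())
    c(paste(c(headerPrefix, names(tab)), collapse = "\t"),
      vapply(seq_len(nrow(tab)), function(i)
          paste(c(rowPrefix, .cellOrNull(unlist(tab[i, ],
              use.names = FALSE))), collapse = "\t"), character(1L)))
}

#' Write an mzTab document
#'
#' Refuses documents whose [checkMzTab()] report contains errors. Output is
#' tab-separated with MTD / PRH+PRT / PEH+PEP / PSH+PSM sections in that
#' order and is byte-stable for equal documents.
#'
#' @param doc an [MzTabDocument-class].
#' @param path output path.
#' @export
writeMzTab <- function(doc, path) {
    report <- checkMzTab(doc)
    if (nrow(report) && any(report$severity == "error"))
        stop(paste0("refusing to write invalid mzTab:\n", paste(
            sprintf("  [%s] %s: %s", report$severity, report$code,
                report$message), collapse = "\n")), call. = FALSE)
    lines <- vapply(names(doc@metadata), function(k)
        paste("MTD", k, doc@metadata[[k]], sep = "\t"), character(1L))
    for (section in list(
        list(doc@proteinTable, "PRH", "PRT"),
        list(doc@peptideTable, "PEH", "PEP"),
        list(doc@psmTable, "PSH", "PSM"))) {
        extra <- .sectionLines(section[[1L]], section[[2L]], section[[3L]])
        if (length(extra)) lines <- c(lines, "", extra)
    }
    con <- file(path, "wb")   # \n endings regardless of platform
    on.exit(close(con))
    writeLines(unname(lines), con, sep = "\n")
    invisible(path)
}

## ---- parser ----------------------------------------------------------------

#' Parse an mzTab 1.0 file
#'
#' Inverse of [writeMzTab()] on valid files; unknown optional columns are
#' preserved. `"null"` cells become `NA` in the model. A data line arriving
#' before its header line, or a row with the wrong field count, is a parse
#' error naming the line.
#'
#' @param path mzTab file.
#' @return an [MzTabDocument-class].
#' @export
parseMzTab <- function(path) {
    lines <- .readTextLines(path)
    meta <- list()
    headers <- list(); rows <- list(PRT = list(), PEP = list(),
        PSM = list())
    headerOf <- c(PRT = "PRH", PEP = "PEH", PSM = "PSH")
    for (i in seq_along(lines)) {
        line <- lines[[i]]
        if (!nzchar(trimws(line)) || startsWith(line, "COM")) next
        fields <- strsplit(line, "\t", fixed = TRUE)[[1]]
        prefix <- fields[[1L]]
        if (prefix == "MTD") {
            if (length(fields) < 3L)
                .parseError(i, "MTD line needs key and value")
            meta[[fields[[2L]]]] <- paste(fields[-(1:2)], collapse = "\t")
        } else if (prefix %in% c("PRH", "PEH", "PSH")) {
            headers[[prefix]] <- fields[-1L]
        } else if (prefix %in% c("PRT", "PEP", "PSM")) {
            h <- headers[[headerOf[[prefix]]]]
            if (is.null(h))
                .parseError(i, sprintf(
                    "%s data line before its %s header line", prefix,
                    headerOf[[prefix]]))
            if (length(fields) - 1L != length(h))
                .parseError(i, sprintf(
                    "%s line has %d fields but %s declared %d", prefix,
                    length(fields) - 1L, headerOf[[prefix]], length(h)))
            rows[[prefix]][[length(rows[[prefix]]) + 1L]] <- fields[-1L]
        }
        ## unknown prefixes are skipped
    }
    toDf <- function(prefix) {
        h <- headers[[headerOf[[prefix]]]]
        if (is.null(h)) return(data.frame())
        r <- rows[[prefix]]
        if (!length(r))
            return(as.data.frame(stats::setNames(
                rep(list(character()), length(h)), h),
                check.names = FALSE))
        m <- do.call(rbind, r)
        colnames(m) <- h
        as.data.frame(m, stringsAsFactors = FALSE, check.names = FALSE,
            row.names = NULL)
    }
    MzTabDocument(metadata = meta, proteinTable = toDf("PRT"),
        peptideTable = toDf("PEP"), psmTable = toDf("PSM"))
}

## ---- checker ----------------------------------------------------------------

.reportRow <- function(severity, code, message) {
    data.frame(severity = severity, code = code, message = message,
        stringsAsFactors = FALSE)
}

#' Structurally check an mzTab document
#'
#' Report-based (never throws): returns zero rows iff the document
#' invariants hold. Each violation carries a stable code.
#'
#' Codes: `MZTAB_VERSION`, `MZTAB_MODE`, `MZTAB_TYPE`, `PRT_ACCESSION_DUP`,
#' `PSM_MSRUN_UNDECLARED`, `SCORE_UNDEFINED`.
#'
#' @param doc an [MzTabDocument-class].
#' @return data.frame with columns `severity`, `code`, `message`.
#' @export
checkMzTab <- function(doc) {
    rep <- .reportRow(character(), character(), character())
    md <- doc@metadata
    if (!identical(md[["mzTab-version"]], "1.0"))
        rep <- rbind(rep, .reportRow("error", "MZTAB_VERSION",
            "mzTab-version must be '1.0'"))
    if (!isTRUE(md[["mzTab-mode"]] %in% c("Summary", "Complete")))
        rep <- rbind(rep, .reportRow("error", "MZTAB_MODE",
            "mzTab-mode must be Summary or Complete"))
    if (!isTRUE(md[["mzTab-type"]] %in%
        c("Identification", "Quantification")))
        rep <- rbind(rep, .reportRow("error", "MZTAB_TYPE",
            "mzTab-type must be Identification or Quantification"))
    prt <- doc@proteinTable
    if (nrow(prt) && "accession" %in% names(prt) &&
        anyDuplicated(prt$accession))
        rep <- rbind(rep, .reportRow("error", "PRT_ACCESSION_DUP",
            sprintf("duplicate protein accession(s): %s", paste(
                unique(prt$accession[duplicated(prt$accession)]),
                collapse = ", "))))
    psm <- doc@psmTable
    if (nrow(psm) && "spectra_ref" %in% names(psm)) {
        refs <- psm$spectra_ref[psm$spectra_ref != .MZTAB_NULL]
        runs <- unique(sub("^(ms_run\\[[0-9]+\\]):.*$", "\\1", refs))
        declared <- vapply(runs, function(r)
            !is.null(md[[paste0(r, "-location")]]), logical(1L))
        for (r in runs[!declared])
            rep <- rbind(rep, .reportRow("error", "PSM_MSRUN_UNDECLARED",
                sprintf("spectra_ref names undeclared %s", r)))
    }
    checkScores <- function(tab, colRe, mdKeyFmt) {
        cols <- grep(colRe, names(tab), value = TRUE)
        for (cl in cols) {
            n <- sub(colRe, "\\1", cl)
            if (is.null(md[[sprintf(mdKeyFmt, as.integer(n))]]))
                rep <<- rbind(rep, .reportRow("error", "SCORE_UNDEFINED",
                    sprintf("column '%s' has no metadata definition", cl)))
        }
    }
    if (nrow(psm)) checkScores(psm, "^search_engine_score\\[([0-9]+)\\]$",
        "psm_search_engine_score[%d]")
    if (nrow(prt)) checkScores(prt,
        "^best_search_engine_score\\[([0-9]+)\\]$",
        "protein_search_engine_score[%d]")
    rep
}

## ---- mzTab -> controller ----------------------------------------------------

#' Build a controller from an mzTab document
#'
#' Enough of the identification hierarchy is reconstructed for the uniform
#' contract: PRT rows become proteins, PSM rows become PSMs, and peptides
#' are grouped per (protein, sequence). Protein abundance columns
#' (`protein_abundance_assay[n]`) become per-assay [QuantValue-class]
#' entries and switch the quantification capability on.
#'
#' @param doc an [MzTabDocument-class].
#' @param path source path recorded on the controller.
#' @return an [InMemoryController-class].
#' @export
mzTabToController <- function(doc, path = "") {
    prt <- doc@proteinTable; psm <- doc@psmTable
    col <- function(tab, name, i) {
        if (name %in% names(tab)) .nullToNA(tab[[name]][[i]])
        else NA_character_
    }
    psms <- list(); byProtSeq <- list()
    if (nrow(psm)) for (i in seq_len(nrow(psm))) {
        id <- col(psm, "PSM_ID", i)
        acc <- col(psm, "accession", i)
        if (is.null(psms[[id]])) {
            expMz <- suppressWarnings(
                as.numeric(col(psm, "exp_mass_to_charge", i)))
            calcMz <- suppressWarnings(
                as.numeric(col(psm, "calc_mass_to_charge", i)))
            rank <- suppressWarnings(
                as.integer(col(psm, "opt_global_rank", i)))
            sref <- col(psm, "spectra_ref", i)
            psms[[id]] <- new("PSM", id = id,
                sequence = col(psm, "sequence", i),
                spectrumRef = if (is.na(sref)) NA_character_
                    else sub("^ms_run\\[[0-9]+\\]:", "", sref),
                charge = as.integer(col(psm, "charge", i)),
                experimentalMz = if (is.na(expMz)) 1 else expMz,
                calculatedMz = calcMz,
                rank = if (is.na(rank)) 1L else rank,
                passThreshold = !identical(
                    col(psm, "opt_global_pass_threshold", i), "0"),
                scores = ParamGroup(),
                isDecoy = identical(col(psm, "opt_global_decoy", i), "1"))
        }
        if (!is.na(acc)) {
            key <- paste0(acc, "\r", psms[[id]]@sequence)
            byProtSeq[[key]] <- unique(c(byProtSeq[[key]], id))
        }
    }
    peptides <- list(); pepsByAcc <- list()
    for (key in names(byProtSeq)) {
        parts <- strsplit(key, "\r", fixed = TRUE)[[1]]
        pepId <- sprintf("%s_pep_%s", parts[[1L]], parts[[2L]])
        peptides[[pepId]] <- new("Peptide", id = pepId,
            sequence = parts[[2L]], psmIds = byProtSeq[[key]])
        pepsByAcc[[parts[[1L]]]] <- c(pepsByAcc[[parts[[1L]]]], pepId)
    }
    proteins <- list(); quant <- list()
    abundCols <- grep("^protein_abundance_assay\\[[0-9]+\\]$", names(prt),
        value = TRUE)
    if (nrow(prt)) for (i in seq_len(nrow(prt))) {
        acc <- col(prt, "accession", i)
        proteins[[acc]] <- new("Protein", id = acc, accession = acc,
            passThreshold = !identical(
                col(prt, "opt_global_pass_threshold", i), "0"),
            scores = ParamGroup(),
            peptideIds = if (is.null(pepsByAcc[[acc]])) character()
                else pepsByAcc[[acc]],
            isDecoy = identical(col(prt, "opt_global_decoy", i), "1"))
        if (length(abundCols)) {
            quant[[acc]] <- lapply(abundCols, function(cl) {
                v <- suppressWarnings(as.numeric(.nullToNA(prt[[cl]][[i]])))
                new("QuantValue", assayId = sub(
                    "^protein_abundance_", "", cl), value = v)
            })
        }
    }
    .newInMemoryController("mztab", path, proteins = proteins,
        peptides = peptides, psms = psms, quant = quant,
        metadata = new("ExperimentMetadata",
            title = if (is.null(doc@metadata$description)) NA_character_
                else doc@metadata$description,
            sourceFormat = "mztab", instrument = ParamGroup(),
            params = ParamGroup()))
}
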