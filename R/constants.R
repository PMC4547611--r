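## Loaders for the plain-text constants tables shipped under inst/extdata.
## Tables are documented TSV so alternates can be dropped in; each loader
## memoises in the package namespace.

.paCache <- new.env(parent = emptyenv())

.extdata <- function(file) {
    path <- system.file("extdata", file, package = "ProteoAccess")
    if (!nzchar(path)) stop("bundled constants file not found: ", file)
    path
}

.readConstantsTable <- function(file) {
    utils::read.table(.extdata(file), header = FALSE, sep = "\t",
        comment.char = "#", stringsAsFactors = FALSE,
        colClasses = "character")
}

#' Load a pKa table
#'
#' The bundled default is the Bjellqvist set (no neighbour-dependent
#' corrections): terminal and side-chain pKa values for D, E, C, Y
#' (acidic) and H, K, R (basic). The return value is a list with elements
#' `name`, `nTerm`, `cTerm`, `acidic` (named numeric) and `basic` (named
#' numeric) and is immutable once loaded.
#'
#' @param name table identifier; `"bjellqvist"` is bundled.
#' @param path optional path to an alternative table in the same TSV layout.
#' @return a pKa table list.
#' @export
loadPkaTable <- function(name = "bjellqvist", path = NULL) {
    key <- paste0("pka:", name, ":", if (is.null(path)) "" else path)
    if (!is.null(.paCache[[key]])) return(.paCache[[key]])
    src <- if (is.null(path)) .extdata(paste0("pka_", name, ".tsv")) else path
    tab <- utils::read.table(src, header = FALSE, sep = "\t",
        comment.char = "#", stringsAsFactors = FALSE,
        col.names = c("group", "pka", "kind"))
    tab$pka <- as.numeric(tab$pka)
    if (any(tab$pka <= 0 | tab$pka >= 14))
        stop("pKa values must lie in (0, 14)")
    side <- tab[!tab$group %in% c("NTERM", "CTERM"), ]
    res <- list(
        name = name,
        nTerm = tab$pka[tab$group == "NTERM"],
        cTerm = tab$pka[tab$group == "CTERM"],
        acidic = stats::setNames(
            side$pka[side$kind == "acidic"], side$group[side$kind == "acidic"]),
        basic = stats::setNames(
            side$pka[side$kind == "basic"], side$group[side$kind == "basic"]))
    .paCache[[key]] <- res
    res
}

#' Load the monoisotopic residue mass table
#'
#' @return a list with `mono` (named numeric over the 20 canonical residues),
#'   `water` (18.010565 Da) and `proton` (1.007276 Da).
#' @export
loadMassTable <- function() {
    if (!is.null(.paCache[["mass"]])) return(.paCache[["mass"]])
    tab <- .readConstantsTable("residue_mono_masses.tsv")
    names(tab) <- c("residue", "mass")
    tab$mass <- as.numeric(tab$mass)
    mono <- stats::setNames(tab$mass, tab$residue)
    res <- list(mono = mono[CANONICAL_RESIDUES],
        water = unname(mono["WATER"]), proton = unname(mono["PROTON"]))
    stopifnot(all(res$mono > 0), !anyNA(res$mono))
    .paCache[["mass"]] <- res
    res
}

#' Load the Kyte-Doolittle hydropathy table
#'
#' @return named numeric vector over the 20 canonical residues, values in
#'   `[-4.5, 4.5]`.
#' @export
loadHydropathyTable <- function() {
    if (!is.null(.paCache[["kd"]])) return(.paCache[["kd"]])
    tab <- .readConstantsTable("hydropathy_kd.tsv")
    names(tab) <- c("residue", "value")
    vals <- stats::setNames(as.numeric(tab$value), tab$residue)
    stopifnot(all(vals >= -4.5 & vals <= 4.5))
    .paCache[["kd"]] <- vals[CANONICAL_RESIDUES]
    .paCache[["kd"]]
}

#' Load the CV homogenisation rule table
#'
#' @return data.frame with columns `source_format`, `source_key`, `cv_label`,
#'   `accession`, `name`; the (source_format, source_key) pairs are unique.
#' @export
loadCvMappingRules <- function() {
    if (!is.null(.paCache[["cvmap"]])) return(.paCache[["cvmap"]])
    tab <- .readConstantsTable("cv_mapping.tsv")
    names(tab) <- c("source_format", "source_key", "cv_label", "accession",
        "name")
    if (anyDuplicated(paste(tab$source_format, tab$source_key)))
        stop("cv mapping rules must be unique per (format, key)")
    .paCache[["cvmap"]] <- tab
    tab
}
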