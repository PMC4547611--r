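## Peptide physicochemical calculators and CV-term homogenisation.
##
## The charge model is the classic Henderson-Hasselbalch treatment: each
## ionizable group contributes its protonated fraction. Basic groups
## (N-terminus, H, K, R) add 10^(pKa-pH) / (1 + 10^(pKa-pH)); acidic groups
## (C-terminus, D, E, C, Y) subtract 10^(pH-pKa) / (1 + 10^(pH-pKa)). The
## net charge is strictly decreasing in pH, so the isoelectric point (the
## unique zero) is found by bisection on [0, 14].

.checkCanonical <- function(sequence) {
    if (!is.character(sequence) || length(sequence) != 1L ||
        is.na(sequence) || !nzchar(sequence))
        stop("sequence must be a single non-empty string")
    chars <- strsplit(sequence, "")[[1]]
    bad <- which(!chars %in% CANONICAL_RESIDUES)
    if (length(bad))
        stop(sprintf(
            "unsupported residue '%s' at position %d (canonical alphabet only)",
            chars[bad[1L]], bad[1L]))
    chars
}

#' Net charge of a peptide at a given pH
#'
#' @param sequence peptide over the canonical 20-letter alphabet.
#' @param ph pH in `[0, 14]` (vectorised).
#' @param table pKa table from [loadPkaTable()].
#' @return net charge (same length as `ph`).
#' @examples
#' netCharge("DKD", 7)
#' @export
netCharge <- function(sequence, ph, table = loadPkaTable()) {
    chars <- .checkCanonical(sequence)
    stopifnot(all(ph >= 0 & ph <= 14))
    counts <- table(factor(chars, levels = CANONICAL_RESIDUES))
    pos <- rep(0, length(ph)); neg <- rep(0, length(ph))
    addBasic <- function(pka, n) 10^(pka - ph) / (1 + 10^(pka - ph)) * n
    addAcid <- function(pka, n) 10^(ph - pka) / (1 + 10^(ph - pka)) * n
    pos <- pos + addBasic(table$nTerm, 1L)
    neg <- neg + addAcid(table$cTerm, 1L)
    for (res in names(table$basic)) {
        n <- counts[[res]]
        if (n > 0) pos <- pos + addBasic(table$basic[[res]], n)
    }
    for (res in names(table$acidic)) {
        n <- counts[[res]]
        if (n > 0) neg <- neg + addAcid(table$acidic[[res]], n)
    }
    pos - neg
}

#' Isoelectric point of a peptide
#'
#' Bisection on pH in `[0, 14]` for the unique zero of [netCharge()];
#' iterates until the absolute net charge falls below `tol` and the pH
#' bracket is below 1e-6, so the returned pH is accurate even where the
#' charge curve is flat around the zero.
#'
#' @param sequence peptide over the canonical alphabet.
#' @param table pKa table from [loadPkaTable()].
#' @param tol convergence tolerance on the net charge (default 1e-4).
#' @return pI in pH units.
#' @examples
#' isoelectricPoint("GG")      # amphoteric closed form: (pKa_N + pKa_C) / 2
#' isoelectricPoint("DKDKDK")
#' @export
isoelectricPoint <- function(sequence, table = loadPkaTable(), tol = 1e-4) {
    .checkCanonical(sequence)
    lo <- 0; hi <- 14
    for (i in seq_len(200L)) {
        mid <- (lo + hi) / 2
        q <- netCharge(sequence, mid, table)
        if ((abs(q) < tol && (hi - lo) < 1e-6) || (hi - lo) < 1e-12)
            return(mid)
        if (q > 0) lo <- mid else hi <- mid
    }
    (lo + hi) / 2
}

#' Monoisotopic mass (or m/z) of a peptide
#'
#' `M = sum(residue masses) + water + sum(modification deltas)`; with a
#' charge `z` the ion m/z `(M + z * proton) / z` is returned instead.
#'
#' @param sequence peptide over the canonical alphabet.
#' @param modifications list of [Modification-class] (their `monoDelta`
#'   values are added).
#' @param charge optional positive integer; when given, returns m/z (Th)
#'   instead of neutral mass (Da).
#' @param table mass table from [loadMassTable()].
#' @return mass in Da, or m/z in Th when `charge` is given.
#' @examples
#' monoisotopicMass("G")                 # 75.032025
#' monoisotopicMass("PEPTIDE", charge = 2L)
#' @export
monoisotopicMass <- function(sequence, modifications = list(), charge = NULL,
                             table = loadMassTable()) {
    chars <- .checkCanonical(sequence)
    m <- sum(table$mono[chars]) + table$water
    if (length(modifications))
        m <- m + sum(vapply(modifications, function(x) x@monoDelta,
            numeric(1L)))
    if (is.null(charge)) return(m)
    charge <- as.integer(charge)
    if (is.na(charge) || charge < 1L) stop("charge must be >= 1")
    (m + charge * table$proton) / charge
}

#' GRAVY index of a peptide
#'
#' Grand average of hydropathy: the arithmetic mean of the per-residue
#' Kyte-Doolittle hydropathy values.
#'
#' @param sequence peptide over the canonical alphabet.
#' @param table hydropathy table from [loadHydropathyTable()].
#' @return GRAVY value.
#' @examples
#' gravyIndex("AAA")   # == hydropathy of A
#' @export
gravyIndex <- function(sequence, table = loadHydropathyTable()) {
    chars <- .checkCanonical(sequence)
    mean(table[chars])
}

## one warning per unmapped (format, key) pair per session
.cvMapWarned <- new.env(parent = emptyenv())

#' Homogenise a native field into a CvParam
#'
#' Maps a format-native field name onto the corresponding PSI-MS term using
#' the bundled rule table, injecting the value. Unmapped keys are never
#' dropped: they pass through as a [UserParam-class] (logged once per key).
#'
#' @param sourceFormat format tag the field comes from.
#' @param sourceKey native field name.
#' @param value field value.
#' @param rules rule table from [loadCvMappingRules()].
#' @return a [CvParam-class] when a rule matches, else a [UserParam-class].
#' @examples
#' mapCvTerm("mgf", "TITLE", "scan=1")
#' mapCvTerm("mgf", "MYFIELD", "x")    # passthrough UserParam
#' @export
mapCvTerm <- function(sourceFormat, sourceKey, value = NA_character_,
                      rules = loadCvMappingRules()) {
    hit <- rules[rules$source_format == sourceFormat &
                 rules$source_key == sourceKey, ]
    if (nrow(hit) == 1L)
        return(CvParam(hit$cv_label, hit$accession, hit$name, value))
    key <- paste0(sourceFormat, ":", sourceKey)
    if (is.null(.cvMapWarned[[key]])) {
        .cvMapWarned[[key]] <- TRUE
        message(sprintf("no CV mapping for %s '%s'; kept as userParam",
            sourceFormat, sourceKey))
    }
    UserParam(sourceKey, value)
}
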