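test_that("net charge has the right limiting behaviour and hand sum", {
    ## limits: only the N-terminus is protonated near pH 0, only the
    ## C-terminus is deprotonated near pH 14
    expect_equal(netCharge("G", 0), 1, tolerance = 1e-3)
    expect_equal(netCharge("G", 14), -1, tolerance = 1e-3)
    ## term-by-term oracle over the 5 ionizable groups of DKD at pH 7
    tab <- loadPkaTable()
    hh <- function(pka, basic, ph) {
        if (basic) 10^(pka - ph) / (1 + 10^(pka - ph))
        else -10^(ph - pka) / (1 + 10^(ph - pka))
    }
    want <- hh(tab$nTerm, TRUE, 7) + hh(tab$cTerm, FALSE, 7) +
        hh(tab$basic[["K"]], TRUE, 7) + 2 * hh(tab$acidic[["D"]], FALSE, 7)
    expect_equal(netCharge("DKD", 7), want, tolerance = 1e-12)
})

test_that("net charge is strictly decreasing in pH for random peptides", {
    set.seed(101)
    grid <- seq(0, 14, by = 0.1)
    for (i in 1:25) {
        sq <- randomPeptideSeq()
        q <- netCharge(sq, grid)
        expect_true(all(diff(q) < 0), info = sq)
    }
})

test_that("pI matches the amphoteric closed form and a grid-scan oracle", {
    tab <- loadPkaTable()
    ## no ionizable side chains: pI = (pKa_N + pKa_C) / 2 exactly
    for (sq in c("GG", "GAG", "APSTV"))
        expect_equal(isoelectricPoint(sq), (tab$nTerm + tab$cTerm) / 2,
            tolerance = 1e-3)
    ## grid-scan oracle: coarse scan for the sign change, pI within 1e-3
    set.seed(7)
    gridScanPI <- function(sq) {
        grid <- seq(0, 14, by = 1e-4)
        q <- netCharge(sq, grid)
        i <- which(q <= 0)[1L]
        (grid[i - 1L] + grid[i]) / 2
    }
    for (i in 1:20) {
        sq <- randomPeptideSeq()
        expect_equal(isoelectricPoint(sq), gridScanPI(sq),
            tolerance = 1e-3, info = sq)
    }
})

test_that("pI bracketing and arginine monotonicity hold", {
    set.seed(13)
    for (i in 1:10) {
        sq <- randomPeptideSeq()
        pI <- isoelectricPoint(sq)
        expect_gt(netCharge(sq, max(pI - 0.1, 0)), 0)
        expect_lt(netCharge(sq, min(pI + 0.1, 14)), 0)
        ## appending a strongly basic residue never decreases the pI
        expect_gte(isoelectricPoint(paste0(sq, "R")) - pI, -1e-3)
    }
})

test_that("monoisotopic mass matches closed forms and is additive", {
    expect_equal(monoisotopicMass("G"), 57.02146 + 18.010565,
        tolerance = 1e-9)
    ## modification additivity
    mods <- list(Modification("UNIMOD:1", "Acetyl", 42.010565, 0L))
    expect_equal(monoisotopicMass("PEPTIDE", mods) -
        monoisotopicMass("PEPTIDE"), 42.010565, tolerance = 1e-12)
    ## charged species: (M + z * proton) / z
    tabl <- loadMassTable()
    M <- monoisotopicMass("PEPTIDE")
    expect_equal(monoisotopicMass("PEPTIDE", charge = 2L),
        (M + 2 * tabl$proton) / 2, tolerance = 1e-12)
    ## concatenation: mass(s1 + s2) == mass(s1) + mass(s2) - water
    set.seed(3)
    for (i in 1:10) {
        a <- randomPeptideSeq(); b <- randomPeptideSeq()
        expect_equal(monoisotopicMass(paste0(a, b)),
            monoisotopicMass(a) + monoisotopicMass(b) - tabl$water,
            tolerance = 1e-9)
    }
    ## brute-force per-character oracle
    oracle <- function(sq) {
        sum(vapply(strsplit(sq, "")[[1]], function(ch) tabl$mono[[ch]],
            numeric(1L))) + tabl$water
    }
    for (i in 1:200) {
        sq <- randomPeptideSeq()
        expect_equal(monoisotopicMass(sq), oracle(sq), tolerance = 1e-9)
    }
})

test_that("GRAVY is the mean hydropathy, order-invariant", {
    kd <- loadHydropathyTable()
    expect_equal(gravyIndex("AAA"), kd[["A"]])
    set.seed(5)
    for (i in 1:50) {
        sq <- randomPeptideSeq()
        chars <- strsplit(sq, "")[[1]]
        expect_equal(gravyIndex(sq), sum(kd[chars]) / length(chars))
        perm <- paste(sample(chars), collapse = "")
        expect_identical(gravyIndex(sq), gravyIndex(perm))
    }
})

test_that("calculators fail fast on non-canonical residues", {
    err <- tryCatch(monoisotopicMass("PEPTIDEX"), error = function(e) e)
    expect_match(conditionMessage(err), "'X' at position 8")
    expect_error(isoelectricPoint("GGB"), "'B'")
    expect_error(gravyIndex("GGU"), "'U'")
    expect_error(netCharge("GGO", 7), "'O'")
    expect_error(monoisotopicMass(""), "non-empty")
})

test_that("CV term homogenisation maps known keys and passes others", {
    p <- mapCvTerm("mgf", "TITLE", "scan=1")
    expect_s4_class(p, "CvParam")
    expect_identical(p@accession, "MS:1000796")
    expect_identical(p@value, "scan=1")
    u <- suppressMessages(mapCvTerm("mgf", "MYFIELD", "x"))
    expect_s4_class(u, "UserParam")
    expect_identical(u@name, "MYFIELD")
    expect_identical(u@value, "x")
    ## rule table self-consistency: one accession per concept name
    rules <- loadCvMappingRules()
    expect_false(anyDuplicated(paste(rules$source_format,
        rules$source_key)) > 0L)
    byName <- split(rules$accession, rules$name)
    for (nm in names(byName))
        expect_length(unique(byName[[nm]]), 1L)
})

test_that("constants tables honour their declared ranges", {
    tab <- loadPkaTable()
    expect_true(all(unlist(tab[c("nTerm", "cTerm", "acidic", "basic")]) >
        0))
    expect_true(all(unlist(tab[c("nTerm", "cTerm", "acidic", "basic")]) <
        14))
    expect_setequal(names(tab$acidic), c("D", "E", "C", "Y"))
    expect_setequal(names(tab$basic), c("H", "K", "R"))
    kd <- loadHydropathyTable()
    expect_length(kd, 20L)
    expect_true(all(kd >= -4.5 & kd <= 4.5))
    m <- loadMassTable()
    expect_length(m$mono, 20L)
    expect_equal(m$water, 18.010565)
    expect_equal(m$proton, 1.007276)
})
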