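test_that("mgf blocks parse fields, charges and peaks", {
    f <- tempfile(fileext = ".mgf")
    writeLines(c("# comment", "BEGIN IONS", "TITLE=scan 1",
        "PEPMASS=500.25 1234.5", "CHARGE=2+", "100.1 10", "200.2 0",
        "END IONS", "", "BEGIN IONS", "TITLE=empty", "PEPMASS=300.1",
        "CHARGE=3-", "END IONS"), f)
    sp <- parseMgf(f)
    expect_length(sp, 2L)
    s <- sp[[1L]]
    expect_identical(s@id, "scan 1")
    expect_equal(s@precursor@mz, 500.25)
    expect_equal(s@precursor@intensity, 1234.5)
    expect_identical(s@precursor@charge, 2L)
    expect_equal(s@mz, c(100.1, 200.2))
    expect_equal(s@intensity, c(10, 0))   # zero intensity preserved
    expect_identical(sp[[2L]]@precursor@charge, -3L)
    expect_length(sp[[2L]]@mz, 0L)        # empty block is valid
    expect_identical(vapply(sp, slot, integer(1L), "index"), 0:1)
})

test_that("mgf parse errors carry 1-based line numbers", {
    f <- tempfile()
    writeLines(c("BEGIN IONS", "100 10", "END IONS", "END IONS"), f)
    err <- tryCatch(parseMgf(f), error = function(e) e)
    expect_s3_class(err, "parseError")
    expect_match(conditionMessage(err), "line 4")
    f2 <- tempfile()
    writeLines(c("BEGIN IONS", "PEPMASS=500", "abc def", "END IONS"), f2)
    expect_error(parseMgf(f2), "line 3")
})

test_that("mgf charge lists keep the first charge and the raw string", {
    f <- tempfile()
    writeLines(c("BEGIN IONS", "PEPMASS=500", "CHARGE=2+ and 3+",
        "100 1", "END IONS"), f)
    s <- parseMgf(f)[[1L]]
    expect_identical(s@precursor@charge, 2L)
    expect_identical(userParamByName(s@params, "CHARGE_raw")@value,
        "2+ and 3+")
})

test_that("write -> parse is the identity on mgf", {
    exp <- smallExperiment()
    f1 <- renderTmp(exp, "mgf")
    sp1 <- parseMgf(f1)
    f2 <- tempfile(fileext = ".mgf")
    writeMgf(sp1, f2)
    sp2 <- parseMgf(f2)
    expect_length(sp2, length(sp1))
    for (i in seq_along(sp1)) expect_true(spectraEqual(sp1[[i]], sp2[[i]]))
    ## an empty spectrum list writes an empty stream
    f3 <- tempfile()
    writeMgf(list(), f3)
    expect_identical(file.size(f3), 0)
})

test_that("dta recovers precursor m/z from the M+H header", {
    f <- tempfile()
    writeLines(c("1000.0 1", "100 5"), f)
    s <- parseDta(f)
    expect_equal(s@precursor@mz, 1000.0)          # z = 1: m/z is M+H
    writeLines(c("1000.0 2", "100 5", "200 6"), f)
    s <- parseDta(f)
    expect_equal(s@precursor@mz, (1000.0 + 1.007276) / 2)  # 500.503638
    expect_identical(userParamByName(s@params, "precursor_is_mh")@value,
        "true")
    writeLines("1000.0 2", f)                     # header only: 0 peaks
    expect_length(parseDta(f)@mz, 0L)
    writeLines("1000.0 2 extra", f)
    expect_error(parseDta(f), "2 tokens")
})

test_that("pkl blocks map the three-token header onto the precursor", {
    f <- tempfile()
    writeLines(c("450.9 12345 2", "100 1", "200 2", "300 3", "",
        "600.1 99 3", "150 1"), f)
    sp <- parsePkl(f)
    expect_length(sp, 2L)
    expect_equal(sp[[1L]]@precursor@mz, 450.9)
    expect_equal(sp[[1L]]@precursor@intensity, 12345)
    expect_identical(sp[[1L]]@precursor@charge, 2L)
    expect_length(sp[[1L]]@mz, 3L)
    expect_identical(sp[[2L]]@id, "index=1")
    writeLines(c("450.9 12345", "100 1"), f)
    expect_error(parsePkl(f), "line 1")
})

test_that("ms2 S/Z/I records build spectra and keep all charge states", {
    f <- tempfile()
    writeLines(c("H\tExtractor\ttest", "S\t1\t1\t500.5", "Z\t2\t1000.0",
        "Z\t3\t1499.5", "I\tRetTime\t12.3", "100 1", "200 2"), f)
    sp <- parseMs2(f)
    expect_length(sp, 1L)
    s <- sp[[1L]]
    expect_identical(s@id, "1")
    expect_equal(s@precursor@mz, 500.5)
    expect_identical(s@precursor@charge, 2L)      # first Z line wins
    zs <- Filter(function(p) p@accession == "MS:1000041", s@params@cvParams)
    expect_length(zs, 2L)                          # both retained as params
    expect_identical(userParamByName(s@params, "RetTime")@value, "12.3")
    writeLines(c("100 1", "S\t1\t1\t500.5"), f)
    expect_error(parseMs2(f), "before first S")
    ## H lines surface as controller metadata
    writeLines(c("H\tExtractor\ttest", "S\t1\t1\t500.5", "100 1"), f)
    ctrl <- openController(f, "ms2")
    expect_identical(
        userParamByName(experimentMetadata(ctrl)@params, "Extractor")@value,
        "test")
})

test_that("apl blocks parse key=value headers and preserve unknown keys", {
    f <- tempfile()
    writeLines(c("peaklist start", "mz=622.8", "charge=2",
        "header=scan A", "fragmentation=HCD", "100 1", "200 2",
        "peaklist end", "", "peaklist start", "mz=700", "charge=3",
        "header=scan B", "peaklist end", "", "peaklist start", "mz=710",
        "charge=2", "header=scan C", "peaklist end"), f)
    sp <- parseApl(f)
    expect_length(sp, 3L)
    expect_identical(vapply(sp, slot, character(1L), "id"),
        c("scan A", "scan B", "scan C"))
    expect_equal(sp[[1L]]@precursor@mz, 622.8)
    expect_identical(sp[[1L]]@precursor@charge, 2L)
    expect_length(sp[[1L]]@mz, 2L)
    expect_identical(
        userParamByName(sp[[1L]]@params, "fragmentation")@value, "HCD")
    writeLines(c("peaklist end"), f)
    expect_error(parseApl(f), "without matching start")
})

test_that("text parsers accept CRLF line endings", {
    f <- tempfile()
    con <- file(f, "wb")
    writeLines(c("BEGIN IONS", "TITLE=x", "PEPMASS=500", "100.5 7",
        "END IONS"), con, sep = "\r\n")
    close(con)
    s <- parseMgf(f)[[1L]]
    expect_equal(s@mz, 100.5)
    expect_equal(s@intensity, 7)
})
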