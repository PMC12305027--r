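cfgDefault <- TagConfig()
anchor <- cfgDefault@anchorSeq

test_that("findAnchor locates exact and reverse-complement anchors", {
    set.seed(1)
    tail160 <- paste(sample(c("A", "C", "G", "T"), 160, replace = TRUE),
                     collapse = "")
    read <- paste0(anchor, tail160)
    hit <- findAnchor(read, cfgDefault)
    expect_equal(hit$strand, "+")
    expect_equal(hit$end, nchar(anchor))
    expect_equal(hit$edits, 0L)
    # reverse-complemented construct: found on '-', symmetric position
    hitRc <- findAnchor(revcomp(read), cfgDefault)
    expect_equal(hitRc$strand, "-")
    expect_equal(hitRc$end, nchar(anchor))
    expect_equal(hitRc$edits, 0L)
})

test_that("findAnchor accepts edits up to the ceiling threshold", {
    # 2 substitutions in the 22 nt anchor; threshold ceiling(0.15*22) = 4
    mut <- anchor
    substr(mut, 3, 3) <- if (substr(mut, 3, 3) == "A") "C" else "A"
    substr(mut, 10, 10) <- if (substr(mut, 10, 10) == "G") "T" else "G"
    set.seed(2)
    read <- paste0("TTT", mut,
                   paste(sample(c("A", "C", "G", "T"), 100, replace = TRUE),
                         collapse = ""))
    hit <- findAnchor(read, cfgDefault)
    expect_false(is.null(hit))
    expect_equal(hit$edits, 2L)
    expect_equal(hit$edits, semiglobalOracle(anchor, read))
    expect_equal(hit$end, 3L + nchar(anchor))
    # a random read has no acceptable hit
    set.seed(3)
    rand <- paste(sample(c("A", "C", "G", "T"), 200, replace = TRUE),
                  collapse = "")
    expect_true(is.null(findAnchor(rand, cfgDefault)) ||
                findAnchor(rand, cfgDefault)$edits <= 4)
})

test_that("semi-global anchor edits match the exhaustive substring oracle", {
    set.seed(4)
    for (i in 1:12) {
        read <- paste(sample(c("A", "C", "G", "T"), 60, replace = TRUE),
                      collapse = "")
        pat <- substr(anchor, 1, 10)
        got <- goten:::.semiglobal_search(pat, read)[1, "edits"]
        expect_equal(unname(got), semiglobalOracle(pat, read))
    }
})

test_that("barcode correction follows exact-first, unique-within-distance rules", {
    wl <- c("AAAAAAAA", "CCCCCCCC", "GGGGGGGG", "AAAAAAAT")
    r <- correctBarcode("CCCCCCCC", wl)
    expect_equal(r$cbc, "CCCCCCCC")
    expect_equal(r$edits, 0L)
    # one substitution from exactly one member
    r <- correctBarcode("CGCCCCCC", wl)
    expect_equal(r$cbc, "CCCCCCCC")
    expect_equal(r$edits, 1L)
    # equidistant from two members -> ambiguous
    r <- correctBarcode("AAAAAAAG", wl)
    expect_equal(r$status, "ambiguous")
    expect_true(is.na(r$cbc))
    # exact match wins even with a distance-1 neighbor in the list
    r <- correctBarcode("AAAAAAAT", wl)
    expect_equal(r$cbc, "AAAAAAAT")
    r <- correctBarcode("TTTTGGGG", wl)
    expect_equal(r$status, "unmatched")
    expect_error(correctBarcode("AAAA", character(0)), "empty")
})

test_that("barcode correction agrees with a brute-force scan oracle", {
    set.seed(5)
    wl <- unique(replicate(60, paste(
        sample(c("A", "C", "G", "T"), 16, replace = TRUE), collapse = "")))
    # raw barcodes: members, 1-edit mutants, and randoms
    raws <- c(wl[1:5],
              vapply(wl[6:15], function(b) {
                  i <- sample(16, 1)
                  substr(b, i, i) <- sample(setdiff(c("A", "C", "G", "T"),
                                                    substr(b, i, i)), 1)
                  b
              }, character(1)),
              replicate(10, paste(sample(c("A", "C", "G", "T"), 16,
                                         replace = TRUE), collapse = "")))
    got <- correctBarcode(unname(raws), wl, 1L)
    for (i in seq_along(raws)) {
        d <- as.integer(utils::adist(raws[i], wl))
        dmin <- min(d)
        if (dmin > 1) {
            expect_equal(got$status[i], "unmatched")
        } else if (sum(d == dmin) == 1 || dmin == 0) {
            expect_equal(got$cbc[i], wl[which.min(d)])
            expect_equal(got$edits[i], dmin)
        } else {
            expect_equal(got$status[i], "ambiguous")
        }
    }
})

test_that("tag extraction recovers barcode, UMI and payload from clean reads", {
    wl <- testWhitelist()
    set.seed(6)
    umi <- paste(sample(c("A", "C", "G", "T"), 12, replace = TRUE),
                 collapse = "")
    payload <- paste(sample(c("A", "C", "G", "T"), 80, replace = TRUE),
                     collapse = "")
    read <- paste0(anchor, wl[3], umi, payload)
    tag <- extractTags(read, wl)
    expect_s3_class(tag, "data.frame")
    expect_equal(tag$cbc, wl[3])
    expect_equal(tag$cbc_edits, 0L)
    expect_equal(tag$umi, umi)
    expect_equal(tag$payload, payload)
    expect_equal(tag$strand, "+")
    # one barcode substitution with a unique whitelist neighbor
    mutated <- read
    substr(mutated, nchar(anchor) + 2L, nchar(anchor) + 2L) <-
        setdiff(c("A", "C", "G", "T"),
                substr(wl[3], 2, 2))[1]
    tag2 <- extractTags(mutated, wl)
    expect_equal(tag2$cbc, wl[3])
    expect_equal(tag2$cbc_edits, 1L)
    # random 200-mer: no anchor
    set.seed(7)
    rand <- paste(sample(c("A", "C", "G", "T"), 200, replace = TRUE),
                  collapse = "")
    expect_equal(extractTags(rand, wl), "no-anchor")
})

test_that("tag extraction is strand-symmetric", {
    sim <- simulateCohort(SimulationConfig(
        nCells = 15L, seqErrorRate = 0, indelRate = 0, readsPerUmi = 1,
        seed = 8L))
    fwd <- tagReads(sim$reads, sim$whitelist)
    rc <- qsdss(revcomp(as.character(sim$reads)),
                lapply(readQualities(sim$reads), rev))
    names(rc) <- names(sim$reads)
    bwd <- tagReads(rc, sim$whitelist)
    expect_equal(nrow(fwd$tags), nrow(bwd$tags))
    m <- match(fwd$tags$read_id, bwd$tags$read_id)
    expect_equal(fwd$tags$cbc, bwd$tags$cbc[m])
    expect_equal(fwd$tags$umi, bwd$tags$umi[m])
    expect_true(all(fwd$tags$strand != bwd$tags$strand[m]))
})

test_that("with error-free reads every read is tagged with its true barcode and UMI", {
    sim <- simulateCohort(SimulationConfig(
        nCells = 25L, seqErrorRate = 0, indelRate = 0, seed = 9L))
    tg <- tagReads(sim$reads, sim$whitelist)
    expect_equal(nrow(tg$tags), length(sim$reads))
    truth <- sim$truthReads[match(tg$tags$read_id, sim$truthReads$read_id), ]
    expect_equal(tg$tags$cbc, truth$cbc)
    expect_equal(tg$tags$umi, truth$umi)
    expect_equal(tg$tags$strand, truth$strand)
})

test_that("corrected barcodes are never farther than maxCbcEdits from the raw barcode", {
    sim <- simulateCohort(SimulationConfig(nCells = 20L, seed = 10L))
    tg <- tagReads(sim$reads, sim$whitelist)
    d <- mapply(function(a, b) as.integer(utils::adist(a, b)),
                tg$tags$cbc_raw, tg$tags$cbc)
    expect_true(all(d <= TagConfig()@maxCbcEdits))
    expect_equal(unname(d), tg$tags$cbc_edits)
    # rejection reasons account for every input read
    expect_equal(nrow(tg$tags) + nrow(tg$rejections), length(sim$reads))
})
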