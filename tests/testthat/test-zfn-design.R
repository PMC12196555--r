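REF_LEFT <- "GCTCTACCC"
REF_RIGHT <- "AGGACGCTT"

test_that("half-site pair selection finds the constructed site and only it", {
    seq <- paste0("GGGTAGAGC", "ACGTACG", "AGGACGCTT")
    cand <- selectHalfSitePairs(seq, spacerRange = 5:7)
    expect_identical(nrow(cand), 1L)
    expect_identical(cand$left, REF_LEFT)
    expect_identical(cand$right, REF_RIGHT)
    expect_identical(cand$spacer, 7L)
    expect_identical(cand$start, 1L)

    ## helix-table coverage constraint: dropping one triplet kills the site
    tbl <- defaultHelixTable()
    expect_identical(
        nrow(selectHalfSitePairs(seq, 5:7, tbl[names(tbl) != "CCC"])), 0L)

    ## a background with no coverable triplets yields nothing
    expect_identical(nrow(selectHalfSitePairs(strrep("A", 60), 5:7)), 0L)
    expect_error(selectHalfSitePairs(seq, integer(0)), "non-empty")
})

test_that("candidates are ordered by offset then spacer", {
    ## two overlapping sites: same start with two admissible spacers
    seq <- paste0("GGGTAGAGC", "ACGTACG", "AGGACGCTT", "TT")
    tbl <- c(defaultHelixTable(), GCT2 = "AAAAAAA")  # padding irrelevant
    cand <- selectHalfSitePairs(paste0(seq, "AGGACGCTT"), spacerRange = 4:20,
                                helixTable = defaultHelixTable())
    expect_false(is.unsorted(cand$start))
    byStart <- split(cand$spacer, cand$start)
    for (s in byStart) expect_false(is.unsorted(s))
})

test_that("ZFP assembly follows the grammar in both finger orders", {
    rightExpected <- paste0(
        "LEPGEKP",
        "YKCPECGKSFS", "TTGALTE", "HQRTH", "TGEKP",
        "YKCPECGKSFS", "RTDTLRD", "HQRTH", "TGEKP",
        "YKCPECGKSFS", "RSDHLTN", "HQRTH",
        "TGKKTS")
    expect_identical(assembleZfp(REF_RIGHT, fingerOrder = "three_prime"),
                     rightExpected)

    left <- assembleZfp(REF_LEFT, fingerOrder = "five_prime")
    expect_identical(nchar(left), 92L)
    ## helices appear in the listed order F1=GCT, F2=CTA, F3=CCC
    expect_lt(regexpr("TSGELVR", left), regexpr("QNSTLTE", left))
    expect_lt(regexpr("QNSTLTE", left), regexpr("SKKHLAE", left))

    expect_error(assembleZfp("AAAAAAAAA"), "AAA")
    expect_error(assembleZfp("ACGTACG"), "9 nt")
})

test_that("every 3-finger assembly is 92 aa with 3 backbone repeats", {
    tbl <- defaultHelixTable()
    set.seed(7)
    trip <- names(tbl)
    for (i in 1:10) {
        hs <- paste(sample(trip, 3, replace = TRUE), collapse = "")
        for (ord in c("five_prime", "three_prime")) {
            p <- assembleZfp(hs, tbl, fingerOrder = ord)
            expect_identical(nchar(p), 92L)
            expect_identical(
                length(gregexpr("YKCPECGKSFS", p, fixed = TRUE)[[1L]]), 3L)
            expect_match(p, "^LEPGEKP")
            expect_match(p, "TGKKTS$")
        }
    }
})

test_that("codon usage table derives valid relative adaptiveness", {
    tab <- syntheticCodonUsage()
    w <- relativeAdaptiveness(tab)
    expect_length(w, 61L)
    expect_true(all(w > 0 & w <= 1))
    aa <- Biostrings::GENETIC_CODE[names(w)]
    expect_true(all(tapply(w, aa, max) == 1))

    ## missing codons get the pseudo-count, never zero w
    partial <- codonUsageTable(c(GCT = 10, GCC = 5))
    wp <- relativeAdaptiveness(partial)
    expect_true(all(wp > 0))
    expect_identical(unname(wp[["GCT"]]), 1)
    expect_identical(unname(wp[["GCC"]]), 0.5)
    expect_identical(unname(wp[["GCA"]]), 0.05)  # 0.5 / 10
})

test_that("codon usage tables read from file, with U and headers tolerated", {
    tf <- withr::local_tempfile(fileext = ".tsv")
    writeLines(c("CODON\tFREQ", "GCU\t20", "GCC\t10"), tf)
    tab <- readCodonUsage(tf)
    expect_identical(unname(relativeAdaptiveness(tab)[["GCT"]]), 1)
})

test_that("CAI matches hand-computed geometric means and is scale-invariant", {
    tab <- syntheticCodonUsage()
    w <- relativeAdaptiveness(tab)

    ## all max-w codons -> 1
    aa <- Biostrings::GENETIC_CODE[names(w)]
    bestOf <- function(a) names(w)[aa == a][which.max(w[aa == a])]
    cds <- paste0(vapply(c("A", "L", "S", "R"), bestOf, character(1)),
                  collapse = "")
    expect_equal(computeCai(cds, tab), 1)

    ## single codon of known w
    half <- names(w)[abs(w - 0.5) < 1e-12][1L]
    expect_equal(computeCai(half, tab), 0.5)

    ## two codons, w = 1 and 0.25 -> sqrt(0.25) = 0.5
    quarter <- names(w)[abs(w - 0.25) < 1e-12][1L]
    expect_equal(computeCai(paste0(bestOf("A"), quarter), tab), 0.5)

    ## geometric mean cross-check on a random coding sequence
    set.seed(3)
    codons <- sample(setdiff(names(w), c("ATG", "TGG")), 20, replace = TRUE)
    expect_equal(computeCai(paste(codons, collapse = ""), tab),
                 prod(w[codons])^(1 / 20))

    ## scale invariance of the usage table
    tab10 <- codonUsageTable(codonFrequencies(tab) * 10)
    expect_equal(computeCai(paste(codons, collapse = ""), tab10),
                 computeCai(paste(codons, collapse = ""), tab))

    ## ATG/TGG exemption: Met-only sequence scores 1
    expect_equal(computeCai("ATGTGG", tab), 1)
    expect_error(computeCai("ATGA", tab), "multiple of 3")
    expect_error(computeCai("ATGTAAGCT", tab), "internal stop")
})

test_that("reverse translation is exact and reaches the exhaustive optimum", {
    tab <- syntheticCodonUsage()

    expect_identical(
        reverseTranslateOptimize("M", tab, forbiddenMotifs = character(0),
                                 flank5 = "", flank3 = "")$coding, "ATG")

    ## unconstrained optimisation reaches CAI 1
    unc <- reverseTranslateOptimize("MDELVRK", tab,
                                    forbiddenMotifs = character(0),
                                    flank5 = "", flank3 = "")
    expect_equal(unc$cai, 1)

    ## random proteins round-trip through translation
    set.seed(11)
    aaAlphabet <- setdiff(unique(Biostrings::GENETIC_CODE), "*")
    for (i in 1:20) {
        p <- paste(sample(aaAlphabet, sample(1:12, 1), replace = TRUE),
                   collapse = "")
        r <- reverseTranslateOptimize(p, tab)
        expect_identical(
            as.character(Biostrings::translate(Biostrings::DNAString(r$coding))),
            p)
        ## constraint holds: no forbidden motif overlaps the coding region
        full <- r$construct
        core <- r$coding
        expect_identical(paste0("TCTAGA", core, "GGATCC"), full)
        inner <- substr(full, 2L, nchar(full) - 1L)
        expect_false(grepl("TCTAGA", substr(full, 2, nchar(full))))
        expect_false(grepl("GGATCC", substr(full, 1, nchar(full) - 1)))
    }

    ## oracle equivalence on short proteins under motif constraints
    set.seed(23)
    for (i in 1:12) {
        p <- paste(sample(aaAlphabet, sample(1:4, 1), replace = TRUE),
                   collapse = "")
        motifs <- c("TCTAGA", "GGATCC")
        got <- reverseTranslateOptimize(p, tab, forbiddenMotifs = motifs,
                                        flank5 = "TCTAGA", flank3 = "GGATCC")
        best <- oracleBestCai(p, tab, motifs, "TCTAGA", "GGATCC")
        expect_equal(got$cai, best, tolerance = 1e-12)
    }

    ## "SR": brute force over all 6x6 synonymous pairs, avoiding TCTAGA
    got <- reverseTranslateOptimize("SR", tab, forbiddenMotifs = "TCTAGA",
                                    flank5 = "", flank3 = "")
    best <- oracleBestCai("SR", tab, "TCTAGA", "", "")
    expect_equal(got$cai, best)
    expect_false(grepl("TCTAGA", got$coding))
})

test_that("designZfnPair bundles consistent proteins, CDS and CAI", {
    d <- designZfnPair(REF_LEFT, REF_RIGHT)
    prot <- zfpProteins(d)
    expect_identical(unname(Biostrings::width(prot)), c(92L, 92L))
    cds <- zfpCodingSeqs(d)
    for (i in 1:2)
        expect_identical(
            as.character(Biostrings::translate(cds[[i]])),
            as.character(prot[[i]]))
    expect_true(all(d@cai > 0 & d@cai <= 1))
    expect_output(show(d), "spacer: 7 nt")
})

test_that("helix tables read from disk match the packaged defaults", {
    path <- system.file("extdata", "recognition_helices.tsv",
                        package = "ZFNtools")
    expect_identical(readHelixTable(path), defaultHelixTable())
})
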