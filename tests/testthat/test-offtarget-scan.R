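REF_LEFT <- "GCTCTACCC"
REF_RIGHT <- "AGGACGCTT"

test_that("pattern enumeration reproduces the published pattern count", {
    pats <- enumeratePatterns(REF_LEFT, REF_RIGHT)
    expect_identical(nrow(pats), 56L)
    expect_false(anyDuplicated(pats$composite) > 0)
    ## 8 arrangements x 7 spacer lengths
    expect_identical(length(unique(pats$arrangement)), 8L)
    expect_identical(sort(unique(pats$spacer)), 4:10)
    ## every composite is 9-mer + N-run + 9-mer
    expect_true(all(grepl("^[ACGT]{9}N+[ACGT]{9}$", pats$composite)))
    expect_identical(unique(nchar(pats$composite) - pats$spacer), 18L)
})

test_that("canonical heterodimer composite matches the hand derivation", {
    pats <- enumeratePatterns(REF_LEFT, REF_RIGHT, spacerRange = 7)
    canonical <- as.data.frame(pats)
    expect_identical(
        canonical$composite[canonical$arrangement == "rcL|R"],
        "GGGTAGAGCNNNNNNNAGGACGCTT")
})

test_that("duplicate composites collapse for degenerate half-site pairs", {
    same <- enumeratePatterns(REF_LEFT, REF_LEFT)
    expect_lt(nrow(same), 56L)
    expect_false(anyDuplicated(same$composite) > 0)
    ## brute-force dedup oracle
    oriented <- c(REF_LEFT, oracleRevComp(REF_LEFT))
    combos <- expand.grid(a = oriented, b = oriented, s = 4:10,
                          stringsAsFactors = FALSE)
    comps <- unique(with(combos, paste0(a, strrep("N", s), b)))
    expect_identical(nrow(same), length(comps))
})

test_that("pattern count scales as arrangements x spacers", {
    p1 <- enumeratePatterns(REF_LEFT, REF_RIGHT, spacerRange = 4:6)
    expect_identical(nrow(p1), 8L * 3L)
    p2 <- enumeratePatterns(REF_LEFT, REF_RIGHT, includeHomodimers = TRUE)
    expect_identical(nrow(p2), 16L * 7L)
})

test_that("a planted exact site is found at its exact coordinates", {
    pats <- enumeratePatterns(REF_LEFT, REF_RIGHT, spacerRange = 7)
    canonical <- "GGGTAGAGCNNNNNNNAGGACGCTT"
    fx <- makeSyntheticGenome(10000, data.frame(
        composite = canonical, offset = 4021L, strand = "+"), seed = 101)
    hits <- scanGenome(fx$genome, pats, maxMismatches = 0)
    ## the canonical pattern hits at the planted interval
    canon <- hits[hits$pattern_id == "rcL_R_s7"]
    expect_identical(GenomicRanges::start(canon), 4021L)
    expect_identical(GenomicRanges::end(canon), 4045L)
    expect_identical(canon$mismatches, 0L)
    ## and its reverse-complement pattern sees the same locus on the
    ## opposite strand
    expect_true(any(GenomicRanges::start(hits) == 4021L &
                    as.character(GenomicRanges::strand(hits)) == "-"))
})

test_that("mismatch budget gates hits and variation is reported", {
    pats <- enumeratePatterns(REF_LEFT, REF_RIGHT, spacerRange = 7)
    canonical <- "GGGTAGAGCNNNNNNNAGGACGCTT"
    fx <- makeSyntheticGenome(3000, data.frame(
        composite = canonical, offset = 1200L, strand = "+",
        mismatch_positions = I(list(c(3L, 14L)))), seed = 17)
    expect_identical(fx$truth$mismatches, 2L)

    strict <- scanGenome(fx$genome, pats, maxMismatches = 1)
    expect_false(any(GenomicRanges::start(strict) == 1200L))
    lax <- scanGenome(fx$genome, pats, maxMismatches = 2)
    hit <- lax[GenomicRanges::start(lax) == 1200L &
               lax$pattern_id == "rcL_R_s7"]
    expect_identical(hit$mismatches, 2L)
    expect_equal(hit$variation, 100 * 2 / 18, tolerance = 1e-12)
})

test_that("variation percent is linear, bounded and matches printed bounds", {
    expect_identical(variationPercent(0), 0)
    expect_equal(variationPercent(2), 11.1, tolerance = 0.01)
    expect_equal(variationPercent(8), 44.4, tolerance = 0.01)
    expect_identical(variationPercent(18), 100)
    v <- variationPercent(0:18)
    expect_true(all(v >= 0 & v <= 100))
    expect_equal(diff(v), rep(100 / 18, 18))
    expect_error(variationPercent(19), "0..18")
    expect_error(variationPercent(-1), "0..18")
})

test_that("scan output equals the brute-force oracle on fixture genomes", {
    pats <- enumeratePatterns(REF_LEFT, REF_RIGHT, spacerRange = c(5, 7))
    canonical <- "GGGTAGAGCNNNNNNNAGGACGCTT"
    set.seed(5)
    cases <- list(
        list(len = 2000, mm = 0, plants = data.frame(
            composite = canonical, offset = 500L, strand = "+")),
        list(len = 3000, mm = 1, plants = data.frame(
            composite = canonical, offset = c(700L, 2200L),
            strand = c("+", "-"),
            mismatch_positions = I(list(1L, integer(0))))),
        list(len = 5000, mm = 2, plants = data.frame(
            composite = canonical, offset = c(100L, 2500L, 4200L),
            strand = c("-", "+", "+"),
            mismatch_positions = I(list(c(2L, 18L), integer(0), 9L)))))
    for (cs in cases) {
        fx <- makeSyntheticGenome(cs$len, cs$plants,
                                  seed = sample.int(1e6, 1))
        contig <- as.character(fx$genome[[1L]])
        hits <- scanGenome(fx$genome, pats, maxMismatches = cs$mm)
        got <- data.frame(start = GenomicRanges::start(hits),
                          end = GenomicRanges::end(hits),
                          strand = as.character(GenomicRanges::strand(hits)),
                          pattern_id = hits$pattern_id,
                          mismatches = hits$mismatches)
        want <- do.call(rbind, lapply(seq_len(nrow(pats)), function(i) {
            o <- oracleScanContig(contig, pats$composite[i], cs$mm)
            if (nrow(o)) cbind(o, pattern_id = pats$pattern_id[i]) else NULL
        }))
        key <- function(d) sort(paste(d$start, d$end, d$strand,
                                      d$pattern_id, d$mismatches))
        expect_identical(key(got), key(want))
        ## all zero-mismatch plants are recovered
        exact <- fx$truth[fx$truth$mismatches == 0, ]
        for (j in seq_len(nrow(exact)))
            expect_true(any(got$start == exact$start[j] &
                            got$strand == exact$strand[j]))
    }
})

test_that("strand symmetry: scanning the reverse-complemented genome mirrors hits", {
    pats <- enumeratePatterns(REF_LEFT, REF_RIGHT, spacerRange = 7)
    canonical <- "GGGTAGAGCNNNNNNNAGGACGCTT"
    set.seed(99)
    for (i in 1:100) {
        strand <- sample(c("+", "-"), 1)
        off <- sample(200:700, 1)
        fx <- makeSyntheticGenome(1000, data.frame(
            composite = canonical, offset = off, strand = strand),
            seed = sample.int(1e6, 1))
        L <- 1000L
        fwd <- scanGenome(fx$genome, pats, maxMismatches = 0)
        rcGenome <- Biostrings::reverseComplement(fx$genome)
        names(rcGenome) <- names(fx$genome)
        rev <- scanGenome(rcGenome, pats, maxMismatches = 0)
        keyF <- sort(paste(GenomicRanges::start(fwd),
                           GenomicRanges::end(fwd),
                           as.character(GenomicRanges::strand(fwd)),
                           fwd$pattern_id))
        keyR <- sort(paste(L - GenomicRanges::end(rev) + 1L,
                           L - GenomicRanges::start(rev) + 1L,
                           ifelse(as.character(GenomicRanges::strand(rev)) ==
                                  "+", "-", "+"),
                           rev$pattern_id))
        expect_identical(keyR, keyF)
        expect_gte(length(fwd), 1L)
    }
})

test_that("context extraction returns strand-oriented flanks with clipping flags", {
    fx <- makeSyntheticGenome(1000, data.frame(
        composite = "GGGTAGAGCNNNNNNNAGGACGCTT", offset = 500L,
        strand = "+"), seed = 31)
    hit <- GenomicRanges::GRanges("chr1", IRanges::IRanges(500, 524),
                                  strand = "+")
    ctx <- extractContext(fx$genome, hit)
    expect_identical(nchar(ctx$upstream), 100L)
    expect_identical(nchar(ctx$downstream), 100L)
    expect_identical(nchar(ctx$upstream) + nchar(ctx$downstream), 200L)
    expect_false(ctx$truncated)
    contig <- as.character(fx$genome[[1L]])
    expect_identical(ctx$match, substr(contig, 500, 524))
    expect_identical(ctx$upstream, substr(contig, 400, 499))

    ## minus-strand hit: flanks are reverse-complemented and swapped
    hitM <- GenomicRanges::GRanges("chr1", IRanges::IRanges(500, 524),
                                   strand = "-")
    ctxM <- extractContext(fx$genome, hitM)
    expect_identical(ctxM$match, oracleRevComp(ctx$match))
    expect_identical(ctxM$upstream, oracleRevComp(ctx$downstream))

    ## clipping at the contig edge
    hitE <- GenomicRanges::GRanges("chr1", IRanges::IRanges(1, 25),
                                   strand = "+")
    ctxE <- extractContext(fx$genome, hitE)
    expect_identical(ctxE$upstream, "")
    expect_true(ctxE$truncated)

    ## zero flanks return the bare match
    ctx0 <- extractContext(fx$genome, hit, flankUp = 0, flankDown = 0)
    expect_identical(ctx0$upstream, "")
    expect_identical(ctx0$downstream, "")
    expect_identical(ctx0$match, ctx$match)
    expect_false(ctx0$truncated)

    expect_error(extractContext(fx$genome,
        GenomicRanges::GRanges("chr1", IRanges::IRanges(990, 1030))),
        "outside")
})

test_that("hits round-trip through BED6 and context FASTA", {
    pats <- enumeratePatterns(REF_LEFT, REF_RIGHT, spacerRange = 7)
    fx <- makeSyntheticGenome(2000, data.frame(
        composite = "GGGTAGAGCNNNNNNNAGGACGCTT", offset = 900L,
        strand = "+"), seed = 41)
    hits <- scanGenome(fx$genome, pats, maxMismatches = 0)
    bed <- withr::local_tempfile(fileext = ".bed")
    fa <- withr::local_tempfile(fileext = ".fa")
    writeHits(hits, bed, genome = fx$genome, fastaPath = fa)

    back <- rtracklayer::import(bed)
    expect_identical(GenomicRanges::start(back), GenomicRanges::start(hits))
    expect_identical(GenomicRanges::end(back), GenomicRanges::end(hits))
    expect_identical(back$name, hits$pattern_id)
    expect_identical(as.integer(back$score), hits$mismatches)
    ## interval length = 18 + spacer
    sp <- as.integer(sub(".*_s(\\d+).*", "\\1", hits$pattern_id))
    expect_identical(GenomicRanges::width(back), 18L + sp)

    ctx <- readFastaRecords(fa)
    expect_identical(length(ctx), length(hits))
    expect_true(all(grepl("^chr1:\\d+-\\d+:[+-]:", names(ctx))))

    ## empty hit set still writes a valid (empty) BED
    bed2 <- withr::local_tempfile(fileext = ".bed")
    writeHits(hits[0], bed2)
    expect_identical(length(rtracklayer::import(bed2)), 0L)
})
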