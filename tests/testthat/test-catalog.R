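test_that("overlapping and bookended deletions merge into single records", {
    cat <- SVCatalog(chrom = "C1", start = c(101, 151), end = c(200, 250),
                     svType = "absence_PAV", altLength = 0,
                     sourceGenomes = list("g1", "g2"))
    m <- mergeSVs(cat)
    expect_equal(length(m), 1L)
    expect_equal(GenomicRanges::start(svRanges(m)), 101)
    expect_equal(GenomicRanges::end(svRanges(m)), 250)
    expect_equal(as.list(sourceGenomes(m))[[1]], c("g1", "g2"))

    # bookended ("continuous") intervals also merge
    cat2 <- SVCatalog(chrom = "C1", start = c(101, 201), end = c(200, 300),
                      svType = "absence_PAV", altLength = 0)
    expect_equal(length(mergeSVs(cat2)), 1L)
    expect_equal(GenomicRanges::end(svRanges(mergeSVs(cat2))), 300)

    # a gap of one base does not merge
    cat3 <- SVCatalog(chrom = "C1", start = c(101, 202), end = c(200, 300),
                      svType = "absence_PAV", altLength = 0)
    expect_equal(length(mergeSVs(cat3)), 2L)
})

test_that("interval merging matches a sweep-line union oracle", {
    withr::with_seed(11, {
        n <- 500
        start <- sample.int(20000, n, replace = TRUE)
        width <- sample(50:500, n, replace = TRUE)
        cat <- SVCatalog(chrom = "C1", start = start,
                         end = start + width - 1L,
                         svType = "absence_PAV", altLength = 0)
        m <- mergeSVs(cat)
        oracle <- oracleSweepUnion(start, start + width - 1L)
        expect_equal(GenomicRanges::start(svRanges(m)),
                     unname(oracle[, "start"]))
        expect_equal(GenomicRanges::end(svRanges(m)),
                     unname(oracle[, "end"]))
    })
})

test_that("merging is idempotent, order-independent and type-separated", {
    withr::with_seed(3, {
        n <- 120
        start <- sample.int(5000, n, replace = TRUE)
        tp <- sample(c("absence_PAV", "CNV"), n, replace = TRUE)
        cat <- SVCatalog(chrom = "C1", start = start, end = start + 99L,
                         svType = tp, altLength = 0,
                         sourceGenomes = as.list(paste0("g", 1:n)))
        m1 <- mergeSVs(cat)
        # idempotent
        m2 <- mergeSVs(m1)
        expect_equal(length(m2), length(m1))
        expect_equal(GenomicRanges::start(svRanges(m2)),
                     GenomicRanges::start(svRanges(m1)))
        # order-independent
        perm <- sample(n)
        mP <- mergeSVs(cat[perm])
        expect_equal(GenomicRanges::start(svRanges(mP)),
                     GenomicRanges::start(svRanges(m1)))
        expect_equal(svType(mP), svType(m1))
        expect_equal(as.list(sourceGenomes(mP)), as.list(sourceGenomes(m1)))
        # never fewer types than present, counts <= input
        expect_lte(length(m1), n)
    })
})

test_that("insertion breakpoint clustering respects both tolerances", {
    mk <- function(bp, len) SVCatalog(chrom = "C1", start = bp, end = bp - 1L,
                                      svType = "presence_PAV",
                                      altLength = len,
                                      sourceGenomes = as.list(
                                          paste0("g", seq_along(bp))))
    # within 10 bp and 10% length: merge
    expect_equal(length(mergeSVs(mk(c(100L, 108L), c(500, 530)))), 1L)
    # breakpoints too far apart
    expect_equal(length(mergeSVs(mk(c(100L, 120L), c(500, 500)))), 2L)
    # lengths too different
    expect_equal(length(mergeSVs(mk(c(100L, 102L), c(500, 800)))), 2L)
    # merged record keeps leftmost breakpoint and longest alt
    m <- mergeSVs(mk(c(108L, 100L), c(530, 500)))
    expect_equal(GenomicRanges::start(svRanges(m)), 100)
    expect_equal(altLength(m), 530)
})

test_that("context labels follow precedence and strand, matching a per-base oracle", {
    ann <- toyAnnotation()
    cfg <- analysisConfig()
    # SV inside an exon that is also near another feature -> exon wins
    cat <- SVCatalog(chrom = "C1", start = 10050, end = 10149,
                     svType = "absence_PAV", altLength = 0)
    expect_equal(annotateContext(cat, ann$genes, ann$cds, cfg), "exon")
    # 2.5 kb 5' of the minus-strand gene gB = coordinate-right of its end
    cat2 <- SVCatalog(chrom = "C1", start = 55500, end = 55560,
                      svType = "absence_PAV", altLength = 0)
    expect_equal(annotateContext(cat2, ann$genes, ann$cds, cfg), "upstream")
    # random SVs vs the per-base oracle
    withr::with_seed(5, {
        n <- 200
        start <- sample.int(70000, n, replace = TRUE)
        catR <- SVCatalog(chrom = "C1", start = start, end = start + 59L,
                          svType = "absence_PAV", altLength = 0)
        got <- annotateContext(catR, ann$genes, ann$cds, cfg)
        feat <- list(
            gene = data.frame(chrom = "C1", start = c(10001, 50001),
                              end = c(13000, 53000)),
            exon = data.frame(chrom = "C1",
                              start = c(10001, 12001, 50001, 52001),
                              end = c(10800, 13000, 50800, 53000)),
            up = data.frame(chrom = "C1", start = c(10001 - 3000, 53001),
                            end = c(10000, 53000 + 3000)),
            down = data.frame(chrom = "C1", start = c(13001, 50001 - 3000),
                              end = c(13000 + 3000, 50000)))
        want <- vapply(seq_len(n), function(i)
            oracleContext(start[i], start[i] + 59L, "C1", feat),
            character(1))
        expect_equal(got, want)
        # labels partition the catalog
        expect_equal(sum(table(got)), n)
    })
})

test_that("density profile is zero without SVs and uniform for a body-covering SV", {
    ann <- toyAnnotation()
    empty <- SVCatalog(chrom = character(), start = integer(),
                       end = integer(), svType = character(),
                       altLength = numeric())
    prof0 <- densityProfile(empty, ann$genes)
    expect_true(all(prof0$density == 0))
    # SV covering exactly gene gA's body
    cat <- SVCatalog(chrom = "C1", start = 10001, end = 13000,
                     svType = "absence_PAV", altLength = 0)
    prof <- densityProfile(cat, ann$genes[1])
    expect_true(all(prof$density[prof$region == "body"] > 0))
    expect_equal(stats::sd(prof$density[prof$region == "body"]), 0)
    expect_true(all(prof$density[prof$region != "body"] == 0))
})

test_that("TE overlap fractions match direct intersection", {
    te <- GenomicRanges::GRanges("C1", IRanges::IRanges(51, 100))
    cat <- SVCatalog(chrom = "C1", start = 1, end = 100,
                     svType = "absence_PAV", altLength = 0)
    expect_equal(unname(teOverlapFractions(cat, te)$perSV), 0.5)
    # no TEs -> all zero
    noTe <- GenomicRanges::GRanges()
    expect_equal(unname(teOverlapFractions(cat, noTe)$perSV), 0)
    # random intervals vs per-base oracle
    withr::with_seed(9, {
        n <- 80
        svS <- sample.int(5000, n, replace = TRUE)
        catR <- SVCatalog(chrom = "C1", start = svS, end = svS + 199L,
                          svType = "absence_PAV", altLength = 0)
        teS <- sample.int(5000, 40, replace = TRUE)
        teR <- GenomicRanges::GRanges("C1",
                                      IRanges::IRanges(teS, teS + 99L))
        got <- unname(teOverlapFractions(catR, teR)$perSV)
        teBase <- unique(unlist(lapply(seq_along(teS), function(i)
            teS[i]:(teS[i] + 99L))))
        want <- vapply(seq_len(n), function(i)
            sum((svS[i]:(svS[i] + 199L)) %in% teBase) / 200, numeric(1))
        expect_equal(got, want)
    })
    # pure insertions have fraction 0
    ins <- SVCatalog(chrom = "C1", start = 60, end = 59,
                     svType = "presence_PAV", altLength = 300)
    expect_equal(unname(teOverlapFractions(ins, te)$perSV), 0)
})

test_that("private-SV counts and rank-sum comparison behave as designed", {
    src <- c(as.list(paste0("g", rep(1:3, times = c(5, 6, 7)))),
             as.list(paste0("h", rep(1:3, times = c(1, 2, 3)))),
             list(c("g1", "h1")))  # shared SV: private nowhere
    n <- length(src)
    cat <- SVCatalog(chrom = "C1",
                     start = seq(1, by = 1000, length.out = n),
                     end = seq(100, by = 1000, length.out = n),
                     svType = "absence_PAV", altLength = 0,
                     sourceGenomes = src)
    st <- privateSvStats(cat, genomeGroups = list(A = paste0("g", 1:3),
                                                  B = paste0("h", 1:3)))
    expect_equal(unname(st$perGenome[paste0("g", 1:3)]), c(5L, 6L, 7L))
    expect_equal(unname(st$perGenome[paste0("h", 1:3)]), c(1L, 2L, 3L))
    # counts A=[5,6,7] vs B=[1,2,3]: exact two-sided rank-sum p = 0.1
    expect_equal(st$test$p.value, 0.1)
    # identical groups -> p = 1
    st2 <- privateSvStats(cat, genomeGroups = list(A = paste0("g", 1:3),
                                                   B = paste0("g", 1:3)))
    expect_equal(st2$test$p.value, 1.0)
    # private counts never exceed catalog size
    expect_lte(sum(st$perGenome), length(cat))
})

test_that("saturation fit recovers a noiseless exponential and flags bad input", {
    n <- 1:27
    y <- 1000 - 800 * exp(-n / 5)
    fit <- saturationFit(y)
    expect_equal(fit$A, 1000, tolerance = 0.01)
    expect_true(is.na(fit$predictedSE))
    # constant counts: A equals the constant
    fitC <- saturationFit(rep(400, 10))
    expect_equal(fitC$A, 400, tolerance = 1e-6)
    # nested panels: fitted asymptote nondecreasing (within fit tolerance)
    As <- vapply(c(10, 15, 20, 27), function(k) saturationFit(y[1:k])$A,
                 numeric(1))
    expect_true(all(diff(As) > -0.01 * As[-length(As)]))
    expect_error(saturationFit(y[1:3]), "at least 4")
    expect_error(saturationFit(c(5, 4, 6, 7, 8)), "nondecreasing")
})

test_that("LTR insertion time follows the molecular clock", {
    expect_equal(ltrInsertionTime(0), 0)
    expect_equal(ltrInsertionTime(0.026, 1.3e-8), 1e6)
    expect_equal(ltrInsertionTime(0.00026, 1.3e-8), 1e4)
    expect_error(ltrInsertionTime(-0.1), ">= 0")
})
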