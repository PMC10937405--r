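test_that("SV-gene linking honours the 10-kb radius and six bins", {
    ann <- toyAnnotation()
    cfg <- analysisConfig()
    # edge-to-edge distance 10,001 bp from gA's end (13000): no link to gA,
    # and gB is even farther from the left, so drop the record
    cat <- SVCatalog(chrom = "C1", start = 23002, end = 23101,
                     svType = "absence_PAV", altLength = 0)
    expect_equal(nrow(linkSvToGene(cat, ann$genes, ann$cds, cfg)), 0L)
    # inside a CDS: distance 0, bin CDS
    cat2 <- SVCatalog(chrom = "C1", start = 10100, end = 10199,
                      svType = "absence_PAV", altLength = 0)
    l2 <- linkSvToGene(cat2, ann$genes, ann$cds, cfg)
    expect_equal(l2$geneID, "gA")
    expect_equal(l2$distance, 0)
    expect_equal(as.character(l2$bin), "CDS")
    # upstream of plus-strand gene: negative signed distance
    cat3 <- SVCatalog(chrom = "C1", start = 9001, end = 9100,
                      svType = "absence_PAV", altLength = 0)
    l3 <- linkSvToGene(cat3, ann$genes, ann$cds, cfg)
    expect_equal(l3$distance, -(10001 - 9100 - 1))
    expect_equal(as.character(l3$bin), "0-1.5kb")
})

test_that("linking matches an all-pairs nearest-gene oracle", {
    ann <- toyAnnotation()
    cfg <- analysisConfig()
    withr::with_seed(13, {
        n <- 300
        start <- sample.int(80000, n, replace = TRUE)
        cat <- SVCatalog(chrom = "C1", start = start, end = start + 79L,
                         svType = "absence_PAV", altLength = 0,
                         svID = sprintf("s%03d", 1:n))
        links <- linkSvToGene(cat, ann$genes, ann$cds, cfg)
        gdf <- data.frame(geneID = c("gA", "gB"),
                          start = c(10001, 50001), end = c(13000, 53000))
        for (i in seq_len(n)) {
            d <- vapply(1:2, function(g)
                oracleGapDistance(start[i], start[i] + 79L,
                                  gdf$start[g], gdf$end[g]), numeric(1))
            row <- links[links$svID == sprintf("s%03d", i), ]
            if (min(d) > cfg$linkRadiusBp) {
                expect_equal(nrow(row), 0L)
            } else {
                expect_equal(nrow(row), 1L)
                expect_equal(abs(row$distance), min(d))
                if (d[1] != d[2])
                    expect_equal(row$geneID, gdf$geneID[which.min(d)])
            }
        }
    })
})

test_that("genotype orientation is reference-free", {
    # insertion: alt allele longer -> alt carriers are presence
    expect_equal(orientGenotypes(c(1L, 0L, NA), refLength = 0,
                                 altLength = 500), c(1L, 0L, NA))
    # deletion: alt allele shorter -> alt carriers are absence
    expect_equal(orientGenotypes(c(1L, 0L, NA), refLength = 500,
                                 altLength = 0), c(0L, 1L, NA))
    # flipping the reference flips alt-carrier codes but not presence
    altCarrier <- c(1L, 1L, 0L, NA, 0L)
    fromRefA <- orientGenotypes(altCarrier, refLength = 0, altLength = 400)
    fromRefB <- orientGenotypes(1L - altCarrier, refLength = 400,
                                altLength = 0)
    expect_equal(fromRefA, fromRefB)
    expect_error(orientGenotypes(1L, 100, 100), "equal allele lengths")
})

test_that("expression filters use strict fractions", {
    cfg <- analysisConfig()
    expect_false(expressedFilter(c(2, 2, 2, 0, 0), "panel", cfg))  # 0.60
    expect_true(expressedFilter(c(2, 2, 2, 2, 0), "panel", cfg))
    pop <- c(rep(5, 31), rep(0, 69))
    expect_true(expressedFilter(pop, "population", cfg))           # 31%
    expect_false(expressedFilter(c(rep(5, 30), rep(0, 70)),
                                 "population", cfg))               # 30%
})

test_that("panel direction calls use the inclusive 1.5-fold rule", {
    ann <- toyAnnotation()
    cfg <- analysisConfig()
    genomes <- paste0("T", 1:10)
    links <- data.frame(svID = "sv1", geneID = "gA", distance = 0,
                        bin = "CDS")
    presence <- matrix(c(rep(1L, 5), rep(0L, 5)), 10, 1,
                       dimnames = list(genomes, "sv1"))
    mkExpr <- function(presVal, absVal) {
        m <- matrix(c(rep(presVal, 5), rep(absVal, 5)), 1, 10,
                    dimnames = list("gA", genomes))
        m
    }
    # ratio exactly 1.5: promoting (inclusive "at least")
    cp <- callDosagePanel(links, presence, mkExpr(3, 2), cfg)
    expect_equal(cp$direction, "promoting")
    expect_equal(cp$foldRatio, 1.5)
    cs <- callDosagePanel(links, presence, mkExpr(2, 3), cfg)
    expect_equal(cs$direction, "suppressing")
    # swap group labels swaps the direction (antisymmetry)
    swapped <- callDosagePanel(links, 1L - presence, mkExpr(3, 2), cfg)
    expect_equal(swapped$direction, "suppressing")
    # zero absence mean with positive presence mean: promoting via +Inf
    cz <- callDosagePanel(links, presence, mkExpr(3, 0), cfg)
    expect_equal(cz$direction, "promoting")
    expect_equal(cz$foldRatio, Inf)
    # minority group below minGenomesPerGroup: skipped with reason
    few <- matrix(c(rep(1L, 2), rep(0L, 8)), 10, 1,
                  dimnames = list(genomes, "sv1"))
    cf <- callDosagePanel(links, few, mkExpr(3, 2), cfg)
    expect_true(is.na(cf$direction))
    expect_match(cf$reason, "group below minimum")
})

test_that("population calls enforce eligibility and significance", {
    cfg <- analysisConfig()
    links <- data.frame(svID = "sv1", geneID = "g1", distance = 0,
                        bin = "CDS")
    acc <- sprintf("a%03d", 1:100)
    mkCall <- function(gvec, expr) {
        gt <- matrix(gvec, length(gvec), 1, dimnames = list(acc, "sv1"))
        em <- matrix(expr, 1, length(expr), dimnames = list("g1", acc))
        callDosagePopulation(links, gt, em, cfg)
    }
    withr::with_seed(2, {
        # 59 genotyped accessions: skipped
        g <- c(rep(1L, 30), rep(0L, 29), rep(NA, 41))
        r <- mkCall(g, rlnorm(100, log(20), 0.3))
        expect_true(is.na(r$direction))
        expect_match(r$reason, "minGenotyped")
        # planted 3x promoter, 50 vs 50
        g2 <- rep(c(1L, 0L), each = 50)
        e2 <- rlnorm(100, log(20), 0.3) * ifelse(g2 == 1L, 3, 1)
        r2 <- mkCall(g2, e2)
        expect_equal(r2$direction, "promoting")
        expect_lt(r2$pValue, 0.05)
        # identically drawn groups: direction none
        r3 <- mkCall(g2, rlnorm(100, log(20), 0.3))
        expect_equal(r3$direction, "none")
    })
})

test_that("binomial asymmetry test is exact and symmetric", {
    expect_equal(asymmetryBinomial(10, 0), 2 * 0.5^10)
    expect_equal(asymmetryBinomial(5, 5), 1.0)
    expect_equal(asymmetryBinomial(3536, 2990), asymmetryBinomial(2990, 3536))
    withr::with_seed(4, {
        for (k in 1:20) {
            a <- rpois(1, 40); b <- rpois(1, 40)
            if (a + b == 0) next
            expect_equal(asymmetryBinomial(a, b), oracleBinomP(a, a + b))
        }
    })
})

test_that("z-score profile standardises rows", {
    expect_equal(unname(zscoreProfile(matrix(1:3, 1, 3))[1, ]),
                 c(-1, 0, 1))
    expect_equal(unname(zscoreProfile(matrix(5, 2, 4))), matrix(0, 2, 4))
    withr::with_seed(6, {
        m <- matrix(rnorm(200), 10, 20)
        z <- zscoreProfile(m)
        expect_true(all(abs(rowMeans(z)) < 1e-12))
        expect_true(all(abs(apply(z, 1, sd) - 1) < 1e-12))
    })
})

test_that("fold-change profile conserves calls and centres unit folds at zero", {
    calls <- data.frame(svID = paste0("s", 1:6), geneID = paste0("g", 1:6),
                        bin = c("CDS", "CDS", "intron", "0-1.5kb",
                                "5-10kb", "5-10kb"),
                        nPresence = 5L, nAbsence = 5L, meanPresence = 1,
                        meanAbsence = 1, foldRatio = 1,
                        direction = "none", pValue = NA_real_,
                        mode = "panel", reason = NA_character_)
    prof <- foldChangeProfile(calls)
    expect_equal(sum(prof$n), 6L)
    expect_true(all(prof$q50[prof$nFinite > 0] == 0))
})
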