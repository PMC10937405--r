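test_that("case-control Fisher reproduces enumeration-derived examples", {
    # balanced-ish table: every outcome is as probable as observed -> p = 1
    r1 <- caseControlFisher(gtFromCounts(2, 3, 3, 2), "case")
    expect_equal(r1$pRaw, 1.0)
    # diagonal table on 10 accessions: p = 2 / choose(10, 5)
    r2 <- caseControlFisher(gtFromCounts(5, 0, 0, 5), "case")
    expect_equal(r2$pRaw, 2 / 252)
    expect_equal(r2$enrichedIn, "case")
    # label symmetry: swapping case and control leaves p unchanged
    r3 <- caseControlFisher(gtFromCounts(4, 19, 17, 6), "case")
    gtSw <- gtFromCounts(17, 6, 4, 19, caseLabel = "case")
    r4 <- caseControlFisher(gtSw, "case")
    expect_equal(r3$pRaw, r4$pRaw)
})

test_that("Fisher p equals exhaustive hypergeometric enumeration on random tables", {
    withr::with_seed(47, {
        for (k in 1:300) {
            repeat {
                cnt <- as.vector(stats::rmultinom(1, sample(8:40, 1),
                                                  rep(0.25, 4)))
                tab <- matrix(cnt, 2, 2)
                if (all(rowSums(tab) > 0) && any(colSums(tab) > 0)) break
            }
            gt <- gtFromCounts(tab[1, 1], tab[1, 2], tab[2, 1], tab[2, 2])
            got <- caseControlFisher(gt, "case")$pRaw
            expect_equal(got, oracleFisherP(tab), tolerance = 1e-12)
        }
    })
})

test_that("missing genotypes are excluded per SV and Bonferroni scales by tests", {
    m <- matrix(c(1L, 0L, NA, 1L, 0L, 0L,
                  1L, 1L, 0L, 0L, NA, 0L), 6, 2,
                dimnames = list(sprintf("a%d", 1:6), c("sv1", "sv2")))
    gt <- GenotypeMatrix(m, data.frame(
        morphotype = rep(c("case", "control"), each = 3),
        row.names = rownames(m)))
    res <- caseControlFisher(gt, "case")
    r1 <- res[res$svID == "sv1", ]
    expect_equal(r1$casePresence + r1$caseAbsence, 2)  # one case missing
    expect_equal(res$pBonferroni, pmin(1, res$pRaw * nrow(res)))
})

test_that("signal selection reports Bonferroni and top-fraction sets", {
    withr::with_seed(51, {
        p <- runif(100)
        res <- data.frame(svID = sprintf("s%03d", 1:100), pRaw = p,
                          pBonferroni = pmin(1, p * 100))
        cfg <- analysisConfig()
        sel <- selectSignals(res, cfg)
        # top 5% of 100 = 5 signals (no ties among runif draws)
        expect_equal(length(sel$topFraction), 5L)
        expect_setequal(sel$topFraction,
                        res$svID[order(p)][1:5])   # sort-based oracle
        expect_true(all(res$pRaw[res$svID %in% sel$bonferroni] <
                        cfg$alpha))                # Bonferroni subset of raw
    })
    # all p = 1: Bonferroni set empty
    res1 <- data.frame(svID = c("a", "b"), pRaw = 1, pBonferroni = 1)
    expect_equal(length(selectSignals(res1, analysisConfig())$bonferroni), 0L)
    # ties at the cut are all included
    res2 <- data.frame(svID = letters[1:4], pRaw = c(.01, .02, .02, .5),
                       pBonferroni = 1)
    sel2 <- selectSignals(res2, analysisConfig(topFraction = 0.5))
    expect_setequal(sel2$topFraction, c("a", "b", "c"))
})

test_that("two-SV haplotype groups map joint genotypes and compare expression", {
    sv1 <- c(a1 = 0L, a2 = 0L, a3 = 1L, a4 = 1L, a5 = NA)
    sv2 <- c(a1 = 0L, a2 = 1L, a3 = 0L, a4 = 1L, a5 = 0L)
    hg <- haplotypeGroups(sv1, sv2)
    expect_equal(as.character(hg$groups[c("a1", "a2", "a3", "a4")]),
                 c("hap1", "hap2", "hap3", "hap4"))
    expect_false("a5" %in% names(hg$groups))
    # population without double carriers: hap4 empty
    withr::with_seed(53, {
        s1 <- rep(c(1L, 0L, 0L), times = c(30, 30, 40))
        s2 <- c(rep(0L, 60), rep(1L, 20), rep(0L, 20))
        names(s1) <- names(s2) <- sprintf("x%03d", 1:100)
        ex <- rlnorm(100, log(10), 0.3)
        names(ex) <- names(s1)
        ex[s1 == 1L] <- ex[s1 == 1L] * 3   # hap3 expresses 3-fold higher
        hg2 <- haplotypeGroups(s1, s2, expression = ex)
    })
    expect_equal(unname(hg2$counts["hap4"]), 0L)
    t13 <- hg2$tests[hg2$tests$group1 == "hap1" & hg2$tests$group2 == "hap3", ]
    expect_lt(t13$p, 0.05)
    expect_gt(t13$mean2, t13$mean1)
})

test_that("LD r2 is the squared dosage correlation with pairwise dropping", {
    sv <- matrix(c(0, 0, 1, 1), 4, 1, dimnames = list(paste0("a", 1:4), "sv"))
    snpSame <- matrix(c(0, 0, 1, 1), 4, 1,
                      dimnames = list(paste0("a", 1:4), "snp1"))
    expect_equal(ldR2(sv, snpSame)$bestR2, 1.0)
    snpFlip <- matrix(c(1, 1, 0, 0), 4, 1,
                      dimnames = list(paste0("a", 1:4), "snp1"))
    expect_equal(ldR2(sv, snpFlip)$bestR2, 1.0)   # sign-free
    withr::with_seed(57, {
        svR <- matrix(rbinom(200, 1, 0.4), 50, 4,
                      dimnames = list(sprintf("a%02d", 1:50),
                                      paste0("sv", 1:4)))
        snpR <- matrix(rbinom(150, 2, 0.3), 50, 3,
                       dimnames = list(sprintf("a%02d", 1:50),
                                       paste0("sn", 1:3)))
        got <- ldR2(svR, snpR)
        for (j in 1:4) {
            # textbook covariance-formula oracle
            r2 <- vapply(1:3, function(s) {
                x <- svR[, j]; y <- snpR[, s]
                cxy <- mean(x * y) - mean(x) * mean(y)
                vx <- mean(x^2) - mean(x)^2; vy <- mean(y^2) - mean(y)^2
                cxy^2 / (vx * vy)
            }, numeric(1))
            expect_equal(got$bestR2[j], max(r2), tolerance = 1e-9)
        }
        expect_equal(got$weakLD, got$bestR2 < 0.5)
    })
    # zero-variance SNP skipped
    snp0 <- matrix(1, 4, 1, dimnames = list(paste0("a", 1:4), "snp0"))
    expect_true(is.na(ldR2(sv, snp0)$bestR2))
})

test_that("cis/trans labelling uses the 20-kb window and the p threshold", {
    genes <- GenomicRanges::GRanges("C1", IRanges::IRanges(100001, 103000),
                                    geneID = "g1")
    svs <- GenomicRanges::GRanges(c("C1", "C1", "C2"),
                                  IRanges::IRanges(c(118001, 128002, 5000),
                                                   c(118100, 128101, 5099)),
                                  svID = c("near", "far", "other"))
    assoc <- data.frame(geneID = "g1", svID = c("near", "far", "other"),
                        p = c(1e-20, 1e-20, 1e-20))
    lab <- classifyCisTrans(assoc, genes, svs)
    expect_equal(lab$regulation, c("cis", "trans", "trans"))
    expect_equal(lab$distance[1], 118001 - 103000 - 1)  # 15,000 bp
    expect_true(is.na(lab$distance[3]))
    # signals above the threshold are dropped
    assoc$p <- c(1e-20, 1e-5, 1e-20)
    expect_equal(nrow(classifyCisTrans(assoc, genes, svs)), 2L)
    expect_error(classifyCisTrans(
        data.frame(geneID = "gX", svID = "near", p = 1e-20), genes, svs),
        "unknown")
})
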