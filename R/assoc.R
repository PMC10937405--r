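#' Case-control Fisher-exact SV association
#'
#' For every SV, accessions are split into a case group (one morphotype) and
#' a control group (all other morphotypes) and a 2x2 presence/absence table
#' of accession counts is tested with a two-tailed Fisher exact test (all
#' tables with point probability not exceeding the observed table's are
#' summed).  Missing genotypes are excluded per SV.  Bonferroni correction
#' multiplies by the number of SVs actually tested.
#'
#' @param genotypes a \code{\linkS4class{GenotypeMatrix}} whose
#'   \code{accessionData} carries a \code{morphotype} column.
#' @param caseLabel morphotype label of the case group.
#' @return data.frame, one row per tested SV: \code{svID},
#'   \code{casePresence}, \code{caseAbsence}, \code{controlPresence},
#'   \code{controlAbsence}, \code{pRaw}, \code{pBonferroni},
#'   \code{enrichedIn} (\code{"case"} or \code{"control"}, by odds of
#'   presence).  SVs with an empty table margin are skipped.
#' @examples
#' \dontrun{
#' res <- caseControlFisher(gt, caseLabel = "cauliflower")
#' head(res[order(res$pRaw), ])
#' }
#' @export
caseControlFisher <- function(genotypes, caseLabel) {
    mt <- morphotypes(genotypes)
    if (!caseLabel %in% mt)
        stop("no accession labelled '", caseLabel, "'")
    m <- calls(genotypes)
    isCase <- mt == caseLabel
    rows <- lapply(colnames(m), function(sv) {
        g <- m[, sv]
        ok <- !is.na(g)
        tab <- matrix(c(sum(g[ok & isCase] == 1L), sum(g[ok & isCase] == 0L),
                        sum(g[ok & !isCase] == 1L),
                        sum(g[ok & !isCase] == 0L)),
                      nrow = 2, byrow = TRUE)
        if (any(rowSums(tab) == 0) || all(colSums(tab) == 0))
            return(NULL)
        p <- stats::fisher.test(tab, alternative = "two.sided")$p.value
        caseRate <- tab[1, 1] / sum(tab[1, ])
        ctrlRate <- tab[2, 1] / sum(tab[2, ])
        data.frame(svID = sv, casePresence = tab[1, 1],
                   caseAbsence = tab[1, 2], controlPresence = tab[2, 1],
                   controlAbsence = tab[2, 2], pRaw = p,
                   enrichedIn = if (caseRate >= ctrlRate) "case" else "control")
    })
    out <- do.call(rbind, rows)
    if (is.null(out))
        return(data.frame(svID = character(), casePresence = integer(),
                          caseAbsence = integer(), controlPresence = integer(),
                          controlAbsence = integer(), pRaw = numeric(),
                          pBonferroni = numeric(), enrichedIn = character()))
    out$pBonferroni <- pmin(1, out$pRaw * nrow(out))
    rownames(out) <- NULL
    out[, c("svID", "casePresence", "caseAbsence", "controlPresence",
            "controlAbsence", "pRaw", "pBonferroni", "enrichedIn")]
}

#' Select significant and top-fraction association signals
#'
#' Two selections from an association table: (i) the Bonferroni-significant
#' set (\code{pBonferroni < alpha}) and (ii) the smallest-p top-fraction
#' set (the \code{ceiling(topFraction * n)} smallest raw p-values, with all
#' ties at the cut included).
#'
#' @param results data.frame from \code{\link{caseControlFisher}} (needs
#'   \code{svID}, \code{pRaw}, \code{pBonferroni}).
#' @param config an \code{\link{analysisConfig}} (uses \code{alpha},
#'   \code{topFraction}).
#' @return List with \code{bonferroni} and \code{topFraction} (character
#'   vectors of svIDs) and \code{pCut} (largest raw p inside the
#'   top-fraction set).
#' @export
selectSignals <- function(results, config = analysisConfig()) {
    stopifnot(nrow(results) > 0)
    bonf <- results$svID[results$pBonferroni < config$alpha]
    k <- ceiling(config$topFraction * nrow(results))
    ord <- order(results$pRaw)
    pCut <- results$pRaw[ord[k]]
    top <- results$svID[results$pRaw <= pCut]
    list(bonferroni = bonf, topFraction = top, pCut = pCut)
}

#' Two-SV haplotype groups and expression comparison
#'
#' Groups accessions by the joint presence/absence calls of two SVs:
#' \code{hap1} = neither SV, \code{hap2} = SV2 only, \code{hap3} = SV1
#' only, \code{hap4} = both.  Accessions missing either call are excluded.
#' When an expression vector is supplied, all pairwise two-sided Student's
#' t-tests among nonempty groups are reported.
#'
#' @param sv1,sv2 integer vectors of presence calls (1/0/NA) on the same
#'   named accessions.
#' @param expression optional named numeric vector of the gene's TPM per
#'   accession.
#' @return List with \code{groups} (factor hap1..hap4 per retained
#'   accession), \code{counts}, and \code{tests} (data.frame of pairwise
#'   comparisons, or NULL when fewer than two groups are nonempty or no
#'   expression is given).
#' @export
haplotypeGroups <- function(sv1, sv2, expression = NULL) {
    stopifnot(length(sv1) == length(sv2))
    if (is.null(names(sv1))) names(sv1) <- names(sv2) <-
            paste0("acc", seq_along(sv1))
    ok <- !is.na(sv1) & !is.na(sv2)
    g <- ifelse(sv1[ok] == 0 & sv2[ok] == 0, "hap1",
         ifelse(sv1[ok] == 0 & sv2[ok] == 1, "hap2",
         ifelse(sv1[ok] == 1 & sv2[ok] == 0, "hap3", "hap4")))
    groups <- factor(g, levels = c("hap1", "hap2", "hap3", "hap4"))
    names(groups) <- names(sv1)[ok]
    counts <- table(groups)
    tests <- NULL
    if (!is.null(expression) && is.null(names(expression)))
        stop("expression must be named by accession")
    if (!is.null(expression) && sum(counts >= 2) >= 2) {
        nonEmpty <- names(counts)[counts >= 2]
        prs <- utils::combn(nonEmpty, 2)
        tests <- do.call(rbind, lapply(seq_len(ncol(prs)), function(j) {
            a <- expression[names(groups)[groups == prs[1, j]]]
            b <- expression[names(groups)[groups == prs[2, j]]]
            tt <- stats::t.test(a, b, alternative = "two.sided")
            data.frame(group1 = prs[1, j], group2 = prs[2, j],
                       mean1 = mean(a), mean2 = mean(b), p = tt$p.value)
        }))
    }
    list(groups = groups, counts = counts, tests = tests)
}

#' LD between SVs and SNPs
#'
#' For each SV, the squared Pearson correlation of allele dosages with each
#' supplied SNP (pairs with missing values dropped pairwise), the best r^2
#' over all SNPs, and a weak-LD flag (best r^2 below \code{weakThreshold}).
#' Zero-variance pairs are skipped.
#'
#' @param svDosages numeric matrix, accessions x SVs.
#' @param snpDosages numeric matrix, accessions x SNPs (same accession
#'   order).
#' @param weakThreshold r^2 below which LD counts as weak (default 0.5).
#' @return data.frame per SV: \code{svID}, \code{bestR2}, \code{bestSnp},
#'   \code{weakLD}.
#' @export
ldR2 <- function(svDosages, snpDosages, weakThreshold = 0.5) {
    stopifnot(nrow(svDosages) == nrow(snpDosages))
    out <- lapply(colnames(svDosages), function(sv) {
        x <- svDosages[, sv]
        r2 <- vapply(colnames(snpDosages), function(sn) {
            y <- snpDosages[, sn]
            ok <- !is.na(x) & !is.na(y)
            if (sum(ok) < 2 || stats::sd(x[ok]) == 0 || stats::sd(y[ok]) == 0)
                return(NA_real_)
            stats::cor(x[ok], y[ok])^2
        }, numeric(1))
        if (all(is.na(r2)))
            return(data.frame(svID = sv, bestR2 = NA_real_,
                              bestSnp = NA_character_, weakLD = NA))
        best <- which.max(r2)
        data.frame(svID = sv, bestR2 = r2[best],
                   bestSnp = colnames(snpDosages)[best],
                   weakLD = r2[best] < weakThreshold)
    })
    out <- do.call(rbind, out)
    rownames(out) <- NULL
    out
}

#' Cis/trans labelling of expression-association signals
#'
#' Retains association rows passing the significance threshold and labels a
#' signal \code{cis} when the SV lies on the same chromosome as the
#' associated gene and within \code{cisWindowBp} of the gene span
#' (edge-to-edge); all other retained signals, including interchromosomal
#' ones, are \code{trans}.
#'
#' @param assoc data.frame with columns \code{geneID}, \code{svID},
#'   \code{p} (association p-values from an external model fit).
#' @param genes \code{GRanges} with \code{geneID}.
#' @param svs \code{GRanges} with \code{svID} (or an \code{SVCatalog}).
#' @param pThreshold significance threshold on \code{p} (default 1e-10).
#' @param config an \code{\link{analysisConfig}} (uses \code{cisWindowBp}).
#' @return The retained rows of \code{assoc} with added columns
#'   \code{distance} (bp to gene span; NA across chromosomes) and
#'   \code{regulation} (\code{"cis"}/\code{"trans"}).
#' @export
classifyCisTrans <- function(assoc, genes, svs, pThreshold = 1e-10,
                             config = analysisConfig()) {
    if (methods::is(svs, "SVCatalog")) svs <- svRanges(svs)
    stopifnot(all(c("geneID", "svID", "p") %in% colnames(assoc)))
    gi <- match(assoc$geneID, genes$geneID)
    si <- match(assoc$svID, svs$svID)
    if (anyNA(gi) || anyNA(si))
        stop("unknown gene or SV id in association table")
    keep <- assoc$p < pThreshold
    assoc <- assoc[keep, , drop = FALSE]
    gi <- gi[keep]; si <- si[keep]
    if (!nrow(assoc)) {
        assoc$distance <- numeric(); assoc$regulation <- character()
        return(assoc)
    }
    sv <- .effectiveRanges(svs[si])
    gn <- genes[gi]
    sameChrom <- as.character(GenomicRanges::seqnames(sv)) ==
        as.character(GenomicRanges::seqnames(gn))
    d <- rep(NA_real_, nrow(assoc))
    if (any(sameChrom))
        d[sameChrom] <- GenomicRanges::distance(sv[sameChrom], gn[sameChrom],
                                                ignore.strand = TRUE)
    assoc$distance <- d
    assoc$regulation <- ifelse(sameChrom & d <= config$cisWindowBp,
                               "cis", "trans")
    rownames(assoc) <- NULL
    assoc
}
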