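#' @include catalog.R
NULL

.DISTANCE_BINS <- c("CDS", "intron", "0-1.5kb", "1.5-3kb", "3-5kb", "5-10kb")

#' Link SVs to their closest genes
#'
#' Assigns every catalog record to the nearest gene by edge-to-edge distance,
#' dropping records farther than \code{linkRadiusBp} from any gene.  The
#' signed distance is strand-aware (negative upstream of the gene, positive
#' downstream, 0 when SV and gene body overlap).  Each link carries one of
#' six distance bins: \code{CDS} (SV overlaps a CDS of the gene),
#' \code{intron} (overlaps the gene body but no CDS), then by absolute
#' distance \code{0-1.5kb}, \code{1.5-3kb}, \code{3-5kb}, \code{5-10kb}.
#'
#' @param catalog an \code{SVCatalog}.
#' @param genes \code{GRanges} of gene bodies with \code{geneID} and strand.
#' @param cds \code{GRanges} of CDS intervals with \code{geneID}.
#' @param config an \code{\link{analysisConfig}} (uses \code{linkRadiusBp}).
#' @return data.frame with columns \code{svID}, \code{geneID},
#'   \code{distance} (signed bp) and \code{bin}; one row per linked SV.
#' @export
linkSvToGene <- function(catalog, genes, cds, config = analysisConfig()) {
    gr <- .effectiveRanges(svRanges(catalog))
    hits <- GenomicRanges::distanceToNearest(gr, genes, ignore.strand = TRUE)
    q <- S4Vectors::queryHits(hits)
    s <- S4Vectors::subjectHits(hits)
    d <- S4Vectors::mcols(hits)$distance
    keep <- d <= config$linkRadiusBp
    q <- q[keep]; s <- s[keep]; d <- d[keep]
    if (!length(q))
        return(data.frame(svID = character(), geneID = character(),
                          distance = numeric(), bin = character()))
    sv <- gr[q]; gn <- genes[s]
    minus <- as.character(GenomicRanges::strand(gn)) == "-"
    leftOfGene <- GenomicRanges::end(sv) < GenomicRanges::start(gn)
    rightOfGene <- GenomicRanges::start(sv) > GenomicRanges::end(gn)
    sign <- ifelse(!leftOfGene & !rightOfGene, 0,
            ifelse(xor(leftOfGene, minus), -1, 1))
    signed <- sign * d
    overlapsBody <- sign == 0
    cdsHit <- logical(length(q))
    if (length(cds)) {
        ov <- GenomicRanges::findOverlaps(sv, cds, ignore.strand = TRUE)
        sameGene <- gn$geneID[S4Vectors::queryHits(ov)] ==
            cds$geneID[S4Vectors::subjectHits(ov)]
        cdsHit[unique(S4Vectors::queryHits(ov)[sameGene])] <- TRUE
    }
    bin <- ifelse(overlapsBody & cdsHit, "CDS",
           ifelse(overlapsBody, "intron",
           ifelse(d <= 1500, "0-1.5kb",
           ifelse(d <= 3000, "1.5-3kb",
           ifelse(d <= 5000, "3-5kb", "5-10kb")))))
    data.frame(svID = sv$svID, geneID = gn$geneID, distance = signed,
               bin = factor(bin, levels = .DISTANCE_BINS))
}

#' Reference-free presence/absence orientation
#'
#' Converts reference-based alternate-allele carrier calls into
#' reference-free presence/absence calls: whatever genome served as
#' reference, the allele with more sequence is \code{presence} (1).  Thus
#' carriers of an insertion allele become presence, carriers of a deletion
#' allele become absence, and re-referencing an SV leaves the labels
#' unchanged.
#'
#' @param altCarrier integer vector or matrix of reference-based calls:
#'   1 = carries the alternate allele (any genotype with at least one
#'   alternate allele), 0 = homozygous reference, NA = missing.
#' @param refLength,altLength lengths in bp of the reference and alternate
#'   alleles at this SV.
#' @return Same shape as \code{altCarrier}, recoded so that 1 marks
#'   carriers of the longer allele.
#' @examples
#' orientGenotypes(c(1L, 0L, NA), refLength = 600, altLength = 100)
#' @export
orientGenotypes <- function(altCarrier, refLength, altLength) {
    if (refLength == altLength)
        stop("equal allele lengths: not a presence/absence variant")
    if (altLength > refLength) altCarrier else 1L - altCarrier
}

#' Expression filter
#'
#' A gene (or genotype group) counts as expressed when strictly more than a
#' configured fraction of its samples reach a TPM floor: panel mode uses
#' TPM >= 1 in more than 60\% of samples; population mode uses TPM >= 5 in
#' more than 30\% of samples.
#'
#' @param tpm numeric vector of TPM values.
#' @param mode \code{"panel"} or \code{"population"}.
#' @param config an \code{\link{analysisConfig}}.
#' @return Logical scalar.
#' @examples
#' expressedFilter(c(2, 2, 2, 0, 0), "panel")   # 3/5 = 0.60, not > 0.60
#' @export
expressedFilter <- function(tpm, mode = c("panel", "population"),
                            config = analysisConfig()) {
    mode <- match.arg(mode)
    stopifnot(length(tpm) >= 1)
    if (mode == "panel")
        mean(tpm >= config$tpmMinPanel) > config$fracMinPanel
    else
        mean(tpm >= config$tpmMinPop) > config$fracMinPop
}

.directionFromMeans <- function(meanPresence, meanAbsence, fold) {
    if (meanPresence == 0 && meanAbsence == 0) return("none")
    if (meanPresence >= fold * meanAbsence) return("promoting")
    if (meanAbsence >= fold * meanPresence) return("suppressing")
    "none"
}

.emptyDosageCalls <- function() {
    data.frame(svID = character(), geneID = character(), bin = character(),
               nPresence = integer(), nAbsence = integer(),
               meanPresence = numeric(), meanAbsence = numeric(),
               foldRatio = numeric(), direction = character(),
               pValue = numeric(), mode = character(), reason = character())
}

#' Panel-mode dosage calls
#'
#' For each SV-gene link, splits the assembly-panel genomes into presence and
#' absence genotype groups and compares mean TPM.  Eligibility follows the
#' panel design: only one SV may link to the gene within the search radius,
#' both genotype groups must hold at least \code{minGenomesPerGroup} genomes,
#' and the gene must pass the panel expression rule in at least one group.
#' Direction is called from the group means at \code{foldThreshold}
#' (inclusive): presence mean at least 1.5-fold above absence mean =
#' promoting; absence mean at least 1.5-fold above presence mean =
#' suppressing; a zero denominator with positive numerator qualifies; both
#' means zero gives \code{none}.
#'
#' @param links data.frame from \code{\link{linkSvToGene}}.
#' @param presence integer matrix of panel presence calls, genomes x SVs
#'   (1 presence / 0 absence / NA).
#' @param expr numeric TPM matrix, genes x genomes.
#' @param config an \code{\link{analysisConfig}}.
#' @return data.frame of dosage calls, one row per link, with
#'   \code{direction} in \{suppressing, promoting, none\} for eligible rows
#'   and a \code{reason} string for skipped rows (direction NA).
#' @export
callDosagePanel <- function(links, presence, expr,
                            config = analysisConfig()) {
    .callDosage(links, presence, expr, config, mode = "panel")
}

#' Population-mode dosage calls
#'
#' As \code{\link{callDosagePanel}}, but on population genotypes and
#' expression: an SV is eligible when at least \code{minGenotyped} accessions
#' are successfully genotyped and each genotype group holds at least
#' \code{minGroupSize} accessions; the gene must pass the population
#' expression rule (TPM >= 5 in more than 30\% of samples).  Group means are
#' compared with a two-sided Mann-Whitney U test and a direction is assigned
#' only when p < alpha and the fold rule holds; otherwise \code{none}.
#'
#' @param links data.frame from \code{\link{linkSvToGene}}.
#' @param genotypes a \code{\linkS4class{GenotypeMatrix}} or an integer
#'   matrix of accession x SV presence calls.
#' @param expr numeric TPM matrix, genes x accessions.
#' @param config an \code{\link{analysisConfig}}.
#' @return data.frame of dosage calls (see \code{\link{callDosagePanel}})
#'   with a Mann-Whitney \code{pValue} per eligible row.
#' @export
callDosagePopulation <- function(links, genotypes, expr,
                                 config = analysisConfig()) {
    m <- if (methods::is(genotypes, "GenotypeMatrix")) calls(genotypes)
         else genotypes
    .callDosage(links, m, expr, config, mode = "population")
}

.callDosage <- function(links, gt, expr, config, mode) {
    # gt: accessions/genomes x SVs
    if (!nrow(links)) return(.emptyDosageCalls())
    multi <- links$geneID[duplicated(links$geneID)]
    samples <- intersect(rownames(gt), colnames(expr))
    rows <- lapply(seq_len(nrow(links)), function(i) {
        svid <- links$svID[i]; gid <- links$geneID[i]
        row <- data.frame(svID = svid, geneID = gid,
                          bin = as.character(links$bin[i]),
                          nPresence = NA_integer_, nAbsence = NA_integer_,
                          meanPresence = NA_real_, meanAbsence = NA_real_,
                          foldRatio = NA_real_, direction = NA_character_,
                          pValue = NA_real_, mode = mode,
                          reason = NA_character_)
        if (gid %in% multi) {
            row$reason <- "multiple SVs within link radius of gene"
            return(row)
        }
        if (!gid %in% rownames(expr) || !svid %in% colnames(gt)) {
            row$reason <- "gene or SV not in supplied matrices"
            return(row)
        }
        g <- gt[samples, svid]
        ok <- !is.na(g)
        g <- g[ok]; smp <- samples[ok]
        tpm <- expr[gid, smp]
        nP <- sum(g == 1L); nA <- sum(g == 0L)
        row$nPresence <- nP; row$nAbsence <- nA
        if (mode == "population" && length(g) < config$minGenotyped) {
            row$reason <- "fewer genotyped samples than minGenotyped"
            return(row)
        }
        minGrp <- if (mode == "panel") config$minGenomesPerGroup
                  else config$minGroupSize
        if (min(nP, nA) < minGrp) {
            row$reason <- "genotype group below minimum size"
            return(row)
        }
        expressed <- if (mode == "panel")
            expressedFilter(tpm[g == 1L], "panel", config) ||
                expressedFilter(tpm[g == 0L], "panel", config)
        else
            expressedFilter(tpm, "population", config)
        if (!expressed) {
            row$reason <- "gene not expressed under mode's rule"
            return(row)
        }
        mp <- mean(tpm[g == 1L]); ma <- mean(tpm[g == 0L])
        row$meanPresence <- mp; row$meanAbsence <- ma
        row$foldRatio <- if (ma > 0) mp / ma else if (mp > 0) Inf else NA_real_
        dir <- .directionFromMeans(mp, ma, config$foldThreshold)
        if (mode == "population") {
            p <- suppressWarnings(
                stats::wilcox.test(tpm[g == 1L], tpm[g == 0L],
                                   alternative = "two.sided"))$p.value
            row$pValue <- p
            if (p >= config$alpha) dir <- "none"
        }
        row$direction <- dir
        row
    })
    out <- do.call(rbind, rows)
    rownames(out) <- NULL
    out
}

#' Two-sided binomial test of suppression/promotion asymmetry
#'
#' Exact two-sided binomial test at null probability 0.5 of the split between
#' suppressing and promoting dosage calls; the two-sided p sums all outcome
#' probabilities not exceeding the observed outcome's probability.  Symmetric
#' in its arguments.
#'
#' @param nSuppressing,nPromoting nonnegative counts, not both zero.
#' @return Two-sided p-value.
#' @examples
#' asymmetryBinomial(10, 0)   # 2 * 0.5^10
#' @export
asymmetryBinomial <- function(nSuppressing, nPromoting) {
    stopifnot(nSuppressing >= 0, nPromoting >= 0,
              nSuppressing + nPromoting > 0)
    stats::binom.test(nSuppressing, nSuppressing + nPromoting,
                      p = 0.5, alternative = "two.sided")$p.value
}

#' Per-gene z-score normalisation
#'
#' Centers and scales each row of an expression submatrix to mean 0 and
#' sample standard deviation 1; constant rows map to all zeros.
#'
#' @param expr numeric matrix, genes x samples (>= 2 samples).
#' @return Matrix of the same shape.
#' @export
zscoreProfile <- function(expr) {
    stopifnot(ncol(expr) >= 2)
    mu <- rowMeans(expr)
    sdv <- apply(expr, 1, stats::sd)
    out <- sweep(expr, 1, mu, "-")
    nz <- sdv > 0
    out[nz, ] <- out[nz, , drop = FALSE] / sdv[nz]
    out[!nz, ] <- 0
    out
}

#' Distance-binned fold-change summary
#'
#' Summarises dosage-call fold ratios (presence mean over absence mean) per
#' distance bin on the log2 scale.
#'
#' @param dosageCalls data.frame from \code{\link{callDosagePanel}} or
#'   \code{\link{callDosagePopulation}}; rows without a finite positive fold
#'   ratio are dropped from the quantiles but counted.
#' @return data.frame per bin: \code{n} (all calls), \code{nFinite},
#'   quantiles \code{q05,q25,q50,q75,q95} of log2 fold ratio.
#' @export
foldChangeProfile <- function(dosageCalls) {
    dc <- dosageCalls[!is.na(dosageCalls$direction), , drop = FALSE]
    bins <- .DISTANCE_BINS
    out <- do.call(rbind, lapply(bins, function(b) {
        sub <- dc[dc$bin == b, , drop = FALSE]
        lf <- log2(sub$foldRatio)
        lf <- lf[is.finite(lf)]
        qs <- if (length(lf)) stats::quantile(lf, c(.05, .25, .5, .75, .95))
              else rep(NA_real_, 5)
        data.frame(bin = b, n = nrow(sub), nFinite = length(lf),
                   q05 = qs[1], q25 = qs[2], q50 = qs[3], q75 = qs[4],
                   q95 = qs[5])
    }))
    rownames(out) <- NULL
    out
}
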