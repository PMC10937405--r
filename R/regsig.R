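#' Weighted methylation level of an interval
#'
#' The weighted methylation level of a region is the sum of methylated CpG
#' read counts divided by the sum of total CpG read counts over all
#' qualifying cytosines in the region; a cytosine qualifies when covered by
#' at least \code{minCpgDepth} reads (default 3).  Pooling two disjoint
#' regions therefore equals the reads-weighted combination of their levels.
#'
#' @param sites data.frame of per-cytosine counts with columns \code{chrom},
#'   \code{pos} (1-based), \code{meth}, \code{total}.
#' @param chrom,start,end optional interval restriction (inclusive); when
#'   omitted, all sites are used.
#' @param config an \code{\link{analysisConfig}} (uses \code{minCpgDepth}).
#' @return Level in [0, 1], or \code{NA} when no site qualifies.
#' @examples
#' s <- data.frame(chrom = "sv1", pos = c(1, 5, 9),
#'                 meth = c(5, 0, 2), total = c(10, 3, 2))
#' weightedMethylation(s)  # (5+0)/(10+3); the depth-2 site is excluded
#' @export
weightedMethylation <- function(sites, chrom = NULL, start = NULL,
                                end = NULL, config = analysisConfig()) {
    stopifnot(all(c("chrom", "pos", "meth", "total") %in% colnames(sites)))
    if (any(sites$meth > sites$total))
        stop("methylated reads exceed total reads")
    keep <- sites$total >= config$minCpgDepth
    if (!is.null(chrom)) keep <- keep & sites$chrom == chrom
    if (!is.null(start)) keep <- keep & sites$pos >= start
    if (!is.null(end)) keep <- keep & sites$pos <= end
    if (!any(keep)) return(NA_real_)
    sum(sites$meth[keep]) / sum(sites$total[keep])
}

#' Detect CpG islands in a DNA sequence
#'
#' Slides a 200-bp window with step 1 and flags windows with GC fraction at
#' least \code{gcMin} (0.50) and observed/expected CpG ratio at least
#' \code{oeMin} (0.60), the Gardiner-Garden and Frommer criteria; the
#' observed/expected ratio is \code{nCpG * L / (nC * nG)}.  Overlapping or
#' contiguous qualifying windows are unioned into maximal islands.
#'
#' @param sequence a \code{DNAString} or single character string over
#'   \{A, C, G, T, N\}.
#' @param windowSize sliding-window width in bp (default 200; also the
#'   minimal island length).
#' @param gcMin minimal GC fraction (default 0.50).
#' @param oeMin minimal observed/expected CpG ratio (default 0.60).
#' @return data.frame of disjoint islands, 1-based inclusive: \code{start},
#'   \code{end}, \code{length}, \code{gcFraction}, \code{obsExpCpG}
#'   (the latter two recomputed on the merged interval).
#' @export
detectCpgIslands <- function(sequence, windowSize = 200L, gcMin = 0.50,
                             oeMin = 0.60) {
    s <- toupper(as.character(sequence))
    n <- nchar(s)
    if (n < windowSize)
        return(data.frame(start = integer(), end = integer(),
                          length = integer(), gcFraction = numeric(),
                          obsExpCpG = numeric()))
    ch <- strsplit(s, "", fixed = TRUE)[[1]]
    isC <- ch == "C"; isG <- ch == "G"
    isCG <- c(isC[-n] & isG[-1], FALSE)        # CG dinucleotide at pos i
    cC <- cumsum(isC); cG <- cumsum(isG); cCG <- cumsum(isCG)
    st <- seq_len(n - windowSize + 1L)
    en <- st + windowSize - 1L
    wc <- cC[en] - c(0, cC)[st]
    wg <- cG[en] - c(0, cG)[st]
    # CG starts inside the window: positions st .. en-1
    wcg <- cCG[en - 1L] - c(0, cCG)[st]
    gc <- (wc + wg) / windowSize
    oe <- ifelse(wc * wg > 0, wcg * windowSize / (wc * wg), 0)
    pass <- gc >= gcMin & oe >= oeMin
    if (!any(pass))
        return(data.frame(start = integer(), end = integer(),
                          length = integer(), gcFraction = numeric(),
                          obsExpCpG = numeric()))
    ir <- IRanges::reduce(IRanges::IRanges(start = st[pass], end = en[pass]))
    istart <- IRanges::start(ir); iend <- IRanges::end(ir)
    L <- iend - istart + 1L
    nC <- cC[iend] - c(0, cC)[istart]
    nG <- cG[iend] - c(0, cG)[istart]
    nCG <- cCG[iend - 1L] - c(0, cCG)[istart]
    data.frame(start = istart, end = iend, length = L,
               gcFraction = (nC + nG) / L,
               obsExpCpG = ifelse(nC * nG > 0, nCG * L / (nC * nG), 0))
}

#' Per-SV CpG-island density and high-methylation ratio
#'
#' For each SV presence-allele sequence: detects CpG islands, computes the
#' island density per kb of SV sequence, scores each island's weighted
#' methylation from the per-cytosine counts (coordinates on the SV
#' sequence), and reports the ratio of highly methylated islands (weighted
#' methylation at or above \code{highMethylationThreshold}) among all
#' islands.
#'
#' @param sequences named \code{DNAStringSet} of SV sequences (names =
#'   svID).
#' @param methylation data.frame of per-cytosine counts with \code{chrom}
#'   (svID), \code{pos}, \code{meth}, \code{total}.
#' @param config an \code{\link{analysisConfig}}.
#' @return data.frame per SV: \code{svID}, \code{length}, \code{nIslands},
#'   \code{islandDensity} (islands per kb), \code{nHigh}, \code{highRatio}
#'   (NA when the SV has no islands).
#' @export
islandStats <- function(sequences, methylation, config = analysisConfig()) {
    out <- lapply(names(sequences), function(id) {
        seq <- sequences[[id]]
        isl <- detectCpgIslands(seq)
        len <- length(seq)
        nH <- 0L
        if (nrow(isl)) {
            wm <- vapply(seq_len(nrow(isl)), function(k)
                weightedMethylation(methylation, chrom = id,
                                    start = isl$start[k], end = isl$end[k],
                                    config = config), numeric(1))
            nH <- sum(!is.na(wm) & wm >= config$highMethylationThreshold)
        }
        data.frame(svID = id, length = len, nIslands = nrow(isl),
                   islandDensity = nrow(isl) / (len / 1000),
                   nHigh = nH,
                   highRatio = if (nrow(isl)) nH / nrow(isl) else NA_real_)
    })
    out <- do.call(rbind, out)
    rownames(out) <- NULL
    out
}

#' Label-permutation test for a two-group mean difference
#'
#' Shuffles group labels \code{nPerm} times and reports the add-one
#' permutation p-value for the absolute difference of group means:
#' \eqn{p = (1 + \#\{|T_{perm}| \ge |T_{obs}|\}) / (1 + nPerm)}, bounded
#' below by \code{1/(nPerm + 1)} and never zero.
#'
#' @param a,b numeric vectors (both nonempty).
#' @param nPerm number of permutations (default 1000).
#' @param seed integer seed; equal seeds give identical p-values.
#' @return List with \code{statistic} (observed mean difference),
#'   \code{p} and \code{nPerm}.
#' @export
permutationTest <- function(a, b, nPerm = 1000L, seed = 1L) {
    stopifnot(length(a) >= 1, length(b) >= 1)
    obs <- mean(a) - mean(b)
    pool <- c(a, b)
    nA <- length(a); nTot <- length(pool)
    exceed <- withr::with_seed(seed, {
        sum(vapply(seq_len(nPerm), function(k) {
            idx <- sample.int(nTot, nA)
            abs(mean(pool[idx]) - mean(pool[-idx])) >= abs(obs)
        }, logical(1)))
    })
    list(statistic = obs, p = (1 + exceed) / (1 + nPerm), nPerm = nPerm)
}

#' Scan sequences for TF-binding-site consensus matches
#'
#' Counts matches of each IUPAC consensus motif on both strands of each
#' sequence (all offsets, overlaps allowed); the reverse strand is scanned
#' via the motif's reverse complement, so a palindromic motif counts once
#' per strand.
#'
#' @param sequences a \code{DNAStringSet} (or named character vector).
#' @param motifs data.frame with columns \code{name} and \code{consensus}
#'   (IUPAC alphabet).
#' @return Integer matrix, sequences x motifs.
#' @examples
#' scanTfbs(Biostrings::DNAStringSet(c(s1 = "AATGACGTAA")),
#'          data.frame(name = "bZIP", consensus = "TGACGT"))
#' @export
scanTfbs <- function(sequences, motifs) {
    if (!methods::is(sequences, "DNAStringSet"))
        sequences <- Biostrings::DNAStringSet(sequences)
    stopifnot(all(c("name", "consensus") %in% colnames(motifs)))
    counts <- vapply(seq_len(nrow(motifs)), function(j) {
        pat <- Biostrings::DNAString(motifs$consensus[j])
        fwd <- Biostrings::vcountPattern(pat, sequences, fixed = "subject")
        rev <- Biostrings::vcountPattern(Biostrings::reverseComplement(pat),
                                         sequences, fixed = "subject")
        fwd + rev
    }, integer(length(sequences)))
    counts <- matrix(counts, nrow = length(sequences),
                     dimnames = list(names(sequences), motifs$name))
    counts
}

#' TF-binding-site enrichment between promoting and suppressing SVs
#'
#' Per motif, the observed statistic is the difference in mean per-kb hit
#' count between the promoting and the suppressing SV sequence sets; set
#' labels are permuted \code{permNTfbs} times (one shared sequence of
#' permutations across motifs) and the add-one two-sided permutation
#' p-value is reported per motif.
#'
#' @param promoting,suppressing \code{DNAStringSet}s of SV sequences; both
#'   nonempty.
#' @param motifs data.frame with \code{name}, \code{consensus}.
#' @param config an \code{\link{analysisConfig}} (uses \code{permNTfbs}).
#' @param seed integer seed.
#' @return data.frame per motif: \code{motif}, \code{meanPromoting},
#'   \code{meanSuppressing} (per-kb rates), \code{statistic}, \code{p}.
#' @export
tfbsEnrichment <- function(promoting, suppressing, motifs,
                           config = analysisConfig(), seed = 1L) {
    if (length(promoting) == 0 || length(suppressing) == 0)
        stop("both SV sequence sets must be nonempty")
    allSeq <- c(promoting, suppressing)
    kb <- Biostrings::width(allSeq) / 1000
    rate <- scanTfbs(allSeq, motifs) / kb
    nP <- length(promoting); nTot <- length(allSeq)
    obs <- colMeans(rate[seq_len(nP), , drop = FALSE]) -
        colMeans(rate[-seq_len(nP), , drop = FALSE])
    nPerm <- config$permNTfbs
    exceed <- withr::with_seed(seed, {
        acc <- integer(ncol(rate))
        for (k in seq_len(nPerm)) {
            idx <- sample.int(nTot, nP)
            tp <- colMeans(rate[idx, , drop = FALSE]) -
                colMeans(rate[-idx, , drop = FALSE])
            acc <- acc + (abs(tp) >= abs(obs))
        }
        acc
    })
    data.frame(motif = colnames(rate),
               meanPromoting = colMeans(rate[seq_len(nP), , drop = FALSE]),
               meanSuppressing = colMeans(rate[-seq_len(nP), , drop = FALSE]),
               statistic = unname(obs),
               p = (1 + exceed) / (1 + nPerm), row.names = NULL)
}
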