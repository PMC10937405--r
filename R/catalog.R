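#' @include SVCatalog-methods.R
NULL

#' Merge per-genome SV records into a nonredundant catalog
#'
#' Records of the same SV type whose reference intervals overlap or are
#' bookended (end of one equals start of the next minus one: "continuous")
#' are unioned into a single record whose \code{sourceGenomes} is the union
#' of the inputs'.  Zero-width insertion records are merged when their
#' breakpoints lie within \code{insBreakpointTol} bp and their alternate
#' lengths differ by at most \code{insLengthTol} (relative); this
#' breakpoint-and-length rule is a desk-scale proxy for sequence clustering
#' at 95\% identity and both knobs are exposed.
#'
#' The operation is idempotent and order-independent: merging a merged
#' catalog returns it unchanged, and permuting the input records yields the
#' identical catalog (records are sorted internally).
#'
#' @param catalog an \code{\linkS4class{SVCatalog}} of per-genome records.
#' @param insBreakpointTol breakpoint tolerance in bp for insertion merging
#'   (default 10).
#' @param insLengthTol relative alternate-length tolerance for insertion
#'   merging (default 0.10).
#' @return A nonredundant \code{SVCatalog}; never more records than the
#'   input.
#' @examples
#' cat <- SVCatalog(chrom = "C1", start = c(101, 151), end = c(200, 250),
#'                  svType = "absence_PAV", altLength = 0,
#'                  sourceGenomes = list("g1", "g2"))
#' length(mergeSVs(cat))  # 1
#' @export
mergeSVs <- function(catalog, insBreakpointTol = 10, insLengthTol = 0.10) {
    gr <- svRanges(catalog)
    if (length(gr) == 0) return(catalog)
    chr <- as.character(GenomicRanges::seqnames(gr))
    isIns <- GenomicRanges::width(gr) == 0
    out <- list()
    for (tp in unique(gr$svType)) {
        sel <- gr$svType == tp & !isIns
        if (any(sel))
            out[[length(out) + 1L]] <- .mergeIntervalRecords(gr[sel], tp)
        sel <- gr$svType == tp & isIns
        if (any(sel))
            out[[length(out) + 1L]] <- .mergeInsertionRecords(
                gr[sel], tp, insBreakpointTol, insLengthTol)
    }
    merged <- do.call(c, unname(out))
    merged <- GenomicRanges::sort(merged, ignore.strand = TRUE)
    merged$svID <- sprintf("nrsv%05d", seq_along(merged))
    methods::new("SVCatalog", ranges = merged)
}

.mergeIntervalRecords <- function(gr, tp) {
    # reduce() with default min.gapwidth = 1 unions overlapping and
    # bookended ("continuous") ranges
    red <- GenomicRanges::reduce(gr, ignore.strand = TRUE)
    hits <- GenomicRanges::findOverlaps(gr, red)
    grp <- S4Vectors::subjectHits(hits)[order(S4Vectors::queryHits(hits))]
    src <- lapply(split(seq_along(gr), grp),
                  function(i) sort(unique(unlist(gr$sourceGenomes[i]))))
    alt <- vapply(split(gr$altLength, grp), max, numeric(1))
    red$svID <- NA_character_
    red$svType <- tp
    red$altLength <- as.numeric(alt)
    red$sourceGenomes <- IRanges::CharacterList(unname(src))
    red$teOverlap <- NA_real_
    red
}

.mergeInsertionRecords <- function(gr, tp, bpTol, lenTol) {
    bp <- GenomicRanges::start(gr)
    chr <- as.character(GenomicRanges::seqnames(gr))
    ord <- order(chr, bp, gr$altLength, gr$svID)
    gr <- gr[ord]; bp <- bp[ord]; chr <- chr[ord]
    n <- length(gr)
    grp <- integer(n)
    cur <- 0L
    anchorBp <- -Inf; anchorLen <- NA_real_; anchorChr <- ""
    for (i in seq_len(n)) {
        len <- gr$altLength[i]
        sameCluster <- cur > 0L && chr[i] == anchorChr &&
            (bp[i] - anchorBp) <= bpTol &&
            abs(len - anchorLen) <= lenTol * max(len, anchorLen)
        if (!sameCluster) {
            cur <- cur + 1L
            anchorBp <- bp[i]; anchorLen <- len; anchorChr <- chr[i]
        }
        grp[i] <- cur
    }
    idx <- split(seq_len(n), grp)
    starts <- vapply(idx, function(i) min(bp[i]), numeric(1))
    chroms <- vapply(idx, function(i) chr[i[1]], character(1))
    alt <- vapply(idx, function(i) max(gr$altLength[i]), numeric(1))
    src <- lapply(idx, function(i) sort(unique(unlist(gr$sourceGenomes[i]))))
    res <- GenomicRanges::GRanges(
        seqnames = chroms,
        ranges = IRanges::IRanges(start = starts, width = 0),
        svID = NA_character_, svType = tp, altLength = as.numeric(alt),
        sourceGenomes = IRanges::CharacterList(unname(src)),
        teOverlap = NA_real_)
    res
}

#' Annotate the genomic context of each SV
#'
#' Labels every catalog record with the region it falls in, using the
#' precedence \code{exon > intron > upstream > downstream > intergenic} when
#' a record touches several.  Upstream/downstream windows extend
#' \code{contextFlankBp} from the gene ends and are strand-aware.  Zero-width
#' insertion breakpoints are treated as the single base to their left.
#'
#' @param catalog an \code{SVCatalog}.
#' @param genes \code{GRanges} of gene bodies carrying \code{geneID} and
#'   strand.
#' @param cds \code{GRanges} of exon/CDS intervals carrying \code{geneID}.
#' @param config an \code{\link{analysisConfig}} (uses
#'   \code{contextFlankBp}).
#' @return Character vector (one label per record) over
#'   \{\code{exon}, \code{intron}, \code{upstream}, \code{downstream},
#'   \code{intergenic}\}.
#' @export
annotateContext <- function(catalog, genes, cds, config = analysisConfig()) {
    gr <- .effectiveRanges(svRanges(catalog))
    flank <- config$contextFlankBp
    up <- GenomicRanges::promoters(genes, upstream = flank, downstream = 0)
    down <- .downstreamFlank(genes, flank)
    lab <- rep("intergenic", length(gr))
    ov <- function(subject) IRanges::overlapsAny(gr, subject,
                                                 ignore.strand = TRUE)
    lab[ov(down)] <- "downstream"
    lab[ov(up)] <- "upstream"
    lab[ov(genes)] <- "intron"
    lab[ov(cds)] <- "exon"
    lab
}

.effectiveRanges <- function(gr) {
    # zero-width insertion breakpoints occupy the base left of the breakpoint
    w0 <- GenomicRanges::width(gr) == 0
    if (any(w0)) {
        st <- GenomicRanges::start(gr)
        GenomicRanges::start(gr)[w0] <- pmax(1L, st[w0] - 1L)
        GenomicRanges::end(gr)[w0] <- pmax(1L, st[w0] - 1L)
    }
    gr
}

.downstreamFlank <- function(genes, flank) {
    minus <- as.character(GenomicRanges::strand(genes)) == "-"
    st <- ifelse(minus,
                 pmax(1L, GenomicRanges::start(genes) - flank),
                 GenomicRanges::end(genes) + 1L)
    en <- ifelse(minus,
                 GenomicRanges::start(genes) - 1L,
                 GenomicRanges::end(genes) + flank)
    keep <- en >= st
    GenomicRanges::GRanges(
        seqnames = GenomicRanges::seqnames(genes)[keep],
        ranges = IRanges::IRanges(start = st[keep], end = en[keep]))
}

#' SV sequence density around genes
#'
#' Mean SV base-pair coverage per bin, averaged over genes, for the upstream
#' flank, the (length-normalised) gene body and the downstream flank.
#' Flanks are cut into absolute bins of \code{binSize} bp; gene bodies are
#' rescaled to \code{nBodyBins} relative bins.  Minus-strand genes are
#' flipped so that bins read 5' to 3'.
#'
#' @param catalog an \code{SVCatalog} (nonredundant).
#' @param genes \code{GRanges} of gene bodies.
#' @param flank flank size in bp (default 5000).
#' @param nBodyBins relative bins across the gene body (default 50).
#' @param binSize absolute flank bin width in bp (default 100).
#' @return data.frame with columns \code{region} (upstream/body/downstream),
#'   \code{bin} (1-based within region) and \code{density} (mean covered bp
#'   per bin per gene; flank bins are additionally divided by
#'   \code{binSize}, body bins by the per-gene bin width, so densities are
#'   per-bp fractions in [0, 1]).
#' @export
densityProfile <- function(catalog, genes, flank = 5000L, nBodyBins = 50L,
                           binSize = 100L) {
    gr <- .effectiveRanges(svRanges(catalog))
    cov <- GenomicRanges::coverage(GenomicRanges::reduce(gr,
                                                         ignore.strand = TRUE))
    nFlankBins <- as.integer(flank / binSize)
    upM <- matrix(0, length(genes), nFlankBins)
    doM <- matrix(0, length(genes), nFlankBins)
    boM <- matrix(0, length(genes), nBodyBins)
    for (i in seq_along(genes)) {
        chr <- as.character(GenomicRanges::seqnames(genes))[i]
        if (!chr %in% names(cov)) next
        v <- cov[[chr]]
        gs <- GenomicRanges::start(genes)[i]
        ge <- GenomicRanges::end(genes)[i]
        minus <- as.character(GenomicRanges::strand(genes))[i] == "-"
        upM[i, ] <- .flankBinCover(v, gs, ge, flank, binSize, left = !minus)
        doM[i, ] <- .flankBinCover(v, gs, ge, flank, binSize, left = minus)
        boM[i, ] <- .bodyBinCover(v, gs, ge, nBodyBins, rev = minus)
    }
    data.frame(
        region = rep(c("upstream", "body", "downstream"),
                     c(nFlankBins, nBodyBins, nFlankBins)),
        bin = c(seq_len(nFlankBins), seq_len(nBodyBins), seq_len(nFlankBins)),
        density = c(colMeans(upM), colMeans(boM), colMeans(doM)))
}

.rleWindowSum <- function(v, from, to) {
    # covered-bp totals from an Rle coverage vector, clipped to [1, length]
    from <- max(1L, from); to <- min(length(v), to)
    if (to < from) return(0)
    sum(as.numeric(S4Vectors::window(v, from, to) > 0))
}

.flankBinCover <- function(v, gs, ge, flank, binSize, left) {
    n <- as.integer(flank / binSize)
    out <- numeric(n)
    for (b in seq_len(n)) {
        if (left) { # bins read outermost -> gene (5' to 3' on + strand)
            from <- gs - flank + (b - 1L) * binSize
            to <- from + binSize - 1L
        } else {
            from <- ge + (b - 1L) * binSize + 1L
            to <- from + binSize - 1L
        }
        out[b] <- .rleWindowSum(v, from, to) / binSize
    }
    if (!left) out else out
}

.bodyBinCover <- function(v, gs, ge, nBins, rev = FALSE) {
    L <- ge - gs + 1L
    edges <- gs + floor(seq(0, L, length.out = nBins + 1L))
    out <- numeric(nBins)
    for (b in seq_len(nBins)) {
        from <- edges[b]
        to <- edges[b + 1L] - 1L
        w <- max(1L, to - from + 1L)
        out[b] <- .rleWindowSum(v, from, to) / w
    }
    if (rev) rev(out) else out
}

#' TE overlap of catalog records
#'
#' Per-record fraction of the reference span covered by transposable-element
#' intervals, and the catalog-level fraction of records with any overlap.
#' Pure insertions carry no reference span, so their fraction is 0 (the
#' alternate allele is not TE-annotated here).
#'
#' @param catalog an \code{SVCatalog}.
#' @param te \code{GRanges} of TE intervals on the same reference.
#' @return List with \code{perSV} (numeric vector of fractions, named by
#'   svID) and \code{anyOverlapFraction} (scalar).
#' @export
teOverlapFractions <- function(catalog, te) {
    gr <- svRanges(catalog)
    te <- GenomicRanges::reduce(te, ignore.strand = TRUE)
    frac <- numeric(length(gr))
    w <- GenomicRanges::width(gr)
    pos <- which(w > 0)
    if (length(pos)) {
        # per-record intersection (records may overlap each other, so
        # compute individually)
        for (i in pos) {
            ov <- GenomicRanges::intersect(GenomicRanges::granges(gr[i]), te,
                                           ignore.strand = TRUE)
            frac[i] <- sum(GenomicRanges::width(ov)) / w[i]
        }
    }
    names(frac) <- gr$svID
    list(perSV = frac,
         anyOverlapFraction = if (length(frac)) mean(frac > 0) else NA_real_)
}

#' Private-SV counts and between-group comparison
#'
#' An SV is private when exactly one panel genome carries it
#' (\code{length(sourceGenomes) == 1}).  Counts are tallied per genome and
#' two chosen genome groups are compared with a two-sided Wilcoxon rank-sum
#' test (exact for small groups, normal approximation with tie correction
#' otherwise, as \code{\link[stats]{wilcox.test}} does).
#'
#' @param catalog an \code{SVCatalog} whose records carry
#'   \code{sourceGenomes}.
#' @param genomeGroups named list of character vectors of genome ids; when
#'   exactly two groups are supplied their private counts are compared.
#' @return List with \code{perGenome} (named integer vector of private-SV
#'   counts; genomes listed in \code{genomeGroups} always appear, others as
#'   observed) and \code{test} (htest or NULL; NULL with a warning when a
#'   group has fewer than 2 members).
#' @export
privateSvStats <- function(catalog, genomeGroups = NULL) {
    src <- sourceGenomes(catalog)
    nSrc <- lengths(src)
    priv <- unlist(src[nSrc == 1L])
    genomes <- sort(unique(c(unlist(src), unlist(genomeGroups))))
    perGenome <- stats::setNames(integer(length(genomes)), genomes)
    if (length(priv)) {
        tab <- table(priv)
        perGenome[names(tab)] <- as.integer(tab)
    }
    test <- NULL
    if (!is.null(genomeGroups)) {
        if (length(genomeGroups) != 2)
            stop("genomeGroups must contain exactly two groups")
        a <- perGenome[genomeGroups[[1]]]
        b <- perGenome[genomeGroups[[2]]]
        if (length(a) < 2 || length(b) < 2) {
            warning("group with fewer than 2 genomes: p undefined")
        } else {
            test <- stats::wilcox.test(a, b, alternative = "two.sided",
                                       exact = (length(a) <= 12 &&
                                                length(b) <= 12 &&
                                                !any(duplicated(c(a, b)))))
        }
    }
    list(perGenome = perGenome, test = test)
}

#' Pan-genome SV saturation fit
#'
#' Fits the exponential saturation model \eqn{P(n) = A - B e^{-n/C}} to
#' cumulative nonredundant SV counts as genomes are added, by least squares
#' (Levenberg-Marquardt).  When a catalog is supplied, cumulative curves are
#' computed over \code{nOrderings} random genome orderings and the predicted
#' total is the mean fitted asymptote A with its standard deviation across
#' orderings.
#'
#' @param x either a numeric vector / matrix of cumulative counts (one curve
#'   per row; column n = panel size n) or an \code{SVCatalog}.
#' @param nOrderings random genome orderings when \code{x} is a catalog
#'   (default 30).
#' @param seed integer seed for the orderings.
#' @return List with \code{A}, \code{B}, \code{C} (mean fitted parameters),
#'   \code{predictedTotal} (mean A), \code{predictedSE} (sd of A across
#'   curves; NA for a single curve) and \code{perCurve} (data.frame of
#'   per-curve parameters).
#' @examples
#' n <- 1:27
#' fit <- saturationFit(1000 - 800 * exp(-n / 5))
#' fit$predictedTotal  # ~1000
#' @export
saturationFit <- function(x, nOrderings = 30L, seed = 1L) {
    if (methods::is(x, "SVCatalog")) {
        curves <- .saturationCurves(x, nOrderings, seed)
    } else if (is.matrix(x)) {
        curves <- x
    } else {
        curves <- matrix(as.numeric(x), nrow = 1)
    }
    if (ncol(curves) < 4)
        stop("need cumulative counts for at least 4 panel sizes")
    if (any(apply(curves, 1, function(r) any(diff(r) < 0))))
        stop("cumulative counts must be nondecreasing in panel size")
    pars <- t(apply(curves, 1, .fitOneSaturation))
    colnames(pars) <- c("A", "B", "C")
    list(A = mean(pars[, "A"]), B = mean(pars[, "B"]), C = mean(pars[, "C"]),
         predictedTotal = mean(pars[, "A"]),
         predictedSE = if (nrow(pars) > 1) stats::sd(pars[, "A"]) else NA_real_,
         perCurve = as.data.frame(pars))
}

.fitOneSaturation <- function(y) {
    n <- seq_along(y)
    if (max(y) - min(y) < 1e-9 * max(abs(y), 1))  # already saturated
        return(c(A = y[1], B = 0, C = 1))
    A0 <- max(y) * 1.05
    B0 <- max(A0 - y[1], 1)
    C0 <- max(length(y) / 3, 1)
    fit <- minpack.lm::nlsLM(
        y ~ A - B * exp(-n / C),
        start = list(A = A0, B = B0, C = C0),
        lower = c(A = 0, B = 0, C = 1e-6),
        control = minpack.lm::nls.lm.control(maxiter = 200))
    stats::coef(fit)[c("A", "B", "C")]
}

.saturationCurves <- function(catalog, nOrderings, seed) {
    src <- sourceGenomes(catalog)
    genomes <- sort(unique(unlist(src)))
    nG <- length(genomes)
    svSets <- lapply(src, function(s) match(s, genomes))
    withr::with_seed(seed, {
        t(vapply(seq_len(nOrderings), function(k) {
            ord <- sample(nG)
            rank <- integer(nG); rank[ord] <- seq_len(nG)
            first <- vapply(svSets, function(s) min(rank[s]), integer(1))
            cumsum(tabulate(first, nbins = nG))
        }, numeric(nG)))
    })
}

#' LTR insertion time from divergence
#'
#' Converts the divergence K (substitutions per site) between the two long
#' terminal repeats of a retrotransposon into an insertion age using the
#' molecular clock \eqn{T = K / (2 r)} with substitution rate r per site per
#' year.
#'
#' @param K divergence, substitutions per site; must be >= 0.
#' @param rate substitution rate per site per year (default 1.3e-8).
#' @return Insertion time in years.
#' @examples
#' ltrInsertionTime(0.026)  # 1e6 years
#' @export
ltrInsertionTime <- function(K, rate = 1.3e-8) {
    if (any(K < 0)) stop("divergence K must be >= 0")
    if (rate <= 0) stop("rate must be > 0")
    K / (2 * rate)
}
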