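# Independent brute-force oracles.  These deliberately avoid the code paths
# (and the packages) used by the implementation they check.

# two-sided Fisher exact p by direct hypergeometric enumeration over the
# table's support; probability ties use the conventional (1 + 1e-7) relative
# guard against log-gamma round-off
oracleFisherP <- function(tab) {
    a <- tab[1, 1]
    m <- sum(tab[1, ]); n <- sum(tab[2, ]); k <- sum(tab[, 1])
    lo <- max(0, k - n); hi <- min(k, m)
    probs <- stats::dhyper(lo:hi, m, n, k)
    obs <- stats::dhyper(a, m, n, k)
    sum(probs[probs <= obs * (1 + 1e-7)])
}

# two-sided binomial p at null 0.5 by direct pmf summation
oracleBinomP <- function(x, n) {
    probs <- stats::dbinom(0:n, n, 0.5)
    obs <- stats::dbinom(x, n, 0.5)
    sum(probs[probs <= obs * (1 + 1e-7)])
}

# sweep-line union of 1-based closed intervals; bookended intervals merge
oracleSweepUnion <- function(start, end) {
    ord <- order(start, end)
    start <- start[ord]; end <- end[ord]
    os <- start[1]; oe <- end[1]
    resS <- integer(); resE <- integer()
    for (i in seq_along(start)[-1]) {
        if (start[i] <= oe + 1L) {
            oe <- max(oe, end[i])
        } else {
            resS <- c(resS, os); resE <- c(resE, oe)
            os <- start[i]; oe <- end[i]
        }
    }
    cbind(start = c(resS, os), end = c(resE, oe))
}

# per-base genomic-context labels with precedence
# exon > intron > upstream > downstream > intergenic; features given as
# data.frames of 1-based closed intervals
oracleContext <- function(svStart, svEnd, svChrom, feat) {
    touches <- function(df) {
        if (!nrow(df)) return(FALSE)
        any(df$chrom == svChrom & df$start <= svEnd & df$end >= svStart)
    }
    if (touches(feat$exon)) return("exon")
    if (touches(feat$gene)) return("intron")
    if (touches(feat$up)) return("upstream")
    if (touches(feat$down)) return("downstream")
    "intergenic"
}

# edge-to-edge distance of 1-based closed intervals (0 when overlapping or
# bookended), as a plain formula
oracleGapDistance <- function(s1, e1, s2, e2) {
    if (s1 <= e2 && s2 <= e1) return(0L)
    if (s2 > e1) max(0L, s2 - e1 - 1L) else max(0L, s1 - e2 - 1L)
}

# exhaustive sliding-window CpG-island detection: every window tested by
# direct substring counting, qualifying window bases unioned, runs reported
oracleCpgIslands <- function(seq, win = 200L, gcMin = 0.5, oeMin = 0.6) {
    n <- nchar(seq)
    if (n < win) return(cbind(start = integer(), end = integer()))
    covered <- logical(n)
    for (st in seq_len(n - win + 1L)) {
        w <- substr(seq, st, st + win - 1L)
        nC <- lengths(regmatches(w, gregexpr("C", w, fixed = TRUE)))
        nG <- lengths(regmatches(w, gregexpr("G", w, fixed = TRUE)))
        nCG <- length(gregexpr("(?=CG)", w, perl = TRUE)[[1]])
        if (gregexpr("(?=CG)", w, perl = TRUE)[[1]][1] == -1) nCG <- 0
        gc <- (nC + nG) / win
        oe <- if (nC * nG > 0) nCG * win / (nC * nG) else 0
        if (gc >= gcMin && oe >= oeMin)
            covered[st:(st + win - 1L)] <- TRUE
    }
    if (!any(covered)) return(cbind(start = integer(), end = integer()))
    r <- rle(covered)
    ends <- cumsum(r$lengths)
    starts <- ends - r$lengths + 1L
    cbind(start = starts[r$values], end = ends[r$values])
}

# naive all-offset IUPAC consensus scan, both strands
oracleScan <- function(seq, consensus) {
    codes <- list(A = "A", C = "C", G = "G", T = "T", R = c("A", "G"),
                  Y = c("C", "T"), S = c("C", "G"), W = c("A", "T"),
                  K = c("G", "T"), M = c("A", "C"), B = c("C", "G", "T"),
                  D = c("A", "G", "T"), H = c("A", "C", "T"),
                  V = c("A", "C", "G"), N = c("A", "C", "G", "T"))
    rc <- function(x) {
        comp <- c(A = "T", C = "G", G = "C", T = "A", R = "Y", Y = "R",
                  S = "S", W = "W", K = "M", M = "K", B = "V", V = "B",
                  D = "H", H = "D", N = "N")
        paste(rev(comp[strsplit(x, "")[[1]]]), collapse = "")
    }
    countOne <- function(seq, pat) {
        p <- strsplit(pat, "")[[1]]
        s <- strsplit(seq, "")[[1]]
        L <- length(p); n <- length(s)
        if (n < L) return(0L)
        hits <- 0L
        for (off in 0:(n - L)) {
            ok <- TRUE
            for (j in seq_len(L)) {
                if (!s[off + j] %in% codes[[p[j]]]) { ok <- FALSE; break }
            }
            if (ok) hits <- hits + 1L
        }
        hits
    }
    countOne(seq, consensus) + countOne(seq, rc(consensus))
}

# uniform random DNA string
randomDna <- function(n, gc = 0.4) {
    paste(sample(c("A", "C", "G", "T"), n, replace = TRUE,
                 prob = c((1 - gc) / 2, gc / 2, gc / 2, (1 - gc) / 2)),
          collapse = "")
}

# small shared fixtures -------------------------------------------------

toyAnnotation <- function() {
    # two genes on one chromosome, opposite strands
    genes <- GenomicRanges::GRanges(
        "C1", IRanges::IRanges(c(10001, 50001), c(13000, 53000)),
        strand = c("+", "-"), geneID = c("gA", "gB"))
    cds <- GenomicRanges::GRanges(
        "C1", IRanges::IRanges(c(10001, 12001, 50001, 52001),
                               c(10800, 13000, 50800, 53000)),
        strand = c("+", "+", "-", "-"),
        geneID = c("gA", "gA", "gB", "gB"))
    list(genes = genes, cds = cds)
}

# build a GenotypeMatrix realising given 2x2 accession counts for one SV
gtFromCounts <- function(casePres, caseAbs, ctrlPres, ctrlAbs,
                         caseLabel = "case", svID = "sv1") {
    n <- casePres + caseAbs + ctrlPres + ctrlAbs
    g <- c(rep(1L, casePres), rep(0L, caseAbs),
           rep(1L, ctrlPres), rep(0L, ctrlAbs))
    m <- matrix(g, n, 1, dimnames = list(sprintf("a%04d", 1:n), svID))
    GenotypeMatrix(m, data.frame(
        morphotype = rep(c(caseLabel, "control"),
                         c(casePres + caseAbs, ctrlPres + ctrlAbs)),
        row.names = rownames(m)))
}

smallBundle <- function(seed = 7, nGenes = 120, nSVs = 60, ...) {
    simulatePanGenome(simConfig(nGenes = nGenes, nSVs = nSVs, seed = seed,
                                ...))
}
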