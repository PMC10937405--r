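#' @include config.R
NULL

.MOTIF_PANEL <- data.frame(
    name = c("TCP", "MYB", "NAC", "ERF", "GRAS"),
    consensus = c("GGNCCCAC", "WAACCA", "CACGTAAG", "GCCGCC", "GTCGGTAA"),
    stringsAsFactors = FALSE)

#' Simulate a pan-genome assembly panel with planted dosage effects
#'
#' Builds a synthetic pan-genome study with a known truth table: gene models
#' on nine chromosomes, one insertion SV per selected gene placed in one of
#' the six distance bins (CDS, intron, 0-1.5, 1.5-3, 3-5, 5-10 kb; flank
#' placements strand-aware on either side), per-genome presence calls, and a
#' panel TPM matrix in which presence-group means are multiplied (promoting)
#' or divided (suppressing) by the planted fold under multiplicative
#' log-normal noise.  Suppressing SV sequences carry an embedded CpG island;
#' promoting SV sequences carry embedded copies of the package's consensus
#' motif panel; null SV sequences are plain random background.
#'
#' Deterministic for a fixed \code{config$seed}: equal configurations yield
#' identical bundles.
#'
#' @param config a \code{\link{simConfig}}.
#' @return A \code{\linkS4class{SyntheticBundle}}.
#' @examples
#' b <- simulatePanGenome(simConfig(nGenes = 60, nSVs = 20, seed = 7))
#' table(svTruth(b)$direction)
#' @export
simulatePanGenome <- function(config = simConfig()) {
    stopifnot(inherits(config, "svdosage_simconfig"))
    withr::with_seed(config$seed, .simulatePanGenomeImpl(config))
}

.simulatePanGenomeImpl <- function(config) {
    nGenes <- config$nGenes; nSVs <- config$nSVs
    nGenomes <- config$nGenomes
    genomes <- sprintf("T%02d", seq_len(nGenomes))
    nChrom <- 9L
    perChrom <- ceiling(nGenes / nChrom)
    idx <- seq_len(nGenes) - 1L
    chrom <- sprintf("C%d", idx %/% perChrom + 1L)
    within <- idx %% perChrom
    gs <- 15001L + within * 24000L
    ge <- gs + 2999L
    strand <- sample(c("+", "-"), nGenes, replace = TRUE)
    geneID <- sprintf("gene%05d", seq_len(nGenes))
    genes <- GenomicRanges::GRanges(chrom, IRanges::IRanges(gs, ge),
                                    strand = strand, geneID = geneID)
    # two CDS exons flanking one intron
    cds <- c(GenomicRanges::GRanges(chrom, IRanges::IRanges(gs, gs + 799L),
                                    strand = strand, geneID = geneID),
             GenomicRanges::GRanges(chrom,
                                    IRanges::IRanges(gs + 2000L, ge),
                                    strand = strand, geneID = geneID))

    # --- SV truth table -----------------------------------------------
    if (nSVs > 0) {
        svGene <- sort(sample.int(nGenes, nSVs))
        bins <- sample(.DISTANCE_BINS, nSVs, replace = TRUE)
        side <- sample(c("upstream", "downstream"), nSVs, replace = TRUE)
        d <- integer(nSVs)
        d[bins == "0-1.5kb"] <- sample(1500L, sum(bins == "0-1.5kb"),
                                       replace = TRUE)
        d[bins == "1.5-3kb"] <- sample(1501:3000, sum(bins == "1.5-3kb"),
                                       replace = TRUE)
        d[bins == "3-5kb"] <- sample(3001:5000, sum(bins == "3-5kb"),
                                     replace = TRUE)
        d[bins == "5-10kb"] <- sample(5001:10000, sum(bins == "5-10kb"),
                                      replace = TRUE)
        gStart <- gs[svGene]; gEnd <- ge[svGene]; gMinus <- strand[svGene] == "-"
        left <- xor(side == "upstream", gMinus)
        bp <- ifelse(bins == "CDS", gStart + 400L,
              ifelse(bins == "intron", gStart + 1500L,
              ifelse(left, gStart - d, gEnd + d + 2L)))
        signedD <- ifelse(bins %in% c("CDS", "intron"), 0L,
                   ifelse(side == "upstream", -d, d))
        nSupp <- floor(config$fracSuppressing * nSVs)
        nProm <- floor(config$fracPromoting * nSVs)
        direction <- sample(rep(c("suppressing", "promoting", "none"),
                                c(nSupp, nProm, nSVs - nSupp - nProm)))
        fold <- ifelse(direction == "none", 1,
                       stats::runif(nSVs, config$effectFoldRange[1],
                                    config$effectFoldRange[2]))
        carrierLo <- min(4L, nGenomes - 1L)
        carrierHi <- max(carrierLo, nGenomes - 4L)
        nCarrier <- carrierLo +
            sample.int(carrierHi - carrierLo + 1L, nSVs, replace = TRUE) - 1L
        altLen <- sample(500:1500, nSVs, replace = TRUE)
        truth <- data.frame(
            svID = sprintf("sv%05d", seq_len(nSVs)),
            chrom = chrom[svGene], start = bp, end = bp - 1L,
            altLength = altLen, svType = "presence_PAV",
            geneID = geneID[svGene], distance = signedD, bin = bins,
            side = ifelse(bins %in% c("CDS", "intron"), NA, side),
            direction = direction, fold = fold, nCarriers = nCarrier,
            islandStart = NA_integer_, islandEnd = NA_integer_,
            stringsAsFactors = FALSE)
    } else {
        truth <- data.frame(
            svID = character(), chrom = character(), start = integer(),
            end = integer(), altLength = integer(), svType = character(),
            geneID = character(), distance = integer(), bin = character(),
            side = character(), direction = character(), fold = numeric(),
            nCarriers = integer(), islandStart = integer(),
            islandEnd = integer(), stringsAsFactors = FALSE)
    }

    # --- panel presence calls ----------------------------------------
    presence <- matrix(0L, nGenomes, nSVs,
                       dimnames = list(genomes, truth$svID))
    for (j in seq_len(nSVs))
        presence[sample.int(nGenomes, truth$nCarriers[j]), j] <- 1L

    # --- panel expression --------------------------------------------
    baseline <- stats::rlnorm(nGenes, meanlog = log(30), sdlog = 0.6)
    names(baseline) <- geneID
    expr <- .expressionWithEffects(baseline, presence, truth,
                                   config$noiseCV, genomes)

    # --- sequences ----------------------------------------------------
    seqs <- .svSequences(truth)
    truth$islandStart <- seqs$islandStart
    truth$islandEnd <- seqs$islandEnd
    promoters <- .randomDNA(nGenes, rep(1000L, nGenes), gcProb = 0.36)
    names(promoters) <- geneID

    cfg <- unclass(config)
    cfg$baseline <- baseline   # per-gene generator baseline, reused by
                               # the population stage
    methods::new("SyntheticBundle", genes = genes, cds = cds,
                 svTruth = truth, panelPresence = presence,
                 panelExpression = expr,
                 svSequences = seqs$sequences, promoters = promoters,
                 motifs = .MOTIF_PANEL, population = list(),
                 methylation = data.frame(), config = cfg)
}

# expression matrix genes x samples given carrier states (samples x SVs)
.expressionWithEffects <- function(baseline, carriers, truth, cv, samples) {
    nGenes <- length(baseline)
    n <- length(samples)
    sdlog <- sqrt(log(1 + cv^2))
    noise <- matrix(stats::rlnorm(nGenes * n, meanlog = -sdlog^2 / 2,
                                  sdlog = sdlog), nGenes, n)
    expr <- baseline * noise
    dimnames(expr) <- list(names(baseline), samples)
    for (j in seq_len(nrow(truth))) {
        if (truth$direction[j] == "none") next
        gid <- truth$geneID[j]
        carr <- carriers[, truth$svID[j]] == 1L
        carr[is.na(carr)] <- FALSE
        f <- truth$fold[j]
        if (truth$direction[j] == "suppressing")
            expr[gid, carr] <- expr[gid, carr] / f
        else
            expr[gid, carr] <- expr[gid, carr] * f
    }
    expr
}

.randomDNA <- function(n, widths, gcProb = 0.36) {
    p <- c(A = (1 - gcProb) / 2, C = gcProb / 2, G = gcProb / 2,
           T = (1 - gcProb) / 2)
    out <- vapply(widths, function(w)
        paste(sample(names(p), w, replace = TRUE, prob = p), collapse = ""),
        character(1))
    Biostrings::DNAStringSet(out)
}

.cpgIslandSegment <- function(len) {
    # CpG-dense, GC-rich segment: frequent CG dinucleotides on a GC-rich
    # background, comfortably beyond the detection criteria
    out <- character(0)
    while (sum(nchar(out)) < len) {
        if (stats::runif(1) < 0.25) out <- c(out, "CG")
        else out <- c(out, sample(c("A", "C", "G", "T"), 1,
                                  prob = c(0.2, 0.3, 0.3, 0.2)))
    }
    substr(paste(out, collapse = ""), 1, len)
}

.concreteMotif <- function(consensus) {
    iupac <- list(A = "A", C = "C", G = "G", T = "T", R = c("A", "G"),
                  Y = c("C", "T"), S = c("C", "G"), W = c("A", "T"),
                  K = c("G", "T"), M = c("A", "C"),
                  B = c("C", "G", "T"), D = c("A", "G", "T"),
                  H = c("A", "C", "T"), V = c("A", "C", "G"),
                  N = c("A", "C", "G", "T"))
    paste(vapply(strsplit(consensus, "")[[1]], function(x) {
        ch <- iupac[[x]]
        if (length(ch) == 1) ch else sample(ch, 1)
    }, character(1)), collapse = "")
}

.svSequences <- function(truth) {
    n <- nrow(truth)
    islandStart <- rep(NA_integer_, n)
    islandEnd <- rep(NA_integer_, n)
    if (n == 0)
        return(list(sequences = Biostrings::DNAStringSet(),
                    islandStart = islandStart, islandEnd = islandEnd))
    seqs <- as.character(.randomDNA(n, truth$altLength, gcProb = 0.36))
    for (j in seq_len(n)) {
        L <- truth$altLength[j]
        if (truth$direction[j] == "suppressing") {
            islLen <- min(L - 20L, sample(250:400, 1))
            off <- sample.int(L - islLen + 1L, 1)
            substr(seqs[j], off, off + islLen - 1L) <-
                .cpgIslandSegment(islLen)
            islandStart[j] <- off
            islandEnd[j] <- off + islLen - 1L
        } else if (truth$direction[j] == "promoting") {
            nIns <- sample(4:8, 1)
            for (k in seq_len(nIns)) {
                m <- .concreteMotif(
                    .MOTIF_PANEL$consensus[sample.int(nrow(.MOTIF_PANEL), 1)])
                off <- sample.int(L - nchar(m) + 1L, 1)
                substr(seqs[j], off, off + nchar(m) - 1L) <- m
            }
        }
    }
    ss <- Biostrings::DNAStringSet(seqs)
    names(ss) <- truth$svID
    list(sequences = ss, islandStart = islandStart, islandEnd = islandEnd)
}

#' Build the SV catalog of a synthetic bundle
#'
#' @param bundle a \code{\linkS4class{SyntheticBundle}}.
#' @return An \code{\linkS4class{SVCatalog}} whose \code{sourceGenomes} are
#'   the panel genomes carrying each SV.
#' @export
bundleCatalog <- function(bundle) {
    tr <- svTruth(bundle)
    pres <- bundle@panelPresence
    src <- lapply(seq_len(nrow(tr)), function(j)
        rownames(pres)[pres[, j] == 1L])
    SVCatalog(chrom = tr$chrom, start = tr$start, end = tr$end,
              svType = tr$svType, altLength = tr$altLength,
              svID = tr$svID, sourceGenomes = src)
}

#' Simulate a genotyped population for a synthetic bundle
#'
#' Draws accession-level presence/absence calls for every SV of the bundle:
#' each SV gets a population presence frequency (Beta(2, 2)) applied
#' independently of morphotype, except the planted morphotype-associated
#' SV(s), which are present in every accession of the target morphotype and
#' absent elsewhere (frequency contrast 1).  Calls are masked to missing at
#' \code{missingRate}; population expression is generated from the true
#' (unmasked) carrier states with the bundle's planted folds and noise.
#' The associated SV defaults to the first promoting SV of the truth table
#' so that its dosage direction is recoverable downstream.
#'
#' @param bundle a \code{\linkS4class{SyntheticBundle}} from
#'   \code{\link{simulatePanGenome}}.
#' @param assocMorphotype morphotype carrying the planted exclusive SV(s)
#'   (default \code{"ornamental_kale"}).
#' @param nAssocSv number of planted morphotype-exclusive SVs (default 1).
#' @return The bundle with its \code{population} slot filled: a
#'   \code{\linkS4class{GenotypeMatrix}} (\code{genotypes}), the unmasked
#'   \code{trueCarriers} matrix, the population \code{expression} matrix and
#'   \code{assocSv} (ids of the planted associated SVs).
#' @export
simulatePopulation <- function(bundle, assocMorphotype = "ornamental_kale",
                               nAssocSv = 1L) {
    config <- bundle@config
    withr::with_seed(config$seed + 1L,
                     .simulatePopulationImpl(bundle, config,
                                             assocMorphotype, nAssocSv))
}

.simulatePopulationImpl <- function(bundle, config, assocMorphotype,
                                    nAssocSv) {
    spec <- config$morphotypeSpec
    if (nAssocSv > 0 && !assocMorphotype %in% names(spec))
        stop("assocMorphotype '", assocMorphotype,
             "' not in morphotypeSpec")
    nAcc <- config$nAccessions
    acc <- sprintf("acc%04d", seq_len(nAcc))
    morpho <- rep(names(spec), spec)
    tr <- svTruth(bundle)
    nSVs <- nrow(tr)
    assocIds <- character(0)
    if (nAssocSv > 0 && nSVs > 0) {
        prom <- tr$svID[tr$direction == "promoting"]
        pool <- c(prom, setdiff(tr$svID, prom))
        assocIds <- pool[seq_len(min(nAssocSv, nSVs))]
    }
    freq <- stats::rbeta(nSVs, 2, 2)
    carriers <- matrix(0L, nAcc, nSVs, dimnames = list(acc, tr$svID))
    for (j in seq_len(nSVs))
        carriers[, j] <- stats::rbinom(nAcc, 1L, freq[j])
    isAssocAcc <- morpho == assocMorphotype
    for (id in assocIds)
        carriers[, id] <- as.integer(isAssocAcc)
    expr <- .expressionWithEffects(.populationBaseline(bundle), carriers,
                                   tr, config$noiseCV, acc)
    g <- carriers
    if (config$missingRate > 0) {
        mask <- matrix(stats::runif(length(g)) < config$missingRate,
                       nrow(g), ncol(g))
        g[mask] <- NA_integer_
    }
    gt <- GenotypeMatrix(g, S4Vectors::DataFrame(morphotype = morpho,
                                                 row.names = acc))
    bundle@population <- list(genotypes = gt, trueCarriers = carriers,
                              expression = expr, assocSv = assocIds,
                              assocMorphotype = assocMorphotype)
    bundle
}

.populationBaseline <- function(bundle) {
    b <- bundle@config$baseline
    if (is.null(b))  # fallback: robust per-gene location from the panel
        b <- apply(bundle@panelExpression, 1, stats::median)
    b
}

#' Simulate per-cytosine CpG methylation counts for SV sequences
#'
#' Emits a bisulfite-style per-cytosine count table over the CpG sites of
#' every SV presence-allele sequence.  Sites inside the planted CpG island
#' of a suppressing SV methylate at \code{targetLevel} (default 0.9); all
#' other sites at \code{baselineLevel} (default 0.1).  Read depth is
#' Poisson(\code{depthMean}); sites drawn at depth 0 are dropped, and sites
#' below the analysis depth floor are excluded later by
#' \code{\link{weightedMethylation}}.
#'
#' @param bundle a \code{\linkS4class{SyntheticBundle}}.
#' @param targetLevel mean methylation inside planted islands.
#' @param baselineLevel mean methylation elsewhere.
#' @param depthMean mean read depth.
#' @return The bundle with its \code{methylation} slot filled
#'   (\code{chrom} = svID, \code{pos}, \code{meth}, \code{total}).
#' @export
simulateMethylome <- function(bundle, targetLevel = 0.9,
                              baselineLevel = 0.1, depthMean = 30) {
    config <- bundle@config
    withr::with_seed(config$seed + 2L, {
        tr <- svTruth(bundle)
        rows <- lapply(seq_len(nrow(tr)), function(j) {
            s <- as.character(bundle@svSequences[[tr$svID[j]]])
            pos <- gregexpr("CG", s, fixed = TRUE)[[1]]
            if (length(pos) == 1 && pos[1] == -1) return(NULL)
            inIsland <- !is.na(tr$islandStart[j]) &
                pos >= tr$islandStart[j] & pos <= tr$islandEnd[j]
            lvl <- ifelse(inIsland, targetLevel, baselineLevel)
            conc <- 60
            siteLvl <- stats::rbeta(length(pos), lvl * conc,
                                    (1 - lvl) * conc)
            depth <- stats::rpois(length(pos), depthMean)
            keep <- depth > 0
            if (!any(keep)) return(NULL)
            data.frame(chrom = tr$svID[j], pos = as.integer(pos[keep]),
                       meth = stats::rbinom(sum(keep), depth[keep],
                                            siteLvl[keep]),
                       total = depth[keep])
        })
        meth <- do.call(rbind, rows)
        if (is.null(meth))
            meth <- data.frame(chrom = character(), pos = integer(),
                               meth = integer(), total = integer())
        rownames(meth) <- NULL
        bundle@methylation <- meth
        bundle
    })
}
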