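#' @include AllGenerics.R
NULL

#' Construct an SVCatalog
#'
#' @param chrom character vector of reference sequence names.
#' @param start,end 1-based closed interval bounds on the reference.  For a
#'   pure insertion pass \code{end = start - 1} (a zero-width breakpoint);
#'   the breakpoint sits immediately left of \code{start}.
#' @param svType SV class per record; see \code{\linkS4class{SVCatalog}}.
#' @param altLength alternate-allele length in bp (0 for pure deletions).
#' @param svID optional unique identifiers; autogenerated when missing.
#' @param sourceGenomes list (or \code{CharacterList}) of carrier genomes per
#'   record; defaults to empty sets.
#' @param teOverlap optional numeric vector in [0, 1].
#'
#' @return An \code{\linkS4class{SVCatalog}}.
#' @examples
#' cat <- SVCatalog(chrom = "C1", start = 101, end = 200,
#'                  svType = "absence_PAV", altLength = 0,
#'                  sourceGenomes = list(c("g1", "g2")))
#' svType(cat)
#' @export
SVCatalog <- function(chrom, start, end, svType, altLength,
                      svID = NULL, sourceGenomes = NULL, teOverlap = NA_real_) {
    n <- length(start)
    if (is.null(svID))
        svID <- sprintf("sv%05d", seq_len(n))
    if (is.null(sourceGenomes))
        sourceGenomes <- rep(list(character()), n)
    gr <- GenomicRanges::GRanges(
        seqnames = chrom,
        ranges = IRanges::IRanges(start = start, end = end),
        svID = as.character(svID),
        svType = as.character(svType),
        altLength = as.numeric(altLength),
        sourceGenomes = IRanges::CharacterList(sourceGenomes),
        teOverlap = rep_len(as.numeric(teOverlap), n))
    methods::new("SVCatalog", ranges = gr)
}

#' @rdname SVCatalog-class
#' @export
setMethod("svRanges", "SVCatalog", function(x) x@ranges)

#' @rdname SVCatalog-class
#' @export
setMethod("svID", "SVCatalog", function(x) x@ranges$svID)

#' @rdname SVCatalog-class
#' @export
setMethod("svType", "SVCatalog", function(x) x@ranges$svType)

#' @rdname SVCatalog-class
#' @export
setMethod("altLength", "SVCatalog", function(x) x@ranges$altLength)

#' @rdname SVCatalog-class
#' @export
setMethod("sourceGenomes", "SVCatalog", function(x) x@ranges$sourceGenomes)

#' @rdname SVCatalog-class
#' @export
setMethod("length", "SVCatalog", function(x) length(x@ranges))

#' @rdname SVCatalog-class
#' @param i index
#' @export
setMethod("[", "SVCatalog", function(x, i) {
    methods::initialize(x, ranges = x@ranges[i])
})

setMethod("show", "SVCatalog", function(object) {
    gr <- object@ranges
    cat("SVCatalog with", length(gr), "records on",
        length(unique(as.character(GenomicRanges::seqnames(gr)))),
        "sequence(s)\n")
    if (length(gr)) {
        tab <- table(gr$svType)
        cat("  types:", paste(names(tab), tab, sep = "=", collapse = ", "),
            "\n")
        cat("  span: ", min(GenomicRanges::start(gr)), "-",
            max(GenomicRanges::end(gr)), "\n", sep = "")
    }
    invisible(NULL)
})

#' Construct a GenotypeMatrix
#'
#' @param calls integer matrix (accessions x SVs) of presence/absence calls:
#'   1 = presence (longer allele carried), 0 = absence, NA = missing.
#' @param accessionData data.frame or DataFrame of per-accession metadata
#'   (a \code{morphotype} column enables the association functions).
#' @return A \code{\linkS4class{GenotypeMatrix}}.
#' @examples
#' m <- matrix(c(1L, 0L, NA, 1L), 2, 2,
#'             dimnames = list(c("a1", "a2"), c("sv1", "sv2")))
#' gt <- GenotypeMatrix(m, data.frame(morphotype = c("cabbage", "kale"),
#'                                    row.names = c("a1", "a2")))
#' calls(gt)
#' @export
GenotypeMatrix <- function(calls, accessionData = NULL) {
    storage.mode(calls) <- "integer"
    if (is.null(accessionData))
        accessionData <- S4Vectors::DataFrame(row.names = rownames(calls))
    if (is.data.frame(accessionData))
        accessionData <- S4Vectors::DataFrame(accessionData)
    methods::new("GenotypeMatrix", calls = calls,
                 accessionData = accessionData)
}

#' @rdname GenotypeMatrix-class
#' @param x a \code{GenotypeMatrix}
#' @export
setMethod("calls", "GenotypeMatrix", function(x) x@calls)

#' @rdname GenotypeMatrix-class
#' @export
setMethod("accessionData", "GenotypeMatrix", function(x) x@accessionData)

#' @rdname GenotypeMatrix-class
#' @export
setMethod("morphotypes", "GenotypeMatrix", function(x) {
    if (!"morphotype" %in% colnames(x@accessionData))
        stop("accessionData has no 'morphotype' column")
    stats::setNames(as.character(x@accessionData$morphotype),
                    rownames(x@calls))
})

#' @rdname GenotypeMatrix-class
#' @export
setMethod("dim", "GenotypeMatrix", function(x) dim(x@calls))

setMethod("show", "GenotypeMatrix", function(object) {
    m <- object@calls
    cat("GenotypeMatrix:", nrow(m), "accessions x", ncol(m), "SVs\n")
    cat(sprintf("  presence %.1f%%, absence %.1f%%, missing %.1f%%\n",
                100 * mean(m == 1L, na.rm = TRUE) * mean(!is.na(m)),
                100 * mean(m == 0L, na.rm = TRUE) * mean(!is.na(m)),
                100 * mean(is.na(m))))
    if ("morphotype" %in% colnames(object@accessionData)) {
        tab <- sort(table(object@accessionData$morphotype), decreasing = TRUE)
        lab <- paste(names(tab), tab, sep = "=")
        cat("  morphotypes:", paste(utils::head(lab, 6), collapse = ", "),
            if (length(lab) > 6) "...\n" else "\n")
    }
    invisible(NULL)
})

#' @rdname SyntheticBundle-class
#' @param x a \code{SyntheticBundle}
#' @export
setMethod("svTruth", "SyntheticBundle", function(x) x@svTruth)

#' @rdname SyntheticBundle-class
#' @export
setMethod("bundleGenes", "SyntheticBundle", function(x) x@genes)

setMethod("show", "SyntheticBundle", function(object) {
    tr <- object@svTruth
    cat("SyntheticBundle:", length(object@genes), "genes,",
        nrow(tr), "SVs,", ncol(object@panelExpression), "panel genomes\n")
    if (nrow(tr))
        cat("  planted:", sum(tr$direction == "suppressing"), "suppressing,",
            sum(tr$direction == "promoting"), "promoting,",
            sum(tr$direction == "none"), "null\n")
    if (length(object@population))
        cat("  population:", nrow(calls(object@population$genotypes)),
            "accessions\n")
    invisible(NULL)
})
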