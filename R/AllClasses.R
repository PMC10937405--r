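#' @import methods
#' @importFrom S4Vectors DataFrame mcols mcols<- metadata metadata<-
#' @importFrom GenomicRanges GRanges granges seqnames start end width strand
#' @importFrom IRanges IRanges
#' @importClassesFrom Biostrings DNAStringSet
NULL

#' SVCatalog: a nonredundant catalog of structural variants
#'
#' An \code{SVCatalog} holds typed structural-variant (SV) records on a single
#' reference genome.  Each record is a reference-genome interval (1-based,
#' closed; zero width for pure insertions) with metadata columns:
#' \describe{
#'   \item{svID}{unique record identifier}
#'   \item{svType}{one of \code{"presence_PAV"}, \code{"absence_PAV"},
#'     \code{"CNV"}, \code{"inversion"}, \code{"translocation"}}
#'   \item{altLength}{length in bp of the alternate (non-reference) allele;
#'     positive for insertions, 0 for pure deletions}
#'   \item{sourceGenomes}{\code{CharacterList} of the panel genomes carrying
#'     the non-reference allele}
#'   \item{teOverlap}{fraction of the reference span covered by annotated
#'     transposable elements (\code{NA} until annotated)}
#' }
#'
#' Presence/absence variants (PAVs) and copy-number variants must satisfy the
#' conventional size floor \code{max(reference span, altLength) >= 50} bp.
#'
#' @slot ranges A \code{\link[GenomicRanges]{GRanges}} with the metadata
#'   columns described above.
#'
#' @seealso \code{\link{SVCatalog}} (constructor), \code{\link{mergeSVs}},
#'   \code{\link{annotateContext}}, \code{\link{teOverlapFractions}}
#' @export
setClass("SVCatalog", representation(ranges = "GRanges"))

.SV_TYPES <- c("presence_PAV", "absence_PAV", "CNV", "inversion",
               "translocation")

setValidity("SVCatalog", function(object) {
    gr <- object@ranges
    msg <- character()
    need <- c("svID", "svType", "altLength", "sourceGenomes", "teOverlap")
    miss <- setdiff(need, colnames(S4Vectors::mcols(gr)))
    if (length(miss))
        return(paste("missing metadata columns:", paste(miss, collapse = ", ")))
    if (anyDuplicated(gr$svID))
        msg <- c(msg, "svID values must be unique")
    if (!all(gr$svType %in% .SV_TYPES))
        msg <- c(msg, paste("svType must be one of:",
                            paste(.SV_TYPES, collapse = ", ")))
    if (any(gr$altLength < 0))
        msg <- c(msg, "altLength must be >= 0")
    sz <- pmax(GenomicRanges::width(gr), gr$altLength)
    small <- gr$svType %in% c("presence_PAV", "absence_PAV", "CNV") & sz < 50
    if (any(small))
        msg <- c(msg, sprintf("%d PAV/CNV record(s) below the 50 bp size floor",
                              sum(small)))
    te <- gr$teOverlap
    if (any(!is.na(te) & (te < 0 | te > 1)))
        msg <- c(msg, "teOverlap must lie in [0, 1]")
    if (length(msg)) msg else TRUE
})

#' GenotypeMatrix: accession-level SV presence/absence calls
#'
#' Rows are accessions (or panel genomes), columns are SVs.  Calls are coded
#' \code{1L} (presence: the accession carries the longer, sequence-bearing
#' allele), \code{0L} (absence) or \code{NA} (missing / failed genotyping).
#' The presence/absence orientation is reference-free: presence is always the
#' allele with more sequence, regardless of which genome served as reference
#' during calling (see \code{\link{orientGenotypes}}).
#'
#' @slot calls Integer matrix (accessions x SVs) over \{0, 1, NA\} with
#'   row and column names.
#' @slot accessionData A \code{DataFrame} of per-accession metadata, one row
#'   per accession; a \code{morphotype} column is required for the
#'   case-control association functions.
#'
#' @seealso \code{\link{GenotypeMatrix}} (constructor),
#'   \code{\link{caseControlFisher}}, \code{\link{callDosagePopulation}}
#' @export
setClass("GenotypeMatrix",
         representation(calls = "matrix", accessionData = "DataFrame"))

setValidity("GenotypeMatrix", function(object) {
    m <- object@calls
    msg <- character()
    if (!is.integer(m) && !all(is.na(m)))
        msg <- c(msg, "calls must be an integer matrix")
    v <- m[!is.na(m)]
    if (length(v) && !all(v %in% c(0L, 1L)))
        msg <- c(msg, "calls must be 0 (absence), 1 (presence) or NA (missing)")
    if (is.null(rownames(m)) || is.null(colnames(m)))
        msg <- c(msg, "calls must carry accession rownames and SV colnames")
    if (nrow(object@accessionData) != nrow(m))
        msg <- c(msg, "accessionData must have one row per accession")
    if (length(msg)) msg else TRUE
})

#' SyntheticBundle: a simulated pan-genome study with a planted truth table
#'
#' Container for one synthetic pan-genome experiment: gene models, an SV truth
#' table (placement, planted direction, planted fold), per-genome presence
#' calls and panel expression, and sequence material (SV presence-allele
#' sequences, promoters, the motif panel) for the regulatory-signature
#' analyses.  Population-level genotypes, expression and methylation are
#' attached by \code{\link{simulatePopulation}} and
#' \code{\link{simulateMethylome}}.
#'
#' @slot genes \code{GRanges} of gene bodies with \code{geneID}, strand and
#'   a \code{cds} \code{GRangesList}-compatible metadata (exon/CDS intervals).
#' @slot cds \code{GRanges} of CDS intervals carrying \code{geneID}.
#' @slot svTruth \code{data.frame}; one row per SV: id, placement, linked
#'   gene, distance bin, planted direction (\code{suppressing},
#'   \code{promoting}, \code{none}), planted fold, island coordinates for
#'   suppressing SVs.
#' @slot panelPresence integer matrix, panel genomes x SVs (0/1).
#' @slot panelExpression numeric matrix, genes x panel genomes (TPM).
#' @slot svSequences \code{DNAStringSet} of presence-allele sequences, named
#'   by svID.
#' @slot promoters \code{DNAStringSet} of per-gene promoter sequences.
#' @slot motifs \code{data.frame} with columns \code{name} and
#'   \code{consensus} (IUPAC).
#' @slot population list; filled by \code{simulatePopulation} with elements
#'   \code{genotypes} (a \code{GenotypeMatrix}), \code{trueCarriers},
#'   \code{expression} and \code{assocSv}.
#' @slot methylation \code{data.frame}; filled by \code{simulateMethylome}.
#' @slot config the \code{simConfig} list used to build the bundle.
#' @export
setClass("SyntheticBundle",
         representation(genes = "GRanges", cds = "GRanges",
                        svTruth = "data.frame",
                        panelPresence = "matrix",
                        panelExpression = "matrix",
                        svSequences = "DNAStringSet",
                        promoters = "DNAStringSet",
                        motifs = "data.frame",
                        population = "list",
                        methylation = "data.frame",
                        config = "list"))
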