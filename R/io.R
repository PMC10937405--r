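#' @include SVCatalog-methods.R
NULL

.VCF_ALT <- c(presence_PAV = "<INS>", absence_PAV = "<DEL>", CNV = "<DUP>",
              inversion = "<INV>", translocation = "<TRA>")

#' Write an SV catalog (and optional genotypes) as VCF
#'
#' VCFv4.2 with symbolic SV alleles.  Dialect: \code{POS} is the first
#' affected reference base (for insertions, the breakpoint start, with
#' \code{END = POS - 1}), \code{END} the last affected base, \code{SVLEN}
#' the alternate-allele length in bp.  Per-sample \code{GT} columns encode
#' alternate-allele carriage (\code{1/1} carrier, \code{0/0} non-carrier,
#' \code{./.} missing); because the alternate of a deletion is the shorter
#' allele, presence/absence orientation is restored on reading via
#' \code{\link{orientGenotypes}}.
#'
#' @param catalog an \code{SVCatalog}.
#' @param path output path.
#' @param genotypes optional integer matrix of presence calls,
#'   accessions x SVs (1/0/NA), columns matching \code{svID(catalog)}.
#' @return \code{path}, invisibly.
#' @export
writeSvVcf <- function(catalog, path, genotypes = NULL) {
    gr <- svRanges(catalog)
    hdr <- c("##fileformat=VCFv4.2",
             "##coordinates=1-based; POS=first affected base; END=last affected base; insertions have END=POS-1",
             '##INFO=<ID=SVTYPE,Number=1,Type=String,Description="SV class">',
             '##INFO=<ID=SVLEN,Number=1,Type=Integer,Description="Alternate allele length in bp">',
             '##INFO=<ID=END,Number=1,Type=Integer,Description="Last affected reference base">',
             '##INFO=<ID=SRC,Number=.,Type=String,Description="Carrier genomes of the nonreference allele">',
             '##FORMAT=<ID=GT,Number=1,Type=String,Description="Genotype">')
    cols <- c("#CHROM", "POS", "ID", "REF", "ALT", "QUAL", "FILTER", "INFO")
    src <- vapply(gr$sourceGenomes, function(s)
        if (length(s)) paste(s, collapse = ",") else ".", character(1))
    info <- sprintf("SVTYPE=%s;SVLEN=%d;END=%d%s",
                    gsub("[<>]", "", .VCF_ALT[gr$svType]),
                    as.integer(gr$altLength), GenomicRanges::end(gr),
                    ifelse(src == ".", "", paste0(";SRC=", src)))
    body <- data.frame(chrom = as.character(GenomicRanges::seqnames(gr)),
                       pos = GenomicRanges::start(gr), id = gr$svID,
                       ref = "N", alt = unname(.VCF_ALT[gr$svType]),
                       qual = ".", filter = "PASS", info = info)
    if (!is.null(genotypes)) {
        stopifnot(identical(colnames(genotypes), gr$svID))
        hdr <- c(hdr)
        cols <- c(cols, "FORMAT", rownames(genotypes))
        # presence call -> alt-carrier code depends on which allele is longer
        refLen <- GenomicRanges::width(gr)
        altLonger <- gr$altLength > refLen
        gtChar <- vapply(seq_along(gr), function(j) {
            pres <- genotypes[, j]
            altCarrier <- if (altLonger[j]) pres else 1L - pres
            paste(ifelse(is.na(altCarrier), "./.",
                         ifelse(altCarrier == 1L, "1/1", "0/0")),
                  collapse = "\t")
        }, character(1))
        lines <- paste(body$chrom, body$pos, body$id, body$ref, body$alt,
                       body$qual, body$filter, body$info, "GT", gtChar,
                       sep = "\t")
    } else {
        lines <- do.call(paste, c(unname(body), list(sep = "\t")))
    }
    writeLines(c(hdr, paste(cols, collapse = "\t"), lines), path)
    invisible(path)
}

#' Read an SV VCF
#'
#' Parses a VCF with symbolic SV alleles (dialect of
#' \code{\link{writeSvVcf}}; SVLEN and END required on symbolic records) and
#' returns the catalog plus reference-free presence/absence genotypes for
#' any sample columns.  Genotypes containing at least one alternate allele
#' count as alternate carriers; \code{./.} is missing; orientation to
#' presence/absence follows the longer allele.
#'
#' @param path VCF path.
#' @return List with \code{catalog} (an \code{SVCatalog}) and
#'   \code{genotypes} (integer matrix accessions x SVs, or NULL).
#' @export
readSvVcf <- function(path) {
    v <- vcfR::read.vcfR(path, verbose = FALSE)
    fix <- vcfR::getFIX(v)
    if (is.null(dim(fix)))   # single-record VCF collapses to a vector
        fix <- matrix(fix, nrow = 1, dimnames = list(NULL, names(fix)))
    alt <- fix[, "ALT"]
    typeMap <- stats::setNames(names(.VCF_ALT), .VCF_ALT)
    svtype <- unname(typeMap[alt])
    svlen <- suppressWarnings(
        as.integer(vcfR::extract.info(v, element = "SVLEN")))
    endv <- suppressWarnings(
        as.integer(vcfR::extract.info(v, element = "END")))
    bad <- which(is.na(svlen) & alt %in% .VCF_ALT)
    if (length(bad))
        stop("missing SVLEN on symbolic allele at record(s): ",
             paste(utils::head(bad, 5), collapse = ", "))
    if (anyNA(svtype))
        stop("unsupported ALT allele: ",
             paste(unique(alt[is.na(svtype)]), collapse = ", "))
    pos <- as.integer(fix[, "POS"])
    src <- vcfR::extract.info(v, element = "SRC")
    srcList <- lapply(src, function(s)
        if (is.na(s) || s == ".") character() else
            strsplit(s, ",", fixed = TRUE)[[1]])
    catalog <- SVCatalog(chrom = fix[, "CHROM"], start = pos, end = endv,
                         svType = svtype, altLength = svlen,
                         svID = fix[, "ID"], sourceGenomes = srcList)
    genotypes <- NULL
    if (ncol(v@gt) > 1) {
        gtRaw <- vcfR::extract.gt(v, element = "GT")
        altCarrier <- matrix(NA_integer_, nrow(gtRaw), ncol(gtRaw),
                             dimnames = dimnames(gtRaw))
        known <- !is.na(gtRaw) & gtRaw != "./." & gtRaw != "."
        altCarrier[known] <- as.integer(grepl("1", gtRaw[known]))
        refLen <- endv - pos + 1L
        pres <- altCarrier
        for (j in seq_len(nrow(pres)))
            pres[j, ] <- orientGenotypes(altCarrier[j, ], refLen[j],
                                         svlen[j])
        genotypes <- t(pres)   # accessions x SVs
        colnames(genotypes) <- fix[, "ID"]
    }
    list(catalog = catalog, genotypes = genotypes)
}

#' Write gene models as GFF3
#'
#' @param genes \code{GRanges} of gene bodies with \code{geneID}.
#' @param cds \code{GRanges} of CDS intervals with \code{geneID}.
#' @param path output path.
#' @return \code{path}, invisibly.
#' @export
writeGff3 <- function(genes, cds, path) {
    g <- genes
    S4Vectors::mcols(g) <- S4Vectors::DataFrame(type = "gene",
                                                ID = genes$geneID)
    cc <- cds
    S4Vectors::mcols(cc) <- S4Vectors::DataFrame(type = "CDS",
                                                 Parent = cds$geneID,
                                                 phase = 0L)
    rtracklayer::export(c(g, cc), path, format = "gff3")
    invisible(path)
}

#' Read gene models from GFF3
#'
#' Genes carry strand and body interval; CDS features attach to their gene
#' via \code{Parent}.  A CDS outside its gene's span is a validation error;
#' genes without CDS are retained and flagged non-coding.
#'
#' @param path GFF3 path.
#' @return List with \code{genes} (\code{GRanges} with \code{geneID},
#'   \code{coding}) and \code{cds} (\code{GRanges} with \code{geneID}).
#' @export
readGff3 <- function(path) {
    gr <- rtracklayer::import(path, format = "gff3")
    genes <- gr[gr$type == "gene"]
    genes$geneID <- as.character(genes$ID)
    cds <- gr[gr$type == "CDS"]
    parent <- cds$Parent
    if (!is.character(parent))   # rtracklayer yields a CharacterList
        parent <- vapply(as.list(parent), function(x)
            if (length(x)) x[[1]] else NA_character_, character(1))
    cds$geneID <- parent
    gi <- match(cds$geneID, genes$geneID)
    if (anyNA(gi)) stop("CDS with unknown Parent gene")
    outside <- GenomicRanges::start(cds) < GenomicRanges::start(genes)[gi] |
        GenomicRanges::end(cds) > GenomicRanges::end(genes)[gi]
    if (any(outside))
        stop("CDS outside its gene span: ",
             paste(utils::head(unique(cds$geneID[outside]), 5),
                   collapse = ", "))
    genes$coding <- genes$geneID %in% cds$geneID
    keepG <- c("geneID", "coding")
    S4Vectors::mcols(genes) <- S4Vectors::mcols(genes)[, keepG]
    S4Vectors::mcols(cds) <- S4Vectors::mcols(cds)[, "geneID", drop = FALSE]
    list(genes = genes, cds = cds)
}

#' Write / read a numeric matrix as TSV
#'
#' Row identifiers go in the first column (\code{id}).  Reading validates
#' numeric coercion (a non-numeric cell is an error naming row and column)
#' and rejects duplicated row ids.
#'
#' @param m numeric matrix with dimnames.
#' @param path TSV path.
#' @return \code{writeMatrixTsv}: \code{path}, invisibly;
#'   \code{readMatrixTsv}: the matrix.
#' @export
writeMatrixTsv <- function(m, path) {
    df <- data.frame(id = rownames(m), m, check.names = FALSE)
    utils::write.table(df, path, sep = "\t", quote = FALSE,
                       row.names = FALSE)
    invisible(path)
}

#' @rdname writeMatrixTsv
#' @export
readMatrixTsv <- function(path) {
    df <- utils::read.delim(path, check.names = FALSE,
                            colClasses = "character")
    ids <- df[[1]]
    if (anyDuplicated(ids))
        stop("duplicated row id: ", ids[duplicated(ids)][1])
    m <- as.matrix(df[, -1, drop = FALSE])
    num <- suppressWarnings(array(as.numeric(m), dim(m), dimnames(m)))
    bad <- which(is.na(num) & !is.na(m) & m != "NA", arr.ind = TRUE)
    if (nrow(bad))
        stop(sprintf("non-numeric value '%s' at row '%s', column '%s'",
                     m[bad[1, 1], bad[1, 2]], ids[bad[1, 1]],
                     colnames(m)[bad[1, 2]]))
    rownames(num) <- ids
    num
}

#' Read / write per-cytosine methylation counts
#'
#' TSV with columns \code{chrom}, \code{pos} (1-based), \code{meth},
#' \code{total}.
#'
#' @param sites data.frame of sites.
#' @param path TSV path.
#' @return \code{writeMethylationTsv}: \code{path}, invisibly;
#'   \code{readMethylationTsv}: the data.frame.
#' @export
writeMethylationTsv <- function(sites, path) {
    utils::write.table(sites, path, sep = "\t", quote = FALSE,
                       row.names = FALSE)
    invisible(path)
}

#' @rdname writeMethylationTsv
#' @export
readMethylationTsv <- function(path) {
    df <- utils::read.delim(path)
    need <- c("chrom", "pos", "meth", "total")
    if (!all(need %in% colnames(df)))
        stop("methylation table needs columns: ",
             paste(need, collapse = ", "))
    if (any(df$meth > df$total))
        stop("methylated reads exceed total reads")
    df
}

#' Read a syntenic family copy-count matrix
#'
#' TSV with columns \code{family}, optional \code{subgenome} and
#' \code{triplet}, then one integer column per genome.
#'
#' @param path TSV path.
#' @return List with \code{fm} (matrix families x genomes),
#'   \code{subgenome} and \code{tripletId} (named vectors or NULL).
#' @export
readFamilyMatrix <- function(path) {
    df <- utils::read.delim(path, check.names = FALSE)
    stopifnot("family" %in% colnames(df))
    if (anyDuplicated(df$family))
        stop("duplicated family id")
    meta <- intersect(c("subgenome", "triplet"), colnames(df))
    genomeCols <- setdiff(colnames(df), c("family", meta))
    fm <- as.matrix(df[, genomeCols, drop = FALSE])
    storage.mode(fm) <- "numeric"
    rownames(fm) <- df$family
    list(fm = fm,
         subgenome = if ("subgenome" %in% meta)
             stats::setNames(as.character(df$subgenome), df$family) else NULL,
         tripletId = if ("triplet" %in% meta)
             stats::setNames(as.character(df$triplet), df$family) else NULL)
}

#' Write a synthetic bundle as a fixture directory
#'
#' Emits every component of a \code{\linkS4class{SyntheticBundle}} in the
#' package's on-disk formats: catalog + panel genotypes VCF, population
#' genotypes VCF, gene models GFF3, expression TSVs, methylation TSV,
#' accession metadata TSV, motif TSV, SV and promoter FASTA, and the truth
#' table TSV.  Deterministic: rewriting the same bundle yields identical
#' files.
#'
#' @param bundle a \code{SyntheticBundle}.
#' @param dir output directory (created if needed).
#' @return \code{dir}, invisibly.
#' @export
writeBundle <- function(bundle, dir) {
    dir.create(dir, showWarnings = FALSE, recursive = TRUE)
    p <- function(f) file.path(dir, f)
    writeSvVcf(bundleCatalog(bundle), p("panel_svs.vcf"),
               genotypes = bundle@panelPresence)
    writeGff3(bundle@genes, bundle@cds, p("genes.gff3"))
    writeMatrixTsv(bundle@panelExpression, p("panel_expression.tsv"))
    utils::write.table(bundle@svTruth, p("sv_truth.tsv"), sep = "\t",
                       quote = FALSE, row.names = FALSE)
    utils::write.table(bundle@motifs, p("motifs.tsv"), sep = "\t",
                       quote = FALSE, row.names = FALSE)
    if (length(bundle@svSequences))
        Biostrings::writeXStringSet(bundle@svSequences,
                                    p("sv_sequences.fasta"))
    Biostrings::writeXStringSet(bundle@promoters, p("promoters.fasta"))
    if (nrow(bundle@methylation))
        writeMethylationTsv(bundle@methylation, p("methylation.tsv"))
    if (length(bundle@population)) {
        pop <- bundle@population
        writeSvVcf(bundleCatalog(bundle), p("population_svs.vcf"),
                   genotypes = calls(pop$genotypes))
        writeMatrixTsv(pop$expression, p("population_expression.tsv"))
        meta <- data.frame(accession = rownames(calls(pop$genotypes)),
                           morphotype = morphotypes(pop$genotypes))
        utils::write.table(meta, p("accessions.tsv"), sep = "\t",
                           quote = FALSE, row.names = FALSE)
    }
    invisible(dir)
}
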