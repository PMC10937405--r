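#' Classify syntenic gene families into pan-genome classes
#'
#' A family's class follows its presence count (copy count >= 1) across the
#' panel: present in all \code{nGenomes} genomes = \code{core}; in at least
#' \code{ceiling(0.9 * nGenomes)} but not all = \code{softcore} (for a
#' 27-genome panel: 25-26); in 2 up to the softcore bound minus one =
#' \code{dispensable} (27 genomes: 2-24); in exactly one = \code{private}.
#' Families present in no genome are rejected.
#'
#' @param fm numeric matrix of copy counts, families x genomes (row and
#'   column names required).
#' @param nGenomes number of panel genomes; defaults to \code{ncol(fm)}.
#' @return Factor of classes (levels core, softcore, dispensable, private),
#'   named by family.
#' @examples
#' fm <- matrix(1, 2, 27, dimnames = list(c("f1", "f2"), paste0("g", 1:27)))
#' fm[2, 3:27] <- 0
#' table(classifyFamilies(fm))
#' @export
classifyFamilies <- function(fm, nGenomes = ncol(fm)) {
    stopifnot(is.matrix(fm), !is.null(rownames(fm)))
    if (any(fm < 0)) stop("copy counts must be >= 0")
    pres <- rowSums(fm >= 1)
    if (any(pres == 0))
        stop("family present in no genome: ",
             paste(utils::head(rownames(fm)[pres == 0], 5), collapse = ", "))
    softLow <- ceiling(0.9 * nGenomes)
    cls <- ifelse(pres == nGenomes, "core",
           ifelse(pres >= softLow, "softcore",
           ifelse(pres >= 2, "dispensable", "private")))
    factor(stats::setNames(cls, rownames(fm)),
           levels = c("core", "softcore", "dispensable", "private"))
}

#' Per-genome pan-class composition
#'
#' For each genome, counts and fractions of its present families by
#' pan-class.  Fractions are over families present in that genome and sum
#' to 1.
#'
#' @param fm copy-count matrix, families x genomes.
#' @param classes factor from \code{\link{classifyFamilies}}.
#' @return data.frame with columns \code{genome}, \code{class},
#'   \code{count}, \code{fraction}.
#' @export
genomeComposition <- function(fm, classes = classifyFamilies(fm)) {
    stopifnot(identical(rownames(fm), names(classes)))
    lv <- levels(classes)
    out <- do.call(rbind, lapply(colnames(fm), function(g) {
        present <- fm[, g] >= 1
        cnt <- table(classes[present])[lv]
        cnt[is.na(cnt)] <- 0
        data.frame(genome = g, class = lv, count = as.integer(cnt),
                   fraction = as.numeric(cnt) / max(sum(cnt), 1L))
    }))
    rownames(out) <- NULL
    out$class <- factor(out$class, levels = lv)
    out
}

#' Morphotype-specific gene-family loss
#'
#' Eligible families are those lost (copy count 0) in at least one genome
#' while retained (copy count >= 1) in strictly more than 50\% of the panel.
#' An eligible family is flagged as specifically lost in morphotype M when
#' strictly more than 70\% of its losing genomes belong to M.  At most one
#' morphotype can be flagged per family.
#'
#' @param fm copy-count matrix, families x genomes.
#' @param genomeMorphotypes named character vector mapping every genome
#'   column to its morphotype.
#' @param lossFraction flagging threshold on the fraction of losers in one
#'   morphotype (default 0.70, strict).
#' @param retainFraction eligibility threshold on the retained fraction of
#'   the panel (default 0.50, strict).
#' @return data.frame with one row per eligible family: \code{family},
#'   \code{nLost}, \code{nRetained}, \code{morphotype} (flagged morphotype
#'   or NA), \code{lossShare} (largest morphotype share among losers).
#' @export
morphotypeSpecificLoss <- function(fm, genomeMorphotypes,
                                   lossFraction = 0.70,
                                   retainFraction = 0.50) {
    stopifnot(is.matrix(fm))
    if (!all(colnames(fm) %in% names(genomeMorphotypes)))
        stop("every genome column must have a morphotype label")
    mt <- genomeMorphotypes[colnames(fm)]
    nG <- ncol(fm)
    pres <- fm >= 1
    nRet <- rowSums(pres)
    nLost <- nG - nRet
    eligible <- nLost >= 1 & nRet > retainFraction * nG
    rows <- lapply(which(eligible), function(i) {
        losers <- mt[!pres[i, ]]
        shares <- table(losers) / length(losers)
        top <- which.max(shares)
        data.frame(family = rownames(fm)[i],
                   nLost = length(losers), nRetained = nRet[[i]],
                   morphotype = if (shares[top] > lossFraction)
                       names(shares)[top] else NA_character_,
                   lossShare = as.numeric(shares[top]))
    })
    out <- if (length(rows)) do.call(rbind, rows) else
        data.frame(family = character(), nLost = integer(),
                   nRetained = integer(), morphotype = character(),
                   lossShare = numeric())
    rownames(out) <- NULL
    out
}

#' Homoeolog triplet copy-retention patterns
#'
#' Homoeolog triplets link up to three syntenic families, one per
#' mesohexaploidy subgenome (LF, MF1, MF2).  Triplets whose three member
#' families are all present in the reference genome (ancestral three-copy
#' state), remain three-copy in strictly more than 50\% of the panel, and
#' show loss in at least one genome are eligible; for those the function
#' reports, per genome, the multiset of retained subgenome copies (e.g.
#' \code{"LF+MF1"}).
#'
#' @param fm copy-count matrix, families x genomes.
#' @param tripletId named character vector (family -> triplet id; NA for
#'   families outside any triplet).
#' @param subgenome named character vector (family -> LF/MF1/MF2).
#' @param referenceGenome column name of the reference genome.
#' @param retainFraction three-copy retention eligibility threshold
#'   (default 0.50, strict).
#' @return List with \code{patterns} (data.frame: triplet, genome, retained
#'   subgenome pattern, nCopies) for eligible triplets and
#'   \code{eligible} (character vector of triplet ids).
#' @export
homoeologRetention <- function(fm, tripletId, subgenome, referenceGenome,
                               retainFraction = 0.50) {
    stopifnot(referenceGenome %in% colnames(fm))
    fams <- rownames(fm)
    tripletId <- tripletId[fams]
    trips <- split(fams, tripletId)
    nG <- ncol(fm)
    keep <- character()
    rows <- list()
    for (tid in names(trips)) {
        members <- trips[[tid]]
        if (length(members) != 3) next
        sg <- subgenome[members]
        if (anyDuplicated(sg) || any(is.na(sg))) {
            warning("triplet ", tid, " lacks three distinct subgenome labels; skipped")
            next
        }
        sub <- fm[members, , drop = FALSE] >= 1
        if (!all(sub[, referenceGenome])) next       # not ancestral 3-copy
        threeCopy <- colSums(sub) == 3
        if (sum(threeCopy) <= retainFraction * nG) next
        if (all(threeCopy)) next                     # no loss anywhere
        keep <- c(keep, tid)
        pat <- vapply(colnames(fm), function(g) {
            ret <- sort(sg[sub[, g]])
            if (length(ret)) paste(ret, collapse = "+") else "none"
        }, character(1))
        rows[[tid]] <- data.frame(triplet = tid, genome = colnames(fm),
                                  pattern = unname(pat),
                                  nCopies = unname(colSums(sub)))
    }
    patterns <- if (length(rows)) do.call(rbind, rows) else
        data.frame(triplet = character(), genome = character(),
                   pattern = character(), nCopies = integer())
    rownames(patterns) <- NULL
    list(patterns = patterns, eligible = keep)
}
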