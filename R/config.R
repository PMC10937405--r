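#' Analysis configuration
#'
#' Bundles every tunable threshold of the pipeline with its default.  The
#' defaults encode the study design this package implements:
#' \itemize{
#'   \item \code{linkRadiusBp} (10000): an SV is assigned to its closest gene
#'     only within this radius ("SV gene" definition).
#'   \item \code{contextFlankBp} (3000): upstream/downstream window for
#'     genomic-context annotation.
#'   \item \code{foldThreshold} (1.5): minimal fold difference of group mean
#'     TPM to call a suppressing/promoting SV; inclusive ("at least").
#'   \item \code{tpmMinPanel} (1) with \code{fracMinPanel} (0.60): a gene is
#'     expressed in a panel genotype group when strictly more than 60\% of its
#'     members have TPM >= 1.
#'   \item \code{minGenomesPerGroup} (4): minimal panel genomes per genotype
#'     group.
#'   \item \code{tpmMinPop} (5) with \code{fracMinPop} (0.30): population
#'     expression rule (strictly more than 30\% of samples at TPM >= 5).
#'   \item \code{minGenotyped} (60), \code{minGroupSize} (10): population
#'     eligibility filters.
#'   \item \code{cisWindowBp} (20000): cis/trans boundary for expression
#'     associations.
#'   \item \code{permNMethylation} (10000), \code{permNTfbs} (1000):
#'     permutation counts for the methylation and TF-binding-site contrasts.
#'   \item \code{substitutionRate} (1.3e-8 per site per year): LTR
#'     insertion-time clock.
#'   \item \code{alpha} (0.05), \code{topFraction} (0.05): significance level
#'     and top-signal fraction for the association stage.
#'   \item \code{highMethylationThreshold} (0.80): weighted methylation at or
#'     above which a CpG island counts as highly methylated.
#'   \item \code{minCpgDepth} (3): minimal read depth for a cytosine to enter
#'     the weighted methylation level.
#' }
#'
#' @param ... named overrides of any default listed above.
#' @return A validated named list of class \code{"svdosage_config"}.
#' @examples
#' cfg <- analysisConfig(foldThreshold = 2)
#' cfg$foldThreshold
#' @export
analysisConfig <- function(...) {
    cfg <- list(
        linkRadiusBp = 10000L,
        contextFlankBp = 3000L,
        foldThreshold = 1.5,
        tpmMinPanel = 1,
        fracMinPanel = 0.60,
        minGenomesPerGroup = 4L,
        tpmMinPop = 5,
        fracMinPop = 0.30,
        minGenotyped = 60L,
        minGroupSize = 10L,
        cisWindowBp = 20000L,
        permNMethylation = 10000L,
        permNTfbs = 1000L,
        substitutionRate = 1.3e-8,
        alpha = 0.05,
        topFraction = 0.05,
        highMethylationThreshold = 0.80,
        minCpgDepth = 3L)
    over <- list(...)
    bad <- setdiff(names(over), names(cfg))
    if (length(bad))
        stop("unknown analysisConfig field(s): ", paste(bad, collapse = ", "))
    cfg[names(over)] <- over
    .validateAnalysisConfig(cfg)
    class(cfg) <- c("svdosage_config", "list")
    cfg
}

.validateAnalysisConfig <- function(cfg) {
    counts <- c("linkRadiusBp", "contextFlankBp", "minGenomesPerGroup",
                "minGenotyped", "minGroupSize", "cisWindowBp",
                "permNMethylation", "permNTfbs", "minCpgDepth")
    for (f in counts)
        if (cfg[[f]] < 0) stop(f, " must be >= 0")
    fracs <- c("fracMinPanel", "fracMinPop", "alpha", "topFraction",
               "highMethylationThreshold")
    for (f in fracs)
        if (cfg[[f]] < 0 || cfg[[f]] > 1) stop(f, " must lie in [0, 1]")
    if (cfg$foldThreshold < 1) stop("foldThreshold must be >= 1")
    if (cfg$substitutionRate <= 0) stop("substitutionRate must be > 0")
    invisible(cfg)
}

#' Read an analysis configuration from YAML
#'
#' Any field of \code{\link{analysisConfig}} may appear in the file; omitted
#' fields keep their defaults, and unknown fields are rejected.
#'
#' @param path path to a YAML file of configuration overrides.
#' @return A validated configuration list (see \code{\link{analysisConfig}}).
#' @export
readAnalysisConfig <- function(path) {
    over <- yaml::read_yaml(path)
    if (is.null(over)) over <- list()
    do.call(analysisConfig, over)
}

#' @export
print.svdosage_config <- function(x, ...) {
    cat("svdosage analysis configuration:\n")
    for (f in names(x))
        cat(sprintf("  %-26s %s\n", f, format(x[[f]])))
    invisible(x)
}

#' Simulation configuration
#'
#' Parameters of the synthetic pan-genome / population generator.  Defaults
#' follow the dimensions of the study design the generator emulates: a
#' 27-genome assembly panel, a 704-accession population whose morphotype
#' composition matches the surveyed germplasm, and bidirectional dosage
#' effects between 1.5- and 10-fold.
#'
#' @param nGenomes number of assembly-panel genomes (default 27).
#' @param nAccessions number of population accessions (default 704).
#' @param nGenes number of annotated genes (default 2000).
#' @param nSVs number of structural variants; at most \code{nGenes}
#'   (each SV is placed relative to its own gene so that the one-SV-per-gene
#'   eligibility rule of the panel analysis holds by construction).
#' @param morphotypeSpec named integer vector mapping morphotype label to
#'   accession count; must sum to \code{nAccessions}.  The default mirrors
#'   the surveyed collection (310 cabbage, 153 cauliflower, 63 broccoli,
#'   46 kohlrabi, 36 wild, 24 Chinese kale, 21 curly kale, 20 brussels
#'   sprouts, 18 ornamental kale, 7 Tronchuda kale, 6 collard greens).
#' @param fracSuppressing,fracPromoting fractions of SVs planted with a
#'   suppressing / promoting expression effect (defaults 0.30 / 0.25,
#'   reproducing the observed excess of suppression over promotion); the
#'   remainder are planted null.
#' @param effectFoldRange length-2 numeric, the range planted folds are drawn
#'   from uniformly (default c(1.5, 10); lower bound must be >= 1).
#' @param noiseCV coefficient of variation of the multiplicative log-normal
#'   TPM noise (default 0.3).
#' @param missingRate fraction of population genotype calls set to missing
#'   (default 0.05).
#' @param seed integer seed; every stochastic draw of the generator flows
#'   from it, so equal configurations yield byte-identical bundles.
#' @return A validated list of class \code{"svdosage_simconfig"}.
#' @examples
#' cfg <- simConfig(nGenes = 50, nSVs = 20, seed = 7)
#' @export
simConfig <- function(nGenomes = 27L, nAccessions = 704L, nGenes = 2000L,
                      nSVs = 600L, morphotypeSpec = NULL,
                      fracSuppressing = 0.30, fracPromoting = 0.25,
                      effectFoldRange = c(1.5, 10), noiseCV = 0.3,
                      missingRate = 0.05, seed = 1L) {
    if (is.null(morphotypeSpec))
        morphotypeSpec <- defaultMorphotypeSpec(nAccessions)
    cfg <- list(nGenomes = as.integer(nGenomes),
                nAccessions = as.integer(nAccessions),
                nGenes = as.integer(nGenes), nSVs = as.integer(nSVs),
                morphotypeSpec = morphotypeSpec,
                fracSuppressing = fracSuppressing,
                fracPromoting = fracPromoting,
                effectFoldRange = effectFoldRange,
                noiseCV = noiseCV, missingRate = missingRate,
                seed = as.integer(seed))
    if (cfg$nGenomes < 2) stop("nGenomes must be >= 2")
    if (cfg$nSVs > cfg$nGenes)
        stop("nSVs must not exceed nGenes (one SV per gene)")
    for (f in c("fracSuppressing", "fracPromoting", "missingRate"))
        if (cfg[[f]] < 0 || cfg[[f]] > 1) stop(f, " must lie in [0, 1]")
    if (cfg$fracSuppressing + cfg$fracPromoting > 1)
        stop("fracSuppressing + fracPromoting must be <= 1")
    if (length(effectFoldRange) != 2 || effectFoldRange[1] < 1 ||
        diff(effectFoldRange) < 0)
        stop("effectFoldRange must be c(low, high) with low >= 1")
    if (noiseCV < 0) stop("noiseCV must be >= 0")
    if (sum(morphotypeSpec) != cfg$nAccessions)
        stop("morphotypeSpec counts must sum to nAccessions")
    class(cfg) <- c("svdosage_simconfig", "list")
    cfg
}

#' Default morphotype composition
#'
#' The 704-accession composition of the emulated germplasm collection,
#' rescaled proportionally (largest-remainder rounding) when
#' \code{nAccessions} differs from 704.
#'
#' @param nAccessions total accession count.
#' @return Named integer vector of per-morphotype accession counts.
#' @export
defaultMorphotypeSpec <- function(nAccessions = 704L) {
    base <- c(cabbage = 310L, cauliflower = 153L, broccoli = 63L,
              kohlrabi = 46L, wild = 36L, chinese_kale = 24L,
              curly_kale = 21L, brussels_sprouts = 20L,
              ornamental_kale = 18L, tronchuda_kale = 7L,
              collard_greens = 6L)
    if (nAccessions == 704L) return(base)
    raw <- base / sum(base) * nAccessions
    out <- floor(raw)
    rem <- nAccessions - sum(out)
    if (rem > 0) {
        ord <- order(raw - out, decreasing = TRUE)
        out[ord[seq_len(rem)]] <- out[ord[seq_len(rem)]] + 1
    }
    out <- out[out > 0]
    storage.mode(out) <- "integer"
    out
}

#' @export
print.svdosage_simconfig <- function(x, ...) {
    cat("svdosage simulation configuration:\n")
    cat(sprintf("  %d genomes, %d accessions, %d genes, %d SVs, seed %d\n",
                x$nGenomes, x$nAccessions, x$nGenes, x$nSVs, x$seed))
    cat(sprintf("  planted: %.0f%% suppressing, %.0f%% promoting, folds %.1f-%.1f\n",
                100 * x$fracSuppressing, 100 * x$fracPromoting,
                x$effectFoldRange[1], x$effectFoldRange[2]))
    cat(sprintf("  noise CV %.2f, missing rate %.2f\n",
                x$noiseCV, x$missingRate))
    invisible(x)
}
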