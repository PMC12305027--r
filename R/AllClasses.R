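#' @import methods
NULL

setClassUnion("characterOrNULL", c("character", "NULL"))

#' Targeted somatic variant
#'
#' Describes one targeted single-nucleotide somatic variant: the gene it lies
#' in, the expected amplicon sequence spanning it, the 0-based position of the
#' variant within that amplicon, and the reference/alternate alleles.
#'
#' @slot variantId Unique identifier for the target.
#' @slot gene Gene symbol the amplicon is designed against.
#' @slot ampliconRef Expected amplicon sequence (uppercase ACGT).
#' @slot variantOffset 0-based offset of the variant base within
#'   \code{ampliconRef}.
#' @slot refAllele,altAllele Single reference / alternate bases.
#' @slot genomicLabel Free-text label, e.g. protein notation such as
#'   "p.E542K".
#'
#' @export
setClass("VariantTarget", representation(
    variantId = "character",
    gene = "character",
    ampliconRef = "character",
    variantOffset = "integer",
    refAllele = "character",
    altAllele = "character",
    genomicLabel = "character"
))

setValidity("VariantTarget", function(object) {
    msg <- character()
    amp <- object@ampliconRef
    if (grepl("[^ACGT]", amp))
        msg <- c(msg, "ampliconRef must contain only uppercase A/C/G/T")
    if (object@variantOffset < 0L || object@variantOffset >= nchar(amp))
        msg <- c(msg, "variantOffset must lie within ampliconRef (0-based)")
    else if (substr(amp, object@variantOffset + 1L,
                    object@variantOffset + 1L) != object@refAllele)
        msg <- c(msg, "ampliconRef base at variantOffset must equal refAllele")
    if (!object@refAllele %in% c("A", "C", "G", "T") ||
        !object@altAllele %in% c("A", "C", "G", "T"))
        msg <- c(msg, "refAllele and altAllele must be single bases in ACGT")
    if (identical(object@refAllele, object@altAllele))
        msg <- c(msg, "refAllele and altAllele must differ")
    if (length(msg)) msg else TRUE
})

#' @param variantId,gene,ampliconRef,variantOffset,refAllele,altAllele,genomicLabel
#'   See slot descriptions.
#' @return A \code{VariantTarget} object.
#' @rdname VariantTarget-class
#' @export
VariantTarget <- function(variantId, gene, ampliconRef, variantOffset,
                          refAllele, altAllele, genomicLabel = "") {
    new("VariantTarget", variantId = variantId, gene = gene,
        ampliconRef = toupper(ampliconRef),
        variantOffset = as.integer(variantOffset),
        refAllele = toupper(refAllele), altAllele = toupper(altAllele),
        genomicLabel = genomicLabel)
}

setMethod("show", "VariantTarget", function(object) {
    cat("VariantTarget", object@variantId, "\n",
        " gene: ", object@gene,
        if (nzchar(object@genomicLabel)) paste0(" (", object@genomicLabel, ")"),
        "\n",
        " amplicon: ", nchar(object@ampliconRef), " nt, ",
        object@refAllele, ">", object@altAllele,
        " at 0-based offset ", object@variantOffset, "\n", sep = "")
})

#' Tag extraction configuration
#'
#' Parameters controlling how the barcode/UMI cassette is located in long
#' amplicon reads. The anchor is the constant sequence immediately 5' of the
#' cell barcode (default: the 10X partial read-1 primer). Anchor hits and
#' barcode corrections both use Levenshtein edit distance, which tolerates the
#' indel-dominated error profile of nanopore reads.
#'
#' @slot anchorSeq Constant sequence preceding the cell barcode.
#' @slot maxAnchorMismatchFrac Maximum edits accepted for an anchor hit, as a
#'   fraction of anchor length (threshold is \code{ceiling(frac * nchar)}).
#' @slot cbcLen,umiLen Cell-barcode and UMI lengths in nt.
#' @slot maxCbcEdits Maximum edit distance for whitelist barcode correction.
#' @slot bothStrands Search the reverse complement as well.
#'
#' @export
setClass("TagConfig", representation(
    anchorSeq = "character",
    maxAnchorMismatchFrac = "numeric",
    cbcLen = "integer",
    umiLen = "integer",
    maxCbcEdits = "integer",
    bothStrands = "logical"
))

setValidity("TagConfig", function(object) {
    msg <- character()
    if (object@maxAnchorMismatchFrac < 0 || object@maxAnchorMismatchFrac >= 0.5)
        msg <- c(msg, "maxAnchorMismatchFrac must be in [0, 0.5)")
    if (object@cbcLen <= 0L || object@umiLen <= 0L)
        msg <- c(msg, "cbcLen and umiLen must be positive")
    if (grepl("[^ACGT]", object@anchorSeq))
        msg <- c(msg, "anchorSeq must be uppercase ACGT")
    if (length(msg)) msg else TRUE
})

#' @param anchorSeq,maxAnchorMismatchFrac,cbcLen,umiLen,maxCbcEdits,bothStrands
#'   See slot descriptions.
#' @return A \code{TagConfig} object.
#' @rdname TagConfig-class
#' @export
TagConfig <- function(anchorSeq = "CTACACGACGCTCTTCCGATCT",
                      maxAnchorMismatchFrac = 0.15,
                      cbcLen = 16L, umiLen = 12L,
                      maxCbcEdits = 1L, bothStrands = TRUE) {
    new("TagConfig", anchorSeq = toupper(anchorSeq),
        maxAnchorMismatchFrac = maxAnchorMismatchFrac,
        cbcLen = as.integer(cbcLen), umiLen = as.integer(umiLen),
        maxCbcEdits = as.integer(maxCbcEdits), bothStrands = bothStrands)
}

setMethod("show", "TagConfig", function(object) {
    cat("TagConfig: anchor ", nchar(object@anchorSeq), " nt (<= ",
        ceiling(object@maxAnchorMismatchFrac * nchar(object@anchorSeq)),
        " edits), CBC ", object@cbcLen, " nt (<= ", object@maxCbcEdits,
        " edits), UMI ", object@umiLen, " nt, ",
        if (object@bothStrands) "both strands" else "forward strand only",
        "\n", sep = "")
})

#' Bayesian per-cell genotype model
#'
#' Parameters of the per-cell genotyper. The genotype space is
#' \{reference-homozygous, heterozygous-mutant\}: the targeted lesional
#' variants are heterozygous somatic, so an alt-homozygous state is excluded.
#' Each UMI consensus is treated as an independent draw: under ref-hom a
#' consensus is alt with its consensus error probability epsilon; under
#' het-mut it is alt with probability \code{beta*(1-eps) + (1-beta)*eps},
#' where \code{beta} is the expected alt-allele expression fraction.
#'
#' @slot epsilonFloor Minimum per-UMI consensus error probability; guards
#'   against overconfident nanopore quality strings.
#' @slot beta Expected fraction of transcripts carrying the alt allele in a
#'   het cell (0.5 = balanced allelic expression).
#' @slot piMut Prior probability that a cell is het-mut.
#' @slot tau Posterior threshold for emitting a ref or mut call.
#' @slot minUmisRefCall Minimum ref-supporting UMI consensuses required for a
#'   ref call; protects against allelic dropout mislabeling het cells.
#' @slot mode "high_specificity" (UMIs must also be seen in matched Illumina
#'   data for the gene) or "high_sensitivity" (no Illumina match required).
#'
#' @export
setClass("GenotypeModel", representation(
    epsilonFloor = "numeric",
    beta = "numeric",
    piMut = "numeric",
    tau = "numeric",
    minUmisRefCall = "integer",
    mode = "character"
))

setValidity("GenotypeModel", function(object) {
    msg <- character()
    if (object@tau <= 0 || object@tau >= 1)
        msg <- c(msg, "tau must be in (0, 1)")
    if (object@beta <= 0 || object@beta >= 1)
        msg <- c(msg, "beta must be in (0, 1)")
    if (object@piMut < 0 || object@piMut > 1)
        msg <- c(msg, "piMut must be in [0, 1]")
    if (object@epsilonFloor <= 0 || object@epsilonFloor > 0.5)
        msg <- c(msg, "epsilonFloor must be in (0, 0.5]")
    if (!object@mode %in% c("high_specificity", "high_sensitivity"))
        msg <- c(msg, "mode must be 'high_specificity' or 'high_sensitivity'")
    if (length(msg)) msg else TRUE
})

#' @param epsilonFloor,beta,piMut,tau,minUmisRefCall,mode See slot
#'   descriptions.
#' @return A \code{GenotypeModel} object.
#' @rdname GenotypeModel-class
#' @export
GenotypeModel <- function(epsilonFloor = 0.005, beta = 0.5, piMut = 0.5,
                          tau = 0.95, minUmisRefCall = 2L,
                          mode = c("high_specificity", "high_sensitivity")) {
    new("GenotypeModel", epsilonFloor = epsilonFloor, beta = beta,
        piMut = piMut, tau = tau, minUmisRefCall = as.integer(minUmisRefCall),
        mode = match.arg(mode))
}

setMethod("show", "GenotypeModel", function(object) {
    cat("GenotypeModel (", object@mode, ")\n",
        " beta = ", object@beta, ", piMut = ", object@piMut,
        ", tau = ", object@tau, "\n",
        " epsilonFloor = ", object@epsilonFloor,
        ", minUmisRefCall = ", object@minUmisRefCall, "\n", sep = "")
})

#' Simulation configuration
#'
#' Conditions for generating a synthetic mosaic cohort with known truth:
#' a cell population in which a fraction of cells carry a heterozygous
#' somatic variant, matched Illumina barcode/UMI tag evidence, cell-type
#' annotations, and noisy long amplicon reads. Bulk variant allele frequency
#' relates to mosaicism as VAF ~ mosaicFraction / 2 for a heterozygous
#' variant.
#'
#' @slot nCells Number of cells.
#' @slot mosaicFraction Probability a cell is het-mut.
#' @slot cellTypeProbs Named categorical distribution over cell types
#'   (must sum to 1).
#' @slot expressionRate Named mean on-target transcripts per cell (Poisson),
#'   one entry per cell type.
#' @slot readsPerUmi Mean long reads per UMI (geometric, minimum 1).
#' @slot seqErrorRate Per-base substitution probability in long reads.
#' @slot indelRate Per-base indel probability (split evenly between
#'   insertion and deletion).
#' @slot betaTrue Alt-allele expression fraction in het cells.
#' @slot captureProb Probability each true (barcode, UMI) is present in the
#'   Illumina tag table.
#' @slot cbcLen,umiLen Barcode and UMI lengths.
#' @slot seed Integer seed; fixed seed gives byte-identical outputs.
#'
#' @export
setClass("SimulationConfig", representation(
    nCells = "integer",
    mosaicFraction = "numeric",
    cellTypeProbs = "numeric",
    expressionRate = "numeric",
    readsPerUmi = "numeric",
    seqErrorRate = "numeric",
    indelRate = "numeric",
    betaTrue = "numeric",
    captureProb = "numeric",
    cbcLen = "integer",
    umiLen = "integer",
    seed = "integer"
))

setValidity("SimulationConfig", function(object) {
    msg <- character()
    if (object@nCells <= 0L) msg <- c(msg, "nCells must be positive")
    if (object@mosaicFraction < 0 || object@mosaicFraction > 1)
        msg <- c(msg, "mosaicFraction must be in [0, 1]")
    if (abs(sum(object@cellTypeProbs) - 1) > 1e-8)
        msg <- c(msg, "cellTypeProbs must sum to 1")
    if (is.null(names(object@cellTypeProbs)))
        msg <- c(msg, "cellTypeProbs must be named")
    if (!setequal(names(object@expressionRate), names(object@cellTypeProbs)))
        msg <- c(msg, "expressionRate must name the same cell types as cellTypeProbs")
    if (any(object@expressionRate < 0) || object@seqErrorRate < 0 ||
        object@indelRate < 0 || object@readsPerUmi < 1)
        msg <- c(msg, "rates must be nonnegative and readsPerUmi >= 1")
    if (object@betaTrue <= 0 || object@betaTrue >= 1)
        msg <- c(msg, "betaTrue must be in (0, 1)")
    if (object@captureProb < 0 || object@captureProb > 1)
        msg <- c(msg, "captureProb must be in [0, 1]")
    if (length(msg)) msg else TRUE
})

#' @param nCells,mosaicFraction,cellTypeProbs,expressionRate,readsPerUmi,seqErrorRate,indelRate,betaTrue,captureProb,cbcLen,umiLen,seed
#'   See slot descriptions.
#' @return A \code{SimulationConfig} object.
#' @rdname SimulationConfig-class
#' @export
SimulationConfig <- function(nCells = 500L,
                             mosaicFraction = 0.3,
                             cellTypeProbs = c(ExN = 0.45, InN = 0.2,
                                               Astro = 0.15, Oligo = 0.15,
                                               Micro = 0.05),
                             expressionRate = c(ExN = 6, InN = 6, Astro = 5,
                                                Oligo = 5, Micro = 4),
                             readsPerUmi = 2.5,
                             seqErrorRate = 0.02,
                             indelRate = 0.01,
                             betaTrue = 0.5,
                             captureProb = 1,
                             cbcLen = 16L, umiLen = 12L,
                             seed = 1L) {
    new("SimulationConfig", nCells = as.integer(nCells),
        mosaicFraction = mosaicFraction, cellTypeProbs = cellTypeProbs,
        expressionRate = expressionRate[names(cellTypeProbs)],
        readsPerUmi = readsPerUmi, seqErrorRate = seqErrorRate,
        indelRate = indelRate, betaTrue = betaTrue,
        captureProb = captureProb, cbcLen = as.integer(cbcLen),
        umiLen = as.integer(umiLen), seed = as.integer(seed))
}

setMethod("show", "SimulationConfig", function(object) {
    cat("SimulationConfig: ", object@nCells, " cells, mosaic fraction ",
        object@mosaicFraction, "\n",
        " cell types: ", paste(names(object@cellTypeProbs), collapse = ", "),
        "\n",
        " error rates: sub ", object@seqErrorRate, ", indel ",
        object@indelRate, "; seed ", object@seed, "\n", sep = "")
})
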