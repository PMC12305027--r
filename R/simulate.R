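#' Simulate a variant target
#'
#' Draws a random amplicon reference of the requested length with a
#' heterozygous SNV target at the given 0-based offset. Uses the current
#' RNG state.
#'
#' @param gene Gene symbol.
#' @param len Amplicon length in nt (default 500).
#' @param offset 0-based variant offset (default 250, i.e. mid-amplicon).
#' @param variantId,genomicLabel Labels for the target.
#' @return A [VariantTarget].
#' @export
simulateTarget <- function(gene = "MTOR", len = 500L, offset = 250L,
                           variantId = paste0(gene, "_sim"),
                           genomicLabel = "synthetic") {
    amp <- randomDna(1, len)
    ref <- substr(amp, offset + 1L, offset + 1L)
    alt <- sample(setdiff(c("A", "C", "G", "T"), ref), 1)
    VariantTarget(variantId = variantId, gene = gene, ampliconRef = amp,
                  variantOffset = offset, refAllele = ref, altAllele = alt,
                  genomicLabel = genomicLabel)
}

# Apply substitution + indel errors to reads and draw per-base qualities.
# Base quality centres on the Phred equivalent of the substitution rate with
# ~2 Phred points of jitter, so quality strings are calibrated on average
# but individual miscalled bases can carry high quality (as in real
# nanopore data; the genotyper's epsilon floor exists for this reason).
.mutateReads <- function(seqs, subRate, indelRate) {
    qBase <- if (subRate > 0) -10 * log10(subRate) else 40
    half <- indelRate / 2
    bases <- c("A", "C", "G", "T")
    chAll <- strsplit(seqs, "", fixed = TRUE)
    out <- lapply(chAll, function(ch) {
        n <- length(ch)
        q <- pmin(40L, pmax(3L, as.integer(round(qBase + stats::rnorm(n, 0, 2)))))
        if (subRate > 0) {
            sub <- stats::runif(n) < subRate
            if (any(sub))
                ch[sub] <- bases[(match(ch[sub], bases) - 1L +
                                  sample.int(3L, sum(sub), replace = TRUE)) %% 4L + 1L]
        }
        if (indelRate > 0) {
            del <- stats::runif(n) < half
            ins <- stats::runif(n) < half
            insBase <- character(n); insQ <- integer(n)
            if (any(ins)) {
                insBase[ins] <- bases[sample.int(4L, sum(ins), replace = TRUE)]
                insQ[ins] <- pmin(40L, pmax(3L, as.integer(
                    round(qBase + stats::rnorm(sum(ins), 0, 2)))))
            }
            keepB <- rbind(ifelse(del, NA_character_, ch),
                           ifelse(ins, insBase, NA_character_))
            keepQ <- rbind(ifelse(del, NA_integer_, q),
                           ifelse(ins, insQ, NA_integer_))
            ch <- as.vector(keepB)[!is.na(as.vector(keepB))]
            q <- as.vector(keepQ)[!is.na(as.vector(keepQ))]
        }
        list(seq = paste(ch, collapse = ""), qual = intToQual(list(q)))
    })
    list(seq = vapply(out, `[[`, character(1), "seq"),
         qual = vapply(out, `[[`, character(1), "qual"))
}

.uniqueRandomDna <- function(n, len) {
    out <- unique(randomDna(n, len))
    while (length(out) < n)
        out <- unique(c(out, randomDna(n - length(out), len)))
    out
}

#' Simulate a mosaic cohort with known truth
#'
#' Generates every pipeline input: a mosaic cell population (each cell
#' het-mut with probability `mosaicFraction`), per-cell on-target
#' transcripts (Poisson by cell type; in het cells each transcript is alt
#' with probability `betaTrue`), noisy long amplicon reads
#' (anchor + barcode + UMI + amplicon payload, geometric reads per UMI,
#' substitution and indel errors at the configured rates, random read
#' orientation), the matched Illumina tag table (each true
#' (barcode, UMI, gene), thinned by `captureProb`), a whitelist (true
#' barcodes plus 10x decoys, to exercise correction), a cell-type
#' annotation, and per-cell / per-read truth tables. A fixed seed gives
#' identical output.
#'
#' @param cfg A [SimulationConfig].
#' @param target A [VariantTarget]; generated with [simulateTarget()] under
#'   the run seed when `NULL`.
#' @param cfgTag A [TagConfig] supplying the anchor sequence.
#' @param dir When non-`NULL`, the inputs are also written there
#'   (reads.fastq.gz, whitelist.txt, tags.tsv, annotation.tsv,
#'   truth_cells.tsv, truth_reads.tsv, targets.yaml).
#' @return A list with `reads` (`QualityScaledDNAStringSet`), `whitelist`,
#'   `tags`, `annotation`, `truthCells`, `truthReads`, `target`, and
#'   `files` (named paths when `dir` was given).
#' @export
simulateCohort <- function(cfg = SimulationConfig(), target = NULL,
                           cfgTag = TagConfig(), dir = NULL) {
    validObject(cfg)
    withSeed(cfg@seed, {
        if (is.null(target)) target <- simulateTarget()

        types <- names(cfg@cellTypeProbs)
        cbcs <- .uniqueRandomDna(cfg@nCells, cfg@cbcLen)
        cellType <- sample(types, cfg@nCells, replace = TRUE,
                           prob = cfg@cellTypeProbs)
        isHet <- stats::runif(cfg@nCells) < cfg@mosaicFraction
        truthCells <- data.frame(
            cbc = cbcs, cell_type = cellType,
            true_genotype = ifelse(isHet, "het-mut", "ref-hom"),
            stringsAsFactors = FALSE)

        nTx <- stats::rpois(cfg@nCells, cfg@expressionRate[cellType])
        cellIdx <- rep.int(seq_len(cfg@nCells), nTx)
        nTot <- sum(nTx)
        umis <- character(nTot)
        for (i in unique(cellIdx)) {
            j <- which(cellIdx == i)
            umis[j] <- .uniqueRandomDna(length(j), cfg@umiLen)
        }
        txAllele <- ifelse(isHet[cellIdx] &
                           stats::runif(nTot) < cfg@betaTrue, "alt", "ref")

        # long reads: geometric (min 1) copies per transcript
        nReads <- 1L + stats::rgeom(nTot, prob = 1 / cfg@readsPerUmi)
        txIdx <- rep.int(seq_len(nTot), nReads)
        ampAlt <- target@ampliconRef
        substr(ampAlt, target@variantOffset + 1L,
               target@variantOffset + 1L) <- target@altAllele
        payload <- ifelse(txAllele[txIdx] == "alt", ampAlt,
                          target@ampliconRef)
        ideal <- paste0(cfgTag@anchorSeq, cbcs[cellIdx[txIdx]], umis[txIdx],
                        payload)
        noisy <- .mutateReads(ideal, cfg@seqErrorRate, cfg@indelRate)
        flip <- stats::runif(length(ideal)) < 0.5
        seqOut <- noisy$seq
        qualOut <- noisy$qual
        if (any(flip)) {
            seqOut[flip] <- revcompStr(seqOut[flip])
            qualOut[flip] <- reverseStr(qualOut[flip])
        }
        readId <- sprintf("r%07d", seq_along(seqOut))
        truthReads <- data.frame(
            read_id = readId, cbc = cbcs[cellIdx[txIdx]], umi = umis[txIdx],
            allele = txAllele[txIdx], strand = ifelse(flip, "-", "+"),
            stringsAsFactors = FALSE)
        reads <- Biostrings::QualityScaledDNAStringSet(
            Biostrings::DNAStringSet(structure(seqOut, names = readId)),
            Biostrings::PhredQuality(qualOut))

        whitelist <- sort(c(cbcs, setdiff(
            .uniqueRandomDna(11L * cfg@nCells, cfg@cbcLen), cbcs)[
                seq_len(10L * cfg@nCells)]))

        tags <- data.frame(cbc = cbcs[cellIdx], umi = umis,
                           gene = target@gene,
                           count = 1L + stats::rpois(nTot, 2),
                           stringsAsFactors = FALSE)
        if (cfg@captureProb < 1)
            tags <- downsampleTags(tags, cfg@captureProb)
        tags <- tags[order(tags$cbc, tags$umi), , drop = FALSE]
        rownames(tags) <- NULL

        annotation <- truthCells[, c("cbc", "cell_type")]

        files <- NULL
        if (!is.null(dir)) {
            if (!dir.exists(dir)) dir.create(dir, recursive = TRUE)
            files <- c(fastq = file.path(dir, "reads.fastq.gz"),
                       whitelist = file.path(dir, "whitelist.txt"),
                       tags = file.path(dir, "tags.tsv"),
                       annotation = file.path(dir, "annotation.tsv"),
                       truth_cells = file.path(dir, "truth_cells.tsv"),
                       truth_reads = file.path(dir, "truth_reads.tsv"),
                       targets = file.path(dir, "targets.yaml"))
            con <- gzfile(files[["fastq"]], "wb")
            writeLines(paste0("@", readId, "\n", seqOut, "\n+\n", qualOut),
                       con)
            close(con)
            writeLines(whitelist, files[["whitelist"]])
            writeTable(tags, files[["tags"]])
            writeTable(annotation, files[["annotation"]])
            writeTable(truthCells, files[["truth_cells"]])
            writeTable(truthReads, files[["truth_reads"]])
            yaml::write_yaml(list(targets = list(list(
                variant_id = target@variantId, gene = target@gene,
                amplicon_ref = target@ampliconRef,
                variant_offset = target@variantOffset,
                ref_allele = target@refAllele,
                alt_allele = target@altAllele,
                genomic_label = target@genomicLabel))), files[["targets"]])
        }

        list(reads = reads, whitelist = whitelist, tags = tags,
             annotation = annotation, truthCells = truthCells,
             truthReads = truthReads, target = target, files = files)
    })
}

#' Thin an Illumina tag table
#'
#' Retains each row independently with probability `captureProb`; models
#' incomplete capture of transcripts in the short-read data (the
#' sensitivity cost of the high-specificity filter).
#'
#' @param tags Tag table data.frame.
#' @param captureProb Retention probability in `[0, 1]`.
#' @param seed Optional seed for reproducible thinning; when `NULL` the
#'   current RNG state is used.
#' @return The thinned tag table.
#' @export
downsampleTags <- function(tags, captureProb, seed = NULL) {
    stopifnot(captureProb >= 0, captureProb <= 1)
    thin <- function() tags[stats::runif(nrow(tags)) < captureProb, ,
                            drop = FALSE]
    out <- if (is.null(seed)) thin() else withSeed(seed, thin())
    rownames(out) <- NULL
    out
}

#' Simulate UMI-consensus evidence directly
#'
#' Generates per-cell UMI consensuses without the read level: each cell is
#' het-mut with probability `mosaicFraction`; UMI counts are
#' `minUmis + Poisson(umiRate)`; in het cells each UMI's true allele is alt
#' with probability `beta`; every consensus is recorded with error
#' probability `epsilon` and flips allele with that probability. Used to
#' study the genotyper's operating characteristics at controlled consensus
#' depth and error, independent of read-level noise.
#'
#' @param nCells Number of cells.
#' @param mosaicFraction Probability a cell is het-mut.
#' @param minUmis Minimum consensuses per cell (default 3).
#' @param umiRate Poisson mean added on top of `minUmis` (default 5).
#' @param epsilon Consensus error probability (default 0.01).
#' @param beta Alt expression fraction in het cells (default 0.5).
#' @param seed Integer seed.
#' @return A list with `consensuses` (data.frame as from [collapseUmis()])
#'   and `truth` (data.frame: `cbc`, `true_genotype`).
#' @export
simulateConsensusEvidence <- function(nCells, mosaicFraction, minUmis = 3L,
                                      umiRate = 5, epsilon = 0.01,
                                      beta = 0.5, seed = 1L) {
    withSeed(seed, {
        cbc <- sprintf("CELL%05d", seq_len(nCells))
        het <- stats::runif(nCells) < mosaicFraction
        nUmi <- minUmis + stats::rpois(nCells, umiRate)
        idx <- rep.int(seq_len(nCells), nUmi)
        trueAlt <- het[idx] & stats::runif(length(idx)) < beta
        obsAlt <- xor(trueAlt, stats::runif(length(idx)) < epsilon)
        cons <- data.frame(
            cbc = cbc[idx],
            umi = sprintf("UMI%07d", seq_along(idx)),
            allele = ifelse(obsAlt, "alt", "ref"),
            n_reads = 1L, epsilon_umi = epsilon,
            stringsAsFactors = FALSE)
        list(consensuses = cons,
             truth = data.frame(cbc = cbc,
                                true_genotype = ifelse(het, "het-mut",
                                                       "ref-hom"),
                                stringsAsFactors = FALSE))
    })
}
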