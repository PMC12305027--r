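# Batch semi-global alignment of payloads against the amplicon reference and
# readout of the variant column. Free end gaps on the payload; an alignment
# is accepted when identity over the aligned span reaches minIdentity and the
# span covers the variant position +/- flank nt (clipped to the amplicon).
.alignBatch <- function(payloads, target, minIdentity = 0.75, flank = 15L) {
    n <- length(payloads)
    res <- data.frame(accepted = rep(FALSE, n), identity = NA_real_,
                      alignment_edits = NA_integer_,
                      variant_base = NA_character_,
                      payload_pos = NA_integer_, stringsAsFactors = FALSE)
    lenOk <- !is.na(payloads) & nchar(payloads) >= 30L
    if (!any(lenOk)) return(res)
    sub <- Biostrings::DNAString(target@ampliconRef)
    mat <- Biostrings::nucleotideSubstitutionMatrix(match = 2, mismatch = -4,
                                                    baseOnly = FALSE)
    pa <- Biostrings::pairwiseAlignment(
        Biostrings::DNAStringSet(payloads[lenOk]), sub, type = "overlap",
        substitutionMatrix = mat, gapOpening = 4, gapExtension = 2)
    patAl <- as.character(Biostrings::pattern(pa))
    subAl <- as.character(Biostrings::subject(pa))
    sStart <- IRanges::start(Biostrings::subject(pa))
    pStart <- IRanges::start(Biostrings::pattern(pa))
    nm <- Biostrings::nmatch(pa)
    cols <- nchar(patAl)
    ampLen <- nchar(target@ampliconRef)
    v1 <- target@variantOffset + 1L
    winLo <- max(1L, v1 - flank)
    winHi <- min(ampLen, v1 + flank)
    idx <- which(lenOk)
    for (j in seq_along(idx)) {
        i <- idx[j]
        if (cols[j] == 0L) next
        identity <- nm[j] / cols[j]
        chS <- strsplit(subAl[j], "", fixed = TRUE)[[1]]
        subjPos <- sStart[j] - 1L + cumsum(chS != "-")
        sEnd <- subjPos[length(subjPos)]
        res$identity[i] <- identity
        res$alignment_edits[i] <- cols[j] - nm[j]
        if (identity < minIdentity || sStart[j] > winLo || sEnd < winHi) next
        res$accepted[i] <- TRUE
        k <- which(chS != "-" & subjPos == v1)
        if (length(k) == 0L) next  # variant column outside aligned span
        chP <- strsplit(patAl[j], "", fixed = TRUE)[[1]]
        if (chP[k] == "-") next    # variant base deleted in the read
        res$variant_base[i] <- chP[k]
        res$payload_pos[i] <- pStart[j] - 1L + sum(chP[seq_len(k)] != "-")
    }
    res
}

#' Align a read payload to the amplicon reference
#'
#' Semi-global alignment (free end gaps on the payload) of a tagged read's
#' payload to the target amplicon. The alignment is accepted when identity
#' over the aligned span is at least `minIdentity` and the span covers the
#' variant position within +/- `flank` nt.
#'
#' @param payload Payload sequence (character).
#' @param target A [VariantTarget].
#' @param minIdentity Minimum aligned identity (default 0.75).
#' @param flank Required coverage around the variant, in nt (default 15).
#' @return `NULL` when unaligned; otherwise a list with `identity`,
#'   `edits`, `variantBase` (`NA` when the variant column is deleted or
#'   uncovered) and `payloadPos` (1-based payload coordinate of that base).
#' @export
alignPayload <- function(payload, target, minIdentity = 0.75, flank = 15L) {
    r <- .alignBatch(as.character(payload), target, minIdentity, flank)
    if (!r$accepted[1]) return(NULL)
    list(identity = r$identity[1], edits = r$alignment_edits[1],
         variantBase = r$variant_base[1], payloadPos = r$payload_pos[1])
}

.classifyAllele <- function(base, target) {
    ifelse(is.na(base), "missing",
           ifelse(base == target@refAllele, "ref",
                  ifelse(base == target@altAllele, "alt", "other")))
}

#' Call the variant allele on one tagged read
#'
#' Aligns the read payload to the amplicon and reads out the base and its
#' Phred quality at the variant column. A deleted or uncovered variant
#' column, or an unalignable payload, yields `allele = "missing"` with a
#' `NULL`-equivalent (`NA`) quality.
#'
#' @param tagged A one-row data.frame as produced by [tagReads()] (needs
#'   `payload` and `payload_qual`); must carry a non-missing corrected
#'   barcode.
#' @param target A [VariantTarget].
#' @param minIdentity,flank Passed to [alignPayload()].
#' @return A list with `allele` (`"ref"`, `"alt"`, `"other"`, `"missing"`),
#'   `baseQuality` (Phred integer or `NA`) and `alignmentEdits`.
#' @export
callReadAllele <- function(tagged, target, minIdentity = 0.75, flank = 15L) {
    stopifnot(nrow(tagged) == 1L, !is.na(tagged$cbc))
    r <- .alignBatch(tagged$payload, target, minIdentity, flank)
    allele <- .classifyAllele(r$variant_base[1], target)
    q <- NA_integer_
    if (!is.na(r$payload_pos[1]))
        q <- qualToInt(substr(tagged$payload_qual, r$payload_pos[1],
                              r$payload_pos[1]))[[1]]
    list(allele = allele, baseQuality = q,
         alignmentEdits = r$alignment_edits[1])
}

#' Call variant alleles for a batch of tagged reads
#'
#' Aligns every tagged read's payload to the amplicon reference and reads
#' out the allele at the variant position. Reads whose payload does not
#' produce an acceptable alignment are dropped and counted as unaligned;
#' aligned reads whose variant column is deleted or uncovered are kept with
#' `allele = "missing"`.
#'
#' @param tags The `tags` data.frame from [tagReads()].
#' @param target A [VariantTarget].
#' @param minIdentity,flank Passed to [alignPayload()].
#' @return A list with `observations` (data.frame: `read_id`, `cbc`, `umi`,
#'   `allele`, `base_quality`, `alignment_edits`) and `nUnaligned`.
#' @export
callAlleles <- function(tags, target, minIdentity = 0.75, flank = 15L) {
    if (nrow(tags) == 0L)
        return(list(observations = data.frame(
            read_id = character(), cbc = character(), umi = character(),
            allele = character(), base_quality = integer(),
            alignment_edits = integer()), nUnaligned = 0L))
    r <- .alignBatch(tags$payload, target, minIdentity, flank)
    keep <- r$accepted
    obs <- data.frame(read_id = tags$read_id[keep], cbc = tags$cbc[keep],
                      umi = tags$umi[keep],
                      allele = .classifyAllele(r$variant_base[keep], target),
                      base_quality = NA_integer_,
                      alignment_edits = r$alignment_edits[keep],
                      stringsAsFactors = FALSE)
    pos <- r$payload_pos[keep]
    hasBase <- !is.na(pos)
    if (any(hasBase)) {
        quals <- substr(tags$payload_qual[keep][hasBase], pos[hasBase],
                        pos[hasBase])
        obs$base_quality[hasBase] <- vapply(
            qualToInt(quals), `[`, integer(1), 1L)
    }
    list(observations = obs, nUnaligned = sum(!keep))
}
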