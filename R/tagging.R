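# Anchor search over both strands for a batch of reads. Coordinates are
# reported in the orientation in which the anchor was found (i.e. for '-'
# hits, within the reverse complement of the read).
.anchorScan <- function(seqs, cfg) {
    anchor <- cfg@anchorSeq
    kmax <- ceiling(cfg@maxAnchorMismatchFrac * nchar(anchor))
    fwd <- .semiglobal_search(anchor, seqs)
    if (cfg@bothStrands) {
        rev <- .semiglobal_search(anchor, revcompStr(seqs))
    } else {
        rev <- matrix(c(rep(nchar(anchor), length(seqs)),
                        rep(0L, length(seqs))), ncol = 2)
    }
    fwdOk <- fwd[, 1] <= kmax
    revOk <- rev[, 1] <= kmax
    # best hit; ties between strands break toward '+'
    usePlus <- fwdOk & (!revOk | fwd[, 1] <= rev[, 1])
    found <- fwdOk | revOk
    data.frame(
        found = found,
        strand = ifelse(usePlus, "+", "-"),
        end = ifelse(usePlus, fwd[, 2], rev[, 2]),
        edits = ifelse(usePlus, fwd[, 1], rev[, 1]),
        # equally good acceptable hits on both strands: likely chimera
        conflict = fwdOk & revOk & fwd[, 1] == rev[, 1],
        stringsAsFactors = FALSE)
}

#' Locate the constant anchor in a long read
#'
#' Finds the best semi-global (edit-distance) occurrence of the anchor
#' sequence in the read and, if configured, in its reverse complement. A hit
#' is accepted when its edit count is at most
#' `ceiling(maxAnchorMismatchFrac * nchar(anchorSeq))`. Ties between strands
#' break toward `+`.
#'
#' @param seq Read sequence (character or `DNAString`).
#' @param cfg A [TagConfig].
#' @return `NULL` if no acceptable hit; otherwise a list with `strand`
#'   (`"+"`/`"-"`), `end` (1-based position of the last anchor base, in the
#'   orientation in which the anchor was found), and `edits`.
#' @export
findAnchor <- function(seq, cfg = TagConfig()) {
    hit <- .anchorScan(toupper(as.character(seq)), cfg)
    if (!hit$found[1]) return(NULL)
    list(strand = hit$strand[1], end = hit$end[1], edits = hit$edits[1])
}

#' Correct raw cell barcodes against a whitelist
#'
#' An exact whitelist match always wins. Otherwise the unique whitelist entry
#' within `maxEdits` Levenshtein edits is returned; if two or more entries
#' tie at the minimal distance the barcode is ambiguous. Base qualities are
#' not used.
#'
#' @param cbcRaw Character vector of raw barcode sequences.
#' @param whitelist Character vector of valid barcodes.
#' @param maxEdits Maximum accepted edit distance (default 1).
#' @return data.frame with columns `cbc` (corrected barcode or `NA`),
#'   `edits` (distance to the corrected barcode, `NA` if uncorrected) and
#'   `status` (`"matched"`, `"unmatched"`, `"ambiguous"`).
#' @export
correctBarcode <- function(cbcRaw, whitelist, maxEdits = 1L) {
    if (length(whitelist) == 0L) stop("whitelist is empty")
    n <- length(cbcRaw)
    cbc <- rep(NA_character_, n)
    edits <- rep(NA_integer_, n)
    status <- rep("unmatched", n)
    exact <- match(cbcRaw, whitelist)
    hitE <- !is.na(exact)
    cbc[hitE] <- whitelist[exact[hitE]]
    edits[hitE] <- 0L
    status[hitE] <- "matched"
    # pigeonhole prefilter for the common maxEdits = 1, fixed-length case:
    # distance 1 between equal-length strings is a single substitution, so
    # either the first or the second half must match exactly
    L <- unique(nchar(whitelist))
    usePre <- maxEdits == 1L && length(L) == 1L
    if (usePre) {
        h <- L %/% 2L
        byPre <- split(seq_along(whitelist), substr(whitelist, 1L, h))
        bySuf <- split(seq_along(whitelist), substr(whitelist, h + 1L, L))
    }
    for (i in which(!hitE)) {
        if (usePre && nchar(cbcRaw[i]) == L) {
            cand <- unique(c(byPre[[substr(cbcRaw[i], 1L, h)]],
                             bySuf[[substr(cbcRaw[i], h + 1L, L)]]))
            if (length(cand) == 0L) next
            d <- .bounded_levenshtein(cbcRaw[i], whitelist[cand], 1L)
            dmin <- min(d)
            if (dmin > maxEdits) next
            best <- cand[which(d == dmin)]
            if (length(best) == 1L) {
                cbc[i] <- whitelist[best]
                edits[i] <- dmin
                status[i] <- "matched"
            } else status[i] <- "ambiguous"
            next
        }
        d <- .bounded_levenshtein(cbcRaw[i], whitelist, as.integer(maxEdits))
        dmin <- min(d)
        if (dmin > maxEdits) next
        best <- which(d == dmin)
        if (length(best) == 1L) {
            cbc[i] <- whitelist[best]
            edits[i] <- dmin
            status[i] <- "matched"
        } else {
            status[i] <- "ambiguous"
        }
    }
    data.frame(cbc = cbc, edits = edits, status = status,
               stringsAsFactors = FALSE)
}

#' Extract barcode, UMI and payload from long reads
#'
#' For every read, locates the anchor (both strands), takes the `cbcLen`
#' bases after it as the raw cell barcode and the next `umiLen` bases as the
#' UMI, corrects the barcode against the whitelist, and keeps the remaining
#' sequence (in anchor orientation) as the payload for allele calling.
#' Reads carrying equally good acceptable anchor hits on both strands are
#' treated as potential chimeras and rejected.
#'
#' Rejection reasons: `too-short` (read cannot hold anchor + barcode + UMI),
#' `no-anchor` (no acceptable hit, or conflicting strand hits),
#' `cbc-unmatched` and `cbc-ambiguous` (whitelist correction failed).
#'
#' @param reads A `QualityScaledDNAStringSet` (see [readFastqRecords()]), or
#'   a character vector of sequences (qualities then default to Q20).
#' @param whitelist Character vector of valid barcodes.
#' @param cfg A [TagConfig].
#' @return A list with `tags` (data.frame: `read_id`, `cbc_raw`, `cbc`,
#'   `umi`, `strand`, `anchor_edits`, `cbc_edits`, `payload`,
#'   `payload_qual`), `rejections` (data.frame: `read_id`, `reason`) and
#'   `summary` (named integer vector of reason counts, including `tagged`).
#' @export
tagReads <- function(reads, whitelist, cfg = TagConfig()) {
    if (is.character(reads)) {
        ids <- if (is.null(names(reads))) paste0("read", seq_along(reads))
               else names(reads)
        seqs <- toupper(reads)
        quals <- vapply(nchar(seqs), function(n)
            paste(rep("5", n), collapse = ""), character(1))
    } else {
        ids <- names(reads)
        seqs <- as.character(reads)
        quals <- as.character(Biostrings::quality(reads))
    }
    n <- length(seqs)
    reason <- rep(NA_character_, n)
    minLen <- nchar(cfg@anchorSeq) + cfg@cbcLen + cfg@umiLen
    tooShort <- nchar(seqs) <= minLen
    reason[tooShort] <- "too-short"

    out <- data.frame(read_id = ids, cbc_raw = NA_character_,
                      cbc = NA_character_, umi = NA_character_,
                      strand = NA_character_, anchor_edits = NA_integer_,
                      cbc_edits = NA_integer_, payload = NA_character_,
                      payload_qual = NA_character_, stringsAsFactors = FALSE)

    idx <- which(!tooShort)
    if (length(idx)) {
        hits <- .anchorScan(seqs[idx], cfg)
        reason[idx[!hits$found | hits$conflict]] <- "no-anchor"
        ok <- which(hits$found & !hits$conflict)
        if (length(ok)) {
            i <- idx[ok]
            s <- seqs[i]; q <- quals[i]
            minus <- hits$strand[ok] == "-"
            if (any(minus)) {
                s[minus] <- revcompStr(s[minus])
                q[minus] <- reverseStr(q[minus])
            }
            aEnd <- hits$end[ok]
            tagEnd <- aEnd + cfg@cbcLen + cfg@umiLen
            short <- nchar(s) < tagEnd
            reason[i[short]] <- "too-short"
            keep <- !short
            i <- i[keep]; s <- s[keep]; q <- q[keep]
            aEnd <- aEnd[keep]; tagEnd <- tagEnd[keep]
            out$cbc_raw[i] <- substr(s, aEnd + 1L, aEnd + cfg@cbcLen)
            out$umi[i] <- substr(s, aEnd + cfg@cbcLen + 1L, tagEnd)
            out$strand[i] <- hits$strand[ok][keep]
            out$anchor_edits[i] <- hits$edits[ok][keep]
            out$payload[i] <- substr(s, tagEnd + 1L, nchar(s))
            out$payload_qual[i] <- substr(q, tagEnd + 1L, nchar(q))
        }
        cand <- which(!is.na(out$cbc_raw))
        if (length(cand)) {
            corr <- correctBarcode(out$cbc_raw[cand], whitelist,
                                   cfg@maxCbcEdits)
            out$cbc[cand] <- corr$cbc
            out$cbc_edits[cand] <- corr$edits
            reason[cand[corr$status == "unmatched"]] <- "cbc-unmatched"
            reason[cand[corr$status == "ambiguous"]] <- "cbc-ambiguous"
        }
    }

    tagged <- is.na(reason)
    rej <- data.frame(read_id = ids[!tagged], reason = reason[!tagged],
                      stringsAsFactors = FALSE)
    summary <- c(tagged = sum(tagged),
                 table(factor(rej$reason,
                              levels = c("no-anchor", "cbc-unmatched",
                                         "cbc-ambiguous", "too-short"))))
    list(tags = out[tagged, , drop = FALSE], rejections = rej,
         summary = summary)
}

#' Extract tags from a single read
#'
#' Single-read convenience wrapper around [tagReads()].
#'
#' @param seq Read sequence (character).
#' @param whitelist Character vector of valid barcodes.
#' @param cfg A [TagConfig].
#' @param qual Optional Phred+33 quality string.
#' @return A one-row data.frame of tag fields, or a character rejection
#'   reason.
#' @export
extractTags <- function(seq, whitelist, cfg = TagConfig(), qual = NULL) {
    seq <- as.character(seq)
    if (!is.null(qual)) {
        sq <- Biostrings::QualityScaledDNAStringSet(
            Biostrings::DNAStringSet(structure(seq, names = "read1")),
            Biostrings::PhredQuality(qual))
        res <- tagReads(sq, whitelist, cfg)
    } else {
        res <- tagReads(structure(seq, names = "read1"), whitelist, cfg)
    }
    if (nrow(res$tags) == 1L) res$tags else res$rejections$reason[1]
}
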