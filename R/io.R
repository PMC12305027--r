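#' Read a FASTQ file of long amplicon reads
#'
#' Reads a (possibly gzip-compressed) FASTQ file into a
#' [Biostrings::QualityScaledDNAStringSet], uppercasing sequences. Qualities
#' are Phred+33; Phred+64 encodings are not supported.
#'
#' @param path Path to a FASTQ or FASTQ.gz file.
#' @return A `QualityScaledDNAStringSet`; read identifiers are the names.
#' @export
readFastqRecords <- function(path) {
    if (!file.exists(path)) stop("FASTQ file not found: ", path)
    reads <- withCallingHandlers(
        tryCatch(
            Biostrings::readQualityScaledDNAStringSet(path),
            error = function(e) stop("malformed FASTQ record in '", path,
                                     "': ", conditionMessage(e),
                                     call. = FALSE)),
        warning = function(w) {
            if (grepl("metadata columns.*dropped", conditionMessage(w)))
                invokeRestart("muffleWarning")
        })
    if (length(reads) == 0L) return(reads)
    # a quality string shorter than its sequence comes back padded with
    # bytes outside the Phred+33 range; detect at the byte level so the
    # error can name the offending record
    af <- Biostrings::alphabetFrequency(Biostrings::quality(reads))
    bad <- which(rowSums(af[, -(34:127), drop = FALSE]) > 0)
    if (length(bad))
        stop("malformed FASTQ record in '", path,
             "': sequence/quality length mismatch for record '",
             names(reads)[bad[1]], "'", call. = FALSE)
    qual <- as.character(Biostrings::quality(reads))
    sq <- Biostrings::DNAStringSet(toupper(as.character(reads)))
    names(sq) <- names(reads)
    Biostrings::QualityScaledDNAStringSet(sq, Biostrings::PhredQuality(qual))
}

#' Per-read integer quality scores
#'
#' @param reads A `QualityScaledDNAStringSet` from [readFastqRecords()].
#' @return A list of integer Phred score vectors, one per read.
#' @export
readQualities <- function(reads) {
    qualToInt(as.character(Biostrings::quality(reads)))
}

#' Read a cell-barcode whitelist
#'
#' One barcode per line; all entries must be equal-length uppercase ACGT
#' strings with no duplicates.
#'
#' @param path Path to the plain-text whitelist.
#' @return Character vector of barcodes.
#' @export
readWhitelist <- function(path) {
    wl <- toupper(readLines(path))
    wl <- wl[nzchar(wl)]
    if (length(wl) == 0L) stop("empty whitelist: ", path)
    if (length(unique(nchar(wl))) != 1L)
        stop("whitelist barcodes must all have the same length")
    if (any(grepl("[^ACGT]", wl)))
        stop("whitelist barcodes must be uppercase ACGT")
    if (anyDuplicated(wl)) stop("duplicate barcodes in whitelist")
    wl
}

#' Read a cell-annotation table
#'
#' A two-column table mapping cell barcode to cell type. Comma- or
#' tab-separated, chosen by file extension (.csv vs anything else).
#'
#' @param path Path to the annotation file with header columns
#'   `cbc,cell_type`.
#' @return data.frame with columns `cbc`, `cell_type`.
#' @export
readCellAnnotation <- function(path) {
    sep <- if (grepl("\\.csv$", path, ignore.case = TRUE)) "," else "\t"
    ann <- utils::read.table(path, header = TRUE, sep = sep,
                             stringsAsFactors = FALSE)
    if (!all(c("cbc", "cell_type") %in% names(ann)))
        stop("annotation must have columns 'cbc' and 'cell_type'")
    if (anyDuplicated(ann$cbc))
        stop("annotation assigns multiple cell types to one barcode")
    ann[, c("cbc", "cell_type")]
}

#' Read variant targets from a YAML configuration
#'
#' The file holds a list of blocks, each with fields `variant_id`, `gene`,
#' `amplicon_ref`, `variant_offset`, `ref_allele`, `alt_allele` and optional
#' `genomic_label`. `variant_offset` is 0-based within the amplicon; a
#' 1-based `variant_pos` field is accepted instead and converted.
#'
#' @param path Path to the YAML file.
#' @return Named list of [VariantTarget] objects (names = variant ids).
#' @export
readVariantTargets <- function(path) {
    cfg <- yaml::read_yaml(path)
    if (!is.null(cfg$targets)) cfg <- cfg$targets
    targets <- lapply(cfg, function(b) {
        off <- if (!is.null(b$variant_offset)) as.integer(b$variant_offset)
               else if (!is.null(b$variant_pos)) as.integer(b$variant_pos) - 1L
               else stop("target block lacks variant_offset/variant_pos")
        VariantTarget(variantId = b$variant_id, gene = b$gene,
                      ampliconRef = b$amplicon_ref, variantOffset = off,
                      refAllele = b$ref_allele, altAllele = b$alt_allele,
                      genomicLabel = if (is.null(b$genomic_label)) ""
                                     else b$genomic_label)
    })
    names(targets) <- vapply(targets, function(t) t@variantId, character(1))
    targets
}

#' Load Illumina short-read barcode/UMI/gene evidence
#'
#' Builds the (barcode, UMI, gene) support table from the matched 10X
#' Illumina snRNA-seq data, used by the high-specificity genotyping filter.
#' Input is either a BAM carrying the standard 10X tag dialect
#' (`CB` corrected barcode, `UB` corrected UMI, `GX` gene) or a pre-extracted
#' TSV with header `cbc,umi,gene` and optional `count`. A trailing GEM-well
#' suffix such as "-1" is stripped from BAM `CB` values so barcodes compare
#' against the whitelist. Rows are restricted to `genes`, and duplicate
#' (cbc, umi, gene) triples are collapsed with summed counts.
#'
#' @param path Path to a BAM or TSV file.
#' @param genes Character vector of gene symbols to keep.
#' @return data.frame with columns `cbc`, `umi`, `gene`, `count`, sorted by
#'   (cbc, umi, gene).
#' @export
loadIlluminaTags <- function(path, genes) {
    if (grepl("\\.bam$", path, ignore.case = TRUE)) {
        p <- Rsamtools::ScanBamParam(tag = c("CB", "UB", "GX"))
        res <- Rsamtools::scanBam(path, param = p)[[1]]$tag
        if (is.null(res$CB) || is.null(res$UB) || is.null(res$GX))
            stop("BAM lacks CB/UB/GX tags: ", path)
        tab <- data.frame(cbc = sub("-[0-9]+$", "", res$CB),
                          umi = res$UB, gene = res$GX, count = 1L,
                          stringsAsFactors = FALSE)
        tab <- tab[!is.na(tab$cbc) & !is.na(tab$umi) & !is.na(tab$gene), ]
    } else {
        tab <- utils::read.table(path, header = TRUE, sep = "\t",
                                 stringsAsFactors = FALSE)
        if (!all(c("cbc", "umi", "gene") %in% names(tab)))
            stop("tag TSV must have columns cbc, umi, gene")
        if (is.null(tab$count)) tab$count <- 1L
    }
    missing <- setdiff(genes, tab$gene)
    if (length(missing))
        warning("no tag rows for gene(s): ", paste(missing, collapse = ", "))
    tab <- tab[tab$gene %in% genes, , drop = FALSE]
    if (nrow(tab) == 0L)
        return(data.frame(cbc = character(), umi = character(),
                          gene = character(), count = integer()))
    agg <- stats::aggregate(count ~ cbc + umi + gene, data = tab, FUN = sum)
    agg <- agg[order(agg$cbc, agg$umi, agg$gene), ]
    rownames(agg) <- NULL
    agg
}

#' Write a result table
#'
#' Tab-separated with a header line, UTF-8, rows sorted by the given key
#' columns for bit-reproducible output. `NA`/`NaN` values are written as
#' "NA".
#'
#' @param x data.frame to write.
#' @param path Output path.
#' @param key Column names to sort by; defaults to all columns left-to-right.
#' @return Invisibly, the path.
#' @export
writeTable <- function(x, path, key = names(x)) {
    x <- as.data.frame(x)
    if (nrow(x) > 0L && length(key))
        x <- x[do.call(order, x[key]), , drop = FALSE]
    ok <- tryCatch({
        utils::write.table(x, path, sep = "\t", quote = FALSE,
                           row.names = FALSE, na = "NA",
                           fileEncoding = "UTF-8")
        TRUE
    }, error = function(e) FALSE, warning = function(w) FALSE)
    if (!ok) stop("cannot write table to: ", path)
    invisible(path)
}

#' Read a table written by [writeTable()]
#'
#' @param path Path to the TSV file.
#' @return data.frame.
#' @export
readTsv <- function(path) {
    utils::read.table(path, header = TRUE, sep = "\t",
                      stringsAsFactors = FALSE, na.strings = "NA")
}
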