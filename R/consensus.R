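# Directional merging of UMIs within one cell: u2 merges into u1 iff their
# edit distance is <= 1 and reads(u1) >= 2*reads(u2) - 1. UMIs are processed
# in deterministic order (descending read count, then lexicographic); each
# UMI joins the first established representative it can merge into.
.clusterOneCell <- function(umis, counts) {
    o <- order(-counts, umis)
    umis <- umis[o]; counts <- counts[o]
    rep <- character(0)
    repCount <- integer(0)
    assign <- character(length(umis))
    for (j in seq_along(umis)) {
        hit <- NA_integer_
        if (length(rep)) {
            d <- .bounded_levenshtein(umis[j], rep, 1L)
            ok <- which(d <= 1L & repCount >= 2L * counts[j] - 1L)
            if (length(ok)) hit <- ok[1]
        }
        if (is.na(hit)) {
            rep <- c(rep, umis[j])
            repCount <- c(repCount, counts[j])
            assign[j] <- umis[j]
        } else {
            assign[j] <- rep[hit]
        }
    }
    names(assign) <- umis
    assign
}

#' Merge sequencing-error UMIs within each cell
#'
#' Directional single-linkage merging of UMI labels among the allele
#' observations of each cell: a UMI absorbs a neighbor at edit distance
#' <= 1 when its read count is at least `2 * neighbor_count - 1`
#' (the standard directional rule for amplification-error UMIs).
#' Processing order is deterministic: descending read count, then
#' lexicographic.
#'
#' @param observations data.frame of allele observations
#'   (see [callAlleles()]).
#' @return The same data.frame with `umi` replaced by the representative
#'   UMI of its cluster.
#' @export
clusterUmis <- function(observations) {
    if (nrow(observations) == 0L) return(observations)
    for (cell in unique(observations$cbc)) {
        i <- which(observations$cbc == cell)
        counts <- table(observations$umi[i])
        map <- .clusterOneCell(names(counts), as.integer(counts))
        observations$umi[i] <- unname(map[observations$umi[i]])
    }
    observations
}

#' Collapse allele observations to per-UMI consensuses
#'
#' Within each (cell, UMI) group, `other` and `missing` observations are
#' dropped; the per-allele weight is the sum of `1 - 10^(-q/10)` over its
#' supporting reads and the consensus is the allele with the larger weight.
#' Groups with an exact weight tie, or with no ref/alt evidence, are
#' discarded. The consensus error probability is the product of `10^(-q/10)`
#' over the consensus-supporting reads (independent errors), floored at
#' `model@epsilonFloor`.
#'
#' @param observations data.frame of allele observations.
#' @param model A [GenotypeModel] (supplies `epsilonFloor`).
#' @return data.frame with columns `cbc`, `umi`, `allele` (`"ref"`/`"alt"`),
#'   `n_reads` (reads supporting the consensus allele) and `epsilon_umi`.
#' @export
collapseUmis <- function(observations, model = GenotypeModel()) {
    empty <- data.frame(cbc = character(), umi = character(),
                        allele = character(), n_reads = integer(),
                        epsilon_umi = numeric(), stringsAsFactors = FALSE)
    obs <- observations[observations$allele %in% c("ref", "alt") &
                        !is.na(observations$base_quality), , drop = FALSE]
    if (nrow(obs) == 0L) return(empty)
    key <- paste(obs$cbc, obs$umi, sep = "\r")
    groups <- split(seq_len(nrow(obs)), key)
    rows <- lapply(groups, function(i) {
        al <- obs$allele[i]
        perr <- phredToErr(obs$base_quality[i])
        wRef <- sum((1 - perr)[al == "ref"])
        wAlt <- sum((1 - perr)[al == "alt"])
        if (wRef == wAlt) return(NULL)  # tie
        cons <- if (wRef > wAlt) "ref" else "alt"
        supp <- al == cons
        data.frame(cbc = obs$cbc[i][1], umi = obs$umi[i][1], allele = cons,
                   n_reads = sum(supp),
                   epsilon_umi = max(model@epsilonFloor, prod(perr[supp])),
                   stringsAsFactors = FALSE)
    })
    rows <- rows[!vapply(rows, is.null, logical(1))]
    if (length(rows) == 0L) return(empty)
    out <- do.call(rbind, rows)
    out <- out[order(out$cbc, out$umi), , drop = FALSE]
    rownames(out) <- NULL
    out
}

#' High-specificity filter: require Illumina UMI support
#'
#' Keeps a UMI consensus only when an exact (cbc, umi, gene) row for the
#' target's gene exists in the matched Illumina tag table. UMI matching is
#' exact (0 edits): the filter exists to maximize specificity.
#'
#' @param consensuses data.frame from [collapseUmis()].
#' @param tags Illumina tag table from [loadIlluminaTags()].
#' @param gene Gene symbol of the target.
#' @return The retained subset of `consensuses`.
#' @export
filterHighSpecificity <- function(consensuses, tags, gene) {
    tg <- tags[tags$gene == gene, , drop = FALSE]
    if (nrow(tg) == 0L) {
        warning("no Illumina tag rows for gene ", gene,
                "; high-specificity filter removes all consensuses")
        return(consensuses[0, , drop = FALSE])
    }
    keep <- paste(consensuses$cbc, consensuses$umi) %in%
        paste(tg$cbc, tg$umi)
    consensuses[keep, , drop = FALSE]
}

# Log-space Bayesian posterior for one cell given per-UMI alleles/epsilons
.posteriorHet <- function(alleles, eps, model) {
    isAlt <- alleles == "alt"
    pAltHet <- model@beta * (1 - eps) + (1 - model@beta) * eps
    lRef <- sum(log(ifelse(isAlt, eps, 1 - eps)))
    lHet <- sum(log(ifelse(isAlt, pAltHet, 1 - pAltHet)))
    if (model@piMut == 0) return(0)
    if (model@piMut == 1) return(1)
    a <- log(model@piMut) + lHet
    b <- log(1 - model@piMut) + lRef
    m <- max(a, b)
    exp(a - m) / (exp(a - m) + exp(b - m))
}

#' Genotype one cell from its UMI consensuses
#'
#' Bayesian two-state genotyper. Under ref-hom each UMI consensus is alt
#' with its error probability epsilon; under het-mut it is alt with
#' probability `beta*(1-eps) + (1-beta)*eps`. The het posterior follows from
#' Bayes' rule with prior `piMut`. A `mut` call requires posterior >= `tau`;
#' a `ref` call requires `1 - posterior >= tau` and at least
#' `minUmisRefCall` ref-supporting consensuses (allelic-dropout guard);
#' anything else is `no-call`.
#'
#' @param consensuses data.frame of UMI consensuses for a single cell.
#' @param model A [GenotypeModel].
#' @return One-row data.frame: `cbc`, `n_umi_ref`, `n_umi_alt`,
#'   `posterior_het`, `call`, `mode`.
#' @export
genotypeCell <- function(consensuses, model = GenotypeModel()) {
    stopifnot(nrow(consensuses) >= 1L,
              length(unique(consensuses$cbc)) == 1L)
    post <- .posteriorHet(consensuses$allele, consensuses$epsilon_umi, model)
    nRef <- sum(consensuses$allele == "ref")
    nAlt <- sum(consensuses$allele == "alt")
    call <- "no-call"
    if (post >= model@tau) call <- "mut"
    else if ((1 - post) >= model@tau && nRef >= model@minUmisRefCall)
        call <- "ref"
    data.frame(cbc = consensuses$cbc[1], n_umi_ref = nRef, n_umi_alt = nAlt,
               posterior_het = post, call = call, mode = model@mode,
               stringsAsFactors = FALSE)
}

#' Genotype every cell in a consensus table
#'
#' Applies the high-specificity filter when the model mode requires it,
#' then calls [genotypeCell()] per cell. Cells with no surviving consensus
#' are absent from the output.
#'
#' @param consensuses data.frame from [collapseUmis()].
#' @param model A [GenotypeModel].
#' @param tags Illumina tag table; required when
#'   `model@mode == "high_specificity"`.
#' @param gene Gene symbol of the target (for the high-specificity filter).
#' @return data.frame of per-cell genotypes, sorted by `cbc`.
#' @export
genotypeCells <- function(consensuses, model = GenotypeModel(),
                          tags = NULL, gene = NULL) {
    if (model@mode == "high_specificity") {
        if (is.null(tags) || is.null(gene))
            stop("high_specificity mode needs the Illumina tag table and gene")
        consensuses <- filterHighSpecificity(consensuses, tags, gene)
    }
    if (nrow(consensuses) == 0L)
        return(data.frame(cbc = character(), n_umi_ref = integer(),
                          n_umi_alt = integer(), posterior_het = numeric(),
                          call = character(), mode = character(),
                          stringsAsFactors = FALSE))
    out <- do.call(rbind, lapply(split(consensuses, consensuses$cbc),
                                 genotypeCell, model = model))
    out <- out[order(out$cbc), , drop = FALSE]
    rownames(out) <- NULL
    out
}
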