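#' Tabulate per-cell genotypes by cell type
#'
#' Joins per-cell genotype calls with the cell-type annotation and counts
#' ref / mut / no-call cells per type. Genotyped barcodes absent from the
#' annotation are tallied under `"unannotated"`.
#'
#' @param genotypes data.frame from [genotypeCells()]; one row per cell.
#' @param annotation data.frame with columns `cbc`, `cell_type`
#'   (see [readCellAnnotation()]).
#' @return data.frame with columns `cell_type`, `n_ref`, `n_mut`,
#'   `n_no_call`, `n_genotyped` (ref + mut), `mut_fraction` (percent,
#'   `NA` when nothing was genotyped), sorted by `cell_type`.
#' @export
tabulateGenotypes <- function(genotypes, annotation) {
    if (anyDuplicated(genotypes$cbc))
        stop("duplicate cell barcode in genotype table")
    type <- annotation$cell_type[match(genotypes$cbc, annotation$cbc)]
    type[is.na(type)] <- "unannotated"
    lev <- sort(unique(c(type, annotation$cell_type)))
    tab <- table(factor(type, levels = lev),
                 factor(genotypes$call, levels = c("ref", "mut", "no-call")))
    out <- data.frame(cell_type = lev,
                      n_ref = as.integer(tab[, "ref"]),
                      n_mut = as.integer(tab[, "mut"]),
                      n_no_call = as.integer(tab[, "no-call"]),
                      stringsAsFactors = FALSE)
    out$n_genotyped <- out$n_ref + out$n_mut
    out$mut_fraction <- mutFraction(out$n_mut, out$n_ref)
    rownames(out) <- NULL
    out
}

#' Mutant-cell fraction
#'
#' Percentage of genotyped cells (ref plus mut) that are mut, reported to
#' one decimal place. A zero denominator yields `NA`.
#'
#' @param kMut Number of mut cells.
#' @param nRef Number of ref cells.
#' @return Numeric vector of percentages.
#' @export
mutFraction <- function(kMut, nRef) {
    denom <- kMut + nRef
    ifelse(denom > 0, round(100 * kMut / denom, 1), NA_real_)
}

#' Per-cell-type mutant enrichment test
#'
#' Normalizes mut counts by the number of genotyped cells per type (to
#' control for differential genotyping efficiency among cell types) and
#' tests each type for enrichment of mut cells with an upper-tail
#' hypergeometric test: with `N` genotyped cells overall of which `K` are
#' mut, the p-value for a type with `n` genotyped and `k` mut cells is
#' `P(X >= k)` for `X ~ Hypergeometric(N, K, n)` (the observed `k` is
#' included in the tail). P-values are Benjamini-Hochberg adjusted across
#' the tested types.
#'
#' @param counts data.frame with columns `cell_type`, `n_genotyped`,
#'   `n_mut` (such as the output of [tabulateGenotypes()]).
#' @param restrictToVariantCarrying If `TRUE` (default), types with zero
#'   mut cells are excluded before forming the population totals, so each
#'   type is compared against the other variant-carrying types only.
#' @return data.frame with columns `cell_type`, `n_genotyped`, `k_mut`,
#'   `mut_fraction`, `p_raw`, `p_adj`, sorted by `p_raw`; the population
#'   totals are attached as attributes `N` and `K`.
#' @export
enrichmentTest <- function(counts, restrictToVariantCarrying = TRUE) {
    stopifnot(all(c("cell_type", "n_genotyped", "n_mut") %in% names(counts)))
    tab <- counts[counts$n_genotyped > 0, , drop = FALSE]
    if (restrictToVariantCarrying)
        tab <- tab[tab$n_mut > 0, , drop = FALSE]
    N <- sum(tab$n_genotyped)
    K <- sum(tab$n_mut)
    if (nrow(tab) == 1L)
        warning("only one tested cell type; enrichment p-value is 1 by construction")
    pRaw <- stats::phyper(tab$n_mut - 1, K, N - K, tab$n_genotyped,
                          lower.tail = FALSE)
    out <- data.frame(cell_type = tab$cell_type,
                      n_genotyped = tab$n_genotyped,
                      k_mut = tab$n_mut,
                      mut_fraction = mutFraction(tab$n_mut,
                                                 tab$n_genotyped - tab$n_mut),
                      p_raw = pRaw,
                      p_adj = stats::p.adjust(pRaw, method = "BH"),
                      stringsAsFactors = FALSE)
    out <- out[order(out$p_raw, out$cell_type), , drop = FALSE]
    rownames(out) <- NULL
    attr(out, "N") <- N
    attr(out, "K") <- K
    out
}

#' Genotyping-efficiency covariate regression
#'
#' Logistic regression of whether a cell was genotyped on its (log1p)
#' target-gene expression plus cell-type indicators. Gene expression is
#' expected to correlate positively with the probability of genotyping
#' (the method genotypes cDNA); cell-type effects flag types that are
#' preferentially captured or missed.
#'
#' @param cells data.frame with columns `genotyped` (logical),
#'   `log1p_expression` (numeric), `cell_type` (character/factor). At least
#'   two cell types and 50 cells are required.
#' @return data.frame with columns `term`, `estimate`, `std_error`, `z`,
#'   `p_value`; attribute `separation` is `TRUE` when the fit showed signs
#'   of perfect separation (coefficients then flagged unstable).
#' @export
genotypingEfficiencyQc <- function(cells) {
    stopifnot(all(c("genotyped", "log1p_expression", "cell_type") %in%
                  names(cells)))
    if (length(unique(cells$cell_type)) < 2L)
        stop("need at least two cell types")
    if (nrow(cells) < 50L)
        stop("need at least 50 cells")
    sep <- FALSE
    fit <- withCallingHandlers(
        stats::glm(genotyped ~ log1p_expression + cell_type,
                   family = stats::binomial(), data = cells),
        warning = function(w) {
            if (grepl("fitted probabilities numerically 0 or 1",
                      conditionMessage(w)))
                sep <<- TRUE
            invokeRestart("muffleWarning")
        })
    cf <- summary(fit)$coefficients
    if (any(abs(cf[, "Estimate"]) > 15) || !fit$converged) sep <- TRUE
    out <- data.frame(term = rownames(cf),
                      estimate = cf[, "Estimate"],
                      std_error = cf[, "Std. Error"],
                      z = cf[, "z value"],
                      p_value = cf[, "Pr(>|z|)"],
                      stringsAsFactors = FALSE)
    rownames(out) <- NULL
    attr(out, "separation") <- sep
    if (sep) warning("possible perfect separation; coefficients unstable")
    out
}

#' Pooled case-level genotyping summary
#'
#' Tallies genotyped / ref / mut cells and the mut fraction per case and
#' pooled over cases.
#'
#' @param perCase data.frame with columns `case`, `n_ref`, `n_mut` (one row
#'   per case).
#' @return data.frame with one row per case plus a `"pooled"` row, columns
#'   `case`, `n_genotyped`, `n_ref`, `n_mut`, `mut_fraction`.
#' @export
caseSummary <- function(perCase) {
    stopifnot(all(c("case", "n_ref", "n_mut") %in% names(perCase)))
    pooled <- data.frame(case = "pooled", n_ref = sum(perCase$n_ref),
                         n_mut = sum(perCase$n_mut),
                         stringsAsFactors = FALSE)
    out <- rbind(perCase[, c("case", "n_ref", "n_mut")], pooled)
    out$n_genotyped <- out$n_ref + out$n_mut
    out$mut_fraction <- mutFraction(out$n_mut, out$n_ref)
    out[, c("case", "n_genotyped", "n_ref", "n_mut", "mut_fraction")]
}
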