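#' @useDynLib goten, .registration = TRUE
#' @importFrom Rcpp sourceCpp
NULL

# Phred -> error probability
phredToErr <- function(q) 10^(-q / 10)

# Decode a Phred+33 quality string to integer scores
qualToInt <- function(qual) {
    lapply(qual, function(q) as.integer(charToRaw(q)) - 33L)
}

intToQual <- function(q) {
    vapply(q, function(x) rawToChar(as.raw(x + 33L)), character(1))
}

revcompStr <- function(x) {
    as.character(Biostrings::reverseComplement(Biostrings::DNAStringSet(x)))
}

reverseStr <- function(x) {
    vapply(strsplit(x, ""), function(ch) paste(rev(ch), collapse = ""),
           character(1))
}

randomDna <- function(n, len) {
    vapply(seq_len(n), function(i)
        paste(sample(c("A", "C", "G", "T"), len, replace = TRUE),
              collapse = ""), character(1))
}

# Preserve the caller's RNG state while running deterministic simulations
withSeed <- function(seed, expr) {
    has <- exists(".Random.seed", envir = globalenv(), inherits = FALSE)
    if (has) old <- get(".Random.seed", envir = globalenv())
    on.exit({
        if (has) assign(".Random.seed", old, envir = globalenv())
        else if (exists(".Random.seed", envir = globalenv(), inherits = FALSE))
            rm(".Random.seed", envir = globalenv())
    })
    set.seed(seed)
    force(expr)
}
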