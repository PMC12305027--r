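# Shared fixtures and independent oracles. Everything is built in code; the
# oracles deliberately use naive arithmetic/enumeration, independent of the
# package implementation.

# A small fixed target: 120 nt amplicon, variant at 0-based offset 60 (C>T)
testTarget <- function() {
    set.seed(4242)
    amp <- paste(sample(c("A", "C", "G", "T"), 120, replace = TRUE),
                 collapse = "")
    substr(amp, 61, 61) <- "C"
    VariantTarget("VAR1", "MTOR", amp, 60L, "C", "T",
                  genomicLabel = "synthetic")
}

testWhitelist <- function(n = 8, len = 16, seed = 11) {
    set.seed(seed)
    unique(vapply(seq_len(n * 2), function(i)
        paste(sample(c("A", "C", "G", "T"), len, replace = TRUE),
              collapse = ""), character(1)))[seq_len(n)]
}

revcomp <- function(x)
    as.character(Biostrings::reverseComplement(Biostrings::DNAStringSet(x)))

# Build a QualityScaledDNAStringSet from sequences + integer qualities
qsdss <- function(seqs, quals = NULL) {
    if (is.null(quals))
        quals <- lapply(nchar(seqs), function(n) rep(30L, n))
    qstr <- vapply(quals, function(q) rawToChar(as.raw(q + 33L)), character(1))
    if (is.null(names(seqs))) names(seqs) <- paste0("read", seq_along(seqs))
    Biostrings::QualityScaledDNAStringSet(
        Biostrings::DNAStringSet(seqs), Biostrings::PhredQuality(qstr))
}

# Observation-row builder for consensus tests
obsDf <- function(cbc, umi, allele, q) {
    data.frame(read_id = paste0("r", seq_along(allele)), cbc = cbc,
               umi = umi, allele = allele, base_quality = q,
               alignment_edits = 0L, stringsAsFactors = FALSE)
}

consDf <- function(alleles, eps, cbc = "CELL1") {
    data.frame(cbc = cbc, umi = sprintf("UMI%03d", seq_along(alleles)),
               allele = alleles, n_reads = 1L,
               epsilon_umi = rep_len(eps, length(alleles)),
               stringsAsFactors = FALSE)
}

phredToErrOracle <- function(q) 10^(-q / 10)

# Brute-force Bayes oracle: plain product arithmetic, no log-space
bayesOracle <- function(alleles, eps, beta = 0.5, piMut = 0.5) {
    eps <- rep_len(eps, length(alleles))
    pAltHet <- beta * (1 - eps) + (1 - beta) * eps
    lRef <- prod(ifelse(alleles == "alt", eps, 1 - eps))
    lHet <- prod(ifelse(alleles == "alt", pAltHet, 1 - pAltHet))
    c(het = piMut * lHet / (piMut * lHet + (1 - piMut) * lRef),
      refhom = (1 - piMut) * lRef / (piMut * lHet + (1 - piMut) * lRef))
}

# Exhaustive hypergeometric upper tail: enumerate every n-subset of N items
# of which K are successes, count subsets with >= k successes
hyperEnumOracle <- function(N, K, n, k) {
    subsets <- utils::combn(N, n)
    hits <- colSums(subsets <= K)  # items 1..K are the successes
    mean(hits >= k)
}

# Semi-global occurrence oracle: min edit distance of pattern over all
# substrings of the subject (Levenshtein via adist)
semiglobalOracle <- function(pattern, subject) {
    n <- nchar(subject); m <- nchar(pattern)
    best <- m
    for (i in seq_len(n)) {
        for (j in i:min(n, i + 2 * m)) {
            d <- as.integer(utils::adist(pattern, substr(subject, i, j)))
            if (d < best) best <- d
        }
    }
    best
}

# Uniform payload noise that never touches the variant column
noisyPayload <- function(amp, rate, protect) {
    ch <- strsplit(amp, "")[[1]]
    hit <- which(stats::runif(length(ch)) < rate)
    hit <- setdiff(hit, protect)
    for (i in hit)
        ch[i] <- sample(setdiff(c("A", "C", "G", "T"), ch[i]), 1)
    paste(ch, collapse = "")
}
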