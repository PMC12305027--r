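test_that("directional UMI merging follows the distance and count rules", {
    # two UMIs 3 edits apart stay separate
    o <- obsDf("C1", rep(c("AAAAAAAA", "AAATTTAA"), c(3, 2)),
               rep("ref", 5), 30L)
    m <- clusterUmis(o)
    expect_equal(sort(unique(m$umi)), c("AAAAAAAA", "AAATTTAA"))
    # a 1-edit neighbor with 1 read merges into the 10-read UMI
    o <- obsDf("C1", rep(c("AAAAAAAA", "AAAAAAAT"), c(10, 1)),
               rep("ref", 11), 30L)
    m <- clusterUmis(o)
    expect_equal(unique(m$umi), "AAAAAAAA")
    # equal 5/5 counts fail the 2n-1 condition
    o <- obsDf("C1", rep(c("AAAAAAAA", "AAAAAAAT"), c(5, 5)),
               rep("ref", 10), 30L)
    m <- clusterUmis(o)
    expect_equal(length(unique(m$umi)), 2L)
    # merging never crosses cells
    o <- obsDf(rep(c("C1", "C2"), c(10, 1)),
               rep(c("AAAAAAAA", "AAAAAAAT"), c(10, 1)),
               rep("ref", 11), 30L)
    m <- clusterUmis(o)
    expect_equal(m$umi[m$cbc == "C2"], "AAAAAAAT")
})

test_that("UMI consensus weighting, ties and error probabilities follow the model", {
    model <- GenotypeModel()
    # 3 ref reads -> ref consensus with n_reads 3
    cons <- collapseUmis(obsDf("C1", "U1", rep("ref", 3), 30L), model)
    expect_equal(cons$allele, "ref")
    expect_equal(cons$n_reads, 3L)
    # hand-computed weights: 2 ref @Q20 (2*0.99) vs 1 alt @Q10 (0.90)
    cons <- collapseUmis(obsDf("C1", "U1", c("ref", "ref", "alt"),
                               c(20L, 20L, 10L)), model)
    expect_equal(cons$allele, "ref")
    expect_equal(cons$n_reads, 2L)
    # epsilon: product of consensus-read error probs, floored
    expect_equal(cons$epsilon_umi, max(model@epsilonFloor, 0.01 * 0.01))
    # a single high-quality read keeps its own error probability
    cons <- collapseUmis(obsDf("C1", "U1", "alt", 17L), model)
    expect_equal(cons$epsilon_umi, phredToErrOracle(17))
    # exact tie -> discarded
    cons <- collapseUmis(obsDf("C1", "U1", c("ref", "alt"), c(20L, 20L)),
                         model)
    expect_equal(nrow(cons), 0L)
    # other/missing-only groups are never emitted
    o <- obsDf("C1", "U1", c("other", "missing"), c(30L, NA))
    expect_equal(nrow(collapseUmis(o, model)), 0L)
    # other reads don't contribute to either allele's weight
    cons <- collapseUmis(obsDf("C1", "U1", c("ref", "other", "other"),
                               c(10L, 40L, 40L)), model)
    expect_equal(cons$allele, "ref")
})

test_that("the high-specificity filter requires an exact Illumina triple", {
    cons <- data.frame(cbc = c("A", "A", "B"), umi = c("U1", "U2", "U1"),
                       allele = "ref", n_reads = 1L, epsilon_umi = 0.005,
                       stringsAsFactors = FALSE)
    tags <- data.frame(cbc = c("A", "C"), umi = c("U1", "U2"),
                       gene = "MTOR", count = 1L, stringsAsFactors = FALSE)
    kept <- filterHighSpecificity(cons, tags, "MTOR")
    expect_equal(nrow(kept), 1L)
    expect_equal(kept$cbc, "A")
    expect_equal(kept$umi, "U1")  # matching UMI under other cbc dropped
    expect_warning(none <- filterHighSpecificity(cons, tags, "PIK3CA"),
                   "PIK3CA")
    expect_equal(nrow(none), 0L)
})

test_that("the Bayesian genotyper matches direct evaluation on the worked cases", {
    model <- GenotypeModel(mode = "high_sensitivity")
    # 5 ref, 0 alt at eps 0.01: posterior 0.5^5 / (0.5^5 + 0.99^5)
    g <- genotypeCell(consDf(rep("ref", 5), 0.01), model)
    expect_equal(g$posterior_het, 0.5^5 / (0.5^5 + 0.99^5), tolerance = 1e-12)
    expect_equal(g$call, "ref")
    # 2 ref + 3 alt: overwhelmingly het
    g <- genotypeCell(consDf(c("ref", "ref", "alt", "alt", "alt"), 0.01),
                      model)
    expect_equal(g$posterior_het,
                 bayesOracle(c("ref", "ref", "alt", "alt", "alt"),
                             0.01)[["het"]], tolerance = 1e-12)
    expect_gt(g$posterior_het, 0.999)
    expect_equal(g$call, "mut")
    # single ref consensus: confident posterior but below the support floor
    g <- genotypeCell(consDf("ref", 0.01), model)
    expect_equal(g$call, "no-call")
    expect_equal(g$n_umi_ref, 1L)
})

test_that("posteriors are normalized and monotone in the evidence", {
    model <- GenotypeModel()
    set.seed(30)
    for (i in 1:40) {
        n <- sample(1:6, 1)
        al <- sample(c("ref", "alt"), n, replace = TRUE)
        eps <- sample(c(0.005, 0.01, 0.05), n, replace = TRUE)
        p <- bayesOracle(al, eps)
        expect_equal(p[["het"]] + p[["refhom"]], 1, tolerance = 1e-12)
        post <- genotypeCell(consDf(al, eps), model)$posterior_het
        expect_equal(post, p[["het"]], tolerance = 1e-10)
        # monotonicity under added evidence
        postAlt <- genotypeCell(consDf(c(al, "alt"), c(eps, 0.01)),
                                model)$posterior_het
        postRef <- genotypeCell(consDf(c(al, "ref"), c(eps, 0.01)),
                                model)$posterior_het
        expect_gte(postAlt, post - 1e-12)
        expect_lte(postRef, post + 1e-12)
    }
})

test_that("cells without consensuses are absent and calls respect thresholds", {
    model <- GenotypeModel(mode = "high_sensitivity", tau = 0.95)
    cons <- rbind(consDf(rep("ref", 6), 0.01, cbc = "CELLA"),
                  consDf(rep("alt", 3), 0.01, cbc = "CELLB"))
    g <- genotypeCells(cons, model)
    expect_equal(nrow(g), 2L)
    expect_equal(g$call[g$cbc == "CELLA"], "ref")
    expect_equal(g$call[g$cbc == "CELLB"], "mut")
    expect_true(all(g$posterior_het >= 0 & g$posterior_het <= 1))
    # empty input -> empty output, not an error
    expect_equal(nrow(genotypeCells(cons[0, ], model)), 0L)
})

test_that("high-specificity cells are a subset of high-sensitivity cells", {
    sim <- simulateCohort(SimulationConfig(nCells = 40L, captureProb = 0.6,
                                           seed = 31L))
    tg <- tagReads(sim$reads, sim$whitelist)
    ca <- callAlleles(tg$tags, sim$target)
    cons <- collapseUmis(clusterUmis(ca$observations))
    gSens <- genotypeCells(cons, GenotypeModel(mode = "high_sensitivity"))
    gSpec <- genotypeCells(cons, GenotypeModel(mode = "high_specificity"),
                           tags = sim$tags, gene = sim$target@gene)
    expect_true(all(gSpec$cbc %in% gSens$cbc))
    # identical surviving evidence must give identical calls
    surv <- filterHighSpecificity(cons, sim$tags, sim$target@gene)
    survCells <- names(which(table(surv$cbc) == table(cons$cbc)[names(table(surv$cbc))]))
    same <- intersect(survCells, gSpec$cbc)
    expect_equal(gSpec$call[match(same, gSpec$cbc)],
                 gSens$call[match(same, gSens$cbc)])
})
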