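.configError <- function(...) {
    stop(structure(class = c("goten_config_error", "error", "condition"),
                   list(message = paste0(...), call = NULL)))
}

.asTagConfig <- function(x) {
    if (is.null(x)) return(TagConfig())
    do.call(TagConfig, x[intersect(names(x), names(formals(TagConfig)))])
}

.asModel <- function(x, mode = NULL) {
    x <- if (is.null(x)) list() else
        x[intersect(names(x), names(formals(GenotypeModel)))]
    if (!is.null(mode)) x$mode <- mode
    do.call(GenotypeModel, x)
}

#' Run the full genotyping pipeline
#'
#' Orchestrates tag -> allele call -> UMI consensus -> per-cell genotype ->
#' per-cell-type enrichment over one variant target, writing stage tables
#' and a machine-readable run manifest (record counts in/out per stage,
#' rejection reasons, config hash, seed, tool version) to `outdir`. With a
#' `simulate:` block in the config the inputs are generated first with
#' [simulateCohort()].
#'
#' Config fields (YAML file or list): either `simulate:` (fields of
#' [SimulationConfig()]) or input paths `fastq`, `whitelist`, `targets`,
#' and optionally `tags` (required for high-specificity mode) and
#' `annotation`; plus optional `tag:` ([TagConfig()] fields), `model:`
#' ([GenotypeModel()] fields), `mode`, and `seed`.
#'
#' @param config Path to a YAML config or an equivalent named list.
#' @param outdir Output directory (created if needed).
#' @return Invisibly, a list with `status` (0 on success), `manifest`, and
#'   `outputs` (named file paths). Config/schema problems raise an error of
#'   class `goten_config_error` (the command-line driver maps it to exit
#'   status 2).
#' @export
runPipeline <- function(config, outdir) {
    configPath <- NULL
    if (is.character(config)) {
        configPath <- config
        if (!file.exists(config)) .configError("config not found: ", config)
        config <- yaml::read_yaml(config)
    }
    if (!is.list(config)) .configError("config must be a list or YAML path")
    if (!dir.exists(outdir)) dir.create(outdir, recursive = TRUE)

    manifest <- list(version = as.character(utils::packageVersion("goten")),
                     seed = config$seed, stages = list())
    if (!is.null(configPath))
        manifest$config_hash <- unname(tools::md5sum(configPath))

    tagCfg <- .asTagConfig(config$tag)
    mode <- if (is.null(config$mode)) "high_specificity" else config$mode
    if (!mode %in% c("high_specificity", "high_sensitivity"))
        .configError("mode must be high_specificity or high_sensitivity")
    model <- .asModel(config$model, mode)

    if (!is.null(config$simulate)) {
        simArgs <- config$simulate
        simArgs$cellTypeProbs <- unlist(simArgs$cellTypeProbs)
        simArgs$expressionRate <- unlist(simArgs$expressionRate)
        simArgs <- simArgs[!vapply(simArgs, is.null, logical(1))]
        if (!is.null(config$seed)) simArgs$seed <- config$seed
        simCfg <- do.call(SimulationConfig, simArgs)
        sim <- simulateCohort(simCfg, cfgTag = tagCfg,
                              dir = file.path(outdir, "sim"))
        config$fastq <- sim$files[["fastq"]]
        config$whitelist <- sim$files[["whitelist"]]
        config$tags <- sim$files[["tags"]]
        config$annotation <- sim$files[["annotation"]]
        config$targets <- sim$files[["targets"]]
        manifest$stages$simulate <- list(
            n_cells = simCfg@nCells, n_reads = length(sim$reads),
            outputs = as.list(sim$files))
    }

    for (f in c("fastq", "whitelist", "targets")) {
        if (is.null(config[[f]])) .configError("config lacks field: ", f)
        if (!file.exists(config[[f]]))
            .configError("missing ", f, " file: ", config[[f]])
    }
    if (mode == "high_specificity" && is.null(config$tags))
        .configError("high_specificity mode requires a 'tags' input")

    targets <- readVariantTargets(config$targets)
    if (length(targets) != 1L)
        .configError("exactly one variant target is supported per run")
    target <- targets[[1]]
    whitelist <- readWhitelist(config$whitelist)
    reads <- readFastqRecords(config$fastq)

    outputs <- c(tagged = file.path(outdir, "tagged.tsv"),
                 rejections = file.path(outdir, "rejections.tsv"),
                 alleles = file.path(outdir, "alleles.tsv"),
                 consensus = file.path(outdir, "consensus.tsv"),
                 genotypes = file.path(outdir, "genotypes.tsv"),
                 tabulation = file.path(outdir, "tabulation.tsv"),
                 enrichment = file.path(outdir, "enrichment.tsv"),
                 manifest = file.path(outdir, "manifest.json"))

    message("[tag] ", length(reads), " reads")
    tg <- tagReads(reads, whitelist, tagCfg)
    writeTable(tg$tags, outputs[["tagged"]], key = "read_id")
    rejSummary <- as.data.frame(table(reason = tg$rejections$reason),
                                stringsAsFactors = FALSE)
    names(rejSummary) <- c("reason", "count")
    writeTable(rejSummary, outputs[["rejections"]], key = "reason")
    manifest$stages$tag <- list(n_in = length(reads),
                                n_out = nrow(tg$tags),
                                rejections = as.list(tg$summary[-1]))

    message("[call] ", nrow(tg$tags), " tagged reads vs ", target@variantId)
    ca <- callAlleles(tg$tags, target)
    writeTable(ca$observations, outputs[["alleles"]], key = "read_id")
    manifest$stages$call <- list(n_in = nrow(tg$tags),
                                 n_out = nrow(ca$observations),
                                 n_unaligned = ca$nUnaligned)

    obs <- clusterUmis(ca$observations)
    cons <- collapseUmis(obs, model)
    writeTable(cons, outputs[["consensus"]], key = c("cbc", "umi"))
    tags <- if (!is.null(config$tags))
        loadIlluminaTags(config$tags, target@gene) else NULL
    geno <- genotypeCells(cons, model, tags = tags, gene = target@gene)
    writeTable(geno, outputs[["genotypes"]], key = "cbc")
    manifest$stages$genotype <- list(
        n_consensus = nrow(cons), n_cells = nrow(geno),
        n_ref = sum(geno$call == "ref"), n_mut = sum(geno$call == "mut"),
        n_no_call = sum(geno$call == "no-call"), mode = mode)

    if (!is.null(config$annotation)) {
        ann <- readCellAnnotation(config$annotation)
        tab <- tabulateGenotypes(geno, ann)
        writeTable(tab, outputs[["tabulation"]], key = "cell_type")
        enr <- tryCatch(enrichmentTest(tab[tab$cell_type != "unannotated", ]),
                        warning = function(w) {
                            suppressWarnings(enrichmentTest(
                                tab[tab$cell_type != "unannotated", ]))
                        })
        writeTable(enr, outputs[["enrichment"]],
                   key = c("p_raw", "cell_type"))
        manifest$stages$enrich <- list(
            n_types_tested = nrow(enr), N = attr(enr, "N"),
            K = attr(enr, "K"),
            n_significant = sum(enr$p_adj < 0.05))
    } else {
        outputs <- outputs[setdiff(names(outputs),
                                   c("tabulation", "enrichment"))]
    }

    manifest$conserved <-
        manifest$stages$tag$n_in ==
            manifest$stages$tag$n_out + nrow(tg$rejections) &&
        manifest$stages$call$n_in ==
            manifest$stages$call$n_out + ca$nUnaligned
    jsonlite::write_json(manifest, outputs[["manifest"]],
                         auto_unbox = TRUE, pretty = TRUE, digits = NA)
    invisible(list(status = 0L, manifest = manifest, outputs = outputs))
}
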