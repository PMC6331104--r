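#' Default pipeline configuration
#'
#' Flat list of every tunable the pipeline stages read. Values can be
#' overridden by a key=value config file ([readPipelineConfig()]) or by
#' the `...` arguments of [runStage()]/[runPipeline()].
#'
#' @return named list of defaults.
#' @export
defaultPipelineConfig <- function() {
  list(outdir = "toxrank_out", seed = 1L, system_label = "SYN",
       # synthetic panel
       n_genes = 2000L, n_compounds = 20L, n_toxic_compounds = 16L,
       n_planted = 100L, responsiveness = 0.6, effect_size = 2.0,
       noise_sd = 0.5, timepoints = "3,9,12,24", replicates = 3L,
       # literature simulation
       overlap_fraction = 1.0, universe_size = 20000L,
       # DE screen
       max_degree = 3L, global_fdr = 0.01, r2_min = 0.6,
       # BIRRA
       birra_bins = 50L, birra_max_iter = 10L, birra_prior = 0.05,
       # literature selection
       fdr_cut = 0.05, min_support = 3L,
       # evaluation
       methods = "MEAN,NC,RRA,STUART,BIRRA,AR", top_k = 400L)
}

#' Read a flat key=value pipeline configuration file
#'
#' Lines of the form `key = value`; blank lines and `#` comments are
#' ignored; unknown keys are rejected. Values are coerced to the type of
#' the corresponding default.
#'
#' @param path config file; `NULL` returns the defaults.
#' @param overrides named list applied after the file.
#' @return full configuration list.
#' @export
readPipelineConfig <- function(path = NULL, overrides = list()) {
  cfg <- defaultPipelineConfig()
  apply1 <- function(key, value) {
    if (!key %in% names(cfg))
      stop("unknown config key: ", key)
    proto <- cfg[[key]]
    cfg[[key]] <<- if (is.integer(proto)) as.integer(value)
    else if (is.numeric(proto)) as.numeric(value)
    else as.character(value)
  }
  if (!is.null(path)) {
    lines <- readLines(path)
    lines <- trimws(lines)
    lines <- lines[nzchar(lines) & !startsWith(lines, "#")]
    for (ln in lines) {
      kv <- strsplit(ln, "=", fixed = TRUE)[[1L]]
      if (length(kv) != 2L)
        stop("malformed config line: ", ln)
      apply1(trimws(kv[1L]), trimws(kv[2L]))
    }
  }
  for (key in names(overrides)) apply1(key, overrides[[key]])
  cfg
}

parseNumList <- function(x) as.numeric(strsplit(as.character(x), ",")[[1L]])
parseStrList <- function(x) trimws(strsplit(as.character(x), ",")[[1L]])

logCounts <- function(outdir, stage, ...) {
  kv <- list(...)
  df <- data.frame(stage = stage, key = names(kv),
                   value = as.character(unlist(kv)))
  path <- file.path(outdir, "pipeline_log.tsv")
  utils::write.table(df, path, sep = "\t", quote = FALSE,
                     row.names = FALSE, col.names = !file.exists(path),
                     append = file.exists(path))
  invisible(df)
}

stageSimulate <- function(cfg) {
  dir.create(cfg$outdir, showWarnings = FALSE, recursive = TRUE)
  logPath <- file.path(cfg$outdir, "pipeline_log.tsv")
  if (file.exists(logPath)) unlink(logPath)  # fresh log per run
  simCfg <- simulationConfig(
    nGenes = cfg$n_genes, nCompounds = cfg$n_compounds,
    nToxicCompounds = cfg$n_toxic_compounds, nPlanted = cfg$n_planted,
    responsiveness = cfg$responsiveness, effectSize = cfg$effect_size,
    noiseSD = cfg$noise_sd, timepoints = parseNumList(cfg$timepoints),
    replicates = cfg$replicates, seed = cfg$seed)
  sim <- simulatePanel(simCfg, system = cfg$system_label)
  for (cpd in names(sim$panels))
    writeExpressionPanel(sim$panels[[cpd]],
                         file.path(cfg$outdir,
                                   paste0("panel_", cpd, ".tsv")),
                         file.path(cfg$outdir,
                                   paste0("meta_", cpd, ".tsv")))
  writeLines(sim$truth$planted, file.path(cfg$outdir, "planted_genes.txt"))
  lit <- simulateLiterature(sim$truth,
                            overlapFraction = cfg$overlap_fraction,
                            universeSize = cfg$universe_size,
                            seed = cfg$seed + 1000L)
  writeGeneAbstractMap(lit$geneAbstracts,
                       file.path(cfg$outdir, "gene2abstract.tsv"))
  writeTopicSet(lit$topic, file.path(cfg$outdir, "topic_abstracts.txt"))
  writeLines(as.character(lit$universeSize),
             file.path(cfg$outdir, "abstract_universe_size.txt"))
  # synthetic genes are their own one-to-one orthologs across two taxa
  genes <- sim$truth$genes
  hom <- data.frame(group_id = seq_along(genes),
                    taxon_id = rep(c("9606", "10116"), each = length(genes)),
                    gene_id = c(genes, genes))
  hom <- hom[order(hom$group_id, hom$taxon_id), ]
  writeHomologTable(hom, file.path(cfg$outdir, "homologs.tsv"))
  logCounts(cfg$outdir, "simulate", n_genes = length(genes),
            n_compounds = length(sim$panels),
            n_planted = length(sim$truth$planted))
  invisible(sim)
}

stageDE <- function(cfg) {
  panels <- list.files(cfg$outdir, pattern = "^panel_.*\\.tsv$")
  if (!length(panels)) stop("no panel files found in ", cfg$outdir)
  params <- deParams(maxDegree = cfg$max_degree,
                     globalFDR = cfg$global_fdr, r2Min = cfg$r2_min)
  for (pf in panels) {
    cpd <- sub("^panel_(.*)\\.tsv$", "\\1", pf)
    panel <- readExpressionPanel(file.path(cfg$outdir, pf),
                                 file.path(cfg$outdir,
                                           paste0("meta_", cpd, ".tsv")))
    de <- deAnalysis(panel, params = params)
    writeDEResults(de, file.path(cfg$outdir, paste0("de_", cpd, ".tsv")))
    logCounts(cfg$outdir, "de", compound = cpd,
              n_selected = sum(de$selected))
  }
  invisible(NULL)
}

stageRank <- function(cfg) {
  deFiles <- list.files(cfg$outdir, pattern = "^de_.*\\.tsv$")
  if (!length(deFiles)) stop("no DE result files found in ", cfg$outdir)
  for (df in deFiles) {
    cpd <- sub("^de_(.*)\\.tsv$", "\\1", df)
    de <- readDEResults(file.path(cfg$outdir, df))
    rl <- rankCompound(de)
    writeRankedList(rl, file.path(cfg$outdir,
                                  paste0("ranked_", cpd, ".tsv")))
    logCounts(cfg$outdir, "rank", compound = cpd,
              n_modulated = length(modulated(rl)))
  }
  invisible(NULL)
}

stageAggregate <- function(cfg) {
  files <- list.files(cfg$outdir, pattern = "^ranked_.*\\.tsv$")
  if (!length(files)) stop("no ranked-list files found in ", cfg$outdir)
  lists <- lapply(file.path(cfg$outdir, files), readRankedList)
  names(lists) <- sub("^ranked_(.*)\\.tsv$", "\\1", files)
  methods <- parseStrList(cfg$methods)
  res <- aggregateAll(lists,
                      birra = birraParams(bins = cfg$birra_bins,
                                          maxIter = cfg$birra_max_iter,
                                          prior = cfg$birra_prior))
  miss <- setdiff(methods, names(res))
  if (length(miss)) stop("unknown aggregation method(s): ",
                         paste(miss, collapse = ", "))
  res <- res[methods]
  for (nm in names(res))
    writeRanking(res[[nm]],
                 file.path(cfg$outdir, paste0("aggregated_", nm, ".tsv")))
  writeCombinedRankings(res, file.path(cfg$outdir, "rankings_wide.tsv"))
  logCounts(cfg$outdir, "aggregate", n_lists = length(lists),
            n_methods = length(res))
  invisible(res)
}

stageLiterature <- function(cfg) {
  map <- readGeneAbstractMap(file.path(cfg$outdir, "gene2abstract.tsv"))
  topic <- readTopicSet(file.path(cfg$outdir, "topic_abstracts.txt"))
  uni <- as.integer(readLines(file.path(cfg$outdir,
                                        "abstract_universe_size.txt"))[1L])
  assoc <- geneTopicAssociation(map, topic, uni)
  homPath <- file.path(cfg$outdir, "homologs.tsv")
  pairs <- if (file.exists(homPath))
    oneToOneOrthologs(readHomologTable(homPath), "9606", "10116")
  else NULL
  cand <- selectCandidates(assoc, fdrCut = cfg$fdr_cut,
                           minSupport = cfg$min_support, pairs = pairs)
  writeCandidates(cand, file.path(cfg$outdir, "candidates.tsv"))
  logCounts(cfg$outdir, "literature", n_tested = nrow(cand),
            n_selected = sum(cand$selected))
  invisible(cand)
}

stageEvaluate <- function(cfg) {
  cand <- utils::read.delim(file.path(cfg$outdir, "candidates.tsv"),
                            colClasses = c(gene_id = "character"))
  positives <- cand$gene_id[cand$selected == 1L]
  if (!length(positives))
    stop("no literature candidates selected; cannot evaluate")
  methods <- parseStrList(cfg$methods)
  aucs <- data.frame(method = character(0), auc = numeric(0))
  for (nm in methods) {
    path <- file.path(cfg$outdir, paste0("aggregated_", nm, ".tsv"))
    if (!file.exists(path)) stop("missing aggregated ranking: ", nm)
    r <- readRanking(path, method = nm)
    roc <- rocAuc(r, intersect(positives, geneIds(r)))
    writeRoc(roc, file.path(cfg$outdir, paste0("roc_", nm, ".tsv")))
    aucs <- rbind(aucs, data.frame(method = nm, auc = roc$auc))
  }
  out <- aucs
  out$auc <- format(out$auc, digits = 15, trim = TRUE)
  utils::write.table(out, file.path(cfg$outdir, "auc_summary.tsv"),
                     sep = "\t", quote = FALSE, row.names = FALSE)
  logCounts(cfg$outdir, "evaluate", n_positives = length(positives))
  invisible(aucs)
}

stageCombine <- function(cfg) {
  arPath <- file.path(cfg$outdir, "aggregated_AR.tsv")
  if (!file.exists(arPath)) stop("missing AR ranking for combine stage")
  ar <- readRanking(arPath, method = "AR")
  comb <- combineSum(list(ar))
  k <- min(cfg$top_k, universeSize(ar))
  top <- topK(comb, k)
  df <- data.frame(gene_id = names(sort(comb$rank)),
                   score = format(comb$score[names(sort(comb$rank))],
                                  digits = 15, trim = TRUE),
                   rank = format(sort(comb$rank), digits = 15,
                                 trim = TRUE))
  utils::write.table(df, file.path(cfg$outdir, "combined_sum.tsv"),
                     sep = "\t", quote = FALSE, row.names = FALSE)
  writeLines(top, file.path(cfg$outdir,
                            sprintf("top_%d_genes.txt", k)))
  logCounts(cfg$outdir, "combine",
            top_k_realized = attr(top, "realizedSize"))
  invisible(comb)
}

#' Run one pipeline stage
#'
#' Stages communicate exclusively through TSV files under `outdir`, so any
#' stage can be re-run standalone from the artifacts of the previous one.
#'
#' @param stage one of `"simulate"`, `"de"`, `"rank"`, `"aggregate"`,
#'   `"literature"`, `"evaluate"`, `"combine"`, `"all"`.
#' @param config configuration list from [readPipelineConfig()], or `NULL`
#'   for the defaults.
#' @param ... key=value overrides applied on top of `config`.
#' @return the stage's main in-memory product, invisibly.
#' @export
runStage <- function(stage, config = NULL, ...) {
  stages <- c("simulate", "de", "rank", "aggregate", "literature",
              "evaluate", "combine")
  stage <- match.arg(stage, c(stages, "all"))
  cfg <- if (is.null(config)) defaultPipelineConfig() else config
  overrides <- list(...)
  if (length(overrides))
    cfg <- readPipelineConfig(NULL, utils::modifyList(cfg, overrides))
  if (stage == "all") {
    for (s in stages) runStage(s, cfg)
    return(invisible(cfg))
  }
  fn <- switch(stage, simulate = stageSimulate, de = stageDE,
               rank = stageRank, aggregate = stageAggregate,
               literature = stageLiterature, evaluate = stageEvaluate,
               combine = stageCombine)
  fn(cfg)
}

#' Run the full pipeline (simulate through combine)
#'
#' @param config configuration list, or `NULL` for the defaults.
#' @param ... key=value overrides.
#' @return the configuration used, invisibly.
#' @export
runPipeline <- function(config = NULL, ...) {
  runStage("all", config, ...)
}
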