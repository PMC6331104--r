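#' Configuration for the synthetic toxicogenomics panel generator
#'
#' Defines the study conditions emulated by [simulatePanel()]: a
#' multi-compound single-dose design with four dose groups
#' (control/low/middle/high), several post-administration timepoints and
#' replicated samples, in which a planted subset of genes responds to a
#' subset of "toxic" compounds with a dose- and time-dependent log2 shift.
#'
#' @param nGenes number of genes in the universe.
#' @param nCompounds number of compounds in the panel.
#' @param nToxicCompounds number of compounds carrying planted signal; the
#'   remainder are signal-free, mirroring the tolerated presence of
#'   non-toxic compounds in a real panel.
#' @param nPlanted number of toxicity-responsive genes.
#' @param responsiveness probability that a planted gene responds in a
#'   given toxic compound.
#' @param effectSize maximal log2 shift, reached at high dose and the
#'   latest timepoint.
#' @param noiseSD residual standard deviation (log2 units).
#' @param timepoints measurement times in hours.
#' @param replicates biological replicates per dose x time group.
#' @param seed integer seed making the panel reproducible.
#' @return a validated `SimulationConfig` list.
#' @export
simulationConfig <- function(nGenes = 2000L, nCompounds = 20L,
                             nToxicCompounds = 16L, nPlanted = 100L,
                             responsiveness = 0.6, effectSize = 2.0,
                             noiseSD = 0.5,
                             timepoints = c(3, 9, 12, 24),
                             replicates = 3L, seed = 1L) {
  cfg <- list(nGenes = as.integer(nGenes),
              nCompounds = as.integer(nCompounds),
              nToxicCompounds = as.integer(nToxicCompounds),
              nPlanted = as.integer(nPlanted),
              responsiveness = responsiveness, effectSize = effectSize,
              noiseSD = noiseSD, timepoints = as.numeric(timepoints),
              replicates = as.integer(replicates), seed = as.integer(seed))
  if (cfg$nPlanted > cfg$nGenes)
    stop("nPlanted must not exceed nGenes")
  if (cfg$nToxicCompounds > cfg$nCompounds)
    stop("nToxicCompounds must not exceed nCompounds")
  if (cfg$responsiveness < 0 || cfg$responsiveness > 1)
    stop("responsiveness must lie in [0, 1]")
  if (length(cfg$timepoints) < 2L)
    stop("at least two timepoints are required")
  if (cfg$replicates < 1L)
    stop("at least one replicate is required")
  if (cfg$noiseSD < 0 || cfg$effectSize < 0)
    stop("effectSize and noiseSD must be non-negative")
  class(cfg) <- "SimulationConfig"
  cfg
}

doseWeights <- c(control = 0, low = 1 / 3, middle = 2 / 3, high = 1)

# monotone saturating time response scaled to [0, 1] over the observed
# span; the rate constant tmax/8 makes a single-dose transcriptional
# response largely established by the earliest measurement, as is typical
# for acute exposures
timeProfile <- function(time, tmax) {
  (1 - exp(-8 * time / tmax)) / (1 - exp(-8))
}

#' Simulate a multi-compound expression panel with planted toxicity signal
#'
#' Generates one [ExpressionPanel-class] per compound under the design in
#' `cfg`. Non-responsive genes are baseline plus Gaussian noise; responsive
#' genes in toxic compounds additionally shift by
#' `effectSize * doseWeight(dose) * g(time)` with dose weights
#' (0, 1/3, 2/3, 1) and a monotone saturating time profile `g` scaled to
#' `[0, 1]`. Identical seeds give identical panels.
#'
#' @param cfg a [simulationConfig()] object.
#' @param system model-system label stamped on all samples.
#' @return list with elements `panels` (named list of
#'   [ExpressionPanel-class], one per compound) and `truth` (the ground
#'   truth: planted genes, per-compound responsive subsets, effect signs,
#'   toxic compound labels, gene universe).
#' @export
simulatePanel <- function(cfg, system = "SYN") {
  stopifnot(inherits(cfg, "SimulationConfig"))
  set.seed(cfg$seed)
  genes <- sprintf("g%0*d", nchar(cfg$nGenes), seq_len(cfg$nGenes))
  compounds <- sprintf("cpd%02d", seq_len(cfg$nCompounds))
  toxic <- compounds[seq_len(cfg$nToxicCompounds)]
  planted <- sort(sample(genes, cfg$nPlanted))
  baseline <- stats::runif(cfg$nGenes, 4, 12)
  names(baseline) <- genes

  grid <- expand.grid(dose = doseLevels, time = cfg$timepoints,
                      replicate = seq_len(cfg$replicates),
                      KEEP.OUT.ATTRS = FALSE, stringsAsFactors = FALSE)
  tmax <- max(cfg$timepoints)

  responsive <- stats::setNames(vector("list", cfg$nCompounds), compounds)
  signs <- stats::setNames(vector("list", cfg$nCompounds), compounds)
  panels <- stats::setNames(vector("list", cfg$nCompounds), compounds)

  for (cpd in compounds) {
    if (cpd %in% toxic) {
      hit <- planted[stats::runif(cfg$nPlanted) < cfg$responsiveness]
    } else {
      hit <- character(0)
    }
    responsive[[cpd]] <- hit
    sgn <- stats::setNames(sample(c(-1, 1), length(hit), replace = TRUE), hit)
    signs[[cpd]] <- sgn

    shift <- cfg$effectSize * doseWeights[grid$dose] *
      timeProfile(grid$time, tmax)
    m <- matrix(baseline, nrow = cfg$nGenes, ncol = nrow(grid),
                dimnames = list(genes, NULL))
    if (length(hit))
      m[hit, ] <- m[hit, ] + outer(sgn, shift)
    m <- m + matrix(stats::rnorm(length(m), 0, cfg$noiseSD),
                    nrow = cfg$nGenes)
    sampleIds <- sprintf("%s_%s_t%g_r%d", cpd, grid$dose, grid$time,
                         grid$replicate)
    colnames(m) <- sampleIds
    meta <- data.frame(sample_id = sampleIds, compound = cpd,
                       dose = grid$dose, time = grid$time,
                       replicate = grid$replicate, system = system)
    panels[[cpd]] <- ExpressionPanel(m, meta)
  }

  truth <- list(genes = genes, planted = planted, responsive = responsive,
                signs = signs, toxicCompounds = toxic,
                effectSize = cfg$effectSize)
  class(truth) <- "GroundTruth"
  list(panels = panels, truth = truth)
}

#' Simulate literature annotations enriched for planted genes
#'
#' Builds a gene-to-abstract map, a topic abstract set and an abstract
#' universe in which a fraction `overlapFraction` of the planted genes is
#' supported by at least three topic-linked abstracts, while the remaining
#' genes draw their abstracts at the background topic rate. Abstract ids
#' are drawn without replacement per gene from the universe.
#'
#' @param truth a `GroundTruth` from [simulatePanel()].
#' @param overlapFraction fraction of planted genes receiving topic
#'   support, in `[0, 1]`.
#' @param universeSize total number of abstracts in the background.
#' @param seed integer seed.
#' @param topicSize number of abstracts in the topic set.
#' @param abstractsPerGene integer range (min, max) of background abstracts
#'   per gene.
#' @param backgroundTopicRate probability that a background abstract is
#'   drawn from the topic set; `NULL` (default) draws uniformly from the
#'   whole universe, i.e. rate `topicSize / universeSize`; `0` keeps
#'   background genes strictly off-topic.
#' @return list with `geneAbstracts` (named list gene -> abstract ids),
#'   `topic` (character vector of abstract ids) and `universeSize`.
#' @export
simulateLiterature <- function(truth, overlapFraction = 1,
                               universeSize = 20000L, seed = 1L,
                               topicSize = max(10L,
                                               round(0.02 * universeSize)),
                               abstractsPerGene = c(2L, 8L),
                               backgroundTopicRate = NULL) {
  stopifnot(inherits(truth, "GroundTruth"))
  if (overlapFraction < 0 || overlapFraction > 1)
    stop("overlapFraction must lie in [0, 1]")
  if (topicSize + 6L > universeSize)
    stop("universe too small for the requested topic size")
  if (max(abstractsPerGene) + 6L > universeSize)
    stop("universe too small for the requested abstracts per gene")
  set.seed(seed)
  universe <- as.character(seq_len(universeSize))
  topic <- sample(universe, topicSize)
  offTopic <- setdiff(universe, topic)

  genes <- truth$genes
  supported <- truth$planted[
    seq_len(round(overlapFraction * length(truth$planted)))]
  nBg <- sample(seq(abstractsPerGene[1L], abstractsPerGene[2L]),
                length(genes), replace = TRUE)
  names(nBg) <- genes

  geneAbstracts <- lapply(genes, function(g) {
    if (is.null(backgroundTopicRate)) {
      bg <- sample(universe, nBg[[g]])
    } else {
      fromTopic <- stats::runif(nBg[[g]]) < backgroundTopicRate
      bg <- c(if (any(fromTopic)) sample(topic, sum(fromTopic)),
              sample(offTopic, sum(!fromTopic)))
    }
    if (g %in% supported)
      bg <- c(bg, sample(topic, sample(3:6, 1L)))
    unique(bg)
  })
  names(geneAbstracts) <- genes
  list(geneAbstracts = geneAbstracts, topic = topic,
       universeSize = as.integer(universeSize))
}
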