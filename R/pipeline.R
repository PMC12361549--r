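## End-to-end orchestration of the synthetic-study pipeline.
##
## One configuration drives generation -> QC -> summarization ->
## differential expression -> trajectory clustering -> cross-organ overlap
## -> mixed-model divergence -> network hubs -> targeted-MS quantitation,
## with per-stage outputs, derived per-stage seeds, and a machine-readable
## manifest (parameters, seeds, input checksums, record counts) that makes
## a run reproducible bit for bit.

#' Default pipeline configuration
#'
#' Returns the configuration list consumed by [runPipeline()].  The
#' `simulate` block is passed to [syntheticConfig()]; stage blocks carry
#' the parameters of the corresponding stage functions.  `stages` selects
#' the enabled subset in pipeline order.
#'
#' @param seed global run seed, fanned out to per-stage seeds by a fixed
#'   counter scheme.
#' @return nested configuration list.
#' @export
defaultPipelineConfig <- function(seed = 1L) {
  list(
    seed = as.integer(seed),
    stages = c("simulate", "qc", "summarize", "diffexp", "trajectory",
               "cross_organ", "lmm", "hubs", "surequant"),
    simulate = list(organs = c("kidney", "spleen", "liver", "lung"),
                    nProteins = 150L),
    summarize = list(impute = "knn", minObsFrac = 0.5),
    diffexp = list(alpha = 0.05, groupA = "20", groupB = "3"),
    trajectory = list(clusters = "auto", minDeps = 10L),
    cross_organ = list(),
    lmm = list(alpha = 0.05, pThreshold = 0.05, maxProteins = 100L),
    hubs = list(top = 10L, scoreThreshold = 400, cliqueSize = 6L,
                noiseEdges = 40L),
    surequant = list(referenceAge = 3, nPeptides = 12L, cv = 0.1))
}

#' Load a pipeline configuration from YAML
#'
#' Reads a YAML file and merges it over [defaultPipelineConfig()] (scalar
#' fields override; stage blocks merge field-wise).
#'
#' @param path YAML file.
#' @return configuration list.
#' @export
loadPipelineConfig <- function(path) {
  user <- yaml::read_yaml(path)
  cfg <- defaultPipelineConfig(user$seed %||% 1L)
  for (nm in names(user)) {
    if (is.list(user[[nm]]) && is.list(cfg[[nm]]))
      cfg[[nm]] <- utils::modifyList(cfg[[nm]], user[[nm]])
    else cfg[[nm]] <- user[[nm]]
  }
  cfg
}

#' Run the pipeline end to end
#'
#' Executes the enabled stages in order on a freshly generated synthetic
#' study, writing each stage's outputs beneath `outDir` and a `manifest.json`
#' recording parameters, derived seeds, per-stage record counts and MD5
#' checksums of every written file.  Identical configuration and seed give
#' identical outputs.  Disabled upstream stages make dependent stages fail
#' fast with a dependency error.
#'
#' @param config configuration list (see [defaultPipelineConfig()]) or a
#'   YAML path.
#' @param outDir output directory, created if needed.
#' @return invisibly, the manifest list.
#' @export
runPipeline <- function(config = defaultPipelineConfig(), outDir) {
  if (is.character(config)) config <- loadPipelineConfig(config)
  dir.create(outDir, showWarnings = FALSE, recursive = TRUE)
  stages <- config$stages
  manifest <- list(seed = config$seed, stages = stages,
                   parameters = config, counts = list())
  state <- new.env(parent = emptyenv())

  .need <- function(what, from) {
    if (is.null(state[[what]]))
      stop("stage '", from, "' requires output of a disabled upstream ",
           "stage ('", what, "')")
  }
  .stage <- function(name, fun) {
    if (!name %in% stages) return(invisible(NULL))
    tryCatch(fun(), error = function(e) {
      manifest$failed_stage <<- name
      .writeJSON(manifest, file.path(outDir, "manifest.json"))
      stop("pipeline stage '", name, "' failed: ", conditionMessage(e),
           call. = FALSE)
    })
  }

  .stage("simulate", function() {
    simCfg <- do.call(syntheticConfig,
                      c(config$simulate, list(seed = config$seed)))
    state$study <- simulateStudy(simCfg)
    writeStudy(state$study, file.path(outDir, "input"))
    manifest$counts$simulate <<- list(
      organs = length(state$study$peptides),
      samples_per_organ = sum(simCfg@replicatesPerAge),
      proteins = simCfg@nProteins)
  })

  .stage("qc", function() {
    .need("study", "qc")
    meta <- state$study$metadata
    state$peptideSE <- list()
    reports <- list()
    for (org in names(state$study$peptides)) {
      m <- meta[meta$organ == org, ]
      rec <- readPeptideTable(
        file.path(outDir, "input", paste0("peptides_", org, ".tsv")), m)
      fl <- filterPeptides(rec)
      state$peptideSE[[org]] <- buildIntensityMatrix(fl$records, m)
      reports[[org]] <- fl$report
    }
    .writeJSON(reports, file.path(outDir, "qc_report.json"))
    manifest$counts$qc <<- lapply(reports, function(r)
      c(input = r$input, surviving = r$surviving))
  })

  .stage("summarize", function() {
    .need("peptideSE", "summarize")
    state$proteins <- list()
    logs <- list()
    for (org in names(state$peptideSE)) {
      se <- logAndCenter(state$peptideSE[[org]])
      pse <- summarizeProteins(se)
      imp <- imputeMissing(pse, method = config$summarize$impute,
                           minObsFrac = config$summarize$minObsFrac,
                           seed = .deriveSeed(config$seed, "impute"))
      mat <- SummarizedExperiment::assay(imp$matrix, "imputed")
      state$proteins[[org]] <- mat
      logs[[org]] <- imp$log
      .writeTSV(data.frame(accession = rownames(mat), mat,
                           check.names = FALSE),
                file.path(outDir, paste0("proteins_", org, ".tsv")))
    }
    .writeJSON(logs, file.path(outDir, "imputation_log.json"))
    manifest$counts$summarize <<- lapply(state$proteins, nrow)
  })

  .stage("diffexp", function() {
    .need("proteins", "diffexp")
    meta <- state$study$metadata
    state$de <- list(); state$deps <- list()
    comparisons <- list()
    for (org in names(state$proteins)) {
      m <- meta[meta$organ == org, ]
      mat <- state$proteins[[org]][, m$sample_id, drop = FALSE]
      de <- runDiffexp(mat, m$age_months, alpha = config$diffexp$alpha,
                       groupA = config$diffexp$groupA,
                       groupB = config$diffexp$groupB)
      cls <- classifyDEPs(de$table, config$diffexp$alpha)
      state$de[[org]] <- de
      state$deps[[org]] <- cls$sets$moderatedF
      .writeTSV(data.frame(accession = rownames(de$table), de$table),
                file.path(outDir, paste0("diffexp_", org, ".tsv")))
      writeLines(cls$sets$moderatedF,
                 file.path(outDir, paste0("deps_", org, ".txt")))
      comparisons[[org]] <- list(
        n_dep = lengths(cls$sets),
        overlap = as.data.frame(cls$overlap))
    }
    .writeJSON(comparisons, file.path(outDir, "method_comparison.json"))
    manifest$counts$diffexp <<- lapply(state$deps, length)
  })

  .stage("trajectory", function() {
    .need("de", "trajectory")
    meta <- state$study$metadata
    state$profiles <- list()
    reports <- list()
    for (org in names(state$deps)) {
      deps <- state$deps[[org]]
      if (length(deps) < config$trajectory$minDeps) next
      m <- meta[meta$organ == org, ]
      mat <- state$proteins[[org]][, m$sample_id, drop = FALSE]
      X <- zscoreProfiles(mat, m$age_months, deps)
      state$profiles[[org]] <- X
      cl <- if (identical(config$trajectory$clusters, "auto"))
        selectClusterCount(X, seed = .deriveSeed(config$seed, "trajectory"))
      else list(c = config$trajectory$clusters,
                clustering = fuzzyCMeans(
                  X, config$trajectory$clusters,
                  seed = .deriveSeed(config$seed, "trajectory")))
      cs <- clusterSummaries(cl$clustering)
      p1 <- pc1Trajectory(X)
      .writeTSV(data.frame(accession = rownames(X),
                           cl$clustering@membership, check.names = FALSE),
                file.path(outDir, paste0("membership_", org, ".tsv")))
      .writeTSV(data.frame(cluster = rownames(cl$clustering@centers),
                           cl$clustering@centers, check.names = FALSE),
                file.path(outDir, paste0("centers_", org, ".tsv")))
      reports[[org]] <- list(
        c = cl$c, pc = cl$clustering@pc, pe = cl$clustering@pe,
        most_enriched = cs$mostEnriched,
        pc1_variance = p1$varianceExplained,
        pc1_scores = as.list(p1$scores))
    }
    .writeJSON(reports, file.path(outDir, "trajectory_report.json"))
    manifest$counts$trajectory <<- names(state$profiles)
  })

  .stage("cross_organ", function() {
    .need("deps", "cross_organ")
    sets <- state$deps[lengths(state$deps) > 0]
    if (length(sets) < 2) return(invisible(NULL))
    inter <- depIntersections(sets)
    organs <- names(sets)
    tests <- list()
    for (i in seq_len(length(organs) - 1)) for (j in seq.int(i + 1,
                                                             length(organs))) {
      uni <- intersect(rownames(state$proteins[[organs[i]]]),
                       rownames(state$proteins[[organs[j]]]))
      k <- inter$pairwise[organs[i], organs[j]]
      tests[[paste(organs[i], organs[j], sep = "&")]] <- list(
        k = k, K = length(sets[[i]]), n = length(sets[[j]]),
        N = length(uni),
        p = hypergeomOverlapTest(k, length(intersect(sets[[i]], uni)),
                                 length(intersect(sets[[j]], uni)),
                                 length(uni)))
    }
    blood <- state$study$truth$blood
    writeLines(blood, file.path(outDir, "blood_list.txt"))
    fb <- filterBloodProteins(sets, blood)
    state$nonBloodDeps <- fb$sets
    .writeTSV(inter$exclusive, file.path(outDir, "intersections.tsv"))
    .writeJSON(list(pairwise_tests = tests,
                    dominant_fraction = as.list(inter$dominantFraction),
                    blood_removed = as.list(fb$removed)),
               file.path(outDir, "overlap_tests.json"))
    manifest$counts$cross_organ <<- list(
      union = sum(inter$exclusive$count),
      non_blood = lengths(fb$sets))
  })

  .stage("lmm", function() {
    .need("proteins", "lmm")
    shared <- Reduce(intersect, lapply(state$proteins, rownames))
    if (length(shared) > config$lmm$maxProteins)
      shared <- shared[seq_len(config$lmm$maxProteins)]
    mats <- lapply(state$proteins, function(m) m[shared, , drop = FALSE])
    res <- runLmmDivergence(mats, state$study$metadata,
                            alpha = config$lmm$alpha,
                            pThreshold = config$lmm$pThreshold)
    .writeTSV(res$lmm, file.path(outDir, "lmm_results.tsv"))
    if (!is.null(res$directionality)) {
      .writeTSV(data.frame(protein = rownames(res$directionality$matrix),
                           res$directionality$matrix, check.names = FALSE),
                file.path(outDir, "directionality.tsv"))
      .writeJSON(as.list(table(res$directionality$categories$category)),
                 file.path(outDir, "category_summary.json"))
    }
    manifest$counts$lmm <<- list(
      tested = nrow(res$lmm),
      significant = sum(res$lmm$q < config$lmm$alpha))
  })

  .stage("hubs", function() {
    .need("deps", "hubs")
    nodesrc <- state$nonBloodDeps %||% state$deps
    nodes <- nodesrc[[which.max(lengths(nodesrc))]]
    if (length(nodes) < config$hubs$cliqueSize + 2)
      nodes <- sprintf("P%05d", seq_len(40))
    sim <- simulateInteractionGraph(
      length(nodes), cliqueSpec = list(config$hubs$cliqueSize),
      noiseEdges = config$hubs$noiseEdges,
      seed = .deriveSeed(config$seed, "hubs"))
    g <- sim$graph
    g <- igraph::set_vertex_attr(g, "name", value = nodes)
    writeStringEdges(g, file.path(outDir, "string_edges.tsv"))
    g2 <- readStringEdges(file.path(outDir, "string_edges.tsv"),
                          scoreThreshold = config$hubs$scoreThreshold)
    scores <- mccScores(g2)
    hubs <- topKHubs(scores, min(config$hubs$top, length(scores)), g2)
    .writeTSV(data.frame(node = names(scores), mcc = scores,
                         rank = rank(-scores, ties.method = "min")),
              file.path(outDir, "hub_ranking.tsv"))
    writeLines(hubs, file.path(outDir, "hubs.txt"))
    manifest$counts$hubs <<- list(nodes = length(scores),
                                  top = length(hubs))
  })

  .stage("surequant", function() {
    .need("study", "surequant")
    meta <- state$study$metadata
    org <- names(state$study$peptides)[1]
    m <- meta[meta$organ == org, ]
    nPep <- config$surequant$nPeptides
    ## first half planted: ratio doubles by 20 months relative to reference
    ratio <- matrix(1, nPep, nrow(m))
    planted <- seq_len(floor(nPep / 2))
    ratio[planted, ] <- rep(1 + (m$age_months - 3) / 17,
                            each = length(planted))
    rep_ <- simulateTransitionReport(
      nPep, samples = m$sample_id, ratioTruth = ratio,
      cv = config$surequant$cv,
      seed = .deriveSeed(config$seed, "surequant"))
    utils::write.csv(rep_, file.path(outDir, "transitions.csv"),
                     row.names = FALSE)
    qn <- quantifyRatios(rep_)
    cmp <- compareToReference(qn, m,
                              referenceAge = config$surequant$referenceAge)
    .writeTSV(qn, file.path(outDir, "surequant_ratios.tsv"))
    .writeTSV(cmp, file.path(outDir, "surequant_tests.tsv"))
    manifest$counts$surequant <<- list(peptides = nPep,
                                       comparisons = nrow(cmp))
  })

  files <- list.files(outDir, recursive = TRUE, full.names = TRUE)
  files <- files[basename(files) != "manifest.json"]
  manifest$checksums <- as.list(tools::md5sum(files))
  names(manifest$checksums) <- sub(paste0("^", outDir, "/?"), "",
                                   names(manifest$checksums))
  .writeJSON(manifest, file.path(outDir, "manifest.json"))
  invisible(manifest)
}
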