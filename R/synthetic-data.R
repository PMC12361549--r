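## Synthetic multi-organ aging study generator.
##
## The generator emulates a cross-sectional mouse aging design: eight organs
## sampled from the same animals at six ages (3, 5, 8, 14, 20, 26 months)
## with 7, 9, 8, 9, 7 and 5 biological replicates per age group.  Intensities
## are built on the log2 scale as
##   protein baseline + planted age trajectory + blood component
##   + mouse random intercept + peptide ionization offset + residual
## and exponentiated into a raw peptide-level quantification table, so that
## every downstream stage can be tested against known ground truth.

.TRAJECTORY_KNOT_AGES <- c(3, 5, 8, 14, 20, 26)

.TRAJECTORY_TEMPLATES <- list(
  ## unit-amplitude log2 offsets at the canonical knot ages
  flat                 = c(0, 0, 0,  0.0,  0.0,  0.0),
  late_decline_recover = c(0, 0, 0,  0.0, -1.0, -0.5),
  early_spleen_decline = c(0, 0, 0, -0.5, -1.0, -0.5),
  late_rise_fall       = c(0, 0, 0,  0.4,  1.0,  0.5),
  midlife_peak         = c(0,  0.4,  1.0,  0.7, 0, 0),
  midlife_dip          = c(0, -0.4, -1.0, -0.7, 0, 0)
)

#' Configuration of a synthetic multi-organ aging study
#'
#' Captures the study design (organs, ages, replicate counts) together with
#' the generative parameters: number of proteins, peptides per protein,
#' per-organ fractions of differentially expressed proteins (DEPs), planted
#' trajectory amplitude, mouse-level random-intercept and residual standard
#' deviations (log2 units), the fraction of blood-associated proteins that
#' carry a shared cross-organ age component, and missingness parameters.
#'
#' @slot organs organ labels.
#' @slot agesMonths ordered ages in months.
#' @slot replicatesPerAge biological replicates per age group.
#' @slot nProteins number of proteins in the accession universe.
#' @slot peptidesPerProtein length-2 numeric, minimum and mean peptide count.
#' @slot depFraction named fraction of proteins planted as DEPs per organ.
#' @slot shapes trajectory template names cycled over planted DEPs.  The
#'   default uses every non-flat template, which (like the real data) is
#'   down-dominated in late life; note that median normalization assumes a
#'   directionally balanced proteome, so strongly unbalanced planted mass
#'   biases null proteins (see the methods vignette).  Use the
#'   `midlife_peak`/`midlife_dip` pair for a balanced design.
#' @slot amplitude planted trajectory amplitude, log2 units.
#' @slot mouseInterceptSd SD of the per-mouse intercept, log2 units.
#' @slot residualSd SD of the peptide-level residual, log2 units.
#' @slot bloodFraction fraction of proteins flagged blood-associated.
#' @slot mcarRate missing-completely-at-random cell rate.
#' @slot mnarStrength intensity-dependent dropout strength (0 disables).
#' @slot qcViolationRate fraction of peptide rows planted to violate one QC
#'   rule each.
#' @slot seed integer seed; generation is a pure function of (config, seed).
#' @export
setClass("SyntheticConfig", representation(
  organs = "character", agesMonths = "numeric", replicatesPerAge = "integer",
  nProteins = "integer", peptidesPerProtein = "numeric",
  depFraction = "numeric", shapes = "character", amplitude = "numeric",
  mouseInterceptSd = "numeric", residualSd = "numeric",
  bloodFraction = "numeric", mcarRate = "numeric", mnarStrength = "numeric",
  qcViolationRate = "numeric", seed = "integer"))

setValidity("SyntheticConfig", function(object) {
  msg <- character()
  if (length(object@replicatesPerAge) != length(object@agesMonths))
    msg <- c(msg, "replicatesPerAge must have one count per age")
  if (!all(names(object@depFraction) %in% object@organs) ||
      !all(object@organs %in% names(object@depFraction)))
    msg <- c(msg, "depFraction must be named by the organs")
  fr <- c(object@depFraction, object@bloodFraction, object@mcarRate,
          object@qcViolationRate)
  if (any(fr < 0 | fr > 1)) msg <- c(msg, "fractions must lie in [0, 1]")
  if (any(c(object@mouseInterceptSd, object@residualSd,
            object@mnarStrength) < 0))
    msg <- c(msg, "standard deviations and mnarStrength must be >= 0")
  if (!all(object@shapes %in% names(.TRAJECTORY_TEMPLATES)))
    msg <- c(msg, "shapes must name known trajectory templates")
  if (length(object@peptidesPerProtein) != 2L ||
      object@peptidesPerProtein[1] < 1 ||
      object@peptidesPerProtein[2] < object@peptidesPerProtein[1])
    msg <- c(msg, "peptidesPerProtein must be c(min >= 1, mean >= min)")
  if (length(msg)) msg else TRUE
})

#' @describeIn SyntheticConfig Constructor with the study-design defaults:
#'   eight organs, ages 3/5/8/14/20/26 months with 7/9/8/9/7/5 replicates,
#'   and per-organ DEP fractions mirroring the observed gradient from
#'   spleen/kidney (largest) down to brain (smallest).
#' @param organs,agesMonths,replicatesPerAge study design.
#' @param nProteins,peptidesPerProtein,depFraction,shapes,amplitude,mouseInterceptSd,residualSd,bloodFraction,mcarRate,mnarStrength,qcViolationRate,seed
#'   generative parameters, see slots.
#' @export
syntheticConfig <- function(organs = c("kidney", "spleen", "liver", "lung",
                                       "brain", "heart", "muscle", "testis"),
                            agesMonths = c(3, 5, 8, 14, 20, 26),
                            replicatesPerAge = c(7L, 9L, 8L, 9L, 7L, 5L),
                            nProteins = 300L,
                            peptidesPerProtein = c(2, 4),
                            depFraction = NULL,
                            shapes = setdiff(names(.TRAJECTORY_TEMPLATES),
                                             "flat"),
                            amplitude = 1.5,
                            mouseInterceptSd = 0.25,
                            residualSd = 0.3,
                            bloodFraction = 0.1,
                            mcarRate = 0.02,
                            mnarStrength = 0,
                            qcViolationRate = 0.02,
                            seed = 1L) {
  if (is.null(depFraction)) {
    defaults <- c(kidney = 0.383, spleen = 0.442, liver = 0.106, lung = 0.03,
                  brain = 0.001, heart = 0.006, muscle = 0.026,
                  testis = 0.009)
    depFraction <- ifelse(organs %in% names(defaults),
                          defaults[organs], 0.05)
    names(depFraction) <- organs
  }
  if (length(agesMonths) != length(replicatesPerAge))
    stop("agesMonths and replicatesPerAge must have the same length")
  methods::new("SyntheticConfig", organs = organs,
               agesMonths = as.numeric(agesMonths),
               replicatesPerAge = as.integer(replicatesPerAge),
               nProteins = as.integer(nProteins),
               peptidesPerProtein = as.numeric(peptidesPerProtein),
               depFraction = depFraction, shapes = shapes,
               amplitude = amplitude,
               mouseInterceptSd = mouseInterceptSd, residualSd = residualSd,
               bloodFraction = bloodFraction, mcarRate = mcarRate,
               mnarStrength = mnarStrength,
               qcViolationRate = qcViolationRate, seed = as.integer(seed))
}

setMethod("show", "SyntheticConfig", function(object) {
  cat("SyntheticConfig:", length(object@organs), "organs x",
      sum(object@replicatesPerAge), "samples each;",
      object@nProteins, "proteins\n")
  cat("  ages (months):", paste(object@agesMonths, collapse = ", "), "\n")
  cat("  replicates   :", paste(object@replicatesPerAge, collapse = ", "),
      "\n")
})

#' Planted mean age-trajectory templates
#'
#' Returns the mean log2 offset at each requested age for a named trajectory
#' shape, scaled by `amplitude`.  Templates are anchored at the canonical
#' ages (3, 5, 8, 14, 20, 26 months) and linearly interpolated in between:
#' `late_decline_recover` is stable from 3 to 14 months, drops to its
#' minimum at 20 and partially recovers by 26 (the kidney-type pattern);
#' `early_spleen_decline` starts declining after 8 months; `late_rise_fall`
#' rises to a 20-month peak and falls back; `midlife_peak` rises to a
#' transient maximum around 8-14 months and is back at baseline by 20
#' (invisible to a 20-vs-3 endpoint contrast) with `midlife_dip` its mirror
#' image; `flat` is all zeros.
#'
#' @param shape one of `trajectoryShapes()`.
#' @param ages ages in months at which to evaluate the template.
#' @param amplitude log2-scale amplitude multiplier.
#' @return numeric vector of log2 offsets, one per age.
#' @export
plantTrajectory <- function(shape, ages = .TRAJECTORY_KNOT_AGES,
                            amplitude = 1) {
  if (!shape %in% names(.TRAJECTORY_TEMPLATES))
    stop("unknown trajectory shape '", shape, "'; available: ",
         paste(names(.TRAJECTORY_TEMPLATES), collapse = ", "))
  tpl <- .TRAJECTORY_TEMPLATES[[shape]]
  if (shape == "flat") return(rep(0, length(ages)))
  amplitude * stats::approx(.TRAJECTORY_KNOT_AGES, tpl, xout = ages,
                            rule = 2)$y
}

#' @rdname plantTrajectory
#' @export
trajectoryShapes <- function() names(.TRAJECTORY_TEMPLATES)

#' Inject missing values into an intensity matrix
#'
#' Removes cells completely at random at rate `mcarRate`, and additionally
#' removes low-intensity cells with probability
#' `plogis(-(log2(x) - q10) / mnarScale)` scaled by `mnarStrength`, the
#' dominant dropout mode of label-free proteomics (low-abundance ions fall
#' below the detection limit).  `q10` is the 10th percentile of the log2
#' intensities.
#'
#' @param x numeric matrix of raw (positive) intensities.
#' @param mcarRate probability of missing completely at random.
#' @param mnarStrength maximum intensity-dependent dropout probability.
#' @param seed integer seed; identical seeds give identical masks.
#' @param mnarScale logistic scale in log2 units.
#' @return list with `matrix` (NAs injected) and logical `mask` of removals.
#' @export
injectMissingness <- function(x, mcarRate = 0, mnarStrength = 0, seed = 1L,
                              mnarScale = 1) {
  .assertFraction(mcarRate, "mcarRate")
  .assertFraction(mnarStrength, "mnarStrength")
  set.seed(.deriveSeed(seed, "simulate"))
  mask <- matrix(stats::runif(length(x)) < mcarRate, nrow(x), ncol(x))
  if (mnarStrength > 0) {
    lx <- log2(x)
    q10 <- stats::quantile(lx, 0.1, na.rm = TRUE)
    pMnar <- mnarStrength * stats::plogis(-(lx - q10) / mnarScale)
    mask <- mask | (matrix(stats::runif(length(x)), nrow(x)) < pMnar)
  }
  x[mask] <- NA_real_
  list(matrix = x, mask = mask)
}

## sample metadata for one full study: every mouse contributes every organ
.sampleMetadata <- function(config) {
  ages <- rep(config@agesMonths, config@replicatesPerAge)
  mice <- sprintf("M%02d", seq_along(ages))
  do.call(rbind, lapply(config@organs, function(org) {
    data.frame(sample_id = paste(org, mice, sep = "_"), organ = org,
               age_months = ages, mouse_id = mice,
               stringsAsFactors = FALSE)
  }))
}

#' Generate a complete synthetic aging study
#'
#' Produces one peptide-level quantification table per organ (raw-scale
#' intensities in the Proteome Discoverer export dialect), the sample
#' metadata, and a ground-truth record.  Differentially expressed proteins
#' are planted per organ by adding a non-flat trajectory template;
#' blood-associated proteins receive one identical age component in every
#' organ, so blood filtering demonstrably removes cross-organ shared signal.
#' A `qcViolationRate` fraction of peptide rows is deliberately altered to
#' violate one QC rule each (cycling through the six rules).
#'
#' @param config a [SyntheticConfig-class].
#' @return list with `peptides` (named list of data.frames, one per organ),
#'   `metadata` (data.frame), and `truth`: a list carrying per-organ planted
#'   DEP accession sets (`depSets`), shape/amplitude assignments (`shapes`),
#'   the blood-associated accession set (`blood`), per-organ age-responsive
#'   sets including blood proteins (`ageResponsive`), the planted per-organ
#'   direction matrix (`directions`, Up/Down/NoChange), and QC-violating row
#'   counts (`qcViolations`).
#' @export
simulateStudy <- function(config) {
  methods::validObject(config)
  set.seed(config@seed)
  ages <- config@agesMonths
  meta <- .sampleMetadata(config)
  acc <- sprintf("P%05d", seq_len(config@nProteins))

  nBlood <- round(config@bloodFraction * config@nProteins)
  blood <- if (nBlood > 0) sort(sample(acc, nBlood)) else character()
  ## each blood protein carries one cross-organ-shared age component;
  ## directions alternate so the contamination mass is balanced
  bloodSign <- rep(c(1, -1), length.out = nBlood)
  bloodOffsets <- plantTrajectory("late_rise_fall", ages, config@amplitude)

  shapesPool <- config@shapes
  nonBlood <- setdiff(acc, blood)
  depSets <- shapes <- list()
  for (org in config@organs) {
    nDep <- round(config@depFraction[[org]] * config@nProteins)
    nDep <- min(nDep, length(nonBlood))
    dep <- if (nDep > 0) sort(sample(nonBlood, nDep)) else character()
    depSets[[org]] <- dep
    shapes[[org]] <- data.frame(
      protein = dep,
      shape = if (nDep > 0)
        shapesPool[(seq_len(nDep) - 1L) %% length(shapesPool) + 1L]
      else character(),
      amplitude = rep(config@amplitude, nDep), stringsAsFactors = FALSE)
  }

  ## planted direction = sign of the least-squares slope of the mean profile
  .direction <- function(offsets) {
    sl <- stats::cov(ages, offsets) / stats::var(ages)
    if (abs(sl) < 1e-9) "NoChange" else if (sl > 0) "Up" else "Down"
  }
  directions <- matrix("NoChange", config@nProteins, length(config@organs),
                       dimnames = list(acc, config@organs))

  ## mouse intercepts shared across organs (matched sampling)
  mice <- unique(meta$mouse_id)
  mouseInt <- stats::rnorm(length(mice), 0, config@mouseInterceptSd)
  names(mouseInt) <- mice

  ## peptide complement per protein, common across organs
  pp <- config@peptidesPerProtein
  nPep <- pmax(pp[1], stats::rpois(config@nProteins, pp[2] - pp[1]) + pp[1])
  aa <- strsplit("ACDEFGHIKLMNPQRSTVWY", "")[[1]]
  pepSeq <- lapply(nPep, function(k)
    vapply(seq_len(k), function(i)
      paste(c(sample(aa, 9, replace = TRUE), "K"), collapse = ""), ""))
  pepOffset <- lapply(nPep, function(k) stats::rnorm(k, 0, 1))
  baseline <- stats::rnorm(config@nProteins, 20, 1.5)

  qcRules <- c("no_accession", "quan_flag", "multi_group", "ambiguous",
               "pep", "qvalue")
  peptides <- list()
  qcViolations <- integer()
  for (org in config@organs) {
    m <- meta[meta$organ == org, ]
    sampleAges <- m$age_months
    shp <- shapes[[org]]
    offsetAtAge <- matrix(0, config@nProteins, length(ages),
                          dimnames = list(acc, NULL))
    if (nrow(shp) > 0) {
      for (i in seq_len(nrow(shp)))
        offsetAtAge[shp$protein[i], ] <-
          plantTrajectory(shp$shape[i], ages, shp$amplitude[i])
    }
    if (length(blood) > 0)
      offsetAtAge[blood, ] <- offsetAtAge[blood, , drop = FALSE] +
        outer(bloodSign, bloodOffsets)
    for (g in rownames(offsetAtAge))
      directions[g, org] <- .direction(offsetAtAge[g, ])

    ageIdx <- match(sampleAges, ages)
    protLevel <- offsetAtAge[, ageIdx, drop = FALSE] + baseline
    protLevel <- sweep(protLevel, 2, mouseInt[m$mouse_id], `+`)

    rows <- sum(nPep)
    log2mat <- matrix(NA_real_, rows, nrow(m))
    seqs <- character(rows)
    accCol <- character(rows)
    r <- 0L
    for (g in seq_len(config@nProteins)) {
      for (p in seq_len(nPep[g])) {
        r <- r + 1L
        log2mat[r, ] <- protLevel[g, ] + pepOffset[[g]][p] +
          stats::rnorm(nrow(m), 0, config@residualSd)
        seqs[r] <- pepSeq[[g]][p]
        accCol[r] <- acc[g]
      }
    }
    raw <- 2^log2mat
    inj <- injectMissingness(raw, config@mcarRate, config@mnarStrength,
                             seed = config@seed + match(org, config@organs))
    raw <- inj$matrix

    tab <- data.frame(
      Sequence = seqs,
      Master.Protein.Accessions = accCol,
      Number.of.Protein.Groups = 1L,
      PSM.Ambiguity = "Unambiguous",
      Quan.Info = "",
      PEP = stats::runif(rows, 0, 0.04),
      q.Value = stats::runif(rows, 0, 0.04),
      stringsAsFactors = FALSE)
    nBad <- round(config@qcViolationRate * rows)
    if (nBad > 0) {
      bad <- sample(rows, nBad)
      rule <- qcRules[(seq_len(nBad) - 1L) %% length(qcRules) + 1L]
      tab$Master.Protein.Accessions[bad[rule == "no_accession"]] <- ""
      tab$Quan.Info[bad[rule == "quan_flag"]] <- "NoQuanValues"
      tab$Number.of.Protein.Groups[bad[rule == "multi_group"]] <- 2L
      tab$PSM.Ambiguity[bad[rule == "ambiguous"]] <- "Ambiguous"
      tab$PEP[bad[rule == "pep"]] <- stats::runif(sum(rule == "pep"),
                                                  0.051, 0.5)
      tab$q.Value[bad[rule == "qvalue"]] <- stats::runif(sum(rule == "qvalue"),
                                                         0.051, 0.5)
    }
    qcViolations[[org]] <- nBad
    intens <- as.data.frame(raw)
    names(intens) <- m$sample_id
    peptides[[org]] <- cbind(tab, intens)
  }

  truth <- list(depSets = depSets, shapes = shapes, blood = blood,
                ageResponsive = lapply(depSets, function(s)
                  sort(union(s, blood))),
                directions = directions, qcViolations = qcViolations,
                mouseIntercepts = mouseInt)
  list(peptides = peptides, metadata = meta, truth = truth)
}

#' Simulate a protein interaction graph with planted cliques
#'
#' Builds an undirected simple graph over `nNodes` labelled nodes, plants
#' the requested cliques, and sprinkles uniformly random noise edges that do
#' not duplicate clique edges.  Used as a fixture with known ground truth
#' for maximal-clique-centrality hub ranking.
#'
#' @param nNodes node count; nodes are labelled `N001`, `N002`, ...
#' @param cliqueSpec list of integer vectors (node indices) or single sizes;
#'   sizes are assigned to consecutive disjoint node blocks.
#' @param noiseEdges number of random extra edges.
#' @param seed integer seed.
#' @return list with `graph` (igraph) and `cliques` (list of planted node
#'   label vectors).
#' @export
simulateInteractionGraph <- function(nNodes, cliqueSpec = list(),
                                     noiseEdges = 0, seed = 1L) {
  set.seed(.deriveSeed(seed, "hubs"))
  labels <- sprintf("N%03d", seq_len(nNodes))
  nextFree <- 1L
  planted <- list()
  edges <- matrix(integer(), ncol = 2)
  for (spec in cliqueSpec) {
    idx <- if (length(spec) == 1L && spec[1] > 0 &&
               spec[1] == round(spec[1]) && is.numeric(spec)) {
      k <- as.integer(spec)
      if (k > nNodes) stop("planted clique larger than nNodes")
      if (nextFree + k - 1L > nNodes)
        stop("not enough free nodes for disjoint planted cliques")
      out <- seq.int(nextFree, nextFree + k - 1L)
      nextFree <- nextFree + k
      out
    } else as.integer(spec)
    if (max(idx) > nNodes) stop("planted clique larger than nNodes")
    planted[[length(planted) + 1L]] <- labels[idx]
    edges <- rbind(edges, t(utils::combn(idx, 2)))
  }
  if (noiseEdges > 0) {
    all <- t(utils::combn(nNodes, 2))
    key <- paste(all[, 1], all[, 2])
    used <- if (nrow(edges)) paste(pmin(edges[, 1], edges[, 2]),
                                   pmax(edges[, 1], edges[, 2])) else character()
    free <- which(!key %in% used)
    pick <- sample(free, min(noiseEdges, length(free)))
    edges <- rbind(edges, all[pick, , drop = FALSE])
  }
  g <- igraph::make_empty_graph(n = nNodes, directed = FALSE)
  g <- igraph::set_vertex_attr(g, "name", value = labels)
  if (nrow(edges))
    g <- igraph::add_edges(g, t(matrix(labels[t(edges)], ncol = 2,
                                       byrow = TRUE)))
  g <- igraph::simplify(g)
  list(graph = g, cliques = planted)
}

#' Simulate a targeted-MS transition report
#'
#' Emulates a Skyline-style export for internal-standard-triggered targeted
#' MS: for each peptide, six (by default) product ions are monitored in a
#' heavy (spiked internal standard) and a light (endogenous) channel.  Heavy
#' areas are drawn around a fixed reference level with an intensity ladder
#' across ions; light areas equal heavy x true ratio x multiplicative
#' log-normal noise.  `dropoutSpec` zeroes the weakest heavy-channel ions of
#' selected peptides to exercise the detectability filter.
#'
#' @param nPeptides number of target peptides.
#' @param samples sample labels.
#' @param ratioTruth true light/heavy ratio; scalar, per-peptide vector, or
#'   peptides x samples matrix.
#' @param ionsPerPeptide monitored product ions per peptide.
#' @param cv coefficient of variation of the multiplicative noise (0 = none).
#' @param dropoutSpec data.frame with columns `peptide` (id) and `n_zero`
#'   (how many of its heavy ions to zero, weakest first, in all samples).
#' @param seed integer seed.
#' @return long-format data.frame with columns peptide_id, charge, fragment,
#'   channel, sample, auc.
#' @export
simulateTransitionReport <- function(nPeptides, samples = c("S1", "S2", "S3"),
                                     ratioTruth = 1, ionsPerPeptide = 6L,
                                     cv = 0, dropoutSpec = NULL, seed = 1L) {
  set.seed(.deriveSeed(seed, "surequant"))
  peps <- sprintf("PEP%03d", seq_len(nPeptides))
  ratio <- matrix(ratioTruth, nPeptides, length(samples))
  frag <- paste0("y", seq(4, length.out = ionsPerPeptide))
  sdlog <- if (cv > 0) sqrt(log(1 + cv^2)) else 0
  out <- list()
  for (i in seq_len(nPeptides)) {
    ## intensity ladder: strongest ion first
    ladder <- 1e5 * 0.6^(seq_len(ionsPerPeptide) - 1)
    nZero <- 0L
    if (!is.null(dropoutSpec)) {
      hit <- dropoutSpec$peptide == peps[i]
      if (any(hit)) nZero <- as.integer(dropoutSpec$n_zero[hit][1])
    }
    for (s in seq_along(samples)) {
      heavy <- ladder * stats::rlnorm(ionsPerPeptide, -sdlog^2 / 2, sdlog)
      if (nZero > 0)
        heavy[seq.int(ionsPerPeptide - nZero + 1L, ionsPerPeptide)] <- 0
      light <- heavy * ratio[i, s] *
        stats::rlnorm(ionsPerPeptide, -sdlog^2 / 2, sdlog)
      out[[length(out) + 1L]] <- data.frame(
        peptide_id = peps[i], charge = 2L, fragment = frag,
        channel = rep(c("heavy", "light"), each = ionsPerPeptide),
        sample = samples[s], auc = c(heavy, light),
        stringsAsFactors = FALSE)
    }
  }
  do.call(rbind, out)
}

#' Write a simulated study to disk
#'
#' Emits one peptide TSV per organ, the metadata CSV, and the ground truth
#' as JSON (directions matrix flattened to a data frame), matching the
#' formats the reading functions consume.
#'
#' @param study result of [simulateStudy()].
#' @param dir output directory (created if needed).
#' @return invisibly, the directory.
#' @export
writeStudy <- function(study, dir) {
  dir.create(dir, showWarnings = FALSE, recursive = TRUE)
  for (org in names(study$peptides))
    .writeTSV(study$peptides[[org]],
              file.path(dir, paste0("peptides_", org, ".tsv")))
  utils::write.csv(study$metadata, file.path(dir, "metadata.csv"),
                   row.names = FALSE)
  truth <- study$truth
  truth$directions <- as.data.frame(truth$directions)
  .writeJSON(truth, file.path(dir, "ground_truth.json"))
  invisible(dir)
}
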