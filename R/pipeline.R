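# End-to-end orchestration: synthetic data -> SDM -> range shift ->
# connectivity -> diversity -> Mantel -> admixture -> divergence landscape,
# as one seeded, stage-toggleable run writing plain-text artifacts.

#' Average several GCM climate stacks variable-by-variable
#'
#' Per-variable, per-cell arithmetic mean over a list of co-registered
#' stacks with identical layer names, the standard way of folding several
#' general circulation models into one future scenario before modelling.
#'
#' @param stacks list of [RasterStack-class] objects.
#' @return a [RasterStack-class].
#' @export
averageGcmStacks <- function(stacks) {
  if (!length(stacks)) stop("no stacks to average")
  ref <- stacks[[1]]
  for (s in stacks[-1]) {
    if (!identical(layerNames(s), layerNames(ref)) ||
        !identical(gridDim(s), gridDim(ref)) ||
        s@xmin != ref@xmin || s@ymin != ref@ymin ||
        s@cellsize != ref@cellsize)
      stop("stacks must share layer names and grids")
  }
  layers <- lapply(layerNames(ref), function(nm) {
    Reduce(`+`, lapply(stacks, getLayer, nm)) / length(stacks)
  })
  names(layers) <- layerNames(ref)
  rasterStack(layers, ref@xmin, ref@ymin, ref@cellsize)
}

pipelineStages <- function() c("data", "sdm", "rangeshift", "connectivity",
                               "popgen", "mantel", "admixture", "landscape")

# Documented seed splitter: stage i of a run with global seed s uses
# s + 1009 * i, keeping every stage independently re-runnable yet
# reproducible from the one global seed.
stageSeed <- function(seed, stage) {
  (seed + 1009L * match(stage, pipelineStages())) %% .Machine$integer.max
}

#' Default pipeline configuration
#'
#' `profile = "test"` uses sizes suitable for fast synthetic checks
#' (20 x 20 rasters, 10 populations, 500 MCMC sweeps); `profile = "paper"`
#' records the full-scale analysis defaults (0.75 correlation pruning, 0.6
#' TSS/AUC gates, 20000/2000 sweeps, K ladder 2-20 with 4 runs each, 9999
#' permutations, IDW power 2 with 12 neighbours).
#'
#' @param profile `"test"` or `"paper"`.
#' @param seed global seed, expanded into per-stage seeds.
#' @param outdir run directory (`NULL` = tempdir).
#' @return nested configuration list accepted by [runPipeline()].
#' @export
defaultPipelineConfig <- function(profile = c("test", "paper"), seed = 1L,
                                  outdir = NULL) {
  profile <- match.arg(profile)
  test <- profile == "test"
  list(
    profile = profile,
    seed = as.integer(seed),
    outdir = outdir,
    stages = pipelineStages(),
    scenario = if (test)
      list(nCells = c(20L, 20L), nVars = 6L, nPops = 10L, nIndPerPop = 6L,
           kTrue = 3L, autocorrRange = 5, futureShift = 0.8, ibr = TRUE)
    else list(ibr = TRUE),
    occurrences = list(n = if (test) 120L else 492L,
                       beta = NULL,          # default: suitability from bio01/bio02
                       rarefy_km = if (test) 0 else 5),
    sdm = list(r_max = 0.75, gate = 0.6,
               algorithms = c("glm", "rf", "cta", "fda"),
               n_repeats = if (test) 2L else 10L, split = 0.75,
               pa_ratio = 1, weighted = FALSE),
    connectivity = list(epsilon = 0.001),
    popgen = list(n_min = 5L),
    mantel = list(n_perm = if (test) 199L else 9999L),
    admixture = list(K_values = if (test) c(1L, 3L) else 2:20,
                     n_runs = if (test) 1L else 4L,
                     sweeps = if (test) 500L else 20000L,
                     burn_in = if (test) 100L else 2000L,
                     thin = if (test) 5L else 10L, n_covariates = 3L,
                     lost_threshold = 0.5),
    landscape = list(cellsize = NULL,       # default: scenario cellsize
                     power = 2, k_neighbors = 12L,
                     max_cells = if (test) 2000L else 5000L)
  )
}

# polynomial rolling hash over a string, for config provenance stamps
configHash <- function(s) {
  h <- 0
  for (b in utf8ToInt(s)) h <- (h * 31 + b) %% 2147483647
  sprintf("%08x", h)
}

writeStageCsv <- function(df, outdir, name) {
  if (!is.null(outdir))
    write.csv(df, file.path(outdir, name), row.names = FALSE, quote = FALSE)
  invisible(NULL)
}

#' Run the full analysis pipeline
#'
#' Executes the enabled stages in order on synthetic data generated from
#' the configured scenario, carrying artifacts forward in a state list and
#' writing plain-text products (tables, matrices, grids, reports) plus a
#' run manifest into the run directory. Each stage draws its own seed from
#' the global one, so a stage re-run on the same upstream state is
#' bit-identical to its output in the full run.
#'
#' @param config list from [defaultPipelineConfig()] (unknown top-level
#'   keys are rejected).
#' @param state optional state list from a previous run to resume from.
#' @param stages stages to execute (default: those enabled in the config).
#' @return invisible state list with all stage artifacts; `$outdir` names
#'   the run directory.
#' @export
runPipeline <- function(config = defaultPipelineConfig(), state = NULL,
                        stages = NULL) {
  known <- c("profile", "seed", "outdir", "stages", "scenario",
             "occurrences", "sdm", "connectivity", "popgen", "mantel",
             "admixture", "landscape")
  unknown <- setdiff(names(config), known)
  if (length(unknown))
    stop("unknown config keys: ", paste(unknown, collapse = ", "))
  if (is.null(stages)) stages <- config$stages
  stages <- match.arg(stages, pipelineStages(), several.ok = TRUE)
  outdir <- config$outdir
  if (is.null(outdir)) outdir <- file.path(tempdir(),
                                           paste0("clgc-run-", config$seed))
  if (!dir.exists(outdir)) dir.create(outdir, recursive = TRUE)
  if (is.null(state)) state <- list()
  state$outdir <- outdir

  for (stage in pipelineStages()) {
    if (!stage %in% stages) next
    t0 <- Sys.time()
    state <- tryCatch(
      runStage(state, stage, config),
      error = function(e) stop("pipeline halted in stage '", stage, "': ",
                               conditionMessage(e), call. = FALSE))
    message(sprintf("[clgc] stage %-12s %6.1fs", stage,
                    as.numeric(difftime(Sys.time(), t0, units = "secs"))))
  }
  manifest <- list(seed = config$seed, profile = config$profile,
                   stages = stages,
                   config_hash = configHash(paste(deparse(config),
                                                  collapse = "")),
                   finished = format(Sys.time(), "%Y-%m-%dT%H:%M:%S"))
  jsonlite::write_json(manifest, file.path(outdir, "manifest.json"),
                       auto_unbox = TRUE, pretty = TRUE)
  invisible(state)
}

#' Run one pipeline stage against cached upstream artifacts
#'
#' @param state state list from a previous [runPipeline()] call (or empty
#'   for the `data` stage).
#' @param stage stage name.
#' @param config pipeline configuration.
#' @return the updated state list.
#' @export
runStage <- function(state, stage, config) {
  seed <- stageSeed(config$seed, stage)
  outdir <- state$outdir
  switch(stage,
    data = {
      sc <- do.call(syntheticScenario,
                    c(list(seed = seed), config$scenario))
      state$scenario <- sc
      stacks <- generateClimateStack(sc)
      state$stack_current <- stacks$current
      state$stack_future <- stacks$future
      beta <- config$occurrences$beta
      if (is.null(beta)) {
        # a warm-edge species with a well-defined climatic envelope:
        # steep logistic response to the two leading bioclim gradients
        # (minority of the landscape suitable), oriented so the uniform
        # positive future trend erodes net suitability
        beta <- rep(0, nLayers(stacks$current) + 1)
        beta[1] <- -3; beta[2] <- -5; beta[3] <- 4
      }
      state$occ_beta <- beta
      state$occurrences <- generateOccurrences(stacks$current, beta,
                                               config$occurrences$n,
                                               seed = seed + 1L)
      gen <- generatePopulationsAndGenotypes(
        sc, stacks$current,
        ibr_suitability = trueSuitability(stacks$current, beta))
      state$pops <- gen$pops
      state$genotypes <- gen$genotypes
      state$haplotypes <- gen$haplotypes
      state$Q_true <- gen$Q_true
      if (!is.null(outdir)) {
        writeStageCsv(state$occurrences, outdir, "occurrences.csv")
        writeStageCsv(gen$pops, outdir, "populations.csv")
        writeGenAlEx(gen$genotypes, file.path(outdir, "genotypes.csv"))
        writeHaplotypes(gen$haplotypes, file.path(outdir,
                                                  "haplotypes.fasta"))
      }
      state
    },
    sdm = {
      cfg <- config$sdm
      pruned <- pruneCorrelatedVariables(state$stack_current, cfg$r_max)
      keep <- attr(pruned, "retained")
      state$stack_pruned <- pruned
      state$stack_future_pruned <-
        rasterStack(state$stack_future@layers[keep],
                    state$stack_future@xmin, state$stack_future@ymin,
                    state$stack_future@cellsize)
      occ <- state$occurrences
      if (config$occurrences$rarefy_km > 0)
        occ <- rarefyOccurrences(occ, config$occurrences$rarefy_km)
      pa <- samplePseudoAbsences(pruned, occ,
                                 max(10L, round(cfg$pa_ratio * nrow(occ))),
                                 seed = seed)
      ens <- fitEnsemble(occ, pa, pruned, algorithms = cfg$algorithms,
                         n_repeats = cfg$n_repeats, split = cfg$split,
                         gate = cfg$gate, seed = seed + 1L)
      state$ensemble <- ens
      state$suit_current <- ensemblePredict(ens, pruned, "current",
                                            cfg$weighted)
      state$suit_future <- ensemblePredict(ens, state$stack_future_pruned,
                                           "future", cfg$weighted)
      state$lpt <- lptThreshold(state$suit_current, occ)
      state$suit_current <- binarize(state$suit_current, state$lpt)
      state$suit_future <- binarize(state$suit_future, state$lpt)
      state$occ_used <- occ
      if (!is.null(outdir)) {
        writeStageCsv(ens$evaluations, outdir, "sdm_evaluations.csv")
        writeAsciiGrid(gridValues(state$suit_current),
                       file.path(outdir, "suitability_current.asc"),
                       pruned@xmin, pruned@ymin, pruned@cellsize)
        writeAsciiGrid(gridValues(state$suit_future),
                       file.path(outdir, "suitability_future.asc"),
                       pruned@xmin, pruned@ymin, pruned@cellsize)
      }
      state
    },
    rangeshift = {
      rs <- rangeShift(state$suit_current, state$suit_future)
      state$range_shift <- rs
      if (!is.null(outdir))
        jsonlite::write_json(
          list(areas_km2 = as.list(rs$areas_km2),
               percent_change = rs$percent_change),
          file.path(outdir, "range_shift.json"), auto_unbox = TRUE,
          digits = NA, pretty = TRUE)
      state
    },
    connectivity = {
      eps <- config$connectivity$epsilon
      state$friction_current <- frictionFromSuitability(state$suit_current,
                                                        eps)
      state$friction_future <- frictionFromSuitability(state$suit_future,
                                                       eps)
      links <- sharedHaplotypeLinks(state$haplotypes)
      state$network_all <- buildNetwork(state$pops, state$friction_current)
      state$network_shared <- buildNetwork(state$pops,
                                           state$friction_current, links)
      state$resistance_current <- resistanceMatrix(state$pops,
                                                   state$friction_current)
      state$resistance_future <- resistanceMatrix(state$pops,
                                                  state$friction_future)
      if (!is.null(outdir)) {
        writeStageCsv(networkEdges(state$network_all), outdir,
                      "network_all_pairs.csv")
        writeStageCsv(networkEdges(state$network_shared), outdir,
                      "network_shared_haplotype.csv")
        writeDistanceMatrixCsv(state$resistance_current,
                               file.path(outdir, "resistance_current.csv"))
        writeDistanceMatrixCsv(state$resistance_future,
                               file.path(outdir, "resistance_future.csv"))
      }
      state
    },
    popgen = {
      st <- diversityStats(state$genotypes, state$haplotypes)
      rc <- cellFromXY(state$suit_current, state$pops$lon, state$pops$lat)
      st$suit_current <- gridValues(state$suit_current)[rc]
      st$suit_future <- gridValues(state$suit_future)[rc]
      state$diversity <- filterMinN(st, config$popgen$n_min)
      state$fst <- pairwiseFst(state$genotypes)
      state$fst_lin <- linearizeFst(state$fst)
      state$future_diversity <- projectFutureDiversity(
        state$genotypes, state$haplotypes, state$pops, state$suit_future,
        state$lpt)
      if (!is.null(outdir)) {
        writeStageCsv(state$diversity, outdir, "diversity_table.csv")
        writeDistanceMatrixCsv(state$fst_lin,
                               file.path(outdir, "fst_linearized.csv"))
        writeStageCsv(state$future_diversity$stats, outdir,
                      "diversity_future.csv")
      }
      state
    },
    mantel = {
      np <- config$mantel$n_perm
      ids <- rownames(state$fst_lin)
      pops <- state$pops[match(ids, state$pops$id), ]
      geo <- geographicDistanceMatrix(pops)
      rc <- state$resistance_current[ids, ids]
      rf <- state$resistance_future[ids, ids]
      state$mantel <- list(
        current = mantelTest(state$fst_lin, rc, np, seed),
        future = mantelTest(state$fst_lin, rf, np, seed + 1L),
        geographic = mantelTest(state$fst_lin, geo, np, seed + 2L),
        partial_current = partialMantelTest(state$fst_lin, rc, geo, np,
                                            seed + 3L),
        partial_future = partialMantelTest(state$fst_lin, rf, geo, np,
                                           seed + 4L))
      state$geo_matrix <- geo
      if (!is.null(outdir)) {
        tab <- do.call(rbind, lapply(names(state$mantel), function(nm) {
          m <- state$mantel[[nm]]
          data.frame(test = nm, r = m$r, p = m$p, n_perm = m$n_perm)
        }))
        writeStageCsv(tab, outdir, "mantel_tests.csv")
      }
      state
    },
    admixture = {
      cfg <- config$admixture
      cov_names <- selectClimateCovariates(state$stack_current, state$pops,
                                           cfg$n_covariates)
      state$covariate_names <- cov_names
      gt <- state$genotypes
      Xc <- extractValues(rasterStack(state$stack_current@layers[cov_names],
                                      state$stack_current@xmin,
                                      state$stack_current@ymin,
                                      state$stack_current@cellsize),
                          gt@coords[, 1], gt@coords[, 2])
      Xf <- extractValues(rasterStack(state$stack_future@layers[cov_names],
                                      state$stack_future@xmin,
                                      state$stack_future@ymin,
                                      state$stack_future@cellsize),
                          gt@coords[, 1], gt@coords[, 2])
      fits <- list()
      for (K in cfg$K_values) for (run in seq_len(cfg$n_runs))
        fits[[length(fits) + 1L]] <-
          fitAdmixture(gt, gt@coords, Xc, K, sweeps = cfg$sweeps,
                       burn_in = cfg$burn_in, thin = cfg$thin,
                       seed = seed + 10L * K + run)
      best <- selectRuns(fits)
      state$admixture_fit <- best
      state$dic_table <- attr(best, "dic_table")
      state$Q_projected <- projectAdmixture(best, Xf)
      state$turnover <- turnoverReport(best@Q_reg, state$Q_projected,
                                       cfg$lost_threshold)
      if (!is.null(outdir)) {
        writeStageCsv(state$dic_table, outdir, "dic_table.csv")
        writeStageCsv(as.data.frame(ancestryQ(best)), outdir,
                      "ancestry_current.csv")
        writeStageCsv(as.data.frame(state$Q_projected), outdir,
                      "ancestry_projected.csv")
        jsonlite::write_json(
          list(overall_r = state$turnover$overall_r,
               per_cluster_r = state$turnover$per_cluster_r,
               lost = state$turnover$lost),
          file.path(outdir, "turnover.json"), auto_unbox = TRUE,
          digits = NA, pretty = TRUE)
      }
      state
    },
    landscape = {
      cfg <- config$landscape
      ids <- rownames(state$fst_lin)
      pops <- state$pops[match(ids, state$pops$id), ]
      samples <- midpointDistances(pops, state$fst_lin)
      cs <- cfg$cellsize
      if (is.null(cs)) cs <- state$suit_current@cellsize
      state$divergence_landscape <-
        idwInterpolate(samples, cs, cfg$power, cfg$k_neighbors,
                       extent = c(state$suit_current@xmin,
                                  state$suit_current@ymin,
                                  state$suit_current@xmin +
                                    ncol(gridValues(state$suit_current)) *
                                    state$suit_current@cellsize,
                                  state$suit_current@ymin +
                                    nrow(gridValues(state$suit_current)) *
                                    state$suit_current@cellsize))
      chg <- suitabilityChange(state$suit_current, state$suit_future)
      state$stability_gam <- stabilityGam(state$divergence_landscape, chg,
                                          max_cells = cfg$max_cells,
                                          seed = seed)
      if (!is.null(outdir)) {
        writeAsciiGrid(state$divergence_landscape$grid,
                       file.path(outdir, "divergence_landscape.asc"),
                       state$divergence_landscape$xmin,
                       state$divergence_landscape$ymin,
                       state$divergence_landscape$cellsize)
        jsonlite::write_json(
          list(r_squared = state$stability_gam$r_squared,
               p_value = state$stability_gam$p_value,
               n = state$stability_gam$n, threshold = state$lpt,
               sign_convention = "future - current (positive = gain)"),
          file.path(outdir, "stability_gam.json"), auto_unbox = TRUE,
          digits = NA, pretty = TRUE)
      }
      state
    },
    stop("unknown stage: ", stage))
}
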