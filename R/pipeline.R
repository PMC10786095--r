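# Config-driven orchestration of the full analysis: simulate -> v1 -> glm
# -> rsa -> cluster -> scramble/DC -> mvpa -> behavior -> report.

#' Pipeline configuration
#'
#' Bundles every stage's parameters with a single global seed from which
#' all stage seeds are derived.  The \code{"test"} profile runs the whole
#' pipeline at desk scale (16^3 grid, 6 subjects, searchlight k = 19,
#' n_perm <= 100, Monte Carlo iterations <= 500); \code{"full"} uses the
#' study-scale settings (20^3 grid, 20 subjects, 1000 scrambles, 5000
#' iterations).
#'
#' @param seed global integer seed.
#' @param profile \code{"test"} or \code{"full"}.
#' @param outdir optional output directory for artifacts.
#' @param ... named overrides of individual defaults (n_subjects, grid,
#'   k, n_perm, n_iter, effect_size, interaction, noise_sd, slope,
#'   criterion_sd, v1_frames, v1_image, voxel_p, alpha, connectivity).
#' @return A \code{PipelineConfig} list.
#' @export
pipelineConfig <- function(seed = 1, profile = c("test", "full"),
                           outdir = NULL, ...) {
  profile <- match.arg(profile)
  base <- if (profile == "test") {
    list(n_subjects = 6, grid = c(16, 16, 16), k = 19, n_perm = 100,
         n_iter = 500, v1_frames = 6, v1_image = 64)
  } else {
    list(n_subjects = 20, grid = c(20, 20, 20), k = 200, n_perm = 1000,
         n_iter = 5000, v1_frames = 30, v1_image = 128)
  }
  cfg <- utils::modifyList(c(base, list(
    effect_size = c(facing = 1, gender = 1, emotion = 1),
    interaction = numeric(0), noise_sd = 11, tuning_sd = 0.5,
    idiosyncratic_sd = 0.3, ar1 = 0.3,
    slope = 1.5, criterion_sd = 1,
    voxel_p = 0.001, alpha = 0.05, connectivity = 26,
    cost = 1, demean = TRUE
  )), list(...))
  if (profile == "test") {
    cfg$n_perm <- min(cfg$n_perm, 100)
    cfg$n_iter <- min(cfg$n_iter, 500)
  }
  cfg$seed <- as.integer(seed)
  cfg$profile <- profile
  cfg$outdir <- outdir
  structure(cfg, class = "PipelineConfig")
}

#' Read a pipeline configuration from YAML
#'
#' @param path YAML file; keys \code{seed}, \code{profile}, \code{outdir}
#'   and any [pipelineConfig()] override.
#' @return A \code{PipelineConfig}.
#' @export
readPipelineConfig <- function(path) {
  y <- yaml::read_yaml(path)
  args <- y[setdiff(names(y), c("seed", "profile", "outdir"))]
  args <- lapply(args, function(v) if (is.list(v)) unlist(v) else v)
  do.call(pipelineConfig, c(list(seed = y$seed %||% 1,
                                 profile = y$profile %||% "test",
                                 outdir = y$outdir), args))
}

`%||%` <- function(a, b) if (is.null(a)) b else a

.stageOrder <- c("simulate", "v1", "glm", "rsa", "cluster", "scramble",
                 "mvpa", "behavior", "report")

.stageDeps <- list(simulate = character(), v1 = character(),
                   glm = "simulate", rsa = c("glm", "v1"), cluster = "rsa",
                   scramble = c("rsa", "cluster"),
                   mvpa = c("glm", "cluster"),
                   behavior = c("glm", "cluster", "simulate"),
                   report = c("cluster", "scramble", "mvpa", "behavior"))

#' Run one pipeline stage
#'
#' Stages are idempotent: when the store already holds the stage's
#' artifact for an identical configuration the stage is skipped.
#'
#' @param name stage name (one of simulate, v1, glm, rsa, cluster,
#'   scramble, mvpa, behavior, report).
#' @param config a [pipelineConfig()].
#' @param store environment holding stage artifacts (created when
#'   missing and returned via the \code{store} attribute).
#' @return The stage artifact (invisibly for large ones).
#' @export
runStage <- function(name, config, store = NULL) {
  name <- match.arg(name, .stageOrder)
  if (is.null(store)) store <- new.env(parent = emptyenv())
  key <- paste0(".done_", name)
  if (!is.null(store[[key]]) && identical(store[[key]], unclass(config))) {
    message(sprintf("[%s] up to date, skipping", name))
    return(invisible(store[[name]]))
  }
  for (dep in .stageDeps[[name]]) {
    if (is.null(store[[dep]])) {
      stop(sprintf("stage '%s' requires stage '%s' to run first", name, dep))
    }
  }
  t0 <- proc.time()[["elapsed"]]
  store[[name]] <- .runStageImpl(name, config, store)
  store[[key]] <- unclass(config)
  message(sprintf("[%s] done in %.1f s", name,
                  proc.time()[["elapsed"]] - t0))
  if (!is.null(config$outdir) && name == "report") {
    dir.create(config$outdir, recursive = TRUE, showWarnings = FALSE)
    saveRDS(store[[name]], file.path(config$outdir, "report.rds"))
    if (requireNamespace("jsonlite", quietly = TRUE)) {
      jsonlite::write_json(store[[name]],
                           file.path(config$outdir, "report.json"),
                           auto_unbox = TRUE, digits = NA, force = TRUE)
    }
  }
  invisible(store[[name]])
}

.runStageImpl <- function(name, cfg, store) {
  labels <- stimulusLabels()
  switch(name,
    simulate = {
      eff <- effectSpec(grid_shape = cfg$grid, effect_size = cfg$effect_size,
                        interaction = cfg$interaction,
                        tuning_sd = cfg$tuning_sd,
                        idiosyncratic_sd = cfg$idiosyncratic_sd,
                        noise_sd = cfg$noise_sd, ar1 = cfg$ar1)
      subjects <- simulateGroup(cfg$n_subjects, designSpec(), eff, labels,
                                base_seed = deriveSeed(cfg$seed, "simulate"))
      ratings <- lapply(seq_len(cfg$n_subjects), function(s) {
        simulateRatings(labels, cfg$slope, cfg$criterion_sd,
                        seed = deriveSeed(cfg$seed, "ratings", s))
      })
      list(subjects = subjects, ratings = ratings, effects = eff,
           labels = labels)
    },
    v1 = {
      ss <- buildStimulusSet(n_frames = cfg$v1_frames,
                             image_size = cfg$v1_image)
      bank <- gaborBank()
      feats <- lapply(ss$stacks, stimulusFeature, bank = bank)
      list(rdm = v1RDM(feats), features = feats)
    },
    glm = {
      sim <- store$simulate
      tmaps <- lapply(sim$subjects, conditionTMaps)
      betas <- lapply(sim$subjects, runBetas)
      list(tmaps = tmaps, betas = betas)
    },
    rsa = {
      sim <- store$simulate
      sl <- defineSearchlights(sim$subjects[[1]]@mask, searchlightSpec(cfg$k))
      theo <- theoreticalRDMs(sim$labels)
      Ys <- lapply(store$glm$tmaps, neuralRDMVectors, sl = sl)
      maps <- lapply(seq_along(Ys), function(s) {
        searchlightRSA(NULL, theo, store$v1$rdm, sl, Y = Ys[[s]])
      })
      list(maps = maps, Ys = Ys, sl = sl, theoretical = theo)
    },
    cluster = {
      rsa <- store$rsa
      tspec <- thresholdSpec(cfg$voxel_p, cfg$n_iter, cfg$alpha,
                             cfg$connectivity,
                             seed = deriveSeed(cfg$seed, "cluster"))
      attrs <- names(rsa$theoretical)
      cl <- lapply(attrs, function(a) {
        M <- t(vapply(rsa$maps, function(m) m@values[, a],
                      numeric(length(rsa$sl@maskIdx))))
        monteCarloCluster(M, tspec, rsa$sl@maskIdx, rsa$sl@dim,
                          fisher = TRUE)
      })
      names(cl) <- attrs
      list(clusters = cl, tspec = tspec)
    },
    scramble = {
      rsa <- store$rsa
      attrs <- names(rsa$theoretical)
      scrambled <- lapply(attrs, function(a) {
        lapply(seq_along(rsa$Ys), function(s) {
          plan <- scramblePlan(a, n_perm = cfg$n_perm,
                               seed = deriveSeed(cfg$seed, "scramble", s))
          scrambledRSA(NULL, rsa$theoretical, store$v1$rdm, rsa$sl, plan,
                       Y = rsa$Ys[[s]])
        })
      })
      names(scrambled) <- attrs
      hier <- hierarchyAnalysis(rsa$maps, scrambled, store$cluster$tspec)
      list(scrambledMaps = scrambled, hierarchy = hier)
    },
    mvpa = {
      sim <- store$simulate
      rsa <- store$rsa
      attrs <- names(rsa$theoretical)
      accRows <- NULL
      network <- character(0)
      for (a in attrs) {
        cs <- store$cluster$clusters[[a]]
        sigVox <- which(significantVoxels(cs))
        if (!length(sigVox)) next
        for (s in seq_along(sim$subjects)) {
          b <- store$glm$betas[[s]]
          for (dec in attrs) {
            am <- searchlightClassify(b$betas, b$condition, b$run,
                                      sim$labels, dec, rsa$sl,
                                      centers = sigVox, cost = cfg$cost,
                                      demean = cfg$demean)
            sig <- cs@table$cluster[cs@table$significant]
            acc <- clusterAccuracy(am, cs, which = sig)
            accRows <- rbind(accRows, data.frame(
              subject = s, cluster = paste0(a, "_", names(acc)),
              attribute = dec, accuracy = unname(acc)))
          }
        }
        sig <- cs@table$cluster[cs@table$significant]
        network[paste0(a, "_cluster", sig)] <- a
      }
      tests <- if (!is.null(accRows)) accuracyTests(accRows, network) else NULL
      list(accuracies = accRows, tests = tests, network = network)
    },
    behavior = {
      sim <- store$simulate
      attrs <- names(store$cluster$clusters)
      out <- list()
      for (a in attrs) {
        cs <- store$cluster$clusters[[a]]
        sig <- cs@table$cluster[cs@table$significant]
        if (!length(sig)) next
        neural <- lapply(seq_along(sim$subjects), function(s) {
          stats::setNames(lapply(sig, function(cl) {
            clusterNeuralRDM(store$glm$tmaps[[s]],
                             which(cs@labels == cl))
          }), paste0("cluster", sig))
        })
        behavioral <- lapply(sim$ratings, behavioralRDM, attribute = a)
        out[[a]] <- behaviorNeuralLink(neural, behavioral)
      }
      out
    },
    report = {
      sim <- store$simulate
      truthDice <- lapply(names(sim$effects$rois), function(a) {
        cs <- store$cluster$clusters[[a]]
        planted <- plantAmplitudes(sim$effects, sim$labels)
        roi <- logical(length(cs@labels))
        roi[planted$roiIdx[[a]]] <- TRUE
        dice(significantVoxels(cs), roi)$dc
      })
      names(truthDice) <- names(sim$effects$rois)
      list(
        profile = cfg$profile, seed = cfg$seed,
        dc = store$scramble$hierarchy$dice,
        clusters = lapply(store$cluster$clusters, function(c) c@table),
        roi_recovery_dice = truthDice,
        mvpa = store$mvpa$tests,
        behavior = store$behavior
      )
    },
    stop("unknown stage"))
}

#' Run the full pipeline
#'
#' Executes all stages in order and returns the machine-readable summary
#' (hierarchy DC table, cluster tables, planted-ROI recovery, MVPA and
#' behavior-link tables).
#'
#' @param config a [pipelineConfig()].
#' @param store optional artifact environment (reused across calls for
#'   idempotent re-runs).
#' @return The report list; the artifact store is attached as attribute
#'   \code{store}.
#' @export
fullPipeline <- function(config, store = NULL) {
  if (is.null(store)) store <- new.env(parent = emptyenv())
  for (st in .stageOrder) runStage(st, config, store)
  structure(store$report, store = store)
}
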