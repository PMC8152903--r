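#' Full synthetic-study configuration
#'
#' Bundles the generator and decoding configurations with the inference
#' settings and the master seed for a complete simulated study.
#'
#' @param synth a [SynthConfig-class].
#' @param decode a [DecodeConfig-class].
#' @param nPerm permutations for the cluster nulls.
#' @param pointAlpha,clusterAlpha per-point and family-wise alphas.
#' @param seed master seed; every stage derives child seeds from it.
#' @param components character subset of
#'   \code{c("timecourse", "confusion", "difference", "crossdim",
#'   "crosstime", "previous", "behavior")} to run.
#' @return A list of class \code{"StudyConfig"}.
#' @export
StudyConfig <- function(synth = SynthConfig(), decode = DecodeConfig(),
                        nPerm = 1000L, pointAlpha = 0.05, clusterAlpha = 0.05,
                        seed = 1L,
                        components = c("timecourse", "confusion", "difference",
                                       "crossdim", "crosstime", "previous",
                                       "behavior")) {
  structure(list(synth = synth, decode = decode, nPerm = as.integer(nPerm),
                 pointAlpha = pointAlpha, clusterAlpha = clusterAlpha,
                 seed = as.integer(seed), components = components),
            class = "StudyConfig")
}

configFingerprint <- function(config) {
  enc <- function(x) {
    if (isVirtualClass(class(x)) || !isS4(x)) return(x)
    sl <- lapply(slotNames(class(x)), function(nm) slot(x, nm))
    names(sl) <- slotNames(class(x))
    sl
  }
  js <- jsonlite::toJSON(list(synth = enc(config$synth),
                              decode = enc(config$decode),
                              nPerm = config$nPerm,
                              pointAlpha = config$pointAlpha,
                              clusterAlpha = config$clusterAlpha,
                              seed = config$seed,
                              components = config$components),
                         auto_unbox = TRUE, digits = NA)
  configHash(as.character(js))
}

preprocessEpochs <- function(epochs, decode) {
  if (!is.na(decode@lowpassHz))
    epochs <- lowpassFilter(epochs, decode@lowpassHz)
  bw <- decode@baselineWindow
  if (!anyNA(bw)) {
    tm <- epochTimes(epochs)
    if (any(tm >= bw[1] & tm < bw[2]))
      epochs <- baselineCorrect(epochs, bw)
  }
  epochs
}

writeTsv <- function(x, path) {
  utils::write.table(x, path, sep = "\t", quote = FALSE, row.names = FALSE)
  path
}

clustersToList <- function(cs) {
  cl <- cs@clusters
  list(tail = cs@tail, pointAlpha = cs@pointAlpha,
       clusterAlpha = cs@clusterAlpha, df = cs@df,
       clusters = cl)
}

#' Run a complete synthetic decoding study
#'
#' End-to-end orchestration: simulate every participant, preprocess
#' (low-pass, baseline), decode face identity and facial expression
#' time courses (plus, per \code{components}: period confusion matrices,
#' the identity-vs-expression difference test, cross-dimension decoding,
#' temporal generalization, previous-trial decoding, and the behavioral
#' t / Bayes-factor report), run the cluster-based permutation tests, and
#' write a TSV/JSON report bundle. Deterministic given the master seed;
#' per-participant prediction stores are cached under
#' \code{file.path(outDir, "stores")} and reused when re-run with an
#' identical configuration fingerprint.
#'
#' @param config a [StudyConfig()].
#' @param outDir output directory (created if needed).
#' @param verbose log one line per participant and stage.
#' @return Invisibly, a list with the accuracy matrices, cluster results,
#'   and paths of everything written.
#' @export
runStudy <- function(config, outDir, verbose = FALSE) {
  stopifnot(inherits(config, "StudyConfig"))
  dir.create(outDir, showWarnings = FALSE, recursive = TRUE)
  storeDir <- file.path(outDir, "stores")
  dir.create(storeDir, showWarnings = FALSE)
  fp <- configFingerprint(config)
  comp <- config$components
  synth <- config$synth
  decode <- config$decode
  nP <- synth@nParticipants
  seeds <- deriveSeeds(config$seed, 3L * nP + 10L)
  log1 <- function(...) if (verbose) message(sprintf(...))

  dims <- c("identity", "expression")
  stores <- list(identity = vector("list", nP), expression = vector("list", nP),
                 prev_identity = vector("list", nP))
  xdim <- list(identity = vector("list", nP), expression = vector("list", nP))
  gen <- list(identity = vector("list", nP), expression = vector("list", nP))

  for (i in seq_len(nP)) {
    cachePath <- file.path(storeDir, sprintf("p%02d_%s.rds", i, fp))
    if (file.exists(cachePath)) {
      cached <- readRDS(cachePath)
      for (nm in names(cached$stores)) stores[[nm]][[i]] <- cached$stores[[nm]]
      for (nm in names(cached$xdim)) xdim[[nm]][[i]] <- cached$xdim[[nm]]
      for (nm in names(cached$gen)) gen[[nm]][[i]] <- cached$gen[[nm]]
      log1("participant %d: loaded cached stores", i)
      next
    }
    t0 <- proc.time()[3]
    topo <- makeTopographies(synth, seeds[3L * i - 2L])
    ep <- simulateParticipant(synth, topo, seeds[3L * i - 1L],
                              participantId = sprintf("sim%02d", i))
    ep <- preprocessEpochs(ep, decode)
    lab <- trialLabels(ep)
    dseed <- seeds[3L * i]
    cached <- list(stores = list(), xdim = list(), gen = list())
    for (dm in dims) {
      res <- decodeTimecourse(ep, collapseDimension(lab, dm), decode, dseed)
      stores[[dm]][[i]] <- cached$stores[[dm]] <- res$store
    }
    if ("previous" %in% comp) {
      rel <- relabelPreviousTrial(lab, "identity")
      sub <- EpochSet(ep@data[rel$keep, , , drop = FALSE], fs = ep@fs,
                      tStart = ep@tStart, channelNames = ep@channelNames,
                      participantId = ep@participantId,
                      labels = lab[rel$keep, , drop = FALSE])
      res <- decodeTimecourse(sub, rel$classLabels, decode, dseed)
      stores$prev_identity[[i]] <- cached$stores$prev_identity <- res$store
    }
    if ("crossdim" %in% comp) for (dm in dims) {
      other <- setdiff(dims, dm)
      res <- decodeCrossdim(ep, collapseDimension(lab, dm),
                            collapseDimension(lab, other), decode)
      xdim[[dm]][[i]] <- cached$xdim[[dm]] <- res$store
    }
    if ("crosstime" %in% comp) for (dm in dims) {
      gen[[dm]][[i]] <- cached$gen[[dm]] <-
        decodeCrosstime(ep, collapseDimension(lab, dm), decode, dseed)
    }
    saveRDS(cached, cachePath)
    log1("participant %d: simulated + decoded in %.1f s (seed lineage %d/%d/%d)",
         i, proc.time()[3] - t0, seeds[3L * i - 2L], seeds[3L * i - 1L], dseed)
  }

  times <- stores$identity[[1]]@times
  sm <- decode@smoothPoints
  accMat <- function(stl) t(vapply(stl, function(st)
    runningMean(colMeans(st@predicted == st@trueClass), sm),
    numeric(length(times))))
  out <- list(fingerprint = fp, seed = config$seed, paths = character(0))
  chance <- chanceLevel(decode)
  statSeed <- seeds[3L * nP + 1L]

  emitAcc <- function(mat, name) {
    df <- data.frame(participant = sprintf("sim%02d", seq_len(nrow(mat))), mat)
    names(df)[-1] <- sprintf("t%g", times)
    p <- writeTsv(df, file.path(outDir, paste0("accuracy_", name, ".tsv")))
    out$paths <<- c(out$paths, p)
  }

  if ("timecourse" %in% comp) {
    for (dm in dims) {
      acc <- accMat(stores[[dm]])
      emitAcc(acc, dm)
      ct <- clusterTestVsChance(stores[[dm]], mu = chance, nPerm = config$nPerm,
                                seed = statSeed, smoothPoints = sm,
                                pointAlpha = config$pointAlpha,
                                clusterAlpha = config$clusterAlpha)
      out[[paste0("clusters_", dm)]] <- ct$clusters
      p <- file.path(outDir, paste0("clusters_", dm, ".json"))
      jsonlite::write_json(c(list(config_hash = fp, seed = config$seed),
                             clustersToList(ct$clusters)),
                           p, auto_unbox = TRUE, digits = NA, dataframe = "rows")
      out$paths <- c(out$paths, p)
      out[[paste0("acc_", dm)]] <- acc
      log1("stats: %s vs chance, %d cluster(s)", dm, nrow(clusters(ct$clusters)))
    }
  }
  if ("difference" %in% comp && !is.null(out$acc_identity)) {
    ct <- clusterTestConditionDiff(out$acc_identity, out$acc_expression,
                                   times = times, nPerm = config$nPerm,
                                   seed = statSeed + 1L,
                                   pointAlpha = config$pointAlpha,
                                   clusterAlpha = config$clusterAlpha)
    out$clusters_difference <- ct$clusters
    p <- file.path(outDir, "clusters_difference.json")
    jsonlite::write_json(c(list(config_hash = fp, seed = config$seed,
                                positive_means = "identity > expression"),
                           clustersToList(ct$clusters)),
                         p, auto_unbox = TRUE, digits = NA, dataframe = "rows")
    out$paths <- c(out$paths, p)
  }
  if ("confusion" %in% comp) {
    for (dm in dims) {
      cms <- lapply(stores[[dm]], confusionByPeriod)
      for (pd in c("perception", "maintenance")) {
        avg <- Reduce(`+`, lapply(cms, `[[`, pd)) / length(cms)
        p <- writeTsv(as.data.frame(round(avg, 6)),
                      file.path(outDir, sprintf("confusion_%s_%s.tsv", dm, pd)))
        out$paths <- c(out$paths, p)
        out[[sprintf("confusion_%s_%s", dm, pd)]] <- avg
      }
    }
  }
  if ("crossdim" %in% comp && !is.null(xdim$identity[[1]])) {
    for (dm in dims) {
      acc <- accMat(xdim[[dm]])
      emitAcc(acc, paste0("crossdim_", dm))
      ct <- clusterTestVsChance(xdim[[dm]], mu = chance, nPerm = config$nPerm,
                                seed = statSeed + 2L, smoothPoints = sm,
                                pointAlpha = config$pointAlpha,
                                clusterAlpha = config$clusterAlpha)
      out[[paste0("clusters_crossdim_", dm)]] <- ct$clusters
      p <- file.path(outDir, sprintf("clusters_crossdim_%s.json", dm))
      jsonlite::write_json(c(list(config_hash = fp, seed = config$seed),
                             clustersToList(ct$clusters)),
                           p, auto_unbox = TRUE, digits = NA, dataframe = "rows")
      out$paths <- c(out$paths, p)
    }
  }
  if ("crosstime" %in% comp && !is.null(gen$identity[[1]])) {
    for (dm in dims) {
      avg <- Reduce(`+`, lapply(gen[[dm]], accuracy)) / nP
      df <- data.frame(trainWindow = gen[[dm]][[1]]@windowTimes, round(avg, 6))
      names(df)[-1] <- sprintf("test%g", gen[[dm]][[1]]@windowTimes)
      p <- writeTsv(df, file.path(outDir, sprintf("genmatrix_%s.tsv", dm)))
      out$paths <- c(out$paths, p)
      out[[paste0("gen_", dm)]] <- avg
    }
  }
  if ("previous" %in% comp && !is.null(stores$prev_identity[[1]])) {
    acc <- accMat(stores$prev_identity)
    emitAcc(acc, "previous_identity")
    ct <- clusterTestVsChance(stores$prev_identity, mu = chance,
                              nPerm = config$nPerm, seed = statSeed + 3L,
                              smoothPoints = sm,
                              pointAlpha = config$pointAlpha,
                              clusterAlpha = config$clusterAlpha)
    out$clusters_previous_identity <- ct$clusters
    p <- file.path(outDir, "clusters_previous_identity.json")
    jsonlite::write_json(c(list(config_hash = fp, seed = config$seed),
                           clustersToList(ct$clusters)),
                         p, auto_unbox = TRUE, digits = NA, dataframe = "rows")
    out$paths <- c(out$paths, p)
  }
  if ("behavior" %in% comp) {
    beh <- simulateBehavior(synth, seeds[3L * nP + 2L])
    tt <- oneSampleTTest(beh$idAcc - beh$exAcc, mu = 0, tail = "two")
    bf <- jzsBF01(tt$t, nrow(beh))
    rep <- list(config_hash = fp, seed = config$seed,
                t = tt$t, df = tt$df, p = tt$p, bf01 = bf)
    p <- file.path(outDir, "behavioral.json")
    jsonlite::write_json(rep, p, auto_unbox = TRUE, digits = NA)
    out$paths <- c(out$paths, p)
    out$behavioral <- rep
  }
  cfgPath <- file.path(outDir, "config.json")
  jsonlite::write_json(list(config_hash = fp, seed = config$seed,
                            synth = attributes(config$synth) [slotNames("SynthConfig")],
                            decode = attributes(config$decode)[slotNames("DecodeConfig")],
                            nPerm = config$nPerm,
                            pointAlpha = config$pointAlpha,
                            clusterAlpha = config$clusterAlpha,
                            components = config$components),
                       cfgPath, auto_unbox = TRUE, digits = NA)
  out$paths <- c(out$paths, cfgPath)
  invisible(out)
}
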