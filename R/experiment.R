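#' @include establishment.R
NULL

#' Derive a reproducible sub-seed
#'
#' Fixed splitting rule used to make grid points and replicates independent
#' given a master seed: a linear-congruential mix of the master seed and an
#' index, folded into the positive 32-bit integer range.
#'
#' @param master master seed (integer).
#' @param index nonnegative index (grid point, replicate, ...).
#' @return A single integer seed in \[1, 2^31 - 19\].
#' @export
subSeed <- function(master, index) {
  as.integer((as.numeric(master) %% 2147483629 * 69621 + index * 7919 +
                1) %% 2147483629 + 1)
}

fnvHash <- function(x) {
  bytes <- as.integer(serialize(x, NULL))
  h <- 5381
  for (b in bytes) h <- (h * 33 + b) %% 2147483647
  sprintf("%08x", as.integer(h))
}

knownConfigKeys <- list(
  top = c("architecture", "source", "island", "scan", "replicates", "seed",
          "tasks"),
  architecture = c("LA", "LR", "muA", "muR", "s", "h", "beta0", "s0Tilde"),
  source = c("rs", "N", "burnIn", "nSamples", "thin", "maxPairs", "IMax",
             "tol", "maxIter"),
  island = c("beta1", "s1Tilde", "r0", "K", "N0", "Tgen",
             "successFraction"),
  scan = c("param", "values"))

#' Read and validate an experiment configuration
#'
#' Configurations are flat YAML with blocks `architecture`, `source`,
#' optional `island`, optional `scan` (a parameter name plus a grid of
#' values), `tasks` (any of "ilec", "sim", "establish"), `replicates` and
#' `seed`. Unknown keys and out-of-range values raise a schema error naming
#' the offending keys.
#'
#' @param path path to a YAML file, or a list already in memory.
#' @return Validated config (classed list `ExperimentConfig`).
#' @export
readExperimentConfig <- function(path) {
  cfg <- if (is.character(path)) yaml::read_yaml(path) else path
  bad <- character()
  chk <- function(block, name) {
    if (is.null(block)) return()
    unknown <- setdiff(names(block), knownConfigKeys[[name]])
    if (length(unknown))
      bad <<- c(bad, paste0(name, ".", unknown))
  }
  unknown <- setdiff(names(cfg), knownConfigKeys$top)
  if (length(unknown)) bad <- c(bad, unknown)
  for (nm in c("architecture", "source", "island", "scan"))
    chk(cfg[[nm]], nm)
  if (length(bad))
    stop("unknown configuration keys: ", paste(bad, collapse = ", "))

  err <- character()
  if (is.null(cfg$architecture)) err <- c(err, "architecture (missing)")
  rs <- cfg$source$rs
  if (!is.null(rs) && (any(rs < 0) || any(rs > 1)))
    err <- c(err, "source.rs (must be in [0, 1])")
  if (!is.null(cfg$scan)) {
    if (is.null(cfg$scan$param) || is.null(cfg$scan$values) ||
        length(cfg$scan$values) == 0L)
      err <- c(err, "scan.values (empty grid)")
    else if (!cfg$scan$param %in% c("rs", unlist(knownConfigKeys[
      c("architecture", "island")])))
      err <- c(err, paste0("scan.param (unknown parameter '",
                           cfg$scan$param, "')"))
    if (identical(cfg$scan$param, "rs") &&
        (any(cfg$scan$values < 0) || any(cfg$scan$values > 1)))
      err <- c(err, "scan.values (rs must be in [0, 1])")
  }
  if (length(err))
    stop("invalid configuration values: ", paste(err, collapse = ", "))
  structure(cfg, class = "ExperimentConfig")
}

archFromConfig <- function(a) {
  architectureParams(LA = a$LA %||% 0, LR = a$LR %||% 0,
                     muA = a$muA %||% 0, muR = a$muR %||% 0,
                     s = a$s %||% 0, h = a$h %||% 0,
                     beta0 = a$beta0, s0Tilde = a$s0Tilde)
}

`%||%` <- function(x, y) if (is.null(x)) y else x

applyScan <- function(cfg, value) {
  p <- cfg$scan$param
  if (p == "rs") cfg$source$rs <- value
  else if (p %in% knownConfigKeys$architecture) cfg$architecture[[p]] <- value
  else cfg$island[[p]] <- value
  cfg
}

gridValues <- function(cfg)
  if (is.null(cfg$scan)) list(NA) else as.list(cfg$scan$values)

oneGridPoint <- function(cfg, value, seed) {
  if (!is.null(cfg$scan)) cfg <- applyScan(cfg, value)
  arch <- archFromConfig(cfg$architecture)
  rs <- cfg$source$rs %||% 0
  tasks <- cfg$tasks %||% "ilec"
  solver <- ilecSolverParams(IMax = cfg$source$IMax %||% 50,
                             tol = cfg$source$tol %||% 1e-12,
                             maxIter = cfg$source$maxIter %||% 1e6)
  row <- list(scanParam = cfg$scan$param %||% NA_character_,
              scanValue = if (is.null(cfg$scan)) NA_real_ else value,
              rs = rs, seed = seed)
  eq <- NULL
  if (any(c("ilec", "establish") %in% tasks)) {
    eq <- ilecEquilibrium(arch, sourceRegime(arch), rs, solver = solver)
    sm <- populationSummaries(eq, arch, sourceRegime(arch))
    v <- sm@values
    row <- c(row, as.list(stats::setNames(v, paste0("ilec_", names(v)))),
             list(ilec_iterations = eq@iterations,
                  ilec_converged = eq@converged))
  }
  if ("sim" %in% tasks) {
    set.seed(seed)
    pop <- initializePopulation(cfg$source$N %||% 1000, arch)
    st <- runToStationarity(pop, arch, sourceRegime(arch), rs,
                            burnIn = cfg$source$burnIn %||% 5000,
                            nSamples = cfg$source$nSamples %||% 20,
                            thin = cfg$source$thin %||% 100,
                            maxPairs = cfg$source$maxPairs %||% 2000)
    v <- st@values
    row <- c(row, as.list(stats::setNames(v, paste0("sim_", names(v)))),
             as.list(stats::setNames(st@se, paste0("se_", names(st@se)))))
  }
  if ("establish" %in% tasks) {
    isl <- islandParams(arch, rs = rs, beta1 = cfg$island$beta1,
                        s1Tilde = cfg$island$s1Tilde,
                        r0 = cfg$island$r0 %||% 1.1,
                        K = cfg$island$K %||% 1000,
                        N0 = cfg$island$N0 %||% 10,
                        Tgen = cfg$island$Tgen %||% 100,
                        successFraction = cfg$island$successFraction %||% 0.1)
    res <- estimateEstablishmentProbability(eq, arch, isl,
                                            R = cfg$replicates %||% 100,
                                            seed = seed)
    row <- c(row, list(pEst = res@pEst, pEstSE = res@se))
  }
  row
}

#' Run a configured experiment scan
#'
#' Executes the configured tasks (cohort-model solve, source simulation,
#' establishment estimate) at every grid point of the scan axis, writing
#' one TSV row per grid point with summary statistics and provenance
#' (config hash, sub-seed, package version). Grid points are independent
#' given their sub-seeds, so output is order-independent; a failing grid
#' point is recorded with a failure marker and the scan continues.
#'
#' @param config path to a YAML config or a list (see
#'   [readExperimentConfig()]).
#' @param outFile optional TSV output path.
#' @return data.frame of results, one row per grid point, invisibly when
#'   written to file.
#' @export
runExperiment <- function(config, outFile = NULL) {
  cfg <- readExperimentConfig(config)
  seed0 <- cfg$seed %||% 1
  hash <- fnvHash(unclass(cfg))
  vals <- gridValues(cfg)
  rows <- vector("list", length(vals))
  for (i in seq_along(vals)) {
    seed <- subSeed(seed0, i)
    rows[[i]] <- tryCatch({
      r <- oneGridPoint(cfg, vals[[i]], seed)
      c(r, list(status = "ok"))
    }, error = function(e)
      list(scanParam = cfg$scan$param %||% NA_character_,
           scanValue = if (is.null(cfg$scan)) NA_real_ else vals[[i]],
           seed = seed, status = paste0("FAILED: ", conditionMessage(e))))
  }
  allNames <- unique(unlist(lapply(rows, names)))
  tab <- do.call(rbind, lapply(rows, function(r) {
    r <- r[allNames]
    names(r) <- allNames
    as.data.frame(lapply(r, function(x) if (is.null(x)) NA else x))
  }))
  tab$configHash <- hash
  tab$masterSeed <- seed0
  tab$package <- as.character(utils::packageVersion("selfEstab"))
  if (!is.null(outFile)) {
    utils::write.table(tab, outFile, sep = "\t", row.names = FALSE,
                       quote = FALSE)
    return(invisible(tab))
  }
  tab
}

#' Compare cohort-model predictions with individual-based simulation
#'
#' For every selfing fraction in the grid, solves the cohort equilibrium
#' and runs the individual-based simulator with the same architecture, then
#' tabulates both estimates with the simulation standard error, the
#' deviation, and a tolerance flag. The tolerance combines the sampling
#' error of the simulation with a systematic allowance for finite-N effects
#' the deterministic model ignores: tol = 1.5 * (3 SE + relTol * |ilec| +
#' absTol).
#'
#' @param config path to YAML or list; must provide architecture and source
#'   blocks and an `rs` scan (or a single source.rs).
#' @param quantities which summary quantities to compare.
#' @param relTol,absTol systematic allowance (relative and absolute).
#' @return data.frame with one row per (rs, quantity).
#' @export
compareIlecVsSim <- function(config,
                             quantities = c("pA", "pR", "meanFitness",
                                            "delta", "idAA", "idRR",
                                            "idAR"),
                             relTol = 0.1, absTol = 0.005) {
  cfg <- readExperimentConfig(config)
  rsGrid <- if (!is.null(cfg$scan) && cfg$scan$param == "rs")
    cfg$scan$values else cfg$source$rs %||% 0
  seed0 <- cfg$seed %||% 1
  arch <- archFromConfig(cfg$architecture)
  out <- list()
  for (i in seq_along(rsGrid)) {
    rs <- rsGrid[i]
    ok <- tryCatch({
      eq <- ilecEquilibrium(arch, sourceRegime(arch), rs)
      ilecStats <- populationSummaries(eq, arch, sourceRegime(arch))
      set.seed(subSeed(seed0, i))
      pop <- initializePopulation(cfg$source$N %||% 1000, arch)
      simStats <- runToStationarity(pop, arch, sourceRegime(arch), rs,
                                    burnIn = cfg$source$burnIn %||% 5000,
                                    nSamples = cfg$source$nSamples %||% 20,
                                    thin = cfg$source$thin %||% 100,
                                    maxPairs = cfg$source$maxPairs %||% 2000)
      for (q in quantities) {
        iv <- unname(ilecStats@values[q])
        sv <- unname(simStats@values[q])
        se <- unname(simStats@se[q])
        dev <- abs(sv - iv)
        tol <- 1.5 * (3 * ifelse(is.na(se), 0, se) +
                        relTol * abs(iv) + absTol)
        out[[length(out) + 1L]] <- data.frame(
          rs = rs, quantity = q, ilec = iv, sim = sv, se = se,
          deviation = dev, tol = tol,
          flag = !is.na(dev) & !is.na(tol) & dev > tol)
      }
      TRUE
    }, error = function(e) {
      out[[length(out) + 1L]] <<- data.frame(
        rs = rs, quantity = "ERROR", ilec = NA_real_, sim = NA_real_,
        se = NA_real_, deviation = NA_real_, tol = NA_real_, flag = TRUE)
      FALSE
    })
  }
  do.call(rbind, out)
}
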