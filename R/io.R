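# Run configuration, serialisation and the command-line front end.
# Configurations are JSON (primary) or YAML; unknown keys are rejected so
# misspelled parameters cannot pass silently. CSV outputs use 17
# significant digits so a reload is lossless.

.specSchema <- list(
  dimension = NULL, shape = NULL, a = NULL, phenotypes = NULL,
  meanDensity = NULL, steps = NULL, seed = NULL,
  rule = c("name", "beta", "betaAgg", "betaAlign", "betaRest", "nCrit"),
  rates = c("birth", "death"),
  output = c("prefix"),
  analysis = c("qPoints", "restThreshold", "argTol")
)

#' Default run configuration
#'
#' @return a named list with every configuration key explicit: lattice
#'   geometry (`dimension`, `shape`, `a`, `phenotypes`), initial
#'   `meanDensity`, `rule` (name and sensitivities), demographic `rates`,
#'   `steps`, `seed`, `output` prefix and `analysis` options.
#' @export
defaultRunSpec <- function() {
  list(dimension = 1, shape = 100, a = 0, phenotypes = 1, meanDensity = 0.5,
       steps = 100, seed = 1,
       rule = list(name = "randomwalk"),
       rates = list(birth = 0, death = 0),
       output = list(prefix = "lgca_run"),
       analysis = list(qPoints = 256, restThreshold = 0.75, argTol = 1e-6))
}

#' Load, validate and save run configurations
#'
#' `loadRunSpec()` reads a JSON (`.json`) or YAML (`.yaml`/`.yml`)
#' configuration, rejects unknown keys (naming each offender), checks
#' required keys (`dimension`, `shape`, `steps`, `rule$name`) and fills
#' every remaining default, so the returned spec is fully explicit.
#' `saveRunSpec()` writes a spec as JSON; `loadRunSpec(saveRunSpec(x))`
#' round-trips losslessly.
#'
#' @param path file path.
#' @param spec a run configuration list.
#' @return `loadRunSpec()` the validated spec; `saveRunSpec()` the path,
#'   invisibly.
#' @export
loadRunSpec <- function(path) {
  if (!file.exists(path)) .lgcaStop("config", "config file '%s' not found", path)
  ext <- tolower(tools::file_ext(path))
  raw <- if (ext %in% c("yaml", "yml")) yaml::read_yaml(path)
         else jsonlite::read_json(path, simplifyVector = TRUE)
  validateRunSpec(raw)
}

#' @rdname loadRunSpec
#' @export
validateRunSpec <- function(spec) {
  problems <- character(0)
  unknown <- setdiff(names(spec), names(.specSchema))
  if (length(unknown))
    problems <- c(problems, sprintf("unknown key '%s'", unknown))
  for (grp in c("rule", "rates", "output", "analysis")) {
    if (!is.null(spec[[grp]])) {
      bad <- setdiff(names(spec[[grp]]), .specSchema[[grp]])
      if (length(bad))
        problems <- c(problems, sprintf("unknown key '%s$%s'", grp, bad))
    }
  }
  for (req in c("dimension", "shape", "steps"))
    if (is.null(spec[[req]]))
      problems <- c(problems, sprintf("missing required key '%s'", req))
  if (is.null(spec$rule$name))
    problems <- c(problems, "missing required key 'rule$name'")
  if (length(problems))
    .lgcaStop("config", "invalid run configuration: %s",
              paste(problems, collapse = "; "))
  def <- defaultRunSpec()
  for (k in setdiff(names(def), c("rule", "rates", "output", "analysis")))
    if (is.null(spec[[k]])) spec[[k]] <- def[[k]]
  for (grp in c("rates", "output", "analysis"))
    for (k in names(def[[grp]]))
      if (is.null(spec[[grp]][[k]])) spec[[grp]][[k]] <- def[[grp]][[k]]
  # canonical numeric storage so save/load round-trips are lossless
  for (k in c("dimension", "shape", "a", "phenotypes", "meanDensity",
              "steps", "seed"))
    if (!is.null(spec[[k]])) spec[[k]] <- as.numeric(spec[[k]])
  spec$rates <- lapply(spec$rates, as.numeric)
  spec$analysis <- lapply(spec$analysis, as.numeric)
  for (k in setdiff(names(spec$rule), "name"))
    spec$rule[[k]] <- as.numeric(spec$rule[[k]])
  spec[names(def)] <- spec[names(def)]   # canonical key order
  spec
}

#' @rdname loadRunSpec
#' @export
saveRunSpec <- function(spec, path) {
  jsonlite::write_json(spec, path, auto_unbox = TRUE, digits = NA,
                       pretty = TRUE)
  invisible(path)
}

# stable content hash of a spec for output provenance
.specHash <- function(spec) {
  tmp <- tempfile(fileext = ".json")
  on.exit(unlink(tmp))
  jsonlite::write_json(spec, tmp, auto_unbox = TRUE, digits = NA)
  unname(tools::md5sum(tmp))
}

.writeCsv <- function(x, path) {
  df <- as.data.frame(x)
  df[] <- lapply(df, function(col)
    if (is.numeric(col)) formatC(col, digits = 17, format = "g") else col)
  utils::write.csv(df, path, row.names = FALSE, quote = FALSE)
  invisible(path)
}

#' Export a simulated trajectory
#'
#' `exportKymograph()` writes the time x node total-density matrix of a
#' trajectory as CSV (`steps + 1` rows, one column per node).
#' `exportTrajectory()` additionally writes the per-axis flux kymographs,
#' the final channel-resolved occupancy matrix, and a JSON metadata
#' sidecar with the geometry, seed, time step and (if a spec is given) the
#' configuration hash.
#'
#' @param trajectory an [LGCATrajectory-class].
#' @param file,prefix output CSV path / path prefix.
#' @param spec optional run configuration recorded in the metadata.
#' @return the written path(s), invisibly.
#' @export
exportKymograph <- function(trajectory, file) {
  dens <- trajectory@density
  if (!nrow(dens)) .lgcaStop("config", "trajectory is empty")
  colnames(dens) <- paste0("node_", seq_len(ncol(dens)))
  .writeCsv(dens, file)
}

#' @rdname exportKymograph
#' @export
exportTrajectory <- function(trajectory, prefix, spec = NULL) {
  g <- trajectory@lattice@geometry
  paths <- character(0)
  paths <- c(paths, exportKymograph(trajectory, paste0(prefix, "_density.csv")))
  for (dd in seq_len(g@dimension)) {
    fx <- trajectory@flux[, , dd, drop = FALSE]
    dim(fx) <- dim(trajectory@flux)[1:2]
    colnames(fx) <- paste0("node_", seq_len(ncol(fx)))
    paths <- c(paths, .writeCsv(fx, sprintf("%s_flux_%s.csv", prefix,
                                            c("x", "y")[dd])))
  }
  occ <- trajectory@lattice@occupancy
  colnames(occ) <- paste0("channel_", seq_len(ncol(occ)))
  paths <- c(paths, .writeCsv(occ, paste0(prefix, "_occupancy.csv")))
  meta <- list(dimension = g@dimension, shape = g@shape, a = g@a, b = g@b,
               K = g@K, phenotypes = g@nPhenotypes,
               timeStep = trajectory@lattice@timeStep,
               seed = if (length(trajectory@seed)) trajectory@seed else NULL,
               configHash = if (!is.null(spec)) .specHash(spec) else NULL)
  metaPath <- paste0(prefix, "_meta.json")
  jsonlite::write_json(meta, metaPath, auto_unbox = TRUE, digits = NA,
                       null = "null")
  invisible(c(paths, metaPath))
}

#' Read a static environment field from CSV
#'
#' Attaches a scalar signal concentration or a vector field to a lattice
#' from a delimited text file with one row per node (row `i` = node `i`;
#' 2D nodes are numbered x-fastest). An optional `node` column gives
#' explicit node indices; the remaining column(s) are the scalar value or
#' the vector components.
#'
#' @param lattice an [LGCALattice-class].
#' @param path CSV file path.
#' @param type `"signal"` (scalar) or `"vector"`.
#' @return the lattice with the field attached.
#' @export
readEnvironmentField <- function(lattice, path, type = c("signal", "vector")) {
  type <- match.arg(type)
  df <- utils::read.csv(path)
  if ("node" %in% names(df)) {
    df <- df[order(df$node), , drop = FALSE]
    df$node <- NULL
  }
  if (nrow(df) != nNodes(lattice))
    .lgcaStop("config", "field file has %d rows, lattice has %d nodes",
              nrow(df), nNodes(lattice))
  if (type == "signal") {
    signalField(lattice) <- df[[1L]]
  } else {
    d <- lattice@geometry@dimension
    if (ncol(df) < d)
      .lgcaStop("config", "vector field needs %d component column(s)", d)
    vectorField(lattice) <- as.matrix(df[, seq_len(d), drop = FALSE])
  }
  lattice
}

.cliUsage <- function() {
  paste(
    "usage: biolgca <subcommand> [options]",
    "",
    "subcommands:",
    "  simulate       --config FILE [--seed N] [--out PREFIX] [--verbose N]",
    "  meanfield      --beta-rho X [--a N] [--out FILE]",
    "  phase-diagram  [--rho X] [--a N] [--n-crit X] [--beta-max X]",
    "                 [--grid N] [--beta-rest X,Y] [--out FILE]",
    "  derive-rule    --autocorrelation FILE --i0 N --dimension D --out FILE",
    "                 | --observable U1,U2,... --targets FILE --out FILE",
    "  fixtures       --dimension D --shape N[,M] [--a N] [--density X]",
    "                 [--seed N] [--out FILE]",
    sep = "\n")
}

.parseCliOptions <- function(args) {
  opts <- list()
  i <- 1L
  while (i <= length(args)) {
    key <- args[i]
    if (!startsWith(key, "--"))
      .lgcaStop("config", "unexpected argument '%s'", key)
    key <- sub("^--", "", key)
    key <- gsub("-(.)", "\\U\\1", key, perl = TRUE)   # kebab -> camel
    if (i == length(args) || startsWith(args[i + 1L], "--"))
      .lgcaStop("config", "option --%s needs a value", key)
    opts[[key]] <- args[i + 1L]
    i <- i + 2L
  }
  opts
}

.optNum <- function(opts, key, default = NULL) {
  if (is.null(opts[[key]])) return(default)
  as.numeric(strsplit(opts[[key]], ",")[[1]])
}

.cliSimulate <- function(opts) {
  if (is.null(opts$config)) .lgcaStop("config", "simulate needs --config")
  spec <- loadRunSpec(opts$config)
  if (!is.null(opts$seed)) spec$seed <- as.integer(opts$seed)
  prefix <- opts$out %||% spec$output$prefix
  verbose <- .optNum(opts, "verbose", 0)
  lat <- createLattice(spec$dimension, spec$shape, a = spec$a %||% 0,
                       phenotypes = spec$phenotypes %||% 1)
  lat <- initializeRandom(lat, spec$meanDensity, seed = spec$seed)
  rule <- makeRule(spec$rule$name, spec$rule)
  rates <- demographicRates(spec$rates$birth, spec$rates$death)
  tr <- lgcaRun(lat, rule, steps = spec$steps, rates = rates,
                seed = spec$seed)
  if (verbose > 0) {
    dens <- trajectoryDensity(tr)
    mfl <- apply(trajectoryFlux(tr), 1, function(m) mean(abs(m)))
    for (k in seq_len(nrow(dens)))
      message(sprintf("step=%d cells=%d meanAbsFlux=%.6g",
                      k - 1L, sum(dens[k, ]), mfl[k]))
  }
  exportTrajectory(tr, prefix, spec = spec)
  message(sprintf("simulate: %d steps, %d cells final, seed %s, outputs '%s_*'",
                  spec$steps, sum(cellCounts(finalLattice(tr))),
                  format(spec$seed), prefix))
  0L
}

.cliMeanfield <- function(opts) {
  betaRho <- .optNum(opts, "betaRho")
  if (is.null(betaRho)) .lgcaStop("config", "meanfield needs --beta-rho")
  a <- .optNum(opts, "a", 2)
  out <- opts$out %||% "meanfield.csv"
  crit <- adhesionCritical(betaRho)
  kappa <- seq(0, pi, length.out = 181)
  tab <- data.frame(kappa = kappa,
                    growthFactor = adhesionGrowthRate(kappa, betaRho, 1, a),
                    betaRho = betaRho, kappaC = crit$kappaC,
                    lambdaC = crit$lambdaC, unstable = crit$unstable)
  .writeCsv(tab, out)
  message(sprintf("meanfield: betaRho=%g unstable=%s lambdaC=%g -> %s",
                  betaRho, crit$unstable, crit$lambdaC, out))
  0L
}

.cliPhaseDiagram <- function(opts) {
  out <- opts$out %||% "phase_diagram.csv"
  n <- .optNum(opts, "grid", 20)
  bmax <- .optNum(opts, "betaMax", 6)
  a <- .optNum(opts, "a", 1)
  tab <- phaseDiagram(betaAgg = seq(0, bmax, length.out = n),
                      betaAlign = seq(0, bmax, length.out = n),
                      betaRest = .optNum(opts, "betaRest", c(0.5, 8)),
                      rhoBar = .optNum(opts, "rho", 0.2),
                      a = a, nCrit = .optNum(opts, "nCrit", a + 2))
  .writeCsv(tab, out)
  message(sprintf("phase-diagram: %d points, phases {%s} -> %s", nrow(tab),
                  paste(sort(unique(tab$phase)), collapse = ", "), out))
  0L
}

.cliDeriveRule <- function(opts) {
  out <- opts$out %||% "derived_rule.csv"
  if (!is.null(opts$autocorrelation)) {
    df <- utils::read.csv(opts$autocorrelation)
    d <- .optNum(opts, "dimension", 2)
    lat <- createLattice(d, if (d == 1) 8 else c(8, 8))
    P <- persistenceFromAutocorrelation(df[[2L]], i0 = .optNum(opts, "i0", 1),
                                        geom = geometry(lat))
    .writeCsv(cbind(step = df[[1L]], P), out)
    message(sprintf("derive-rule: %d-step persistence probabilities -> %s",
                    nrow(P), out))
  } else if (!is.null(opts$observable)) {
    if (is.null(opts$targets))
      .lgcaStop("config", "derive-rule needs --targets with --observable")
    u <- .optNum(opts, "observable")
    df <- utils::read.csv(opts$targets)
    beta <- maxcalMultipliers(u, df[[ncol(df)]])
    .writeCsv(data.frame(step = seq_along(beta) - 1L, beta = beta), out)
    message(sprintf("derive-rule: %d fitted multiplier(s) -> %s",
                    length(beta), out))
  } else {
    .lgcaStop("config", "derive-rule needs --autocorrelation or --observable")
  }
  0L
}

.cliFixtures <- function(opts) {
  d <- .optNum(opts, "dimension", 1)
  shape <- .optNum(opts, "shape", 100)
  lat <- createLattice(d, shape, a = .optNum(opts, "a", 0))
  lat <- initializeRandom(lat, .optNum(opts, "density", 1),
                          seed = .optNum(opts, "seed", 1))
  out <- opts$out %||% "fixture_occupancy.csv"
  occ <- latticeOccupancy(lat)
  colnames(occ) <- paste0("channel_", seq_len(ncol(occ)))
  .writeCsv(occ, out)
  message(sprintf("fixtures: %d nodes, %d cells -> %s", nNodes(lat),
                  sum(occ == "1" | occ == 1), out))
  0L
}

#' Command-line entry point
#'
#' Dispatches the subcommands `simulate`, `meanfield`, `phase-diagram`,
#' `derive-rule` and `fixtures` (see `inst/scripts/biolgca.R` for the
#' Rscript wrapper). Returns an exit status instead of quitting so it can
#' be called programmatically: 0 on success, 1 on error, 2 on usage
#' problems.
#'
#' @param args character vector of command-line arguments.
#' @return integer exit status.
#' @export
cliMain <- function(args = commandArgs(trailingOnly = TRUE)) {
  if (!length(args)) { message(.cliUsage()); return(2L) }
  sub <- args[1L]
  handler <- switch(sub,
    "simulate" = .cliSimulate, "meanfield" = .cliMeanfield,
    "phase-diagram" = .cliPhaseDiagram, "derive-rule" = .cliDeriveRule,
    "fixtures" = .cliFixtures, NULL)
  if (is.null(handler)) { message(.cliUsage()); return(2L) }
  tryCatch({
    opts <- .parseCliOptions(args[-1L])
    handler(opts)
  }, error = function(e) {
    message("error: ", conditionMessage(e))
    1L
  })
}
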