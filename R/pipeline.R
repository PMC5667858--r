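## End-to-end orchestration: simulate -> collective dynamics -> PRS ->
## conservation/coupling -> networks -> rigidity, with a flat config, a run
## manifest and a TSV/JSON report bundle.  Reruns from a manifest are
## bit-identical: every stochastic stage re-seeds from the manifest seed.

#' Default pipeline configuration
#'
#' All stage parameters with their standard defaults (contact cutoffs 8 A
#' for the square-well model and 7.0 A for the elastic network, well
#' half-widths 0.05/0.1, H-bond energy cutoff -1.0 kcal/mol, hydrophobic
#' margin 0.25 A, community stability 0.75, alignment coverage 0.5).
#'
#' @return named list of parameters
#' @export
defaultConfig <- function() {
  list(
    seed = 1, out_dir = "allodyn_run",
    stages = c("simulate", "enm", "prs", "conserve", "network", "rigidity"),
    synthetic = "two-lobe", n1 = 20, n2 = 20,
    pdb = NULL, chain = NULL, msa = NULL,
    n_events = 200000, temperature = 1, nu = 1, snapshot_every = 1000,
    rc_dmd = 8, sigma_bond = 0.05, sigma_native = 0.1, dhc = 4,
    rc_gnm = 7, n_modes = 10,
    ca_cutoff = 7.5, i_min = 3, occupancy_min = 0.5,
    stability_min = 0.75, n_stability_frames = 8, k_clique = 3,
    coverage_min = 0.5, msa_nseq = 200, msa_ncol = 40,
    e_cut_hb = -1, d_cut_hp = 0.25,
    rigidity_fixture_nres = 12, rigidity_conformers = 5,
    rigidity_jitter = 0.03)
}

.mergeConfig <- function(config) {
  cfg <- defaultConfig()
  for (nm in names(config)) cfg[[nm]] <- config[[nm]]
  cfg
}

.writeTsv <- function(df, path) {
  write.table(df, path, sep = "\t", quote = FALSE, row.names = FALSE)
  path
}

#' Run the full analysis pipeline
#'
#' Executes the enabled stages on either a PDB input or the synthetic
#' two-lobe system, writing a report bundle (trajectory, per-residue TSV
#' tracks, edge lists, communities JSON, weak spots) plus a manifest holding
#' every parameter and seed.  Deterministic given the config.
#'
#' @param config named list; see \code{defaultConfig} for keys.  Unknown
#'   keys are rejected.
#' @return invisible list of the computed objects and output paths
#' @export
runPipeline <- function(config = list()) {
  bad <- setdiff(names(config), names(defaultConfig()))
  if (length(bad))
    stop("unknown config key(s): ", paste(bad, collapse = ", "),
         call. = FALSE)
  cfg <- .mergeConfig(config)
  dir.create(cfg$out_dir, showWarnings = FALSE, recursive = TRUE)
  out <- list(config = cfg)
  stage <- function(name) name %in% cfg$stages
  fail <- function(name, msg) stop(sprintf("stage '%s' failed: %s",
                                           name, msg), call. = FALSE)

  ## input structure
  trace <- NULL
  if (!is.null(cfg$pdb)) {
    if (!file.exists(cfg$pdb))
      fail("input", paste("PDB file not found:", cfg$pdb))
    structs <- readPdb(readLines(cfg$pdb))
    trace <- extractCaTrace(structs[[1]], chain = cfg$chain)
  } else if (identical(cfg$synthetic, "two-lobe")) {
    trace <- makeTwoLobeToy(cfg$n1, cfg$n2, seed = cfg$seed)
  } else if (identical(cfg$synthetic, "helix")) {
    trace <- makeHelix(cfg$n1)
  }
  if (is.null(trace)) fail("input", "no PDB path and no synthetic spec")
  out$trace <- trace

  ensemble <- NULL
  if (stage("simulate")) {
    model <- buildGoModel(trace, rc = cfg$rc_dmd, sigmaBond = cfg$sigma_bond,
                          sigmaNative = cfg$sigma_native, dhc = cfg$dhc)
    ensemble <- runDmd(model, trace, nEvents = cfg$n_events,
                       temperature = cfg$temperature, nu = cfg$nu,
                       snapshotEvery = cfg$snapshot_every,
                       seed = cfg$seed)
    writeTrajectory(ensemble, "xyz",
                    file = file.path(cfg$out_dir, "trajectory.xyz"))
    writeResidueProfile(computeBfactors(ensemble),
                        file.path(cfg$out_dir, "bfactors.tsv"))
    out$model <- model
    out$ensemble <- ensemble
  }

  if (stage("enm")) {
    gamma <- buildKirchhoff(trace, rc = cfg$rc_gnm)
    modes <- gnmModes(gamma)
    m <- min(cfg$n_modes, length(modes@values) - modes@nZero)
    mob <- mobilityProfile(modes, m = m, ids = trace@ids)
    writeResidueProfile(mob, file.path(cfg$out_dir, "mobility.tsv"))
    hinges <- identifyHinges(mob)
    .writeTsv(data.frame(residue = hinges),
              file.path(cfg$out_dir, "hinges.tsv"))
    out$kirchhoff <- gamma; out$modes <- modes
    out$mobility <- mob; out$hinges <- hinges
    if (!is.null(ensemble) && nFrames(ensemble) >= 10) {
      pca <- pcaEnsemble(ensemble)
      writeResidueProfile(pca$residueDisplacement,
                          file.path(cfg$out_dir, "pca_displacement.tsv"))
      .writeTsv(data.frame(component = seq_along(pca$eigenvalues),
                           variance_fraction = pca$varianceFraction,
                           cumulative = pca$cumulativeVariance),
                file.path(cfg$out_dir, "pca_variance.tsv"))
      out$pca <- pca
    }
  }

  if (stage("prs")) {
    if (is.null(out$kirchhoff)) out$kirchhoff <- buildKirchhoff(trace,
                                                               cfg$rc_gnm)
    S <- prsScan(out$kirchhoff)
    eff <- effectorProfile(S, ids = trace@ids)
    sen <- sensorProfile(S, ids = trace@ids)
    writeResidueProfile(eff, file.path(cfg$out_dir, "effector.tsv"))
    writeResidueProfile(sen, file.path(cfg$out_dir, "sensor.tsv"))
    write.table(S@mat, file.path(cfg$out_dir, "prs_matrix.tsv"),
                sep = "\t", quote = FALSE,
                row.names = FALSE, col.names = FALSE)
    out$prs <- S; out$effector <- eff; out$sensor <- sen
  }

  if (stage("conserve")) {
    msa <- if (!is.null(cfg$msa)) readMsa(cfg$msa)
           else makeSyntheticMsa(cfg$msa_nseq, cfg$msa_ncol,
                                 conservedCols = c(5, 17),
                                 covaryingPairs = list(c(9, 28)),
                                 seed = cfg$seed + 1)
    msa <- filterMsa(msa, minCoverage = cfg$coverage_min)
    kl <- klConservation(msa)
    writeResidueProfile(kl, file.path(cfg$out_dir, "kl_conservation.tsv"))
    mi <- columnMi(msa, weighting = nrow(msa@seqs) <= 500)
    pairs <- which(upper.tri(mi@mat) & !is.na(mi@mat), arr.ind = TRUE)
    .writeTsv(data.frame(i = pairs[, 1], j = pairs[, 2],
                         mi = mi@mat[pairs]),
              file.path(cfg$out_dir, "mi_pairs.tsv"))
    out$msa <- msa; out$kl <- kl; out$mi <- mi
  }

  if (stage("network")) {
    if (is.null(ensemble))
      fail("network", "requires the simulate stage (needs an ensemble)")
    rmi <- dynamicRmi(ensemble)
    rin <- buildRin(ensemble, rmi, mode = "ca_contact",
                    caCutoff = cfg$ca_cutoff,
                    occupancyMin = cfg$occupancy_min)
    writeGraph(rin, file.path(cfg$out_dir, "edges.tsv"))
    paths <- shortestPaths(rin)
    nb <- nodeBetweenness(rin, paths)
    eb <- edgeBetweenness(rin, paths)
    .writeTsv(cbind(trace@ids, betweenness = nb),
              file.path(cfg$out_dir, "node_betweenness.tsv"))
    .writeTsv(cbind(rin@edges[, c("i", "j")], betweenness = eb),
              file.path(cfg$out_dir, "edge_betweenness.tsv"))
    gn <- girvanNewman(rin)
    kc <- kCliqueCommunities(rin, k = cfg$k_clique)
    ## per-frame partitions on a thinned frame set for the stability rule
    nf <- nFrames(ensemble)
    sel <- unique(round(seq(1, nf, length.out = min(cfg$n_stability_frames,
                                                    nf))))
    parts <- lapply(sel, function(f) {
      sub <- .newEnsemble(ensemble@coords[f, , , drop = FALSE],
                          trace, times = 1)
      girvanNewman(buildRin(sub, rmi, caCutoff = cfg$ca_cutoff,
                            occupancyMin = 0.5))
    })
    stab <- communityStability(parts, stabilityMin = cfg$stability_min)
    comm <- list(
      girvan_newman = list(modularity = gn@modularity,
                           communities = gn@communities),
      k_clique = list(k = cfg$k_clique, communities = kc@communities),
      stable = list(threshold = cfg$stability_min,
                    communities = stab@communities,
                    frequency = stab@stability))
    jsonlite::write_json(comm, file.path(cfg$out_dir, "communities.json"),
                         auto_unbox = TRUE, digits = NA)
    out$rmi <- rmi; out$rin <- rin; out$paths <- paths
    out$nodeBetweenness <- nb; out$edgeBetweenness <- eb
    out$communities <- gn; out$kClique <- kc; out$stable <- stab
  }

  if (stage("rigidity")) {
    structs <- NULL
    if (!is.null(cfg$pdb)) {
      all <- readPdb(readLines(cfg$pdb))
      if (!any(all[[1]]@atoms$element == "H"))
        fail("rigidity",
             "all-atom input with hydrogens required (or use the synthetic helix fixture)")
      structs <- all
    } else {
      base <- makeAllAtomHelix(cfg$rigidity_fixture_nres)
      structs <- lapply(seq_len(cfg$rigidity_conformers), function(k) {
        s <- base
        .withSeed(cfg$seed + 100 + k, {
          s@atoms[, c("x", "y", "z")] <- s@atoms[, c("x", "y", "z")] +
            matrix(rnorm(nrow(s@atoms) * 3, sd = cfg$rigidity_jitter),
                   ncol = 3)
        })
        s
      })
    }
    dil <- lapply(structs, function(s)
      hbDilution(buildConstraintNetwork(
        s, detectHbonds(s), detectHydrophobic(s, dCut = cfg$d_cut_hp),
        eCut = cfg$e_cut_hb)))
    nRes <- length(unique(paste(structs[[1]]@atoms$chain,
                                structs[[1]]@atoms$resno,
                                structs[[1]]@atoms$icode)))
    ws <- weakSpotFrequency(dil, nRes)
    .writeTsv(cbind(ws@ids, frequency = ws@frequency, rank = ws@rank),
              file.path(cfg$out_dir, "weak_spots.tsv"))
    .writeTsv(data.frame(step = seq_along(dil[[1]]@giantSize) - 1,
                         giant_size = dil[[1]]@giantSize),
              file.path(cfg$out_dir, "dilution.tsv"))
    out$dilution <- dil; out$weakSpots <- ws
  }

  manifest <- cfg
  manifest$package_version <- as.character(utils::packageVersion("AlloDyn"))
  jsonlite::write_json(manifest, file.path(cfg$out_dir, "manifest.json"),
                       auto_unbox = TRUE, digits = NA, null = "null")
  invisible(out)
}

#' Re-run a pipeline from a manifest
#'
#' @param path path to a manifest.json written by \code{runPipeline}
#' @param out_dir optional new output directory
#' @return as \code{runPipeline}
#' @export
runFromManifest <- function(path, out_dir = NULL) {
  cfg <- jsonlite::read_json(path, simplifyVector = TRUE)
  cfg$package_version <- NULL
  if (!is.null(out_dir)) cfg$out_dir <- out_dir
  cfg <- cfg[!vapply(cfg, is.null, logical(1))]
  runPipeline(cfg)
}

.cliUsage <- function() {
  cat("usage: allodyn <simulate|enm|prs|conserve|network|rigidity|all>",
      "[--seed N] [--out DIR] [--config FILE] [--synthetic two-lobe|helix]",
      "[--n1 N] [--n2 N] [--pdb FILE] [--chain C] [--msa FILE]",
      "[--events N] [--rc X]\n")
}

#' Command-line entry point
#'
#' Thin argv-level front end over \code{runPipeline}; see
#' \code{inst/scripts/allodyn.R} for the Rscript wrapper.
#'
#' @param args character vector of command-line arguments
#' @return integer exit status (0 on success)
#' @export
pipelineCli <- function(args) {
  if (!length(args)) { .cliUsage(); return(1L) }
  sub <- args[1]
  allStages <- c("simulate", "enm", "prs", "conserve", "network", "rigidity")
  if (!sub %in% c(allStages, "all")) {
    message("unknown subcommand: ", sub); .cliUsage(); return(1L)
  }
  cfg <- list()
  i <- 2
  flagMap <- c("--seed" = "seed", "--out" = "out_dir",
               "--synthetic" = "synthetic", "--n1" = "n1", "--n2" = "n2",
               "--pdb" = "pdb", "--chain" = "chain", "--msa" = "msa",
               "--events" = "n_events", "--rc" = "rc_gnm")
  while (i <= length(args)) {
    flag <- args[i]
    if (flag == "--config") {
      cfgFile <- jsonlite::read_json(args[i + 1], simplifyVector = TRUE)
      for (nm in names(cfgFile)) cfg[[nm]] <- cfgFile[[nm]]
      i <- i + 2; next
    }
    if (!flag %in% names(flagMap)) {
      message("unknown flag: ", flag); .cliUsage(); return(1L)
    }
    if (i + 1 > length(args)) {
      message("missing value for ", flag); .cliUsage(); return(1L)
    }
    val <- args[i + 1]
    key <- flagMap[[flag]]
    if (key %in% c("seed", "n1", "n2", "n_events")) val <- as.numeric(val)
    if (key == "rc_gnm") val <- as.numeric(val)
    cfg[[key]] <- val
    i <- i + 2
  }
  cfg$stages <- if (sub == "all") allStages
                else if (sub == "network") c("simulate", "network")
                else sub
  status <- tryCatch({
    message("AlloDyn pipeline: stages ", paste(cfg$stages, collapse = ", "),
            ", seed ", cfg$seed %||% defaultConfig()$seed)
    runPipeline(cfg)
    0L
  }, error = function(e) {
    message("error: ", conditionMessage(e))
    1L
  })
  status
}
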