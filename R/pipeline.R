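# Orchestration: run the full analysis (simulate -> associate -> concord ->
# enrich -> coevolve) from one validated config, writing TSV outputs and a
# manifest. Stage seeds are derived from the master seed by a fixed
# splitting rule so stages can be re-run in isolation.

STAGE_NAMES <- c("simulate", "associate", "concord", "enrich", "coevolve")

# documented seed split: offset per stage, modulo the 32-bit integer range
STAGE_OFFSETS <- c(simulate = 101L, trees = 211L, trait = 307L,
                   expression = 401L, partner = 503L, promoters = 601L,
                   library = 701L, motif = 809L, decoy = 907L)

#' Derive a stage seed from the master seed
#' @param master master integer seed.
#' @param stage one of the documented stage labels.
#' @return an integer seed below 2^31.
#' @export
deriveSeed <- function(master, stage) {
  off <- STAGE_OFFSETS[[stage]]
  as.integer((as.numeric(master) * 1009 + off * 9176) %% 2147483647)
}

configError <- function(...) {
  stop(errorCondition(paste0(...), class = c("lifecon_config_error",
                                             "error", "condition")))
}

dataError <- function(...) {
  stop(errorCondition(paste0(...), class = c("lifecon_data_error",
                                             "error", "condition")))
}

defaultConfig <- function() {
  list(
    seed = 1L, out_dir = "lifecon_run",
    stages = c("simulate", "associate", "concord"),
    simulate = list(n_species = 29L, n_genes = 2000L, n_planted = 200L,
                    effect_slope = 1, phylo_noise_sd = 0.12,
                    iid_noise_sd = 0.46, missing_rate = 0.1,
                    concordance_target = 3, partner_size = 300L,
                    n_trees = 10L),
    associate = list(methods = c("spearman", "pgls"), fdr = 0.10,
                     min_species = 10L),
    concord = list(fdr = 0.05),
    enrich = list(fdr = 0.05, n_terms = 20L, term_size = 50L),
    coevolve = list(n_set_genes = 30L, n_bg_genes = 120L,
                    promoter_length = 1000L, motif_width = 8L,
                    max_insertions = 5L, fdr = 0.05, p_threshold = 1e-4),
    inputs = list())
}

mergeConfig <- function(user, defaults) {
  for (nm in names(user)) {
    if (is.list(user[[nm]]) && is.list(defaults[[nm]]))
      defaults[[nm]] <- mergeConfig(user[[nm]], defaults[[nm]])
    else defaults[[nm]] <- user[[nm]]
  }
  defaults
}

validateConfig <- function(cfg) {
  known <- c("seed", "out_dir", "stages", "inputs", STAGE_NAMES)
  unknown <- setdiff(names(cfg), known)
  if (length(unknown))
    configError("unknown config key(s): ", paste(unknown, collapse = ", "))
  bad <- setdiff(cfg$stages, STAGE_NAMES)
  if (length(bad))
    configError("unknown stage(s): ", paste(bad, collapse = ", "))
  if (!length(cfg$stages)) configError("no stages enabled")
  sim <- "simulate" %in% cfg$stages
  if ("associate" %in% cfg$stages && !sim &&
      is.null(cfg$inputs$expression))
    configError("associate enabled but no expression input and no ",
                "simulate stage")
  if ("concord" %in% cfg$stages && !sim &&
      is.null(cfg$inputs$partner_set))
    configError("concord enabled but no partner-set input and no ",
                "simulate stage")
  if ("concord" %in% cfg$stages && !"associate" %in% cfg$stages)
    configError("concord requires the associate stage")
  if ("enrich" %in% cfg$stages && !"associate" %in% cfg$stages)
    configError("enrich requires the associate stage")
  if ("coevolve" %in% cfg$stages && !"associate" %in% cfg$stages)
    configError("coevolve requires the associate stage")
  invisible(cfg)
}

writeResultTsv <- function(df, path, params = character()) {
  con <- file(path, "w")
  on.exit(close(con))
  writeLines(tsvHeaderComment(params), con)
  suppressWarnings(utils::write.table(df, con, sep = "\t", quote = FALSE,
                                      row.names = FALSE))
  path
}

countRows <- function(path) {
  lines <- readLines(path)
  sum(!startsWith(lines, "#")) - 1L   # minus the column header
}

#' Run the analysis pipeline from a config
#'
#' Executes the enabled stages in dependency order. With the `simulate`
#' stage enabled, all inputs are generated synthetically (deterministically
#' from the master seed); otherwise file paths under `inputs:` are read.
#' Every stage writes TSV outputs into `out_dir` and the run is summarized
#' in `manifest.yaml` (config snapshot, tool version, per-stage outputs
#' with row counts, derived seeds, timestamps). Re-running an identical
#' config reproduces byte-identical TSVs.
#'
#' @param config path to a YAML config file, or an equivalent named list.
#'   Unknown keys, unknown stages and missing stage inputs raise a config
#'   error before any computation.
#' @param outDir overrides the config's `out_dir`.
#' @return the manifest, invisibly.
#' @export
runPipeline <- function(config, outDir = NULL) {
  user <- if (is.character(config)) yaml::read_yaml(config) else config
  if (!is.list(user)) configError("config must be a file path or a list")
  cfg <- mergeConfig(user, defaultConfig())
  if (!is.null(outDir)) cfg$out_dir <- outDir
  validateConfig(cfg)
  dir.create(cfg$out_dir, showWarnings = FALSE, recursive = TRUE)
  master <- as.integer(cfg$seed)
  manifest <- list(tool = "lifecon",
                   version = as.character(utils::packageVersion("lifecon")),
                   config = cfg, seeds = list(master = master),
                   started = format(Sys.time(), usetz = TRUE),
                   stages = list())
  out <- function(f) file.path(cfg$out_dir, f)
  state <- list()

  record <- function(stage, files) {
    manifest$stages[[stage]] <<- list(
      outputs = files,
      rows = vapply(files, countRows, integer(1)),
      at = format(Sys.time(), usetz = TRUE))
    message("[lifecon] stage ", stage, " done: ",
            paste(basename(files), collapse = ", "))
  }

  # ---- simulate ----------------------------------------------------------
  if ("simulate" %in% cfg$stages) {
    s <- cfg$simulate
    scfg <- simulationConfig(
      n_species = s$n_species, n_genes = s$n_genes,
      n_planted = s$n_planted, effect_slope = s$effect_slope,
      phylo_noise_sd = s$phylo_noise_sd, iid_noise_sd = s$iid_noise_sd,
      missing_rate = s$missing_rate,
      concordance_target = s$concordance_target,
      partner_size = s$partner_size,
      seed = deriveSeed(master, "expression"))
    manifest$seeds$simulate <- scfg$seed
    trees <- lapply(seq_len(s$n_trees), function(i)
      simulateTree(s$n_species, seed = deriveSeed(master, "trees") + i))
    trait <- simulateTraitBm(trees[[1L]], sigma = scfg$trait_sigma,
                             rootValue = scfg$trait_root,
                             seed = deriveSeed(master, "trait"))
    sim <- simulateExpression(scfg, trees[[1L]], trait)
    partner <- simulateSignedPartnerSet(
      rownames(sim$expr), sim$planted, s$concordance_target,
      s$partner_size, seed = deriveSeed(master, "partner"))
    state$expr <- sim$expr
    state$species <- sim$species
    state$trees <- trees
    state$planted <- sim$planted
    state$partner <- partner
    files <- c(writeExpressionTsv(sim$expr, out("expression.tsv")),
               writeSpeciesTable(sim$species, out("species.tsv")),
               writeNewickEnsemble(trees, out("trees.nwk")),
               writeSignedGeneSet(sim$planted, out("truth_genes.tsv")),
               writeSignedGeneSet(partner, out("partner_set.tsv")))
    record("simulate", files)
  } else {
    ins <- cfg$inputs
    for (f in c("expression", "species"))
      if (is.null(ins[[f]]))
        configError("associate needs inputs$", f)
    if (!file.exists(ins$expression))
      dataError("missing input file: ", ins$expression)
    state$expr <- readExpressionTsv(ins$expression)
    state$species <- readSpeciesTable(ins$species)
    if (!is.null(ins$trees)) state$trees <- readNewickEnsemble(ins$trees)
    if (!is.null(ins$partner_set))
      state$partner <- readSignedGeneSet(ins$partner_set)
  }

  # ---- associate ---------------------------------------------------------
  if ("associate" %in% cfg$stages) {
    a <- cfg$associate
    mls <- setNames(state$species$mls_years, state$species$species_id)
    methods <- intersect(a$methods, c("spearman", "pgls"))
    if (!length(methods)) configError("no valid associate method")
    if ("pgls" %in% methods && is.null(state$trees))
      configError("pgls requested but no tree ensemble available")
    tab <- associateMLS(state$expr, mls, trees = state$trees,
                        methods = methods, minSpecies = a$min_species,
                        fdrLevel = a$fdr)
    recs <- associationRecords(tab)
    state$assoc <- tab
    state$universe <- unique(recs$gene)
    calls <- lapply(methods, function(m)
      callSignedSet(tab, method = m))
    state$mlsSet <- Reduce(mergeMethodCalls, calls)
    recs$called <- paste(recs$gene, recs$method) %in%
      paste(recs$gene, recs$method)[!is.na(recs$q_value) &
                                      recs$q_value < a$fdr]
    files <- c(writeResultTsv(recs, out("assoc.tsv"),
                              c(fdr = a$fdr,
                                methods = paste(methods, collapse = ","),
                                min_species = a$min_species)),
               writeSignedGeneSet(state$mlsSet, out("mls_set.tsv")))
    record("associate", files)
  }

  # ---- concord -----------------------------------------------------------
  if ("concord" %in% cfg$stages) {
    if (is.null(state$partner)) dataError("no partner set available")
    res <- concordanceBattery(list(list(a = state$mlsSet,
                                        b = state$partner,
                                        universe = state$universe,
                                        label = "mls_vs_partner")),
                              fdr = cfg$concord$fdr)
    state$concord <- res
    record("concord", writeResultTsv(res, out("concord.tsv"),
                                     c(fdr = cfg$concord$fdr)))
  }

  # ---- enrich ------------------------------------------------------------
  if ("enrich" %in% cfg$stages) {
    e <- cfg$enrich
    if (!is.null(cfg$inputs$gmt)) {
      lib <- readGmt(cfg$inputs$gmt)
    } else {
      # synthetic annotation library: term 1 is enriched in the called set,
      # the rest are random draws from the universe
      set.seed(deriveSeed(master, "library"))
      lib <- list()
      called <- geneIds(state$mlsSet)
      nPick <- min(length(called), e$term_size %/% 2L)
      lib[["term_enriched"]] <- unique(c(
        sample(called, nPick),
        sample(state$universe, e$term_size - nPick)))
      for (i in seq_len(e$n_terms - 1L))
        lib[[sprintf("term_%03d", i)]] <-
          sample(state$universe, e$term_size)
      writeGmt(lib, out("library.gmt"))
    }
    if (!length(geneIds(state$mlsSet)))
      dataError("no called genes to enrich")
    res <- fisherEnrichment(geneIds(state$mlsSet), lib, state$universe,
                            fdr = e$fdr)
    state$enrich <- res
    record("enrich", writeResultTsv(res, out("enrich.tsv"),
                                    c(fdr = e$fdr)))
  }

  # ---- coevolve ----------------------------------------------------------
  if ("coevolve" %in% cfg$stages) {
    cv <- cfg$coevolve
    motif <- simulateMotif("planted_motif", cv$motif_width,
                           seed = deriveSeed(master, "motif"),
                           balanced = TRUE)
    decoy <- simulateMotif("decoy_motif", cv$motif_width,
                           seed = deriveSeed(master, "decoy"))
    setGenes <- head(geneIds(state$mlsSet), cv$n_set_genes)
    if (length(setGenes) < 2L)
      dataError("too few called genes for the coevolve stage")
    bgGenes <- head(setdiff(state$universe, setGenes), cv$n_bg_genes)
    proms <- c(
      simulatePromoters(state$species, setGenes, motif, trend = "gain",
                        length = cv$promoter_length,
                        maxInsertions = cv$max_insertions,
                        seed = deriveSeed(master, "promoters")),
      simulatePromoters(state$species, bgGenes, motif, trend = "none",
                        length = cv$promoter_length,
                        seed = deriveSeed(master, "promoters") + 1L))
    writeFastaPromoters(proms, out("promoters.fa"))
    mls <- setNames(state$species$mls_years, state$species$species_id)
    res <- motifCoevolution(proms, list(motif, decoy), setGenes,
                            bgGenes, mls, pThreshold = cv$p_threshold,
                            fdr = cv$fdr)
    state$coevolve <- res
    record("coevolve", writeResultTsv(res$trend, out("coevo.tsv"),
                                      c(fdr = cv$fdr,
                                        p_threshold = cv$p_threshold)))
  }

  manifest$finished <- format(Sys.time(), usetz = TRUE)
  yaml::write_yaml(manifest, file.path(cfg$out_dir, "manifest.yaml"))
  manifest$state <- state
  invisible(manifest)
}
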