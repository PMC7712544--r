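#' Assemble a pipeline configuration
#'
#' Defaults reproduce the reference analysis settings: MAF >= 0.01
#' autosomal filter; stage-1 screening forest with 1000 trees, mtry 1/3
#' and a 10% node-size limit, corrected-impurity screen at p < 0.01; r2VIM
#' with 11 forests of 10,000 trees and relative-importance threshold 1;
#' ensemble and interaction FDR thresholds of 0.05. Tests and examples use
#' a documented "desk profile" with fewer trees — the method, not the
#' scale, is the contract.
#'
#' @param simulation optional [simulation_spec()] for synthetic input.
#' @param tped,tfam optional PLINK transposed-text input paths (used when
#'   `simulation` is NULL).
#' @param out_dir output directory for stage TSVs and the manifest.
#' @param seed global seed; each stage derives its own stream from it.
#' @param maf_min,autosomes_only variant filters.
#' @param include_sex add the sex covariate (when present and complete) as
#'   an ordinary binary feature column for the forest stages.
#' @param stage1 list: `n_trees`, `mtry_fraction`, `min_node_fraction`,
#'   `p_threshold`.
#' @param r2vim list: `n_forests`, `n_trees`, `mtry_fraction`,
#'   `min_node_fraction`, `threshold`.
#' @param fdr_ensemble,fdr_interaction FDR thresholds.
#' @param min_cell interaction-regression cell floor.
#' @param network list: `alpha`, `min_leaf`, `or_mode`.
#' @param write_genotypes also write the (filtered) genotypes as
#'   .tped/.tfam into `out_dir`.
#' @return list of class `pipeline_config`.
#' @export
pipeline_config <- function(simulation = NULL, tped = NULL, tfam = NULL,
                            out_dir = tempfile("epiforest_run_"),
                            seed = 1L, maf_min = 0.01,
                            autosomes_only = TRUE, include_sex = TRUE,
                            stage1 = list(), r2vim = list(),
                            fdr_ensemble = 0.05, fdr_interaction = 0.05,
                            min_cell = 10,
                            network = list(), write_genotypes = FALSE) {
  stage1 <- modifyList(list(n_trees = 1000, mtry_fraction = 1 / 3,
                            min_node_fraction = 0.1, p_threshold = 0.01),
                       stage1)
  r2vim <- modifyList(list(n_forests = 11, n_trees = 10000,
                           mtry_fraction = 1 / 3, min_node_fraction = 0.1,
                           threshold = 1), r2vim)
  network <- modifyList(list(alpha = 0.05, min_leaf = 20,
                             or_mode = "complement"), network)
  if (is.null(simulation) && (is.null(tped) || is.null(tfam)))
    stopf("either a simulation spec or tped+tfam paths are required")
  structure(list(simulation = simulation, tped = tped, tfam = tfam,
                 out_dir = out_dir, seed = as.integer(seed),
                 maf_min = maf_min, autosomes_only = autosomes_only,
                 include_sex = include_sex, stage1 = stage1,
                 r2vim = r2vim, fdr_ensemble = fdr_ensemble,
                 fdr_interaction = fdr_interaction, min_cell = min_cell,
                 network = network, write_genotypes = write_genotypes),
            class = "pipeline_config")
}

#' Read a pipeline configuration from a JSON file
#'
#' The JSON mirrors the arguments of [pipeline_config()]; a `simulation`
#' object is passed on to [simulation_spec()].
#'
#' @param path JSON config file.
#' @return a `pipeline_config`.
#' @export
read_pipeline_config <- function(path) {
  raw <- jsonlite::read_json(path, simplifyVector = TRUE,
                             simplifyDataFrame = TRUE)
  if (!is.null(raw$simulation))
    raw$simulation <- do.call(simulation_spec, as.list(raw$simulation))
  do.call(pipeline_config, raw)
}

pipeline_stages <- c("input", "gwas", "stage1", "r2vim", "epistasis",
                     "interaction", "networks")

#' Run the full epistasis-screening pipeline
#'
#' Stage order: input (read or simulate, then variant filters) -> additive
#' GWAS baseline -> stage-1 screening forest with corrected-impurity
#' p < threshold selection -> r2VIM consensus selection (final forest
#' retained) -> forest-structure pair screen -> interaction regressions ->
#' network condensation and decision trees. Every stage writes its TSV into
#' `config$out_dir` and the run ends with a deterministic JSON manifest
#' (seeds, thresholds, feature/pair counts in and out, output files). Any
#' stage error aborts with the stage name; artifacts of completed stages
#' are preserved.
#'
#' @param config a [pipeline_config()].
#' @param upto last stage to execute (default `"networks"` = all); earlier
#'   stages always run, which under the per-stage seed streams reproduces
#'   identical artifacts, so any stage can be re-run in isolation.
#' @return invisibly, a list with the stage `results` and the `manifest`.
#' @export
run_pipeline <- function(config, upto = "networks") {
  stopifnot(inherits(config, "pipeline_config"))
  upto <- match.arg(upto, pipeline_stages)
  n_upto <- match(upto, pipeline_stages)
  dir.create(config$out_dir, showWarnings = FALSE, recursive = TRUE)
  manifest <- list(seed = config$seed,
                   config = config[setdiff(names(config),
                                           c("simulation", "out_dir"))],
                   stages = list())
  if (!is.null(config$simulation))
    manifest$config$simulation <- unclass(config$simulation)
  res <- list()
  note <- function(name, seed, n_in, n_out, outputs = character()) {
    manifest$stages[[length(manifest$stages) + 1L]] <<-
      list(name = name, seed = seed, n_in = n_in, n_out = n_out,
           outputs = outputs)
  }
  run_stage <- function(name, expr) {
    tryCatch(expr, error = function(e)
      stopf("pipeline stage '%s' failed: %s", name, conditionMessage(e)))
  }

  # -- input ---------------------------------------------------------------
  s_in <- derive_seed(config$seed, 1L)
  run_stage("input", {
    if (!is.null(config$simulation)) {
      spec <- config$simulation
      spec$seed <- as.integer(s_in %% 2147483647)
      sim <- simulate_dataset(spec)
      gm_raw <- sim$genotypes
      pheno <- sim$phenotypes
      res$truth <- sim$truth
    } else {
      inp <- read_tped(config$tped, config$tfam)
      gm_raw <- inp$genotypes
      pheno <- inp$phenotypes
    }
    gm <- filter_variants(gm_raw, config$maf_min, config$autosomes_only)
    outs <- character()
    if (config$write_genotypes) {
      write_tped(gm, pheno, file.path(config$out_dir, "filtered"))
      outs <- c("filtered.tped", "filtered.tfam")
    }
    res$genotypes <- gm
    res$phenotypes <- pheno
    note("input", s_in, ncol(gm_raw$dosages), ncol(gm$dosages), outs)
  })
  gm <- res$genotypes
  pheno <- res$phenotypes
  check_aligned(gm, pheno)

  # feature matrix for the forest stages (sex as an ordinary column)
  X <- gm$dosages
  if (config$include_sex && !is.null(pheno$sex) && !anyNA(pheno$sex))
    X <- cbind(X, sex = as.integer(pheno$sex))

  # -- gwas ----------------------------------------------------------------
  if (n_upto >= 2L) run_stage("gwas", {
    scan <- additive_scan(gm, pheno)
    write_gwas(scan, file.path(config$out_dir, "gwas.tsv"))
    res$gwas <- scan
    note("gwas", NA, ncol(gm$dosages), nrow(scan), "gwas.tsv")
  })

  # -- stage1 --------------------------------------------------------------
  sel1 <- integer(0)
  if (n_upto >= 3L) run_stage("stage1", {
    s1 <- derive_seed(config$seed, 3L)
    forest1 <- train_forest(X, pheno$status,
                            n_trees = config$stage1$n_trees,
                            mtry_fraction = config$stage1$mtry_fraction,
                            min_node_fraction = config$stage1$min_node_fraction,
                            seed = s1)
    imp <- suppressWarnings(corrected_impurity(forest1))
    write_tsv(imp, file.path(config$out_dir, "stage1_importance.tsv"))
    sel1 <- which(imp$pvalue < config$stage1$p_threshold)
    res$stage1 <- list(forest = forest1, importance = imp,
                        selected = sel1)
    note("stage1", s1, ncol(X), length(sel1), "stage1_importance.tsv")
  })

  # -- r2vim ---------------------------------------------------------------
  sel2 <- character(0)
  if (n_upto >= 4L) run_stage("r2vim", {
    s2 <- derive_seed(config$seed, 4L)
    if (length(sel1) >= 1L) {
      Xs <- X[, sel1, drop = FALSE]
      rv <- run_r2vim(Xs, pheno$status,
                      n_forests = config$r2vim$n_forests,
                      n_trees = config$r2vim$n_trees,
                      mtry_fraction = config$r2vim$mtry_fraction,
                      min_node_fraction = config$r2vim$min_node_fraction,
                      threshold = config$r2vim$threshold, seed = s2)
      write_tsv(r2vim_table(rv), file.path(config$out_dir, "r2vim.tsv"))
      write_forest_json(rv$final_forest,
                        file.path(config$out_dir, "final_forest.json"))
      sel2 <- rv$feature_names[rv$selected]
      res$r2vim <- rv
      note("r2vim", s2, length(sel1), length(sel2),
           c("r2vim.tsv", "final_forest.json"))
    } else {
      note("r2vim", s2, 0L, 0L)
    }
  })

  # -- epistasis screen ----------------------------------------------------
  retained <- NULL
  if (n_upto >= 5L) run_stage("epistasis", {
    if (length(sel2) >= 2L) {
      rv <- res$r2vim
      feat_idx <- which(rv$feature_names %in% sel2)
      pairs <- screen_pairs(rv$final_forest, feat_idx,
                            fdr_threshold = config$fdr_ensemble)
    } else {
      pairs <- screen_pairs(structure(list(trees = list(),
                                           feature_names = character(),
                                           n_features = 0L),
                                      class = "epi_forest"), integer(0),
                            config$fdr_ensemble)
    }
    write_tsv(as.data.frame(pairs), file.path(config$out_dir, "pairs.tsv"))
    retained <- pairs[pairs$retained, , drop = FALSE]
    res$pairs <- pairs
    note("epistasis", NA, if (length(sel2) >= 2L) nrow(pairs) else 0L,
         nrow(retained), "pairs.tsv")
  })

  # -- interaction regressions --------------------------------------------
  if (n_upto >= 6L) run_stage("interaction", {
    conf <- interaction_confirm(gm, pheno, retained,
                                min_cell = config$min_cell,
                                threshold = config$fdr_interaction)
    write_tsv(conf, file.path(config$out_dir, "interactions.tsv"))
    res$interactions <- conf
    note("interaction", NA, nrow(retained), nrow(conf),
         "interactions.tsv")
  })

  # -- networks ------------------------------------------------------------
  if (n_upto >= 7L) run_stage("networks", {
    nets <- condense_networks(retained)
    outs <- "networks.tsv"
    net_rows <- list()
    res$network_trees <- list()
    for (nw in nets) {
      tr <- fit_network_tree(nw, gm, pheno,
                             alpha = config$network$alpha,
                             min_leaf = config$network$min_leaf)
      ors <- terminal_odds_ratios(tr, config$network$or_mode)
      leaf_file <- sprintf("network_%d_leaves.tsv", nw$id)
      dot_file <- sprintf("network_%d.dot", nw$id)
      write_tsv(ors, file.path(config$out_dir, leaf_file))
      network_tree_dot(tr, file.path(config$out_dir, dot_file),
                       config$network$or_mode)
      outs <- c(outs, leaf_file, dot_file)
      net_rows[[nw$id]] <- data.frame(network = nw$id,
                                      members = paste(nw$members,
                                                      collapse = "|"),
                                      n_pairs = nrow(nw$pairs))
      res$network_trees[[nw$id]] <- list(network = nw, tree = tr,
                                          leaves = ors)
    }
    net_df <- if (length(net_rows)) do.call(rbind, net_rows) else
      data.frame(network = integer(), members = character(),
                 n_pairs = integer())
    write_tsv(net_df, file.path(config$out_dir, "networks.tsv"))
    res$networks <- nets
    note("networks", NA, nrow(retained), length(nets), outs)
  })

  manifest$n_stages <- length(manifest$stages)
  jsonlite::write_json(manifest, file.path(config$out_dir, "manifest.json"),
                       auto_unbox = TRUE, digits = NA, na = "null",
                       pretty = TRUE)
  invisible(list(results = res, manifest = manifest))
}
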