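#' Run the full analysis pipeline from a config
#'
#' Chains simulate (or load) -> qc -> pca -> screen -> gradient -> admix,
#' writing every stage's outputs under `out_dir` and finishing with a
#' manifest (JSON) recording the package version, the config hash, every
#' output file's MD5, the seeds used and the stage order — enough to rerun
#' and byte-compare deterministic stages. A failure in stage k leaves the
#' outputs of stages before k on disk; the manifest is only written after
#' a complete run.
#'
#' Config (YAML file or equivalent list): `out_dir` and `seed` at the top
#' level; a `simulate` block (`scenario` name plus [scenario_spec()]
#' overrides) or an `input` block (`geno`, `snp`, `ind`, `format`,
#' optional `metadata`); optional `qc` (threshold overrides), `pca`
#' (`k`, `sign_anchor`), `screen` (`groups`, `arity`, `z_threshold`),
#' `gradient` (`reference_sets`, `pcs`), `admix` (`target`, `sources`,
#' `right`, `reps`, `block_size`). Stages without a block are skipped
#' (except pca, which downstream stages need).
#'
#' @param config path to a YAML file, or a list with the same structure.
#' @return Invisibly, a list with the `manifest`, per-stage result objects
#'   and output `paths`.
#' @export
run_pipeline <- function(config) {
  if (is.character(config)) {
    if (!file.exists(config)) stop("config file not found: ", config)
    config <- yaml::read_yaml(config)
  }
  .require_cfg(config, "out_dir")
  .require_cfg(config, "seed")
  out_dir <- config$out_dir
  dir.create(out_dir, recursive = TRUE, showWarnings = FALSE)
  seed <- as.integer(config$seed)
  paths <- character(0)
  results <- list()
  stages_run <- character(0)
  log_stage <- function(stage, n_samples, n_snps) {
    message(sprintf("[cryptpc] %-9s %6d samples x %6d SNPs", stage,
                    n_samples, n_snps))
  }

  # --- stage 1: genotypes --------------------------------------------------
  if (!is.null(config$simulate)) {
    sc <- config$simulate
    spec <- if (!is.null(sc$scenario)) {
      make_paper_analogue_scenario(
        sc$scenario,
        n_snps = if (is.null(sc$n_snps)) 20000 else sc$n_snps,
        missing_rate = if (is.null(sc$missing_rate)) 0.3 else sc$missing_rate,
        seed = seed)
    } else {
      stop("config$simulate$scenario is required ",
           "(one of barbaricum5, gradient, three_wave)")
    }
    sim <- simulate_scenario(spec)
    files <- write_scenario(sim, file.path(out_dir, "genotypes"))
    paths <- c(paths, files)
    results$simulate <- sim
    mat <- sim$matrix
    stages_run <- c(stages_run, "simulate")
  } else if (!is.null(config$input)) {
    inp <- config$input
    .require_cfg(inp, "geno", "config$input")
    .require_cfg(inp, "ind", "config$input")
    fmt <- if (is.null(inp$format)) "eigenstrat" else inp$format
    mat <- read_genotypes(inp$geno, inp$snp, inp$ind, format = fmt)
    if (!is.null(inp$metadata)) {
      mat <- attach_sample_metadata(mat, read_sample_metadata(inp$metadata))
    }
    stages_run <- c(stages_run, "load")
  } else {
    stop("config needs either a 'simulate' or an 'input' block")
  }
  log_stage(stages_run[1], nrow(mat$calls), ncol(mat$calls))

  # --- stage 2: qc ---------------------------------------------------------
  if (!is.null(config$qc)) {
    th <- do.call(qc_thresholds, config$qc)
    qc_out <- apply_qc_pipeline(mat, th)
    mat <- qc_out$matrix
    p <- file.path(out_dir, "qc_report.tsv")
    write_qc_report(qc_out$report, p, "tsv")
    p2 <- file.path(out_dir, "qc_report.json")
    write_qc_report(qc_out$report, p2, "json")
    paths <- c(paths, qc_tsv = p, qc_json = p2)
    results$qc <- qc_out$report
    stages_run <- c(stages_run, "qc")
    log_stage("qc", nrow(mat$calls), ncol(mat$calls))
  }

  # --- stage 3: pca --------------------------------------------------------
  pcfg <- if (is.null(config$pca)) list() else config$pca
  k <- if (is.null(pcfg$k)) 20 else pcfg$k
  pcs <- compute_pcs(mat, K = min(k, nrow(mat$calls) - 1),
                     sign_anchor_population = pcfg$sign_anchor)
  p <- file.path(out_dir, "pc_scores.tsv")
  write_pc_scores(pcs, p)
  paths <- c(paths, pc_scores = p)
  results$pca <- pcs
  stages_run <- c(stages_run, "pca")
  message(sprintf("[cryptpc] %-9s %6d samples x %6d components", "pca",
                  nrow(pcs$scores), ncol(pcs$scores)))

  selected_triple <- NULL
  # --- stage 4: screening --------------------------------------------------
  if (!is.null(config$screen)) {
    scfg <- config$screen
    .require_cfg(scfg, "groups", "config$screen")
    if (ncol(pcs$scores) < 3) {
      warning("fewer than 3 PCs available; marginal screening is degenerate")
    }
    spec <- discrimination_spec(
      scfg$groups,
      min_group_n = if (is.null(scfg$min_group_n)) 3 else scfg$min_group_n)
    arity <- if (is.null(scfg$arity)) min(3, ncol(pcs$scores)) else scfg$arity
    zthr <- if (is.null(scfg$z_threshold)) 2.0 else scfg$z_threshold
    rep <- pc_screening_report(pcs$scores, mat$samples, spec,
                               arity = arity, z_threshold = zthr)
    p <- file.path(out_dir, "screening_report.json")
    write_screening_report(rep, p, "json")
    paths <- c(paths, screening = p)
    results$screen <- rep
    selected_triple <- rep$selected_triple
    stages_run <- c(stages_run, "screen")
    message(sprintf("[cryptpc] screen    selected PCs: %s",
                    paste(selected_triple, collapse = ", ")))
  }

  # --- stage 5: distance gradient ------------------------------------------
  if (!is.null(config$gradient)) {
    gcfg <- config$gradient
    .require_cfg(gcfg, "reference_sets", "config$gradient")
    subset_pcs <- if (!is.null(gcfg$pcs)) as.integer(gcfg$pcs)
                  else if (!is.null(selected_triple)) selected_triple
                  else seq_len(min(3, ncol(pcs$scores)))
    grad <- nearest_reference_distances(pcs$scores, mat$samples,
                                        gcfg$reference_sets, subset_pcs)
    p <- file.path(out_dir, "gradient_distances.tsv")
    utils::write.table(grad, p, sep = "\t", quote = FALSE, row.names = FALSE)
    pm <- population_mean_distances(grad)
    p2 <- file.path(out_dir, "gradient_population_means.tsv")
    utils::write.table(pm, p2, sep = "\t", quote = FALSE, row.names = FALSE)
    d <- .pc_distance_matrix(pcs$scores, subset_pcs)
    p5 <- file.path(out_dir, "pc_distance_matrix.tsv")
    utils::write.table(d, p5, sep = "\t", quote = FALSE)
    tree <- ward_clustering(d)
    p3 <- file.path(out_dir, "ward_dendrogram.nwk")
    write_dendrogram_newick(tree, p3)
    mds <- classical_mds(d, dims = 2)
    p4 <- file.path(out_dir, "mds_coordinates.tsv")
    utils::write.table(data.frame(sample_id = rownames(mds), mds),
                       p4, sep = "\t", quote = FALSE, row.names = FALSE)
    paths <- c(paths, gradient = p, gradient_means = p2, dendrogram = p3,
               mds = p4, distance_matrix = p5)
    results$gradient <- list(table = grad, population_means = pm,
                             tree = tree, mds = mds, pc_subset = subset_pcs)
    stages_run <- c(stages_run, "gradient")
    message(sprintf("[cryptpc] %-9s %6d samples in PC subspace {%s}",
                    "gradient", nrow(grad),
                    paste(subset_pcs, collapse = ", ")))
  }

  # --- stage 6: admixture modelling ----------------------------------------
  if (!is.null(config$admix)) {
    acfg <- config$admix
    .require_cfg(acfg, "target", "config$admix")
    .require_cfg(acfg, "sources", "config$admix")
    .require_cfg(acfg, "right", "config$admix")
    reps <- if (is.null(acfg$reps)) 1000 else acfg$reps
    bs <- if (is.null(acfg$block_size)) 500 else acfg$block_size
    fit <- block_bootstrap_ci(mat, acfg$target, unlist(acfg$sources),
                              unlist(acfg$right), n_reps = reps,
                              block_size_snps = bs,
                              seed = substream_seed(seed, "admix-stage"))
    p <- file.path(out_dir, "admixture_fit.tsv")
    write_admixture_fit(fit, p, "tsv")
    p2 <- file.path(out_dir, "admixture_fit.json")
    write_admixture_fit(fit, p2, "json")
    paths <- c(paths, admix_tsv = p, admix_json = p2)
    results$admix <- fit
    stages_run <- c(stages_run, "admix")
    message(sprintf("[cryptpc] admix     %s: %s (p = %.3g)", acfg$target,
                    paste(sprintf("%.3f", fit$weights), collapse = "/"),
                    fit$p_value))
  }

  manifest <- list(
    tool = "cryptpc",
    version = as.character(utils::packageVersion("cryptpc")),
    seed = seed,
    config_hash = .hash_object(config),
    stages = stages_run,
    outputs = lapply(stats::setNames(as.list(unname(paths)),
                                     names(paths)), function(f) {
      list(path = f, md5 = unname(tools::md5sum(f)))
    }))
  manifest_path <- file.path(out_dir, "manifest.json")
  jsonlite::write_json(manifest, manifest_path, auto_unbox = TRUE,
                       digits = NA)
  invisible(list(manifest = manifest, results = results,
                 paths = c(paths, manifest = manifest_path)))
}

.require_cfg <- function(cfg, field, prefix = "config") {
  if (is.null(cfg[[field]])) {
    stop("missing required field: ", prefix, "$", field)
  }
}

.hash_object <- function(x) {
  tmp <- tempfile()
  on.exit(unlink(tmp))
  writeLines(jsonlite::toJSON(x, auto_unbox = TRUE, force = TRUE), tmp)
  unname(tools::md5sum(tmp))
}
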