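# End-to-end pipeline driver and command-line entry point. Each stage is a
# thin orchestration over the exported module functions; all randomness is
# seeded so identical configurations give byte-identical outputs.

#' Default pipeline configuration
#'
#' @return named list of default parameters for [run_pipeline()].
#' @export
default_config <- function() {
  list(
    seed = 1,
    outdir = "polyprof_out",
    simulate = list(n_archetypes = 8, n_genes = 200, depth = 2e6,
                    dispersion = 20, n_replicates = 2),
    cluster = list(k = 8, k_samples = 4, stability_resamples = 100),
    compare = list(n_high = 2, n_low = 2, n_boot = 2000, alpha = 0.001),
    project = list(n_stages = 7, cells_per_stage = 8, switch_rate = 0.1,
                   k_external = 7, expression_threshold = 1),
    paths = list(counts = NULL, gtf = NULL, fasta = NULL,
                 external = NULL, external_samples = NULL)
  )
}

read_config <- function(path) {
  cfg <- yaml::read_yaml(path)
  utils::modifyList(default_config(), cfg)
}

#' Run the full analysis pipeline
#'
#' Stages: simulate (or load) counts and annotation; normalize (VST,
#' filter, center); cluster isoform profiles and samples with stability
#' resampling; tabulate features; compare gene-linked isoforms between
#' high- and low-polysome clusters; project the external matrix onto the
#' reference clusters and call switches. All artifacts are written as
#' TSV/JSON/Newick under `config$outdir`, with a provenance manifest.
#'
#' @param config list as from [default_config()] (or a YAML path).
#' @param stages subset of
#'   `c("simulate", "normalize", "cluster", "features", "compare",
#'      "project")`.
#' @return invisibly, a list with the in-memory stage results.
#' @export
run_pipeline <- function(config = default_config(),
                         stages = c("simulate", "normalize", "cluster",
                                    "features", "compare", "project")) {
  if (is.character(config)) config <- read_config(config)
  out <- config$outdir
  dir.create(out, showWarnings = FALSE, recursive = TRUE)
  seed <- as.integer(config$seed)
  res <- list()

  if ("simulate" %in% stages) {
    arch <- make_archetypes(config$simulate$n_archetypes)
    sim <- simulate_counts(arch, n_genes = config$simulate$n_genes,
                           depth = config$simulate$depth,
                           dispersion = config$simulate$dispersion,
                           n_replicates = config$simulate$n_replicates,
                           seed = seed)
    ann <- simulate_annotation(sim$truth, seed = seed + 1)
    ext <- simulate_external(ann$truth,
                             n_stages = config$project$n_stages,
                             cells_per_stage = config$project$cells_per_stage,
                             switch_rate = config$project$switch_rate,
                             seed = seed + 2)
    write_counts(sim$counts, file.path(out, "counts.tsv"))
    write_gtf(ann$gtf, file.path(out, "annotation.gtf"))
    write_fasta(ann$genome, file.path(out, "genome.fa"))
    write_fasta(ann$transcripts, file.path(out, "transcripts.fa"))
    write_table(ann$truth, file.path(out, "truth.tsv"))
    write_counts(ext$tpm, file.path(out, "external_tpm.tsv"))
    write_table(ext$samples, file.path(out, "external_samples.tsv"))
    write_table(ext$switches, file.path(out, "planted_switches.tsv"))
    res$sim <- sim; res$ann <- ann; res$ext <- ext
  } else {
    res$sim <- list(counts = read_counts(config$paths$counts))
    gtf <- read_gtf(config$paths$gtf)
    genome <- read_fasta(config$paths$fasta)
    res$ann <- list(gtf = gtf, genome = genome, truth = NULL)
    if (!is.null(config$paths$external)) {
      res$ext <- list(tpm = read_counts(config$paths$external),
                      samples = read_table(config$paths$external_samples))
    }
  }

  if ("normalize" %in% stages) {
    v <- vst(res$sim$counts)
    rel <- filter_and_center(v)
    write_counts(v, file.path(out, "vst.tsv"))
    write_counts(rel, file.path(out, "relative_expression.tsv"))
    res$vst <- v; res$rel <- rel
  }

  if ("cluster" %in% stages) {
    d <- spearman_distance_matrix(res$rel[, RIBO_FRACTIONS])
    tree <- hcluster(d, "ward.D2")
    cl <- cut_to_clusters(tree, k = config$cluster$k)
    names(cl$assignments) <- rownames(res$rel)
    mp <- meta_profiles(res$rel[, RIBO_FRACTIONS], cl$assignments)
    stree <- cluster_samples(res$vst)
    sgroups <- cluster_samples(res$vst, k = config$cluster$k_samples)
    stab <- jaccard_stability(
      t(res$vst), function(m) stats::cutree(
        stats::hclust(stats::dist(m), "complete"),
        k = config$cluster$k_samples),
      n = config$cluster$stability_resamples, seed = seed + 3)
    write_table(data.frame(isoform_id = names(cl$assignments),
                           cluster = unname(cl$assignments)),
                file.path(out, "isoform_clusters.tsv"))
    write_table(do.call(rbind, lapply(mp, function(p)
      data.frame(cluster = p$cluster, fraction = names(p$mean),
                 mean = unname(p$mean), sd = unname(p$sd), n = p$n))),
      file.path(out, "meta_profiles.tsv"))
    write_newick(stree, file.path(out, "sample_dendrogram.nwk"))
    jsonlite::write_json(
      list(mean_jaccard = as.data.frame(stab$mean_jaccard),
           n_resamples = stab$n_resamples),
      file.path(out, "stability.json"), auto_unbox = TRUE, pretty = TRUE,
      digits = NA)
    res$clusters <- cl; res$meta <- mp; res$sample_groups <- sgroups
    res$stability <- stab
  }

  if ("features" %in% stages) {
    models <- decompose_all(res$ann$gtf, res$ann$genome)
    expr <- sapply(FRACTIONS, function(f)
      rowMeans(res$sim$counts[, grep(paste0("^", f, "_"),
                                     colnames(res$sim$counts)),
                              drop = FALSE]))
    feats <- tabulate_features(models, expression = expr,
                               codon_usage = res$ann$codon_usage,
                               mirna_sites = res$ann$mirna_sites,
                               half_life = res$ann$half_life,
                               uorf_table = res$ann$uorfs,
                               expressed_mirnas = res$ann$expressed_mirnas)
    write_table(feats, file.path(out, "features.tsv"))
    res$models <- models; res$features <- feats
  }

  if ("compare" %in% stages) {
    skew <- rank_clusters_by_polysome(res$meta)
    hi <- as.integer(names(skew)[seq_len(config$compare$n_high)])
    lo <- as.integer(names(skew)[seq(length(skew) -
                                       config$compare$n_low + 1,
                                     length(skew))])
    gene_map <- if (!is.null(res$ann$truth))
      res$ann$truth[, c("isoform_id", "gene_id")]
    else data.frame(isoform_id = names(res$clusters$assignments),
                    gene_id = sub("\\.\\d+$", "",
                                  names(res$clusters$assignments)))
    sets <- build_linked_sets(res$clusters$assignments, hi, lo, gene_map)
    eff <- compare_features(res$features, sets$high_ids, sets$low_ids,
                            n_boot = config$compare$n_boot, seed = seed + 4,
                            alpha = config$compare$alpha)
    write_table(sets$pairs, file.path(out, "linked_pairs.tsv"))
    write_table(eff, file.path(out, "effect_sizes.tsv"))
    res$linked <- sets; res$effects <- eff
    res$high_clusters <- hi; res$low_clusters <- lo
  }

  if ("project" %in% stages && !is.null(res$ext)) {
    ec <- cluster_external(res$ext$tpm, res$ext$samples,
                           k = config$project$k_external)
    sm <- map_to_reference(res$ext$tpm, res$ext$samples,
                           res$clusters$assignments,
                           config$project$expression_threshold)
    stage <- res$ext$samples$stage[match(colnames(res$ext$tpm),
                                         res$ext$samples$cell)]
    avg <- sapply(unique(stage), function(s)
      rowMeans(res$ext$tpm[, stage == s, drop = FALSE]))
    prof <- meta_profiles(log2(avg[names(ec$assignments), ] + 1),
                          ec$assignments)
    gene_map <- if (!is.null(res$ann$truth))
      res$ann$truth[, c("isoform_id", "gene_id")]
    else data.frame(isoform_id = names(res$clusters$assignments),
                    gene_id = sub("\\.\\d+$", "",
                                  names(res$clusters$assignments)))
    sw <- find_switches(ec$assignments, res$clusters$assignments,
                        res$high_clusters, res$low_clusters, gene_map,
                        external_profiles = prof)
    write_table(as.data.frame(sm), file.path(out, "stage_map.tsv"))
    write_table(sw, file.path(out, "switches.tsv"))
    res$external_clusters <- ec; res$stage_map <- sm; res$switches <- sw
  }

  write_manifest(file.path(out, "manifest.json"),
                 params = config,
                 inputs = unlist(config$paths, use.names = FALSE))
  invisible(res)
}

#' Command-line entry point
#'
#' Subcommands: `simulate`, `normalize`, `cluster`, `features`, `compare`,
#' `project`, `run-all`. Options: `--config <yaml>`, `--seed <int>`,
#' `--out <dir>`. Returns a shell exit code (0 success, 2 validation
#' failure); the installed script `inst/cli/polyprof.R` wraps this
#' function.
#'
#' @param argv character vector of command-line arguments.
#' @return integer exit code.
#' @export
cli_main <- function(argv = commandArgs(trailingOnly = TRUE)) {
  cmds <- c("simulate", "normalize", "cluster", "features", "compare",
            "project", "run-all")
  if (length(argv) < 1 || !argv[1] %in% cmds) {
    message("usage: polyprof <", paste(cmds, collapse = "|"),
            "> [--config file.yaml] [--seed N] [--out dir]")
    return(2L)
  }
  cmd <- argv[1]
  parser <- optparse::OptionParser(option_list = list(
    optparse::make_option("--config", type = "character", default = NULL),
    optparse::make_option("--seed", type = "integer", default = NULL),
    optparse::make_option("--out", type = "character", default = NULL)))
  opts <- tryCatch(
    optparse::parse_args(parser, args = argv[-1]),
    error = function(e) { message(conditionMessage(e)); NULL })
  if (is.null(opts)) return(2L)
  cfg <- if (!is.null(opts$config)) {
    if (!file.exists(opts$config)) {
      message("config file not found: ", opts$config)
      return(2L)
    }
    read_config(opts$config)
  } else default_config()
  if (!is.null(opts$seed)) cfg$seed <- opts$seed
  if (!is.null(opts$out)) cfg$outdir <- opts$out
  stages <- if (cmd == "run-all")
    c("simulate", "normalize", "cluster", "features", "compare", "project")
  else cmd
  # Stages after "simulate" need inputs: either simulated here or on disk.
  if (!"simulate" %in% stages) {
    need <- c("counts", "gtf", "fasta")
    miss <- need[vapply(need, function(p)
      is.null(cfg$paths[[p]]) || !file.exists(cfg$paths[[p]]), logical(1))]
    if (length(miss)) {
      message("missing input path(s): ", paste(miss, collapse = ", "))
      return(2L)
    }
    stages <- c(stages)
  }
  message("polyprof ", cmd, " (seed ", cfg$seed, ", out ", cfg$outdir, ")")
  tryCatch({
    if (cmd == "run-all") run_pipeline(cfg)
    else if (cmd == "simulate") run_pipeline(cfg, stages = "simulate")
    else run_pipeline(cfg, stages = unique(c(
      "normalize",
      intersect(c("cluster", "features", "compare", "project"),
                seq_stages(cmd)))))
    0L
  }, error = function(e) {
    message("error: ", conditionMessage(e))
    1L
  })
}

# Stages required (in order) up to and including `cmd`.
seq_stages <- function(cmd) {
  order <- c("cluster", "features", "compare", "project")
  order[seq_len(match(cmd, order, nomatch = 0))]
}
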