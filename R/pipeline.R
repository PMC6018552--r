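# --- pipeline orchestration -------------------------------------------------

pipeline_default_config <- function() {
  list(
    seed = 1L, outdir = "grn_out",
    # input paths (NULL = use the synthetic world written by `simulate`)
    plate = NULL, coexpression = NULL, promoters = NULL, pwms = NULL,
    ref_genes = c("ref1", "ref2"), seeds = NULL,
    # quantification / screening
    amplification_base = 2, alpha = 0.05, min_stages = 2L, min_fins = 2L,
    # stepwise selection
    k_select = 9L, k_extend = 5L, min_support = 1L, rounds = 2L,
    # motifs / TF prediction
    widths = 6:10, top_m = 5L, alpha_enrich = 0.05, threshold_fraction = 0.5,
    top_t = 3L, score_fraction = 0.8, min_overlap = 5L,
    # network
    alpha_pooled = 0.01, alpha_fin = 0.01,
    # synthetic world
    n_tfs = 3L, n_targets = 12L, n_nulls = 20L, effect_size = 1,
    tfs_per_target = 1L, plant_rate = 0.9, info_content = 1.9,
    n_pwms = 10L, pwm_width = 8L
  )
}

#' Build and validate a pipeline configuration
#'
#' Starts from the package defaults, overlays values read from a JSON
#' config file (if any) and then explicit overrides. Unknown keys and
#' out-of-range thresholds are rejected before any computation.
#'
#' @param config_file optional path to a JSON file of settings.
#' @param ... named overrides of individual settings.
#' @return validated configuration list of class `pipeline_config`.
#' @export
pipeline_config <- function(config_file = NULL, ...) {
  cfg <- pipeline_default_config()
  overlay <- function(cfg, vals, origin) {
    unknown <- setdiff(names(vals), names(cfg))
    if (length(unknown)) {
      stop("unknown configuration key(s) ", origin, ": ",
           paste(unknown, collapse = ", "), call. = FALSE)
    }
    utils::modifyList(cfg, vals)
  }
  if (!is.null(config_file)) {
    cfg <- overlay(cfg, jsonlite::read_json(config_file, simplifyVector = TRUE),
                   "in config file")
  }
  dots <- list(...)
  if (length(dots)) cfg <- overlay(cfg, dots, "")
  for (key in c("alpha", "alpha_pooled", "alpha_fin", "alpha_enrich",
                "score_fraction", "threshold_fraction", "plant_rate")) {
    v <- cfg[[key]]
    if (!is.numeric(v) || length(v) != 1 || v < 0 || v > 1) {
      stop("configuration value out of range (must be in [0, 1]): ", key,
           call. = FALSE)
    }
  }
  for (key in c("k_select", "k_extend", "rounds", "top_m", "top_t",
                "n_tfs", "n_targets", "n_pwms")) {
    if (!is_count(cfg[[key]])) {
      stop("configuration value must be a positive integer: ", key, call. = FALSE)
    }
  }
  if (cfg$info_content < 0 || cfg$info_content > 2) {
    stop("info_content must be in [0, 2]", call. = FALSE)
  }
  class(cfg) <- "pipeline_config"
  cfg
}

config_digest <- function(cfg) {
  cfg <- unclass(cfg)
  cfg$outdir <- NULL  # digest the analysis settings, not the destination
  tmp <- tempfile()
  on.exit(unlink(tmp))
  writeLines(jsonlite::toJSON(cfg, auto_unbox = TRUE, null = "null"), tmp)
  unname(tools::md5sum(tmp))
}

stage_header <- function(cfg) {
  c(sprintf("grnstep %s", as.character(utils::packageVersion("grnstep"))),
    sprintf("seed=%d config_digest=%s", as.integer(cfg$seed), config_digest(cfg)))
}

out_path <- function(cfg, name) file.path(cfg$outdir, name)

world_sim_config <- function(cfg) {
  simulation_config(seed = cfg$seed)
}

stage_simulate <- function(cfg) {
  dir.create(cfg$outdir, showWarnings = FALSE, recursive = TRUE)
  sim <- world_sim_config(cfg)
  net <- generate_planted_network(cfg$n_tfs, cfg$n_targets, cfg$n_nulls,
                                  effect_size = cfg$effect_size,
                                  seed = cfg$seed,
                                  tfs_per_target = cfg$tfs_per_target)
  expr <- simulate_expression(net, sim)
  plate <- expression_to_cq(expr, sim, ref_gene_ids = cfg$ref_genes)
  db <- build_coexpression_db(net, sim)
  library <- generate_pwm_library(cfg$n_pwms,
                                  width_range = c(cfg$pwm_width, cfg$pwm_width),
                                  info_content = cfg$info_content,
                                  seed = cfg$seed, tf_ids = net$tf_ids)
  proms <- generate_promoters(net, library, sim, plant_rate = cfg$plant_rate)
  hdr <- stage_header(cfg)
  write_cq_plate(plate, out_path(cfg, "plate.tsv"), hdr)
  write_coexpression_db(db, out_path(cfg, "coexpression.tsv"), hdr)
  write_fasta(proms, out_path(cfg, "promoters.fasta"))
  write_transfac(library, out_path(cfg, "pwms.transfac"))
  truth <- list(
    tf_ids = net$tf_ids, target_ids = net$target_ids, null_ids = net$null_ids,
    edges = net$edges, seeds = default_seeds(net),
    planted_sites = attr(proms, "sites"))
  jsonlite::write_json(truth, out_path(cfg, "truth.json"), auto_unbox = TRUE,
                       digits = NA)
  invisible(list(net = net, plate = plate, db = db, library = library,
                 promoters = proms))
}

pipeline_inputs <- function(cfg) {
  list(
    plate = read_cq_plate(cfg$plate %||% out_path(cfg, "plate.tsv")),
    db = read_coexpression_db(cfg$coexpression %||% out_path(cfg, "coexpression.tsv")),
    promoters = read_fasta(cfg$promoters %||% out_path(cfg, "promoters.fasta")),
    library = read_transfac(cfg$pwms %||% out_path(cfg, "pwms.transfac"))
  )
}

pipeline_seeds <- function(cfg) {
  if (!is.null(cfg$seeds)) return(cfg$seeds)
  truth_path <- out_path(cfg, "truth.json")
  if (file.exists(truth_path)) {
    return(unlist(jsonlite::read_json(truth_path, simplifyVector = TRUE)$seeds))
  }
  stop("no seed genes configured and no synthetic truth manifest found",
       call. = FALSE)
}

stage_quantify <- function(cfg) {
  inp <- pipeline_inputs(cfg)
  rq <- relative_quantities(inp$plate, cfg$ref_genes, E = cfg$amplification_base)
  write_tsv(as.data.frame(rq), out_path(cfg, "rq.tsv"), stage_header(cfg))
  invisible(rq)
}

stage_difftest <- function(cfg) {
  rq <- read_rq(out_path(cfg, "rq.tsv"))
  sig <- paired_lvs_tests(rq, alpha = cfg$alpha)
  rep <- consistency_call(sig, alpha = cfg$alpha, min_stages = cfg$min_stages,
                          min_fins = cfg$min_fins)
  hdr <- stage_header(cfg)
  write_tsv(as.data.frame(sig), out_path(cfg, "significance.tsv"), hdr)
  write_tsv(as.data.frame(rep), out_path(cfg, "consistency.tsv"), hdr)
  invisible(rep)
}

stage_select <- function(cfg) {
  inp <- pipeline_inputs(cfg)
  res <- run_stepwise(pipeline_seeds(cfg), inp$db, inp$plate,
                      ref_genes = cfg$ref_genes, k_select = cfg$k_select,
                      k_extend = cfg$k_extend, min_support = cfg$min_support,
                      alpha = cfg$alpha, min_stages = cfg$min_stages,
                      min_fins = cfg$min_fins, rounds = cfg$rounds,
                      E = cfg$amplification_base)
  hdr <- stage_header(cfg)
  write_tsv(res$final, out_path(cfg, "final_genes.tsv"), hdr)
  write_tsv(res$log, out_path(cfg, "round_log.tsv"), hdr)
  write_tsv(as.data.frame(res$report), out_path(cfg, "screen_report.tsv"), hdr)
  invisible(res)
}

stage_motifs <- function(cfg) {
  inp <- pipeline_inputs(cfg)
  final <- read_tsv(out_path(cfg, "final_genes.tsv"))
  up <- final$gene[final$direction == "higher-L"]
  if (length(up) < 3) stop("fewer than 3 higher-L genes for motif discovery",
                           call. = FALSE)
  proms <- inp$promoters[up]
  motifs <- discover_motifs(proms, widths = cfg$widths, top_m = cfg$top_m,
                            alpha = cfg$alpha_enrich)
  shared <- filter_shared_motifs(motifs, length(up),
                                 threshold_fraction = cfg$threshold_fraction)
  # screen every gene on the plate (TFs included) for the verdicts
  rq <- relative_quantities(inp$plate, cfg$ref_genes, E = cfg$amplification_base)
  rep <- consistency_call(paired_lvs_tests(rq, alpha = cfg$alpha),
                          alpha = cfg$alpha, min_stages = cfg$min_stages,
                          min_fins = cfg$min_fins)
  nom <- nominate_tfs(shared, inp$library, rep, promoters = inp$promoters,
                      top_t = cfg$top_t, score_fraction = cfg$score_fraction,
                      min_overlap = cfg$min_overlap)
  hdr <- stage_header(cfg)
  motif_df <- do.call(rbind, lapply(shared, function(m) {
    data.frame(motif = m$pwm$id, width = m$width, seed_word = m$seed_word,
               presence = m$presence, presence_fraction = m$presence_fraction,
               p_value = m$p_value, stringsAsFactors = FALSE)
  })) %||% data.frame()
  write_tsv(motif_df, out_path(cfg, "motifs.tsv"), hdr)
  write_tsv(nom$shortlist, out_path(cfg, "tf_shortlist.tsv"), hdr)
  write_tsv(nom$audit, out_path(cfg, "tf_audit.tsv"), hdr)
  write_tsv(nom$repressor_sites, out_path(cfg, "repressor_sites.tsv"), hdr)
  invisible(nom)
}

stage_network <- function(cfg) {
  inp <- pipeline_inputs(cfg)
  final <- read_tsv(out_path(cfg, "final_genes.tsv"))
  short <- read_tsv(out_path(cfg, "tf_shortlist.tsv"))
  genes <- sort(unique(c(final$gene, short$tf)))
  rq <- relative_quantities(inp$plate, cfg$ref_genes, E = cfg$amplification_base)
  pooled <- pairwise_correlations(rq, genes)
  fins <- sort(unique(rq$fin))
  per_fin <- stats::setNames(lapply(fins, function(f) {
    pairwise_correlations(rq, genes, fin = f)
  }), fins)
  edges <- build_network(pooled, per_fin, alpha_pooled = cfg$alpha_pooled,
                         alpha_fin = cfg$alpha_fin)
  roles <- classify_tf_roles(edges, short$tf, final$gene)
  hdr <- stage_header(cfg)
  write_tsv(as.data.frame(edges), out_path(cfg, "network_edges.tsv"), hdr)
  write_tsv(roles, out_path(cfg, "tf_roles.tsv"), hdr)
  if (nrow(edges)) {
    export_network(edges, out_path(cfg, "network.sif"), "sif")
    export_network(edges, out_path(cfg, "network.graphml"), "graphml")
  }
  invisible(edges)
}

#' Read an RQ table written by the pipeline
#'
#' @param path file path.
#' @return `rq_table` data.frame.
#' @export
read_rq <- function(path) {
  rq <- read_tsv(path)
  class(rq) <- c("rq_table", "data.frame")
  rq
}

#' Run one pipeline stage (or all of them)
#'
#' Stages mirror the deduction workflow: `simulate` writes a complete
#' synthetic input world; `quantify` turns the Cq plate into relative
#' quantities; `difftest` applies the paired-t consistency screen;
#' `select` runs the stepwise co-expression selection; `motifs` discovers
#' shared promoter motifs and nominates TFs; `network` assembles the
#' correlation network; `run-all` chains them in order. Every output file
#' starts with comment lines recording the tool version, seed and config
#' digest; reruns with identical config and inputs are byte-identical.
#'
#' @param name one of `"simulate"`, `"quantify"`, `"difftest"`,
#'   `"select"`, `"motifs"`, `"network"`, `"run-all"`.
#' @param config a [pipeline_config()].
#' @return the stage's main in-memory result, invisibly.
#' @export
run_subcommand <- function(name, config) {
  stopifnot(inherits(config, "pipeline_config"))
  stages <- list(simulate = stage_simulate, quantify = stage_quantify,
                 difftest = stage_difftest, select = stage_select,
                 motifs = stage_motifs, network = stage_network)
  if (name == "run-all") {
    dir.create(config$outdir, showWarnings = FALSE, recursive = TRUE)
    for (s in names(stages)) {
      if (s == "simulate" && !is.null(config$plate)) next
      tryCatch(stages[[s]](config), error = function(e) {
        stop(sprintf("stage '%s' failed: %s", s, conditionMessage(e)),
             call. = FALSE)
      })
    }
    return(invisible(TRUE))
  }
  if (!name %in% names(stages)) {
    stop("unknown subcommand: ", name, call. = FALSE)
  }
  dir.create(config$outdir, showWarnings = FALSE, recursive = TRUE)
  stages[[name]](config)
}

#' Command-line entry point
#'
#' Parses `<subcommand> [--config FILE] [--seed N] [--outdir DIR]
#' [--log-level LEVEL]` and dispatches to [run_subcommand()]. Designed to
#' be called from the installed `scripts/grnstep` Rscript wrapper.
#'
#' @param argv character vector of command-line arguments.
#' @return exit status (0 on success), invisibly.
#' @export
grn_cli <- function(argv = commandArgs(trailingOnly = TRUE)) {
  if (!length(argv)) {
    message("usage: grnstep <simulate|quantify|difftest|select|motifs|network|run-all> ",
            "[--config FILE] [--seed N] [--outdir DIR] [--log-level LEVEL]")
    return(invisible(1L))
  }
  name <- argv[1]
  rest <- argv[-1]
  opts <- list()
  i <- 1
  while (i <= length(rest)) {
    key <- sub("^--", "", rest[i])
    if (!key %in% c("config", "seed", "outdir", "log-level")) {
      stop("unknown flag: ", rest[i], call. = FALSE)
    }
    opts[[key]] <- rest[i + 1]
    i <- i + 2
  }
  args <- list(config_file = opts$config)
  if (!is.null(opts$seed)) args$seed <- as.integer(opts$seed)
  if (!is.null(opts$outdir)) args$outdir <- opts$outdir
  cfg <- do.call(pipeline_config, args)
  status <- tryCatch({
    run_subcommand(name, cfg)
    0L
  }, error = function(e) {
    message("error: ", conditionMessage(e))
    1L
  })
  invisible(status)
}
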