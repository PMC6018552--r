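#' Simulation configuration for the synthetic fin world
#'
#' Bundles the design of the simulated experiment: three unpaired fins
#' (dorsal, anal, caudal; the caudal fin contributing two elongated
#' regions), three regeneration stages, and three biological replicates,
#' together with the noise model and the sizes of the auxiliary inputs
#' (promoter length, co-expression compendium).
#'
#' @param fins fins to simulate (subset of `names(fin_layout())`).
#' @param stages integer vector of regeneration stages.
#' @param n_replicates biological replicates per sample cell (>= 2).
#' @param noise_sd_cq technical noise added to every Cq well, in cycles
#'   (default 0.15, typical SYBR-green technical scatter; note each paired
#'   L-minus-S log2-RQ difference accumulates this noise from the target
#'   and reference wells of both samples).
#' @param replicate_sd SD of the per-gene, per-fin biological replicate
#'   effect, in log2 units.
#' @param noise_sd_expr residual expression noise SD, log2 units.
#' @param promoter_length length of simulated upstream sequences, bases.
#' @param compendium_size number of simulated co-expression compendium
#'   samples (>= 50).
#' @param n_batches number of independent compendium batches used for the
#'   supportability score.
#' @param mutual_rank_n neighbours must fall in each other's top-N ranks
#'   within a batch to support a pair.
#' @param compendium_noise_sd residual noise SD in compendium samples.
#' @param seed integer seed; all generator randomness derives from it.
#' @return object of class `simulation_config`.
#' @export
simulation_config <- function(fins = c("dorsal", "anal", "caudal"),
                              stages = 0:2,
                              n_replicates = 3,
                              noise_sd_cq = 0.15,
                              replicate_sd = 0.15,
                              noise_sd_expr = 0.1,
                              promoter_length = 4000,
                              compendium_size = 200,
                              n_batches = 4,
                              mutual_rank_n = 5,
                              compendium_noise_sd = 0.5,
                              seed = 1) {
  stopifnot(all(fins %in% names(fin_layout())), length(fins) >= 1)
  stopifnot(length(stages) >= 1)
  if (!is_count(n_replicates) || n_replicates < 2) {
    stop("n_replicates must be an integer >= 2", call. = FALSE)
  }
  sds <- c(noise_sd_cq, replicate_sd, noise_sd_expr, compendium_noise_sd)
  if (any(!is.finite(sds)) || any(sds < 0)) {
    stop("all noise SDs must be finite and >= 0", call. = FALSE)
  }
  if (!is_count(promoter_length)) stop("promoter_length must be a positive integer", call. = FALSE)
  structure(list(
    fins = fins, stages = stages, n_replicates = as.integer(n_replicates),
    noise_sd_cq = noise_sd_cq, replicate_sd = replicate_sd,
    noise_sd_expr = noise_sd_expr,
    promoter_length = as.integer(promoter_length),
    compendium_size = as.integer(compendium_size),
    n_batches = as.integer(n_batches),
    mutual_rank_n = as.integer(mutual_rank_n),
    compendium_noise_sd = compendium_noise_sd,
    seed = as.integer(seed)
  ), class = "simulation_config")
}

#' Sample sheet implied by a simulation configuration
#'
#' One row per (fin, region, stage, replicate) cell, covering every region
#' of every configured fin.
#'
#' @param cfg a [simulation_config()].
#' @return data.frame with columns fin, region, stage, replicate.
#' @export
sample_sheet <- function(cfg) {
  lay <- fin_layout()[cfg$fins]
  rows <- do.call(rbind, lapply(names(lay), function(f) {
    regions <- unlist(lay[[f]], use.names = FALSE)
    expand.grid(fin = f, region = regions, stage = cfg$stages,
                replicate = seq_len(cfg$n_replicates),
                stringsAsFactors = FALSE, KEEP.OUT.ATTRS = FALSE)
  }))
  rows <- rows[order(rows$fin, rows$region, rows$stage, rows$replicate), ]
  rownames(rows) <- NULL
  rows
}

#' Generate a planted ground-truth regulatory network
#'
#' Creates TF, target and unregulated decoy gene identifiers and a set of
#' signed TF->target edges. Signs are assigned per target so that at least
#' one target carries repressive regulation (a synthetic analogue of a
#' repressed, higher-S gene). Per-TF region effects (the L-minus-S
#' difference in TF activity, log2 units) are constant across fins and
#' stages at `effect_size`.
#'
#' @param n_tfs,n_targets,n_nulls positive gene counts.
#' @param effect_size planted L-minus-S activity difference, log2 units (> 0).
#' @param seed integer seed (construction is deterministic given it).
#' @param tfs_per_target how many TFs regulate each target (1 =
#'   block-structured modules; `n_tfs` = dense shared regulation).
#' @param fins,stages design over which region effects are laid out.
#' @return object of class `planted_network`.
#' @export
generate_planted_network <- function(n_tfs, n_targets, n_nulls,
                                     effect_size = 1, seed = 1,
                                     tfs_per_target = 1,
                                     fins = c("dorsal", "anal", "caudal"),
                                     stages = 0:2) {
  if (!is_count(n_tfs) || !is_count(n_targets) || !is.numeric(n_nulls) ||
      n_nulls < 0 || n_nulls != floor(n_nulls)) {
    stop("n_tfs and n_targets must be positive integers, n_nulls >= 0",
         call. = FALSE)
  }
  if (!is.numeric(effect_size) || effect_size <= 0) {
    stop("effect_size must be > 0", call. = FALSE)
  }
  stopifnot(is_count(tfs_per_target), tfs_per_target <= n_tfs)
  tf_ids <- sprintf("tf%02d", seq_len(n_tfs))
  target_ids <- sprintf("tg%02d", seq_len(n_targets))
  null_ids <- if (n_nulls > 0) sprintf("nl%02d", seq_len(n_nulls)) else character(0)

  # per-target sign: mostly activated; the tail of the target list is
  # repressed so that at least one "higher-S" gene exists
  n_neg <- if (n_targets == 1) 1L else max(1L, round(0.15 * n_targets))
  sign_target <- c(rep(1L, n_targets - n_neg), rep(-1L, n_neg))

  primary <- rep(seq_len(n_tfs), each = ceiling(n_targets / n_tfs))[seq_len(n_targets)]
  edges <- do.call(rbind, lapply(seq_len(n_targets), function(j) {
    tfs <- ((primary[j] - 1 + seq_len(tfs_per_target) - 1) %% n_tfs) + 1
    data.frame(tf = tf_ids[tfs], target = target_ids[j],
               sign = sign_target[j], weight = 1,
               stringsAsFactors = FALSE)
  }))
  rownames(edges) <- NULL

  tf_region_effect <- expand.grid(tf = tf_ids, fin = fins, stage = stages,
                                  stringsAsFactors = FALSE,
                                  KEEP.OUT.ATTRS = FALSE)
  tf_region_effect$effect <- effect_size

  structure(list(
    tf_ids = tf_ids, target_ids = target_ids, null_ids = null_ids,
    edges = edges, tf_region_effect = tf_region_effect,
    effect_size = effect_size, seed = as.integer(seed)
  ), class = "planted_network")
}

#' @export
print.planted_network <- function(x, ...) {
  cat("planted_network:", length(x$tf_ids), "TFs,", length(x$target_ids),
      "targets,", length(x$null_ids), "decoys,", nrow(x$edges), "edges",
      sprintf("(%d repressive)\n", sum(x$edges$sign < 0)))
  invisible(x)
}

network_genes <- function(net) c(net$tf_ids, net$target_ids, net$null_ids)

gene_baselines <- function(net) {
  genes <- network_genes(net)
  set.seed(derive_seed(net$seed, 11L))
  stats::setNames(stats::runif(length(genes), 4, 8), genes)
}

#' Simulate log2 expression from a planted network
#'
#' Expression of each gene in each (fin, region, stage, replicate) sample
#' is its baseline plus the signed, weighted activity of its regulators
#' (TF activity differs by the planted region effect between L and S
#' regions), plus a per-gene per-fin replicate effect and Gaussian noise.
#' TF genes express their own activity; decoy genes receive no TF term.
#'
#' @param net a [generate_planted_network()] result.
#' @param cfg a [simulation_config()].
#' @return numeric matrix (genes x samples, log2 abundance) with the
#'   sample sheet attached as attribute `"samples"`.
#' @export
simulate_expression <- function(net, cfg) {
  stopifnot(inherits(net, "planted_network"), inherits(cfg, "simulation_config"))
  samples <- sample_sheet(cfg)
  genes <- network_genes(net)
  baseline <- gene_baselines(net)
  n_s <- nrow(samples)

  # TF activity per sample: region effect applies only in L regions
  eff <- net$tf_region_effect
  act <- sapply(net$tf_ids, function(tf) {
    e <- eff[eff$tf == tf, ]
    key <- paste(e$fin, e$stage)
    eft <- stats::setNames(e$effect, key)
    ifelse(region_class(samples$region) == "L",
           eft[paste(samples$fin, samples$stage)], 0)
  })
  act <- matrix(act, nrow = n_s, dimnames = list(NULL, net$tf_ids))

  expr <- matrix(rep(baseline, each = n_s), nrow = n_s,
                 dimnames = list(NULL, genes))
  # regulatory contribution for targets
  for (i in seq_len(nrow(net$edges))) {
    ed <- net$edges[i, ]
    expr[, ed$target] <- expr[, ed$target] + ed$sign * ed$weight * act[, ed$tf]
  }
  # TFs express their own activity
  expr[, net$tf_ids] <- expr[, net$tf_ids, drop = FALSE] + act

  set.seed(derive_seed(cfg$seed, 21L))
  # per (gene, fin, replicate) biological replicate effect
  if (cfg$replicate_sd > 0) {
    combos <- unique(samples[, c("fin", "replicate")])
    re <- array(stats::rnorm(length(genes) * nrow(combos), 0, cfg$replicate_sd),
                dim = c(length(genes), nrow(combos)))
    idx <- match(paste(samples$fin, samples$replicate),
                 paste(combos$fin, combos$replicate))
    expr <- expr + t(re[, idx, drop = FALSE])
  }
  if (cfg$noise_sd_expr > 0) {
    expr <- expr + matrix(stats::rnorm(n_s * length(genes), 0, cfg$noise_sd_expr),
                          nrow = n_s)
  }
  out <- t(expr)
  attr(out, "samples") <- samples
  out
}

#' Convert a log2 expression matrix into a raw Cq plate
#'
#' Inverts the quantification model: `Cq = offset(gene) - log2 expression
#' + N(0, noise_sd_cq)`. Reference genes are appended with constant
#' expression (plus the same Cq noise), so that the noiseless plate
#' round-trips exactly through delta-delta-Cq quantification.
#'
#' @param expr matrix from [simulate_expression()].
#' @param cfg a [simulation_config()].
#' @param ref_gene_ids names of the reference genes to append (nonempty).
#' @return data.frame of class `cq_plate` (columns gene, fin, region,
#'   stage, replicate, cq, is_reference).
#' @export
expression_to_cq <- function(expr, cfg, ref_gene_ids = c("ref1", "ref2")) {
  stopifnot(inherits(cfg, "simulation_config"))
  if (length(ref_gene_ids) < 1) stop("ref_gene_ids must be nonempty", call. = FALSE)
  samples <- attr(expr, "samples")
  stopifnot(!is.null(samples))
  genes <- rownames(expr)
  set.seed(derive_seed(cfg$seed, 31L))
  offset <- stats::setNames(stats::runif(length(genes) + length(ref_gene_ids), 30, 34),
                            c(genes, ref_gene_ids))
  ref_expr <- 6  # constant reference-gene abundance, log2 units
  n_s <- nrow(samples)

  rows <- lapply(c(genes, ref_gene_ids), function(g) {
    e <- if (g %in% genes) expr[g, ] else rep(ref_expr, n_s)
    data.frame(gene = g, samples, cq = offset[[g]] - e,
               is_reference = !(g %in% genes), stringsAsFactors = FALSE)
  })
  plate <- do.call(rbind, rows)
  if (cfg$noise_sd_cq > 0) {
    plate$cq <- plate$cq + stats::rnorm(nrow(plate), 0, cfg$noise_sd_cq)
  }
  rownames(plate) <- NULL
  as_cq_plate(plate)
}

#' Simulate a co-expression neighbour database from the planted network
#'
#' Draws `compendium_size` random-condition samples (independent standard
#' normal TF activities propagated through the signed edges plus noise),
#' computes all pairwise Pearson correlations, and stores for each gene
#' its neighbours ranked by descending correlation. The supportability
#' score of a pair is the number of independent compendium batches in
#' which the two genes fall within each other's top-N mutual ranks.
#'
#' @param net a [generate_planted_network()] result.
#' @param cfg a [simulation_config()]; `compendium_size` must be >= 50.
#' @return data.frame of class `coexpression_db` (columns gene, neighbor,
#'   rank, correlation, supportability).
#' @export
build_coexpression_db <- function(net, cfg) {
  stopifnot(inherits(net, "planted_network"), inherits(cfg, "simulation_config"))
  if (cfg$compendium_size < 50) {
    stop("compendium_size must be >= 50", call. = FALSE)
  }
  genes <- network_genes(net)
  m <- cfg$compendium_size
  set.seed(derive_seed(cfg$seed, 41L))
  act <- matrix(stats::rnorm(m * length(net$tf_ids)), nrow = m,
                dimnames = list(NULL, net$tf_ids))
  expr <- matrix(0, nrow = m, ncol = length(genes),
                 dimnames = list(NULL, genes))
  for (i in seq_len(nrow(net$edges))) {
    ed <- net$edges[i, ]
    expr[, ed$target] <- expr[, ed$target] + ed$sign * ed$weight * act[, ed$tf]
  }
  expr[, net$tf_ids] <- expr[, net$tf_ids, drop = FALSE] + act
  expr <- expr + matrix(stats::rnorm(m * length(genes), 0, cfg$compendium_noise_sd),
                        nrow = m)

  full_cor <- stats::cor(expr)
  batch <- rep(seq_len(cfg$n_batches), length.out = m)[order(seq_len(m))]
  batch <- sort(batch)
  support <- matrix(0L, length(genes), length(genes),
                    dimnames = list(genes, genes))
  for (b in seq_len(cfg$n_batches)) {
    cb <- stats::cor(expr[batch == b, , drop = FALSE])
    diag(cb) <- -Inf
    # top-N neighbour matrix: in_top[i, j] TRUE if j is among i's top N
    in_top <- t(apply(cb, 1, function(r) {
      rank(-r, ties.method = "first") <= cfg$mutual_rank_n
    }))
    mutual <- in_top & t(in_top)
    support <- support + mutual
  }

  db <- do.call(rbind, lapply(genes, function(g) {
    nb <- setdiff(genes, g)
    r <- full_cor[g, nb]
    ord <- order(-r, nb)
    data.frame(gene = g, neighbor = nb[ord], rank = seq_along(nb),
               correlation = unname(r[ord]),
               supportability = support[g, nb[ord]],
               stringsAsFactors = FALSE)
  }))
  rownames(db) <- NULL
  class(db) <- c("coexpression_db", "data.frame")
  db
}

#' Neighbour list of one gene in a co-expression database
#'
#' @param db a [build_coexpression_db()] result (or one read from file).
#' @param gene gene identifier; must be present in the database.
#' @return data.frame of neighbours in rank order.
#' @export
db_neighbors <- function(db, gene) {
  if (!gene %in% db$gene) {
    stop("gene absent from co-expression database: ", gene, call. = FALSE)
  }
  out <- db[db$gene == gene, , drop = FALSE]
  out[order(out$rank), , drop = FALSE]
}

#' Default seed genes of a planted network
#'
#' One lexicographically-first positively-regulated target per TF, plus
#' the first repressed target (the synthetic analogue of starting from a
#' known higher-S gene).
#'
#' @param net a [generate_planted_network()] result.
#' @return character vector of target identifiers.
#' @export
default_seeds <- function(net) {
  ed <- net$edges
  pos <- vapply(net$tf_ids, function(tf) {
    tg <- sort(ed$target[ed$tf == tf & ed$sign > 0])
    if (length(tg)) tg[1] else NA_character_
  }, character(1))
  neg <- sort(ed$target[ed$sign < 0])
  seeds <- unique(c(pos[!is.na(pos)], if (length(neg)) neg[1]))
  sort(seeds)
}
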