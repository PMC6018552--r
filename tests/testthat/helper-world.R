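# Synthetic-world builders shared across the suite. All fixtures are
# generated in code; nothing is read from disk.

make_world <- function(seed = 1, n_tfs = 3, n_targets = 12, n_nulls = 20,
                       effect_size = 1, tfs_per_target = 1, ...) {
  cfg <- simulation_config(seed = seed, ...)
  net <- generate_planted_network(n_tfs, n_targets, n_nulls,
                                  effect_size = effect_size, seed = seed,
                                  tfs_per_target = tfs_per_target)
  expr <- simulate_expression(net, cfg)
  plate <- expression_to_cq(expr, cfg)
  list(cfg = cfg, net = net, expr = expr, plate = plate)
}

noiseless_config <- function(seed = 1, ...) {
  simulation_config(seed = seed, noise_sd_cq = 0, replicate_sd = 0,
                    noise_sd_expr = 0, ...)
}

# rq_table scaffold for direct statistical tests: one gene, one fin,
# paired L/S log2-RQ observations by replicate
make_rq_pairs <- function(l, s, fin = "dorsal", stage = 0, gene = "g1") {
  lay <- fin_layout()[[fin]]
  df <- rbind(
    data.frame(gene = gene, fin = fin, region = lay$L[1], stage = stage,
               replicate = seq_along(l), log_rq = l, stringsAsFactors = FALSE),
    data.frame(gene = gene, fin = fin, region = lay$S[1], stage = stage,
               replicate = seq_along(s), log_rq = s, stringsAsFactors = FALSE)
  )
  df$rq <- 2^df$log_rq
  df$delta_cq <- -df$log_rq
  df$delta_delta_cq <- -df$log_rq
  class(df) <- c("rq_table", "data.frame")
  df
}

# hand-built significance matrix rows for consistency_call tests
sig_row <- function(gene, fin, l_region, stage, p, direction) {
  data.frame(gene = gene, fin = fin, l_region = l_region, stage = stage,
             n = 3L, mean_diff = ifelse(direction == "higher-L", 1, -1),
             t = 5, df = 2L, p = p, direction = direction, degenerate = FALSE,
             stringsAsFactors = FALSE)
}

as_sig <- function(...) {
  m <- do.call(rbind, list(...))
  class(m) <- c("significance_matrix", "data.frame")
  m
}

# minimal hand-built co-expression database
make_db <- function(rows) {
  db <- do.call(rbind, lapply(rows, function(r) {
    data.frame(gene = r$gene, neighbor = r$neighbor,
               rank = seq_along(r$neighbor),
               correlation = r$correlation,
               supportability = r$supportability, stringsAsFactors = FALSE)
  }))
  class(db) <- c("coexpression_db", "data.frame")
  db
}

# independent reverse complement used by the oracles
reverse_complement_chr <- function(x) {
  vapply(x, function(s) {
    paste(rev(strsplit(chartr("ACGT", "TGCA", s), "")[[1]]), collapse = "")
  }, character(1), USE.NAMES = FALSE)
}

# rq_table over a pooled design for direct correlation tests;
# values: named list gene -> numeric vector (up to 9 observations)
rq_from_values <- function(values) {
  n <- length(values[[1]])
  design <- expand.grid(replicate = 1:3, fin = c("dorsal", "anal", "caudal"),
                        stringsAsFactors = FALSE)[seq_len(n), ]
  design$stage <- 0
  design$region <- vapply(design$fin, function(f) fin_layout()[[f]]$L[1], "")
  df <- do.call(rbind, lapply(names(values), function(g) {
    cbind(data.frame(gene = g, stringsAsFactors = FALSE), design,
          data.frame(log_rq = values[[g]]))
  }))
  df$rq <- 2^df$log_rq
  class(df) <- c("rq_table", "data.frame")
  df
}
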