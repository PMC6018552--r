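#' Pairwise Pearson correlations on log2 RQ
#'
#' Observations for a gene pair are all (fin, region, stage, replicate)
#' cells shared by the two genes, either pooled across fins or restricted
#' to one fin. The two-tailed p-value comes from the t transform with
#' n - 2 degrees of freedom; pairs with fewer than 4 shared observations
#' are reported as not computable (NA), not as an error.
#'
#' @param rq_table a [relative_quantities()] table.
#' @param genes genes to correlate (default all in the table).
#' @param fin optional fin name to restrict the observations to.
#' @return list of matrices `r`, `p`, `n`.
#' @export
pairwise_correlations <- function(rq_table, genes = NULL, fin = NULL) {
  d <- rq_table
  if (!is.null(fin)) d <- d[d$fin == fin, , drop = FALSE]
  genes <- genes %||% sort(unique(d$gene))
  key <- sample_key(d$fin, d$region, d$stage, d$replicate)
  cells <- sort(unique(key))
  mat <- matrix(NA_real_, nrow = length(cells), ncol = length(genes),
                dimnames = list(cells, genes))
  idx <- d$gene %in% genes
  mat[cbind(match(key[idx], cells), match(d$gene[idx], genes))] <- d$log_rq[idx]

  k <- length(genes)
  r <- matrix(NA_real_, k, k, dimnames = list(genes, genes))
  p <- r
  nmat <- matrix(0L, k, k, dimnames = list(genes, genes))
  for (i in seq_len(k)) {
    for (j in seq_len(k)) {
      if (j <= i) next
      ok <- stats::complete.cases(mat[, c(i, j)])
      n <- sum(ok)
      nmat[i, j] <- nmat[j, i] <- n
      if (n < 4) next
      rij <- stats::cor(mat[ok, i], mat[ok, j])
      r[i, j] <- r[j, i] <- rij
      if (abs(rij) >= 1) {
        p[i, j] <- p[j, i] <- 0
      } else {
        tv <- rij * sqrt((n - 2) / (1 - rij^2))
        p[i, j] <- p[j, i] <- 2 * stats::pt(-abs(tv), df = n - 2)
      }
    }
  }
  diag(r) <- 1
  diag(p) <- 0
  diag(nmat) <- 0L
  list(r = r, p = p, n = nmat)
}

#' Build the correlation network
#'
#' Creates an edge for every gene pair whose pooled two-tailed p-value is
#' below `alpha_pooled` (no multiple-testing correction, by design). The
#' `all_fins` flag marks edges that are also significant within every fin
#' separately at `alpha_fin`.
#'
#' @param pooled result of [pairwise_correlations()] on pooled data.
#' @param per_fin named list of per-fin [pairwise_correlations()] results
#'   on the same gene set.
#' @param alpha_pooled,alpha_fin significance levels (defaults 0.01).
#' @return data.frame of class `network_edges`: gene_a, gene_b, r, p,
#'   sign, per-fin r/p/significance columns, all_fins.
#' @export
build_network <- function(pooled, per_fin = list(), alpha_pooled = 0.01,
                          alpha_fin = 0.01) {
  stopifnot(alpha_pooled > 0, alpha_pooled <= 1, alpha_fin > 0, alpha_fin <= 1)
  genes <- colnames(pooled$r)
  for (pf in per_fin) {
    if (!identical(colnames(pf$r), genes)) {
      stop("per-fin matrices must cover the same gene set", call. = FALSE)
    }
  }
  edges <- list()
  for (i in seq_along(genes)) {
    for (j in seq_along(genes)) {
      if (j <= i) next
      pv <- pooled$p[i, j]
      if (is.na(pv) || pv >= alpha_pooled) next
      row <- data.frame(gene_a = genes[i], gene_b = genes[j],
                        r = pooled$r[i, j], p = pv,
                        sign = ifelse(pooled$r[i, j] >= 0, "+", "-"),
                        stringsAsFactors = FALSE)
      all_fins <- length(per_fin) > 0
      for (f in names(per_fin)) {
        rf <- per_fin[[f]]$r[i, j]
        pf <- per_fin[[f]]$p[i, j]
        sig <- !is.na(pf) && pf < alpha_fin
        row[[paste0("r_", f)]] <- rf
        row[[paste0("p_", f)]] <- pf
        row[[paste0("sig_", f)]] <- sig
        all_fins <- all_fins && sig
      }
      row$all_fins <- all_fins
      edges[[length(edges) + 1]] <- row
    }
  }
  out <- if (length(edges)) do.call(rbind, edges) else
    data.frame(gene_a = character(), gene_b = character(), r = numeric(),
               p = numeric(), sign = character(), all_fins = logical(),
               stringsAsFactors = FALSE)
  rownames(out) <- NULL
  attr(out, "alpha_pooled") <- alpha_pooled
  attr(out, "alpha_fin") <- alpha_fin
  class(out) <- c("network_edges", "data.frame")
  out
}

#' Classify candidate regulator roles from edge signs
#'
#' Counts, for each TF, its positive and negative network edges to the
#' network genes: a TF whose positive edges strictly dominate is an
#' activator candidate, one dominated by negative edges a repressor
#' candidate, ties are ambiguous. Purely descriptive.
#'
#' @param edges a [build_network()] edge table.
#' @param tf_ids TF gene ids.
#' @param network_gene_ids the (non-TF) network gene ids.
#' @return data.frame (tf, n_positive, n_negative, role).
#' @export
classify_tf_roles <- function(edges, tf_ids, network_gene_ids) {
  rows <- lapply(sort(tf_ids), function(tf) {
    sel <- (edges$gene_a == tf & edges$gene_b %in% network_gene_ids) |
      (edges$gene_b == tf & edges$gene_a %in% network_gene_ids)
    np <- sum(edges$sign[sel] == "+")
    nn <- sum(edges$sign[sel] == "-")
    role <- if (np > nn) "activator-candidate" else
      if (nn > np) "repressor-candidate" else "ambiguous"
    data.frame(tf = tf, n_positive = np, n_negative = nn, role = role,
               stringsAsFactors = FALSE)
  })
  out <- do.call(rbind, rows)
  rownames(out) <- NULL
  out
}

num17 <- function(x) {
  ifelse(is.na(x), "NA", sprintf("%.17g", x))
}

#' Export a correlation network
#'
#' Writes the edge list as SIF (topology only), GraphML (with r, p, sign
#' and the all-fins flag as edge attributes; round-trips losslessly
#' through [read_network_graphml()]), or a plain TSV.
#'
#' @param edges a [build_network()] edge table.
#' @param path output file path.
#' @param format one of `"sif"`, `"graphml"`, `"tsv"`.
#' @param force allow writing an empty network (default FALSE).
#' @return `path`, invisibly.
#' @export
export_network <- function(edges, path, format = c("sif", "graphml", "tsv"),
                           force = FALSE) {
  format <- match.arg(format)
  if (!nrow(edges) && !force) {
    stop("refusing to export an empty network (use force = TRUE)", call. = FALSE)
  }
  if (format == "sif") {
    lines <- sprintf("%s\t%s\t%s", edges$gene_a,
                     ifelse(edges$sign == "+", "positive", "negative"),
                     edges$gene_b)
    writeLines(lines, path)
  } else if (format == "tsv") {
    utils::write.table(edges, path, sep = "\t", quote = FALSE, row.names = FALSE)
  } else {
    nodes <- sort(unique(c(edges$gene_a, edges$gene_b)))
    con <- file(path, "w")
    on.exit(close(con))
    writeLines(c(
      '<?xml version="1.0" encoding="UTF-8"?>',
      '<graphml xmlns="http://graphml.graphdrawing.org/xmlns">',
      '  <key id="r" for="edge" attr.name="r" attr.type="double"/>',
      '  <key id="p" for="edge" attr.name="p" attr.type="double"/>',
      '  <key id="sign" for="edge" attr.name="sign" attr.type="string"/>',
      '  <key id="all_fins" for="edge" attr.name="all_fins" attr.type="boolean"/>',
      '  <graph id="G" edgedefault="undirected">'), con)
    writeLines(sprintf('    <node id="%s"/>', nodes), con)
    if (nrow(edges)) {
      writeLines(sprintf(paste0(
        '    <edge source="%s" target="%s">',
        '<data key="r">%s</data><data key="p">%s</data>',
        '<data key="sign">%s</data><data key="all_fins">%s</data></edge>'),
        edges$gene_a, edges$gene_b, num17(edges$r), num17(edges$p),
        edges$sign, tolower(as.character(edges$all_fins))), con)
    }
    writeLines(c("  </graph>", "</graphml>"), con)
  }
  invisible(path)
}

#' Read a GraphML network written by [export_network()]
#'
#' @param path GraphML file path.
#' @return data.frame (gene_a, gene_b, r, p, sign, all_fins).
#' @export
read_network_graphml <- function(path) {
  doc <- xml2::read_xml(path)
  ns <- xml2::xml_ns_rename(xml2::xml_ns(doc), d1 = "g")
  es <- xml2::xml_find_all(doc, ".//g:edge", ns)
  get_data <- function(e, key) {
    xml2::xml_text(xml2::xml_find_first(e, sprintf(".//g:data[@key='%s']", key), ns))
  }
  rows <- lapply(es, function(e) {
    data.frame(gene_a = xml2::xml_attr(e, "source"),
               gene_b = xml2::xml_attr(e, "target"),
               r = as.numeric(get_data(e, "r")),
               p = as.numeric(get_data(e, "p")),
               sign = get_data(e, "sign"),
               all_fins = get_data(e, "all_fins") == "true",
               stringsAsFactors = FALSE)
  })
  out <- if (length(rows)) do.call(rbind, rows) else
    data.frame(gene_a = character(), gene_b = character(), r = numeric(),
               p = numeric(), sign = character(), all_fins = logical(),
               stringsAsFactors = FALSE)
  rownames(out) <- NULL
  out
}

#' Read a SIF file written by [export_network()]
#'
#' @param path SIF file path.
#' @return data.frame (gene_a, sign, gene_b).
#' @export
read_network_sif <- function(path) {
  d <- utils::read.table(path, sep = "\t", header = FALSE,
                         col.names = c("gene_a", "interaction", "gene_b"),
                         stringsAsFactors = FALSE)
  d$sign <- ifelse(d$interaction == "positive", "+", "-")
  d[, c("gene_a", "sign", "gene_b")]
}
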