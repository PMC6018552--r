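#' Construct a position weight matrix object
#'
#' @param id motif identifier.
#' @param mat 4 x width numeric matrix of per-column base frequencies,
#'   rows in A, C, G, T order; each column must sum to 1 (to 1e-9).
#' @param tf optional transcription-factor gene this PWM models.
#' @param pseudocount probability mass added per base before log-odds or
#'   correlation computations (default 0.01).
#' @param background background base frequencies (default uniform).
#' @return object of class `pwm`.
#' @export
pwm <- function(id, mat, tf = NULL, pseudocount = 0.01,
                background = rep(0.25, 4)) {
  mat <- as.matrix(mat)
  if (nrow(mat) != 4) stop("PWM matrix must have 4 rows (A, C, G, T)", call. = FALSE)
  if (ncol(mat) < 4) stop("PWM width must be >= 4", call. = FALSE)
  if (any(abs(colSums(mat) - 1) > 1e-9)) {
    stop("each PWM column must sum to 1", call. = FALSE)
  }
  rownames(mat) <- DNA_BASES
  structure(list(id = id, matrix = mat, tf = tf,
                 pseudocount = pseudocount, background = background),
            class = "pwm")
}

#' @export
print.pwm <- function(x, ...) {
  cat(sprintf("pwm %s (width %d%s), consensus %s, %.2f bits/column\n",
              x$id, pwm_width(x),
              if (is.null(x$tf)) "" else paste0(", TF ", x$tf),
              pwm_consensus(x), mean(pwm_ic(x))))
  invisible(x)
}

#' @export
#' @rdname pwm
pwm_width <- function(x) ncol(x$matrix)

#' Per-column information content of a PWM, in bits
#' @param x a [pwm()] object.
#' @return numeric vector (one value per column).
#' @export
pwm_ic <- function(x) {
  apply(x$matrix, 2, function(p) {
    p <- p[p > 0]
    2 + sum(p * log2(p))
  })
}

#' @export
#' @rdname pwm_ic
pwm_consensus <- function(x) {
  paste(DNA_BASES[apply(x$matrix, 2, which.max)], collapse = "")
}

#' Reverse complement of a PWM
#' @param x a [pwm()] object.
#' @return a [pwm()] with columns reversed and bases complemented.
#' @export
pwm_revcomp <- function(x) {
  m <- x$matrix[c("T", "G", "C", "A"), rev(seq_len(pwm_width(x))), drop = FALSE]
  rownames(m) <- DNA_BASES
  pwm(paste0(x$id, "_rc"), m, tf = x$tf, pseudocount = x$pseudocount,
      background = x$background)
}

# pseudocount-regularized frequencies
pwm_freq <- function(x) {
  (x$matrix + x$pseudocount) / (1 + 4 * x$pseudocount)
}

# base frequency giving a column information content of `ic` bits when one
# base has probability p and the rest share (1 - p) equally
solve_consensus_p <- function(ic) {
  ic <- min(max(ic, 0), 2 - 1e-9)
  if (ic < 1e-9) return(0.25)
  f <- function(p) 2 + p * log2(p) + (1 - p) * log2((1 - p) / 3) - ic
  stats::uniroot(f, c(0.25 + 1e-9, 1 - 1e-12), tol = 1e-12)$root
}

#' Generate a synthetic PWM library
#'
#' Builds `n_pwms` position weight matrices with per-column information
#' content fixed at `info_content` bits (a random consensus base holds
#' the solved probability mass, the remaining bases share the rest).
#' When `tf_ids` is given, the first matrices are assigned to those TFs
#' (ids `M_<tf>`); the remainder are unassigned distractors.
#'
#' @param n_pwms number of matrices (>= length(tf_ids)).
#' @param width_range inclusive (min, max) width; must satisfy
#'   4 <= min <= max <= 20.
#' @param info_content target bits per column in [0, 2].
#' @param seed integer seed.
#' @param tf_ids optional TF gene ids to anchor the leading matrices.
#' @return list of [pwm()] objects.
#' @export
generate_pwm_library <- function(n_pwms, width_range = c(8, 12),
                                 info_content = 1.9, seed = 1,
                                 tf_ids = NULL) {
  stopifnot(is_count(n_pwms), length(width_range) == 2)
  if (width_range[1] < 4 || width_range[2] > 20 ||
      width_range[1] > width_range[2]) {
    stop("width_range must satisfy 4 <= min <= max <= 20", call. = FALSE)
  }
  if (!is.null(tf_ids) && n_pwms < length(tf_ids)) {
    stop("n_pwms must cover all tf_ids", call. = FALSE)
  }
  set.seed(derive_seed(seed, 51L))
  p <- solve_consensus_p(info_content)
  widths <- seq(width_range[1], width_range[2])
  lapply(seq_len(n_pwms), function(i) {
    w <- widths[sample.int(length(widths), 1)]
    cons <- sample(4, w, replace = TRUE)
    mat <- matrix((1 - p) / 3, nrow = 4, ncol = w)
    mat[cbind(cons, seq_len(w))] <- p
    tf <- if (!is.null(tf_ids) && i <= length(tf_ids)) tf_ids[i] else NULL
    id <- if (is.null(tf)) sprintf("M%03d", i) else paste0("M_", tf)
    pwm(id, mat, tf = tf)
  })
}

#' Generate promoter sequences with planted binding sites
#'
#' Background sequences are order-0 uniform random DNA of
#' `cfg$promoter_length` bases, one per gene of the network (TFs,
#' targets and decoys). For every regulatory edge, with probability
#' `plant_rate` a site sampled column-wise from the regulating TF's PWM
#' is written into the target's promoter at a random position and
#' strand. Planted positions are logged as ground truth.
#'
#' @param net a [generate_planted_network()] result.
#' @param library PWM library containing a matrix for every TF of `net`.
#' @param cfg a [simulation_config()].
#' @param plant_rate per-edge planting probability (default 0.9, so that
#'   sites are occasionally missing).
#' @return object of class `promoter_set`: named character vector of
#'   sequences with the site log in attribute `"sites"`.
#' @export
generate_promoters <- function(net, library, cfg, plant_rate = 0.9) {
  stopifnot(inherits(net, "planted_network"), inherits(cfg, "simulation_config"))
  tfs_with_pwm <- unlist(lapply(library, `[[`, "tf"))
  missing <- setdiff(unique(net$edges$tf), tfs_with_pwm)
  if (length(missing)) {
    stop("no PWM in library for TF(s): ", paste(missing, collapse = ", "),
         call. = FALSE)
  }
  max_w <- max(vapply(library, pwm_width, integer(1)))
  if (cfg$promoter_length < max_w) {
    stop("promoter_length must be >= the widest PWM", call. = FALSE)
  }
  genes <- network_genes(net)
  L <- cfg$promoter_length
  set.seed(derive_seed(cfg$seed, 61L))
  seqs <- stats::setNames(vapply(genes, function(g) {
    paste(sample(DNA_BASES, L, replace = TRUE), collapse = "")
  }, character(1)), genes)

  by_tf <- stats::setNames(
    lapply(unique(net$edges$tf), function(tf) {
      library[[which(tfs_with_pwm == tf)[1] ]]
    }), unique(net$edges$tf))

  sites <- list()
  for (i in seq_len(nrow(net$edges))) {
    ed <- net$edges[i, ]
    if (stats::runif(1) >= plant_rate) next
    pw <- by_tf[[ed$tf]]
    w <- pwm_width(pw)
    site <- paste(apply(pw$matrix, 2, function(p) sample(DNA_BASES, 1, prob = p)),
                  collapse = "")
    pos <- sample.int(L - w + 1, 1) - 1L  # 0-based start
    strand <- sample(c("+", "-"), 1)
    inserted <- if (strand == "+") site else reverse_complement(site)
    substr(seqs[[ed$target]], pos + 1, pos + w) <- inserted
    sites[[length(sites) + 1]] <- data.frame(
      gene = ed$target, pwm = pw$id, tf = ed$tf, start = pos,
      end = pos + w, strand = strand, site = site, stringsAsFactors = FALSE)
  }
  site_log <- if (length(sites)) do.call(rbind, sites) else
    data.frame(gene = character(), pwm = character(), tf = character(),
               start = integer(), end = integer(), strand = character(),
               site = character(), stringsAsFactors = FALSE)
  structure(seqs, sites = site_log, class = "promoter_set")
}

#' Extract upstream promoter windows from a genome
#'
#' For plus-strand genes the `length` bases ending at (and excluding) the
#' TSS; for minus-strand genes the reverse complement of the `length`
#' bases starting at the TSS. Coordinates are 0-based and half-open.
#' Windows truncated at contig edges are flagged.
#'
#' @param genome named character vector (or `Biostrings::DNAStringSet`)
#'   of contig sequences.
#' @param annotation data.frame with columns gene, seqname, tss, strand
#'   (tss 0-based, strand `"+"`/`"-"`).
#' @param length window length in bases (>= 1).
#' @return named character vector of promoter sequences, attribute
#'   `"truncated"` flagging shortened windows.
#' @export
extract_promoters <- function(genome, annotation, length = 4000) {
  if (methods::is(genome, "DNAStringSet")) genome <- as.character(genome)
  stopifnot(is_count(length))
  absent <- setdiff(annotation$seqname, names(genome))
  if (nrow(annotation) && length(absent)) {
    bad <- annotation$gene[annotation$seqname %in% absent]
    stop("contig absent from genome for gene(s): ",
         paste(bad, collapse = ", "), call. = FALSE)
  }
  res <- character(nrow(annotation))
  trunc <- logical(nrow(annotation))
  for (i in seq_len(nrow(annotation))) {
    a <- annotation[i, ]
    contig <- genome[[a$seqname]]
    clen <- nchar(contig)
    if (a$strand == "+") {
      from <- max(0, a$tss - length)
      to <- min(a$tss, clen)
      s <- substr(contig, from + 1, to)
    } else {
      from <- max(0, a$tss)
      to <- min(a$tss + length, clen)
      s <- reverse_complement(substr(contig, from + 1, to))
    }
    trunc[i] <- nchar(s) < length
    res[i] <- s
  }
  names(res) <- annotation$gene
  attr(res, "truncated") <- stats::setNames(trunc, annotation$gene)
  res
}

encode_dna <- function(seq) {
  code <- match(strsplit(toupper(seq), "", fixed = TRUE)[[1]], DNA_BASES)
  code
}

#' Scan a promoter for PWM binding sites
#'
#' Computes the base-2 log-odds score of the PWM (pseudocount-regularized
#' frequencies against its background model) at every offset on both
#' strands and reports hits scoring at least `score_fraction` of the
#' maximum attainable score. Positions are 0-based, half-open, in
#' forward-strand coordinates; minus-strand hits carry strand `"-"`.
#'
#' @param x a [pwm()] object.
#' @param promoter a single sequence (character scalar).
#' @param score_fraction fraction of the maximum score required (default 0.8).
#' @return data.frame of class `motif_hits` (start, end, strand, score).
#' @export
scan_binding_sites <- function(x, promoter, score_fraction = 0.8) {
  w <- pwm_width(x)
  L <- nchar(promoter)
  if (L < w) stop("promoter shorter than PWM width", call. = FALSE)
  lo_f <- log2(pwm_freq(x) / x$background)
  lo_r <- log2(pwm_freq(pwm_revcomp(x)) / x$background)
  max_score <- sum(apply(lo_f, 2, max))
  threshold <- score_fraction * max_score
  code <- encode_dna(promoter)
  n_off <- L - w + 1
  score_strand <- function(lo) {
    s <- numeric(n_off)
    for (j in seq_len(w)) {
      v <- lo[, j][code[seq_len(n_off) + j - 1]]
      v[is.na(v)] <- -Inf  # non-ACGT base voids the window
      s <- s + v
    }
    s
  }
  sf <- score_strand(lo_f)
  sr <- score_strand(lo_r)
  strand_hits <- function(s, strand) {
    idx <- which(s >= threshold)
    data.frame(start = idx - 1L, strand = rep(strand, length(idx)),
               score = s[idx], stringsAsFactors = FALSE)
  }
  hits <- rbind(strand_hits(sf, "+"), strand_hits(sr, "-"))
  hits$end <- hits$start + w
  hits <- hits[order(hits$start, hits$strand), c("start", "end", "strand", "score")]
  rownames(hits) <- NULL
  attr(hits, "max_score") <- max_score
  class(hits) <- c("motif_hits", "data.frame")
  hits
}

col_correlation <- function(a, b) {
  if (stats::sd(a) == 0 || stats::sd(b) == 0) return(0)
  stats::cor(a, b)
}

match_orientation <- function(A, B) {
  # mean per-column Pearson over all ungapped offsets; returns best
  wa <- ncol(A); wb <- ncol(B)
  best <- list(score = -Inf, offset = NA_integer_)
  for (off in seq(-(wa - 1), wb - 1)) {
    ia <- seq_len(wa)
    ib <- ia + off
    keep <- ib >= 1 & ib <= wb
    if (!any(keep)) next
    ia <- ia[keep]; ib <- ib[keep]
    cors <- vapply(seq_along(ia), function(k) {
      col_correlation(A[, ia[k]], B[, ib[k]])
    }, numeric(1))
    sc <- mean(cors)
    if (length(ia) >= attr(A, "min_overlap") && sc > best$score) {
      best <- list(score = sc, offset = off, overlap = length(ia))
    }
  }
  best
}

#' Match a motif against a PWM library by column correlation
#'
#' Aligns the motif to every library matrix over all ungapped offsets and
#' both orientations with at least `min_overlap` overlapping columns; the
#' score of an alignment is the mean per-column Pearson correlation of
#' the pseudocount-regularized frequency columns. The best alignment per
#' library entry is reported, ranked by descending score (ties broken by
#' library id).
#'
#' @param motif a [pwm()] object.
#' @param library nonempty list of [pwm()] objects.
#' @param min_overlap minimum overlapping columns (default 5).
#' @return data.frame (library_id, tf, score, offset, orientation).
#' @export
match_motif_to_library <- function(motif, library, min_overlap = 5) {
  if (!length(library)) stop("PWM library is empty", call. = FALSE)
  if (min_overlap > pwm_width(motif) ||
      any(min_overlap > vapply(library, pwm_width, integer(1)))) {
    stop("min_overlap exceeds a PWM width", call. = FALSE)
  }
  A <- pwm_freq(motif)
  attr(A, "min_overlap") <- min_overlap
  rows <- lapply(library, function(lib) {
    fw <- match_orientation(A, pwm_freq(lib))
    rv <- match_orientation(A, pwm_freq(pwm_revcomp(lib)))
    if (fw$score >= rv$score) {
      data.frame(library_id = lib$id, tf = lib$tf %||% NA_character_,
                 score = fw$score, offset = fw$offset, orientation = "+",
                 stringsAsFactors = FALSE)
    } else {
      data.frame(library_id = lib$id, tf = lib$tf %||% NA_character_,
                 score = rv$score, offset = rv$offset, orientation = "-",
                 stringsAsFactors = FALSE)
    }
  })
  out <- do.call(rbind, rows)
  out <- out[order(-out$score, out$library_id), ]
  rownames(out) <- NULL
  out
}
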