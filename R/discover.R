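# --- enumerative motif discovery -------------------------------------------
#
# A transparent stand-in for EM-based discovery tools: words of each width
# are counted on both strands (a word and its reverse complement form one
# class), scored by the binomial tail probability of their promoter
# presence against an analytic symmetric order-0 background, Bonferroni-
# corrected within each width, and greedily collapsed (a chosen seed masks
# classes within Hamming distance 1). Each accepted seed is expanded into
# a PWM from its exact and one-mismatch occurrences.

word_ids <- function(code, w) {
  n <- length(code) - w + 1
  if (n < 1) return(list(id = numeric(0), rc = numeric(0)))
  id <- numeric(n)
  rc <- numeric(n)
  for (j in seq_len(w)) {
    v <- code[seq_len(n) + j - 1]
    id <- id + (v - 1) * 4^(w - j)
    rc <- rc + (4 - v) * 4^(j - 1)
  }
  list(id = id, rc = rc)
}

id_to_digits <- function(id, w) {
  d <- integer(w)
  for (j in seq(w, 1)) {
    d[j] <- as.integer(id %% 4)
    id <- id %/% 4
  }
  d + 1L
}

digits_to_id <- function(d, w) sum((d - 1) * 4^(seq(w, 1) - 1))

digits_rc <- function(d) rev(5L - d)

# canonical ids of all words within Hamming distance 1 of the class
hd1_class_ids <- function(d, w) {
  ids <- digits_to_id(d, w)
  for (j in seq_len(w)) {
    for (b in setdiff(1:4, d[j])) {
      dd <- d
      dd[j] <- b
      ids <- c(ids, digits_to_id(dd, w))
    }
  }
  rcs <- vapply(ids, function(i) digits_to_id(digits_rc(id_to_digits(i, w)), w),
                numeric(1))
  unique(pmin(ids, rcs))
}

#' Discover over-represented motifs in a promoter set
#'
#' Enumerates all words of each width on both strands of the promoter
#' set, scores each word class (a word and its reverse complement) by
#' the binomial tail probability of the number of promoters containing
#' it, against an analytic symmetric order-0 background estimated from
#' the input, and keeps classes passing a per-width Bonferroni threshold
#' at `alpha`. Significant classes are picked greedily by ascending
#' p-value; an accepted seed masks all classes within Hamming distance 1.
#' Each seed's PWM is built from its occurrences with at most one
#' mismatch (both strands, oriented to the seed) with pseudocounts.
#'
#' @param promoters named character vector (or `promoter_set`) of at
#'   least 3 sequences, each at least `max(widths)` long.
#' @param widths word widths to scan (default 6:10).
#' @param top_m maximum number of motifs to return, ranked by enrichment.
#' @param alpha per-width family-wise significance level (default 0.05).
#' @return list of motifs; each has elements `pwm`, `seed_word`, `width`,
#'   `presence`, `presence_fraction`, `p_value`, `enrichment`.
#' @export
discover_motifs <- function(promoters, widths = 6:10, top_m = 5, alpha = 0.05) {
  seqs <- as.character(promoters)
  names(seqs) <- names(promoters)
  if (length(seqs) < 3) stop("need >= 3 promoter sequences", call. = FALSE)
  if (any(nchar(seqs) < max(widths))) {
    stop("promoters shorter than the maximum motif width", call. = FALSE)
  }
  codes <- lapply(seqs, encode_dna)
  n_prom <- length(codes)

  # symmetric background base frequencies (input plus reverse complement)
  tab <- table(factor(unlist(codes), levels = 1:4))
  pb <- as.numeric(tab + rev(tab)) / (2 * sum(tab))

  found <- list()
  for (w in widths) {
    ids <- lapply(codes, word_ids, w = w)
    canon <- lapply(ids, function(x) pmin(x$id, x$rc))
    presence_tab <- table(unlist(lapply(canon, unique)))
    pres <- as.integer(presence_tab)
    cls <- as.numeric(names(presence_tab))
    n_classes <- 4^w / 2
    n_pos <- mean(nchar(seqs)) - w + 1

    digits <- t(vapply(cls, id_to_digits, integer(w), w = w))
    log_p_word <- rowSums(matrix(log(pb[digits]), ncol = w))
    palindrome <- vapply(seq_along(cls), function(i) {
      all(digits_rc(digits[i, ]) == digits[i, ])
    }, logical(1))
    p_class <- exp(log_p_word) * ifelse(palindrome, 1, 2)
    q <- 1 - (1 - p_class)^n_pos
    pval <- stats::pbinom(pres - 1, n_prom, q, lower.tail = FALSE)
    keep <- which(pval * n_classes < alpha)
    if (!length(keep)) next

    word_str <- apply(digits, 1, function(d) paste(DNA_BASES[d], collapse = ""))
    ord <- keep[order(pval[keep], word_str[keep])]
    masked <- numeric(0)
    for (i in ord) {
      if (cls[i] %in% masked) next
      d <- digits[i, ]
      masked <- c(masked, hd1_class_ids(d, w))
      mot <- build_seed_pwm(codes, d, w)
      mot$seed_word <- word_str[i]
      mot$width <- w
      mot$presence <- pres[i]
      mot$presence_fraction <- pres[i] / n_prom
      mot$p_value <- pval[i] * n_classes
      mot$enrichment <- -log10(max(pval[i] * n_classes, 1e-300))
      found[[length(found) + 1]] <- mot
    }
  }
  if (!length(found)) return(list())
  ord <- order(vapply(found, `[[`, numeric(1), "p_value"),
               vapply(found, `[[`, character(1), "seed_word"))
  found[utils::head(ord, top_m)]
}

build_seed_pwm <- function(codes, seed_digits, w) {
  rc_digits <- digits_rc(seed_digits)
  counts <- matrix(0, nrow = 4, ncol = w)
  for (code in codes) {
    n <- length(code) - w + 1
    if (n < 1) next
    hd_f <- integer(n)
    hd_r <- integer(n)
    for (j in seq_len(w)) {
      v <- code[seq_len(n) + j - 1]
      hd_f <- hd_f + (v != seed_digits[j])
      hd_r <- hd_r + (v != rc_digits[j])
    }
    for (i in which(hd_f <= 1)) {
      win <- code[i:(i + w - 1)]
      counts[cbind(win, seq_len(w))] <- counts[cbind(win, seq_len(w))] + 1
    }
    for (i in which(hd_r <= 1 & hd_f > 1)) {
      win <- 5L - rev(code[i:(i + w - 1)])  # orient to the seed
      counts[cbind(win, seq_len(w))] <- counts[cbind(win, seq_len(w))] + 1
    }
  }
  counts <- counts + 0.25  # pseudocount
  freq <- sweep(counts, 2, colSums(counts), "/")
  seed_word <- paste(DNA_BASES[seed_digits], collapse = "")
  list(pwm = pwm(paste0("m", w, "_", seed_word), freq))
}

#' Keep motifs present in at least a fraction of the promoters
#'
#' Retains motifs whose promoter presence count reaches
#' `ceiling(threshold_fraction * n_genes)`.
#'
#' @param motifs list from [discover_motifs()].
#' @param n_genes number of promoters the motifs were discovered in.
#' @param threshold_fraction required fraction (default 0.5).
#' @return filtered list.
#' @export
filter_shared_motifs <- function(motifs, n_genes, threshold_fraction = 0.5) {
  stopifnot(threshold_fraction >= 0, threshold_fraction <= 1)
  need <- ceiling(threshold_fraction * n_genes)
  Filter(function(m) m$presence >= need, motifs)
}

#' Nominate upstream transcription factors from shared motifs
#'
#' Matches every filtered motif against the PWM library, takes the
#' `top_t` matches per motif, and deduplicates the matched TFs. Nominees
#' present in the consistency report are kept on the shortlist only with
#' a consistent verdict (annotated with direction); nominees absent from
#' the expression data are retained in the audit trail flagged as
#' untested. For every higher-S gene in the report whose promoter is
#' supplied, binding sites of shortlisted TFs are scanned and reported
#' (the repressor-candidate table).
#'
#' @param motifs filtered motif list (see [filter_shared_motifs()]).
#' @param library PWM library (entries carrying `tf` anchor nominees).
#' @param report a [consistency_call()] report that includes the TF genes.
#' @param promoters optional named sequences for the repressor scan.
#' @param top_t matches taken per motif (default 3).
#' @param score_fraction site-scan threshold (default 0.8).
#' @param min_overlap alignment overlap for matching (default 5).
#' @return list with `shortlist`, `nominations` (audit trail) and
#'   `repressor_sites` data.frames.
#' @export
nominate_tfs <- function(motifs, library, report, promoters = NULL,
                         top_t = 3, score_fraction = 0.8, min_overlap = 5) {
  if (!length(motifs)) {
    empty <- data.frame(tf = character(), direction = character(),
                        best_score = numeric(), stringsAsFactors = FALSE)
    return(list(shortlist = empty, nominations = data.frame(),
                audit = data.frame(), repressor_sites = data.frame()))
  }
  noms <- do.call(rbind, lapply(motifs, function(m) {
    hits <- utils::head(match_motif_to_library(m$pwm, library,
                                               min_overlap = min_overlap), top_t)
    hits$motif <- m$pwm$id
    hits
  }))
  noms <- noms[!is.na(noms$tf), , drop = FALSE]
  verdict <- stats::setNames(report$verdict, report$gene)
  direction <- stats::setNames(report$direction, report$gene)
  tfs <- sort(unique(noms$tf))
  audit <- data.frame(
    tf = tfs,
    best_score = vapply(tfs, function(t) max(noms$score[noms$tf == t]), numeric(1)),
    motifs = vapply(tfs, function(t) paste(sort(unique(noms$motif[noms$tf == t])),
                                           collapse = ","), character(1)),
    tested = tfs %in% names(verdict),
    verdict = ifelse(tfs %in% names(verdict), verdict[tfs], "untested"),
    stringsAsFactors = FALSE)
  rownames(audit) <- NULL
  short <- audit[audit$tested & startsWith(audit$verdict, "consistent"), ,
                 drop = FALSE]
  shortlist <- data.frame(tf = short$tf,
                          direction = direction[short$tf],
                          best_score = short$best_score,
                          stringsAsFactors = FALSE)
  rownames(shortlist) <- NULL

  rep_sites <- data.frame(gene = character(), tf = character(),
                          start = integer(), end = integer(),
                          strand = character(), score = numeric(),
                          stringsAsFactors = FALSE)
  if (!is.null(promoters) && nrow(shortlist)) {
    higher_s <- report$gene[report$verdict == "consistent-higher-S"]
    higher_s <- intersect(higher_s, names(promoters))
    tf_pwms <- Filter(function(p) !is.null(p$tf) && p$tf %in% shortlist$tf, library)
    for (g in higher_s) {
      for (pw in tf_pwms) {
        h <- scan_binding_sites(pw, promoters[[g]], score_fraction = score_fraction)
        if (nrow(h)) {
          rep_sites <- rbind(rep_sites, data.frame(
            gene = g, tf = pw$tf, start = h$start, end = h$end,
            strand = h$strand, score = h$score, stringsAsFactors = FALSE))
        }
      }
    }
  }
  list(shortlist = shortlist, nominations = noms[, c("motif", "library_id", "tf",
                                                     "score", "offset", "orientation")],
       audit = audit, repressor_sites = rep_sites)
}
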