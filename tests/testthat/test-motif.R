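test_that("pwm construction validates and summarizes information content", {
  m <- matrix(0.25, 4, 8)
  p <- pwm("u", m)
  expect_equal(pwm_width(p), 8)
  expect_equal(pwm_ic(p), rep(0, 8))
  expect_error(pwm("bad", m[, 1:3]), "width")
  expect_error(pwm("bad", m * 2), "sum to 1")

  lib <- generate_pwm_library(6, c(8, 8), info_content = 2, seed = 1)
  expect_true(all(vapply(lib, function(x) {
    max(abs(colSums(x$matrix) - 1)) < 1e-9
  }, logical(1))))
  # IC ~ 2: near-deterministic consensus columns
  expect_true(all(vapply(lib, function(x) min(apply(x$matrix, 2, max)), numeric(1)) > 0.999))
  flat <- generate_pwm_library(3, c(8, 8), info_content = 0, seed = 1)
  expect_true(all(abs(flat[[1]]$matrix - 0.25) < 1e-9))
  mid <- generate_pwm_library(3, c(8, 8), info_content = 1.5, seed = 1)
  expect_equal(mean(pwm_ic(mid[[1]])), 1.5, tolerance = 1e-6)
  expect_error(generate_pwm_library(3, c(2, 8)), "width_range")
})

test_that("pwm reverse complement is an involution", {
  lib <- generate_pwm_library(3, c(8, 10), info_content = 1.2, seed = 3)
  for (p in lib) {
    rc2 <- pwm_revcomp(pwm_revcomp(p))
    expect_equal(rc2$matrix, p$matrix)
  }
})

test_that("TRANSFAC and MEME readers parse what they should", {
  lib <- generate_pwm_library(4, c(8, 10), info_content = 1.5, seed = 2,
                              tf_ids = c("tf01", "tf02"))
  path <- tempfile(fileext = ".transfac")
  write_transfac(lib, path)
  back <- read_transfac(path)
  expect_length(back, 4)
  for (i in seq_along(lib)) {
    expect_equal(back[[i]]$id, lib[[i]]$id)
    expect_equal(back[[i]]$tf, lib[[i]]$tf)
    expect_equal(back[[i]]$matrix, lib[[i]]$matrix, tolerance = 1e-5)
  }
  meme <- tempfile(fileext = ".meme")
  writeLines(c(
    "MEME version 4", "", "ALPHABET= ACGT", "",
    "MOTIF crp", "letter-probability matrix: alength= 4 w= 4 nsites= 17 E= 4.1e-009",
    " 0.0 0.5 0.5 0.0", " 1.0 0.0 0.0 0.0", " 0.25 0.25 0.25 0.25",
    " 0.1 0.2 0.3 0.4"), meme)
  got <- read_meme(meme)
  expect_length(got, 1)
  expect_equal(got[[1]]$id, "crp")
  expect_equal(got[[1]]$matrix[, 2], c(A = 1, C = 0, G = 0, T = 0))
})

test_that("extract_promoters respects strand, window and truncation contracts", {
  set.seed(10)
  contig <- paste(sample(c("A", "C", "G", "T"), 6000, replace = TRUE),
                  collapse = "")
  genome <- c(chr1 = contig)
  ann <- data.frame(gene = c("plus", "minus", "short"),
                    seqname = "chr1", tss = c(5000, 1000, 2000),
                    strand = c("+", "-", "+"), stringsAsFactors = FALSE)
  out <- extract_promoters(genome, ann, length = 4000)
  expect_equal(out[["plus"]], substr(contig, 1001, 5000))
  expect_equal(out[["minus"]],
               reverse_complement_chr(substr(contig, 1001, 5000)))
  expect_equal(nchar(out[["short"]]), 2000)
  expect_equal(attr(out, "truncated"),
               c(plus = FALSE, minus = FALSE, short = TRUE))
  bad <- data.frame(gene = "x", seqname = "chr9", tss = 10, strand = "+")
  expect_error(extract_promoters(genome, bad, 4000), "x")
})

test_that("scan_binding_sites agrees with a brute-force oracle", {
  lib <- generate_pwm_library(2, c(8, 8), info_content = 1.5, seed = 4)
  p <- lib[[1]]
  set.seed(11)
  seqs <- vapply(1:20, function(i) {
    paste(sample(c("A", "C", "G", "T"), 300, replace = TRUE), collapse = "")
  }, character(1))
  # naive position-by-position rescoring, independent of the scanner
  naive_scan <- function(pw, s, frac) {
    f <- (pw$matrix + pw$pseudocount) / (1 + 4 * pw$pseudocount)
    lo <- log2(f / pw$background)
    w <- ncol(lo)
    maxs <- sum(apply(lo, 2, max))
    hits <- list()
    for (i in 1:(nchar(s) - w + 1)) {
      word <- substr(s, i, i + w - 1)
      for (strand in c("+", "-")) {
        x <- if (strand == "+") word else reverse_complement_chr(word)
        sc <- sum(vapply(seq_len(w), function(j) {
          lo[substr(x, j, j), j]
        }, numeric(1)))
        if (sc >= frac * maxs) {
          hits[[length(hits) + 1]] <- data.frame(
            start = i - 1L, end = i - 1L + w, strand = strand, score = sc,
            stringsAsFactors = FALSE)
        }
      }
    }
    if (length(hits)) do.call(rbind, hits) else
      data.frame(start = integer(), end = integer(), strand = character(),
                 score = numeric())
  }
  for (s in seqs[1:5]) {
    got <- scan_binding_sites(p, s, score_fraction = 0.6)
    want <- naive_scan(p, s, 0.6)
    want <- want[order(want$start, want$strand), ]
    expect_equal(nrow(got), nrow(want))
    if (nrow(got)) {
      expect_equal(got$start, want$start)
      expect_equal(got$strand, want$strand)
      expect_equal(got$score, want$score, tolerance = 1e-9)
    }
  }
  # consensus scores exactly the maximum attainable
  cons <- pwm_consensus(p)
  filler <- paste(rep("A", 50), collapse = "")
  hit <- scan_binding_sites(p, paste0(filler, cons, filler), score_fraction = 1)
  expect_true(any(abs(hit$score - attr(hit, "max_score")) < 1e-9))
  # strand involution: reverse-complementing the promoter mirrors the hits
  s <- paste0(seqs[6], pwm_consensus(p), seqs[7])
  fw <- scan_binding_sites(p, s, score_fraction = 0.5)
  rv <- scan_binding_sites(p, reverse_complement_chr(s), score_fraction = 0.5)
  expect_gt(nrow(fw), 0)
  mapped <- data.frame(start = nchar(s) - fw$end,
                       strand = as.character(ifelse(fw$strand == "+", "-", "+")),
                       score = fw$score)
  mapped <- mapped[order(mapped$start, mapped$strand), ]
  expect_equal(rv$start, mapped$start)
  expect_equal(rv$strand, mapped$strand)
  expect_equal(rv$score, mapped$score, tolerance = 1e-9)
})

test_that("match_motif_to_library satisfies its identities and oracle", {
  lib <- generate_pwm_library(5, c(8, 8), info_content = 1.5, seed = 5)
  a <- lib[[1]]
  hits <- match_motif_to_library(a, lib)
  self <- hits[hits$library_id == a$id, ]
  expect_equal(self$score, 1, tolerance = 1e-12)
  expect_equal(self$offset, 0)
  expect_equal(self$orientation, "+")
  # against its own reverse complement: perfect score, minus orientation
  rc <- pwm_revcomp(a); rc$id <- "rc"
  m <- match_motif_to_library(a, list(rc))
  expect_equal(m$score, 1, tolerance = 1e-12)
  expect_equal(m$orientation, "-")
  # symmetry of the best score
  b <- lib[[2]]
  expect_equal(match_motif_to_library(a, list(b))$score,
               match_motif_to_library(b, list(a))$score, tolerance = 1e-12)

  # exhaustive enumeration oracle over all offsets and orientations
  naive_best <- function(A, B, min_overlap = 5) {
    fa <- (A$matrix + 0.01) / 1.04
    best <- -Inf
    for (orient in 1:2) {
      Bm <- if (orient == 1) B$matrix else pwm_revcomp(B)$matrix
      fb <- (Bm + 0.01) / 1.04
      wa <- ncol(fa); wb <- ncol(fb)
      for (off in -(wa - 1):(wb - 1)) {
        ia <- seq_len(wa); ib <- ia + off
        k <- ib >= 1 & ib <= wb
        if (sum(k) < min_overlap) next
        cc <- mapply(function(i, j) {
          if (sd(fa[, i]) == 0 || sd(fb[, j]) == 0) 0 else cor(fa[, i], fb[, j])
        }, ia[k], ib[k])
        best <- max(best, mean(cc))
      }
    }
    best
  }
  for (i in 2:5) {
    expect_equal(match_motif_to_library(a, lib[i])$score,
                 naive_best(a, lib[[i]]), tolerance = 1e-9)
  }
  expect_error(match_motif_to_library(a, list()), "empty")
})

test_that("discovery finds a planted motif and collapses strand classes", {
  net <- generate_planted_network(1, 12, 0, effect_size = 1, seed = 8,
                                  tfs_per_target = 1)
  net$edges$sign <- 1  # all activated: 12 promoters share one motif
  cfg <- simulation_config(seed = 8, promoter_length = 2000)
  lib <- generate_pwm_library(1, c(8, 8), info_content = 1.95, seed = 8,
                              tf_ids = net$tf_ids)
  proms <- generate_promoters(net, lib, cfg, plant_rate = 1)
  mot <- discover_motifs(proms[net$target_ids], widths = 8, top_m = 3)
  expect_gte(length(mot), 1)
  top <- mot[[1]]
  cons <- pwm_consensus(lib[[1]])
  expect_true(top$seed_word %in% c(cons, reverse_complement_chr(cons)))
  expect_gte(top$presence_fraction, 0.5)
  # the discovered PWM matches the generating PWM closely
  sc <- match_motif_to_library(top$pwm, lib)$score[1]
  expect_gte(sc, 0.8)
  # determinism
  mot2 <- discover_motifs(proms[net$target_ids], widths = 8, top_m = 3)
  expect_identical(lapply(mot, `[[`, "seed_word"), lapply(mot2, `[[`, "seed_word"))
  expect_error(discover_motifs(proms[1:2]), ">= 3")
})

test_that("filter_shared_motifs applies the ceiling rule", {
  stub <- function(presence) list(presence = presence)
  motifs <- lapply(c(6, 5, 11), stub)
  kept <- filter_shared_motifs(motifs, n_genes = 11)
  # 6 of 11 >= ceiling(5.5) kept; 5 of 11 dropped
  expect_equal(vapply(kept, `[[`, numeric(1), "presence"), c(6, 11))
  expect_length(filter_shared_motifs(motifs, 11, threshold_fraction = 0), 3)
})
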