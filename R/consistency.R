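#' Paired L-versus-S t-tests per gene, fin, L region and stage
#'
#' For every gene and every (fin, stage) cell, performs a two-tailed
#' paired t-test on log2 RQ between each elongated region of that fin and
#' the fin's short region, pairing observations by biological replicate.
#' The caudal fin contributes two separate comparisons (dcL vs cS and
#' vcL vs cS). Direction is the sign of the mean paired difference.
#'
#' Zero-variance differences are handled explicitly: if all paired
#' differences are identical and nonzero the p-value is reported as 0
#' with `degenerate = TRUE`; if all differences are zero, t = 0 and p = 1.
#'
#' @param rq_table a [relative_quantities()] table.
#' @param alpha significance level recorded with the matrix (default 0.05).
#' @return data.frame of class `significance_matrix` (gene, fin, l_region,
#'   stage, n, mean_diff, t, df, p, direction, degenerate).
#' @export
paired_lvs_tests <- function(rq_table, alpha = 0.05) {
  stopifnot(is.data.frame(rq_table), alpha > 0, alpha <= 1)
  lay <- fin_layout()
  out <- list()
  for (g in sort(unique(rq_table$gene))) {
    sub <- rq_table[rq_table$gene == g, , drop = FALSE]
    for (f in sort(unique(sub$fin))) {
      s_region <- lay[[f]]$S
      for (st in sort(unique(sub$stage[sub$fin == f]))) {
        cell <- sub[sub$fin == f & sub$stage == st, , drop = FALSE]
        s_obs <- cell[cell$region == s_region, , drop = FALSE]
        for (lr in lay[[f]]$L) {
          l_obs <- cell[cell$region == lr, , drop = FALSE]
          if (!nrow(l_obs)) next
          reps <- intersect(l_obs$replicate, s_obs$replicate)
          if (length(reps) < nrow(l_obs) || length(reps) < nrow(s_obs)) {
            stop(sprintf("unpaired replicates for gene %s in %s/%s stage %s",
                         g, f, lr, st), call. = FALSE)
          }
          if (length(reps) < 2) {
            stop("paired tests need >= 2 replicate pairs", call. = FALSE)
          }
          d <- l_obs$log_rq[match(reps, l_obs$replicate)] -
            s_obs$log_rq[match(reps, s_obs$replicate)]
          n <- length(d)
          m <- mean(d)
          s <- stats::sd(d)
          degenerate <- FALSE
          if (s == 0) {
            if (m == 0) {
              tv <- 0; p <- 1
            } else {
              tv <- sign(m) * Inf; p <- 0; degenerate <- TRUE
            }
          } else {
            tv <- m / (s / sqrt(n))
            p <- 2 * stats::pt(-abs(tv), df = n - 1)
          }
          out[[length(out) + 1]] <- data.frame(
            gene = g, fin = f, l_region = lr, stage = st, n = n,
            mean_diff = m, t = tv, df = n - 1, p = p,
            direction = if (m > 0) "higher-L" else if (m < 0) "higher-S" else NA_character_,
            degenerate = degenerate, stringsAsFactors = FALSE)
        }
      }
    }
  }
  res <- do.call(rbind, out)
  rownames(res) <- NULL
  attr(res, "alpha") <- alpha
  class(res) <- c("significance_matrix", "data.frame")
  res
}

build_model_frame <- function(rq_table, gene) {
  d <- rq_table[rq_table$gene == gene, , drop = FALSE]
  d$region_cl <- factor(region_class(d$region), levels = c("S", "L"))
  d$fin <- droplevels(factor(d$fin))
  d$stage <- droplevels(factor(d$stage))
  d$replicate <- factor(d$replicate)
  d
}

#' Mixed linear model screen for a region effect
#'
#' For each gene, fits a linear model of log2 RQ with fixed effects for
#' region (L vs S), fin and stage, the region x fin and region x stage
#' interactions, and a random intercept per biological replicate.
#' P-values come from maximum-likelihood likelihood-ratio tests: the
#' region main effect is tested in the additive model (region + fin +
#' stage vs fin + stage) and each interaction by dropping it from the
#' full model. Bonferroni adjustment multiplies the region p-value by the
#' number of genes in the batch, capped at 1.
#'
#' Singular random-intercept fits (common with three replicates) fall
#' back to the corresponding fixed-effects models, with `fallback = TRUE`
#' flagged; the screen's decision rule remains the paired-t consistency
#' call.
#'
#' @param rq_table a [relative_quantities()] table.
#' @param genes genes to fit (default: all in the table).
#' @param interactions also test the two interaction terms (default TRUE;
#'   disable to halve the fitting cost in large screens).
#' @return data.frame (gene, p_region, p_region_adj, p_interaction_fin,
#'   p_interaction_stage, singular, fallback).
#' @export
fit_region_model <- function(rq_table, genes = NULL, interactions = TRUE) {
  genes <- genes %||% sort(unique(rq_table$gene))
  res <- lapply(genes, function(g) {
    d <- build_model_frame(rq_table, g)
    if (length(unique(d$replicate)) < 2) {
      stop("fit_region_model needs >= 2 replicates", call. = FALSE)
    }
    cells <- table(d$region_cl, d$fin, d$stage)
    if (any(cells < 1)) {
      stop(sprintf("singular design for gene %s: empty region x fin x stage cell", g),
           call. = FALSE)
    }
    multi_fin <- nlevels(droplevels(d$fin)) > 1
    multi_stage <- nlevels(droplevels(d$stage)) > 1
    rhs_full <- paste(c("region_cl", if (multi_fin) "fin", if (multi_stage) "stage",
                        if (multi_fin) "region_cl:fin",
                        if (multi_stage) "region_cl:stage"), collapse = " + ")
    rhs_add <- paste(c("region_cl", if (multi_fin) "fin", if (multi_stage) "stage"),
                     collapse = " + ")
    rhs_null <- paste(c("1", if (multi_fin) "fin", if (multi_stage) "stage"),
                      collapse = " + ")

    fit_pair <- function(rhs1, rhs0) {
      f1 <- stats::as.formula(paste("log_rq ~", rhs1, "+ (1 | replicate)"))
      f0 <- stats::as.formula(paste("log_rq ~", rhs0, "+ (1 | replicate)"))
      m1 <- suppressMessages(suppressWarnings(
        lme4::lmer(f1, data = d, REML = FALSE,
                   control = lme4::lmerControl(check.conv.singular = "ignore"))))
      m0 <- suppressMessages(suppressWarnings(
        lme4::lmer(f0, data = d, REML = FALSE,
                   control = lme4::lmerControl(check.conv.singular = "ignore"))))
      sing <- lme4::isSingular(m1) || lme4::isSingular(m0)
      if (sing) {
        l1 <- stats::lm(stats::as.formula(paste("log_rq ~", rhs1)), data = d)
        l0 <- stats::lm(stats::as.formula(paste("log_rq ~", rhs0)), data = d)
        a <- stats::anova(l0, l1)
        list(p = a[["Pr(>F)"]][2], singular = TRUE)
      } else {
        a <- stats::anova(m0, m1)
        list(p = a[["Pr(>Chisq)"]][2], singular = FALSE)
      }
    }

    drop_term <- function(rhs, term) {
      parts <- strsplit(rhs, " + ", fixed = TRUE)[[1]]
      paste(setdiff(parts, term), collapse = " + ")
    }
    region <- fit_pair(rhs_add, rhs_null)
    int_fin <- if (interactions && multi_fin) {
      fit_pair(rhs_full, drop_term(rhs_full, "region_cl:fin"))
    }
    int_stage <- if (interactions && multi_stage) {
      fit_pair(rhs_full, drop_term(rhs_full, "region_cl:stage"))
    }

    data.frame(gene = g,
               p_region = region$p,
               p_interaction_fin = if (is.null(int_fin)) NA_real_ else int_fin$p,
               p_interaction_stage = if (is.null(int_stage)) NA_real_ else int_stage$p,
               singular = region$singular,
               fallback = region$singular,
               stringsAsFactors = FALSE)
  })
  out <- do.call(rbind, res)
  out$p_region_adj <- pmin(1, out$p_region * length(genes))
  rownames(out) <- NULL
  out[, c("gene", "p_region", "p_region_adj", "p_interaction_fin",
          "p_interaction_stage", "singular", "fallback")]
}

#' Cross-fin, cross-stage consistency verdict
#'
#' A (fin, stage) cell counts as significant for a gene only if every
#' L-vs-S comparison in that cell (the caudal fin has two) passes `alpha`
#' and agrees in direction. A gene is `consistent-higher-L` (or `-S`)
#' when at least `min_stages` significant same-direction cells occur in
#' each of at least `min_fins` fins; genes with significant cells of
#' opposing directions in different fins are `inconsistent`.
#'
#' @param sig a [paired_lvs_tests()] significance matrix.
#' @param alpha significance level for a comparison (default 0.05).
#' @param min_stages,min_fins consistency thresholds (defaults 2 and 2).
#' @param caudal_rule `"all"` (default) requires both caudal L regions to
#'   agree and pass; `"any"` lets a single passing region carry the cell
#'   provided no opposing significant region exists in it.
#' @return data.frame of class `consistency_report` (gene, verdict,
#'   direction, n_cells, supporting cells as attribute `"cells"`).
#' @export
consistency_call <- function(sig, alpha = 0.05, min_stages = 2, min_fins = 2,
                             caudal_rule = c("all", "any")) {
  caudal_rule <- match.arg(caudal_rule)
  stopifnot(alpha > 0, alpha <= 1, is_count(min_stages), is_count(min_fins))
  cell_rows <- list()
  verdicts <- list()
  for (g in sort(unique(sig$gene))) {
    sg <- sig[sig$gene == g, , drop = FALSE]
    cells <- unique(sg[, c("fin", "stage")])
    cells$direction <- NA_character_
    cells$significant <- FALSE
    for (i in seq_len(nrow(cells))) {
      tests <- sg[sg$fin == cells$fin[i] & sg$stage == cells$stage[i], , drop = FALSE]
      hits <- tests[tests$p < alpha & !is.na(tests$direction), , drop = FALSE]
      agree_all <- nrow(hits) == nrow(tests) && length(unique(hits$direction)) == 1
      agree_any <- nrow(hits) >= 1 && length(unique(hits$direction)) == 1
      ok <- if (caudal_rule == "all") agree_all else agree_any
      if (ok) {
        cells$significant[i] <- TRUE
        cells$direction[i] <- hits$direction[1]
      }
    }
    sig_cells <- cells[cells$significant, , drop = FALSE]
    dirs <- unique(sig_cells$direction)
    verdict <- "inconsistent"
    direction <- NA_character_
    if (length(dirs) == 1) {
      per_fin <- table(sig_cells$fin)
      if (sum(per_fin >= min_stages) >= min_fins) {
        verdict <- paste0("consistent-", dirs)
        direction <- dirs
      }
    }
    verdicts[[g]] <- data.frame(gene = g, verdict = verdict,
                                direction = direction,
                                n_cells = nrow(sig_cells),
                                stringsAsFactors = FALSE)
    if (nrow(sig_cells)) {
      cell_rows[[g]] <- cbind(gene = g, sig_cells[, c("fin", "stage", "direction")])
    }
  }
  report <- do.call(rbind, verdicts)
  rownames(report) <- NULL
  attr(report, "cells") <- if (length(cell_rows)) {
    cr <- do.call(rbind, cell_rows); rownames(cr) <- NULL; cr
  } else {
    data.frame(gene = character(), fin = character(), stage = integer(),
               direction = character(), stringsAsFactors = FALSE)
  }
  attr(report, "parameters") <- list(alpha = alpha, min_stages = min_stages,
                                     min_fins = min_fins, caudal_rule = caudal_rule)
  class(report) <- c("consistency_report", "data.frame")
  report
}
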