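#' Select strongly co-expressed candidate genes for each seed
#'
#' For each seed gene, takes the top-`k` neighbours from the
#' co-expression database (neighbours are ranked by descending
#' correlation, ties broken lexicographically) after filtering by the
#' supportability score and removing genes that were already tested.
#' Candidates shared by several seeds are reported once, with all
#' contributing seeds in the provenance.
#'
#' @param seeds seed gene ids; each must exist in the database.
#' @param db a [build_coexpression_db()] database.
#' @param k neighbours to take per seed (default 9).
#' @param min_support minimum supportability score (default 1).
#' @param exclude genes to skip (already-tested genes, including seeds).
#' @return data.frame (candidate, provenance) where provenance is a
#'   comma-separated list of seeds; attribute `"per_seed"` holds the
#'   per-seed candidate lists.
#' @export
select_candidates <- function(seeds, db, k = 9, min_support = 1,
                              exclude = character()) {
  stopifnot(length(seeds) >= 1, is_count(k))
  missing <- setdiff(seeds, unique(db$gene))
  if (length(missing)) {
    stop("seed(s) absent from co-expression database: ",
         paste(missing, collapse = ", "), call. = FALSE)
  }
  skip <- union(exclude, seeds)
  per_seed <- lapply(seeds, function(s) {
    nb <- db_neighbors(db, s)
    nb <- nb[nb$supportability >= min_support & !(nb$neighbor %in% skip), ,
             drop = FALSE]
    utils::head(nb$neighbor, k)
  })
  names(per_seed) <- seeds
  if (all(lengths(per_seed) == 0)) {
    warning("no candidate passed the supportability filter", call. = FALSE)
  }
  cand <- sort(unique(unlist(per_seed)))
  prov <- vapply(cand, function(g) {
    paste(seeds[vapply(per_seed, function(x) g %in% x, logical(1))],
          collapse = ",")
  }, character(1))
  out <- data.frame(candidate = cand, provenance = unname(prov),
                    stringsAsFactors = FALSE)
  attr(out, "per_seed") <- per_seed
  out
}

#' Combine seeds and consistent candidates into expression modules
#'
#' Each seed with a consistent verdict founds a module containing the
#' candidates selected from it that share its L/S direction. Candidates
#' with an inconsistent verdict are dropped from every module; a
#' candidate qualifying for several modules is assigned to the first
#' (seed order). Seeds without any same-direction hit yield singleton
#' modules; seeds that are themselves inconsistent found no module.
#'
#' @param seeds seed gene ids (order fixes module numbering).
#' @param report a [consistency_call()] report covering seeds and candidates.
#' @param selection a [select_candidates()] result.
#' @return list of modules; each is a list(seed, members, direction).
#' @export
assemble_modules <- function(seeds, report, selection) {
  per_seed <- attr(selection, "per_seed")
  verdict <- stats::setNames(report$verdict, report$gene)
  direction <- stats::setNames(report$direction, report$gene)
  covered <- c(seeds, unlist(per_seed))
  not_covered <- setdiff(covered, report$gene)
  if (length(not_covered)) {
    stop("consistency report does not cover: ",
         paste(unique(not_covered), collapse = ", "), call. = FALSE)
  }
  assigned <- character(0)
  modules <- list()
  for (s in seeds) {
    if (!startsWith(verdict[[s]], "consistent")) next
    dir <- direction[[s]]
    hits <- per_seed[[s]]
    hits <- hits[!is.na(verdict[hits]) &
                   verdict[hits] == paste0("consistent-", dir) &
                   !(hits %in% assigned)]
    members <- c(s, sort(hits))
    assigned <- c(assigned, members)
    modules[[length(modules) + 1]] <- list(seed = s, members = members,
                                           direction = dir)
  }
  modules
}

#' Extend a module with genes co-expressed with all of its members
#'
#' Candidate genes must appear (after the supportability filter) in the
#' neighbour list of every module member; they are ranked by the minimum
#' correlation with any member - the most conservative aggregate - and
#' the top `k` are returned. An empty intersection yields an empty list
#' with a warning, not an error.
#'
#' @param module a module from [assemble_modules()].
#' @param db co-expression database.
#' @param k candidates to return (default 5).
#' @param min_support minimum supportability score (default 1).
#' @param exclude genes to skip (already-tested genes).
#' @return character vector of candidate gene ids (possibly empty).
#' @export
extend_module <- function(module, db, k = 5, min_support = 1,
                          exclude = character()) {
  stopifnot(length(module$members) >= 1, is_count(k))
  nb <- lapply(module$members, function(m) {
    x <- db_neighbors(db, m)
    x[x$supportability >= min_support, , drop = FALSE]
  })
  shared <- Reduce(intersect, lapply(nb, `[[`, "neighbor"))
  shared <- setdiff(shared, union(exclude, module$members))
  if (!length(shared)) {
    warning("module extension: empty neighbour intersection", call. = FALSE)
    return(character(0))
  }
  min_cor <- vapply(shared, function(g) {
    min(vapply(nb, function(x) x$correlation[x$neighbor == g][1], numeric(1)))
  }, numeric(1))
  shared <- shared[order(-min_cor, shared)]
  utils::head(shared, k)
}

#' Run the full stepwise candidate-selection procedure
#'
#' Round 1 selects top co-expressed candidates per seed, quantifies them
#' from the Cq plate, applies the paired-t consistency screen and
#' assembles direction-coherent modules. Round 2 extends each module of
#' at least two members with genes co-expressed with all its members,
#' quantifies and screens those, and adds the consistent same-direction
#' hits. No gene is quantified twice: the exclusion set grows
#' monotonically across rounds.
#'
#' @param seeds seed gene ids (nonempty).
#' @param db co-expression database.
#' @param plate Cq plate containing all genes to be tested.
#' @param ref_genes reference gene ids on the plate.
#' @param k_select,k_extend candidates per seed / per module (9 and 5).
#' @param min_support supportability filter (default 1).
#' @param alpha,min_stages,min_fins consistency-screen parameters.
#' @param rounds number of rounds (default 2; round 1 is selection,
#'   each further round is one extension pass).
#' @param E amplification base for quantification.
#' @return list with elements `final` (data.frame gene, direction, round,
#'   provenance), `modules`, `report` (pooled consistency report) and
#'   `log` (one row per tested gene per round).
#' @export
run_stepwise <- function(seeds, db, plate, ref_genes = c("ref1", "ref2"),
                         k_select = 9, k_extend = 5, min_support = 1,
                         alpha = 0.05, min_stages = 2, min_fins = 2,
                         rounds = 2, E = 2) {
  if (length(seeds) < 1) stop("seeds must be nonempty", call. = FALSE)
  stopifnot(is_count(rounds))
  plate <- as_cq_plate(as.data.frame(plate))
  quantify_and_screen <- function(genes) {
    sub <- plate[plate$gene %in% c(genes, ref_genes), , drop = FALSE]
    absent <- setdiff(genes, unique(sub$gene))
    if (length(absent)) {
      stop("gene(s) not on plate: ", paste(absent, collapse = ", "),
           call. = FALSE)
    }
    rq <- relative_quantities(sub, ref_genes, E = E)
    sig <- paired_lvs_tests(rq, alpha = alpha)
    consistency_call(sig, alpha = alpha, min_stages = min_stages,
                     min_fins = min_fins)
  }

  selection <- select_candidates(seeds, db, k = k_select,
                                 min_support = min_support)
  tested1 <- sort(unique(c(seeds, selection$candidate)))
  report <- quantify_and_screen(tested1)
  modules <- assemble_modules(seeds, report, selection)
  exclude <- tested1
  log <- data.frame(round = 1L, gene = tested1,
                    stage = "select+screen", stringsAsFactors = FALSE)

  prov <- stats::setNames(selection$provenance, selection$candidate)
  final <- do.call(rbind, lapply(modules, function(m) {
    data.frame(gene = m$members, direction = m$direction,
               round = 1L,
               provenance = ifelse(m$members == m$seed, "seed",
                                   unname(prov[m$members])),
               stringsAsFactors = FALSE)
  }))
  if (is.null(final)) {
    final <- data.frame(gene = character(), direction = character(),
                        round = integer(), provenance = character(),
                        stringsAsFactors = FALSE)
  }

  round_no <- 1L
  while (round_no < rounds) {
    round_no <- round_no + 1L
    ext <- lapply(modules, function(m) {
      if (length(m$members) < 2) return(character(0))
      # an exhausted intersection is routine once earlier rounds have
      # consumed the neighbourhood; it is recorded via the round log
      suppressWarnings(extend_module(m, db, k = k_extend,
                                     min_support = min_support,
                                     exclude = exclude))
    })
    new_genes <- sort(unique(unlist(ext)))
    if (!length(new_genes)) break
    rep2 <- quantify_and_screen(new_genes)
    exclude <- sort(union(exclude, new_genes))
    log <- rbind(log, data.frame(round = round_no, gene = new_genes,
                                 stage = "extend+screen",
                                 stringsAsFactors = FALSE))
    v2 <- stats::setNames(rep2$verdict, rep2$gene)
    for (i in seq_along(modules)) {
      m <- modules[[i]]
      hits <- intersect(ext[[i]], new_genes)
      hits <- hits[v2[hits] == paste0("consistent-", m$direction)]
      hits <- setdiff(hits, final$gene)
      if (length(hits)) {
        modules[[i]]$members <- c(m$members, hits)
        final <- rbind(final, data.frame(
          gene = hits, direction = m$direction, round = round_no,
          provenance = paste0("module:", m$seed), stringsAsFactors = FALSE))
      }
    }
    report <- rbind(report, rep2[!(rep2$gene %in% report$gene), , drop = FALSE])
  }
  final <- final[order(final$round, final$gene), ]
  rownames(final) <- NULL
  list(final = final, modules = modules, report = report, log = log)
}
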