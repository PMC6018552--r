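#' Validate a raw Cq plate
#'
#' A plate is a long-format table of quantification-cycle measurements
#' keyed by (gene, fin, region, stage, replicate). Validation checks that
#' Cq values are finite and positive and that region labels are legal for
#' their fin.
#'
#' @param df data.frame with columns gene, fin, region, stage, replicate,
#'   cq, is_reference.
#' @return the validated plate, classed `cq_plate`.
#' @export
as_cq_plate <- function(df) {
  needed <- c("gene", "fin", "region", "stage", "replicate", "cq", "is_reference")
  missing <- setdiff(needed, names(df))
  if (length(missing)) {
    stop("plate is missing column(s): ", paste(missing, collapse = ", "),
         call. = FALSE)
  }
  if (any(!is.finite(df$cq)) || any(df$cq <= 0)) {
    stop("all Cq values must be finite and > 0", call. = FALSE)
  }
  check_regions_legal(df$fin, df$region)
  dup <- duplicated(df[, c("gene", "fin", "region", "stage", "replicate")])
  if (any(dup)) stop("duplicate plate rows for the same (gene, sample)", call. = FALSE)
  class(df) <- c("cq_plate", "data.frame")
  df
}

#' Per-sample reference value
#'
#' The arithmetic mean of the reference genes' Cq values in each
#' (fin, region, stage, replicate) sample.
#'
#' @param plate a [as_cq_plate()] plate.
#' @param ref_genes character vector of reference gene ids; every sample
#'   holding any target gene must also hold all of them.
#' @return data.frame (fin, region, stage, replicate, cq_reference).
#' @export
reference_cq <- function(plate, ref_genes) {
  stopifnot(length(ref_genes) >= 1)
  key <- sample_key(plate$fin, plate$region, plate$stage, plate$replicate)
  sample_keys <- unique(key)
  refs <- plate[plate$gene %in% ref_genes, , drop = FALSE]
  rkey <- sample_key(refs$fin, refs$region, refs$stage, refs$replicate)
  counts <- table(factor(rkey, levels = sample_keys), factor(refs$gene, levels = ref_genes))
  bad <- rownames(counts)[apply(counts, 1, function(x) any(x < 1))]
  if (length(bad)) {
    stop("reference gene(s) missing in sample(s): ", paste(bad, collapse = "; "),
         call. = FALSE)
  }
  agg <- stats::aggregate(cq ~ fin + region + stage + replicate, data = refs, FUN = mean)
  names(agg)[names(agg) == "cq"] <- "cq_reference"
  agg
}

default_calibrators <- function(fins) {
  lay <- fin_layout()
  stats::setNames(vapply(fins, function(f) lay[[f]]$L[1], character(1)), fins)
}

#' Delta-delta-Cq relative quantification
#'
#' Computes, per target gene and sample, `dCq = Cq_target - Cq_reference`
#' (the reference being the mean Cq of the reference genes), normalizes to
#' the calibrator sample of the gene's fin (`ddCq = dCq - dCq_calibrator`)
#' and derives the relative quantity `RQ = E^-ddCq`. By default the
#' calibrator is the (first) elongated region of each fin at stage 0,
#' biological replicate `calibrator_replicate` (a fixed, reproducible
#' stand-in for the study design's arbitrarily chosen replicate).
#'
#' @param plate a [as_cq_plate()] plate.
#' @param ref_genes reference gene ids.
#' @param calibrators named character vector fin -> calibrator region
#'   label; defaults to the first L region of each fin at stage 0.
#' @param E amplification base (> 1; default 2).
#' @param calibrator_stage,calibrator_replicate calibrator sample address.
#' @return data.frame of class `rq_table` with the full dCq/ddCq lineage
#'   (columns gene, fin, region, stage, replicate, delta_cq,
#'   delta_delta_cq, rq, log_rq) and attribute `E`.
#' @export
relative_quantities <- function(plate, ref_genes, calibrators = NULL, E = 2,
                                calibrator_stage = NULL, calibrator_replicate = 1) {
  if (!is.numeric(E) || E <= 1) stop("amplification base E must be > 1", call. = FALSE)
  plate <- as_cq_plate(as.data.frame(plate))
  refv <- reference_cq(plate, ref_genes)
  targets <- plate[!(plate$gene %in% ref_genes), , drop = FALSE]
  fins <- unique(targets$fin)
  if (is.null(calibrators)) calibrators <- default_calibrators(fins)
  if (is.null(calibrator_stage)) calibrator_stage <- min(targets$stage)
  if (!all(fins %in% names(calibrators))) {
    stop("no calibrator region given for fin(s): ",
         paste(setdiff(fins, names(calibrators)), collapse = ", "), call. = FALSE)
  }

  merged <- merge(targets, refv, by = c("fin", "region", "stage", "replicate"),
                  sort = FALSE)
  merged$delta_cq <- merged$cq - merged$cq_reference

  is_cal <- merged$region == calibrators[merged$fin] &
    merged$stage == calibrator_stage &
    merged$replicate == calibrator_replicate
  cal <- merged[is_cal, c("gene", "fin", "delta_cq")]
  names(cal)[3] <- "dcq_calibrator"
  missing_cal <- unique(merged[!paste(merged$gene, merged$fin) %in%
                                 paste(cal$gene, cal$fin), c("gene", "fin")])
  if (nrow(missing_cal)) {
    stop("calibrator sample absent for: ",
         paste(missing_cal$gene, missing_cal$fin, sep = "/", collapse = ", "),
         call. = FALSE)
  }
  out <- merge(merged, cal, by = c("gene", "fin"), sort = FALSE)
  out$delta_delta_cq <- out$delta_cq - out$dcq_calibrator
  out$rq <- E^(-out$delta_delta_cq)
  out$log_rq <- log2(out$rq)
  out <- out[order(out$gene, out$fin, out$region, out$stage, out$replicate),
             c("gene", "fin", "region", "stage", "replicate",
               "delta_cq", "delta_delta_cq", "rq", "log_rq")]
  rownames(out) <- NULL
  attr(out, "E") <- E
  class(out) <- c("rq_table", "data.frame")
  out
}

#' QC report on amplification efficiencies
#'
#' Flags genes whose estimated amplification efficiency (in percent, as
#' produced by amplification-curve analysis tools) falls outside the
#' accepted window; bounds are inclusive. Purely descriptive - no data
#' are altered or removed.
#'
#' @param efficiencies named numeric vector, gene -> efficiency in percent.
#' @param bounds inclusive lower/upper acceptance bounds (default 89-111).
#' @return data.frame (gene, efficiency, pass).
#' @export
qc_efficiencies <- function(efficiencies, bounds = c(89, 111)) {
  stopifnot(length(bounds) == 2, bounds[1] <= bounds[2])
  if (any(!is.finite(efficiencies)) || any(efficiencies <= 0)) {
    stop("efficiencies must be positive and finite", call. = FALSE)
  }
  data.frame(gene = names(efficiencies),
             efficiency = unname(efficiencies),
             pass = unname(efficiencies >= bounds[1] & efficiencies <= bounds[2]),
             stringsAsFactors = FALSE)
}
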