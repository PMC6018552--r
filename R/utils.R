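#' @keywords internal
"_PACKAGE"

`%||%` <- function(x, y) if (is.null(x)) y else x

DNA_BASES <- c("A", "C", "G", "T")

#' Fin/region layout of the unpaired fins
#'
#' Returns the mapping from fin type to its elongated (L) and short (S)
#' region labels. The caudal fin carries two elongated regions (dorsal
#' `dcL` and ventral `vcL`) that share a single short region `cS`; the
#' dorsal and anal fins have one of each (`dL`/`dS`, `aL`/`aS`).
#'
#' @return Named list; each element has character vectors `L` and `S`.
#' @export
fin_layout <- function() {
  list(
    dorsal = list(L = "dL", S = "dS"),
    anal   = list(L = "aL", S = "aS"),
    caudal = list(L = c("dcL", "vcL"), S = "cS")
  )
}

#' Classify a region label as elongated or short
#'
#' @param region character vector of region labels (e.g. `"dL"`, `"cS"`).
#' @return character vector of `"L"` / `"S"`.
#' @export
region_class <- function(region) {
  ifelse(grepl("L$", region), "L", "S")
}

all_region_labels <- function() {
  unlist(lapply(fin_layout(), unlist), use.names = FALSE)
}

check_regions_legal <- function(fin, region) {
  lay <- fin_layout()
  ok <- mapply(function(f, r) {
    f %in% names(lay) && r %in% unlist(lay[[f]])
  }, fin, region)
  if (!all(ok)) {
    bad <- unique(paste(fin[!ok], region[!ok], sep = "/"))
    stop("illegal fin/region combination(s): ", paste(bad, collapse = ", "),
         call. = FALSE)
  }
  invisible(TRUE)
}

# deterministic sub-seed derivation; keeps values well below 2^31
derive_seed <- function(seed, offset) {
  (abs(as.integer(seed)) + 1009L * as.integer(offset)) %% 2147480000L
}

sample_key <- function(fin, region, stage, replicate) {
  paste(fin, region, stage, replicate, sep = ":")
}

reverse_complement <- function(x) {
  comp <- chartr("ACGTacgt", "TGCAtgca", x)
  vapply(strsplit(comp, "", fixed = TRUE), function(ch) {
    paste(rev(ch), collapse = "")
  }, character(1))
}

is_count <- function(x) {
  is.numeric(x) && length(x) == 1 && is.finite(x) && x >= 1 && x == floor(x)
}
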