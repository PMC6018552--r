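# --- tabular and sequence file formats -------------------------------------
#
# All tabular files are tab-separated with a header row; lines starting
# with '#' are metadata comments and ignored on read.

write_tsv <- function(df, path, header_lines = character()) {
  con <- file(path, "w")
  on.exit(close(con))
  if (length(header_lines)) writeLines(paste0("# ", header_lines), con)
  utils::write.table(df, con, sep = "\t", quote = FALSE, row.names = FALSE)
  invisible(path)
}

read_tsv <- function(path) {
  utils::read.table(path, sep = "\t", header = TRUE, comment.char = "#",
                    stringsAsFactors = FALSE, check.names = FALSE)
}

#' Write / read a Cq plate file
#'
#' Tab-separated long format with columns gene, fin, region, stage,
#' replicate, cq, is_reference.
#'
#' @param plate a [as_cq_plate()] plate.
#' @param path file path.
#' @param header_lines optional comment lines to prepend.
#' @return the path (write) or a validated plate (read).
#' @export
write_cq_plate <- function(plate, path, header_lines = character()) {
  write_tsv(as.data.frame(plate), path, header_lines)
}

#' @rdname write_cq_plate
#' @export
read_cq_plate <- function(path) {
  as_cq_plate(read_tsv(path))
}

#' Write / read a co-expression neighbour file
#'
#' Tab-separated columns gene, neighbor, rank, correlation, supportability.
#'
#' @param db a [build_coexpression_db()] database.
#' @param path file path.
#' @param header_lines optional comment lines to prepend.
#' @return the path (write) or a `coexpression_db` (read).
#' @export
write_coexpression_db <- function(db, path, header_lines = character()) {
  write_tsv(as.data.frame(db), path, header_lines)
}

#' @rdname write_coexpression_db
#' @export
read_coexpression_db <- function(path) {
  db <- read_tsv(path)
  class(db) <- c("coexpression_db", "data.frame")
  db
}

#' Write / read promoter FASTA
#'
#' @param seqs named character vector of sequences (a `promoter_set`).
#' @param path file path.
#' @return the path (write) or a named character vector (read).
#' @export
write_fasta <- function(seqs, path) {
  x <- Biostrings::DNAStringSet(as.character(seqs))
  names(x) <- names(seqs)
  Biostrings::writeXStringSet(x, path)
  invisible(path)
}

#' @rdname write_fasta
#' @export
read_fasta <- function(path) {
  x <- Biostrings::readDNAStringSet(path)
  stats::setNames(as.character(x), names(x))
}

#' Write a PWM library in TRANSFAC-style count-matrix text
#'
#' Each record has an `ID` line (and a `BF` line when the matrix is
#' anchored to a TF gene), a `P0 A C G T` header, one row of counts per
#' position, and ends with `XX` and `//`. Frequencies are written as
#' counts out of 1000.
#'
#' @param library list of [pwm()] objects.
#' @param path file path.
#' @return the path, invisibly.
#' @export
write_transfac <- function(library, path) {
  con <- file(path, "w")
  on.exit(close(con))
  for (p in library) {
    writeLines(paste("ID", p$id), con)
    if (!is.null(p$tf)) writeLines(paste("BF", p$tf), con)
    writeLines("P0\tA\tC\tG\tT", con)
    m <- round(p$matrix * 1000, 6)
    for (j in seq_len(ncol(m))) {
      writeLines(sprintf("%02d\t%s", j,
                         paste(format(m[, j], trim = TRUE, scientific = FALSE),
                               collapse = "\t")), con)
    }
    writeLines(c("XX", "//"), con)
  }
  invisible(path)
}

#' Read a TRANSFAC-style PWM library
#'
#' Accepts the dialect written by [write_transfac()]: per-position counts
#' are renormalized to frequencies.
#'
#' @param path file path.
#' @return list of [pwm()] objects.
#' @export
read_transfac <- function(path) {
  lines <- readLines(path)
  library <- list()
  id <- NULL; tf <- NULL; rows <- list()
  flush <- function() {
    if (is.null(id)) return()
    m <- do.call(cbind, rows)
    m <- sweep(m, 2, colSums(m), "/")
    library[[length(library) + 1]] <<- pwm(id, m, tf = tf)
    id <<- NULL; tf <<- NULL; rows <<- list()
  }
  for (ln in lines) {
    if (grepl("^ID\\s", ln)) {
      id <- sub("^ID\\s+", "", ln)
    } else if (grepl("^BF\\s", ln)) {
      tf <- sub("^BF\\s+", "", ln)
    } else if (grepl("^[0-9]+\\s", ln)) {
      vals <- as.numeric(strsplit(ln, "\\s+")[[1]][2:5])
      rows[[length(rows) + 1]] <- vals
    } else if (grepl("^//", ln)) {
      flush()
    }
  }
  flush()
  library
}

#' Read a MEME minimal-format motif file
#'
#' Parses the `MOTIF` / `letter-probability matrix` records of MEME's
#' minimal text format into [pwm()] objects.
#'
#' @param path file path.
#' @return list of [pwm()] objects.
#' @export
read_meme <- function(path) {
  lines <- readLines(path)
  library <- list()
  i <- 1
  while (i <= length(lines)) {
    ln <- lines[i]
    if (grepl("^MOTIF\\s", ln)) {
      id <- strsplit(trimws(sub("^MOTIF", "", ln)), "\\s+")[[1]][1]
      j <- i + 1
      while (j <= length(lines) && !grepl("^letter-probability", lines[j])) j <- j + 1
      if (j > length(lines)) break
      w <- as.integer(sub(".*w=\\s*(\\d+).*", "\\1", lines[j]))
      block <- lines[(j + 1):(j + w)]
      m <- t(vapply(block, function(b) {
        as.numeric(strsplit(trimws(b), "\\s+")[[1]][1:4])
      }, numeric(4)))
      m <- sweep(t(m), 2, colSums(t(m)), "/")
      library[[length(library) + 1]] <- pwm(id, m)
      i <- j + w
    }
    i <- i + 1
  }
  library
}

#' Write motif hits as BED-like TSV
#'
#' Columns: gene, start, end, pwm, score, strand (0-based, half-open,
#' forward-strand coordinates).
#'
#' @param hits data.frame with those columns.
#' @param path file path.
#' @return the path, invisibly.
#' @export
write_hits_bed <- function(hits, path) {
  write_tsv(hits, path)
}
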