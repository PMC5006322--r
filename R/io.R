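#' Write an atlas count matrix with its sample metadata header
#'
#' The TSV starts with a commented metadata block (one `#animal`, `#sex`,
#' `#tissue`, `#organ` row each, aligned with the sample columns), followed
#' by the matrix with miRNA ids in the first column.
#'
#' @param counts an `atlas_counts`.
#' @param path output path.
#' @return invisibly, `path`.
#' @export
write_atlas_counts <- function(counts, path) {
  stopifnot(inherits(counts, "atlas_counts"))
  con <- file(path, "w")
  on.exit(close(con))
  s <- counts$samples
  for (fld in c("animal", "sex", "tissue", "organ")) {
    writeLines(paste(c(paste0("#", fld), s[[fld]]), collapse = "\t"), con)
  }
  writeLines(paste(c("mirna", s$sample), collapse = "\t"), con)
  m <- counts$counts
  for (i in seq_len(nrow(m))) {
    writeLines(paste(c(rownames(m)[i], format(m[i, ], trim = TRUE,
                                              scientific = FALSE)),
                     collapse = "\t"), con)
  }
  invisible(path)
}

#' Read an atlas count matrix written by [write_atlas_counts()]
#'
#' @param path input path.
#' @return an `atlas_counts`.
#' @export
read_atlas_counts <- function(path) {
  lines <- readLines(path)
  meta <- list()
  i <- 1L
  while (startsWith(lines[i], "#")) {
    f <- strsplit(lines[i], "\t", fixed = TRUE)[[1L]]
    meta[[sub("^#", "", f[1L])]] <- f[-1L]
    i <- i + 1L
  }
  header <- strsplit(lines[i], "\t", fixed = TRUE)[[1L]]
  body <- strsplit(lines[-seq_len(i)], "\t", fixed = TRUE)
  mirnas <- vapply(body, `[`, character(1), 1L)
  m <- t(vapply(body, function(x) as.numeric(x[-1L]),
                numeric(length(header) - 1L)))
  if (length(header) == 2L) m <- matrix(m, ncol = 1L)
  dimnames(m) <- list(mirnas, header[-1L])
  samples <- data.frame(
    sample = header[-1L],
    animal = meta$animal, sex = meta$sex,
    tissue = meta$tissue, organ = meta$organ,
    stringsAsFactors = FALSE
  )
  atlas_counts(m, samples)
}

#' Write classification calls, assignments or any result table as TSV
#'
#' @param tab a data.frame.
#' @param path output path.
#' @return invisibly, `path`.
#' @export
write_result_tsv <- function(tab, path) {
  utils::write.table(tab, path, sep = "\t", quote = FALSE, row.names = FALSE,
                     na = "NA")
  invisible(path)
}

#' Write reads as FASTA (optionally collapsed ids) or FASTQ
#'
#' @param sequences character vector of reads.
#' @param path output path; format chosen by extension (.fa/.fasta vs
#'   .fq/.fastq).
#' @param ids optional sequence ids (default read_1, ...).
#' @return invisibly, `path`.
#' @export
write_reads <- function(sequences, path, ids = NULL) {
  if (is.null(ids)) ids <- sprintf("read_%d", seq_along(sequences))
  dna <- Biostrings::DNAStringSet(sequences)
  names(dna) <- ids
  if (grepl("\\.(fq|fastq)$", path)) {
    q <- Biostrings::BStringSet(vapply(nchar(sequences), function(n) {
      paste(rep("I", n), collapse = "")
    }, character(1)))
    Biostrings::writeXStringSet(dna, path, format = "fastq", qualities = q)
  } else {
    Biostrings::writeXStringSet(dna, path)
  }
  invisible(path)
}

#' Read raw reads from FASTA or FASTQ
#'
#' @param path input path; format chosen by extension.
#' @return character vector of read sequences (names = ids).
#' @export
read_reads <- function(path) {
  fmt <- if (grepl("\\.(fq|fastq)$", path)) "fastq" else "fasta"
  dna <- Biostrings::readDNAStringSet(path, format = fmt)
  out <- as.character(dna)
  names(out) <- sub("\\s.*$", "", names(dna))
  out
}
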