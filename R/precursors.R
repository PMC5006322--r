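#' Construct a precursor hairpin set
#'
#' A precursor set holds hairpin sequences together with the coordinates of
#' their annotated mature arms. Coordinates are 1-based inclusive; sequences
#' are normalised to uppercase DNA (U -> T).
#'
#' @param sequences named character vector: precursor name -> hairpin
#'   sequence.
#' @param windows data.frame with columns `precursor`, `mature_name`,
#'   `arm` ("5p"/"3p"), `start`, `end` (1-based inclusive).
#' @param species single species label for the whole set (e.g. "rat").
#' @return object of class `precursor_set`.
#' @export
precursor_set <- function(sequences, windows, species = "rat") {
  if (is.null(names(sequences)) || anyDuplicated(names(sequences))) {
    stop("`sequences` must be uniquely named", call. = FALSE)
  }
  sequences <- vapply(sequences, normalize_seq, character(1))
  req <- c("precursor", "mature_name", "arm", "start", "end")
  if (!all(req %in% names(windows))) {
    stop("`windows` needs columns: ", paste(req, collapse = ", "), call. = FALSE)
  }
  bad <- setdiff(windows$precursor, names(sequences))
  if (length(bad)) stop("windows refer to unknown precursor(s): ",
                        paste(unique(bad), collapse = ", "), call. = FALSE)
  if (!all(windows$arm %in% c("5p", "3p"))) {
    stop("`arm` must be '5p' or '3p'", call. = FALSE)
  }
  len <- nchar(sequences)[windows$precursor]
  if (any(windows$start < 1 | windows$end < windows$start |
          windows$end > len)) {
    stop("mature windows must satisfy 1 <= start <= end <= hairpin length",
         call. = FALSE)
  }
  # arms within one precursor must not overlap each other
  for (p in unique(windows$precursor)) {
    w <- windows[windows$precursor == p, , drop = FALSE]
    if (nrow(w) > 1L) {
      w <- w[order(w$start), , drop = FALSE]
      if (any(w$start[-1L] <= w$end[-nrow(w)])) {
        stop("mature windows overlap within precursor ", p, call. = FALSE)
      }
    }
  }
  windows$start <- as.integer(windows$start)
  windows$end <- as.integer(windows$end)
  rownames(windows) <- NULL
  structure(list(sequences = sequences, windows = windows, species = species),
            class = "precursor_set")
}

#' @export
print.precursor_set <- function(x, ...) {
  cat(sprintf("precursor_set (%s): %d hairpins, %d mature windows\n",
              x$species, length(x$sequences), nrow(x$windows)))
  invisible(x)
}

#' Write a precursor set as FASTA plus a TSV annotation table
#'
#' @param ps a `precursor_set`.
#' @param fasta path for the hairpin FASTA.
#' @param annot path for the annotation TSV
#'   (precursor_id, arm, start, end, mature_name).
#' @return invisibly, the two paths.
#' @export
write_precursor_set <- function(ps, fasta, annot) {
  stopifnot(inherits(ps, "precursor_set"))
  dna <- Biostrings::DNAStringSet(ps$sequences)
  Biostrings::writeXStringSet(dna, fasta)
  tab <- data.frame(
    precursor_id = ps$windows$precursor,
    arm = ps$windows$arm,
    start = ps$windows$start,
    end = ps$windows$end,
    mature_name = ps$windows$mature_name
  )
  utils::write.table(tab, annot, sep = "\t", quote = FALSE, row.names = FALSE)
  invisible(c(fasta = fasta, annot = annot))
}

#' Read a precursor set from FASTA plus annotation TSV
#'
#' @param fasta hairpin FASTA path.
#' @param annot annotation TSV path with columns precursor_id, arm, start,
#'   end, mature_name (1-based inclusive coordinates).
#' @param species species label to attach.
#' @return a `precursor_set`.
#' @export
read_precursor_set <- function(fasta, annot, species = "rat") {
  dna <- Biostrings::readDNAStringSet(fasta)
  seqs <- as.character(dna)
  # keep only the first whitespace-delimited token of each FASTA header
  names(seqs) <- sub("\\s.*$", "", names(seqs))
  tab <- utils::read.delim(annot, stringsAsFactors = FALSE)
  precursor_set(
    seqs,
    data.frame(
      precursor = tab$precursor_id,
      mature_name = tab$mature_name,
      arm = tab$arm,
      start = tab$start,
      end = tab$end
    ),
    species = species
  )
}
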