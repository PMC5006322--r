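#' Trimming profiles
#'
#' Three named presets reflecting common small-RNA pipelines:
#' * `lilly`: adapter trimmed anywhere, minimum insert 17 nt, no upper
#'   bound, reads containing `N` discarded (quality trimming at Q20 applies
#'   to FASTQ input only and is a no-op on FASTA).
#' * `maastricht`: the adapter is recognised by a perfect match to its
#'   first 8 bases; inserts outside 16-35 nt are discarded.
#' * `niehs`: 14-24 nt insert window.
#'
#' @param name one of "lilly", "maastricht", "niehs".
#' @return list of trimming parameters.
#' @export
trimming_profile <- function(name = c("maastricht", "lilly", "niehs")) {
  name <- match.arg(name)
  switch(name,
    lilly = list(name = "lilly", min_len = 17L, max_len = Inf,
                 match_prefix_len = 8L, drop_n = TRUE, keep_untrimmed = TRUE),
    maastricht = list(name = "maastricht", min_len = 16L, max_len = 35L,
                      match_prefix_len = 8L, drop_n = FALSE,
                      keep_untrimmed = TRUE),
    niehs = list(name = "niehs", min_len = 14L, max_len = 24L,
                 match_prefix_len = 8L, drop_n = FALSE, keep_untrimmed = TRUE)
  )
}

#' Trim the 3' adapter off raw reads
#'
#' Each read is truncated at the first occurrence of the adapter's first
#' `match_prefix_len` bases. The trimmed insert is kept only when its length
#' lies in `[min_len, max_len]`; reads with no adapter occurrence are kept
#' untrimmed if within the window (`keep_untrimmed = TRUE`, the default) or
#' discarded in strict mode; reads containing ambiguous bases are discarded
#' when `drop_n = TRUE`.
#'
#' @param reads character vector of raw read sequences.
#' @param adapter 3' adapter sequence.
#' @param min_len,max_len allowed insert length window.
#' @param match_prefix_len adapter prefix length that must match exactly.
#' @param drop_n discard reads containing `N`.
#' @param keep_untrimmed keep adapter-free reads that fit the window.
#' @return data.frame with columns `read`, `insert`, `keep` (logical) and
#'   `reason` ("ok", "no_adapter", "too_short", "too_long",
#'   "ambiguous_base", "empty").
#' @export
#' @examples
#' trim_adapter("ACGTACGTACGTACGTTGGAATTCXX", "TGGAATTCTCGGGTGCCAAGG")
trim_adapter <- function(reads, adapter,
                         min_len = 16L, max_len = 35L,
                         match_prefix_len = 8L,
                         drop_n = FALSE, keep_untrimmed = TRUE) {
  if (!nzchar(adapter)) stop("`adapter` must be non-empty", call. = FALSE)
  if (match_prefix_len > nchar(adapter)) {
    stop("`match_prefix_len` exceeds adapter length", call. = FALSE)
  }
  reads <- normalize_seq(reads)
  prefix <- normalize_seq(substr(adapter, 1L, match_prefix_len))
  pos <- as.integer(regexpr(prefix, reads, fixed = TRUE))
  ins <- ifelse(pos > 0L, substr(reads, 1L, pos - 1L), reads)
  len <- nchar(ins)
  reason <- rep("ok", length(reads))
  reason[pos <= 0L] <- "no_adapter"
  keep <- rep(TRUE, length(reads))
  if (!keep_untrimmed) keep[pos <= 0L] <- FALSE
  empty <- len == 0L
  keep[empty] <- FALSE
  reason[empty] <- "empty"
  short <- !empty & len < min_len
  keep[short] <- FALSE
  reason[short] <- "too_short"
  long <- len > max_len
  keep[long] <- FALSE
  reason[long] <- "too_long"
  if (drop_n) {
    amb <- grepl("N", ins, fixed = TRUE)
    keep[amb] <- FALSE
    reason[amb] <- "ambiguous_base"
  }
  reason[pos <= 0L & keep] <- "no_adapter"
  data.frame(read = reads, insert = ins, keep = keep, reason = reason,
             stringsAsFactors = FALSE)
}

#' Collapse identical reads within a sample
#'
#' Identical sequences are combined into a single record with ids of the
#' form `NNN_#_x#`: the sample code, a unique integer (first-occurrence
#' order), and the multiplicity.
#'
#' @param reads character vector of (trimmed) read sequences.
#' @param sample_code short alphabetic sample code (e.g. "LIV").
#' @return data.frame with columns `id`, `sequence`, `count`; the counts
#'   sum to `length(reads)`.
#' @export
#' @examples
#' collapse_reads(c("ACGT", "ACGT", "ACGT", "AAAA"), "LIV")
collapse_reads <- function(reads, sample_code) {
  if (!grepl("^[A-Za-z]+$", sample_code)) {
    stop("`sample_code` must be alphabetic", call. = FALSE)
  }
  if (length(reads) == 0L) {
    return(data.frame(id = character(0), sequence = character(0),
                      count = integer(0)))
  }
  reads <- normalize_seq(reads)
  uniq <- unique(reads)
  cnt <- as.integer(table(factor(reads, levels = uniq)))
  data.frame(
    id = sprintf("%s_%d_x%d", sample_code, seq_along(uniq), cnt),
    sequence = uniq,
    count = cnt,
    stringsAsFactors = FALSE
  )
}

# Substring index for one precursor set: for a given read length L, a
# named list mapping each L-mer of each hairpin to its start positions.
.substring_index <- function(ps, L) {
  out <- list()
  for (p in names(ps$sequences)) {
    s <- ps$sequences[[p]]
    n <- nchar(s)
    if (n < L) next
    starts <- seq_len(n - L + 1L)
    subs <- substring(s, starts, starts + L - 1L)
    out[[p]] <- split(starts, subs)
  }
  out
}

#' Exact-match read mapping against precursor hairpins
#'
#' Reports every exact substring occurrence (including overlapping ones) of
#' each query sequence in each hairpin, with 1-based inclusive coordinates.
#' No mismatches or gaps are allowed.
#'
#' @param sequences character vector of query sequences (U normalised to T).
#' @param precursors a `precursor_set`.
#' @return data.frame with columns `sequence`, `precursor`, `start`, `end`;
#'   sequences with no occurrence contribute no rows.
#' @export
map_exact <- function(sequences, precursors) {
  stopifnot(inherits(precursors, "precursor_set"))
  sequences <- normalize_seq(sequences)
  uniq <- unique(sequences)
  res <- vector("list", length(uniq))
  by_len <- split(seq_along(uniq), nchar(uniq))
  for (Lc in names(by_len)) {
    L <- as.integer(Lc)
    if (L == 0L) next
    idx <- .substring_index(precursors, L)
    for (k in by_len[[Lc]]) {
      sq <- uniq[k]
      hit <- list()
      for (p in names(idx)) {
        st <- idx[[p]][[sq]]
        if (!is.null(st)) {
          hit[[p]] <- data.frame(sequence = sq, precursor = p,
                                 start = st, end = st + L - 1L)
        }
      }
      if (length(hit)) res[[k]] <- do.call(rbind, hit)
    }
  }
  res <- res[!vapply(res, is.null, logical(1))]
  if (!length(res)) {
    return(data.frame(sequence = character(0), precursor = character(0),
                      start = integer(0), end = integer(0)))
  }
  out <- do.call(rbind, res)
  out <- out[order(match(out$sequence, uniq), out$precursor, out$start), ,
             drop = FALSE]
  rownames(out) <- NULL
  out
}

# Label one locus: the mature name when the locus is associated with an
# annotated mature window, else "<precursor>-pre". Association uses the
# configurable rule: |start - window start| <= start_tol and overlap of at
# least min_overlap of the window.
.locus_label <- function(precursor, start, end, windows, hairpin_len,
                         start_tol = 3L, min_overlap = 0.75) {
  w <- windows[windows$precursor == precursor, , drop = FALSE]
  arm <- NULL
  label <- NULL
  if (nrow(w)) {
    ov <- pmax(0L, pmin(end, w$end) - pmax(start, w$start) + 1L)
    wlen <- w$end - w$start + 1L
    assoc <- abs(start - w$start) <= start_tol & ov >= min_overlap * wlen
    if (any(assoc)) {
      label <- w$mature_name[assoc]
      arm <- w$arm[which(assoc)[1L]]
    } else if (any(ov > 0L)) {
      arm <- w$arm[which.max(ov)]
    }
  }
  if (is.null(label)) label <- paste0(precursor, "-pre")
  if (is.null(arm)) arm <- if (start <= hairpin_len / 2) "5p" else "3p"
  list(label = label, arm = arm)
}

#' Assign an isomiR name and mature identity to one mapped sequence
#'
#' Given every exact-match locus of a sequence, each locus contributes a
#' label: the mature miRNA name when the locus sits on an annotated mature
#' window (start within `start_tol` nt of the window start and overlapping
#' at least `min_overlap` of it), otherwise `<precursor>-pre`. Distinct
#' labels are joined lexicographically with ";" into a composite identity.
#' The isomiR name `<precursor>_<arm>_<start>_<end>` is taken from the
#' first locus in (precursor, start) order.
#'
#' @param locus_hits data.frame with columns `precursor`, `start`, `end`
#'   (one sequence's loci, e.g. a subset of [map_exact()] output).
#' @param precursors the `precursor_set` the loci refer to.
#' @param start_tol tolerance (nt) on the 5' start for mature association.
#' @param min_overlap minimum fraction of the mature window covered.
#' @return list with `isomir_name`, `assigned_mature`, `arm`, `n_loci`.
#' @export
assign_isomir <- function(locus_hits, precursors,
                          start_tol = 3L, min_overlap = 0.75) {
  if (nrow(locus_hits) < 1L) {
    stop("assign_isomir needs at least one locus", call. = FALSE)
  }
  locus_hits <- locus_hits[order(locus_hits$precursor, locus_hits$start), ,
                           drop = FALSE]
  labels <- character(nrow(locus_hits))
  arms <- character(nrow(locus_hits))
  for (j in seq_len(nrow(locus_hits))) {
    ll <- .locus_label(locus_hits$precursor[j], locus_hits$start[j],
                       locus_hits$end[j], precursors$windows,
                       nchar(precursors$sequences[[locus_hits$precursor[j]]]),
                       start_tol, min_overlap)
    labels[j] <- paste(ll$label, collapse = ";")
    arms[j] <- ll$arm
  }
  composite <- paste(sort(unique(unlist(strsplit(labels, ";", fixed = TRUE)))),
                     collapse = ";")
  list(
    isomir_name = sprintf("%s_%s_%d_%d", locus_hits$precursor[1L], arms[1L],
                          locus_hits$start[1L], locus_hits$end[1L]),
    assigned_mature = composite,
    arm = arms[1L],
    n_loci = nrow(locus_hits)
  )
}

# Map and assign a batch of collapsed reads against one precursor set.
# Returns one row per (sequence, locus).
.assign_batch <- function(collapsed, ps, tier, start_tol, min_overlap) {
  hits <- map_exact(collapsed$sequence, ps)
  if (!nrow(hits)) return(NULL)
  rows <- list()
  for (sq in unique(hits$sequence)) {
    h <- hits[hits$sequence == sq, , drop = FALSE]
    a <- assign_isomir(h, ps, start_tol, min_overlap)
    i <- match(sq, collapsed$sequence)
    h <- h[order(h$precursor, h$start), , drop = FALSE]
    arms <- character(nrow(h))
    for (j in seq_len(nrow(h))) {
      arms[j] <- .locus_label(h$precursor[j], h$start[j], h$end[j],
                              ps$windows, nchar(ps$sequences[[h$precursor[j]]]),
                              start_tol, min_overlap)$arm
    }
    rows[[sq]] <- data.frame(
      id = collapsed$id[i], sequence = sq,
      precursor = h$precursor, start = h$start, end = h$end, arm = arms,
      isomir_name = sprintf("%s_%s_%d_%d", h$precursor, arms, h$start, h$end),
      assigned_mature = a$assigned_mature,
      species_tier = tier,
      count = collapsed$count[i], n_loci = a$n_loci,
      stringsAsFactors = FALSE
    )
  }
  do.call(rbind, rows)
}

#' Assign collapsed reads across ordered species tiers
#'
#' Sequences are first matched against the first tier's precursors; any
#' sequence with no exact hit falls through to the next tier, and so on.
#' Each assigned sequence records the tier that identified it; sequences
#' with no hit at any tier are returned as unidentified.
#'
#' @param collapsed output of [collapse_reads()].
#' @param tiers named ordered list of `precursor_set` objects
#'   (e.g. rat, mouse, human, celegans).
#' @param start_tol,min_overlap mature-association rule, see
#'   [assign_isomir()].
#' @return list with `assignments` (one row per sequence x locus: id,
#'   sequence, precursor, start, end, arm, isomir_name, assigned_mature,
#'   species_tier, count, n_loci) and `unidentified` (rows of `collapsed`).
#' @export
cross_species_assign <- function(collapsed, tiers,
                                 start_tol = 3L, min_overlap = 0.75) {
  if (is.null(names(tiers))) {
    names(tiers) <- vapply(tiers, function(t) t$species, character(1))
  }
  remaining <- collapsed
  out <- list()
  for (tn in names(tiers)) {
    if (!nrow(remaining)) break
    batch <- .assign_batch(remaining, tiers[[tn]], tn, start_tol, min_overlap)
    if (!is.null(batch)) {
      out[[tn]] <- batch
      remaining <- remaining[!(remaining$sequence %in% batch$sequence), ,
                             drop = FALSE]
    }
  }
  assignments <- if (length(out)) do.call(rbind, out) else
    data.frame(id = character(0), sequence = character(0),
               precursor = character(0), start = integer(0), end = integer(0),
               arm = character(0), isomir_name = character(0),
               assigned_mature = character(0), species_tier = character(0),
               count = numeric(0), n_loci = integer(0))
  rownames(assignments) <- NULL
  rownames(remaining) <- NULL
  list(assignments = assignments, unidentified = remaining)
}

#' Divide multi-locus read counts across their loci
#'
#' Each sequence's total count is split evenly over its assigned loci:
#' per-locus count = total / n_loci (fractions allowed), so summing over a
#' sequence's loci restores the original count exactly.
#'
#' @param assignments the `assignments` data.frame from
#'   [cross_species_assign()] (one row per sequence x locus, `count`
#'   holding the undivided total).
#' @return the same data.frame with `count` replaced by the per-locus share.
#' @export
divide_multilocus_counts <- function(assignments) {
  if (!nrow(assignments)) return(assignments)
  if (any(assignments$n_loci < 1L)) stop("n_loci must be >= 1", call. = FALSE)
  assignments$count <- assignments$count / assignments$n_loci
  assignments
}

#' Express isomiR counts as a percentage of their parent mature miRNA
#'
#' @param tab data.frame with columns `mature` (parent id), `isomir`
#'   (isomiR name) and `count`.
#' @return data.frame with an added `pct` column
#'   (100 * count / parent total); per-parent percentages sum to 100.
#'   Rows whose parent total is 0 get `pct = NA` and `undefined = TRUE`
#'   rather than a misleading 0.
#' @export
isomir_fraction_of_mature <- function(tab) {
  stopifnot(all(c("mature", "isomir", "count") %in% names(tab)))
  tot <- tapply(tab$count, tab$mature, sum)
  parent_total <- as.numeric(tot[tab$mature])
  pct <- ifelse(parent_total > 0, 100 * tab$count / parent_total, NA_real_)
  out <- tab
  out$pct <- pct
  out$undefined <- parent_total <= 0
  out
}
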