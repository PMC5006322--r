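#' Aggregate animal-level counts to tissue level
#'
#' Tissue-level counts are obtained for each miRNA by summing over all
#' animals sampled for that tissue.
#'
#' @param counts an `atlas_counts`.
#' @return numeric matrix, miRNAs x tissues.
#' @export
aggregate_tissue <- function(counts) {
  stopifnot(inherits(counts, "atlas_counts"))
  tis <- unique(counts$samples$tissue)
  out <- sapply(tis, function(t) {
    cols <- counts$samples$tissue == t
    rowSums(counts$counts[, cols, drop = FALSE])
  })
  out <- matrix(out, nrow = nrow(counts$counts),
                dimnames = list(rownames(counts$counts), tis))
  out
}

#' Aggregate tissue-level counts to organ level
#'
#' The organ count is the maximum of its member tissues' counts (so a
#' brain-wide signal and a hippocampus-only signal both register at the
#' brain column).
#'
#' @param tissue_matrix miRNA x tissue matrix.
#' @param organ_map named character vector tissue -> organ
#'   (default [default_organ_map()]).
#' @return miRNA x organ matrix.
#' @export
aggregate_organ <- function(tissue_matrix, organ_map = default_organ_map()) {
  missing <- setdiff(colnames(tissue_matrix), names(organ_map))
  if (length(missing)) {
    stop("tissues missing from organ map: ", paste(missing, collapse = ", "),
         call. = FALSE)
  }
  organs <- unique(unname(organ_map[colnames(tissue_matrix)]))
  out <- sapply(organs, function(o) {
    cols <- organ_map[colnames(tissue_matrix)] == o
    apply(tissue_matrix[, cols, drop = FALSE], 1L, max)
  })
  matrix(out, nrow = nrow(tissue_matrix),
         dimnames = list(rownames(tissue_matrix), organs))
}

# Canonical TMM factor of one library against a reference: the weighted
# trimmed mean of per-gene log2 ratios M (library-size adjusted), trimming
# the extremes of M and of average abundance A, with inverse-variance
# weights.
.tmm_pair <- function(obs, ref, logratio_trim = 0.3, sum_trim = 0.05,
                      weighted = TRUE) {
  n_o <- sum(obs)
  n_r <- sum(ref)
  keep <- obs > 0 & ref > 0
  obs <- obs[keep]
  ref <- ref[keep]
  if (!length(obs)) return(1)
  m <- log2((obs / n_o) / (ref / n_r))
  a <- (log2(obs / n_o) + log2(ref / n_r)) / 2
  w <- (n_o - obs) / (n_o * obs) + (n_r - ref) / (n_r * ref)
  fin <- is.finite(m) & is.finite(a)
  m <- m[fin]; a <- a[fin]; w <- w[fin]
  if (!length(m)) return(1)
  if (max(abs(m)) < 1e-6) return(1)
  n <- length(m)
  lo_m <- floor(n * logratio_trim) + 1
  hi_m <- n + 1 - lo_m
  lo_a <- floor(n * sum_trim) + 1
  hi_a <- n + 1 - lo_a
  keep2 <- rank(m) >= lo_m & rank(m) <= hi_m &
    rank(a) >= lo_a & rank(a) <= hi_a
  if (!any(keep2)) return(1)
  f <- if (weighted) {
    sum(m[keep2] / w[keep2]) / sum(1 / w[keep2])
  } else {
    mean(m[keep2])
  }
  if (!is.finite(f)) f <- 0
  2^f
}

#' TMM normalisation of a count matrix
#'
#' Computes trimmed-mean-of-M-values composition factors against a
#' reference sample and returns per-sample scaling factors on the effective
#' library-size scale: `factor = TMM x library size / (TMM_ref x library
#' size_ref)`, so a library that is an exact 2x copy of the reference gets
#' factor 2 and its normalised counts equal the reference's. Trim fractions
#' default to the method's canonical 30% on M and 5% on A.
#'
#' @param mat miRNA x sample count matrix.
#' @param ref reference sample (column name or index); by default the
#'   sample whose upper quartile is closest to the mean upper quartile.
#' @param logratio_trim,sum_trim trim fractions on M and A.
#' @param weighted use inverse-variance (delta-method) weights in the
#'   trimmed mean (default TRUE); unweighted averaging is exactly
#'   scale-equivariant.
#' @return list with `factors` (per-sample scale, reference = 1) and `norm`
#'   (counts divided by their factor).
#' @export
tmm_normalize <- function(mat, ref = NULL,
                          logratio_trim = 0.3, sum_trim = 0.05,
                          weighted = TRUE) {
  mat <- as.matrix(mat)
  lib <- colSums(mat)
  if (any(lib <= 0)) {
    stop("TMM factor undefined for all-zero sample(s): ",
         paste(colnames(mat)[lib <= 0], collapse = ", "), call. = FALSE)
  }
  if (is.null(ref)) {
    uq <- apply(mat, 2L, function(x) q3(x) / sum(x))
    ref <- which.min(abs(uq - mean(uq)))
  }
  if (is.character(ref)) ref <- match(ref, colnames(mat))
  refv <- mat[, ref]
  f_comp <- vapply(seq_len(ncol(mat)), function(j) {
    .tmm_pair(mat[, j], refv, logratio_trim, sum_trim, weighted)
  }, numeric(1))
  factors <- f_comp * lib / (f_comp[ref] * lib[ref])
  names(factors) <- colnames(mat)
  norm <- sweep(mat, 2L, factors, "/")
  list(factors = factors, norm = norm, ref = ref)
}

#' Drop miRNAs that never reach a minimum normalised count
#'
#' A miRNA is retained iff at least one sample has a (normalised) count at
#' or above `threshold` (default 10 reads).
#'
#' @param mat miRNA x sample matrix.
#' @param threshold minimum count (default 10).
#' @return the filtered matrix.
#' @export
filter_low_counts <- function(mat, threshold = 10) {
  keep <- apply(mat, 1L, function(x) any(x >= threshold))
  mat[keep, , drop = FALSE]
}

#' Transcripts-per-million normalisation with zero imputation and ceiling
#'
#' Optionally imputes zero cells with 1.0 before scaling, converts each
#' sample to reads-per-million, and optionally ceils the result to integers
#' for count-based downstream models.
#'
#' @param mat miRNA x sample count matrix.
#' @param impute_zero replace zeros by 1.0 before scaling (default TRUE).
#' @param ceil ceiling the scaled values to integers (default TRUE).
#' @return normalised matrix.
#' @export
tpm_normalize <- function(mat, impute_zero = TRUE, ceil = TRUE) {
  mat <- as.matrix(mat)
  if (impute_zero) mat[mat == 0] <- 1.0
  tot <- colSums(mat)
  if (any(tot <= 0)) {
    stop("TPM undefined for sample(s) with zero total", call. = FALSE)
  }
  out <- sweep(mat, 2L, tot, "/") * 1e6
  if (ceil) out <- ceiling(out)
  out
}
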