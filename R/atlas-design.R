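#' Default tissue-to-organ map (23 tissues, 14 organs)
#'
#' The atlas samples 23 tissues drawn from 14 organs; four of the tissues
#' (cerebrum, cerebellum, hippocampus, brainstem) belong to the brain, and a
#' handful of other organs contribute more than one tissue. Single-sex
#' tissues (testis, ovary, uterus) are sampled in one sex only, so a full
#' design of 5 males and 5 females yields 20 x 10 + 3 x 5 = 215 samples.
#'
#' @return named character vector mapping tissue name to organ name.
#' @export
#' @examples
#' om <- default_organ_map()
#' length(om)                  # 23 tissues
#' length(unique(om))          # 14 organs
default_organ_map <- function() {
  c(
    liver                 = "liver",
    heart                 = "heart",
    pancreas              = "pancreas",
    adrenal               = "adrenal",
    dorsal_root_ganglion  = "dorsal_root_ganglion",
    testis                = "testis",
    ovary                 = "ovary",
    uterus                = "uterus",
    whole_blood           = "whole_blood",
    kidney                = "kidney",
    medulla               = "kidney",
    cortex                = "kidney",
    soleus                = "muscle",
    biceps_femoris        = "muscle",
    glandular_stomach     = "stomach",
    nonglandular_stomach  = "stomach",
    duodenum              = "intestine",
    jejunum               = "intestine",
    ileum                 = "intestine",
    cerebrum              = "brain",
    cerebellum            = "brain",
    hippocampus           = "brain",
    brainstem             = "brain"
  )
}

#' Tissues restricted to a single sex in the default design
#' @return named character vector: tissue -> sex ("M" or "F").
#' @export
single_sex_tissues <- function() {
  c(testis = "M", ovary = "F", uterus = "F")
}

#' Describe a synthetic atlas design
#'
#' Bundles everything [generate_atlas_counts()] needs: the tissue panel with
#' its organ mapping, the animal layout, per-miRNA enrichment patterns, and
#' the two Poisson intensities of the planted high/low expression mixture.
#'
#' @param n_mirnas number of miRNAs to simulate.
#' @param tissues named character vector mapping tissue to organ
#'   (default [default_organ_map()]).
#' @param n_animals_per_sex animals per sex (default 5, i.e. 5 M + 5 F).
#' @param enrichment_patterns list of character vectors, one per miRNA
#'   (recycled names `mir_1`, ...): the tissues in which that miRNA is
#'   planted as highly expressed. An empty vector means background only.
#' @param sex_pattern optional character vector (`NA`, `"M"` or `"F"` per
#'   miRNA): a non-`NA` entry plants a sex-specific miRNA whose counts are
#'   forced to zero in the opposite sex.
#' @param lambda_high Poisson mean in enriched tissues.
#' @param lambda_low Poisson mean elsewhere (background); may be 0.
#' @param library_scale per-sample multiplicative depth factor; either a
#'   single number or a vector recycled over samples.
#' @param dispersion_size optional negative-binomial size for an
#'   overdispersion knob; `Inf` (default) gives pure Poisson counts.
#' @param seed integer seed.
#' @return object of class `atlas_design`.
#' @export
atlas_design <- function(n_mirnas,
                         tissues = default_organ_map(),
                         n_animals_per_sex = 5L,
                         enrichment_patterns = NULL,
                         sex_pattern = NULL,
                         lambda_high = 500,
                         lambda_low = 1,
                         library_scale = 1,
                         dispersion_size = Inf,
                         seed = 1L) {
  stopifnot_scalar_count(n_mirnas, "n_mirnas")
  stopifnot_scalar_count(n_animals_per_sex, "n_animals_per_sex")
  if (is.null(names(tissues)) || any(!nzchar(names(tissues)))) {
    stop("`tissues` must be a named vector: tissue -> organ", call. = FALSE)
  }
  if (anyDuplicated(names(tissues))) {
    stop("tissue names must be unique (each tissue maps to exactly one organ)",
         call. = FALSE)
  }
  if (!(lambda_high > lambda_low) || lambda_low < 0) {
    stop("need lambda_high > lambda_low >= 0", call. = FALSE)
  }
  if (is.null(enrichment_patterns)) {
    enrichment_patterns <- rep(list(character(0)), n_mirnas)
  }
  if (length(enrichment_patterns) != n_mirnas) {
    stop("`enrichment_patterns` must have one entry per miRNA", call. = FALSE)
  }
  bad <- setdiff(unlist(enrichment_patterns), names(tissues))
  if (length(bad)) {
    stop("enrichment pattern names unknown tissue(s): ",
         paste(bad, collapse = ", "), call. = FALSE)
  }
  if (is.null(sex_pattern)) sex_pattern <- rep(NA_character_, n_mirnas)
  if (length(sex_pattern) != n_mirnas ||
      !all(is.na(sex_pattern) | sex_pattern %in% c("M", "F"))) {
    stop("`sex_pattern` must be NA/'M'/'F' per miRNA", call. = FALSE)
  }
  structure(
    list(
      n_mirnas = as.integer(n_mirnas),
      tissues = tissues,
      n_animals_per_sex = as.integer(n_animals_per_sex),
      enrichment_patterns = enrichment_patterns,
      sex_pattern = sex_pattern,
      lambda_high = lambda_high,
      lambda_low = lambda_low,
      library_scale = library_scale,
      dispersion_size = dispersion_size,
      seed = as.integer(seed)
    ),
    class = "atlas_design"
  )
}

#' @export
print.atlas_design <- function(x, ...) {
  cat(sprintf(
    "atlas_design: %d miRNAs, %d tissues / %d organs, %d animals per sex\n",
    x$n_mirnas, length(x$tissues), length(unique(x$tissues)),
    x$n_animals_per_sex
  ))
  cat(sprintf("  lambda_high = %g, lambda_low = %g, seed = %d\n",
              x$lambda_high, x$lambda_low, x$seed))
  n_enr <- sum(lengths(x$enrichment_patterns) > 0)
  cat(sprintf("  %d miRNA(s) with planted enrichment, %d sex-specific\n",
              n_enr, sum(!is.na(x$sex_pattern))))
  invisible(x)
}

#' Construct an atlas count container
#'
#' A light container pairing a miRNA x sample count matrix with its sample
#' metadata (animal, sex, tissue, organ), in the spirit of a DGEList.
#'
#' @param counts numeric matrix, rows = miRNAs, columns = samples.
#' @param samples data.frame with columns `sample`, `animal`, `sex`,
#'   `tissue`, `organ`; rows aligned with `colnames(counts)`.
#' @return object of class `atlas_counts`.
#' @export
atlas_counts <- function(counts, samples) {
  counts <- as.matrix(counts)
  req <- c("sample", "animal", "sex", "tissue", "organ")
  if (!all(req %in% names(samples))) {
    stop("`samples` needs columns: ", paste(req, collapse = ", "), call. = FALSE)
  }
  if (ncol(counts) != nrow(samples)) {
    stop("ncol(counts) must equal nrow(samples)", call. = FALSE)
  }
  if (is.null(rownames(counts))) {
    rownames(counts) <- sprintf("mir_%d", seq_len(nrow(counts)))
  }
  if (is.null(colnames(counts))) colnames(counts) <- samples$sample
  if (!identical(colnames(counts), as.character(samples$sample))) {
    stop("colnames(counts) must match samples$sample", call. = FALSE)
  }
  if (any(counts < 0)) stop("counts must be non-negative", call. = FALSE)
  if (anyDuplicated(rownames(counts))) {
    stop("miRNA ids (rownames) must be unique", call. = FALSE)
  }
  t2o <- unique(samples[, c("tissue", "organ")])
  if (anyDuplicated(t2o$tissue)) {
    stop("every tissue must map to exactly one organ", call. = FALSE)
  }
  structure(list(counts = counts, samples = samples), class = "atlas_counts")
}

#' @export
print.atlas_counts <- function(x, ...) {
  cat(sprintf("atlas_counts: %d miRNAs x %d samples (%d tissues, %d organs)\n",
              nrow(x$counts), ncol(x$counts),
              length(unique(x$samples$tissue)),
              length(unique(x$samples$organ))))
  invisible(x)
}

#' @export
dim.atlas_counts <- function(x) dim(x$counts)
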