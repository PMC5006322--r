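#' Rule-based tissue-specific / enriched / sex-specific classification
#'
#' A tissue counts as "expressed" for a miRNA when at least a quorum of its
#' animals show a raw count above `expressed_threshold` (default: count > 1
#' in 8 of 10 animals; the quorum rescales proportionally for single-sex
#' tissues sampled in 5 animals, giving 4 of 5). A miRNA expressed in
#' exactly one tissue is specific; in 2 to `enriched_max_tissues` tissues,
#' enriched. A miRNA with count > `expressed_threshold` in at least 4 of 5
#' animals of one sex and in none of the opposite sex (in some tissue) is
#' sex-specific. Calls are mutually exclusive with precedence
#' specific > sex_specific > enriched.
#'
#' @param counts an `atlas_counts` (raw counts by default; pass a
#'   normalised copy for a normalised-mode analysis).
#' @param expressed_threshold count that must be exceeded (default 1).
#' @param quorum_frac fraction of a tissue's animals that must express
#'   (default 0.8; quorum = ceiling(frac x n animals)).
#' @param enriched_max_tissues upper bound of the enriched tissue-set size
#'   (default 5).
#' @param sex_quorum_frac quorum fraction within the expressing sex for the
#'   sex rule (default 0.8, i.e. 4 of 5).
#' @return data.frame of calls: `mirna`, `label`
#'   (specific/enriched/sex_specific/none), `tissues` (";"-joined),
#'   `organs`, `method` = "rule", `score` (number of expressed tissues),
#'   `sex`.
#' @export
classify_rule_based <- function(counts,
                                expressed_threshold = 1,
                                quorum_frac = 0.8,
                                enriched_max_tissues = 5L,
                                sex_quorum_frac = 0.8) {
  stopifnot(inherits(counts, "atlas_counts"))
  smp <- counts$samples
  tissues <- unique(smp$tissue)
  t2o <- smp$organ[match(tissues, smp$tissue)]
  y <- counts$counts
  n_mir <- nrow(y)

  expr_mat <- matrix(FALSE, n_mir, length(tissues),
                     dimnames = list(rownames(y), tissues))
  sex_call <- matrix(NA_character_, n_mir, length(tissues))
  for (ti in seq_along(tissues)) {
    cols <- which(smp$tissue == tissues[ti])
    nA <- length(cols)
    quorum <- ceiling(quorum_frac * nA)
    if (quorum > nA) stop("quorum exceeds animal count for tissue ",
                          tissues[ti], call. = FALSE)
    over <- y[, cols, drop = FALSE] > expressed_threshold
    expr_mat[, ti] <- rowSums(over) >= quorum
    sx <- smp$sex[cols]
    if (length(unique(sx)) == 2L) {
      nM <- sum(sx == "M"); nF <- sum(sx == "F")
      m_over <- rowSums(over[, sx == "M", drop = FALSE])
      f_over <- rowSums(over[, sx == "F", drop = FALSE])
      m_only <- m_over >= ceiling(sex_quorum_frac * nM) & f_over == 0
      f_only <- f_over >= ceiling(sex_quorum_frac * nF) & m_over == 0
      sex_call[m_only, ti] <- "M"
      sex_call[f_only, ti] <- "F"
    }
  }

  label <- rep("none", n_mir)
  tset <- character(n_mir)
  oset <- character(n_mir)
  sex <- rep(NA_character_, n_mir)
  score <- rowSums(expr_mat)
  for (i in seq_len(n_mir)) {
    exp_t <- tissues[expr_mat[i, ]]
    sex_t <- tissues[!is.na(sex_call[i, ])]
    if (length(exp_t) == 1L) {
      label[i] <- "specific"
      tset[i] <- exp_t
      oset[i] <- t2o[match(exp_t, tissues)]
    } else if (length(sex_t) > 0L) {
      label[i] <- "sex_specific"
      tset[i] <- paste(sort(sex_t), collapse = ";")
      oset[i] <- paste(sort(unique(t2o[match(sex_t, tissues)])),
                       collapse = ";")
      sex[i] <- sex_call[i, which(!is.na(sex_call[i, ]))[1L]]
    } else if (length(exp_t) >= 2L && length(exp_t) <= enriched_max_tissues) {
      label[i] <- "enriched"
      tset[i] <- paste(sort(exp_t), collapse = ";")
      oset[i] <- paste(sort(unique(t2o[match(exp_t, tissues)])),
                       collapse = ";")
    }
  }
  data.frame(mirna = rownames(y), label = label, tissues = tset,
             organs = oset, method = "rule", score = score, sex = sex,
             stringsAsFactors = FALSE)
}

#' Read-fraction tissue-specificity classification
#'
#' Computes each tissue's share of a miRNA's total reads; a share above
#' `specific_threshold` percent makes the miRNA specific to that tissue,
#' else a share above `enriched_threshold` percent makes it enriched.
#' When an organ map is supplied, shares are additionally evaluated for
#' tissue groups (summing member tissues), so a signal split across, say,
#' the four brain tissues is still recognised; a multi-tissue group passing
#' a threshold yields an enriched call over its member tissues.
#'
#' @param tissue_matrix miRNA x tissue matrix (see [aggregate_tissue()]).
#' @param specific_threshold percent of total reads for "specific"
#'   (default 90).
#' @param enriched_threshold percent for "enriched" (default 50).
#' @param organ_map optional named vector tissue -> group for grouped
#'   evaluation.
#' @return data.frame of calls (`mirna`, `label`, `tissues`, `organs`,
#'   `method` = "percentage", `score` = winning share in percent, `sex` =
#'   NA). Zero-total miRNAs are labelled none with `score = NA`.
#' @export
classify_percentage <- function(tissue_matrix,
                                specific_threshold = 90,
                                enriched_threshold = 50,
                                organ_map = NULL) {
  tm <- as.matrix(tissue_matrix)
  tot <- rowSums(tm)
  label <- rep("none", nrow(tm))
  tset <- character(nrow(tm))
  oset <- character(nrow(tm))
  score <- rep(NA_real_, nrow(tm))
  if (!is.null(organ_map)) {
    missing <- setdiff(colnames(tm), names(organ_map))
    if (length(missing)) stop("tissues missing from organ map: ",
                              paste(missing, collapse = ", "), call. = FALSE)
  }
  for (i in seq_len(nrow(tm))) {
    if (tot[i] <= 0) next
    share <- 100 * tm[i, ] / tot[i]
    best <- which.max(share)
    if (share[best] > specific_threshold) {
      label[i] <- "specific"
      tset[i] <- colnames(tm)[best]
      score[i] <- share[best]
      if (!is.null(organ_map)) oset[i] <- organ_map[[colnames(tm)[best]]]
      next
    }
    gbest <- NULL
    if (!is.null(organ_map)) {
      grp <- organ_map[colnames(tm)]
      gshare <- 100 * tapply(tm[i, ], grp, sum) / tot[i]
      gi <- which.max(gshare)
      if (gshare[gi] > enriched_threshold) {
        gbest <- list(group = names(gshare)[gi], share = gshare[[gi]])
      }
    }
    if (share[best] > enriched_threshold) {
      label[i] <- "enriched"
      tset[i] <- colnames(tm)[best]
      score[i] <- share[best]
      if (!is.null(organ_map)) oset[i] <- organ_map[[colnames(tm)[best]]]
    } else if (!is.null(gbest)) {
      members <- colnames(tm)[organ_map[colnames(tm)] == gbest$group]
      label[i] <- "enriched"
      tset[i] <- paste(sort(members), collapse = ";")
      oset[i] <- gbest$group
      score[i] <- gbest$share
    }
  }
  data.frame(mirna = rownames(tm), label = label, tissues = tset,
             organs = oset, method = "percentage", score = score,
             sex = NA_character_, stringsAsFactors = FALSE)
}

#' Refine organ-specific NMF candidates to tissue-level calls
#'
#' For each candidate miRNA a two-component Poisson mixture is fitted to
#' its animal-level counts across all tissues; a tissue is "high" when the
#' majority of its animals have posterior probability of the high component
#' of at least `posterior_cutoff`. Exactly one high tissue gives a specific
#' call; several give an enriched call over the high tissues; none (or a
#' collapsed one-component fit, which offers no high/low separation) gives
#' none.
#'
#' @param candidates data.frame from [organ_specific_candidates()].
#' @param counts the `atlas_counts` the candidates came from.
#' @param posterior_cutoff posterior threshold for calling an animal high
#'   (default 0.5).
#' @return data.frame of calls with `method` = "nmf_mixture"; `score` holds
#'   the fitted high-component intensity.
#' @export
refine_tissue_specific <- function(candidates, counts,
                                   posterior_cutoff = 0.5) {
  stopifnot(inherits(counts, "atlas_counts"))
  smp <- counts$samples
  tissues <- unique(smp$tissue)
  t2o <- smp$organ[match(tissues, smp$tissue)]
  rows <- list()
  for (r in seq_len(nrow(candidates))) {
    mir <- candidates$mirna[r]
    y <- counts$counts[mir, ]
    fit <- fit_poisson_mixture(as.integer(round(y)))
    label <- "none"; tset <- ""; oset <- ""
    if (!fit$collapsed) {
      high_t <- character(0)
      for (ti in seq_along(tissues)) {
        cols <- which(smp$tissue == tissues[ti])
        n_high <- sum(fit$posterior_high[cols] >= posterior_cutoff)
        if (n_high > length(cols) / 2) high_t <- c(high_t, tissues[ti])
      }
      if (length(high_t) == 1L) {
        label <- "specific"; tset <- high_t
        oset <- t2o[match(high_t, tissues)]
      } else if (length(high_t) >= 2L) {
        label <- "enriched"
        tset <- paste(sort(high_t), collapse = ";")
        oset <- paste(sort(unique(t2o[match(high_t, tissues)])),
                      collapse = ";")
      }
    }
    rows[[r]] <- data.frame(
      mirna = mir, label = label, tissues = tset, organs = oset,
      method = "nmf_mixture", score = fit$lambda_high, sex = NA_character_,
      stringsAsFactors = FALSE
    )
  }
  if (!length(rows)) {
    return(data.frame(mirna = character(0), label = character(0),
                      tissues = character(0), organs = character(0),
                      method = character(0), score = numeric(0),
                      sex = character(0)))
  }
  out <- do.call(rbind, rows)
  rownames(out) <- NULL
  out
}

#' NMF + Poisson-mixture tissue-specificity pipeline
#'
#' Convenience wrapper: aggregates animal counts to tissue and organ level,
#' factorises the organ matrix, nominates organ-specific candidates, and
#' refines them to tissue-level calls with the Poisson mixture.
#'
#' @param counts an `atlas_counts`.
#' @param k NMF rank (default one factor per organ).
#' @param seed seed for the NMF restarts.
#' @param dominance factor-dominance threshold, see
#'   [organ_specific_candidates()].
#' @param organ_map tissue -> organ map (default [default_organ_map()]).
#' @param ... passed to [refine_tissue_specific()].
#' @return list with `calls`, `fit` (the `nmf_fit`) and `candidates`.
#' @export
classify_nmf_mixture <- function(counts, k = NULL, seed = 1L,
                                 dominance = 0.5,
                                 organ_map = default_organ_map(), ...) {
  tm <- aggregate_tissue(counts)
  om <- aggregate_organ(tm, organ_map)
  if (is.null(k)) k <- min(14L, ncol(om))
  fit <- nmf_factorize(om, k = k, seed = seed)
  cand <- organ_specific_candidates(fit, dominance = dominance)
  calls <- refine_tissue_specific(cand, counts, ...)
  list(calls = calls, fit = fit, candidates = cand)
}

#' Overlap table of enriched-miRNA call sets
#'
#' Reports the size and membership of every intersection of the supplied
#' sets (singletons, all pairs, up to the full intersection).
#'
#' @param call_sets named list of character vectors (miRNA ids).
#' @return data.frame with columns `sets` (";"-joined set names), `degree`,
#'   `n`, `members` (";"-joined ids).
#' @export
#' @examples
#' venn_compare(list(A = letters[1:5], B = letters[3:7], C = letters[5:9]))
venn_compare <- function(call_sets) {
  if (length(call_sets) < 2L) stop("need at least 2 sets", call. = FALSE)
  if (is.null(names(call_sets)) || any(!nzchar(names(call_sets)))) {
    stop("`call_sets` must be named", call. = FALSE)
  }
  nm <- names(call_sets)
  rows <- list()
  for (d in seq_along(nm)) {
    for (comb in utils::combn(nm, d, simplify = FALSE)) {
      inter <- Reduce(intersect, call_sets[comb])
      rows[[length(rows) + 1L]] <- data.frame(
        sets = paste(comb, collapse = ";"),
        degree = d,
        n = length(inter),
        members = paste(sort(inter), collapse = ";"),
        stringsAsFactors = FALSE
      )
    }
  }
  out <- do.call(rbind, rows)
  rownames(out) <- NULL
  out
}
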