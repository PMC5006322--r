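#' One-vs-rest quasi-Poisson differential expression (DEMiR test)
#'
#' For every (miRNA, tissue) pair, counts are modelled by a quasi-Poisson
#' regression on an indicator of the target tissue with a per-sample offset
#' equal to the natural log of that sample's third quartile of counts
#' (upper-quartile normalisation inside the model). For a single binary
#' factor the quasi-likelihood fit has a closed form (each group's rate is
#' its count total over its offset total), which this implementation uses;
#' it is algebraically identical to `glm(..., family = quasipoisson)`.
#' Per-miRNA Pearson dispersions are shrunk toward a pooled (trimmed-mean)
#' dispersion with prior weight `d0`, and the tissue effect is tested with
#' an F statistic (likelihood-ratio deviance over shrunken dispersion) on
#' `1` and `df + d0` degrees of freedom. A miRNA is flagged significant in
#' a tissue at nominal `p < alpha` (no multiple-testing correction by
#' default; `adjust = "BH"` is available).
#'
#' @param counts an `atlas_counts`.
#' @param alpha nominal significance level (default 0.01).
#' @param d0 prior degrees of freedom of the dispersion shrinkage
#'   (default 10).
#' @param trim trim fraction (each side) of the pooled dispersion mean
#'   (default 0.1).
#' @param by group samples by "tissue" (default) or "organ".
#' @param adjust "none" (default) or "BH".
#' @return data.frame with one row per (miRNA, group): `mirna`, `tissue`,
#'   `log2fd` (one-vs-rest log2 fold difference), `dispersion_raw`,
#'   `dispersion_shrunk`, `stat`, `p`, `significant`, `flagged`
#'   (degenerate all-equal rows where p is set to 1). Sample offsets are
#'   attached as `attr(, "offset")`.
#' @export
demir_one_vs_rest <- function(counts, alpha = 0.01, d0 = 10, trim = 0.1,
                              by = c("tissue", "organ"), adjust = "none") {
  stopifnot(inherits(counts, "atlas_counts"))
  by <- match.arg(by)
  y <- counts$counts
  if (any(y != floor(y))) stop("counts must be integers", call. = FALSE)
  grp <- counts$samples[[by]]
  groups <- unique(grp)
  n <- ncol(y)
  if (any(table(grp) < 2L) || n - min(table(grp)) < 2L) {
    stop("need at least 2 samples in the target group and in the rest",
         call. = FALSE)
  }

  # per-sample offset: log Q3 of the sample's counts; Q3 = 0 falls back to
  # the sample mean count
  q3s <- apply(y, 2L, q3)
  fallback <- colSums(y) / nrow(y)
  q3s[q3s <= 0] <- fallback[q3s <= 0]
  if (any(q3s <= 0)) {
    stop("offset undefined: sample(s) with no reads at all", call. = FALSE)
  }
  off <- q3s  # exp of the log-Q3 offset

  # poisson deviance of y against mean mu, with 0 * log(0) = 0 and the
  # convention that mu = 0 forces y = 0 (true at the MLE)
  pdev <- function(y, mu) {
    term <- ifelse(y > 0, y * log(y / pmax(mu, .Machine$double.eps)), 0)
    2 * (term - (y - mu))
  }

  res <- vector("list", length(groups))
  for (gi in seq_along(groups)) {
    tcols <- grp == groups[gi]
    s_t <- rowSums(y[, tcols, drop = FALSE])
    s_r <- rowSums(y[, !tcols, drop = FALSE])
    e_t <- sum(off[tcols])
    e_r <- sum(off[!tcols])
    r_t <- s_t / e_t
    r_r <- s_r / e_r
    r_0 <- (s_t + s_r) / (e_t + e_r)

    mu_full <- cbind(r_t %o% off[tcols], r_r %o% off[!tcols])
    y_perm <- cbind(y[, tcols, drop = FALSE], y[, !tcols, drop = FALSE])
    mu_null <- r_0 %o% off[c(which(tcols), which(!tcols))]
    d_full <- rowSums(pdev(y_perm, mu_full))
    d_null <- rowSums(pdev(y_perm, mu_null))
    lrt <- pmax(d_null - d_full, 0)

    pearson <- ifelse(mu_full > 0, (y_perm - mu_full)^2 / mu_full, 0)
    df <- n - 2L
    disp_raw <- rowSums(pearson) / df

    degenerate <- (s_t + s_r) == 0 |
      apply(y, 1L, function(v) length(unique(v)) == 1L)
    ok <- !degenerate & is.finite(disp_raw)
    pooled <- if (any(ok)) mean(disp_raw[ok], trim = trim) else 1
    pooled <- max(pooled, 1e-8)
    disp_shr <- (d0 * pooled + df * disp_raw) / (d0 + df)
    disp_shr <- pmax(disp_shr, 1e-8)

    stat <- lrt / disp_shr
    p <- stats::pf(stat, 1, df + d0, lower.tail = FALSE)
    p[degenerate] <- 1
    log2fd <- log2(r_t / r_r)
    res[[gi]] <- data.frame(
      mirna = rownames(y), tissue = groups[gi], log2fd = log2fd,
      dispersion_raw = disp_raw, dispersion_shrunk = disp_shr,
      stat = stat, p = p, flagged = degenerate,
      stringsAsFactors = FALSE
    )
  }
  out <- do.call(rbind, res)
  rownames(out) <- NULL
  if (adjust == "BH") {
    out$p_adj <- stats::p.adjust(out$p, "BH")
    out$significant <- out$p_adj < alpha
  } else {
    out$significant <- out$p < alpha
  }
  attr(out, "offset") <- log(q3s)
  out
}

#' Enriched-miRNA set from DEMiR results
#'
#' A miRNA enters the set when it is significantly *up* in at least one
#' tissue (positive one-vs-rest log2 fold difference).
#'
#' @param res result of [demir_one_vs_rest()].
#' @param min_log2fd minimum log2 fold difference (default 0, i.e. any
#'   upward contrast).
#' @return character vector of miRNA ids.
#' @export
demir_enriched_set <- function(res, min_log2fd = 0) {
  sig <- res$significant & !res$flagged & res$log2fd > min_log2fd
  sort(unique(res$mirna[sig]))
}
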