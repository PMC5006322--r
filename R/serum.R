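#' Quality-control a qPCR Ct measurement against its negative controls
#'
#' A Ct is acceptable when it sits at least `margin` cycles (default 10)
#' below every *detected* negative control (no-template and no-RT); an
#' undetected control (NA) imposes no constraint. Assays whose melt curve
#' shows more than one peak are rejected outright, as are undetected
#' targets.
#'
#' @param ct target Ct value(s); `NA` = undetected.
#' @param ntc no-template control Ct (`NA` = no signal).
#' @param no_rt no-reverse-transcriptase control Ct (`NA` = no signal).
#' @param melt_multi_peak logical: melt curve had more than one peak.
#' @param margin required clearance in cycles (default 10).
#' @return data.frame with `accept` (logical) and `reason`
#'   ("ok", "no_amplification", "near_ntc", "near_no_rt", "multi_peak").
#' @export
#' @examples
#' qc_ct(25, ntc = 40, no_rt = 40)           # accept
#' qc_ct(33, ntc = NA, no_rt = 40)           # reject: 7 < 10
#' qc_ct(30, ntc = NA, no_rt = NA)           # accept: controls silent
qc_ct <- function(ct, ntc = NA_real_, no_rt = NA_real_,
                  melt_multi_peak = FALSE, margin = 10) {
  if (margin <= 0) stop("`margin` must be > 0", call. = FALSE)
  k <- max(length(ct), length(ntc), length(no_rt), length(melt_multi_peak))
  ct <- rep_len(ct, k); ntc <- rep_len(ntc, k)
  no_rt <- rep_len(no_rt, k); melt_multi_peak <- rep_len(melt_multi_peak, k)
  accept <- rep(TRUE, k)
  reason <- rep("ok", k)
  near_ntc <- !is.na(ntc) & !is.na(ct) & ct > ntc - margin
  accept[near_ntc] <- FALSE; reason[near_ntc] <- "near_ntc"
  near_rt <- !is.na(no_rt) & !is.na(ct) & ct > no_rt - margin
  accept[near_rt] <- FALSE; reason[near_rt] <- "near_no_rt"
  accept[melt_multi_peak] <- FALSE; reason[melt_multi_peak] <- "multi_peak"
  und <- is.na(ct)
  accept[und] <- FALSE; reason[und] <- "no_amplification"
  data.frame(accept = accept, reason = reason, stringsAsFactors = FALSE)
}

#' Spike-in-normalised delta-delta-Ct fold changes
#'
#' Per (animal, timepoint): delta-Ct = target Ct - spike-in Ct (well means
#' if replicated); delta-delta-Ct subtracts the mean delta-Ct of the
#' reference observations; FC = 2^(-delta-delta-Ct). Two reference
#' conventions are supported: `"vehicle"` references the first (vehicle)
#' group at the matched timepoint, `"predose"` references the earliest
#' timepoint pooled over groups. Samples without a spike-in measurement
#' are excluded and listed in `attr(, "excluded")`.
#'
#' @param study a `qpcr_study` (see [generate_qpcr_study()]) or a
#'   compatible list with `wells`, `spike`, `target`.
#' @param reference "vehicle" or "predose".
#' @param vehicle_group name of the vehicle group (default: first group
#'   present).
#' @return data.frame with `animal`, `group`, `timepoint`, `target`,
#'   `dct`, `ddct`, `fc`, `log2fc`.
#' @export
spike_normalized_fold_change <- function(study,
                                         reference = c("vehicle", "predose"),
                                         vehicle_group = NULL) {
  reference <- match.arg(reference)
  w <- study$wells
  w <- w[w$well_type == "sample" & !is.na(w$animal), , drop = FALSE]
  tgt <- w[w$target == study$target, , drop = FALSE]
  spk <- w[w$target == study$spike, , drop = FALSE]
  agg_t <- stats::aggregate(ct ~ animal + group + timepoint, tgt, mean)
  agg_s <- stats::aggregate(ct ~ animal + timepoint, spk, mean)
  m <- merge(agg_t, agg_s, by = c("animal", "timepoint"),
             suffixes = c("_target", "_spike"), all.x = TRUE)
  excluded <- m[is.na(m$ct_spike), c("animal", "timepoint"), drop = FALSE]
  m <- m[!is.na(m$ct_spike), , drop = FALSE]
  m$dct <- m$ct_target - m$ct_spike
  if (is.null(vehicle_group)) {
    vehicle_group <- unique(w$group[!is.na(w$group)])[1L]
  }
  if (!vehicle_group %in% m$group) {
    stop("vehicle group '", vehicle_group, "' has no observations",
         call. = FALSE)
  }
  if (reference == "vehicle") {
    ref_mean <- tapply(m$dct[m$group == vehicle_group],
                       m$timepoint[m$group == vehicle_group], mean)
    if (anyNA(ref_mean[as.character(m$timepoint)])) {
      stop("no vehicle observations at some timepoint", call. = FALSE)
    }
    m$ddct <- m$dct - as.numeric(ref_mean[as.character(m$timepoint)])
  } else {
    t0 <- min(m$timepoint)
    m$ddct <- m$dct - mean(m$dct[m$timepoint == t0])
  }
  m$fc <- 2^(-m$ddct)
  m$log2fc <- -m$ddct
  out <- data.frame(animal = m$animal, group = m$group,
                    timepoint = m$timepoint, target = study$target,
                    dct = m$dct, ddct = m$ddct, fc = m$fc,
                    log2fc = m$log2fc, stringsAsFactors = FALSE)
  out <- out[order(out$group, out$animal, out$timepoint), , drop = FALSE]
  rownames(out) <- NULL
  attr(out, "excluded") <- excluded
  attr(out, "vehicle_group") <- vehicle_group
  out
}

#' Repeated-measures two-way ANOVA of log2 fold changes with AR(1) errors
#'
#' Fits group x timepoint cell means by generalised least squares with
#' within-animal autocorrelation (AR(1) by default, compound symmetry
#' optionally), estimating the correlation from the data. Each cell's fold
#' change is reported as the *contrast* between its cell mean and the
#' reference cell mean -- the vehicle group at the matched timepoint
#' (`reference = "vehicle"`) or the same group's earliest timepoint
#' (`reference = "predose"`). Estimating the difference inside the model
#' propagates the reference cells' sampling noise (and any within-animal
#' correlation with them) into the standard errors, which a naive fit on
#' pre-subtracted values would ignore. Reference cells themselves are
#' fixed at fold change 1 (log2 = 0). Because the contrast cancels any
#' per-timepoint constant, the fit gives identical inference whether `fc`
#' holds raw delta-Ct-derived values or already reference-normalised
#' log2 fold changes.
#'
#' @param fc data.frame with columns `log2fc`, `group`, `timepoint`,
#'   `animal` (e.g. from [spike_normalized_fold_change()]).
#' @param reference "vehicle" (matched-time vehicle contrast) or "predose"
#'   (within-group contrast against the earliest timepoint).
#' @param vehicle_group reference group name (default: the
#'   `vehicle_group` attribute set by [spike_normalized_fold_change()],
#'   else the first group in the data).
#' @param correlation "ar1" (default) or "cs" (compound symmetry).
#' @param conf_level confidence level (default 0.95).
#' @return object of class `fold_change_fit`: data.frame with `group`,
#'   `timepoint`, `reference` (logical), `log2fc`, `se`, `ci_low`,
#'   `ci_high`, `fc`, `fc_low`, `fc_high`, `p`; the estimated correlation
#'   is in `attr(, "rho")` and the underlying `gls` fit in
#'   `attr(, "model")`.
#' @export
fit_repeated_anova <- function(fc, reference = c("vehicle", "predose"),
                               vehicle_group = NULL,
                               correlation = c("ar1", "cs"),
                               conf_level = 0.95) {
  reference <- match.arg(reference)
  correlation <- match.arg(correlation)
  req <- c("log2fc", "group", "timepoint", "animal")
  if (!all(req %in% names(fc))) {
    stop("`fc` needs columns: ", paste(req, collapse = ", "), call. = FALSE)
  }
  if (length(unique(fc$timepoint)) < 2L) {
    stop("need at least 2 timepoints", call. = FALSE)
  }
  tab <- table(fc$group, fc$timepoint)
  if (any(tab == 0L)) {
    empty <- which(tab == 0L, arr.ind = TRUE)[1L, ]
    stop(sprintf("singular design: no observations for group '%s' at time %s",
                 rownames(tab)[empty[1L]], colnames(tab)[empty[2L]]),
         call. = FALSE)
  }
  if (min(table(fc$group)) / length(unique(fc$timepoint)) < 2) {
    stop("need at least 2 animals per group", call. = FALSE)
  }
  if (is.null(vehicle_group)) {
    vehicle_group <- attr(fc, "vehicle_group") %||% fc$group[1L]
  }
  if (reference == "vehicle" && !vehicle_group %in% fc$group) {
    stop("vehicle group '", vehicle_group, "' not present", call. = FALSE)
  }
  d <- fc
  d$cell <- interaction(d$group, d$timepoint, drop = TRUE, sep = "@")
  d$time_rank <- as.numeric(factor(d$timepoint,
                                   levels = sort(unique(d$timepoint))))
  d <- d[order(d$animal, d$time_rank), , drop = FALSE]
  cs <- switch(correlation,
               ar1 = nlme::corAR1(form = ~ time_rank | animal),
               cs = nlme::corCompSymm(form = ~ 1 | animal))
  mod <- nlme::gls(log2fc ~ 0 + cell, data = d, correlation = cs,
                   method = "REML")
  est <- stats::coef(mod)
  vc <- stats::vcov(mod)
  df <- nrow(d) - length(est)
  tcrit <- stats::qt(1 - (1 - conf_level) / 2, df)
  cells <- sub("^cell", "", names(est))
  parts <- strsplit(cells, "@", fixed = TRUE)
  grp <- vapply(parts, `[`, character(1), 1L)
  tp <- as.numeric(vapply(parts, `[`, character(1), 2L))
  t0 <- min(tp)
  ref_of <- function(i) {
    if (reference == "vehicle") {
      which(grp == vehicle_group & tp == tp[i])
    } else {
      which(grp == grp[i] & tp == t0)
    }
  }
  k <- length(est)
  delta <- numeric(k); dse <- numeric(k); is_ref <- logical(k)
  for (i in seq_len(k)) {
    j <- ref_of(i)
    if (length(j) != 1L) stop("reference cell not found", call. = FALSE)
    is_ref[i] <- i == j
    delta[i] <- est[i] - est[j]
    dse[i] <- sqrt(vc[i, i] + vc[j, j] - 2 * vc[i, j])
  }
  out <- data.frame(
    group = grp, timepoint = tp, reference = is_ref,
    log2fc = delta,
    se = ifelse(is_ref, 0, dse),
    ci_low = ifelse(is_ref, 0, delta - tcrit * dse),
    ci_high = ifelse(is_ref, 0, delta + tcrit * dse),
    p = ifelse(is_ref, NA_real_, 2 * stats::pt(-abs(delta / dse), df)),
    stringsAsFactors = FALSE
  )
  out$fc <- 2^out$log2fc
  out$fc_low <- 2^out$ci_low
  out$fc_high <- 2^out$ci_high
  out <- out[order(out$group, out$timepoint), , drop = FALSE]
  rownames(out) <- NULL
  rho <- tryCatch(
    as.numeric(stats::coef(mod$modelStruct$corStruct, unconstrained = FALSE)),
    error = function(e) NA_real_
  )
  attr(out, "rho") <- rho
  attr(out, "model") <- mod
  class(out) <- c("fold_change_fit", class(out))
  out
}

#' Correlate qPCR Ct values with sequencing counts across tissues
#'
#' Ct decreases as abundance increases, so a perfect agreement gives a
#' correlation of -1. Counts are log10(count + 1) transformed before the
#' Pearson correlation (Ct is itself a log-scale quantity); the Spearman
#' rank correlation is reported alongside so the transform choice is
#' auditable. Undetected Ct values (NA) are excluded, not imputed.
#'
#' @param ct per-tissue Ct values (NA = undetected / rejected by QC).
#' @param counts per-tissue sequencing raw counts, aligned with `ct`.
#' @return list with `pearson`, `spearman`, `n` (pairs used) and `flag`
#'   ("ok", "too_few_pairs", or "constant_input").
#' @export
correlate_qpcr_seq <- function(ct, counts) {
  keep <- !is.na(ct) & !is.na(counts)
  ct <- ct[keep]
  counts <- counts[keep]
  n <- length(ct)
  if (n < 3L) {
    return(list(pearson = NA_real_, spearman = NA_real_, n = n,
                flag = "too_few_pairs"))
  }
  lx <- log10(counts + 1)
  if (stats::sd(lx) == 0 || stats::sd(ct) == 0) {
    return(list(pearson = NA_real_, spearman = NA_real_, n = n,
                flag = "constant_input"))
  }
  list(
    pearson = stats::cor(ct, lx, method = "pearson"),
    spearman = stats::cor(ct, lx, method = "spearman"),
    n = n,
    flag = "ok"
  )
}
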