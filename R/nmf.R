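#' Non-negative matrix factorisation of an organ count matrix
#'
#' Decomposes a non-negative miRNA x organ matrix X into W (miRNA x k) and
#' H (k x organ) by multiplicative updates minimising the generalised
#' Kullback-Leibler divergence D(X || WH), the natural objective for count
#' data. Each column of W defines a miRNA group and each row of H the
#' expression pattern of that group across organs. Several random restarts
#' are run and the best (lowest-divergence) fit kept.
#'
#' @param x non-negative matrix (miRNAs x organs).
#' @param k factorisation rank (default `min(14, ncol(x))`, one factor per
#'   organ).
#' @param seed integer seed for the random non-negative initialisations.
#' @param n_restarts random restarts (default 10); best objective kept.
#' @param max_iter maximum multiplicative updates per restart (default 500).
#' @param tol relative objective-change convergence threshold (default
#'   1e-6).
#' @return object of class `nmf_fit`: list with `W`, `H`, `k`, `objective`
#'   (final divergence), `objective_trace`, `converged`, `seed`.
#' @export
nmf_factorize <- function(x, k = min(14L, ncol(x)), seed = 1L,
                          n_restarts = 10L, max_iter = 500L, tol = 1e-6) {
  x <- as.matrix(x)
  if (any(x < 0)) stop("matrix must be non-negative", call. = FALSE)
  if (all(x == 0)) stop("all-zero matrix cannot be factorised", call. = FALSE)
  if (k > ncol(x)) stop("rank k must not exceed the number of columns",
                        call. = FALSE)
  eps <- .Machine$double.eps
  kl_div <- function(x, wh) {
    pos <- x > 0
    sum(x[pos] * log(x[pos] / wh[pos])) - sum(x) + sum(wh)
  }
  run_once <- function() {
    w <- matrix(stats::runif(nrow(x) * k), nrow(x), k) * sqrt(mean(x))
    h <- matrix(stats::runif(k * ncol(x)), k, ncol(x)) * sqrt(mean(x))
    wh <- w %*% h
    obj <- kl_div(x, wh)
    trace <- obj
    converged <- FALSE
    for (it in seq_len(max_iter)) {
      # W update
      w <- w * ((x / pmax(wh, eps)) %*% t(h)) /
        pmax(matrix(colSums(t(h)), nrow(x), k, byrow = TRUE), eps)
      wh <- w %*% h
      # H update
      h <- h * (t(w) %*% (x / pmax(wh, eps))) /
        pmax(matrix(colSums(w), k, ncol(x)), eps)
      wh <- w %*% h
      new_obj <- kl_div(x, wh)
      trace <- c(trace, new_obj)
      denom <- max(abs(obj), eps)
      if (abs(obj - new_obj) / denom < tol) {
        obj <- new_obj
        converged <- TRUE
        break
      }
      obj <- new_obj
    }
    list(W = w, H = h, objective = obj, objective_trace = trace,
         converged = converged)
  }
  best <- with_seed(seed, {
    fits <- replicate(n_restarts, run_once(), simplify = FALSE)
    fits[[which.min(vapply(fits, `[[`, numeric(1), "objective"))]]
  })
  rownames(best$W) <- rownames(x)
  colnames(best$H) <- colnames(x)
  structure(c(best, list(k = as.integer(k), seed = as.integer(seed))),
            class = "nmf_fit")
}

#' @export
print.nmf_fit <- function(x, ...) {
  cat(sprintf("nmf_fit: rank %d, KL divergence %.6g (%sconverged)\n",
              x$k, x$objective, if (x$converged) "" else "not "))
  invisible(x)
}

#' Nominate organ-specific miRNA candidates from an NMF fit
#'
#' Each miRNA is assigned to its dominant factor (argmax over its W row);
#' each factor maps to the organ carrying the largest share of its H row. A
#' candidate is emitted only when that organ carries more than `dominance`
#' of the factor's total H mass, i.e. the factor really is an organ-private
#' expression pattern.
#'
#' @param fit an `nmf_fit`.
#' @param dominance minimum organ share of the factor's H mass (default
#'   0.5).
#' @return data.frame with columns `mirna`, `organ`, `factor`,
#'   `organ_share`, `w_weight`.
#' @export
organ_specific_candidates <- function(fit, dominance = 0.5) {
  stopifnot(inherits(fit, "nmf_fit"))
  h_share <- fit$H / pmax(rowSums(fit$H), .Machine$double.eps)
  fac_organ <- apply(h_share, 1L, which.max)
  fac_share <- h_share[cbind(seq_len(fit$k), fac_organ)]
  rows <- list()
  for (i in seq_len(nrow(fit$W))) {
    if (all(fit$W[i, ] == 0)) next
    f <- which.max(fit$W[i, ])
    if (fac_share[f] > dominance) {
      rows[[length(rows) + 1L]] <- data.frame(
        mirna = rownames(fit$W)[i],
        organ = colnames(fit$H)[fac_organ[f]],
        factor = f,
        organ_share = fac_share[f],
        w_weight = fit$W[i, f],
        stringsAsFactors = FALSE
      )
    }
  }
  if (!length(rows)) {
    return(data.frame(mirna = character(0), organ = character(0),
                      factor = integer(0), organ_share = numeric(0),
                      w_weight = numeric(0)))
  }
  out <- do.call(rbind, rows)
  rownames(out) <- NULL
  out
}
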