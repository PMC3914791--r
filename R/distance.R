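#' Pairwise distances from a protein alignment
#'
#' Computes a symmetric distance matrix from a multiple protein alignment.
#' With `model = "dayhoff_ml"` each pairwise distance is the
#' maximum-likelihood number of substitutions per site under the Dayhoff
#' empirical rate matrix, found by scalar optimization of the pair
#' likelihood (the PROTDIST approach). With `model = "kimura_corrected"`
#' the distance is \eqn{-\ln(1 - p - 0.2 p^2)} with `p` the observed
#' mismatch proportion.
#'
#' Gap handling is pairwise deletion by default: a column is used for a
#' pair when neither member has a gap (or ambiguity) there. With
#' `gap_handling = "complete"` only columns without gaps in any sequence
#' are used at all.
#'
#' Pairs whose distance cannot be estimated (Kimura correction out of
#' domain, or the ML optimum hitting the ceiling) are flagged saturated and
#' set to `ceiling`.
#'
#' @param alignment named character vector of equal-length gapped
#'   amino-acid strings.
#' @param model `"dayhoff_ml"` or `"kimura_corrected"`.
#' @param gap_handling `"pairwise"` (default) or `"complete"`.
#' @param ceiling distance assigned to saturated pairs (default 10).
#' @param refine for `dayhoff_ml`, polish each pair's grid optimum by
#'   scalar optimization (default TRUE; bootstrap replicates disable it
#'   for speed, where grid resolution of a few percent is ample).
#' @return Symmetric numeric matrix with zero diagonal and a logical
#'   attribute matrix `saturated`.
#' @export
protein_distance <- function(alignment,
                             model = c("dayhoff_ml", "kimura_corrected"),
                             gap_handling = c("pairwise", "complete"),
                             ceiling = 10, refine = TRUE) {
  model <- match.arg(model)
  gap_handling <- match.arg(gap_handling)
  labels <- names(alignment)
  assert_that(length(alignment) >= 2, "alignment must hold at least 2 sequences")
  assert_that(!is.null(labels) && !anyDuplicated(labels),
              "sequences must carry unique names")
  lens <- nchar(alignment)
  assert_that(length(unique(lens)) == 1, "alignment rows must have equal length")

  mat <- do.call(rbind, strsplit(toupper(alignment), ""))
  code <- matrix(match(mat, AA_ORDER), nrow = nrow(mat))  # NA: gap/ambiguity
  if (gap_handling == "complete") {
    code <- code[, !apply(is.na(code), 2, any), drop = FALSE]
  }
  n <- length(alignment)
  d <- matrix(0, n, n, dimnames = list(labels, labels))
  sat <- matrix(FALSE, n, n, dimnames = list(labels, labels))

  pair_idx <- which(upper.tri(d), arr.ind = TRUE)
  if (model == "kimura_corrected") {
    for (r in seq_len(nrow(pair_idx))) {
      i <- pair_idx[r, 1]; j <- pair_idx[r, 2]
      use <- !is.na(code[i, ]) & !is.na(code[j, ])
      if (!any(use)) {
        abort(sprintf("no comparable columns for pair (%s, %s)",
                      labels[i], labels[j]))
      }
      p <- mean(code[i, use] != code[j, use])
      arg <- 1 - p - 0.2 * p^2
      if (arg <= 0) {
        d[i, j] <- d[j, i] <- ceiling
        sat[i, j] <- sat[j, i] <- TRUE
      } else {
        d[i, j] <- d[j, i] <- min(-log(arg), ceiling)
      }
    }
    attr(d, "saturated") <- sat
    return(d)
  }

  # Dayhoff ML: evaluate every pair's log-likelihood on a shared grid of
  # branch lengths (one matrix product), then refine the optimum of each
  # pair by scalar optimization inside the bracketing grid interval.
  grid <- dayhoff_ll_grid(ceiling)
  counts <- matrix(0, nrow(pair_idx), 400L)
  n_same <- integer(nrow(pair_idx))
  n_comp <- integer(nrow(pair_idx))
  for (r in seq_len(nrow(pair_idx))) {
    i <- pair_idx[r, 1]; j <- pair_idx[r, 2]
    use <- !is.na(code[i, ]) & !is.na(code[j, ])
    if (!any(use)) {
      abort(sprintf("no comparable columns for pair (%s, %s)",
                    labels[i], labels[j]))
    }
    a <- code[i, use]; b <- code[j, use]
    counts[r, ] <- tabulate((a - 1L) * 20L + b, 400L)
    n_same[r] <- sum(a == b)
    n_comp[r] <- length(a)
  }
  ll <- counts %*% grid$ll            # n_pairs x n_grid
  best <- max.col(ll, ties.method = "first")
  model_obj <- dayhoff_model()
  for (r in seq_len(nrow(pair_idx))) {
    i <- pair_idx[r, 1]; j <- pair_idx[r, 2]
    if (n_same[r] == n_comp[r]) next  # identical -> distance 0
    k <- best[r]
    est <- grid$t[k]
    saturated <- FALSE
    if (k == length(grid$t)) {
      est <- ceiling; saturated <- TRUE
    } else if (refine) {
      lo <- grid$t[max(1, k - 1)]
      hi <- grid$t[min(length(grid$t), k + 1)]
      cnt <- counts[r, ]
      nz <- which(cnt > 0)
      negll <- function(t) {
        P <- dayhoff_pt(t, model_obj)
        -sum(cnt[nz] * log(pmax(model_obj$pi * P, 1e-300))[nz])
      }
      est <- optimize(negll, interval = c(lo, hi), tol = 1e-8)$minimum
    }
    d[i, j] <- d[j, i] <- est
    sat[i, j] <- sat[j, i] <- saturated
  }
  attr(d, "saturated") <- sat
  d
}

# log(pi_a P_ab(t)) flattened to 400 rows, evaluated on a log-spaced grid
# of branch lengths; cached per ceiling.
dayhoff_ll_grid <- function(ceiling) {
  key <- paste0("llgrid_", format(ceiling))
  if (!is.null(.rga_cache[[key]])) return(.rga_cache[[key]])
  model <- dayhoff_model()
  t_grid <- c(exp(seq(log(1e-4), log(ceiling), length.out = 160L)))
  ll <- vapply(t_grid, function(t) {
    P <- dayhoff_pt(t, model)
    as.vector(t(log(pmax(model$pi * P, 1e-300))))  # row-major: (a-1)*20+b
  }, numeric(400L))
  .rga_cache[[key]] <- list(t = t_grid, ll = ll)
  .rga_cache[[key]]
}
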