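# The Dayhoff (1978) empirical amino-acid replacement model: symmetric
# exchangeabilities (lower triangle, column-wise, PAML residue order
# ARNDCQEGHILKMFPSTWYV) and equilibrium frequencies, as distributed with
# Phylip-lineage software. Values are embedded so distance computation has
# no runtime dependency.
DAYHOFF_EXCHANGE <- c(
  27, 98, 120, 36, 89, 198, 240, 23, 65, 41, 26, 72, 18, 250,
  409, 371, 0, 24, 208, 32, 0, 23, 246, 1, 9, 240, 64, 15, 464,
  90, 14, 103, 154, 26, 201, 8, 24, 905, 0, 103, 148, 139, 535,
  77, 34, 318, 1, 14, 42, 495, 229, 23, 95, 15, 0, 134, 1153, 125,
  86, 24, 0, 71, 0, 0, 13, 95, 66, 0, 0, 18, 0, 0, 11, 28, 44,
  0, 0, 0, 0, 19, 161, 16, 0, 96, 49, 716, 28, 606, 18, 73, 153,
  114, 0, 153, 56, 53, 0, 0, 35, 81, 43, 61, 11, 83, 30, 0, 51,
  79, 34, 0, 22, 37, 10, 0, 7, 27, 17, 15, 34, 234, 30, 0, 0, 54,
  7, 44, 26, 0, 48, 94, 35, 22, 27, 127, 44, 257, 46, 336, 196,
  12, 24, 192, 0, 37, 889, 18, 527, 157, 32, 17, 33, 46, 28, 175,
  243, 0, 33, 96, 136, 0, 13, 10, 92, 17, 62, 104, 0, 0, 258, 11,
  46, 13, 76, 698, 12, 245, 78, 0, 0, 48, 550, 75, 34, 30, 0, 42,
  157, 61, 0, 28
)

DAYHOFF_FREQS <- c(
  A = 0.08712691, R = 0.04090396, N = 0.04043196, D = 0.04687195,
  C = 0.03347397, Q = 0.03825496, E = 0.04952995, G = 0.08861191,
  H = 0.03361797, I = 0.03688596, L = 0.08535691, K = 0.08048192,
  M = 0.01475299, F = 0.03977196, P = 0.05067995, S = 0.06957693,
  T = 0.05854194, W = 0.01049399, Y = 0.02991597, V = 0.06471794
)

AA_ORDER <- names(DAYHOFF_FREQS)

# package-level cache for model decompositions and NG86 lookup tables
.rga_cache <- new.env(parent = emptyenv())

#' Dayhoff rate model
#'
#' Builds the instantaneous rate matrix Q of the Dayhoff empirical model,
#' scaled so that one unit of branch length equals one expected
#' substitution per site at equilibrium, together with its symmetric
#' eigendecomposition for fast computation of transition probabilities
#' P(t) = exp(Qt).
#'
#' @return List with `Q`, `pi`, and eigendecomposition parts (`values`,
#'   `vectors`, `inv`), cached after the first call.
#' @keywords internal
dayhoff_model <- function() {
  if (!is.null(.rga_cache$dayhoff)) return(.rga_cache$dayhoff)
  S <- matrix(0, 20, 20, dimnames = list(AA_ORDER, AA_ORDER))
  S[lower.tri(S)] <- DAYHOFF_EXCHANGE
  S <- S + t(S)
  pi <- DAYHOFF_FREQS
  Q <- S * rep(pi, each = 20)          # Q_ij = S_ij * pi_j  (i in rows)
  diag(Q) <- -rowSums(Q)
  rate <- -sum(pi * diag(Q))
  Q <- Q / rate
  # reversible: diag(sqrt(pi)) Q diag(1/sqrt(pi)) is symmetric
  sp <- sqrt(pi)
  B <- Q * (sp %o% (1 / sp))
  B <- (B + t(B)) / 2
  e <- eigen(B, symmetric = TRUE)
  model <- list(
    Q = Q, pi = pi, values = e$values,
    vectors = e$vectors * (1 / sp),        # row-scaled:  (1/sqrt(pi)) V
    inv = t(e$vectors * sp)                # V^T diag(sqrt(pi))
  )
  .rga_cache$dayhoff <- model
  model
}

# Transition probability matrix P(t) under the Dayhoff model.
dayhoff_pt <- function(t, model = dayhoff_model()) {
  P <- model$vectors %*% (exp(model$values * t) * model$inv)
  P[P < 0] <- 0
  dimnames(P) <- list(AA_ORDER, AA_ORDER)
  P
}
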