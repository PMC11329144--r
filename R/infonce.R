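#' Cosine similarity
#'
#' `sim(u, v) = u'v / (||u|| ||v||)`, the similarity used inside the InfoNCE
#' contrastive loss. Symmetric and invariant to positive rescaling of either
#' argument.
#'
#' @param u,v Nonzero numeric vectors of equal length.
#' @return A number in \[-1, 1\].
#' @export
cosine_sim <- function(u, v) {
  stopifnot(length(u) == length(v))
  nu <- sqrt(sum(u^2)); nv <- sqrt(sum(v^2))
  if (nu == 0 || nv == 0) stop("cosine_sim: zero vector")
  sum(u * v) / (nu * nv)
}

# 2N x 2N cosine similarity matrix of the rows of Z
cosine_sim_matrix <- function(Z) {
  nrm <- sqrt(rowSums(Z^2))
  if (any(nrm == 0)) stop("infonce: zero embedding vector")
  Zn <- Z / nrm
  tcrossprod(Zn)
}

#' InfoNCE loss of one ordered pair
#'
#' `l(i, j) = -log[ exp(sim(z_i, z_j)/tau) / sum_{k != i} exp(sim(z_i, z_k)/tau) ]`,
#' where the sum runs over all 2N embeddings except `k = i` (the positive
#' partner `j` is *included* in the denominator). Always >= 0; identically 0
#' when N = 1 since the denominator's only term is the numerator.
#'
#' @param i,j Anchor and positive-partner row indices (1-based, `i != j`).
#' @param Z Matrix of 2N embeddings (rows).
#' @param tau Temperature, > 0: smaller values sharpen the softmax over
#'   negatives.
#' @return The pair loss, a non-negative scalar.
#' @export
infonce_pair_loss <- function(i, j, Z, tau = 0.5) {
  Z <- as.matrix(Z)
  n <- nrow(Z)
  stopifnot(n >= 2, n %% 2 == 0, tau > 0)
  if (i < 1 || i > n || j < 1 || j > n) stop("infonce_pair_loss: index out of range")
  if (i == j) stop("infonce_pair_loss: i == j")
  S <- cosine_sim_matrix(Z) / tau
  m <- max(S[i, -i])                              # log-sum-exp stabilization
  denom <- m + log(sum(exp(S[i, -i] - m)))
  denom - S[i, j]
}

#' InfoNCE minibatch loss
#'
#' Rows of `Z` must be ordered so that rows `(2k - 1, 2k)` are the embeddings
#' of the two random crops of recording `k`. The loss is the average of the
#' pair losses over both orderings of every positive pair:
#' `L = (1/2N) sum_k [ l(2k-1, 2k) + l(2k, 2k-1) ]`.
#'
#' Closed forms used as tests: `L = 0` at `N = 1`; `L = log(2N - 1)` when all
#' embeddings are identical.
#'
#' @param Z Matrix of 2N embeddings (rows), pair-ordered.
#' @param tau Temperature, > 0.
#' @return The batch loss, a non-negative scalar.
#' @export
infonce_batch_loss <- function(Z, tau = 0.5) {
  Z <- as.matrix(Z)
  n2 <- nrow(Z)
  if (n2 %% 2 != 0) stop("infonce_batch_loss: odd number of embeddings")
  stopifnot(n2 >= 2, tau > 0)
  S <- cosine_sim_matrix(Z) / tau
  diag(S) <- -Inf                                 # excludes k = i only
  m <- apply(S, 1, max)
  lse <- m + log(rowSums(exp(S - m)))             # per-anchor log denominator
  partner <- ifelse(seq_len(n2) %% 2 == 1, seq_len(n2) + 1, seq_len(n2) - 1)
  pos <- S[cbind(seq_len(n2), partner)]
  mean(lse - pos)
}
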