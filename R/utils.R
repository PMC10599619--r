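# Internal numerical helpers shared across modules.

# Symmetric square root of a PSD matrix; tolerates zero/semi-definite input
# (plain chol() does not).
psd_sqrt <- function(S, tol = 1e-12) {
  S <- (S + t(S)) / 2
  e <- eigen(S, symmetric = TRUE)
  ev <- e$values
  if (any(ev < -tol * max(abs(ev), 1)))
    stop("matrix is not positive semi-definite")
  ev[ev < 0] <- 0
  e$vectors %*% (sqrt(ev) * t(e$vectors))
}

# Project a symmetric matrix onto the PSD cone by eigenvalue clipping.
psd_project <- function(S, floor_frac = 0) {
  S <- (S + t(S)) / 2
  e <- eigen(S, symmetric = TRUE)
  lo <- floor_frac * max(e$values, 0)
  ev <- pmax(e$values, lo)
  e$vectors %*% (ev * t(e$vectors))
}

is_symmetric_psd <- function(S, tol = 1e-8) {
  if (!isSymmetric(unname(S), tol = tol)) return(FALSE)
  ev <- eigen((S + t(S)) / 2, symmetric = TRUE, only.values = TRUE)$values
  all(ev > -tol * max(abs(ev), 1))
}

# Deterministic counter-based seed splitter: derived streams do not depend on
# execution order. Keeps results inside the 32-bit integer range.
derive_seed <- function(master, counter) {
  master <- as.double(master) %% 2147483647
  x <- (master * 48271 + as.double(counter) * 2654435 + 11) %% 2147483629
  as.integer(x) + 1L
}

# Draw from an inverse-Wishart with scale matrix Psi and df nu
# (mean Psi / (nu - k - 1) for nu > k + 1), via stats::rWishart.
riwish <- function(nu, Psi) {
  k <- nrow(Psi)
  if (nu <= k - 1) stop("inverse-Wishart df must exceed k - 1")
  W <- stats::rWishart(1, df = nu, Sigma = solve(Psi))[, , 1]
  S <- solve(W)
  (S + t(S)) / 2
}

# Tip-set lookup for every node of a phylo object: list indexed by node id
# (1..n are the tips themselves).
node_tip_sets <- function(tree) {
  n <- length(tree$tip.label)
  m <- tree$Nnode
  sets <- vector("list", n + m)
  for (i in seq_len(n)) sets[[i]] <- i
  # accumulate children into parents in reverse edge order (postorder-ish)
  edge <- tree$edge[order(tree$edge[, 1], decreasing = TRUE), , drop = FALSE]
  for (r in seq_len(nrow(edge))) {
    p <- edge[r, 1]; ch <- edge[r, 2]
    sets[[p]] <- c(sets[[p]], sets[[ch]])
  }
  lapply(sets, sort)
}

stopifnot_scalar <- function(x, name) {
  if (!(is.numeric(x) && length(x) == 1 && is.finite(x)))
    stop(sprintf("'%s' must be a finite numeric scalar", name), call. = FALSE)
}
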