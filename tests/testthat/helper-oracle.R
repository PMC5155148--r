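# From-first-principles MUSIC reference, independent of the package's SVD
# path: dense eigendecomposition of the window covariance G G^T and explicit
# projector matrices onto the signal / null subspaces. Used to cross-check
# run_musical() on single-window stacks. Requires K >= N so the retained
# basis is complete.
oracle_window_indicator <- function(M, psf, N_w, s, alpha, tau, eps = 1e-12) {
  N <- nrow(M)
  stopifnot(N == N_w^2, ncol(M) >= N)
  e <- eigen(tcrossprod(M), symmetric = TRUE)
  sv <- sqrt(pmax(e$values, 0))
  U <- e$vectors
  sig <- sv >= tau * sv[1]
  Us <- U[, sig, drop = FALSE]
  Ps <- Us %*% t(Us)
  Pn <- diag(N) - Ps
  h <- (N_w - 1) / 2
  wp <- window_pixels(c(h, h), N_w)
  Tn <- N_w * s
  vals <- matrix(0, Tn, Tn)
  for (j in seq_len(Tn)) {
    for (i in seq_len(Tn)) {
      tp <- c((i - 0.5) / s - 0.5, (j - 0.5) / s - 0.5)
      a <- sample_psf_vector(psf, tp, wp)
      dPR <- sqrt(sum((Ps %*% a)^2))
      dPN <- sqrt(sum((Pn %*% a)^2))
      vals[i, j] <- (dPR / max(dPN, eps))^alpha
    }
  }
  vals
}
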