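# Shared small fixtures and independent oracles for the test suite.

# tiny sample table on an arbitrary short grid
toy_table <- function(M, ids = NULL, class = "black") {
  n <- nrow(M)
  tibble::tibble(
    id = if (is.null(ids)) sprintf("s%02d", seq_len(n)) else ids,
    class = rep(class, length.out = n),
    fraction_black = 1, fraction_green = 0, fraction_red = 0,
    Al_g_kg = 2, Pb_mg_kg = 1, As_mg_kg = 0.1, Hg_mg_kg = 0,
    Cu_mg_kg = 15
  ) |>
    dplyr::bind_cols(stats::setNames(
      tibble::as_tibble(as.data.frame(M)), wl_colnames(seq_len(ncol(M)))))
}

# small default library shared by the slower integration tests
small_config <- function(seed = 7, n_total = 90L, ...) {
  generator_config(seed = seed, n_total = n_total, ...)
}

# independent NIPALS PLS1 (no residual standardization); oracle for the
# MPLS factor-1 weight comparison
pls1_oracle <- function(X, y, ncomp) {
  Xr <- scale(X, scale = FALSE); yr <- y - mean(y)
  W <- matrix(0, ncol(X), ncomp)
  for (k in seq_len(ncomp)) {
    w <- drop(crossprod(Xr, yr)); w <- w / sqrt(sum(w^2))
    t_k <- drop(Xr %*% w)
    p_k <- drop(crossprod(Xr, t_k)) / sum(t_k^2)
    q_k <- sum(yr * t_k) / sum(t_k^2)
    Xr <- Xr - tcrossprod(t_k, p_k)
    yr <- yr - q_k * t_k
    W[, k] <- w
  }
  W
}
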