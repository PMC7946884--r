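# Independent oracles and fixture builders used across the suite.

# Brute-force Pearson correlation from the textbook sum formula, written
# without cor() so it is independent of the implementation path it checks.
pearson_oracle <- function(x, y) {
  x <- x - sum(x) / length(x)
  y <- y - sum(y) / length(y)
  sum(x * y) / sqrt(sum(x^2) * sum(y^2))
}

abs_cor_matrix_oracle <- function(traces) {
  n <- nrow(traces)
  R <- diag(1, n)
  for (i in seq_len(n)) for (j in seq_len(n)) if (i != j)
    R[i, j] <- abs(pearson_oracle(traces[i, ], traces[j, ]))
  R
}

# singular values of a centered 2-column matrix via the eigenvalues of the
# 2x2 cross-product (closed form independent of svd())
singular_values_oracle <- function(X) {
  X <- sweep(X, 2, colMeans(X))
  M <- crossprod(X)
  tr <- M[1, 1] + M[2, 2]
  det2 <- M[1, 1] * M[2, 2] - M[1, 2]^2
  ev <- c((tr + sqrt(tr^2 - 4 * det2)) / 2, (tr - sqrt(tr^2 - 4 * det2)) / 2)
  sqrt(pmax(ev, 0))
}

# small hand-built shift table: per-residue delta_H trace across states with
# constant delta_N (so the SVD projection reduces to the centered 1H trace)
h_trace_table <- function(h_traces, states = c("apo", "s2", "s3", "s4"),
                          lw_H = 0.03, lw_N = 0.3) {
  recs <- do.call(rbind, lapply(seq_along(h_traces), function(i) {
    data.frame(residue_id = i, state = states,
               delta_H = 8 + h_traces[[i]], delta_N = 115,
               lw_H = lw_H, lw_N = lw_N, stringsAsFactors = FALSE)
  }))
  shift_table(recs, states = states)
}

# a chesca_matrix object built directly from a given |R| matrix (white-box
# input for the community aggregation contract)
make_chesca_matrix <- function(R, residues = seq_len(nrow(R)), cutoff = 0.98) {
  dimnames(R) <- list(residues, residues)
  structure(list(R = R, residues = as.integer(residues),
                 states = c("a", "b", "c", "d"), cutoff = cutoff,
                 traces = NULL, linearity = NULL),
            class = "chesca_matrix")
}

quiet_config <- function(...) {
  # near-noiseless study configuration used where exact network recovery is
  # asserted
  synthetic_shift_config(noise_sd_H = 0, noise_sd_N = 0, ...)
}
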