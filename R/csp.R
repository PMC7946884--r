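#' Combined amide chemical-shift perturbation
#'
#' Combines 1H and 15N shift changes into a single perturbation using the
#' standard amide weighting that compensates for the wider 15N dispersion:
#' `sqrt(dH^2 + (w * dN)^2)` with `w = 0.154`.
#'
#' @param dH,dN shift changes in the 1H and 15N dimensions (ppm); vectorized.
#' @param n_weight 15N weighting factor.
#' @return Combined CSP(s) in ppm (1H scale), >= 0.
#' @examples
#' combined_csp(0.1, 0.5)  # 0.1262...
#' @export
combined_csp <- function(dH, dN, n_weight = 0.154) {
  if (any(!is.finite(dH)) || any(!is.finite(dN)))
    stop("shift changes must be finite", call. = FALSE)
  sqrt(dH^2 + (n_weight * dN)^2)
}

#' Per-residue CSP profile between two ligation states
#'
#' Computes the combined CSP for every residue observed in both states and
#' flags significant responders. A residue is significant when its CSP exceeds
#' the profile mean plus `sd_multiplier` standard deviations; residues below
#' one SD are conventionally regarded as non-responding.
#'
#' @param table a [shift_table()].
#' @param state_a,state_b the two states compared (deltas are b minus a).
#' @param sd_multiplier significance multiplier on the profile SD.
#' @param n_weight 15N weighting factor passed to [combined_csp()].
#' @return Data frame with `residue_id`, `delta_dH`, `delta_dN`, `combined`,
#'   `significant`; attribute `threshold` records the cutoff used.
#' @export
csp_profile <- function(table, state_a, state_b, sd_multiplier = 1.0,
                        n_weight = 0.154) {
  stopifnot(inherits(table, "shift_table"))
  for (s in c(state_a, state_b))
    if (!s %in% shift_states(table))
      stop("unknown state label: ", s, call. = FALSE)
  res <- complete_residues(table, c(state_a, state_b))
  if (length(res) < 3L)
    stop("fewer than 3 residues complete in both states", call. = FALSE)

  a <- table[table$state == state_a & table$residue_id %in% res, ]
  b <- table[table$state == state_b & table$residue_id %in% res, ]
  a <- a[order(a$residue_id), ]; b <- b[order(b$residue_id), ]
  ddH <- b$delta_H - a$delta_H
  ddN <- b$delta_N - a$delta_N
  combined <- combined_csp(ddH, ddN, n_weight)
  threshold <- mean(combined) + sd_multiplier * stats::sd(combined)
  out <- data.frame(residue_id = a$residue_id,
                    delta_dH = ddH, delta_dN = ddN,
                    combined = combined,
                    significant = combined > threshold)
  attr(out, "threshold") <- threshold
  attr(out, "states") <- c(state_a, state_b)
  out
}
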