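#' Configuration for the multi-state synthetic shift generator
#'
#' The generator emulates the statistical structure that covariance-based
#' allostery analyses assume: a set of "networked" residues whose amide shifts
#' move linearly along a single latent open-to-closed coordinate lambda as the
#' kinase binds nucleotide and pseudo-substrate, plus non-networked residues
#' whose small state-to-state displacements are uncorrelated. Four ligation
#' states are modelled by default (apo, ADP-bound, ATPgN-bound, and the
#' ATPgN/PKI ternary complex), with lambda(apo) = 0 and lambda(ternary) = 1.
#'
#' @param n_residues number of residues (>= 2).
#' @param state_lambdas named numeric vector, state -> lambda in `[0, 1]`;
#'   names give the canonical state order.
#' @param networked_fraction fraction of residues on the allosteric network.
#' @param community_count number of communities used for the residue map.
#' @param response_scale_H,response_scale_N typical full-transition response
#'   amplitude (ppm) of a networked residue in each dimension.
#' @param nonnetworked_scale per-state displacement scale of non-networked
#'   residues, as a fraction of the response scale. Kept small so that
#'   non-responsive residues move well within their linewidths.
#' @param noise_sd_H,noise_sd_N measurement noise SD (ppm).
#' @param linewidth_H,linewidth_N linewidths Delta-nu recorded on every peak
#'   (ppm).
#' @param seed integer seed governing all draws.
#' @return A list of class `"synthetic_shift_config"`.
#' @export
synthetic_shift_config <- function(n_residues = 100L,
                                   state_lambdas = c(apo = 0, ADP = 0.45,
                                                     ATPgN = 0.55,
                                                     `ATPgN-PKI` = 1),
                                   networked_fraction = 0.6,
                                   community_count = 9L,
                                   response_scale_H = 0.15,
                                   response_scale_N = 0.8,
                                   nonnetworked_scale = 0.02,
                                   noise_sd_H = 0.005,
                                   noise_sd_N = 0.025,
                                   linewidth_H = 0.03,
                                   linewidth_N = 0.15,
                                   seed = 1L) {
  if (n_residues < 2L) stop("n_residues must be >= 2", call. = FALSE)
  if (any(state_lambdas < 0 | state_lambdas > 1))
    stop("state lambdas must lie in [0, 1]", call. = FALSE)
  if (is.null(names(state_lambdas)) || any(!nzchar(names(state_lambdas))))
    stop("state_lambdas must be a named vector", call. = FALSE)
  if (networked_fraction < 0 || networked_fraction > 1)
    stop("networked_fraction must lie in [0, 1]", call. = FALSE)
  if (noise_sd_H < 0 || noise_sd_N < 0)
    stop("noise SDs must be >= 0", call. = FALSE)
  structure(list(n_residues = as.integer(n_residues),
                 state_lambdas = state_lambdas,
                 networked_fraction = networked_fraction,
                 community_count = as.integer(community_count),
                 response_scale_H = response_scale_H,
                 response_scale_N = response_scale_N,
                 nonnetworked_scale = nonnetworked_scale,
                 noise_sd_H = noise_sd_H, noise_sd_N = noise_sd_N,
                 linewidth_H = linewidth_H, linewidth_N = linewidth_N,
                 seed = as.integer(seed)),
            class = "synthetic_shift_config")
}

#' Generate a ground-truth multi-state shift dataset
#'
#' Networked residue i in state s receives
#' `delta_i(s) = delta_i0 + a_i * lambda_s + eps`, with a residue-specific
#' response vector `a_i = (a_H, a_N)` and measurement noise
#' `eps ~ N(0, noise_sd)`. Before noise, every pair of networked residues is
#' therefore exactly collinear across states (|Pearson| = 1). Non-networked
#' residues instead receive independent per-state displacements of scale
#' `nonnetworked_scale * response_scale` (plus the same noise), so the
#' linewidth-based responsiveness filter is meaningfully exercised. All draws
#' derive from the single config seed, so outputs are byte-stable.
#'
#' @param config a [synthetic_shift_config()].
#' @param protein_id identifier for the generated table.
#' @return A list with elements `shifts` (a [shift_table()]), `communities`
#'   (a [community_map()]) and `truth` (generator ground truth: network
#'   membership, response vectors, lambdas, community assignment).
#' @examples
#' d <- generate_shift_dataset(synthetic_shift_config(n_residues = 20, seed = 7))
#' head(d$truth$network_members)
#' @export
generate_shift_dataset <- function(config, protein_id = "synthetic") {
  stopifnot(inherits(config, "synthetic_shift_config"))
  n <- config$n_residues
  lambdas <- config$state_lambdas
  states <- names(lambdas)
  n_states <- length(states)
  set.seed(config$seed)

  n_net <- round(n * config$networked_fraction)
  network_members <- sort(sample.int(n, n_net))
  is_net <- seq_len(n) %in% network_members

  community_labels <- c("ComA", "ComB", "ComC", "ComD", "ComE",
                        "ComF", "ComF1", "ComG", "ComH")
  community_labels <- community_labels[seq_len(min(config$community_count,
                                                   length(community_labels)))]
  communities <- sample(community_labels, n, replace = TRUE)

  # baseline amide positions in typical ppm ranges
  delta_H0 <- stats::runif(n, 7.0, 10.0)
  delta_N0 <- stats::runif(n, 105, 130)

  # response amplitudes: magnitude 0.5-1.5 x scale, random sign, never zero
  a_H <- stats::runif(n, 0.5, 1.5) * sample(c(-1, 1), n, replace = TRUE) *
    config$response_scale_H
  a_N <- stats::runif(n, 0.5, 1.5) * sample(c(-1, 1), n, replace = TRUE) *
    config$response_scale_N

  recs <- vector("list", n)
  for (i in seq_len(n)) {
    if (is_net[i]) {
      mu_H <- delta_H0[i] + a_H[i] * lambdas
      mu_N <- delta_N0[i] + a_N[i] * lambdas
    } else {
      mu_H <- delta_H0[i] + stats::rnorm(n_states, 0,
                config$nonnetworked_scale * config$response_scale_H)
      mu_N <- delta_N0[i] + stats::rnorm(n_states, 0,
                config$nonnetworked_scale * config$response_scale_N)
    }
    dH <- mu_H + stats::rnorm(n_states, 0, config$noise_sd_H)
    dN <- mu_N + stats::rnorm(n_states, 0, config$noise_sd_N)
    recs[[i]] <- data.frame(residue_id = i,
                            residue_label = paste0("X", i),
                            state = states,
                            delta_H = dH, delta_N = dN,
                            lw_H = config$linewidth_H,
                            lw_N = config$linewidth_N,
                            stringsAsFactors = FALSE)
  }
  table <- shift_table(do.call(rbind, recs), states = states,
                       protein_id = protein_id)
  map <- community_map(data.frame(residue_id = seq_len(n),
                                  community = communities,
                                  stringsAsFactors = FALSE))
  truth <- list(network_members = network_members,
                a_H = a_H, a_N = a_N,
                state_lambdas = lambdas,
                communities = communities,
                config = config)
  list(shifts = table, communities = map, truth = truth)
}

#' Simulate an ITC titration under the Wiseman model
#'
#' Per-injection normalized heats are computed from the analytic derivative of
#' the 1:1 binding isotherm ([wiseman_derivative()]) on a grid of molar ratios,
#' with optional additive Gaussian noise. The generating parameters are kept in
#' the result for recovery tests.
#'
#' @param kd dissociation constant (uM).
#' @param dH binding enthalpy (kcal/mol).
#' @param n_inject number of injections.
#' @param cell_conc total protein concentration in the cell (uM).
#' @param syringe_conc titrant concentration (uM); metadata only, the molar
#'   ratios are specified directly.
#' @param v0 cell volume factor multiplying the heats.
#' @param noise_sd additive heat noise SD (same units as the heats).
#' @param seed seed for the noise draw (ignored when `noise_sd = 0`).
#' @param rm_min,rm_max range of molar ratios covered by the titration.
#' @return An object of class `"itc_isotherm"`: list with `molar_ratio`,
#'   `heat`, `cell_conc`, `v0`, `temperature`, and `truth = list(kd, dH)`.
#' @export
generate_itc_isotherm <- function(kd, dH = -10, n_inject = 25L,
                                  cell_conc = 100, syringe_conc = NULL,
                                  v0 = 1, noise_sd = 0, seed = NULL,
                                  rm_min = 0.05, rm_max = 2.5) {
  if (kd <= 0) stop("kd must be > 0", call. = FALSE)
  if (cell_conc <= 0) stop("cell_conc must be > 0", call. = FALSE)
  rm <- seq(rm_min, rm_max, length.out = n_inject)
  r <- kd / cell_conc
  q <- wiseman_derivative(rm, r, dH, v0)
  if (noise_sd > 0) {
    if (!is.null(seed)) set.seed(seed)
    q <- q + stats::rnorm(n_inject, 0, noise_sd)
  }
  structure(list(molar_ratio = rm, heat = q, cell_conc = cell_conc,
                 syringe_conc = syringe_conc, v0 = v0, temperature = 300,
                 truth = list(kd = kd, dH = dH)),
            class = "itc_isotherm")
}

#' Simulate steady-state Michaelis--Menten velocities
#'
#' `v = Vmax * S / (KM + S) + eps`, `eps ~ N(0, noise_sd)`.
#'
#' @param vmax maximal velocity (uM/s).
#' @param km Michaelis constant (uM).
#' @param s_grid substrate concentrations (uM).
#' @param noise_sd velocity noise SD (uM/s).
#' @param seed seed for the noise draw.
#' @param enzyme_conc enzyme concentration (uM), carried as metadata for
#'   kcat computation.
#' @return Data frame of class `"velocity_dataset"` with columns
#'   `substrate_uM`, `velocity_uM_per_s`; attributes `enzyme_conc` and
#'   `truth = list(vmax, km)`.
#' @export
generate_mm_dataset <- function(vmax, km, s_grid, noise_sd = 0, seed = NULL,
                                enzyme_conc = NA_real_) {
  if (vmax <= 0 || km <= 0) stop("vmax and km must be > 0", call. = FALSE)
  if (length(s_grid) == 0L) stop("s_grid must be non-empty", call. = FALSE)
  v <- vmax * s_grid / (km + s_grid)
  if (noise_sd > 0) {
    if (!is.null(seed)) set.seed(seed)
    v <- v + stats::rnorm(length(s_grid), 0, noise_sd)
  }
  structure(data.frame(substrate_uM = s_grid, velocity_uM_per_s = v),
            enzyme_conc = enzyme_conc,
            truth = list(vmax = vmax, km = km),
            class = c("velocity_dataset", "data.frame"))
}
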