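# CONCISE: per-residue PCA over ligation states, pooled per-state score
# densities, mean PC positions along the open<->closed equilibrium, and the
# percent-closed -> free-energy mapping.

#' Per-residue PCA scores and per-state densities along the conformational
#' equilibrium
#'
#' Each residue's per-state (delta H, w * delta N) points are mean-centered and
#' projected onto their first principal direction ([project_trajectory()]).
#' Residues whose trajectory is not sufficiently linear (first-to-second
#' singular value ratio below `linearity_min`) are excluded: only residues that
#' respond linearly to the open-to-closed transition report on the global
#' equilibrium. Retained traces are standardized per residue (unit SD) so each
#' residue contributes equally, their axes are flipped to agree with the
#' consensus direction, and the global axis is oriented so the first (apo)
#' state sits at the minimum mean score. The pooled scores of each state are
#' summarized by a maximum-likelihood Gaussian (sample mean and SD); the mean
#' is the state's position `<PC>` on the equilibrium coordinate.
#'
#' @param table a [shift_table()].
#' @param states ordered analyzed states (first = open reference, last =
#'   closed reference); default: all states of the table.
#' @param residues optional residue subset (default: all complete residues).
#' @param linearity_min minimal singular-value ratio for admission.
#' @param n_weight 15N scaling applied before PCA.
#' @return Object of class `"concise_result"`: `residues_used`, `scores`
#'   (residues x states matrix of oriented standardized PC scores),
#'   `density` (data frame `state`, `mean`, `sd`), `mean_pc` (named vector),
#'   `states`.
#' @export
concise_scores <- function(table, states = NULL, residues = NULL,
                           linearity_min = 3.0, n_weight = 0.154) {
  stopifnot(inherits(table, "shift_table"))
  if (is.null(states)) states <- shift_states(table)
  if (length(states) < 3L)
    stop("at least 3 states are required", call. = FALSE)
  complete <- complete_residues(table, states)
  residues <- if (is.null(residues)) complete
              else sort(intersect(as.integer(residues), complete))
  if (length(residues) < 1L)
    stop("no residues complete across the requested states", call. = FALSE)

  arr <- shift_array(table, residues, states)
  traces <- matrix(NA_real_, length(residues), length(states),
                   dimnames = list(residues, states))
  keep <- logical(length(residues))
  for (i in seq_along(residues)) {
    pr <- project_trajectory(cbind(arr$H[i, ], arr$N[i, ]), n_weight)
    s <- stats::sd(pr$trace)
    if (pr$linearity >= linearity_min && s > 0) {
      traces[i, ] <- pr$trace / s
      keep[i] <- TRUE
    }
  }
  if (!any(keep))
    stop("all residues rejected by the linearity filter (min ratio ",
         linearity_min, ")", call. = FALSE)
  traces <- traces[keep, , drop = FALSE]
  used <- residues[keep]

  # two-pass consensus orientation: first orient each residue so its last
  # state scores above its first, then re-flip against the consensus trace
  for (i in seq_len(nrow(traces)))
    if (traces[i, length(states)] < traces[i, 1]) traces[i, ] <- -traces[i, ]
  consensus <- colMeans(traces)
  for (i in seq_len(nrow(traces))) {
    cc <- stats::cor(traces[i, ], consensus)
    if (is.finite(cc) && cc < 0) traces[i, ] <- -traces[i, ]
  }

  mean_pc <- colMeans(traces)
  if (mean_pc[1] > mean_pc[length(states)]) {
    traces <- -traces
    mean_pc <- -mean_pc
  }
  sd_pc <- apply(traces, 2, stats::sd)
  if (nrow(traces) == 1L) sd_pc[] <- 0

  structure(list(residues_used = used,
                 scores = traces,
                 density = data.frame(state = states, mean = mean_pc,
                                      sd = sd_pc, row.names = NULL),
                 mean_pc = stats::setNames(as.numeric(mean_pc), states),
                 states = states),
            class = "concise_result")
}

#' @export
print.concise_result <- function(x, ...) {
  cat(sprintf("CONCISE result: %d residues, states %s\n",
              length(x$residues_used), paste(x$states, collapse = " -> ")))
  print(round(x$mean_pc, 3))
  invisible(x)
}

#' Community-resolved CONCISE analysis
#'
#' Runs an independent CONCISE analysis restricted to each community's
#' residues, revealing whether individual structural/functional communities
#' track the global equilibrium or lag behind it. Communities with fewer than
#' `min_residues` usable residues are reported as `NULL` with a warning.
#'
#' @param table a [shift_table()].
#' @param map a [community_map()].
#' @inheritParams concise_scores
#' @param min_residues minimal community size for a defined result.
#' @return Named list of [concise_scores()] results (or `NULL`), one per
#'   community, with a `summary` attribute (data frame community x state of
#'   mean PC values).
#' @export
community_concise <- function(table, map, states = NULL, linearity_min = 3.0,
                              n_weight = 0.154, min_residues = 3L) {
  stopifnot(inherits(table, "shift_table"), inherits(map, "community_map"))
  if (is.null(states)) states <- shift_states(table)
  labels <- sort(unique(map$community))
  out <- stats::setNames(vector("list", length(labels)), labels)
  for (l in labels) {
    members <- map$residue_id[map$community == l]
    usable <- intersect(members, complete_residues(table, states))
    if (length(usable) < min_residues) {
      warning("community ", l, " has fewer than ", min_residues,
              " usable residues; result undefined", call. = FALSE)
      next
    }
    out[[l]] <- tryCatch(
      concise_scores(table, states = states, residues = usable,
                     linearity_min = linearity_min, n_weight = n_weight),
      error = function(e) {
        warning("community ", l, ": ", conditionMessage(e), call. = FALSE)
        NULL
      })
  }
  summ <- do.call(rbind, lapply(labels, function(l) {
    mp <- if (is.null(out[[l]])) rep(NA_real_, length(states))
          else out[[l]]$mean_pc
    data.frame(community = l, state = states, mean_pc = as.numeric(mp),
               row.names = NULL)
  }))
  attr(out, "summary") <- summ
  out
}

#' Map mean PC positions to percent closed
#'
#' Linear interpolation between an open and a closed reference state:
#' `100 * (<PC>_s - <PC>_open) / (<PC>_closed - <PC>_open)`. Values outside
#' `[0, 100]` are allowed (a state can sit beyond a reference) and flagged.
#'
#' @param mean_pc named numeric vector of state positions (e.g.
#'   `result$mean_pc`).
#' @param open_ref,closed_ref names of the reference states (0% and 100%
#'   closed).
#' @return Named numeric vector of percent-closed values with attribute
#'   `outside` flagging states outside `[0, 100]`.
#' @export
percent_closed <- function(mean_pc, open_ref, closed_ref) {
  if (open_ref == closed_ref)
    stop("open and closed references must differ", call. = FALSE)
  if (!all(c(open_ref, closed_ref) %in% names(mean_pc)))
    stop("reference state(s) not found in mean_pc", call. = FALSE)
  span <- mean_pc[[closed_ref]] - mean_pc[[open_ref]]
  if (span == 0)
    stop("degenerate references: equal <PC> positions", call. = FALSE)
  pct <- 100 * (mean_pc - mean_pc[[open_ref]]) / span
  attr(pct, "outside") <- names(pct)[pct < 0 | pct > 100]
  pct
}

#' Free energy change from extent of closure
#'
#' Affine map anchored on two reference points: an open anchor (0% closed,
#' `ddg_open`, conventionally 0) and a closed anchor (100% closed,
#' `ddg_closed`). With the calorimetric reference of the wild-type kinase,
#' the closed anchor is -15 kcal/mol -- the summed binding free energies of
#' the nucleotide and pseudo-substrate steps at 300 K.
#'
#' @param pct percent closed (vectorized).
#' @param ddg_closed free energy at 100% closed (kcal/mol).
#' @param ddg_open free energy at 0% closed (kcal/mol).
#' @return Free energy change(s), kcal/mol.
#' @export
ddg_from_closure <- function(pct, ddg_closed = -15, ddg_open = 0) {
  if (ddg_closed == ddg_open)
    stop("anchors must be distinct", call. = FALSE)
  ddg_open + pct / 100 * (ddg_closed - ddg_open)
}

#' Percent-closed / free-energy table for a CONCISE result
#'
#' Combines [percent_closed()] and [ddg_from_closure()] and propagates the
#' per-state density SD into uncertainties on both quantities.
#'
#' @param result a [concise_scores()] result.
#' @param open_ref,closed_ref reference states; default first and last state.
#' @param ddg_closed,ddg_open free-energy anchors (kcal/mol).
#' @return Data frame `state`, `mean_pc`, `pct_closed`, `pct_sd`, `ddg`,
#'   `ddg_sd`, `outside`.
#' @export
concise_free_energy <- function(result, open_ref = NULL, closed_ref = NULL,
                                ddg_closed = -15, ddg_open = 0) {
  stopifnot(inherits(result, "concise_result"))
  states <- result$states
  if (is.null(open_ref)) open_ref <- states[1]
  if (is.null(closed_ref)) closed_ref <- states[length(states)]
  pct <- percent_closed(result$mean_pc, open_ref, closed_ref)
  span <- abs(result$mean_pc[[closed_ref]] - result$mean_pc[[open_ref]])
  pct_sd <- 100 * result$density$sd / span
  ddg <- ddg_from_closure(as.numeric(pct), ddg_closed, ddg_open)
  ddg_sd <- pct_sd / 100 * abs(ddg_closed - ddg_open)
  data.frame(state = states,
             mean_pc = as.numeric(result$mean_pc),
             pct_closed = as.numeric(pct),
             pct_sd = pct_sd,
             ddg = ddg,
             ddg_sd = ddg_sd,
             outside = states %in% attr(pct, "outside"),
             row.names = NULL)
}
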