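# Chemical-shift covariance analysis (CHESCA): linewidth-based residue
# filtering, SVD projection of per-residue multi-state trajectories, the
# |Pearson| correlation matrix, per-residue correlation scores, agglomerative
# clustering, and community-level correlation scores.

# residues x states array of shifts for the residues complete across `states`
shift_array <- function(table, residues, states) {
  sub <- table[table$residue_id %in% residues & table$state %in% states, ]
  H <- matrix(NA_real_, length(residues), length(states),
              dimnames = list(residues, states))
  N <- H; lwH <- H; lwN <- H
  idx_r <- match(sub$residue_id, residues)
  idx_s <- match(sub$state, states)
  H[cbind(idx_r, idx_s)] <- sub$delta_H
  N[cbind(idx_r, idx_s)] <- sub$delta_N
  lwH[cbind(idx_r, idx_s)] <- sub$lw_H
  lwN[cbind(idx_r, idx_s)] <- sub$lw_N
  list(H = H, N = N, lw_H = lwH, lw_N = lwN)
}

#' Filter residues whose shift changes exceed their linewidths
#'
#' A residue enters covariance analysis only if, for at least one pair of
#' states (A, B) and at least one dimension (1H or 15N), its shift change
#' between the two states exceeds the mean of its two linewidths in that
#' dimension: `|delta(A) - delta(B)| > (lw_A + lw_B) / 2`. There is no
#' requirement on which pair of states satisfies the inequality. Residues
#' whose motion stays within their linewidths carry no resolvable state
#' dependence and would only add noise to the correlation matrix.
#'
#' @param table a [shift_table()] whose records carry linewidths (`lw_H`,
#'   `lw_N`); missing linewidths fall back to `default_lw_H` / `default_lw_N`
#'   with a warning.
#' @param states the analyzed states (default: all states of the table).
#' @param default_lw_H,default_lw_N fallback linewidths (ppm); set to `NULL`
#'   to make missing linewidths an error.
#' @return Sorted integer vector of retained residue ids.
#' @export
filter_responsive_residues <- function(table, states = NULL,
                                       default_lw_H = 0.03,
                                       default_lw_N = 0.3) {
  stopifnot(inherits(table, "shift_table"))
  if (is.null(states)) states <- shift_states(table)
  residues <- complete_residues(table, states)
  if (length(residues) == 0L) return(integer(0))
  arr <- shift_array(table, residues, states)

  if (anyNA(arr$lw_H) || anyNA(arr$lw_N)) {
    if (is.null(default_lw_H) || is.null(default_lw_N))
      stop("linewidths are missing and no defaults are configured",
           call. = FALSE)
    warning("missing linewidths replaced by defaults (",
            default_lw_H, " ppm 1H, ", default_lw_N, " ppm 15N)",
            call. = FALSE)
    arr$lw_H[is.na(arr$lw_H)] <- default_lw_H
    arr$lw_N[is.na(arr$lw_N)] <- default_lw_N
  }

  pairs <- utils::combn(length(states), 2)
  keep <- vapply(seq_along(residues), function(i) {
    for (p in seq_len(ncol(pairs))) {
      a <- pairs[1, p]; b <- pairs[2, p]
      if (abs(arr$H[i, a] - arr$H[i, b]) >
          (arr$lw_H[i, a] + arr$lw_H[i, b]) / 2) return(TRUE)
      if (abs(arr$N[i, a] - arr$N[i, b]) >
          (arr$lw_N[i, a] + arr$lw_N[i, b]) / 2) return(TRUE)
    }
    FALSE
  }, logical(1))
  residues[keep]
}

#' Project a residue's multi-state trajectory onto its principal direction
#'
#' The per-state (delta H, w * delta N) points are mean-centered and projected
#' onto the first right singular vector, yielding a one-dimensional trace (one
#' value per state) that summarizes the residue's response. The ratio of the
#' first to the second singular value measures how linear the trajectory is
#' (`Inf` for perfectly collinear points).
#'
#' @param points numeric matrix, states x 2, columns (delta_H, delta_N) in ppm.
#' @param n_weight 15N scaling applied before projection.
#' @return List of class `"residue_trajectory"`: `trace` (one value per
#'   state), `linearity` (s1/s2), `singular_values`, `direction`.
#' @export
project_trajectory <- function(points, n_weight = 0.154) {
  points <- as.matrix(points)
  if (nrow(points) < 3L)
    stop("at least 3 states are required to project a trajectory",
         call. = FALSE)
  X <- cbind(points[, 1], n_weight * points[, 2])
  X <- sweep(X, 2, colMeans(X))
  sv <- svd(X)
  linearity <- if (sv$d[2] < .Machine$double.eps * max(sv$d[1], 1)) Inf
               else sv$d[1] / sv$d[2]
  structure(list(trace = as.numeric(X %*% sv$v[, 1]),
                 linearity = linearity,
                 singular_values = sv$d,
                 direction = sv$v[, 1]),
            class = "residue_trajectory")
}

#' Inter-residue |Pearson| correlation matrix
#'
#' For every pair of residues, computes the absolute Pearson correlation
#' between their one-dimensional SVD-projected traces across the ligation
#' states ([project_trajectory()]). Allosterically coupled residues respond
#' collinearly to the perturbation series and show |R| near 1. Correlations
#' may alternatively be computed on the raw 1H or 15N traces.
#'
#' @param table a [shift_table()].
#' @param residues residues to include (e.g. from
#'   [filter_responsive_residues()]); default: all complete residues.
#' @param states analyzed states (>= 4 recommended; >= 3 required).
#' @param cutoff correlation cutoff stored with the matrix (default 0.98).
#' @param combine `"svd"` (projected trace, default), `"H"` or `"N"`.
#' @param n_weight 15N scaling for the projection.
#' @return Object of class `"chesca_matrix"`: list with `R` (symmetric
#'   residues x residues matrix of |Pearson| values, unit diagonal),
#'   `residues`, `states`, `cutoff`, `traces` (residues x states),
#'   `linearity`.
#' @export
correlation_matrix <- function(table, residues = NULL, states = NULL,
                               cutoff = 0.98, combine = c("svd", "H", "N"),
                               n_weight = 0.154) {
  stopifnot(inherits(table, "shift_table"))
  combine <- match.arg(combine)
  if (is.null(states)) states <- shift_states(table)
  if (length(states) < 3L)
    stop("at least 3 states are required", call. = FALSE)
  complete <- complete_residues(table, states)
  residues <- if (is.null(residues)) complete
              else sort(intersect(as.integer(residues), complete))
  if (length(residues) < 2L)
    stop("at least 2 residues are required", call. = FALSE)

  arr <- shift_array(table, residues, states)
  traces <- matrix(NA_real_, length(residues), length(states),
                   dimnames = list(residues, states))
  linearity <- stats::setNames(numeric(length(residues)), residues)
  for (i in seq_along(residues)) {
    pr <- project_trajectory(cbind(arr$H[i, ], arr$N[i, ]), n_weight)
    traces[i, ] <- switch(combine,
                          svd = pr$trace,
                          H = arr$H[i, ] - mean(arr$H[i, ]),
                          N = arr$N[i, ] - mean(arr$N[i, ]))
    linearity[i] <- pr$linearity
  }

  sds <- apply(traces, 1, stats::sd)
  degenerate <- sds == 0 | !is.finite(sds)
  if (any(degenerate)) {
    warning("residue(s) with zero-variance trace dropped: ",
            paste(residues[degenerate], collapse = ", "), call. = FALSE)
    traces <- traces[!degenerate, , drop = FALSE]
    residues <- residues[!degenerate]
    linearity <- linearity[!degenerate]
  }
  if (length(residues) < 2L)
    stop("fewer than 2 residues with non-degenerate traces", call. = FALSE)

  R <- abs(stats::cor(t(traces)))
  diag(R) <- 1
  dimnames(R) <- list(residues, residues)
  structure(list(R = R, residues = residues, states = states,
                 cutoff = cutoff, traces = traces, linearity = linearity),
            class = "chesca_matrix")
}

#' @export
print.chesca_matrix <- function(x, ...) {
  n_above <- sum(x$R[upper.tri(x$R)] > x$cutoff)
  cat(sprintf("CHESCA matrix: %d residues, %d states, %d pairs with |R| > %.2f\n",
              length(x$residues), length(x$states), n_above, x$cutoff))
  invisible(x)
}

#' Per-residue correlation scores
#'
#' For each residue, counts the partners correlated above the cutoff
#' (excluding itself) and divides by a fixed denominator -- conventionally the
#' total number of residues in the protein (350 for the kinase catalytic
#' subunit), so that scores are comparable across constructs.
#'
#' @param matrix a `"chesca_matrix"`.
#' @param denominator total residue count used as the normalizer; defaults to
#'   the number of residues in the matrix.
#' @param cutoff correlation cutoff; defaults to the matrix's own.
#' @return Data frame `residue_id`, `n_partners`, `score`.
#' @export
correlation_scores <- function(matrix, denominator = NULL, cutoff = NULL) {
  stopifnot(inherits(matrix, "chesca_matrix"))
  if (is.null(cutoff)) cutoff <- matrix$cutoff
  if (is.null(denominator)) denominator <- length(matrix$residues)
  if (denominator <= 0) stop("denominator must be > 0", call. = FALSE)
  R <- matrix$R
  diag(R) <- 0
  n_partners <- rowSums(R > cutoff)
  data.frame(residue_id = matrix$residues,
             n_partners = as.integer(n_partners),
             score = n_partners / denominator)
}

#' Agglomerative clustering of the correlation matrix
#'
#' Hierarchical clustering on the dissimilarity `1 - |R|`, cut at a height
#' threshold; only clusters of two or more residues constitute networks.
#'
#' @param matrix a `"chesca_matrix"`.
#' @param linkage `"average"` or `"complete"`.
#' @param threshold dissimilarity cut height (default `1 - cutoff`).
#' @return List with `assignment` (named integer vector, residue -> cluster; 0
#'   marks singletons) and `clusters` (list of residue-id vectors, size >= 2).
#' @export
cluster_residues <- function(matrix, linkage = c("average", "complete"),
                             threshold = NULL) {
  stopifnot(inherits(matrix, "chesca_matrix"))
  linkage <- match.arg(linkage)
  if (is.null(threshold)) threshold <- 1 - matrix$cutoff
  d <- stats::as.dist(1 - matrix$R)
  hc <- stats::hclust(d, method = linkage)
  cut <- stats::cutree(hc, h = threshold)
  sizes <- table(cut)
  keep <- as.integer(names(sizes)[sizes >= 2])
  clusters <- lapply(keep, function(k) matrix$residues[cut == k])
  assignment <- ifelse(cut %in% keep, match(cut, keep), 0L)
  names(assignment) <- matrix$residues
  list(assignment = assignment, clusters = clusters)
}

#' Community-level correlation scores
#'
#' Aggregates the residue-pair correlation matrix over predefined functional
#' communities. For communities X != Y with `n_X` and `n_Y` scored residues,
#' `R_XY = #\{(i in X, j in Y): R_ij > cutoff\} / (n_X * n_Y)`; the diagonal
#' uses unordered distinct pairs within the community, normalized by
#' `n_X * (n_X - 1) / 2`. Residues absent from the map (or filtered out
#' upstream) contribute neither to the counts nor to the `n`s; communities
#' left without scored residues are reported as `NA`, not 0.
#'
#' @param matrix a `"chesca_matrix"`.
#' @param map a [community_map()].
#' @param r_cutoff correlation cutoff (default 0.8, lower than the
#'   residue-level 0.98 so that sparser inter-community coupling is resolved).
#' @return Object of class `"community_matrix"`: list with `R_XY` (symmetric
#'   communities x communities matrix), `n` (scored residues per community),
#'   `r_cutoff`.
#' @export
community_correlation <- function(matrix, map, r_cutoff = 0.8) {
  stopifnot(inherits(matrix, "chesca_matrix"), inherits(map, "community_map"))
  comm_of <- stats::setNames(map$community, map$residue_id)
  scored <- matrix$residues[as.character(matrix$residues) %in% names(comm_of)]
  labels <- sort(unique(map$community))
  n <- vapply(labels, function(l)
    sum(comm_of[as.character(scored)] == l), integer(1))
  names(n) <- labels

  R_XY <- matrix(NA_real_, length(labels), length(labels),
                 dimnames = list(labels, labels))
  adj <- matrix$R > r_cutoff
  diag(adj) <- FALSE
  idx <- match(matrix$residues, scored)  # NA for unmapped residues
  for (xi in seq_along(labels)) {
    in_x <- which(!is.na(idx) &
                    comm_of[as.character(matrix$residues)] == labels[xi])
    for (yi in xi:length(labels)) {
      in_y <- which(!is.na(idx) &
                      comm_of[as.character(matrix$residues)] == labels[yi])
      if (xi == yi) {
        if (n[xi] >= 2) {
          cnt <- sum(adj[in_x, in_x, drop = FALSE]) / 2
          R_XY[xi, xi] <- cnt / (n[xi] * (n[xi] - 1) / 2)
        }
      } else if (n[xi] >= 1 && n[yi] >= 1) {
        cnt <- sum(adj[in_x, in_y, drop = FALSE])
        R_XY[xi, yi] <- R_XY[yi, xi] <- cnt / (n[xi] * n[yi])
      }
    }
  }
  structure(list(R_XY = R_XY, n = n, r_cutoff = r_cutoff),
            class = "community_matrix")
}

#' @export
print.community_matrix <- function(x, ...) {
  cat(sprintf("Community CHESCA matrix (%d communities, cutoff %.2f)\n",
              length(x$n), x$r_cutoff))
  print(round(x$R_XY, 3))
  invisible(x)
}
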