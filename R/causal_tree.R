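#' Parameters of the honest causal forest
#'
#' @param n_trees number of honest trees.
#' @param min_leaf minimum treated AND control count required in each leaf,
#'   enforced on both the split half and the estimation half.
#' @param mtry covariates drawn per node; default
#'   `min(ceiling(sqrt(p)) + 20, p)` (the reference-software convention,
#'   which keeps low-cardinality indicator covariates in contention at
#'   every node when p is modest).
#' @param max_depth depth cap (root = depth 1); unlimited by default.
#' @param sample_frac fraction of records subsampled per tree (without
#'   replacement by default, the honest-forest convention).
#' @param replace subsample with replacement instead (fidelity mode for
#'   bootstrap-style forests).
#' @param nuisance_trees trees used for each nuisance regression forest.
#' @param gain_tol relative split-gain improvement below which a node stops
#'   splitting.
#' @return a `forest_params` list.
#' @export
forest_params <- function(n_trees = 200L, min_leaf = 5L, mtry = NULL,
                          max_depth = Inf, sample_frac = 0.5, replace = FALSE,
                          nuisance_trees = 200L, gain_tol = 1e-10) {
  stopifnot(n_trees >= 1, min_leaf >= 1, sample_frac > 0, sample_frac <= 1)
  structure(list(n_trees = as.integer(n_trees), min_leaf = as.integer(min_leaf),
                 mtry = mtry, max_depth = max_depth, sample_frac = sample_frac,
                 replace = replace, nuisance_trees = as.integer(nuisance_trees),
                 gain_tol = gain_tol),
            class = "forest_params")
}

#' Leaf-local orthogonalized treatment-effect estimate
#'
#' The residual-on-residual ratio over an index set \eqn{N}:
#' \deqn{\hat\tau = \frac{\sum_{i \in N} (W_i - \hat p_i)(Y_i - \hat m_i)}
#'                      {\sum_{i \in N} (W_i - \hat p_i)^2}}
#' the building block of every leaf and forest-level effect estimate.
#'
#' @param residuals list with `y_res`, `w_res` (see [orthogonalize()]).
#' @param index_set integer indices of the records in the neighborhood.
#' @return the scalar local effect estimate.
#' @export
local_tau <- function(residuals, index_set) {
  if (!length(index_set)) stop("index set is empty", call. = FALSE)
  wr <- residuals$w_res[index_set]
  denom <- sum(wr^2)
  if (denom <= 0) stop("all treatment residuals are zero: effect undefined", call. = FALSE)
  sum(wr * residuals$y_res[index_set]) / denom
}

#' Heterogeneity gain of a candidate split
#'
#' Scores a split of a node into children L and R by
#' \eqn{n_L \hat\tau_L^2 + n_R \hat\tau_R^2}: splits that separate records
#' with different local effects score higher. Per-arm minimum-count
#' admissibility is the caller's responsibility (inadmissible candidates
#' are rejected, not errors).
#'
#' @param residuals list with `y_res`, `w_res`.
#' @param left_set,right_set disjoint index sets of the two children.
#' @return the scalar gain.
#' @export
split_gain <- function(residuals, left_set, right_set) {
  length(left_set) * local_tau(residuals, left_set)^2 +
    length(right_set) * local_tau(residuals, right_set)^2
}

# vectorized best-split search over mtry covariates at one node.
# S: split-half indices; E_t/E_c: estimation-half indices by arm.
find_best_split <- function(X, residuals, W, S, E_t, E_c, params) {
  p <- ncol(X)
  mtry <- if (is.null(params$mtry)) min(ceiling(sqrt(p)) + 20L, p) else min(params$mtry, p)
  vars <- sample.int(p, mtry)
  wr_all <- residuals$w_res
  yr_all <- residuals$y_res
  nS <- length(S)
  tS <- sum(W[S])
  best <- NULL
  for (v in vars) {
    xs <- X[S, v]
    ord <- order(xs)
    xo <- xs[ord]
    cuts <- which(xo[-nS] < xo[-1])            # positions where the value changes
    if (!length(cuts)) next
    thresholds <- (xo[cuts] + xo[cuts + 1]) / 2
    wr <- wr_all[S][ord]; yr <- yr_all[S][ord]; tr <- W[S][ord]
    cw2 <- cumsum(wr^2); cwy <- cumsum(wr * yr); ct <- cumsum(tr)
    nL <- cuts; nR <- nS - cuts
    tL <- ct[cuts]; cL <- nL - tL; tR <- tS - tL; cR <- nR - tR
    d2L <- cw2[cuts]; d2R <- cw2[nS] - d2L
    ok <- tL >= params$min_leaf & cL >= params$min_leaf &
          tR >= params$min_leaf & cR >= params$min_leaf & d2L > 0 & d2R > 0
    if (length(E_t)) {
      et <- sort(X[E_t, v])
      eLt <- findInterval(thresholds, et)
      ok <- ok & eLt >= params$min_leaf & (length(et) - eLt) >= params$min_leaf
    } else ok <- ok & FALSE
    if (length(E_c)) {
      ec <- sort(X[E_c, v])
      eLc <- findInterval(thresholds, ec)
      ok <- ok & eLc >= params$min_leaf & (length(ec) - eLc) >= params$min_leaf
    } else ok <- ok & FALSE
    if (!any(ok)) next
    tauL <- cwy[cuts] / d2L
    tauR <- (cwy[nS] - cwy[cuts]) / d2R
    gain <- nL * tauL^2 + nR * tauR^2
    gain[!ok] <- -Inf
    j <- which.max(gain)
    if (is.null(best) || gain[j] > best$gain) {
      best <- list(var = v, threshold = thresholds[j], gain = gain[j])
    }
  }
  best
}

#' Grow one honest causal tree
#'
#' Splits are chosen greedily on the split half of the subsample by the
#' heterogeneity gain of [split_gain()] over `mtry` randomly drawn
#' covariates per node (candidate thresholds are midpoints of sorted
#' unique values); leaf effects are computed by [local_tau()] on the
#' estimation half only. This "honesty" separation means the records that
#' shape the tree never contribute to its effect estimates. Recursion
#' stops when no admissible split improves the gain beyond a relative
#' tolerance, or at the depth cap.
#'
#' @param X numeric covariate matrix for the full training sample.
#' @param residuals list with `y_res`, `w_res` for the full sample.
#' @param W 0/1 treatment vector (for per-arm leaf-size admissibility).
#' @param subsample integer indices of this tree's subsample.
#' @param params a [forest_params()].
#' @param seed RNG seed (honest-half draw and per-node mtry draws).
#' @return object of class `causal_tree`: `nodes` (list; internal nodes
#'   carry `var`, `threshold`, `left`, `right`; leaves carry the global
#'   estimation index set `est_idx`, `tau`, and the leaf sums used by the
#'   forest aggregation), `split_idx`, `est_idx`.
#' @export
grow_causal_tree <- function(X, residuals, W, subsample, params, seed = 1L) {
  set.seed(seed)
  if (length(unique(W[subsample])) < 2) {
    stop("subsample lacks one treatment arm", call. = FALSE)
  }
  m <- length(subsample)
  if (m < 4 * params$min_leaf) stop("subsample too small for honest halves", call. = FALSE)
  perm <- sample(subsample, m)
  half <- floor(m / 2)
  split_idx <- perm[seq_len(half)]
  est_idx <- perm[(half + 1):m]

  nodes <- list()
  add_node <- function(node) { nodes[[length(nodes) + 1L]] <<- node; length(nodes) }

  make_leaf <- function(E, depth) {
    wr <- residuals$w_res[E]
    s2 <- sum(wr^2)
    tau <- if (length(E) && s2 > 0) sum(wr * residuals$y_res[E]) / s2 else NA_real_
    add_node(list(leaf = TRUE, depth = depth, est_idx = E, tau = tau,
                  n_est = length(E),
                  s1 = if (length(E)) sum(wr * residuals$y_res[E]) / length(E) else 0,
                  s2 = if (length(E)) s2 / length(E) else 0))
  }

  build <- function(S, E, depth) {
    if (depth >= params$max_depth || length(S) < 2) return(make_leaf(E, depth))
    wrS <- residuals$w_res[S]
    d2 <- sum(wrS^2)
    if (d2 <= 0) return(make_leaf(E, depth))
    tau_parent <- sum(wrS * residuals$y_res[S]) / d2
    parent_gain <- length(S) * tau_parent^2
    best <- find_best_split(X, residuals, W, S,
                            E[W[E] == 1], E[W[E] == 0], params)
    if (is.null(best) ||
        (best$gain - parent_gain) <= params$gain_tol * max(abs(parent_gain), 1)) {
      return(make_leaf(E, depth))
    }
    id <- add_node(list(leaf = FALSE, depth = depth, var = best$var,
                        threshold = best$threshold, left = NA_integer_,
                        right = NA_integer_))
    goes_left_S <- X[S, best$var] <= best$threshold
    goes_left_E <- X[E, best$var] <= best$threshold
    left <- build(S[goes_left_S], E[goes_left_E], depth + 1)
    right <- build(S[!goes_left_S], E[!goes_left_E], depth + 1)
    nodes[[id]]$left <<- left
    nodes[[id]]$right <<- right
    id
  }

  root <- build(split_idx, est_idx, 1L)
  structure(list(nodes = nodes, root = root,
                 split_idx = sort(split_idx), est_idx = sort(est_idx)),
            class = "causal_tree")
}

# leaf node index in `tree` for each row of Xq
tree_leaf_ids <- function(tree, Xq) {
  out <- integer(nrow(Xq))
  assign_rows <- function(id, rows) {
    node <- tree$nodes[[id]]
    if (isTRUE(node$leaf)) { out[rows] <<- id; return(invisible()) }
    left <- Xq[rows, node$var] <= node$threshold
    if (any(left)) assign_rows(node$left, rows[left])
    if (any(!left)) assign_rows(node$right, rows[!left])
  }
  if (nrow(Xq)) assign_rows(tree$root, seq_len(nrow(Xq)))
  out
}

# structural skeleton (split variables/thresholds only), for honesty audits
tree_structure <- function(tree) {
  lapply(tree$nodes, function(n) {
    if (isTRUE(n$leaf)) list(leaf = TRUE, depth = n$depth)
    else list(leaf = FALSE, depth = n$depth, var = n$var, threshold = n$threshold,
              left = n$left, right = n$right)
  })
}
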