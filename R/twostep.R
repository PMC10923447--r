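# Two-step cluster analysis for continuous features: log-likelihood
# distance between clusters, agglomeration from singletons, BIC trace over
# candidate cluster counts, and the two-stage automatic choice of k.
#
# The tightness of cluster v is
#   xi_v = -N_v * sum_k 0.5 * log(sigma2_k + sigma2_vk)
# with N_v the cluster size, sigma2_vk the within-cluster biased variance
# of feature k, and sigma2_k the whole-dataset biased variance of feature
# k acting as a regularizer that keeps the log finite for singletons.
# The distance between clusters j and s is
#   d(j, s) = xi_j + xi_s - xi_{j union s},
# and BIC(J) = -2 * sum_j xi_j + m_J log n with m_J = 2 * p * J free
# parameters (a mean and a variance per feature per cluster).

#' Standardize a feature matrix
#'
#' Centers each column to mean 0 and scales to sd 1, storing the
#' transform so cluster summaries can be reported on the original scale.
#'
#' @param x numeric matrix (n x p), complete cases.
#' @return Matrix with attributes `center` and `scale`.
#' @export
ts_standardize <- function(x) {
  x <- as.matrix(x)
  if (nrow(x) < 2) stop_bad("standardization needs n >= 2")
  if (anyNA(x)) stop_bad("feature matrix must be complete-case")
  ctr <- colMeans(x)
  scl <- apply(x, 2, sd)
  if (any(scl <= 0)) stop_bad("zero-variance feature: ",
                              paste(colnames(x)[scl <= 0], collapse = ", "))
  out <- sweep(sweep(x, 2, ctr), 2, scl, `/`)
  attr(out, "center") <- ctr
  attr(out, "scale") <- scl
  out
}

# xi from sufficient statistics: sizes N (vector), per-feature sums S and
# sums of squares Q (matrices, one row per cluster), global biased
# variances gv. Vectorized over clusters.
xi_from_stats <- function(N, S, Q, gv) {
  wvar <- Q / N - (S / N)^2
  wvar[wvar < 0] <- 0  # guard tiny negative rounding
  -N * rowSums(0.5 * log(sweep(wvar, 2, gv, `+`)))
}

#' Log-likelihood tightness of a cluster
#'
#' @param features feature matrix of the whole dataset.
#' @param members integer indices of the cluster's members.
#' @param global_var whole-dataset biased (1/n) feature variances;
#'   computed from `features` when omitted.
#' @return The scalar tightness xi of the member set.
#' @export
cluster_tightness <- function(features, members = seq_len(nrow(features)),
                              global_var = biased_var(features)) {
  if (!length(members)) stop_bad("cluster must be nonempty")
  x <- features[members, , drop = FALSE]
  xi_from_stats(length(members), rbind(colSums(x)), rbind(colSums(x^2)),
                global_var)
}

#' Log-likelihood distance between two disjoint clusters
#'
#' `d(j, s) = xi_j + xi_s - xi_{j union s}`; symmetric and non-negative
#' (up to floating tolerance) for continuous features.
#'
#' @inheritParams cluster_tightness
#' @param members_j,members_s disjoint member index sets.
#' @return The merge cost d(j, s).
#' @export
loglik_distance <- function(features, members_j, members_s,
                            global_var = biased_var(features)) {
  if (length(intersect(members_j, members_s)))
    stop_bad("clusters must be disjoint")
  cluster_tightness(features, members_j, global_var) +
    cluster_tightness(features, members_s, global_var) -
    cluster_tightness(features, c(members_j, members_s), global_var)
}

#' Agglomerate from singletons with the log-likelihood distance
#'
#' Repeatedly merges the pair of clusters with the smallest distance until
#' one cluster remains, recording the merge cost at every step, the BIC of
#' each partition with `J <= J_max` clusters, and the assignments at each
#' of those cuts. Ties on the merge distance are broken deterministically
#' in favor of the earliest cluster pair in storage order.
#'
#' @param features numeric matrix (already standardized by [twostep_fit()]).
#' @param J_max largest cluster count traced (default 15).
#' @return List with `bic_trace` (BIC(J), J = 1..J_max), `merge_dist`
#'   (`merge_dist[J]` = cost of the merge performed when J clusters were
#'   active, i.e. reducing J to J-1 clusters; J = 2..n), `cuts` (list of
#'   assignment vectors for J = 1..J_max), `n`, `global_var`.
#' @export
ts_agglomerate <- function(features, J_max = 15) {
  x <- as.matrix(features)
  n <- nrow(x)
  if (n == 0) stop_bad("no rows to cluster")
  p <- ncol(x)
  J_max <- min(J_max, n)
  gv <- biased_var(x)

  N <- rep(1, n)
  S <- x
  Q <- x^2
  xi <- xi_from_stats(N, S, Q, gv)
  active <- rep(TRUE, n)
  assign <- seq_len(n)          # representative index per sample
  merge_dist <- rep(NA_real_, n + 1)
  cuts <- vector("list", J_max)
  sum_xi <- rep(NA_real_, J_max)
  if (n <= J_max) {
    cuts[[n]] <- assign
    sum_xi[n] <- sum(xi)
  }

  # pairwise merge-cost matrix; Inf marks inactive/diagonal
  dist_to <- function(i, js) {
    Nm <- N[i] + N[js]
    Sm <- sweep(S[js, , drop = FALSE], 2, S[i, ], `+`)
    Qm <- sweep(Q[js, , drop = FALSE], 2, Q[i, ], `+`)
    xi[i] + xi[js] - xi_from_stats(Nm, Sm, Qm, gv)
  }
  D <- matrix(Inf, n, n)
  if (n > 1) {
    for (i in seq_len(n - 1)) {
      js <- (i + 1):n
      D[js, i] <- D[i, js] <- dist_to(i, js)
    }
  }

  for (J in (if (n >= 2) n:2 else integer(0))) {
    k <- arrayInd(which.min(D), dim(D))
    a <- min(k); b <- max(k)
    merge_dist[J] <- D[a, b]
    # merge b into a
    N[a] <- N[a] + N[b]; S[a, ] <- S[a, ] + S[b, ]; Q[a, ] <- Q[a, ] + Q[b, ]
    xi[a] <- xi_from_stats(N[a], S[a, , drop = FALSE], Q[a, , drop = FALSE], gv)
    active[b] <- FALSE
    assign[assign == b] <- a
    D[b, ] <- Inf; D[, b] <- Inf
    js <- which(active); js <- js[js != a]
    if (length(js)) D[js, a] <- D[a, js] <- dist_to(a, js)
    if (J - 1 <= J_max) {
      cuts[[J - 1]] <- assign
      sum_xi[J - 1] <- sum(xi[active])
    }
  }
  bic <- -2 * sum_xi + (2 * p) * seq_len(J_max) * log(n)
  list(bic_trace = bic, merge_dist = merge_dist, cuts = cuts,
       n = n, global_var = gv)
}

#' Automatic choice of the number of clusters
#'
#' Two-stage heuristic. Stage 1 (coarse, BIC): if BIC(2) >= BIC(1) return
#' 1; otherwise take the largest J whose BIC improvement ratio
#' `(BIC(J) - BIC(J-1)) / (BIC(2) - BIC(1))` still exceeds 0.04. Stage 2
#' (fine, merge distances): among 2 <= J <= J_coarse compute the distance
#' -change ratio `R(J) = merge_dist[J] / merge_dist[J + 1]` (the cost of
#' dissolving J clusters relative to dissolving J + 1); if the largest R
#' exceeds the second largest by more than a factor 1.15 its J is chosen,
#' otherwise the larger of the two candidate J's is.
#'
#' @param bic_trace BIC(J) for J = 1..J_max.
#' @param merge_dist merge-cost vector indexed as in [ts_agglomerate()].
#' @param J_max maximum candidate count.
#' @param bic_ratio,dist_ratio heuristic constants (defaults 0.04, 1.15).
#' @return The chosen cluster count.
#' @export
choose_k <- function(bic_trace, merge_dist, J_max = length(bic_trace),
                     bic_ratio = 0.04, dist_ratio = 1.15) {
  J_max <- min(J_max, length(bic_trace))
  if (J_max < 2) return(1L)
  if (all(abs(diff(bic_trace[seq_len(J_max)])) < 1e-12)) {
    warning("degenerate BIC trace; returning k = 1")
    return(1L)
  }
  d1 <- bic_trace[2] - bic_trace[1]
  if (d1 >= 0) return(1L)
  ratios <- (bic_trace[2:J_max] - bic_trace[1:(J_max - 1)]) / d1
  ok <- which(ratios > bic_ratio)     # ratios[J-1] is the step J-1 -> J
  J_c <- if (length(ok)) max(ok) + 1L else 2L
  if (J_c < 2) return(1L)
  cand <- 2:J_c
  R <- merge_dist[cand] / merge_dist[cand + 1]
  R[!is.finite(R)] <- 0
  if (length(cand) == 1) return(cand)
  ord <- order(R, decreasing = TRUE)
  top <- ord[1]; second <- ord[2]
  if (R[second] <= 0 || R[top] / R[second] > dist_ratio) cand[top]
  else max(cand[top], cand[second])
}

#' Fit the two-step clustering
#'
#' Standardizes the features, agglomerates from singletons with the
#' log-likelihood distance, selects the number of clusters with
#' [choose_k()], and assigns each sample to the cluster of the chosen
#' merge-tree cut. Rows with missing features are removed (listwise
#' deletion) with a message; the deletion count is stored in the fit.
#'
#' @param features numeric matrix or data.frame (samples x features),
#'   typically columns (grs, fev1pct, onset_age); rownames are sample ids.
#' @param J_max largest candidate cluster count (default 15; lowered to n
#'   with a warning when n < J_max).
#' @param standardize z-score the columns first (default TRUE).
#' @return An object of class `twostep_fit`: `k`, `assignments` (integer
#'   labels 1..k in order of first appearance), `centers` and
#'   `within_sd` on the original scale, `sizes`, `bic_trace`,
#'   `merge_dist`, `selection` (the heuristic's inputs), `n`, `n_dropped`.
#' @export
twostep_fit <- function(features, J_max = 15, standardize = TRUE) {
  x <- as.matrix(features)
  storage.mode(x) <- "double"
  cc <- complete.cases(x)
  n_dropped <- sum(!cc)
  if (n_dropped) {
    message("listwise deletion removed ", n_dropped, " incomplete row(s)")
    x <- x[cc, , drop = FALSE]
  }
  if (nrow(x) < 2) stop_bad("need at least 2 complete rows")
  if (J_max > nrow(x)) {
    warning("J_max lowered to n = ", nrow(x))
    J_max <- nrow(x)
  }
  z <- if (standardize) ts_standardize(x) else x
  agg <- ts_agglomerate(z, J_max = J_max)
  k <- choose_k(agg$bic_trace, agg$merge_dist, J_max)
  reps <- agg$cuts[[k]]
  labels <- match(reps, unique(reps))   # 1..k by order of appearance
  centers <- t(vapply(seq_len(k), function(j)
    colMeans(x[labels == j, , drop = FALSE]), numeric(ncol(x))))
  wsd <- t(vapply(seq_len(k), function(j)
    apply(x[labels == j, , drop = FALSE], 2, sd), numeric(ncol(x))))
  colnames(centers) <- colnames(wsd) <- colnames(x)
  structure(list(k = k, assignments = setNames(labels, rownames(x)),
                 centers = centers, within_sd = wsd,
                 sizes = tabulate(labels, k),
                 bic_trace = agg$bic_trace, merge_dist = agg$merge_dist,
                 n = nrow(x), n_dropped = n_dropped,
                 standardized = standardize),
            class = "twostep_fit")
}

#' @export
print.twostep_fit <- function(x, ...) {
  cat(sprintf("<twostep_fit> n = %d, k = %d (sizes: %s)\n",
              x$n, x$k, paste(x$sizes, collapse = ", ")))
  cat("cluster centers (original scale):\n")
  print(round(x$centers, 2))
  invisible(x)
}
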