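# GrabCut foreground refinement: alternate full-covariance Gaussian-mixture
# colour modelling of the current foreground/background partition with a
# minimum graph cut (igraph max-flow) over the 8-connected pixel grid.

fit_gmm <- function(X, assign, K) {
  comps <- list()
  for (k in seq_len(K)) {
    idx <- which(assign == k)
    if (length(idx) < 1L) next
    Xi <- X[idx, , drop = FALSE]
    mu <- colMeans(Xi)
    S <- if (nrow(Xi) > 1) stats::cov(Xi) else matrix(0, 3, 3)
    S <- S + diag(1e-5, 3)  # regularize solid-colour components
    comps[[length(comps) + 1L]] <- list(mu = mu, sigma = S,
                                        w = length(idx) / nrow(X))
  }
  comps
}

# log density of each row of X under each mixture component (n x K matrix)
gmm_component_logdens <- function(X, comps) {
  out <- matrix(-Inf, nrow(X), length(comps))
  for (k in seq_along(comps)) {
    cmp <- comps[[k]]
    ch <- chol(cmp$sigma)
    d <- forwardsolve(t(ch), t(X) - cmp$mu)
    out[, k] <- log(cmp$w) - sum(log(diag(ch))) -
      1.5 * log(2 * pi) - 0.5 * colSums(d^2)
  }
  out
}

gmm_logdens <- function(X, comps) {
  ld <- gmm_component_logdens(X, comps)
  m <- apply(ld, 1, max)
  m + log(rowSums(exp(ld - m)))
}

seeded_kmeans_assign <- function(X, K, seed) {
  K <- min(K, max(1L, nrow(unique(X))))
  if (K == 1L) return(rep(1L, nrow(X)))
  with_seed(seed, {
    tryCatch(stats::kmeans(X, centers = K, nstart = 1L,
                           iter.max = 30L)$cluster,
             error = function(e) rep(1L, nrow(X)))
  })
}

#' GrabCut mask refinement
#'
#' Refines an initial foreground guess by iterating Gaussian-mixture colour
#' modelling and min-cut labelling. Initial-mask pixels enter as probable
#' foreground and the rest as probable background; there are no hard
#' constraints, so either side may be relabelled. The min cut is solved by a
#' Dinic max-flow specialised to the pixel grid: terminal links carry the
#' negative log-likelihoods under the two colour models and neighbour links
#' `gamma / dist * exp(-beta * |z_i - z_j|^2)` with `beta` set from the mean
#' squared neighbour difference.
#'
#' @param image numeric `(H, W, 3)` RGB array in `[0, 1]`.
#' @param init_mask logical `H x W` matrix; must contain both `TRUE` and
#'   `FALSE` pixels.
#' @param iters number of model/cut iterations (default 3).
#' @param seed integer seed for the k-means initialisation of the colour
#'   models; fixed seed gives identical masks on identical input.
#' @param n_components mixture components per colour model.
#' @param gamma smoothness strength of the neighbour links.
#' @return Logical `H x W` foreground mask.
#' @export
grabcut_refine <- function(image, init_mask, iters = 3L, seed = 0L,
                           n_components = 5L, gamma = 50) {
  assert_rgb(image)
  H <- dim(image)[1]; W <- dim(image)[2]
  if (!is.logical(init_mask) || !identical(dim(init_mask), c(H, W))) {
    stop("`init_mask` must be a logical matrix matching the image",
         call. = FALSE)
  }
  if (!any(init_mask) || all(init_mask)) {
    stop(errorCondition(
      "degenerate GrabCut initialization: mask is empty or covers everything",
      class = c("pestscout_degenerate_init", "error", "condition")))
  }
  n <- H * W
  Z <- cbind(as.numeric(image[, , 1]), as.numeric(image[, , 2]),
             as.numeric(image[, , 3]))

  m <- matrix(seq_len(n), H, W)
  pa <- c(m[, seq_len(W - 1)], m[seq_len(H - 1), ],
          m[seq_len(H - 1), seq_len(W - 1)], m[seq_len(H - 1), -1])
  pb <- c(m[, -1], m[-1, ],
          m[-1, -1], m[-1, seq_len(W - 1)])
  invd <- c(rep(1, (W - 1) * H), rep(1, (H - 1) * W),
            rep(1 / sqrt(2), 2 * (H - 1) * (W - 1)))
  sq <- rowSums((Z[pa, , drop = FALSE] - Z[pb, , drop = FALSE])^2)
  beta <- if (mean(sq) > 0) 1 / (2 * mean(sq)) else 1e6
  wN <- gamma * invd * exp(-beta * sq)

  alpha <- as.vector(init_mask)
  fg_assign <- NULL; bg_assign <- NULL
  for (it in seq_len(iters)) {
    F <- which(alpha); B <- which(!alpha)
    if (length(F) == 0L || length(B) == 0L) break
    if (it == 1L) {
      fg_assign <- seeded_kmeans_assign(Z[F, , drop = FALSE], n_components,
                                        seed + 1L)
      bg_assign <- seeded_kmeans_assign(Z[B, , drop = FALSE], n_components,
                                        seed + 2L)
    }
    gmm_f <- fit_gmm(Z[F, , drop = FALSE], fg_assign, max(fg_assign))
    gmm_b <- fit_gmm(Z[B, , drop = FALSE], bg_assign, max(bg_assign))
    Ufg <- pmin(-gmm_logdens(Z, gmm_f), 1e6)
    Ubg <- pmin(-gmm_logdens(Z, gmm_b), 1e6)
    shift <- pmin(Ufg, Ubg)  # per-pixel shift leaves the optimal cut unchanged
    mc <- grid_mincut_cpp(pa, pb, wN, Ubg - shift, Ufg - shift)
    new_alpha <- mc$foreground
    if (!any(new_alpha) || all(new_alpha)) {
      alpha <- new_alpha
      break
    }
    # reassign pixels to the most likely component of their new label
    alpha <- new_alpha
    F <- which(alpha); B <- which(!alpha)
    fg_assign <- max.col(gmm_component_logdens(Z[F, , drop = FALSE], gmm_f),
                         ties.method = "first")
    bg_assign <- max.col(gmm_component_logdens(Z[B, , drop = FALSE], gmm_b),
                         ties.method = "first")
  }
  matrix(alpha, H, W)
}
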