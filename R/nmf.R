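# Maximum-likelihood KL (Poisson) non-negative matrix factorisation with
# multiplicative updates, multi-restart, and BIC-based rank selection.

kl_divergence <- function(X, M) {
  pos <- X > 0
  sum(X[pos] * log(X[pos] / M[pos])) - sum(X) + sum(M)
}

# one KL-NMF fit at fixed rank; multiplicative updates are monotone in the
# generalized KL divergence, which is asserted every iteration
klnmf_fit <- function(X, k, max_iter = 5000, tol = 1e-8, eps = 1e-12,
                      W0 = NULL, H0 = NULL) {
  n <- nrow(X); g <- ncol(X)
  W <- W0 %||% matrix(stats::runif(n * k, 0.5, 1.5), n, k)
  H <- H0 %||% matrix(stats::runif(k * g, 0.5, 1.5) * sum(X) / (k * g), k, g)
  M <- W %*% H
  d_prev <- kl_divergence(X, M)
  for (it in seq_len(max_iter)) {
    R <- X / pmax(M, eps)
    W <- W * (R %*% t(H)) / pmax(matrix(rowSums(H), n, k, byrow = TRUE), eps)
    M <- W %*% H
    R <- X / pmax(M, eps)
    H <- H * (t(W) %*% R) / pmax(matrix(colSums(W), k, g), eps)
    M <- W %*% H
    d <- kl_divergence(X, M)
    if (d > d_prev + 1e-6 * (1 + abs(d_prev))) {
      stop("KL divergence increased during multiplicative updates",
           call. = FALSE)
    }
    if (abs(d_prev - d) < tol * (1 + abs(d_prev))) {
      d_prev <- d
      break
    }
    d_prev <- d
  }
  list(W = W, H = H, kl = d_prev, n_iter = it)
}

poisson_loglik <- function(X, M) {
  pos <- M > 0 | X == 0
  if (!all(pos)) return(-Inf)
  sum(stats::dpois(X, pmax(M, 1e-300), log = TRUE))
}

#' Extract mutational signatures by KL-NMF with BIC rank selection
#'
#' Factorises a 96 x G context count matrix as `P %*% E` with
#' column-stochastic signature profiles `P` (96 x k) and non-negative
#' exposures `E` (k x G). For each candidate rank, the Poisson-likelihood
#' (generalised KL) NMF is fit with `n_restarts` random initialisations,
#' keeping the best; the selected rank minimises
#' `BIC = -2 logLik + (96 k + k G - k) log(N)` with `N` the total mutation
#' count, breaking near-ties (within 1 BIC unit) toward the smaller rank.
#'
#' @param counts 96 x G non-negative count matrix (canonical channel
#'   order; see [context_matrix()]).
#' @param k_range candidate ranks (positive integers).
#' @param n_restarts random restarts per rank.
#' @param seed RNG seed (all restarts derive from it).
#' @param max_iter,tol multiplicative-update convergence controls.
#' @return object of class `signature_model`: `P`, `E`, `k`, per-rank
#'   table `bic_table` (`k`, `loglik`, `bic`, `kl`), and the selected
#'   fit's KL divergence.
#' @export
extract_signatures <- function(counts, k_range = 1:4, n_restarts = 20,
                               seed = 1, max_iter = 5000, tol = 1e-8) {
  X <- as.matrix(counts)
  if (nrow(X) != 96) stop("count matrix must have 96 rows", call. = FALSE)
  if (any(X < 0)) stop("negative counts", call. = FALSE)
  if (any(colSums(X) == 0)) {
    stop("every sample column must contain at least one mutation",
         call. = FALSE)
  }
  k_range <- sort(unique(as.integer(k_range)))
  if (length(k_range) == 0 || any(k_range < 1)) {
    stop("empty or invalid rank range", call. = FALSE)
  }
  g <- ncol(X)
  N <- sum(X)
  set.seed(seed)
  per_k <- lapply(k_range, function(k) {
    best <- NULL
    for (r in seq_len(n_restarts)) {
      fit <- klnmf_fit(X, k, max_iter = max_iter, tol = tol)
      if (is.null(best) || fit$kl < best$kl) best <- fit
    }
    ll <- poisson_loglik(X, best$W %*% best$H)
    npar <- 96 * k + k * g - k   # column-stochastic P absorbs k constraints
    list(k = k, fit = best, loglik = ll, bic = -2 * ll + npar * log(N))
  })
  bic_table <- data.frame(
    k = vapply(per_k, `[[`, integer(1), "k"),
    loglik = vapply(per_k, `[[`, numeric(1), "loglik"),
    bic = vapply(per_k, function(z) z$bic, numeric(1)),
    kl = vapply(per_k, function(z) z$fit$kl, numeric(1)))
  best_bic <- min(bic_table$bic)
  k_sel <- min(bic_table$k[bic_table$bic <= best_bic + 1])
  sel <- per_k[[match(k_sel, bic_table$k)]]$fit
  scale <- colSums(sel$W)
  P <- sweep(sel$W, 2, scale, "/")
  E <- sel$H * scale
  colnames(P) <- paste0("sig", seq_len(k_sel))
  rownames(P) <- rownames(X) %||% sbs_channels()
  rownames(E) <- colnames(P)
  colnames(E) <- colnames(X)
  structure(list(P = P, E = E, k = k_sel, bic_table = bic_table,
                 kl = sel$kl, n_iter = sel$n_iter, seed = seed),
            class = "signature_model")
}

#' @export
print.signature_model <- function(x, ...) {
  cat(sprintf("KL-NMF signature model: k = %d (%d channels x %d groups), KL = %.4g\n",
              x$k, nrow(x$P), ncol(x$E), x$kl))
  print(x$bic_table, row.names = FALSE)
  invisible(x)
}

#' Cluster extracted signatures with a reference catalog
#'
#' Joins extracted signature profiles, any externally supplied profiles
#' and the reference catalog into one 96-channel panel, computes pairwise
#' Pearson correlation, and clusters with `1 - correlation` as the
#' distance (average linkage by default). Also reports each extracted
#' signature's nearest catalog entries by correlation.
#'
#' @param model `signature_model` from [extract_signatures()], or a
#'   column-stochastic 96 x k matrix.
#' @param catalog 96 x S reference matrix (see
#'   [read_signature_catalog()]).
#' @param extra optional list of additional 96 x k matrices (e.g.
#'   signatures published by other studies).
#' @param linkage hclust agglomeration method.
#' @param n_nearest how many nearest references to report per signature.
#' @return list with `tree` (hclust), `nearest` (data.frame: signature,
#'   reference, correlation, rank) and the correlation matrix.
#' @export
cluster_with_catalog <- function(model, catalog, extra = NULL,
                                 linkage = "average", n_nearest = 3) {
  P <- if (inherits(model, "signature_model")) model$P else as.matrix(model)
  panels <- c(list(extracted = P), extra %||% list(),
              list(catalog = catalog))
  for (m in panels) {
    if (nrow(m) != 96) stop("all panels must have 96 rows", call. = FALSE)
    rn <- rownames(m)
    if (!is.null(rn) && !identical(rn, sbs_channels())) {
      stop("channel order mismatch between panels", call. = FALSE)
    }
  }
  all <- do.call(cbind, panels)
  colnames(all) <- unname(unlist(lapply(panels, colnames)))
  cm <- stats::cor(all)
  tree <- stats::hclust(stats::as.dist(1 - cm), method = linkage)
  nearest <- do.call(rbind, lapply(colnames(P), function(s) {
    r <- cm[s, colnames(catalog)]
    ord <- order(r, decreasing = TRUE)[seq_len(min(n_nearest, length(r)))]
    data.frame(signature = s, reference = colnames(catalog)[ord],
               correlation = unname(r[ord]),
               rank = seq_along(ord), stringsAsFactors = FALSE)
  }))
  list(tree = tree, nearest = nearest, correlation = cm)
}

#' Write a signature clustering tree in Newick format
#' @param clustering result of [cluster_with_catalog()].
#' @param path output file.
#' @export
write_signature_tree <- function(clustering, path) {
  phy <- ape::as.phylo(clustering$tree)
  ape::write.tree(phy, file = path)
  invisible(path)
}
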