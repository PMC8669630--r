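#' Module-detection configuration
#'
#' Controls the spectral module search.  The default scan range of 25-30
#' modules reflects the number of gene-set subnetworks each cell-death
#' network is typically separated into.
#'
#' @param k_min,k_max Bounds of the module-count scan (defaults 25 and 30).
#' @param seed Integer seed; identical `(input, config, seed)` gives an
#'   identical partition.
#' @param restarts Number of seeded k-means restarts per candidate `k`
#'   (default 10); the restart with the best refined likelihood is kept.
#' @param min_module_size Modules smaller than this are merged into their
#'   highest-connectivity neighbour module unless `keep_small` (default 2).
#' @param k_selection Strategy for choosing the module count within
#'   `[k_min, k_max]`: `"likelihood"` (default; penalized planted-partition
#'   likelihood), `"modularity"` (Newman modularity of the induced
#'   partition), `"eigengap"` (largest Laplacian spectral gap) or
#'   `"fixed"` (use `k`).
#' @param k Module count when `k_selection = "fixed"`.
#' @param regularize Add a small constant (mean degree / n) to the
#'   off-diagonal degree normalization to stabilize eigenvectors on
#'   fragmented graphs (default `TRUE`).
#' @param refine Apply planted-partition likelihood refinement (ICM sweeps,
#'   targeted merge+split moves and a Gibbs marginal polish) after k-means
#'   (default `TRUE`).  With `refine = FALSE` the partition is the plain
#'   spectral embedding + k-means result.
#' @param keep_small Keep modules smaller than `min_module_size` instead of
#'   merging them (default `FALSE`).
#' @return A `clustering_config` list.
#' @export
clustering_config <- function(k_min = 25, k_max = 30, seed = 1,
                              restarts = 10, min_module_size = 2,
                              k_selection = c("likelihood", "modularity",
                                              "eigengap", "fixed"),
                              k = NULL, regularize = TRUE, refine = TRUE,
                              keep_small = FALSE) {
  k_selection <- match.arg(k_selection)
  if (k_min < 1 || k_min > k_max) abort_usage("need 1 <= k_min <= k_max")
  if (restarts < 1) abort_usage("restarts must be >= 1")
  if (k_selection == "fixed" && is.null(k)) {
    abort_usage("k_selection = \"fixed\" needs `k`")
  }
  structure(list(k_min = as.integer(k_min), k_max = as.integer(k_max),
                 seed = as.integer(seed), restarts = as.integer(restarts),
                 min_module_size = as.integer(min_module_size),
                 k_selection = k_selection,
                 k = if (is.null(k)) NULL else as.integer(k),
                 regularize = isTRUE(regularize),
                 refine = isTRUE(refine),
                 keep_small = isTRUE(keep_small)),
            class = "clustering_config")
}

# ---- internal spectral machinery ------------------------------------------

# Symmetric normalized Laplacian of the zero-diagonal aggregate, optionally
# regularized: the aggregate is shifted by tau/n off-diagonal with
# tau = mean degree, which stabilizes the leading eigenvectors when the
# graph is fragmented.
laplacian_eigen <- function(M, regularize = TRUE) {
  n <- nrow(M)
  diag(M) <- 0
  d <- rowSums(M)
  tau <- if (regularize) mean(d) else 0
  Mr <- M + tau / n
  diag(Mr) <- 0
  dr <- rowSums(Mr)
  if (any(dr <= 0)) {
    abort_contract("degree normalization impossible: zero-degree gene after regularization")
  }
  dis <- 1 / sqrt(dr)
  L <- diag(n) - dis * sweep(Mr, 2, dis, `*`)
  eigen((L + t(L)) / 2, symmetric = TRUE)
}

# Row-normalized spectral embedding on the k smallest-eigenvalue vectors.
spectral_embedding <- function(eig, k) {
  n <- nrow(eig$vectors)
  U <- eig$vectors[, n:(n - k + 1), drop = FALSE]
  rn <- sqrt(rowSums(U^2))
  rn[rn == 0] <- 1
  U / rn
}

# Bernoulli planted-partition log-likelihood of a hard partition of the
# binarized graph, with rates profiled out.
pp_rates <- function(B, memb) {
  n <- nrow(B)
  ks <- sort(unique(memb))
  Z <- outer(memb, ks, `==`) + 0
  sizes <- colSums(Z)
  within <- sum(diag(crossprod(Z, B %*% Z))) / 2
  m <- sum(B) / 2
  pw <- sum(sizes * (sizes - 1)) / 2
  poss <- n * (n - 1) / 2
  list(p_in = min(max(within / max(pw, 1), 1e-9), 1 - 1e-9),
       p_out = min(max((m - within) / max(poss - pw, 1), 1e-12), 1 - 1e-9),
       within = within, pw = pw, m = m, poss = poss)
}

pp_loglik <- function(B, memb) {
  r <- pp_rates(B, memb)
  r$within * log(r$p_in) + (r$pw - r$within) * log(1 - r$p_in) +
    (r$m - r$within) * log(r$p_out) +
    (r$poss - r$pw - (r$m - r$within)) * log(1 - r$p_out)
}

# Penalized likelihood used for k selection: complete-data likelihood with
# mixing proportions minus a BIC-style penalty on the number of modules.
pp_penalized <- function(B, memb) {
  n <- nrow(B)
  tab <- table(memb)
  keff <- length(tab)
  pp_loglik(B, memb) + sum(tab * log(tab / n)) - 0.5 * (keff - 1) * log(n)
}

# Iterated conditional modes: greedy single-gene reassignment under the
# planted-partition likelihood, rates re-estimated each sweep.  Ties break
# toward the lowest module id; sweep order is gene index order, so the
# result is deterministic.  Module count is held fixed (a module never
# empties).
pp_icm <- function(B, memb, sweeps = 50) {
  n <- nrow(B)
  K <- max(memb)
  for (sw in seq_len(sweeps)) {
    Z <- outer(memb, seq_len(K), `==`) + 0
    sizes <- colSums(Z)
    Wk <- B %*% Z
    r <- pp_rates(B, memb)
    if (r$p_in <= r$p_out) break
    a <- log(r$p_in / r$p_out)
    b <- log(1 - r$p_out) - log(1 - r$p_in)
    changed <- 0L
    for (i in seq_len(n)) {
      cur <- memb[i]
      if (sizes[cur] <= 1) next
      sc <- a * Wk[i, ] - b * (sizes - (seq_len(K) == cur))
      best <- which.max(sc)
      if (best != cur && sc[best] > sc[cur] + 1e-12) {
        nb <- which(B[i, ] > 0)
        Wk[nb, cur] <- Wk[nb, cur] - B[i, nb]
        Wk[nb, best] <- Wk[nb, best] + B[i, nb]
        sizes[cur] <- sizes[cur] - 1
        sizes[best] <- sizes[best] + 1
        memb[i] <- best
        changed <- changed + 1L
      }
    }
    if (changed == 0L) break
  }
  memb
}

# Spectral bisection of one module's induced subgraph (leading eigenvector
# of the modularity-centered submatrix).
pp_bisect <- function(B, idx) {
  S <- B[idx, idx, drop = FALSE]
  d <- rowSums(S)
  if (sum(d) == 0) return(NULL)
  v <- eigen(S - outer(d, d) / sum(d), symmetric = TRUE)$vectors[, 1]
  g <- as.integer(v > 0) + 1L
  if (length(unique(g)) < 2) return(NULL)
  g
}

# Targeted merge+split search at fixed module count: merge the module pair
# with the largest exact likelihood gain and split the module whose spectral
# bisection gains most, accept jointly when the refined likelihood improves.
pp_move_search <- function(B, memb, max_rounds = 12) {
  for (round in seq_len(max_rounds)) {
    ll0 <- pp_loglik(B, memb)
    K <- max(memb)
    ks <- seq_len(K)
    Z <- outer(memb, ks, `==`) + 0
    sizes <- colSums(Z)
    Blk <- crossprod(Z, B %*% Z)
    r <- pp_rates(B, memb)
    la <- log(r$p_in / r$p_out)
    lb <- log(1 - r$p_in) - log(1 - r$p_out)
    MG <- Blk * la + (outer(sizes, sizes) - Blk) * lb
    diag(MG) <- -Inf
    SG <- rep(-Inf, K)
    SPL <- vector("list", K)
    for (c in ks) {
      idx <- which(memb == c)
      if (length(idx) < 4) next
      g <- pp_bisect(B, idx)
      if (is.null(g)) next
      i1 <- idx[g == 1]
      i2 <- idx[g == 2]
      cross <- sum(B[i1, i2])
      SG[c] <- -(cross * la + (length(i1) * length(i2) - cross) * lb)
      SPL[[c]] <- i2
    }
    flat <- which(MG > -Inf, arr.ind = TRUE)
    if (nrow(flat) == 0) break
    ord <- order(MG[flat], decreasing = TRUE)
    top_m <- flat[head(ord, 15), , drop = FALSE]
    top_s <- order(SG, decreasing = TRUE)[seq_len(min(5, K))]
    best <- NULL
    for (t in seq_len(nrow(top_m))) {
      c1 <- top_m[t, 1]; c2 <- top_m[t, 2]
      if (c1 >= c2) next
      for (e in top_s) {
        if (e == c1 || e == c2 || SG[e] == -Inf) next
        gain <- MG[c1, c2] + SG[e]
        if (gain <= 1e-9) next
        if (is.null(best) || gain > best$gain) {
          best <- list(c1 = c1, c2 = c2, e = e, gain = gain)
        }
      }
    }
    if (is.null(best)) break
    m2 <- memb
    m2[m2 == best$c2] <- best$c1
    m2[SPL[[best$e]]] <- best$c2
    m2 <- pp_icm(B, m2, sweeps = 30)
    if (pp_loglik(B, m2) > ll0 + 1e-9) memb <- m2 else break
  }
  memb
}

# Gibbs sampler over gene assignments at fixed module count with Beta(1,1)
# priors on the within/between edge rates; returns the per-gene majority
# module over the retained sweeps (a marginal-posterior polish of the MAP
# search).  Labels cannot drift between modules of a stationary chain
# initialized at a high-likelihood partition, so the majority vote is taken
# on raw labels.
pp_gibbs_polish <- function(B, memb, seed, chains = 3, burn = 50,
                            samples = 200) {
  n <- nrow(B)
  K <- max(memb)
  m <- sum(B) / 2
  poss <- n * (n - 1) / 2
  counts <- matrix(0, n, K)
  for (ch in seq_len(chains)) {
    set.seed(sub_seed(seed, paste0("gibbs", ch)))
    mb <- memb
    Z <- outer(mb, seq_len(K), `==`) + 0
    sizes <- colSums(Z)
    Wk <- B %*% Z
    for (sw in seq_len(burn + samples)) {
      within <- sum(vapply(seq_len(K),
                           function(c) sum(Wk[mb == c, c]), 0)) / 2
      pw <- sum(sizes * (sizes - 1)) / 2
      p_in <- rbeta(1, within + 1, pmax(pw - within, 0) + 1)
      p_out <- rbeta(1, (m - within) + 1,
                     pmax(poss - pw - (m - within), 0) + 1)
      if (p_out >= p_in) {
        tmp <- p_in; p_in <- p_out; p_out <- tmp
      }
      p_out <- max(p_out, 1e-12)
      a <- log(p_in / p_out)
      b <- log(1 - p_out) - log(1 - p_in)
      for (i in seq_len(n)) {
        cur <- mb[i]
        lg <- a * Wk[i, ] - b * (sizes - (seq_len(K) == cur))
        lg <- lg - max(lg)
        pr <- exp(lg)
        new <- sample.int(K, 1, prob = pr / sum(pr))
        if (new != cur) {
          nb <- which(B[i, ] > 0)
          Wk[nb, cur] <- Wk[nb, cur] - B[i, nb]
          Wk[nb, new] <- Wk[nb, new] + B[i, nb]
          sizes[cur] <- sizes[cur] - 1
          sizes[new] <- sizes[new] + 1
          mb[i] <- new
        }
      }
      if (sw > burn) {
        counts[cbind(seq_len(n), mb)] <- counts[cbind(seq_len(n), mb)] + 1
      }
    }
  }
  max.col(counts, ties.method = "first")
}

# One full candidate solution at a given k: seeded k-means restarts on the
# embedding, keep the best refined likelihood.
solve_at_k <- function(B, U, k, config) {
  best <- NULL
  for (r in seq_len(config$restarts)) {
    set.seed(sub_seed(config$seed, paste0("kmeans", k, "_", r)))
    cl <- kmeans(U, centers = k, nstart = 1, iter.max = 100)$cluster
    if (config$refine) cl <- pp_icm(B, cl)
    ll <- pp_loglik(B, cl)
    if (is.null(best) || ll > best$ll) best <- list(cl = cl, ll = ll)
  }
  cl <- best$cl
  if (config$refine) cl <- pp_move_search(B, cl)
  cl
}

# Canonical contiguous labels ordered by first occurrence in gene order.
relabel_first_seen <- function(memb) {
  match(memb, unique(memb))
}

# ---- exported operations ---------------------------------------------------

#' Detect subnetwork modules by spectral clustering
#'
#' Forms the symmetric normalized Laplacian of the zero-diagonal aggregated
#' weight matrix, embeds genes on the `k` smallest-eigenvalue eigenvectors
#' (row-normalized), clusters the rows by seeded k-means, and by default
#' refines the partition under a planted-partition likelihood (iterated
#' conditional modes, targeted merge+split moves and a Gibbs marginal
#' polish).  The module count is chosen within `[k_min, k_max]` by the
#' configured strategy.  Isolated (zero-degree) genes are excluded from
#' clustering and listed separately.  Identical input, configuration and
#' seed give an identical partition.
#'
#' @param W A `weight_matrix` from [aggregate_layers()].
#' @param config A [clustering_config()].
#' @return A `module_partition`: list with `assignment` (tibble `gene`,
#'   `module`), `k`, `isolated`, `quality` (Newman modularity), `k_scan`
#'   (tibble of scanned candidates) and the `config`.
#' @examples
#' net <- simulate_multilayer(synth_config(n_genes = 60, k_true = 3,
#'                                         p_in = 0.6, p_out = 0.02,
#'                                         seed = 1))$network
#' W <- aggregate_layers(net)
#' part <- spectral_partition(W, clustering_config(k_min = 2, k_max = 5,
#'                                                 seed = 1))
#' glance(part)
#' @export
spectral_partition <- function(W, config = clustering_config()) {
  stopifnot(inherits(W, "weight_matrix"))
  if (!isTRUE(all.equal(W$M, t(W$M)))) {
    abort_contract("weight matrix is not symmetric")
  }
  keep <- !(W$genes %in% W$isolated)
  genes <- W$genes[keep]
  n <- length(genes)
  if (n < 2) abort_contract("need at least 2 non-isolated genes")
  M <- W$M[keep, keep, drop = FALSE]
  diag(M) <- 0
  B <- (M > 0) + 0

  k_max_eff <- min(config$k_max, floor(n / max(config$min_module_size, 1)), n)
  k_min_eff <- min(config$k_min, k_max_eff)
  if (config$k_selection == "fixed") {
    if (config$k > n) abort_contract("k exceeds the number of non-isolated genes")
    krange <- config$k
  } else {
    krange <- seq(k_min_eff, k_max_eff)
  }
  if (length(krange) == 0) abort_contract("empty module-count scan range")

  eig <- laplacian_eigen(M, config$regularize)
  vals <- rev(eig$values)

  scan <- vector("list", length(krange))
  for (idx in seq_along(krange)) {
    k <- krange[idx]
    cl <- if (k == 1) rep(1L, n) else {
      U <- spectral_embedding(eig, k)
      solve_at_k(B, U, k, config)
    }
    scan[[idx]] <- list(
      k = k, cl = cl,
      modularity = modularity_memb(M, cl),
      penalized = pp_penalized(B, cl),
      eigengap = if (k < n) vals[k + 1] - vals[k] else NA_real_)
  }
  k_scan <- tibble(
    k = vapply(scan, `[[`, 0L, "k"),
    modularity = vapply(scan, `[[`, 0, "modularity"),
    penalized_loglik = vapply(scan, `[[`, 0, "penalized"),
    eigengap = vapply(scan, `[[`, 0, "eigengap"))

  crit <- switch(config$k_selection,
                 fixed = rep(1, length(krange)),
                 modularity = k_scan$modularity,
                 eigengap = k_scan$eigengap,
                 likelihood = k_scan$penalized_loglik)
  pick <- which(crit == max(crit))[1]   # ties -> smallest k (scan ascending)
  cl <- scan[[pick]]$cl

  if (config$refine && max(cl) > 1) {
    cl <- relabel_first_seen(cl)
    cl <- pp_gibbs_polish(B, cl, seed = config$seed)
    cl <- pp_icm(B, cl)
  }
  cl <- merge_small_modules(M, cl, config$min_module_size, config$keep_small)
  cl <- relabel_first_seen(cl)

  structure(list(
    assignment = tibble(gene = genes, module = as.integer(cl)),
    k = max(cl),
    isolated = W$isolated,
    quality = modularity_memb(M, cl),
    k_scan = k_scan,
    config = config), class = "module_partition")
}

# Merge modules below the size floor into their highest-connectivity
# neighbour module (by total edge weight to the module).
merge_small_modules <- function(M, memb, min_size, keep_small) {
  if (keep_small || min_size <= 1) return(memb)
  repeat {
    tab <- table(memb)
    small <- names(tab)[tab < min_size]
    if (length(small) == 0 || length(tab) <= 1) break
    c0 <- as.integer(small[1])
    idx <- which(memb == c0)
    w_to <- tapply(colSums(M[idx, , drop = FALSE]), memb, sum)
    w_to[as.character(c0)] <- -Inf
    target <- as.integer(names(w_to)[which.max(w_to)])
    memb[idx] <- target
  }
  memb
}

#' Choose the module count
#'
#' Scans `k` over `[k_min, min(k_max, floor(n / min_module_size))]` and
#' returns the count maximizing the configured criterion (penalized
#' likelihood, Newman modularity of the induced partition, or the Laplacian
#' eigengap); ties break toward the smallest `k`.
#'
#' @inheritParams spectral_partition
#' @return The selected module count (integer).
#' @export
select_k <- function(W, config = clustering_config()) {
  if (config$k_selection == "fixed") {
    abort_usage("select_k needs a non-fixed k_selection strategy")
  }
  part <- spectral_partition(W, config)
  part$k
}

# Weighted Newman-Girvan modularity for a membership vector over the rows
# of the zero-diagonal matrix M.
modularity_memb <- function(M, memb) {
  diag(M) <- 0
  m2 <- sum(M)
  if (m2 == 0) return(0)
  d <- rowSums(M)
  q <- 0
  for (c in unique(memb)) {
    idx <- memb == c
    q <- q + sum(M[idx, idx]) / m2 - (sum(d[idx]) / m2)^2
  }
  q
}

#' Newman modularity of a partition
#'
#' Standard weighted Newman-Girvan modularity of a module partition on the
#' aggregated network (diagonal excluded).  Values lie in `[-0.5, 1]`; a
#' single-module partition has modularity 0.
#'
#' @param W A `weight_matrix`.
#' @param partition A `module_partition`, or a data frame with columns
#'   `gene` and `module`.
#' @return The modularity value.
#' @export
modularity <- function(W, partition) {
  stopifnot(inherits(W, "weight_matrix"))
  asg <- if (inherits(partition, "module_partition")) partition$assignment
         else as_tibble(partition)
  if (!all(c("gene", "module") %in% names(asg))) {
    abort_usage("partition needs columns gene, module")
  }
  covered <- setdiff(W$genes, W$isolated)
  if (!setequal(asg$gene, covered)) {
    abort_contract("partition does not cover the matrix's non-isolated genes")
  }
  keep <- match(asg$gene, W$genes)
  M <- W$M[keep, keep, drop = FALSE]
  modularity_memb(M, asg$module)
}

#' @export
print.module_partition <- function(x, ...) {
  cat(sprintf("<module_partition: %d modules over %d genes (%d isolated), modularity %.3f>\n",
              x$k, nrow(x$assignment), length(x$isolated), x$quality))
  invisible(x)
}

#' @export
tidy.module_partition <- function(x, ...) {
  x$assignment
}

#' @export
glance.module_partition <- function(x, ...) {
  tibble(k = x$k,
         n_genes = nrow(x$assignment),
         n_isolated = length(x$isolated),
         modularity = x$quality,
         min_size = min(table(x$assignment$module)),
         max_size = max(table(x$assignment$module)))
}

#' Write a partition as a two-column TSV
#'
#' @param partition A `module_partition`.
#' @param path Output path.
#' @return The path, invisibly.
#' @export
write_partition <- function(partition, path) {
  write_xtsv(partition$assignment, path)
}
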