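## Tree inference and tree-to-tree distances.
##
## Distance and NJ steps delegate to ape; the GTR+Gamma maximum-likelihood
## search (NNI rearrangements) delegates to phangorn::optim.pml behind
## optimize_tree(). log_likelihood() is an independent Felsenstein-pruning
## implementation (4 equal-probability discrete-gamma categories,
## mean-of-bin rates) used for verification and for per-site work.
## Robinson-Foulds and the generalized (clustering-information matching)
## Robinson-Foulds distance are implemented here; trees are always pruned
## to their common tip set first, mirroring per-locus accession exclusion.

#' Pairwise distances from an alignment
#'
#' p distance, Jukes-Cantor (JC69) or Kimura 2-parameter (K2P), with
#' pairwise deletion of sites containing gaps or ambiguities in either
#' sequence.
#'
#' @param alignment a \code{plastid_alignment} (>= 3 rows).
#' @param model "JC69" (default), "p" or "K2P".
#' @param cap if TRUE, saturated (undefined) distances are capped at 3
#'   substitutions/site instead of raising an error.
#' @return symmetric numeric matrix with a \code{model} attribute.
#' @export
pairwise_distances <- function(alignment, model = c("JC69", "p", "K2P"),
                               cap = FALSE) {
  model <- match.arg(model)
  m <- as_alignment(alignment)
  if (nrow(m) < 3L) stop("need >= 3 sequences")
  bin <- ape::as.DNAbin(unclass(m))
  amod <- c(JC69 = "JC69", p = "raw", K2P = "K80")[[model]]
  d <- ape::dist.dna(bin, model = amod, pairwise.deletion = TRUE,
                     as.matrix = TRUE)
  bad <- !is.finite(d)
  diag(bad) <- FALSE
  if (any(bad)) {
    if (!cap) {
      ij <- which(bad, arr.ind = TRUE)[1, ]
      stop("saturated/undefined ", model, " distance between '",
           rownames(d)[ij[1]], "' and '", colnames(d)[ij[2]], "'")
    }
    d[bad] <- 3
  }
  attr(d, "model") <- model
  d
}

#' Neighbor-joining tree
#'
#' Saitou-Nei neighbor joining (via ape), with negative branch lengths
#' clamped to zero.
#'
#' @param d symmetric distance matrix (>= 3 taxa).
#' @return unrooted \code{phylo}.
#' @export
nj_tree <- function(d) {
  d <- as.matrix(d)
  if (nrow(d) < 3L) stop("need >= 3 taxa")
  if (!isTRUE(all.equal(d, t(d), tolerance = 1e-8)))
    stop("distance matrix is not symmetric")
  tr <- ape::nj(stats::as.dist(d))
  tr$edge.length[tr$edge.length < 0] <- 0
  tr
}

## ---- GTR + discrete gamma likelihood ------------------------------------

#' Discrete-gamma category rates (mean-of-bin convention)
#' @param alpha gamma shape (= rate); Inf gives equal rates.
#' @param k number of equal-probability categories.
#' @return numeric vector of k rates with mean 1.
#' @export
gamma_category_rates <- function(alpha, k = 4L) {
  if (!is.finite(alpha)) return(rep(1, k))
  q <- stats::qgamma(seq(0, 1, length.out = k + 1), shape = alpha, rate = alpha)
  ## mean of each equal-probability bin, via the incomplete-gamma identity
  p <- stats::pgamma(q, shape = alpha + 1, rate = alpha)
  r <- k * diff(p)
  r / mean(r)
}

## scaled GTR rate matrix; rates = (AC, AG, AT, CG, CT, GT)
gtr_rate_matrix <- function(rates = rep(1, 6), bf = rep(0.25, 4)) {
  stopifnot(length(rates) == 6, length(bf) == 4, all(rates > 0),
            abs(sum(bf) - 1) < 1e-8)
  Q <- matrix(0, 4, 4, dimnames = list(c("A", "C", "G", "T"),
                                       c("A", "C", "G", "T")))
  Q[1, 2] <- rates[1]; Q[1, 3] <- rates[2]; Q[1, 4] <- rates[3]
  Q[2, 3] <- rates[4]; Q[2, 4] <- rates[5]; Q[3, 4] <- rates[6]
  Q <- Q + t(Q)
  Q <- Q %*% diag(bf)
  diag(Q) <- -rowSums(Q)
  scale <- -sum(bf * diag(Q))
  Q / scale
}

## eigen-decomposition of a reversible Q for fast matrix exponentials
gtr_eigen <- function(Q, bf) {
  rs <- sqrt(bf)
  B <- diag(rs) %*% Q %*% diag(1 / rs)
  e <- eigen((B + t(B)) / 2, symmetric = TRUE)
  list(vals = e$values,
       V = diag(1 / rs) %*% e$vectors,
       Vi = t(e$vectors) %*% diag(rs))
}

pmat <- function(eig, t) {
  P <- eig$V %*% (exp(eig$vals * t) * eig$Vi)
  P[P < 0] <- 0
  P
}

#' GTR+Gamma log-likelihood by Felsenstein pruning
#'
#' Averages the site likelihood over 4 equal-probability discrete-gamma
#' rate categories (mean-of-bin rates). Gaps and ambiguity codes are
#' missing data (partial likelihood 1 over all states).
#'
#' @param tree \code{phylo} with branch lengths (substitutions/site); tips
#'   must be alignment rows.
#' @param alignment a \code{plastid_alignment} (or coercible).
#' @param model list with elements \code{rates} (6 GTR exchangeabilities,
#'   default all 1), \code{bf} (base frequencies, default equal),
#'   \code{alpha} (gamma shape, default Inf = rate homogeneity),
#'   \code{k} (categories, default 4).
#' @return log-likelihood (numeric scalar).
#' @export
log_likelihood <- function(tree, alignment, model = list()) {
  m <- as_alignment(alignment)
  rates <- model$rates %||% rep(1, 6)
  bf <- model$bf %||% rep(0.25, 4)
  alpha <- model$alpha %||% Inf
  k <- model$k %||% 4L
  if (any(rates <= 0)) stop("GTR exchangeabilities must be > 0")
  if (abs(sum(bf) - 1) > 1e-6) stop("base frequencies must sum to 1")
  if (!all(tree$tip.label %in% rownames(m)))
    stop("tree tips must be alignment rows")
  if (any(tree$edge.length < 0)) stop("negative branch length")
  tree <- stats::reorder(tree, "postorder")
  mat <- m[tree$tip.label, , drop = FALSE]
  ## site-pattern compression
  pat <- apply(mat, 2, paste, collapse = "")
  tab <- table(pat)
  upat <- names(tab)
  w <- as.numeric(tab)
  cols <- match(upat, pat)
  ntip <- length(tree$tip.label)
  npat <- length(cols)
  ## tip partials (4 x npat per tip)
  tipP <- lapply(seq_len(ntip), function(t) {
    ch <- mat[t, cols]
    out <- matrix(1, 4, npat)
    base <- match(ch, c("A", "C", "G", "T"))
    obs <- !is.na(base)
    out[, obs] <- 0
    out[cbind(base[obs], which(obs))] <- 1
    out
  })
  Q <- gtr_rate_matrix(rates, bf)
  eig <- gtr_eigen(Q, bf)
  crates <- gamma_category_rates(alpha, k)
  parent <- tree$edge[, 1]; child <- tree$edge[, 2]
  el <- tree$edge.length
  nnode <- ntip + tree$Nnode
  sitelik <- matrix(0, length(crates), npat)
  for (ci in seq_along(crates)) {
    part <- vector("list", nnode)
    part[seq_len(ntip)] <- tipP
    done <- c(rep(TRUE, ntip), rep(FALSE, tree$Nnode))
    for (e in seq_along(parent)) {
      p <- parent[e]
      P <- pmat(eig, el[e] * crates[ci])
      contrib <- P %*% part[[child[e]]]
      if (!done[p]) { part[[p]] <- contrib; done[p] <- TRUE }
      else part[[p]] <- part[[p]] * contrib
    }
    root <- parent[length(parent)]
    sitelik[ci, ] <- as.numeric(bf %*% part[[root]])
  }
  lik <- colMeans(sitelik)
  sum(w * log(lik))
}

#' Maximum-likelihood tree under GTR+Gamma with NNI search
#'
#' Starts from a neighbor-joining tree (or a supplied start tree),
#' optimizes branch lengths, GTR exchangeabilities, base frequencies and
#' the gamma shape, and searches topologies by nearest-neighbor
#' interchange (the search engine is phangorn's optim.pml). The returned
#' log-likelihood is never below the start tree's. With fewer than four
#' taxa the (unique) NJ topology is returned without search.
#'
#' @param alignment a \code{plastid_alignment}.
#' @param gamma optimize a 4-category discrete-gamma shape (default TRUE).
#' @param start optional start \code{phylo}; default NJ on JC69 distances
#'   (p distances if JC69 saturates).
#' @param rearrangement "NNI" (default) or "none" (branch lengths and
#'   model only).
#' @return object of class \code{plastid_ml}: list with \code{tree},
#'   \code{log_lik}, \code{start_log_lik}, \code{bf}, \code{gtr_rates},
#'   \code{alpha}.
#' @export
optimize_tree <- function(alignment, gamma = TRUE, start = NULL,
                          rearrangement = c("NNI", "none")) {
  rearrangement <- match.arg(rearrangement)
  m <- as_alignment(alignment)
  if (is.null(start)) {
    d <- tryCatch(pairwise_distances(m, "JC69"),
                  error = function(e) pairwise_distances(m, "p"))
    start <- nj_tree(d)
  }
  if (nrow(m) < 4L) {
    return(structure(list(tree = start, log_lik = NA_real_,
                          start_log_lik = NA_real_, bf = rep(0.25, 4),
                          gtr_rates = rep(1, 6), alpha = Inf),
                     class = "plastid_ml"))
  }
  start <- ape::unroot(start)
  start$edge.length[start$edge.length <= 0] <- 1e-8
  dat <- phangorn::phyDat(unclass(m), type = "DNA")
  k <- if (gamma) 4L else 1L
  fit0 <- phangorn::pml(start, dat, k = k, shape = 1)
  fit <- phangorn::optim.pml(
    fit0, model = "GTR", optGamma = gamma, optBf = TRUE, optQ = TRUE,
    optEdge = TRUE,
    rearrangement = if (rearrangement == "NNI") "NNI" else "none",
    control = phangorn::pml.control(trace = 0))
  tr <- fit$tree
  tr$edge.length[tr$edge.length < 0] <- 0
  structure(list(tree = tr, log_lik = as.numeric(stats::logLik(fit)),
                 start_log_lik = as.numeric(stats::logLik(fit0)),
                 bf = fit$bf, gtr_rates = fit$Q, alpha = fit$shape),
            class = "plastid_ml")
}

#' @export
print.plastid_ml <- function(x, ...) {
  cat("GTR+Gamma ML tree:", length(x$tree$tip.label), "tips, logLik =",
      format(x$log_lik), "\n")
  invisible(x)
}

#' Bootstrap trees and majority-rule consensus
#'
#' Resamples alignment columns with replacement, infers a tree per
#' replicate (NJ by default, or the full ML search), and returns the
#' majority-rule consensus containing the splits present in more than
#' \code{threshold} of the replicates, annotated with percentage support.
#'
#' @param alignment a \code{plastid_alignment}.
#' @param B number of replicates (default 100; the headline analyses in
#'   this field commonly use 1000).
#' @param threshold retention fraction, 0.5 <= threshold < 1.
#' @param seed RNG seed for reproducibility.
#' @param method "nj" or "ml" per-replicate inference.
#' @return \code{phylo} with \code{node.label} giving percent support.
#' @export
bootstrap_consensus <- function(alignment, B = 100L, threshold = 0.5,
                                seed = NULL, method = c("nj", "ml")) {
  method <- match.arg(method)
  stopifnot(B >= 1, threshold >= 0.5, threshold < 1)
  m <- as_alignment(alignment)
  if (!is.null(seed)) set.seed(seed)
  infer <- function(a) {
    if (method == "nj") {
      d <- tryCatch(pairwise_distances(a, "JC69"),
                    error = function(e) pairwise_distances(a, "p"))
      nj_tree(d)
    } else optimize_tree(a, rearrangement = "NNI")$tree
  }
  trees <- vector("list", B)
  for (b in seq_len(B)) {
    cols <- sample.int(ncol(m), ncol(m), replace = TRUE)
    trees[[b]] <- infer(as_alignment(m[, cols, drop = FALSE]))
  }
  counts <- new.env(parent = emptyenv())
  for (tr in trees) for (key in split_keys(tr))
    assign(key, (get0(key, counts) %||% 0) + 1, counts)
  if (B == 1L) {
    cons <- trees[[1]]
  } else {
    cons <- ape::consensus(trees, p = threshold + 1e-9, check.labels = TRUE)
  }
  freqs <- vapply(split_keys_of_nodes(cons), function(key) {
    if (is.na(key)) NA_real_ else 100 * ((get0(key, counts) %||% 0) / B)
  }, 0)
  cons$node.label <- ifelse(is.na(freqs), "", sprintf("%.0f", freqs))
  cons
}

## ---- splits and tree distances ------------------------------------------

## canonical non-trivial splits of an unrooted tree as character keys:
## sorted labels of the side NOT containing the lexicographically smallest
## tip, collapsed with "|"
split_sides <- function(tree) {
  labs <- tree$tip.label
  n <- length(labs)
  pp <- ape::prop.part(tree)
  anchor <- sort(labs)[1]
  sides <- list()
  for (cl in pp) {
    side <- labs[cl]
    if (length(side) < 2L || length(side) > n - 2L) next
    if (anchor %in% side) side <- setdiff(labs, side)
    if (length(side) < 2L) next
    sides[[paste(sort(side), collapse = "|")]] <- sort(side)
  }
  sides
}

split_keys <- function(tree) names(split_sides(tree))

## split key per internal node of a tree (NA for trivial/root), aligned
## with node.label order
split_keys_of_nodes <- function(tree) {
  labs <- tree$tip.label
  n <- length(labs)
  anchor <- sort(labs)[1]
  ntip <- n
  keys <- rep(NA_character_, tree$Nnode)
  for (nd in seq_len(tree$Nnode) + ntip) {
    tips <- labs[unlist(phangorn::Descendants(tree, nd, "tips"))]
    if (length(tips) < 2L || length(tips) > n - 2L) next
    side <- if (anchor %in% tips) setdiff(labs, tips) else tips
    if (length(side) < 2L) next
    keys[nd - ntip] <- paste(sort(side), collapse = "|")
  }
  keys
}

prune_to_common <- function(t1, t2) {
  shared <- intersect(t1$tip.label, t2$tip.label)
  if (length(shared) < 3L) stop("fewer than 3 shared tips")
  list(ape::keep.tip(t1, shared), ape::keep.tip(t2, shared), shared)
}

#' Robinson-Foulds distance
#'
#' Symmetric-difference count over non-trivial bipartitions, computed
#' after pruning both trees to their shared tip set. Normalized by the
#' total number of non-trivial splits in the two trees (0/0 = 0).
#'
#' @param t1,t2 \code{phylo} trees with >= 3 shared tips.
#' @return object of class \code{tree_distance}: method, raw, normalized,
#'   n_shared.
#' @export
rf_distance <- function(t1, t2) {
  pr <- prune_to_common(t1, t2)
  s1 <- split_keys(pr[[1]]); s2 <- split_keys(pr[[2]])
  raw <- length(setdiff(s1, s2)) + length(setdiff(s2, s1))
  denom <- length(s1) + length(s2)
  structure(list(method = "rf", raw = raw,
                 normalized = if (denom) raw / denom else 0,
                 n_shared = length(pr[[3]])), class = "tree_distance")
}

#' Generalized Robinson-Foulds distance (clustering-information matching)
#'
#' Splits of the two trees are paired by maximum-weight bipartite matching
#' (Hungarian algorithm) where a pair's weight is the mutual clustering
#' information (bits) of the two bipartitions of the shared tip set. The
#' distance is \code{1 - 2 S / (H1 + H2)} where S is the matching score
#' and Hk the summed clustering entropies of tree k's splits; two trees
#' with no non-trivial splits are at distance 0.
#'
#' @param t1,t2 \code{phylo} trees with >= 3 shared tips.
#' @return object of class \code{tree_distance}; \code{raw} is the
#'   unmatched information \code{(H1 + H2)/2 - S} in bits.
#' @export
generalized_rf <- function(t1, t2) {
  pr <- prune_to_common(t1, t2)
  n <- length(pr[[3]])
  sides1 <- split_sides(pr[[1]]); sides2 <- split_sides(pr[[2]])
  H1 <- sum(vapply(sides1, function(s) split_entropy(length(s), n), 0))
  H2 <- sum(vapply(sides2, function(s) split_entropy(length(s), n), 0))
  if (H1 + H2 == 0)
    return(structure(list(method = "gen_rf_matching", raw = 0,
                          normalized = 0, n_shared = n),
                     class = "tree_distance"))
  W <- matrix(0, length(sides1), length(sides2))
  for (i in seq_along(sides1)) for (j in seq_along(sides2))
    W[i, j] <- split_mutual_info(sides1[[i]], sides2[[j]], pr[[3]])
  S <- hungarian_max(W)$score
  structure(list(method = "gen_rf_matching",
                 raw = (H1 + H2) / 2 - S,
                 normalized = max(0, 1 - 2 * S / (H1 + H2)),
                 n_shared = n), class = "tree_distance")
}

#' @export
print.tree_distance <- function(x, ...) {
  cat(sprintf("%s distance: raw = %.4g, normalized = %.4g (%d shared tips)\n",
              x$method, x$raw, x$normalized, x$n_shared))
  invisible(x)
}

split_entropy <- function(a, n) {
  p <- c(a, n - a) / n
  -sum(p * log2(p))
}

## mutual clustering information (bits) of two bipartitions of `taxa`
split_mutual_info <- function(sideA, sideB, taxa) {
  n <- length(taxa)
  inA <- taxa %in% sideA
  inB <- taxa %in% sideB
  cnt <- c(sum(inA & inB), sum(inA & !inB), sum(!inA & inB), sum(!inA & !inB))
  pA <- mean(inA); pB <- mean(inB)
  marg <- c(pA * pB, pA * (1 - pB), (1 - pA) * pB, (1 - pA) * (1 - pB))
  p <- cnt / n
  sum(ifelse(p > 0, p * log2(p / marg), 0))
}

## maximum-weight bipartite matching via the Hungarian (Jonker-style
## potentials) algorithm on the padded square matrix; weights >= 0
hungarian_max <- function(W) {
  if (!length(W)) return(list(score = 0, match = integer(0)))
  n0 <- nrow(W); m0 <- ncol(W)
  n <- max(n0, m0)
  C <- matrix(max(W), n, n)
  C[seq_len(n0), seq_len(m0)] <- max(W) - W  # min-cost form, all >= 0
  INF <- .Machine$double.xmax / 4
  u <- numeric(n + 1); v <- numeric(n + 1)
  p <- integer(n + 1)  # p[j]: row matched to column j (0 = none)
  way <- integer(n + 1)
  for (i in seq_len(n)) {
    p[1] <- i
    j0 <- 1L
    minv <- rep(INF, n + 1)
    used <- rep(FALSE, n + 1)
    repeat {
      used[j0] <- TRUE
      i0 <- p[j0]; delta <- INF; j1 <- 0L
      for (j in seq_len(n) + 1L) {
        if (used[j]) next
        cur <- C[i0, j - 1L] - u[i0 + 1L] - v[j]
        if (cur < minv[j]) { minv[j] <- cur; way[j] <- j0 }
        if (minv[j] < delta) { delta <- minv[j]; j1 <- j }
      }
      for (j in seq_len(n + 1L)) {
        if (used[j]) { u[p[j] + 1L] <- u[p[j] + 1L] + delta; v[j] <- v[j] - delta }
        else minv[j] <- minv[j] - delta
      }
      j0 <- j1
      if (p[j0] == 0L) break
    }
    repeat {
      j1 <- way[j0]
      p[j0] <- p[j1]
      j0 <- j1
      if (j0 == 1L) break
    }
  }
  match <- integer(n0)
  score <- 0
  for (j in seq_len(n) + 1L) {
    r <- p[j]
    if (r >= 1 && r <= n0 && (j - 1L) <= m0) {
      match[r] <- j - 1L
      score <- score + W[r, j - 1L]
    }
  }
  list(score = score, match = match)
}
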