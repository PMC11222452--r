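## Per-site substitution-rate estimation and Townsend phylogenetic
## informativeness profiling per locus.
##
## Site rates come either from normalized Fitch parsimony step counts
## (fast, deterministic; the default) or from per-site maximum-likelihood
## scaling of a Jukes-Cantor pruning likelihood on the guide tree. Both are
## normalized to mean 1 over all sites of the locus, so net (summed)
## informativeness is comparable across loci: longer loci legitimately
## score higher.

## tip states -> bitmasks A=1 C=2 G=4 T=8, anything else = full set
.state_mask <- function(ch) {
  m <- rep(15L, length(ch))
  m[ch == "A"] <- 1L; m[ch == "C"] <- 2L
  m[ch == "G"] <- 4L; m[ch == "T"] <- 8L
  m
}

## Fitch step counts for every column of a character matrix, vectorized
## over columns. Tree must be binary (bifurcating); tips must cover rows.
fitch_counts <- function(mat, tree) {
  if (!ape::is.binary(tree)) tree <- ape::multi2di(tree)
  tree <- stats::reorder(tree, "postorder")
  ntip <- length(tree$tip.label)
  if (!all(tree$tip.label %in% rownames(mat)))
    stop("tree tip absent from alignment: ",
         paste(setdiff(tree$tip.label, rownames(mat)), collapse = ", "))
  nc <- ncol(mat)
  nnode <- ntip + tree$Nnode
  masks <- matrix(0L, nnode, nc)
  has <- logical(nnode)
  for (t in seq_len(ntip)) {
    masks[t, ] <- .state_mask(mat[tree$tip.label[t], ])
    has[t] <- TRUE
  }
  steps <- integer(nc)
  parent <- tree$edge[, 1]; child <- tree$edge[, 2]
  for (e in seq_along(parent)) {
    p <- parent[e]; cmask <- masks[child[e], ]
    if (!has[p]) { masks[p, ] <- cmask; has[p] <- TRUE }
    else {
      inter <- bitwAnd(masks[p, ], cmask)
      zero <- inter == 0L
      steps <- steps + zero
      masks[p, ] <- ifelse(zero, bitwOr(masks[p, ], cmask), inter)
    }
  }
  steps
}

#' Minimum substitution count for one site (Fitch parsimony)
#'
#' @param column named character vector of states (taxon -> base); states
#'   outside A/C/G/T count as missing (full state set).
#' @param tree a bifurcating \code{phylo} whose tips all appear in
#'   \code{column}.
#' @return integer minimum number of substitutions.
#' @export
fitch_steps <- function(column, tree) {
  mat <- matrix(toupper(column), ncol = 1,
                dimnames = list(names(column), NULL))
  fitch_counts(mat, tree)
}

#' Estimate per-site substitution rates on a guide tree
#'
#' \code{fitch_norm}: rates proportional to Fitch parsimony steps.
#' \code{ml_jc}: per-site rate maximizing the Jukes-Cantor pruning
#' likelihood with all branch lengths scaled by the rate. Both are
#' normalized to mean 1 over all sites (variable and invariant); invariant
#' sites get rate 0.
#'
#' @param alignment a \code{plastid_alignment} (or coercible).
#' @param tree guide \code{phylo}; rescaled to unit maximum root-to-tip
#'   depth internally so rates are in substitutions per unit tree depth.
#' @param method "fitch_norm" or "ml_jc".
#' @param locus locus label stored in the result.
#' @return object of class \code{site_rates}: list with \code{locus},
#'   \code{rates} (length = alignment columns), \code{raw} (unnormalized
#'   per-site estimates), \code{method}.
#' @export
estimate_site_rates <- function(alignment, tree,
                                method = c("fitch_norm", "ml_jc"),
                                locus = "locus") {
  method <- match.arg(method)
  m <- as_alignment(alignment)
  tree <- rescale_unit_depth(tree)
  raw <- switch(method,
    fitch_norm = as.numeric(fitch_counts(m, tree)),
    ml_jc = ml_jc_rates(m, tree))
  rates <- raw
  if (any(raw > 0)) rates <- raw / mean(raw)
  else warning("all sites invariant; informativeness will be 0")
  structure(list(locus = locus, rates = rates, raw = raw, method = method),
            class = "site_rates")
}

## scale edge lengths so max root-to-tip depth is 1
rescale_unit_depth <- function(tree) {
  if (is.null(tree$edge.length)) {
    tree <- ape::compute.brlen(tree)
  }
  dep <- max(ape::node.depth.edgelength(tree))
  if (dep > 0) tree$edge.length <- tree$edge.length / dep
  tree
}

## per-site ML rate under Jukes-Cantor, by one-dimensional optimization
ml_jc_rates <- function(m, tree) {
  tree <- stats::reorder(tree, "postorder")
  ntip <- length(tree$tip.label)
  parent <- tree$edge[, 1]; child <- tree$edge[, 2]
  el <- tree$edge.length
  mat <- m[tree$tip.label, , drop = FALSE]
  nc <- ncol(mat)
  variable <- fitch_counts(mat, tree) > 0L
  ## tip partial likelihoods per column, 4 x ntip, built on demand
  tip_part <- function(ch) {
    out <- matrix(1, 4, length(ch))
    base <- match(ch, c("A", "C", "G", "T"))
    obs <- !is.na(base)
    out[, obs] <- 0
    out[cbind(base[obs], which(obs))] <- 1
    out
  }
  site_loglik <- function(col_part, lambda) {
    ## col_part: 4 x ntip matrix of tip partials for this site
    nnode <- ntip + tree$Nnode
    part <- matrix(NA_real_, 4, nnode)
    part[, seq_len(ntip)] <- col_part
    done <- c(rep(TRUE, ntip), rep(FALSE, tree$Nnode))
    for (e in seq_along(parent)) {
      p <- parent[e]
      t <- el[e] * lambda
      ee <- exp(-4 * t / 3)
      pii <- 0.25 + 0.75 * ee; pij <- 0.25 * (1 - ee)
      cp <- part[, child[e]]
      contrib <- pij * sum(cp) + (pii - pij) * cp
      if (!done[p]) { part[, p] <- contrib; done[p] <- TRUE }
      else part[, p] <- part[, p] * contrib
    }
    root <- parent[length(parent)]
    log(sum(0.25 * part[, root]))
  }
  rates <- numeric(nc)
  for (s in which(variable)) {
    cp <- tip_part(mat[, s])
    opt <- stats::optimize(function(lg) site_loglik(cp, exp(lg)),
                           interval = c(log(1e-3), log(200)), maximum = TRUE)
    rates[s] <- exp(opt$maximum)
  }
  rates
}

#' Townsend phylogenetic-informativeness profile of a locus
#'
#' Per-site informativeness is the quartet form
#' \eqn{\rho(t;\lambda) = 16\lambda^2 t e^{-4\lambda t}}, peaking at
#' \eqn{t = 1/(4\lambda)}; the net profile sums over sites. Time is in
#' units of guide-tree depth; the summary is the trapezoid area of the net
#' profile on t in [0, 1].
#'
#' @param rates a \code{site_rates} object.
#' @param t_grid ordered non-negative times (default 0..1 by 0.01).
#' @return object of class \code{pi_profile}: list with \code{locus},
#'   \code{t}, \code{rho}, \code{auc}.
#' @export
pi_profile <- function(rates, t_grid = seq(0, 1, by = 0.01)) {
  stopifnot(inherits(rates, "site_rates"))
  if (any(t_grid < 0)) stop("negative time in t_grid")
  lam <- rates$rates[rates$rates > 0]
  rho <- vapply(t_grid, function(t) sum(rho_site(t, lam)), 0)
  keep <- t_grid <= 1
  structure(list(locus = rates$locus, t = t_grid, rho = rho,
                 auc = trapz(t_grid[keep], rho[keep])),
            class = "pi_profile")
}

#' Per-site quartet informativeness
#' @param t time (units of tree depth), scalar or vector.
#' @param lambda site rate(s).
#' @return informativeness value(s).
#' @export
rho_site <- function(t, lambda) 16 * lambda^2 * t * exp(-4 * lambda * t)

#' @export
print.pi_profile <- function(x, ...) {
  cat(sprintf("PI profile '%s': net area on [0,1] = %.4g (peak %.4g at t = %.3g)\n",
              x$locus, x$auc, max(x$rho), x$t[which.max(x$rho)]))
  invisible(x)
}

#' @export
plot.pi_profile <- function(x, ...) {
  graphics::plot(x$t, x$rho, type = "l", xlab = "t (tree depths)",
                 ylab = expression(rho(t)), main = x$locus, ...)
  invisible(x)
}

#' Rank loci by net phylogenetic informativeness
#'
#' @param profiles list of \code{pi_profile} objects.
#' @param k number of loci to return (default 10).
#' @return data frame: locus, auc, rank (ties broken alphabetically).
#' @export
rank_loci_by_pi <- function(profiles, k = 10L) {
  stopifnot(length(profiles) >= 1)
  df <- data.frame(locus = vapply(profiles, function(p) p$locus, ""),
                   auc = vapply(profiles, function(p) p$auc, 0),
                   stringsAsFactors = FALSE)
  df <- df[order(-df$auc, df$locus), , drop = FALSE]
  df$rank <- seq_len(nrow(df))
  rownames(df) <- NULL
  utils::head(df, k)
}
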