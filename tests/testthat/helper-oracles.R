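## Independent oracles used across the suite. These deliberately avoid the
## package's own code paths: brute-force enumeration, closed forms, and
## naive recomputation.

bases4 <- c("A", "C", "G", "T")

random_alignment <- function(n, L, gap_frac = 0, amb_frac = 0) {
  ch <- sample(bases4, n * L, replace = TRUE)
  if (gap_frac > 0) ch[sample(n * L, round(gap_frac * n * L))] <- "-"
  if (amb_frac > 0) ch[sample(n * L, round(amb_frac * n * L))] <- "N"
  m <- matrix(ch, n, L, dimnames = list(paste0("t", seq_len(n)), NULL))
  m
}

## naive per-pair, per-column pi over a window of an alignment matrix
pi_brute <- function(m, cols, deletion = "complete") {
  sub <- m[, cols, drop = FALSE]
  if (deletion == "complete") {
    keep <- apply(sub, 2, function(cc) !any(cc == "-"))
    sub <- sub[, keep, drop = FALSE]
  }
  n <- nrow(sub)
  tot <- 0; np <- 0
  for (i in seq_len(n - 1)) for (j in (i + 1):n) {
    np <- np + 1
    num <- 0; den <- 0
    for (s in seq_len(ncol(sub))) {
      a <- sub[i, s]; b <- sub[j, s]
      if (a %in% bases4 && b %in% bases4) {
        den <- den + 1
        if (a != b) num <- num + 1
      }
    }
    if (den > 0) tot <- tot + num / den
  }
  tot / np
}

## exhaustive Fitch: minimum substitutions over all internal labelings
fitch_enum <- function(column, tree) {
  tree <- ape::multi2di(tree)
  ntip <- length(tree$tip.label)
  internal <- sort(unique(tree$edge[, 1]))
  best <- Inf
  grid <- do.call(expand.grid, rep(list(bases4), length(internal)))
  for (g in seq_len(nrow(grid))) {
    lab <- as.character(unlist(grid[g, ]))
    names(lab) <- internal
    cost <- 0
    for (e in seq_len(nrow(tree$edge))) {
      p <- as.character(tree$edge[e, 1]); c0 <- tree$edge[e, 2]
      cstate <- if (c0 <= ntip) column[[tree$tip.label[c0]]] else lab[[as.character(c0)]]
      if (!(cstate %in% bases4)) next  # missing tip: free
      if (cstate != lab[[p]]) cost <- cost + 1
    }
    best <- min(best, cost)
  }
  best
}

## independent split enumeration: adjacency traversal over tree edges
splits_brute <- function(tree) {
  tree <- ape::unroot(tree)
  labs <- tree$tip.label
  n <- length(labs)
  nn <- max(tree$edge)
  adj <- vector("list", nn)
  for (e in seq_len(nrow(tree$edge))) {
    a <- tree$edge[e, 1]; b <- tree$edge[e, 2]
    adj[[a]] <- c(adj[[a]], b); adj[[b]] <- c(adj[[b]], a)
  }
  anchor <- sort(labs)[1]
  out <- character(0)
  for (e in seq_len(nrow(tree$edge))) {
    a <- tree$edge[e, 1]; b <- tree$edge[e, 2]
    ## tips reachable from b without crossing edge (a,b)
    seen <- c(a, b); queue <- b
    while (length(queue)) {
      v <- queue[1]; queue <- queue[-1]
      for (w in adj[[v]]) if (!(w %in% seen)) { seen <- c(seen, w); queue <- c(queue, w) }
    }
    side <- labs[intersect(seen[-1], seq_len(n))]
    if (length(side) < 2 || length(side) > n - 2) next
    if (anchor %in% side) side <- setdiff(labs, side)
    out <- c(out, paste(sort(side), collapse = "|"))
  }
  sort(unique(out))
}

rf_brute <- function(t1, t2) {
  s1 <- splits_brute(t1); s2 <- splits_brute(t2)
  length(setdiff(s1, s2)) + length(setdiff(s2, s1))
}

split_entropy_b <- function(a, n) { p <- c(a, n - a) / n; -sum(p * log2(p)) }

mutual_info_b <- function(sideA, sideB, taxa) {
  n <- length(taxa)
  inA <- taxa %in% sideA; inB <- taxa %in% sideB
  cnt <- c(sum(inA & inB), sum(inA & !inB), sum(!inA & inB), sum(!inA & !inB))
  pA <- mean(inA); pB <- mean(inB)
  marg <- c(pA * pB, pA * (1 - pB), (1 - pA) * pB, (1 - pA) * (1 - pB))
  p <- cnt / n
  sum(ifelse(p > 0, p * log2(p / marg), 0))
}

## generalized RF by exhaustive enumeration of all split matchings
grf_brute <- function(t1, t2) {
  taxa <- sort(intersect(t1$tip.label, t2$tip.label))
  t1 <- ape::keep.tip(t1, taxa); t2 <- ape::keep.tip(t2, taxa)
  n <- length(taxa)
  s1 <- lapply(splits_brute(t1), function(k) strsplit(k, "|", fixed = TRUE)[[1]])
  s2 <- lapply(splits_brute(t2), function(k) strsplit(k, "|", fixed = TRUE)[[1]])
  H1 <- sum(vapply(s1, function(s) split_entropy_b(length(s), n), 0))
  H2 <- sum(vapply(s2, function(s) split_entropy_b(length(s), n), 0))
  if (H1 + H2 == 0) return(0)
  ## enumerate injections from the smaller split set into the larger
  if (length(s1) > length(s2)) { tmp <- s1; s1 <- s2; s2 <- tmp }
  k1 <- length(s1); k2 <- length(s2)
  best <- 0
  if (k1 == 0) return(1)
  idx <- seq_len(k2)
  rec <- function(i, used, acc) {
    if (i > k1) { best <<- max(best, acc); return(invisible()) }
    rec(i + 1, used, acc)  # split i unmatched
    for (j in setdiff(idx, used))
      rec(i + 1, c(used, j), acc + mutual_info_b(s1[[i]], s2[[j]], taxa))
  }
  rec(1, integer(0), 0)
  max(0, 1 - 2 * best / (H1 + H2))
}

## brute-force likelihood: sum over all internal state assignments, with
## JC transition probabilities computed from the closed form
lik_enum_jc <- function(tree, mat) {
  tree <- stats::reorder(tree, "postorder")
  ntip <- length(tree$tip.label)
  internal <- sort(unique(tree$edge[, 1]))
  pjc <- function(same, t) if (same) 0.25 + 0.75 * exp(-4 * t / 3) else 0.25 * (1 - exp(-4 * t / 3))
  root <- tree$edge[nrow(tree$edge), 1]
  total_ll <- 0
  for (s in seq_len(ncol(mat))) {
    grid <- do.call(expand.grid, rep(list(bases4), length(internal)))
    sitelik <- 0
    for (g in seq_len(nrow(grid))) {
      lab <- as.character(unlist(grid[g, ])); names(lab) <- internal
      pr <- 0.25  # root prior
      ok <- TRUE
      for (e in seq_len(nrow(tree$edge))) {
        p <- unname(lab[[as.character(tree$edge[e, 1])]])
        c0 <- tree$edge[e, 2]
        cstate <- unname(if (c0 <= ntip) mat[tree$tip.label[c0], s]
                         else lab[[as.character(c0)]])
        if (!(cstate %in% bases4)) next  # missing data: marginalized below
        pr <- pr * pjc(p == cstate, tree$edge.length[e])
      }
      ## note: missing tips contribute factor sum_x P(anc -> x) = 1
      if (ok) sitelik <- sitelik + pr
    }
    ## the root state is part of `internal` labels only if root is internal
    total_ll <- total_ll + log(sitelik)
  }
  total_ll
}

## all 15 unrooted binary 5-leaf topologies
all_5leaf_trees <- function() {
  labs <- c("A", "B", "C", "D", "E")
  out <- list()
  seen <- character(0)
  combs <- combn(5, 2)
  for (i in seq_len(ncol(combs))) {
    pair1 <- labs[combs[, i]]
    rest <- setdiff(labs, pair1)
    for (j in 1:3) {
      pair2 <- rest[-j]
      single <- rest[j]
      nwk <- sprintf("((%s,%s),%s,(%s,%s));", pair1[1], pair1[2], single,
                     pair2[1], pair2[2])
      tr <- ape::read.tree(text = nwk)
      key <- paste(splits_brute(tr), collapse = ";")
      if (!(key %in% seen)) { seen <- c(seen, key); out[[length(out) + 1]] <- tr }
    }
  }
  out
}
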