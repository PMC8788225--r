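# Independent oracles used to validate the package implementations.
# These deliberately use naive algorithms (exhaustive enumeration,
# per-base expansion, direct recomputation) and never share code with
# the functions they check.

# -- brute-force minimal-cost ancestral assignment (linear cost) -------------
oracle_sankoff <- function(leaf_counts, phy, max_count) {
  ntip <- ape::Ntip(phy)
  nnode <- phy$Nnode
  states <- 0:max_count
  grid <- as.matrix(expand.grid(rep(list(states), nnode)))
  node_state <- function(node) {
    if (node <= ntip) rep(leaf_counts[[phy$tip.label[node]]], nrow(grid))
    else grid[, node - ntip]
  }
  cost <- numeric(nrow(grid))
  for (e in seq_len(nrow(phy$edge)))
    cost <- cost + abs(node_state(phy$edge[e, 1]) - node_state(phy$edge[e, 2]))
  min(cost)
}

# -- brute-force NG86 pathway enumeration for one ordered codon pair ---------
oracle_codon_pair <- function(a, b, code) {
  diff_pos <- which(strsplit(a, "")[[1]] != strsplit(b, "")[[1]])
  k <- length(diff_pos)
  if (k == 0) return(c(0, 0))
  perms <- combinat_perms(diff_pos)
  res <- matrix(NA_real_, 0, 2)
  for (p in seq_len(nrow(perms))) {
    cur <- a
    sdnd <- c(0, 0)
    blocked <- FALSE
    for (pos in perms[p, ]) {
      nxt <- cur
      substr(nxt, pos, pos) <- substr(b, pos, pos)
      if (code[[nxt]] == "*") { blocked <- TRUE; break }
      if (code[[nxt]] == code[[cur]]) sdnd[1] <- sdnd[1] + 1
      else sdnd[2] <- sdnd[2] + 1
      cur <- nxt
    }
    if (!blocked) res <- rbind(res, sdnd)
  }
  if (nrow(res) == 0) return(c(NA_real_, NA_real_))
  colMeans(res)
}

combinat_perms <- function(v) {
  if (length(v) == 1) return(matrix(v, 1, 1))
  out <- NULL
  for (i in seq_along(v)) {
    sub <- combinat_perms(v[-i])
    out <- rbind(out, cbind(v[i], sub))
  }
  out
}

# -- per-position synonymous site fraction, computed directly ----------------
oracle_syn_sites <- function(codon, code) {
  tot <- 0
  for (pos in 1:3) {
    n_syn <- 0; n_ok <- 0
    for (nt in setdiff(c("A", "C", "G", "T"), substr(codon, pos, pos))) {
      mut <- codon
      substr(mut, pos, pos) <- nt
      if (code[[mut]] == "*") next
      n_ok <- n_ok + 1
      if (code[[mut]] == code[[codon]]) n_syn <- n_syn + 1
    }
    if (n_ok > 0) tot <- tot + n_syn / n_ok
  }
  tot
}

# -- naive average-linkage agglomeration: cluster distance recomputed as the
#    mean of all original pairwise distances (no Lance-Williams update) ------
oracle_average_linkage <- function(d) {
  n <- nrow(d)
  clusters <- lapply(seq_len(n), identity)
  heights <- numeric(0)
  merges <- list()
  while (length(clusters) > 1) {
    best <- c(NA, NA); best_d <- Inf
    for (i in seq_along(clusters)) for (j in seq_along(clusters)) {
      if (i >= j) next
      dd <- mean(d[clusters[[i]], clusters[[j]]])
      if (dd < best_d - 1e-12) { best_d <- dd; best <- c(i, j) }
    }
    heights <- c(heights, best_d)
    merges <- c(merges, list(sort(unlist(clusters[best]))))
    clusters[[best[1]]] <- sort(unlist(clusters[best]))
    clusters <- clusters[-best[2]]
  }
  list(heights = heights, merges = merges)
}

# -- per-base expansion of a track over CDS intervals ------------------------
oracle_track_mean <- function(gene, track, default = 0) {
  vals <- numeric(0)
  for (i in seq_len(nrow(gene))) {
    for (p in gene$start[i]:gene$end[i]) {  # 1-based position
      tr <- track[track$scaffold == gene$scaffold[i] &
                    track$start < p & track$end >= p, , drop = FALSE]
      vals <- c(vals, if (nrow(tr) == 1) tr$value else default)
    }
  }
  mean(vals)
}

# -- Rand index between two partitions ---------------------------------------
rand_index <- function(a, b) {
  stopifnot(length(a) == length(b))
  n <- length(a)
  same_a <- outer(a, a, "==")[upper.tri(diag(n))]
  same_b <- outer(b, b, "==")[upper.tri(diag(n))]
  mean(same_a == same_b)
}
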