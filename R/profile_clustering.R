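# Hierarchical clustering of family evolutionary profiles: z-scaling, four
# distance functions x four linkage methods, multiscale-bootstrap AU
# support per clade, the Dice-normalized family subtree co-occurrence
# score accumulated over all bootstrap replicates of all combinations,
# and PCA of the profile matrix.

CLUSTER_DISTANCES <- c("pearson", "spearman", "kendall", "euclidean")
CLUSTER_LINKAGES <- c("single", "complete", "average", "median")

#' Column-wise z-scaling of a family x metric matrix
#'
#' Each metric column is centered by its mean and divided by its sample
#' standard deviation. A constant column cannot be scaled and becomes all
#' zeros, with a warning.
#'
#' @param mat numeric matrix (families x metrics).
#' @return scaled matrix.
#' @export
scale_profile_matrix <- function(mat) {
  out <- mat
  for (j in seq_len(ncol(mat))) {
    x <- mat[, j]
    s <- stats::sd(x, na.rm = TRUE)
    if (is.na(s) || s == 0) {
      warning("constant metric column '", colnames(mat)[j],
              "' scaled to zeros", call. = FALSE)
      out[, j] <- ifelse(is.na(x), NA_real_, 0)
    } else {
      out[, j] <- (x - mean(x, na.rm = TRUE)) / s
    }
  }
  out
}

#' Dissimilarity matrix between family profile rows
#'
#' Correlation methods use `d = 1 - r` computed across metrics between
#' family rows (pairwise-complete observations); `euclidean` is the L2
#' distance between rows.
#'
#' @param mat scaled family x metric matrix.
#' @param method one of `"pearson"`, `"spearman"`, `"kendall"`,
#'   `"euclidean"`.
#' @return symmetric dissimilarity matrix with zero diagonal.
#' @export
profile_distance <- function(mat, method = CLUSTER_DISTANCES) {
  method <- match.arg(method)
  if (method == "euclidean") {
    d <- as.matrix(stats::dist(mat))
  } else {
    defined <- rowSums(!is.na(mat))
    if (any(defined < 3))
      stop("row(s) with fewer than 3 defined metrics: ",
           paste(rownames(mat)[defined < 3], collapse = ", "), call. = FALSE)
    r <- suppressWarnings(
      stats::cor(t(mat), method = method, use = "pairwise.complete.obs"))
    # a zero-variance row (possible in degenerate bootstrap resamples)
    # has undefined correlation: treat as uncorrelated, d = 1
    r[is.na(r)] <- 0
    d <- 1 - r
    diag(d) <- 0
  }
  dimnames(d) <- list(rownames(mat), rownames(mat))
  d
}

# Lance-Williams update coefficients; median linkage operates on squared
# distances per the standard (Gower) formulation.
lw_update <- function(linkage, d_ik, d_jk, d_ij, n_i, n_j) {
  switch(linkage,
         single = pmin(d_ik, d_jk),
         complete = pmax(d_ik, d_jk),
         average = (n_i * d_ik + n_j * d_jk) / (n_i + n_j),
         median = 0.5 * d_ik + 0.5 * d_jk - 0.25 * d_ij)
}

#' Agglomerative hierarchical clustering with deterministic tie-breaking
#'
#' Standard agglomeration under single, complete, average or median
#' linkage (median on squared distances, heights reported on the original
#' scale; height inversions are possible for median linkage and are
#' flagged via the `inversions` attribute). Ties in the minimal distance
#' are broken by the lexicographically smallest pair of cluster labels,
#' where a cluster is labeled by its smallest member leaf.
#'
#' @param d symmetric dissimilarity matrix with dimnames.
#' @param linkage one of `"single"`, `"complete"`, `"average"`, `"median"`.
#' @return an `hclust` object.
#' @export
hcluster <- function(d, linkage = CLUSTER_LINKAGES) {
  linkage <- match.arg(linkage)
  labels <- rownames(d)
  n <- nrow(d)
  if (n < 2L) stop("need at least 2 items", call. = FALSE)
  work <- if (linkage == "median") d^2 else d
  active <- seq_len(n)
  # cluster bookkeeping: id < 0 = singleton (-leaf), > 0 = merge row
  ids <- -seq_len(n)
  sizes <- rep(1L, n)
  minlab <- labels  # smallest member label per active cluster
  merge <- matrix(0L, n - 1L, 2L)
  height <- numeric(n - 1L)
  dm <- work
  diag(dm) <- Inf
  for (step in seq_len(n - 1L)) {
    live <- which(!is.na(sizes))
    sub <- dm[live, live, drop = FALSE]
    mn <- min(sub)
    cand <- which(sub == mn, arr.ind = TRUE)
    cand <- cand[cand[, 1] < cand[, 2], , drop = FALSE]
    # deterministic tie-break: smallest (label_i, label_j) pair
    li <- minlab[live[cand[, 1]]]; lj <- minlab[live[cand[, 2]]]
    a <- pmin(li, lj); b <- pmax(li, lj)
    pick <- order(a, b)[1]
    i <- live[cand[pick, 1]]; j <- live[cand[pick, 2]]
    merge[step, ] <- sort(c(ids[i], ids[j]))
    height[step] <- if (linkage == "median") sqrt(max(mn, 0)) else mn
    for (k in setdiff(live, c(i, j))) {
      dm[i, k] <- dm[k, i] <-
        lw_update(linkage, dm[i, k], dm[j, k], dm[i, j], sizes[i], sizes[j])
    }
    sizes[i] <- sizes[i] + sizes[j]
    sizes[j] <- NA_integer_
    minlab[i] <- min(minlab[i], minlab[j])
    ids[i] <- step
    dm[j, ] <- dm[, j] <- Inf
  }
  hc <- list(merge = merge, height = height,
             order = hclust_order(merge), labels = labels,
             method = linkage, call = match.call(),
             dist.method = "user")
  class(hc) <- "hclust"
  attr(hc, "inversions") <- any(diff(height) < -1e-12)
  hc
}

# leaf order for plotting/validity: left-to-right traversal of merges
hclust_order <- function(merge) {
  walk <- function(i) {
    if (i < 0) return(-i)
    c(walk(merge[i, 1]), walk(merge[i, 2]))
  }
  walk(nrow(merge))
}

#' Leaf sets of all internal nodes of a dendrogram
#' @param hc `hclust` object.
#' @return list of sorted character vectors, one per merge (the root clade,
#'   all leaves, included last).
#' @export
dendro_clades <- function(hc) {
  n <- length(hc$labels)
  members <- vector("list", n - 1L)
  for (i in seq_len(n - 1L)) {
    get_m <- function(x) if (x < 0) hc$labels[-x] else members[[x]]
    members[[i]] <- sort(c(get_m(hc$merge[i, 1]), get_m(hc$merge[i, 2])))
  }
  members
}

# one bootstrap replicate tree: resample metric columns with replacement
boot_tree <- function(mat, cols, distance, linkage) {
  bm <- mat[, cols, drop = FALSE]
  colnames(bm) <- paste0("b", seq_along(cols))
  d <- profile_distance(bm, distance)
  hcluster(d, linkage)
}

# AU fit for one clade: weighted least squares of qnorm(1 - BP_r) on
# (sqrt(r), 1/sqrt(r)); AU = 1 - pnorm(v - c), BP smoothed at r = 1.
# Scales where the clade is present in no or in every replicate carry no
# probit information and would drag the fit toward 0.5, so they are
# excluded; when fewer than two informative scales remain the degenerate
# proportions are clamped to 1/(2B), 1 - 1/(2B) and all scales are used
# (flagged "clamped").
au_fit_one <- function(bp, scales, n_per_scale) {
  if (all(bp == 0)) return(list(au = 0, bp_fit = 0, flag = "never"))
  if (all(bp == 1)) return(list(au = 1, bp_fit = 1, flag = "always"))
  use <- bp > 0 & bp < 1
  flag <- ""
  if (sum(use) < 2) {
    use <- rep(TRUE, length(bp))
    flag <- "clamped"
  }
  bp_c <- pmin(pmax(bp[use], 1 / (2 * n_per_scale)),
               1 - 1 / (2 * n_per_scale))
  z <- stats::qnorm(1 - bp_c)
  w <- n_per_scale * stats::dnorm(z)^2 / (bp_c * (1 - bp_c))
  X <- cbind(sqrt(scales[use]), 1 / sqrt(scales[use]))
  fit <- stats::lm.fit(X * sqrt(w), z * sqrt(w))
  v <- fit$coefficients[1]; cc <- fit$coefficients[2]
  au <- 1 - stats::pnorm(v - cc)
  list(au = max(0, min(1, au)),
       bp_fit = 1 - stats::pnorm(v + cc), flag = flag)
}

#' Multiscale bootstrap support (BP/AU) for one distance-linkage combination
#'
#' Resamples the metric columns (the observations defining the family
#' distances) with replacement at each scale factor r, drawing
#' `round(r * n_metrics)` columns, reclusters, and records clade presence.
#' AU values come from a weighted least-squares fit of the
#' probit-transformed per-scale bootstrap proportions BP(r) against
#' (sqrt(r), 1/sqrt(r)); the fitted signed distance v and curvature c give
#' `AU = 1 - pnorm(v - c)`. BP is reported as the raw proportion at r = 1.
#' Clades absent (present) from every replicate at every scale are clamped
#' to AU = 0 (1) and flagged. The replicate clade co-occurrence counts
#' needed by [subtree_cooccurrence_matrix()] are accumulated on the fly.
#'
#' @param mat scaled family x metric matrix.
#' @param distance,linkage distance and linkage method names.
#' @param scales bootstrap scale factors (default 0.5..1.4).
#' @param n_per_scale replicates per scale (pvclust-style: the stated
#'   10,000 total replicates are 1,000 per scale x 10 scales).
#' @param seed integer seed.
#' @return list: `tree` (consensus `hclust` on the full data), `clades`,
#'   `bp` (per-clade proportion at r = 1), `au`, `flags`, `bp_by_scale`
#'   (clades x scales matrix), `pair_counts` (families x families replicate
#'   co-occurrence counts), `n_replicates`.
#' @export
multiscale_bootstrap <- function(mat, distance = "pearson",
                                 linkage = "average",
                                 scales = seq(0.5, 1.4, by = 0.1),
                                 n_per_scale = 1000L, seed = 1L) {
  tree <- hcluster(profile_distance(mat, distance), linkage)
  clades <- dendro_clades(tree)
  keys <- vapply(clades, paste, "", collapse = "\r")
  n_metrics <- ncol(mat)
  fams <- rownames(mat)
  hit <- matrix(0L, length(clades), length(scales),
                dimnames = list(keys, paste0("r", scales)))
  pair_counts <- matrix(0L, length(fams), length(fams),
                        dimnames = list(fams, fams))
  set.seed(seed)
  for (si in seq_along(scales)) {
    m_r <- max(2L, round(scales[si] * n_metrics))
    for (b in seq_len(n_per_scale)) {
      cols <- sample.int(n_metrics, m_r, replace = TRUE)
      bt <- boot_tree(mat, cols, distance, linkage)
      bkeys <- vapply(dendro_clades(bt), paste, "", collapse = "\r")
      hit[, si] <- hit[, si] + (keys %in% bkeys)
      pair_counts <- pair_counts + minclade_pair_matrix(bt)
    }
  }
  bp_by_scale <- hit / n_per_scale
  at1 <- which.min(abs(scales - 1))
  fits <- lapply(seq_along(clades), function(i)
    au_fit_one(bp_by_scale[i, ], scales, n_per_scale))
  list(tree = tree, clades = clades,
       bp = bp_by_scale[, at1],
       au = vapply(fits, `[[`, numeric(1), "au"),
       flags = vapply(fits, `[[`, "", "flag"),
       bp_by_scale = bp_by_scale,
       pair_counts = pair_counts,
       n_replicates = length(scales) * n_per_scale,
       distance = distance, linkage = linkage)
}

# 0/1 matrix: families i, j co-occur in this tree when one belongs to the
# other's minimal non-singleton clade (the clade of the other's parent).
minclade_pair_matrix <- function(hc) {
  labels <- hc$labels
  n <- length(labels)
  out <- matrix(0L, n, n, dimnames = list(labels, labels))
  members <- dendro_clades(hc)
  for (leaf in seq_len(n)) {
    row <- which(hc$merge == -leaf, arr.ind = TRUE)[1, 1]
    clade <- members[[row]]
    others <- setdiff(clade, labels[leaf])
    out[labels[leaf], others] <- 1L
  }
  # symmetric OR: count once per unordered pair
  pmin(out + t(out), 1L)
}

#' Dice-normalized family subtree co-occurrence scores
#'
#' Two families co-occur in a replicate tree when one belongs to the
#' other's minimal non-singleton clade. Counts are summed over all
#' replicate trees (typically across every distance-linkage combination)
#' and normalized as `2 C12 / (C1. + C2.)` where `Ci.` is family i's total
#' co-occurrence count with any family. A pair that is sister in every
#' replicate (and whose cherry never absorbs a lone leaf) scores 1; a pair
#' never found in the same minimal clade scores 0. The diagonal is 1.
#'
#' @param pair_counts accumulated co-occurrence count matrix.
#' @return `family_similarity` matrix in \[0, 1\].
#' @export
subtree_cooccurrence_matrix <- function(pair_counts) {
  if (all(pair_counts == 0))
    stop("zero replicates accumulated", call. = FALSE)
  tot <- rowSums(pair_counts)
  denom <- outer(tot, tot, "+")
  s <- ifelse(denom > 0, 2 * pair_counts / denom, 0)
  diag(s) <- 1
  class(s) <- c("family_similarity", class(s))
  s
}

#' Subtree co-occurrence score from an explicit list of replicate trees
#' @param trees list of `hclust` objects over the same leaf set.
#' @return `family_similarity` matrix.
#' @export
subtree_cooccurrence <- function(trees) {
  if (length(trees) == 0L) stop("zero replicates", call. = FALSE)
  counts <- Reduce(`+`, lapply(trees, minclade_pair_matrix))
  subtree_cooccurrence_matrix(counts)
}

#' Bootstrap clustering across all distance-linkage combinations
#'
#' Runs [multiscale_bootstrap()] for every combination and accumulates the
#' replicate co-occurrence counts into one family similarity matrix.
#'
#' @param mat scaled family x metric matrix.
#' @param distances,linkages method sets (defaults: all four of each).
#' @param scales,n_per_scale bootstrap design per combination.
#' @param seed integer seed; combination i uses `seed + i`.
#' @return list: `combinations` (list of [multiscale_bootstrap()] results,
#'   named `<distance>.<linkage>`), `similarity` (family similarity
#'   matrix), `n_replicates_total`.
#' @export
cluster_family_profiles <- function(mat, distances = CLUSTER_DISTANCES,
                                    linkages = CLUSTER_LINKAGES,
                                    scales = seq(0.5, 1.4, by = 0.1),
                                    n_per_scale = 1000L, seed = 1L) {
  combos <- expand.grid(distance = distances, linkage = linkages,
                        stringsAsFactors = FALSE)
  out <- vector("list", nrow(combos))
  names(out) <- paste(combos$distance, combos$linkage, sep = ".")
  pair_counts <- NULL
  for (i in seq_len(nrow(combos))) {
    res <- multiscale_bootstrap(mat, combos$distance[i], combos$linkage[i],
                                scales = scales, n_per_scale = n_per_scale,
                                seed = seed + i)
    out[[i]] <- res
    pair_counts <- if (is.null(pair_counts)) res$pair_counts
                   else pair_counts + res$pair_counts
  }
  list(combinations = out,
       similarity = subtree_cooccurrence_matrix(pair_counts),
       n_replicates_total = nrow(combos) * length(scales) * n_per_scale)
}

#' Bookkeeping of the clustering robustness design
#'
#' Enumerates the distance-linkage combinations and the bootstrap
#' replicate counts of the full design.
#'
#' @param distances,linkages method sets.
#' @param n_boot_per_combo bootstrap replicates per combination (default
#'   10,000 = 1,000 per scale x 10 scales).
#' @return list: `combinations` (data.frame), `n_combinations`,
#'   `n_boot_per_combo`, `n_boot_total`.
#' @export
clustering_design <- function(distances = CLUSTER_DISTANCES,
                              linkages = CLUSTER_LINKAGES,
                              n_boot_per_combo = 10000L) {
  combos <- expand.grid(distance = distances, linkage = linkages,
                        stringsAsFactors = FALSE)
  list(combinations = combos,
       n_combinations = nrow(combos),
       n_boot_per_combo = n_boot_per_combo,
       n_boot_total = nrow(combos) * n_boot_per_combo)
}

#' PCA of a family x metric profile matrix
#'
#' Thin wrapper over the standard eigendecomposition of the (optionally
#' scaled) covariance of the centered table.
#'
#' @param mat family x metric matrix (no missing values).
#' @param center,scale. passed to [stats::prcomp()].
#' @return list: `loadings` (metrics x components), `scores`
#'   (families x components), `variance_explained` (fractions summing
#'   to 1).
#' @export
pca_profiles <- function(mat, center = TRUE, scale. = FALSE) {
  if (anyNA(mat)) stop("PCA input contains missing values", call. = FALSE)
  p <- stats::prcomp(mat, center = center, scale. = scale.)
  ve <- p$sdev^2 / sum(p$sdev^2)
  list(loadings = p$rotation, scores = p$x, variance_explained = ve)
}

#' Export a dendrogram with AU/BP node support to newick
#'
#' Internal node comments carry the AU and BP values as
#' `[&au=..,bp=..]`-style labels.
#'
#' @param boot result of [multiscale_bootstrap()].
#' @param path output file.
#' @export
write_dendrogram_newick <- function(boot, path) {
  phy <- ape::as.phylo(boot$tree)
  # ape orders internal nodes by as.phylo's traversal; match clades by leaf set
  clade_key <- vapply(boot$clades, paste, "", collapse = "\r")
  node_lab <- character(phy$Nnode)
  for (ni in seq_len(phy$Nnode)) {
    tips <- sort(phy$tip.label[unlist(ape::prop.part(phy)[ni])])
    i <- match(paste(tips, collapse = "\r"), clade_key)
    if (!is.na(i))
      node_lab[ni] <- sprintf("au%.3f_bp%.3f", boot$au[i], boot$bp[i])
  }
  phy$node.label <- node_lab
  ape::write.tree(phy, file = path)
  invisible(path)
}
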