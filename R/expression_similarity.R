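# Family expression similarity on a clustered expression map: occupied
# cell/supercell sets, Jaccard co-occurrence scores, permutation nulls
# preserving cell-size and family-size marginals, a module-partition
# variant, pairing with evolutionary similarity, and graph export.

cell_id <- function(row, col, grid_cols) row * grid_cols + col

#' Occupied cell or supercell sets per family
#'
#' At cell resolution a family occupies the cells holding at least one
#' member. At supercell resolution (one supercell per cell, indexed by its
#' center) a family occupies the supercell centered at c when at least one
#' member lies in the 3x3 block centered at c; on a toroidal map the block
#' wraps at the edges.
#'
#' @param map `expression_map`.
#' @param catalog `gene_catalog` (only mapped genes contribute).
#' @param resolution `"cell"` or `"supercell"`.
#' @return named list: family -> integer vector of occupied unit ids.
#' @export
family_cell_sets <- function(map, catalog, resolution = c("cell", "supercell")) {
  resolution <- match.arg(resolution)
  cells <- map$cells
  idx <- match(catalog$gene_id, cells$gene_id)
  keep <- !is.na(idx)
  fam <- catalog$family[keep]
  row <- cells$row[idx[keep]]; col <- cells$col[idx[keep]]
  sets <- lapply(split(seq_along(fam), fam), function(i) {
    occ <- unique(cell_id(row[i], col[i], map$grid_cols))
    if (resolution == "cell") return(sort(occ))
    sort(unique(supercell_dilate(occ, map)))
  })
  sets
}

# centers whose 3x3 block covers at least one occupied cell = the 3x3
# neighborhood of each occupied cell (toroidal wrap when declared)
supercell_dilate <- function(occ, map) {
  r <- occ %/% map$grid_cols
  c_ <- occ %% map$grid_cols
  out <- integer(0)
  for (dr in -1:1) for (dc in -1:1) {
    rr <- r + dr; cc <- c_ + dc
    if (map$toroidal) {
      rr <- rr %% map$grid_rows; cc <- cc %% map$grid_cols
      out <- c(out, cell_id(rr, cc, map$grid_cols))
    } else {
      ok <- rr >= 0 & rr < map$grid_rows & cc >= 0 & cc < map$grid_cols
      out <- c(out, cell_id(rr[ok], cc[ok], map$grid_cols))
    }
  }
  unique(out)
}

#' Jaccard co-occurrence score of two occupied-unit sets
#'
#' `|A intersect B| / |A union B|`: 1 when the sets are identical, 0 when
#' disjoint; missing when either family occupies nothing.
#'
#' @param set_a,set_b unit id vectors.
#' @return score in \[0, 1\] or NA.
#' @export
cooccurrence_score <- function(set_a, set_b) {
  if (length(set_a) == 0L || length(set_b) == 0L) return(NA_real_)
  length(intersect(set_a, set_b)) / length(union(set_a, set_b))
}

#' Permutation test for a family pair's co-occurrence score
#'
#' Gene-to-cell assignments are shuffled, preserving the number of genes
#' in each cell and in each family (a random bijection of genes onto the
#' fixed multiset of cell slots). The p-value is the number of permutation
#' scores strictly greater than the observed score divided by the number
#' of permutations (`strict = FALSE` uses >=; `add_one` applies the
#' (b+1)/(m+1) correction).
#'
#' @param map `expression_map`.
#' @param catalog `gene_catalog`.
#' @param family_a,family_b family acronyms.
#' @param resolution `"cell"` or `"supercell"`.
#' @param n_perm number of permutations (>= 100).
#' @param seed integer seed.
#' @param strict strictly-greater comparison (default, as stated).
#' @param add_one (b+1)/(m+1) correction (off by default).
#' @return list: `score`, `p_value`, `n_perm`.
#' @export
cooccurrence_permutation_test <- function(map, catalog, family_a, family_b,
                                          resolution = c("cell", "supercell"),
                                          n_perm = 10000L, seed = 1L,
                                          strict = TRUE, add_one = FALSE) {
  resolution <- match.arg(resolution)
  if (n_perm < 100L) stop("n_perm must be >= 100", call. = FALSE)
  sets <- family_cell_sets(map, catalog, resolution)
  if (!family_a %in% names(sets) || !family_b %in% names(sets) ||
      length(sets[[family_a]]) == 0L || length(sets[[family_b]]) == 0L)
    return(list(score = NA_real_, p_value = NA_real_, n_perm = n_perm))
  obs <- cooccurrence_score(sets[[family_a]], sets[[family_b]])
  cells <- map$cells
  pool <- cell_id(cells$row, cells$col, map$grid_cols)  # fixed cell slots
  in_a <- catalog$gene_id[catalog$family == family_a]
  in_b <- catalog$gene_id[catalog$family == family_b]
  n_a <- sum(cells$gene_id %in% in_a)
  n_b <- sum(cells$gene_id %in% in_b)
  sc <- if (resolution == "supercell")
    function(u) sort(unique(supercell_dilate(unique(u), map))) else unique
  set.seed(seed)
  b <- 0L
  for (i in seq_len(n_perm)) {
    draw <- sample(pool, n_a + n_b)
    s <- cooccurrence_score(sc(draw[seq_len(n_a)]),
                            sc(draw[n_a + seq_len(n_b)]))
    b <- b + if (strict) (s > obs) else (s >= obs)
  }
  p <- if (add_one) (b + 1) / (n_perm + 1) else b / n_perm
  list(score = obs, p_value = p, n_perm = n_perm)
}

#' Co-occurrence scores and p-values for all family pairs
#'
#' @param map `expression_map`.
#' @param catalog `gene_catalog`.
#' @param resolution `"cell"` or `"supercell"`.
#' @param n_perm,seed permutation design; pair k uses `seed + k`.
#' @param strict,add_one see [cooccurrence_permutation_test()].
#' @return `cooccurrence_table` data.frame: `family_a`, `family_b`,
#'   `score`, `p_value`, `resolution`, `n_perm`, `seed`.
#' @export
family_cooccurrence_table <- function(map, catalog,
                                      resolution = c("cell", "supercell"),
                                      n_perm = 10000L, seed = 1L,
                                      strict = TRUE, add_one = FALSE) {
  resolution <- match.arg(resolution)
  fams <- sort(unique(catalog$family))
  pairs <- utils::combn(fams, 2)
  rows <- vector("list", ncol(pairs))
  for (k in seq_len(ncol(pairs))) {
    r <- cooccurrence_permutation_test(map, catalog, pairs[1, k], pairs[2, k],
                                       resolution = resolution,
                                       n_perm = n_perm, seed = seed + k,
                                       strict = strict, add_one = add_one)
    rows[[k]] <- data.frame(family_a = pairs[1, k], family_b = pairs[2, k],
                            score = r$score, p_value = r$p_value,
                            resolution = resolution, n_perm = n_perm,
                            seed = seed + k, stringsAsFactors = FALSE)
  }
  out <- do.call(rbind, rows)
  class(out) <- c("cooccurrence_table", "data.frame")
  out
}

#' Module-resolution co-occurrence (module membership as the unit)
#'
#' Identical scoring and permutation machinery with coexpression modules
#' instead of map cells; there is no supercell notion. Declaring every
#' cell of a map as its own module reproduces the cell-resolution result.
#'
#' @param partition named character/integer vector: gene -> module.
#' @param catalog `gene_catalog`.
#' @param n_perm,seed permutation design.
#' @param strict,add_one see [cooccurrence_permutation_test()].
#' @return `cooccurrence_table` with resolution `"module"`.
#' @export
module_cooccurrence <- function(partition, catalog, n_perm = 10000L,
                                seed = 1L, strict = TRUE, add_one = FALSE) {
  modules <- sort(unique(as.character(partition)))
  cells <- data.frame(gene_id = names(partition),
                      row = 0L,
                      col = match(as.character(partition), modules) - 1L,
                      stringsAsFactors = FALSE)
  map <- expression_map(cells, grid_rows = 1L, grid_cols = length(modules),
                        toroidal = FALSE)
  out <- family_cooccurrence_table(map, catalog, resolution = "cell",
                                   n_perm = n_perm, seed = seed,
                                   strict = strict, add_one = add_one)
  out$resolution <- "module"
  out
}

#' Lightweight coexpression module partition from an expression matrix
#'
#' Hierarchical clustering (Pearson distance, average linkage) of gene
#' expression rows restricted to a condition subset, cut at `k` modules or
#' at height `h`. Constant-expression genes cannot be correlated and are
#' assigned to an `"unclustered"` module. This is a deliberately simple
#' substitute for weighted correlation network module detection.
#'
#' @param expr genes x conditions matrix.
#' @param conditions column subset (names or indices); >= 2 required.
#' @param k number of modules (default) or `h` cut height.
#' @param h optional cut height on the 1 - r scale.
#' @return named character vector: gene -> module (`"M1"`, `"M2"`, ...,
#'   `"unclustered"`).
#' @export
expression_partition_from_matrix <- function(expr, conditions = colnames(expr),
                                             k = NULL, h = NULL) {
  sub <- expr[, conditions, drop = FALSE]
  if (ncol(sub) < 2L) stop("need >= 2 conditions", call. = FALSE)
  v <- apply(sub, 1, stats::sd)
  constant <- is.na(v) | v == 0
  out <- stats::setNames(rep("unclustered", nrow(sub)), rownames(sub))
  varying <- sub[!constant, , drop = FALSE]
  if (nrow(varying) >= 2L) {
    d <- 1 - stats::cor(t(varying))
    hc <- stats::hclust(stats::as.dist(d), method = "average")
    if (is.null(k) && is.null(h)) k <- 2L
    grp <- if (!is.null(k)) stats::cutree(hc, k = min(k, nrow(varying)))
           else stats::cutree(hc, h = h)
    out[rownames(varying)] <- paste0("M", grp)
  }
  out
}

#' Pair evolutionary similarity with expression similarity per family pair
#'
#' One row per unordered family pair present in both inputs; pairs absent
#' from either are dropped (and reported via the `dropped` attribute).
#' Significance is flagged at `p < 0.05`.
#'
#' @param evo `family_similarity` matrix ([subtree_cooccurrence_matrix()]).
#' @param expr `cooccurrence_table`.
#' @return data.frame: `family_a`, `family_b`, `evo_score`, `expr_score`,
#'   `expr_p`, `resolution`, `significant`.
#' @export
evo_expr_pairing <- function(evo, expr) {
  fams <- rownames(evo)
  in_both <- expr$family_a %in% fams & expr$family_b %in% fams &
    !is.na(expr$score)
  dropped <- expr[!in_both, c("family_a", "family_b")]
  kept <- expr[in_both, , drop = FALSE]
  out <- data.frame(family_a = kept$family_a, family_b = kept$family_b,
                    evo_score = evo[cbind(kept$family_a, kept$family_b)],
                    expr_score = kept$score, expr_p = kept$p_value,
                    resolution = kept$resolution,
                    significant = !is.na(kept$p_value) & kept$p_value < 0.05,
                    stringsAsFactors = FALSE)
  rownames(out) <- NULL
  attr(out, "dropped") <- dropped
  out
}

#' Export a family co-occurrence table as a DOT graph
#'
#' Nodes are families; edges connect pairs whose p-value falls below the
#' loosest threshold, with a `class` attribute naming the tightest
#' threshold met (e.g. `"p<0.005"`). No layout coordinates are written.
#'
#' @param table `cooccurrence_table`.
#' @param path output `.dot` file.
#' @param thresholds descending significance thresholds.
#' @return number of edges written, invisibly.
#' @export
export_similarity_graph <- function(table, path,
                                    thresholds = c(0.05, 0.01, 0.005)) {
  thresholds <- sort(thresholds, decreasing = TRUE)
  fams <- sort(unique(c(table$family_a, table$family_b)))
  sig <- table[!is.na(table$p_value) & table$p_value < max(thresholds), ,
               drop = FALSE]
  cls <- vapply(sig$p_value, function(p)
    paste0("p<", min(thresholds[p < thresholds])), "")
  lines <- c("graph family_coexpression {",
             sprintf("  \"%s\";", fams),
             if (nrow(sig) > 0)
               sprintf("  \"%s\" -- \"%s\" [class=\"%s\", p=%g, score=%g];",
                       sig$family_a, sig$family_b, cls, sig$p_value, sig$score),
             "}")
  writeLines(lines, path)
  invisible(nrow(sig))
}
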