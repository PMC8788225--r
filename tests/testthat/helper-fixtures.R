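# Small in-code fixtures shared across test files.

toy_tree <- function() species_tree(ape::read.tree(text = "((A:1,B:1):1,C:2);"))

toy_orthology <- function() {
  members <- data.frame(
    og_id = c("og1", "og1", "og1", "og2", "og2", "og3", "og3", "og3", "og3"),
    gene_id = c("a1", "b1", "c1", "a2", "b2", "a3", "a3b", "b3", "c3"),
    species = c("A", "B", "C", "A", "B", "A", "A", "B", "C"),
    stringsAsFactors = FALSE)
  orthology_table(members, c("A", "B", "C"))
}

# two species, 5 single-copy OGs, one translocation in s2 (O2 moved last)
toy_synteny <- function() {
  og <- paste0("O", 1:5)
  members <- rbind(
    data.frame(og_id = og, gene_id = paste0("g", 1:5), species = "s1"),
    data.frame(og_id = og, gene_id = paste0("h", 1:5), species = "s2"))
  orth <- orthology_table(members, c("s1", "s2"))
  orders <- gene_orders(rbind(
    data.frame(species = "s1", scaffold = "c1", position = 1:5,
               gene_id = paste0("g", 1:5)),
    data.frame(species = "s2", scaffold = "c1", position = 1:5,
               gene_id = paste0("h", c(1, 3, 4, 5, 2)))))
  list(orthology = orth, orders = orders)
}

# family x metric matrix with two sign-pattern blocks (Pearson-separable)
planted_block_matrix <- function(n_per_block = 5, n_metrics = 18, noise = 0.3,
                                 seed = 1) {
  set.seed(seed)
  pat <- rep(c(1, -1), length.out = n_metrics)
  m <- rbind(
    matrix(rep(pat, each = n_per_block), n_per_block, n_metrics) +
      rnorm(n_per_block * n_metrics, 0, noise),
    matrix(rep(-pat, each = n_per_block), n_per_block, n_metrics) +
      rnorm(n_per_block * n_metrics, 0, noise))
  dimnames(m) <- list(sprintf("F%02d", seq_len(2 * n_per_block)),
                      sprintf("m%02d", seq_len(n_metrics)))
  m
}

# hclust tree built from a crafted distance matrix (single linkage)
tree_from_dist <- function(d_entries, labels) {
  n <- length(labels)
  d <- matrix(5, n, n, dimnames = list(labels, labels))
  diag(d) <- 0
  for (e in d_entries) d[e[[1]], e[[2]]] <- d[e[[2]], e[[1]]] <- e[[3]]
  hcluster(d, "single")
}
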