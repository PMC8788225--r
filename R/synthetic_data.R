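# Seeded generators for every pipeline input, each carrying a ground-truth
# record so downstream estimators can be validated without external data:
# ultrametric trees, copy-number evolution by gain/loss events, codon
# substitution with a controlled nonsynonymous acceptance ratio, Poisson
# SNP counts, piecewise-constant conservation tracks, gene orders with
# translocations, and a toroidal expression map with planted family
# co-clustering.

#' Simulate a random ultrametric species tree
#'
#' Coalescent-shaped topology rescaled so the root sits at `root_age` My.
#'
#' @param n_leaves number of species (>= 2).
#' @param root_age root age in My.
#' @param seed integer seed.
#' @return `species_tree`.
#' @export
simulate_species_tree <- function(n_leaves, root_age = 100, seed = 1L) {
  if (n_leaves < 2L) stop("need >= 2 leaves", call. = FALSE)
  set.seed(seed)
  phy <- ape::rcoal(n_leaves, tip.label = sprintf("sp%02d", seq_len(n_leaves)))
  depth <- max(ape::node.depth.edgelength(phy))
  phy$edge.length <- phy$edge.length * root_age / depth
  species_tree(phy)
}

# gain/loss Gillespie walk along one branch: state k, total rate
# (lambda + mu) * k, gain with probability lambda/(lambda+mu), absorbing
# at 0. Returns final count and the signed event tally.
evolve_branch <- function(k, len, gain_rate, loss_rate) {
  gains <- 0L; losses <- 0L
  t <- 0
  total_rate <- (gain_rate + loss_rate)
  while (k > 0L) {
    if (total_rate == 0) break
    t <- t + stats::rexp(1, rate = total_rate * k)
    if (t > len) break
    if (stats::runif(1) < gain_rate / total_rate) {
      k <- k + 1L; gains <- gains + 1L
    } else {
      k <- k - 1L; losses <- losses + 1L
    }
  }
  list(k = k, gains = gains, losses = losses)
}

#' Simulate orthology by copy-number evolution along a tree
#'
#' Each OG starts at the root with `root_count` copies and evolves along
#' every branch by a continuous-time gain/loss process (total event rate
#' `(gain_rate + loss_rate) * k`, gain with probability
#' `gain_rate / (gain_rate + loss_rate)`, absorbing at zero). Leaf counts
#' are emitted as an orthology table with synthetic gene identifiers; OGs
#' extinct in all species are dropped (their number is recorded). The
#' truth record keeps per-OG per-branch net changes.
#'
#' @param tree `species_tree`.
#' @param n_ogs number of OGs to simulate.
#' @param gain_rate,loss_rate events per My per copy.
#' @param root_count starting copy number (integer, or a function of no
#'   arguments returning one).
#' @param seed integer seed.
#' @return list: `orthology` (`orthology_table`), `truth` (data.frame
#'   `og_id`, `branch`, `net_change`, plus leaf/root counts attributes),
#'   `n_extinct`.
#' @export
simulate_orthology <- function(tree, n_ogs = 100L, gain_rate = 0.002,
                               loss_rate = 0.002, root_count = 1L,
                               seed = 1L) {
  set.seed(seed)
  phy <- tree$phylo
  ntip <- ape::Ntip(phy)
  po <- ape::reorder.phylo(phy, "postorder")
  pre_edges <- po$edge[rev(seq_len(nrow(po$edge))), , drop = FALSE]
  pre_lens <- po$edge.length[rev(seq_len(nrow(po$edge)))]
  labels <- branch_labels(tree)
  lab_of_child <- stats::setNames(labels, tree$phylo$edge[, 2])
  members <- list(); truth <- list(); n_extinct <- 0L
  root_draw <- if (is.function(root_count)) root_count else function() root_count
  for (g in seq_len(n_ogs)) {
    og <- sprintf("OG%04d", g)
    state <- integer(ntip + phy$Nnode)
    state[ntip + 1L] <- as.integer(root_draw())
    net <- integer(nrow(pre_edges))
    for (e in seq_len(nrow(pre_edges))) {
      parent <- pre_edges[e, 1]; child <- pre_edges[e, 2]
      ev <- evolve_branch(state[parent], pre_lens[e], gain_rate, loss_rate)
      state[child] <- ev$k
      net[e] <- ev$gains - ev$losses
    }
    leaf_counts <- stats::setNames(state[seq_len(ntip)], phy$tip.label)
    if (all(leaf_counts == 0L)) { n_extinct <- n_extinct + 1L; next }
    rows <- lapply(names(leaf_counts)[leaf_counts > 0], function(sp) {
      data.frame(og_id = og,
                 gene_id = sprintf("%s_%s_g%d", og, sp, seq_len(leaf_counts[[sp]])),
                 species = sp, stringsAsFactors = FALSE)
    })
    members[[og]] <- do.call(rbind, rows)
    truth[[og]] <- data.frame(og_id = og,
                              branch = lab_of_child[as.character(pre_edges[, 2])],
                              net_change = net, stringsAsFactors = FALSE)
  }
  if (length(members) == 0L) stop("all simulated OGs went extinct", call. = FALSE)
  orth <- orthology_table(do.call(rbind, members), phy$tip.label)
  truth_df <- do.call(rbind, truth)
  rownames(truth_df) <- NULL
  list(orthology = orth, truth = truth_df, n_extinct = n_extinct)
}

random_sense_codons <- function(n, code) {
  sense <- names(code)[code != "*"]
  sample(sense, n, replace = TRUE)
}

#' Simulate a codon alignment under a star tree with acceptance ratio omega
#'
#' From a random stop-free ancestor, each lineage receives
#' `Poisson(branch_mutations)` single-nucleotide proposals at random
#' positions: synonymous changes are always accepted, nonsynonymous
#' changes are accepted with probability `omega`, and stop-producing
#' changes never. The truth record counts realized synonymous and
#' nonsynonymous substitutions per lineage.
#'
#' @param n_taxa number of sequences.
#' @param n_codons alignment length in codons.
#' @param omega nonsynonymous acceptance probability.
#' @param branch_mutations expected proposals per lineage.
#' @param seed integer seed.
#' @param code genetic code table.
#' @return list: `alignment` (named character vector), `truth` (data.frame
#'   `taxon`, `n_syn_sub`, `n_nonsyn_sub`), `omega`.
#' @export
simulate_codon_alignment <- function(n_taxa = 4L, n_codons = 300L,
                                     omega = 0.5, branch_mutations = 30,
                                     seed = 1L,
                                     code = standard_genetic_code()) {
  set.seed(seed)
  anc <- random_sense_codons(n_codons, code)
  seqs <- character(n_taxa); nsyn <- integer(n_taxa); nnon <- integer(n_taxa)
  for (tx in seq_len(n_taxa)) {
    cods <- anc
    n_prop <- stats::rpois(1, branch_mutations)
    for (p in seq_len(n_prop)) {
      ci <- sample.int(n_codons, 1)
      pos <- sample.int(3L, 1)
      old <- cods[ci]
      nt <- sample(setdiff(NUCS, substr(old, pos, pos)), 1)
      new <- old
      substr(new, pos, pos) <- nt
      if (code[[new]] == "*") next
      if (code[[new]] == code[[old]]) {
        cods[ci] <- new; nsyn[tx] <- nsyn[tx] + 1L
      } else if (stats::runif(1) < omega) {
        cods[ci] <- new; nnon[tx] <- nnon[tx] + 1L
      }
    }
    seqs[tx] <- paste(cods, collapse = "")
  }
  names(seqs) <- sprintf("tx%02d", seq_len(n_taxa))
  list(alignment = seqs,
       truth = data.frame(taxon = names(seqs), n_syn_sub = nsyn,
                          n_nonsyn_sub = nnon, stringsAsFactors = FALSE),
       omega = omega)
}

#' Simulate per-species gene orders with random translocations
#'
#' All species start from a shared ancestral order (the OG order of the
#' orthology table, multicopy genes adjacent); each species then undergoes
#' `n_translocations` single-gene moves to random positions. Gene content
#' is preserved by construction.
#'
#' @param orthology `orthology_table`.
#' @param n_translocations moves per species.
#' @param seed integer seed.
#' @param scaffold scaffold name used for all genes.
#' @return list: `orders` (`gene_orders`), `truth` (moves per species).
#' @export
simulate_genome_orders <- function(orthology, n_translocations = 0L,
                                   seed = 1L, scaffold = "chr1") {
  set.seed(seed)
  mem <- orthology$members
  og_rank <- match(mem$og_id, orthology$og_ids)
  rows <- list()
  for (sp in orthology$species) {
    genes <- mem$gene_id[mem$species == sp][order(og_rank[mem$species == sp])]
    if (length(genes) == 0L) next
    for (t in seq_len(n_translocations)) {
      if (length(genes) < 2L) break
      from <- sample.int(length(genes), 1)
      g <- genes[from]
      genes <- genes[-from]
      to <- sample.int(length(genes) + 1L, 1)
      genes <- append(genes, g, after = to - 1L)
    }
    rows[[sp]] <- data.frame(species = sp, scaffold = scaffold,
                             position = seq_along(genes), gene_id = genes,
                             stringsAsFactors = FALSE)
  }
  list(orders = gene_orders(do.call(rbind, rows)),
       truth = list(n_translocations = n_translocations, seed = seed))
}

#' Simulate SNP counts and conservation tracks for a set of genes
#'
#' SNP counts are Poisson with per-nucleotide rates over each gene's CDS
#' length. Tracks are piecewise constant over the gene span with segment
#' values drawn from `track_profile` (recycled).
#'
#' @param n_genes number of genes.
#' @param cds_length CDS length per gene (nt, divisible by 3; recycled).
#' @param syn_rate,nonsyn_rate SNPs per nucleotide.
#' @param track_profile numeric vector of segment values for the PHC-style
#'   track (one segment per gene span division).
#' @param seed integer seed.
#' @param scaffold scaffold name.
#' @return list: `snps` (SNP table), `models` (`gene_models`), `track`
#'   (`nucleotide_track`), `truth` (rates).
#' @export
simulate_snps_tracks <- function(n_genes = 100L, cds_length = 1500L,
                                 syn_rate = 0.02, nonsyn_rate = 0.005,
                                 track_profile = c(0.7), seed = 1L,
                                 scaffold = "chr1") {
  set.seed(seed)
  len <- rep_len(cds_length, n_genes)
  gene_id <- sprintf("gene%04d", seq_len(n_genes))
  snps <- data.frame(gene_id = gene_id,
                     n_syn = stats::rpois(n_genes, syn_rate * len),
                     n_nonsyn = stats::rpois(n_genes, nonsyn_rate * len),
                     cds_length = len, stringsAsFactors = FALSE)
  starts <- cumsum(c(1L, utils::head(len, -1) + 100L))  # 100 nt gaps
  models <- gene_models(data.frame(gene_id = gene_id, scaffold = scaffold,
                                   strand = "+", start = starts,
                                   end = starts + len - 1L,
                                   stringsAsFactors = FALSE))
  seg <- lapply(seq_len(n_genes), function(i) {
    vals <- rep_len(track_profile, max(1L, length(track_profile)))
    bounds <- round(seq(starts[i] - 1L, starts[i] + len[i] - 1L,
                        length.out = length(vals) + 1L))
    data.frame(scaffold = scaffold, start = bounds[-length(bounds)],
               end = bounds[-1], value = vals, stringsAsFactors = FALSE)
  })
  seg <- do.call(rbind, seg)
  seg <- seg[seg$end > seg$start, , drop = FALSE]
  list(snps = snp_table(snps), models = models,
       track = nucleotide_track(seg, range = c(0, 1), default = 0),
       truth = list(syn_rate = syn_rate, nonsyn_rate = nonsyn_rate,
                    expected_nsp = nonsyn_rate / (syn_rate + nonsyn_rate)))
}

#' Simulate a toroidal expression map with planted family co-clustering
#'
#' Non-planted genes fall uniformly over the grid. For each planted family
#' pair a small shared cell subset is chosen; every gene of both families
#' lands inside the shared subset with probability `rho` and uniformly
#' otherwise (`rho = 1`: identical subsets; `rho = 0`: independent of the
#' plant).
#'
#' @param families named integer vector of family sizes.
#' @param grid_rows,grid_cols grid dimensions (default 30 x 30).
#' @param planted_pairs list of `list(pair = c(f1, f2), rho = , n_cells = )`.
#' @param n_background extra uncataloged genes filling the map.
#' @param seed integer seed.
#' @return list: `map` (`expression_map`), `catalog` (`gene_catalog`),
#'   `truth` (planted subsets).
#' @export
simulate_expression_map <- function(families, grid_rows = 30L, grid_cols = 30L,
                                    planted_pairs = list(),
                                    n_background = 500L, seed = 1L) {
  set.seed(seed)
  n_cells <- grid_rows * grid_cols
  planted_sets <- list()
  rho_of <- stats::setNames(rep(0, length(families)), names(families))
  subset_of <- stats::setNames(vector("list", length(families)), names(families))
  for (pp in planted_pairs) {
    cells_shared <- sample.int(n_cells, pp$n_cells %||% 3L) - 1L
    for (f in pp$pair) {
      rho_of[f] <- pp$rho
      subset_of[[f]] <- cells_shared
    }
    planted_sets[[paste(pp$pair, collapse = "-")]] <- cells_shared
  }
  rows <- list(); cat_rows <- list()
  for (f in names(families)) {
    ids <- sprintf("%s_gene%03d", f, seq_len(families[[f]]))
    cell <- integer(families[[f]])
    for (i in seq_along(cell)) {
      cell[i] <- if (!is.null(subset_of[[f]]) && stats::runif(1) < rho_of[f])
        sample(subset_of[[f]], 1) else sample.int(n_cells, 1) - 1L
    }
    rows[[f]] <- data.frame(gene_id = ids, row = cell %/% grid_cols,
                            col = cell %% grid_cols, stringsAsFactors = FALSE)
    cat_rows[[f]] <- data.frame(gene_id = ids, family = f, species = "sp01",
                                stringsAsFactors = FALSE)
  }
  if (n_background > 0L) {
    cell <- sample.int(n_cells, n_background, replace = TRUE) - 1L
    rows[["bg"]] <- data.frame(gene_id = sprintf("bg_gene%04d", seq_len(n_background)),
                               row = cell %/% grid_cols, col = cell %% grid_cols,
                               stringsAsFactors = FALSE)
  }
  map <- expression_map(do.call(rbind, rows), grid_rows, grid_cols,
                        toroidal = TRUE)
  list(map = map,
       catalog = gene_catalog(do.call(rbind, cat_rows)),
       truth = list(planted = planted_sets, seed = seed))
}

#' The packaged immune gene family catalog fixture
#'
#' Per-family gene and OG counts for the mosquito and fly immunity gene
#' catalogs (36 families), as shipped in `inst/extdata`.
#'
#' @return data.frame: `family`, `description`, `ag_genes`, `ag_ogs`,
#'   `dm_genes`, `dm_ogs`.
#' @export
table2_fixture <- function() {
  path <- system.file("extdata", "immune_catalog_table2.tsv",
                      package = "evoprofiler", mustWork = TRUE)
  utils::read.delim(path, stringsAsFactors = FALSE)
}

#' Instantiate a synthetic catalog + orthology realizing the fixture counts
#'
#' Generates synthetic gene and OG identifiers so that each family has
#' exactly the fixture's per-species gene and OG counts (gene identifiers
#' are synthetic; the real catalogs do not print them). Genes are spread
#' over the family's OGs round-robin so every OG is non-empty.
#'
#' @param species_column `"ag"` (mosquito) or `"dm"` (fly).
#' @param species_name species label used in the output.
#' @return list: `catalog` (`gene_catalog`), `members` (orthology
#'   membership data.frame restricted to this species).
#' @export
instantiate_catalog <- function(species_column = c("ag", "dm"),
                                species_name = NULL) {
  species_column <- match.arg(species_column)
  fix <- table2_fixture()
  genes_col <- paste0(species_column, "_genes")
  ogs_col <- paste0(species_column, "_ogs")
  species_name <- species_name %||%
    if (species_column == "ag") "anopheles_gambiae" else "drosophila_melanogaster"
  cat_rows <- list(); mem_rows <- list()
  for (i in seq_len(nrow(fix))) {
    n_genes <- fix[[genes_col]][i]; n_ogs <- fix[[ogs_col]][i]
    if (n_genes == 0L) next
    fam <- fix$family[i]
    ids <- sprintf("%s_%s_g%03d", tolower(fam), species_column, seq_len(n_genes))
    ogs <- sprintf("%s_%s_og%03d", tolower(fam), species_column,
                   rep_len(seq_len(n_ogs), n_genes))
    cat_rows[[fam]] <- data.frame(gene_id = ids, family = fam,
                                  species = species_name,
                                  stringsAsFactors = FALSE)
    mem_rows[[fam]] <- data.frame(og_id = ogs, gene_id = ids,
                                  species = species_name,
                                  stringsAsFactors = FALSE)
  }
  list(catalog = gene_catalog(do.call(rbind, cat_rows)),
       members = do.call(rbind, mem_rows))
}

#' Write a complete synthetic input bundle to a directory
#'
#' Generates every pipeline input under one seed and writes them in the
#' standard formats plus a plain-text truth summary.
#'
#' @param out_dir output directory (created if needed).
#' @param seed integer master seed.
#' @param n_species,n_ogs,n_families bundle dimensions.
#' @return list of file paths, invisibly; the generated objects as value.
#' @export
simulate_bundle <- function(out_dir, seed = 1L, n_species = 8L,
                            n_ogs = 60L, n_families = 6L) {
  dir.create(out_dir, showWarnings = FALSE, recursive = TRUE)
  tree <- simulate_species_tree(n_species, root_age = 100, seed = seed)
  sim <- simulate_orthology(tree, n_ogs = n_ogs, gain_rate = 0.003,
                            loss_rate = 0.003, root_count = 1L,
                            seed = seed + 1L)
  orders <- simulate_genome_orders(sim$orthology, n_translocations = 2L,
                                   seed = seed + 2L)
  # catalog: first species' genes of the first n_families * k OGs
  set.seed(seed + 3L)
  fams <- sprintf("FAM%02d", seq_len(n_families))
  mem <- sim$orthology$members
  og_fam <- stats::setNames(sample(fams, length(sim$orthology$og_ids),
                                   replace = TRUE), sim$orthology$og_ids)
  catalog <- gene_catalog(data.frame(gene_id = mem$gene_id,
                                     family = og_fam[mem$og_id],
                                     species = mem$species,
                                     stringsAsFactors = FALSE))
  st <- simulate_snps_tracks(n_genes = nrow(mem), seed = seed + 4L)
  id_map <- stats::setNames(mem$gene_id, st$snps$gene_id)
  st$snps$gene_id <- mem$gene_id
  st$models$gene_id <- id_map[st$models$gene_id]
  fam_sizes <- stats::setNames(rep(8L, n_families), fams)
  em <- simulate_expression_map(fam_sizes, planted_pairs = list(
    list(pair = fams[1:2], rho = 0.9, n_cells = 3L)), seed = seed + 5L)
  # one catalog covering both the orthology genes and the mapped genes
  catalog <- gene_catalog(rbind(as.data.frame(catalog),
                                as.data.frame(em$catalog)))
  paths <- list(
    tree = write_species_tree(tree, file.path(out_dir, "species_tree.nwk")),
    orthology = write_orthology(sim$orthology, file.path(out_dir, "orthology.tsv")),
    orders = write_gene_orders(orders$orders, file.path(out_dir, "gene_orders.tsv")),
    catalog = write_tsv(as.data.frame(catalog), file.path(out_dir, "catalog.tsv")),
    snps = write_tsv(st$snps, file.path(out_dir, "snps.tsv")),
    models = write_gene_models(st$models, file.path(out_dir, "genes.gff3")),
    track = write_track(st$track, file.path(out_dir, "phastcons.bedgraph")),
    map = write_expression_map(em$map, file.path(out_dir, "expression_map.tsv")))
  writeLines(c(paste("seed", seed),
               paste("n_extinct_ogs", sim$n_extinct),
               paste("expected_nsp", st$truth$expected_nsp)),
             file.path(out_dir, "truth.txt"))
  invisible(list(paths = paths, tree = tree, orthology = sim$orthology,
                 orders = orders$orders, catalog = catalog, snps = st$snps,
                 models = st$models, track = st$track, map = em$map,
                 truth = list(orthology = sim$truth, expression = em$truth)))
}
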