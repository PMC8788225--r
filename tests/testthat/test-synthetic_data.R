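test_that("simulated species trees are seeded, ultrametric, and scaled", {
  t2 <- simulate_species_tree(2, 50, seed = 1)
  expect_equal(t2$n_tips, 2)
  expect_equal(t2$root_age, 50)
  expect_equal(unname(t2$node_age[1:2]), c(0, 0))

  # invariant sweep over seeds
  for (s in 1:20) {
    tr <- simulate_species_tree(sample(3:12, 1), 100, seed = s)
    expect_equal(unname(tr$node_age[seq_len(tr$n_tips)]),
                 rep(0, tr$n_tips), tolerance = 1e-8)
    expect_equal(tr$root_age, 100, tolerance = 1e-8)
    expect_false(anyDuplicated(tr$phylo$tip.label) > 0)
  }

  a <- simulate_species_tree(10, 100, seed = 5)
  b <- simulate_species_tree(10, 100, seed = 5)
  expect_identical(ape::write.tree(a$phylo), ape::write.tree(b$phylo))
})

test_that("orthology simulation respects rates and reconciles truth", {
  tree <- simulate_species_tree(6, 100, seed = 2)
  # zero rates: all leaf counts equal the root count
  sim0 <- simulate_orthology(tree, n_ogs = 20, gain_rate = 0, loss_rate = 0,
                             root_count = 1L, seed = 3)
  expect_true(all(sim0$orthology$counts == 1))
  expect_equal(og_metrics(sim0$orthology, tree)$DUP, rep(0, 20))

  # gain-dominated: mean ACN exceeds the root count
  simg <- simulate_orthology(tree, n_ogs = 300, gain_rate = 0.004,
                             loss_rate = 0.0005, root_count = 1L, seed = 4)
  expect_gt(mean(og_metrics(simg$orthology, tree)$ACN), 1)

  # truth bookkeeping: root count + net changes along the path = leaf count
  sim <- simulate_orthology(tree, n_ogs = 50, gain_rate = 0.003,
                            loss_rate = 0.003, root_count = 2L, seed = 5)
  phy <- tree$phylo
  labs <- branch_labels(tree)
  for (og in sample(sim$orthology$og_ids, 10)) {
    tr_og <- sim$truth[sim$truth$og_id == og, ]
    net <- setNames(tr_og$net_change, tr_og$branch)
    for (sp in phy$tip.label) {
      node <- which(phy$tip.label == sp)
      path_net <- 0
      while (node != ape::Ntip(phy) + 1) {
        e <- which(phy$edge[, 2] == node)
        path_net <- path_net + net[[labs[e]]]
        node <- phy$edge[e, 1]
      }
      expect_equal(unname(sim$orthology$counts[og, sp]), 2 + path_net,
                   info = paste(og, sp))
    }
  }
  # determinism
  sim_b <- simulate_orthology(tree, n_ogs = 50, gain_rate = 0.003,
                              loss_rate = 0.003, root_count = 2L, seed = 5)
  expect_identical(sim$orthology$members, sim_b$orthology$members)
})

test_that("codon alignment simulation obeys omega extremes and determinism", {
  s0 <- simulate_codon_alignment(3, 100, omega = 0, branch_mutations = 20,
                                 seed = 6)
  expect_equal(sum(s0$truth$n_nonsyn_sub), 0)
  v0 <- og_divergence(s0$alignment)
  expect_equal(v0$PDN, 0)

  sm0 <- simulate_codon_alignment(3, 100, omega = 0.5, branch_mutations = 0,
                                  seed = 7)
  expect_equal(length(unique(sm0$alignment)), 1)

  # realized nonsyn/syn substitution ratio increases with omega
  ratio_at <- function(om) {
    counts <- vapply(1:30, function(r) {
      s <- simulate_codon_alignment(2, 300, omega = om,
                                    branch_mutations = 40, seed = 500 + r)
      c(sum(s$truth$n_syn_sub), sum(s$truth$n_nonsyn_sub))
    }, numeric(2))
    sum(counts[2, ]) / sum(counts[1, ])
  }
  r <- vapply(c(0.1, 0.5, 1.0), ratio_at, numeric(1))
  expect_true(all(diff(r) > 0))
})

test_that("genome order simulation preserves gene content", {
  tree <- simulate_species_tree(4, 100, seed = 8)
  sim <- simulate_orthology(tree, n_ogs = 40, seed = 9)
  g0 <- simulate_genome_orders(sim$orthology, 0, seed = 10)$orders
  g5 <- simulate_genome_orders(sim$orthology, 5, seed = 10)$orders
  for (sp in unique(g0$species)) {
    expect_setequal(g0$gene_id[g0$species == sp],
                    sim$orthology$members$gene_id[
                      sim$orthology$members$species == sp])
    expect_setequal(g5$gene_id[g5$species == sp],
                    g0$gene_id[g0$species == sp])
  }
})

test_that("snp/track simulation hits declared rates and track values", {
  st <- simulate_snps_tracks(n_genes = 50, cds_length = 900,
                             syn_rate = 0, nonsyn_rate = 0,
                             track_profile = 0.7, seed = 11)
  expect_true(all(st$snps$n_syn == 0 & st$snps$n_nonsyn == 0))
  m <- snp_metrics(st$snps)
  expect_true(all(is.na(m$NSP)))
  means <- gene_track_means(st$models, st$track)
  expect_equal(unname(means), rep(0.7, 50), tolerance = 1e-9)
})

test_that("expression map simulation plants overlap and stays in bounds", {
  fams <- setNames(rep(10L, 4), c("F1", "F2", "F3", "F4"))
  sim <- simulate_expression_map(fams, grid_rows = 10, grid_cols = 10,
                                 planted_pairs = list(
                                   list(pair = c("F1", "F2"), rho = 1,
                                        n_cells = 3)),
                                 n_background = 100, seed = 12)
  expect_true(all(sim$map$cells$row >= 0 & sim$map$cells$row < 10))
  expect_true(all(sim$map$cells$col >= 0 & sim$map$cells$col < 10))
  sets <- family_cell_sets(sim$map, sim$catalog, "cell")
  planted_score <- cooccurrence_score(sets$F1, sets$F2)
  null_score <- cooccurrence_score(sets$F3, sets$F4)
  expect_gt(planted_score, null_score)
  expect_equal(sort(unique(sets$F1)), sort(sim$truth$planted[["F1-F2"]]))
})

test_that("the packaged catalog fixture reproduces the printed counts", {
  fix <- table2_fixture()
  expect_equal(nrow(fix), 36)
  expect_equal(sum(fix$ag_genes), 420)
  expect_equal(sum(fix$ag_ogs), 298)
  expect_equal(sum(fix$dm_genes), 354)
  expect_equal(sum(fix$dm_ogs), 276)
  lrim <- fix[fix$family == "LRIM", ]
  expect_equal(c(lrim$ag_genes, lrim$ag_ogs, lrim$dm_genes, lrim$dm_ogs),
               c(24, 20, 0, 0))
  ppo <- fix[fix$family == "PPO", ]
  expect_equal(c(ppo$ag_genes, ppo$ag_ogs, ppo$dm_genes, ppo$dm_ogs),
               c(9, 1, 3, 1))

  inst <- instantiate_catalog("ag")
  expect_equal(nrow(inst$catalog), 420)
  expect_equal(length(unique(inst$members$og_id)), 298)
  tab <- table(inst$catalog$family)
  expect_equal(as.integer(tab[fix$family[fix$ag_genes > 0]]),
               as.integer(fix$ag_genes[fix$ag_genes > 0]))

  inst_dm <- instantiate_catalog("dm")
  expect_equal(nrow(inst_dm$catalog), 354)
  expect_equal(length(unique(inst_dm$members$og_id)), 276)
})
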