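test_that("read_orthology tallies counts, rejects bad input, round-trips", {
  tsv <- tempfile(fileext = ".tsv")
  writeLines(c("og_id\tgene_id\tspecies",
               "og1\tgA\tA", "og1\tgB\tB", "og2\tgA2\tA"), tsv)
  orth <- read_orthology(tsv, c("A", "B", "C"))
  expect_equal(unname(og_counts(orth, "og1")), c(1L, 1L, 0L))
  expect_equal(colnames(orth$counts), c("A", "B", "C"))

  # column sums equal per-species totals in members
  expect_equal(colSums(orth$counts),
               c(A = 2, B = 1, C = 0))

  empty <- tempfile(fileext = ".tsv")
  writeLines("og_id\tgene_id\tspecies", empty)
  expect_error(read_orthology(empty, "A"), "no records")

  bad <- tempfile(fileext = ".tsv")
  writeLines(c("og_id\tgene_id\tspecies", "og1\tg1\tZZ"), bad)
  expect_error(read_orthology(bad, c("A", "B")), "ZZ")

  dup <- data.frame(og_id = "og1", gene_id = c("g", "g"), species = "A")
  expect_error(orthology_table(dup, "A"), "duplicate")

  out <- tempfile(fileext = ".tsv")
  write_orthology(orth, out)
  back <- read_orthology(out, c("A", "B", "C"))
  expect_identical(back$counts, orth$counts)
  expect_identical(back$members, orth$members)
})

test_that("read_species_tree computes ages and flags non-ultrametric trees", {
  nwk <- tempfile(fileext = ".nwk")
  writeLines("((A:1,B:1):1,C:2);", nwk)
  tr <- read_species_tree(nwk)
  expect_equal(tr$root_age, 2)
  internal <- tr$node_age[tr$n_tips + 2]  # non-root internal node
  expect_equal(unname(internal), 1)
  expect_equal(unname(tr$node_age[1:3]), c(0, 0, 0))

  bad <- tempfile(fileext = ".nwk")
  writeLines("(A:1,B:2);", bad)
  expect_warning(read_species_tree(bad), "ultrametric")

  # round-trip preserves ages on a larger random ultrametric tree
  tr43 <- simulate_species_tree(43, root_age = 350, seed = 11)
  f <- tempfile(fileext = ".nwk")
  write_species_tree(tr43, f)
  back <- read_species_tree(f)
  expect_equal(sort(back$node_age), sort(tr43$node_age), tolerance = 1e-8)
  expect_setequal(back$phylo$tip.label, tr43$phylo$tip.label)
})

test_that("parse_cafe_report classifies branch deltas against the tree", {
  tr <- toy_tree()
  labs <- branch_labels(tr)
  f <- tempfile(fileext = ".tsv")
  df <- data.frame(og_id = "og1", branch = labs, delta = 0L)
  df$delta[df$branch == "A"] <- 1L
  utils::write.table(df, f, sep = "\t", quote = FALSE, row.names = FALSE)
  ev <- parse_cafe_report(f, tr)
  expect_equal(ev$label[ev$branch == "A"], "gain")
  expect_true(all(ev$label[ev$branch != "A"] == "stable"))

  bad <- data.frame(og_id = "og1", branch = "nosuch", delta = 1)
  utils::write.table(bad, f, sep = "\t", quote = FALSE, row.names = FALSE)
  expect_error(parse_cafe_report(f, tr), "nosuch")

  # round-trip: simulator truth -> report -> classification matches signs
  tree <- simulate_species_tree(6, 100, seed = 3)
  sim <- simulate_orthology(tree, n_ogs = 10, gain_rate = 0.004,
                            loss_rate = 0.004, seed = 4)
  rep_df <- data.frame(og_id = sim$truth$og_id, branch = sim$truth$branch,
                       delta = sim$truth$net_change)
  utils::write.table(rep_df, f, sep = "\t", quote = FALSE, row.names = FALSE)
  ev2 <- parse_cafe_report(f, tree)
  expect_equal(ev2$label, ifelse(sim$truth$net_change > 0, "gain",
                                 ifelse(sim$truth$net_change < 0, "loss",
                                        "stable")))
})

test_that("parse_paml_m0 extracts dS, dN, and guards dS = 0", {
  f <- tempfile()
  writeLines(c("some header", "tree length for dS:  0.5",
               "tree length for dN:  0.1", "omega (dN/dS) = 0.2"), f)
  v <- parse_paml_m0(f)
  expect_equal(v$PDS, 0.5)
  expect_equal(v$PDN, 0.1)
  expect_equal(v$SEL, 0.2)

  writeLines(c("dS = 0", "dN = 0.1"), f)
  v0 <- parse_paml_m0(f)
  expect_true(is.na(v0$SEL))

  writeLines("nothing useful", f)
  expect_error(parse_paml_m0(f), "dS")
})

test_that("track and gene model readers validate and round-trip", {
  f <- tempfile(fileext = ".bedgraph")
  writeLines(c("track type=bedGraph", "chr1\t0\t50\t0.5", "chr1\t50\t100\t1"), f)
  tr <- read_track(f, range = c(0, 1))
  expect_equal(nrow(tr), 2)
  expect_equal(tr$value, c(0.5, 1))

  writeLines(c("chr1\t0\t50\t0.5", "chr1\t40\t100\t1"), f)
  expect_error(read_track(f), "overlapping")
  writeLines("chr1\t0\t50\t7", f)
  expect_error(read_track(f, range = c(0, 1)), "range")

  g <- tempfile(fileext = ".gff3")
  writeLines(c("##gff-version 3",
               "chr1\tsrc\tgene\t1\t900\t.\t+\t.\tID=gene1",
               "chr1\tsrc\tCDS\t1\t300\t.\t+\t0\tID=cds1;Parent=gene1",
               "chr1\tsrc\tCDS\t401\t900\t.\t+\t0\tID=cds2;Parent=gene1"), g)
  gm <- read_gene_models(g)
  expect_equal(nrow(gm), 2)
  expect_equal(gm$gene_id, c("gene1", "gene1"))
  expect_equal(gm$start, c(1, 401))

  out <- tempfile(fileext = ".gff3")
  write_gene_models(gm, out)
  expect_equal(as.data.frame(read_gene_models(out)), as.data.frame(gm))
})

test_that("og_metric_table rejects out-of-range values instead of coercing", {
  ok <- data.frame(og_id = "og1", UNI = 0.5, DUP = 0, ACN = 1.5, CNV = 0.2,
                   EXP = 0.25, CON = 0.25, STA = 0.5)
  expect_silent(og_metric_table(ok))
  expect_error(og_metric_table(data.frame(og_id = "x", UNI = 0)), "UNI")
  expect_error(og_metric_table(data.frame(og_id = "x", ACN = 0.5)), "ACN")
  expect_error(og_metric_table(
    data.frame(og_id = "x", EXP = 0.5, CON = 0.5, STA = 0.5)), "EXP")
  # NA passes through untouched
  na_tab <- og_metric_table(data.frame(og_id = "x", UNI = NA_real_))
  expect_true(is.na(na_tab$UNI))
})

test_that("expression map and catalog readers validate bounds/uniqueness", {
  cells <- data.frame(gene_id = c("g1", "g2"), row = c(0, 4), col = c(0, 4))
  m <- expression_map(cells, 5, 5)
  expect_equal(m$grid_rows, 5L)
  expect_error(expression_map(data.frame(gene_id = "g", row = 5, col = 0), 5, 5),
               "outside")
  expect_error(gene_catalog(data.frame(gene_id = c("g", "g"),
                                       family = c("A", "B"),
                                       species = "s")), "more than one")
})
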