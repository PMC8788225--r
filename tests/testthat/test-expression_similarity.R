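simple_map <- function(assign, rows = 5, cols = 5, toroidal = TRUE) {
  cells <- data.frame(gene_id = names(assign),
                      row = vapply(assign, `[`, numeric(1), 1),
                      col = vapply(assign, `[`, numeric(1), 2))
  expression_map(cells, rows, cols, toroidal)
}

simple_catalog <- function(fam_of) {
  gene_catalog(data.frame(gene_id = names(fam_of), family = unname(fam_of),
                          species = "sp", stringsAsFactors = FALSE))
}

test_that("supercell occupancy wraps toroidally and matches the 3x3 oracle", {
  map <- simple_map(list(g1 = c(0, 0)))
  cat <- simple_catalog(c(g1 = "F1"))
  sets <- family_cell_sets(map, cat, "supercell")
  # occupied supercell centers include the wrapped corners
  expect_true((4 * 5 + 4) %in% sets$F1)  # (4,4)
  expect_true((0 * 5 + 1) %in% sets$F1)  # (0,1)
  expect_length(sets$F1, 9)
  expect_length(family_cell_sets(map, cat, "cell")$F1, 1)

  # brute-force dilation oracle on random maps
  set.seed(14)
  for (i in 1:10) {
    n <- 12
    assign <- lapply(seq_len(n), function(j) c(sample(0:5, 1), sample(0:6, 1)))
    names(assign) <- paste0("g", seq_len(n))
    map_r <- simple_map(assign, rows = 6, cols = 7)
    cat_r <- simple_catalog(setNames(rep("F1", n), names(assign)))
    got <- family_cell_sets(map_r, cat_r, "supercell")$F1
    occ <- unique(vapply(assign, function(x) x[1] * 7 + x[2], numeric(1)))
    want <- c()
    for (r in 0:5) for (cc in 0:6) {
      block <- as.vector(outer((r + -1:1) %% 6, (cc + -1:1) %% 7,
                               function(a, b) a * 7 + b))
      if (any(block %in% occ)) want <- c(want, r * 7 + cc)
    }
    expect_setequal(got, want)
  }
})

test_that("cooccurrence_score is Jaccard with empty-set guard", {
  expect_equal(cooccurrence_score(1:3, 1:3), 1)
  expect_equal(cooccurrence_score(1:3, 4:5), 0)
  expect_equal(cooccurrence_score(c(1, 2, 3), c(3, 4)), 1 / 4)
  expect_true(is.na(cooccurrence_score(integer(0), 1:3)))
})

test_that("permutation test detects planted overlap and preserves marginals", {
  set.seed(20)
  # two families planted in the same 3 cells of a 10x10 map
  shared <- c(3, 50, 97)
  fam_cells <- sample(shared, 20, replace = TRUE)
  assign <- c(lapply(fam_cells[1:10], function(s) c(s %/% 10, s %% 10)),
              lapply(fam_cells[11:20], function(s) c(s %/% 10, s %% 10)),
              lapply(sample(0:99, 150, replace = TRUE),
                     function(s) c(s %/% 10, s %% 10)))
  names(assign) <- paste0("g", seq_along(assign))
  map <- simple_map(assign, 10, 10)
  fam_of <- setNames(c(rep("F1", 10), rep("F2", 10),
                       rep("BG", 150)), names(assign))
  cat <- simple_catalog(fam_of)
  res <- cooccurrence_permutation_test(map, cat, "F1", "F2",
                                       resolution = "cell",
                                       n_perm = 1000, seed = 2)
  expect_gt(res$score, 0.8)
  expect_lte(res$p_value, 0.01)

  # empty family -> missing
  res_na <- cooccurrence_permutation_test(map, cat, "F1", "ABSENT",
                                          n_perm = 100, seed = 1)
  expect_true(is.na(res_na$p_value))
})

test_that("module co-occurrence reduces to cell resolution when cells = modules", {
  set.seed(21)
  n <- 60
  cells <- data.frame(gene_id = paste0("g", 1:n),
                      row = 0L, col = sample(0:9, n, replace = TRUE))
  map <- expression_map(cells, 1, 10, toroidal = FALSE)
  fam_of <- setNames(sample(c("F1", "F2", "BG"), n, replace = TRUE),
                     cells$gene_id)
  cat <- simple_catalog(fam_of)
  tab_cell <- family_cooccurrence_table(map, cat, "cell",
                                        n_perm = 300, seed = 5)
  partition <- setNames(sprintf("%02d", cells$col), cells$gene_id)
  tab_mod <- module_cooccurrence(partition, cat, n_perm = 300, seed = 5)
  expect_equal(tab_mod$score, tab_cell$score)
  expect_equal(tab_mod$p_value, tab_cell$p_value)
  expect_equal(unique(tab_mod$resolution), "module")

  # one module holding both families entirely -> 1; disjoint modules -> 0
  p1 <- setNames(rep("M1", 6), paste0("x", 1:6))
  cat1 <- simple_catalog(setNames(rep(c("A", "B"), 3), names(p1)))
  t1 <- module_cooccurrence(p1, cat1, n_perm = 100, seed = 1)
  expect_equal(t1$score, 1)
  p2 <- setNames(rep(c("M1", "M2"), each = 3), paste0("x", 1:6))
  cat2 <- simple_catalog(setNames(rep(c("A", "B"), each = 3), names(p2)))
  t2 <- module_cooccurrence(p2, cat2, n_perm = 100, seed = 1)
  t2ab <- t2$score[t2$family_a == "A" & t2$family_b == "B"]
  expect_equal(t2ab, 0)
})

test_that("expression partition recovers planted blocks and flags constants", {
  set.seed(22)
  rand_ok <- vapply(1:20, function(r) {
    b1 <- matrix(rep(sin(1:10), each = 15), 15, 10) + rnorm(150, 0, 0.2)
    b2 <- matrix(rep(cos(1:10) * 2 - 1, each = 15), 15, 10) + rnorm(150, 0, 0.2)
    expr <- rbind(b1, b2)
    rownames(expr) <- paste0("g", 1:30)
    colnames(expr) <- paste0("c", 1:10)
    part <- expression_partition_from_matrix(expr, k = 2)
    truth <- rep(c(1, 2), each = 15)
    rand_index(unname(part[rownames(expr)]), truth)
  }, numeric(1))
  expect_gte(mean(rand_ok >= 0.95), 0.9)

  expr <- matrix(rnorm(40), 4, 10,
                 dimnames = list(paste0("g", 1:4), paste0("c", 1:10)))
  expr[1, ] <- 7  # constant gene
  part <- expression_partition_from_matrix(expr, k = 2)
  expect_equal(unname(part["g1"]), "unclustered")
  expect_equal(length(unique(part[paste0("g", 2:4)])), 2)
  expect_error(expression_partition_from_matrix(expr[, 1, drop = FALSE]),
               "2 conditions")
})

test_that("evo_expr_pairing joins pairs present in both inputs", {
  evo <- matrix(c(1, 0.5, 0.2,
                  0.5, 1, 0.1,
                  0.2, 0.1, 1), 3, 3,
                dimnames = list(c("A", "B", "C"), c("A", "B", "C")))
  expr <- data.frame(family_a = c("A", "A", "B", "A"),
                     family_b = c("B", "C", "C", "ZZ"),
                     score = c(0.7, 0.1, 0.2, 0.9),
                     p_value = c(0.004, 0.3, 0.06, 0.001),
                     resolution = "cell")
  pr <- evo_expr_pairing(evo, expr)
  expect_equal(nrow(pr), 3)  # C(3,2); ZZ pair dropped
  expect_equal(pr$evo_score[pr$family_a == "A" & pr$family_b == "B"], 0.5)
  expect_equal(pr$significant, c(TRUE, FALSE, FALSE))
  expect_equal(nrow(attr(pr, "dropped")), 1)
})

test_that("similarity graph export bins edges by threshold", {
  tab <- data.frame(family_a = c("A", "A", "B", "C"),
                    family_b = c("B", "C", "C", "D"),
                    score = c(0.5, 0.4, 0.3, 0.2),
                    p_value = c(0.004, 0.02, 0.3, 0.06),
                    resolution = "cell")
  f <- tempfile(fileext = ".dot")
  n_edges <- export_similarity_graph(tab, f)
  expect_equal(n_edges, 2)  # p < 0.05 only
  lines <- readLines(f)
  expect_true(any(grepl("\"A\" -- \"B\" \\[class=\"p<0.005\"", lines)))
  expect_true(any(grepl("\"A\" -- \"C\" \\[class=\"p<0.05\"", lines)))
  expect_equal(sum(grepl(" -- ", lines)), 2)
  expect_equal(sum(grepl("^  \"[A-D]\";$", lines)), 4)

  # empty significant set: nodes only
  tab$p_value <- 0.9
  n0 <- export_similarity_graph(tab, f)
  expect_equal(n0, 0)
  expect_equal(sum(grepl(" -- ", readLines(f))), 0)
})
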