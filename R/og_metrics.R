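# Orthology-based evolutionary feature metrics computed per orthologous
# group: taxonomic age, universality, duplicability, copy-number statistics,
# synteny conservation and normalized protein divergence.

#' Taxonomic age of an OG
#'
#' Age (My) of the most recent common ancestor of the species present in the
#' OG, read off the ultrametric species tree. A single-species OG has age 0
#' (leaf age): OGs are normally defined at the ancestor of at least two
#' species, but degenerate input still yields a value.
#'
#' @param species_present character vector of species with >= 1 member.
#' @param tree `species_tree`.
#' @return age in My.
#' @export
compute_age <- function(species_present, tree) {
  species_present <- unique(species_present)
  if (length(species_present) == 0L) stop("empty OG", call. = FALSE)
  missing <- setdiff(species_present, tree$phylo$tip.label)
  if (length(missing) > 0L)
    stop("OG species not in tree: ", paste(missing, collapse = ", "),
         call. = FALSE)
  if (length(species_present) == 1L) return(0)
  node <- ape::getMRCA(tree$phylo, species_present)
  tree$node_age[node]
}

#' Universality of an OG
#'
#' Proportion of the total species set present in the OG (all species
#' present gives UNI = 1).
#'
#' @param counts named integer vector of per-species copy counts (full
#'   species set).
#' @param n_total_species total species count; defaults to `length(counts)`.
#' @return proportion in (0, 1].
#' @export
compute_uni <- function(counts, n_total_species = length(counts)) {
  if (n_total_species <= 0) stop("n_total_species must be > 0", call. = FALSE)
  n_present <- sum(counts > 0)
  if (n_present == 0L) stop("empty OG", call. = FALSE)
  n_present / n_total_species
}

#' Duplicability of an OG
#'
#' Proportion of species present in the OG that have multicopy (>= 2)
#' orthologs.
#'
#' @param counts per-species copy counts.
#' @return proportion in \[0, 1\].
#' @export
compute_dup <- function(counts) {
  present <- counts[counts > 0]
  if (length(present) == 0L) stop("empty OG", call. = FALSE)
  mean(present >= 2)
}

#' Average copy number and copy-number variation of an OG
#'
#' ACN is the mean ortholog copy number over species present (absent
#' species are excluded, not counted as zero). CNV is the standard
#' deviation of those counts divided by ACN; a single-species OG has
#' sd = 0, hence CNV = 0. The sample standard deviation (n - 1 denominator,
#' the default of the statistical environment) is used unless
#' `sd_type = "population"`.
#'
#' @param counts per-species copy counts.
#' @param sd_type `"sample"` (default) or `"population"`.
#' @return list with `ACN` and `CNV`.
#' @export
compute_acn_cnv <- function(counts, sd_type = c("sample", "population")) {
  sd_type <- match.arg(sd_type)
  x <- counts[counts > 0]
  if (length(x) == 0L) stop("empty OG", call. = FALSE)
  acn <- mean(x)
  s <- if (length(x) < 2L) 0 else stats::sd(x)
  if (sd_type == "population" && length(x) >= 2L)
    s <- s * sqrt((length(x) - 1) / length(x))
  list(ACN = acn, CNV = s / acn)
}

# Flanking-OG lookup shared by all compute_syn calls: for every gene in the
# gene orders, the set of OGs of its <= window neighbors per side.
# Neighbors not assigned to any OG are unmatchable and dropped.
build_flank_index <- function(orthology, orders, window = 1L) {
  gene_og <- stats::setNames(orthology$members$og_id, orthology$members$gene_id)
  flanks <- new.env(parent = emptyenv())
  sp_scaf <- split(orders$gene_id, list(orders$species, orders$scaffold),
                   drop = TRUE)
  for (genes in sp_scaf) {
    n <- length(genes)
    for (i in seq_len(n)) {
      lo <- max(1L, i - window); hi <- min(n, i + window)
      nb <- genes[setdiff(lo:hi, i)]
      ogs <- unique(gene_og[nb])
      ogs <- ogs[!is.na(ogs)]
      assign(genes[i], ogs, envir = flanks)
    }
  }
  flanks
}

#' Synteny conservation of an OG
#'
#' For every ordered evaluation pair (gene g in species s, other species s'
#' with >= 1 ortholog of g in the OG), the pair is "maintained" when the OG
#' set of g's flanking genes (up to `window` per side) intersects the flank
#' OG set of at least one ortholog in s'. SYN is maintained / evaluated
#' pairs. Pairs where g has no flanks, or where no ortholog in s' has
#' flanks, are excluded from the denominator. With `per_gene = TRUE` the
#' unit is the gene: a gene counts as maintained when its neighborhood is
#' maintained in at least one other species.
#'
#' @param og_id OG identifier.
#' @param orthology `orthology_table` (used both for membership and to map
#'   neighbor genes to their own OGs).
#' @param orders `gene_orders`.
#' @param window flank width per side (genes); default 1.
#' @param per_gene count per gene instead of per ordered species pair.
#' @param flank_index optional precomputed [build_flank_index()] result.
#' @return proportion in \[0,1\], or NA when nothing is evaluable.
#' @export
compute_syn <- function(og_id, orthology, orders, window = 1L,
                        per_gene = FALSE, flank_index = NULL) {
  mem <- orthology$members[orthology$members$og_id == og_id, , drop = FALSE]
  if (nrow(mem) == 0L) stop("unknown OG: ", og_id, call. = FALSE)
  if (!all(mem$gene_id %in% orders$gene_id)) return(NA_real_)
  if (is.null(flank_index))
    flank_index <- build_flank_index(orthology, orders, window)
  fl <- function(g) if (exists(g, envir = flank_index)) get(g, envir = flank_index)
                    else character(0)
  species <- unique(mem$species)
  if (length(species) < 2L) return(NA_real_)
  genes_by_sp <- split(mem$gene_id, mem$species)
  flank_sets <- lapply(stats::setNames(mem$gene_id, mem$gene_id), fl)
  evaluated <- 0L; maintained <- 0L
  gene_eval <- 0L; gene_main <- 0L
  for (s in species) {
    for (g in genes_by_sp[[s]]) {
      fg <- flank_sets[[g]]
      if (length(fg) == 0L) next  # flankless gene: excluded
      g_any <- FALSE; g_evaluable <- FALSE
      for (s2 in setdiff(species, s)) {
        orth_flanks <- flank_sets[genes_by_sp[[s2]]]
        orth_flanks <- orth_flanks[lengths(orth_flanks) > 0]
        if (length(orth_flanks) == 0L) next  # no flanked ortholog in s2
        g_evaluable <- TRUE
        evaluated <- evaluated + 1L
        hit <- any(vapply(orth_flanks,
                          function(fo) length(intersect(fg, fo)) > 0, TRUE))
        if (hit) { maintained <- maintained + 1L; g_any <- TRUE }
      }
      if (g_evaluable) {
        gene_eval <- gene_eval + 1L
        if (g_any) gene_main <- gene_main + 1L
      }
    }
  }
  if (per_gene) {
    if (gene_eval == 0L) return(NA_real_)
    return(gene_main / gene_eval)
  }
  if (evaluated == 0L) return(NA_real_)
  maintained / evaluated
}

#' Normalized protein evolutionary rate of an OG
#'
#' Mean over unordered species pairs present in the OG of
#' `(100 - mean member identity) / (100 - background identity)`, a
#' background-normalized divergence ratio standing in for the orthology
#' database's internal rate computation (which is not printed). Pairs whose
#' background identity is 100 are skipped.
#'
#' @param og_identity data.frame `sp1`, `sp2`, `identity`: mean protein
#'   percent identity between OG members of the two species.
#' @param background data.frame `sp1`, `sp2`, `identity`: genome-wide mean
#'   identity per species pair; must cover every pair used.
#' @return non-negative rate, or NA when no valid pair exists.
#' @export
compute_evr <- function(og_identity, background) {
  if (nrow(og_identity) == 0L) return(NA_real_)
  pair_key <- function(a, b) paste(pmin(a, b), pmax(a, b))
  bg <- stats::setNames(background$identity, pair_key(background$sp1, background$sp2))
  keys <- pair_key(og_identity$sp1, og_identity$sp2)
  if (anyDuplicated(keys)) stop("duplicate species pair in og_identity", call. = FALSE)
  if (!all(keys %in% names(bg)))
    stop("background identity missing for pair(s): ",
         paste(setdiff(keys, names(bg)), collapse = ", "), call. = FALSE)
  b <- bg[keys]
  keep <- b < 100
  if (!any(keep)) return(NA_real_)
  mean((100 - og_identity$identity[keep]) / (100 - b[keep]))
}

#' Compute all orthology-based metrics for every OG
#'
#' @param orthology `orthology_table`.
#' @param tree `species_tree`.
#' @param orders optional `gene_orders` (SYN is NA when absent).
#' @param identities optional list with `og` (data.frame `og_id`, `sp1`,
#'   `sp2`, `identity`) and `background` (data.frame `sp1`, `sp2`,
#'   `identity`); EVR is NA when absent.
#' @param window SYN flank window.
#' @param sd_type CNV standard-deviation convention.
#' @return data.frame `og_id`, AGE, UNI, DUP, ACN, CNV, SYN, EVR.
#' @export
og_metrics <- function(orthology, tree, orders = NULL, identities = NULL,
                       window = 1L, sd_type = "sample") {
  ogs <- orthology$og_ids
  n_sp <- length(orthology$species)
  flanks <- if (!is.null(orders))
    build_flank_index(orthology, orders, window) else NULL
  members_by_og <- split(orthology$members$species, orthology$members$og_id)
  res <- lapply(ogs, function(og) {
    cnt <- orthology$counts[og, ]
    ac <- compute_acn_cnv(cnt, sd_type = sd_type)
    syn <- if (is.null(orders)) NA_real_ else
      compute_syn(og, orthology, orders, window = window, flank_index = flanks)
    evr <- if (is.null(identities)) NA_real_ else {
      oid <- identities$og[identities$og$og_id == og, , drop = FALSE]
      if (nrow(oid) == 0L) NA_real_ else compute_evr(oid, identities$background)
    }
    data.frame(og_id = og,
               AGE = compute_age(unique(members_by_og[[og]]), tree),
               UNI = compute_uni(cnt, n_sp),
               DUP = compute_dup(cnt),
               ACN = ac$ACN, CNV = ac$CNV,
               SYN = syn, EVR = evr,
               stringsAsFactors = FALSE)
  })
  out <- do.call(rbind, res)
  rownames(out) <- NULL
  out
}
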