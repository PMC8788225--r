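# Domain types and readers/writers for the standard formats the pipeline
# touches. Coordinate conventions are centralized here: GFF3 gene models are
# 1-based inclusive, nucleotide tracks are 0-based half-open (bedGraph).
# Missing metric values are always NA, never 0.

`%||%` <- function(a, b) if (is.null(a)) b else a

stop_io <- function(...) stop(..., call. = FALSE)

read_tsv_checked <- function(path, required_cols) {
  if (!file.exists(path)) stop_io("file not found: ", path)
  df <- utils::read.delim(path, header = TRUE, sep = "\t",
                          stringsAsFactors = FALSE, check.names = FALSE)
  if (nrow(df) == 0L) stop_io("no records in ", path)
  missing <- setdiff(required_cols, names(df))
  if (length(missing) > 0L)
    stop_io("missing column(s) in ", path, ": ", paste(missing, collapse = ", "))
  df
}

write_tsv <- function(df, path) {
  utils::write.table(df, path, sep = "\t", quote = FALSE,
                     row.names = FALSE, col.names = TRUE)
  invisible(path)
}

# ---- SpeciesTree -----------------------------------------------------------

#' Construct a species tree with node ages from an ape phylo
#'
#' Wraps a rooted `phylo` object, computes node ages (millions of years
#' before present) from root-to-tip path lengths, and validates
#' ultrametricity: all leaves must sit at age zero within a relative
#' tolerance. Non-ultrametric input beyond tolerance triggers a warning and
#' ages are taken from the maximum root-to-node depth.
#'
#' @param phy rooted `phylo` with branch lengths (My).
#' @param tol relative ultrametricity tolerance.
#' @return `species_tree`: list with `phylo`, `node_age` (numeric, indexed by
#'   ape node number), `root_age`, `n_tips`.
#' @export
species_tree <- function(phy, tol = 1e-6) {
  if (!inherits(phy, "phylo")) stop_io("phy must be a phylo object")
  if (is.null(phy$edge.length)) stop_io("tree has no branch lengths")
  if (anyNA(phy$tip.label) || any(phy$tip.label == ""))
    stop_io("tree has unlabeled leaves")
  if (anyDuplicated(phy$tip.label))
    stop_io("duplicate leaf labels: ",
            paste(unique(phy$tip.label[duplicated(phy$tip.label)]), collapse = ", "))
  depth <- ape::node.depth.edgelength(phy)
  tip_depth <- depth[seq_len(ape::Ntip(phy))]
  root_age <- max(depth)
  if (root_age <= 0) stop_io("tree has zero total depth")
  if (diff(range(tip_depth)) > tol * root_age)
    warning("tree is not ultrametric within tolerance; ",
            "node ages taken from maximum depth", call. = FALSE)
  node_age <- root_age - depth
  node_age[abs(node_age) <= tol * root_age] <- 0
  structure(list(phylo = phy, node_age = node_age,
                 root_age = root_age, n_tips = ape::Ntip(phy)),
            class = "species_tree")
}

#' Read an ultrametric species tree from a newick file
#'
#' @param path newick file.
#' @param tol relative ultrametricity tolerance.
#' @return `species_tree` object.
#' @export
read_species_tree <- function(path, tol = 1e-6) {
  phy <- ape::read.tree(path)
  if (is.null(phy)) stop_io("could not parse newick in ", path)
  species_tree(phy, tol = tol)
}

#' Write a species tree to newick
#' @param tree `species_tree`.
#' @param path output file.
#' @export
write_species_tree <- function(tree, path) {
  ape::write.tree(tree$phylo, file = path)
  invisible(path)
}

#' @export
print.species_tree <- function(x, ...) {
  cat("species_tree:", x$n_tips, "leaves, root age", format(x$root_age), "My\n")
  invisible(x)
}

# ---- OrthologyTable --------------------------------------------------------

#' Construct an orthology table from gene-level membership
#'
#' @param members data.frame with columns `og_id`, `gene_id`, `species`.
#' @param species_list full ordered species set (columns of the count
#'   matrix); species in `members` must be a subset.
#' @return `orthology_table`: list with `counts` (OG x species integer
#'   matrix), `members`, `og_ids`, `species`.
#' @export
orthology_table <- function(members, species_list) {
  req <- c("og_id", "gene_id", "species")
  if (!all(req %in% names(members))) stop_io("members needs og_id, gene_id, species")
  if (nrow(members) == 0L) stop_io("no records")
  bad_sp <- setdiff(unique(members$species), species_list)
  if (length(bad_sp) > 0L)
    stop_io("species not in declared species list: ", paste(bad_sp, collapse = ", "))
  key <- paste(members$og_id, members$species, members$gene_id)
  if (anyDuplicated(key)) {
    dup <- members[duplicated(key), , drop = FALSE]
    stop_io("duplicate gene record(s), e.g. gene ", dup$gene_id[1],
            " in OG ", dup$og_id[1], " species ", dup$species[1])
  }
  og_ids <- unique(members$og_id)
  counts <- table(factor(members$og_id, levels = og_ids),
                  factor(members$species, levels = species_list))
  counts <- matrix(as.integer(counts), nrow = length(og_ids),
                   dimnames = list(og_ids, species_list))
  structure(list(counts = counts,
                 members = members[, req],
                 og_ids = og_ids, species = species_list),
            class = "orthology_table")
}

#' Read an orthology table from TSV
#'
#' Expects columns `og_id`, `gene_id`, `species`; one row per gene. The
#' count matrix is tallied from membership and any species not in
#' `species_list` is rejected by name.
#'
#' @param path TSV file.
#' @param species_list declared species set.
#' @return `orthology_table`.
#' @export
read_orthology <- function(path, species_list) {
  df <- read_tsv_checked(path, c("og_id", "gene_id", "species"))
  orthology_table(df, species_list)
}

#' Write an orthology table to TSV (round-trips with [read_orthology()])
#' @param x `orthology_table`.
#' @param path output file.
#' @export
write_orthology <- function(x, path) write_tsv(x$members, path)

#' @export
print.orthology_table <- function(x, ...) {
  cat("orthology_table:", length(x$og_ids), "OGs,",
      length(x$species), "species,", nrow(x$members), "genes\n")
  invisible(x)
}

#' Species-presence counts for one OG
#' @param x `orthology_table`.
#' @param og_id OG identifier.
#' @return named integer vector over the full species list.
#' @export
og_counts <- function(x, og_id) {
  if (!og_id %in% x$og_ids) stop_io("unknown OG: ", og_id)
  x$counts[og_id, ]
}

# ---- GeneCatalog -----------------------------------------------------------

#' Read a gene catalog mapping genes to immune families
#'
#' @param path TSV with columns `gene_id`, `family`, `species`.
#' @param families optional declared family vocabulary; unknown acronyms are
#'   rejected when supplied.
#' @return data.frame of class `gene_catalog`.
#' @export
read_gene_catalog <- function(path, families = NULL) {
  df <- read_tsv_checked(path, c("gene_id", "family", "species"))
  gene_catalog(df, families = families)
}

#' Construct/validate a gene catalog
#' @param df data.frame with `gene_id`, `family`, `species`.
#' @param families optional declared vocabulary of family acronyms.
#' @return `gene_catalog` data.frame.
#' @export
gene_catalog <- function(df, families = NULL) {
  if (anyDuplicated(df$gene_id))
    stop_io("gene(s) mapped to more than one family: ",
            paste(unique(df$gene_id[duplicated(df$gene_id)])[1:3], collapse = ", "))
  if (!is.null(families)) {
    bad <- setdiff(unique(df$family), families)
    if (length(bad) > 0L)
      stop_io("family acronym(s) outside declared vocabulary: ",
              paste(bad, collapse = ", "))
  }
  class(df) <- c("gene_catalog", "data.frame")
  df
}

# ---- GenomeGeneOrder -------------------------------------------------------

#' Read per-species gene-order lists
#'
#' @param path TSV with columns `species`, `scaffold`, `position`, `gene_id`;
#'   `position` is the rank of the gene along its scaffold (ascending start
#'   coordinate).
#' @return `gene_orders` data.frame sorted by species, scaffold, position.
#' @export
read_gene_orders <- function(path) {
  df <- read_tsv_checked(path, c("species", "scaffold", "position", "gene_id"))
  gene_orders(df)
}

#' Construct/validate a gene-order table
#' @param df data.frame with `species`, `scaffold`, `position`, `gene_id`.
#' @return `gene_orders` data.frame.
#' @export
gene_orders <- function(df) {
  key <- paste(df$species, df$gene_id)
  if (anyDuplicated(key))
    stop_io("gene appears more than once in a species gene order: ",
            key[duplicated(key)][1])
  df <- df[order(df$species, df$scaffold, df$position), , drop = FALSE]
  rownames(df) <- NULL
  class(df) <- c("gene_orders", "data.frame")
  df
}

#' Write a gene-order table to TSV
#' @param x `gene_orders`.
#' @param path output file.
#' @export
write_gene_orders <- function(x, path) write_tsv(as.data.frame(x), path)

# ---- CodonAlignmentSet -----------------------------------------------------

#' Read a codon alignment from FASTA
#'
#' Validates equal sequence lengths, length divisible by 3 and the
#' `{A,C,G,T,-,N}` alphabet (case-insensitive).
#'
#' @param path FASTA file.
#' @return named character vector of aligned sequences.
#' @export
read_codon_alignment <- function(path) {
  ss <- Biostrings::readBStringSet(path)
  if (length(ss) == 0L) stop_io("no sequences in ", path)
  seqs <- toupper(as.character(ss))
  validate_codon_alignment(seqs, path)
  seqs
}

validate_codon_alignment <- function(seqs, label = "alignment") {
  lens <- nchar(seqs)
  if (length(unique(lens)) != 1L)
    stop_io("unequal sequence lengths in ", label)
  if (lens[1] %% 3L != 0L)
    stop_io("alignment length not divisible by 3 in ", label)
  if (any(grepl("[^ACGTN-]", seqs)))
    stop_io("alphabet outside {A,C,G,T,-,N} in ", label)
  invisible(seqs)
}

#' Read a directory of per-OG codon alignments
#' @param dir directory of `<og_id>.fasta` files.
#' @return named list of alignments (one per OG).
#' @export
read_codon_alignment_set <- function(dir) {
  files <- list.files(dir, pattern = "\\.(fa|fasta)$", full.names = TRUE)
  if (length(files) == 0L) stop_io("no FASTA files in ", dir)
  out <- lapply(files, read_codon_alignment)
  names(out) <- sub("\\.(fa|fasta)$", "", basename(files))
  out
}

#' Write a codon alignment to FASTA
#' @param seqs named character vector.
#' @param path output file.
#' @export
write_codon_alignment <- function(seqs, path) {
  Biostrings::writeXStringSet(Biostrings::BStringSet(seqs), path, width = 80L)
  invisible(path)
}

# ---- SnpAnnotationTable ----------------------------------------------------

#' Read a per-gene SNP annotation table
#'
#' @param path TSV with columns `gene_id`, `n_syn`, `n_nonsyn`, `cds_length`.
#' @return validated data.frame.
#' @export
read_snp_table <- function(path) {
  df <- read_tsv_checked(path, c("gene_id", "n_syn", "n_nonsyn", "cds_length"))
  snp_table(df)
}

#' Validate a SNP annotation table
#' @param df data.frame with `gene_id`, `n_syn`, `n_nonsyn`, `cds_length`.
#' @return the validated data.frame.
#' @export
snp_table <- function(df) {
  if (any(df$n_syn < 0) || any(df$n_nonsyn < 0))
    stop_io("negative SNP counts")
  if (any(df$cds_length <= 0))
    stop_io("non-positive cds_length for gene ",
            df$gene_id[df$cds_length <= 0][1])
  if (any(df$cds_length %% 3L != 0L))
    stop_io("cds_length not divisible by 3 for gene ",
            df$gene_id[df$cds_length %% 3L != 0L][1])
  df
}

# ---- NucleotideTrack -------------------------------------------------------

#' Read a per-nucleotide track from bedGraph
#'
#' Intervals are 0-based half-open, per the bedGraph convention. Values are
#' validated against a declared range; overlapping intervals are rejected.
#' Positions not covered by any interval take `default` (bedGraph sparsity).
#'
#' @param path bedGraph file (track lines are skipped).
#' @param range numeric length-2 declared value range, e.g. `c(0, 1)` for a
#'   constraint score or `c(0, n_species)` for alignability depth.
#' @param default value for uncovered positions.
#' @return `nucleotide_track` data.frame (`scaffold`, `start`, `end`,
#'   `value`) with attribute `default`.
#' @export
read_track <- function(path, range = c(-Inf, Inf), default = 0) {
  lines <- readLines(path)
  lines <- lines[!grepl("^(track|#|browser)", lines) & nzchar(lines)]
  if (length(lines) == 0L) stop_io("no records in ", path)
  con <- textConnection(lines)
  on.exit(close(con))
  df <- utils::read.table(con, sep = "\t", stringsAsFactors = FALSE,
                          col.names = c("scaffold", "start", "end", "value"))
  nucleotide_track(df, range = range, default = default)
}

#' Construct/validate a nucleotide track
#' @param df data.frame with `scaffold`, `start` (0-based), `end`, `value`.
#' @param range declared value range.
#' @param default value for uncovered positions.
#' @return `nucleotide_track` data.frame.
#' @export
nucleotide_track <- function(df, range = c(-Inf, Inf), default = 0) {
  if (any(df$end <= df$start)) stop_io("empty or inverted track interval")
  if (any(df$value < range[1] | df$value > range[2]))
    stop_io("track value outside declared range [",
            range[1], ", ", range[2], "]")
  df <- df[order(df$scaffold, df$start), , drop = FALSE]
  overlap <- unlist(tapply(seq_len(nrow(df)), df$scaffold, function(i) {
    if (length(i) < 2) return(FALSE)
    df$start[i][-1] < df$end[i][-length(i)]
  }), use.names = FALSE)
  if (any(overlap)) stop_io("overlapping track intervals")
  rownames(df) <- NULL
  attr(df, "default") <- default
  class(df) <- c("nucleotide_track", "data.frame")
  df
}

#' Write a track to bedGraph
#' @param x `nucleotide_track`.
#' @param path output file.
#' @export
write_track <- function(x, path) {
  utils::write.table(as.data.frame(x)[, c("scaffold", "start", "end", "value")],
                     path, sep = "\t", quote = FALSE,
                     row.names = FALSE, col.names = FALSE)
  invisible(path)
}

# ---- GeneModel -------------------------------------------------------------

#' Read gene models (CDS intervals) from GFF3
#'
#' Keeps `CDS` features; the owning gene is taken from the `Parent`
#' attribute (or `ID` when absent). Coordinates stay in the GFF3 convention:
#' 1-based, inclusive. Strand is recorded but ignored by the averaging
#' operations, which are strand-symmetric.
#'
#' @param path GFF3 file.
#' @return `gene_models` data.frame (`gene_id`, `scaffold`, `strand`,
#'   `start`, `end`), one row per CDS interval.
#' @export
read_gene_models <- function(path) {
  lines <- readLines(path)
  lines <- lines[!grepl("^#", lines) & nzchar(lines)]
  if (length(lines) == 0L) stop_io("no records in ", path)
  con <- textConnection(lines)
  on.exit(close(con))
  gff <- utils::read.table(con, sep = "\t", stringsAsFactors = FALSE,
                           quote = "", comment.char = "",
                           col.names = c("seqid", "source", "type", "start",
                                         "end", "score", "strand", "phase",
                                         "attributes"))
  cds <- gff[gff$type == "CDS", , drop = FALSE]
  if (nrow(cds) == 0L) stop_io("no CDS features in ", path)
  get_attr <- function(attrs, key) {
    m <- regmatches(attrs, regexec(paste0("(?:^|;)", key, "=([^;]+)"), attrs))
    vapply(m, function(x) if (length(x) == 2) x[2] else NA_character_, "")
  }
  gene_id <- get_attr(cds$attributes, "Parent")
  gene_id[is.na(gene_id)] <- get_attr(cds$attributes[is.na(gene_id)], "ID")
  if (anyNA(gene_id)) stop_io("CDS feature without Parent/ID attribute")
  gene_models(data.frame(gene_id = gene_id, scaffold = cds$seqid,
                         strand = cds$strand, start = cds$start,
                         end = cds$end, stringsAsFactors = FALSE))
}

#' Construct/validate gene models
#' @param df data.frame with `gene_id`, `scaffold`, `strand`, `start`, `end`
#'   (1-based inclusive).
#' @return `gene_models` data.frame.
#' @export
gene_models <- function(df, ...) {
  if (any(df$end < df$start)) stop_io("inverted CDS interval")
  df <- df[order(df$gene_id, df$start), , drop = FALSE]
  by_gene <- split(seq_len(nrow(df)), df$gene_id)
  for (i in by_gene) {
    if (length(i) > 1 && any(df$start[i][-1] <= df$end[i][-length(i)]))
      stop_io("overlapping CDS intervals for gene ", df$gene_id[i[1]])
  }
  rownames(df) <- NULL
  class(df) <- c("gene_models", "data.frame")
  df
}

#' Write gene models to GFF3
#' @param x `gene_models`.
#' @param path output file.
#' @export
write_gene_models <- function(x, path) {
  df <- as.data.frame(x)
  lines <- c("##gff-version 3",
             sprintf("%s\tevoprofiler\tCDS\t%d\t%d\t.\t%s\t0\tParent=%s",
                     df$scaffold, df$start, df$end, df$strand, df$gene_id))
  writeLines(lines, path)
  invisible(path)
}

# ---- ExpressionMap / ExpressionMatrix --------------------------------------

#' Construct a clustered expression map
#'
#' Grid cells are addressed by 0-based `(row, col)`; the map is toroidal by
#' default (supercell neighborhoods wrap at the edges).
#'
#' @param cells data.frame with `gene_id`, `row`, `col`.
#' @param grid_rows,grid_cols grid dimensions.
#' @param toroidal logical.
#' @return `expression_map` object.
#' @export
expression_map <- function(cells, grid_rows, grid_cols, toroidal = TRUE) {
  if (anyDuplicated(cells$gene_id))
    stop_io("gene mapped to more than one cell: ",
            cells$gene_id[duplicated(cells$gene_id)][1])
  if (any(cells$row < 0 | cells$row >= grid_rows |
          cells$col < 0 | cells$col >= grid_cols))
    stop_io("gene mapped outside the grid")
  structure(list(cells = cells[, c("gene_id", "row", "col")],
                 grid_rows = as.integer(grid_rows),
                 grid_cols = as.integer(grid_cols),
                 toroidal = isTRUE(toroidal)),
            class = "expression_map")
}

#' Read an expression map from TSV
#' @param path TSV with `gene_id`, `row`, `col` (0-based).
#' @param grid_rows,grid_cols grid dimensions.
#' @param toroidal logical.
#' @return `expression_map`.
#' @export
read_expression_map <- function(path, grid_rows, grid_cols, toroidal = TRUE) {
  df <- read_tsv_checked(path, c("gene_id", "row", "col"))
  expression_map(df, grid_rows, grid_cols, toroidal)
}

#' Write an expression map to TSV
#' @param x `expression_map`.
#' @param path output file.
#' @export
write_expression_map <- function(x, path) write_tsv(x$cells, path)

#' Read a genes x conditions expression matrix from TSV
#' @param path TSV whose first column is `gene_id`, remaining columns are
#'   log2 expression means per condition.
#' @return numeric matrix with gene ids as rownames.
#' @export
read_expression_matrix <- function(path) {
  df <- read_tsv_checked(path, "gene_id")
  m <- as.matrix(df[, setdiff(names(df), "gene_id"), drop = FALSE])
  mode(m) <- "numeric"
  rownames(m) <- df$gene_id
  m
}

# ---- OGMetricTable ---------------------------------------------------------

#' Validate an OG metric table against the declared metric ranges
#'
#' Checks UNI in (0,1], DUP in \[0,1\], ACN >= 1, CNV >= 0,
#' EXP + CON + STA = 1 when all present, SYN and NSP in \[0,1\],
#' non-negative divergence/density metrics and PHC in \[0,1\]. Missing
#' values (NA) are allowed for any metric.
#'
#' @param df data.frame with column `og_id` plus any of [EVO_METRICS].
#' @param n_species number of species (upper bound for WGA); `Inf` skips
#'   that check.
#' @return the validated data.frame, columns ordered og_id then Table-1
#'   metric order.
#' @export
og_metric_table <- function(df, n_species = Inf) {
  if (!"og_id" %in% names(df)) stop_io("og_id column required")
  chk <- function(col, ok, what) {
    if (!col %in% names(df)) return(invisible())
    v <- df[[col]]
    bad <- !is.na(v) & !ok(v)
    if (any(bad)) stop_io(col, " ", what, " violated for OG ", df$og_id[bad][1])
  }
  chk("UNI", function(v) v > 0 & v <= 1, "in (0,1]")
  chk("DUP", function(v) v >= 0 & v <= 1, "in [0,1]")
  chk("ACN", function(v) v >= 1, ">= 1")
  chk("CNV", function(v) v >= 0, ">= 0")
  chk("SYN", function(v) v >= 0 & v <= 1, "in [0,1]")
  chk("NSP", function(v) v >= 0 & v <= 1, "in [0,1]")
  chk("PHC", function(v) v >= 0 & v <= 1, "in [0,1]")
  chk("WGA", function(v) v >= 0 & v <= n_species, "in [0, n_species]")
  for (col in c("PDS", "PDN", "SEL", "NSD", "SSD", "EVR", "AGE"))
    chk(col, function(v) v >= 0, ">= 0")
  if (all(c("EXP", "CON", "STA") %in% names(df))) {
    s <- df$EXP + df$CON + df$STA
    bad <- !is.na(s) & abs(s - 1) > 1e-9
    if (any(bad)) stop_io("EXP+CON+STA != 1 for OG ", df$og_id[bad][1])
  }
  keep <- c("og_id", intersect(EVO_METRICS, names(df)))
  df[, keep, drop = FALSE]
}

#' Write an OG or family metric table to TSV in deterministic column order
#' @param df metric table.
#' @param path output file.
#' @export
write_metric_table <- function(df, path) write_tsv(df, path)

#' Read a metric table written by [write_metric_table()]
#' @param path TSV file.
#' @return data.frame.
#' @export
read_metric_table <- function(path) read_tsv_checked(path, "og_id")

# ---- External report parsers ----------------------------------------------

#' Parse a gene-turnover (CAFE-style) report of per-branch count changes
#'
#' The report is a TSV with columns `og_id`, `branch`, `delta`, one row per
#' family (OG) per branch; `branch` names the child node of the edge (tip
#' label, or internal node label as assigned by [branch_labels()]). Each
#' branch is classified gain/loss/stable by the sign of `delta`.
#'
#' @param path report file.
#' @param tree `species_tree` whose branch labels the report must match.
#' @return `branch_events` data.frame (`og_id`, `branch`, `delta`, `label`).
#' @export
parse_cafe_report <- function(path, tree) {
  df <- read_tsv_checked(path, c("og_id", "branch", "delta"))
  labels <- branch_labels(tree)
  bad <- setdiff(unique(df$branch), labels)
  if (length(bad) > 0L)
    stop_io("branch label(s) not in tree: ", paste(bad, collapse = ", "))
  df$delta <- as.integer(df$delta)
  df$label <- ifelse(df$delta > 0, "gain", ifelse(df$delta < 0, "loss", "stable"))
  class(df) <- c("branch_events", "data.frame")
  df
}

#' Parse dS, dN and dN/dS from a PAML M0 (codeml mlc) output file
#'
#' Scans for `dS = <x>`/`dS: <x>` and `dN = <x>`/`dN: <x>` summary fields
#' (also matching codeml's `tree length for dN:`/`for dS:` lines). SEL is
#' dN/dS and is missing (NA) when dS = 0.
#'
#' @param path mlc-style file.
#' @return list with `PDS`, `PDN`, `SEL`.
#' @export
parse_paml_m0 <- function(path) {
  lines <- readLines(path)
  grab <- function(key) {
    pat <- paste0("(?:^|[^A-Za-z/])", key, "\\s*[:=]\\s*([0-9]*\\.?[0-9]+(?:[eE][+-]?[0-9]+)?)")
    hits <- regmatches(lines, regexec(pat, lines))
    vals <- unlist(lapply(hits, function(x) if (length(x) == 2) x[2] else NULL))
    if (length(vals) == 0L) stop_io("required field '", key, "' absent in ", path)
    as.numeric(vals[1])
  }
  # exclude dN/dS lines from the plain dS/dN matches by masking the ratio
  lines <- gsub("dN/dS", "omega", lines, fixed = TRUE)
  pds <- grab("dS")
  pdn <- grab("dN")
  sel <- if (pds == 0) NA_real_ else pdn / pds
  list(PDS = pds, PDN = pdn, SEL = sel)
}
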