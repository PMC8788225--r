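# Variation-based (NSP, NSD, SSD) and alignment-based (WGA, PHC) metrics:
# per-gene values from SNP annotation tables and per-nucleotide tracks,
# aggregated to per-OG values by unweighted gene means.

#' Per-gene SNP metrics: NSP, NSD, SSD
#'
#' NSP is the proportion of coding SNPs that are nonsynonymous (missing
#' when the gene has no coding SNPs at all); NSD and SSD are the
#' nonsynonymous and synonymous SNP densities over coding-sequence length.
#'
#' @param snps validated SNP annotation table ([snp_table()]).
#' @return data.frame `gene_id`, `NSP`, `NSD`, `SSD`.
#' @export
snp_metrics <- function(snps) {
  snps <- snp_table(snps)
  tot <- snps$n_syn + snps$n_nonsyn
  data.frame(gene_id = snps$gene_id,
             NSP = ifelse(tot == 0, NA_real_, snps$n_nonsyn / tot),
             NSD = snps$n_nonsyn / snps$cds_length,
             SSD = snps$n_syn / snps$cds_length,
             stringsAsFactors = FALSE)
}

#' Length-weighted mean of a nucleotide track over a gene's CDS
#'
#' Averages per-nucleotide track values over the union of the gene's CDS
#' intervals. CDS coordinates are 1-based inclusive (GFF3); track
#' intervals are 0-based half-open (bedGraph). Positions not covered by
#' any track interval contribute the track's declared default value.
#' Strand is ignored: per-nucleotide averages are strand-symmetric.
#'
#' @param gene `gene_models` rows for a single gene.
#' @param track `nucleotide_track`.
#' @return length-weighted mean.
#' @export
track_mean_over_cds <- function(gene, track) {
  if (nrow(gene) == 0L) stop("no CDS intervals", call. = FALSE)
  if (length(unique(gene$gene_id)) != 1L)
    stop("gene must contain a single gene_id", call. = FALSE)
  default <- attr(track, "default") %||% 0
  cds_len <- sum(gene$end - gene$start + 1L)
  if (cds_len <= 0L) stop("zero CDS length", call. = FALSE)
  total <- 0
  for (i in seq_len(nrow(gene))) {
    scaf <- gene$scaffold[i]
    lo <- gene$start[i] - 1L   # 0-based half-open [lo, hi)
    hi <- gene$end[i]
    tr <- track[track$scaffold == scaf, , drop = FALSE]
    covered <- 0L
    if (nrow(tr) > 0L) {
      ov_lo <- pmax(tr$start, lo)
      ov_hi <- pmin(tr$end, hi)
      len <- pmax(0L, ov_hi - ov_lo)
      total <- total + sum(len * tr$value)
      covered <- sum(len)
    }
    total <- total + (hi - lo - covered) * default
  }
  total / cds_len
}

#' Track means for every gene in a model set
#' @param models `gene_models`.
#' @param track `nucleotide_track`.
#' @return named numeric vector (by gene id).
#' @export
gene_track_means <- function(models, track) {
  genes <- unique(models$gene_id)
  vapply(genes, function(g)
    track_mean_over_cds(models[models$gene_id == g, , drop = FALSE], track),
    numeric(1))
}

#' Aggregate per-gene values to per-OG values
#'
#' Unweighted mean over member genes with defined values; missing (NA)
#' when no member gene has a value. When `focal_species` is given, only
#' member genes from that species are considered (the variation and
#' alignment data are single-reference-genome measurements).
#'
#' @param values named numeric vector (by gene id), NA allowed.
#' @param orthology `orthology_table`.
#' @param focal_species optional species restriction.
#' @return named numeric vector over OG ids.
#' @export
aggregate_gene_to_og <- function(values, orthology, focal_species = NULL) {
  mem <- orthology$members
  if (!is.null(focal_species))
    mem <- mem[mem$species == focal_species, , drop = FALSE]
  v <- values[match(mem$gene_id, names(values))]
  out <- tapply(v, factor(mem$og_id, levels = orthology$og_ids),
                function(x) if (all(is.na(x))) NA_real_ else mean(x, na.rm = TRUE))
  stats::setNames(as.numeric(out), orthology$og_ids)
}

#' Compute all site-based metrics per OG
#'
#' @param orthology `orthology_table`.
#' @param snps optional SNP annotation table.
#' @param models optional `gene_models`.
#' @param wga_track,phc_track optional `nucleotide_track`s (alignability
#'   depth and constraint score).
#' @param focal_species optional focal species for all per-gene data.
#' @return data.frame `og_id` plus whichever of NSP, NSD, SSD, WGA, PHC
#'   have inputs.
#' @export
site_metrics <- function(orthology, snps = NULL, models = NULL,
                         wga_track = NULL, phc_track = NULL,
                         focal_species = NULL) {
  out <- data.frame(og_id = orthology$og_ids, stringsAsFactors = FALSE)
  if (!is.null(snps)) {
    sm <- snp_metrics(snps)
    for (col in c("NSP", "NSD", "SSD")) {
      v <- stats::setNames(sm[[col]], sm$gene_id)
      out[[col]] <- aggregate_gene_to_og(v, orthology, focal_species)
    }
  }
  for (spec in list(c("WGA", "wga"), c("PHC", "phc"))) {
    track <- if (spec[2] == "wga") wga_track else phc_track
    if (is.null(track) || is.null(models)) next
    v <- gene_track_means(models, track)
    out[[spec[1]]] <- aggregate_gene_to_og(v, orthology, focal_species)
  }
  out
}
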