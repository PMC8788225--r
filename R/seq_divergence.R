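# Codon-level divergence per OG via the Nei-Gojobori (1986) counting
# method with equal substitution-pathway weighting and Jukes-Cantor
# correction. This is the package's desk-scale substitute for maximum
# likelihood codon models; parsed likelihood-program output takes
# precedence when supplied (see parse_paml_m0).

NUCS <- c("A", "C", "G", "T")

codon_strings <- function() {
  as.vector(outer(outer(NUCS, NUCS, paste0), NUCS, paste0))
}

#' Standard genetic code, named by codon
#' @return named character vector (64 codons to amino acids, `*` = stop).
#' @export
standard_genetic_code <- function() {
  gc <- Biostrings::GENETIC_CODE
  stats::setNames(as.character(gc), names(gc))
}

# Per-codon synonymous site count: for each position, the fraction of the
# three single-nucleotide changes that are synonymous, with stop-producing
# changes excluded from the denominator. Stop codons get NA.
codon_syn_sites <- function(code = standard_genetic_code()) {
  codons <- codon_strings()
  s <- stats::setNames(numeric(64), codons)
  for (cd in codons) {
    aa <- code[[cd]]
    if (aa == "*") { s[cd] <- NA_real_; next }
    tot <- 0
    for (pos in 1:3) {
      nts <- setdiff(NUCS, substr(cd, pos, pos))
      mut <- vapply(nts, function(n) { x <- cd; substr(x, pos, pos) <- n; x }, "")
      aas <- code[mut]
      valid <- aas != "*"
      if (!any(valid)) next
      tot <- tot + sum(aas[valid] == aa) / sum(valid)
    }
    s[cd] <- tot
  }
  s
}

# Pathway-averaged synonymous/nonsynonymous difference counts for one codon
# pair. Pathways (orderings of the differing positions) passing through a
# stop codon are excluded; if every pathway is blocked the codon pair is
# non-comparable (NA). Returns c(sd, nd) or c(NA, NA).
codon_pair_diffs <- function(a, b, code = standard_genetic_code()) {
  if (a == b) return(c(sd = 0, nd = 0))
  pos <- which(strsplit(a, "")[[1]] != strsplit(b, "")[[1]])
  perms <- if (length(pos) == 1L) list(pos)
           else if (length(pos) == 2L) list(pos, rev(pos))
           else list(pos[c(1,2,3)], pos[c(1,3,2)], pos[c(2,1,3)],
                     pos[c(2,3,1)], pos[c(3,1,2)], pos[c(3,2,1)])
  sd_tot <- 0; nd_tot <- 0; n_valid <- 0L
  for (ord in perms) {
    cur <- a; sd_p <- 0; nd_p <- 0; ok <- TRUE
    for (p in ord) {
      nxt <- cur
      substr(nxt, p, p) <- substr(b, p, p)
      if (code[[nxt]] == "*") { ok <- FALSE; break }
      if (code[[nxt]] == code[[cur]]) sd_p <- sd_p + 1 else nd_p <- nd_p + 1
      cur <- nxt
    }
    if (ok) { sd_tot <- sd_tot + sd_p; nd_tot <- nd_tot + nd_p; n_valid <- n_valid + 1L }
  }
  if (n_valid == 0L) return(c(sd = NA_real_, nd = NA_real_))
  c(sd = sd_tot / n_valid, nd = nd_tot / n_valid)
}

# cache of the 64-codon site table for the standard code
.ng86_cache <- new.env(parent = emptyenv())

#' Nei-Gojobori (NG86) pairwise codon counts and distances
#'
#' Splits the two aligned sequences into codons; codons containing gaps, N,
#' or a stop in either sequence are skipped pairwise. Synonymous site
#' counts per codon are the summed per-position fractions of non-stop
#' single-nucleotide changes that are synonymous, averaged over the two
#' sequences. Multi-nucleotide codon differences are averaged over all
#' stop-free substitution pathways with equal weight. Proportions are
#' Jukes-Cantor corrected: `d = -(3/4) log(1 - (4/3) p)`; a proportion
#' >= 3/4 leaves the distance undefined (NA).
#'
#' @param seq_a,seq_b aligned nucleotide strings, equal length, length
#'   divisible by 3.
#' @param code genetic code table (named codon -> amino acid, `*` = stop).
#' @return list: `S_sites`, `N_sites`, `Sd`, `Nd`, `pS`, `pN`, `dS`, `dN`,
#'   `n_codons` (comparable codons). All NA when no codon is comparable.
#' @export
ng86_pair <- function(seq_a, seq_b, code = standard_genetic_code()) {
  seq_a <- toupper(seq_a); seq_b <- toupper(seq_b)
  if (nchar(seq_a) != nchar(seq_b)) stop("unequal lengths", call. = FALSE)
  if (nchar(seq_a) %% 3L != 0L) stop("length not divisible by 3", call. = FALSE)
  std <- missing(code) || identical(code, standard_genetic_code())
  if (std && is.null(.ng86_cache$sites)) .ng86_cache$sites <- codon_syn_sites()
  sites <- if (std) .ng86_cache$sites else codon_syn_sites(code)
  n <- nchar(seq_a) / 3L
  starts <- 3L * (seq_len(n) - 1L) + 1L
  ca <- substring(seq_a, starts, starts + 2L)
  cb <- substring(seq_b, starts, starts + 2L)
  clean <- !grepl("[^ACGT]", ca) & !grepl("[^ACGT]", cb)
  clean[clean] <- code[ca[clean]] != "*" & code[cb[clean]] != "*"
  ca <- ca[clean]; cb <- cb[clean]
  empty <- list(S_sites = NA_real_, N_sites = NA_real_, Sd = NA_real_,
                Nd = NA_real_, pS = NA_real_, pN = NA_real_,
                dS = NA_real_, dN = NA_real_, n_codons = 0L)
  if (length(ca) == 0L) return(empty)
  diffs <- vapply(seq_along(ca),
                  function(i) codon_pair_diffs(ca[i], cb[i], code), numeric(2))
  usable <- !is.na(diffs[1, ])
  ca <- ca[usable]; cb <- cb[usable]
  if (length(ca) == 0L) return(empty)
  diffs <- diffs[, usable, drop = FALSE]
  s_sites <- (sum(sites[ca]) + sum(sites[cb])) / 2
  n_sites <- 3 * length(ca) - s_sites
  sd_ <- sum(diffs[1, ]); nd_ <- sum(diffs[2, ])
  ps <- if (s_sites > 0) sd_ / s_sites else 0
  pn <- if (n_sites > 0) nd_ / n_sites else 0
  jc <- function(p) if (p >= 0.75) NA_real_ else -0.75 * log(1 - 4 * p / 3)
  list(S_sites = s_sites, N_sites = n_sites, Sd = sd_, Nd = nd_,
       pS = ps, pN = pn, dS = jc(ps), dN = jc(pn), n_codons = length(ca))
}

#' Per-OG divergence metrics (PDS, PDN, SEL) from a codon alignment
#'
#' PDS and PDN are unweighted means of pairwise NG86 dS and dN over all
#' sequence pairs with defined values; SEL = PDN / PDS, missing when
#' PDS = 0 (or undefined).
#'
#' @param alignment named character vector of aligned coding sequences
#'   (>= 2 sequences).
#' @param code genetic code table.
#' @return list with `PDS`, `PDN`, `SEL`.
#' @export
og_divergence <- function(alignment, code = standard_genetic_code()) {
  if (length(alignment) < 2L) stop(">= 2 sequences required", call. = FALSE)
  validate_codon_alignment(alignment)
  idx <- utils::combn(length(alignment), 2)
  ds <- numeric(0); dn <- numeric(0)
  for (j in seq_len(ncol(idx))) {
    p <- ng86_pair(alignment[[idx[1, j]]], alignment[[idx[2, j]]], code)
    if (!is.na(p$dS)) ds <- c(ds, p$dS)
    if (!is.na(p$dN)) dn <- c(dn, p$dN)
  }
  pds <- if (length(ds) > 0) mean(ds) else NA_real_
  pdn <- if (length(dn) > 0) mean(dn) else NA_real_
  sel <- if (is.na(pds) || pds == 0) NA_real_ else pdn / pds
  list(PDS = pds, PDN = pdn, SEL = sel)
}

#' Divergence metrics for a set of OG alignments
#'
#' @param alignments named list of codon alignments (per OG).
#' @param paml optional named list of [parse_paml_m0()] results; when an OG
#'   is present there, the parsed values take precedence over NG86.
#' @param code genetic code table.
#' @return data.frame `og_id`, `PDS`, `PDN`, `SEL`.
#' @export
divergence_metrics <- function(alignments, paml = NULL,
                               code = standard_genetic_code()) {
  rows <- lapply(names(alignments), function(og) {
    v <- if (!is.null(paml) && og %in% names(paml)) paml[[og]]
         else og_divergence(alignments[[og]], code)
    data.frame(og_id = og, PDS = v$PDS, PDN = v$PDN, SEL = v$SEL,
               stringsAsFactors = FALSE)
  })
  out <- do.call(rbind, rows)
  rownames(out) <- NULL
  out
}
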