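# Family-level aggregation of OG metrics: delta-mean profiles, per-metric
# scaling, and significance by Wilcoxon rank-sum plus a size-matched
# permutation test.

#' OG sets per family
#'
#' An OG belongs to a family when it contains at least one cataloged gene
#' of that family; OGs may belong to several families.
#'
#' @param catalog `gene_catalog`.
#' @param orthology `orthology_table`.
#' @return named list: family -> character vector of OG ids.
#' @export
family_og_sets <- function(catalog, orthology) {
  gene_og <- stats::setNames(orthology$members$og_id, orthology$members$gene_id)
  ogs <- gene_og[match(catalog$gene_id, names(gene_og))]
  keep <- !is.na(ogs)
  lapply(split(ogs[keep], catalog$family[keep]), function(x) sort(unique(x)))
}

#' Family aggregates and delta statistics for every metric
#'
#' For each family and metric, computes the mean and the median over the
#' family's member OGs, and the delta: family aggregate minus the
#' aggregate over all other immune-family OGs. The OG universe is the
#' union of all families' OG sets. The complement of a family is the
#' universe minus the family's own OGs (`complement = "exclusive"`,
#' default: "all other OGs that contain an immune gene"); with
#' `"inclusive"` the complement is the union of the other families' OG
#' sets, so OGs shared between two families also appear in each other's
#' complement.
#'
#' @param og_metrics OG metric table (`og_id` + metric columns).
#' @param catalog `gene_catalog`.
#' @param orthology `orthology_table`.
#' @param stat aggregate for the delta: `"mean"` or `"median"`.
#' @param complement `"exclusive"` or `"inclusive"`.
#' @return long data.frame: `family`, `metric`, `n_ogs`, `mean`, `median`,
#'   `delta`.
#' @export
family_delta <- function(og_metrics, catalog, orthology,
                         stat = c("mean", "median"),
                         complement = c("exclusive", "inclusive")) {
  stat <- match.arg(stat)
  complement <- match.arg(complement)
  fam_ogs <- family_og_sets(catalog, orthology)
  universe <- sort(unique(unlist(fam_ogs)))
  metrics <- intersect(EVO_METRICS, names(og_metrics))
  agg_fun <- if (stat == "mean") mean else stats::median
  rows <- list()
  for (fam in names(fam_ogs)) {
    own <- fam_ogs[[fam]]
    comp <- if (complement == "exclusive") setdiff(universe, own)
            else sort(unique(unlist(fam_ogs[names(fam_ogs) != fam])))
    for (m in metrics) {
      v <- stats::setNames(og_metrics[[m]], og_metrics$og_id)
      vo <- v[own]; vc <- v[comp]
      vo <- vo[!is.na(vo)]; vc <- vc[!is.na(vc)]
      delta <- if (length(vo) == 0L || length(vc) == 0L) NA_real_
               else agg_fun(vo) - agg_fun(vc)
      rows[[length(rows) + 1L]] <- data.frame(
        family = fam, metric = m, n_ogs = length(vo),
        mean = if (length(vo)) mean(vo) else NA_real_,
        median = if (length(vo)) stats::median(vo) else NA_real_,
        delta = delta, stringsAsFactors = FALSE)
    }
  }
  out <- do.call(rbind, rows)
  out$metric <- factor(out$metric, levels = metrics)
  out <- out[order(out$family, out$metric), ]
  out$metric <- as.character(out$metric)
  rownames(out) <- NULL
  out
}

#' Scale deltas by the absolute maximum delta per metric
#'
#' `scaled_delta = delta / max_f |delta|` within each metric, so the most
#' deviant family per metric attains +1 or -1. A metric whose deltas are
#' all zero (or all missing) scales to all zeros.
#'
#' @param profile output of [family_delta()].
#' @return the profile with a `scaled_delta` column added.
#' @export
scale_deltas <- function(profile) {
  profile$scaled_delta <- NA_real_
  for (m in unique(profile$metric)) {
    i <- profile$metric == m
    d <- profile$delta[i]
    mx <- suppressWarnings(max(abs(d), na.rm = TRUE))
    profile$scaled_delta[i] <-
      if (!is.finite(mx) || mx == 0) ifelse(is.na(d), NA_real_, 0) else d / mx
  }
  profile
}

#' Significance stars for a p-value
#' @param p numeric p-value (NA allowed).
#' @return `"***"` for p <= 0.01, `"**"` for p <= 0.05, `"*"` for p <= 0.1,
#'   otherwise `""`.
#' @export
star_label <- function(p) {
  ifelse(is.na(p), "",
         ifelse(p <= 0.01, "***", ifelse(p <= 0.05, "**", ifelse(p <= 0.1, "*", ""))))
}

#' Wilcoxon and size-matched permutation significance for one family/metric
#'
#' Tests the family's OG metric values against all other immune-family OG
#' values. The Wilcoxon rank-sum test is two-sided. The permutation test
#' redraws size-matched sets without replacement from the pooled values and
#' compares permutation deltas with the observed delta; by default both
#' tails count (`|delta_perm| >= |delta_obs|`), matching the signed deltas
#' of the family profiles; `alternative = "greater"` counts only
#' `delta_perm > delta_obs` (the strictly one-sided reading). The plain
#' b/m estimate is reported; `add_one` applies the (b+1)/(m+1) correction.
#'
#' @param family_values numeric vector of the family's OG values.
#' @param other_values numeric vector of the complement's OG values.
#' @param n_perm number of permutations (>= 100).
#' @param seed integer seed for the permutation draw.
#' @param stat `"mean"` or `"median"` delta.
#' @param alternative `"two.sided"` (default) or `"greater"`.
#' @param add_one apply the (b+1)/(m+1) correction (off by default).
#' @return list: `p_wilcoxon`, `p_permutation`, `p_min`, `star`, `delta`.
#' @export
family_significance <- function(family_values, other_values, n_perm = 10000L,
                                seed = 1L, stat = c("mean", "median"),
                                alternative = c("two.sided", "greater"),
                                add_one = FALSE) {
  stat <- match.arg(stat)
  alternative <- match.arg(alternative)
  family_values <- family_values[!is.na(family_values)]
  other_values <- other_values[!is.na(other_values)]
  if (length(family_values) == 0L || length(other_values) == 0L)
    return(list(p_wilcoxon = NA_real_, p_permutation = NA_real_,
                p_min = NA_real_, star = "", delta = NA_real_))
  if (n_perm < 100L) stop("n_perm must be >= 100", call. = FALSE)
  agg <- if (stat == "mean") mean else stats::median
  obs <- agg(family_values) - agg(other_values)
  pw <- suppressWarnings(
    stats::wilcox.test(family_values, other_values,
                       alternative = "two.sided")$p.value)
  pool <- c(family_values, other_values)
  k <- length(family_values); n <- length(pool)
  old_seed <- get0(".Random.seed", envir = globalenv())
  set.seed(seed)
  perm_delta <- if (stat == "mean") {
    # means of random subsets from subset sums: vectorized
    idx <- replicate(n_perm, sample.int(n, k))
    s <- colSums(matrix(pool[idx], nrow = k))
    s / k - (sum(pool) - s) / (n - k)
  } else {
    vapply(seq_len(n_perm), function(i) {
      j <- sample.int(n, k)
      agg(pool[j]) - agg(pool[-j])
    }, numeric(1))
  }
  if (!is.null(old_seed)) assign(".Random.seed", old_seed, envir = globalenv())
  b <- if (alternative == "two.sided") sum(abs(perm_delta) >= abs(obs))
       else sum(perm_delta > obs)
  pp <- if (add_one) (b + 1) / (n_perm + 1) else b / n_perm
  pmin_ <- min(pw, pp, na.rm = TRUE)
  list(p_wilcoxon = pw, p_permutation = pp, p_min = pmin_,
       star = star_label(pmin_), delta = obs)
}

#' Full family profile table with significance
#'
#' Combines [family_delta()], [scale_deltas()] and [family_significance()]
#' for every family and metric.
#'
#' @param og_metrics OG metric table.
#' @param catalog `gene_catalog`.
#' @param orthology `orthology_table`.
#' @param stat aggregate statistic for deltas (`"mean"` for the headline
#'   profiles, `"median"` for clustering input).
#' @param n_perm permutations for the permutation test.
#' @param seed integer seed; each family/metric uses a sub-seed derived
#'   deterministically from it.
#' @param complement complement convention, see [family_delta()].
#' @return `family_profile` data.frame: `family`, `metric`, `n_ogs`,
#'   `mean`, `median`, `delta`, `scaled_delta`, `p_wilcoxon`,
#'   `p_permutation`, `p_min`, `star`.
#' @export
family_profile_table <- function(og_metrics, catalog, orthology,
                                 stat = c("mean", "median"),
                                 n_perm = 10000L, seed = 1L,
                                 complement = "exclusive") {
  stat <- match.arg(stat)
  prof <- family_delta(og_metrics, catalog, orthology, stat = stat,
                       complement = complement)
  prof <- scale_deltas(prof)
  fam_ogs <- family_og_sets(catalog, orthology)
  universe <- sort(unique(unlist(fam_ogs)))
  prof$p_wilcoxon <- NA_real_; prof$p_permutation <- NA_real_
  prof$p_min <- NA_real_; prof$star <- ""
  for (r in seq_len(nrow(prof))) {
    fam <- prof$family[r]; m <- prof$metric[r]
    v <- stats::setNames(og_metrics[[m]], og_metrics$og_id)
    own <- v[fam_ogs[[fam]]]
    comp <- v[setdiff(universe, fam_ogs[[fam]])]
    if (sum(!is.na(own)) < 2L) next
    sig <- family_significance(own, comp, n_perm = n_perm,
                               seed = seed + r, stat = stat)
    prof$p_wilcoxon[r] <- sig$p_wilcoxon
    prof$p_permutation[r] <- sig$p_permutation
    prof$p_min[r] <- sig$p_min
    prof$star[r] <- sig$star
  }
  attr(prof, "stat") <- stat
  attr(prof, "seed") <- seed
  attr(prof, "n_perm") <- n_perm
  class(prof) <- c("family_profile", "data.frame")
  prof
}

#' Family x metric matrix from a profile table
#'
#' @param profile `family_profile` (or [family_delta()] output).
#' @param value which column to spread (`"median"`, `"mean"`,
#'   `"scaled_delta"`, ...).
#' @return numeric matrix, families as rows, metrics as columns (Table-1
#'   metric order).
#' @export
profile_matrix <- function(profile, value = "median") {
  fams <- sort(unique(profile$family))
  mets <- intersect(EVO_METRICS, unique(profile$metric))
  m <- matrix(NA_real_, length(fams), length(mets),
              dimnames = list(fams, mets))
  m[cbind(match(profile$family, fams), match(profile$metric, mets))] <-
    profile[[value]]
  m
}
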