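#' Select individuals carrying one Native ancestry component
#'
#' Applies the panel-selection thresholds for ancestry-conditioned allele
#' frequencies: individuals with more than `min_target` estimated ancestry
#' from the target Native group, at most `max_other_native` combined
#' ancestry from all other Native groups, and at most `max_east_asian` East
#' Asian ancestry.
#'
#' @param ancestry Tibble of per-individual ancestry proportions:
#'   `individual` plus one column per component.
#' @param group Column name of the target Native component.
#' @param other_native Character vector of the other Native component
#'   columns.
#' @param east_asian Character vector of East Asian component columns.
#' @param min_target,max_other_native,max_east_asian Selection thresholds.
#' @return Character vector of qualifying individual ids.
#' @export
select_ancestry_panel <- function(ancestry, group, other_native,
                                  east_asian = character(),
                                  min_target = 0.10,
                                  max_other_native = 0.01,
                                  max_east_asian = 0.01) {
  stopifnot(group %in% names(ancestry),
            all(other_native %in% names(ancestry)),
            all(east_asian %in% names(ancestry)))
  tgt <- ancestry[[group]]
  other <- if (length(other_native)) {
    rowSums(as.matrix(ancestry[, other_native, drop = FALSE]))
  } else 0
  ea <- if (length(east_asian)) {
    rowSums(as.matrix(ancestry[, east_asian, drop = FALSE]))
  } else 0
  ancestry$individual[tgt > min_target & other < max_other_native &
                        ea < max_east_asian]
}

#' Ancestry-conditioned allele frequencies
#'
#' Pools, per SNP, the alleles carried on haplotypes whose local ancestry
#' is the target ancestry (e.g. Native), across a selected panel of
#' individuals, and computes the allele frequency. Haplotypes with other
#' local ancestries are excluded from both numerator and denominator. SNPs
#' with no qualifying haplotype are kept with `n_hap = 0`, `frequency = NA`
#' and `flagged = TRUE`.
#'
#' @param calls Haplotype-call tibble: `individual`, `snp`, `hap`
#'   (haplotype index), `allele` (0/1), `local_ancestry` (categorical).
#' @param individuals Ids of panel members (see
#'   [select_ancestry_panel()]); `NULL` keeps everyone.
#' @param target_ancestry Local-ancestry value whose alleles are pooled.
#' @return Tibble: `snp`, `allele_count`, `n_hap`, `frequency`, `flagged`.
#' @export
aggregate_ancestry_frequencies <- function(calls, individuals = NULL,
                                           target_ancestry = "Native") {
  stopifnot(all(c("individual", "snp", "allele", "local_ancestry") %in%
                  names(calls)))
  if (!all(calls$allele %in% c(0L, 1L))) abort("alleles must be 0/1")
  keep <- calls
  if (!is.null(individuals)) {
    keep <- dplyr::filter(keep, .data$individual %in% individuals)
  }
  counted <- keep |>
    dplyr::filter(.data$local_ancestry == target_ancestry) |>
    dplyr::group_by(.data$snp) |>
    dplyr::summarise(allele_count = sum(.data$allele),
                     n_hap = dplyr::n(), .groups = "drop")
  tibble::tibble(snp = unique(calls$snp)) |>
    dplyr::left_join(counted, by = "snp") |>
    dplyr::mutate(allele_count = dplyr::coalesce(.data$allele_count, 0L),
                  n_hap = dplyr::coalesce(.data$n_hap, 0L),
                  frequency = dplyr::if_else(.data$n_hap > 0,
                                             .data$allele_count / .data$n_hap,
                                             NA_real_),
                  flagged = .data$n_hap == 0)
}

#' Welch two-sample t-test on allele frequencies
#'
#' Two-sample t-test assuming unequal variances, computed from Bernoulli
#' summary statistics: `t = (fA - fB) / sqrt(fA(1-fA)/nA + fB(1-fB)/nB)`
#' with Welch-Satterthwaite degrees of freedom, algebraically identical to
#' running `t.test` on the raw 0/1 allele vectors. Vectorized over SNPs.
#'
#' @param freq_a,freq_b Allele frequencies in the two groups.
#' @param n_a,n_b Haplotype counts (>= 2).
#' @return Tibble: `estimate` (fA - fB), `statistic`, `df`, `p_value`,
#'   `degenerate` (both variances zero with unequal frequencies, where the
#'   p-value degenerates to 0).
#' @export
welch_freq_test <- function(freq_a, n_a, freq_b, n_b) {
  stopifnot(all(n_a >= 2), all(n_b >= 2),
            all(freq_a >= 0 & freq_a <= 1), all(freq_b >= 0 & freq_b <= 1))
  va <- freq_a * (1 - freq_a) / n_a
  vb <- freq_b * (1 - freq_b) / n_b
  se <- sqrt(va + vb)
  diff <- freq_a - freq_b
  tstat <- ifelse(se > 0, diff / se, ifelse(diff == 0, 0, Inf * sign(diff)))
  df <- ifelse(se > 0,
               (va + vb)^2 / (va^2 / (n_a - 1) + vb^2 / (n_b - 1)),
               Inf)
  p <- ifelse(is.finite(tstat), 2 * pt(-abs(tstat), df),
              0)
  p[se == 0 & diff == 0] <- 1
  tibble::tibble(estimate = diff, statistic = tstat, df = df, p_value = p,
                 degenerate = se == 0 & diff != 0)
}

#' Benjamini-Hochberg FDR adjustment
#'
#' Step-up false-discovery-rate adjusted p-values (monotone, capped at 1),
#' with significance conventionally called at 0.05.
#'
#' @param p Numeric vector of p-values in `[0, 1]`.
#' @return Adjusted p-values, same length and order.
#' @export
fdr_adjust <- function(p) {
  if (!length(p)) abort("empty p-value vector")
  stopifnot(all(p >= 0 & p <= 1))
  p.adjust(p, method = "BH")
}

#' Build matched-SNP candidate pools for the resampling null
#'
#' For each index SNP, finds genome-wide SNPs matched on statistical power:
#' haplotype counts in both groups within `count_tolerance` of the index
#' SNP's, and minor-allele frequency within `maf_tolerance` in group A
#' (set I) or group B (set II). Index SNPs themselves are always excluded
#' from the pools.
#'
#' @param index_snps,genome_snps Tibbles with columns `snp`, `n_a`, `n_b`,
#'   `freq_a`, `freq_b`. Minor-allele frequencies are derived as
#'   `min(f, 1 - f)` per group.
#' @param count_tolerance Allowed absolute difference in haplotype counts.
#' @param maf_tolerance Allowed absolute difference in MAF.
#' @return Tibble: `index_snp`, `snp`, `set` ("I" or "II"). Errors, naming
#'   the SNP, if any index SNP has an empty pool in either set.
#' @export
build_matched_pools <- function(index_snps, genome_snps,
                                count_tolerance = 20, maf_tolerance = 0.01) {
  need <- c("snp", "n_a", "n_b", "freq_a", "freq_b")
  stopifnot(all(need %in% names(index_snps)), all(need %in% names(genome_snps)))
  cand <- dplyr::filter(genome_snps, !(.data$snp %in% index_snps$snp))
  maf <- function(f) pmin(f, 1 - f)
  pools <- purrr::map_dfr(seq_len(nrow(index_snps)), function(i) {
    ix <- index_snps[i, ]
    counts_ok <- abs(cand$n_a - ix$n_a) <= count_tolerance &
      abs(cand$n_b - ix$n_b) <= count_tolerance
    set1 <- counts_ok & abs(maf(cand$freq_a) - maf(ix$freq_a)) <= maf_tolerance
    set2 <- counts_ok & abs(maf(cand$freq_b) - maf(ix$freq_b)) <= maf_tolerance
    dplyr::bind_rows(
      tibble::tibble(index_snp = ix$snp, snp = cand$snp[set1], set = "I"),
      tibble::tibble(index_snp = ix$snp, snp = cand$snp[set2], set = "II"))
  })
  for (s in c("I", "II")) {
    sizes <- table(factor(pools$index_snp[pools$set == s],
                          levels = index_snps$snp))
    if (any(sizes == 0)) {
      abort(paste0("empty set-", s, " matched pool for index SNP: ",
                   paste(names(sizes)[sizes == 0], collapse = ", ")))
    }
  }
  pools
}

#' Empirical p-value for joint allele-frequency differentiation
#'
#' Tests whether a set of index SNPs is jointly more differentiated between
#' two ancestry groups than matched random SNPs. The statistic is the mean
#' over index SNPs of `-log p` from the Welch test; each of `n_sets`
#' resampling iterations draws one matched SNP per index SNP from its pool
#' and recomputes the statistic. The empirical p-value is `(k + 1) /
#' (n_sets + 1)`, where with the default `tail = "ge"` k counts random sets
#' at least as differentiated as the observed (`tail = "le"` counts sets at
#' most as differentiated).
#'
#' @param index_snps Tibble with `snp`, `n_a`, `n_b`, `freq_a`, `freq_b`.
#' @param pools Matched-pool tibble from [build_matched_pools()], already
#'   filtered to one set.
#' @param genome_snps SNP summary table supplying the pool SNPs' counts and
#'   frequencies.
#' @param n_sets Number of random sets.
#' @param tail Which tail defines k (see above).
#' @param seed Optional integer seed.
#' @return One-row tibble: `observed` (mean -log p), `p_empirical`,
#'   `n_sets`, `tail`.
#' @export
empirical_differentiation_p <- function(index_snps, pools, genome_snps,
                                        n_sets = 10000,
                                        tail = c("ge", "le"), seed = NULL) {
  tail <- match.arg(tail)
  if (!is.null(seed)) set.seed(seed)
  if (!nrow(pools)) abort("empty matched pools")
  neglogp <- function(tbl) {
    -log(pmax(welch_freq_test(tbl$freq_a, tbl$n_a, tbl$freq_b, tbl$n_b)$p_value,
              1e-300))
  }
  observed <- mean(neglogp(index_snps))
  lk <- genome_snps[match(pools$snp, genome_snps$snp), ]
  pool_stat <- split(neglogp(lk), factor(pools$index_snp,
                                         levels = index_snps$snp))
  if (any(lengths(pool_stat) == 0)) {
    abort(paste0("no pool SNPs for index SNP: ",
                 paste(names(pool_stat)[lengths(pool_stat) == 0],
                       collapse = ", ")))
  }
  draws <- vapply(pool_stat,
                  function(v) v[sample.int(length(v), n_sets, replace = TRUE)],
                  numeric(n_sets))
  stat <- rowMeans(draws)
  k <- if (tail == "ge") sum(stat >= observed) else sum(stat <= observed)
  tibble::tibble(observed = observed,
                 p_empirical = (k + 1) / (n_sets + 1),
                 n_sets = n_sets, tail = tail)
}

#' Direction-of-effect consistency check
#'
#' For each SNP, checks whether the allele at higher frequency in group A
#' than group B has the same direction of effect in the source GWAS as the
#' ancestry-contrast regression: consistent iff
#' `sign(fA - fB) * sign(gwas_beta) == sign(contrast_beta)`. Equal
#' frequencies are flagged indeterminate.
#'
#' @param freq_a,freq_b Group allele frequencies for the counted allele.
#' @param gwas_beta GWAS effect sizes for the counted allele.
#' @param contrast_beta Ancestry-contrast regression coefficient(s);
#'   recycled if scalar.
#' @return Tibble: `consistent` (logical, NA when indeterminate),
#'   `indeterminate`.
#' @export
direction_consistency <- function(freq_a, freq_b, gwas_beta, contrast_beta) {
  n <- length(freq_a)
  contrast_beta <- rep_len(contrast_beta, n)
  ind <- freq_a == freq_b
  cons <- sign(freq_a - freq_b) * sign(gwas_beta) == sign(contrast_beta)
  cons[ind] <- NA
  tibble::tibble(consistent = cons, indeterminate = ind)
}
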