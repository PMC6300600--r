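test_that("panel selection applies the ancestry thresholds", {
  anc <- tibble::tibble(individual = paste0("i", 1:5),
                        andes = c(0.15, 0.10, 0.30, 0.12, 0.5),
                        mapuche = c(0.005, 0.0, 0.02, 0.005, 0.0),
                        east_asia = c(0.0, 0.0, 0.0, 0.02, 0.005))
  got <- select_ancestry_panel(anc, "andes", other_native = "mapuche",
                               east_asian = "east_asia")
  # i2 fails >10% target, i3 fails <1% other native, i4 fails <1% East Asian
  expect_equal(got, c("i1", "i5"))
})

test_that("ancestry-conditioned frequencies pool only target-ancestry haplotypes", {
  calls <- tibble::tibble(
    individual = rep(c("i1", "i2"), each = 2),
    snp = "rs1", hap = rep(1:2, 2),
    allele = c(1L, 1L, 0L, 0L),
    local_ancestry = "Native")
  fr <- aggregate_ancestry_frequencies(calls)
  expect_equal(fr$frequency, 0.5)
  expect_equal(fr$n_hap, 4L)

  calls$local_ancestry[2] <- "European"
  fr2 <- aggregate_ancestry_frequencies(calls)
  expect_equal(fr2$n_hap, 3L)
  expect_equal(fr2$frequency, 1 / 3)

  # toy table of 5 individuals x 3 SNPs vs exhaustive hand tally
  set.seed(31)
  toy <- tidyr::expand_grid(individual = paste0("i", 1:5),
                            snp = paste0("rs", 1:3), hap = 1:2) |>
    dplyr::mutate(allele = rbinom(dplyr::n(), 1, 0.4),
                  local_ancestry = sample(c("Native", "European", "African"),
                                          dplyr::n(), replace = TRUE))
  keep_ids <- c("i1", "i2", "i4")
  got <- aggregate_ancestry_frequencies(toy, individuals = keep_ids)
  for (s in paste0("rs", 1:3)) {
    sub <- toy[toy$snp == s & toy$individual %in% keep_ids &
                 toy$local_ancestry == "Native", ]
    expect_equal(got$allele_count[got$snp == s], sum(sub$allele))
    expect_equal(got$n_hap[got$snp == s], nrow(sub))
  }

  # a SNP with no qualifying haplotypes is flagged, not dropped
  toy2 <- dplyr::mutate(toy, local_ancestry =
                          ifelse(snp == "rs2", "European", local_ancestry))
  got2 <- aggregate_ancestry_frequencies(toy2)
  expect_true(got2$flagged[got2$snp == "rs2"])
  expect_true(is.na(got2$frequency[got2$snp == "rs2"]))
})

test_that("Welch test from frequency summaries matches direct formulas", {
  null_case <- welch_freq_test(0.5, 50, 0.5, 80)
  expect_equal(null_case$statistic, 0)
  expect_equal(null_case$p_value, 1)

  wt <- welch_freq_test(0.6, 100, 0.4, 100)
  expect_equal(wt$statistic, 0.2 / sqrt(0.0048), tolerance = 1e-4)
  expect_equal(wt$statistic, 2.8868, tolerance = 1e-4)

  # p-value vs numeric integration of the t density at the Welch df
  va <- 0.6 * 0.4 / 100; vb <- 0.4 * 0.6 / 100
  df <- (va + vb)^2 / (va^2 / 99 + vb^2 / 99)
  tail_mass <- stats::integrate(function(x) stats::dt(x, df),
                                abs(wt$statistic), Inf,
                                rel.tol = 1e-10)$value
  expect_equal(wt$p_value, 2 * tail_mass, tolerance = 1e-6)

  # t.test on the raw 0/1 vectors differs only by the Bessel n/(n-1)
  # variance factor; at n = 100 the two agree to well under 1%
  a <- rep(c(1, 0), c(60, 40)); b <- rep(c(1, 0), c(40, 60))
  tt <- stats::t.test(a, b)
  expect_equal(wt$statistic, unname(tt$statistic), tolerance = 0.01)
  expect_equal(wt$p_value, tt$p.value, tolerance = 0.05)

  degen <- welch_freq_test(1, 10, 0, 10)
  expect_true(degen$degenerate)
  expect_equal(degen$p_value, 0)
})

test_that("BH adjustment matches the step-up formula and is idempotent", {
  expect_equal(fdr_adjust(0.05), 0.05)
  expect_equal(fdr_adjust(c(0.01, 0.04)), c(0.02, 0.04))
  set.seed(41)
  p <- runif(50)^2
  adj <- fdr_adjust(p)
  expect_equal(adj, bh_step_up(p), tolerance = 1e-12)
  # monotone on sorted inputs, idempotent as a selection rule
  expect_true(all(diff(adj[order(p)]) >= -1e-12))
  expect_true(all(fdr_adjust(adj) >= adj - 1e-12))
  expect_error(fdr_adjust(numeric(0)), "empty")
})

test_that("matched pools respect the count and MAF windows exactly", {
  index <- tibble::tibble(snp = "idx", n_a = 100L, n_b = 120L,
                          freq_a = 0.30, freq_b = 0.45)
  genome <- tibble::tibble(
    snp = c("clone", "edge20", "edge21", "maf_far", "maf_b_only", "folded"),
    n_a = c(100L, 120L, 121L, 100L, 100L, 100L),
    n_b = c(120L, 100L, 120L, 120L, 120L, 120L),
    freq_a = c(0.30, 0.305, 0.30, 0.50, 0.50, 0.70),
    freq_b = c(0.45, 0.45, 0.45, 0.45, 0.4505, 0.45))
  pools <- build_matched_pools(index, genome)
  s1 <- pools$snp[pools$set == "I"]
  # maf is the folded frequency, so freq_a = 0.70 matches maf 0.30;
  # the 21-off count is excluded
  expect_setequal(s1, c("clone", "edge20", "folded"))
  s2 <- pools$snp[pools$set == "II"]
  expect_setequal(s2, c("clone", "edge20", "maf_far", "maf_b_only", "folded"))

  # brute-force predicate scan on a random 500-SNP table
  set.seed(51)
  gtab <- tibble::tibble(snp = paste0("g", 1:500),
                         n_a = sample(60:140, 500, replace = TRUE),
                         n_b = sample(80:160, 500, replace = TRUE),
                         freq_a = runif(500), freq_b = runif(500))
  pools2 <- build_matched_pools(index, gtab)
  maf <- function(f) pmin(f, 1 - f)
  pred1 <- with(gtab, abs(n_a - 100) <= 20 & abs(n_b - 120) <= 20 &
                  abs(maf(freq_a) - 0.30) <= 0.01)
  expect_setequal(pools2$snp[pools2$set == "I"], gtab$snp[pred1])

  empty_idx <- tibble::tibble(snp = "lonely", n_a = 10000L, n_b = 10000L,
                              freq_a = 0.5, freq_b = 0.5)
  expect_error(build_matched_pools(empty_idx, gtab), "lonely")
})

test_that("empirical differentiation p-value matches enumeration", {
  # degenerate null: every pool SNP carries the index SNP's own p-value
  index <- tibble::tibble(snp = c("i1", "i2"),
                          n_a = 100L, n_b = 100L,
                          freq_a = c(0.6, 0.7), freq_b = c(0.4, 0.5))
  clones <- tibble::tibble(
    snp = c(paste0("c1_", 1:3), paste0("c2_", 1:3)),
    n_a = 100L, n_b = 100L,
    freq_a = rep(index$freq_a, each = 3),
    freq_b = rep(index$freq_b, each = 3))
  pools <- tibble::tibble(index_snp = rep(c("i1", "i2"), each = 3),
                          snp = clones$snp, set = "I")
  out <- empirical_differentiation_p(index, pools, clones, n_sets = 200,
                                     seed = 1)
  expect_equal(out$p_empirical, 1)

  # index strictly more differentiated than every pool SNP
  weak <- dplyr::mutate(clones, freq_a = 0.5, freq_b = 0.52)
  out2 <- empirical_differentiation_p(index, pools, weak, n_sets = 200,
                                      seed = 2)
  expect_equal(out2$p_empirical, 1 / 201)
  # and the literal opposite tail flips the verdict
  out2le <- empirical_differentiation_p(index, pools, weak, n_sets = 200,
                                        tail = "le", seed = 2)
  expect_equal(out2le$p_empirical, 1)

  # tiny instance vs full enumeration of 5 x 5 pool combinations
  set.seed(61)
  pool_tbl <- tibble::tibble(snp = paste0("p", 1:10),
                             n_a = 100L, n_b = 100L,
                             freq_a = runif(10, 0.3, 0.7),
                             freq_b = runif(10, 0.3, 0.7))
  pools3 <- tibble::tibble(index_snp = rep(c("i1", "i2"), each = 5),
                           snp = pool_tbl$snp, set = "I")
  nl <- function(fa, fb, n = 100) {
    -log(welch_freq_test(fa, n, fb, n)$p_value)
  }
  obs <- mean(c(nl(0.6, 0.4), nl(0.7, 0.5)))
  s1 <- vapply(1:5, function(i) nl(pool_tbl$freq_a[i], pool_tbl$freq_b[i]),
               numeric(1))
  s2 <- vapply(6:10, function(i) nl(pool_tbl$freq_a[i], pool_tbl$freq_b[i]),
               numeric(1))
  enum <- mean(outer(s1, s2, function(x, y) (x + y) / 2) >= obs)
  n_mc <- 4000
  got <- empirical_differentiation_p(index, pools3, pool_tbl, n_sets = n_mc,
                                     seed = 3)
  se <- sqrt(enum * (1 - enum) / n_mc)
  expect_lt(abs(got$p_empirical - (enum * n_mc + 1) / (n_mc + 1)), 3 * se + 1e-9)
})

test_that("direction consistency follows the sign truth table", {
  expect_true(direction_consistency(0.6, 0.4, 1.2, 0.5)$consistent)
  expect_false(direction_consistency(0.6, 0.4, 1.2, -0.5)$consistent)

  # all 8 sign combinations
  signs <- expand.grid(d = c(-1, 1), g = c(-1, 1), c = c(-1, 1))
  got <- direction_consistency(0.5 + 0.1 * signs$d, 0.5,
                               signs$g, signs$c)
  expect_equal(got$consistent, signs$d * signs$g == signs$c)

  tie <- direction_consistency(0.5, 0.5, 1, 1)
  expect_true(tie$indeterminate)
  expect_true(is.na(tie$consistent))
})
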