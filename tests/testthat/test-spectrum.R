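mk_obs <- function(counts, additions = NULL, starts = NULL, ends = NULL,
                   mature = "miR-t", sample = "s1") {
  n <- length(counts)
  if (is.null(additions)) additions <- rep("", n)
  if (is.null(starts)) starts <- rep(10L, n)
  if (is.null(ends)) ends <- 30L + seq_len(n)
  tibble::tibble(sample_id = sample, mature_id = mature,
                 precursor_id = "p", template_start = as.integer(starts),
                 template_end = as.integer(ends), addition = additions,
                 count = as.integer(counts),
                 sequence = sprintf("%s-%02d", mature, seq_len(n)))
}

test_that("spectra compute percentages, dominance fold and the report floor", {
  sp <- build_spectrum(mk_obs(c(900, 100)), "miR-t")
  expect_equal(sp$species$percentage, c(90, 10))
  expect_equal(sp$fold_most_secondary, 9)

  expect_identical(nrow(build_spectrum(mk_obs(9), "miR-t")$species), 0L)
  expect_identical(nrow(build_spectrum(mk_obs(10), "miR-t")$species), 1L)

  sp <- build_spectrum(mk_obs(c(117, 100)), "miR-t")
  expect_equal(sp$fold_most_secondary, 1.17)
})

test_that("spectrum percentages sum to 100 and the floor is monotone", {
  set.seed(8)
  for (i in 1:10) {
    counts <- sample(1:500, sample(2:8, 1))
    obs <- mk_obs(counts)
    sp10 <- build_spectrum(obs, "miR-t", min_count = 10L)
    if (nrow(sp10$species) > 0) {
      expect_equal(sum(sp10$species$percentage), 100, tolerance = 1e-9)
    }
    for (floor2 in c(50L, 100L)) {
      sp2 <- build_spectrum(obs, "miR-t", min_count = floor2)
      expect_lte(nrow(sp2$species), nrow(sp10$species))
    }
  }
})

test_that("addition shares are computed under both denominators", {
  obs <- dplyr::bind_rows(mk_obs(c(90, 10), c("", "A")),
                          mk_obs(c(300, 40, 20), c("", "T", "AA"),
                                 mature = "miR-u"))
  s <- nta_summary(build_spectra(obs))
  expect_equal(s$totals$type_fraction, 3 / 5)
  expect_equal(s$totals$count_fraction, 70 / 460)
  ba <- s$by_addition
  # per-addition fractions sum exactly to the totals
  expect_equal(sum(ba$type_fraction_all), s$totals$type_fraction)
  expect_equal(sum(ba$count_fraction_all), s$totals$count_fraction)
  expect_equal(sum(ba$type_fraction_modified), 1)
  expect_equal(sum(ba$count_fraction_modified), 1)
  expect_identical(s$doubles$addition, "AA")
  # U printed for T additions
  expect_setequal(ba$addition, c("A", "U", "AA"))

  # all-unmodified input: every share is exactly zero
  s0 <- nta_summary(build_spectra(mk_obs(c(50, 60))))
  expect_identical(s0$totals$type_fraction, 0)
  expect_identical(s0$totals$count_fraction, 0)
  expect_identical(nrow(s0$by_addition), 0L)
})

test_that("type and count shares agree between global and per-locus passes", {
  cfg <- sim_config(n_loci = 12, n_reads = 30000, seed = 17)
  ref <- generate_reference(cfg)
  lib <- generate_library(ref, cfg, "normal", seed = 41)
  obs <- call_sample_isomirs(list(normal = lib$reads_cs), ref)
  spectra <- build_spectra(obs)
  s <- nta_summary(spectra)
  per_locus <- dplyr::summarise(
    dplyr::group_by(spectra, mature_id),
    n_mod = sum(nzchar(addition)), n = dplyr::n(),
    c_mod = sum(count[nzchar(addition)]), c = sum(count))
  expect_equal(s$totals$type_fraction,
               sum(per_locus$n_mod) / sum(per_locus$n))
  expect_equal(s$totals$count_fraction,
               sum(per_locus$c_mod) / sum(per_locus$c))
})

test_that("end heterogeneity counts 5' and 3' template variants", {
  prec <- tibble::tibble(precursor_id = "p",
                         sequence = paste(rep("ACGT", 20), collapse = ""))
  ann <- tibble::tibble(mature_id = "miR-t", precursor_id = "p",
                        start = 44L, end = 65L)
  ref <- reference_set(prec, ann)
  obs <- mk_obs(c(100, 50, 30, 20),
                additions = c("", "", "", "A"),
                starts = c(44L, 44L, 43L, 44L),
                ends = c(65L, 61L, 65L, 65L))
  het <- end_heterogeneity(build_spectra(obs), ref)
  # additions excluded; of 3 template species one is 3'-variant, one 5'
  expect_equal(het$frac_3p_variant, 1 / 3)
  expect_equal(het$frac_5p_variant, 1 / 3)

  only_canon <- end_heterogeneity(build_spectra(mk_obs(100, starts = 44L,
                                                       ends = 65L)), ref)
  expect_equal(only_canon$frac_3p_variant, 0)
  expect_equal(only_canon$frac_5p_variant, 0)
})

test_that("length distributions are count-weighted with a reported mode", {
  obs <- mk_obs(c(100, 800, 100), ends = c(30L, 31L, 32L))  # lengths 21/22/23
  ld <- length_distribution(obs)
  expect_identical(ld$length, c(21L, 22L, 23L))
  expect_identical(unname(attr(ld, "mode")), 22L)
  expect_identical(nrow(length_distribution(mk_obs(integer(0))[0, ])), 0L)
  # additions count toward length
  ld2 <- length_distribution(mk_obs(10, additions = "AA", ends = 30L))
  expect_identical(ld2$length, 23L)
})

test_that("expression/type correlation handles coupled, decoupled and tiny inputs", {
  # perfectly coupled: type number strictly increases with expression
  obs <- dplyr::bind_rows(lapply(1:6, function(i) {
    mk_obs(rep(2000 * i, i + 1), mature = sprintf("miR-%02d", i))
  }))
  ec <- expression_type_correlation(build_spectra(obs), species_min = 99,
                                    locus_min = 999)
  expect_equal(unname(ec$rho["s1"]), 1)

  # two qualifying loci: undefined correlation, table still emitted
  obs2 <- dplyr::bind_rows(mk_obs(5000, mature = "miR-a"),
                           mk_obs(4000, mature = "miR-b"))
  ec2 <- expression_type_correlation(build_spectra(obs2))
  expect_true(is.na(ec2$rho["s1"]))
  expect_identical(nrow(ec2$table), 2L)

  # decoupled generator: type count independent of expression
  set.seed(123)
  obs3 <- dplyr::bind_rows(lapply(1:50, function(i) {
    k <- sample(1:6, 1)
    mk_obs(rep(round(stats::rlnorm(1, 9, 0.7)), k),
           mature = sprintf("miR-%03d", i))
  }))
  ec3 <- expression_type_correlation(build_spectra(obs3))
  expect_lt(abs(unname(ec3$rho["s1"])), 0.3)
})
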