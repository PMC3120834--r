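mk_spectra <- function(...) {
  build_spectra(dplyr::bind_rows(...))
}

sp1 <- function(counts, mature, sample, additions = NULL) {
  n <- length(counts)
  if (is.null(additions)) additions <- rep("", n)
  tibble::tibble(sample_id = sample, mature_id = mature, precursor_id = "p",
                 template_start = 10L, template_end = 30L + seq_len(n),
                 addition = additions, count = as.integer(counts),
                 sequence = sprintf("%s%02d", mature, seq_len(n)))
}

test_that("quantification schemes: most-abundant isomiR versus sum", {
  spectra <- mk_spectra(sp1(c(1000, 200, 50), "miR-a", "s1"),
                        sp1(c(400, 100), "miR-b", "s1"))
  most <- quantify(spectra, "most")
  sums <- quantify(spectra, "sum")
  expect_identical(most$value[most$mature_id == "miR-a"], 1000L)
  expect_identical(sums$value[sums$mature_id == "miR-a"], 1250L)
  expect_true(all(dplyr::left_join(sums, most,
                                   by = c("sample_id", "mature_id"),
                                   suffix = c("_s", "_m"))$value_s >=
                    dplyr::left_join(sums, most,
                                     by = c("sample_id", "mature_id"),
                                     suffix = c("_s", "_m"))$value_m))
})

test_that("top-N ranking is deterministic under ties", {
  profile <- tibble::tibble(sample_id = "s1",
                            mature_id = c("a", "b", "c"),
                            value = c(5L, 9L, 1L))
  expect_identical(top_loci(profile, 2)$mature_id, c("b", "a"))
  tie <- tibble::tibble(sample_id = "s1", mature_id = c("b", "a"),
                        value = c(5L, 5L))
  expect_identical(top_loci(tie, 1)$mature_id, "a")
})

test_that("venn regions cover both the exclusive and plain-intersection readings", {
  lists <- list(A = c("x", "y", "z", "w"), B = c("x", "y", "q"),
                C = c("x", "r"))
  v <- shared_species(lists)
  expect_identical(v$all, 1L)                       # {x}
  expect_identical(unname(v$pairwise["A&B"]), 2L)   # {x, y}
  expect_identical(unname(v$regions["A&B"]), 1L)    # {y} (x excluded)
  # exclusive regions partition the union
  expect_identical(sum(v$regions), length(unique(unlist(lists))))
  expect_error(shared_species(list(A = c("x", "x"), B = "y")), "duplicate")
  expect_error(shared_species(list(A = "x")), "2 or 3")
  v2 <- shared_species(lists[1:2])
  expect_identical(unname(v2$regions["A&B"]), 2L)
})

test_that("fold-change imputation reproduces the worked values", {
  fc <- log2_fold_change(160, 10)
  expect_equal(fc$log2fc, 4)         # b imputed to 10
  expect_false(fc$imputed_a)
  expect_true(fc$imputed_b)
  fc <- log2_fold_change(0, 2048)
  expect_equal(fc$log2fc, log2(10 / 2048), tolerance = 1e-12)
  expect_equal(round(fc$log2fc, 2), -7.68)
  fc <- log2_fold_change(500, 500)
  expect_equal(fc$log2fc, 0)
  expect_false(fc$imputed_a || fc$imputed_b)
  # antisymmetry under the shared imputation rule
  set.seed(4)
  a <- sample(0:5000, 50); b <- sample(0:5000, 50)
  expect_equal(log2_fold_change(a, b)$log2fc, -log2_fold_change(b, a)$log2fc)
})

test_that("miRNA DE calls respect the abundance floor and threshold", {
  spectra <- mk_spectra(
    sp1(5000, "miR-big", "s1"), sp1(50, "miR-big", "s2"),
    sp1(800, "miR-low", "s1"), sp1(900, "miR-low", "s2"),
    sp1(1500, "miR-null", "s1"), sp1(1400, "miR-null", "s2"))
  de <- de_mirnas(quantify(spectra, "most"), c("s1", "s2"))
  expect_false("miR-low" %in% de$unit)   # neither sample above 999
  big <- de[de$unit == "miR-big", ]
  expect_equal(big$log2fc, log2(5000 / 10))
  expect_true(big$significant)
  expect_false(de$significant[de$unit == "miR-null"])
  # a doubled library produces no significant calls
  spectra2 <- mk_spectra(sp1(3000, "miR-x", "s1"), sp1(6000, "miR-x", "s2"))
  de2 <- de_mirnas(quantify(spectra2, "most"), c("s1", "s2"))
  expect_false(any(de2$significant))
})

test_that("modified-isomiR DE uses its own floor and can disagree with the locus", {
  spectra <- mk_spectra(
    sp1(c(8000, 400), "miR-m", "s1", c("", "A")),
    sp1(c(8100, 20), "miR-m", "s2", c("", "A")),
    sp1(c(250), "miR-r", "s1", "T"), sp1(c(250), "miR-r", "s2", "T"))
  de_mod <- de_modified_isomirs(spectra, c("s1", "s2"))
  expect_identical(nrow(de_mod), 1L)     # the 250/250 species is below floor
  expect_equal(de_mod$log2fc, log2(400 / 10))
  expect_true(de_mod$significant)
  # ... while the host locus itself is not differentially expressed
  de_locus <- de_mirnas(quantify(spectra, "most"), c("s1", "s2"))
  expect_false(de_locus$significant[de_locus$unit == "miR-m"])
})

test_that("scheme agreement is measured by the Jaccard of significant sets", {
  spectra <- mk_spectra(
    sp1(c(6000, 2000), "miR-a", "s1"), sp1(c(60, 20), "miR-a", "s2"),
    sp1(c(3000, 1000), "miR-b", "s1"), sp1(c(3000, 1000), "miR-b", "s2"))
  de_m <- de_mirnas(quantify(spectra, "most"), c("s1", "s2"))
  de_s <- de_mirnas(quantify(spectra, "sum"), c("s1", "s2"))
  cons <- scheme_consistency(de_m, de_s)
  expect_equal(cons$jaccard, 1)
  expect_identical(cons$both, "miR-a")
  # empty sets agree by convention; disjoint sets score zero
  empty <- de_m[0, ]
  expect_equal(scheme_consistency(empty, empty)$jaccard, 1)
  fake_a <- de_m; fake_a$significant <- c(TRUE, FALSE)
  fake_b <- de_m; fake_b$significant <- c(FALSE, TRUE)
  expect_equal(scheme_consistency(fake_a, fake_b)$jaccard, 0)
})
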