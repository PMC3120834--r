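test_that("read collapsing conserves counts with deterministic order", {
  reads <- tibble::tibble(read_id = c("a", "b", "c"),
                          sequence = c("ACGT", "ACGT", "TTTT"))
  col <- collapse_reads(reads)
  expect_identical(col$count, c(2L, 1L))
  expect_identical(col$sequence, c("ACGT", "TTTT"))
  expect_identical(nrow(collapse_reads(reads[0, ])), 0L)

  set.seed(2)
  pool <- c("AAAA", "CCCC", "GGGG")
  many <- tibble::tibble(sequence = sample(pool, 1000, replace = TRUE))
  col <- collapse_reads(many)
  expect_identical(nrow(col), 3L)
  expect_identical(sum(col$count), 1000L)
})

test_that("blacklist filtering removes substring matches at the mismatch bound", {
  trna <- paste(rep("GCAT", 18), collapse = "")
  bl <- tibble::tibble(id = "tRNA-1", sequence = trna)
  frag <- substr(trna, 5, 26)
  stopifnot(substr(frag, 11, 11) != "T")
  near <- paste0(substr(frag, 1, 10), "T", substr(frag, 12, 22))
  reads <- tibble::tibble(sequence = c(frag, near, "ACGTACGTACGTACGTACGTAC"),
                          count = c(3L, 2L, 1L))
  kept <- filter_blacklist(reads, bl, max_mm = 0L)
  expect_identical(kept$sequence, reads$sequence[-1])  # exact hit removed
  expect_identical(attr(kept, "removed_count"), 3L)
  kept1 <- filter_blacklist(reads, bl, max_mm = 1L)
  expect_identical(nrow(kept1), 1L)  # Hamming-1 read removed too
  # empty blacklist is the identity
  none <- filter_blacklist(reads, NULL)
  expect_identical(nrow(none), nrow(reads))
})

test_that("alignment recovers canonical spans, additions and the mismatch bound", {
  ref <- toy_reference(2)
  idx <- build_align_index(ref)
  prec <- ref$precursors$sequence[1]
  pb <- strsplit(prec, "")[[1]]

  # canonical span: exact hit, no addition
  hits <- align_read(toy_read(prec, 20, 41), idx)
  expect_identical(hits$precursor_id[1], "toy-mir-01")
  expect_identical(hits$start[1], 20L)
  expect_identical(hits$aligned_len[1], 22L)
  expect_identical(hits$boundary_flag[1], "none")

  # single non-template addition
  add <- setdiff(ORACLE_BASES, pb[41])[1]
  hits <- align_read(toy_read(prec, 20, 40, add), idx)
  expect_identical(hits$aligned_len[1], 21L)
  expect_identical(hits$addition[1], add)
  expect_identical(hits$boundary_flag[1], "single_nta")

  # double non-template addition
  a1 <- setdiff(ORACLE_BASES, pb[42])[1]
  a2 <- setdiff(ORACLE_BASES, pb[43])[1]
  hits <- align_read(toy_read(prec, 20, 41, paste0(a1, a2)), idx)
  expect_identical(hits$addition[1], paste0(a1, a2))
  expect_identical(hits$boundary_flag[1], "double_nta")

  # one internal color error is corrected; two kill the hit
  colors <- toy_read(prec, 20, 41)
  cc <- as.integer(strsplit(colors, "")[[1]])
  cc1 <- cc; cc1[8] <- (cc1[8] + 1L) %% 4L
  h1 <- align_read(paste(cc1, collapse = ""), idx)
  expect_identical(h1$n_color_mismatches[1], 1L)
  expect_identical(h1$start[1], 20L)
  cc2 <- cc1; cc2[14] <- (cc2[14] + 2L) %% 4L
  h2 <- align_read(paste(cc2, collapse = ""), idx)
  expect_true(nrow(h2) == 0L || h2$weak[1] || h2$start[1] != 20L)
})

test_that("emitted additions never match the template at their position", {
  cfg <- sim_config(n_loci = 10, n_reads = 20000, seed = 31, error_rate = 0.002)
  ref <- generate_reference(cfg)
  lib <- generate_library(ref, cfg, "normal", seed = 77)
  obs <- call_sample_isomirs(list(normal = lib$reads_cs), ref)
  mod <- obs[nzchar(obs$addition), ]
  for (k in seq_len(nrow(mod))) {
    pseq <- ref$precursors$sequence[
      ref$precursors$precursor_id == mod$precursor_id[k]]
    add <- strsplit(mod$addition[k], "")[[1]]
    for (j in seq_along(add)) {
      pos <- mod$template_end[k] + j
      if (pos <= nchar(pseq)) {
        expect_true(substr(pseq, pos, pos) != add[j])
      }
    }
  }
})

test_that("counts are conserved through filtering, alignment and assignment", {
  cfg <- sim_config(n_loci = 8, n_reads = 15000, seed = 13, error_rate = 0.004)
  ref <- generate_reference(cfg)
  lib <- generate_library(ref, cfg, "mild", seed = 99)
  obs <- call_sample_isomirs(list(mild = lib$reads_cs), ref)
  a <- attr(obs, "audit")
  expect_identical(a$total,
                   a$blacklisted + a$unaligned + a$unassigned + a$assigned)
  # reads with a single injected error are never lost
  expect_lte(a$unaligned, sum(lib$truth$species$n_error2_reads))
})

test_that("mature assignment follows the half-overlap rule", {
  ref <- toy_reference(1)
  idx <- build_align_index(ref)
  prec <- ref$precursors$sequence[1]
  # span centred on the annotation (20..41): assigned
  reads <- tibble::tibble(read_id = "r", primer = "T",
                          colors = toy_read(prec, 25, 46), count = 5L)
  aligned <- align_reads(reads, idx, "colorspace")
  obs <- call_isomirs(aligned, ref)
  expect_identical(obs$mature_id, "toy-miR-01")
  # far-away precursor fragment: unassigned, logged, excluded
  reads2 <- tibble::tibble(read_id = "r2", primer = "T",
                           colors = toy_read(prec, 45, 66), count = 2L)
  aligned2 <- align_reads(reads2, idx, "colorspace")
  obs2 <- call_isomirs(aligned2, ref)
  expect_identical(nrow(obs2), 0L)
  expect_identical(sum(attr(obs2, "unassigned")$count), 2L)
})

test_that("isomiR labels follow the miR-addition and span conventions", {
  prec <- tibble::tibble(
    precursor_id = "hsa-mir-24-1",
    sequence = paste(rep("ACGT", 22), collapse = ""))
  ann <- tibble::tibble(mature_id = "hsa-miR-24", precursor_id = "hsa-mir-24-1",
                        start = 44L, end = 65L)
  ref <- reference_set(prec, ann)
  obs <- tibble::tibble(
    mature_id = "hsa-miR-24", precursor_id = "hsa-mir-24-1",
    template_start = c(44L, 44L, 44L),
    template_end = c(62L, 65L, 64L),
    addition = c("A", "", "A"),
    count = c(10L, 10L, 10L),
    sequence = c("x", "y", "z"))
  lab <- label_isomirs(obs, ref)
  expect_identical(lab$name, c("miR-24-A", "miR-24", "miR-24-A"))
  expect_identical(lab$span,
                   c("44–63 (44–65)", "44–65", "44–65"))
  # U is printed for T additions
  obs$addition <- c("T", "", "T")
  lab <- label_isomirs(obs, ref)
  expect_identical(lab$name[1], "miR-24-U")
  expect_identical(reported_end(obs), c(63L, 65L, 65L))
})

test_that("colorspace and base-space modes agree on error-free data", {
  cfg <- sim_config(n_loci = 6, n_reads = 8000, seed = 21, error_rate = 0)
  ref <- generate_reference(cfg)
  lib <- generate_library(ref, cfg, "severe", seed = 64)
  obs_cs <- call_sample_isomirs(list(severe = lib$reads_cs), ref)
  obs_bs <- call_sample_isomirs(list(severe = lib$reads_bs), ref,
                                pipeline_config(mode = "basespace"))
  expect_identical(canon_obs(obs_cs), canon_obs(obs_bs))
})
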