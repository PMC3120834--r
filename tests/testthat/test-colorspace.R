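test_that("di-base color code matches the published SOLiD matrix", {
  for (b1 in ORACLE_BASES) {
    for (b2 in ORACLE_BASES) {
      expect_identical(color_of(b1, b2), ORACLE_COLOR[b1, b2])
    }
  }
  # structural properties: 0 on the diagonal, symmetric, each row a
  # bijection onto {0,1,2,3}
  expect_true(all(color_of(ORACLE_BASES, ORACLE_BASES) == 0L))
  for (b1 in ORACLE_BASES) {
    expect_setequal(color_of(rep(b1, 4), ORACLE_BASES), 0:3)
    expect_identical(color_of(rep(b1, 4), ORACLE_BASES),
                     color_of(ORACLE_BASES, rep(b1, 4)))
  }
  expect_error(color_of("A", "N"), "invalid base")
})

test_that("encoding pairs primer with first base and has length contract", {
  expect_identical(cs_encode("AAAA", primer = "T"),
                   paste0(oracle_color("T", "A"), "000"))
  expect_identical(nchar(cs_encode("G", primer = "T")), 1L)
  expect_identical(cs_encode("ACGT", "T"), oracle_encode("ACGT", "T"))
})

test_that("decode inverts encode and empty colors decode to empty", {
  expect_identical(cs_decode("T", cs_encode("ACGT", "T")), "ACGT")
  expect_identical(cs_decode("T", ""), "")
  set.seed(11)
  for (k in c(1L, 5L, 12L, 25L)) {
    s <- paste(sample(ORACLE_BASES, k, replace = TRUE), collapse = "")
    for (p in c("T", "G")) {
      expect_identical(cs_decode(p, cs_encode(s, p)), s)
    }
  }
})

test_that("a single corrupted color cascades through all downstream bases", {
  seq <- "ACGTCA"
  colors <- cs_encode(seq, "T")
  cc <- as.integer(strsplit(colors, "")[[1]])
  cc[3] <- (cc[3] + 1L) %% 4L
  corrupted <- cs_decode("T", paste(cc, collapse = ""))
  same <- strsplit(corrupted, "")[[1]] == strsplit(seq, "")[[1]]
  expect_identical(same, c(TRUE, TRUE, rep(FALSE, 4)))
})

test_that("CSFASTA round trip preserves records and skips comments", {
  path <- withr::local_tempfile(fileext = ".csfasta")
  writeLines(c("# comment line", ">r1", "T012", ">r2", "G3210"), path)
  reads <- read_csfasta(path)
  expect_identical(reads$read_id, c("r1", "r2"))
  expect_identical(reads$primer, c("T", "G"))
  expect_identical(reads$colors, c("012", "3210"))
  out <- withr::local_tempfile(fileext = ".csfasta")
  write_csfasta(reads, out)
  expect_identical(as.data.frame(read_csfasta(out)), as.data.frame(reads))
})

test_that("CSFASTA rejects malformed lines and handles empty files", {
  path <- withr::local_tempfile(fileext = ".csfasta")
  writeLines(c(">r1", "0123"), path)   # first char must be a base
  expect_error(read_csfasta(path), "malformed")
  writeLines(c(">r1", "T01X"), path)
  expect_error(read_csfasta(path), "malformed")
  writeLines(character(0), path)
  expect_identical(nrow(read_csfasta(path)), 0L)
})

test_that("boundary classification separates errors from addition candidates", {
  # reference colors: 20 aligned colors + expected junction color
  set.seed(3)
  ref <- sample(0:3, 21, replace = TRUE)
  read_match <- paste(c(ref, 0L), collapse = "")
  expect_identical(nrow(classify_boundary(read_match, ref, 20L)), 0L)

  internal <- ref
  internal[5] <- (internal[5] + 2L) %% 4L
  cls <- classify_boundary(paste(c(internal, 0L), collapse = ""), ref, 20L)
  expect_identical(cls$position, 5L)
  expect_identical(cls$kind, "sequencing_error")

  # terminal mismatch with mismatching junction color: addition candidate
  nta <- ref
  nta[20] <- (nta[20] + 1L) %% 4L
  nta[21] <- (nta[21] + 1L) %% 4L
  cls <- classify_boundary(paste(c(nta, 0L), collapse = ""), ref, 20L)
  expect_identical(cls$kind, "terminal_addition_candidate")
  expect_identical(cls$position, 20L)

  # terminal mismatch but junction matches: corrected sequencing error
  term <- ref
  term[20] <- (term[20] + 1L) %% 4L
  cls <- classify_boundary(paste(c(term, 0L), collapse = ""), ref, 20L)
  expect_identical(cls$kind, "sequencing_error")

  # two aligned mismatches: unexplained true change
  two <- ref
  two[4] <- (two[4] + 1L) %% 4L
  two[9] <- (two[9] + 1L) %% 4L
  cls <- classify_boundary(paste(c(two, 0L), collapse = ""), ref, 20L)
  expect_identical(cls$kind, rep("true_change", 2))
  expect_identical(cls$position, c(4L, 9L))

  expect_error(classify_boundary("0123", 0:3, 4L), "fewer than")
})

test_that("planted single additions are classified as addition candidates", {
  # synthesized reads with a planted non-template addition and no errors
  # always trip the boundary rule
  ref3 <- toy_reference(1)
  prec <- ref3$precursors$sequence[1]
  pb <- strsplit(prec, "")[[1]]
  for (rep_i in 1:20) {
    set.seed(rep_i)
    s <- sample(10:30, 1)
    e <- s + 21L
    tmpl_next <- pb[e + 1L]
    add <- sample(setdiff(ORACLE_BASES, tmpl_next), 1)
    colors <- toy_read(prec, s, e, add)
    aligned_len <- (e - s + 1L) + 1L  # insert includes the addition
    expc <- integer(aligned_len + 1L)
    expc[1] <- oracle_color("T", pb[s])
    for (i in 2:aligned_len) expc[i] <- oracle_color(pb[s + i - 2L], pb[s + i - 1L])
    expc[aligned_len + 1L] <- oracle_color(pb[s + aligned_len - 1L], "C")
    cls <- classify_boundary(colors, expc, aligned_len)
    expect_identical(cls$kind, "terminal_addition_candidate")
  }
})
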