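# Shared fixtures and an independent brute-force oracle for the colorspace
# aligner. The oracle is written against the published SOLiD di-base matrix
# (hard-coded below) and plain position loops; it never calls the package's
# candidate-evaluation internals.

ORACLE_BASES <- c("A", "C", "G", "T")
ORACLE_COLOR <- matrix(
  c(0L, 1L, 2L, 3L,
    1L, 0L, 3L, 2L,
    2L, 3L, 0L, 1L,
    3L, 2L, 1L, 0L),
  nrow = 4, byrow = TRUE, dimnames = list(ORACLE_BASES, ORACLE_BASES))

oracle_color <- function(b1, b2) ORACLE_COLOR[b1, b2]

oracle_encode <- function(seq, primer = "T") {
  b <- strsplit(seq, "")[[1]]
  prev <- primer
  out <- integer(length(b))
  for (i in seq_along(b)) {
    out[i] <- oracle_color(prev, b[i])
    prev <- b[i]
  }
  paste(out, collapse = "")
}

oracle_decode <- function(primer, colors) {
  cc <- as.integer(strsplit(colors, "")[[1]])
  prev <- primer
  out <- character(length(cc))
  for (i in seq_along(cc)) {
    out[i] <- ORACLE_BASES[which(ORACLE_COLOR[prev, ] == cc[i])]
    prev <- out[i]
  }
  paste(out, collapse = "")
}

# base reached by applying one color to a starting base
oracle_step <- function(base, color) {
  ORACLE_BASES[which(ORACLE_COLOR[base, ] == color)]
}

# Brute-force colorspace alignment of one read against a reference tibble
# (precursor_id, sequence). Enumerates every (precursor, offset, insert
# length) triple and applies the boundary semantics directly; returns the
# single best hit (list) or NULL.
oracle_align <- function(colors, precursors, primer = "T",
                         adaptor = solmir_default_adaptor,
                         min_t = 16L, max_t = 30L) {
  cc <- as.integer(strsplit(colors, "")[[1]])
  L <- length(cc)
  ad <- strsplit(adaptor, "")[[1]]
  ord <- order(precursors$precursor_id, method = "radix")
  strong <- list()
  weak <- list()
  for (pi in seq_along(ord)) {
    pid <- precursors$precursor_id[ord[pi]]
    pseq <- strsplit(precursors$sequence[ord[pi]], "")[[1]]
    plen <- length(pseq)
    for (s in seq_len(max(0L, plen - min_t + 1L))) {
      maxT <- min(L, plen - s + 1L)
      expc <- integer(maxT)
      expc[1] <- oracle_color(primer, pseq[s])
      if (maxT >= 2L) {
        for (i in 2:maxT) expc[i] <- oracle_color(pseq[s + i - 2L], pseq[s + i - 1L])
      }
      mism <- cc[seq_len(maxT)] != expc
      junction_ok <- function(last_base, n) {
        cc[n + 1L] == oracle_color(last_base, ad[1]) &&
          (n + 2L > L || cc[n + 2L] == oracle_color(ad[1], ad[2]))
      }
      for (n in min_t:min(L - 1L, maxT + 2L, max_t + 2L)) {
        hit <- NULL
        if (n <= maxT && n <= max_t && sum(mism[1:n]) <= 1L &&
            junction_ok(pseq[s + n - 1L], n)) {
          hit <- list(i = pi, prec = pid, s = s, t = n, n = n, add = "",
                      mm = sum(mism[1:n]))
        }
        if (is.null(hit)) {
          t1 <- n - 1L
          if (t1 >= min_t && t1 <= max_t && t1 <= plen - s + 1L &&
              sum(mism[1:t1]) <= 1L) {
            b1 <- oracle_step(pseq[s + t1 - 1L], cc[n])
            nontmpl <- (s + n - 1L > plen) || (pseq[s + n - 1L] != b1)
            if (nontmpl && junction_ok(b1, n)) {
              hit <- list(i = pi, prec = pid, s = s, t = t1, n = n, add = b1,
                          mm = sum(mism[1:t1]))
            }
          }
        }
        if (is.null(hit)) {
          t2 <- n - 2L
          if (t2 >= min_t && t2 <= max_t && t2 <= plen - s + 1L &&
              sum(mism[1:t2]) <= 1L) {
            b1 <- oracle_step(pseq[s + t2 - 1L], cc[n - 1L])
            b2 <- oracle_step(b1, cc[n])
            ok1 <- (s + t2 > plen) || (pseq[s + t2] != b1)
            ok2 <- (s + t2 + 1L > plen) || (pseq[s + t2 + 1L] != b2)
            if (ok1 && ok2 && junction_ok(b2, n)) {
              hit <- list(i = pi, prec = pid, s = s, t = t2, n = n,
                          add = paste0(b1, b2), mm = sum(mism[1:t2]))
            }
          }
        }
        if (!is.null(hit)) strong[[length(strong) + 1L]] <- hit
      }
      # weak fallback bookkeeping: best templated prefix with <= 1 mismatch
      ns <- min_t:min(maxT, max_t)
      if (length(ns) > 0L) {
        mmn <- vapply(ns, function(n) sum(mism[1:n]), integer(1))
        ok <- ns[mmn <= 1L]
        if (length(ok) > 0L) {
          best <- ok[order(mmn[match(ok, ns)], -ok)][1L]
          weak[[length(weak) + 1L]] <-
            list(i = pi, prec = pid, s = s, t = best, n = best, add = "",
                 mm = sum(mism[1:best]))
        }
      }
    }
  }
  if (length(strong) > 0L) {
    keys <- vapply(strong, function(h) {
      sprintf("%05d_%05d_%05d_%d", h$i, h$s, 99999L - h$n, nchar(h$add))
    }, "")
    return(strong[[order(keys)[1L]]])
  }
  if (length(weak) > 0L) {
    keys <- vapply(weak, function(h) {
      sprintf("%d_%05d_%05d_%05d", h$mm, h$i, h$s, 99999L - h$n)
    }, "")
    h <- weak[[order(keys)[1L]]]
    h$weak <- TRUE
    return(h)
  }
  NULL
}

# Deterministic toy reference built in code.
toy_reference <- function(n = 3L, plen = 70L, seed = 424L) {
  set.seed(seed)
  precursors <- tibble::tibble(
    precursor_id = sprintf("toy-mir-%02d", seq_len(n)),
    sequence = vapply(seq_len(n), function(i) {
      paste(sample(c("A", "C", "G", "T"), plen, replace = TRUE), collapse = "")
    }, ""))
  annotations <- tibble::tibble(
    mature_id = sprintf("toy-miR-%02d", seq_len(n)),
    precursor_id = precursors$precursor_id,
    start = rep(20L, n), end = rep(41L, n),
    arm = rep(c("5p", "3p"), length.out = n))
  reference_set(precursors, annotations)
}

# Construct a colorspace read: template span of a precursor plus an
# optional non-template tail, adaptor appended, truncated to n_colors.
toy_read <- function(prec_seq, s, e, addition = "",
                     adaptor = solmir_default_adaptor, primer = "T",
                     n_colors = 35L) {
  insert <- paste0(substr(prec_seq, s, e), addition)
  substr(oracle_encode(paste0(insert, adaptor), primer), 1L, n_colors)
}

# Canonical form of an observation table for order-insensitive comparison.
canon_obs <- function(obs) {
  obs <- as.data.frame(obs)
  cols <- intersect(c("sample_id", "mature_id", "precursor_id",
                      "template_start", "template_end", "addition", "count"),
                    names(obs))
  obs <- obs[do.call(order, obs[cols]), cols]
  rownames(obs) <- NULL
  obs
}
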