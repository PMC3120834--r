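# Read collapsing, blacklist filtering, precursor alignment and isomiR
# calling.
#
# Colorspace mode is the reference implementation of the boundary rule: a
# read is scanned against every precursor offset on the sense strand; at a
# candidate insert length n the expected colors are the precursor's
# two-base colors (the first color pairing the library primer with the
# first template base).  At most one internal color mismatch is tolerated
# and corrected to the reference.  The insert/adaptor junction color
# (position n + 1) anchors the insert length: a templated end predicts
# color(last template base, adaptor[1]); one or two trailing color
# mismatches whose decoded bases are non-template and whose junction color
# matches color(last added base, adaptor[1]) are called 3' non-template
# additions.  Base-space mode applies the same span/addition semantics by
# trailing-tail analysis and must agree with colorspace mode on error-free
# reads.

.MIN_TEMPLATE <- 16L
.MAX_TEMPLATE <- 30L

#' Collapse identical reads into unique species with counts
#'
#' @param reads tibble of reads with a `colors` (colorspace) or `sequence`
#'   (base space) column and optionally `count` (default 1 per row).
#' @return tibble of unique reads with summed `count`, ordered by count
#'   descending then key ascending (deterministic).
#' @export
collapse_reads <- function(reads) {
  key_col <- if ("colors" %in% names(reads)) "colors" else "sequence"
  if (!key_col %in% names(reads)) {
    stop("reads need a 'colors' or 'sequence' column", call. = FALSE)
  }
  if (!"count" %in% names(reads)) reads$count <- 1L
  if (nrow(reads) == 0L) {
    out <- reads[c(key_col, if ("primer" %in% names(reads)) "primer", "count")]
    return(tibble::as_tibble(out))
  }
  grp_cols <- c(key_col, if ("primer" %in% names(reads)) "primer")
  out <- reads %>%
    dplyr::group_by(dplyr::across(dplyr::all_of(grp_cols))) %>%
    dplyr::summarise(count = sum(.data$count), .groups = "drop")
  out[order(-out$count, out[[key_col]], method = "radix"), ]
}

#' Remove reads matching a blacklist of other non-coding RNAs
#'
#' A read is removed when its (decoded) sequence occurs as a substring of
#' any blacklist sequence with at most `max_mm` mismatches.  Colorspace
#' reads carry the adaptor, so every candidate insert-length prefix of the
#' decoded read (16 to 32 nt) is tested.
#'
#' @param reads collapsed read tibble (`sequence` or `colors` + `primer`).
#' @param blacklist tibble with `id`, `sequence` (e.g. from
#'   [read_blacklist_fasta()]); empty or `NULL` is the identity.
#' @param max_mm maximum mismatches for a substring match (default 0).
#' @return filtered reads; the removed rows and their total count are
#'   attached as attributes `removed` and `removed_count`.
#' @export
filter_blacklist <- function(reads, blacklist, max_mm = 0L) {
  if (is.null(blacklist) || nrow(blacklist) == 0L || nrow(reads) == 0L) {
    attr(reads, "removed") <- reads[0, ]
    attr(reads, "removed_count") <- 0L
    return(reads)
  }
  subjects <- lapply(blacklist$sequence, Biostrings::BString)
  hit_in_blacklist <- function(seqs) {
    vapply(seqs, function(q) {
      if (nchar(q) < 8L) return(FALSE)
      for (s in subjects) {
        if (nchar(q) <= length(s) &&
            Biostrings::countPattern(q, s, max.mismatch = max_mm) > 0L) {
          return(TRUE)
        }
      }
      FALSE
    }, logical(1), USE.NAMES = FALSE)
  }
  if ("sequence" %in% names(reads)) {
    drop <- hit_in_blacklist(reads$sequence)
  } else {
    decoded <- mapply(cs_decode, reads$primer, reads$colors, USE.NAMES = FALSE)
    drop <- vapply(decoded, function(d) {
      lens <- seq(.MIN_TEMPLATE, min(nchar(d), .MAX_TEMPLATE + 2L))
      if (length(lens) == 0L) return(FALSE)
      any(hit_in_blacklist(substr(rep(d, length(lens)), 1L, lens)))
    }, logical(1), USE.NAMES = FALSE)
  }
  out <- reads[!drop, ]
  attr(out, "removed") <- reads[drop, ]
  attr(out, "removed_count") <- sum(reads$count[drop])
  out
}

# ---- alignment index -------------------------------------------------------

.seed_env <- function(strs, k) {
  e <- new.env(hash = TRUE, parent = emptyenv())
  for (i in seq_along(strs)) {
    s <- strs[i]
    n <- nchar(s)
    if (n < k) next
    for (q in seq_len(n - k + 1L)) {
      key <- substr(s, q, q + k - 1L)
      prev <- if (exists(key, envir = e, inherits = FALSE)) get(key, envir = e) else integer(0)
      assign(key, c(prev, i, q), envir = e)
    }
  }
  e
}

#' Build an alignment index over a reference set
#'
#' Precomputes per-precursor base codes, internal two-base colors and seed
#' lookup tables. Precursors are held in lexicographic id order so that
#' multi-mapping ties resolve to the same "first" precursor as
#' [resolve_locus()].
#'
#' @param ref a `reference_set`.
#' @param primer library primer base (colorspace mode).
#' @param adaptor 3' adaptor sequence whose first base defines the expected
#'   junction color.
#' @return an opaque index object for [align_read()] / [align_reads()].
#' @export
build_align_index <- function(ref, primer = solmir_default_primer,
                              adaptor = solmir_default_adaptor) {
  ad <- base_codes(adaptor)
  if (length(ad) < 2L) {
    stop("adaptor must be at least 2 nt: two junction colors are needed to ",
         "anchor the insert/adaptor boundary", call. = FALSE)
  }
  if (ad[1] == ad[2]) {
    warning("adaptor starts with a homodimer; additions of its first base ",
            "cannot be distinguished from templated adaptor read-through")
  }
  d <- bitwXor(ad[-length(ad)], ad[-1L])
  dimer_recurs <- any(ad[-(1:2)][seq_len(max(0L, length(ad) - 2L))] == ad[1] &
                        c(ad[-(1:3)], -1L)[seq_len(max(0L, length(ad) - 2L))] == ad[2])
  if (dimer_recurs || any(d[-1L] == d[1])) {
    warning("adaptor junction structure is self-similar (leading dinucleotide ",
            "or leading pair color recurs); frame-shifted junction ",
            "reinterpretations may pass the boundary check")
  }
  ord <- order(ref$precursors$precursor_id, method = "radix")
  prec <- ref$precursors[ord, ]
  codes <- lapply(prec$sequence, base_codes)
  pc <- lapply(codes, function(z) {
    if (length(z) >= 2L) bitwXor(z[-length(z)], z[-1L]) else integer(0)
  })
  pc_str <- vapply(pc, function(z) paste(z, collapse = ""), "")
  seq_str <- prec$sequence
  list(ref = ref,
       prec_ids = prec$precursor_id,
       codes = codes, pc = pc,
       seed8 = .seed_env(pc_str, 8L),
       seed7b = .seed_env(pc_str, 7L),
       bseed8 = .seed_env(seq_str, 8L),
       bseed7b = .seed_env(seq_str, 7L),
       primer_code = base_codes(primer),
       ad1 = ad[1],
       ad12 = bitwXor(ad[1], ad[2]))
}

.seed_candidates <- function(e8, e7, key8, key7, off8, off7) {
  c8 <- if (exists(key8, envir = e8, inherits = FALSE)) get(key8, envir = e8) else integer(0)
  c7 <- if (exists(key7, envir = e7, inherits = FALSE)) get(key7, envir = e7) else integer(0)
  cand <- matrix(c(c8, c7), nrow = 2L)
  if (ncol(cand) == 0L) return(cand)
  # map seed position q to candidate start s
  cand[2L, seq_len(length(c8) / 2L)] <- cand[2L, seq_len(length(c8) / 2L)] + off8
  if (length(c7) > 0L) {
    j <- (length(c8) / 2L + 1L):(ncol(cand))
    cand[2L, j] <- cand[2L, j] + off7
  }
  cand[, !duplicated(t(cand)), drop = FALSE]
}

# Evaluate all candidate interpretations of one colorspace read at one
# (precursor, start). Returns a list of hit records (possibly empty).
.cs_eval_candidate <- function(cc, i, s, idx, want_weak) {
  codes <- idx$codes[[i]]
  pc <- idx$pc[[i]]
  plen <- length(codes)
  L <- length(cc)
  if (s < 1L || s > plen - .MIN_TEMPLATE + 1L) return(list())
  maxT <- min(L, plen - s + 1L)
  r <- c(bitwXor(idx$primer_code, codes[s]),
         if (maxT >= 2L) pc[s + seq_len(maxT - 1L) - 1L] else integer(0))
  mm <- cc[seq_len(maxT)] != r
  cmm <- cumsum(mm)
  ad1 <- idx$ad1
  # two junction colors anchor where the adaptor starts: the first pairs
  # the last insert base with adaptor base 1, the second is the constant
  # adaptor-internal color(adaptor[1], adaptor[2])
  junction_ok <- function(last_code, n) {
    cc[n + 1L] == bitwXor(last_code, ad1) &&
      (n + 2L > L || cc[n + 2L] == idx$ad12)
  }
  hits <- list()
  n_hi <- min(L - 1L, maxT + 2L, .MAX_TEMPLATE + 2L)
  if (n_hi < .MIN_TEMPLATE) return(list())
  for (n in .MIN_TEMPLATE:n_hi) {
    # templated end (no addition)
    if (n <= maxT && n <= .MAX_TEMPLATE && cmm[n] <= 1L) {
      if (junction_ok(codes[s + n - 1L], n)) {
        hits[[length(hits) + 1L]] <-
          list(i = i, s = s, t = n, n = n, add = integer(0),
               mm = cmm[n], weak = FALSE)
        next
      }
    }
    # single 3' non-template addition
    t1 <- n - 1L
    if (t1 >= .MIN_TEMPLATE && t1 <= .MAX_TEMPLATE &&
        t1 <= plen - s + 1L && cmm[t1] <= 1L) {
      b1 <- bitwXor(codes[s + t1 - 1L], cc[n])
      nontmpl <- (s + n - 1L > plen) || (codes[s + n - 1L] != b1)
      if (nontmpl && junction_ok(b1, n)) {
        hits[[length(hits) + 1L]] <-
          list(i = i, s = s, t = t1, n = n, add = b1,
               mm = cmm[t1], weak = FALSE)
        next
      }
    }
    # double 3' non-template addition
    t2 <- n - 2L
    if (t2 >= .MIN_TEMPLATE && t2 <= .MAX_TEMPLATE &&
        t2 <= plen - s + 1L && cmm[t2] <= 1L) {
      b1 <- bitwXor(codes[s + t2 - 1L], cc[n - 1L])
      b2 <- bitwXor(b1, cc[n])
      ok1 <- (s + t2 > plen) || (codes[s + t2] != b1)
      ok2 <- (s + t2 + 1L > plen) || (codes[s + t2 + 1L] != b2)
      if (ok1 && ok2 && junction_ok(b2, n)) {
        hits[[length(hits) + 1L]] <-
          list(i = i, s = s, t = t2, n = n, add = c(b1, b2),
               mm = cmm[t2], weak = FALSE)
      }
    }
  }
  if (length(hits) == 0L && want_weak) {
    # no junction-consistent interpretation: tolerate a junction/adaptor
    # sequencing error and keep the best templated alignment so a read
    # with a single color error is never lost
    ns <- .MIN_TEMPLATE:min(maxT, .MAX_TEMPLATE)
    ok <- ns[cmm[ns] <= 1L]
    if (length(ok) > 0L) {
      best <- ok[order(cmm[ok], -ok)][1L]
      hits[[1L]] <- list(i = i, s = s, t = best, n = best, add = integer(0),
                         mm = cmm[best], weak = TRUE)
    }
  }
  hits
}

.bs_eval_candidate <- function(q, i, s, idx) {
  codes <- idx$codes[[i]]
  plen <- length(codes)
  n <- length(q)
  if (s < 1L || s > plen - .MIN_TEMPLATE + 1L) return(list())
  maxT <- min(n, plen - s + 1L)
  mm <- q[seq_len(maxT)] != codes[s + seq_len(maxT) - 1L]
  cmm <- cumsum(mm)
  hits <- list()
  for (a in 0:2) {
    t <- n - a
    if (t < .MIN_TEMPLATE || t > .MAX_TEMPLATE || t > maxT) next
    m <- cmm[t]
    if (m > 1L) next
    # a mismatch at the template's last position is a longer tail, not a
    # correctable error, whatever the claimed addition length
    if (m == 1L && mm[t]) next
    if (a > 0L) {
      addv <- q[(t + 1L):n]
      pos <- s + t - 1L + seq_len(a)
      if (!all(pos > plen | codes[pmin(pos, plen)] != addv)) next
    } else {
      addv <- integer(0)
    }
    hits[[length(hits) + 1L]] <-
      list(i = i, s = s, t = t, n = n, add = addv, mm = m, weak = FALSE)
  }
  hits
}

.hits_to_tibble <- function(hits, idx) {
  if (length(hits) == 0L) {
    return(tibble::tibble(precursor_id = character(), start = integer(),
                          aligned_len = integer(), addition = character(),
                          n_color_mismatches = integer(),
                          boundary_flag = character(), weak = logical()))
  }
  prec_i <- vapply(hits, `[[`, 0L, "i")
  tibble::tibble(
    precursor_id = idx$prec_ids[prec_i],
    start = vapply(hits, `[[`, 0L, "s"),
    aligned_len = vapply(hits, `[[`, 0L, "t"),
    addition = vapply(hits, function(h) {
      paste(.codes_to_bases(h$add), collapse = "")
    }, ""),
    n_color_mismatches = vapply(hits, `[[`, 0L, "mm"),
    boundary_flag = vapply(hits, function(h) {
      c("none", "single_nta", "double_nta")[length(h$add) + 1L]
    }, ""),
    weak = vapply(hits, `[[`, TRUE, "weak"))
}

.order_hits <- function(hits) {
  if (length(hits) <= 1L) return(hits)
  i <- vapply(hits, `[[`, 0L, "i")
  s <- vapply(hits, `[[`, 0L, "s")
  n <- vapply(hits, `[[`, 0L, "n")
  a <- vapply(hits, function(h) length(h$add), 0L)
  weak <- vapply(hits, `[[`, TRUE, "weak")
  mm <- vapply(hits, `[[`, 0L, "mm")
  hits[order(weak, mm * weak, i, s, -n, a)]
}

.align_one <- function(read_key, primer_code_or_null, idx, mode) {
  if (mode == "colorspace") {
    cc <- color_codes(read_key)
    L <- length(cc)
    if (L < .MIN_TEMPLATE + 1L) return(list())
    if (L >= 17L) {
      key8 <- substr(read_key, 2L, 9L)
      key7 <- substr(read_key, 10L, 16L)
      cand <- .seed_candidates(idx$seed8, idx$seed7b, key8, key7, 0L, -8L)
    } else {
      cand <- NULL
    }
    if (is.null(cand)) {
      cand_list <- unlist(lapply(seq_along(idx$codes), function(i) {
        lapply(seq_len(max(0L, length(idx$codes[[i]]) - .MIN_TEMPLATE + 1L)),
               function(s) c(i, s))
      }), recursive = FALSE)
    } else {
      cand_list <- if (ncol(cand) > 0L) {
        lapply(seq_len(ncol(cand)), function(j) cand[, j])
      } else {
        list()
      }
    }
    hits <- list()
    for (p in cand_list) {
      hits <- c(hits, .cs_eval_candidate(cc, p[1], p[2], idx, want_weak = TRUE))
    }
    strong <- Filter(function(h) !h$weak, hits)
    if (length(strong) > 0L) hits <- strong
  } else {
    q <- base_codes(read_key)
    n <- length(q)
    if (n < .MIN_TEMPLATE) return(list())
    key8 <- substr(read_key, 1L, 8L)
    key7 <- substr(read_key, 9L, 15L)
    cand <- .seed_candidates(idx$bseed8, idx$bseed7b, key8, key7, 0L, -8L)
    hits <- list()
    if (ncol(cand) > 0L) {
      for (j in seq_len(ncol(cand))) {
        hits <- c(hits, .bs_eval_candidate(q, cand[1, j], cand[2, j], idx))
      }
    }
  }
  .order_hits(hits)
}

#' Align one small-RNA read to the precursor reference
#'
#' Exhaustively scans every precursor offset (sense strand, via an exact
#' seed filter that cannot miss a qualifying hit) and returns every
#' alignment with at most one internal (corrected) mismatch, with the 3'
#' boundary classified as `none`, `single_nta` or `double_nta`. Hits are
#' ordered by the deterministic preference used throughout: junction-
#' consistent before weak, then precursor id (the [resolve_locus()] order),
#' then smallest start, then longest insert.
#'
#' @param read one read: a color string (colorspace mode) or a base string
#'   (base-space mode), or a one-row read tibble.
#' @param index index from [build_align_index()].
#' @param mode `"colorspace"` or `"basespace"`.
#' @return tibble of hits (possibly empty): `precursor_id`, `start`,
#'   `aligned_len` (template length), `addition`, `n_color_mismatches`,
#'   `boundary_flag`, `weak`.
#' @export
align_read <- function(read, index, mode = c("colorspace", "basespace")) {
  mode <- match.arg(mode)
  key <- if (is.character(read)) read else {
    if (mode == "colorspace") read$colors else read$sequence
  }
  .hits_to_tibble(.align_one(key, NULL, index, mode), index)
}

#' Align a table of collapsed reads and keep the best hit per read
#'
#' @param reads collapsed read tibble (`colors` or `sequence`, plus
#'   `count`).
#' @param index index from [build_align_index()].
#' @param mode `"colorspace"` or `"basespace"`.
#' @return tibble with one row per input read: the read key and count plus
#'   best-hit columns (`NA` when unaligned).
#' @export
align_reads <- function(reads, index, mode = c("colorspace", "basespace")) {
  mode <- match.arg(mode)
  key_col <- if (mode == "colorspace") "colors" else "sequence"
  if (!key_col %in% names(reads)) {
    stop("reads lack the '", key_col, "' column required for ", mode, " mode",
         call. = FALSE)
  }
  n <- nrow(reads)
  prec <- character(n); start <- integer(n); tlen <- integer(n)
  add <- character(n); mm <- integer(n); weak <- logical(n)
  aligned <- logical(n)
  for (k in seq_len(n)) {
    hits <- .align_one(reads[[key_col]][k], NULL, index, mode)
    if (length(hits) == 0L) {
      aligned[k] <- FALSE
      prec[k] <- NA_character_; start[k] <- NA_integer_; tlen[k] <- NA_integer_
      add[k] <- NA_character_; mm[k] <- NA_integer_; weak[k] <- NA
    } else {
      h <- hits[[1L]]
      aligned[k] <- TRUE
      prec[k] <- index$prec_ids[h$i]; start[k] <- h$s; tlen[k] <- h$t
      add[k] <- paste(.codes_to_bases(h$add), collapse = "")
      mm[k] <- h$mm; weak[k] <- h$weak
    }
  }
  out <- reads
  out$aligned <- aligned
  out$precursor_id <- prec
  out$template_start <- start
  out$template_end <- start + tlen - 1L
  out$addition <- add
  out$n_mismatches <- mm
  out$weak <- weak
  out
}

#' Assign aligned reads to mature miRNAs and emit isomiR observations
#'
#' An alignment is assigned to the mature annotation (on its precursor)
#' that it overlaps by at least half of the annotated mature length; among
#' several such annotations the largest overlap wins (ties by mature id).
#' Alignments overlapping no annotation are unassigned precursor fragments
#' and are excluded from spectra but logged. Counts are aggregated per
#' isomiR species: (mature_id, template_start, template_end, addition).
#'
#' @param aligned output of [align_reads()], optionally with a `sample_id`
#'   column.
#' @param ref the `reference_set`.
#' @param min_overlap_frac assignment rule, default 0.5.
#' @return tibble of observations: `sample_id` (if present), `mature_id`,
#'   `precursor_id`, `template_start`, `template_end`, `addition`,
#'   `count`, `sequence`. Attributes `unassigned` and `unaligned` carry
#'   the logged remainders.
#' @export
call_isomirs <- function(aligned, ref, min_overlap_frac = 0.5) {
  has_sample <- "sample_id" %in% names(aligned)
  unaligned <- aligned[!aligned$aligned, ]
  hits <- aligned[aligned$aligned, ]
  ann <- ref$annotations
  m <- nrow(hits)
  mature <- rep(NA_character_, m)
  if (m > 0L) {
    for (k in seq_len(m)) {
      cand <- ann[ann$precursor_id == hits$precursor_id[k], , drop = FALSE]
      if (nrow(cand) == 0L) next
      ov <- pmin(hits$template_end[k], cand$end) -
        pmax(hits$template_start[k], cand$start) + 1L
      frac_ok <- ov >= min_overlap_frac * (cand$end - cand$start + 1L)
      cand <- cand[frac_ok & ov > 0L, , drop = FALSE]
      ov <- ov[frac_ok & ov > 0L]
      if (nrow(cand) == 0L) next
      best <- order(-ov, cand$mature_id, method = "radix")[1L]
      mature[k] <- cand$mature_id[best]
    }
  }
  hits$mature_id <- mature
  unassigned <- hits[is.na(mature), ]
  hits <- hits[!is.na(mature), ]
  grp <- c(if (has_sample) "sample_id", "mature_id", "precursor_id",
           "template_start", "template_end", "addition")
  obs <- hits %>%
    dplyr::group_by(dplyr::across(dplyr::all_of(grp))) %>%
    dplyr::summarise(count = sum(.data$count), .groups = "drop")
  pseq <- ref$precursors$sequence[match(obs$precursor_id,
                                        ref$precursors$precursor_id)]
  obs$sequence <- paste0(substr(pseq, obs$template_start, obs$template_end),
                         obs$addition)
  obs <- obs[order(obs$mature_id,
                   if (has_sample) obs$sample_id else rep("", nrow(obs)),
                   -obs$count, obs$sequence, method = "radix"), ]
  attr(obs, "unassigned") <- unassigned
  attr(obs, "unaligned") <- unaligned
  obs
}

#' Reported (addition-inclusive) end of an isomiR observation
#' @param obs observation tibble.
#' @return integer vector `template_end + nchar(addition)`.
#' @export
reported_end <- function(obs) {
  obs$template_end + nchar(obs$addition)
}

#' Human-readable isomiR labels in miR-addition / span style
#'
#' Names are the mature id stripped of its species prefix with the addition
#' appended (printing U for T), e.g. `miR-24-A`; the span is the
#' addition-inclusive `start-end`, with the canonical reference span in
#' parentheses when it differs (an empty parenthesis part means the
#' location matches the reference exactly).
#'
#' @param obs observation tibble.
#' @param ref the `reference_set` (canonical spans via [resolve_locus()]).
#' @return `obs` with `name` and `span` columns added.
#' @export
label_isomirs <- function(obs, ref) {
  short <- sub("^[a-z]{3,4}-", "", obs$mature_id)
  add_u <- gsub("T", "U", obs$addition, fixed = TRUE)
  obs$name <- ifelse(nzchar(add_u), paste0(short, "-", add_u), short)
  rend <- reported_end(obs)
  canon <- do.call(rbind, lapply(unique(obs$mature_id), function(m) {
    a <- resolve_locus(m, ref)
    data.frame(mature_id = m, c_start = a$start, c_end = a$end)
  }))
  i <- match(obs$mature_id, canon$mature_id)
  same <- obs$template_start == canon$c_start[i] & rend == canon$c_end[i]
  span <- paste0(obs$template_start, "\u2013", rend)
  ref_span <- paste0(" (", canon$c_start[i], "\u2013", canon$c_end[i], ")")
  obs$span <- ifelse(same, span, paste0(span, ref_span))
  obs
}
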