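# SOLiD two-base code. Bases map to 2-bit codes (A=0, C=1, G=2, T=3) and the
# color of an adjacent base pair is the bitwise XOR of the two codes. This
# reproduces the published di-base matrix: identical pairs give color 0, the
# code is symmetric, and each base paired with all four bases yields all four
# colors.

.SOLMIR_BASES <- c("A", "C", "G", "T")

#' Default sequencing adaptor used for colorspace boundary inference
#'
#' The 3' adaptor assumed to follow every sequenced insert. Its first base
#' determines the expected insert/adaptor junction color, which is what the
#' terminal-mismatch rule for non-template additions inspects; the second
#' junction color (the adaptor-internal color of bases 1-2) anchors the
#' reading frame. The adaptor is constructed with no self-similar junction
#' structure: its first two bases differ, its leading dinucleotide never
#' recurs, and the color of its leading base pair never recurs among its
#' adjacent pairs -- so a frame-shifted reinterpretation of the
#' insert/adaptor boundary always fails the two-color junction check.
#'
#' @format A single character string (base space).
#' @export
solmir_default_adaptor <- "CAAGATTCGGCTAAGGCCT"

#' Default SOLiD library primer base
#' @format A single character, `"T"`.
#' @export
solmir_default_primer <- "T"

#' Convert bases to 2-bit integer codes
#' @param x character vector of single bases or a single string.
#' @return integer vector of codes in 0..3.
#' @keywords internal
base_codes <- function(x) {
  if (length(x) == 1L && nchar(x) > 1L) x <- strsplit(x, "", fixed = TRUE)[[1]]
  codes <- match(toupper(x), .SOLMIR_BASES) - 1L
  if (anyNA(codes)) {
    bad <- unique(x[is.na(codes)])
    stop("invalid base(s): ", paste(bad, collapse = ", "), call. = FALSE)
  }
  codes
}

.codes_to_bases <- function(codes) .SOLMIR_BASES[codes + 1L]

#' Color string to integer vector
#' @keywords internal
color_codes <- function(colors) {
  if (length(colors) == 1L) colors <- strsplit(colors, "", fixed = TRUE)[[1]]
  v <- match(colors, c("0", "1", "2", "3")) - 1L
  if (anyNA(v)) {
    stop("invalid color digit(s): ",
         paste(unique(colors[is.na(v)]), collapse = ", "), call. = FALSE)
  }
  v
}

#' SOLiD di-base color of a pair of bases
#'
#' Vectorised over both arguments. The color is 0 for identical pairs,
#' symmetric in its arguments, and each base paired with all four bases
#' yields all four colors.
#'
#' @param b1,b2 character vectors of bases in `A`, `C`, `G`, `T`.
#' @return integer vector of colors in 0..3.
#' @export
#' @examples
#' color_of("A", "A") # 0
#' color_of("A", "C") == color_of("C", "A")
color_of <- function(b1, b2) {
  bitwXor(base_codes(b1), base_codes(b2))
}

#' Encode a base sequence into SOLiD colorspace
#'
#' The first color pairs the library primer base with the first sequence
#' base; color `i` then pairs bases `i - 1` and `i`. The color string has
#' the same length as the sequence.
#'
#' @param seq base string (length >= 1).
#' @param primer primer base, default `"T"`.
#' @return color digit string.
#' @export
#' @examples
#' cs_encode("ACGT", "T")
cs_encode <- function(seq, primer = solmir_default_primer) {
  codes <- base_codes(seq)
  if (length(codes) == 0L) stop("cannot encode an empty sequence", call. = FALSE)
  prev <- c(base_codes(primer), codes[-length(codes)])
  paste(bitwXor(prev, codes), collapse = "")
}

#' Decode a SOLiD color string back to bases
#'
#' Cascaded inversion of [cs_encode()]: base `i` is the primer code XORed
#' with the running XOR of the first `i` colors. A single corrupted color
#' therefore changes every decoded base downstream of it -- the property
#' that motivates aligning in color space rather than decoding first.
#'
#' @param primer primer base.
#' @param colors color digit string (may be empty).
#' @return decoded base string.
#' @export
#' @examples
#' cs_decode("T", cs_encode("ACGT", "T"))
cs_decode <- function(primer, colors) {
  if (nchar(colors) == 0L) return("")
  cc <- color_codes(colors)
  codes <- bitwXor(base_codes(primer), cumxor(cc))
  paste(.codes_to_bases(codes), collapse = "")
}

#' Running XOR of an integer vector
#' @keywords internal
cumxor <- function(x) {
  n <- length(x)
  if (n == 0L) return(integer(0))
  out <- integer(n)
  acc <- 0L
  for (i in seq_len(n)) {
    acc <- bitwXor(acc, x[i])
    out[i] <- acc
  }
  out
}

#' Read a CSFASTA file of colorspace reads
#'
#' CSFASTA dialect: header lines start with `>`, comment lines with `#` are
#' skipped, and each sequence line is a primer base followed by color
#' digits (e.g. `"T0123..."`). Optional quality (`.QV`) information is not
#' used by any downstream rule and is ignored.
#'
#' @param path file path.
#' @return tibble with columns `read_id`, `primer`, `colors`, `count`
#'   (always 1 on read; collapse with [collapse_reads()]).
#' @export
read_csfasta <- function(path) {
  lines <- readLines(path, warn = FALSE)
  lines <- lines[!startsWith(lines, "#")]
  lines <- lines[nzchar(lines)]
  if (length(lines) == 0L) {
    return(tibble::tibble(read_id = character(), primer = character(),
                          colors = character(), count = integer()))
  }
  is_hdr <- startsWith(lines, ">")
  if (!is_hdr[1] || length(lines) %% 2L != 0L ||
      !all(is_hdr == rep(c(TRUE, FALSE), length(lines) / 2L))) {
    stop("malformed CSFASTA: expected alternating '>' header and sequence lines",
         call. = FALSE)
  }
  ids <- sub("^>", "", lines[is_hdr])
  seqs <- lines[!is_hdr]
  primer <- toupper(substr(seqs, 1L, 1L))
  colors <- substr(seqs, 2L, nchar(seqs))
  bad <- !(primer %in% .SOLMIR_BASES) | !grepl("^[0-3]+$", colors)
  if (any(bad)) {
    stop("malformed CSFASTA sequence line for read(s): ",
         paste(utils::head(ids[bad], 5L), collapse = ", "), call. = FALSE)
  }
  tibble::tibble(read_id = ids, primer = primer, colors = colors,
                 count = rep(1L, length(ids)))
}

#' Write colorspace reads to a CSFASTA file
#'
#' Reads with `count > 1` are written once per record; the count is encoded
#' in the header as `id_xN` only when `expand = FALSE`.
#'
#' @param reads tibble with `read_id`, `primer`, `colors` (and optionally
#'   `count`).
#' @param path output path.
#' @param expand if `TRUE`, write `count` identical records per collapsed
#'   read (default `FALSE`).
#' @return `path`, invisibly.
#' @export
write_csfasta <- function(reads, path, expand = FALSE) {
  stopifnot(all(c("read_id", "primer", "colors") %in% names(reads)))
  if (expand && "count" %in% names(reads)) {
    idx <- rep(seq_len(nrow(reads)), reads$count)
    copy <- stats::ave(idx, idx, FUN = seq_along)
    lines <- as.vector(rbind(paste0(">", reads$read_id[idx], ".", copy),
                             paste0(reads$primer[idx], reads$colors[idx])))
  } else {
    hdr <- reads$read_id
    if ("count" %in% names(reads) && any(reads$count != 1L)) {
      hdr <- paste0(hdr, "_x", reads$count)
    }
    lines <- as.vector(rbind(paste0(">", hdr),
                             paste0(reads$primer, reads$colors)))
  }
  writeLines(lines, path)
  invisible(path)
}

#' Classify color mismatches at an alignment's 3' boundary
#'
#' Implements the terminal-mismatch rule for SOLiD small RNA reads: a single
#' isolated mismatch at an internal color is a sequencing error (to be
#' corrected to the reference); a mismatch at the final aligned color whose
#' following color (the first color of the insert/adaptor junction) also
#' mismatches its expectation marks a candidate 3' non-template addition; a
#' terminal mismatch whose junction color matches is a sequencing error at
#' the last color; anything with two or more aligned-region mismatches is an
#' unexplained true change.
#'
#' @param read a color string, or a one-row tibble/list with a `colors`
#'   field.
#' @param ref_colors expected colors: string or integer vector of length at
#'   least `aligned_len + 1`, where entry `aligned_len + 1` is the color
#'   expected at the junction were the insert to end on template (i.e. the
#'   first adaptor color after the last template base).
#' @param aligned_len number of aligned colors (the candidate insert
#'   length).
#' @return tibble with columns `position` (1-based color index) and `kind`
#'   (`"sequencing_error"`, `"terminal_addition_candidate"` or
#'   `"true_change"`); zero rows for a perfect match.
#' @export
classify_boundary <- function(read, ref_colors, aligned_len) {
  colors <- if (is.character(read) && length(read) == 1L) read else read$colors
  cc <- color_codes(colors)
  rc <- if (is.character(ref_colors)) color_codes(ref_colors) else as.integer(ref_colors)
  if (length(cc) < aligned_len + 1L) {
    stop("read has fewer than aligned_len + 1 colors", call. = FALSE)
  }
  if (length(rc) < aligned_len + 1L) {
    stop("ref_colors must cover aligned_len + 1 positions", call. = FALSE)
  }
  mism <- which(cc[seq_len(aligned_len)] != rc[seq_len(aligned_len)])
  if (length(mism) == 0L) {
    return(tibble::tibble(position = integer(), kind = character()))
  }
  boundary_mm <- cc[aligned_len + 1L] != rc[aligned_len + 1L]
  if (length(mism) == 1L) {
    kind <- if (mism < aligned_len) {
      "sequencing_error"
    } else if (boundary_mm) {
      "terminal_addition_candidate"
    } else {
      "sequencing_error"
    }
    return(tibble::tibble(position = mism, kind = kind))
  }
  tibble::tibble(position = mism, kind = rep("true_change", length(mism)))
}
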