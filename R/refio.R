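# Reference handling: precursor hairpins, mature coordinates, blacklist.
# Coordinates are 1-based inclusive throughout (matching miRBase-style
# "start-end" spans); they are converted only at I/O edges, never internally.

#' Read miRNA precursor sequences from FASTA
#'
#' The token before the first whitespace in each header becomes the
#' precursor id. Sequences are uppercased and U is normalised to T (one
#' canonical internal alphabet); output tables print U for addition
#' nucleotides.
#'
#' @param path FASTA file path.
#' @return tibble with columns `precursor_id`, `sequence`.
#' @export
read_precursor_fasta <- function(path) {
  set <- Biostrings::readBStringSet(path)
  ids <- sub("\\s.*$", "", names(set))
  seqs <- toupper(as.character(set))
  seqs <- gsub("U", "T", seqs, fixed = TRUE)
  if (anyDuplicated(ids)) {
    stop("duplicate precursor id(s): ",
         paste(unique(ids[duplicated(ids)]), collapse = ", "), call. = FALSE)
  }
  empty <- !nzchar(seqs)
  if (any(empty)) {
    stop("empty sequence for record(s): ",
         paste(ids[empty], collapse = ", "), call. = FALSE)
  }
  bad <- grepl("[^ACGT]", seqs)
  if (any(bad)) {
    stop("non-ACGTU character(s) in record(s): ",
         paste(ids[bad], collapse = ", "), call. = FALSE)
  }
  tibble::tibble(precursor_id = unname(ids), sequence = unname(seqs))
}

#' Write precursors to FASTA
#' @param precursors tibble with `precursor_id`, `sequence`.
#' @param path output path.
#' @return `path`, invisibly.
#' @export
write_precursor_fasta <- function(precursors, path) {
  writeLines(as.vector(rbind(paste0(">", precursors$precursor_id),
                             precursors$sequence)), path)
  invisible(path)
}

#' Read a mature-miRNA annotation table
#'
#' Tab-delimited with a header row and columns `mature_id`, `precursor_id`,
#' `start`, `end` and optionally `arm`. Coordinates are 1-based inclusive
#' positions on the precursor. When `arm` is absent it is inferred from the
#' mature midpoint: `5p` if the midpoint lies in the 5' half of the
#' precursor, else `3p`.
#'
#' @param path TSV path.
#' @param precursors precursor tibble from [read_precursor_fasta()], used to
#'   validate coordinates.
#' @return tibble with columns `mature_id`, `precursor_id`, `start`, `end`,
#'   `arm`.
#' @export
read_mature_annotations <- function(path, precursors) {
  ann <- readr::read_tsv(path, show_col_types = FALSE, progress = FALSE)
  req <- c("mature_id", "precursor_id", "start", "end")
  if (!all(req %in% names(ann))) {
    stop("annotation table must have columns: ", paste(req, collapse = ", "),
         call. = FALSE)
  }
  ann$start <- as.integer(ann$start)
  ann$end <- as.integer(ann$end)
  if (!"arm" %in% names(ann)) ann$arm <- NA_character_
  validate_annotations(ann, precursors)
}

#' Validate (and complete) a mature annotation tibble
#' @keywords internal
validate_annotations <- function(ann, precursors) {
  unknown <- setdiff(ann$precursor_id, precursors$precursor_id)
  if (length(unknown) > 0L) {
    stop("annotation references unknown precursor_id(s): ",
         paste(unknown, collapse = ", "), call. = FALSE)
  }
  plen <- nchar(precursors$sequence)[match(ann$precursor_id, precursors$precursor_id)]
  bad <- ann$start < 1L | ann$start >= ann$end | ann$end > plen
  if (any(bad)) {
    stop("invalid coordinates (need 1 <= start < end <= precursor length) for: ",
         paste(ann$mature_id[bad], collapse = ", "), call. = FALSE)
  }
  len <- ann$end - ann$start + 1L
  if (any(len < 16L | len > 30L)) {
    stop("mature length outside 16..30 nt for: ",
         paste(ann$mature_id[len < 16L | len > 30L], collapse = ", "),
         call. = FALSE)
  }
  mid <- (ann$start + ann$end) / 2
  inferred <- ifelse(mid <= plen / 2, "5p", "3p")
  ann$arm <- ifelse(is.na(ann$arm), inferred, ann$arm)
  if (!all(ann$arm %in% c("5p", "3p"))) {
    stop("arm must be '5p' or '3p'", call. = FALSE)
  }
  key <- paste(ann$mature_id, ann$precursor_id)
  if (anyDuplicated(key)) {
    stop("duplicate (mature_id, precursor_id) pair(s): ",
         paste(unique(key[duplicated(key)]), collapse = "; "), call. = FALSE)
  }
  tibble::as_tibble(ann[c("mature_id", "precursor_id", "start", "end", "arm")])
}

#' Write mature annotations to TSV
#' @param annotations annotation tibble.
#' @param path output path.
#' @return `path`, invisibly.
#' @export
write_mature_annotations <- function(annotations, path) {
  readr::write_tsv(annotations, path, progress = FALSE)
  invisible(path)
}

#' Bundle precursors, annotations and a blacklist into a reference set
#'
#' @param precursors tibble from [read_precursor_fasta()].
#' @param annotations tibble from [read_mature_annotations()] (or built in
#'   code with the same columns; `arm` may be `NA` and is then inferred).
#' @param blacklist optional tibble with `id`, `sequence` of other ncRNAs
#'   (tRNA/rRNA/snoRNA/snRNA fragments to remove before alignment).
#' @return object of class `reference_set`.
#' @export
reference_set <- function(precursors, annotations, blacklist = NULL) {
  stopifnot(is.data.frame(precursors), is.data.frame(annotations))
  if (anyDuplicated(precursors$precursor_id)) {
    stop("duplicate precursor ids in reference", call. = FALSE)
  }
  if (!"arm" %in% names(annotations)) annotations$arm <- NA_character_
  annotations <- validate_annotations(tibble::as_tibble(annotations), precursors)
  if (is.null(blacklist)) {
    blacklist <- tibble::tibble(id = character(), sequence = character())
  } else {
    blacklist$sequence <- gsub("U", "T", toupper(blacklist$sequence), fixed = TRUE)
  }
  structure(list(precursors = tibble::as_tibble(precursors),
                 annotations = annotations,
                 blacklist = tibble::as_tibble(blacklist)),
            class = "reference_set")
}

#' @export
print.reference_set <- function(x, ...) {
  cat("<reference_set> ", nrow(x$precursors), " precursors, ",
      nrow(x$annotations), " mature annotations, ",
      nrow(x$blacklist), " blacklist sequences\n", sep = "")
  invisible(x)
}

#' Resolve the reference locus of a multicopy mature miRNA
#'
#' A mature miRNA annotated on several paralogous precursors is reported
#' against its "first" precursor, defined (deterministically) as the
#' lexicographically smallest `precursor_id` in C-locale byte order.
#'
#' @param mature_id mature miRNA id.
#' @param ref a `reference_set`.
#' @return the single chosen annotation row (tibble).
#' @export
resolve_locus <- function(mature_id, ref) {
  ann <- ref$annotations[ref$annotations$mature_id == mature_id, , drop = FALSE]
  if (nrow(ann) == 0L) {
    stop("unknown mature_id: ", mature_id, call. = FALSE)
  }
  ann[order(ann$precursor_id, method = "radix"), , drop = FALSE][1L, ]
}

#' Read a blacklist FASTA of other non-coding RNAs
#' @param path FASTA path.
#' @return tibble with `id`, `sequence` (T alphabet).
#' @export
read_blacklist_fasta <- function(path) {
  p <- read_precursor_fasta(path)
  tibble::tibble(id = p$precursor_id, sequence = p$sequence)
}
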