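# Synthetic three-sample study generator. Emulates the structure of a
# SOLiD placental small RNA experiment: per-locus isomiR spectra with 1-3
# abundant species, 3' end shifts more frequent than 5' shifts,
# adenosine-biased single and double 3' non-template additions carried by
# minor species, per-color sequencing errors, planted per-locus fold
# changes between samples, and machine-readable ground truth.
#
# The species structure (which isomiRs exist per locus and their within-
# locus proportions) is drawn once from the configuration seed and shared
# by all samples -- the conserved-spectrum baseline; per-sample randomness
# (multinomial sampling, error injection) uses the per-library seed.

#' Simulation configuration
#'
#' All probabilities must be in `[0, 1]`; addition base weights must sum
#' to 1; the seed is mandatory (no silent nondeterminism).
#'
#' @param n_loci number of miRNA loci (default 30).
#' @param n_reads reads per library (default 1e5).
#' @param precursor_length inclusive range of precursor lengths (nt).
#' @param mature_length inclusive range of canonical mature lengths (nt).
#' @param samples sample ids; the first is the baseline (normal) sample.
#' @param abundance_meanlog,abundance_sdlog log-normal parameters of the
#'   per-locus abundance weights.
#' @param shift3_prob,shift5_prob per-variant-slot probabilities that a
#'   locus gains a 3'-shifted / 5'-shifted template species (two slots per
#'   locus; 3' shifts dominate, mirroring end-heterogeneity bias).
#' @param shift_decay geometric decay of shift offset magnitudes (offsets
#'   are capped at 2 nt).
#' @param nta_type_share target share of isomiR species carrying a 3'
#'   addition (species-level planting; 0 disables additions entirely).
#' @param nta_base_weights named addition base weights (U accepted),
#'   adenosine-biased by default.
#' @param nta_double_prob probability that a planted modified species
#'   carries a double (2 nt) addition.
#' @param nta_rel_abundance range of the modified/parent count ratio.
#' @param nta_min_expected floor on a modified species' expected count so
#'   planted species survive the report threshold.
#' @param error_rate per-color sequencing error probability.
#' @param read_colors total colors per read (insert + adaptor, SOLiD-style
#'   fixed length).
#' @param adaptor 3' adaptor appended to every insert before encoding.
#' @param primer library primer base.
#' @param de_effects tibble (`locus`, `sample_id`, `log2fc`) of planted
#'   per-locus log2 effects relative to the baseline sample, applied as a
#'   symmetric split (baseline scaled down, target scaled up); `NULL`
#'   plants the default six +/-6 effects on loci 1-6 in the last sample.
#' @param spectrum_shift integer locus indices whose dominant template
#'   species is swapped with the secondary one in every non-baseline
#'   sample (dominant-spectrum switching between normal and disease).
#' @param seed integer seed governing the shared species structure.
#' @return validated object of class `sim_config`.
#' @export
sim_config <- function(n_loci = 30L,
                       n_reads = 1e5L,
                       precursor_length = c(70L, 90L),
                       mature_length = c(20L, 23L),
                       samples = c("normal", "mild", "severe"),
                       abundance_meanlog = 0,
                       abundance_sdlog = 1,
                       shift3_prob = 0.8,
                       shift5_prob = 0.1,
                       shift_decay = 0.5,
                       nta_type_share = 0.31,
                       nta_base_weights = c(A = 0.60, U = 0.25, C = 0.12, G = 0.03),
                       nta_double_prob = 0.10,
                       nta_rel_abundance = c(0.03, 0.12),
                       nta_min_expected = 20,
                       error_rate = 0.001,
                       read_colors = 35L,
                       adaptor = solmir_default_adaptor,
                       primer = solmir_default_primer,
                       de_effects = NULL,
                       spectrum_shift = integer(0),
                       seed = NULL) {
  if (is.null(seed)) stop("sim_config requires an explicit seed", call. = FALSE)
  probs <- c(shift3_prob, shift5_prob, shift_decay, nta_type_share,
             nta_double_prob, error_rate)
  if (any(probs < 0 | probs > 1)) {
    stop("all probabilities must be in [0, 1]", call. = FALSE)
  }
  if (shift3_prob + shift5_prob > 1) {
    stop("shift3_prob + shift5_prob must not exceed 1", call. = FALSE)
  }
  names(nta_base_weights) <- gsub("U", "T", toupper(names(nta_base_weights)))
  if (!setequal(names(nta_base_weights), .SOLMIR_BASES) ||
      abs(sum(nta_base_weights) - 1) > 1e-9) {
    stop("nta_base_weights must be named A/C/G/T (or U) and sum to 1",
         call. = FALSE)
  }
  if (nta_type_share >= 1) stop("nta_type_share must be < 1", call. = FALSE)
  stopifnot(n_loci >= 1, n_reads >= 1,
            length(precursor_length) == 2L,
            precursor_length[1] >= 40L, precursor_length[2] <= 200L,
            precursor_length[1] <= precursor_length[2],
            length(mature_length) == 2L,
            mature_length[1] >= 16L, mature_length[2] <= 30L,
            length(samples) >= 1L, !anyDuplicated(samples),
            nta_rel_abundance[1] > 0,
            nta_rel_abundance[1] <= nta_rel_abundance[2])
  if (is.null(de_effects)) {
    n_eff <- min(6L, n_loci)
    de_effects <- tibble::tibble(
      locus = seq_len(n_eff),
      sample_id = samples[length(samples)],
      log2fc = rep_len(c(6, -6), n_eff))
  }
  de_effects <- tibble::as_tibble(de_effects)
  stopifnot(all(c("locus", "sample_id", "log2fc") %in% names(de_effects)),
            all(de_effects$locus %in% seq_len(n_loci)),
            all(de_effects$sample_id %in% samples[-1]))
  stopifnot(all(spectrum_shift %in% seq_len(n_loci)))
  structure(list(n_loci = as.integer(n_loci), n_reads = as.integer(n_reads),
                 precursor_length = as.integer(precursor_length),
                 mature_length = as.integer(mature_length),
                 samples = samples,
                 abundance_meanlog = abundance_meanlog,
                 abundance_sdlog = abundance_sdlog,
                 shift3_prob = shift3_prob, shift5_prob = shift5_prob,
                 shift_decay = shift_decay,
                 nta_type_share = nta_type_share,
                 nta_base_weights = nta_base_weights[.SOLMIR_BASES],
                 nta_double_prob = nta_double_prob,
                 nta_rel_abundance = nta_rel_abundance,
                 nta_min_expected = nta_min_expected,
                 error_rate = error_rate,
                 read_colors = as.integer(read_colors),
                 adaptor = toupper(adaptor), primer = toupper(primer),
                 de_effects = de_effects,
                 spectrum_shift = as.integer(spectrum_shift),
                 seed = as.integer(seed)),
            class = "sim_config")
}

#' Generate a random reference set of precursors with mature annotations
#'
#' One precursor and one mature annotation per locus; arms alternate at
#' random, with coordinates leaving margins for end shifts and templated
#' extensions. Reproducible: the same seed yields byte-identical output.
#'
#' @param config a `sim_config`.
#' @param seed seed (defaults to `config$seed`).
#' @return a `reference_set`.
#' @export
generate_reference <- function(config, seed = config$seed) {
  stopifnot(inherits(config, "sim_config"))
  set.seed(seed)
  n <- config$n_loci
  plen <- sample(seq(config$precursor_length[1], config$precursor_length[2]),
                 n, replace = TRUE)
  seqs <- vapply(plen, function(L) {
    paste(sample(.SOLMIR_BASES, L, replace = TRUE), collapse = "")
  }, "")
  lens <- seq(config$mature_length[1], config$mature_length[2])
  # canonical lengths peak at 22 nt (the dominant small-RNA length) when the
  # configured range allows it, otherwise uniform
  lw <- stats::dnorm(lens, 22, 0.5)
  if (sum(lw) < 1e-6) lw <- rep(1, length(lens))
  mlen <- sample(lens, n, replace = TRUE, prob = lw)
  arm <- sample(c("5p", "3p"), n, replace = TRUE)
  start <- integer(n)
  for (i in seq_len(n)) {
    if (arm[i] == "5p") {
      hi <- floor(plen[i] / 2) - ceiling(mlen[i] / 2)
      start[i] <- sample(seq(5L, max(5L, hi)), 1L)
    } else {
      lo <- ceiling(plen[i] / 2) + ceiling(mlen[i] / 2) - mlen[i] + 2L
      hi <- plen[i] - 4L - mlen[i] + 1L
      start[i] <- sample(seq(lo, max(lo, hi)), 1L)
    }
  }
  precursors <- tibble::tibble(
    precursor_id = sprintf("sim-mir-%03d", seq_len(n)),
    sequence = seqs)
  annotations <- tibble::tibble(
    mature_id = sprintf("sim-miR-%03d", seq_len(n)),
    precursor_id = precursors$precursor_id,
    start = start, end = start + mlen - 1L, arm = arm)
  reference_set(precursors, annotations)
}

# Shared species structure: template species per locus (spans +
# proportions), modified siblings, per-locus base abundances. Drawn from
# config$seed so every sample sees the same spectrum.
.plant_species <- function(ref, config) {
  set.seed(config$seed + 1L)
  n <- config$n_loci
  ann <- ref$annotations
  lambda <- stats::rlnorm(n, config$abundance_meanlog, config$abundance_sdlog)
  species <- list()
  geom_mag <- function() min(1L + stats::rgeom(1L, 1 - config$shift_decay), 2L)
  for (i in seq_len(n)) {
    a <- ann[i, ]
    spans <- data.frame(start = a$start, end = a$end)
    for (slot in 1:2) {
      u <- stats::runif(1)
      if (u < config$shift3_prob) {
        off <- geom_mag() * sample(c(-1L, 1L), 1L)
        spans <- rbind(spans, data.frame(start = a$start, end = a$end + off))
      } else if (u < config$shift3_prob + config$shift5_prob) {
        off <- geom_mag() * sample(c(-1L, 1L), 1L)
        spans <- rbind(spans, data.frame(start = a$start + off, end = a$end))
      }
    }
    spans <- spans[!duplicated(spans), , drop = FALSE]
    k <- nrow(spans)
    # dominance-structured proportions: the canonical species leads
    w <- c(stats::runif(1, 0.5, 0.8), stats::runif(k - 1L, 0.1, 0.35))
    w <- w / sum(w)
    species[[i]] <- tibble::tibble(
      locus = i, mature_id = a$mature_id, precursor_id = a$precursor_id,
      template_start = as.integer(spans$start),
      template_end = as.integer(spans$end),
      proportion = w)
  }
  tmpl <- dplyr::bind_rows(species)
  tmpl$addition <- ""
  # species-level planting of 3' additions at the configured type share
  n_tmpl <- nrow(tmpl)
  n_mod <- round(config$nta_type_share / (1 - config$nta_type_share) * n_tmpl)
  mods <- NULL
  if (n_mod > 0L) {
    cand <- which(tmpl$proportion >= 0.1)
    pick <- sample(rep(cand, length.out = max(n_mod, length(cand))))[seq_len(n_mod)]
    prec_seq <- ref$precursors$sequence
    prec_of <- match(tmpl$precursor_id, ref$precursors$precursor_id)
    draw_addition <- function(te, pi) {
      len <- if (stats::runif(1) < config$nta_double_prob) 2L else 1L
      plen <- nchar(prec_seq[pi])
      bases <- character(len)
      for (j in seq_len(len)) {
        pos <- te + j
        repeat {
          b <- sample(.SOLMIR_BASES, 1L, prob = config$nta_base_weights)
          if (pos > plen || substr(prec_seq[pi], pos, pos) != b) break
        }
        bases[j] <- b
      }
      paste(bases, collapse = "")
    }
    mods <- tmpl[pick, ]
    mods$addition <- vapply(seq_along(pick), function(k) {
      draw_addition(mods$template_end[k], prec_of[pick[k]])
    }, "")
    rel <- stats::runif(n_mod, config$nta_rel_abundance[1],
                        config$nta_rel_abundance[2])
    mods$proportion <- mods$proportion * rel
    # key modified species by (span, addition); merge accidental duplicates
    mods <- mods %>%
      dplyr::group_by(.data$locus, .data$mature_id, .data$precursor_id,
                      .data$template_start, .data$template_end,
                      .data$addition) %>%
      dplyr::summarise(proportion = sum(.data$proportion), .groups = "drop")
  }
  list(template = tmpl, modified = mods, lambda = lambda)
}

# Per-sample expected species table (before multinomial sampling).
.sample_expectation <- function(ref, config, plant, sample_id) {
  tmpl <- plant$template
  lam <- plant$lambda
  # planted fold changes: symmetric split between baseline and target
  eff <- rep(0, config$n_loci)
  de <- config$de_effects
  base_down <- rep(0, config$n_loci)
  for (r in seq_len(nrow(de))) {
    l <- de$locus[r]
    base_down[l] <- base_down[l] + de$log2fc[r] / 2
    if (de$sample_id[r] == sample_id) eff[l] <- de$log2fc[r] / 2
  }
  scale <- if (sample_id == config$samples[1]) 2^(-base_down) else 2^(eff)
  lam <- lam * scale
  tmpl$weight <- lam[tmpl$locus] * tmpl$proportion
  # dominant-spectrum switching in non-baseline samples
  if (sample_id != config$samples[1] && length(config$spectrum_shift) > 0L) {
    for (l in config$spectrum_shift) {
      rows <- which(tmpl$locus == l)
      if (length(rows) >= 2L) {
        o <- rows[order(-tmpl$weight[rows])]
        w <- tmpl$weight[o]
        tmpl$weight[o[1:2]] <- w[2:1]
      }
    }
  }
  out <- tmpl
  if (!is.null(plant$modified)) {
    mods <- plant$modified
    # modified species scale with their locus; floor their expected count
    mods$weight <- lam[mods$locus] * mods$proportion
    total_w <- sum(out$weight) + sum(mods$weight)
    floor_w <- config$nta_min_expected * total_w / config$n_reads
    mods$weight <- pmax(mods$weight, floor_w)
    out <- dplyr::bind_rows(out, mods)
  }
  out$expected <- out$weight / sum(out$weight)
  out$sample_id <- sample_id
  out
}

#' Generate one sample's read library with ground truth
#'
#' Species counts are multinomial draws from the planted expectation;
#' every read is the template substring plus any 3' addition, encoded to
#' colorspace with the library primer, the adaptor appended, the color
#' string truncated to `read_colors`, and per-color errors injected.
#' Base-space reads (the error-free insert sequences) are emitted in
#' parallel for the portable base-space mode.
#'
#' @param ref the `reference_set` from [generate_reference()].
#' @param config the `sim_config`.
#' @param sample_id one of `config$samples`.
#' @param seed per-library seed (use a different one per sample; the
#'   shared spectrum structure is governed by `config$seed`).
#' @return list with `reads_cs` (collapsed colorspace reads: `read_id`,
#'   `primer`, `colors`, `count`), `reads_bs` (collapsed base-space
#'   reads), and `truth` (list of `species` and `loci` tibbles).
#' @export
generate_library <- function(ref, config, sample_id, seed) {
  stopifnot(inherits(config, "sim_config"), sample_id %in% config$samples)
  plant <- .plant_species(ref, config)
  exp_tbl <- .sample_expectation(ref, config, plant, sample_id)
  set.seed(seed)
  counts <- as.vector(stats::rmultinom(1L, config$n_reads, exp_tbl$expected))
  exp_tbl$count <- counts
  keep <- exp_tbl$count > 0L
  sp <- exp_tbl[keep, ]
  prec_seq <- ref$precursors$sequence[match(sp$precursor_id,
                                            ref$precursors$precursor_id)]
  sp$sequence <- paste0(substr(prec_seq, sp$template_start, sp$template_end),
                        sp$addition)
  # colorspace encoding: insert + adaptor, truncated to read_colors
  full <- paste0(sp$sequence, config$adaptor)
  colors <- vapply(full, cs_encode, "", primer = config$primer,
                   USE.NAMES = FALSE)
  colors <- substr(colors, 1L, config$read_colors)
  if (any(nchar(colors) < nchar(sp$sequence) + 2L)) {
    stop("read_colors too short: need at least insert + 2 adaptor colors",
         call. = FALSE)
  }
  # per-color sequencing errors: reads carrying at least one error become
  # individual records; clean reads stay collapsed per species
  L <- nchar(colors)
  n_err_reads <- stats::rbinom(nrow(sp), sp$count,
                               1 - (1 - config$error_rate)^L)
  reads_cs <- tibble::tibble(
    read_id = sprintf("%s_sp%04d", sample_id, seq_len(nrow(sp))),
    primer = config$primer,
    colors = colors,
    count = sp$count - n_err_reads)
  dirty_total <- sum(n_err_reads)
  n_err2_reads <- integer(nrow(sp))
  if (dirty_total > 0L) {
    di <- rep(seq_len(nrow(sp)), n_err_reads)
    dirty <- character(dirty_total)
    for (k in seq_along(di)) {
      cc <- color_codes(colors[di[k]])
      Lk <- length(cc)
      # at least one error, others at the conditional per-color rate
      n_e <- 1L + stats::rbinom(1L, Lk - 1L, config$error_rate)
      if (n_e >= 2L) n_err2_reads[di[k]] <- n_err2_reads[di[k]] + 1L
      pos <- sample.int(Lk, n_e)
      cc[pos] <- (cc[pos] + sample(1:3, n_e, replace = TRUE)) %% 4L
      dirty[k] <- paste(cc, collapse = "")
    }
    reads_cs <- dplyr::bind_rows(
      reads_cs,
      tibble::tibble(read_id = sprintf("%s_err%05d", sample_id,
                                       seq_len(dirty_total)),
                     primer = config$primer, colors = dirty,
                     count = 1L))
  }
  reads_cs <- reads_cs[reads_cs$count > 0L, ]
  reads_bs <- tibble::tibble(
    read_id = sprintf("%s_sp%04d", sample_id, seq_len(nrow(sp))),
    sequence = sp$sequence,
    count = sp$count)
  truth_species <- tibble::tibble(
    sample_id = sample_id,
    mature_id = sp$mature_id, precursor_id = sp$precursor_id,
    template_start = sp$template_start, template_end = sp$template_end,
    addition = sp$addition, modified = nzchar(sp$addition),
    count = sp$count, n_error_reads = n_err_reads,
    n_error2_reads = n_err2_reads)
  de <- config$de_effects
  loci <- tibble::tibble(
    locus = seq_len(config$n_loci),
    mature_id = ref$annotations$mature_id,
    precursor_id = ref$annotations$precursor_id,
    lambda = plant$lambda,
    log2_effect = vapply(seq_len(config$n_loci), function(l) {
      hit <- de$locus == l & de$sample_id == sample_id
      if (any(hit)) sum(de$log2fc[hit]) else 0
    }, numeric(1)),
    spectrum_shifted = seq_len(config$n_loci) %in% config$spectrum_shift &
      sample_id != config$samples[1])
  list(reads_cs = reads_cs, reads_bs = reads_bs,
       truth = list(species = truth_species, loci = loci))
}

#' Write / read a ground-truth table
#'
#' Two stable-column-order TSVs: `<path>_species.tsv` and
#' `<path>_loci.tsv`.
#'
#' @param truth the `truth` element of [generate_library()] (or several
#'   samples' truths row-bound).
#' @param path path prefix.
#' @return `path` invisibly / the truth list.
#' @export
write_truth <- function(truth, path) {
  readr::write_tsv(truth$species, paste0(path, "_species.tsv"),
                   progress = FALSE)
  readr::write_tsv(truth$loci, paste0(path, "_loci.tsv"), progress = FALSE)
  invisible(path)
}

#' @rdname write_truth
#' @export
read_truth <- function(path) {
  species <- readr::read_tsv(paste0(path, "_species.tsv"),
                             show_col_types = FALSE, progress = FALSE)
  species$addition[is.na(species$addition)] <- ""
  loci <- readr::read_tsv(paste0(path, "_loci.tsv"),
                          show_col_types = FALSE, progress = FALSE)
  list(species = species, loci = loci)
}

#' Write base-space reads to FASTA
#' @param reads tibble with `read_id`, `sequence`, optionally `count`.
#' @param path output path.
#' @return `path`, invisibly.
#' @export
write_read_fasta <- function(reads, path) {
  hdr <- reads$read_id
  if ("count" %in% names(reads) && any(reads$count != 1L)) {
    hdr <- paste0(hdr, "_x", reads$count)
  }
  writeLines(as.vector(rbind(paste0(">", hdr), reads$sequence)), path)
  invisible(path)
}
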