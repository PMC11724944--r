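#' Allele-length classifier configuration
#'
#' Two thresholds drive variant classification: `sv_min_delta`, the minimum
#' absolute reference/alternate length difference (bp) for a variant to be
#' flagged a structural variant (inclusive, both directions), and
#' `indel_max_len`, below which length-changing variants are categorized as
#' indels rather than insertions/deletions.
#'
#' @param sv_min_delta Minimum |length difference| for the SV flag (default
#'   50 bp).
#' @param indel_max_len Length-change magnitude at and above which a variant
#'   is an insertion or deletion rather than an indel (default 1000 bp).
#' @return A `classifier_config` list.
#' @export
classifier_config <- function(sv_min_delta = 50L, indel_max_len = 1000L) {
  if (!(sv_min_delta > 0 && sv_min_delta < indel_max_len)) {
    abort("need 0 < sv_min_delta < indel_max_len")
  }
  structure(list(sv_min_delta = as.integer(sv_min_delta),
                 indel_max_len = as.integer(indel_max_len)),
            class = "classifier_config")
}

# strip one shared leading base, then the maximal shared trailing run
anchor_trim <- function(ref, alt) {
  if (nchar(ref) > 0 && nchar(alt) > 0 &&
      substr(ref, 1, 1) == substr(alt, 1, 1)) {
    ref <- substring(ref, 2)
    alt <- substring(alt, 2)
  }
  while (nchar(ref) > 0 && nchar(alt) > 0 &&
         substr(ref, nchar(ref), nchar(ref)) ==
         substr(alt, nchar(alt), nchar(alt))) {
    ref <- substr(ref, 1, nchar(ref) - 1L)
    alt <- substr(alt, 1, nchar(alt) - 1L)
  }
  c(ref, alt)
}

#' Classify a reference/alternate allele pair by length rules
#'
#' With `delta = nchar(alt) - nchar(ref)`:
#' * `delta == 0`, both length 1: `snv`; longer: `mnv`.
#' * `0 < |delta| < indel_max_len`: `indel`.
#' * `delta >= indel_max_len`: `insertion`; `delta <= -indel_max_len`:
#'   `deletion`.
#' * a length-changing pair where anchor trimming (one shared leading base,
#'   then the shared trailing run) leaves both alleles longer than 1 bp is a
#'   substitution entangled with the length change and is reported as
#'   `complex`.
#'
#' The SV flag is independent of the class: `is_sv` iff
#' `|delta| >= sv_min_delta`.
#'
#' @param ref_allele,alt_allele Nucleotide strings over `ACGTN`
#'   (case-insensitive); vectorized, recycled to common length.
#' @param config A [classifier_config()].
#' @return Tibble with one row per pair: `ref_len`, `alt_len`, `delta`,
#'   `variant_class`, `is_sv`.
#' @examples
#' classify_allele("A", "T")                     # snv
#' classify_allele(strrep("A", 120), "A")        # 119 bp loss: SV, indel
#' classify_allele("A", paste0("A", strrep("C", 1500)))  # insertion
#' @export
classify_allele <- function(ref_allele, alt_allele,
                            config = classifier_config()) {
  stopifnot(inherits(config, "classifier_config"))
  n <- max(length(ref_allele), length(alt_allele))
  ref <- str_to_upper(rep_len(ref_allele, n))
  alt <- str_to_upper(rep_len(alt_allele, n))
  ok <- grepl("^[ACGTN]+$", ref) & grepl("^[ACGTN]+$", alt)
  if (!all(ok)) {
    abort(paste0("allele(s) with characters outside ACGTN (symbolic or ",
                 "breakend alleles are not supported): ",
                 paste(utils::head(alt[!ok], 3), collapse = ", ")))
  }
  ref_len <- nchar(ref)
  alt_len <- nchar(alt)
  delta <- alt_len - ref_len
  cls <- character(n)
  for (i in seq_len(n)) {
    if (delta[i] == 0L) {
      cls[i] <- if (ref_len[i] == 1L) "snv" else "mnv"
    } else {
      trimmed <- anchor_trim(ref[i], alt[i])
      if (nchar(trimmed[1]) > 1L && nchar(trimmed[2]) > 1L) {
        cls[i] <- "complex"
      } else if (abs(delta[i]) < config$indel_max_len) {
        cls[i] <- "indel"
      } else {
        cls[i] <- if (delta[i] > 0L) "insertion" else "deletion"
      }
    }
  }
  tibble(ref_len = ref_len, alt_len = alt_len, delta = delta,
         variant_class = cls,
         is_sv = abs(delta) >= config$sv_min_delta)
}

read_vcf_obj <- function(vcf) {
  if (inherits(vcf, "vcfR")) return(vcf)
  vcfR::read.vcfR(vcf, verbose = FALSE)
}

#' Extract the variants carried by one sample from a multi-sample VCF
#'
#' Emulates per-sample subsetting with allele trimming: a record is kept iff
#' the sample's genotype contains at least one non-reference, non-missing
#' allele index; alternate alleles the sample does not carry are dropped and
#' the genotype indices renumbered against the trimmed alternate list.
#' Records whose genotype field cannot be parsed are skipped with a warning
#' and counted in the `n_skipped` attribute.
#'
#' @param vcf Path to a VCF 4.x file (plain or bgzip) or a `vcfR` object.
#' @param sample Sample name; must appear in the VCF header.
#' @param exclusive If `TRUE`, additionally require that no *other* sample
#'   carries a non-reference allele at the record (private variants only).
#' @return Tibble with one row per retained record: `chrom`, `pos`, `ref`,
#'   `alt` (list-column of carried alternate alleles, in renumbered order)
#'   and `gt` (the renumbered genotype string, separators preserved).
#' @export
extract_sample_variants <- function(vcf, sample, exclusive = FALSE) {
  v <- read_vcf_obj(vcf)
  gt_mat <- v@gt
  samples <- colnames(gt_mat)[-1]
  if (!sample %in% samples) {
    abort(paste0("sample '", sample, "' not in VCF header; samples: ",
                 paste(samples, collapse = ", ")))
  }
  fix <- v@fix
  n_skipped <- 0L
  rows <- vector("list", nrow(fix))
  for (i in seq_len(nrow(fix))) {
    raw <- gt_mat[i, sample]
    if (is.na(raw)) next  # fully missing genotype carries nothing
    gt_field <- strsplit(raw, ":", fixed = TRUE)[[1]][1]
    toks <- strsplit(gt_field, "[/|]")[[1]]
    if (!length(toks) || any(!grepl("^([0-9]+|\\.)$", toks))) {
      warn(sprintf("record %s:%s: unparseable genotype '%s'; skipped",
                   fix[i, "CHROM"], fix[i, "POS"], gt_field))
      n_skipped <- n_skipped + 1L
      next
    }
    idx <- suppressWarnings(as.integer(toks[toks != "."]))
    carried <- sort(unique(idx[idx > 0L]))
    if (!length(carried)) next
    alts <- strsplit(fix[i, "ALT"], ",", fixed = TRUE)[[1]]
    if (any(carried > length(alts))) {
      warn(sprintf("record %s:%s: genotype index beyond ALT list; skipped",
                   fix[i, "CHROM"], fix[i, "POS"]))
      n_skipped <- n_skipped + 1L
      next
    }
    if (exclusive) {
      other_carries <- any(map_lgl(samples[samples != sample], function(s) {
        r <- gt_mat[i, s]
        if (is.na(r)) return(FALSE)
        f <- strsplit(r, ":", fixed = TRUE)[[1]][1]
        tk <- strsplit(f, "[/|]")[[1]]
        any(grepl("^[0-9]+$", tk) & suppressWarnings(as.integer(tk)) > 0L)
      }))
      if (other_carries) next
    }
    renum <- stats::setNames(seq_along(carried), carried)
    new_gt <- vapply(toks, function(t) {
      if (t == "." || t == "0") t else as.character(renum[[t]])
    }, character(1))
    sep <- if (grepl("|", gt_field, fixed = TRUE)) "|" else "/"
    rows[[i]] <- tibble(
      chrom = fix[i, "CHROM"],
      pos = as.integer(fix[i, "POS"]),
      ref = fix[i, "REF"],
      alt = list(alts[carried]),
      gt = paste(new_gt, collapse = sep))
  }
  out <- bind_rows(rows)
  if (!nrow(out)) {
    out <- tibble(chrom = character(), pos = integer(), ref = character(),
                  alt = list(), gt = character())
  }
  attr(out, "n_skipped") <- n_skipped
  out
}

#' Classify every carried alternate allele of extracted records
#'
#' Each distinct carried alternate allele yields one classification (a `1/2`
#' genotype yields two rows).
#'
#' @param records Output of [extract_sample_variants()].
#' @param config A [classifier_config()].
#' @return Tibble with `chrom`, `pos`, `ref`, `alt` and the columns of
#'   [classify_allele()].
#' @export
classify_sample_variants <- function(records, config = classifier_config()) {
  long <- tidyr::unnest(records, "alt")
  if (!nrow(long)) {
    return(tibble(chrom = character(), pos = integer(), ref = character(),
                  alt = character(), ref_len = integer(),
                  alt_len = integer(), delta = integer(),
                  variant_class = character(), is_sv = logical()))
  }
  dplyr::bind_cols(long[, c("chrom", "pos", "ref", "alt")],
                   classify_allele(long$ref, long$alt, config))
}

#' One-call per-sample VCF classification
#'
#' Convenience pipeline: [extract_sample_variants()] then
#' [classify_sample_variants()].
#'
#' @inheritParams extract_sample_variants
#' @inheritParams classify_sample_variants
#' @return See [classify_sample_variants()].
#' @export
sv_classify_sample <- function(vcf, sample, config = classifier_config(),
                               exclusive = FALSE) {
  classify_sample_variants(
    extract_sample_variants(vcf, sample, exclusive = exclusive), config)
}

#' Tally classified variants per class and per chromosome
#'
#' @param classified Output of [classify_sample_variants()].
#' @return A `class_tally`: tibble of (`chrom`, `variant_class`, `n`)
#'   counts, with per-class totals available via [glance()]. Class counts
#'   partition the input: their sum equals `nrow(classified)`.
#' @export
sv_tally <- function(classified) {
  tbl <- classified |>
    count(.data$chrom, .data$variant_class, name = "n") |>
    arrange(.data$chrom, .data$variant_class)
  structure(tbl,
            n_total = nrow(classified),
            n_sv = sum(classified$is_sv),
            class = c("class_tally", class(tbl)))
}

#' @method glance class_tally
#' @export
glance.class_tally <- function(x, ...) {
  totals <- as_tibble(x) |>
    group_by(.data$variant_class) |>
    summarise(n = sum(.data$n), .groups = "drop") |>
    tidyr::pivot_wider(names_from = "variant_class", values_from = "n")
  dplyr::bind_cols(
    tibble(n_variants = attr(x, "n_total"), n_sv = attr(x, "n_sv")),
    totals)
}

#' @method tidy class_tally
#' @export
tidy.class_tally <- function(x, ...) as_tibble(x)

#' @export
print.class_tally <- function(x, ...) {
  cat(sprintf("<class_tally> %d variants (%d SVs) across %d chromosomes\n",
              attr(x, "n_total"), attr(x, "n_sv"),
              dplyr::n_distinct(x$chrom)))
  print(as_tibble(x), ...)
  invisible(x)
}

#' @method autoplot class_tally
#' @export
autoplot.class_tally <- function(object, ...) {
  ggplot(as_tibble(object),
         aes(x = .data$chrom, y = .data$n, fill = .data$variant_class)) +
    geom_col() +
    labs(x = "chromosome", y = "variants", fill = "class",
         title = "Variant classes by chromosome") +
    theme_minimal()
}
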