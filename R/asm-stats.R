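#' Scan a FASTA assembly into per-scaffold base counts
#'
#' One row per sequence with its length and counts of G+C, unambiguous
#' A/C/G/T, and N. Counting is case-insensitive; IUPAC ambiguity codes
#' other than N count toward length only. Sequence names are the first
#' whitespace-delimited token of the header.
#'
#' @param file FASTA path (plain or gzip).
#' @return Tibble with columns `name`, `length`, `gc_count`, `acgt_count`,
#'   `n_count`.
#' @export
scan_fasta <- function(file) {
  seqs <- Biostrings::readDNAStringSet(file)
  nm <- sub("\\s.*$", "", names(seqs))
  if (anyDuplicated(nm)) {
    abort(paste0("duplicate sequence name(s): ",
                 paste(unique(nm[duplicated(nm)]), collapse = ", ")))
  }
  if (any(Biostrings::width(seqs) == 0L)) {
    warn("empty sequence(s) present; recorded with length 0")
  }
  if (!length(seqs)) {
    return(tibble(name = character(), length = integer(),
                  gc_count = integer(), acgt_count = integer(),
                  n_count = integer()))
  }
  af <- Biostrings::alphabetFrequency(seqs, baseOnly = FALSE)
  tibble(
    name = nm,
    length = Biostrings::width(seqs),
    gc_count = as.integer(af[, "G"] + af[, "C"]),
    acgt_count = as.integer(af[, "A"] + af[, "C"] + af[, "G"] + af[, "T"]),
    n_count = as.integer(af[, "N"])
  )
}

#' N50 and L50 of a scaffold length set
#'
#' Sorts lengths descending and accumulates until the running sum reaches
#' half of `total`: N50 is the length at the crossing, L50 the number of
#' scaffolds needed. `total` defaults to `sum(lengths)` but may be given
#' externally — e.g. a whole-assembly size when only the chromosome-scale
#' scaffolds are listed and every unlisted scaffold is known to be shorter
#' than the crossing length.
#'
#' @param lengths Non-empty numeric vector of scaffold lengths (bp).
#' @param total Assembly size the half-way point refers to; must be
#'   reachable by the cumulative sum of `lengths`.
#' @return One-row tibble: `n50`, `l50`.
#' @examples
#' nx_stats(c(10, 9, 8, 7, 6), total = 40)  # n50 8, l50 3
#' @export
nx_stats <- function(lengths, total = sum(lengths)) {
  if (!length(lengths)) abort("no scaffold lengths supplied")
  if (total < sum(lengths)) {
    abort("total is smaller than the sum of the supplied lengths")
  }
  sorted <- sort(as.numeric(lengths), decreasing = TRUE)
  cum <- cumsum(sorted)
  cross <- which(cum >= total / 2)
  if (!length(cross)) {
    abort("supplied lengths never reach half of total; N50 undetermined")
  }
  l50 <- cross[1]
  tibble(n50 = sorted[l50], l50 = l50)
}

#' Percent-of-assembly report for scaffold lengths
#'
#' @param scaffolds Data frame with columns `name` and `length`.
#' @param total Assembly size the percentages refer to (default: sum of the
#'   lengths, in which case the percentages sum to 100).
#' @return Tibble `name`, `length`, `percent` with
#'   `percent = 100 * length / total` at full double precision.
#' @export
percent_report <- function(scaffolds, total = sum(scaffolds$length)) {
  if (total <= 0) abort("total must be positive")
  scaffolds |>
    as_tibble() |>
    select("name", "length") |>
    mutate(percent = 100 * .data$length / total)
}

#' Assembly GC content over unambiguous bases
#'
#' `100 * sum(gc_count) / sum(acgt_count)`: N and other ambiguity codes are
#' excluded from both numerator and denominator.
#'
#' @param records Tibble from [scan_fasta()].
#' @return GC percentage (scalar).
#' @export
gc_percent <- function(records) {
  denom <- sum(as.numeric(records$acgt_count))
  if (denom == 0) abort("no unambiguous bases; GC content undefined")
  100 * sum(as.numeric(records$gc_count)) / denom
}

#' Full assembly summary report
#'
#' @param x A FASTA path or a [scan_fasta()] tibble.
#' @return An `assembly_report`: the per-scaffold tibble (`name`, `length`,
#'   `percent`, sorted by length descending) carrying summary attributes;
#'   [glance()] returns `genome_size`, `scaffold_count`, `n50`, `l50`,
#'   `largest`, `gc_percent`.
#' @export
assembly_report <- function(x) {
  records <- if (is.character(x)) scan_fasta(x) else as_tibble(x)
  nx <- nx_stats(records$length)
  per <- percent_report(records) |> arrange(desc(.data$length))
  structure(per,
            genome_size = sum(as.numeric(records$length)),
            scaffold_count = nrow(records),
            n50 = nx$n50, l50 = nx$l50,
            largest = max(records$length),
            gc_percent = if ("gc_count" %in% names(records)) {
              gc_percent(records)
            } else NA_real_,
            class = c("assembly_report", class(per)))
}

#' @method glance assembly_report
#' @export
glance.assembly_report <- function(x, ...) {
  tibble(
    genome_size = attr(x, "genome_size"),
    scaffold_count = attr(x, "scaffold_count"),
    n50 = attr(x, "n50"),
    l50 = attr(x, "l50"),
    largest = attr(x, "largest"),
    gc_percent = attr(x, "gc_percent")
  )
}

#' @method tidy assembly_report
#' @export
tidy.assembly_report <- function(x, ...) as_tibble(x)

#' @export
print.assembly_report <- function(x, ...) {
  g <- glance(x)
  cat(sprintf(
    "<assembly_report> %s bp in %d scaffolds; N50 %s (L50 %d); GC %s%%\n",
    format(g$genome_size, big.mark = ","), g$scaffold_count,
    format(g$n50, big.mark = ","), g$l50,
    ifelse(is.na(g$gc_percent), "?", sprintf("%.2f", g$gc_percent))))
  print(as_tibble(x), ...)
  invisible(x)
}

#' @method autoplot assembly_report
#' @export
autoplot.assembly_report <- function(object, ...) {
  d <- as_tibble(object) |> mutate(rank = row_number())
  ggplot(d, aes(x = .data$rank, y = cumsum(.data$length))) +
    geom_line() + geom_point(size = 0.8) +
    labs(x = "scaffolds (largest first)", y = "cumulative length (bp)",
         title = "Cumulative scaffold length") +
    theme_minimal()
}
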