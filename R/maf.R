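#' Read MAF alignment blocks into a tidy row table
#'
#' Parses Multiple Alignment Format text (such as the output of HAL-to-MAF
#' conversion) into one tibble row per `s` line, grouped by a `block`
#' index. `e`, `i` and `q` lines and `#` comments are skipped. The genome
#' name is the `src` field up to its first `.`; the remainder (which may
#' itself contain dots) is the contig.
#'
#' @param file Path to a MAF file (plain or gzip), or a connection.
#' @return Tibble with columns `block`, `score`, `src`, `genome`, `contig`,
#'   `start`, `size`, `strand`, `src_size`, `text`; attribute `n_blocks`.
#'   Within a block all `text` strings have equal length and each row's
#'   `size` equals its count of non-gap characters (violations are errors
#'   naming the offending line).
#' @export
read_maf <- function(file) {
  lines <- if (inherits(file, "connection")) {
    readLines(file)
  } else {
    con <- if (grepl("\\.gz$", file)) gzfile(file) else base::file(file)
    on.exit(close(con), add = TRUE)
    readLines(con)
  }
  block <- 0L
  in_block <- FALSE
  score <- NA_real_
  rows <- list()
  for (ln in seq_along(lines)) {
    line <- lines[ln]
    if (!nzchar(trimws(line))) { in_block <- FALSE; next }
    first <- substr(trimws(line), 1L, 1L)
    if (first == "#") next
    f <- strsplit(trimws(line), "[ \t]+")[[1]]
    if (f[1] == "a") {
      block <- block + 1L
      in_block <- TRUE
      sc <- f[startsWith(f, "score=")]
      score <- if (length(sc)) as.numeric(sub("^score=", "", sc[1])) else NA_real_
      next
    }
    if (f[1] == "s") {
      if (!in_block) abort(sprintf("line %d: s line outside a block", ln))
      if (length(f) < 7L) abort(sprintf("line %d: malformed s line", ln))
      size <- as.integer(f[4])
      text <- f[7]
      if (str_count(text, "[^-]") != size) {
        abort(sprintf(
          "line %d: s-line size %d disagrees with %d non-gap characters",
          ln, size, str_count(text, "[^-]")))
      }
      start <- as.integer(f[3])
      src_size <- as.integer(f[6])
      if (start + size > src_size) {
        abort(sprintf("line %d: start + size exceeds source length", ln))
      }
      rows[[length(rows) + 1L]] <- tibble(
        block = block, score = score, src = f[2],
        genome = sub("\\..*$", "", f[2]),
        contig = sub("^[^.]*\\.?", "", f[2]),
        start = start, size = size, strand = f[5],
        src_size = src_size, text = text)
      next
    }
    # e, i, q and anything else within a block: tolerated and skipped
  }
  out <- if (length(rows)) bind_rows(rows) else {
    tibble(block = integer(), score = double(), src = character(),
           genome = character(), contig = character(), start = integer(),
           size = integer(), strand = character(), src_size = integer(),
           text = character())
  }
  bad <- out |>
    group_by(.data$block) |>
    summarise(ok = dplyr::n_distinct(nchar(.data$text)) <= 1L,
              .groups = "drop") |>
    filter(!.data$ok)
  if (nrow(bad)) {
    abort(paste0("block(s) with unequal alignment text lengths: ",
                 paste(bad$block, collapse = ", ")))
  }
  attr(out, "n_blocks") <- block
  out
}

#' Drop MAF blocks containing ancestral, synthetic or reference rows
#'
#' A block is excluded iff *any* of its rows belongs to a genome in the
#' exclusion set; surviving blocks pass through unchanged. The default set
#' matches the HAL pipeline's ancestral root, its synthetic graph genome,
#' and the chicken reference assembly.
#'
#' @param blocks Tibble from [read_maf()].
#' @param exclude Non-empty character vector of genome names to exclude
#'   (default `c("Anc0", "MINIGRAPH", "GRCg7b")`).
#' @return The retained rows, with attributes `retained_blocks` and
#'   `excluded_blocks` (`retained + excluded` equals the number of blocks
#'   parsed).
#' @export
filter_nonreference <- function(blocks,
                                exclude = c("Anc0", "MINIGRAPH", "GRCg7b")) {
  if (!length(exclude)) abort("exclusion set must be non-empty")
  excluded_ids <- unique(blocks$block[blocks$genome %in% exclude])
  out <- filter(blocks, !.data$block %in% excluded_ids)
  attr(out, "retained_blocks") <- dplyr::n_distinct(out$block)
  attr(out, "excluded_blocks") <- length(excluded_ids)
  out
}

#' Census non-reference MAF blocks per assembly and by multiplicity
#'
#' Sums each row's ungapped size (the `s`-line `size` field, i.e. sequence
#' bp, not alignment columns) per genome, and counts blocks by the number
#' of *distinct* genomes they contain: a genome with several rows in one
#' block contributes all its rows' bp but counts once toward that block's
#' multiplicity.
#'
#' @param blocks Retained rows from [filter_nonreference()] (or any
#'   [read_maf()] table).
#' @return A `maf_census` with components `per_assembly` (tibble `assembly`,
#'   `bp`), `multiplicity` (tibble `n_assemblies`, `n_blocks`),
#'   `retained_blocks` and `excluded_blocks`.
#' @export
maf_census <- function(blocks) {
  per_assembly <- blocks |>
    group_by(assembly = .data$genome) |>
    summarise(bp = sum(as.numeric(.data$size)), .groups = "drop") |>
    arrange(desc(.data$bp), .data$assembly)
  multiplicity <- blocks |>
    group_by(.data$block) |>
    summarise(n_assemblies = dplyr::n_distinct(.data$genome),
              .groups = "drop") |>
    count(.data$n_assemblies, name = "n_blocks") |>
    arrange(.data$n_assemblies)
  structure(
    list(per_assembly = per_assembly,
         multiplicity = multiplicity,
         retained_blocks = dplyr::n_distinct(blocks$block),
         excluded_blocks = attr(blocks, "excluded_blocks") %||% NA_integer_),
    class = "maf_census")
}

#' @method glance maf_census
#' @export
glance.maf_census <- function(x, ...) {
  tibble(
    n_assemblies = nrow(x$per_assembly),
    total_bp = sum(x$per_assembly$bp),
    retained_blocks = x$retained_blocks,
    excluded_blocks = x$excluded_blocks
  )
}

#' @param x A `maf_census`.
#' @param what `"assembly"` for per-assembly bp totals, `"multiplicity"`
#'   for the block-frequency histogram.
#' @rdname maf_census
#' @method tidy maf_census
#' @export
tidy.maf_census <- function(x, what = c("assembly", "multiplicity"), ...) {
  switch(match.arg(what),
         assembly = x$per_assembly,
         multiplicity = x$multiplicity)
}

#' @export
print.maf_census <- function(x, ...) {
  cat(sprintf("<maf_census> %d assemblies, %s bp over %d retained blocks (%s excluded)\n",
              nrow(x$per_assembly),
              format(sum(x$per_assembly$bp), big.mark = ","),
              x$retained_blocks,
              ifelse(is.na(x$excluded_blocks), "?", x$excluded_blocks)))
  invisible(x)
}

#' @method autoplot maf_census
#' @export
autoplot.maf_census <- function(object, what = c("assembly", "multiplicity"),
                                ...) {
  what <- match.arg(what)
  if (what == "assembly") {
    d <- object$per_assembly
    d$assembly <- factor(d$assembly, levels = rev(d$assembly))
    ggplot(d, aes(x = .data$assembly, y = .data$bp)) +
      geom_col() + scale_y_log10() + coord_flip() +
      labs(x = NULL, y = "non-reference bp (log scale)",
           title = "Non-reference sequence per assembly") +
      theme_minimal()
  } else {
    ggplot(object$multiplicity,
           aes(x = .data$n_assemblies, y = .data$n_blocks)) +
      geom_col() + scale_y_log10() +
      labs(x = "assemblies in block", y = "blocks (log scale)",
           title = "Non-reference block multiplicity") +
      theme_minimal()
  }
}
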