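#' Attribute pangenome sequence to assemblies by greedy novelty
#'
#' Implements the reference-first, largest-remaining-contributor-next
#' accounting of graph sequence. All nodes covered by any path of the
#' reference sample are attributed to the reference and removed from every
#' other sample's covered set; then, repeatedly, the sample whose remaining
#' set holds the most base pairs is selected, its contribution recorded, and
#' its nodes removed from all remaining sets, until every sample has been
#' evaluated. Samples reaching their turn with nothing left are still
#' recorded, at 0 bp. Nodes covered by no path accumulate into
#' `unassigned_bp`.
#'
#' Node sequence is counted once per node regardless of traversal
#' multiplicity or orientation. Ties on remaining bp break lexicographically
#' by sample name, making the ledger deterministic.
#'
#' @param graph A `pangenome_graph` whose paths include the reference sample.
#' @param reference_sample Name of the reference assembly.
#' @return A `contribution_ledger`: tibble with columns `round`, `sample`,
#'   `bp`, `nodes` (reference in round 0, then greedy rounds 1..k), carrying
#'   attributes `reference_sample`, `unassigned_bp` and `total_bp`. The
#'   conservation identity `sum(bp) + unassigned_bp == total_bp` always
#'   holds.
#' @examples
#' seg <- tibble::tibble(id = c("A", "B", "C", "D"),
#'                       sequence = NA_character_,
#'                       length = c(10L, 5L, 3L, 7L))
#' paths <- tibble::tibble(
#'   sample = c("REF", "S1", "S2"), contig = "chr1",
#'   steps = list(tibble::tibble(segment = "A", orient = "+"),
#'                tibble::tibble(segment = c("A", "B", "C"), orient = "+"),
#'                tibble::tibble(segment = c("A", "C", "D"), orient = "+")))
#' g <- pangenome_graph(seg, paths = paths)
#' attribute_novel_sequence(g, "REF")
#' @export
attribute_novel_sequence <- function(graph, reference_sample) {
  stopifnot(inherits(graph, "pangenome_graph"))
  cov <- sample_coverage(graph)
  samples <- unique(cov$sample)
  if (!reference_sample %in% samples) {
    abort(paste0(
      "reference sample '", reference_sample, "' has no path in the graph; ",
      "available samples: ",
      if (length(samples)) paste(samples, collapse = ", ") else "(none)"))
  }
  lens <- segment_lengths(graph)
  total_bp <- sum(graph$segments$length)

  sets <- split(cov$segment, cov$sample)
  ref_nodes <- sets[[reference_sample]]
  entries <- list(tibble(round = 0L, sample = reference_sample,
                         bp = sum(lens[ref_nodes]),
                         nodes = length(ref_nodes)))
  taken <- ref_nodes
  sets[[reference_sample]] <- NULL
  sets <- map(sets, ~ setdiff(.x, taken))

  round_i <- 0L
  pending <- sort(names(sets))
  while (length(pending)) {
    round_i <- round_i + 1L
    remaining_bp <- map_dbl(sets[pending], ~ sum(lens[.x]))
    # which.max on a name-sorted vector gives the lexicographically first
    # maximum, the documented tie-break
    pick <- pending[which.max(remaining_bp)]
    pick_nodes <- sets[[pick]]
    entries[[length(entries) + 1L]] <- tibble(
      round = round_i, sample = pick,
      bp = sum(lens[pick_nodes]), nodes = length(pick_nodes))
    taken <- c(taken, pick_nodes)
    pending <- setdiff(pending, pick)
    sets[pending] <- map(sets[pending], ~ setdiff(.x, pick_nodes))
  }

  ledger <- bind_rows(entries)
  new_contribution_ledger(ledger, reference_sample,
                          unassigned_bp = total_bp - sum(ledger$bp),
                          total_bp = total_bp)
}

new_contribution_ledger <- function(tbl, reference_sample, unassigned_bp,
                                    total_bp) {
  structure(as_tibble(tbl),
            reference_sample = reference_sample,
            unassigned_bp = unassigned_bp,
            total_bp = total_bp,
            class = c("contribution_ledger", class(as_tibble(tbl))))
}

#' Rank-ordered report of a contribution ledger
#'
#' Rows sorted by attributed bp descending, with the reference first
#' regardless of its bp, and a `rank` column. Zero-bp samples are retained.
#'
#' @param ledger A `contribution_ledger`.
#' @return Tibble with columns `rank`, `sample`, `bp`, `nodes`, `round`.
#' @export
ledger_report <- function(ledger) {
  stopifnot(inherits(ledger, "contribution_ledger"))
  ref <- attr(ledger, "reference_sample")
  out <- as_tibble(ledger) |>
    mutate(.is_ref = .data$sample == ref) |>
    arrange(desc(.data$.is_ref), desc(.data$bp), .data$sample) |>
    mutate(rank = row_number()) |>
    select("rank", "sample", "bp", "nodes", "round")
  out
}

#' @method glance contribution_ledger
#' @export
glance.contribution_ledger <- function(x, ...) {
  tibble(
    reference_sample = attr(x, "reference_sample"),
    reference_bp = x$bp[x$round == 0L],
    n_samples = nrow(x),
    novel_bp = sum(x$bp[x$round > 0L]),
    unassigned_bp = attr(x, "unassigned_bp"),
    total_bp = attr(x, "total_bp")
  )
}

#' @method tidy contribution_ledger
#' @export
tidy.contribution_ledger <- function(x, ...) ledger_report(x)

#' @export
print.contribution_ledger <- function(x, ...) {
  cat(sprintf("<contribution_ledger> reference %s; %d samples; %s bp total (%s unassigned)\n",
              attr(x, "reference_sample"), nrow(x),
              format(attr(x, "total_bp"), big.mark = ","),
              format(attr(x, "unassigned_bp"), big.mark = ",")))
  print(as_tibble(x), ...)
  invisible(x)
}

#' @method autoplot contribution_ledger
#' @export
autoplot.contribution_ledger <- function(object, ...) {
  rep <- ledger_report(object)
  rep$sample <- factor(rep$sample, levels = rev(rep$sample))
  ggplot(rep, aes(x = .data$sample, y = pmax(.data$bp, 0.5))) +
    geom_col() +
    scale_y_log10() +
    coord_flip() +
    labs(x = NULL, y = "attributed sequence (bp, log scale)",
         title = "Sequence contributed to the pangenome") +
    theme_minimal()
}
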