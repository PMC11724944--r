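# Shared in-code fixtures and independent oracles.

# four-node toy: REF covers A; S1 covers A,B,C; S2 covers A,C,D
toy_graph <- function() {
  seg <- tibble::tibble(id = c("A", "B", "C", "D"),
                        sequence = NA_character_,
                        length = c(10L, 5L, 3L, 7L))
  steps <- function(ids) tibble::tibble(segment = ids, orient = "+")
  paths <- tibble::tibble(
    sample = c("REF", "S1", "S2"),
    contig = "chr1",
    steps = list(steps("A"), steps(c("A", "B", "C")), steps(c("A", "C", "D"))))
  pangenome_graph(seg, paths = paths)
}

gfa_fixture_lines <- function() {
  c("H\tVN:Z:1.1",
    "S\t1\tACGT",
    "S\t2\tACGTA",
    "S\t3\tACGTAC",
    "L\t1\t+\t2\t+\t0M",
    "L\t2\t+\t3\t+\t0M",
    "P\tREF#0#chr1\t1+,2+,3+\t*")
}

write_text_vcf <- function(records, samples, path = withr::local_tempfile(
                             fileext = ".vcf", .local_envir = parent.frame())) {
  header <- c(
    "##fileformat=VCFv4.2",
    "##FORMAT=<ID=GT,Number=1,Type=String,Description=\"Genotype\">",
    paste(c("#CHROM", "POS", "ID", "REF", "ALT", "QUAL", "FILTER", "INFO",
            "FORMAT", samples), collapse = "\t"))
  writeLines(c(header, records), path)
  path
}

# brute-force N50/L50: test every prefix of the descending-sorted lengths
brute_nx <- function(lengths, total = sum(lengths)) {
  sorted <- sort(lengths, decreasing = TRUE)
  for (k in seq_along(sorted)) {
    if (sum(sorted[seq_len(k)]) >= total / 2) {
      return(list(n50 = sorted[k], l50 = k))
    }
  }
  NULL
}

# attribution under one explicit sample evaluation order (reference always
# first); used to enumerate all orders as a brute-force oracle
attribution_in_order <- function(graph, reference, order) {
  cov <- sample_coverage(graph)
  lens <- stats::setNames(graph$segments$length, graph$segments$id)
  sets <- split(cov$segment, cov$sample)
  taken <- sets[[reference]]
  out <- stats::setNames(numeric(length(order)), order)
  for (s in order) {
    mine <- setdiff(sets[[s]], taken)
    out[[s]] <- sum(lens[mine])
    taken <- union(taken, mine)
  }
  out
}

all_orders <- function(x) {
  if (length(x) <= 1L) return(list(x))
  do.call(c, lapply(seq_along(x), function(i) {
    lapply(all_orders(x[-i]), function(rest) c(x[i], rest))
  }))
}

# bundles shared by the slower end-to-end tests, generated once per run
.bundle_cache <- new.env(parent = emptyenv())
cached_bundle <- function(seed, params = sim_params(seed = seed)) {
  key <- paste0("s", seed)
  if (is.null(.bundle_cache[[key]])) {
    .bundle_cache[[key]] <-
      generate_pangenome(params, file.path(tempdir(), "bundles", key))
  }
  .bundle_cache[[key]]
}
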