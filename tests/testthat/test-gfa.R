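test_that("an empty stream yields an empty graph", {
  g <- read_gfa(textConnection(character()))
  expect_equal(nrow(g$segments), 0)
  expect_equal(nrow(g$links), 0)
  expect_equal(nrow(g$paths), 0)
  expect_warning(s <- graph_stats(g), "no nodes")
  expect_equal(unlist(s[, c("node_count", "edge_count", "total_length",
                            "mean_degree")], use.names = FALSE),
               c(0, 0, 0, 0))
})

test_that("S/L/P records and PanSN path names parse into the expected graph", {
  g <- read_gfa(textConnection(gfa_fixture_lines()))
  s <- graph_stats(g)
  expect_equal(s$node_count, 3)
  expect_equal(s$edge_count, 2)
  expect_equal(s$total_length, 15)
  expect_equal(round(s$mean_degree, 3), 0.667)
  expect_equal(s$sample_count, 1)
  expect_equal(g$paths$sample, "REF")
  expect_equal(g$paths$haplotype, "0")
  expect_equal(g$paths$contig, "chr1")
  expect_equal(g$paths$steps[[1]]$segment, c("1", "2", "3"))
})

test_that("W-line walks carry sample, haplotype, contig and orientations", {
  lines <- c("S\t1\tAAAA", "S\t2\tCCCCC", "S\t3\tGGGGGG",
             "W\tS1\t0\tchr1\t0\t15\t>1>2<3")
  g <- read_gfa(textConnection(lines))
  p <- g$paths
  expect_equal(p$sample, "S1")
  expect_equal(p$haplotype, "0")
  expect_equal(p$contig, "chr1")
  expect_equal(p$line_type, "W")
  expect_equal(p$steps[[1]]$segment, c("1", "2", "3"))
  expect_equal(p$steps[[1]]$orient, c("+", "+", "-"))
})

test_that("path-name fallbacks cover PanSN, dotted and bare names", {
  nm <- parse_pansn(c("S1#0#chr1", "GRCg6a.chr2", "plain"))
  expect_equal(nm$sample, c("S1", "GRCg6a", "plain"))
  expect_equal(nm$contig, c("chr1", "chr2", NA))
})

test_that("malformed or inconsistent records are rejected with context", {
  # sequence-less segment without an LN tag
  expect_error(read_gfa(textConnection(c("S\t1\t*"))), "LN:i")
  # path step referencing an unknown segment
  expect_error(
    read_gfa(textConnection(c("S\t1\tACGT", "P\tX#0#c\t1+,9+\t*"))),
    "unknown segment")
  # link endpoint referencing an unknown segment
  expect_error(
    read_gfa(textConnection(c("S\t1\tACGT", "L\t1\t+\t9\t+\t0M"))),
    "unknown segment")
  expect_error(
    read_gfa(textConnection(c("S\t1\tACGT", "S\t1\tTT"))), "duplicate")
})

test_that("segments may precede or follow the records that use them", {
  shuffled <- c("P\tREF#0#chr1\t1+,2+\t*", "L\t1\t+\t2\t+\t0M",
                "S\t2\tCC", "S\t1\tAAA")
  g <- read_gfa(textConnection(shuffled))
  expect_equal(graph_stats(g)$total_length, 5)
})

test_that("unknown record types are skipped and reported, not fatal", {
  lines <- c("S\t1\tACGT", "X\tcustom\tstuff", "J\tmore")
  expect_message(g <- read_gfa(textConnection(lines)), "skipped record types")
  expect_equal(nrow(g$segments), 1)
})

test_that("sequence-less segments take their length from LN tags", {
  g <- read_gfa(textConnection(c("S\t1\t*\tLN:i:42", "S\t2\tACGT")))
  expect_equal(sum(g$segments$length), 46)
})

test_that("coverage is a deduplicated per-sample node set", {
  expect_equal(nrow(sample_coverage(pangenome_graph(
    tibble::tibble(id = "A", sequence = "AA", length = 2L)))), 0)

  cov <- sample_coverage(toy_graph())
  sets <- split(cov$segment, cov$sample)
  expect_equal(sort(sets$REF), "A")
  expect_equal(sort(sets$S1), c("A", "B", "C"))
  expect_equal(sort(sets$S2), c("A", "C", "D"))

  # a node traversed twice (forward then reverse) counts once
  g2 <- pangenome_graph(
    tibble::tibble(id = "A", sequence = "AAAA", length = 4L),
    paths = tibble::tibble(
      sample = "S1", contig = "c",
      steps = list(tibble::tibble(segment = c("A", "A"),
                                  orient = c("+", "-")))))
  expect_equal(nrow(sample_coverage(g2)), 1)
})

test_that("write/parse round-trips synthetic graphs, preserving the W dialect", {
  for (seed in 1:5) {
    b <- cached_bundle(seed)
    g <- read_gfa(b$gfa)
    f <- withr::local_tempfile(fileext = ".gfa")
    write_gfa(g, f)
    g2 <- read_gfa(f)
    expect_equal(dplyr::arrange(g$segments, id),
                 dplyr::arrange(g2$segments, id))
    expect_equal(dplyr::arrange(g$links, from_id, to_id),
                 dplyr::arrange(g2$links, from_id, to_id))
    expect_equal(g$paths$line_type, g2$paths$line_type)
    expect_equal(g$paths$sample, g2$paths$sample)
    expect_equal(g$paths$steps, g2$paths$steps)
    expect_equal(graph_stats(g), graph_stats(g2))
  }
})

test_that("graph statistics on generator output equal the planted counts", {
  b <- cached_bundle(3)
  s <- graph_stats(read_gfa(b$gfa))
  expect_equal(s$node_count, b$truth$graph_counts$nodes)
  expect_equal(s$edge_count, b$truth$graph_counts$edges)
  expect_equal(s$total_length, b$truth$graph_counts$total_bp)
})
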