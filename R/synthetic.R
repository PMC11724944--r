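#' Parameters for the synthetic pangenome generator
#'
#' Describes a miniature pangenome with the statistical structure the
#' accounting pipeline assumes: a reference core shared by all assemblies,
#' sample-private insertions (novel sequence), shared insertion/deletion
#' bubbles with random carrier subsets, and SNVs. Default lengths straddle
#' the 50 bp structural-variant and 1 kb insertion/deletion thresholds so
#' every variant class is exercised.
#'
#' @param n_samples Number of assemblies including the reference (>= 1).
#' @param reference_name Name of the reference assembly.
#' @param core_length Total bp of the shared reference core.
#' @param core_segment_count Number of backbone segments the core is split
#'   into; variants occupy junctions between consecutive core segments, so
#'   at most `core_segment_count - 1` variants fit.
#' @param unique_insertions_per_sample Sample-private insertions per
#'   non-reference sample.
#' @param unique_insertion_len Length range (min, max bp) of private
#'   insertions.
#' @param shared_variant_count Number of shared insertion bubbles.
#' @param carrier_fraction Expected fraction of non-reference samples
#'   carrying each shared variant (at least one carrier is always drawn).
#' @param deletion_count Number of deletion bubbles (carriers skip a
#'   reference segment).
#' @param deletion_len Length range (min, max bp) of deletions.
#' @param snv_count Number of single-nucleotide variants.
#' @param seed Integer seed; identical parameters and seed give
#'   byte-identical output files.
#' @return A `sim_params` list.
#' @export
sim_params <- function(n_samples = 5,
                       reference_name = "REF",
                       core_length = 6000,
                       core_segment_count = 40,
                       unique_insertions_per_sample = 2,
                       unique_insertion_len = c(40, 1500),
                       shared_variant_count = 4,
                       carrier_fraction = 0.5,
                       deletion_count = 3,
                       deletion_len = c(30, 1200),
                       snv_count = 5,
                       seed = 1L) {
  p <- list(n_samples = as.integer(n_samples),
            reference_name = reference_name,
            core_length = as.integer(core_length),
            core_segment_count = as.integer(core_segment_count),
            unique_insertions_per_sample =
              as.integer(unique_insertions_per_sample),
            unique_insertion_len = as.integer(unique_insertion_len),
            shared_variant_count = as.integer(shared_variant_count),
            carrier_fraction = carrier_fraction,
            deletion_count = as.integer(deletion_count),
            deletion_len = as.integer(deletion_len),
            snv_count = as.integer(snv_count),
            seed = as.integer(seed))
  validate_sim_params(p)
  structure(p, class = "sim_params")
}

validate_sim_params <- function(p) {
  if (p$n_samples < 1L) abort("n_samples must be >= 1")
  counts <- c(p$unique_insertions_per_sample, p$shared_variant_count,
              p$deletion_count, p$snv_count)
  if (any(counts < 0L)) abort("variant counts must be non-negative")
  for (rng in list(p$unique_insertion_len, p$deletion_len)) {
    if (length(rng) != 2L || rng[1] < 1L || rng[1] > rng[2]) {
      abort("length ranges must satisfy 1 <= min <= max")
    }
  }
  n_nonref <- p$n_samples - 1L
  n_var <- p$snv_count + p$deletion_count + p$shared_variant_count +
    p$unique_insertions_per_sample * n_nonref
  if (n_var > 0L && n_nonref == 0L) {
    abort("variants require at least one non-reference sample")
  }
  if (n_var > p$core_segment_count - 1L) {
    abort(sprintf(
      "%d variants cannot be placed in %d junctions; increase core_segment_count",
      n_var, p$core_segment_count - 1L))
  }
  if (p$core_segment_count > p$core_length) {
    abort("core_length must be at least core_segment_count")
  }
  invisible(p)
}

random_dna <- function(n) {
  paste(sample(c("A", "C", "G", "T"), n, replace = TRUE), collapse = "")
}

draw_carriers <- function(samples, fraction) {
  k <- max(1L, stats::rbinom(1L, length(samples), fraction))
  sort(sample(samples, k))
}

# expected class/SV flag from the planted length change, by plain threshold
# arithmetic (independent of classify_allele's trimming logic)
planted_class <- function(type, len) {
  switch(type,
         snv = list(class = "snv", is_sv = FALSE),
         del = list(class = if (len < 1000L) "indel" else "deletion",
                    is_sv = len >= 50L),
         list(class = if (len < 1000L) "indel" else "insertion",
              is_sv = len >= 50L))
}

#' Generate a ground-truthed synthetic pangenome bundle
#'
#' Builds the plan (core segments, variant bubbles, carrier sets) from the
#' seeded RNG, then emits every file format the accounting pipeline
#' consumes, all spelling out the *same* planted pangenome:
#' * `graph.gfa` — the graph, reference path as a PanSN-named `P` line and
#'   sample paths as `W` lines;
#' * `ref.fa` and `samples/<S>.fa` — each assembly's sequence, obtained by
#'   walking its path;
#' * `variants.vcf` — the planted variants as a multi-sample VCF
#'   (anchor-base convention for indels, haploid genotypes);
#' * `aln.maf` — one alignment block per novel (alternate) sequence with a
#'   row per carrier, plus decoy blocks containing ancestral (`Anc0`),
#'   synthetic (`MINIGRAPH`) and reference rows that the exclusion filter
#'   must drop;
#' * `truth.json` — the expected values (graph counts, contribution
#'   ledger computed from the plan, per-variant classes, MAF census).
#'
#' @param params A [sim_params()].
#' @param dir Output directory (created if needed).
#' @return A `pangenome_bundle`: list with `dir`, file paths, `params` and
#'   `truth` (list of tibbles/values; see [verify_bundle()]).
#' @export
generate_pangenome <- function(params, dir) {
  stopifnot(inherits(params, "sim_params"))
  set.seed(params$seed)
  dir.create(file.path(dir, "samples"), recursive = TRUE,
             showWarnings = FALSE)
  n_nonref <- params$n_samples - 1L
  samples <- if (n_nonref > 0L) sprintf("S%d", seq_len(n_nonref)) else character()
  ref <- params$reference_name

  ## ---- plan: core backbone ----
  k <- params$core_segment_count
  base_len <- params$core_length %/% k
  core_len <- rep(base_len, k)
  extra <- params$core_length - base_len * k
  if (extra > 0L) core_len[seq_len(extra)] <- core_len[seq_len(extra)] + 1L
  core <- tibble(id = sprintf("c%d", seq_len(k)),
                 seq = map_chr(core_len, random_dna),
                 len = core_len)

  ## ---- plan: variants at distinct junctions ----
  specs <- list()
  add <- function(type, len, carriers) {
    specs[[length(specs) + 1L]] <<- list(type = type, len = len,
                                         carriers = carriers)
  }
  for (i in seq_len(params$snv_count)) {
    add("snv", 1L, draw_carriers(samples, params$carrier_fraction))
  }
  for (i in seq_len(params$deletion_count)) {
    add("del", sample(params$deletion_len[1]:params$deletion_len[2], 1L),
        draw_carriers(samples, params$carrier_fraction))
  }
  for (i in seq_len(params$shared_variant_count)) {
    add("ins",
        sample(params$unique_insertion_len[1]:params$unique_insertion_len[2],
               1L),
        draw_carriers(samples, params$carrier_fraction))
  }
  for (s in samples) {
    for (i in seq_len(params$unique_insertions_per_sample)) {
      add("unique_ins",
          sample(params$unique_insertion_len[1]:params$unique_insertion_len[2],
                 1L),
          s)
    }
  }
  n_var <- length(specs)
  junctions <- if (n_var > 0L) sort(sample(seq_len(k - 1L), n_var)) else integer()

  plan <- if (n_var > 0L) {
    # specs are assigned to sorted junctions in a shuffled order so variant
    # types are interleaved along the genome
    ord <- sample.int(n_var)
    bind_rows(map(seq_len(n_var), function(j) {
      sp <- specs[[ord[j]]]
      ref_seq <- alt_seq <- NA_character_
      if (sp$type == "snv") {
        ref_seq <- random_dna(1L)
        alt_seq <- sample(setdiff(c("A", "C", "G", "T"), ref_seq), 1L)
      } else if (sp$type == "del") {
        ref_seq <- random_dna(sp$len)
      } else {
        alt_seq <- random_dna(sp$len)
      }
      tibble(var = j, junction = junctions[j], type = sp$type, len = sp$len,
             ref_seq = ref_seq, alt_seq = alt_seq,
             ref_seg = if (!is.na(ref_seq)) sprintf("r%d", j) else NA_character_,
             alt_seg = if (!is.na(alt_seq)) sprintf("a%d", j) else NA_character_,
             carriers = list(sp$carriers))
    }))
  } else {
    tibble(var = integer(), junction = integer(), type = character(),
           len = integer(), ref_seq = character(), alt_seq = character(),
           ref_seg = character(), alt_seg = character(), carriers = list())
  }

  ## ---- segments table ----
  segments <- bind_rows(
    tibble(id = core$id, sequence = core$seq, length = core$len),
    if (n_var > 0L) {
      p_r <- plan[!is.na(plan$ref_seg), ]
      tibble(id = p_r$ref_seg, sequence = p_r$ref_seq,
             length = nchar(p_r$ref_seq))
    },
    if (n_var > 0L) {
      p_a <- plan[!is.na(plan$alt_seg), ]
      tibble(id = p_a$alt_seg, sequence = p_a$alt_seq,
             length = nchar(p_a$alt_seq))
    }
  )
  seq_of <- stats::setNames(segments$sequence, segments$id)
  len_of <- stats::setNames(segments$length, segments$id)

  ## ---- paths: one contig per assembly ----
  plan_by_junction <- split(plan, plan$junction)
  walk_of <- function(who) {
    steps <- character()
    for (j in seq_len(k)) {
      steps <- c(steps, core$id[j])
      pj <- plan_by_junction[[as.character(j)]]
      if (!is.null(pj)) {
        v <- pj[1, ]
        is_carrier <- !identical(who, ref) && who %in% v$carriers[[1]]
        if (is_carrier) {
          if (!is.na(v$alt_seg)) steps <- c(steps, v$alt_seg)
        } else if (!is.na(v$ref_seg)) {
          steps <- c(steps, v$ref_seg)
        }
      }
    }
    steps
  }
  walks <- stats::setNames(map(c(ref, samples), walk_of), c(ref, samples))

  ## ---- GFA ----
  edge_pairs <- distinct(bind_rows(map(walks, function(w) {
    if (length(w) < 2L) return(NULL)
    tibble(from_id = w[-length(w)], to_id = w[-1])
  })))
  paths_tbl <- bind_rows(
    tibble(sample = ref, haplotype = "0", contig = "chr1", line_type = "P",
           name = paste0(ref, "#0#chr1"),
           w_start = NA_integer_, w_end = NA_integer_,
           steps = list(tibble(segment = walks[[ref]], orient = "+"))),
    bind_rows(map(samples, function(s) {
      w <- walks[[s]]
      tibble(sample = s, haplotype = "0", contig = "chr1", line_type = "W",
             name = NA_character_, w_start = 0L,
             w_end = as.integer(sum(len_of[w])),
             steps = list(tibble(segment = w, orient = "+")))
    }))
  )
  graph <- pangenome_graph(segments,
                           links = mutate(edge_pairs, from_orient = "+",
                                          to_orient = "+", overlap = "*"),
                           paths = paths_tbl)
  gfa_path <- file.path(dir, "graph.gfa")
  write_gfa(graph, gfa_path)

  ## ---- FASTA ----
  genome_seq <- map_chr(walks, ~ paste(seq_of[.x], collapse = ""))
  write_fasta_one <- function(path, name, seq) {
    writeLines(c(paste0(">", name),
                 substring(seq, seq(1, nchar(seq), 70),
                           pmin(seq(1, nchar(seq), 70) + 69, nchar(seq)))),
               path)
  }
  ref_fa <- file.path(dir, "ref.fa")
  write_fasta_one(ref_fa, "chr1", genome_seq[[ref]])
  sample_fa <- map_chr(samples, function(s) {
    p <- file.path(dir, "samples", paste0(s, ".fa"))
    write_fasta_one(p, "chr1", genome_seq[[s]])
    p
  })

  ## ---- coordinates: 0-based offset of each segment in each walk ----
  offsets <- map(walks, function(w) {
    lens <- as.numeric(len_of[w])
    stats::setNames(cumsum(c(0, lens[-length(lens)])), w)
  })

  ## ---- VCF (reference coordinates, anchor-base convention) ----
  vcf_rows <- if (n_var > 0L) {
    bind_rows(pmap(plan, function(var, junction, type, len, ref_seq, alt_seq,
                                  ref_seg, alt_seg, carriers) {
      ref_off <- offsets[[ref]]
      if (type == "snv") {
        pos <- ref_off[[ref_seg]] + 1
        vref <- ref_seq
        valt <- alt_seq
      } else {
        anchor_seg <- core$id[junction]
        anchor_base <- substr(seq_of[[anchor_seg]], len_of[[anchor_seg]],
                              len_of[[anchor_seg]])
        pos <- ref_off[[anchor_seg]] + len_of[[anchor_seg]]
        if (type == "del") {
          vref <- paste0(anchor_base, ref_seq)
          valt <- anchor_base
        } else {
          vref <- anchor_base
          valt <- paste0(anchor_base, alt_seq)
        }
      }
      tibble(pos = pos, id = sprintf("v%d", var), ref = vref, alt = valt,
             carriers = list(carriers))
    }))
  } else {
    tibble(pos = double(), id = character(), ref = character(),
           alt = character(), carriers = list())
  }
  vcf_rows <- arrange(vcf_rows, .data$pos)
  vcf_path <- file.path(dir, "variants.vcf")
  gts <- map(vcf_rows$carriers, function(cs) {
    ifelse(samples %in% cs, "1", "0")
  })
  header <- c(
    "##fileformat=VCFv4.2",
    sprintf("##contig=<ID=chr1,length=%d>", nchar(genome_seq[[ref]])),
    "##FORMAT=<ID=GT,Number=1,Type=String,Description=\"Genotype\">",
    paste(c("#CHROM", "POS", "ID", "REF", "ALT", "QUAL", "FILTER", "INFO",
            "FORMAT", samples), collapse = "\t"))
  body <- if (nrow(vcf_rows)) {
    vapply(seq_len(nrow(vcf_rows)), function(i) {
      paste(c("chr1", format(vcf_rows$pos[i], scientific = FALSE),
              vcf_rows$id[i], vcf_rows$ref[i], vcf_rows$alt[i],
              ".", "PASS", ".", "GT", gts[[i]]), collapse = "\t")
    }, character(1))
  } else character()
  writeLines(c(header, body), vcf_path)

  ## ---- MAF: one retained block per novel sequence + decoy blocks ----
  maf_lines <- c("##maf version=1")
  maf_row <- function(genome, contig, start, size, src_size, text) {
    sprintf("s %s.%s %d %d + %d %s", genome, contig, start, size, src_size,
            text)
  }
  novel <- plan[!is.na(plan$alt_seg) & plan$type != "snv", ]
  retained_truth <- list()
  if (nrow(novel)) {
    for (i in seq_len(nrow(novel))) {
      v <- novel[i, ]
      cs <- v$carriers[[1]]
      maf_lines <- c(maf_lines, "", "a score=0")
      for (s in cs) {
        maf_lines <- c(maf_lines, maf_row(
          s, "chr1", as.integer(offsets[[s]][[v$alt_seg]]), v$len,
          nchar(genome_seq[[s]]), v$alt_seq))
      }
      retained_truth[[length(retained_truth) + 1L]] <-
        tibble(assembly = cs, bp = v$len, multiplicity = length(cs))
    }
  }
  # decoys: always emitted so the exclusion filter is exercised
  decoy_seq <- core$seq[1]
  decoy_carrier <- if (length(samples)) samples[1] else ref
  maf_lines <- c(
    maf_lines, "", "a score=0",
    maf_row("Anc0", "refChr0", 0L, core$len[1], core$len[1], decoy_seq),
    maf_row("MINIGRAPH", "s1", 0L, core$len[1], core$len[1], decoy_seq),
    maf_row(decoy_carrier, "chr1",
            as.integer(offsets[[decoy_carrier]][["c1"]]), core$len[1],
            nchar(genome_seq[[decoy_carrier]]), decoy_seq),
    "", "a score=0",
    maf_row(ref, "chr1", 0L, core$len[1], nchar(genome_seq[[ref]]),
            decoy_seq),
    maf_row(decoy_carrier, "chr1",
            as.integer(offsets[[decoy_carrier]][["c1"]]), core$len[1],
            nchar(genome_seq[[decoy_carrier]]), decoy_seq))
  n_excluded <- 2L
  maf_path <- file.path(dir, "aln.maf")
  writeLines(maf_lines, maf_path)

  ## ---- truth ----
  ref_nodes <- c(core$id, plan$ref_seg[!is.na(plan$ref_seg)])
  truth_ledger <- plan_greedy_ledger(plan, samples, ref,
                                     reference_bp = sum(len_of[ref_nodes]),
                                     ref_node_count = length(ref_nodes))
  retained_tbl <- bind_rows(retained_truth)
  maf_truth <- list(
    per_assembly = if (nrow(retained_tbl)) {
      retained_tbl |>
        group_by(.data$assembly) |>
        summarise(bp = sum(as.numeric(.data$bp)), .groups = "drop") |>
        arrange(desc(.data$bp), .data$assembly)
    } else tibble(assembly = character(), bp = double()),
    multiplicity = if (nrow(novel)) {
      # one histogram entry per retained block, keyed by distinct carriers
      tibble(multiplicity = map_int(novel$carriers, length)) |>
        count(n_assemblies = .data$multiplicity, name = "n_blocks") |>
        arrange(.data$n_assemblies)
    } else tibble(n_assemblies = integer(), n_blocks = integer()),
    retained_blocks = nrow(novel),
    excluded_blocks = n_excluded
  )

  planted_variants <- if (n_var > 0L) {
    cls <- map(seq_len(nrow(plan)), ~ planted_class(plan$type[.x],
                                                    plan$len[.x]))
    vr <- arrange(
      mutate(vcf_rows,
             type = plan$type[match(.data$id, sprintf("v%d", plan$var))],
             len = plan$len[match(.data$id, sprintf("v%d", plan$var))]),
      .data$pos)
    mutate(vr,
           expected_class = map_chr(seq_len(nrow(vr)), function(i) {
             planted_class(vr$type[i], vr$len[i])$class
           }),
           expected_is_sv = map_lgl(seq_len(nrow(vr)), function(i) {
             planted_class(vr$type[i], vr$len[i])$is_sv
           }),
           chrom = "chr1") |>
      select("chrom", "pos", "id", "ref", "alt", "type", "len",
             "carriers", "expected_class", "expected_is_sv")
  } else {
    tibble(chrom = character(), pos = double(), id = character(),
           ref = character(), alt = character(), type = character(),
           len = integer(), carriers = list(),
           expected_class = character(), expected_is_sv = logical())
  }

  truth <- list(
    graph_counts = list(nodes = nrow(segments),
                        edges = nrow(edge_pairs),
                        total_bp = sum(segments$length)),
    reference_bp = sum(len_of[ref_nodes]),
    per_sample_unique_bp = if (length(samples)) {
      uniq <- plan[plan$type == "unique_ins", ]
      stats::setNames(
        map_dbl(samples,
                ~ sum(uniq$len[map_chr(uniq$carriers, 1) == .x])),
        samples)
    } else stats::setNames(numeric(), character()),
    expected_ledger = truth_ledger,
    planted_variants = planted_variants,
    maf_truth = maf_truth
  )
  truth_path <- file.path(dir, "truth.json")
  jsonlite::write_json(truth, truth_path, auto_unbox = TRUE, digits = NA,
                       pretty = TRUE)

  structure(list(dir = dir, gfa = gfa_path, ref_fasta = ref_fa,
                 sample_fastas = sample_fa, vcf = vcf_path, maf = maf_path,
                 truth_json = truth_path, params = params, truth = truth),
            class = "pangenome_bundle")
}

# greedy attribution computed directly from the plan (variant -> carriers),
# never from the emitted files: the independent route verify() compares
# against the graph pipeline
plan_greedy_ledger <- function(plan, samples, ref, reference_bp,
                               ref_node_count) {
  alt <- plan[!is.na(plan$alt_seg), ]
  remaining <- stats::setNames(map(samples, function(s) {
    alt$alt_seg[map_lgl(alt$carriers, ~ s %in% .x)]
  }), samples)
  lens <- stats::setNames(alt$len, alt$alt_seg)
  entries <- list(tibble(round = 0L, sample = ref, bp = reference_bp,
                         nodes = ref_node_count))
  pending <- sort(samples)
  r <- 0L
  while (length(pending)) {
    r <- r + 1L
    bps <- map_dbl(remaining[pending], ~ sum(lens[.x]))
    pick <- pending[which.max(bps)]
    picked <- remaining[[pick]]
    entries[[length(entries) + 1L]] <-
      tibble(round = r, sample = pick, bp = sum(lens[picked]),
             nodes = length(picked))
    pending <- setdiff(pending, pick)
    remaining[pending] <- map(remaining[pending], ~ setdiff(.x, picked))
  }
  bind_rows(entries)
}

#' Re-run every pipeline stage on a generated bundle and compare to truth
#'
#' Reads the emitted GFA/VCF/MAF files back through the package's own
#' parsers and analyses, and checks each result against the bundle's
#' planted truth: graph node/edge/length counts, the contribution ledger,
#' per-sample variant class tallies, and the non-reference MAF census.
#'
#' @param bundle A `pangenome_bundle` from [generate_pangenome()].
#' @return Tibble with columns `component`, `check`, `ok`, `detail`;
#'   attribute `pass` is `TRUE` iff every row is ok.
#' @export
verify_bundle <- function(bundle) {
  stopifnot(inherits(bundle, "pangenome_bundle"))
  truth <- bundle$truth
  params <- bundle$params
  rows <- list()
  note <- function(component, check, ok, detail = "") {
    rows[[length(rows) + 1L]] <<- tibble(component = component,
                                         check = check, ok = ok,
                                         detail = detail)
  }

  g <- read_gfa(bundle$gfa)
  gs <- graph_stats(g)
  note("gfa_graph", "node count", gs$node_count == truth$graph_counts$nodes,
       sprintf("%d vs %d", gs$node_count, truth$graph_counts$nodes))
  note("gfa_graph", "edge count", gs$edge_count == truth$graph_counts$edges,
       sprintf("%d vs %d", gs$edge_count, truth$graph_counts$edges))
  note("gfa_graph", "total length",
       gs$total_length == truth$graph_counts$total_bp,
       sprintf("%d vs %d", gs$total_length, truth$graph_counts$total_bp))

  ledger <- attribute_novel_sequence(g, params$reference_name)
  exp_ledger <- as_tibble(truth$expected_ledger)
  got <- as_tibble(ledger)[, c("round", "sample", "bp", "nodes")]
  note("contribution", "ledger equals plan-derived greedy ledger",
       isTRUE(all.equal(as.data.frame(got),
                        as.data.frame(exp_ledger[, names(got)]),
                        check.attributes = FALSE)),
       "")
  note("contribution", "conservation",
       sum(ledger$bp) + attr(ledger, "unassigned_bp") ==
         attr(ledger, "total_bp"), "")

  pv <- truth$planted_variants
  samples <- setdiff(
    if (params$n_samples > 1L) sprintf("S%d", seq_len(params$n_samples - 1L))
    else character(), character())
  count_by_class <- function(x) {
    t <- table(x)
    stats::setNames(as.integer(t), names(t))[sort(names(t))]
  }
  sv_ok <- TRUE
  sv_detail <- character()
  for (s in samples) {
    got_cls <- sv_classify_sample(bundle$vcf, s)
    exp_idx <- map_lgl(pv$carriers, ~ s %in% .x)
    if (!identical(count_by_class(pv$expected_class[exp_idx]),
                   count_by_class(got_cls$variant_class))) {
      sv_ok <- FALSE
      sv_detail <- c(sv_detail, s)
    }
  }
  note("sv_classify", "per-sample class tallies equal planted truth",
       sv_ok, paste(sv_detail, collapse = ","))

  maf <- read_maf(bundle$maf)
  kept <- filter_nonreference(
    maf, exclude = c("Anc0", "MINIGRAPH", params$reference_name))
  cen <- maf_census(kept)
  mt <- truth$maf_truth
  note("maf_census", "per-assembly bp equals planted truth",
       isTRUE(all.equal(as.data.frame(cen$per_assembly),
                        as.data.frame(as_tibble(mt$per_assembly)),
                        check.attributes = FALSE)), "")
  note("maf_census", "multiplicity histogram equals planted truth",
       isTRUE(all.equal(as.data.frame(cen$multiplicity),
                        as.data.frame(as_tibble(mt$multiplicity)),
                        check.attributes = FALSE)), "")
  note("maf_census", "retained/excluded block counts",
       cen$retained_blocks == mt$retained_blocks &&
         cen$excluded_blocks == mt$excluded_blocks, "")

  out <- bind_rows(rows)
  attr(out, "pass") <- all(out$ok)
  out
}
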