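#' Read a path-covered pangenome graph from GFA v1.1
#'
#' Parses `S` (segment), `L` (link), `P` (path) and `W` (walk) records into a
#' `pangenome_graph` object: a list of three tibbles (`segments`, `links`,
#' `paths`). `H` header lines are tolerated; any other record type is skipped
#' and reported to standard error with per-type counts. Record order carries
#' no meaning: segments may appear after the links and paths that use them.
#'
#' Path membership follows the conventions of graph-building pipelines:
#' `W` lines carry the sample name in their own field; `P` line names are
#' interpreted as PanSN `sample#haplotype#contig`, falling back to splitting
#' on the first `.` and finally to the whole name when no separator exists.
#'
#' @param file Path to a GFA file (plain or gzip-compressed), or a connection.
#' @return A `pangenome_graph`: list with tibbles `segments`
#'   (`id`, `sequence`, `length`), `links` (`from_id`, `from_orient`, `to_id`,
#'   `to_orient`, `overlap`) and `paths` (`sample`, `haplotype`, `contig`,
#'   `line_type`, `name`, `steps` list-column of tibbles with `segment`,
#'   `orient`).
#' @examples
#' gfa <- c("H\tVN:Z:1.1", "S\t1\tACGT", "S\t2\tTT",
#'          "L\t1\t+\t2\t+\t0M", "P\tS1#0#chr1\t1+,2+\t*")
#' g <- read_gfa(textConnection(gfa))
#' glance(g)
#' @seealso [graph_stats()], [sample_coverage()], [write_gfa()]
#' @export
read_gfa <- function(file) {
  lines <- if (inherits(file, "connection")) {
    readLines(file)
  } else {
    con <- if (grepl("\\.gz$", file)) gzfile(file) else base::file(file)
    on.exit(close(con), add = TRUE)
    readLines(con)
  }
  parse_gfa_lines(lines)
}

parse_gfa_lines <- function(lines) {
  lines <- lines[nzchar(lines)]
  rectype <- substr(lines, 1L, 1L)
  lineno <- seq_along(lines)

  known <- c("H", "S", "L", "P", "W")
  skipped <- table(rectype[!rectype %in% known])
  if (length(skipped)) {
    inform(paste0(
      "read_gfa: skipped record types: ",
      paste(sprintf("%s (%d)", names(skipped), as.integer(skipped)),
            collapse = ", ")
    ))
  }

  fields <- strsplit(lines, "\t", fixed = TRUE)

  segments <- parse_s_lines(fields[rectype == "S"], lineno[rectype == "S"])
  links <- parse_l_lines(fields[rectype == "L"], lineno[rectype == "L"])
  paths <- bind_rows(
    parse_p_lines(fields[rectype == "P"], lineno[rectype == "P"]),
    parse_w_lines(fields[rectype == "W"], lineno[rectype == "W"])
  )
  if (nrow(paths) == 0L) paths <- empty_paths_tbl()

  g <- new_pangenome_graph(segments, links, paths)
  validate_pangenome_graph(g)
  g
}

empty_paths_tbl <- function() {
  tibble(sample = character(), haplotype = character(), contig = character(),
         line_type = character(), name = character(),
         w_start = integer(), w_end = integer(), steps = list())
}

parse_s_lines <- function(fields, lineno) {
  if (!length(fields)) {
    return(tibble(id = character(), sequence = character(),
                  length = integer()))
  }
  rows <- map2(fields, lineno, function(f, ln) {
    if (length(f) < 3L) {
      abort(sprintf("malformed S line at line %d: expected id and sequence",
                    ln))
    }
    id <- f[2]
    seq <- f[3]
    if (seq == "*") {
      tags <- f[-(1:3)]
      lntag <- tags[startsWith(tags, "LN:i:")]
      if (!length(lntag)) {
        abort(sprintf(
          "malformed S line at line %d: segment '%s' has no sequence and no LN:i tag",
          ln, id))
      }
      len <- suppressWarnings(as.integer(sub("^LN:i:", "", lntag[1])))
      if (is.na(len) || len <= 0L) {
        abort(sprintf("malformed S line at line %d: invalid LN:i tag", ln))
      }
      list(id = id, sequence = NA_character_, length = len)
    } else {
      list(id = id, sequence = seq, length = nchar(seq))
    }
  })
  out <- bind_rows(rows)
  dup <- out$id[duplicated(out$id)]
  if (length(dup)) {
    abort(paste0("duplicate segment id(s): ",
                 paste(unique(dup), collapse = ", ")))
  }
  out
}

parse_l_lines <- function(fields, lineno) {
  if (!length(fields)) {
    return(tibble(from_id = character(), from_orient = character(),
                  to_id = character(), to_orient = character(),
                  overlap = character()))
  }
  rows <- map2(fields, lineno, function(f, ln) {
    if (length(f) < 5L) {
      abort(sprintf("malformed L line at line %d", ln))
    }
    list(from_id = f[2], from_orient = f[3], to_id = f[4], to_orient = f[5],
         overlap = if (length(f) >= 6L) f[6] else "*")
  })
  bind_rows(rows)
}

#' Split a P-line path name into sample, haplotype and contig
#'
#' PanSN names (`sample#haplotype#contig`) are split on `#`; names without
#' `#` are split on the first `.`; names with neither separator are taken
#' whole as the sample.
#' @param name Character vector of path names.
#' @return Tibble with columns `sample`, `haplotype`, `contig`.
#' @export
parse_pansn <- function(name) {
  parts <- str_split(name, "#")
  bind_rows(map(parts, function(p) {
    if (length(p) >= 3L) {
      list(sample = p[1], haplotype = p[2],
           contig = paste(p[-(1:2)], collapse = "#"))
    } else if (length(p) == 2L) {
      list(sample = p[1], haplotype = NA_character_, contig = p[2])
    } else if (grepl(".", p, fixed = TRUE)) {
      list(sample = sub("\\..*$", "", p), haplotype = NA_character_,
           contig = sub("^[^.]*\\.", "", p))
    } else {
      list(sample = p, haplotype = NA_character_, contig = NA_character_)
    }
  }))
}

parse_p_lines <- function(fields, lineno) {
  if (!length(fields)) return(empty_paths_tbl())
  rows <- map2(fields, lineno, function(f, ln) {
    if (length(f) < 3L) abort(sprintf("malformed P line at line %d", ln))
    steps_raw <- strsplit(f[3], ",", fixed = TRUE)[[1]]
    if (!length(steps_raw) || !all(grepl("^.+[+-]$", steps_raw))) {
      abort(sprintf("malformed P line at line %d: bad step list", ln))
    }
    steps <- tibble(
      segment = sub("[+-]$", "", steps_raw),
      orient = sub("^.*([+-])$", "\\1", steps_raw)
    )
    nm <- parse_pansn(f[2])
    tibble(sample = nm$sample, haplotype = nm$haplotype, contig = nm$contig,
           line_type = "P", name = f[2],
           w_start = NA_integer_, w_end = NA_integer_, steps = list(steps))
  })
  bind_rows(rows)
}

parse_w_lines <- function(fields, lineno) {
  if (!length(fields)) return(empty_paths_tbl())
  rows <- map2(fields, lineno, function(f, ln) {
    if (length(f) < 7L) abort(sprintf("malformed W line at line %d", ln))
    walk <- f[7]
    toks <- regmatches(walk, gregexpr("[><][^><]+", walk))[[1]]
    if (!length(toks)) {
      abort(sprintf("malformed W line at line %d: empty walk", ln))
    }
    steps <- tibble(
      segment = substring(toks, 2L),
      orient = ifelse(substr(toks, 1L, 1L) == ">", "+", "-")
    )
    tibble(sample = f[2], haplotype = f[3], contig = f[4],
           line_type = "W", name = NA_character_,
           w_start = suppressWarnings(as.integer(f[5])),
           w_end = suppressWarnings(as.integer(f[6])),
           steps = list(steps))
  })
  bind_rows(rows)
}

new_pangenome_graph <- function(segments, links, paths) {
  structure(list(segments = as_tibble(segments), links = as_tibble(links),
                 paths = as_tibble(paths)),
            class = "pangenome_graph")
}

#' Construct a pangenome graph from component tibbles
#'
#' Direct constructor used by tests and the synthetic generator; validates
#' referential integrity (every link endpoint and path step must name an
#' existing segment) and segment invariants.
#'
#' @param segments Tibble with `id`, `sequence` (may be `NA`), `length`.
#' @param links Tibble with `from_id`, `from_orient`, `to_id`, `to_orient`,
#'   `overlap`; may be omitted.
#' @param paths Tibble with `sample`, `haplotype`, `contig`, `line_type`,
#'   `name`, `steps`; may be omitted.
#' @return A validated `pangenome_graph`.
#' @export
pangenome_graph <- function(segments,
                            links = NULL,
                            paths = NULL) {
  if (is.null(links)) {
    links <- tibble(from_id = character(), from_orient = character(),
                    to_id = character(), to_orient = character(),
                    overlap = character())
  }
  if (is.null(paths)) paths <- empty_paths_tbl()
  paths <- as_tibble(paths)
  for (col in c("haplotype", "contig", "name")) {
    if (!col %in% names(paths)) paths[[col]] <- NA_character_
  }
  if (!"line_type" %in% names(paths)) paths$line_type <- "P"
  if (!"w_start" %in% names(paths)) paths$w_start <- NA_integer_
  if (!"w_end" %in% names(paths)) paths$w_end <- NA_integer_
  paths <- paths[, names(empty_paths_tbl())]
  g <- new_pangenome_graph(segments, links, paths)
  validate_pangenome_graph(g)
  g
}

validate_pangenome_graph <- function(g) {
  seg <- g$segments
  if (anyDuplicated(seg$id)) abort("duplicate segment ids")
  has_seq <- !is.na(seg$sequence)
  if (any(seg$length[has_seq] != nchar(seg$sequence[has_seq]))) {
    abort("segment length disagrees with its sequence")
  }
  if (any(seg$length[!has_seq] <= 0L)) {
    abort("sequence-less segment must have positive length")
  }
  ids <- seg$id
  bad_link <- setdiff(c(g$links$from_id, g$links$to_id), ids)
  if (length(bad_link)) {
    abort(paste0("link endpoint(s) reference unknown segment(s): ",
                 paste(utils::head(bad_link, 5), collapse = ", ")))
  }
  if (nrow(g$paths)) {
    if (any(map_int(g$paths$steps, nrow) == 0L)) {
      abort("path with no steps")
    }
    step_ids <- unique(unlist(map(g$paths$steps, "segment")))
    bad_step <- setdiff(step_ids, ids)
    if (length(bad_step)) {
      abort(paste0("path step(s) reference unknown segment(s): ",
                   paste(utils::head(bad_step, 5), collapse = ", ")))
    }
  }
  invisible(g)
}

#' Write a pangenome graph as GFA v1.1
#'
#' Serializes segments, links and paths. Paths parsed from `W` lines are
#' written back as `W` lines (and `P`-line paths as `P` lines), so the GFA
#' dialect round-trips. `read_gfa(write_gfa(g, f))` reproduces `g` up to
#' record order.
#'
#' @param graph A `pangenome_graph`.
#' @param file Output path or connection.
#' @return `file`, invisibly.
#' @export
write_gfa <- function(graph, file) {
  stopifnot(inherits(graph, "pangenome_graph"))
  validate_pangenome_graph(graph)
  seg <- graph$segments
  s_lines <- ifelse(
    is.na(seg$sequence),
    sprintf("S\t%s\t*\tLN:i:%d", seg$id, seg$length),
    sprintf("S\t%s\t%s", seg$id, seg$sequence)
  )
  lk <- graph$links
  l_lines <- sprintf("L\t%s\t%s\t%s\t%s\t%s", lk$from_id, lk$from_orient,
                     lk$to_id, lk$to_orient, lk$overlap)
  p <- graph$paths
  path_lines <- if (nrow(p)) {
    pmap(p, function(sample, haplotype, contig, line_type, name,
                     w_start, w_end, steps) {
      if (identical(line_type, "W")) {
        bp <- sum(segment_lengths(graph)[steps$segment])
        sprintf("W\t%s\t%s\t%s\t%d\t%d\t%s",
                sample,
                if (is.na(haplotype)) "0" else haplotype,
                contig,
                if (is.na(w_start)) 0L else w_start,
                if (is.na(w_end)) as.integer(bp) else w_end,
                paste0(ifelse(steps$orient == "+", ">", "<"), steps$segment,
                       collapse = ""))
      } else {
        nm <- if (!is.na(name)) name else {
          paste(sample, if (is.na(haplotype)) "0" else haplotype, contig,
                sep = "#")
        }
        sprintf("P\t%s\t%s\t*", nm,
                paste0(steps$segment, steps$orient, collapse = ","))
      }
    })
  } else list()
  out <- c("H\tVN:Z:1.1", s_lines, l_lines, unlist(path_lines))
  writeLines(out, file)
  invisible(file)
}

segment_lengths <- function(graph) {
  stats::setNames(graph$segments$length, graph$segments$id)
}

#' @export
print.pangenome_graph <- function(x, ...) {
  cat(sprintf(
    "<pangenome_graph> %d segments (%s bp), %d links, %d paths (%d samples)\n",
    nrow(x$segments), format(sum(x$segments$length), big.mark = ","),
    nrow(x$links), nrow(x$paths), dplyr::n_distinct(x$paths$sample)))
  invisible(x)
}
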