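#' Published chromosome-scale scaffold lengths of the KLC assembly
#'
#' The 40 chromosome-level scaffold lengths (chromosomes 1-39 and Z) of the
#' published Korean long-tailed chicken (KLC, *Gallus gallus*) genome
#' assembly, together with the percent-of-assembly values as printed in the
#' assembly report. The percentages refer to the whole assembly size
#' (see [klc_assembly_summary()]), which includes 264 unplaced scaffolds
#' whose individual lengths are not part of this table.
#'
#' @return Tibble with columns `name` (chromosome), `length` (bp) and
#'   `percent_published` (percent of assembly, as printed).
#' @seealso [klc_assembly_summary()], [nx_stats()], [percent_report()]
#' @export
klc_scaffold_lengths <- function() {
  tibble::tribble(
    ~name, ~length, ~percent_published,
    "1", 195432966, 19.10081949,
    "2", 148948886, 14.55765546,
    "3", 110375418, 10.78764232,
    "4", 90511606, 8.846234508,
    "5", 59345498, 5.800186468,
    "6", 35192565, 3.439577494,
    "7", 36216801, 3.539682135,
    "8", 29284060, 2.862104359,
    "9", 23499132, 2.296709136,
    "10", 19909730, 1.945895652,
    "11", 19513749, 1.907194087,
    "12", 20096594, 1.964158976,
    "13", 18023899, 1.761582236,
    "14", 15117088, 1.477482407,
    "15", 12737682, 1.244928988,
    "16", 1176078, 0.1149450578,
    "17", 10679723, 1.043792485,
    "18", 11299519, 1.104368813,
    "19", 10034254, 0.9807069824,
    "20", 13953091, 1.363718097,
    "21", 6807633, 0.6653502312,
    "22", 4736118, 0.4628888199,
    "23", 5818881, 0.5687136509,
    "24", 6365640, 0.6221516413,
    "25", 2932729, 0.2866329483,
    "26", 5325154, 0.5204587915,
    "27", 5718884, 0.5589403528,
    "28", 5174667, 0.5057508071,
    "29", 436614, 0.04267286823,
    "30", 970373, 0.09484029173,
    "31", 1572772, 0.1537163084,
    "32", 234640, 0.02293275478,
    "33", 2109227, 0.2061472279,
    "34", 2859599, 0.2794855209,
    "35", 745058, 0.07281892435,
    "36", 367897, 0.03595674942,
    "37", 123200, 0.01204106456,
    "38", 769429, 0.0752008463,
    "39", 192591, 0.01882305735,
    "Z", 76830679, 7.509116608
  )
}

#' Published summary statistics of the KLC assembly and pangenome
#'
#' Headline numbers of the published KLC (Korean long-tailed chicken)
#' resource: the scaffolded assembly totals, and the node/edge/length
#' counts of the 40-assembly *Gallus gallus* pangenome graph it was
#' incorporated into. Useful as worked-example inputs for [nx_stats()],
#' [percent_report()] and [mean_node_degree()].
#'
#' @return One-row tibble: `genome_size` (bp), `scaffold_count`,
#'   `chromosome_scale_bp` (bp in the 40 chromosome-scale scaffolds),
#'   `n50`, `l50`, `gc_percent`, and pangenome-graph `graph_nodes`,
#'   `graph_edges`, `graph_bp`.
#' @export
klc_assembly_summary <- function() {
  tibble(
    genome_size = 1023165347,
    scaffold_count = 304L,
    chromosome_scale_bp = 1008187434,
    n50 = 90511606,
    l50 = 4L,
    gc_percent = 42.04,
    graph_nodes = 87934214,
    graph_edges = 121720974,
    graph_bp = 1709850352
  )
}
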