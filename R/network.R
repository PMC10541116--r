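#' Filter cross-link records by FDR and score
#'
#' Standard cleavable-linker acceptance: keep records with
#' `fdr <= fdr_max` (inclusive) and `score > score_min` (strict, matching
#' the "score > 40" convention). `NA` FDR (column absent from the export)
#' passes. Order is preserved; removal counts are attached as attributes
#' `"removed_by_fdr"` and `"removed_by_score"`.
#'
#' @param records an `xl_records` data frame.
#' @param fdr_max maximum FDR, default 0.01.
#' @param score_min strict lower score bound, default 40.
#' @return Filtered `xl_records`.
#' @export
filter_records <- function(records, fdr_max = 0.01, score_min = 40) {
  records <- validate_xl_records(as.data.frame(records))
  stopifnot(is.finite(fdr_max), is.finite(score_min))
  pass_fdr <- is.na(records$fdr) | records$fdr <= fdr_max
  pass_score <- records$score > score_min
  out <- records[pass_fdr & pass_score, , drop = FALSE]
  rownames(out) <- NULL
  out <- validate_xl_records(out)
  attr(out, "removed_by_fdr") <- sum(!pass_fdr)
  attr(out, "removed_by_score") <- sum(!pass_score)
  out
}

# Canonical endpoint ordering: lexicographic by group id, then residue.
# Returns a logical vector: TRUE where (a) endpoint sorts after (b) and the
# pair must be swapped.
needs_swap <- function(ga, ra, gb, rb) {
  ga > gb | (ga == gb & ra > rb)
}

#' Deduplicate cross-link records into unique residue-pair links
#'
#' Records sharing the same unordered (group, residue) endpoint pair — in
#' either orientation, from any dataset — collapse into one unique link with
#' `support` = number of supporting records and `best_score` = their maximum
#' score. Endpoints are stored in canonical order (lexicographic by group,
#' then residue), and the output is sorted canonically, so the result is
#' invariant under record permutation and endpoint swaps. A link is
#' `intermolecular` iff its two groups differ.
#'
#' @param records orthogroup-labelled `xl_records` (accession-level keys are
#'   equally valid for sensitivity analysis — the key is whatever the
#'   protein fields hold).
#' @return A `data.frame` of class `xl_links` with columns `group_a`,
#'   `residue_a`, `group_b`, `residue_b`, `kind`, `support`, `best_score`;
#'   attribute `"n_records"` holds the input record count.
#' @export
deduplicate_links <- function(records) {
  records <- validate_xl_records(as.data.frame(records))
  ga <- records$protein_a; ra <- records$residue_a
  gb <- records$protein_b; rb <- records$residue_b
  sw <- needs_swap(ga, ra, gb, rb)
  tmp <- ga[sw]; ga[sw] <- gb[sw]; gb[sw] <- tmp
  tmpr <- ra[sw]; ra[sw] <- rb[sw]; rb[sw] <- tmpr
  key <- paste(ga, ra, gb, rb, sep = "\r")
  agg_support <- tapply(rep(1L, length(key)), key, sum)
  agg_score <- if (length(key) > 0) tapply(records$score, key, max) else numeric()
  uk <- names(agg_support)
  parts <- if (length(uk) > 0) do.call(rbind, strsplit(uk, "\r", fixed = TRUE))
    else matrix(character(), 0, 4)
  links <- data.frame(
    group_a = parts[, 1], residue_a = as.integer(parts[, 2]),
    group_b = parts[, 3], residue_b = as.integer(parts[, 4]),
    stringsAsFactors = FALSE
  )
  links$kind <- ifelse(links$group_a == links$group_b,
                       "intramolecular", "intermolecular")
  links$support <- as.integer(agg_support[uk])
  links$best_score <- as.numeric(agg_score[uk])
  ord <- order(links$group_a, links$residue_a, links$group_b, links$residue_b)
  links <- links[ord, , drop = FALSE]
  rownames(links) <- NULL
  class(links) <- unique(c("xl_links", class(links)))
  attr(links, "n_records") <- nrow(records)
  links
}

#' @export
print.xl_links <- function(x, ...) {
  cat("<xl_links> ", nrow(x), " unique link(s): ",
      sum(x$kind == "intramolecular"), " intramolecular, ",
      sum(x$kind == "intermolecular"), " intermolecular\n", sep = "")
  print.data.frame(utils::head(as.data.frame(x), 6), ...)
  if (nrow(x) > 6) cat("  ... ", nrow(x) - 6, " more row(s)\n", sep = "")
  invisible(x)
}

link_labels <- function(links) {
  sprintf("%s:%d--%s:%d", links$group_a, links$residue_a,
          links$group_b, links$residue_b)
}

#' Summarise a cross-link network
#'
#' The countable quantities of an XL/MS interactome: total records (CSMs),
#' unique residue-pair links, unique group pairs, distinct proteins/groups
#' incident to at least one link, and the intra/inter split. By
#' construction `n_intramolecular + n_intermolecular == n_unique_links` and
#' `n_unique_links <= n_records`.
#'
#' @param links an `xl_links` data frame (see [deduplicate_links()]).
#' @param records the records the links were built from; defaults to the
#'   count stored on `links`.
#' @return A list of class `xl_network_summary`.
#' @export
summarize_network <- function(links, records = NULL) {
  n_records <- if (!is.null(records)) nrow(records)
    else if (!is.null(attr(links, "n_records"))) attr(links, "n_records")
    else NA_integer_
  gp <- unique(paste(links$group_a, links$group_b, sep = "\r"))
  structure(list(
    n_records = n_records,
    n_unique_links = nrow(links),
    n_unique_group_pairs = length(gp),
    n_proteins = length(unique(c(links$group_a, links$group_b))),
    n_intermolecular = sum(links$kind == "intermolecular"),
    n_intramolecular = sum(links$kind == "intramolecular")
  ), class = "xl_network_summary")
}

#' @export
print.xl_network_summary <- function(x, ...) {
  cat("<xl_network_summary>\n",
      "  cross-link records (CSMs): ", x$n_records, "\n",
      "  unique residue-pair links: ", x$n_unique_links,
      " (", x$n_intramolecular, " intra, ", x$n_intermolecular, " inter)\n",
      "  unique group pairs:        ", x$n_unique_group_pairs, "\n",
      "  proteins/groups linked:    ", x$n_proteins, "\n", sep = "")
  invisible(x)
}

#' Per-protein arc-diagram data
#'
#' For each requested protein/group: its sequence length and the arcs of
#' links touching it — intramolecular arcs connect two positions on the
#' protein, intermolecular arcs carry the partner group and its position.
#'
#' @param links an `xl_links` data frame.
#' @param protein_lengths named integer vector, group -> sequence length
#'   (typically `nchar()` of the FASTA sequences).
#' @param groups groups to include; a group without a known length is
#'   dropped with a warning.
#' @return `data.frame(group, length, pos_i, pos_j, kind, partner,
#'   partner_pos)`; for intramolecular arcs `partner` is the group itself.
#' @export
arc_diagram_data <- function(links, protein_lengths, groups) {
  unknown <- setdiff(groups, names(protein_lengths))
  if (length(unknown) > 0) {
    warning("no sequence length for group(s): ",
            paste(unknown, collapse = ", "), "; omitted")
    groups <- setdiff(groups, unknown)
  }
  rows <- lapply(groups, function(g) {
    touch <- links$group_a == g | links$group_b == g
    sub <- links[touch, , drop = FALSE]
    if (nrow(sub) == 0)
      return(data.frame(group = character(), length = integer(),
                        pos_i = integer(), pos_j = integer(),
                        kind = character(), partner = character(),
                        partner_pos = integer(), stringsAsFactors = FALSE))
    on_a <- sub$group_a == g
    pos_i <- ifelse(on_a, sub$residue_a, sub$residue_b)
    partner <- ifelse(on_a, sub$group_b, sub$group_a)
    partner_pos <- ifelse(on_a, sub$residue_b, sub$residue_a)
    data.frame(group = g, length = unname(protein_lengths[g]),
               pos_i = pos_i,
               pos_j = ifelse(sub$kind == "intramolecular", partner_pos,
                              NA_integer_),
               kind = sub("molecular", "", sub$kind),
               partner = partner, partner_pos = partner_pos,
               stringsAsFactors = FALSE)
  })
  empty <- data.frame(group = character(), length = integer(),
                      pos_i = integer(), pos_j = integer(),
                      kind = character(), partner = character(),
                      partner_pos = integer(), stringsAsFactors = FALSE)
  out <- do.call(rbind, c(list(empty), rows))
  rownames(out) <- NULL
  out
}

#' Export a link network
#'
#' Formats: `"xiview-csv"` (residue-level rows with columns
#' `Protein1,PepPos1,Protein2,PepPos2,Score` as consumed by the xiView
#' viewer), `"tsv"` (lossless round-trip of the link table, see
#' [read_network_tsv()]), and `"graphml"` (residue-level graph via igraph;
#' node attributes `group` and `residue`, edge attributes `kind`, `support`,
#' `best_score`). An empty link list yields a valid header-only file with a
#' warning.
#'
#' @param links an `xl_links` data frame.
#' @param path output path.
#' @param format one of `"xiview-csv"`, `"tsv"`, `"graphml"`.
#' @return `path`, invisibly.
#' @export
write_network <- function(links, path, format = c("xiview-csv", "tsv", "graphml")) {
  format <- match.arg(format)
  if (nrow(links) == 0 && format != "graphml")
    warning("writing an empty network to ", basename(path))
  if (format == "xiview-csv") {
    out <- data.frame(Protein1 = links$group_a, PepPos1 = links$residue_a,
                      Protein2 = links$group_b, PepPos2 = links$residue_b,
                      Score = links$best_score)
    utils::write.table(out, path, sep = ",", row.names = FALSE, quote = FALSE)
  } else if (format == "tsv") {
    utils::write.table(as.data.frame(links)[, c("group_a", "residue_a",
                                                "group_b", "residue_b",
                                                "kind", "support",
                                                "best_score")],
                       path, sep = "\t", row.names = FALSE, quote = FALSE)
  } else {
    if (nrow(links) == 0) warning("writing an empty network to ", basename(path))
    va <- paste(links$group_a, links$residue_a, sep = ":")
    vb <- paste(links$group_b, links$residue_b, sep = ":")
    verts <- unique(data.frame(name = c(va, vb),
                               group = c(links$group_a, links$group_b),
                               residue = c(links$residue_a, links$residue_b),
                               stringsAsFactors = FALSE))
    g <- igraph::graph_from_data_frame(
      data.frame(from = va, to = vb, kind = links$kind,
                 support = links$support, best_score = links$best_score,
                 stringsAsFactors = FALSE),
      directed = FALSE, vertices = verts)
    igraph::write_graph(g, path, format = "graphml")
  }
  invisible(path)
}

#' Read back a tsv network export
#' @param path file written by [write_network()] with `format = "tsv"`.
#' @return An `xl_links` data frame.
#' @export
read_network_tsv <- function(path) {
  links <- utils::read.table(path, header = TRUE, sep = "\t",
                             stringsAsFactors = FALSE, quote = "")
  links$residue_a <- as.integer(links$residue_a)
  links$residue_b <- as.integer(links$residue_b)
  links$support <- as.integer(links$support)
  class(links) <- unique(c("xl_links", class(links)))
  links
}
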