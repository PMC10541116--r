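#' Read a FASTA file of protein sequences
#'
#' Accessions are the header up to the first whitespace. Duplicate
#' accessions are a hard error.
#'
#' @param path FASTA file.
#' @return Named character vector, accession -> sequence.
#' @export
read_fasta <- function(path) {
  if (!file.exists(path)) stop("FASTA file not found: ", path)
  set <- Biostrings::readAAStringSet(path)
  acc <- sub("\\s.*$", "", names(set))
  if (anyDuplicated(acc))
    stop("duplicate accession(s) in ", path, ": ",
         paste(unique(acc[duplicated(acc)]), collapse = ", "))
  stats::setNames(as.character(set), acc)
}

#' Write protein sequences as FASTA
#' @param sequences named character vector, accession -> sequence.
#' @param path output path.
#' @return `path`, invisibly.
#' @export
write_fasta <- function(sequences, path) {
  set <- Biostrings::AAStringSet(sequences)
  Biostrings::writeXStringSet(set, path)
  invisible(path)
}

#' Construct an orthogroup membership map
#'
#' Collapsing paralogs into eukaryotic ortholog groups (eggNOG-style) lets
#' cross-links on different co-orthologs be considered together and matched
#' to human gene names. Each accession maps to at most one orthogroup.
#'
#' @param entries named character vector, protein accession -> orthogroup id.
#' @param group_names optional named character vector, orthogroup id ->
#'   human-readable label (e.g. the human ortholog gene name).
#' @return An object of class `ortho_map`.
#' @export
ortho_map <- function(entries, group_names = character()) {
  if (anyDuplicated(names(entries)))
    stop("accession(s) mapped more than once: ",
         paste(unique(names(entries)[duplicated(names(entries))]), collapse = ", "))
  structure(list(entries = entries, group_names = group_names),
            class = "ortho_map")
}

#' @export
print.ortho_map <- function(x, ...) {
  cat("<ortho_map> ", length(x$entries), " accession(s) in ",
      length(unique(x$entries)), " orthogroup(s)\n", sep = "")
  invisible(x)
}

#' Read an orthogroup membership table
#'
#' Tab-separated columns: accession, orthogroup id, optional human-readable
#' label. An accession assigned to two distinct groups is a hard error.
#'
#' @param path TSV file (header optional, detected by a non-data first line
#'   named `accession`).
#' @return An [ortho_map()].
#' @export
read_orthomap <- function(path) {
  if (!file.exists(path)) stop("orthogroup table not found: ", path)
  tab <- utils::read.table(path, header = FALSE, sep = "\t",
                           stringsAsFactors = FALSE, quote = "",
                           comment.char = "#", fill = TRUE)
  if (nrow(tab) > 0 && tolower(tab[1, 1]) %in% c("accession", "protein"))
    tab <- tab[-1, , drop = FALSE]
  if (ncol(tab) < 2) stop("orthogroup table needs >= 2 columns (accession, group)")
  tab <- unique(tab[, seq_len(min(3, ncol(tab))), drop = FALSE])
  acc <- as.character(tab[[1]]); grp <- as.character(tab[[2]])
  conflicting <- unique(acc[duplicated(acc)])
  if (length(conflicting) > 0)
    stop("accession(s) mapped to more than one orthogroup in ", path, ": ",
         paste(conflicting, collapse = ", "))
  group_names <- character()
  if (ncol(tab) >= 3) {
    lab <- as.character(tab[[3]])
    ok <- !is.na(lab) & lab != ""
    group_names <- stats::setNames(lab[ok], grp[ok])
    group_names <- group_names[!duplicated(names(group_names))]
  }
  ortho_map(stats::setNames(grp, acc), group_names)
}

#' Collapse cross-link records onto orthogroups
#'
#' Replaces protein accessions by their orthogroup ids so that paralogs
#' mapping to the same eukaryotic ortholog group are considered together.
#' Original accessions are retained in `orig_protein_a`/`orig_protein_b`.
#' Accessions without an orthogroup keep their accession as a singleton
#' group; they are reported in the `"unmapped"` attribute, never dropped.
#' Collapsing changes labels only — never the number of records.
#'
#' @param records an `xl_records` data frame.
#' @param orthomap an [ortho_map()].
#' @return `xl_records` with group-level protein fields, provenance columns,
#'   and attributes `"unmapped"` (accessions lacking a group) and
#'   `"n_unmapped_records"`.
#' @export
collapse_to_orthogroups <- function(records, orthomap) {
  records <- validate_xl_records(as.data.frame(records))
  lookup <- orthomap$entries
  map1 <- function(acc) {
    g <- unname(lookup[acc])
    ifelse(is.na(g), acc, g)
  }
  out <- records
  out$orig_protein_a <- records$protein_a
  out$orig_protein_b <- records$protein_b
  out$protein_a <- map1(records$protein_a)
  out$protein_b <- map1(records$protein_b)
  unmapped <- sort(unique(c(records$protein_a, records$protein_b)))
  unmapped <- unmapped[!(unmapped %in% names(lookup))]
  out <- validate_xl_records(out)
  attr(out, "unmapped") <- unmapped
  attr(out, "n_unmapped_records") <-
    sum(!(records$protein_a %in% names(lookup)) |
          !(records$protein_b %in% names(lookup)))
  out
}

# BLOSUM62 with X scored 0 against everything (unknown residues are
# alignment-neutral).
scoring_matrix <- function(name = "BLOSUM62") {
  mat <- get(utils::data(list = name, package = "Biostrings",
                         envir = environment()))
  if ("X" %in% rownames(mat)) {
    mat["X", ] <- 0L
    mat[, "X"] <- 0L
  }
  mat
}

#' Global pairwise alignment of two protein sequences
#'
#' Needleman-Wunsch with affine gaps (a gap of length L costs
#' `gap_open + L * gap_extend`), BLOSUM62 by default, `X` scored 0. Used to
#' transfer residue positions between orthologous sequences (e.g. placing
#' cross-linked residues from one species onto a structure solved in
#' another).
#'
#' @param seq_a,seq_b non-empty amino-acid strings.
#' @param substitution_matrix matrix name available in Biostrings
#'   (default `"BLOSUM62"`) or a numeric matrix.
#' @param gap_open,gap_extend affine gap parameters (positive costs).
#' @return An object of class `xl_alignment`: `columns` is a data frame of
#'   aligned positions (`pos_a`, `pos_b`, `NA` marks a gap), plus `score`
#'   and `identity` (percent identical over all alignment columns).
#' @export
global_align <- function(seq_a, seq_b, substitution_matrix = "BLOSUM62",
                         gap_open = 11, gap_extend = 1) {
  if (!nzchar(seq_a) || !nzchar(seq_b))
    stop("cannot align an empty sequence")
  mat <- if (is.matrix(substitution_matrix)) substitution_matrix
    else scoring_matrix(substitution_matrix)
  ali <- Biostrings::pairwiseAlignment(
    Biostrings::AAString(seq_a), Biostrings::AAString(seq_b),
    type = "global", substitutionMatrix = mat,
    gapOpening = gap_open, gapExtension = gap_extend)
  ga <- strsplit(as.character(Biostrings::alignedPattern(ali)), "")[[1]]
  gb <- strsplit(as.character(Biostrings::alignedSubject(ali)), "")[[1]]
  pos_a <- ifelse(ga == "-", NA_integer_, cumsum(ga != "-"))
  pos_b <- ifelse(gb == "-", NA_integer_, cumsum(gb != "-"))
  identical_col <- !is.na(pos_a) & !is.na(pos_b) & ga == gb
  structure(list(
    accession_a = "seq_a", accession_b = "seq_b",
    length_a = nchar(seq_a), length_b = nchar(seq_b),
    columns = data.frame(pos_a = as.integer(pos_a),
                         pos_b = as.integer(pos_b)),
    score = Biostrings::score(ali),
    identity = 100 * sum(identical_col) / length(ga)
  ), class = "xl_alignment")
}

#' Vectorised global alignment scores
#'
#' Optimal global (Needleman-Wunsch, affine-gap) alignment scores of many
#' query sequences against one subject, without traceback. Same scoring
#' convention as [global_align()].
#'
#' @param seqs_a character vector of query sequences.
#' @param seq_b one subject sequence.
#' @inheritParams global_align
#' @return Numeric vector of optimal scores, one per query.
#' @export
global_align_score <- function(seqs_a, seq_b, substitution_matrix = "BLOSUM62",
                               gap_open = 11, gap_extend = 1) {
  if (any(!nzchar(seqs_a)) || !nzchar(seq_b))
    stop("cannot align an empty sequence")
  mat <- if (is.matrix(substitution_matrix)) substitution_matrix
    else scoring_matrix(substitution_matrix)
  Biostrings::pairwiseAlignment(
    Biostrings::AAStringSet(seqs_a), Biostrings::AAString(seq_b),
    type = "global", substitutionMatrix = mat,
    gapOpening = gap_open, gapExtension = gap_extend, scoreOnly = TRUE)
}

#' @export
print.xl_alignment <- function(x, ...) {
  cat("<xl_alignment> ", nrow(x$columns), " column(s), score ", x$score,
      ", identity ", sprintf("%.1f%%", x$identity), "\n", sep = "")
  invisible(x)
}

#' Transfer residue positions onto a structure chain via an alignment
#'
#' Builds the full source-position -> author-number map for one chain: the
#' alignment's subject must be the chain's residue sequence (see
#' [chain_sequence()]). A position aligned to a gap is `"unaligned"`; one
#' aligned to a residue whose Calpha is missing from the coordinates is
#' `"missing_in_structure"`. When global identity is below `min_identity`
#' percent the transfer is refused and every position is `"unaligned"`
#' (guards against spurious cross-species mapping). The mapping is injective
#' and monotone on aligned positions.
#'
#' @param alignment an [global_align()] result with the source protein as
#'   query and the chain sequence as subject.
#' @param structure an [xl_structure()].
#' @param chain chain id within `structure`.
#' @param min_identity percent-identity gate, default 20.
#' @return An object of class `residue_transfer`: data frame with columns
#'   `source_pos`, `author_number` (`NA` unless status `"ok"`) and `status`
#'   in `{"ok", "unaligned", "missing_in_structure"}`.
#' @export
residue_transfer <- function(alignment, structure, chain, min_identity = 20) {
  res <- chain_residues(structure, chain)
  if (alignment$length_b != nrow(res))
    stop("alignment subject length (", alignment$length_b,
         ") does not match chain '", chain, "' residue count (", nrow(res), ")")
  n <- alignment$length_a
  author <- rep(NA_integer_, n)
  status <- rep("unaligned", n)
  if (alignment$identity >= min_identity) {
    cols <- alignment$columns
    both <- !is.na(cols$pos_a) & !is.na(cols$pos_b)
    src <- cols$pos_a[both]
    tgt <- cols$pos_b[both]
    author[src] <- res$author_number[tgt]
    status[src] <- ifelse(is.na(res$x[tgt]), "missing_in_structure", "ok")
    author[src][status[src] != "ok"] <- NA_integer_
  }
  structure(data.frame(source_pos = seq_len(n), author_number = author,
                       status = status, stringsAsFactors = FALSE),
            class = c("residue_transfer", "data.frame"),
            chain = chain, structure_id = structure$id)
}

#' Transfer one residue position
#'
#' Single-position convenience over [residue_transfer()].
#'
#' @inheritParams residue_transfer
#' @param pos 1-based position in the source sequence; out of range is a
#'   hard error.
#' @return The author number (integer) when mapped, otherwise the string
#'   `"unaligned"` or `"missing_in_structure"`.
#' @export
transfer_residue <- function(alignment, structure, chain, pos,
                             min_identity = 20) {
  if (length(pos) != 1 || is.na(pos) || pos < 1 || pos > alignment$length_a)
    stop("position ", pos, " outside source sequence (length ",
         alignment$length_a, ")")
  tr <- residue_transfer(alignment, structure, chain, min_identity)
  if (tr$status[pos] == "ok") tr$author_number[pos] else tr$status[pos]
}

#' Identity residue transfer
#'
#' For chains whose author numbering IS the source numbering (same-species
#' structures): maps source position p to author number p when that residue
#' exists in the chain, flagging missing Calphas.
#'
#' @param structure an [xl_structure()].
#' @param chain chain id.
#' @param length_a source sequence length; defaults to the chain's largest
#'   author number.
#' @return A `residue_transfer` object.
#' @export
identity_transfer <- function(structure, chain, length_a = NULL) {
  res <- chain_residues(structure, chain)
  if (is.null(length_a)) length_a <- max(res$author_number)
  idx <- match(seq_len(length_a), res$author_number)
  status <- ifelse(is.na(idx), "unaligned",
                   ifelse(is.na(res$x[idx]), "missing_in_structure", "ok"))
  author <- ifelse(status == "ok", res$author_number[idx], NA_integer_)
  structure(data.frame(source_pos = seq_len(length_a),
                       author_number = as.integer(author),
                       status = status, stringsAsFactors = FALSE),
            class = c("residue_transfer", "data.frame"),
            chain = chain, structure_id = structure$id)
}
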