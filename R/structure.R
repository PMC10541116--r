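#' Construct a structure of Calpha-resolved residues
#'
#' A structure is a residue table: one row per residue with its chain id,
#' author numbering (integer, possibly non-contiguous, with insertion code),
#' one-letter amino-acid code and an optional Calpha coordinate in Angstrom.
#' Residues lacking a Calpha record carry `NA` coordinates (an explicit
#' missing marker, never a sentinel value). Within a chain, the author sort
#' key `(author_number, icode)` is strictly increasing.
#'
#' @param id structure label (e.g. a PDB id).
#' @param residues `data.frame` with columns `chain`, `author_number`,
#'   `icode` (empty string when absent), `aa` (one-letter code), `x`, `y`,
#'   `z` (`NA` for missing Calpha).
#' @return An object of class `xl_structure`.
#' @export
xl_structure <- function(id, residues) {
  required <- c("chain", "author_number", "icode", "aa", "x", "y", "z")
  missing <- setdiff(required, names(residues))
  if (length(missing) > 0)
    stop("residue table is missing column(s): ", paste(missing, collapse = ", "))
  residues$chain <- as.character(residues$chain)
  residues$author_number <- as.integer(residues$author_number)
  residues$icode <- as.character(residues$icode)
  residues$aa <- as.character(residues$aa)
  ord <- order(residues$chain, residues$author_number, residues$icode)
  residues <- residues[ord, , drop = FALSE]
  rownames(residues) <- NULL
  for (ch in unique(residues$chain)) {
    sub <- residues[residues$chain == ch, , drop = FALSE]
    key <- paste(sub$author_number, sub$icode, sep = "|")
    if (anyDuplicated(key))
      stop("duplicate residue ", key[duplicated(key)][1], " in chain ", ch)
  }
  structure(list(id = as.character(id), residues = residues),
            class = "xl_structure")
}

#' @export
print.xl_structure <- function(x, ...) {
  ch <- table(x$residues$chain)
  n_missing <- sum(is.na(x$residues$x))
  cat("<xl_structure> '", x$id, "': ", nrow(x$residues), " residue(s) in ",
      length(ch), " chain(s) [",
      paste(sprintf("%s:%d", names(ch), as.integer(ch)), collapse = ", "),
      "]", sep = "")
  if (n_missing > 0) cat("; ", n_missing, " without Calpha", sep = "")
  cat("\n")
  invisible(x)
}

#' @rdname xl_structure
#' @param x an object.
#' @export
is_xl_structure <- function(x) inherits(x, "xl_structure")

#' Chains of a structure
#' @param structure an [xl_structure()].
#' @return Character vector of chain ids in residue-table order.
#' @export
structure_chains <- function(structure) unique(structure$residues$chain)

#' One-letter sequence of one chain, in author-number order
#'
#' Includes residues whose Calpha is missing (sequence is defined by the
#' residue record, not the coordinates).
#'
#' @param structure an [xl_structure()].
#' @param chain chain id.
#' @return Single character string.
#' @export
chain_sequence <- function(structure, chain) {
  sub <- structure$residues[structure$residues$chain == chain, , drop = FALSE]
  if (nrow(sub) == 0) stop("no chain '", chain, "' in structure ", structure$id)
  paste(sub$aa, collapse = "")
}

# Residue rows for one chain (already author-ordered by construction).
chain_residues <- function(structure, chain) {
  sub <- structure$residues[structure$residues$chain == chain, , drop = FALSE]
  if (nrow(sub) == 0) stop("no chain '", chain, "' in structure ", structure$id)
  sub
}

# Calpha coordinate of (chain, author_number); NA row if absent or missing.
residue_ca <- function(structure, chain, author_number) {
  sub <- structure$residues
  i <- which(sub$chain == chain & sub$author_number == author_number)
  if (length(i) == 0) return(c(NA_real_, NA_real_, NA_real_))
  c(sub$x[i[1]], sub$y[i[1]], sub$z[i[1]])
}

# All Calpha coordinates of a structure as an n x 3 matrix (NA rows kept),
# row names "chain|author_number|icode".
ca_matrix <- function(structure) {
  r <- structure$residues
  m <- cbind(r$x, r$y, r$z)
  rownames(m) <- paste(r$chain, r$author_number, r$icode, sep = "|")
  m
}

three_to_one <- function(resid) {
  out <- suppressWarnings(bio3d::aa321(resid))
  out[is.na(out) | out == ""] <- "X"
  out
}

# Build the residue table from a bio3d atom data.frame: altloc resolution
# (highest occupancy, ties alphabetical), missing-Calpha flagging, per-chain
# author ordering.
residues_from_bio3d <- function(atom, source = "structure") {
  atom <- atom[atom$type == "ATOM", , drop = FALSE]
  if (nrow(atom) == 0) stop("no ATOM records in ", source)
  atom$chain[is.na(atom$chain)] <- " "
  atom$insert[is.na(atom$insert)] <- ""
  atom$alt[is.na(atom$alt)] <- ""
  if (!("o" %in% names(atom)) || all(is.na(atom$o))) atom$o <- 1
  atom$o[is.na(atom$o)] <- 1

  res_key <- paste(atom$chain, atom$resno, atom$insert, sep = "|")
  first <- !duplicated(res_key)
  res <- data.frame(chain = atom$chain[first],
                    author_number = atom$resno[first],
                    icode = atom$insert[first],
                    aa = three_to_one(atom$resid[first]),
                    stringsAsFactors = FALSE)
  key_first <- res_key[first]

  ca <- atom[atom$elety == "CA", , drop = FALSE]
  coords <- matrix(NA_real_, nrow(res), 3)
  if (nrow(ca) > 0) {
    ca_key <- paste(ca$chain, ca$resno, ca$insert, sep = "|")
    # altloc: highest occupancy wins, ties broken alphabetically
    ord <- order(ca_key, -ca$o, ca$alt)
    ca <- ca[ord, , drop = FALSE]
    ca <- ca[!duplicated(ca_key[ord]), , drop = FALSE]
    idx <- match(paste(ca$chain, ca$resno, ca$insert, sep = "|"), key_first)
    coords[idx, ] <- cbind(ca$x, ca$y, ca$z)
  }
  res$x <- coords[, 1]; res$y <- coords[, 2]; res$z <- coords[, 3]

  empty <- tapply(is.na(res$x), res$chain, all)
  if (any(empty))
    warning("chain(s) with zero Calpha atoms retained: ",
            paste(names(empty)[empty], collapse = ", "))
  res
}

#' Read an atomic structure from PDB or mmCIF
#'
#' Extracts one Calpha coordinate per residue. Alternate locations are
#' resolved by highest occupancy (ties broken alphabetically by altloc id);
#' insertion codes are part of the author numbering; residues without a
#' Calpha atom are flagged missing, never fabricated. Both readers agree
#' exactly on Calpha coordinates for equivalent content.
#'
#' @param path a `.pdb`/`.ent` or `.cif`/`.mmcif` file. Format is
#'   auto-detected from the extension, falling back to content sniffing.
#' @param format `"auto"`, `"pdb"` or `"cif"`.
#' @return An [xl_structure()] whose id is the file stem.
#' @export
read_structure <- function(path, format = c("auto", "pdb", "cif")) {
  format <- match.arg(format)
  if (!file.exists(path)) stop("structure file not found: ", path)
  if (format == "auto") {
    ext <- tolower(tools::file_ext(path))
    format <- if (ext %in% c("cif", "mmcif")) "cif"
      else if (ext %in% c("pdb", "ent")) "pdb"
      else {
        head_lines <- readLines(path, n = 20L, warn = FALSE)
        if (any(grepl("^data_|^loop_|^_atom_site", head_lines))) "cif" else "pdb"
      }
  }
  parsed <- tryCatch(
    suppressWarnings(
      if (format == "cif") bio3d::read.cif(path, rm.alt = FALSE)
      else bio3d::read.pdb(path, rm.alt = FALSE)),
    error = function(e) stop("cannot read ", format, " file ", path, ": ",
                             conditionMessage(e)))
  xl_structure(id = tools::file_path_sans_ext(basename(path)),
               residues = residues_from_bio3d(parsed$atom, source = path))
}

#' Write a structure's Calpha trace as a PDB file
#'
#' One ATOM record per residue with a resolved Calpha; intended for the
#' synthetic-data bundle and for export to external viewers. Chain ids must
#' be single characters (PDB format constraint).
#'
#' @param structure an [xl_structure()].
#' @param path output path.
#' @return `path`, invisibly.
#' @export
write_structure_pdb <- function(structure, path) {
  r <- structure$residues[!is.na(structure$residues$x), , drop = FALSE]
  if (any(nchar(r$chain) != 1))
    stop("PDB chain ids must be single characters; found: ",
         paste(unique(r$chain[nchar(r$chain) != 1]), collapse = ", "))
  aa3 <- bio3d::aa123(r$aa)
  aa3[is.na(aa3)] <- "UNK"
  lines <- sprintf(
    "ATOM  %5d  CA  %3s %1s%4d%1s   %8.3f%8.3f%8.3f%6.2f%6.2f           C",
    seq_len(nrow(r)), aa3, r$chain, r$author_number,
    ifelse(r$icode == "", " ", r$icode), r$x, r$y, r$z, 1, 0)
  writeLines(c(lines, "END"), path)
  invisible(path)
}

# Apply a rigid transform p -> R p + t to every resolved Calpha.
transform_structure <- function(structure, rotation, translation) {
  r <- structure$residues
  ok <- !is.na(r$x)
  if (any(ok)) {
    p <- cbind(r$x[ok], r$y[ok], r$z[ok]) %*% t(rotation)
    p <- sweep(p, 2, translation, `+`)
    r$x[ok] <- p[, 1]; r$y[ok] <- p[, 2]; r$z[ok] <- p[, 3]
  }
  structure$residues <- r
  structure
}
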