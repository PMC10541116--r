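#' Construct a conformational ensemble
#'
#' An ordered set of structures representing alternative conformations of
#' the same complex (e.g. the binding states of a dynein motor). Members
#' share the chain/residue naming; they may differ in which residues are
#' resolved.
#'
#' @param label ensemble label.
#' @param members named list of [xl_structure()] objects; names default to
#'   each member's id.
#' @return An object of class `xl_ensemble`.
#' @export
xl_ensemble <- function(label, members) {
  if (length(members) < 1) stop("an ensemble needs at least one member")
  if (is.null(names(members)) || any(!nzchar(names(members))))
    names(members) <- vapply(members, function(s) s$id, character(1))
  for (m in members)
    if (!is_xl_structure(m)) stop("ensemble members must be xl_structure objects")
  structure(list(label = label, members = members), class = "xl_ensemble")
}

#' @export
print.xl_ensemble <- function(x, ...) {
  cat("<xl_ensemble> '", x$label, "': ", length(x$members),
      " conformation(s): ", paste(names(x$members), collapse = ", "),
      "\n", sep = "")
  invisible(x)
}

#' Per-conformation distance matrix of links across an ensemble
#'
#' Entry (i, j) is the mapped Calpha-Calpha distance of link i on
#' conformation j (in Angstrom), `NA` where the link is unmappable on that
#' member. Per-link minima and their argmin conformation are attached; a
#' per-link flag marks links unmappable on every member.
#'
#' @param links an `xl_links` data frame.
#' @param ensemble an [xl_ensemble()].
#' @param chain_map,transfers,thresholds as in [map_links()], shared by all
#'   members.
#' @return Numeric matrix (links x conformations) of class `xl_heatmap`
#'   with attributes `min`, `argmin` (conformation label, `NA` when no cell
#'   is numeric) and `all_unmappable`.
#' @export
distance_heatmap <- function(links, ensemble, chain_map, transfers = NULL,
                             thresholds = xl_thresholds()) {
  cols <- lapply(ensemble$members, function(m)
    map_links(links, m, chain_map, transfers, thresholds)$distance)
  mat <- do.call(cbind, cols)
  dimnames(mat) <- list(link_labels(links), names(ensemble$members))
  mins <- apply(mat, 1, function(r) if (all(is.na(r))) NA_real_ else min(r, na.rm = TRUE))
  argm <- apply(mat, 1, function(r) if (all(is.na(r))) NA_character_
                else colnames(mat)[which.min(r)])
  structure(mat, class = c("xl_heatmap", class(mat)),
            min = mins, argmin = argm, all_unmappable = is.na(mins))
}

#' Satisfied-by-at-least-one-conformation verdicts
#'
#' A link violated on one conformation may simply have been formed in
#' another: the verdict is true iff the minimum over the link's numeric
#' cells is at most `cutoff`. Unmappable cells are ignored by the minimum
#' (never treated as infinite violations); a link unmappable everywhere
#' gets an `NA` verdict.
#'
#' @param heatmap a [distance_heatmap()] result (or plain matrix with links
#'   as rows).
#' @param cutoff Angstrom, default 30.
#' @return `data.frame(link, min_distance, best_member, satisfiable)`.
#' @export
satisfiable_by_any <- function(heatmap, cutoff = 30) {
  mat <- unclass(heatmap)
  mins <- apply(mat, 1, function(r) if (all(is.na(r))) NA_real_ else min(r, na.rm = TRUE))
  argm <- apply(mat, 1, function(r) if (all(is.na(r))) NA_character_
                else colnames(mat)[which.min(r)])
  data.frame(link = rownames(mat),
             min_distance = unname(mins),
             best_member = unname(argm),
             satisfiable = unname(mins <= cutoff),
             stringsAsFactors = FALSE)
}

#' Construct a rigid-body oligomer lattice
#'
#' Rigid copies of a base complex repeated by powers of one transform
#' (rotation then translation), modelling e.g. the head-to-tail repetition
#' of outer dynein arms along the axoneme: copy k has coordinates
#' T^(k-1)(base). The repeat transform is user input (taken from a
#' determined structure or tomogram), never assumed.
#'
#' @param base an [xl_structure()].
#' @param rotation 3x3 proper rotation matrix (orthonormal, det +1).
#' @param translation length-3 numeric, Angstrom.
#' @param n_copies number of copies, >= 2 (default 3).
#' @return An object of class `xl_lattice`.
#' @export
xl_lattice <- function(base, rotation = diag(3), translation = c(0, 0, 0),
                       n_copies = 3) {
  stopifnot(is_xl_structure(base), n_copies >= 2, length(translation) == 3)
  rotation <- as.matrix(rotation)
  if (!all(dim(rotation) == c(3, 3)) ||
      max(abs(crossprod(rotation) - diag(3))) > 1e-6 ||
      abs(det(rotation) - 1) > 1e-6)
    stop("rotation must be a proper rotation matrix (orthonormal, det +1)")
  structure(list(base = base, rotation = rotation,
                 translation = as.numeric(translation),
                 n_copies = as.integer(n_copies)),
            class = "xl_lattice")
}

#' Expand a lattice into one structure with copies as distinct chains
#'
#' Copy k's chains are suffixed `"_k"` (copy 1 is the base itself); copy k
#' coordinates apply the lattice transform k-1 times.
#'
#' @param lattice an [xl_lattice()].
#' @return An [xl_structure()] named `"<base id>_lattice"`.
#' @export
expand_lattice <- function(lattice) {
  pieces <- vector("list", lattice$n_copies)
  rot <- diag(3); tra <- c(0, 0, 0)
  for (k in seq_len(lattice$n_copies)) {
    copy <- transform_structure(lattice$base, rot, tra)
    r <- copy$residues
    r$chain <- paste0(r$chain, "_", k)
    pieces[[k]] <- r
    # compose one more application of T: p -> R p + t
    tra <- as.numeric(lattice$rotation %*% tra + lattice$translation)
    rot <- lattice$rotation %*% rot
  }
  xl_structure(paste0(lattice$base$id, "_lattice"),
               do.call(rbind, pieces))
}

#' Reinterpret violated intramolecular links as inter-copy links
#'
#' A link that is an extreme violation within one complex may join adjacent
#' copies of that complex in a lattice (head-to-tail oligomers): for each
#' link (i, j) the minimal distance over ordered copy pairs k != l between
#' copy k's residue i and copy l's residue j is computed, together with the
#' minimizing pair and a verdict `distance <= cutoff`. The copy-pair search
#' is exhaustive, avoiding adjacency assumptions.
#'
#' @param links an `xl_links` data frame (complex-level intramolecular
#'   links).
#' @param lattice an [xl_lattice()].
#' @param chain_map named list, group id -> chain id(s) of the base
#'   structure; defaults to mapping every group to all base chains.
#' @param cutoff Angstrom, default 30.
#' @param transfers optional per-group [residue_transfer()] list.
#' @return `data.frame(link, monomer_distance, lattice_distance, copy_a,
#'   copy_b, satisfied)`.
#' @export
reinterpret_intralinks <- function(links, lattice, chain_map = NULL,
                                   cutoff = 30, transfers = NULL) {
  base <- lattice$base
  if (is.null(chain_map)) {
    chains <- structure_chains(base)
    groups <- unique(c(links$group_a, links$group_b))
    chain_map <- stats::setNames(rep(list(chains), length(groups)), groups)
  }
  mono <- map_links(links, base, chain_map, transfers)
  n <- nrow(links)
  lat_d <- rep(NA_real_, n)
  copy_a <- copy_b <- rep(NA_integer_, n)
  # per-copy coordinates of each endpoint
  rot <- diag(3); tra <- c(0, 0, 0)
  copies <- vector("list", lattice$n_copies)
  for (k in seq_len(lattice$n_copies)) {
    copies[[k]] <- list(rotation = rot, translation = tra)
    tra <- as.numeric(lattice$rotation %*% tra + lattice$translation)
    rot <- lattice$rotation %*% rot
  }
  endpoint_coord <- function(group, residue) {
    e <- resolve_endpoint(base, group, residue, chain_map, transfers)
    if (!is.null(e$reason)) return(NULL)
    # minimal-distance rule is applied over chains later; here take all
    do.call(rbind, lapply(e$candidates, function(c) c$coord))
  }
  for (i in seq_len(n)) {
    pa <- endpoint_coord(links$group_a[i], links$residue_a[i])
    pb <- endpoint_coord(links$group_b[i], links$residue_b[i])
    if (is.null(pa) || is.null(pb)) next
    best <- Inf; bk <- NA_integer_; bl <- NA_integer_
    for (k in seq_len(lattice$n_copies)) for (l in seq_len(lattice$n_copies)) {
      if (k == l) next
      qa <- sweep(pa %*% t(copies[[k]]$rotation), 2, copies[[k]]$translation, `+`)
      qb <- sweep(pb %*% t(copies[[l]]$rotation), 2, copies[[l]]$translation, `+`)
      d2 <- outer(seq_len(nrow(qa)), seq_len(nrow(qb)), Vectorize(function(u, v)
        sum((qa[u, ] - qb[v, ])^2)))
      d <- sqrt(min(d2))
      if (d < best) { best <- d; bk <- k; bl <- l }
    }
    if (is.finite(best)) { lat_d[i] <- best; copy_a[i] <- bk; copy_b[i] <- bl }
  }
  data.frame(link = link_labels(links),
             monomer_distance = mono$distance,
             lattice_distance = lat_d,
             copy_a = copy_a, copy_b = copy_b,
             satisfied = lat_d <= cutoff,
             stringsAsFactors = FALSE)
}
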