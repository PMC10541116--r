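#' Optimal rigid-body superposition (Kabsch algorithm)
#'
#' Finds the proper rotation R and translation t minimizing the RMSD of
#' `R a_i + t` against `b_i` over corresponded coordinate rows, by SVD of
#' the cross-covariance of the centred sets. Reflections are corrected by
#' flipping the sign of the smallest singular direction when the
#' determinant would be -1, so R is always a proper rotation.
#'
#' @param coords_a,coords_b n x 3 numeric matrices of corresponded points
#'   (n >= 3, not all collinear).
#' @return An object of class `xl_superposition`: `rotation` (3x3),
#'   `translation` (length 3, Angstrom), `rmsd` (Angstrom), `n_atoms`.
#' @export
kabsch <- function(coords_a, coords_b) {
  coords_a <- as.matrix(coords_a); coords_b <- as.matrix(coords_b)
  if (!all(dim(coords_a) == dim(coords_b)) || ncol(coords_a) != 3)
    stop("coordinate sets must be equal-size n x 3 matrices")
  n <- nrow(coords_a)
  if (n < 3) stop("superposition needs at least 3 points")
  if (anyNA(coords_a) || anyNA(coords_b))
    stop("coordinate sets must not contain NA")
  ca <- colMeans(coords_a); cb <- colMeans(coords_b)
  a <- sweep(coords_a, 2, ca); b <- sweep(coords_b, 2, cb)
  sv_a <- svd(a)$d
  if (sv_a[2] < 1e-8 * max(sv_a[1], 1))
    stop("degenerate (collinear) coordinate set; rotation is not determined")
  h <- crossprod(a, b)            # 3x3 cross-covariance
  sv <- svd(h)
  d <- sign(det(sv$v %*% t(sv$u)))
  rot <- sv$v %*% diag(c(1, 1, d)) %*% t(sv$u)
  trans <- as.numeric(cb - rot %*% ca)
  fitted <- sweep(a %*% t(rot), 2, cb, `+`)
  rmsd <- sqrt(mean(rowSums((fitted - coords_b)^2)))
  structure(list(rotation = rot, translation = trans, rmsd = rmsd,
                 n_atoms = n, correspondence = "row-wise"),
            class = "xl_superposition")
}

#' @export
print.xl_superposition <- function(x, ...) {
  cat(sprintf("<xl_superposition> rmsd %.3f A over %d atom(s)\n",
              x$rmsd, x$n_atoms))
  invisible(x)
}

#' Apply a superposition to coordinates
#' @param superposition an [kabsch()] result.
#' @param coords n x 3 matrix.
#' @return Transformed n x 3 matrix.
#' @export
apply_superposition <- function(superposition, coords) {
  sweep(as.matrix(coords) %*% t(superposition$rotation), 2,
        superposition$translation, `+`)
}

# Resolved Calpha trace of one chain: m x 3 matrix with author numbers as
# rownames, in author order.
chain_ca_trace <- function(structure, chain) {
  res <- chain_residues(structure, chain)
  res <- res[!is.na(res$x), , drop = FALSE]
  m <- cbind(res$x, res$y, res$z)
  rownames(m) <- res$author_number
  m
}

#' Fit a candidate model onto a target chain
#'
#' Places a model's Calpha trace onto an (often unassigned) chain of a
#' target structure, either by sliding the model along the chain's resolved
#' Calpha positions and superposing at every offset (`"sliding-window"`),
#' or by corresponding residues through a global sequence alignment
#' (`"sequence-aligned"`). The minimal-RMSD placement wins; sliding-window
#' ties break toward the smallest offset.
#'
#' @param model_cas m x 3 matrix of the model's Calpha coordinates, in
#'   residue order.
#' @param target an [xl_structure()].
#' @param chain target chain id.
#' @param mode `"sliding-window"` (default) or `"sequence-aligned"`.
#' @param model_seq model sequence, required for `"sequence-aligned"`.
#' @param min_identity identity gate for the alignment mode.
#' @return A list of class `xl_fit`: `superposition` (the best
#'   [kabsch()] result), `offset` (0-based start along the resolved trace;
#'   `NA` in alignment mode), and `profile`
#'   (`data.frame(offset, rmsd)`, sliding-window only).
#' @export
fit_model_to_chain <- function(model_cas, target, chain,
                               mode = c("sliding-window", "sequence-aligned"),
                               model_seq = NULL, min_identity = 20) {
  mode <- match.arg(mode)
  model_cas <- as.matrix(model_cas)
  trace <- chain_ca_trace(target, chain)
  m <- nrow(model_cas)
  if (mode == "sliding-window") {
    if (m > nrow(trace))
      stop("model (", m, " residues) longer than the target's resolved ",
           "Calpha trace (", nrow(trace), ")")
    offsets <- 0:(nrow(trace) - m)
    rmsds <- vapply(offsets, function(o)
      kabsch(model_cas, trace[(o + 1):(o + m), , drop = FALSE])$rmsd,
      numeric(1))
    best_i <- which.min(rmsds)   # which.min takes the first (smallest offset)
    best_o <- offsets[best_i]
    sp <- kabsch(model_cas, trace[(best_o + 1):(best_o + m), , drop = FALSE])
    structure(list(superposition = sp, offset = best_o,
                   profile = data.frame(offset = offsets, rmsd = rmsds),
                   mode = mode),
              class = "xl_fit")
  } else {
    if (is.null(model_seq)) stop("sequence-aligned mode needs model_seq")
    ali <- global_align(model_seq, chain_sequence(target, chain))
    tr <- residue_transfer(ali, target, chain, min_identity)
    ok <- tr$status == "ok"
    if (sum(ok) < 3)
      stop("fewer than 3 aligned, resolved residues; cannot superpose")
    tgt <- trace[match(tr$author_number[ok], as.integer(rownames(trace))), ,
                 drop = FALSE]
    sp <- kabsch(model_cas[tr$source_pos[ok], , drop = FALSE], tgt)
    structure(list(superposition = sp, offset = NA_integer_,
                   profile = NULL, mode = mode, alignment = ali),
              class = "xl_fit")
  }
}

#' @export
print.xl_fit <- function(x, ...) {
  cat(sprintf("<xl_fit> mode %s, best rmsd %.3f A", x$mode,
              x$superposition$rmsd))
  if (!is.na(x$offset)) cat(" at offset ", x$offset, sep = "")
  cat("\n")
  invisible(x)
}

#' Check cross-link consistency of a model placement
#'
#' After placing a model into a target structure by a superposition, each
#' link's Calpha-Calpha distance between the placed model and the target is
#' computed and classified with the usual linker thresholds — the model
#' assignment is supported when the links it should explain are satisfied.
#'
#' @param superposition an [kabsch()] result (or an `xl_fit`).
#' @param model an [xl_structure()] holding the model in its own frame.
#' @param target an [xl_structure()].
#' @param links an `xl_links` data frame.
#' @param chain_map named list, group -> chain ids; model chains are
#'   addressed by their id suffixed `"_fit"` in the merged structure.
#' @param thresholds an [xl_thresholds()].
#' @param transfers optional per-group [residue_transfer()] list.
#' @return An `xl_mapped` data frame over the merged structure.
#' @export
check_crosslink_consistency <- function(superposition, model, target, links,
                                        chain_map,
                                        thresholds = xl_thresholds(),
                                        transfers = NULL) {
  if (inherits(superposition, "xl_fit"))
    superposition <- superposition$superposition
  placed <- transform_structure(model, superposition$rotation,
                                superposition$translation)
  pr <- placed$residues
  pr$chain <- paste0(pr$chain, "_fit")
  merged <- xl_structure(paste0(target$id, "+", model$id),
                         rbind(target$residues, pr))
  map_links(links, merged, chain_map, transfers, thresholds)
}
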