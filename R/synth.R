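AA20 <- c("A", "C", "D", "E", "F", "G", "H", "I", "K", "L",
          "M", "N", "P", "Q", "R", "S", "T", "V", "W", "Y")

#' Specification of a synthetic cross-linking study
#'
#' Fixes every stochastic ingredient of the generator: number and lengths
#' of proteins, chain geometry, how many true links are sampled within the
#' linker's reach, the rate of false (random-pair) links, the duplicate
#' rate, and the score/FDR distributions for true vs false links. All
#' randomness flows from `seed` through named sub-streams, so adding one
#' generator never perturbs another.
#'
#' @param seed master seed.
#' @param n_proteins number of synthetic proteins (default 5).
#' @param length_range inclusive residue-count range (default 60..120).
#' @param geometry `"random-walk"` (3.8 Angstrom steps, self-avoiding) or
#'   `"extended-helix"` (ideal alpha-helical Calpha trace).
#' @param n_true_links true links sampled from residue pairs within
#'   `true_max_dist` (default 60).
#' @param true_max_dist Angstrom, default 25 (comfortably within the 30
#'   Angstrom DSSO constraint).
#' @param false_rate fraction of emitted links that are false, in \[0, 1\]
#'   (default 0.1).
#' @param duplicate_rate probability that a link is emitted a second time,
#'   endpoint-swapped (default 0.1).
#' @param true_score,false_score,true_fdr,false_fdr sampling functions
#'   `function(n)`; defaults give scores passing the `> 40` filter and FDRs
#'   within 1 percent.
#' @return A list of class `synth_spec`.
#' @export
synth_spec <- function(seed = 1, n_proteins = 5, length_range = c(60, 120),
                       geometry = c("random-walk", "extended-helix"),
                       n_true_links = 60, true_max_dist = 25,
                       false_rate = 0.1, duplicate_rate = 0.1,
                       true_score = function(n) pmax(41, stats::rnorm(n, 120, 25)),
                       false_score = function(n) pmax(41, stats::rnorm(n, 60, 15)),
                       true_fdr = function(n) stats::runif(n, 0, 0.005),
                       false_fdr = function(n) stats::runif(n, 0, 0.01)) {
  geometry <- match.arg(geometry)
  stopifnot(false_rate >= 0, false_rate <= 1,
            duplicate_rate >= 0, duplicate_rate <= 1,
            true_max_dist > 0, n_proteins >= 1)
  structure(list(seed = seed, n_proteins = n_proteins,
                 length_range = length_range, geometry = geometry,
                 n_true_links = n_true_links, true_max_dist = true_max_dist,
                 false_rate = false_rate, duplicate_rate = duplicate_rate,
                 true_score = true_score, false_score = false_score,
                 true_fdr = true_fdr, false_fdr = false_fdr),
            class = "synth_spec")
}

# One self-avoiding random-walk Calpha trace: fixed 3.8 A steps, uniform
# random directions, minimum 3.0 A to every earlier Calpha.
random_walk_trace <- function(n, start = c(0, 0, 0), step = 3.8,
                              min_sep = 3.0, max_tries = 500) {
  pts <- matrix(NA_real_, n, 3)
  pts[1, ] <- start
  for (i in seq_len(n - 1)) {
    placed <- FALSE
    for (try in seq_len(max_tries)) {
      u <- stats::rnorm(3)
      u <- u / sqrt(sum(u^2))
      cand <- pts[i, ] + step * u
      prev <- pts[seq_len(max(1, i - 1)), , drop = FALSE]
      if (min(sqrt(rowSums(sweep(prev, 2, cand)^2))) >= min_sep) {
        pts[i + 1, ] <- cand
        placed <- TRUE
        break
      }
    }
    if (!placed) stop("self-avoiding walk stuck after ", max_tries, " tries")
  }
  pts
}

# Ideal alpha-helical Calpha trace: radius 2.3 A, rise 1.5 A per residue,
# 100 degrees per residue, axis +z through `start`.
helix_trace <- function(n, start = c(0, 0, 0), radius = 2.3, rise = 1.5,
                        twist_deg = 100) {
  theta <- (seq_len(n) - 1) * twist_deg * pi / 180
  cbind(start[1] + radius * cos(theta),
        start[2] + radius * sin(theta),
        start[3] + (seq_len(n) - 1) * rise)
}

#' Generate one synthetic protein structure with known Calpha geometry
#'
#' Consecutive Calpha spacing is 3.8 Angstrom (the trans-peptide
#' convention); random-walk chains are self-avoiding at 3.0 Angstrom. The
#' returned structure carries its amino-acid sequence (attribute
#' `"sequence"`), consistent with the residue count. Deterministic given
#' `seed`.
#'
#' @param length residue count.
#' @param geometry `"random-walk"` or `"extended-helix"`.
#' @param seed integer seed.
#' @param id structure id, `chain` chain id, `start` first-Calpha position.
#' @return An [xl_structure()] with attribute `"sequence"`.
#' @export
make_structure <- function(length, geometry = c("random-walk", "extended-helix"),
                           seed = 1, id = "SYN", chain = "A",
                           start = c(0, 0, 0)) {
  geometry <- match.arg(geometry)
  with_stream_seed(seed, paste0("structure/", id, "/", chain), {
    pts <- if (geometry == "random-walk") random_walk_trace(length, start)
      else helix_trace(length, start)
    seq <- paste(sample(AA20, length, replace = TRUE), collapse = "")
    st <- xl_structure(id, data.frame(
      chain = chain, author_number = seq_len(length), icode = "",
      aa = strsplit(seq, "")[[1]],
      x = pts[, 1], y = pts[, 2], z = pts[, 3],
      stringsAsFactors = FALSE))
    attr(st, "sequence") <- seq
    st
  })
}

#' Generate a multi-protein synthetic system
#'
#' One structure with one chain per protein (chains `A`, `B`, ...), the
#' matching FASTA sequences, a one-group-per-protein orthogroup map and the
#' chain map used for mapping links back. Chain start points are drawn in a
#' compact box so inter-protein residue pairs within linker reach exist.
#'
#' @param spec a [synth_spec()].
#' @return List with elements `structure`, `sequences` (named character),
#'   `orthomap` ([ortho_map()]), `chain_map`, `accessions`.
#' @export
make_synth_system <- function(spec = synth_spec()) {
  k <- spec$n_proteins
  acc <- sprintf("SYNP%02d", seq_len(k))
  grp <- sprintf("OG%04d", seq_len(k))
  chains <- LETTERS[seq_len(k)]
  lens <- with_stream_seed(spec$seed, "lengths",
    sample(spec$length_range[1]:spec$length_range[2], k, replace = TRUE))
  starts <- with_stream_seed(spec$seed, "starts",
    matrix(stats::runif(3 * k, -20, 20), k, 3))
  pieces <- vector("list", k)
  seqs <- character(k)
  for (i in seq_len(k)) {
    st <- make_structure(lens[i], spec$geometry, seed = spec$seed,
                         id = "SYSTEM", chain = chains[i],
                         start = starts[i, ])
    pieces[[i]] <- st$residues
    seqs[i] <- attr(st, "sequence")
  }
  structure_all <- xl_structure("SYSTEM", do.call(rbind, pieces))
  list(structure = structure_all,
       sequences = stats::setNames(seqs, acc),
       orthomap = ortho_map(stats::setNames(grp, acc),
                            stats::setNames(sprintf("GENE%d", seq_len(k)), grp)),
       chain_map = stats::setNames(as.list(chains), grp),
       accessions = stats::setNames(acc, chains))
}

#' Sample a synthetic cross-link table with ground truth
#'
#' True links are drawn uniformly from residue pairs whose Calpha distance
#' is at most `spec$true_max_dist`; false links uniformly from all residue
#' pairs; duplicates (endpoint-swapped re-observations) are injected at the
#' duplicate rate; scores and FDRs come from the spec's distributions. The
#' ground-truth table records each unique link's generating class and true
#' distance.
#'
#' @param system a [make_synth_system()] result.
#' @param spec the [synth_spec()] used to build the system.
#' @return List: `records` (`xl_records`, protein accessions and residue
#'   positions), `truth` (`data.frame` of unique planted links with `class`
#'   in `{"true", "false"}` and `true_distance`).
#' @export
sample_crosslinks <- function(system, spec = synth_spec()) {
  res <- system$structure$residues
  acc_of_chain <- system$accessions
  coords <- cbind(res$x, res$y, res$z)
  n <- nrow(res)
  d2 <- as.matrix(stats::dist(coords))^2
  within <- which(upper.tri(d2) & d2 <= spec$true_max_dist^2, arr.ind = TRUE)
  allpairs <- which(upper.tri(d2), arr.ind = TRUE)
  n_true <- spec$n_true_links
  n_false <- if (spec$false_rate >= 1) n_true
    else round(n_true * spec$false_rate / (1 - spec$false_rate))
  if (spec$false_rate >= 1) n_true <- 0
  if (n_true > nrow(within))
    stop("only ", nrow(within), " residue pairs within ", spec$true_max_dist,
         " A; cannot sample ", n_true, " true links")
  with_stream_seed(spec$seed, "crosslinks", {
    ti <- within[sample.int(nrow(within), n_true), , drop = FALSE]
    fi <- allpairs[sample.int(nrow(allpairs), n_false, replace = FALSE), ,
                   drop = FALSE]
    idx <- rbind(ti, fi)
    cls <- c(rep("true", n_true), rep("false", n_false))
    truth <- data.frame(
      protein_a = unname(acc_of_chain[res$chain[idx[, 1]]]),
      residue_a = res$author_number[idx[, 1]],
      protein_b = unname(acc_of_chain[res$chain[idx[, 2]]]),
      residue_b = res$author_number[idx[, 2]],
      class = cls,
      true_distance = sqrt(d2[idx]),
      stringsAsFactors = FALSE)
    # a false draw may coincide with a true pair; keep the first occurrence
    key <- paste(pmin(idx[, 1], idx[, 2]), pmax(idx[, 1], idx[, 2]))
    truth <- truth[!duplicated(key), , drop = FALSE]
    rownames(truth) <- NULL
    score <- numeric(nrow(truth))
    fdr <- numeric(nrow(truth))
    is_true <- truth$class == "true"
    score[is_true] <- spec$true_score(sum(is_true))
    score[!is_true] <- spec$false_score(sum(!is_true))
    fdr[is_true] <- spec$true_fdr(sum(is_true))
    fdr[!is_true] <- spec$false_fdr(sum(!is_true))
    records <- data.frame(
      protein_a = truth$protein_a, residue_a = truth$residue_a,
      protein_b = truth$protein_b, residue_b = truth$residue_b,
      score = score, fdr = fdr, dataset_id = "SYNTH",
      spectral_count = 1L, stringsAsFactors = FALSE)
    dup <- stats::runif(nrow(records)) < spec$duplicate_rate
    if (any(dup)) {
      extra <- records[dup, , drop = FALSE]
      extra <- data.frame(   # endpoint-swapped re-observation
        protein_a = extra$protein_b, residue_a = extra$residue_b,
        protein_b = extra$protein_a, residue_b = extra$residue_a,
        score = extra$score * 0.95, fdr = extra$fdr,
        dataset_id = "SYNTH", spectral_count = 1L,
        stringsAsFactors = FALSE)
      records <- rbind(records, extra)
    }
    perm <- sample.int(nrow(records))
    records <- records[perm, , drop = FALSE]
    rownames(records) <- NULL
    list(records = validate_xl_records(records), truth = truth)
  })
}

#' Hinge a structure into a conformational ensemble
#'
#' Members share all residues; in member m the residues past the pivot are
#' rotated by `angles[m]` about `axis` through the pivot's Calpha,
#' emulating a domain motion. Pre-pivot coordinates are identical across
#' members. Member 1 should usually use angle 0 (the input conformation).
#'
#' @param structure a single-chain [xl_structure()].
#' @param pivot author number of the hinge residue.
#' @param angles rotation angles in degrees, one member each (default
#'   `c(0, 60)`).
#' @param axis rotation axis (default z), normalised internally.
#' @param label ensemble label.
#' @return An [xl_ensemble()] with members `state1`, `state2`, ...
#' @export
make_ensemble <- function(structure, pivot, angles = c(0, 60),
                          axis = c(0, 0, 1), label = "hinge") {
  chain <- structure_chains(structure)
  if (length(chain) != 1) stop("make_ensemble expects a single-chain structure")
  res <- structure$residues
  pidx <- which(res$author_number == pivot)
  if (length(pidx) == 0) stop("pivot residue ", pivot, " not in structure")
  pc <- c(res$x[pidx], res$y[pidx], res$z[pidx])
  axis <- axis / sqrt(sum(axis^2))
  members <- lapply(seq_along(angles), function(m) {
    th <- angles[m] * pi / 180
    rot <- rotation_about_axis(axis, th)
    r <- res
    after <- which(r$author_number > pivot & !is.na(r$x))
    if (length(after) > 0) {
      p <- cbind(r$x[after], r$y[after], r$z[after])
      p <- sweep(sweep(p, 2, pc) %*% t(rot), 2, pc, `+`)
      r$x[after] <- p[, 1]; r$y[after] <- p[, 2]; r$z[after] <- p[, 3]
    }
    st <- xl_structure(paste0(structure$id, "_state", m), r)
    st
  })
  names(members) <- paste0("state", seq_along(angles))
  xl_ensemble(label, members)
}

# Rodrigues rotation matrix about a unit axis.
rotation_about_axis <- function(axis, theta) {
  k <- axis / sqrt(sum(axis^2))
  kx <- matrix(c(0, k[3], -k[2], -k[3], 0, k[1], k[2], -k[1], 0), 3, 3)
  diag(3) + sin(theta) * kx + (1 - cos(theta)) * (kx %*% kx)
}

#' Construct a head-to-tail oligomer test case with planted inter-copy links
#'
#' An extended helical monomer repeated by a pure translation of one
#' molecule length, with links planted between the last and first few
#' residues: each planted link spans more than `extreme_min` Angstrom
#' within the monomer but at most 25 Angstrom between adjacent copies — the
#' geometry that makes extreme intramolecular violations reinterpretable as
#' inter-copy links.
#'
#' @param seed integer seed.
#' @param length monomer length (default 120 residues, about 180 Angstrom
#'   end to end).
#' @param n_copies lattice copies (default 3).
#' @param n_links planted links (default 6).
#' @param extreme_min minimal monomer-frame distance of planted links
#'   (default 100).
#' @return List: `base` structure, `lattice` ([xl_lattice()]), `links`
#'   (`xl_links` of planted intramolecular links), `group` id used.
#' @export
make_oligomer_testcase <- function(seed = 1, length = 120, n_copies = 3,
                                   n_links = 6, extreme_min = 100) {
  base <- make_structure(length, "extended-helix", seed = seed, id = "OLIGO")
  res <- base$residues
  p <- cbind(res$x, res$y, res$z)
  # head-to-tail repeat: translate by one molecule length plus one step
  translation <- (p[length, ] - p[1, ]) + (p[length, ] - p[length - 1, ])
  lat <- xl_lattice(base, diag(3), translation, n_copies)
  ends <- with_stream_seed(seed, "oligo-links", {
    i <- sample((length - 2):length, n_links, replace = TRUE)
    j <- sample(1:3, n_links, replace = TRUE)
    cbind(i, j)
  })
  d_mono <- sqrt(rowSums((p[ends[, 1], , drop = FALSE] -
                            p[ends[, 2], , drop = FALSE])^2))
  keep <- d_mono > extreme_min
  ends <- ends[keep, , drop = FALSE]
  recs <- xl_records(protein_a = "OG_OLIGO", residue_a = pmin(ends[, 1], ends[, 2]),
                     protein_b = "OG_OLIGO", residue_b = pmax(ends[, 1], ends[, 2]),
                     score = 100, fdr = 0.001, dataset_id = "SYNTH")
  links <- deduplicate_links(recs)
  list(base = base, lattice = lat, links = links, group = "OG_OLIGO")
}

#' Write a synthetic study bundle to disk
#'
#' FASTA sequences, per-system PDB (Calpha trace), cross-link CSV,
#' orthogroup TSV and ground-truth TSV — the complete set of pipeline
#' inputs with known answers.
#'
#' @param dir output directory (created if needed).
#' @param spec a [synth_spec()].
#' @return Invisibly, a named list of the written paths plus the in-memory
#'   `system` and `xl` objects.
#' @export
write_synth_bundle <- function(dir, spec = synth_spec()) {
  dir.create(dir, showWarnings = FALSE, recursive = TRUE)
  system <- make_synth_system(spec)
  xl <- sample_crosslinks(system, spec)
  paths <- list(
    fasta = file.path(dir, "proteins.fasta"),
    pdb = file.path(dir, "system.pdb"),
    xl_csv = file.path(dir, "crosslinks.csv"),
    orthomap = file.path(dir, "orthogroups.tsv"),
    truth = file.path(dir, "ground_truth.tsv"))
  write_fasta(system$sequences, paths$fasta)
  write_structure_pdb(system$structure, paths$pdb)
  write_xl_table(xl$records, paths$xl_csv)
  om <- system$orthomap
  utils::write.table(
    data.frame(accession = names(om$entries), group = unname(om$entries),
               label = unname(om$group_names[om$entries])),
    paths$orthomap, sep = "\t", row.names = FALSE, col.names = FALSE,
    quote = FALSE)
  utils::write.table(xl$truth, paths$truth, sep = "\t", row.names = FALSE,
                     quote = FALSE)
  invisible(c(paths, list(system = system, xl = xl)))
}
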