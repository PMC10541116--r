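# Independent oracles, deliberately naive: exhaustive enumeration of global
# alignments (no dynamic programming) under the affine convention where a
# gap of length L costs open + L * extend.

# All monotone move strings from (0,0) to (la,lb); D consumes one residue
# of each sequence, U a residue of A only (gap in B), L of B only.
enum_move_strings <- function(la, lb) {
  if (la == 0 && lb == 0) return("")
  out <- character(0)
  if (la > 0 && lb > 0)
    out <- c(out, paste0("D", enum_move_strings(la - 1, lb - 1)))
  if (la > 0)
    out <- c(out, paste0("U", enum_move_strings(la - 1, lb)))
  if (lb > 0)
    out <- c(out, paste0("L", enum_move_strings(la, lb - 1)))
  out
}

# Match index pairs and gap cost of one move string (sequence-independent
# gap cost; maximal runs of U or L are separate gaps).
path_features <- function(moves, open, extend) {
  mv <- strsplit(moves, "")[[1]]
  i <- 0L; j <- 0L
  mi <- integer(0); mj <- integer(0)
  gapcost <- 0
  run <- ""
  runlen <- 0L
  close_run <- function() if (runlen > 0) open + runlen * extend else 0
  for (m in mv) {
    if (m == "D") {
      gapcost <- gapcost + close_run(); run <- ""; runlen <- 0L
      i <- i + 1L; j <- j + 1L
      mi <- c(mi, i); mj <- c(mj, j)
    } else {
      if (m != run) { gapcost <- gapcost + close_run(); run <- m; runlen <- 0L }
      runlen <- runlen + 1L
      if (m == "U") i <- i + 1L else j <- j + 1L
    }
  }
  gapcost <- gapcost + close_run()
  list(mi = mi, mj = mj, gapcost = gapcost)
}

# Optimal global alignment score by brute force over every alignment.
nw_enumerate_score <- function(a, b, mat, open = 11, extend = 1) {
  av <- strsplit(a, "")[[1]]; bv <- strsplit(b, "")[[1]]
  paths <- enum_move_strings(length(av), length(bv))
  best <- -Inf
  for (p in paths) {
    f <- path_features(p, open, extend)
    s <- -f$gapcost
    if (length(f$mi) > 0)
      s <- s + sum(mat[cbind(av[f$mi], bv[f$mj])])
    if (s > best) best <- s
  }
  best
}

# Vectorised variant: optimal scores for EVERY pair of sequences of the
# given lengths over an alphabet, as a (n_a x n_b) matrix. Enumerates
# paths once per length pair, then scores all sequence pairs at once.
nw_enumerate_all <- function(seqs_a, seqs_b, mat, open = 11, extend = 1) {
  la <- nchar(seqs_a[1]); lb <- nchar(seqs_b[1])
  A <- do.call(rbind, strsplit(seqs_a, ""))
  B <- do.call(rbind, strsplit(seqs_b, ""))
  best <- matrix(-Inf, length(seqs_a), length(seqs_b))
  for (p in enum_move_strings(la, lb)) {
    f <- path_features(p, open, extend)
    s <- matrix(-f$gapcost, length(seqs_a), length(seqs_b))
    for (k in seq_along(f$mi))
      s <- s + mat[A[, f$mi[k]], B[, f$mj[k]], drop = FALSE]
    best <- pmax(best, s)
  }
  best
}

# RMSD after optimal superposition, via numerical minimisation over Euler
# angles (independent of the closed-form Kabsch path).
rmsd_by_optim <- function(a, b) {
  a <- sweep(a, 2, colMeans(a)); b <- sweep(b, 2, colMeans(b))
  rot_euler <- function(ang) {
    cz <- cos(ang[1]); sz <- sin(ang[1])
    cy <- cos(ang[2]); sy <- sin(ang[2])
    cx <- cos(ang[3]); sx <- sin(ang[3])
    rz <- matrix(c(cz, sz, 0, -sz, cz, 0, 0, 0, 1), 3, 3)
    ry <- matrix(c(cy, 0, -sy, 0, 1, 0, sy, 0, cy), 3, 3)
    rx <- matrix(c(1, 0, 0, 0, cx, sx, 0, -sx, cx), 3, 3)
    rz %*% ry %*% rx
  }
  obj <- function(ang) sqrt(mean(rowSums((a %*% t(rot_euler(ang)) - b)^2)))
  best <- Inf
  for (start in list(c(0, 0, 0), c(pi / 2, 0, 0), c(0, pi / 2, 0),
                     c(0, 0, pi / 2), c(pi, pi / 3, -pi / 3), c(2, -1, 1))) {
    r <- stats::optim(start, obj, method = "Nelder-Mead",
                      control = list(maxit = 2000, reltol = 1e-12))
    best <- min(best, r$value)
  }
  best
}
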