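test_that("random-walk traces keep Calpha spacing and self-avoidance", {
  s <- make_structure(50, "random-walk", seed = 1, id = "W")
  p <- as.matrix(s$residues[, c("x", "y", "z")])
  steps <- sqrt(rowSums(diff(p)^2))
  expect_true(all(steps >= 3.7 & steps <= 3.9))
  d <- as.matrix(dist(p))
  diag(d) <- Inf
  expect_true(all(d >= 3.0 - 1e-9))
  expect_equal(nchar(attr(s, "sequence")), 50)

  s2 <- make_structure(50, "random-walk", seed = 1, id = "W")
  expect_identical(s$residues, s2$residues)  # deterministic under seed
  s3 <- make_structure(50, "random-walk", seed = 2, id = "W")
  expect_false(identical(s$residues$x, s3$residues$x))
})

test_that("extended helices follow the helical rise geometry", {
  n <- 40
  s <- make_structure(n, "extended-helix", seed = 1, id = "H")
  p <- as.matrix(s$residues[, c("x", "y", "z")])
  # independent geometry: radius 2.3, rise 1.5/residue, 100 deg/residue
  theta <- (seq_len(n) - 1) * 100 * pi / 180
  expected_end_to_end <- sqrt(
    (2.3 * (cos(theta[n]) - cos(theta[1])))^2 +
    (2.3 * (sin(theta[n]) - sin(theta[1])))^2 +
    ((n - 1) * 1.5)^2)
  expect_equal(sqrt(sum((p[n, ] - p[1, ])^2)), expected_end_to_end,
               tolerance = 1e-9)
  steps <- sqrt(rowSums(diff(p)^2))
  expect_true(all(abs(steps - steps[1]) < 1e-9))
  expect_true(all(steps >= 3.7 & steps <= 3.9))
})

test_that("hinged ensembles rotate only past the pivot", {
  s <- make_structure(30, "random-walk", seed = 6, id = "H")
  ens0 <- make_ensemble(s, pivot = 15, angles = c(0, 0))
  expect_identical(ens0$members[[1]]$residues, ens0$members[[2]]$residues)

  ens <- make_ensemble(s, pivot = 15, angles = c(0, 120), axis = c(1, 0, 0))
  a <- ens$members[[1]]$residues; b <- ens$members[[2]]$residues
  pre <- a$author_number <= 15
  expect_equal(a[pre, c("x", "y", "z")], b[pre, c("x", "y", "z")])
  expect_false(isTRUE(all.equal(a[!pre, c("x", "y", "z")],
                                b[!pre, c("x", "y", "z")])))

  # 180 degrees: displacement of a rotated point is twice its distance to
  # the axis through the pivot
  ens180 <- make_ensemble(s, pivot = 15, angles = c(0, 180), axis = c(0, 0, 1))
  a0 <- ens180$members[[1]]$residues; b0 <- ens180$members[[2]]$residues
  pc <- unlist(a0[a0$author_number == 15, c("x", "y", "z")])
  term <- which(a0$author_number == 30)
  pt <- unlist(a0[term, c("x", "y", "z")])
  dist_to_axis <- sqrt(sum((pt[1:2] - pc[1:2])^2))  # axis = z through pivot
  displacement <- sqrt(sum((unlist(b0[term, c("x", "y", "z")]) - pt)^2))
  expect_equal(displacement, 2 * dist_to_axis, tolerance = 1e-9)
})

test_that("with zero false rate every emitted link is within the true range", {
  spec <- synth_spec(seed = 3, false_rate = 0, duplicate_rate = 0)
  sys <- make_synth_system(spec)
  xl <- sample_crosslinks(sys, spec)
  expect_true(all(xl$truth$class == "true"))
  expect_true(all(xl$truth$true_distance <= spec$true_max_dist))
  expect_equal(nrow(xl$records), spec$n_true_links)
})

test_that("pure false links follow the uniform-pair null, not the linker range", {
  spec <- synth_spec(seed = 8, false_rate = 1, n_true_links = 80)
  sys <- make_synth_system(spec)
  xl <- sample_crosslinks(sys, spec)
  expect_true(all(xl$truth$class == "false"))
  # oracle: quantiles of the all-pairs distance distribution
  p <- as.matrix(sys$structure$residues[, c("x", "y", "z")])
  d_all <- as.matrix(dist(p))[upper.tri(diag(nrow(p)))]
  # a uniform draw from all pairs must reach far beyond the linker range
  expect_gt(max(xl$truth$true_distance), 40)
  expect_gt(mean(xl$truth$true_distance), quantile(d_all, 0.25))
  expect_lt(mean(xl$truth$true_distance), quantile(d_all, 0.75))
})

test_that("deduplication recovers exactly the planted unique set", {
  spec <- synth_spec(seed = 5, n_true_links = 100, false_rate = 0,
                     duplicate_rate = 0.5)
  sys <- make_synth_system(spec)
  xl <- sample_crosslinks(sys, spec)
  expect_gt(nrow(xl$records), 100)  # duplicates present
  links <- deduplicate_links(xl$records)
  canon <- function(ga, ra, gb, rb) {
    e1 <- paste(ga, ra); e2 <- paste(gb, rb)
    paste(pmin(e1, e2), pmax(e1, e2), sep = "|")
  }
  got <- sort(canon(links$group_a, links$residue_a,
                    links$group_b, links$residue_b))
  want <- sort(canon(xl$truth$protein_a, xl$truth$residue_a,
                     xl$truth$protein_b, xl$truth$residue_b))
  expect_equal(got, want)
  expect_equal(nrow(links), nrow(xl$truth))
})

test_that("oligomer test cases plant extreme violations satisfiable in-lattice", {
  oc <- make_oligomer_testcase(seed = 11)
  ri <- reinterpret_intralinks(oc$links, oc$lattice, cutoff = 25)
  expect_true(all(ri$satisfied))
  expect_true(all(ri$monomer_distance > 100))

  # negative control: shuffled endpoints fall back to background rates
  set.seed(40)
  n_res <- nrow(oc$base$residues)
  shuffled <- deduplicate_links(xl_records(
    oc$links$group_a, sample(20:60, nrow(oc$links)),
    oc$links$group_b, sample(61:100, nrow(oc$links)),
    score = 100, fdr = 0.001))
  ri_neg <- reinterpret_intralinks(shuffled, oc$lattice, cutoff = 25)
  expect_lt(mean(ri_neg$satisfied), mean(ri$satisfied))

  oc2 <- make_oligomer_testcase(seed = 11)
  expect_identical(oc$links, oc2$links)  # deterministic under seed
})

test_that("synthetic bundles round-trip through their on-disk formats", {
  dir <- withr::local_tempdir()
  spec <- synth_spec(seed = 17, n_proteins = 3, n_true_links = 25)
  bundle <- write_synth_bundle(dir, spec)
  expect_true(all(file.exists(unlist(bundle[c("fasta", "pdb", "xl_csv",
                                              "orthomap", "truth")]))))
  seqs <- read_fasta(bundle$fasta)
  expect_identical(seqs, bundle$system$sequences)
  st <- read_structure(bundle$pdb)
  expect_equal(st$residues[, c("chain", "author_number")],
               bundle$system$structure$residues[, c("chain", "author_number")])
  expect_equal(st$residues$x, bundle$system$structure$residues$x,
               tolerance = 1e-3)  # PDB stores 3 decimals
  rec <- read_xl_table(bundle$xl_csv,
                       xl_dialect(dataset_id = "Dataset",
                                  spectral_count = "SpectralCount"))
  expect_equal(nrow(rec), nrow(bundle$xl$records))
  om <- read_orthomap(bundle$orthomap)
  expect_identical(om$entries, bundle$system$orthomap$entries)
})
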