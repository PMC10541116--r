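test_that("score filter is strict and FDR filter inclusive at the boundary", {
  r <- recs(c("A", "A", "A"), 1:3, c("B", "B", "B"), 4:6,
            score = c(40, 40.1, 55), fdr = 0.005)
  expect_equal(nrow(filter_records(r, score_min = 40)), 2)

  r2 <- recs(c("A", "A"), 1:2, c("B", "B"), 3:4, score = 50,
             fdr = c(0.01, 0.011))
  f2 <- filter_records(r2, fdr_max = 0.01)
  expect_equal(nrow(f2), 1)
  expect_equal(f2$fdr, 0.01)
  expect_equal(attr(f2, "removed_by_fdr"), 1)
})

test_that("filtering matches a brute-force count on 1000 synthetic records", {
  set.seed(2)
  n <- 1000
  r <- recs(sprintf("P%d", sample(30, n, TRUE)), sample(400, n, TRUE),
            sprintf("Q%d", sample(30, n, TRUE)), sample(400, n, TRUE),
            score = runif(n, 20, 80), fdr = runif(n, 0, 0.03))
  f <- filter_records(r, fdr_max = 0.01, score_min = 40)
  expect_equal(nrow(f), sum(r$fdr <= 0.01 & r$score > 40))
  expect_equal(attr(f, "removed_by_score"), sum(r$score <= 40))
  # order preserved
  expect_true(!is.unsorted(match(paste(f$protein_a, f$residue_a, f$score),
                                 paste(r$protein_a, r$residue_a, r$score))))
})

test_that("symmetric and repeated records collapse to one unique link", {
  r <- recs(c("A", "B", "A"), c(10, 20, 10), c("B", "A", "B"), c(20, 10, 20),
            score = c(50, 60, 45))
  l <- deduplicate_links(r)
  expect_equal(nrow(l), 1)
  expect_equal(l$support, 3L)
  expect_equal(l$best_score, 60)
  expect_equal(l$kind, "intermolecular")

  r2 <- recs(c("A", "A"), c(10, 50), c("A", "A"), c(50, 10))
  l2 <- deduplicate_links(r2)
  expect_equal(nrow(l2), 1)
  expect_equal(l2$kind, "intramolecular")
  expect_equal(l2$residue_a, 10L)  # canonical order
})

test_that("unique-link count equals the brute-force set of frozen pairs", {
  set.seed(4)
  n <- 500
  r <- recs(sprintf("G%d", sample(10, n, TRUE)), sample(200, n, TRUE),
            sprintf("G%d", sample(10, n, TRUE)), sample(200, n, TRUE))
  l <- deduplicate_links(r)
  frozen <- unique(vapply(seq_len(n), function(i) {
    e <- sort(c(paste(r$protein_a[i], r$residue_a[i]),
                paste(r$protein_b[i], r$residue_b[i])))
    paste(e, collapse = "|")
  }, character(1)))
  expect_equal(nrow(l), length(frozen))
  expect_true(all(l$kind == ifelse(l$group_a == l$group_b,
                                   "intramolecular", "intermolecular")))
})

test_that("deduplication is idempotent and invariant under permutation/swap", {
  set.seed(8)
  n <- 300
  pa <- sprintf("G%d", sample(6, n, TRUE)); ra <- sample(100, n, TRUE)
  pb <- sprintf("G%d", sample(6, n, TRUE)); rb <- sample(100, n, TRUE)
  ok <- !(pa == pb & ra == rb)  # drop accidental self-links
  n <- sum(ok)
  r <- recs(pa[ok], ra[ok], pb[ok], rb[ok], score = runif(n, 41, 100))
  l <- deduplicate_links(r)

  # permute records
  perm <- r[sample(n), ]
  expect_equal(as.data.frame(deduplicate_links(perm)), as.data.frame(l),
               ignore_attr = TRUE)

  # swap endpoints of a random subset
  swapped <- as.data.frame(r)
  idx <- sample(n, 150)
  tmp <- swapped[idx, c("protein_a", "residue_a")]
  swapped[idx, c("protein_a", "residue_a")] <-
    swapped[idx, c("protein_b", "residue_b")]
  swapped[idx, c("protein_b", "residue_b")] <- tmp
  expect_equal(as.data.frame(deduplicate_links(validate_xl_records(swapped))),
               as.data.frame(l), ignore_attr = TRUE)

  # idempotence: expanding each unique link into `support` records and
  # re-deduplicating reproduces the link set
  expanded <- l[rep(seq_len(nrow(l)), l$support), ]
  expanded_rec <- xl_records(expanded$group_a, expanded$residue_a,
                             expanded$group_b, expanded$residue_b,
                             score = expanded$best_score)
  l2 <- deduplicate_links(expanded_rec)
  expect_equal(l2[, 1:6], as.data.frame(l)[, 1:6], ignore_attr = TRUE)
})

test_that("network summary identities hold, including on empty input", {
  empty <- deduplicate_links(recs(character(), integer(), character(), integer()))
  s0 <- summarize_network(empty)
  expect_equal(s0$n_unique_links, 0)
  expect_equal(s0$n_proteins, 0)

  r <- recs(c("A", "B", "A"), c(1, 2, 3), c("B", "C", "A"), c(9, 8, 7))
  l <- deduplicate_links(r)
  s <- summarize_network(l, r)
  expect_equal(s$n_proteins, 3)
  expect_equal(s$n_records, 3)
  expect_equal(s$n_intramolecular + s$n_intermolecular, s$n_unique_links)
  expect_lte(s$n_unique_links, s$n_records)

  set.seed(10)
  n <- 400
  pa <- sprintf("G%d", sample(7, n, TRUE)); ra <- sample(50, n, TRUE)
  pb <- sprintf("G%d", sample(7, n, TRUE)); rb <- sample(50, n, TRUE)
  ok2 <- !(pa == pb & ra == rb)
  rr <- recs(pa[ok2], ra[ok2], pb[ok2], rb[ok2])
  ll <- deduplicate_links(rr)
  ss <- summarize_network(ll, rr)
  expect_equal(ss$n_intramolecular + ss$n_intermolecular, ss$n_unique_links)
  expect_lte(ss$n_unique_links, ss$n_records)
  expect_equal(ss$n_proteins, length(unique(c(ll$group_a, ll$group_b))))
})

test_that("arc-diagram data lists intra and inter arcs per protein", {
  r <- recs(c("A", "A"), c(10, 30), c("A", "B"), c(50, 7))
  l <- deduplicate_links(r)
  arcs <- arc_diagram_data(l, c(A = 100, B = 60), "A")
  expect_equal(nrow(arcs), 2)
  expect_setequal(arcs$kind, c("intra", "inter"))
  intra <- arcs[arcs$kind == "intra", ]
  expect_equal(sort(c(intra$pos_i, intra$pos_j)), c(10, 50))
  inter <- arcs[arcs$kind == "inter", ]
  expect_equal(inter$partner, "B")
  expect_equal(inter$partner_pos, 7)
  expect_warning(empty <- arc_diagram_data(l, c(A = 100), "Zzz"), "Zzz")
  expect_equal(nrow(empty), 0)
})

test_that("arc multiset equals a direct filter of the link table", {
  set.seed(12)
  n <- 200
  r <- recs(sprintf("G%d", sample(5, n, TRUE)), sample(80, n, TRUE),
            sprintf("G%d", sample(5, n, TRUE)), sample(80, n, TRUE))
  l <- deduplicate_links(r)
  lens <- setNames(rep(100, 5), sprintf("G%d", 1:5))
  arcs <- arc_diagram_data(l, lens, "G3")
  expect_equal(nrow(arcs), sum(l$group_a == "G3" | l$group_b == "G3"))
  expect_equal(sum(arcs$kind == "intra"),
               sum(l$group_a == "G3" & l$group_b == "G3"))
})
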