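test_that("Calpha distances are Euclidean, symmetric and non-negative", {
  s <- struct_from_coords(rbind(c(0, 0, 0), c(3, 4, 0)))
  expect_equal(as.numeric(ca_distance(s, "A", 1, "A", 2)), 5)
  expect_equal(as.numeric(ca_distance(s, "A", 2, "A", 1)), 5)
  expect_equal(as.numeric(ca_distance(s, "A", 1, "A", 1)), 0)

  set.seed(3)
  for (i in 1:100) {
    p <- matrix(rnorm(6, sd = 20), 2)
    st <- struct_from_coords(p)
    expect_equal(as.numeric(ca_distance(st, "A", 1, "A", 2)),
                 sqrt(sum((p[1, ] - p[2, ])^2)))
  }
})

test_that("distances are invariant under rigid transformation of the structure", {
  set.seed(6)
  s <- struct_from_coords(matrix(rnorm(30, sd = 15), 10))
  rot <- random_rotation()
  s2 <- axoxl:::transform_structure(s, rot, c(12, -7, 30))
  for (i in 1:9)
    expect_equal(as.numeric(ca_distance(s2, "A", i, "A", i + 1)),
                 as.numeric(ca_distance(s, "A", i, "A", i + 1)),
                 tolerance = 1e-10)
})

test_that("distance categories follow the inclusive DSSO boundaries", {
  th <- xl_thresholds()
  expect_equal(classify_distance(30, th), "satisfied")   # <= 30 is satisfied
  expect_equal(classify_distance(29.99, th), "satisfied")
  expect_equal(classify_distance(35, th), "moderate")    # 30 < d <= 40
  expect_equal(classify_distance(40, th), "moderate")
  expect_equal(classify_distance(40.01, th), "violated")
  expect_equal(classify_distance(100, th), "violated")
  expect_equal(classify_distance(150, th), "extreme")    # > 100
  expect_equal(classify_distance(c(10, NA, 101), th),
               c("satisfied", NA, "extreme"))
  expect_error(xl_thresholds(40, 30, 100), "satisfied <= moderate")
  expect_error(classify_distance(-1, th), "non-negative")
})

test_that("raising the satisfied cutoff never decreases the within count", {
  set.seed(19)
  d <- runif(200, 0, 120)
  counts <- vapply(seq(5, 100, by = 5), function(cut)
    sum(classify_distance(d, xl_thresholds(cut, cut + 1, 150)) == "satisfied"),
    numeric(1))
  expect_true(all(diff(counts) >= 0))
})

test_that("links map to numeric distances or carry an unmappable reason", {
  s <- struct_from_coords(rbind(c(0, 0, 0), c(10, 0, 0), c(0, 24, 0)))
  links <- deduplicate_links(recs(c("OGA", "OGA"), c(1, 1),
                                  c("OGA", "OGX"), c(3, 2),
                                  fdr = 0.001))
  m <- map_links(links, s, chain_map = list(OGA = "A"))
  intra <- m[m$group_b == "OGA", ]
  expect_equal(intra$distance, 24)
  expect_equal(intra$category, "satisfied")
  absent <- m[m$group_b == "OGX", ]
  expect_true(is.na(absent$distance))
  expect_equal(absent$reason, "protein_absent")
})

test_that("homo-oligomer links take the minimal-distance chain pair", {
  # two copies of a 3-residue chain, copy B offset by (100, 0, 0)
  base <- rbind(c(0, 0, 0), c(4, 0, 0), c(8, 0, 0))
  s <- merge_structures("DIMER",
                        struct_from_coords(base, chain = "A"),
                        struct_from_coords(sweep(base, 2, c(100, 0, 0), `+`),
                                           chain = "B"))
  links <- deduplicate_links(recs("OG1", 1, "OG1", 3, fdr = 0.001))
  m <- map_links(links, s, chain_map = list(OG1 = c("A", "B")))
  # brute force over the 4 chain pairings
  cands <- c(
    AA = 8, BB = 8,
    AB = sqrt(sum((base[1, ] - (base[3, ] + c(100, 0, 0)))^2)),
    BA = sqrt(sum(((base[1, ] + c(100, 0, 0)) - base[3, ])^2)))
  expect_equal(m$distance, min(cands))
  expect_equal(unname(c(m$chain_a, m$chain_b)), c("A", "A"))

  # planted shorter inter-copy geometry must win over the same-chain pair
  s2 <- merge_structures("DIMER2",
                         struct_from_coords(rbind(c(0, 0, 0), c(50, 0, 0),
                                                  c(120, 0, 0)), chain = "A"),
                         struct_from_coords(rbind(c(118, 0, 0), c(150, 0, 0),
                                                  c(190, 0, 0)), chain = "B"))
  m2 <- map_links(links, s2, chain_map = list(OG1 = c("A", "B")))
  expect_equal(m2$distance, 2)  # A:1 (0) vs B:3 is 190; A:3 (120) vs B:... min is |120-118|
  expect_equal(unname(c(m2$chain_a, m2$chain_b)), c("B", "A"))
})

test_that("satisfaction summary counts, fractions and intra/inter means", {
  s <- struct_from_coords(rbind(c(0, 0, 0), c(10, 0, 0), c(20, 0, 0),
                                c(35, 0, 0), c(200, 0, 0)))
  links <- deduplicate_links(recs(
    c("OG1", "OG1", "OG1", "OG1"), c(1, 1, 1, 1),
    c("OG1", "OG1", "OG1", "OG1"), c(2, 3, 4, 5), fdr = 0.001))
  m <- map_links(links, s, chain_map = list(OG1 = "A"))
  ss <- satisfaction_summary(m)
  expect_equal(ss$n_mapped, 4)
  expect_equal(ss$n_within_satisfied, 2)  # 10, 20
  expect_equal(ss$n_within_moderate, 3)   # + 35
  expect_equal(ss$n_extreme, 1)           # 200
  expect_equal(ss$frac_within_satisfied, 0.5)
  expect_true(ss$n_within_satisfied <= ss$n_within_moderate)
  expect_lte(ss$n_within_moderate, ss$n_mapped)
  expect_equal(sum(ss$histogram$intra_n), 4)
  expect_equal(sum(ss$histogram$inter_n), 0)

  empty <- satisfaction_summary(m[0, ])
  expect_equal(empty$n_mapped, 0)
  expect_equal(empty$frac_within_satisfied, 0)
})

test_that("a synthetic cohort's summary matches brute force", {
  spec <- synth_spec(seed = 5, n_true_links = 40, false_rate = 0.2)
  sys <- make_synth_system(spec)
  xl <- sample_crosslinks(sys, spec)
  rec <- collapse_to_orthogroups(xl$records, sys$orthomap)
  links <- deduplicate_links(filter_records(rec))
  m <- map_links(links, sys$structure, sys$chain_map)
  ss <- satisfaction_summary(m)
  d <- m$distance[!is.na(m$distance)]
  expect_equal(ss$n_mapped, length(d))
  expect_equal(ss$n_within_satisfied, sum(d <= 30))
  expect_equal(ss$n_within_moderate, sum(d <= 40))
  expect_equal(ss$frac_within_moderate, sum(d <= 40) / length(d))
  expect_equal(ss$mean_distance_intra,
               mean(m$distance[m$kind == "intramolecular" & !is.na(m$distance)]))
})

test_that("zero-noise synthetic links are classified to ground truth exactly", {
  spec <- synth_spec(seed = 13, false_rate = 0, duplicate_rate = 0)
  sys <- make_synth_system(spec)
  xl <- sample_crosslinks(sys, spec)
  rec <- collapse_to_orthogroups(xl$records, sys$orthomap)
  links <- deduplicate_links(rec)
  m <- map_links(links, sys$structure, sys$chain_map)
  # all true links were sampled at <= 25 A; mapping back must recover that
  expect_true(all(!is.na(m$distance)))
  expect_true(all(m$distance <= 25 + 1e-9))
  expect_true(all(m$category == "satisfied"))
})
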