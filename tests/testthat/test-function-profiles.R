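test_that("profiles aggregate record counts to the level ancestor", {
  cat4 <- tiny_hierarchy()
  # two functions under the same h1; counts 3 + 2 roll up to 5
  h1 <- names(which.max(table(cat4$paths$h1)))
  funs <- cat4$paths$fun[cat4$paths$h1 == h1][1:2]
  recs <- records_from(cat4, funs, c(3L, 2L))
  p1 <- build_profile(recs, 1)
  expect_equal(unname(p1$counts[h1]), 5)
})

test_that("hand-aggregated level-2 relative abundances are 0.4 and 0.6", {
  # 3 functions under 2 h2 parents with counts (4, 1, 5):
  # parent A gets 4, parent B gets 1 + 5 = 6 -> RA (0.4, 0.6)
  cat4 <- tiny_hierarchy()
  p <- cat4$paths
  sizes <- sort(table(p$h2), decreasing = TRUE)
  h2s <- c(names(sizes)[2], names(sizes)[1])  # second category holds 2 functions
  fa <- p$fun[p$h2 == h2s[1]][1]
  fb <- p$fun[p$h2 == h2s[2]][1:2]
  recs <- records_from(cat4, c(fa, fb), c(4L, 1L, 5L))
  p2 <- build_profile(recs, 2)
  expect_equal(unname(p2$rel_abundance[h2s[1]]), 0.4)
  expect_equal(unname(p2$rel_abundance[h2s[2]]), 0.6)
  expect_equal(sum(p2$rel_abundance), 1, tolerance = 1e-9)
})

test_that("unknown-function records are excluded from abundances but tracked", {
  cat4 <- tiny_hierarchy()
  recs <- records_from(cat4, cat4$paths$fun[1:2], c(6L, 2L))
  recs[2, c("h1", "h2", "h3", "fun")] <- NA
  p <- build_profile(recs, 1)
  expect_equal(p$unknown_fraction, 2 / 8)
  expect_equal(sum(p$rel_abundance), 1)
  expect_equal(p$total_known, 6)
})

test_that("empty records give an empty profile with undefined unknown fraction", {
  p <- build_profile(data.frame(), 1)
  expect_length(p$counts, 0)
  expect_true(is.na(p$unknown_fraction))
})

test_that("mixed samples and bad levels are rejected", {
  cat4 <- tiny_hierarchy()
  recs <- rbind(records_from(cat4, cat4$paths$fun[1], 1L, sample_id = "A"),
                records_from(cat4, cat4$paths$fun[2], 1L, sample_id = "B"))
  expect_error(build_profile(recs, 1), "mix")
  expect_error(build_profile(records_from(cat4, cat4$paths$fun[1], 1L), 5), "1..4")
})

test_that("hierarchical conservation: level-k counts aggregate to level-(k-1)", {
  cat4 <- generate_function_catalog(c(3, 6, 12, 40), seed = 6)
  com <- generate_community(community_config(8, "lognormal", seed = 6), cat4)
  recs <- sample_gene_catalog(com, "S", depth_scale = 5000, seed = 6)
  profs <- lapply(1:4, function(l) build_profile(recs, l))
  parent_map <- list(cat4$parent$h2, cat4$parent$h3, cat4$parent$fun)
  for (k in 2:4) {
    fine <- profs[[k]]$counts
    rolled <- tapply(fine, parent_map[[k - 1]][names(fine)], sum)
    coarse <- profs[[k - 1]]$counts
    expect_equal(as.numeric(rolled[names(coarse)]), as.numeric(coarse))
    expect_equal(sum(profs[[k]]$rel_abundance), 1, tolerance = 1e-9)
  }
})

test_that("core and pan follow set algebra with the declared gene-sequence counts", {
  pA <- profile_from_counts("S1", 4, c(A = 4, B = 2, C = 1))
  pB <- profile_from_counts("S2", 4, c(B = 1, C = 3, D = 2))
  pC <- profile_from_counts("S3", 4, c(B = 7, C = 2))
  cf <- core_functions(list(pA, pB, pC))
  expect_equal(cf$core, c("B", "C"))
  expect_equal(cf$pan, c("A", "B", "C", "D"))
  # two-sample hand sum: S1{B:2,C:1} + S2{B:1,C:3} = 7
  cf2 <- core_functions(list(pA, pB))
  expect_equal(cf2$core_gene_sequence_count, 2 + 1 + 1 + 3)
  # single sample: core = pan = own set
  cf1 <- core_functions(list(pA))
  expect_equal(cf1$core, cf1$pan)
  expect_equal(cf1$core_gene_sequence_count, cf1$pan_gene_sequence_count)
})

test_that("adding a sample never grows the core and never shrinks the pan", {
  withr::with_seed(77, {
    universe <- LETTERS[1:12]
    profs <- lapply(1:6, function(i) {
      f <- sample(universe, sample(3:10, 1))
      profile_from_counts(paste0("S", i), 4,
                          stats::setNames(sample(1:5, length(f), replace = TRUE), f))
    })
    for (k in 2:6) {
      prev <- core_functions(profs[seq_len(k - 1)])
      cur <- core_functions(profs[seq_len(k)])
      expect_true(all(cur$core %in% prev$core))
      expect_true(all(prev$pan %in% cur$pan))
    }
  })
})

test_that("enrichment matches the declared percent formula and sentinels", {
  a <- profile_from_counts("a", 2, c(X = 2, Y = 1, Z = 1))
  b <- profile_from_counts("b", 2, c(X = 1, Y = 2, W = 1))
  e <- enrichment_signature(a, b)
  ex <- function(cat, col) e[e$category == cat, col]
  expect_equal(ex("X", "enrichment_pct"), 100)           # 0.5 vs 0.25
  expect_equal(ex("Z", "status"), "exclusive_a")
  expect_true(is.na(ex("Z", "enrichment_pct")))
  expect_equal(ex("W", "enrichment_pct"), -100)          # absent from a
  # identical profiles -> 0 everywhere
  e0 <- enrichment_signature(a, a)
  expect_true(all(e0$enrichment_pct == 0))
  expect_error(enrichment_signature(a, profile_from_counts("b", 3, c(X = 1))),
               "levels")
})

test_that("enrichment antisymmetry: (1 + e_ab/100)(1 + e_ba/100) = 1", {
  withr::with_seed(5, {
    for (i in 1:5) {
      cats <- paste0("c", 1:8)
      a <- profile_from_counts("a", 2, stats::setNames(sample(1:50, 8), cats))
      b <- profile_from_counts("b", 2, stats::setNames(sample(1:50, 8), cats))
      eab <- enrichment_signature(a, b)$enrichment_pct
      eba <- enrichment_signature(b, a)$enrichment_pct
      expect_equal((1 + eab / 100) * (1 + eba / 100), rep(1, 8), tolerance = 1e-12)
    }
  })
})

test_that("min_abundance omits categories rare in both profiles", {
  a <- profile_from_counts("a", 2, c(X = 98, Y = 1, Z = 1))
  b <- profile_from_counts("b", 2, c(X = 96, Y = 3, Z = 1))
  e <- enrichment_signature(a, b, min_abundance = 0.02)
  expect_false("Z" %in% e$category)  # 1% in both
  expect_true(all(c("X", "Y") %in% e$category))
})

test_that("pathway-unique protein counts give the declared percent excess", {
  cat4 <- generate_function_catalog(c(1, 1, 1, 20), seed = 8)
  h1 <- cat4$levels$h1[1]
  funs <- cat4$levels$fun
  ra <- records_from(cat4, funs[1:7], rep(1L, 7), sample_id = "A")
  rb <- records_from(cat4, funs[8:12], rep(1L, 5), sample_id = "B")
  res <- pathway_unique_proteins(ra, rb, h1, cat4)
  expect_equal(res$n_unique_a, 7L)
  expect_equal(res$n_unique_b, 5L)
  expect_equal(res$percent_excess, 40)
  # identical repertoires -> undefined
  same <- pathway_unique_proteins(ra, ra, h1, cat4)
  expect_equal(same$status, "undefined")
  # b empty under the pathway -> exclusive sentinel
  excl <- pathway_unique_proteins(ra, rb[0, ], h1, cat4)
  expect_equal(excl$status, "exclusive_a")
  expect_error(pathway_unique_proteins(ra, rb, "bogus", cat4), "unknown")
})

test_that("PCA coordinates match an independent eigendecomposition", {
  counts <- list(c(a = 10, b = 1, c = 4), c(a = 8, b = 2, c = 6),
                 c(a = 1, b = 9, c = 5), c(a = 2, b = 11, c = 3))
  profs <- lapply(seq_along(counts), function(i) {
    profile_from_counts(paste0("S", i), 2, counts[[i]])
  })
  m <- t(vapply(counts, function(x) x[order(names(x))] / sum(x), numeric(3)))
  xc <- scale(m, center = TRUE, scale = FALSE)
  eig <- eigen(crossprod(xc) / (nrow(m) - 1))
  oracle_scores <- xc %*% eig$vectors
  ord <- ordinate_profiles(profs, n_components = 2)
  for (j in 1:2) {
    expect_equal(abs(ord$coordinates[[paste0("PC", j)]]),
                 abs(unname(oracle_scores[, j])), tolerance = 1e-8)
  }
  ev <- eig$values / sum(eig$values)
  expect_equal(ord$explained_variance, ev[1:2], tolerance = 1e-8)
  expect_true(all(diff(ord$explained_variance) <= 1e-12))
})

test_that("PCA separates constructed groups on PC1 and handles degenerate input", {
  mk <- function(id, hi) profile_from_counts(id, 2,
    c(a = if (hi) 50 else 10, b = 20, c = 20))
  profs <- list(mk("g1a", TRUE), mk("g1b", TRUE), mk("g2a", FALSE), mk("g2b", FALSE))
  ord <- ordinate_profiles(profs)
  pc1 <- ord$coordinates$PC1
  expect_true(sign(mean(pc1[1:2])) != sign(mean(pc1[3:4])))
  # identical profiles: zero variance, all at the origin
  same <- lapply(1:3, function(i) profile_from_counts(paste0("S", i), 2, c(a = 1, b = 1)))
  o0 <- ordinate_profiles(same)
  expect_true(all(abs(unlist(o0$coordinates[, -1])) < 1e-12))
  expect_error(ordinate_profiles(same, n_components = 10), "exceeds")
})

test_that("clustering separates tight groups and merges duplicates at height 0", {
  mk <- function(id, base) profile_from_counts(id, 2, base)
  g1 <- c(a = 50, b = 5, c = 5); g2 <- c(a = 5, b = 50, c = 5)
  profs <- list(mk("x1", g1), mk("x2", g1 + c(1, 0, 0)),
                mk("y1", g2), mk("y2", g2 + c(0, 1, 0)))
  hc <- cluster_profiles(profs, "single")
  top <- stats::cutree(hc, k = 2)
  expect_equal(unname(top[c("x1", "x2")]), rep(top[["x1"]], 2))
  expect_equal(unname(top[c("y1", "y2")]), rep(top[["y1"]], 2))
  expect_false(top[["x1"]] == top[["y1"]])
  dup <- list(mk("d1", g1), mk("d2", g1), mk("d3", g2))
  hd <- cluster_profiles(dup, "single")
  expect_equal(min(hd$height), 0)
  expect_error(cluster_profiles(profs[1]), "at least 2")
})

test_that("single-linkage merge order matches a hand trace", {
  # 1-d profiles at positions 0, 1, 3, 7 (as two categories summing to 10):
  # single linkage merges (0,1) at 1, then 3 at 2, then 7 at 4
  pos <- c(0, 1, 3, 7)
  profs <- lapply(seq_along(pos), function(i) {
    profile_from_counts(paste0("S", i), 2, c(a = pos[i] + 1, b = 11 - pos[i]))
  })
  hc <- cluster_profiles(profs, "single")
  d <- sqrt(2) * diff(c(0, 1, 3, 7)) / 12  # Euclidean dist on RA vectors
  expect_equal(hc$height, c(d[1], d[2], d[3]), tolerance = 1e-12)
  expect_equal(hc$merge[1, ], c(-1, -2))
})
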