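test_that("LD r-squared follows correlation identities", {
  set.seed(40)
  d <- rbinom(2000, 2, 0.3)
  expect_equal(ld_r2(d, d), 1)
  expect_equal(ld_r2(d, 2 - d), 1)     # sign-invariance of r-squared
  # pairwise-complete handling
  d2 <- d; d2[1:100] <- NA
  expect_equal(ld_r2(d, d2), 1)
  # independent variants are near-uncorrelated in large samples
  low <- vapply(1:100, function(i) {
    ld_r2(rbinom(10000, 2, 0.3), rbinom(10000, 2, 0.3)) < 0.01
  }, logical(1))
  expect_gte(mean(low), 0.95)
})

# build correlated dosage pairs with a controllable r2
correlated_pair <- function(n, p, flip_frac, seed) {
  set.seed(seed)
  d1 <- rbinom(n, 2, p)
  flip <- runif(n) < flip_frac
  d2 <- ifelse(flip, rbinom(n, 2, p), d1)
  cbind(d1, d2)
}

test_that("clumping applies the proximity-and-LD membership rule", {
  n <- 2000
  D <- correlated_pair(n, 0.3, 0.3, 41)   # r2 well above 0.1
  g <- toy_genos(D, pos = c(1000000L, 1100000L))   # 100 kb apart
  tab <- data.frame(chrom = "1", pos = g$variants$pos, id = g$variants$id,
                    p = c(1e-9, 1e-10), stringsAsFactors = FALSE)
  cl <- clump(tab, g, p_threshold = 5e-8)
  expect_length(cl, 1L)
  expect_identical(cl[[1]]$index_id, "v002")   # lower p is the index
  expect_setequal(cl[[1]]$members$id, c("v001", "v002"))
  # single significant variant forms its own clump
  tab1 <- tab; tab1$p <- c(1e-9, 0.5)
  cl1 <- clump(tab1, g, p_threshold = 5e-8)
  expect_length(cl1, 1L)
  expect_identical(cl1[[1]]$members$id, "v001")
  # within the window but uncorrelated: founds its own clump
  set.seed(42)
  D2 <- cbind(rbinom(n, 2, 0.3), rbinom(n, 2, 0.3))
  g2 <- toy_genos(D2, pos = c(1000000L, 1100000L))
  cl2 <- clump(tab, g2, p_threshold = 5e-8)
  expect_length(cl2, 2L)
  expect_error(clump(data.frame(chrom = "1", pos = 1L, id = "ghost", p = 1e-9),
                     g), "missing from genotypes")
})

test_that("clumping matches the brute-force oracle on random instances", {
  for (inst in 1:30) {
    set.seed(500 + inst)
    m <- sample(10:50, 1)
    n <- 400
    # blocks of correlated variants at random positions
    spec <- simulation_spec(n_samples = n, n_variants = m, ld_block_size = 5,
                            ld_rho = 0.85, maf_range = c(0.1, 0.5),
                            seed = 500 + inst)
    g <- simulate_genotypes(spec)
    g$variants$pos <- sort(sample.int(2000000L, m))
    colnames(g$dosages) <- g$variants$id
    tab <- data.frame(chrom = "1", pos = g$variants$pos, id = g$variants$id,
                      p = 10^runif(m, -12, -2), stringsAsFactors = FALSE)
    r2mat <- abs(cor(g$dosages))^2
    dimnames(r2mat) <- list(g$variants$id, g$variants$id)
    got <- clump(tab, g, p_threshold = 1e-4, r2_threshold = 0.1,
                 window_bp = 250000L)
    want <- clump_oracle(tab, r2mat, 1e-4, 0.1, 250000L)
    got_sets <- lapply(got, function(cl) sort(cl$members$id))
    names(got_sets) <- vapply(got, `[[`, "", "index_id")
    want_sets <- lapply(want, sort)
    expect_identical(got_sets[order(names(got_sets))],
                     want_sets[order(names(want_sets))],
                     info = paste("instance", inst))
  }
})

test_that("every significant variant lands in exactly one clump", {
  set.seed(43)
  spec <- simulation_spec(n_samples = 300, n_variants = 40, ld_block_size = 8,
                          ld_rho = 0.9, seed = 43)
  g <- simulate_genotypes(spec)
  tab <- data.frame(chrom = "1", pos = g$variants$pos, id = g$variants$id,
                    p = 10^runif(40, -10, -6), stringsAsFactors = FALSE)
  cl <- clump(tab, g, p_threshold = 1e-5)
  all_members <- unlist(lapply(cl, function(x) x$members$id))
  expect_setequal(all_members, tab$id)
  expect_equal(anyDuplicated(all_members), 0L)
  # indices pairwise fail (within-window AND r2 >= threshold)
  idx <- vapply(cl, `[[`, "", "index_id")
  pos <- tab$pos[match(idx, tab$id)]
  if (length(idx) > 1) {
    for (a in seq_along(idx)) for (b in seq_along(idx)) {
      if (a < b) {
        close_by <- abs(pos[a] - pos[b]) <= 250000L
        r2 <- ld_r2(g$dosages[, idx[a]], g$dosages[, idx[b]])
        expect_false(close_by && r2 >= 0.1)
      }
    }
  }
})

make_clumps <- function(spans, ps = NULL) {
  # spans: list of c(start, end); one member per end plus index
  lapply(seq_along(spans), function(i) {
    s <- spans[[i]]
    p <- if (is.null(ps)) 10^(-8 - i) else ps[i]
    list(chrom = "1", index_id = paste0("idx", i), index_pos = s[1],
         min_p = p,
         members = data.frame(id = paste0("idx", i, c("a", "b")),
                              pos = c(s[1], s[2]), p = c(p, p * 10),
                              stringsAsFactors = FALSE),
         start = s[1], end = s[2])
  })
}

test_that("span merging respects the 250-kb gap rule transitively", {
  # 200 kb apart: merged
  two <- make_clumps(list(c(1000000, 1100000), c(1300000, 1400000)))
  m <- merge_clumps(two)
  expect_equal(nrow(m), 1L)
  expect_equal(m$start, 1000000); expect_equal(m$end, 1400000)
  # 300 kb apart: separate
  far <- make_clumps(list(c(1000000, 1100000), c(1400001, 1500000)))
  expect_equal(nrow(merge_clumps(far)), 2L)
  # transitive chain A-B 200 kb, B-C 200 kb, A-C 400 kb: one locus
  chain <- make_clumps(list(c(1000000, 1000000), c(1200000, 1200000),
                            c(1400000, 1400000)))
  mc <- merge_clumps(chain)
  expect_equal(nrow(mc), 1L)
  expect_equal(mc$n_members, 6L)
  # index is the overall minimum-p member (clump 3 carries the smallest p)
  expect_identical(mc$index_id, "idx3a")
  expect_equal(mc$min_p, 1e-11)
})

test_that("merging is idempotent", {
  cl <- make_clumps(list(c(1000000, 1100000), c(1250000, 1300000),
                         c(2000000, 2100000)))
  m1 <- merge_clumps(cl)
  # re-merge by rebuilding clump-shaped input from the loci
  cl2 <- lapply(seq_len(nrow(m1)), function(i) {
    list(chrom = m1$chrom[i], index_id = m1$index_id[i],
         index_pos = m1$index_pos[i], min_p = m1$min_p[i],
         members = data.frame(id = m1$members[[i]],
                              pos = c(m1$start[i],
                                      rep(m1$end[i], length(m1$members[[i]]) - 1)),
                              p = rep(m1$min_p[i], length(m1$members[[i]]))),
         start = m1$start[i], end = m1$end[i])
  })
  m2 <- merge_clumps(cl2)
  expect_equal(nrow(m2), nrow(m1))
  expect_equal(m2$start, m1$start)
  expect_equal(m2$end, m1$end)
})

test_that("locus extension pads, floors and merges 1-bp overlaps", {
  loci <- data.frame(chrom = "1", start = 1000000L, end = 1000000L,
                     min_p = 1e-9, index_id = "a", index_pos = 1000000L)
  e <- extend_loci(loci)
  expect_equal(e$start, 750000)
  expect_equal(e$end, 1250000)
  lo <- data.frame(chrom = "1", start = 100000L, end = 100000L,
                   min_p = 1e-9, index_id = "a", index_pos = 100000L)
  expect_equal(extend_loci(lo)$start, 1)
  # two extended intervals overlapping by exactly 1 bp count as one
  pair <- data.frame(chrom = "1", start = c(1000000L, 1500000L),
                     end = c(1000000L, 1500000L), min_p = c(1e-9, 1e-8),
                     index_id = c("a", "b"), index_pos = c(1000000L, 1500000L))
  e2 <- extend_loci(pair)   # spans touch at 1250000/1250000
  expect_equal(nrow(e2), 1L)
  expect_equal(e2$n_merged_from, 2L)
  pair$start[2] <- pair$end[2] <- 1500001L
  expect_equal(nrow(extend_loci(pair)), 2L)
})

test_that("raising the p threshold never decreases the locus count", {
  set.seed(44)
  spec <- simulation_spec(n_samples = 300, n_variants = 60, ld_block_size = 6,
                          ld_rho = 0.8, seed = 44)
  g <- simulate_genotypes(spec)
  tab <- data.frame(chrom = "1", pos = g$variants$pos, id = g$variants$id,
                    p = 10^runif(60, -10, -3), stringsAsFactors = FALSE)
  counts <- vapply(c(1e-8, 1e-6, 1e-4, 1e-2), function(thr) {
    length(clump(tab, g, p_threshold = thr))
  }, 0L)
  expect_true(all(diff(counts) >= 0))
})

test_that("known-locus overlap respects interval boundaries", {
  loci <- data.frame(chrom = c("1", "1", "2"),
                     start = c(100, 500, 100), end = c(200, 600, 200))
  known <- data.frame(chrom = "1", start = 150, end = 499)
  expect_identical(overlap_known(loci, known), c(TRUE, FALSE, FALSE))
  inner <- data.frame(chrom = "1", start = 120, end = 130)
  expect_true(overlap_known(inner, data.frame(chrom = "1", start = 100,
                                              end = 200)))
  expect_identical(overlap_known(loci, known[0, ]), rep(FALSE, 3))
})

test_that("nearest protein-coding gene lookup and tie-breaks", {
  genes <- data.frame(chrom = "1",
                      start = c(1000, 30000, 90000),
                      end = c(5000, 40000, 95000),
                      symbol = c("GENEC", "GENEA", "GENEB"),
                      biotype = c("protein_coding", "protein_coding",
                                  "lincRNA"),
                      stringsAsFactors = FALSE)
  inside <- nearest_gene("1", 3000, genes)
  expect_identical(inside$symbol, "GENEC")
  expect_equal(inside$distance, 0)
  # 10 kb downstream of GENEA; GENEB is non-coding and ignored
  ng <- nearest_gene("1", 50000, genes)
  expect_identical(ng$symbol, "GENEA")
  expect_equal(ng$distance, 10000)
  # exact midpoint tie: smaller start wins
  tie_genes <- data.frame(chrom = "1", start = c(1000, 9000),
                          end = c(2000, 10000),
                          symbol = c("LEFT", "RIGHT"),
                          biotype = "protein_coding")
  tie <- nearest_gene("1", 5500, tie_genes)
  expect_identical(tie$symbol, "LEFT")
  none <- nearest_gene("2", 100, genes)
  expect_true(is.na(none$symbol))
})
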