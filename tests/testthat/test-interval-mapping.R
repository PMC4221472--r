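test_that("haplotype origin calls follow the single-carrier rule", {
  expect_equal(assign_haplotype("A/G", "A", "G"), "AFFECTED_HAP")
  expect_equal(assign_haplotype("G/G", "A", "G"), "UNAFFECTED_HAP")
  expect_equal(assign_haplotype("T/T", "A", "G"), "UNINFORMATIVE")
  expect_equal(assign_haplotype("A/A", "A", "G"), "AFFECTED_HAP")
  expect_equal(assign_haplotype("./.", "A", "G"), "UNINFORMATIVE")
  expect_equal(assign_haplotype(c("A|G", "G/T"), "A", "G"),
               c("AFFECTED_HAP", "UNINFORMATIVE"))
})

make_rb1_table <- function(calls, pos, aff = "A", unaff = "G") {
  geno <- vapply(calls, function(x) {
    switch(x, AFF = paste(aff, unaff, sep = "/"),
           UNAFF = paste(unaff, unaff, sep = "/"),
           UNINF = "T/T")
  }, character(1))
  marker_table(pos, rep(aff, length(pos)), rep(unaff, length(pos)),
               list(RB1 = geno))
}

test_that("a recombinant's UNAFF run reproduces the narrowed critical interval", {
  # 9 markers; RB1 carries the affected haplotype except over markers 3-5
  pos <- c(86150000, 86300000, 86476559, 86520000, 86601705,
           86650000, 86700000, 86790000, 86830000)
  tab <- make_rb1_table(c("AFF", "AFF", "UNAFF", "UNAFF", "UNAFF",
                          "AFF", "AFF", "AFF", "AFF"), pos)
  original <- genomic_interval("chr2", 86110000, 86850000)
  ivs <- exclusion_map(tab, original, "RB1")
  expect_length(ivs, 1L)
  expect_equal(ivs[[1]]$start, 86476559)
  expect_equal(ivs[[1]]$end, 86601705)
  expect_equal(interval_span(ivs[[1]]), 125146)
})

test_that("an all-UNAFF excluder and zero excluders leave the interval unchanged", {
  pos <- seq(2000, 10000, length.out = 5)
  tab <- make_rb1_table(rep("UNAFF", 5), pos)
  original <- genomic_interval("chr2", 1000, 20000)
  ivs <- exclusion_map(tab, original, "RB1")
  expect_length(ivs, 1L)
  expect_equal(ivs[[1]], original)
  expect_equal(exclusion_map(tab, original, character()), list(original))
})

test_that("all-uninformative markers warn and leave the interval unchanged", {
  pos <- seq(2000, 10000, length.out = 4)
  tab <- make_rb1_table(rep("UNINF", 4), pos)
  original <- genomic_interval("chr2", 1000, 20000)
  expect_warning(ivs <- exclusion_map(tab, original, "RB1"), "informative")
  expect_equal(ivs, list(original))
})

test_that("markers outside the original interval are rejected", {
  tab <- make_rb1_table(c("AFF", "UNAFF"), c(500, 2000))
  expect_error(exclusion_map(tab, genomic_interval("chr2", 1000, 3000), "RB1"),
               "outside")
})

test_that("exclusion mapping matches the run-scanning oracle on random tables", {
  set.seed(23)
  original <- genomic_interval("chr2", 1, 200000)
  for (case in 1:50) {
    n <- 12
    pos <- sort(sample(seq(100, 199000), n))
    calls <- sample(c("AFF", "UNAFF", "UNINF"), n, replace = TRUE,
                    prob = c(.4, .4, .2))
    tab <- make_rb1_table(calls, pos)
    origin <- c(AFF = "AFFECTED_HAP", UNAFF = "UNAFFECTED_HAP",
                UNINF = "UNINFORMATIVE")[calls]
    expected <- oracle_exclusion_map(pos, matrix(origin, ncol = 1), original)
    got <- suppressWarnings(exclusion_map(tab, original, "RB1"))
    got_pairs <- lapply(got, function(iv) c(iv$start, iv$end))
    expect_equal(got_pairs, expected, ignore_attr = TRUE)
  }
})

test_that("exclusion-map intervals are disjoint, within the original, and avoid AFF markers", {
  set.seed(31)
  original <- genomic_interval("chr2", 1, 50000)
  for (case in 1:25) {
    n <- sample(4:12, 1)
    pos <- sort(sample(seq(10, 49990), n))
    calls <- sample(c("AFF", "UNAFF", "UNINF"), n, replace = TRUE)
    tab <- make_rb1_table(calls, pos)
    ivs <- suppressWarnings(exclusion_map(tab, original, "RB1"))
    if (length(ivs) == 0) next
    starts <- vapply(ivs, function(iv) iv$start, numeric(1))
    ends <- vapply(ivs, function(iv) iv$end, numeric(1))
    expect_true(all(starts >= original$start & ends <= original$end))
    if (length(ivs) > 1) expect_true(all(starts[-1] > ends[-length(ends)]))
    aff_pos <- pos[calls == "AFF"]
    for (p in aff_pos) {
      expect_false(any(starts <= p & p <= ends))
    }
  }
})

test_that("adding an excluder never grows the retained union", {
  set.seed(37)
  original <- genomic_interval("chr2", 1, 100000)
  union_len <- function(ivs) {
    if (length(ivs) == 0) return(0)
    sum(vapply(ivs, interval_span, numeric(1)))
  }
  for (case in 1:20) {
    n <- 10
    pos <- sort(sample(seq(100, 99000), n))
    g <- function() vapply(sample(c("AFF", "UNAFF", "UNINF"), n, replace = TRUE),
                           function(x) switch(x, AFF = "A/G", UNAFF = "G/G",
                                              UNINF = "T/T"), character(1))
    tab <- marker_table(pos, rep("A", n), rep("G", n),
                        list(RB1 = g(), RB2 = g()))
    one <- suppressWarnings(exclusion_map(tab, original, "RB1"))
    both <- suppressWarnings(exclusion_map(tab, original, c("RB1", "RB2")))
    expect_lte(union_len(both), union_len(one))
  }
})

test_that("variant-interval intersection respects bounds and kind filter", {
  d <- default_design()
  v <- make_variants(matrix(rep(d$expected_class, 3), ncol = 6, byrow = TRUE),
                     d, pos = c(86594449, 86830975, 86500000))
  v$ref[2] <- paste(rep("A", 56), collapse = ""); v$alt[2] <- "A"
  v$kind <- classify_variant_kind(v$ref, v$alt)
  iv <- genomic_interval("chr2", 86476559, 86601705)
  expect_equal(variants_in_interval(v, iv)$pos, c(86594449, 86500000))
  expect_equal(variants_in_interval(v, iv, kind_filter = "SNP")$pos,
               c(86594449, 86500000))
  expect_equal(nrow(variants_in_interval(v, genomic_interval("chr3", 1, 1e9))),
               0L)
  expect_equal(nrow(variants_in_interval(v[0, ], iv)), 0L)
  # the 55 bp deletion lies beyond the narrowed interval
  expect_false(86830975 %in% variants_in_interval(v, iv)$pos)
})
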