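mk_table <- function(g) {
  ids <- sprintf("m%02d", seq_len(nrow(g)))
  rownames(g) <- ids
  marker_table(data.frame(marker_id = ids, scaffold_id = "s1",
                          position = seq_len(nrow(g)) * 100L,
                          stringsAsFactors = FALSE), g)
}

test_that("call-rate filtering reaches the fixed point of the 80/80 rule", {
  ## marker present in 79% of samples is dropped
  g <- matrix("AA", 2, 100)
  g[1, 1:21] <- NA
  tab <- filter_markers(mk_table(g))
  expect_equal(rownames(tab$genotypes), "m02")

  ## complete matrix is untouched
  g <- matrix("AB", 5, 10)
  tab <- filter_markers(mk_table(g))
  expect_equal(dim(tab$genotypes), c(5L, 10L))
  expect_equal(sum(attr(tab, "filter_rounds")[, -1]), 0)

  ## crafted 10x10 where dropping one bad sample rescues a marker
  g <- matrix("AA", 10, 10)
  g[, 1] <- NA          # sample 1 is empty
  g[1, 1:3] <- NA       # marker 1: 7/10 present, but 7/9 = 0.78 ... craft:
  g[1, ] <- "AA"; g[1, c(1, 2)] <- NA  # marker 1: 8/10 = 0.8 ok either way
  g[2, c(1, 2, 3)] <- NA               # marker 2: 7/10 < 0.8; after sample-1
                                       # drop: 7/9 < 0.8; still dropped
  g[3, 1] <- NA                        # marker 3: 9/10; after: 9/9
  got <- filter_markers(mk_table(g))$genotypes
  want <- oracle_filter_8080(mk_table(g)$genotypes, 0.8, 0.8)
  expect_equal(got, want)

  ## random matrices agree with the one-at-a-time oracle, and raising
  ## marker_min never increases the surviving marker count
  set.seed(41)
  for (rep in 1:5) {
    g <- matrix(sample(c("AA", "AB", "BB", NA), 200, replace = TRUE,
                       prob = c(0.3, 0.3, 0.25, 0.15)), 20, 10)
    tab <- mk_table(g)
    got <- filter_markers(tab, 0.7, 0.7)$genotypes
    want <- oracle_filter_8080(tab$genotypes, 0.7, 0.7)
    expect_equal(got, want)
    n_surv <- vapply(c(0.5, 0.7, 0.9),
                     function(th) suppressWarnings(
                       nrow(filter_markers(tab, th, 0.7)$genotypes)),
                     numeric(1))
    expect_true(all(diff(n_surv) <= 0))
  }
})

test_that("flank repeat filter drops markers with long non-self alignments", {
  g <- matrix("AA", 3, 4)
  tab <- mk_table(g)
  aln <- data.frame(
    query_id = c("m01", "m01", "m02", "m03"),
    query_len = 301L, query_start = 0L,
    query_end = c(301L, 200L, 301L, 140L),
    strand = "+", target_id = c("m01", "m09", "m02", "m07"),
    target_len = 301L, target_start = 0L,
    target_end = c(301L, 200L, 301L, 140L),
    matches = 100L, align_len = c(301L, 200L, 301L, 140L),
    score = 100, stringsAsFactors = FALSE)
  got <- flank_repeat_filter(tab, aln, flank = 150L)
  ## m01: 200-base non-self hit -> dropped; m02: only the self-hit ->
  ## kept; m03: short non-self hit -> kept
  expect_equal(got$markers$marker_id, c("m02", "m03"))
})

test_that("flank extraction clips at scaffold edges and flags the marker", {
  asm <- assembly_from_strings(c(s1 = strrep("ACGT", 300)))
  g <- matrix("AA", 2, 2)
  rownames(g) <- c("edge", "mid")
  tab <- marker_table(data.frame(marker_id = c("edge", "mid"),
                                 scaffold_id = "s1",
                                 position = c(10L, 600L),
                                 stringsAsFactors = FALSE), g)
  fl <- extract_flanks(tab, asm, flank = 150L)
  expect_equal(fl$clipped, c(TRUE, FALSE))
  expect_equal(width(fl$regions), c(161L, 301L))
  kept <- flank_repeat_filter(tab, inilcurate:::empty_alignments(),
                              clipped = fl$clipped)
  expect_equal(kept$markers$clipped_flag, c(TRUE, FALSE))
})

test_that("scaffold chimeras are called at LG switches across a gap", {
  mk <- function(pos, lg, sc = "scf") {
    data.frame(marker_id = sprintf("%s_m%d", sc, seq_along(pos)),
               scaffold_id = sc, position = pos, lg = lg,
               stringsAsFactors = FALSE)
  }
  gaps <- data.frame(scaffold_id = "scf", start = 5000L, end = 5100L,
                     length = 100L, stringsAsFactors = FALSE)
  ev <- detect_scaffold_chimeras(
    mk(c(1000, 2000, 3000, 6000, 7000), c("LG2", "LG2", "LG2", "LG7", "LG7")),
    gaps)
  expect_equal(ev$resolution, "split_two")
  expect_equal(c(ev$junction_start, ev$junction_end), c(5000L, 5100L))
  expect_equal(c(ev$left_lg, ev$right_lg), c("LG2", "LG7"))

  ## single linkage group: silence
  expect_equal(nrow(detect_scaffold_chimeras(
    mk(c(1000, 6000), c("LG2", "LG2")), gaps)), 0L)

  ## alternating singletons without a gap between blocks: flag only
  ev <- detect_scaffold_chimeras(
    mk(c(100, 200, 300, 400), c("LG2", "LG7", "LG2", "LG7")),
    gaps[0, ])
  expect_equal(ev$resolution, "flagged_only")

  ## longest gap wins when several lie between the blocks
  gaps2 <- rbind(gaps, data.frame(scaffold_id = "scf", start = 4000L,
                                  end = 4050L, length = 50L))
  ev <- detect_scaffold_chimeras(
    mk(c(1000, 2000, 6000, 7000), c("LG2", "LG2", "LG7", "LG7")), gaps2)
  expect_equal(ev$junction_start, 5000L)
})

test_that("scaffold splitting discards the junction and conserves non-N bases", {
  set.seed(8)
  left <- rand_dna(5000)
  right <- rand_dna(4900)
  asm <- assembly_from_strings(c(x = paste0(left, strrep("N", 100), right)))
  kids <- split_scaffold(asm, "x", 5000L, 5100L)
  expect_equal(names(kids), c("x_1", "x_2"))
  expect_equal(width(kids), c(5000L, 4900L))
  ## reassembly reproduces the original
  expect_equal(paste0(as.character(kids[[1]]), strrep("N", 100),
                      as.character(kids[[2]])),
               as.character(asm[[1]]))
  expect_error(split_scaffold(asm, "x", 0L, 100L), "edge")

  ## forged chimera suite: exact junctions, no false splits
  set.seed(12)
  chroms <- assembly_from_strings(setNames(
    vapply(1:14, function(i) rand_dna(20000), character(1)),
    sprintf("c%02d", 1:14)))
  ch <- make_chimeras(chroms, n_events = 5L, seed = 12L)
  ev <- detect_scaffold_chimeras(ch$markers, find_gap_runs(ch$assembly))
  splits <- ev[ev$resolution == "split_two", ]
  expect_equal(nrow(splits), 5L)
  m <- merge(splits, ch$truth, by = "scaffold_id")
  expect_equal(m$junction_start.x, m$junction_start.y)
  expect_equal(m$junction_end.x, m$junction_end.y)
  expect_true(all(ev$scaffold_id %in% ch$truth$scaffold_id))  # clean silent
  sp <- apply_chimera_splits(ch$assembly, ev)
  expect_equal(
    sum(Biostrings::letterFrequency(sp$assembly, "ACGT")),
    sum(Biostrings::letterFrequency(ch$assembly, "ACGT")))
})

test_that("contig chimeras split in three with the junction inside the middle", {
  mk <- function(pos, lg) {
    data.frame(marker_id = sprintf("m%d", seq_along(pos)),
               scaffold_id = "ctg", position = pos, lg = lg,
               stringsAsFactors = FALSE)
  }
  ev <- detect_contig_chimeras(
    mk(c(10000, 25000, 40000, 60000, 75000, 90000),
       c("LGa", "LGa", "LGa", "LGb", "LGb", "LGb")), 100000L)
  expect_equal(ev$resolution, "split_three")
  expect_equal(c(ev$boundary_left, ev$boundary_right), c(40000L, 60000L))

  expect_equal(nrow(detect_contig_chimeras(
    mk(c(10000, 40000), c("LGa", "LGa")), 100000L)), 0L)

  ## BAC anchors refine (never override) the marker block edges
  anchors <- data.frame(position = c(45000L, 55000L), lg = c("LGa", "LGb"))
  ev <- detect_contig_chimeras(
    mk(c(10000, 40000, 60000, 90000), c("LGa", "LGa", "LGb", "LGb")),
    100000L, bac_anchors = anchors)
  expect_equal(c(ev$boundary_left, ev$boundary_right), c(45000L, 55000L))

  set.seed(21)
  chroms <- assembly_from_strings(setNames(
    vapply(1:6, function(i) rand_dna(30000), character(1)),
    sprintf("k%02d", 1:6)))
  ch <- make_chimeras(chroms, n_contig_events = 2L, seed = 33L)
  for (i in seq_len(nrow(ch$truth))) {
    id <- ch$truth$scaffold_id[i]
    ev <- detect_contig_chimeras(
      ch$markers[ch$markers$scaffold_id == id, ],
      width(ch$assembly)[names(ch$assembly) == id])
    expect_equal(ev$resolution, "split_three")
    expect_lte(ev$boundary_left, ch$truth$junction_start[i])
    expect_gte(ev$boundary_right, ch$truth$junction_start[i])
    kids <- split_contig_three(ch$assembly, id, ev$boundary_left,
                               ev$boundary_right)
    expect_equal(paste(vapply(seq_along(kids), function(j)
      as.character(kids[[j]]), character(1)), collapse = ""),
      as.character(ch$assembly[[id]]))
  }
})

test_that("pseudo-chromosomes order by cM, orient by concordance, and report anchoring", {
  set.seed(6)
  asm <- assembly_from_strings(c(a = rand_dna(1000), b = rand_dna(2000),
                                 c = rand_dna(3000), d = rand_dna(4000)))
  markers <- data.frame(
    marker_id = c("a1", "a2", "b1", "b2", "c1", "c2"),
    scaffold_id = c("a", "a", "b", "b", "c", "c"),
    position = c(100L, 900L, 100L, 1900L, 100L, 2900L),
    stringsAsFactors = FALSE)
  map <- data.frame(
    lg = "1",
    marker_id = c("a1", "a2", "b1", "b2", "c1", "c2"),
    cM = c(0, 5, 10, 15, 25, 20),  # c decreases along position
    stringsAsFactors = FALSE)
  pc <- build_pseudochromosomes(asm, map, markers, gap_size = 100L)
  expect_equal(pc$plan$scaffold_id, c("a", "b", "c"))
  expect_equal(pc$plan$orientation, c("+", "+", "-"))
  expect_equal(width(pc$sequences), 1000L + 2000L + 3000L + 200L)
  expect_equal(pc$unanchored, "d")
  expect_equal(pc$anchored_fraction, 6000 / 10000)
  ## the reverse-oriented scaffold appears reverse-complemented
  expect_equal(as.character(Biostrings::subseq(pc$sequences[[1]],
                                               3201L, 6200L)),
               rc(as.character(asm[["c"]])))
  ## AGP fidelity: reconstruction is byte-identical
  rec <- reconstruct_from_agp(pc$agp, asm)
  expect_identical(as.character(rec), as.character(pc$sequences))
  f <- withr::local_tempfile(fileext = ".agp")
  write_agp(pc$agp, f)
  rec2 <- reconstruct_from_agp(read_agp(f), asm)
  expect_identical(as.character(rec2), as.character(pc$sequences))
  ## non-N conservation through construction
  expect_equal(sum(Biostrings::letterFrequency(pc$sequences, "ACGT")) +
                 sum(width(asm[pc$unanchored])),
               sum(Biostrings::letterFrequency(asm, "ACGT")))

  ## two of four equal-length scaffolds anchored -> 0.50
  asm4 <- assembly_from_strings(setNames(
    vapply(1:4, function(i) rand_dna(1000), character(1)), letters[1:4]))
  pc4 <- build_pseudochromosomes(
    asm4, map[map$marker_id %in% c("a1", "a2", "b1", "b2"), ], markers)
  expect_equal(pc4$anchored_fraction, 0.5)

  ## scaffold with markers in two groups is a hard error
  map2 <- map
  map2$lg[map2$marker_id == "a2"] <- "2"
  expect_error(build_pseudochromosomes(asm, map2, markers), "chimera")

  ## a scaffold with a single informative marker is included unoriented
  map3 <- map[map$marker_id != "a2", ]
  pc3 <- build_pseudochromosomes(asm, map3, markers)
  expect_equal(pc3$plan$orientation[pc3$plan$scaffold_id == "a"],
               "unoriented")
})
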