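canonical_element <- function(tir5, tir3, srr5, srr3, k5 = 3L, k3 = 3L,
                              interior = 500L, invert_srr3 = FALSE,
                              drop_srr3_to = NULL) {
  s3block <- if (!is.null(drop_srr3_to)) {
    substr(strrep(srr3, 1L), 1L, drop_srr3_to)
  } else {
    strrep(srr3, k3)
  }
  if (invert_srr3) s3block <- rc(s3block)
  paste0(tir5, strrep(srr5, k5), rand_dna(interior), s3block, rc(tir3))
}

test_that("scan_tirs finds exact and mismatched seed occurrences", {
  set.seed(2)
  seed5 <- rand_dna(28)
  seeds <- inilcurate:::seed_frame("five_prime", seed5)
  asm <- assembly_from_strings(c(
    s1 = paste0(rand_dna(100), seed5, rand_dna(200))))
  h <- scan_tirs(asm, seeds, max_mismatches = 3L)
  expect_equal(nrow(h), 1L)
  expect_equal(c(h$start, h$end), c(100L, 128L))
  expect_equal(h$end_type, "five_prime")
  expect_equal(h$strand, "+")
  expect_equal(h$mismatches, 0L)

  polyA <- assembly_from_strings(c(s = strrep("A", 1000)))
  seeds_c <- inilcurate:::seed_frame("five_prime",
                                     paste0(strrep("A", 20), "CCCCCCCC"))
  expect_equal(nrow(scan_tirs(polyA, seeds_c, 3L)), 0L)

  expect_error(
    scan_tirs(polyA, inilcurate:::seed_frame("five_prime",
                                             paste0(strrep("A", 27), "N")),
              3L),
    "must not contain N")
})

test_that("scan_tirs equals the exhaustive sliding-window Hamming oracle", {
  set.seed(7)
  seed5 <- rand_dna(28)
  seed3 <- rand_dna(28)
  seeds <- rbind(inilcurate:::seed_frame("five_prime", seed5),
                 inilcurate:::seed_frame("three_prime", seed3))
  bg <- strsplit(rand_dna(50000), "")[[1]]
  ## plant 10 copies, two carrying 2 substitutions
  pos <- seq(2000, 47000, length.out = 10)
  for (i in seq_along(pos)) {
    cp <- if (i %% 2) seed5 else rc(seed3)
    if (i <= 2) {
      cc <- strsplit(cp, "")[[1]]
      cc[c(5, 20)] <- c("A", "A")
      cp <- paste(cc, collapse = "")
    }
    bg[pos[i]:(pos[i] + 27)] <- strsplit(cp, "")[[1]]
  }
  asm <- assembly_from_strings(c(chr = paste(bg, collapse = "")))
  got <- scan_tirs(asm, seeds, max_mismatches = 2L)
  want <- oracle_scan_tirs(asm, seeds, 2L)
  expect_gte(nrow(got), 10L)
  expect_equal(got, want)
})

test_that("pair_tirs keeps convergent cross-type pairs and matches all-pairs enumeration", {
  one5 <- data.frame(scaffold_id = "s", start = 100L, end = 128L,
                     end_type = "five_prime", strand = "+",
                     mismatches = 0L, stringsAsFactors = FALSE)
  one3 <- data.frame(scaffold_id = "s", start = 1000L, end = 1028L,
                     end_type = "three_prime", strand = "-",
                     mismatches = 1L, stringsAsFactors = FALSE)
  cand <- pair_tirs(rbind(one5, one3), 60L, 50000L)
  expect_equal(nrow(cand), 1L)
  expect_equal(c(cand$start, cand$end), c(100L, 1028L))
  expect_equal(cand$orientation, "+")
  expect_equal(cand$tir_mismatches, 1L)

  same <- rbind(one5, transform(one5, start = 500L, end = 528L))
  expect_equal(nrow(pair_tirs(same, 60L, 50000L)), 0L)
  expect_error(pair_tirs(one5, 100L, 100L), "min_span")

  set.seed(13)
  hits <- data.frame(
    scaffold_id = sample(c("a", "b"), 20, replace = TRUE),
    start = sample.int(30000, 20),
    end_type = sample(c("five_prime", "three_prime"), 20, replace = TRUE),
    strand = sample(c("+", "-"), 20, replace = TRUE),
    mismatches = sample(0:3, 20, replace = TRUE),
    stringsAsFactors = FALSE)
  hits$end <- hits$start + 28L
  hits <- hits[order(hits$scaffold_id, hits$start), ]
  got <- pair_tirs(hits, 60L, 50000L)
  want <- oracle_pair_tirs(hits, 60L, 50000L)
  rownames(got) <- rownames(want) <- NULL
  expect_equal(got, want)
})

test_that("call_tsd prefers longer exact duplications and tolerates one mismatch at 3", {
  set.seed(23)
  body <- rand_dna(200)
  mk_asm <- function(lf, rf) {
    assembly_from_strings(c(s = paste0(rand_dna(20), lf, body, rf,
                                       rand_dna(20))))
  }
  cand <- data.frame(scaffold_id = "s", start = 23L, end = 23L + 200L,
                     stringsAsFactors = FALSE)

  got <- call_tsd(mk_asm("TAA", "TAA"), cand)
  expect_equal(got$tsd_len, 3L)
  expect_equal(got$tsd_hamming, 0L)
  expect_true(got$tsd_at)

  cand5 <- data.frame(scaffold_id = "s", start = 25L, end = 25L + 200L,
                      stringsAsFactors = FALSE)
  got <- call_tsd(mk_asm("ACGTA", "ACGTA"), cand5)
  expect_equal(got$tsd_len, 5L)
  expect_equal(got$tsd_left, "ACGTA")

  got <- call_tsd(mk_asm("AAA", "CCC"), cand)
  expect_true(is.na(got$tsd_len))

  got <- call_tsd(mk_asm("TGA", "TGC"), cand)  # Hamming 1 at length 3
  expect_equal(got$tsd_len, 3L)
  expect_equal(got$tsd_hamming, 1L)
})

test_that("detect_srr scores SRR integrity and element orientation", {
  set.seed(5)
  tir5 <- rand_dna(28); tir3 <- rand_dna(28)
  srr5 <- rand_dna(122); srr3 <- rand_dna(104)
  srr_seeds <- rbind(inilcurate:::seed_frame("five_prime", srr5),
                     inilcurate:::seed_frame("three_prime", srr3))
  wrap <- function(body) {
    asm <- assembly_from_strings(c(s = paste0(rand_dna(50), body,
                                              rand_dna(50))))
    list(asm = asm,
         span = data.frame(scaffold_id = "s", start = 50L,
                           end = 50L + nchar(body),
                           stringsAsFactors = FALSE))
  }
  fwd <- wrap(canonical_element(tir5, tir3, srr5, srr3))
  got <- detect_srr(fwd$asm, fwd$span, srr_seeds)
  expect_equal(got[c("srr5_status", "srr3_status", "orientation")],
               list(srr5_status = "present", srr3_status = "present",
                    orientation = "+"))

  mir <- wrap(rc(canonical_element(tir5, tir3, srr5, srr3)))
  got <- detect_srr(mir$asm, mir$span, srr_seeds)
  expect_equal(got$orientation, "-")
  expect_equal(got$srr5_status, "present")
  expect_equal(got$srr3_status, "present")

  ## one inverted copy only at the 3' end -> rearranged
  deg <- wrap(canonical_element(tir5, tir3, srr5, srr3, k3 = 1L,
                                invert_srr3 = TRUE))
  got <- detect_srr(deg$asm, deg$span, srr_seeds)
  expect_equal(got$srr3_status, "rearranged")

  ## no 3' SRR at all -> absent
  none <- wrap(paste0(tir5, strrep(srr5, 3), rand_dna(700), rc(tir3)))
  got <- detect_srr(none$asm, none$span, srr_seeds)
  expect_equal(got$srr3_status, "absent")
})

test_that("nominate_elements recovers planted truth and resolves conflicts", {
  fg <- small_forge()
  catalog <- nominate_elements(fg$assembly, fg$tir_seeds, fg$srr_seeds)
  truth <- fg$truth[fg$truth$feature_type == "tpn_element", ]
  el <- catalog$elements
  expect_setequal(paste(el$scaffold_id, el$start, el$end),
                  paste(truth$scaffold_id, truth$start, truth$end))
  m <- merge(truth, el, by = c("scaffold_id", "start"))
  expect_equal(m$activity_class, m$class)
  expect_equal(m$orientation, m$strand)
  expect_equal(m$tsd_left, m$payload)
  ## accepted elements are pairwise non-overlapping
  for (sc in unique(el$scaffold_id)) {
    e <- el[el$scaffold_id == sc, ]
    e <- e[order(e$start), ]
    if (nrow(e) > 1) expect_true(all(e$start[-1] >= e$end[-nrow(e)]))
  }
  ## stats equal recomputation from the element list
  expect_equal(catalog$stats, catalog_stats(el))

  ## a TIR pair whose flanks share no TSD yields nothing
  set.seed(31)
  tir5 <- rand_dna(28); tir3 <- rand_dna(28)
  seeds <- rbind(inilcurate:::seed_frame("five_prime", tir5),
                 inilcurate:::seed_frame("three_prime", tir3))
  asm <- assembly_from_strings(c(
    s = paste0("AAAAA", tir5, rand_dna(500), rc(tir3), "CCCCC")))
  got <- nominate_elements(asm, seeds, fg$srr_seeds)
  expect_equal(got$stats$count, 0L)
  expect_true(got$stats$ratios_undefined)
})

test_that("nested candidates sharing a TIR resolve by the documented tie-break", {
  set.seed(17)
  tir5 <- rand_dna(28); tir3 <- rand_dna(28)
  seeds <- rbind(inilcurate:::seed_frame("five_prime", tir5),
                 inilcurate:::seed_frame("three_prime", tir3))
  srr_seeds <- rbind(inilcurate:::seed_frame("five_prime", rand_dna(122)),
                     inilcurate:::seed_frame("three_prime", rand_dna(104)))
  ## one left TIR, two right TIRs, both spans TSD-valid (TGA everywhere):
  ## equal mismatches and TSD hamming -> the longer span must win
  s <- paste0(rand_dna(30), "TGA", tir5, rand_dna(200), rc(tir3), "TGA",
              rand_dna(300), rc(tir3), "TGA", rand_dna(30))
  asm <- assembly_from_strings(c(s = s))
  hits <- scan_tirs(asm, seeds, 3L)
  cand <- call_tsd(asm, pair_tirs(hits, 60L, 50000L))
  cand <- cand[!is.na(cand$tsd_len), ]
  expect_gte(nrow(cand), 2L)
  got <- nominate_elements(asm, seeds, srr_seeds)
  expect_equal(got$stats$count, 1L)
  ## brute-force tie-break over the enumerated candidates
  ord <- order(cand$tir_mismatches, cand$tsd_hamming,
               -(cand$end - cand$start), cand$start)
  expect_equal(got$elements$start, cand$start[ord[1]])
  expect_equal(got$elements$end, cand$end[ord[1]])
})

test_that("gene context uses midpoint containment with exon priority", {
  el <- data.frame(
    element_id = c("e1", "e2", "e3"), scaffold_id = "s1",
    start = c(1100L, 5000L, 1900L), end = c(1300L, 5200L, 2150L),
    length = c(200L, 200L, 250L), orientation = "+",
    tsd_len = 3L, tsd_left = "TAA", tsd_right = "TAA", tsd_hamming = 0L,
    tsd_at = TRUE, srr5_status = "present", srr3_status = "present",
    activity_class = "putatively_active", gene_context = "none",
    parent_gene = NA_character_, stringsAsFactors = FALSE)
  catalog <- structure(list(elements = el, stats = NULL),
                       class = "tpn_catalog")
  gm <- data.frame(
    scaffold_id = "s1",
    start = c(500L, 500L, 500L, 1000L, 2000L),
    end = c(2500L, 2500L, 1000L, 2000L, 2500L),
    strand = "+",
    feature_type = c("gene", "mRNA", "exon", "intron", "exon"),
    id = c("g1", "m1", NA, NA, NA),
    parent = c(NA, "g1", "m1", "m1", "m1"), stringsAsFactors = FALSE)
  got <- annotate_gene_context(catalog, gm)$elements
  expect_equal(got$gene_context, c("intron", "none", "exon"))
  expect_equal(got$parent_gene, c("m1", NA, "m1"))
  # e3 straddles the intron/exon boundary; midpoint 2025 is exonic
})

test_that("catalog statistics recompute from elements", {
  el <- data.frame(
    element_id = c("a", "b"), scaffold_id = "s",
    start = c(0L, 1000L), end = c(100L, 1300L),
    length = c(100L, 300L), orientation = "+", tsd_len = c(3L, 5L),
    tsd_left = c("TAA", "GGCCG"), tsd_right = c("TAA", "GGCCG"),
    tsd_hamming = c(0L, 0L), tsd_at = c(TRUE, FALSE),
    srr5_status = c("present", "absent"),
    srr3_status = c("present", "absent"),
    activity_class = c("putatively_active", "rearranged_inactive"),
    gene_context = c("intron", "none"),
    parent_gene = c("m1", NA), stringsAsFactors = FALSE)
  s <- catalog_stats(el)
  expect_equal(s$count, 2L)
  expect_equal(c(s$mean_len, s$min_len, s$max_len), c(200, 100, 300))
  expect_equal(s$tsd_len_histogram, list(`3` = 1L, `5` = 1L))
  expect_equal(s$tsd_at_fraction, 0.5)
  expect_equal(s$rearranged_count, 1L)
  expect_equal(s$in_gene_count, 1L)

  ## counting oracle at 19/20 AT-containing
  el20 <- el[rep(1, 20), ]
  el20$element_id <- sprintf("e%02d", 1:20)
  el20$tsd_at <- c(rep(TRUE, 19), FALSE)
  expect_equal(catalog_stats(el20)$tsd_at_fraction, 0.95)

  s0 <- catalog_stats(el[0, ])
  expect_equal(s0$count, 0L)
  expect_true(s0$ratios_undefined)
})

test_that("mining the reverse complement yields the mirror-image catalog", {
  fg <- small_forge(seed = 77L)
  fwd <- nominate_elements(fg$assembly, fg$tir_seeds, fg$srr_seeds)
  rev_asm <- Biostrings::reverseComplement(fg$assembly)
  names(rev_asm) <- names(fg$assembly)
  rev <- nominate_elements(rev_asm, fg$tir_seeds, fg$srr_seeds)
  L <- setNames(width(fg$assembly), names(fg$assembly))
  mirrored_start <- L[fwd$elements$scaffold_id] - fwd$elements$end
  mirrored_end <- L[fwd$elements$scaffold_id] - fwd$elements$start
  expect_setequal(
    paste(rev$elements$scaffold_id, rev$elements$start, rev$elements$end),
    paste(fwd$elements$scaffold_id, mirrored_start, mirrored_end))
  m <- merge(
    data.frame(key = paste(fwd$elements$scaffold_id, mirrored_start),
               ori = fwd$elements$orientation),
    data.frame(key = paste(rev$elements$scaffold_id, rev$elements$start),
               ori = rev$elements$orientation), by = "key")
  expect_true(all(m$ori.x != m$ori.y))
})

test_that("seed-free random sequence of 10 Mb yields zero nominations", {
  set.seed(19)
  tir5 <- rand_dna(28); tir3 <- rand_dna(28)
  seeds <- rbind(inilcurate:::seed_frame("five_prime", tir5),
                 inilcurate:::seed_frame("three_prime", tir3))
  srr_seeds <- rbind(inilcurate:::seed_frame("five_prime", rand_dna(122)),
                     inilcurate:::seed_frame("three_prime", rand_dna(104)))
  asm <- assembly_from_strings(c(r1 = rand_dna(5e6), r2 = rand_dna(5e6)))
  got <- nominate_elements(asm, seeds, srr_seeds)
  expect_equal(got$stats$count, 0L)
})
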