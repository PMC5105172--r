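## Independent oracles and small fixture builders used across the suite.
## Each oracle restates the operation's contract from first principles
## (character vectors and explicit loops), never via the implementation
## under test.

rand_dna <- function(n, probs = c(0.25, 0.25, 0.25, 0.25)) {
  paste(sample(c("A", "C", "G", "T"), n, replace = TRUE, prob = probs),
        collapse = "")
}

rc <- function(x) {
  as.character(Biostrings::reverseComplement(Biostrings::DNAString(x)))
}

## exhaustive sliding-window Hamming scan over every offset and strand
oracle_scan_tirs <- function(assembly, seeds, max_mm) {
  rows <- list()
  for (si in seq_len(nrow(seeds))) {
    for (ci in seq_along(assembly)) {
      s <- strsplit(toupper(as.character(assembly[[ci]])), "")[[1]]
      n <- length(s)
      for (strand in c("+", "-")) {
        pat <- if (strand == "+") seeds$seq[si] else rc(seeds$seq[si])
        p <- strsplit(pat, "")[[1]]
        k <- length(p)
        if (n < k) next
        mm <- integer(n - k + 1L)
        for (j in seq_len(k)) {
          mm <- mm + as.integer(s[j:(n - k + j)] != p[j])
        }
        hit <- which(mm <= max_mm)
        if (!length(hit)) next
        rows[[length(rows) + 1L]] <- data.frame(
          scaffold_id = names(assembly)[ci], start = hit - 1L,
          end = hit - 1L + k, end_type = seeds$end_type[si],
          strand = strand, mismatches = mm[hit],
          stringsAsFactors = FALSE)
      }
    }
  }
  if (!length(rows)) return(inilcurate:::empty_tir_hits())
  h <- do.call(rbind, rows)
  h <- h[order(match(h$scaffold_id, names(assembly)), h$start,
               h$end_type, h$strand, h$mismatches), ]
  h <- h[!duplicated(paste(h$scaffold_id, h$start, h$end_type)), ]
  rownames(h) <- NULL
  h
}

## brute-force all-pairs candidate enumeration
oracle_pair_tirs <- function(hits, min_span, max_span) {
  rows <- list()
  n <- nrow(hits)
  for (i in seq_len(n)) {
    for (j in seq_len(n)) {
      if (hits$scaffold_id[i] != hits$scaffold_id[j]) next
      if (hits$strand[i] != "+" || hits$strand[j] != "-") next
      if (hits$end_type[i] == hits$end_type[j]) next
      if (hits$start[j] <= hits$start[i]) next
      span <- hits$end[j] - hits$start[i]
      if (span < min_span || span > max_span) next
      rows[[length(rows) + 1L]] <- data.frame(
        scaffold_id = hits$scaffold_id[i], start = hits$start[i],
        end = hits$end[j],
        orientation = if (hits$end_type[i] == "five_prime") "+" else "-",
        tir_mismatches = hits$mismatches[i] + hits$mismatches[j],
        stringsAsFactors = FALSE)
    }
  }
  if (!length(rows)) return(NULL)
  out <- do.call(rbind, rows)
  out[order(out$scaffold_id, out$start, out$end), ]
}

## single-pass character scan for maximal N runs
oracle_gap_runs <- function(seq_chr, min_len) {
  s <- strsplit(toupper(seq_chr), "")[[1]]
  runs <- rle(s == "N")
  ends <- cumsum(runs$lengths)
  starts <- ends - runs$lengths + 1L
  keep <- runs$values & runs$lengths >= min_len
  data.frame(start = starts[keep] - 1L, end = ends[keep],
             length = runs$lengths[keep])
}

## per-mRNA pairwise exon-gap enumeration
oracle_introns <- function(feats) {
  rows <- list()
  mrna <- feats[feats$feature_type == "mRNA", ]
  for (i in seq_len(nrow(mrna))) {
    ex <- feats[feats$feature_type == "exon" &
                !is.na(feats$parent) & feats$parent == mrna$id[i], ]
    ex <- ex[order(ex$start), ]
    if (nrow(ex) < 2L) next
    for (j in seq_len(nrow(ex) - 1L)) {
      if (ex$end[j] < ex$start[j + 1L]) {
        rows[[length(rows) + 1L]] <- data.frame(
          parent = mrna$id[i], start = ex$end[j],
          end = ex$start[j + 1L], stringsAsFactors = FALSE)
      }
    }
  }
  if (!length(rows)) return(NULL)
  do.call(rbind, rows)
}

## sort-and-scan N50
oracle_n50 <- function(lengths) {
  s <- sort(lengths, decreasing = TRUE)
  half <- sum(s) / 2
  acc <- 0
  for (i in seq_along(s)) {
    acc <- acc + s[i]
    if (acc >= half) return(list(n50 = s[i], l50 = i))
  }
}

## boolean-mask interval union length over [0, len)
oracle_union_len <- function(starts, ends, len) {
  mask <- logical(len)
  for (i in seq_along(starts)) {
    mask[(starts[i] + 1L):ends[i]] <- TRUE
  }
  sum(mask)
}

## one-at-a-time iterated 80/80 filtering until stable
oracle_filter_8080 <- function(g, marker_min, sample_min) {
  repeat {
    bad_m <- which(rowMeans(!is.na(g)) < marker_min)
    if (length(bad_m)) {
      g <- g[-bad_m[1], , drop = FALSE]
      next
    }
    bad_s <- which(colMeans(!is.na(g)) < sample_min)
    if (length(bad_s)) {
      g <- g[, -bad_s[1], drop = FALSE]
      next
    }
    break
  }
  g
}

## small forged genome shared by several tests
small_forge <- function(seed = 42L) {
  forge_genome(forge_config(
    seed = seed, n_chromosomes = 3L, chromosome_len = 100000L,
    tpn = list(n_intact = 4L, n_rearranged = 2L,
               len_range = c(161L, 5000L), min_separation = 10000L),
    telomere = list(n_arrays = 2L), centromere = list(n_arrays = 2L),
    rdna = list(n_units = 2L, n_5s = 5L)))
}
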