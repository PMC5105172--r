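## Tpn1/CACTA transposon mining.
##
## Pipeline: TIR Hamming scan -> convergent TIR pairing -> TSD call ->
## SRR orientation/integrity -> overlap resolution -> activity class ->
## gene context -> catalog statistics.
##
## CACTA elements are bounded by ~28-bp terminal inverted repeats (TIRs),
## flanked by a 3-5 bp target-site duplication (TSD), and carry
## sub-terminal repetitive regions (SRRs: tandem 122-bp units at the 5'
## end, 104-bp at the 3' end) that are cis-requirements for transposition.
## An element whose SRRs are intact is putatively active; one with
## missing or inverted SRR copies is classified rearranged/inactive.

#' Load TIR or SRR seed sequences from FASTA
#'
#' Seed ids must encode the element end they belong to: the id (first
#' whitespace-delimited token) has to contain `five_prime` or
#' `three_prime`.
#'
#' @param path FASTA of seed sequences.
#' @return `data.frame` with columns `end_type`, `seq`, `unit_len`.
#' @export
load_seeds <- function(path) {
  ss <- load_genome(path)
  ids <- names(ss)
  end_type <- ifelse(grepl("five_prime", ids), "five_prime",
                     ifelse(grepl("three_prime", ids), "three_prime", NA))
  if (anyNA(end_type)) {
    stop("seed id(s) lacking five_prime/three_prime tag: ",
         paste(ids[is.na(end_type)], collapse = ", "))
  }
  data.frame(end_type = end_type, seq = toupper(as.character(ss)),
             unit_len = width(ss), stringsAsFactors = FALSE)
}

seed_frame <- function(end_type, seq) {
  data.frame(end_type = end_type, seq = toupper(seq),
             unit_len = nchar(seq), stringsAsFactors = FALSE)
}

hamming <- function(a, b) {
  sum(strsplit(a, "", fixed = TRUE)[[1]] != strsplit(b, "", fixed = TRUE)[[1]])
}

revcomp_chr <- function(x) {
  as.character(reverseComplement(DNAString(x)))
}

empty_tir_hits <- function() {
  data.frame(scaffold_id = character(), start = integer(), end = integer(),
             end_type = character(), strand = character(),
             mismatches = integer(), stringsAsFactors = FALSE)
}

#' Scan a genome for TIR seed occurrences
#'
#' Ungapped Hamming scan of every seed against both strands of every
#' scaffold. Reports each occurrence with at most `max_mismatches`
#' substitutions; no indels. Case is ignored. Hits at the same
#' (scaffold, position, end_type) arising from both strands of a
#' near-palindromic seed are reported once (plus strand preferred).
#'
#' @param assembly Named `DNAStringSet`.
#' @param seeds Seed `data.frame` from [load_seeds()] or [seed_frame()];
#'   seeds must be N-free.
#' @param max_mismatches Maximum Hamming distance (default 3 for the
#'   28-bp TIRs); must be below a quarter of the shortest seed length.
#' @return `data.frame` with columns `scaffold_id`, `start`, `end`
#'   (0-based half-open), `end_type`, `strand`, `mismatches`, sorted by
#'   scaffold (assembly order) then start.
#' @export
scan_tirs <- function(assembly, seeds, max_mismatches = 3L) {
  stopifnot(nrow(seeds) >= 1L)
  if (any(grepl("N", seeds$seq, fixed = TRUE))) {
    stop("seed sequences must not contain N")
  }
  if (max_mismatches >= min(nchar(seeds$seq)) / 4) {
    stop("max_mismatches must be < seed length / 4")
  }
  out <- list()
  for (si in seq_len(nrow(seeds))) {
    pat_f <- DNAString(seeds$seq[si])
    pat_r <- reverseComplement(pat_f)
    for (ci in seq_along(assembly)) {
      subj <- assembly[[ci]]
      for (strand in c("+", "-")) {
        pat <- if (strand == "+") pat_f else pat_r
        m <- matchPattern(pat, subj, max.mismatch = max_mismatches,
                          with.indels = FALSE, fixed = TRUE)
        if (!length(m)) next
        pch <- strsplit(as.character(pat), "", fixed = TRUE)[[1]]
        mm <- vapply(strsplit(toupper(as.character(m)), "", fixed = TRUE),
                     function(x) sum(x != pch), integer(1))
        out[[length(out) + 1L]] <- data.frame(
          scaffold_id = names(assembly)[ci],
          start = BiocGenerics::start(m) - 1L,
          end = BiocGenerics::end(m),
          end_type = seeds$end_type[si], strand = strand,
          mismatches = mm, stringsAsFactors = FALSE)
      }
    }
  }
  if (!length(out)) return(empty_tir_hits())
  hits <- do.call(rbind, out)
  ## dedup palindromic double-reports on (scaffold, start, end_type)
  hits <- hits[order(match(hits$scaffold_id, names(assembly)), hits$start,
                     hits$end_type, hits$strand, hits$mismatches), ]
  key <- paste(hits$scaffold_id, hits$start, hits$end_type)
  hits <- hits[!duplicated(key), ]
  rownames(hits) <- NULL
  hits
}

#' Pair TIR hits into candidate element spans
#'
#' A candidate element is a convergent pair of TIR hits on one scaffold:
#' a plus-strand hit on the left and a minus-strand hit of the other end
#' type on the right (a forward element has its 5' TIR forward on the
#' left and its 3' TIR reverse-complemented on the right; the mirrored
#' arrangement is a reverse element). All eligible ordered pairs with a
#' span in `[min_span, max_span]` are returned; conflicting/nested
#' candidates are resolved downstream by the TSD filter and greedy
#' selection.
#'
#' @param hits TIR hit `data.frame` from [scan_tirs()].
#' @param min_span,max_span Allowed span (`right.end - left.start`) in
#'   bases. Defaults 60 and 50000 cover the family's observed 161-40619
#'   bp range.
#' @return `data.frame` of candidates: `scaffold_id`, `start`, `end`,
#'   `orientation`, `tir_mismatches`.
#' @export
pair_tirs <- function(hits, min_span = 60L, max_span = 50000L) {
  if (min_span >= max_span) stop("min_span must be < max_span")
  empty <- data.frame(scaffold_id = character(), start = integer(),
                      end = integer(), orientation = character(),
                      tir_mismatches = integer(), stringsAsFactors = FALSE)
  if (!nrow(hits)) return(empty)
  out <- list()
  for (sc in unique(hits$scaffold_id)) {
    h <- hits[hits$scaffold_id == sc, ]
    left <- h[h$strand == "+", ]
    right <- h[h$strand == "-", ]
    if (!nrow(left) || !nrow(right)) next
    for (i in seq_len(nrow(left))) {
      for (j in seq_len(nrow(right))) {
        if (left$end_type[i] == right$end_type[j]) next
        span <- right$end[j] - left$start[i]
        if (right$start[j] <= left$start[i]) next
        if (span < min_span || span > max_span) next
        out[[length(out) + 1L]] <- data.frame(
          scaffold_id = sc, start = left$start[i], end = right$end[j],
          orientation = if (left$end_type[i] == "five_prime") "+" else "-",
          tir_mismatches = left$mismatches[i] + right$mismatches[j],
          stringsAsFactors = FALSE)
      }
    }
  }
  if (!length(out)) return(empty)
  out <- do.call(rbind, out)
  out <- out[order(out$scaffold_id, out$start, out$end), ]
  rownames(out) <- NULL
  out
}

#' Call target-site duplications for candidate spans
#'
#' Extracts the bases immediately flanking each candidate span and looks
#' for a duplicated target site, preferring longer exact duplications:
#' exact 5-mer, then exact 4-mer, then exact 3-mer, then 3-mer with one
#' mismatch. A candidate whose flanks run off the scaffold, or whose
#' flanks admit no duplication under those rules, gets `tsd_len = NA`.
#'
#' @param assembly Named `DNAStringSet`.
#' @param candidates Candidate `data.frame` from [pair_tirs()].
#' @param tsd_lengths Candidate TSD lengths (default 3:5).
#' @param max_hamming Mismatches tolerated at the shortest length
#'   (default 1).
#' @return `candidates` with columns `tsd_len`, `tsd_left`, `tsd_right`,
#'   `tsd_hamming`, `tsd_at` appended.
#' @export
call_tsd <- function(assembly, candidates, tsd_lengths = 3:5,
                     max_hamming = 1L) {
  n <- nrow(candidates)
  res <- data.frame(tsd_len = rep(NA_integer_, n),
                    tsd_left = rep(NA_character_, n),
                    tsd_right = rep(NA_character_, n),
                    tsd_hamming = rep(NA_integer_, n),
                    tsd_at = rep(NA, n), stringsAsFactors = FALSE)
  if (!n) return(cbind(candidates, res))
  lens <- sort(tsd_lengths, decreasing = TRUE)
  for (i in seq_len(n)) {
    sc <- candidates$scaffold_id[i]
    L <- width(assembly[names(assembly) == sc])
    s <- candidates$start[i]; e <- candidates$end[i]
    found <- FALSE
    ## pass 1: exact match, longest first; pass 2: Hamming<=max at 3
    for (k in lens) {
      if (s - k < 0L || e + k > L) next
      lf <- toupper(as.character(subseq(assembly[[sc]], s - k + 1L, s)))
      rf <- toupper(as.character(subseq(assembly[[sc]], e + 1L, e + k)))
      if (lf == rf) {
        res[i, ] <- list(k, lf, rf, 0L, grepl("[AT]", lf))
        found <- TRUE
        break
      }
    }
    if (!found && max_hamming >= 1L) {
      k <- min(tsd_lengths)
      if (s - k >= 0L && e + k <= L) {
        lf <- toupper(as.character(subseq(assembly[[sc]], s - k + 1L, s)))
        rf <- toupper(as.character(subseq(assembly[[sc]], e + 1L, e + k)))
        h <- hamming(lf, rf)
        if (h <= max_hamming) {
          res[i, ] <- list(k, lf, rf, h, grepl("[AT]", lf))
        }
      }
    }
  }
  cbind(candidates, res)
}

## Count seed occurrences in a window on both orientations and measure
## the longest tandem chain (successive starts <= 1.5 unit lengths apart)
## among same-orientation matches.
srr_window_counts <- function(window, seed, divergence) {
  ulen <- nchar(seed)
  mm <- floor(divergence * ulen)
  cnt <- function(pat) {
    if (length(window) < ulen) return(integer())
    m <- matchPattern(DNAString(pat), window, max.mismatch = mm,
                      with.indels = FALSE, fixed = TRUE)
    BiocGenerics::start(m)
  }
  fwd <- cnt(seed)
  rev <- cnt(revcomp_chr(seed))
  chain <- 0L
  if (length(fwd)) {
    gaps <- diff(sort(fwd))
    runs <- rle(gaps <= 1.5 * ulen)
    chain <- 1L + max(0L, if (any(runs$values)) max(runs$lengths[runs$values]) else 0L)
    if (!length(gaps)) chain <- 1L
  }
  list(n_fwd = length(fwd), n_rev = length(rev), tandem = chain)
}

#' Assess sub-terminal repetitive regions of a candidate element
#'
#' Looks for tandem copies of the end-appropriate SRR unit (122-bp type
#' at the 5' end, 104-bp type at the 3' end) inside a window at each end
#' of the element. An end is `present` when at least `min_srr_copies`
#' tandem copies match on the expected orientation, `rearranged` when
#' copies exist but are too few or inverted, `absent` otherwise.
#' Orientation of the element is `+` when the 5'-type unit sits at the
#' left end, `-` when at the right.
#'
#' @param assembly Named `DNAStringSet`.
#' @param span One-row `data.frame` (or list) with `scaffold_id`,
#'   `start`, `end`.
#' @param srr_seeds Seed `data.frame` with one `five_prime` (122-bp) and
#'   one `three_prime` (104-bp) entry.
#' @param subterminal_window Window searched at each end (default 600
#'   bases; clipped to half the span).
#' @param min_srr_copies Tandem copies required for `present` (default 2).
#' @param srr_divergence Per-unit mismatch fraction tolerated (default
#'   0.10).
#' @param orientation Optional known orientation (`"+"`/`"-"`); inferred
#'   from the 122-bp unit's position when `NULL`.
#' @return `list(srr5_status, srr3_status, orientation)`.
#' @export
detect_srr <- function(assembly, span, srr_seeds, subterminal_window = 600L,
                       min_srr_copies = 2L, srr_divergence = 0.10,
                       orientation = NULL) {
  sc <- span$scaffold_id
  eseq <- subseq(assembly[[sc]], span$start + 1L, span$end)
  L <- length(eseq)
  ## clip the window to the element; for short elements the two end
  ## windows overlap, which is harmless since each is searched for a
  ## different seed, while clipping to span/2 would truncate the SRR
  ## block of a minimal intact element
  w <- min(subterminal_window, L)
  seed5 <- srr_seeds$seq[srr_seeds$end_type == "five_prime"][1]
  seed3 <- srr_seeds$seq[srr_seeds$end_type == "three_prime"][1]
  left_w <- subseq(eseq, 1L, max(1L, w))
  right_w <- subseq(eseq, max(1L, L - w + 1L), L)
  if (is.null(orientation)) {
    l5 <- srr_window_counts(left_w, seed5, srr_divergence)
    r5 <- srr_window_counts(right_w, seed5, srr_divergence)
    n_l <- l5$n_fwd + l5$n_rev
    n_r <- r5$n_fwd + r5$n_rev
    if (n_l + n_r > 0L) {
      orientation <- if (n_l >= n_r) "+" else "-"
    } else {
      l3 <- srr_window_counts(left_w, seed3, srr_divergence)
      r3 <- srr_window_counts(right_w, seed3, srr_divergence)
      orientation <- if (l3$n_fwd + l3$n_rev >
                         r3$n_fwd + r3$n_rev) "-" else "+"
    }
  }
  ## work on the element's own 5'->3' strand
  if (orientation == "-") {
    eseq <- reverseComplement(eseq)
    left_w <- subseq(eseq, 1L, max(1L, w))
    right_w <- subseq(eseq, max(1L, L - w + 1L), L)
  }
  status_of <- function(window, seed) {
    cc <- srr_window_counts(window, seed, srr_divergence)
    if (cc$tandem >= min_srr_copies && cc$n_fwd >= min_srr_copies) "present"
    else if (cc$n_fwd + cc$n_rev >= 1L) "rearranged"
    else "absent"
  }
  list(srr5_status = status_of(left_w, seed5),
       srr3_status = status_of(right_w, seed3),
       orientation = orientation)
}

#' Default configuration for element nomination
#'
#' @param max_mismatches TIR scan Hamming tolerance.
#' @param min_span,max_span Candidate span bounds in bases.
#' @param tsd_lengths,tsd_max_hamming TSD calling rules.
#' @param subterminal_window,min_srr_copies,srr_divergence SRR rules.
#' @return Named list of parameters.
#' @export
tpn_config <- function(max_mismatches = 3L, min_span = 60L,
                       max_span = 50000L, tsd_lengths = 3:5,
                       tsd_max_hamming = 1L, subterminal_window = 600L,
                       min_srr_copies = 2L, srr_divergence = 0.10) {
  as.list(environment())
}

#' Nominate Tpn1-family elements genome-wide
#'
#' Runs the full mining pipeline: TIR scan, convergent pairing, TSD
#' calling, greedy overlap resolution, SRR assessment, activity
#' classification, optional gene-context annotation, and catalog
#' statistics. Overlapping candidates are resolved greedily by lowest
#' total TIR mismatches, then lowest TSD Hamming distance, then longest
#' span, then leftmost start; accepted elements never overlap.
#'
#' @param assembly Named `DNAStringSet`.
#' @param tir_seeds,srr_seeds Seed `data.frame`s (see [load_seeds()]).
#' @param gene_models Optional gene-model `data.frame` from
#'   [load_gene_models()].
#' @param config Parameter list from [tpn_config()].
#' @return A `tpn_catalog`: `list(elements = data.frame, stats = list)`.
#' @export
nominate_elements <- function(assembly, tir_seeds, srr_seeds,
                              gene_models = NULL, config = tpn_config()) {
  hits <- scan_tirs(assembly, tir_seeds, config$max_mismatches)
  cand <- pair_tirs(hits, config$min_span, config$max_span)
  cand <- call_tsd(assembly, cand, config$tsd_lengths,
                   config$tsd_max_hamming)
  cand <- cand[!is.na(cand$tsd_len), , drop = FALSE]
  ## greedy overlap resolution
  if (nrow(cand)) {
    ord <- order(cand$tir_mismatches, cand$tsd_hamming,
                 -(cand$end - cand$start), cand$start)
    cand <- cand[ord, ]
    keep <- logical(nrow(cand))
    acc <- list()
    for (i in seq_len(nrow(cand))) {
      sc <- cand$scaffold_id[i]
      prev <- acc[[sc]]
      if (is.null(prev) ||
          !any(cand$start[i] < prev[, 2] & cand$end[i] > prev[, 1])) {
        keep[i] <- TRUE
        acc[[sc]] <- rbind(prev, c(cand$start[i], cand$end[i]))
      }
    }
    cand <- cand[keep, , drop = FALSE]
    cand <- cand[order(match(cand$scaffold_id, names(assembly)),
                       cand$start), , drop = FALSE]
  }
  n <- nrow(cand)
  el <- data.frame(
    element_id = if (n) sprintf("tpn_%04d", seq_len(n)) else character(),
    scaffold_id = cand$scaffold_id,
    start = cand$start, end = cand$end,
    length = cand$end - cand$start,
    orientation = cand$orientation,
    tsd_len = cand$tsd_len, tsd_left = cand$tsd_left,
    tsd_right = cand$tsd_right, tsd_hamming = cand$tsd_hamming,
    tsd_at = cand$tsd_at,
    srr5_status = character(n), srr3_status = character(n),
    activity_class = character(n),
    gene_context = rep("none", n), parent_gene = rep(NA_character_, n),
    stringsAsFactors = FALSE)
  for (i in seq_len(n)) {
    srr <- detect_srr(assembly, el[i, ], srr_seeds,
                      config$subterminal_window, config$min_srr_copies,
                      config$srr_divergence,
                      orientation = el$orientation[i])
    el$srr5_status[i] <- srr$srr5_status
    el$srr3_status[i] <- srr$srr3_status
  }
  el$activity_class <- ifelse(
    el$srr5_status == "present" & el$srr3_status == "present",
    "putatively_active", "rearranged_inactive")
  catalog <- structure(list(elements = el, stats = NULL),
                       class = "tpn_catalog")
  if (!is.null(gene_models)) {
    catalog <- annotate_gene_context(catalog, gene_models)
  }
  catalog$stats <- catalog_stats(catalog)
  catalog
}

#' Annotate the gene context of catalog elements
#'
#' An element's context is the highest-priority gene feature that
#' contains its midpoint: `exon` over `five_prime_UTR` over `intron`,
#' else `none`. The containing feature's parent mRNA is recorded.
#'
#' @param catalog A `tpn_catalog`.
#' @param gene_models Gene-model `data.frame` (with derived introns)
#'   from [load_gene_models()].
#' @return The catalog with `gene_context`/`parent_gene` filled and
#'   stats refreshed.
#' @export
annotate_gene_context <- function(catalog, gene_models) {
  el <- catalog$elements
  prio <- c(exon = 1L, five_prime_UTR = 2L, intron = 3L)
  gm <- gene_models[gene_models$feature_type %in% names(prio), ]
  for (i in seq_len(nrow(el))) {
    mid <- floor((el$start[i] + el$end[i]) / 2)
    hit <- gm[gm$scaffold_id == el$scaffold_id[i] &
              gm$start <= mid & mid < gm$end, ]
    if (!nrow(hit)) {
      el$gene_context[i] <- "none"
      el$parent_gene[i] <- NA_character_
      next
    }
    hit <- hit[order(prio[hit$feature_type]), ]
    el$gene_context[i] <- hit$feature_type[1]
    el$parent_gene[i] <- hit$parent[1]
  }
  catalog$elements <- el
  catalog$stats <- catalog_stats(catalog)
  catalog
}

#' Summary statistics of an element catalog
#'
#' @param catalog A `tpn_catalog` or its `elements` data.frame.
#' @return List with `count`, `mean_len`, `min_len`, `max_len`,
#'   `tsd_len_histogram`, `tsd_mismatch_count`, `tsd_at_fraction`,
#'   `rearranged_count`, `in_gene_count`, and `ratios_undefined` (TRUE
#'   for an empty catalog).
#' @export
catalog_stats <- function(catalog) {
  el <- if (inherits(catalog, "tpn_catalog")) catalog$elements else catalog
  n <- nrow(el)
  if (!n) {
    return(list(count = 0L, mean_len = NA_real_, min_len = NA_integer_,
                max_len = NA_integer_, tsd_len_histogram = list(),
                tsd_mismatch_count = 0L, tsd_at_fraction = NA_real_,
                rearranged_count = 0L, in_gene_count = 0L,
                ratios_undefined = TRUE))
  }
  hist <- table(el$tsd_len)
  list(count = n,
       mean_len = mean(el$length),
       min_len = min(el$length),
       max_len = max(el$length),
       tsd_len_histogram = as.list(setNames(as.integer(hist), names(hist))),
       tsd_mismatch_count = sum(el$tsd_hamming > 0L),
       tsd_at_fraction = mean(el$tsd_at),
       rearranged_count = sum(el$activity_class == "rearranged_inactive"),
       in_gene_count = sum(el$gene_context != "none"),
       ratios_undefined = FALSE)
}

#' @export
print.tpn_catalog <- function(x, ...) {
  s <- x$stats
  cat(sprintf("tpn_catalog: %d elements", s$count))
  if (s$count) {
    cat(sprintf(" (mean %.0f bp, range %d-%d bp; %d rearranged, %d in genes)",
                s$mean_len, s$min_len, s$max_len, s$rearranged_count,
                s$in_gene_count))
  }
  cat("\n")
  invisible(x)
}

#' Write an element catalog to disk
#'
#' Emits the per-element table (TSV), the element intervals (GFF3 type
#' `terminal_inverted_repeat_element`, and BED6), and the stats block
#' (JSON).
#'
#' @param catalog A `tpn_catalog`.
#' @param dir Output directory (created if needed).
#' @param prefix File name prefix.
#' @return The directory, invisibly.
#' @export
write_tpn_catalog <- function(catalog, dir, prefix = "tpn") {
  dir.create(dir, recursive = TRUE, showWarnings = FALSE)
  el <- catalog$elements
  write.table(el, file.path(dir, paste0(prefix, "_elements.tsv")),
              sep = "\t", quote = FALSE, row.names = FALSE)
  gff <- data.frame(scaffold_id = el$scaffold_id, start = el$start,
                    end = el$end, strand = el$orientation,
                    feature_type = "terminal_inverted_repeat_element",
                    id = el$element_id, stringsAsFactors = FALSE)
  write_gff3(gff, file.path(dir, paste0(prefix, "_elements.gff3")))
  bed <- data.frame(scaffold_id = el$scaffold_id, start = el$start,
                    end = el$end, name = el$element_id, score = 0,
                    strand = el$orientation, stringsAsFactors = FALSE)
  write_bed(bed, file.path(dir, paste0(prefix, "_elements.bed")))
  jsonlite::write_json(catalog$stats,
                       file.path(dir, paste0(prefix, "_stats.json")),
                       auto_unbox = TRUE, digits = NA)
  invisible(dir)
}
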