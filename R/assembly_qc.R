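## Assembly validation: N50-family statistics, BAC-end paired best-hit
## scoring, and EST coverage summaries.

#' Assembly length statistics
#'
#' N50 is the length of the sequence at which the cumulative
#' descending-sorted lengths first reach half the assembly total; L50
#' is that sequence's rank.
#'
#' @param lengths Vector of sequence lengths (all > 0).
#' @return List with `n_seqs`, `total`, `n50`, `l50`, `longest`.
#' @export
compute_stats <- function(lengths) {
  if (!length(lengths)) stop("empty length list")
  stopifnot(all(lengths > 0))
  s <- sort(as.numeric(lengths), decreasing = TRUE)
  cum <- cumsum(s)
  l50 <- which(cum >= sum(s) / 2)[1]
  list(n_seqs = length(s), total = sum(s), n50 = s[l50], l50 = l50,
       longest = s[1])
}

#' Score BAC-end read pairs against an assembly
#'
#' For each read pair, every combination of one hit per read is
#' enumerated; a combination is eligible when both hits land on the
#' same target, on opposite strands, facing inward (the plus-strand hit
#' upstream of the minus-strand hit), with an implied insert at most
#' `max_insert`. The eligible combination with the highest combined
#' score (sum of the two hits' scores; ties broken towards the smaller
#' insert) defines a `same_scaffold` call with
#' `insert_len = right.end - left.start`. Pairs whose reads both align
#' but admit no eligible combination are `cross_scaffold` (each read's
#' best hit retained); pairs with one aligned read are `unpaired`, with
#' none `unaligned`. Summary rates are computed over pairs with both
#' reads aligned, the denominator used for the headline same-scaffold
#' percentage; the rate over all pairs is reported alongside.
#'
#' @param hits Alignment `data.frame` (see [load_alignments()]) whose
#'   `query_id`s end in `/1` or `/2`, identifying the two reads of a
#'   pair.
#' @param pair_ids Optional vector of all pair ids (so fully unaligned
#'   pairs are counted); defaults to the pairs present in `hits`.
#' @param max_insert Maximum accepted insert (default 400000 bases, 4x
#'   the ~100 kb BAC insert).
#' @return `list(calls, summary)`: per-pair `data.frame` and a summary
#'   list with `same_scaffold_rate`, `cross_scaffold_rate`,
#'   `unpaired_rate`, `same_scaffold_rate_all`, `insert_mean`,
#'   `insert_median`, `n_pairs`, `n_both_aligned`.
#' @export
pair_bac_ends <- function(hits, pair_ids = NULL, max_insert = 400000L) {
  pid <- sub("/[12]$", "", hits$query_id)
  mate <- sub("^.*/", "", hits$query_id)
  if (!all(mate %in% c("1", "2"))) {
    stop("query ids must end in /1 or /2")
  }
  if (is.null(pair_ids)) pair_ids <- unique(pid)
  calls <- vector("list", length(pair_ids))
  for (i in seq_along(pair_ids)) {
    h1 <- hits[pid == pair_ids[i] & mate == "1", , drop = FALSE]
    h2 <- hits[pid == pair_ids[i] & mate == "2", , drop = FALSE]
    status <- "unaligned"
    insert <- NA_real_
    target <- NA_character_
    if (nrow(h1) && nrow(h2)) {
      best <- NULL
      for (a in seq_len(nrow(h1))) {
        for (b in seq_len(nrow(h2))) {
          if (h1$target_id[a] != h2$target_id[b]) next
          if (h1$strand[a] == h2$strand[b]) next
          left <- if (h1$strand[a] == "+") h1[a, ] else h2[b, ]
          right <- if (h1$strand[a] == "+") h2[b, ] else h1[a, ]
          if (left$target_start > right$target_start) next  # not inward
          ins <- right$target_end - left$target_start
          if (ins > max_insert) next
          sc <- h1$score[a] + h2$score[b]
          if (is.null(best) || sc > best$sc ||
              (sc == best$sc && ins < best$ins)) {
            best <- list(sc = sc, ins = ins, target = left$target_id)
          }
        }
      }
      if (!is.null(best)) {
        status <- "same_scaffold"
        insert <- best$ins
        target <- best$target
      } else {
        status <- "cross_scaffold"
      }
    } else if (nrow(h1) || nrow(h2)) {
      status <- "unpaired"
    }
    calls[[i]] <- data.frame(pair_id = pair_ids[i], status = status,
                             insert_len = insert, target_id = target,
                             stringsAsFactors = FALSE)
  }
  calls <- do.call(rbind, calls)
  both <- calls$status %in% c("same_scaffold", "cross_scaffold")
  n_both <- sum(both)
  same <- sum(calls$status == "same_scaffold")
  summary <- list(
    same_scaffold_rate = if (n_both) same / n_both else NA_real_,
    cross_scaffold_rate = if (n_both)
      sum(calls$status == "cross_scaffold") / n_both else NA_real_,
    unpaired_rate = if (n_both) 0 else NA_real_,
    same_scaffold_rate_all = if (nrow(calls)) same / nrow(calls)
      else NA_real_,
    insert_mean = if (same) mean(calls$insert_len[calls$status ==
                                                  "same_scaffold"])
      else NA_real_,
    insert_median = if (same)
      median(calls$insert_len[calls$status == "same_scaffold"])
      else NA_real_,
    n_pairs = nrow(calls), n_both_aligned = n_both)
  list(calls = calls, summary = summary)
}

#' EST alignment coverage summary
#'
#' Per query (EST), coverage is the fraction of the query covered by
#' the union of its query-side aligned spans against its best target
#' (the target with the highest total score for that query).
#'
#' @param hits Alignment `data.frame` (see [load_alignments()]).
#' @param query_lens Named vector of query lengths for every EST
#'   (aligned or not); names are query ids.
#' @param covered_threshold Coverage counted as "well covered" (default
#'   0.90).
#' @return List with `aligned_fraction`, `well_covered_fraction`,
#'   `n_queries`, and `per_query` coverage `data.frame`.
#' @export
est_coverage <- function(hits, query_lens, covered_threshold = 0.90) {
  stopifnot(!is.null(names(query_lens)))
  qs <- names(query_lens)
  cov <- setNames(numeric(length(qs)), qs)
  aligned <- setNames(logical(length(qs)), qs)
  for (q in unique(hits$query_id)) {
    if (!q %in% qs) stop("hit for unknown query: ", q)
    h <- hits[hits$query_id == q, ]
    if (any(h$query_end > query_lens[q])) {
      stop("query span exceeds query length for ", q)
    }
    aligned[q] <- TRUE
    sc <- tapply(h$score, h$target_id, sum)
    best <- names(sc)[which.max(sc)]
    hb <- h[h$target_id == best, ]
    covered <- sum(width(IRanges::reduce(
      IRanges(hb$query_start + 1L, hb$query_end))))
    cov[q] <- covered / query_lens[q]
  }
  list(aligned_fraction = mean(aligned),
       well_covered_fraction = mean(cov >= covered_threshold),
       n_queries = length(qs),
       per_query = data.frame(query_id = qs, aligned = aligned,
                              coverage = cov, row.names = NULL,
                              stringsAsFactors = FALSE))
}
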