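## Tandem-repeat landscape: monomer-seeded array detection, telomere
## classification (monomer AAACCCT), centromere stretch merging (~173-bp
## monomer, >3 kb stretches merged within 50 kb), and rDNA/NOR
## cataloguing (18S-5.8S-25S units, 5S clusters).

#' Find tandem arrays of a known monomer
#'
#' Detects maximal runs of consecutive monomer copies on either strand.
#' Each copy may diverge from the monomer by up to `max_divergence`
#' substitutions per unit; any rotation (phase) of the monomer is
#' detected, and runs separated by no more than one monomer length are
#' merged, so a single decayed unit does not break an array. Array
#' boundaries are extended base-by-base while the sequence continues the
#' monomer phase, so partial terminal units contribute fractional
#' copies: `copies = span / monomer length`.
#'
#' @param assembly Named `DNAStringSet`.
#' @param monomer Monomer sequence (character), length >= 2.
#' @param min_copies Minimum (fractional) copies to report (default 2).
#' @param max_divergence Per-unit mismatch fraction tolerated (default
#'   0.10; must be < 0.5).
#' @return `data.frame` with columns `scaffold_id`, `start`, `end`,
#'   `monomer`, `monomer_len`, `copies`, `identity`, `strand`.
#' @export
find_tandem_arrays <- function(assembly, monomer, min_copies = 2,
                               max_divergence = 0.10) {
  monomer <- toupper(monomer)
  L <- nchar(monomer)
  stopifnot(L >= 2L, max_divergence >= 0, max_divergence < 0.5)
  mm <- floor(max_divergence * L)
  out <- list()
  for (ci in seq_along(assembly)) {
    subj <- assembly[[ci]]
    slen <- length(subj)
    schars <- strsplit(toupper(as.character(subj)), "", fixed = TRUE)[[1]]
    for (strand in c("+", "-")) {
      pat <- if (strand == "+") monomer else revcomp_chr(monomer)
      pchars <- strsplit(pat, "", fixed = TRUE)[[1]]
      m <- matchPattern(DNAString(pat), subj, max.mismatch = mm,
                        with.indels = FALSE, fixed = TRUE)
      if (!length(m)) next
      starts <- BiocGenerics::start(m) - 1L  # 0-based
      starts <- sort(starts)
      grp <- cumsum(c(1L, as.integer(diff(starts) > 2L * L)))
      for (g in split(starts, grp)) {
        core_s <- min(g)
        core_e <- max(g) + L
        ## phase-true extension over exactly matching bases
        p <- core_s - 1L
        while (p >= 0L &&
               schars[p + 1L] == pchars[((p - core_s) %% L) + 1L]) {
          p <- p - 1L
        }
        ext_s <- p + 1L
        p <- core_e
        while (p < slen &&
               schars[p + 1L] == pchars[((p - core_s) %% L) + 1L]) {
          p <- p + 1L
        }
        ext_e <- p
        span <- ext_e - ext_s
        if (span < L * min_copies) next
        idx <- ext_s:(ext_e - 1L)
        ident <- mean(schars[idx + 1L] == pchars[((idx - core_s) %% L) + 1L])
        out[[length(out) + 1L]] <- data.frame(
          scaffold_id = names(assembly)[ci], start = ext_s, end = ext_e,
          monomer = monomer, monomer_len = L, copies = span / L,
          identity = ident, strand = strand, stringsAsFactors = FALSE)
      }
    }
  }
  if (!length(out)) {
    return(data.frame(scaffold_id = character(), start = integer(),
                      end = integer(), monomer = character(),
                      monomer_len = integer(), copies = double(),
                      identity = double(), strand = character(),
                      stringsAsFactors = FALSE))
  }
  arr <- do.call(rbind, out)
  ## a (near-)palindromic monomer reports the same region on both
  ## strands; keep the plus-strand copy
  arr <- arr[order(match(arr$scaffold_id, names(assembly)), arr$start,
                   arr$strand), ]
  drop <- logical(nrow(arr))
  for (i in which(arr$strand == "-")) {
    same <- arr$strand == "+" & arr$scaffold_id == arr$scaffold_id[i] &
      arr$start < arr$end[i] & arr$end > arr$start[i]
    if (any(same)) {
      ov <- pmin(arr$end[same], arr$end[i]) - pmax(arr$start[same], arr$start[i])
      if (any(ov >= 0.5 * (arr$end[i] - arr$start[i]))) drop[i] <- TRUE
    }
  }
  arr <- arr[!drop, ]
  rownames(arr) <- NULL
  arr
}

#' Classify scaffolds by telomeric-array position
#'
#' A scaffold has telomeric repeats at `both_ends` when arrays intersect
#' windows at both scaffold ends, `one_end` when exactly one,
#' `internal_only` when arrays exist but touch neither end window, and
#' `none` otherwise. `fully_telomeric` overrides everything when the
#' arrays cover at least `full_cover_fraction` of the scaffold (such
#' scaffolds are pure telomeric repeat and cannot be anchored to a map).
#'
#' @param assembly Named `DNAStringSet`.
#' @param arrays Array `data.frame` from [find_tandem_arrays()] run with
#'   the telomere monomer.
#' @param end_window Window at each scaffold end (default 10000 bases).
#' @param full_cover_fraction Coverage for `fully_telomeric` (default
#'   0.95).
#' @return `data.frame` with `scaffold_id`, `status`, `n_arrays`,
#'   `coverage`.
#' @export
classify_telomeres <- function(assembly, arrays, end_window = 10000L,
                               full_cover_fraction = 0.95) {
  out <- data.frame(scaffold_id = names(assembly),
                    status = "none", n_arrays = 0L, coverage = 0,
                    stringsAsFactors = FALSE)
  for (i in seq_along(assembly)) {
    sc <- names(assembly)[i]
    L <- width(assembly)[i]
    a <- arrays[arrays$scaffold_id == sc, ]
    out$n_arrays[i] <- nrow(a)
    if (!nrow(a)) next
    cov <- sum(width(IRanges::reduce(IRanges(a$start + 1L, a$end)))) / L
    out$coverage[i] <- cov
    w <- min(end_window, L)
    left <- any(a$start < w)
    right <- any(a$end > L - w)
    status <- if (left && right) "both_ends"
      else if (left || right) "one_end"
      else "internal_only"
    if (cov >= full_cover_fraction) status <- "fully_telomeric"
    out$status[i] <- status
  }
  out
}

#' Infer the dominant tandem monomer of a window
#'
#' Estimates the repeat period by self-alignment: for every candidate
#' lag in `[2, max_period]` the mismatch fraction between the window and
#' its lag-shifted copy is computed, and the smallest lag within 0.01 of
#' the global minimum is taken (so harmonics of the true period do not
#' win by noise). Returns `NULL` when even the best lag mismatches more
#' than 25% of positions, i.e. the window is not periodic. The consensus
#' is the column-majority base over the window folded at the period.
#'
#' @param window DNA sequence (character or `DNAString`); must be at
#'   least 4 times `max_period` long.
#' @param max_period Largest period considered (default 200, comfortably
#'   above the ~173-bp centromeric monomer).
#' @return `list(period, consensus)` or `NULL`.
#' @export
infer_monomer <- function(window, max_period = 200L) {
  s <- strsplit(toupper(as.character(window)), "", fixed = TRUE)[[1]]
  n <- length(s)
  stopifnot(n >= 4L * max_period)
  lags <- 2:max_period
  frac <- vapply(lags, function(k) {
    mean(s[seq_len(n - k)] != s[(k + 1L):n])
  }, numeric(1))
  best <- min(frac)
  if (best > 0.25) return(NULL)
  period <- lags[which(frac <= best + 0.01)[1]]
  cols <- ((seq_len(n) - 1L) %% period) + 1L
  consensus <- vapply(seq_len(period), function(j) {
    tab <- table(s[cols == j])
    names(tab)[which.max(tab)]
  }, character(1))
  list(period = period, consensus = paste(consensus, collapse = ""))
}

#' Merge centromeric arrays into candidate stretches
#'
#' Applies the centromere cataloguing rule: keep arrays whose monomer
#' length falls in `monomer_len_range` and whose span exceeds
#' `min_stretch`, merge stretches on one scaffold lying within
#' `merge_gap` of each other, and report the longest merged stretch per
#' scaffold as the putative centromere position.
#'
#' @param arrays Array `data.frame` from [find_tandem_arrays()].
#' @param min_stretch Minimum contributing-array span (default 3000
#'   bases, i.e. stretches > 3 kb).
#' @param merge_gap Maximum gap merged across (default 50000 bases).
#' @param monomer_len_range Accepted monomer lengths (default 160-190,
#'   a band around the 173-bp monomer).
#' @return `list(stretches, longest)`: merged stretches and the longest
#'   per scaffold, both `data.frame`s with `scaffold_id`, `start`,
#'   `end`, `merged_from`, `monomer_len`.
#' @export
find_centromere_candidates <- function(arrays, min_stretch = 3000L,
                                       merge_gap = 50000L,
                                       monomer_len_range = c(160L, 190L)) {
  a <- arrays[arrays$monomer_len >= monomer_len_range[1] &
              arrays$monomer_len <= monomer_len_range[2] &
              (arrays$end - arrays$start) > min_stretch, , drop = FALSE]
  empty <- data.frame(scaffold_id = character(), start = integer(),
                      end = integer(), merged_from = integer(),
                      monomer_len = integer(), stringsAsFactors = FALSE)
  if (!nrow(a)) return(list(stretches = empty, longest = empty))
  a <- a[order(a$scaffold_id, a$start), ]
  out <- list()
  for (sc in unique(a$scaffold_id)) {
    x <- a[a$scaffold_id == sc, ]
    cur_s <- x$start[1]; cur_e <- x$end[1]; nfrom <- 1L
    flush <- function() data.frame(scaffold_id = sc, start = cur_s,
                                   end = cur_e, merged_from = nfrom,
                                   monomer_len = x$monomer_len[1],
                                   stringsAsFactors = FALSE)
    if (nrow(x) > 1L) {
      for (i in 2:nrow(x)) {
        if (x$start[i] - cur_e <= merge_gap) {
          cur_e <- max(cur_e, x$end[i]); nfrom <- nfrom + 1L
        } else {
          out[[length(out) + 1L]] <- flush()
          cur_s <- x$start[i]; cur_e <- x$end[i]; nfrom <- 1L
        }
      }
    }
    out[[length(out) + 1L]] <- flush()
  }
  stretches <- do.call(rbind, out)
  rownames(stretches) <- NULL
  longest <- do.call(rbind, lapply(split(stretches, stretches$scaffold_id),
                                   function(x) {
    x[which.max(x$end - x$start), ]
  }))
  rownames(longest) <- NULL
  list(stretches = stretches, longest = longest)
}

#' Chain rDNA component hits into NOR units and 5S clusters
#'
#' A complete rDNA (NOR) unit is a strand-consistent 18S, 5.8S, 25S
#' triple in transcription order along the scaffold (reversed order on
#' the minus strand) with inter-component gaps at most `unit_spacing`.
#' 5S hits are clustered independently: hits on one scaffold within
#' `cluster_gap` of each other form one cluster.
#'
#' @param hits Alignment `data.frame` (see [load_alignments()]) with an
#'   extra `component` column over `{18S, 5.8S, 25S, 5S}`.
#' @param unit_spacing Maximum gap inside a unit (default 5000 bases).
#' @param cluster_gap Maximum gap inside a 5S cluster (default 50000).
#' @return `list(units, units_per_scaffold, clusters_5s)`.
#' @export
detect_rdna_units <- function(hits, unit_spacing = 5000L,
                              cluster_gap = 50000L) {
  allowed <- c("18S", "5.8S", "25S", "5S")
  if (is.null(hits$component) || !all(hits$component %in% allowed)) {
    bad <- setdiff(unique(hits$component), allowed)
    stop("unknown rDNA component label(s): ",
         paste(if (length(bad)) bad else "<missing column>", collapse = ", "))
  }
  nor <- hits[hits$component %in% c("18S", "5.8S", "25S"), ]
  units <- list()
  for (sc in unique(nor$target_id)) {
    for (st in c("+", "-")) {
      h <- nor[nor$target_id == sc & nor$strand == st, ]
      if (nrow(h) < 3L) next
      h <- h[order(h$target_start), ]
      want <- if (st == "+") c("18S", "5.8S", "25S") else
        c("25S", "5.8S", "18S")
      used <- logical(nrow(h))
      for (i in seq_len(nrow(h))) {
        if (used[i] || h$component[i] != want[1]) next
        j <- which(!used & h$component == want[2] &
                   h$target_start >= h$target_end[i] &
                   h$target_start - h$target_end[i] <= unit_spacing)
        if (!length(j)) next
        j <- j[1]
        k <- which(!used & h$component == want[3] &
                   h$target_start >= h$target_end[j] &
                   h$target_start - h$target_end[j] <= unit_spacing)
        if (!length(k)) next
        k <- k[1]
        used[c(i, j, k)] <- TRUE
        units[[length(units) + 1L]] <- data.frame(
          scaffold_id = sc, start = h$target_start[i],
          end = h$target_end[k], strand = st,
          stringsAsFactors = FALSE)
      }
    }
  }
  units <- if (length(units)) do.call(rbind, units) else
    data.frame(scaffold_id = character(), start = integer(),
               end = integer(), strand = character(),
               stringsAsFactors = FALSE)
  per_scaf <- if (nrow(units)) {
    as.data.frame(table(scaffold_id = units$scaffold_id),
                  responseName = "n_units", stringsAsFactors = FALSE)
  } else data.frame(scaffold_id = character(), n_units = integer(),
                    stringsAsFactors = FALSE)
  s5 <- hits[hits$component == "5S", ]
  clusters <- list()
  for (sc in unique(s5$target_id)) {
    x <- s5[s5$target_id == sc, ]
    x <- x[order(x$target_start), ]
    grp <- cumsum(c(1L, as.integer(
      x$target_start[-1L] - x$target_end[-nrow(x)] > cluster_gap)))
    for (g in split(seq_len(nrow(x)), grp)) {
      clusters[[length(clusters) + 1L]] <- data.frame(
        scaffold_id = sc, start = min(x$target_start[g]),
        end = max(x$target_end[g]), n_copies = length(g),
        stringsAsFactors = FALSE)
    }
  }
  clusters <- if (length(clusters)) do.call(rbind, clusters) else
    data.frame(scaffold_id = character(), start = integer(),
               end = integer(), n_copies = integer(),
               stringsAsFactors = FALSE)
  list(units = units, units_per_scaffold = per_scaf,
       clusters_5s = clusters)
}
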