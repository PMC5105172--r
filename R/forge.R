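## Synthetic-genome forge: seeded generator of genomes with planted
## Tpn1-type elements, telomeric/centromeric/rDNA arrays, chimeric
## scaffolds, F2 genotype matrices and BAC-end placements, each with a
## machine-readable truth table.
##
## Determinism: every feature class draws from its own RNG stream
## derived from the master seed, so enabling one class never perturbs
## another. All stream seeds stay below 2^31.

stream_seed <- function(seed, offset) {
  as.integer((as.numeric(seed) * 1009 + offset * 9176) %% 2147483647)
}

random_dna <- function(n, probs = c(A = 0.25, C = 0.25, G = 0.25, T = 0.25)) {
  paste(sample(c("A", "C", "G", "T"), n, replace = TRUE, prob = probs),
        collapse = "")
}

## per-base substitution of a DNA string (used for divergent repeat units)
mutate_dna <- function(seq, rate) {
  if (rate <= 0) return(seq)
  s <- strsplit(seq, "", fixed = TRUE)[[1]]
  hit <- which(runif(length(s)) < rate)
  for (i in hit) {
    s[i] <- sample(setdiff(c("A", "C", "G", "T"), s[i]), 1L)
  }
  paste(s, collapse = "")
}

#' Draw target-site duplications with the AT-rich base weights
#'
#' TSD bases are drawn independently with P(A) = P(T) = 0.316 and
#' P(C) = P(G) = 0.184, so that a 3-bp TSD contains at least one A or T
#' with probability 1 - 0.368^3, about 0.95 — the AT-rich regime
#' observed for Tpn1 insertions.
#'
#' @param n Number of TSDs.
#' @param len TSD length (default 3).
#' @param weights Base probabilities in A, C, G, T order.
#' @return Character vector of TSD sequences.
#' @export
sample_tsd <- function(n, len = 3L,
                       weights = c(A = 0.316, C = 0.184,
                                   G = 0.184, T = 0.316)) {
  vapply(seq_len(n), function(i) {
    paste(sample(c("A", "C", "G", "T"), len, replace = TRUE,
                 prob = weights), collapse = "")
  }, character(1))
}

#' Forge configuration
#'
#' Defaults describe the study conditions the pipeline is designed for:
#' 28-bp TIRs, 122/104-bp SRR units, element lengths log-uniform over
#' 161-40619 bp (whose mean, ~7.3 kb, sits near the observed 7,081 bp
#' average), AT-rich 3-bp TSDs at the 95% A/T-containing regime,
#' AAACCCT telomeres, a ~173-bp centromeric monomer at 2% divergence,
#' 18S-5.8S-25S rDNA units, and ~100 kb BAC inserts.
#'
#' @param seed Master seed (integer).
#' @param n_chromosomes,chromosome_len Background genome dimensions.
#' @param base_composition Background base probabilities (A, C, G, T).
#' @param tpn,telomere,centromere,rdna,chimera,f2,bac Per-feature-class
#'   option lists; see the entries set below for the available fields.
#' @return Nested configuration list.
#' @export
forge_config <- function(seed = 1L, n_chromosomes = 3L,
                         chromosome_len = 200000L,
                         base_composition = c(A = 0.32, C = 0.18,
                                              G = 0.18, T = 0.32),
                         tpn = list(), telomere = list(),
                         centromere = list(), rdna = list(),
                         chimera = list(), f2 = list(), bac = list()) {
  merge_opts <- function(defaults, user) {
    defaults[names(user)] <- user
    defaults
  }
  cfg <- list(
    seed = as.integer(seed),
    n_chromosomes = n_chromosomes,
    chromosome_len = chromosome_len,
    base_composition = base_composition,
    tpn = merge_opts(list(
      n_intact = 0L, n_rearranged = 0L,
      len_range = c(161L, 40619L), tsd_len = 3L, n_tsd5 = 0L,
      tir_len = 28L, srr5_len = 122L, srr3_len = 104L,
      srr_copies_range = c(2L, 3L), min_separation = 50020L), tpn),
    telomere = merge_opts(list(
      n_arrays = 0L, monomer = "AAACCCT", copies_range = c(50L, 300L),
      at_ends = TRUE), telomere),
    centromere = merge_opts(list(
      n_arrays = 0L, monomer_len = 173L, copies_range = c(25L, 60L),
      divergence = 0.02), centromere),
    rdna = merge_opts(list(
      n_units = 0L, n_5s = 0L,
      component_lens = c(`18S` = 1800L, `5.8S` = 160L, `25S` = 3400L,
                         `5S` = 120L),
      spacer = 200L), rdna),
    chimera = merge_opts(list(
      n_events = 0L, n_contig_events = 0L, gap_len = 100L,
      markers_per_side = 3L), chimera),
    f2 = merge_opts(list(
      n_progeny = 200L, marker_spacing_cM = 10, n_markers = 10L,
      missing_rate = 0.05), f2),
    bac = merge_opts(list(
      n_pairs = 500L, insert_mean = 100000L, insert_sd = 10000L,
      read_len = 500L, cross_fraction = 0), bac))
  stopifnot(abs(sum(cfg$base_composition) - 1) < 1e-8,
            cfg$tpn$len_range[1] >= 60L, cfg$tpn$len_range[2] <= 50000L)
  cfg
}

## Reserve a random non-overlapping placement of `len` bases (with
## `margin` clearance) on a chromosome; returns the 0-based start or
## errors after too many attempts.
place_feature <- function(occupied, len, chrom_len, margin = 20L) {
  for (try in 1:2000) {
    s <- floor(runif(1, margin, chrom_len - len - margin))
    if (!nrow(occupied) ||
        !any(s < occupied$end + margin & s + len > occupied$start - margin)) {
      return(s)
    }
  }
  stop("cannot place feature without overlap; reduce feature counts ",
       "or enlarge chromosomes")
}

## Free segments of a chromosome: the complement of the occupied
## intervals (inflated by `pad`) within the edge-trimmed chromosome.
## Returns 0-based half-open segments plus a flag marking which side(s)
## abut the chromosome edge.
free_segments <- function(occupied, chrom_len, edge = 20L, pad = 20L) {
  all <- IRanges(edge + 1L, chrom_len - edge)
  if (nrow(occupied)) {
    occ <- IRanges::reduce(IRanges(pmax(1L, occupied$start - pad + 1L),
                                   pmin(chrom_len, occupied$end + pad)))
    gaps <- BiocGenerics::setdiff(all, occ)
  } else {
    gaps <- all
  }
  if (!length(gaps)) {
    return(data.frame(start = integer(), end = integer(),
                      left_edge = logical(), right_edge = logical()))
  }
  data.frame(start = BiocGenerics::start(gaps) - 1L,
             end = BiocGenerics::end(gaps),
             left_edge = BiocGenerics::start(gaps) == edge + 1L,
             right_edge = BiocGenerics::end(gaps) == chrom_len - edge)
}

## Place features of the given lengths into free segments such that any
## two features end up at least `min_sep` apart (also across segment
## boundaries, via half-separation padding at internal boundaries).
## First-fit decreasing for feasibility, randomised gap slack for
## variety; deterministic success whenever capacity suffices. Returns
## 0-based starts in input order.
layout_features <- function(segments, lens, min_sep, edge_pad = 20L) {
  if (!length(lens)) return(integer())
  ord <- order(lens, decreasing = TRUE)
  assign <- vector("list", nrow(segments))
  pads <- function(j) {
    c(if (segments$left_edge[j]) edge_pad else ceiling(min_sep / 2),
      if (segments$right_edge[j]) edge_pad else ceiling(min_sep / 2))
  }
  for (i in ord) {
    placed <- FALSE
    for (j in seq_len(nrow(segments))) {
      cur <- assign[[j]]
      need <- sum(lens[cur]) + lens[i] + length(cur) * min_sep +
        sum(pads(j))
      if (need <= segments$end[j] - segments$start[j]) {
        assign[[j]] <- c(cur, i)
        placed <- TRUE
        break
      }
    }
    if (!placed) {
      stop("cannot place features without overlap at the required ",
           "separation; reduce feature counts or enlarge chromosomes")
    }
  }
  starts <- integer(length(lens))
  for (j in seq_len(nrow(segments))) {
    idx <- assign[[j]]
    if (!length(idx)) next
    idx <- idx[sample.int(length(idx))]
    m <- length(idx)
    pd <- pads(j)
    slack <- (segments$end[j] - segments$start[j]) - sum(lens[idx]) -
      (m - 1L) * min_sep - sum(pd)
    w <- runif(m + 1L)
    extra <- floor(slack * w / sum(w))
    pos <- segments$start[j] + pd[1] + extra[1]
    for (k in seq_len(m)) {
      starts[idx[k]] <- pos
      pos <- pos + lens[idx[k]] + min_sep + extra[k + 1L]
    }
  }
  starts
}

truth_row <- function(feature_type, scaffold_id, start, end, strand = "+",
                      payload = NA_character_, class = NA_character_) {
  data.frame(feature_type = feature_type, scaffold_id = scaffold_id,
             start = as.integer(start), end = as.integer(end),
             strand = strand, payload = payload, class = class,
             stringsAsFactors = FALSE)
}

#' Forge a genome with planted features and an exact truth table
#'
#' Generates `n_chromosomes` random-background scaffolds and plants the
#' configured feature classes: Tpn1-type elements (intact and
#' SRR-rearranged), telomeric arrays at scaffold ends, divergent
#' centromeric arrays, and rDNA (NOR) units plus a 5S cluster. Output
#' is byte-deterministic for a fixed config and seed.
#'
#' @param config Configuration from [forge_config()].
#' @return List with `assembly` (`DNAStringSet`), `truth`
#'   (`data.frame`, 0-based half-open, one row per planted feature),
#'   `tir_seeds`/`srr_seeds` (seed `data.frame`s), `rdna_hits`
#'   (component-labelled alignment table for [detect_rdna_units()]),
#'   and `config`.
#' @export
forge_genome <- function(config = forge_config()) {
  cfg <- config
  n_chr <- cfg$n_chromosomes
  chrom_names <- sprintf("chr%02d", seq_len(n_chr))

  set.seed(stream_seed(cfg$seed, 1L))
  seqs <- vapply(seq_len(n_chr), function(i) {
    random_dna(cfg$chromosome_len, cfg$base_composition)
  }, character(1))
  names(seqs) <- chrom_names
  occupied <- lapply(chrom_names, function(x)
    data.frame(start = integer(), end = integer()))
  names(occupied) <- chrom_names
  truth <- list()
  plant <- function(chrom, start, payload_seq) {
    substr(seqs[[chrom]], start + 1L,
           start + nchar(payload_seq)) <<- payload_seq
    occupied[[chrom]] <<- rbind(occupied[[chrom]],
                                data.frame(start = start,
                                           end = start + nchar(payload_seq)))
  }

  ## seeds for the element family (fixed per genome)
  set.seed(stream_seed(cfg$seed, 2L))
  tir5 <- random_dna(cfg$tpn$tir_len)
  tir3 <- random_dna(cfg$tpn$tir_len)
  srr5 <- random_dna(cfg$tpn$srr5_len)
  srr3 <- random_dna(cfg$tpn$srr3_len)
  tir_seeds <- rbind(seed_frame("five_prime", tir5),
                     seed_frame("three_prime", tir3))
  srr_seeds <- rbind(seed_frame("five_prime", srr5),
                     seed_frame("three_prime", srr3))

  ## telomeres: arrays at both ends of the first n_arrays chromosomes
  set.seed(stream_seed(cfg$seed, 3L))
  tel <- cfg$telomere
  if (tel$n_arrays > 0L) {
    mono <- toupper(tel$monomer)
    for (i in seq_len(min(tel$n_arrays, n_chr))) {
      ch <- chrom_names[i]
      for (side in c("left", "right")) {
        cp <- sample(tel$copies_range[1]:tel$copies_range[2], 1L)
        arr <- strrep(mono, cp)
        st <- if (side == "left") 0L else
          cfg$chromosome_len - nchar(arr)
        plant(ch, st, arr)
        truth[[length(truth) + 1L]] <- truth_row(
          "telomere", ch, st, st + nchar(arr), payload = mono)
      }
    }
  }

  ## centromeres: one divergent array per chromosome
  set.seed(stream_seed(cfg$seed, 4L))
  cen <- cfg$centromere
  cen_monomers <- character(0)
  if (cen$n_arrays > 0L) {
    for (i in seq_len(min(cen$n_arrays, n_chr))) {
      ch <- chrom_names[i]
      mono <- random_dna(cen$monomer_len)
      cen_monomers[ch] <- mono
      cp <- sample(cen$copies_range[1]:cen$copies_range[2], 1L)
      arr <- paste(vapply(seq_len(cp), function(k)
        mutate_dna(mono, cen$divergence), character(1)), collapse = "")
      st <- place_feature(occupied[[ch]], nchar(arr), cfg$chromosome_len)
      plant(ch, st, arr)
      truth[[length(truth) + 1L]] <- truth_row(
        "centromere", ch, st, st + nchar(arr), payload = mono)
    }
  }

  ## rDNA: NOR units in tandem on chr 1, a 5S cluster on the last chr
  set.seed(stream_seed(cfg$seed, 5L))
  rd <- cfg$rdna
  rdna_hits <- list()
  if (rd$n_units > 0L || rd$n_5s > 0L) {
    comp <- lapply(rd$component_lens, random_dna)
    if (rd$n_units > 0L) {
      ch <- chrom_names[1]
      unit <- paste0(comp[["18S"]], strrep("A", rd$spacer),
                     comp[["5.8S"]], strrep("A", rd$spacer),
                     comp[["25S"]], strrep("A", rd$spacer))
      block <- strrep(unit, rd$n_units)
      st <- place_feature(occupied[[ch]], nchar(block),
                          cfg$chromosome_len)
      plant(ch, st, block)
      off <- st
      for (u in seq_len(rd$n_units)) {
        pos <- off
        for (cname in c("18S", "5.8S", "25S")) {
          clen <- rd$component_lens[[cname]]
          rdna_hits[[length(rdna_hits) + 1L]] <- data.frame(
            query_id = cname, query_len = clen, query_start = 0L,
            query_end = clen, strand = "+", target_id = ch,
            target_len = cfg$chromosome_len, target_start = pos,
            target_end = pos + clen, matches = clen, align_len = clen,
            score = clen, component = cname, stringsAsFactors = FALSE)
          pos <- pos + clen + rd$spacer
        }
        truth[[length(truth) + 1L]] <- truth_row(
          "nor_unit", ch, off, off + nchar(unit))
        off <- off + nchar(unit)
      }
    }
    if (rd$n_5s > 0L) {
      ch <- chrom_names[n_chr]
      clen <- rd$component_lens[["5S"]]
      block <- strrep(paste0(comp[["5S"]], strrep("A", rd$spacer)),
                      rd$n_5s)
      st <- place_feature(occupied[[ch]], nchar(block),
                          cfg$chromosome_len)
      plant(ch, st, block)
      for (u in seq_len(rd$n_5s)) {
        pos <- st + (u - 1L) * (clen + rd$spacer)
        rdna_hits[[length(rdna_hits) + 1L]] <- data.frame(
          query_id = "5S", query_len = clen, query_start = 0L,
          query_end = clen, strand = "+", target_id = ch,
          target_len = cfg$chromosome_len, target_start = pos,
          target_end = pos + clen, matches = clen, align_len = clen,
          score = clen, component = "5S", stringsAsFactors = FALSE)
      }
      truth[[length(truth) + 1L]] <- truth_row(
        "cluster_5s", ch, st, st + nchar(block),
        payload = as.character(rd$n_5s))
    }
  }

  ## Tpn1-type elements. Elements are spread round-robin over the
  ## chromosomes and laid out at least `min_separation` apart, so no
  ## spurious cross-element TIR pairing can fall inside the miner's
  ## span bounds and truth recovery is unambiguous.
  set.seed(stream_seed(cfg$seed, 6L))
  tp <- cfg$tpn
  n_el <- tp$n_intact + tp$n_rearranged
  if (n_el > 0L) {
    classes <- c(rep("putatively_active", tp$n_intact),
                 rep("rearranged_inactive", tp$n_rearranged))
    classes <- sample(classes)
    tsd_lens <- rep(tp$tsd_len, n_el)
    if (tp$n_tsd5 > 0L) tsd_lens[seq_len(min(tp$n_tsd5, n_el))] <- 5L
    payloads <- character(n_el)
    strands <- character(n_el)
    tsds <- character(n_el)
    for (i in seq_len(n_el)) {
      intact <- classes[i] == "putatively_active"
      k5 <- sample(tp$srr_copies_range[1]:tp$srr_copies_range[2], 1L)
      k3 <- sample(tp$srr_copies_range[1]:tp$srr_copies_range[2], 1L)
      fixed <- 2L * tp$tir_len + k5 * tp$srr5_len + k3 * tp$srr3_len
      drawn <- round(exp(runif(1, log(tp$len_range[1]),
                               log(tp$len_range[2]))))
      body_len <- max(drawn, fixed + 10L)
      interior <- random_dna(body_len - fixed, cfg$base_composition)
      srr3_block <- strrep(srr3, k3)
      if (!intact) srr3_block <- revcomp_chr(srr3_block)
      body <- paste0(tir5, strrep(srr5, k5), interior, srr3_block,
                     revcomp_chr(tir3))
      strands[i] <- sample(c("+", "-"), 1L)
      if (strands[i] == "-") body <- revcomp_chr(body)
      tsds[i] <- sample_tsd(1L, tsd_lens[i])
      payloads[i] <- paste0(tsds[i], body, tsds[i])
    }
    chrom_of <- chrom_names[((seq_len(n_el) - 1L) %% n_chr) + 1L]
    for (ch in unique(chrom_of)) {
      idx <- which(chrom_of == ch)
      segs <- free_segments(occupied[[ch]], cfg$chromosome_len)
      starts <- layout_features(segs, nchar(payloads[idx]),
                                tp$min_separation)
      for (k in seq_along(idx)) {
        i <- idx[k]
        plant(ch, starts[k], payloads[i])
        el_start <- starts[k] + nchar(tsds[i])
        el_end <- starts[k] + nchar(payloads[i]) - nchar(tsds[i])
        truth[[length(truth) + 1L]] <- truth_row(
          "tpn_element", ch, el_start, el_end, strand = strands[i],
          payload = tsds[i], class = classes[i])
      }
    }
  }

  truth <- if (length(truth)) do.call(rbind, truth) else
    truth_row(character(), character(), integer(), integer(),
              character(), character(), character())[0, ]
  rownames(truth) <- NULL
  list(assembly = DNAStringSet(seqs), truth = truth,
       tir_seeds = tir_seeds, srr_seeds = srr_seeds,
       rdna_hits = if (length(rdna_hits)) do.call(rbind, rdna_hits) else
         NULL,
       cen_monomers = cen_monomers,
       config = cfg)
}

#' Forge chimeric scaffolds with marker truth
#'
#' Builds chimeric scaffolds by joining the prefix of one chromosome to
#' the suffix of another — across an N gap (`scaffold` mode) or
#' directly (`contig` mode) — and emits linkage markers on every
#' resulting scaffold: prefix markers carry the first chromosome's
#' linkage group, suffix markers the second's. Chromosomes not consumed
#' by a chimera pass through as clean single-group scaffolds.
#'
#' @param chromosomes Named `DNAStringSet`; each chromosome is its own
#'   linkage group (`lg_<i>`).
#' @param n_events Gap-junction chimeras to build.
#' @param n_contig_events Gap-free (contig-level) chimeras to build.
#' @param gap_len N-gap length for scaffold-mode chimeras.
#' @param markers_per_side Markers planted per linkage block.
#' @param seed RNG seed.
#' @return List with `assembly`, `markers` (`marker_id`, `scaffold_id`,
#'   `position`, `lg`) and `truth` (`scaffold_id`, `type`,
#'   `junction_start`, `junction_end`, `left_lg`, `right_lg`).
#' @export
make_chimeras <- function(chromosomes, n_events = 0L,
                          n_contig_events = 0L, gap_len = 100L,
                          markers_per_side = 3L, seed = 1L) {
  n_src <- 2L * (n_events + n_contig_events)
  if (n_src > length(chromosomes)) {
    stop("need at least ", n_src, " chromosomes for ",
         n_events + n_contig_events, " chimeras")
  }
  set.seed(stream_seed(seed, 7L))
  lg <- setNames(paste0("lg_", seq_along(chromosomes)),
                 names(chromosomes))
  src <- sample(names(chromosomes), n_src)
  seqs <- character(0)
  markers <- list()
  truth <- list()
  add_markers <- function(scaf, lo, hi, group) {
    group <- unname(group)
    pos <- sort(sample(lo:(hi - 1L), markers_per_side))
    markers[[length(markers) + 1L]] <<- data.frame(
      marker_id = sprintf("%s_%s_m%d", scaf, group,
                          seq_len(markers_per_side)),
      scaffold_id = scaf, position = pos, lg = group,
      stringsAsFactors = FALSE)
  }
  types <- c(rep("scaffold", n_events), rep("contig", n_contig_events))
  for (k in seq_along(types)) {
    a <- src[2L * k - 1L]; b <- src[2L * k]
    la <- width(chromosomes)[names(chromosomes) == a]
    lb <- width(chromosomes)[names(chromosomes) == b]
    cut_a <- floor(la / 2); cut_b <- floor(lb / 2)
    prefix <- as.character(subseq(chromosomes[[a]], 1L, cut_a))
    suffix <- as.character(subseq(chromosomes[[b]], cut_b + 1L, lb))
    id <- sprintf("chimera_%02d", k)
    if (types[k] == "scaffold") {
      seqs[id] <- paste0(prefix, strrep("N", gap_len), suffix)
      js <- cut_a; je <- cut_a + gap_len
    } else {
      seqs[id] <- paste0(prefix, suffix)
      js <- je <- cut_a
    }
    suffix_off <- if (types[k] == "scaffold") cut_a + gap_len else cut_a
    add_markers(id, 1L, cut_a, lg[a])
    add_markers(id, suffix_off + 1L, suffix_off + nchar(suffix), lg[b])
    truth[[length(truth) + 1L]] <- data.frame(
      scaffold_id = id, type = types[k], junction_start = js,
      junction_end = je, left_lg = unname(lg[a]),
      right_lg = unname(lg[b]), stringsAsFactors = FALSE)
  }
  clean <- setdiff(names(chromosomes), src)
  for (ch in clean) {
    L <- width(chromosomes)[names(chromosomes) == ch]
    seqs[ch] <- as.character(chromosomes[[ch]])
    add_markers(ch, 1L, floor(L / 2), lg[ch])
    add_markers(ch, floor(L / 2) + 1L, L, lg[ch])
  }
  list(assembly = DNAStringSet(seqs),
       markers = do.call(rbind, markers),
       truth = if (length(truth)) do.call(rbind, truth) else NULL)
}

#' Simulate an F2 genotype matrix under the Haldane map function
#'
#' Each progeny receives two independent gametes. Within a linkage
#' group, the allele at the first marker is Bernoulli(1/2) and a
#' crossover occurs in each adjacent-marker interval independently with
#' probability `r = (1 - exp(-2d)) / 2` for map distance `d` in Morgans
#' (Haldane: no interference). Genotypes are `AA`/`AB`/`BB`; entries
#' are set missing at `missing_rate`.
#'
#' @param linkage_map `data.frame` with `lg`, `marker_id`, `cM`
#'   (non-decreasing within a group).
#' @param n_progeny Progeny count (default 200).
#' @param missing_rate Missing-genotype rate (default 0.05).
#' @param seed RNG seed.
#' @return List with `genotypes` (marker x sample character matrix),
#'   `gametes` (list of the two 0/1 allele matrices, pre-missingness)
#'   and `map`.
#' @export
simulate_f2 <- function(linkage_map, n_progeny = 200L,
                        missing_rate = 0.05, seed = 1L) {
  set.seed(stream_seed(seed, 8L))
  map <- linkage_map[order(linkage_map$lg, linkage_map$cM), ]
  n_mk <- nrow(map)
  g1 <- g2 <- matrix(0L, n_mk, n_progeny,
                     dimnames = list(map$marker_id,
                                     sprintf("F2_%03d", seq_len(n_progeny))))
  for (lg in unique(map$lg)) {
    idx <- which(map$lg == lg)
    d <- diff(map$cM[idx]) / 100
    r <- (1 - exp(-2 * d)) / 2
    for (gam in 1:2) {
      m <- if (gam == 1) g1 else g2
      first <- rbinom(n_progeny, 1L, 0.5)
      m[idx[1], ] <- first
      if (length(idx) > 1L) {
        for (j in seq_along(r)) {
          sw <- rbinom(n_progeny, 1L, r[j])
          m[idx[j + 1L], ] <- (m[idx[j], ] + sw) %% 2L
        }
      }
      if (gam == 1) g1 <- m else g2 <- m
    }
  }
  codes <- c("AA", "AB", "BB")
  geno <- matrix(codes[g1 + g2 + 1L], n_mk, ncol(g1),
                 dimnames = dimnames(g1))
  if (missing_rate > 0) {
    miss <- matrix(runif(length(geno)) < missing_rate, n_mk, ncol(geno))
    geno[miss] <- NA_character_
  }
  list(genotypes = geno, gametes = list(g1, g2), map = map)
}

#' Simulate concordant BAC-end read placements
#'
#' Pairs are dropped uniformly on the assembly with insert lengths
#' drawn from a positive-truncated Normal(`insert_mean`, `insert_sd`);
#' reads face inward. A configurable fraction of pairs has its second
#' read displaced to a different scaffold (discordant truth). Output is
#' an alignment table directly consumable by [pair_bac_ends()].
#'
#' @param assembly Named `DNAStringSet`; `insert_mean` must be below
#'   the shortest scaffold.
#' @param n_pairs Number of pairs (default 500).
#' @param insert_mean,insert_sd Insert distribution (defaults 100000
#'   and 10000 bases).
#' @param read_len Read length (default 500).
#' @param cross_fraction Fraction of pairs made cross-scaffold.
#' @param seed RNG seed.
#' @return List with `hits` (alignment `data.frame`) and `truth`
#'   (`pair_id`, `scaffold_id`, `insert_len`, `cross`).
#' @export
simulate_bac_ends <- function(assembly, n_pairs = 500L,
                              insert_mean = 100000L, insert_sd = 10000L,
                              read_len = 500L, cross_fraction = 0,
                              seed = 1L) {
  stopifnot(insert_mean < min(width(assembly)))
  set.seed(stream_seed(seed, 9L))
  hits <- list()
  truth <- list()
  n_cross <- round(cross_fraction * n_pairs)
  is_cross <- c(rep(TRUE, n_cross), rep(FALSE, n_pairs - n_cross))
  mk_hit <- function(qid, target, tstart, tend, strand) {
    data.frame(query_id = qid, query_len = read_len, query_start = 0L,
               query_end = read_len, strand = strand, target_id = target,
               target_len = width(assembly)[names(assembly) == target],
               target_start = as.integer(tstart),
               target_end = as.integer(tend), matches = read_len,
               align_len = read_len, score = as.numeric(read_len),
               stringsAsFactors = FALSE)
  }
  for (i in seq_len(n_pairs)) {
    repeat {
      sc <- sample(names(assembly), 1L)
      L <- width(assembly)[names(assembly) == sc]
      ins <- round(rnorm(1, insert_mean, insert_sd))
      if (ins > 2L * read_len && ins < L) break
    }
    st <- floor(runif(1, 0, L - ins))
    pid <- sprintf("bac_%05d", i)
    hits[[length(hits) + 1L]] <- mk_hit(paste0(pid, "/1"), sc, st,
                                        st + read_len, "+")
    if (is_cross[i] && length(assembly) > 1L) {
      other <- sample(setdiff(names(assembly), sc), 1L)
      Lo <- width(assembly)[names(assembly) == other]
      st2 <- floor(runif(1, 0, Lo - read_len))
      hits[[length(hits) + 1L]] <- mk_hit(paste0(pid, "/2"), other, st2,
                                          st2 + read_len, "-")
    } else {
      hits[[length(hits) + 1L]] <- mk_hit(paste0(pid, "/2"), sc,
                                          st + ins - read_len, st + ins,
                                          "-")
    }
    truth[[length(truth) + 1L]] <- data.frame(
      pair_id = pid, scaffold_id = sc, insert_len = ins,
      cross = is_cross[i] && length(assembly) > 1L,
      stringsAsFactors = FALSE)
  }
  list(hits = do.call(rbind, hits), truth = do.call(rbind, truth))
}

#' Forge simple gene models
#'
#' Non-overlapping genes with a 5' UTR and 2-4 exons, emitted in the
#' layout of [load_gene_models()] (introns included), for exercising
#' gene-context annotation.
#'
#' @param assembly Named `DNAStringSet`.
#' @param n_genes Genes to place.
#' @param seed RNG seed.
#' @return Gene-model `data.frame`.
#' @export
forge_gene_models <- function(assembly, n_genes = 20L, seed = 1L) {
  set.seed(stream_seed(seed, 10L))
  occ <- lapply(names(assembly), function(x)
    data.frame(start = integer(), end = integer()))
  names(occ) <- names(assembly)
  rows <- list()
  for (i in seq_len(n_genes)) {
    ch <- sample(names(assembly), 1L)
    L <- width(assembly)[names(assembly) == ch]
    n_ex <- sample(2:4, 1L)
    ex_len <- sample(150:400, n_ex, replace = TRUE)
    in_len <- sample(200:800, n_ex - 1L, replace = TRUE)
    span <- sum(ex_len) + sum(in_len)
    st <- place_feature(occ[[ch]], span, L)
    occ[[ch]] <- rbind(occ[[ch]], data.frame(start = st, end = st + span))
    gid <- sprintf("gene_%03d", i)
    mid <- sprintf("mrna_%03d", i)
    strand <- sample(c("+", "-"), 1L)
    rows[[length(rows) + 1L]] <- data.frame(
      scaffold_id = ch, start = st, end = st + span, strand = strand,
      feature_type = c("gene", "mRNA"), id = c(gid, mid),
      parent = c(NA, gid), stringsAsFactors = FALSE)
    pos <- st
    for (e in seq_len(n_ex)) {
      rows[[length(rows) + 1L]] <- data.frame(
        scaffold_id = ch, start = pos, end = pos + ex_len[e],
        strand = strand, feature_type = "exon", id = NA_character_,
        parent = mid, stringsAsFactors = FALSE)
      if (e == 1L) {
        rows[[length(rows) + 1L]] <- data.frame(
          scaffold_id = ch, start = pos, end = pos + 100L,
          strand = strand, feature_type = "five_prime_UTR",
          id = NA_character_, parent = mid, stringsAsFactors = FALSE)
      }
      if (e < n_ex) {
        rows[[length(rows) + 1L]] <- data.frame(
          scaffold_id = ch, start = pos + ex_len[e],
          end = pos + ex_len[e] + in_len[e], strand = strand,
          feature_type = "intron", id = NA_character_, parent = mid,
          stringsAsFactors = FALSE)
        pos <- pos + ex_len[e] + in_len[e]
      }
    }
  }
  out <- do.call(rbind, rows)
  rownames(out) <- NULL
  out
}

#' Write forge output to a directory
#'
#' Emits `genome.fasta`, `truth.bed`, `truth.json`, `tir_seeds.fasta`,
#' `srr_seeds.fasta` and, when present, `rdna_hits.paf`.
#'
#' @param forge Output of [forge_genome()].
#' @param dir Output directory.
#' @return `dir`, invisibly.
#' @export
write_forge_output <- function(forge, dir) {
  dir.create(dir, recursive = TRUE, showWarnings = FALSE)
  write_genome(forge$assembly, file.path(dir, "genome.fasta"))
  tr <- forge$truth
  write_bed(data.frame(scaffold_id = tr$scaffold_id, start = tr$start,
                       end = tr$end, name = tr$feature_type, score = 0,
                       strand = tr$strand, stringsAsFactors = FALSE),
            file.path(dir, "truth.bed"))
  jsonlite::write_json(tr, file.path(dir, "truth.json"), digits = NA)
  seeds_fa <- function(df, path) {
    ss <- DNAStringSet(df$seq)
    names(ss) <- paste0(df$end_type, "_seed")
    writeXStringSet(ss, path)
  }
  seeds_fa(forge$tir_seeds, file.path(dir, "tir_seeds.fasta"))
  seeds_fa(forge$srr_seeds, file.path(dir, "srr_seeds.fasta"))
  if (!is.null(forge$rdna_hits)) {
    write_paf(forge$rdna_hits, file.path(dir, "rdna_hits.paf"))
  }
  invisible(dir)
}
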