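## Core I/O: genome FASTA, gap runs, tabular alignments (PAF / BLAST-6),
## gene models (GFF3) with derived introns.
##
## Coordinate convention: everything in memory is 0-based half-open.
## GFF3 and AGP are 1-based inclusive; conversion happens only in the
## readers/writers in this file and in write_agp()/read_agp().

VALID_DNA_CHARS <- c("A", "C", "G", "T", "N", "a", "c", "g", "t", "n")

#' Load a genome assembly from FASTA
#'
#' Reads scaffolds into a [Biostrings::DNAStringSet] and validates the
#' assembly contract: unique ids (the first whitespace-delimited token of
#' each header), non-empty records, and an alphabet restricted to
#' `A,C,G,T,N` (either case; lowercase soft-masking is preserved but
#' treated as ordinary sequence by every downstream matcher).
#'
#' @param path Path to a FASTA file.
#' @return A named `DNAStringSet`, one element per scaffold, file order
#'   preserved.
#' @export
load_genome <- function(path) {
  stopifnot(file.exists(path))
  raw <- Biostrings::readBStringSet(path)
  ids <- sub("\\s.*$", "", names(raw))
  if (anyDuplicated(ids)) {
    stop("duplicate scaffold id(s): ",
         paste(unique(ids[duplicated(ids)]), collapse = ", "))
  }
  if (any(width(raw) == 0L)) {
    stop("empty record(s): ", paste(ids[width(raw) == 0L], collapse = ", "))
  }
  for (i in seq_along(raw)) {
    s <- strsplit(as.character(raw[[i]]), "", fixed = TRUE)[[1]]
    bad <- which(!(s %in% VALID_DNA_CHARS))
    if (length(bad)) {
      stop(sprintf("illegal character '%s' in scaffold '%s' at position %d",
                   s[bad[1]], ids[i], bad[1]))
    }
  }
  out <- DNAStringSet(raw)
  names(out) <- ids
  out
}

#' Write a genome assembly to FASTA
#'
#' @param assembly A named `DNAStringSet`.
#' @param path Output path.
#' @param width Line width for wrapping.
#' @return `path`, invisibly.
#' @export
write_genome <- function(assembly, path, width = 70L) {
  stopifnot(is(assembly, "DNAStringSet"), !is.null(names(assembly)))
  writeXStringSet(assembly, filepath = path, width = width)
  invisible(path)
}

#' Build an assembly from named character strings
#'
#' Convenience constructor used throughout the tests and the forge.
#'
#' @param seqs Named character vector of DNA sequences.
#' @return A named `DNAStringSet`.
#' @export
assembly_from_strings <- function(seqs) {
  stopifnot(is.character(seqs), !is.null(names(seqs)),
            !anyDuplicated(names(seqs)))
  DNAStringSet(seqs)
}

#' Find maximal N runs (assembly gaps)
#'
#' Scaffold junctions in a scaffolded assembly are runs of N. Returns
#' every maximal run of `N`/`n` of length at least `min_gap_len`,
#' sorted by scaffold (input order) then start.
#'
#' @param assembly A named `DNAStringSet`.
#' @param min_gap_len Minimum run length to report (default 10; runs of
#'   one or a few N inside contigs are not split candidates).
#' @return `data.frame` with columns `scaffold_id`, `start`, `end`
#'   (0-based half-open), `length`.
#' @export
find_gap_runs <- function(assembly, min_gap_len = 10L) {
  stopifnot(min_gap_len >= 1L)
  out <- lapply(seq_along(assembly), function(i) {
    m <- gregexpr("[Nn]+", as.character(assembly[[i]]))[[1]]
    if (m[1] == -1L) return(NULL)
    len <- attr(m, "match.length")
    keep <- len >= min_gap_len
    if (!any(keep)) return(NULL)
    data.frame(scaffold_id = names(assembly)[i],
               start = as.integer(m[keep]) - 1L,
               end = as.integer(m[keep]) - 1L + len[keep],
               length = len[keep],
               stringsAsFactors = FALSE)
  })
  out <- do.call(rbind, out)
  if (is.null(out)) {
    out <- data.frame(scaffold_id = character(), start = integer(),
                      end = integer(), length = integer(),
                      stringsAsFactors = FALSE)
  }
  rownames(out) <- NULL
  out
}

.alignment_cols <- c("query_id", "query_len", "query_start", "query_end",
                     "strand", "target_id", "target_len", "target_start",
                     "target_end", "matches", "align_len", "score")

empty_alignments <- function() {
  out <- data.frame(query_id = character(), query_len = integer(),
                    query_start = integer(), query_end = integer(),
                    strand = character(), target_id = character(),
                    target_len = integer(), target_start = integer(),
                    target_end = integer(), matches = integer(),
                    align_len = integer(), score = double(),
                    stringsAsFactors = FALSE)
  out
}

#' Load tabular alignments (PAF or BLAST outfmt 6)
#'
#' The dialect is always explicit; there is no auto-detection. All
#' coordinates are normalised to 0-based half-open on both query and
#' target. BLAST-6 1-based inclusive coordinates are converted, and
#' reversed subject coordinates (`sstart > send`) become forward
#' coordinates with strand `-`. The `score` column is the file's native
#' score: the bit score for BLAST-6, the residue-match count for PAF.
#'
#' @param path Path to the alignment table.
#' @param dialect `"paf"` or `"blast6"`.
#' @return `data.frame` with columns `query_id`, `query_len`,
#'   `query_start`, `query_end`, `strand`, `target_id`, `target_len`,
#'   `target_start`, `target_end`, `matches`, `align_len`, `score`.
#'   `query_len`/`target_len` are `NA` for BLAST-6, which does not carry
#'   them.
#' @export
load_alignments <- function(path, dialect = c("paf", "blast6")) {
  dialect <- match.arg(dialect)
  lines <- readLines(path)
  lines <- lines[nzchar(lines)]
  if (!length(lines)) return(empty_alignments())
  fields <- strsplit(lines, "\t", fixed = TRUE)
  n_req <- if (dialect == "paf") 12L else 12L
  rows <- vector("list", length(fields))
  for (i in seq_along(fields)) {
    f <- fields[[i]]
    if (length(f) < n_req) {
      stop(sprintf("malformed %s line %d: %d fields (expected >= %d)",
                   dialect, i, length(f), n_req))
    }
    if (dialect == "paf") {
      num <- suppressWarnings(as.numeric(f[c(2:4, 7:12)]))
      if (anyNA(num) || !(f[5] %in% c("+", "-"))) {
        stop(sprintf("malformed paf line %d", i))
      }
      rows[[i]] <- data.frame(
        query_id = f[1], query_len = as.integer(f[2]),
        query_start = as.integer(f[3]), query_end = as.integer(f[4]),
        strand = f[5], target_id = f[6], target_len = as.integer(f[7]),
        target_start = as.integer(f[8]), target_end = as.integer(f[9]),
        matches = as.integer(f[10]), align_len = as.integer(f[11]),
        score = as.numeric(f[10]), stringsAsFactors = FALSE)
    } else {
      num <- suppressWarnings(as.numeric(f[3:12]))
      if (anyNA(num)) stop(sprintf("malformed blast6 line %d", i))
      qs <- as.integer(f[7]); qe <- as.integer(f[8])
      ss <- as.integer(f[9]); se <- as.integer(f[10])
      strand <- if (ss <= se) "+" else "-"
      ts <- min(ss, se); te <- max(ss, se)
      alen <- as.integer(f[4])
      rows[[i]] <- data.frame(
        query_id = f[1], query_len = NA_integer_,
        query_start = qs - 1L, query_end = qe,
        strand = strand, target_id = f[2], target_len = NA_integer_,
        target_start = ts - 1L, target_end = te,
        matches = as.integer(round(as.numeric(f[3]) / 100 * alen)),
        align_len = alen, score = as.numeric(f[12]),
        stringsAsFactors = FALSE)
    }
  }
  out <- do.call(rbind, rows)
  bad <- which(out$query_start >= out$query_end |
               out$target_start >= out$target_end)
  if (length(bad)) stop(sprintf("malformed %s line %d: empty interval",
                                dialect, bad[1]))
  out
}

#' Write alignments as PAF
#'
#' @param hits Alignment `data.frame` as returned by [load_alignments()].
#' @param path Output path.
#' @return `path`, invisibly.
#' @export
write_paf <- function(hits, path) {
  stopifnot(all(.alignment_cols %in% names(hits)))
  lines <- sprintf("%s\t%d\t%d\t%d\t%s\t%s\t%d\t%d\t%d\t%d\t%d\t%d",
                   hits$query_id, hits$query_len, hits$query_start,
                   hits$query_end, hits$strand, hits$target_id,
                   hits$target_len, hits$target_start, hits$target_end,
                   hits$matches, hits$align_len, 255L)
  writeLines(lines, path)
  invisible(path)
}

#' Load gene models from GFF3 and derive introns
#'
#' Parses a GFF3 file of gene/mRNA/exon/CDS (and optionally
#' `five_prime_UTR`) features and derives introns as the gaps between
#' consecutive exons of each mRNA. Every derived intron carries its
#' parent mRNA id.
#'
#' @param path Path to a GFF3 file.
#' @return `data.frame` with columns `scaffold_id`, `start`, `end`
#'   (0-based half-open), `strand`, `feature_type`, `id`, `parent`.
#'   Contains the file's features plus rows with `feature_type`
#'   `"intron"`.
#' @export
load_gene_models <- function(path) {
  gr <- rtracklayer::import(path, format = "gff3")
  md <- mcols(gr)
  parent <- if ("Parent" %in% names(md)) {
    vapply(md$Parent, function(p) if (length(p)) p[[1]] else NA_character_,
           character(1))
  } else rep(NA_character_, length(gr))
  id <- if ("ID" %in% names(md)) as.character(md$ID) else
    rep(NA_character_, length(gr))
  feats <- data.frame(
    scaffold_id = as.character(GenomicRanges::seqnames(gr)),
    start = GenomicRanges::start(gr) - 1L,
    end = GenomicRanges::end(gr),
    strand = as.character(GenomicRanges::strand(gr)),
    feature_type = as.character(gr$type),
    id = id, parent = parent, stringsAsFactors = FALSE)
  feats$strand[feats$strand == "*"] <- "."
  introns <- derive_introns(feats)
  rbind(feats, introns)
}

## Introns = gaps between consecutive exons of one mRNA. An exon falling
## outside its parent mRNA span is a hard error: it means the GFF3 is
## inconsistent and downstream context calls would be wrong.
derive_introns <- function(feats) {
  mrna <- feats[feats$feature_type %in% c("mRNA", "transcript"), ]
  exons <- feats[feats$feature_type == "exon", ]
  out <- list()
  for (i in seq_len(nrow(mrna))) {
    ex <- exons[!is.na(exons$parent) & exons$parent == mrna$id[i], ]
    if (!nrow(ex)) next
    if (any(ex$start < mrna$start[i] | ex$end > mrna$end[i])) {
      stop(sprintf("exon outside parent span for mRNA '%s'", mrna$id[i]))
    }
    ex <- ex[order(ex$start), ]
    if (nrow(ex) < 2L) next
    gs <- ex$end[-nrow(ex)]
    ge <- ex$start[-1L]
    keep <- gs < ge
    if (!any(keep)) next
    out[[length(out) + 1L]] <- data.frame(
      scaffold_id = mrna$scaffold_id[i], start = gs[keep], end = ge[keep],
      strand = mrna$strand[i], feature_type = "intron",
      id = NA_character_, parent = mrna$id[i], stringsAsFactors = FALSE)
  }
  if (!length(out)) {
    return(data.frame(scaffold_id = character(), start = integer(),
                      end = integer(), strand = character(),
                      feature_type = character(), id = character(),
                      parent = character(), stringsAsFactors = FALSE))
  }
  do.call(rbind, out)
}

#' Write intervals as GFF3
#'
#' Generic interval writer used for element catalogs and forge gene
#' models. Internal 0-based half-open coordinates are converted to GFF3
#' 1-based inclusive on the way out.
#'
#' @param df `data.frame` with columns `scaffold_id`, `start`, `end`,
#'   `strand`, `feature_type` and optionally `id`, `parent`, `score`.
#' @param path Output path.
#' @param source Value of the GFF3 source column.
#' @return `path`, invisibly.
#' @export
write_gff3 <- function(df, path, source = "inilcurate") {
  attrs <- vapply(seq_len(nrow(df)), function(i) {
    a <- character()
    if (!is.null(df$id) && !is.na(df$id[i]))
      a <- c(a, paste0("ID=", df$id[i]))
    if (!is.null(df$parent) && !is.na(df$parent[i]))
      a <- c(a, paste0("Parent=", df$parent[i]))
    if (!length(a)) "." else paste(a, collapse = ";")
  }, character(1))
  score <- if (is.null(df$score)) rep(".", nrow(df)) else
    ifelse(is.na(df$score), ".", as.character(df$score))
  lines <- sprintf("%s\t%s\t%s\t%d\t%d\t%s\t%s\t.\t%s",
                   df$scaffold_id, source, df$feature_type,
                   df$start + 1L, df$end, score, df$strand, attrs)
  writeLines(c("##gff-version 3", lines), path)
  invisible(path)
}

#' Write intervals as BED6
#'
#' BED is natively 0-based half-open, matching the internal convention.
#'
#' @param df `data.frame` with columns `scaffold_id`, `start`, `end` and
#'   optionally `name`, `score`, `strand`.
#' @param path Output path.
#' @return `path`, invisibly.
#' @export
write_bed <- function(df, path) {
  name <- if (is.null(df$name)) rep(".", nrow(df)) else df$name
  score <- if (is.null(df$score)) rep(0, nrow(df)) else df$score
  strand <- if (is.null(df$strand)) rep(".", nrow(df)) else df$strand
  lines <- sprintf("%s\t%d\t%d\t%s\t%s\t%s",
                   df$scaffold_id, df$start, df$end, name,
                   as.character(score), strand)
  writeLines(lines, path)
  invisible(path)
}
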