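.PRE_CORE <- "TGAAAC"

#' Scan a promoter sequence for pheromone response elements
#'
#' Reports every 8-mer window, on both strands, whose six core positions
#' (positions 2-7) match the Ste12 binding-site core TGAAAC with at most
#' `max_mismatch` mismatches. The consensus site is nTGAAACn: the flanking
#' "n" positions are unconstrained, so matching is on the 6-bp core and the
#' 8-mer is reported for context (it may be truncated at the sequence edges
#' as long as the core is fully inside). `N` never matches a core base.
#' Sites with zero core mismatches are "consensus"; sites with 1 to
#' `max_mismatch` mismatches are "non_consensus". Minus-strand hits are
#' reported in plus-strand coordinates with strand "-". Overlapping hits
#' are all reported.
#'
#' Coordinates are 0-based half-open on the supplied promoter sequence,
#' which is taken 5' to 3' toward the start codon; `distance_to_atg` is the
#' distance from the site end to the 3' end of the sequence, assuming the
#' sequence ends at the base immediately upstream of the ATG.
#'
#' @param sequence promoter sequence: a character string or a
#'   [Biostrings::DNAString] over A, C, G, T, N; length >= 8.
#' @param max_mismatch maximal core mismatches reported (default 1;
#'   raise to 2 to recover weaker degenerate sites).
#' @param promoter_id optional id copied into the output.
#' @return data.frame: promoter_id, start, end, strand, site_seq (as read
#'   on the hit strand), core_mismatches, klass, distance_to_atg,
#'   nucleosome_overlap (NA until [annotateNucleosomes()]); sorted by
#'   start.
#' @examples
#' scanPRE("ATGAAACA")            # one consensus hit on the plus strand
#' scanPRE("TGTTTCAT")            # its reverse complement, strand "-"
#' @export
scanPRE <- function(sequence, max_mismatch = 1, promoter_id = NA_character_) {
  seq_chr <- toupper(as.character(sequence))
  bad <- regexpr("[^ACGTN]", seq_chr)
  if (bad > 0)
    stop(sprintf("invalid character '%s' at offset %d",
                 substr(seq_chr, bad, bad), bad - 1L))
  L <- nchar(seq_chr)
  if (L < 8) stop("sequence shorter than 8 nt")
  subject <- Biostrings::DNAString(seq_chr)
  rc <- Biostrings::reverseComplement(subject)
  core_len <- nchar(.PRE_CORE)

  hits_on <- function(subj) {
    m <- Biostrings::matchPattern(.PRE_CORE, subj,
                                  max.mismatch = max_mismatch,
                                  with.indels = FALSE, fixed = TRUE)
    starts <- Biostrings::start(m)
    # overhanging partial matches are not sites: the core must be inside
    starts <- starts[starts >= 1 & starts + core_len - 1 <= length(subj)]
    if (length(starts) == 0)
      return(data.frame(core_start = integer(0), mism = integer(0)))
    mism <- vapply(starts, function(p) {
      frag <- substr(as.character(subj), p, p + core_len - 1)
      sum(strsplit(frag, "")[[1]] != strsplit(.PRE_CORE, "")[[1]])
    }, integer(1))
    data.frame(core_start = starts, mism = mism)
  }

  fwd <- hits_on(subject)
  rev <- hits_on(rc)
  rows <- list()
  add_hit <- function(cs1, ce1, strand, mism) {
    # 8-mer window = core +/- 1, clamped at the sequence edges
    w1 <- max(1L, cs1 - 1L); w2 <- min(L, ce1 + 1L)
    site <- substr(seq_chr, w1, w2)
    if (strand == "-")
      site <- as.character(Biostrings::reverseComplement(
        Biostrings::DNAString(site)))
    data.frame(promoter_id = promoter_id,
               start = w1 - 1L, end = w2, strand = strand,
               site_seq = site, core_mismatches = mism,
               klass = if (mism == 0) "consensus" else "non_consensus",
               distance_to_atg = L - w2,
               nucleosome_overlap = NA,
               stringsAsFactors = FALSE)
  }
  for (i in seq_len(nrow(fwd)))
    rows[[length(rows) + 1L]] <-
      add_hit(fwd$core_start[i], fwd$core_start[i] + core_len - 1L,
              "+", fwd$mism[i])
  for (i in seq_len(nrow(rev))) {
    q <- rev$core_start[i]
    cs1 <- L - (q + core_len - 1L) + 1L       # core start on plus strand
    rows[[length(rows) + 1L]] <-
      add_hit(cs1, cs1 + core_len - 1L, "-", rev$mism[i])
  }
  if (length(rows) == 0)
    return(data.frame(promoter_id = character(0), start = integer(0),
                      end = integer(0), strand = character(0),
                      site_seq = character(0), core_mismatches = integer(0),
                      klass = character(0), distance_to_atg = integer(0),
                      nucleosome_overlap = logical(0),
                      stringsAsFactors = FALSE))
  out <- do.call(rbind, rows)
  out <- out[order(out$start, out$strand), , drop = FALSE]
  rownames(out) <- NULL
  out
}

#' Annotate PRE hits with nucleosome overlap
#'
#' A site overlaps a nucleosome when its interval intersects any nucleosome
#' interval by at least 1 bp (both 0-based half-open on the same promoter
#' coordinate frame). Sites with `nucleosome_overlap = FALSE` lie in
#' nucleosome-depleted regions and are accessible to Ste12 before
#' stimulation.
#'
#' @param hits data.frame from [scanPRE()].
#' @param track nucleosome intervals: a data.frame with 0-based half-open
#'   `start`, `end` columns, or a `GRanges` (1-based, converted).
#' @return `hits` with `nucleosome_overlap` filled in.
#' @export
annotateNucleosomes <- function(hits, track) {
  if (is(track, "GRanges")) {
    gdf <- as.data.frame(track)
    track <- data.frame(start = gdf$start - 1L, end = gdf$end)
  }
  stopifnot(is.data.frame(track), all(c("start", "end") %in% names(track)))
  if (any(track$start >= track$end))
    stop("malformed nucleosome interval (start >= end)")
  if (nrow(hits) == 0) return(hits)
  q <- IRanges::IRanges(start = hits$start + 1L, end = hits$end)
  s <- IRanges::IRanges(start = track$start + 1L, end = track$end)
  hits$nucleosome_overlap <- IRanges::countOverlaps(q, s) > 0
  hits
}

#' Accessible consensus-site pairs
#'
#' All unordered pairs of consensus sites lying outside nucleosomes, with
#' their center-to-center spacing — the configuration that permits a Ste12
#' dimer before stimulation and distinguishes early-promoter architecture
#' (at least one such pair) from late promoters (none).
#'
#' @param hits data.frame from [annotateNucleosomes()].
#' @return data.frame with one row per pair: start1, end1, start2, end2,
#'   spacing_bp (center-to-center); zero rows when fewer than two
#'   accessible consensus sites exist.
#' @export
accessibleDimerPairs <- function(hits) {
  if (nrow(hits) > 0 && any(is.na(hits$nucleosome_overlap)))
    stop("hits must be annotated with annotateNucleosomes() first")
  acc <- hits[hits$klass == "consensus" & !hits$nucleosome_overlap, ,
              drop = FALSE]
  empty <- data.frame(start1 = integer(0), end1 = integer(0),
                      start2 = integer(0), end2 = integer(0),
                      spacing_bp = numeric(0))
  if (nrow(acc) < 2) return(empty)
  idx <- utils::combn(nrow(acc), 2)
  center <- (acc$start + acc$end) / 2
  data.frame(start1 = acc$start[idx[1, ]], end1 = acc$end[idx[1, ]],
             start2 = acc$start[idx[2, ]], end2 = acc$end[idx[2, ]],
             spacing_bp = abs(center[idx[2, ]] - center[idx[1, ]]))
}

#' Scan promoters from a FASTA file
#'
#' Reads promoter sequences with [Biostrings::readDNAStringSet()], scans
#' each with [scanPRE()], and, when a nucleosome BED file is given,
#' annotates hits whose promoter name matches the BED seqname.
#'
#' @param fasta path to a promoter FASTA file.
#' @param nucleosome_bed optional path to a BED file (0-based half-open) of
#'   nucleosome intervals on the promoter coordinate frames; requires the
#'   rtracklayer package.
#' @param max_mismatch passed to [scanPRE()].
#' @return data.frame of hits across all promoters.
#' @export
scanPromoters <- function(fasta, nucleosome_bed = NULL, max_mismatch = 1) {
  seqs <- Biostrings::readDNAStringSet(fasta)
  nuc <- NULL
  if (!is.null(nucleosome_bed)) {
    if (!requireNamespace("rtracklayer", quietly = TRUE))
      stop("rtracklayer is required to read BED files")
    gr <- as.data.frame(rtracklayer::import(nucleosome_bed, format = "BED"))
    nuc <- data.frame(seqname = as.character(gr$seqnames),
                      start = gr$start - 1L, end = gr$end)
  }
  res <- lapply(seq_along(seqs), function(i) {
    id <- names(seqs)[i]
    h <- scanPRE(seqs[[i]], max_mismatch = max_mismatch, promoter_id = id)
    if (!is.null(nuc)) {
      tr <- nuc[nuc$seqname == id, c("start", "end"), drop = FALSE]
      if (nrow(tr) > 0) h <- annotateNucleosomes(h, tr)
    }
    h
  })
  out <- do.call(rbind, res)
  rownames(out) <- NULL
  out
}

#' Write PRE hits as BED6
#'
#' Emits one BED line per hit (0-based half-open), with the site class as
#' name and the core mismatch count as score.
#'
#' @param hits data.frame from [scanPRE()] / [scanPromoters()].
#' @param path output file path.
#' @return `path`, invisibly.
#' @export
writePreBed <- function(hits, path) {
  if (nrow(hits) == 0) stop("no hits to write")
  bed <- data.frame(chrom = hits$promoter_id, start = hits$start,
                    end = hits$end, name = hits$klass,
                    score = hits$core_mismatches, strand = hits$strand)
  utils::write.table(bed, path, sep = "\t", quote = FALSE,
                     row.names = FALSE, col.names = FALSE)
  invisible(path)
}
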