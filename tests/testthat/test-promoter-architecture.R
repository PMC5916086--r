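test_that("the canonical PRE and its reverse complement are found", {
  h <- scanPRE("ATGAAACA")
  expect_equal(nrow(h), 1)
  expect_equal(h$strand, "+")
  expect_equal(h$core_mismatches, 0)
  expect_equal(h$klass, "consensus")
  expect_equal(c(h$start, h$end), c(0, 8))
  expect_equal(h$site_seq, "ATGAAACA")

  hrc <- scanPRE("TGTTTCAT")
  expect_equal(nrow(hrc), 1)
  expect_equal(hrc$strand, "-")
  expect_equal(hrc$core_mismatches, 0)
  expect_equal(hrc$site_seq, "ATGAAACA")   # read on its own strand

  expect_error(scanPRE("ATGAXACA"), "invalid character.*offset 4")
})

test_that("scanner equals brute-force 8-mer enumeration on random sequences", {
  set.seed(101)
  for (k in 1:12) {
    s <- randomSeq(200)
    for (mm in 0:1) {
      got <- scanPRE(s, max_mismatch = mm)
      want <- bruteScanPRE(s, max_mismatch = mm)
      cols <- c("start", "end", "strand", "core_mismatches")
      rownames(want) <- NULL
      expect_equal(got[cols], want[cols])
    }
  }
})

test_that("scanning is an involution under reverse complement", {
  set.seed(102)
  for (k in 1:10) {
    s <- randomSeq(150)
    L <- nchar(s)
    h <- scanPRE(s, max_mismatch = 1)
    hrc <- scanPRE(revComp(s), max_mismatch = 1)
    # mirror coordinates and swap strands
    mirrored <- data.frame(start = L - hrc$end, end = L - hrc$start,
                           strand = as.character(
                             ifelse(hrc$strand == "+", "-", "+")),
                           core_mismatches = hrc$core_mismatches,
                           stringsAsFactors = FALSE)
    mirrored <- mirrored[order(mirrored$start, mirrored$strand), ]
    rownames(mirrored) <- NULL
    expect_equal(h[c("start", "end", "strand", "core_mismatches")],
                 mirrored)
  }
})

test_that("raising the mismatch budget only adds hits", {
  set.seed(103)
  for (k in 1:5) {
    s <- randomSeq(300)
    h1 <- scanPRE(s, max_mismatch = 0)
    h2 <- scanPRE(s, max_mismatch = 1)
    h3 <- scanPRE(s, max_mismatch = 2)
    key <- function(h) paste(h$start, h$strand)
    expect_true(all(key(h1) %in% key(h2)))
    expect_true(all(key(h2) %in% key(h3)))
  }
})

test_that("nucleosome overlap is a half-open 1-bp-intersection rule", {
  hits <- data.frame(promoter_id = "p", start = c(100L, 100L),
                     end = c(108L, 108L), strand = "+",
                     site_seq = "ATGAAACA", core_mismatches = 0L,
                     klass = "consensus", distance_to_atg = 0L,
                     nucleosome_overlap = NA)
  ov <- annotateNucleosomes(hits[1, ], data.frame(start = 50, end = 120))
  expect_true(ov$nucleosome_overlap)
  no <- annotateNucleosomes(hits[1, ], data.frame(start = 108, end = 250))
  expect_false(no$nucleosome_overlap)   # half-open boundary touch
  expect_error(annotateNucleosomes(hits, data.frame(start = 10, end = 10)),
               "malformed")
  # random fixture against direct interval intersection
  set.seed(104)
  hs <- data.frame(promoter_id = "p", start = sample(0:490, 15),
                   strand = "+", site_seq = "x", core_mismatches = 0L,
                   klass = "consensus", distance_to_atg = 0L,
                   nucleosome_overlap = NA)
  hs$end <- hs$start + 8L
  track <- data.frame(start = c(30, 200, 400), end = c(120, 260, 470))
  got <- annotateNucleosomes(hs, track)$nucleosome_overlap
  want <- vapply(seq_len(nrow(hs)), function(i)
    any(pmin(hs$end[i], track$end) - pmax(hs$start[i], track$start) >= 1),
    logical(1))
  expect_equal(got, want)
})

test_that("accessible dimer pairs enumerate depleted consensus sites", {
  mkhits <- function(n_acc, extra_overlap = 1) {
    h <- data.frame(promoter_id = "p",
                    start = seq(0, by = 50,
                                length.out = n_acc + extra_overlap),
                    strand = "+", site_seq = "ATGAAACA",
                    core_mismatches = 0L, klass = "consensus",
                    distance_to_atg = 0L,
                    nucleosome_overlap = c(rep(FALSE, n_acc),
                                           rep(TRUE, extra_overlap)))
    h$end <- h$start + 8L
    h
  }
  expect_equal(nrow(accessibleDimerPairs(mkhits(2))), 1)
  expect_equal(nrow(accessibleDimerPairs(mkhits(1))), 0)  # late architecture
  p3 <- accessibleDimerPairs(mkhits(3))
  expect_equal(nrow(p3), 3)                               # combinatorial
  expect_equal(sort(p3$spacing_bp), c(50, 50, 100))
  un <- mkhits(2); un$nucleosome_overlap <- NA
  expect_error(accessibleDimerPairs(un), "annotate")
})

test_that("FASTA promoters scan with BED nucleosome annotation", {
  fa <- tempfile(fileext = ".fa")
  writeLines(c(">pEARLY", paste0(strrep("C", 20), "ATGAAACA",
                                 strrep("C", 20), "TTGAAACT",
                                 strrep("C", 20)),
               ">pLATE", paste0(strrep("G", 30), "ATGAAACA",
                                strrep("G", 30))), fa)
  hits <- scanPromoters(fa)
  expect_equal(sum(hits$promoter_id == "pEARLY"), 2)
  expect_equal(sum(hits$promoter_id == "pLATE"), 1)
  expect_true(all(hits$klass == "consensus"))
  # distance to the ATG-proximal end of the sequence
  late <- hits[hits$promoter_id == "pLATE", ]
  expect_equal(late$distance_to_atg, 68 - late$end)
  if (requireNamespace("rtracklayer", quietly = TRUE)) {
    bed <- tempfile(fileext = ".bed")
    writeLines("pEARLY\t40\t60\tnuc1", bed)
    ann <- scanPromoters(fa, nucleosome_bed = bed)
    early <- ann[ann$promoter_id == "pEARLY", ]
    expect_equal(early$nucleosome_overlap[order(early$start)],
                 c(FALSE, TRUE))
  }
  # BED6 export round-trips through a plain reader
  out <- tempfile(fileext = ".bed")
  writePreBed(hits, out)
  bed_in <- read.table(out, sep = "\t")
  expect_equal(nrow(bed_in), nrow(hits))
  expect_equal(bed_in$V2, hits$start)
})
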