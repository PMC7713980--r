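# Alignment filtering, mapping metrics, SAM I/O, and the toy mapper.

.rec <- function(qname = "r", flag = 0x1L, rname = "c1", pos = 1L,
                 mapq = 60L, cigar = "4M", seq = "ACGT") {
  data.table::data.table(qname = qname, flag = as.integer(flag), rname = rname,
                         pos = as.integer(pos), mapq = as.integer(mapq),
                         cigar = cigar, seq = seq)
}

test_that("filter_alignments applies MAPQ and flag criteria", {
  recs <- rbind(
    .rec("pass_mapq20", flag = 0x0, mapq = 20),
    .rec("fail_secondary", flag = 0x100, mapq = 60),
    .rec("fail_unmapped", flag = 0x4, rname = NA_character_, mapq = 60),
    .rec("fail_qc", flag = 0x200, mapq = 60),
    .rec("fail_supp", flag = 0x800, mapq = 60),
    .rec("fail_mapq19", flag = 0x0, mapq = 19),
    .rec("pass_duplicate", flag = 0x400, mapq = 60))
  out <- filter_alignments(recs)
  expect_setequal(out$qname, c("pass_mapq20", "pass_duplicate"))
})

test_that("compute_metrics matches the worked examples", {
  # 10 total reads: 6 pass, 2 mapped but MAPQ<20, 2 unmapped
  ref <- genome(c(c1 = strrep("A", 50)))
  recs <- rbind(
    do.call(rbind, lapply(1:6, function(i) .rec(paste0("p", i), mapq = 60))),
    .rec("low1", mapq = 10), .rec("low2", mapq = 5),
    .rec("un1", flag = 0x4, rname = NA_character_),
    .rec("un2", flag = 0x4, rname = NA_character_))
  m <- compute_metrics(recs, ref, total_reads = 10)
  expect_equal(m$mapped_pct, 60)

  # breadth/depth: 10 bp reference, two 4 bp matches at pos 0 and 2 (0-based)
  ref10 <- genome(c(c1 = "ACGTACGTAC"))
  recs2 <- rbind(.rec("a", pos = 1), .rec("b", pos = 3))
  m2 <- compute_metrics(recs2, ref10, total_reads = 2)
  expect_equal(m2$breadth_pct, 60)
  expect_equal(m2$mean_depth, 0.8)

  # N-exclusion: covered everywhere, 8 non-N bases
  refn <- genome(c(c1 = "ACGTNNACGT"))
  m3 <- compute_metrics(.rec("a", cigar = "10M", seq = strrep("A", 10)),
                        refn, total_reads = 1)
  expect_equal(m3$breadth_pct, 100)
  expect_equal(m3$mean_depth, 1)
  expect_equal(m3$ref_missing, 2)
  expect_equal(m3$ref_total_length, 10)
})

test_that("deletions consume reference depth; insertions and clips do not", {
  ref <- genome(c(c1 = strrep("G", 20)))
  recs <- .rec("d", cigar = "3M2D3M2I2M", seq = strrep("G", 10), pos = 1)
  m <- compute_metrics(recs, ref, total_reads = 1)
  # reference span: 3 + 2 + 3 + 0 + 2 = 10 positions
  expect_equal(m$breadth_pct, 50)
  expect_equal(m$mean_depth, 0.5)
})

test_that("compute_metrics equals brute-force pileup on random cases", {
  with_seed(91, {
    for (rep in 1:8) {
      nseq <- sample(1:2, 1)
      ref <- genome(setNames(vapply(seq_len(nseq), function(i)
        paste(sample(c("A", "C", "G", "T", "N"), sample(30:80, 1), TRUE,
                     prob = c(.22, .22, .22, .22, .12)), collapse = ""),
        character(1)), paste0("c", seq_len(nseq))))
      lens <- nchar(unclass(ref))
      n <- sample(5:25, 1)
      recs <- do.call(rbind, lapply(seq_len(n), function(i) {
        nm <- sample(names(ref), 1)
        w <- sample(3:10, 1)
        pos <- sample(max(1, lens[[nm]] - w - 6), 1)
        cig <- sample(c(sprintf("%dM", w), sprintf("%dM%dD%dM", w, 2, 3),
                        sprintf("%dS%dM", 2, w)), 1)
        .rec(paste0("r", i),
             flag = sample(c(0x0, 0x4, 0x100, 0x400), 1),
             rname = nm, pos = pos, mapq = sample(c(0, 19, 20, 60), 1),
             cigar = cig, seq = strrep("A", w + 5))
      }))
      recs$rname[bitwAnd(recs$flag, 0x4) != 0] <- NA_character_
      total <- n + sample(0:5, 1)
      got <- compute_metrics(recs, ref, total_reads = total)
      want <- brute_metrics(recs, ref, total_reads = total)
      expect_equal(got$mapped_pct, want$mapped_pct)
      expect_equal(got$breadth_pct, want$breadth_pct)
      expect_equal(got$mean_depth, want$mean_depth)
    }
  })
})

test_that("adding a passing record never decreases breadth or depth", {
  with_seed(92, {
    ref <- genome(c(c1 = paste(sample(c("A", "C", "G", "T"), 60, TRUE),
                               collapse = "")))
    recs <- .rec("a", pos = 5, cigar = "10M", seq = strrep("A", 10))
    m1 <- compute_metrics(recs, ref, total_reads = 5)
    recs2 <- rbind(recs, .rec("b", pos = 30, cigar = "10M", seq = strrep("A", 10)))
    m2 <- compute_metrics(recs2, ref, total_reads = 5)
    expect_gte(m2$breadth_pct, m1$breadth_pct)
    expect_gte(m2$mean_depth, m1$mean_depth)
  })
})

test_that("compute_metrics validates the reference against the header", {
  ref <- genome(c(c1 = strrep("A", 50)))
  recs <- .rec("a")
  data.table::setattr(recs, "header", data.frame(sn = "c1", ln = 49L))
  expect_error(compute_metrics(recs, ref, total_reads = 1), "header")
})

test_that("the toy mapper places, ranks and rejects reads correctly", {
  with_seed(93, {
    base <- paste(sample(c("A", "C", "G", "T"), 3000, TRUE), collapse = "")
    dup <- substr(base, 101, 200)
    ref <- genome(c(c1 = paste0(base, dup)))    # a 100 bp exact repeat
    # unique exact read
    rd <- substr(base, 501, 600)
    pairs <- data.frame(name = "u", read1 = rd, read2 = .rc_str(rd))
    rec <- toy_map(pairs, ref)
    r1 <- rec[bitwAnd(rec$flag, 0x40) == 0x40, ]
    expect_equal(r1$pos, 501L)
    expect_equal(r1$mapq, 60L)
    expect_equal(r1$cigar, "100M")
    # read present twice -> MAPQ 0
    amb <- data.frame(name = "a", read1 = dup, read2 = .rc_str(dup))
    reca <- toy_map(amb, ref)
    expect_true(all(reca$mapq == 0L))
    expect_true(all(bitwAnd(reca$flag, 0x4) == 0))
    # hopeless read -> unmapped
    junk <- strrep("AC", 50)
    recj <- toy_map(data.frame(name = "j", read1 = junk, read2 = junk),
                    genome(c(c1 = paste(sample(c("G", "T"), 2000, TRUE),
                                        collapse = ""))),
                    max_mismatch = 5)
    expect_true(all(bitwAnd(recj$flag, 0x4) == 0x4))
    # mate 2 maps on the reverse strand of its fragment
    expect_true(any(bitwAnd(rec$flag, 0x10) == 0x10))
  })
})

test_that("SAM text round-trips through write_sam/read_sam", {
  with_seed(94, {
    g <- genome(c(ctg = paste(sample(c("A", "C", "G", "T"), 2000, TRUE),
                              collapse = "")))
    pairs <- simulate_reads(g, 30, read_len = 50, fragment_mean = 150, seed = 3)
    rec <- toy_map(pairs, g)
    path <- withr::local_tempfile(fileext = ".sam")
    write_sam(rec, path)
    back <- read_sam(path)
    expect_equal(attr(back, "header")$sn, "ctg")
    expect_equal(attr(back, "header")$ln, 2000L)
    expect_equal(back$flag, rec$flag)
    expect_equal(back$pos, rec$pos)
    expect_equal(back$mapq, rec$mapq)
    expect_equal(back$cigar, rec$cigar)
    m1 <- compute_metrics(rec, g, total_reads = 60)
    m2 <- compute_metrics(back, g, total_reads = 60)
    expect_equal(m1$breadth_pct, m2$breadth_pct)
    expect_equal(m1$mean_depth, m2$mean_depth)
    expect_error(read_sam(withr::local_tempfile(lines = "r1\t0\tc\t1\t60\t4M\t*\t0\t0\tACGT\t*")),
                 "header")
  })
})
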