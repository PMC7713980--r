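# Replacement planning, hybrid splicing, aligned-fraction construction.

.seg <- function(seq_name, start, end, replacement, score = 100,
                 strand = "+", block_index = 1L, node_id = "N1") {
  structure(list(node_id = node_id, block_index = block_index,
                 columns = seq_len(nchar(replacement)),
                 sequence = replacement, posteriors = NULL,
                 max_prob = rep(1, nchar(replacement)),
                 anchor_placement = NULL,
                 sister_placement = list(seq_name = seq_name, start = start,
                                         end = end, strand = strand),
                 score = score), class = "ancestral_segment")
}

test_that("overlapping candidate intervals resolve by block score", {
  sis <- genome(c(c1 = strrep("A", 50)))
  s1 <- .seg("c1", 10, 20, strrep("G", 10), score = 900, block_index = 1L)
  s2 <- .seg("c1", 15, 30, strrep("C", 15), score = 400, block_index = 2L)
  plan <- plan_replacements(list(s1, s2), sis)
  expect_equal(nrow(plan$c1), 1L)
  expect_equal(plan$c1$block_index, 1L)

  # no segments -> empty plan -> identity
  empty <- plan_replacements(list(), sis)
  expect_identical(unclass(build_hybrid(sis, empty)$genome), unclass(sis))

  # segments without a sister placement are skipped and counted
  s3 <- .seg("c1", 5, 8, "GG")
  s3$sister_placement <- NULL
  p2 <- plan_replacements(list(s3, s1), sis)
  expect_equal(attr(p2, "n_skipped"), 1L)

  # minus-strand placements are recorded
  s4 <- .seg("c1", 0, 4, "ACGT", strand = "-")
  p3 <- plan_replacements(list(s4), sis)
  expect_equal(p3$c1$strand, "-")

  # out-of-bounds placements name the offending block
  s5 <- .seg("c1", 45, 60, strrep("T", 10), block_index = 7L)
  expect_error(plan_replacements(list(s5), sis), "block 7")
})

test_that("splice arithmetic is exact", {
  sis <- genome(c(c1 = strrep("ACGTT", 20)))   # 100 bp
  s1 <- .seg("c1", 10, 20, strrep("G", 12))
  hb <- build_hybrid(sis, plan_replacements(list(s1), sis))
  out <- unclass(hb$genome)[["c1"]]
  expect_equal(nchar(out), 102L)
  expect_equal(substr(out, 1, 10), substr(sis[["c1"]], 1, 10))
  expect_equal(substr(out, 11, 22), strrep("G", 12))
  expect_equal(substr(out, 23, 102), substr(sis[["c1"]], 21, 100))
  expect_equal(hb$intervals$new_start, 10)
  expect_equal(hb$intervals$new_end, 22)

  # replacement identical to the sister segment leaves the genome unchanged
  same <- .seg("c1", 10, 20, substr(sis[["c1"]], 11, 20))
  hb2 <- build_hybrid(sis, plan_replacements(list(same), sis))
  expect_identical(unclass(hb2$genome), unclass(sis))
})

test_that("minus-strand replacements are reverse-complemented on splice", {
  sis <- genome(c(c1 = "AAAAAAAAAA"))
  s <- .seg("c1", 2, 6, "ACGT", strand = "-")
  hb <- build_hybrid(sis, plan_replacements(list(s), sis))
  expect_equal(unclass(hb$genome)[["c1"]], "AAACGTAAAA")
})

test_that("randomized splices agree with brute-force string surgery", {
  with_seed(71, {
    for (rep in 1:20) {
      nseq <- sample(1:3, 1)
      sis <- genome(setNames(
        vapply(seq_len(nseq), function(i)
          paste(sample(c("A", "C", "G", "T", "N"), sample(80:200, 1),
                       replace = TRUE, prob = c(.24, .24, .24, .24, .04)),
                collapse = ""), character(1)),
        paste0("c", seq_len(nseq))))
      segs <- list()
      for (nm in names(sis)) {
        len <- nchar(sis[[nm]])
        cuts <- sort(sample(0:len, sample(2:6, 1)))
        if (length(cuts) < 2) next
        for (j in seq_len(length(cuts) - 1)) {
          if (runif(1) < 0.4) next
          st <- cuts[j]; en <- cuts[j + 1]
          if (en <= st) next
          repl <- paste(sample(c("A", "C", "G", "T"),
                               max(1, rpois(1, en - st)), replace = TRUE),
                        collapse = "")
          segs[[length(segs) + 1L]] <-
            .seg(nm, st, en, repl, score = sample(100:999, 1),
                 strand = sample(c("+", "-"), 1),
                 block_index = length(segs) + 1L)
        }
      }
      plan <- plan_replacements(segs, sis)
      hb <- build_hybrid(sis, plan)
      want <- brute_splice(sis, plan)
      expect_identical(unclass(hb$genome), want)
      # splice length identity per sequence
      for (nm in names(sis)) {
        tab <- plan[[nm]]
        expect_equal(nchar(unclass(hb$genome)[[nm]]),
                     nchar(sis[[nm]]) - sum(tab$end - tab$start) +
                       sum(nchar(tab$replacement)))
      }
      # untouched positions map bijectively through the interval table
      for (nm in names(sis)) {
        tab <- plan[[nm]]
        if (!nrow(tab)) next
        imap <- hb$intervals[hb$intervals$seq_name == nm, ]
        old <- sis[[nm]]; new <- unclass(hb$genome)[[nm]]
        for (probe in 1:5) {
          p <- sample(nchar(old), 1)
          inside <- any(imap$old_start < p & p <= imap$old_end)
          if (inside) next
          offs <- sum((imap$new_end[imap$old_end <= p - 1] -
                         imap$new_start[imap$old_end <= p - 1]) -
                        (imap$old_end[imap$old_end <= p - 1] -
                           imap$old_start[imap$old_end <= p - 1]))
          expect_equal(substr(new, p + offs, p + offs), substr(old, p, p))
        }
      }
    }
  })
})

test_that("aligned fraction is additive over blocks and honors masking", {
  sp <- c("anc", "sis", "x")
  mk <- function(w, start) read_maf(c(
    "a score=10",
    sprintf("s anc.chr1 %d %d + 10000 %s", start, w, strrep("A", w)),
    sprintf("s sis.chr2 %d %d + 10000 %s", start, w, strrep("C", w)),
    sprintf("s x.chr3 %d %d + 10000 %s", start, w, strrep("G", w))))[[1]]
  blocks <- list(mk(150, 0), mk(200, 200), mk(120, 500))
  af <- build_aligned_fraction(blocks, species_id = "sis", species_set = sp)
  expect_length(af, 3L)
  expect_equal(sum(nchar(unclass(af))), 470L)

  # block with the sister fully gapped contributes no sister contig
  bg <- read_maf(c("a score=10",
                   "s anc.chr1 900 4 + 10000 ACGT",
                   "s x.chr3 900 4 + 10000 ACGT"))[[1]]
  af2 <- build_aligned_fraction(c(blocks, list(bg)), species_id = "sis",
                                species_set = sp, max_missing_frac = 0.9)
  expect_length(af2, 3L)
  expect_error(build_aligned_fraction(blocks, species_id = "zz",
                                      species_set = sp), "absent")
})

test_that("ancestral aligned fraction retains sister-gapped columns", {
  # sister gapped in half the block: the ancestral contig keeps those
  # columns, so it is longer than the sister aligned fraction
  tr <- read_newick("((a:0.05,sis:0.05):0.02,c:0.05);")
  m <- substitution_model("GTR")
  b <- read_maf(c("a score=50",
                  "s a.chr1 0 40 + 100 ACGTACGTACGTACGTACGTACGTACGTACGTACGTACGT",
                  "s sis.chr2 0 20 + 50 ACGTACGTACGTACGTACGT--------------------",
                  "s c.chr3 0 40 + 100 ACGTACGTACGTACGTACGTACGTACGTACGTACGTACGT"))[[1]]
  segs <- reconstruct_nodes(list(b), tr, m, "N1", sister_species = "sis")
  anc <- ancestral_genome(segs, "N1")
  af_sis <- build_aligned_fraction(list(b), species_id = "sis",
                                   species_set = c("a", "sis", "c"))
  expect_equal(sum(nchar(unclass(anc))), 40L)
  expect_equal(sum(nchar(unclass(af_sis))), 20L)
  expect_gt(sum(nchar(unclass(anc))), sum(nchar(unclass(af_sis))))
})
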