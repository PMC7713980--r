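# Clade and read simulation.

test_that("no evolution means identical genomes and one block per contig", {
  tr <- read_newick("((a:0,b:0):0,c:0);")
  m <- substitution_model("GTR")
  sim <- evolve_clade(tr, m, root_length = c(chrA = 500, chrB = 300),
                      indel_rate = 0, seed = 4)
  for (lab in c("a", "b", "c"))
    expect_identical(unclass(sim$genomes[[lab]]),
                     unclass(sim$genomes[[tr$node.label[1]]]))
  expect_length(sim$blocks, 2L)
  expect_false(any(grepl("-", sim$blocks[[1]]$rows$text, fixed = TRUE)))
})

test_that("identical seed and configuration are bit-identical", {
  tr <- bird_clade_tree()
  m <- default_clade_model()
  s1 <- evolve_clade(tr, m, root_length = c(chr1 = 4000), seed = 123)
  s2 <- evolve_clade(tr, m, root_length = c(chr1 = 4000), seed = 123)
  expect_identical(s1$blocks, s2$blocks)
  expect_identical(lapply(s1$genomes, unclass), lapply(s2$genomes, unclass))
  s3 <- evolve_clade(tr, m, root_length = c(chr1 = 4000), seed = 124)
  expect_false(identical(s1$blocks, s3$blocks))
})

test_that("pairwise divergence matches the JC69 expectation", {
  # one branch of length 0.1 under JC69; pooled over seeds
  tr <- read_newick("(a:0.1,b:0);")
  jc <- substitution_model("GTR")
  p_exp <- 3 / 4 * (1 - exp(-4 * 0.1 / 3))
  diffs <- 0; total <- 0
  for (s in 1:20) {
    sim <- evolve_clade(tr, jc, root_length = c(chr1 = 20000), indel_rate = 0,
                        seed = 200 + s)
    a <- strsplit(sim$genomes$a[["chr1"]], "")[[1]]
    b <- strsplit(sim$genomes$b[["chr1"]], "")[[1]]
    diffs <- diffs + sum(a != b); total <- total + length(a)
  }
  se <- sqrt(p_exp * (1 - p_exp) / total)
  expect_lt(abs(diffs / total - p_exp), 3 * se)
})

test_that("long branches converge to the stationary distribution", {
  pi <- c(A = .4, C = .1, G = .2, T = .3)
  m <- substitution_model("GTR", base_freqs = pi)
  tr <- read_newick("(a:5,b:0);")
  sim <- evolve_clade(tr, m, root_length = c(chr1 = 30000), indel_rate = 0,
                      seed = 77)
  obs <- table(strsplit(sim$genomes$a[["chr1"]], "")[[1]])[c("A", "C", "G", "T")]
  n <- sum(obs)
  for (b in names(pi)) {
    se <- sqrt(pi[[b]] * (1 - pi[[b]]) / n)
    expect_lt(abs(obs[[b]] / n - pi[[b]]), 3 * se)
  }
})

test_that("indels split the truth MAF into gap-consistent anchor blocks", {
  tr <- bird_clade_tree()
  sim <- evolve_clade(tr, default_clade_model(), root_length = c(chr1 = 8000),
                      indel_rate = 0.01, seed = 31, anchor_species = "TAEGU")
  expect_gt(length(sim$blocks), 1L)
  for (b in sim$blocks) {
    # rows are gapless within blocks and satisfy the MAF invariants
    expect_false(any(grepl("-", b$rows$text, fixed = TRUE)))
    expect_true(all(nchar(b$rows$text) == b$n_columns))
    expect_true(all(b$rows$start + b$rows$size <= b$rows$src_size))
    expect_equal(b$rows$species[1], "TAEGU")
  }
  # per-species block sizes tile each genome contiguously
  for (sp in tr$tip.label) {
    spans <- do.call(rbind, lapply(sim$blocks, function(b) {
      j <- match(sp, b$rows$species)
      if (is.na(j)) NULL else b$rows[j, c("start", "size")]
    }))
    spans <- spans[order(spans$start), ]
    expect_true(all(diff(c(0, spans$start + spans$size)) >= 0))
    expect_lte(max(spans$start + spans$size),
               nchar(sim$genomes[[sp]][["chr1"]]))
    # block text matches the genome at the recorded coordinates
    b1 <- sim$blocks[[1]]
    j <- match(sp, b1$rows$species)
    if (!is.na(j))
      expect_equal(substr(sim$genomes[[sp]][["chr1"]], b1$rows$start[j] + 1,
                          b1$rows$start[j] + b1$rows$size[j]),
                   b1$rows$text[j])
  }
  # event log accounts for the indels that split the alignment
  expect_gt(sum(sim$event_log$insertions + sim$event_log$deletions), 0)
})

test_that("the truth MAF round-trips and survives filter/dedupe unchanged", {
  tr <- bird_clade_tree()
  sim <- evolve_clade(tr, default_clade_model(), root_length = c(chr1 = 6000),
                      indel_rate = 0.005, seed = 32)
  path <- withr::local_tempfile(fileext = ".maf")
  write_maf(sim$blocks, path)
  back <- read_maf(path)
  expect_equal(length(back), length(sim$blocks))
  expect_equal(back[[3]]$rows, sim$blocks[[3]]$rows)
  # blocks are non-overlapping by construction: dedupe keeps everything
  dd <- dedupe_best_hit(sim$blocks)
  expect_equal(length(dd), length(sim$blocks))
})

test_that("error-free reads match the genome at their encoded coordinates", {
  with_seed(81, {
    g <- genome(c(ctg = paste(sample(c("A", "C", "G", "T"), 5000, TRUE),
                              collapse = "")))
    pairs <- simulate_reads(g, 200, read_len = 50, fragment_mean = 200,
                            fragment_sd = 20, seed = 9)
    expect_equal(nrow(pairs), 200L)
    info <- do.call(rbind, strsplit(pairs$name, "_"))
    st <- as.integer(info[, 2]); en <- as.integer(info[, 3])
    rc <- function(s) chartr("ACGT", "TGCA",
                             paste(rev(strsplit(s, "")[[1]]), collapse = ""))
    for (i in c(1, 50, 200)) {
      expect_equal(pairs$read1[i], substr(g[["ctg"]], st[i], st[i] + 49))
      expect_equal(pairs$read2[i], rc(substr(g[["ctg"]], en[i] - 49, en[i])))
    }
  })
})

test_that("read simulation edge cases", {
  g <- genome(c(ctg = strrep("ACGT", 500)))
  p0 <- simulate_reads(g, 0, read_len = 50, fragment_mean = 100, seed = 1)
  expect_equal(nrow(p0), 0L)
  expect_error(simulate_reads(genome(c(c = "ACGT")), 5, read_len = 100,
                              fragment_mean = 100), "shorter")
  # determinism
  pa <- simulate_reads(g, 50, read_len = 30, fragment_mean = 80, seed = 5)
  pb <- simulate_reads(g, 50, read_len = 30, fragment_mean = 80, seed = 5)
  expect_identical(pa, pb)
  # N-containing fragments are rejected
  gn <- genome(c(ctg = paste0(strrep("A", 300), strrep("N", 100),
                              strrep("C", 300))))
  pn <- simulate_reads(gn, 100, read_len = 40, fragment_mean = 60,
                       fragment_sd = 5, seed = 6)
  expect_false(any(grepl("N", pn$read1, fixed = TRUE)))
  expect_false(any(grepl("N", pn$read2, fixed = TRUE)))
})

test_that("fragment starts are uniform across a single contig", {
  with_seed(82, {
    g <- genome(c(ctg = paste(sample(c("A", "C", "G", "T"), 100000, TRUE),
                              collapse = "")))
    pairs <- simulate_reads(g, 10000, read_len = 100, fragment_mean = 300,
                            fragment_sd = 10, seed = 44)
    st <- as.integer(vapply(strsplit(pairs$name, "_"), `[[`, "", 2))
    h <- table(cut(st, breaks = seq(0, 100000, by = 10000)))
    expect_gt(chisq.test(h)$p.value, 0.01)
  })
})

test_that("FASTQ round trip preserves reads and wgsim-style names", {
  g <- genome(c(ctg = strrep("ACGTG", 200)))
  pairs <- simulate_reads(g, 20, read_len = 30, fragment_mean = 80, seed = 2)
  f1 <- withr::local_tempfile(fileext = ".fq")
  f2 <- withr::local_tempfile(fileext = ".fq")
  write_fastq(pairs, f1, f2)
  l1 <- readLines(f1)
  expect_equal(length(l1), 80L)
  expect_true(all(startsWith(l1[seq(1, 80, 4)], "@ctg_")))
  expect_true(all(l1[seq(4, 80, 4)] == strrep("I", 30)))
  back <- read_fastq_pairs(f1, f2)
  expect_equal(back$read1, pairs$read1)
  expect_equal(back$read2, pairs$read2)
  expect_equal(back$name, pairs$name)
})
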