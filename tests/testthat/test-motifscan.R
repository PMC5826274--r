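fixture_pwm <- function() {
  read_jaspar(system.file("extdata", "synthetic_foxp2_like.jaspar",
                          package = "songnet"))
}

test_that("PWM construction gives log2 odds against a uniform background", {
  # a pure-A column with no pseudocount scores log2(4) = 2 for A
  counts <- matrix(c(1, 0, 0, 0), 4, 1, dimnames = list(c("A", "C", "G", "T"), NULL))
  pwm <- pwm_from_counts(counts, pseudocount = 0)
  expect_equal(unname(pwm$weights["A", 1]), 2)
  expect_equal(pwm$consensus, "A")

  # uniform column scores 0 for every base, at any pseudocount
  uni <- matrix(5, 4, 3, dimnames = list(c("A", "C", "G", "T"), NULL))
  expect_equal(unname(pwm_from_counts(uni, pseudocount = 0.8)$weights),
               matrix(0, 4, 3))

  expect_error(pwm_from_counts(matrix(1, 3, 2)), "4 rows")
  expect_error(pwm_from_counts(matrix(c(1, 1, 1, 1, 0, 0, 0, 0), 4, 2)), "positive")
})

test_that("JASPAR parsing recovers the consensus as column argmax letters", {
  pwm <- fixture_pwm()
  expect_equal(ncol(pwm$weights), 10)
  expect_equal(pwm$consensus, "TGTTTACTTA")
  expect_equal(attr(pwm, "motif_id"), "SYNTH0001 synthetic_forkhead_like")
  expect_gte(pwm$max_score, pwm$min_score)
  # max/min scores really bound every achievable window score
  expect_equal(relative_pwm_score(pwm, pwm$consensus), 1)
})

test_that("relative scores are invariant to per-column constant shifts", {
  pwm <- fixture_pwm()
  shifted <- pwm
  shifted$weights <- sweep(pwm$weights, 2, runif(10, -2, 2), "+")
  shifted$pos_max <- apply(shifted$weights, 2, max)
  shifted$pos_min <- apply(shifted$weights, 2, min)
  shifted$max_score <- sum(shifted$pos_max)
  shifted$min_score <- sum(shifted$pos_min)
  set.seed(5)
  for (i in 1:20) {
    w <- paste(sample(c("A", "C", "G", "T"), 10, replace = TRUE), collapse = "")
    expect_equal(relative_pwm_score(pwm, w), relative_pwm_score(shifted, w),
                 tolerance = 1e-12)
  }
})

test_that("a planted consensus is found at its offset with relative score 1", {
  pwm <- fixture_pwm()
  set.seed(88)
  bg <- paste(sample(c("A", "C", "G", "T"), 1000, replace = TRUE), collapse = "")
  seqv <- bg
  substr(seqv, 289, 298) <- pwm$consensus  # 0-based offset 288
  hits <- scan_pwm(c(prom1 = seqv), pwm, min_relative = 0.95, both_strands = FALSE)
  expect_true(any(hits$offset == 288 & hits$relative_score == 1))
  top <- hits[hits$offset == 288, ]
  expect_equal(top$match, pwm$consensus)

  # min_relative = 1 reports only exact-maximum windows
  only_max <- scan_pwm(c(prom1 = seqv), pwm, min_relative = 1, both_strands = FALSE)
  expect_true(all(only_max$relative_score == 1))
  expect_true(288 %in% only_max$offset)
})

test_that("reverse-strand hits map back to forward coordinates", {
  pwm <- fixture_pwm()
  set.seed(13)
  bg <- paste(sample(c("A", "C", "G", "T"), 300, replace = TRUE), collapse = "")
  rc_motif <- as.character(Biostrings::reverseComplement(
    Biostrings::DNAString(pwm$consensus)))
  seqv <- bg
  substr(seqv, 101, 110) <- rc_motif  # forward offset 100 on the minus strand
  hits <- scan_pwm(c(p = seqv), pwm, min_relative = 0.99)
  minus <- hits[hits$strand == "-", ]
  expect_true(100 %in% minus$offset)

  # single-strand scans of a sequence and its reverse complement are
  # mirror images: a minus-strand hit on seq at forward offset o equals a
  # plus-strand hit on revcomp(seq) at offset len - L - o
  rc_seq <- as.character(Biostrings::reverseComplement(Biostrings::DNAString(seqv)))
  on_rc <- scan_pwm(c(p = rc_seq), pwm, min_relative = 0.8, both_strands = FALSE)
  minus_on_seq <- hits2 <- scan_pwm(c(p = seqv), pwm, min_relative = 0.8)
  minus_on_seq <- hits2[hits2$strand == "-", ]
  expect_setequal(minus_on_seq$offset, nchar(seqv) - 10 - on_rc$offset)
  expect_equal(sort(minus_on_seq$relative_score), sort(on_rc$relative_score))
})

test_that("windows containing N are skipped and short sequences yield no hits", {
  pwm <- fixture_pwm()
  seqn <- paste0(pwm$consensus, "NNNNN", pwm$consensus)
  hits <- scan_pwm(c(p = seqn), pwm, min_relative = 0.8, both_strands = FALSE)
  expect_setequal(hits$offset, c(0, 15))
  short <- scan_pwm(c(p = "ACGT"), pwm)
  expect_equal(nrow(short), 0)
})

test_that("planted above-threshold motifs are all recovered at their offsets", {
  pwm <- fixture_pwm()
  prom <- simulate_promoters(pwm, n = 120, motif_rate = 0.7, seed = 41)
  hits <- scan_pwm(prom$sequences, pwm, min_relative = 0.80)
  expect_true(all(hits$relative_score >= 0.80))  # no sub-threshold report
  strong <- prom$planted[prom$planted$relative_score >= 0.80, ]
  expect_gt(nrow(strong), 10)
  found <- paste(hits$seq_id, hits$offset)
  expect_true(all(paste(strong$seq_id, strong$offset) %in% found))
})

test_that("promoter extraction follows strand-aware 0-based arithmetic", {
  set.seed(3)
  contig <- paste(sample(c("A", "C", "G", "T"), 3000, replace = TRUE), collapse = "")
  genes <- tibble::tibble(
    gene_id = c("plus", "minus", "short"),
    seq_id = "chr1",
    tss = c(1000, 500, 500),
    strand = c("+", "-", "+")
  )
  expect_warning(
    prom <- extract_promoters(genes, c(chr1 = contig), upstream = 1000),
    "truncated"
  )
  expect_equal(prom[["plus"]], substr(contig, 1, 1000))   # bases 0..999
  expect_equal(nchar(prom[["short"]]), 500)
  # minus strand: reverse complement of (tss, tss + 1000]
  span <- substr(contig, 502, 1501)
  expect_equal(prom[["minus"]],
               as.character(Biostrings::reverseComplement(Biostrings::DNAString(span))))
  bad <- tibble::tibble(gene_id = "x", seq_id = "chr1", tss = 5000, strand = "+")
  expect_error(extract_promoters(bad, c(chr1 = contig)), "outside")
})

test_that("FASTA round-trip preserves sequences and ids", {
  seqs <- c(p1 = "ACGTACGT", p2 = "TTTTAAAA")
  path <- withr::local_tempfile(fileext = ".fasta")
  write_fasta(seqs, path)
  back <- read_fasta(path)
  expect_equal(back, seqs)
})

test_that("in-package scanning agrees with Biostrings matchPWM", {
  pwm <- fixture_pwm()
  set.seed(19)
  seqv <- paste(sample(c("A", "C", "G", "T"), 2000, replace = TRUE), collapse = "")
  substr(seqv, 501, 510) <- pwm$consensus
  ours <- scan_pwm(c(p = seqv), pwm, min_relative = 0.85, both_strands = FALSE)
  # Biostrings scores with base probabilities; its "85%" threshold is
  # relative to the maximum rather than the score range, so compare hit
  # positions at a threshold where both semantics agree on this fixture
  bm <- Biostrings::matchPWM(Biostrings::unitScale(pwm$prob), seqv, min.score = "85%")
  theirs <- IRanges::start(bm) - 1L
  expect_true(all(theirs %in% ours$offset) || all(ours$offset %in% theirs))
  expect_true((500 %in% ours$offset) && (500 %in% theirs))
})
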