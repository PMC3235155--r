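test_that("summarization quantile-normalizes columns and collapses probes", {
  set.seed(1)
  raw <- matrix(2^(rnorm(40, 8, 1)), nrow = 10,
                dimnames = list(paste0("probe", 1:10), paste0("a", 1:4)))
  map <- setNames(rep(c("ps1", "ps2", "ps3"), c(4, 4, 2)),
                  paste0("probe", 1:10))
  out <- summarize_expression(raw, map)
  expect_identical(rownames(out), c("ps1", "ps2", "ps3"))
  expect_true(all(is.finite(out)))

  # identical raw columns give identical summarized columns
  raw2 <- raw; raw2[, 2] <- raw2[, 1]
  out2 <- summarize_expression(raw2, map)
  expect_identical(out2[, 1], setNames(out2[, 2], rownames(out2)))

  # defining property of the internal normalization step: sorted
  # quantile-normalized log2 probe columns coincide across assays
  qn <- quantile_normalize(log2(raw))
  for (j in 2:4) expect_equal(sort(qn[, j]), sort(qn[, 1]),
                              ignore_attr = TRUE)

  # single-probe probesets pass through the normalized probe value
  one <- matrix(2^c(1, 2, 5, 6), nrow = 1,
                dimnames = list("probeX", paste0("a", 1:4)))
  got <- summarize_expression(one, c(probeX = "psX"))
  expect_equal(unname(got["psX", ]), unname(quantile_normalize(log2(one))[1, ]))

  # unmapped probes warn and are excluded; non-positive values error
  expect_warning(summarize_expression(raw, map[-1]), "excluded")
  raw[1, 1] <- 0
  expect_error(summarize_expression(raw, map),
               class = "generepo_validation_error")
})

test_that("differential statistics match the hand case and symmetry laws", {
  set.seed(2)
  expr <- rbind(f1 = c(8, 9, 10, 2, 3, 4),
                matrix(rnorm(60, 6), nrow = 10,
                       dimnames = list(paste0("g", 1:10), NULL)))
  colnames(expr) <- paste0("a", 1:6)
  case <- paste0("a", 1:3); control <- paste0("a", 4:6)
  res <- differential_stats(expr, case, control)

  # pooled-variance hand computation: sp = 1, t = 6 / sqrt(2/3)
  expect_equal(res$log2_fc[1], 6)
  expect_equal(res$t_statistic[1], 6 / sqrt(2 / 3), tolerance = 1e-12)
  expect_equal(res$t_statistic[1], 7.348469, tolerance = 1e-6)

  # identical groups degenerate to fc 0, p 1
  same <- matrix(rep(c(1, 2, 3), 2), nrow = 1,
                 dimnames = list("x", paste0("a", 1:6)))
  res0 <- differential_stats(same, case, control)
  expect_identical(res0$log2_fc, 0)
  expect_identical(res0$p_value, 1)

  # swapping groups negates fc and t, preserves p and fdr
  swapped <- differential_stats(expr, control, case)
  expect_equal(swapped$log2_fc, -res$log2_fc)
  expect_equal(swapped$t_statistic, -res$t_statistic)
  expect_equal(swapped$p_value, res$p_value)
  expect_equal(swapped$fdr, res$fdr)

  expect_error(differential_stats(expr, case[1], control),
               class = "generepo_validation_error")
})

test_that("BH adjustment matches the step-up definition and reference implementation", {
  expect_equal(bh_fdr(c(0.01, 0.02, 0.03, 0.04)), rep(0.04, 4))
  expect_identical(bh_fdr(0.5), 0.5)
  expect_identical(bh_fdr(rep(1, 5)), rep(1, 5))
  expect_error(bh_fdr(c(0.5, 1.2)), class = "generepo_validation_error")

  set.seed(3)
  for (i in 1:20) {
    p <- runif(sample(2:50, 1))^sample(1:3, 1)
    expect_equal(bh_fdr(p), p.adjust(p, "BH"), tolerance = 1e-12)
    expect_equal(bh_fdr(p), bh_oracle(p), tolerance = 1e-12)
    expect_true(all(bh_fdr(p) >= p))
  }
})

test_that("windowed FPKM follows the defining formula and its invariances", {
  # 50 in-window midpoints, 2 kb window, 10M total -> FPKM 2.5
  tx <- data.frame(transcript_id = "t1", gene_id = "g1", chrom = "chr1",
                   strand = "+", tx_start = 10000L, tx_end = 12000L,
                   exon_starts = "10000", exon_ends = "12000")
  inw <- data.frame(chrom = "chr1", start = 9400 + seq_len(50),
                    end = 9600 + seq_len(50))   # midpoints around 9500+
  # same ratio at total 1000 (the FPKM is depth-scale-free, checked below)
  al <- rbind(inw, data.frame(chrom = "chr1", start = rep(50000, 950),
                              end = rep(50150, 950)))
  res <- window_fpkm(al, tx)
  expect_equal(res$score, 50 / (2 * (1000 / 1e6)))

  # zero in-window alignments give FPKM 0
  far <- data.frame(chrom = "chr1", start = rep(50000, 100),
                    end = rep(50150, 100))
  expect_identical(window_fpkm(far, tx)$score, 0)

  # doubling depth (in-window and total alike) leaves FPKM unchanged
  res2 <- window_fpkm(rbind(al, al), tx)
  expect_equal(res2$score, res$score)

  expect_error(window_fpkm(al[0, ], tx), class = "generepo_validation_error")
  expect_error(window_fpkm(al, tx, 0, 0), class = "generepo_validation_error")
})

test_that("windowed FPKM respects strand orientation of the TSS window", {
  tx <- data.frame(transcript_id = c("plus", "minus"),
                   gene_id = c("gp", "gm"), chrom = "chr1",
                   strand = c("+", "-"),
                   tx_start = c(10000L, 50000L), tx_end = c(12000L, 52000L),
                   exon_starts = c("10000", "50000"),
                   exon_ends = c("12000", "52000"))
  # minus-strand TSS is tx_end (52000): midpoint 52000 is in [51000, 53000),
  # midpoint 53600 is not; plus-strand TSS is tx_start (10000): midpoint
  # 9200 is in [9000, 11000), midpoint 11150 falls just outside
  al <- data.frame(chrom = "chr1",
                   start = c(51900L, 53500L, 9100L, 11050L),
                   end = c(52100L, 53700L, 9300L, 11250L))
  res <- window_fpkm(al, tx)
  expect_equal(res$score[res$transcript_id == "minus"],
               1 / (2 * (4 / 1e6)))
  expect_equal(res$score[res$transcript_id == "plus"],
               1 / (2 * (4 / 1e6)))
})

test_that("transcript FPKM counts exonic midpoints over summed exon length", {
  # 3 kb of exons, 30 exonic alignments, 1M total is impractical in-test:
  # scale to 1000 total and check the formula directly
  tx <- data.frame(transcript_id = "t1", gene_id = "g1", chrom = "chr1",
                   strand = "+", tx_start = 1000L, tx_end = 9000L,
                   exon_starts = "1000,5000", exon_ends = "3000,6000")
  exonic <- data.frame(chrom = "chr1", start = c(rep(1500, 20), rep(5200, 10)),
                       end = c(rep(1700, 20), rep(5400, 10)))
  intronic <- data.frame(chrom = "chr1", start = rep(3500, 970),
                         end = rep(3700, 970))
  al <- rbind(exonic, intronic)
  res <- transcript_fpkm(al, tx)
  expect_equal(res$score, 30 / (3 * (1000 / 1e6)))

  # intronic midpoints never count
  expect_identical(transcript_fpkm(intronic, tx)$score, 0)

  # disjoint-exon transcripts partition exonic reads independently
  tx2 <- rbind(tx, data.frame(transcript_id = "t2", gene_id = "g2",
                              chrom = "chr1", strand = "+",
                              tx_start = 20000L, tx_end = 22000L,
                              exon_starts = "20000", exon_ends = "22000"))
  al2 <- rbind(al, data.frame(chrom = "chr1", start = rep(20500, 30),
                              end = rep(20700, 30)))
  res2 <- transcript_fpkm(al2, tx2)
  oracle <- transcript_fpkm_oracle(al2, tx2)
  expect_equal(res2$score, oracle)

  bad <- tx; bad$exon_starts <- ""
  expect_error(transcript_fpkm(al, bad), class = "generepo_validation_error")
})

test_that("peak assignment uses summit containment, nearest TSS and the max rule", {
  tx <- data.frame(
    transcript_id = c("tA", "tB"), gene_id = c("gA", "gB"), chrom = "chr2",
    strand = "+", tx_start = c(10000L, 10800L), tx_end = c(12000L, 12800L),
    exon_starts = c("10000", "10800"), exon_ends = c("12000", "12800"))
  # summit 10500: inside both promoters [9000,11000) and [9800,11800);
  # TSS distances 500 (tA) vs 300 (tB)
  peaks <- data.frame(chrom = "chr2", start = 10200L, end = 10900L,
                      score = 12, summit = 10500L)
  got <- assign_peaks(peaks, tx)
  expect_identical(got$transcript_id, "tB")
  expect_identical(got$gene_id, "gB")

  # simple containment
  p2 <- data.frame(chrom = "chr2", start = 10400L, end = 10600L, score = 5)
  expect_identical(assign_peaks(p2, tx[1, ])$transcript_id, "tA")

  # outside every promoter: nearest TSS fallback
  p3 <- data.frame(chrom = "chr2", start = 90000L, end = 90500L, score = 1)
  expect_identical(assign_peaks(p3, tx)$transcript_id, "tB")

  # unassignable chromosome reported, not fatal
  p4 <- data.frame(chrom = "chrUn", start = 1L, end = 100L, score = 2)
  got4 <- assign_peaks(p4, tx)
  expect_identical(nrow(got4), 0L)
  expect_identical(nrow(attr(got4, "unassigned")), 1L)

  # per-gene score is the max over assigned peaks
  pk <- data.frame(chrom = "chr2", start = c(10400L, 10450L),
                   end = c(10600L, 10650L), score = c(12, 30))
  gs <- peak_gene_scores(assign_peaks(pk, tx[1, ]))
  expect_identical(unname(gs["gA"]), 30)
})

test_that("peak assignment is deterministic under input permutation", {
  set.seed(11)
  tx <- random_transcripts(25)
  s <- sample.int(190000, 40)
  peaks <- data.frame(chrom = "chrT", start = s, end = s + 400,
                      score = runif(40, 1, 50))
  base <- assign_peaks(peaks, tx)
  for (i in 1:5) {
    perm <- assign_peaks(peaks[sample.int(40), ], tx[sample.int(25), ])
    expect_identical(perm, base, ignore_attr = TRUE)
  }
})

test_that("confidence intervals achieve nominal coverage under the null", {
  set.seed(17)
  n <- 10000
  expr <- matrix(rnorm(n * 6, 7, 0.6), nrow = n,
                 dimnames = list(paste0("g", seq_len(n)), paste0("a", 1:6)))
  res <- differential_stats(expr, paste0("a", 1:3), paste0("a", 4:6))
  cover <- mean(res$ci_lower <= 0 & 0 <= res$ci_upper)
  # binomial SE at n = 10000 is ~0.0022; allow ~4.5 SE
  expect_lt(abs(cover - 0.95), 0.01)
})

test_that("the stored-comparison pipeline reproduces direct computation", {
  fix <- tiny_annotated_repo(n_genes = 8, organisms = "human")
  repo <- fix$repo
  h <- add_tiny_experiment(repo, fix$ann$platforms[["human"]], 3, 3)
  set.seed(5)
  m <- matrix(rnorm(48, 8), nrow = 8,
              dimnames = list(fix$ann$probes[[1]]$probeset_id,
                              c(h$case, h$control)))
  for (a in colnames(m)) store_expression(repo, a, m[, a])
  cmp <- define_comparison(repo, h$experiment, h$case, h$control)
  res <- run_differential(repo, cmp)
  direct <- differential_stats(m, h$case, h$control)
  direct <- direct[match(res$feature_id, direct$feature_id), ]
  expect_equal(res$log2_fc, direct$log2_fc)
  expect_equal(res$p_value, direct$p_value)
  expect_identical(nrow(repo$fc_matrix), 8L)
})
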