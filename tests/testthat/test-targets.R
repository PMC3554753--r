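MIR <- "TGACAGAAGAGAGTGAGCACA"   # 21 nt, G/U available at many positions

test_that("duplex scoring counts mismatches as 1 and wobbles as 0.5", {
  perfect <- score_duplex(MIR, mirfill:::revcomp(MIR))
  expect_equal(perfect$total_score, 0)
  expect_true(all(perfect$states == "WC"))
  one_gu <- score_duplex(MIR, make_site(MIR, gu_at = 1))
  expect_equal(one_gu$total_score, 0.5)
  gu8 <- score_duplex(MIR, make_site(MIR, gu_at = c(1, 2, 6, 9, 11, 13, 15, 17)))
  expect_equal(gu8$total_score, 4.0)
  mixed <- score_duplex(MIR, make_site(MIR, mm_at = c(3, 15), gu_at = 6))
  expect_equal(mixed$total_score, 2.5)
  expect_error(score_duplex(MIR, "ACGT"), "equal length")
})

test_that("total_score is invariant under viewing the duplex from the other strand", {
  # swapping the strand roles keeps the physical base pairs (and hence the
  # weighted score); complementing both strands would not, because G:U
  # wobbles are not complement-symmetric
  set.seed(17)
  for (i in 1:20) {
    m <- paste(sample(c("A", "C", "G", "T"), 21, replace = TRUE), collapse = "")
    s <- paste(sample(c("A", "C", "G", "T"), 21, replace = TRUE), collapse = "")
    a <- score_duplex(m, s); b <- score_duplex(s, m)
    expect_equal(a$total_score, b$total_score)
    expect_equal(a$states, rev(b$states))
    expect_equal(a$mfe, b$mfe)
  }
})

test_that("the six rules reject and accept on their stated boundaries", {
  # mismatch at position 10 only: rule 4 fails, hit rejected
  f10 <- apply_target_rules(score_duplex(MIR, make_site(MIR, mm_at = 10)))
  expect_false(f10[["pos_10_11"]]); expect_false(f10[["pass"]])
  # G:U at position 11 is not a mismatch for the positional rule
  g11 <- apply_target_rules(score_duplex(MIR, make_site(MIR, gu_at = 11)))
  expect_true(g11[["pos_10_11"]])
  # adjacent mismatches at 13-14 (outside 2-12): seed rules hold, run of 2 ok
  f1314 <- apply_target_rules(score_duplex(MIR, make_site(MIR, mm_at = c(13, 14))))
  expect_true(f1314[["total_score"]] && f1314[["seed_adjacent"]] &&
                f1314[["pos_10_11"]] && f1314[["seed_score"]] &&
                f1314[["adjacent"]])
  # adjacent mismatches with both positions inside 2-12: rule 3 fails
  f56 <- apply_target_rules(score_duplex(MIR, make_site(MIR, mm_at = c(5, 6))))
  expect_false(f56[["seed_adjacent"]])
  # three consecutive mismatches anywhere: rule 2 fails
  f3run <- apply_target_rules(score_duplex(MIR, make_site(MIR, mm_at = 13:15)))
  expect_false(f3run[["adjacent"]])
  # seed weights above 2.5: rule 5 fails (3 mismatches in 1-12, spread out)
  fseed <- apply_target_rules(score_duplex(MIR, make_site(MIR, mm_at = c(2, 5, 8))))
  expect_false(fseed[["seed_score"]])
  # more than 4 weighted mismatches in total: rule 1 fails
  ftot <- apply_target_rules(score_duplex(
    MIR, make_site(MIR, mm_at = c(2, 5, 13, 15, 18))))
  expect_false(ftot[["total_score"]])
})

test_that("the duplex energy ratio implements the 75 % rule", {
  perfect <- score_duplex(MIR, mirfill:::revcomp(MIR))
  expect_equal(perfect$mfe / perfect$mfe_perfect, 1.0)
  expect_true(apply_target_rules(perfect)[["mfe_ratio"]])
  # an all-mismatch site has ~zero duplex energy
  all_mm <- score_duplex(MIR, make_site(MIR, mm_at = 1:21))
  expect_gte(all_mm$mfe, -1e-9)
  expect_false(apply_target_rules(all_mm)[["mfe_ratio"]])
  expect_equal(duplex_mfe(MIR, mirfill:::revcomp(MIR)), perfect$mfe)
})

test_that("converting a Watson-Crick pair to a mismatch never rescues a rejected site", {
  set.seed(23)
  for (i in 1:30) {
    mm0 <- sort(sample(1:21, sample(0:4, 1)))
    site <- make_site(MIR, mm_at = mm0)
    before <- apply_target_rules(score_duplex(MIR, site))[["pass"]]
    wc <- setdiff(1:21, mm0)
    extra <- sample(wc, 1)
    after <- apply_target_rules(score_duplex(
      MIR, make_site(MIR, mm_at = sort(c(mm0, extra)))))[["pass"]]
    if (!before) expect_false(after)
  }
})

test_that("transcriptome scanning equals brute-force window evaluation", {
  set.seed(41)
  txs <- setNames(lapply(1:3, function(i)
    paste(sample(c("A", "C", "G", "T"), 400, replace = TRUE), collapse = "")),
    paste0("tx", 1:3))
  # plant a perfect site and a 13-14 double mismatch site
  txs$tx1 <- paste0(substr(txs$tx1, 1, 100), mirfill:::revcomp(MIR),
                    substr(txs$tx1, 122, 400))
  txs$tx2 <- paste0(substr(txs$tx2, 1, 50), make_site(MIR, mm_at = c(13, 14)),
                    substr(txs$tx2, 72, 400))
  txs <- vapply(txs, identity, character(1))
  hits <- scan_transcriptome(c(mir1 = MIR), txs)
  expect_true(any(hits$transcript == "tx1" & hits$start == 100))
  expect_true(any(hits$transcript == "tx2" & hits$start == 50))
  # brute force over every window
  brute <- list()
  for (tid in names(txs)) {
    n <- nchar(txs[[tid]])
    for (pos in seq_len(n - 21 + 1)) {
      site <- substr(txs[[tid]], pos, pos + 20)
      if (apply_target_rules(score_duplex(MIR, site))[["pass"]]) {
        brute[[length(brute) + 1]] <- data.frame(transcript = tid,
                                                 start = pos - 1L)
      }
    }
  }
  brute <- do.call(rbind, brute)
  expect_equal(hits[, c("transcript", "start")],
               brute[order(brute$transcript, brute$start), ],
               ignore_attr = TRUE)
  expect_false(any(duplicated(hits[, c("mirna", "transcript", "start")])))
})

test_that("planted sites in the simulated transcriptome are all recovered", {
  w <- shared_world()
  dge <- simulate_dge(w$sim$truth, w$cfg)
  pm <- w$sim$truth$planted_mirnas
  mirnas <- setNames(pm$mature, pm$id)
  hits <- scan_transcriptome(mirnas, dge$transcripts)
  for (i in seq_len(nrow(dge$pairs))) {
    expect_true(any(hits$mirna == dge$pairs$mirna[i] &
                      hits$transcript == dge$pairs$gene[i] &
                      hits$start == dge$pairs$site_start[i]))
  }
})

test_that("duplex rendering marks WC bars and G:U colons", {
  lines <- render_duplex(score_duplex(MIR, make_site(MIR, gu_at = 1)))
  expect_length(lines, 3)
  bars <- strsplit(sub("^ {10}", "", lines[2]), "")[[1]]
  expect_equal(bars[1], ":")
  expect_true(all(bars[-1] == "|"))
})
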