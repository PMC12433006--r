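cfg0 <- prediction_config()

test_that("classify_cpg_status applies the three eligibility criteria", {
  site <- data.frame(group = rep(c("control", "tumor"), each = 3),
                     depth = 20,
                     meth_pct = c(2, 5, 0, 90, 88, 92))
  expect_equal(classify_cpg_status(site, cfg0), "eligible")

  hot <- site; hot$meth_pct[2] <- 15     # > maxMethControl 10
  expect_equal(classify_cpg_status(hot, cfg0), "control_methylated")

  cold <- site; cold$meth_pct[4:6] <- 30 # all tumors < 50
  expect_equal(classify_cpg_status(cold, cfg0), "tumor_unmethylated")

  thin <- site; thin$depth[5] <- 3       # < min_site_depth 5
  expect_equal(classify_cpg_status(thin, cfg0), "low_depth")

  expect_error(classify_cpg_status(site[site$group == "tumor", ], cfg0),
               "control")
})

test_that("find_primer_sites reports maximal CpG windows exactly once", {
  s <- find_primer_sites(c(110, 115, 120), cfg0, chrom = "c")
  expect_equal(nrow(s), 1L)
  expect_true(s$start <= 110 && s$end >= 122)
  expect_true(s$end - s$start >= 18 && s$end - s$start <= 24)
  expect_equal(s$n_cpgs, 3L)

  expect_equal(nrow(find_primer_sites(c(110, 150), cfg0)), 0L)
  expect_equal(nrow(find_primer_sites(c(110, 115, 140), cfg0)), 0L)
  expect_equal(nrow(find_primer_sites(numeric(0), cfg0)), 0L)
})

test_that("find_primer_sites equals the brute-force window oracle", {
  withr::local_seed(42)
  for (rep in 1:25) {
    pos <- sort(sample(seq(0, 600, by = 2), sample(5:30, 1)))
    got <- find_primer_sites(pos, cfg0)
    want <- oracle_primer_sites(pos, cfg0)
    expect_equal(got[c("start", "end", "cpgs")],
                 want[c("start", "end", "cpgs")],
                 ignore_attr = TRUE)
  }
})

test_that("pair_sites_to_regions applies outer-span amplicon bounds", {
  mk <- function(s, e) data.frame(chrom = "c", start = s, end = e,
                                  n_cpgs = 3L,
                                  cpgs = paste(s, s + 6, s + 12, sep = ","),
                                  stringsAsFactors = FALSE)
  one <- pair_sites_to_regions(rbind(mk(100, 120), mk(150, 172)), cfg0)
  expect_equal(nrow(one), 1L)
  expect_equal(one$end - one$start, 72)

  expect_equal(nrow(pair_sites_to_regions(rbind(mk(100, 120), mk(130, 150)),
                                          cfg0)), 0L)  # span 50 < 60
  expect_equal(nrow(pair_sites_to_regions(rbind(mk(100, 120), mk(550, 572)),
                                          cfg0)), 0L)  # span 472 > 400
})

test_that("score is tumor meth-fraction times depth, summed", {
  regions <- data.frame(chrom = "c", start = 100, end = 180,
                        fwd_start = 100, fwd_end = 120,
                        rev_start = 160, rev_end = 180,
                        fwd_cpgs = "100,106,112", rev_cpgs = "160,166,172",
                        score = NA_real_, stringsAsFactors = FALSE)
  cpgs <- c(100, 106, 112, 160, 166, 172)
  manifest <- data.frame(sample_id = c("t1", "t2", "t3", "c1"),
                         group = c("tumor", "tumor", "tumor", "control"))
  records <- do.call(rbind, lapply(manifest$sample_id, function(id)
    make_records(cpgs, 20, 90, chrom = "c", sample_id = id)))
  out <- score_msp_regions(regions, records, manifest)
  expect_equal(out$score, 6 * 3 * 0.9 * 20)  # 324; controls don't count

  zero <- score_msp_regions(
    regions, transform(records, meth_pct = 0), manifest)
  expect_equal(zero$score, 0)

  dbl <- score_msp_regions(
    regions, transform(records, depth = depth * 2), manifest)
  expect_equal(dbl$score, 2 * out$score)  # linear in depth

  expect_error(
    score_msp_regions(regions, records[records$pos != 166, ], manifest),
    "missing tumor measurement at c:166")
})

test_that("cluster_and_select is greedy by score with overlap suppression", {
  reg <- function(s, e, score)
    data.frame(chrom = "c", start = s, end = e, fwd_start = s,
               fwd_end = s + 20, rev_start = e - 20, rev_end = e,
               fwd_cpgs = "", rev_cpgs = "", score = score,
               stringsAsFactors = FALSE)
  abc <- rbind(reg(0, 200, 9000), reg(100, 300, 7000), reg(500, 700, 6500))
  out <- cluster_and_select(abc, 0)
  expect_equal(out$score, c(9000, 6500))  # B suppressed by A

  expect_equal(nrow(cluster_and_select(abc, 10000)), 0L)

  disjoint <- rbind(reg(0, 100, 5000), reg(200, 300, 5000))
  expect_equal(nrow(cluster_and_select(disjoint, 0)), 2L)
})

test_that("predict_msp_regions finds planted DM islands only", {
  dir <- withr::local_tempdir()
  # DM island: 24 CpGs spaced 6 nt; non-DM island: same shape but
  # control-methylated
  dm_pos <- 1000 + seq(0, by = 6, length.out = 24)
  bg_pos <- 5000 + seq(0, by = 6, length.out = 24)
  man <- write_dm_fixture(dir, c(dm_pos, bg_pos),
                          eligible = rep(c(TRUE, FALSE), each = 24))
  islands <- data.frame(chrom = "chrT", start = c(1000, 5000),
                        end = c(1200, 5200), name = c("dm", "bg"),
                        strand = ".")
  pred <- predict_msp_regions(man, cfg0, islands = islands)
  expect_gt(nrow(pred$regions), 0)
  expect_true(all(pred$regions$start >= 1000 & pred$regions$end <= 1200))
  expect_equal(pred$report$island_overlap_fraction, 1.0)
  expect_true(validate_msp_regions(pred$regions,
                                   aggregate_cpg_strands(do.call(rbind,
                                     lapply(seq_len(nrow(man)), function(i)
                                       read_bedmethyl(man$path[i],
                                         sample_id = man$sample_id[i])))),
                                   man, cfg0))

  all_control <- man; all_control$group <- "control"
  expect_error(predict_msp_regions(all_control, cfg0), "tumor")
})

test_that("pre-clustering pipeline equals brute-force enumeration", {
  withr::local_seed(7)
  for (rep in 1:10) {
    dir <- withr::local_tempdir()
    pos <- sort(sample(seq(0, 3000, by = 2), sample(10:40, 1)))
    eligible <- runif(length(pos)) < 0.7
    man <- write_dm_fixture(dir, pos, eligible)
    pred <- predict_msp_regions(man, cfg0, select = FALSE)
    want <- oracle_regions(pos[eligible], cfg0)
    got <- pred$candidates[order(pred$candidates$fwd_start,
                                 pred$candidates$rev_start),
                           c("fwd_start", "fwd_end", "rev_start", "rev_end")]
    expect_equal(got, want, ignore_attr = TRUE)
  }
})

test_that("tightening thresholds never yields more regions", {
  dir <- withr::local_tempdir()
  withr::local_seed(3)
  pos <- sort(sample(seq(0, 2000, by = 2), 40))
  man <- write_dm_fixture(dir, pos, eligible = runif(40) < 0.8)
  base <- predict_msp_regions(man, cfg0, select = FALSE)
  stricter_cpgs <- predict_msp_regions(
    man, prediction_config(min_cpgs = 4), select = FALSE)
  stricter_ctrl <- predict_msp_regions(
    man, prediction_config(max_meth_control = 1), select = FALSE)
  expect_lte(nrow(stricter_cpgs$candidates), nrow(base$candidates))
  expect_lte(nrow(stricter_ctrl$candidates), nrow(base$candidates))
})
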